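# Multitask segment classifier: subjectivity (3-way), clinical role (9-way)
# and probable (binary) heads over a shared encoder, trained with the
# weighted-sum cross-entropy loss
#
#   L_all = lambda_sub * L_sub + lambda_role * L_role + lambda_prob * L_prob
#
# where the lambdas are nonnegative and sum to 1. Only the encoder's
# trainable tail and the three task heads receive gradients; the encoder
# body is frozen, mirroring fine-tuning of a pretrained encoder on its
# final layer only.
#
# The default encoder is deterministic and self-contained: hashed
# character n-gram counts, L2-normalized and scaled. The large feature
# scale is deliberate — the training protocol fixes a very small Adam step
# (1e-5 over ~1.5k steps), tuned for large pretrained networks, so the
# stand-in encoder must place class-discriminative mass where tiny weight
# increments translate into decisive logits.

.SUB_CLASSES <- c("low", "middle", "high")

#' Default deterministic encoder
#'
#' Frozen body: character n-grams (default orders 2-4) hashed into
#' `dim` count buckets, L2-normalized, then multiplied by `scale`.
#' Trainable tail: a linear layer initialized to the identity. No
#' pretrained weights are needed; any object with the same contract
#' (`$encode(texts)` returning a fixed-dimension matrix, `$init_tail()`)
#' may be substituted, e.g. a transformer encoder.
#'
#' @param dim Output dimension (default 256).
#' @param scale L2 norm given to each feature vector (default 5000; see
#'   the package vignette for why this is large).
#' @param ngrams Integer vector of character n-gram orders.
#' @return A `ds_encoder` object.
#' @export
default_encoder <- function(dim = 256L, scale = 5000, ngrams = 2:4) {
  dim <- as.integer(dim)
  enc <- list(name = "hashed_char_ngram", dim = dim, scale = scale,
              ngrams = ngrams)
  enc$encode <- function(texts) {
    X <- matrix(0, length(texts), dim)
    for (i in seq_along(texts)) {
      ch <- strsplit(texts[[i]], "", fixed = FALSE)[[1]]
      n <- length(ch)
      grams <- character(0)
      for (g in ngrams) {
        if (n >= g) {
          grams <- c(grams, vapply(seq_len(n - g + 1L), function(s) {
            paste(ch[s:(s + g - 1L)], collapse = "")
          }, character(1)))
        }
      }
      if (!length(grams)) next
      h <- vapply(grams, function(g) {
        cp <- utf8ToInt(g)
        sum(cp * 7 * 31^(seq_along(cp) - 1))
      }, numeric(1))
      idx <- (h %% dim) + 1
      for (j in seq_along(idx)) X[i, idx[j]] <- X[i, idx[j]] + 1
    }
    X / pmax(sqrt(rowSums(X^2)), 1e-8) * scale
  }
  enc$init_tail <- function() list(Wt = diag(dim), bt = rep(0, dim))
  structure(enc, class = "ds_encoder")
}

#' Task weights of the multitask loss
#'
#' @param sub,role,prob Nonnegative weights; must sum to 1 within 1e-9
#'   unless `normalize = TRUE`.
#' @param normalize Divide by the sum first.
#' @return Named numeric vector of class `ds_task_weights`.
#' @export
#' @examples
#' task_weights(0.5, 0.25, 0.25)
task_weights <- function(sub, role, prob, normalize = FALSE) {
  w <- c(sub = sub, role = role, prob = prob)
  if (any(w < 0)) stop("task weights must be nonnegative")
  if (normalize) w <- w / sum(w)
  if (abs(sum(w) - 1) > 1e-9) stop("task weights must sum to 1")
  structure(w, class = "ds_task_weights")
}

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate 1e-5,
#' 20 epochs, batch size 32, 300 held-out samples each for development and
#' test, results averaged over 3 seeds, three-layer perceptron heads
#' (two ReLU hidden layers of encoder width plus a softmax output layer).
#'
#' @param epochs,learning_rate,batch_size Optimization protocol.
#' @param n_heldout Samples drawn for the dev set and again for the test set.
#' @param n_seeds Seeds averaged over in [grid_search()].
#' @param seed Base RNG seed.
#' @param head_hidden_layers Total layers per head (hidden + output).
#' @param adam_beta1,adam_beta2,adam_eps Adam moment hyperparameters
#'   (conventional defaults).
#' @return A list of class `ds_train_config`.
#' @export
train_config <- function(epochs = 20L, learning_rate = 1e-5, batch_size = 32L,
                         n_heldout = 300L, n_seeds = 3L, seed = 1L,
                         head_hidden_layers = 3L,
                         adam_beta1 = 0.9, adam_beta2 = 0.999, adam_eps = 1e-8) {
  stopifnot(epochs >= 0L, learning_rate > 0, batch_size >= 1L,
            n_heldout >= 0L, n_seeds >= 1L, head_hidden_layers >= 1L)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 n_heldout = as.integer(n_heldout),
                 n_seeds = as.integer(n_seeds), seed = as.integer(seed),
                 head_hidden_layers = as.integer(head_hidden_layers),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps),
            class = "ds_train_config")
}

# ---- labeled-data plumbing ---------------------------------------------

#' Flatten labeled summary segments into a training frame
#'
#' Accepts a corpus (list of cases), a list of segments, or a data frame
#' already holding `text`, `subjectivity`, `role`, `probable`.
#'
#' @param x Corpus, segment list or data frame.
#' @return Data frame with columns `segment_id`, `text`, `subjectivity`,
#'   `role`, `probable`.
#' @export
segments_frame <- function(x) {
  if (is.data.frame(x)) {
    need <- c("text", "subjectivity", "role", "probable")
    miss <- setdiff(need, names(x))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
    if (is.null(x$segment_id)) x$segment_id <- sprintf("seg-%d", seq_len(nrow(x)))
    return(x[, c("segment_id", need)])
  }
  segs <- if (length(x) && inherits(x[[1]], "ds_case")) {
    unlist(lapply(x, function(case) {
      Filter(function(s) s$doc_kind == "discharge_summary", case$segments)
    }), recursive = FALSE)
  } else {
    x
  }
  rows <- lapply(segs, function(s) {
    if (is.null(s$gold_labels)) {
      stop("segment ", s$segment_id, " is missing gold labels")
    }
    data.frame(segment_id = s$segment_id, text = s$text,
               subjectivity = s$gold_labels$subjectivity,
               role = s$gold_labels$role, probable = s$gold_labels$probable,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

encode_targets <- function(df) {
  list(sub = match(df$subjectivity, .SUB_CLASSES),
       role = match(df$role, clinical_roles()),
       prob = as.integer(df$probable) + 1L)
}

# ---- numerics -----------------------------------------------------------

softmax_ce <- function(Z, y) {
  Z <- Z - apply(Z, 1, max)
  P <- exp(Z)
  P <- P / rowSums(P)
  ii <- cbind(seq_len(nrow(Z)), y)
  loss <- -mean(log(pmax(P[ii], 1e-12)))
  G <- P
  G[ii] <- G[ii] - 1
  list(loss = loss, grad = G / nrow(Z))
}

# ReLU hidden layers initialized to the identity: with nonnegative count
# features the head starts as a linear softmax on interpretable n-gram
# coordinates, which the protocol's very small Adam steps can shape
# effectively; the layers are free to leave the identity during training.
new_head <- function(d, k_out, n_layers) {
  h <- list()
  for (l in seq_len(n_layers - 1L)) {
    h[[paste0("W", l)]] <- diag(d)
    h[[paste0("b", l)]] <- rep(0, d)
  }
  h[[paste0("W", n_layers)]] <- matrix(0, d, k_out)  # zero logits at init
  h[[paste0("b", n_layers)]] <- rep(0, k_out)
  h
}

head_forward <- function(head, X, n_layers) {
  acts <- vector("list", n_layers)
  A <- X
  for (l in seq_len(n_layers - 1L)) {
    A <- pmax(sweep(A %*% head[[paste0("W", l)]], 2, head[[paste0("b", l)]], "+"), 0)
    acts[[l]] <- A
  }
  Z <- sweep(A %*% head[[paste0("W", n_layers)]], 2, head[[paste0("b", n_layers)]], "+")
  list(acts = acts, Z = Z)
}

head_backward <- function(head, X, fwd, G, n_layers) {
  g <- list()
  A_prev <- if (n_layers > 1L) fwd$acts[[n_layers - 1L]] else X
  g[[paste0("W", n_layers)]] <- crossprod(A_prev, G)
  g[[paste0("b", n_layers)]] <- colSums(G)
  dA <- G %*% t(head[[paste0("W", n_layers)]])
  for (l in rev(seq_len(n_layers - 1L))) {
    dA <- dA * (fwd$acts[[l]] > 0)
    A_prev <- if (l > 1L) fwd$acts[[l - 1L]] else X
    g[[paste0("W", l)]] <- crossprod(A_prev, dA)
    g[[paste0("b", l)]] <- colSums(dA)
    dA <- dA %*% t(head[[paste0("W", l)]])
  }
  list(grads = g, dX = dA)
}

adam_step <- function(P, M, V, G, t, cfg) {
  b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2; eps <- cfg$adam_eps
  lr <- cfg$learning_rate
  upd <- function(p, m, v, g) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    list(p = p - lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps),
         m = m, v = v)
  }
  for (k1 in names(G)) {
    if (is.list(G[[k1]])) {
      for (k2 in names(G[[k1]])) {
        r <- upd(P[[k1]][[k2]], M[[k1]][[k2]], V[[k1]][[k2]], G[[k1]][[k2]])
        P[[k1]][[k2]] <- r$p; M[[k1]][[k2]] <- r$m; V[[k1]][[k2]] <- r$v
      }
    } else {
      r <- upd(P[[k1]], M[[k1]], V[[k1]], G[[k1]])
      P[[k1]] <- r$p; M[[k1]] <- r$m; V[[k1]] <- r$v
    }
  }
  list(P = P, M = M, V = V)
}

#' Multitask weighted-sum loss
#'
#' Per-task mean cross-entropy over a batch plus their weighted sum.
#'
#' @param head_outputs List with score matrices `sub` (n x 3), `role`
#'   (n x 9), `prob` (n x 2).
#' @param gold List with integer class indices `sub`, `role`, `prob`
#'   (1-based), aligned with the rows.
#' @param w A [task_weights()].
#' @return List `L_sub`, `L_role`, `L_prob`, `L_all`.
#' @export
compute_loss <- function(head_outputs, gold, w) {
  dims <- c(sub = 3L, role = 9L, prob = 2L)
  for (task in names(dims)) {
    Z <- head_outputs[[task]]
    if (is.null(Z) || ncol(Z) != dims[[task]]) {
      stop(sprintf("head '%s' must have %d columns", task, dims[[task]]))
    }
    if (nrow(Z) != length(gold[[task]])) {
      stop(sprintf("head '%s': %d rows but %d gold labels",
                   task, nrow(Z), length(gold[[task]])))
    }
  }
  L_sub <- softmax_ce(head_outputs$sub, gold$sub)$loss
  L_role <- softmax_ce(head_outputs$role, gold$role)$loss
  L_prob <- softmax_ce(head_outputs$prob, gold$prob)$loss
  list(L_sub = L_sub, L_role = L_role, L_prob = L_prob,
       L_all = unname(w[["sub"]] * L_sub + w[["role"]] * L_role +
                        w[["prob"]] * L_prob))
}

forward_all <- function(P, X, n_layers) {
  E <- sweep(X %*% P$tail$Wt, 2, P$tail$bt, "+")
  list(E = E,
       sub = head_forward(P$sub, E, n_layers),
       role = head_forward(P$role, E, n_layers),
       prob = head_forward(P$prob, E, n_layers))
}

init_params <- function(encoder, n_layers) {
  d <- encoder$dim
  list(tail = encoder$init_tail(),
       sub = new_head(d, 3L, n_layers),
       role = new_head(d, 9L, n_layers),
       prob = new_head(d, 2L, n_layers))
}

#' Train the multitask classifier
#'
#' Splits the data into dev/test (`n_heldout` each, seeded sampling) and
#' training remainder, then optimizes tail + heads with Adam on the
#' weighted-sum loss. Identical seed, data and config give an identical
#' loss trace and parameters.
#'
#' @param data Labeled data accepted by [segments_frame()].
#' @param encoder A `ds_encoder` (default [default_encoder()]).
#' @param w A [task_weights()].
#' @param cfg A [train_config()]; `cfg$seed` drives the split, head
#'   initialization and batch shuffling.
#' @return A `ds_model`: parameters, per-epoch loss trace (`$trace`),
#'   split indices (`$split`), and the configuration used.
#' @export
train <- function(data, encoder = default_encoder(),
                  w = task_weights(1 / 3, 1 / 3, 1 / 3), cfg = train_config()) {
  df <- segments_frame(data)
  if (anyNA(df$subjectivity) || anyNA(df$role) || anyNA(df$probable)) {
    stop("every segment needs all three gold labels")
  }
  y <- encode_targets(df)
  if (anyNA(y$sub) || anyNA(y$role)) stop("unknown label value in data")
  n <- nrow(df)
  if (2L * cfg$n_heldout >= n) stop("n_heldout too large for dataset")
  X <- encoder$encode(df$text)
  nl <- cfg$head_hidden_layers

  with_seed(cfg$seed, {
    perm <- sample.int(n)
    dev <- perm[seq_len(cfg$n_heldout)]
    tst <- perm[cfg$n_heldout + seq_len(cfg$n_heldout)]
    trn <- perm[-seq_len(2L * cfg$n_heldout)]
    P <- init_params(encoder, nl)
    M <- rapply(P, function(a) a * 0, how = "replace")
    V <- M
    t <- 0L
    trace <- data.frame(epoch = integer(0), L_sub = numeric(0),
                        L_role = numeric(0), L_prob = numeric(0),
                        L_all = numeric(0))
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(trn)
      ep_loss <- c(L_sub = 0, L_role = 0, L_prob = 0, L_all = 0)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      for (b in batches) {
        Xb <- X[b, , drop = FALSE]
        fwd <- forward_all(P, Xb, nl)
        cs <- softmax_ce(fwd$sub$Z, y$sub[b])
        cr <- softmax_ce(fwd$role$Z, y$role[b])
        cp <- softmax_ce(fwd$prob$Z, y$prob[b])
        bs <- head_backward(P$sub, fwd$E, fwd$sub, cs$grad * w[["sub"]], nl)
        br <- head_backward(P$role, fwd$E, fwd$role, cr$grad * w[["role"]], nl)
        bp <- head_backward(P$prob, fwd$E, fwd$prob, cp$grad * w[["prob"]], nl)
        dE <- bs$dX + br$dX + bp$dX
        G <- list(tail = list(Wt = crossprod(Xb, dE), bt = colSums(dE)),
                  sub = bs$grads, role = br$grads, prob = bp$grads)
        t <- t + 1L
        st <- adam_step(P, M, V, G, t, cfg)
        P <- st$P; M <- st$M; V <- st$V
        L_all <- w[["sub"]] * cs$loss + w[["role"]] * cr$loss + w[["prob"]] * cp$loss
        ep_loss <- ep_loss + c(cs$loss, cr$loss, cp$loss, L_all) * length(b)
      }
      ep_loss <- ep_loss / length(trn)
      trace <- rbind(trace, data.frame(epoch = ep, L_sub = ep_loss[[1]],
                                       L_role = ep_loss[[2]],
                                       L_prob = ep_loss[[3]],
                                       L_all = ep_loss[[4]]))
    }
    structure(list(params = P, trace = trace,
                   split = list(train = trn, dev = dev, test = tst),
                   encoder = encoder, w = w, cfg = cfg,
                   data_ids = df$segment_id),
              class = "ds_model")
  })
}

#' @export
print.ds_model <- function(x, ...) {
  cat(sprintf("<ds_model> encoder %s (d=%d), weights (%.2f, %.2f, %.2f), %d epoch(s)\n",
              x$encoder$name, x$encoder$dim, x$w[["sub"]], x$w[["role"]],
              x$w[["prob"]], nrow(x$trace)))
  invisible(x)
}

#' Predict labels for segments
#'
#' Arg-max per task; deterministic for fixed parameters. The returned
#' `subjectivity` is the head's own prediction; aggregation applies the
#' probable-implies-high override via [effective_subjectivity()].
#'
#' @param object A `ds_model`.
#' @param segments Character vector of texts, a corpus, a segment list, or
#'   a data frame with a `text` column.
#' @param ... Unused.
#' @return Data frame with `segment_id` (when available), `subjectivity`,
#'   `role`, `probable`.
#' @export
predict.ds_model <- function(object, segments, ...) {
  if (is.character(segments)) {
    df <- data.frame(segment_id = sprintf("seg-%d", seq_along(segments)),
                     text = segments, stringsAsFactors = FALSE)
  } else if (is.data.frame(segments)) {
    df <- segments
    if (is.null(df$segment_id)) df$segment_id <- sprintf("seg-%d", seq_len(nrow(df)))
  } else {
    segs <- if (length(segments) && inherits(segments[[1]], "ds_case")) {
      unlist(lapply(segments, function(case) {
        Filter(function(s) s$doc_kind == "discharge_summary", case$segments)
      }), recursive = FALSE)
    } else {
      segments
    }
    df <- data.frame(segment_id = vapply(segs, function(s) s$segment_id, character(1)),
                     text = vapply(segs, function(s) s$text, character(1)),
                     stringsAsFactors = FALSE)
  }
  X <- object$encoder$encode(df$text)
  fwd <- forward_all(object$params, X, object$cfg$head_hidden_layers)
  data.frame(segment_id = df$segment_id,
             subjectivity = .SUB_CLASSES[max.col(fwd$sub$Z, ties.method = "first")],
             role = clinical_roles()[max.col(fwd$role$Z, ties.method = "first")],
             probable = max.col(fwd$prob$Z, ties.method = "first") == 2L,
             stringsAsFactors = FALSE)
}

#' The quarter-step weight grid
#'
#' All 15 nonnegative quarter-step triples summing to 1, plus the uniform
#' triple (1/3, 1/3, 1/3): 16 settings.
#'
#' @return Data frame with columns `lambda_sub`, `lambda_role`, `lambda_prob`.
#' @export
quarter_step_grid <- function() {
  rows <- list()
  for (a in 0:4) for (b in 0:(4 - a)) {
    rows[[length(rows) + 1L]] <- c(a, b, 4 - a - b) / 4
  }
  g <- do.call(rbind, rows)
  g <- rbind(g, c(1, 1, 1) / 3)
  g <- g[order(-g[, 1], -g[, 2], -g[, 3]), ]
  data.frame(lambda_sub = g[, 1], lambda_role = g[, 2], lambda_prob = g[, 3])
}

dev_macro_f1 <- function(model, df, y) {
  idx <- model$split$dev
  X <- model$encoder$encode(df$text[idx])
  fwd <- forward_all(model$params, X, model$cfg$head_hidden_layers)
  pred <- list(sub = max.col(fwd$sub$Z, ties.method = "first"),
               role = max.col(fwd$role$Z, ties.method = "first"),
               prob = max.col(fwd$prob$Z, ties.method = "first"))
  c(F1_sub = macro_f1_int(pred$sub, y$sub[idx], 3L),
    F1_role = macro_f1_int(pred$role, y$role[idx], 9L),
    F1_prob = macro_f1_int(pred$prob, y$prob[idx], 2L))
}

#' Grid search over task weights
#'
#' Trains one model per weight setting of [quarter_step_grid()] (per
#' seed), reporting development-set macro F1 per task averaged over
#' `cfg$n_seeds` runs.
#'
#' @param data Labeled data accepted by [segments_frame()].
#' @param encoder A `ds_encoder`.
#' @param cfg A [train_config()]; seeds used are `cfg$seed + 0:(n_seeds-1)`.
#' @param grid Data frame of weight settings; default the 16-point grid.
#' @return `grid` with `F1_sub`, `F1_role`, `F1_prob` columns appended.
#' @export
grid_search <- function(data, encoder = default_encoder(), cfg = train_config(),
                        grid = quarter_step_grid()) {
  df <- segments_frame(data)
  y <- encode_targets(df)
  out <- grid
  out$F1_sub <- out$F1_role <- out$F1_prob <- NA_real_
  for (i in seq_len(nrow(grid))) {
    w <- task_weights(grid$lambda_sub[i], grid$lambda_role[i],
                      grid$lambda_prob[i], normalize = TRUE)
    f1 <- matrix(0, cfg$n_seeds, 3)
    for (s in seq_len(cfg$n_seeds)) {
      cfg_s <- cfg
      cfg_s$seed <- cfg$seed + s - 1L
      model <- train(df, encoder, w, cfg_s)
      f1[s, ] <- dev_macro_f1(model, df, y)
    }
    out$F1_sub[i] <- mean(f1[, 1])
    out$F1_role[i] <- mean(f1[, 2])
    out$F1_prob[i] <- mean(f1[, 3])
  }
  out
}
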