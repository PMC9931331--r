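# Word tokenization.
#
# The audit needs "word" bi-grams for both whitespace-delimited text and
# unsegmented Japanese. The default tokenizer splits on whitespace and on
# changes of script class (Latin, digit, hiragana, katakana, han), dropping
# punctuation; it is deterministic and can be replaced by any function with
# the same signature (e.g. a morphological analyzer) wherever a tokenizer
# argument is accepted.

.SCRIPT_CLASSES <- c(latin = "[A-Za-z]",
                     digit = "[0-9]",
                     hira  = "\\p{Hiragana}",
                     kata  = "\\p{Katakana}",
                     han   = "\\p{Han}")

tokenize_one <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  ch <- strsplit(text, "", fixed = FALSE)[[1]]
  cls <- rep("other", length(ch))
  for (nm in names(.SCRIPT_CLASSES)) {
    hit <- grepl(.SCRIPT_CLASSES[[nm]], ch, perl = TRUE)
    cls[hit & cls == "other"] <- nm
  }
  cls[grepl("\\s", ch, perl = TRUE)] <- "drop"
  cls[cls == "other"] <- "drop"  # punctuation and symbols are not words
  r <- rle(cls)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values != "drop"
  if (!any(keep)) return(character(0))
  vapply(which(keep), function(i) paste(ch[starts[i]:ends[i]], collapse = ""),
         character(1))
}

#' Default word tokenizer
#'
#' @return `function(text) -> character vector` of word tokens. Empty
#'   strings tokenize to an empty vector.
#' @export
#' @examples
#' default_tokenizer()("renal abscess 2020")
default_tokenizer <- function() {
  function(text) tokenize_one(text)
}
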