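#' Evaluate an expression with a temporary RNG seed
#'
#' All stochastic operations in the package funnel their randomness through
#' this helper so that a caller-supplied integer seed fully determines the
#' output without disturbing the session RNG state.
#'
#' @param seed Integer scalar.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# derive a deterministic sub-seed for a named substream, kept below 2^31
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

BASES <- c("A", "C", "G", "T")

# collapse a character vector of bases to a string and back
seq_to_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
chars_to_seq <- function(x) paste(x, collapse = "")

assert_seq <- function(x, what = "sequence", allow_n = TRUE) {
  if (!is.character(x) || length(x) != 1L || !nzchar(x))
    stop(what, " must be a non-empty character scalar", call. = FALSE)
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  if (!grepl(pat, x))
    stop(what, " contains characters outside {A,C,G,T",
         if (allow_n) ",N", "}", call. = FALSE)
  invisible(x)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, na.strings = ".",
             stringsAsFactors = FALSE)
}
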