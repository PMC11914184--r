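## Internal helpers shared across modules.

# Fixed per-stream offsets so adding a generator never shifts the draws of
# another. All derived seeds stay below 2^31 - 1.
.stream_offsets <- c(
  calls    = 101L,
  reads    = 211L,
  telomere = 307L,
  catalog  = 401L,
  tree     = 503L,
  sv       = 601L,
  cn       = 701L,
  msi      = 809L
)

stream_seed <- function(seed, stream) {
  offset <- .stream_offsets[[stream]]
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

with_stream <- function(seed, stream, code) {
  withr::with_seed(stream_seed(seed, stream), code)
}

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x <= 1)
}

#' Write a data frame as a plain TSV
#'
#' Thin wrapper used by all pipeline writers so every table on disk shares
#' the same conventions (tab separated, no quoting, no row names).
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain TSV written by [write_tsv()]
#'
#' @param path input path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
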