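# Internal helpers shared across modules.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
DNA4 <- c("A", "C", "G", "T")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write a data frame as plain TSV
#'
#' Tab-separated, no quoting, no row names; the on-disk dialect used for every
#' persisted pipeline intermediate so stages are diffable and independently
#' re-runnable.
#'
#' @param x data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain TSV into a data frame
#'
#' @param path file path; lines starting with `#` are treated as comments.
#' @return data frame with character columns left as-is.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_fraction <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stopf("%s must lie in [0, 1]", what)
  }
  invisible(x)
}

# Deterministic string hash -> u in (0, 1). Polynomial rolling hash modulo the
# Mersenne prime 2^31 - 1 with two multiplicative scrambling rounds; all
# arithmetic stays below 2^53 so doubles are exact. Used by the toy predictor
# so its output is a pure function of (key, seed) with no RNG state.
hash_u01 <- function(keys, seed = 0L) {
  m <- 2147483647
  vapply(keys, function(k) {
    h <- (abs(as.numeric(seed)) + 11) %% m
    for (c in utf8ToInt(k)) h <- (h * 131 + c) %% m
    h <- (h * 48271) %% m
    h <- (h * 48271) %% m
    (h + 0.5) / (m + 1)
  }, numeric(1), USE.NAMES = FALSE)
}

# Run a block with a private RNG stream: saves and restores .Random.seed so
# seeded package code never perturbs (or is perturbed by) the caller's RNG.
with_private_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Canonical token for an amino-acid exchange, e.g. "KRAS:G12D".
change_token <- function(gene, position, ref_aa, alt_aa) {
  paste0(gene, ":", ref_aa, position, alt_aa)
}
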