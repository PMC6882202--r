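# Pluggable MHC class I binding predictors.
#
# A predictor is an object of class "binding_predictor" with a $predict
# function taking parallel vectors of peptides and allele names and
# returning a data frame with columns ic50_nm and binder_class (one of
# "non", "weak", "strong"). Two implementations ship: a deterministic toy
# predictor for synthetic runs and an adapter over NetMHCcons-style tabular
# output.

#' Default HLA class I allele panel
#'
#' The 11 frequent HLA-1 alleles used for candidate selection, as shipped
#' with the U.S. population tables.
#'
#' @return character vector of allele names in `HLA-A*02:01` form.
#' @export
default_allele_panel <- function() {
  us_hla_frequencies()$allele
}

new_binding_predictor <- function(predict, name) {
  stopifnot(is.function(predict))
  structure(list(predict = predict, name = name), class = "binding_predictor")
}

#' @export
print.binding_predictor <- function(x, ...) {
  cat("<binding_predictor:", x$name, ">\n")
  invisible(x)
}

# Single entry point used by the pipeline: validates the predictor contract.
predict_pairs <- function(predictor, peptides, alleles) {
  if (!inherits(predictor, "binding_predictor")) {
    stopf("predictor must be a binding_predictor object")
  }
  res <- tryCatch(predictor$predict(peptides, alleles), error = function(e) e)
  if (inherits(res, "error")) {
    stopf("binding predictor failed on (%s, %s): %s",
          peptides[1], alleles[1], conditionMessage(res))
  }
  if (!is.data.frame(res) || nrow(res) != length(peptides) ||
      !all(c("ic50_nm", "binder_class") %in% names(res))) {
    stopf("binding predictor returned a malformed result")
  }
  bad <- which(!is.finite(res$ic50_nm) | res$ic50_nm <= 0 |
                 !(res$binder_class %in% c("non", "weak", "strong")))
  if (length(bad) > 0) {
    stopf("binding predictor failed on (%s, %s): invalid ic50/class",
          peptides[bad[1]], alleles[bad[1]])
  }
  res
}

toy_ic50 <- function(peptides, alleles, seed, bonus_factor) {
  u <- hash_u01(paste0(peptides, "|", alleles), seed = seed)
  ic50 <- 10 ^ (u * log10(50000))
  # Allele-specific anchor motif: one preferred residue at peptide position 2
  # and one at the C terminus, derived deterministically from the allele name.
  a2 <- AA20[1 + floor(hash_u01(paste0("anchor2|", alleles), seed) * 20)]
  ac <- AA20[1 + floor(hash_u01(paste0("anchorC|", alleles), seed) * 20)]
  p2 <- substr(peptides, 2, 2)
  pc <- substr(peptides, nchar(peptides), nchar(peptides))
  hit <- p2 == a2 & pc == ac
  ic50[hit] <- ic50[hit] / bonus_factor
  ic50
}

# Uniform random 9-11-mers from a private, seed-determined RNG stream
# (class thresholds must be calibrated on the same peptide distribution the
# predictor is queried with; structured hash keys are not uniform enough).
toy_reference_peptides <- function(n, seed) {
  with_private_seed(seed + 104729L, {
    lens <- sample(c(9L, 10L, 11L), n, replace = TRUE)
    vapply(lens, function(L) {
      paste(sample(AA20, L, replace = TRUE), collapse = "")
    }, character(1))
  })
}

#' Deterministic toy MHC binding predictor
#'
#' A stand-in predictor for synthetic cohorts and tests. The IC50 for a
#' (peptide, allele) pair is a pure function of the pair and the seed: a
#' string hash mapped log-uniformly onto [1, 50000] nM, divided by
#' `bonus_factor` when the peptide matches an allele-specific anchor motif
#' (preferred residues at position 2 and the C terminus). Binder classes
#' follow the rank-based convention of NetMHC-family tools: per allele,
#' "strong" below the 0.5% quantile and "weak" below the 2% quantile of the
#' predictor's own score distribution, estimated once from a seeded
#' reference sample of random 9-11-mers.
#'
#' @param seed integer controlling the hash stream and reference sample.
#' @param bonus_factor IC50 divisor for anchor-motif matches.
#' @param strong_quantile,weak_quantile rank thresholds for the classes.
#' @param reference_n reference sample size per allele for the thresholds.
#' @return a `binding_predictor`.
#' @export
toy_binding_predictor <- function(seed = 1L, bonus_factor = 50,
                                  strong_quantile = 0.005,
                                  weak_quantile = 0.02,
                                  reference_n = 10000L) {
  refs <- toy_reference_peptides(reference_n, seed)
  thresholds <- new.env(parent = emptyenv())
  get_thresholds <- function(allele) {
    if (!is.null(thresholds[[allele]])) return(thresholds[[allele]])
    scores <- toy_ic50(refs, rep(allele, length(refs)), seed, bonus_factor)
    th <- stats::quantile(scores, c(strong_quantile, weak_quantile),
                          names = FALSE, type = 7)
    thresholds[[allele]] <- th
    th
  }
  predict <- function(peptides, alleles) {
    stopifnot(length(peptides) == length(alleles))
    ic50 <- toy_ic50(peptides, alleles, seed, bonus_factor)
    cls <- character(length(ic50))
    for (al in unique(alleles)) {
      th <- get_thresholds(al)
      i <- alleles == al
      cls[i] <- ifelse(ic50[i] <= th[1], "strong",
                       ifelse(ic50[i] <= th[2], "weak", "non"))
    }
    data.frame(ic50_nm = ic50, binder_class = cls, stringsAsFactors = FALSE)
  }
  new_binding_predictor(predict, sprintf("toy(seed=%d)", as.integer(seed)))
}

#' Read a NetMHCcons-style prediction table
#'
#' Parses whitespace- or tab-delimited tabular predictor output with one row
#' per (peptide, allele) pair. Column names are mapped through `col_map` and
#' binder-level labels through `level_map` (defaults accept both the
#' SB/WB/NB shorthand and already-normalized labels).
#'
#' @param path file path.
#' @param col_map named character vector mapping the roles `peptide`,
#'   `allele`, `ic50`, `level` to column names in the file.
#' @param level_map named character vector normalizing binder labels.
#' @return data frame with `peptide`, `allele`, `ic50_nm`, `binder_class`.
#' @export
read_netmhccons_table <- function(path,
                                  col_map = c(peptide = "peptide",
                                              allele = "allele",
                                              ic50 = "ic50_nm",
                                              level = "binder_class"),
                                  level_map = c(SB = "strong", WB = "weak",
                                                NB = "non",
                                                strong = "strong",
                                                weak = "weak", non = "non")) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#", check.names = FALSE)
  miss <- setdiff(unname(col_map), names(tab))
  if (length(miss) > 0) {
    stopf("prediction table is missing column(s): %s",
          paste(miss, collapse = ", "))
  }
  cls <- unname(level_map[as.character(tab[[col_map[["level"]]]])])
  if (anyNA(cls)) stopf("unrecognized binder level in %s", path)
  data.frame(peptide = as.character(tab[[col_map[["peptide"]]]]),
             allele = as.character(tab[[col_map[["allele"]]]]),
             ic50_nm = as.numeric(tab[[col_map[["ic50"]]]]),
             binder_class = cls, stringsAsFactors = FALSE)
}

#' Binding predictor backed by a precomputed prediction table
#'
#' Wraps the output of an external predictor (e.g. NetMHCcons run offline)
#' as a `binding_predictor`. Querying a (peptide, allele) pair absent from
#' the table is a hard error carrying the pair.
#'
#' @param table data frame as returned by [read_netmhccons_table()], or a
#'   file path to one.
#' @param ... passed to [read_netmhccons_table()] when `table` is a path.
#' @return a `binding_predictor`.
#' @export
table_predictor <- function(table, ...) {
  if (is.character(table)) table <- read_netmhccons_table(table, ...)
  key <- paste0(table$peptide, "|", table$allele)
  if (anyDuplicated(key)) {
    if (any(table$ic50_nm != table$ic50_nm[match(key, key)])) {
      stopf("prediction table has conflicting rows for a (peptide, allele) pair")
    }
    table <- table[!duplicated(key), , drop = FALSE]
    key <- key[!duplicated(key)]
  }
  predict <- function(peptides, alleles) {
    idx <- match(paste0(peptides, "|", alleles), key)
    if (anyNA(idx)) {
      i <- which(is.na(idx))[1]
      stopf("no prediction available for (%s, %s)", peptides[i], alleles[i])
    }
    data.frame(ic50_nm = table$ic50_nm[idx],
               binder_class = table$binder_class[idx],
               stringsAsFactors = FALSE)
  }
  new_binding_predictor(predict, "table")
}
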