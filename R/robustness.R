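# Robustness of patient coverage to false-positive candidates.
#
# Candidates (protein change + HLA allele pairs) are repeatedly flagged as
# false positives at a given fraction, uniformly at random without
# replacement; the fraction of patients still matched by the retained
# candidates is summarized over iterations.

#' Flagged and retained candidate counts at a false-positive fraction
#'
#' The number flagged is the nearest integer to `total * fp_fraction` with
#' half-up rounding (e.g. 674 candidates at 90% gives 607 flagged, 67
#' retained); retained is the remainder.
#'
#' @param total total number of candidates.
#' @param fp_fraction assumed false-positive fraction in [0, 1] (vectorized).
#' @return data frame with columns `fp_fraction`, `flagged`, `retained`.
#' @export
flagged_and_retained <- function(total, fp_fraction) {
  if (total < 0) stopf("total must be non-negative")
  assert_fraction(fp_fraction, "fp_fraction")
  flagged <- as.integer(floor(total * fp_fraction + 0.5))
  data.frame(fp_fraction = fp_fraction, flagged = flagged,
             retained = as.integer(total) - flagged)
}

#' Read patient HLA/mutation profiles
#'
#' @param path TSV with columns `patient_id`, `study_id`, `hla_alleles`
#'   (semicolon-separated allele names) and `changes` (semicolon-separated
#'   `GENE:RposA` tokens, e.g. `KRAS:G12D`).
#' @return data frame with list columns `hla_alleles` and `changes`.
#' @export
read_profiles <- function(path) {
  tab <- read_tsv(path)
  need <- c("patient_id", "study_id", "hla_alleles", "changes")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stopf("profile table is missing column(s): %s", paste(miss, collapse = ", "))
  }
  split_semi <- function(x) {
    lapply(as.character(x), function(s) {
      if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
    })
  }
  tab$hla_alleles <- split_semi(tab$hla_alleles)
  tab$changes <- split_semi(tab$changes)
  tab
}

candidate_keys <- function(candidates) {
  paste0(change_token(candidates$gene, candidates$position,
                      candidates$ref_aa, candidates$alt_aa),
         "|", candidates$allele)
}

#' Does a candidate set match a patient profile?
#'
#' A patient is matched when at least one candidate's mutation is in the
#' patient's change set AND the candidate's HLA allele is in the patient's
#' allele set.
#'
#' @param changes character vector of the patient's change tokens
#'   (`GENE:RposA`).
#' @param hla_alleles character vector of the patient's HLA alleles.
#' @param candidates candidate table with `gene`, `position`, `ref_aa`,
#'   `alt_aa`, `allele`.
#' @return logical scalar.
#' @export
patient_matched <- function(changes, hla_alleles, candidates) {
  if (nrow(candidates) == 0) return(FALSE)
  tok <- change_token(candidates$gene, candidates$position,
                      candidates$ref_aa, candidates$alt_aa)
  any(tok %in% changes & candidates$allele %in% hla_alleles)
}

# Logical patient x candidate incidence matrix.
match_matrix <- function(profiles, candidates) {
  tok <- change_token(candidates$gene, candidates$position,
                      candidates$ref_aa, candidates$alt_aa)
  m <- matrix(FALSE, nrow = nrow(profiles), ncol = nrow(candidates))
  for (i in seq_len(nrow(profiles))) {
    m[i, ] <- tok %in% profiles$changes[[i]] &
      candidates$allele %in% profiles$hla_alleles[[i]]
  }
  m
}

#' Fraction of patients matched by a candidate set
#'
#' @param profiles profile data frame (see [read_profiles()]); must be
#'   non-empty.
#' @param candidates candidate table.
#' @return matched patients / total patients.
#' @export
match_fraction <- function(profiles, candidates) {
  if (nrow(profiles) == 0) stopf("profiles must be non-empty")
  mean(rowSums(match_matrix(profiles, candidates)) > 0)
}

#' Resampling configuration
#'
#' @param fp_fractions false-positive fractions to scan.
#' @param n_iterations random flaggings per fraction.
#' @param seed RNG seed (a private stream; the caller's RNG is untouched).
#' @return object of class `resampling_config`.
#' @export
resampling_config <- function(fp_fractions = c(0.5, 0.8, 0.9, 0.95),
                              n_iterations = 1000L, seed = 1L) {
  assert_fraction(fp_fractions, "fp_fractions")
  if (n_iterations < 1) stopf("n_iterations must be >= 1")
  structure(list(fp_fractions = fp_fractions,
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed)),
            class = "resampling_config")
}

# Draw the flagged-candidate index sets: one draw per (iteration, fraction),
# identical for the global and per-study summaries so entities are compared
# on the same retained sets.
draw_flags <- function(n_candidates, config) {
  fr <- flagged_and_retained(n_candidates, config$fp_fractions)
  with_private_seed(config$seed, {
    lapply(seq_len(config$n_iterations), function(it) {
      lapply(seq_along(config$fp_fractions), function(j) {
        sample.int(n_candidates, fr$flagged[j])
      })
    })
  })
}

summarize_fractions <- function(mat, fr) {
  # mat: n_iterations x n_fractions matrix of matched fractions
  data.frame(
    fp_fraction = fr$fp_fraction, flagged = fr$flagged,
    retained = fr$retained,
    mean = colMeans(mat),
    median = apply(mat, 2, stats::median),
    p2.5 = apply(mat, 2, stats::quantile, probs = 0.025, names = FALSE),
    p97.5 = apply(mat, 2, stats::quantile, probs = 0.975, names = FALSE),
    stringsAsFactors = FALSE)
}

#' Resample false-positive candidate flaggings
#'
#' For each configured false-positive fraction, flags the corresponding
#' number of candidates uniformly at random (without replacement)
#' `n_iterations` times and records the fraction of patients still matched
#' by the retained candidates. The 95% interval is the empirical 2.5/97.5
#' percentile of the iteration distribution (linear interpolation between
#' order statistics). Fully reproducible per seed. An iteration with zero
#' retained candidates has matched fraction 0.
#'
#' @param profiles profile data frame (see [read_profiles()]).
#' @param candidates candidate table.
#' @param config a [resampling_config()].
#' @return object of class `robustness_summary`: data frame with one row
#'   per fraction (`fp_fraction`, `flagged`, `retained`, `mean`, `median`,
#'   `p2.5`, `p97.5`) carrying the per-iteration fraction matrix as
#'   attribute `"iterations"`.
#' @export
resample_false_positives <- function(profiles, candidates,
                                     config = resampling_config()) {
  if (nrow(candidates) < 1) stopf("need at least one candidate")
  if (nrow(profiles) == 0) stopf("profiles must be non-empty")
  m <- match_matrix(profiles, candidates)
  flags <- draw_flags(nrow(candidates), config)
  fr <- flagged_and_retained(nrow(candidates), config$fp_fractions)
  mat <- matrix(0, nrow = config$n_iterations,
                ncol = length(config$fp_fractions))
  for (it in seq_len(config$n_iterations)) {
    for (j in seq_along(config$fp_fractions)) {
      flagged <- flags[[it]][[j]]
      retained <- if (length(flagged) == 0) m
                  else m[, -flagged, drop = FALSE]
      mat[it, j] <- if (ncol(retained) == 0) 0 else mean(rowSums(retained) > 0)
    }
  }
  out <- summarize_fractions(mat, fr)
  attr(out, "iterations") <- mat
  class(out) <- c("robustness_summary", "data.frame")
  out
}

#' Per-study robustness summaries
#'
#' Same procedure as [resample_false_positives()], restricted to each
#' study's patients; the random flagging draw of each iteration is shared
#' across studies (and identical to the global draw under the same config),
#' so per-study numbers are directly comparable.
#'
#' @inheritParams resample_false_positives
#' @return named list of `robustness_summary` objects, one per study.
#' @export
per_study_summaries <- function(profiles, candidates,
                                config = resampling_config()) {
  if (nrow(candidates) < 1) stopf("need at least one candidate")
  m <- match_matrix(profiles, candidates)
  flags <- draw_flags(nrow(candidates), config)
  fr <- flagged_and_retained(nrow(candidates), config$fp_fractions)
  studies <- sort(unique(profiles$study_id))
  out <- lapply(studies, function(s) {
    rows <- which(profiles$study_id == s)
    ms <- m[rows, , drop = FALSE]
    mat <- matrix(0, nrow = config$n_iterations,
                  ncol = length(config$fp_fractions))
    for (it in seq_len(config$n_iterations)) {
      for (j in seq_along(config$fp_fractions)) {
        flagged <- flags[[it]][[j]]
        retained <- if (length(flagged) == 0) ms
                    else ms[, -flagged, drop = FALSE]
        mat[it, j] <- if (ncol(retained) == 0) 0
                      else mean(rowSums(retained) > 0)
      }
    }
    res <- summarize_fractions(mat, fr)
    attr(res, "iterations") <- mat
    class(res) <- c("robustness_summary", "data.frame")
    res
  })
  names(out) <- studies
  out
}

#' @export
print.robustness_summary <- function(x, ...) {
  cat("False-positive resampling summary (matched patient fraction)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
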