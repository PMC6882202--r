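# Homopolymer-context QC and cancer-gene enrichment tests.
#
# Variant calls inside homopolymer runs are a known sequencing/alignment
# artifact. Each call carries an 11-base reference context (mutated base at
# the center, 5 flanking bases each side); the observed fraction of calls
# whose center lies in a run of >= min_run identical bases is compared to
# the expectation under an equiprobable-sequence null with an exact upper
# binomial tail, Benjamini-Hochberg corrected across studies.

#' Is the context center inside a homopolymer run?
#'
#' True iff the maximal run of identical bases covering the center position
#' has length at least `min_run`. Runs adjacent to but not covering the
#' center do not count.
#'
#' @param contexts character vector of odd-length A/C/G/T strings (the
#'   variant base at the center).
#' @param min_run minimum qualifying run length.
#' @return logical vector.
#' @export
in_homopolymer <- function(contexts, min_run = 6L) {
  vapply(contexts, function(ctx) {
    b <- strsplit(ctx, "")[[1]]
    if (length(b) %% 2 != 1) stopf("context length must be odd: %s", ctx)
    if (any(!(b %in% DNA4))) stopf("non-ACGT base in context %s", ctx)
    center <- (length(b) + 1L) %/% 2L
    run <- 1L
    i <- center - 1L
    while (i >= 1 && b[i] == b[center]) { run <- run + 1L; i <- i - 1L }
    i <- center + 1L
    while (i <= length(b) && b[i] == b[center]) { run <- run + 1L; i <- i + 1L }
    run >= min_run
  }, logical(1), USE.NAMES = FALSE)
}

#' Expected homopolymer fraction under the equiprobable null
#'
#' Exact probability that [in_homopolymer()] is true for an iid uniform
#' A/C/G/T window. The run covering the center decomposes into truncated-
#' geometric left and right extensions (flank length F = (window-1)/2;
#' P(extension = k) = (1/4)^k * 3/4 for k < F and (1/4)^F at the
#' truncation), and the probability that 1 + left + right >= min_run is
#' summed over the (F+1) x (F+1) grid. Matches full 4^window enumeration.
#'
#' @param min_run minimum qualifying run length.
#' @param window odd window size.
#' @return probability.
#' @export
expected_repeat_fraction <- function(min_run = 6L, window = 11L) {
  if (window %% 2 != 1) stopf("window must be odd")
  if (min_run < 1 || min_run > window) stopf("min_run must be in [1, window]")
  f <- (window - 1L) %/% 2L
  p_ext <- c((1 / 4) ^ (0:(f - 1)) * (3 / 4), (1 / 4) ^ f)  # k = 0..F
  if (f == 0) p_ext <- 1
  total <- 0
  for (l in 0:f) for (r in 0:f) {
    if (1 + l + r >= min_run) total <- total + p_ext[l + 1] * p_ext[r + 1]
  }
  total
}

#' Upper binomial tail probability for repeat-context counts
#'
#' P(X >= n_in_repeat) for X ~ Binomial(n_variants, p0): the probability,
#' under the equiprobable null, of seeing at least the observed number of
#' calls in repeat loci. Exact (no normal approximation).
#'
#' @param n_in_repeat observed count in repeat contexts.
#' @param n_variants total calls.
#' @param p0 null per-call repeat probability.
#' @return tail probability.
#' @export
repeat_tail_probability <- function(n_in_repeat, n_variants, p0) {
  if (n_in_repeat < 0 || n_in_repeat > n_variants) {
    stopf("n_in_repeat must be in [0, n_variants]")
  }
  assert_fraction(p0, "p0")
  if (n_in_repeat == 0) return(1)
  stats::pbinom(n_in_repeat - 1, n_variants, p0, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment with rejection flags
#'
#' Standard step-up adjusted p values (monotone-enforced, via
#' `stats::p.adjust`); a test is rejected iff its adjusted value is at most
#' `alpha`.
#'
#' @param p_values raw p values in [0, 1].
#' @param alpha significance level.
#' @return list with `adjusted` and logical `rejected`.
#' @export
bh_adjust <- function(p_values, alpha = 0.05) {
  assert_fraction(p_values, "p values")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adj, rejected = adj <= alpha)
}

#' Per-study homopolymer QC
#'
#' Partitions each study's calls into singletons (observed in exactly one
#' patient of the cohort) or multi-occurrence variants, computes the
#' fraction falling in homopolymer contexts, the exact binomial tail
#' probability against the equiprobable-null expectation, and BH-adjusts
#' across studies. Calls without a context are excluded and counted.
#'
#' @param variants data frame with columns `study_id`, `patient_id`,
#'   `gene`, `position`, `ref_aa`, `alt_aa`, `context11` (11-base reference
#'   context; NA/empty = missing).
#' @param unique_only if `TRUE` analyse singleton variants, else variants
#'   seen in more than one patient.
#' @param min_run minimum qualifying run length.
#' @param alpha significance level after correction.
#' @return data frame with one row per study: `study_id`, `n_variants`,
#'   `n_in_repeat`, `n_missing_context`, `expected_fraction`, `p_value`,
#'   `p_adjusted`, `significant`.
#' @export
run_repeat_qc <- function(variants, unique_only = TRUE, min_run = 6L,
                          alpha = 0.05) {
  window <- unique(nchar(variants$context11[!is.na(variants$context11) &
                                              nzchar(variants$context11)]))
  if (length(window) > 1) stopf("mixed context lengths")
  if (length(window) == 0) window <- 11L
  p0 <- expected_repeat_fraction(min_run, window)

  vkey <- paste(variants$study_id, variants$gene, variants$position,
                variants$ref_aa, variants$alt_aa, sep = "\r")
  carriers <- tapply(variants$patient_id, vkey,
                     function(p) length(unique(p)))
  n_pat <- as.integer(carriers[vkey])
  branch <- if (unique_only) n_pat == 1L else n_pat > 1L
  sel <- variants[branch, , drop = FALSE]

  studies <- sort(unique(variants$study_id))
  rows <- lapply(studies, function(s) {
    sv <- sel[sel$study_id == s, , drop = FALSE]
    missing <- is.na(sv$context11) | !nzchar(sv$context11)
    ctx <- sv$context11[!missing]
    n <- length(ctx)
    n_rep <- if (n == 0) 0L else sum(in_homopolymer(ctx, min_run))
    p <- if (n == 0) 1 else repeat_tail_probability(n_rep, n, p0)
    data.frame(study_id = s, n_variants = n, n_in_repeat = n_rep,
               n_missing_context = sum(missing), expected_fraction = p0,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  bh <- bh_adjust(out$p_value, alpha)
  out$p_adjusted <- bh$adjusted
  out$significant <- bh$rejected
  rownames(out) <- NULL
  out
}

#' Pearson chi-squared test on a contingency table
#'
#' Classic test of association between variant sets and gene classes
#' (oncogene / tumor suppressor / other), without continuity correction.
#' A zero row or column margin is a hard error.
#'
#' @param table integer matrix (at least 2x2) of non-negative counts.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
enrichment_chisq <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) stopf("table must be at least 2x2")
  if (any(table < 0)) stopf("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stopf("zero row/column margin: expected counts undefined")
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Build the gene-class contingency table for enrichment testing
#'
#' Cross-tabulates two sets of protein changes (e.g. all unique changes vs
#' unique recurrent changes) against gene classes.
#'
#' @param sets named list of data frames, each with a `gene` column.
#' @param gene_classes data frame with columns `gene`, `class` (e.g.
#'   `oncogene`, `tsg`, `other`); genes absent from the table count as
#'   `other`.
#' @return integer matrix, rows = sets, columns = classes.
#' @export
gene_class_table <- function(sets, gene_classes) {
  classes <- sort(unique(c(gene_classes$class, "other")))
  out <- matrix(0L, nrow = length(sets), ncol = length(classes),
                dimnames = list(names(sets), classes))
  for (i in seq_along(sets)) {
    g <- sets[[i]]$gene
    cl <- gene_classes$class[match(g, gene_classes$gene)]
    cl[is.na(cl)] <- "other"
    tab <- table(factor(cl, levels = classes))
    out[i, ] <- as.integer(tab)
  }
  out
}
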