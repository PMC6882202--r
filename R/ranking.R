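# Expected-patient ranking and disease-by-HLA coverage tables.
#
# The ranking statistic for a candidate (protein change, HLA allele h) is
# the expected annual number of newly diagnosed patients carrying both the
# mutation and the allele:
#
#     n_h = f_h * sum_d r_d * N_d
#
# where f_h is the population frequency of allele h, r_d the observed
# carrier fraction of the change in disease d, and N_d the annual incidence
# of disease d. The sum runs over diseases present in BOTH the incidence
# and variant-frequency tables; sub-threshold observed frequencies still
# contribute. Coverage cells combine candidates under an independence
# assumption: cell(d, h) = N_d * f_h * (1 - prod_v (1 - r_{v,d})).

#' Shipped U.S. population tables
#'
#' HLA class I allele frequencies (11 frequent alleles, U.S. population
#' averages) and annual cancer incidence for the 18 disease entities with a
#' matching TCGA study, as distributed with the package.
#'
#' @return `us_hla_frequencies()`: data frame `allele`, `frequency`.
#' @export
us_hla_frequencies <- function() {
  read_tsv(system.file("extdata", "hla_freq_us.tsv", package = "recurneo",
                       mustWork = TRUE))
}

#' @rdname us_hla_frequencies
#' @return `us_incidence()`: data frame `disease`, `disease_name`,
#'   `annual_cases`.
#' @export
us_incidence <- function() {
  read_tsv(system.file("extdata", "incidence_us.tsv", package = "recurneo",
                       mustWork = TRUE))
}

#' Read an HLA allele-frequency table
#'
#' @param path TSV with columns `allele`, `frequency`.
#' @return data frame with those columns; frequencies validated to [0, 1].
#' @export
read_hla_frequencies <- function(path) {
  tab <- read_tsv(path)
  if (!all(c("allele", "frequency") %in% names(tab))) {
    stopf("allele-frequency table needs columns allele, frequency")
  }
  assert_fraction(tab$frequency, "allele frequency")
  tab
}

#' Read a cancer incidence table
#'
#' @param path TSV with columns `disease`, `annual_cases`.
#' @return data frame with those columns.
#' @export
read_incidence <- function(path) {
  tab <- read_tsv(path)
  if (!all(c("disease", "annual_cases") %in% names(tab))) {
    stopf("incidence table needs columns disease, annual_cases")
  }
  if (any(tab$annual_cases < 0)) stopf("annual_cases must be non-negative")
  tab
}

hla_lookup <- function(hla_freq, allele, diploid = FALSE) {
  i <- match(allele, hla_freq$allele)
  if (anyNA(i)) {
    stopf("allele(s) missing from the frequency table: %s",
          paste(unique(allele[is.na(i)]), collapse = ", "))
  }
  f <- hla_freq$frequency[i]
  # diploid carrier frequency: P(at least one copy) under Hardy-Weinberg
  if (diploid) 1 - (1 - f)^2 else f
}

# Per-disease r_d vector for one change, restricted to diseases in both
# tables ("both the TCGA projects and the cancer incidence data").
change_disease_freqs <- function(variant_freq, gene, position, ref_aa, alt_aa,
                                 diseases) {
  sel <- variant_freq$gene == gene & variant_freq$position == position &
    variant_freq$ref_aa == ref_aa & variant_freq$alt_aa == alt_aa &
    variant_freq$disease %in% diseases
  variant_freq[sel, c("disease", "frequency"), drop = FALSE]
}

#' Expected number of target patients for one candidate
#'
#' @param gene,position,ref_aa,alt_aa the protein change.
#' @param allele the candidate's HLA allele (must be in `hla_freq`).
#' @param hla_freq allele-frequency table (`allele`, `frequency`).
#' @param incidence incidence table (`disease`, `annual_cases`).
#' @param variant_freq observed carrier fractions (`gene`, `position`,
#'   `ref_aa`, `alt_aa`, `disease`, `frequency`), e.g. from
#'   [observed_frequencies()].
#' @param diploid if `TRUE`, use the diploid carrier frequency
#'   `1 - (1 - f_h)^2` instead of the allele frequency `f_h`.
#' @return list with `n_h` (patients/year) and `terms` (per-disease data
#'   frame with the f_h * r_d * N_d contributions).
#' @export
expected_patients <- function(gene, position, ref_aa, alt_aa, allele,
                              hla_freq, incidence, variant_freq,
                              diploid = FALSE) {
  f_h <- hla_lookup(hla_freq, allele, diploid)
  r <- change_disease_freqs(variant_freq, gene, position, ref_aa, alt_aa,
                            incidence$disease)
  assert_fraction(r$frequency, "variant frequency")
  N_d <- incidence$annual_cases[match(r$disease, incidence$disease)]
  terms <- data.frame(disease = r$disease, r_d = r$frequency, N_d = N_d,
                      expected = f_h * r$frequency * N_d,
                      stringsAsFactors = FALSE)
  list(n_h = sum(terms$expected), terms = terms)
}

#' Rank candidates by expected number of target patients
#'
#' Computes n_h for every candidate and sorts in descending order; ties are
#' broken lexicographically by (gene, position, alt_aa, allele) so output is
#' stable across runs.
#'
#' @param candidates candidate table from [neo_candidates()] (only the
#'   change and `allele` columns are used).
#' @param hla_freq,incidence,variant_freq,diploid see [expected_patients()].
#' @return `candidates` with an `n_h` column, one column
#'   `expected_<disease>` per disease with any contribution, sorted.
#' @export
rank_candidates <- function(candidates, hla_freq, incidence, variant_freq,
                            diploid = FALSE) {
  if (nrow(candidates) == 0) {
    candidates$n_h <- numeric(0)
    return(candidates)
  }
  per <- lapply(seq_len(nrow(candidates)), function(i) {
    expected_patients(candidates$gene[i], candidates$position[i],
                      candidates$ref_aa[i], candidates$alt_aa[i],
                      candidates$allele[i], hla_freq, incidence, variant_freq,
                      diploid)
  })
  candidates$n_h <- vapply(per, `[[`, numeric(1), "n_h")
  diseases <- sort(unique(unlist(lapply(per, function(p) p$terms$disease))))
  for (d in diseases) {
    candidates[[paste0("expected_", d)]] <- vapply(per, function(p) {
      i <- match(d, p$terms$disease)
      if (is.na(i)) 0 else p$terms$expected[i]
    }, numeric(1))
  }
  ord <- order(-candidates$n_h, candidates$gene, candidates$position,
               candidates$alt_aa, candidates$allele)
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Probability of at least one of several independent events
#'
#' `1 - prod(1 - r)` over the given frequencies; the independence model
#' behind the coverage table. An empty list gives 0.
#'
#' @param freqs numeric vector of frequencies in [0, 1].
#' @return scalar probability.
#' @export
prob_at_least_one <- function(freqs) {
  if (length(freqs) == 0) return(0)
  assert_fraction(freqs, "frequencies")
  1 - prod(1 - freqs)
}

#' Disease-by-HLA coverage table
#'
#' For each (disease d, allele h), the expected number of newly diagnosed
#' patients of HLA type h who harbor at least one candidate binding h:
#' `N_d * f_h * prob_at_least_one({r_{v,d}})` over the candidate changes v
#' with a prediction for h. Also emits column totals and a per-allele
#' candidate count.
#'
#' @inheritParams rank_candidates
#' @return object of class `coverage_table`: list with `cells` (disease x
#'   allele matrix), `totals` (per-allele column sums), and
#'   `candidate_counts` (number of candidate pairs per allele).
#' @export
coverage_table <- function(candidates, hla_freq, incidence, variant_freq,
                           diploid = FALSE) {
  alleles <- hla_freq$allele
  diseases <- incidence$disease
  cells <- matrix(0, nrow = length(diseases), ncol = length(alleles),
                  dimnames = list(diseases, alleles))
  for (h in alleles) {
    f_h <- hla_lookup(hla_freq, h, diploid)
    ch <- unique(candidates[candidates$allele == h,
                            c("gene", "position", "ref_aa", "alt_aa"),
                            drop = FALSE])
    if (nrow(ch) == 0) next
    for (d in diseases) {
      rs <- numeric(0)
      for (i in seq_len(nrow(ch))) {
        sel <- variant_freq$gene == ch$gene[i] &
          variant_freq$position == ch$position[i] &
          variant_freq$ref_aa == ch$ref_aa[i] &
          variant_freq$alt_aa == ch$alt_aa[i] &
          variant_freq$disease == d
        if (any(sel)) rs <- c(rs, variant_freq$frequency[sel][1])
      }
      N_d <- incidence$annual_cases[match(d, incidence$disease)]
      cells[d, h] <- N_d * f_h * prob_at_least_one(rs)
    }
  }
  counts <- vapply(alleles, function(h) {
    nrow(unique(candidates[candidates$allele == h,
                           c("gene", "position", "ref_aa", "alt_aa"),
                           drop = FALSE]))
  }, integer(1))
  structure(list(cells = cells, totals = colSums(cells),
                 candidate_counts = counts),
            class = "coverage_table")
}

#' @export
print.coverage_table <- function(x, digits = 1, ...) {
  cat("Expected patients with >= 1 candidate, by disease and HLA type\n")
  print(round(x$cells, digits))
  cat("Totals:\n")
  print(round(x$totals, digits))
  cat("Candidates per allele:\n")
  print(x$candidate_counts)
  invisible(x)
}
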