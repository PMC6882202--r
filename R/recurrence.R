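# Per-cohort recurrence calling at the protein level.

#' Read a clinical cohort-membership table
#'
#' @param path TSV with columns `patient_id`, `study_id`.
#' @return data frame with those two columns.
#' @export
read_clinical <- function(path) {
  cl <- read_tsv(path)
  need <- c("patient_id", "study_id")
  miss <- setdiff(need, names(cl))
  if (length(miss) > 0) {
    stopf("clinical table is missing column(s): %s", paste(miss, collapse = ", "))
  }
  cl[need]
}

check_cohorts <- function(clinical) {
  if (anyDuplicated(clinical$patient_id)) {
    dup <- unique(clinical$patient_id[duplicated(clinical$patient_id)])
    stopf("patient(s) assigned to multiple studies: %s",
          paste(utils::head(dup, 3), collapse = ", "))
  }
  invisible(clinical)
}

#' Retain study cohorts large enough for recurrence calling
#'
#' Cohort size is the number of patients with clinical information in the
#' study, including patients without any surviving variant. The default
#' keeps cohorts with more than 100 patients (i.e. at least 101); together
#' with the 1% recurrence threshold this guarantees every recurrent call is
#' supported by at least 2 patients.
#'
#' @param clinical data frame with `patient_id`, `study_id`.
#' @param min_patients minimum cohort size (inclusive).
#' @return subset of `clinical` restricted to eligible studies.
#' @export
eligible_cohorts <- function(clinical, min_patients = 101L) {
  check_cohorts(clinical)
  sizes <- table(clinical$study_id)
  keep <- names(sizes)[sizes >= min_patients]
  out <- clinical[clinical$study_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call recurrent protein changes per cohort
#'
#' A protein change is recurrent in a study when the fraction of the study's
#' clinical patients carrying it is at least `threshold` (inclusive). The
#' denominator is always the full clinical-patient count of the cohort.
#' Carrier counts are kept as integers and the threshold comparison is
#' performed as `n_carriers >= threshold * cohort_size` with a 1e-9 guard
#' against binary-float artifacts, so boundary cases are decided exactly.
#'
#' @param carriers carrier relation from [patient_protein_changes()]
#'   (columns `patient_id`, `gene`, `position`, `ref_aa`, `alt_aa`; any
#'   `study_id` column is ignored in favour of the clinical table).
#' @param clinical eligible cohort table (see [eligible_cohorts()]).
#' @param threshold recurrence frequency threshold (inclusive).
#' @return data frame with one row per recurrent (study, change):
#'   `study_id`, `gene`, `position`, `ref_aa`, `alt_aa`, `n_carriers`,
#'   `cohort_size`, `frequency`; sorted by study, descending frequency, then
#'   gene/position/alt.
#' @export
call_recurrent <- function(carriers, clinical, threshold = 0.01) {
  assert_fraction(threshold, "threshold")
  check_cohorts(clinical)
  empty <- data.frame(study_id = character(), gene = character(),
                      position = integer(), ref_aa = character(),
                      alt_aa = character(), n_carriers = integer(),
                      cohort_size = integer(), frequency = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(carriers) == 0) return(empty)
  idx <- match(carriers$patient_id, clinical$patient_id)
  if (anyNA(idx)) {
    missing <- unique(carriers$patient_id[is.na(idx)])
    stopf("carrier patient(s) not present in the cohort table: %s",
          paste(utils::head(missing, 3), collapse = ", "))
  }
  carriers$study_id <- clinical$study_id[idx]
  carriers <- unique(carriers[c("patient_id", "study_id", "gene", "position",
                                "ref_aa", "alt_aa")])
  sizes <- table(clinical$study_id)
  key <- paste(carriers$study_id, carriers$gene, carriers$position,
               carriers$ref_aa, carriers$alt_aa, sep = "\r")
  counts <- table(key)
  first <- carriers[!duplicated(key), , drop = FALSE]
  n_car <- as.integer(counts[paste(first$study_id, first$gene, first$position,
                                   first$ref_aa, first$alt_aa, sep = "\r")])
  size <- as.integer(sizes[first$study_id])
  rec <- n_car >= threshold * size - 1e-9
  out <- data.frame(study_id = first$study_id, gene = first$gene,
                    position = first$position, ref_aa = first$ref_aa,
                    alt_aa = first$alt_aa, n_carriers = n_car,
                    cohort_size = size, frequency = n_car / size,
                    stringsAsFactors = FALSE)[rec, , drop = FALSE]
  out <- out[order(out$study_id, -out$frequency, out$gene, out$position,
                   out$alt_aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Observed per-cohort frequencies of a set of protein changes
#'
#' Companion to [call_recurrent()]: for each given change, the observed
#' carrier fraction in every eligible cohort where it is seen at all,
#' including sub-threshold frequencies. These feed the expected-patient
#' ranking, where a candidate's below-threshold occurrences in other
#' diseases still contribute patients.
#'
#' @inheritParams call_recurrent
#' @param changes data frame with `gene`, `position`, `ref_aa`, `alt_aa`;
#'   `NULL` means all observed changes.
#' @return data frame `gene`, `position`, `ref_aa`, `alt_aa`, `disease`
#'   (study id), `frequency`.
#' @export
observed_frequencies <- function(carriers, clinical, changes = NULL) {
  all_freq <- call_recurrent(carriers, clinical, threshold = 0)
  if (!is.null(changes)) {
    want <- paste(changes$gene, changes$position, changes$ref_aa,
                  changes$alt_aa, sep = "\r")
    have <- paste(all_freq$gene, all_freq$position, all_freq$ref_aa,
                  all_freq$alt_aa, sep = "\r")
    all_freq <- all_freq[have %in% want, , drop = FALSE]
  }
  data.frame(gene = all_freq$gene, position = all_freq$position,
             ref_aa = all_freq$ref_aa, alt_aa = all_freq$alt_aa,
             disease = all_freq$study_id, frequency = all_freq$frequency,
             stringsAsFactors = FALSE)
}

#' Deduplicate recurrence calls across studies
#'
#' @param records recurrence table from [call_recurrent()].
#' @return data frame of unique changes (`gene`, `position`, `ref_aa`,
#'   `alt_aa`), sorted.
#' @export
unique_changes <- function(records) {
  out <- unique(records[c("gene", "position", "ref_aa", "alt_aa")])
  out <- out[order(out$gene, out$position, out$alt_aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge recurrent changes that hit the same codon
#'
#' Distinct alternate residues at one (gene, amino-acid position) — e.g. a
#' codon mutated to several different residues across cohorts — merge into a
#' single codon group, the unit used for comparison against external hotspot
#' lists.
#'
#' @param records recurrence table from [call_recurrent()].
#' @return data frame with one row per (gene, position): `gene`, `position`,
#'   `alt_residues` (comma-separated, sorted), `n_records`,
#'   `total_carriers`; sorted by total carrier count descending.
#' @export
group_by_codon <- function(records) {
  empty <- data.frame(gene = character(), position = integer(),
                      alt_residues = character(), n_records = integer(),
                      total_carriers = integer(), stringsAsFactors = FALSE)
  if (nrow(records) == 0) return(empty)
  key <- paste(records$gene, records$position, sep = "\r")
  groups <- split(records, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(gene = g$gene[1], position = g$position[1],
               alt_residues = paste(sort(unique(g$alt_aa)), collapse = ","),
               n_records = nrow(g),
               total_carriers = sum(g$n_carriers),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$total_carriers, out$gene, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap of codon groups with an external hotspot list
#'
#' @param groups codon groups from [group_by_codon()].
#' @param hotspots data frame with `gene`, `position` and optionally
#'   `flagged` (0/1; presumptive false-positive entries).
#' @return list with `n_overlap`, `overlap` (matching groups), and `flagged`
#'   (groups matching flagged hotspot entries).
#' @export
hotspot_overlap <- function(groups, hotspots) {
  if (nrow(hotspots) == 0) {
    return(list(n_overlap = 0L, overlap = groups[0, , drop = FALSE],
                flagged = groups[0, , drop = FALSE]))
  }
  gk <- paste(groups$gene, groups$position, sep = "\r")
  hk <- paste(hotspots$gene, hotspots$position, sep = "\r")
  hit <- gk %in% hk
  flagged_keys <- if ("flagged" %in% names(hotspots)) {
    hk[as.logical(hotspots$flagged) %in% TRUE | hotspots$flagged == 1]
  } else character()
  list(n_overlap = sum(hit),
       overlap = groups[hit, , drop = FALSE],
       flagged = groups[gk %in% flagged_keys, , drop = FALSE])
}
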