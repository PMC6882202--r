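# MAF reading and high-confidence missense SNV filtering.
#
# The filter chain mirrors standard somatic-variant hygiene for cohort-level
# recurrence analysis: structural validation of each record, restriction to
# missense single-nucleotide variants with a parseable protein annotation,
# read-support and VAF thresholds, and removal of likely germline
# polymorphisms via a precomputed population allele-frequency annotation.

MAF_REQUIRED_COLUMNS <- c(
  "Tumor_Sample_Barcode", "Hugo_Symbol", "Transcript_ID", "HGVSp_Short",
  "Chromosome", "Start_Position", "Reference_Allele", "Tumor_Seq_Allele2",
  "Variant_Type", "Variant_Classification", "Mutation_Status",
  "t_depth", "t_ref_count", "t_alt_count"
)

#' Filter configuration
#'
#' Thresholds for the high-confidence missense SNV filter chain. Defaults
#' encode the standard settings: at least 5 alternate-allele reads, variant
#' allele fraction (VAF) at least 10% (both inclusive), and exclusion of
#' variants seen at more than 1% in any reference population (strictly
#' greater; equality at 1% is kept).
#'
#' @param min_alt_reads minimum alternate-read support (inclusive).
#' @param min_vaf minimum variant allele fraction (inclusive).
#' @param max_pop_af maximum population allele frequency; records strictly
#'   above this are dropped, records without annotation are kept.
#' @param required_classification `Variant_Classification` value to keep.
#' @param required_type `Variant_Type` value to keep.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(min_alt_reads = 5L, min_vaf = 0.10,
                          max_pop_af = 0.01,
                          required_classification = "Missense_Mutation",
                          required_type = "SNP") {
  assert_fraction(min_vaf, "min_vaf")
  assert_fraction(max_pop_af, "max_pop_af")
  if (min_alt_reads < 0) stopf("min_alt_reads must be non-negative")
  structure(
    list(min_alt_reads = as.integer(min_alt_reads), min_vaf = min_vaf,
         max_pop_af = max_pop_af,
         required_classification = required_classification,
         required_type = required_type),
    class = "filter_config"
  )
}

new_filter_report <- function() {
  data.frame(stage = character(), n_in = integer(), n_out = integer(),
             n_rejected = integer(), stringsAsFactors = FALSE)
}

add_report_stage <- function(report, stage, n_in, n_out) {
  rbind(report, data.frame(stage = stage, n_in = as.integer(n_in),
                           n_out = as.integer(n_out),
                           n_rejected = as.integer(n_in - n_out),
                           stringsAsFactors = FALSE))
}

#' Read a MAF-dialect somatic variant table
#'
#' Reads a tab-delimited mutation table in the GDC MAF dialect (see
#' `MAF_REQUIRED_COLUMNS` for required column names; order is irrelevant;
#' `max_pop_af` is optional; `#` lines are comments). Rows with a missing or
#' empty required field are rejected with a reason rather than imputed; in
#' particular a row without a transcript identifier is rejected with reason
#' `"no valid ENSEMBL transcript ID"`.
#'
#' @param path path to the tab-delimited file.
#' @param study_id study label attached to every record.
#' @return list with `records` (kept rows, plus a `study_id` column),
#'   `rejections` (data frame of row numbers and reasons) and `report`
#'   (one-stage filter report).
#' @export
read_maf <- function(path, study_id) {
  maf <- utils::read.delim(path, sep = "\t", header = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(MAF_REQUIRED_COLUMNS, names(maf))
  if (length(missing_cols) > 0) {
    stopf("MAF file %s is missing required column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  validate_maf_records(maf, study_id)
}

# Shared by read_maf() and the synthetic generator (which hands over an
# in-memory data frame): field-completeness screen + numeric coercion.
validate_maf_records <- function(maf, study_id) {
  n <- nrow(maf)
  reason <- character(n)
  if (n > 0) {
    for (col in MAF_REQUIRED_COLUMNS) {
      v <- as.character(maf[[col]])
      bad <- (is.na(v) | !nzchar(trimws(v))) & !nzchar(reason)
      if (col == "Transcript_ID") {
        reason[bad] <- "no valid ENSEMBL transcript ID"
      } else {
        reason[bad] <- paste0("missing field ", col)
      }
    }
    for (col in c("Start_Position", "t_depth", "t_ref_count", "t_alt_count")) {
      num <- suppressWarnings(as.numeric(maf[[col]]))
      bad <- (!is.finite(num) | num < 0) & !nzchar(reason)
      reason[bad] <- paste0("non-numeric field ", col)
    }
  }
  keep <- !nzchar(reason)
  records <- maf[keep, , drop = FALSE]
  for (col in c("Start_Position", "t_depth", "t_ref_count", "t_alt_count")) {
    records[[col]] <- as.integer(round(as.numeric(records[[col]])))
  }
  if ("max_pop_af" %in% names(records)) {
    records$max_pop_af <- suppressWarnings(as.numeric(records$max_pop_af))
  }
  # a pre-existing study_id column (in-memory tables) wins over the argument
  if (!("study_id" %in% names(records))) {
    records$study_id <- rep(study_id, nrow(records))
  }
  rownames(records) <- NULL
  rejections <- data.frame(row = which(!keep), reason = reason[!keep],
                           stringsAsFactors = FALSE)
  report <- add_report_stage(new_filter_report(), "read", n, nrow(records))
  list(records = records, rejections = rejections, report = report)
}

#' Parse short protein HGVS notation into an amino-acid exchange
#'
#' Accepts strictly the single-residue missense pattern
#' `p.<refAA><pos><altAA>` with standard single-letter amino-acid codes.
#' Frameshifts, stop gains, synonymous annotations, and anything else are
#' rejections (returned as a value, not an error).
#'
#' @param x character vector of `HGVSp_Short` strings.
#' @return data frame with columns `ok`, `position`, `ref_aa`, `alt_aa`,
#'   `reason` (empty when `ok`).
#' @export
parse_hgvsp <- function(x) {
  x <- as.character(x)
  m <- regmatches(x, regexec("^p\\.([A-Z])([0-9]+)([A-Z])$", x))
  out <- data.frame(ok = logical(length(x)), position = NA_integer_,
                    ref_aa = NA_character_, alt_aa = NA_character_,
                    reason = "", stringsAsFactors = FALSE)
  for (i in seq_along(x)) {
    g <- m[[i]]
    if (length(g) != 4) {
      out$reason[i] <- "not a single-residue missense exchange"
      next
    }
    ref <- g[2]; pos <- as.integer(g[3]); alt <- g[4]
    if (!(ref %in% AA20) || !(alt %in% AA20)) {
      out$reason[i] <- "non-standard amino acid code"
    } else if (ref == alt) {
      out$reason[i] <- "synonymous"
    } else if (pos < 1) {
      out$reason[i] <- "invalid position"
    } else {
      out$ok[i] <- TRUE
      out$position[i] <- pos
      out$ref_aa[i] <- ref
      out$alt_aa[i] <- alt
    }
  }
  out
}

#' Format an amino-acid exchange in short protein HGVS notation
#'
#' Inverse of [parse_hgvsp()] on well-formed exchanges.
#'
#' @param position,ref_aa,alt_aa vectors describing the exchange.
#' @return character vector like `"p.H1047R"`.
#' @export
format_hgvsp <- function(position, ref_aa, alt_aa) {
  paste0("p.", ref_aa, position, alt_aa)
}

#' Structural consistency check of variant records
#'
#' A record is accepted iff `Mutation_Status` equals "somatic"
#' case-insensitively, the total depth equals the sum of reference and
#' alternate read counts, and both alleles are a single A/C/G/T nucleotide.
#' Failures are rejected with a reason, never silently fixed.
#'
#' @param records data frame of MAF records from [read_maf()].
#' @return logical `accept` vector with a `reason` attribute (character,
#'   empty where accepted).
#' @export
validate_consistency <- function(records) {
  n <- nrow(records)
  reason <- character(n)
  if (n > 0) {
    ok_status <- tolower(records$Mutation_Status) == "somatic"
    reason[!ok_status] <- "mutation status not somatic"
    ok_depth <- records$t_depth == records$t_ref_count + records$t_alt_count
    reason[ok_status & !ok_depth] <- "depth mismatch"
    single <- function(x) nchar(x) == 1L & x %in% DNA4
    ok_nt <- single(records$Reference_Allele) & single(records$Tumor_Seq_Allele2)
    reason[ok_status & ok_depth & !ok_nt] <- "not single nucleotide"
  }
  structure(!nzchar(reason), reason = reason)
}

#' Restrict to missense single-nucleotide variants
#'
#' Keeps records whose `Variant_Type` and `Variant_Classification` match the
#' configured values, whose `HGVSp_Short` parses as a single-residue
#' exchange, and whose transcript identifier is non-empty.
#'
#' @param records data frame of validated records.
#' @param config a [filter_config()].
#' @return the kept subset of `records`.
#' @export
select_missense_snv <- function(records, config = filter_config()) {
  if (nrow(records) == 0) return(records)
  parsed <- parse_hgvsp(records$HGVSp_Short)
  keep <- records$Variant_Type == config$required_type &
    records$Variant_Classification == config$required_classification &
    parsed$ok &
    nzchar(trimws(records$Transcript_ID))
  records[keep, , drop = FALSE]
}

#' Read-support and VAF filter
#'
#' Keeps records with at least `min_alt_reads` alternate-allele reads and
#' VAF (`t_alt_count / t_depth`) at least `min_vaf`; both thresholds
#' inclusive. A zero-depth record reaching this stage is a pipeline ordering
#' error (such records must be rejected upstream) and raises a hard error.
#'
#' @inheritParams select_missense_snv
#' @return the kept subset of `records`.
#' @export
apply_support_filter <- function(records, config = filter_config()) {
  if (nrow(records) == 0) return(records)
  if (any(records$t_depth == 0)) {
    stopf("zero-depth record reached the support filter: pipeline misordering")
  }
  vaf <- records$t_alt_count / records$t_depth
  keep <- records$t_alt_count >= config$min_alt_reads & vaf >= config$min_vaf
  records[keep, , drop = FALSE]
}

#' Population allele-frequency filter
#'
#' Drops records whose `max_pop_af` annotation (maximum allele frequency over
#' reference populations, precomputed upstream) is strictly greater than
#' `config$max_pop_af`. Records without the annotation (column absent or NA)
#' are kept: absence of evidence of a polymorphism is not evidence.
#'
#' @inheritParams select_missense_snv
#' @return the kept subset of `records`.
#' @export
apply_population_filter <- function(records, config = filter_config()) {
  if (nrow(records) == 0 || !("max_pop_af" %in% names(records))) {
    return(records)
  }
  af <- records$max_pop_af
  drop <- !is.na(af) & af > config$max_pop_af
  records[!drop, , drop = FALSE]
}

#' Collapse filtered records to the patient-by-protein-change carrier relation
#'
#' Distinct genomic SNVs producing the same amino-acid exchange in the same
#' patient (codon redundancy) collapse to a single carrier pair, so
#' recurrence is counted strictly at the protein level.
#'
#' @param records fully filtered records.
#' @return data frame with one row per distinct (patient, change):
#'   `patient_id`, `study_id`, `gene`, `position`, `ref_aa`, `alt_aa`.
#' @export
patient_protein_changes <- function(records) {
  empty <- data.frame(patient_id = character(), study_id = character(),
                      gene = character(), position = integer(),
                      ref_aa = character(), alt_aa = character(),
                      stringsAsFactors = FALSE)
  if (nrow(records) == 0) return(empty)
  parsed <- parse_hgvsp(records$HGVSp_Short)
  if (any(!parsed$ok)) stopf("unparseable HGVSp reached carrier collapse")
  out <- data.frame(patient_id = records$Tumor_Sample_Barcode,
                    study_id = records$study_id,
                    gene = records$Hugo_Symbol,
                    position = parsed$position,
                    ref_aa = parsed$ref_aa,
                    alt_aa = parsed$alt_aa,
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$study_id, out$patient_id, out$gene, out$position,
                   out$alt_aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full variant filter chain
#'
#' Applies, in order: record reading/validation, structural consistency,
#' missense-SNV selection, read-support/VAF thresholds, and the population
#' allele-frequency filter; then collapses to the carrier relation. Every
#' stage is accounted for in the filter report (records in = out + rejected).
#'
#' @param maf either a file path or a data frame of raw MAF rows.
#' @param study_id study label (used when `maf` is a path or lacks one).
#' @param config a [filter_config()].
#' @return object of class `filter_result`: list with `records` (surviving
#'   rows), `carriers` (see [patient_protein_changes()]), `report` (stage
#'   table) and `rejections` from the read stage.
#' @export
filter_variants <- function(maf, study_id = "STUDY", config = filter_config()) {
  rd <- if (is.character(maf)) read_maf(maf, study_id)
        else validate_maf_records(maf, study_id)
  report <- rd$report
  recs <- rd$records

  acc <- validate_consistency(recs)
  out <- recs[acc, , drop = FALSE]
  report <- add_report_stage(report, "consistency", nrow(recs), nrow(out))
  recs <- out

  out <- select_missense_snv(recs, config)
  report <- add_report_stage(report, "missense_snv", nrow(recs), nrow(out))
  recs <- out

  out <- apply_support_filter(recs, config)
  report <- add_report_stage(report, "support", nrow(recs), nrow(out))
  recs <- out

  out <- apply_population_filter(recs, config)
  report <- add_report_stage(report, "population", nrow(recs), nrow(out))
  recs <- out
  rownames(recs) <- NULL

  structure(list(records = recs, carriers = patient_protein_changes(recs),
                 report = report, rejections = rd$rejections),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("High-confidence missense SNV filter\n")
  print(x$report, row.names = FALSE)
  cat(sprintf("%d records retained; %d distinct (patient, protein change) pairs\n",
              nrow(x$records), nrow(x$carriers)))
  invisible(x)
}
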