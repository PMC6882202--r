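# End-to-end orchestration: filter -> recurrence -> epitopes -> ranking,
# with optional robustness resampling and homopolymer QC. Intermediate
# results are persisted as TSV when an output directory is given, so any
# stage can be re-run and diffed independently; identical config + seed
# produce byte-identical TSV outputs.

#' Pipeline configuration
#'
#' Collects every stage parameter with defaults matching the package's
#' standard settings (5 alternate reads, 10% VAF, 1% population-AF cutoff,
#' cohorts over 100 patients, 1% recurrence, 9-11-mer windows, strong
#' binders, 1000 resampling iterations at 50/80/90/95% false positives).
#'
#' @param maf MAF data frame or file path.
#' @param clinical clinical table (data frame or path).
#' @param proteome named sequence vector or FASTA path.
#' @param predictor a `binding_predictor`.
#' @param hla_freq,incidence population tables (data frames or paths);
#'   default the shipped U.S. tables.
#' @param hotspots optional hotspot table (`gene`, `position`, `flagged`).
#' @param filter a [filter_config()].
#' @param min_cohort minimum cohort size.
#' @param recurrence_threshold recurrence frequency threshold.
#' @param alleles allele panel.
#' @param lengths peptide window lengths.
#' @param keep binder classes retained as candidates.
#' @param profiles optional patient profiles for robustness resampling.
#' @param resampling a [resampling_config()].
#' @param qc_contexts optional variant context table for homopolymer QC
#'   (`study_id`, `patient_id`, `gene`, `position`, `ref_aa`, `alt_aa`,
#'   `context11`).
#' @param seed master seed echoed into stage seeds.
#' @param out_dir optional output directory for persisted TSVs.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(maf, clinical, proteome, predictor,
                            hla_freq = us_hla_frequencies(),
                            incidence = us_incidence(),
                            hotspots = NULL,
                            filter = filter_config(),
                            min_cohort = 101L,
                            recurrence_threshold = 0.01,
                            alleles = default_allele_panel(),
                            lengths = c(9L, 10L, 11L),
                            keep = "strong",
                            profiles = NULL,
                            resampling = resampling_config(),
                            qc_contexts = NULL,
                            seed = 1L,
                            out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

# A single unnamed string is a file path; anything else is in-memory data
# (a named sequence vector is data, not a path).
load_if_path <- function(x, loader) {
  if (is.character(x) && length(x) == 1 && is.null(names(x))) loader(x) else x
}

#' Run the full candidate-identification pipeline
#'
#' Stages run in order: variant filtering, per-cohort recurrence calling,
#' neo-epitope candidate generation, expected-patient ranking and coverage;
#' robustness resampling and homopolymer QC run when their inputs are
#' provided. Any stage hard error aborts the run naming the stage.
#'
#' @param config a [pipeline_config()].
#' @return object of class `recurneo_run`: list with `filter`, `recurrent`,
#'   `codon_groups`, `hotspot`, `candidates`, `ranking`, `coverage`,
#'   `robustness`, `qc`, and a `manifest` of per-stage record counts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }
  clinical <- load_if_path(config$clinical, read_clinical)
  proteome <- load_if_path(config$proteome, read_proteome)
  hla_freq <- load_if_path(config$hla_freq, read_hla_frequencies)
  incidence <- load_if_path(config$incidence, read_incidence)

  filt <- run_stage("filter", {
    filter_variants(config$maf, study_id = "NA", config = config$filter)
  })
  cohorts <- run_stage("recurrence", eligible_cohorts(clinical, config$min_cohort))
  carriers <- filt$carriers[filt$carriers$patient_id %in% cohorts$patient_id, ,
                            drop = FALSE]
  recurrent <- run_stage("recurrence", {
    call_recurrent(carriers, cohorts, config$recurrence_threshold)
  })
  uniq <- unique_changes(recurrent)
  groups <- group_by_codon(recurrent)
  hs <- if (!is.null(config$hotspots)) {
    run_stage("recurrence", hotspot_overlap(groups, config$hotspots))
  } else NULL

  candidates <- run_stage("epitopes", {
    neo_candidates(uniq, proteome, config$predictor, config$alleles,
                   config$lengths, config$keep)
  })

  variant_freq <- run_stage("ranking", {
    observed_frequencies(carriers, cohorts, changes = uniq)
  })
  ranking <- run_stage("ranking", {
    rank_candidates(candidates, hla_freq, incidence, variant_freq)
  })
  coverage <- run_stage("ranking", {
    coverage_table(candidates, hla_freq, incidence, variant_freq)
  })

  robustness <- NULL
  if (!is.null(config$profiles) && nrow(candidates) > 0) {
    robustness <- run_stage("robustness", {
      resample_false_positives(config$profiles, candidates,
                               config$resampling)
    })
  }
  qc <- NULL
  if (!is.null(config$qc_contexts)) {
    qc <- run_stage("qc", run_repeat_qc(config$qc_contexts))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("recurneo")),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    counts = list(
      records_read = filt$report$n_in[1],
      records_filtered = nrow(filt$records),
      carriers = nrow(filt$carriers),
      eligible_patients = nrow(cohorts),
      recurrent_calls = nrow(recurrent),
      unique_changes = nrow(uniq),
      codon_groups = nrow(groups),
      candidates = nrow(candidates)),
    filter_report = filt$report)

  res <- structure(list(filter = filt, recurrent = recurrent,
                        codon_groups = groups, hotspot = hs,
                        candidates = candidates, ranking = ranking,
                        coverage = coverage, robustness = robustness,
                        qc = qc, manifest = manifest),
                   class = "recurneo_run")
  if (!is.null(config$out_dir)) write_run(res, config$out_dir)
  res
}

# Persist all stage outputs as diffable TSV plus a JSON manifest.
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(run$filter$records, file.path(out_dir, "filtered_variants.tsv"))
  write_tsv(run$filter$report, file.path(out_dir, "filter_report.tsv"))
  write_tsv(run$filter$carriers, file.path(out_dir, "carriers.tsv"))
  write_tsv(run$recurrent, file.path(out_dir, "recurrent_variants.tsv"))
  write_tsv(run$codon_groups, file.path(out_dir, "codon_groups.tsv"))
  write_tsv(run$candidates, file.path(out_dir, "candidates.tsv"))
  write_tsv(run$ranking, file.path(out_dir, "ranking.tsv"))
  cov <- data.frame(disease = rownames(run$coverage$cells),
                    run$coverage$cells, check.names = FALSE)
  write_tsv(cov, file.path(out_dir, "coverage.tsv"))
  if (!is.null(run$robustness)) {
    write_tsv(as.data.frame(run$robustness),
              file.path(out_dir, "robustness.tsv"))
  }
  if (!is.null(run$qc)) write_tsv(run$qc, file.path(out_dir, "qc.tsv"))
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.recurneo_run <- function(x, ...) {
  cat("recurneo pipeline run\n")
  cnt <- x$manifest$counts
  cat(sprintf("  %d MAF records read, %d retained after filtering\n",
              cnt$records_read, cnt$records_filtered))
  cat(sprintf("  %d recurrent calls (%d unique changes, %d codon groups)\n",
              cnt$recurrent_calls, cnt$unique_changes, cnt$codon_groups))
  cat(sprintf("  %d neo-epitope candidates retained\n", cnt$candidates))
  if (!is.null(x$robustness)) cat("  robustness resampling: yes\n")
  if (!is.null(x$qc)) cat("  homopolymer QC: yes\n")
  invisible(x)
}

#' @export
summary.recurneo_run <- function(object, n_top = 10, ...) {
  cat("Filter report:\n")
  print(object$filter$report, row.names = FALSE)
  cat("\nTop candidates by expected patients per year:\n")
  cols <- intersect(c("gene", "position", "ref_aa", "alt_aa", "allele",
                      "peptide", "mut_ic50_nm", "n_h"),
                    names(object$ranking))
  print(utils::head(object$ranking[cols], n_top), row.names = FALSE)
  invisible(object)
}
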