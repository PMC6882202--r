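# Synthetic cohort generator with ground-truth labels.
#
# Emulates the inputs of a cohort-level recurrence analysis: MAF-dialect
# variant tables with planted recurrent protein changes, read-depth/VAF
# structure, labelled contaminant records violating exactly one filter
# each, patient HLA genotypes drawn under Hardy-Weinberg independence, a
# random proteome, and population tables. Every generator is a pure
# function of (config, seed): private RNG streams leave the caller's RNG
# untouched.

#' Simulate a random proteome
#'
#' Uniform-random sequences over the 20 standard amino acids, written as
#' `GENE0001`, `GENE0002`, ... Minimum length 23 so every interior position
#' admits all 11-mer windows.
#'
#' @param n_genes number of sequences.
#' @param length_range (min, max) sequence lengths; min must be >= 23.
#' @param seed RNG seed.
#' @return named character vector of sequences.
#' @export
simulate_proteome <- function(n_genes, length_range = c(300L, 700L), seed = 1L) {
  if (length_range[1] < 23) stopf("minimum protein length must be >= 23")
  with_private_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n_genes, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(AA20, L, replace = TRUE), collapse = "")
    }, character(1))
    names(seqs) <- sprintf("GENE%04d", seq_len(n_genes))
    seqs
  })
}

#' Write sequences as a FASTA file
#'
#' @param seqs named character vector of protein sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(seqs, path) {
  aa <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Cohort simulation configuration
#'
#' @param studies data frame with `study_id`, `n_patients`.
#' @param planted data frame of planted protein changes: `gene`,
#'   `position`, `alt_aa`, `study_id`, and either `carriers` (exact mode:
#'   that many carriers, drawn at random from the cohort) or `frequency`
#'   (stochastic mode: Binomial(n_patients, frequency) carriers). The
#'   reference residue is taken from the proteome.
#' @param background_per_patient mean of the Poisson count of additional
#'   non-recurrent changes per patient. In exact mode these are drawn
#'   without cross-patient duplication so they can never reach the
#'   recurrence threshold by collision.
#' @param depth_mean,depth_dispersion negative-binomial read-depth model
#'   (mu / size parameterization).
#' @param vaf_shape (alpha, beta) of the Beta VAF distribution, truncated
#'   so planted and background records pass the support filter.
#' @param contaminants named integer vector of labelled filter-violating
#'   records to add per study; names from `contaminant_labels()`.
#' @param seed RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(studies, planted = NULL, background_per_patient = 2,
                       depth_mean = 80, depth_dispersion = 10,
                       vaf_shape = c(8, 12), contaminants = NULL, seed = 1L) {
  stopifnot(all(c("study_id", "n_patients") %in% names(studies)))
  if (!is.null(planted)) {
    stopifnot(all(c("gene", "position", "alt_aa", "study_id") %in% names(planted)))
    if (!("carriers" %in% names(planted)) && !("frequency" %in% names(planted))) {
      stopf("planted changes need a 'carriers' or 'frequency' column")
    }
  }
  if (!is.null(contaminants)) {
    bad <- setdiff(names(contaminants), contaminant_labels()$label)
    if (length(bad) > 0) {
      stopf("unknown contaminant label(s): %s", paste(bad, collapse = ", "))
    }
  }
  structure(list(studies = studies, planted = planted,
                 background_per_patient = background_per_patient,
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 vaf_shape = vaf_shape, contaminants = contaminants,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Contaminant record labels
#'
#' Each label names the single filter its records violate and the pipeline
#' stage expected to reject them.
#'
#' @return data frame with `label` and `stage`.
#' @export
contaminant_labels <- function() {
  data.frame(
    label = c("missing_transcript", "bad_status", "depth_mismatch",
              "multi_nt", "wrong_classification", "wrong_type", "bad_hgvsp",
              "low_support", "low_vaf", "high_pop_af"),
    stage = c("read", "consistency", "consistency", "consistency",
              "missense_snv", "missense_snv", "missense_snv",
              "support", "support", "population"),
    stringsAsFactors = FALSE)
}

# A clean passing MAF row for patient/change; fields overridden by
# contaminant fabrication below.
sim_maf_row <- function(patient, study, gene, gene_index, position, ref_aa,
                        alt_aa, depth, alt_count, pop_af = NA_real_) {
  data.frame(
    Tumor_Sample_Barcode = patient, Hugo_Symbol = gene,
    Transcript_ID = sprintf("ENST%08d", gene_index),
    HGVSp_Short = format_hgvsp(position, ref_aa, alt_aa),
    Chromosome = as.character(1 + (gene_index - 1) %% 22),
    Start_Position = 3L * position,
    Reference_Allele = DNA4[1 + (position %% 4)],
    Tumor_Seq_Allele2 = DNA4[1 + ((position + 1) %% 4)],
    Variant_Type = "SNP", Variant_Classification = "Missense_Mutation",
    Mutation_Status = "Somatic", t_depth = depth,
    t_ref_count = depth - alt_count, t_alt_count = alt_count,
    max_pop_af = pop_af, study_id = study, stringsAsFactors = FALSE)
}

# Depth and alt count passing the support filter (alt >= 5, VAF >= 0.1).
sim_support <- function(n, config) {
  depth <- stats::rnbinom(n, mu = config$depth_mean,
                          size = config$depth_dispersion)
  depth <- pmax(depth, 50L)
  vaf <- stats::rbeta(n, config$vaf_shape[1], config$vaf_shape[2])
  alt <- pmax(round(vaf * depth), 5L)
  alt <- pmin(alt, depth)
  bad <- alt / depth < 0.1
  alt[bad] <- ceiling(0.1 * depth[bad])
  data.frame(depth = as.integer(depth), alt = as.integer(alt))
}

#' Simulate a synthetic cohort
#'
#' Fabricates a MAF table, clinical table and truth record for the
#' configured studies: planted changes at exact carrier counts or Binomial
#' frequencies, Poisson background changes per patient, and contaminant
#' rows each violating exactly the filter its label names while passing all
#' others.
#'
#' @param proteome named sequences from [simulate_proteome()].
#' @param config a [sim_config()].
#' @return list with `maf` (data frame in MAF dialect), `clinical`
#'   (`patient_id`, `study_id`) and `truth` (planted carrier assignments
#'   and contaminant labels).
#' @export
simulate_cohort <- function(proteome, config) {
  with_private_seed(config$seed, {
    clinical <- do.call(rbind, lapply(seq_len(nrow(config$studies)), function(i) {
      s <- config$studies$study_id[i]
      n <- config$studies$n_patients[i]
      data.frame(patient_id = sprintf("%s-P%04d", s, seq_len(n)),
                 study_id = s, stringsAsFactors = FALSE)
    }))
    gene_index <- stats::setNames(seq_along(proteome), names(proteome))
    rows <- list()
    truth_planted <- list()

    # planted recurrent changes
    if (!is.null(config$planted)) {
      for (i in seq_len(nrow(config$planted))) {
        pl <- config$planted[i, ]
        if (!(pl$gene %in% names(proteome))) {
          stopf("planted gene %s not in proteome", pl$gene)
        }
        ref <- substr(proteome[[pl$gene]], pl$position, pl$position)
        if (ref == pl$alt_aa) stopf("planted alt equals reference residue")
        cohort <- clinical$patient_id[clinical$study_id == pl$study_id]
        n_car <- if (!is.null(pl$carriers) && !is.na(pl$carriers)) {
          as.integer(pl$carriers)
        } else {
          stats::rbinom(1, length(cohort), pl$frequency)
        }
        if (n_car > length(cohort)) {
          stopf("planted carriers exceed cohort size for %s", pl$study_id)
        }
        carriers <- sample(cohort, n_car)
        sup <- sim_support(n_car, config)
        if (n_car > 0) {
          rows[[length(rows) + 1L]] <- sim_maf_row(
            carriers, pl$study_id, pl$gene, gene_index[[pl$gene]],
            pl$position, ref, pl$alt_aa, sup$depth, sup$alt)
        }
        truth_planted[[length(truth_planted) + 1L]] <- data.frame(
          gene = pl$gene, position = pl$position, ref_aa = ref,
          alt_aa = pl$alt_aa, study_id = pl$study_id, n_carriers = n_car,
          cohort_size = length(cohort),
          true_frequency = if (!is.null(pl$frequency) && !is.na(pl$frequency))
            pl$frequency else n_car / length(cohort),
          stringsAsFactors = FALSE)
      }
    }

    # background: non-recurrent passenger changes, unique (gene, position)
    # slots across the whole run so none can collide into recurrence
    planted_slots <- if (is.null(config$planted)) character() else
      paste(config$planted$gene, config$planted$position, sep = "\r")
    n_bg <- stats::rpois(nrow(clinical), config$background_per_patient)
    total_bg <- sum(n_bg)
    if (total_bg > 0) {
      lens <- nchar(proteome)
      slots_per_gene <- lens - 22L  # interior positions 12..L-11
      cum <- cumsum(as.numeric(slots_per_gene))
      if (total_bg > cum[length(cum)] - length(planted_slots)) {
        stopf("background rate too high for proteome size")
      }
      picked <- character(0)
      slot_gene <- integer(total_bg); slot_pos <- integer(total_bg)
      k <- 0L
      while (k < total_bg) {
        u <- sample.int(cum[length(cum)], 1)
        g <- findInterval(u - 0.5, c(0, cum))
        pos <- 11L + (u - c(0, cum)[g])
        key <- paste(names(proteome)[g], pos, sep = "\r")
        if (key %in% picked || key %in% planted_slots) next
        picked <- c(picked, key)
        k <- k + 1L
        slot_gene[k] <- g; slot_pos[k] <- as.integer(pos)
      }
      idx <- 0L
      for (p in seq_len(nrow(clinical))) {
        if (n_bg[p] == 0) next
        take <- idx + seq_len(n_bg[p]); idx <- idx + n_bg[p]
        for (t in take) {
          g <- slot_gene[t]; pos <- slot_pos[t]
          ref <- substr(proteome[[g]], pos, pos)
          alt <- sample(setdiff(AA20, ref), 1)
          sup <- sim_support(1, config)
          rows[[length(rows) + 1L]] <- sim_maf_row(
            clinical$patient_id[p], clinical$study_id[p],
            names(proteome)[g], g, pos, ref, alt, sup$depth, sup$alt)
        }
      }
    }

    # contaminants: each violates exactly its labelled filter
    truth_contaminants <- list()
    if (!is.null(config$contaminants)) {
      labels <- contaminant_labels()
      for (lab in names(config$contaminants)) {
        n_con <- config$contaminants[[lab]]
        for (j in seq_len(n_con)) {
          p <- sample.int(nrow(clinical), 1)
          g <- sample.int(length(proteome), 1)
          pos <- sample(12:(nchar(proteome[[g]]) - 11L), 1)
          ref <- substr(proteome[[g]], pos, pos)
          alt <- sample(setdiff(AA20, ref), 1)
          sup <- sim_support(1, config)
          row <- sim_maf_row(clinical$patient_id[p], clinical$study_id[p],
                             names(proteome)[g], g, pos, ref, alt,
                             sup$depth, sup$alt)
          row <- switch(lab,
            missing_transcript = { row$Transcript_ID <- ""; row },
            bad_status = { row$Mutation_Status <- "LOH"; row },
            depth_mismatch = { row$t_ref_count <- row$t_ref_count + 1L; row },
            multi_nt = { row$Reference_Allele <- "AC"; row },
            wrong_classification = { row$Variant_Classification <- "Silent"; row },
            wrong_type = { row$Variant_Type <- "DEL"
                           row$Variant_Classification <- "Frame_Shift_Del"; row },
            bad_hgvsp = { row$HGVSp_Short <- sprintf("p.%s%d*", ref, pos); row },
            low_support = { row$t_depth <- 40L; row$t_alt_count <- 4L
                            row$t_ref_count <- 36L; row },
            low_vaf = { row$t_depth <- 100L; row$t_alt_count <- 6L
                        row$t_ref_count <- 94L; row },
            high_pop_af = { row$max_pop_af <- 0.02; row })
          rows[[length(rows) + 1L]] <- row
          truth_contaminants[[length(truth_contaminants) + 1L]] <- data.frame(
            patient_id = row$Tumor_Sample_Barcode, gene = row$Hugo_Symbol,
            start_position = row$Start_Position, label = lab,
            stage = labels$stage[labels$label == lab],
            stringsAsFactors = FALSE)
        }
      }
    }

    maf <- if (length(rows) == 0) {
      empty <- sim_maf_row("x", "x", "x", 1L, 1L, "A", "C", 10L, 5L)[0, ]
      empty
    } else do.call(rbind, rows)
    maf <- maf[order(maf$study_id, maf$Tumor_Sample_Barcode, maf$Hugo_Symbol,
                     maf$Start_Position), , drop = FALSE]
    rownames(maf) <- NULL
    list(maf = maf,
         clinical = clinical,
         truth = list(
           planted = if (length(truth_planted)) do.call(rbind, truth_planted)
                     else NULL,
           contaminants = if (length(truth_contaminants))
             do.call(rbind, truth_contaminants) else NULL))
  })
}

#' Simulate patient HLA genotypes
#'
#' Per locus, two independent draws from the locus allele-frequency
#' distribution (Hardy-Weinberg independence); frequencies may sum to less
#' than one, the remainder standing for alleles outside the panel (emitted
#' as `<locus>*other` placeholders). The profile allele set is the union
#' over loci.
#'
#' @param patient_ids character vector.
#' @param locus_freqs named list (one element per locus, e.g. `"HLA-A"`) of
#'   named frequency vectors.
#' @param seed RNG seed.
#' @return list of allele-set character vectors, named by patient.
#' @export
simulate_hla_genotypes <- function(patient_ids, locus_freqs, seed = 1L) {
  for (l in names(locus_freqs)) {
    assert_fraction(locus_freqs[[l]], sprintf("locus %s frequencies", l))
    if (sum(locus_freqs[[l]]) > 1 + 1e-9) {
      stopf("locus %s frequencies sum to more than 1", l)
    }
  }
  with_private_seed(seed, {
    out <- lapply(patient_ids, function(p) {
      alleles <- character(0)
      for (l in names(locus_freqs)) {
        f <- locus_freqs[[l]]
        probs <- c(f, other = max(0, 1 - sum(f)))
        draws <- sample(names(probs), 2, replace = TRUE, prob = probs)
        draws[draws == "other"] <- paste0(l, "*other")
        alleles <- c(alleles, draws)
      }
      sort(unique(alleles))
    })
    names(out) <- patient_ids
    out
  })
}

#' Build patient profiles from a cohort and its genotypes
#'
#' Combines the carrier relation of a filtered cohort with simulated (or
#' supplied) HLA genotypes into the profile table consumed by the
#' robustness module.
#'
#' @param carriers carrier relation (see [patient_protein_changes()]).
#' @param clinical clinical table.
#' @param genotypes named list of allele sets per patient.
#' @return profile data frame with list columns `hla_alleles`, `changes`.
#' @export
build_profiles <- function(carriers, clinical, genotypes) {
  tok <- change_token(carriers$gene, carriers$position, carriers$ref_aa,
                      carriers$alt_aa)
  by_patient <- split(tok, carriers$patient_id)
  data.frame(
    patient_id = clinical$patient_id, study_id = clinical$study_id,
    hla_alleles = I(unname(genotypes[clinical$patient_id])),
    changes = I(lapply(clinical$patient_id, function(p) {
      unique(by_patient[[p]]) %||% character(0)
    })),
    stringsAsFactors = FALSE)
}

#' Simulate population tables
#'
#' Random allele-frequency and incidence tables within the given ranges;
#' deterministic per seed. For the shipped U.S. values use
#' [us_hla_frequencies()] and [us_incidence()].
#'
#' @param n_alleles,n_diseases table sizes.
#' @param freq_range,incidence_range value ranges.
#' @param seed RNG seed.
#' @return list with `hla_freq` and `incidence` data frames.
#' @export
simulate_population_tables <- function(n_alleles = 11L, n_diseases = 18L,
                                       freq_range = c(0.01, 0.25),
                                       incidence_range = c(1000L, 250000L),
                                       seed = 1L) {
  with_private_seed(seed, {
    list(
      hla_freq = data.frame(
        allele = sprintf("HLA-A*%02d:01", seq_len(n_alleles)),
        frequency = stats::runif(n_alleles, freq_range[1], freq_range[2]),
        stringsAsFactors = FALSE),
      incidence = data.frame(
        disease = sprintf("DISEASE%02d", seq_len(n_diseases)),
        annual_cases = sample(incidence_range[1]:incidence_range[2],
                              n_diseases, replace = TRUE),
        stringsAsFactors = FALSE))
  })
}
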