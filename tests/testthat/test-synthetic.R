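test_that("simulated proteomes are deterministic per seed with unique ids", {
  p1 <- simulate_proteome(5, c(30, 50), seed = 7)
  p2 <- simulate_proteome(5, c(30, 50), seed = 7)
  expect_identical(p1, p2)
  expect_false(identical(p1, simulate_proteome(5, c(30, 50), seed = 8)))
  expect_equal(anyDuplicated(names(p1)), 0)
  expect_true(all(nchar(p1) >= 30 & nchar(p1) <= 50))
  expect_error(simulate_proteome(5, c(10, 50)), ">= 23")
  # FASTA round-trip through Biostrings
  path <- tempfile(fileext = ".fasta")
  write_proteome_fasta(p1, path)
  expect_identical(read_proteome(path), p1)
})

test_that("proteome residue frequencies are near-uniform over the 20-letter alphabet", {
  p <- simulate_proteome(40, c(500, 700), seed = 21)
  residues <- strsplit(paste(p, collapse = ""), "")[[1]]
  counts <- table(factor(residues, levels = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  # goodness of fit against the uniform multinomial (20 cells)
  gof <- stats::chisq.test(counts, p = rep(0.05, 20))
  expect_gt(gof$p.value, 0.001)
  # and every individual cell within 4 SE of 0.05
  n <- length(residues)
  se <- sqrt(0.05 * 0.95 / n)
  expect_true(all(abs(counts / n - 0.05) < 4 * se))
})

test_that("exact-mode planted changes round-trip through the filter and recurrence stages", {
  prot <- simulate_proteome(8, c(60, 100), seed = 2)
  ref <- substr(prot[["GENE0003"]], 40, 40)
  planted <- data.frame(gene = "GENE0003", position = 40L,
                        alt_aa = setdiff(c("A", "V"), ref)[1],
                        study_id = "STUDY-A", carriers = 5L)
  cfg <- sim_config(studies = data.frame(study_id = "STUDY-A", n_patients = 200),
                    planted = planted, background_per_patient = 0.5, seed = 31)
  sim <- simulate_cohort(prot, cfg)
  expect_equal(sim$truth$planted$n_carriers, 5L)
  f <- filter_variants(sim$maf)
  rec <- call_recurrent(f$carriers, eligible_cohorts(sim$clinical))
  hit <- rec[rec$gene == "GENE0003" & rec$position == 40, ]
  expect_equal(hit$n_carriers, 5L)
  expect_equal(hit$frequency, 0.025)
  # determinism of the whole cohort
  sim2 <- simulate_cohort(prot, cfg)
  expect_identical(sim$maf, sim2$maf)
})

test_that("each contaminant is rejected at exactly its labelled stage", {
  prot <- simulate_proteome(6, c(60, 100), seed = 5)
  labels <- contaminant_labels()
  contam <- stats::setNames(rep(2L, nrow(labels)), labels$label)
  cfg <- sim_config(studies = data.frame(study_id = "S", n_patients = 150),
                    planted = NULL, background_per_patient = 1,
                    contaminants = contam, seed = 13)
  sim <- simulate_cohort(prot, cfg)
  res <- filter_variants(sim$maf)
  rep <- res$report
  stage_rejects <- stats::setNames(rep$n_rejected, rep$stage)
  expected <- table(sim$truth$contaminants$stage)
  for (s in names(expected)) {
    expect_equal(unname(stage_rejects[s]), unname(as.integer(expected[s])),
                 info = s)
  }
  # stages not targeted by any contaminant reject nothing
  for (s in setdiff(rep$stage, names(expected))) {
    expect_equal(unname(stage_rejects[s]), 0L, info = s)
  }
  # all clean records survive
  n_clean <- nrow(sim$maf) - sum(expected)
  expect_equal(nrow(res$records), n_clean)
})

test_that("stochastic-mode carrier counts are Binomial around the planted frequency", {
  prot <- simulate_proteome(4, c(40, 60), seed = 1)
  ref <- substr(prot[["GENE0001"]], 20, 20)
  alt <- setdiff(c("A", "V"), ref)[1]
  n <- 400; freq <- 0.05
  counts <- vapply(1:60, function(s) {
    cfg <- sim_config(studies = data.frame(study_id = "S", n_patients = n),
                      planted = data.frame(gene = "GENE0001", position = 20L,
                                           alt_aa = alt, study_id = "S",
                                           frequency = freq),
                      background_per_patient = 0, seed = 1000 + s)
    simulate_cohort(prot, cfg)$truth$planted$n_carriers
  }, 0)
  se <- sqrt(n * freq * (1 - freq) / length(counts))
  expect_lt(abs(mean(counts) - n * freq), 3 * se)
})

test_that("HLA genotype simulation follows Hardy-Weinberg carrier rates", {
  freqs <- list("HLA-A" = c("HLA-A*02:01" = 0.2, "HLA-A*01:01" = 0))
  pts <- sprintf("P%04d", 1:4000)
  geno <- simulate_hla_genotypes(pts, freqs, seed = 9)
  expect_identical(geno, simulate_hla_genotypes(pts, freqs, seed = 9))
  # frequency-zero allele never drawn
  expect_false(any(vapply(geno, function(a) "HLA-A*01:01" %in% a, TRUE)))
  carrier <- mean(vapply(geno, function(a) "HLA-A*02:01" %in% a, TRUE))
  expected <- 1 - 0.8^2
  se <- sqrt(expected * (1 - expected) / length(pts))
  expect_lt(abs(carrier - expected), 3 * se)
  # frequency one: every patient homozygous for the single allele
  geno1 <- simulate_hla_genotypes(pts[1:50],
                                  list("HLA-B" = c("HLA-B*07:02" = 1)), seed = 2)
  expect_true(all(vapply(geno1, identical, TRUE, "HLA-B*07:02")))
})

test_that("toy predictor is deterministic, motif-sensitive and rank-calibrated", {
  pred <- toy_binding_predictor(seed = 6)
  a <- pred$predict(c("KLLEIFTEL", "KLLEIFTEL"), rep("HLA-A*02:01", 2))
  expect_equal(a$ic50_nm[1], a$ic50_nm[2])
  # independent predictor objects with the same seed agree
  pred2 <- toy_binding_predictor(seed = 6)
  expect_equal(pred2$predict("KLLEIFTEL", "HLA-A*02:01"), a[1, ])
  # strong-binder rate over random peptides close to the 0.5% design rate
  set.seed(99)
  peps <- vapply(1:20000, function(i) {
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 9,
                 replace = TRUE), collapse = "")
  }, "")
  cls <- pred$predict(peps, rep("HLA-B*07:02", length(peps)))$binder_class
  rate <- mean(cls == "strong")
  # sampling noise from the query sample plus the finite reference sample
  # that set the class threshold
  se <- sqrt(0.005 * 0.995 * (1 / length(peps) + 1 / 10000))
  expect_lt(abs(rate - 0.005), 3 * se)
  expect_gt(mean(cls == "weak"), 0)
})

test_that("random population tables are seed-deterministic and well-formed", {
  t1 <- simulate_population_tables(seed = 4)
  t2 <- simulate_population_tables(seed = 4)
  expect_identical(t1, t2)
  expect_equal(nrow(t1$hla_freq), 11)
  expect_equal(nrow(t1$incidence), 18)
  expect_true(all(t1$hla_freq$frequency > 0 & t1$hla_freq$frequency < 1))
  expect_true(all(t1$incidence$annual_cases >= 0))
})

test_that("profiles built from a cohort expose each patient's changes and alleles", {
  prot <- simulate_proteome(5, c(60, 80), seed = 3)
  ref <- substr(prot[["GENE0002"]], 30, 30)
  planted <- data.frame(gene = "GENE0002", position = 30L,
                        alt_aa = setdiff(c("A", "V"), ref)[1],
                        study_id = "S", carriers = 4L)
  cfg <- sim_config(studies = data.frame(study_id = "S", n_patients = 120),
                    planted = planted, background_per_patient = 0, seed = 8)
  sim <- simulate_cohort(prot, cfg)
  f <- filter_variants(sim$maf)
  geno <- simulate_hla_genotypes(sim$clinical$patient_id,
                                 list("HLA-A" = c("HLA-A*02:01" = 0.3)), seed = 1)
  profs <- build_profiles(f$carriers, sim$clinical, geno)
  expect_equal(nrow(profs), 120)
  tok <- paste0("GENE0002:", ref, 30, planted$alt_aa)
  n_tok <- sum(vapply(profs$changes, function(ch) tok %in% ch, TRUE))
  expect_equal(n_tok, 4)
})
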