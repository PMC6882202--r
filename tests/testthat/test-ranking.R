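vf_row <- function(disease, frequency, gene = "PIK3CA", position = 1047L,
                   ref = "H", alt = "R") {
  data.frame(gene = gene, position = position, ref_aa = ref, alt_aa = alt,
             disease = disease, frequency = frequency, stringsAsFactors = FALSE)
}

hla1 <- data.frame(allele = "HLA-A*02:01", frequency = 0.2036)
cand1 <- data.frame(gene = "PIK3CA", position = 1047L, ref_aa = "H",
                    alt_aa = "R", allele = "HLA-A*02:01",
                    stringsAsFactors = FALSE)

test_that("expected patients is f_h times the incidence-weighted variant frequency sum", {
  inc <- data.frame(disease = "d1", annual_cases = 10000L)
  ep <- expected_patients("PIK3CA", 1047L, "H", "R", "HLA-A*02:01",
                          hla1, inc, vf_row("d1", 0.05))
  expect_equal(ep$n_h, 0.2036 * 0.05 * 10000)  # 101.8
  expect_equal(ep$n_h, 101.8)
  # no observed frequency anywhere -> 0
  ep0 <- expected_patients("PIK3CA", 1047L, "H", "R", "HLA-A*02:01",
                           hla1, inc, vf_row("d1", 0.05)[0, ])
  expect_equal(ep0$n_h, 0)
  # additivity over diseases
  inc2 <- data.frame(disease = c("d1", "d2"), annual_cases = c(10000L, 4000L))
  vf2 <- rbind(vf_row("d1", 0.05), vf_row("d2", 0.02))
  ep2 <- expected_patients("PIK3CA", 1047L, "H", "R", "HLA-A*02:01",
                           hla1, inc2, vf2)
  one <- function(d, vf) expected_patients("PIK3CA", 1047L, "H", "R",
                                           "HLA-A*02:01", hla1,
                                           inc2[inc2$disease == d, ], vf)$n_h
  expect_equal(ep2$n_h, one("d1", vf2) + one("d2", vf2))
  # diseases absent from the incidence table do not contribute
  vf3 <- rbind(vf2, vf_row("d3", 0.5))
  expect_equal(expected_patients("PIK3CA", 1047L, "H", "R", "HLA-A*02:01",
                                 hla1, inc2, vf3)$n_h, ep2$n_h)
  # missing allele is a hard error
  expect_error(expected_patients("PIK3CA", 1047L, "H", "R", "HLA-Z*99:99",
                                 hla1, inc2, vf2), "HLA-Z")
  # diploid carrier-frequency variant of the statistic
  ep_d <- expected_patients("PIK3CA", 1047L, "H", "R", "HLA-A*02:01",
                            hla1, inc, vf_row("d1", 0.05), diploid = TRUE)
  expect_equal(ep_d$n_h, (1 - (1 - 0.2036)^2) * 0.05 * 10000)
  expect_gt(ep_d$n_h, ep$n_h)
})

test_that("candidate ranking is descending in n_h with deterministic tie-breaks", {
  inc <- data.frame(disease = "d1", annual_cases = 10000L)
  cands <- rbind(cand1,
                 data.frame(gene = "KRAS", position = 12L, ref_aa = "G",
                            alt_aa = "D", allele = "HLA-A*02:01"),
                 data.frame(gene = "BRAF", position = 600L, ref_aa = "V",
                            alt_aa = "E", allele = "HLA-A*02:01"))
  vf <- rbind(vf_row("d1", 0.02),
              vf_row("d1", 0.08, gene = "KRAS", position = 12L, ref = "G", alt = "D"),
              vf_row("d1", 0.08, gene = "BRAF", position = 600L, ref = "V", alt = "E"))
  rk <- rank_candidates(cands, hla1, inc, vf)
  expect_equal(rk$gene, c("BRAF", "KRAS", "PIK3CA"))  # ties: lexicographic
  expect_true(all(diff(rk$n_h) <= 0))
  expect_equal(rk$expected_d1, rk$n_h)
  # repeatable
  expect_identical(rk, rank_candidates(cands[c(2, 3, 1), ], hla1, inc, vf))
})

test_that("prob_at_least_one matches exhaustive outcome enumeration", {
  expect_equal(prob_at_least_one(c(0.5, 0.5)), 0.75)
  expect_equal(prob_at_least_one(numeric(0)), 0)
  expect_error(prob_at_least_one(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  for (n in c(1, 3, 7, 10)) {
    freqs <- stats::runif(n, 0, 0.5)
    expect_equal(prob_at_least_one(freqs), enum_prob_at_least_one(freqs))
  }
})

test_that("coverage cells follow the independence model and its degeneracies", {
  inc <- data.frame(disease = "d1", annual_cases = 10000L)
  # single candidate: cell equals the expected-patient term
  cov1 <- coverage_table(cand1, hla1, inc, vf_row("d1", 0.05))
  expect_equal(unname(cov1$cells["d1", "HLA-A*02:01"]), 101.8)
  expect_equal(unname(cov1$candidate_counts), 1L)
  # no candidates for an allele: zero cell and count
  hla2 <- rbind(hla1, data.frame(allele = "HLA-B*07:02", frequency = 0.0651))
  cov2 <- coverage_table(cand1, hla2, inc, vf_row("d1", 0.05))
  expect_equal(unname(cov2$cells["d1", "HLA-B*07:02"]), 0)
  expect_equal(unname(cov2$candidate_counts["HLA-B*07:02"]), 0L)
  # two candidates at r = 0.5 each: 0.75 * N * f
  cands <- rbind(cand1, data.frame(gene = "KRAS", position = 12L, ref_aa = "G",
                                   alt_aa = "D", allele = "HLA-A*02:01"))
  vf <- rbind(vf_row("d1", 0.5),
              vf_row("d1", 0.5, gene = "KRAS", position = 12L, ref = "G", alt = "D"))
  cov3 <- coverage_table(cands, hla1, inc, vf)
  expect_equal(unname(cov3$cells["d1", "HLA-A*02:01"]), 0.75 * 10000 * 0.2036)
})

test_that("coverage obeys monotonicity, the union bound and scale equivariance", {
  inc <- data.frame(disease = c("d1", "d2"), annual_cases = c(10000L, 5000L))
  cands <- rbind(cand1, data.frame(gene = "KRAS", position = 12L, ref_aa = "G",
                                   alt_aa = "D", allele = "HLA-A*02:01"))
  vf <- rbind(vf_row("d1", 0.04), vf_row("d2", 0.01),
              vf_row("d1", 0.03, gene = "KRAS", position = 12L, ref = "G", alt = "D"))
  cov_both <- coverage_table(cands, hla1, inc, vf)
  cov_one <- coverage_table(cand1, hla1, inc, vf)
  # adding a candidate never decreases any cell
  expect_true(all(cov_both$cells >= cov_one$cells - 1e-12))
  # union bound: cell <= sum of single-candidate terms, equality iff one r > 0
  ub_d1 <- 10000 * 0.2036 * (0.04 + 0.03)
  expect_lte(cov_both$cells["d1", 1], ub_d1)
  expect_equal(unname(cov_both$cells["d2", 1]), 5000 * 0.2036 * 0.01)
  # doubling all incidence doubles cells and n_h exactly
  inc2 <- transform(inc, annual_cases = annual_cases * 2L)
  cov2 <- coverage_table(cands, hla1, inc2, vf)
  expect_equal(cov2$cells, cov_both$cells * 2)
  rk <- rank_candidates(cands, hla1, inc, vf)
  rk2 <- rank_candidates(cands, hla1, inc2, vf)
  expect_equal(rk2$n_h, rk$n_h * 2)
  # increasing an r never decreases n_h
  vf_up <- vf; vf_up$frequency[1] <- 0.08
  rk_up <- rank_candidates(cands, hla1, inc, vf_up)
  expect_true(all(rk_up$n_h[match(rk$gene, rk_up$gene)] >= rk$n_h - 1e-12))
})

test_that("shipped U.S. tables have the expected shape and marquee values", {
  hla <- us_hla_frequencies()
  inc <- us_incidence()
  expect_equal(nrow(hla), 11)
  expect_equal(nrow(inc), 18)
  expect_equal(hla$frequency[hla$allele == "HLA-A*02:01"], 0.2036)
  expect_equal(inc$annual_cases[inc$disease == "TCGA-SKCM"], 75000)
  expect_equal(sum(inc$annual_cases), 1161958)
  expect_true(all(hla$frequency > 0 & hla$frequency < 1))
})
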