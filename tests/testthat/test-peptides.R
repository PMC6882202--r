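test_that("applying a variant changes exactly one residue and checks the reference", {
  ctx <- apply_variant_to_protein("ARNDS", 5, "S", "L")
  expect_equal(ctx$mutant, "ARNDL")
  expect_equal(ctx$wild, "ARNDS")
  expect_equal(ctx$mutated_index, 5L)
  expect_error(apply_variant_to_protein("ARNDS", 5, "T", "L"),
               "expected T, found S")
  expect_error(apply_variant_to_protein("ARNDS", 9, "S", "L"), "outside")
  # a longer context: single position differs
  p <- tiny_proteome()[["GENEA"]]
  ctx2 <- apply_variant_to_protein(p, 20, substr(p, 20, 20), "W")
  diff <- which(strsplit(ctx2$wild, "")[[1]] != strsplit(ctx2$mutant, "")[[1]])
  expect_equal(diff, 20L)
})

test_that("window enumeration matches the brute-force slider everywhere", {
  # interior position: 9 + 10 + 11 = 30 windows
  ctx <- apply_variant_to_protein(strrep("A", 30), 15, "A", "L")
  win <- enumerate_windows(ctx)
  expect_equal(nrow(win), 30)
  # terminal position: one window per length
  ctx1 <- apply_variant_to_protein(strrep("A", 30), 1, "A", "L")
  expect_equal(nrow(enumerate_windows(ctx1)), 3)
  # protein of length 9: a single window
  ctx9 <- apply_variant_to_protein(strrep("A", 9), 4, "A", "L")
  expect_equal(nrow(enumerate_windows(ctx9)), 1)
  # exhaustive check against the independent slider for all (L, pos)
  for (L in 9:40) {
    for (pos in seq_len(L)) {
      ctx <- apply_variant_to_protein(strrep("A", L), pos, "A", "L")
      expect_equal(nrow(enumerate_windows(ctx)), brute_force_windows(L, pos),
                   info = sprintf("L=%d pos=%d", L, pos))
    }
  }
})

test_that("every window contains the alternate residue at its variant offset", {
  p <- tiny_proteome()[["GENEA"]]
  for (pos in c(1, 2, 11, 25, nchar(p))) {
    ref <- substr(p, pos, pos)
    alt <- setdiff(c("W", "Y"), ref)[1]
    win <- enumerate_windows(apply_variant_to_protein(p, pos, ref, alt))
    expect_true(all(substr(win$sequence, win$variant_offset,
                           win$variant_offset) == alt))
    expect_true(all(win$start + win$length - 1 <= nchar(p)))
    expect_true(all(win$start <= pos & pos <= win$start + win$length - 1))
  }
})

test_that("binding prediction yields one row per window-allele pair, deterministically", {
  ctx <- apply_variant_to_protein(strrep("A", 30), 15, "A", "L")
  win <- enumerate_windows(ctx)
  pred <- toy_binding_predictor(seed = 5)
  alleles <- default_allele_panel()
  b <- predict_bindings(win, alleles, pred)
  expect_equal(nrow(b), 30 * 11)
  b2 <- predict_bindings(win, alleles, pred)
  expect_identical(b$ic50_nm, b2$ic50_nm)
  expect_true(all(b$ic50_nm > 0))
  expect_true(all(b$binder_class %in% c("non", "weak", "strong")))
})

test_that("redundancy collapse retains the argmin window per allele, order-invariantly", {
  win <- data.frame(sequence = c("AAAAAAAAL", "AAAAAAALA", "AAAAAALAA"),
                    start = 1:3, length = 9L, variant_offset = c(9L, 8L, 7L))
  preds <- rbind(
    cbind(win, allele = "H1", ic50_nm = c(30, 8.8, 500), binder_class = "weak"),
    cbind(win, allele = "H2", ic50_nm = c(5, 7, 2), binder_class = "strong"))
  col <- collapse_redundancy(preds)
  expect_equal(nrow(col), 2)
  expect_equal(col$ic50_nm[col$allele == "H1"], 8.8)
  expect_equal(col$ic50_nm[col$allele == "H2"], 2)
  # permuting rows changes nothing
  set.seed(1)
  col2 <- collapse_redundancy(preds[sample(nrow(preds)), ])
  rownames(col2) <- NULL
  expect_identical(col, col2)
  # single window: itself
  single <- preds[preds$start == 1 & preds$allele == "H1", ]
  expect_equal(collapse_redundancy(single)$ic50_nm, 30)
})

test_that("collapse equals an exhaustive argmin scan on random scores", {
  set.seed(11)
  ctx <- apply_variant_to_protein(strrep("A", 40), 20, "A", "L")
  win <- enumerate_windows(ctx)
  for (rep in 1:5) {
    scores <- stats::runif(nrow(win), 1, 50000)
    preds <- cbind(win, allele = "HLA-A*02:01", ic50_nm = scores,
                   binder_class = "non", stringsAsFactors = FALSE)
    col <- collapse_redundancy(preds)
    expect_equal(col$ic50_nm, min(scores))
    expect_equal(col$start, win$start[which.min(scores)])
  }
})

test_that("collapse ties break by shortest then leftmost then lexicographic peptide", {
  win <- data.frame(sequence = c("CCCCCCCCCC", "BBBBBBBBB", "AAAAAAAAA"),
                    start = c(1L, 2L, 1L), length = c(10L, 9L, 9L),
                    variant_offset = 5L)
  preds <- cbind(win, allele = "H", ic50_nm = 7, binder_class = "weak",
                 stringsAsFactors = FALSE)
  col <- collapse_redundancy(preds)
  expect_equal(col$sequence, "AAAAAAAAA")  # shortest, then start 1, then lexicographic
})

test_that("wild-type attachment queries the swap-back peptide from the same coordinates", {
  p <- tiny_proteome()[["GENEA"]]
  pos <- 10L
  ref <- substr(p, pos, pos)
  ctx <- apply_variant_to_protein(p, pos, ref, "W")
  win <- enumerate_windows(ctx)
  pred <- toy_binding_predictor(seed = 2)
  col <- collapse_redundancy(predict_bindings(win, "HLA-A*02:01", pred))
  cand <- attach_wild_type(col, ctx, pred)
  expect_true(all(c("wt_peptide", "wt_ic50_nm", "mut_ic50_nm") %in% names(cand)))
  # wt peptide differs from mutant peptide at exactly the variant offset
  mut_chars <- strsplit(cand$sequence, "")[[1]]
  wt_chars <- strsplit(cand$wt_peptide, "")[[1]]
  expect_equal(which(mut_chars != wt_chars), cand$variant_offset)
  expect_equal(wt_chars[cand$variant_offset], ref)
  # the wt IC50 is the predictor's own answer for that peptide
  expect_equal(cand$wt_ic50_nm,
               pred$predict(cand$wt_peptide, cand$allele)$ic50_nm)
})

test_that("binder-class filtering keeps the requested classes", {
  cand <- data.frame(binder_class = c("strong", "weak", "non"))
  expect_equal(nrow(filter_binders(cand, "strong")), 1)
  expect_equal(nrow(filter_binders(cand, c("strong", "weak"))), 2)
  expect_equal(nrow(filter_binders(cand[0, , drop = FALSE])), 0)
})

test_that("the NetMHCcons-style table adapter round-trips a prediction file", {
  tab <- data.frame(peptide = c("KLLEIFTEL", "KLSEIFTEL"),
                    allele = "HLA-A*02:01",
                    ic50_nm = c(8.8, 912.4), binder_class = c("SB", "NB"))
  path <- tempfile(fileext = ".txt")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  parsed <- read_netmhccons_table(path)
  expect_equal(parsed$ic50_nm, c(8.8, 912.4))
  expect_equal(parsed$binder_class, c("strong", "non"))
  pred <- table_predictor(parsed)
  res <- pred$predict("KLLEIFTEL", "HLA-A*02:01")
  expect_equal(res$ic50_nm, 8.8)
  expect_equal(res$binder_class, "strong")
  # unknown pair is a hard error carrying the pair
  expect_error(predict_bindings(
    data.frame(sequence = "AAAAAAAAA", start = 1L, length = 9L,
               variant_offset = 1L),
    "HLA-A*02:01", pred), "AAAAAAAAA")
})

test_that("candidate generation is unique per (change, allele) and respects keep classes", {
  prot <- tiny_proteome()
  changes <- data.frame(gene = "GENEA", position = 20L,
                        ref_aa = substr(prot[["GENEA"]], 20, 20), alt_aa = "W")
  pred <- toy_binding_predictor(seed = 5)
  cand <- neo_candidates(changes, prot, pred, keep = c("strong", "weak", "non"))
  expect_equal(anyDuplicated(paste(cand$gene, cand$position, cand$alt_aa,
                                   cand$allele)), 0)
  expect_equal(nrow(cand), 11)  # every allele has exactly one best epitope
  strong <- neo_candidates(changes, prot, pred, keep = "strong")
  expect_true(all(strong$binder_class == "strong"))
  expect_error(neo_candidates(data.frame(gene = "NOGENE", position = 1,
                                         ref_aa = "A", alt_aa = "R"),
                              prot, pred), "NOGENE")
})
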