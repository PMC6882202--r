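# Shared fixtures and independent oracles, built in code at test time.

# One clean MAF row that passes every filter; override fields as needed.
maf_row <- function(patient = "P1", gene = "KRAS", transcript = "ENST00000256078",
                    hgvsp = "p.G12D", chrom = "12", pos = 25245350,
                    ref = "C", alt = "T", type = "SNP",
                    classification = "Missense_Mutation", status = "Somatic",
                    depth = 50L, ref_count = 45L, alt_count = 5L,
                    pop_af = NA_real_) {
  data.frame(Tumor_Sample_Barcode = patient, Hugo_Symbol = gene,
             Transcript_ID = transcript, HGVSp_Short = hgvsp,
             Chromosome = chrom, Start_Position = pos,
             Reference_Allele = ref, Tumor_Seq_Allele2 = alt,
             Variant_Type = type, Variant_Classification = classification,
             Mutation_Status = status, t_depth = depth,
             t_ref_count = ref_count, t_alt_count = alt_count,
             max_pop_af = pop_af, stringsAsFactors = FALSE)
}

write_maf_file <- function(rows, path = tempfile(fileext = ".maf"),
                           drop_cols = NULL, comment = TRUE) {
  if (!is.null(drop_cols)) rows <- rows[setdiff(names(rows), drop_cols)]
  con <- file(path, "w")
  if (comment) writeLines("#version gdc-like", con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

# Brute-force window oracle: slide every window of each length over a
# protein of length L and keep those covering pos.
brute_force_windows <- function(L, pos, lengths = c(9, 10, 11)) {
  out <- 0L
  for (k in lengths) {
    for (s in seq_len(max(L - k + 1, 0))) {
      if (s <= pos && pos <= s + k - 1) out <- out + 1L
    }
  }
  out
}

# Full 4^window enumeration oracle for the homopolymer null: length of the
# run of identical bases covering the center, for every possible window.
enum_center_run_lengths <- function(window) {
  n <- 4^window
  center <- (window + 1) %/% 2
  digits <- matrix(0L, nrow = n, ncol = window)
  idx <- 0:(n - 1)
  for (j in seq_len(window)) {
    digits[, j] <- idx %% 4L
    idx <- idx %/% 4L
  }
  run <- rep(1L, n)
  ctr <- digits[, center]
  blocked_left <- rep(FALSE, n)
  for (d in seq_len(center - 1)) {
    same <- !blocked_left & digits[, center - d] == ctr
    run <- run + same
    blocked_left <- blocked_left | !same
  }
  blocked_right <- rep(FALSE, n)
  for (d in seq_len(window - center)) {
    same <- !blocked_right & digits[, center + d] == ctr
    run <- run + same
    blocked_right <- blocked_right | !same
  }
  run
}

enum_repeat_fraction <- function(min_run, window) {
  mean(enum_center_run_lengths(window) >= min_run)
}

# Exhaustive-outcome oracle for prob_at_least_one (<= ~15 events).
enum_prob_at_least_one <- function(freqs) {
  n <- length(freqs)
  if (n == 0) return(0)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    p <- prod(ifelse(bits, freqs, 1 - freqs))
    if (any(bits)) total <- total + p
  }
  total
}

# Direct-summation oracle for the upper binomial tail.
sum_binom_tail <- function(k, n, p) {
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), 0))
}

# Tiny deterministic proteome for peptide tests.
tiny_proteome <- function() {
  c(GENEA = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEKAVQ",
    GENEB = "ARNDCQEGHILKMFPSTWYVARNDCQEGHILKMFPSTWYV")
}
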