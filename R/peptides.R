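# Mutant peptide window enumeration and neo-epitope candidate selection.

#' Read a proteome FASTA
#'
#' Loads protein sequences via Biostrings and validates them against the
#' standard 20-letter alphabet; sequences containing selenocysteine or
#' ambiguity codes are rejected at load with a hard error naming the record.
#' Sequence ids are taken as the first whitespace-delimited token of each
#' FASTA header (gene symbol or transcript id, matching the variant tables).
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(aa))
  bad <- vapply(seqs, function(s) {
    !nzchar(s) || grepl(paste0("[^", paste(AA20, collapse = ""), "]"), s)
  }, logical(1))
  if (any(bad)) {
    stopf("proteome sequence(s) outside the 20-letter alphabet (or empty): %s",
          paste(utils::head(names(seqs)[bad], 3), collapse = ", "))
  }
  if (anyDuplicated(names(seqs))) stopf("duplicate sequence ids in %s", path)
  seqs
}

#' Apply an amino-acid exchange to a protein sequence
#'
#' @param seq single protein sequence (character scalar).
#' @param position 1-based residue index.
#' @param ref_aa expected reference residue; a mismatch with the sequence is
#'   a hard error naming expected vs found.
#' @param alt_aa alternate residue.
#' @return object of class `mutant_context`: list with `wild`, `mutant`
#'   (sequences differing at exactly one position) and `mutated_index`.
#' @export
apply_variant_to_protein <- function(seq, position, ref_aa, alt_aa) {
  if (position < 1 || position > nchar(seq)) {
    stopf("variant position %d outside protein of length %d",
          position, nchar(seq))
  }
  found <- substr(seq, position, position)
  if (found != ref_aa) {
    stopf("reference mismatch at position %d: expected %s, found %s",
          position, ref_aa, found)
  }
  mutant <- seq
  substr(mutant, position, position) <- alt_aa
  structure(list(wild = seq, mutant = mutant,
                 mutated_index = as.integer(position)),
            class = "mutant_context")
}

#' Enumerate peptide windows covering the mutated residue
#'
#' All windows of the requested lengths that lie fully inside the protein
#' and contain the mutated position, sliced from the mutant sequence.
#'
#' @param context a [apply_variant_to_protein()] result.
#' @param lengths window lengths (default 9, 10 and 11).
#' @return data frame ordered by (length, start) with columns `sequence`,
#'   `start` (1-based in the protein), `length`, `variant_offset` (1-based
#'   position of the exchanged residue within the peptide).
#' @export
enumerate_windows <- function(context, lengths = c(9L, 10L, 11L)) {
  L <- nchar(context$mutant)
  pos <- context$mutated_index
  rows <- list()
  for (k in sort(as.integer(lengths))) {
    starts <- seq.int(max(1L, pos - k + 1L), min(pos, L - k + 1L))
    starts <- starts[starts >= 1L & starts + k - 1L <= L]
    if (length(starts) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = substring(context$mutant, starts, starts + k - 1L),
      start = starts, length = k, variant_offset = pos - starts + 1L,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(sequence = character(), start = integer(),
                      length = integer(), variant_offset = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predict binding for every (window, allele) pair
#'
#' @param windows window table from [enumerate_windows()].
#' @param alleles character vector of HLA allele names.
#' @param predictor a `binding_predictor`.
#' @return data frame with one row per (window, allele): the window columns
#'   plus `allele`, `ic50_nm`, `binder_class`.
#' @export
predict_bindings <- function(windows, alleles, predictor) {
  if (nrow(windows) == 0 || length(alleles) == 0) {
    return(cbind(windows[0, , drop = FALSE],
                 data.frame(allele = character(), ic50_nm = numeric(),
                            binder_class = character())))
  }
  grid <- expand.grid(w = seq_len(nrow(windows)), allele = alleles,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pred <- predict_pairs(predictor, windows$sequence[grid$w], grid$allele)
  out <- cbind(windows[grid$w, , drop = FALSE],
               data.frame(allele = grid$allele, ic50_nm = pred$ic50_nm,
                          binder_class = pred$binder_class,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Collapse overlapping windows to one best epitope per allele
#'
#' For each allele, retains the window with the lowest predicted mutant
#' IC50; ties are broken deterministically by shorter length, then smaller
#' start, then lexicographic peptide. The result is a function of the
#' prediction set only (order-invariant).
#'
#' @param predictions output of [predict_bindings()] for one protein change.
#' @return data frame with one row per allele present in `predictions`.
#' @export
collapse_redundancy <- function(predictions) {
  if (nrow(predictions) == 0) return(predictions)
  ord <- order(predictions$allele, predictions$ic50_nm, predictions$length,
               predictions$start, predictions$sequence)
  sorted <- predictions[ord, , drop = FALSE]
  out <- sorted[!duplicated(sorted$allele), , drop = FALSE]
  out <- out[order(out$allele), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach the wild-type IC50 to collapsed candidates
#'
#' The wild-type peptide is the same window coordinates sliced from the
#' unmutated sequence (it differs from the retained mutant peptide at
#' exactly the variant offset); its IC50 is obtained from the same
#' predictor.
#'
#' @param candidates collapsed candidates from [collapse_redundancy()].
#' @param context the matching `mutant_context`.
#' @param predictor a `binding_predictor`.
#' @return `candidates` with columns `wt_peptide` and `wt_ic50_nm` added and
#'   `ic50_nm` renamed to `mut_ic50_nm`.
#' @export
attach_wild_type <- function(candidates, context, predictor) {
  if (nrow(candidates) == 0) {
    candidates$wt_peptide <- character(0)
    candidates$wt_ic50_nm <- numeric(0)
    names(candidates)[names(candidates) == "ic50_nm"] <- "mut_ic50_nm"
    return(candidates)
  }
  wt <- substring(context$wild, candidates$start,
                  candidates$start + candidates$length - 1L)
  pred <- predict_pairs(predictor, wt, candidates$allele)
  candidates$wt_peptide <- wt
  candidates$wt_ic50_nm <- pred$ic50_nm
  names(candidates)[names(candidates) == "ic50_nm"] <- "mut_ic50_nm"
  candidates
}

#' Filter candidates by mutant binder class
#'
#' @param candidates candidate table with a `binder_class` column.
#' @param keep classes to retain (default strong binders only).
#' @return the retained subset.
#' @export
filter_binders <- function(candidates, keep = "strong") {
  keep <- match.arg(keep, c("non", "weak", "strong"), several.ok = TRUE)
  out <- candidates[candidates$binder_class %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate neo-epitope candidates for a set of recurrent changes
#'
#' End-to-end peptide stage: for each unique protein change, builds the
#' mutant sequence, enumerates the 9-11-mer windows covering the exchanged
#' residue, predicts binding for every (window, allele) pair, collapses to
#' the single strongest mutant binder per allele, attaches the wild-type
#' IC50, and keeps the requested binder classes.
#'
#' @param changes data frame with `gene`, `position`, `ref_aa`, `alt_aa`.
#' @param proteome named sequence vector from [read_proteome()]; matched to
#'   changes by `gene` against the sequence id.
#' @param alleles allele panel (default the shipped 11-allele panel).
#' @param predictor a `binding_predictor`.
#' @param lengths window lengths.
#' @param keep binder classes to retain.
#' @return data frame with columns `gene`, `position`, `ref_aa`, `alt_aa`,
#'   `allele`, `peptide`, `start`, `length`, `variant_offset`,
#'   `mut_ic50_nm`, `wt_ic50_nm`, `binder_class`.
#' @export
neo_candidates <- function(changes, proteome, predictor,
                           alleles = default_allele_panel(),
                           lengths = c(9L, 10L, 11L), keep = "strong") {
  changes <- unique(changes[c("gene", "position", "ref_aa", "alt_aa")])
  changes <- changes[order(changes$gene, changes$position, changes$alt_aa), ,
                     drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(changes))) {
    ch <- changes[i, ]
    if (!(ch$gene %in% names(proteome))) {
      stopf("no proteome sequence for gene %s", ch$gene)
    }
    ctx <- apply_variant_to_protein(proteome[[ch$gene]], ch$position,
                                    ch$ref_aa, ch$alt_aa)
    win <- enumerate_windows(ctx, lengths)
    pred <- predict_bindings(win, alleles, predictor)
    cand <- attach_wild_type(collapse_redundancy(pred), ctx, predictor)
    if (nrow(cand) == 0) next
    out[[length(out) + 1L]] <- data.frame(
      gene = ch$gene, position = ch$position, ref_aa = ch$ref_aa,
      alt_aa = ch$alt_aa, allele = cand$allele, peptide = cand$sequence,
      start = cand$start, length = cand$length,
      variant_offset = cand$variant_offset, mut_ic50_nm = cand$mut_ic50_nm,
      wt_ic50_nm = cand$wt_ic50_nm, binder_class = cand$binder_class,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out) == 0) {
    data.frame(gene = character(), position = integer(), ref_aa = character(),
               alt_aa = character(), allele = character(), peptide = character(),
               start = integer(), length = integer(), variant_offset = integer(),
               mut_ic50_nm = numeric(), wt_ic50_nm = numeric(),
               binder_class = character(), stringsAsFactors = FALSE)
  } else do.call(rbind, out)
  rownames(res) <- NULL
  filter_binders(res, keep)
}
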