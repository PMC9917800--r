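# Independent oracles used across the suite.  All alignment oracles go
# through Biostrings::pairwiseAlignment, a full dynamic-programming
# implementation developed independently of the package's aligner, with
# the identical scoring convention (gap of length L costs |open| +
# L*|extend|).

oracle_submat <- function(params = assignment_params()) {
  Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                           mismatch = params$mismatch,
                                           baseOnly = TRUE)
}

oracle_score <- function(read, seg, params = assignment_params()) {
  as.integer(Biostrings::pairwiseAlignment(
    read, seg, type = "local", substitutionMatrix = oracle_submat(params),
    gapOpening = -params$gap_open, gapExtension = -params$gap_extend,
    scoreOnly = TRUE))
}

# best (genes, score) over a candidate set; returns all score-tied genes
oracle_best <- function(read, cand, params = assignment_params()) {
  scores <- vapply(cand$sequence, oracle_score, 0L, read = read,
                   params = params, USE.NAMES = FALSE)
  mx <- max(scores)
  list(genes = cand$gene_name[scores == mx], score = mx)
}

# project a segment anchor position onto the read by walking the
# columns of the oracle's own traceback
oracle_project_anchor <- function(read, seg, anchor,
                                  params = assignment_params()) {
  aln <- Biostrings::pairwiseAlignment(
    read, seg, type = "local", substitutionMatrix = oracle_submat(params),
    gapOpening = -params$gap_open, gapExtension = -params$gap_extend)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  rpos <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  spos <- Biostrings::start(Biostrings::subject(aln)) - 1L
  for (k in seq_along(p)) {
    if (s[k] != "-" && spos == anchor) {
      return(if (p[k] == "-") NA_integer_ else rpos)
    }
    if (p[k] != "-") rpos <- rpos + 1L
    if (s[k] != "-") spos <- spos + 1L
  }
  NA_integer_
}

# brute-force clonotype counting oracle: hash identical keys, count,
# rank by count then lexicographic key
oracle_clonotypes <- function(v, j, aa) {
  key <- paste(v, j, aa, sep = "\t")
  counts <- table(key)
  df <- do.call(rbind, strsplit(names(counts), "\t"))
  out <- data.frame(v_gene = df[, 1], j_gene = df[, 2], cdr3_aa = df[, 3],
                    copy_count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$copy_count, out$v_gene, out$j_gene, out$cdr3_aa), ]
  out$frequency_pct <- 100 * out$copy_count / sum(out$copy_count)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# check one (read, type) assignment against the oracle.  A no-hit is
# valid when the best score is sub-threshold OR the best alignment's
# identity (recomputed with thresholds disabled) is below min_identity.
expect_matches_oracle <- function(read, db, type, chain, params) {
  cand <- ref_segments(db, type, chain)
  min_score <- if (type == "V") params$min_score_v else params$min_score_j
  hit <- assign_segment(read, db, type, chain, params)
  orc <- oracle_best(read, cand, params)
  if (is.null(hit)) {
    relaxed <- assignment_params(
      match = params$match, mismatch = params$mismatch,
      gap_open = params$gap_open, gap_extend = params$gap_extend,
      min_score_v = 0L, min_score_j = 0L, min_identity = 0)
    best <- assign_segment(read, db, type, chain, relaxed)
    if (is.null(best)) {
      expect_lte(orc$score, 0L)
    } else {
      expect_equal(best$score, orc$score)
      expect_true(best$score < min_score ||
                    best$identity < params$min_identity)
    }
  } else {
    expect_equal(hit$score, orc$score)
    expect_true(hit$gene_name %in% orc$genes)
  }
  invisible(NULL)
}

random_read <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
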