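#' Alignment parameters for V/J segment assignment
#'
#' Scoring scheme for the Smith-Waterman local alignment used to assign
#' reads to reference segments.  A gap of length L scores
#' `gap_open + L * gap_extend` (both negative).  The thresholds decide
#' when a best hit is reported at all: the alignment score must reach
#' `min_score_v` / `min_score_j` and the column identity (matches /
#' aligned columns) must reach `min_identity`.
#'
#' Defaults (match +2, mismatch -2, open -4, extend -1, min_score_v 40,
#' min_score_j 24, min_identity 0.85) separate the bundled toy reference
#' segments cleanly; all are configuration, not constants of the method.
#'
#' @param match,mismatch Per-base scores; `match > 0 > mismatch`.
#' @param gap_open,gap_extend Gap penalties (negative).
#' @param min_score_v,min_score_j Minimum reported alignment scores.
#' @param min_identity Minimum fraction of matching columns.
#' @return An `assignment_params` list.
#' @export
assignment_params <- function(match = 2L, mismatch = -2L,
                              gap_open = -4L, gap_extend = -1L,
                              min_score_v = 40L, min_score_j = 24L,
                              min_identity = 0.85) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0,
            min_score_v >= 0, min_score_j >= 0,
            min_identity >= 0, min_identity <= 1)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_score_v = as.integer(min_score_v),
                 min_score_j = as.integer(min_score_j),
                 min_identity = min_identity),
            class = "assignment_params")
}

# internal: align one read against one segment sequence
sw_align <- function(read, seg, params) {
  .sw_align_cpp(read, seg, params$match, params$mismatch,
                -params$gap_open, -params$gap_extend)
}

#' Assign the best-matching V or J segment to a read
#'
#' Runs an exhaustive Smith-Waterman local alignment of the read against
#' every reference segment of the requested type and chain and returns
#' the best hit, or `NULL` when no alignment reaches the score and
#' identity thresholds.  Equal best scores are broken deterministically:
#' higher identity first, then longer aligned span, then the
#' lexicographically smallest gene name.
#'
#' @param read Nucleotide string (uppercase ACGT).
#' @param db A `ReferenceDB`.
#' @param segment_type `"V"` or `"J"`.
#' @param chain `"TRA"` or `"TRB"`.
#' @param params An [assignment_params()] object.
#' @return A `segment_hit` list with `gene_name`, `allele`, `score`,
#'   `identity`, 0-based half-open `read_start`/`read_end` and
#'   `seg_start`/`seg_end`, plus `seg_map` projecting segment positions
#'   onto read positions (used for anchor projection); or `NULL`.
#' @export
assign_segment <- function(read, db, segment_type, chain,
                           params = assignment_params()) {
  stopifnot(is.character(read), length(read) == 1L, nchar(read) >= 1L)
  cand <- ref_segments(db, segment_type, chain)
  if (nrow(cand) == 0L) {
    stop("reference has no ", segment_type, " segments for chain ", chain)
  }
  min_score <- if (segment_type == "V") params$min_score_v else params$min_score_j
  assign_best(read, cand$gene_name, cand$allele, cand$sequence,
              min_score, params)
}

# internal workhorse over plain vectors: one score-only sweep across all
# candidates, full traceback only for those tied at the maximum score
assign_best <- function(read, genes, alleles, seqs, min_score, params) {
  scores <- .sw_scores_cpp(read, seqs, params$match, params$mismatch,
                           -params$gap_open, -params$gap_extend)
  mx <- max(scores)
  if (mx <= 0L || mx < min_score) return(NULL)
  best <- NULL
  for (k in which(scores == mx)) {
    a <- sw_align(read, seqs[k], params)
    hit <- list(gene_name = genes[k], allele = alleles[k],
                score = a$score,
                identity = a$n_match / a$aln_len,
                aln_len = a$aln_len,
                read_start = a$read_start, read_end = a$read_end,
                seg_start = a$seg_start, seg_end = a$seg_end,
                seg_map = a$seg_map)
    if (is.null(best) || hit_better(hit, best)) best <- hit
  }
  if (best$identity < params$min_identity) return(NULL)
  structure(best, class = "segment_hit")
}

# deterministic hit ordering: score, identity, aligned span, gene name
hit_better <- function(a, b) {
  if (a$score != b$score) return(a$score > b$score)
  if (a$identity != b$identity) return(a$identity > b$identity)
  if (a$aln_len != b$aln_len) return(a$aln_len > b$aln_len)
  a$gene_name < b$gene_name
}

# reverse complement (used only when both_strands scanning is enabled)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Annotate reads with V/J assignments and extracted CDR3s
#'
#' For each read, assigns V and J independently (optionally scanning the
#' reverse strand and keeping the orientation with the better V score),
#' requires the V block to end before the J block begins, then projects
#' the reference anchor codons through the alignments to extract and
#' translate the CDR3 (see [locate_cdr3()]).  Reads that fail any stage
#' carry a machine-readable `fail_reason`: `no_v`, `no_j`, `vj_overlap`,
#' `no_anchor_c`, `no_anchor_fg`, `out_of_frame` or `stop_codon`;
#' passing reads have `fail_reason = "none"` and `productive = TRUE`.
#'
#' @param reads Tibble with columns `read_id`, `sequence` (e.g. from
#'   [read_fastq()] or [generate_reads()]).
#' @param db A `ReferenceDB`.
#' @param params [assignment_params()].
#' @param chain `"TRA"` or `"TRB"`.
#' @param both_strands Also scan the reverse complement. Amplicons from
#'   5'-adaptor libraries have fixed orientation, so the default is
#'   `FALSE`.
#' @param max_vj_overlap Maximum tolerated overlap (nt) between the V
#'   and J aligned blocks on the read.  Junctional micro-homology —
#'   bases shared between the trimmed V end and the J start — routinely
#'   lets both local alignments extend a base or two across the true
#'   boundary, so small overlaps are normal in valid rearrangements;
#'   overlaps beyond this allowance (or anchor codons in crossed order)
#'   indicate a chimeric read and flag `vj_overlap`.
#' @return Tibble with one row per read: hit coordinates and scores,
#'   `cdr3_nt`, `cdr3_aa`, `productive`, `fail_reason`.
#' @export
annotate_reads <- function(reads, db, params = assignment_params(),
                           chain = "TRA", both_strands = FALSE,
                           max_vj_overlap = 8L) {
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  vs <- ref_segments(db, "V", chain)
  js <- ref_segments(db, "J", chain)
  if (nrow(vs) == 0L || nrow(js) == 0L) {
    stop("reference has no V/J segments for chain ", chain)
  }
  anchors <- stats::setNames(db$segments$anchor_codon_start,
                             paste(db$segments$gene_name,
                                   db$segments$allele))
  # identical sequences get identical annotations: align each unique
  # amplicon once and expand (the flip side of copy counting)
  seq_all <- toupper(reads$sequence)
  uniq <- unique(seq_all)
  if (length(uniq) < nrow(reads)) {
    idx <- match(seq_all, uniq)
    ua <- annotate_reads(tibble(read_id = as.character(seq_along(uniq)),
                                sequence = uniq),
                         db, params, chain, both_strands, max_vj_overlap)
    out <- ua[idx, ]
    out$read_id <- reads$read_id
    out$sequence <- seq_all  # pre-orientation input sequence
    if (both_strands) out$sequence <- ua$sequence[idx]
    return(out)
  }
  n <- nrow(reads)
  col <- list(
    read_id = reads$read_id, sequence = toupper(reads$sequence),
    v_gene = rep(NA_character_, n), v_allele = rep(NA_character_, n),
    v_score = rep(NA_integer_, n), v_identity = rep(NA_real_, n),
    v_read_start = rep(NA_integer_, n), v_read_end = rep(NA_integer_, n),
    j_gene = rep(NA_character_, n), j_allele = rep(NA_character_, n),
    j_score = rep(NA_integer_, n), j_identity = rep(NA_real_, n),
    j_read_start = rep(NA_integer_, n), j_read_end = rep(NA_integer_, n),
    cdr3_nt = rep(NA_character_, n), cdr3_aa = rep(NA_character_, n),
    productive = rep(FALSE, n), fail_reason = rep("none", n)
  )
  for (i in seq_len(n)) {
    seq <- col$sequence[i]
    v <- assign_best(seq, vs$gene_name, vs$allele, vs$sequence,
                     params$min_score_v, params)
    if (both_strands) {
      rc <- revcomp(seq)
      v_rc <- assign_best(rc, vs$gene_name, vs$allele, vs$sequence,
                          params$min_score_v, params)
      if (!is.null(v_rc) && (is.null(v) || v_rc$score > v$score)) {
        seq <- rc
        col$sequence[i] <- rc
        v <- v_rc
      }
    }
    if (is.null(v)) {
      col$fail_reason[i] <- "no_v"
      next
    }
    col$v_gene[i] <- v$gene_name; col$v_allele[i] <- v$allele
    col$v_score[i] <- v$score; col$v_identity[i] <- v$identity
    col$v_read_start[i] <- v$read_start; col$v_read_end[i] <- v$read_end
    j <- assign_best(seq, js$gene_name, js$allele, js$sequence,
                     params$min_score_j, params)
    if (is.null(j)) {
      col$fail_reason[i] <- "no_j"
      next
    }
    col$j_gene[i] <- j$gene_name; col$j_allele[i] <- j$allele
    col$j_score[i] <- j$score; col$j_identity[i] <- j$identity
    col$j_read_start[i] <- j$read_start; col$j_read_end[i] <- j$read_end
    if (v$read_end - j$read_start > max_vj_overlap) {
      col$fail_reason[i] <- "vj_overlap"
      next
    }
    loc <- locate_cdr3_at(seq, v, j,
                          anchors[[paste(v$gene_name, v$allele)]],
                          anchors[[paste(j$gene_name, j$allele)]])
    if (!is.null(loc$cdr3_nt)) {
      col$cdr3_nt[i] <- loc$cdr3_nt
      col$cdr3_aa[i] <- loc$cdr3_aa
    }
    if (!is.null(loc$fail_reason)) {
      col$fail_reason[i] <- loc$fail_reason
      next
    }
    col$productive[i] <- call_productivity(
      list(fail_reason = "none", cdr3_aa = loc$cdr3_aa))
  }
  as_tibble(col)
}
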