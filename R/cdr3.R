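#' Locate the CDR3 junction on a read by anchor projection
#'
#' The CDR3 spans the conserved cysteine codon at IMGT position 104 (the
#' last codon housed in the V reference's anchor metadata) through the
#' conserved phenylalanine/tryptophan codon at position 118 (the J
#' anchor), both inclusive; the codon immediately following must
#' translate to glycine (position 119), which validates the J reading
#' frame but is not part of the junction.
#'
#' Anchors are projected from reference coordinates onto the read
#' through the alignment tracebacks.  The call is conservative: if any
#' anchor base falls outside the aligned block or aligns to a gap, the
#' read fails (`no_anchor_c` / `no_anchor_fg`) rather than guessing a
#' shifted anchor, and the projected anchor codons are re-checked on the
#' read itself (they must still translate to C and F/W — a sequencing
#' error in an anchor invalidates the junction).
#'
#' @param read Read sequence (uppercase ACGT).
#' @param v_hit,j_hit `segment_hit` objects from [assign_segment()].
#' @param db The `ReferenceDB` the hits came from.
#' @return On success, a list with 0-based half-open `cdr3_start`,
#'   `cdr3_end`, `cdr3_nt`, `cdr3_aa` and `fail_reason = NULL`; on
#'   failure a list whose `fail_reason` is one of `no_anchor_c`,
#'   `no_anchor_fg`, `out_of_frame`, `stop_codon` (for `stop_codon` the
#'   junction fields are still filled in).
#' @export
locate_cdr3 <- function(read, v_hit, j_hit, db) {
  v_ref <- ref_lookup(db, v_hit$gene_name, v_hit$allele)
  j_ref <- ref_lookup(db, j_hit$gene_name, j_hit$allele)
  locate_cdr3_at(read, v_hit, j_hit,
                 v_ref$anchor_codon_start, j_ref$anchor_codon_start)
}

# anchor positions supplied directly (hot path used by annotate_reads)
locate_cdr3_at <- function(read, v_hit, j_hit, v_anchor, j_anchor_ref) {
  start <- project_codon(v_hit, v_anchor)
  if (is.null(start) ||
      !identical(codon_aa(substr(read, start + 1L, start + 3L)), "C")) {
    return(list(fail_reason = "no_anchor_c"))
  }
  j_anchor <- project_codon(j_hit, j_anchor_ref)
  if (is.null(j_anchor)) {
    return(list(fail_reason = "no_anchor_fg"))
  }
  end <- j_anchor + 3L  # half-open, Phe118/Trp codon inclusive
  if (!codon_aa(substr(read, j_anchor + 1L, j_anchor + 3L)) %in% c("F", "W")) {
    return(list(fail_reason = "no_anchor_fg"))
  }
  # Gly119 frame check on the codon following the J anchor
  if (end + 3L > nchar(read) ||
      !identical(codon_aa(substr(read, end + 1L, end + 3L)), "G")) {
    return(list(fail_reason = "no_anchor_fg"))
  }
  if (end - start < 6L) {  # anchors crossed or abutting: chimeric read
    return(list(fail_reason = "vj_overlap"))
  }
  if ((end - start) %% 3L != 0L) {
    return(list(fail_reason = "out_of_frame"))
  }
  nt <- substr(read, start + 1L, end)
  codons <- substring(nt, seq(1L, nchar(nt), 3L), seq(3L, nchar(nt), 3L))
  aas <- unname(Biostrings::GENETIC_CODE[codons])
  aas[is.na(aas)] <- "X"  # ambiguous bases translate to X
  aa <- paste(aas, collapse = "")
  if (grepl("*", aa, fixed = TRUE)) {
    return(list(fail_reason = "stop_codon", cdr3_start = start,
                cdr3_end = end, cdr3_nt = nt, cdr3_aa = aa))
  }
  list(fail_reason = NULL, cdr3_start = start, cdr3_end = end,
       cdr3_nt = nt, cdr3_aa = aa)
}

# project a reference codon start onto the read through a hit's seg_map;
# NULL when the codon is outside the aligned block or broken by a gap
project_codon <- function(hit, anchor) {
  if (anchor < hit$seg_start || anchor + 3L > hit$seg_end) return(NULL)
  idx <- anchor - hit$seg_start + 1L
  pos <- hit$seg_map[idx:(idx + 2L)]
  if (anyNA(pos)) return(NULL)
  if (pos[2] != pos[1] + 1L || pos[3] != pos[1] + 2L) return(NULL)
  pos[1]
}

#' Translate a nucleotide sequence with the standard genetic code
#'
#' Stop codons are rendered `*`.  Errors on length not divisible by 3 or
#' on non-ACGT characters, matching the strictness the junction
#' bookkeeping relies on.
#'
#' @param nt Nucleotide string.
#' @return Amino-acid string.
#' @examples
#' translate_nt("TGTGCTGTG")  # "CAV"
#' @export
translate_nt <- function(nt) {
  stopifnot(is.character(nt), length(nt) == 1L)
  n <- nchar(nt)
  if (n %% 3L != 0L) {
    stop("sequence length ", n, " is not divisible by 3")
  }
  if (grepl("[^ACGT]", nt)) stop("sequence contains non-ACGT characters")
  if (n == 0L) return("")
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

# single-codon lookup on the standard code (internal hot path)
codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  if (is.na(aa)) NA_character_ else unname(aa)
}

#' Productivity call for an annotated read
#'
#' A junction is productive when its translation contains no stop codon,
#' begins with the conserved cysteine and ends with phenylalanine or
#' tryptophan.
#'
#' @param ar One-row annotated read (needs `cdr3_aa` and
#'   `fail_reason == "none"`).
#' @return Logical.
#' @examples
#' call_productivity(list(fail_reason = "none", cdr3_aa = "CALSEKSSGSWQLIF"))
#' @export
call_productivity <- function(ar) {
  if (!identical(ar$fail_reason, "none")) return(FALSE)
  aa <- ar$cdr3_aa
  if (is.na(aa) || nchar(aa) < 2L) return(FALSE)
  !grepl("*", aa, fixed = TRUE) &&
    substr(aa, 1L, 1L) == "C" &&
    substr(aa, nchar(aa), nchar(aa)) %in% c("F", "W")
}
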