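#' Read a FASTQ file into a read table
#'
#' Strict 4-line-record FASTQ reader (gz-transparent by file
#' extension).  Malformed input — truncated final record, a header not
#' starting `@`, a separator not starting `+`, or sequence/quality
#' length mismatch — aborts with the offending line number.
#'
#' @param path FASTQ path (`.gz` allowed).
#' @return Tibble `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop("truncated FASTQ record at line ", (n %/% 4L) * 4L + 1L,
         " of ", path)
  }
  if (n == 0L) {
    return(tibble(read_id = character(0), sequence = character(0),
                  quality = character(0)))
  }
  hdr <- lines[seq(1L, n, 4L)]
  seq <- lines[seq(2L, n, 4L)]
  plus <- lines[seq(3L, n, 4L)]
  qual <- lines[seq(4L, n, 4L)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop("malformed FASTQ header at line ", (bad[1] - 1L) * 4L + 1L)
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop("malformed FASTQ separator at line ", (bad[1] - 1L) * 4L + 3L)
  }
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    stop("sequence/quality length mismatch at line ",
         (bad[1] - 1L) * 4L + 2L)
  }
  tibble(read_id = sub("^@", "", sub("\\s.*$", "", hdr)),
         sequence = toupper(seq), quality = qual)
}

#' Read a FASTA file into a read table
#'
#' @param path FASTA path (`.gz` allowed).
#' @return Tibble `read_id`, `sequence`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  seqs <- Biostrings::readDNAStringSet(path)
  tibble(read_id = sub("\\s.*$", "", names(seqs)),
         sequence = toupper(as.character(seqs)))
}

#' Write reads as FASTQ
#'
#' @param reads Tibble with `read_id`, `sequence` (and optionally
#'   `quality`; constant Q40 `I` otherwise).
#' @param path Output path (`.gz` for gzip).
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("quality" %in% names(reads)) reads$quality else NULL
  if (is.null(qual)) {
    qual <- vapply(nchar(reads$sequence), function(n) {
      paste(rep("I", n), collapse = "")
    }, "")
  }
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  writeLines(lines, con)
  invisible(path)
}

# AIRR Rearrangement columns written by write_airr
airr_columns <- c("sequence_id", "sequence", "v_call", "j_call", "junction",
                  "junction_aa", "productive", "duplicate_count",
                  "fail_reason")

#' Write annotated reads as an AIRR Rearrangement TSV
#'
#' One row per read with the community-standard columns `sequence_id`,
#' `sequence`, `v_call`, `j_call`, `junction`, `junction_aa`,
#' `productive` (T/F), `duplicate_count`, plus `fail_reason` as a
#' custom column.  Failed stages leave their fields empty.  The file
#' round-trips through [read_airr()].
#'
#' @param annotated Tibble from [annotate_reads()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_airr <- function(annotated, path) {
  call <- function(gene, allele) {
    ifelse(is.na(gene), "", paste0(gene, "*", allele))
  }
  out <- tibble(
    sequence_id = annotated$read_id,
    sequence = annotated$sequence,
    v_call = call(annotated$v_gene, annotated$v_allele),
    j_call = call(annotated$j_gene, annotated$j_allele),
    junction = ifelse(is.na(annotated$cdr3_nt), "", annotated$cdr3_nt),
    junction_aa = ifelse(is.na(annotated$cdr3_aa), "", annotated$cdr3_aa),
    productive = ifelse(annotated$productive, "T", "F"),
    duplicate_count = 1L,
    fail_reason = annotated$fail_reason
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an AIRR Rearrangement TSV written by [write_airr()]
#'
#' @param path TSV path.
#' @return Tibble in [annotate_reads()] layout (gene/allele split out of
#'   the calls; empty fields become `NA`).
#' @export
read_airr <- function(path) {
  stopifnot(file.exists(path))
  raw <- as_tibble(read.delim(path, colClasses = "character",
                              na.strings = NULL, check.names = FALSE))
  missing_cols <- setdiff(airr_columns, names(raw))
  if (length(missing_cols)) {
    stop("not an AIRR table from this package; missing: ",
         paste(missing_cols, collapse = ", "))
  }
  split_call <- function(x, part) {
    out <- rep(NA_character_, length(x))
    ok <- nzchar(x)
    pieces <- strsplit(x[ok], "*", fixed = TRUE)
    out[ok] <- vapply(pieces, `[[`, "", part)
    out
  }
  tibble(
    read_id = raw$sequence_id,
    sequence = raw$sequence,
    v_gene = split_call(raw$v_call, 1L),
    v_allele = split_call(raw$v_call, 2L),
    j_gene = split_call(raw$j_call, 1L),
    j_allele = split_call(raw$j_call, 2L),
    cdr3_nt = ifelse(nzchar(raw$junction), raw$junction, NA_character_),
    cdr3_aa = ifelse(nzchar(raw$junction_aa), raw$junction_aa,
                     NA_character_),
    productive = raw$productive == "T",
    fail_reason = raw$fail_reason
  )
}

#' Write a clonotype table as TSV
#'
#' Frequencies are printed with 2 decimals (full precision is retained
#' in the in-memory table).
#'
#' @param clonotypes Tibble from [aggregate_clonotypes()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_clonotypes <- function(clonotypes, path) {
  out <- clonotypes[, c("rank", "v_gene", "j_gene", "cdr3_aa",
                        "copy_count", "frequency_pct")]
  out$frequency_pct <- sprintf("%.2f", out$frequency_pct)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
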