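#' Aggregate annotated reads into clonotypes
#'
#' A clonotype is the equivalence class of reads sharing V gene, J gene
#' and CDR3 amino-acid sequence (gene-level, allele ignored; a
#' nucleotide-level grouping is available via `key_nt = TRUE`).  Copy
#' numbers are counted, percentage frequencies computed over the
#' eligible-read denominator, and clonotypes ranked by copy count
#' (descending), ties broken lexicographically by (v_gene, j_gene,
#' cdr3_aa) for determinism.
#'
#' By default only productive reads count; `include_unproductive = TRUE`
#' additionally counts reads whose junction was extractable but contains
#' a stop codon.  Reads without an extractable junction never count.
#'
#' @param annotated Tibble from [annotate_reads()].
#' @param include_unproductive Include stop-codon junctions.
#' @param key_nt Group by nucleotide junction instead of amino acid.
#' @return Tibble with `v_gene`, `j_gene`, `cdr3_aa` (and `cdr3_nt` when
#'   `key_nt`), `copy_count`, `frequency_pct`, `rank`.
#' @export
aggregate_clonotypes <- function(annotated, include_unproductive = FALSE,
                                 key_nt = FALSE) {
  el <- eligible_reads(annotated, include_unproductive)
  if (nrow(el) == 0L) stop("empty repertoire: no eligible reads")
  keys <- if (key_nt) c("v_gene", "j_gene", "cdr3_nt", "cdr3_aa") else
    c("v_gene", "j_gene", "cdr3_aa")
  tab <- el %>%
    group_by(dplyr::across(dplyr::all_of(keys))) %>%
    summarise(copy_count = dplyr::n(), .groups = "drop") %>%
    mutate(frequency_pct = 100 * .data$copy_count / sum(.data$copy_count)) %>%
    arrange(desc(.data$copy_count), .data$v_gene, .data$j_gene,
            .data$cdr3_aa) %>%
    mutate(rank = row_number())
  tab
}

# the shared eligibility rule behind every percentage denominator
eligible_reads <- function(annotated, include_unproductive = FALSE) {
  stopifnot(is.data.frame(annotated))
  keep <- annotated$productive
  if (include_unproductive) {
    keep <- keep | annotated$fail_reason == "stop_codon"
  }
  annotated[keep & !is.na(annotated$cdr3_aa), , drop = FALSE]
}

#' V / J / VxJ gene-usage frequencies
#'
#' Percentage occurrence frequencies of V genes, J genes, or V-J
#' combinations, read-weighted over the same denominator as
#' [aggregate_clonotypes()] (each eligible read counts once; pass a
#' clonotype table and counts are weighted by `copy_count`).
#'
#' @param x Annotated-read tibble or clonotype tibble (recognised by a
#'   `copy_count` column).
#' @param level `"V"`, `"J"` or `"VJ"`.
#' @param include_unproductive Passed to the eligibility rule when `x`
#'   is an annotated-read table.
#' @return For `"V"`/`"J"`: tibble `gene`, `frequency_pct`.  For
#'   `"VJ"`: a `usage_matrix` — V genes x J genes matrix of percentages
#'   whose grand total is 100.
#' @export
gene_usage <- function(x, level = c("V", "J", "VJ"),
                       include_unproductive = FALSE) {
  level <- match.arg(level)
  if (!"copy_count" %in% names(x)) {
    x <- eligible_reads(x, include_unproductive)
    if (nrow(x) == 0L) stop("empty repertoire: no eligible reads")
    x$copy_count <- 1L
  }
  if (nrow(x) == 0L) stop("empty clonotype table")
  total <- sum(x$copy_count)
  if (level %in% c("V", "J")) {
    col <- if (level == "V") "v_gene" else "j_gene"
    out <- x %>%
      group_by(gene = .data[[col]]) %>%
      summarise(frequency_pct = 100 * sum(.data$copy_count) / total,
                .groups = "drop") %>%
      arrange(desc(.data$frequency_pct), .data$gene)
    return(out)
  }
  long <- x %>%
    group_by(.data$v_gene, .data$j_gene) %>%
    summarise(pct = 100 * sum(.data$copy_count) / total, .groups = "drop")
  v_genes <- sort(unique(long$v_gene))
  j_genes <- sort(unique(long$j_gene))
  m <- matrix(0, length(v_genes), length(j_genes),
              dimnames = list(v_genes, j_genes))
  m[cbind(match(long$v_gene, v_genes), match(long$j_gene, j_genes))] <-
    long$pct
  structure(m, class = c("usage_matrix", "matrix"))
}

#' @export
print.usage_matrix <- function(x, ...) {
  cat("<usage_matrix> ", nrow(x), " V x ", ncol(x),
      " J, grand total ", format(sum(x)), "%\n", sep = "")
  print(unclass(round(x, 2)))
  invisible(x)
}

#' Long-format view of a usage matrix
#'
#' @param um A `usage_matrix` from [gene_usage()].
#' @param drop_zero Drop empty V-J combinations.
#' @return Tibble `v_gene`, `j_gene`, `pct`.
#' @export
usage_long <- function(um, drop_zero = TRUE) {
  stopifnot(inherits(um, "usage_matrix"))
  out <- tibble(
    v_gene = rep(rownames(um), times = ncol(um)),
    j_gene = rep(colnames(um), each = nrow(um)),
    pct = as.vector(um)
  )
  if (drop_zero) out <- out[out$pct > 0, ]
  out
}

#' Perspective plot of a V x J usage matrix
#'
#' Renders the usage surface (V genes on one horizontal axis, J genes on
#' the other, percentage frequency as height), the conventional 3-D
#' display of repertoire skewing.
#'
#' @param um A `usage_matrix`.
#' @param file Optional PNG path; when given the plot is written there.
#' @param ... Passed to [graphics::persp()].
#' @return Invisibly, the matrix.
#' @export
plot_usage_matrix <- function(um, file = NULL, ...) {
  stopifnot(inherits(um, "usage_matrix"))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  graphics::persp(x = seq_len(nrow(um)), y = seq_len(ncol(um)),
                  z = unclass(um), xlab = "TRAV", ylab = "TRAJ",
                  zlab = "frequency (%)", theta = 40, phi = 25,
                  col = "lightsteelblue", shade = 0.4, ...)
  invisible(um)
}

#' Top-ranked clonotypes
#'
#' The first `n` rows of the ranked clonotype table (fewer when the
#' repertoire has fewer clonotypes), the standard "top 30" repertoire
#' summary.
#'
#' @param clonotypes Tibble from [aggregate_clonotypes()].
#' @param n Number of rows (default 30).
#' @return Tibble with columns `rank`, `v_gene`, `j_gene`, `cdr3_aa`,
#'   `copy_count`, `frequency_pct`.
#' @export
top_clonotypes <- function(clonotypes, n = 30L) {
  if (n < 1L) stop("n must be >= 1")
  clonotypes %>%
    arrange(.data$rank) %>%
    head(n) %>%
    select("rank", "v_gene", "j_gene", "cdr3_aa", "copy_count",
           "frequency_pct")
}
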