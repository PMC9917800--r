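#' Bundle a clonotype table with sample metadata
#'
#' @param sample_id Unique sample identifier.
#' @param clonotypes Tibble from [aggregate_clonotypes()].
#' @param tissue e.g. `"OM"` (oral mucosa) or `"LY"` (cervical lymph
#'   node).
#' @param group e.g. `"ACM"` (allergic) or `"ICM"` (irritant).
#' @param day Day post-challenge.
#' @return A `repertoire_sample` list.
#' @export
repertoire_sample <- function(sample_id, clonotypes, tissue = NA_character_,
                              group = NA_character_, day = NA_integer_) {
  stopifnot(is.character(sample_id), nzchar(sample_id),
            is.data.frame(clonotypes),
            all(c("v_gene", "j_gene", "cdr3_aa", "frequency_pct") %in%
                  names(clonotypes)))
  structure(list(sample_id = sample_id, tissue = tissue, group = group,
                 day = as.integer(day), clonotypes = as_tibble(clonotypes)),
            class = "repertoire_sample")
}

#' @export
print.repertoire_sample <- function(x, ...) {
  cat("<repertoire_sample> ", x$sample_id, " (", x$tissue, "/", x$group,
      ", day ", x$day, "): ", nrow(x$clonotypes), " clonotypes\n", sep = "")
  invisible(x)
}

#' Cross-sample shared-clonotype table
#'
#' Builds the clonotype-by-sample frequency cross-tabulation: rows are
#' the union of clonotype keys over all samples, one frequency column
#' per sample, `NA` where a clonotype was not detected in that sample
#' (serialised as the literal `"N.D."` by [write_shared_table()]).
#' Rows are ordered by decreasing maximum (or mean) frequency across
#' samples, then by clonotype key.
#'
#' @param samples List of [repertoire_sample()] objects (at least 2,
#'   unique `sample_id`s).
#' @param order_by `"max"` or `"mean"` across-sample frequency.
#' @return Tibble: `v_gene`, `j_gene`, `cdr3_aa`, then one numeric
#'   column per sample_id.
#' @export
shared_clonotypes <- function(samples, order_by = c("max", "mean")) {
  order_by <- match.arg(order_by)
  stopifnot(is.list(samples), length(samples) >= 2L,
            all(vapply(samples, inherits, TRUE, "repertoire_sample")))
  ids <- vapply(samples, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id: ", ids[duplicated(ids)][1])
  }
  long <- bind_rows(lapply(samples, function(s) {
    tibble(sample_id = s$sample_id,
           v_gene = s$clonotypes$v_gene,
           j_gene = s$clonotypes$j_gene,
           cdr3_aa = s$clonotypes$cdr3_aa,
           frequency_pct = s$clonotypes$frequency_pct)
  }))
  wide <- tidyr::pivot_wider(long, names_from = "sample_id",
                             values_from = "frequency_pct")
  wide <- wide[, c("v_gene", "j_gene", "cdr3_aa", ids)]
  stat <- apply(as.matrix(wide[, ids, drop = FALSE]), 1, function(r) {
    if (order_by == "max") max(r, na.rm = TRUE) else mean(r, na.rm = TRUE)
  })
  wide[order(-stat, wide$v_gene, wide$j_gene, wide$cdr3_aa), ]
}

#' Write a shared-clonotype table with N.D. markers
#'
#' Frequencies are printed with 2 decimals; clonotypes absent from a
#' sample are written as the literal string `N.D.` ("not detected").
#'
#' @param tab Tibble from [shared_clonotypes()] (optionally after
#'   [annotate_invariants()]).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_shared_table <- function(tab, path) {
  out <- tab
  num <- vapply(out, is.numeric, TRUE)
  for (col in names(out)[num]) {
    v <- sprintf("%.2f", out[[col]])
    v[is.na(out[[col]])] <- "N.D."
    out[[col]] <- v
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load invariant T-cell clonotype definitions
#'
#' The bundled defaults define mouse iNKT cells by TRAV11* paired with
#' TRAJ18 and MAIT cells by TRAV1* paired with TRAJ33; the canonical
#' CDR3 sequences (CVVGDRGSALGRLHF, CAVRDSNYQLIW) ride along as
#' documentation, not as matching requirements — the gene pair defines
#' the population.
#'
#' @param path Definitions TSV (columns `label`, `v_gene_pattern`,
#'   `j_gene`, `cdr3_aa`); defaults to the bundled file.
#' @return Tibble of definitions.
#' @export
load_invariant_definitions <- function(path = NULL) {
  path <- path %||% system.file("extdata", "invariant_definitions.tsv",
                                package = "tcrclone")
  defs <- as_tibble(read.delim(path, colClasses = "character",
                               na.strings = NULL))
  stopifnot(all(c("label", "v_gene_pattern", "j_gene", "cdr3_aa") %in%
                  names(defs)),
            all(nzchar(defs$label)))
  if (any(!nzchar(defs$v_gene_pattern) & !nzchar(defs$j_gene) &
            !nzchar(defs$cdr3_aa))) {
    stop("each definition needs at least one matching field")
  }
  defs
}

#' Annotate clonotypes with invariant T-cell labels
#'
#' Each row gains the first matching definition's label (definitions
#' are tried in list order; overlapping definitions are allowed).  A
#' definition matches when the V gene starts with `v_gene_pattern`
#' (prefix match, so `TRAV11` also matches the `TRAV11d`/`TRAV11D`
#' spelling variants), the J gene is equal, and — only if the
#' definition gives one — the CDR3 amino-acid sequence is equal.
#'
#' @param tab Any tibble with `v_gene`, `j_gene`, `cdr3_aa` columns
#'   (clonotype table or shared-clonotype table).
#' @param defs Definitions tibble; defaults to
#'   [load_invariant_definitions()].
#' @return `tab` with a `label` column (`NA` where nothing matches).
#' @export
annotate_invariants <- function(tab, defs = load_invariant_definitions()) {
  stopifnot(all(c("v_gene", "j_gene", "cdr3_aa") %in% names(tab)))
  label <- rep(NA_character_, nrow(tab))
  for (k in seq_len(nrow(defs))) {
    d <- defs[k, ]
    hit <- startsWith(tab$v_gene, d$v_gene_pattern) &
      tab$j_gene == d$j_gene
    if (nzchar(d$cdr3_aa %||% "") && !is.na(d$cdr3_aa) && nzchar(d$cdr3_aa)) {
      hit <- hit & tab$cdr3_aa == d$cdr3_aa
    }
    label[is.na(label) & hit] <- d$label
  }
  tab$label <- label
  tab
}

#' Frequency of one clonotype across a time course
#'
#' Tracks a single clonotype key through samples taken on different
#' days (samples must share tissue and group); days where the clonotype
#' is not detected yield `NA` frequency.
#'
#' @param samples List of [repertoire_sample()] objects.
#' @param v_gene,j_gene,cdr3_aa The clonotype key to follow.
#' @return Tibble `day`, `sample_id`, `frequency_pct`, ordered by day.
#' @export
presence_over_time <- function(samples, v_gene, j_gene, cdr3_aa) {
  if (length(samples) == 0L) stop("empty sample list")
  stopifnot(all(vapply(samples, inherits, TRUE, "repertoire_sample")))
  tis <- unique(vapply(samples, `[[`, "", "tissue"))
  grp <- unique(vapply(samples, `[[`, "", "group"))
  if (length(tis) > 1L || length(grp) > 1L) {
    stop("samples must share tissue and group for a time course")
  }
  rows <- lapply(samples, function(s) {
    ct <- s$clonotypes
    hit <- ct$v_gene == v_gene & ct$j_gene == j_gene &
      ct$cdr3_aa == cdr3_aa
    tibble(day = s$day, sample_id = s$sample_id,
           frequency_pct = if (any(hit)) ct$frequency_pct[which(hit)[1]]
           else NA_real_)
  })
  bind_rows(rows) %>% arrange(.data$day)
}
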