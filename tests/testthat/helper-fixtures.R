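# Shared fixtures.  The toy reference ships with the package; larger
# simulations are cached per (seed, error_rate) so acceptance tests can
# share the standard study-sized run without recomputing it.

toy_db <- function() toy_reference()

# standard study-sized simulation: 50 random clones + the 3 canonical
# spiked clonotypes, 10,000 reads
study_config <- function(seed = 1L, error_rate = 0) {
  simulation_config(n_clones = 50L, read_count = 10000L,
                    error_rate = error_rate,
                    spike_ins = canonical_spike_ins(), seed = seed)
}

.sim_cache <- new.env(parent = emptyenv())

study_run <- function(seed = 1L, error_rate = 0, annotate = TRUE) {
  key <- paste0("s", seed, "_e", error_rate, "_a", annotate)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  db <- toy_db()
  cfg <- study_config(seed, error_rate)
  clones <- simulate_repertoire(cfg, db)
  rr <- generate_reads(clones, cfg, db)
  res <- list(db = db, cfg = cfg, clones = clones,
              reads = rr$reads, truth = rr$truth)
  if (annotate) res$annotated <- annotate_reads(rr$reads, db)
  .sim_cache[[key]] <- res
  res
}

clonotype_key <- function(v, j, aa) paste(v, j, aa, sep = "|")

# a small custom reference written to temp files, returned as paths
write_mini_reference <- function(segs, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("miniref")
    dir.create(dir)
  }
  fasta <- file.path(dir, "ref.fasta")
  anchors <- file.path(dir, "anchors.tsv")
  writeLines(unlist(lapply(segs, function(s) {
    c(paste0(">", s$gene, "|", s$allele %||% "01", "|", s$type, "|",
             s$chain %||% "TRA"), s$seq)
  })), fasta)
  tab <- data.frame(
    gene_name = vapply(segs, `[[`, "", "gene"),
    allele = vapply(segs, function(s) s$allele %||% "01", ""),
    segment_type = vapply(segs, `[[`, "", "type"),
    chain = vapply(segs, function(s) s$chain %||% "TRA", ""),
    anchor_codon_start = vapply(segs, function(s) as.integer(s$anchor), 1L),
    frame_offset = vapply(segs, function(s) as.integer(s$anchor %% 3L), 1L)
  )
  write.table(tab, anchors, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fasta, anchors = anchors)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
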