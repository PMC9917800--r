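#' Pipeline configuration
#'
#' Everything [run_pipeline()] needs: reference paths, alignment
#' parameters, extraction flags and output location.  Referenced files
#' are checked at validation time.
#'
#' @param reference_fasta,anchor_table Reference paths (see
#'   [load_reference()]).
#' @param out_dir Output directory (created if needed).
#' @param chain `"TRA"` or `"TRB"`.
#' @param params [assignment_params()].
#' @param include_unproductive Count stop-codon junctions in clonotype
#'   frequencies.
#' @param both_strands Scan reverse complements during assignment.
#' @param max_vj_overlap Chimera threshold passed to [annotate_reads()].
#' @param top_n Rows in the top-clonotype table.
#' @param seed Integer seed recorded in the manifest (the analysis
#'   itself is deterministic; the seed matters when the pipeline drives
#'   a simulation).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(reference_fasta, anchor_table, out_dir,
                            chain = "TRA", params = assignment_params(),
                            include_unproductive = FALSE,
                            both_strands = FALSE, max_vj_overlap = 8L,
                            top_n = 30L, seed = 1L) {
  stopifnot(file.exists(reference_fasta), file.exists(anchor_table),
            chain %in% c("TRA", "TRB"), top_n >= 1L)
  structure(list(reference_fasta = reference_fasta,
                 anchor_table = anchor_table, out_dir = out_dir,
                 chain = chain, params = params,
                 include_unproductive = isTRUE(include_unproductive),
                 both_strands = isTRUE(both_strands),
                 max_vj_overlap = as.integer(max_vj_overlap),
                 top_n = as.integer(top_n), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full annotation pipeline on a read file
#'
#' Reads FASTQ/FASTA input, assigns V and J segments, extracts CDR3s,
#' aggregates clonotypes and V-J usage, and writes the output bundle:
#' `annotated.tsv` (AIRR Rearrangement), `clonotypes.tsv`,
#' `top_clonotypes.tsv`, `usage_vj.tsv` (long format) and
#' `manifest.json`.  The manifest records the tool version, a config
#' hash, the input checksum and the read accounting — every input read
#' appears exactly once across the pass/fail categories
#' (`n_input = n_pass + sum(n_fail_by_reason)`).  On failure, partial
#' outputs are removed.  Given identical inputs and configuration the
#' outputs are byte-identical.
#'
#' @param cfg A [pipeline_config()].
#' @param reads_path FASTQ (`.fastq`/`.fq`, optionally `.gz`) or FASTA
#'   input.
#' @return Invisibly, a list with `annotated`, `clonotypes`, `usage`,
#'   `manifest` and the output paths.
#' @export
run_pipeline <- function(cfg, reads_path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!file.exists(reads_path)) stop("unreadable input: ", reads_path)
  reads <- if (grepl("\\.(fastq|fq)(\\.gz)?$", reads_path)) {
    read_fastq(reads_path)
  } else {
    read_fasta(reads_path)
  }
  if (nrow(reads) == 0L) stop("no reads in ", reads_path)
  db <- load_reference(cfg$reference_fasta, cfg$anchor_table, quiet = TRUE)

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(cfg$out_dir, c(
    annotated = "annotated.tsv", clonotypes = "clonotypes.tsv",
    top = "top_clonotypes.tsv", usage = "usage_vj.tsv",
    manifest = "manifest.json"))
  names(paths) <- c("annotated", "clonotypes", "top", "usage", "manifest")
  written <- character(0)
  tryCatch({
    annotated <- annotate_reads(reads, db, cfg$params, cfg$chain,
                                cfg$both_strands, cfg$max_vj_overlap)
    write_airr(annotated, paths[["annotated"]])
    written <- c(written, paths[["annotated"]])

    clon <- aggregate_clonotypes(annotated, cfg$include_unproductive)
    write_clonotypes(clon, paths[["clonotypes"]])
    written <- c(written, paths[["clonotypes"]])
    write_clonotypes(top_clonotypes(clon, cfg$top_n), paths[["top"]])
    written <- c(written, paths[["top"]])

    um <- gene_usage(clon, "VJ")
    long <- usage_long(um, drop_zero = FALSE)
    write.table(long, paths[["usage"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    written <- c(written, paths[["usage"]])

    fail_counts <- table(annotated$fail_reason[annotated$fail_reason != "none"])
    manifest <- list(
      tool = "tcrclone",
      version = as.character(packageVersion("tcrclone")),
      config_hash = config_hash(cfg),
      input = reads_path,
      input_md5 = unname(tools::md5sum(reads_path)),
      seed = cfg$seed,
      n_input = nrow(reads),
      n_pass = sum(annotated$fail_reason == "none"),
      n_fail_by_reason = as.list(fail_counts),
      n_productive = sum(annotated$productive),
      n_clonotypes = nrow(clon)
    )
    stopifnot(manifest$n_input ==
                manifest$n_pass + sum(unlist(manifest$n_fail_by_reason)))
    jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                         pretty = TRUE)
    written <- c(written, paths[["manifest"]])
    invisible(list(annotated = annotated, clonotypes = clon, usage = um,
                   manifest = manifest, paths = paths))
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
}

# stable md5 over the serialised configuration
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  flat <- cfg
  flat$params <- unclass(flat$params)
  jsonlite::write_json(unclass(flat), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
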