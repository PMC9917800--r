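#' Simulation configuration for synthetic V(D)J repertoires
#'
#' Collects every knob of the repertoire/read simulator.  Clone
#' abundances follow a renormalised lognormal (default meanlog 0,
#' sdlog 1.5 — a strongly skewed spectrum in which a handful of clones
#' dominate the top of the ranking, as real amplicon repertoires do) or
#' a power law.  Junctional diversity: V 3' and J 5' trimming uniform on
#' `0..trim_max` (anchors are never trimmed away), N-insert length
#' geometric with success probability `n_insert_geom_p`, bases i.i.d.
#' uniform.  Sequencing error is i.i.d. per-base substitution.
#'
#' @param n_clones Number of randomly generated clones (spike-ins are
#'   added on top).
#' @param chain `"TRA"` or `"TRB"`.
#' @param abundance_model `"lognormal"` or `"powerlaw"`.
#' @param abundance_params Model parameters: `list(meanlog=, sdlog=)` or
#'   `list(alpha=)`.
#' @param trim_max Maximum nucleotides trimmed from the V 3' / J 5' end.
#' @param n_insert_geom_p Geometric success probability for the
#'   untemplated insert length.
#' @param max_insert Cap on insert length (nt).
#' @param read_count Reads to generate.
#' @param error_rate Per-base substitution probability in `[0, 1]`.
#' @param productive_only Only emit productive clones (in-frame,
#'   stop-free C...F/W junctions).
#' @param spike_ins Data frame with columns `v_gene`, `j_gene`,
#'   `cdr3_aa`, `frequency` — clonotypes injected at fixed frequency
#'   (must sum to < 1).
#' @param seed Integer seed; identical configuration and seed give
#'   byte-identical output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_clones = 100L, chain = "TRA",
                              abundance_model = c("lognormal", "powerlaw"),
                              abundance_params = NULL,
                              trim_max = 6L, n_insert_geom_p = 0.4,
                              max_insert = 12L,
                              read_count = 10000L, error_rate = 0,
                              productive_only = TRUE,
                              spike_ins = NULL, seed = 1L) {
  abundance_model <- match.arg(abundance_model)
  if (is.null(abundance_params)) {
    abundance_params <- if (abundance_model == "lognormal") {
      list(meanlog = 0, sdlog = 1.5)
    } else {
      list(alpha = 1.5)
    }
  }
  stopifnot(n_clones >= 0L, chain %in% c("TRA", "TRB"),
            trim_max >= 0L, n_insert_geom_p > 0, n_insert_geom_p <= 1,
            error_rate >= 0, error_rate <= 1, read_count >= 0L)
  if (!is.null(spike_ins)) {
    spike_ins <- as_tibble(spike_ins)
    stopifnot(all(c("v_gene", "j_gene", "cdr3_aa", "frequency") %in%
                    names(spike_ins)),
              all(spike_ins$frequency >= 0 & spike_ins$frequency <= 1))
    if (sum(spike_ins$frequency) >= 1) {
      stop("spike-in frequencies must sum to < 1")
    }
  }
  structure(list(n_clones = as.integer(n_clones), chain = chain,
                 abundance_model = abundance_model,
                 abundance_params = abundance_params,
                 trim_max = as.integer(trim_max),
                 n_insert_geom_p = n_insert_geom_p,
                 max_insert = as.integer(max_insert),
                 read_count = as.integer(read_count),
                 error_rate = error_rate,
                 productive_only = isTRUE(productive_only),
                 spike_ins = spike_ins, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Canonical invariant / Cr-associated spike-in set
#'
#' The three TRA clonotypes repeatedly observed in murine oral-mucosa
#' metal-allergy repertoires: the iNKT invariant chain
#' TRAV11-TRAJ18 / CVVGDRGSALGRLHF, the Cr-associated
#' TRAV12D-1-TRAJ22 / CALSEKSSGSWQLIF, and the MAIT invariant chain
#' TRAV1-TRAJ33 / CAVRDSNYQLIW.  Default frequencies (0.15 / 0.08 /
#' 0.04) reproduce the observed ordering with the iNKT clone dominant.
#'
#' @param frequencies Numeric length-3 vector of spike frequencies in
#'   the order iNKT, Cr-associated, MAIT.
#' @return Tibble usable as `spike_ins` in [simulation_config()].
#' @export
canonical_spike_ins <- function(frequencies = c(0.15, 0.08, 0.04)) {
  stopifnot(length(frequencies) == 3L, all(frequencies >= 0),
            sum(frequencies) < 1)
  tibble(
    v_gene = c("TRAV11", "TRAV12D-1", "TRAV1"),
    j_gene = c("TRAJ18", "TRAJ22", "TRAJ33"),
    cdr3_aa = c("CVVGDRGSALGRLHF", "CALSEKSSGSWQLIF", "CAVRDSNYQLIW"),
    frequency = frequencies
  )
}

# amino acid -> lexicographically smallest codon, from the standard code
smallest_codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- sort(names(gc))  # lexicographic
  tab <- tapply(codons, gc[codons], function(x) x[1])
  tab[names(tab) != "*"]
}

# Build a spike-in clone: template whole codons greedily from the V
# anchor forward and the J anchor backward, reverse-translate the
# interior with the lexicographically smallest codons.
build_spike_clone <- function(v_gene, j_gene, cdr3_aa, db) {
  v <- ref_lookup(db, v_gene)
  j <- ref_lookup(db, j_gene)
  aa <- strsplit(cdr3_aa, "")[[1]]
  n_aa <- length(aa)
  if (n_aa < 2L) stop("CDR3 must have at least 2 residues")
  v_anchor_aa <- translate_nt(substr(v$sequence, v$anchor_codon_start + 1L,
                                     v$anchor_codon_start + 3L))
  if (aa[1] != v_anchor_aa) {
    stop("cannot place CDR3 ", cdr3_aa, " on ", v_gene,
         ": first residue must be ", v_anchor_aa)
  }
  j_anchor_aa <- translate_nt(substr(j$sequence, j$anchor_codon_start + 1L,
                                     j$anchor_codon_start + 3L))
  if (aa[n_aa] != j_anchor_aa) {
    stop("cannot place CDR3 ", cdr3_aa, " on ", j_gene,
         ": last residue must be ", j_anchor_aa)
  }
  v_len <- nchar(v$sequence)
  # whole codons available in V after the anchor codon
  v_codons_avail <- (v_len - (v$anchor_codon_start + 3L)) %/% 3L
  v_tmpl <- 0L
  while (v_tmpl < v_codons_avail && 2L + v_tmpl <= n_aa - 1L) {
    s <- v$anchor_codon_start + 3L + 3L * v_tmpl
    if (translate_nt(substr(v$sequence, s + 1L, s + 3L)) != aa[2L + v_tmpl]) break
    v_tmpl <- v_tmpl + 1L
  }
  # whole codons available in J before the anchor codon (on its frame)
  j_codons_avail <- j$anchor_codon_start %/% 3L
  j_tmpl <- 0L
  while (j_tmpl < j_codons_avail && n_aa - 1L - j_tmpl >= 2L + v_tmpl) {
    s <- j$anchor_codon_start - 3L * (j_tmpl + 1L)
    if (translate_nt(substr(j$sequence, s + 1L, s + 3L)) !=
        aa[n_aa - 1L - j_tmpl]) break
    j_tmpl <- j_tmpl + 1L
  }
  mid <- aa[seq_len(n_aa)[-c(seq_len(1L + v_tmpl),
                             (n_aa - j_tmpl):n_aa)]]
  tab <- smallest_codon_table()
  if (!all(mid %in% names(tab))) {
    stop("CDR3 contains non-standard residue: ",
         paste(setdiff(mid, names(tab)), collapse = ""))
  }
  n_insert <- paste(tab[mid], collapse = "")
  v_trim <- v_len - (v$anchor_codon_start + 3L + 3L * v_tmpl)
  j_trim <- j$anchor_codon_start - 3L * j_tmpl
  clone_from_parts(v, j, v_trim, j_trim, n_insert)
}

# assemble junction/read structure for given parts; returns clone fields
clone_from_parts <- function(v, j, v_trim, j_trim, n_insert) {
  v_len <- nchar(v$sequence)
  junction_nt <- paste0(
    substr(v$sequence, v$anchor_codon_start + 1L, v_len - v_trim),
    n_insert,
    substr(j$sequence, j_trim + 1L, j$anchor_codon_start + 3L)
  )
  aa <- if (nchar(junction_nt) %% 3L == 0L) translate_nt(junction_nt) else NA_character_
  productive <- !is.na(aa) && !grepl("*", aa, fixed = TRUE) &&
    substr(aa, 1L, 1L) == "C" &&
    substr(aa, nchar(aa), nchar(aa)) %in% c("F", "W")
  list(v_gene = v$gene_name, j_gene = j$gene_name,
       v_trim = as.integer(v_trim), j_trim = as.integer(j_trim),
       n_insert = n_insert, junction_nt = junction_nt,
       cdr3_aa = aa, productive = productive)
}

#' Simulate a ground-truthed clonal repertoire
#'
#' Draws `n_clones` random clones (V/J choice uniform, junctional
#' trimming and N-insertion per the configuration) plus the configured
#' spike-ins, which are constructed by reverse translation so that they
#' carry exactly the requested (V, J, CDR3) and are reproduced verbatim
#' by error-free sequencing.  True frequencies are lognormal/power-law
#' draws renormalised so that, together with the fixed spike
#' frequencies, they sum to 1.  Clonotype keys (V, J, CDR3 amino acid)
#' are unique across the repertoire.  Fully deterministic given the
#' seed.
#'
#' @param cfg A [simulation_config()].
#' @param db A `ReferenceDB`; all spike-in genes must exist in it.
#' @return Tibble of clones: `clone_id`, `v_gene`, `j_gene`, `v_trim`,
#'   `j_trim`, `n_insert`, `junction_nt`, `cdr3_aa`, `productive`,
#'   `true_frequency`.
#' @export
simulate_repertoire <- function(cfg, db) {
  stopifnot(inherits(cfg, "simulation_config"), inherits(db, "ReferenceDB"))
  with_seed(cfg$seed, simulate_repertoire_impl(cfg, db))
}

simulate_repertoire_impl <- function(cfg, db) {
  spikes <- list()
  spike_freq <- numeric(0)
  if (!is.null(cfg$spike_ins) && nrow(cfg$spike_ins)) {
    for (k in seq_len(nrow(cfg$spike_ins))) {
      s <- cfg$spike_ins[k, ]
      cl <- build_spike_clone(s$v_gene, s$j_gene, s$cdr3_aa, db)
      cl$clone_id <- sprintf("spike-%d", k)
      spikes[[k]] <- cl
    }
    spike_freq <- cfg$spike_ins$frequency
  }
  used_keys <- vapply(spikes, function(cl) {
    paste(cl$v_gene, cl$j_gene, cl$cdr3_aa, sep = "|")
  }, "")

  vs <- ref_segments(db, "V", cfg$chain)
  js <- ref_segments(db, "J", cfg$chain)
  if (cfg$n_clones > 0L && (nrow(vs) == 0L || nrow(js) == 0L)) {
    stop("reference has no V/J segments for chain ", cfg$chain)
  }
  clones <- vector("list", cfg$n_clones)
  i <- 0L
  while (i < cfg$n_clones) {
    cl <- random_clone(vs, js, cfg)
    key <- paste(cl$v_gene, cl$j_gene, cl$cdr3_aa, sep = "|")
    if (key %in% used_keys) next
    used_keys <- c(used_keys, key)
    i <- i + 1L
    cl$clone_id <- sprintf("clone-%03d", i)
    clones[[i]] <- cl
  }

  w <- switch(cfg$abundance_model,
    lognormal = rlnorm(cfg$n_clones, cfg$abundance_params$meanlog,
                       cfg$abundance_params$sdlog),
    powerlaw = seq_len(cfg$n_clones)^(-cfg$abundance_params$alpha)
  )
  rand_freq <- if (cfg$n_clones > 0L) {
    w / sum(w) * (1 - sum(spike_freq))
  } else {
    numeric(0)
  }
  all_clones <- c(spikes, clones)
  out <- bind_rows(lapply(all_clones, function(cl) {
    as_tibble(cl[c("clone_id", "v_gene", "j_gene", "v_trim", "j_trim",
                   "n_insert", "junction_nt", "cdr3_aa", "productive")])
  }))
  out$true_frequency <- c(spike_freq, rand_freq)
  out$true_frequency <- out$true_frequency / sum(out$true_frequency)
  out
}

# one random clone; resamples until productive when required
random_clone <- function(vs, js, cfg, max_tries = 500L) {
  for (t in seq_len(max_tries)) {
    v <- vs[sample.int(nrow(vs), 1L), ]
    j <- js[sample.int(nrow(js), 1L), ]
    v_len <- nchar(v$sequence)
    v_avail <- v_len - (v$anchor_codon_start + 3L)  # nt after anchor codon
    v_trim <- sample.int(min(cfg$trim_max, v_avail) + 1L, 1L) - 1L
    j_trim <- sample.int(min(cfg$trim_max, j$anchor_codon_start) + 1L, 1L) - 1L
    ins_len <- min(rgeom(1L, cfg$n_insert_geom_p), cfg$max_insert)
    if (cfg$productive_only) {
      v_contrib <- 3L + v_avail - v_trim
      j_contrib <- j$anchor_codon_start + 3L - j_trim
      ins_len <- ins_len + (3L - (v_contrib + ins_len + j_contrib) %% 3L) %% 3L
    }
    n_insert <- if (ins_len > 0L) {
      paste(sample(c("A", "C", "G", "T"), ins_len, TRUE), collapse = "")
    } else {
      ""
    }
    cl <- clone_from_parts(v, j, v_trim, j_trim, n_insert)
    if (!cfg$productive_only || cl$productive) return(cl)
  }
  stop("failed to generate a productive clone after ", max_tries, " tries")
}

# full amplicon for one clone: trimmed V + insert + trimmed J
clone_amplicon <- function(clone, db) {
  v <- ref_lookup(db, clone$v_gene)
  j <- ref_lookup(db, clone$j_gene)
  paste0(substr(v$sequence, 1L, nchar(v$sequence) - clone$v_trim),
         clone$n_insert,
         substr(j$sequence, clone$j_trim + 1L, nchar(j$sequence)))
}

#' Generate sequencing reads from a simulated repertoire
#'
#' Samples `read_count` reads multinomially by true clone frequency.
#' Each read is the clone's merged amplicon — the trimmed V segment,
#' untemplated insert and trimmed J segment — with i.i.d. per-base
#' substitution errors at `error_rate` (substitutions only; no indel
#' errors).  Read order is shuffled.  Quality, when a FASTQ is written,
#' is constant `I` (Q40).  Deterministic given the configuration seed.
#'
#' @param clones Output of [simulate_repertoire()].
#' @param cfg The same [simulation_config()].
#' @param db The same `ReferenceDB`.
#' @param fastq Optional path; when given, reads are also written as a
#'   4-line-record FASTQ (gzipped if the path ends in `.gz`).
#' @param truth Optional path for the truth table TSV.
#' @return List with `reads` (tibble `read_id`, `sequence`) and `truth`
#'   (tibble `read_id`, `clone_id`, `v_gene`, `j_gene`, `cdr3_aa`).
#' @export
generate_reads <- function(clones, cfg, db, fastq = NULL, truth = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$read_count <= 0L) stop("read_count must be positive")
  res <- with_seed(cfg$seed + 1L, generate_reads_impl(clones, cfg, db))
  if (!is.null(fastq)) write_fastq(res$reads, fastq)
  if (!is.null(truth)) {
    write.table(res$truth, truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  res
}

generate_reads_impl <- function(clones, cfg, db) {
  amplicons <- vapply(seq_len(nrow(clones)), function(i) {
    clone_amplicon(clones[i, ], db)
  }, "")
  counts <- as.vector(rmultinom(1L, cfg$read_count, clones$true_frequency))
  idx <- rep(seq_len(nrow(clones)), counts)
  idx <- idx[sample.int(length(idx))]
  seqs <- amplicons[idx]
  if (cfg$error_rate > 0) {
    seqs <- vapply(seqs, mutate_read, "", rate = cfg$error_rate,
                   USE.NAMES = FALSE)
  }
  read_id <- sprintf("read-%06d", seq_along(seqs))
  list(
    reads = tibble(read_id = read_id, sequence = seqs),
    truth = tibble(read_id = read_id,
                   clone_id = clones$clone_id[idx],
                   v_gene = clones$v_gene[idx],
                   j_gene = clones$j_gene[idx],
                   cdr3_aa = clones$cdr3_aa[idx])
  )
}

# i.i.d. substitution errors: each error replaces the base with one of
# the three other bases uniformly
mutate_read <- function(seq, rate) {
  n <- nchar(seq)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  bases <- strsplit(seq, "")[[1]]
  for (p in pos) {
    bases[p] <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1L)
  }
  paste(bases, collapse = "")
}
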