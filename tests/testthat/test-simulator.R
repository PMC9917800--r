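test_that("spike-in clones carry exactly the requested clonotypes", {
  db <- toy_db()
  cfg <- simulation_config(n_clones = 5L, read_count = 100L, seed = 42L,
                           spike_ins = canonical_spike_ins())
  cl <- simulate_repertoire(cfg, db)
  expect_equal(nrow(cl), 5L + 3L)
  sp <- cl[1:3, ]
  expect_equal(sp$v_gene, c("TRAV11", "TRAV12D-1", "TRAV1"))
  expect_equal(sp$j_gene, c("TRAJ18", "TRAJ22", "TRAJ33"))
  expect_equal(sp$cdr3_aa,
               c("CVVGDRGSALGRLHF", "CALSEKSSGSWQLIF", "CAVRDSNYQLIW"))
  expect_true(all(sp$productive))
  # frequencies: spikes keep their requested values after renormalisation
  expect_equal(sp$true_frequency, c(0.15, 0.08, 0.04))
  expect_equal(sum(cl$true_frequency), 1, tolerance = 1e-9)
})

test_that("junctions are reconstructible from their V/trim/insert/J parts", {
  db <- toy_db()
  cfg <- simulation_config(n_clones = 30L, read_count = 10L, seed = 9L,
                           spike_ins = canonical_spike_ins())
  cl <- simulate_repertoire(cfg, db)
  for (i in seq_len(nrow(cl))) {
    v <- ref_lookup(db, cl$v_gene[i])
    j <- ref_lookup(db, cl$j_gene[i])
    rebuilt <- paste0(
      substr(v$sequence, v$anchor_codon_start + 1L,
             nchar(v$sequence) - cl$v_trim[i]),
      cl$n_insert[i],
      substr(j$sequence, cl$j_trim[i] + 1L, j$anchor_codon_start + 3L)
    )
    expect_identical(rebuilt, cl$junction_nt[i])
  }
})

test_that("productive clones have in-frame stop-free C...F/W junctions", {
  cl <- study_run(seed = 5L, annotate = FALSE)$clones
  expect_true(all(cl$productive))
  expect_true(all(nchar(cl$junction_nt) %% 3L == 0L))
  expect_true(all(substr(cl$cdr3_aa, 1, 1) == "C"))
  expect_true(all(substr(cl$cdr3_aa, nchar(cl$cdr3_aa),
                         nchar(cl$cdr3_aa)) %in% c("F", "W")))
  expect_false(any(grepl("*", cl$cdr3_aa, fixed = TRUE)))
  expect_identical(vapply(cl$junction_nt, translate_nt, ""),
                   setNames(cl$cdr3_aa, cl$junction_nt))
})

test_that("a single clone without spikes is normalised to frequency 1", {
  cfg <- simulation_config(n_clones = 1L, read_count = 10L, seed = 2L)
  cl <- simulate_repertoire(cfg, toy_db())
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$true_frequency, 1)
})

test_that("identical configuration and seed give identical output", {
  db <- toy_db()
  cfg <- simulation_config(n_clones = 20L, read_count = 500L, seed = 77L,
                           error_rate = 0.01,
                           spike_ins = canonical_spike_ins())
  a <- simulate_repertoire(cfg, db)
  b <- simulate_repertoire(cfg, db)
  expect_identical(a, b)
  ra <- generate_reads(a, cfg, db)
  rb <- generate_reads(b, cfg, db)
  expect_identical(ra, rb)
})

test_that("zero-error reads reproduce the clone amplicon verbatim", {
  db <- toy_db()
  cfg <- simulation_config(n_clones = 1L, read_count = 10L, seed = 3L)
  cl <- simulate_repertoire(cfg, db)
  rr <- generate_reads(cl, cfg, db)
  expect_equal(nrow(rr$reads), 10L)
  amp <- tcrclone:::clone_amplicon(cl[1, ], db)
  expect_true(all(rr$reads$sequence == amp))
  expect_true(all(rr$truth$clone_id == cl$clone_id[1]))
})

test_that("substitution errors match the binomial expectation", {
  db <- toy_db()
  cfg <- simulation_config(n_clones = 5L, read_count = 200L, seed = 11L,
                           error_rate = 0.01)
  cl <- simulate_repertoire(cfg, db)
  rr <- generate_reads(cl, cfg, db)
  amps <- vapply(seq_len(nrow(cl)), function(i) {
    tcrclone:::clone_amplicon(cl[i, ], db)
  }, "")
  names(amps) <- cl$clone_id
  mism <- 0L
  total <- 0L
  for (i in seq_len(nrow(rr$reads))) {
    truth_amp <- amps[[rr$truth$clone_id[i]]]
    a <- strsplit(rr$reads$sequence[i], "")[[1]]
    b <- strsplit(truth_amp, "")[[1]]
    expect_equal(length(a), length(b))
    mism <- mism + sum(a != b)
    total <- total + length(a)
  }
  # observed substitutions within 3 sigma of Binomial(total, 0.01);
  # note i.i.d. errors can coincide on a site and cancel, so compare to
  # the effective per-site mismatch probability
  p_eff <- 0.01  # back-mutation at rate 0.01 is O(1e-4), negligible
  sigma <- sqrt(total * p_eff * (1 - p_eff))
  expect_lt(abs(mism - total * p_eff), 3 * sigma)
})

test_that("per-clone read counts match the multinomial expectation", {
  db <- toy_db()
  cfg <- simulation_config(n_clones = 2L, read_count = 1000L, seed = 13L)
  cl <- simulate_repertoire(cfg, db)
  p <- cl$true_frequency
  rr <- generate_reads(cl, cfg, db)
  counts <- table(factor(rr$truth$clone_id, levels = cl$clone_id))
  for (k in 1:2) {
    expected <- 1000 * p[k]
    sigma <- sqrt(1000 * p[k] * (1 - p[k]))
    expect_lt(abs(counts[[k]] - expected), 3 * sigma)
  }
})

test_that("invalid configurations and spike requests fail loudly", {
  db <- toy_db()
  expect_error(simulation_config(spike_ins = data.frame(
    v_gene = "TRAV11", j_gene = "TRAJ18", cdr3_aa = "CVVF",
    frequency = 1.2)))
  expect_error(simulation_config(error_rate = 2))
  # unknown spike gene
  cfg <- simulation_config(n_clones = 0L, spike_ins = data.frame(
    v_gene = "TRAV99", j_gene = "TRAJ18", cdr3_aa = "CVVGDRGSALGRLHF",
    frequency = 0.5), seed = 1L)
  expect_error(simulate_repertoire(cfg, db), "unknown gene")
  # CDR3 incompatible with the J anchor (TRAJ33 anchor is Trp, not Phe)
  cfg2 <- simulation_config(n_clones = 0L, spike_ins = data.frame(
    v_gene = "TRAV1", j_gene = "TRAJ33", cdr3_aa = "CAVRDSNYQLIF",
    frequency = 0.5), seed = 1L)
  expect_error(simulate_repertoire(cfg2, db), "cannot place")
  # generate_reads with non-positive read count
  cfg3 <- simulation_config(n_clones = 1L, read_count = 0L, seed = 1L)
  cl <- simulate_repertoire(cfg3, db)
  expect_error(generate_reads(cl, cfg3, db), "read_count")
})
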