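test_that("a read equal to a full V segment matches itself perfectly", {
  db <- toy_db()
  for (gene in c("TRAV1", "TRAV12D-1", "TRBV19")) {
    seg <- ref_lookup(db, gene)
    hit <- assign_segment(seg$sequence, db, "V", seg$chain)
    expect_equal(hit$gene_name, gene)
    expect_equal(hit$score, 2L * nchar(seg$sequence))
    expect_equal(hit$identity, 1)
    expect_equal(hit$read_start, 0L)
    expect_equal(hit$read_end, nchar(seg$sequence))
  }
})

test_that("single substitutions keep the right gene at the oracle's score", {
  db <- toy_db()
  params <- assignment_params()
  cand <- ref_segments(db, "V", "TRA")
  withr::local_seed(21)
  for (gene in c("TRAV1", "TRAV11", "TRAV6")) {
    seg <- ref_lookup(db, gene)
    read <- seg$sequence
    pos <- sample.int(nchar(read), 1L)
    old <- substr(read, pos, pos)
    substr(read, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    hit <- assign_segment(read, db, "V", "TRA", params)
    orc <- oracle_best(read, cand, params)
    expect_equal(hit$gene_name, gene)
    expect_true(hit$gene_name %in% orc$genes)
    expect_equal(hit$score, orc$score)
  }
})

test_that("a random 30-mer scores below the V reporting threshold", {
  db <- toy_db()
  params <- assignment_params()
  withr::local_seed(33)
  for (rep in 1:5) {
    read <- random_read(30L)
    expect_null(assign_segment(read, db, "V", "TRA", params))
    # the oracle agrees the best score is sub-threshold
    orc <- oracle_best(read, ref_segments(db, "V", "TRA"), params)
    expect_lt(orc$score, params$min_score_v)
  }
})

test_that("best hits equal the exhaustive alignment oracle on mixed reads", {
  run <- study_run(seed = 8L, error_rate = 0.005, annotate = FALSE)
  db <- run$db
  params <- assignment_params()
  withr::local_seed(8)
  reads <- c(run$reads$sequence[sample.int(nrow(run$reads), 30L)],
             vapply(1:10, function(i) random_read(sample(40:150, 1L)), ""))
  for (type in c("V", "J")) {
    for (read in reads) {
      expect_matches_oracle(read, db, type, "TRA", params)
    }
  }
})

test_that("adding segments to the reference never lowers the best score", {
  db <- toy_db()
  params <- assignment_params()
  small <- tcrclone:::new_reference_db(
    db$segments[db$segments$segment_type == "V" &
                  db$segments$chain == "TRA", ][1:3, ])
  withr::local_seed(12)
  reads <- c(vapply(1:8, function(i) random_read(sample(40:120, 1L)), ""),
             ref_segments(db, "V", "TRA")$sequence[4:6])
  score_of <- function(hit) if (is.null(hit)) 0L else hit$score
  relaxed <- assignment_params(min_score_v = 0L, min_identity = 0)
  for (read in reads) {
    s_small <- score_of(assign_segment(read, small, "V", "TRA", relaxed))
    s_full <- score_of(assign_segment(read, db, "V", "TRA", relaxed))
    expect_gte(s_full, s_small)
  }
})

test_that("score ties break deterministically by gene name", {
  seq <- paste0(strrep("ACGGTT", 8L), "TGTGCTGTG")
  p <- write_mini_reference(list(
    list(gene = "TRAVT2", type = "V", anchor = 48L, seq = seq),
    list(gene = "TRAVT1", type = "V", anchor = 48L, seq = seq),
    list(gene = "TRAJT", type = "J", anchor = 3L,
         seq = paste0("AAATTT", "GGA", strrep("CGTA", 5L)))
  ))
  db <- load_reference(p$fasta, p$anchors, quiet = TRUE)
  hit <- assign_segment(seq, db, "V", "TRA")
  expect_equal(hit$gene_name, "TRAVT1")
})

test_that("reads missing a segment or chimeric reads get flagged", {
  db <- toy_db()
  j <- ref_lookup(db, "TRAJ18")
  ann <- annotate_reads(tibble::tibble(read_id = "r1",
                                       sequence = j$sequence), db)
  expect_equal(ann$fail_reason, "no_v")

  v <- ref_lookup(db, "TRAV1")
  ann2 <- annotate_reads(tibble::tibble(read_id = "r2",
                                        sequence = v$sequence), db)
  expect_equal(ann2$fail_reason, "no_j")

  # chimeric read: J engineered to share the V's 3' 12-mer, so the V
  # and J alignment blocks overlap by 12 nt on the read
  v_seq <- paste0(strrep("GATTAC", 8L), "TGTGCTGTG")     # 57 nt
  shared <- substr(v_seq, nchar(v_seq) - 11L, nchar(v_seq))
  j_seq <- paste0(shared, "CATCTG", "TTC", "GGA", strrep("TTGA", 6L))
  p <- write_mini_reference(list(
    list(gene = "TRAVC", type = "V", anchor = 48L, seq = v_seq),
    list(gene = "TRAJC", type = "J", anchor = 18L, seq = j_seq)
  ))
  cdb <- load_reference(p$fasta, p$anchors, quiet = TRUE)
  read <- paste0(v_seq, substr(j_seq, 13L, nchar(j_seq)))
  ann3 <- annotate_reads(tibble::tibble(read_id = "r3", sequence = read),
                         cdb)
  expect_equal(ann3$fail_reason, "vj_overlap")
})

test_that("on error-free simulated reads V/J assignment is always right", {
  run <- study_run(seed = 1L)
  m <- dplyr::left_join(run$annotated, run$truth, by = "read_id",
                        suffix = c("", ".true"))
  expect_true(all(m$v_gene == m$v_gene.true))
  expect_true(all(m$j_gene == m$j_gene.true))
})
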