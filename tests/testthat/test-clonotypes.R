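# minimal annotated-read table for constructed cases
fake_annotated <- function(v, j, aa, productive = TRUE,
                           fail = "none") {
  tibble::tibble(read_id = sprintf("r%03d", seq_along(v)),
                 sequence = "", v_gene = v, j_gene = j,
                 cdr3_nt = NA_character_, cdr3_aa = aa,
                 productive = productive, fail_reason = fail)
}

test_that("copy counts, frequencies and ranks follow the definitions", {
  ann <- fake_annotated(
    v = c("TRAV1", "TRAV1", "TRAV1", "TRAV11"),
    j = c("TRAJ33", "TRAJ33", "TRAJ33", "TRAJ18"),
    aa = c(rep("CAVRDSNYQLIW", 3), "CVVGDRGSALGRLHF"))
  ct <- aggregate_clonotypes(ann)
  expect_equal(nrow(ct), 2L)
  expect_equal(ct$copy_count, c(3L, 1L))
  expect_equal(ct$frequency_pct, c(75, 25))
  expect_equal(ct$rank, c(1L, 2L))
  expect_equal(ct$v_gene[1], "TRAV1")

  single <- aggregate_clonotypes(fake_annotated("TRAV1", "TRAJ33",
                                                "CAVRDSNYQLIW"))
  expect_equal(single$frequency_pct, 100)
  expect_equal(single$rank, 1L)

  expect_error(aggregate_clonotypes(fake_annotated(character(0),
                                                   character(0),
                                                   character(0))),
               "empty repertoire")
  expect_error(aggregate_clonotypes(
    fake_annotated("TRAV1", "TRAJ33", NA_character_,
                   productive = FALSE, fail = "no_j")),
    "empty repertoire")
})

test_that("aggregation equals the brute-force counting oracle on a run", {
  run <- study_run(seed = 2L)
  ct <- aggregate_clonotypes(run$annotated)
  el <- run$annotated[run$annotated$productive, ]
  orc <- oracle_clonotypes(el$v_gene, el$j_gene, el$cdr3_aa)
  expect_equal(ct$v_gene, orc$v_gene)
  expect_equal(ct$j_gene, orc$j_gene)
  expect_equal(ct$cdr3_aa, orc$cdr3_aa)
  expect_equal(ct$copy_count, orc$copy_count)
  expect_equal(ct$frequency_pct, orc$frequency_pct)
  expect_equal(ct$rank, orc$rank)
  # conservation: copies sum to the eligible reads
  expect_equal(sum(ct$copy_count), nrow(el))
  # top-30 is the head of the same ranking
  expect_equal(top_clonotypes(ct, 30L)$cdr3_aa, head(orc$cdr3_aa, 30L))
})

test_that("input order never matters and duplication scales counts", {
  run <- study_run(seed = 2L)
  ann <- run$annotated
  withr::local_seed(99)
  shuffled <- ann[sample.int(nrow(ann)), ]
  expect_equal(aggregate_clonotypes(shuffled),
               aggregate_clonotypes(ann))
  doubled <- dplyr::bind_rows(ann, ann)
  ct1 <- aggregate_clonotypes(ann)
  ct2 <- aggregate_clonotypes(doubled)
  expect_equal(ct2$copy_count, 2L * ct1$copy_count)
  expect_equal(ct2$frequency_pct, ct1$frequency_pct)
  expect_equal(ct2$rank, ct1$rank)
})

test_that("gene usage marginalises correctly and sums to 100", {
  ann <- fake_annotated(
    v = c(rep("TRAV1", 3), rep("TRAV11", 2)),
    j = rep("TRAJ18", 5),
    aa = c(rep("CAVRF", 3), rep("CVVGF", 2)))
  vu <- gene_usage(ann, "V")
  expect_equal(vu$frequency_pct[vu$gene == "TRAV1"], 60)
  expect_equal(vu$frequency_pct[vu$gene == "TRAV11"], 40)
  ju <- gene_usage(ann, "J")
  expect_equal(ju$frequency_pct, 100)

  run <- study_run(seed = 2L)
  um <- gene_usage(run$annotated, "VJ")
  expect_s3_class(um, "usage_matrix")
  expect_equal(sum(um), 100, tolerance = 1e-6)
  expect_true(all(um >= 0))
  # row/column sums equal the per-gene usage tables
  vu2 <- gene_usage(run$annotated, "V")
  expect_equal(rowSums(um)[vu2$gene], setNames(vu2$frequency_pct,
                                               vu2$gene))
  # independent recount of one well-populated cell
  el <- run$annotated[run$annotated$productive, ]
  expect_equal(um["TRAV11", "TRAJ18"],
               100 * sum(el$v_gene == "TRAV11" & el$j_gene == "TRAJ18") /
                 nrow(el))
  # usage computed from the clonotype table matches (read-weighted)
  um2 <- gene_usage(aggregate_clonotypes(run$annotated), "VJ")
  expect_equal(unclass(um), unclass(um2))
})

test_that("a dominant spiked V-J pair shows up at its usage cell", {
  db <- toy_db()
  cfg <- simulation_config(n_clones = 5L, read_count = 4000L, seed = 31L,
                           spike_ins = canonical_spike_ins(c(0.5, 0.2, 0.1)))
  cl <- simulate_repertoire(cfg, db)
  rr <- generate_reads(cl, cfg, db)
  um <- gene_usage(annotate_reads(rr$reads, db), "VJ")
  # exact expectation: total truth frequency carried by that V-J pair
  p <- sum(cl$true_frequency[cl$v_gene == "TRAV11" &
                               cl$j_gene == "TRAJ18"])
  sigma <- 100 * sqrt(p * (1 - p) / cfg$read_count)
  expect_lt(abs(um["TRAV11", "TRAJ18"] - 100 * p), 3 * sigma)
  expect_gt(um["TRAV11", "TRAJ18"], um["TRAV1", "TRAJ33"])
})

test_that("top_n truncates and validates", {
  ann <- fake_annotated(
    v = paste0("TRAV", 1:5), j = rep("TRAJ18", 5),
    aa = paste0("CAV", LETTERS[1:5], "F"))
  ct <- aggregate_clonotypes(ann)
  expect_equal(nrow(top_clonotypes(ct, 30L)), 5L)
  expect_equal(nrow(top_clonotypes(ct, 1L)), 1L)
  expect_error(top_clonotypes(ct, 0L), ">= 1")
  expect_equal(names(top_clonotypes(ct, 2L)),
               c("rank", "v_gene", "j_gene", "cdr3_aa", "copy_count",
                 "frequency_pct"))
})
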