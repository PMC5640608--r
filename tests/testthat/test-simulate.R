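small_design <- function(...) {
  simulation_design(n_genes = 300, seed = 42, ...)
}

test_that("simulated annotation plants the duplicate-identity groups and rRNA genes", {
  ann <- simulate_annotation(small_design())
  g <- ann$genes
  expect_equal(sum(!is.na(g$duplicate_group)), 8 * 2 + 5 * 5)
  sizes <- table(table(g$duplicate_group[!is.na(g$duplicate_group)]))
  expect_equal(unname(sizes[["2"]]), 8)
  expect_equal(unname(sizes[["5"]]), 5)
  expect_equal(sum(g$is_rrna), 4)
  # group members share one identical sequence
  for (grp in unique(stats::na.omit(g$duplicate_group))) {
    members <- g$gene_id[!is.na(g$duplicate_group) & g$duplicate_group == grp]
    seqs <- as.character(ann$sequences[members])
    expect_equal(length(unique(seqs)), 1L)
  }
  expect_true(all(g$length_bp > 0))
})

test_that("an infeasible or empty design is handled", {
  expect_error(simulation_design(n_genes = 10), "infeasible")
  ann <- simulate_annotation(simulation_design(n_genes = 0, n_rrna = 0,
                                               duplicate_pairs = 0,
                                               duplicate_quintets = 0))
  expect_equal(nrow(ann$genes), 0L)
  expect_equal(length(ann$sequences), 0L)
})

test_that("generators are deterministic under a fixed seed", {
  d <- small_design()
  a1 <- simulate_annotation(d); a2 <- simulate_annotation(d)
  expect_identical(a1$genes, a2$genes)
  expect_identical(as.character(a1$sequences), as.character(a2$sequences))
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(a1$sequences, f1); write_fasta(a2$sequences, f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical files

  t1 <- simulate_truth(d, a1$genes); t2 <- simulate_truth(d, a1$genes)
  expect_identical(t1, t2)
  c1 <- simulate_counts(d, t1, a1$genes); c2 <- simulate_counts(d, t1, a1$genes)
  expect_identical(c1$counts, c2$counts)
  r1 <- simulate_reads(d, a1$genes, 500); r2 <- simulate_reads(d, a1$genes, 500)
  expect_identical(r1$reads, r2$reads)
  p1 <- simulate_proteome(50, 5, seed = 3); p2 <- simulate_proteome(50, 5, seed = 3)
  expect_identical(as.character(p1$proteins), as.character(p2$proteins))
})

test_that("null counts behave like Poisson as dispersion vanishes", {
  d <- simulation_design(n_genes = 5000, fraction_de = 0, dispersion = 0,
                         library_size_cv = 0,   # isolate the count model
                         n_rrna = 0, duplicate_pairs = 0,
                         duplicate_quintets = 0, expr_log2_sd = 0.5, seed = 8)
  ann <- simulate_annotation(d)
  tr <- simulate_truth(d, ann$genes)
  cm <- simulate_counts(d, tr, ann$genes)
  # within-condition variance/mean ratio near 1 across many genes
  x <- cm$counts[, cm$conditions == "fructose"]
  ratio <- apply(x, 1, var) / pmax(rowMeans(x), 1e-9)
  expect_lt(abs(mean(ratio, na.rm = TRUE) - 1), 0.1)
})

test_that("fold-change estimates center on truth", {
  # null design: estimated folds center on 1
  d0 <- simulation_design(n_genes = 2000, fraction_de = 0, seed = 13)
  ann0 <- simulate_annotation(d0)
  tr0 <- simulate_truth(d0, ann0$genes)
  cm0 <- simulate_counts(d0, tr0, ann0$genes)
  de0 <- call_de(cm0, "h2co2_vs_fructose", genes = ann0$genes)
  raw_fold <- ifelse(de0$direction == "up", de0$fold_change, 1 / de0$fold_change)
  expect_lt(abs(median(log2(raw_fold))), 0.1)

  # planted 16-fold genes: median estimated fold within [12, 20]
  d1 <- simulation_design(n_genes = 2000, fraction_de = 0.1,
                          fold_log2_range = c(4, 4), seed = 14)
  ann1 <- simulate_annotation(d1)
  tr1 <- simulate_truth(d1, ann1$genes)
  cm1 <- simulate_counts(d1, tr1, ann1$genes)
  de1 <- call_de(cm1, "h2co2_vs_fructose", genes = ann1$genes)
  up <- tr1$gene_id[tr1$log2_fold == 4]
  up <- intersect(up, de1$gene_id)  # collective records keep the representative id
  est <- de1$fold_change[match(up, de1$gene_id)]
  expect_gt(median(est), 12)
  expect_lt(median(est), 20)
})

test_that("read batches respect the planted rule-violation bookkeeping", {
  d <- small_design()
  sim <- simulate_reads(d, simulate_annotation(d)$genes, n_reads = 2000)
  expect_equal(sim$bookkeeping[["rrna"]], 200)
  expect_equal(sim$bookkeeping[["multimap"]], 100)
  expect_equal(sim$bookkeeping[["himismatch"]], 60)
  res <- filter_reads(sim$reads)
  expect_equal(res$tally[["kept"]], sim$bookkeeping[["clean"]])
  expect_equal(res$tally[["rrna"]], sim$bookkeeping[["rrna"]])
  expect_equal(res$tally[["multimap"]], sim$bookkeeping[["multimap"]])
  expect_equal(res$tally[["mismatch"]], sim$bookkeeping[["himismatch"]])

  clean <- simulate_reads(simulation_design(n_genes = 300, seed = 2,
                                            read_rrna_frac = 0,
                                            read_multimap_frac = 0,
                                            read_himismatch_frac = 0),
                          simulate_annotation(small_design())$genes, 500)
  expect_equal(filter_reads(clean$reads)$tally[["kept"]], 500)
})

test_that("array intensities reduce to truth when noise and offsets vanish", {
  d <- simulation_design(n_genes = 60, n_rrna = 0, duplicate_pairs = 0,
                         duplicate_quintets = 0, probe_affinity_sd = 0,
                         block_offset = 0, array_noise_sd = 0, seed = 21)
  ann <- simulate_annotation(d)
  tr <- simulate_truth(d, ann$genes)
  ps <- simulate_array(d, tr, ann$genes)
  gi <- summarize_probes(ps, normalize = FALSE)
  for (cc in d$conditions) {
    j <- which(as.character(ps$conditions) == cc)[1]
    expected <- tr[[paste0("rpkm_", cc)]][match(rownames(gi), tr$gene_id)] + 1
    expect_equal(unname(gi[, j]), expected, tolerance = 1e-9)
  }
})

test_that("probe tables have the documented shape", {
  d <- simulation_design(n_genes = 50, n_rrna = 0, duplicate_pairs = 0,
                         duplicate_quintets = 0, probes_per_gene = 1, seed = 22)
  ann <- simulate_annotation(d)
  tr <- simulate_truth(d, ann$genes)
  ps <- simulate_array(d, tr, ann$genes)
  expect_equal(nrow(ps$intensities), 50 * 1 * 2)   # genes x probes x blocks
  expect_equal(ncol(ps$intensities), length(d$conditions) * d$replicates)
  expect_setequal(unique(ps$probe_info$block), c("BLOCK1", "BLOCK2"))
  # duplicate groups are probed only through their representative
  d2 <- simulation_design(n_genes = 60, n_rrna = 0, seed = 23)
  ann2 <- simulate_annotation(d2)
  ps2 <- simulate_array(d2, simulate_truth(d2, ann2$genes), ann2$genes)
  probed <- unique(ps2$probe_info$gene_id)
  reps <- ann2$genes$gene_id[is.na(ann2$genes$duplicate_group) |
                               !duplicated(ann2$genes$duplicate_group)]
  expect_setequal(probed, reps)
})

test_that("a clean proteome yields essentially no flags at three SD", {
  # the right-skewed background makes an occasional 3-SD excursion possible;
  # tolerate at most a 2% tail
  sim <- simulate_proteome(n = 100, outliers = 0, residue = "H", seed = 5)
  scr <- aa_screen(sim$proteins, residue = "H", k = 3)
  expect_lte(sum(scr$table$flagged), 2L)
})
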