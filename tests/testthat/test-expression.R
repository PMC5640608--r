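make_reads <- function(n_rrna = 0, n_multi = 0, n_mism = 0, n_clean = 1) {
  n <- n_rrna + n_multi + n_mism + n_clean
  data.frame(
    read_id = sprintf("r%04d", seq_len(n)),
    assigned_gene = rep("G1", n),
    n_loci_matched = rep(c(1L, 3L, 1L, 1L), c(n_rrna, n_multi, n_mism, n_clean)),
    mismatches = rep(c(0L, 0L, 4L, 2L), c(n_rrna, n_multi, n_mism, n_clean)),
    is_rrna_hit = rep(c(TRUE, FALSE, FALSE, FALSE),
                      c(n_rrna, n_multi, n_mism, n_clean)),
    stringsAsFactors = FALSE)
}

test_that("read filtering keeps unique non-rRNA reads with at most two mismatches", {
  # exactly two mismatches is retained ("more than two" are discarded)
  two <- data.frame(read_id = "r1", assigned_gene = "G1",
                    n_loci_matched = 1L, mismatches = 2L,
                    is_rrna_hit = FALSE, stringsAsFactors = FALSE)
  expect_equal(filter_reads(two)$tally[["kept"]], 1L)

  empty <- filter_reads(make_reads(0, 0, 0, 0)[0, ])
  expect_equal(nrow(empty$kept), 0L)
  expect_true(all(empty$tally == 0))

  batch <- make_reads(100, 50, 30, 820)
  res <- filter_reads(batch)
  expect_equal(unname(res$tally[c("kept", "rrna", "multimap", "mismatch")]),
               c(820L, 100L, 50L, 30L))
})

test_that("read filtering is idempotent", {
  batch <- make_reads(10, 5, 3, 82)
  once <- filter_reads(batch)
  twice <- filter_reads(once$kept)
  expect_equal(twice$kept, once$kept)
  expect_equal(twice$tally[["kept"]], once$tally[["kept"]])
})

tiny_genes <- function() {
  gene_models(c("G1", "G2", "G3"), c(1000L, 500L, 2000L))
}

test_that("RPKM matches its unit definition and an independent formula oracle", {
  cm <- count_matrix(matrix(c(1L, 0L, 10L), 3, 1,
                            dimnames = list(c("G1", "G2", "G3"), "s1")),
                     conditions = "a", lib_sizes = 1e6)
  r <- compute_rpkm(cm, tiny_genes())
  expect_equal(r["G1", 1], 1.0)   # 1 read, 1 kb gene, 1e6 mapped
  expect_equal(r["G2", 1], 0.0)

  set.seed(5)
  counts <- matrix(rpois(30, 50), 3, 10,
                   dimnames = list(c("G1", "G2", "G3"), paste0("s", 1:10)))
  libs <- runif(10, 5e5, 2e6)
  cm2 <- count_matrix(counts, rep("a", 10), lib_sizes = libs)
  r2 <- compute_rpkm(cm2, tiny_genes())
  # independent elementwise re-evaluation of the definition
  for (i in 1:3) for (j in 1:10) {
    expect_equal(r2[i, j],
                 counts[i, j] / (tiny_genes()$length_bp[i] / 1000) / (libs[j] / 1e6))
  }
})

test_that("RPKM is invariant to scaling depth and strictly monotone in counts", {
  set.seed(6)
  counts <- matrix(rpois(9, 40), 3, 3,
                   dimnames = list(c("G1", "G2", "G3"), paste0("s", 1:3)))
  g <- tiny_genes()
  r1 <- compute_rpkm(count_matrix(counts, rep("a", 3), lib_sizes = rep(1e6, 3)), g)
  r2 <- compute_rpkm(count_matrix(2L * counts, rep("a", 3), lib_sizes = rep(2e6, 3)), g)
  expect_equal(r1, r2)

  bumped <- counts; bumped["G2", 2] <- bumped["G2", 2] + 5L
  r3 <- compute_rpkm(count_matrix(bumped, rep("a", 3), lib_sizes = rep(1e6, 3)), g)
  expect_gt(r3["G2", 2], r1["G2", 2])
  expect_equal(r3[-2, ], r1[-2, ])
  expect_equal(r3["G2", -2], r1["G2", -2])
})

test_that("duplicate-identity groups are pooled onto one collective record", {
  g <- gene_models(c("G1", "G2", "G3"), c(1000L, 1000L, 500L),
                   duplicate_group = c("d1", "d1", NA))
  counts <- matrix(c(3L, 7L, 4L), 3, 1, dimnames = list(g$gene_id, "s1"))
  cm <- count_matrix(counts, "a", lib_sizes = 1e6)
  r <- compute_rpkm(cm, g)
  expect_equal(nrow(r), 2L)
  expect_equal(r["G1", 1], 10 / 1)   # pooled 10 reads over the representative's 1 kb
  expect_equal(attr(r, "genes")$n_members[attr(r, "genes")$gene_id == "G1"], 2L)
  # mismatched lengths warn and fall back to the mean length
  g2 <- gene_models(c("G1", "G2"), c(1000L, 2000L), duplicate_group = "d1")
  cm2 <- count_matrix(matrix(c(3L, 3L), 2, 1, dimnames = list(g2$gene_id, "s1")),
                      "a", lib_sizes = 1e6)
  expect_warning(r2 <- compute_rpkm(cm2, g2), "mismatched lengths")
  expect_equal(r2["G1", 1], 6 / 1.5)
  expect_error(compute_rpkm(count_matrix(counts, "a", lib_sizes = 1e6) |>
                              (\(x) { x$lib_sizes <- 0; x })(), g),
               "zero library size")
})

test_that("replicate merging averages per condition and assigns boundary-correct status", {
  rpkm <- rbind(G1 = c(32, 32, 32, 40, 40, 40),
                G2 = c(16, 16, 16, 20, 20, 20),
                G3 = c(0, 0, 0, 0, 0, 0))
  conds <- rep(c("fructose", "h2co2"), each = 3)
  m <- merge_replicates(rpkm, conds)
  expect_equal(m$rpkm_fructose, c(32, 16, 0))
  expect_equal(m$status, c("detected", "below_threshold", "not_detected"))
  # log2 mean RPKM exactly 5 passes the threshold
  expect_equal(m$log2_rpkm[1], log2(40))
  m2 <- merge_replicates(rbind(G1 = rep(31.99, 6)), conds)
  expect_equal(m2$status, "below_threshold")
})

test_that("DE calling flags planted strong effects and not identical replicates", {
  g <- gene_models(c("G1", "G2"), c(1000L, 1000L))
  counts <- rbind(G1 = c(2000L, 2050L, 1980L, 100L, 102L, 98L),
                  G2 = c(500L, 500L, 500L, 500L, 500L, 500L))
  cm <- count_matrix(counts, rep(c("h2co2", "fructose"), each = 3),
                     lib_sizes = rep(1e6, 6))
  de <- call_de(cm, "h2co2_vs_fructose", genes = g)
  g1 <- de[de$gene_id == "G1", ]
  expect_true(g1$significant && g1$strong)
  expect_equal(g1$direction, "up")
  expect_gt(g1$fold_change, 10)
  g2 <- de[de$gene_id == "G2", ]
  expect_equal(g2$fold_change, 1)
  expect_false(g2$significant)
  expect_equal(g2$p_value, 1)
})

test_that("DE calling requires two replicates and names the offending condition", {
  g <- gene_models("G1", 1000L)
  counts <- matrix(c(5L, 5L, 5L, 7L), 1, 4,
                   dimnames = list("G1", paste0("s", 1:4)))
  cm <- count_matrix(counts, c("fructose", "fructose", "fructose", "h2co2"),
                     lib_sizes = rep(1e6, 4))
  expect_error(call_de(cm, "h2co2_vs_fructose", genes = g), "'h2co2'")
})

test_that("downregulation is reported as an inverse fold with direction down", {
  g <- gene_models("G1", 1000L)
  counts <- matrix(c(10L, 11L, 9L, 200L, 205L, 195L), 1, 6,
                   dimnames = list("G1", paste0("s", 1:6)))
  cm <- count_matrix(counts, rep(c("h2co2", "fructose"), each = 3),
                     lib_sizes = rep(1e6, 6))
  de <- call_de(cm, "h2co2_vs_fructose", genes = g)
  expect_equal(de$direction, "down")
  expect_gt(de$fold_change, 10)
})

# helpers building call/expression fixtures for reconciliation tests
fake_call <- function(gene_id, platform, p, fold, contrast = "h2co2_vs_fructose") {
  data.frame(gene_id = gene_id, platform = platform, contrast = contrast,
             fold_change = fold, direction = "up", p_value = p,
             significant = p <= 0.05, strong = p <= 0.05 & fold >= 10,
             stringsAsFactors = FALSE)
}
fake_records <- function(gene_id, status) {
  data.frame(gene_id = gene_id, status = status, stringsAsFactors = FALSE)
}

test_that("reconciliation applies the two-condition disqualification rule", {
  # significant on microarray only, below RNA-Seq threshold: qualified
  arr <- fake_call("G1", "microarray", 0.01, 5)
  rna <- fake_call("G1", "rnaseq", 0.50, 1.2)
  m1 <- reconcile(arr, rna, fake_records("G1", "below_threshold"))
  expect_true(m1$qualified)
  expect_false(m1$disqualified)
  # below threshold AND microarray p > 0.05: disqualified
  arr2 <- fake_call("G2", "microarray", 0.40, 1.5)
  rna2 <- fake_call("G2", "rnaseq", 0.01, 4)
  m2 <- reconcile(arr2, rna2, fake_records("G2", "below_threshold"))
  expect_true(m2$disqualified)
  expect_false(m2$qualified)
  # a called gene missing from the expression records is an error
  expect_error(reconcile(arr, rna, fake_records("GX", "detected")),
               "absent from expression records")
})

test_that("qualified and disqualified partition the called set and ranking is deterministic", {
  arr <- rbind(fake_call(c("G1", "G2", "G3"), "microarray",
                         c(0.01, 0.30, 0.02), c(12, 2, 4)),
               fake_call("G4", "microarray", 0.9, 1.1))
  rna <- rbind(fake_call(c("G1", "G2", "G3"), "rnaseq",
                         c(0.20, 0.01, 0.03), c(3, 8, 4)),
               fake_call("G4", "rnaseq", 0.8, 1.0))
  rec <- fake_records(paste0("G", 1:4),
                      c("detected", "below_threshold", "detected", "detected"))
  m <- reconcile(arr, rna, rec)
  expect_true(all(xor(m$qualified, m$disqualified)[m$called]))
  expect_false(any(m$qualified & m$disqualified))
  expect_equal(sort(m$gene_id[m$called]),
               sort(m$gene_id[m$qualified | m$disqualified]))
  expect_false(m$called[m$gene_id == "G4"])
  # ranks: G1 fold 12 then G3 fold 4 (G3 ties broken by id if needed)
  expect_equal(m$rank[m$gene_id == "G1"], 1L)
  expect_equal(m$rank[m$gene_id == "G3"], 2L)
  expect_true(is.na(m$rank[m$gene_id == "G2"]))  # disqualified
})

test_that("regulation labels honour the strong-fold and significance gates", {
  calls <- rbind(fake_call("G1", "rnaseq", 0.01, 23.5),
                 fake_call("G2", "rnaseq", 0.01, 9.99),
                 fake_call("G3", "rnaseq", 0.20, 12))
  labs <- classify_regulation(calls)
  expect_equal(labs$label[labs$gene_id == "G1"], "strongly_up")
  expect_equal(labs$label[labs$gene_id == "G2"], "up")
  expect_equal(labs$label[labs$gene_id == "G3"], "ns")
})

test_that("the pooled t is calibrated at n = 3 where Welch is conservative", {
  set.seed(404)
  n <- 20000
  mu <- exp(rnorm(n, log(200), 1))
  counts <- matrix(rnbinom(n * 6, mu = rep(mu, 6), size = 10), n, 6)
  x <- log2(counts + 0.5)
  pooled <- acetoscope:::row_t_test(x, 1:3, 4:6, "pooled")
  welch <- acetoscope:::row_t_test(x, 1:3, 4:6, "welch")
  rate_p <- mean(pooled <= 0.05)
  rate_w <- mean(welch <= 0.05)
  half <- qnorm(0.995) * sqrt(0.05 * 0.95 / n)
  expect_gt(rate_p, 0.05 - half)
  expect_lt(rate_p, 0.05 + half)
  expect_lt(rate_w, 0.045)   # Welch under-rejects at this sample size
})
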