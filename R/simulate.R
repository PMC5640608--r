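#' Simulation design
#'
#' Parameters of the synthetic-data generators, defaulting to the study's
#' stated conditions: triplicate samples per growth condition (fructose,
#' H2/CO2, syngas; the RNA-Seq arm covers fructose and H2/CO2), eight
#' duplicate-identity gene pairs plus five quintets measured collectively,
#' up to 8 microarray probes per gene duplicated in two array blocks, and a
#' detection threshold at the median log2 RPKM (5). Counts are negative
#' binomial (dispersion 0.1); planted fold changes are log-uniform in
#' [2, 32], straddling the 10-fold "strong" boundary.
#'
#' @param n_genes number of genes (default 2000).
#' @param conditions growth conditions.
#' @param rnaseq_conditions conditions sequenced by RNA-Seq.
#' @param replicates biological replicates per condition (default 3).
#' @param fraction_de fraction of genes differentially expressed under
#'   lithotrophic conditions (default 0.1).
#' @param fold_log2_range range of planted |log2 fold changes| (default
#'   c(1, 5), i.e. 2- to 32-fold).
#' @param dispersion negative-binomial overdispersion (default 0.1).
#' @param library_size mean RNA-Seq library size (default 5e6).
#' @param library_size_cv coefficient of variation of library sizes.
#' @param expr_log2_median,expr_log2_sd log2 RPKM distribution of true
#'   expression (median 5 so that half the genes sit above the study's
#'   detection threshold; spread 1.5 keeps the summed mRNA signal safely
#'   below the mapped-library total in every condition, so RPKM stays an
#'   unbiased readout of the truth).
#' @param duplicate_pairs,duplicate_quintets numbers of 2- and 5-member
#'   identical gene sets (defaults 8 and 5).
#' @param n_rrna number of rRNA genes.
#' @param gene_length_meanlog,gene_length_sdlog log-normal gene length
#'   parameters (median ~900 bp).
#' @param probes_per_gene microarray probes per gene (<= 8).
#' @param probe_affinity_sd SD of fixed per-probe affinity offsets (log2).
#' @param block_offset additive log2 offset of array BLOCK2.
#' @param array_noise_sd per-measurement Gaussian noise SD (log2).
#' @param read_rrna_frac,read_multimap_frac,read_himismatch_frac disjoint
#'   planted fractions of reads violating each filter rule.
#' @param seed integer seed fixing every downstream draw.
#' @return List of class `simulation_design`.
#' @export
simulation_design <- function(n_genes = 2000,
                              conditions = c("fructose", "h2co2", "syngas"),
                              rnaseq_conditions = c("fructose", "h2co2"),
                              replicates = 3,
                              fraction_de = 0.1,
                              fold_log2_range = c(1, 5),
                              dispersion = 0.1,
                              library_size = 5e6,
                              library_size_cv = 0.1,
                              expr_log2_median = 5,
                              expr_log2_sd = 1.5,
                              duplicate_pairs = 8,
                              duplicate_quintets = 5,
                              n_rrna = 4,
                              gene_length_meanlog = log(900),
                              gene_length_sdlog = 0.45,
                              probes_per_gene = 8,
                              probe_affinity_sd = 0.5,
                              block_offset = 0.1,
                              array_noise_sd = 0.25,
                              read_rrna_frac = 0.10,
                              read_multimap_frac = 0.05,
                              read_himismatch_frac = 0.03,
                              seed = 1) {
  d <- as.list(environment())
  stopifnot(d$fraction_de >= 0, d$fraction_de <= 1,
            d$read_rrna_frac + d$read_multimap_frac +
              d$read_himismatch_frac <= 1,
            d$probes_per_gene >= 1, d$probes_per_gene <= 8,
            d$replicates >= 1, d$dispersion >= 0)
  needed <- 2 * d$duplicate_pairs + 5 * d$duplicate_quintets + d$n_rrna
  if (d$n_genes > 0 && d$n_genes < needed)
    stop(sprintf("infeasible design: %d genes cannot host %d duplicate-group and rRNA genes",
                 d$n_genes, needed))
  structure(d, class = "simulation_design")
}

# Internal: deterministic sub-seed per generator stage so each stage draws an
# independent, reproducible stream from the one design seed.
stage_seed <- function(design, stage) {
  offs <- c(annotation = 101L, truth = 202L, counts = 303L, reads = 404L,
            array = 505L, proteome = 606L)
  (design$seed %% .Machine$integer.max) + offs[[stage]]
}

#' Simulate a gene annotation
#'
#' Gene lengths are log-normal (median ~900 bp); duplicate-identity groups
#' (pairs and quintets) share one identical sequence and length; a handful of
#' genes are rRNA. Genes are laid head-to-tail on a single contig with 100 bp
#' spacers (1-based inclusive coordinates in the GFF3 sense).
#'
#' @param design a [simulation_design()].
#' @return List with `genes` (a [gene_models()] table plus coordinates),
#'   and `sequences` (a `Biostrings::DNAStringSet`).
#' @export
simulate_annotation <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  n <- design$n_genes
  if (n == 0L) {
    return(list(genes = gene_models(character(0), integer(0)),
                sequences = Biostrings::DNAStringSet()))
  }
  set.seed(stage_seed(design, "annotation"))
  ids <- sprintf("GENE_%05d", seq_len(n))
  len <- pmax(90L, as.integer(round(stats::rlnorm(
    n, design$gene_length_meanlog, design$gene_length_sdlog))))
  grp <- rep(NA_character_, n)
  idx <- seq_len(n)
  # rRNA genes first, then duplicate groups among the remaining genes
  rrna <- logical(n)
  if (design$n_rrna > 0) {
    r <- idx[seq_len(design$n_rrna)]
    rrna[r] <- TRUE
    len[r] <- c(1500L, 2900L)[1 + (seq_along(r) %% 2)]  # 16S/23S-like
    idx <- setdiff(idx, r)
  }
  gi <- 0L
  for (size in c(rep(2L, design$duplicate_pairs),
                 rep(5L, design$duplicate_quintets))) {
    gi <- gi + 1L
    members <- idx[seq_len(size)]
    idx <- setdiff(idx, members)
    grp[members] <- sprintf("dup%02d", gi)
    len[members] <- len[members[1L]]   # identical sequence => same length
  }
  seqs <- character(n)
  for (i in seq_len(n)) {
    if (!is.na(grp[i])) {
      first <- match(grp[i], grp)
      if (first < i) { seqs[i] <- seqs[first]; next }
    }
    seqs[i] <- paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE),
                     collapse = "")
  }
  starts <- cumsum(c(1L, utils::head(len, -1) + 100L))
  genes <- gene_models(ids, len, grp, rrna)
  genes$start <- starts
  genes$end <- starts + len - 1L
  genes$strand <- "+"
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- ids
  list(genes = genes, sequences = dna)
}

#' Simulate expression ground truth
#'
#' Draws each gene's true fructose-condition RPKM from a log-normal with
#' median `2^expr_log2_median`, plants differential expression in the
#' lithotrophic conditions for a `fraction_de` subset (log-uniform fold in
#' `2^fold_log2_range`, random direction; duplicate-group members share one
#' truth record), and leaves rRNA genes non-DE.
#'
#' @param design a [simulation_design()].
#' @param genes annotation table from [simulate_annotation()].
#' @return data.frame: `gene_id`, `duplicate_group`, `is_rrna`, per-condition
#'   true RPKM columns `rpkm_<condition>`, `log2_fold` (signed; 0 = null),
#'   `is_de`.
#' @export
simulate_truth <- function(design, genes) {
  set.seed(stage_seed(design, "truth"))
  n <- nrow(genes)
  base <- 2^stats::rnorm(n, design$expr_log2_median, design$expr_log2_sd)
  lfc <- numeric(n)
  # one truth per duplicate group: members inherit the representative's draw
  rep_idx <- seq_len(n)
  if (any(!is.na(genes$duplicate_group))) {
    first_of <- tapply(seq_len(n), genes$duplicate_group, min)
    grp <- genes$duplicate_group
    rep_idx[!is.na(grp)] <- first_of[grp[!is.na(grp)]]
    base <- base[rep_idx]
  }
  eligible <- which(!genes$is_rrna & rep_idx == seq_len(n))
  n_de <- round(design$fraction_de * length(eligible))
  if (n_de > 0) {
    de <- sample(eligible, n_de)
    mag <- stats::runif(n_de, design$fold_log2_range[1L],
                        design$fold_log2_range[2L])
    lfc[de] <- mag * sample(c(-1, 1), n_de, replace = TRUE)
  }
  lfc <- lfc[rep_idx]
  out <- data.frame(gene_id = genes$gene_id,
                    duplicate_group = genes$duplicate_group,
                    is_rrna = genes$is_rrna, stringsAsFactors = FALSE)
  for (cc in design$conditions) {
    out[[paste0("rpkm_", cc)]] <-
      if (cc == "fructose") base else base * 2^lfc
  }
  out$log2_fold <- lfc
  out$is_de <- lfc != 0
  out
}

#' Simulate an RNA-Seq count matrix
#'
#' Negative-binomial counts with per-gene condition means implied by the true
#' RPKM, gene length and a drawn library size:
#' `mean = rpkm * (length/1000) * (lib/1e6)`; `size = 1/dispersion`
#' (Poisson in the dispersion -> 0 limit). The drawn library size is reported
#' as the replicate's total mapped reads: assigned counts cover only the
#' simulated gene subset, the remainder standing in for rRNA and intergenic
#' signal (hence totals >= assigned column sums, as in real libraries).
#'
#' @param design a [simulation_design()].
#' @param truth from [simulate_truth()].
#' @param genes from [simulate_annotation()].
#' @return A [count_matrix()] over `design$rnaseq_conditions`.
#' @export
simulate_counts <- function(design, truth, genes) {
  set.seed(stage_seed(design, "counts"))
  conds <- rep(design$rnaseq_conditions, each = design$replicates)
  libs <- stats::rlnorm(length(conds),
                        log(design$library_size) -
                          log(1 + design$library_size_cv^2) / 2,
                        sqrt(log(1 + design$library_size_cv^2)))
  n <- nrow(genes)
  reps <- stats::ave(seq_along(conds), conds, FUN = seq_along)
  counts <- matrix(0L, n, length(conds),
                   dimnames = list(genes$gene_id,
                                   paste0(conds, "_rep", reps)))
  len_kb <- genes$length_bp / 1000
  for (j in seq_along(conds)) {
    mu <- truth[[paste0("rpkm_", conds[j])]] * len_kb * libs[j] / 1e6
    counts[, j] <- if (design$dispersion > 0)
      stats::rnbinom(n, mu = mu, size = 1 / design$dispersion)
    else stats::rpois(n, mu)
  }
  count_matrix(counts, conds, lib_sizes = pmax(libs, colSums(counts)))
}

#' Simulate a read-record batch exercising the filter rules
#'
#' Plants disjoint fractions of reads that are rRNA hits, multimapped
#' (matched to more than one genomic segment), or carry more than two
#' mismatches; all remaining reads are clean (single locus, 0-2 mismatches).
#' The realized planted counts are emitted as bookkeeping, so the filter's
#' output can be checked exactly.
#'
#' @param design a [simulation_design()].
#' @param genes annotation table (for assigning reads to genes).
#' @param n_reads batch size (default 10000).
#' @return List with `reads` (data.frame: read_id, assigned_gene,
#'   n_loci_matched, mismatches, is_rrna_hit) and `bookkeeping` (named
#'   counts: n_reads, rrna, multimap, himismatch, clean).
#' @export
simulate_reads <- function(design, genes, n_reads = 10000) {
  set.seed(stage_seed(design, "reads"))
  n1 <- round(design$read_rrna_frac * n_reads)
  n2 <- round(design$read_multimap_frac * n_reads)
  n3 <- round(design$read_himismatch_frac * n_reads)
  n0 <- n_reads - n1 - n2 - n3
  stopifnot(n0 >= 0)
  kind <- sample(rep(c("rrna", "multimap", "himismatch", "clean"),
                     c(n1, n2, n3, n0)))
  mrna <- genes$gene_id[!genes$is_rrna]
  rrna_genes <- genes$gene_id[genes$is_rrna]
  if (!length(rrna_genes)) rrna_genes <- NA_character_
  if (!length(mrna)) mrna <- NA_character_
  reads <- data.frame(
    read_id = sprintf("read_%06d", seq_len(n_reads)),
    assigned_gene = ifelse(kind == "rrna",
                           sample(rrna_genes, n_reads, replace = TRUE),
                           sample(mrna, n_reads, replace = TRUE)),
    n_loci_matched = ifelse(kind == "multimap",
                            sample(2:5, n_reads, replace = TRUE), 1L),
    mismatches = ifelse(kind == "himismatch",
                        sample(3:5, n_reads, replace = TRUE),
                        sample(0:2, n_reads, replace = TRUE)),
    is_rrna_hit = kind == "rrna",
    stringsAsFactors = FALSE)
  list(reads = reads,
       bookkeeping = c(n_reads = n_reads, rrna = n1, multimap = n2,
                       himismatch = n3, clean = n0))
}

#' Simulate probe-level microarray intensities
#'
#' Each gene gets `probes_per_gene` probes, each synthesized in two array
#' blocks; the measured intensity is
#' `2 ^ (true log2 intensity + probe affinity + block offset + noise)` with
#' fixed per-probe affinities, a fixed BLOCK2 offset, and i.i.d. Gaussian
#' noise. The true log2 intensity of a gene on an array is
#' `log2(true RPKM + 1)` of the array's condition. Duplicate-identity groups
#' are probed only through their representative (the study omitted duplicated
#' genes from probe sets).
#'
#' @param design a [simulation_design()].
#' @param truth from [simulate_truth()].
#' @param genes from [simulate_annotation()].
#' @return A [probe_set()] over all `design$conditions`.
#' @export
simulate_array <- function(design, truth, genes) {
  set.seed(stage_seed(design, "array"))
  keep <- is.na(genes$duplicate_group) |
    !duplicated(genes$duplicate_group)
  keep <- keep & !genes$is_rrna
  gid <- genes$gene_id[keep]
  np <- design$probes_per_gene
  conds <- rep(design$conditions, each = design$replicates)
  arrays <- paste0(conds, "_rep",
                   stats::ave(seq_along(conds), conds, FUN = seq_along))
  probe_id <- paste0(rep(gid, each = np), "_p", rep(seq_len(np), length(gid)))
  affinity <- stats::rnorm(length(probe_id), 0, design$probe_affinity_sd)
  info <- data.frame(
    probe_id = rep(probe_id, times = 2L),
    gene_id = rep(rep(gid, each = np), times = 2L),
    block = rep(c("BLOCK1", "BLOCK2"), each = length(probe_id)),
    stringsAsFactors = FALSE)
  base_l2 <- sapply(design$conditions, function(cc)
    log2(truth[[paste0("rpkm_", cc)]][match(gid, truth$gene_id)] + 1))
  rows_aff <- rep(affinity, times = 2L)
  rows_block <- rep(c(0, design$block_offset), each = length(probe_id))
  m <- matrix(NA_real_, nrow(info), length(arrays),
              dimnames = list(NULL, arrays))
  for (j in seq_along(arrays)) {
    tr <- base_l2[match(info$gene_id, gid), conds[j]]
    noise <- stats::rnorm(nrow(info), 0, design$array_noise_sd)
    m[, j] <- 2^(tr + rows_aff + rows_block + noise)
  }
  probe_set(m, info, conds)
}

#' Simulate a proteome with planted high-residue outliers
#'
#' Background proteins draw residues from natural amino-acid frequencies with
#' a per-protein jitter on the chosen residue's propensity (giving a
#' proteome-wide spread comparable to the study's 1.4% +/- 1.1% histidine
#' distribution). Planted outliers are long proteins with a strongly elevated
#' propensity for the residue, placing them well beyond mean + 3 SD.
#'
#' @param n number of proteins.
#' @param outliers number of planted outliers.
#' @param residue amino-acid letter (default `"H"`).
#' @param seed integer seed.
#' @param outlier_propensity residue probability in outlier proteins
#'   (default 0.165).
#' @return List with `proteins` (`AAStringSet`) and `truth` (data.frame:
#'   protein_id, is_outlier).
#' @export
simulate_proteome <- function(n = 500, outliers = 10, residue = "H",
                              seed = 1, outlier_propensity = 0.165) {
  stopifnot(outliers <= n)
  set.seed((seed %% .Machine$integer.max) + 606L)
  aa <- strsplit(AA_CANONICAL, "")[[1L]]
  # approximate natural frequencies, His set near the study's 1.4% mean
  freq <- c(A = 7.9, C = 1.1, D = 5.2, E = 6.3, F = 4.1, G = 7.0, H = 1.4,
            I = 6.9, K = 6.5, L = 9.9, M = 2.6, N = 4.0, P = 4.3, Q = 3.7,
            R = 4.8, S = 5.9, T = 5.3, V = 6.9, W = 1.0, Y = 3.4)
  freq <- freq[aa] / sum(freq[aa])
  is_out <- c(rep(TRUE, outliers), rep(FALSE, n - outliers))
  is_out <- sample(is_out)
  lens <- pmax(60L, as.integer(round(stats::rlnorm(n, log(300), 0.4))))
  lens[is_out] <- pmax(lens[is_out], 800L)  # long outliers: tight fractions
  seqs <- character(n)
  for (i in seq_len(n)) {
    p <- freq
    if (is_out[i]) {
      p[residue] <- outlier_propensity
    } else {
      # per-protein propensity jitter for the screened residue
      p[residue] <- stats::rgamma(1, shape = 4, rate = 4 / freq[[residue]])
    }
    p <- p / sum(p)
    seqs[i] <- paste(sample(aa, lens[i], replace = TRUE, prob = p),
                     collapse = "")
  }
  ids <- sprintf("PROT_%04d", seq_len(n))
  prot <- Biostrings::AAStringSet(seqs)
  names(prot) <- ids
  list(proteins = prot,
       truth = data.frame(protein_id = ids, is_outlier = is_out,
                          stringsAsFactors = FALSE))
}

#' Simulate a complete study-shaped dataset
#'
#' Runs every generator from the one design seed: annotation, expression
#' truth, RNA-Seq counts, read batch and probe-level array intensities.
#'
#' @param design a [simulation_design()].
#' @param n_reads read-batch size.
#' @return List: `design`, `genes`, `sequences`, `truth`, `counts`, `reads`
#'   (with bookkeeping), `probes`.
#' @export
simulate_dataset <- function(design = simulation_design(), n_reads = 10000) {
  ann <- simulate_annotation(design)
  truth <- simulate_truth(design, ann$genes)
  counts <- simulate_counts(design, truth, ann$genes)
  reads <- simulate_reads(design, ann$genes, n_reads)
  probes <- simulate_array(design, truth, ann$genes)
  list(design = design, genes = ann$genes, sequences = ann$sequences,
       truth = truth, counts = counts, reads = reads, probes = probes)
}
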