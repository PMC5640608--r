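#' Gene model table
#'
#' Validates and normalizes the annotation table the pipeline consumes.
#' Near-identical duplicated genes (which hybridization or read mapping can
#' only measure collectively) carry a shared `duplicate_group` id.
#'
#' @param gene_id character gene identifiers (unique).
#' @param length_bp positive integer gene lengths.
#' @param duplicate_group optional group id (NA = singleton).
#' @param is_rrna logical rRNA flag.
#' @return data.frame of class `gene_models`.
#' @export
gene_models <- function(gene_id, length_bp, duplicate_group = NA,
                        is_rrna = FALSE) {
  stopifnot(!anyDuplicated(gene_id), all(length_bp > 0))
  df <- data.frame(gene_id = as.character(gene_id),
                   length_bp = as.integer(length_bp),
                   duplicate_group = rep_len(as.character(duplicate_group),
                                             length(gene_id)),
                   is_rrna = rep_len(as.logical(is_rrna), length(gene_id)),
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Count matrix with replicate conditions and library sizes
#'
#' @param counts non-negative integer matrix, genes x replicates, with
#'   dimnames.
#' @param conditions condition label per replicate column.
#' @param lib_sizes total mapped reads per replicate; must be at least the
#'   column sums of assigned counts. Default: the column sums.
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(counts, conditions, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), !is.null(rownames(counts)),
            length(conditions) == ncol(counts),
            length(lib_sizes) == ncol(counts))
  if (any(lib_sizes < colSums(counts) - 1e-9))
    stop("lib_sizes must be >= column sums of assigned counts")
  structure(list(counts = counts, conditions = factor(conditions),
                 lib_sizes = as.numeric(lib_sizes)),
            class = "count_matrix")
}

#' Probe-level microarray intensities
#'
#' @param intensities matrix, probe measurements x arrays. Each physical probe
#'   appears once per array block.
#' @param probe_info data.frame with columns `probe_id`, `gene_id`, `block`,
#'   one row per intensity row.
#' @param conditions condition label per array column.
#' @return Object of class `probe_set`.
#' @export
probe_set <- function(intensities, probe_info, conditions) {
  intensities <- as.matrix(intensities)
  stopifnot(nrow(probe_info) == nrow(intensities),
            all(c("probe_id", "gene_id", "block") %in% names(probe_info)),
            length(conditions) == ncol(intensities))
  structure(list(intensities = intensities, probe_info = probe_info,
                 conditions = factor(conditions)),
            class = "probe_set")
}

#' Filter read records by the study's discard rules
#'
#' Keeps exactly the reads that are not 16S/23S rRNA hits, map to a single
#' genomic segment, and carry at most two mismatches. Discards are tallied by
#' the first failing rule in the order rRNA, multimap, mismatches; reads
#' matching no locus at all are tallied separately as `unassigned`.
#'
#' @param reads data.frame with columns `read_id`, `assigned_gene`,
#'   `n_loci_matched`, `mismatches`, `is_rrna_hit`.
#' @return List with `kept` (the retained rows) and `tally` (named counts:
#'   kept, rrna, multimap, mismatch, unassigned).
#' @export
filter_reads <- function(reads) {
  need <- c("read_id", "n_loci_matched", "mismatches", "is_rrna_hit")
  stopifnot(all(need %in% names(reads)))
  if (nrow(reads) == 0L) {
    return(list(kept = reads,
                tally = c(kept = 0L, rrna = 0L, multimap = 0L,
                          mismatch = 0L, unassigned = 0L)))
  }
  stopifnot(all(reads$n_loci_matched >= 0))
  rrna <- reads$is_rrna_hit
  multi <- !rrna & reads$n_loci_matched > 1
  mism <- !rrna & !multi & reads$mismatches > 2
  unas <- !rrna & !multi & !mism & reads$n_loci_matched == 0
  keep <- !(rrna | multi | mism | unas)
  list(kept = reads[keep, , drop = FALSE],
       tally = c(kept = sum(keep), rrna = sum(rrna), multimap = sum(multi),
                 mismatch = sum(mism), unassigned = sum(unas)))
}

# Collapse counts of duplicate-identity groups onto one collective record.
# The collective id is the lexicographically first member; its length is the
# representative's (group members are ~100% identical, so lengths match;
# mismatched lengths warn and use the mean).
pool_duplicate_counts <- function(counts, genes) {
  stopifnot(all(rownames(counts) %in% genes$gene_id))
  g <- genes[match(rownames(counts), genes$gene_id), ]
  key <- ifelse(is.na(g$duplicate_group), g$gene_id,
                paste0(".grp.", g$duplicate_group))
  pooled <- rowsum(counts, key, reorder = FALSE)
  info <- do.call(rbind, lapply(split(seq_len(nrow(g)), key)[unique(key)],
    function(idx) {
      members <- sort(g$gene_id[idx])
      len <- g$length_bp[idx][order(g$gene_id[idx])]
      if (length(unique(len)) > 1L) {
        warning("duplicate group with mismatched lengths (",
                paste(members, collapse = ","), "); using mean length")
        use_len <- mean(len)
      } else use_len <- len[1L]
      data.frame(gene_id = members[1L], length_bp = use_len,
                 n_members = length(members),
                 duplicate_group = g$duplicate_group[idx][1L],
                 is_rrna = any(g$is_rrna[idx]), stringsAsFactors = FALSE)
    }))
  rownames(pooled) <- info$gene_id
  rownames(info) <- NULL
  list(counts = pooled, genes = info)
}

#' RPKM normalization
#'
#' Reads assigned per kilobase of target per million mapped reads:
#' `count / (length_bp/1000) / (lib_size/1e6)`. Counts of duplicate-identity
#' gene groups are pooled onto one collective record first (their expression
#' can only be measured collectively).
#'
#' @param x a [count_matrix()].
#' @param genes a [gene_models()] table covering the count rows.
#' @param pool_duplicates collapse duplicate groups (default TRUE).
#' @param pseudocount added to every count before normalization (0 for
#'   reporting; the DE test uses 0.5).
#' @return RPKM matrix with attribute `genes`: the (collapsed) gene table.
#' @export
compute_rpkm <- function(x, genes, pool_duplicates = TRUE, pseudocount = 0) {
  stopifnot(inherits(x, "count_matrix"))
  if (any(x$lib_sizes <= 0)) stop("zero library size")
  counts <- x$counts
  gtab <- genes
  if (pool_duplicates && any(!is.na(genes$duplicate_group))) {
    pooled <- pool_duplicate_counts(counts, genes)
    counts <- pooled$counts
    gtab <- pooled$genes
  } else {
    gtab <- genes[match(rownames(counts), genes$gene_id), ]
  }
  len_kb <- gtab$length_bp[match(rownames(counts), gtab$gene_id)] / 1000
  rpkm <- sweep((counts + pseudocount) / len_kb, 2, x$lib_sizes / 1e6, "/")
  attr(rpkm, "genes") <- gtab
  rpkm
}

#' Merge biological replicates and assign detection status
#'
#' Replicate RPKM values are averaged per condition. A gene is `not_detected`
#' if no read was assigned to it in any replicate of any condition;
#' `below_threshold` if detected but its log2 mean RPKM stays below the
#' threshold in every condition; `detected` otherwise (a log2 mean RPKM
#' exactly at the threshold passes).
#'
#' @param rpkm RPKM matrix (genes x replicates), e.g. from [compute_rpkm()].
#' @param conditions condition label per column.
#' @param log2_threshold detection threshold on log2 mean RPKM (default 5,
#'   the study's median log2 RPKM).
#' @return data.frame: `gene_id`, one `rpkm_<condition>` column per
#'   condition, `log2_rpkm` (max over conditions), `status`.
#' @export
merge_replicates <- function(rpkm, conditions, log2_threshold = 5) {
  conditions <- factor(conditions)
  stopifnot(length(conditions) == ncol(rpkm), all(table(conditions) >= 1))
  means <- vapply(levels(conditions), function(cc)
    rowMeans(rpkm[, conditions == cc, drop = FALSE]), numeric(nrow(rpkm)))
  means <- matrix(means, nrow = nrow(rpkm),
                  dimnames = list(rownames(rpkm), levels(conditions)))
  maxmean <- apply(means, 1, max)
  status <- ifelse(rowSums(rpkm) == 0, "not_detected",
                   ifelse(log2(maxmean) < log2_threshold,
                          "below_threshold", "detected"))
  out <- data.frame(gene_id = rownames(rpkm), means,
                    log2_rpkm = log2(maxmean), status = status,
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[1 + seq_len(ncol(means))] <- paste0("rpkm_", colnames(means))
  out
}

# Vectorized two-sample t-test on rows of a matrix.
# method "pooled": equal-variance Student t (calibrated at n = 3 under the
# generator's equal-dispersion conditions); "welch": unequal-variance.
# Degenerate rows (zero variance in both groups) get p = 1 when the means
# agree and p = 0 otherwise.
row_t_test <- function(x, ia, ib, method = c("pooled", "welch")) {
  method <- match.arg(method)
  na <- length(ia); nb <- length(ib)
  stopifnot(na >= 2, nb >= 2)
  xa <- x[, ia, drop = FALSE]; xb <- x[, ib, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  if (method == "pooled") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep.int(na + nb - 2, nrow(x))
  } else {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (ma - mb) / sqrt(se2)
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  degen <- se2 == 0
  p[degen] <- ifelse(ma[degen] == mb[degen], 1, 0)
  p
}

parse_contrast <- function(contrast) {
  if (length(contrast) == 1L && grepl("_vs_", contrast))
    contrast <- strsplit(contrast, "_vs_", fixed = TRUE)[[1L]]
  stopifnot(length(contrast) == 2L)
  contrast
}

de_call_frame <- function(gene_id, platform, contrast, fold_raw, p,
                          p_cutoff, strong_fold) {
  up <- fold_raw >= 1
  fold <- ifelse(up, fold_raw, 1 / fold_raw)
  sig <- p <= p_cutoff
  data.frame(gene_id = gene_id, platform = platform,
             contrast = paste0(contrast[1L], "_vs_", contrast[2L]),
             fold_change = fold, direction = ifelse(up, "up", "down"),
             p_value = p, significant = sig,
             strong = sig & fold >= strong_fold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene differential-expression calls
#'
#' Computes per-gene fold changes (ratio of condition means; folds below one
#' are reported as the inverse with `direction = "down"`, the study's
#' "exponent -1" rendering) and p-values from a two-sample test on
#' log2-transformed replicate values. A gene is `significant` at
#' `p <= p_cutoff` (inclusive) and `strong` when also changed
#' `strong_fold`-fold or more (inclusive).
#'
#' For RNA-Seq ([count_matrix()]) the replicate values are RPKM computed after
#' adding `pseudocount` to each count. For microarrays ([probe_set()]) the
#' probe intensities are quantile-normalized across arrays, then averaged per
#' gene per array over all probes in both array blocks.
#'
#' @param x a `count_matrix` or `probe_set`.
#' @param contrast the two condition labels, test first, reference second
#'   (or a single `"test_vs_reference"` string).
#' @param ... passed to methods.
#' @return data.frame of DE calls: `gene_id`, `platform`, `contrast`,
#'   `fold_change` (>= 1), `direction`, `p_value`, `significant`, `strong`.
#' @export
call_de <- function(x, contrast, ...) UseMethod("call_de")

#' @rdname call_de
#' @param genes a [gene_models()] table (RNA-Seq method).
#' @param p_cutoff significance level (default 0.05).
#' @param strong_fold fold cutoff for "strongly" regulated (default 10).
#' @param test `"pooled"` (default) or `"welch"`.
#' @param pseudocount count offset stabilizing log2 RPKM (default 0.5).
#' @export
call_de.count_matrix <- function(x, contrast, genes, p_cutoff = 0.05,
                                 strong_fold = 10, test = "pooled",
                                 pseudocount = 0.5, ...) {
  contrast <- parse_contrast(contrast)
  cond <- as.character(x$conditions)
  for (cc in contrast) {
    n <- sum(cond == cc)
    if (n < 2) stop("fewer than 2 replicates in condition '", cc, "'")
  }
  rpkm <- compute_rpkm(x, genes, pseudocount = pseudocount)
  ia <- which(cond == contrast[1L]); ib <- which(cond == contrast[2L])
  fold_raw <- rowMeans(rpkm[, ia, drop = FALSE]) /
    rowMeans(rpkm[, ib, drop = FALSE])
  p <- row_t_test(log2(rpkm), ia, ib, method = test)
  de_call_frame(rownames(rpkm), "rnaseq", contrast, fold_raw, p,
                p_cutoff, strong_fold)
}

#' Per-gene, per-array intensities from probe-level data
#'
#' Optionally quantile-normalizes intensities across arrays, then averages the
#' probe values of each gene (up to 8 probes, duplicated in two array blocks)
#' per array.
#'
#' @param x a [probe_set()].
#' @param normalize quantile-normalize across arrays first (default TRUE).
#' @return Gene x array intensity matrix (linear scale).
#' @export
summarize_probes <- function(x, normalize = TRUE) {
  stopifnot(inherits(x, "probe_set"))
  ints <- x$intensities
  if (normalize) ints <- limma::normalizeQuantiles(ints)
  n <- rowsum(matrix(1, nrow(ints), 1), x$probe_info$gene_id)
  sums <- rowsum(ints, x$probe_info$gene_id)
  sums / as.vector(n)
}

#' @rdname call_de
#' @param normalize quantile-normalize microarray intensities (default TRUE).
#' @export
call_de.probe_set <- function(x, contrast, p_cutoff = 0.05, strong_fold = 10,
                              test = "pooled", normalize = TRUE, ...) {
  contrast <- parse_contrast(contrast)
  cond <- as.character(x$conditions)
  for (cc in contrast) {
    if (sum(cond == cc) < 2)
      stop("fewer than 2 replicates in condition '", cc, "'")
  }
  gene_int <- summarize_probes(x, normalize = normalize)
  ia <- which(cond == contrast[1L]); ib <- which(cond == contrast[2L])
  fold_raw <- rowMeans(gene_int[, ia, drop = FALSE]) /
    rowMeans(gene_int[, ib, drop = FALSE])
  p <- row_t_test(log2(gene_int), ia, ib, method = test)
  de_call_frame(rownames(gene_int), "microarray", contrast, fold_raw, p,
                p_cutoff, strong_fold)
}

#' Reconcile microarray and RNA-Seq differential-expression calls
#'
#' A gene is *called* when significant on at least one platform (any
#' contrast). A called gene is *disqualified* when its RNA-Seq expression is
#' below the detection threshold AND it did not meet the p-value criterion on
#' the microarray; every other called gene is *qualified* (in particular,
#' genes detected only by the microarray retain their microarray-only calls).
#' Qualified genes are ranked by their largest significant fold change across
#' platforms and contrasts (descending; ties broken by gene id).
#'
#' @param array_calls microarray calls from [call_de()].
#' @param rnaseq_calls RNA-Seq calls from [call_de()].
#' @param expr_records RNA-Seq expression records from [merge_replicates()]
#'   covering every called gene.
#' @return data.frame of class `merged_table`: per gene, platform
#'   significance flags, RNA-Seq status, `called`/`qualified`/`disqualified`
#'   flags, `best_fold` (largest significant fold), `rank` (NA if not
#'   qualified). The combined call table is attached as attribute `calls`.
#' @export
reconcile <- function(array_calls, rnaseq_calls, expr_records) {
  calls <- rbind(array_calls, rnaseq_calls)
  ids <- sort(unique(calls$gene_id))
  missing <- setdiff(ids, expr_records$gene_id)
  if (length(missing))
    stop("gene(s) present in calls but absent from expression records: ",
         paste(utils::head(missing, 5), collapse = ", "))
  status <- expr_records$status[match(ids, expr_records$gene_id)]
  arr_sig <- vapply(ids, function(g)
    any(array_calls$significant[array_calls$gene_id == g]), logical(1))
  rna_sig <- vapply(ids, function(g)
    any(rnaseq_calls$significant[rnaseq_calls$gene_id == g]), logical(1))
  called <- arr_sig | rna_sig
  below <- status == "below_threshold"
  disq <- called & below & !arr_sig
  qual <- called & !disq
  best <- vapply(ids, function(g) {
    f <- calls$fold_change[calls$gene_id == g & calls$significant]
    if (length(f)) max(f) else NA_real_
  }, numeric(1))
  out <- data.frame(gene_id = ids, array_significant = arr_sig,
                    rnaseq_significant = rna_sig, rnaseq_status = status,
                    called = called, qualified = qual, disqualified = disq,
                    best_fold = best, rank = NA_integer_,
                    row.names = NULL, stringsAsFactors = FALSE)
  qi <- which(out$qualified)
  ord <- qi[order(-out$best_fold[qi], out$gene_id[qi])]
  out$rank[ord] <- seq_along(ord)
  attr(out, "calls") <- calls
  class(out) <- c("merged_table", "data.frame")
  out
}

#' Regulation labels per gene and contrast
#'
#' For each gene and contrast, takes the call with the largest significant
#' fold change across platforms and labels it `up` / `down` (significant),
#' `strongly_up` / `strongly_down` (significant and at least the strong-fold
#' cutoff), or `ns`.
#'
#' @param merged a `merged_table` from [reconcile()] (or a raw call
#'   data.frame).
#' @return data.frame: `gene_id`, `contrast`, `label`, `fold_change`,
#'   `p_value`.
#' @export
classify_regulation <- function(merged) {
  calls <- if (inherits(merged, "merged_table")) attr(merged, "calls")
           else merged
  stopifnot(is.data.frame(calls), nrow(calls) > 0 || TRUE)
  if (nrow(calls) == 0L)
    return(data.frame(gene_id = character(), contrast = character(),
                      label = character(), fold_change = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  key <- interaction(calls$gene_id, calls$contrast, drop = TRUE)
  picked <- do.call(rbind, lapply(split(calls, key), function(d) {
    sig <- d[d$significant, , drop = FALSE]
    best <- if (nrow(sig)) sig[which.max(sig$fold_change), ]
            else d[which.min(d$p_value), ]
    lab <- if (!best$significant) "ns"
           else if (best$strong) paste0("strongly_", best$direction)
           else best$direction
    data.frame(gene_id = best$gene_id, contrast = best$contrast, label = lab,
               fold_change = best$fold_change, p_value = best$p_value,
               stringsAsFactors = FALSE)
  }))
  rownames(picked) <- NULL
  picked[order(picked$gene_id, picked$contrast), , drop = FALSE]
}
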