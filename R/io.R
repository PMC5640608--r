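#' Read and write FASTA
#'
#' Thin wrappers over Biostrings with the error reporting the pipeline
#' expects (file and offending record named on failure).
#'
#' @param file path to a FASTA file.
#' @param type `"DNA"` or `"AA"`.
#' @return `read_fasta`: a `DNAStringSet` or `AAStringSet`.
#' @export
read_fasta <- function(file, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (!file.exists(file)) stop("FASTA file not found: ", file)
  first <- readLines(file, n = 1L)
  if (length(first) && !startsWith(first, ">"))
    stop(sprintf("%s:1: malformed FASTA (expected '>' header, got '%s')",
                 file, substr(first, 1, 30)))
  tryCatch(
    switch(type, DNA = Biostrings::readDNAStringSet(file),
           AA = Biostrings::readAAStringSet(file)),
    error = function(e)
      stop(sprintf("failed to parse FASTA %s: %s", file, conditionMessage(e))))
}

#' @rdname read_fasta
#' @param x an `XStringSet` (or named character vector) to write.
#' @return `write_fasta`: the file path, invisibly.
#' @export
write_fasta <- function(x, file) {
  if (is.character(x)) {
    x <- Biostrings::BStringSet(x)
  }
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

#' Read gene models from GFF3
#'
#' Imports gene/CDS features with rtracklayer (GFF3 coordinates are 1-based
#' inclusive) and converts them to the package's internal 0-based half-open
#' convention; `length_bp = end0 - start0`. A `duplicate_group` attribute, if
#' present, is carried through; strand is recorded but ignored for counting.
#'
#' @param file GFF3 path.
#' @param feature feature types to keep (default gene and CDS).
#' @return A [gene_models()] table with `start0`, `end0`, `seqid`, `strand`.
#' @export
read_gff3_genes <- function(file, feature = c("gene", "CDS")) {
  if (!file.exists(file)) stop("GFF3 file not found: ", file)
  gr <- rtracklayer::import(file, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature]
  if (!length(gr)) stop("no ", paste(feature, collapse = "/"),
                        " features in ", file)
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
    as.character(gr$Name)
  start0 <- GenomicRanges::start(gr) - 1L   # 1-based inclusive -> 0-based half-open
  end0 <- GenomicRanges::end(gr)
  grp <- if ("duplicate_group" %in% names(S4Vectors::mcols(gr)))
    as.character(gr$duplicate_group) else NA_character_
  rr <- if ("is_rrna" %in% names(S4Vectors::mcols(gr)))
    as.logical(gr$is_rrna) else FALSE
  g <- gene_models(ids, end0 - start0, grp, rr)
  g$start0 <- start0
  g$end0 <- end0
  g$seqid <- as.character(GenomicRanges::seqnames(gr))
  g$strand <- as.character(GenomicRanges::strand(gr))
  g
}

#' Write simulated gene models as GFF3
#'
#' Restores 1-based inclusive coordinates on write.
#'
#' @param genes annotation table from [simulate_annotation()] (columns
#'   `gene_id`, `start`, `end`, `strand`, `length_bp`, `duplicate_group`,
#'   `is_rrna`).
#' @param file output path.
#' @param seqid contig name.
#' @return The file path, invisibly.
#' @export
write_gff3_genes <- function(genes, file, seqid = "contig_1") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$duplicate_group <- genes$duplicate_group
  gr$is_rrna <- genes$is_rrna
  rtracklayer::export(gr, file, format = "gff3")
  invisible(file)
}

#' Read/write a tab-delimited numeric matrix
#'
#' TSV with a header row of column ids and row ids in the first column;
#' UTF-8, Unix newlines.
#'
#' @param file path.
#' @return `read_tsv_matrix`: numeric matrix with dimnames.
#' @export
read_tsv_matrix <- function(file) {
  if (!file.exists(file)) stop("TSV file not found: ", file)
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop(file, ": non-numeric values in matrix body")
  rownames(m) <- df[[1L]]
  m
}

#' @rdname read_tsv_matrix
#' @param x matrix to write.
#' @param id_col name for the row-id column.
#' @export
write_tsv_matrix <- function(x, file, id_col = "gene_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a results table
#'
#' @param table data.frame.
#' @param file output path.
#' @param format `"tsv"` (default) or `"json"`.
#' @export
write_results <- function(table, file, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv")
    utils::write.table(table, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  else jsonlite::write_json(table, file, dataframe = "rows",
                            auto_unbox = TRUE, digits = NA)
  invisible(file)
}

# The study-faithful defaults of the analysis configuration.
config_defaults <- function() {
  list(p_cutoff = 0.05,            # significance level, inclusive
       log2_rpkm_threshold = 5,    # detection threshold (median log2 RPKM)
       strong_fold = 10,           # "strongly" regulated cut, inclusive
       de_test = "pooled",         # or "welch"
       pseudocount = 0.5,          # count offset before RPKM for the test
       fdr_correction = FALSE,     # optional BH mode, off for faithful runs
       atp_per_proton = 3 / 11,
       rnf_protons_per_pair = 1,
       methylene_thf_mode = "nadh_only",
       wlp_atp_net = 0,
       composition_k = 2,
       seed = 1)
}

#' Load and validate an analysis configuration
#'
#' Reads a YAML configuration and merges it over the study-faithful defaults
#' (p <= 0.05, log2 RPKM >= 5, 10-fold strong cut, 3 ATP per 11 protons,
#' k = 2 SD for the composition screen). Unknown keys are an error that lists
#' the valid ones; negative thresholds are rejected.
#'
#' @param file YAML path, YAML text, or NULL/empty for pure defaults.
#' @return Named list of validated settings.
#' @export
load_config <- function(file = NULL) {
  cfg <- config_defaults()
  user <- if (is.null(file)) NULL else parse_structured(file)
  if (!is.null(user)) {
    bad <- setdiff(names(user), names(cfg))
    if (length(bad))
      stop("unknown config key(s): ", paste(bad, collapse = ", "),
           "; valid keys: ", paste(names(cfg), collapse = ", "))
    cfg[names(user)] <- user
  }
  numeric_pos <- c("p_cutoff", "log2_rpkm_threshold", "strong_fold",
                   "atp_per_proton", "pseudocount", "composition_k")
  for (k in numeric_pos) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0)
      stop("config key '", k, "' must be a non-negative number")
  }
  if (cfg$rnf_protons_per_pair < 0)
    stop("config key 'rnf_protons_per_pair' must be >= 0")
  if (!cfg$de_test %in% c("pooled", "welch"))
    stop("config key 'de_test' must be 'pooled' or 'welch'")
  if (!cfg$methylene_thf_mode %in% c("nadh_only", "bifurcating"))
    stop("config key 'methylene_thf_mode' must be 'nadh_only' or 'bifurcating'")
  cfg
}

#' Write a run manifest
#'
#' Records what a run did: command, configuration snapshot, input file
#' checksums, seed, package version and timestamp, so that equal-manifest
#' reruns produce equal outputs.
#'
#' @param file output JSON path.
#' @param command short command description.
#' @param config configuration list.
#' @param inputs character vector of input file paths (checksummed if they
#'   exist).
#' @param seed integer seed used.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(file, command, config = load_config(),
                               inputs = character(0), seed = config$seed) {
  sums <- vapply(inputs, function(f)
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_,
    character(1))
  manifest <- list(command = command, config = config,
                   inputs = as.list(sums), seed = seed,
                   package_version = as.character(utils::packageVersion("acetoscope")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
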