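#' Read and write FASTA references
#'
#' Thin wrappers over Biostrings keeping the package's in-memory
#' representation (named character vectors of sequences).
#'
#' @param path File path.
#' @return `read_fasta()`: a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Read and write 4-line-record FASTQ
#'
#' The reader validates record framing first (a `@` header on every
#' fourth line, `+` on the third line of each record, matching
#' sequence/quality lengths) and reports the offending line number
#' before handing parsing to Biostrings. The writer emits constant
#' placeholder qualities (`"I"`).
#'
#' @param path File path.
#' @return `read_fastq()`: named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ: ", length(lines),
         " lines is not a multiple of 4 (truncated record at line ",
         length(lines), ")")
  for (i in seq(1, length(lines), by = 4)) {
    if (!startsWith(lines[i], "@"))
      stop("malformed FASTQ at line ", i, ": expected '@' header")
    if (!startsWith(lines[i + 2], "+"))
      stop("malformed FASTQ at line ", i + 2, ": expected '+' separator")
    if (nchar(lines[i + 1]) != nchar(lines[i + 3]))
      stop("malformed FASTQ at line ", i + 3,
           ": quality length differs from sequence length")
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fastq
#' @param reads Character vector of read sequences.
#' @param ids Optional read identifiers.
#' @param quality Single quality character replicated across each read.
#' @export
write_fastq <- function(reads, path, ids = NULL, quality = "I") {
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  x <- Biostrings::DNAStringSet(stats::setNames(reads, ids))
  quals <- Biostrings::BStringSet(strrep(quality, nchar(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read and write BED interval files
#'
#' BED is 0-based half-open; the in-memory representation keeps that
#' convention (`start0`, `end0`). Parsing and serialisation go through
#' rtracklayer.
#'
#' @param path File path.
#' @return `read_bed()`: data frame with `ref`, `start0`, `end0` and,
#'   when present in the file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(ref = as.character(GenomicRanges::seqnames(gr)),
                   start0 = GenomicRanges::start(gr) - 1L,
                   end0 = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  md <- GenomicRanges::mcols(gr)
  if (!is.null(md$name)) df$name <- md$name
  if (!is.null(md$score)) df$score <- md$score
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) df$strand <- st
  df
}

#' @rdname read_bed
#' @param df Data frame with columns `ref`, `start0`, `end0` and
#'   optionally `name`, `score`, `strand`.
#' @export
write_bed <- function(df, path) {
  if (any(df$end0 <= df$start0)) stop("BED intervals require start0 < end0")
  gr <- GenomicRanges::GRanges(
    seqnames = df$ref,
    ranges = IRanges::IRanges(start = df$start0 + 1L, end = df$end0),
    strand = if ("strand" %in% names(df)) df$strand else "*")
  if ("name" %in% names(df)) gr$name <- as.character(df$name)
  if ("score" %in% names(df)) gr$score <- as.numeric(df$score)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read and write per-site count tables (TSV)
#'
#' The interchange format between pipeline stages: a tab-separated table
#' with header `ref, pos0, refbase, strand, condition, replicate, n_T,
#' n_C, n_other, depth`, coordinates 0-based.
#'
#' @param path File path.
#' @return `read_counts_tsv()`: the count data frame.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  # refbase/strand columns must stay character ("T" would parse as logical)
  chr_cols <- c(ref = "character", refbase = "character",
                strand = "character", condition = "character")
  hdr <- names(utils::read.delim(path, nrows = 0))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = chr_cols[names(chr_cols) %in% hdr])
  need <- c("ref", "pos0", "refbase", "strand", "condition", "replicate",
            "n_T", "n_C", "n_other", "depth")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("count TSV missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_counts_tsv
#' @param df A count (or signal) data frame.
#' @export
write_counts_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the simulate -> pileup -> call pipeline end to end
#'
#' Executes the computational stages of the conversion-sequencing
#' workflow on a synthetic amplicon: generates the reference and truth,
#' simulates treated and no-oxidation control counts, derives signals,
#' calls sites against the control, and writes all artifacts (counts,
#' signals, calls TSV, significant-sites BED, truth BED, resolved config
#' JSON, run-summary JSON) under `out_dir`. All randomness derives from
#' the single `seed`; rerunning the same config reproduces byte-identical
#' outputs.
#'
#' @param config Named list: `model_id` (`"ODN1"`, `"ODN2"`, `"ODN3"`),
#'   `depth`, `replicates`, `seed`, `fdr`, `min_depth`, `out_dir`, and
#'   optionally `fastq = TRUE` to also emit per-replicate FASTQ.
#' @return Invisibly, a list with the calls table and the paths written.
#' @export
run_pipeline <- function(config) {
  defaults <- list(model_id = "ODN1", depth = 1000, replicates = 3,
                   seed = 1, fdr = 0.1, min_depth = 100, fastq = FALSE,
                   out_dir = ".", schema_version = 1L)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(cfg$out_dir, f)

  odn <- make_odn(cfg$model_id, seed = cfg$seed)
  model <- if (cfg$model_id == "ODN1")
    list(conversion_preset("ODN1_site1"), conversion_preset("ODN1_site2"))
  else conversion_preset("ODN1_site1")
  if (is.list(model) && !inherits(model, "conversion_model") &&
      length(model) != nrow(odn$profile)) model <- model[[1]]

  treated <- simulate_counts(odn$reference, odn$profile, model, cfg$depth,
                             cfg$replicates, "treated", seed = cfg$seed)
  control <- simulate_counts(odn$reference, odn$profile, model, cfg$depth,
                             cfg$replicates, "control", seed = cfg$seed)

  write_fasta(odn$reference, pth("reference.fa"))
  write_truth_bed(odn$profile, pth("truth.bed"))
  write_counts_tsv(treated, pth("counts_treated.tsv"))
  write_counts_tsv(control, pth("counts_control.tsv"))

  signals <- rbind(site_signal(treated), site_signal(control))
  write_counts_tsv(signals, pth("signals.tsv"))

  calls <- call_sites(treated, control, fdr = cfg$fdr,
                      min_depth = cfg$min_depth)
  write_counts_tsv(calls, pth("calls.tsv"))
  sig <- calls[calls$significant, , drop = FALSE]
  if (nrow(sig) > 0) {
    write_bed(data.frame(ref = sig$ref, start0 = sig$pos0,
                         end0 = sig$pos0 + 1L,
                         name = sprintf("%.3g", sig$q_value),
                         score = 0, strand = sig$strand,
                         stringsAsFactors = FALSE),
              pth("significant.bed"))
  } else {
    writeLines(character(0), pth("significant.bed"))
  }

  if (isTRUE(cfg$fastq) && cfg$model_id %in% c("ODN1", "ODN2")) {
    for (cond in c("treated", "control")) {
      cc <- if (cond == "treated") treated else control
      for (r in seq_len(cfg$replicates)) {
        slice <- cc[cc$replicate == r, , drop = FALSE]
        emit_fastq(odn$reference, slice,
                   pth(sprintf("reads_%s_rep%d.fastq", cond, r)),
                   seed = derive_seed(cfg$seed, 500L + r))
      }
    }
  }

  jsonlite::write_json(cfg, pth("config.json"), auto_unbox = TRUE,
                       digits = NA)
  summary <- list(n_sites_tested = nrow(calls),
                  n_significant = sum(calls$significant),
                  n_true_sites = nrow(odn$profile),
                  seed = cfg$seed)
  jsonlite::write_json(summary, pth("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(calls = calls, config = cfg,
                 paths = list(out_dir = cfg$out_dir)))
}
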