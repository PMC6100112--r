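#' Pile up amplicon reads into per-site base counts
#'
#' Positional (gap-free) pileup for full-length amplicon reads: every read
#' is compared to the reference column by column. Each reference T is a
#' scored site; a read contributes to `n_T` if it shows T, `n_C` if it
#' shows C and `n_other` otherwise. Reverse-strand sites (reference A)
#' can be scored additionally, with G counted as the C-equivalent signal
#' and A as the T-equivalent. Reads whose length differs from the
#' reference are dropped and reported in the `n_dropped` attribute.
#'
#' @param reads Character vector of reads.
#' @param reference A single reference sequence (named character of
#'   length 1).
#' @param reverse_sites Optional integer vector of 0-based A positions to
#'   score as reverse-strand sites.
#' @param condition,replicate Labels carried into the output table.
#' @return A data frame of per-site counts (schema as
#'   [simulate_counts()]), with attribute `n_dropped` giving the number of
#'   length-mismatched reads discarded.
#' @export
#' @examples
#' ref <- c(amp = "ACTGTA")
#' counts <- count_bases(c("ACTGTA", "ACCGTA"), ref)
#' counts[, c("pos0", "n_T", "n_C")]
count_bases <- function(reads, reference, reverse_sites = integer(0),
                        condition = NA_character_, replicate = NA_integer_) {
  stopifnot(length(reference) == 1L)
  refseq <- reference[[1]]
  if (is.null(names(reference))) names(reference) <- "ref1"
  if (nchar(refseq) == 0) stop("empty reference")
  chars <- strsplit(refseq, "")[[1]]
  t_pos0 <- which(chars == "T") - 1L
  reverse_sites <- as.integer(reverse_sites)
  if (length(reverse_sites) > 0 &&
      !all(chars[reverse_sites + 1L] == "A"))
    stop("reverse_sites must address A positions in the reference")
  if (length(t_pos0) == 0 && length(reverse_sites) == 0)
    stop("reference contains no T (and no reverse-strand site is configured)")
  keep <- nchar(reads) == nchar(refseq)
  n_dropped <- sum(!keep)
  reads <- reads[keep]
  if (length(reads) > 0) {
    mat <- matrix(unlist(strsplit(reads, ""), use.names = FALSE),
                  nrow = length(reads), byrow = TRUE)
  } else {
    mat <- matrix(character(0), nrow = 0, ncol = nchar(refseq))
  }
  tally <- function(pos0, strand) {
    col <- if (nrow(mat) > 0) mat[, pos0 + 1L] else character(0)
    t_eq <- if (strand == "+") "T" else "A"
    c_eq <- if (strand == "+") "C" else "G"
    n_t <- sum(col == t_eq); n_c <- sum(col == c_eq)
    data.frame(ref = names(reference), pos0 = pos0,
               refbase = if (strand == "+") "T" else "A", strand = strand,
               condition = condition, replicate = replicate,
               n_T = n_t, n_C = n_c, n_other = length(col) - n_t - n_c,
               depth = length(col), stringsAsFactors = FALSE)
  }
  out <- rbind(
    do.call(rbind, lapply(t_pos0, tally, strand = "+")),
    if (length(reverse_sites) > 0)
      do.call(rbind, lapply(reverse_sites, tally, strand = "-")))
  out <- out[order(out$pos0), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Derive per-site base-composition signals from counts
#'
#' Computes the proportions of reads giving T, C or other signal over all
#' reads at each site (`pct_T`, `pct_C`, `pct_other`) and the conversion
#' signal `c_over_ct = n_C / (n_C + n_T)`. Zero-depth sites are flagged
#' missing (`NA` proportions) rather than raising an error, and
#' `c_over_ct` is `NA` where `n_C + n_T = 0`.
#'
#' @param counts A count data frame (schema as [simulate_counts()]).
#' @return The input with columns `pct_T`, `pct_C`, `pct_other`,
#'   `c_over_ct` appended.
#' @export
#' @examples
#' x <- data.frame(ref = "amp", pos0 = 0, refbase = "T", strand = "+",
#'                 condition = "treated", replicate = 1,
#'                 n_T = 504, n_C = 394, n_other = 99, depth = 997)
#' site_signal(x)$pct_C   # 0.395
site_signal <- function(counts) {
  d <- counts$depth
  ct <- counts$n_C + counts$n_T
  counts$pct_T <- ifelse(d > 0, counts$n_T / d, NA_real_)
  counts$pct_C <- ifelse(d > 0, counts$n_C / d, NA_real_)
  counts$pct_other <- ifelse(d > 0, counts$n_other / d, NA_real_)
  counts$c_over_ct <- ifelse(ct > 0, counts$n_C / ct, NA_real_)
  counts
}

#' Aggregate technical replicates per site and condition
#'
#' Mean and sample standard deviation (n - 1 denominator) of each signal
#' proportion across replicates, grouped by site and condition; the
#' mean +/- SD summary used for triplicate amplicon readouts. With a
#' single replicate the SD is reported missing.
#'
#' @param signals Output of [site_signal()], possibly several replicates
#'   and conditions.
#' @return A data frame with one row per (ref, pos0, strand, condition)
#'   and columns `n_rep`, `mean_*` and `sd_*` for `pct_T`, `pct_C`,
#'   `pct_other`, `c_over_ct`.
#' @export
aggregate_replicates <- function(signals) {
  need <- c("ref", "pos0", "strand", "condition", "replicate",
            "pct_T", "pct_C", "pct_other", "c_over_ct")
  if (!all(need %in% names(signals)))
    stop("signals must contain columns: ", paste(need, collapse = ", "))
  key <- paste(signals$ref, signals$pos0, signals$strand, signals$condition,
               signals$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated replicate within a site/condition group; ",
         "each group must hold one condition with distinct replicates")
  grp <- paste(signals$ref, signals$pos0, signals$strand, signals$condition,
               sep = "\r")
  pieces <- split(signals, grp)
  out <- do.call(rbind, lapply(pieces, function(g) {
    s <- function(col) {
      v <- g[[col]]
      c(mean(v), if (length(v) > 1) stats::sd(v) else NA_real_)
    }
    pt <- s("pct_T"); pc <- s("pct_C"); po <- s("pct_other")
    cc <- s("c_over_ct")
    data.frame(ref = g$ref[1], pos0 = g$pos0[1], strand = g$strand[1],
               condition = g$condition[1], n_rep = nrow(g),
               mean_pct_T = pt[1], sd_pct_T = pt[2],
               mean_pct_C = pc[1], sd_pct_C = pc[2],
               mean_pct_other = po[1], sd_pct_other = po[2],
               mean_c_over_ct = cc[1], sd_c_over_ct = cc[2],
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$ref, out$pos0, out$condition), , drop = FALSE]
  rownames(out) <- NULL
  out
}
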