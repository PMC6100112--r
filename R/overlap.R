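#' Interval set on one reference
#'
#' Half-open 0-based intervals on a single reference sequence, as read
#' from BED. Intervals are merged (union of overlapping/adjacent runs)
#' before any overlap counting so that counts never double-count.
#'
#' @param start0,end0 Integer vectors, 0-based half-open (`start0 < end0`).
#' @param chrom_length Reference length; all intervals must fit.
#' @param ref Reference name.
#' @return Object of class `interval_set`.
#' @export
interval_set <- function(start0, end0, chrom_length, ref = "chr") {
  start0 <- as.integer(start0); end0 <- as.integer(end0)
  if (length(start0) != length(end0)) stop("start0/end0 length mismatch")
  if (any(end0 <= start0)) stop("intervals must satisfy start0 < end0")
  if (length(start0) > 0 && (any(start0 < 0) || any(end0 > chrom_length)))
    stop("intervals must lie within [0, chrom_length)")
  merged <- IRanges::reduce(IRanges::IRanges(start = start0 + 1L,
                                             end = end0))
  structure(list(ref = ref, ranges = merged,
                 chrom_length = as.integer(chrom_length)),
            class = "interval_set")
}

#' Count sites falling inside a region set
#'
#' @param sites Integer vector of 0-based site positions.
#' @param regions An [interval_set()].
#' @return Number of sites inside any merged region.
#' @export
#' @examples
#' overlap_count(c(5, 50), interval_set(0, 10, 100))  # 1
overlap_count <- function(sites, regions) {
  stopifnot(inherits(regions, "interval_set"))
  if (length(sites) == 0) return(0L)
  sites <- as.integer(sites)
  if (any(sites < 0 | sites >= regions$chrom_length))
    stop("site position outside [0, chrom_length)")
  sum(IRanges::overlapsAny(IRanges::IRanges(start = sites + 1L, width = 1L),
                           regions$ranges))
}

#' Random placements of sites over candidate T positions
#'
#' Null model for the overlap test: each permutation redraws the observed
#' number of sites uniformly without replacement from the candidate
#' positions (all Ts of the reference), preserving the site count.
#'
#' @param sites Observed 0-based site positions.
#' @param candidates 0-based candidate positions (must contain at least
#'   `length(sites)` positions).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Integer matrix, `n_perm` rows x `length(sites)` columns.
#' @export
permute_sites <- function(sites, candidates, n_perm, seed = 1) {
  k <- length(sites)
  candidates <- as.integer(candidates)
  if (length(candidates) < k)
    stop("need at least as many candidate positions as sites")
  if (n_perm < 1) stop("n_perm must be at least 1")
  withr::with_seed(derive_seed(seed, 5L), {
    t(vapply(seq_len(n_perm),
             function(i) sample(candidates, k, replace = FALSE),
             integer(k)))
  })
}

#' Permutation test of site/region overlap
#'
#' Tests whether called single-base sites overlap a region set (for
#' example enrichment-derived 5hmU peaks) more often than expected when
#' the same number of sites is placed at random candidate T positions.
#' One-sided (enrichment) empirical p-value with the add-one correction:
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, so `p >= 1/(1+n_perm)`
#' always. Under uniform sampling of candidates the null overlap count is
#' hypergeometric, which the permutation distribution approaches as
#' `n_perm` grows.
#'
#' @inheritParams permute_sites
#' @param regions An [interval_set()].
#' @param n_perm Number of permutations (default 10000).
#' @return Object of class `overlap_test`: list with `observed`,
#'   `null_counts`, `null_mean`, `null_sd`, `p_value`, `n_perm`, `seed`.
#' @export
permutation_pvalue <- function(sites, regions, candidates,
                               n_perm = 10000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  observed <- overlap_count(sites, regions)
  if (length(candidates) > 0 &&
      any(candidates < 0 | candidates >= regions$chrom_length))
    stop("candidate position outside [0, chrom_length)")
  in_region <- IRanges::overlapsAny(
    IRanges::IRanges(start = as.integer(candidates) + 1L, width = 1L),
    regions$ranges)
  k <- length(sites)
  if (length(candidates) < k)
    stop("need at least as many candidate positions as sites")
  null_counts <- withr::with_seed(derive_seed(seed, 5L), {
    vapply(seq_len(n_perm),
           function(i) sum(in_region[sample.int(length(candidates), k)]),
           integer(1))
  })
  p <- (1 + sum(null_counts >= observed)) / (1 + n_perm)
  structure(list(observed = observed, null_counts = null_counts,
                 null_mean = mean(null_counts),
                 null_sd = stats::sd(null_counts),
                 p_value = p, n_perm = n_perm, seed = seed),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat("Permutation overlap test\n")
  cat(sprintf("  observed overlap: %d\n", x$observed))
  cat(sprintf("  null mean +/- SD: %.2f +/- %.2f (%d permutations)\n",
              x$null_mean, x$null_sd, x$n_perm))
  cat(sprintf("  empirical p-value (one-sided, add-one): %.4g\n", x$p_value))
  invisible(x)
}

#' Extract candidate T positions from a reference sequence
#'
#' @param reference A single reference sequence (character of length 1).
#' @return Integer vector of 0-based positions of every T.
#' @export
t_positions <- function(reference) {
  which(strsplit(reference[[1]], "")[[1]] == "T") - 1L
}
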