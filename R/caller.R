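#' One-sided exact test for C-signal excess over the control
#'
#' Tests one site's pooled C/T counts in the treated library against the
#' no-oxidation control with a one-sided Fisher's exact test on the 2x2
#' table `[[treated C, treated T], [control C, control T]]`, alternative:
#' C enrichment in the treated arm. The p-value is the exact
#' hypergeometric upper-tail probability of observing at least the seen
#' number of treated C reads given the table margins. All arguments are
#' vectorised. An all-zero table yields p = 1 by convention.
#'
#' @param treated_c,treated_t Pooled C and T counts, treated condition.
#' @param control_c,control_t Pooled C and T counts, control condition.
#' @return Vector of one-sided p-values.
#' @export
#' @examples
#' site_test(50, 50, 0, 100)    # strong treated C excess
#' site_test(0, 100, 0, 100)    # no C anywhere: p = 1
site_test <- function(treated_c, treated_t, control_c, control_t) {
  n <- max(length(treated_c), length(treated_t),
           length(control_c), length(control_t))
  treated_c <- rep_len(treated_c, n); treated_t <- rep_len(treated_t, n)
  control_c <- rep_len(control_c, n); control_t <- rep_len(control_t, n)
  if (any(c(treated_c, treated_t, control_c, control_t) < 0))
    stop("counts must be non-negative")
  # P(X >= treated_c) for X ~ Hypergeometric(white = all C, black = all T,
  # drawn = treated reads)
  stats::phyper(treated_c - 1, treated_c + control_c,
                treated_t + control_t, treated_c + treated_t,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment; a thin wrapper around
#' [stats::p.adjust()] with input validation and empty-input handling, so
#' callers can treat q-values as a first-class quantity.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must be in [0, 1] and non-missing")
  stats::p.adjust(p, method = "BH")
}

#' Fold change of conversion signal versus the control
#'
#' Ratio of the pseudocounted conversion signal
#' `(n_C + psi) / (n_C + n_T + 2 psi)` between treated and control; the
#' pseudocount keeps the ratio finite when the control shows no C reads.
#' Vectorised.
#'
#' @param treated_c,treated_t Treated C and T counts.
#' @param control_c,control_t Control C and T counts.
#' @param pseudocount Additive pseudocount psi (default 0.5).
#' @return Numeric fold-change vector.
#' @export
#' @examples
#' fold_change(394, 504, 22, 973)  # ~19.4
fold_change <- function(treated_c, treated_t, control_c, control_t,
                        pseudocount = 0.5) {
  psi <- pseudocount
  ((treated_c + psi) / (treated_c + treated_t + 2 * psi)) /
    ((control_c + psi) / (control_c + control_t + 2 * psi))
}

#' Call 5hmU sites from treated and control count tables
#'
#' Pools replicates by summing counts per site and condition, keeps the
#' sites with pooled depth at least `min_depth` in both arms, tests each
#' with [site_test()], adjusts with [bh_fdr()] and flags significance at
#' `q < fdr` (default 0.1). Sites present in only one condition are
#' excluded with a message. Results are sorted by reference and position.
#'
#' @param treated,control Count data frames (schema as
#'   [simulate_counts()]), one per condition.
#' @param fdr FDR threshold for the significance flag.
#' @param min_depth Minimum pooled depth per condition for a site to be
#'   tested.
#' @param pseudocount Pseudocount for [fold_change()].
#' @return A data frame of class `site_calls`: site identity, pooled
#'   counts per arm, `p_value`, `q_value`, `fold_change`, `significant`.
#' @export
call_sites <- function(treated, control, fdr = 0.1, min_depth = 100,
                       pseudocount = 0.5) {
  pool <- function(x) {
    grp <- paste(x$ref, x$pos0, x$refbase, x$strand, sep = "\r")
    agg <- stats::aggregate(x[c("n_T", "n_C", "n_other", "depth")],
                            by = list(grp = grp), FUN = sum)
    id <- x[!duplicated(grp), c("ref", "pos0", "refbase", "strand")]
    id <- id[match(agg$grp, unique(grp)), , drop = FALSE]
    cbind(id, agg[c("n_T", "n_C", "n_other", "depth")])
  }
  tp <- pool(treated); cp <- pool(control)
  m <- merge(tp, cp, by = c("ref", "pos0", "refbase", "strand"),
             suffixes = c("_treated", "_control"))
  n_lost <- nrow(tp) + nrow(cp) - 2 * nrow(m)
  if (n_lost > 0)
    message(n_lost, " site record(s) present in only one condition; excluded")
  m <- m[m$depth_treated >= min_depth & m$depth_control >= min_depth, ,
         drop = FALSE]
  m <- m[order(m$ref, m$pos0), , drop = FALSE]
  if (nrow(m) == 0) {
    out <- cbind(m[, c("ref", "pos0", "refbase", "strand")],
                 data.frame(n_C_treated = integer(0), n_T_treated = integer(0),
                            n_C_control = integer(0), n_T_control = integer(0),
                            p_value = numeric(0), q_value = numeric(0),
                            fold_change = numeric(0), significant = logical(0)))
    class(out) <- c("site_calls", "data.frame")
    return(out)
  }
  p <- site_test(m$n_C_treated, m$n_T_treated, m$n_C_control, m$n_T_control)
  q <- bh_fdr(p)
  out <- data.frame(
    ref = m$ref, pos0 = m$pos0, refbase = m$refbase, strand = m$strand,
    n_C_treated = m$n_C_treated, n_T_treated = m$n_T_treated,
    n_C_control = m$n_C_control, n_T_control = m$n_T_control,
    depth_treated = m$depth_treated, depth_control = m$depth_control,
    p_value = p, q_value = q,
    fold_change = fold_change(m$n_C_treated, m$n_T_treated,
                              m$n_C_control, m$n_T_control, pseudocount),
    significant = q < fdr, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("site_calls", "data.frame")
  out
}

# Exact rank-sum tail probabilities with midrank ties, by dynamic
# programming over doubled ranks (midranks are multiples of 1/2, so
# doubling makes them integers). Counts, for each achievable doubled
# rank sum s, the number of size-n1 subsets of the pooled sample attaining
# it; tails follow by summation. Exact for any tie pattern.
ranksum_tails <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r2 <- as.integer(round(2 * rank(c(x, y))))
  w_obs <- sum(r2[seq_len(n1)])
  smax <- sum(r2)
  # counts[k + 1, s + 1]: subsets of size k with doubled-rank sum s
  counts <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
  counts[1L, 1L] <- 1
  for (r in r2) {
    kmax <- min(n1, nrow(counts) - 1L)
    for (k in seq.int(kmax, 1L)) {
      idx <- seq_len(smax + 1L - r)
      counts[k + 1L, idx + r] <- counts[k + 1L, idx + r] + counts[k, idx]
    }
  }
  dist <- counts[n1 + 1L, ]
  total <- sum(dist)                       # = choose(n, n1)
  list(p_le = sum(dist[seq_len(w_obs + 1L)]) / total,
       p_ge = sum(dist[seq.int(w_obs + 1L, smax + 1L)]) / total)
}

#' Replicate-level rank-sum test of modified versus unmodified signal
#'
#' Wilcoxon rank-sum (Mann-Whitney) comparison of per-replicate signal at
#' a modified site against the signal at proximal unmodified Ts, as used
#' to establish that per-site C readout at 5hmU exceeds background across
#' technical replicates. For small samples (both groups at most
#' `exact_max`) the p-value is exact, computed by full enumeration of the
#' rank-sum distribution with midrank handling of ties; larger samples
#' use the normal approximation with tie correction and continuity
#' correction (via [stats::wilcox.test()]).
#'
#' @param x Signal values for the modified site across replicates.
#' @param y Signal values for unmodified T sites (sites x replicates).
#' @param alternative `"two.sided"` (default), `"greater"` (x exceeds y)
#'   or `"less"`.
#' @param exact_max Largest per-group size for which the exact
#'   distribution is enumerated.
#' @return A list with `p_value`, `statistic` (rank sum of `x`), `exact`.
#' @export
#' @examples
#' # complete separation, 3 vs 7: one-sided p = 1 / choose(10, 3)
#' replicate_rank_test(c(8, 9, 10), 1:7, alternative = "greater")$p_value
replicate_rank_test <- function(x, y,
                                alternative = c("two.sided", "greater", "less"),
                                exact_max = 12) {
  alternative <- match.arg(alternative)
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 values")
  if (any(is.na(c(x, y)))) stop("missing values not supported")
  w <- sum(rank(c(x, y))[seq_along(x)])
  if (length(x) <= exact_max && length(y) <= exact_max) {
    tails <- ranksum_tails(x, y)
    p <- switch(alternative,
                greater = tails$p_ge,
                less = tails$p_le,
                two.sided = min(1, 2 * min(tails$p_ge, tails$p_le)))
    list(p_value = p, statistic = w, exact = TRUE)
  } else {
    wt <- stats::wilcox.test(x, y, alternative = alternative,
                             exact = FALSE, correct = TRUE)
    list(p_value = wt$p.value, statistic = w, exact = FALSE)
  }
}
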