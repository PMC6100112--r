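# Independent oracles used across test files. These deliberately avoid the
# code paths they check: the hypergeometric tail is summed from explicit
# binomial coefficients, and the rank-sum distribution is enumerated over
# all group assignments.

# P(treated C >= tc) for the 2x2 table [[tc, tt], [cc, ct]] with fixed
# margins, by direct enumeration of the hypergeometric pmf.
hyper_tail_oracle <- function(tc, tt, cc, ct) {
  K <- tc + cc          # C reads in total
  n1 <- tc + tt         # treated reads
  N <- tc + tt + cc + ct
  xs <- max(0, K - (N - n1)):min(K, n1)
  pmf <- exp(lchoose(n1, xs) + lchoose(N - n1, K - xs) - lchoose(N, K))
  sum(pmf[xs >= tc])
}

# Exact rank-sum p-value by brute-force enumeration of all C(n, n1)
# assignments of the pooled values to the first group (midranks for ties).
ranksum_brute_oracle <- function(x, y,
                                 alternative = c("two.sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(n, n1)
  ws <- colSums(matrix(r[sets], nrow = n1))
  ge <- mean(ws >= w_obs - 1e-9)
  le <- mean(ws <= w_obs + 1e-9)
  switch(alternative, greater = ge, less = le,
         two.sided = min(1, 2 * min(ge, le)))
}

# Shared fixture: the two-site fully modified amplicon with its per-site
# rate presets.
odn1_fixture <- function(seed = 1) {
  odn <- make_odn("ODN1", seed = seed)
  odn$models <- list(conversion_preset("ODN1_site1"),
                     conversion_preset("ODN1_site2"))
  odn
}

# Random chromosome with planted fully modified sites, for genome-mode
# calling tests.
genome_fixture <- function(seed, length = 40000, n_true = 10) {
  withr::with_seed(seed, {
    chrom <- stats::setNames(
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = ""), "chr_sim")
    tp <- t_positions(chrom)
    truth <- sort(sample(tp, n_true))
    list(reference = chrom,
         profile = modification_profile("chr_sim", truth, "+", 1),
         t_positions = tp, truth = truth)
  })
}
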