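test_that("one-sided exact site test equals the hypergeometric oracle", {
  # spec'd edge cases
  expect_equal(site_test(0, 100, 0, 100), 1)
  expect_equal(site_test(0, 0, 0, 0), 1)
  expect_gt(site_test(5, 5, 5, 5), 0.5)
  expect_equal(site_test(5, 5, 5, 5), hyper_tail_oracle(5, 5, 5, 5))
  expect_equal(site_test(50, 50, 0, 100), hyper_tail_oracle(50, 50, 0, 100))
  expect_error(site_test(-1, 5, 5, 5), "non-negative")

  # randomised tables with margins up to 40
  withr::with_seed(42, {
    for (i in 1:300) {
      n1 <- sample(0:40, 1); n2 <- sample(0:40, 1)
      tc <- if (n1 > 0) sample(0:n1, 1) else 0
      cc <- if (n2 > 0) sample(0:n2, 1) else 0
      expect_equal(site_test(tc, n1 - tc, cc, n2 - cc),
                   hyper_tail_oracle(tc, n1 - tc, cc, n2 - cc),
                   tolerance = 1e-12)
    }
  })
})

test_that("BH adjustment reproduces the step-up procedure", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")

  withr::with_seed(7, {
    p <- runif(50)
    q <- bh_fdr(p)
    expect_gte(min(q), min(p))
    expect_true(all(q >= 0 & q <= 1))
    perm <- sample(50)
    expect_equal(bh_fdr(p[perm]), q[perm])  # permutation equivariance
  })
})

test_that("exact rank-sum test matches closed forms and brute enumeration", {
  # complete separation, 3 vs 7
  sep <- replicate_rank_test(c(8, 9, 10), 1:7, alternative = "greater")
  expect_true(sep$exact)
  expect_equal(sep$p_value, 1 / choose(10, 3))
  expect_equal(replicate_rank_test(c(8, 9, 10), 1:7)$p_value,
               2 / choose(10, 3))

  # groups equal as multisets
  expect_equal(replicate_rank_test(c(1, 2, 3), c(3, 1, 2))$p_value, 1)
  expect_equal(replicate_rank_test(c(5, 5), c(5, 5))$p_value, 1)
  expect_error(replicate_rank_test(1, c(1, 2)), "at least 2")

  # brute-force enumeration oracle, with and without ties
  withr::with_seed(13, {
    for (i in 1:25) {
      n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
      x <- sample(1:5, n1, replace = TRUE)   # replace=TRUE forces ties
      y <- sample(1:5, n2, replace = TRUE)
      for (alt in c("two.sided", "greater", "less"))
        expect_equal(replicate_rank_test(x, y, alternative = alt)$p_value,
                     ranksum_brute_oracle(x, y, alternative = alt))
    }
  })

  # tie-free case agrees with the reference exact implementation
  withr::with_seed(14, {
    x <- sample(1:100, 8); y <- sample(101:200, 9) / 2
    expect_equal(replicate_rank_test(x, y)$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
  })

  # large samples fall back to the tie-corrected normal approximation
  withr::with_seed(15, {
    x <- rnorm(30, 1); y <- rnorm(40)
    big <- replicate_rank_test(x, y)
    expect_false(big$exact)
    expect_equal(big$p_value,
                 stats::wilcox.test(x, y, exact = FALSE)$p.value)
  })
})

test_that("fold change is pseudocounted, unit at equality, monotone", {
  expect_equal(fold_change(10, 90, 10, 90), 1)
  expect_equal(fold_change(394, 504, 22, 973),
               (394.5 / 899) / (22.5 / 996))
  fc <- fold_change(c(10, 20, 30), 90, 5, 95)
  expect_true(all(diff(fc) > 0))
  expect_true(is.finite(fold_change(50, 50, 0, 100)))
})

test_that("site calling recovers planted sites and respects the FDR flag", {
  g <- genome_fixture(101)
  m <- conversion_preset("ODN1_site1")
  tr <- simulate_counts(g$reference, g$profile, m, depth = 100,
                        replicates = 3, "treated", seed = 55)
  ct <- simulate_counts(g$reference, g$profile, m, depth = 100,
                        replicates = 3, "control", seed = 55)
  calls <- call_sites(tr, ct, fdr = 0.1, min_depth = 100)
  expect_s3_class(calls, "site_calls")
  expect_false(is.unsorted(calls$pos0))
  expect_true(all(calls$q_value >= 0 & calls$q_value <= 1))
  expect_equal(calls$significant, calls$q_value < 0.1)

  sig_pos <- calls$pos0[calls$significant]
  expect_true(all(g$truth %in% sig_pos))           # full recovery
  fdp <- 1 - length(intersect(sig_pos, g$truth)) / max(1, length(sig_pos))
  expect_lte(fdp, 0.5)                             # no flood of false calls

  # lowering the threshold can only shrink the called set (nesting)
  strict <- call_sites(tr, ct, fdr = 0.01, min_depth = 100)
  expect_true(all(strict$pos0[strict$significant] %in% sig_pos))

  # treated identical to control: nothing is called
  null_calls <- call_sites(tr, tr, fdr = 0.1, min_depth = 100)
  expect_equal(sum(null_calls$significant), 0)
  expect_true(all(null_calls$p_value > 0.45))  # symmetric tables

  # a site present in only one condition is excluded, with a message
  expect_message(
    shorter <- call_sites(tr, ct[ct$pos0 != ct$pos0[1], ], min_depth = 100),
    "only one condition")
  expect_false(ct$pos0[1] %in% shorter$pos0)

  # depth screen: nothing passes an unreachable min_depth
  expect_equal(nrow(call_sites(tr, ct, min_depth = 1e6)), 0)
})

test_that("fully modified sites are always recovered at high depth", {
  # triplicates at 1000x with the amplicon presets: every level-1 site
  # must reach q < 0.1
  odn <- odn1_fixture()
  for (s in 1:5) {
    tr <- simulate_counts(odn$reference, odn$profile, odn$models,
                          depth = 1000, replicates = 3, "treated",
                          seed = 60 + s)
    ct <- simulate_counts(odn$reference, odn$profile, odn$models,
                          depth = 1000, replicates = 3, "control",
                          seed = 60 + s)
    calls <- call_sites(tr, ct, fdr = 0.1, min_depth = 100)
    expect_true(all(odn$profile$pos0 %in% calls$pos0[calls$significant]))
  }
})

test_that("null p-values are uniform or conservative", {
  # treated and control generated from the same background model
  g <- genome_fixture(103, length = 40000, n_true = 0)
  m <- conversion_preset("ODN1_site1")
  tr <- simulate_counts(g$reference, modification_profile(), m, depth = 100,
                        replicates = 1, "treated", seed = 71)
  ct <- simulate_counts(g$reference, modification_profile(), m, depth = 100,
                        replicates = 1, "control", seed = 72)
  p <- site_test(tr$n_C, tr$n_T, ct$n_C, ct$n_T)
  n <- length(p)
  expect_gt(n, 5000)
  for (t in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    # empirical cdf must not exceed the uniform beyond sampling error
    expect_lte(mean(p <= t), t + 3 * sqrt(t * (1 - t) / n))
  }
})
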