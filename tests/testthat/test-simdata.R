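test_that("ODN designs have the advertised structure and are reproducible", {
  odn1 <- make_odn("ODN1", seed = 1)
  expect_equal(nchar(odn1$reference[[1]]), 80)
  expect_equal(nrow(odn1$profile), 2)
  expect_true(all(odn1$profile$level == 1))
  # two modified plus exactly seven unmodified Ts
  expect_equal(length(t_positions(odn1$reference)), 9)
  expect_true(all(odn1$profile$pos0 %in% t_positions(odn1$reference)))

  # same seed, same output; different seed, different backbone
  expect_identical(make_odn("ODN1", seed = 1), odn1)
  expect_false(identical(make_odn("ODN1", seed = 2)$reference,
                         odn1$reference))

  odn2 <- make_odn("ODN2", seed = 3)
  expect_true(all(odn2$profile$level >= 0 & odn2$profile$level <= 0.26))
  expect_equal(make_odn("ODN2", seed = 3,
                        levels = c(0.05, 0.2))$profile$level, c(0.05, 0.2))
  expect_error(make_odn("ODN2", levels = c(1.5, 0)), "levels")

  expect_error(make_odn("ODN9"), "unknown model_id")
})

test_that("ODN3 variants enumerate all 16 trinucleotide contexts exactly once", {
  odn3 <- make_odn("ODN3", seed = 7)
  expect_length(odn3$reference, 16)
  expect_equal(nrow(odn3$profile), 16)
  ctx <- sub("^ODN3_", "", names(odn3$reference))
  expect_setequal(ctx, as.vector(outer(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T"), paste0)))
  expect_false(anyDuplicated(ctx) > 0)
  # names match the realised flanks around the modified T
  for (i in seq_along(odn3$reference)) {
    chars <- strsplit(odn3$reference[[i]], "")[[1]]
    p <- odn3$profile$pos0[i] + 1L
    expect_equal(chars[p], "T")
    expect_equal(paste0(chars[p - 1L], chars[p + 1L]), ctx[i])
  }
})

test_that("simulated counts conserve depth and follow the generative rates", {
  odn <- odn1_fixture()
  site1 <- odn$profile$pos0[1]
  cnt <- simulate_counts(odn$reference, odn$profile, odn$models,
                         depth = 500, replicates = 3, "treated", seed = 5)
  expect_true(all(cnt$n_T + cnt$n_C + cnt$n_other == cnt$depth))
  expect_identical(cnt,
                   simulate_counts(odn$reference, odn$profile, odn$models,
                                   depth = 500, replicates = 3, "treated",
                                   seed = 5))

  # law of large numbers against the generative rates at depth 1e6
  prof1 <- modification_profile(names(odn$reference), site1, "+", 1)
  m1 <- conversion_preset("ODN1_site1")
  big_t <- simulate_counts(odn$reference, prof1, m1, depth = 1e6,
                           replicates = 1, "treated", seed = 11)
  expect_lt(abs(big_t$n_C[big_t$pos0 == site1] / 1e6 - 0.394), 0.002)
  big_c <- simulate_counts(odn$reference, prof1, m1, depth = 1e6,
                           replicates = 1, "control", seed = 11)
  expect_lt(abs(big_c$n_C[big_c$pos0 == site1] / 1e6 - 0.022), 0.002)

  # zero background rate gives exactly zero C at unmodified sites
  m0 <- conversion_model(p_conv = 0.4, p_other_mod = 0.1,
                         p_bg_c = 0, p_bg_other = 0)
  z <- simulate_counts(odn$reference, modification_profile(), m0,
                       depth = 1000, replicates = 2, "treated", seed = 1)
  expect_true(all(z$n_C == 0))

  # a profile entry that does not address a T is rejected
  bad_pos <- which(strsplit(odn$reference[[1]], "")[[1]] != "T")[1] - 1L
  expect_error(
    simulate_counts(odn$reference,
                    modification_profile(names(odn$reference), bad_pos,
                                         "+", 1),
                    m1, depth = 10, replicates = 1, "treated"),
    "expected T")
})

test_that("expected conversion signal is monotone in incorporation level", {
  ref <- c(amp = "ACGACGACGATGACGACGACG")
  m <- conversion_preset("ODN1_site1")
  levels <- seq(0, 1, by = 0.1)
  fr <- vapply(seq_along(levels), function(i) {
    cnt <- simulate_counts(ref, modification_profile("amp", 10, "+",
                                                     levels[i]),
                           m, depth = 2e5, replicates = 1, "treated",
                           seed = 20 + i)
    cnt$n_C[cnt$pos0 == 10] / cnt$depth[cnt$pos0 == 10]
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
  # and the endpoints straddle the generative extremes
  expect_lt(abs(fr[1] - m$p_bg_c), 0.002)
  expect_lt(abs(fr[11] - m$p_conv), 0.005)
})

test_that("treated and control distributions coincide at unmodified sites", {
  ref <- c(amp = "ACGACGACGATGACGACGACG")
  m <- conversion_preset("ODN1_site1")
  prof0 <- modification_profile("amp", 10, "+", 0)  # level 0: unmodified
  tr <- simulate_counts(ref, prof0, m, depth = 500, replicates = 400,
                        "treated", seed = 31)
  ct <- simulate_counts(ref, prof0, m, depth = 500, replicates = 400,
                        "control", seed = 32)
  ks <- suppressWarnings(stats::ks.test(tr$n_C[tr$pos0 == 10],
                                        ct$n_C[ct$pos0 == 10]))
  expect_gt(ks$p.value, 0.001)
})

test_that("emitted reads realise the count table exactly", {
  odn <- odn1_fixture()
  cnt <- simulate_counts(odn$reference, odn$profile, odn$models,
                         depth = 200, replicates = 2, "treated", seed = 8)
  slice <- cnt[cnt$replicate == 1, , drop = FALSE]
  reads <- counts_to_reads(odn$reference, slice, seed = 4)
  expect_length(reads, 200)
  pile <- count_bases(reads, odn$reference)
  got <- pile[, c("pos0", "n_T", "n_C", "n_other")]
  want <- slice[, c("pos0", "n_T", "n_C", "n_other")]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)

  # deterministic limit: full conversion, no background, no other events
  m1 <- conversion_model(p_conv = 1, p_other_mod = 0, p_bg_c = 0,
                         p_bg_other = 0, p_ctrl_c = 0, p_ctrl_other = 0)
  prof1 <- odn$profile[1, , drop = FALSE]
  det <- simulate_counts(odn$reference, prof1, m1, depth = 100,
                         replicates = 1, "treated", seed = 2)
  reads1 <- counts_to_reads(odn$reference, det, seed = 2)
  site1 <- prof1$pos0 + 1L
  expect_true(all(substr(reads1, site1, site1) == "C"))
  other_t <- setdiff(t_positions(odn$reference), prof1$pos0) + 1L
  for (j in other_t) expect_true(all(substr(reads1, j, j) == "T"))
})

test_that("FASTQ emission writes full-length reads plus a matching truth BED", {
  odn <- odn1_fixture()
  cnt <- simulate_counts(odn$reference, odn$profile, odn$models,
                         depth = 50, replicates = 1, "treated", seed = 3)
  fq <- withr::local_tempfile(fileext = ".fastq")
  bed <- withr::local_tempfile(fileext = ".bed")
  emit_fastq(odn$reference, cnt, fq, profile = odn$profile, bed_path = bed,
             seed = 3)
  back <- read_fastq(fq)
  expect_length(back, 50)
  expect_true(all(nchar(back) == nchar(odn$reference[[1]])))
  truth <- read_bed(bed)
  expect_equal(nrow(truth), nrow(odn$profile))
  expect_equal(truth$start0, odn$profile$pos0)
  expect_equal(truth$end0, odn$profile$pos0 + 1L)
  expect_equal(truth$score, odn$profile$level * 1000)
  expect_error(emit_fastq(odn$reference, cnt, fq, read_length = 10),
               "full-length")
})

test_that("reverse-strand sites are simulated as A-to-G and piled up as such", {
  ref <- c(amp = "CCGACGACGAAGCCGACGACG")   # A at pos0 10, no other T/A scoring
  prof <- modification_profile("amp", 10, "-", 1)
  m <- conversion_preset("ODN1_site1")
  cnt <- simulate_counts(ref, prof, m, depth = 300, replicates = 1,
                         "treated", seed = 6)
  row <- cnt[cnt$pos0 == 10, ]
  expect_equal(row$refbase, "A")
  expect_equal(row$strand, "-")
  reads <- counts_to_reads(ref, cnt, seed = 6)
  # converted signal appears as G on the forward read
  expect_equal(sum(substr(reads, 11, 11) == "G"), row$n_C)
  pile <- count_bases(reads, ref, reverse_sites = 10)
  prow <- pile[pile$pos0 == 10, ]
  expect_equal(prow$n_C, row$n_C)
  expect_equal(prow$n_T, row$n_T)
  expect_equal(prow$n_other, row$n_other)
})
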