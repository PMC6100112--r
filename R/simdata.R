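# Deterministically derive a child seed from a top-level seed; keeps all
# randomness in a pipeline traceable to one integer while giving each
# stage/iteration an independent stream. Result stays inside 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %%
               2147483647)
}

BASES <- c("A", "C", "G", "T")

#' Generate a synthetic oligonucleotide (ODN) model
#'
#' Builds reference sequences and the matching ground-truth modification
#' profile for the three amplicon designs used to characterise the
#' chemistry:
#' \describe{
#'   \item{ODN1}{one 80-nt amplicon with two fully modified 5hmU sites
#'     (level 1) and exactly seven unmodified proximal Ts; all other
#'     positions are drawn from A/C/G so the T count is by design.}
#'   \item{ODN2}{same backbone with two 5hmU sites at sub-stoichiometric
#'     incorporation levels (default 0.26 and 0.13, configurable via
#'     `levels`, each in [0, 0.26] by design of the titration range).}
#'   \item{ODN3}{sixteen 41-nt variants sharing one backbone, each with a
#'     single fully modified 5hmU at the centre and flanking bases
#'     enumerating all (N1, N2) in \{A,C,G,T\}^2 — the 16 trinucleotide
#'     contexts N1-5hmU-N2.}
#' }
#'
#' @param model_id `"ODN1"`, `"ODN2"` or `"ODN3"`.
#' @param seed Integer seed; the same seed reproduces the same sequences.
#' @param levels For ODN2 only: numeric vector of length 2 of incorporation
#'   levels for the two sites.
#' @return A list with elements `reference` (named character vector of
#'   sequences) and `profile` (a [modification_profile()]).
#' @export
#' @examples
#' odn <- make_odn("ODN1", seed = 1)
#' nchar(odn$reference)
#' odn$profile
make_odn <- function(model_id, seed = 1, levels = c(0.26, 0.13)) {
  if (!is.character(model_id) || length(model_id) != 1L ||
      !model_id %in% c("ODN1", "ODN2", "ODN3"))
    stop("unknown model_id: must be one of 'ODN1', 'ODN2', 'ODN3'")
  withr::with_seed(derive_seed(seed, 1L), {
    if (model_id %in% c("ODN1", "ODN2")) {
      len <- 80L
      t_pos0 <- seq(7L, 71L, by = 8L)            # nine T sites, spaced
      mod_pos0 <- t_pos0[c(3L, 7L)]              # two modified, 7 plain Ts
      chars <- sample(c("A", "C", "G"), len, replace = TRUE)
      chars[t_pos0 + 1L] <- "T"
      refname <- paste0(model_id, "_amplicon")
      reference <- stats::setNames(paste(chars, collapse = ""), refname)
      lv <- if (model_id == "ODN1") c(1, 1) else {
        if (length(levels) != 2L || any(levels < 0 | levels > 1))
          stop("ODN2 'levels' must be two values in [0, 1]")
        levels
      }
      profile <- modification_profile(ref = refname, pos0 = mod_pos0,
                                      strand = "+", level = lv)
    } else {
      len <- 41L
      centre <- 20L                               # 0-based modified T
      backbone <- sample(c("A", "C", "G"), len, replace = TRUE)
      ctx <- expand.grid(N2 = BASES, N1 = BASES,
                         stringsAsFactors = FALSE)[, c("N1", "N2")]
      seqs <- vapply(seq_len(nrow(ctx)), function(i) {
        chars <- backbone
        chars[centre] <- ctx$N1[i]
        chars[centre + 1L] <- "T"
        chars[centre + 2L] <- ctx$N2[i]
        paste(chars, collapse = "")
      }, character(1))
      names(seqs) <- paste0("ODN3_", ctx$N1, ctx$N2)
      reference <- seqs
      profile <- modification_profile(ref = names(seqs),
                                      pos0 = rep(centre, 16L),
                                      strand = "+", level = 1)
    }
    validate_profile(profile, reference)
    list(reference = reference, profile = profile)
  })
}

# Effective (p_T, p_C, p_other) at one site for a condition/level/model.
site_rates <- function(level, model, condition, modified) {
  if (!modified || level == 0) {
    p_c <- model$p_bg_c; p_o <- model$p_bg_other
  } else if (condition == "treated") {
    p_c <- level * model$p_conv + (1 - level) * model$p_bg_c
    p_o <- level * model$p_other_mod + (1 - level) * model$p_bg_other
  } else {
    p_c <- level * model$p_ctrl_c + (1 - level) * model$p_bg_c
    p_o <- level * model$p_ctrl_other + (1 - level) * model$p_bg_other
  }
  c(T = 1 - p_c - p_o, C = p_c, other = p_o)
}

# All scored site coordinates for a set of references: every forward T,
# plus any reverse-strand (A) positions named in the profile.
scored_sites <- function(references, profile) {
  out <- lapply(names(references), function(rf) {
    chars <- strsplit(references[[rf]], "")[[1]]
    t_pos <- which(chars == "T") - 1L
    df <- data.frame(ref = rep(rf, length(t_pos)), pos0 = t_pos,
                     refbase = rep("T", length(t_pos)),
                     strand = rep("+", length(t_pos)),
                     stringsAsFactors = FALSE)
    rev <- profile[profile$ref == rf & profile$strand == "-", , drop = FALSE]
    if (nrow(rev) > 0)
      df <- rbind(df, data.frame(ref = rf, pos0 = rev$pos0, refbase = "A",
                                 strand = "-", stringsAsFactors = FALSE))
    df[order(df$pos0), , drop = FALSE]
  })
  do.call(rbind, out)
}

#' Simulate per-site base counts under the conversion model
#'
#' For every scored site (each T of the reference, plus configured
#' reverse-strand A sites) and each replicate, draws a trinomial
#' (T, C, other) readout of size `depth`. Modified sites use the
#' treated conversion rates only in the treated condition and the
#' no-oxidation control rates otherwise; unmodified Ts use background
#' rates in both conditions. Incorporation level `L` mixes conversion and
#' background rates as `L * p_conv + (1 - L) * p_bg_c`.
#'
#' @param reference Named character vector of reference sequences.
#' @param profile A [modification_profile()] of ground-truth 5hmU sites.
#' @param model A [conversion_model()], or a list of one model per profile
#'   entry (background rates for unmodified sites are taken from the first
#'   model).
#' @param depth Reads per site (fixed by default; Poisson-distributed with
#'   this mean when `depth_mode = "poisson"`).
#' @param replicates Number of technical replicates.
#' @param condition `"treated"` or `"control"`.
#' @param seed Integer seed; identical inputs and seed reproduce identical
#'   counts.
#' @param depth_mode `"fixed"` or `"poisson"`.
#' @return A data frame with one row per site and replicate: `ref`,
#'   `pos0`, `refbase`, `strand`, `condition`, `replicate`, `n_T`, `n_C`,
#'   `n_other`, `depth` (with `n_T + n_C + n_other == depth`).
#' @export
#' @examples
#' odn <- make_odn("ODN1", seed = 1)
#' cnt <- simulate_counts(odn$reference, odn$profile,
#'                        conversion_preset("ODN1_site1"),
#'                        depth = 1000, replicates = 3,
#'                        condition = "treated", seed = 1)
#' head(cnt)
simulate_counts <- function(reference, profile, model, depth, replicates,
                            condition = c("treated", "control"), seed = 1,
                            depth_mode = c("fixed", "poisson")) {
  condition <- match.arg(condition)
  depth_mode <- match.arg(depth_mode)
  stopifnot(depth >= 1, replicates >= 1)
  if (is.null(names(reference)))
    names(reference) <- paste0("ref", seq_along(reference))
  validate_profile(profile, reference)
  models <- if (inherits(model, "conversion_model")) {
    rep(list(model), max(1L, nrow(profile)))
  } else {
    if (!is.list(model) || length(model) != nrow(profile) ||
        !all(vapply(model, inherits, logical(1), "conversion_model")))
      stop("'model' must be a conversion_model or a list of one per profile entry")
    model
  }
  bg_model <- models[[1]]
  sites <- scored_sites(reference, profile)
  key <- paste(sites$ref, sites$pos0)
  mod_key <- paste(profile$ref, profile$pos0)
  mod_idx <- match(key, mod_key)             # NA for unmodified sites

  # per-site (p_C, p_other) under this condition
  rates <- vapply(seq_len(nrow(sites)), function(i) {
    mi <- mod_idx[i]
    pr <- if (is.na(mi)) site_rates(0, bg_model, condition, FALSE)
          else site_rates(profile$level[mi], models[[mi]], condition, TRUE)
    pr[c("C", "other")]
  }, numeric(2))

  n_sites <- nrow(sites)
  idx <- rep(seq_len(n_sites), each = replicates)   # site index per row
  p_c <- rates[1, idx]
  p_o <- rates[2, idx]
  withr::with_seed(derive_seed(seed, match(condition, c("treated", "control"))), {
    d <- if (depth_mode == "fixed") rep.int(as.integer(depth), length(idx))
         else stats::rpois(length(idx), depth)
    # trinomial (T, C, other) as two sequential binomials
    n_c <- stats::rbinom(length(idx), d, p_c)
    p_o_rest <- ifelse(p_c < 1, p_o / (1 - p_c), 0)
    n_o <- stats::rbinom(length(idx), d - n_c, pmin(p_o_rest, 1))
    data.frame(
      ref = sites$ref[idx], pos0 = sites$pos0[idx],
      refbase = sites$refbase[idx], strand = sites$strand[idx],
      condition = condition, replicate = rep(seq_len(replicates), n_sites),
      n_T = as.integer(d - n_c - n_o), n_C = as.integer(n_c),
      n_other = as.integer(n_o), depth = as.integer(d),
      stringsAsFactors = FALSE)
  })
}

#' Simulate a full treated + control experiment
#'
#' Convenience wrapper running [simulate_counts()] for both conditions
#' with a shared design (reference, truth, depth, replicates) as in the
#' triplicate-plus-control layout of the amplicon experiments.
#'
#' @inheritParams simulate_counts
#' @return An object of class `hmu_experiment`: a list with `reference`,
#'   `profile`, `model`, `counts` (both conditions row-bound), and `seed`.
#' @export
simulate_experiment <- function(reference, profile, model, depth,
                                replicates = 3, seed = 1,
                                depth_mode = "fixed") {
  counts <- rbind(
    simulate_counts(reference, profile, model, depth, replicates,
                    "treated", seed, depth_mode),
    simulate_counts(reference, profile, model, depth, replicates,
                    "control", seed, depth_mode))
  structure(list(reference = reference, profile = profile, model = model,
                 counts = counts, seed = seed),
            class = "hmu_experiment")
}

#' Materialise a count table as full-length amplicon reads
#'
#' Converts one replicate/condition slice of a simulated count table into
#' reads that are exact copies of the reference except at scored sites,
#' where exactly `n_C` reads carry the C-equivalent base and `n_other`
#' reads the other-equivalent base (read identity assignment is random).
#' On the forward strand the C signal is written as C and "other" as G;
#' at reverse-strand (A) sites the C signal is G and "other" is C. A
#' pileup of the emitted reads therefore reproduces the count table
#' exactly.
#'
#' @param reference A single reference sequence (named character of
#'   length 1).
#' @param counts Count-table rows for one reference, one condition, one
#'   replicate; all depths must be equal (fixed-depth amplicon mode).
#' @param seed Integer seed for read-assignment shuffling.
#' @return Character vector of reads, length equal to the shared depth.
#' @export
counts_to_reads <- function(reference, counts, seed = 1) {
  stopifnot(length(reference) == 1L)
  if (nrow(counts) == 0) stop("empty count table")
  if (length(unique(counts$ref)) != 1L ||
      length(unique(counts$condition)) != 1L ||
      length(unique(counts$replicate)) != 1L)
    stop("counts must be a single reference/condition/replicate slice")
  d <- unique(counts$depth)
  if (length(d) != 1L)
    stop("amplicon read emission requires equal depth at every site")
  chars <- strsplit(reference[[1]], "")[[1]]
  mat <- matrix(rep(chars, each = d), nrow = d)
  withr::with_seed(derive_seed(seed, 3L), {
    for (i in seq_len(nrow(counts))) {
      j <- counts$pos0[i] + 1L
      fwd <- counts$strand[i] == "+"
      ord <- sample.int(d)
      nc <- counts$n_C[i]; no <- counts$n_other[i]
      if (nc > 0) mat[ord[seq_len(nc)], j] <- if (fwd) "C" else "G"
      if (no > 0) mat[ord[nc + seq_len(no)], j] <- if (fwd) "G" else "C"
      if (fwd) mat[ord[seq(nc + no + 1, length.out = d - nc - no)], j] <- "T"
      else mat[ord[seq(nc + no + 1, length.out = d - nc - no)], j] <- "A"
    }
    apply(mat, 1, paste, collapse = "")
  })
}

#' Emit simulated reads as FASTQ (with truth BED)
#'
#' Writes full-length amplicon reads for one replicate/condition count
#' slice as a 4-line-record FASTQ with constant placeholder qualities,
#' and optionally the ground-truth modification BED (0-based half-open,
#' score = incorporation level x 1000).
#'
#' @inheritParams counts_to_reads
#' @param fastq_path Output FASTQ path.
#' @param profile Optional [modification_profile()]; when supplied with
#'   `bed_path`, the truth BED is written alongside.
#' @param bed_path Optional truth BED path.
#' @param read_length Read length; must equal the reference length
#'   (full-length amplicon reads).
#' @return Invisibly, the reads written.
#' @export
emit_fastq <- function(reference, counts, fastq_path, profile = NULL,
                       bed_path = NULL, read_length = nchar(reference[[1]]),
                       seed = 1) {
  if (read_length != nchar(reference[[1]]))
    stop("amplicon mode emits full-length reads: read_length must equal ",
         "the reference length (", nchar(reference[[1]]), ")")
  reads <- counts_to_reads(reference, counts, seed = seed)
  ids <- sprintf("%s_%s_rep%s_read%06d", counts$ref[1], counts$condition[1],
                 counts$replicate[1], seq_along(reads))
  write_fastq(reads, fastq_path, ids = ids)
  if (!is.null(bed_path)) {
    if (is.null(profile)) stop("profile required to write a truth BED")
    write_truth_bed(profile, bed_path)
  }
  invisible(reads)
}

#' Write a ground-truth modification BED
#'
#' One record per modified site, 0-based half-open (width 1), with the
#' incorporation level x 1000 in the score column.
#'
#' @param profile A [modification_profile()].
#' @param path Output BED path.
#' @export
write_truth_bed <- function(profile, path) {
  write_bed(data.frame(ref = profile$ref, start0 = profile$pos0,
                       end0 = profile$pos0 + 1L,
                       name = paste0("hmU_", profile$strand),
                       score = round(profile$level * 1000),
                       strand = profile$strand,
                       stringsAsFactors = FALSE), path)
  invisible(path)
}
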