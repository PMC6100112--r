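# Single-site titration reference: one T in an A/C/G backbone, so the
# modified site is the only scored position.
TITRATION_REF <- c(titration_amplicon = "ACGACGACGATGACGACGACG")
TITRATION_POS0 <- 10L

#' Titrate incorporation level against detection at fixed coverage
#'
#' Simulates a single 5hmU site at each incorporation level of a
#' titration series, in treated and no-oxidation control arms with
#' technical replicates, and asks at which level the site becomes
#' detectable at the assessed coverage. Detection at a level requires a
#' pseudocounted fold change of the conversion signal over the control
#' above `fc_threshold` AND a BH-adjusted one-sided exact test q-value
#' below `fdr` (adjustment across the levels of the series). The
#' detection limit is the smallest detected level. Mean treated
#' conversion signal is also regressed on level by ordinary least
#' squares, since the expected signal is affine in level under the
#' generative model.
#'
#' @param levels Sorted incorporation levels in [0, 1] (default 0 to 0.26
#'   in steps of 0.01, the range spanned by the titration amplicon).
#' @param model A [conversion_model()] (default the site-1 amplicon
#'   preset).
#' @param depth Reads per site per replicate (default 100, the assessed
#'   coverage).
#' @param replicates Technical replicates per arm (default 3).
#' @param seed Integer seed.
#' @param fc_threshold Fold-change cutoff for detection (default 2).
#' @param fdr BH q-value cutoff for detection (default 0.1).
#' @return An object of class `titration_result`: list with `table` (one
#'   row per level: mean/sd signal per arm, pooled counts, fold change,
#'   p, q, detected), `fit` (slope, intercept, r_squared of signal ~
#'   level), `detection_limit` (smallest detected level, `NA` if none),
#'   and the run parameters.
#' @export
titrate <- function(levels = seq(0, 0.26, by = 0.01),
                    model = conversion_preset("ODN1_site1"),
                    depth = 100, replicates = 3, seed = 1,
                    fc_threshold = 2, fdr = 0.1) {
  stopifnot(depth >= 1, replicates >= 1)
  if (any(levels < 0 | levels > 1)) stop("levels must lie in [0, 1]")
  if (is.unsorted(levels, strictly = FALSE)) stop("levels must be sorted")
  if (length(unique(levels)) < 2)
    stop("linear fit needs at least 2 distinct levels")
  rows <- lapply(seq_along(levels), function(i) {
    lv <- levels[i]
    prof <- modification_profile(ref = names(TITRATION_REF),
                                 pos0 = TITRATION_POS0, level = lv)
    sd_i <- derive_seed(seed, 100L + i)
    tr <- simulate_counts(TITRATION_REF, prof, model, depth, replicates,
                          "treated", seed = sd_i)
    ct <- simulate_counts(TITRATION_REF, prof, model, depth, replicates,
                          "control", seed = sd_i)
    tr <- site_signal(tr[tr$pos0 == TITRATION_POS0, ])
    ct <- site_signal(ct[ct$pos0 == TITRATION_POS0, ])
    data.frame(
      level = lv,
      treated_mean = mean(tr$c_over_ct), treated_sd = stats::sd(tr$c_over_ct),
      control_mean = mean(ct$c_over_ct), control_sd = stats::sd(ct$c_over_ct),
      n_C_treated = sum(tr$n_C), n_T_treated = sum(tr$n_T),
      n_C_control = sum(ct$n_C), n_T_control = sum(ct$n_T))
  })
  tab <- do.call(rbind, rows)
  tab$fold_change <- fold_change(tab$n_C_treated, tab$n_T_treated,
                                 tab$n_C_control, tab$n_T_control)
  tab$p_value <- site_test(tab$n_C_treated, tab$n_T_treated,
                           tab$n_C_control, tab$n_T_control)
  tab$q_value <- bh_fdr(tab$p_value)
  tab$detected <- tab$fold_change > fc_threshold & tab$q_value < fdr
  fit <- stats::lm(treated_mean ~ level, data = tab)
  detection_limit <- if (any(tab$detected)) min(tab$level[tab$detected])
                     else NA_real_
  structure(list(
    table = tab,
    fit = list(slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = summary(fit)$r.squared),
    detection_limit = detection_limit,
    params = list(depth = depth, replicates = replicates, seed = seed,
                  fc_threshold = fc_threshold, fdr = fdr)),
    class = "titration_result")
}

#' Distribution of the detection limit over simulation seeds
#'
#' The detection limit at low coverage is a stochastic quantity; this
#' repeats [titrate()] over independent seeds and reports the full
#' distribution together with its mode (smallest level among modal ties;
#' runs in which no level was detected are tallied separately).
#'
#' @inheritParams titrate
#' @param n_seeds Number of independent titration runs.
#' @return List with `limits` (per-seed detection limits, `NA` when
#'   undetected), `modal` (modal detection limit) and `n_undetected`.
#' @export
detection_limit_scan <- function(n_seeds = 200, seed = 1,
                                 levels = seq(0, 0.26, by = 0.01),
                                 model = conversion_preset("ODN1_site1"),
                                 depth = 100, replicates = 3,
                                 fc_threshold = 2, fdr = 0.1) {
  limits <- vapply(seq_len(n_seeds), function(s) {
    titrate(levels = levels, model = model, depth = depth,
            replicates = replicates, seed = derive_seed(seed, 1000L + s),
            fc_threshold = fc_threshold, fdr = fdr)$detection_limit
  }, numeric(1))
  finite <- limits[!is.na(limits)]
  modal <- if (length(finite) == 0) NA_real_ else {
    tb <- table(finite)
    min(as.numeric(names(tb)[tb == max(tb)]))
  }
  list(limits = limits, modal = modal, n_undetected = sum(is.na(limits)))
}

#' Simulate the 16-context trinucleotide experiment
#'
#' Generates the ODN3-style experiment: sixteen amplicons whose flanking
#' bases realise every N1-5hmU-N2 trinucleotide context around one fully
#' modified site, simulated in treated and control arms. Optional
#' per-context multipliers on the conversion rate let the analysis be
#' exercised under context bias (default: context-uniform rates).
#'
#' @param model Base [conversion_model()].
#' @param depth Reads per site per replicate.
#' @param replicates Technical replicates per arm.
#' @param seed Integer seed.
#' @param multipliers Optional named numeric vector (names like `"GG"`)
#'   multiplying `p_conv` for specific contexts; contexts not named keep
#'   multiplier 1.
#' @return An `hmu_experiment` with a `contexts` element mapping each
#'   reference to its (N1, N2) pair.
#' @export
simulate_context <- function(model = conversion_preset("ODN1_site1"),
                             depth = 1000, replicates = 3, seed = 1,
                             multipliers = NULL) {
  odn <- make_odn("ODN3", seed = seed)
  ctx <- sub("^ODN3_", "", names(odn$reference))
  mult <- stats::setNames(rep(1, 16), ctx)
  if (!is.null(multipliers)) {
    if (is.null(names(multipliers)) ||
        !all(names(multipliers) %in% ctx))
      stop("multipliers must be named by context, e.g. c(GG = 2)")
    mult[names(multipliers)] <- multipliers
  }
  counts <- lapply(seq_along(odn$reference), function(i) {
    m <- model
    m$p_conv <- min(model$p_conv * mult[[ctx[i]]], 1 - model$p_other_mod)
    refname <- names(odn$reference)[i]
    prof <- odn$profile[odn$profile$ref == refname, , drop = FALSE]
    ref_i <- odn$reference[i]
    sd_i <- derive_seed(seed, 200L + i)
    rbind(simulate_counts(ref_i, prof, m, depth, replicates, "treated",
                          seed = sd_i),
          simulate_counts(ref_i, prof, m, depth, replicates, "control",
                          seed = sd_i))
  })
  structure(list(reference = odn$reference, profile = odn$profile,
                 model = model, counts = do.call(rbind, counts),
                 seed = seed,
                 contexts = data.frame(ref = names(odn$reference),
                                       N1 = substr(ctx, 1, 1),
                                       N2 = substr(ctx, 2, 2),
                                       stringsAsFactors = FALSE)),
            class = "hmu_experiment")
}

#' Per-trinucleotide-context conversion signal and detectability
#'
#' Summarises an ODN3-style experiment into the 16-row context table:
#' pooled conversion signal `%C/(C+T)` at the modified site for each
#' N1-5hmU-N2 context in both arms, with a detectability flag using the
#' same rule as [titrate()] (fold change above threshold and BH q below
#' `fdr`, adjusted across the 16 contexts).
#'
#' @param experiment An `hmu_experiment` from [simulate_context()], or
#'   `NULL` if `treated`/`control`/`contexts` are given directly.
#' @param treated,control Count data frames restricted to the modified
#'   sites (used when `experiment` is `NULL`).
#' @param contexts Data frame with columns `ref`, `N1`, `N2` mapping
#'   references to contexts (used when `experiment` is `NULL`).
#' @param profile Modified-site profile matching `treated`/`control`.
#' @param fc_threshold,fdr Detection rule thresholds.
#' @return A data frame of class `context_table` with exactly 16 rows:
#'   `N1`, `N2`, `treated_signal`, `control_signal`, `fold_change`,
#'   `p_value`, `q_value`, `detected`.
#' @export
context_signal <- function(experiment = NULL, treated = NULL,
                           control = NULL, contexts = NULL, profile = NULL,
                           fc_threshold = 2, fdr = 0.1) {
  if (!is.null(experiment)) {
    stopifnot(inherits(experiment, "hmu_experiment"))
    contexts <- experiment$contexts
    profile <- experiment$profile
    treated <- experiment$counts[experiment$counts$condition == "treated", ]
    control <- experiment$counts[experiment$counts$condition == "control", ]
  }
  if (is.null(contexts) || is.null(profile))
    stop("need an experiment, or treated/control/contexts/profile")
  want <- expand.grid(N2 = BASES, N1 = BASES,
                      stringsAsFactors = FALSE)[, c("N1", "N2")]
  have <- paste0(contexts$N1, contexts$N2)
  missing_ctx <- setdiff(paste0(want$N1, want$N2), have)
  if (length(missing_ctx) > 0)
    stop("missing trinucleotide context(s): ",
         paste(missing_ctx, collapse = ", "))
  site_key <- paste(profile$ref, profile$pos0)
  pool_site <- function(x, rf) {
    z <- x[x$ref == rf & paste(x$ref, x$pos0) %in% site_key, , drop = FALSE]
    if (nrow(z) == 0) stop("no modified-site counts for reference '", rf, "'")
    c(n_C = sum(z$n_C), n_T = sum(z$n_T))
  }
  rows <- lapply(seq_len(nrow(contexts)), function(i) {
    rf <- contexts$ref[i]
    tp <- pool_site(treated, rf); cp <- pool_site(control, rf)
    data.frame(N1 = contexts$N1[i], N2 = contexts$N2[i],
               treated_signal = tp["n_C"] / (tp["n_C"] + tp["n_T"]),
               control_signal = cp["n_C"] / (cp["n_C"] + cp["n_T"]),
               n_C_treated = tp[["n_C"]], n_T_treated = tp[["n_T"]],
               n_C_control = cp[["n_C"]], n_T_control = cp[["n_T"]],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$fold_change <- fold_change(tab$n_C_treated, tab$n_T_treated,
                                 tab$n_C_control, tab$n_T_control)
  tab$p_value <- site_test(tab$n_C_treated, tab$n_T_treated,
                           tab$n_C_control, tab$n_T_control)
  tab$q_value <- bh_fdr(tab$p_value)
  tab$detected <- tab$fold_change > fc_threshold & tab$q_value < fdr
  tab <- tab[order(tab$N1, tab$N2), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("context_table", "data.frame")
  tab
}
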