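#' Configuration for a two-sample MR analysis
#'
#' @param exposure_p_threshold Genome-wide significance threshold on the
#'   exposure association used to select instruments (default 5e-8).
#' @param instrument_r2 r-squared bound for instrument independence
#'   (default 0.8; the stricter sensitivity setting is 0.2).
#' @param exclusion_trait Optional trait id: instruments associated with
#'   this secondary trait are removed after pruning.
#' @param exclusion_p Nominal threshold for the exclusion (0.05 or 0.01);
#'   required iff `exclusion_trait` is given.
#' @param delta_order `"second"` (default) or `"first"` order delta-method
#'   standard error for the Wald ratio.
#' @return A list of class `mr_config`.
#' @export
mr_config <- function(exposure_p_threshold = 5e-8, instrument_r2 = 0.8,
                      exclusion_trait = NULL, exclusion_p = NULL,
                      delta_order = c("second", "first")) {
  delta_order <- match.arg(delta_order)
  stopifnot(exposure_p_threshold > 0, exposure_p_threshold < 1,
            instrument_r2 > 0, instrument_r2 <= 1)
  if (is.null(exclusion_trait) != is.null(exclusion_p))
    stop("exclusion_trait and exclusion_p must be given together")
  if (!is.null(exclusion_p))
    stopifnot(exclusion_p > 0, exclusion_p < 1)
  structure(list(exposure_p_threshold = exposure_p_threshold,
                 instrument_r2 = instrument_r2,
                 exclusion_trait = exclusion_trait,
                 exclusion_p = exclusion_p, delta_order = delta_order),
            class = "mr_config")
}

#' Per-SNP Wald ratio with delta-method standard error
#'
#' The instrumental-variable estimate for one SNP: the SNP-outcome effect
#' divided by the SNP-exposure effect. The standard error is the delta-method
#' approximation for a ratio of independent estimates (zero cross-covariance,
#' as in the two-sample setting): first order `sy/|bx|`, second order
#' `sqrt(sy^2/bx^2 + by^2 sx^2/bx^4)`.
#'
#' @param bx,sx Exposure effect and standard error (`sx > 0`; `sx = 0`
#'   accepted as the exact-exposure limit).
#' @param by,sy Outcome effect and standard error (`sy > 0`).
#' @param order `"second"` (default) or `"first"`.
#' @return List with `ratio`, `se` and `weight` (1/se^2). Vectorized over
#'   its first four arguments.
#' @export
wald_ratio <- function(bx, sx, by, sy, order = c("second", "first")) {
  order <- match.arg(order)
  if (any(bx == 0)) stop("undefined instrument: exposure beta is zero")
  if (any(sy <= 0) || any(sx < 0)) stop("standard errors must be positive")
  ratio <- by / bx
  se <- if (order == "first") sy / abs(bx)
        else sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  list(ratio = ratio, se = se, weight = 1 / se^2)
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Pools estimates with weights `w = 1/se^2`: pooled beta is the weighted
#' mean, pooled SE is `1/sqrt(sum w)`, and the P value is the two-sided
#' normal tail of beta/se.
#'
#' @param beta Numeric vector of estimates.
#' @param se Positive numeric vector of standard errors.
#' @return List with `beta`, `se`, `z`, `pvalue`.
#' @export
pool_fixed_effects <- function(beta, se) {
  if (length(beta) == 0L) stop("no estimates to pool")
  stopifnot(length(beta) == length(se), all(se > 0))
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  z <- b / s
  list(beta = b, se = s, z = z, pvalue = 2 * stats::pnorm(-abs(z)))
}

#' Select MR instruments from a harmonized panel
#'
#' Filters exposure associations at `exposure_p_threshold`, prunes to
#' pairwise independence at `instrument_r2` (keeping the smallest exposure
#' P per correlated group), then, if configured, removes instruments
#' associated with the exclusion trait at `exclusion_p`. The exclusion is
#' applied after pruning and does not trigger re-selection of replacement
#' instruments. SNPs flagged as zero-exposure are never selected.
#'
#' @param panel A [build_panel()] result.
#' @param ld An [ld_table()].
#' @param config An [mr_config()].
#' @return List with `instruments` (SNP ids), `n_excluded` (removed by the
#'   exclusion trait) and `n_candidates` (significant before pruning).
#' @export
select_instruments <- function(panel, ld, config = mr_config()) {
  stopifnot(inherits(panel, "harmonized_panel"))
  expo <- panel_trait(panel, panel$exposure, with_positions = TRUE)
  usable <- !panel$snps$zero_exposure[match(expo$snp_id, panel$snps$snp_id)]
  sig <- expo[usable & expo$pvalue < config$exposure_p_threshold, ]
  if (nrow(sig) == 0L)
    stop("no instruments: no exposure association passes P < ",
         format(config$exposure_p_threshold))
  kept <- prune_independent(sig, ld, r2_threshold = config$instrument_r2)
  n_excluded <- 0L
  if (!is.null(config$exclusion_trait)) {
    excl <- panel_trait(panel, config$exclusion_trait)
    p <- excl$pvalue[match(kept, excl$snp_id)]
    drop <- !is.na(p) & p < config$exclusion_p
    n_excluded <- sum(drop)
    kept <- kept[!drop]
    if (length(kept) == 0L)
      stop("no instruments: all removed by the ", config$exclusion_trait,
           " exclusion at P < ", config$exclusion_p)
  }
  list(instruments = kept, n_excluded = n_excluded,
       n_candidates = nrow(sig))
}

#' Two-sample Mendelian randomization of one outcome on the exposure
#'
#' Runs the full ratio procedure: instrument selection
#' ([select_instruments()]), per-instrument Wald ratios ([wald_ratio()]),
#' and fixed-effects pooling ([pool_fixed_effects()]). Instruments without
#' an outcome cell are dropped and counted. For binary outcomes the pooled
#' log-odds estimate is also reported as an odds ratio with 95% CI.
#'
#' @param panel A [build_panel()] result (exposure-raising orientation).
#' @param ld An [ld_table()].
#' @param outcome_trait Trait id of the outcome.
#' @param config An [mr_config()].
#' @return An object of class `mr_result`: pooled beta/se/CI/P, odds ratio
#'   fields when the outcome is binary, instrument counts, and the per-SNP
#'   ratio table in `$estimates`.
#' @export
run_mr <- function(panel, ld, outcome_trait, config = mr_config()) {
  sel <- select_instruments(panel, ld, config)
  expo <- panel_trait(panel, panel$exposure)
  outc <- panel_trait(panel, outcome_trait)
  ex <- expo[match(sel$instruments, expo$snp_id), ]
  oy <- outc[match(sel$instruments, outc$snp_id), ]
  have <- !is.na(oy$beta) & !is.na(oy$se)
  n_missing <- sum(!have)
  if (!any(have))
    stop("no instrument has a ", outcome_trait, " association cell")
  ex <- ex[have, ]; oy <- oy[have, ]
  iv <- wald_ratio(ex$beta, ex$se, oy$beta, oy$se,
                   order = config$delta_order)
  pooled <- pool_fixed_effects(iv$ratio, iv$se)
  zc <- stats::qnorm(0.975)
  ci <- c(pooled$beta - zc * pooled$se, pooled$beta + zc * pooled$se)
  binary <- panel$traits[[outcome_trait]]$kind == "binary"
  res <- list(
    exposure = panel$exposure, outcome = outcome_trait,
    beta = pooled$beta, se = pooled$se, ci95 = ci, pvalue = pooled$pvalue,
    odds_ratio = if (binary) exp(pooled$beta) else NULL,
    or_ci95 = if (binary) exp(ci) else NULL,
    n_snps_used = nrow(ex), n_snps_excluded = sel$n_excluded,
    n_snps_missing_outcome = n_missing,
    estimates = data.frame(snp_id = ex$snp_id, bx = ex$beta, sx = ex$se,
                           by = oy$beta, sy = oy$se, ratio = iv$ratio,
                           se = iv$se, weight = iv$weight,
                           stringsAsFactors = FALSE),
    config = config)
  class(res) <- "mr_result"
  res
}

#' @export
print.mr_result <- function(x, digits = 4, ...) {
  cat(sprintf("Mendelian randomization: %s -> %s (%d instruments",
              x$exposure, x$outcome, x$n_snps_used))
  if (x$n_snps_excluded > 0)
    cat(sprintf(", %d excluded via %s", x$n_snps_excluded,
                x$config$exclusion_trait))
  cat(")\n")
  cat(sprintf("  causal estimate %s (95%% CI %s, %s), P = %s\n",
              signif(x$beta, digits), signif(x$ci95[1], digits),
              signif(x$ci95[2], digits), format(x$pvalue, digits = 3)))
  if (!is.null(x$odds_ratio))
    cat(sprintf("  causal OR %s (95%% CI %s, %s)\n",
                signif(x$odds_ratio, digits), signif(x$or_ci95[1], digits),
                signif(x$or_ci95[2], digits)))
  invisible(x)
}
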