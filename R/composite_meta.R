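#' Configuration for the glycemic burden composite
#'
#' @param traits Ordered character vector of trait ids to combine (>= 2).
#'   Order matters: redundancy screening retains the earliest trait of any
#'   highly correlated pair.
#' @param scheme `"stderr"` (inverse-variance meta-analysis of betas and
#'   SEs, the default) or `"samplesize"` (sqrt-N weighted Z scores; useful
#'   because the contributing traits are on different unit scales).
#' @param tau_exclusion_threshold Kendall-tau threshold at or above which a
#'   later trait is excluded as redundant (default 0.75).
#' @param significance_threshold Per-SNP significance threshold reported for
#'   the composite (default 5e-8).
#' @param screen_max_snps Cap on SNPs used to estimate pairwise tau
#'   (deterministic thinning; tau is O(n^2) to compute and a few thousand
#'   SNPs estimate it to ~0.02).
#' @return A list of class `composite_config`.
#' @export
composite_config <- function(traits, scheme = c("stderr", "samplesize"),
                             tau_exclusion_threshold = 0.75,
                             significance_threshold = 5e-8,
                             screen_max_snps = 5000L) {
  scheme <- match.arg(scheme)
  stopifnot(length(traits) >= 2, tau_exclusion_threshold > 0,
            tau_exclusion_threshold <= 1, significance_threshold > 0,
            significance_threshold <= 1)
  structure(list(traits = as.character(traits), scheme = scheme,
                 tau_exclusion_threshold = tau_exclusion_threshold,
                 significance_threshold = significance_threshold,
                 screen_max_snps = as.integer(screen_max_snps)),
            class = "composite_config")
}

#' Inverse-variance meta-analysis of betas and standard errors
#'
#' The same fixed-effects kernel as [pool_fixed_effects()], returned with
#' its Z score.
#'
#' @param betas,ses Equal-length numeric vectors (>= 1 pair, ses > 0).
#' @return List with `beta`, `se`, `z`, `pvalue`.
#' @export
meta_stderr <- function(betas, ses) {
  pooled <- pool_fixed_effects(betas, ses)
  pooled[c("beta", "se", "z", "pvalue")]
}

#' Sample-size-weighted Z-score meta-analysis
#'
#' `z = sum(sqrt(n_i) z_i) / sqrt(sum n_i)`, two-sided normal P.
#'
#' @param zs,ns Equal-length numeric vectors (>= 1 pair, ns > 0).
#' @return List with `z`, `pvalue`.
#' @export
meta_samplesize <- function(zs, ns) {
  if (length(zs) == 0L) stop("no studies to combine")
  stopifnot(length(zs) == length(ns), all(ns > 0))
  z <- sum(sqrt(ns) * zs) / sqrt(sum(ns))
  list(z = z, pvalue = 2 * stats::pnorm(-abs(z)))
}

#' Kendall rank correlation (tau-b) over complete pairs
#'
#' Tie-corrected tau; observations where either vector is missing are
#' dropped.
#'
#' @param x,y Equal-length numeric vectors with >= 2 complete pairs.
#' @return Tau in \[-1, 1\].
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !(is.na(x) | is.na(y))
  if (sum(ok) < 2L) stop("fewer than 2 complete pairs")
  stats::cor(x[ok], y[ok], method = "kendall")
}

#' Genomic-control inflation factor
#'
#' `lambda = median(z^2) / 0.4549364`, the median chi-square(1) under the
#' null; values well above 1 indicate inflation of the test statistics.
#'
#' @param zs Numeric vector of Z scores (NAs dropped).
#' @return Lambda (positive scalar).
#' @export
genomic_lambda <- function(zs) {
  zs <- zs[!is.na(zs)]
  if (length(zs) == 0L) stop("no Z scores")
  stats::median(zs^2) / stats::qchisq(0.5, df = 1)
}

#' Screen traits for rank-correlation redundancy
#'
#' Computes pairwise Kendall tau between the traits' Z-score vectors over
#' shared SNPs, then walks the traits in config order: a trait is excluded
#' when its |tau| with any earlier retained trait is at or above the
#' threshold. This reproduces the removal of near-duplicate traits (e.g.
#' HOMA indices derived from fasting insulin) that would otherwise count
#' the same individuals several times and inflate the composite.
#'
#' @param z_by_trait Numeric matrix of Z scores, rows = SNPs, columns =
#'   traits in config order (e.g. from [panel_matrix()]).
#' @param config A [composite_config()].
#' @return List of class `screen_report`: `tau` (symmetric matrix with unit
#'   diagonal), `retained`, `excluded`, and `triggers` (data frame of
#'   excluded trait, partner trait, tau).
#' @export
screen_traits <- function(z_by_trait, config) {
  traits <- config$traits
  stopifnot(all(traits %in% colnames(z_by_trait)))
  z <- z_by_trait[, traits, drop = FALSE]
  if (nrow(z) > config$screen_max_snps) {
    idx <- unique(round(seq(1, nrow(z), length.out = config$screen_max_snps)))
    z <- z[idx, , drop = FALSE]
  }
  k <- length(traits)
  tau <- diag(1, k)
  dimnames(tau) <- list(traits, traits)
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    tau[i, j] <- tau[j, i] <- kendall_tau(z[, i], z[, j])
  }
  retained <- character(0)
  triggers <- data.frame(excluded = character(0), partner = character(0),
                         tau = numeric(0), stringsAsFactors = FALSE)
  for (t in traits) {
    hit <- retained[abs(tau[t, retained]) >= config$tau_exclusion_threshold]
    if (length(hit)) {
      worst <- hit[which.max(abs(tau[t, hit]))]
      triggers <- rbind(triggers, data.frame(
        excluded = t, partner = worst, tau = tau[t, worst],
        stringsAsFactors = FALSE))
    } else retained <- c(retained, t)
  }
  structure(list(tau = tau, retained = retained,
                 excluded = triggers$excluded, triggers = triggers),
            class = "screen_report")
}

#' Build the multi-trait glycemic burden composite
#'
#' Screens the configured traits for redundancy ([screen_traits()]), then
#' meta-analyzes each SNP across the retained traits (every SNP with at
#' least one retained-trait cell contributes; the number of contributing
#' traits is recorded). The genomic-control lambda of the resulting Z set
#' and the count of SNPs below the significance threshold are reported.
#'
#' @param panel A [build_panel()] result containing the composite traits.
#' @param config A [composite_config()].
#' @param screen Set `FALSE` to skip redundancy screening (all configured
#'   traits contribute); used to quantify the inflation a redundant trait
#'   causes.
#' @return An object of class `composite_result`: `snps` (per-SNP beta/se
#'   under the stderr scheme, z, pvalue, n_traits), `lambda_gc`, `screen`
#'   (report or NULL), `n_significant`, and the config.
#' @export
build_composite <- function(panel, config, screen = TRUE) {
  stopifnot(inherits(panel, "harmonized_panel"),
            inherits(config, "composite_config"))
  missing_traits <- setdiff(config$traits, names(panel$traits))
  if (length(missing_traits))
    stop("traits absent from panel: ", paste(missing_traits, collapse = ", "))
  screen_report <- NULL
  traits <- config$traits
  if (isTRUE(screen)) {
    screen_report <- screen_traits(panel_matrix(panel, "z", traits), config)
    traits <- screen_report$retained
    if (length(traits) == 0L)
      stop("all composite traits were screened out as redundant")
  }
  cells <- panel$cells[panel$cells$trait_id %in% traits, ]
  ids <- panel$snps$snp_id
  idx <- match(cells$snp_id, ids)
  acc <- function(v) { # per-SNP sums aligned to ids, empty SNPs = 0
    out <- numeric(length(ids))
    t <- rowsum(v, idx)
    out[as.integer(rownames(t))] <- t[, 1]
    out
  }
  if (config$scheme == "stderr") {
    w <- 1 / cells$se^2
    sw <- acc(w)
    beta <- acc(w * cells$beta) / sw
    se <- 1 / sqrt(sw)
    z <- beta / se
  } else {
    zi <- cells$beta / cells$se
    sn <- acc(cells$n)
    z <- acc(sqrt(cells$n) * zi) / sqrt(sn)
    beta <- rep(NA_real_, length(z))
    se <- rep(NA_real_, length(z))
  }
  n_traits <- acc(rep(1, nrow(cells)))
  has <- n_traits > 0
  snps <- data.frame(snp_id = ids, beta = beta, se = se, z = z,
                     pvalue = 2 * stats::pnorm(-abs(z)),
                     n_traits_contributing = n_traits,
                     stringsAsFactors = FALSE)[has, ]
  rownames(snps) <- NULL
  structure(list(snps = snps,
                 lambda_gc = genomic_lambda(snps$z),
                 screen = screen_report,
                 n_significant = sum(snps$pvalue <
                                       config$significance_threshold),
                 traits_used = traits, config = config),
            class = "composite_result")
}

#' @export
print.composite_result <- function(x, ...) {
  cat(sprintf(
    "Glycemic burden composite (%s scheme): %d SNPs over traits %s\n",
    x$config$scheme, nrow(x$snps), paste(x$traits_used, collapse = ", ")))
  if (!is.null(x$screen) && length(x$screen$excluded))
    cat("  screened out: ", paste(x$screen$excluded, collapse = ", "), "\n")
  cat(sprintf("  genomic-control lambda = %.3f; %d SNPs at P < %s\n",
              x$lambda_gc, x$n_significant,
              format(x$config$significance_threshold)))
  invisible(x)
}
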