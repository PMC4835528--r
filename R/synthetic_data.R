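#' Configuration for the synthetic summary-statistics generator
#'
#' Defaults describe the study conditions the pipeline targets: GWAS-scale
#' sample sizes (exposure 95,454; CAD 63,746/130,681; T2D 34,840/114,981;
#' MAGIC-like glycemic trait sizes), a planted causal effect of the exposure
#' on CAD of log(1.63) and on T2D of log(0.86) per SD of exposure, and
#' per-SNP exposure effects realistic for genome-wide-significant lipid loci.
#'
#' LD is emulated at the summary-statistic level: SNPs come in blocks with
#' exchangeable allelic correlation `within_block_rho` (the emitted r2 table
#' holds rho^2), marginal true effects are LD-smeared sums of the block's
#' joint effects, and estimation noise is exchangeably correlated within a
#' block. Each block is one gene/locus carrying a planted label: a
#' `neutral_candidate` block has exposure (and hence outcome) signal but no
#' glycemic signal, a `glycemic_liability` block additionally loads on the
#' glycemic traits, and a `null` block has no signal at all.
#'
#' @param n_snps,n_blocks Panel size and number of LD blocks (= loci).
#' @param within_block_rho Exchangeable allelic correlation r within a
#'   block, in \[0, 1); the LD table is emitted as r^2.
#' @param maf_range Uniform range for minor-allele frequencies.
#' @param causal_fraction Fraction of SNPs in non-null blocks with a
#'   nonzero joint exposure effect (at least one per non-null block).
#'   Liability blocks additionally carry a glycemic signal on every member
#'   SNP (a dense architecture emulating tight local LD with a shared
#'   causal glycemic variant, the pattern seen at statin-target loci).
#' @param exposure_effect_sd SD of nonzero joint exposure effects, in SD
#'   units of the exposure trait.
#' @param theta_cad,theta_t2d True causal effects of the exposure on the
#'   binary outcomes, log-odds per SD.
#' @param pleiotropy_fraction,pleiotropy_sd Fraction of SNPs with a direct
#'   (exposure-bypassing) outcome effect and its SD.
#' @param glycemic_traits Named list of glycemic traits; each element a list
#'   with `n` (sample size) and `loading` (scale of the shared glycemic
#'   signal in that trait's units).
#' @param glycemic_effect_sd SD of the shared per-SNP glycemic signal (units
#'   of a loading-1 trait) planted in liability blocks.
#' @param t2d_glycemic_loading Loading of the glycemic signal on T2D
#'   log-odds (liability blocks also raise T2D association).
#' @param duplicate_trait_of Optional trait id to duplicate (emulating a
#'   HOMA-style derived trait measured on the same individuals); the
#'   duplicate's Z vector is the base trait's plus noise.
#' @param duplicate_trait_id Name of the duplicated trait.
#' @param duplicate_noise_sd SD of the Z-scale noise added to the duplicate
#'   (0.1 gives Kendall tau about 0.94 with the base trait).
#' @param n_exposure Exposure GWAS sample size.
#' @param n_cases_cad,n_controls_cad,n_cases_t2d,n_controls_t2d Case/control
#'   counts for the binary outcomes.
#' @param neutral_blocks,liable_blocks Numbers of blocks planted as neutral
#'   drug-target candidates and as glycemic liabilities (the rest are null).
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 2000L, n_blocks = 40L,
                       within_block_rho = 0.3,
                       maf_range = c(0.05, 0.5),
                       causal_fraction = 0.1,
                       exposure_effect_sd = 0.05,
                       theta_cad = log(1.63), theta_t2d = log(0.86),
                       pleiotropy_fraction = 0, pleiotropy_sd = 0,
                       glycemic_traits = list(
                         FG = list(n = 133010, loading = 1.0),
                         FI = list(n = 108557, loading = 0.8),
                         PROINS = list(n = 10701, loading = 0.5),
                         HBA1C = list(n = 46368, loading = 0.6)),
                       glycemic_effect_sd = 0.02,
                       t2d_glycemic_loading = 1.0,
                       duplicate_trait_of = NULL,
                       duplicate_trait_id = "HOMA_IR",
                       duplicate_noise_sd = 0.1,
                       n_exposure = 95454,
                       n_cases_cad = 63746, n_controls_cad = 130681,
                       n_cases_t2d = 34840, n_controls_t2d = 114981,
                       neutral_blocks = 8L, liable_blocks = 6L,
                       seed = 1L) {
  cfg <- as.list(environment())
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(n_snps >= n_blocks && n_blocks >= 1, "need n_snps >= n_blocks >= 1")
  chk(within_block_rho >= 0 && within_block_rho < 1,
      "within_block_rho must lie in [0, 1)")
  chk(length(maf_range) == 2 && maf_range[1] > 0 && maf_range[2] <= 0.5 &&
        maf_range[1] <= maf_range[2], "maf_range must be within (0, 0.5]")
  chk(causal_fraction >= 0 && causal_fraction <= 1,
      "causal_fraction must lie in [0, 1]")
  chk(pleiotropy_fraction >= 0 && pleiotropy_fraction <= 1,
      "pleiotropy_fraction must lie in [0, 1]")
  chk(all(c(n_exposure, n_cases_cad, n_controls_cad, n_cases_t2d,
            n_controls_t2d) > 0), "sample sizes must be positive")
  chk(neutral_blocks >= 0 && liable_blocks >= 0 &&
        neutral_blocks + liable_blocks <= n_blocks,
      "block label counts must fit in n_blocks")
  chk(is.null(duplicate_trait_of) ||
        duplicate_trait_of %in% c(names(glycemic_traits), "T2D"),
      "duplicate_trait_of must name a glycemic trait or T2D")
  for (gt in glycemic_traits)
    chk(is.list(gt) && gt$n > 0, "glycemic traits need positive n")
  if (length(problems))
    stop("invalid simulation config:\n  ",
         paste(problems, collapse = "\n  "))
  structure(cfg, class = "sim_config")
}

se_quantitative <- function(n, maf) 1 / sqrt(2 * n * maf * (1 - maf))

se_binary <- function(n_cases, n_controls, maf) {
  n_eff <- 4 / (1 / n_cases + 1 / n_controls)
  1 / sqrt(2 * n_eff * maf * (1 - maf))
}

#' Generate a synthetic multi-trait GWAS summary-statistics dataset
#'
#' Produces per-trait summary-statistic tables (exposure, CAD-like and
#' T2D-like binary outcomes, the configured glycemic traits and optionally a
#' duplicated trait), a pairwise LD table, one gene interval per block, a
#' drug-annotation table, and a machine-readable truth record. Estimated
#' betas are the LD-smeared marginal true effects plus exchangeably
#' correlated noise with closed-form standard errors
#' (`1/sqrt(2 n maf (1-maf))`, with the effective sample size
#' `4/(1/cases + 1/controls)` for binary traits). Each trait's rows are
#' emitted with a random allele orientation so the harmonization stage has
#' real work to do. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_dataset`: list with `sumstats` (named
#'   list of `sumstats` tables), `ld` ([ld_table()]), `genes`, `drugs`,
#'   `truth` (`$snps` per-SNP effects and labels, `$loci` per-block labels)
#'   and `config`.
#' @export
simulate_gwas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- as.integer(cfg$n_snps)
  B <- as.integer(cfg$n_blocks)
  rho <- cfg$within_block_rho

  sizes <- rep(n %/% B, B)
  if (n %% B > 0) sizes[seq_len(n %% B)] <- sizes[seq_len(n %% B)] + 1L
  block <- rep(seq_len(B), sizes)
  snp_id <- sprintf("rs%05d", seq_len(n))
  gene <- sprintf("GENE%03d", block)

  chrom_of_block <- as.character(((seq_len(B) - 1L) %% 22L) + 1L)
  ord_on_chrom <- stats::ave(seq_len(B), chrom_of_block,
                             FUN = seq_along)
  block_start <- 1e6 + (ord_on_chrom - 1) * 2e6
  within <- unlist(lapply(sizes, seq_len))
  chrom <- chrom_of_block[block]
  pos <- as.integer(block_start[block] + (within - 1L) * 1000L)

  maf <- stats::runif(n, cfg$maf_range[1], cfg$maf_range[2])
  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, n, replace = TRUE)
  a2 <- bases[((match(a1, bases) - 1L +
                  sample.int(3L, n, replace = TRUE)) %% 4L) + 1L]

  labels <- sample(c(rep("neutral_candidate", cfg$neutral_blocks),
                     rep("glycemic_liability", cfg$liable_blocks),
                     rep("null", B - cfg$neutral_blocks -
                           cfg$liable_blocks)))
  lab_snp <- labels[block]
  causal <- lab_snp != "null" & stats::runif(n) < cfg$causal_fraction
  # every non-null block carries at least one causal SNP
  first_of_block <- !duplicated(block)
  need <- labels != "null" &
    !as.logical(tapply(causal, block, any)[as.character(seq_len(B))])
  causal[first_of_block & need[block]] <- TRUE

  marginalize <- function(joint) {
    bs <- stats::ave(joint, block, FUN = sum)
    joint + rho * (bs - joint)
  }
  corr_noise <- function() {
    zb <- stats::rnorm(B)[block]
    sqrt(rho) * zb + sqrt(1 - rho) * stats::rnorm(n)
  }

  b_joint <- ifelse(causal, stats::rnorm(n, 0, cfg$exposure_effect_sd), 0)
  # dense glycemic architecture in liability blocks: every member loads,
  # emulating tight local LD with a shared causal glycemic variant
  g_joint <- ifelse(lab_snp == "glycemic_liability",
                    stats::rnorm(n, 0, cfg$glycemic_effect_sd), 0)
  pleio <- function() ifelse(stats::runif(n) < cfg$pleiotropy_fraction,
                             stats::rnorm(n, 0, cfg$pleiotropy_sd), 0)
  cad_joint <- cfg$theta_cad * b_joint + pleio()
  t2d_joint <- cfg$theta_t2d * b_joint + pleio() +
    cfg$t2d_glycemic_loading * g_joint

  bx <- marginalize(b_joint)
  g_marg <- marginalize(g_joint)
  cad_marg <- marginalize(cad_joint)
  t2d_marg <- marginalize(t2d_joint)

  emit <- function(true_marg, se, meta) {
    beta_hat <- true_marg + se * corr_noise()
    swap <- stats::runif(n) < 0.5
    df <- data.frame(
      snp_id = snp_id, chrom = chrom, pos = pos,
      effect_allele = ifelse(swap, a2, a1),
      other_allele = ifelse(swap, a1, a2),
      beta = ifelse(swap, -beta_hat, beta_hat),
      se = se,
      pvalue = 2 * stats::pnorm(-abs(beta_hat / se)),
      n = if (meta$kind == "binary") meta$n_cases + meta$n_controls
          else meta$default_n,
      eaf = ifelse(swap, 1 - maf, maf),
      trait_id = meta$trait_id, stringsAsFactors = FALSE)
    new_sumstats(df, meta)
  }

  sumstats <- list()
  sumstats$LDL <- emit(bx, se_quantitative(cfg$n_exposure, maf),
                       trait_meta("LDL", "quantitative", "SD of LDL-C",
                                  default_n = cfg$n_exposure))
  sumstats$CAD <- emit(cad_marg,
                       se_binary(cfg$n_cases_cad, cfg$n_controls_cad, maf),
                       trait_meta("CAD", "binary", "log-odds",
                                  n_cases = cfg$n_cases_cad,
                                  n_controls = cfg$n_controls_cad))
  sumstats$T2D <- emit(t2d_marg,
                       se_binary(cfg$n_cases_t2d, cfg$n_controls_t2d, maf),
                       trait_meta("T2D", "binary", "log-odds",
                                  n_cases = cfg$n_cases_t2d,
                                  n_controls = cfg$n_controls_t2d))
  for (tid in names(cfg$glycemic_traits)) {
    gt <- cfg$glycemic_traits[[tid]]
    sumstats[[tid]] <- emit(gt$loading * g_marg,
                            se_quantitative(gt$n, maf),
                            trait_meta(tid, "quantitative",
                                       "trait units", default_n = gt$n))
  }
  if (!is.null(cfg$duplicate_trait_of)) {
    base <- sumstats[[cfg$duplicate_trait_of]]
    z_dup <- base$beta / base$se +
      cfg$duplicate_noise_sd * stats::rnorm(n)
    dup_meta <- trait_meta(cfg$duplicate_trait_id, "quantitative",
                           "trait units",
                           default_n = attr(base, "trait_meta")$default_n)
    df <- as.data.frame(base)
    df$beta <- z_dup * df$se
    df$pvalue <- 2 * stats::pnorm(-abs(z_dup))
    df$trait_id <- cfg$duplicate_trait_id
    sumstats[[cfg$duplicate_trait_id]] <- new_sumstats(df, dup_meta)
  }

  # LD table: all within-block pairs at r2 = rho^2
  if (rho > 0) {
    pair_a <- integer(0); pair_b <- integer(0)
    offset <- c(0L, cumsum(sizes))
    for (b in seq_len(B)) {
      m <- sizes[b]
      if (m < 2L) next
      cmb <- utils::combn(m, 2L)
      pair_a <- c(pair_a, offset[b] + cmb[1, ])
      pair_b <- c(pair_b, offset[b] + cmb[2, ])
    }
    ld <- ld_table(snp_id[pair_a], snp_id[pair_b],
                   rep(rho^2, length(pair_a)))
  } else ld <- ld_table()

  genes <- data.frame(
    gene = sprintf("GENE%03d", seq_len(B)), chrom = chrom_of_block,
    start = as.integer(pmax(1, block_start - 10000)),
    end = as.integer(block_start + (sizes - 1L) * 1000L + 10000L),
    stringsAsFactors = FALSE)

  druggable <- which(labels != "null")
  drugs <- data.frame(
    gene = sprintf("GENE%03d", druggable),
    drug = sprintf("compound_%03d", druggable),
    interaction = ifelse(druggable %% 2L == 0L, "pharmacodynamic",
                         "other"), stringsAsFactors = FALSE)

  truth <- list(
    snps = data.frame(
      snp_id = snp_id, block = block, gene = gene, label = lab_snp,
      chrom = chrom, pos = pos, maf = maf, causal = causal,
      beta_exposure_joint = b_joint, beta_exposure_marginal = bx,
      beta_cad_marginal = cad_marg, beta_t2d_marginal = t2d_marg,
      glycemic_marginal = g_marg, stringsAsFactors = FALSE),
    loci = data.frame(
      gene = sprintf("GENE%03d", seq_len(B)), block = seq_len(B),
      chrom = chrom_of_block, label = labels, n_snps = sizes,
      n_causal = as.integer(tapply(causal, block,
                                   sum)[as.character(seq_len(B))]),
      stringsAsFactors = FALSE))

  structure(list(sumstats = sumstats, ld = ld, genes = genes,
                 drugs = drugs, truth = truth, config = cfg),
            class = "sim_dataset")
}

#' Configuration of the shipped locus-triage fixture
#'
#' The fixture on which triage is expected to recover the planted
#' neutral/liable labels exactly. It differs from the plain defaults in two
#' deliberate ways. First, the causal exposure-to-T2D effect is set to zero:
#' under a nonzero causal effect every exposure-associated locus carries a
#' mediated T2D association, so "glycemia-neutral" is only ever relative to
#' power; an exactly recoverable ground truth requires loci whose glycemic
#' channel is genuinely absent. Second, the exposure architecture is denser
#' and stronger (causal_fraction 0.2, effect SD 0.1) so that every non-null
#' locus reliably contains a genome-wide-significant SNP, making detection
#' failures a property of the method rather than of an underpowered
#' fixture. Third, within-block correlation is switched off: the per-locus
#' Fisher enrichment treats member SNPs as independent draws, and
#' block-correlated estimation noise would shift whole blocks and produce
#' label errors that reflect LD pseudo-replication, not the triage logic
#' (LD handling itself is exercised by the clumping and pruning tests).
#'
#' @param seed Integer seed (default 20160305).
#' @param ... Further overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
triage_fixture_config <- function(seed = 20160305L, ...) {
  sim_config(theta_t2d = 0, exposure_effect_sd = 0.1,
             causal_fraction = 0.2, within_block_rho = 0,
             seed = seed, ...)
}

#' Configuration of the MR estimator-calibration study
#'
#' A small panel of independent SNPs in the strong-instrument regime, used
#' for replicate studies of causal-effect recovery and confidence-interval
#' coverage. Half the SNPs carry large exposure effects (SD 0.35 per SD of
#' exposure, common-variant MAFs), the rest are null, and the outcomes act
#' purely through the planted causal effects. The ratio/IVW estimator is
#' consistent only when instruments are strong; near the selection
#' threshold it inherits an O(se_x^2/beta_x^2) regression-dilution bias, so
#' a coverage study of the estimator itself must be run where that bias is
#' negligible relative to the pooled standard error. Instrument counts
#' (about 35-40 per replicate) keep the pooled CI wide enough that the
#' residual finite-instrument bias does not distort coverage.
#'
#' @param seed Integer seed.
#' @param ... Further overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
mr_recovery_config <- function(seed, ...) {
  sim_config(n_snps = 80L, n_blocks = 80L, within_block_rho = 0,
             causal_fraction = 1, exposure_effect_sd = 0.35,
             maf_range = c(0.2, 0.5), neutral_blocks = 40L,
             liable_blocks = 0L, glycemic_traits = list(),
             seed = seed, ...)
}

#' Configuration of the consortium-scale synthetic reproduction run
#'
#' A single large panel of independent SNPs at the real consortium sample
#' sizes, with a couple of hundred genome-wide-significant instruments
#' (mirroring the scale of an LDL-C instrument set), used to re-derive the
#' headline causal odds ratios from a full pipeline run: the CAD estimate,
#' the T2D estimate, and the CAD estimate after excluding instruments
#' nominally associated with T2D. The per-SNP exposure effect SD (0.1)
#' balances instrument strength against a realistic minority-to-moderate
#' fraction of instruments reaching nominal T2D significance through the
#' mediated channel, so the exclusion step removes part, not all, of the
#' instrument set.
#'
#' @param seed Integer seed.
#' @param ... Further overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
consortium_scale_config <- function(seed, ...) {
  sim_config(n_snps = 600L, n_blocks = 600L, within_block_rho = 0,
             causal_fraction = 1, exposure_effect_sd = 0.1,
             neutral_blocks = 300L, liable_blocks = 0L,
             seed = seed, ...)
}

#' Machine-readable truth of a simulated dataset
#'
#' @param dataset A [simulate_gwas()] result.
#' @return The per-SNP truth table: planted locus labels and true joint and
#'   marginal effects, suitable for test assertions.
#' @export
truth_report <- function(dataset) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dataset$truth$snps
}

#' Write a simulated dataset to a directory of text files
#'
#' Writes each trait's summary statistics (canonical dialect), the LD
#' table, gene intervals, drug annotations and the truth tables, in the
#' formats the ingest functions read.
#'
#' @param dataset A [simulate_gwas()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tid in names(dataset$sumstats))
    write_table(dataset$sumstats[[tid]],
                file.path(dir, paste0(tid, ".tsv")))
  ab <- strsplit(dataset$ld$key, "\r", fixed = TRUE)
  ld_df <- data.frame(snp_a = vapply(ab, `[`, "", 1L),
                      snp_b = vapply(ab, `[`, "", 2L),
                      r2 = dataset$ld$r2, stringsAsFactors = FALSE)
  write_table(ld_df, file.path(dir, "ld.tsv"))
  write_table(dataset$genes, file.path(dir, "genes.tsv"))
  write_table(dataset$drugs, file.path(dir, "drugs.tsv"))
  write_table(dataset$truth$snps, file.path(dir, "truth_snps.tsv"))
  write_table(dataset$truth$loci, file.path(dir, "truth_loci.tsv"))
  invisible(dir)
}

#' @export
print.sim_dataset <- function(x, ...) {
  lab <- table(x$truth$loci$label)
  cat(sprintf(
    "Synthetic GWAS dataset: %d SNPs in %d blocks (%s), traits: %s\n",
    nrow(x$truth$snps), nrow(x$truth$loci),
    paste(names(lab), lab, sep = "=", collapse = ", "),
    paste(names(x$sumstats), collapse = ", ")))
  invisible(x)
}
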