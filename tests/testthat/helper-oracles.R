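# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive each quantity from first principles (pair
# counting, full enumeration, literal rule application) and share no code
# with the functions they check.

# Kendall tau-b by explicit pair counting with tie corrections
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    dx <- sign(x[i] - x[j])
    dy <- sign(y[i] - y[j])
    if (dx == 0 && dy == 0) next
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# Fisher two-sided p by full hypergeometric enumeration over all tables
# with the observed margins: sum of probabilities <= observed (with the
# customary 1e-7 relative slack for ties in floating point)
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  a_range <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(a_range, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Literal re-application of the clumping rule: repeatedly take the best
# remaining SNP by (P, chrom, pos, id), make it a lead, remove everything
# correlated and in window
oracle_clump <- function(snps, r2_of, r2_threshold, window_kb) {
  remaining <- snps[order(snps$pvalue, snps$chrom, snps$pos, snps$snp_id), ]
  leads <- character(0)
  assignment <- character(0)
  while (nrow(remaining) > 0) {
    lead <- remaining[1, ]
    leads <- c(leads, lead$snp_id)
    assignment[lead$snp_id] <- lead$snp_id
    remaining <- remaining[-1, , drop = FALSE]
    if (nrow(remaining) == 0) break
    member <- remaining$chrom == lead$chrom &
      abs(remaining$pos - lead$pos) <= window_kb * 1000 &
      mapply(r2_of, remaining$snp_id,
             MoreArgs = list(b = lead$snp_id)) >= r2_threshold
    assignment[remaining$snp_id[member]] <- lead$snp_id
    remaining <- remaining[!member, , drop = FALSE]
  }
  list(leads = leads, assignment = assignment)
}

# quick builders -------------------------------------------------------

make_ss <- function(..., trait = "X", kind = "quantitative", n = 1e5) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  as_sumstats(df, trait_meta(trait, kind, default_n = n))
}

# random clumping instance on one or two chromosomes
random_clump_instance <- function(n_snps, p_ties = 0.2) {
  ids <- sprintf("s%02d", seq_len(n_snps))
  pv <- signif(stats::runif(n_snps), 3)
  ties <- stats::runif(n_snps) < p_ties
  pv[ties] <- pv[sample(seq_len(n_snps), sum(ties), replace = TRUE)]
  snps <- data.frame(
    snp_id = ids,
    chrom = sample(c("1", "2"), n_snps, replace = TRUE),
    pos = sample.int(500000L, n_snps),
    pvalue = pv, stringsAsFactors = FALSE)
  pairs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < 0.5
  ld <- ld_table(pairs[keep, 1], pairs[keep, 2],
                 stats::runif(sum(keep)))
  list(snps = snps, ld = ld)
}

default_glycemic_traits <- c("FG", "FI", "PROINS", "HBA1C", "T2D")

build_sim_panel <- function(ds, outcomes = setdiff(names(ds$sumstats),
                                                   "LDL")) {
  build_panel(ds$sumstats$LDL, ds$sumstats[outcomes])
}
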