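#' Assign SNPs to their nearest gene
#'
#' A SNP inside a gene interval is assigned to that gene; otherwise to the
#' nearest interval boundary on the same chromosome. Distance ties go to the
#' gene with the smaller start, then lexicographically smaller name. SNPs on
#' chromosomes with no genes stay unassigned and are counted.
#'
#' @param snps Data frame with columns `snp_id`, `chrom`, `pos`.
#' @param genes Data frame with columns `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive; see [read_gene_intervals()]).
#' @return List of class `locus_assignment`: `assignment` (named character,
#'   snp_id -> gene, NA when unassigned), `members` (gene -> SNP ids) and
#'   `n_unassigned`.
#' @export
assign_loci <- function(snps, genes) {
  stopifnot(nrow(genes) > 0, all(c("snp_id", "chrom", "pos") %in%
                                   names(snps)))
  out <- rep(NA_character_, nrow(snps))
  for (ch in unique(snps$chrom)) {
    si <- which(snps$chrom == ch)
    g <- genes[genes$chrom == ch, ]
    if (nrow(g) == 0L) next
    # stable tie order: smaller start, then gene name
    g <- g[order(g$start, g$gene), ]
    for (i in si) {
      pos <- snps$pos[i]
      d <- pmax(g$start - pos, pos - g$end, 0)
      out[i] <- g$gene[which.min(d)]
    }
  }
  assignment <- setNames(out, snps$snp_id)
  members <- split(names(assignment)[!is.na(assignment)],
                   assignment[!is.na(assignment)])
  structure(list(assignment = assignment, members = members,
                 n_unassigned = sum(is.na(out))),
            class = "locus_assignment")
}

#' Exact binomial probability under a fair-coin null
#'
#' The default (`"point"`) is the binomial mass at the observed count,
#' `C(n, k) * 0.5^n`: this is the quantity printed alongside the
#' cross-trait concordance counts (e.g. 22 of 25 concordant loci gives
#' 6.85e-5). One- and two-sided tail probabilities are also available,
#' clearly labelled: `"one_sided"` sums the tail from k away from n/2, and
#' `"two_sided"` doubles it (capped at 1).
#'
#' @param n Number of trials (>= 1).
#' @param k Observed count, 0 <= k <= n.
#' @param method `"point"`, `"one_sided"` or `"two_sided"`.
#' @return Probability in (0, 1\].
#' @export
binomial_point_probability <- function(n, k, method = c("point", "one_sided",
                                                        "two_sided")) {
  method <- match.arg(method)
  if (length(n) != 1L || length(k) != 1L || n < 1 || k < 0 || k > n ||
      n != round(n) || k != round(k))
    stop("need integers 0 <= k <= n, n >= 1")
  if (method == "point") return(stats::dbinom(k, n, 0.5))
  tail <- if (k >= n / 2) sum(stats::dbinom(k:n, n, 0.5))
          else sum(stats::dbinom(0:k, n, 0.5))
  if (method == "one_sided") tail else min(1, 2 * tail)
}

#' Cross-trait directional concordance of loci
#'
#' Selects SNPs passing the exposure threshold on the exposure trait and the
#' nominal threshold on the outcome, groups them by locus, and takes one
#' representative SNP per locus (smallest outcome P; ties by smallest
#' exposure P, then SNP id). Because the panel is oriented to the
#' exposure-raising allele, a locus is concordant exactly when the
#' representative outcome beta is positive. Loci whose representative
#' outcome beta is exactly zero are dropped with a warning.
#'
#' @param panel A [build_panel()] result.
#' @param loci A [assign_loci()] result.
#' @param outcome_trait Outcome trait id.
#' @param exposure_p Exposure significance threshold (default 5e-8).
#' @param outcome_p Outcome nominal threshold (default 0.05).
#' @return List of class `concordance_result`: `directions` (per-locus
#'   representative SNP, per-trait signs and P values), `n_loci`,
#'   `k_concordant`, `binomial_p` (point mass at the observed count),
#'   `n_snps_qualifying`.
#' @export
concordance_test <- function(panel, loci, outcome_trait,
                             exposure_p = 5e-8, outcome_p = 0.05) {
  stopifnot(inherits(panel, "harmonized_panel"),
            inherits(loci, "locus_assignment"))
  expo <- panel_trait(panel, panel$exposure)
  outc <- panel_trait(panel, outcome_trait)
  m <- match(expo$snp_id, outc$snp_id)
  ok <- expo$pvalue < exposure_p & !is.na(m) &
    outc$pvalue[m] < outcome_p
  ok[is.na(ok)] <- FALSE
  q <- data.frame(snp_id = expo$snp_id[ok],
                  exposure_beta = expo$beta[ok],
                  exposure_p = expo$pvalue[ok],
                  outcome_beta = outc$beta[m[ok]],
                  outcome_p = outc$pvalue[m[ok]],
                  stringsAsFactors = FALSE)
  q$gene <- loci$assignment[q$snp_id]
  q <- q[!is.na(q$gene), ]
  if (nrow(q) == 0L) stop("no locus passes both thresholds")
  q <- q[order(q$outcome_p, q$exposure_p, q$snp_id), ]
  rep_rows <- q[!duplicated(q$gene), ]
  zero <- rep_rows$outcome_beta == 0
  if (any(zero)) {
    warning(sum(zero), " locus/loci dropped: representative outcome beta",
            " is exactly zero")
    rep_rows <- rep_rows[!zero, ]
  }
  if (nrow(rep_rows) == 0L) stop("no locus passes both thresholds")
  rep_rows <- rep_rows[order(rep_rows$gene), ]
  directions <- data.frame(
    gene = rep_rows$gene, snp_id = rep_rows$snp_id,
    exposure_sign = 1L,
    outcome_sign = ifelse(rep_rows$outcome_beta > 0, 1L, -1L),
    exposure_p = rep_rows$exposure_p, outcome_p = rep_rows$outcome_p,
    stringsAsFactors = FALSE)
  n <- nrow(directions)
  k <- sum(directions$outcome_sign > 0)
  structure(list(directions = directions, n_loci = n, k_concordant = k,
                 binomial_p = binomial_point_probability(n, k),
                 n_snps_qualifying = nrow(q)),
            class = "concordance_result")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided P value by the standard rule (sum of hypergeometric
#' probabilities of all tables with the same margins whose probability does
#' not exceed the observed table's). The odds ratio is the sample
#' cross-product `(a d)/(b c)` (`Inf` when `b c = 0` with `a d > 0`, 0 in
#' the reverse case), not the conditional MLE.
#'
#' @param a,b,c,d Non-negative integer cell counts, reading the table
#'   row-wise; at least one margin must be positive.
#' @return List with `odds_ratio` and `pvalue`.
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  if (sum(cells) == 0) stop("all cells are zero")
  p <- stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else a * d / (b * c)
  list(odds_ratio = or, pvalue = min(p, 1))
}

#' Per-locus over-representation of composite-associated SNPs
#'
#' For each candidate locus, compares the proportion of its (pruned) SNPs
#' associated with the composite (P < `composite_alpha`) to the proportion
#' among all other pruned SNPs, by Fisher's exact test. A locus is flagged
#' over-represented when the Fisher P is strictly below `alpha` and the
#' odds ratio exceeds 1. Loci with no pruned SNPs are skipped.
#'
#' @param composite_p Named numeric vector: composite P value per pruned
#'   SNP (names = SNP ids). Must cover every pruned SNP considered.
#' @param loci A [assign_loci()] result (or any list with `assignment`).
#' @param candidate_genes Genes to test (default: every gene with a pruned
#'   SNP).
#' @param alpha Fisher significance threshold (default 0.05, strict `<`).
#' @param composite_alpha Per-SNP composite threshold (default 0.05,
#'   strict `<`).
#' @return Data frame of class `enrichment_result`: gene, a, b, c, d,
#'   odds_ratio, fisher_p, over_represented.
#' @export
locus_enrichment <- function(composite_p, loci, candidate_genes = NULL,
                             alpha = 0.05, composite_alpha = 0.05) {
  snp_ids <- names(composite_p)
  if (is.null(snp_ids) || any(is.na(composite_p)))
    stop("composite_p must be a named vector with no missing values")
  gene_of <- loci$assignment[snp_ids]
  sig <- composite_p < composite_alpha
  if (is.null(candidate_genes))
    candidate_genes <- sort(unique(gene_of[!is.na(gene_of)]))
  rows <- lapply(candidate_genes, function(g) {
    inl <- !is.na(gene_of) & gene_of == g
    if (!any(inl)) return(NULL) # no pruned SNP in locus: skipped
    a <- sum(sig & inl); b <- sum(!sig & inl)
    cc <- sum(sig & !inl); dd <- sum(!sig & !inl)
    ft <- fisher_exact(a, b, cc, dd)
    data.frame(gene = g, a = a, b = b, c = cc, d = dd,
               odds_ratio = ft$odds_ratio, fisher_p = ft$pvalue,
               over_represented = ft$pvalue < alpha &
                 !is.nan(ft$odds_ratio) & ft$odds_ratio > 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0),
                      odds_ratio = numeric(0), fisher_p = numeric(0),
                      over_represented = logical(0))
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Triage loci into glycemia-neutral candidates and glycemic liabilities
#'
#' Two routes over the pruned SNP set. A locus is a
#' `glycemia_neutral_candidate` when it contains at least one pruned SNP
#' with exposure P < `exposure_p`, CAD P < `outcome_p` and composite
#' P > `composite_alpha`, and the locus is not over-represented for
#' composite-associated SNPs ([locus_enrichment()]). It is a
#' `glycemic_liability` when it contains at least one pruned SNP with
#' exposure P < `exposure_p`, CAD P < `outcome_p` and composite
#' P < `composite_alpha`, and the locus is over-represented. Anything else
#' among the candidate loci (those with a qualifying exposure+outcome SNP)
#' is `indeterminate`. All thresholds are strict; boundary cases fall on
#' the non-significant side. Drug annotations, when given, are joined by
#' gene label and pharmacodynamic interactions flagged.
#'
#' @param panel A [build_panel()] result.
#' @param composite A [build_composite()] result.
#' @param pruned A [clump()]/[prune_independent()] result (its leads) or a
#'   character vector of pruned SNP ids.
#' @param loci A [assign_loci()] result.
#' @param drugs Optional drug table ([read_drug_annotations()]).
#' @param outcome_trait Outcome trait id (default `"CAD"`).
#' @param exposure_p,outcome_p,composite_alpha,fisher_alpha Thresholds
#'   (defaults 5e-8, 0.05, 0.05, 0.05).
#' @return Data frame of class `triage_result`, one row per candidate
#'   locus: direction of exposure and outcome effects at the representative
#'   SNP, qualifying-SNP counts, Fisher verdict, classification, joined
#'   drugs. The enrichment table is attached as attribute `enrichment`.
#' @export
triage <- function(panel, composite, pruned, loci, drugs = NULL,
                   outcome_trait = "CAD", exposure_p = 5e-8,
                   outcome_p = 0.05, composite_alpha = 0.05,
                   fisher_alpha = 0.05) {
  stopifnot(inherits(panel, "harmonized_panel"),
            inherits(composite, "composite_result"),
            inherits(loci, "locus_assignment"))
  if (inherits(pruned, "clump_result")) pruned <- pruned$leads
  pruned <- intersect(pruned, composite$snps$snp_id)
  if (length(pruned) == 0L) stop("no pruned SNP has a composite P value")
  comp_p <- setNames(
    composite$snps$pvalue[match(pruned, composite$snps$snp_id)], pruned)

  expo <- panel_trait(panel, panel$exposure)
  outc <- panel_trait(panel, outcome_trait)
  ex_p <- expo$pvalue[match(pruned, expo$snp_id)]
  oc_i <- match(pruned, outc$snp_id)
  oc_p <- outc$pvalue[oc_i]
  oc_b <- outc$beta[oc_i]
  qual <- !is.na(ex_p) & ex_p < exposure_p & !is.na(oc_p) & oc_p < outcome_p
  gene_of <- loci$assignment[pruned]

  candidates <- sort(unique(gene_of[qual & !is.na(gene_of)]))
  enr <- locus_enrichment(comp_p, loci, candidate_genes = candidates,
                          alpha = fisher_alpha,
                          composite_alpha = composite_alpha)
  rows <- lapply(candidates, function(g) {
    in_locus <- !is.na(gene_of) & gene_of == g
    qi <- which(in_locus & qual)
    over <- enr$over_represented[match(g, enr$gene)]
    comp_null <- any(comp_p[qi] > composite_alpha)
    comp_assoc <- any(comp_p[qi] < composite_alpha)
    cls <- if (isTRUE(over) && comp_assoc) "glycemic_liability"
           else if (!isTRUE(over) && comp_null) "glycemia_neutral_candidate"
           else "indeterminate"
    rep_i <- qi[order(oc_p[qi], ex_p[qi], pruned[qi])][1]
    data.frame(gene = g,
               n_pruned_snps = sum(in_locus), n_qualifying = length(qi),
               exposure_sign = 1L,
               outcome_sign = ifelse(oc_b[rep_i] > 0, 1L,
                                     ifelse(oc_b[rep_i] < 0, -1L, 0L)),
               representative_snp = pruned[rep_i],
               any_composite_null = comp_null,
               any_composite_assoc = comp_assoc,
               over_represented = isTRUE(over),
               fisher_p = enr$fisher_p[match(g, enr$gene)],
               classification = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(0), n_pruned_snps = integer(0),
                      n_qualifying = integer(0), exposure_sign = integer(0),
                      outcome_sign = integer(0),
                      representative_snp = character(0),
                      any_composite_null = logical(0),
                      any_composite_assoc = logical(0),
                      over_represented = logical(0), fisher_p = numeric(0),
                      classification = character(0))
  if (!is.null(drugs)) {
    out$drugs <- vapply(out$gene, function(g) {
      paste(drugs$drug[drugs$gene == g], collapse = ";")
    }, character(1))
    out$pharmacodynamic <- vapply(out$gene, function(g) {
      any(drugs$interaction[drugs$gene == g] == "pharmacodynamic")
    }, logical(1))
  } else {
    out$drugs <- ""
    out$pharmacodynamic <- FALSE
  }
  rownames(out) <- NULL
  attr(out, "enrichment") <- enr
  class(out) <- c("triage_result", "data.frame")
  out
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "Concordance: %d of %d loci share the exposure direction (binomial P = %s)\n",
    x$k_concordant, x$n_loci, format(x$binomial_p, digits = 3)))
  invisible(x)
}
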