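#' Greedy P-value-prioritized LD clumping
#'
#' SNPs are visited in ascending priority P value (ties broken by chromosome,
#' then position, then SNP id, for determinism). Each not-yet-assigned SNP
#' becomes a lead; every other unassigned SNP on the same chromosome within
#' `window_kb` of the lead and with r-squared >= `r2_threshold` to it is
#' assigned to that lead. Cross-chromosome LD is ignored even if present in
#' the table; absent pairs count as r-squared 0.
#'
#' @param snps Data frame with columns `snp_id`, `chrom`, `pos` and a
#'   priority P value column `pvalue` (e.g. from [panel_trait()] with
#'   `with_positions = TRUE`).
#' @param ld An [ld_table()].
#' @param r2_threshold Members with r-squared >= this to the lead are
#'   clumped (default 0.5).
#' @param window_kb Half-window around the lead in kilobases (default 250);
#'   `Inf` means whole chromosome.
#' @return An object of class `clump_result`: list with `leads` (ordered by
#'   priority) and `assignment` (named character vector, member -> lead;
#'   leads map to themselves).
#' @export
clump <- function(snps, ld, r2_threshold = 0.5, window_kb = 250) {
  stopifnot(inherits(ld, "ld_table"),
            all(c("snp_id", "chrom", "pos", "pvalue") %in% names(snps)))
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop("r2_threshold must lie in (0, 1]")
  if (any(is.na(snps$pos)) || any(is.na(snps$chrom)))
    stop("every SNP needs a chromosome and position for clumping")
  n <- nrow(snps)
  ord <- order(snps$pvalue, snps$chrom, snps$pos, snps$snp_id)
  id <- snps$snp_id[ord]
  chrom <- snps$chrom[ord]
  pos <- snps$pos[ord]
  window <- window_kb * 1000
  assigned <- rep(NA_character_, n)
  leads <- character(0)
  for (i in seq_len(n)) {
    if (!is.na(assigned[i])) next
    assigned[i] <- id[i]
    leads <- c(leads, id[i])
    cand <- which(is.na(assigned) & chrom == chrom[i] &
                    abs(pos - pos[i]) <= window)
    if (length(cand)) {
      hit <- ld_r2(ld, id[cand], rep(id[i], length(cand))) >= r2_threshold
      assigned[cand[hit]] <- id[i]
    }
  }
  structure(list(leads = leads, assignment = setNames(assigned, id)),
            class = "clump_result")
}

#' Prune SNPs to a pairwise-independent set
#'
#' The lead set of [clump()] with a whole-chromosome window: the retained
#' SNPs are pairwise below the r-squared threshold, keeping the best
#' (smallest) priority P value in each correlated group.
#'
#' @inheritParams clump
#' @param r2_threshold Pairs at or above this r-squared are dependent
#'   (default 0.8).
#' @return Character vector of retained SNP ids, ordered by priority.
#' @export
prune_independent <- function(snps, ld, r2_threshold = 0.8) {
  clump(snps, ld, r2_threshold = r2_threshold, window_kb = Inf)$leads
}

#' @export
print.clump_result <- function(x, ...) {
  cat(sprintf("LD clumping: %d SNPs in %d clumps\n",
              length(x$assignment), length(x$leads)))
  invisible(x)
}
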