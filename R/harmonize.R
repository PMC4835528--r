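#' Orient one summary record to a target allele pair
#'
#' If the record's alleles already equal (target_effect, target_other) the
#' record is returned unchanged; if they equal the swapped pair, the alleles
#' are swapped, the beta negated and the effect-allele frequency reflected
#' (eaf -> 1 - eaf). SE, P and N are orientation-invariant.
#'
#' @param record A one-row `sumstats` data frame (or list with fields
#'   `effect_allele`, `other_allele`, `beta`, `eaf`).
#' @param target_effect,target_other Single-base target alleles.
#' @return The oriented record. Throws an error of class
#'   `mrtriage_allele_mismatch` when the record's allele pair is not the
#'   target pair in either order; panel assembly catches this, drops the
#'   record and counts it.
#' @export
orient_record <- function(record, target_effect, target_other) {
  ea <- record$effect_allele
  oa <- record$other_allele
  if (ea == target_effect && oa == target_other) return(record)
  if (ea == target_other && oa == target_effect) {
    record$effect_allele <- target_effect
    record$other_allele <- target_other
    record$beta <- -record$beta
    if (!is.null(record$eaf) && !is.na(record$eaf))
      record$eaf <- 1 - record$eaf
    return(record)
  }
  stop(structure(class = c("mrtriage_allele_mismatch", "error", "condition"),
                 list(message = sprintf(
                   "allele pair (%s, %s) does not match target (%s, %s)",
                   ea, oa, target_effect, target_other),
                   call = sys.call(-1))))
}

is_palindromic <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Assemble a harmonized multi-trait panel
#'
#' The exposure table defines the SNP universe and, per SNP, the reference
#' allele: the allele that raises the exposure (so oriented exposure betas
#' are all non-negative). Every outcome record is re-oriented to that
#' reference allele; records whose allele pair does not match are dropped
#' and counted, SNPs absent from an outcome leave that cell empty.
#' Palindromic SNPs (A/T or C/G) are flagged, and dropped only when
#' `drop_palindromic = TRUE`. SNPs with exposure beta exactly zero keep the
#' alphabetically first allele as reference and are flagged as unusable
#' instruments.
#'
#' @param exposure A `sumstats` table for the exposure trait.
#' @param outcomes A single `sumstats` table or a list of them.
#' @param drop_palindromic Remove palindromic SNPs entirely (default keeps
#'   and flags them).
#' @return An object of class `harmonized_panel`: list with `snps` (SNP
#'   metadata incl. reference alleles and flags), `cells` (long table of
#'   oriented beta/se/p/n per SNP x trait), `exposure` (trait id), `traits`
#'   (list of [trait_meta()]) and `report` (alignment counts).
#' @export
build_panel <- function(exposure, outcomes = list(),
                        drop_palindromic = FALSE) {
  stopifnot(inherits(exposure, "sumstats"))
  if (inherits(outcomes, "sumstats")) outcomes <- list(outcomes)
  if (nrow(exposure) == 0L) stop("exposure record set is empty")
  exp_meta <- attr(exposure, "trait_meta")
  exposure <- as.data.frame(exposure)

  # exposure-raising reference allele
  flip <- !is.na(exposure$beta) & exposure$beta < 0
  zero <- !is.na(exposure$beta) & exposure$beta == 0
  # zero-effect SNPs: alphabetically first allele as reference
  flip[zero] <- exposure$other_allele[zero] < exposure$effect_allele[zero]
  ea <- ifelse(flip, exposure$other_allele, exposure$effect_allele)
  oa <- ifelse(flip, exposure$effect_allele, exposure$other_allele)
  beta <- ifelse(flip, -exposure$beta, exposure$beta)
  eaf <- ifelse(flip & !is.na(exposure$eaf), 1 - exposure$eaf, exposure$eaf)

  snps <- data.frame(
    snp_id = exposure$snp_id, chrom = exposure$chrom, pos = exposure$pos,
    effect_allele = ea, other_allele = oa,
    palindromic = is_palindromic(ea, oa),
    zero_exposure = zero, stringsAsFactors = FALSE)
  report <- list(n_exposure_snps = nrow(snps),
                 n_palindromic = sum(snps$palindromic),
                 n_zero_exposure = sum(zero),
                 exposure_flipped = sum(flip & !zero))
  if (drop_palindromic) {
    keep <- !snps$palindromic
    report$dropped_palindromic <- sum(!keep)
    snps <- snps[keep, ]
    exposure <- exposure[keep, ]
    ea <- ea[keep]; oa <- oa[keep]; beta <- beta[keep]; eaf <- eaf[keep]
  }

  cells <- data.frame(
    snp_id = snps$snp_id, trait_id = exp_meta$trait_id,
    beta = beta, se = exposure$se, pvalue = exposure$pvalue, n = exposure$n,
    eaf = eaf, stringsAsFactors = FALSE)

  traits <- setNames(list(exp_meta), exp_meta$trait_id)
  per_trait <- list()
  for (oc in outcomes) {
    stopifnot(inherits(oc, "sumstats"))
    meta <- attr(oc, "trait_meta")
    if (meta$trait_id %in% names(traits))
      stop("duplicate trait id in panel: ", meta$trait_id)
    oc <- as.data.frame(oc)
    idx <- match(snps$snp_id, oc$snp_id)
    present <- !is.na(idx)
    o <- oc[idx[present], ]
    ref_ea <- snps$effect_allele[present]
    ref_oa <- snps$other_allele[present]
    same <- o$effect_allele == ref_ea & o$other_allele == ref_oa
    swapped <- o$effect_allele == ref_oa & o$other_allele == ref_ea
    mism <- !(same | swapped)
    o$beta[swapped] <- -o$beta[swapped]
    o$eaf[swapped] <- ifelse(is.na(o$eaf[swapped]), NA_real_,
                             1 - o$eaf[swapped])
    keep <- !mism
    cells <- rbind(cells, data.frame(
      snp_id = snps$snp_id[present][keep],
      trait_id = rep(meta$trait_id, sum(keep)),
      beta = o$beta[keep], se = o$se[keep], pvalue = o$pvalue[keep],
      n = o$n[keep], eaf = o$eaf[keep], stringsAsFactors = FALSE))
    per_trait[[meta$trait_id]] <- c(
      matched = sum(present) - sum(mism), flipped = sum(swapped & !mism),
      dropped_allele_mismatch = sum(mism),
      absent_in_trait = sum(!present),
      discarded_not_in_exposure = sum(!oc$snp_id %in% snps$snp_id))
    traits[[meta$trait_id]] <- meta
  }
  report$outcomes <- per_trait
  structure(list(snps = snps, cells = cells, exposure = exp_meta$trait_id,
                 traits = traits, report = report),
            class = "harmonized_panel")
}

#' Extract one trait's oriented cells from a panel
#'
#' @param panel A `harmonized_panel`.
#' @param trait_id Trait identifier.
#' @param with_positions Merge in SNP chrom/pos metadata.
#' @return Data frame of oriented cells (one row per SNP with data).
#' @export
panel_trait <- function(panel, trait_id, with_positions = FALSE) {
  stopifnot(inherits(panel, "harmonized_panel"))
  if (!trait_id %in% names(panel$traits))
    stop("trait not in panel: ", trait_id)
  out <- panel$cells[panel$cells$trait_id == trait_id, ]
  rownames(out) <- NULL
  if (with_positions) {
    m <- match(out$snp_id, panel$snps$snp_id)
    out$chrom <- panel$snps$chrom[m]
    out$pos <- panel$snps$pos[m]
  }
  out
}

#' SNP-by-trait matrix of one field from a panel
#'
#' @param panel A `harmonized_panel`.
#' @param field One of `"beta"`, `"se"`, `"pvalue"`, `"n"`, or `"z"`
#'   (beta/se).
#' @param traits Traits to include (default: all).
#' @return Numeric matrix, rows = panel SNPs, columns = traits; empty cells
#'   are NA.
#' @export
panel_matrix <- function(panel, field = "z", traits = names(panel$traits)) {
  stopifnot(inherits(panel, "harmonized_panel"))
  cells <- panel$cells[panel$cells$trait_id %in% traits, ]
  val <- if (field == "z") cells$beta / cells$se else cells[[field]]
  m <- matrix(NA_real_, nrow(panel$snps), length(traits),
              dimnames = list(panel$snps$snp_id, traits))
  m[cbind(match(cells$snp_id, panel$snps$snp_id),
          match(cells$trait_id, traits))] <- val
  m
}

#' Serialize a harmonized panel to text files
#'
#' Writes `<prefix>_cells.tsv` (long-format oriented cells),
#' `<prefix>_snps.tsv` (SNP metadata) and `<prefix>_meta.json` (exposure
#' id, trait metadata, alignment report).
#'
#' @param panel A `harmonized_panel`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_panel <- function(panel, prefix) {
  stopifnot(inherits(panel, "harmonized_panel"))
  write_table(panel$cells, paste0(prefix, "_cells.tsv"))
  write_table(panel$snps, paste0(prefix, "_snps.tsv"))
  meta <- list(exposure = panel$exposure,
               traits = lapply(panel$traits, unclass),
               report = panel$report)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(prefix)
}

#' Read a harmonized panel written by [write_panel()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `harmonized_panel`.
#' @export
read_panel <- function(prefix) {
  cells <- utils::read.table(paste0(prefix, "_cells.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  snps <- utils::read.table(paste0(prefix, "_snps.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  snps$chrom <- as.character(snps$chrom)
  cells$trait_id <- as.character(cells$trait_id)
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  traits <- lapply(meta$traits, function(t) {
    do.call(trait_meta, t[!vapply(t, is.null, logical(1))])
  })
  structure(list(snps = snps, cells = cells, exposure = meta$exposure,
                 traits = traits, report = meta$report),
            class = "harmonized_panel")
}

#' @export
print.harmonized_panel <- function(x, ...) {
  cat(sprintf(
    "Harmonized panel: %d SNPs, exposure '%s', traits: %s\n",
    nrow(x$snps), x$exposure, paste(names(x$traits), collapse = ", ")))
  cat(sprintf("  palindromic: %d, zero-exposure: %d\n",
              x$report$n_palindromic, x$report$n_zero_exposure))
  invisible(x)
}
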