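#' Describe a trait
#'
#' Metadata attached to every summary-statistic table: the trait identifier,
#' whether it is quantitative or binary (binary effects are log-odds), the
#' units of the effect column, and sample-size information used when the
#' table itself carries no per-row N.
#'
#' @param trait_id Short unique identifier, e.g. `"LDL"`, `"CAD"`, `"FG"`.
#' @param kind `"quantitative"` or `"binary"`.
#' @param units Free-text units of the effect column (e.g. `"SD of LDL-C"`,
#'   `"log-odds"`, `"mmol/l"`).
#' @param default_n Sample size used for rows without an N column.
#' @param n_cases,n_controls Case/control counts; required for binary traits
#'   when neither a per-row N column nor `default_n` is available.
#' @return An object of class `trait_meta`.
#' @export
trait_meta <- function(trait_id, kind = c("quantitative", "binary"),
                       units = "", default_n = NULL,
                       n_cases = NULL, n_controls = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(trait_id), length(trait_id) == 1L, nzchar(trait_id))
  if (!is.null(default_n) && default_n <= 0) stop("default_n must be positive")
  if (kind == "binary" && is.null(default_n) &&
      (is.null(n_cases) || is.null(n_controls))) {
    # per-row N may still rescue this at read time; keep but remember
    n_cases <- n_cases
  }
  structure(list(trait_id = trait_id, kind = kind, units = units,
                 default_n = default_n, n_cases = n_cases,
                 n_controls = n_controls),
            class = "trait_meta")
}

#' Define a summary-statistics column dialect
#'
#' Maps the canonical field names used throughout the package to the column
#' headers of a particular source file. `snp_id`, `effect_allele`,
#' `other_allele`, `beta` and `se` are mandatory; `pvalue` is derived from
#' beta/se (two-sided normal) when unmapped or missing.
#'
#' @param snp_id,effect_allele,other_allele,beta,se Source column headers
#'   (mandatory).
#' @param pvalue,chrom,pos,n,eaf Source column headers (optional; `NULL`
#'   means the field is absent from the file).
#' @param fold_alleles Uppercase alleles on read (default `TRUE`).
#' @param missing_tokens Strings treated as missing values.
#' @return An object of class `column_dialect`.
#' @seealso [sumstats_dialect()] for shipped presets, [read_dialect()] for
#'   YAML-defined dialects.
#' @export
column_dialect <- function(snp_id, effect_allele, other_allele, beta, se,
                           pvalue = NULL, chrom = NULL, pos = NULL,
                           n = NULL, eaf = NULL, fold_alleles = TRUE,
                           missing_tokens = c("NA", "", ".", "na", "NaN")) {
  mandatory <- list(snp_id = snp_id, effect_allele = effect_allele,
                    other_allele = other_allele, beta = beta, se = se)
  bad <- names(mandatory)[!vapply(mandatory, function(x)
    is.character(x) && length(x) == 1L && nzchar(x), logical(1))]
  if (length(bad))
    stop("mandatory dialect mappings missing or invalid: ",
         paste(bad, collapse = ", "))
  structure(list(map = c(mandatory,
                         list(pvalue = pvalue, chrom = chrom, pos = pos,
                              n = n, eaf = eaf)),
                 fold_alleles = isTRUE(fold_alleles),
                 missing_tokens = as.character(missing_tokens)),
            class = "column_dialect")
}

#' Shipped column-dialect presets
#'
#' Presets named after the four public consortium downloads the pipeline was
#' designed around (GLGC lipids, MAGIC glycemic traits, DIAGRAM T2D,
#' CARDIoGRAMplusC4D CAD), plus `"canonical"`, the package's own output
#' dialect. Header names are editable stand-ins for the era's distribution
#' files; use [column_dialect()] or [read_dialect()] when your copy differs.
#'
#' @param name One of `"canonical"`, `"glgc"`, `"magic"`, `"diagram"`,
#'   `"cardiogramplusc4d"`.
#' @return A `column_dialect`.
#' @export
sumstats_dialect <- function(name = c("canonical", "glgc", "magic",
                                      "diagram", "cardiogramplusc4d")) {
  name <- match.arg(name)
  switch(name,
    canonical = column_dialect(
      snp_id = "snp_id", effect_allele = "effect_allele",
      other_allele = "other_allele", beta = "beta", se = "se",
      pvalue = "pvalue", chrom = "chrom", pos = "pos", n = "n", eaf = "eaf"),
    glgc = column_dialect(
      snp_id = "rsid", effect_allele = "A1", other_allele = "A2",
      beta = "beta", se = "se", pvalue = "P-value", chrom = "chr",
      pos = "pos", n = "N", eaf = "Freq.A1"),
    magic = column_dialect(
      snp_id = "snp", effect_allele = "effect_allele",
      other_allele = "other_allele", beta = "effect", se = "stderr",
      pvalue = "pvalue", eaf = "maf"),
    diagram = column_dialect(
      snp_id = "SNP", effect_allele = "RISK_ALLELE",
      other_allele = "OTHER_ALLELE", beta = "LOG_ODDS", se = "SE",
      pvalue = "P_VALUE", chrom = "CHROMOSOME", pos = "POSITION"),
    cardiogramplusc4d = column_dialect(
      snp_id = "markername", effect_allele = "effect_allele",
      other_allele = "noneffect_allele", beta = "beta", se = "se_dgc",
      pvalue = "p_dgc", chrom = "chr", pos = "bp_hg19",
      eaf = "effect_allele_freq"))
}

#' Read a column dialect from a YAML config file
#'
#' The file holds one mapping with keys among `snp_id`, `effect_allele`,
#' `other_allele`, `beta`, `se`, `pvalue`, `chrom`, `pos`, `n`, `eaf`,
#' `fold_alleles`, `missing_tokens`.
#'
#' @param path Path to a YAML file.
#' @return A `column_dialect`.
#' @export
read_dialect <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- cfg[names(cfg) %in% c("snp_id", "effect_allele", "other_allele",
                                "beta", "se", "pvalue", "chrom", "pos",
                                "n", "eaf", "fold_alleles", "missing_tokens")]
  do.call(column_dialect, args)
}

canonical_cols <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                    "beta", "se", "pvalue", "n", "eaf", "trait_id")

new_sumstats <- function(df, meta, report = NULL) {
  rownames(df) <- NULL
  structure(df, class = c("sumstats", "data.frame"),
            trait_meta = meta, parse_report = report)
}

#' Read a GWAS summary-statistics table
#'
#' Reads a whitespace- or tab-delimited table with header in the column
#' dialect given, validates every row, and returns the valid rows as a
#' `sumstats` data frame (canonical columns: snp_id, chrom, pos,
#' effect_allele, other_allele, beta, se, pvalue, n, eaf, trait_id). Rows
#' violating the record invariants (non-positive SE, malformed or identical
#' alleles, P outside (0,1], missing beta/SE, missing N) are dropped and
#' counted in the parse report; duplicated SNP ids are resolved by keeping
#' the row with the smallest P value. A missing P value is derived from
#' beta/se as a two-sided normal tail.
#'
#' @param path Path to the file.
#' @param dialect A [column_dialect()] (default: canonical).
#' @param meta A [trait_meta()].
#' @return A `sumstats` data frame; see [parse_report()] for drop counts.
#' @export
read_summary_stats <- function(path, dialect = sumstats_dialect("canonical"),
                               meta = trait_meta("trait")) {
  stopifnot(inherits(dialect, "column_dialect"), inherits(meta, "trait_meta"))
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE,
                      na.strings = dialect$missing_tokens,
                      colClasses = "character", comment.char = ""),
    error = function(e) stop("could not parse ", path, ": ",
                             conditionMessage(e)))
  if (nrow(raw) == 0L && ncol(raw) == 0L) stop("empty file: ", path)
  map <- dialect$map
  mandatory <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  for (f in mandatory)
    if (!map[[f]] %in% names(raw))
      stop("mandatory column '", map[[f]], "' (", f, ") absent from ", path)

  pull <- function(field) {
    col <- map[[field]]
    if (is.null(col) || !col %in% names(raw)) rep(NA_character_, nrow(raw))
    else raw[[col]]
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  df <- data.frame(
    snp_id = pull("snp_id"),
    chrom = pull("chrom"),
    pos = suppressWarnings(as.integer(num(pull("pos")))),
    effect_allele = pull("effect_allele"),
    other_allele = pull("other_allele"),
    beta = num(pull("beta")),
    se = num(pull("se")),
    pvalue = num(pull("pvalue")),
    n = num(pull("n")),
    eaf = num(pull("eaf")),
    stringsAsFactors = FALSE)
  df$trait_id <- meta$trait_id
  if (dialect$fold_alleles) {
    df$effect_allele <- toupper(df$effect_allele)
    df$other_allele <- toupper(df$other_allele)
  }
  n_total <- nrow(df)
  if (n_total == 0L) stop("no data rows in ", path)

  # fill N from metadata when the file has none
  if (all(is.na(df$n))) {
    fallback <- meta$default_n
    if (is.null(fallback) && !is.null(meta$n_cases) &&
        !is.null(meta$n_controls))
      fallback <- meta$n_cases + meta$n_controls
    if (!is.null(fallback)) df$n <- fallback
  }

  drop <- list()
  mark <- function(bad, reason) {
    bad[is.na(bad)] <- FALSE
    drop[[reason]] <<- sum(bad & keep)
    keep <<- keep & !bad
  }
  keep <- rep(TRUE, n_total)
  mark(is.na(df$snp_id), "missing_snp_id")
  mark(is.na(df$beta) | is.na(df$se), "missing_beta_se")
  mark(df$se <= 0, "se_nonpositive")
  valid_allele <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  mark(!(valid_allele(df$effect_allele) & valid_allele(df$other_allele)) |
         df$effect_allele == df$other_allele, "bad_alleles")
  mark(!is.na(df$pvalue) & (df$pvalue <= 0 | df$pvalue > 1), "bad_pvalue")
  mark(is.na(df$n) | df$n <= 0, "missing_n")
  eaf_bad <- !is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1)
  df$eaf[eaf_bad] <- NA_real_

  df <- df[keep, canonical_cols]
  # derive missing P from beta/se
  miss_p <- is.na(df$pvalue)
  df$pvalue[miss_p] <- 2 * stats::pnorm(-abs(df$beta[miss_p] / df$se[miss_p]))

  # duplicate SNPs: keep the smallest P (open choice, logged in the report)
  n_dup <- 0L
  if (anyDuplicated(df$snp_id)) {
    ord <- order(df$pvalue, seq_len(nrow(df)))
    df <- df[ord, ]
    dup <- duplicated(df$snp_id)
    n_dup <- sum(dup)
    df <- df[!dup, ]
    df <- df[order(match(df$snp_id, unique(df$snp_id))), ]
  }
  drop$duplicate_snp <- n_dup
  report <- list(n_rows = n_total, n_kept = nrow(df),
                 n_dropped = n_total - nrow(df),
                 dropped = unlist(drop), duplicates_resolved = n_dup,
                 eaf_set_missing = sum(eaf_bad))
  new_sumstats(df, meta, report)
}

#' Build a summary-statistics table from an in-memory data frame
#'
#' For data already in R: validates the canonical columns, derives missing
#' P values from beta/se, and attaches the trait metadata. Unlike
#' [read_summary_stats()] this does not drop rows; invalid rows raise an
#' error.
#'
#' @param df Data frame with at least snp_id, effect_allele, other_allele,
#'   beta, se; chrom, pos, pvalue, n, eaf are optional (filled with NA or
#'   derived).
#' @param meta A [trait_meta()].
#' @return A `sumstats` data frame.
#' @export
as_sumstats <- function(df, meta = trait_meta("trait")) {
  need <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)),
                                    collapse = ", "))
  for (col in c("chrom", "pos", "pvalue", "n", "eaf"))
    if (!col %in% names(df)) df[[col]] <- NA
  if (all(is.na(df$n))) {
    fallback <- meta$default_n
    if (is.null(fallback) && !is.null(meta$n_cases) &&
        !is.null(meta$n_controls))
      fallback <- meta$n_cases + meta$n_controls
    if (!is.null(fallback)) df$n <- fallback
  }
  if (any(is.na(df$beta) | is.na(df$se) | df$se <= 0))
    stop("beta/se missing or se non-positive")
  if (any(df$effect_allele == df$other_allele))
    stop("effect and other allele identical")
  miss <- is.na(df$pvalue)
  df$pvalue[miss] <- 2 * stats::pnorm(-abs(df$beta[miss] / df$se[miss]))
  df$trait_id <- meta$trait_id
  new_sumstats(df[canonical_cols], meta)
}

#' Parse report of a summary-statistics read
#'
#' @param x A `sumstats` object returned by [read_summary_stats()].
#' @return A list with `n_rows`, `n_kept`, `n_dropped`, per-reason `dropped`
#'   counts and `duplicates_resolved`.
#' @export
parse_report <- function(x) attr(x, "parse_report")

#' Write a table of records or results
#'
#' Tab-delimited with header, canonical column names and full numeric
#' precision; `sumstats` tables round-trip through [read_summary_stats()]
#' with the `"canonical"` dialect.
#'
#' @param x A data frame (e.g. a `sumstats` table or a per-SNP result table).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  df <- as.data.frame(x)
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

ld_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Build a pairwise LD table
#'
#' Symmetric lookup of r-squared values. Self-pairs are implicitly 1 and
#' absent pairs 0. Duplicated pairs are resolved by keeping the maximum
#' r-squared, with a warning.
#'
#' @param snp_a,snp_b Character vectors of SNP ids.
#' @param r2 Numeric vector of r-squared values in \[0, 1\].
#' @return An object of class `ld_table`.
#' @export
ld_table <- function(snp_a = character(), snp_b = character(),
                     r2 = numeric()) {
  stopifnot(length(snp_a) == length(snp_b), length(snp_b) == length(r2))
  if (any(is.na(r2)) || any(r2 < 0 | r2 > 1))
    stop("r2 values must lie in [0, 1]")
  self <- snp_a == snp_b
  snp_a <- snp_a[!self]; snp_b <- snp_b[!self]; r2 <- r2[!self]
  key <- ld_key(snp_a, snp_b)
  if (anyDuplicated(key)) {
    warning("duplicate LD pairs resolved by keeping the maximum r2")
    ord <- order(key, -r2)
    keep <- !duplicated(key[ord])
    key <- key[ord][keep]; r2 <- r2[ord][keep]
  }
  structure(list(key = key, r2 = r2), class = "ld_table")
}

#' Read a pairwise LD table
#'
#' Three-column delimited file (snp_a, snp_b, r2), with or without a header
#' line.
#'
#' @param path Path to the file.
#' @return An `ld_table`.
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "[ \t]+")[[1]]
  has_header <- length(first) >= 3 &&
    is.na(suppressWarnings(as.numeric(first[3])))
  df <- utils::read.table(path, header = has_header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("LD table must have three columns")
  r2 <- suppressWarnings(as.numeric(df[[3]]))
  if (any(is.na(r2))) stop("non-numeric r2 values in ", path)
  ld_table(as.character(df[[1]]), as.character(df[[2]]), r2)
}

#' Look up pairwise r-squared values
#'
#' Vectorized and symmetric; self-pairs return 1, absent pairs 0.
#'
#' @param ld An `ld_table`.
#' @param a,b Character vectors of SNP ids (recycled to a common length).
#' @return Numeric vector of r-squared values.
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_table"))
  r2 <- ld$r2[match(ld_key(a, b), ld$key)]
  r2[is.na(r2)] <- 0
  r2[a == b] <- 1
  r2
}

#' Read gene intervals
#'
#' Accepts BED (no header, 0-based half-open; converted to 1-based inclusive
#' on read) or a 4-column TSV with header `gene`, `chrom`, `start`, `end`
#' (already 1-based inclusive).
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"bed"` or `"tsv"`.
#' @return A data frame with columns gene, chrom, start, end.
#' @export
read_gene_intervals <- function(path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  if (format == "bed") {
    df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 4L) stop("BED file needs chrom, start, end, name")
    out <- data.frame(gene = as.character(df[[4]]),
                      chrom = as.character(df[[1]]),
                      start = as.integer(df[[2]]) + 1L,
                      end = as.integer(df[[3]]),
                      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("gene", "chrom", "start", "end")
    if (!all(need %in% names(df)))
      stop("gene TSV must have columns: ", paste(need, collapse = ", "))
    out <- data.frame(gene = as.character(df$gene),
                      chrom = as.character(df$chrom),
                      start = as.integer(df$start), end = as.integer(df$end),
                      stringsAsFactors = FALSE)
  }
  if (any(out$start > out$end)) stop("gene interval with start > end")
  out
}

#' Read a static drug-gene annotation table
#'
#' Three-column TSV with header `gene`, `drug`, `interaction` (values
#' `pharmacodynamic` or `other`); (gene, drug) pairs must be unique.
#'
#' @param path Path to the file.
#' @return A data frame with columns gene, drug, interaction.
#' @export
read_drug_annotations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene", "drug", "interaction")
  if (!all(need %in% names(df)))
    stop("drug table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df[c("gene", "drug")]))
    stop("duplicate (gene, drug) pairs in drug table")
  df$interaction <- ifelse(df$interaction == "pharmacodynamic",
                           "pharmacodynamic", "other")
  df[need]
}

#' @export
print.sumstats <- function(x, ...) {
  meta <- attr(x, "trait_meta")
  cat(sprintf("Summary statistics for trait '%s' (%s): %d SNPs\n",
              meta$trait_id, meta$kind, nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
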