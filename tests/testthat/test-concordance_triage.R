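genes2 <- data.frame(gene = c("G1", "G2"), chrom = "1",
                     start = c(100L, 300L), end = c(200L, 400L),
                     stringsAsFactors = FALSE)

test_that("SNPs map to containing or nearest gene with stated tie rules", {
  snps <- data.frame(snp_id = c("s1", "s2", "s3", "s4"),
                     chrom = c("1", "1", "1", "9"),
                     pos = c(150L, 250L, 260L, 5L),
                     stringsAsFactors = FALSE)
  la <- assign_loci(snps, genes2)
  expect_equal(unname(la$assignment["s1"]), "G1")  # containment
  expect_equal(unname(la$assignment["s2"]), "G1")  # 50/50 tie -> smaller start
  expect_equal(unname(la$assignment["s3"]), "G2")  # 60 vs 40 -> nearest
  expect_true(is.na(la$assignment["s4"]))          # chromosome without genes
  expect_equal(la$n_unassigned, 1L)
  expect_equal(sort(la$members$G1), c("s1", "s2"))
})

test_that("binomial point probabilities match exact rational values", {
  expect_equal(binomial_point_probability(25, 22), 2300 / 2^25,
               tolerance = 1e-12)
  expect_equal(binomial_point_probability(6, 6), 1 / 64)
  expect_equal(binomial_point_probability(2, 1), 0.5)
  expect_equal(binomial_point_probability(19, 9), 92378 / 524288,
               tolerance = 1e-12)
  expect_equal(binomial_point_probability(19, 9), 0.176197,
               tolerance = 1e-6)
  for (n in c(1, 7, 18, 30))
    expect_equal(sum(vapply(0:n, function(k)
      binomial_point_probability(n, k), numeric(1))), 1,
      tolerance = 1e-12)
  expect_error(binomial_point_probability(5, 6), "k <= n")

  # labelled tail variants
  expect_equal(binomial_point_probability(6, 6, "one_sided"), 1 / 64)
  expect_equal(binomial_point_probability(6, 6, "two_sided"), 2 / 64)
  expect_equal(binomial_point_probability(3, 0, "one_sided"), 1 / 8)
})

test_that("fisher_exact matches enumeration and the cross-product OR", {
  f <- fisher_exact(3, 1, 1, 3)
  expect_equal(f$odds_ratio, 9)
  expect_equal(f$pvalue, 34 / 70, tolerance = 1e-9)

  g <- fisher_exact(0, 5, 5, 0)
  expect_equal(g$odds_ratio, 0)
  expect_equal(g$pvalue, 2 / 252, tolerance = 1e-9)

  h <- fisher_exact(2, 2, 2, 2)
  expect_equal(h$odds_ratio, 1)
  expect_equal(h$pvalue, 1)

  expect_equal(fisher_exact(3, 0, 0, 3)$odds_ratio, Inf)
  expect_error(fisher_exact(0, 0, 0, 0), "zero")
  expect_error(fisher_exact(1.5, 1, 1, 1), "integers")
})

toy_panel <- function() {
  # three loci; qualifying SNPs engineered so locus representatives have
  # outcome betas (+, +, -)
  expo <- make_ss(snp_id = sprintf("s%d", 1:6), chrom = "1",
                  pos = c(110L, 150L, 310L, 350L, 610L, 650L),
                  effect_allele = "A", other_allele = "G",
                  beta = 0.3, se = 0.02, pvalue = 1e-9, trait = "LDL")
  outc <- make_ss(snp_id = sprintf("s%d", 1:6), chrom = "1",
                  pos = c(110L, 150L, 310L, 350L, 610L, 650L),
                  effect_allele = "A", other_allele = "G",
                  beta = c(0.2, -0.1, 0.15, 0.3, -0.25, 0.1),
                  se = 0.05,
                  pvalue = c(0.001, 0.2, 0.003, 0.04, 0.002, 0.3),
                  trait = "CAD", kind = "binary", n = 2e5)
  build_panel(expo, outc)
}

genes3 <- data.frame(gene = c("L1", "L2", "L3"), chrom = "1",
                     start = c(100L, 300L, 600L), end = c(200L, 400L, 700L),
                     stringsAsFactors = FALSE)

test_that("concordance takes one representative per locus by outcome P", {
  panel <- toy_panel()
  la <- assign_loci(panel$snps, genes3)
  res <- concordance_test(panel, la, "CAD")
  expect_equal(res$n_loci, 3L)
  expect_equal(res$k_concordant, 2L)  # representatives s1 (+), s3 (+), s5 (-)
  expect_equal(res$binomial_p, choose(3, 2) / 8)
  expect_equal(res$directions$snp_id, c("s1", "s3", "s5"))
  expect_equal(res$directions$outcome_sign, c(1L, 1L, -1L))
  expect_true(all(res$directions$exposure_sign == 1L))

  # input order invariance
  panel2 <- toy_panel()
  perm <- c(4, 2, 6, 1, 3, 5)
  panel2$cells <- panel2$cells[sample(nrow(panel2$cells)), ]
  panel2$snps <- panel2$snps[perm, ]
  res2 <- concordance_test(panel2, assign_loci(panel2$snps, genes3), "CAD")
  expect_equal(res2$directions, res$directions)

  # all-concordant six loci reduce to the (6, 6) point mass
  expect_equal(binomial_point_probability(6, 6), 0.015625)
})

test_that("zero outcome beta at the representative drops the locus", {
  panel <- toy_panel()
  panel$cells$beta[panel$cells$trait_id == "CAD" &
                     panel$cells$snp_id == "s1"] <- 0
  la <- assign_loci(panel$snps, genes3)
  expect_warning(res <- concordance_test(panel, la, "CAD"), "zero")
  expect_equal(res$n_loci, 2L)
  expect_error(concordance_test(panel, la, "CAD", outcome_p = 1e-10),
               "no locus")
})

test_that("locus enrichment builds the stated 2x2 tables", {
  cp <- c(setNames(rep(0.001, 5), sprintf("in%d", 1:5)),
          setNames(c(rep(0.001, 5), rep(0.5, 90)), sprintf("bg%d", 1:95)))
  genes <- data.frame(gene = c("LOC", "OTHER"), chrom = "1",
                      start = c(1L, 1000L), end = c(10L, 991000L),
                      stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = names(cp), chrom = "1",
                     pos = c(1:5, seq(1000L, by = 10000L,
                                      length.out = 95)),
                     stringsAsFactors = FALSE)
  la <- assign_loci(snps, genes)
  enr <- locus_enrichment(cp, la, candidate_genes = "LOC")
  expect_equal(enr$a, 5); expect_equal(enr$b, 0)
  expect_equal(enr$c, 5); expect_equal(enr$d, 90)
  expect_equal(enr$fisher_p, oracle_fisher_p(5, 0, 5, 90),
               tolerance = 1e-9)
  expect_true(enr$over_represented)

  # a locus at exactly the background rate is unremarkable
  cp2 <- setNames(rep(c(0.01, 0.8), 50), sprintf("s%d", 1:100))
  snps2 <- data.frame(snp_id = names(cp2), chrom = "1",
                      pos = c(1:10, seq(1000L, by = 10000L,
                                        length.out = 90)),
                      stringsAsFactors = FALSE)
  la2 <- assign_loci(snps2, genes)
  enr2 <- locus_enrichment(cp2, la2, candidate_genes = "LOC")
  expect_equal(enr2$odds_ratio, 1)
  expect_false(enr2$over_represented)

  # loci without pruned SNPs are skipped
  enr3 <- locus_enrichment(cp2, la2, candidate_genes = c("LOC", "GHOST"))
  expect_equal(enr3$gene, c("LOC"))
})

test_that("triage routes intersect thresholds with the Fisher verdict", {
  # one locus qualifying for route A thresholds but over-represented:
  # composite-significant everywhere in-locus against a null background
  n_bg <- 60
  ids <- c(sprintf("q%d", 1:4), sprintf("n%d", 1:n_bg))
  pos <- c(110L, 130L, 150L, 170L,
           seq(10000L, by = 5000L, length.out = n_bg))
  expo <- make_ss(snp_id = ids, chrom = "1", pos = pos,
                  effect_allele = "A", other_allele = "G",
                  beta = c(rep(0.3, 4), rep(0.01, n_bg)), se = 0.02,
                  pvalue = c(rep(1e-9, 4), rep(0.5, n_bg)), trait = "LDL")
  outc <- make_ss(snp_id = ids, chrom = "1", pos = pos,
                  effect_allele = "A", other_allele = "G",
                  beta = 0.2, se = 0.05,
                  pvalue = c(rep(0.01, 4), rep(0.6, n_bg)),
                  trait = "CAD", kind = "binary", n = 2e5)
  panel <- build_panel(expo, outc)
  genes <- data.frame(gene = c("HIT", "BG"), chrom = "1",
                      start = c(100L, 9000L), end = c(200L, 400000L),
                      stringsAsFactors = FALSE)
  la <- assign_loci(panel$snps, genes)
  comp_p <- c(rep(0.3, 3), 0.001, rep(0.9, n_bg))  # q4 composite-assoc
  composite <- structure(list(
    snps = data.frame(snp_id = ids, pvalue = comp_p, z = 0,
                      stringsAsFactors = FALSE)),
    class = "composite_result")

  res <- triage(panel, composite, pruned = ids, loci = la)
  expect_equal(res$classification[res$gene == "HIT"],
               "glycemia_neutral_candidate")

  # flip the locus to dense composite association: over-represented and
  # with a qualifying associated SNP -> glycemic liability
  composite$snps$pvalue[1:4] <- 1e-4
  res2 <- triage(panel, composite, pruned = ids, loci = la)
  expect_equal(res2$classification[res2$gene == "HIT"],
               "glycemic_liability")
  expect_true(res2$over_represented[res2$gene == "HIT"])

  # over-represented locus whose qualifying SNPs are all composite-null is
  # indeterminate (rule intersection): add in-locus non-qualifying SNPs
  # that carry the composite association
  ids4 <- c(ids, sprintf("x%d", 1:4))
  expo4 <- make_ss(snp_id = ids4, chrom = "1",
                   pos = c(pos, 181L, 185L, 190L, 195L),
                   effect_allele = "A", other_allele = "G",
                   beta = c(rep(0.3, 4), rep(0.01, n_bg), rep(0.01, 4)),
                   se = 0.02,
                   pvalue = c(rep(1e-9, 4), rep(0.5, n_bg + 4)),
                   trait = "LDL")
  outc4 <- make_ss(snp_id = ids4, chrom = "1",
                   pos = c(pos, 181L, 185L, 190L, 195L),
                   effect_allele = "A", other_allele = "G",
                   beta = 0.2, se = 0.05,
                   pvalue = c(rep(0.01, 4), rep(0.6, n_bg + 4)),
                   trait = "CAD", kind = "binary", n = 2e5)
  panel4 <- build_panel(expo4, outc4)
  la4 <- assign_loci(panel4$snps, genes)
  composite4 <- structure(list(
    snps = data.frame(snp_id = ids4,
                      pvalue = c(rep(0.3, 4), rep(0.9, n_bg),
                                 rep(1e-4, 4)),
                      z = 0, stringsAsFactors = FALSE)),
    class = "composite_result")
  res3 <- triage(panel4, composite4, pruned = ids4, loci = la4)
  hit3 <- res3[res3$gene == "HIT", ]
  expect_true(hit3$over_represented)
  expect_false(hit3$any_composite_assoc)
  expect_equal(hit3$classification, "indeterminate")

  # classifications are mutually exclusive levels over candidate loci
  expect_true(all(res$classification %in%
                    c("glycemia_neutral_candidate", "glycemic_liability",
                      "indeterminate")))
})

test_that("drug annotations join by gene with a pharmacodynamic flag", {
  ds <- simulate_gwas(triage_fixture_config(seed = 5))
  panel <- build_sim_panel(ds)
  comp <- build_composite(panel,
                          composite_config(default_glycemic_traits))
  pruned <- clump(panel_trait(panel, "LDL", with_positions = TRUE),
                  ds$ld, 0.5, 250)
  la <- assign_loci(panel$snps, ds$genes)
  res <- triage(panel, comp, pruned, la, drugs = ds$drugs)
  joined <- res[res$drugs != "", ]
  expect_gt(nrow(joined), 0)
  i <- match(joined$gene[1], ds$drugs$gene)
  expect_equal(joined$drugs[1], ds$drugs$drug[i])
  expect_equal(joined$pharmacodynamic[1],
               ds$drugs$interaction[i] == "pharmacodynamic")
})
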