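test_that("meta_stderr evaluates the inverse-variance closed form", {
  m <- meta_stderr(c(0.1, 0.3), c(0.1, 0.1))
  expect_equal(m$beta, 0.2)
  expect_equal(m$se, sqrt(1 / 200), tolerance = 1e-12)
  expect_equal(m$se, 0.070711, tolerance = 1e-5)
  expect_equal(m$z, 2.828427, tolerance = 1e-6)
  expect_equal(m$pvalue, 2 * pnorm(-sqrt(8)), tolerance = 1e-12)
  expect_equal(m$pvalue, 0.004678, tolerance = 1e-4)

  one <- meta_stderr(0.4, 0.1)
  expect_equal(one$beta, 0.4)
  expect_equal(one$se, 0.1)

  sym <- meta_stderr(c(0.1, -0.1), c(0.2, 0.2))
  expect_equal(sym$beta, 0)
  expect_equal(sym$pvalue, 1)

  # shared kernel with pool_fixed_effects
  set.seed(3)
  b <- rnorm(7); s <- runif(7, 0.05, 0.5)
  expect_identical(meta_stderr(b, s)$beta, pool_fixed_effects(b, s)$beta)
  expect_identical(meta_stderr(b, s)$se, pool_fixed_effects(b, s)$se)
})

test_that("meta_samplesize weights Z scores by sqrt(n)", {
  expect_equal(meta_samplesize(c(1, 1), c(1000, 1000))$z, sqrt(2),
               tolerance = 1e-9)
  expect_equal(meta_samplesize(2.5, 5000)$z, 2.5)
  expect_equal(meta_samplesize(c(1, -1), c(400, 400))$z, 0)
  expect_error(meta_samplesize(numeric(0), numeric(0)), "no studies")
})

test_that("kendall_tau is tie-corrected and drops incomplete pairs", {
  expect_equal(kendall_tau(1:5, 1:5), 1.0)
  expect_equal(kendall_tau(1:5, 5:1), -1.0)
  expect_equal(kendall_tau(c(1, 2, 3), c(1, 3, 2)), 1 / 3,
               tolerance = 1e-9)
  expect_equal(kendall_tau(c(1, 2, NA, 3), c(1, 3, 0, 2)), 1 / 3,
               tolerance = 1e-9)
  expect_error(kendall_tau(c(1, NA), c(NA, 1)), "complete pairs")

  set.seed(21)
  for (i in 1:15) {
    x <- sample(1:6, 12, replace = TRUE)  # heavy ties
    y <- x + sample(-2:2, 12, replace = TRUE)
    expect_equal(kendall_tau(x, y), oracle_tau_b(x, y), tolerance = 1e-12)
  }
})

test_that("genomic lambda is the median chi-square ratio", {
  expect_equal(genomic_lambda(1.0), 1 / 0.4549364, tolerance = 1e-6)
  expect_equal(genomic_lambda(1.0), 2.198108, tolerance = 1e-6)
  zs <- c(-1, 0.2, sqrt(qchisq(0.5, 1)), 3, -2)
  expect_equal(genomic_lambda(zs),
               median(zs^2) / qchisq(0.5, 1))
})

test_that("screen_traits excludes later traits at or above the tau bound", {
  set.seed(8)
  z <- matrix(rnorm(400), ncol = 4,
              dimnames = list(NULL, c("A", "B", "C", "D")))
  z[, "C"] <- z[, "A"]  # duplicated trait
  cfg <- composite_config(c("A", "B", "C", "D"))
  rep <- screen_traits(z, cfg)
  expect_equal(rep$excluded, "C")
  expect_equal(rep$triggers$partner, "A")
  expect_equal(rep$tau["A", "C"], 1.0)
  expect_true(isSymmetric(rep$tau))
  expect_equal(unname(diag(rep$tau)), rep(1, 4))

  # the rule is inclusive: a pair exactly at the threshold is excluded
  tau_bd <- kendall_tau(z[, "B"], z[, "D"])
  cfg2 <- composite_config(c("B", "D"),
                           tau_exclusion_threshold = abs(tau_bd))
  expect_equal(screen_traits(z, cfg2)$excluded, "D")

  # independent traits are all retained
  z2 <- matrix(rnorm(300), ncol = 3,
               dimnames = list(NULL, c("A", "B", "C")))
  rep2 <- screen_traits(z2, composite_config(c("A", "B", "C")))
  expect_equal(rep2$retained, c("A", "B", "C"))
})

test_that("build_composite equals row-wise meta and honours the scheme", {
  expo <- make_ss(snp_id = c("rs1", "rs2", "rs3"), chrom = "1",
                  pos = c(1L, 2L, 3L), effect_allele = "A",
                  other_allele = "G", beta = c(0.1, 0.2, 0.3), se = 0.01,
                  trait = "LDL")
  t1 <- make_ss(snp_id = c("rs1", "rs2", "rs3"), chrom = "1",
                pos = c(1L, 2L, 3L), effect_allele = "A",
                other_allele = "G", beta = c(0.1, -0.2, 0.05),
                se = c(0.1, 0.05, 0.2), trait = "G1", n = 1000)
  t2 <- make_ss(snp_id = c("rs1", "rs2"), chrom = "1", pos = c(1L, 2L),
                effect_allele = "A", other_allele = "G",
                beta = c(0.3, 0.1), se = c(0.1, 0.1), trait = "G2",
                n = 4000)
  panel <- build_panel(expo, list(t1, t2))
  cfg <- composite_config(c("G1", "G2"))
  comp <- build_composite(panel, cfg, screen = FALSE)

  r1 <- meta_stderr(c(0.1, 0.3), c(0.1, 0.1))
  row1 <- comp$snps[comp$snps$snp_id == "rs1", ]
  expect_equal(row1$beta, r1$beta)
  expect_equal(row1$se, r1$se)
  expect_equal(row1$pvalue, r1$pvalue)
  # rs3 has a single contributing trait
  expect_equal(comp$snps$n_traits_contributing,
               c(2, 2, 1))
  expect_equal(comp$snps$beta[3], 0.05)

  ss <- build_composite(panel, composite_config(c("G1", "G2"),
                                                scheme = "samplesize"),
                        screen = FALSE)
  z1 <- meta_samplesize(c(0.1 / 0.1, 0.3 / 0.1), c(1000, 4000))
  expect_equal(ss$snps$z[1], z1$z)
  expect_true(all(is.na(ss$snps$beta)))
})

test_that("a duplicated trait inflates lambda and is screened off", {
  ds <- simulate_gwas(sim_config(n_snps = 1500, n_blocks = 30,
                                 duplicate_trait_of = "FI", seed = 14))
  panel <- build_sim_panel(ds)
  with_dup <- composite_config(c(default_glycemic_traits, "HOMA_IR"))
  without <- composite_config(default_glycemic_traits)
  lam_with <- build_composite(panel, with_dup, screen = FALSE)$lambda_gc
  lam_wo <- build_composite(panel, without, screen = FALSE)$lambda_gc
  expect_gt(lam_with, lam_wo)

  # with screening on, the duplicate is dropped and lambda recovers
  screened <- build_composite(panel, with_dup)
  expect_equal(screened$screen$excluded, "HOMA_IR")
  expect_equal(screened$lambda_gc, lam_wo)
})

test_that("the composite is standard normal under the global null", {
  ds <- simulate_gwas(sim_config(n_snps = 3000, n_blocks = 3000,
                                 within_block_rho = 0, neutral_blocks = 0,
                                 liable_blocks = 0, seed = 33))
  panel <- build_sim_panel(ds, outcomes = default_glycemic_traits)
  comp <- build_composite(panel,
                          composite_config(default_glycemic_traits),
                          screen = FALSE)
  expect_gt(comp$lambda_gc, 0.9)
  expect_lt(comp$lambda_gc, 1.1)
  expect_equal(comp$n_significant, 0)
  ks <- suppressWarnings(ks.test(comp$snps$z, "pnorm"))
  expect_lt(unname(ks$statistic), 0.03)
})

test_that("empty trait sets and all-screened panels are errors", {
  expect_error(composite_config("A"), "traits")
  z <- matrix(rnorm(40), ncol = 2, dimnames = list(NULL, c("A", "B")))
  z[, "B"] <- z[, "A"]
  expo <- make_ss(snp_id = sprintf("rs%d", 1:20), chrom = "1",
                  pos = 1:20, effect_allele = "A", other_allele = "G",
                  beta = abs(z[, 1]), se = 1, trait = "LDL")
  a <- make_ss(snp_id = sprintf("rs%d", 1:20), chrom = "1", pos = 1:20,
               effect_allele = "A", other_allele = "G", beta = z[, 1],
               se = 1, trait = "A", n = 10)
  panel <- build_panel(expo, a)
  expect_error(build_composite(panel, composite_config(c("A", "B"))),
               "absent from panel")
})
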