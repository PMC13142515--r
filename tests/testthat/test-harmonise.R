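test_that("major-ancestry MAF follows the population-choice rules", {
  freq <- data.frame(variant_id = c("1_10_A_G", "1_20_C_T"),
                     NFE = c(0.8, 0.3), EAS = c(0.5, 0.6),
                     stringsAsFactors = FALSE)
  r <- annotate_major_ancestry_maf(list(NFE = 1.0), "1_10_A_G", freq)
  expect_equal(r$maf, 0.2)
  expect_false(r$failed)

  r <- annotate_major_ancestry_maf(list(EAS = 0.5, NFE = 0.5), "1_20_C_T", freq)
  expect_identical(r$population, "NFE")
  expect_equal(r$maf, 0.3)

  r <- annotate_major_ancestry_maf(list(EAS = 0.7, NFE = 0.3), "1_20_C_T", freq)
  expect_identical(r$population, "EAS")
  expect_equal(r$maf, 0.4)

  r <- annotate_major_ancestry_maf(list(NFE = 1.0), "1_99_A_G", freq)
  expect_true(r$failed)
  expect_true(is.na(r$maf))

  expect_error(annotate_major_ancestry_maf(list(), "1_10_A_G", freq), "empty")
})

test_that("effect rescaling matches the closed formulas and null limit", {
  r <- rescale_effect(p = 0.05, sign_char = "+", n = 1e4, f = 0.5,
                      trait_type = "quantitative")
  expect_equal(r$se_hat, 1 / sqrt(5000), tolerance = 1e-12)
  expect_equal(r$se_hat, 0.014142, tolerance = 1e-4)

  r1 <- rescale_effect(p = 1, sign_char = "+", n = 1e4, f = 0.3,
                       trait_type = "quantitative")
  expect_equal(r1$beta_resc, 0)

  # binary-trait standard error carries the K(1-K) factor
  rb <- rescale_effect(p = 1e-10, sign_char = "-", n = 5e4, f = 0.2, K = 0.25,
                       trait_type = "binary")
  expect_equal(rb$se_hat, 1 / sqrt(2 * 5e4 * 0.2 * 0.8 * 0.25 * 0.75),
               tolerance = 1e-12)
  expect_lt(rb$beta_resc, 0)

  # unknown sign: magnitude only, excluded from direction analyses
  ru <- rescale_effect(p = 1e-10, sign_char = "unknown", n = 5e4, f = 0.2,
                       trait_type = "quantitative")
  expect_false(ru$direction_usable)
  expect_gt(ru$beta_resc, 0)

  expect_error(rescale_effect(p = 0, sign_char = "+", n = 1e4, f = 0.5,
                              trait_type = "quantitative"), "log10_p")
})

test_that("rescaling round-trips simulated effects and survives underflow", {
  set.seed(42)
  for (i in 1:100) {
    n <- round(runif(1, 5e3, 5e5))
    f <- runif(1, 0.01, 0.5)
    beta <- rnorm(1, 0, 0.3)
    se <- 1 / sqrt(2 * n * f * (1 - f))
    z <- beta / se
    log10_p <- stats::pchisq(z^2, df = 1, lower.tail = FALSE,
                             log.p = TRUE) / log(10)
    r <- rescale_effect(sign_char = if (beta >= 0) "+" else "-", n = n, f = f,
                        trait_type = "quantitative", log10_p = log10_p)
    expect_equal(r$beta_resc, beta, tolerance = 1e-6)
  }
  # a p-value far below double-precision underflow still yields a finite Z
  r <- rescale_effect(sign_char = "+", n = 1e5, f = 0.25,
                      trait_type = "quantitative", log10_p = -400)
  expect_true(is.finite(r$z))
  expect_gt(r$z, 40)
})

test_that("power formula: boundary, monotonicity and invariances", {
  expect_equal(compute_power(0, 1e5, 0.3), 1e-8, tolerance = 1e-12)

  # strictly increasing below saturation, non-decreasing throughout
  betas <- seq(0.01, 0.12, by = 0.01)
  pw <- compute_power(betas, 5e4, 0.2)
  expect_true(all(diff(pw) > 0))
  expect_true(all(diff(compute_power(seq(0.1, 0.8, 0.1), 5e4, 0.2)) >= 0))

  expect_equal(compute_power(-0.3, 5e4, 0.2), compute_power(0.3, 5e4, 0.2))
  expect_equal(compute_power(0.3, 5e4, 0.2), compute_power(0.3, 5e4, 0.8))
  expect_true(all(pw >= 1e-8 & pw <= 1))
})

test_that("most severe consequence follows the fixed category order", {
  expect_identical(resolve_most_severe(c("enhancer", "PAV")), "PAV")
  expect_identical(resolve_most_severe("intergenic"), "intergenic")
  expect_identical(resolve_most_severe(c("promoter", "enhancer")), "promoter")
  expect_identical(resolve_most_severe(c("intergenic", "intragenic", "enhancer")),
                   "enhancer")
  expect_error(resolve_most_severe(character(0)), "at least one")
  expect_error(resolve_most_severe("frameshift"), "unknown")
})

test_that("lead-variant filtering keeps one representative CS per variant-trait", {
  df <- data.frame(
    cs_id = c("A", "B", "C", "D", "E"),
    lead_variant = c("v1", "v1", "v2", "v3", "v4"),
    trait_id = c("T1", "T1", "T1", "T2", "T3"),
    qualified = c(TRUE, TRUE, TRUE, TRUE, TRUE),
    replicated = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    lead_pip = c(0.9, 0.8, 0.49, 0.5, 0.9),
    abs_beta_resc = c(0.2, 0.5, 0.3, 0.1, 0.4),
    stringsAsFactors = FALSE)
  out <- filter_lead_variants_for_consequence_analysis(df)
  # B wins v1-T1 on |beta| 0.5 > 0.2; C dropped at PIP 0.49; E not replicated
  expect_setequal(out$cs_id, c("B", "D"))

  all_pass <- df[df$cs_id == "D", ]
  expect_identical(filter_lead_variants_for_consequence_analysis(all_pass)$cs_id,
                   "D")
})

test_that("replication needs a different cohort, publication or ancestry (GWAS)", {
  studies <- data.frame(
    study_id = c("S1", "S2", "S3", "Q1", "Q2"),
    cohort = c("BIOBANK_A", "BIOBANK_B", "BIOBANK_A", "X", "Y"),
    year = c(2020, 2020, 2020, 2021, 2022),
    stringsAsFactors = FALSE)
  studies$ancestry <- list(list(NFE = 1), list(NFE = 1), list(NFE = 1),
                           list(NFE = 1), list(NFE = 1))
  cs <- data.frame(
    cs_id = c("c1", "c2", "c3", "c4", "q1", "q2"),
    study_id = c("S1", "S2", "S3", "S3", "Q1", "Q2"),
    lead_variant = c("v1", "v1", "v2", "v2", "v9", "v9"),
    trait_id = c("T", "T", "U", "U", NA, NA),
    gene_id = c(NA, NA, NA, NA, "G1", "G1"),
    class = c("gwas", "gwas", "gwas", "gwas", "molqtl", "molqtl"),
    stringsAsFactors = FALSE)
  rep <- flag_replication(cs, studies)
  expect_true(rep[1] && rep[2])      # two cohorts, same trait
  expect_false(rep[3] || rep[4])     # twice within one study: not replicated
  expect_true(rep[5] && rep[6])      # molQTL lead-gene pair seen twice anywhere
})

test_that("study qualification enforces strict sample-size and prevalence bounds", {
  studies <- data.frame(
    study_id = paste0("S", 1:5),
    study_type = c("disease", "disease", "disease", "measurement", "measurement"),
    n = c(1000, 50000, 20000, 30000, 30000),
    n_cases = c(500, 40, 5000, NA, NA),
    is_quantitative = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    trait_class = c("", "", "", "", "protein"),
    stringsAsFactors = FALSE)
  q <- qualify_studies(studies)
  expect_false(q[1])  # n = 1000 exactly: "exceed" is strict
  expect_false(q[2])  # prevalence 0.0008 < 0.001
  expect_true(q[3])
  expect_true(q[4])
  expect_false(q[5])  # protein measurement excluded
})

test_that("credible-set qualification: MAC, |beta| and the rare-lead rule", {
  base <- data.frame(study_qualified = TRUE, n = 50000, maf = 0.3,
                     abs_beta_resc = 0.1, has_molqtl_coloc = FALSE,
                     has_pav = FALSE, replicated = FALSE)
  expect_true(qualify_credible_sets(base))

  rare <- transform(base, maf = 0.005)
  expect_false(qualify_credible_sets(rare))
  expect_true(qualify_credible_sets(transform(rare, has_pav = TRUE)))
  expect_true(qualify_credible_sets(transform(rare, has_molqtl_coloc = TRUE)))
  expect_true(qualify_credible_sets(transform(rare, replicated = TRUE)))

  expect_false(qualify_credible_sets(transform(base, abs_beta_resc = 3.0)))
  expect_false(qualify_credible_sets(transform(base, maf = 1e-4)))  # MAC 10 < 20

  # monotone: adding evidence never un-qualifies
  set.seed(1)
  for (i in 1:50) {
    row <- data.frame(study_qualified = TRUE, n = round(runif(1, 2000, 1e5)),
                      maf = runif(1, 1e-4, 0.5),
                      abs_beta_resc = runif(1, 0, 4),
                      has_molqtl_coloc = runif(1) < 0.5,
                      has_pav = runif(1) < 0.5, replicated = runif(1) < 0.5)
    before <- qualify_credible_sets(row)
    boosted <- transform(row, has_molqtl_coloc = TRUE, has_pav = TRUE,
                         replicated = TRUE)
    expect_true(!before || qualify_credible_sets(boosted))
  }
})

test_that("therapeutic-area assignment picks the priority area or falls back", {
  edges <- toy_ontology()
  expect_identical(assign_therapeutic_area("ovarian_cancer", edges),
                   "cancer or benign tumour")
  expect_identical(assign_therapeutic_area("childhood_asthma", edges),
                   "respiratory or thoracic disease")
  expect_identical(assign_therapeutic_area("orphan_term", edges), "other")
  expect_identical(assign_therapeutic_area("cancer or benign tumour", edges),
                   "cancer or benign tumour")
})
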