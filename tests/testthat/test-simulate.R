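test_that("LD genome construction: identity, determinism, PSD blocks", {
  g1 <- simulate_ld_genome(sim_config(seed = 3, n_ld_blocks = 1,
                                      variants_per_block = 1))
  expect_equal(unname(g1$ld[[1]]), matrix(1.0, 1, 1))

  ga <- simulate_ld_genome(sim_config(seed = 11, n_ld_blocks = 3,
                                      variants_per_block = 20))
  gb <- simulate_ld_genome(sim_config(seed = 11, n_ld_blocks = 3,
                                      variants_per_block = 20))
  expect_identical(ga$variants, gb$variants)
  expect_identical(ga$ld, gb$ld)

  g <- simulate_ld_genome(sim_config(seed = 5, n_ld_blocks = 10,
                                     variants_per_block = 50))
  for (R in g$ld) {
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
    expect_equal(diag(R), setNames(rep(1, nrow(R)), rownames(R)))
    expect_equal(R, t(R))
  }
  for (chrom in unique(g$variants$chromosome)) {
    pos <- g$variants$position[g$variants$chromosome == chrom]
    expect_true(all(diff(pos) > 0))
  }
})

test_that("null studies produce no spurious genome-wide significant hits", {
  cfg <- sim_config(seed = 2, n_ld_blocks = 10, variants_per_block = 100,
                    n_disease_studies = 1)
  genome <- simulate_ld_genome(cfg)
  null_truth <- list(signals = data.frame(trait_id = character(0),
                                          variant_id = character(0),
                                          beta = numeric(0)))
  hits <- 0L
  for (s in 1:5) {
    study <- list(study_id = paste0("NULL_", s), trait_id = "EFO_NULL",
                  n = 1e5, n_cases = NA_integer_, is_quantitative = TRUE)
    ss <- simulate_study_sumstats(genome, study, null_truth)
    hits <- hits + sum(ss$p_value <= 1e-8)
  }
  # 5000 null tests at alpha = 1e-8: zero hits expected
  expect_identical(hits, 0L)
})

test_that("a planted effect sized for 99% power is recovered as GWS in >= 95/100 seeds", {
  n <- 5e4
  maf_target <- 0.25
  recovered <- 0L
  for (s in 1:100) {
    cfg <- sim_config(seed = s, n_ld_blocks = 1, variants_per_block = 50)
    genome <- simulate_ld_genome(cfg)
    v <- genome$variants[which.min(abs(genome$variants$maf - maf_target)), ]
    beta <- beta_for_power(0.99, n, v$maf)
    truth <- list(signals = data.frame(trait_id = "EFO_X",
                                       variant_id = v$variant_id,
                                       beta = beta, stringsAsFactors = FALSE))
    study <- list(study_id = "S", trait_id = "EFO_X", n = n,
                  n_cases = NA_integer_, is_quantitative = TRUE)
    ss <- simulate_study_sumstats(genome, study, truth)
    if (ss$p_value[ss$variant_id == v$variant_id] <= 1e-8) {
      recovered <- recovered + 1L
    }
  }
  expect_gte(recovered, 95L)
})

test_that("planting unknown causal variants fails naming the id", {
  cfg <- sim_config(seed = 4, n_ld_blocks = 1, variants_per_block = 10)
  genome <- simulate_ld_genome(cfg)
  truth <- list(signals = data.frame(trait_id = "EFO_X",
                                     variant_id = "99_123_A_G", beta = 0.1,
                                     stringsAsFactors = FALSE))
  study <- list(study_id = "S", trait_id = "EFO_X", n = 1e4,
                n_cases = NA_integer_, is_quantitative = TRUE)
  expect_error(simulate_study_sumstats(genome, study, truth), "99_123_A_G")
})

test_that("mean |beta-hat| of GWS leads decreases across MAF bins", {
  # plant one causal variant per MAF bin in many studies and pool GWS leads
  cfg <- sim_config(seed = 9, n_ld_blocks = 12, variants_per_block = 60,
                    maf_shape1 = 0.4, maf_shape2 = 2)
  genome <- simulate_ld_genome(cfg)
  bins <- list(c(0.002, 0.01), c(0.01, 0.1), c(0.1, 0.5))
  n <- 2e5
  beta_by_bin <- list(numeric(0), numeric(0), numeric(0))
  for (s in 1:30) {
    for (bi in seq_along(bins)) {
      cand <- genome$variants[genome$variants$maf > bins[[bi]][1] &
                                genome$variants$maf <= bins[[bi]][2], ]
      if (nrow(cand) == 0L) next
      v <- cand[1 + (s %% nrow(cand)), ]
      beta <- 0.02 * (2 * v$maf * (1 - v$maf))^(-0.5)
      truth <- list(signals = data.frame(trait_id = "EFO_X",
                                         variant_id = v$variant_id,
                                         beta = beta, stringsAsFactors = FALSE))
      study <- list(study_id = sprintf("S%d_%d", s, bi), trait_id = "EFO_X",
                    n = n, n_cases = NA_integer_, is_quantitative = TRUE)
      ss <- simulate_study_sumstats(genome, study, truth)
      gws <- ss[ss$p_value <= 1e-8, ]
      if (nrow(gws) == 0L) next
      lead <- gws[which.min(gws$p_value), ]
      beta_by_bin[[bi]] <- c(beta_by_bin[[bi]], abs(lead$beta))
    }
  }
  means <- vapply(beta_by_bin, mean, numeric(1))
  expect_true(all(!is.na(means)))
  expect_gt(means[1], means[2])
  expect_gt(means[2], means[3])
})

test_that("molQTL credible sets share their top variant with planted signals", {
  cfg <- sim_config(seed = 21, n_ld_blocks = 6, variants_per_block = 40)
  genome <- simulate_ld_genome(cfg)
  truth <- make_truth_table(genome, cfg)
  mq <- simulate_molqtl_cs(genome, truth, cfg)
  planted <- unique(truth$signals[c("gene_id", "variant_id")])
  for (cs in mq) {
    expect_true(cs$lead_variant %in%
                  planted$variant_id[planted$gene_id == cs$gene_id])
    expect_gte(sum(cs$members$pip), 0.95)
    expect_lte(sum(cs$members$pip), 1 + 1e-9)
    expect_true(all(cs$members$pip >= 0 & cs$members$pip <= 1))
  }
})

test_that("planted colocalising pairs score CLPP >= 0.01, random pairs do not", {
  sig_clpp <- numeric(0)
  null_clpp <- numeric(0)
  for (s in 1:40) {
    cfg <- sim_config(seed = 100 + s, n_ld_blocks = 4, variants_per_block = 40)
    genome <- simulate_ld_genome(cfg)
    truth <- make_truth_table(genome, cfg)
    pair <- truth$signals[1, ]
    with_stream(cfg$seed, "cs_pair", {
      gwas <- simulate_signal_cs(genome, pair$variant_id, "CS_G", "G")
      qtl <- simulate_signal_cs(genome, pair$variant_id, "CS_Q", "Q")
      other <- genome$variants$variant_id[
        genome$variants$block != pair$block][1]
      unrelated <- simulate_signal_cs(genome, other, "CS_U", "U")
      sig_clpp <- c(sig_clpp, clpp(gwas, qtl)$clpp)
      null_clpp <- c(null_clpp, clpp(gwas, unrelated)$clpp)
    })
  }
  expect_gte(mean(sig_clpp >= 0.01), 0.9)
  expect_lt(median(null_clpp), 0.01)
})

test_that("annotation generator respects PAV rates and score ranges", {
  cfg0 <- sim_config(seed = 31, n_ld_blocks = 4, variants_per_block = 50,
                     pav_rate_by_maf = c("(0,0.01]" = 0, "(0.01,0.1]" = 0,
                                         "(0.1,0.5]" = 0))
  genome <- simulate_ld_genome(cfg0)
  ann0 <- simulate_annotations(genome, truth = NULL, cfg0)
  expect_false(any(ann0$variant_annotation$category == "PAV"))
  expect_true(all(ann0$variant_annotation$pathogenicity >= 0 &
                    ann0$variant_annotation$pathogenicity <= 1))

  # empirical PAV rates match the configured per-bin rates within binomial CI
  rates <- c("(0,0.01]" = 0.4, "(0.01,0.1]" = 0.2, "(0.1,0.5]" = 0.05)
  cfg1 <- sim_config(seed = 32, n_ld_blocks = 20, variants_per_block = 80,
                     maf_shape1 = 0.4, maf_shape2 = 2, pav_rate_by_maf = rates)
  genome1 <- simulate_ld_genome(cfg1)
  ann1 <- simulate_annotations(genome1, truth = NULL, cfg1)
  va <- merge(ann1$variant_annotation,
              genome1$variants[c("variant_id", "maf")], by = "variant_id")
  va$bin <- as.character(cut(va$maf, breaks = c(0, 0.01, 0.1, 0.5)))
  for (b in names(rates)) {
    sub <- va[va$bin == b, ]
    if (nrow(sub) < 10L) next
    k <- sum(sub$category == "PAV")
    ci <- stats::binom.test(k, nrow(sub))$conf.int
    expect_true(rates[[b]] >= ci[1] && rates[[b]] <= ci[2])
  }
})

test_that("TI pipeline: null support gives OR near 1, link inversion stays valid", {
  plan <- list(n_ti = 4000L, p12 = 0.7, p23 = 0.55,
               base_logodds = stats::qlogis(0.10), b_support = 0,
               b_logpleio = 0, b_logpleio_sq = 0, support_rate = 0.3)
  covered <- 0L
  for (s in 1:30) {
    ti <- simulate_ti_pipeline(NULL, plan, seed = s)
    expect_true(all(ti$max_phase %in% 1:4))
    expect_true(all(ti$approved == (ti$max_phase == 4L)))
    e <- fisher_enrichment(ti$support == 1, ti$approved)
    if (!any(is.na(e$or_ci)) && e$or_ci[1] <= 1 && e$or_ci[2] >= 1) {
      covered <- covered + 1L
    }
  }
  expect_gte(covered, 27L)  # 90% of 30 seeds

  bad <- plan
  bad$p12 <- 1.5
  expect_error(simulate_ti_pipeline(NULL, bad, seed = 1), "\\[0,1\\]")
})

test_that("truth table closes: planted ids all resolve and gPS sizes match", {
  cfg <- sim_config(seed = 13)
  genome <- simulate_ld_genome(cfg)
  truth <- make_truth_table(genome, cfg)
  expect_true(all(truth$signals$variant_id %in% genome$variants$variant_id))
  expect_true(all(truth$signals$gene_id %in% genome$genes$gene_id))
  for (g in names(truth$gene_diseases)) {
    planted <- truth$gene_diseases[[g]]
    sig <- truth$signals[truth$signals$gene_id == g &
                           grepl("^EFO_D", truth$signals$trait_id), ]
    expect_setequal(sig$trait_id, planted)
  }
})
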