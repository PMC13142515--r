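mk_cs_df <- function(n, leads = paste0("v", seq_len(n)),
                     traits = paste0("D", seq_len(n))) {
  data.frame(cs_id = sprintf("CS%02d", seq_len(n)), lead_variant = leads,
             lead_p = 10^-(20 - seq_len(n)), abs_beta = rep(0.1, n),
             trait_id = traits, ta = paste0("TA_", traits),
             stringsAsFactors = FALSE)
}

no_pairs <- data.frame(left = character(0), right = character(0))

test_that("clustering: singletons, lead-sharing expansion, vps/ta counting", {
  df <- mk_cs_df(4)
  out <- cluster_credible_sets(df, no_pairs)
  expect_identical(length(unique(out$cluster_id)), 4L)
  expect_true(all(out$vps == 1L))

  # A-B colocalised; B and C share a lead variant -> one cluster {A, B, C}
  df3 <- mk_cs_df(3, leads = c("v1", "v2", "v2"), traits = c("D1", "D2", "D3"))
  pairs <- data.frame(left = "CS01", right = "CS02", stringsAsFactors = FALSE)
  out3 <- cluster_credible_sets(df3, pairs)
  expect_identical(length(unique(out3$cluster_id)), 1L)
  expect_true(all(out3$vps == 3L))
  expect_identical(unique(out3$n_leads), 2L)
})

test_that("clustering equals graph reachability on random toy graphs", {
  skip_if_not_installed("igraph")
  set.seed(19)
  for (i in 1:200) {
    k <- sample(3:12, 1)
    df <- mk_cs_df(k,
                   leads = paste0("v", sample.int(max(2L, k - 2L), k,
                                                  replace = TRUE)),
                   traits = paste0("D", sample.int(k, k, replace = TRUE)))
    m <- sample(0:(k), 1)
    pairs <- if (m > 0) {
      data.frame(left = df$cs_id[sample.int(k, m, replace = TRUE)],
                 right = df$cs_id[sample.int(k, m, replace = TRUE)],
                 stringsAsFactors = FALSE)
    } else no_pairs
    pairs <- pairs[pairs$left != pairs$right, , drop = FALSE]
    got <- cluster_credible_sets(df, pairs)

    g <- igraph::make_empty_graph(n = k, directed = FALSE)
    igraph::V(g)$name <- df$cs_id
    for (j in seq_len(nrow(pairs))) {
      g <- igraph::add_edges(g, c(pairs$left[j], pairs$right[j]))
    }
    for (v in unique(df$lead_variant)) {
      ids <- df$cs_id[df$lead_variant == v]
      if (length(ids) > 1) {
        for (j in 2:length(ids)) g <- igraph::add_edges(g, c(ids[1], ids[j]))
      }
    }
    comp <- igraph::components(g)$membership
    want <- split(df$cs_id, comp[df$cs_id])
    got_split <- split(got$cs_id, got$cluster_id)
    norm <- function(l) sort(vapply(l, function(x) paste(sort(x), collapse = ","), ""))
    expect_identical(unname(norm(got_split)), unname(norm(want)))
  }
})

test_that("vps, concordance and gps follow the union rules", {
  cl <- data.frame(trait_id = c("D1", "D2", "D1"), ta = c("A", "B", "A"))
  v <- compute_vps(cl)
  expect_identical(v$vps, 2L)
  expect_identical(v$ta_count, 2L)
  single <- compute_vps(data.frame(trait_id = "D1", ta = "A"))
  expect_identical(single$vps, 1L)

  expect_equal(beta_concordance(c("+", "+", "-")), 2 / 3, tolerance = 1e-12)
  expect_equal(beta_concordance("+"), 1)
  expect_equal(beta_concordance(c("+", "-")), 0.5)
  expect_error(beta_concordance(c("+", "?")), "usable")

  pri <- data.frame(gene_id = c("G", "G", "G", "H"),
                    trait_id = c("A", "B", "B", "C"),
                    ta = c("t1", "t1", "t1", "t2"), stringsAsFactors = FALSE)
  gps <- compute_gps(pri)
  expect_identical(gps$gps[gps$gene_id == "G"], 2L)
  expect_identical(gps$gps[gps$gene_id == "H"], 1L)

  # planted gene with disease-set size 7 recovers gps 7 when all detected
  pri7 <- data.frame(gene_id = "G7",
                     trait_id = c(paste0("D", 1:4), paste0("D", 3:7)),
                     ta = "t", stringsAsFactors = FALSE)
  expect_identical(compute_gps(pri7)$gps, 7L)

  # monotone: adding associations never decreases gps
  expect_gte(compute_gps(rbind(pri7, data.frame(gene_id = "G7", trait_id = "D8",
                                                ta = "t")))$gps,
             compute_gps(pri7)$gps)
})

test_that("tissue specificity scores the HPA-style categories", {
  base <- setNames(rep(1, 8), paste0("T", 1:8))
  enriched <- base; enriched["T1"] <- 10
  r <- score_tissue_specificity(enriched)
  expect_equal(r$score, 1)
  expect_identical(r$binary, 1L)

  r_unif <- score_tissue_specificity(base)
  expect_equal(r_unif$score, -1)
  expect_identical(r_unif$binary, 0L)

  exact4 <- base; exact4["T1"] <- 4
  expect_equal(score_tissue_specificity(exact4)$score, 1)

  grp <- base; grp[c("T1", "T2", "T3")] <- 5
  rg <- score_tissue_specificity(grp)
  expect_equal(rg$score, 0.75)
  expect_identical(rg$binary, 0L)

  # top tissue under 4x the runner-up, no qualifying group, but 4x the mean
  enh <- c(6, 2.5, 2.0, 1.5, 1.2, 1.0, 0.8, 0.5)
  expect_equal(score_tissue_specificity(enh)$score, 0.5)

  expect_true(is.na(score_tissue_specificity(c(0, 0))$score))
  expect_error(score_tissue_specificity(5), "2 tissues")
})

test_that("count model: null, planted recovery, degenerate covariate", {
  set.seed(8)
  n <- 2000L
  cov_null <- data.frame(a = runif(n), b = runif(n))
  y_null <- rpois(n, 2)
  f0 <- fit_count_model(y_null, cov_null, mode = "joint")
  expect_lt(f0$r2, 0.02)
  expect_true(all(abs(f0$coefficients[-1, "Estimate"]) < 0.3))

  # planted Poisson response with known coefficient on a power-like covariate
  n <- 5000L
  power_cov <- runif(n)
  other <- runif(n)
  b_true <- 1.2
  y <- rpois(n, exp(0.3 + b_true * power_cov))
  f1 <- fit_count_model(y, data.frame(power = power_cov, other = other),
                        mode = "joint")
  est <- f1$coefficients["power", "Estimate"]
  se <- f1$coefficients["power", "Std. Error"]
  expect_lt(abs(est - b_true), 2 * se)
  expect_gt(f1$r2_deltas[["power"]], 0)

  expect_warning(
    fit_count_model(y_null, data.frame(a = runif(length(y_null)),
                                       const = rep(1, length(y_null)))),
    "constant")

  uni <- fit_count_model(y, data.frame(power = power_cov), mode = "univariate")
  expect_named(uni, "power")
  expect_gt(uni$power$r2, 0.1)
})

test_that("gene-set enrichment: null behaviour, planted log-odds, skip rule", {
  set.seed(4)
  n <- 8000L
  gps <- data.frame(gene_id = paste0("G", seq_len(n)),
                    gps = 1L + rpois(n, 3), stringsAsFactors = FALSE)
  # planted: odds of membership double per gps doubling (log-odds log(2))
  eta <- -3 + log(2) * log2(gps$gps)
  member <- runif(n) < plogis(eta)
  sets <- list(planted = gps$gene_id[member],
               null = sample(gps$gene_id, 500),
               empty = c("NOPE1", "NOPE2"))
  expect_message(res <- gene_set_enrichment(gps, sets), "no overlap")
  expect_setequal(res$gene_set, c("planted", "null"))
  pl <- res[res$gene_set == "planted", ]
  expect_lt(abs(pl$log_odds - log(2)), 2 * pl$se)
  nl <- res[res$gene_set == "null", ]
  expect_lt(abs(nl$log_odds), 3 * nl$se)
})

test_that("gps correlates with ta_count on planted cohorts", {
  # synthetic diseases map injectively to therapeutic areas, so the
  # disease and TA counts of a recovered gene should track each other
  res <- run_all(small_config(seed = 4))
  expect_gte(nrow(res$gps), 3L)
  rho <- suppressWarnings(
    cor(res$gps$gps, res$gps$ta_count, method = "spearman"))
  expect_gte(rho, 0)
})
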