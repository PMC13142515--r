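# variant- and gene-level pleiotropy: colocalisation-driven clustering of
# disease credible sets, vPS/gPS counting, directionality concordance,
# negative-binomial covariate models, gene-set logistic enrichment

#' Cluster disease credible sets by colocalisation and shared leads
#'
#' Iterative partition: seed with the unassigned credible set of smallest
#' lead p-value (ties by larger |beta|, then cs_id); pull in every unassigned
#' set significantly colocalised with any member; take the union of member
#' lead variants and pull in every remaining set sharing one of them; repeat
#' the two expansions to a fixed point, emit the cluster, and continue until
#' all sets are assigned. An isolated set forms a singleton cluster. The
#' resulting partition equals the connected components of the union relation
#' (colocalisation edges plus shared-lead edges), visited in significance
#' order.
#'
#' @param cs_df data frame with `cs_id`, `lead_variant`, `lead_p`,
#'   `abs_beta`, `trait_id`, `ta`.
#' @param coloc_pairs data frame of significant pairs (`left`, `right`).
#' @return data frame with `cluster_id`, `cs_id`, plus per-cluster columns
#'   `vps` (unique diseases), `ta_count` and `n_leads` joined on.
#' @export
cluster_credible_sets <- function(cs_df, coloc_pairs) {
  n <- nrow(cs_df)
  ord <- order(cs_df$lead_p, -cs_df$abs_beta, cs_df$cs_id)
  edges <- coloc_pairs[coloc_pairs$left %in% cs_df$cs_id &
                         coloc_pairs$right %in% cs_df$cs_id, , drop = FALSE]
  assigned <- rep(FALSE, n)
  cluster <- integer(n)
  next_id <- 0L
  for (i in ord) {
    if (assigned[i]) next
    next_id <- next_id + 1L
    members <- i
    repeat {
      ids <- cs_df$cs_id[members]
      # expansion 1: significant colocalisation with any current member
      linked <- unique(c(edges$right[edges$left %in% ids],
                         edges$left[edges$right %in% ids]))
      # expansion 2: sharing any current member's lead variant
      leads <- unique(cs_df$lead_variant[members])
      shared <- cs_df$cs_id[cs_df$lead_variant %in% leads]
      new <- which(!assigned & !(seq_len(n) %in% members) &
                     cs_df$cs_id %in% union(linked, shared))
      if (length(new) == 0L) break
      members <- c(members, new)
    }
    assigned[members] <- TRUE
    cluster[members] <- next_id
  }
  out <- data.frame(cluster_id = sprintf("CL_%03d", cluster),
                    cs_df, stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(out, out$cluster_id), function(d) {
    data.frame(cluster_id = d$cluster_id[1],
               vps = length(unique(d$trait_id)),
               ta_count = length(unique(d$ta)),
               n_leads = length(unique(d$lead_variant)),
               stringsAsFactors = FALSE)
  }))
  merge(out, agg, by = "cluster_id", sort = FALSE)
}

#' Variant-cluster pleiotropy score
#'
#' The number of unique diseases in the cluster (union over all lead
#' variants for multi-lead clusters), plus the unique therapeutic-area count.
#'
#' @param cluster_df rows of one cluster with `trait_id` and `ta`.
#' @return list with `vps` and `ta_count`.
#' @export
compute_vps <- function(cluster_df) {
  list(vps = length(unique(cluster_df$trait_id)),
       ta_count = length(unique(cluster_df$ta)))
}

#' Directionality concordance of a variant's disease associations
#'
#' The largest proportion of same-direction effects, in [0.5, 1]; a single
#' association (non-pleiotropic variant) scores 1.
#'
#' @param signs character (`"+"`/`"-"`) or numeric sign vector; every entry
#'   must be usable.
#' @return concordance in [0.5, 1].
#' @export
beta_concordance <- function(signs) {
  if (is.character(signs)) {
    assert_that(all(signs %in% c("+", "-")), "all signs must be usable (+/-)")
    s <- ifelse(signs == "+", 1, -1)
  } else {
    assert_that(all(signs %in% c(-1, 1)), "all signs must be usable (-1/+1)")
    s <- signs
  }
  max(sum(s > 0), sum(s < 0)) / length(s)
}

#' Gene pleiotropy score
#'
#' Per gene, the count of unique diseases over all prioritised credible sets
#' whose effector gene is that gene; the therapeutic-area count is the
#' analogous union.
#'
#' @param prioritisations data frame with `gene_id`, `trait_id`, `ta`.
#' @return data frame with `gene_id`, `gps`, `ta_count`.
#' @export
compute_gps <- function(prioritisations) {
  out <- do.call(rbind, lapply(split(prioritisations, prioritisations$gene_id),
                               function(d) {
    data.frame(gene_id = d$gene_id[1],
               gps = length(unique(d$trait_id)),
               ta_count = length(unique(d$ta)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Tissue-specificity score of a gene
#'
#' From a per-tissue expression vector: tissue enriched (at least 4-fold
#' higher in one tissue than any other) scores 1; group enriched (2-5
#' tissues each at least 4-fold above all others) scores 0.75; tissue
#' enhanced (top tissue at least 4-fold above the mean of the others)
#' scores 0.5; otherwise low specificity, -1. The binary indicator is 1 only
#' for tissue enriched (score > 0.75). Genes with no detected expression are
#' excluded (NA).
#'
#' @param expr named numeric vector of expression over at least 2 tissues.
#' @return list with `score` and `binary`.
#' @export
score_tissue_specificity <- function(expr) {
  assert_that(length(expr) >= 2L, "at least 2 tissues required")
  if (all(expr <= 0)) return(list(score = NA_real_, binary = NA_integer_))
  e <- sort(expr, decreasing = TRUE)
  score <- if (e[1] >= 4 * e[2]) {
    1
  } else {
    group <- FALSE
    for (k in 2:min(5L, length(e) - 1L)) {
      if (e[k] >= 4 * e[k + 1L]) { group <- TRUE; break }
    }
    if (group) 0.75
    else if (e[1] >= 4 * mean(e[-1])) 0.5
    else -1
  }
  list(score = score, binary = as.integer(score > 0.75))
}

#' Negative-binomial covariate model for pleiotropy counts
#'
#' Fits a negative-binomial GLM (log link) of a count response on min-max
#' scaled covariates, with a Poisson fallback when the dispersion estimate
#' diverges. Reports the Pearson R-squared between predicted and observed
#' counts; in joint mode, each covariate's contribution is
#' R2(full) - R2(model without it). Constant covariates are dropped with a
#' warning.
#'
#' @param response non-negative integer counts.
#' @param covariates data frame of numeric covariates.
#' @param mode `"joint"` or `"univariate"`.
#' @return list with `coefficients`, `theta` (NA under the Poisson fallback),
#'   `family`, `r2`, and in joint mode `r2_deltas`; in univariate mode a
#'   per-covariate list of fits.
#' @export
fit_count_model <- function(response, covariates,
                            mode = c("joint", "univariate")) {
  mode <- match.arg(mode)
  assert_that(all(response >= 0) && all(response == round(response)),
              "response must be non-negative integer counts")
  scaled <- list()
  for (nm in names(covariates)) {
    s <- minmax_scale(covariates[[nm]])
    if (is.null(s)) {
      warning(sprintf("covariate '%s' is constant after scaling; dropped", nm))
    } else {
      scaled[[nm]] <- s
    }
  }
  assert_that(length(scaled) > 0L, "no usable covariates")
  dat <- data.frame(.y = response, scaled)
  fit_one <- function(formula) {
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(formula, data = dat)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || !is.finite(fit$theta) ||
        fit$theta > 1e5) {
      fit <- stats::glm(formula, data = dat, family = stats::poisson())
      fam <- "poisson"; theta <- NA_real_
    } else {
      fam <- "negative_binomial"; theta <- fit$theta
    }
    pred <- stats::predict(fit, type = "response")
    r2 <- if (stats::sd(pred) == 0) 0 else stats::cor(pred, response)^2
    list(coefficients = summary(fit)$coefficients, theta = theta,
         family = fam, r2 = r2, fit = fit)
  }
  if (mode == "univariate") {
    out <- lapply(names(scaled), function(nm) {
      fit_one(stats::as.formula(paste(".y ~", nm)))
    })
    names(out) <- names(scaled)
    return(out)
  }
  full <- fit_one(stats::as.formula(paste(".y ~", paste(names(scaled), collapse = " + "))))
  deltas <- vapply(names(scaled), function(nm) {
    rest <- setdiff(names(scaled), nm)
    red <- if (length(rest)) {
      fit_one(stats::as.formula(paste(".y ~", paste(rest, collapse = " + "))))
    } else {
      list(r2 = 0)
    }
    full$r2 - red$r2
  }, numeric(1))
  full$r2_deltas <- deltas
  full
}

#' Gene-set logistic enrichment on the gene pleiotropy score
#'
#' For each gene set, fits a logistic regression of set membership on
#' log2(gPS) over the background of all disease-associated genes, reporting
#' the log-odds, standard error, Wald p-value, and a Benjamini-Hochberg
#' q-value across sets. Sets with no overlap with the background are skipped
#' with a message.
#'
#' @param gps_table data frame with `gene_id` and `gps` (the background).
#' @param gene_sets named list of gene-id vectors.
#' @return data frame with one row per tested set.
#' @export
gene_set_enrichment <- function(gps_table, gene_sets) {
  rows <- list()
  for (nm in names(gene_sets)) {
    member <- as.integer(gps_table$gene_id %in% gene_sets[[nm]])
    if (sum(member) == 0L) {
      message(sprintf("gene set '%s' has no overlap with background; skipped", nm))
      next
    }
    x <- log2(gps_table$gps)
    fit <- suppressWarnings(
      stats::glm(member ~ x, family = stats::binomial()))
    co <- summary(fit)$coefficients
    rows[[nm]] <- data.frame(
      gene_set = nm, n_overlap = sum(member),
      log_odds = co["x", "Estimate"], se = co["x", "Std. Error"],
      p = co["x", "Pr(>|z|)"], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    out$q <- stats::p.adjust(out$p, method = "BH")
    rownames(out) <- NULL
  }
  out
}
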