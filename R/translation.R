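# genetic-support enrichment in clinical success: ontology-propagated
# evidence attachment, Fisher OR / relative success, stratified logistic
# comparisons, non-linear log-pleiotropy models, phase transitions

#' Attach genetic support to target-indication records
#'
#' Evidence on a gene-trait pair supports a target-indication pair when the
#' evidence trait exactly matches the indication or is one of its ontology
#' descendants (evidence is propagated upward from descendants; ancestors do
#' not count except on exact match). Oncology indications are removed before
#' modelling. Evidence attribute columns (e.g. `pav`, `maf`, `abs_beta`,
#' `gps`, `ta_count`) are carried over from the matching evidence rows
#' (taking the strongest value per pair), and stratum flags are populated.
#'
#' @param ti data frame of target-indication records (`target`, `indication`,
#'   `max_phase`).
#' @param evidence data frame of gene-trait evidence (`gene_id`, `trait_id`,
#'   optional `pav`, `maf`, `abs_beta`, `gps`, `ta_count`).
#' @param edges ontology edges (`child`, `parent`).
#' @param oncology_terms indication terms (and their descendants) to exclude.
#' @return TIRecord data frame with `approved`, `support` and stratum flags.
#' @export
attach_genetic_support <- function(ti, evidence, edges,
                                   oncology_terms = character(0)) {
  onc <- unique(c(oncology_terms,
                  unlist(lapply(oncology_terms, descendants_of, edges = edges))))
  out <- ti[!(ti$indication %in% onc), , drop = FALSE]
  assert_that(all(out$max_phase %in% 1:4), "max_phase must be in 1..4")
  out$approved <- out$max_phase == 4L
  n <- nrow(out)
  out$support <- FALSE
  out$pav_support <- FALSE
  out$rare_support <- FALSE
  out$large_effect_support <- FALSE
  out$gps <- NA_real_
  out$ta_count <- NA_real_
  if (nrow(evidence)) {
    for (i in seq_len(n)) {
      ind <- out$indication[i]
      terms <- c(ind, descendants_of(ind, edges))
      hit <- evidence[evidence$gene_id == out$target[i] &
                        evidence$trait_id %in% terms, , drop = FALSE]
      if (nrow(hit) == 0L) next
      out$support[i] <- TRUE
      out$pav_support[i] <- any(hit$pav %||% FALSE)
      out$rare_support[i] <- any((hit$maf %||% NA_real_) < 0.01, na.rm = TRUE)
      out$large_effect_support[i] <-
        any((hit$abs_beta %||% NA_real_) > 0.5, na.rm = TRUE)
      if (!is.null(hit$gps)) out$gps[i] <- max(hit$gps, na.rm = TRUE)
      if (!is.null(hit$ta_count)) out$ta_count[i] <- max(hit$ta_count, na.rm = TRUE)
    }
  }
  out$strict_support <- define_strict_support(out$pav_support, out$ta_count)
  out
}

#' Strict genetic-support flag
#'
#' Support by a protein-altering variant combined with intermediate
#' pleiotropy: genetic support observed in 2 to 5 therapeutic areas.
#'
#' @param pav_support logical PAV-support flags.
#' @param ta_count therapeutic-area counts (NA where unsupported).
#' @return logical flags.
#' @export
define_strict_support <- function(pav_support, ta_count) {
  pav_support & !is.na(ta_count) & ta_count >= 2 & ta_count <= 5
}

#' Fisher enrichment of genetic support in approval
#'
#' Builds the 2x2 table of a stratum flag against approval, with cells
#' a = supported approved, b = supported not approved, c = unsupported
#' approved, d = unsupported not approved. Reports the sample odds ratio
#' OR = ad / bc (the conditional maximum-likelihood estimate when a cell is
#' zero, with the 0/Inf limits), the relative success
#' RS = P(approved | support) / P(approved | no support), the two-sided
#' Fisher exact p-value, and normal-approximation confidence intervals for
#' both on the log scale.
#'
#' @param support logical (or 0/1) stratum flags, or a 2x2 table/matrix
#'   `(a, b, c, d)` given row-wise.
#' @param approved logical approval outcomes (ignored when `support` is a
#'   matrix).
#' @param conf confidence level (default 0.95).
#' @return list with the cells, `or`, `rs`, `p`, `or_ci`, `rs_ci`.
#' @export
fisher_enrichment <- function(support, approved = NULL, conf = 0.95) {
  if (is.matrix(support)) {
    tab <- support
  } else {
    support <- as.logical(support); approved <- as.logical(approved)
    tab <- matrix(c(sum(support & approved), sum(support & !approved),
                    sum(!support & approved), sum(!support & !approved)),
                  nrow = 2, byrow = TRUE)
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  ft <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))
  or <- if (min(a, b, c, d) == 0) {
    if (a == 0 || d == 0) {
      if ((a == 0 && b > 0 && c > 0) || (d == 0 && b > 0 && c > 0)) {
        if (a == 0) 0 else Inf
      } else unname(ft$estimate)
    } else Inf
  } else {
    a * d / (b * c)
  }
  rs <- if ((a + b) == 0 || (c + d) == 0 || c == 0) {
    if (a == 0) 0 else Inf
  } else {
    (a / (a + b)) / (c / (c + d))
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  or_ci <- if (min(a, b, c, d) > 0) {
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    exp(log(or) + c(-1, 1) * z * se)
  } else c(NA_real_, NA_real_)
  rs_ci <- if (a > 0 && c > 0) {
    se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
    exp(log(rs) + c(-1, 1) * z * se)
  } else c(NA_real_, NA_real_)
  list(a = a, b = b, c = c, d = d, or = or, rs = rs, p = ft$p.value,
       or_ci = or_ci, rs_ci = rs_ci)
}

#' Compare two genetic-evidence strata by logistic regression
#'
#' Fits approval ~ flagA + flagB with two independent binary predictors and
#' tests the difference of their coefficients with a t-test (Wald, using the
#' coefficient covariance). When several comparisons are supplied, p-values
#' are Benjamini-Hochberg adjusted.
#'
#' @param ti TIRecord data frame with an `approved` column.
#' @param comparisons list of character pairs naming flag columns of `ti`.
#' @return data frame with one row per comparison: coefficients, difference,
#'   t statistic, p and BH q.
#' @export
compare_strata_logistic <- function(ti, comparisons) {
  rows <- lapply(comparisons, function(pair) {
    fa <- pair[1]; fb <- pair[2]
    assert_that(sum(ti[[fa]]) > 0, sprintf("stratum '%s' is empty", fa))
    assert_that(sum(ti[[fb]]) > 0, sprintf("stratum '%s' is empty", fb))
    dat <- data.frame(y = as.integer(ti$approved),
                      A = as.integer(ti[[fa]]), B = as.integer(ti[[fb]]))
    if (identical(dat$A, dat$B)) {
      # perfectly collinear strata carry the same coefficient by definition
      fit1 <- stats::glm(y ~ A, data = dat, family = stats::binomial())
      coA <- unname(stats::coef(fit1)["A"])
      return(data.frame(stratum_a = fa, stratum_b = fb, coef_a = coA,
                        coef_b = coA, difference = 0, se = NA_real_,
                        t = 0, p = 1, stringsAsFactors = FALSE))
    }
    fit <- stats::glm(y ~ A + B, data = dat, family = stats::binomial())
    co <- stats::coef(fit)
    V <- stats::vcov(fit)
    diff <- co["A"] - co["B"]
    se <- sqrt(V["A", "A"] + V["B", "B"] - 2 * V["A", "B"])
    t <- diff / se
    p <- 2 * stats::pt(-abs(t), df = stats::df.residual(fit))
    data.frame(stratum_a = fa, stratum_b = fb,
               coef_a = unname(co["A"]), coef_b = unname(co["B"]),
               difference = unname(diff), se = unname(se),
               t = unname(t), p = unname(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Non-linear pleiotropy model of clinical success
#'
#' Fits three nested logistic models of approval: baseline
#' (~ support), plus the linear log-pleiotropy term log(count + 1), plus its
#' square; compares them with likelihood-ratio tests. Predicted approval
#' probabilities over a pleiotropy grid carry percentile-bootstrap 95% bands
#' (200 resamples, seeded), and a LOWESS curve of the raw outcomes is
#' computed over the same grid.
#'
#' @param ti TIRecord data frame with `approved` and `support`.
#' @param counts per-record pleiotropy counts (unique diseases or TAs).
#' @param n_boot bootstrap resamples (default 200).
#' @param lowess_span LOWESS smoother span (default 0.6).
#' @param seed integer seed for the bootstrap.
#' @return list with the three fits, `lrt` (linear vs baseline, quadratic vs
#'   linear), `grid` with predictions and bootstrap bands, and `lowess`.
#' @export
nonlinear_pleiotropy_model <- function(ti, counts, n_boot = 200L,
                                       lowess_span = 0.6, seed = 1L) {
  assert_that(nrow(ti) > 0, "zero records")
  assert_that(length(counts) == nrow(ti), "counts must align with records")
  dat <- data.frame(y = as.integer(ti$approved),
                    support = as.integer(ti$support),
                    L = log(counts + 1))
  m0 <- stats::glm(y ~ support, data = dat, family = stats::binomial())
  m1 <- stats::glm(y ~ support + L, data = dat, family = stats::binomial())
  m2 <- stats::glm(y ~ support + L + I(L^2), data = dat,
                   family = stats::binomial())
  lrt <- function(small, big) {
    stat <- small$deviance - big$deviance
    df <- small$df.residual - big$df.residual
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  }
  grid_counts <- seq(min(counts), max(counts), length.out = 50)
  grid <- data.frame(support = 1L, L = log(grid_counts + 1))
  pred <- stats::predict(m2, newdata = grid, type = "response")
  boot <- with_stream(seed, "pleio_boot", {
    replicate(n_boot, {
      idx <- sample.int(nrow(dat), replace = TRUE)
      fit <- suppressWarnings(
        stats::glm(y ~ support + L + I(L^2), data = dat[idx, ],
                   family = stats::binomial()))
      stats::predict(fit, newdata = grid, type = "response")
    })
  })
  bands <- apply(boot, 1, stats::quantile, probs = c(0.025, 0.975))
  lw <- stats::lowess(counts, dat$y, f = lowess_span)
  list(fits = list(baseline = m0, linear = m1, quadratic = m2),
       lrt = c(linear_vs_baseline = lrt(m0, m1),
               quadratic_vs_linear = lrt(m1, m2)),
       grid = data.frame(count = grid_counts, predicted = pred,
                         lower = bands[1, ], upper = bands[2, ]),
       lowess = lw)
}

#' Phase-transition probabilities by pleiotropy group
#'
#' For each group (default Low = 1 TA, Medium = 2-5, High = >= 6), estimates
#' P(Phase II | Phase I), P(Phase III | Phase II) and
#' P(approval | Phase III) with Wilson 95% intervals, and runs pairwise
#' two-proportion tests per transition with Benjamini-Hochberg correction.
#' Empty groups are omitted with a message.
#'
#' @param ti TIRecord data frame with `max_phase`.
#' @param groups factor/character of group labels aligned with `ti` rows
#'   (NA rows are dropped).
#' @return list with `transitions` (per group and transition: k, n, estimate,
#'   Wilson bounds) and `pairwise` (BH-adjusted two-proportion tests).
#' @export
phase_transitions <- function(ti, groups) {
  keep <- !is.na(groups)
  ti <- ti[keep, , drop = FALSE]
  groups <- as.character(groups[keep])
  trans <- list(c("P(II|I)", 1L, 2L), c("P(III|II)", 2L, 3L),
                c("P(approval|III)", 3L, 4L))
  rows <- list()
  for (g in unique(groups)) {
    sub <- ti[groups == g, , drop = FALSE]
    if (nrow(sub) == 0L) {
      message(sprintf("pleiotropy group '%s' is empty; omitted", g))
      next
    }
    for (tr in trans) {
      at_risk <- sum(sub$max_phase >= as.integer(tr[2]))
      k <- sum(sub$max_phase >= as.integer(tr[3]))
      if (at_risk == 0L) next
      ci <- wilson_ci(k, at_risk)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, transition = tr[1], k = k, n = at_risk,
        estimate = ci$estimate, lower = ci$lower, upper = ci$upper,
        stringsAsFactors = FALSE)
    }
  }
  transitions <- do.call(rbind, rows)
  pw <- list()
  if (!is.null(transitions)) {
    for (tr in unique(transitions$transition)) {
      sub <- transitions[transitions$transition == tr, , drop = FALSE]
      if (nrow(sub) < 2L) next
      cmb <- utils::combn(nrow(sub), 2)
      for (j in seq_len(ncol(cmb))) {
        i1 <- cmb[1, j]; i2 <- cmb[2, j]
        pt <- suppressWarnings(stats::prop.test(
          c(sub$k[i1], sub$k[i2]), c(sub$n[i1], sub$n[i2])))
        pw[[length(pw) + 1L]] <- data.frame(
          transition = tr, group_a = sub$group[i1], group_b = sub$group[i2],
          p = pt$p.value, stringsAsFactors = FALSE)
      }
    }
  }
  pairwise <- do.call(rbind, pw)
  if (!is.null(pairwise)) pairwise$q <- stats::p.adjust(pairwise$p, "BH")
  list(transitions = transitions, pairwise = pairwise)
}

#' Default pleiotropy grouping by therapeutic-area count
#'
#' @param ta_count numeric TA counts.
#' @return character labels `Low` (1), `Medium` (2-5), `High` (>= 6), NA
#'   where the count is missing or below 1.
#' @export
pleiotropy_group <- function(ta_count) {
  ifelse(is.na(ta_count) | ta_count < 1, NA_character_,
         ifelse(ta_count == 1, "Low",
                ifelse(ta_count <= 5, "Medium", "High")))
}
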