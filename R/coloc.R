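# colocalisation of overlapping credible sets: CLPP, five-hypothesis
# posteriors, and effect-direction concordance

cs_class <- function(cs) {
  if (!is.null(cs$qtl_type) && !is.na(cs$qtl_type %||% NA)) "molqtl" else "gwas"
}

#' Find overlapping credible-set pairs
#'
#' All unordered pairs of credible sets sharing at least one member variant,
#' labelled by pair class (gwas-gwas, gwas-molqtl, molqtl-molqtl).
#'
#' @param cs_list list of credible sets.
#' @return data frame with `left`, `right` (cs ids), `n_shared`, `pair_class`.
#' @export
find_overlaps <- function(cs_list) {
  if (length(cs_list) < 2L) {
    return(data.frame(left = character(0), right = character(0),
                      n_shared = integer(0), pair_class = character(0)))
  }
  ids <- vapply(cs_list, function(cs) cs$cs_id, "")
  classes <- vapply(cs_list, cs_class, "")
  var2cs <- list()
  for (i in seq_along(cs_list)) {
    for (v in cs_list[[i]]$members$variant) {
      var2cs[[v]] <- c(var2cs[[v]], i)
    }
  }
  counts <- new.env(parent = emptyenv())
  for (v in names(var2cs)) {
    idx <- unique(var2cs[[v]])
    if (length(idx) < 2L) next
    for (a in seq_len(length(idx) - 1L)) {
      for (b in (a + 1L):length(idx)) {
        i <- min(idx[a], idx[b]); j <- max(idx[a], idx[b])
        key <- paste(i, j)
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  keys <- ls(counts)
  if (length(keys) == 0L) {
    return(data.frame(left = character(0), right = character(0),
                      n_shared = integer(0), pair_class = character(0)))
  }
  ij <- do.call(rbind, strsplit(keys, " "))
  i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2])
  pc <- vapply(seq_along(i), function(k) {
    paste(sort(c(classes[i[k]], classes[j[k]])), collapse = "-")
  }, "")
  out <- data.frame(left = ids[i], right = ids[j],
                    n_shared = vapply(keys, function(k) counts[[k]], 0L),
                    pair_class = pc, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$left, out$right), , drop = FALSE]
}

#' Colocalisation posterior probability (CLPP)
#'
#' Sum over shared variants of the product of the two credible sets' PIPs.
#' Significant when at least 0.01.
#'
#' @param cs_a,cs_b credible sets.
#' @return list with `clpp`, `n_shared`, `significant`.
#' @export
clpp <- function(cs_a, cs_b) {
  shared <- intersect(cs_a$members$variant, cs_b$members$variant)
  val <- if (length(shared)) {
    pa <- cs_a$members$pip[match(shared, cs_a$members$variant)]
    pb <- cs_b$members$pip[match(shared, cs_b$members$variant)]
    sum(pa * pb)
  } else 0
  list(clpp = val, n_shared = length(shared), significant = val >= 0.01)
}

# Wakefield log approximate Bayes factor from beta, se and prior sd
labf <- function(beta, se, prior_sd) {
  v <- se^2
  r <- prior_sd^2 / (prior_sd^2 + v)
  z2 <- (beta / se)^2
  0.5 * (log(1 - r) + r * z2)
}

# stable log(exp(a) - exp(b)) for a >= b
logdiff <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Five-hypothesis colocalisation posterior (H0..H4)
#'
#' Combines per-variant approximate Bayes factors for two traits over their
#' shared region into posteriors for the five hypotheses (no association;
#' trait-1 only; trait-2 only; two distinct causal variants; one shared
#' causal variant), enumerating single-causal-variant configurations.
#' Significant when H4 is at least 0.8.
#'
#' @param stats_a,stats_b data frames with columns `variant`, `beta`, `se`
#'   over the union region (aligned on the same variants).
#' @param p1,p2 prior probability a variant is causal for trait 1 / trait 2
#'   (default 1e-4).
#' @param p12 prior probability a variant is causal for both (default 1e-5).
#' @param prior_sd_a,prior_sd_b prior effect standard deviations (defaults
#'   0.15, the quantitative-trait prior; use 0.2 for binary traits).
#' @return list with `h` (named numeric H0..H4, summing to 1), `significant`,
#'   `status` (`"ok"` or `"unknown"` when fewer than 2 region variants).
#' @export
coloc_h4 <- function(stats_a, stats_b, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                     prior_sd_a = 0.15, prior_sd_b = 0.15) {
  shared <- intersect(stats_a$variant, stats_b$variant)
  if (length(shared) < 2L) {
    return(list(h = stats::setNames(rep(NA_real_, 5),
                                    paste0("H", 0:4)),
                significant = NA, status = "unknown"))
  }
  a <- stats_a[match(shared, stats_a$variant), ]
  b <- stats_b[match(shared, stats_b$variant), ]
  l1 <- labf(a$beta, a$se, prior_sd_a)
  l2 <- labf(b$beta, b$se, prior_sd_b)
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  lh <- c(H0 = 0,
          H1 = log(p1) + s1,
          H2 = log(p2) + s2,
          H3 = log(p1) + log(p2) + logdiff(s1 + s2, s12),
          H4 = log(p12) + s12)
  h <- exp(lh - logsumexp(lh))
  h <- h / sum(h)
  list(h = h, significant = unname(h["H4"]) >= 0.8, status = "ok")
}

strand_ambiguous <- function(ea, oa) {
  pair <- paste(pmin(ea, oa), pmax(ea, oa))
  pair %in% c("A T", "C G")
}

#' Effect-direction concordance of a colocalising pair
#'
#' Aligns the two signals to an identical effect allele (flipping the second
#' beta when effect and other alleles are swapped), then compares the signs
#' of the shared-variant effect products: all-positive products are
#' concordant, all-negative discordant. Any unusable sign, allele mismatch,
#' strand-ambiguous A/T or C/G pair at MAF above 0.4, or tied product signs
#' gives `unknown`.
#'
#' @param eff_a,eff_b data frames with `variant`, `beta`, `effect_allele`,
#'   `other_allele` and optionally `maf`.
#' @return `"concordant"`, `"discordant"` or `"unknown"`.
#' @export
coloc_direction <- function(eff_a, eff_b) {
  shared <- intersect(eff_a$variant, eff_b$variant)
  if (length(shared) == 0L) return("unknown")
  a <- eff_a[match(shared, eff_a$variant), ]
  b <- eff_b[match(shared, eff_b$variant), ]
  if (any(is.na(a$beta)) || any(is.na(b$beta))) return("unknown")
  maf <- pmin(a$maf %||% rep(0, length(shared)), 0.5)
  if (any(strand_ambiguous(a$effect_allele, a$other_allele) & maf > 0.4)) {
    return("unknown")
  }
  same <- a$effect_allele == b$effect_allele & a$other_allele == b$other_allele
  swapped <- a$effect_allele == b$other_allele & a$other_allele == b$effect_allele
  if (any(!same & !swapped)) return("unknown")
  bb <- ifelse(swapped, -b$beta, b$beta)
  s <- sign(a$beta * bb)
  if (any(s == 0)) return("unknown")
  total <- sum(s)
  if (total > 0) "concordant" else if (total < 0) "discordant" else "unknown"
}

#' Colocalise all overlapping credible-set pairs
#'
#' Runs [find_overlaps()], computes CLPP for every pair, the five-hypothesis
#' posterior where per-variant summary statistics are supplied for both
#' sides, and direction where lead effects are usable. A pair is significant
#' when CLPP >= 0.01 or H4 >= 0.8.
#'
#' @param cs_list list of credible sets.
#' @param stats_by_cs optional named list (by cs_id) of data frames
#'   `variant`, `beta`, `se` covering the set's region.
#' @return data frame of colocalisation results.
#' @export
colocalise_all <- function(cs_list, stats_by_cs = NULL) {
  ov <- find_overlaps(cs_list)
  if (nrow(ov) == 0L) {
    return(cbind(ov, data.frame(clpp = numeric(0), h4 = numeric(0),
                                direction = character(0),
                                significant = logical(0))))
  }
  by_id <- stats::setNames(cs_list, vapply(cs_list, function(x) x$cs_id, ""))
  res <- lapply(seq_len(nrow(ov)), function(k) {
    a <- by_id[[ov$left[k]]]; b <- by_id[[ov$right[k]]]
    cl <- clpp(a, b)
    h4 <- NA_real_
    if (!is.null(stats_by_cs) &&
        !is.null(stats_by_cs[[a$cs_id]]) && !is.null(stats_by_cs[[b$cs_id]])) {
      hh <- coloc_h4(stats_by_cs[[a$cs_id]], stats_by_cs[[b$cs_id]])
      if (hh$status == "ok") h4 <- unname(hh$h["H4"])
    }
    dir <- if (a$beta_sign %in% c("+", "-") && b$beta_sign %in% c("+", "-")) {
      if (a$beta_sign == b$beta_sign) "concordant" else "discordant"
    } else "unknown"
    data.frame(clpp = cl$clpp, h4 = h4, direction = dir,
               significant = cl$clpp >= 0.01 || (!is.na(h4) && h4 >= 0.8),
               stringsAsFactors = FALSE)
  })
  cbind(ov, do.call(rbind, res))
}
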