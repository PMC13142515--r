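# locus definition by three clumping strategies, and PICS fine-mapping

# order of "most significant": smallest p, then larger |beta|, then variant id
significance_order <- function(p, beta, id) {
  order(p, -abs(beta), id)
}

new_locus <- function(chrom, members, top_variant, origin) {
  members <- members[order(members$base_pair_location), , drop = FALSE]
  list(chrom = chrom,
       start = min(members$base_pair_location),
       end = max(members$base_pair_location),
       top_variant = top_variant,
       members = members,
       origin = origin)
}

#' Distance-based clumping
#'
#' Iteratively takes the most significant remaining genome-wide significant
#' variant and absorbs all remaining variants within +/- `window` of it into
#' one locus, until no genome-wide significant variant remains. Ties in
#' significance are broken by larger |beta|, then variant id. Every variant
#' lands in at most one locus.
#'
#' @param sumstats summary-statistic data frame (`variant_id`, `chromosome`,
#'   `base_pair_location`, `p_value`, `beta`).
#' @param window half-width in bp (default 500,000).
#' @param gws genome-wide significance threshold (default 1e-8).
#' @return list of loci (`chrom`, `start`, `end`, `top_variant`, `members`,
#'   `origin = "distance"`).
#' @export
clump_by_distance <- function(sumstats, window = 5e5, gws = 1e-8) {
  loci <- list()
  for (chrom in unique(sumstats$chromosome)) {
    ss <- sumstats[sumstats$chromosome == chrom, , drop = FALSE]
    remaining <- rep(TRUE, nrow(ss))
    repeat {
      cand <- which(remaining & ss$p_value <= gws)
      if (length(cand) == 0L) break
      top <- cand[significance_order(ss$p_value[cand], ss$beta[cand],
                                     ss$variant_id[cand])[1L]]
      inwin <- remaining &
        abs(ss$base_pair_location - ss$base_pair_location[top]) <= window
      loci[[length(loci) + 1L]] <- new_locus(chrom, ss[inwin, , drop = FALSE],
                                             ss$variant_id[top], "distance")
      remaining[inwin] <- FALSE
    }
  }
  loci
}

#' LD-based clumping
#'
#' Greedy by significance over genome-wide significant variants: each round
#' the most significant remaining variant seeds a locus that absorbs every
#' remaining variant with r-squared at or above `r2_min` to it. Assignment is
#' greedy, not a transitive closure: a chain a-b-c with weak a-c LD splits
#' according to which seed claims each variant first.
#'
#' @param sumstats summary-statistic data frame.
#' @param ld square signed-r matrix keyed by variant id (r-squared is its
#'   square); missing entries are treated as r = 0.
#' @param r2_min absorption threshold (default 0.5).
#' @param gws genome-wide significance threshold (default 1e-8).
#' @return list of loci with `origin = "ld"`.
#' @export
clump_by_ld <- function(sumstats, ld, r2_min = 0.5, gws = 1e-8) {
  gws_ids <- sumstats$variant_id[sumstats$p_value <= gws]
  missing <- setdiff(gws_ids, rownames(ld))
  assert_that(length(missing) == 0L,
              paste("LD unavailable for GWS variants:",
                    paste(missing, collapse = ", ")))
  loci <- list()
  for (chrom in unique(sumstats$chromosome)) {
    ss <- sumstats[sumstats$chromosome == chrom, , drop = FALSE]
    remaining <- rep(TRUE, nrow(ss))
    repeat {
      cand <- which(remaining & ss$p_value <= gws)
      if (length(cand) == 0L) break
      top <- cand[significance_order(ss$p_value[cand], ss$beta[cand],
                                     ss$variant_id[cand])[1L]]
      top_id <- ss$variant_id[top]
      r2 <- rep(0, nrow(ss))
      present <- ss$variant_id %in% colnames(ld)
      if (top_id %in% rownames(ld)) {
        r2[present] <- ld[top_id, ss$variant_id[present]]^2
      }
      r2[top] <- 1
      absorb <- remaining & r2 >= r2_min
      loci[[length(loci) + 1L]] <- new_locus(chrom, ss[absorb, , drop = FALSE],
                                             top_id, "ld")
      remaining[absorb] <- FALSE
    }
  }
  loci
}

#' Locus-breaker clumping
#'
#' Three steps: (1) standard distance-based clumping to obtain lead SNPs;
#' (2) keep variants with p below `p_cluster`, chain-cluster those within
#' `gap` of a neighbour, and retain clusters containing at least one
#' genome-wide significant variant; (3) clusters spanning more than
#' `max_span` are split around the step-1 lead SNPs into sub-loci of
#' +/- `half_window` (each cluster variant goes to its nearest lead). Every
#' output locus spans at most `max_span`.
#'
#' @param sumstats summary-statistic data frame.
#' @param p_cluster sub-threshold inclusion p-value (default 1e-5).
#' @param gap chaining distance in bp (default 250,000).
#' @param gws genome-wide significance threshold (default 1e-8).
#' @param max_span maximal locus span in bp (default 1,500,000).
#' @param half_window sub-locus half width in bp (default 750,000).
#' @param window step-1 distance-clumping half width (default 500,000).
#' @return list of loci with `origin = "locus_breaker"`.
#' @export
locus_breaker <- function(sumstats, p_cluster = 1e-5, gap = 2.5e5,
                          gws = 1e-8, max_span = 1.5e6, half_window = 7.5e5,
                          window = 5e5) {
  step1 <- clump_by_distance(sumstats, window = window, gws = gws)
  leads <- vapply(step1, function(l) l$top_variant, "")
  loci <- list()
  for (chrom in unique(sumstats$chromosome)) {
    ss <- sumstats[sumstats$chromosome == chrom &
                     sumstats$p_value < p_cluster, , drop = FALSE]
    if (nrow(ss) == 0L) next
    ss <- ss[order(ss$base_pair_location), , drop = FALSE]
    breaks <- c(0L, which(diff(ss$base_pair_location) > gap), nrow(ss))
    for (i in seq_len(length(breaks) - 1L)) {
      cl <- ss[(breaks[i] + 1L):breaks[i + 1L], , drop = FALSE]
      if (!any(cl$p_value <= gws)) next
      span <- max(cl$base_pair_location) - min(cl$base_pair_location)
      if (span <= max_span) {
        top <- cl$variant_id[significance_order(cl$p_value, cl$beta,
                                                cl$variant_id)[1L]]
        loci[[length(loci) + 1L]] <- new_locus(chrom, cl, top, "locus_breaker")
      } else {
        in_cl <- leads[leads %in% cl$variant_id]
        if (length(in_cl) == 0L) next
        lead_pos <- cl$base_pair_location[match(in_cl, cl$variant_id)]
        nearest <- apply(abs(outer(cl$base_pair_location, lead_pos, "-")),
                         1L, which.min)
        for (j in seq_along(in_cl)) {
          sub <- cl[nearest == j &
                      abs(cl$base_pair_location - lead_pos[j]) <= half_window,
                    , drop = FALSE]
          if (nrow(sub) == 0L) next
          loci[[length(loci) + 1L]] <- new_locus(chrom, sub, in_cl[j],
                                                 "locus_breaker")
        }
      }
    }
  }
  loci
}

# PICS proxy weight: two-sided normal tail of the lead's -log10 p at the
# proxy's expected value r2*S and spread sqrt(1 - r^exponent) * sqrt(S) / 2.
# A perfect proxy (r2 = 1) has zero spread and ties with the lead (weight 1).
pics_weight <- function(r2, S, exponent = 6.4) {
  mu <- r2 * S
  sd <- sqrt(pmax(0, 1 - r2^(exponent / 2))) * sqrt(S) / 2
  w <- ifelse(sd == 0, as.numeric(abs(S - mu) < 1e-12),
              2 * stats::pnorm(abs(S - mu) / ifelse(sd == 0, 1, sd),
                               lower.tail = FALSE))
  w
}

#' PICS fine-mapping of one locus
#'
#' Assigns each LD proxy of the lead variant (r-squared at or above
#' `r2_min`) a causal probability from the lead's significance and the
#' proxy's r-squared, normalised to sum to 1 over the proxy set. The 95%
#' credible set is the smallest prefix of variants in descending probability
#' whose cumulative sum reaches 0.95.
#'
#' @param locus a locus from one of the clumping functions; members carry
#'   `variant_id`, `p_value`, `base_pair_location`.
#' @param ld_row named vector of signed r between the lead and each member
#'   (the lead's LD matrix row).
#' @param lead_variant lead variant id (default: the locus top variant).
#' @param r2_min proxy threshold (default 0.5).
#' @param exponent LD-decay exponent of the spread term (default 6.4, applied
#'   to signed r, i.e. r2^(exponent/2)).
#' @param study_id study identifier stamped on the credible set.
#' @param cs_id credible-set identifier (default derived from the lead).
#' @param ... extra fields passed to [new_credible_set()].
#' @return a [new_credible_set()] with `method = "pics"` and full-locus PIPs
#'   attached as attribute `pips`.
#' @export
pics_finemap <- function(locus, ld_row, lead_variant = locus$top_variant,
                         r2_min = 0.5, exponent = 6.4,
                         study_id = NA_character_,
                         cs_id = paste0("CS_", lead_variant), ...) {
  members <- locus$members
  assert_that(lead_variant %in% members$variant_id,
              "lead variant missing from locus members")
  assert_that(all(members$variant_id %in% names(ld_row)),
              "lead LD row missing for some locus members")
  lead_p <- members$p_value[members$variant_id == lead_variant][1]
  S <- -log10(max(lead_p, 1e-300))
  r2 <- ld_row[members$variant_id]^2
  r2[lead_variant] <- 1
  proxies <- members[r2 >= r2_min, , drop = FALSE]
  w <- pics_weight(r2[proxies$variant_id], S, exponent)
  pip <- w / sum(w)
  ord <- order(-pip, proxies$variant_id)
  cum <- cumsum(pip[ord])
  k <- which(cum >= 0.95)[1L]
  sel <- ord[seq_len(k)]
  cs_members <- data.frame(variant = proxies$variant_id[sel], pip = pip[sel],
                           stringsAsFactors = FALSE)
  full <- data.frame(variant = proxies$variant_id, pip = pip,
                     stringsAsFactors = FALSE)
  cs <- new_credible_set(cs_id = cs_id, study_id = study_id,
                         lead_variant = lead_variant, members = cs_members,
                         method = "pics", lead_p = lead_p,
                         region = list(chrom = locus$chrom,
                                       start = locus$start, end = locus$end),
                         ...)
  attr(cs, "pips") <- full
  cs
}

#' Apply source-class lead p-value thresholds to credible sets
#'
#' GWAS-class credible sets are kept when the lead p-value is at most 1e-5,
#' molQTL-class when at most 1e-3. Designated studies may carry a stricter
#' study-specific genome-wide threshold (e.g. 1.7e-11) that overrides the
#' class threshold.
#'
#' @param cs_list list of credible sets.
#' @param class `"gwas"` or `"molqtl"` (recycled over the list).
#' @param gwas_threshold lead threshold for GWAS-class sets (default 1e-5).
#' @param molqtl_threshold lead threshold for molQTL-class sets (default 1e-3).
#' @param study_overrides named numeric vector of per-study thresholds.
#' @return the filtered list.
#' @export
apply_lead_p_threshold <- function(cs_list, class = "gwas",
                                   gwas_threshold = 1e-5,
                                   molqtl_threshold = 1e-3,
                                   study_overrides = NULL) {
  class <- rep_len(class, length(cs_list))
  keep <- vapply(seq_along(cs_list), function(i) {
    cs <- cs_list[[i]]
    thr <- if (!is.null(study_overrides) && cs$study_id %in% names(study_overrides)) {
      study_overrides[[cs$study_id]]
    } else if (class[i] == "gwas") gwas_threshold else molqtl_threshold
    isTRUE(cs$lead_p <= thr)
  }, logical(1))
  cs_list[keep]
}
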