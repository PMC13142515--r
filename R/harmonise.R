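#' Default therapeutic-area hierarchy
#'
#' A totally ordered table of 23 therapeutic areas. When a trait's ontology
#' ancestors reach several areas, the highest-priority (smallest rank) one is
#' chosen; oncology outranks organ-system areas, so an ovarian-cancer-like
#' term maps to the cancer area rather than the reproductive-system one.
#' `measurement` is never assigned (measurement traits are handled
#' separately) and `other` is the fallback for traits reaching no area.
#'
#' @return data frame with columns `ta` and `rank`.
#' @export
default_ta_hierarchy <- function() {
  tas <- c("cancer or benign tumour",
           "infectious disease",
           "pregnancy or perinatal disease",
           "immune system disease",
           "nervous system disease",
           "cardiovascular disease",
           "respiratory or thoracic disease",
           "endocrine system disease",
           "digestive system disease",
           "musculoskeletal or connective tissue disease",
           "urinary system disease",
           "reproductive system or breast disease",
           "integumentary system disease",
           "hematologic disease",
           "nutritional or metabolic disease",
           "psychiatric disorder",
           "head and neck disorder",
           "eye disease",
           "ear disease",
           "genetic, familial or congenital disease",
           "injury, poisoning or other complication",
           "measurement",
           "other")
  data.frame(ta = tas, rank = seq_along(tas), stringsAsFactors = FALSE)
}

#' Major-ancestry minor allele frequency for a variant
#'
#' Chooses the study's major population and reads that population's effect
#' allele frequency: (1) a single population is used directly; (2) with
#' uneven proportions the largest wins; (3) an exact tie prefers NFE, else
#' the first population listed. MAF = min(EAF, 1 - EAF). A variant absent
#' from the table (or with an undefined frequency for the major population)
#' yields a failed-annotation record rather than a value.
#'
#' @param ancestry named list or vector of population proportions (sums to 1).
#' @param variant variant id.
#' @param freq_table data frame with `variant_id` and one EAF column per
#'   population.
#' @return list with `population`, `maf` (NA on failure) and `failed`.
#' @export
annotate_major_ancestry_maf <- function(ancestry, variant, freq_table) {
  props <- unlist(ancestry)
  assert_that(length(props) > 0, "empty ancestry composition")
  assert_that(abs(sum(props) - 1) < 1e-6, "ancestry proportions must sum to 1")
  pops <- setdiff(names(freq_table), "variant_id")
  assert_that(length(pops) >= 1L, "frequency table has no population column")
  if (length(props) == 1L) {
    major <- names(props)
  } else {
    mx <- max(props)
    tied <- names(props)[props >= mx - 1e-12]
    major <- if (length(tied) == 1L) tied
             else if ("NFE" %in% tied) "NFE"
             else tied[1L]
  }
  row <- freq_table[freq_table$variant_id == variant, , drop = FALSE]
  if (nrow(row) == 0L || !(major %in% pops) || is.na(row[[major]][1])) {
    return(list(population = major, maf = NA_real_, failed = TRUE))
  }
  eaf <- row[[major]][1]
  list(population = major, maf = min(eaf, 1 - eaf), failed = FALSE)
}

#' Rescale a marginal effect from its p-value
#'
#' Re-estimates the effect size and standard error from the association
#' p-value: |Z| is the square root of the (1-p) quantile of chi-squared(1);
#' the standard error is 1/sqrt(2 n f (1-f) K (1-K)) for binary traits
#' (logistic beta) and 1/sqrt(2 n f (1-f)) for quantitative traits (linear
#' beta); the rescaled effect is SE * Z with the reported sign. P-values may
#' be supplied as log10(p) via `log10_p` so genome-wide significant values
#' never underflow. A record with unknown sign only carries the magnitude and
#' is flagged unusable for direction analyses.
#'
#' @param p p-value in (0, 1]; ignored when `log10_p` is given.
#' @param sign_char `"+"`, `"-"` or `"unknown"`.
#' @param n sample size.
#' @param f major-ancestry MAF in (0, 0.5].
#' @param K case proportion in (0,1) (binary traits only).
#' @param trait_type `"binary"` or `"quantitative"`.
#' @param log10_p optional log10 of the p-value (<= 0), for underflowing p.
#' @return list with `z` (|Z|), `se_hat`, `beta_resc` (signed, or magnitude
#'   when the sign is unknown), `direction_usable`.
#' @export
rescale_effect <- function(p = NULL, sign_char = "unknown", n, f, K = NULL,
                           trait_type = c("quantitative", "binary"),
                           log10_p = NULL) {
  trait_type <- match.arg(trait_type)
  assert_that(f > 0 && f <= 0.5, "f must be in (0, 0.5]")
  assert_that(n > 0, "n must be positive")
  if (is.null(log10_p)) {
    assert_that(!is.null(p) && p > 0 && p <= 1,
                "p must be in (0,1]; use log10_p for underflowing p-values")
    log10_p <- log10(p)
  }
  assert_that(log10_p <= 0, "log10_p must be <= 0")
  # complementary quantile in log space: qchisq(p, lower.tail = FALSE) with
  # log p never materialising a subnormal double
  z <- sqrt(stats::qchisq(log10_p * log(10), df = 1, lower.tail = FALSE,
                          log.p = TRUE))
  se_hat <- if (trait_type == "binary") {
    assert_that(!is.null(K) && K > 0 && K < 1, "binary trait requires K in (0,1)")
    1 / sqrt(2 * n * f * (1 - f) * K * (1 - K))
  } else {
    1 / sqrt(2 * n * f * (1 - f))
  }
  usable <- sign_char %in% c("+", "-")
  beta <- se_hat * z * if (identical(sign_char, "-")) -1 else 1
  list(z = z, se_hat = se_hat,
       beta_resc = if (usable) beta else abs(beta),
       direction_usable = usable)
}

#' Expected power to detect an association
#'
#' Non-centrality NCP = maxBeta^2 * maxEffN * 2 * maxMAF * (1 - maxMAF) /
#' `divisor`, with power the upper-tail probability of a non-central
#' chi-squared(1, NCP) beyond the central (1 - 1e-8) quantile. The default
#' divisor 11 scales the observed maximal effect down by an order of
#' magnitude, modelling detection of this variant's associations with most
#' traits at much smaller effects; `divisor = 1` gives the variant's own
#' detection power.
#'
#' @param max_beta maximal absolute rescaled effect (the sign is irrelevant).
#' @param max_eff_n maximal effective sample size.
#' @param max_maf maximal MAF; an allele frequency f in (0, 1) is accepted
#'   since 2 f (1 - f) is symmetric in f and 1 - f.
#' @param divisor NCP scaling divisor (default 11).
#' @return power in [1e-8, 1].
#' @export
compute_power <- function(max_beta, max_eff_n, max_maf, divisor = 11) {
  assert_that(all(max_eff_n > 0) && all(max_maf > 0) && all(max_maf < 1),
              "max_eff_n must be positive and max_maf in (0, 1)")
  ncp <- max_beta^2 * max_eff_n * 2 * max_maf * (1 - max_maf) / divisor
  thr <- stats::qchisq(1e-8, df = 1, lower.tail = FALSE)
  stats::pchisq(thr, df = 1, ncp = ncp, lower.tail = FALSE)
}

consequence_order <- c("PAV", "promoter", "enhancer", "intragenic", "intergenic")

#' Resolve the most severe consequence for a variant-gene pair
#'
#' Multiple predicted impacts collapse to one category by the fixed severity
#' order PAV > promoter > enhancer > intragenic > intergenic.
#'
#' @param categories character vector of candidate categories.
#' @return the single most severe category.
#' @export
resolve_most_severe <- function(categories) {
  assert_that(length(categories) >= 1L, "at least one candidate category required")
  bad <- setdiff(categories, consequence_order)
  assert_that(length(bad) == 0L,
              paste("unknown consequence categories:", paste(bad, collapse = ", ")))
  consequence_order[min(match(categories, consequence_order))]
}

#' Filter lead variants for consequence-level analyses
#'
#' Drops credible sets that are not replicated, not qualified, or whose lead
#' PIP is below 0.5; then, where a variant is associated with the same trait
#' several times, keeps the single representative credible set with the
#' largest absolute rescaled effect.
#'
#' @param cs_df data frame with columns `cs_id`, `lead_variant`, `trait_id`,
#'   `qualified`, `replicated`, `lead_pip`, `abs_beta_resc`.
#' @return the filtered data frame.
#' @export
filter_lead_variants_for_consequence_analysis <- function(cs_df) {
  need <- c("cs_id", "lead_variant", "trait_id", "qualified", "replicated",
            "lead_pip", "abs_beta_resc")
  assert_that(all(need %in% names(cs_df)),
              paste("cs_df must carry", paste(need, collapse = ", ")))
  keep <- cs_df$qualified & cs_df$replicated & cs_df$lead_pip >= 0.5
  out <- cs_df[keep, , drop = FALSE]
  if (nrow(out) == 0L) return(out)
  key <- paste(out$lead_variant, out$trait_id, sep = "\r")
  ord <- order(key, -out$abs_beta_resc, out$cs_id)
  out <- out[ord, , drop = FALSE]
  out[!duplicated(key[ord]), , drop = FALSE]
}

#' Flag credible-set replication
#'
#' A GWAS credible set is replicated when its lead variant-trait pair recurs
#' in a different cohort/biobank, publication, or ancestry group. A molQTL
#' credible set is replicated when its lead variant-gene pair is seen at
#' least twice anywhere.
#'
#' @param cs_df data frame with `cs_id`, `study_id`, `lead_variant`,
#'   `trait_id`, `gene_id` (molQTLs), `class` (`"gwas"` or `"molqtl"`).
#' @param studies study metadata with `study_id`, `cohort`, `year` and
#'   `ancestry` (the ancestry group label is the name of the largest
#'   component).
#' @return logical vector of replicated flags aligned with `cs_df` rows.
#' @export
flag_replication <- function(cs_df, studies) {
  anc_label <- vapply(studies$ancestry, function(a) {
    p <- unlist(a); names(p)[which.max(p)]
  }, "")
  meta <- data.frame(study_id = studies$study_id, cohort = studies$cohort,
                     year = studies$year, anc = anc_label,
                     stringsAsFactors = FALSE)
  m <- merge(cs_df, meta, by = "study_id", all.x = TRUE, sort = FALSE)
  m <- m[match(cs_df$cs_id, m$cs_id), ]
  rep_flag <- logical(nrow(m))
  gw <- which(m$class == "gwas")
  if (length(gw)) {
    key <- paste(m$lead_variant[gw], m$trait_id[gw], sep = "\r")
    for (k in unique(key)) {
      rows <- gw[key == k]
      if (length(rows) < 2L) next
      distinct <- length(unique(m$cohort[rows])) > 1L ||
        length(unique(m$year[rows])) > 1L ||
        length(unique(m$anc[rows])) > 1L
      rep_flag[rows] <- distinct
    }
  }
  mq <- which(m$class == "molqtl")
  if (length(mq)) {
    key <- paste(m$lead_variant[mq], m$gene_id[mq], sep = "\r")
    tab <- table(key)
    rep_flag[mq] <- tab[key] >= 2L
  }
  rep_flag
}

#' Qualify studies
#'
#' Disease studies qualify when binary with total sample size strictly above
#' 1,000 and in-study prevalence (n_cases / n) strictly above 0.1%.
#' Measurement studies qualify when quantitative and the trait is not a
#' protein or microbiome measurement.
#'
#' @param studies study metadata data frame (see [simulate_studies()]); an
#'   optional `trait_class` column marks `"protein"` / `"microbiome"`
#'   measurements.
#' @return logical vector of qualified flags.
#' @export
qualify_studies <- function(studies) {
  tc <- studies$trait_class %||% rep("", nrow(studies))
  ifelse(studies$study_type == "disease",
         !studies$is_quantitative & studies$n > 1000 &
           !is.na(studies$n_cases) & studies$n_cases / studies$n > 0.001,
         studies$is_quantitative & !(tc %in% c("protein", "microbiome")))
}

#' Qualify credible sets
#'
#' Requires the parent study to be qualified, a minor allele count
#' 2 * n * MAF of at least 20 and an absolute rescaled effect strictly below
#' 3. Rare leads (MAF < 1%) additionally need at least one of: a significant
#' molQTL colocalisation, a PAV in the credible set, or replication. Adding
#' evidence can therefore only qualify, never un-qualify, a set.
#'
#' @param cs_df data frame with `study_qualified`, `n`, `maf`,
#'   `abs_beta_resc`, `has_molqtl_coloc`, `has_pav`, `replicated`.
#' @return logical vector of qualified flags.
#' @export
qualify_credible_sets <- function(cs_df) {
  need <- c("study_qualified", "n", "maf", "abs_beta_resc",
            "has_molqtl_coloc", "has_pav", "replicated")
  assert_that(all(need %in% names(cs_df)),
              paste("cs_df must carry", paste(need, collapse = ", ")))
  mac <- 2 * cs_df$n * cs_df$maf
  base <- cs_df$study_qualified & !is.na(cs_df$maf) & mac >= 20 &
    cs_df$abs_beta_resc < 3
  rare_ok <- cs_df$maf >= 0.01 |
    cs_df$has_molqtl_coloc | cs_df$has_pav | cs_df$replicated
  base & rare_ok
}

#' Assign a therapeutic area to a trait
#'
#' Walks the ontology upward from the trait, collects every therapeutic-area
#' root reached, drops `measurement`, and returns the highest-priority area
#' in the hierarchy; a trait reaching no area maps to `other`.
#'
#' @param trait_id ontology term.
#' @param edges two-column data frame (`child`, `parent`) of ontology edges.
#' @param hierarchy therapeutic-area hierarchy table
#'   (default [default_ta_hierarchy()]); `ta` column entries must appear as
#'   ontology nodes to be reachable.
#' @return therapeutic-area label.
#' @export
assign_therapeutic_area <- function(trait_id, edges,
                                    hierarchy = default_ta_hierarchy()) {
  anc <- ancestors_of(trait_id, edges)
  hit <- hierarchy[hierarchy$ta %in% c(trait_id, anc) &
                     hierarchy$ta != "measurement", , drop = FALSE]
  if (nrow(hit) == 0L) return("other")
  hit$ta[which.min(hit$rank)]
}

# all ancestors of a node (excluding itself) over (child, parent) edges
ancestors_of <- function(node, edges) {
  assert_that(all(c("child", "parent") %in% names(edges)),
              "edges must have columns child, parent")
  seen <- character(0)
  frontier <- node
  while (length(frontier)) {
    parents <- unique(edges$parent[edges$child %in% frontier])
    new <- setdiff(parents, c(seen, node))
    seen <- c(seen, new)
    frontier <- new
  }
  seen
}

# all descendants of a node (excluding itself)
descendants_of <- function(node, edges) {
  seen <- character(0)
  frontier <- node
  while (length(frontier)) {
    children <- unique(edges$child[edges$parent %in% frontier])
    new <- setdiff(children, c(seen, node))
    seen <- c(seen, new)
    frontier <- new
  }
  seen
}
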