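#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions for a seeded synthetic cohort: an LD-blocked
#' genome, disease/measurement/molQTL studies with planted causal variants,
#' planted pleiotropic genes shared across diseases and therapeutic areas,
#' molQTL credible sets colocalising with the planted GWAS signals, and a
#' target-indication clinical pipeline whose approval odds depend on genetic
#' support and a log-shaped pleiotropy term.
#'
#' @param seed integer root seed; all randomness flows from it through named
#'   child streams (one per operation), so identical configs reproduce
#'   byte-identical outputs.
#' @param n_ld_blocks number of independent LD blocks.
#' @param block_size_bp width of each block in base pairs.
#' @param variants_per_block variants per block.
#' @param genes_per_block genes per block.
#' @param n_disease_studies,n_measurement_studies,n_molqtl_studies study counts.
#' @param maf_shape1,maf_shape2 beta-distribution shape parameters of the MAF
#'   spectrum (MAF = 0.5 * Beta(shape1, shape2), floored at 5e-4).
#' @param effect_coupling exponent alpha of the inverse MAF-effect coupling
#'   |beta| proportional to (2 f (1-f))^-alpha.
#' @param ld_rho AR(1) decay of within-block LD (signed r).
#' @param target_power detection power aimed at for planted signals at the
#'   median MAF (the MAF coupling moves individual signals around it).
#' @param prop_distal fraction of planted signals whose causal gene is not the
#'   nearest gene (regulatory evidence carries the assignment instead).
#' @param pleiotropy_plan data frame with columns `gene_id` (plan index, 1-based
#'   gene rank), `n_diseases`: genes planted as causal for several diseases.
#'   `NULL` uses a default plan (one gene with 5 diseases, one with 3, one
#'   with 2, remaining diseases unique).
#' @param pav_rate_by_maf named numeric vector of PAV probabilities per MAF bin
#'   (breaks 0, 0.01, 0.1, 0.5), decreasing in MAF.
#' @param ti_plan list with `n_ti` (records), `p12`, `p23` (baseline phase
#'   transition probabilities), `base_logodds` (baseline approval log-odds),
#'   `b_support`, `b_logpleio`, `b_logpleio_sq` (approval log-odds
#'   coefficients), `support_rate` (fraction of records with genetic support
#'   when generated standalone).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_ld_blocks = 30L,
                       block_size_bp = 1e6,
                       variants_per_block = 60L,
                       genes_per_block = 3L,
                       n_disease_studies = 12L,
                       n_measurement_studies = 6L,
                       n_molqtl_studies = 10L,
                       maf_shape1 = 0.8,
                       maf_shape2 = 2.5,
                       effect_coupling = 0.5,
                       ld_rho = 0.9,
                       target_power = 0.95,
                       prop_distal = 0.3,
                       pav_rate_by_maf = c("(0,0.01]" = 0.25,
                                           "(0.01,0.1]" = 0.12,
                                           "(0.1,0.5]" = 0.05),
                       pleiotropy_plan = NULL,
                       ti_plan = list(n_ti = 4000L, p12 = 0.7, p23 = 0.55,
                                      base_logodds = stats::qlogis(0.10),
                                      b_support = log(3.6),
                                      b_logpleio = 0, b_logpleio_sq = 0,
                                      support_rate = 0.2)) {
  cfg <- list(seed = as.integer(seed), n_ld_blocks = as.integer(n_ld_blocks),
              block_size_bp = block_size_bp,
              variants_per_block = as.integer(variants_per_block),
              genes_per_block = as.integer(genes_per_block),
              n_disease_studies = as.integer(n_disease_studies),
              n_measurement_studies = as.integer(n_measurement_studies),
              n_molqtl_studies = as.integer(n_molqtl_studies),
              maf_shape1 = maf_shape1, maf_shape2 = maf_shape2,
              effect_coupling = effect_coupling, ld_rho = ld_rho,
              target_power = target_power, prop_distal = prop_distal,
              pav_rate_by_maf = pav_rate_by_maf,
              pleiotropy_plan = pleiotropy_plan, ti_plan = ti_plan)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_ld_blocks, cfg$variants_per_block, cfg$genes_per_block,
              cfg$n_disease_studies, cfg$n_measurement_studies,
              cfg$n_molqtl_studies, cfg$block_size_bp)
  assert_that(all(counts > 0), "all counts must be positive")
  probs <- c(cfg$target_power, cfg$prop_distal, cfg$pav_rate_by_maf,
             cfg$ti_plan$p12, cfg$ti_plan$p23, cfg$ti_plan$support_rate)
  assert_that(all(probs >= 0 & probs <= 1), "all probabilities must be in [0,1]")
  assert_that(abs(cfg$ld_rho) < 1, "ld_rho must be in (-1, 1)")
  invisible(cfg)
}

# project a symmetric matrix to the nearest PSD matrix by eigenvalue clipping
project_psd <- function(m, eps = 1e-10) {
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / (d %o% d)  # restore unit diagonal
  (out + t(out)) / 2
}

#' Simulate an LD-blocked genome
#'
#' Each block gets an AR(1)-style signed correlation matrix
#' (r_ij = s_i s_j rho^|i-j| for random per-variant signs s), which is
#' positive definite by construction; a nearest-PSD projection with bounded
#' retries guards degenerate numerical cases. Variant positions are strictly
#' increasing within each chromosome, MAFs follow the configured beta
#' spectrum, and each block carries a handful of genes with TSS and
#' footprint intervals.
#'
#' @param config a [sim_config()].
#' @param max_retries retries of the PSD construction before failing.
#' @return list with `variants` (data frame: variant_id, chromosome, position,
#'   ref, alt, maf, block), `ld` (list of per-block matrices keyed by variant
#'   id), `genes` (data frame with tss, footprint, constraint covariates) and
#'   the config.
#' @export
simulate_ld_genome <- function(config, max_retries = 5L) {
  validate_sim_config(config)
  with_stream(config$seed, "genome", {
    bases <- c("A", "C", "G", "T")
    vlist <- list(); ld <- list(); glist <- list()
    for (b in seq_len(config$n_ld_blocks)) {
      chrom <- as.character(((b - 1L) %% 22L) + 1L)
      rank_on_chrom <- (b - 1L) %/% 22L
      offset <- rank_on_chrom * (config$block_size_bp + 2e6)
      m <- config$variants_per_block
      pos <- sort(sample.int(config$block_size_bp, m)) + offset
      maf <- pmax(5e-4, 0.5 * stats::rbeta(m, config$maf_shape1, config$maf_shape2))
      ref <- sample(bases, m, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
      vid <- variant_id(chrom, pos, ref, alt)
      vlist[[b]] <- data.frame(variant_id = vid, chromosome = chrom,
                               position = pos, ref = ref, alt = alt,
                               maf = maf, block = b, stringsAsFactors = FALSE)
      signs <- sample(c(-1, 1), m, replace = TRUE)
      base_r <- config$ld_rho ^ abs(outer(seq_len(m), seq_len(m), "-"))
      R <- (signs %o% signs) * base_r
      diag(R) <- 1
      tries <- 0L
      while (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
        tries <- tries + 1L
        if (tries > max_retries) stop("failed to construct a PSD LD block")
        R <- project_psd(R)
      }
      dimnames(R) <- list(vid, vid)
      ld[[b]] <- R
      ng <- config$genes_per_block
      tss <- sort(sample.int(config$block_size_bp, ng)) + offset
      glen <- round(stats::runif(ng, 2e4, 2e5))
      gid <- sprintf("GENE_%04d", (b - 1L) * ng + seq_len(ng))
      glist[[b]] <- data.frame(
        gene_id = gid, chromosome = chrom, tss = tss,
        footprint_start = tss, footprint_end = tss + glen,
        gene_length = glen, block = b,
        protein_coding = stats::runif(ng) < 0.9,
        lof_constraint = stats::runif(ng),
        missense_constraint = stats::runif(ng),
        pathway_count = stats::rpois(ng, 5),
        stringsAsFactors = FALSE)
    }
    list(variants = do.call(rbind, vlist), ld = ld,
         genes = do.call(rbind, glist), config = config)
  })
}

# therapeutic area assigned to each synthetic disease, cycling over the
# non-oncology areas of the default hierarchy so pleiotropy plans span TAs
disease_ta_map <- function(n_diseases) {
  tas <- setdiff(default_ta_hierarchy()$ta, c("cancer or benign tumour",
                                              "measurement", "other"))
  data.frame(trait_id = sprintf("EFO_D%02d", seq_len(n_diseases)),
             ta = tas[((seq_len(n_diseases) - 1L) %% length(tas)) + 1L],
             stringsAsFactors = FALSE)
}

#' Build the truth table of planted signals
#'
#' Chooses causal genes and variants for every disease and measurement study,
#' following the pleiotropy plan: planted pleiotropic genes are causal for
#' several diseases (through the same causal variant, so colocalisation can
#' recover the sharing), and every planted gene's true gene-level pleiotropy
#' score equals the size of its planted disease set. Effect sizes follow the
#' inverse MAF coupling |beta| = c * (2f(1-f))^-alpha with c calibrated so the
#' median-MAF signal reaches the configured detection power.
#'
#' @param genome output of [simulate_ld_genome()].
#' @param config the [sim_config()] (defaults to the genome's).
#' @return list with `signals` (one row per planted study signal),
#'   `gene_diseases` (planted disease set per gene), `disease_ta` map and the
#'   planted TI coefficients.
#' @export
make_truth_table <- function(genome, config = genome$config) {
  with_stream(config$seed, "truth", {
    nd <- config$n_disease_studies
    dis <- sprintf("EFO_D%02d", seq_len(nd))
    plan <- config$pleiotropy_plan
    if (is.null(plan)) {
      sizes <- c(5L, 3L, 2L)
      sizes <- sizes[sizes <= nd]
      plan <- data.frame(gene_rank = seq_along(sizes), n_diseases = sizes)
    }
    pc_genes <- genome$genes$gene_id[genome$genes$protein_coding]
    # spread planted genes over blocks; recycle the pool when the cohort asks
    # for more planted genes than the genome carries
    gene_pool <- sample(pc_genes)
    needed <- nrow(if (is.data.frame(plan)) plan else as.data.frame(plan)) +
      nd + config$n_measurement_studies
    gene_pool <- rep(gene_pool, length.out = max(needed, length(gene_pool)))
    assign <- list(); used <- 0L
    di <- 1L
    for (i in seq_len(nrow(plan))) {
      g <- gene_pool[i]
      k <- min(plan$n_diseases[i], nd - di + 1L)
      if (k <= 0) break
      assign[[length(assign) + 1L]] <- data.frame(
        gene_id = g, trait_id = dis[di:(di + k - 1L)], stringsAsFactors = FALSE)
      di <- di + k
    }
    used <- nrow(plan)
    while (di <= nd) {
      used <- used + 1L
      assign[[length(assign) + 1L]] <- data.frame(
        gene_id = gene_pool[used], trait_id = dis[di], stringsAsFactors = FALSE)
      di <- di + 1L
    }
    gd <- do.call(rbind, assign)
    # measurement studies each get one causal gene too
    meas <- sprintf("EFO_M%02d", seq_len(config$n_measurement_studies))
    gm <- data.frame(gene_id = gene_pool[used + seq_along(meas)],
                     trait_id = meas, stringsAsFactors = FALSE)
    all_pairs <- rbind(gd, gm)

    # one causal variant per planted gene, shared across its diseases
    genes <- genome$genes
    variants <- genome$variants
    causal <- vapply(unique(all_pairs$gene_id), function(g) {
      grow <- genes[genes$gene_id == g, ]
      cand <- variants[variants$block == grow$block, ]
      distal <- stats::runif(1) < config$prop_distal
      if (distal) {
        # park the causal variant near a *different* gene of the same block
        others <- genes[genes$block == grow$block & genes$gene_id != g, ]
        anchor <- if (nrow(others)) others$tss[sample.int(nrow(others), 1L)] else grow$tss
      } else {
        anchor <- grow$tss
      }
      cand$variant_id[which.min(abs(cand$position - anchor))]
    }, "")
    causal_df <- data.frame(gene_id = names(causal), variant_id = causal,
                            stringsAsFactors = FALSE)
    sig <- merge(all_pairs, causal_df, by = "gene_id")
    sig <- merge(sig, variants[c("variant_id", "maf", "block")], by = "variant_id")
    # calibrate the coupling constant at the median MAF for the target power
    n_eff_ref <- 4 / (1 / 2e4 + 1 / 8e4)   # reference disease cohort below
    med_maf <- stats::median(variants$maf)
    beta_ref <- beta_for_power(config$target_power, n_eff_ref, med_maf)
    c0 <- beta_ref * (2 * med_maf * (1 - med_maf))^config$effect_coupling
    sig$beta <- sign(stats::runif(nrow(sig)) - 0.5) *
      c0 * (2 * sig$maf * (1 - sig$maf))^(-config$effect_coupling)
    sig$signal_id <- sprintf("SIG_%03d", seq_len(nrow(sig)))
    sig$distal <- !mapply(function(v, g) {
      grow <- genes[genes$gene_id == g, ]
      vrow <- variants[variants$variant_id == v, ]
      near <- genes[genes$block == vrow$block, ]
      near$gene_id[which.min(abs(near$tss - vrow$position))] == g
    }, sig$variant_id, sig$gene_id)
    gd_sets <- split(gd$trait_id, gd$gene_id)
    list(signals = sig,
         gene_diseases = gd_sets,
         disease_ta = disease_ta_map(nd),
         ti_coefficients = config$ti_plan[c("base_logodds", "b_support",
                                            "b_logpleio", "b_logpleio_sq")])
  })
}

#' Effect size reaching a given detection power
#'
#' Inverts the non-central chi-squared power curve at the genome-wide
#' significance threshold: finds beta such that a variant with allele
#' frequency `maf` in a study of effective size `n_eff` is detected with the
#' requested probability.
#'
#' @param power target detection probability in (1e-8, 1).
#' @param n_eff effective sample size.
#' @param maf minor allele frequency in (0, 0.5].
#' @return positive effect size.
#' @export
beta_for_power <- function(power, n_eff, maf) {
  stopifnot(power > 1e-8, power < 1, n_eff > 0, maf > 0, maf <= 0.5)
  thr <- stats::qchisq(1e-8, df = 1, lower.tail = FALSE)
  f <- function(log_ncp) {
    stats::pchisq(thr, df = 1, ncp = exp(log_ncp), lower.tail = FALSE) - power
  }
  ncp <- exp(stats::uniroot(f, c(log(1e-6), log(1e5)))$root)
  sqrt(ncp / (n_eff * 2 * maf * (1 - maf)))
}

#' Simulate the study metadata table
#'
#' @param config a [sim_config()].
#' @return data frame of study records (see `StudyRecord` fields).
#' @export
simulate_studies <- function(config) {
  with_stream(config$seed, "studies", {
    mk <- function(ids, type, traits, quantitative) {
      n <- length(ids)
      total <- round(stats::runif(n, 5e4, 2e5))
      ncase <- if (quantitative) rep(NA_integer_, n) else
        round(total * stats::runif(n, 0.1, 0.3))
      anc <- replicate(n, {
        if (stats::runif(1) < 0.8) list(NFE = 1.0)
        else list(NFE = 0.6, AFR = 0.4)
      }, simplify = FALSE)
      data.frame(study_id = ids, study_type = type, trait_id = traits,
                 n = total, n_cases = ncase,
                 year = sample(2010:2024, n, replace = TRUE),
                 cohort = sample(c("BIOBANK_A", "BIOBANK_B", "META_C"), n,
                                 replace = TRUE),
                 is_quantitative = quantitative,
                 ancestry = I(anc), stringsAsFactors = FALSE)
    }
    nd <- config$n_disease_studies
    nm <- config$n_measurement_studies
    rbind(
      mk(sprintf("GWAS_D%02d", seq_len(nd)), "disease",
         sprintf("EFO_D%02d", seq_len(nd)), quantitative = FALSE),
      mk(sprintf("GWAS_M%02d", seq_len(nm)), "measurement",
         sprintf("EFO_M%02d", seq_len(nm)), quantitative = TRUE)
    )
  })
}

effective_n <- function(n, n_cases, quantitative) {
  if (quantitative || is.na(n_cases)) return(n)
  4 / (1 / n_cases + 1 / (n - n_cases))
}

#' Simulate GWAS summary statistics for one study
#'
#' Marginal z-scores follow the standard summary-statistic model
#' z = R lambda + eps, eps ~ N(0, R) per LD block, where lambda carries the
#' planted causal signals (lambda_j = beta_j sqrt(2 f_j (1-f_j) n_eff)). The
#' planted causal variant therefore reaches genome-wide significance with the
#' probability given by the non-central chi-squared power curve at its own
#' non-centrality.
#'
#' @param genome output of [simulate_ld_genome()].
#' @param study one row of [simulate_studies()] (data frame or list).
#' @param truth output of [make_truth_table()].
#' @return GWAS-SSF-style data frame of summary statistics.
#' @export
simulate_study_sumstats <- function(genome, study, truth) {
  study <- as.list(study)
  config <- genome$config
  sig <- truth$signals[truth$signals$trait_id == study$trait_id, , drop = FALSE]
  unknown <- setdiff(sig$variant_id, genome$variants$variant_id)
  assert_that(length(unknown) == 0L,
              paste("planted causal variant not in genome:",
                    paste(unknown, collapse = ", ")))
  n_eff <- effective_n(study$n, study$n_cases, isTRUE(study$is_quantitative))
  with_stream(config$seed, paste0("sumstats/", study$study_id), {
    out <- lapply(seq_along(genome$ld), function(b) {
      R <- genome$ld[[b]]
      v <- genome$variants[genome$variants$block == b, ]
      m <- nrow(v)
      lambda <- numeric(m)
      idx <- match(sig$variant_id, v$variant_id)
      keep <- !is.na(idx)
      if (any(keep)) {
        f <- v$maf[idx[keep]]
        lambda[idx[keep]] <- sig$beta[keep] * sqrt(2 * f * (1 - f) * n_eff)
      }
      L <- tryCatch(chol(R), error = function(e) chol(R + diag(1e-8, m)))
      z <- as.numeric(R %*% lambda + t(L) %*% stats::rnorm(m))
      se <- if (isTRUE(study$is_quantitative)) {
        1 / sqrt(2 * study$n * v$maf * (1 - v$maf))
      } else {
        K <- study$n_cases / study$n
        1 / sqrt(2 * study$n * v$maf * (1 - v$maf) * K * (1 - K))
      }
      data.frame(variant_id = v$variant_id, chromosome = v$chromosome,
                 base_pair_location = v$position,
                 effect_allele = v$alt, other_allele = v$ref,
                 beta = z * se, standard_error = se,
                 p_value = stats::pchisq(z^2, df = 1, lower.tail = FALSE),
                 n = study$n,
                 n_cases = if (is.null(study$n_cases)) NA_integer_ else study$n_cases,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Simulate a credible set around a causal variant
#'
#' PIP-generation helper shared by the molQTL and ingested-GWAS credible-set
#' generators: the causal variant leads with a high PIP, its LD proxies
#' (r-squared at least 0.5) share the remaining mass proportionally to
#' r-squared, and the total mass lands in [0.95, 1]. Draws from the current
#' RNG state (wrap in [with_stream()] for reproducibility).
#'
#' @param genome output of [simulate_ld_genome()].
#' @param causal_variant variant id of the planted causal variant.
#' @param cs_id,study_id identifiers stamped on the set.
#' @param method,lead_p,beta_sign,... passed to [new_credible_set()].
#' @return a credible set led by the causal variant.
#' @export
simulate_signal_cs <- function(genome, causal_variant, cs_id, study_id,
                               method = "ingested", lead_p = 1e-12,
                               beta_sign = "+", ...) {
  v <- genome$variants[genome$variants$variant_id == causal_variant, ]
  assert_that(nrow(v) == 1L, paste("unknown variant id:", causal_variant))
  R <- genome$ld[[v$block]]
  r2 <- R[causal_variant, ]^2
  proxies <- names(r2)[r2 >= 0.5 & names(r2) != causal_variant]
  lead_pip <- stats::runif(1, 0.6, 0.85)
  total <- stats::runif(1, 0.96, 0.995)
  if (length(proxies)) {
    w <- r2[proxies] / sum(r2[proxies])
    pips <- c(lead_pip, (total - lead_pip) * w)
    members <- data.frame(variant = c(causal_variant, proxies), pip = pips,
                          stringsAsFactors = FALSE)
  } else {
    members <- data.frame(variant = causal_variant, pip = total,
                          stringsAsFactors = FALSE)
  }
  pos <- genome$variants$position[match(members$variant, genome$variants$variant_id)]
  new_credible_set(cs_id = cs_id, study_id = study_id,
                   lead_variant = causal_variant, members = members,
                   method = method, lead_p = lead_p, beta_sign = beta_sign,
                   region = list(chrom = v$chromosome, start = min(pos),
                                 end = max(pos)), ...)
}

#' Simulate molQTL credible sets colocalising with planted GWAS signals
#'
#' For every planted (gene, causal variant) pair, emits one or more molecular
#' QTL credible sets (eQTL/pQTL/sQTL) whose highest-PIP variant is the planted
#' causal variant, so each planted colocalising pair shares its top variant.
#' Per-set PIP sums land in [0.95, 1].
#'
#' @param genome output of [simulate_ld_genome()].
#' @param truth output of [make_truth_table()].
#' @param config the [sim_config()] (defaults to the genome's).
#' @return list of credible sets with `gene_id` and `qtl_type` fields.
#' @export
simulate_molqtl_cs <- function(genome, truth, config = genome$config) {
  validate_sim_config(config)
  with_stream(config$seed, "molqtl", {
    pairs <- unique(truth$signals[c("gene_id", "variant_id")])
    n_cs <- config$n_molqtl_studies
    # cycle through planted pairs until the requested number of CSs is reached;
    # repeats give molQTL replication (same lead-gene pair seen >= 2 times)
    idx <- rep(seq_len(nrow(pairs)), length.out = n_cs)
    out <- vector("list", n_cs)
    types <- c("eqtl", "pqtl", "sqtl")
    for (i in seq_len(n_cs)) {
      p <- pairs[idx[i], ]
      qt <- sample(types, 1L, prob = c(0.6, 0.25, 0.15))
      out[[i]] <- simulate_signal_cs(
        genome, p$variant_id,
        cs_id = sprintf("CS_QTL_%03d", i),
        study_id = sprintf("%s_%s_%02d", toupper(qt), p$gene_id, i),
        method = "ingested",
        lead_p = 10^(-stats::runif(1, 6, 20)),
        beta_sign = sample(c("+", "-"), 1L),
        gene_id = p$gene_id, qtl_type = qt,
        trait_id = paste0("MOL_", p$gene_id),
        lead_beta = stats::rnorm(1, 0.5, 0.1) * sample(c(-1, 1), 1))
    }
    out
  })
}

#' Simulate variant annotations and gene covariates
#'
#' Draws a consequence category per variant-gene pair from
#' \{PAV, promoter, enhancer, intragenic, intergenic\} with a configurable
#' per-MAF-bin PAV rate, a pathogenicity score in [0,1] (planted causal
#' variants receive a high score on their true gene, which is what carries
#' the locus-to-gene signal for distal planted genes), and per-population
#' effect-allele frequencies. Also attaches a gene-by-tissue expression
#' matrix with a few strongly tissue-specific genes.
#'
#' @param genome output of [simulate_ld_genome()].
#' @param truth optional truth table; when given, causal variants are
#'   annotated as pathogenic for their causal gene.
#' @param config the [sim_config()] (defaults to the genome's).
#' @return list with `variant_annotation` (variant_id, gene_id, category,
#'   pathogenicity), `frequencies` (per-population EAF), `expression`
#'   (gene x tissue matrix).
#' @export
simulate_annotations <- function(genome, truth = NULL, config = genome$config) {
  validate_sim_config(config)
  with_stream(config$seed, "annotations", {
    variants <- genome$variants
    genes <- genome$genes
    cats <- c("PAV", "promoter", "enhancer", "intragenic", "intergenic")
    bin <- cut(variants$maf, breaks = c(0, 0.01, 0.1, 0.5))
    pav_rate <- config$pav_rate_by_maf[as.character(bin)]
    pav_rate[is.na(pav_rate)] <- 0
    rows <- lapply(seq_len(nrow(variants)), function(i) {
      v <- variants[i, ]
      near <- genes[genes$block == v$block, ]
      if (nrow(near) == 0L) return(NULL)
      g <- near$gene_id[which.min(abs(near$tss - v$position))]
      is_pav <- stats::runif(1) < pav_rate[i]
      cat_i <- if (is_pav) "PAV" else
        sample(cats[-1], 1L, prob = c(0.15, 0.2, 0.3, 0.35))
      patho <- if (cat_i == "PAV") stats::runif(1, 0.5, 1) else stats::runif(1, 0, 0.3)
      data.frame(variant_id = v$variant_id, gene_id = g, category = cat_i,
                 pathogenicity = patho, stringsAsFactors = FALSE)
    })
    ann <- do.call(rbind, rows)
    if (!is.null(truth)) {
      # planted causal variants are deleterious for their causal gene
      for (i in seq_len(nrow(truth$signals))) {
        s <- truth$signals[i, ]
        hit <- ann$variant_id == s$variant_id & ann$gene_id == s$gene_id
        if (any(hit)) {
          ann$pathogenicity[hit] <- pmax(ann$pathogenicity[hit],
                                         stats::runif(1, 0.7, 1))
        } else {
          ann <- rbind(ann, data.frame(
            variant_id = s$variant_id, gene_id = s$gene_id,
            category = "PAV", pathogenicity = stats::runif(1, 0.7, 1),
            stringsAsFactors = FALSE))
        }
      }
    }
    pops <- c("NFE", "AFR", "EAS", "CSA", "FIN")
    flip <- stats::runif(nrow(variants)) < 0.5
    eaf_base <- ifelse(flip, 1 - variants$maf, variants$maf)
    freq <- data.frame(variant_id = variants$variant_id, stringsAsFactors = FALSE)
    for (p in pops) {
      # population drift on the logit scale preserves rare frequencies
      freq[[p]] <- stats::plogis(stats::qlogis(eaf_base) +
                                   stats::rnorm(nrow(variants), 0, 0.1))
    }
    tissues <- paste0("TISSUE_", 1:8)
    ng <- nrow(genes)
    expr <- matrix(stats::rgamma(ng * length(tissues), shape = 2, rate = 0.5),
                   nrow = ng, dimnames = list(genes$gene_id, tissues))
    specific <- sample.int(ng, max(1L, round(0.2 * ng)))
    for (g in specific) {
      t <- sample.int(length(tissues), 1L)
      expr[g, t] <- expr[g, t] + 6 * max(expr[g, -t])
    }
    list(variant_annotation = ann, frequencies = freq, expression = expr)
  })
}

#' Simulate a target-indication clinical pipeline
#'
#' Approval follows the planted logistic model: approval log-odds =
#' base + b_support * support + b_logpleio * log(uniqueDiseases + 1) +
#' b_logpleio_sq * log(uniqueDiseases + 1)^2. Records not approved get a
#' maximum phase of 1-3 from sequential Bernoulli phase transitions with the
#' configured baseline probabilities, so every record has a maximal observed
#' phase starting from Phase I.
#'
#' @param targets data frame with columns `target`, `indication`, `support`
#'   (0/1), `unique_diseases` (>= 1 where supported, 0 allowed for
#'   unsupported), optionally `ta_count`. If `NULL`, a standalone table of
#'   `ti_plan$n_ti` records is generated with the configured support rate.
#' @param ti_plan plan list (see [sim_config()]).
#' @param seed integer seed.
#' @return data frame of TI records with `max_phase` in 1..4 and `approved`.
#' @export
simulate_ti_pipeline <- function(targets = NULL, ti_plan, seed = 1L) {
  probs <- c(ti_plan$p12, ti_plan$p23)
  assert_that(all(probs >= 0 & probs <= 1),
              "phase transition probabilities outside [0,1]")
  with_stream(seed, "ti_pipeline", {
    if (is.null(targets)) {
      n <- ti_plan$n_ti
      support <- as.integer(stats::runif(n) < ti_plan$support_rate)
      ud <- ifelse(support == 1,
                   1L + stats::rpois(n, 1.5),
                   pmax(0L, stats::rpois(n, 0.4)))
      targets <- data.frame(
        target = sprintf("GENE_%04d", sample.int(2000, n, replace = TRUE)),
        indication = sprintf("EFO_I%03d", sample.int(300, n, replace = TRUE)),
        support = support, unique_diseases = ud, stringsAsFactors = FALSE)
    }
    assert_that(all(c("target", "indication", "support", "unique_diseases")
                    %in% names(targets)),
                "targets must carry target, indication, support, unique_diseases")
    n <- nrow(targets)
    L <- log(targets$unique_diseases + 1)
    eta <- ti_plan$base_logodds + ti_plan$b_support * targets$support +
      ti_plan$b_logpleio * L + ti_plan$b_logpleio_sq * L^2
    p_appr <- stats::plogis(eta)
    assert_that(all(p_appr >= 0 & p_appr <= 1),
                "approval probabilities outside [0,1] after link inversion")
    approved <- stats::runif(n) < p_appr
    phase <- integer(n)
    phase[approved] <- 4L
    na <- which(!approved)
    reach2 <- stats::runif(length(na)) < ti_plan$p12
    reach3 <- reach2 & (stats::runif(length(na)) < ti_plan$p23)
    phase[na] <- 1L + as.integer(reach2) + as.integer(reach3)
    out <- targets
    out$max_phase <- phase
    out$approved <- approved
    out
  })
}

#' Simulate a full synthetic cohort
#'
#' Runs the full generator: genome, truth table, study metadata, per-study
#' summary statistics, molQTL credible sets and annotations. This is the
#' entry point the pipeline orchestrator uses.
#'
#' @param config a [sim_config()].
#' @return list with `genome`, `truth`, `studies`, `sumstats` (named list per
#'   study), `molqtl_cs`, `annotations`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  genome <- simulate_ld_genome(config)
  truth <- make_truth_table(genome, config)
  studies <- simulate_studies(config)
  sumstats <- lapply(seq_len(nrow(studies)), function(i) {
    simulate_study_sumstats(genome, studies[i, ], truth)
  })
  names(sumstats) <- studies$study_id
  molqtl <- simulate_molqtl_cs(genome, truth, config)
  ann <- simulate_annotations(genome, truth, config)
  list(genome = genome, truth = truth, studies = studies,
       sumstats = sumstats, molqtl_cs = molqtl, annotations = ann,
       config = config)
}
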