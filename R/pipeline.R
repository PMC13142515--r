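# end-to-end orchestration over the synthetic cohort: simulate -> harmonise
# -> finemap -> coloc -> l2g -> pleiotropy -> translate

#' Fine-map every study of a cohort with PICS
#'
#' Distance-based clumping per study followed by PICS fine-mapping of each
#' locus (using the lead's LD row from the genome block), then the
#' source-class lead p-value threshold.
#'
#' @param cohort output of [simulate_cohort()].
#' @param gws genome-wide significance threshold (default 1e-8).
#' @return list of PICS credible sets tagged with study and trait.
#' @export
finemap_cohort <- function(cohort, gws = 1e-8) {
  out <- list()
  for (i in seq_len(nrow(cohort$studies))) {
    st <- cohort$studies[i, ]
    ss <- cohort$sumstats[[st$study_id]]
    loci <- clump_by_distance(ss, gws = gws)
    for (loc in loci) {
      block <- cohort$genome$variants$block[
        match(loc$top_variant, cohort$genome$variants$variant_id)]
      ld_row <- cohort$genome$ld[[block]][loc$top_variant, ]
      members_in_ld <- loc$members[loc$members$variant_id %in% names(ld_row), ,
                                   drop = FALSE]
      if (nrow(members_in_ld) == 0L) next
      lead_beta <- ss$beta[match(loc$top_variant, ss$variant_id)]
      cs <- pics_finemap(
        list(chrom = loc$chrom, start = loc$start, end = loc$end,
             top_variant = loc$top_variant, members = members_in_ld),
        ld_row, study_id = st$study_id,
        cs_id = sprintf("CS_%s_%s", st$study_id, loc$top_variant),
        beta_sign = if (lead_beta >= 0) "+" else "-",
        trait_id = st$trait_id, lead_beta = lead_beta)
      out[[length(out) + 1L]] <- cs
    }
  }
  apply_lead_p_threshold(out, class = "gwas")
}

#' Harmonise credible sets: MAF, rescaled effects, power, flags
#'
#' Annotates each credible-set lead with the study's major-ancestry MAF,
#' re-estimates the effect size and standard error from the lead p-value,
#' computes detection power, and applies the replication, study- and
#' CS-qualification rules.
#'
#' @param cs_list GWAS credible sets from [finemap_cohort()].
#' @param studies study metadata.
#' @param frequencies per-population EAF table.
#' @param annotation variant annotation (`variant_id`, `gene_id`,
#'   `category`, `pathogenicity`).
#' @param coloc_df optional colocalisation results used for the rare-lead
#'   molQTL-colocalisation rule.
#' @return per-CS data frame with annotation columns and `qualified`.
#' @export
harmonise_credible_sets <- function(cs_list, studies, frequencies,
                                    annotation, coloc_df = NULL) {
  tab <- cs_table(cs_list)
  idx <- match(tab$study_id, studies$study_id)
  tab$n <- studies$n[idx]
  tab$trait_id <- studies$trait_id[idx]
  tab$class <- "gwas"
  ann <- lapply(seq_len(nrow(tab)), function(i) {
    st <- studies[idx[i], ]
    m <- annotate_major_ancestry_maf(st$ancestry[[1]], tab$lead_variant[i],
                                     frequencies)
    if (m$failed) {
      return(list(maf = NA_real_, abs_beta_resc = NA_real_, power = NA_real_))
    }
    quantitative <- isTRUE(st$is_quantitative)
    r <- rescale_effect(p = max(tab$lead_p[i], 1e-300),
                        sign_char = tab$beta_sign[i], n = st$n, f = m$maf,
                        K = if (quantitative) NULL else st$n_cases / st$n,
                        trait_type = if (quantitative) "quantitative" else "binary")
    n_eff <- effective_n(st$n, st$n_cases, quantitative)
    list(maf = m$maf, abs_beta_resc = abs(r$beta_resc),
         power = compute_power(abs(r$beta_resc), n_eff, m$maf))
  })
  tab$maf <- vapply(ann, `[[`, numeric(1), "maf")
  tab$abs_beta_resc <- vapply(ann, `[[`, numeric(1), "abs_beta_resc")
  tab$power <- vapply(ann, `[[`, numeric(1), "power")
  tab$replicated <- flag_replication(tab, studies)
  tab$study_qualified <- qualify_studies(studies)[idx]
  pav_variants <- unique(annotation$variant_id[annotation$category == "PAV"])
  tab$has_pav <- vapply(cs_list, function(cs) {
    any(cs$members$variant %in% pav_variants)
  }, logical(1))
  tab$has_molqtl_coloc <- FALSE
  if (!is.null(coloc_df) && nrow(coloc_df)) {
    sig <- coloc_df[coloc_df$significant & coloc_df$pair_class == "gwas-molqtl", ]
    tab$has_molqtl_coloc <- tab$cs_id %in% c(sig$left, sig$right)
  }
  tab$abs_beta_resc_f <- ifelse(is.na(tab$abs_beta_resc), Inf, tab$abs_beta_resc)
  tab$qualified <- qualify_credible_sets(
    data.frame(study_qualified = tab$study_qualified, n = tab$n,
               maf = tab$maf, abs_beta_resc = tab$abs_beta_resc_f,
               has_molqtl_coloc = tab$has_molqtl_coloc,
               has_pav = tab$has_pav, replicated = tab$replicated))
  tab$abs_beta_resc_f <- NULL
  tab
}

#' Validate pipeline input files
#'
#' Per-file format checks with line-numbered diagnostics: summary-statistic
#' TSVs must carry the GWAS-SSF columns and have monotone positions per
#' chromosome; credible-set JSON Lines must have PIPs in [0,1].
#'
#' @param paths named list with any of `sumstats` (TSV paths) and `cs`
#'   (JSON Lines paths).
#' @return data frame report (`file`, `line`, `level`, `message`); zero rows
#'   when everything is well-formed.
#' @export
validate_inputs <- function(paths) {
  report <- list()
  note <- function(file, line, level, msg) {
    report[[length(report) + 1L]] <<- data.frame(
      file = file, line = line, level = level, message = msg,
      stringsAsFactors = FALSE)
  }
  for (f in paths$sumstats %||% character(0)) {
    ss <- tryCatch(read_sumstats(f), error = function(e) NULL)
    if (is.null(ss)) { note(f, NA, "error", "unreadable sumstats TSV"); next }
    need <- c("variant_id", "chromosome", "base_pair_location", "beta",
              "standard_error", "p_value", "n")
    miss <- setdiff(need, names(ss))
    if (length(miss)) {
      note(f, 1L, "error", paste("missing columns:", paste(miss, collapse = ", ")))
      next
    }
    bad_p <- which(ss$p_value < 0 | ss$p_value > 1)
    for (i in bad_p) note(f, i + 1L, "error", "p_value outside [0,1]")
    for (chrom in unique(ss$chromosome)) {
      pos <- ss$base_pair_location[ss$chromosome == chrom]
      if (is.unsorted(pos)) {
        note(f, NA, "warning",
             sprintf("positions unsorted on chromosome %s", chrom))
      }
    }
  }
  for (f in paths$cs %||% character(0)) {
    lines <- tryCatch(readLines(f), error = function(e) NULL)
    if (is.null(lines)) { note(f, NA, "error", "unreadable JSON Lines"); next }
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
      if (is.null(rec)) { note(f, i, "error", "invalid JSON"); next }
      pips <- rec$members$pip
      if (any(pips < 0 | pips > 1)) {
        note(f, i, "error", "PIP outside [0,1]")
      }
    }
  }
  out <- do.call(rbind, report)
  if (is.null(out)) {
    out <- data.frame(file = character(0), line = integer(0),
                      level = character(0), message = character(0))
  }
  out
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes simulate, harmonise, finemap, coloc, l2g, pleiotropy and
#' translate in order, writing each stage's outputs as plain text under
#' `out_dir` and returning every stage object plus a run manifest (config
#' hash, per-stage output paths and digests, seeds, timestamps). Identical
#' configs reproduce identical outputs and digests.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing); `NULL` skips file
#'   output.
#' @return list of stage results and `manifest`.
#' @export
run_all <- function(config = sim_config(), out_dir = NULL) {
  t0 <- Sys.time()
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  paths <- character(0)
  emit <- function(name, writer) {
    if (is.null(out_dir)) return(invisible(NULL))
    p <- file.path(out_dir, name)
    writer(p)
    paths[[name]] <<- p
  }

  # stage 1: simulate
  cohort <- simulate_cohort(config)
  emit("config.yaml", function(p) {
    yaml::write_yaml(unclass(config)[setdiff(names(config), "pleiotropy_plan")], p)
  })
  emit("studies.tsv", function(p) {
    st <- cohort$studies
    st$ancestry <- vapply(st$ancestry, function(a) {
      paste(sprintf("%s=%g", names(unlist(a)), unlist(a)), collapse = ";")
    }, "")
    utils::write.table(st, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  if (!is.null(out_dir)) {
    ssdir <- file.path(out_dir, "sumstats")
    dir.create(ssdir, showWarnings = FALSE)
    for (sid in names(cohort$sumstats)) {
      emit(file.path("sumstats", paste0(sid, ".tsv")), function(p) {
        write_sumstats(cohort$sumstats[[sid]], p)
      })
    }
  }

  # stage 2: finemap (PICS credible sets per study)
  gwas_cs <- finemap_cohort(cohort)
  emit("credible_sets.jsonl", function(p) write_credible_sets(gwas_cs, p))

  # stage 3: coloc over GWAS + molQTL credible sets
  all_cs <- c(gwas_cs, cohort$molqtl_cs)
  stats_by_cs <- lapply(gwas_cs, function(cs) {
    ss <- cohort$sumstats[[cs$study_id]]
    rows <- ss[ss$variant_id %in% cs$members$variant, ]
    data.frame(variant = rows$variant_id, beta = rows$beta,
               se = rows$standard_error, stringsAsFactors = FALSE)
  })
  names(stats_by_cs) <- vapply(gwas_cs, function(cs) cs$cs_id, "")
  coloc_df <- colocalise_all(all_cs, stats_by_cs)
  emit("coloc.tsv", function(p) {
    utils::write.table(coloc_df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # stage 4: harmonise + qualification
  cs_ann <- harmonise_credible_sets(gwas_cs, cohort$studies,
                                    cohort$annotations$frequencies,
                                    cohort$annotations$variant_annotation,
                                    coloc_df)
  ta_edges <- data.frame(child = cohort$truth$disease_ta$trait_id,
                         parent = cohort$truth$disease_ta$ta,
                         stringsAsFactors = FALSE)
  cs_ann$ta <- vapply(cs_ann$trait_id, function(tr) {
    assign_therapeutic_area(tr, ta_edges)
  }, "")
  emit("credible_sets_annotated.tsv", function(p) {
    utils::write.table(cs_ann, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # stage 5: l2g
  fm <- build_feature_matrix(gwas_cs, cohort$genome$genes,
                             cohort$genome$variants, cohort$molqtl_cs,
                             coloc_df, cohort$annotations$variant_annotation)
  gold <- unique(data.frame(
    gene_id = cohort$truth$signals$gene_id,
    trait_id = cohort$truth$signals$trait_id, stringsAsFactors = FALSE))
  cs_trait <- unique(cs_ann[c("cs_id", "trait_id")])
  split <- assemble_training_set(fm, gold, cs_trait, seed = config$seed)
  l2g <- train_and_score(split, seed = config$seed)
  scores <- score_feature_matrix(l2g$model, fm)
  selected <- select_effector_genes(scores)
  emit("l2g_scores.tsv", function(p) {
    utils::write.table(scores, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # stage 6: pleiotropy (qualified disease credible sets only)
  dis <- cs_ann[cs_ann$qualified & grepl("^EFO_D", cs_ann$trait_id), ,
                drop = FALSE]
  pleio <- NULL
  gps <- NULL
  if (nrow(dis) > 0L) {
    sig_pairs <- coloc_df[coloc_df$significant & coloc_df$pair_class == "gwas-gwas",
                          c("left", "right"), drop = FALSE]
    pleio <- cluster_credible_sets(
      data.frame(cs_id = dis$cs_id, lead_variant = dis$lead_variant,
                 lead_p = dis$lead_p,
                 abs_beta = ifelse(is.na(dis$abs_beta_resc), 0, dis$abs_beta_resc),
                 trait_id = dis$trait_id, ta = dis$ta,
                 stringsAsFactors = FALSE),
      sig_pairs)
    pri <- merge(selected, unique(dis[c("cs_id", "trait_id", "ta")]), by = "cs_id")
    if (nrow(pri) > 0L) gps <- compute_gps(pri)
    emit("clusters.tsv", function(p) {
      utils::write.table(pleio, p, sep = "\t", quote = FALSE, row.names = FALSE)
    })
    if (!is.null(gps)) {
      emit("gene_scores.tsv", function(p) {
        utils::write.table(gps, p, sep = "\t", quote = FALSE, row.names = FALSE)
      })
    }
  }

  # stage 7: translate
  translation <- NULL
  if (!is.null(gps) && nrow(gps) > 0L) {
    evidence <- merge(
      unique(merge(selected, dis[c("cs_id", "trait_id")], by = "cs_id")
             [c("gene_id", "trait_id")]),
      gps, by = "gene_id")
    n_ti <- config$ti_plan$n_ti
    targets <- with_stream(config$seed, "ti_targets", {
      all_genes <- cohort$genome$genes$gene_id
      all_traits <- unique(cohort$truth$disease_ta$trait_id)
      data.frame(target = sample(all_genes, n_ti, replace = TRUE),
                 indication = sample(all_traits, n_ti, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    key <- paste(targets$target, targets$indication)
    ekey <- paste(evidence$gene_id, evidence$trait_id)
    targets$support <- as.integer(key %in% ekey)
    targets$unique_diseases <- ifelse(
      targets$support == 1L, gps$gps[match(targets$target, gps$gene_id)], 0)
    ti <- simulate_ti_pipeline(targets, config$ti_plan, seed = config$seed)
    ti_rec <- attach_genetic_support(
      ti, data.frame(gene_id = evidence$gene_id, trait_id = evidence$trait_id,
                     pav = TRUE, maf = 0.1, abs_beta = 0.1,
                     gps = evidence$gps, ta_count = evidence$ta_count),
      ta_edges)
    enr <- fisher_enrichment(ti_rec$support, ti_rec$approved)
    translation <- list(ti = ti_rec, enrichment = enr)
    emit("enrichment.tsv", function(p) {
      utils::write.table(
        data.frame(a = enr$a, b = enr$b, c = enr$c, d = enr$d,
                   or = enr$or, rs = enr$rs, p = enr$p),
        p, sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  digests <- if (length(paths)) {
    d <- tools::md5sum(unlist(paths))
    names(d) <- names(paths)
    d
  } else character(0)
  manifest <- list(
    config_seed = config$seed,
    config_digest = {
      tmp <- tempfile()
      writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                  force = TRUE), tmp)
      unname(tools::md5sum(tmp))
    },
    stages = c("simulate", "finemap", "coloc", "harmonise", "l2g",
               "pleiotropy", "translate"),
    outputs = as.list(paths),
    digests = as.list(digests),
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    version = as.character(utils::packageVersion("pleiomap")))
  if (!is.null(out_dir)) {
    writeLines(jsonlite::toJSON(manifest[setdiff(names(manifest),
                                                 c("started", "finished"))],
                                auto_unbox = TRUE, pretty = TRUE),
               file.path(out_dir, "manifest.json"))
  }
  list(cohort = cohort, credible_sets = gwas_cs, coloc = coloc_df,
       cs_annotated = cs_ann, feature_matrix = fm, l2g = l2g,
       scores = scores, selected = selected, clusters = pleio, gps = gps,
       translation = translation, manifest = manifest)
}
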