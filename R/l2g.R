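# locus-to-gene: 28-feature credible-set x gene matrix, training-set
# assembly from gold standards, gradient-boosted classifier, effector-gene
# selection

l2g_individual_features <- c(
  "distanceSentinelTss", "distanceMeanTss",
  "distanceSentinelFootprint", "distanceMeanFootprint",
  "eqtlColocClppMaximum", "eqtlColocH4Maximum",
  "pqtlColocClppMaximum", "pqtlColocH4Maximum",
  "sqtlColocClppMaximum", "sqtlColocH4Maximum",
  "vepMean", "vepMaximum")

#' Feature roster of the locus-to-gene model
#'
#' Twelve individual features (distance to TSS and to gene footprint, each
#' sentinel and PIP-mean; maximal CLPP and H4 per molQTL type; PIP-weighted
#' mean and maximal pathogenicity), their twelve neighbourhood counterparts
#' (individual value divided by the maximum over genes of the same credible
#' set), and four locus-level features: candidate gene counts (all and
#' protein-coding, unscaled), a credible-set confidence tier, and a
#' nearest-protein-coding-gene indicator.
#'
#' @return character vector of the 28 feature names.
#' @export
l2g_feature_names <- function() {
  c(l2g_individual_features,
    paste0(l2g_individual_features, "Neighbourhood"),
    "geneCountAll", "geneCountProteinCoding",
    "credibleSetConfidence", "isProteinCodingNearest")
}

distance_score <- function(d, max_d = 5e5) 1 - pmin(d, max_d) / max_d

dist_to_interval <- function(pos, start, end) {
  ifelse(pos < start, start - pos, ifelse(pos > end, pos - end, 0))
}

cs_confidence <- function(method) {
  c(susie = 1, pics = 0.75, ingested = 0.5)[method]
}

#' Build the credible-set by gene feature matrix
#'
#' For each credible set, candidate genes are those within `window` of the
#' set's region. Individual features follow feature-specific rules (distance
#' scores 1 - min(d, 500kb)/500kb; maximal colocalisation scores against
#' molQTL sets of the gene; PIP-weighted and maximal pathogenicity);
#' neighbourhood features divide each by the per-set maximum (zero maximum
#' gives zero). Absent evidence is encoded 0. Credible sets with no
#' candidate gene produce no rows.
#'
#' @param gwas_cs list of GWAS credible sets.
#' @param genes gene annotation data frame (`gene_id`, `chromosome`, `tss`,
#'   `footprint_start`, `footprint_end`, `protein_coding`).
#' @param variants variant table (`variant_id`, `position`).
#' @param molqtl_cs optional list of molQTL credible sets (with `gene_id`,
#'   `qtl_type`).
#' @param coloc_df optional colocalisation results from [colocalise_all()]
#'   run on `c(gwas_cs, molqtl_cs)`.
#' @param annotation optional variant annotation (`variant_id`, `gene_id`,
#'   `pathogenicity`).
#' @param window candidate-gene window in bp (default 500,000).
#' @return data frame with `cs_id`, `gene_id` and the 28 features.
#' @export
build_feature_matrix <- function(gwas_cs, genes, variants,
                                 molqtl_cs = NULL, coloc_df = NULL,
                                 annotation = NULL, window = 5e5) {
  vpos <- stats::setNames(variants$position, variants$variant_id)
  qtl_meta <- if (length(molqtl_cs)) {
    data.frame(cs_id = vapply(molqtl_cs, function(x) x$cs_id, ""),
               gene_id = vapply(molqtl_cs, function(x) x$gene_id %||% NA_character_, ""),
               qtl_type = vapply(molqtl_cs, function(x) x$qtl_type %||% NA_character_, ""),
               stringsAsFactors = FALSE)
  } else NULL
  rows <- lapply(gwas_cs, function(cs) {
    cand <- genes[genes$chromosome == cs$region$chrom &
                    genes$tss >= cs$region$start - window &
                    genes$tss <= cs$region$end + window, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    lead_pos <- vpos[[cs$lead_variant]]
    mem_pos <- vpos[cs$members$variant]
    pip <- cs$members$pip
    nearest_pc <- {
      pc <- cand[cand$protein_coding, , drop = FALSE]
      if (nrow(pc)) pc$gene_id[which.min(abs(pc$tss - lead_pos))] else NA_character_
    }
    # molQTL colocalisations of this credible set, keyed by gene and type
    qtl_scores <- NULL
    if (!is.null(coloc_df) && !is.null(qtl_meta) && nrow(coloc_df) > 0L) {
      hit <- coloc_df[(coloc_df$left == cs$cs_id & coloc_df$right %in% qtl_meta$cs_id) |
                        (coloc_df$right == cs$cs_id & coloc_df$left %in% qtl_meta$cs_id),
                      , drop = FALSE]
      if (nrow(hit)) {
        other <- ifelse(hit$left == cs$cs_id, hit$right, hit$left)
        qtl_scores <- data.frame(
          gene_id = qtl_meta$gene_id[match(other, qtl_meta$cs_id)],
          qtl_type = qtl_meta$qtl_type[match(other, qtl_meta$cs_id)],
          clpp = hit$clpp, h4 = ifelse(is.na(hit$h4), 0, hit$h4),
          stringsAsFactors = FALSE)
      }
    }
    feat <- lapply(seq_len(nrow(cand)), function(gi) {
      g <- cand[gi, ]
      d_tss <- abs(mem_pos - g$tss)
      d_fp <- dist_to_interval(mem_pos, g$footprint_start, g$footprint_end)
      vep <- 0
      if (!is.null(annotation)) {
        arows <- annotation[annotation$gene_id == g$gene_id &
                              annotation$variant_id %in% cs$members$variant,
                            , drop = FALSE]
        vep <- stats::setNames(rep(0, nrow(cs$members)), cs$members$variant)
        vep[arows$variant_id] <- arows$pathogenicity
      }
      qtl_max <- function(type, col) {
        if (is.null(qtl_scores)) return(0)
        sel <- qtl_scores[qtl_scores$gene_id == g$gene_id &
                            qtl_scores$qtl_type == type, col]
        if (length(sel) == 0L) 0 else max(sel)
      }
      c(distanceSentinelTss = distance_score(abs(lead_pos - g$tss)),
        distanceMeanTss = sum(pip * distance_score(d_tss)),
        distanceSentinelFootprint = distance_score(
          dist_to_interval(lead_pos, g$footprint_start, g$footprint_end)),
        distanceMeanFootprint = sum(pip * distance_score(d_fp)),
        eqtlColocClppMaximum = qtl_max("eqtl", "clpp"),
        eqtlColocH4Maximum = qtl_max("eqtl", "h4"),
        pqtlColocClppMaximum = qtl_max("pqtl", "clpp"),
        pqtlColocH4Maximum = qtl_max("pqtl", "h4"),
        sqtlColocClppMaximum = qtl_max("sqtl", "clpp"),
        sqtlColocH4Maximum = qtl_max("sqtl", "h4"),
        vepMean = if (length(vep) > 1 || is.numeric(vep)) sum(pip * vep) else 0,
        vepMaximum = max(vep))
    })
    fm <- do.call(rbind, feat)
    nb <- apply(fm, 2, function(col) {
      m <- max(col)
      if (m == 0) rep(0, length(col)) else col / m
    })
    colnames(nb) <- paste0(colnames(fm), "Neighbourhood")
    out <- data.frame(cs_id = cs$cs_id, gene_id = cand$gene_id,
                      fm, nb,
                      geneCountAll = nrow(cand),
                      geneCountProteinCoding = sum(cand$protein_coding),
                      credibleSetConfidence = unname(cs_confidence(cs$method)),
                      isProteinCodingNearest =
                        as.numeric(cand$gene_id == nearest_pc & !is.na(nearest_pc)),
                      protein_coding = cand$protein_coding,
                      stringsAsFactors = FALSE)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the labelled training split from gold standards
#'
#' Positives are feature-matrix rows whose (gene, trait) pair appears in the
#' de-duplicated gold-standard list; for each positive pair, all other
#' protein-coding genes on the same credible set become negatives. The split
#' into training and held-out test is by unique positive genes (80%/20% by
#' default), so no positive gene spans both partitions and every row of a
#' credible set follows its positive gene's partition.
#'
#' @param feature_matrix output of [build_feature_matrix()].
#' @param gold data frame of gold-standard pairs (`gene_id`, `trait_id`).
#' @param cs_trait data frame mapping `cs_id` to `trait_id`.
#' @param test_fraction held-out fraction of positive genes (default 0.2).
#' @param seed integer seed for the gene split.
#' @return list with `train` and `test` data frames carrying a `label`
#'   column (1 positive, 0 negative).
#' @export
assemble_training_set <- function(feature_matrix, gold, cs_trait,
                                  test_fraction = 0.2, seed = 1L) {
  gold <- unique(gold[c("gene_id", "trait_id")])
  fm <- merge(feature_matrix, cs_trait, by = "cs_id", sort = FALSE)
  key <- paste(fm$gene_id, fm$trait_id)
  gkey <- paste(gold$gene_id, gold$trait_id)
  fm$label <- ifelse(key %in% gkey, 1L, NA_integer_)
  pos_cs <- unique(fm$cs_id[fm$label %in% 1L])
  neg <- fm$cs_id %in% pos_cs & is.na(fm$label) & fm$protein_coding
  fm$label[neg] <- 0L
  lab <- fm[!is.na(fm$label), , drop = FALSE]
  pos_genes <- unique(lab$gene_id[lab$label == 1L])
  with_stream(seed, "l2g_split", {
    n_test <- max(1L, round(test_fraction * length(pos_genes)))
    test_genes <- sample(pos_genes, n_test)
  })
  cs_part <- vapply(split(lab$gene_id[lab$label == 1L], lab$cs_id[lab$label == 1L]),
                    function(g) any(g %in% test_genes), logical(1))
  test_cs <- names(cs_part)[cs_part]
  list(train = lab[!(lab$cs_id %in% test_cs), , drop = FALSE],
       test = lab[lab$cs_id %in% test_cs, , drop = FALSE])
}

#' Average precision of a score vector
#'
#' @param score numeric scores.
#' @param label 0/1 labels.
#' @return average precision (area under the precision-recall step curve).
#' @export
average_precision <- function(score, label) {
  ord <- order(-score)
  lab <- label[ord]
  if (sum(lab) == 0L) return(NA_real_)
  cum_tp <- cumsum(lab)
  prec <- cum_tp / seq_along(lab)
  sum(prec[lab == 1L]) / sum(lab)
}

rank_auc <- function(score, label) {
  n1 <- sum(label == 1L); n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train the locus-to-gene classifier and score pairs
#'
#' Fits a gradient-boosted binary classifier on the training partition,
#' choosing depth, learning rate and tree count by cross-validated average
#' precision on a small grid, then scores the held-out test partition and
#' reports metrics there.
#'
#' @param split output of [assemble_training_set()].
#' @param grid data frame of hyperparameters (`max_depth`, `eta`, `nrounds`);
#'   a small default grid is used when `NULL`.
#' @param nfold cross-validation folds (default 3).
#' @param seed integer seed.
#' @return list with `model`, `chosen` hyperparameters, `scores` (test rows
#'   with `score`), `metrics` (average precision, AUC, recall and FDR at
#'   score 0.5).
#' @export
train_and_score <- function(split, grid = NULL, nfold = 3L, seed = 1L) {
  feats <- l2g_feature_names()
  xtr <- as.matrix(split$train[feats])
  ytr <- split$train$label
  xte <- as.matrix(split$test[feats])
  yte <- split$test$label
  if (is.null(grid)) {
    grid <- expand.grid(max_depth = c(2L, 3L), eta = c(0.1, 0.3),
                        nrounds = c(50L, 100L))
  }
  fit_xgb <- function(x, y, max_depth, eta, nrounds) {
    xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = max_depth,
                    eta = eta, nthread = 1L),
      data = xgboost::xgb.DMatrix(x, label = y),
      nrounds = nrounds, verbose = 0)
  }
  with_stream(seed, "l2g_train", {
    cv_ap <- vapply(seq_len(nrow(grid)), function(i) {
      set.seed(child_seed(seed, paste0("l2g_cv", i)))
      folds <- sample(rep_len(seq_len(nfold), nrow(xtr)))
      aps <- vapply(seq_len(nfold), function(f) {
        tr <- folds != f
        m <- fit_xgb(xtr[tr, , drop = FALSE], ytr[tr],
                     grid$max_depth[i], grid$eta[i], grid$nrounds[i])
        pr <- stats::predict(m, xgboost::xgb.DMatrix(xtr[!tr, , drop = FALSE]))
        average_precision(pr, ytr[!tr])
      }, numeric(1))
      mean(aps, na.rm = TRUE)
    }, numeric(1))
    best <- which.max(cv_ap)
    set.seed(child_seed(seed, "l2g_final"))
    model <- fit_xgb(xtr, ytr, grid$max_depth[best], grid$eta[best],
                     grid$nrounds[best])
    score <- stats::predict(model, xgboost::xgb.DMatrix(xte))
    sel <- score >= 0.5
    metrics <- list(
      average_precision = average_precision(score, yte),
      auc = rank_auc(score, yte),
      recall_at_0.5 = if (sum(yte) > 0) sum(sel & yte == 1L) / sum(yte) else NA_real_,
      fdr_at_0.5 = if (sum(sel) > 0) sum(sel & yte == 0L) / sum(sel) else NA_real_)
    out <- split$test[c("cs_id", "gene_id")]
    out$score <- score
    list(model = model, chosen = grid[best, ], scores = out, metrics = metrics)
  })
}

#' Score arbitrary feature-matrix rows with a trained model
#'
#' @param model trained xgboost model from [train_and_score()].
#' @param feature_matrix feature-matrix rows to score.
#' @return the rows with a `score` column appended.
#' @export
score_feature_matrix <- function(model, feature_matrix) {
  out <- feature_matrix[c("cs_id", "gene_id")]
  out$score <- stats::predict(
    model, xgboost::xgb.DMatrix(as.matrix(feature_matrix[l2g_feature_names()])))
  out
}

#' Select effector genes per credible set
#'
#' Per credible set: every gene scoring at least 0.5 is selected; when none
#' does, the single top gene is selected if it scores at least 0.1;
#' otherwise the set gets no assignment.
#'
#' @param scores data frame with `cs_id`, `gene_id`, `score`.
#' @param threshold main selection threshold (default 0.5).
#' @param floor fallback top-gene floor (default 0.1).
#' @return the selected rows.
#' @export
select_effector_genes <- function(scores, threshold = 0.5, floor = 0.1) {
  out <- lapply(split(scores, scores$cs_id), function(df) {
    hi <- df[df$score >= threshold, , drop = FALSE]
    if (nrow(hi) > 0L) return(hi)
    top <- df[which.max(df$score), , drop = FALSE]
    if (top$score >= floor) top else df[0, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
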