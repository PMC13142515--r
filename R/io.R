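#' Write GWAS summary statistics in GWAS-SSF-style TSV
#'
#' Columns: `variant_id`, `chromosome`, `base_pair_location`,
#' `effect_allele`, `other_allele`, `beta`, `standard_error`, `p_value`,
#' `n`, `n_cases`.
#'
#' @param sumstats data frame of summary statistics.
#' @param path output file path.
#' @export
write_sumstats <- function(sumstats, path) {
  cols <- c("variant_id", "chromosome", "base_pair_location",
            "effect_allele", "other_allele", "beta", "standard_error",
            "p_value", "n", "n_cases")
  missing <- setdiff(cols, names(sumstats))
  assert_that(length(missing) == 0L,
              paste("sumstats missing columns:", paste(missing, collapse = ", ")))
  utils::write.table(sumstats[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read GWAS summary statistics from a GWAS-SSF-style TSV
#'
#' @param path input file path.
#' @return data frame of summary statistics.
#' @export
read_sumstats <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c(chromosome = "character"),
                           stringsAsFactors = FALSE)
  if ("n_cases" %in% names(out)) out$n_cases <- as.integer(out$n_cases)
  out
}

#' Write credible sets as JSON Lines
#'
#' One JSON object per line with fields `cs_id`, `study_id`, `lead_variant`,
#' `method`, `lead_p`, `beta_sign`, `region` and a `members` array of
#' `{variant, pip}` pairs.
#'
#' @param cs_list list of credible-set objects (see [new_credible_set()]).
#' @param path output file path.
#' @export
write_credible_sets <- function(cs_list, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cs in cs_list) {
    rec <- list(
      cs_id = cs$cs_id, study_id = cs$study_id,
      lead_variant = cs$lead_variant, method = cs$method,
      lead_p = cs$lead_p, beta_sign = cs$beta_sign,
      region = cs$region,
      members = data.frame(variant = cs$members$variant,
                           pip = cs$members$pip)
    )
    extras <- intersect(c("trait_id", "gene_id", "qtl_type", "lead_beta"),
                        names(cs))
    rec[extras] <- cs[extras]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read credible sets from JSON Lines
#'
#' @param path input file path.
#' @return list of credible-set objects.
#' @export
read_credible_sets <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln)
    rec$members <- as.data.frame(rec$members)
    do.call(new_credible_set, rec)
  })
}

#' Write an LD matrix as a TSV keyed by variant id
#'
#' @param ld square numeric matrix of signed r with variant-id dimnames.
#' @param path output file path.
#' @export
write_ld_matrix <- function(ld, path) {
  assert_that(!is.null(rownames(ld)), "LD matrix must have variant-id dimnames")
  df <- data.frame(variant_id = rownames(ld), ld, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an LD matrix from TSV
#'
#' @param path input file path.
#' @return square numeric matrix with variant-id dimnames.
#' @export
read_ld_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$variant_id
  storage.mode(m) <- "double"
  m
}
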