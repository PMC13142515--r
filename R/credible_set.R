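#' Construct a credible set
#'
#' A credible set is one association signal: a study-linked set of variants
#' with posterior inclusion probabilities (PIPs), a lead variant, and quality
#' flags. For 95% sets the PIPs sum to at least 0.95 and at most 1; the lead
#' variant is the member with maximal PIP.
#'
#' @param cs_id credible-set identifier.
#' @param study_id study identifier.
#' @param lead_variant lead variant id (`chr_pos_ref_alt`).
#' @param members data frame with columns `variant` and `pip`.
#' @param method one of `"susie"`, `"pics"`, `"ingested"`.
#' @param lead_p lead variant p-value.
#' @param beta_sign `"+"`, `"-"` or `"unknown"`.
#' @param region list with `chrom`, `start`, `end` (1-based inclusive).
#' @param flags named logical list, e.g. `qualified`, `replicated`.
#' @param ... further fields attached verbatim (`trait_id`, `gene_id`,
#'   `qtl_type`, `lead_beta`, ...).
#' @return object of class `credible_set`.
#' @export
new_credible_set <- function(cs_id, study_id, lead_variant, members,
                             method = c("susie", "pics", "ingested"),
                             lead_p = NA_real_, beta_sign = "unknown",
                             region = NULL, flags = list(), ...) {
  method <- match.arg(method)
  assert_that(is.data.frame(members) && all(c("variant", "pip") %in% names(members)),
              "members must be a data frame with columns variant, pip")
  assert_that(all(members$pip >= 0 & members$pip <= 1 + 1e-9),
              sprintf("PIPs out of [0,1] in credible set %s", cs_id))
  s <- sum(members$pip)
  assert_that(s >= 0.95 - 1e-9 && s <= 1 + 1e-9,
              sprintf("PIP sum %.4f outside [0.95, 1] in credible set %s", s, cs_id))
  assert_that(lead_variant %in% members$variant,
              sprintf("lead variant %s not among members of %s", lead_variant, cs_id))
  lead_pip <- members$pip[members$variant == lead_variant][1]
  assert_that(lead_pip >= max(members$pip) - 1e-9,
              sprintf("lead variant of %s does not have maximal PIP", cs_id))
  assert_that(beta_sign %in% c("+", "-", "unknown"), "invalid beta_sign")
  structure(
    c(list(cs_id = cs_id, study_id = study_id, lead_variant = lead_variant,
           members = members[order(-members$pip, members$variant), , drop = FALSE],
           method = method, lead_p = lead_p, beta_sign = beta_sign,
           region = region, flags = flags),
      list(...)),
    class = "credible_set"
  )
}

#' @export
print.credible_set <- function(x, ...) {
  cat(sprintf("<credible_set %s> study %s, lead %s (PIP %.3f), %d variants, method %s\n",
              x$cs_id, x$study_id, x$lead_variant,
              max(x$members$pip), nrow(x$members), x$method))
  invisible(x)
}

# lead PIP helper used throughout
lead_pip <- function(cs) cs$members$pip[cs$members$variant == cs$lead_variant][1]

# flatten a list of credible sets into a per-CS data frame of scalar fields
cs_table <- function(cs_list) {
  do.call(rbind, lapply(cs_list, function(cs) {
    data.frame(cs_id = cs$cs_id, study_id = cs$study_id,
               lead_variant = cs$lead_variant, method = cs$method,
               lead_p = cs$lead_p, beta_sign = cs$beta_sign,
               lead_pip = lead_pip(cs),
               n_members = nrow(cs$members),
               trait_id = cs$trait_id %||% NA_character_,
               gene_id = cs$gene_id %||% NA_character_,
               qtl_type = cs$qtl_type %||% NA_character_,
               lead_beta = cs$lead_beta %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
}
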