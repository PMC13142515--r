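# shared fixtures built in code

# a minimal credible set from parallel vectors
toy_cs <- function(id, variants, pips, study = "S1", lead = variants[which.max(pips)],
                   lead_p = 1e-10, sign = "+",
                   region = list(chrom = "1", start = 1L, end = 2e6), ...) {
  new_credible_set(cs_id = id, study_id = study, lead_variant = lead,
                   members = data.frame(variant = variants, pip = pips,
                                        stringsAsFactors = FALSE),
                   method = "ingested", lead_p = lead_p, beta_sign = sign,
                   region = region, ...)
}

# summary statistics on one chromosome from parallel vectors
toy_sumstats <- function(pos, p, beta = rep(0.1, length(pos)), chrom = "1") {
  data.frame(variant_id = sprintf("%s_%d_A_G", chrom, pos),
             chromosome = chrom, base_pair_location = pos,
             effect_allele = "G", other_allele = "A",
             beta = beta, standard_error = 0.01, p_value = p,
             n = 1e5, n_cases = NA_integer_, stringsAsFactors = FALSE)
}

# small cohort configuration used by pipeline-level tests
small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_ld_blocks = 8L, variants_per_block = 40L,
             n_disease_studies = 8L, n_measurement_studies = 3L,
             n_molqtl_studies = 8L,
             ti_plan = list(n_ti = 1500L, p12 = 0.7, p23 = 0.55,
                            base_logodds = stats::qlogis(0.10),
                            b_support = log(3.6), b_logpleio = 0,
                            b_logpleio_sq = 0, support_rate = 0.2), ...)
}

# toy ontology: oncology and organ-system areas above a few traits
toy_ontology <- function() {
  data.frame(
    child = c("ovarian_cancer", "ovarian_cancer",
              "asthma", "childhood_asthma",
              "cancer or benign tumour", "reproductive system or breast disease",
              "respiratory or thoracic disease"),
    parent = c("cancer or benign tumour", "reproductive system or breast disease",
               "respiratory or thoracic disease", "asthma",
               "disease", "disease", "disease"),
    stringsAsFactors = FALSE)
}
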