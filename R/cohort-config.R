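#' Default planted protein-IR effects
#'
#' Builds the deterministic set of planted per-protein effects used by the
#' default synthetic cohort: a block of muscle-axis proteins, a block of
#' liver-axis proteins, and a block associated with both axes. Effect sizes
#' are log2-abundance differences per full \[0,1\] IR range, spaced evenly
#' over `beta_range` with alternating sign, mirroring the mixed up/down
#' regulation seen in plasma proteomics of insulin resistance.
#'
#' @param n_muscle,n_liver,n_both Number of planted proteins per axis class.
#' @param beta_range Magnitude range (log2 units per full IR range) over which
#'   planted effect sizes are spread.
#' @param offset Index of the first planted aptamer (planted aptamers occupy
#'   consecutive indices starting there).
#' @return A data frame with columns `aptamer` (integer index), `axis`
#'   (`"muscle"`, `"liver"` or `"both"`) and `beta`.
#' @export
default_planted_effects <- function(n_muscle = 50, n_liver = 30, n_both = 10,
                                    beta_range = c(0.5, 1.0), offset = 1L) {
  n <- n_muscle + n_liver + n_both
  if (n == 0L) {
    return(data.frame(aptamer = integer(0), axis = character(0),
                      beta = numeric(0), stringsAsFactors = FALSE))
  }
  mag <- seq(beta_range[1], beta_range[2], length.out = n)
  data.frame(
    aptamer = seq.int(offset, length.out = n),
    axis = rep(c("muscle", "liver", "both"), c(n_muscle, n_liver, n_both)),
    beta = mag * rep_len(c(1, -1), n),
    stringsAsFactors = FALSE
  )
}

#' Default synthetic gene-set collection layout
#'
#' Three planted-enriched sets (overpopulated with genes of planted-effect
#' aptamers) plus null sets whose members are drawn uniformly from the gene
#' universe, with sizes cycling over a realistic pathway-size range.
#'
#' @param n_null Number of null (non-enriched) sets.
#' @param null_sizes Sizes recycled across the null sets.
#' @param enriched_sizes Sizes of the planted-enriched sets.
#' @return Data frame with columns `name`, `size`, `enriched`.
#' @export
default_gene_sets <- function(n_null = 47, null_sizes = seq(20, 80, by = 10),
                              enriched_sizes = c(40, 50, 60)) {
  n_enr <- length(enriched_sizes)
  data.frame(
    name = c(sprintf("PLANTED_SET_%02d", seq_len(n_enr)),
             sprintf("NULL_SET_%02d", seq_len(n_null))),
    size = c(enriched_sizes, rep_len(null_sizes, n_null)),
    enriched = rep(c(TRUE, FALSE), c(n_enr, n_null)),
    stringsAsFactors = FALSE
  )
}

#' Synthetic cohort configuration
#'
#' Bundles every parameter of the synthetic-cohort generator. The defaults
#' emulate the study conditions the pipeline targets: 535 adults with
#' overweight/obesity from 8 European centers (61% female, age 24-63 years,
#' BMI 25.6-52 kg/m^2), a 1128-aptamer plasma proteomics panel, 5-point OGTT
#' sampling at 0/30/60/90/120 min, and a gene-set collection with three
#' planted-enriched pathways.
#'
#' @param n_subjects Number of subjects.
#' @param n_aptamers Number of aptamers on the proteomics panel.
#' @param n_centers Number of study centers.
#' @param proportion_female Expected fraction of female subjects.
#' @param age_range,bmi_range Truncation ranges (years; kg/m^2) for the
#'   covariate distributions.
#' @param age_mean,age_sd,bmi_mean,bmi_sd Location/scale of the truncated
#'   normal covariate distributions.
#' @param latent_rho Gaussian-copula correlation between the latent muscle and
#'   liver IR degrees (both marginally Beta(2,2) on \[0,1\]).
#' @param planted_effects Data frame as returned by
#'   [default_planted_effects()]; aptamer indices must be within
#'   `1:n_aptamers`.
#' @param var_prior_df,var_prior_scale Parameters d0 and s0^2 of the scaled
#'   inverse-chi-square distribution from which per-protein residual variances
#'   are drawn (log2-abundance units squared).
#' @param covariate_effect_sds Named numeric vector of per-covariate effect
#'   scales (`sex`, `age`, `centre`, `bmi`) on the log2-abundance scale.
#' @param ogtt_noise_sd Named numeric vector: additive Gaussian measurement
#'   noise SD for `glucose` (mmol/L) and `insulin` (pmol/L).
#' @param concentration_floor Floor to which negative post-noise
#'   concentrations are clipped.
#' @param misi_slope_range Range `c(min, max)` of the insulin-normalized
#'   glucose decline rate (mmol/L per min per pmol/L); the muscle IR latent
#'   interpolates from `max` (fully sensitive) down to `min` (fully
#'   resistant), so `min` is the decline rate of a maximally resistant
#'   subject.
#' @param multimap_fraction Fraction of aptamers mapping to more than one
#'   gene.
#' @param n_genes Size of the synthetic gene pool (default 90% of
#'   `n_aptamers`, which induces N:1 aptamer-to-gene collapses).
#' @param gene_sets Data frame as returned by [default_gene_sets()].
#' @param enriched_overlap Fraction of a planted-enriched set drawn from
#'   planted-effect genes.
#' @param seed Integer seed; each generator stage derives its own stream from
#'   it so stages are individually reproducible.
#' @return A validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_subjects = 535L,
                          n_aptamers = 1128L,
                          n_centers = 8L,
                          proportion_female = 0.61,
                          age_range = c(24, 63),
                          bmi_range = c(25.6, 52.0),
                          age_mean = 41.9, age_sd = 10,
                          bmi_mean = 34.4, bmi_sd = 4.6,
                          latent_rho = 0.3,
                          planted_effects = default_planted_effects(),
                          var_prior_df = 4,
                          var_prior_scale = 0.25,
                          covariate_effect_sds = c(sex = 0.2, age = 0.01,
                                                   centre = 0.1, bmi = 0.02),
                          ogtt_noise_sd = c(glucose = 0.15, insulin = 8),
                          concentration_floor = 0.1,
                          misi_slope_range = c(1.5e-5, 1.2e-4),
                          multimap_fraction = 0.1,
                          n_genes = NULL,
                          gene_sets = default_gene_sets(),
                          enriched_overlap = 0.8,
                          seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_aptamers = as.integer(n_aptamers),
    n_centers = as.integer(n_centers),
    proportion_female = proportion_female,
    age_range = age_range, bmi_range = bmi_range,
    age_mean = age_mean, age_sd = age_sd,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    latent_rho = latent_rho,
    planted_effects = planted_effects,
    var_prior_df = var_prior_df,
    var_prior_scale = var_prior_scale,
    covariate_effect_sds = covariate_effect_sds,
    ogtt_noise_sd = ogtt_noise_sd,
    concentration_floor = concentration_floor,
    misi_slope_range = misi_slope_range,
    multimap_fraction = multimap_fraction,
    n_genes = if (is.null(n_genes)) ceiling(0.9 * n_aptamers) else
      as.integer(n_genes),
    gene_sets = gene_sets,
    enriched_overlap = enriched_overlap,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_subjects < 0L) stop("n_subjects must be >= 0")
  if (cfg$n_aptamers < 0L) stop("n_aptamers must be >= 0")
  if (cfg$n_centers < 1L) stop("n_centers must be >= 1")
  for (f in c("proportion_female", "multimap_fraction", "enriched_overlap")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop(sprintf("%s must lie in [0, 1]", f))
    }
  }
  if (abs(cfg$latent_rho) > 1) stop("latent_rho must lie in [-1, 1]")
  if (cfg$var_prior_scale <= 0 || cfg$var_prior_df <= 0) {
    stop("variance prior parameters must be positive")
  }
  pe <- cfg$planted_effects
  if (nrow(pe) > 0) {
    if (any(pe$aptamer < 1L | pe$aptamer > cfg$n_aptamers)) {
      stop("planted aptamer index out of range")
    }
    if (anyDuplicated(pe$aptamer)) stop("duplicate planted aptamer index")
    if (!all(pe$axis %in% c("muscle", "liver", "both"))) {
      stop("planted axis must be one of 'muscle', 'liver', 'both'")
    }
  }
  if (any(cfg$misi_slope_range <= 0) ||
      diff(cfg$misi_slope_range) < 0) {
    stop("misi_slope_range must be positive and increasing")
  }
  invisible(cfg)
}

# Per-stage RNG stream: deterministic offset from the config seed so each
# generator stage is reproducible on its own and stages stay decoupled.
stage_seed <- function(cfg, offset) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed + offset)
  invisible(NULL)
}
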