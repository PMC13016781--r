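# Subjects are labelled S0001..., aptamers APT0001..., genes GENE0001...;
# all cross-references between stage outputs use these ids.
aptamer_ids <- function(n) sprintf("APT%04d", seq_len(n))

subject_ids <- function(n) sprintf("S%04d", seq_len(n))

gene_pool <- function(n) sprintf("GENE%04d", seq_len(n))

# truncated-normal draw by rejection; ranges are wide so acceptance is high
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    x <- rnorm(length(todo), mean, sd)
    ok <- x >= lower & x <= upper
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

#' Generate subject covariates and latent IR degrees
#'
#' Draws one row per subject: sex (Bernoulli with the configured female
#' fraction), age and BMI (truncated normal within the configured ranges) and
#' study center (uniform over centers). Latent muscle and liver IR degrees
#' are marginally Beta(2,2) on \[0,1\] and coupled through a Gaussian copula
#' with correlation `latent_rho`, reflecting that the two IR phenotypes
#' overlap partially in the same individual.
#'
#' @param config A [cohort_config()].
#' @return A list with `covariates` (data frame: `subject_id`, `sex`, `age`,
#'   `bmi`, `centre`) and `latents` (data frame: `subject_id`,
#'   `latent_ir_muscle`, `latent_ir_liver`).
#' @export
generate_covariates <- function(config) {
  validate_cohort_config(config)
  n <- config$n_subjects
  stage_seed(config, 0L)
  if (n == 0L) {
    cov <- data.frame(subject_id = character(0),
                      sex = factor(character(0), levels = c("male", "female")),
                      age = numeric(0), bmi = numeric(0),
                      centre = factor(character(0)),
                      stringsAsFactors = FALSE)
    lat <- data.frame(subject_id = character(0),
                      latent_ir_muscle = numeric(0),
                      latent_ir_liver = numeric(0))
    return(list(covariates = cov, latents = lat))
  }
  rho <- config$latent_rho
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  lat_m <- qbeta(pnorm(z1), 2, 2)
  lat_l <- qbeta(pnorm(z2), 2, 2)
  sex <- factor(ifelse(runif(n) < config$proportion_female,
                       "female", "male"),
                levels = c("male", "female"))
  age <- rtruncnorm(n, config$age_mean, config$age_sd,
                    config$age_range[1], config$age_range[2])
  bmi <- rtruncnorm(n, config$bmi_mean, config$bmi_sd,
                    config$bmi_range[1], config$bmi_range[2])
  centre <- factor(sample(sprintf("C%d", seq_len(config$n_centers)), n,
                          replace = TRUE),
                   levels = sprintf("C%d", seq_len(config$n_centers)))
  ids <- subject_ids(n)
  list(
    covariates = data.frame(subject_id = ids, sex = sex, age = age,
                            bmi = bmi, centre = centre,
                            stringsAsFactors = FALSE),
    latents = data.frame(subject_id = ids, latent_ir_muscle = lat_m,
                         latent_ir_liver = lat_l, stringsAsFactors = FALSE)
  )
}

#' Simulate 5-point OGTT glucose and insulin curves
#'
#' Mechanism-light parametric generator for oral glucose tolerance test
#' curves at 0/30/60/90/120 min. Insulin starts at a baseline that rises with
#' liver IR, peaks at 30 min with an excursion amplitude that also grows with
#' liver IR, and decays thereafter. Glucose rises from a (liver-IR-shifted)
#' fasting value to a 30-min peak whose 0-30-min excursion grows with liver
#' IR, then declines linearly at rate `mean_insulin * k(muscle IR)`, where
#' the insulin-normalized uptake rate `k` interpolates the configured
#' `misi_slope_range` from its maximum (fully insulin sensitive) down to its
#' minimum (fully resistant). By construction the muscle insulin sensitivity
#' index computed downstream is a strictly decreasing function of the muscle
#' latent (it tracks `k` up to a modest spline-induced inflation of the
#' fitted slope near the peak), and the
#' hepatic IR index is a strictly increasing function of the liver latent, so
#' noise-free rank correlations between latents and recovered IR degrees are
#' essentially 1.
#'
#' Additive Gaussian measurement noise (configurable SD per analyte) is
#' applied last; values falling below `concentration_floor` are clipped and
#' the clip count reported via `message()`.
#'
#' @param latents Data frame from [generate_covariates()]`$latents`.
#' @param config A [cohort_config()].
#' @return Long-format data frame: `subject_id`, `time_min`,
#'   `glucose_mmol_l`, `insulin`, `insulin_unit` (always `"pmol_l"`).
#' @export
simulate_ogtt_curves <- function(latents, config) {
  validate_cohort_config(config)
  stopifnot(all(latents$latent_ir_muscle >= 0 & latents$latent_ir_muscle <= 1),
            all(latents$latent_ir_liver >= 0 & latents$latent_ir_liver <= 1))
  stage_seed(config, 1L)
  n <- nrow(latents)
  times <- c(0, 30, 60, 90, 120)
  if (n == 0L) {
    return(data.frame(subject_id = character(0), time_min = numeric(0),
                      glucose_mmol_l = numeric(0), insulin = numeric(0),
                      insulin_unit = character(0), stringsAsFactors = FALSE))
  }
  m <- latents$latent_ir_muscle
  l <- latents$latent_ir_liver

  # insulin: baseline + peaked excursion, both increasing in liver IR
  shape <- c(0, 1, 0.8, 0.5, 0.25)
  ins0 <- 40 + 30 * l
  ins_amp <- 200 + 400 * l
  ins <- matrix(ins0, n, 5) + outer(ins_amp, shape)      # pmol/L

  # trapezoidal time-average weights for equally spaced 5-point sampling
  w <- c(0.5, 1, 1, 1, 0.5) / 4
  mean_ins <- drop(ins %*% w)

  # glucose: fasting value and 0-30 excursion increase in liver IR; linear
  # post-peak decline at rate mean insulin x k(muscle IR)
  k_rng <- config$misi_slope_range
  k <- k_rng[2] - (k_rng[2] - k_rng[1]) * m
  slope <- mean_ins * k                                   # mmol/L per min
  g0 <- 5.0 + 0.8 * l
  g30 <- g0 + 2.0 + 2.5 * l
  decline_floor <- 3.0                                    # mmol/L
  glu <- cbind(g0, g30,
               pmax(g30 - 30 * slope, decline_floor),
               pmax(g30 - 60 * slope, decline_floor),
               pmax(g30 - 90 * slope, decline_floor))

  sds <- config$ogtt_noise_sd
  if (sds[["glucose"]] > 0) {
    glu <- glu + matrix(rnorm(n * 5, 0, sds[["glucose"]]), n, 5)
  }
  if (sds[["insulin"]] > 0) {
    ins <- ins + matrix(rnorm(n * 5, 0, sds[["insulin"]]), n, 5)
  }
  floor_ <- config$concentration_floor
  n_clip <- sum(glu < floor_) + sum(ins < floor_)
  if (n_clip > 0) {
    message(sprintf("simulate_ogtt_curves: clipped %d values to floor %g",
                    n_clip, floor_))
    glu <- pmax(glu, floor_)
    ins <- pmax(ins, floor_)
  }

  data.frame(
    subject_id = rep(latents$subject_id, each = 5),
    time_min = rep(times, n),
    glucose_mmol_l = as.vector(t(glu)),
    insulin = as.vector(t(ins)),
    insulin_unit = "pmol_l",
    stringsAsFactors = FALSE
  )
}

#' Simulate a subjects x aptamers log2-abundance matrix with planted effects
#'
#' Generates `Y_j = b0_j + b1_j * IRmuscle + b2_j * IRliver + sex + age +
#' centre + BMI terms + e`, the generative inverse of the per-protein model
#' fitted downstream. IR covariates are the latent degrees; non-planted
#' aptamers have `b1 = b2 = 0`. Residual variances are drawn from a scaled
#' inverse-chi-square distribution (`var_prior_df`, `var_prior_scale`) so the
#' empirical-Bayes moderation stage sees the heteroskedasticity it is
#' designed for. Covariate effects are drawn per protein with the configured
#' scales; age and BMI enter centered at 45 years and 34 kg/m^2.
#'
#' @param latents,covariates Aligned outputs of [generate_covariates()].
#' @param config A [cohort_config()].
#' @return List with `matrix` (n_subjects x n_aptamers, dimnames set),
#'   `sigma2` (true per-aptamer residual variances) and `true_effects`
#'   (data frame `aptamer_id`, `axis`, `beta_muscle`, `beta_liver`).
#' @export
simulate_proteome <- function(latents, covariates, config) {
  validate_cohort_config(config)
  stopifnot(identical(latents$subject_id, covariates$subject_id))
  stage_seed(config, 2L)
  n <- nrow(covariates)
  p <- config$n_aptamers
  sigma2 <- config$var_prior_df * config$var_prior_scale /
    rchisq(p, df = config$var_prior_df)
  beta0 <- rnorm(p, 10, 0.5)
  sds <- config$covariate_effect_sds
  b_sex <- rnorm(p, 0, sds[["sex"]])
  b_age <- rnorm(p, 0, sds[["age"]])
  b_bmi <- rnorm(p, 0, sds[["bmi"]])
  b_centre <- matrix(rnorm(config$n_centers * p, 0, sds[["centre"]]),
                     config$n_centers, p)

  beta_m <- numeric(p)
  beta_l <- numeric(p)
  pe <- config$planted_effects
  if (nrow(pe) > 0) {
    is_m <- pe$axis %in% c("muscle", "both")
    is_l <- pe$axis %in% c("liver", "both")
    beta_m[pe$aptamer[is_m]] <- pe$beta[is_m]
    beta_l[pe$aptamer[is_l]] <- pe$beta[is_l]
  }

  ids <- aptamer_ids(p)
  if (n == 0L) {
    y <- matrix(numeric(0), 0, p, dimnames = list(NULL, ids))
  } else {
    female <- as.numeric(covariates$sex == "female")
    age_c <- covariates$age - 45
    bmi_c <- covariates$bmi - 34
    centre_idx <- as.integer(covariates$centre)
    y <- matrix(beta0, n, p, byrow = TRUE) +
      outer(latents$latent_ir_muscle, beta_m) +
      outer(latents$latent_ir_liver, beta_l) +
      outer(female, b_sex) +
      outer(age_c, b_age) +
      outer(bmi_c, b_bmi) +
      b_centre[centre_idx, , drop = FALSE] +
      matrix(rnorm(n * p), n, p) *
        matrix(sqrt(sigma2), n, p, byrow = TRUE)
    dimnames(y) <- list(covariates$subject_id, ids)
  }

  true_effects <- data.frame(
    aptamer_id = ids[pe$aptamer],
    axis = pe$axis,
    beta_muscle = beta_m[pe$aptamer],
    beta_liver = beta_l[pe$aptamer],
    stringsAsFactors = FALSE
  )
  list(matrix = y, sigma2 = sigma2, true_effects = true_effects)
}

#' Simulate an aptamer-to-gene annotation with 1:N and N:1 mappings
#'
#' Each aptamer maps to at least one gene drawn from a pool smaller than the
#' panel (so several aptamers share genes, the N:1 case); a configurable
#' fraction of aptamers receives a second gene (the 1:N case) and is flagged
#' `multimap`.
#'
#' @param config A [cohort_config()].
#' @return Long-format data frame `aptamer_id`, `gene_id`, `multimap_flag`
#'   (one row per aptamer-gene pair; the flag marks aptamers mapping to more
#'   than one gene).
#' @export
simulate_aptamer_map <- function(config) {
  validate_cohort_config(config)
  stage_seed(config, 3L)
  p <- config$n_aptamers
  if (p < 1L) stop("n_aptamers must be >= 1 to build an annotation")
  pool <- gene_pool(config$n_genes)
  ids <- aptamer_ids(p)
  primary <- sample(pool, p, replace = TRUE)
  extra_n <- rbinom(p, 1, config$multimap_fraction)
  rows_apt <- c(ids, ids[extra_n == 1])
  rows_gene <- c(primary, vapply(which(extra_n == 1), function(i) {
    sample(setdiff(pool, primary[i]), 1)
  }, character(1)))
  flag <- rows_apt %in% ids[extra_n == 1]
  out <- data.frame(aptamer_id = rows_apt, gene_id = rows_gene,
                    multimap_flag = flag, stringsAsFactors = FALSE)
  out[order(out$aptamer_id, out$gene_id), , drop = FALSE]
}

#' Simulate a gene-set collection with planted enrichment
#'
#' Planted-enriched sets draw a fraction `enriched_overlap` of their members
#' from the genes of planted-effect aptamers and the remainder uniformly from
#' the universe; null sets are uniform draws.
#'
#' @param universe Character vector of all genes in the annotation.
#' @param config A [cohort_config()] whose `gene_sets` field gives set names,
#'   sizes and enrichment flags.
#' @param planted_genes Genes mapped from planted-effect aptamers (may be
#'   empty, in which case "enriched" sets degrade to uniform draws).
#' @return List with `collection` (a [gene_set_collection()]) and
#'   `enriched_sets` (character vector of planted set names).
#' @export
simulate_gene_sets <- function(universe, config, planted_genes = character()) {
  validate_cohort_config(config)
  if (length(universe) == 0) stop("universe must be nonempty")
  stage_seed(config, 4L)
  spec <- config$gene_sets
  sets <- vector("list", nrow(spec))
  names(sets) <- spec$name
  planted_genes <- intersect(planted_genes, universe)
  for (i in seq_len(nrow(spec))) {
    size <- spec$size[i]
    if (size > length(universe)) {
      stop(sprintf("gene set '%s' requests %d genes but universe has %d",
                   spec$name[i], size, length(universe)))
    }
    if (spec$enriched[i] && length(planted_genes) > 0) {
      n_pl <- min(round(config$enriched_overlap * size),
                  length(planted_genes), size)
      core <- sample(planted_genes, n_pl)
      rest <- sample(setdiff(universe, core), size - n_pl)
      sets[[i]] <- sort(c(core, rest))
    } else {
      sets[[i]] <- sort(sample(universe, size))
    }
  }
  desc <- ifelse(spec$enriched, "synthetic planted-enriched set",
                 "synthetic null set")
  list(
    collection = gene_set_collection(sets, setNames(desc, spec$name)),
    enriched_sets = spec$name[spec$enriched]
  )
}

#' Simulate a complete synthetic cohort
#'
#' Runs all generator stages in order (covariates and latent IR degrees, OGTT
#' curves, proteome matrix, aptamer-to-gene annotation, gene-set collection)
#' and collects the ground truth needed for parameter-recovery and power
#' evaluation.
#'
#' @param config A [cohort_config()].
#' @return A list of class `"synthetic_cohort"` with elements `covariates`,
#'   `ogtt`, `proteome` (matrix), `annotation`, `gene_sets`
#'   (a [gene_set_collection()]) and `truth` (latents, true effects, true
#'   residual variances, enriched set names).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  cov <- generate_covariates(config)
  ogtt <- simulate_ogtt_curves(cov$latents, config)
  prot <- simulate_proteome(cov$latents, cov$covariates, config)
  ann <- simulate_aptamer_map(config)
  planted_genes <- unique(ann$gene_id[ann$aptamer_id %in%
                                        prot$true_effects$aptamer_id])
  gs <- simulate_gene_sets(unique(ann$gene_id), config, planted_genes)
  out <- list(
    covariates = cov$covariates,
    ogtt = ogtt,
    proteome = prot$matrix,
    annotation = ann,
    gene_sets = gs$collection,
    truth = list(
      latents = cov$latents,
      true_effects = prot$true_effects,
      sigma2 = prot$sigma2,
      enriched_sets = gs$enriched_sets
    ),
    config = config
  )
  class(out) <- "synthetic_cohort"
  out
}

#' Write all synthetic-cohort artifacts to disk
#'
#' Emits the plain-text stage files the pipeline stages consume: covariates
#' CSV, OGTT long CSV, proteome CSV (subjects x aptamers, `subject_id` first
#' column), annotation TSV, gene sets GMT and a ground-truth JSON.
#'
#' @param cohort A `"synthetic_cohort"` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    covariates = file.path(dir, "covariates.csv"),
    ogtt = file.path(dir, "ogtt.csv"),
    proteome = file.path(dir, "proteome.csv"),
    annotation = file.path(dir, "annotation.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    truth = file.path(dir, "truth.json")
  )
  write.csv(cohort$covariates, paths[["covariates"]], row.names = FALSE)
  write.csv(cohort$ogtt, paths[["ogtt"]], row.names = FALSE)
  prot <- data.frame(subject_id = rownames(cohort$proteome),
                     cohort$proteome, check.names = FALSE,
                     stringsAsFactors = FALSE)
  write.csv(prot, paths[["proteome"]], row.names = FALSE)
  write.table(cohort$annotation, paths[["annotation"]], sep = "\t",
              row.names = FALSE, quote = FALSE)
  write_gmt(cohort$gene_sets, paths[["gene_sets"]])
  truth <- cohort$truth
  jsonlite::write_json(
    list(latents = truth$latents, true_effects = truth$true_effects,
         sigma2 = truth$sigma2, enriched_sets = truth$enriched_sets),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
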