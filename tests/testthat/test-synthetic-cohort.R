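test_that("covariate generation: empty cohort, determinism, composition", {
  cfg0 <- small_config(n_subjects = 0, n_aptamers = 10,
                       planted = default_planted_effects(0, 0, 0))
  empty <- generate_covariates(cfg0)
  expect_equal(nrow(empty$covariates), 0)
  expect_equal(nrow(empty$latents), 0)

  cfg <- small_config(n_subjects = 150, n_aptamers = 10,
                      planted = default_planted_effects(0, 0, 0))
  a <- generate_covariates(cfg)
  b <- generate_covariates(cfg)
  expect_identical(a, b)

  lat <- a$latents
  expect_true(all(lat$latent_ir_muscle >= 0 & lat$latent_ir_muscle <= 1))
  expect_true(all(lat$latent_ir_liver >= 0 & lat$latent_ir_liver <= 1))
  cov <- a$covariates
  expect_true(all(cov$age >= cfg$age_range[1] & cov$age <= cfg$age_range[2]))
  expect_true(all(cov$bmi >= cfg$bmi_range[1] & cov$bmi <= cfg$bmi_range[2]))
  expect_equal(nlevels(cov$centre), cfg$n_centers)
})

test_that("female fraction matches the binomial expectation", {
  cfg <- cohort_config(n_subjects = 10000, n_aptamers = 1,
                       proportion_female = 0.61,
                       planted_effects = default_planted_effects(0, 0, 0),
                       seed = 2024)
  cov <- generate_covariates(cfg)$covariates
  frac <- mean(cov$sex == "female")
  band <- 3 * sqrt(0.61 * 0.39 / 10000)
  expect_lt(abs(frac - 0.61), band)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_centers = 0), "n_centers")
  expect_error(cohort_config(proportion_female = 1.2), "0, 1")
  expect_error(cohort_config(n_aptamers = 10,
                             planted_effects = data.frame(
                               aptamer = 11L, axis = "muscle", beta = 1)),
               "out of range")
  expect_error(cohort_config(multimap_fraction = -0.1), "0, 1")
})

test_that("OGTT curves have the 5-point design and respond to latents", {
  cfg <- small_config(n_subjects = 40, n_aptamers = 10,
                      planted = default_planted_effects(0, 0, 0))
  cov <- generate_covariates(cfg)
  ogtt <- simulate_ogtt_curves(cov$latents, cfg)
  expect_equal(nrow(ogtt), 40 * 5)
  per <- split(ogtt$time_min, ogtt$subject_id)
  expect_true(all(vapply(per, function(t)
    identical(sort(t), c(0, 30, 60, 90, 120)), logical(1))))
  expect_true(all(ogtt$glucose_mmol_l >= cfg$concentration_floor))
  expect_identical(simulate_ogtt_curves(cov$latents, cfg), ogtt)
})

test_that("noise-free curves recover latent IR degrees by rank", {
  cfg <- small_config(n_subjects = 500, n_aptamers = 10,
                      planted = default_planted_effects(0, 0, 0),
                      noise = c(glucose = 0, insulin = 0))
  cov <- generate_covariates(cfg)
  ogtt <- simulate_ogtt_curves(cov$latents, cfg)
  ir <- compute_ir_profiles(ogtt)
  expect_gt(cor(cov$latents$latent_ir_liver, ir$hiri, method = "spearman"),
            0.9)
  expect_gt(cor(cov$latents$latent_ir_muscle, ir$ir_muscle,
                method = "spearman"), 0.9)
})

test_that("maximal muscle IR pins the decline rate at its minimum", {
  cfg <- small_config(n_subjects = 10, n_aptamers = 5,
                      planted = default_planted_effects(0, 0, 0),
                      noise = c(glucose = 0, insulin = 0))
  lat_res <- data.frame(subject_id = sprintf("R%02d", 1:10),
                        latent_ir_muscle = rep(1, 10),
                        latent_ir_liver = seq(0.05, 0.95, length.out = 10))
  lat_sen <- data.frame(subject_id = sprintf("N%02d", 1:10),
                        latent_ir_muscle = rep(0, 10),
                        latent_ir_liver = seq(0.05, 0.95, length.out = 10))
  ir_res <- compute_ir_profiles(simulate_ogtt_curves(lat_res, cfg))
  ir_sen <- compute_ir_profiles(simulate_ogtt_curves(lat_sen, cfg))
  k_min <- cfg$misi_slope_range[1]
  # spline fitting inflates the raw decline slope somewhat, but maximal
  # muscle IR must keep MISI near the configured floor and every fully
  # resistant subject below every fully sensitive one
  expect_true(all(ir_res$misi >= k_min * 0.9 & ir_res$misi <= k_min * 1.6))
  expect_lt(max(ir_res$misi), min(ir_sen$misi))
})

test_that("proteome generator is the inverse of the fitted model", {
  # planted beta recovered by an independent lm() refit of the generating
  # model at n = 400
  cfg <- cohort_config(
    n_subjects = 400, n_aptamers = 10, seed = 31,
    planted_effects = data.frame(aptamer = 5L, axis = "muscle", beta = 1.0),
    gene_sets = default_gene_sets(1, null_sizes = 4, enriched_sizes = 4))
  cov <- generate_covariates(cfg)
  prot <- simulate_proteome(cov$latents, cov$covariates, cfg)
  d <- cbind(cov$covariates, cov$latents[-1], y = prot$matrix[, 5])
  fit <- lm(y ~ latent_ir_muscle + latent_ir_liver + sex + age + centre + bmi,
            data = d)
  est <- summary(fit)$coefficients["latent_ir_muscle", ]
  expect_lt(abs(est["Estimate"] - 1.0), 3 * est["Std. Error"])

  # seed determinism
  expect_identical(simulate_proteome(cov$latents, cov$covariates, cfg)$matrix,
                   prot$matrix)
})

test_that("noise-free proteome returns planted coefficients exactly", {
  cfg <- cohort_config(
    n_subjects = 120, n_aptamers = 8, seed = 5,
    planted_effects = data.frame(aptamer = c(2L, 3L),
                                 axis = c("muscle", "both"),
                                 beta = c(0.8, -0.6)),
    var_prior_scale = 1e-24,
    covariate_effect_sds = c(sex = 0, age = 0, centre = 0, bmi = 0),
    gene_sets = default_gene_sets(1, null_sizes = 4, enriched_sizes = 4))
  cov <- generate_covariates(cfg)
  prot <- simulate_proteome(cov$latents, cov$covariates, cfg)
  design <- build_design_matrix(cov$covariates,
                                latent_ir_profiles(cov$latents))
  fit <- fit_linear_models(prot$matrix, design)
  expect_lt(abs(fit$coefficients["APT0002", "ir_muscle"] - 0.8), 1e-8)
  expect_lt(abs(fit$coefficients["APT0003", "ir_muscle"] + 0.6), 1e-8)
  expect_lt(abs(fit$coefficients["APT0003", "ir_liver"] + 0.6), 1e-8)
  expect_lt(max(abs(fit$coefficients[c(1, 4:8), "ir_muscle"])), 1e-8)
})

test_that("null generator with no effects gives constant columns", {
  cfg <- cohort_config(
    n_subjects = 50, n_aptamers = 6, seed = 8,
    planted_effects = default_planted_effects(0, 0, 0),
    var_prior_scale = 1e-30,
    covariate_effect_sds = c(sex = 0, age = 0, centre = 0, bmi = 0),
    gene_sets = default_gene_sets(1, null_sizes = 3, enriched_sizes = 3))
  cov <- generate_covariates(cfg)
  prot <- simulate_proteome(cov$latents, cov$covariates, cfg)
  expect_lt(max(apply(prot$matrix, 2, sd)), 1e-10)
})

test_that("aptamer map: 1:1 limit, binomial multimap rate, gene closure", {
  cfg11 <- small_config(n_aptamers = 50, multimap_fraction = 0,
                        planted = default_planted_effects(0, 0, 0))
  ann <- simulate_aptamer_map(cfg11)
  expect_equal(nrow(ann), 50)
  expect_false(any(ann$multimap_flag))

  cfg <- cohort_config(n_subjects = 10, n_aptamers = 1000,
                       multimap_fraction = 0.1, seed = 77,
                       planted_effects = default_planted_effects(0, 0, 0))
  ann2 <- simulate_aptamer_map(cfg)
  n_flagged <- length(unique(ann2$aptamer_id[ann2$multimap_flag]))
  band <- 3 * sqrt(1000 * 0.1 * 0.9)
  expect_lt(abs(n_flagged - 100), band)
  # closure: every referenced gene is in the emitted pool
  expect_true(all(ann2$gene_id %in% sprintf("GENE%04d", 1:cfg$n_genes)))
  # flagged aptamers map to >1 gene, unflagged to exactly 1
  per <- table(ann2$aptamer_id)
  flagged <- unique(ann2$aptamer_id[ann2$multimap_flag])
  expect_true(all(per[flagged] > 1))
  expect_true(all(per[setdiff(names(per), flagged)] == 1))
})

test_that("gene sets: uniform nulls, planted enrichment, GMT round trip", {
  cfg <- small_config(planted = default_planted_effects(0, 0, 0))
  universe <- sprintf("GENE%04d", 1:40)
  gs0 <- simulate_gene_sets(universe, cfg)
  expect_length(gs0$collection, 13)
  expect_true(all(unlist(gs0$collection$sets) %in% universe))
  expect_equal(unname(lengths(gs0$collection$sets)),
               cfg$gene_sets$size)

  # planted set with 80% of a 50-gene DE truth in a universe of 1000 is
  # essentially impossible under uniform sampling
  big_universe <- sprintf("GENE%04d", 1:1000)
  de_truth <- big_universe[1:50]
  cfg2 <- cohort_config(n_subjects = 10, n_aptamers = 1000, seed = 12,
                        planted_effects = default_planted_effects(5, 3, 2),
                        gene_sets = data.frame(name = "P1", size = 50,
                                               enriched = TRUE))
  gs2 <- simulate_gene_sets(big_universe, cfg2, planted_genes = de_truth)
  enr <- hypergeom_enrich(de_truth, big_universe, gs2$collection)
  expect_lt(enr$p_value[enr$set == "P1"], 1e-6)

  # GMT round trip is the identity
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs0$collection, path)
  back <- read_gmt(path)
  expect_equal(back$sets, gs0$collection$sets)
  expect_equal(unname(back$descriptions), unname(gs0$collection$descriptions))

  expect_error(simulate_gene_sets(character(0), cfg), "nonempty")
  expect_error(simulate_gene_sets(universe[1:5], cfg), "universe has")
})

test_that("whole-cohort simulation is seed-deterministic", {
  cfg <- small_config(n_subjects = 30)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$proteome, b$proteome)
  expect_identical(a$ogtt, b$ogtt)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$gene_sets$sets, b$gene_sets$sets)
  expect_identical(a$truth, b$truth)
})

test_that("null cohort p-values are uniform", {
  cfg <- cohort_config(n_subjects = 150, n_aptamers = 1000, seed = 404,
                       planted_effects = default_planted_effects(0, 0, 0),
                       gene_sets = default_gene_sets(2, null_sizes = 20,
                                                     enriched_sizes = 20))
  cov <- generate_covariates(cfg)
  prot <- simulate_proteome(cov$latents, cov$covariates, cfg)
  da <- run_differential_abundance(prot$matrix, cov$covariates,
                                   latent_ir_profiles(cov$latents))
  for (ax in c("muscle", "liver")) {
    p <- da$results$p_value[da$results$axis == ax]
    expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  }
})
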