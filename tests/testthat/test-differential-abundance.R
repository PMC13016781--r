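make_design_inputs <- function(n = 60, n_centers = 8, seed = 1) {
  set.seed(seed)
  cov <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    sex = factor(sample(c("male", "female"), n, replace = TRUE),
                 levels = c("male", "female")),
    age = runif(n, 25, 64),
    bmi = runif(n, 26, 50),
    centre = factor(sample(sprintf("C%d", seq_len(n_centers)), n,
                           replace = TRUE)),
    stringsAsFactors = FALSE
  )
  ir <- data.frame(subject_id = cov$subject_id,
                   ir_muscle = runif(n), ir_liver = runif(n),
                   stringsAsFactors = FALSE)
  list(cov = cov, ir = ir)
}

test_that("design matrix: column layout, degenerate blocks, alignment", {
  inp <- make_design_inputs()
  x <- build_design_matrix(inp$cov, inp$ir)
  # intercept + 2 IR axes + sex + age + 7 centre dummies + bmi
  expect_equal(ncol(x), 13)
  expect_equal(colnames(x)[1:3], c("(Intercept)", "ir_muscle", "ir_liver"))
  expect_equal(colnames(x)[ncol(x)], "bmi")
  expect_true(all(x[, "ir_muscle"] >= 0 & x[, "ir_muscle"] <= 1))

  one_centre <- inp$cov
  one_centre$centre <- factor(rep("C1", nrow(one_centre)))
  expect_warning(x1 <- build_design_matrix(one_centre, inp$ir),
                 "single study center")
  expect_equal(ncol(x1), 6)

  # shuffling covariate rows does not change fitted coefficients
  set.seed(9)
  y <- matrix(rnorm(nrow(x) * 3), ncol = 3,
              dimnames = list(inp$cov$subject_id, paste0("P", 1:3)))
  fit <- fit_linear_models(y, x)
  perm <- sample(nrow(inp$cov))
  x2 <- build_design_matrix(inp$cov[perm, ], inp$ir)
  fit2 <- fit_linear_models(y, x2)
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-10)

  collinear <- inp$ir
  collinear$ir_liver <- collinear$ir_muscle
  expect_error(build_design_matrix(inp$cov, collinear), "collinear")
})

test_that("per-protein OLS matches the normal-equations oracle", {
  set.seed(42)
  for (i in 1:10) {
    x <- cbind(1, matrix(rnorm(10 * 3), 10, 3))
    colnames(x) <- c("(Intercept)", "a", "b", "c")
    y <- matrix(rnorm(10 * 4), 10, 4, dimnames = list(NULL, paste0("P", 1:4)))
    fit <- fit_linear_models(y, x)
    oracle <- solve(t(x) %*% x) %*% t(x) %*% y
    expect_equal(unname(fit$coefficients), unname(t(oracle)),
                 tolerance = 1e-10)
    res <- y - x %*% oracle
    expect_equal(unname(fit$sigma2), unname(colSums(res^2) / (10 - 4)),
                 tolerance = 1e-10)
  }
})

test_that("a response equal to a design column is an exact fit", {
  inp <- make_design_inputs(n = 40, n_centers = 2)
  x <- build_design_matrix(inp$cov, inp$ir)
  y <- matrix(x[, "ir_muscle"], ncol = 1,
              dimnames = list(rownames(x), "P1"))
  fit <- fit_linear_models(y, x)
  expect_equal(unname(fit$coefficients[1, "ir_muscle"]), 1,
               tolerance = 1e-10)
  expect_lt(max(abs(fit$coefficients[1, colnames(x) != "ir_muscle"])), 1e-10)
  expect_true(fit$zero_variance[1])
})

test_that("missing values trigger per-protein complete-case refits", {
  inp <- make_design_inputs(n = 50, n_centers = 3)
  x <- build_design_matrix(inp$cov, inp$ir)
  set.seed(4)
  y <- matrix(rnorm(50 * 2), 50, 2, dimnames = list(rownames(x),
                                                    c("P1", "P2")))
  y[c(3, 17), 2] <- NA
  expect_message(fit <- fit_linear_models(y, x), "complete cases")
  keep <- !is.na(y[, 2])
  oracle <- lm.fit(x[keep, ], y[keep, 2])
  expect_equal(unname(fit$coefficients[2, ]), unname(oracle$coefficients),
               tolerance = 1e-10)
  expect_equal(fit$df_residual[2], sum(keep) - ncol(x))
})

test_that("variance moderation recovers generating prior and shrinks", {
  set.seed(7)
  d0 <- 4; s02 <- 0.25; d <- 20
  sigma2 <- d0 * s02 / rchisq(1000, d0)
  s2 <- sigma2 * rchisq(1000, d) / d
  mod <- moderate_variances(s2, d)
  expect_gt(mod$df_prior, 2.5)
  expect_lt(mod$df_prior, 6.5)
  expect_lt(abs(mod$var_prior - s02) / s02, 0.2)
  # shrinkage: posterior lies between the observation and the prior
  lo <- pmin(s2, mod$var_prior); hi <- pmax(s2, mod$var_prior)
  expect_true(all(mod$var_post >= lo - 1e-12 & mod$var_post <= hi + 1e-12))
})

test_that("moderation degenerate branches", {
  # exact ties: infinitely strong prior located at the common value
  mod <- moderate_variances(rep(0.3, 50), 10)
  expect_identical(mod$df_prior, Inf)
  expect_equal(mod$var_prior, 0.3, tolerance = 1e-12)
  expect_equal(mod$var_post, rep(0.3, 50), tolerance = 1e-12)
  # non-positive variances are excluded with a warning
  s2 <- c(rep(0.2, 20), 0, -1)
  expect_warning(mod2 <- moderate_variances(s2, 10), "excluded")
  expect_true(all(is.na(mod2$var_post[21:22])))
  expect_error(moderate_variances(rep(0.1, 5), 10), "at least 10")
})

test_that("moderated tests: null statistic and classical limit", {
  tst <- moderated_tests(0, 0.5, 0.2, 16, 4)
  expect_equal(tst$t_stat, 0)
  expect_equal(tst$p_value, 1)

  # df_prior = 0 reproduces the classical OLS t-test exactly
  inp <- make_design_inputs(n = 30, n_centers = 2, seed = 3)
  x <- build_design_matrix(inp$cov, inp$ir)
  set.seed(11)
  y <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(rownames(x),
                                                    paste0("P", 1:5)))
  fit <- fit_linear_models(y, x)
  tst2 <- moderated_tests(fit$coefficients[, "ir_muscle"],
                          fit$stdev_unscaled[, "ir_muscle"],
                          fit$sigma2, fit$df_residual, df_prior = 0)
  for (j in 1:5) {
    ols <- summary(lm(y[, j] ~ x - 1))$coefficients
    expect_equal(tst2$t_stat[j], ols["xir_muscle", "t value"],
                 tolerance = 1e-12)
    expect_equal(tst2$p_value[j], ols["xir_muscle", "Pr(>|t|)"],
                 tolerance = 1e-12)
  }
})

test_that("moderation pipeline agrees with the limma reference", {
  skip_if_not_installed("limma")
  inp <- make_design_inputs(n = 50, n_centers = 4, seed = 21)
  x <- build_design_matrix(inp$cov, inp$ir)
  set.seed(22)
  sigma2 <- 4 * 0.25 / rchisq(300, 4)
  y <- t(matrix(rnorm(50 * 300, sd = rep(sqrt(sigma2), each = 50)), 50, 300))
  rownames(y) <- paste0("P", 1:300)
  colnames(y) <- rownames(x)

  fit <- fit_linear_models(t(y), x)
  mod <- moderate_variances(fit$sigma2, fit$df_residual)

  lfit <- limma::lmFit(y, x)
  sq <- limma::squeezeVar(lfit$sigma^2, lfit$df.residual)
  expect_equal(mod$df_prior, sq$df.prior, tolerance = 1e-6)
  expect_equal(mod$var_prior, sq$var.prior, tolerance = 1e-6)
  expect_equal(unname(mod$var_post), unname(sq$var.post), tolerance = 1e-8)

  eb <- limma::eBayes(lfit)
  tst <- moderated_tests(fit$coefficients[, "ir_muscle"],
                         fit$stdev_unscaled[, "ir_muscle"],
                         mod$var_post, fit$df_residual, mod$df_prior)
  expect_equal(unname(tst$t_stat), unname(eb$t[, "ir_muscle"]),
               tolerance = 1e-8)
  expect_equal(unname(tst$p_value), unname(eb$p.value[, "ir_muscle"]),
               tolerance = 1e-8)
})

test_that("Benjamini-Hochberg step-up behaviour", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.037), 0.037)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  set.seed(14)
  p <- runif(200)^2
  q <- bh_adjust(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))  # monotone in sorted p
  expect_true(all(q <= 1 & q >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("two-tier classification and shared set", {
  res <- data.frame(aptamer_id = c("A", "B", "A", "B"),
                    axis = c("muscle", "muscle", "liver", "liver"),
                    logFC = c(1, -1, 0.5, -0.2),
                    p_value = c(1, 1, 1, 1), q_value = c(1, 1, 1, 1))
  cls <- classify_de(res)
  expect_false(any(cls$da))
  expect_false(any(cls$significant))
  expect_equal(cls$direction, c("up", "down", "up", "down"))

  # a protein planted on both axes lands in the shared set
  cfg <- cohort_config(
    n_subjects = 250, n_aptamers = 40, seed = 19,
    planted_effects = data.frame(aptamer = 7L, axis = "both", beta = 1.2),
    gene_sets = default_gene_sets(1, null_sizes = 5, enriched_sizes = 5))
  cov <- generate_covariates(cfg)
  prot <- simulate_proteome(cov$latents, cov$covariates, cfg)
  da <- run_differential_abundance(prot$matrix, cov$covariates,
                                   latent_ir_profiles(cov$latents))
  expect_true("APT0007" %in% da$shared_ids)
  cnt <- da_counts(da)
  expect_equal(cnt$total, cnt$up + cnt$down)
})

test_that("constant rescaling of a protein leaves IR logFC unchanged", {
  cfg <- small_config(n_subjects = 100, n_aptamers = 10)
  cov <- generate_covariates(cfg)
  prot <- simulate_proteome(cov$latents, cov$covariates, cfg)
  ir <- latent_ir_profiles(cov$latents)
  da1 <- run_differential_abundance(prot$matrix, cov$covariates, ir)
  shifted <- prot$matrix
  shifted[, 3] <- shifted[, 3] + 2.5   # x 2^2.5 on the raw scale
  da2 <- run_differential_abundance(shifted, cov$covariates, ir)
  r1 <- da1$results[da1$results$aptamer_id == "APT0003", ]
  r2 <- da2$results[da2$results$aptamer_id == "APT0003", ]
  expect_equal(r2$logFC, r1$logFC, tolerance = 1e-9)
})
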