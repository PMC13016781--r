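#' Build the mutually adjusted per-protein design matrix
#'
#' Assembles the fixed design shared by all proteins: intercept, the scaled
#' degrees of muscle and liver IR (both included simultaneously, so each
#' coefficient is adjusted for the other axis), sex and study-center
#' treatment-coded dummies, age and BMI. Column order is deterministic:
#' `(Intercept)`, `ir_muscle`, `ir_liver`, sex dummy, `age`, center dummies,
#' `bmi`.
#'
#' A cohort observed in a single center cannot identify center effects; the
#' center block is dropped with a warning. Perfectly collinear IR axes are an
#' error, as are other rank deficiencies.
#'
#' @param covariates Data frame with `subject_id`, `sex`, `age`, `bmi`,
#'   `centre`.
#' @param ir_profiles Data frame with `subject_id`, `ir_muscle`, `ir_liver`
#'   (as from [compute_ir_profiles()]).
#' @return Numeric matrix with rownames = subject ids and attribute
#'   `ir_columns` naming the two IR columns.
#' @export
build_design_matrix <- function(covariates, ir_profiles) {
  if (!all(covariates$subject_id %in% ir_profiles$subject_id)) {
    stop("every covariate row needs a matching IR profile")
  }
  ir <- ir_profiles[match(covariates$subject_id, ir_profiles$subject_id), ]
  if (any(ir$ir_muscle < 0 | ir$ir_muscle > 1) ||
      any(ir$ir_liver < 0 | ir$ir_liver > 1)) {
    stop("IR degrees must lie in [0, 1]")
  }
  df <- data.frame(
    ir_muscle = ir$ir_muscle,
    ir_liver = ir$ir_liver,
    sex = droplevels(factor(covariates$sex)),
    age = covariates$age,
    centre = droplevels(factor(covariates$centre)),
    bmi = covariates$bmi
  )
  form <- ~ ir_muscle + ir_liver + sex + age + centre + bmi
  if (nlevels(df$centre) < 2) {
    warning("single study center: dropping the center block from the design")
    form <- ~ ir_muscle + ir_liver + sex + age + bmi
  }
  if (nlevels(df$sex) < 2) {
    warning("single sex level: dropping sex from the design")
    form <- update(form, ~ . - sex)
  }
  if (isTRUE(all.equal(cor(df$ir_muscle, df$ir_liver), 1)) ||
      isTRUE(all.equal(cor(df$ir_muscle, df$ir_liver), -1))) {
    stop("IR axes are perfectly collinear; mutual adjustment is impossible")
  }
  x <- model.matrix(form, df)
  rownames(x) <- covariates$subject_id
  if (qr(x)$rank < ncol(x)) stop("design matrix is rank deficient")
  attr(x, "ir_columns") <- c(muscle = "ir_muscle", liver = "ir_liver")
  x
}

#' Ordinary least squares fits for all proteins against a shared design
#'
#' Fits `Y_j = X b_j + e_j` for every protein with a single QR factorization
#' of the design, reused across proteins. Proteins with missing values are
#' refitted on their complete cases (counts reported via `message()`);
#' proteins with zero residual variance are flagged and excluded from
#' downstream moderation.
#'
#' @param proteome Numeric matrix, subjects x proteins (rownames = subject
#'   ids matching the design rownames).
#' @param design Matrix from [build_design_matrix()].
#' @return List of class `"protein_fit"`: `coefficients` (proteins x
#'   columns), `sigma2`, `df_residual`, `stdev_unscaled` (proteins x
#'   columns), `zero_variance` (logical), `ir_columns`.
#' @export
fit_linear_models <- function(proteome, design) {
  stopifnot(is.matrix(proteome), is.matrix(design))
  if (!is.null(rownames(proteome))) {
    if (!all(rownames(design) %in% rownames(proteome))) {
      stop("proteome rows do not cover the design subjects")
    }
    proteome <- proteome[rownames(design), , drop = FALSE]
  } else if (nrow(proteome) != nrow(design)) {
    stop("proteome and design have different numbers of subjects")
  }
  n <- nrow(design)
  k <- ncol(design)
  if (n <= k) stop("need more subjects than design columns")
  p <- ncol(proteome)

  qrx <- qr(design)
  rank <- qrx$rank
  df_res <- n - rank
  xtx_inv <- chol2inv(qr.R(qrx))
  sd_unscaled_full <- sqrt(diag(xtx_inv))

  has_na <- colSums(is.na(proteome)) > 0
  coefs <- matrix(NA_real_, p, k, dimnames = list(colnames(proteome),
                                                  colnames(design)))
  sdu <- matrix(sd_unscaled_full, p, k, byrow = TRUE,
                dimnames = dimnames(coefs))
  sigma2 <- numeric(p)
  dfs <- rep(df_res, p)

  idx_ok <- which(!has_na)
  if (length(idx_ok) > 0) {
    y <- proteome[, idx_ok, drop = FALSE]
    b <- qr.coef(qrx, y)
    res <- y - design %*% b
    coefs[idx_ok, ] <- t(b)
    sigma2[idx_ok] <- colSums(res^2) / df_res
  }
  if (any(has_na)) {
    message(sprintf("fit_linear_models: %d proteins refit on complete cases",
                    sum(has_na)))
    for (j in which(has_na)) {
      keep <- complete.cases(proteome[, j])
      nj <- sum(keep)
      if (nj <= k) {
        sigma2[j] <- NA_real_
        next
      }
      qj <- qr(design[keep, , drop = FALSE])
      coefs[j, ] <- qr.coef(qj, proteome[keep, j])
      sdu[j, ] <- sqrt(diag(chol2inv(qr.R(qj))))
      dfs[j] <- nj - qj$rank
      sigma2[j] <- sum(qr.resid(qj, proteome[keep, j])^2) / dfs[j]
    }
  }
  zero_var <- is.finite(sigma2) & sigma2 <= .Machine$double.eps * n
  structure(
    list(coefficients = coefs, sigma2 = sigma2, df_residual = dfs,
         stdev_unscaled = sdu, zero_variance = zero_var,
         ir_columns = attr(design, "ir_columns")),
    class = "protein_fit"
  )
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Thin, empty-safe wrapper around `p.adjust(method = "BH")`:
#' `q_(i) = min_{k >= i} min(1, m p_(k) / k)` over the sorted p-values.
#'
#' @param p Numeric vector of p-values in \[0,1\].
#' @return Adjusted q-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Run the mutually adjusted differential-abundance analysis
#'
#' For every protein fits the linear model
#' `Y_j = b0 + b1 IRmuscle + b2 IRliver + b3 Sex + b4 Age + b5 Centre +
#' b6 BMI + e`, moderates the residual variances across proteins by
#' empirical Bayes (optional), computes moderated t-statistics and two-sided
#' p-values for each IR axis, and applies Benjamini-Hochberg FDR control per
#' axis. `logFC` is the fitted IR-axis coefficient on the log2-abundance
#' scale, i.e. the abundance contrast across the full \[0,1\] IR range; a
#' negative value means decreasing abundance with increasing IR.
#'
#' Two tiers are reported per axis: the differentially abundant (DA) tier at
#' unadjusted `p < alpha_nominal` (the input to pathway analysis) and the
#' significant tier at `q < alpha_fdr`.
#'
#' @param proteome Subjects x proteins abundance matrix; log2-transformed
#'   here when `transform = "log2"` (values must then be positive).
#' @param covariates,ir_profiles Passed to [build_design_matrix()].
#' @param transform `"none"` (data already on log2 scale, default) or
#'   `"log2"`.
#' @param moderation `TRUE` for empirical-Bayes moderation, `FALSE` for
#'   classical per-protein OLS t-tests.
#' @param alpha_nominal Unadjusted-p threshold of the DA tier.
#' @param alpha_fdr q-value threshold of the significant tier.
#' @return List of class `"da_result"`: `results` (long data frame with
#'   `aptamer_id`, `axis`, `logFC`, `t_stat`, `p_value`, `q_value`,
#'   `direction`, `da`, `significant`, `df_residual`, `df_prior`), `venn`
#'   (list `muscle_only`/`liver_only`/`shared`), `fit`, `moderation`
#'   (df_prior/var_prior), and the thresholds used.
#' @export
run_differential_abundance <- function(proteome, covariates, ir_profiles,
                                       transform = c("none", "log2"),
                                       moderation = TRUE,
                                       alpha_nominal = 0.05,
                                       alpha_fdr = 0.05) {
  transform <- match.arg(transform)
  if (transform == "log2") {
    if (any(proteome <= 0, na.rm = TRUE)) {
      stop("log2 transform requires strictly positive abundances")
    }
    proteome <- log2(proteome)
  }
  design <- build_design_matrix(covariates, ir_profiles)
  fit <- fit_linear_models(proteome, design)

  usable <- !fit$zero_variance & is.finite(fit$sigma2)
  if (moderation) {
    mod <- moderate_variances(ifelse(usable, fit$sigma2, NA_real_),
                              fit$df_residual)
    df_prior <- mod$df_prior
    var_prior <- mod$var_prior
    var_post <- mod$var_post
  } else {
    df_prior <- 0
    var_prior <- NA_real_
    var_post <- ifelse(usable, fit$sigma2, NA_real_)
  }

  res <- do.call(rbind, lapply(names(fit$ir_columns), function(axis) {
    col <- fit$ir_columns[[axis]]
    tst <- moderated_tests(fit$coefficients[, col],
                           fit$stdev_unscaled[, col],
                           var_post, fit$df_residual, df_prior)
    data.frame(
      aptamer_id = rownames(fit$coefficients),
      axis = axis,
      logFC = fit$coefficients[, col],
      t_stat = tst$t_stat,
      p_value = tst$p_value,
      q_value = bh_adjust(tst$p_value),
      df_residual = fit$df_residual,
      df_prior = df_prior,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
  res$direction <- ifelse(res$logFC > 0, "up", "down")
  res <- classify_de(res, alpha_nominal = alpha_nominal,
                     alpha_fdr = alpha_fdr)

  da_sets <- split(res$aptamer_id[res$da], res$axis[res$da])
  shared <- intersect(da_sets[["muscle"]] %||% character(0),
                      da_sets[["liver"]] %||% character(0))
  structure(
    list(
      results = res,
      venn = list(
        muscle_only = length(setdiff(da_sets[["muscle"]] %||% character(0),
                                     shared)),
        liver_only = length(setdiff(da_sets[["liver"]] %||% character(0),
                                    shared)),
        shared = length(shared)
      ),
      shared_ids = shared,
      fit = fit,
      moderation = list(df_prior = df_prior, var_prior = var_prior),
      alpha_nominal = alpha_nominal,
      alpha_fdr = alpha_fdr
    ),
    class = "da_result"
  )
}

#' Classify proteins into DA and significant tiers
#'
#' Adds the two-tier classification to a long results table: `da` marks the
#' differentially abundant tier (`p_value < alpha_nominal`, the pathway-
#' analysis input) and `significant` the FDR-controlled tier
#' (`q_value < alpha_fdr`); `direction` follows the sign of `logFC`.
#'
#' @param results Long data frame with at least `aptamer_id`, `axis`,
#'   `logFC`, `p_value`, `q_value`.
#' @param alpha_nominal,alpha_fdr Tier thresholds.
#' @return The input with `direction`, `da` and `significant` columns
#'   (re)computed.
#' @export
classify_de <- function(results, alpha_nominal = 0.05, alpha_fdr = 0.05) {
  results$direction <- ifelse(results$logFC > 0, "up", "down")
  results$da <- !is.na(results$p_value) & results$p_value < alpha_nominal
  results$significant <- !is.na(results$q_value) &
    results$q_value < alpha_fdr
  results
}

#' Per-axis DA counts with direction tallies
#'
#' @param da A `"da_result"` from [run_differential_abundance()].
#' @return Data frame with one row per axis: `axis`, `total`, `up`, `down`
#'   (DA tier), `significant` (FDR tier).
#' @export
da_counts <- function(da) {
  stopifnot(inherits(da, "da_result"))
  res <- da$results
  out <- do.call(rbind, lapply(split(res, res$axis), function(r) {
    data.frame(axis = r$axis[1],
               total = sum(r$da),
               up = sum(r$da & r$direction == "up"),
               down = sum(r$da & r$direction == "down"),
               significant = sum(r$significant),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  if (is.null(out)) {
    out <- data.frame(axis = character(0), total = integer(0),
                      up = integer(0), down = integer(0),
                      significant = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
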