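#' Trapezoidal area under a sampled concentration curve
#'
#' Integrates a piecewise-linear curve over `[t_start, t_end]` with the
#' trapezoidal rule. Window endpoints that fall between measured times are
#' linearly interpolated. Time is converted from minutes to hours, so the
#' result is in concentration-hours.
#'
#' @param times Sampling times in minutes, strictly increasing.
#' @param values Concentrations at `times` (any unit).
#' @param t_start,t_end Integration window in minutes; must lie within the
#'   measured range.
#' @return Area in `unit(values) * hours`.
#' @examples
#' trapezoid_auc(c(0, 30), c(5, 8), 0, 30)  # (5+8)/2 * 0.5 = 3.25
#' @export
trapezoid_auc <- function(times, values, t_start = min(times),
                          t_end = max(times)) {
  stopifnot(length(times) == length(values), length(times) >= 2,
            !is.unsorted(times, strictly = TRUE))
  if (t_start >= t_end) stop("t_start must be < t_end")
  if (t_start < min(times) || t_end > max(times)) {
    stop("integration window outside measured time range")
  }
  inner <- times > t_start & times < t_end
  tt <- c(t_start, times[inner], t_end)
  vv <- c(approx(times, values, xout = t_start)$y,
          values[inner],
          approx(times, values, xout = t_end)$y)
  sum(diff(tt) * (head(vv, -1) + vv[-1]) / 2) / 60
}

#' Hepatic insulin resistance index (HIRI)
#'
#' The hepatic IR index reflects how poorly insulin suppresses endogenous
#' glucose production: both glucose and insulin excursions in the first 30
#' minutes after the glucose load rise with liver IR. It is computed as the
#' square root of the product of the 0-30-minute glucose and insulin areas
#' under the curve,
#' `sqrt(AUC_glucose(0-30) * AUC_insulin(0-30))`,
#' with the insulin AUC in pmol/L h and the glucose AUC either in mol/L h
#' (`glucose_auc_unit = "mol_l_h"`, the default) or mmol/L h
#' (`"mmol_l_h"`); the two modes differ exactly by a factor `sqrt(1000)`.
#'
#' @param times Sampling times in minutes (must bracket 0 and 30).
#' @param glucose Glucose in mmol/L at `times`.
#' @param insulin Insulin at `times` in `insulin_unit`.
#' @param insulin_unit `"pmol_l"` or `"mu_l"` (milliunits/L, converted to
#'   pmol/L by `insulin_conversion`).
#' @param glucose_auc_unit Unit in which the glucose AUC enters the product.
#' @param insulin_conversion pmol/L per mU/L (conversion conventions vary;
#'   6.0 by default).
#' @return HIRI in arbitrary units (strictly positive for positive curves).
#' @examples
#' compute_hiri(c(0, 30), c(5, 8), c(60, 300))  # sqrt(0.00325 * 90)
#' @export
compute_hiri <- function(times, glucose, insulin,
                         insulin_unit = c("pmol_l", "mu_l"),
                         glucose_auc_unit = c("mol_l_h", "mmol_l_h"),
                         insulin_conversion = 6.0) {
  insulin_unit <- match.arg(insulin_unit)
  glucose_auc_unit <- match.arg(glucose_auc_unit)
  stopifnot(all(glucose >= 0), all(insulin >= 0))
  if (min(times) > 0 || max(times) < 30) {
    stop("HIRI needs samples covering the 0-30 min window")
  }
  if (insulin_unit == "mu_l") insulin <- insulin * insulin_conversion
  auc_g <- trapezoid_auc(times, glucose, 0, 30)
  if (glucose_auc_unit == "mol_l_h") auc_g <- auc_g / 1000
  auc_i <- trapezoid_auc(times, insulin, 0, 30)
  sqrt(auc_g * auc_i)
}

#' Interpolating natural cubic spline through OGTT samples
#'
#' Fits a natural cubic spline passing exactly through all measured points;
#' with only five OGTT samples an interpolating (rather than smoothing)
#' spline is the only estimable choice, and it serves its purpose here:
#' refining the location of the glucose peak and nadir between samples.
#'
#' @param times Sampling times in minutes (>= 4 distinct values).
#' @param values Measurements at `times`.
#' @return A function of time (as from [stats::splinefun()]) with attributes
#'   `range` (time range) and `knots`.
#' @export
fit_curve_spline <- function(times, values) {
  stopifnot(length(times) == length(values))
  if (anyDuplicated(times)) stop("duplicate times in OGTT record")
  if (length(times) < 4) stop("spline fit needs at least 4 points")
  f <- splinefun(times, values, method = "natural")
  attr(f, "range") <- range(times)
  attr(f, "knots") <- times
  f
}

#' Locate the glucose peak and subsequent nadir on a fitted curve
#'
#' Evaluates the fitted curve on a regular grid and returns the time of its
#' maximum and the time of the minimum at or after that maximum; ties are
#' broken towards the earliest time. A curve that never declines after its
#' peak (peak at the last grid point) is flagged `NO_DECLINE`.
#'
#' @param curve Function from [fit_curve_spline()].
#' @param grid_step Evaluation grid step in minutes.
#' @return List with `t_peak`, `t_nadir` (minutes) and `flags` (character).
#' @export
locate_peak_nadir <- function(curve, grid_step = 1) {
  rng <- attr(curve, "range")
  grid <- seq(rng[1], rng[2], by = grid_step)
  if (grid[length(grid)] < rng[2]) grid <- c(grid, rng[2])
  y <- curve(grid)
  i_peak <- which.max(y)
  i_nadir <- i_peak - 1L + which.min(y[i_peak:length(y)])
  flags <- character(0)
  if (i_peak == i_nadir) flags <- "NO_DECLINE"
  list(t_peak = grid[i_peak], t_nadir = grid[i_nadir], flags = flags)
}

#' Muscle insulin sensitivity index (MISI)
#'
#' The post-peak decline of OGTT glucose mainly reflects insulin-stimulated
#' uptake by skeletal muscle. MISI is the magnitude of the rate of that
#' decline divided by the mean insulin concentration over the test:
#' the glucose curve is interpolated with a natural cubic spline, the
#' ordinary-least-squares slope is fitted to the spline values on a regular
#' grid between the peak and the subsequent nadir (mmol/L per minute), and
#' the mean insulin is the trapezoidal time-average over the whole OGTT
#' (or the arithmetic mean of the samples, if selected). Higher values mean
#' greater insulin sensitivity. A curve with no post-peak decline gets
#' MISI 0 and flag `NO_DECLINE`.
#'
#' @param times Sampling times in minutes (>= 5 points for a 5-point OGTT).
#' @param glucose Glucose in mmol/L.
#' @param insulin Insulin concentrations (any unit; MISI scales inversely).
#' @param grid_step Spline evaluation grid step in minutes.
#' @param mean_insulin `"trapezoid"` (time-weighted, default) or
#'   `"arithmetic"`.
#' @return List with `misi` (arbitrary units, >= 0), `slope` (mmol/L/min),
#'   `t_peak`, `t_nadir` and `flags`.
#' @examples
#' # exactly linear decline 9 -> 5 mmol/L over 120 min, constant insulin 100
#' compute_misi(seq(0, 120, 30), c(9, 8, 7, 6, 5), rep(100, 5))$misi
#' @export
compute_misi <- function(times, glucose, insulin, grid_step = 1,
                         mean_insulin = c("trapezoid", "arithmetic")) {
  mean_insulin <- match.arg(mean_insulin)
  stopifnot(length(times) == length(glucose),
            length(times) == length(insulin))
  if (length(times) < 5) stop("MISI needs at least 5 OGTT points")
  mi <- if (mean_insulin == "trapezoid") {
    trapezoid_auc(times, insulin) / ((max(times) - min(times)) / 60)
  } else {
    mean(insulin)
  }
  if (mi <= 0) stop("mean insulin must be positive")
  curve <- fit_curve_spline(times, glucose)
  pk <- locate_peak_nadir(curve, grid_step = grid_step)
  if ("NO_DECLINE" %in% pk$flags || pk$t_nadir - pk$t_peak < grid_step) {
    return(list(misi = 0, slope = 0, t_peak = pk$t_peak,
                t_nadir = pk$t_nadir,
                flags = union(pk$flags, "NO_DECLINE")))
  }
  grid <- seq(pk$t_peak, pk$t_nadir, by = grid_step)
  y <- curve(grid)
  slope <- abs(cov(grid, y) / var(grid))
  list(misi = slope / mi, slope = slope, t_peak = pk$t_peak,
       t_nadir = pk$t_nadir, flags = pk$flags)
}

#' Homeostatic model assessment of insulin resistance (HOMA-IR)
#'
#' Fasting-state surrogate: `glucose * insulin / 22.5` with glucose in
#' mmol/L and insulin in mU/L.
#'
#' @param fasting_glucose Fasting glucose, mmol/L (> 0).
#' @param fasting_insulin Fasting insulin, mU/L (> 0).
#' @return HOMA-IR in arbitrary units.
#' @export
compute_homa_ir <- function(fasting_glucose, fasting_insulin) {
  if (any(fasting_glucose <= 0) || any(fasting_insulin <= 0)) {
    stop("HOMA-IR inputs must be positive")
  }
  fasting_glucose * fasting_insulin / 22.5
}

#' Scale index values to a [0,1] degree of insulin resistance
#'
#' Min-max scales a cohort's index values so that 0 represents the most
#' insulin-sensitive subject and 1 the most resistant. For indices that grow
#' with resistance (HIRI) use `direction = "resistance"`
#' (`(x - min) / (max - min)`); for indices that grow with sensitivity (MISI)
#' use `direction = "sensitivity"` (`(max - x) / (max - min)`). Scaling is
#' always relative to the supplied cohort.
#'
#' @param values Numeric index values (>= 2 distinct values required).
#' @param direction `"resistance"` or `"sensitivity"`.
#' @return Values in \[0,1\] with both endpoints attained.
#' @export
scale_to_ir_degree <- function(values,
                               direction = c("resistance", "sensitivity")) {
  direction <- match.arg(direction)
  rng <- range(values, na.rm = TRUE)
  if (!is.finite(diff(rng)) || diff(rng) == 0) {
    stop("all values identical; IR degree scaling undefined")
  }
  if (direction == "resistance") {
    (values - rng[1]) / diff(rng)
  } else {
    (rng[2] - values) / diff(rng)
  }
}

#' Per-subject IR profiles from a cohort of OGTT records
#'
#' Computes MISI, HIRI, HOMA-IR and the cohort-scaled \[0,1\] degrees of
#' muscle and liver IR for every subject in a long-format OGTT table.
#' `ir_muscle` is the sensitivity-direction scaling of MISI (so subjects with
#' no glucose decline map to maximal muscle IR) and `ir_liver` the
#' resistance-direction scaling of HIRI.
#'
#' @param ogtt Long-format data frame with columns `subject_id`, `time_min`,
#'   `glucose_mmol_l`, `insulin`, `insulin_unit` (single unit per cohort,
#'   `"pmol_l"` or `"mu_l"`).
#' @param glucose_auc_unit,insulin_conversion Passed to [compute_hiri()].
#' @param grid_step,mean_insulin Passed to [compute_misi()].
#' @return Data frame with one row per subject: `subject_id`, `misi`,
#'   `hiri`, `homa_ir`, `ir_muscle`, `ir_liver`, `qc_flags`
#'   (`;`-separated, empty when clean).
#' @export
compute_ir_profiles <- function(ogtt,
                                glucose_auc_unit = c("mol_l_h", "mmol_l_h"),
                                insulin_conversion = 6.0,
                                grid_step = 1,
                                mean_insulin = c("trapezoid", "arithmetic")) {
  glucose_auc_unit <- match.arg(glucose_auc_unit)
  mean_insulin <- match.arg(mean_insulin)
  need <- c("subject_id", "time_min", "glucose_mmol_l", "insulin",
            "insulin_unit")
  if (!all(need %in% names(ogtt))) {
    stop("ogtt table must have columns: ", paste(need, collapse = ", "))
  }
  unit <- unique(ogtt$insulin_unit)
  if (length(unit) != 1) stop("mixed insulin units in OGTT table")
  recs <- split(ogtt, ogtt$subject_id)
  # keep first-appearance subject order rather than alphabetical split order
  recs <- recs[unique(ogtt$subject_id)]
  one <- function(r) {
    o <- order(r$time_min)
    tt <- r$time_min[o]
    gl <- r$glucose_mmol_l[o]
    ins <- r$insulin[o]
    mis <- compute_misi(tt, gl, ins, grid_step = grid_step,
                        mean_insulin = mean_insulin)
    hiri <- compute_hiri(tt, gl, ins, insulin_unit = unit,
                         glucose_auc_unit = glucose_auc_unit,
                         insulin_conversion = insulin_conversion)
    ins_mu_l <- if (unit == "pmol_l") ins[1] / insulin_conversion else ins[1]
    homa <- if (gl[1] > 0 && ins_mu_l > 0) {
      compute_homa_ir(gl[1], ins_mu_l)
    } else {
      NA_real_
    }
    list(misi = mis$misi, hiri = hiri, homa_ir = homa,
         flags = paste(mis$flags, collapse = ";"))
  }
  res <- lapply(recs, one)
  out <- data.frame(
    subject_id = names(recs),
    misi = vapply(res, `[[`, numeric(1), "misi"),
    hiri = vapply(res, `[[`, numeric(1), "hiri"),
    homa_ir = vapply(res, `[[`, numeric(1), "homa_ir"),
    stringsAsFactors = FALSE
  )
  out$ir_muscle <- scale_to_ir_degree(out$misi, "sensitivity")
  out$ir_liver <- scale_to_ir_degree(out$hiri, "resistance")
  out$qc_flags <- vapply(res, `[[`, character(1), "flags")
  rownames(out) <- NULL
  out
}
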