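#' Fit an exponential dose-calibration curve
#'
#' Least-squares fit of `y = a * exp(b * x) + c` with `b > 0` (rising
#' response), the reference calibration family for the MSL descriptor versus
#' copper dose. The three-parameter form lets two exposure times share a
#' dose-0 intercept `a + c` while differing in growth rate `b`. Degenerate
#' (flat) data collapse to `a ~ 0` with a warning; non-monotonic behaviour
#' beyond the residual scale also warns.
#'
#' @param doses non-negative, distinct dose values (uM), length >= 4.
#' @param values measured descriptor values (one per dose point; replicate
#'   fields appear as repeated doses).
#' @param exposure exposure tag stored on the model ("T2"/"T3").
#' @return object of class `calibration_model` with `family =
#'   "exponential"`, coefficients `a`, `b`, `c`, the dose `domain`, and
#'   `residual_scale` (RMS residual).
#' @examples
#' d <- c(0, 5, 10, 15, 25, 35, 50)
#' y <- 2 * exp(0.05 * d) + 1
#' m <- fit_exponential(d, y)
#' unlist(m$coefficients)
#' @export
fit_exponential <- function(doses, values, exposure = "T3") {
  stopifnot(length(doses) == length(values), all(doses >= 0),
            all(is.finite(doses)), all(is.finite(values)))
  if (length(unique(doses)) < 4)
    stop("exponential calibration needs >= 4 distinct dose points")
  ord <- order(doses)
  x <- doses[ord]; y <- values[ord]

  if (stats::sd(y) < 1e-12 * max(abs(y), 1)) {
    warning("constant calibration data: degenerate flat fit (a ~ 0)")
    cf <- list(a = 0, b = 1e-6, c = mean(y))
    return(new_calibration_model("exponential", cf, range(x), 0, exposure))
  }

  # starting values from a log-linear fit of the baseline-subtracted data
  c0 <- min(y) - 0.05 * diff(range(y)) - 1e-9
  pos <- y - c0
  b0 <- unname(stats::coef(stats::lm(log(pos) ~ x))[2])
  if (!is.finite(b0) || b0 <= 0) b0 <- 1 / max(max(x), 1)
  a0 <- max(pos[1], 1e-6)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * exp(b * x) + c,
      start = list(a = a0, b = b0, c = c0),
      lower = c(a = 0, b = 1e-8, c = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("singular exponential fit: ", conditionMessage(e))
  )
  cf <- as.list(stats::coef(fit))
  resid_scale <- sqrt(mean(stats::resid(fit)^2))

  # monotonicity sanity check on the dose means
  mu <- tapply(y, x, mean)
  if (any(diff(mu) < -2 * resid_scale - 1e-12))
    warning("calibration data decrease with dose beyond the residual scale")
  new_calibration_model("exponential", cf, range(x), resid_scale, exposure)
}

#' Fit a cubic low-dose calibration curve
#'
#' Least-squares cubic polynomial for the entropy descriptor over the
#' low-dose domain, where the entropy response is steep but not
#' exponential-shaped. Monotonicity is checked on the fitted curve within
#' the data's dose domain only; a violation warns and inversion later uses
#' the monotone restriction.
#'
#' @param doses dose values (uM) within the low-dose domain, >= 5 points.
#' @param values measured entropy descriptor values.
#' @param exposure exposure tag.
#' @return `calibration_model` with `family = "cubic"` and coefficients
#'   `p0..p3` (ascending powers).
#' @export
fit_cubic <- function(doses, values, exposure = "T3") {
  stopifnot(length(doses) == length(values), all(is.finite(doses)),
            all(is.finite(values)))
  if (length(doses) < 5)
    stop("cubic calibration needs >= 5 points")
  fit <- stats::lm(values ~ poly(doses, 3, raw = TRUE))
  cf <- unname(stats::coef(fit))
  cf[is.na(cf)] <- 0
  cf <- list(p0 = cf[1], p1 = cf[2], p2 = cf[3], p3 = cf[4])
  resid_scale <- sqrt(mean(stats::resid(fit)^2))
  dom <- range(doses)
  grid <- seq(dom[1], dom[2], length.out = 512)
  if (any(diff(eval_calibration_poly(cf, grid)) < 0))
    warning("fitted cubic is not monotone on the dose domain; ",
            "inversion will use the monotone restriction")
  new_calibration_model("cubic", cf, dom, resid_scale, exposure)
}

#' @keywords internal
new_calibration_model <- function(family, coefficients, domain,
                                  residual_scale, exposure) {
  structure(list(family = family, coefficients = coefficients,
                 domain = domain, residual_scale = residual_scale,
                 exposure = exposure),
            class = "calibration_model")
}

#' @keywords internal
eval_calibration_poly <- function(cf, x) {
  cf$p0 + cf$p1 * x + cf$p2 * x^2 + cf$p3 * x^3
}

#' Evaluate a calibration model at given doses
#'
#' @param object `calibration_model`; @param x doses (uM); @param ... unused.
#' @return predicted descriptor values.
#' @export
predict.calibration_model <- function(object, x, ...) {
  cf <- object$coefficients
  switch(object$family,
         exponential = cf$a * exp(cf$b * x) + cf$c,
         cubic = eval_calibration_poly(cf, x),
         stop("unknown calibration family: ", object$family))
}

#' @export
print.calibration_model <- function(x, ...) {
  cf <- signif(unlist(x$coefficients), 5)
  eq <- if (x$family == "exponential")
    sprintf("y = %g * exp(%g x) + %g", cf["a"], cf["b"], cf["c"])
  else
    sprintf("y = %g + %g x + %g x^2 + %g x^3",
            cf["p0"], cf["p1"], cf["p2"], cf["p3"])
  cat("Calibration model (", x$family, ", ", x$exposure, "): ", eq, "\n",
      sep = "")
  cat("  dose domain [", x$domain[1], ",", x$domain[2], "] uM, residual scale",
      signif(x$residual_scale, 4), "\n")
  invisible(x)
}

#' Invert a calibration curve: descriptor value to dose
#'
#' Exponential models invert in closed form, `x = log((y - c) / a) / b`;
#' cubic models by root bracketing (`uniroot`) on the monotone restriction
#' within the dose domain. Values outside the curve's range over the domain
#' clamp to the nearest domain endpoint and set `out_of_range = TRUE`; for
#' an exponential, `y <= c` clamps to dose 0.
#'
#' @param model `calibration_model`; @param value measured descriptor value.
#' @return list: `dose_uM`, `out_of_range` flag.
#' @export
invert_calibration <- function(model, value) {
  stopifnot(inherits(model, "calibration_model"), is.finite(value))
  dom <- model$domain
  if (model$family == "exponential") {
    cf <- model$coefficients
    if (cf$a <= 0 || value <= cf$c)
      return(list(dose_uM = max(dom[1], 0), out_of_range = TRUE))
    x <- log((value - cf$c) / cf$a) / cf$b
    if (x < dom[1]) return(list(dose_uM = dom[1], out_of_range = TRUE))
    if (x > dom[2]) return(list(dose_uM = dom[2], out_of_range = TRUE))
    return(list(dose_uM = x, out_of_range = FALSE))
  }
  # cubic: bisection on the monotone (nondecreasing envelope) restriction
  grid <- seq(dom[1], dom[2], length.out = 2048)
  yy <- cummax(predict(model, grid))
  if (value <= yy[1]) return(list(dose_uM = dom[1], out_of_range = TRUE))
  if (value >= yy[length(yy)]) return(list(dose_uM = dom[2], out_of_range = TRUE))
  i <- findInterval(value, yy)
  lo <- grid[i]; hi <- grid[i + 1]
  f <- function(x) predict(model, x) - value
  root <- tryCatch(
    stats::uniroot(f, lower = lo, upper = hi, tol = 1e-9)$root,
    error = function(e) (lo + hi) / 2   # flat envelope segment
  )
  list(dose_uM = root, out_of_range = FALSE)
}

#' Build the two-step dose-interval decision table
#'
#' Step 1 bins the MSL-derived dose estimate against `step1_bounds`
#' (half-open intervals, unbounded on top). If the estimate falls in the
#' lowest interval, step 2 refines it against `step2_bounds`, which
#' partition exactly that lowest interval. The defaults reproduce the
#' published structure: step 1 at \{17.5, 22.5, 30\} uM and step 2 at
#' \{2.5, 7.5, 12.5\} uM give seven distinct dose intervals; the lower-slope
#' T2-only variant uses `step1_bounds = c(30, 42.5)` and no step 2.
#'
#' @param step1_bounds strictly increasing positive boundaries (uM).
#' @param step2_bounds strictly increasing boundaries inside
#'   `(0, min(step1_bounds))`, or `NULL` for a single-step table.
#' @return object of class `decision_table` with interval `labels`.
#' @examples
#' tab <- build_decision_table()
#' tab$labels # 7 intervals
#' @export
build_decision_table <- function(step1_bounds = c(17.5, 22.5, 30),
                                 step2_bounds = c(2.5, 7.5, 12.5)) {
  stopifnot(length(step1_bounds) >= 1, all(step1_bounds > 0))
  if (is.unsorted(step1_bounds, strictly = TRUE))
    stop("step-1 boundaries must be strictly increasing")
  if (!is.null(step2_bounds)) {
    if (is.unsorted(step2_bounds, strictly = TRUE))
      stop("step-2 boundaries must be strictly increasing")
    if (min(step2_bounds) <= 0 || max(step2_bounds) >= step1_bounds[1])
      stop("step-2 boundaries must partition the lowest step-1 interval (0, ",
           step1_bounds[1], ")")
  }
  step1_labels <- interval_labels(c(0, step1_bounds, Inf))
  step2_labels <- if (is.null(step2_bounds)) character(0)
    else interval_labels(c(0, step2_bounds, step1_bounds[1]))
  labels <- c(step2_labels, step1_labels[-1])
  if (is.null(step2_bounds)) labels <- step1_labels
  structure(list(
    step1_bounds = step1_bounds,
    step2_bounds = step2_bounds,
    step1_labels = step1_labels,
    step2_labels = step2_labels,
    labels = labels
  ), class = "decision_table")
}

#' @keywords internal
interval_labels <- function(edges) {
  n <- length(edges) - 1
  vapply(seq_len(n), function(i) {
    hi <- if (is.infinite(edges[i + 1])) "Inf)" else paste0(edges[i + 1], ")")
    paste0("[", edges[i], ", ", hi, " uM")
  }, character(1))
}

#' @export
print.decision_table <- function(x, ...) {
  cat("Two-step dose decision table (", length(x$labels), "intervals):\n")
  cat("  step 1 bounds:", paste(x$step1_bounds, collapse = ", "), "uM\n")
  if (!is.null(x$step2_bounds))
    cat("  step 2 bounds:", paste(x$step2_bounds, collapse = ", "),
        "uM (within [0,", x$step1_bounds[1], "))\n")
  cat("  labels:", paste(x$labels, collapse = " | "), "\n")
  invisible(x)
}

# Bin a dose estimate against half-open [lo, hi) intervals with edges
# c(0, bounds, Inf); boundary values assign upward.
#' @keywords internal
bin_dose <- function(dose, bounds) {
  findInterval(dose, c(0, bounds), left.open = FALSE) # 1 = lowest interval
}

#' Two-step classification of a measured field of view
#'
#' Step 1 inverts the MSL calibration curve to a dose estimate and bins it.
#' If (and only if) the estimate lands in the lowest step-1 interval, step 2
#' inverts the entropy calibration curve and refines the call into one of
#' the low-dose sub-intervals. The final label is always a member of the
#' table's label set.
#'
#' @param msl measured MSL value.
#' @param delta_s measured range GLCM entropy (bits); may be `NA` when the
#'   step-2 trigger cannot fire.
#' @param models list with `msl` (exponential `calibration_model`) and,
#'   when step 2 is enabled, `entropy` (cubic `calibration_model`).
#' @param table [build_decision_table()] output.
#' @return object of class `dose_call`: inputs, per-step dose estimates,
#'   which steps ran, out-of-range flags, and the final interval `label`.
#' @export
classify_dose <- function(msl, delta_s = NA_real_, models,
                          table = build_decision_table()) {
  stopifnot(inherits(table, "decision_table"),
            inherits(models$msl, "calibration_model"), is.finite(msl))
  inv1 <- invert_calibration(models$msl, msl)
  bin1 <- bin_dose(inv1$dose_uM, table$step1_bounds)
  step2 <- !is.null(table$step2_bounds) && bin1 == 1L

  step2_dose <- NA_real_
  step2_oor <- NA
  if (step2) {
    if (!is.finite(delta_s))
      stop("step-2 trigger fired (dose estimate below ", table$step1_bounds[1],
           " uM) but no entropy measurement was supplied")
    if (!inherits(models$entropy, "calibration_model"))
      stop("step-2 trigger fired but no entropy calibration model was supplied")
    inv2 <- invert_calibration(models$entropy, delta_s)
    step2_dose <- min(inv2$dose_uM, table$step1_bounds[1] - 1e-9)
    step2_oor <- inv2$out_of_range
    bin2 <- bin_dose(step2_dose, table$step2_bounds)
    label <- table$step2_labels[bin2]
  } else {
    label <- table$step1_labels[bin1]
  }
  structure(list(
    msl = msl, delta_s = delta_s,
    step1_dose_uM = inv1$dose_uM, step1_out_of_range = inv1$out_of_range,
    step2_ran = step2, step2_dose_uM = step2_dose,
    step2_out_of_range = step2_oor,
    label = label
  ), class = "dose_call")
}

#' @export
print.dose_call <- function(x, ...) {
  cat("Dose call:", x$label, "\n")
  cat("  step 1: MSL", signif(x$msl, 4), "-> dose",
      signif(x$step1_dose_uM, 4), "uM",
      if (x$step1_out_of_range) "(out of calibration range)" else "", "\n")
  if (x$step2_ran)
    cat("  step 2: delta_s", signif(x$delta_s, 4), "-> dose",
        signif(x$step2_dose_uM, 4), "uM\n")
  invisible(x)
}

#' Map a copper dose and exposure time to a stress severity
#'
#' The synthetic bridge between the assay's dose axis (uM) and the scene
#' generator's severity axis: damage accrues linearly with dose up to
#' saturation, at a rate that doubles from the shorter exposure T2 to the
#' sensitivity-optimal T3 (twice the exposure time, twice the accumulated
#' damage), so the two exposures share the dose-0 state but respond with
#' different growth rates.
#'
#' @param dose_uM copper dose (uM).
#' @param exposure "T2" or "T3".
#' @return severity in \[0, 1\].
#' @export
severity_from_dose <- function(dose_uM, exposure = "T3") {
  stopifnot(all(dose_uM >= 0), exposure %in% c("T2", "T3"))
  k <- if (exposure == "T3") 1 / 60 else 1 / 120
  pmin(k * dose_uM, 1)
}
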