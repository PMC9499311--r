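# KJMA repair model: f(t) = theta * (1 - exp(-(t/tau)^m))
#
# theta is the asymptotic fraction of cells that repair a lesion at all,
# tau the characteristic time (minutes) and m the Avrami exponent linked
# to anomalous diffusion (m < 1 subdiffusive, m > 1 superdiffusive).
# f(t)/theta is exactly the Weibull(shape = m, scale = tau) CDF.

#' Construct a set of KJMA repair parameters
#'
#' Bundles a fitted (or hypothesised) parameter triple of the KJMA repair
#' function `f(t) = theta * (1 - exp(-(t/tau)^m))` together with fit
#' diagnostics. `beta = 1/tau` is derived and always kept consistent.
#'
#' @param m Avrami exponent, dimensionless, `> 0`.
#' @param tau Characteristic repair time in minutes, `> 0`.
#' @param theta Maximal repair fraction in `(0, 1]`.
#' @param adj_r2 Adjusted R-squared of the linearized fit (`NA` if not
#'   obtained from a fit).
#' @param r2_original R-squared computed in the original repair-fraction
#'   space, reported for transparency alongside the linearized-space
#'   criterion actually maximised.
#' @param n_points_used Number of time points that entered the regression.
#' @param degenerate `TRUE` for two-point fits, which interpolate exactly
#'   and carry no residual information.
#'
#' @return An object of class `"kjma_params"`: a list with fields `m`,
#'   `tau`, `theta`, `beta`, `adj_r2`, `r2_original`, `n_points_used`,
#'   `degenerate`.
#' @examples
#' p <- kjma_params(m = 2, tau = 60, theta = 0.8)
#' repair_fraction(p, c(0, 20, 60, 120))
#' @export
kjma_params <- function(m, tau, theta, adj_r2 = NA_real_,
                        r2_original = NA_real_,
                        n_points_used = NA_integer_, degenerate = FALSE) {
  stopifnot(is.numeric(m), length(m) == 1L, is.finite(m), m > 0,
            is.numeric(tau), length(tau) == 1L, is.finite(tau), tau > 0,
            is.numeric(theta), length(theta) == 1L, theta > 0, theta <= 1)
  if (!is.na(adj_r2) && adj_r2 > 1 + 1e-12)
    stop("adj_r2 cannot exceed 1")
  structure(
    list(m = as.numeric(m), tau = as.numeric(tau), theta = as.numeric(theta),
         beta = 1 / as.numeric(tau), adj_r2 = as.numeric(adj_r2),
         r2_original = as.numeric(r2_original),
         n_points_used = as.integer(n_points_used),
         degenerate = isTRUE(degenerate)),
    class = "kjma_params"
  )
}

#' @export
print.kjma_params <- function(x, ...) {
  cat(sprintf("KJMA repair parameters: m = %.4g, tau = %.4g min, theta = %.3g (beta = %.4g /min)\n",
              x$m, x$tau, x$theta, x$beta))
  if (!is.na(x$adj_r2))
    cat(sprintf("  adj R2 (linearized) = %.6g; R2 (repair space) = %.6g; points used = %d%s\n",
                x$adj_r2, x$r2_original, x$n_points_used,
                if (x$degenerate) " [degenerate two-point fit]" else ""))
  invisible(x)
}

#' Repair fraction under the KJMA model
#'
#' Evaluates `f(t) = theta * (1 - exp(-(t/tau)^m))`, the expected fraction
#' of cells that have repaired a lesion by time `t`.
#'
#' @param params A [kjma_params] object.
#' @param t Time(s) since irradiation, minutes, `>= 0`.
#' @return Numeric vector of repair fractions in `[0, theta)`, monotone
#'   non-decreasing in `t`.
#' @examples
#' repair_fraction(kjma_params(1, 60, 1), 60)  # 1 - exp(-1)
#' @export
repair_fraction <- function(params, t) {
  stopifnot(inherits(params, "kjma_params"), is.numeric(t))
  if (any(t < 0)) stop("repair_fraction is undefined for negative times")
  params$theta * (1 - exp(-(t / params$tau)^params$m))
}

#' Instantaneous repair rate under the KJMA model
#'
#' The time derivative of [repair_fraction]:
#' `m * theta * t^(m-1) / tau^m * exp(-(t/tau)^m)`, i.e. the density of
#' ongoing repair events per minute. This is the model quantity compared
#' with excision-repair (XR-seq style) signals.
#'
#' @inheritParams repair_fraction
#' @param t Time(s) in minutes, `> 0`; `t = 0` is allowed only for
#'   `m >= 1` (limit `theta/tau` at `m = 1`, `0` for `m > 1`); for
#'   `m < 1` the rate diverges at the origin and a domain error is
#'   signalled.
#' @return Non-negative numeric vector of rates per minute.
#' @export
repair_rate <- function(params, t) {
  stopifnot(inherits(params, "kjma_params"), is.numeric(t))
  if (any(t < 0)) stop("repair_rate is undefined for negative times")
  if (params$m < 1 && any(t == 0))
    stop("repair rate diverges at t = 0 for m < 1")
  m <- params$m; tau <- params$tau; theta <- params$theta
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- m * theta * t[pos]^(m - 1) / tau^m * exp(-(t[pos] / tau)^m)
  if (any(!pos)) out[!pos] <- if (m == 1) theta / tau else 0
  out
}

#' Double-log linearization of a repair time course
#'
#' Applying the natural logarithm twice to the KJMA form (for a fixed
#' `theta`) gives `ln ln(1 / (1 - R(t)/theta)) = m ln t + m ln(1/tau)`,
#' a line in `ln t` with slope `m` and intercept `m * ln(1/tau)`.
#'
#' Zero-valued repair points make the double logarithm undefined and are
#' dropped (their count is recorded in the `n_dropped` attribute).
#' Points numerically saturated at `theta` (value/theta within machine
#' precision of 1, where the inner logarithm diverges; this includes
#' fully repaired points at `theta = 1`) are dropped the same way.
#'
#' @param times Sampling times in minutes, all `> 0`. Repeated times are
#'   allowed (pooled courses, e.g. both strands of a non-TCR block).
#' @param values Repair fractions in `[0, 1]`, same length as `times`.
#' @param theta Candidate maximal repair fraction; must exceed
#'   `max(values)` for the transform to be defined.
#' @return A `data.frame` with columns `log_t` and `y` (one row per
#'   retained point) and attribute `n_dropped`.
#' @export
kjma_linearize <- function(times, values, theta) {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values), length(times) >= 2L,
            all(times > 0), is.numeric(theta), length(theta) == 1L,
            theta > 0, theta <= 1)
  ratio <- values / theta
  saturated <- ratio >= 1 - 4 * .Machine$double.eps
  if (any(ratio > 1 + 1e-9) || (theta <= max(values) && !any(saturated)))
    stop(infeasible_theta_condition(theta, max(values)))
  keep <- values > 0 & !saturated
  if (sum(keep) < 2L)
    stop(unfittable_condition("fewer than 2 usable (non-zero, non-saturated) repair points"))
  x <- log(times[keep])
  y <- log(-log1p(-ratio[keep]))
  out <- data.frame(log_t = x, y = y)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

infeasible_theta_condition <- function(theta, vmax) {
  structure(
    class = c("repairkinetics_infeasible_theta", "error", "condition"),
    list(message = sprintf("theta = %g is not above the maximal observed repair %g",
                           theta, vmax),
         call = NULL)
  )
}

unfittable_condition <- function(msg) {
  structure(
    class = c("repairkinetics_unfittable", "error", "condition"),
    list(message = msg, call = NULL)
  )
}

#' Fit m and tau for a fixed theta
#'
#' Ordinary least squares on the [kjma_linearize] pairs: the slope is `m`
#' and `tau = exp(-intercept/m)`. The goodness of fit is the adjusted
#' R-squared in the linearized space, `1 - (1 - R2)(n - 1)/(n - 2)` with
#' one predictor; a two-point fit interpolates exactly and is reported
#' with `adj_r2 = 1` and `degenerate = TRUE`.
#'
#' Failure modes (infeasible `theta`, fewer than two usable points,
#' non-positive slope) do not raise errors but return an invalid-fit
#' marker (`ok = FALSE` with a `reason`), so that batch fitting over many
#' regions proceeds.
#'
#' @inheritParams kjma_linearize
#' @return A list with `ok`, and when `ok` is `TRUE`: `m`, `tau`,
#'   `adj_r2`, `r2_original`, `n_points_used`, `degenerate`; when `FALSE`
#'   a human-readable `reason`.
#' @export
kjma_fit_theta <- function(times, values, theta) {
  lin <- tryCatch(kjma_linearize(times, values, theta),
                  repairkinetics_infeasible_theta = function(e) e,
                  repairkinetics_unfittable = function(e) e)
  if (inherits(lin, "condition"))
    return(list(ok = FALSE, reason = conditionMessage(lin)))
  x <- lin$log_t; y <- lin$y
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0)
    return(list(ok = FALSE, reason = "all usable points share one time"))
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  if (!is.finite(slope) || slope <= 0)
    return(list(ok = FALSE, reason = "non-positive slope (m must be > 0)"))
  intercept <- mean(y) - slope * mean(x)
  tau <- exp(-intercept / slope)
  if (!is.finite(tau) || tau <= 0)
    return(list(ok = FALSE, reason = "non-finite tau"))
  fitted_y <- intercept + slope * x
  ss_res <- sum((y - fitted_y)^2)
  ss_tot <- sum((y - mean(y))^2)
  degenerate <- n == 2L
  if (degenerate || ss_tot == 0) {
    r2 <- 1
    adj_r2 <- 1
  } else {
    r2 <- 1 - ss_res / ss_tot
    adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
  }
  # original (repair-fraction) space R2, reported for transparency
  p <- kjma_params(slope, tau, theta)
  fitted_f <- repair_fraction(p, times)
  sst0 <- sum((values - mean(values))^2)
  r2o <- if (sst0 > 0) 1 - sum((values - fitted_f)^2) / sst0 else 1
  list(ok = TRUE, m = slope, tau = tau, adj_r2 = adj_r2, r2_original = r2o,
       n_points_used = n, degenerate = degenerate)
}

#' Fit the KJMA repair function with a theta grid search
#'
#' Evaluates [kjma_fit_theta] over the grid `theta_min, theta_min +
#' theta_step, ..., 1.0`, skipping grid values at or below the maximal
#' observed repair (where the double-log transform is undefined), and
#' returns the parameter set maximising the adjusted R-squared. Ties (to
#' `1e-12`) are broken towards the smallest `theta`, which makes the
#' search deterministic.
#'
#' @inheritParams kjma_linearize
#' @param theta_min Lower end of the theta grid. Conventionally `0.5` for
#'   transcribed/TCR regions and `0.4` otherwise.
#' @param theta_step Grid increment, default `0.01`.
#' @return A [kjma_params] object for the selected theta.
#' @seealso [filter_params] for the downstream parameter-range filter.
#' @examples
#' truth <- kjma_params(2, 60, 0.8)
#' v <- repair_fraction(truth, c(20, 60, 120))
#' kjma_fit(c(20, 60, 120), v, theta_min = 0.4)
#' @export
kjma_fit <- function(times, values, theta_min = 0.4, theta_step = 0.01) {
  stopifnot(theta_min > 0, theta_min <= 1, theta_step > 0)
  # build the grid on integer steps to avoid accumulation error
  n_steps <- floor((1 - theta_min) / theta_step + 1e-9)
  grid <- theta_min + theta_step * seq(0L, n_steps)
  if (grid[length(grid)] < 1 - 1e-9) grid <- c(grid, 1)
  grid[grid > 1] <- 1
  best <- NULL
  for (theta in grid) {
    fit <- kjma_fit_theta(times, values, theta)
    if (!isTRUE(fit$ok)) next
    if (is.null(best) || fit$adj_r2 > best$adj_r2 + 1e-12) {
      fit$theta <- theta
      best <- fit
    }
  }
  if (is.null(best))
    stop(unfittable_condition("no feasible theta grid point yields a valid fit"))
  kjma_params(best$m, best$tau, best$theta, adj_r2 = best$adj_r2,
              r2_original = best$r2_original,
              n_points_used = best$n_points_used,
              degenerate = best$degenerate)
}

#' Parameter-range filter for fitted regions
#'
#' Regions whose fitted parameters fall outside a plausible physical
#' range are excluded from downstream association analysis. The default
#' window is `m` in `[0.5, 5]` and `tau` in `[20, 200]` minutes; `theta`
#' is already constrained by the fitting grid.
#'
#' @param params A [kjma_params] object.
#' @param m_range,tau_range Length-2 numeric inclusive bounds.
#' @return `TRUE` if the parameters pass the filter.
#' @export
filter_params <- function(params, m_range = c(0.5, 5), tau_range = c(20, 200)) {
  stopifnot(inherits(params, "kjma_params"),
            length(m_range) == 2L, length(tau_range) == 2L)
  params$m >= m_range[1] && params$m <= m_range[2] &&
    params$tau >= tau_range[1] && params$tau <= tau_range[2]
}

#' Fit many regions and tabulate the results
#'
#' Batch front-end to [kjma_fit]: takes a long-format table of repair
#' time courses and returns one row per region. Unfittable regions (all
#' zero repair, infeasible grid, negative slope everywhere) are retained
#' with `NA` parameters rather than aborting the run.
#'
#' @param courses `data.frame` with columns `region_id`, `time`, `value`
#'   (rectified repair fractions). A region may contribute repeated times
#'   when strands are pooled.
#' @param tcr Optional logical vector or named logical (by region id):
#'   `TRUE` selects the transcribed/TCR theta floor `theta_min_tcr`.
#' @param theta_min_tcr,theta_min_other,theta_step Grid parameters.
#' @param m_range,tau_range Passed to [filter_params].
#' @return `data.frame` with columns `region_id`, `class`, `m`, `tau`,
#'   `beta`, `theta`, `adj_r2`, `n_points_used`, `degenerate`,
#'   `passes_filter`.
#' @export
fit_regions <- function(courses, tcr = NULL,
                        theta_min_tcr = 0.5, theta_min_other = 0.4,
                        theta_step = 0.01,
                        m_range = c(0.5, 5), tau_range = c(20, 200)) {
  stopifnot(is.data.frame(courses),
            all(c("region_id", "time", "value") %in% names(courses)))
  ids <- unique(courses$region_id)
  if (is.null(tcr)) tcr <- stats::setNames(rep(FALSE, length(ids)), ids)
  if (is.null(names(tcr))) {
    stopifnot(length(tcr) == length(ids))
    names(tcr) <- ids
  }
  rows <- lapply(ids, function(id) {
    sub <- courses[courses$region_id == id, , drop = FALSE]
    is_tcr <- isTRUE(unname(tcr[as.character(id)]))
    theta_min <- if (is_tcr) theta_min_tcr else theta_min_other
    fit <- tryCatch(
      kjma_fit(sub$time, sub$value, theta_min = theta_min,
               theta_step = theta_step),
      repairkinetics_unfittable = function(e) NULL,
      error = function(e) NULL)
    if (is.null(fit)) {
      data.frame(region_id = id, class = if (is_tcr) "TCR" else "other",
                 m = NA_real_, tau = NA_real_, beta = NA_real_,
                 theta = NA_real_, adj_r2 = NA_real_,
                 n_points_used = NA_integer_, degenerate = NA,
                 passes_filter = FALSE)
    } else {
      data.frame(region_id = id, class = if (is_tcr) "TCR" else "other",
                 m = fit$m, tau = fit$tau, beta = fit$beta,
                 theta = fit$theta, adj_r2 = fit$adj_r2,
                 n_points_used = fit$n_points_used,
                 degenerate = fit$degenerate,
                 passes_filter = filter_params(fit, m_range, tau_range))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a table of fitted parameters as TSV
#'
#' @param fits Output of [fit_regions].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fits <- function(fits, path) {
  utils::write.table(fits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table of fitted parameters from TSV
#'
#' @param path File written by [write_fits].
#' @return `data.frame` of fits.
#' @export
read_fits <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
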