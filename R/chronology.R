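# Age-diameter chronology: the growth law g(D) (cm/y) defines the ODE
# dD/dt = g(D); tree age at a target diameter is the quadrature
# age = \int dD / g(D). All simulators and estimators share these solvers.

# guard for laws that vanish or diverge at D = 0 (power, lognormal, ...):
# integration and ODE solves start at EPS_DBH instead of 0 when g(d) is not
# a positive finite number at the requested start.
EPS_DBH <- 0.1

effective_start <- function(law, d_start) {
  g0 <- tryCatch(growth_rate(law, max(d_start, 1e-12)),
                 error = function(e) NA_real_)
  if (!is.finite(g0) || g0 <= 1e-12) max(d_start, EPS_DBH) else d_start
}

# classify sign of g on [lo, hi]: "ok", "divergent" (g -> 0/negative only in
# a region touching the upper end, e.g. an asymptote K <= hi), or a hard
# error naming the offending interval.
check_positive_growth <- function(law, lo, hi, n_grid = 400L) {
  dd <- seq(max(lo, 1e-9), hi, length.out = n_grid)
  gv <- growth_rate(law, dd)
  bad <- which(!is.finite(gv) | gv <= 0)
  if (!length(bad)) return("ok")
  # contiguous run ending at the upper boundary (asymptote below the target)
  # -> divergent age; non-positive growth at or after the start -> error
  if (bad[1] > 1L && all(diff(bad) == 1L) && bad[length(bad)] == n_grid) {
    return("divergent")
  }
  stop(sprintf(
    "growth rate is non-positive on part of [%.3g, %.3g] cm (first at %.3g cm)",
    lo, hi, dd[bad[1]]), call. = FALSE)
}

#' Age needed to grow between two diameters
#'
#' Integrates the reciprocal growth rate, \eqn{\int_{D_0}^{D_1} dD / g(D)},
#' by adaptive quadrature (relative tolerance 1e-8). If the growth rate
#' vanishes at the approach of \code{d_target} (an asymptotic law with
#' \eqn{K \le} target), the age diverges and \code{Inf} is returned: the
#' target is not datable by that law.
#'
#' @param law a [growth_law()].
#' @param d_start starting diameter (cm); laws singular at 0 are started at
#'   0.1 cm.
#' @param d_target target diameter (cm), > \code{d_start}.
#' @return age in years (possibly \code{Inf}).
#' @examples
#' integrate_growth(growth_law("mean", c(c = 0.44)), 0, 72) # 163.64 y
#' @export
integrate_growth <- function(law, d_start = 0, d_target) {
  stopifnot(inherits(law, "growth_law"), is.numeric(d_target),
            length(d_target) == 1L)
  if (d_target <= d_start) stop("d_target must exceed d_start", call. = FALSE)
  lo <- effective_start(law, d_start)
  if (lo >= d_target) return(0)
  status <- check_positive_growth(law, lo, d_target)
  if (status == "divergent") return(Inf)
  val <- stats::integrate(function(D) 1 / growth_rate(law, D),
                          lower = lo, upper = d_target,
                          rel.tol = 1e-8, subdivisions = 1000L)
  val$value
}

#' Diameter reached after a given time
#'
#' Solves the growth ODE \eqn{dD/dt = g(D)} forward from \code{d_start} and
#' returns the diameter at each requested age. This is the same solution
#' (lsoda, rtol 1e-8) used by the cohort simulator, so simulated inventories
#' and estimated ages share one source of truth.
#'
#' @param law a [growth_law()].
#' @param ages vector of ages (years, >= 0).
#' @param d_start starting diameter (cm) at age 0.
#' @return numeric vector of diameters (cm).
#' @export
age_to_diameter <- function(law, ages, d_start = 0) {
  stopifnot(inherits(law, "growth_law"), all(ages >= 0))
  d0 <- effective_start(law, d_start)
  if (growth_rate(law, max(d0, 1e-9)) <= 0) {
    stop("growth law has non-positive growth at the starting diameter; ",
         "ages would diverge", call. = FALSE)
  }
  tt <- sort(unique(c(0, ages)))
  sol <- deSolve::lsoda(
    y = d0, times = tt,
    func = function(t, y, parms) list(growth_rate(law, pmax(y, 1e-9))),
    rtol = 1e-8, atol = 1e-10)
  dd <- stats::approx(sol[, 1], sol[, 2], xout = ages)$y
  dd
}

#' Age-diameter trajectory of a growth law
#'
#' Tabulates the age at which each diameter on a regular grid is reached.
#' Grid points below 10 cm are flagged \code{extrapolated}: inventories and
#' growth monitoring only cover stems above that threshold, so the early
#' part of the trajectory is a model extrapolation.
#'
#' @inheritParams integrate_growth
#' @param d_max largest diameter of the grid (cm).
#' @param step grid spacing (cm).
#' @return data frame (class \code{fc_trajectory}) with columns
#'   \code{age_yr}, \code{dbh_cm}, \code{extrapolated}.
#' @export
trajectory <- function(law, d_start = 0, d_max, step = 1) {
  stopifnot(d_max > d_start, step > 0)
  lo <- effective_start(law, d_start)
  status <- check_positive_growth(law, lo, d_max)
  grid <- seq(lo, d_max, by = step)
  if (grid[length(grid)] < d_max) grid <- c(grid, d_max)
  if (status == "divergent") {
    gv <- growth_rate(law, grid)
    keep <- gv > 1e-12
    keep[cumsum(!keep) > 0] <- FALSE  # stop the grid at the asymptote
    grid <- grid[keep]
  }
  steps <- vapply(seq_len(length(grid) - 1L), function(i) {
    stats::integrate(function(D) 1 / growth_rate(law, D),
                     grid[i], grid[i + 1L],
                     rel.tol = 1e-10, subdivisions = 200L)$value
  }, numeric(1))
  out <- data.frame(age_yr = c(0, cumsum(steps)), dbh_cm = grid,
                    extrapolated = grid < 10)
  class(out) <- c("fc_trajectory", "data.frame")
  out
}

#' Date the mode of a diameter distribution by mean growth
#'
#' The headline dating arithmetic: a modal diameter divided by the species'
#' mean annual diameter increment gives the age of the modal cohort, which
#' the inventory reference year converts to a calendar date. Uncertainty,
#' when standard errors are supplied, is propagated to first order (delta
#' method).
#'
#' @param mode_dbh modal diameter (cm), > 0.
#' @param mai mean annual diameter increment (cm/y), > 0.
#' @param reference_year calendar year of the inventory (default AD 2000).
#' @param species optional species label.
#' @param mode_se,mai_se optional standard errors of the two inputs.
#' @return an \code{age_estimate}: exact and rounded age (y) and calendar
#'   date (AD).
#' @examples
#' age_at_mode(72, 0.44)   # 163.6 y -> AD 1836
#' age_at_mode(90.3, 0.58) # 155.7 y -> AD 1844
#' @export
age_at_mode <- function(mode_dbh, mai, reference_year = 2000,
                        species = NA_character_,
                        mode_se = NULL, mai_se = NULL) {
  stopifnot(mode_dbh > 0, mai > 0)
  age <- mode_dbh / mai
  date <- reference_year - age
  se <- NULL
  if (!is.null(mode_se) || !is.null(mai_se)) {
    mode_se <- if (is.null(mode_se)) 0 else mode_se
    mai_se <- if (is.null(mai_se)) 0 else mai_se
    se <- sqrt((mode_se / mai)^2 + (mode_dbh * mai_se / mai^2)^2)
  }
  structure(list(
    species = species, mode_dbh = mode_dbh, mai = mai,
    age_yr = age, date_ad = date,
    age_rounded = round(age), date_ad_rounded = round(date),
    age_se = se, reference_year = reference_year,
    method = "mean_growth"), class = "age_estimate")
}

#' Date a diameter by a growth-model ODE
#'
#' Alternative to [age_at_mode()]: the age of the modal cohort is obtained
#' by integrating a fitted growth law from 0 cm up to the modal diameter.
#' Asymptotic laws whose ceiling lies below the mode yield an infinite age
#' ("not datable by this model").
#'
#' @inheritParams integrate_growth
#' @inheritParams age_at_mode
#' @return an \code{age_estimate} with method \code{"model_ode"}.
#' @export
age_at_mode_ode <- function(law, mode_dbh, reference_year = 2000,
                            species = NA_character_) {
  age <- integrate_growth(law, 0, mode_dbh)
  structure(list(
    species = species, mode_dbh = mode_dbh, mai = NA_real_,
    age_yr = age, date_ad = reference_year - age,
    age_rounded = round(age), date_ad_rounded = round(reference_year - age),
    age_se = NULL, reference_year = reference_year,
    method = "model_ode", model = law$model), class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  cat("Age estimate (", x$method, ")\n", sep = "")
  if (!is.na(x$species)) cat("  species:", x$species, "\n")
  cat(sprintf("  mode dbh: %.1f cm", x$mode_dbh))
  if (is.finite(x$mai)) cat(sprintf(";  MAI_d: %.3g cm/y", x$mai))
  cat("\n")
  if (!is.finite(x$age_yr)) {
    cat("  age: not datable by this model (diverging trajectory)\n")
    return(invisible(x))
  }
  cat(sprintf("  age: %.1f y (~%d y)", x$age_yr, x$age_rounded))
  if (!is.null(x$age_se)) cat(sprintf(" +/- %.1f", x$age_se))
  cat(sprintf("\n  calendar date: AD %d (reference AD %d)\n",
              x$date_ad_rounded, x$reference_year))
  invisible(x)
}

#' Validate age predictions against tree-ring data
#'
#' For each ring-counted (age, diameter) pair, the age at that diameter is
#' predicted (i) by integrating the growth law from 0 cm and (ii) by the
#' mean-growth shortcut diameter/MAI, and prediction errors are summarised.
#'
#' @inheritParams integrate_growth
#' @param ring_data data frame with columns \code{age_yr} and \code{dbh_cm}.
#' @param mai mean annual increment (cm/y) for the mean-growth route;
#'   defaults to the mean of \code{dbh_cm / age_yr} over the ring data.
#' @return list with the per-datum table and RMSE/bias for both methods.
#' @export
validate_against_rings <- function(law, ring_data, mai = NULL) {
  stopifnot(is.data.frame(ring_data), nrow(ring_data) > 0,
            all(c("age_yr", "dbh_cm") %in% names(ring_data)))
  if (is.null(mai)) mai <- mean(ring_data$dbh_cm / ring_data$age_yr)
  age_ode <- vapply(ring_data$dbh_cm,
                    function(d) integrate_growth(law, 0, d), numeric(1))
  age_mean <- ring_data$dbh_cm / mai
  tab <- data.frame(ring_data[c("age_yr", "dbh_cm")],
                    age_ode = age_ode, age_mean = age_mean,
                    err_ode = age_ode - ring_data$age_yr,
                    err_mean = age_mean - ring_data$age_yr)
  structure(list(
    table = tab, mai = mai,
    rmse = c(model_ode = sqrt(mean(tab$err_ode^2)),
             mean_growth = sqrt(mean(tab$err_mean^2))),
    bias = c(model_ode = mean(tab$err_ode),
             mean_growth = mean(tab$err_mean))), class = "ring_validation")
}

#' @export
print.ring_validation <- function(x, ...) {
  cat("Ring validation over", nrow(x$table), "age-diameter pairs\n")
  cat(sprintf("  RMSE  (y): model ODE %.2f | mean growth %.2f\n",
              x$rmse[1], x$rmse[2]))
  cat(sprintf("  bias  (y): model ODE %+.2f | mean growth %+.2f\n",
              x$bias[1], x$bias[2]))
  invisible(x)
}
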