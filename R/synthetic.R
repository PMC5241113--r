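# Synthetic forest histories: the forward model the estimation chain is
# tested against. A recruitment history (epochs of constant recruitment,
# age-independent annual mortality) plus a growth law generate inventories,
# growth monitoring tables, ring series and radiocarbon dates with the
# statistical structure the downstream analyses assume.

#' Recruitment history of a cohort community
#'
#' Epochs are half-open year intervals \code{(start, end]}: recruits enter
#' the population in years \code{start + 1, ..., end} at the stated rate
#' (stems/year). Mortality is an age-independent annual Bernoulli survival
#' probability of \code{1 - mortality_rate}.
#'
#' @param epochs data frame with columns \code{start}, \code{end}
#'   (calendar years AD) and \code{rate} (stems/year, >= 0); epochs must be
#'   ordered and non-overlapping.
#' @param mortality_rate annual mortality fraction, in \[0, 1).
#' @param census_year calendar year of the inventory census.
#' @return an object of class \code{recruitment_history}.
#' @examples
#' recruitment_history(data.frame(start = 1300, end = 1850, rate = 2000),
#'                     mortality_rate = 0.025, census_year = 2000)
#' @export
recruitment_history <- function(epochs, mortality_rate = 0.025,
                                census_year = 2000) {
  stopifnot(is.data.frame(epochs),
            all(c("start", "end", "rate") %in% names(epochs)))
  epochs <- epochs[order(epochs$start), , drop = FALSE]
  if (any(epochs$end <= epochs$start)) {
    stop("each epoch must have end > start", call. = FALSE)
  }
  if (nrow(epochs) > 1 &&
      any(epochs$start[-1] < epochs$end[-nrow(epochs)])) {
    stop("epochs must be non-overlapping", call. = FALSE)
  }
  if (any(epochs$rate < 0)) stop("recruitment rates must be >= 0",
                                 call. = FALSE)
  if (mortality_rate < 0 || mortality_rate >= 1) {
    stop("mortality_rate must be in [0, 1)", call. = FALSE)
  }
  structure(list(epochs = epochs, mortality_rate = mortality_rate,
                 census_year = census_year), class = "recruitment_history")
}

# expand the epochs to per-year recruit counts; Poisson by default, exact
# (rounded) counts when deterministic
recruit_years <- function(history, deterministic = FALSE) {
  out <- lapply(seq_len(nrow(history$epochs)), function(i) {
    e <- history$epochs[i, ]
    yrs <- seq.int(e$start + 1L, e$end)
    n <- if (deterministic) rep.int(round(e$rate), length(yrs))
         else stats::rpois(length(yrs), e$rate)
    rep.int(yrs, n)
  })
  unlist(out, use.names = FALSE)
}

#' Simulate a forest inventory
#'
#' Forward model for a diameter structure: each recruit of year \eqn{t}
#' that survives to the census gets the diameter obtained by integrating
#' the growth law over its age \eqn{census - t} (shared ODE solution, see
#' [age_to_diameter()]), optionally perturbed by accumulated growth noise
#' with standard deviation \code{noise_sd * sqrt(age)}. Only stems at or
#' above the inventory threshold are returned.
#'
#' @param history a [recruitment_history()].
#' @param law a [growth_law()]; must have strictly positive growth at the
#'   starting diameter.
#' @param seed integer seed; all randomness (recruitment, survival, noise)
#'   is reproducible under it.
#' @param genus,site labels attached to the simulated stems.
#' @param min_dbh inventory threshold (cm), default 30.
#' @param deterministic if TRUE, per-year recruit counts are exactly the
#'   (rounded) epoch rates instead of Poisson draws.
#' @return data frame with columns \code{site}, \code{genus}, \code{dbh_cm},
#'   \code{recruit_year}, \code{age_yr}.
#' @export
simulate_inventory <- function(history, law, seed = NULL,
                               genus = "Synthetica", site = "site1",
                               min_dbh = 30, deterministic = FALSE) {
  stopifnot(inherits(history, "recruitment_history"),
            inherits(law, "growth_law"))
  g0 <- growth_rate(law, max(EPS_DBH, 1e-9))
  if (!is.finite(g0) || g0 <= 0) {
    stop("growth law has non-positive growth at the starting diameter; ",
         "recruit ages would diverge", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  t_rec <- recruit_years(history, deterministic)
  empty <- data.frame(site = character(0), genus = character(0),
                      dbh_cm = numeric(0), recruit_year = integer(0),
                      age_yr = numeric(0))
  if (!length(t_rec)) return(empty)
  age <- history$census_year - t_rec
  keep <- age >= 0
  t_rec <- t_rec[keep]; age <- age[keep]
  # age-independent annual Bernoulli survival; common uniforms so that a
  # higher mortality at the same seed thins a superset of the same stems
  u <- stats::runif(length(age))
  alive <- u < (1 - history$mortality_rate)^age
  t_rec <- t_rec[alive]; age <- age[alive]
  if (!length(age)) return(empty)
  # one ODE solve over the age range, then exact lookup at integer ages
  amax <- max(age)
  dbh_at <- age_to_diameter(law, ages = 0:amax, d_start = 0)
  dbh <- dbh_at[age + 1L]
  if (law$noise_sd > 0) {
    dbh <- pmax(0, dbh + stats::rnorm(length(dbh),
                                      0, law$noise_sd * sqrt(pmax(age, 1))))
  }
  keep <- dbh >= min_dbh
  out <- data.frame(site = site, genus = genus, dbh_cm = dbh[keep],
                    recruit_year = t_rec[keep], age_yr = age[keep])
  rownames(out) <- NULL
  out
}

#' Simulate growth-monitoring observations
#'
#' Emulates a table of mean annual diameter increments from repeated
#' censuses: for each supplied diameter the observed increment is the law's
#' rate plus Gaussian noise (sd \code{law$noise_sd}), truncated below at 0.
#'
#' @inheritParams simulate_inventory
#' @param diameters stem diameters (cm), > 0.
#' @return data frame with columns \code{tree_id}, \code{dbh_cm},
#'   \code{mai_cm_yr}, \code{dawkins}.
#' @export
simulate_growth_observations <- function(law, diameters, seed = NULL) {
  stopifnot(inherits(law, "growth_law"), all(diameters > 0))
  if (!is.null(seed)) set.seed(seed)
  n <- length(diameters)
  mai <- growth_rate(law, diameters)
  if (law$noise_sd > 0) mai <- mai + stats::rnorm(n, 0, law$noise_sd)
  data.frame(tree_id = sprintf("t%04d", seq_len(n)),
             dbh_cm = as.numeric(diameters),
             mai_cm_yr = pmax(0, mai),
             dawkins = NA_integer_)
}

#' Simulate tree-ring age-diameter series
#'
#' Grows \code{n_trees} stems from 0 cm by annual steps: each year the
#' diameter advances by the exact ODE increment of the growth law over one
#' year (same solver as [age_to_diameter()]) plus Gaussian increment noise.
#' The full annual (age, dbh) series of every tree is returned, emulating
#' ring-width measurements on discs.
#'
#' @inheritParams simulate_inventory
#' @param n_trees number of trees (0 gives an empty table).
#' @param max_age number of annual rings per tree.
#' @return data frame with columns \code{tree_id}, \code{age_yr},
#'   \code{dbh_cm}.
#' @export
simulate_tree_ring_series <- function(law, n_trees, seed = NULL,
                                      max_age = 100) {
  stopifnot(inherits(law, "growth_law"), n_trees >= 0, max_age >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (n_trees == 0) {
    return(data.frame(tree_id = character(0), age_yr = numeric(0),
                      dbh_cm = numeric(0)))
  }
  d0 <- effective_start(law, 0)
  D <- rep(d0, n_trees)
  traj <- matrix(NA_real_, nrow = max_age, ncol = n_trees)
  for (a in seq_len(max_age)) {
    sol <- deSolve::lsoda(
      y = D, times = c(0, 1),
      func = function(t, y, parms) list(growth_rate(law, pmax(y, 1e-9))),
      rtol = 1e-8, atol = 1e-10)
    D <- as.numeric(sol[2, -1])
    if (law$noise_sd > 0) {
      D <- pmax(D + stats::rnorm(n_trees, 0, law$noise_sd), 1e-3)
    }
    traj[a, ] <- D
  }
  data.frame(tree_id = rep(sprintf("d%03d", seq_len(n_trees)),
                           each = max_age),
             age_yr = rep(seq_len(max_age), times = n_trees),
             dbh_cm = as.numeric(traj))
}

#' Simulate uncalibrated radiocarbon dates
#'
#' For each true calendar year the measured radiocarbon age is the
#' calibration curve's mean at that year plus Gaussian laboratory error.
#'
#' @param calendar_years_ad true calendar years (AD) of the dated events;
#'   must fall within the curve support.
#' @param curve a [calibration_curve()].
#' @param sigma laboratory 1-sigma error (14C years), > 0.
#' @param seed integer seed.
#' @param site,material labels attached to the simulated dates.
#' @return data frame with columns \code{lab_id}, \code{c14_bp},
#'   \code{sigma}, \code{site}, \code{material}.
#' @export
simulate_radiocarbon_dates <- function(calendar_years_ad, curve, sigma,
                                       seed = NULL, site = "synthetic",
                                       material = "charcoal") {
  stopifnot(inherits(curve, "calibration_curve"), sigma > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- length(calendar_years_ad)
  if (!n) {
    return(data.frame(lab_id = character(0), c14_bp = numeric(0),
                      sigma = numeric(0), site = character(0),
                      material = character(0)))
  }
  cal_bp <- bp_ad_convert(calendar_years_ad, "ad_to_bp")
  if (any(cal_bp < min(curve$cal_bp) | cal_bp > max(curve$cal_bp))) {
    stop("calendar years outside the calibration-curve support",
         call. = FALSE)
  }
  mu <- stats::approx(curve$cal_bp, curve$c14_bp, xout = cal_bp)$y
  data.frame(lab_id = sprintf("SYN-%03d", seq_len(n)),
             c14_bp = mu + stats::rnorm(n, 0, sigma),
             sigma = sigma, site = site, material = material)
}

#' Read a simulation scenario from a YAML file
#'
#' A scenario file holds the epochs (\code{start}, \code{end}, \code{rate}),
#' \code{mortality_rate}, \code{census_year}, a growth law (\code{model},
#' \code{params}, \code{noise_sd}) and an optional \code{seed}.
#'
#' @param path path to the YAML file.
#' @return list with elements \code{history}, \code{law}, \code{seed}.
#' @export
read_scenario <- function(path) {
  sc <- yaml::read_yaml(path)
  ep <- do.call(rbind, lapply(sc$epochs, as.data.frame))
  list(
    history = recruitment_history(
      ep, mortality_rate = sc$mortality_rate %||% 0.025,
      census_year = sc$census_year %||% 2000),
    law = growth_law(sc$law$model, unlist(sc$law$params),
                     noise_sd = sc$law$noise_sd %||% 0),
    seed = sc$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
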