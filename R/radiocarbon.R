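# Radiocarbon calibration and summed probability distributions (SPDs).
# A calibration curve maps calendar years (cal BP) to expected 14C ages
# with their own uncertainty; a measured age t +/- s calibrates to
#   p(cal) proportional to Normal(t; mu(cal), sqrt(s^2 + sigma_curve(cal)^2))
# on a 1-year calendar grid, normalized to sum to one. The SPD is the
# pointwise sum of calibrated densities, a proxy for the intensity of dated
# human activity through time.

#' Build a calibration curve on a 1-year grid
#'
#' @param cal_bp calendar years (cal BP); any order, linearly interpolated
#'   to 1-year spacing.
#' @param c14_bp curve mean radiocarbon ages (BP) at \code{cal_bp}.
#' @param sigma curve 1-sigma uncertainty (years); scalar or vector.
#' @return data frame of class \code{calibration_curve} with columns
#'   \code{cal_bp}, \code{c14_bp}, \code{sigma} on a strictly increasing
#'   1-year grid.
#' @export
calibration_curve <- function(cal_bp, c14_bp, sigma = 0) {
  stopifnot(length(cal_bp) == length(c14_bp), all(is.finite(cal_bp)),
            all(is.finite(c14_bp)), all(sigma >= 0))
  if (length(sigma) == 1L) sigma <- rep(sigma, length(cal_bp))
  o <- order(cal_bp)
  cal_bp <- cal_bp[o]; c14_bp <- c14_bp[o]; sigma <- sigma[o]
  if (anyDuplicated(cal_bp)) stop("duplicated calendar years in curve",
                                  call. = FALSE)
  grid <- seq(ceiling(min(cal_bp)), floor(max(cal_bp)), by = 1)
  out <- data.frame(
    cal_bp = grid,
    c14_bp = stats::approx(cal_bp, c14_bp, xout = grid)$y,
    sigma = stats::approx(cal_bp, sigma, xout = grid)$y)
  class(out) <- c("calibration_curve", "data.frame")
  out
}

#' Read a published-format calibration curve file
#'
#' Accepts the 5-column release format (cal BP, 14C age BP, 1-sigma, and
#' two Delta-14C columns), comma- or whitespace-separated, with \code{#}
#' comment lines. Only the first three columns are used.
#'
#' @param path path to the curve file.
#' @return a [calibration_curve()].
#' @export
read_calibration_curve <- function(path) {
  ln <- readLines(path, n = 50L)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  sep <- if (grepl(",", ln[1])) "," else ""
  df <- utils::read.table(path, sep = sep, comment.char = "#",
                          header = FALSE, strip.white = TRUE)
  if (ncol(df) < 3) stop("calibration curve file needs at least 3 columns",
                         call. = FALSE)
  calibration_curve(df[[1]], df[[2]], df[[3]])
}

#' Identity calibration curve (for tests and simulations)
#'
#' A straight-line curve with \code{c14_bp = slope * cal_bp + intercept}:
#' with the defaults, radiocarbon age equals calendar age.
#'
#' @param cal_bp_range two-element range of calendar years (cal BP).
#' @param slope,intercept line parameters.
#' @param sigma curve 1-sigma (years).
#' @return a [calibration_curve()].
#' @export
linear_calibration_curve <- function(cal_bp_range, slope = 1,
                                     intercept = 0, sigma = 0) {
  grid <- seq(min(cal_bp_range), max(cal_bp_range), by = 1)
  calibration_curve(grid, slope * grid + intercept, sigma)
}

#' Calibrate a radiocarbon date
#'
#' Evaluates the calendar-age posterior on the curve's 1-year grid and
#' normalizes it to sum to one, with highest-posterior-density intervals at
#' 68.2\% and 95.4\%. An error is raised when non-negligible probability
#' mass reaches either end of the curve support.
#'
#' @param c14_age measured radiocarbon age (BP).
#' @param sigma laboratory 1-sigma error (years), > 0.
#' @param curve a [calibration_curve()].
#' @param lab_id optional identifier carried on the result.
#' @return object of class \code{cal_date}: \code{cal_bp} grid,
#'   \code{density}, \code{hpd68}, \code{hpd95} (data frames of interval
#'   bounds in cal BP), and the inputs.
#' @export
calibrate <- function(c14_age, sigma, curve, lab_id = NULL) {
  stopifnot(inherits(curve, "calibration_curve"), is.finite(c14_age),
            sigma > 0)
  s <- sqrt(sigma^2 + curve$sigma^2)
  dens <- stats::dnorm(c14_age, mean = curve$c14_bp, sd = s)
  if (sum(dens) <= 0) {
    stop("date has no support on the calibration curve", call. = FALSE)
  }
  edge <- 1e-5 * sum(dens)  # non-negligible mass truncated at a boundary
  if (dens[1] > edge) {
    stop("calibrated range exceeds the curve support at the younger end",
         call. = FALSE)
  }
  if (dens[length(dens)] > edge) {
    stop("calibrated range exceeds the curve support at the older end",
         call. = FALSE)
  }
  dens <- dens / sum(dens)
  structure(list(cal_bp = curve$cal_bp, density = dens,
                 hpd68 = hpd_interval(curve$cal_bp, dens, 0.682),
                 hpd95 = hpd_interval(curve$cal_bp, dens, 0.954),
                 c14_age = c14_age, sigma = sigma, lab_id = lab_id),
            class = "cal_date")
}

# highest-posterior-density region on a discrete 1-y grid: the smallest set
# of years whose density sums to `level`, reported as contiguous intervals
hpd_interval <- function(grid, dens, level) {
  o <- order(dens, decreasing = TRUE)
  take <- o[seq_len(which(cumsum(dens[o]) >= level)[1])]
  yrs <- sort(grid[take])
  breaks <- which(diff(yrs) > 1)
  lo <- yrs[c(1, breaks + 1)]
  hi <- yrs[c(breaks, length(yrs))]
  data.frame(from_bp = lo, to_bp = hi)
}

#' @export
print.cal_date <- function(x, ...) {
  cat(sprintf("Calibrated date%s: %.0f +/- %.0f BP\n",
              if (is.null(x$lab_id)) "" else paste0(" ", x$lab_id),
              x$c14_age, x$sigma))
  f <- function(h) paste(sprintf("[%d, %d]", h$from_bp, h$to_bp),
                         collapse = ", ")
  cat("  68.2% HPD (cal BP):", f(x$hpd68), "\n")
  cat("  95.4% HPD (cal BP):", f(x$hpd95), "\n")
  invisible(x)
}

#' Calibrate a table of radiocarbon dates
#'
#' @param dates data frame with columns \code{lab_id}, \code{c14_bp},
#'   \code{sigma} (the [simulate_radiocarbon_dates()] schema).
#' @param curve a [calibration_curve()].
#' @return list of \code{cal_date} objects, named by lab id.
#' @export
calibrate_dates <- function(dates, curve) {
  stopifnot(all(c("c14_bp", "sigma") %in% names(dates)))
  ids <- if ("lab_id" %in% names(dates)) dates$lab_id
         else sprintf("date%03d", seq_len(nrow(dates)))
  out <- lapply(seq_len(nrow(dates)), function(i) {
    calibrate(dates$c14_bp[i], dates$sigma[i], curve, lab_id = ids[i])
  })
  names(out) <- ids
  out
}

#' Summed probability distribution of calibrated dates
#'
#' Pointwise sum of the calibrated densities on a common 1-year grid
#' (densities are resampled with zero fill where grids differ). The
#' unnormalized SPD sums to the number of dates; with
#' \code{normalize = TRUE} it is divided by that number and sums to one.
#'
#' @param densities list of \code{cal_date} objects.
#' @param normalize divide by the number of dates?
#' @return data frame of class \code{c14_spd} with columns \code{cal_bp},
#'   \code{cal_ad}, \code{density}; attributes \code{n_dates} and
#'   \code{normalized}.
#' @export
sum_probabilities <- function(densities, normalize = FALSE) {
  stopifnot(length(densities) > 0)
  if (inherits(densities, "cal_date")) densities <- list(densities)
  rng <- range(unlist(lapply(densities, function(d) range(d$cal_bp))))
  grid <- seq(rng[1], rng[2], by = 1)
  total <- numeric(length(grid))
  for (d in densities) {
    y <- stats::approx(d$cal_bp, d$density, xout = grid,
                       yleft = 0, yright = 0)$y
    total <- total + y
  }
  if (normalize) total <- total / length(densities)
  out <- data.frame(cal_bp = grid,
                    cal_ad = bp_ad_convert(grid, "bp_to_ad"),
                    density = total)
  class(out) <- c("c14_spd", "data.frame")
  attr(out, "n_dates") <- length(densities)
  attr(out, "normalized") <- normalize
  out
}

#' Local maxima of an SPD
#'
#' Finds strict local maxima of the summed density above a height
#' threshold, keeping only the most prominent peak within any
#' \code{min_sep} window.
#'
#' @param spd a [sum_probabilities()] result.
#' @param min_height minimum peak height as a fraction of the tallest peak.
#' @param min_sep minimum separation between reported peaks (years).
#' @return data frame with \code{cal_bp}, \code{cal_ad}, \code{density} of
#'   each peak, ordered by decreasing height.
#' @export
spd_peaks <- function(spd, min_height = 0.2, min_sep = 50) {
  y <- spd$density
  n <- length(y)
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                      y[2:(n - 1)] >= y[3:n], FALSE)
  idx <- which(is_peak & y >= min_height * max(y))
  idx <- idx[order(y[idx], decreasing = TRUE)]
  keep <- integer(0)
  for (i in idx) {
    if (!length(keep) || all(abs(spd$cal_bp[keep] - spd$cal_bp[i]) >=
                             min_sep)) {
      keep <- c(keep, i)
    }
  }
  spd[keep, c("cal_bp", "cal_ad", "density")]
}

#' Screen a dated context for outliers
#'
#' For each date the agreement score is the overlap coefficient (sum of
#' pointwise minima) between its calibrated density and the leave-one-out
#' pooled density of the remaining dates; dates scoring below the threshold
#' are flagged, never deleted. A light-weight screening standing in for a
#' full hierarchical outlier model.
#'
#' @param dates data frame of dates (see [calibrate_dates()]), at least 3.
#' @param curve a [calibration_curve()].
#' @param threshold agreement score below which a date is flagged.
#' @return data frame with \code{lab_id}, \code{score}, \code{flagged}.
#' @export
screen_outliers <- function(dates, curve, threshold = 0.05) {
  if (nrow(dates) < 3) {
    stop("outlier screening needs at least 3 dates from one context",
         call. = FALSE)
  }
  cals <- calibrate_dates(dates, curve)
  rng <- range(unlist(lapply(cals, function(d) range(d$cal_bp))))
  grid <- seq(rng[1], rng[2], by = 1)
  mat <- vapply(cals, function(d) {
    stats::approx(d$cal_bp, d$density, xout = grid,
                  yleft = 0, yright = 0)$y
  }, numeric(length(grid)))
  score <- vapply(seq_len(ncol(mat)), function(i) {
    pooled <- rowMeans(mat[, -i, drop = FALSE])
    pooled <- pooled / sum(pooled)
    sum(pmin(mat[, i], pooled))
  }, numeric(1))
  data.frame(lab_id = names(cals), score = score,
             flagged = score < threshold, row.names = NULL)
}

#' Convert between calendar AD and cal BP
#'
#' \code{cal BP = 1950 - AD}; the transform is its own inverse.
#'
#' @param value year(s) to convert.
#' @param direction \code{"bp_to_ad"} or \code{"ad_to_bp"}.
#' @return converted year(s).
#' @examples
#' bp_ad_convert(1850, "ad_to_bp") # 100
#' bp_ad_convert(0, "bp_to_ad")    # 1950
#' @export
bp_ad_convert <- function(value, direction = c("bp_to_ad", "ad_to_bp")) {
  match.arg(direction)
  1950 - value
}
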