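# Fitting the growth-model suite to (dbh, MAI_d) observations and ranking
# models by BIC under a Gaussian error model:
#   BIC = n ln(RSS/n) + p ln(n),  p = number of model parameters + 1
# (the +1 counts the estimated error variance).

#' Mean annual diameter increment from repeated censuses
#'
#' For each monitored tree with at least two measurements spanning a
#' positive time interval, \eqn{MAI_d = (last dbh - first dbh) / elapsed
#' years}. Negative increments (shrinkage/measurement error) are floored at
#' 0 and counted; trees with a single usable measurement are skipped and
#' counted. The representative diameter of a tree is the mean of its first
#' and last measurement.
#'
#' @param measurements data frame with columns \code{tree_id}, \code{date}
#'   (decimal calendar years, or \code{Date}), \code{dbh_cm}; optional
#'   columns \code{species} and \code{dawkins} are carried through.
#' @return data frame with columns \code{tree_id}, \code{dbh_cm},
#'   \code{mai_cm_yr} (plus carried columns); attributes \code{n_skipped}
#'   and \code{n_floored} report the exclusions.
#' @examples
#' m <- data.frame(tree_id = "t1", date = c(1995, 2000),
#'                 dbh_cm = c(50.0, 52.2))
#' compute_mai(m)$mai_cm_yr # 0.44
#' @export
compute_mai <- function(measurements) {
  stopifnot(all(c("tree_id", "date", "dbh_cm") %in% names(measurements)))
  dt <- measurements$date
  if (inherits(dt, "Date")) dt <- as.numeric(dt) / 365.25 + 1970
  measurements$.yr <- as.numeric(dt)
  sp <- split(measurements, factor(measurements$tree_id,
                                   levels = unique(measurements$tree_id)))
  n_skipped <- 0L
  n_floored <- 0L
  rows <- lapply(sp, function(d) {
    d <- d[order(d$.yr), , drop = FALSE]
    span <- d$.yr[nrow(d)] - d$.yr[1]
    if (nrow(d) < 2 || span <= 0) {
      n_skipped <<- n_skipped + 1L
      return(NULL)
    }
    mai <- (d$dbh_cm[nrow(d)] - d$dbh_cm[1]) / span
    if (mai < 0) {
      n_floored <<- n_floored + 1L
      mai <- 0
    }
    out <- data.frame(tree_id = d$tree_id[1],
                      dbh_cm = mean(d$dbh_cm[c(1, nrow(d))]),
                      mai_cm_yr = mai)
    for (extra in intersect(c("species", "dawkins"), names(d))) {
      out[[extra]] <- d[[extra]][1]
    }
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(tree_id = character(0), dbh_cm = numeric(0),
                      mai_cm_yr = numeric(0))
  }
  rownames(out) <- NULL
  if (n_skipped) message(n_skipped, " tree(s) without two dated ",
                         "measurements skipped")
  if (n_floored) message(n_floored, " negative increment(s) floored at 0")
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_floored") <- n_floored
  out
}

# pull (dbh, mai) columns out of a growth table, tolerating short names
growth_xy <- function(data) {
  dn <- intersect(c("dbh_cm", "dbh"), names(data))[1]
  mn <- intersect(c("mai_cm_yr", "mai_d", "mai"), names(data))[1]
  if (is.na(dn) || is.na(mn)) {
    stop("growth table needs diameter (dbh_cm) and increment (mai_cm_yr) ",
         "columns", call. = FALSE)
  }
  list(D = as.numeric(data[[dn]]), y = as.numeric(data[[mn]]))
}

#' Fit one growth model by least squares
#'
#' Mean and linear models are solved in closed form; \code{power_mult} is
#' the power law fitted by ordinary least squares on the log scale
#' (multiplicative error; zero increments are excluded from that fit); the
#' remaining models are minimized by multi-start Nelder-Mead with a BFGS
#' polish on log-transformed positive parameters. The reported RSS and BIC
#' are always computed on the original MAI_d scale so the criterion is
#' comparable across the suite.
#'
#' @param model model name, see [growth_law()].
#' @param data data frame with diameter and increment columns (from
#'   [compute_mai()] or [simulate_growth_observations()]).
#' @param dawkins optional vector of Dawkins classes to retain (requires a
#'   \code{dawkins} column), e.g. \code{4:5} for canopy trees only.
#' @return object of class \code{growth_model_fit}: \code{model},
#'   \code{params}, \code{n}, \code{rss}, \code{bic}, \code{converged}.
#' @export
fit_growth_model <- function(model, data, dawkins = NULL) {
  model <- match.arg(model, growth_model_names())
  if (!is.null(dawkins)) {
    stopifnot("dawkins" %in% names(data))
    data <- data[data$dawkins %in% dawkins, , drop = FALSE]
  }
  xy <- growth_xy(data)
  D <- xy$D; y <- xy$y
  n <- length(y)
  p_model <- length(growth_model_params(model))
  if (n < p_model + 2) {
    stop(sprintf("need at least %d observations to fit '%s'",
                 p_model + 2, model), call. = FALSE)
  }
  fit <- switch(model,
    mean = list(params = list(c = mean(y)), converged = TRUE),
    linear = {
      co <- stats::coef(stats::lm(y ~ D))
      list(params = list(a = unname(co[1]), b = unname(co[2])),
           converged = TRUE)
    },
    power_mult = {
      pos <- y > 0
      if (sum(pos) < p_model + 2) {
        list(params = list(a = NA_real_, b = NA_real_), converged = FALSE)
      } else {
        co <- stats::coef(stats::lm(log(y[pos]) ~ log(D[pos])))
        list(params = list(a = exp(unname(co[1])), b = unname(co[2])),
             converged = TRUE)
      }
    },
    fit_growth_nls(model, D, y))
  rss <- if (fit$converged) {
    sum((y - evaluate_model(model, fit$params, D))^2)
  } else {
    Inf
  }
  bic <- if (fit$converged) n * log(rss / n) + (p_model + 1) * log(n)
         else Inf
  structure(list(model = model, params = fit$params, n = n,
                 rss = rss, bic = bic, converged = fit$converged),
            class = "growth_model_fit")
}

# multi-start least squares on transformed parameters
fit_growth_nls <- function(model, D, y) {
  to_p <- switch(model,
    power = function(th) list(a = exp(th[1]), b = th[2]),
    gompertz = function(th) list(a = exp(th[1]), K = exp(th[2])),
    verhulst = function(th) list(r = exp(th[1]), K = exp(th[2])),
    canham = function(th) list(gmax = exp(th[1]), Dopt = exp(th[2]),
                               Sd = exp(th[3])),
    lognormal = function(th) list(A = exp(th[1]), m = th[2],
                                  w = exp(th[3])))
  obj <- function(th) {
    r <- y - evaluate_model(model, to_p(th), D)
    v <- sum(r * r)
    if (!is.finite(v)) 1e12 else v
  }
  base <- growth_start(model, D, y)
  starts <- c(list(base),
              lapply(c(-0.5, 0.5, -1, 1), function(f) base + f * 0.3))
  best <- NULL
  for (st in starts) {
    o <- tryCatch(stats::optim(st, obj, method = "Nelder-Mead",
                  control = list(maxit = 2000, reltol = 1e-12)),
                  error = function(e) NULL)
    if (is.null(o)) next
    o2 <- tryCatch(stats::optim(o$par, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)),
                   error = function(e) NULL)
    if (!is.null(o2) && o2$value < o$value) o <- o2
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best) || !is.finite(best$value)) {
    return(list(params = to_p(base), converged = FALSE))
  }
  list(params = to_p(best$par), converged = TRUE)
}

# moment / smoother-based starting values on the transformed scale
growth_start <- function(model, D, y) {
  Dmax <- max(D)
  ys <- pmax(y, 1e-6)
  loglog <- stats::coef(stats::lm(log(ys) ~ log(D)))
  sm <- suppressWarnings(stats::lowess(D, y, f = 0.4))
  Dopt0 <- max(sm$x[which.max(sm$y)], 1e-3)
  g0 <- max(max(sm$y), 1e-4)
  switch(model,
    power = c(loglog[[1]], loglog[[2]]),
    gompertz = {
      K0 <- 1.5 * Dmax   # asymptote above the observed range at start
      c(log(mean(ys / (D * pmax(log(K0 / D), 0.05)))), log(K0))
    },
    verhulst = {
      K0 <- 1.5 * Dmax
      c(log(mean(ys / (D * pmax(1 - D / K0, 0.05)))), log(K0))
    },
    canham = c(log(g0), log(Dopt0), 0),
    lognormal = {
      w0 <- 1
      m0 <- log(Dopt0) + w0^2
      c(log(g0 * w0 * sqrt(2 * pi) * exp(m0 - w0^2 / 2)), m0, log(w0))
    })
}

#' Fit the full eight-model suite
#' @inheritParams fit_growth_model
#' @return named list of \code{growth_model_fit} objects.
#' @export
fit_all_growth_models <- function(data, dawkins = NULL) {
  fits <- lapply(growth_model_names(), fit_growth_model, data = data,
                 dawkins = dawkins)
  names(fits) <- growth_model_names()
  fits
}

#' Select the best growth model by BIC
#'
#' Argmin of BIC over converged fits; exact ties are broken toward the
#' model with fewer parameters, then alphabetically.
#'
#' @param fits a list of \code{growth_model_fit} objects (e.g. from
#'   [fit_all_growth_models()]), or a named numeric vector of BIC values.
#' @return the selected model name.
#' @examples
#' select_best_model(c(canham = 196.6, mean = 210.0)) # "canham"
#' select_best_model(c(mean = -99.1, canham = -50))   # "mean"
#' @export
select_best_model <- function(fits) {
  if (is.numeric(fits)) {
    stopifnot(!is.null(names(fits)))
    bic <- fits
    conv <- is.finite(bic)
  } else {
    bic <- vapply(fits, function(f) f$bic, numeric(1))
    conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
    if (is.null(names(bic))) {
      names(bic) <- vapply(fits, function(f) f$model, character(1))
    }
  }
  if (!any(conv)) stop("no converged fit to select from", call. = FALSE)
  bic <- bic[conv]
  np <- vapply(names(bic),
               function(nm) length(growth_model_params(nm)), numeric(1))
  ord <- order(bic, np, names(bic))
  names(bic)[ord[1]]
}

#' @export
print.growth_model_fit <- function(x, ...) {
  cat(sprintf("Growth model '%s' (n = %d)%s\n", x$model, x$n,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (x$converged) {
    cat("  params:", paste(names(x$params), signif(unlist(x$params), 5),
                           sep = " = ", collapse = ", "), "\n")
    cat(sprintf("  RSS = %.5g, BIC = %.2f\n", x$rss, x$bic))
  }
  invisible(x)
}
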