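#' Diameter-growth laws
#'
#' A growth law relates stem diameter (dbh, cm) to the expected annual
#' diameter increment (cm/y). Eight laws are supported, the classical suite
#' used to describe ontogenic variation in tropical tree growth:
#'
#' \describe{
#'   \item{mean}{\eqn{g(D) = c} — size-independent mean increment.}
#'   \item{linear}{\eqn{g(D) = a + bD}.}
#'   \item{power}{\eqn{g(D) = a D^b}, additive Gaussian error when fitted.}
#'   \item{power_mult}{same form as \code{power}, fitted with multiplicative
#'     (log-scale) error.}
#'   \item{gompertz}{\eqn{g(D) = a D \ln(K/D)}, positive for \eqn{D < K}.}
#'   \item{verhulst}{logistic, \eqn{g(D) = r D (1 - D/K)}.}
#'   \item{canham}{\eqn{g(D) = g_{max} \exp(-\tfrac12 (\ln(D/D_{opt})/S_d)^2)},
#'     a lognormal-shaped bump peaking at \eqn{D_{opt}}.}
#'   \item{lognormal}{\eqn{g(D) = \frac{A}{D w \sqrt{2\pi}}
#'     \exp(-(\ln D - m)^2 / (2 w^2))}; differs from \code{canham} by the
#'     \eqn{1/D} prefactor.}
#' }
#'
#' @param model one of \code{"mean"}, \code{"linear"}, \code{"power"},
#'   \code{"power_mult"}, \code{"gompertz"}, \code{"verhulst"},
#'   \code{"canham"}, \code{"lognormal"}.
#' @param params named numeric vector or list of the law's parameters
#'   (names as in the formulas above).
#' @param noise_sd standard deviation (cm/y) of the annual increment noise
#'   used by the simulators; must be >= 0.
#' @return an object of class \code{growth_law}.
#' @examples
#' law <- growth_law("verhulst", c(r = 0.02, K = 100))
#' growth_rate(law, 50) # 0.02 * 50 * (1 - 0.5) = 0.5
#' @export
growth_law <- function(model, params, noise_sd = 0) {
  model <- match.arg(model, growth_model_names())
  params <- as.list(params)
  need <- growth_model_params(model)
  if (!all(need %in% names(params))) {
    stop(sprintf("growth law '%s' needs parameters: %s", model,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  params <- lapply(params[need], as.numeric)
  if (any(!vapply(params, is.finite, logical(1)))) {
    stop("growth-law parameters must be finite", call. = FALSE)
  }
  check_growth_params(model, params)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("noise_sd must be a single non-negative number", call. = FALSE)
  }
  structure(list(model = model, params = params, noise_sd = noise_sd),
            class = "growth_law")
}

#' @export
print.growth_law <- function(x, ...) {
  cat("Growth law:", x$model, "\n")
  cat("  params:", paste(names(x$params), signif(unlist(x$params), 5),
                         sep = " = ", collapse = ", "), "\n")
  cat("  noise sd (cm/y):", x$noise_sd, "\n")
  invisible(x)
}

#' @rdname growth_law
#' @export
growth_model_names <- function() {
  c("mean", "linear", "power", "power_mult", "gompertz", "verhulst",
    "canham", "lognormal")
}

#' Parameter names of a growth model
#' @param model model name, see [growth_law()].
#' @return character vector of parameter names.
#' @export
growth_model_params <- function(model) {
  switch(match.arg(model, growth_model_names()),
    mean       = "c",
    linear     = c("a", "b"),
    power      = c("a", "b"),
    power_mult = c("a", "b"),
    gompertz   = c("a", "K"),
    verhulst   = c("r", "K"),
    canham     = c("gmax", "Dopt", "Sd"),
    lognormal  = c("A", "m", "w"))
}

# positivity constraints; scale/rate parameters must be > 0
check_growth_params <- function(model, p) {
  pos <- switch(model,
    mean = "c", linear = character(0), power = "a", power_mult = "a",
    gompertz = c("a", "K"), verhulst = c("r", "K"),
    canham = c("gmax", "Dopt", "Sd"), lognormal = c("A", "w"))
  bad <- pos[vapply(pos, function(nm) p[[nm]] <= 0, logical(1))]
  if (length(bad)) {
    stop(sprintf("growth law '%s': parameter(s) %s must be > 0", model,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Evaluate a growth model at given diameters
#'
#' Returns the expected annual diameter increment (cm/y) of the named model
#' at diameters \code{dbh}.
#'
#' @param model model name (see [growth_law()]), or a \code{growth_law}
#'   object (in which case \code{params} is ignored).
#' @param params named parameters of the model.
#' @param dbh diameters (cm), strictly positive.
#' @return numeric vector of growth rates, same length as \code{dbh}.
#' @examples
#' evaluate_model("canham", c(gmax = 0.6, Dopt = 60, Sd = 1), 60) # 0.6
#' @export
evaluate_model <- function(model, params = NULL, dbh) {
  if (inherits(model, "growth_law")) {
    params <- model$params
    model <- model$model
  }
  model <- match.arg(model, growth_model_names())
  p <- as.list(params)
  if (any(dbh <= 0)) stop("dbh must be strictly positive", call. = FALSE)
  D <- as.numeric(dbh)
  switch(model,
    mean       = rep(p$c, length(D)),
    linear     = p$a + p$b * D,
    power      = p$a * D^p$b,
    power_mult = p$a * D^p$b,
    gompertz   = p$a * D * log(p$K / D),
    verhulst   = p$r * D * (1 - D / p$K),
    canham     = p$gmax * exp(-0.5 * (log(D / p$Dopt) / p$Sd)^2),
    lognormal  = p$A / (D * p$w * sqrt(2 * pi)) *
                   exp(-(log(D) - p$m)^2 / (2 * p$w^2)))
}

#' @rdname evaluate_model
#' @param law a \code{growth_law} object.
#' @export
growth_rate <- function(law, dbh) {
  stopifnot(inherits(law, "growth_law"))
  evaluate_model(law$model, law$params, dbh)
}
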