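# FWHM of a Gaussian = fwhm_factor * sigma
fwhm_factor <- function() 2 * sqrt(2 * log(2))

#' Convert between Gaussian sigma and full width at half maximum
#'
#' For a Gaussian peak the full width at half maximum (FWHM) is
#' `2 * sqrt(2 * log(2)) * sigma` (~2.3548 sigma).
#'
#' @param sigma,fwhm Gaussian standard deviation / FWHM, same units.
#' @return Numeric vector.
#' @export
sigma_to_fwhm <- function(sigma) fwhm_factor() * sigma

#' @rdname sigma_to_fwhm
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / fwhm_factor()

# Deterministic child seeds from one master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Evaluate an expression with a local RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Standard error of the mean, NA-aware
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  sd(x) / sqrt(length(x))
}

assert_profile <- function(profile, min_points = 2) {
  if (!is.data.frame(profile) || !all(c("x_um", "intensity") %in% names(profile))) {
    abort("`profile` must be a data frame with columns `x_um` and `intensity`.")
  }
  ok <- is.finite(profile$x_um) & is.finite(profile$intensity)
  profile <- profile[ok, , drop = FALSE]
  if (nrow(profile) < min_points) {
    abort(sprintf("profile needs at least %d finite points (has %d).", min_points, nrow(profile)))
  }
  profile[order(profile$x_um), , drop = FALSE]
}

# Levenberg-Marquardt least squares with analytic Jacobian.
#
# `eval_fun` is a deriv()-generated evaluator taking the parameters (in the
# order of `start`) followed by the predictor vector `x`, returning fitted
# values with a "gradient" attribute. Returns NULL on failure; otherwise a
# list with named `par`, `se`, `vcov`, `deviance`, `converged`.
try_ls <- function(eval_fun, start, lower, upper, x, y, weights = NULL) {
  sw <- if (is.null(weights)) rep(1, length(y)) else sqrt(weights)
  pn <- names(start)
  fn <- function(p) {
    v <- do.call(eval_fun, c(as.list(p), list(x)))
    sw * (y - as.numeric(v))
  }
  jac <- function(p) {
    v <- do.call(eval_fun, c(as.list(p), list(x)))
    -sw * attr(v, "gradient")
  }
  res <- try(suppressWarnings(minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper, fn = fn, jac = jac,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)
  )), silent = TRUE)
  if (inherits(res, "try-error")) return(NULL)
  par <- setNames(as.numeric(res$par), pn)
  if (any(!is.finite(par))) return(NULL)
  n <- length(y); p <- length(par)
  dev <- sum(fn(par)^2)
  J <- jac(par)
  V <- try({
    s2 <- dev / max(n - p, 1)
    Vi <- solve(crossprod(J)) * s2
    dimnames(Vi) <- list(pn, pn)
    Vi
  }, silent = TRUE)
  if (inherits(V, "try-error")) {
    V <- matrix(NA_real_, p, p, dimnames = list(pn, pn))
  }
  list(par = par, se = setNames(sqrt(pmax(diag(V), 0)), pn), vcov = V,
       deviance = dev, converged = res$info %in% 1:4)
}
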