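#' Exponential calibration models
#'
#' The calibration relations all take one of two three-parameter forms:
#' growth `y = a * exp(x / b) + c` and decay `y = a * exp(-x / b) + c`
#' (decay requires `b > 0`). These describe, respectively, resealing time
#' versus laser fluence, loading efficiency versus resealing time, and
#' loading efficiency versus tracer molecular weight.
#'
#' @param form `"growth"` or `"decay"`.
#' @param a Amplitude (units of y).
#' @param b Rate constant (units of x); non-zero, and positive for decay.
#' @param c Offset (units of y).
#' @return Object of class `exp_model`.
#' @export
exp_model <- function(form = c("growth", "decay"), a, b, c) {
  form <- match.arg(form)
  stopifnot(is.finite(a), is.finite(b), is.finite(c), b != 0)
  if (form == "decay" && b <= 0) stop("decay form requires b > 0")
  structure(list(form = form, a = a, b = b, c = c), class = "exp_model")
}

#' @rdname exp_model
#' @param object An `exp_model` or `exp_fit`.
#' @param x Predictor values.
#' @param ... Unused.
#' @export
predict.exp_model <- function(object, x, ...) {
  sgn <- if (object$form == "growth") 1 else -1
  object$a * exp(sgn * x / object$b) + object$c
}

#' @rdname exp_model
#' @export
predict.exp_fit <- function(object, x, ...) predict(object$model, x)

# Given b (already signed: exponent is x/b for growth, -x/b encoded by the
# caller flipping the sign), solve the conditionally-linear (c, a) by OLS
# and return the profiled residual sum of squares.
profile_linear <- function(x, y, b_signed) {
  e <- exp(x / b_signed)
  if (any(!is.finite(e))) return(NULL)
  X <- cbind(1, e)
  co <- tryCatch(qr.solve(X, y), error = function(e) NULL)
  if (is.null(co) || any(!is.finite(co))) return(NULL)
  co <- unname(co)
  list(c = co[1], a = co[2], ss = sum((y - X %*% co)^2))
}

fit_exp <- function(x, y, form, starts = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 4, all(is.finite(x)),
            all(is.finite(y)))
  if (diff(range(x)) == 0) stop("x values must not all be equal")
  sgn <- if (form == "growth") 1 else -1
  n <- length(x)

  # degenerate constant response: a = 0 family, c = mean(y)
  if (diff(range(y)) == 0) {
    model <- exp_model(form, a = 0, b = diff(range(x)), c = mean(y))
    return(structure(list(model = model, r_squared = NA_real_,
                          residuals = y - mean(y), fitted = rep(mean(y), n),
                          n_points = n, converged = TRUE, degenerate = TRUE,
                          start_values = NULL, sum_sq = 0),
                     class = "exp_fit"))
  }

  xr <- diff(range(x))
  if (is.null(starts)) {
    bgrid <- exp(seq(log(0.1 * xr), log(10 * xr), length.out = 20))
    # the growth family admits saturating curves via negative rate
    # constants, so the multi-start grid covers both signs
    if (form == "growth") bgrid <- c(bgrid, -bgrid)
    cand <- list()
    for (b0 in bgrid) {
      pl <- profile_linear(x, y, sgn * b0)
      if (!is.null(pl)) cand[[length(cand) + 1L]] <- list(a = pl$a, b = b0, c = pl$c, ss = pl$ss)
    }
    if (length(cand) == 0) stop("no usable starting values on the b grid")
    cand <- cand[order(vapply(cand, `[[`, 0, "ss"))]
    starts_list <- cand[seq_len(min(5, length(cand)))]
  } else {
    starts_list <- list(list(a = starts[["a"]], b = starts[["b"]], c = starts[["c"]],
                             ss = Inf))
  }

  best <- NULL; best_ss <- Inf; converged <- FALSE
  dat <- data.frame(x = x, y = y)
  for (st in starts_list) {
    fml <- if (form == "growth") y ~ a * exp(x / b) + c else y ~ a * exp(-x / b) + c
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, data = dat,
                        start = list(a = st$a, b = st$b, c = st$c),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      co <- coef(fit)
      ok <- all(is.finite(co)) && co["b"] != 0 && (form != "decay" || co["b"] > 0)
      if (ok) {
        ss <- sum((y - predict(fit))^2)
        if (is.finite(ss) && ss < best_ss) {
          best_ss <- ss
          best <- list(a = unname(co["a"]), b = unname(co["b"]), c = unname(co["c"]))
          converged <- TRUE
        }
      }
    }
  }
  if (!converged) {            # fall back to the best profiled grid point
    st <- starts_list[[1]]
    best <- list(a = st$a, b = st$b, c = st$c)
    best_ss <- st$ss
  }
  model <- exp_model(form, best$a, best$b, best$c)
  fitted <- predict(model, x)
  structure(list(model = model,
                 r_squared = r_squared(y, fitted),
                 residuals = y - fitted, fitted = fitted, n_points = n,
                 converged = converged, degenerate = FALSE,
                 start_values = starts_list[[1]][c("a", "b", "c")],
                 sum_sq = best_ss),
            class = "exp_fit")
}

#' Fit the exponential calibration forms by nonlinear least squares
#'
#' Levenberg-Marquardt least squares with deterministic multi-start: the
#' rate constant is profiled on a log-spaced grid spanning 0.1x to 10x the
#' x-range (both signs for the growth form, whose family then also covers
#' saturating curves), the conditionally linear amplitude and offset are
#' solved exactly at each grid point, and the best few starts are refined.
#' The procedure involves no randomness.
#'
#' @param x,y Data vectors (at least 4 points; x not all equal).
#' @param starts Optional named list/vector `a`, `b`, `c` to use as the
#'   single starting point.
#' @return Object of class `exp_fit`: `model` ([exp_model()]), `r_squared`,
#'   `residuals`, `fitted`, `n_points`, `converged`, `degenerate`,
#'   `start_values`, `sum_sq`.
#' @export
fit_exp_growth <- function(x, y, starts = NULL) fit_exp(x, y, "growth", starts)

#' @rdname fit_exp_growth
#' @export
fit_exp_decay <- function(x, y, starts = NULL) fit_exp(x, y, "decay", starts)

#' @export
print.exp_fit <- function(x, ...) {
  m <- x$model
  op <- if (m$form == "growth") "" else "-"
  cat(sprintf("Exponential %s fit: y = %.6g * exp(%sx / %.6g) + %.6g\n",
              m$form, m$a, op, m$b, m$c))
  cat(sprintf("  n = %d, R^2 = %s, converged = %s\n", x$n_points,
              format(x$r_squared), x$converged))
  invisible(x)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` with `SS_tot` taken about the mean of the
#' observations.
#'
#' @param y_obs Observed values.
#' @param y_pred Predicted values, same length (>= 2).
#' @return R-squared (can be negative for fits worse than the mean).
#' @export
r_squared <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 2)
  ss_tot <- sum((y_obs - mean(y_obs))^2)
  if (ss_tot == 0) stop("total sum of squares is zero; R^2 undefined")
  1 - sum((y_obs - y_pred)^2) / ss_tot
}

#' Predict resealing time from laser fluence
#'
#' Evaluates a fluence-to-resealing-time growth calibration; a non-positive
#' prediction is unphysical and raises an error.
#'
#' @param model An `exp_model` (or `exp_fit`) fitted with fluence as x and
#'   resealing time (s) as y.
#' @param fluence Laser fluence in J/cm^2.
#' @return Resealing time(s) in seconds.
#' @export
fluence_to_resealing <- function(model, fluence) {
  if (inherits(model, "exp_fit")) model <- model$model
  stopifnot(inherits(model, "exp_model"))
  y <- predict(model, fluence)
  if (any(y <= 0))
    stop(sprintf("predicted resealing time is non-positive at fluence %s",
                 paste(fluence[y <= 0], collapse = ", ")))
  y
}

#' Concordance of simulated and measured loading efficiencies
#'
#' Ordinary least squares of the measured values on the simulated ones,
#' summarising how well the Monte Carlo model predicts experiment.
#'
#' @param sim_values Simulated loading efficiencies.
#' @param exp_values Paired measured loading efficiencies (length >= 3).
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
concordance <- function(sim_values, exp_values) {
  stopifnot(length(sim_values) == length(exp_values), length(sim_values) >= 3)
  if (sd(sim_values) == 0 || sd(exp_values) == 0)
    stop("degenerate variance: concordance undefined")
  fit <- lm(exp_values ~ sim_values)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r_squared(exp_values, fitted(fit)),
       n = length(sim_values))
}
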