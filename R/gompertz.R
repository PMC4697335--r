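#' Modified Gompertz growth value
#'
#' Zwietering's reparameterized Gompertz function on the log-growth scale
#' `y = ln(OD/OD0)`:
#' `y(t) = A * exp(-exp(mu_max * e / A * (lambda - t) + 1))`,
#' with asymptote `A` (dimensionless), maximum specific growth rate `mu_max`
#' (per hour) and lag time `lambda` (hours).
#'
#' @param t Time in hours.
#' @param A Asymptotic `ln(OD/OD0)` (> 0).
#' @param mu_max Maximum specific growth rate, h^-1 (> 0).
#' @param lambda Lag time, h (>= 0).
#' @return Numeric vector of `ln(OD/OD0)` values.
#' @examples
#' gompertz_curve(0:48, A = 2, mu_max = 0.1, lambda = 5)
#' @export
gompertz_curve <- function(t, A, mu_max, lambda) {
  A * exp(-exp(mu_max * exp(1) / A * (lambda - t) + 1))
}

#' Fit the modified Gompertz model to an OD600 time course
#'
#' Fits `y(t) = A exp(-exp(mu_max e / A (lambda - t) + 1))` to
#' `y = ln(od / od0)` by nonlinear least squares (Levenberg-Marquardt with
#' box constraints), with data-driven starting values: `A0 = max(y)`,
#' `mu_max0` the steepest finite-difference slope, and `lambda0` the
#' time-axis intercept of the tangent at the steepest point. The generation
#' (doubling) time is `ln(2) / mu_max`.
#'
#' @param curve Data frame with a time column (hours) and an OD column.
#' @param time,od Column names (strings) for time and OD600.
#' @param od0 Baseline OD; defaults to the first OD value. Must be > 0.
#' @return A `gompertz_fit` object with elements `A`, `mu_max`, `lambda`,
#'   `generation_time`, `rss`, `converged`, the fitted `nls` object and the
#'   data. Supports `tidy()`, `glance()`, `predict()` and
#'   [ggplot2::autoplot()].
#' @examples
#' tt <- seq(0, 48, by = 2)
#' od <- 0.02 * exp(gompertz_curve(tt, A = 2, mu_max = 0.1, lambda = 5))
#' fit <- fit_gompertz(data.frame(time_h = tt, od600 = od))
#' glance(fit)
#' @export
fit_gompertz <- function(curve, time = "time_h", od = "od600", od0 = NULL) {
  stopifnot(is.data.frame(curve), time %in% names(curve),
            od %in% names(curve))
  tt <- curve[[time]]
  odv <- curve[[od]]
  if (length(tt) < 5) stop("need at least 5 time points", call. = FALSE)
  if (is.unsorted(tt, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(odv < 0)) stop("negative OD values", call. = FALSE)
  if (is.null(od0)) od0 <- odv[1]
  if (od0 <= 0) stop("od0 must be > 0", call. = FALSE)
  if (any(odv <= 0)) {
    stop("OD values must be > 0 for the log transform", call. = FALSE)
  }
  y <- log(odv / od0)
  if (max(y) < 0.05) {
    stop("no growth detected: max ln(OD/OD0) = ",
         format(max(y), digits = 3), " < 0.05", call. = FALSE)
  }

  # data-driven starts
  A0 <- max(y)
  slopes <- diff(y) / diff(tt)
  k <- which.max(slopes)
  mu0 <- max(slopes[k], 1e-6)
  t_mid <- (tt[k] + tt[k + 1]) / 2
  y_mid <- (y[k] + y[k + 1]) / 2
  lambda0 <- max(t_mid - y_mid / mu0, 0)

  df <- data.frame(t = tt, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-exp(mu * exp(1) / A * (lambda - t) + 1)),
      data = df,
      start = list(A = A0, mu = mu0, lambda = lambda0),
      lower = c(A = 1e-8, mu = 1e-8, lambda = 0),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(
      list(A = NA_real_, mu_max = NA_real_, lambda = NA_real_,
           generation_time = NA_real_, rss = NA_real_, converged = FALSE,
           message = conditionMessage(fit), data = df, od0 = od0, nls = NULL),
      class = "gompertz_fit"
    ))
  }
  cf <- stats::coef(fit)
  structure(
    list(A = unname(cf["A"]), mu_max = unname(cf["mu"]),
         lambda = unname(cf["lambda"]),
         generation_time = generation_time(unname(cf["mu"])),
         rss = sum(stats::resid(fit)^2),
         converged = fit$convInfo$isConv %||% TRUE,
         message = NULL, data = df, od0 = od0, nls = fit),
    class = "gompertz_fit"
  )
}

#' Generation (doubling) time from the maximum specific growth rate
#'
#' @param mu_max Maximum specific growth rate, h^-1 (> 0).
#' @return Generation time in hours, `ln(2) / mu_max`.
#' @examples
#' generation_time(0.1)  # 6.93 h
#' @export
generation_time <- function(mu_max) {
  if (any(mu_max <= 0)) stop("mu_max must be > 0", call. = FALSE)
  log(2) / mu_max
}

#' @export
print.gompertz_fit <- function(x, ...) {
  if (!x$converged && is.na(x$A)) {
    cat("<gompertz_fit> fit failed:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<gompertz_fit> A = %.4g, mu_max = %.4g h^-1, lambda = %.4g h\n",
    x$A, x$mu_max, x$lambda))
  cat(sprintf("  generation time = %.3g h, RSS = %.3g, converged: %s\n",
              x$generation_time, x$rss, x$converged))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gompertz_fit <- function(x, ...) {
  tibble::tibble(
    term = c("A", "mu_max", "lambda"),
    estimate = c(x$A, x$mu_max, x$lambda),
    unit = c("ln(OD/OD0)", "1/h", "h")
  )
}

#' @exportS3Method generics::glance
glance.gompertz_fit <- function(x, ...) {
  tibble::tibble(
    A = x$A, mu_max = x$mu_max, lambda = x$lambda,
    generation_time_h = x$generation_time,
    rss = x$rss, n = nrow(x$data), converged = x$converged
  )
}

#' @export
predict.gompertz_fit <- function(object, newtimes = NULL, ...) {
  t <- if (is.null(newtimes)) object$data$t else newtimes
  y <- gompertz_curve(t, object$A, object$mu_max, object$lambda)
  tibble::tibble(time_h = t, log_growth = y,
                 od600 = object$od0 * exp(y))
}
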