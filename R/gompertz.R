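#' Gompertz growth curve
#'
#' Increasing Gompertz curve `W(t) = A * exp(-B * exp(-k * t))`: `A` is the
#' asymptotic (mature) weight in kg, `B` a unitless shape parameter setting
#' the weight at t = 0 (`A * exp(-B)`), and `k` (per day) the maturation
#' rate. All three must be positive for a monotone increasing curve.
#'
#' @param A,B,k Curve parameters, all > 0.
#' @param t Age in days (vectorized).
#' @return Expected weight in kg.
#' @examples
#' gompertz_predict(100, 4, 0.0148, 0)    # 100 * exp(-4) ~ 1.83 kg
#' gompertz_predict(100, 4, 0.0148, 100)  # ~ 40.2 kg
#' @export
gompertz_predict <- function(A, B, k, t) {
  if (any(A <= 0) || any(B <= 0) || any(k <= 0))
    stop("A, B and k must all be positive")
  A * exp(-B * exp(-k * t))
}

#' Fit a Gompertz growth curve to one animal's weights
#'
#' Nonlinear least squares on all supplied (age, weight) points, optionally
#' supplemented with anchor weights recorded outside the feeding-station
#' window (birth, 14 d, start and end of test). Residuals are returned only
#' for the points inside `residual_window` (the daily AFS records), so
#' deviation traits are comparable between animals with and without anchors.
#'
#' Starting values come from a log-log linearization
#' (`log(-log(w / A0))` regressed on age with `A0` just above the maximum
#' observed weight); fitting uses `nls` (port algorithm, positivity bounds)
#' and falls back to Levenberg-Marquardt (`minpack.lm::nlsLM`) when that
#' fails. Non-convergence is flagged, not raised, so downstream traits can
#' be set missing.
#'
#' @param age,weight Numeric vectors of AFS ages (days) and weights (kg);
#'   missing weights are dropped.
#' @param anchor_age,anchor_weight Optional extra points used for fitting
#'   only.
#' @param residual_window Age range over which residuals are computed
#'   (default `c(95, 155)`).
#' @param max_iter Maximum number of optimizer iterations (default 200).
#' @param tol Convergence tolerance on the relative offset / parameter
#'   change (default 1e-8; the RSS-based stopping criterion uses `tol^2`
#'   scaling internally in `nls`).
#' @return An object of class `gompertz_fit`: list with `A`, `B`, `k`,
#'   `converged`, `n_iter`, `rss`, `residuals` (named by age) and
#'   `fitted_age`.
#' @export
fit_gompertz <- function(age, weight, anchor_age = NULL, anchor_weight = NULL,
                         residual_window = c(95, 155), max_iter = 200L,
                         tol = 1e-8) {
  keep <- is.finite(age) & is.finite(weight)
  age <- age[keep]; weight <- weight[keep]
  t_all <- c(age, anchor_age)
  w_all <- c(weight, anchor_weight)
  ok <- is.finite(t_all) & is.finite(w_all) & w_all > 0
  t_all <- t_all[ok]; w_all <- w_all[ok]
  if (length(t_all) < 4L || diff(range(t_all)) < 20)
    stop("need at least 4 points spanning at least 20 days")

  fail <- list(A = NA_real_, B = NA_real_, k = NA_real_, converged = FALSE,
               n_iter = 0L, rss = NA_real_,
               residuals = stats::setNames(rep(NA_real_, length(age)), age),
               fitted_age = age)
  class(fail) <- "gompertz_fit"

  # linearized start: log(-log(w/A0)) = log(B) - k t
  A0 <- max(w_all) * 1.15
  z <- suppressWarnings(log(-log(pmin(w_all / A0, 0.999))))
  cf <- stats::coef(stats::lm(z ~ t_all))
  start <- list(A = A0, B = exp(unname(cf[1])),
                k = max(1e-4, -unname(cf[2])))
  dat <- data.frame(t = t_all, w = w_all)
  ctl <- stats::nls.control(maxiter = max_iter, tol = 1e-10,
                            minFactor = 1e-12, warnOnly = FALSE)
  fit <- tryCatch(
    stats::nls(w ~ A * exp(-B * exp(-k * t)), data = dat, start = start,
               algorithm = "port", lower = c(A = 1e-3, B = 1e-6, k = 1e-6),
               control = ctl),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- tryCatch(
      minpack.lm::nlsLM(w ~ A * exp(-B * exp(-k * t)), data = dat,
                        start = start,
                        lower = c(A = 1e-3, B = 1e-6, k = 1e-6),
                        control = minpack.lm::nls.lm.control(
                          maxiter = max_iter, ftol = 1e-12, ptol = tol)),
      error = function(e) NULL)
  if (is.null(fit)) return(fail)

  p <- stats::coef(fit)
  in_win <- age >= residual_window[1] & age <= residual_window[2]
  res <- weight - gompertz_predict(p[["A"]], p[["B"]], p[["k"]], age)
  out <- list(A = p[["A"]], B = p[["B"]], k = p[["k"]], converged = TRUE,
              n_iter = tryCatch(fit$convInfo$finIter,
                                error = function(e) NA_integer_),
              rss = sum(stats::resid(fit)^2),
              residuals = stats::setNames(res[in_win], age[in_win]),
              fitted_age = age[in_win])
  class(out) <- "gompertz_fit"
  out
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat("Gompertz fit: A =", format(x$A, digits = 5),
      "B =", format(x$B, digits = 5),
      "k =", format(x$k, digits = 5),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}
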