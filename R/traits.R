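#' Log residual variance
#'
#' Natural logarithm of the sample (n-1) variance of the daily differences
#' between observed and expected values. The core deviation statistic: a
#' higher value means larger day-to-day deviations from the animal's own
#' expected trajectory, i.e. lower resilience.
#'
#' @param residuals Numeric vector of residuals (>= 2 values).
#' @return `ln(var(residuals))`; `NA` when the variance is zero.
#' @examples
#' residual_lnvar(c(1, -1, 1, -1))  # log(4/3)
#' @export
residual_lnvar <- function(residuals) {
  residuals <- residuals[is.finite(residuals)]
  if (length(residuals) < 2L) stop("need at least 2 residuals")
  v <- stats::var(residuals)
  if (v <= 0) return(NA_real_)
  log(v)
}

#' Skewness of residuals
#'
#' Moment (population) skewness g1 = m3 / m2^(3/2). Asymmetry of the
#' deviations: negative skew indicates occasional sharp drops below the
#' expected trajectory.
#'
#' @param residuals Numeric vector (>= 3 values).
#' @param adjusted Use the adjusted Fisher-Pearson estimator instead of g1.
#' @return Skewness; `NA` for zero variance.
#' @export
residual_skew <- function(residuals, adjusted = FALSE) {
  residuals <- residuals[is.finite(residuals)]
  n <- length(residuals)
  if (n < 3L) stop("need at least 3 residuals")
  m <- mean(residuals)
  m2 <- mean((residuals - m)^2)
  if (m2 <= 0) return(NA_real_)
  g1 <- mean((residuals - m)^3) / m2^1.5
  if (adjusted) g1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  g1
}

#' Lag-one autocorrelation of residuals
#'
#' Mean-centered autocorrelation at lag 1 with the divisor-n convention
#' (as `acf` uses): r1 = sum (x_t - xbar)(x_(t+1) - xbar) / sum (x_t - xbar)^2.
#' When ages are supplied, only records separated by the series' sampling
#' interval pair up in the numerator: for daily data that interval is 1 d,
#' so a QC-created gap breaks the pair rather than treating values days
#' apart as adjacent; for a uniformly thinned series (one record every k
#' days) consecutive records pair at lag k. The interval defaults to the
#' modal spacing of the supplied ages and can be fixed with `gap`.
#'
#' @param residuals Numeric residual vector.
#' @param age Optional ages (days) aligned with `residuals`; default assumes
#'   consecutive days.
#' @param gap Spacing (days) at which records count as adjacent; `NULL`
#'   uses the modal spacing.
#' @return Lag-1 autocorrelation; `NA` for zero variance.
#' @examples
#' residual_lag1(c(1, -1, 1, -1))  # -0.75
#' residual_lag1(1:4)              # 0.25
#' @export
residual_lag1 <- function(residuals, age = seq_along(residuals),
                          gap = NULL) {
  keep <- is.finite(residuals) & is.finite(age)
  residuals <- residuals[keep]; age <- age[keep]
  o <- order(age)
  residuals <- residuals[o]; age <- age[o]
  n <- length(residuals)
  if (n < 2L) stop("need at least 2 residuals")
  x <- residuals - mean(residuals)
  den <- sum(x^2)
  if (den <= 0) return(NA_real_)
  dd <- diff(age)
  if (is.null(gap)) {
    tb <- table(dd)
    gap <- as.numeric(names(tb)[which.max(tb)])
  }
  adj <- which(dd == gap)
  sum(x[adj] * x[adj + 1]) / den
}

#' Log mean squared error of a linear fit on age
#'
#' Ordinary least squares of the value on age for one animal; MSE = RSS / n
#' (the maximum-likelihood residual variance, so lnMSE is comparable to
#' lnvar). Applied to weight, feed intake, visit duration and visit count
#' series alike.
#'
#' @param age,value Numeric vectors (>= 3 complete pairs).
#' @param ml Divide RSS by n (default). `FALSE` uses RSS / (n - 2).
#' @return `ln(MSE)`; `NA` for a perfect fit (RSS = 0).
#' @examples
#' lnmse_linear(c(0, 1, 2), c(0, 1, 0))  # log(2/9)
#' @export
lnmse_linear <- function(age, value, ml = TRUE) {
  keep <- is.finite(age) & is.finite(value)
  age <- age[keep]; value <- value[keep]
  n <- length(age)
  if (n < 3L) stop("need at least 3 points")
  fit <- stats::lm.fit(cbind(1, age), value)
  rss <- sum(fit$residuals^2)
  # a numerically perfect fit has no residual variance to take a log of
  if (rss <= 1e-18 * max(sum(value^2), 1)) return(NA_real_)
  log(rss / if (ml) n else (n - 2))
}

#' Standardize weights by age across the population
#'
#' For each integer age, weights are centered and scaled across animals
#' (sample SD), giving z-scores with mean 0 and SD 1 per day. This uses the
#' population, rather than the animal's own fitted curve, as the reference
#' trajectory and so avoids the circularity of curve-based expectations.
#' Ages observed on fewer than two animals are excluded for everyone.
#'
#' @param records Post-QC records with `animal_id`, `age_d`, `weight_kg`.
#' @return `records` with a `weight_z` column added (NA where excluded).
#' @export
standardize_weights <- function(records) {
  w <- records$weight_kg
  age <- records$age_d
  mu <- tapply(w, age, mean, na.rm = TRUE)
  sdv <- tapply(w, age, stats::sd, na.rm = TRUE)
  nn <- tapply(!is.na(w), age, sum)
  key <- as.character(age)
  z <- (w - mu[key]) / sdv[key]
  z[nn[key] < 2 | !is.finite(z)] <- NA_real_
  records$weight_z <- as.numeric(z)
  records
}

#' Per-animal log variance of standardized weights
#'
#' @param records Output of [standardize_weights()] (or raw post-QC records,
#'   which are standardized first).
#' @return Named vector of `ln(var(z))` per animal; `NA` where the variance
#'   is zero or fewer than 2 standardized values exist.
#' @export
standardized_lnvar <- function(records) {
  if (is.null(records$weight_z)) records <- standardize_weights(records)
  vapply(split(records$weight_z, records$animal_id), function(z) {
    z <- z[is.finite(z)]
    if (length(z) < 2L) return(NA_real_)
    v <- stats::var(z)
    if (v <= 0) NA_real_ else log(v)
  }, 0)
}

#' Trajectory straightness and mean speed of a weight series
#'
#' The weight series is treated as a trajectory in the (age in d, weight in
#' kg) plane. Path length is the sum of Euclidean segment lengths between
#' consecutive recorded points; straightness is the start-to-end Euclidean
#' distance divided by the path length (1 = perfectly straight, smaller
#' values = more deviations); mean speed is the path length divided by the
#' age span (>= 1 for daily records, inflated by weight deviations).
#'
#' @param age,weight Numeric vectors; ages must span a positive range.
#' @return List with `straightness` and `mean_speed`.
#' @examples
#' trajectory_metrics(c(0, 1, 2), c(0, 1, 0))
#' @export
trajectory_metrics <- function(age, weight) {
  keep <- is.finite(age) & is.finite(weight)
  age <- age[keep]; weight <- weight[keep]
  o <- order(age)
  age <- age[o]; weight <- weight[o]
  if (length(age) < 2L) stop("need at least 2 points")
  span <- age[length(age)] - age[1]
  if (span <= 0) stop("zero age span")
  path <- sum(sqrt(diff(age)^2 + diff(weight)^2))
  euclid <- sqrt(span^2 + (weight[length(weight)] - weight[1])^2)
  list(straightness = euclid / path, mean_speed = path / span)
}

#' Off-feed days from pooled quantile regression
#'
#' Fits a linear quantile regression (check loss, level `tau`) of the value
#' on age jointly over all animal-days, then counts per animal the days with
#' an observed value strictly below the fitted line. Applied to feed intake
#' (`QR_FI`) and visit duration (`QR_dur`): days in the lowest 5% quantile
#' are interpreted as off-feed days.
#'
#' @param records Data frame with `animal_id`, `age_d` and the value column.
#' @param value Name of the value column (e.g. `"fi_g_per_d"`).
#' @param tau Quantile level in (0, 1), default 0.05.
#' @return Named integer vector of off-day counts per animal (zero for
#'   animals never below the line). The fitted coefficients are attached as
#'   attribute `"coef"`.
#' @export
quantile_offdays <- function(records, value = "fi_g_per_d", tau = 0.05) {
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)")
  y <- records[[value]]
  keep <- is.finite(y) & is.finite(records$age_d)
  y <- y[keep]; age <- records$age_d[keep]; id <- records$animal_id[keep]
  fit <- withCallingHandlers(
    quantreg::rq(y ~ age, tau = tau,
                 method = if (length(y) > 5000) "fn" else "br"),
    warning = function(w) {
      # ties in discrete-valued series make the vertex solution nonunique;
      # any minimizer yields the same check loss and flag counts
      if (grepl("nonunique", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  below <- y < stats::predict(fit, newdata = data.frame(age = age))
  counts <- tapply(below, id, sum)
  all_ids <- unique(records$animal_id)
  out <- stats::setNames(integer(length(all_ids)), all_ids)
  out[names(counts)] <- as.integer(counts)
  attr(out, "coef") <- stats::coef(fit)
  out
}

#' Production traits for one animal
#'
#' ADG is the weight difference between the last and first recorded AFS day
#' divided by the age span (kg/d); AFI is total feed intake divided by the
#' number of days with a feed record (g/d); FCR is AFI / ADG in g feed per g
#' gain, missing when ADG <= 0.
#'
#' @param age,weight AFS ages (d) and weights (kg); missing weights ignored.
#' @param fi Feed intake (g/d) aligned with `age`; missing values ignored.
#' @return List with `ADG` (kg/d), `AFI` (g/d), `FCR` (g/g).
#' @export
production_traits <- function(age, weight, fi) {
  wk <- is.finite(age) & is.finite(weight)
  if (sum(wk) < 2L) stop("need at least 2 weight records")
  aw <- age[wk]; ww <- weight[wk]
  o <- order(aw)
  span <- aw[o][sum(wk)] - aw[o][1]
  if (span <= 0) stop("zero age span")
  adg <- (ww[o][sum(wk)] - ww[o][1]) / span
  fik <- is.finite(fi)
  afi <- if (any(fik)) sum(fi[fik]) / sum(fik) else NA_real_
  fcr <- if (is.finite(adg) && adg > 0 && is.finite(afi))
    afi / (adg * 1000) else NA_real_
  list(ADG = adg, AFI = afi, FCR = fcr)
}

#' Four-SD outlier filter on derived traits
#'
#' Per trait column, values more than 4 sample standard deviations from the
#' across-animal mean (single pass) are set to missing.
#'
#' @param traits Data frame of per-animal traits; non-numeric columns and
#'   `animal_id` are left untouched.
#' @param sd_mult Threshold multiplier (default 4).
#' @return List with `traits` (filtered) and `n_removed` (named counts).
#' @export
trait_outlier_filter <- function(traits, sd_mult = 4) {
  cols <- setdiff(names(traits)[vapply(traits, is.numeric, TRUE)],
                  "animal_id")
  removed <- stats::setNames(integer(length(cols)), cols)
  for (cl in cols) {
    x <- traits[[cl]]
    m <- mean(x, na.rm = TRUE); s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) next
    bad <- !is.na(x) & abs(x - m) > sd_mult * s
    removed[cl] <- sum(bad)
    traits[[cl]][bad] <- NA_real_
  }
  list(traits = traits, n_removed = removed)
}

#' Derive the full per-animal trait table
#'
#' Runs growth-curve fitting and all trait operations over a post-QC record
#' set: production traits (ADG, AFI, FCR), Gompertz parameters and
#' Gompertz-residual traits (lnvar, skewness, lag-1 autocorrelation),
#' linear-model lnMSE for weight, feed intake, visit duration and visit
#' count, standardized-weight lnvar, trajectory straightness and mean speed,
#' and quantile-regression off-feed day counts.
#'
#' @param records Post-QC records (columns as produced by the simulator /
#'   accepted by [run_qc()]).
#' @param anchors Optional data.frame `animal_id`, `age_d`, `weight_kg` of
#'   anchor weights used for Gompertz fitting only.
#' @param tau Quantile level for the off-feed traits (default 0.05).
#' @param outlier_filter Apply [trait_outlier_filter()] (default TRUE).
#' @param min_points Minimum weight records required per animal for the
#'   curve-based traits (default 4).
#' @return A data.frame with one row per animal and all trait columns;
#'   attribute `"outliers_removed"` carries the 4-SD filter counts.
#' @export
derive_traits <- function(records, anchors = NULL, tau = 0.05,
                          outlier_filter = TRUE, min_points = 4L) {
  ids <- unique(records$animal_id)
  recs <- split(records, records$animal_id)[as.character(ids)]
  lnvar_std <- standardized_lnvar(records)

  one <- function(r) {
    age <- r$age_d; w <- r$weight_kg
    out <- list(ADG = NA_real_, AFI = NA_real_, FCR = NA_real_,
                A = NA_real_, B = NA_real_, k = NA_real_,
                gompertz_converged = FALSE,
                lnvar_weight = NA_real_, skew_weight = NA_real_,
                lag1_weight = NA_real_, lnMSE_weight = NA_real_,
                straightness = NA_real_, mean_speed = NA_real_,
                lnMSE_FI = NA_real_, lnMSE_dur = NA_real_,
                lnMSE_n_visit = NA_real_)
    wk <- is.finite(w)
    if (sum(wk) >= 2L && diff(range(age[wk])) > 0) {
      pt <- tryCatch(production_traits(age, w, r$fi_g_per_d),
                     error = function(e) NULL)
      if (!is.null(pt)) out[c("ADG", "AFI", "FCR")] <- pt
      tm <- tryCatch(trajectory_metrics(age, w), error = function(e) NULL)
      if (!is.null(tm)) {
        out$straightness <- tm$straightness
        out$mean_speed <- tm$mean_speed
      }
    }
    if (sum(wk) >= min_points) {
      aa <- anchors[anchors$animal_id == r$animal_id[1], , drop = FALSE]
      gf <- tryCatch(fit_gompertz(age[wk], w[wk],
                                  anchor_age = aa$age_d,
                                  anchor_weight = aa$weight_kg),
                     error = function(e) NULL)
      if (!is.null(gf) && gf$converged) {
        out$A <- gf$A; out$B <- gf$B; out$k <- gf$k
        out$gompertz_converged <- TRUE
        res <- gf$residuals
        if (length(res) >= 3L) {
          out$lnvar_weight <- residual_lnvar(res)
          out$skew_weight <- residual_skew(res)
          out$lag1_weight <- residual_lag1(res, gf$fitted_age)
        }
      }
    }
    if (sum(wk) >= 3L)
      out$lnMSE_weight <- tryCatch(lnmse_linear(age[wk], w[wk]),
                                   error = function(e) NA_real_)
    series <- c(lnMSE_FI = "fi_g_per_d", lnMSE_dur = "dur_s_per_d",
                lnMSE_n_visit = "nvisits_per_d")
    for (lab in names(series)) {
      vv <- r[[series[[lab]]]]
      if (!is.null(vv) && sum(is.finite(vv)) >= 3L)
        out[[lab]] <- tryCatch(lnmse_linear(age, vv),
                               error = function(e) NA_real_)
    }
    out
  }
  rows <- lapply(recs, one)
  traits <- data.frame(animal_id = ids,
                       do.call(rbind, lapply(rows, function(x)
                         as.data.frame(x, stringsAsFactors = FALSE))))
  rownames(traits) <- NULL
  traits$lnvar_weight_standardized <- unname(lnvar_std[as.character(ids)])
  qr_fi <- if ("fi_g_per_d" %in% names(records))
    quantile_offdays(records, "fi_g_per_d", tau) else NULL
  qr_dur <- if ("dur_s_per_d" %in% names(records))
    quantile_offdays(records, "dur_s_per_d", tau) else NULL
  traits$QR_FI <- if (is.null(qr_fi)) NA_integer_ else
    unname(qr_fi[as.character(ids)])
  traits$QR_dur <- if (is.null(qr_dur)) NA_integer_ else
    unname(qr_dur[as.character(ids)])
  attr(traits, "tau") <- tau

  if (outlier_filter) {
    conv <- traits$gompertz_converged
    fl <- trait_outlier_filter(traits[setdiff(names(traits),
                                              "gompertz_converged")])
    traits <- fl$traits
    traits$gompertz_converged <- conv
    attr(traits, "outliers_removed") <- fl$n_removed
    attr(traits, "tau") <- tau
  }
  traits
}
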