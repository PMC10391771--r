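#' Quality-control configuration
#'
#' Thresholds of the multi-stage QC cascade for automated-feeding-station
#' records. Boundary conventions are literal: "below 10 kg" is strictly
#' below, "more than 3 kg" strictly above, "exceeding mean + 4 SD" strictly
#' above, "gaps larger than ten days" strictly above.
#'
#' @param weight_min_kg Weights strictly below this are set missing (10).
#' @param weight_max_kg,weight_max_age_d Weights strictly above
#'   `weight_max_kg` before `weight_max_age_d` days of age are set missing
#'   (160 kg before 160 d).
#' @param min_weight_records Animals with fewer non-missing weights are
#'   dropped (20).
#' @param rolling_window_d Width in days of the centered rolling-median
#'   window (10).
#' @param rolling_dev_kg Deviation from the rolling median beyond which a
#'   weight is set missing (3 kg, strict).
#' @param rolling_min_obs Minimum observations in a window for the filter to
#'   act (3).
#' @param max_gap_d Animals with an inter-record age gap strictly larger
#'   than this are dropped (10 d).
#' @param feed_sd_mult Feed/behaviour values strictly above
#'   mean + `feed_sd_mult` * SD are set missing (4).
#' @param age_window Records outside this age range are dropped ([95, 155]).
#' @param max_start_age_d Animals whose first record is after this age are
#'   dropped (110).
#' @param min_max_age_d Animals whose last record is before this age are
#'   dropped (120).
#' @param max_missing_frac Animals with more than this fraction of possible
#'   days missing weight or feed are dropped (0.30).
#' @param min_days_with_records Animals with fewer distinct record days are
#'   dropped (20).
#' @param pen_dev_kg Deviation threshold (after removing the animal's median
#'   offset from the pen regression) used to flag records within outlying
#'   pens (4 kg).
#' @param pen_long_run_d Flagged runs of at least this many consecutive days
#'   remove the whole animal (20).
#' @param pen_iqr_mult Pens with RMSE above Q3 + `pen_iqr_mult` * IQR of pen
#'   RMSEs are flagged (1.5).
#' @param rolling_detrend `"quadratic"` (default) applies the rolling-median
#'   rule to residuals from a per-animal second-order polynomial fit of
#'   weight on age, so the growth trend does not masquerade as deviation in
#'   the one-sided windows at the ends of a series; `"none"` applies it to
#'   the raw weights.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(weight_min_kg = 10, weight_max_kg = 160,
                      weight_max_age_d = 160, min_weight_records = 20L,
                      rolling_window_d = 10, rolling_dev_kg = 3,
                      rolling_min_obs = 3L, max_gap_d = 10,
                      feed_sd_mult = 4, age_window = c(95L, 155L),
                      max_start_age_d = 110, min_max_age_d = 120,
                      max_missing_frac = 0.30, min_days_with_records = 20L,
                      pen_dev_kg = 4, pen_long_run_d = 20L,
                      pen_iqr_mult = 1.5,
                      rolling_detrend = c("quadratic", "none")) {
  rolling_detrend <- match.arg(rolling_detrend)
  cfg <- list(weight_min_kg = weight_min_kg, weight_max_kg = weight_max_kg,
              weight_max_age_d = weight_max_age_d,
              min_weight_records = min_weight_records,
              rolling_window_d = rolling_window_d,
              rolling_dev_kg = rolling_dev_kg,
              rolling_min_obs = rolling_min_obs,
              max_gap_d = max_gap_d, feed_sd_mult = feed_sd_mult,
              age_window = as.integer(age_window),
              max_start_age_d = max_start_age_d,
              min_max_age_d = min_max_age_d,
              max_missing_frac = max_missing_frac,
              min_days_with_records = min_days_with_records,
              pen_dev_kg = pen_dev_kg, pen_long_run_d = pen_long_run_d,
              pen_iqr_mult = pen_iqr_mult, rolling_detrend = rolling_detrend)
  stopifnot(all(vapply(cfg[sapply(cfg, is.numeric)], function(x)
    all(x > 0), TRUE)), cfg$age_window[1] < cfg$age_window[2])
  class(cfg) <- "qc_config"
  cfg
}

# Robust per-animal trend residuals: quadratic OLS, then one refit with
# gross outliers (|r - med| > 4 MAD) excluded so spikes and adaptation runs
# do not leverage the trend. Returns residuals and the trim flag.
robust_trend_residuals <- function(age, w) {
  X2 <- cbind(1, age, age^2)
  r <- stats::lm.fit(X2, w)$residuals
  keep <- abs(r - stats::median(r)) <= 4 * stats::mad(r) + 1e-9
  if (sum(keep) >= 4L && !all(keep)) {
    f2 <- stats::lm.fit(X2[keep, , drop = FALSE], w[keep])
    r <- as.numeric(w - X2 %*% f2$coefficients)
    keep <- abs(r - stats::median(r[keep])) <= 4 * stats::mad(r[keep]) + 1e-9
  }
  list(residuals = r, keep = keep)
}

# internal: append removals to a ledger environment
qc_note <- function(env, stage, animal_id, age_d) {
  if (!length(animal_id)) return(invisible())
  env$ledger[[length(env$ledger) + 1L]] <-
    data.frame(animal_id = animal_id, age_d = age_d, stage = stage)
  invisible()
}

#' Gross weight limits
#'
#' Weights strictly below `weight_min_kg`, or strictly above
#' `weight_max_kg` before `weight_max_age_d` days of age, are set missing.
#' Other fields are untouched.
#'
#' @param records AFS records with `weight_kg` and `age_d`.
#' @param cfg A [qc_config()].
#' @param ledger Internal ledger environment (optional).
#' @return Records with offending weights set to `NA`.
#' @export
apply_gross_limits <- function(records, cfg = qc_config(), ledger = NULL) {
  w <- records$weight_kg
  bad <- !is.na(w) &
    (w < cfg$weight_min_kg |
       (w > cfg$weight_max_kg & records$age_d < cfg$weight_max_age_d))
  if (!is.null(ledger))
    qc_note(ledger, "gross_limits", records$animal_id[bad],
            records$age_d[bad])
  records$weight_kg[bad] <- NA_real_
  records
}

#' Minimum weight-record filter
#'
#' Animals with fewer than `min_weight_records` non-missing weights are
#' removed entirely.
#' @inheritParams apply_gross_limits
#' @export
min_record_filter <- function(records, cfg = qc_config(), ledger = NULL) {
  counts <- tapply(!is.na(records$weight_kg), records$animal_id, sum)
  drop_ids <- names(counts)[counts < cfg$min_weight_records]
  bad <- records$animal_id %in% drop_ids
  if (!is.null(ledger))
    qc_note(ledger, "min_records", records$animal_id[bad],
            records$age_d[bad])
  records[!bad, , drop = FALSE]
}

# per-pen RMSE of weight regressed on age
pen_rmse_table <- function(records) {
  keep <- !is.na(records$weight_kg)
  sp <- split(records[keep, c("age_d", "weight_kg")], records$pen[keep])
  rmse <- vapply(sp, function(d) {
    if (nrow(d) < 3L) return(NA_real_)
    f <- stats::lm.fit(cbind(1, d$age_d), d$weight_kg)
    sqrt(mean(f$residuals^2))
  }, 0)
  data.frame(pen = names(sp), n = vapply(sp, nrow, 0L), rmse = rmse,
             row.names = NULL)
}

#' Pen-level RMSE screen
#'
#' Per pen, weight is regressed on age by ordinary least squares and the
#' RMSE computed; pens with RMSE above Q3 + 1.5 IQR of the pen RMSEs are
#' flagged. Within a flagged pen, each record's deviation from the pen
#' regression line -- after subtracting the animal's own median offset from
#' that line -- is compared against `pen_dev_kg`: short flagged stretches
#' (< `pen_long_run_d` consecutive days) are set to missing, while animals
#' with at least `pen_long_run_d` consecutive flagged days are removed.
#'
#' @inheritParams apply_gross_limits
#' @return List with `records`, `flagged_pens` and the pen `rmse` table.
#' @export
pen_rmse_screen <- function(records, cfg = qc_config(), ledger = NULL) {
  tab <- pen_rmse_table(records)
  if (any(is.na(tab$rmse)))
    warning("pens with < 3 records skipped in RMSE screen")
  q <- stats::quantile(tab$rmse, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  thr <- q[2] + cfg$pen_iqr_mult * (q[2] - q[1])
  flagged <- tab$pen[!is.na(tab$rmse) & tab$rmse > thr]

  drop_animals <- character()
  set_missing <- logical(nrow(records))
  for (p in flagged) {
    in_pen <- which(as.character(records$pen) == p)
    d <- records[in_pen, ]
    # judge each animal against its own robust growth trend, so that
    # between-animal differences in level and slope within the pen do not
    # masquerade as erroneous recordings
    for (a in unique(d$animal_id)) {
      ra <- which(d$animal_id == a)
      ra <- ra[order(d$age_d[ra])]
      ok <- !is.na(d$weight_kg[ra])
      if (sum(ok) < 4L) next
      rt <- robust_trend_residuals(d$age_d[ra][ok], d$weight_kg[ra][ok])
      fl <- abs(rt$residuals) > cfg$pen_dev_kg
      if (!any(fl)) next
      ages_fl <- d$age_d[ra][ok][fl]
      br <- cumsum(c(1, diff(ages_fl) != 1))
      if (max(tabulate(br)) >= cfg$pen_long_run_d)
        drop_animals <- c(drop_animals, as.character(a))
      else set_missing[in_pen[ra[ok][fl]]] <- TRUE
    }
  }
  if (!is.null(ledger)) {
    qc_note(ledger, "pen_screen_missing",
            records$animal_id[set_missing], records$age_d[set_missing])
    badrows <- records$animal_id %in% drop_animals
    qc_note(ledger, "pen_screen_animal",
            records$animal_id[badrows], records$age_d[badrows])
  }
  records$weight_kg[set_missing] <- NA_real_
  records <- records[!(records$animal_id %in% drop_animals), , drop = FALSE]
  list(records = records, flagged_pens = flagged, rmse = tab)
}

#' Rolling-median weight filter
#'
#' Per animal, a centered rolling median over an age window of
#' `rolling_window_d` days is computed; weights deviating strictly more than
#' `rolling_dev_kg` from their window median are set missing. Windows with
#' fewer than `rolling_min_obs` observations leave the record unfiltered.
#'
#' By default the rule operates on residuals from a per-animal quadratic
#' fit of weight on age (the rolling median of the detrended series): pigs
#' gain roughly 1 kg/d, so at the ends of a series -- where the centered
#' window is necessarily one-sided -- the raw rolling median lags or leads
#' the trend by up to half a window's growth and would flag clean records.
#' Detrending removes that bias while leaving genuine spikes untouched.
#' Set `rolling_detrend = "none"` for the raw-weight version.
#'
#' @inheritParams apply_gross_limits
#' @export
rolling_median_filter <- function(records, cfg = qc_config(), ledger = NULL) {
  half <- cfg$rolling_window_d / 2
  tol <- cfg$rolling_dev_kg + 1e-9      # strictly "more than", numerically
  bad_all <- logical(nrow(records))
  idx <- split(seq_len(nrow(records)), records$animal_id)
  for (rows in idx) {
    age <- records$age_d[rows]; w <- records$weight_kg[rows]
    o <- order(age)
    age <- age[o]; w <- w[o]; rows <- rows[o]
    obs <- !is.na(w)
    # iterate to a fixpoint: removing a flagged weight changes the trend
    # fit and the window medians, so re-filter until stable (this also
    # makes the whole cascade idempotent)
    for (pass in 1:10) {
      if (sum(obs) < cfg$rolling_min_obs) break
      x <- w
      trim <- obs
      if (cfg$rolling_detrend == "quadratic" && sum(obs) >= 4L) {
        rt <- robust_trend_residuals(age[obs], w[obs])
        x[obs] <- rt$residuals
        trim[obs] <- rt$keep
      }
      new_bad <- logical(length(w))
      for (j in which(obs)) {
        win <- obs & abs(age - age[j]) <= half
        # take the window median over trim-passing values where possible:
        # a multi-day run of corrupted weights must not dominate its own
        # median; if the whole window is contaminated, fall back to the
        # animal's global trimmed median of the detrended series
        wm <- if (sum(win & trim) >= cfg$rolling_min_obs) win & trim
        else if (sum(trim) >= cfg$rolling_min_obs) trim
        else win
        if (sum(wm) < cfg$rolling_min_obs) next
        med <- stats::median(x[wm])
        if (abs(x[j] - med) > tol) new_bad[j] <- TRUE
      }
      if (!any(new_bad)) break
      bad_all[rows[new_bad]] <- TRUE
      obs[new_bad] <- FALSE
      w[new_bad] <- NA_real_
    }
  }
  if (!is.null(ledger))
    qc_note(ledger, "rolling_median", records$animal_id[bad_all],
            records$age_d[bad_all])
  records$weight_kg[bad_all] <- NA_real_
  records
}

#' Gap filter
#'
#' Animals whose maximum age gap between consecutive non-missing weight
#' records is strictly larger than `max_gap_d` are removed.
#' @inheritParams apply_gross_limits
#' @export
gap_filter <- function(records, cfg = qc_config(), ledger = NULL) {
  keep <- !is.na(records$weight_kg)
  gaps <- tapply(records$age_d[keep], records$animal_id[keep], function(a)
    if (length(a) < 2L) 0 else max(diff(sort(a))))
  drop_ids <- names(gaps)[gaps > cfg$max_gap_d]
  bad <- records$animal_id %in% drop_ids
  if (!is.null(ledger))
    qc_note(ledger, "gap", records$animal_id[bad], records$age_d[bad])
  records[!bad, , drop = FALSE]
}

#' Upper limits on feed intake and feeding behaviour
#'
#' For feed intake, visit duration and visit count, values strictly above
#' the dataset mean plus `feed_sd_mult` sample standard deviations are set
#' missing (one pass over the current dataset).
#' @inheritParams apply_gross_limits
#' @export
feed_behaviour_limits <- function(records, cfg = qc_config(), ledger = NULL) {
  for (col in intersect(c("fi_g_per_d", "dur_s_per_d", "nvisits_per_d"),
                        names(records))) {
    x <- records[[col]]
    if (all(is.na(x))) {
      warning("column ", col, " all missing; limit stage skipped")
      next
    }
    thr <- mean(x, na.rm = TRUE) + cfg$feed_sd_mult * stats::sd(x, na.rm = TRUE)
    bad <- !is.na(x) & x > thr
    if (!is.null(ledger))
      qc_note(ledger, paste0("limit_", col), records$animal_id[bad],
              records$age_d[bad])
    records[[col]][bad] <- NA_real_
  }
  records
}

#' Age window and eligibility rules
#'
#' Records outside the age window are dropped; then animals are removed when
#' (i) their first record is after `max_start_age_d`, (ii) their last record
#' is before `min_max_age_d`, (iii) more than `max_missing_frac` of their
#' possible days lack a weight or feed record, or (iv) they have fewer than
#' `min_days_with_records` distinct days with records.
#' @inheritParams apply_gross_limits
#' @export
age_window_and_eligibility <- function(records, cfg = qc_config(),
                                       ledger = NULL) {
  out <- records$age_d < cfg$age_window[1] | records$age_d > cfg$age_window[2]
  if (!is.null(ledger))
    qc_note(ledger, "age_window", records$animal_id[out], records$age_d[out])
  records <- records[!out, , drop = FALSE]

  n_days <- diff(cfg$age_window) + 1L
  drop_ids <- character()
  for (sp in split(records, records$animal_id)) {
    has_rec <- !is.na(sp$weight_kg) | (!is.null(sp$fi_g_per_d) &
                                         !is.na(sp$fi_g_per_d))
    ages <- sp$age_d[has_rec]
    id <- as.character(sp$animal_id[1])
    if (!length(ages)) { drop_ids <- c(drop_ids, id); next }
    n_missing_w <- n_days - sum(!is.na(sp$weight_kg))
    n_missing_f <- if (is.null(sp$fi_g_per_d)) 0 else
      n_days - sum(!is.na(sp$fi_g_per_d))
    if (min(ages) > cfg$max_start_age_d ||
        max(ages) < cfg$min_max_age_d ||
        max(n_missing_w, n_missing_f) / n_days > cfg$max_missing_frac ||
        length(unique(ages)) < cfg$min_days_with_records)
      drop_ids <- c(drop_ids, id)
  }
  bad <- as.character(records$animal_id) %in% drop_ids
  if (!is.null(ledger))
    qc_note(ledger, "eligibility", records$animal_id[bad],
            records$age_d[bad])
  records[!bad, , drop = FALSE]
}

#' Run the full QC cascade
#'
#' Applies the stages in order: gross limits, minimum record count, pen
#' RMSE screen, rolling median filter, gap filter, pen re-screen, feed and
#' behaviour limits, age window and eligibility rules. The cascade is
#' idempotent: running it on its own output changes nothing.
#'
#' @param records Raw AFS records.
#' @param cfg A [qc_config()].
#' @return List with `records` (clean), `report` (per-stage animal / record
#'   counts), `ledger` (one row per removal: animal, age, stage) and
#'   `flagged_pens`.
#' @export
run_qc <- function(records, cfg = qc_config()) {
  if (!nrow(records)) stop("empty input")
  led <- new.env(); led$ledger <- list()
  stages <- character(); n_animals <- integer(); n_records <- integer()
  snap <- function(nm, r) {
    stages <<- c(stages, nm)
    n_animals <<- c(n_animals, length(unique(r$animal_id)))
    n_records <<- c(n_records, sum(!is.na(r$weight_kg)))
  }
  snap("input", records)
  records <- apply_gross_limits(records, cfg, led); snap("gross_limits", records)
  records <- min_record_filter(records, cfg, led); snap("min_records", records)
  ps <- pen_rmse_screen(records, cfg, led)
  records <- ps$records; snap("pen_screen", records)
  records <- rolling_median_filter(records, cfg, led)
  snap("rolling_median", records)
  records <- gap_filter(records, cfg, led); snap("gap", records)
  ps2 <- pen_rmse_screen(records, cfg, led)
  records <- ps2$records; snap("pen_rescreen", records)
  records <- feed_behaviour_limits(records, cfg, led)
  snap("feed_limits", records)
  records <- age_window_and_eligibility(records, cfg, led)
  snap("eligibility", records)

  ledger <- if (length(led$ledger)) do.call(rbind, led$ledger) else
    data.frame(animal_id = integer(), age_d = integer(), stage = character())
  rownames(ledger) <- NULL
  list(records = records,
       report = data.frame(stage = stages, n_animals = n_animals,
                           n_weight_records = n_records),
       ledger = ledger,
       flagged_pens = unique(c(ps$flagged_pens, ps2$flagged_pens)),
       pen_rmse = ps$rmse)
}
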