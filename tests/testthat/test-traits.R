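test_that("Gompertz prediction matches the closed form", {
  expect_equal(gompertz_predict(100, 4, 0.0148, 0), 100 * exp(-4))
  expect_equal(gompertz_predict(100, 4, 0.0148, 100),
               100 * exp(-4 * exp(-1.48)))
  expect_equal(gompertz_predict(100, 4, 0.0148, 100), 40.2297,
               tolerance = 1e-4)
  # asymptote
  expect_equal(gompertz_predict(250, 6, 0.015, 1e6), 250)
  expect_error(gompertz_predict(-1, 4, 0.01, 5), "positive")
})

test_that("Gompertz fitting: round trip, noise, degenerate input", {
  t <- 95:155
  w <- gompertz_predict(250, 6.75, 0.0148, t)
  anchors_t <- c(1, 14, 81, 161)
  gf <- fit_gompertz(t, w, anchor_age = anchors_t,
                     anchor_weight = gompertz_predict(250, 6.75, 0.0148,
                                                      anchors_t))
  expect_true(gf$converged)
  expect_lt(max(abs(c(gf$A / 250, gf$B / 6.75, gf$k / 0.0148) - 1)), 1e-6)
  expect_length(gf$residuals, 61)
  expect_lt(max(abs(gf$residuals)), 1e-8)
  # residual variance under 1-kg noise recovers approximately 1
  set.seed(2)
  vars <- replicate(15, {
    wn <- w + rnorm(61)
    f <- fit_gompertz(t, wn, anchor_age = anchors_t,
                      anchor_weight = gompertz_predict(250, 6.75, 0.0148,
                                                       anchors_t))
    stats::var(f$residuals)
  })
  expect_lt(abs(mean(vars) - 1), 0.3)
  # too few points is a precondition error; constant weight flags only
  expect_error(fit_gompertz(95:97, c(40, 41, 42)), "at least 4")
  flat <- fit_gompertz(seq(95, 155, by = 2), rep(50, 31))
  expect_false(is.na(flat$converged))
})

test_that("log residual variance: hand value, degenerate case, scaling", {
  expect_equal(residual_lnvar(c(1, -1, 1, -1)), log(4 / 3))
  expect_true(is.na(residual_lnvar(rep(0, 10))))
  expect_error(residual_lnvar(1), "at least 2")
  set.seed(1); r <- rnorm(30)
  expect_equal(residual_lnvar(3 * r), residual_lnvar(r) + 2 * log(3))
})

test_that("skewness: symmetry, hand value, antisymmetry", {
  expect_equal(residual_skew(c(1, -1, 1, -1)), 0)
  expect_equal(residual_skew(c(0, 0, 0, 3)), 2.53125 / 1.6875^1.5)
  expect_equal(residual_skew(c(0, 0, 0, 3)), 1.1547, tolerance = 1e-4)
  set.seed(2); r <- rnorm(25)
  expect_equal(residual_skew(-r), -residual_skew(r))
  expect_true(is.na(residual_skew(rep(2, 5))))
})

test_that("lag-1 autocorrelation: hand values, gaps, white noise", {
  expect_equal(residual_lag1(c(1, -1, 1, -1)), -0.75)
  expect_equal(residual_lag1(c(1, 2, 3, 4)), 0.25)
  # matches acf() on a gap-free series
  set.seed(3); r <- rnorm(40)
  expect_equal(residual_lag1(r),
               unname(stats::acf(r, lag.max = 1, plot = FALSE,
                                 demean = TRUE)$acf[2]))
  # a gap breaks the pair: removing the middle day drops those products
  x <- c(5, -3, 4, -2, 6)
  ages <- c(1, 2, 3, 5, 6)           # gap between 3 and 5
  xc <- x - mean(x)
  manual <- (xc[1] * xc[2] + xc[2] * xc[3] + xc[4] * xc[5]) / sum(xc^2)
  expect_equal(residual_lag1(x, ages), manual)
  # iid noise: near zero
  set.seed(4); big <- rnorm(10000)
  expect_lt(abs(residual_lag1(big)), 3 / sqrt(10000))
})

test_that("lnMSE of the linear fit: hand OLS, perfect fit, scaling", {
  expect_equal(lnmse_linear(c(0, 1, 2), c(0, 1, 0)), log(2 / 9))
  expect_equal(lnmse_linear(c(0, 1, 2), c(0, 1, 0)), -1.5041,
               tolerance = 1e-4)
  expect_true(is.na(lnmse_linear(1:10, 2 + 3 * (1:10))))
  set.seed(5)
  age <- 95:155; y <- age + rnorm(61)
  expect_equal(lnmse_linear(age, 4 * y) - lnmse_linear(age, y),
               2 * log(4), tolerance = 1e-9)
  expect_error(lnmse_linear(1:2, 1:2), "at least 3")
})

test_that("weight standardization is exact per age and flags degeneracy", {
  rec <- data.frame(animal_id = rep(1:3, each = 2),
                    age_d = rep(c(100, 101), 3),
                    weight_kg = c(10, 40, 20, 50, 30, 60))
  st <- standardize_weights(rec)
  expect_equal(st$weight_z[st$age_d == 100], c(-1, 0, 1))
  expect_equal(st$weight_z[st$age_d == 101], c(-1, 0, 1))
  # per-day mean 0, SD 1 on a larger set
  sim <- simulate_afs(tiny_cfg(seed = 41), artifacts = FALSE)
  st2 <- standardize_weights(sim$records)
  mu <- tapply(st2$weight_z, st2$age_d, mean)
  sdv <- tapply(st2$weight_z, st2$age_d, sd)
  expect_lt(max(abs(mu)), 1e-12)
  expect_lt(max(abs(sdv - 1)), 1e-12)
  # an animal pinned at the population mean has zero variance: missing
  lv <- standardized_lnvar(st)
  expect_true(all(is.finite(lv) | is.na(lv)))
})

test_that("trajectory metrics: collinearity, toy geometry, identity", {
  # any collinear series has straightness exactly 1
  tm <- trajectory_metrics(95:155, -55 + 1.3 * (95:155))
  expect_equal(tm$straightness, 1)
  tm2 <- trajectory_metrics(c(0, 1, 2), c(0, 1, 0))
  expect_equal(tm2$straightness, 2 / (2 * sqrt(2)))
  expect_equal(tm2$mean_speed, sqrt(2))
  expect_equal(round(tm2$straightness, 5), 0.70711)
  expect_equal(round(tm2$mean_speed, 5), 1.41421)
  # constant weight: pure age displacement
  tm3 <- trajectory_metrics(1:30, rep(80, 30))
  expect_equal(tm3$mean_speed, 1)
  expect_equal(tm3$straightness, 1)
  expect_error(trajectory_metrics(c(5, 5), c(1, 2)), "zero age span")
  # identity: straightness * speed * span = start-end distance; speed >= 1
  set.seed(6)
  for (i in 1:5) {
    ages <- 95:155
    w <- 45 + cumsum(runif(61, 0.5, 1.5)) + rnorm(61)
    m <- trajectory_metrics(ages, w)
    euclid <- sqrt(60^2 + (w[61] - w[1])^2)
    expect_equal(m$straightness * m$mean_speed * 60, euclid)
    expect_gte(m$mean_speed, 1)
    expect_lte(m$straightness, 1)
  }
})

test_that("production traits: arithmetic, FCR direction, degeneracy", {
  pt <- production_traits(c(95, 155), c(46.5, 108.9), c(2300, 2352))
  expect_equal(pt$ADG, (108.9 - 46.5) / 60)
  expect_equal(round(pt$ADG, 3), 1.040)
  expect_equal(pt$AFI, 2326)
  # printed population means: AFI 2326 g/d over ADG 1038 g/d gives ~2.241
  pt2 <- production_traits(c(95, 155), c(46.5, 46.5 + 62.28), c(2326, 2326))
  expect_equal(round(pt2$FCR, 3), 2.241)
  # non-growing animal: FCR undefined
  pt3 <- production_traits(c(95, 155), c(50, 50), c(2000, 2000))
  expect_true(is.na(pt3$FCR))
  expect_error(production_traits(c(95, 95), c(50, 51), 2000), "zero age span")
})

test_that("four-SD trait filter removes only planted outliers", {
  set.seed(7)
  tr <- data.frame(animal_id = 1:200, x = rnorm(200), y = rnorm(200))
  fl0 <- trait_outlier_filter(tr)
  expect_equal(sum(fl0$n_removed), 0L)
  tr$x[1] <- mean(tr$x) + 10 * sd(tr$x)
  fl1 <- trait_outlier_filter(tr)
  expect_equal(unname(fl1$n_removed["x"]), 1L)
  expect_true(is.na(fl1$traits$x[1]))
  # all-equal trait: untouched
  tr$z <- 1
  expect_equal(unname(trait_outlier_filter(tr)$n_removed["z"]), 0L)
})

test_that("off-feed days: QR line level, zero counts, planted off days", {
  set.seed(8)
  n_an <- 300; nd <- 40
  rec <- data.frame(animal_id = rep(seq_len(n_an), each = nd),
                    age_d = rep(96:(95 + nd), n_an))
  rec$fi_g_per_d <- 1500 + 10 * rec$age_d + rnorm(nrow(rec), 0, 250)
  qr <- quantile_offdays(rec, "fi_g_per_d", tau = 0.05)
  frac <- sum(qr) / nrow(rec)
  expect_lt(abs(frac - 0.05), 0.01)
  # an animal lifted far above the line is never flagged
  rec2 <- rec
  rec2$fi_g_per_d[rec2$animal_id == 5] <- 9000
  qr2 <- quantile_offdays(rec2, "fi_g_per_d", tau = 0.05)
  expect_equal(unname(qr2[["5"]]), 0L)
  # zeroing three days adds exactly three off-feed days for that animal
  rec3 <- rec
  base <- unname(qr[["7"]])
  idx <- which(rec3$animal_id == 7)[1:3]
  above <- rec3$fi_g_per_d[idx] > 1500 + 10 * rec3$age_d[idx] - 200
  rec3$fi_g_per_d[idx] <- 0
  qr3 <- quantile_offdays(rec3, "fi_g_per_d", tau = 0.05)
  expect_gte(unname(qr3[["7"]]), base + 3 - sum(!above))
  expect_error(quantile_offdays(rec, tau = 1.2), "tau")
})

test_that("tiny-n quantile regression matches the vertex-enumeration oracle", {
  # the check-loss minimum over lines is attained at a line through two
  # data points; exhaustive enumeration is an exact oracle at small n
  rho <- function(u, tau) sum(u * (tau - (u < 0)))
  set.seed(9)
  for (tau in c(0.05, 0.25, 0.5)) {
    x <- runif(12, 0, 10); y <- 3 + 0.7 * x + rnorm(12)
    best <- Inf
    for (i in 1:11) for (j in (i + 1):12) {
      b <- (y[j] - y[i]) / (x[j] - x[i]); a <- y[i] - b * x[i]
      best <- min(best, rho(y - a - b * x, tau))
    }
    f <- quantreg::rq(y ~ x, tau = tau)
    expect_equal(rho(stats::resid(f), tau), best, tolerance = 1e-9)
  }
})

test_that("derived lnvar tracks true residual variability across animals", {
  sim <- simulate_afs(sim_config(n_sires = 6, n_dams = 30,
                                 offspring_per_litter = 5, seed = 55),
                      artifacts = FALSE, perturbations = FALSE)
  tr <- derive_traits(sim$records, outlier_filter = FALSE)
  v <- sim$animals$v[match(tr$animal_id, sim$animals$id)]
  rho <- stats::cor(exp(v), tr$lnvar_weight, method = "spearman",
                    use = "complete.obs")
  expect_gt(rho, 0.8)
})

test_that("trait table is complete and internally consistent", {
  sim <- simulate_afs(tiny_cfg(seed = 61), artifacts = FALSE)
  tr <- derive_traits(sim$records)
  expect_setequal(tr$animal_id, unique(sim$records$animal_id))
  needed <- c("ADG", "AFI", "FCR", "A", "B", "k", "lnvar_weight",
              "lnMSE_weight", "lnvar_weight_standardized", "skew_weight",
              "lag1_weight", "straightness", "mean_speed", "lnMSE_FI",
              "lnMSE_dur", "lnMSE_n_visit", "QR_FI", "QR_dur")
  expect_true(all(needed %in% names(tr)))
  expect_true(all(tr$straightness <= 1, na.rm = TRUE))
  expect_true(all(tr$mean_speed >= 1, na.rm = TRUE))
  expect_true(all(tr$QR_FI >= 0 & tr$QR_FI <= 61, na.rm = TRUE))
  expect_gt(mean(tr$gompertz_converged), 0.95)
})
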