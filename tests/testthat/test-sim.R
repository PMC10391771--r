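test_that("pedigree structure: counts, valid parents, determinism", {
  cfg <- sim_config(n_sires = 2, n_dams = 4, offspring_per_litter = 5,
                    seed = 3)
  sp <- simulate_pedigree(cfg)
  ped <- sp$pedigree
  off <- sp$animals
  expect_equal(nrow(off), 20L)
  # offspring have one sire and one dam, both present and older
  expect_true(all(off$sire %in% ped$id & off$dam %in% ped$id))
  parents <- ped[match(off$id, ped$id), ]
  expect_true(all(parents$sire > 0 & parents$dam > 0))
  expect_true(all(match(off$sire, ped$id) < match(off$id, ped$id)))
  # the recorded generation sits on 2 sires x 4 dams
  expect_equal(length(unique(off$sire)), 2L)
  expect_equal(length(unique(off$dam)), 4L)
  expect_true(all(table(off$dam) == 5L))
  # same config, same seed: identical output
  sp2 <- simulate_pedigree(cfg)
  expect_identical(sp, sp2)
})

test_that("whole simulation is byte-identical under a fixed seed", {
  cfg <- tiny_cfg(seed = 77)
  s1 <- simulate_afs(cfg, genotypes = TRUE)
  s2 <- simulate_afs(cfg, genotypes = TRUE)
  expect_identical(s1, s2)
})

test_that("founder breeding values match the configured variance", {
  cfg <- sim_config(n_sires = 900, n_dams = 4500, offspring_per_litter = 1,
                    seed = 5)
  sp <- simulate_pedigree(cfg)
  sp <- simulate_genetic_values(sp, cfg)
  fo <- sp$founder_values
  expect_gt(nrow(fo), 1000)
  sig2_A <- cfg$h2_curve[["A"]] * cfg$curve_sd[["A"]]^2
  tol <- 3 * sig2_A * sqrt(2 / nrow(fo))
  expect_lt(abs(stats::var(fo$a_A) - sig2_A), tol)
  tol_v <- 3 * cfg$sigma2_av * sqrt(2 / nrow(fo))
  expect_lt(abs(stats::var(fo$v) - cfg$sigma2_av), tol_v)
})

test_that("offspring breeding values centre on the parent average", {
  cfg <- sim_config(n_sires = 1, n_dams = 1, offspring_per_litter = 400,
                    seed = 11)
  sp <- simulate_pedigree(cfg)
  sp <- simulate_genetic_values(sp, cfg)
  an <- sp$animals
  gv <- sp$genetic_values
  sig2_A <- cfg$h2_curve[["A"]] * cfg$curve_sd[["A"]]^2
  mid <- 0.5 * (gv$a_A[gv$id == an$sire[1]] + gv$a_A[gv$id == an$dam[1]])
  # sib mean ~ N(midparent, 0.5 sig2 / 400)
  expect_lt(abs(mean(an$a_A) - mid), 3 * sqrt(0.5 * sig2_A / 400))
  # sib spread equals the mendelian-sampling variance sig2 / 2
  expect_lt(abs(stats::var(an$a_A) - 0.5 * sig2_A),
            3 * 0.5 * sig2_A * sqrt(2 / 400))
})

test_that("sigma2_av = 0 collapses all animals to one residual SD", {
  cfg <- tiny_cfg(seed = 2, sigma2_av = 0)
  sp <- simulate_genetic_values(simulate_pedigree(cfg), cfg)
  expect_true(all(sp$animals$v == 0))
})

test_that("noise-free growth sits exactly on the Gompertz curve and refits", {
  cfg <- tiny_cfg(seed = 4, cg_sd_A = 1e-8)
  sp <- simulate_genetic_values(simulate_pedigree(cfg), cfg)
  gr <- simulate_growth_and_feeding(sp, cfg, perturbations = FALSE,
                                    noise = FALSE)
  an <- sp$animals[1, ]
  r <- gr$records[gr$records$animal_id == an$id, ]
  expect_equal(r$weight_kg,
               gompertz_predict(gr$A_eff[[as.character(an$id)]],
                                an$true_B, an$true_k, r$age_d),
               tolerance = 1e-12)
  gf <- fit_gompertz(r$age_d, r$weight_kg,
                     anchor_age = c(1, 14, 81, 161),
                     anchor_weight = gompertz_predict(
                       gr$A_eff[[as.character(an$id)]], an$true_B,
                       an$true_k, c(1, 14, 81, 161)))
  rel <- abs(c(gf$A, gf$B, gf$k) /
               c(gr$A_eff[[as.character(an$id)]], an$true_B, an$true_k) - 1)
  expect_true(all(rel < 1e-6))
})

test_that("total feed-intake shutdown flattens growth, then growth resumes", {
  cfg <- tiny_cfg(seed = 6, perturbation_depth = 1,
                  perturbation_rate = 1, perturbation_duration = 4)
  sp <- simulate_genetic_values(simulate_pedigree(cfg), cfg)
  gr <- simulate_growth_and_feeding(sp, cfg, noise = FALSE)
  ev <- gr$events
  expect_gt(nrow(ev), 0)
  e <- ev[1, ]
  r <- gr$records[gr$records$animal_id == e$animal_id, ]
  r <- r[order(r$age_d), ]
  in_ev <- r$age_d >= e$onset_d & r$age_d < e$onset_d + e$duration_d
  # depth 1: no feed on event days
  expect_true(all(r$fi_g_per_d[in_ev] == 0))
  # daily gain during the event is reduced against the clean expectation
  clean <- simulate_growth_and_feeding(sp, cfg, perturbations = FALSE,
                                       noise = FALSE)
  rc <- clean$records[clean$records$animal_id == e$animal_id, ]
  rc <- rc[order(rc$age_d), ]
  deficit <- rc$weight_kg - r$weight_kg
  expect_true(all(diff(deficit) >= -1e-9))       # deficit never shrinks
  expect_gt(deficit[length(deficit)], 0)
  after <- r$age_d > e$onset_d + e$duration_d
  if (sum(after) > 2)                            # growth resumes after event
    expect_true(all(diff(r$weight_kg[after]) > 0))
})

test_that("animal-specific residual SD follows exp(v/2)", {
  cfg <- tiny_cfg(seed = 8)
  sp <- simulate_genetic_values(simulate_pedigree(cfg), cfg)
  # force two animals 2 ln 2 apart in v: SD ratio must be 2
  sp$animals$v[1] <- 0.3
  sp$animals$v[2] <- 0.3 + 2 * log(2)
  gr <- simulate_growth_and_feeding(sp, cfg, perturbations = FALSE)
  r1 <- gr$records[gr$records$animal_id == sp$animals$id[1], ]
  r2 <- gr$records[gr$records$animal_id == sp$animals$id[2], ]
  f1 <- fit_gompertz(r1$age_d, r1$weight_kg)
  f2 <- fit_gompertz(r2$age_d, r2$weight_kg)
  ratio <- stats::sd(f2$residuals) / stats::sd(f1$residuals)
  expect_gt(ratio, 1.3)   # 2 in expectation, wide sampling band at n = 61
  expect_lt(ratio, 3.1)
})

test_that("artifact injection: identity at zero rates, ledger completeness", {
  cfg0 <- tiny_cfg(seed = 9, artifact_rates = c(spike = 0, adaptation = 0,
                                                missing = 0, gross = 0))
  sp <- simulate_genetic_values(simulate_pedigree(cfg0), cfg0)
  gr <- simulate_growth_and_feeding(sp, cfg0)
  ia <- inject_artifacts(gr$records, cfg0)
  expect_identical(ia$records, gr$records)
  expect_equal(nrow(ia$ledger), 0L)

  cfg1 <- tiny_cfg(seed = 9)
  ia1 <- inject_artifacts(gr$records, cfg1)
  expect_gt(nrow(ia1$ledger), 0)
  # every gross-error cell really is outside [10, 160] kg
  gross <- ia1$ledger[ia1$ledger$type == "gross", ]
  w <- ia1$records$weight_kg[match(cell_key(gross), cell_key(ia1$records))]
  expect_true(all(w < 10 | w > 160))
  # and the gross-limit stage removes them all
  cleaned <- apply_gross_limits(ia1$records, qc_config())
  w2 <- cleaned$weight_kg[match(cell_key(gross), cell_key(cleaned))]
  expect_true(all(is.na(w2)))
  bad_rates <- tryCatch(tiny_cfg(artifact_rates = c(spike = 1.2,
                                                    adaptation = 0,
                                                    missing = 0, gross = 0)),
                        error = function(e) e)
  expect_s3_class(bad_rates, "error")
})

test_that("spike count follows the binomial at the configured rate", {
  cfg <- sim_config(n_sires = 10, n_dams = 170, offspring_per_litter = 10,
                    seed = 13,
                    artifact_rates = c(spike = 0.01, adaptation = 0,
                                       missing = 0, gross = 0))
  sp <- simulate_genetic_values(simulate_pedigree(cfg), cfg)
  gr <- simulate_growth_and_feeding(sp, cfg, perturbations = FALSE)
  n_days <- nrow(gr$records)
  expect_gt(n_days, 100000)
  ia <- inject_artifacts(gr$records, cfg)
  expected <- 0.01 * n_days
  expect_lt(abs(nrow(ia$ledger) - expected),
            3 * sqrt(expected * 0.99))
})

test_that("gene dropping: Mendelian dosages and founder frequencies", {
  cfg <- sim_config(n_sires = 300, n_dams = 1500, offspring_per_litter = 1,
                    n_snps = 60, seed = 21)
  sp <- simulate_pedigree(cfg)
  g <- simulate_genotypes(sp, cfg)
  M <- g$dosages
  ped <- sp$pedigree
  # parent pair (2, 0) forces a heterozygous offspring
  off <- ped[ped$sire > 0, ]
  ds <- M[match(off$sire, ped$id), , drop = FALSE]
  dd <- M[match(off$dam, ped$id), , drop = FALSE]
  do <- M[match(off$id, ped$id), , drop = FALSE]
  fixed_cross <- (ds == 2 & dd == 0) | (ds == 0 & dd == 2)
  expect_gt(sum(fixed_cross), 100)
  expect_true(all(do[fixed_cross] == 1))
  # realized founder allele frequency close to configured p
  fnd <- ped$id[ped$sire == 0 & ped$dam == 0]
  pf <- colMeans(M[match(fnd, ped$id), , drop = FALSE]) / 2
  se <- sqrt(g$freq * (1 - g$freq) / (2 * length(fnd)))
  expect_true(mean(abs(pf - g$freq) < 3.5 * se) > 0.95)
  expect_error(sim_config(n_snps = 0), "counts")
})

test_that("written dataset round-trips through plain-text files", {
  cfg <- tiny_cfg(seed = 31)
  sim <- simulate_afs(cfg, genotypes = TRUE)
  dir <- tempfile("afs")
  paths <- write_afs_dataset(sim, dir)
  rec <- utils::read.csv(paths[["records"]])
  expect_equal(nrow(rec), nrow(sim$records))
  expect_equal(rec$weight_kg, sim$records$weight_kg)
  ped <- utils::read.csv(paths[["pedigree"]])
  expect_equal(ped, sim$pedigree)
  expect_true(file.exists(paths[["truth"]]))
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(length(truth$animals), nrow(sim$animals))
  unlink(dir, recursive = TRUE)
})
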