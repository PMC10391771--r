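#' Simulate daily AFS records from true growth curves
#'
#' Expected weight follows the increasing Gompertz curve
#' `W(t) = A * exp(-B * exp(-k * t))`, with the contemporary-group effect
#' added to the asymptote. Daily feed intake is maintenance
#' (`feed_maint_g_per_kg * W`) plus expected gain times `feed_per_gain`.
#' Perturbation events (Poisson onsets, Beta depths, geometric durations)
#' multiply feed intake and visit duration by `1 - depth` while active; the
#' resulting feed deficit converts into a persistent weight-gain deficit at
#' `fcr_deficit_g_per_kg` g feed per kg of lost gain (no compensatory
#' growth). Observed weight is the expected weight minus the cumulative
#' deficit plus i.i.d. noise with animal-specific SD `exp((mu_v + v_i)/2)`;
#' feed intake, visit duration and visit count get noise scaled by
#' `exp(v_i / 2)` so less resilient animals are more variable throughout.
#'
#' @param sim Output of [simulate_genetic_values()].
#' @param cfg A [sim_config()] object.
#' @param perturbations Set `FALSE` to suppress perturbation events.
#' @param noise Set `FALSE` for noise-free records (useful for round-trip
#'   checks of curve fitting).
#' @return A list with `records` (one row per animal-day) and `events`
#'   (data.frame of perturbation events: `animal_id`, `onset_d`,
#'   `duration_d`, `depth`).
#' @export
simulate_growth_and_feeding <- function(sim, cfg, perturbations = TRUE,
                                        noise = TRUE) {
  validate_sim_config(cfg)
  set.seed(sim_seed(cfg, "records"))
  an <- sim$animals
  if (is.null(an$true_A)) stop("run simulate_genetic_values() first")
  ages <- seq(cfg$age_range[1], cfg$age_range[2])
  nd <- length(ages)
  n <- nrow(an)

  cg_levels <- sort(unique(an$cg))
  cg_eff <- stats::rnorm(length(cg_levels), 0, cfg$cg_sd_A)
  names(cg_eff) <- cg_levels
  A_eff <- an$true_A + cg_eff[an$cg]

  # perturbation events
  ev <- NULL
  if (perturbations && cfg$perturbation_rate > 0) {
    n_ev <- stats::rpois(n, cfg$perturbation_rate)
    tot <- sum(n_ev)
    if (tot > 0) {
      mu_d <- cfg$perturbation_depth
      ev <- data.frame(
        animal_id = rep(an$id, n_ev),
        onset_d = sample(ages, tot, replace = TRUE),
        duration_d = 1L + stats::rgeom(tot, 1 / cfg$perturbation_duration),
        depth = stats::rbeta(tot, 2, 2 * (1 - mu_d) / mu_d))
    }
  }

  sd_w <- exp((cfg$mu_v + an$v) / 2)
  disp <- exp(an$v / 2)
  dur_mu <- stats::rnorm(n, cfg$dur_mean_s, cfg$dur_between_sd_s)
  nv_mu <- stats::rnorm(n, cfg$nvisit_mean, cfg$nvisit_between_sd)

  out <- vector("list", n)
  for (i in seq_len(n)) {
    Wexp <- gompertz_predict(A_eff[i], an$true_B[i], an$true_k[i], ages)
    gain_g <- 1000 * (gompertz_predict(A_eff[i], an$true_B[i], an$true_k[i],
                                       ages + 1) - Wexp)
    fi_exp <- cfg$feed_maint_g_per_kg * Wexp + cfg$feed_per_gain * gain_g
    depth_t <- numeric(nd)
    if (!is.null(ev)) {
      evi <- ev[ev$animal_id == an$id[i], , drop = FALSE]
      for (k in seq_len(nrow(evi))) {
        span <- ages >= evi$onset_d[k] &
          ages < evi$onset_d[k] + evi$duration_d[k]
        depth_t[span] <- pmin(1, depth_t[span] + evi$depth[k])
      }
    }
    fi_obs <- fi_exp * (1 - depth_t)
    deficit_kg <- cumsum(fi_exp * depth_t) / cfg$fcr_deficit_g_per_kg
    w_obs <- Wexp - deficit_kg
    dur <- pmax(0, dur_mu[i] * (1 - depth_t))
    nv <- rep(max(1, nv_mu[i]), nd)
    if (noise) {
      fi_obs <- pmax(0, fi_obs + stats::rnorm(nd, 0, cfg$fi_sd_g * disp[i]))
      w_obs <- w_obs + stats::rnorm(nd, 0, sd_w[i])
      dur <- pmax(0, dur + stats::rnorm(nd, 0, cfg$dur_sd_s * disp[i]))
      nv <- pmax(1, round(nv + stats::rnorm(nd, 0, cfg$nvisit_sd * disp[i])))
    }
    out[[i]] <- data.frame(
      animal_id = an$id[i], age_d = ages, weight_kg = w_obs,
      fi_g_per_d = fi_obs, dur_s_per_d = dur, nvisits_per_d = nv)
  }
  records <- do.call(rbind, out)
  j <- match(records$animal_id, an$id)
  records$pen <- an$pen[j]
  records$compartment <- an$compartment[j]
  records$farm <- an$farm[j]
  records$cg <- an$cg[j]
  records$entry_date <- an$entry_date[j]
  records$sex <- an$sex[j]
  records$birth_date <- an$birth_date[j]
  rownames(records) <- NULL
  list(records = records,
       events = if (is.null(ev)) data.frame(animal_id = integer(),
                                            onset_d = integer(),
                                            duration_d = integer(),
                                            depth = numeric()) else ev,
       cg_effects = cg_eff, A_eff = stats::setNames(A_eff, an$id))
}

#' Inject technical artifacts into AFS records
#'
#' Reproduces the error modes of raw feeding-station data: (i) single-day
#' weight spikes of 5--25 kg in either direction, (ii) inflated weights over
#' the first 3--6 days after entry (adaptation phase: penmates on the scale
#' add 20--60 kg), (iii) missing days and (iv) gross recording errors
#' (values below 10 kg or above 160 kg). Every corrupted or deleted weight
#' cell is recorded in a ledger so QC sensitivity and specificity can be
#' scored against ground truth.
#'
#' @param records Records data.frame from [simulate_growth_and_feeding()].
#' @param cfg A [sim_config()] object (uses `artifact_rates`, `seed`).
#' @return A list with `records` (corrupted) and `ledger` (data.frame
#'   `animal_id`, `age_d`, `type`). `missing` rows are deleted from the
#'   records; the other types alter `weight_kg` in place.
#' @export
inject_artifacts <- function(records, cfg) {
  validate_sim_config(cfg)
  rates <- cfg$artifact_rates
  if (any(rates < 0 | rates > 1)) stop("artifact rates must be in [0, 1]")
  set.seed(sim_seed(cfg, "artifacts"))
  n <- nrow(records)
  led <- list()

  spike <- which(stats::runif(n) < rates[["spike"]])
  if (length(spike)) {
    sgn <- sample(c(-1, 1), length(spike), replace = TRUE)
    records$weight_kg[spike] <- records$weight_kg[spike] +
      sgn * stats::runif(length(spike), 5, 25)
    led$spike <- data.frame(animal_id = records$animal_id[spike],
                            age_d = records$age_d[spike], type = "spike")
  }

  ids <- unique(records$animal_id)
  adapt_animals <- ids[stats::runif(length(ids)) < rates[["adaptation"]]]
  if (length(adapt_animals)) {
    rows <- unlist(lapply(adapt_animals, function(a) {
      r <- which(records$animal_id == a)
      r[order(records$age_d[r])][seq_len(sample(3:6, 1))]
    }))
    records$weight_kg[rows] <- records$weight_kg[rows] +
      stats::runif(length(rows), 20, 60)
    led$adaptation <- data.frame(animal_id = records$animal_id[rows],
                                 age_d = records$age_d[rows],
                                 type = "adaptation")
  }

  gross <- which(stats::runif(n) < rates[["gross"]])
  gross <- setdiff(gross, spike)
  if (length(gross)) {
    lo <- stats::runif(length(gross)) < 0.5
    records$weight_kg[gross] <- ifelse(lo, stats::runif(length(gross), 0.5, 9.5),
                                       stats::runif(length(gross), 161, 400))
    led$gross <- data.frame(animal_id = records$animal_id[gross],
                            age_d = records$age_d[gross], type = "gross")
  }

  miss <- which(stats::runif(n) < rates[["missing"]])
  if (length(miss)) {
    led$missing <- data.frame(animal_id = records$animal_id[miss],
                              age_d = records$age_d[miss], type = "missing")
    records <- records[-miss, , drop = FALSE]
  }

  ledger <- if (length(led)) do.call(rbind, led) else
    data.frame(animal_id = integer(), age_d = integer(), type = character())
  rownames(ledger) <- rownames(records) <- NULL
  list(records = records, ledger = ledger)
}

#' One-stop synthetic AFS dataset
#'
#' Runs pedigree simulation, genetic-value sampling, record simulation,
#' artifact injection and (optionally) genotype simulation with a single
#' configuration.
#'
#' @param cfg A [sim_config()] object.
#' @param artifacts,perturbations,noise,genotypes Stage switches.
#' @return A list: `pedigree`, `animals` (with true values), `records`,
#'   `clean_records` (pre-artifact), `events`, `ledger`, `cg_effects`,
#'   `A_eff` and optionally `genotypes`.
#' @examples
#' sim <- simulate_afs(sim_config(n_sires = 2, n_dams = 6,
#'                                offspring_per_litter = 3, n_snps = 20))
#' head(sim$records)
#' @export
simulate_afs <- function(cfg = sim_config(), artifacts = TRUE,
                         perturbations = TRUE, noise = TRUE,
                         genotypes = FALSE) {
  sim <- simulate_pedigree(cfg)
  sim <- simulate_genetic_values(sim, cfg)
  gr <- simulate_growth_and_feeding(sim, cfg, perturbations = perturbations,
                                    noise = noise)
  out <- list(pedigree = sim$pedigree, animals = sim$animals,
              clean_records = gr$records, events = gr$events,
              cg_effects = gr$cg_effects, A_eff = gr$A_eff)
  if (artifacts) {
    ia <- inject_artifacts(gr$records, cfg)
    out$records <- ia$records
    out$ledger <- ia$ledger
  } else {
    out$records <- gr$records
    out$ledger <- data.frame(animal_id = integer(), age_d = integer(),
                             type = character())
  }
  if (genotypes) out$genotypes <- simulate_genotypes(sim, cfg)
  out$config <- cfg
  out
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `records.csv`, `pedigree.csv` (id, sire, dam; 0 = unknown),
#' optionally `genotypes.csv`, and `truth.json` (ground-truth animal
#' parameters, perturbation events and artifact ledger).
#'
#' @param sim Output of [simulate_afs()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_afs_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(records = file.path(dir, "records.csv"),
             pedigree = file.path(dir, "pedigree.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(sim$records, paths[["records"]], row.names = FALSE)
  utils::write.csv(sim$pedigree, paths[["pedigree"]], row.names = FALSE)
  if (!is.null(sim$genotypes)) {
    paths <- c(paths, genotypes = file.path(dir, "genotypes.csv"))
    utils::write.csv(data.frame(id = rownames(sim$genotypes$dosages),
                                sim$genotypes$dosages),
                     paths[["genotypes"]], row.names = FALSE)
  }
  truth <- list(animals = sim$animals, events = sim$events,
                ledger = sim$ledger)
  jsonlite::write_json(truth, paths[["truth"]], dataframe = "rows",
                       digits = NA, na = "null")
  invisible(paths)
}
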