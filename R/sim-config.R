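#' Configuration for the synthetic AFS data generator
#'
#' Builds and validates the parameter set used by [simulate_afs()] and the
#' individual simulation stages. Defaults emulate a nucleus pig test barn:
#' pens of 15 pigs housed in compartments of 10 pens, daily automated feeding
#' station (AFS) records over the 95--155 d finishing window, near-linear
#' Gompertz growth, heritable growth-curve parameters and heritable
#' log-residual-variance of daily weight, contemporary-group effects,
#' perturbation events that depress feed intake and subsequently weight gain,
#' and the technical artifact modes seen in raw AFS data (single-day weight
#' spikes, inflated weights during an adaptation phase after entry, missing
#' days, gross recording errors).
#'
#' @param n_sires,n_dams,offspring_per_litter Mating structure: each dam
#'   produces one litter; dams are split evenly over sires.
#' @param pigs_per_pen Pigs housed per pen (default 15).
#' @param age_range Integer vector `c(start, end)` of ages in days with AFS
#'   records (default `c(95, 155)`).
#' @param sex_ratio Proportion of males (default 0.978, a boar-testing barn).
#' @param n_farms Number of farms; compartments are split between farms.
#' @param n_cg Number of contemporary groups (farm x compartment x entry
#'   date). `NULL` (default) derives one group per compartment.
#' @param h2_curve Heritabilities of the Gompertz parameters (A, B, k).
#' @param curve_mean,curve_sd Means and phenotypic SDs of (A, B, k);
#'   A in kg, B unitless, k per day.
#' @param curve_cor Correlation matrix (3x3) shared by the additive and
#'   environmental parts of (A, B, k).
#' @param cg_sd_A SD (kg) of the contemporary-group effect acting on the
#'   asymptote of the expected growth curve.
#' @param mu_v Mean log-residual-variance of daily weight (kg^2 scale);
#'   per-animal daily weight noise SD is `exp((mu_v + v_i)/2)`.
#' @param sigma2_av Additive genetic variance of the log-residual-variance
#'   `v`; 0 makes all animals equally variable.
#' @param perturbation_rate Expected number of perturbation events per animal
#'   over the recording window.
#' @param perturbation_depth Mean fractional feed-intake drop during an
#'   event; realized depths are Beta-distributed around this mean.
#' @param perturbation_duration Mean event duration in days.
#' @param artifact_rates Named numeric vector with elements `spike`
#'   (per animal-day), `adaptation` (per animal), `missing` (per animal-day)
#'   and `gross` (per animal-day).
#' @param feed_maint_g_per_kg Maintenance feed, g/d per kg body weight.
#' @param feed_per_gain Feed required per unit expected gain (g feed / g
#'   gain) on top of maintenance.
#' @param fcr_deficit_g_per_kg Feed deficit (g) needed to lose 1 kg of
#'   expected gain during a perturbation (whole-animal conversion).
#' @param fi_sd_g Baseline daily feed-intake noise SD (g/d).
#' @param dur_mean_s,dur_between_sd_s,dur_sd_s Visit duration model:
#'   population mean, between-animal SD, daily noise SD (s/d).
#' @param nvisit_mean,nvisit_between_sd,nvisit_sd Daily visit count model.
#' @param n_snps Number of simulated SNPs.
#' @param seed Integer seed; all stages are deterministic given the seed.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_sires = 2, n_dams = 4, offspring_per_litter = 5)
#' cfg$pigs_per_pen
#' @export
sim_config <- function(n_sires = 20,
                       n_dams = 100,
                       offspring_per_litter = 5,
                       pigs_per_pen = 15,
                       age_range = c(95L, 155L),
                       sex_ratio = 0.978,
                       n_farms = 2,
                       n_cg = NULL,
                       h2_curve = c(A = 0.3, B = 0.3, k = 0.3),
                       curve_mean = c(A = 225, B = 6.75, k = 0.0148),
                       curve_sd = c(A = 25, B = 0.8, k = 0.0018),
                       curve_cor = matrix(c(1, -0.4, -0.7,
                                            -0.4, 1, 0.8,
                                            -0.7, 0.8, 1), 3, 3),
                       cg_sd_A = 8,
                       mu_v = -0.6,
                       sigma2_av = 0.2,
                       perturbation_rate = 0.6,
                       perturbation_depth = 0.3,
                       perturbation_duration = 5,
                       artifact_rates = c(spike = 0.01, adaptation = 0.03,
                                          missing = 0.02, gross = 0.002),
                       feed_maint_g_per_kg = 15,
                       feed_per_gain = 1.1,
                       fcr_deficit_g_per_kg = 2240,
                       fi_sd_g = 300,
                       dur_mean_s = 4000, dur_between_sd_s = 700, dur_sd_s = 700,
                       nvisit_mean = 10, nvisit_between_sd = 2, nvisit_sd = 2.5,
                       n_snps = 500,
                       seed = 1L) {
  cfg <- list(n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
              offspring_per_litter = as.integer(offspring_per_litter),
              pigs_per_pen = as.integer(pigs_per_pen),
              age_range = as.integer(age_range), sex_ratio = sex_ratio,
              n_farms = as.integer(n_farms),
              n_cg = if (is.null(n_cg)) NULL else as.integer(n_cg),
              h2_curve = h2_curve, curve_mean = curve_mean,
              curve_sd = curve_sd, curve_cor = curve_cor, cg_sd_A = cg_sd_A,
              mu_v = mu_v, sigma2_av = sigma2_av,
              perturbation_rate = perturbation_rate,
              perturbation_depth = perturbation_depth,
              perturbation_duration = perturbation_duration,
              artifact_rates = artifact_rates,
              feed_maint_g_per_kg = feed_maint_g_per_kg,
              feed_per_gain = feed_per_gain,
              fcr_deficit_g_per_kg = fcr_deficit_g_per_kg,
              fi_sd_g = fi_sd_g,
              dur_mean_s = dur_mean_s, dur_between_sd_s = dur_between_sd_s,
              dur_sd_s = dur_sd_s,
              nvisit_mean = nvisit_mean, nvisit_between_sd = nvisit_between_sd,
              nvisit_sd = nvisit_sd,
              n_snps = as.integer(n_snps), seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c(cfg$n_sires, cfg$n_dams, cfg$offspring_per_litter,
              cfg$pigs_per_pen, cfg$n_farms, cfg$n_snps)
  if (any(counts <= 0)) stop("all counts must be > 0")
  if (cfg$sex_ratio < 0 || cfg$sex_ratio > 1)
    stop("sex_ratio must be in [0, 1]")
  if (length(cfg$age_range) != 2L || cfg$age_range[1] >= cfg$age_range[2])
    stop("age_range must be an ordered pair start < end")
  if (cfg$sigma2_av < 0) stop("sigma2_av must be >= 0")
  if (any(cfg$h2_curve < 0 | cfg$h2_curve > 1))
    stop("h2_curve entries must be in [0, 1]")
  if (any(cfg$artifact_rates < 0 | cfg$artifact_rates > 1))
    stop("artifact rates must be in [0, 1]")
  if (cfg$perturbation_depth <= 0 || cfg$perturbation_depth > 1)
    stop("perturbation_depth must be in (0, 1]")
  invisible(cfg)
}

# stage-specific deterministic seeds derived from the config seed
sim_seed <- function(cfg, stage) {
  offsets <- c(pedigree = 11L, genetics = 23L, records = 37L,
               artifacts = 53L, genotypes = 71L)
  (cfg$seed %% 1000000000L) + offsets[[stage]]
}
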