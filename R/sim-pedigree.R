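#' Simulate a pedigree with housing structure
#'
#' Three generations: a grandparent founder generation, from which the
#' sires and dams of the recorded animals descend (giving the parent
#' generation half- and full-sib structure, so that masked families still
#' have phenotyped relatives through the wider pedigree), then one litter
#' per dam by a single sire, dams being split evenly over sires. Litters
#' are housed in blocks: consecutive litters fill pens of `pigs_per_pen`,
#' pens fill compartments of 10, compartments alternate between farms and
#' receive one entry date each (14-day batch spacing), so a contemporary
#' group (farm x compartment x entry date) corresponds to a compartment
#' unless `n_cg` coarsens it. Because dams are assigned to sires round-robin
#' each sire's progeny spread over many compartments and entry dates.
#'
#' @param cfg A [sim_config()] object.
#' @return A list with `pedigree` (data.frame `id`, `sire`, `dam`; 0 =
#'   unknown) and `animals` (offspring-level housing and identity metadata:
#'   pen, compartment, farm, cg, sex, birth_date, entry_date).
#' @export
simulate_pedigree <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(sim_seed(cfg, "pedigree"))
  ns <- cfg$n_sires; nd <- cfg$n_dams; opl <- cfg$offspring_per_litter
  n_off <- nd * opl
  # grandparent generation: a small sire pool creates half-sib structure
  # among the parents of the recorded animals
  ngs <- max(2L, ceiling(ns / 3))
  ngd <- max(2L, ceiling((ns + nd) / 4))
  gs_id <- seq_len(ngs)
  gd_id <- ngs + seq_len(ngd)
  n_gp <- ngs + ngd
  sire_id <- n_gp + seq_len(ns)
  dam_id <- n_gp + ns + seq_len(nd)
  par_sire <- sample(gs_id, ns + nd, replace = TRUE)
  par_dam <- sample(gd_id, ns + nd, replace = TRUE)
  n_founder <- n_gp + ns + nd
  off_id <- n_founder + seq_len(n_off)
  # dams split evenly over sires (rounds out remainders)
  dam_sire <- sire_id[1L + (seq_len(nd) - 1L) %% ns]
  off_dam <- rep(dam_id, each = opl)
  off_sire <- rep(dam_sire, each = opl)

  pedigree <- data.frame(
    id = c(gs_id, gd_id, sire_id, dam_id, off_id),
    sire = c(rep(0L, n_gp), par_sire, off_sire),
    dam = c(rep(0L, n_gp), par_dam, off_dam))

  # housing: consecutive litters fill pens (litters are born and housed in
  # batches, as in a test barn)
  n_pens <- ceiling(n_off / cfg$pigs_per_pen)
  pen <- rep(seq_len(n_pens), each = cfg$pigs_per_pen)[seq_len(n_off)]
  compartment <- (pen - 1L) %/% 10L + 1L
  n_comp <- max(compartment)
  farm <- (compartment - 1L) %% cfg$n_farms + 1L
  if (!is.null(cfg$n_cg)) {              # coarsen compartments into n_cg groups
    compartment <- (compartment - 1L) %% cfg$n_cg + 1L
    farm <- (compartment - 1L) %% cfg$n_farms + 1L
    n_comp <- cfg$n_cg
  }
  entry <- as.Date("2020-01-06") + 14L * (compartment - 1L)
  animals <- data.frame(
    id = off_id,
    sire = off_sire,
    dam = off_dam,
    sex = ifelse(stats::runif(n_off) < cfg$sex_ratio, "M", "F"),
    pen = pen,
    compartment = compartment,
    farm = farm,
    cg = paste0("f", farm, ".c", compartment),
    entry_date = entry,
    birth_date = entry - cfg$age_range[1],
    stringsAsFactors = FALSE)
  list(pedigree = pedigree, animals = animals)
}

#' Draw breeding values and true growth-curve parameters
#'
#' Additive genetic values for the Gompertz parameters (A, B, k) and for the
#' log-residual-variance `v` of daily weight are sampled by recursive
#' Mendelian sampling down the pedigree: founders from N(0, Sigma_a) and each
#' offspring as the parent average plus a deviation with covariance
#' Sigma_a / 2. Environmental deviations of (A, B, k) are i.i.d. with the
#' complementary covariance so phenotypic variances match `curve_sd^2` and
#' per-parameter heritabilities match `h2_curve`. The per-animal daily weight
#' noise SD is `exp((mu_v + v_i)/2)` with `v` purely additive,
#' `var(v) = sigma2_av`.
#'
#' @param sim Output of [simulate_pedigree()].
#' @param cfg A [sim_config()] object.
#' @return `sim` with the `animals` data.frame extended by additive values
#'   (`a_A`, `a_B`, `a_k`, `v`), environmental parts and realized curve
#'   parameters `true_A`, `true_B`, `true_k` (all positive), plus a
#'   `founder_values` data.frame for the founders.
#' @export
simulate_genetic_values <- function(sim, cfg) {
  validate_sim_config(cfg)
  set.seed(sim_seed(cfg, "genetics"))
  ped <- sim$pedigree
  n <- nrow(ped)
  sig_a <- sqrt(cfg$h2_curve) * cfg$curve_sd
  sig_e <- sqrt(1 - cfg$h2_curve) * cfg$curve_sd
  Sa <- diag(sig_a) %*% cfg$curve_cor %*% diag(sig_a)
  Se <- diag(sig_e) %*% cfg$curve_cor %*% diag(sig_e)
  La <- t(chol(Sa)); Le <- t(chol(Se))
  idx <- match(seq_len(max(ped$id)), ped$id)

  a <- matrix(0, n, 3)                     # additive (A, B, k)
  v <- numeric(n)                          # additive log-residual-variance
  sd_v <- sqrt(cfg$sigma2_av)
  half <- sqrt(0.5)
  for (i in seq_len(n)) {                  # parents precede offspring
    s <- ped$sire[i]; d <- ped$dam[i]
    if (s == 0L && d == 0L) {
      a[i, ] <- La %*% stats::rnorm(3)
      v[i] <- stats::rnorm(1, 0, sd_v)
    } else {
      as_ <- if (s > 0L) a[idx[s], ] else c(0, 0, 0)
      ad_ <- if (d > 0L) a[idx[d], ] else c(0, 0, 0)
      vs <- if (s > 0L) v[idx[s]] else 0
      vd <- if (d > 0L) v[idx[d]] else 0
      a[i, ] <- 0.5 * (as_ + ad_) + half * (La %*% stats::rnorm(3))
      v[i] <- 0.5 * (vs + vd) + half * stats::rnorm(1, 0, sd_v)
    }
  }
  rownames(a) <- ped$id

  an <- sim$animals
  j <- match(an$id, ped$id)
  e <- t(Le %*% matrix(stats::rnorm(3 * nrow(an)), 3))
  an$a_A <- a[j, 1]; an$a_B <- a[j, 2]; an$a_k <- a[j, 3]
  an$e_A <- e[, 1];  an$e_B <- e[, 2];  an$e_k <- e[, 3]
  an$v <- v[j]
  mu <- cfg$curve_mean
  an$true_A <- pmax(mu[1] + an$a_A + an$e_A, 0.2 * mu[1])
  an$true_B <- pmax(mu[2] + an$a_B + an$e_B, 0.2 * mu[2])
  an$true_k <- pmax(mu[3] + an$a_k + an$e_k, 0.2 * mu[3])
  sim$animals <- an
  sim$genetic_values <- data.frame(id = ped$id, a_A = a[, 1], a_B = a[, 2],
                                   a_k = a[, 3], v = v)
  fo <- ped$sire == 0 & ped$dam == 0
  sim$founder_values <- data.frame(id = ped$id[fo], a_A = a[fo, 1],
                                   v = v[fo])
  sim
}

#' Simulate SNP genotypes by gene dropping
#'
#' Founder allele frequencies are drawn from Uniform(0.05, 0.95); founder
#' alleles are Bernoulli draws and offspring inherit one random allele per
#' parent per locus (gene dropping). Dosages are counts of the reference
#' allele in \{0, 1, 2\}.
#'
#' @param sim Output of [simulate_pedigree()].
#' @param cfg A [sim_config()] object (`n_snps`, `seed`).
#' @return A list with `dosages` (animals x SNPs integer matrix, rownames =
#'   animal ids) and `freq` (founder allele frequencies used).
#' @export
simulate_genotypes <- function(sim, cfg) {
  validate_sim_config(cfg)
  if (cfg$n_snps <= 0) stop("n_snps must be > 0")
  set.seed(sim_seed(cfg, "genotypes"))
  ped <- sim$pedigree
  n <- nrow(ped); m <- cfg$n_snps
  p <- stats::runif(m, 0.05, 0.95)
  idx <- match(seq_len(max(ped$id)), ped$id)
  h1 <- matrix(0L, n, m); h2 <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (s == 0L) {
      h1[i, ] <- as.integer(stats::runif(m) < p)
    } else {
      k <- idx[s]
      pick <- stats::runif(m) < 0.5
      h1[i, ] <- ifelse(pick, h1[k, ], h2[k, ])
    }
    if (d == 0L) {
      h2[i, ] <- as.integer(stats::runif(m) < p)
    } else {
      k <- idx[d]
      pick <- stats::runif(m) < 0.5
      h2[i, ] <- ifelse(pick, h1[k, ], h2[k, ])
    }
  }
  M <- h1 + h2
  rownames(M) <- ped$id
  colnames(M) <- paste0("snp", seq_len(m))
  list(dosages = M, freq = p)
}
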