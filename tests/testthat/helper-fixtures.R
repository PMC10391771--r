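# Shared fixture builders; everything is generated in code at test time.

# small default simulation config used across tests
tiny_cfg <- function(seed = 1, ...) {
  sim_config(n_sires = 4, n_dams = 16, offspring_per_litter = 5,
             n_snps = 50, seed = seed, ...)
}

# balanced paternal half-sib pedigree: ns sires, k offspring each, dams unknown
half_sib_pedigree <- function(ns, k) {
  data.frame(id = 1:(ns + ns * k),
             sire = c(rep(0L, ns), rep(1:ns, each = k)),
             dam = 0L)
}

# simulate a phenotype with additive values drawn down a pedigree
sim_trait_on_pedigree <- function(ped, ids, h2, mu = 0, seed = 1) {
  set.seed(seed)
  A <- build_A(ped)
  a <- as.numeric(t(chol(A)) %*% stats::rnorm(nrow(A))) * sqrt(h2)
  names(a) <- ped$id
  y <- mu + a[as.character(ids)] + stats::rnorm(length(ids), 0, sqrt(1 - h2))
  list(y = y, a = a)
}

# records for one animal on a deterministic linear trajectory
linear_records <- function(id = 1L, ages = 95:155, intercept = -55,
                           slope = 1, pen = 1L) {
  data.frame(animal_id = id, age_d = ages,
             weight_kg = intercept + slope * ages,
             fi_g_per_d = 2000, dur_s_per_d = 3600, nvisits_per_d = 10,
             pen = pen, compartment = 1L, farm = 1L, cg = "f1.c1",
             entry_date = as.Date("2020-01-06"), sex = "M",
             birth_date = as.Date("2019-10-03"))
}

# several pens of clean linear-growth animals with Gaussian noise
pen_fixture <- function(n_pens = 8, per_pen = 10, noise_sd = 0.5,
                        intercept_sd = 2, seed = 1) {
  set.seed(seed)
  out <- list()
  id <- 0L
  for (p in seq_len(n_pens)) for (j in seq_len(per_pen)) {
    id <- id + 1L
    r <- linear_records(id, intercept = -55 + rnorm(1, 0, intercept_sd),
                        pen = p)
    r$weight_kg <- r$weight_kg + rnorm(nrow(r), 0, noise_sd)
    out[[id]] <- r
  }
  do.call(rbind, out)
}

# key for matching (animal, day) cells between ledgers and record sets
cell_key <- function(d) paste(d$animal_id, d$age_d)
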