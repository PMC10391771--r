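#' Assign cross-validation masking folds
#'
#' Three masking designs over phenotyped animals:
#' `within_family` splits each sire's offspring into `folds` folds
#' (remainders balanced round-robin after a random shuffle), so masked
#' animals keep close relatives in the training set; `across_family` splits
#' the sires into folds and masks all their progeny together, testing
#' prediction across families; `temporal` is a single split masking animals
#' born after `cutoff`.
#'
#' @param animals Data frame with `id`, `sire` and (for temporal)
#'   `birth_date`.
#' @param scheme One of `"within_family"`, `"across_family"`, `"temporal"`.
#' @param folds Number of folds (default 5).
#' @param replicates Number of replicates (default 10; temporal has 1).
#' @param cutoff Date for temporal masking.
#' @param seed Integer seed.
#' @return Data frame `replicate`, `fold`, `animal_id`. For the family
#'   schemes every animal is masked exactly once per replicate.
#' @export
assign_folds <- function(animals, scheme = c("within_family",
                                             "across_family", "temporal"),
                         folds = 5L, replicates = 10L, cutoff = NULL,
                         seed = 1L) {
  scheme <- match.arg(scheme)
  set.seed(seed)
  if (scheme == "temporal") {
    if (is.null(cutoff) || is.na(as.Date(cutoff)))
      stop("temporal masking needs a cutoff date")
    if (is.null(animals$birth_date) || anyNA(animals$birth_date))
      stop("temporal masking needs birth dates for every animal")
    masked <- animals$id[animals$birth_date > as.Date(cutoff)]
    if (!length(masked))
      stop("no animals born after the temporal cutoff ", cutoff)
    return(data.frame(replicate = 1L, fold = 1L, animal_id = masked))
  }
  if (is.null(animals$sire) || any(animals$sire == 0))
    stop("family masking needs a known sire for every animal")
  out <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    if (scheme == "within_family") {
      pieces <- lapply(split(animals$id, animals$sire), function(ids) {
        ids <- sample(ids)
        data.frame(fold = 1L + (seq_along(ids) - 1L) %% folds,
                   animal_id = ids)
      })
      asg <- do.call(rbind, pieces)
    } else {
      sires <- sample(unique(animals$sire))
      sire_fold <- stats::setNames(1L + (seq_along(sires) - 1L) %% folds,
                                   sires)
      asg <- data.frame(fold = unname(sire_fold[as.character(animals$sire)]),
                        animal_id = animals$id)
    }
    asg$replicate <- r
    out[[r]] <- asg[c("replicate", "fold", "animal_id")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Adjusted phenotypes from a full-data fit
#'
#' Removes the estimated fixed and contemporary-group effects from the
#' observed phenotypes: `y* = y - X b_hat - W c_hat = a_hat + e_hat`,
#' estimated once on the full data and reused across all folds.
#'
#' @param fit A `reml_fit` on the full data.
#' @return Named vector of adjusted phenotypes (by animal id).
#' @export
adjust_phenotypes <- function(fit) {
  md <- fit$model
  if (is.null(md)) stop("fit does not carry its model frame")
  ystar <- md$y - drop(md$X %*% fit$fixef)
  if (!is.null(md$cg)) ystar <- ystar - fit$cgef[as.integer(md$cg)]
  stats::setNames(as.numeric(ystar), md$animal)
}

#' Breeding values of masked animals
#'
#' Removes the masked animals' phenotypes, re-solves the mixed-model
#' equations at the full-data variance components, and returns the masked
#' animals' EBVs.
#'
#' @param fit A `reml_fit`.
#' @param mask Animal ids to mask (non-empty).
#' @return Named vector of EBVs for the masked animals.
#' @export
predict_masked <- function(fit, mask) {
  mask <- as.character(mask)
  if (!length(mask)) stop("masked set is empty")
  sol <- solve_mme(fit, mask = mask)
  sol$ebv[mask[mask %in% names(sol$ebv)]]
}

#' Predictive ability and accuracy
#'
#' Predictive ability is the Pearson correlation between masked animals'
#' EBVs and their adjusted phenotypes; accuracy divides it by the square
#' root of the heritability estimated on the full data.
#'
#' @param ebv_masked Named EBVs of masked animals.
#' @param ystar Named adjusted phenotypes.
#' @param h2 Full-data heritability.
#' @return List with `r` and `accuracy` (NA when either input is constant).
#' @export
predictive_ability <- function(ebv_masked, ystar, h2) {
  common <- intersect(names(ebv_masked), names(ystar))
  if (length(common) < 3L) stop("need at least 3 masked animals with y*")
  a <- ebv_masked[common]; b <- ystar[common]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, accuracy = NA_real_))
  r <- stats::cor(a, b)
  list(r = r, accuracy = r / sqrt(h2))
}

#' Run a masking cross-validation
#'
#' For each replicate x fold, masks the fold's animals, re-solves the MME at
#' the full-data variance components and scores predictive ability against
#' the adjusted phenotypes (family schemes: `replicates * folds` model
#' solves, e.g. 10 x 5 = 50; temporal: one).
#'
#' @param fit Full-data `reml_fit`.
#' @param animals Data frame with `id`, `sire`, `birth_date` for fold
#'   assignment (phenotyped animals).
#' @param scheme,folds,replicates,cutoff,seed Passed to [assign_folds()].
#' @return List with `results` (one row per fit: replicate, fold, n_masked,
#'   r, accuracy) and `summary` (mean and SD over fits).
#' @export
run_crossval <- function(fit, animals, scheme = "within_family", folds = 5L,
                         replicates = 10L, cutoff = NULL, seed = 1L) {
  ystar <- adjust_phenotypes(fit)
  asg <- assign_folds(animals, scheme, folds = folds,
                      replicates = replicates, cutoff = cutoff, seed = seed)
  combos <- unique(asg[c("replicate", "fold")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    mk <- asg$animal_id[asg$replicate == combos$replicate[i] &
                          asg$fold == combos$fold[i]]
    eb <- predict_masked(fit, mk)
    pa <- predictive_ability(eb, ystar, fit$h2)
    data.frame(replicate = combos$replicate[i], fold = combos$fold[i],
               n_masked = length(mk), r = pa$r, accuracy = pa$accuracy)
  })
  results <- do.call(rbind, rows)
  list(results = results,
       summary = data.frame(
         n_fits = nrow(results),
         r_mean = mean(results$r, na.rm = TRUE),
         r_sd = if (nrow(results) > 1) stats::sd(results$r, na.rm = TRUE)
         else NA_real_,
         accuracy_mean = mean(results$accuracy, na.rm = TRUE),
         accuracy_sd = if (nrow(results) > 1)
           stats::sd(results$accuracy, na.rm = TRUE) else NA_real_))
}
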