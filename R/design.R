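#' Thin records to a lower observation frequency
#'
#' Keeps 1 record out of every `keep_every` per animal, by position in the
#' animal's age-sorted sequence of available records (offset selects which
#' phase of the cycle is kept). Emulates recording once every `keep_every`
#' days on gap-free data.
#'
#' @param records Records data frame with `animal_id`, `age_d`.
#' @param keep_every Keep 1 in this many records (1 = identity; 4, 7, 14 in
#'   the reduced-frequency designs).
#' @param offset Integer in `[0, keep_every)`; 0 keeps the first record.
#' @return The thinned records.
#' @export
thin_records <- function(records, keep_every, offset = 0L) {
  stopifnot(keep_every >= 1, offset >= 0, offset < keep_every)
  if (keep_every == 1) return(records)
  keep <- unlist(lapply(split(seq_len(nrow(records)), records$animal_id),
                        function(rows) {
                          rows <- rows[order(records$age_d[rows])]
                          rows[(seq_along(rows) - 1L) %% keep_every == offset]
                        }))
  out <- records[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split records into observation periods
#'
#' Divides the finishing window into contiguous 20-day periods: early
#' [95, 115), middle [115, 135), late [135, 155] (left-closed, so the
#' boundary days 115 and 135 belong to the later period).
#'
#' @param records Records data frame.
#' @param breaks Period boundaries (default `c(95, 115, 135, 155)`).
#' @param labels Period labels.
#' @return Named list of record subsets.
#' @export
split_periods <- function(records, breaks = c(95, 115, 135, 155),
                          labels = c("early", "middle", "late")) {
  k <- length(breaks) - 1L
  stopifnot(length(labels) == k, !is.unsorted(breaks))
  out <- vector("list", k)
  for (i in seq_len(k)) {
    lo <- breaks[i]; hi <- breaks[i + 1]
    inb <- records$age_d >= lo &
      (if (i == k) records$age_d <= hi else records$age_d < hi)
    out[[i]] <- records[inb, , drop = FALSE]
    rownames(out[[i]]) <- NULL
  }
  names(out) <- labels
  out
}

#' Robustness correlations between full and reduced trait versions
#'
#' Phenotypic correlation (Pearson, on animals with both versions) and,
#' when an inverse relationship matrix is supplied, the genetic correlation
#' from a bivariate animal model treating the full and reduced versions as
#' two traits.
#'
#' @param trait_full,trait_reduced Named vectors (by animal id).
#' @param Kinv Optional inverse relationship matrix for the genetic
#'   correlation.
#' @param fixed Optional fixed-effect model matrix (rows in the order of
#'   the union of animals, see Details); default intercept only.
#' @param cg Optional contemporary-group factor, same alignment.
#' @param min_overlap Minimum animals with both versions (default 50).
#' @return List with `r_p`, `n_overlap`, and `r_g`, `h2` when `Kinv` given.
#' @export
robustness_correlations <- function(trait_full, trait_reduced, Kinv = NULL,
                                    fixed = NULL, cg = NULL,
                                    min_overlap = 50L) {
  common <- intersect(names(trait_full), names(trait_reduced))
  common <- common[is.finite(trait_full[common]) &
                     is.finite(trait_reduced[common])]
  if (length(common) < min_overlap)
    stop("fewer than ", min_overlap, " animals with both trait versions")
  r_p <- stats::cor(trait_full[common], trait_reduced[common])
  out <- list(r_p = r_p, n_overlap = length(common))
  if (!is.null(Kinv)) {
    ids <- union(names(trait_full), names(trait_reduced))
    y1 <- trait_full[match(ids, names(trait_full))]
    y2 <- trait_reduced[match(ids, names(trait_reduced))]
    bf <- reml_bivariate(unname(y1), unname(y2), fixed1 = fixed,
                         fixed2 = fixed, animal = ids, cg = cg, Kinv = Kinv)
    out$r_g <- bf$r_g
    out$h2 <- bf$h2
  }
  out
}
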