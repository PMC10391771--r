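#' Sort a pedigree so parents precede offspring
#'
#' Topological sort by generation; unknown parents are coded 0. Errors on
#' cycles or on parents that never appear as animals.
#'
#' @param pedigree Data frame with columns `id`, `sire`, `dam`.
#' @return The pedigree reordered, with attribute `"generation"`.
#' @export
sort_pedigree <- function(pedigree) {
  id <- pedigree$id
  par <- unique(c(pedigree$sire, pedigree$dam))
  par <- par[par != 0]
  if (!all(par %in% id))
    stop("parent(s) referenced but not present as animals: ",
         paste(utils::head(setdiff(par, id)), collapse = ", "))
  n <- nrow(pedigree)
  gen <- rep(NA_integer_, n)
  names(gen) <- id
  remaining <- rep(TRUE, n)
  g <- 0L
  while (any(remaining)) {
    s <- pedigree$sire; d <- pedigree$dam
    ready <- remaining &
      (s == 0 | !is.na(gen[as.character(s)])) &
      (d == 0 | !is.na(gen[as.character(d)]))
    if (!any(ready)) stop("pedigree contains a cycle")
    gen[ready] <- g
    remaining[ready] <- FALSE
    g <- g + 1L
  }
  o <- order(gen, seq_len(n))
  out <- pedigree[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "generation") <- gen[o]
  out
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' @param pedigree Sorted pedigree (parents before offspring; use
#'   [sort_pedigree()]).
#' @return Named vector of inbreeding coefficients F.
#' @export
inbreeding <- function(pedigree) {
  id <- pedigree$id
  n <- length(id)
  s <- match(pedigree$sire, id, nomatch = 0L)
  d <- match(pedigree$dam, id, nomatch = 0L)
  if (any(s >= seq_len(n) & s > 0) || any(d >= seq_len(n) & d > 0))
    stop("pedigree must be sorted parents-before-offspring")
  f <- numeric(n)
  L <- numeric(n)
  ANC <- integer(n)
  # Meuwissen & Luo (1992): trace ancestors of each animal, accumulating
  # the diagonal of the Cholesky factor of A.
  point <- integer(n)
  for (i in seq_len(n)) {
    is_ <- s[i]; id_ <- d[i]
    if (is_ == 0L && id_ == 0L) { f[i] <- 0; next }
    fi <- 0
    L[i] <- 1
    np <- 0L
    point[1] <- i
    np <- 1L
    while (np > 0L) {
      # pop the youngest animal in the list
      j <- max(point[seq_len(np)])
      wh <- which.max(point[seq_len(np)])
      point[wh] <- point[np]; np <- np - 1L
      sj <- s[j]; dj <- d[j]
      dii <- 0.5 - 0.25 * ((if (sj > 0) f[sj] else -1) +
                             (if (dj > 0) f[dj] else -1))
      if (j == i) dii <- dii  # same formula for the animal itself
      fi <- fi + L[j]^2 * dii
      half <- 0.5 * L[j]
      for (p in c(sj, dj)) {
        if (p > 0L) {
          if (L[p] == 0 && !(p %in% point[seq_len(np)])) {
            np <- np + 1L; point[np] <- p
          }
          L[p] <- L[p] + half
        }
      }
      L[j] <- 0
    }
    f[i] <- fi - 1
    L[] <- 0
  }
  stats::setNames(f, id)
}

#' Numerator relationship matrix (tabular method)
#'
#' Dense A matrix by the recursive tabular method; suitable up to a few
#' thousand animals. Diagonal is 1 + F.
#'
#' @param pedigree Pedigree data frame (`id`, `sire`, `dam`); sorted
#'   internally.
#' @return Dense symmetric matrix with dimnames = animal ids.
#' @export
build_A <- function(pedigree) {
  ped <- sort_pedigree(pedigree)
  id <- ped$id
  n <- length(id)
  s <- match(ped$sire, id, nomatch = 0L)
  d <- match(ped$dam, id, nomatch = 0L)
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (si > 0) A[j, si] else 0) +
                      (if (di > 0) A[j, di] else 0))
      A[j, i] <- A[i, j] <- aij
    }
    A[i, i] <- 1 + if (si > 0 && di > 0) 0.5 * A[si, di] else 0
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes
#' 1/d_i to its own diagonal and the corresponding -1/2 and 1/4 terms to its
#' parents, where d_i is the Mendelian-sampling variance
#' (0.5 - 0.25 (F_s + F_d) with both parents known).
#'
#' @param pedigree Pedigree data frame; sorted internally.
#' @return List with `Ainv` (sparse dsCMatrix, dimnames = ids), `logdetA`
#'   (log determinant of A) and `f` (inbreeding coefficients).
#' @export
build_A_inverse <- function(pedigree) {
  ped <- sort_pedigree(pedigree)
  id <- ped$id
  n <- length(id)
  s <- match(ped$sire, id, nomatch = 0L)
  d <- match(ped$dam, id, nomatch = 0L)
  f <- inbreeding(ped)
  fs <- rep(-1, n); fs[s > 0] <- f[s[s > 0]]
  fd <- rep(-1, n); fd[d > 0] <- f[d[d > 0]]
  di <- 0.5 - 0.25 * (fs + fd)
  alpha <- 1 / di
  ii <- list(); jj <- list(); xx <- list()
  add <- function(i, j, v) {
    k <- length(ii) + 1L
    ii[[k]] <<- i; jj[[k]] <<- j; xx[[k]] <<- v
  }
  add(seq_len(n), seq_len(n), alpha)
  both <- which(s > 0)
  add(both, s[both], -0.5 * alpha[both])
  add(s[both], both, -0.5 * alpha[both])
  add(s[both], s[both], 0.25 * alpha[both])
  bothd <- which(d > 0)
  add(bothd, d[bothd], -0.5 * alpha[bothd])
  add(d[bothd], bothd, -0.5 * alpha[bothd])
  add(d[bothd], d[bothd], 0.25 * alpha[bothd])
  cross <- which(s > 0 & d > 0)
  add(s[cross], d[cross], 0.25 * alpha[cross])
  add(d[cross], s[cross], 0.25 * alpha[cross])
  Ainv <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                               x = unlist(xx), dims = c(n, n),
                               dimnames = list(id, id), symmetric = FALSE)
  Ainv <- Matrix::forceSymmetric((Ainv + Matrix::t(Ainv)) / 2)
  # log|A| = sum log d_i (A = T D T' with unit-triangular T)
  list(Ainv = Ainv, logdetA = sum(log(di)), f = f)
}

#' Genomic relationship matrix (first method)
#'
#' Z = M - 2p, G = ZZ' / (2 * sum p_j (1 - p_j)). Monomorphic SNPs are
#' dropped; allele frequencies default to the observed ones.
#'
#' @param dosages Animals x SNPs matrix of 0/1/2 dosages (rownames = ids).
#' @param freq Optional allele frequencies; computed from `dosages` if
#'   missing.
#' @return Dense genomic relationship matrix.
#' @export
build_G <- function(dosages, freq = NULL) {
  if (is.null(freq)) freq <- colMeans(dosages) / 2
  poly <- freq > 0 & freq < 1
  if (!any(poly)) stop("all SNPs monomorphic")
  M <- dosages[, poly, drop = FALSE]
  p <- freq[poly]
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(rownames(dosages), rownames(dosages))
  G
}

#' Single-step H-inverse
#'
#' Combines pedigree and genomic relationships:
#' `Hinv = Ainv + [0 0; 0 Ginv* - A22inv]` on the genotyped block, with
#' `G* = (1 - blend) * (beta G + alpha) + blend * A22` where (alpha, beta)
#' scale G so its mean diagonal and mean off-diagonal match A22.
#'
#' @param pedigree Pedigree data frame.
#' @param G Genomic relationship matrix for the genotyped animals (dimnames
#'   must identify them).
#' @param genotyped Ids of genotyped animals (defaults to rownames of G).
#' @param blend Weight on A22 in the blended G* (default 0.05).
#' @param tol Condition tolerance; a singular blended G* is an error.
#' @return List with `Hinv` (sparse, full pedigree order), `Ainv`,
#'   `logdetH`, `logdetA`, `A22`, `Gstar` and the scaling coefficients.
#' @export
build_H_inverse <- function(pedigree, G = NULL, genotyped = rownames(G),
                            blend = 0.05, tol = 1e-12) {
  ai <- build_A_inverse(pedigree)
  if (is.null(G) || length(genotyped) == 0)
    return(list(Hinv = ai$Ainv, Ainv = ai$Ainv, logdetH = ai$logdetA,
                logdetA = ai$logdetA))
  ids <- rownames(ai$Ainv)
  if (!all(genotyped %in% ids)) stop("genotyped animals must be in pedigree")
  A <- build_A(pedigree)[genotyped, genotyped, drop = FALSE]
  G <- G[genotyped, genotyped, drop = FALSE]
  n2 <- length(genotyped)
  offd <- row(A) != col(A)
  # match means: beta * G + alpha = A22 in mean diagonal and off-diagonal
  gd <- mean(diag(G)); go <- if (n2 > 1) mean(G[offd]) else 0
  ad <- mean(diag(A)); ao <- if (n2 > 1) mean(A[offd]) else 0
  beta <- if (abs(gd - go) > tol) (ad - ao) / (gd - go) else 1
  alpha <- ad - beta * gd
  Gs <- (1 - blend) * (beta * G + alpha) + blend * A
  ev <- eigen(Gs, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < tol * max(ev))
    stop("blended G* is singular; raise the blend weight")
  Gs_inv <- chol2inv(chol(Gs))
  A22_inv <- chol2inv(chol(A))
  delta <- Gs_inv - A22_inv
  gi <- match(genotyped, ids)
  Hinv <- as(ai$Ainv, "TsparseMatrix")
  Dd <- Matrix::sparseMatrix(i = rep(gi, times = n2),
                             j = rep(gi, each = n2),
                             x = as.numeric(t(delta)),
                             dims = dim(ai$Ainv), dimnames = dimnames(ai$Ainv))
  Hinv <- Matrix::forceSymmetric(ai$Ainv + Dd)
  # log|H| = log|A| + log|G*| - log|A22|
  logdetH <- ai$logdetA +
    as.numeric(determinant(Gs, logarithm = TRUE)$modulus) -
    as.numeric(determinant(A, logarithm = TRUE)$modulus)
  list(Hinv = Hinv, Ainv = ai$Ainv, logdetH = logdetH, logdetA = ai$logdetA,
       A22 = A, Gstar = Gs, alpha = alpha, beta = beta)
}
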