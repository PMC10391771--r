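#' Bivariate REML animal model
#'
#' Two-trait animal model with a 2x2 additive genetic covariance matrix
#' (Kronecker with the relationship matrix K), a 2x2 contemporary-group
#' covariance matrix, and trait-specific independent residuals (residual
#' covariance fixed at zero, so the traits may be recorded on different or
#' overlapping animals). The restricted likelihood is maximized directly
#' over a log-Cholesky parameterization of the two covariance matrices --
#' which keeps them positive semi-definite by construction -- plus the two
#' log residual variances.
#'
#' @param y1,y2 Numeric responses aligned with `animal`; `NA` = trait not
#'   recorded.
#' @param fixed1,fixed2 Fixed-effect model matrices per trait (or NULL for
#'   intercepts).
#' @param animal Animal ids aligned with the responses.
#' @param cg Optional contemporary-group factor.
#' @param Kinv Inverse relationship matrix with dimnames.
#' @param logdetK `log|K|` (computed if NULL).
#' @param init Optional list with `Sa`, `Sc` (2x2), `se2` (length 2).
#' @param max_iter Optimizer iteration cap.
#' @param se Compute a standard error for the genetic correlation from the
#'   inverse numerical observed information (delta method).
#' @return Object of class `reml_biv`: `Sa`, `Sc`, `se2`, `r_g`, `r_g_se`,
#'   `loglik`, `converged`, plus per-trait heritabilities `h2`.
#' @export
reml_bivariate <- function(y1, y2, fixed1 = NULL, fixed2 = NULL, animal,
                           cg = NULL, Kinv, logdetK = NULL, init = NULL,
                           max_iter = 1000L, se = FALSE) {
  if (all(!is.finite(y1)) || all(!is.finite(y2)))
    stop("a trait is entirely missing")
  animal <- as.character(animal)
  ids <- rownames(Kinv)
  if (!all(animal[is.finite(y1) | is.finite(y2)] %in% ids))
    stop("animals missing from Kinv")
  q <- length(ids)
  Kinv <- methods::as(methods::as(Kinv, "generalMatrix"), "CsparseMatrix")
  if (is.null(logdetK))
    logdetK <- -as.numeric(Matrix::determinant(Kinv, logarithm = TRUE)$modulus)

  use_cg <- !is.null(cg)
  if (use_cg) cg <- factor(cg)
  m <- if (use_cg) nlevels(cg) else 0L

  prep <- function(y, fixed) {
    keep <- is.finite(y)
    n <- sum(keep)
    X <- if (is.null(fixed)) matrix(1, n, 1) else
      as.matrix(fixed)[keep, , drop = FALSE]
    qrX <- qr(X)
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    Z <- Matrix::sparseMatrix(i = seq_len(n),
                              j = match(animal[keep], ids), dims = c(n, q))
    W <- if (use_cg) Matrix::sparseMatrix(i = seq_len(n),
                                          j = as.integer(cg[keep]),
                                          dims = c(n, m)) else NULL
    list(y = y[keep], X = Matrix::Matrix(X, sparse = TRUE), Z = Z, W = W,
         n = n, p = ncol(X))
  }
  t1 <- prep(y1, fixed1); t2 <- prep(y2, fixed2)
  p1 <- t1$p; p2 <- t2$p

  # column blocks: b1 b2 | a1 a2 | c1 c2
  zero <- function(nr, nc) Matrix::Matrix(0, nr, nc, sparse = TRUE)
  C1 <- cbind(t1$X, zero(t1$n, p2), t1$Z, zero(t1$n, q),
              if (use_cg) cbind(t1$W, zero(t1$n, m)) else NULL)
  C2 <- cbind(zero(t2$n, p1), t2$X, zero(t2$n, q), t2$Z,
              if (use_cg) cbind(zero(t2$n, m), t2$W) else NULL)
  CtC1 <- Matrix::crossprod(C1); CtC2 <- Matrix::crossprod(C2)
  Cty1 <- as.numeric(Matrix::crossprod(C1, t1$y))
  Cty2 <- as.numeric(Matrix::crossprod(C2, t2$y))
  yty1 <- sum(t1$y^2); yty2 <- sum(t2$y^2)
  p <- p1 + p2
  Im <- if (use_cg) Matrix::Diagonal(m) else NULL

  assemble <- function(th) {
    La <- matrix(c(exp(th[1]), th[2], 0, exp(th[3])), 2, 2)
    Sa <- La %*% t(La)
    k <- 3L
    if (use_cg) {
      Lc <- matrix(c(exp(th[4]), th[5], 0, exp(th[6])), 2, 2)
      Sc <- Lc %*% t(Lc)
      k <- 6L
    } else Sc <- NULL
    se2 <- exp(th[k + 1:2])
    list(Sa = Sa, Sc = Sc, se2 = se2)
  }
  neg2ll <- function(th) {
    pa <- assemble(th)
    Sa_i <- tryCatch(solve(pa$Sa), error = function(e) NULL)
    if (is.null(Sa_i)) return(1e10)
    blocks <- list(Matrix::Diagonal(p, 0), Matrix::kronecker(Sa_i, Kinv))
    if (use_cg) blocks <- c(blocks, Matrix::kronecker(solve(pa$Sc), Im))
    M <- CtC1 / pa$se2[1] + CtC2 / pa$se2[2] + Matrix::bdiag(blocks)
    M <- Matrix::forceSymmetric(M)
    ch <- tryCatch(suppressWarnings(
      Matrix::Cholesky(M, LDL = FALSE, perm = TRUE)),
      error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    rhs <- Cty1 / pa$se2[1] + Cty2 / pa$se2[2]
    sol <- as.numeric(Matrix::solve(ch, rhs))
    logdetM <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
    ypy <- yty1 / pa$se2[1] + yty2 / pa$se2[2] - sum(rhs * sol)
    val <- (t1$n + t2$n - p) * log(2 * pi) +
      t1$n * log(pa$se2[1]) + t2$n * log(pa$se2[2]) +
      q * as.numeric(determinant(pa$Sa, logarithm = TRUE)$modulus) +
      2 * logdetK +
      (if (use_cg) m * as.numeric(determinant(pa$Sc,
                                              logarithm = TRUE)$modulus) else 0) +
      logdetM + ypy
    if (!is.finite(val)) 1e10 else val
  }

  v1 <- stats::var(t1$y); v2 <- stats::var(t2$y)
  if (is.null(init))
    init <- list(Sa = diag(c(0.3 * v1, 0.3 * v2)),
                 Sc = diag(c(0.1 * v1, 0.1 * v2)),
                 se2 = c(0.6 * v1, 0.6 * v2))
  th0 <- c(0.5 * log(init$Sa[1, 1]), 0, 0.5 * log(init$Sa[2, 2]))
  if (use_cg) th0 <- c(th0, 0.5 * log(init$Sc[1, 1]), 0,
                       0.5 * log(init$Sc[2, 2]))
  th0 <- c(th0, log(init$se2))

  opt <- stats::optim(th0, neg2ll, method = "Nelder-Mead",
                      control = list(maxit = max_iter, reltol = 1e-12))
  opt <- stats::optim(opt$par, neg2ll, method = "Nelder-Mead",
                      control = list(maxit = max_iter, reltol = 1e-12))
  pa <- assemble(opt$par)
  r_g <- pa$Sa[1, 2] / sqrt(pa$Sa[1, 1] * pa$Sa[2, 2])

  r_g_se <- NA_real_
  if (se) {
    H <- num_hessian(function(th) 0.5 * neg2ll(th), opt$par,
                     h = rep(1e-4, length(opt$par)))
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      g <- sapply(seq_along(opt$par), function(j) {
        e <- opt$par; e[j] <- e[j] + 1e-5
        pe <- assemble(e)
        (pe$Sa[1, 2] / sqrt(pe$Sa[1, 1] * pe$Sa[2, 2]) - r_g) / 1e-5
      })
      vr <- drop(t(g) %*% V %*% g)
      if (is.finite(vr) && vr > 0) r_g_se <- sqrt(vr)
    }
  }

  tot1 <- pa$Sa[1, 1] + (if (use_cg) pa$Sc[1, 1] else 0) + pa$se2[1]
  tot2 <- pa$Sa[2, 2] + (if (use_cg) pa$Sc[2, 2] else 0) + pa$se2[2]
  structure(list(Sa = pa$Sa, Sc = pa$Sc, se2 = pa$se2, r_g = r_g,
                 r_g_se = r_g_se,
                 h2 = c(pa$Sa[1, 1] / tot1, pa$Sa[2, 2] / tot2),
                 loglik = -0.5 * opt$value,
                 converged = opt$convergence == 0,
                 n = c(t1$n, t2$n)),
            class = "reml_biv")
}

#' @export
print.reml_biv <- function(x, ...) {
  cat("Bivariate REML animal model, n =", paste(x$n, collapse = " / "), "\n")
  cat("Genetic covariance:\n"); print(round(x$Sa, 5))
  cat("r_g =", format(x$r_g, digits = 4))
  if (is.finite(x$r_g_se)) cat(" (se", format(x$r_g_se, digits = 3), ")")
  cat("  h2 =", paste(round(x$h2, 3), collapse = ", "), "\n")
  invisible(x)
}
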