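#' Univariate REML animal model
#'
#' Fits `y = Xb + Za + Wc + e` with `a ~ N(0, K sigma2_a)` for a pedigree
#' (A), genomic (G) or combined (H) relationship matrix K, contemporary
#' groups `c ~ N(0, I sigma2_c)` and i.i.d. residuals, by restricted maximum
#' likelihood.
#'
#' The default engine maximizes the restricted log-likelihood directly on
#' the log-variance scale: each evaluation assembles the mixed-model
#' equations (MME), takes one sparse Cholesky factorization and uses the
#' determinant identity `log|V| + log|X'V^-1 X| = log|R| + log|G| + log|M|`.
#' `method = "em"` instead runs classical EM-REML iterations on the dense
#' MME (expectation of quadratic forms via the full inverse) and is intended
#' for small problems and for verifying the likelihood is non-decreasing;
#' both methods maximize the same criterion.
#'
#' @param y Numeric response (one record per animal); `NA`s are dropped.
#' @param fixed Fixed-effect model matrix (rows aligned with `y`), or
#'   `NULL` for an intercept only. Aliased columns are dropped.
#' @param animal Animal ids aligned with `y`; must appear in
#'   `rownames(Kinv)`.
#' @param cg Optional contemporary-group factor aligned with `y`.
#' @param Kinv Inverse relationship matrix (sparse or dense) over all
#'   animals to evaluate, with dimnames.
#' @param logdetK `log|K|`; computed from `Kinv` when `NULL`.
#' @param method `"direct"` (default) or `"em"`.
#' @param init Optional starting values `c(a = , cg = , e = )` as variances.
#' @param max_iter,tol Iteration cap and relative convergence tolerance.
#' @param se Compute approximate standard errors from the inverse numerical
#'   observed information (default TRUE).
#' @return An object of class `reml_fit` with components `sigma2` (named
#'   vector a/cg/e), `h2`, `c2`, `se` (of components, h2, c2), `loglik`,
#'   `ebv` (all animals in `Kinv`), `fixef`, `cgef`, `converged`, `n_iter`,
#'   and the model frame pieces needed to re-solve the MME.
#' @export
reml_univariate <- function(y, fixed = NULL, animal, cg = NULL, Kinv,
                            logdetK = NULL, method = c("direct", "em"),
                            init = NULL, max_iter = 500L, tol = 1e-8,
                            se = TRUE) {
  method <- match.arg(method)
  keep <- is.finite(y)
  y <- y[keep]
  n <- length(y)
  if (n < 3L) stop("need at least 3 observations")
  X <- if (is.null(fixed)) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  else as.matrix(fixed)[keep, , drop = FALSE]
  qrX <- qr(X)
  X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  p <- ncol(X)
  animal <- as.character(animal)[keep]
  ids <- rownames(Kinv)
  if (!all(animal %in% ids)) stop("animals missing from Kinv")
  q <- length(ids)
  Kinv <- methods::as(methods::as(Kinv, "generalMatrix"), "CsparseMatrix")
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = match(animal, ids),
                            dims = c(n, q))
  use_cg <- !is.null(cg)
  if (use_cg) {
    cg <- droplevels(factor(cg[keep]))
    if (nlevels(cg) < 2L) { use_cg <- FALSE; cg <- NULL }
  }
  W <- if (use_cg) Matrix::sparseMatrix(i = seq_len(n),
                                        j = as.integer(cg),
                                        dims = c(n, nlevels(cg))) else NULL
  m <- if (use_cg) nlevels(cg) else 0L
  if (is.null(logdetK))
    logdetK <- -as.numeric(Matrix::determinant(Kinv, logarithm = TRUE)$modulus)

  C <- if (use_cg) cbind(Matrix::Matrix(X, sparse = TRUE), Z, W)
  else cbind(Matrix::Matrix(X, sparse = TRUE), Z)
  CtC <- Matrix::crossprod(C)
  Cty <- as.numeric(Matrix::crossprod(C, y))
  yty <- sum(y^2)
  ia <- p + seq_len(q)
  ic <- if (use_cg) p + q + seq_len(m) else integer()

  chol_cache <- NULL
  mme <- function(s2) {
    blocks <- list(Matrix::Diagonal(p, 0), Kinv / s2[["a"]])
    if (use_cg) blocks <- c(blocks, Matrix::Diagonal(m, 1 / s2[["cg"]]))
    M <- CtC / s2[["e"]] + Matrix::bdiag(blocks)
    M <- Matrix::forceSymmetric(M)
    ok <- tryCatch({
      suppressWarnings({
        if (is.null(chol_cache))
          chol_cache <<- Matrix::Cholesky(M, LDL = FALSE, perm = TRUE)
        else chol_cache <<- Matrix::update(chol_cache, M)
      })
      TRUE
    }, error = function(e) FALSE)
    if (!ok) return(NULL)
    sol <- as.numeric(Matrix::solve(chol_cache, Cty / s2[["e"]]))
    logdetM <- 2 * as.numeric(Matrix::determinant(chol_cache, sqrt = TRUE)$modulus)
    list(sol = sol, logdetM = logdetM)
  }
  neg2ll <- function(s2) {
    r <- mme(s2)
    if (is.null(r)) return(1e10)     # indefinite trial point
    ypy <- yty / s2[["e"]] - sum(Cty * r$sol) / s2[["e"]]
    val <- (n - p) * log(2 * pi) + n * log(s2[["e"]]) +
      q * log(s2[["a"]]) + logdetK +
      (if (use_cg) m * log(s2[["cg"]]) else 0) +
      r$logdetM + ypy
    if (!is.finite(val)) 1e10 else val
  }
  unpack <- function(par) {
    s2 <- exp(par)
    names(s2) <- if (use_cg) c("a", "cg", "e") else c("a", "e")
    s2
  }

  vy <- stats::var(y)
  if (is.null(init))
    init <- c(a = 0.3 * vy, cg = if (use_cg) 0.1 * vy else NULL,
              e = 0.6 * vy)
  init <- init[if (use_cg) c("a", "cg", "e") else c("a", "e")]

  trace_ll <- NULL
  if (method == "direct") {
    fn <- function(par) neg2ll(unpack(par))
    lb <- log(1e-8 * vy); ub <- log(1e4 * vy)
    opt <- tryCatch(
      stats::optim(log(unlist(init)), fn, method = "L-BFGS-B",
                   lower = lb, upper = ub,
                   control = list(maxit = max_iter, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(opt))
      opt <- stats::optim(log(unlist(init)), fn, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12))
    s2 <- unpack(opt$par)
    converged <- opt$convergence == 0
    n_iter <- opt$counts[1]
    ll <- -0.5 * opt$value
  } else {
    # EM-REML on the dense MME; monotone in the restricted likelihood
    s2 <- unlist(init)
    Md <- function(s2) {
      M <- as.matrix(CtC) / s2[["e"]]
      M[ia, ia] <- M[ia, ia] + as.matrix(Kinv) / s2[["a"]]
      if (use_cg) M[ic, ic] <- M[ic, ic] + diag(m) / s2[["cg"]]
      M
    }
    converged <- FALSE; n_iter <- 0L
    for (it in seq_len(max_iter)) {
      M <- Md(s2)
      Minv <- solve(M)
      sol <- as.numeric(Minv %*% (Cty / s2[["e"]]))
      a_hat <- sol[ia]
      new <- s2
      Kq <- as.matrix(Kinv)
      # M is in R^-1 form, so Minv already equals sigma2_e times the
      # lambda-form C-inverse: the PEV terms need no extra factor
      new[["a"]] <- (sum(a_hat * (Kq %*% a_hat)) +
                       sum(Kq * Minv[ia, ia])) / q
      if (use_cg) {
        c_hat <- sol[ic]
        new[["cg"]] <- (sum(c_hat^2) + sum(diag(Minv)[ic])) / m
      }
      new[["e"]] <- (yty - sum(sol * Cty)) / (n - p)
      trace_ll <- c(trace_ll, -0.5 * neg2ll(s2))
      delta <- max(abs(new - s2) / pmax(abs(s2), 1e-12))
      s2 <- new
      n_iter <- it
      if (delta < tol) { converged <- TRUE; break }
    }
    trace_ll <- c(trace_ll, -0.5 * neg2ll(s2))
    ll <- -0.5 * neg2ll(s2)
  }

  final <- mme(s2)
  if (is.null(final)) stop("mixed-model equations singular at the optimum")
  sol <- final$sol
  tot <- sum(s2)
  h2 <- s2[["a"]] / tot
  c2 <- if (use_cg) s2[["cg"]] / tot else 0

  se_out <- NULL
  if (se) {
    H <- num_hessian(function(v) {
      vv <- s2; vv[] <- v
      if (any(vv <= 0)) return(NA_real_)
      0.5 * neg2ll(vv)
    }, unlist(s2))
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(is.finite(V)) && all(diag(V) > 0)) {
      g_h2 <- grad_ratio(unlist(s2), which(names(s2) == "a"))
      se_h2 <- sqrt(drop(t(g_h2) %*% V %*% g_h2))
      se_c2 <- if (use_cg) {
        g_c2 <- grad_ratio(unlist(s2), which(names(s2) == "cg"))
        sqrt(drop(t(g_c2) %*% V %*% g_c2))
      } else NA_real_
      se_out <- list(sigma2 = sqrt(pmax(diag(V), 0)), h2 = se_h2, c2 = se_c2)
    }
  }

  structure(list(
    sigma2 = s2, h2 = h2, c2 = c2, loglik = ll, se = se_out,
    converged = converged, n_iter = n_iter, loglik_trace = trace_ll,
    fixef = stats::setNames(sol[seq_len(p)], colnames(X)),
    ebv = stats::setNames(sol[ia], ids),
    cgef = if (use_cg) stats::setNames(sol[ic], levels(cg)) else NULL,
    n = n, p = p, method = method,
    model = list(y = y, X = X, animal = animal, cg = cg, Kinv = Kinv,
                 logdetK = logdetK, ids = ids)),
    class = "reml_fit")
}

# gradient of s2[j]/sum(s2) w.r.t. s2
grad_ratio <- function(s2, j) {
  tot <- sum(s2)
  g <- rep(-s2[j] / tot^2, length(s2))
  g[j] <- g[j] + 1 / tot
  g
}

# central-difference Hessian
num_hessian <- function(f, x, h = pmax(1e-4 * abs(x), 1e-8)) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) for (j in i:k) {
    if (i == j) {
      H[i, i] <- (f(x + h * (seq_len(k) == i)) - 2 * f(x) +
                    f(x - h * (seq_len(k) == i))) / h[i]^2
    } else {
      ei <- h * (seq_len(k) == i); ej <- h * (seq_len(k) == j)
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
           f(x - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML animal model (", x$method, "), n = ", x$n, "\n", sep = "")
  comp <- rbind(`variance` = x$sigma2)
  print(round(comp, 5))
  cat("h2 =", format(x$h2, digits = 4))
  if (!is.null(x$se)) cat(" (se", format(x$se$h2, digits = 3), ")")
  if (!is.null(x$cgef))
    cat(", c2 =", format(x$c2, digits = 4))
  cat(", logLik =", format(x$loglik, digits = 8),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' @export
summary.reml_fit <- function(object, ...) {
  out <- list(sigma2 = object$sigma2, h2 = object$h2, c2 = object$c2,
              se = object$se, loglik = object$loglik,
              fixef = object$fixef, n = object$n,
              converged = object$converged)
  class(out) <- "summary.reml_fit"
  out
}

#' @export
print.summary.reml_fit <- function(x, ...) {
  cat("Variance components:\n")
  print(x$sigma2)
  if (!is.null(x$se)) {
    cat("Approximate SEs:\n")
    print(x$se$sigma2)
  }
  cat(sprintf("h2 = %.4f  c2 = %.4f  logLik = %.4f\n", x$h2, x$c2, x$loglik))
  cat("Fixed effects:\n")
  print(x$fixef)
  invisible(x)
}

#' @export
coef.reml_fit <- function(object, ...) object$fixef

#' Extract estimated breeding values
#'
#' @param object A `reml_fit`.
#' @param ... Unused.
#' @return Named vector of EBVs for every animal in the relationship matrix.
#' @export
ebv <- function(object, ...) UseMethod("ebv")

#' @export
ebv.reml_fit <- function(object, ...) object$ebv

#' Solve the mixed-model equations at fixed variance components
#'
#' Re-solves BLUP/BLUE solutions for a (possibly masked) subset of the
#' observations used in a fitted model, keeping the variance components
#' fixed. Used by the cross-validation masking schemes.
#'
#' @param fit A `reml_fit`.
#' @param mask Animal ids whose phenotypes are removed before solving.
#' @return List with `fixef`, `ebv`, `cgef`.
#' @export
solve_mme <- function(fit, mask = NULL) {
  md <- fit$model
  keep <- !(md$animal %in% as.character(mask))
  if (!any(keep)) stop("masking removed every observation")
  y <- md$y[keep]
  X <- md$X[keep, , drop = FALSE]
  qrX <- qr(X)
  X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  p <- ncol(X)
  n <- length(y)
  ids <- md$ids
  q <- length(ids)
  Z <- Matrix::sparseMatrix(i = seq_len(n),
                            j = match(md$animal[keep], ids),
                            dims = c(n, q))
  use_cg <- !is.null(md$cg)
  W <- if (use_cg) Matrix::sparseMatrix(
    i = seq_len(n), j = as.integer(md$cg[keep]),
    dims = c(n, nlevels(md$cg))) else NULL
  m <- if (use_cg) nlevels(md$cg) else 0L
  s2 <- fit$sigma2
  C <- if (use_cg) cbind(Matrix::Matrix(X, sparse = TRUE), Z, W)
  else cbind(Matrix::Matrix(X, sparse = TRUE), Z)
  blocks <- list(Matrix::Diagonal(p, 0), md$Kinv / s2[["a"]])
  if (use_cg) blocks <- c(blocks, Matrix::Diagonal(m, 1 / s2[["cg"]]))
  M <- Matrix::crossprod(C) / s2[["e"]] + Matrix::bdiag(blocks)
  rhs <- as.numeric(Matrix::crossprod(C, y)) / s2[["e"]]
  sol <- as.numeric(Matrix::solve(Matrix::forceSymmetric(M), rhs))
  list(fixef = stats::setNames(sol[seq_len(p)], colnames(X)),
       ebv = stats::setNames(sol[p + seq_len(q)], ids),
       cgef = if (use_cg) stats::setNames(sol[p + q + seq_len(m)],
                                          levels(md$cg)) else NULL)
}

#' Genetic coefficient of variation
#'
#' For traits already on a natural-log scale (lnvar, lnMSE), the additive SD
#' itself is the genetic coefficient of variation of the underlying
#' (exponential-scale) variability; for linear-scale traits GCV is the
#' additive SD divided by the trait mean.
#'
#' @param vc A `reml_fit` or a number (`sigma2_a`).
#' @param log_scale Is the trait on a log scale?
#' @param mean Trait mean, required when `log_scale = FALSE`.
#' @return The GCV (proportion; multiply by 100 for percent).
#' @export
gcv <- function(vc, log_scale = TRUE, mean = NULL) {
  s2a <- if (inherits(vc, "reml_fit")) vc$sigma2[["a"]] else vc
  if (s2a < 0) stop("sigma2_a must be >= 0")
  if (log_scale) return(sqrt(s2a))
  if (is.null(mean) || mean == 0)
    stop("trait mean required (and nonzero) for linear-scale GCV")
  sqrt(s2a) / mean
}
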