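#' Fit a pairwise mixed model with MLPE covariance
#'
#' Regresses a dyadic genetic distance on dyadic predictors under the
#' maximum-likelihood population-effects (MLPE) covariance: each dyad loads
#' on iid normal random effects of its two members,
#' `y_ij = b0 + sum_m b_m x_m,ij + u_i + u_j + e_ij`, which induces
#' correlation between dyads sharing an individual. Predictors are z-scored
#' before fitting. The node-variance / residual-variance ratio is profiled
#' out and the remaining one-dimensional likelihood is maximized to high
#' precision; solves use the Woodbury identity on the dyad-incidence
#' design, so cost scales with the number of individuals, not dyads.
#'
#' @param y a [pairwise_matrix()] response (e.g. Rousset's a-hat).
#' @param X a [pairwise_matrix()], or named list of them, of dyadic
#'   predictors (e.g. commute or Euclidean distances).
#' @param method `"ML"` (default; used for model comparison) or `"REML"`.
#' @param standardize z-score the predictors (default `TRUE`).
#' @param fix_ratio optionally fix the node/residual variance ratio instead
#'   of estimating it; `fix_ratio = 0` gives the degenerate covariance
#'   under which the fit reduces exactly to ordinary least squares on the
#'   dyads.
#' @return An `mlpe_fit`: coefficients `beta` (with `se`), variance
#'   components `varcomp` (node, residual), `logL`, parameter count `k`,
#'   `n_individuals`, `aic`, `aicc`.
#'
#' @details The information-criterion parameter count is
#'   `k = n_fixed_effects + 2` (intercept and slopes, node variance,
#'   residual variance). `aicc` uses `n = n_individuals`, the convention
#'   under which printed AICc values of optimized-surface model tables are
#'   reproducible from their log-likelihoods.
#' @export
fit_mlpe <- function(y, X, method = c("ML", "REML"), standardize = TRUE,
                     fix_ratio = NULL) {
  method <- match.arg(method)
  if (inherits(X, "pairwise_matrix")) X <- list(x = X)
  if (!length(X)) stop("no predictors supplied")
  if (is.null(names(X)) || any(names(X) == ""))
    names(X) <- paste0("x", seq_along(X))
  ids <- pm_ids(y)
  n <- length(ids)
  if (n < 4L) stop("need at least four individuals")
  dy <- dyad_values(y)
  yv <- dy$value
  if (anyNA(yv)) stop("response has missing dyads")
  Xcols <- lapply(X, function(m) dyad_values(pm_restrict(m, ids))$value)
  Xm <- do.call(cbind, Xcols)
  if (anyNA(Xm)) stop("predictors have missing dyads")
  if (standardize) {
    sds <- apply(Xm, 2, stats::sd)
    if (any(sds == 0)) stop("constant predictor: ",
                            paste(names(X)[sds == 0], collapse = ", "))
    Xm <- scale(Xm)
  }
  Xd <- cbind(`(Intercept)` = 1, Xm)
  q <- ncol(Xd)
  p <- length(yv)
  qrX <- qr(Xd)
  if (qrX$rank < q) {
    bad <- colnames(Xd)[qrX$pivot[(qrX$rank + 1):q]]
    stop("rank-deficient predictors; collinear terms: ",
         paste(bad, collapse = ", "))
  }

  ii <- match(dy$id1, ids)
  jj <- match(dy$id2, ids)
  Z <- Matrix::sparseMatrix(i = rep(seq_len(p), 2L), j = c(ii, jj), x = 1,
                            dims = c(p, n))
  ZtZ <- as.matrix(Matrix::crossprod(Z))
  Zty <- as.vector(Matrix::crossprod(Z, yv))
  ZtX <- as.matrix(Matrix::crossprod(Z, Xd))

  # profiled -2*logLik over theta = sigma2_node / sigma2_resid
  profile_fit <- function(ltheta) {
    th <- exp(ltheta)
    Mi <- chol2inv(chol(diag(n) / th + ZtZ))
    applyW_t <- function(Ztv, v) v - as.vector(Z %*% (Mi %*% Ztv))
    Wy <- applyW_t(Zty, yv)
    WX <- Xd - as.matrix(Z %*% (Mi %*% ZtX))
    XtWX <- crossprod(Xd, WX)
    XtWy <- crossprod(Xd, Wy)
    beta <- solve(XtWX, XtWy)
    r <- yv - as.vector(Xd %*% beta)
    Ztr <- Zty - ZtX %*% beta
    rss <- sum(r * (r - as.vector(Z %*% (Mi %*% Ztr))))
    logdetV <- 2 * sum(log(diag(chol(diag(n) + th * ZtZ))))
    if (method == "ML") {
      s2 <- rss / p
      logL <- -0.5 * (p * log(2 * pi * s2) + logdetV + p)
    } else {
      s2 <- rss / (p - q)
      logL <- -0.5 * ((p - q) * log(2 * pi * s2) + logdetV +
                        determinant(XtWX, logarithm = TRUE)$modulus +
                        (p - q))
    }
    list(logL = as.numeric(logL), beta = beta, s2 = s2, th = th,
         XtWX = XtWX)
  }

  if (!is.null(fix_ratio)) {
    if (fix_ratio < 0) stop("fix_ratio must be non-negative")
    best <- profile_fit(log(max(fix_ratio, 1e-300)))
    best$th <- fix_ratio
  } else {
    obj <- function(ltheta) -profile_fit(ltheta)$logL
    opt <- stats::optimize(obj, interval = c(-25, 15), tol = 1e-9)
    # boundary: vanishing node variance (OLS limit)
    cand <- c(opt$minimum, -25)
    fits <- lapply(cand, profile_fit)
    best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "logL"))]]
    if (best$th < 2e-11) best$th <- 0
  }

  beta <- stats::setNames(as.vector(best$beta), colnames(Xd))
  se <- sqrt(diag(best$s2 * solve(best$XtWX)))
  k <- q + 2L
  out <- list(beta = beta, se = stats::setNames(se, colnames(Xd)),
              varcomp = c(node = best$th * best$s2, residual = best$s2),
              logL = best$logL, k = k, n_individuals = n, n_dyads = p,
              method = method,
              aic = -2 * best$logL + 2 * k,
              aicc = if (n > k + 1L) aicc(best$logL, k, n) else NA_real_)
  class(out) <- "mlpe_fit"
  out
}

#' @export
print.mlpe_fit <- function(x, ...) {
  cat(sprintf("<mlpe_fit> %s; %d individuals, %d dyads\n",
              x$method, x$n_individuals, x$n_dyads))
  print(round(cbind(beta = x$beta, se = x$se), 5))
  cat(sprintf("  varcomp: node %.5g, residual %.5g\n",
              x$varcomp["node"], x$varcomp["residual"]))
  cat(sprintf("  logL = %.4f, k = %d, AIC = %.4f, AICc = %.4f\n",
              x$logL, x$k, x$aic, x$aicc))
  invisible(x)
}

#' @export
logLik.mlpe_fit <- function(object, ...) {
  structure(object$logL, df = object$k, nobs = object$n_dyads,
            class = "logLik")
}

#' Small-sample corrected Akaike Information Criterion
#'
#' `AICc = -2 logL + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param logL maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size; must exceed `k + 1`.
#' @return The AICc value.
#' @export
aicc <- function(logL, k, n) {
  if (any(n <= k + 1)) stop("AICc undefined: n must exceed k + 1")
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Isolation-by-distance regression
#'
#' Pearson correlation between a genetic distance and Euclidean distance
#' over dyads, with the variance explained expressed as a percentage.
#'
#' @param genetic,euclid [pairwise_matrix()] objects over the same ids.
#' @return List with `pearson_r` and `r_squared_pct` (= `100 r^2`).
#' @export
ibd_regression <- function(genetic, euclid) {
  ids <- pm_ids(genetic)
  gv <- dyad_values(genetic)$value
  ev <- dyad_values(pm_restrict(euclid, ids))$value
  keep <- is.finite(gv) & is.finite(ev)
  r <- stats::cor(gv[keep], ev[keep])
  list(pearson_r = r, r_squared_pct = 100 * r^2)
}
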