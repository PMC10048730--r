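#' Bootstrap model selection across candidate distance matrices
#'
#' Repeatedly subsamples individuals, refits the MLPE model of genetic
#' distance on each candidate's (fixed, not re-optimized) distance matrix
#' restricted to the subsample, ranks candidates by AICc, and accumulates
#' the rank, the Akaike weight `w_m = exp(-D_m/2) / sum exp(-D/2)` and a
#' top-model indicator. Reported per candidate: parameter count `k`,
#' average rank, average weight `omega_bar`, and `pi_hat`, the percentage
#' of iterations in which the candidate ranked first — the bootstrap
#' analogue of the Akaike weight.
#'
#' AICc ties are broken in favor of fewer parameters; remaining exact ties
#' are resolved uniformly at random (reproducible under `seed`).
#'
#' @param candidates named list of [pairwise_matrix()] distance candidates;
#'   include a Euclidean `"Distance"` null.
#' @param genetic a [pairwise_matrix()] of genetic distances.
#' @param frac subsample fraction in (0, 1); each iteration uses
#'   `ceiling(frac * n)` individuals without replacement.
#' @param iters bootstrap iterations.
#' @param seed RNG seed.
#' @param k optional named vector of per-candidate parameter counts for the
#'   AICc ranking (e.g. transformation parameter counts); defaults to each
#'   fit's own count (slopes + intercept + 2 variance components).
#' @param keep_iterations also return the per-iteration AICc and weight
#'   matrices.
#' @return A `bootstrap_summary` data frame (candidate, k, avg_rank,
#'   omega_bar, pi_hat) with iteration metadata in attributes.
#' @export
bootstrap_select <- function(candidates, genetic, frac = 0.75,
                             iters = 1000, seed = 1L, k = NULL,
                             keep_iterations = FALSE) {
  if (is.null(names(candidates)) || any(names(candidates) == ""))
    stop("candidates must be named")
  if (frac <= 0 || frac >= 1) stop("frac must be in (0, 1)")
  ids <- pm_ids(genetic)
  n <- length(ids)
  m <- ceiling(frac * n)
  M <- length(candidates)
  nm <- names(candidates)
  kvec <- stats::setNames(rep(NA_real_, M), nm)
  if (!is.null(k)) kvec[names(k)] <- k

  set.seed(seed)
  rank_sum <- stats::setNames(numeric(M), nm)
  w_sum <- stats::setNames(numeric(M), nm)
  top_count <- stats::setNames(numeric(M), nm)
  aicc_mat <- if (keep_iterations) matrix(NA_real_, iters, M,
                                          dimnames = list(NULL, nm))
  w_mat <- if (keep_iterations) matrix(NA_real_, iters, M,
                                       dimnames = list(NULL, nm))
  n_resampled <- 0L

  it <- 1L
  while (it <= iters) {
    sub <- sort(sample(ids, m))
    gsub <- pm_restrict(genetic, sub)
    ac <- numeric(M)
    ok <- TRUE
    for (c_i in seq_len(M)) {
      fit <- fit_mlpe(gsub, list(d = pm_restrict(candidates[[c_i]], sub)),
                      method = "ML")
      kc <- if (is.finite(kvec[c_i])) kvec[c_i] else fit$k
      if (m <= kc + 1) { ok <- FALSE; break }
      ac[c_i] <- aicc(fit$logL, kc, m)
    }
    if (!ok) {
      n_resampled <- n_resampled + 1L
      if (n_resampled > 100L)
        stop("subsample too small for the requested parameter counts")
      message("subsample too small for fitting; resampling iteration")
      next
    }
    kc_all <- ifelse(is.finite(kvec), kvec, 3)
    # rank by AICc; exact ties -> fewer parameters -> random
    ord <- order(round(ac, 10), kc_all, stats::runif(M))
    rnk <- integer(M); rnk[ord] <- seq_len(M)
    delta <- ac - min(ac)
    w <- exp(-delta / 2)
    w <- w / sum(w)
    rank_sum <- rank_sum + rnk
    w_sum <- w_sum + w
    top_count[ord[1L]] <- top_count[ord[1L]] + 1
    if (keep_iterations) {
      aicc_mat[it, ] <- ac
      w_mat[it, ] <- w
    }
    it <- it + 1L
  }

  out <- data.frame(
    candidate = nm,
    k = ifelse(is.finite(kvec), kvec, 3),
    avg_rank = rank_sum / iters,
    omega_bar = w_sum / iters,
    pi_hat = 100 * top_count / iters,
    row.names = NULL)
  out <- out[order(out$avg_rank), ]
  attr(out, "iterations") <- iters
  attr(out, "subsample_fraction") <- frac
  attr(out, "subsample_size") <- m
  attr(out, "n_resampled") <- n_resampled
  if (keep_iterations) {
    attr(out, "aicc_iterations") <- aicc_mat
    attr(out, "weight_iterations") <- w_mat
  }
  class(out) <- c("bootstrap_summary", "data.frame")
  out
}

#' Spearman rank correlation between two surfaces
#'
#' Rank correlation over cells valid in both rasters, used to screen
#' candidate surfaces for redundancy before building composites.
#'
#' @param a,b aligned [raster_surface()] objects.
#' @return Spearman's rho.
#' @export
spearman_correlation <- function(a, b) {
  stopifnot_raster(a); stopifnot_raster(b)
  if (!all(dim(a$values) == dim(b$values)))
    stop("surfaces are not aligned")
  ok <- is.finite(a$values) & is.finite(b$values)
  stats::cor(a$values[ok], b$values[ok], method = "spearman")
}
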