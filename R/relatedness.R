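#' Maximum-likelihood pairwise relatedness
#'
#' Estimates the relatedness coefficient r for every dyad by maximizing the
#' multilocus genotype-pair likelihood over the Cotterman coefficients
#' (k0, k1, k2) — the probabilities that a dyad shares 0, 1 or 2 alleles
#' identical by descent — subject to `k1^2 >= 4 k0 k2` (no inbreeding),
#' with `r = k2 + k1 / 2`. Sample allele frequencies are used as the
#' population frequencies. Loci missing in either member of a dyad are
#' dropped from that dyad's likelihood.
#'
#' @param g a [genotype_table()] with at least two individuals and at least
#'   one polymorphic locus.
#' @param freqs optional list of per-locus allele frequency vectors (named
#'   by allele label) to use instead of the sample frequencies, e.g. when
#'   population frequencies are known from a larger reference sample.
#' @return A [pairwise_matrix()] with metric `"relatedness_r"`, values in
#'   `[0, 1]`.
#' @export
estimate_relatedness <- function(g, freqs = NULL) {
  n <- n_individuals(g)
  if (n < 2L) stop("need at least two individuals")
  if (is.null(freqs)) freqs <- allele_freqs(g)
  if (length(freqs) != n_loci(g))
    stop("freqs must have one frequency vector per locus")
  poly <- vapply(freqs, function(p) length(p) > 1L, logical(1))
  if (!any(poly))
    stop("all loci are monomorphic; relatedness is unidentifiable")
  for (l in seq_len(n_loci(g))) {
    obs <- unique(stats::na.omit(as.vector(g$alleles[, l, ])))
    miss <- setdiff(as.character(obs), names(freqs[[l]]))
    if (length(miss))
      stop("allele(s) ", paste(miss, collapse = ", "),
           " at locus ", locus_names(g)[l], " absent from supplied freqs")
  }
  r <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      P <- dyad_ibd_components(g, i, j, freqs)
      r[i, j] <- r[j, i] <- if (is.null(P)) NA_real_ else ml_relatedness(P)
    }
  }
  if (anyNA(r[upper.tri(r)]))
    warning("some dyads share no typed polymorphic locus; r is NA there")
  pairwise_matrix(r, ids = g$ids, metric = "relatedness_r")
}

# Per-locus likelihood components P0, P1, P2 (probability of the observed
# genotype pair given 0/1/2 alleles shared identical by descent), for every
# polymorphic locus typed in both individuals. Returns a 3-column matrix or
# NULL when no usable locus exists.
dyad_ibd_components <- function(g, i, j, freqs) {
  out <- NULL
  for (l in seq_len(n_loci(g))) {
    p <- freqs[[l]]
    if (length(p) < 2L) next
    a <- g$alleles[i, l, ]
    b <- g$alleles[j, l, ]
    if (anyNA(a) || anyNA(b)) next
    out <- rbind(out, genotype_pair_probs(as.character(a), as.character(b), p))
  }
  out
}

# P(G1, G2 | S) for unordered genotypes G1 = {a1, a2}, G2 = {b1, b2} under
# S = 0, 1, 2 pairs of alleles identical by descent; p is the named allele
# frequency vector.
genotype_pair_probs <- function(a, b, p) {
  gp <- function(x, y) if (x == y) p[[x]]^2 else 2 * p[[x]] * p[[y]]
  P0 <- gp(a[1], a[2]) * gp(b[1], b[2])
  P2 <- if (setequal(a, b) &&
            (a[1] == a[2]) == (b[1] == b[2])) gp(a[1], a[2]) else 0
  # one shared IBD allele x: remaining gene copies drawn independently
  q1 <- function(x, gt) {
    if (gt[1] == gt[2]) {
      if (gt[1] == x) p[[x]] else 0
    } else if (x == gt[1]) p[[gt[2]]]
    else if (x == gt[2]) p[[gt[1]]]
    else 0
  }
  cand <- intersect(unique(a), unique(b))
  P1 <- 0
  for (x in cand) P1 <- P1 + p[[x]] * q1(x, a) * q1(x, b)
  c(P0 = P0, P1 = P1, P2 = P2)
}

# Maximize sum(log(k %*% P)) over the (k0, k1, k2) simplex subject to
# k1^2 >= 4 k0 k2, return r = k2 + k1/2. The log-likelihood is concave on
# the simplex, so an interior search from several canonical starts finds
# the unconstrained optimum; when that violates the constraint the
# constrained optimum lies on the boundary curve
# (a^2, 2a(1-a), (1-a)^2), a in [0, 1], which is searched directly.
ml_relatedness <- function(P) {
  ll_k <- function(k) sum(log(pmax(P %*% k, 1e-300)))
  ll_t <- function(t) {
    e <- exp(c(0, t) - max(0, t))
    ll_k(e / sum(e))
  }
  starts <- list(c(-6, -6),          # ~unrelated
                 c(0, -6),           # ~half-sib
                 c(0.7, 0),          # ~full-sib
                 c(6, -6))           # ~parent-offspring
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, ll_t, method = "Nelder-Mead",
                      control = list(fnscale = -1, maxit = 400,
                                     reltol = 1e-10))
    if (is.null(best) || o$value > best$value) best <- o
  }
  e <- exp(c(0, best$par) - max(0, best$par))
  k <- e / sum(e)
  if (k[2]^2 + 1e-9 >= 4 * k[1] * k[3]) return(min(1, max(0, k[3] + k[2] / 2)))
  ll_a <- function(a) ll_k(c(a^2, 2 * a * (1 - a), (1 - a)^2))
  oa <- stats::optimize(ll_a, c(0, 1), maximum = TRUE, tol = 1e-9)
  a_best <- oa$maximum
  if (ll_a(0) > oa$objective) a_best <- 0
  if (ll_a(1) > max(oa$objective, ll_a(0))) a_best <- 1
  min(1, max(0, 1 - a_best))
}

#' Remove related dyads from a genotype table
#'
#' Drops individuals until no retained dyad has relatedness strictly above
#' `threshold` (dyads at exactly the threshold are kept). Removal is greedy:
#' at each step the individual with the most above-threshold partners is
#' removed, ties broken by lexicographically smallest id, which keeps the
#' largest number of individuals in typical configurations.
#'
#' @param g a [genotype_table()].
#' @param r a [pairwise_matrix()] of relatedness covering all ids of `g`.
#' @param threshold retain dyads with `r <= threshold` (default 0.5).
#' @return A [genotype_table()] free of above-threshold dyads.
#' @export
filter_related <- function(g, r, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  rm_ <- pm_restrict(r, g$ids)
  adj <- !is.na(rm_) & rm_ > threshold
  diag(adj) <- FALSE
  keep <- g$ids
  repeat {
    deg <- rowSums(adj[keep, keep, drop = FALSE])
    if (!length(deg) || max(deg) == 0L) break
    worst <- names(deg)[deg == max(deg)]
    drop_id <- sort(worst)[1L]
    keep <- setdiff(keep, drop_id)
  }
  subset_individuals(g, keep)
}
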