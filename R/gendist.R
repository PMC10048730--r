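#' Rousset's a-hat individual genetic distance
#'
#' Individual-level analogue of Fst / (1 - Fst): for a dyad (i, j),
#' `a_ij = (Qw - Q_ij) / (1 - Qw)`, where `Q_ij` is the probability that one
#' gene copy drawn from each individual is identical in state (the mean of
#' the four allele cross-comparisons) and `Qw` is the mean within-individual
#' gene identity (homozygosity) across the sample. Loci are pooled as a
#' ratio of sums: per-locus numerators `Qw_l - Q_ij,l` and denominators
#' `1 - Qw_l` are summed over the loci typed in both individuals before
#' taking the ratio.
#'
#' @param g a [genotype_table()] with at least three individuals and one
#'   polymorphic locus.
#' @return A [pairwise_matrix()] with metric `"rousset_ar"`.
#' @export
rousset_ar <- function(g) {
  n <- n_individuals(g)
  if (n < 3L) stop("need at least three individuals")
  L <- n_loci(g)
  typed <- typed_matrix(g)
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  any_locus <- matrix(FALSE, n, n)
  for (l in seq_len(L)) {
    ok <- typed[, l]
    if (sum(ok) < 2L) next
    a1 <- g$alleles[, l, 1]
    a2 <- g$alleles[, l, 2]
    qw <- mean(a1[ok] == a2[ok])
    # mean identity of the four cross-individual allele draws
    Q <- (outer(a1, a1, "==") + outer(a1, a2, "==") +
          outer(a2, a1, "==") + outer(a2, a2, "==")) / 4
    both <- outer(ok, ok, "&")
    num[both] <- num[both] + (qw - Q[both])
    den[both] <- den[both] + (1 - qw)
    any_locus <- any_locus | both
  }
  if (!any(any_locus[upper.tri(any_locus)]))
    stop("no dyad shares a typed locus")
  if (any(den[any_locus] == 0))
    stop("within-individual identity is 1 at every shared locus for some ",
         "dyad; Rousset's a-hat is undefined")
  ar <- num / den
  ar[!any_locus] <- NA_real_
  pairwise_matrix(ar, ids = g$ids, metric = "rousset_ar")
}

#' Proportion of shared alleles (Dps)
#'
#' For each dyad, the proportion of alleles shared between the two diploid
#' genotypes, averaged over the loci typed in both individuals:
#' `Dps = (1/L) * sum_l [ sum_a min(c_i(a), c_j(a)) ] / 2`, where `c_i(a)`
#' is individual i's count (0, 1, 2) of allele `a` at locus l. A similarity
#' in `[0, 1]` (1 = identical genotypes). Dyads sharing no typed locus get
#' `NA` with a warning.
#'
#' @param g a [genotype_table()].
#' @return A [pairwise_matrix()] with metric `"dps"`.
#' @export
dps <- function(g) {
  n <- n_individuals(g)
  if (n < 2L) stop("need at least two individuals")
  L <- n_loci(g)
  typed <- typed_matrix(g)
  shared_sum <- matrix(0, n, n)
  loci_count <- matrix(0L, n, n)
  for (l in seq_len(L)) {
    ok <- typed[, l]
    alleles <- sort(unique(stats::na.omit(c(g$alleles[, l, ]))))
    shared <- matrix(0, n, n)
    for (a in alleles) {
      cnt <- (g$alleles[, l, 1] == a) + (g$alleles[, l, 2] == a)
      cnt[!ok] <- 0L
      shared <- shared + outer(cnt, cnt, pmin)
    }
    both <- outer(ok, ok, "&")
    shared_sum[both] <- shared_sum[both] + shared[both] / 2
    loci_count <- loci_count + both
  }
  d <- shared_sum / loci_count
  if (any(loci_count[upper.tri(loci_count)] == 0L))
    warning("dyads with no shared typed locus; Dps is NA there")
  d[loci_count == 0L] <- NA_real_
  pairwise_matrix(d, ids = g$ids, metric = "dps")
}
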