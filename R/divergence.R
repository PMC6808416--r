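#' Splice-site usage distribution of one unit
#'
#' Converts a vector of junction read counts within one splicing unit into
#' the fraction of reads supporting each alternative splice site: each count
#' is divided by the unit total.
#'
#' @param counts Non-negative numeric vector with a positive sum.
#' @return Numeric vector of the same length summing to 1.
#' @export
#' @examples
#' usage_distribution(c(5, 3, 2))   # 0.5 0.3 0.2
usage_distribution <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- sum(counts)
  if (tot <= 0) stop("cannot normalize an all-zero count vector")
  counts / tot
}

#' Pseudo-count unobserved splice sites in a harmonized unit
#'
#' When two samples use different sets of splice sites within a unit, the
#' site unobserved in one sample receives a pseudo-count equal to 1/`denom`
#' (default 1/100) of that sample's own total read count in the unit, so
#' that both usage distributions share a support set. Entries observed in
#' both samples are left unchanged; normalization happens afterwards.
#'
#' @param counts_p,counts_q Equal-length non-negative count vectors over
#'   the unit's members, each with a positive total. No member may be zero
#'   in both vectors (unit members come from the union of observed
#'   junctions, which guarantees this).
#' @param denom Pseudo-count denominator (default 100).
#' @return A list with modified copies `counts_p` and `counts_q`.
#' @export
#' @examples
#' apply_pseudocounts(c(5, 3, 2), c(4, 0, 6))  # q becomes (4, 0.1, 6)
apply_pseudocounts <- function(counts_p, counts_q, denom = 100) {
  if (length(counts_p) != length(counts_q)) {
    stop("count vectors must have equal length")
  }
  if (denom <= 0) stop("pseudo-count denominator must be positive")
  tot_p <- sum(counts_p)
  tot_q <- sum(counts_q)
  if (tot_p <= 0 || tot_q <= 0) {
    stop("each sample must have a positive unit total before pseudo-counting")
  }
  if (any(counts_p == 0 & counts_q == 0)) {
    stop("a unit member is unobserved in both samples; ",
         "members must come from the union of observed junctions")
  }
  zp <- counts_p == 0
  zq <- counts_q == 0
  counts_p[zp] <- tot_p / denom
  counts_q[zq] <- tot_q / denom
  list(counts_p = counts_p, counts_q = counts_q)
}

#' Intermediate distribution between two usage distributions
#'
#' The elementwise average `(p + q) / 2`, used as the reference point for
#' the bidirectional Kullback-Leibler divergences inside the
#' Jensen-Shannon divergence.
#'
#' @param p,q Equal-length probability vectors.
#' @return Probability vector of the same length.
#' @export
intermediate_distribution <- function(p, q) {
  if (length(p) != length(q)) stop("distributions must have equal length")
  (p + q) / 2
}

#' Kullback-Leibler divergence in bits
#'
#' `sum(p * log2(p / m))` with the `0 * log(0) = 0` convention. `m` must be
#' positive wherever `p` is; with `m` the intermediate distribution of `p`
#' and another distribution this always holds, and a violation signals a
#' pseudo-counting bug upstream.
#'
#' @param p,m Equal-length probability vectors.
#' @return Non-negative numeric scalar (bits).
#' @export
kld <- function(p, m) {
  if (length(p) != length(m)) stop("distributions must have equal length")
  pos <- p > 0
  if (any(pos & m == 0)) {
    stop("KLD is infinite: p > 0 where m == 0")
  }
  sum(p[pos] * log2(p[pos] / m[pos]))
}

#' Jensen-Shannon divergence of two usage distributions, in bits
#'
#' The average of the two Kullback-Leibler divergences from the
#' intermediate distribution `m = (p + q) / 2`. With base-2 logarithms the
#' value lies in `[0, 1]`: 0 means identical splice-site usage, 1 means
#' completely disjoint usage.
#'
#' @param p,q Equal-length probability vectors.
#' @return Numeric scalar in `[0, 1]`.
#' @export
#' @examples
#' jsd(c(1, 0), c(0, 1))        # 1: disjoint support
#' jsd(c(0.5, 0.5), c(0.5, 0.5))  # 0: identical usage
jsd <- function(p, q) {
  m <- intermediate_distribution(p, q)
  val <- (kld(p, m) + kld(q, m)) / 2
  min(max(val, 0), 1)
}
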