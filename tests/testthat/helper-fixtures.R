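# Quick junction-profile builder: ends sharing a start form one unit.
make_profile <- function(chrom, start, end, strand = "+", count,
                         sample_id = "sample") {
  junction_profile(
    data.frame(chrom = chrom, start = as.integer(start),
               end = as.integer(end), strand = strand, count = count),
    sample_id = sample_id)
}

# Independent JSD oracle via the entropy formulation
# H((p+q)/2) - (H(p) + H(q))/2, a different route than the package's
# averaged bidirectional KLDs.
shannon_oracle <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}
jsd_oracle <- function(p, q) {
  shannon_oracle((p + q) / 2) - (shannon_oracle(p) + shannon_oracle(q)) / 2
}

# Brute-force connected components by iterated transitive closure over the
# pairwise "shares an endpoint coordinate on the same chrom+strand" relation.
components_oracle <- function(jx) {
  n <- nrow(jx)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      same_class <- jx$chrom[i] == jx$chrom[j] &&
        jx$strand[i] == jx$strand[j]
      shares <- length(intersect(c(jx$start[i], jx$end[i]),
                                 c(jx$start[j], jx$end[j]))) > 0
      adj[i, j] <- same_class && shares
    }
  }
  repeat {
    closure <- adj | (adj %*% adj > 0)
    if (identical(closure, adj)) break
    adj <- closure
  }
  # canonical component label: smallest member index
  apply(adj, 1, function(row) min(which(row)))
}

# Random junction set on a small coordinate grid so endpoint collisions
# (and hence multi-junction units) are common.
random_junction_set <- function(n, n_sites = 12L) {
  sites <- sort(sample.int(1000L, n_sites))
  a <- sample(sites, n, replace = TRUE)
  b <- sample(sites, n, replace = TRUE)
  jx <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                   start = pmin(a, b), end = pmax(a, b),
                   strand = sample(c("+", "-", "."), n, replace = TRUE))
  jx[!duplicated(jx), , drop = FALSE]
}
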