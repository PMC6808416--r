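#' Generate a synthetic gene pool with intron structures
#'
#' Builds gene models for the entropy-validation experiment: each gene
#' carries a number of isoforms drawn from `isoform_range` and
#' `units_per_gene` intronic splicing units. Within a unit, each isoform
#' supports exactly one of the unit's alternative junctions and every
#' junction is supported by at least one isoform (a random surjection), so
#' junction usage is a coarsening of isoform usage — some isoform pairs are
#' indistinguishable within a given intron, as in real gene structures.
#'
#' @param n_genes Number of genes (default 10).
#' @param isoform_range Integer range of isoforms per gene (default 2-5).
#' @param units_per_gene Intronic splicing units per gene (default 3).
#' @param seed Integer seed.
#' @return A list of gene models (`n_iso`, per-unit member coordinates and
#'   isoform-to-junction maps), class `gene_pool`.
#' @export
generate_gene_pool <- function(n_genes = 10L, isoform_range = c(2L, 5L),
                               units_per_gene = 3L, seed = 1L) {
  stopifnot(isoform_range[1] >= 2L, isoform_range[2] >= isoform_range[1],
            n_genes >= 1L, units_per_gene >= 1L)
  .with_seed(seed, {
    pool <- lapply(seq_len(n_genes), function(g) {
      n_iso <- sample(isoform_range[1]:isoform_range[2], 1L)
      units <- lapply(seq_len(units_per_gene), function(u) {
        m <- if (n_iso == 2L) 2L else sample(2L:n_iso, 1L)
        # random surjection isoform -> junction
        map <- integer(n_iso)
        perm <- sample.int(n_iso)
        map[perm[seq_len(m)]] <- seq_len(m)
        if (n_iso > m) {
          map[perm[(m + 1L):n_iso]] <- sample.int(m, n_iso - m,
                                                  replace = TRUE)
        }
        base <- 1000000L * g + 10000L * u
        list(m = m, map = map,
             chrom = "chr1", strand = "+",
             start = base,
             end = base + 1000L + 500L * (seq_len(m) - 1L))
      })
      list(gene_id = sprintf("gene%02d", g), n_iso = n_iso, units = units)
    })
    structure(pool, class = "gene_pool")
  })
}

#' Simulate one sample's isoform fractions and junction profile
#'
#' Draws per-gene isoform mixing fractions at a given heterogeneity level
#' and derives the sample's junction counts from them through the pool's
#' intron structures. The representative (first) isoform of each gene gets
#' weight `1 - level`; the remaining weight `level` is split among the
#' minor isoforms by a uniform Dirichlet draw. Junction counts are the
#' exact expected counts `depth * (summed fractions of isoforms supporting
#' the junction)`.
#'
#' @param pool A [generate_gene_pool()] object.
#' @param level Heterogeneity level in `[0, 1]`: 0 = only the
#'   representative isoform, 1 = only minor isoforms.
#' @param depth Read depth per splicing unit (default 1000).
#' @param seed Integer seed.
#' @param sample_id Sample name.
#' @return A list with `fractions` (named list of per-gene isoform
#'   fractions) and `profile` (a [junction_profile()]).
#' @export
simulate_isoform_sample <- function(pool, level, depth = 1000, seed = 1L,
                                    sample_id = "synthetic") {
  stopifnot(inherits(pool, "gene_pool"), level >= 0, level <= 1)
  .with_seed(seed, {
    fractions <- lapply(pool, function(gene) {
      minor <- .rdirichlet(gene$n_iso - 1L, 1)
      c(1 - level, level * minor)
    })
    names(fractions) <- vapply(pool, `[[`, character(1), "gene_id")
    rows <- lapply(seq_along(pool), function(g) {
      gene <- pool[[g]]
      do.call(rbind, lapply(gene$units, function(u) {
        cnt <- depth * as.vector(rowsum(fractions[[g]], u$map))
        data.frame(chrom = u$chrom, start = u$start, end = u$end,
                   strand = u$strand, count = cnt)
      }))
    })
    tab <- do.call(rbind, rows)
    tab <- tab[tab$count > 0, , drop = FALSE]
    list(fractions = fractions,
         profile = junction_profile(tab, sample_id = sample_id))
  })
}

#' Run the transcript-vs-intron entropy validation experiment
#'
#' Checks that heterogeneity measured per intron can stand in for
#' heterogeneity measured per whole transcript: several gene pools are
#' generated, each pool yields samples at random heterogeneity levels, and
#' for every sample both the whole-transcript entropy
#' ([transcript_entropy()], on the isoform fractions) and the intron-level
#' entropy ([intron_entropy()], on the derived junction profile) are
#' computed.
#'
#' @param n_pools Number of random gene pools (default 20).
#' @param samples_per_pool Samples per pool (default 10).
#' @param n_genes Genes per pool (default 10).
#' @param isoform_range Isoforms per gene (default 2-5).
#' @param units_per_gene Splicing units per gene (default 3).
#' @param depth Read depth per unit (default 1000).
#' @param seed Master seed.
#' @return A data.frame with one row per sample: `pool`, `sample`,
#'   `level`, `ith_transcript`, `ith_intron`.
#' @export
run_entropy_experiment <- function(n_pools = 20L, samples_per_pool = 10L,
                                   n_genes = 10L,
                                   isoform_range = c(2L, 5L),
                                   units_per_gene = 3L, depth = 1000,
                                   seed = 1L) {
  n_samples <- n_pools * samples_per_pool
  seeds <- .with_seed(seed, sample.int(2147483646L, n_pools + n_samples))
  levels <- .with_seed(seed + 1L, stats::runif(n_samples))
  rows <- vector("list", n_samples)
  idx <- 0L
  for (p in seq_len(n_pools)) {
    pool <- generate_gene_pool(n_genes = n_genes,
                               isoform_range = isoform_range,
                               units_per_gene = units_per_gene,
                               seed = seeds[p])
    for (s in seq_len(samples_per_pool)) {
      idx <- idx + 1L
      sim <- simulate_isoform_sample(pool, level = levels[idx],
                                     depth = depth,
                                     seed = seeds[n_pools + idx])
      rows[[idx]] <- data.frame(
        pool = p, sample = idx, level = levels[idx],
        ith_transcript = transcript_entropy(sim$fractions),
        ith_intron = intron_entropy(sim$profile))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
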