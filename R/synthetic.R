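# Run code under a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

.rdirichlet <- function(n, concentration) {
  g <- stats::rgamma(n, shape = concentration)
  if (sum(g) == 0) g <- rep(1, n)   # guards tiny concentrations
  g / sum(g)
}

#' Parameters of the synthetic junction-profile generator
#'
#' Bundles the knobs of the synthetic "normal tissue" generator and the
#' cell perturbation used by the mixture experiment.
#'
#' @param n_units Number of intronic splicing units to emit (default 300).
#' @param members_range Integer range (low, high) of alternative junctions
#'   per unit; all units share a donor site as in the canonical
#'   alternative-acceptor pattern (default 2-5).
#' @param depth Mean total read depth per unit; unit totals are Poisson
#'   around this mean (default 200).
#' @param concentration Symmetric Dirichlet concentration of the drawn
#'   splice-site usage distributions; 1 is uniform on the simplex, smaller
#'   values give sharper usage (default 1).
#' @param perturbation How far a synthetic cancer-cell profile moves from
#'   the normal usage, as the mixing weight toward an independently
#'   resampled target usage, in (0, 1] (default 0.8).
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(n_units = 300L, members_range = c(2L, 5L),
                             depth = 200, concentration = 1,
                             perturbation = 0.8) {
  stopifnot(n_units >= 1L, depth > 0, concentration > 0,
            perturbation > 0, perturbation <= 1,
            length(members_range) == 2L, members_range[1] >= 2L,
            members_range[2] >= members_range[1])
  structure(list(n_units = as.integer(n_units),
                 members_range = as.integer(members_range),
                 depth = depth,
                 concentration = concentration,
                 perturbation = perturbation),
            class = "generator_params")
}

#' Generate a synthetic normal-tissue junction profile
#'
#' Emits `n_units` intronic splicing units. Each unit consists of 2 or more
#' alternative junctions sharing a donor site, a usage distribution drawn
#' from a symmetric Dirichlet, and integer junction counts drawn
#' multinomially at a Poisson total depth. Draws are conditioned on the
#' unit staying multi-observed (at least two junctions with reads), so
#' every emitted unit passes the default sITH filters. Deterministic given
#' `seed`; the caller's RNG state is untouched.
#'
#' The drawn ("true") usage fractions are stored in the `truth` attribute
#' for generator diagnostics.
#'
#' @param params A [generator_params()] object.
#' @param seed Integer seed.
#' @param sample_id Sample name (default `"normal"`).
#' @return A [junction_profile()] with attribute `truth`, a data.frame of
#'   drawn usage fractions per junction.
#' @export
generate_normal_profile <- function(params = generator_params(), seed = 1L,
                                    sample_id = "normal") {
  stopifnot(inherits(params, "generator_params"))
  .with_seed(seed, {
    rows <- vector("list", params$n_units)
    for (k in seq_len(params$n_units)) {
      m <- sample(params$members_range[1]:params$members_range[2], 1L)
      usage <- .rdirichlet(m, params$concentration)
      repeat {
        total <- stats::rpois(1L, params$depth)
        if (total < 2L) next
        counts <- as.vector(stats::rmultinom(1L, total, usage))
        if (sum(counts > 0) >= 2L) break
      }
      base <- 10000L * k
      rows[[k]] <- data.frame(
        chrom = "chr1",
        start = base,
        end = base + 1000L + 500L * (seq_len(m) - 1L),
        strand = if (k %% 2L == 0L) "-" else "+",
        count = counts,
        usage = usage,
        unit_index = k)
    }
    tab <- do.call(rbind, rows)
    truth <- tab[c("chrom", "start", "end", "strand", "usage", "unit_index")]
    profile <- junction_profile(
      tab[tab$count > 0, c("chrom", "start", "end", "strand", "count")],
      sample_id = sample_id)
    attr(profile, "truth") <- truth
    profile
  })
}

#' Perturb a normal profile into a synthetic cancer-cell profile
#'
#' Emulates a single cancer cell whose splice-site usage has drifted from
#' the tissue of origin: within each splicing unit of `normal`, the
#' empirical usage distribution is mixed with an independently drawn
#' Dirichlet target, `usage_cell = (1 - strength) * usage_normal +
#' strength * target`, and cell counts are the exact expected counts
#' `usage_cell * unit_total` (fractional; the perturbation models usage
#' drift, not resampling noise). At `strength -> 0` the cell's usage
#' converges to the normal's; distinct seeds give distinct cells.
#'
#' Optionally each unit gains a novel junction (absent from the normal)
#' with probability `novel_rate`, emulating tumor-specific junctions.
#'
#' @param normal A [junction_profile()].
#' @param strength Mixing weight toward the resampled target, in (0, 1].
#' @param seed Integer seed.
#' @param concentration Dirichlet concentration of the target usage.
#' @param novel_rate Per-unit probability of adding a novel junction
#'   (default 0).
#' @param sample_id Sample name.
#' @return A [junction_profile()].
#' @export
perturb_profile <- function(normal, strength, seed = 1L, concentration = 1,
                            novel_rate = 0, sample_id = NULL) {
  stopifnot(inherits(normal, "junction_profile"),
            strength > 0, strength <= 1,
            novel_rate >= 0, novel_rate <= 1)
  if (is.null(sample_id)) {
    sample_id <- paste0(attr(normal, "sample_id"), "_cell", seed)
  }
  jx <- group_junctions(as.data.frame(normal))
  .with_seed(seed, {
    out <- lapply(split(jx, factor(jx$unit_id, levels = unique(jx$unit_id))),
                  function(u) {
      total <- sum(u$count)
      usage_n <- u$count / total
      target <- .rdirichlet(nrow(u), concentration)
      usage_c <- (1 - strength) * usage_n + strength * target
      if (novel_rate > 0 && stats::runif(1) < novel_rate) {
        f_new <- strength * stats::runif(1, 0.05, 0.2)
        u <- rbind(u, data.frame(
          unit_id = u$unit_id[1], chrom = u$chrom[1],
          start = u$start[1], end = max(u$end) + 500L,
          strand = u$strand[1], count = 0))
        usage_c <- c(usage_c * (1 - f_new), f_new)
      }
      data.frame(chrom = u$chrom, start = u$start, end = u$end,
                 strand = u$strand, count = usage_c * total)
    })
    tab <- do.call(rbind, out)
    junction_profile(tab, sample_id = sample_id)
  })
}

#' Mix cancer-cell profiles into a normal profile
#'
#' Synthesizes a bulk mixture with a designed heterogeneity level: with
#' `i = level` cells each contributing 1% of the sample, every junction
#' count is the affine combination
#' `MIX(j) = NT(j) * (1 - i/100) + sum_l SC(l, j) / 100`
#' over the union of the profiles' junctions (absent junctions count 0).
#' Counts are kept fractional; the mixture is defined on the count
#' arithmetic, not on resampled reads.
#'
#' @param normal Normal-tissue [junction_profile()] (`NT`).
#' @param cells List of cell [junction_profile()] objects (`SC`).
#' @param level Number of cells to mix, `0 <= level <= length(cells)`;
#'   the first `level` cells are used (default all).
#' @param sample_id Sample name.
#' @return A [junction_profile()] with fractional counts.
#' @export
synthesize_mixture <- function(normal, cells, level = length(cells),
                               sample_id = sprintf("mix_%d", level)) {
  stopifnot(inherits(normal, "junction_profile"))
  if (level > length(cells)) {
    stop("level (", level, ") exceeds the number of available cells (",
         length(cells), ")")
  }
  tabs <- c(list(as.data.frame(normal)),
            lapply(cells[seq_len(level)], as.data.frame))
  allj <- do.call(rbind, lapply(tabs, function(tb) {
    tb[c("chrom", "start", "end", "strand")]
  }))
  keys <- .junction_key(allj)
  first <- !duplicated(keys)
  un <- allj[first, , drop = FALSE]
  ukeys <- keys[first]
  count_on_union <- function(tb) {
    v <- numeric(nrow(un))
    v[match(.junction_key(tb), ukeys)] <- tb$count
    v
  }
  mix <- count_on_union(tabs[[1]]) * (1 - level / 100)
  for (tb in tabs[-1]) {
    mix <- mix + count_on_union(tb) / 100
  }
  keep <- mix > 0
  junction_profile(
    data.frame(chrom = un$chrom[keep], start = un$start[keep],
               end = un$end[keep], strand = un$strand[keep],
               count = mix[keep]),
    sample_id = sample_id)
}

#' Run the synthetic cell-into-normal mixture experiment
#'
#' The desk-scale analog of mixing single cancer cells into normal tissue
#' at 1% per cell: one synthetic normal profile and `n_cells` perturbed
#' cell profiles are generated, then for every heterogeneity level
#' `i = 1..n_levels` and every replicate a random subset of `i` cells is
#' mixed into the normal ([synthesize_mixture()]) and the mixture's sITH
#' against the normal is computed. Samples mixed from more cells are more
#' heterogeneous by design, so sITH should increase with level.
#'
#' @param params [generator_params()] controlling the generator.
#' @param n_cells Number of distinct cell profiles in the pool (default 39).
#' @param n_levels Number of heterogeneity levels, `<= n_cells`
#'   (default 39).
#' @param reps Replicates per level (default 10).
#' @param seed Master seed; all sub-seeds derive from it.
#' @param min_members,min_reads,pseudo_denom Passed to [sith_pair()].
#' @return A data.frame with columns `level`, `replicate`, `sith`
#'   (`n_levels * reps` rows).
#' @export
run_mixture_experiment <- function(params = generator_params(),
                                   n_cells = 39L, n_levels = 39L,
                                   reps = 10L, seed = 1L,
                                   min_members = 2L, min_reads = 1,
                                   pseudo_denom = 100) {
  stopifnot(n_levels <= n_cells, n_levels >= 1L, reps >= 1L)
  n_seeds <- 1L + n_cells + n_levels * reps
  seeds <- .with_seed(seed, sample.int(2147483646L, n_seeds))
  normal <- generate_normal_profile(params, seed = seeds[1])
  cells <- lapply(seq_len(n_cells), function(l) {
    perturb_profile(normal, strength = params$perturbation,
                    seed = seeds[1L + l],
                    concentration = params$concentration)
  })
  rows <- vector("list", n_levels * reps)
  idx <- 0L
  for (j in seq_len(reps)) {
    for (i in seq_len(n_levels)) {
      idx <- idx + 1L
      sel <- .with_seed(seeds[1L + n_cells + idx],
                        sample.int(n_cells, i))
      mix <- synthesize_mixture(normal, cells[sel], level = i,
                                sample_id = sprintf("mix_L%d_R%d", i, j))
      res <- sith_pair(mix, normal, min_members = min_members,
                       min_reads = min_reads, pseudo_denom = pseudo_denom)
      rows[[idx]] <- data.frame(level = i, replicate = j, sith = res$sith)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with average-rank tie handling, the readout used for
#' the mixture experiment (heterogeneity level vs sITH).
#'
#' @param x,y Equal-length numeric vectors of length at least 3.
#' @return Numeric scalar in `[-1, 1]`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Spearman correlation undefined for a constant vector")
  }
  stats::cor(x, y, method = "spearman")
}
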