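test_that("the normal-profile generator is seed-deterministic and well-formed", {
  params <- generator_params(n_units = 40L, depth = 100)
  a <- generate_normal_profile(params, seed = 9)
  b <- generate_normal_profile(params, seed = 9)
  expect_true(profiles_equal(a, b))
  c <- generate_normal_profile(params, seed = 10)
  expect_false(profiles_equal(a, c))

  # grouping recovers exactly the constructed units, all filter-safe
  g <- group_junctions(as.data.frame(a))
  expect_equal(length(unique(g$unit_id)), 40L)
  per_unit_n <- table(g$unit_id)
  expect_true(all(per_unit_n >= 2))
  expect_true(all(per_unit_n <= 5))

  # generators leave the caller's RNG stream untouched
  set.seed(77); before <- runif(1)
  set.seed(77); invisible(generate_normal_profile(params, seed = 3))
  expect_identical(runif(1), before)
})

test_that("empirical usage approaches the drawn usage at high depth", {
  deep <- generate_normal_profile(
    generator_params(n_units = 50L, members_range = c(2L, 4L),
                     depth = 1e5), seed = 21)
  truth <- attr(deep, "truth")
  d <- as.data.frame(deep)
  g <- group_junctions(d)
  tot <- ave(g$count, g$unit_id, FUN = sum)
  emp <- g$count / tot
  key <- paste(g$chrom, g$start, g$end, g$strand)
  tkey <- paste(truth$chrom, truth$start, truth$end, truth$strand)
  expect_lt(max(abs(emp - truth$usage[match(key, tkey)])), 0.01)
})

test_that("cell perturbation is continuous at zero, distinct by seed, monotone in strength", {
  normal <- generate_normal_profile(
    generator_params(n_units = 60L, depth = 500), seed = 5)
  weak <- perturb_profile(normal, strength = 1e-4, seed = 1)
  expect_lt(sith_pair(weak, normal)$sith, 1e-4)

  cell1 <- perturb_profile(normal, strength = 0.8, seed = 1)
  cell2 <- perturb_profile(normal, strength = 0.8, seed = 2)
  expect_false(profiles_equal(cell1, cell2))

  divergences <- vapply(seq(0.1, 0.9, by = 0.2), function(s) {
    sith_pair(perturb_profile(normal, strength = s, seed = 3), normal)$sith
  }, numeric(1))
  expect_true(all(diff(divergences) > 0))
})

test_that("mixture counts follow the 1%-per-cell affine combination exactly", {
  # worked arithmetic: NT = 100, two cells 50 and 30
  nt <- make_profile("chr1", c(100, 100), c(200, 300), count = c(100, 80),
                     sample_id = "NT")
  sc1 <- make_profile("chr1", c(100, 100), c(200, 300), count = c(50, 10),
                      sample_id = "SC1")
  sc2 <- make_profile("chr1", c(100, 100), c(200, 300), count = c(30, 20),
                      sample_id = "SC2")
  mix <- synthesize_mixture(nt, list(sc1, sc2))
  expect_equal(mix$count[mix$end == 200], 100 * 0.98 + (50 + 30) / 100)

  # level 0 is the pure normal
  expect_true(profiles_equal(synthesize_mixture(nt, list(sc1), level = 0),
                             nt))

  # junction absent from all cells scales by (1 - i/100) only
  nt2 <- make_profile("chr1", c(100, 100, 900), c(200, 300, 950),
                      count = c(100, 80, 40), sample_id = "NT")
  mix10 <- synthesize_mixture(nt2, rep(list(sc1), 10))
  expect_equal(mix10$count[mix10$end == 950], 0.9 * 40)

  expect_error(synthesize_mixture(nt, list(sc1), level = 5), "exceeds")
})

test_that("mixtures match an independent per-junction loop over the union", {
  set.seed(404)
  normal <- generate_normal_profile(
    generator_params(n_units = 20L, depth = 80), seed = 31)
  cells <- lapply(1:4, function(l) {
    perturb_profile(normal, strength = 0.7, seed = 30 + l)
  })
  i <- 3L
  mix <- synthesize_mixture(normal, cells, level = i)

  tabs <- lapply(c(list(normal), cells[seq_len(i)]), as.data.frame)
  keys <- unique(unlist(lapply(tabs, function(tb) {
    paste(tb$chrom, tb$start, tb$end, tb$strand)
  })))
  lookup <- function(tb, k) {
    hit <- match(k, paste(tb$chrom, tb$start, tb$end, tb$strand))
    if (is.na(hit)) 0 else tb$count[hit]
  }
  expected <- vapply(keys, function(k) {
    nt <- lookup(tabs[[1]], k)
    sc <- sum(vapply(tabs[-1], lookup, numeric(1), k = k))
    nt * (1 - i / 100) + sc / 100
  }, numeric(1))
  got <- vapply(keys, lookup, numeric(1), tb = as.data.frame(mix))
  expect_equal(unname(got), unname(expected), tolerance = 1e-12)
})

test_that("the mixture experiment yields the designed level/replicate grid", {
  params <- generator_params(n_units = 50L, depth = 120)
  tab <- run_mixture_experiment(params, n_cells = 8L, n_levels = 8L,
                                reps = 2L, seed = 77)
  expect_equal(nrow(tab), 16L)
  expect_equal(sort(unique(tab$level)), 1:8)
  expect_true(all(tab$sith > 0))

  # deterministic given the master seed
  tab2 <- run_mixture_experiment(params, n_cells = 8L, n_levels = 8L,
                                 reps = 2L, seed = 77)
  expect_identical(tab, tab2)

  # mean sITH grows with the number of mixed cells
  m <- tapply(tab$sith, tab$level, mean)
  expect_gt(spearman_cor(1:8, as.vector(m)), 0.9)
})

test_that("Spearman correlation handles monotone, reversed and tied inputs", {
  expect_equal(spearman_cor(c(1, 2, 3), c(10, 20, 30)), 1)
  expect_equal(spearman_cor(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(spearman_cor(c(1, 2), c(1, 2)), "at least 3")
  expect_error(spearman_cor(1:3, c(2, 2, 2)), "constant")
  expect_error(spearman_cor(1:3, 1:4), "equal length")
})

test_that("gene pools derive junction usage as a coarsening of isoform usage", {
  pool <- generate_gene_pool(n_genes = 5L, seed = 13)
  expect_equal(length(pool), 5L)
  pool2 <- generate_gene_pool(n_genes = 5L, seed = 13)
  expect_identical(pool, pool2)
  for (gene in pool) {
    for (u in gene$units) {
      expect_equal(length(u$map), gene$n_iso)
      expect_setequal(unique(u$map), seq_len(u$m))  # surjective
    }
  }

  sim <- simulate_isoform_sample(pool, level = 0.4, seed = 3)
  expect_equal(length(sim$fractions), 5L)
  for (fr in sim$fractions) expect_equal(sum(fr), 1)
  # per-unit junction counts sum to the unit depth
  g <- group_junctions(as.data.frame(sim$profile))
  expect_equal(unname(as.vector(tapply(g$count, g$unit_id, sum))),
               rep(1000, length(unique(g$unit_id))))

  # a pure single-isoform sample has zero entropy both ways
  pure <- simulate_isoform_sample(pool, level = 0, seed = 3)
  expect_equal(transcript_entropy(pure$fractions), 0)
})

test_that("transcript and intron entropies track each other across samples", {
  tab <- run_entropy_experiment(n_pools = 4L, samples_per_pool = 5L,
                                seed = 11)
  expect_equal(nrow(tab), 20L)
  expect_gt(cor(tab$ith_transcript, tab$ith_intron), 0.5)
  tab2 <- run_entropy_experiment(n_pools = 4L, samples_per_pool = 5L,
                                 seed = 11)
  expect_identical(tab, tab2)
})
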