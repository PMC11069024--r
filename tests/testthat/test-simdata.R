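# Wright-Fisher simulator and perturbation operators.

test_that("simulation is deterministic for a fixed seed", {
  cfg <- sim_config(ne = 20, n_chromosomes = 2, loci_per_chromosome = 30,
                    burnin_generations = 15, seed = 77)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$genotypes$map, b$genotypes$map)
  expect_identical(a$genotypes$q, b$genotypes$q)
  expect_identical(a$true_ne_trajectory, b$true_ne_trajectory)
})

test_that("two demes without migration keep ancestry q exactly in {0, 1}", {
  cfg <- sim_config(ne = 15, n_demes = 2, migration_rate = 0,
                    divergence_burnin = 20, burnin_generations = 10,
                    loci_per_chromosome = 20, seed = 3)
  pop <- simulate_population(cfg)
  expect_true(all(pop$genotypes$q %in% c(0, 1)))
  # and q = 1 individuals are exactly the deme-A residents (no admixture
  # possible, migration moves nothing)
  expect_identical(pop$genotypes$q == 1, pop$genotypes$deme == "A")
  sel <- stratify_by_q(pop, 0.99, "A")
  expect_identical(sort(sel$ids),
                   sort(pop$genotypes$ids[pop$genotypes$deme == "A"]))
})

test_that("config validation rejects degenerate worlds", {
  expect_error(sim_config(ne = 1), "N < 2")
  expect_error(sim_config(ne = 50, migration_rate = 0.1), "n_demes")
  expect_error(sim_config(ne = 50, loci_per_chromosome = 1), "loci_per_chromosome")
  expect_error(sim_config(ne = 50, init_freq_low = 0), "bounds")
  tr <- data.frame(generation = c(0, 10), N = c(50, 1))
  expect_error(sim_config(ne = tr), "N < 2")
})

test_that("heterozygosity decays at the closed-form drift rate", {
  # E[H_g] = H_0 (1 - 1/(2N))^g; check the implied per-generation decay
  # over replicate runs (scaled-down Monte Carlo).
  N <- 50; g <- 30; reps <- 40
  ratios <- vapply(seq_len(reps), function(r) {
    pop <- simulate_population(sim_config(
      ne = N, loci_per_chromosome = 200, burnin_generations = g,
      seed = 5000 + r))
    p0 <- pop$init_freqs
    pg <- allele_freq(pop$genotypes)
    mean(2 * pg * (1 - pg)) / mean(2 * p0 * (1 - p0))
  }, numeric(1))
  per_gen <- mean(ratios)^(1 / g)
  expect_lt(abs(per_gen - (1 - 1 / (2 * N))), 0.003)
})

test_that("single-generation transitions conserve frequency and match drift variance", {
  N <- 30; reps <- 200
  num <- 0; den <- 0; zsum <- 0; zn <- 0
  for (r in seq_len(reps)) {
    pop <- simulate_population(sim_config(
      ne = N, loci_per_chromosome = 200, burnin_generations = 1,
      seed = 6000 + r))
    p0 <- pop$init_freqs
    p1 <- allele_freq(pop$genotypes)
    use <- p0 > 0 & p0 < 1
    dp <- p1[use] - p0[use]
    v <- p0[use] * (1 - p0[use])
    num <- num + sum(dp^2 / v); den <- den + sum(use)
    zsum <- zsum + sum(dp / sqrt(v)); zn <- zn + sum(use)
  }
  # E[dp] = 0: standardized mean change is a ~N(0, 1/sqrt(n 2N)) average
  expect_lt(abs(zsum / zn), 3 / sqrt(zn * 2 * N))
  # Var[dp] = p(1-p)/(2N)
  expect_lt(abs(num / den * 2 * N - 1), 0.10)
})

test_that("mean r2 decays with map distance after burn-in", {
  hits <- 0
  for (r in 1:10) {
    pop <- cached_sim(sim_config(ne = 50, n_chromosomes = 2,
                                 loci_per_chromosome = 150,
                                 seed = 7000 + r))
    s <- pairwise_r2(pop, pair_policy("linked_binned", seed = r))
    s <- s[s$n_pairs >= 30 & !is.na(s$mean_r2), ]
    rho <- cor(s$mean_r2, s$c_bar, method = "spearman")
    if (rho <= 0) hits <- hits + 1
  }
  expect_gte(hits, 6)
})

test_that("sample_individuals keeps metadata, order, and errors cleanly", {
  G <- toy_matrix(S = 30, L = 20, n_chrom = 2, seed = 11)
  full <- sample_individuals(G, 30, seed = 1)
  expect_identical(full$dosages, G$dosages)
  sub <- sample_individuals(G, 10, seed = 1)
  expect_equal(length(unique(sub$ids)), 10)
  expect_true(all(sub$ids %in% G$ids))
  # order normalized: rows appear in original relative order
  expect_identical(sub$ids, G$ids[sort(match(sub$ids, G$ids))])
  expect_error(sample_individuals(G, 31, seed = 1), "31.*30|30.*31")
  s1 <- sample_individuals(G, 5, seed = 1)
  s2 <- sample_individuals(G, 5, seed = 2)
  expect_false(identical(s1$ids, s2$ids))
  # the sweep sizes used in sample-size experiments work
  pop100 <- toy_matrix(S = 100, L = 20, n_chrom = 2, seed = 12)
  expect_equal(n_individuals(sample_individuals(pop100, 15, 1)), 15)
  expect_equal(n_individuals(sample_individuals(pop100, 75, 1)), 75)
})

test_that("inject_missing is MCAR at the requested per-individual rates", {
  G <- toy_matrix(S = 100, L = 1000, n_chrom = 4, seed = 21)
  expect_identical(inject_missing(G, 0, seed = 1)$dosages, G$dosages)
  Gm <- inject_missing(G, 0.4, seed = 1)
  realized <- attr(Gm, "realized_missing")
  # binomial 99% bounds around 0.4 with L = 1000 trials
  bound <- 2.58 * sqrt(0.4 * 0.6 / 1000)
  expect_true(all(abs(realized - 0.4) < bound + 0.01))
  # vector rate: one individual nearly fully missing, others untouched
  rates <- c(0.95, rep(0, 99))
  Gv <- inject_missing(G, rates, seed = 2)
  rv <- attr(Gv, "realized_missing")
  expect_gt(rv[1], 0.9)
  expect_true(all(rv[-1] == 0))
  expect_error(inject_missing(G, 1.0), "rate")
  # het_factor inflates missingness of heterozygotes specifically
  Gh <- inject_missing(G, 0.1, seed = 3, het_factor = 3)
  het <- G$dosages == 1L
  expect_gt(mean(is.na(Gh$dosages)[het]), 2 * mean(is.na(Gh$dosages)[!het]))
})

test_that("downsample_loci preserves map order and subsets exactly", {
  G <- toy_matrix(S = 10, L = 60, n_chrom = 3, seed = 31)
  expect_identical(downsample_loci(G, 60, seed = 1)$dosages, G$dosages)
  Gs <- downsample_loci(G, 25, seed = 1)
  expect_equal(n_loci(Gs), 25)
  expect_false(is.unsorted(order(Gs$map$chrom, Gs$map$bp)))
  expect_true(all(paste(Gs$map$chrom, Gs$map$bp) %in%
                  paste(G$map$chrom, G$map$bp)))
  expect_error(downsample_loci(G, 61), "61.*60|60.*61")
})

test_that("fragment_map splits blocks near-equally and rescales to 1 Morgan", {
  expect_equal(lengths(ldner:::split_blocks(10, 3)), c(4L, 3L, 3L))
  G <- toy_matrix(S = 5, L = 128, n_chrom = 8, seed = 41)
  for (k in c(8, 16, 32, 64, 128)) {
    fm <- fragment_map(G$map, k)
    expect_equal(sort(unique(fm$chrom)), seq_len(k))
    expect_identical(fm$bp, G$map$bp)  # locus order untouched
    expect_true(all(fm$genetic_pos >= 0 & fm$genetic_pos <= 1))
    # within-block sizes differ by at most one
    expect_lte(diff(range(table(fm$chrom))), 1)
  }
  expect_error(fragment_map(G$map, 12), "multiple")
  expect_error(fragment_map(G$map, 4), "multiple")
})

test_that("stratify_by_q applies thresholds and fails on empty selection", {
  G <- toy_matrix(S = 20, L = 10, n_chrom = 2, seed = 51)
  G$q <- seq(0, 1, length.out = 20)
  expect_equal(n_individuals(stratify_by_q(G, 0, "A")), 20)
  for (qm in c(0.70, 0.80, 0.90, 0.95, 0.99))
    expect_equal(n_individuals(stratify_by_q(G, qm, "A")), sum(G$q >= qm))
  expect_equal(n_individuals(stratify_by_q(G, 0.9, "B")), sum(1 - G$q >= 0.9))
  G$q <- rep(0.5, 20)
  expect_error(stratify_by_q(G, 0.99, "A"), "empty selection")
})

test_that("perturbation operators never mutate their input", {
  G <- toy_matrix(S = 15, L = 30, n_chrom = 3, seed = 61)
  G$q <- runif(15)
  snap <- unserialize(serialize(G, NULL))
  invisible(sample_individuals(G, 5, 1))
  invisible(inject_missing(G, 0.3, 1))
  invisible(downsample_loci(G, 10, 1))
  invisible(fragment_map(G$map, 6))
  invisible(stratify_by_q(G, 0.2, "A"))
  expect_identical(G, snap)
})
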