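# Composite r2, pairing policies, and the Ne estimators.

test_that("haldane_c has the right closed form and limits", {
  expect_equal(haldane_c(0), 0)
  expect_equal(haldane_c(0.5), 0.5 * (1 - exp(-1)))
  expect_lt(haldane_c(5), 0.5)        # asymptote never attained...
  expect_lte(haldane_c(50), 0.5)      # ...though it underflows to 0.5
  expect_gt(haldane_c(50), 0.5 - 1e-12)
  expect_true(all(diff(haldane_c(seq(0, 3, 0.1))) > 0))
  expect_error(haldane_c(-0.1), ">= 0")
})

test_that("composite_r2 matches hand computation and basic symmetries", {
  x <- c(0, 1, 1, 2); y <- c(0, 1, 2, 1)
  expect_equal(composite_r2(x, y), 0.25)
  expect_equal(composite_r2(x, x), 1)
  # symmetry and allele-relabel invariance over random pairs
  for (k in 1:20) {
    a <- with_seed(k, rbinom(25, 2, 0.4))
    b <- with_seed(k + 100, rbinom(25, 2, 0.6))
    if (var(a) == 0 || var(b) == 0) next
    r2 <- composite_r2(a, b)
    expect_gte(r2, 0); expect_lte(r2, 1)
    expect_equal(composite_r2(b, a), r2)
    expect_equal(composite_r2(2L - a, b), r2)
    expect_equal(composite_r2(a, 2L - b), r2)
  }
  expect_true(is.na(composite_r2(c(1, 1, 1, 1), y)))
  expect_true(is.na(composite_r2(c(0, NA, NA, NA), y)))
})

test_that("the quadratic inversions round-trip exactly in both regimes", {
  # large-S regime: forward relation r2' = 1/(3N) - 0.69/N^2
  r2p <- 1 / (3 * 100) - 0.69 / 100^2
  expect_equal(waples_ne(r2p, 100), 100, tolerance = 1e-6)
  # small-S regime: r2' = 0.308/N - 0.52/N^2
  r2p_s <- 0.308 / 40 - 0.52 / 40^2
  expect_equal(waples_ne(r2p_s, 20), 40, tolerance = 1e-6)
  # no signal goes infinite; an over-saturated signal (negative
  # discriminant, e.g. strong mixture LD) pins to the invertible floor
  expect_identical(waples_ne(0, 50), Inf)
  expect_identical(waples_ne(-0.01, 50), Inf)
  expect_equal(waples_ne(0.9, 50), 2.76 / (2 / 3))
  expect_equal(waples_ne(0.9, 20), 2.08 / (2 * 0.308))
  # continuity at the discriminant boundary
  r2_edge <- (1 / 9) / 2.76
  expect_equal(waples_ne(r2_edge, 50), 2.76 / (2 / 3), tolerance = 1e-9)
  # agreement with the root-finding oracle across the invertible range
  for (r2p in c(1e-4, 1e-3, 5e-3, 0.02)) {
    expect_equal(waples_ne(r2p, 100), oracle_invert(r2p, 100),
                 tolerance = 1e-10)
    expect_equal(waples_ne(r2p, 15), oracle_invert(r2p, 15),
                 tolerance = 1e-10)
  }
})

test_that("the estimator is strictly decreasing in r2' in both regimes", {
  grid <- 10^seq(-5, -1.5, length.out = 40)
  for (S in c(15, 100)) {
    ne <- vapply(grid, waples_ne, numeric(1), S = S)
    fin <- is.finite(ne)
    expect_true(all(diff(ne[fin]) < 0))
  }
})

test_that("sved inversion round-trips and sets the time reference", {
  S <- 50
  r2 <- 1 / (1 + 4 * 100 * 0.05) + sampling_r2(S)
  expect_equal(sved_ne(r2 - sampling_r2(S), 0.05), 100, tolerance = 1e-6)
  expect_equal(1 / (2 * 0.05), 10)        # bin time reference
  expect_equal(1 / (2 * 0.5), 1)          # c = 0.5 bin is one generation ago
  expect_identical(sved_ne(0, 0.3), Inf)
})

test_that("weir_hill_ne matches Sved at small c and 1/(3N) at c = 0.5", {
  # round trip through the forward relation
  fwd <- function(N, c) ((1 - c)^2 + c^2) / (2 * N * c * (2 - c))
  for (c in c(0.01, 0.1, 0.3, 0.5))
    expect_equal(weir_hill_ne(fwd(100, c), c), 100, tolerance = 1e-12)
  # agreement with the Sved inversion in its regime (small c, small r2')
  expect_lt(abs(weir_hill_ne(1e-3, 0.001) / sved_ne(1e-3, 0.001) - 1), 0.005)
  expect_lt(abs(weir_hill_ne(fwd(200, 0.05), 0.05) /
                sved_ne(fwd(200, 0.05), 0.05) - 1), 0.06)
  # c = 0.5 limit is the unlinked drift expectation 1/(3N)
  expect_equal(fwd(100, 0.5), 1 / 300)
  expect_identical(weir_hill_ne(-0.1, 0.2), Inf)
})

test_that("pair_policy validates bin edges", {
  expect_error(pair_policy(bin_edges = c(0.1, 0.05, 0.5)), "increasing")
  expect_error(pair_policy(bin_edges = c(0.1, 0.3)), "0.5")
  expect_error(pair_policy(bin_edges = c(0, 0.1, 0.5)), "0.5|\\(0, 0.5\\]")
  p <- pair_policy()
  expect_equal(length(p$bin_edges), 13)
  expect_equal(p$bin_edges[13], 0.5)
})

test_that("pairwise_r2 summarises the between-chromosome class correctly", {
  G <- toy_matrix(S = 25, L = 40, n_chrom = 4, seed = 9)
  s <- pairwise_r2(G, pair_policy("unlinked"))
  expect_s3_class(s, "ld_summary")
  expect_equal(s$class, "between")
  expect_equal(s$c_bar, 0.5)
  expect_gte(s$mean_r2, 0); expect_lte(s$mean_r2, 1)
  expect_lte(s$s_harm, 25)
  # pair count equals the exhaustive between-chromosome count over
  # polymorphic loci
  poly <- !monomorphic_loci(G)
  ch <- G$map$chrom[poly]
  n_between <- (sum(poly)^2 - sum(table(ch)^2)) / 2
  expect_equal(s$n_pairs + s$n_skipped, n_between)
})

test_that("mean r2 of independent loci matches the 1/(S-1) null", {
  G <- toy_matrix(S = 400, L = 60, n_chrom = 4, seed = 19,
                  freq_lo = 0.1, freq_hi = 0.9)
  s <- pairwise_r2(G, pair_policy("unlinked"))
  expect_lt(abs(s$mean_r2 / (1 / 399) - 1), 0.15)
  expect_lt(abs(s$mean_r2_adj / sampling_r2(400) - 1), 0.15)
})

test_that("estimator and summary match the brute-force oracle exactly", {
  cases <- list(
    list(S = 20, L = 40, nc = 4, miss = 0,   seed = 101),
    list(S = 30, L = 50, nc = 5, miss = 0.1, seed = 202),
    list(S = 24, L = 30, nc = 5, miss = 0.3, seed = 303)
  )
  for (cs in cases) {
    G <- toy_matrix(S = cs$S, L = cs$L, n_chrom = cs$nc, seed = cs$seed,
                    miss_rate = cs$miss)
    est <- estimate_ne_unlinked(G, pair_policy("unlinked"))
    orc <- oracle_ne_unlinked(G)
    expect_equal(est$n_pairs, orc$n_pairs)
    expect_equal(est$r2_mean, orc$r2_mean, tolerance = 1e-10)
    expect_equal(est$r2_prime, orc$r2_prime, tolerance = 1e-10)
    expect_equal(est$s_harm, orc$s_harm, tolerance = 1e-10)
    expect_equal(est$jackknife_sd, orc$jackknife_sd, tolerance = 1e-10)
    expect_equal(est$point, orc$point, tolerance = 1e-10)
    expect_equal(est$ci_low, orc$ci_low, tolerance = 1e-10)
    expect_equal(est$ci_high, orc$ci_high, tolerance = 1e-10)
    if (is.finite(est$ci_high)) expect_lte(est$point, est$ci_high)
    if (is.finite(est$ci_low)) expect_gte(est$point, est$ci_low)
  }
})

test_that("no drift signal yields an infinite estimate with the flag set", {
  # orthogonal balanced columns: every between-chromosome pair has r2 = 0,
  # so r2' = -E_samp < 0
  x <- rep(0:1, each = 8); y <- rep(rep(0:1, each = 4), 2)
  z <- rep(rep(0:1, each = 2), 4); w <- rep(0:1, 8)
  dos <- cbind(x, y, z, w) * 2L
  map <- locus_map(c(1, 1, 2, 2), c(1, 2, 1, 2), c(0, 0.5, 0, 0.5))
  G <- genotype_matrix(dos, map)
  est <- estimate_ne_unlinked(G, pair_policy("unlinked"))
  expect_identical(est$point, Inf)
  expect_true(est$flags$infinite)
  expect_true(est$flags$negative_r2_prime)
})

test_that("degenerate inputs raise the documented errors", {
  G1 <- toy_matrix(S = 20, L = 20, n_chrom = 1, seed = 5)
  expect_error(estimate_ne_unlinked(G1, pair_policy("unlinked")),
               "too few SNP pairs")
  G3 <- toy_matrix(S = 3, L = 20, n_chrom = 2, seed = 6)
  expect_error(estimate_ne_unlinked(G3, pair_policy("unlinked", min_pair_S = 2)),
               "below the minimum of 4")
  expect_error(estimate_ne_unlinked(G1, pair_policy("linked_binned")),
               "policy")
  expect_error(estimate_ne_trajectory(G1, pair_policy("unlinked")), "policy")
})

test_that("trajectory output is ordered, positive, and time-referenced", {
  pop <- recovery_sim(1)
  G <- exclude_singletons(sample_individuals(pop, 50, seed = 1))
  tr <- suppressWarnings(estimate_ne_trajectory(
    G, pair_policy("linked_binned", seed = 1)))
  expect_s3_class(tr, "ne_trajectory")
  expect_true(all(diff(tr$t) > 0))
  expect_equal(tr$t, 1 / (2 * tr$c_bar))
  expect_true(all(tr$ne > 0))
  expect_true(all(tr$n_pairs >= pair_policy()$min_pairs_per_bin))
})

test_that("trajectory recovers constant N within factor 1.5 on recent bins", {
  vals <- vapply(1:10, function(r) {
    pop <- recovery_sim(r)
    G <- exclude_singletons(sample_individuals(pop, 50, seed = r))
    summarize_recent_ne(suppressWarnings(
      estimate_ne_trajectory(G, pair_policy("linked_binned", seed = r))))
  }, numeric(1))
  gm <- exp(mean(log(vals[is.finite(vals)])))
  expect_gt(gm, 100 / 1.5)
  expect_lt(gm, 100 * 1.5)
})
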