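# Fixture builders and a per-run simulation cache (simulations are reused
# across test files to keep the suite inside its time budget).

# Random dosage matrix built directly (independent of the simulator):
# binomial dosages at uniform frequencies, optional MCAR missingness.
toy_matrix <- function(S = 20, L = 40, n_chrom = 4, seed = 1,
                       miss_rate = 0, freq_lo = 0.15, freq_hi = 0.85) {
  stopifnot(L %% n_chrom == 0)
  withr_seed <- function(expr) ldner::with_seed(seed, expr)
  withr_seed({
    p <- runif(L, freq_lo, freq_hi)
    dos <- matrix(rbinom(S * L, 2, rep(p, each = S)), S, L)
    if (miss_rate > 0)
      dos[matrix(runif(S * L) < miss_rate, S, L)] <- NA_integer_
    per <- L / n_chrom
    gpos <- as.vector(replicate(n_chrom, sort(runif(per))))
    chrom <- rep(seq_len(n_chrom), each = per)
    bp <- unlist(lapply(split(gpos, chrom), function(g)
      cummax(as.integer(round(g * 1e8)) + 1L) + seq_along(g) - 1L),
      use.names = FALSE)
    ldner::genotype_matrix(dos, ldner::locus_map(chrom, bp, gpos))
  })
}

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(config) {
  key <- paste0("s", config$seed, "_", digest_cfg(config))
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- ldner::simulate_population(config)
  .sim_cache[[key]]
}

digest_cfg <- function(config) {
  paste(config$ne_trajectory$N[nrow(config$ne_trajectory)], config$n_demes,
        config$n_chromosomes, config$loci_per_chromosome,
        config$burnin_generations, config$divergence_burnin,
        round(config$migration_rate * 1e6), sep = "_")
}

# Shared constant-N populations used by several files (N = 100, 4 x 500
# loci, default burn-in): replicate r has seed 1000 + r.
recovery_sim <- function(r) {
  cached_sim(ldner::sim_config(ne = 100, n_chromosomes = 4,
                               loci_per_chromosome = 500, seed = 1000 + r))
}
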