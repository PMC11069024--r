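# Forward Wright-Fisher simulator: diploid, monoecious random mating with
# selfing permitted (probability 1/N), recombination via per-interval
# Haldane switch probabilities, optional two-deme structure with migration
# and pedigree ancestry (Q) tracking.

#' Configure a forward Wright-Fisher simulation
#'
#' The simulated world is an idealized Wright-Fisher population: discrete
#' generations, monoecious random mating with selfing allowed (each
#' offspring draws its mother and father uniformly with replacement within
#' its deme), standing variation only (no mutation during the run). Loci
#' start in linkage equilibrium at Uniform(`init_freq_low`,
#' `init_freq_high`) frequencies; LD accumulates over `burnin_generations`
#' of drift. Each chromosome is `chrom_length_morgans` long (default 1
#' Morgan, the convention LD-based tools assume when maps are absent).
#'
#' With `n_demes = 2`, both demes are founded from the same ancestral
#' allele-frequency pool, evolve separately for `divergence_burnin`
#' generations, and then evolve for `burnin_generations` further
#' generations during which each parent draw comes from the other deme
#' with probability `migration_rate`. Founders carry ancestry `q = 1`
#' (deme A) or `q = 0` (deme B); offspring `q` is the mean of the parental
#' values, i.e. the pedigree ancestry fraction.
#'
#' @param ne Either a single diploid population size per deme (constant
#'   trajectory) or a `data.frame(generation, N)` of step-function
#'   breakpoints forward in time (generation 0 = founding).
#' @param n_demes 1 or 2.
#' @param migration_rate Probability per parent draw in `[0, 1)`; must be 0
#'   when `n_demes = 1`.
#' @param divergence_burnin Generations the two demes evolve in isolation
#'   before the migration phase (ignored for one deme).
#' @param n_chromosomes,loci_per_chromosome Map dimensions; at least 2 loci
#'   per chromosome.
#' @param chrom_length_morgans Genetic length per chromosome.
#' @param init_freq_low,init_freq_high Bounds of the uniform initial
#'   allele-frequency distribution, within (0, 1).
#' @param burnin_generations Generations of evolution before sampling
#'   (for two demes: the contact phase after divergence). Default
#'   `min(4 * N_final, 500)`, enough for LD at recombination fractions of
#'   0.01 or more to approach drift-recombination stationarity at desk
#'   scale.
#' @param seed RNG seed for the run.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(ne = 100,
                       n_demes = 1,
                       migration_rate = 0,
                       divergence_burnin = 0,
                       n_chromosomes = 1,
                       loci_per_chromosome = 100,
                       chrom_length_morgans = 1.0,
                       init_freq_low = 0.05,
                       init_freq_high = 0.95,
                       burnin_generations = NULL,
                       seed = 1L) {
  if (is.numeric(ne) && length(ne) == 1L)
    ne <- data.frame(generation = 0L, N = ne)
  stopifnot(is.data.frame(ne), all(c("generation", "N") %in% names(ne)))
  ne <- ne[order(ne$generation), , drop = FALSE]
  if (ne$generation[1] != 0) stop("ne trajectory must start at generation 0")
  if (any(ne$N < 2)) stop("invalid config: trajectory implies N < 2")
  if (!n_demes %in% c(1, 2)) stop("n_demes must be 1 or 2")
  if (migration_rate < 0 || migration_rate >= 1)
    stop("migration_rate must lie in [0, 1)")
  if (n_demes == 1 && migration_rate != 0)
    stop("migration_rate must be 0 when n_demes = 1")
  if (!is_count(n_chromosomes)) stop("n_chromosomes must be a positive integer")
  if (!is_count(loci_per_chromosome, min = 2))
    stop("loci_per_chromosome must be an integer >= 2")
  if (chrom_length_morgans <= 0) stop("chrom_length_morgans must be > 0")
  if (init_freq_low <= 0 || init_freq_high >= 1 || init_freq_low >= init_freq_high)
    stop("initial frequency bounds must satisfy 0 < low < high < 1")
  if (divergence_burnin < 0) stop("divergence_burnin must be >= 0")
  n_final <- ne$N[nrow(ne)]
  if (is.null(burnin_generations))
    burnin_generations <- min(4 * n_final, 500)
  if (burnin_generations < 0) stop("burnin_generations must be >= 0")
  structure(list(
    ne_trajectory = ne,
    n_demes = as.integer(n_demes),
    migration_rate = migration_rate,
    divergence_burnin = as.integer(divergence_burnin),
    n_chromosomes = as.integer(n_chromosomes),
    loci_per_chromosome = as.integer(loci_per_chromosome),
    chrom_length_morgans = chrom_length_morgans,
    init_freq_low = init_freq_low,
    init_freq_high = init_freq_high,
    burnin_generations = as.integer(burnin_generations),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Step-function lookup of per-deme N at generation g (forward time).
trajectory_n <- function(traj, g) {
  idx <- findInterval(g, traj$generation)
  as.integer(traj$N[pmax(idx, 1L)])
}

# Random genetic map for one run: per chromosome, sorted uniform genetic
# positions; bp at 1 cM = 1 Mb, nudged to be strictly increasing (bp
# carries order only).
random_locus_map <- function(n_chrom, loci_per_chrom, chrom_len) {
  chrom <- rep(seq_len(n_chrom), each = loci_per_chrom)
  gpos <- unlist(lapply(seq_len(n_chrom), function(i)
    sort(runif(loci_per_chrom, 0, chrom_len))), use.names = FALSE)
  bp <- unlist(lapply(split(gpos, chrom), function(g) {
    b <- cummax(as.integer(round(g * 1e8)) + 1L)
    b + seq_along(b) - 1L
  }), use.names = FALSE)
  locus_map(chrom, bp, gpos)
}

# Per-locus haplotype switch probabilities: 0.5 at each chromosome start
# (fair-coin start + independence between chromosomes), Haldane c of the
# map interval elsewhere.
switch_probs <- function(map) {
  L <- nrow(map)
  cs <- numeric(L)
  first <- !duplicated(map$chrom)
  d <- c(0, diff(map$genetic_pos))
  cs[!first] <- haldane_c(d[!first])
  cs[first] <- 0.5
  cs
}

#' Run a forward Wright-Fisher simulation
#'
#' Simulates the configured population and returns the final generation as
#' a [genotype_matrix()] together with the realized trajectory, the
#' generation-0 allele frequencies (for drift calibration) and per
#' individual pedigree ancestry. Deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_population`: list with elements
#'   `genotypes` ([genotype_matrix()] of the whole final generation),
#'   `true_ne_trajectory` (`data.frame(generation, N)` per deme, as
#'   realized), `init_freqs`, `config` and `seed`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_population_impl(config))
}

simulate_population_impl <- function(config) {
  L <- config$n_chromosomes * config$loci_per_chromosome
  map <- random_locus_map(config$n_chromosomes, config$loci_per_chromosome,
                          config$chrom_length_morgans)
  cs <- switch_probs(map)
  nd <- config$n_demes
  traj <- config$ne_trajectory
  n0 <- trajectory_n(traj, 0)

  p0 <- runif(L, config$init_freq_low, config$init_freq_high)
  ntot <- n0 * nd
  # founders: linkage equilibrium, both demes drawn from the same pool
  hap1 <- matrix(as.integer(runif(ntot * L) < rep(p0, each = ntot)), ntot, L)
  hap2 <- matrix(as.integer(runif(ntot * L) < rep(p0, each = ntot)), ntot, L)
  deme <- rep(seq_len(nd), each = n0)
  q <- if (nd == 2) as.numeric(deme == 1L) else rep(1, ntot)
  init_freqs <- colMeans(hap1 + hap2) / 2

  phases <- if (nd == 2) {
    list(c(config$divergence_burnin, 0),
         c(config$burnin_generations, config$migration_rate))
  } else {
    list(c(config$burnin_generations, 0))
  }

  g <- 0L
  realized <- list(data.frame(generation = 0L, N = n0))
  for (ph in phases) {
    ngen <- ph[1]; m <- ph[2]
    for (k in seq_len(ngen)) {
      g <- g + 1L
      n_off <- trajectory_n(traj, g)
      off_deme <- rep(seq_len(nd), each = n_off)
      mothers <- draw_parents(off_deme, deme, m)
      fathers <- draw_parents(off_deme, deme, m)
      new1 <- wf_gametes_cpp(hap1, hap2, mothers, cs)
      new2 <- wf_gametes_cpp(hap1, hap2, fathers, cs)
      q <- (q[mothers] + q[fathers]) / 2
      hap1 <- new1; hap2 <- new2; deme <- off_deme
      realized[[length(realized) + 1L]] <- data.frame(generation = g, N = n_off)
    }
  }

  dos <- hap1 + hap2
  storage.mode(dos) <- "integer"
  G <- genotype_matrix(dos, map,
                       deme = c("A", "B")[deme],
                       q = q)
  mono <- monomorphic_loci(G)
  if (all(mono))
    warning("all loci fixed after burn-in; no polymorphism left")
  structure(list(
    genotypes = G,
    true_ne_trajectory = do.call(rbind, realized),
    init_freqs = init_freqs,
    n_monomorphic = sum(mono),
    config = config,
    seed = config$seed
  ), class = "sim_population")
}

# One parent index per offspring: uniform within the offspring's deme,
# switched to the other deme with probability m (gamete migration).
draw_parents <- function(off_deme, parent_deme, m) {
  nd <- max(parent_deme)
  src <- off_deme
  if (m > 0 && nd == 2L) {
    mig <- runif(length(src)) < m
    src[mig] <- 3L - src[mig]
  }
  idx_by_deme <- lapply(seq_len(nd), function(d) which(parent_deme == d))
  out <- integer(length(src))
  for (d in seq_len(nd)) {
    sel <- src == d
    pool <- idx_by_deme[[d]]
    out[sel] <- pool[sample.int(length(pool), sum(sel), replace = TRUE)]
  }
  out
}

#' @export
print.sim_population <- function(x, ...) {
  tr <- x$true_ne_trajectory
  cat("sim_population: ", n_individuals(x$genotypes), " individuals (",
      x$config$n_demes, " deme(s)), ", n_loci(x$genotypes), " loci, ",
      max(tr$generation), " generations, seed ", x$seed, "\n", sep = "")
  print(x$genotypes)
  invisible(x)
}

#' Write the realized Ne trajectory as TSV
#'
#' @param pop A [simulate_population()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(pop, path) {
  stopifnot(inherits(pop, "sim_population"))
  write.table(pop$true_ne_trajectory, path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
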