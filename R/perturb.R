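# Perturbation operators used by the robustness experiments. All operators
# are pure: they return a new genotype_matrix and never modify the input.

#' Sample individuals without replacement
#'
#' @param G A [genotype_matrix()] or [simulate_population()] result.
#' @param n Number of distinct individuals to keep (1 <= n <= S).
#' @param seed RNG seed.
#' @return A [genotype_matrix()] with `n` individuals, metadata carried,
#'   row order normalized to the original order.
#' @export
sample_individuals <- function(G, n, seed = 1L) {
  G <- as_genotype_matrix(G)
  S <- n_individuals(G)
  if (!is_count(n) || n > S)
    stop("cannot sample ", n, " individuals from ", S, " available")
  keep <- with_seed(seed, sort(sample.int(S, n)))
  subset_genotypes(G, individuals = keep)
}

#' Inject missing genotypes completely at random (MCAR)
#'
#' Each genotype of individual `i` is independently set to missing with
#' probability `rate[i]`. Optionally, the missingness probability of
#' heterozygous genotypes is inflated by `het_factor` (capped at 1) to
#' probe genotype-dependent (non-random) missingness, as can arise from
#' depth-based genotype filtering.
#'
#' @param G A [genotype_matrix()] or simulation result.
#' @param rate Missing rate in `[0, 1)`, scalar or one value per individual.
#' @param seed RNG seed.
#' @param het_factor Multiplier on the rate for heterozygote genotypes
#'   (default 1 = MCAR).
#' @return A new [genotype_matrix()]; attribute `realized_missing` reports
#'   the realized per-individual missing fraction.
#' @export
inject_missing <- function(G, rate, seed = 1L, het_factor = 1) {
  G <- as_genotype_matrix(G)
  S <- n_individuals(G); L <- n_loci(G)
  rate <- rep_len(as.numeric(rate), S)
  if (any(rate < 0 | rate >= 1)) stop("missing rate must lie in [0, 1)")
  if (het_factor < 1) stop("het_factor must be >= 1")
  dos <- G$dosages
  with_seed(seed, {
    p <- matrix(rate, S, L)
    if (het_factor > 1)
      p[which(dos == 1L)] <- pmin(p[which(dos == 1L)] * het_factor, 1)
    hit <- matrix(runif(S * L), S, L) < p
    dos[hit] <- NA_integer_
  })
  out <- genotype_matrix(dos, G$map, ids = G$ids, deme = G$deme, q = G$q)
  attr(out, "realized_missing") <- rowMeans(is.na(dos))
  out
}

#' Downsample loci without replacement
#'
#' @param G A [genotype_matrix()] or simulation result.
#' @param n Number of distinct loci to keep (1 <= n <= L).
#' @param seed RNG seed.
#' @return A [genotype_matrix()] over `n` loci; the map is subset in step
#'   and the original (chrom, bp) order is preserved.
#' @export
downsample_loci <- function(G, n, seed = 1L) {
  G <- as_genotype_matrix(G)
  L <- n_loci(G)
  if (!is_count(n) || n > L)
    stop("cannot sample ", n, " loci from ", L, " available")
  keep <- with_seed(seed, sort(sample.int(L, n)))
  subset_genotypes(G, loci = keep)
}

#' Fragment a chromosome map into pseudo-chromosomes
#'
#' Emulates treating sub-chromosomal assembly scaffolds as chromosomes:
#' each chromosome's locus list is split into `n_chrom_assumed / k`
#' consecutive blocks of near-equal locus count (sizes differing by at most
#' one), where `k` is the current chromosome count. Pseudo-chromosomes are
#' renumbered `1..n_chrom_assumed` and, following the "each chromosome is
#' about 1 Morgan" convention of map-free tools, each block's genetic
#' positions are reassigned proportionally to physical position across the
#' block, spanning exactly 1 Morgan. True genetic positions are therefore
#' deliberately discarded in the returned map (keep the original map to
#' measure the induced bias).
#'
#' @param map A [locus_map()].
#' @param n_chrom_assumed Target chromosome count; must be a multiple of
#'   the current count and at least equal to it.
#' @return A new [locus_map()].
#' @export
fragment_map <- function(map, n_chrom_assumed) {
  stopifnot(inherits(map, "locus_map"))
  k <- length(unique(map$chrom))
  if (!is_count(n_chrom_assumed) || n_chrom_assumed < k ||
      n_chrom_assumed %% k != 0)
    stop("n_chrom_assumed (", n_chrom_assumed,
         ") must be an integer multiple of the current chromosome count (",
         k, ")")
  per <- n_chrom_assumed / k
  new_chrom <- integer(nrow(map))
  new_gpos <- numeric(nrow(map))
  nxt <- 1L
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    for (b in split_blocks(length(idx), per)) {
      blk <- idx[b]
      new_chrom[blk] <- nxt
      bp <- map$bp[blk]
      span <- max(bp) - min(bp)
      new_gpos[blk] <- if (span > 0) (bp - min(bp)) / span else 0
      nxt <- nxt + 1L
    }
  }
  locus_map(new_chrom, map$bp, new_gpos, ref = map$ref, alt = map$alt)
}

# Indices 1..n split into k consecutive blocks, sizes differing by <= 1
# (earlier blocks take the remainder: 10 into 3 -> 4, 3, 3).
split_blocks <- function(n, k) {
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  if (any(sizes == 0)) stop("cannot split ", n, " loci into ", k, " blocks")
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  Map(seq.int, starts, ends)
}

#' Select individuals by ancestry (Q-value) threshold
#'
#' Keeps the individuals whose pedigree ancestry fraction in the stated
#' deme is at least `q_min` (ancestry in deme "A" is `q`; in deme "B",
#' `1 - q`).
#'
#' @param G A [genotype_matrix()] or simulation result with `q` values.
#' @param q_min Lower ancestry bound in `[0, 1]`.
#' @param deme `"A"` or `"B"`.
#' @return A [genotype_matrix()] of the selected individuals.
#' @export
stratify_by_q <- function(G, q_min, deme = c("A", "B")) {
  G <- as_genotype_matrix(G)
  deme <- match.arg(deme)
  if (is.null(G$q)) stop("genotype matrix carries no q values")
  if (q_min < 0 || q_min > 1) stop("q_min must lie in [0, 1]")
  anc <- if (deme == "A") G$q else 1 - G$q
  keep <- which(anc >= q_min)
  if (!length(keep))
    stop("empty selection: no individual has ancestry >= ", q_min,
         " in deme ", deme)
  subset_genotypes(G, individuals = keep)
}

# Accept either a genotype_matrix or a sim_population wherever genotypes
# are expected.
as_genotype_matrix <- function(G) {
  if (inherits(G, "sim_population")) return(G$genotypes)
  if (inherits(G, "genotype_matrix")) return(G)
  stop("expected a genotype_matrix or sim_population")
}
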