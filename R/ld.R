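# LD core: composite r^2 on unphased dosages, the unlinked-pair
# contemporary Ne estimator with sample-size bias correction and
# delete-one jackknife CIs, and the Sved-binned recent-history trajectory.
#
# The pair statistic is the squared Pearson correlation of dosage vectors
# over pairwise-complete individuals: the composite (Burrows-type)
# surrogate for gametic r^2 with unphased data under random mating.
# Before the sampling correction, the estimators scale each pair's r^2 by
# (S_pair/(S_pair - 1))^2 -- the Burrows covariance bias-correction factor
# of the classical LD-Ne tools, whose null expectation
# (1/(S-1)) * (S/(S-1))^2 matches the calibration below to four decimals
# at every S (plain Pearson r^2 has null expectation 1/(S-1) and would be
# over-corrected by ~1.5x at S = 50). Calibration (random mating):
#   S >= 30: E_samp = 1/S + 3.19/S^2,   N = (1/3 + sqrt(1/9 - 2.76 r2'))/(2 r2')
#   S  < 30: E_samp = 0.0018 + 0.907/S + 4.44/S^2,
#            N = (0.308 + sqrt(0.308^2 - 2.08 r2'))/(2 r2')
# with r2' = mean(adjusted r^2) - E_samp(S~) and S~ the harmonic mean of
# pairwise-complete sample sizes.

PAIR_ENUM_LIMIT <- 3e6  # above this many candidate pairs, sample instead

#' Haldane map function
#'
#' Converts a genetic distance in Morgans to a recombination fraction,
#' assuming crossovers occur as a Poisson process with no interference:
#' `c = 0.5 * (1 - exp(-2 d))`.
#'
#' @param d Distance in Morgans (>= 0), vectorized.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @export
haldane_c <- function(d) {
  if (any(d < 0)) stop("map distance must be >= 0 Morgans")
  0.5 * (1 - exp(-2 * d))
}

#' Expected sampling contribution to r-squared
#'
#' The expected value of the composite r^2 for truly independent loci in a
#' finite sample of `S` individuals (random-mating calibration); subtracted
#' from the observed mean r^2 before inverting for Ne.
#'
#' @param S (Harmonic mean) sample size, vectorized.
#' @return Expected r^2 under the null.
#' @export
sampling_r2 <- function(S) {
  ifelse(S >= 30, 1 / S + 3.19 / S^2, 0.0018 + 0.907 / S + 4.44 / S^2)
}

#' Invert drift r-squared to Ne (unlinked loci)
#'
#' Solves the random-mating drift expectation for Ne given the
#' sampling-corrected mean r^2 of unlinked (c = 0.5) locus pairs. Returns
#' `Inf` when `r2_prime <= 0` (no drift signal distinguishable from
#' sampling noise). When `r2_prime` exceeds the maximum the forward
#' relation can produce (negative discriminant, e.g. under strong mixture
#' LD from pooled gene pools), the estimate saturates at the invertible
#' floor -- the Ne at which the forward relation peaks (about 4.1 / 3.4
#' diploids in the two regimes) -- rather than going infinite, since such
#' data imply an extremely *small* apparent Ne; [estimate_ne_unlinked()]
#' flags this case.
#'
#' @param r2_prime Sampling-corrected mean r^2.
#' @param S Harmonic mean sample size (selects the calibration regime).
#' @return Estimated Ne (diploid individuals), possibly `Inf`.
#' @export
waples_ne <- function(r2_prime, S) {
  stopifnot(length(r2_prime) == 1, length(S) == 1)
  if (!is.finite(r2_prime) || r2_prime <= 0) return(Inf)
  if (S >= 30) { a <- 1 / 3; k <- 2.76 } else { a <- 0.308; k <- 2.08 }
  disc <- a^2 - k * r2_prime
  if (disc < 0) return(k / (2 * a))  # floor: peak of the forward relation
  (a + sqrt(disc)) / (2 * r2_prime)
}

# TRUE when r2_prime lies beyond the invertible range of the calibration.
waples_saturated <- function(r2_prime, S) {
  is.finite(r2_prime) && r2_prime > 0 &&
    (if (S >= 30) 1 / 9 - 2.76 * r2_prime else 0.308^2 - 2.08 * r2_prime) < 0
}

#' Invert the Sved relation to Ne (linked loci)
#'
#' From `E[r^2] = 1 / (1 + 4 N c)` (plus the sampling term, already
#' subtracted): `N = (1/r2' - 1) / (4 c)`. LD at recombination fraction `c`
#' reflects Ne roughly `1 / (2 c)` generations ago.
#'
#' @param r2_prime Sampling-corrected mean r^2 in the distance bin.
#' @param c_bar Mean recombination fraction of the bin, in (0, 0.5].
#' @return Estimated Ne, `Inf` when `r2_prime <= 0`.
#' @export
sved_ne <- function(r2_prime, c_bar) {
  stopifnot(c_bar > 0, c_bar <= 0.5)
  if (!is.finite(r2_prime) || r2_prime <= 0) return(Inf)
  max((1 / r2_prime - 1) / (4 * c_bar), 0)
}

#' Invert the Weir-Hill drift expectation to Ne (linked loci)
#'
#' The Sved form `1/(1 + 4Nc)` is accurate only for tightly linked loci;
#' for the composite r^2 under monoecious random mating the drift
#' expectation across the whole c range is
#' `E[r^2] = ((1-c)^2 + c^2) / (2 N c (2-c))`, which reduces to `1/(4Nc)`
#' as `c -> 0` and to `1/(3N)` at `c = 0.5`. [estimate_ne_trajectory()]
#' inverts this form per bin (using Sved instead inflates recent-Ne bins
#' by ~1.5x; see the methods vignette).
#'
#' @param r2_prime Sampling-corrected mean r^2 in the distance bin.
#' @param c_bar Mean recombination fraction of the bin, in (0, 0.5].
#' @return Estimated Ne, `Inf` when `r2_prime <= 0`.
#' @export
weir_hill_ne <- function(r2_prime, c_bar) {
  stopifnot(c_bar > 0, c_bar <= 0.5)
  if (!is.finite(r2_prime) || r2_prime <= 0) return(Inf)
  ((1 - c_bar)^2 + c_bar^2) / (2 * c_bar * (2 - c_bar) * r2_prime)
}

#' Composite r-squared for a pair of dosage vectors
#'
#' Squared Pearson correlation over pairwise-complete individuals.
#'
#' @param x,y Dosage vectors (0/1/2/NA) of equal length.
#' @return r^2 in `[0, 1]`, or `NA` if fewer than 2 complete pairs or a
#'   vector is constant over the complete subset.
#' @export
composite_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Pairing policy for LD computations
#'
#' Controls which locus pairs enter the LD summary: `"unlinked"` uses only
#' between-chromosome pairs (assigned c = 0.5), `"linked_binned"` uses
#' within-chromosome pairs binned by recombination fraction (Haldane of the
#' map distance), `"all"` uses both.
#'
#' @param mode `"unlinked"`, `"linked_binned"` or `"all"`.
#' @param bin_edges Breaks of the recombination-fraction bins (strictly
#'   increasing, within (0, 0.5], last exactly 0.5). Default: 12 log-spaced
#'   bins over `[0.001, 0.5]`. Within-chromosome pairs below the first edge
#'   are dropped and counted.
#' @param max_pairs_per_bin Cap per pair class/bin; larger sets are
#'   subsampled with `seed` (analogous to the per-chromosome SNP caps of
#'   genome-scale LD tools).
#' @param min_pair_S Minimum pairwise-complete individuals for a pair to be
#'   retained (missingness otherwise makes r^2 unstable).
#' @param min_pairs_per_bin Bins with fewer retained pairs are dropped from
#'   trajectories, with a warning.
#' @param seed Seed for pair subsampling.
#' @return A `pair_policy` list.
#' @export
pair_policy <- function(mode = c("unlinked", "linked_binned", "all"),
                        bin_edges = NULL,
                        max_pairs_per_bin = 50000,
                        min_pair_S = 10,
                        min_pairs_per_bin = 100,
                        seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(bin_edges)) {
    bin_edges <- exp(seq(log(0.001), log(0.5), length.out = 13))
    bin_edges[length(bin_edges)] <- 0.5
  }
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be strictly increasing")
  if (bin_edges[1] <= 0 || abs(bin_edges[length(bin_edges)] - 0.5) > 1e-12)
    stop("bin edges must lie in (0, 0.5] with last edge 0.5")
  if (!is_count(max_pairs_per_bin)) stop("max_pairs_per_bin must be a positive integer")
  if (!is_count(min_pair_S, min = 2)) stop("min_pair_S must be an integer >= 2")
  structure(list(mode = mode, bin_edges = bin_edges,
                 max_pairs_per_bin = as.integer(max_pairs_per_bin),
                 min_pair_S = as.integer(min_pair_S),
                 min_pairs_per_bin = as.integer(min_pairs_per_bin),
                 seed = as.integer(seed)),
            class = "pair_policy")
}

# ---- pair enumeration ------------------------------------------------------

# All unordered pairs (i < j) of 1..n as two integer vectors.
all_pairs_idx <- function(n) {
  if (n < 2) return(list(i = integer(0), j = integer(0)))
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  list(i = i, j = j)
}

# k unordered pairs sampled uniformly (rejection on i < j and uniqueness);
# filter keeps only pairs satisfying the predicate on (i, j).
sample_pairs_idx <- function(n, k, keep = NULL) {
  got_i <- integer(0); got_j <- integer(0)
  seen <- character(0)
  tries <- 0L
  while (length(got_i) < k && tries < 50L) {
    m <- ceiling((k - length(got_i)) * 2.5)
    a <- sample.int(n, m, replace = TRUE)
    b <- sample.int(n, m, replace = TRUE)
    lo <- pmin(a, b); hi <- pmax(a, b)
    ok <- lo < hi
    lo <- lo[ok]; hi <- hi[ok]
    if (!is.null(keep)) {
      ok2 <- keep(lo, hi)
      lo <- lo[ok2]; hi <- hi[ok2]
    }
    key <- paste(lo, hi)
    new <- !duplicated(key) & !(key %in% seen)
    got_i <- c(got_i, lo[new]); got_j <- c(got_j, hi[new])
    seen <- c(seen, key[new])
    tries <- tries + 1L
  }
  if (length(got_i) > k) { got_i <- got_i[seq_len(k)]; got_j <- got_j[seq_len(k)] }
  list(i = got_i, j = got_j)
}

# Between-chromosome candidate pairs, capped at `cap` (subsampled with the
# policy seed when necessary).
between_pairs <- function(map, cap, seed) {
  L <- nrow(map)
  chrom <- map$chrom
  n_within <- sum(vapply(split(seq_len(L), chrom),
                         function(ix) choose(length(ix), 2), numeric(1)))
  n_between <- choose(L, 2) - n_within
  if (n_between == 0) return(list(i = integer(0), j = integer(0)))
  if (choose(L, 2) <= PAIR_ENUM_LIMIT) {
    p <- all_pairs_idx(L)
    keep <- chrom[p$i] != chrom[p$j]
    p <- list(i = p$i[keep], j = p$j[keep])
    if (length(p$i) > cap) {
      sel <- with_seed(seed, sample.int(length(p$i), cap))
      p <- list(i = p$i[sel], j = p$j[sel])
    }
    p
  } else {
    with_seed(seed, sample_pairs_idx(
      L, min(cap, n_between),
      keep = function(a, b) chrom[a] != chrom[b]))
  }
}

# Within-chromosome candidate pairs with recombination fractions.
within_pairs <- function(map, cap_total, seed) {
  chrom <- map$chrom; gpos <- map$genetic_pos
  out_i <- list(); out_j <- list()
  with_seed(seed, {
    for (ix in split(seq_len(nrow(map)), chrom)) {
      n <- length(ix)
      if (n < 2) next
      npairs <- choose(n, 2)
      p <- if (npairs <= PAIR_ENUM_LIMIT) all_pairs_idx(n)
           else sample_pairs_idx(n, cap_total)
      out_i[[length(out_i) + 1L]] <- ix[p$i]
      out_j[[length(out_j) + 1L]] <- ix[p$j]
    }
  })
  i <- unlist(out_i, use.names = FALSE) %||% integer(0)
  j <- unlist(out_j, use.names = FALSE) %||% integer(0)
  cfrac <- haldane_c(abs(gpos[j] - gpos[i]))
  list(i = i, j = j, c = cfrac)
}

# ---- pairwise sufficient statistics ---------------------------------------

# Per-pair pairwise-complete sums, chunked to bound memory:
# n, Sx, Sy, Sxy, Sxx, Syy with missing entries zeroed out.
pair_stats <- function(dos, pi, pj) {
  S <- nrow(dos)
  M <- !is.na(dos); storage.mode(M) <- "double"
  Xz <- dos; Xz[is.na(Xz)] <- 0L; storage.mode(Xz) <- "double"
  X2 <- Xz * Xz
  P <- length(pi)
  out <- list(n = numeric(P), Sx = numeric(P), Sy = numeric(P),
              Sxy = numeric(P), Sxx = numeric(P), Syy = numeric(P))
  chunk <- max(1L, as.integer(2e6 / max(S, 1L)))
  for (s in seq(1L, P, by = chunk)) {
    e <- min(s + chunk - 1L, P)
    ii <- pi[s:e]; jj <- pj[s:e]
    ma <- M[, ii, drop = FALSE]; mb <- M[, jj, drop = FALSE]
    a <- Xz[, ii, drop = FALSE]; b <- Xz[, jj, drop = FALSE]
    out$n[s:e] <- colSums(ma * mb)
    out$Sx[s:e] <- colSums(a * mb)
    out$Sy[s:e] <- colSums(b * ma)
    out$Sxy[s:e] <- colSums(a * b)
    out$Sxx[s:e] <- colSums(X2[, ii, drop = FALSE] * mb)
    out$Syy[s:e] <- colSums(X2[, jj, drop = FALSE] * ma)
  }
  out
}

# r^2 per pair from sufficient statistics; NA where the pair has fewer than
# min_n complete individuals or zero variance.
r2_from_stats <- function(st, min_n) {
  num <- st$n * st$Sxy - st$Sx * st$Sy
  dx <- st$n * st$Sxx - st$Sx^2
  dy <- st$n * st$Syy - st$Sy^2
  r2 <- num^2 / (dx * dy)
  r2[st$n < min_n | dx <= 0 | dy <= 0] <- NA_real_
  r2
}

# Delete-one-individual downdate of the sufficient statistics.
delete_one_stats <- function(st, dos, pi, pj, d) {
  xd <- dos[d, pi]; yd <- dos[d, pj]
  mx <- as.numeric(!is.na(xd)); my <- as.numeric(!is.na(yd))
  xd[is.na(xd)] <- 0; yd[is.na(yd)] <- 0
  xd <- as.numeric(xd); yd <- as.numeric(yd)
  list(n = st$n - mx * my,
       Sx = st$Sx - xd * my,
       Sy = st$Sy - yd * mx,
       Sxy = st$Sxy - xd * yd,
       Sxx = st$Sxx - xd^2 * my,
       Syy = st$Syy - yd^2 * mx)
}

# ---- user-facing LD summary ------------------------------------------------

#' Pairwise composite r-squared summary
#'
#' Computes, for each pair class of the policy (between-chromosome pairs at
#' c = 0.5 and/or within-chromosome pairs binned by recombination
#' fraction), the arithmetic mean composite r^2, the harmonic mean
#' pairwise-complete sample size, the retained pair count and the mean
#' recombination fraction. Monomorphic loci are excluded up front and
#' pairs with too few complete individuals or zero variance are skipped
#' and counted.
#'
#' @param G A [genotype_matrix()] or simulation result.
#' @param policy A [pair_policy()].
#' @return A `data.frame` of class `ld_summary` with columns `class`,
#'   `bin`, `c_bar`, `mean_r2` (plain Pearson, bounded by `[0, 1]`),
#'   `mean_r2_adj` (with the per-pair Burrows `(S/(S-1))^2` bias-correction
#'   factor, the value the Ne estimators consume), `s_harm`, `n_pairs`,
#'   `n_skipped`; attribute `n_monomorphic_dropped`.
#' @export
pairwise_r2 <- function(G, policy = pair_policy()) {
  G <- as_genotype_matrix(G)
  if (n_individuals(G) < 2) stop("need at least 2 individuals")
  mono <- monomorphic_loci(G)
  Gp <- if (any(mono)) subset_genotypes(G, loci = which(!mono)) else G
  if (n_loci(Gp) < 2)
    stop("too few SNP pairs: fewer than 2 polymorphic loci after filtering")
  rows <- list()
  if (policy$mode %in% c("unlinked", "all")) {
    bp <- between_pairs(Gp$map, policy$max_pairs_per_bin, policy$seed)
    rows[[length(rows) + 1L]] <-
      summarize_class(Gp, bp$i, bp$j, rep(0.5, length(bp$i)),
                      class = "between", bin = NA_integer_, policy)
  }
  if (policy$mode %in% c("linked_binned", "all")) {
    wp <- within_pairs(Gp$map, policy$max_pairs_per_bin, policy$seed)
    binned <- assign_bins(wp, policy)
    for (b in seq_len(length(policy$bin_edges) - 1L)) {
      sel <- which(binned$bin == b)
      rows[[length(rows) + 1L]] <-
        summarize_class(Gp, binned$i[sel], binned$j[sel], binned$c[sel],
                        class = "within", bin = b, policy)
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("ld_summary", "data.frame"),
            n_monomorphic_dropped = sum(mono))
}

# Bin within-chromosome pairs by c; cap each bin at max_pairs_per_bin.
assign_bins <- function(wp, policy) {
  edges <- policy$bin_edges
  bin <- findInterval(wp$c, edges, rightmost.closed = TRUE)
  bin[wp$c < edges[1] | wp$c > edges[length(edges)]] <- NA_integer_
  keep <- !is.na(bin)
  i <- wp$i[keep]; j <- wp$j[keep]; cf <- wp$c[keep]; bin <- bin[keep]
  # per-bin cap
  sel <- with_seed(policy$seed, unlist(lapply(
    split(seq_along(bin), bin),
    function(ix) if (length(ix) > policy$max_pairs_per_bin)
      ix[sample.int(length(ix), policy$max_pairs_per_bin)] else ix),
    use.names = FALSE))
  sel <- sort(sel %||% integer(0))
  list(i = i[sel], j = j[sel], c = cf[sel], bin = bin[sel],
       n_below_first_edge = sum(!keep))
}

summarize_class <- function(G, pi, pj, cfrac, class, bin, policy) {
  if (!length(pi)) {
    return(data.frame(class = class, bin = bin, c_bar = NA_real_,
                      mean_r2 = NA_real_, mean_r2_adj = NA_real_,
                      s_harm = NA_real_, n_pairs = 0L, n_skipped = 0L))
  }
  st <- pair_stats(G$dosages, pi, pj)
  r2 <- r2_from_stats(st, policy$min_pair_S)
  ok <- !is.na(r2)
  data.frame(class = class, bin = bin,
             c_bar = if (any(ok)) mean(cfrac[ok]) else NA_real_,
             mean_r2 = if (any(ok)) mean(r2[ok]) else NA_real_,
             mean_r2_adj = if (any(ok)) mean(burrows_adjust(r2, st$n)[ok])
                           else NA_real_,
             s_harm = if (any(ok)) harmonic_mean(st$n[ok]) else NA_real_,
             n_pairs = sum(ok), n_skipped = sum(!ok))
}

# Burrows covariance bias-correction: per pair, r^2 * (n/(n-1))^2 with n
# the pair's complete sample size. This is what makes the adopted E_samp
# calibration (whose null value is (1/(n-1)) * (n/(n-1))^2) applicable.
burrows_adjust <- function(r2, n) r2 * (n / (n - 1))^2

# ---- Ne estimators ---------------------------------------------------------

new_ne_estimate <- function(point, ci_low, ci_high, method, r2_mean, r2_prime,
                            s_harm, n_pairs, n_skipped, n_loci_used,
                            n_monomorphic_dropped, generations_ago,
                            jackknife_sd = NA_real_, correction = NULL) {
  structure(list(
    point = point, ci_low = ci_low, ci_high = ci_high, method = method,
    r2_mean = r2_mean, r2_prime = r2_prime, s_harm = s_harm,
    n_pairs = n_pairs, n_skipped = n_skipped, n_loci_used = n_loci_used,
    n_monomorphic_dropped = n_monomorphic_dropped,
    generations_ago = generations_ago, jackknife_sd = jackknife_sd,
    correction = correction,
    flags = list(infinite = !is.finite(point),
                 negative_r2_prime = is.finite(r2_prime) && r2_prime <= 0,
                 saturated = waples_saturated(r2_prime, s_harm))
  ), class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  fmt <- function(v) if (!is.finite(v)) "Inf" else format(round(v, 1), nsmall = 1)
  cat("Ne estimate (", x$method, "): ", fmt(x$point),
      "  [", fmt(x$ci_low), "-", fmt(x$ci_high), "]\n", sep = "")
  cat("  mean r2 = ", signif(x$r2_mean, 5), ", r2' = ", signif(x$r2_prime, 5),
      ", S~ = ", round(x$s_harm, 2), ", pairs = ", x$n_pairs, "\n", sep = "")
  if (!is.null(x$correction))
    cat("  physical-linkage correction applied: y = ",
        signif(x$correction$y, 5), " (Chr = ", x$correction$chr_count, ")\n",
        sep = "")
  invisible(x)
}

#' Contemporary Ne from unlinked locus pairs
#'
#' Estimates Ne from the mean composite r^2 of between-chromosome (or, with
#' an `"all"` policy, all) locus pairs. Each pair's squared dosage
#' correlation is scaled by the Burrows covariance bias-correction factor
#' `(S_pair/(S_pair - 1))^2` (making the adopted `E_samp` calibration
#' applicable; see [sampling_r2()]), corrected for the sampling
#' contribution and inverted through the random-mating drift calibration.
#' Confidence intervals come from a delete-one jackknife over individuals:
#' the jackknife variance is computed on the corrected r2' scale (where the
#' normal approximation is reasonable) and the endpoints are transformed
#' through the same inversion; a non-invertible endpoint is reported as
#' `Inf`. The estimate refers to Ne in the most recent generations
#' (`1 / (2 c)` with c = 0.5 gives ~1 generation back).
#'
#' @param G A [genotype_matrix()] or simulation result.
#' @param policy A [pair_policy()] with mode `"unlinked"` or `"all"`.
#' @param ci Compute the jackknife CI (set `FALSE` to save time in
#'   replicate sweeps that only need the point estimate).
#' @param conf Confidence level (default 0.95).
#' @return An object of class `ne_estimate`.
#' @export
estimate_ne_unlinked <- function(G, policy = pair_policy("unlinked"),
                                 ci = TRUE, conf = 0.95) {
  G <- as_genotype_matrix(G)
  if (!policy$mode %in% c("unlinked", "all"))
    stop("estimate_ne_unlinked requires an 'unlinked' or 'all' pair policy")
  S <- n_individuals(G)
  if (S < 2) stop("need at least 2 individuals")
  mono <- monomorphic_loci(G)
  Gp <- if (any(mono)) subset_genotypes(G, loci = which(!mono)) else G
  if (n_loci(Gp) < 2)
    stop("too few SNP pairs (class between-chromosome): fewer than 2 usable loci")
  pr <- between_pairs(Gp$map, policy$max_pairs_per_bin, policy$seed)
  cfrac <- rep(0.5, length(pr$i))
  if (policy$mode == "all") {
    wp <- within_pairs(Gp$map, policy$max_pairs_per_bin, policy$seed)
    bn <- assign_bins(wp, policy)
    pr <- list(i = c(pr$i, bn$i), j = c(pr$j, bn$j))
    cfrac <- c(cfrac, bn$c)
  }
  if (!length(pr$i))
    stop("too few SNP pairs (class between-chromosome): no eligible pairs")
  st <- pair_stats(Gp$dosages, pr$i, pr$j)
  r2 <- r2_from_stats(st, policy$min_pair_S)
  ok <- !is.na(r2)
  if (!any(ok))
    stop("too few SNP pairs (class between-chromosome): ",
         "all pairs skipped (missingness or zero variance)")
  s_harm <- harmonic_mean(st$n[ok])
  if (s_harm < 4)
    stop("harmonic mean pairwise sample size (", round(s_harm, 2),
         ") below the minimum of 4")
  r2_mean <- mean(burrows_adjust(r2, st$n)[ok])
  r2p <- r2_mean - sampling_r2(s_harm)
  point <- waples_ne(r2p, s_harm)

  ci_low <- NA_real_; ci_high <- NA_real_; jsd <- NA_real_
  if (ci) {
    theta <- vapply(seq_len(S), function(d) {
      std <- delete_one_stats(st, Gp$dosages, pr$i, pr$j, d)
      r2d <- r2_from_stats(std, policy$min_pair_S)
      okd <- !is.na(r2d)
      if (!any(okd)) return(NA_real_)
      sh <- harmonic_mean(std$n[okd])
      mean(burrows_adjust(r2d, std$n)[okd]) - sampling_r2(sh)
    }, numeric(1))
    theta <- theta[!is.na(theta)]
    ns <- length(theta)
    if (ns >= 2) {
      jsd <- sqrt((ns - 1) / ns * sum((theta - mean(theta))^2))
      z <- stats::qnorm(1 - (1 - conf) / 2)
      ci_low <- waples_ne(r2p + z * jsd, s_harm)
      ci_high <- waples_ne(r2p - z * jsd, s_harm)
      # inversion is decreasing in r2'; keep the interval ordered around
      # the point even in degenerate corners
      ci_low <- min(ci_low, point)
      ci_high <- max(ci_high, point)
    }
  }
  new_ne_estimate(point, ci_low, ci_high, method = "unlinked",
                  r2_mean = r2_mean, r2_prime = r2p, s_harm = s_harm,
                  n_pairs = sum(ok), n_skipped = sum(!ok),
                  n_loci_used = n_loci(Gp),
                  n_monomorphic_dropped = sum(mono),
                  generations_ago = 1 / (2 * mean(cfrac)),
                  jackknife_sd = jsd)
}

#' Recent-history Ne trajectory from distance-binned linked pairs
#'
#' Bins within-chromosome pairs by recombination fraction, corrects each
#' bin's mean r^2 for sampling, and inverts the drift expectation per bin
#' (the Weir-Hill form, [weir_hill_ne()], which matches Sved's
#' `E[r^2] = 1/(1 + 4 N c)` for tightly linked pairs but stays calibrated
#' up to c = 0.5). A bin with mean recombination fraction
#' `c` is referenced to `t = 1/(2 c)` generations ago, so loosely linked
#' pairs inform recent Ne and tightly linked pairs older Ne. Bins below the
#' retained-pair minimum are dropped with a warning; bins whose corrected
#' r^2 is non-positive are reported infinite.
#'
#' @param G A [genotype_matrix()] or simulation result.
#' @param policy A [pair_policy()] with mode `"linked_binned"`.
#' @return A `data.frame` of class `ne_trajectory`, ordered by `t`, with
#'   columns `t`, `ne`, `c_bar`, `n_pairs`, `s_harm`, `r2_mean`,
#'   `r2_prime`.
#' @export
estimate_ne_trajectory <- function(G, policy = pair_policy("linked_binned")) {
  G <- as_genotype_matrix(G)
  if (policy$mode != "linked_binned")
    stop("estimate_ne_trajectory requires a 'linked_binned' pair policy")
  summ <- pairwise_r2(G, policy)
  summ <- summ[summ$class == "within", , drop = FALSE]
  thin <- summ$n_pairs < policy$min_pairs_per_bin
  if (any(thin))
    warning(sum(thin), " bin(s) dropped with fewer than ",
            policy$min_pairs_per_bin, " retained pairs")
  summ <- summ[!thin, , drop = FALSE]
  if (!nrow(summ))
    stop("too few SNP pairs (class within-chromosome): all bins empty")
  r2p <- summ$mean_r2_adj - sampling_r2(summ$s_harm)
  ne <- mapply(weir_hill_ne, r2p, summ$c_bar)
  out <- data.frame(t = 1 / (2 * summ$c_bar), ne = ne, c_bar = summ$c_bar,
                    n_pairs = summ$n_pairs, s_harm = summ$s_harm,
                    r2_mean = summ$mean_r2, r2_prime = r2p)
  out <- out[order(out$t), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ne_trajectory", "data.frame"))
}

#' Summarize a trajectory into a recent-Ne scalar
#'
#' Geometric mean of the finite per-bin estimates with mean recombination
#' fraction at least `c_min` (default 0.1, i.e. the most recent ~5
#' generations). Returns `Inf` when every qualifying bin is infinite.
#'
#' @param traj An [estimate_ne_trajectory()] result.
#' @param c_min Minimum bin recombination fraction to include.
#' @return A single Ne value.
#' @export
summarize_recent_ne <- function(traj, c_min = 0.1) {
  stopifnot(inherits(traj, "ne_trajectory"))
  sel <- traj$c_bar >= c_min
  if (!any(sel)) stop("no bins with c_bar >= ", c_min)
  vals <- traj$ne[sel]
  fin <- vals[is.finite(vals)]
  if (!length(fin)) return(Inf)
  geometric_mean(fin)
}
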