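# Independent brute-force oracle for the LD estimators: explicit loops,
# mean-centred sums, and numerical root-finding for the Ne inversion.
# Deliberately shares no code path with the package internals.

oracle_pair_r2 <- function(x, y, adjust = FALSE) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 2) return(list(r2 = NA_real_, n = n))
  x <- x[ok]; y <- y[ok]
  dx <- x - mean(x); dy <- y - mean(y)
  if (sum(dx^2) == 0 || sum(dy^2) == 0) return(list(r2 = NA_real_, n = n))
  r <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  r2 <- r^2
  if (adjust) r2 <- r2 * (n / (n - 1))^2
  list(r2 = r2, n = n)
}

oracle_esamp <- function(S) {
  if (S >= 30) 1 / S + 3.19 / S^2 else 0.0018 + 0.907 / S + 4.44 / S^2
}

# Inversion by root finding on the forward drift relation (the package
# uses the closed-form quadratic instead).
oracle_invert <- function(r2p, S) {
  if (!is.finite(r2p) || r2p <= 0) return(Inf)
  if (S >= 30) { a <- 1 / 3; b <- -0.69 } else { a <- 0.308; b <- -0.52 }
  f <- function(N) a / N + b / N^2 - r2p
  # beyond the attainable maximum of the forward relation, the estimate
  # saturates at the peak (numerically located, independent of the
  # package's closed form)
  peak <- stats::optimize(function(N) a / N + b / N^2,
                          interval = c(0.5, 1000), maximum = TRUE,
                          tol = 1e-12)$maximum
  if (f(-2 * b / a) < 0) return(peak)
  N <- stats::uniroot(f, lower = -2 * b / a, upper = 1e12, tol = 1e-10)$root
  for (k in 1:4) N <- N - f(N) / (-a / N^2 - 2 * b / N^3)  # Newton polish
  N
}

# Full-pipeline oracle: enumerate every between-chromosome pair of
# polymorphic loci, loop-compute each r^2, mean / harmonic mean, E_samp,
# inversion, and a from-scratch delete-one jackknife.
oracle_ne_unlinked <- function(G, min_pair_S = 10, conf = 0.95) {
  dos <- G$dosages
  chrom <- G$map$chrom
  poly <- logical(ncol(dos))
  for (l in seq_len(ncol(dos))) {
    v <- dos[, l][!is.na(dos[, l])]
    poly[l] <- length(v) > 0 && min(v) != max(v)
  }
  keep <- which(poly)
  core <- function(rows) {
    r2s <- c(); ns <- c()
    for (ai in seq_along(keep)) for (bi in seq_along(keep)) {
      if (bi <= ai) next
      a <- keep[ai]; b <- keep[bi]
      if (chrom[a] == chrom[b]) next
      pr <- oracle_pair_r2(dos[rows, a], dos[rows, b], adjust = TRUE)
      if (is.na(pr$r2) || pr$n < min_pair_S) next
      r2s <- c(r2s, pr$r2); ns <- c(ns, pr$n)
    }
    if (!length(r2s)) return(NULL)
    sh <- length(ns) / sum(1 / ns)
    list(r2_mean = mean(r2s), s_harm = sh,
         r2p = mean(r2s) - oracle_esamp(sh), n_pairs = length(r2s))
  }
  S <- nrow(dos)
  full <- core(seq_len(S))
  point <- oracle_invert(full$r2p, full$s_harm)
  theta <- sapply(seq_len(S), function(d) {
    part <- core(setdiff(seq_len(S), d))
    if (is.null(part)) NA_real_ else part$r2p
  })
  theta <- theta[!is.na(theta)]
  ns <- length(theta)
  jsd <- sqrt((ns - 1) / ns * sum((theta - mean(theta))^2))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(point = point,
       ci_low = min(oracle_invert(full$r2p + z * jsd, full$s_harm), point),
       ci_high = max(oracle_invert(full$r2p - z * jsd, full$s_harm), point),
       r2_mean = full$r2_mean, r2_prime = full$r2p,
       s_harm = full$s_harm, n_pairs = full$n_pairs, jackknife_sd = jsd)
}

# Type-7 quantile by hand: sort and linearly interpolate at h = (n-1)p.
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  sapply(p, function(pp) {
    h <- (n - 1) * pp
    lo <- floor(h) + 1
    hi <- ceiling(h) + 1
    x[lo] + (h - floor(h)) * (x[hi] - x[lo])
  })
}
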