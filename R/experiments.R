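# Replicate robustness experiments: perturbation sweeps over missing data,
# SNP count, sample size, ancestry stratification and map fragmentation,
# summarized by geometric mean and percentile intervals.

#' Geometric mean with percentile confidence interval
#'
#' `exp(mean(log(x)))` over the finite positive values, with empirical
#' quantiles at `(1 - conf)/2` and `1 - (1 - conf)/2` (linear-interpolation
#' type-7 quantiles, fixed for reproducibility). Infinite values are
#' excluded and counted.
#'
#' @param values Positive replicate estimates (may contain `Inf`/`NA`).
#' @param conf Confidence level, default 0.95.
#' @return List with `gmean`, `low`, `high`, `n_finite`, `n_infinite`.
#' @export
geometric_mean_ci <- function(values, conf = 0.95) {
  n_inf <- sum(is.infinite(values))
  x <- values[is.finite(values) & !is.na(values)]
  if (any(x <= 0)) stop("estimates must be positive")
  if (!length(x)) stop("undefined result: no finite estimates")
  alpha <- (1 - conf) / 2
  qs <- quantile(x, probs = c(alpha, 1 - alpha), type = 7, names = FALSE)
  list(gmean = geometric_mean(x), low = qs[1], high = qs[2],
       n_finite = length(x), n_infinite = n_inf)
}

#' Define a robustness experiment
#'
#' An experiment applies one perturbation at several levels, `n_replicates`
#' times per level with independent derived seeds, estimates Ne for each
#' perturbed dataset and summarizes each level with [geometric_mean_ci()].
#'
#' Kinds and level semantics:
#' \describe{
#'   \item{missing_data}{levels = per-individual MCAR missing rates;
#'     perturbation = [inject_missing()].}
#'   \item{snp_titration}{levels = locus counts; [downsample_loci()].}
#'   \item{sample_size}{levels = individual counts; [sample_individuals()].}
#'   \item{admixture_gradient}{levels = `q_min` ancestry thresholds, plus a
#'     `"pooled"` level combining both demes; each subset is resampled to a
#'     standardized size (default: the size of the smallest threshold
#'     subset).}
#'   \item{fragmentation}{levels = assumed chromosome counts; the same
#'     genotypes are re-analyzed under [fragment_map()]-derived maps.}
#' }
#'
#' @param kind One of the five kinds above.
#' @param levels Ordered level values (>= 2 levels; for
#'   `admixture_gradient`, numeric thresholds; the pooled level is added
#'   via `pooled = TRUE`).
#' @param base A [genotype_matrix()], [simulate_population()] result, or a
#'   [sim_config()] (simulated once, at the experiment seed).
#' @param n_replicates Replicates per level (default 50, as in standard
#'   resampling designs; scale down for quick runs).
#' @param estimator `"unlinked"` ([estimate_ne_unlinked()]) or
#'   `"trajectory"` ([estimate_ne_trajectory()] summarized by
#'   [summarize_recent_ne()]).
#' @param seed Root seed; per-(level, replicate) streams are derived.
#' @param policy [pair_policy()] for the estimator (mode is forced to match
#'   the estimator).
#' @param deme Deme for `admixture_gradient` stratification.
#' @param pooled Add the pooled-demes level to `admixture_gradient`.
#' @param standardize_n Resample size for `admixture_gradient`; default is
#'   the size of the smallest threshold subset.
#' @param singleton_filter Apply [exclude_singletons()] before estimating
#'   (default TRUE).
#' @param ci Compute jackknife CIs per replicate (default FALSE; the level
#'   summary interval comes from replicates).
#' @return An `experiment_design` list.
#' @export
experiment_design <- function(kind = c("missing_data", "snp_titration",
                                       "sample_size", "admixture_gradient",
                                       "fragmentation"),
                              levels, base, n_replicates = 50,
                              estimator = c("unlinked", "trajectory"),
                              seed = 1L, policy = NULL,
                              deme = "A", pooled = TRUE,
                              standardize_n = NULL,
                              singleton_filter = TRUE, ci = FALSE) {
  kind <- match.arg(kind)
  estimator <- match.arg(estimator)
  if (length(levels) < 2) stop("an experiment needs at least 2 levels")
  if (!is_count(n_replicates, min = 2) && !(kind == "fragmentation"))
    stop("n_replicates must be an integer >= 2")
  if (is.null(policy))
    policy <- pair_policy(if (estimator == "unlinked") "unlinked"
                          else "linked_binned")
  structure(list(kind = kind, levels = levels, base = base,
                 n_replicates = as.integer(n_replicates),
                 estimator = estimator, seed = as.integer(seed),
                 policy = policy, deme = deme, pooled = pooled,
                 standardize_n = standardize_n,
                 singleton_filter = singleton_filter, ci = ci),
            class = "experiment_design")
}

#' Run a robustness experiment
#'
#' @param design An [experiment_design()].
#' @return An object of class `experiment_result`: list with `table` (long
#'   format: level, replicate, estimate, finite flag, note), `summary`
#'   (per level: geometric mean, 95% percentile CI, counts, failure
#'   reason), and the `design`. Infeasible levels are marked failed and
#'   the run continues.
#' @export
run_experiment <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  base <- design$base
  if (inherits(base, "sim_config"))
    base <- simulate_population(base)$genotypes
  base <- as_genotype_matrix(base)

  levels <- design$levels
  level_labels <- as.character(levels)
  if (design$kind == "admixture_gradient" && design$pooled) {
    level_labels <- c(level_labels, "pooled")
  }

  std_n <- NULL
  if (design$kind == "admixture_gradient") {
    sizes <- vapply(levels, function(q)
      tryCatch(n_individuals(stratify_by_q(base, q, design$deme)),
               error = function(e) 0L), integer(1))
    std_n <- design$standardize_n %||% min(sizes[sizes > 0])
  }

  rows <- list(); summ <- list()
  for (li in seq_along(level_labels)) {
    lab <- level_labels[li]
    lev <- if (lab == "pooled") NA else levels[li]
    ests <- rep(NA_real_, design$n_replicates)
    notes <- character(design$n_replicates)
    level_failed <- NULL
    for (r in seq_len(design$n_replicates)) {
      sd_lr <- derive_seed(design$seed, li, r)
      res <- tryCatch({
        Gp <- perturb_for_level(base, design, lab, lev, std_n, sd_lr)
        est_pipeline(Gp, design, sd_lr)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        notes[r] <- conditionMessage(res)
        if (grepl("empty selection|cannot sample", notes[r])) {
          level_failed <- notes[r]
          break
        }
      } else ests[r] <- res
    }
    rows[[li]] <- data.frame(level = lab, replicate = seq_along(ests),
                             estimate = ests,
                             finite = is.finite(ests),
                             note = notes, stringsAsFactors = FALSE)
    summ[[li]] <- summarize_level(lab, ests, level_failed)
  }
  structure(list(table = do.call(rbind, rows),
                 summary = do.call(rbind, summ),
                 design = design),
            class = "experiment_result")
}

perturb_for_level <- function(base, design, lab, lev, std_n, seed) {
  switch(design$kind,
    missing_data = inject_missing(base, rate = lev, seed = seed),
    snp_titration = downsample_loci(base, n = lev, seed = seed),
    sample_size = sample_individuals(base, n = lev, seed = seed),
    admixture_gradient = {
      sub <- if (lab == "pooled") base
             else stratify_by_q(base, q_min = lev, deme = design$deme)
      sample_individuals(sub, n = std_n, seed = seed)
    },
    fragmentation = {
      G <- base
      G$map <- fragment_map(base$map, lev)
      G
    })
}

est_pipeline <- function(G, design, seed) {
  if (design$singleton_filter) G <- exclude_singletons(G)
  pol <- design$policy
  pol$seed <- derive_seed(seed, 997L)  # independent pair-subsample stream
  if (design$estimator == "unlinked") {
    estimate_ne_unlinked(G, pol, ci = design$ci)$point
  } else {
    summarize_recent_ne(suppressWarnings(estimate_ne_trajectory(G, pol)))
  }
}

summarize_level <- function(lab, ests, failed) {
  if (!is.null(failed) || !any(is.finite(ests))) {
    return(data.frame(level = lab, gmean = NA_real_, low = NA_real_,
                      high = NA_real_, n_finite = sum(is.finite(ests)),
                      n_infinite = sum(is.infinite(ests)),
                      failed = failed %||% "no finite estimates",
                      stringsAsFactors = FALSE))
  }
  s <- geometric_mean_ci(ests)
  data.frame(level = lab, gmean = s$gmean, low = s$low, high = s$high,
             n_finite = s$n_finite, n_infinite = s$n_infinite,
             failed = NA_character_, stringsAsFactors = FALSE)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment:", x$design$kind, "(", x$design$estimator,
      "estimator,", x$design$n_replicates, "replicates/level )\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
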