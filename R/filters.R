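# Locus filters, the physical-linkage bias correction, missingness
# profiling and the GONE-style input validator.

#' Exclude singleton and monomorphic loci
#'
#' Low-frequency alleles upwardly bias LD-based Ne, so the standard
#' recommendation is to drop singletons before estimation. A singleton is
#' defined on allele copies: a locus whose minor allele is observed exactly
#' once among the `2 x` non-missing individuals (a single heterozygote
#' counts as one copy, hence a singleton). Monomorphic loci are removed as
#' well.
#'
#' @param G A [genotype_matrix()] or simulation result.
#' @return A filtered [genotype_matrix()]; attribute `n_removed` records
#'   `c(singleton = ..., monomorphic = ...)`.
#' @export
exclude_singletons <- function(G) {
  G <- as_genotype_matrix(G)
  mac <- minor_allele_count(G)
  mono <- mac == 0L
  single <- mac == 1L
  keep <- !(mono | single)
  if (!any(keep))
    stop("empty panel: all loci are singletons or monomorphic")
  out <- subset_genotypes(G, loci = which(keep))
  attr(out, "n_removed") <- c(singleton = sum(single), monomorphic = sum(mono))
  out
}

#' Filter loci by minor-allele frequency
#'
#' Removes loci with minor-allele frequency (computed over non-missing
#' gene copies) below `threshold`. Note that MAF filtering is not required
#' by GONE-style estimation and can cause a small upward bias in Ne; a
#' warning says so whenever a positive threshold is used.
#'
#' @param G A [genotype_matrix()] or simulation result.
#' @param threshold MAF threshold in `[0, 0.5)`; 0 removes only
#'   monomorphic loci.
#' @return A filtered [genotype_matrix()] with attribute `n_removed`.
#' @export
maf_filter <- function(G, threshold) {
  G <- as_genotype_matrix(G)
  if (threshold < 0 || threshold >= 0.5)
    stop("MAF threshold must lie in [0, 0.5)")
  if (threshold > 0)
    warning("MAF filtering is not required upstream of GONE-style ",
            "estimation and may cause a small upward bias in Ne")
  p <- allele_freq(G)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf > 0 & maf >= threshold
  if (!any(keep)) stop("empty panel: no loci pass the MAF filter")
  out <- subset_genotypes(G, loci = which(keep))
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Physical-linkage bias correction for chromosome number
#'
#' Ne estimates computed from locus pairs that include physically linked
#' pairs are biased downward because linked pairs carry extra LD. The
#' printed genome-size correction divides the estimate by
#' `y = 0.098 + 0.219 * ln(Chr)`, `Chr` the haploid chromosome number.
#' Point estimate and CI endpoints are divided by `y`; infinite values stay
#' infinite. Estimates computed under an `"unlinked"` policy already
#' exclude within-chromosome pairs and should not be corrected; a message
#' notes when the correction is skipped for that reason unless `force` is
#' set.
#'
#' @param ne An `ne_estimate` or a bare positive number.
#' @param chr_count Haploid chromosome number `Chr >= 1`.
#' @param force Apply even to `"unlinked"`-policy estimates.
#' @return Same type as `ne`, divided by `y`; for `ne_estimate` input the
#'   `correction` field records `y` and `Chr`.
#' @export
correct_physical_linkage <- function(ne, chr_count, force = FALSE) {
  if (!is_count(chr_count)) stop("Chr must be an integer >= 1")
  y <- linkage_correction_y(chr_count)
  if (is.numeric(ne)) {
    if (any(is.finite(ne) & ne <= 0)) stop("estimate must be positive")
    return(ne / y)
  }
  stopifnot(inherits(ne, "ne_estimate"))
  if (identical(ne$method, "unlinked") && !force) {
    message("unlinked-pair estimates exclude within-chromosome pairs; ",
            "physical-linkage correction skipped (use force = TRUE to apply)")
    return(ne)
  }
  ne$point <- ne$point / y
  ne$ci_low <- ne$ci_low / y
  ne$ci_high <- ne$ci_high / y
  ne$correction <- list(y = y, chr_count = chr_count)
  ne
}

#' @rdname correct_physical_linkage
#' @export
linkage_correction_y <- function(chr_count) {
  if (any(chr_count < 1)) stop("Chr must be >= 1")
  0.098 + 0.219 * log(chr_count)
}

#' Missingness profile of a genotype matrix
#'
#' @param G A [genotype_matrix()] or simulation result.
#' @param guideline Per-individual missing fraction above which an
#'   individual is flagged (default 0.20, the practical upper bound for
#'   reliable LD-based estimation).
#' @return A list with `per_individual`, `per_locus`, `summary`
#'   (mean/median/max per individual) and `flagged` (ids above the
#'   guideline).
#' @export
missingness_profile <- function(G, guideline = 0.20) {
  G <- as_genotype_matrix(G)
  miss <- is.na(G$dosages)
  per_ind <- rowMeans(miss)
  names(per_ind) <- G$ids
  per_loc <- colMeans(miss)
  list(
    per_individual = per_ind,
    per_locus = per_loc,
    summary = c(mean = mean(per_ind), median = stats::median(per_ind),
                max = max(per_ind)),
    guideline = guideline,
    flagged = G$ids[per_ind > guideline]
  )
}

#' Validate a dataset against GONE-style input limits
#'
#' Reporting-only check of the documented input constraints of the GONE
#' program: at most 200 chromosomes, at most 10 million SNPs in total and
#' at most 1 million SNPs on any chromosome (errors); a warning when the
#' average SNP count per chromosome/scaffold falls below
#' `sparse_threshold` (sparse maps are the empirical failure mode behind
#' the "too few SNPs" error); and a note when a chromosome exceeds 50,000
#' SNPs (only a random subset of that many per chromosome is used).
#'
#' @param G A [genotype_matrix()] or simulation result.
#' @param sparse_threshold Average SNPs per chromosome below which the
#'   sparse-data warning fires. Default 300, bracketing the empirical
#'   failure (~250 SNPs/scaffold failed, ~670 succeeded); configurable
#'   because the program's internal criterion is not published.
#' @return A `data.frame` of class `validation_report` with columns
#'   `rule`, `severity`, `message`, `observed`, `limit`; attribute
#'   `passes` is `TRUE` iff no error-severity rows exist.
#' @export
validate_gone_input <- function(G, sparse_threshold = 300) {
  G <- as_genotype_matrix(G)
  per_chrom <- table(G$map$chrom)
  n_chrom <- length(per_chrom)
  n_snp <- nrow(G$map)
  rows <- list()
  add <- function(rule, severity, message, observed, limit)
    rows[[length(rows) + 1L]] <<- data.frame(
      rule = rule, severity = severity, message = message,
      observed = observed, limit = limit, stringsAsFactors = FALSE)
  if (n_chrom > 200)
    add("max-chromosomes", "error",
        "more than 200 chromosomes/scaffolds", n_chrom, 200)
  if (n_snp > 1e7)
    add("max-total-snps", "error",
        "more than 10 million SNPs in total", n_snp, 1e7)
  if (max(per_chrom) > 1e6)
    add("max-snps-per-chromosome", "error",
        "a chromosome carries more than 1 million SNPs", max(per_chrom), 1e6)
  avg <- n_snp / n_chrom
  if (avg < sparse_threshold)
    add("sparse-data", "warning",
        paste0("average SNPs per chromosome/scaffold (", round(avg, 1),
               ") is sparse; expect a 'too few SNPs' failure"),
        avg, sparse_threshold)
  if (max(per_chrom) > 5e4)
    add("subset-use", "note",
        "chromosomes exceed 50,000 SNPs; only a random subset would be used",
        max(per_chrom), 5e4)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rule = character(0), severity = character(0),
               message = character(0), observed = numeric(0),
               limit = numeric(0), stringsAsFactors = FALSE)
  structure(out, class = c("validation_report", "data.frame"),
            passes = !any(out$severity == "error"))
}
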