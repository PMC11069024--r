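# Core containers: locus map and unphased genotype (dosage) matrix.

#' Create a locus map
#'
#' A locus map records, for each biallelic SNP, its linkage group
#' (chromosome or scaffold), physical position and genetic position.
#' Loci must be sorted by (chromosome, bp) and genetic positions must be
#' non-decreasing within a chromosome.
#'
#' @param chrom Integer vector of chromosome ids (>= 1).
#' @param bp Integer physical positions (1-based).
#' @param genetic_pos Genetic position in Morgans from the chromosome start.
#' @param ref,alt Allele labels; dosage counts copies of `alt`.
#' @return A `data.frame` of class `locus_map` with columns `chrom`, `bp`,
#'   `genetic_pos`, `ref`, `alt`.
#' @export
locus_map <- function(chrom, bp, genetic_pos, ref = "A", alt = "C") {
  n <- length(chrom)
  stopifnot(length(bp) == n, length(genetic_pos) == n)
  chrom <- as.integer(chrom)
  bp <- as.integer(bp)
  genetic_pos <- as.numeric(genetic_pos)
  if (any(is.na(chrom)) || any(chrom < 1L))
    stop("chromosome ids must be integers >= 1")
  if (any(is.na(bp)))
    stop("bp positions must be non-missing integers")
  ord <- order(chrom, bp)
  if (any(ord != seq_len(n)))
    stop("loci must be sorted by (chrom, bp)")
  if (any(genetic_pos < 0))
    stop("genetic positions must be >= 0 Morgans")
  for (ch in unique(chrom)) {
    g <- genetic_pos[chrom == ch]
    if (is.unsorted(g)) stop("genetic_pos must be non-decreasing within chromosome ", ch)
  }
  ref <- rep_len(as.character(ref), n)
  alt <- rep_len(as.character(alt), n)
  structure(
    data.frame(chrom = chrom, bp = bp, genetic_pos = genetic_pos,
               ref = ref, alt = alt, stringsAsFactors = FALSE),
    class = c("locus_map", "data.frame")
  )
}

#' Create a genotype matrix
#'
#' Unphased diploid genotypes stored as alt-allele dosages in
#' `{0, 1, 2, NA}`; `NA` is the missing sentinel (a dosage of 0 is a valid
#' homozygote, never a missing code). Rows are individuals, columns loci;
#' columns are bound to a [locus_map()]. Individuals may carry a deme label
#' and an ancestry fraction `q` (proportion of pedigree ancestry in deme
#' "A", in `[0, 1]`).
#'
#' @param dosages Integer matrix, individuals x loci, values 0/1/2/NA.
#' @param map A [locus_map()] with one row per column of `dosages`.
#' @param ids Individual identifiers (default `ind1..indS`).
#' @param deme Optional per-individual deme labels.
#' @param q Optional per-individual ancestry fractions in `[0, 1]`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, map, ids = NULL, deme = NULL, q = NULL) {
  if (!is.matrix(dosages)) stop("dosages must be a matrix")
  if (!inherits(map, "locus_map")) stop("map must be a locus_map")
  if (ncol(dosages) != nrow(map))
    stop("dosage column count (", ncol(dosages), ") must equal map length (",
         nrow(map), ")")
  storage.mode(dosages) <- "integer"
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA")
  S <- nrow(dosages)
  ids <- as.character(ids %||% paste0("ind", seq_len(S)))
  if (length(ids) != S) stop("ids length must equal number of individuals")
  if (!is.null(deme) && length(deme) != S)
    stop("deme length must equal number of individuals")
  if (!is.null(q)) {
    if (length(q) != S) stop("q length must equal number of individuals")
    if (any(!is.na(q) & (q < 0 | q > 1))) stop("q values must lie in [0, 1]")
  }
  dimnames(dosages) <- list(ids, NULL)
  structure(
    list(dosages = dosages, map = map, ids = ids,
         deme = if (is.null(deme)) NULL else as.character(deme),
         q = if (is.null(q)) NULL else as.numeric(q)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", nrow(x$dosages), " individuals x ",
      ncol(x$dosages), " loci on ", length(unique(x$map$chrom)),
      " chromosome(s)\n", sep = "")
  mono <- monomorphic_loci(x)
  cat("  missing: ", round(100 * mean(is.na(x$dosages)), 2), "%;  monomorphic loci: ",
      sum(mono), "\n", sep = "")
  if (!is.null(x$q))
    cat("  ancestry q: [", round(min(x$q), 3), ", ", round(max(x$q), 3), "]\n", sep = "")
  invisible(x)
}

#' Number of individuals / loci in a genotype matrix
#' @param G A [genotype_matrix()].
#' @return Integer count.
#' @export
n_individuals <- function(G) nrow(G$dosages)

#' @rdname n_individuals
#' @export
n_loci <- function(G) ncol(G$dosages)

#' Alt-allele frequencies over non-missing gene copies
#' @param G A [genotype_matrix()].
#' @return Numeric vector, one frequency per locus (NaN if fully missing).
#' @export
allele_freq <- function(G) {
  colMeans(G$dosages, na.rm = TRUE) / 2
}

#' Minor-allele copy counts over non-missing gene copies
#' @param G A [genotype_matrix()].
#' @return Integer vector: per locus, the smaller of the two allele counts.
#' @export
minor_allele_count <- function(G) {
  alt <- colSums(G$dosages, na.rm = TRUE)
  nobs <- colSums(!is.na(G$dosages))
  pmin(alt, 2L * nobs - alt)
}

#' Flag monomorphic loci
#'
#' A locus is monomorphic when at most one allele is observed among
#' non-missing gene copies. Such loci carry no LD information and are never
#' silently used by the estimators: they are dropped with a recorded count.
#'
#' @param G A [genotype_matrix()].
#' @return Logical vector per locus.
#' @export
monomorphic_loci <- function(G) {
  minor_allele_count(G) == 0L | colSums(!is.na(G$dosages)) == 0L
}

# Subset a genotype matrix by individuals and/or loci, keeping metadata and
# the map in step. Internal: user-facing subsetting goes through the
# perturbation operators.
subset_genotypes <- function(G, individuals = NULL, loci = NULL) {
  dos <- G$dosages
  ids <- G$ids; deme <- G$deme; q <- G$q; map <- G$map
  if (!is.null(individuals)) {
    dos <- dos[individuals, , drop = FALSE]
    ids <- ids[individuals]
    if (!is.null(deme)) deme <- deme[individuals]
    if (!is.null(q)) q <- q[individuals]
  }
  if (!is.null(loci)) {
    dos <- dos[, loci, drop = FALSE]
    map <- structure(map[loci, , drop = FALSE],
                     class = c("locus_map", "data.frame"))
    rownames(map) <- NULL
  }
  genotype_matrix(dos, map, ids = ids, deme = deme, q = q)
}
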