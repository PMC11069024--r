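# PED/MAP (PLINK-style text, GONE dialect) and minimal VCF genotype I/O,
# plus result serialization.
#
# PED dialect: six leading columns (family id, individual id, then four
# neutral placeholders "0 0 0 -9"), followed by one allele pair per locus.
# Alleles are the map's ref/alt labels; a missing genotype is written as
# "0 0". The MAP file has four columns: chromosome id, SNP id, genetic
# position in cM, bp. On reading, dosage counts the second allele in ASCII
# sort order among the alleles observed at that locus; loci where only one
# allele is observed read back as monomorphic dosage 0 (round trips are
# exact for polymorphic loci).

#' Write a genotype matrix as PED/MAP files
#'
#' @param G A [genotype_matrix()] or simulation result.
#' @param prefix Output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return The two paths, invisibly.
#' @export
write_ped_map <- function(G, prefix) {
  G <- as_genotype_matrix(G)
  map <- G$map
  map_df <- data.frame(chrom = map$chrom,
                       id = paste0("snp", seq_len(nrow(map))),
                       cm = map$genetic_pos * 100,
                       bp = map$bp)
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  write.table(map_df, map_path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  dos <- G$dosages
  L <- ncol(dos)
  a1 <- matrix(rep(map$ref, each = nrow(dos)), nrow(dos), L)
  a2 <- a1
  altm <- matrix(rep(map$alt, each = nrow(dos)), nrow(dos), L)
  a1[which(dos >= 1L)] <- altm[which(dos >= 1L)]
  a2[which(dos == 2L)] <- altm[which(dos == 2L)]
  a1[is.na(dos)] <- "0"; a2[is.na(dos)] <- "0"
  geno <- matrix("", nrow(dos), 2L * L)
  geno[, seq(1L, 2L * L, 2L)] <- a1
  geno[, seq(2L, 2L * L, 2L)] <- a2
  lead <- cbind("FAM1", G$ids, "0", "0", "0", "-9")
  lines <- apply(cbind(lead, geno), 1, paste, collapse = " ")
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read PED/MAP files into a genotype matrix
#'
#' @param prefix Path prefix of `<prefix>.ped` / `<prefix>.map`, or a
#'   length-2 vector of explicit (ped, map) paths.
#' @return A [genotype_matrix()].
#' @export
read_ped_map <- function(prefix) {
  if (length(prefix) == 2) {
    ped_path <- prefix[1]; map_path <- prefix[2]
  } else {
    ped_path <- paste0(prefix, ".ped"); map_path <- paste0(prefix, ".map")
  }
  map_raw <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map_raw) != 4)
    stop("malformed MAP file: expected 4 columns, found ", ncol(map_raw))
  L <- nrow(map_raw)
  ped_lines <- readLines(ped_path)
  toks <- strsplit(trimws(ped_lines), "[ \t]+")
  nf <- lengths(toks)
  expected <- 6L + 2L * L
  bad <- which(nf != expected)
  if (length(bad))
    stop("ragged PED line ", bad[1], ": ", nf[bad[1]], " fields, expected ",
         expected, " (6 + 2 x ", L, " map records)")
  S <- length(toks)
  ids <- vapply(toks, `[[`, character(1), 2L)
  al <- matrix(unlist(lapply(toks, `[`, -(1:6))), nrow = S, byrow = TRUE)
  a1 <- al[, seq(1L, 2L * L, 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * L, 2L), drop = FALSE]
  half_missing <- xor(a1 == "0", a2 == "0")
  if (any(half_missing))
    stop("malformed PED genotype: half-missing allele pair at line ",
         which(rowSums(half_missing) > 0)[1])
  dos <- matrix(NA_integer_, S, L)
  ref <- character(L); alt <- character(L)
  for (l in seq_len(L)) {
    obs <- c(a1[, l], a2[, l])
    alleles <- sort(setdiff(unique(obs), "0"))
    if (length(alleles) > 2)
      stop("locus ", l, " has more than two allele codes: ",
           paste(alleles, collapse = "/"))
    ref[l] <- if (length(alleles)) alleles[1] else "A"
    alt[l] <- if (length(alleles) == 2) alleles[2] else "C"
    miss <- a1[, l] == "0"
    dos[, l] <- ifelse(miss, NA_integer_,
                       (a1[, l] == alt[l]) + (a2[, l] == alt[l]))
  }
  map <- locus_map(map_raw[[1]], map_raw[[4]], map_raw[[3]] / 100,
                   ref = ref, alt = alt)
  genotype_matrix(dos, map, ids = ids)
}

#' Read genotypes from a minimal VCF
#'
#' Supports plain-text VCF with a GT entry in FORMAT. Biallelic SNP records
#' are converted to alt-allele dosage (`0/0 -> 0`, `0/1` or `1/0 -> 1`,
#' `1/1 -> 2`, `./.` -> missing); phase separators (`|`) are accepted and
#' ignored. Multiallelic records and non-diploid GT values are skipped and
#' counted. Genetic positions are filled from bp at the 1 cM = 1 Mb
#' convention (the "each chromosome about 1 Morgan" assumption of map-free
#' tools); contigs are mapped to integer chromosome ids in order of
#' appearance and the mapping is attached as an attribute.
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @return A [genotype_matrix()] with attributes `contig_map` and
#'   `n_skipped`.
#' @export
read_vcf_genotypes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  if (!length(lines) || !startsWith(lines[1], "#CHROM"))
    stop("malformed VCF: missing #CHROM header line")
  hdr <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  if (length(hdr) < 10) stop("VCF carries no sample columns")
  samples <- hdr[-(1:9)]
  body <- lines[-1]
  body <- body[nzchar(body)]
  n_skip_multi <- 0L; n_skip_gt <- 0L
  rec_chrom <- character(0); rec_bp <- integer(0)
  rec_ref <- character(0); rec_alt <- character(0)
  dosage_rows <- list()
  for (k in seq_along(body)) {
    f <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(hdr))
      stop("malformed VCF record at data line ", k, ": ", length(f),
           " fields, expected ", length(hdr))
    if (grepl(",", f[5], fixed = TRUE)) { n_skip_multi <- n_skip_multi + 1L; next }
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_idx <- match("GT", fmt)
    if (is.na(gt_idx)) stop("record at data line ", k, " has no GT format key")
    gts <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE), `[`, character(1), gt_idx)
    gts <- gsub("|", "/", gts, fixed = TRUE)
    parts <- strsplit(gts, "/", fixed = TRUE)
    if (any(lengths(parts) != 2)) {
      warning("non-diploid GT at data line ", k, "; record skipped")
      n_skip_gt <- n_skip_gt + 1L
      next
    }
    am <- matrix(unlist(parts), nrow = 2)
    dose <- ifelse(am[1, ] == "." | am[2, ] == ".", NA_integer_,
                   suppressWarnings(as.integer(am[1, ]) + as.integer(am[2, ])))
    rec_chrom <- c(rec_chrom, f[1]); rec_bp <- c(rec_bp, as.integer(f[2]))
    rec_ref <- c(rec_ref, f[4]); rec_alt <- c(rec_alt, f[5])
    dosage_rows[[length(dosage_rows) + 1L]] <- dose
  }
  if (!length(dosage_rows)) stop("no usable biallelic records in VCF")
  dos <- t(do.call(rbind, dosage_rows))
  contigs <- unique(rec_chrom)
  chrom_id <- match(rec_chrom, contigs)
  ord <- order(chrom_id, rec_bp)
  map <- locus_map(chrom_id[ord], rec_bp[ord],
                   genetic_pos_from_bp(chrom_id[ord], rec_bp[ord]),
                   ref = rec_ref[ord], alt = rec_alt[ord])
  out <- genotype_matrix(dos[, ord, drop = FALSE], map, ids = samples)
  attr(out, "contig_map") <- setNames(seq_along(contigs), contigs)
  attr(out, "n_skipped") <- c(multiallelic = n_skip_multi,
                              non_diploid = n_skip_gt)
  out
}

# 1 cM = 1 Mb, measured from the first SNP of each chromosome.
genetic_pos_from_bp <- function(chrom, bp) {
  g <- numeric(length(bp))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    g[sel] <- (bp[sel] - min(bp[sel])) / 1e8
  }
  g
}

#' Serialize results to TSV or JSON
#'
#' Writes an `ne_estimate`, `ne_trajectory`, `experiment_result` or
#' `validation_report` to disk. Infinite values are serialized as the
#' string `"Inf"` in both formats.
#'
#' @param result One of the supported result objects.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- results_frame(result)
  if (format == "tsv") {
    out <- df
    for (cn in names(out)) {
      if (is.numeric(out[[cn]])) {
        v <- as.character(out[[cn]])
        v[is.infinite(out[[cn]])] <- "Inf"
        out[[cn]] <- v
      }
    }
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lst <- lapply(seq_len(nrow(df)), function(r) {
      row <- as.list(df[r, , drop = FALSE])
      lapply(row, function(v)
        if (is.numeric(v) && is.infinite(v)) "Inf" else unname(v))
    })
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

results_frame <- function(result) {
  if (inherits(result, "ne_estimate")) {
    data.frame(point = result$point, ci_low = result$ci_low,
               ci_high = result$ci_high, method = result$method,
               r2_mean = result$r2_mean, r2_prime = result$r2_prime,
               s_harm = result$s_harm, n_pairs = result$n_pairs,
               stringsAsFactors = FALSE)
  } else if (inherits(result, "ne_trajectory")) {
    as.data.frame(result)
  } else if (inherits(result, "experiment_result")) {
    result$table
  } else if (inherits(result, "validation_report")) {
    as.data.frame(result)
  } else stop("unsupported result type: ", paste(class(result), collapse = "/"))
}

#' Read a flat key-value simulation config file
#'
#' Lines of `key value` (or `key = value`) pairs; `#` comments and blank
#' lines ignored. Keys match the arguments of [sim_config()]; `ne` may be
#' a single number or a comma-separated `gen:N` list
#' (e.g. `ne 0:500,100:100`).
#'
#' @param path Config file path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(gsub("=", " ", lines), "[ \t]+")
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " "), character(1))
  args <- as.list(setNames(vals, keys))
  if (!is.null(args$ne)) {
    if (grepl(":", args$ne)) {
      pieces <- strsplit(strsplit(args$ne, ",")[[1]], ":")
      args$ne <- data.frame(
        generation = as.integer(vapply(pieces, `[[`, character(1), 1)),
        N = as.numeric(vapply(pieces, `[[`, character(1), 2)))
    } else args$ne <- as.numeric(args$ne)
  }
  numkeys <- c("n_demes", "migration_rate", "divergence_burnin",
               "n_chromosomes", "loci_per_chromosome", "chrom_length_morgans",
               "init_freq_low", "init_freq_high", "burnin_generations", "seed")
  for (k in intersect(names(args), numkeys)) args[[k]] <- as.numeric(args[[k]])
  unknown <- setdiff(names(args), c("ne", numkeys))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, args)
}
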