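#' SNP genotype matrix
#'
#' Container for biallelic SNP genotypes: an individuals x loci integer matrix
#' with entries 0/1/2 counting copies of the alternate allele and `NA` for
#' missing calls. Each SNP carries the id of the RAD locus it belongs to and
#' a position used to order SNPs within a RAD locus.
#'
#' @param genotypes integer matrix, individuals in rows, loci in columns;
#'   entries in `{0, 1, 2, NA}`. Row names are sample ids, column names locus
#'   ids (generated when absent).
#' @param radlocus_ids character vector, RAD locus of each SNP column.
#'   Defaults to one RAD locus per SNP.
#' @param pos integer vector of SNP positions (used by
#'   [one_snp_per_radlocus()]); defaults to column index.
#' @return An object of class `snp_matrix`.
#' @export
snp_matrix <- function(genotypes, radlocus_ids = NULL, pos = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(rownames(genotypes)) && nrow(genotypes) > 0)
    rownames(genotypes) <- paste0("ind", seq_len(nrow(genotypes)))
  if (is.null(colnames(genotypes)) && ncol(genotypes) > 0)
    colnames(genotypes) <- paste0("L", seq_len(ncol(genotypes)))
  if (anyDuplicated(colnames(genotypes)))
    stop("locus ids must be unique")
  bad <- !(genotypes %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype entries must be 0, 1, 2 or NA")
  if (ncol(genotypes) > 0 && any(colSums(!is.na(genotypes)) == 0))
    stop("every locus needs at least one non-missing genotype")
  if (is.null(radlocus_ids)) radlocus_ids <- colnames(genotypes)
  if (length(radlocus_ids) != ncol(genotypes))
    stop("radlocus_ids must align with loci")
  if (is.null(pos)) pos <- seq_len(ncol(genotypes))
  structure(list(genotypes = genotypes,
                 radlocus = as.character(radlocus_ids),
                 pos = as.integer(pos)),
            class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  g <- x$genotypes
  miss <- if (length(g)) mean(is.na(g)) else 0
  cat(sprintf("snp_matrix: %d individuals x %d loci (%d RAD loci), %.1f%% missing\n",
              nrow(g), ncol(g), length(unique(x$radlocus)), 100 * miss))
  invisible(x)
}

#' @export
dim.snp_matrix <- function(x) dim(x$genotypes)

n_loci <- function(m) ncol(m$genotypes)
sample_ids <- function(m) rownames(m$genotypes)
locus_ids <- function(m) colnames(m$genotypes)

keep_loci <- function(m, keep) {
  snp_matrix(m$genotypes[, keep, drop = FALSE],
             radlocus_ids = m$radlocus[keep], pos = m$pos[keep])
}

#' Population map
#'
#' Sample-to-population-to-group assignment with population coordinates.
#'
#' @param sample,population,group character vectors, one entry per sample.
#' @param lat,lon numeric, decimal-degree coordinates of each sample's
#'   population (repeated per sample).
#' @return A `pop_map` data frame with columns sample, population, group,
#'   lat, lon.
#' @export
pop_map <- function(sample, population, group, lat, lon) {
  df <- data.frame(sample = as.character(sample),
                   population = as.character(population),
                   group = as.character(group),
                   lat = as.numeric(lat), lon = as.numeric(lon),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample)) stop("duplicate sample ids in population map")
  if (anyNA(df)) stop("population map must be complete")
  pg <- unique(df[, c("population", "group")])
  if (anyDuplicated(pg$population))
    stop("each population must belong to exactly one group")
  pc <- unique(df[, c("population", "lat", "lon")])
  if (anyDuplicated(pc$population))
    stop("each population must have a single coordinate")
  class(df) <- c("pop_map", "data.frame")
  df
}

#' @rdname pop_map
#' @param path CSV file with columns sample, population, group, lat, lon.
#' @export
read_pop_map <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  pop_map(df$sample, df$population, df$group, df$lat, df$lon)
}

# population / group factor aligned to the rows of m (errors on mismatch)
match_pops <- function(m, pmap, what = "population") {
  idx <- match(sample_ids(m), pmap$sample)
  if (anyNA(idx)) stop("samples missing from population map: ",
                       paste(head(sample_ids(m)[is.na(idx)]), collapse = ", "))
  factor(pmap[[what]][idx], levels = unique(pmap[[what]]))
}

pop_coords <- function(pmap) {
  pc <- unique(as.data.frame(pmap)[, c("population", "lat", "lon")])
  rownames(pc) <- pc$population
  pc
}

#' Load a SNP genotype matrix
#'
#' Reads biallelic SNP genotypes either from a VCF (one sample column per
#' individual, `GT` field) or from a tab-separated table of 0/1/2/NA codes
#' with samples in rows and loci in columns. Multiallelic VCF records are
#' rejected. Missing calls map to `NA`; sample order is preserved.
#'
#' @param path input file.
#' @param format `"vcf"` or `"table"`.
#' @param radlocus_ids optional RAD locus ids for table input (VCF input takes
#'   them from the CHROM column).
#' @return A [snp_matrix()].
#' @export
load_genotypes <- function(path, format = c("vcf", "table"),
                           radlocus_ids = NULL) {
  format <- match.arg(format)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- v@fix
    if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
      stop("multiallelic records are not supported; split or drop them first")
    gt <- vcfR::extract.gt(v, element = "GT")
    code <- function(x) {
      x <- gsub("|", "/", x, fixed = TRUE)
      out <- rep(NA_integer_, length(x))
      out[x %in% "0/0"] <- 0L
      out[x %in% c("0/1", "1/0")] <- 1L
      out[x %in% "1/1"] <- 2L
      out
    }
    g <- apply(gt, 2, code)
    g <- matrix(g, nrow = nrow(gt), dimnames = dimnames(gt))
    snp_matrix(t(g), radlocus_ids = unname(fix[, "CHROM"]),
               pos = as.integer(fix[, "POS"]))
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                      check.names = FALSE)
    snp_matrix(as.matrix(tab), radlocus_ids = radlocus_ids)
  }
}

#' Write a SNP genotype matrix
#'
#' Inverse of [load_genotypes()]: `"table"` writes the 0/1/2/NA matrix as TSV;
#' `"vcf"` writes a minimal plain-text VCF 4.2 with CHROM = RAD locus id,
#' POS = SNP position and placeholder REF/ALT alleles.
#'
#' @param m a [snp_matrix()].
#' @param path output file.
#' @param format `"vcf"` or `"table"`.
#' @export
write_genotypes <- function(m, path, format = c("vcf", "table")) {
  format <- match.arg(format)
  g <- m$genotypes
  if (format == "table") {
    write.table(g, path, sep = "\t", quote = FALSE, col.names = NA)
  } else {
    gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow = nrow(g),
                 dimnames = dimnames(g))
    gt[is.na(gt)] <- "./."
    hdr <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(g)), collapse = "\t"))
    body <- vapply(seq_len(ncol(g)), function(j) {
      paste(c(m$radlocus[j], m$pos[j], colnames(g)[j], "A", "T", ".", "PASS",
              ".", "GT", gt[, j]), collapse = "\t")
    }, character(1))
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' Keep loci genotyped in a minimum fraction of each population
#'
#' A locus survives only if, in every population, at least
#' `ceiling(min_frac * n_pop)` individuals have a genotype call. Ties at
#' exactly the threshold are kept.
#'
#' @param m a [snp_matrix()].
#' @param pmap a [pop_map()].
#' @param min_frac minimum within-population genotyped fraction, in (0, 1].
#' @return Filtered [snp_matrix()], locus order preserved.
#' @export
filter_within_pop_presence <- function(m, pmap, min_frac = 0.6) {
  stopifnot(min_frac > 0, min_frac <= 1)
  pop <- match_pops(m, pmap)
  if (any(table(pop) == 0)) stop("population with zero samples")
  called <- rowsum((!is.na(m$genotypes)) + 0, pop)
  need <- ceiling(min_frac * as.vector(table(pop)[rownames(called)]))
  keep <- colSums(called >= need) == nrow(called)
  keep_loci(m, keep)
}

#' Keep loci genotyped in a minimum number of samples
#'
#' Implements dataset-level coverage thresholds (e.g. 85/120/160 calls for
#' progressively stricter matrices).
#'
#' @param m a [snp_matrix()].
#' @param min_samples minimum number of non-missing genotypes per locus.
#' @return Filtered [snp_matrix()].
#' @export
filter_sample_coverage <- function(m, min_samples) {
  stopifnot(min_samples <= nrow(m$genotypes))
  keep_loci(m, colSums(!is.na(m$genotypes)) >= min_samples)
}

#' Minor allele frequency filter
#'
#' MAF is computed over observed (non-missing) alleles; loci with
#' MAF < `threshold` are removed, ties at the threshold kept.
#'
#' @param m a [snp_matrix()].
#' @param threshold MAF cutoff in \[0, 0.5\].
#' @return Filtered [snp_matrix()].
#' @export
filter_maf <- function(m, threshold = 0.01) {
  stopifnot(threshold >= 0, threshold <= 0.5)
  p <- colMeans(m$genotypes / 2, na.rm = TRUE)
  keep_loci(m, pmin(p, 1 - p) >= threshold)
}

#' Retain one SNP per RAD locus
#'
#' @param m a [snp_matrix()].
#' @param rule `"first"` keeps the lowest-position SNP of each RAD locus
#'   (deterministic default); `"random"` draws one uniformly (uses the
#'   current RNG state, so seed it for reproducibility).
#' @return Filtered [snp_matrix()] with one column per RAD locus.
#' @export
one_snp_per_radlocus <- function(m, rule = c("first", "random")) {
  rule <- match.arg(rule)
  idx <- split(seq_len(n_loci(m)), m$radlocus)
  pick <- vapply(idx, function(i) {
    if (rule == "first") i[which.min(m$pos[i])]
    else if (length(i) == 1L) i else i[sample.int(length(i), 1L)]
  }, integer(1))
  keep_loci(m, sort(unname(pick)))
}
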