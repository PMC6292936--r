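# Shared containers: SNP lists, sample metadata, genotype and allele-depth
# matrices, and VCF / TSV readers and writers.
#
# Genotype codes are integers throughout: 0 = homozygous reference,
# 1 = heterozygous, 2 = homozygous alternate, NA = missing.

GT_HOM_REF <- 0L
GT_HET <- 1L
GT_HOM_ALT <- 2L

.valid_bases <- c("A", "C", "G", "T")

#' Construct a SNP list
#'
#' A SNP list is a data frame of sites (one row per site) with columns
#' `chrom`, `pos` (1-based), `ref` and `alt`. Multi-allelic sites carry their
#' alternate alleles comma-separated in `alt`; `n_alt` records how many there
#' are, so a site is biallelic iff `n_alt == 1`. Rows are sorted by
#' chromosome then position and duplicated (chrom, pos) pairs are collapsed
#' to the first occurrence with a warning.
#'
#' @param chrom character vector of chromosome identifiers.
#' @param pos integer vector of 1-based positions.
#' @param ref character vector of reference alleles (single nucleotides).
#' @param alt character vector of alternate alleles; multiple alleles
#'   comma-separated (e.g. `"A,T"`).
#' @param name optional provenance label stored as an attribute.
#' @return A `snp_list` data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `n_alt`.
#' @export
snp_list <- function(chrom, pos, ref, alt, name = NULL) {
  pos <- as.integer(pos)
  if (anyNA(pos)) stop("positions must be integers")
  if (length(pos) && any(pos < 1L)) stop("positions must be >= 1")
  chrom <- as.character(chrom)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  stopifnot(length(chrom) == length(pos), length(ref) == length(pos),
            length(alt) == length(pos))
  if (length(ref) && !all(ref %in% .valid_bases))
    stop("ref alleles must be single nucleotides in {A,C,G,T}")
  alt_split <- strsplit(alt, ",", fixed = TRUE)
  if (length(alt) && !all(unlist(alt_split) %in% .valid_bases))
    stop("alt alleles must be single nucleotides in {A,C,G,T}")
  if (any(mapply(function(r, a) r %in% a, ref, alt_split)))
    stop("ref allele must not appear among alt alleles")
  x <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                  n_alt = lengths(alt_split), stringsAsFactors = FALSE)
  key <- paste(x$chrom, x$pos, sep = ":")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate (chrom, pos) entries collapsed",
            " to first occurrence")
    x <- x[!duplicated(key), , drop = FALSE]
  }
  x <- x[order(x$chrom, x$pos), , drop = FALSE]
  rownames(x) <- NULL
  attr(x, "name") <- name
  class(x) <- c("snp_list", "data.frame")
  x
}

#' @export
print.snp_list <- function(x, ...) {
  nm <- attr(x, "name")
  cat("SNP list", if (!is.null(nm)) paste0("'", nm, "'"), "with", nrow(x),
      "sites on", length(unique(x$chrom)), "chromosome(s)\n")
  NextMethod()
}

site_key <- function(sites) paste(sites$chrom, sites$pos, sep = ":")

#' Read a SNP list from a TSV file
#'
#' Expects a tab-separated file with a header and columns
#' `chrom  pos  ref  alt`.
#'
#' @param path file path.
#' @param name optional provenance label (defaults to the file name).
#' @return A [snp_list()].
#' @export
read_snp_list <- function(path, name = basename(path)) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "character")
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(x)))
    stop("SNP list must have columns: ", paste(need, collapse = ", "))
  pos <- suppressWarnings(as.integer(x$pos))
  if (nrow(x) && anyNA(pos)) stop("non-integer position in ", path)
  snp_list(x$chrom, pos, x$ref, x$alt, name = name)
}

#' Write a SNP list to a TSV file
#' @param x a [snp_list()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_snp_list <- function(x, path) {
  utils::write.table(x[, c("chrom", "pos", "ref", "alt")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from a TSV file
#'
#' Expects columns `sample_id`, `subpopulation`, `population_class`
#' (`DIVERSE_PANEL`, `FOUR_PARENT_CROSS` or `DOUBLED_HAPLOID`) and
#' `nominal_coverage` (fold coverage, > 0).
#'
#' @param path file path.
#' @return A data frame of sample metadata.
#' @export
read_sample_info <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("sample_id", "subpopulation", "population_class",
            "nominal_coverage")
  if (!all(need %in% names(x)))
    stop("sample metadata must have columns: ", paste(need, collapse = ", "))
  sample_info(x$sample_id, x$subpopulation, x$population_class,
              x$nominal_coverage)
}

#' Construct a sample metadata table
#' @param sample_id character vector of unique sample identifiers.
#' @param subpopulation subpopulation labels (used for per-group MAF).
#' @param population_class one of `"DIVERSE_PANEL"`, `"FOUR_PARENT_CROSS"`,
#'   `"DOUBLED_HAPLOID"` per sample.
#' @param nominal_coverage targeted fold coverage per sample (> 0).
#' @return A data frame of sample metadata.
#' @export
sample_info <- function(sample_id, subpopulation = "all",
                        population_class = "DIVERSE_PANEL",
                        nominal_coverage = 1) {
  n <- length(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample_id")
  classes <- c("DIVERSE_PANEL", "FOUR_PARENT_CROSS", "DOUBLED_HAPLOID")
  population_class <- rep_len(as.character(population_class), n)
  if (n && !all(population_class %in% classes))
    stop("population_class must be one of: ", paste(classes, collapse = ", "))
  nominal_coverage <- rep_len(as.numeric(nominal_coverage), n)
  if (n && any(nominal_coverage <= 0)) stop("nominal_coverage must be > 0")
  data.frame(sample_id = as.character(sample_id),
             subpopulation = rep_len(as.character(subpopulation), n),
             population_class = population_class,
             nominal_coverage = nominal_coverage,
             stringsAsFactors = FALSE)
}

#' Write a sample metadata table to a TSV file
#' @param x a [sample_info()] table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sample_info <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a genotype matrix
#'
#' The central object of the pipeline: a sites x samples grid of genotype
#' codes (0 hom-ref, 1 het, 2 hom-alt, NA missing) together with its site
#' index (a [snp_list()]) and sample metadata.
#'
#' @param geno integer matrix, sites in rows, samples in columns.
#' @param sites a [snp_list()] with one row per matrix row.
#' @param samples a [sample_info()] table with one row per matrix column.
#' @return A `geno_matrix` object.
#' @export
geno_matrix <- function(geno, sites, samples) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(sites))
    stop("geno has ", nrow(geno), " rows but sites has ", nrow(sites))
  if (ncol(geno) != nrow(samples))
    stop("geno has ", ncol(geno), " columns but samples has ", nrow(samples))
  ok <- geno %in% c(GT_HOM_REF, GT_HET, GT_HOM_ALT) | is.na(geno)
  if (!all(ok)) stop("genotype codes must be 0, 1, 2 or NA")
  dimnames(geno) <- list(site_key(sites), samples$sample_id)
  structure(list(geno = geno, sites = sites, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$geno), "sites x", ncol(x$geno), "samples;",
      sum(is.na(x$geno)), "missing cells\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Construct an allele-depth matrix
#'
#' Per-cell read counts split into reference, alternate and other-allele
#' reads; `total depth = ref + alt + other`. Shares its site and sample
#' indices with the paired [geno_matrix()].
#'
#' @param ref,alt,other non-negative integer matrices of identical dimension.
#' @param sites a [snp_list()]; @param samples a [sample_info()] table.
#' @return A `depth_matrix` object.
#' @export
depth_matrix <- function(ref, alt, other = NULL, sites, samples) {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  if (is.null(other)) other <- array(0L, dim(ref))
  other <- as.matrix(other)
  storage.mode(ref) <- "integer"
  storage.mode(alt) <- "integer"
  storage.mode(other) <- "integer"
  if (!identical(dim(ref), dim(alt)) || !identical(dim(ref), dim(other)))
    stop("ref, alt and other must have identical dimensions")
  if (nrow(ref) != nrow(sites) || ncol(ref) != nrow(samples))
    stop("depth matrix dimensions do not match site/sample indices")
  if (anyNA(ref) || anyNA(alt) || anyNA(other) ||
      any(ref < 0L) || any(alt < 0L) || any(other < 0L))
    stop("read counts must be non-negative integers")
  dn <- list(site_key(sites), samples$sample_id)
  dimnames(ref) <- dn; dimnames(alt) <- dn; dimnames(other) <- dn
  structure(list(ref = ref, alt = alt, other = other,
                 sites = sites, samples = samples),
            class = "depth_matrix")
}

#' @export
print.depth_matrix <- function(x, ...) {
  cat("depth_matrix:", nrow(x$ref), "sites x", ncol(x$ref), "samples;",
      "mean depth", round(mean(total_depth(x)), 2), "\n")
  invisible(x)
}

#' @export
dim.depth_matrix <- function(x) dim(x$ref)

#' Total read depth per cell
#' @param adm a [depth_matrix()].
#' @return Integer matrix of `ref + alt + other` counts.
#' @export
total_depth <- function(adm) adm$ref + adm$alt + adm$other

# Subset both indices of a geno/depth matrix to a logical or integer site
# selection, preserving class.
subset_sites <- function(x, keep) {
  x$sites <- x$sites[keep, , drop = FALSE]
  rownames(x$sites) <- NULL
  if (inherits(x, "geno_matrix")) {
    x$geno <- x$geno[keep, , drop = FALSE]
  } else {
    x$ref <- x$ref[keep, , drop = FALSE]
    x$alt <- x$alt[keep, , drop = FALSE]
    x$other <- x$other[keep, , drop = FALSE]
  }
  x
}

.gt_from_code <- function(code) {
  out <- rep("./.", length(code))
  out[!is.na(code) & code == GT_HOM_REF] <- "0/0"
  out[!is.na(code) & code == GT_HET] <- "0/1"
  out[!is.na(code) & code == GT_HOM_ALT] <- "1/1"
  out
}

#' Read genotype and depth matrices from a VCF file
#'
#' Parses a VCF (v4.2, optionally gzipped) with FORMAT fields GT and DP (AD
#' optional) into a paired [geno_matrix()] / [depth_matrix()]. Genotypes are
#' mapped 0/0 -> hom-ref, 0/1 or 1/0 -> het, 1/1 -> hom-alt, `./.` or `.` ->
#' missing; phased separators (`|`) are treated like unphased. Multi-allelic
#' records are retained with all alternate alleles recorded so triallelic
#' handling can act on them downstream. When AD is absent the DP total is
#' attributed to the called allele(s) and the matrix is flagged
#' `ad_available = FALSE`; operations that need the ref/alt split should
#' check that flag.
#'
#' Sample order follows the metadata table, not the VCF header; samples
#' present in the file but absent from the metadata (or vice versa) are an
#' error.
#'
#' @param path VCF file path.
#' @param sample_meta a [sample_info()] table covering the VCF's samples.
#' @return A list with elements `geno` (a `geno_matrix`) and `depth`
#'   (a `depth_matrix`, attribute `ad_available`).
#' @export
read_vcf <- function(path, sample_meta) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  n_site <- nrow(fix)
  vcf_samples <- colnames(v@gt)[-1]
  missing_meta <- setdiff(vcf_samples, sample_meta$sample_id)
  if (length(missing_meta))
    stop("samples in VCF absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  missing_vcf <- setdiff(sample_meta$sample_id, vcf_samples)
  if (length(missing_vcf))
    stop("samples in metadata absent from VCF: ",
         paste(missing_vcf, collapse = ", "))
  sites <- snp_list(fix[, "CHROM"], as.integer(fix[, "POS"]),
                    fix[, "REF"], fix[, "ALT"], name = basename(path))
  n_site <- nrow(sites)
  # rows in sorted (and deduplicated) site order, columns in metadata order
  fix_key <- paste(fix[, "CHROM"], fix[, "POS"], sep = ":")
  row_ord <- match(site_key(sites), fix_key)

  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                 error = function(e) NULL)
  reorder <- function(m) {
    if (is.null(m)) return(NULL)
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(fix),
                                     dimnames = list(NULL, vcf_samples))
    m[row_ord, sample_meta$sample_id, drop = FALSE]
  }
  gt <- reorder(gt); dp <- reorder(dp); ad <- reorder(ad)

  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, n_site, nrow(sample_meta))
  code[gt_clean %in% "0/0"] <- GT_HOM_REF
  code[gt_clean %in% c("0/1", "1/0")] <- GT_HET
  code[gt_clean %in% "1/1"] <- GT_HOM_ALT
  unknown <- !is.na(gt_clean) & !(gt_clean %in%
    c("0/0", "0/1", "1/0", "1/1", "./.", "."))
  if (any(unknown)) code[unknown] <- NA_integer_  # e.g. 1/2 at triallelics

  dp[is.na(dp)] <- 0
  dp <- round(dp)
  ad_available <- !is.null(ad) && any(!is.na(ad))
  if (ad_available) {
    split_ad <- function(i) {
      parts <- strsplit(ifelse(is.na(ad), "0,0", ad), ",", fixed = TRUE)
      vapply(parts, function(p) {
        p <- suppressWarnings(as.integer(p))
        p[is.na(p)] <- 0L
        if (length(p) >= i) p[i] else 0L
      }, integer(1))
    }
    ref_n <- matrix(split_ad(1), n_site)
    alt_n <- matrix(split_ad(2), n_site)
    other_n <- pmax(matrix(as.integer(dp), n_site) - ref_n - alt_n, 0L)
  } else {
    # DP only: attribute depth to the called genotype's alleles
    ref_n <- matrix(0L, n_site, nrow(sample_meta))
    alt_n <- matrix(0L, n_site, nrow(sample_meta))
    dpi <- matrix(as.integer(dp), n_site)
    ref_n[!is.na(code) & code == GT_HOM_REF] <-
      dpi[!is.na(code) & code == GT_HOM_REF]
    alt_n[!is.na(code) & code == GT_HOM_ALT] <-
      dpi[!is.na(code) & code == GT_HOM_ALT]
    het <- !is.na(code) & code == GT_HET
    ref_n[het] <- dpi[het] %/% 2L
    alt_n[het] <- dpi[het] - ref_n[het]
    miss <- is.na(code)
    ref_n[miss] <- dpi[miss]
    other_n <- matrix(0L, n_site, nrow(sample_meta))
  }
  gm <- geno_matrix(code, sites, sample_meta)
  adm <- depth_matrix(ref_n, alt_n, other_n, sites, sample_meta)
  attr(adm, "ad_available") <- ad_available
  list(geno = gm, depth = adm)
}

#' Write genotype and depth matrices to a VCF file
#'
#' Emits VCF v4.2 text with FORMAT `GT:DP:AD`. `read_vcf()` of the output
#' recovers the genotype codes, DP and AD exactly (round-trip identity).
#'
#' @param gm a [geno_matrix()].
#' @param adm the paired [depth_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, adm, path) {
  if (!identical(dim(gm), dim(adm)))
    stop("genotype and depth matrices must have identical dimensions")
  n_site <- nrow(gm$geno)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=skimeval",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
           "\"Allelic depths (ref, alt[, other])\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples$sample_id), collapse = "\t"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  if (n_site == 0L) return(invisible(path))
  dp <- total_depth(adm)
  gt <- matrix(.gt_from_code(gm$geno), n_site)
  cell <- matrix(paste0(gt, ":", dp, ":", adm$ref, ",", adm$alt,
                        ifelse(adm$other > 0L, paste0(",", adm$other), "")),
                 n_site)
  body <- paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref,
                gm$sites$alt, ".", "PASS", ".", "GT:DP:AD",
                apply(cell, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}
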