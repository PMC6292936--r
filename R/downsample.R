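# In silico construction of skim sets: fraction-of-reads FASTQ subsetting
# and its matrix-level analogue, binomial depth thinning.

#' Fraction of reads retained when skimming to a target coverage
#'
#' @param target_coverage desired fold coverage.
#' @param nominal_coverage assumed coverage of the input (every sample is
#'   treated as having this coverage regardless of its realized value).
#' @return A `skim_fraction` list with `fraction = target/nominal` in (0, 1].
#' @export
skim_fraction <- function(target_coverage, nominal_coverage = 10) {
  frac <- target_coverage / nominal_coverage
  if (!is.finite(frac) || frac <= 0 || frac > 1)
    stop("target/nominal must give a fraction in (0, 1]")
  structure(list(target_coverage = target_coverage,
                 nominal_coverage = nominal_coverage,
                 fraction = frac),
            class = "skim_fraction")
}

.as_fraction <- function(frac) {
  if (inherits(frac, "skim_fraction")) frac <- frac$fraction
  if (frac <= 0 || frac > 1) stop("fraction must be in (0, 1]")
  frac
}

# Stable per-file stream seed derived from a master seed and the file name,
# so adding samples never perturbs existing outputs. Kept below 2^31.
.stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) + h * 7919L) %% 2147483587L
}

#' Subsample FASTQ files to a coverage fraction
#'
#' Each read (or read pair) is kept independently with probability
#' `fraction`, so the output count is Binomial(N, fraction) — preserving the
#' coverage variability a pooled skim run shows rather than hitting an exact
#' count. Pairs are kept or dropped together, keyed on record order, so R1
#' and R2 outputs carry identical read-id sequences. Deterministic for a
#' fixed seed; the per-file stream seed is derived from the master seed and
#' the file name.
#'
#' @param r1 input FASTQ path; @param r2 optional mate FASTQ path.
#' @param out1,out2 output paths (out2 required with r2).
#' @param frac a [skim_fraction()] or a bare fraction in (0, 1].
#' @param seed master integer seed.
#' @return Named integer vector: reads in and reads kept.
#' @export
subsample_fastq <- function(r1, out1, frac, r2 = NULL, out2 = NULL,
                            seed = 1L) {
  frac <- .as_fraction(frac)
  reads1 <- Biostrings::readDNAStringSet(r1, format = "fastq",
                                         with.qualities = TRUE)
  n <- length(reads1)
  if (!is.null(r2)) {
    if (is.null(out2)) stop("out2 is required for paired input")
    reads2 <- Biostrings::readDNAStringSet(r2, format = "fastq",
                                           with.qualities = TRUE)
    if (length(reads2) != n)
      stop("paired FASTQ files have unequal record counts (",
           n, " vs ", length(reads2), ")")
  }
  set.seed(.stream_seed(seed, basename(r1)))
  keep <- if (frac >= 1) rep(TRUE, n) else stats::runif(n) < frac
  write_fq <- function(x, keep, path) {
    x <- x[keep]
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = S4Vectors::mcols(x)$qualities)
  }
  write_fq(reads1, keep, out1)
  if (!is.null(r2)) write_fq(reads2, keep, out2)
  c(n_in = n, n_kept = sum(keep))
}

#' Thin an allele-depth matrix to a coverage fraction
#'
#' Every read count `c` is replaced by a Binomial(`c`, fraction) draw, with
#' ref, alt and other counts thinned independently — the matrix-level
#' analogue of read subsetting. By Poisson thinning, Poisson(lambda) input
#' depths yield Poisson(fraction * lambda) output depths.
#'
#' @param adm a [depth_matrix()].
#' @param frac a [skim_fraction()] or bare fraction in (0, 1].
#' @param seed integer seed.
#' @return A thinned [depth_matrix()].
#' @export
thin_depths <- function(adm, frac, seed = 1L) {
  stopifnot(inherits(adm, "depth_matrix"))
  frac <- .as_fraction(frac)
  if (frac >= 1) return(adm)
  set.seed(seed)
  thin <- function(m) matrix(stats::rbinom(length(m), m, frac),
                             nrow(m), ncol(m))
  depth_matrix(thin(adm$ref), thin(adm$alt), thin(adm$other),
               adm$sites, adm$samples)
}
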