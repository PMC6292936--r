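# Generative model of skim whole-genome resequencing: genotype truth for
# three population classes, gamma-dispersed per-sample coverage, Poisson read
# depth with binomial allele sampling, sequencing error and collapsed-paralog
# heterozygote artifacts.

#' Describe a population to simulate
#'
#' @param population_class `"DIVERSE_PANEL"` (outbred panel with optional
#'   inbreeding coefficient `f`), `"FOUR_PARENT_CROSS"` (families of
#'   offspring uniting two of four founder gametes) or `"DOUBLED_HAPLOID"`
#'   (fully homozygous; any heterozygous call downstream is an error signal).
#' @param n_samples,n_sites positive counts.
#' @param maf_distribution function of `n` returning alternate-allele
#'   frequencies in (0, 0.5]; default uniform on \[0.05, 0.5\].
#' @param f inbreeding coefficient in \[0, 1\]; heterozygote deficit for the
#'   diverse panel (f = 1 removes heterozygotes entirely).
#' @param n_families number of families for `FOUR_PARENT_CROSS`; defaults to
#'   about one family per 19 offspring, the granularity of the doubled-
#'   haploid material this emulates.
#' @param seed integer seed used by [simulate_truth()].
#' @return A `population_spec` list.
#' @export
population_spec <- function(population_class = "DIVERSE_PANEL",
                            n_samples, n_sites,
                            maf_distribution = function(n)
                              stats::runif(n, 0.05, 0.5),
                            f = 0, n_families = NULL, seed = 1L) {
  classes <- c("DIVERSE_PANEL", "FOUR_PARENT_CROSS", "DOUBLED_HAPLOID")
  population_class <- match.arg(population_class, classes)
  if (n_samples <= 0 || n_sites <= 0)
    stop("n_samples and n_sites must be positive")
  if (f < 0 || f > 1) stop("f must be in [0, 1]")
  if (is.null(n_families)) n_families <- max(1L, round(n_samples / 19))
  structure(list(population_class = population_class,
                 n_samples = as.integer(n_samples),
                 n_sites = as.integer(n_sites),
                 maf_distribution = maf_distribution,
                 f = f, n_families = as.integer(n_families),
                 seed = as.integer(seed)),
            class = "population_spec")
}

.sim_sites <- function(n_sites, rng_ready = TRUE) {
  pos <- sort(sample.int(n_sites * 100L, n_sites))
  ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
  snp_list(rep("chr1", n_sites), pos, ref, alt, name = "simulated")
}

#' Simulate true genotypes for a population
#'
#' Per site an alternate-allele frequency `p` is drawn from the spec's MAF
#' distribution. Diverse-panel genotypes follow inbreeding-adjusted
#' Hardy-Weinberg proportions `{(1-p)^2 + f p (1-p), 2 p (1-p) (1-f),
#' p^2 + f p (1-p)}`; doubled haploids are hom-alt with probability `p`,
#' else hom-ref; four-parent-cross offspring unite two distinct gametes
#' drawn from their family's four founder gametes (founder alleles
#' Bernoulli(`p`)). Truth contains no missing cells.
#'
#' @param spec a [population_spec()].
#' @return A [geno_matrix()]; simulated sites on one chromosome, sample
#'   metadata carrying the population class.
#' @export
simulate_truth <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  n_si <- spec$n_sites; n_sa <- spec$n_samples
  sites <- .sim_sites(n_si)
  p <- spec$maf_distribution(n_si)
  if (any(p <= 0 | p > 0.5))
    stop("maf_distribution must return frequencies in (0, 0.5]")
  g <- switch(spec$population_class,
    DIVERSE_PANEL = {
      f <- spec$f
      pr_het <- 2 * p * (1 - p) * (1 - f)
      pr_alt <- p^2 + f * p * (1 - p)
      u <- matrix(stats::runif(n_si * n_sa), n_si, n_sa)
      gg <- matrix(GT_HOM_REF, n_si, n_sa)
      gg[u < pr_alt + pr_het] <- GT_HET
      gg[u < pr_alt] <- GT_HOM_ALT
      gg
    },
    DOUBLED_HAPLOID = {
      matrix(ifelse(stats::runif(n_si * n_sa) < rep(p, n_sa),
                    GT_HOM_ALT, GT_HOM_REF), n_si, n_sa)
    },
    FOUR_PARENT_CROSS = {
      fam <- sort(rep_len(seq_len(spec$n_families), n_sa))
      gg <- matrix(GT_HOM_REF, n_si, n_sa)
      for (fm in seq_len(spec$n_families)) {
        idx <- which(fam == fm)
        gametes <- matrix(stats::rbinom(n_si * 4L, 1L, p), n_si, 4L)
        for (j in idx) {
          pick <- sample.int(4L, 2L)
          gg[, j] <- gametes[, pick[1L]] + gametes[, pick[2L]]
        }
      }
      gg
    })
  storage.mode(g) <- "integer"
  samples <- sample_info(sprintf("S%04d", seq_len(n_sa)),
                         subpopulation = "all",
                         population_class = spec$population_class,
                         nominal_coverage = 1)
  geno_matrix(g, sites, samples)
}

#' Sample a cross-sample coverage profile
#'
#' Pooled library preparation spreads realized coverage around the mean;
#' per-sample multipliers are drawn from a Gamma distribution with mean 1
#' and the requested coefficient of variation (shape `1/cv^2`, scale
#' `cv^2`), so `mean_coverage * multiplier` is each sample's expected depth.
#'
#' @param mean_coverage mean fold coverage (> 0).
#' @param cv cross-sample coefficient of variation (>= 0); `cv = 0` gives
#'   all multipliers exactly 1.
#' @param n number of samples.
#' @param seed integer seed.
#' @return A `coverage_profile` list with fields `mean_coverage`, `cv`,
#'   `multiplier` (length `n`, mean approximately 1).
#' @export
coverage_profile <- function(mean_coverage, cv = 0.27, n, seed = 1L) {
  if (mean_coverage < 0) stop("mean_coverage must be >= 0")
  if (cv < 0) stop("cv must be >= 0")
  if (cv == 0) {
    mult <- rep(1, n)
  } else {
    set.seed(seed)
    mult <- stats::rgamma(n, shape = 1 / cv^2, scale = cv^2)
  }
  structure(list(mean_coverage = mean_coverage, cv = cv, multiplier = mult),
            class = "coverage_profile")
}

#' Describe the read-level error model
#'
#' @param per_read_error probability a read at a homozygous cell reports the
#'   paired alternate allele (and vice versa).
#' @param artifact_site_fraction fraction of sites that are collapsed-paralog
#'   artifacts: at those sites every individual's read pool carries both
#'   alleles (a constant heterozygosity signal regardless of genotype) —
#'   the mechanism behind spurious heterozygous calls in doubled haploids.
#' @param other_read_rate probability a read reports a third allele;
#'   non-zero values exercise triallelic handling. Default 0.
#' @return An `error_model` list.
#' @export
error_model <- function(per_read_error = 0, artifact_site_fraction = 0,
                        other_read_rate = 0) {
  vals <- c(per_read_error, artifact_site_fraction, other_read_rate)
  if (any(vals < 0 | vals > 1)) stop("error-model rates must be in [0, 1]")
  structure(list(per_read_error = per_read_error,
                 artifact_site_fraction = artifact_site_fraction,
                 other_read_rate = other_read_rate),
            class = "error_model")
}

#' Simulate skim read counts over a genotype truth
#'
#' Depth at (site, sample) is Poisson with mean
#' `mean_coverage * multiplier[sample]`. At heterozygous cells (and at every
#' cell of an artifact site) each read is reference with probability 1/2; at
#' homozygous cells each read reports the true allele, flipped to the paired
#' allele with probability `per_read_error`. Artifact sites are drawn once
#' per call — the same sites for all samples, emulating consistent
#' misalignment. Each read independently becomes an other-allele read with
#' probability `other_read_rate`.
#'
#' @param truth a [geno_matrix()] with no missing cells.
#' @param profile a [coverage_profile()] whose length matches the samples.
#' @param err an [error_model()].
#' @param seed integer seed; identical inputs and seed give bit-identical
#'   output.
#' @return A [depth_matrix()]; attribute `artifact_sites` holds the row
#'   indices drawn as artifacts.
#' @export
simulate_reads <- function(truth, profile, err = error_model(), seed = 1L) {
  stopifnot(inherits(truth, "geno_matrix"),
            inherits(profile, "coverage_profile"),
            inherits(err, "error_model"))
  n_si <- nrow(truth$geno); n_sa <- ncol(truth$geno)
  if (length(profile$multiplier) != n_sa)
    stop("coverage profile length does not match sample count")
  if (anyNA(truth$geno)) stop("truth matrix must not contain missing cells")
  set.seed(seed)
  n_art <- round(err$artifact_site_fraction * n_si)
  artifact <- if (n_art > 0) sort(sample.int(n_si, n_art)) else integer(0)

  lambda <- matrix(profile$mean_coverage, n_si, n_sa) *
    matrix(profile$multiplier, n_si, n_sa, byrow = TRUE)
  depth <- matrix(stats::rpois(n_si * n_sa, lambda), n_si, n_sa)
  other <- if (err$other_read_rate > 0)
    matrix(stats::rbinom(n_si * n_sa, depth, err$other_read_rate), n_si, n_sa)
  else matrix(0L, n_si, n_sa)
  rem <- depth - other

  # probability a remaining read is the reference allele
  p_ref <- matrix(NA_real_, n_si, n_sa)
  p_ref[truth$geno == GT_HOM_REF] <- 1 - err$per_read_error
  p_ref[truth$geno == GT_HET] <- 0.5
  p_ref[truth$geno == GT_HOM_ALT] <- err$per_read_error
  if (length(artifact)) p_ref[artifact, ] <- 0.5

  ref <- matrix(stats::rbinom(n_si * n_sa, rem, p_ref), n_si, n_sa)
  alt <- rem - ref
  out <- depth_matrix(ref, alt, other, truth$sites, truth$samples)
  attr(out, "artifact_sites") <- artifact
  out
}
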