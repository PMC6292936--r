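# Closed-form design calculator: genotype call rates and heterozygote
# under-calling under Poisson coverage, and the library + per-Gb sequencing
# cost model for the coverage vs sample-number trade-off.

#' Sequencing cost model
#'
#' @param lib_cost_per_sample library preparation cost per sample (currency;
#'   default 12).
#' @param cost_per_gb sequencing cost per gigabase (default 30).
#' @param gb_per_1x gigabases needed for 1x coverage of the genome per
#'   sample (default 1.0, a genome of roughly 1 Gbp; e.g. 4.3 for pea).
#' @return A `cost_model` list.
#' @export
cost_model <- function(lib_cost_per_sample = 12, cost_per_gb = 30,
                       gb_per_1x = 1.0) {
  if (any(c(lib_cost_per_sample, cost_per_gb, gb_per_1x) < 0))
    stop("cost parameters must be >= 0")
  structure(list(lib_cost_per_sample = lib_cost_per_sample,
                 cost_per_gb = cost_per_gb, gb_per_1x = gb_per_1x),
            class = "cost_model")
}

#' Probability a cell is callable at a minimum depth
#'
#' `P(Poisson(lambda) >= d)`: the chance a site in one sample receives at
#' least `d` reads at mean coverage `lambda`. Increasing in `lambda`,
#' decreasing in `d`.
#'
#' @param lambda mean fold coverage (> 0).
#' @param d minimum read depth (>= 0).
#' @return A probability.
#' @export
p_called <- function(lambda, d) {
  if (any(lambda <= 0)) stop("lambda must be > 0")
  if (any(d < 0)) stop("d must be >= 0")
  stats::ppois(d - 1, lambda, lower.tail = FALSE)
}

#' Probability a heterozygote is under-called at a given depth
#'
#' With error-free reads, all `k` reads at a heterozygous site carry the
#' same allele with probability `2^(1-k)` — insufficient allele sampling,
#' the mechanism that makes heterozygotes appear homozygous in skim data.
#'
#' @param d_obs observed read depth (>= 1).
#' @return The probability of a single-allele read pool.
#' @export
p_het_undercall <- function(d_obs) {
  if (any(d_obs < 1)) stop("d_obs must be >= 1")
  2^(1 - d_obs)
}

# Probability the ML caller returns each genotype given truth, depth k and
# per-read error eps; used by the analytic accuracy mixture.
.p_correct_given_depth <- function(k, truth, eps, params) {
  r <- 0:k
  p_r <- switch(truth,
    HOM_REF = stats::dbinom(r, k, 1 - eps),
    HET = stats::dbinom(r, k, 0.5),
    HOM_ALT = stats::dbinom(r, k, eps))
  call <- call_genotype(r, k - r, params)
  want <- switch(truth, HOM_REF = GT_HOM_REF, HET = GT_HET,
                 HOM_ALT = GT_HOM_ALT)
  sum(p_r[!is.na(call) & call == want])
}

#' Expected accuracy of called genotypes under the skim model
#'
#' Analytic companion to the simulate -> call -> evaluate pipeline: mixes
#' the ML caller's per-depth correctness over the Poisson depth distribution
#' truncated at `max(d, 1)` (zero-depth cells are missing, not wrong) and
#' over the population's genotype mix (`het_rate` heterozygotes, the rest
#' split evenly between the homozygotes — homozygote accuracy is symmetric
#' in the allele, so the split does not matter).
#'
#' @param lambda mean fold coverage.
#' @param d minimum read depth filter.
#' @param het_rate fraction of heterozygous truth cells.
#' @param eps per-read error probability (shared by generator and caller).
#' @return Expected fraction of called genotypes that match truth.
#' @export
expected_called_accuracy <- function(lambda, d, het_rate, eps = 0) {
  m <- max(d, 1)
  kmax <- max(stats::qpois(1 - 1e-12, lambda), m + 1)
  ks <- m:kmax
  w <- stats::dpois(ks, lambda)
  w <- w / sum(w)  # depth conditional on k >= m
  params <- caller_params(per_read_error = eps)
  acc_k <- vapply(ks, function(k) {
    het <- .p_correct_given_depth(k, "HET", eps, params)
    hom <- (.p_correct_given_depth(k, "HOM_REF", eps, params) +
            .p_correct_given_depth(k, "HOM_ALT", eps, params)) / 2
    het_rate * het + (1 - het_rate) * hom
  }, numeric(1))
  sum(w * acc_k)
}

#' Total sequencing cost for a design
#'
#' `n_samples * (library cost + coverage * Gb-per-1x * cost per Gb)`:
#' library preparation is a fixed per-sample cost while sequencing scales
#' linearly with coverage.
#'
#' @param n_samples number of samples (>= 0).
#' @param coverage fold coverage per sample.
#' @param model a [cost_model()].
#' @return Total cost in the model's currency.
#' @export
cost_total <- function(n_samples, coverage, model = cost_model()) {
  if (n_samples < 0 || coverage < 0) stop("inputs must be >= 0")
  n_samples * (model$lib_cost_per_sample +
                 coverage * model$gb_per_1x * model$cost_per_gb)
}

#' Samples affordable at a fixed budget
#'
#' Budget divided by the per-sample cost, rounded to the nearest whole
#' sample.
#'
#' @param budget available funds (>= 0).
#' @param coverage fold coverage per sample.
#' @param model a [cost_model()].
#' @return Number of samples.
#' @export
affordable_samples <- function(budget, coverage, model = cost_model()) {
  if (budget < 0) stop("budget must be >= 0")
  per_sample <- cost_total(1, coverage, model)
  if (per_sample <= 0) stop("per-sample cost must be > 0")
  round(budget / per_sample)
}

#' Coverage/depth/cost trade-off table
#'
#' One row per (coverage, min depth) pair: callable-cell probability,
#' heterozygote under-call probability at the filter depth, expected called
#' accuracy, and cost for `n_samples` (or samples affordable at `budget`).
#'
#' @param coverages fold coverages to tabulate.
#' @param depths minimum read depths to tabulate.
#' @param het_rate population heterozygosity; @param eps per-read error.
#' @param n_samples samples to cost; @param budget optional fixed budget.
#' @param model a [cost_model()].
#' @return A data frame.
#' @export
design_table <- function(coverages = c(0.25, 0.5, 1:5), depths = 2:5,
                         het_rate = 0.1, eps = 0.01, n_samples = 100,
                         budget = NULL, model = cost_model()) {
  grid <- expand.grid(coverage = coverages, min_depth = depths)
  grid$p_called <- mapply(p_called, grid$coverage, grid$min_depth)
  grid$p_het_undercall <- p_het_undercall(pmax(grid$min_depth, 1))
  grid$expected_accuracy <- mapply(expected_called_accuracy, grid$coverage,
                                   grid$min_depth, het_rate, eps)
  grid$cost <- vapply(grid$coverage, cost_total, numeric(1),
                      n_samples = n_samples, model = model)
  if (!is.null(budget))
    grid$affordable_samples <- vapply(grid$coverage, affordable_samples,
                                      numeric(1), budget = budget,
                                      model = model)
  grid
}
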