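# End-to-end workflows wiring the stages together: the in silico
# coverage x depth-filter evaluation grid, and the experimental-application
# presets for four-parent crosses and doubled haploids.

#' Run the in silico skim evaluation grid
#'
#' For every (coverage, depth) pair: thin the deep allele-depth matrix to
#' the target coverage, call genotypes at the listed sites, mask at the
#' minimum depth and apply the missing-data filter, then evaluate against
#' the deep reference at the matched depth. Produces the SNP-count grid,
#' the match/mismatch/missing decomposition, and the cumulative
#' missing-data accuracy table per grid point.
#'
#' @param deep_adm deep [depth_matrix()] (the full-coverage data).
#' @param sites [snp_list()] of sites to genotype.
#' @param coverages target fold coverages (fractions of `deep_coverage`).
#' @param depths minimum read depths.
#' @param deep_coverage nominal coverage of `deep_adm` (default 10).
#' @param caller a [caller_params()].
#' @param max_missing per-site missing filter applied to each skim set.
#' @param seed master seed; each grid point derives its own stream.
#' @return A `study_bundle` list: `grid` (data frame with coverage, depth,
#'   SNP count, concordance percentages) and `reports` (per-point list of
#'   `concordance` and `cumulative` tables). Identical seeds give identical
#'   bundles.
#' @export
run_in_silico_study <- function(deep_adm, sites,
                                coverages = c(0.25, 0.5, 1),
                                depths = 2:5, deep_coverage = 10,
                                caller = caller_params(),
                                max_missing = 0.5, seed = 1L) {
  deep_gm <- genotype_matrix(deep_adm, sites, caller)
  reports <- list()
  rows <- list()
  for (cv in coverages) {
    frac <- skim_fraction(cv, deep_coverage)
    skim_adm <- thin_depths(deep_adm, frac,
                            seed = .stream_seed(seed, paste0("cov", cv)))
    for (d in depths) {
      gm <- genotype_matrix(skim_adm, sites, caller)
      gm <- mask_by_depth(gm, skim_adm, d)
      gm <- filter_missing(gm, max_missing)
      conc <- concordance(gm, deep_gm, d, deep_adm)
      cum <- cumulative_accuracy_table(gm, deep_gm, d, deep_adm)
      key <- sprintf("cov%g_dp%d", cv, d)
      reports[[key]] <- list(concordance = conc, cumulative = cum)
      rows[[key]] <- data.frame(
        coverage = cv, min_depth = d, n_snps = nrow(gm$geno),
        overall_match_pct = conc$overall_match_pct,
        mismatch_pct = conc$mismatch_pct,
        missing_pct = conc$missing_pct,
        called_accuracy = conc$called_accuracy)
    }
  }
  structure(list(grid = do.call(rbind, c(rows, make.row.names = FALSE)),
                 reports = reports, seed = seed),
            class = "study_bundle")
}

#' Run an experimental-application workflow
#'
#' Applies the population-class preset to a called genotype matrix over a
#' depth grid and reports the accounting and per-individual yields the
#' experimental workflows produce. Presets: `"four-parent"` (MAF 0.01,
#' missing 0.5, depth grid 2-5) and `"doubled-haploid"` (triallelic sites
#' set missing, depth grid 1-5, no MAF/missing/heterozygosity filter);
#' `"diversity-panel"` adds MAF 0.05 and heterozygosity 0.1.
#'
#' @param gm called [geno_matrix()]; @param adm paired [depth_matrix()].
#' @param preset preset name (see [filter_preset()]).
#' @param depths minimum read depths (defaults per preset).
#' @param maf_groups optional subpopulation vector for per-group MAF.
#' @return A data-frame summary (one row per depth: surviving sites, total
#'   data points, residual missing, yield average/min/max) with the full
#'   per-depth `filter_report`s and `yield_summary`s attached as attributes.
#' @export
run_experimental <- function(gm, adm,
                             preset = c("four-parent", "doubled-haploid",
                                        "diversity-panel"),
                             depths = NULL, maf_groups = NULL) {
  preset <- match.arg(preset)
  if (is.null(depths))
    depths <- if (preset == "doubled-haploid") 1:5 else 2:5
  reports <- list(); yields <- list(); rows <- list()
  for (d in depths) {
    fp <- filter_preset(preset, min_depth = d, maf_groups = maf_groups)
    res <- apply_filter_pipeline(gm, adm, fp)
    y <- yield_summary(res$geno)
    key <- paste0("dp", d)
    reports[[key]] <- res$report; yields[[key]] <- y
    rows[[key]] <- data.frame(
      min_depth = d, n_snps = res$report$sites_out,
      total_data_points = res$report$total_data_points,
      residual_missing_pct =
        100 * res$report$residual_missing_fraction,
      yield_avg = y$average, yield_min = y$minimum, yield_max = y$maximum)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "reports") <- reports
  attr(out, "yields") <- yields
  out
}
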