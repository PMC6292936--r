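# Accuracy and summary machinery: matched-depth concordance of a skim
# genotype matrix against a deep reference, cumulative missing-data accuracy
# tables, per-chromosome SNP density, per-individual genotype yields, and the
# de novo vs list-based discovery audit.

#' Reference depth matched to a skim filtering depth
#'
#' A skim set filtered at minimum depth `d` is compared against the deep
#' reference masked at the same depth, floored at 2: `max(d, 2)`. The floor
#' keeps the reference itself from being judged on single-read evidence.
#'
#' @param skim_d skim minimum read depth (>= 0).
#' @return The reference minimum depth.
#' @export
matched_reference_depth <- function(skim_d) {
  if (any(skim_d < 0)) stop("skim_d must be >= 0")
  pmax(skim_d, 2L)
}

#' Classify a skim/reference genotype pair
#'
#' Categories: the reference being missing makes the cell `NOT_EVALUABLE`
#' (no truth to compare against); otherwise a missing skim call is
#' `MISSING_IN_SKIM`; otherwise equal codes are a `MATCH`, unequal a
#' `MISMATCH`. Vectorized.
#'
#' @param skim_gt,ref_gt integer genotype codes (0/1/2/NA).
#' @return Character vector in
#'   `{"MATCH","MISMATCH","MISSING_IN_SKIM","NOT_EVALUABLE"}`.
#' @export
classify_cell <- function(skim_gt, ref_gt) {
  out <- ifelse(is.na(ref_gt), "NOT_EVALUABLE",
         ifelse(is.na(skim_gt), "MISSING_IN_SKIM",
         ifelse(skim_gt == ref_gt, "MATCH", "MISMATCH")))
  if (!is.null(dim(skim_gt))) dim(out) <- dim(skim_gt)
  out
}

.concordance_counts <- function(skim_geno, ref_geno) {
  cls <- classify_cell(skim_geno, ref_geno)
  c(n_match = sum(cls == "MATCH"),
    n_mismatch = sum(cls == "MISMATCH"),
    n_missing_in_skim = sum(cls == "MISSING_IN_SKIM"),
    n_not_evaluable = sum(cls == "NOT_EVALUABLE"))
}

.concordance_report <- function(counts) {
  total <- sum(counts)
  called <- counts[["n_match"]] + counts[["n_mismatch"]]
  structure(c(as.list(counts), list(
    total_cells = total,
    overall_match_pct = 100 * counts[["n_match"]] / total,
    mismatch_pct = 100 * counts[["n_mismatch"]] / total,
    missing_pct = 100 * counts[["n_missing_in_skim"]] / total,
    not_evaluable_pct = 100 * counts[["n_not_evaluable"]] / total,
    called_accuracy = if (called > 0) counts[["n_match"]] / called
                      else NA_real_)),
    class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(paste0("concordance over %s cells: %.1f%% match, %.1f%% ",
                     "mismatch, %.1f%% missing, %.1f%% not evaluable\n"),
              format(x$total_cells, big.mark = ","), x$overall_match_pct,
              x$mismatch_pct, x$missing_pct, x$not_evaluable_pct))
  if (is.na(x$called_accuracy))
    cat("  called accuracy undefined (no evaluable called cells)\n")
  else
    cat(sprintf("  accuracy of called genotypes: %.1f%%\n",
                100 * x$called_accuracy))
  invisible(x)
}

#' Matched-depth concordance of a skim set against a deep reference
#'
#' The reference is masked at [matched_reference_depth()] of the skim's
#' filtering depth using its own depth matrix, then every cell of the shared
#' site set is classified with [classify_cell()]. `called_accuracy` is
#' matches over matches-plus-mismatches: missing-in-skim and not-evaluable
#' cells are excluded from both numerator and denominator.
#'
#' @param skim a skim [geno_matrix()] (already depth-filtered at `skim_d`).
#' @param reference the deep [geno_matrix()] covering the skim's sites.
#' @param skim_d the skim set's minimum read depth.
#' @param ref_adm the reference's [depth_matrix()], used for matched-depth
#'   masking.
#' @return A `concordance_report`: the four cell counts, their percentages
#'   of all cells, and `called_accuracy`.
#' @export
concordance <- function(skim, reference, skim_d, ref_adm) {
  ref_keep <- match(site_key(skim$sites), site_key(reference$sites))
  if (anyNA(ref_keep))
    stop("reference does not cover every skim site")
  ref <- subset_sites(reference, ref_keep)
  ref_d <- subset_sites(ref_adm,
                        match(site_key(skim$sites), site_key(ref_adm$sites)))
  ref <- mask_by_depth(ref, ref_d, matched_reference_depth(skim_d))
  .concordance_report(.concordance_counts(skim$geno, ref$geno))
}

#' Cumulative SNP counts and accuracy by maximum missing data
#'
#' For each bin upper edge `b` the table restricts to sites whose per-site
#' missing fraction (in the skim set) is strictly below `b`, and reports the
#' site count and the accuracy of called genotypes over that restriction.
#' Counts are cumulative: non-decreasing in `b`.
#'
#' @inheritParams concordance
#' @param bins bin upper edges (default 10% increments up to 50%).
#' @return A data frame with columns `max_missing`, `snp_count`,
#'   `called_accuracy_pct`.
#' @export
cumulative_accuracy_table <- function(skim, reference, skim_d, ref_adm,
                                      bins = seq(0.1, 0.5, by = 0.1)) {
  ref <- subset_sites(reference,
                      match(site_key(skim$sites), site_key(reference$sites)))
  ref_d <- subset_sites(ref_adm,
                        match(site_key(skim$sites), site_key(ref_adm$sites)))
  ref <- mask_by_depth(ref, ref_d, matched_reference_depth(skim_d))
  miss <- .site_missing(skim)
  rows <- lapply(bins, function(b) {
    in_bin <- miss < b
    counts <- .concordance_counts(skim$geno[in_bin, , drop = FALSE],
                                  ref$geno[in_bin, , drop = FALSE])
    called <- counts[["n_match"]] + counts[["n_mismatch"]]
    data.frame(max_missing = b, snp_count = sum(in_bin),
               called_accuracy_pct = if (called > 0)
                 100 * counts[["n_match"]] / called else NA_real_)
  })
  do.call(rbind, rows)
}

#' Per-chromosome SNP density summary
#'
#' Density is SNPs per Mbp (count over chromosome length); relative density
#' scales by the densest chromosome, which gets 1. Also bins sites into
#' half-open 1-Mbp windows `[k Mbp, (k+1) Mbp)`.
#'
#' @param sites a [snp_list()].
#' @param chrom_lengths data frame with columns `chrom` and `length` (bp)
#'   covering every chromosome in `sites`.
#' @param per_mbp if `FALSE`, use raw counts instead of per-Mbp densities.
#' @return A list: `chromosomes` (data frame with `chrom`, `snp_count`,
#'   `length`, `density`, `relative_density`) and `bins` (data frame with
#'   `chrom`, `bin_start`, `count`).
#' @export
density_summary <- function(sites, chrom_lengths, per_mbp = TRUE) {
  unknown <- setdiff(unique(sites$chrom), chrom_lengths$chrom)
  if (length(unknown))
    stop("no length for chromosome(s): ", paste(unknown, collapse = ", "))
  tab <- table(factor(sites$chrom, levels = chrom_lengths$chrom))
  counts <- as.integer(tab)
  dens <- if (per_mbp) counts / (chrom_lengths$length / 1e6) else counts
  rel <- if (max(dens) > 0) dens / max(dens) else dens
  chroms <- data.frame(chrom = chrom_lengths$chrom, snp_count = counts,
                       length = chrom_lengths$length, density = dens,
                       relative_density = rel, stringsAsFactors = FALSE)
  bin_start <- sites$pos %/% 1000000L * 1000000L
  bins <- as.data.frame(table(chrom = sites$chrom, bin_start = bin_start),
                        stringsAsFactors = FALSE)
  bins <- bins[bins$Freq > 0, , drop = FALSE]
  bins$bin_start <- as.integer(bins$bin_start)
  names(bins)[3] <- "count"
  rownames(bins) <- NULL
  list(chromosomes = chroms, bins = bins[order(bins$chrom, bins$bin_start), ])
}

#' Audit de novo discovery against list-based genotyping
#'
#' Compares the site yields of the two modes and classifies the genotypes at
#' novel sites (discovered de novo but absent from the list-based set)
#' against the deep reference: consistent, missing-in-skim, or incorrect
#' fractions over evaluable cells.
#'
#' @param denovo a [snp_list()] of de novo discovered (and filtered) sites.
#' @param listbased a [snp_list()] of list-based surviving sites.
#' @param denovo_gm optional [geno_matrix()] of de novo genotypes (for the
#'   novel-site audit); @param deep_gm optional deep reference
#'   [geno_matrix()] covering the union of sites.
#' @return A `denovo_comparison` list: `n_denovo`, `n_listbased`,
#'   `pct_list_reidentified`, `fold_increase` (1 decimal),
#'   `absolute_increase`, and (when matrices are given) `novel_audit`
#'   with fractions `consistent`, `missing`, `incorrect`.
#' @export
denovo_audit <- function(denovo, listbased, denovo_gm = NULL,
                         deep_gm = NULL) {
  n_de <- if (is.data.frame(denovo)) nrow(denovo) else as.numeric(denovo)
  n_list <- if (is.data.frame(listbased)) nrow(listbased)
            else as.numeric(listbased)
  fold <- if (n_list > 0) round(n_de / n_list, 1) else NA_real_
  pct_reid <- if (is.data.frame(denovo) && is.data.frame(listbased)) {
    if (n_list > 0)
      100 * sum(site_key(listbased) %in% site_key(denovo)) / n_list
    else NA_real_
  } else NA_real_
  audit <- NULL
  if (!is.null(denovo_gm) && !is.null(deep_gm) &&
      is.data.frame(denovo) && is.data.frame(listbased)) {
    novel <- setdiff(site_key(denovo), site_key(listbased))
    idx <- match(novel, site_key(denovo_gm$sites))
    idx <- idx[!is.na(idx)]
    if (length(idx)) {
      sub <- subset_sites(denovo_gm, idx)
      ref_idx <- match(site_key(sub$sites), site_key(deep_gm$sites))
      if (anyNA(ref_idx)) stop("deep reference does not cover novel sites")
      ref <- subset_sites(deep_gm, ref_idx)
      counts <- .concordance_counts(sub$geno, ref$geno)
      evaluable <- sum(counts) - counts[["n_not_evaluable"]]
      audit <- list(
        consistent = counts[["n_match"]] / evaluable,
        missing = counts[["n_missing_in_skim"]] / evaluable,
        incorrect = counts[["n_mismatch"]] / evaluable)
    } else audit <- list(consistent = NA_real_, missing = NA_real_,
                         incorrect = NA_real_)
  }
  structure(list(n_denovo = n_de, n_listbased = n_list,
                 pct_list_reidentified = pct_reid,
                 fold_increase = fold,
                 absolute_increase = n_de - n_list,
                 novel_audit = audit),
            class = "denovo_comparison")
}

#' @export
print.denovo_comparison <- function(x, ...) {
  cat("de novo:", x$n_denovo, "sites vs list-based:", x$n_listbased,
      sprintf("(%.1f-fold, +%s)\n", x$fold_increase,
              format(x$absolute_increase, big.mark = ",")))
  if (!is.na(x$pct_list_reidentified))
    cat(sprintf("  %.2f%% of list-based sites re-identified de novo\n",
                x$pct_list_reidentified))
  invisible(x)
}

#' Log-linear fit of marker counts against sequencing coverage
#'
#' Least-squares fit of `log(count) ~ coverage`, the usual way to summarise
#' the exponential growth of retained SNP numbers with coverage. Returns the
#' growth rate per fold coverage and the R-squared of the log-linear fit.
#'
#' @param coverage numeric vector of fold coverages.
#' @param count positive marker counts at each coverage.
#' @return A list: `rate` (slope on the log scale), `intercept`,
#'   `r_squared`.
#' @export
fit_exponential_growth <- function(coverage, count) {
  if (length(coverage) != length(count) || length(count) < 3)
    stop("need at least 3 (coverage, count) pairs")
  if (any(count <= 0)) stop("counts must be positive")
  fit <- stats::lm(log(count) ~ coverage)
  list(rate = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

#' Per-individual genotype yield summary
#'
#' @param gm a [geno_matrix()].
#' @return A `yield_summary` list: per-sample non-missing genotype counts
#'   (`per_sample`) and their `average`, `minimum` and `maximum`.
#' @export
yield_summary <- function(gm) {
  n <- colSums(!is.na(gm$geno))
  structure(list(per_sample = n, average = mean(n),
                 minimum = min(n), maximum = max(n)),
            class = "yield_summary")
}

#' @export
print.yield_summary <- function(x, ...) {
  cat(sprintf("genotypes per individual: average %s, min %s, max %s\n",
              format(round(x$average), big.mark = ","),
              format(x$minimum, big.mark = ","),
              format(x$maximum, big.mark = ",")))
  invisible(x)
}
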