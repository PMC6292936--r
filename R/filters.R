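# The site/cell filtering stack: triallelic handling, per-cell minimum read
# depth, per-site maximum missing data, per-group minimum MAF and maximum
# heterozygosity, with an accounting report.

#' Filtering parameters
#'
#' Thresholds are inclusive on the retain side throughout: a site survives
#' with missing fraction <= `max_missing`, MAF >= `min_maf` (in at least one
#' group), heterozygosity <= `max_het`.
#'
#' @param min_depth minimum reads per cell; shallower cells are set missing
#'   (0 disables).
#' @param max_missing maximum per-site missing fraction (NA disables).
#' @param min_maf minimum minor allele frequency (NA disables). Conventional
#'   presets: 0.05 for a diversity panel, 0.01 for four-parent crosses,
#'   disabled for doubled haploids.
#' @param max_het maximum per-site heterozygote fraction among called
#'   genotypes (NA disables; used for the diversity panel, where excess
#'   heterozygosity marks paralog collapse).
#' @param maf_groups optional character/factor vector partitioning samples
#'   into subpopulations; MAF is computed per group and a site is retained
#'   if it passes in at least one group (`maf_rule = "any"`) or must pass in
#'   all (`"all"`).
#' @param triallelic_policy `"DROP_SITE"` (remove sites with more than one
#'   alternate allele, the biallelic-VCF convention), `"SET_MISSING"` (keep
#'   the site, all cells missing — the doubled-haploid convention) or
#'   `"KEEP"`.
#' @param maf_rule `"any"` or `"all"`; see `maf_groups`.
#' @return A `filter_params` list.
#' @export
filter_params <- function(min_depth = 0L, max_missing = NA, min_maf = NA,
                          max_het = NA, maf_groups = NULL,
                          triallelic_policy = "KEEP", maf_rule = "any") {
  triallelic_policy <- match.arg(triallelic_policy,
                                 c("KEEP", "DROP_SITE", "SET_MISSING"))
  maf_rule <- match.arg(maf_rule, c("any", "all"))
  if (min_depth < 0) stop("min_depth must be >= 0")
  for (v in list(max_missing, min_maf, max_het))
    if (!is.na(v) && (v < 0 || v > 1)) stop("thresholds must lie in [0, 1]")
  structure(list(min_depth = as.integer(min_depth),
                 max_missing = max_missing, min_maf = min_maf,
                 max_het = max_het, maf_groups = maf_groups,
                 triallelic_policy = triallelic_policy,
                 maf_rule = maf_rule),
            class = "filter_params")
}

#' Preset filter parameters per population class
#'
#' `"diversity-panel"`: MAF 0.05 (per subpopulation, any-group rule), missing
#' 0.5, heterozygosity 0.1, triallelics dropped. `"four-parent"`: MAF 0.01,
#' missing 0.5, no heterozygosity filter. `"doubled-haploid"`: triallelic
#' sites set missing, no MAF/missing/heterozygosity filters.
#'
#' @param preset preset name.
#' @param min_depth minimum read depth for the preset.
#' @param maf_groups optional subpopulation vector (diversity panel).
#' @return A [filter_params()].
#' @export
filter_preset <- function(preset = c("diversity-panel", "four-parent",
                                     "doubled-haploid"),
                          min_depth = 2L, maf_groups = NULL) {
  switch(match.arg(preset),
    "diversity-panel" = filter_params(min_depth, max_missing = 0.5,
                                      min_maf = 0.05, max_het = 0.1,
                                      maf_groups = maf_groups,
                                      triallelic_policy = "DROP_SITE"),
    "four-parent" = filter_params(min_depth, max_missing = 0.5,
                                  min_maf = 0.01,
                                  triallelic_policy = "DROP_SITE"),
    "doubled-haploid" = filter_params(min_depth,
                                      triallelic_policy = "SET_MISSING"))
}

#' Mask genotype cells below a minimum read depth
#'
#' Cells whose total depth (ref + alt + other) is below `d` are set missing;
#' `d = 0` is the identity.
#'
#' @param gm a [geno_matrix()]; @param adm the paired [depth_matrix()].
#' @param d minimum reads per cell.
#' @return The masked [geno_matrix()].
#' @export
mask_by_depth <- function(gm, adm, d) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(adm, "depth_matrix"))
  if (!identical(dim(gm), dim(adm)))
    stop("genotype and depth matrices must have identical dimensions")
  if (d > 0) gm$geno[total_depth(adm) < d] <- NA_integer_
  gm
}

.site_missing <- function(gm) rowMeans(is.na(gm$geno))

#' Remove sites exceeding a maximum missing-data fraction
#'
#' The missing fraction is computed over all samples (after any depth
#' masking); sites with fraction strictly greater than `max_missing` are
#' removed — a site at exactly the threshold is retained.
#'
#' @param gm a [geno_matrix()].
#' @param max_missing maximum missing fraction.
#' @return The filtered [geno_matrix()].
#' @export
filter_missing <- function(gm, max_missing = 0.5) {
  subset_sites(gm, .site_missing(gm) <= max_missing)
}

# Per-group alternate-allele frequencies among called genotypes; HET cells
# contribute one allele to each count, missing cells to neither.
.group_maf <- function(gm, groups) {
  if (is.null(groups)) groups <- rep("all", ncol(gm$geno))
  groups <- as.character(groups)
  if (length(groups) != ncol(gm$geno))
    stop("maf_groups length must equal the sample count")
  cols <- lapply(split(seq_along(groups), groups), function(idx) {
    if (!length(idx)) stop("empty MAF group")
    g <- gm$geno[, idx, drop = FALSE]
    n_called <- rowSums(!is.na(g))
    alt_alleles <- rowSums(g, na.rm = TRUE)  # codes 0/1/2 = alt dose
    p <- alt_alleles / (2 * n_called)
    pmin(p, 1 - p)  # NaN when a group has no called genotypes
  })
  do.call(cbind, cols)
}

#' Remove sites below a minimum minor allele frequency
#'
#' MAF is `min(p, 1-p)` with `p` the alternate-allele frequency among called
#' genotypes, computed per subpopulation group. A site is retained iff its
#' MAF meets `min_maf` in at least one group (`maf_rule = "any"`, default)
#' or in all groups (`"all"`); sites with no called genotypes in any group
#' are removed.
#'
#' @param gm a [geno_matrix()].
#' @param min_maf minimum MAF.
#' @param groups optional per-sample subpopulation labels.
#' @param maf_rule `"any"` or `"all"`.
#' @return The filtered [geno_matrix()].
#' @export
filter_maf <- function(gm, min_maf = 0.05, groups = NULL,
                       maf_rule = c("any", "all")) {
  maf_rule <- match.arg(maf_rule)
  maf <- .group_maf(gm, groups)
  pass <- !is.nan(maf) & maf >= min_maf
  keep <- if (maf_rule == "any") rowSums(pass) >= 1L
          else rowSums(pass) == ncol(pass)
  keep[rowSums(!is.nan(maf)) == 0L] <- FALSE
  subset_sites(gm, keep)
}

#' Remove sites with excess heterozygosity
#'
#' Sites where the heterozygote fraction among called genotypes exceeds
#' `max_het` are removed (boundary retained). Sites with no called
#' genotypes are retained (nothing to judge; the missing-data filter owns
#' them).
#'
#' @param gm a [geno_matrix()].
#' @param max_het maximum heterozygote fraction.
#' @return The filtered [geno_matrix()].
#' @export
filter_het <- function(gm, max_het = 0.1) {
  g <- gm$geno
  n_called <- rowSums(!is.na(g))
  n_het <- rowSums(g == GT_HET, na.rm = TRUE)
  frac <- ifelse(n_called > 0, n_het / n_called, 0)
  subset_sites(gm, frac <= max_het)
}

#' Handle sites with more than one alternate allele
#'
#' A site is triallelic when its VCF record carries more than one alternate
#' allele (`n_alt > 1` in the site index). Policies: `"DROP_SITE"` removes
#' the site, `"SET_MISSING"` keeps it with every cell missing, `"KEEP"` is
#' the identity.
#'
#' @param gm a [geno_matrix()].
#' @param policy triallelic policy.
#' @return The handled [geno_matrix()].
#' @export
handle_triallelic <- function(gm, policy = c("KEEP", "DROP_SITE",
                                             "SET_MISSING")) {
  policy <- match.arg(policy)
  tri <- gm$sites$n_alt > 1L
  switch(policy,
         KEEP = gm,
         DROP_SITE = subset_sites(gm, !tri),
         SET_MISSING = { gm$geno[tri, ] <- NA_integer_; gm })
}

#' Accounting report for a filtering run
#'
#' @param sites_in sites entering the pipeline.
#' @param removed named integer vector of sites removed per rule, in
#'   application order.
#' @param n_samples number of samples.
#' @param n_missing number of missing genotype cells among surviving sites.
#' @return A `filter_report` list; `total_data_points` is
#'   `sites_out * n_samples` and `residual_missing_fraction` is
#'   `n_missing / total_data_points`.
#' @export
filter_report <- function(sites_in, removed = integer(0), n_samples,
                          n_missing = 0) {
  sites_out <- sites_in - sum(removed)
  stopifnot(sites_out >= 0)
  total <- as.numeric(sites_out) * n_samples  # avoid integer overflow
  structure(list(sites_in = sites_in,
                 sites_removed_per_rule = removed,
                 sites_out = sites_out,
                 n_samples = n_samples,
                 total_data_points = total,
                 n_missing_genotypes = n_missing,
                 residual_missing_fraction =
                   if (total > 0) n_missing / total else NA_real_),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", x$sites_in, "sites in ->", x$sites_out, "out;",
      format(x$total_data_points, big.mark = ","), "data points;",
      if (!is.na(x$residual_missing_fraction))
        paste0(round(100 * x$residual_missing_fraction, 1),
               "% residual missing"), "\n")
  if (length(x$sites_removed_per_rule)) {
    cat("  removed per rule:\n")
    for (nm in names(x$sites_removed_per_rule))
      cat("   ", nm, ":", x$sites_removed_per_rule[[nm]], "\n")
  }
  invisible(x)
}

#' Apply the full filtering stack
#'
#' Order: triallelic handling, per-cell depth masking, then the site filters
#' (missing data, MAF, heterozygosity) computed on the depth-masked
#' genotypes. The pipeline is idempotent, and the surviving site count is
#' non-increasing in `min_depth`.
#'
#' @param gm a [geno_matrix()]; @param adm the paired [depth_matrix()].
#' @param params a [filter_params()].
#' @return A list: `geno` (filtered [geno_matrix()]) and `report`
#'   (a [filter_report()]).
#' @export
apply_filter_pipeline <- function(gm, adm, params) {
  stopifnot(inherits(params, "filter_params"))
  removed <- integer(0)
  n0 <- nrow(gm$geno)

  g <- handle_triallelic(gm, params$triallelic_policy)
  removed["triallelic"] <- n0 - nrow(g$geno)
  adm_f <- subset_sites(adm, site_key(adm$sites) %in% site_key(g$sites))

  g <- mask_by_depth(g, adm_f, params$min_depth)

  if (!is.na(params$max_missing)) {
    n_before <- nrow(g$geno)
    g <- filter_missing(g, params$max_missing)
    removed["missing"] <- n_before - nrow(g$geno)
  }
  if (!is.na(params$min_maf)) {
    n_before <- nrow(g$geno)
    g <- filter_maf(g, params$min_maf, params$maf_groups, params$maf_rule)
    removed["maf"] <- n_before - nrow(g$geno)
  }
  if (!is.na(params$max_het)) {
    n_before <- nrow(g$geno)
    g <- filter_het(g, params$max_het)
    removed["het"] <- n_before - nrow(g$geno)
  }
  rep <- filter_report(n0, removed, ncol(g$geno), sum(is.na(g$geno)))
  list(geno = g, report = rep)
}
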