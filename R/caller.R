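# A two-allele maximum-likelihood genotype caller over ref/alt read counts,
# standing in for a full pileup caller: list-based genotyping of known sites
# or de novo discovery of sites with variant evidence. Keeping the caller
# this transparent makes the allele-sampling arithmetic exact and testable.

#' Genotype caller parameters
#'
#' @param per_read_error probability `eps` (in \[0, 0.5)) that a read at a
#'   homozygous cell reports the other allele of the pair.
#' @param mode `"LIST_BASED"` (genotype only listed sites) or `"DE_NOVO"`
#'   (emit any site with variant evidence).
#' @param min_alt_reads_for_discovery de novo only: a site is discovered iff
#'   at least one sample shows this many alternate reads, or at least two
#'   samples show at least one. The default of 2 means a single-read error
#'   in a single sample can never create a site.
#' @return A `caller_params` list.
#' @export
caller_params <- function(per_read_error = 0.01, mode = "LIST_BASED",
                          min_alt_reads_for_discovery = 2L) {
  mode <- match.arg(mode, c("LIST_BASED", "DE_NOVO"))
  if (per_read_error < 0 || per_read_error >= 0.5)
    stop("per_read_error must be in [0, 0.5)")
  structure(list(per_read_error = per_read_error, mode = mode,
                 min_alt_reads_for_discovery =
                   as.integer(min_alt_reads_for_discovery)),
            class = "caller_params")
}

#' Call genotypes from reference/alternate read counts
#'
#' Maximum-likelihood call over {hom-ref, het, hom-alt} with per-read
#' emission model: a homozygote emits the other allele with probability
#' `eps`, a heterozygote emits each allele with probability 1/2. Zero total
#' depth is missing (NA). Exact likelihood ties break toward the homozygote
#' of the majority allele, then hom-ref. Vectorized over its inputs.
#'
#' With `eps = 0` a heterozygous truth cell covered by `k` reads is called
#' homozygous with probability `2^(1-k)` — the insufficient-allele-sampling
#' mechanism that drives skim genotyping error.
#'
#' @param ref_reads,alt_reads non-negative integer vectors (or matrices).
#' @param params a [caller_params()].
#' @return Integer genotype codes (0/1/2/NA), same shape as the input.
#' @export
call_genotype <- function(ref_reads, alt_reads, params = caller_params()) {
  eps <- params$per_read_error
  r <- ref_reads; a <- alt_reads
  if (any(r < 0, na.rm = TRUE) || any(a < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  # log-likelihoods; at eps = 0 a homozygote seeing the other allele has
  # likelihood 0 (-Inf on the log scale), handled as the exact limit
  if (eps > 0) {
    ll_rr <- r * log(1 - eps) + a * log(eps)
    ll_aa <- r * log(eps) + a * log(1 - eps)
  } else {
    ll_rr <- ifelse(a > 0, -Inf, 0)
    ll_aa <- ifelse(r > 0, -Inf, 0)
  }
  ll_het <- (r + a) * log(0.5)
  best <- pmax(ll_rr, ll_het, ll_aa)
  out <- rep(NA_integer_, length(r))
  # assign in reverse preference order so higher-priority calls overwrite:
  # het first, then the minority homozygote, then the majority homozygote
  # (majority = hom-ref when ref >= alt), implementing the tie-break.
  out[ll_het == best] <- GT_HET
  maj_ref <- r >= a
  out[!maj_ref & ll_rr == best] <- GT_HOM_REF
  out[maj_ref & ll_aa == best] <- GT_HOM_ALT
  out[maj_ref & ll_rr == best] <- GT_HOM_REF
  out[!maj_ref & ll_aa == best] <- GT_HOM_ALT
  out[r + a == 0] <- NA_integer_
  if (!is.null(dim(r))) dim(out) <- dim(r)
  out
}

#' Genotype an allele-depth matrix at listed sites
#'
#' List-based genotyping: every listed site present in the matrix is
#' genotyped in every sample via [call_genotype()]; sites absent from the
#' list are dropped. Other-allele reads are ignored by the caller (they are
#' counted by the triallelic detector in the filtering stage).
#'
#' @param adm a [depth_matrix()].
#' @param sites a [snp_list()] of sites to genotype.
#' @param params a [caller_params()] in `"LIST_BASED"` mode.
#' @return A [geno_matrix()] over `sites` intersected with the matrix rows.
#' @export
genotype_matrix <- function(adm, sites, params = caller_params()) {
  stopifnot(inherits(adm, "depth_matrix"))
  if (params$mode != "LIST_BASED")
    stop("genotype_matrix requires LIST_BASED mode; use discover_sites() ",
         "for de novo discovery")
  keep <- site_key(adm$sites) %in% site_key(sites)
  if (!any(keep) && nrow(sites) > 0 &&
      !any(sites$chrom %in% adm$sites$chrom))
    stop("no shared chromosomes between SNP list and matrix")
  sub <- subset_sites(adm, keep)
  g <- call_genotype(sub$ref, sub$alt, params)
  geno_matrix(g, sub$sites, sub$samples)
}

#' Discover variant sites de novo from an allele-depth matrix
#'
#' A site enters the discovered list iff at least one sample carries
#' `min_alt_reads_for_discovery` alternate reads, or at least two samples
#' carry at least one alternate read each.
#'
#' @param adm a [depth_matrix()].
#' @param params a [caller_params()] in `"DE_NOVO"` mode.
#' @return A [snp_list()] of discovered sites (sorted).
#' @export
discover_sites <- function(adm, params = caller_params(mode = "DE_NOVO")) {
  stopifnot(inherits(adm, "depth_matrix"))
  if (params$mode != "DE_NOVO")
    stop("discover_sites requires DE_NOVO mode")
  m <- params$min_alt_reads_for_discovery
  hit <- rowSums(adm$alt >= m) >= 1L | rowSums(adm$alt >= 1L) >= 2L
  out <- adm$sites[hit, , drop = FALSE]
  snp_list(out$chrom, out$pos, out$ref, out$alt, name = "de novo")
}
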