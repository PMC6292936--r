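# Shared fixture builders: tiny genotype/depth matrices constructed in code,
# and independent brute-force oracles for the caller and cell classifier.

toy_sites <- function(n, chrom = "chr1") {
  snp_list(rep(chrom, n), seq_len(n) * 10L,
           rep_len(c("A", "C", "G", "T"), n),
           rep_len(c("G", "T", "A", "C"), n))
}

toy_samples <- function(n, class = "DIVERSE_PANEL", subpop = "all") {
  sample_info(sprintf("S%02d", seq_len(n)), subpopulation = subpop,
              population_class = class, nominal_coverage = 1)
}

toy_gm <- function(codes, class = "DIVERSE_PANEL", subpop = "all") {
  codes <- as.matrix(codes)
  geno_matrix(codes, toy_sites(nrow(codes)),
              toy_samples(ncol(codes), class, subpop))
}

toy_adm <- function(ref, alt = NULL, other = NULL) {
  ref <- as.matrix(ref)
  if (is.null(alt)) alt <- array(0L, dim(ref))
  depth_matrix(ref, alt, other, toy_sites(nrow(ref)),
               toy_samples(ncol(ref)))
}

# uniform-depth matrix: every cell has `ref_n` ref reads and `alt_n` alt
flat_adm <- function(n_sites, n_samples, ref_n, alt_n = 0L) {
  toy_adm(matrix(ref_n, n_sites, n_samples),
          matrix(alt_n, n_sites, n_samples))
}

# Brute-force ML caller over explicit likelihoods, independent of the
# package's vectorized log-space implementation. Ties break toward the
# homozygote of the majority allele, then hom-ref.
oracle_call <- function(r, a, eps) {
  if (r + a == 0) return(NA_integer_)
  lik <- c(rr = (1 - eps)^r * eps^a,
           het = 0.5^(r + a),
           aa = eps^r * (1 - eps)^a)
  best <- names(lik)[lik == max(lik)]
  if (length(best) == 1)
    return(switch(best, rr = 0L, het = 1L, aa = 2L))
  maj <- if (r >= a) "rr" else "aa"
  if (maj %in% best) return(switch(maj, rr = 0L, aa = 2L))
  if ("rr" %in% best) return(0L)
  if ("aa" %in% best) return(2L)
  1L
}

# Exhaustive 16-pair classification oracle (codes 0/1/2/NA each side).
oracle_classify_table <- function() {
  codes <- c(0L, 1L, 2L, NA_integer_)
  out <- expand.grid(skim = codes, ref = codes)
  out$class <- apply(out, 1L, function(row) {
    s <- row[["skim"]]; r <- row[["ref"]]
    if (is.na(r)) "NOT_EVALUABLE"
    else if (is.na(s)) "MISSING_IN_SKIM"
    else if (s == r) "MATCH" else "MISMATCH"
  })
  out
}

# Truth matrix with an exact heterozygote rate mix, for closure tests.
mixed_truth <- function(n_sites, n_samples, het_rate, seed) {
  set.seed(seed)
  g <- matrix(sample(c(0L, 1L, 2L), n_sites * n_samples, replace = TRUE,
                     prob = c((1 - het_rate) / 2, het_rate,
                              (1 - het_rate) / 2)),
              n_sites, n_samples)
  toy_gm(g)
}
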