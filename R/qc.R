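#' Quality-control thresholds
#'
#' Defaults are the study's screening rules: samples need a 95% genotype
#' call rate; SNPs are excluded for minor allele frequency below 5%,
#' Hardy-Weinberg departure at p < 0.01, or missingness of 5% or more.
#' Note the asymmetry at the boundaries: MAF exactly 0.05 survives
#' (exclusion is "< 5%"), missingness exactly 0.05 does not (">= 5%").
#'
#' @param min_sample_call_rate minimum per-sample fraction of non-missing
#'   calls.
#' @param min_maf minimum minor allele frequency (computed on non-missing
#'   calls).
#' @param hwe_alpha Hardy-Weinberg exact-test exclusion level.
#' @param max_snp_missing per-SNP missingness at or above which the SNP is
#'   removed.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_sample_call_rate = 0.95, min_maf = 0.05,
                          hwe_alpha = 0.01, max_snp_missing = 0.05) {
  th <- list(min_sample_call_rate = min_sample_call_rate, min_maf = min_maf,
             hwe_alpha = hwe_alpha, max_snp_missing = max_snp_missing)
  if (any(unlist(th) <= 0 | unlist(th) >= 1))
    stop("all thresholds must lie in (0, 1)")
  structure(th, class = "qc_thresholds")
}

#' Per-sample genotype call rates
#'
#' @param g subjects x SNPs genotype matrix coded `{-1, 0, 1, 2}`.
#' @return numeric vector, fraction of non-missing calls per subject.
#' @export
sample_call_rates <- function(g) {
  if (!length(g)) stop("empty genotype matrix")
  rowMeans(g >= 0L)
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value sums the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count.
#' Monomorphic sites return p = 1 by convention (no departure is testable).
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("no genotypes")
  n_rare <- 2L * min(n_hom_ref, n_hom_alt) + n_het
  if (n_rare == 0L || n_rare == 2L * n) return(1)
  h <- seq.int(n_rare %% 2L, n_rare, by = 2L)
  h <- h[(n_rare - h) %% 2L == 0L & (2L * n - n_rare - h) >= 0L]
  logp <- lfactorial(n) - lfactorial((n_rare - h) / 2) - lfactorial(h) -
    lfactorial(n - (n_rare + h) / 2) + h * log(2) +
    lfactorial(n_rare) + lfactorial(2L * n - n_rare) - lfactorial(2L * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_het, h)]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

# per-SNP genotype counts for a coded matrix
.geno_counts <- function(g) {
  list(n0 = colSums(g == 0L), n1 = colSums(g == 1L), n2 = colSums(g == 2L),
       nm = colSums(g == -1L))
}

#' Filter SNPs on MAF, Hardy-Weinberg equilibrium and missingness
#'
#' Surviving SNPs satisfy MAF >= `min_maf`, HWE exact p >= `hwe_alpha` and
#' missingness < `max_snp_missing`; input order is preserved. Each removed
#' SNP is assigned one primary reason, checked in the order
#' maf, hwe, missingness. HWE is tested in cases and controls combined.
#'
#' @param g subjects x SNPs genotype matrix.
#' @param map SNP map aligned to the columns of `g`.
#' @param thresholds a [qc_thresholds()].
#' @return list: filtered `genotypes` and `map`, and `report` (data.frame
#'   with per-SNP `maf`, `hwe_p`, `missing`, `kept`, `reason`).
#' @export
snp_filter <- function(g, map, thresholds = qc_thresholds()) {
  stopifnot(ncol(g) == nrow(map))
  cnt <- .geno_counts(g)
  n_obs <- cnt$n0 + cnt$n1 + cnt$n2
  missing <- cnt$nm / nrow(g)
  f_alt <- ifelse(n_obs > 0, (cnt$n1 + 2 * cnt$n2) / (2 * n_obs), 0)
  maf <- pmin(f_alt, 1 - f_alt)
  hwe_p <- vapply(seq_len(ncol(g)), function(j) {
    if (n_obs[j] == 0) return(1)
    hwe_exact_test(cnt$n0[j], cnt$n1[j], cnt$n2[j])
  }, 0)
  reason <- rep(NA_character_, ncol(g))
  reason[is.na(reason) & maf < thresholds$min_maf] <- "maf"
  reason[is.na(reason) & hwe_p < thresholds$hwe_alpha] <- "hwe"
  reason[is.na(reason) & missing >= thresholds$max_snp_missing] <- "missing"
  kept <- is.na(reason)
  if (!any(kept)) stop("no SNPs survive QC; downstream scan undefined")
  report <- data.frame(id = map$id, maf = maf, hwe_p = hwe_p,
                       missing = missing, kept = kept, reason = reason,
                       stringsAsFactors = FALSE)
  list(genotypes = g[, kept, drop = FALSE],
       map = map[kept, , drop = FALSE], report = report)
}

#' Apply the full sample-then-SNP quality-control screen
#'
#' Samples are filtered first on call rate; SNP filters are then computed
#' on the surviving samples (this ordering mirrors the usual screening
#' narrative and is fixed).
#'
#' @inheritParams snp_filter
#' @param pheno optional phenotype table; returned subset to kept samples.
#' @return list: `genotypes`, `map`, `pheno`, `report` (list with
#'   `sample_call_rate` data.frame and the SNP report of [snp_filter()]).
#' @export
qc_filter <- function(g, map, pheno = NULL, thresholds = qc_thresholds()) {
  cr <- sample_call_rates(g)
  keep_s <- cr >= thresholds$min_sample_call_rate
  if (!any(keep_s)) stop("no samples survive the call-rate screen")
  sample_report <- data.frame(id = rownames(g), call_rate = cr,
                              kept = keep_s, stringsAsFactors = FALSE)
  g2 <- g[keep_s, , drop = FALSE]
  snp <- snp_filter(g2, map, thresholds)
  if (!is.null(pheno))
    pheno <- pheno[pheno$id %in% rownames(g2), , drop = FALSE]
  list(genotypes = snp$genotypes, map = snp$map, pheno = pheno,
       report = list(samples = sample_report, snps = snp$report))
}
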