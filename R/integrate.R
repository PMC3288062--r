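#' Configuration for region-expression integration
#'
#' @param flank_bp extension applied to each significant region on both
#'   sides before gene mapping (default 250 kb).
#' @param univariate_alpha significance level applied to
#'   Bonferroni-adjusted univariate p-values.
#' @param stratified_alpha significance level for the smoking-stratified
#'   per-gene screen.
#' @param ns_cutoff p-values above this are labelled not significant
#'   (`NS`) in the stratified table.
#' @return an `integration_config` list.
#' @export
integration_config <- function(flank_bp = 250000, univariate_alpha = 0.01,
                               stratified_alpha = 1e-4, ns_cutoff = 0.1) {
  stopifnot(flank_bp >= 0, univariate_alpha > 0, univariate_alpha < 1,
            stratified_alpha > 0, stratified_alpha < 1)
  structure(list(flank_bp = flank_bp, univariate_alpha = univariate_alpha,
                 stratified_alpha = stratified_alpha,
                 ns_cutoff = ns_cutoff),
            class = "integration_config")
}

#' Extend regions by a flank on both sides
#'
#' Intervals are 1-based inclusive; the extended start is clamped to 1 and
#' the end to the chromosome length when known.
#'
#' @param regions data.frame with `id`, `chrom`, `start_bp`, `end_bp`.
#' @param flank_bp flank in bp.
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return the regions with extended `start_bp`/`end_bp`.
#' @export
extend_regions <- function(regions, flank_bp = 250000,
                           chrom_lengths = NULL) {
  out <- regions
  out$start_bp <- pmax(1, regions$start_bp - flank_bp)
  end <- regions$end_bp + flank_bp
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[as.character(regions$chrom)]
    end <- ifelse(is.na(lim), end, pmin(end, lim))
  }
  out$end_bp <- end
  out
}

#' Map genes to (extended) region intervals
#'
#' A gene maps to a region when their spans overlap by at least 1 bp on
#' the same chromosome. Gene coordinates are 0-based half-open (BED);
#' intervals are 1-based inclusive. When the expression matrix is
#' supplied, mapped genes absent from it are reported separately,
#' mirroring the usual attrition between an annotation and an array.
#'
#' @param intervals data.frame with `id`, `chrom`, `start_bp`, `end_bp`.
#' @param genes gene annotation (`gene`, `chrom`, `start`, `end`).
#' @param expr optional expression matrix with gene row names.
#' @return list: `mapped` (data.frame `region`, `gene`, `on_array`),
#'   `genes_on_array`, `genes_off_array` (character vectors, unique).
#' @export
map_genes <- function(intervals, genes, expr = NULL) {
  if (!nrow(intervals) || !nrow(genes)) {
    mapped <- data.frame(region = character(), gene = character(),
                         on_array = logical(), stringsAsFactors = FALSE)
    return(list(mapped = mapped, genes_on_array = character(),
                genes_off_array = character()))
  }
  gr_reg <- GenomicRanges::GRanges(
    as.character(intervals$chrom),
    IRanges::IRanges(intervals$start_bp, intervals$end_bp))
  gr_gene <- GenomicRanges::GRanges(
    as.character(genes$chrom),
    IRanges::IRanges(genes$start + 1L, pmax(genes$end, genes$start + 1L)))
  hits <- GenomicRanges::findOverlaps(gr_reg, gr_gene)
  mapped <- data.frame(
    region = intervals$id[S4Vectors::queryHits(hits)],
    gene = genes$gene[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  on_array <- if (is.null(expr)) rep(TRUE, nrow(mapped)) else
    mapped$gene %in% rownames(expr)
  mapped$on_array <- on_array
  u <- !duplicated(mapped$gene)
  list(mapped = mapped,
       genes_on_array = mapped$gene[u & on_array],
       genes_off_array = mapped$gene[u & !on_array])
}

# z-score a numeric vector; returns NULL for zero variance
.zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(NULL)
  (x - mean(x)) / s
}

#' Univariate tumor/normal screen over mapped genes
#'
#' Per gene, a logistic regression of tumor status on the z-scored (log2)
#' expression values; the raw p-value is the Wald chi-square of the slope
#' and the Bonferroni factor is the number of genes tested. Zero-variance
#' genes are skipped with a flag.
#'
#' @param expr genes x samples expression matrix.
#' @param samples sample table with `sample` and `tumor` columns aligned
#'   to the matrix columns.
#' @param gene_list genes to test (default: all rows present).
#' @param config an [integration_config()].
#' @return data.frame: `gene`, `coef`, `or`, `p`, `p_bonferroni`,
#'   `significant`, `skipped`.
#' @export
univariate_gene_screen <- function(expr, samples,
                                   gene_list = rownames(expr),
                                   config = integration_config()) {
  gene_list <- intersect(gene_list, rownames(expr))
  y <- samples$tumor
  stopifnot(length(y) == ncol(expr), sum(y == 1) >= 2, sum(y == 0) >= 2)
  m <- length(gene_list)
  rows <- lapply(gene_list, function(gn) {
    z <- .zscore(expr[gn, ])
    if (is.null(z))
      return(data.frame(gene = gn, coef = NA_real_, or = NA_real_,
                        p = NA_real_, skipped = TRUE,
                        stringsAsFactors = FALSE))
    fit <- fit_logistic(y, cbind(1, z = z))
    w <- wald_test(fit$coef[["z"]], fit$se[["z"]])
    data.frame(gene = gn, coef = fit$coef[["z"]],
               or = exp(fit$coef[["z"]]), p = w$p, skipped = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p * m, 1)
  out$significant <- !is.na(out$p_bonferroni) &
    out$p_bonferroni < config$univariate_alpha
  rownames(out) <- NULL
  out
}

#' Smoking-stratified per-gene risk
#'
#' Within each smoking stratum (ever = former or current; never), a
#' logistic regression of tumor status on expression z-scored within the
#' stratum, so the odds ratio is per within-stratum SD. Complete
#' separation yields the conventional 0 / Inf odds-ratio sentinel with the
#' sign of the diverging coefficient; p-values above `ns_cutoff` are
#' labelled `NS`. Strata with fewer than 10 samples are flagged `low_n`.
#'
#' @param expr genes x samples expression matrix.
#' @param samples sample table with `tumor` and `smoking` columns.
#' @param gene_list genes to test.
#' @param config an [integration_config()].
#' @return data.frame, one row per gene x stratum: `gene`, `stratum`,
#'   `or`, `ci_lo`, `ci_hi`, `p`, `label`, `separation`, `low_n`.
#' @export
stratified_gene_risk <- function(expr, samples,
                                 gene_list = rownames(expr),
                                 config = integration_config()) {
  gene_list <- intersect(gene_list, rownames(expr))
  strata <- list(ever = samples$smoking >= 1L,
                 never = samples$smoking == 0L)
  zc <- stats::qnorm(0.975)
  rows <- list()
  for (snm in names(strata)) {
    sel <- strata[[snm]]
    y <- samples$tumor[sel]
    low_n <- sum(sel) < 10L
    for (gn in gene_list) {
      z <- .zscore(expr[gn, sel])
      row <- data.frame(gene = gn, stratum = snm, or = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                        label = NA_character_, separation = FALSE,
                        low_n = low_n, stringsAsFactors = FALSE)
      if (!is.null(z) && length(unique(y)) == 2L) {
        fit <- tryCatch(fit_logistic(y, cbind(1, z = z)),
                        error = function(e) NULL)
        if (!is.null(fit)) {
          b <- fit$coef[["z"]]
          if (fit$separation) {
            row$or <- if (b > 0) Inf else 0
            row$separation <- TRUE
            row$label <- if (b > 0) "Inf" else "0.00"
          } else {
            s <- fit$se[["z"]]
            w <- wald_test(b, s)
            row$or <- exp(b)
            row$ci_lo <- exp(b - zc * s); row$ci_hi <- exp(b + zc * s)
            row$p <- w$p
            row$label <- if (!is.na(w$p) && w$p > config$ns_cutoff) "NS"
              else format(round(exp(b), 2), nsmall = 2)
          }
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bi-clustering of an expression submatrix
#'
#' Rows (genes) are standardized to mean 0 / SD 1; genes and samples are
#' then clustered agglomeratively with average linkage on a
#' 1 - Pearson-correlation distance. Orderings are deterministic (hclust
#' leaf order, ties broken by input index).
#'
#' @param expr genes x samples matrix (>= 2 genes, >= 2 samples).
#' @return list: `gene_order`, `sample_order` (permutations),
#'   `gene_heights`, `sample_heights` (non-decreasing merge heights),
#'   `standardized` matrix, and the two `hclust` trees.
#' @export
hierarchical_cluster <- function(expr) {
  stopifnot(nrow(expr) >= 2, ncol(expr) >= 2)
  sds <- apply(expr, 1, stats::sd)
  if (any(!is.finite(sds) | sds == 0))
    stop("constant expression row(s): ",
         paste(rownames(expr)[!is.finite(sds) | sds == 0], collapse = ", "))
  z <- t(scale(t(expr)))
  gene_d <- stats::as.dist(1 - stats::cor(t(z)))
  sample_d <- stats::as.dist(1 - stats::cor(z))
  gene_h <- stats::hclust(gene_d, method = "average")
  sample_h <- stats::hclust(sample_d, method = "average")
  list(gene_order = gene_h$order, sample_order = sample_h$order,
       gene_heights = gene_h$height, sample_heights = sample_h$height,
       standardized = z, gene_tree = gene_h, sample_tree = sample_h)
}
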