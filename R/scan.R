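#' Parameters for the tract-of-homozygosity scan
#'
#' The default detection floor of 100 homozygous calls matches the
#' consensus-region rule downstream (10 subjects sharing 100 calls) and the
#' observed first quartile of ~108 SNPs per tract in array-scale catalogs.
#' By default no heterozygous call is tolerated inside a run, and missing
#' calls are tolerated up to 2% of the spanned SNPs (they do not count
#' toward the homozygous-call total).
#'
#' @param min_snps minimum homozygous calls per tract (>= 2).
#' @param max_het_in_run heterozygous calls tolerated inside a run.
#' @param max_missing_fraction_in_run missing fraction tolerated, relative
#'   to spanned SNPs.
#' @param min_length_bp minimum tract length in bp (0 disables).
#' @return a `scan_params` list.
#' @export
scan_params <- function(min_snps = 100L, max_het_in_run = 0L,
                        max_missing_fraction_in_run = 0.02,
                        min_length_bp = 0) {
  stopifnot(min_snps >= 2, max_het_in_run >= 0,
            max_missing_fraction_in_run >= 0,
            max_missing_fraction_in_run < 1, min_length_bp >= 0)
  structure(list(min_snps = as.integer(min_snps),
                 max_het_in_run = as.integer(max_het_in_run),
                 max_missing_fraction_in_run = max_missing_fraction_in_run,
                 min_length_bp = min_length_bp),
            class = "scan_params")
}

# greedy scan of one het-free stretch [s, e] (all calls hom or missing);
# returns matrix with columns start, end, n_hom, n_miss
.scan_stretch <- function(calls, s, e, params) {
  idx <- s:e
  is_miss <- calls[idx] < 0L
  hompos <- idx[!is_miss]
  if (!length(hompos)) return(NULL)
  cap <- params$max_missing_fraction_in_run
  # trimmed stretch passes the cap as a whole -> single maximal run
  st0 <- hompos[1]; en0 <- hompos[length(hompos)]
  span0 <- en0 - st0 + 1L
  nm0 <- span0 - length(hompos)
  out <- NULL
  if (nm0 <= cap * span0) {
    if (length(hompos) >= params$min_snps)
      out <- matrix(c(st0, en0, length(hompos), nm0), 1)
    return(out)
  }
  # cap binds: greedy left-to-right over sub-windows
  miss_cum <- c(0L, cumsum(as.integer(is_miss)))
  nh <- length(hompos)
  cur <- 1L
  segs <- list()
  while (cur <= nh) {
    st <- hompos[cur]
    cand <- hompos[cur:nh]
    span <- cand - st + 1L
    nmiss <- miss_cum[cand - s + 2L] - miss_cum[st - s + 1L]
    ok <- nmiss <= cap * span
    en <- max(cand[ok])  # st itself is always ok (0 missing)
    k <- which(cand == en)
    n_hom <- k  # homozygous calls between cur and cur+k-1
    if (n_hom >= params$min_snps) {
      segs[[length(segs) + 1L]] <- c(st, en, n_hom, nmiss[k])
      cur <- cur + k
    } else {
      cur <- cur + 1L
    }
  }
  if (length(segs)) do.call(rbind, segs) else NULL
}

#' Scan one subject's chromosome for tracts of homozygosity
#'
#' Finds maximal runs in which every non-missing call is homozygous (up to
#' `max_het_in_run` heterozygous exceptions), the spanned missing fraction
#' is at most `max_missing_fraction_in_run`, and at least `min_snps`
#' homozygous calls are present. Runs begin and end on homozygous calls.
#' Construction is greedy left to right: from the leftmost usable
#' homozygous call the run is extended as far right as the constraints
#' allow, emitted, and the scan resumes after it; per-subject runs are
#' therefore disjoint and the output is deterministic.
#'
#' @param calls integer vector coded `{-1, 0, 1, 2}` for one chromosome, in
#'   map order.
#' @param params a [scan_params()].
#' @return data.frame with 1-based inclusive `start_snp`, `end_snp`,
#'   homozygous-call count `n_snps` and `n_missing` per run (zero rows if
#'   none).
#' @export
scan_subject_chromosome <- function(calls, params = scan_params()) {
  m <- .scan_calls(calls, params)
  if (is.null(m))
    return(data.frame(start_snp = integer(), end_snp = integer(),
                      n_snps = integer(), n_missing = integer()))
  data.frame(start_snp = m[, 1], end_snp = m[, 2], n_snps = m[, 3],
             n_missing = m[, 4])
}

# matrix-valued core of the per-chromosome scan (NULL when no runs)
.scan_calls <- function(calls, params) {
  n <- length(calls)
  if (n == 0) return(NULL)
  if (params$max_het_in_run == 0L) {
    het <- which(calls == 1L)
    ss <- c(1L, het + 1L)
    ee <- c(het - 1L, n)
    long <- which(ee - ss + 1L >= params$min_snps)
    if (!length(long)) return(NULL)
    segs <- list()
    for (i in long) {
      r <- .scan_stretch(calls, ss[i], ee[i], params)
      if (!is.null(r)) segs[[length(segs) + 1L]] <- r
    }
    if (!length(segs)) return(NULL)
    do.call(rbind, segs)
  } else {
    .scan_het_tolerant(calls, params)
  }
}

# general greedy scan allowing up to max_het_in_run heterozygous calls
.scan_het_tolerant <- function(calls, params) {
  n <- length(calls)
  hom <- calls == 0L | calls == 2L
  hompos <- which(hom)
  if (!length(hompos)) return(NULL)
  het_cum <- c(0L, cumsum(calls == 1L))
  miss_cum <- c(0L, cumsum(calls < 0L))
  hom_cum <- c(0L, cumsum(hom))
  cap <- params$max_missing_fraction_in_run
  segs <- list()
  cur <- 1L; nh <- length(hompos)
  while (cur <= nh) {
    st <- hompos[cur]
    cand <- hompos[cur:nh]
    n_het <- het_cum[cand + 1L] - het_cum[st]
    cand <- cand[n_het <= params$max_het_in_run]
    span <- cand - st + 1L
    nmiss <- miss_cum[cand + 1L] - miss_cum[st]
    ok <- nmiss <= cap * span
    if (any(ok)) {
      en <- max(cand[ok])
      n_hom <- hom_cum[en + 1L] - hom_cum[st]
      if (n_hom >= params$min_snps) {
        segs[[length(segs) + 1L]] <-
          c(st, en, n_hom, miss_cum[en + 1L] - miss_cum[st])
        cur <- which(hompos > en)[1]
        if (is.na(cur)) break
        next
      }
    }
    cur <- cur + 1L
  }
  if (length(segs)) do.call(rbind, segs) else NULL
}

#' Scan a cohort for tracts of homozygosity
#'
#' Runs [scan_subject_chromosome()] per subject and chromosome and
#' assembles the catalog with bp spans and boundary SNP ids taken from the
#' map. Deterministic for fixed input.
#'
#' @param g subjects x SNPs genotype matrix (QC-passed).
#' @param map SNP map aligned to `g`'s columns.
#' @param params a [scan_params()].
#' @return a `toh_catalog` data.frame: `subject`, `chrom`, `start_snp`,
#'   `end_snp` (1-based within chromosome), `start_bp`, `end_bp`,
#'   `start_rs`, `end_rs`, `n_snps`, `n_missing`, `length_bp`.
#' @export
scan_cohort <- function(g, map, params = scan_params()) {
  stopifnot(ncol(g) == nrow(map))
  subjects <- rownames(g)
  if (is.null(subjects)) subjects <- as.character(seq_len(nrow(g)))
  chroms <- unique(map$chrom)
  seg_mats <- list()
  seg_subj <- list()
  seg_chrom <- list()
  for (ch in chroms) {
    cols <- which(map$chrom == ch)
    sub <- g[, cols, drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      m <- .scan_calls(sub[i, ], params)
      if (is.null(m)) next
      k <- length(seg_mats) + 1L
      seg_mats[[k]] <- m
      seg_subj[[k]] <- rep(subjects[i], nrow(m))
      seg_chrom[[k]] <- rep(ch, nrow(m))
    }
  }
  if (length(seg_mats)) {
    m <- do.call(rbind, seg_mats)
    ch_all <- unlist(seg_chrom)
    cols_of <- lapply(setNames(chroms, chroms),
                      function(ch) which(map$chrom == ch))
    glob <- vapply(seq_len(nrow(m)),
                   function(i) cols_of[[ch_all[i]]][1] - 1L, 0L)
    cat <- data.frame(
      subject = unlist(seg_subj), chrom = ch_all,
      start_snp = m[, 1], end_snp = m[, 2],
      start_bp = map$pos[glob + m[, 1]], end_bp = map$pos[glob + m[, 2]],
      start_rs = map$id[glob + m[, 1]], end_rs = map$id[glob + m[, 2]],
      n_snps = m[, 3], n_missing = m[, 4], stringsAsFactors = FALSE)
    cat$length_bp <- cat$end_bp - cat$start_bp + 1L
    if (params$min_length_bp > 0)
      cat <- cat[cat$length_bp >= params$min_length_bp, , drop = FALSE]
    cat <- cat[, c("subject", "chrom", "start_snp", "end_snp", "start_bp",
                   "end_bp", "start_rs", "end_rs", "n_snps", "n_missing",
                   "length_bp")]
  } else {
    cat <- data.frame(subject = character(), chrom = character(),
                      start_snp = integer(), end_snp = integer(),
                      start_bp = integer(), end_bp = integer(),
                      start_rs = character(), end_rs = character(),
                      n_snps = integer(), n_missing = integer(),
                      length_bp = integer(), stringsAsFactors = FALSE)
  }
  rownames(cat) <- NULL
  structure(cat, class = c("toh_catalog", "data.frame"),
            n_subjects = nrow(g), subjects = subjects)
}

#' Summarize a tract catalog
#'
#' Mean, median and quartiles (linear-interpolation quantiles) of tract
#' length in bp and of homozygous-call counts, plus tract counts by case
#' status when phenotypes are supplied.
#'
#' @param cat a `toh_catalog` from [scan_cohort()].
#' @param pheno optional phenotype table with `id` and `case`.
#' @return list of summary statistics; for an empty catalog a sentinel list
#'   with `empty = TRUE` and `n_tracts = 0`.
#' @export
catalog_summary <- function(cat, pheno = NULL) {
  if (!nrow(cat)) return(list(empty = TRUE, n_tracts = 0L))
  qs <- function(x) c(mean = mean(x), median = stats::median(x),
                      q1 = unname(stats::quantile(x, 0.25)),
                      q3 = unname(stats::quantile(x, 0.75)))
  out <- list(empty = FALSE, n_tracts = nrow(cat),
              length_bp = qs(cat$length_bp), n_snps = qs(cat$n_snps))
  if (!is.null(pheno)) {
    case <- pheno$case[match(cat$subject, pheno$id)]
    out$n_tracts_cases <- sum(case == 1L, na.rm = TRUE)
    out$n_tracts_controls <- sum(case == 0L, na.rm = TRUE)
  }
  out
}
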