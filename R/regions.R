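#' Parameters for consensus-region and allelic-match calling
#'
#' Defaults are the operational rules of the method: a consensus region
#' (cTOH) requires 10 or more subjects sharing 100 consecutive homozygous
#' calls; two carrier segments match allelically when at least 0.95 of
#' their jointly non-missing, jointly homozygous sites carry identical
#' genotypes; and allelic subgroups (aTOH) are retained for association
#' only when present in at least 5 cases and 5 controls.
#'
#' @param min_carriers minimum subjects covering every SNP of a region.
#' @param min_shared_snps minimum consecutive SNPs per region; also the
#'   overlap (in SNPs) a tract needs to count a subject as a region
#'   carrier.
#' @param allelic_match_threshold inclusive identity fraction for a match.
#' @param min_cases_per_atoh,min_controls_per_atoh retention floors.
#' @return a `consensus_params` list.
#' @export
consensus_params <- function(min_carriers = 10L, min_shared_snps = 100L,
                             allelic_match_threshold = 0.95,
                             min_cases_per_atoh = 5L,
                             min_controls_per_atoh = 5L) {
  stopifnot(min_carriers >= 2, min_shared_snps >= 1,
            allelic_match_threshold > 0, allelic_match_threshold <= 1)
  structure(list(min_carriers = as.integer(min_carriers),
                 min_shared_snps = as.integer(min_shared_snps),
                 allelic_match_threshold = allelic_match_threshold,
                 min_cases_per_atoh = as.integer(min_cases_per_atoh),
                 min_controls_per_atoh = as.integer(min_controls_per_atoh)),
            class = "consensus_params")
}

#' Per-SNP carrier counts from a tract catalog
#'
#' For every SNP of the map, the number of subjects whose tract spans it.
#'
#' @param cat a `toh_catalog` from [scan_cohort()].
#' @param map the SNP map the catalog was built on.
#' @return integer vector aligned to the rows of `map`.
#' @export
snp_carrier_counts <- function(cat, map) {
  counts <- integer(nrow(map))
  if (!nrow(cat)) return(counts)
  for (ch in unique(cat$chrom)) {
    cols <- which(map$chrom == ch)
    n <- length(cols)
    seg <- cat[cat$chrom == ch, , drop = FALSE]
    d <- integer(n + 1L)
    for (i in seq_len(nrow(seg))) {
      d[seg$start_snp[i]] <- d[seg$start_snp[i]] + 1L
      d[seg$end_snp[i] + 1L] <- d[seg$end_snp[i] + 1L] - 1L
    }
    counts[cols] <- cumsum(d[seq_len(n)])
  }
  counts
}

#' Call consensus (cTOH) regions from carrier counts
#'
#' A region is a maximal run of at least `min_shared_snps` consecutive SNPs
#' each covered by at least `min_carriers` tracts. A subject is a region
#' carrier when one of its tracts overlaps the region span by at least
#' `min_shared_snps` SNPs. Regions are ordered and numbered by
#' (chromosome, start).
#'
#' @param counts per-SNP carrier counts from [snp_carrier_counts()].
#' @param cat the `toh_catalog` the counts came from.
#' @param map the SNP map.
#' @param params a [consensus_params()].
#' @return a `ctoh_regions` data.frame: `id`, `chrom`, `start_snp`,
#'   `end_snp` (1-based inclusive within chromosome), `start_bp`, `end_bp`,
#'   `start_rs`, `end_rs`, `n_snps`, `length_bp`, `n_carriers` and a list
#'   column `carriers` of subject ids.
#' @export
call_ctoh_regions <- function(counts, cat, map,
                              params = consensus_params()) {
  regions <- list()
  for (ch in unique(map$chrom)) {
    cols <- which(map$chrom == ch)
    cc <- counts[cols]
    r <- rle(cc >= params$min_carriers)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- r$values & r$lengths >= params$min_shared_snps
    if (!any(ok)) next
    seg <- cat[cat$chrom == ch, , drop = FALSE]
    for (k in which(ok)) {
      s <- starts[k]; e <- ends[k]
      ov <- pmin(seg$end_snp, e) - pmax(seg$start_snp, s) + 1L
      hit <- seg[ov >= params$min_shared_snps, , drop = FALSE]
      carriers <- unique(hit$subject)
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch, start_snp = s, end_snp = e,
        start_bp = map$pos[cols[s]], end_bp = map$pos[cols[e]],
        start_rs = map$id[cols[s]], end_rs = map$id[cols[e]],
        n_snps = e - s + 1L,
        length_bp = map$pos[cols[e]] - map$pos[cols[s]] + 1L,
        n_carriers = length(carriers), stringsAsFactors = FALSE)
      regions[[length(regions)]]$carriers <- I(list(carriers))
    }
  }
  if (!length(regions)) {
    out <- data.frame(id = character(), chrom = character(),
                      start_snp = integer(), end_snp = integer(),
                      start_bp = integer(), end_bp = integer(),
                      start_rs = character(), end_rs = character(),
                      n_snps = integer(), length_bp = integer(),
                      n_carriers = integer(), stringsAsFactors = FALSE)
    out$carriers <- I(list())
    return(structure(out, class = c("ctoh_regions", "data.frame")))
  }
  out <- do.call(rbind, regions)
  ord <- order(suppressWarnings(as.integer(out$chrom)), out$chrom,
               out$start_snp, na.last = FALSE)
  out <- out[ord, , drop = FALSE]
  out <- cbind(data.frame(id = paste0("cTOH", seq_len(nrow(out))),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  structure(out, class = c("ctoh_regions", "data.frame"))
}

#' Binary subject-by-region carrier matrix
#'
#' @param regions a `ctoh_regions` or `atoh_groups` data.frame with a
#'   `carriers` list column and `id` column.
#' @param subjects character vector of all subject ids (row order).
#' @return integer 0/1 matrix, subjects x regions.
#' @export
carrier_matrix <- function(regions, subjects) {
  m <- matrix(0L, length(subjects), nrow(regions),
              dimnames = list(subjects, regions$id))
  for (j in seq_len(nrow(regions)))
    m[match(regions$carriers[[j]], subjects), j] <- 1L
  m
}

#' Allelic match between two carrier segments
#'
#' Over the SNPs of `cols` where both subjects are non-missing and both
#' homozygous, counts identical genotype codes. A match is declared when
#' the identical fraction reaches `threshold` (inclusive). With no joint
#' sites the fraction is undefined (`NaN`) and the pair does not match.
#'
#' @param g genotype matrix.
#' @param subj_a,subj_b subject ids (row names of `g`).
#' @param cols column indices of the comparison span.
#' @param threshold inclusive match threshold.
#' @return list: `n_joint`, `n_identical`, `fraction`, `is_match`.
#' @export
allelic_match <- function(g, subj_a, subj_b, cols, threshold = 0.95) {
  a <- g[subj_a, cols]
  b <- g[subj_b, cols]
  joint <- (a == 0L | a == 2L) & (b == 0L | b == 2L)
  n_joint <- sum(joint)
  n_id <- sum(a[joint] == b[joint])
  frac <- if (n_joint > 0) n_id / n_joint else NaN
  list(n_joint = n_joint, n_identical = n_id, fraction = frac,
       is_match = isTRUE(n_joint > 0 && frac >= threshold))
}

#' Partition a region's carrier segments into allelic (aTOH) groups
#'
#' All carrier segments of a consensus region are compared pairwise with
#' [allelic_match()] over the intersection of the region span with both
#' segments; single-linkage connected components of the resulting match
#' graph form the allelic groups (mirroring segment-pool allelic matching).
#' Groups partition the carriers and are ordered by their smallest member
#' subject id.
#'
#' @param region one row of a `ctoh_regions` data.frame.
#' @param cat the `toh_catalog`.
#' @param g genotype matrix.
#' @param map SNP map.
#' @param params a [consensus_params()].
#' @return an `atoh_groups` data.frame: `id`, `parent`, `chrom`,
#'   `start_snp`, `end_snp`, `start_bp`, `end_bp`, `start_rs`, `end_rs`,
#'   `n_snps`, `n_carriers` plus a `carriers` list column. The consensus
#'   span is the intersection of member segment spans with the region.
#' @export
group_atohs <- function(region, cat, g, map, params = consensus_params()) {
  stopifnot(nrow(region) == 1)
  cols_chrom <- which(map$chrom == region$chrom)
  seg <- cat[cat$chrom == region$chrom, , drop = FALSE]
  ov <- pmin(seg$end_snp, region$end_snp) -
    pmax(seg$start_snp, region$start_snp) + 1L
  seg <- seg[ov >= params$min_shared_snps, , drop = FALSE]
  # one segment per carrier: the one overlapping the region most
  seg <- seg[order(seg$subject, -(pmin(seg$end_snp, region$end_snp) -
                                    pmax(seg$start_snp, region$start_snp))), ]
  seg <- seg[!duplicated(seg$subject), , drop = FALSE]
  seg <- seg[order(seg$subject), , drop = FALSE]
  nseg <- nrow(seg)
  if (nseg == 0)
    return(.empty_atoh_groups())
  edges <- list()
  if (nseg > 1) {
    for (i in seq_len(nseg - 1L)) {
      for (j in seq.int(i + 1L, nseg)) {
        s <- max(region$start_snp, seg$start_snp[i], seg$start_snp[j])
        e <- min(region$end_snp, seg$end_snp[i], seg$end_snp[j])
        if (s > e) next
        mr <- allelic_match(g, seg$subject[i], seg$subject[j],
                            cols_chrom[s:e],
                            params$allelic_match_threshold)
        if (mr$is_match)
          edges[[length(edges) + 1L]] <- c(i, j)
      }
    }
  }
  gr <- igraph::make_empty_graph(n = nseg, directed = FALSE)
  if (length(edges))
    gr <- igraph::add_edges(gr, unlist(edges))
  comp <- igraph::components(gr)$membership
  groups <- split(seq_len(nseg), comp)
  # deterministic order: by smallest member subject id
  first_subj <- vapply(groups, function(ix) min(seg$subject[ix]), "")
  groups <- groups[order(first_subj)]
  out <- lapply(seq_along(groups), function(k) {
    ix <- groups[[k]]
    s <- max(region$start_snp, max(seg$start_snp[ix]))
    e <- min(region$end_snp, min(seg$end_snp[ix]))
    if (s > e) { s <- region$start_snp; e <- region$end_snp }
    d <- data.frame(id = paste0(region$id, ".aTOH", k), parent = region$id,
                    chrom = region$chrom, start_snp = s, end_snp = e,
                    start_bp = map$pos[cols_chrom[s]],
                    end_bp = map$pos[cols_chrom[e]],
                    start_rs = map$id[cols_chrom[s]],
                    end_rs = map$id[cols_chrom[e]],
                    n_snps = e - s + 1L, n_carriers = length(ix),
                    stringsAsFactors = FALSE)
    d$carriers <- I(list(seg$subject[ix]))
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, class = c("atoh_groups", "data.frame"))
}

.empty_atoh_groups <- function() {
  out <- data.frame(id = character(), parent = character(),
                    chrom = character(), start_snp = integer(),
                    end_snp = integer(), start_bp = integer(),
                    end_bp = integer(), start_rs = character(),
                    end_rs = character(), n_snps = integer(),
                    n_carriers = integer(), stringsAsFactors = FALSE)
  out$carriers <- I(list())
  structure(out, class = c("atoh_groups", "data.frame"))
}

#' Retain allelic groups present in enough cases and controls
#'
#' Keeps groups carried by at least `min_cases_per_atoh` cases and
#' `min_controls_per_atoh` controls (inclusive), and records the counts.
#'
#' @param groups an `atoh_groups` data.frame.
#' @param pheno phenotype table with `id` and `case`.
#' @param params a [consensus_params()].
#' @return the retained groups with `n_cases` and `n_controls` columns.
#' @export
filter_atohs <- function(groups, pheno, params = consensus_params()) {
  if (!nrow(groups)) {
    groups$n_cases <- integer(0); groups$n_controls <- integer(0)
    return(groups)
  }
  n_cases <- vapply(groups$carriers, function(s)
    sum(pheno$case[match(s, pheno$id)] == 1L), 0L)
  n_controls <- vapply(groups$carriers, function(s)
    sum(pheno$case[match(s, pheno$id)] == 0L), 0L)
  groups$n_cases <- n_cases
  groups$n_controls <- n_controls
  keep <- n_cases >= params$min_cases_per_atoh &
    n_controls >= params$min_controls_per_atoh
  out <- groups[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
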