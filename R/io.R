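#' Write genotypes to PLINK text format (.ped/.map)
#'
#' Alleles are written from the map's `a1`/`a2` columns: code 0 becomes
#' `a1 a1`, 1 becomes `a1 a2`, 2 becomes `a2 a2` and missing (-1) the PLINK
#' convention `0 0`. The `.map` file has the standard four columns
#' (chromosome, id, genetic distance = 0, 1-based bp position).
#'
#' @param g subjects x SNPs integer matrix coded `{-1, 0, 1, 2}`.
#' @param map SNP map data.frame with `id`, `chrom`, `pos`, `a1`, `a2`.
#' @param prefix output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @param pheno optional phenotype data.frame (`id`, `case`, `sex`);
#'   used for the ped sex/phenotype columns (PLINK coding: phenotype
#'   1 = control, 2 = case).
#' @return `prefix`, invisibly.
#' @export
write_plink_text <- function(g, map, prefix, pheno = NULL) {
  stopifnot(ncol(g) == nrow(map))
  ids <- rownames(g)
  if (is.null(ids)) ids <- sprintf("S%05d", seq_len(nrow(g)))
  sex <- rep(0L, nrow(g)); phe <- rep(-9L, nrow(g))
  if (!is.null(pheno)) {
    i <- match(ids, pheno$id)
    if ("sex" %in% names(pheno)) sex <- pheno$sex[i]
    if ("case" %in% names(pheno)) phe <- pheno$case[i] + 1L
  }
  m <- nrow(map)
  allele_str <- matrix("", nrow(g), m)
  for (code in c(-1L, 0L, 1L, 2L)) {
    idx <- which(g == code, arr.ind = TRUE)
    if (!nrow(idx)) next
    str <- switch(as.character(code),
                  "-1" = rep("0 0", nrow(idx)),
                  "0" = paste(map$a1[idx[, 2]], map$a1[idx[, 2]]),
                  "1" = paste(map$a1[idx[, 2]], map$a2[idx[, 2]]),
                  "2" = paste(map$a2[idx[, 2]], map$a2[idx[, 2]]))
    allele_str[idx] <- str
  }
  ped <- cbind(ids, ids, 0L, 0L, sex, phe, allele_str)
  data.table::fwrite(data.table::as.data.table(ped),
                     paste0(prefix, ".ped"), sep = " ", col.names = FALSE,
                     quote = FALSE)
  data.table::fwrite(data.table::data.table(map$chrom, map$id, 0L, map$pos),
                     paste0(prefix, ".map"), sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(prefix)
}

#' Read PLINK text genotypes (.ped/.map)
#'
#' Genotype allele pairs are recoded to alternate-allele counts
#' `{0, 1, 2}` with `-1` for the PLINK missing pair `0 0`. The allele order
#' is taken from `alleles` when supplied (exact inverse of
#' [write_plink_text()]); otherwise the alternate allele at each SNP is
#' inferred as the minor (less frequent) observed allele, ties broken
#' alphabetically.
#'
#' @param ped_path,map_path input files.
#' @param alleles optional data.frame/matrix with per-SNP `a1`, `a2`.
#' @return list: `genotypes` (subjects x SNPs integer matrix), `map`
#'   (data.frame `id`, `chrom`, `pos`, `a1`, `a2`), `subjects` (ids).
#' @export
read_plink_text <- function(ped_path, map_path, alleles = NULL) {
  if (!file.exists(ped_path)) stop("ped file not found: ", ped_path)
  if (!file.exists(map_path)) stop("map file not found: ", map_path)
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  names(map) <- c("chrom", "id", "cm", "pos")
  if (anyDuplicated(map$id))
    stop("duplicate SNP ids in map: line ",
         which(duplicated(map$id))[1])
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      bad <- which(map$chrom == ch)[which(diff(p) <= 0)[1] + 1L]
      stop("map not strictly sorted by position: line ", bad)
    }
  }
  m <- nrow(map)
  nf <- utils::count.fields(ped_path)
  expected <- 6L + 2L * m
  if (any(nf != expected))
    stop("ragged ped row: line ", which(nf != expected)[1],
         " has ", nf[nf != expected][1], " fields, expected ", expected)
  ped <- data.table::fread(ped_path, header = FALSE, colClasses = "character",
                           sep = " ", data.table = FALSE)
  if (ncol(ped) == 1L)  # single-space detection failed; fall back
    ped <- utils::read.table(ped_path, header = FALSE,
                             colClasses = "character")
  subjects <- ped[[2]]
  a_mat <- as.matrix(ped[, -(1:6), drop = FALSE])
  n <- nrow(a_mat)
  al1 <- a_mat[, seq(1, 2 * m, by = 2), drop = FALSE]
  al2 <- a_mat[, seq(2, 2 * m, by = 2), drop = FALSE]
  if (is.null(alleles)) {
    ref <- character(m); alt <- character(m)
    for (j in seq_len(m)) {
      obs <- c(al1[, j], al2[, j])
      obs <- obs[obs != "0"]
      tab <- sort(table(obs), decreasing = TRUE)
      u <- names(tab)
      if (length(u) > 2)
        stop("more than two alleles at SNP ", map$id[j], ": ",
             paste(u, collapse = "/"))
      if (length(u) == 0) u <- c("0", "0")
      if (length(u) == 1) u <- c(u, u)
      if (tab[1] == tab[length(tab)]) u <- sort(u)  # tie: alphabetical
      ref[j] <- u[1]; alt[j] <- u[2]
    }
  } else {
    ref <- as.character(alleles[[1]]); alt <- as.character(alleles[[2]])
  }
  refm <- matrix(ref, n, m, byrow = TRUE)
  altm <- matrix(alt, n, m, byrow = TRUE)
  known <- (al1 == refm | al1 == altm) & (al2 == refm | al2 == altm)
  miss <- al1 == "0" | al2 == "0"
  if (any(!known & !miss)) {
    bad <- which(!known & !miss, arr.ind = TRUE)[1, ]
    stop("unknown allele at ped line ", bad[1], ", SNP ", map$id[bad[2]])
  }
  g <- (al1 == altm) + (al2 == altm)
  g[miss] <- -1L
  storage.mode(g) <- "integer"
  dimnames(g) <- list(subjects, map$id)
  out_map <- data.frame(id = map$id, chrom = map$chrom, pos = map$pos,
                        a1 = ref, a2 = alt, stringsAsFactors = FALSE)
  list(genotypes = g, map = out_map, subjects = subjects)
}

#' Read diploid genotypes from a VCF file
#'
#' Bi-allelic records are recoded from the GT field: `0/0` to 0, `0/1` or
#' `1/0` to 1, `1/1` to 2 and `./.` to -1; phase separators (`|`) are
#' ignored since homozygosity is phase-invariant. Multi-allelic records are
#' skipped (with a message) when `skip_multiallelic = TRUE`, otherwise they
#' raise an error.
#'
#' @param path VCF file (plain or bgzipped).
#' @param skip_multiallelic drop records with more than one ALT allele.
#' @return list: `genotypes`, `map`, `subjects` as in [read_plink_text()].
#' @export
read_vcf <- function(path, skip_multiallelic = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    if (!skip_multiallelic)
      stop(sum(multi), " multi-allelic record(s); ",
           "set skip_multiallelic = TRUE to drop them")
    message("skipping ", sum(multi), " multi-allelic record(s)")
  }
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  gt_clean <- gsub("\\|", "/", gt)
  code_one <- function(x) {
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0")] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% c("1/1")] <- 2L
    out[is.na(x) | x %in% c("./.", ".")] <- -1L
    out
  }
  g <- apply(gt_clean, 2, code_one)
  if (is.null(dim(g))) g <- matrix(g, nrow = 1)
  if (anyNA(g)) {
    bad <- which(is.na(g), arr.ind = TRUE)[1, ]
    stop("malformed GT '", gt_clean[bad[1], bad[2]], "' at record ",
         fix$ID[bad[1]])
  }
  g <- t(g)
  storage.mode(g) <- "integer"
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[
    is.na(ids) | ids == "."]
  dimnames(g) <- list(colnames(gt), ids)
  map <- data.frame(id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                    a1 = fix$REF, a2 = fix$ALT, stringsAsFactors = FALSE)
  list(genotypes = g, map = map, subjects = colnames(gt))
}

#' Write regions to a BED file
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open, so a region spanning bp 1001..2000 is written as
#' `chrom 1000 2000`. The score column is `-log10(p)` clamped to
#' `[0, 1000]` (0 when no p-value is available).
#'
#' @param regions data.frame with `chrom`, `start_bp`, `end_bp`, `id` and
#'   optionally `p`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tscore", con)
  if (nrow(regions)) {
    score <- if ("p" %in% names(regions) && !all(is.na(regions$p)))
      pmin(pmax(-log10(pmax(regions$p, 1e-1000)), 0), 1000) else
        rep(0, nrow(regions))
    score[is.na(score)] <- 0
    lines <- sprintf("%s\t%d\t%d\t%s\t%g", regions$chrom,
                     as.integer(regions$start_bp) - 1L,
                     as.integer(regions$end_bp), regions$id, score)
    writeLines(lines, con)
  }
  invisible(path)
}
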