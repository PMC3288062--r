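make_pheno <- function(subjects, n_cases) {
  data.frame(id = subjects,
             case = rep(c(1L, 0L), c(n_cases, length(subjects) - n_cases)),
             age_cat = 1L, sex = 1L, smoking = 0L,
             stringsAsFactors = FALSE)
}

test_that("carrier counts match planted coverage", {
  fix <- planted_block_cohort(n_subjects = 40, n_snps_total = 500,
                              carriers = 1:12, start = 201, n_snps = 120)
  cat1 <- scan_cohort(fix$g, fix$map, scan_params())
  counts <- snp_carrier_counts(cat1, fix$map)
  expect_equal(length(counts), 500L)
  expect_true(all(counts[201:320] == 12L))
  expect_true(all(counts[-(201:320)] == 0L))
  expect_true(all(counts <= 40L))
  # empty catalog -> all zero
  empty <- cat1[0, ]
  expect_true(all(snp_carrier_counts(empty, fix$map) == 0L))
})

test_that("consensus calling enforces both sharing thresholds exactly", {
  run_case <- function(n_carriers, n_snps) {
    fix <- planted_block_cohort(n_subjects = 30, n_snps_total = 400,
                                carriers = seq_len(n_carriers),
                                start = 101, n_snps = n_snps)
    p_scan <- scan_params(min_snps = min(100L, n_snps))
    cat1 <- scan_cohort(fix$g, fix$map, p_scan)
    counts <- snp_carrier_counts(cat1, fix$map)
    call_ctoh_regions(counts, cat1, fix$map, consensus_params())
  }
  # 10 carriers x 100 SNPs -> exactly one region of exactly 100 SNPs
  regs <- run_case(10, 100)
  expect_equal(nrow(regs), 1L)
  expect_equal(regs$n_snps, 100L)
  expect_equal(regs$n_carriers, 10L)
  expect_equal(c(regs$start_snp, regs$end_snp), c(101L, 200L))
  # 9 carriers x 150 SNPs -> below the carrier floor
  expect_equal(nrow(run_case(9, 150)), 0L)
  # 10 carriers x 99 SNPs -> below the run floor
  expect_equal(nrow(run_case(10, 99)), 0L)
})

test_that("called regions are maximal and match a brute-force window scan", {
  set.seed(31)
  for (rep in 1:10) {
    n_subj <- 25; n_snp <- 300
    g <- matrix(1L, n_subj, n_snp)
    # plant 1-3 blocks with random carrier sets/positions
    for (b in seq_len(sample(1:3, 1))) {
      start <- sample(1:(n_snp - 60), 1)
      len <- sample(30:60, 1)
      who <- sample(n_subj, sample(8:14, 1))
      hap <- sample(c(0L, 2L), len, replace = TRUE)
      for (i in who) g[i, seq(start, length.out = len)] <- hap
    }
    rownames(g) <- sprintf("S%03d", 1:n_subj)
    map <- data.frame(id = paste0("rs", 1:n_snp), chrom = "1",
                      pos = 1:n_snp * 100L, a1 = "A", a2 = "G")
    colnames(g) <- map$id
    params <- consensus_params(min_carriers = 8L, min_shared_snps = 25L)
    cat1 <- scan_cohort(g, map, scan_params(min_snps = 25L))
    counts <- snp_carrier_counts(cat1, map)
    regs <- call_ctoh_regions(counts, cat1, map, params)
    # brute force: maximal runs of counts >= min_carriers
    ok <- counts >= params$min_carriers
    runs <- rle(ok)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
    keep <- runs$values & runs$lengths >= params$min_shared_snps
    expect_equal(nrow(regs), sum(keep))
    if (nrow(regs)) {
      expect_equal(regs$start_snp, starts[keep], ignore_attr = TRUE)
      expect_equal(regs$end_snp, ends[keep], ignore_attr = TRUE)
      # maximality: flanking SNPs fail the constraint
      for (j in seq_len(nrow(regs))) {
        if (regs$start_snp[j] > 1) expect_false(ok[regs$start_snp[j] - 1])
        if (regs$end_snp[j] < n_snp) expect_false(ok[regs$end_snp[j] + 1])
      }
    }
  }
})

test_that("allelic matching counts joint homozygous sites correctly", {
  map <- data.frame(id = paste0("rs", 1:100), chrom = "1",
                    pos = 1:100 * 10L)
  hap <- rep(0L, 100)
  g <- rbind(A = hap, B = hap)
  # identical homozygous segments
  m <- allelic_match(g, "A", "B", 1:100)
  expect_equal(m$fraction, 1)
  expect_true(m$is_match)
  expect_equal(m$n_joint, 100L)
  # 95/100 identical: inclusive boundary; 94 -> no match
  g95 <- g; g95["B", 1:5] <- 2L
  m95 <- allelic_match(g95, "A", "B", 1:100)
  expect_equal(m95$fraction, 0.95)
  expect_true(m95$is_match)
  g94 <- g; g94["B", 1:6] <- 2L
  m94 <- allelic_match(g94, "A", "B", 1:100)
  expect_equal(m94$fraction, 0.94)
  expect_false(m94$is_match)
  # symmetry
  ab <- allelic_match(g94, "A", "B", 1:100)
  ba <- allelic_match(g94, "B", "A", 1:100)
  expect_identical(ab[c("n_joint", "n_identical", "fraction", "is_match")],
                   ba[c("n_joint", "n_identical", "fraction", "is_match")])
  # 10-SNP toy: A missing at 2, remaining 8 jointly homozygous, 7 identical
  a <- c(-1L, -1L, rep(0L, 8))
  b <- c(0L, 0L, 2L, rep(0L, 7))
  gt <- rbind(A = a, B = b)
  mt <- allelic_match(gt, "A", "B", 1:10)
  expect_equal(mt$n_joint, 8L)
  expect_equal(mt$fraction, 7 / 8)
  expect_false(mt$is_match)
  # no joint sites -> undefined fraction, no match
  g0 <- rbind(A = rep(-1L, 10), B = rep(0L, 10))
  m0 <- allelic_match(g0, "A", "B", 1:10)
  expect_true(is.nan(m0$fraction))
  expect_false(m0$is_match)
})

test_that("allelic grouping splits planted haplotypes and filters by a 5+5 rule", {
  # two haplotypes differing at 20% of sites, 6 carriers each
  set.seed(8)
  n_snp <- 300L
  hap1 <- sample(c(0L, 2L), 120, replace = TRUE)
  hap2 <- hap1
  flip <- sample(120, 24)
  hap2[flip] <- 2L - hap2[flip]
  g <- matrix(1L, 30, n_snp)
  for (i in 1:6) g[i, 101:220] <- hap1
  for (i in 7:12) g[i, 101:220] <- hap2
  rownames(g) <- sprintf("S%03d", 1:30)
  map <- data.frame(id = paste0("rs", 1:n_snp), chrom = "1",
                    pos = 1:n_snp * 50L)
  colnames(g) <- map$id
  cat1 <- scan_cohort(g, map, scan_params())
  counts <- snp_carrier_counts(cat1, map)
  regs <- call_ctoh_regions(counts, cat1, map, consensus_params())
  expect_equal(nrow(regs), 1L)
  groups <- group_atohs(regs[1, ], cat1, g, map, consensus_params())
  expect_equal(nrow(groups), 2L)
  expect_setequal(groups$carriers[[1]], sprintf("S%03d", 1:6))
  expect_setequal(groups$carriers[[2]], sprintf("S%03d", 7:12))
  # all identical -> one group
  g2 <- g
  for (i in 7:12) g2[i, 101:220] <- hap1
  cat2 <- scan_cohort(g2, map, scan_params())
  regs2 <- call_ctoh_regions(snp_carrier_counts(cat2, map), cat2, map,
                             consensus_params())
  one <- group_atohs(regs2[1, ], cat2, g2, map, consensus_params())
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_carriers, 12L)
  # retention at exactly 5 cases + 5 controls is inclusive
  pheno <- make_pheno(rownames(g2), n_cases = 5L)  # S001-5 cases
  kept <- filter_atohs(one, pheno, consensus_params())
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$n_cases, 5L)
  expect_equal(kept$n_controls, 7L)
  pheno4 <- make_pheno(rownames(g2), n_cases = 4L)
  expect_equal(nrow(filter_atohs(one, pheno4, consensus_params())), 0L)
  # empty input -> empty output
  empty <- one[0, ]
  expect_equal(nrow(filter_atohs(empty, pheno, consensus_params())), 0L)
})

test_that("carrier matrices reconcile with stored carrier counts", {
  fix <- planted_block_cohort(n_subjects = 30, n_snps_total = 400,
                              carriers = 3:14, start = 101, n_snps = 120)
  cat1 <- scan_cohort(fix$g, fix$map, scan_params())
  regs <- call_ctoh_regions(snp_carrier_counts(cat1, fix$map), cat1,
                            fix$map, consensus_params())
  cm <- carrier_matrix(regs, rownames(fix$g))
  expect_equal(unname(colSums(cm)), regs$n_carriers)
  expect_setequal(rownames(cm)[cm[, 1] == 1], regs$carriers[[1]])
})
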