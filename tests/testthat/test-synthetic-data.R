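test_that("simulated SNP maps are sorted, unique and deterministic", {
  cfg <- sim_config(n_chromosomes = 2L, snps_per_chrom = 1000L,
                    mean_snp_spacing_bp = 6000, seed = 42L)
  map <- simulate_snp_map(cfg)
  expect_equal(nrow(map), 2000L)
  expect_false(anyDuplicated(map$id) > 0)
  for (ch in unique(map$chrom)) {
    pos <- map$pos[map$chrom == ch]
    expect_false(is.unsorted(pos, strictly = TRUE))
  }
  # span of 1000 SNPs at 6 kb spacing ~ 6 Mb
  span <- max(map$pos[map$chrom == "1"])
  expect_gt(span, 4e6); expect_lt(span, 8e6)
  # a 141-SNP tract at this spacing has expected length near the ~886 kb
  # average tract length of array-scale catalogs
  expect_equal(141 * 6000, 846000, tolerance = 0)
  map2 <- simulate_snp_map(cfg)
  expect_identical(map, map2)
  expect_error(simulate_snp_map(sim_config(snps_per_chrom = 0L)),
               "positive")
})

test_that("cohort simulation respects genotype legality and truth flags", {
  cfg <- sim_config(n_cases = 150L, n_controls = 150L, n_chromosomes = 2L,
                    snps_per_chrom = 800L,
                    planted_tracts = list(
                      planted_tract("1", 100L, 120L, "h1", 0.10, 0.05),
                      planted_tract("2", 300L, 110L, "h2", 0.05, 0.10)),
                    missing_rate = 0.01, seed = 9L)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$genotypes %in% c(-1L, 0L, 1L, 2L)))
  expect_equal(dim(sim$genotypes), c(300L, 1600L))
  expect_equal(sum(sim$phenotypes$case), 150L)
  # truth consistency: carriers homozygous and allele-identical to the
  # haplotype wherever non-missing
  for (k in 1:2) {
    tr <- sim$truth$tracts[k, ]
    cols <- which(sim$map$chrom == tr$chrom)[tr$start_snp:tr$end_snp]
    hap <- sim$truth$haplotypes[[k]]
    for (i in which(sim$truth$carriers[, k])) {
      calls <- sim$genotypes[i, cols]
      obs <- calls >= 0L
      expect_identical(unname(calls[obs]), hap[obs])
    }
  }
  # determinism
  sim2 <- simulate_cohort(cfg)
  expect_identical(sim$genotypes, sim2$genotypes)
  expect_identical(sim$phenotypes, sim2$phenotypes)
  expect_error(simulate_cohort(
    sim_config(planted_tracts = list(
      planted_tract("1", 4990L, 120L, "x", 0.1, 0.1)))), "overruns")
})

test_that("missingness and carrier odds ratios match their targets", {
  cfg <- sim_config(n_cases = 500L, n_controls = 500L, n_chromosomes = 1L,
                    snps_per_chrom = 1000L, planted_tracts = list(
                      planted_tract("1", 200L, 120L, "h1", 0.06, 0.03)),
                    missing_rate = 0.02, seed = 5L)
  sim <- simulate_cohort(cfg)
  # 10^6 calls at 2%: observed fraction within +/- 0.005
  expect_equal(mean(sim$genotypes == -1L), 0.02, tolerance = 0.25)
  expect_lt(abs(mean(sim$genotypes == -1L) - 0.02), 0.005)
  # closed-form target OR for 0.06 vs 0.03 carrier frequencies
  expect_equal(sim$truth$tracts$target_or,
               (0.06 / 0.94) / (0.03 / 0.97), tolerance = 1e-12)
  # crude OR over several seeds concentrates near ~2.06
  ors <- vapply(1:8, function(s) {
    cfg$seed <- s
    x <- simulate_cohort(cfg)
    car <- x$truth$carriers[, 1]
    y <- x$phenotypes$case
    a <- sum(car & y == 1); b <- sum(!car & y == 1)
    c_ <- sum(car & y == 0); d <- sum(!car & y == 0)
    (a * d) / (b * c_)
  }, 0)
  expect_equal(mean(ors), 2.064, tolerance = 0.25)
})

test_that("prospective sampling reproduces the logistic null", {
  cfg <- sim_config(n_cases = 2000L, n_controls = 2000L,
                    n_chromosomes = 1L, snps_per_chrom = 50L,
                    planted_tracts = list(),
                    covariate_effects = c(age = 0, sex_female = 0,
                                          smoke_former = 0,
                                          smoke_current = 0),
                    baseline_prevalence_logit = -0.5,
                    sampling = "prospective", seed = 3L)
  sim <- simulate_cohort(cfg)
  p_hat <- mean(sim$phenotypes$case)
  p_exp <- plogis(-0.5)
  expect_lt(abs(p_hat - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 4000))
})

test_that("background genotypes sit in Hardy-Weinberg equilibrium", {
  cfg <- sim_config(n_cases = 250L, n_controls = 250L, n_chromosomes = 1L,
                    snps_per_chrom = 1200L, planted_tracts = list(),
                    missing_rate = 0, seed = 21L)
  sim <- simulate_cohort(cfg)
  p <- vapply(seq_len(1200L), function(j) {
    g <- sim$genotypes[, j]
    hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, 0)
  # the exact test is discrete and conservative, so p-values sit slightly
  # above uniform; sanity-check the KS distance and the rejection rates
  # rather than demanding strict uniformity
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.2)
  expect_gt(mean(p < 0.05), 0.01)
  expect_lte(mean(p < 0.05), 0.06)
  expect_lte(mean(p < 0.01), 0.015)
})

test_that("expression simulation plants effects where asked", {
  cfg <- sim_config(seed = 13L, n_chromosomes = 1L, snps_per_chrom = 500L,
                    planted_tracts = list())
  map <- simulate_snp_map(cfg)
  genes <- simulate_gene_annotation(map, genes_per_chrom = 30L, seed = 13L)
  # null: no planted effects -> mean tumor/normal differences near 0
  ex0 <- simulate_expression(NULL, genes, cfg)
  d0 <- rowMeans(ex0$expr[, ex0$samples$tumor == 1]) -
    rowMeans(ex0$expr[, ex0$samples$tumor == 0])
  expect_lt(max(abs(d0)), 1)       # |diff| ~ N(0, ~0.2)
  expect_lt(abs(mean(d0)), 0.1)
  # planted +2 SD effect: two-sample z ~ 2/sqrt(1/58+1/49) ~ 10.3
  de <- data.frame(gene = genes$gene[3], effect_sd = 2, stratum = "all")
  ex1 <- simulate_expression(NULL, genes, cfg, de_genes = de)
  tum <- ex1$samples$tumor == 1
  z <- (mean(ex1$expr[3, tum]) - mean(ex1$expr[3, !tum])) /
    sqrt(1 / sum(tum) + 1 / sum(!tum))
  expect_equal(z, 2 / sqrt(1 / 58 + 1 / 49), tolerance = 0.35)
  # stratum-restricted effect leaves never-smokers unshifted
  de2 <- data.frame(gene = genes$gene[5], effect_sd = 2, stratum = "ever")
  ex2 <- simulate_expression(NULL, genes, cfg, de_genes = de2)
  nev <- ex2$samples$smoking == 0
  d_never <- mean(ex2$expr[5, nev & tum]) - mean(ex2$expr[5, nev & !tum])
  d_ever <- mean(ex2$expr[5, !nev & tum]) - mean(ex2$expr[5, !nev & !tum])
  expect_lt(abs(d_never), 1)
  expect_gt(d_ever, 1)
  expect_error(simulate_expression(NULL, genes, cfg,
                                   de_genes = data.frame(
                                     gene = "NOPE", effect_sd = 1,
                                     stratum = "all")), "unknown gene")
})
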