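#' Describe a homozygous tract to plant in a simulated cohort
#'
#' A planted tract is a fixed homozygous haplotype spanning `n_snps`
#' consecutive SNPs on one chromosome. Carrier subjects receive the
#' haplotype on both chromosomes (forced homozygosity), which is exactly the
#' observable a tract-of-homozygosity scan detects. Carrier frequency is
#' specified separately in cases and controls, so the implied crude odds
#' ratio is `(fc/(1-fc)) / (fk/(1-fk))` for case frequency `fc` and control
#' frequency `fk`.
#'
#' Two tracts sharing the same span but different `haplotype_id` create two
#' allelically distinct carrier groups inside one consensus region, i.e. two
#' aTOHs within one cTOH.
#'
#' @param chrom chromosome label (character or coercible).
#' @param start_snp 1-based index of the first spanned SNP on `chrom`.
#' @param n_snps number of SNPs spanned; tracts meant to seed consensus
#'   regions should span at least 100.
#' @param haplotype_id label distinguishing haplotypes within one span.
#' @param carrier_freq_cases,carrier_freq_controls carrier probabilities in
#'   `(0, 1)` for cases and controls respectively.
#' @return a `planted_tract` list.
#' @export
planted_tract <- function(chrom, start_snp, n_snps, haplotype_id,
                          carrier_freq_cases, carrier_freq_controls) {
  stopifnot(n_snps >= 2, start_snp >= 1,
            carrier_freq_cases > 0, carrier_freq_cases < 1,
            carrier_freq_controls > 0, carrier_freq_controls < 1)
  structure(list(
    chrom = as.character(chrom),
    start_snp = as.integer(start_snp),
    n_snps = as.integer(n_snps),
    haplotype_id = as.character(haplotype_id),
    carrier_freq_cases = carrier_freq_cases,
    carrier_freq_controls = carrier_freq_controls,
    target_or = (carrier_freq_cases / (1 - carrier_freq_cases)) /
      (carrier_freq_controls / (1 - carrier_freq_controls))
  ), class = "planted_tract")
}

#' Default planted tracts for the standard synthetic cohort
#'
#' Four tracts on three chromosomes: a risk tract (crude OR ~ 3.0), a
#' protective tract (OR ~ 0.33), and one span carrying two distinct
#' haplotypes with opposite effects so that the consensus region splits
#' into two allelic subgroups. Carrier frequencies (1.2-5% of a group) and
#' implied odds ratios (0.3-3) sit in the range reported for region-level
#' carrier variants in case-control cohorts of this size. Spans of
#' 141-150 SNPs leave headroom for SNP-level QC attrition: strongly shared
#' homozygosity is itself a (true-positive) Hardy-Weinberg departure, so a
#' handful of tract SNPs are expected to fall to the HWE filter.
#'
#' @return list of [planted_tract()] objects.
#' @export
default_planted_tracts <- function() {
  list(
    planted_tract("1", 1000L, 141L, "risk1",  0.050, 0.017),
    planted_tract("2", 2000L, 141L, "prot1",  0.017, 0.050),
    planted_tract("3", 1400L, 180L, "mixA",   0.030, 0.010),
    planted_tract("3", 1400L, 180L, "mixB",   0.010, 0.030)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions of a SNP-array lung-cancer
#' case-control cohort: 788 cases and 830 controls; age recorded in 5
#' ordered categories with population mean ~1.63; sex 967 male / 651 female;
#' smoking never/former/current split 156/703/759; ~6 kb mean SNP spacing so
#' that a ~141-SNP tract spans ~850 kb. The full-scale study used ~514k
#' autosomal SNPs; the default here is a scaled-down 4 x 5,000 SNP genome
#' suitable for testing, with the same per-SNP properties.
#'
#' @param n_cases,n_controls cohort sizes.
#' @param n_chromosomes,snps_per_chrom simulated genome dimensions.
#' @param mean_snp_spacing_bp mean inter-SNP distance (exponential spacings).
#' @param maf_range minor-allele-frequency range, inside `(0, 0.5]`.
#' @param planted_tracts list of [planted_tract()]; default
#'   [default_planted_tracts()].
#' @param covariate_effects named log-odds: `age` (per category above 1),
#'   `sex_female` (vs male), `smoke_former`, `smoke_current` (vs never).
#' @param baseline_prevalence_logit baseline log-odds of case status used by
#'   the prospective sampling mode.
#' @param missing_rate per-call no-call probability, in `[0, 0.05)`.
#' @param sampling `"retrospective"` (default; fixed case/control counts,
#'   carriers drawn at the per-group frequencies) or `"prospective"`
#'   (case labels drawn from the logistic model).
#' @param seed integer seed; identical configurations give identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cases = 788L,
                       n_controls = 830L,
                       n_chromosomes = 4L,
                       snps_per_chrom = 5000L,
                       mean_snp_spacing_bp = 6000,
                       maf_range = c(0.05, 0.5),
                       planted_tracts = default_planted_tracts(),
                       covariate_effects = c(age = 0.25, sex_female = -0.2,
                                             smoke_former = 1.0,
                                             smoke_current = 1.5),
                       baseline_prevalence_logit = 0,
                       missing_rate = 0.005,
                       sampling = c("retrospective", "prospective"),
                       seed = 1L) {
  sampling <- match.arg(sampling)
  if (any(c(n_cases, n_controls, n_chromosomes, snps_per_chrom) <= 0))
    stop("cohort and genome dimensions must be positive counts")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  needed <- c("age", "sex_female", "smoke_former", "smoke_current")
  if (!all(needed %in% names(covariate_effects)))
    stop("covariate_effects must name: ", paste(needed, collapse = ", "))
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_chromosomes = as.integer(n_chromosomes),
    snps_per_chrom = as.integer(snps_per_chrom),
    mean_snp_spacing_bp = mean_snp_spacing_bp,
    maf_range = maf_range,
    planted_tracts = planted_tracts,
    covariate_effects = covariate_effects,
    baseline_prevalence_logit = baseline_prevalence_logit,
    missing_rate = missing_rate,
    sampling = sampling,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Baseline covariate level probabilities (population margins).
.age_probs <- c(0.60, 0.25, 0.09, 0.04, 0.02)          # categories 1..5
.sex_probs <- c(male = 967, female = 651) / 1618        # coded 1 / 2
.smoke_probs <- c(never = 156, former = 703, current = 759) / 1618  # 0/1/2

#' Simulate a SNP map
#'
#' Positions are cumulative exponential spacings (rounded up to at least
#' 1 bp), giving strictly increasing 1-based coordinates whose density
#' emulates a genotyping array at the configured mean spacing. Each SNP gets
#' an rs-style identifier, a reference/alternate allele pair, and a minor
#' allele frequency drawn uniformly from `maf_range`.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `id`, `chrom`, `pos`, `a1`, `a2`, `maf`,
#'   sorted by (chromosome, position).
#' @export
simulate_snp_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$snps_per_chrom
  bases <- c("A", "C", "G", "T")
  maps <- lapply(seq_len(config$n_chromosomes), function(ch) {
    gaps <- ceiling(stats::rexp(n, rate = 1 / config$mean_snp_spacing_bp))
    pos <- cumsum(pmax(1, gaps))
    a1 <- sample(bases, n, replace = TRUE)
    a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1L), "")
    data.frame(chrom = as.character(ch), pos = as.integer(pos),
               a1 = a1, a2 = a2,
               maf = stats::runif(n, config$maf_range[1], config$maf_range[2]),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  map <- do.call(rbind, maps)
  map <- data.frame(id = paste0("rs", seq_len(nrow(map))), map,
                    stringsAsFactors = FALSE)
  rownames(map) <- NULL
  map
}

# sample a covariate level tilted by case status: P(k | case) ~ p_k exp(eta_k)
.sample_tilted <- function(n_case, n_ctrl, probs, eta) {
  p_case <- probs * exp(eta); p_case <- p_case / sum(p_case)
  lev <- seq_along(probs)
  c(sample(lev, n_case, replace = TRUE, prob = p_case),
    sample(lev, n_ctrl, replace = TRUE, prob = probs))
}

#' Simulate a genotyped case-control cohort with planted homozygous tracts
#'
#' Background genotypes are drawn independently per SNP under
#' Hardy-Weinberg equilibrium at the map's allele frequency (no background
#' linkage disequilibrium). Carrier subjects of each planted tract are
#' overwritten with the tract's fixed homozygous haplotype across its span;
#' no-calls are then injected uniformly at `missing_rate`.
#'
#' Two sampling modes are supported. The default retrospective mode fixes
#' the case/control counts and draws tract carriers at the per-group
#' frequencies (realizing the implied odds ratio directly); covariates are
#' drawn from population margins, tilted in cases by `covariate_effects`.
#' The prospective mode draws covariates and carriers (at the control
#' frequency) for `n_cases + n_controls` subjects and then draws case labels
#' from the logistic model
#' `logit P(case) = baseline + covariate effects + sum(log OR_t * carrier_t)`.
#'
#' @param config a [sim_config()].
#' @param map optional SNP map; defaults to [simulate_snp_map()] of the same
#'   configuration (and hence the same seed).
#' @return list with class `toh_sim`: `genotypes` (subjects x SNPs integer
#'   matrix coded 0/1/2 alt-allele counts, -1 missing), `map`, `phenotypes`
#'   (data.frame: `id`, `case`, `age_cat`, `sex`, `smoking`), and `truth`
#'   (planted tract table, per-subject carrier matrix, haplotypes).
#' @export
simulate_cohort <- function(config, map = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(map)) map <- simulate_snp_map(config)
  set.seed(config$seed + 1L)

  tracts <- config$planted_tracts
  chrom_sizes <- table(map$chrom)
  for (tr in tracts) {
    if (!tr$chrom %in% names(chrom_sizes))
      stop("planted tract on unknown chromosome ", tr$chrom)
    if (tr$start_snp + tr$n_snps - 1L > chrom_sizes[[tr$chrom]])
      stop("planted tract overruns chromosome ", tr$chrom)
  }

  n_case <- config$n_cases; n_ctrl <- config$n_controls
  n <- n_case + n_ctrl
  m <- nrow(map)
  eff <- config$covariate_effects
  ids <- sprintf("S%05d", seq_len(n))

  if (config$sampling == "retrospective") {
    case <- c(rep(1L, n_case), rep(0L, n_ctrl))
    age <- .sample_tilted(n_case, n_ctrl, .age_probs,
                          eff[["age"]] * (0:4))
    sex <- .sample_tilted(n_case, n_ctrl, .sex_probs,
                          c(0, eff[["sex_female"]]))
    smoke <- .sample_tilted(n_case, n_ctrl, .smoke_probs,
                            c(0, eff[["smoke_former"]],
                              eff[["smoke_current"]])) - 1L
  } else {
    age <- sample(1:5, n, replace = TRUE, prob = .age_probs)
    sex <- sample(1:2, n, replace = TRUE, prob = .sex_probs)
    smoke <- sample(0:2, n, replace = TRUE, prob = .smoke_probs)
  }

  # carriers: at most one haplotype per subject over overlapping spans
  n_tr <- length(tracts)
  carrier <- matrix(FALSE, n, n_tr)
  tr_tab <- if (n_tr == 0)
    data.frame(tract = integer(), haplotype_id = character(),
               chrom = character(), start_snp = integer(),
               end_snp = integer(), carrier_freq_cases = numeric(),
               carrier_freq_controls = numeric(), target_or = numeric(),
               stringsAsFactors = FALSE)
  else do.call(rbind, lapply(seq_along(tracts), function(k) {
    tr <- tracts[[k]]
    data.frame(tract = k, haplotype_id = tr$haplotype_id, chrom = tr$chrom,
               start_snp = tr$start_snp,
               end_snp = tr$start_snp + tr$n_snps - 1L,
               carrier_freq_cases = tr$carrier_freq_cases,
               carrier_freq_controls = tr$carrier_freq_controls,
               target_or = tr$target_or, stringsAsFactors = FALSE)
  }))
  overlaps <- function(a, b)
    tr_tab$chrom[a] == tr_tab$chrom[b] &&
      tr_tab$start_snp[a] <= tr_tab$end_snp[b] &&
      tr_tab$start_snp[b] <= tr_tab$end_snp[a]
  if (n_tr > 0) {
    if (config$sampling == "retrospective") {
      grp_freq <- function(k) ifelse(case == 1L,
                                     tracts[[k]]$carrier_freq_cases,
                                     tracts[[k]]$carrier_freq_controls)
    } else {
      grp_freq <- function(k) rep(tracts[[k]]$carrier_freq_controls, n)
    }
    for (k in seq_len(n_tr)) {
      cand <- stats::rbinom(n, 1L, grp_freq(k)) == 1L
      if (k > 1) {
        for (j in seq_len(k - 1L)) {
          if (overlaps(k, j)) cand <- cand & !carrier[, j]
        }
      }
      carrier[, k] <- cand
    }
  }

  if (config$sampling == "prospective") {
    eta <- config$baseline_prevalence_logit +
      eff[["age"]] * (age - 1) +
      eff[["sex_female"]] * (sex == 2) +
      eff[["smoke_former"]] * (smoke == 1) +
      eff[["smoke_current"]] * (smoke == 2)
    if (n_tr > 0)
      eta <- eta + as.numeric(carrier %*% vapply(tracts, function(t)
        log(t$target_or), 0))
    case <- stats::rbinom(n, 1L, stats::plogis(eta))
  }

  # background genotypes: alt-allele counts, HWE at each SNP's MAF
  g <- matrix(stats::rbinom(n * m, 2L, rep(map$maf, each = n)),
              nrow = n, ncol = m)
  storage.mode(g) <- "integer"

  # plant tracts (fixed homozygous haplotypes, codes in {0, 2})
  chrom_offset <- c(0L, cumsum(as.integer(chrom_sizes)))
  names(chrom_offset) <- c(names(chrom_sizes), "")
  haplotypes <- vector("list", n_tr)
  for (k in seq_len(n_tr)) {
    tr <- tracts[[k]]
    cols <- chrom_offset[[tr$chrom]] + seq(tr$start_snp, length.out = tr$n_snps)
    hap <- 2L * stats::rbinom(tr$n_snps, 1L, map$maf[cols])
    haplotypes[[k]] <- hap
    who <- which(carrier[, k])
    if (length(who))
      g[who, cols] <- matrix(hap, nrow = length(who), ncol = tr$n_snps,
                             byrow = TRUE)
  }

  # uniform missingness
  if (config$missing_rate > 0) {
    n_miss <- stats::rbinom(1L, n * m, config$missing_rate)
    if (n_miss > 0) g[sample.int(n * m, n_miss)] <- -1L
  }

  dimnames(g) <- list(ids, map$id)
  pheno <- data.frame(id = ids, case = as.integer(case),
                      age_cat = as.integer(age), sex = as.integer(sex),
                      smoking = as.integer(smoke), stringsAsFactors = FALSE)
  colnames(carrier) <- if (n_tr) paste0("tract", seq_len(n_tr)) else NULL
  rownames(carrier) <- ids
  structure(list(genotypes = g, map = map, phenotypes = pheno,
                 truth = list(tracts = tr_tab, carriers = carrier,
                              haplotypes = haplotypes)),
            class = "toh_sim")
}

#' Simulate a gene annotation on the synthetic genome
#'
#' Genes are placed at uniformly random starts along each simulated
#' chromosome with exponentially distributed lengths (mean
#' `mean_length_bp`). Coordinates are 0-based half-open, the BED
#' convention.
#'
#' @param map SNP map from [simulate_snp_map()].
#' @param genes_per_chrom genes per chromosome.
#' @param mean_length_bp mean gene length.
#' @param seed integer seed.
#' @return data.frame: `gene`, `chrom`, `start`, `end` (0-based half-open).
#' @export
simulate_gene_annotation <- function(map, genes_per_chrom = 40L,
                                     mean_length_bp = 30000, seed = 1L) {
  set.seed(seed + 2L)
  out <- lapply(split(map$pos, map$chrom), function(pos) {
    span <- max(pos)
    start <- sort(sample.int(span, genes_per_chrom))
    len <- pmax(1000, ceiling(stats::rexp(genes_per_chrom,
                                          1 / mean_length_bp)))
    data.frame(start = start - 1L, end = pmin(start - 1L + len, span))
  })
  chroms <- names(out)
  ann <- do.call(rbind, Map(function(d, ch) {
    d$chrom <- ch; d
  }, out, chroms))
  ann <- ann[order(as.integer(ann$chrom), ann$start), ]
  ann <- data.frame(gene = sprintf("GENE%04d", seq_len(nrow(ann))),
                    chrom = ann$chrom, start = as.integer(ann$start),
                    end = as.integer(ann$end), stringsAsFactors = FALSE)
  rownames(ann) <- NULL
  ann
}

#' Simulate a tumor/normal expression matrix with planted differential genes
#'
#' Emulates a normalized (log2-scale) expression study of 58 tumor and 49
#' normal lung tissues with never/former/current smoking annotation.
#' Baseline per-gene means are drawn once; every value receives Gaussian
#' noise with `noise_sd = 1`, so planted effects (in SD units) translate
#' directly into mean shifts in tumor samples. An effect can be restricted
#' to a smoking stratum (`"ever"` = former or current, `"never"`).
#'
#' @param truth truth set from [simulate_cohort()] (may be `NULL`; used only
#'   to record the planted differential genes alongside the tract truth).
#' @param genes gene annotation from [simulate_gene_annotation()].
#' @param config a [sim_config()] (supplies the seed).
#' @param de_genes `NULL`, or data.frame with columns `gene`, `effect_sd`,
#'   `stratum` (`"all"`, `"ever"` or `"never"`).
#' @param n_tumor,n_normal sample sizes.
#' @param noise_sd residual SD on the log2 scale.
#' @return list: `expr` (genes x samples matrix), `samples` (data.frame
#'   `sample`, `tumor`, `smoking`), `de_genes`.
#' @export
simulate_expression <- function(truth, genes, config, de_genes = NULL,
                                n_tumor = 58L, n_normal = 49L,
                                noise_sd = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  if (!is.null(de_genes)) {
    bad <- setdiff(de_genes$gene, genes$gene)
    if (length(bad))
      stop("unknown gene ids in de_genes: ", paste(bad, collapse = ", "))
    if (!all(de_genes$stratum %in% c("all", "ever", "never")))
      stop("de_genes$stratum must be 'all', 'ever' or 'never'")
  }
  n_s <- n_tumor + n_normal
  samples <- data.frame(
    sample = sprintf("E%03d", seq_len(n_s)),
    tumor = c(rep(1L, n_tumor), rep(0L, n_normal)),
    smoking = sample(0:2, n_s, replace = TRUE,
                     prob = c(20, 26, 28) / 74),
    stringsAsFactors = FALSE)
  n_g <- nrow(genes)
  mu <- stats::rnorm(n_g, mean = 7, sd = 1)
  expr <- matrix(stats::rnorm(n_g * n_s, mean = mu, sd = noise_sd),
                 nrow = n_g, ncol = n_s)
  if (!is.null(de_genes) && nrow(de_genes)) {
    for (i in seq_len(nrow(de_genes))) {
      gi <- match(de_genes$gene[i], genes$gene)
      in_stratum <- switch(de_genes$stratum[i],
                           all = rep(TRUE, n_s),
                           ever = samples$smoking >= 1L,
                           never = samples$smoking == 0L)
      affected <- samples$tumor == 1L & in_stratum
      expr[gi, affected] <- expr[gi, affected] +
        de_genes$effect_sd[i] * noise_sd
    }
  }
  dimnames(expr) <- list(genes$gene, samples$sample)
  list(expr = expr, samples = samples,
       de_genes = if (is.null(de_genes))
         data.frame(gene = character(), effect_sd = numeric(),
                    stratum = character()) else de_genes)
}
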