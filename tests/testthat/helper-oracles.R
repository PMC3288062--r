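# Independent brute-force oracles used to validate the package's
# implementations on small inputs. These deliberately recompute results by
# exhaustive enumeration rather than sharing code with the package.

# Greedy tract scan recomputed by exhaustive window enumeration: a window
# [s, e] is valid when it starts and ends on a homozygous call, contains at
# most max_het_in_run heterozygous calls, its spanned missing fraction is
# at most the cap, and it holds at least min_snps homozygous calls. From
# the smallest usable start the largest valid end is taken, the window
# emitted, and the scan resumes after it.
oracle_scan <- function(calls, params) {
  n <- length(calls)
  hom <- calls == 0L | calls == 2L
  cum_het <- c(0L, cumsum(calls == 1L))
  cum_mis <- c(0L, cumsum(calls < 0L))
  cum_hom <- c(0L, cumsum(hom))
  segs <- NULL
  pos <- 1L
  while (pos <= n) {
    emitted <- FALSE
    for (s in pos:n) {
      if (!hom[s]) next
      e_all <- s:n
      ok <- hom[e_all] &
        (cum_het[e_all + 1L] - cum_het[s]) <= params$max_het_in_run &
        (cum_mis[e_all + 1L] - cum_mis[s]) <=
          params$max_missing_fraction_in_run * (e_all - s + 1L) &
        (cum_hom[e_all + 1L] - cum_hom[s]) >= params$min_snps
      if (any(ok)) {
        e <- max(e_all[ok])
        segs <- rbind(segs, c(s, e, cum_hom[e + 1L] - cum_hom[s],
                              cum_mis[e + 1L] - cum_mis[s]))
        pos <- e + 1L
        emitted <- TRUE
        break
      }
    }
    if (!emitted) break
  }
  segs
}

# Hardy-Weinberg exact test by direct enumeration of every genotype
# configuration compatible with the observed allele counts, using choose()
# for the conditional probabilities.
oracle_hwe <- function(n0, n1, n2) {
  N <- n0 + n1 + n2
  nA <- 2L * n0 + n1  # count of the first allele
  h_all <- seq.int(nA %% 2L, min(nA, 2L * N - nA), by = 2L)
  pr <- vapply(h_all, function(h) {
    a <- (nA - h) / 2            # hom for first allele
    b <- N - a - h               # hom for second allele
    if (a < 0 || b < 0) return(0)
    choose(N, a) * choose(N - a, h) * 2^h
  }, 0)
  pr <- pr / sum(pr)
  p_obs <- pr[match(n1, h_all)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}

# Benjamini-Hochberg step-up adjustment from its definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- vapply(seq_len(m), function(i)
    min(pmin(1, m * ranked[i:m] / (i:m))), 0)
  out <- numeric(m)
  out[o] <- adj
  out
}

# All-pairs interval overlap (1-based inclusive intervals vs 0-based
# half-open genes).
oracle_map_genes <- function(intervals, genes) {
  hits <- NULL
  for (i in seq_len(nrow(intervals))) {
    for (j in seq_len(nrow(genes))) {
      if (intervals$chrom[i] != genes$chrom[j]) next
      g_start <- genes$start[j] + 1L  # first covered bp, 1-based
      g_end <- genes$end[j]
      if (g_start <= intervals$end_bp[i] && g_end >= intervals$start_bp[i])
        hits <- rbind(hits, data.frame(region = intervals$id[i],
                                       gene = genes$gene[j]))
    }
  }
  hits
}

# Random genotype vector generator for scanner property tests.
random_calls <- function(n, p_hom = 0.55, p_het = 0.35, p_mis = 0.1) {
  sample(c(0L, 2L, 1L, -1L), n, replace = TRUE,
         prob = c(p_hom / 2, p_hom / 2, p_het, p_mis))
}

# Small cohort with a planted, perfectly aligned homozygous block:
# `carriers` subjects share `n_snps` consecutive homozygous calls starting
# at `start`; everyone else (and the flanks) alternates heterozygous.
planted_block_cohort <- function(n_subjects, n_snps_total, carriers, start,
                                 n_snps, hap = NULL, seed = 1) {
  set.seed(seed)
  g <- matrix(1L, n_subjects, n_snps_total)
  if (is.null(hap)) hap <- sample(c(0L, 2L), n_snps, replace = TRUE)
  for (i in carriers)
    g[i, seq(start, length.out = n_snps)] <- hap
  rownames(g) <- sprintf("S%03d", seq_len(n_subjects))
  map <- data.frame(id = paste0("rs", seq_len(n_snps_total)), chrom = "1",
                    pos = seq_len(n_snps_total) * 1000L,
                    a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  colnames(g) <- map$id
  list(g = g, map = map, hap = hap)
}
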