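#' Full pipeline configuration
#'
#' Bundles the per-stage parameter objects with a single global seed. The
#' seed fans out to the stages by fixed offsets so that a stage rerun in
#' isolation reproduces its output.
#'
#' @param sim a [sim_config()] (its seed is overridden by `seed`).
#' @param qc a [qc_thresholds()].
#' @param scan a [scan_params()].
#' @param consensus a [consensus_params()].
#' @param assoc an [assoc_config()].
#' @param integration an [integration_config()].
#' @param genes_per_chrom genes simulated per chromosome for the
#'   expression stage.
#' @param de_effect_sd planted expression effect (SD units) for genes
#'   inside planted risk tracts.
#' @param seed global integer seed.
#' @return a `toh_config` list.
#' @export
toh_config <- function(sim = sim_config(), qc = qc_thresholds(),
                       scan = scan_params(),
                       consensus = consensus_params(),
                       assoc = assoc_config(),
                       integration = integration_config(),
                       genes_per_chrom = 40L, de_effect_sd = 2,
                       seed = 1L) {
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, qc = qc, scan = scan, consensus = consensus,
                 assoc = assoc, integration = integration,
                 genes_per_chrom = as.integer(genes_per_chrom),
                 de_effect_sd = de_effect_sd, seed = as.integer(seed)),
            class = "toh_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `sim`, `qc`, `scan`, `consensus`, `assoc`,
#' `integration`, `genes_per_chrom`, `de_effect_sd` and `seed`; each
#' stage key holds arguments for the corresponding constructor, and
#' omitted values take the documented defaults. `sim$planted_tracts` is a
#' list of [planted_tract()] argument sets.
#'
#' @param path YAML file.
#' @return a [toh_config()].
#' @export
toh_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$planted_tracts))
    sim_args$planted_tracts <- lapply(sim_args$planted_tracts, function(a)
      do.call(planted_tract, a))
  if (!is.null(sim_args$maf_range))
    sim_args$maf_range <- as.numeric(sim_args$maf_range)
  if (!is.null(sim_args$covariate_effects))
    sim_args$covariate_effects <- unlist(sim_args$covariate_effects)
  args <- list(sim = do.call(sim_config, sim_args),
               qc = do.call(qc_thresholds, y$qc %||% list()),
               scan = do.call(scan_params, y$scan %||% list()),
               consensus = do.call(consensus_params, y$consensus %||% list()),
               assoc = do.call(assoc_config, y$assoc %||% list()),
               integration = do.call(integration_config,
                                     y$integration %||% list()))
  if (!is.null(y$genes_per_chrom)) args$genes_per_chrom <- y$genes_per_chrom
  if (!is.null(y$de_effect_sd)) args$de_effect_sd <- y$de_effect_sd
  if (!is.null(y$seed)) args$seed <- y$seed
  do.call(toh_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the homozygosity-tract pipeline end to end
#'
#' Stages: simulate (or take supplied) genotypes; quality control; tract
#' scan; consensus-region calling; allelic grouping and retention;
#' covariate-adjusted association screens over cTOH regions and aTOH
#' groups; interaction models for significant regions; expression
#' simulation and integration (gene mapping over the flanked significant
#' regions, univariate screen, smoking-stratified risk, bi-clustering).
#' Rerunning with the same configuration reproduces all results exactly.
#'
#' @param config a [toh_config()].
#' @param out_dir optional directory; when given, stage tables (catalog,
#'   regions, carrier matrix, association results, integration tables,
#'   BED export) and a JSON run manifest are written there.
#' @param input optional pre-made input list (`genotypes`, `map`,
#'   `phenotypes`) to use instead of the simulator; the truth set is then
#'   unavailable and expression integration uses simulated annotation only.
#' @return list with all stage outputs (`sim`, `qc`, `catalog`,
#'   `catalog_summary`, `regions`, `ctoh_assoc`, `atoh_groups`,
#'   `atoh_assoc`, `interactions`, `expression`, `integration`,
#'   `manifest`).
#' @export
run_toh_pipeline <- function(config = toh_config(), out_dir = NULL,
                             input = NULL) {
  stopifnot(inherits(config, "toh_config"))
  t_all <- proc.time()[["elapsed"]]
  timing <- c()
  tick <- function(stage, t0) {
    timing[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }

  # --- simulate or load -----------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  if (is.null(input)) {
    sim <- simulate_cohort(config$sim)
  } else {
    sim <- list(genotypes = input$genotypes, map = input$map,
                phenotypes = input$phenotypes, truth = input$truth)
  }
  tick("simulate", t0)

  # --- qc --------------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  qc <- qc_filter(sim$genotypes, sim$map, sim$phenotypes, config$qc)
  tick("qc", t0)

  # --- scan ------------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  catalog <- scan_cohort(qc$genotypes, qc$map, config$scan)
  csum <- catalog_summary(catalog, qc$pheno)
  tick("scan", t0)

  # --- consensus regions ----------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  counts <- snp_carrier_counts(catalog, qc$map)
  regions <- call_ctoh_regions(counts, catalog, qc$map, config$consensus)
  tick("regions", t0)

  # --- cTOH association ------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  subjects <- qc$pheno$id
  if (nrow(regions)) {
    cmat <- carrier_matrix(regions, subjects)
    ctoh_assoc <- run_screen(cmat, qc$pheno, config$assoc)
    ctoh_assoc <- merge(
      regions[, c("id", "chrom", "start_rs", "end_rs", "start_bp",
                  "end_bp", "length_bp", "n_snps")],
      ctoh_assoc, by.x = "id", by.y = "region", sort = FALSE)
  } else {
    cmat <- NULL
    ctoh_assoc <- data.frame()
  }
  interactions <- list()
  if (nrow(regions)) {
    for (id in ctoh_assoc$id[ctoh_assoc$significant %in% TRUE])
      interactions[[id]] <- fit_interaction(cmat[, id], qc$pheno,
                                            config$assoc)
  }
  tick("ctoh_assoc", t0)

  # --- aTOH grouping + association ------------------------------------
  t0 <- proc.time()[["elapsed"]]
  atoh_all <- .empty_atoh_groups()
  if (nrow(regions)) {
    gl <- lapply(seq_len(nrow(regions)), function(i)
      group_atohs(regions[i, ], catalog, qc$genotypes, qc$map,
                  config$consensus))
    atoh_all <- do.call(rbind, gl)
  }
  atoh_kept <- filter_atohs(atoh_all, qc$pheno, config$consensus)
  if (nrow(atoh_kept)) {
    amat <- carrier_matrix(atoh_kept, subjects)
    atoh_assoc <- run_screen(amat, qc$pheno, config$assoc)
    atoh_assoc <- merge(
      atoh_kept[, c("id", "parent", "chrom", "start_rs", "end_rs",
                    "start_bp", "end_bp", "n_snps")],
      atoh_assoc, by.x = "id", by.y = "region", sort = FALSE)
  } else {
    atoh_assoc <- data.frame()
  }
  tick("atoh", t0)

  # --- expression integration -----------------------------------------
  t0 <- proc.time()[["elapsed"]]
  genes <- simulate_gene_annotation(sim$map, config$genes_per_chrom,
                                    seed = config$seed)
  de_genes <- NULL
  if (!is.null(sim$truth) && nrow(sim$truth$tracts)) {
    tr <- sim$truth$tracts
    tr_bp <- do.call(rbind, lapply(seq_len(nrow(tr)), function(k) {
      cols <- which(sim$map$chrom == tr$chrom[k])
      data.frame(chrom = tr$chrom[k],
                 start = sim$map$pos[cols[tr$start_snp[k]]],
                 end = sim$map$pos[cols[tr$end_snp[k]]],
                 risk = tr$target_or[k] > 1)
    }))
    hit <- genes$chrom %in% tr_bp$chrom &
      vapply(seq_len(nrow(genes)), function(i) {
        any(tr_bp$chrom == genes$chrom[i] & genes$start[i] < tr_bp$end &
              genes$end[i] > tr_bp$start)
      }, TRUE)
    if (any(hit)) {
      sign_eff <- vapply(which(hit), function(i) {
        j <- which(tr_bp$chrom == genes$chrom[i] &
                     genes$start[i] < tr_bp$end & genes$end[i] > tr_bp$start)[1]
        if (tr_bp$risk[j]) 1 else -1
      }, 0)
      de_genes <- data.frame(gene = genes$gene[hit],
                             effect_sd = config$de_effect_sd * sign_eff,
                             stratum = "all", stringsAsFactors = FALSE)
    }
  }
  ex <- simulate_expression(sim$truth, genes, config$sim,
                            de_genes = de_genes)
  sig_regions <- rbind(
    if (nrow(ctoh_assoc))
      ctoh_assoc[ctoh_assoc$significant %in% TRUE,
                 c("id", "chrom", "start_bp", "end_bp")] else NULL,
    if (nrow(atoh_assoc))
      atoh_assoc[atoh_assoc$significant %in% TRUE,
                 c("id", "chrom", "start_bp", "end_bp")] else NULL)
  integration <- list(mapped = NULL, univariate = NULL, stratified = NULL,
                      cluster = NULL)
  if (!is.null(sig_regions) && nrow(sig_regions)) {
    chrom_len <- tapply(sim$map$pos, sim$map$chrom, max)
    ext <- extend_regions(sig_regions, config$integration$flank_bp,
                          chrom_len)
    mg <- map_genes(ext, genes, ex$expr)
    integration$mapped <- mg
    if (length(mg$genes_on_array)) {
      uni <- univariate_gene_screen(ex$expr, ex$samples,
                                    mg$genes_on_array,
                                    config$integration)
      integration$univariate <- uni
      sig_genes <- uni$gene[uni$significant %in% TRUE]
      if (length(sig_genes)) {
        integration$stratified <- stratified_gene_risk(
          ex$expr, ex$samples, sig_genes, config$integration)
        if (length(sig_genes) >= 2)
          integration$cluster <- hierarchical_cluster(
            ex$expr[sig_genes, , drop = FALSE])
      }
    }
  }
  tick("integration", t0)

  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("tohscan")),
    counts = list(
      subjects_in = nrow(sim$genotypes), snps_in = nrow(sim$map),
      subjects_qc = nrow(qc$genotypes), snps_qc = nrow(qc$map),
      tohs = nrow(catalog), ctoh_regions = nrow(regions),
      atoh_groups_all = nrow(atoh_all), atoh_groups_kept = nrow(atoh_kept),
      significant_ctoh = if (nrow(ctoh_assoc))
        sum(ctoh_assoc$significant, na.rm = TRUE) else 0L,
      significant_atoh = if (nrow(atoh_assoc))
        sum(atoh_assoc$significant, na.rm = TRUE) else 0L,
      genes_simulated = nrow(genes),
      genes_mapped = if (!is.null(integration$mapped))
        length(unique(integration$mapped$mapped$gene)) else 0L,
      genes_significant = if (!is.null(integration$univariate))
        sum(integration$univariate$significant, na.rm = TRUE) else 0L),
    wall_time_s = as.list(timing),
    total_wall_time_s = round(proc.time()[["elapsed"]] - t_all, 3))

  result <- list(sim = sim, qc = qc, catalog = catalog,
                 catalog_summary = csum, counts = counts,
                 regions = regions, ctoh_assoc = ctoh_assoc,
                 interactions = interactions, atoh_groups = atoh_kept,
                 atoh_groups_all = atoh_all, atoh_assoc = atoh_assoc,
                 expression = ex, genes = genes,
                 integration = integration, manifest = manifest)
  if (!is.null(out_dir)) .write_pipeline_outputs(result, out_dir)
  result
}

# write stage tables + manifest under out_dir
.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(res$catalog, "toh_catalog.tsv")
  if (nrow(res$regions)) {
    flat <- res$regions[, setdiff(names(res$regions), "carriers")]
    wt(flat, "ctoh_regions.tsv")
    cm <- carrier_matrix(res$regions, res$qc$pheno$id)
    wt(data.frame(id = rownames(cm), cm, check.names = FALSE),
       "ctoh_carriers.tsv")
    bed <- data.frame(chrom = res$regions$chrom,
                      start_bp = res$regions$start_bp,
                      end_bp = res$regions$end_bp, id = res$regions$id,
                      p = if (nrow(res$ctoh_assoc))
                        res$ctoh_assoc$p[match(res$regions$id,
                                               res$ctoh_assoc$id)] else NA)
    write_regions_bed(bed, file.path(out_dir, "ctoh_regions.bed"))
  }
  if (nrow(res$ctoh_assoc)) wt(res$ctoh_assoc, "ctoh_assoc.tsv")
  if (nrow(res$atoh_assoc)) wt(res$atoh_assoc, "atoh_assoc.tsv")
  if (!is.null(res$integration$univariate))
    wt(res$integration$univariate, "gene_univariate.tsv")
  if (!is.null(res$integration$stratified))
    wt(res$integration$stratified, "gene_stratified.tsv")
  jsonlite::write_json(res$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
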