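## Pipeline orchestration: runs the seven stages in dependency order on a
## single output directory, logging each stage and recording a manifest of
## input/output digests so reruns can be verified byte-for-byte.

.pipeline_stages <- c("simulate", "filter_snv", "filter_sv",
                      "fit_signatures", "telomere", "cn_msi", "clonal")

pipeline_log <- function(level, stage, msg, min_level = "info") {
  levels <- c(debug = 1L, info = 2L, warn = 3L)
  if (levels[[level]] >= levels[[min_level]]) {
    message(sprintf("[%s] %s: %s", level, stage, msg))
  }
}

require_inputs <- function(stage, paths) {
  missing <- paths[!file.exists(paths)]
  assert_that(length(missing) == 0L,
              sprintf("missing-dependency error in stage '%s': %s",
                      stage, paste(basename(missing), collapse = ", ")))
}

#' Load and validate a pipeline configuration
#'
#' The configuration is a single JSON object with a `cohort` block (any
#' [cohort_config()] argument) and optional per-stage threshold overrides,
#' all defaulting to the pipeline's standard values (consensus 2/3,
#' normal-panel 3 reads / 2 normals, enrichment log2 ratio 0.5, MSI 4
#' indels/Mb, reporting 15% with 500/50/10 minimums).
#'
#' @param config path to a JSON file or an equivalent named list.
#' @return validated configuration list.
#' @export
load_pipeline_config <- function(config) {
  if (is.character(config)) {
    assert_that(file.exists(config), "schema violation: config file not found")
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  assert_that(is.list(config), "schema violation: config must be a JSON object")
  defaults <- list(
    cohort = list(),
    tmb_effective_mb = 3100,
    panel_min_reads = 3, panel_min_normals = 2,
    sv_max_samples = 2,
    enrichment_threshold = 0.5,
    msi_threshold = 4.0,
    report_min_proportion = 0.15,
    join_min_markers = 50,
    exclusion_min_reads = 3,
    k_clusters = 2
  )
  unknown <- setdiff(names(config), names(defaults))
  assert_that(length(unknown) == 0L,
              paste0("schema violation: unknown config field(s) ",
                     paste(unknown, collapse = ", ")))
  utils::modifyList(defaults, config)
}

stage_simulate <- function(cfg, outdir, seed, log_level) {
  cohort_args <- cfg$cohort
  cohort_args$seed <- seed
  cc <- do.call(cohort_config, cohort_args)
  calls <- simulate_caller_calls(cc)
  dir.create(file.path(outdir, "calls"), showWarnings = FALSE)
  for (sid in calls$samples$sample_id) {
    obs <- calls$observations[calls$observations$sample_id == sid, ]
    write_caller_vcf(obs, file.path(outdir, "calls",
                                    paste0(sid, ".vcf")), cc$callers)
  }
  write_tsv(calls$normal_support, file.path(outdir, "normal_panel.tsv"))
  segments <- simulate_cn_segments(cc)
  write_tsv(segments, file.path(outdir, "segments.tsv"))
  telo <- simulate_telomere_profiles(cc)
  write_tsv(telo, file.path(outdir, "telomere.tsv"))
  sv <- simulate_sv_calls(cc)
  write_tsv(sv, file.path(outdir, "sv_calls.tsv"))
  write_tsv(simulate_msi_inputs(cc), file.path(outdir, "msi.tsv"))

  sigs <- load_synthetic_signatures()
  sample_ids <- calls$samples$sample_id
  catalogs <- vapply(seq_along(sample_ids), function(i) {
    simulate_signature_catalog(sigs, cc$signature_mix,
                               cc$n_catalog_mutations,
                               stream_seed(seed, "catalog") + i)$catalog
  }, numeric(nrow(sigs)))
  colnames(catalogs) <- sample_ids
  write_tsv(data.frame(class = rownames(sigs), catalogs,
                       check.names = FALSE),
            file.path(outdir, "catalog.tsv"))

  # one patient's recall grid for the clonal stage
  patient1 <- calls$samples$sample_id[calls$samples$patient_id ==
                                        calls$samples$patient_id[1]]
  seg1 <- segments[segments$sample_id %in% patient1, ]
  clonal <- simulate_clonal_reads(cc, seg1,
                                  n_variants = max(50L,
                                                   cc$n_true_variants %/% 4L))
  grid <- expand.grid(variant_id = clonal$truth$variant_ids,
                      sample_id = patient1, stringsAsFactors = FALSE)
  grid$alt <- clonal$matrix$alt[cbind(grid$variant_id, grid$sample_id)]
  grid$total <- clonal$matrix$total[cbind(grid$variant_id, grid$sample_id)]
  write_tsv(grid, file.path(outdir, "clonal_grid.tsv"))
  write_tsv(clonal$positions, file.path(outdir, "clonal_positions.tsv"))

  truth <- list(
    snv = calls$truth,
    clonal = list(phi = clonal$truth$phi,
                  assignment = clonal$truth$assignment),
    telomere = setNames(telo$scenario[telo$role == "tumour"],
                        telo$sample_id[telo$role == "tumour"])
  )
  jsonlite::write_json(truth, file.path(outdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cc)
}

stage_filter_snv <- function(cfg, outdir, log_level) {
  vcfs <- list.files(file.path(outdir, "calls"), "\\.vcf$",
                     full.names = TRUE)
  require_inputs("filter_snv",
                 c(file.path(outdir, "normal_panel.tsv"),
                   if (length(vcfs) == 0L) file.path(outdir, "calls")))
  obs <- do.call(rbind, lapply(vcfs, read_caller_vcf))
  callers <- c("vardict", "strelka2", "mutect2")
  status <- as.matrix(obs[, callers])
  obs$accepted <- rowSums(status == "pass") >= 2L
  accepted <- unique(obs$variant_id[obs$accepted])
  panel <- build_normal_panel_blacklist(
    read_tsv(file.path(outdir, "normal_panel.tsv")),
    min_reads = cfg$panel_min_reads, min_normals = cfg$panel_min_normals
  )
  ratio <- build_reject_ratio_blacklist(obs, callers)
  filtered <- apply_filters(accepted, list(panel, ratio))
  blk <- rbind(
    if (nrow(panel)) data.frame(variant_id = panel$variant_id,
                                source = panel$source),
    if (nrow(ratio)) data.frame(variant_id = ratio$variant_id,
                                source = ratio$source)
  )
  if (is.null(blk)) blk <- data.frame(variant_id = character(),
                                      source = character())
  write_tsv(blk, file.path(outdir, "snv_blacklist.tsv"))
  kept_obs <- obs[obs$accepted & obs$variant_id %in% filtered$kept, ]
  write_tsv(kept_obs[, c("variant_id", "chrom", "pos", "ref", "alt",
                         "sample_id", "alt_reads", "depth")],
            file.path(outdir, "filtered_snv.tsv"))
  tmb <- vapply(split(kept_obs$variant_id, kept_obs$sample_id), function(v) {
    tumour_mutation_burden(length(unique(v)), cfg$tmb_effective_mb)
  }, numeric(1))
  write_tsv(data.frame(sample_id = names(tmb), tmb_mut_per_mb = unname(tmb)),
            file.path(outdir, "tmb.tsv"))
  pipeline_log("info", "filter_snv",
               sprintf("%d accepted, %d blacklisted, %d kept",
                       length(accepted), nrow(blk),
                       length(filtered$kept)), log_level)
}

stage_filter_sv <- function(cfg, outdir, log_level) {
  path <- file.path(outdir, "sv_calls.tsv")
  require_inputs("filter_sv", path)
  calls <- read_tsv(path)
  blacklist <- build_sv_recurrence_blacklist(calls, cfg$sv_max_samples)
  candidates <- calls[calls$caller_status == "pass", ]
  kept <- apply_sv_filters(candidates, blacklist)
  write_tsv(kept, file.path(outdir, "filtered_sv.tsv"))
  write_tsv(data.frame(sv_key = blacklist),
            file.path(outdir, "sv_blacklist.tsv"))
  pipeline_log("info", "filter_sv",
               sprintf("%d candidates, %d kept", nrow(candidates),
                       nrow(kept)), log_level)
}

stage_fit_signatures <- function(cfg, outdir, log_level) {
  path <- file.path(outdir, "catalog.tsv")
  require_inputs("fit_signatures", path)
  tab <- read_tsv(path)
  catalogs <- as.matrix(tab[, -1, drop = FALSE])
  rownames(catalogs) <- tab$class
  sigs <- load_synthetic_signatures()
  exposures <- fit_exposures_matrix(catalogs, sigs)
  write_tsv(data.frame(signature = rownames(exposures), exposures,
                       check.names = FALSE),
            file.path(outdir, "exposures.tsv"))
  write_tsv(report_signatures(exposures, "SBS96",
                              cfg$report_min_proportion),
            file.path(outdir, "reported_signatures.tsv"))
}

stage_telomere <- function(cfg, outdir, log_level) {
  path <- file.path(outdir, "telomere.tsv")
  require_inputs("telomere", path)
  prof <- read_tsv(path)
  tum <- prof[prof$role == "tumour", ]
  blo <- prof[prof$role == "blood", ]
  blo <- blo[match(tum$sample_id, blo$sample_id), ]
  content_t <- telomere_content(tum$intratelomeric_reads,
                                tum$gc_matched_total_reads)
  content_b <- telomere_content(blo$intratelomeric_reads,
                                blo$gc_matched_total_reads)
  enr <- enrichment_ratio(content_t, content_b, cfg$enrichment_threshold)
  stats <- data.frame(
    sample_id = tum$sample_id,
    content_tumour = content_t,
    content_blood = content_b,
    log2_ratio = enr$log2_ratio,
    enriched = enr$enriched,
    canonical_proportion = canonical_tvr_proportion(
      tum$tvr_TTAGGG, tum$intratelomeric_reads),
    ccircle_status = tum$ccircle_status
  )
  write_tsv(stats, file.path(outdir, "telomere_stats.tsv"))
  tvr <- rbind(tvr_differential(prof, "total"),
               tvr_differential(prof, "intratelomeric"))
  write_tsv(tvr, file.path(outdir, "tvr_stats.tsv"))
}

stage_cn_msi <- function(cfg, outdir, log_level) {
  seg_path <- file.path(outdir, "segments.tsv")
  msi_path <- file.path(outdir, "msi.tsv")
  require_inputs("cn_msi", c(seg_path, msi_path))
  segments <- read_tsv(seg_path)
  write_gistic_seg(segments, file.path(outdir, "gistic_input.seg"),
                   cfg$join_min_markers)
  pga <- vapply(split(segments, segments$sample_id),
                percent_genome_altered, numeric(1))
  write_tsv(data.frame(sample_id = names(pga), pga_percent = unname(pga)),
            file.path(outdir, "pga.tsv"))
  msi_in <- read_tsv(msi_path)
  ms <- msi_score(msi_in$microsatellite_indel_count,
                  msi_in$callable_megabases, cfg$msi_threshold)
  write_tsv(data.frame(sample_id = msi_in$sample_id,
                       msi_score = ms$score, msi = ms$msi),
            file.path(outdir, "msi_scores.tsv"))
}

stage_clonal <- function(cfg, outdir, seed, log_level) {
  grid_path <- file.path(outdir, "clonal_grid.tsv")
  pos_path <- file.path(outdir, "clonal_positions.tsv")
  seg_path <- file.path(outdir, "segments.tsv")
  require_inputs("clonal", c(grid_path, pos_path, seg_path))
  grid <- read_tsv(grid_path)
  mat <- unify_and_exclude(grid, cfg$exclusion_min_reads)
  mat <- add_vrp(mat, read_tsv(pos_path), read_tsv(seg_path))
  model <- cluster_frequencies(mat, min(cfg$k_clusters, nrow(mat$alt)),
                               seed = stream_seed(seed, "tree"))
  long <- data.frame(
    variant_id = rep(mat$variant_ids, ncol(mat$alt)),
    sample_id = rep(mat$sample_ids, each = nrow(mat$alt)),
    alt = as.vector(mat$alt), total = as.vector(mat$total),
    vrp = as.vector(mat$vrp)
  )
  write_tsv(long, file.path(outdir, "clonal_matrix.tsv"))
  jsonlite::write_json(
    list(k = nrow(model$phi), phi = model$phi, pi = model$pi,
         assignment = as.list(model$assignment), loglik = model$loglik,
         excluded = mat$excluded$variant_id),
    file.path(outdir, "clone_model.json"), auto_unbox = TRUE, digits = NA
  )
  if (ncol(mat$alt) == 2L) {
    part <- partition_shared_private(mat, cfg$exclusion_min_reads)
    write_tsv(data.frame(shared = part$shared, private_a = part$private_a,
                         private_b = part$private_b),
              file.path(outdir, "partition.tsv"))
  }
  pipeline_log("info", "clonal",
               sprintf("%d variants retained, %d excluded, loglik %.2f",
                       nrow(mat$alt), nrow(mat$excluded), model$loglik),
               log_level)
}

#' Run the full demo pipeline
#'
#' Executes the seven stages — simulate, filter_snv, filter_sv,
#' fit_signatures, telomere, cn_msi, clonal — in dependency order against
#' one output directory and writes `manifest.json` recording the seed,
#' configuration digest and an MD5 digest of every output file. Re-running
#' with the same seed and configuration reproduces identical digests.
#'
#' @param config path to a JSON configuration or an equivalent list (see
#'   [load_pipeline_config()]).
#' @param outdir output directory (created if needed).
#' @param seed integer root seed.
#' @param log_level `"debug"`, `"info"` or `"warn"`.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, outdir, seed = 1L, log_level = "info") {
  cfg <- load_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  for (stage in .pipeline_stages) {
    pipeline_log("info", stage, "starting", log_level)
    switch(stage,
      simulate = stage_simulate(cfg, outdir, seed, log_level),
      filter_snv = stage_filter_snv(cfg, outdir, log_level),
      filter_sv = stage_filter_sv(cfg, outdir, log_level),
      fit_signatures = stage_fit_signatures(cfg, outdir, log_level),
      telomere = stage_telomere(cfg, outdir, log_level),
      cn_msi = stage_cn_msi(cfg, outdir, log_level),
      clonal = stage_clonal(cfg, outdir, seed, log_level)
    )
  }
  outputs <- setdiff(list.files(outdir, recursive = TRUE),
                     "manifest.json")
  digests <- tools::md5sum(file.path(outdir, outputs))
  manifest <- list(
    tool = paste0("pcpgsomatics ",
                  as.character(utils::packageVersion("pcpgsomatics"))),
    seed = seed,
    config_digest = unname(tools::md5sum(
      {
        tmp <- tempfile()
        jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
        tmp
      }
    )),
    stages = .pipeline_stages,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = as.list(setNames(unname(digests), outputs))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

cli_args <- function(argv) {
  flags <- list()
  i <- 1L
  while (i <= length(argv)) {
    if (startsWith(argv[i], "--")) {
      flags[[substring(argv[i], 3L)]] <- argv[i + 1L]
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  flags
}

#' Command-line entry point
#'
#' Dispatches the `pcpg-somatics` subcommands. `run` executes the full
#' pipeline; `simulate`, `filter-snv`, `filter-sv`, `fit-signatures`,
#' `telomere`, `gistic-prep`, `msi`, `pga`, `vrp`, `cluster` and
#' `partition` re-run individual stages against an existing output
#' directory. Global flags: `--config`, `--outdir`, `--seed`,
#' `--log-level`.
#'
#' @param argv character vector of arguments (defaults to the command
#'   line).
#' @return invisibly, the value of the dispatched stage.
#' @export
pcpg_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  assert_that(length(argv) >= 1L,
              "usage: pcpg-somatics <subcommand> [--config F] [--outdir D] [--seed N]")
  cmd <- argv[1]
  flags <- cli_args(argv[-1])
  outdir <- flags$outdir %||% "."
  seed <- as.integer(flags$seed %||% "1")
  log_level <- flags$`log-level` %||% "info"
  cfg <- load_pipeline_config(flags$config %||% list())
  result <- switch(cmd,
    run = run_pipeline(flags$config %||% list(), outdir, seed, log_level),
    simulate = stage_simulate(cfg, outdir, seed, log_level),
    `filter-snv` = stage_filter_snv(cfg, outdir, log_level),
    `filter-sv` = stage_filter_sv(cfg, outdir, log_level),
    `fit-signatures` = stage_fit_signatures(cfg, outdir, log_level),
    telomere = stage_telomere(cfg, outdir, log_level),
    `gistic-prep` = ,
    pga = ,
    msi = stage_cn_msi(cfg, outdir, log_level),
    vrp = ,
    cluster = ,
    partition = stage_clonal(cfg, outdir, seed, log_level),
    stop("unknown subcommand: ", cmd, call. = FALSE)
  )
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
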