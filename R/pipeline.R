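#' Pipeline configuration
#'
#' Collects all stage parameters with defaults matching the analysis
#' conventions used throughout the package: QC thresholds (>= 200 and
#' < 10,000 total UMIs, < 10% mitochondrial, >= 100 genes per cell, genes in
#' >= 3 cells, 3-MAD multiplet removal), 10,000-UMI log normalization, the
#' four default neuropeptide axes, 2.5-h smoothing, the 23.5-34.5 h initiated
#' period window and the RAE < 0.3 rhythmicity cutoff.
#'
#' @param out_dir directory for stage artifacts.
#' @param seed integer seed for stochastic stages.
#' @param qc list of QC thresholds (see [qc_thresholds()]).
#' @param scale_factor normalization scale factor.
#' @param k number of clusters.
#' @param cluster_method `"kmeans"` or `"graph"`.
#' @param de_alpha significance level for DE / marker calls.
#' @param axes list of [axis_spec]s.
#' @param smooth_window_h,baseline_window_h detrending parameters (h).
#' @param period_range initiated-period bounds (h).
#' @param rae_max RAE rhythmicity cutoff.
#' @param sc_config an [sc_sim_config] for the `simulate` stage.
#' @param rhythm_cfg a [rhythm_config] for the `rhythm` stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "chronocell_out", seed = 1L,
                            qc = qc_thresholds(), scale_factor = 1e4,
                            k = 2, cluster_method = "kmeans",
                            de_alpha = 0.05, axes = default_axes(),
                            smooth_window_h = 2.5, baseline_window_h = 24,
                            period_range = c(23.5, 34.5), rae_max = 0.3,
                            sc_config = NULL, rhythm_cfg = NULL) {
  stopifnot(scale_factor > 0, de_alpha > 0, smooth_window_h > 0,
            baseline_window_h > 0, rae_max > 0, length(axes) >= 1)
  structure(list(out_dir = out_dir, seed = as.integer(seed), qc = qc,
                 scale_factor = scale_factor, k = k,
                 cluster_method = cluster_method, de_alpha = de_alpha,
                 axes = axes, smooth_window_h = smooth_window_h,
                 baseline_window_h = baseline_window_h,
                 period_range = period_range, rae_max = rae_max,
                 sc_config = sc_config, rhythm_cfg = rhythm_cfg),
            class = "pipeline_config")
}

.manifest <- function(cfg, stage, inputs, outputs, extra = list()) {
  list(stage = stage,
       timestamp = format(Sys.time(), tz = "UTC"),
       seed = cfg$seed,
       package_version = as.character(utils::packageVersion("chronocell")),
       inputs = inputs, outputs = outputs, parameters = extra)
}

.write_manifest <- function(man, dir, stage) {
  path <- file.path(dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  path
}

.require_artifact <- function(path, stage_needed) {
  if (!file.exists(path))
    stop("missing artifact '", path, "': run stage '", stage_needed,
         "' first")
  path
}

#' Run a pipeline stage
#'
#' Stages: `simulate` writes a synthetic MTX triplet, ground truth and a
#' trace CSV; `qc` filters and normalizes the counts; `cluster` assigns and
#' scores clusters; `de` runs the day/night NB exact test; `topology` builds
#' the per-axis day/night networks; `rhythm` detrends and fits the trace.
#' Every stage writes its outputs plus a JSON run manifest (inputs,
#' parameters, seed, package version) under `cfg$out_dir`.
#'
#' @param cfg a [pipeline_config].
#' @param stage one of the stage names above.
#' @return The stage's main result object, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(cfg, stage = c("simulate", "qc", "cluster", "de",
                                        "topology", "rhythm")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- match.arg(stage)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- cfg$out_dir
  message("[chronocell] stage: ", stage)

  result <- switch(stage,
    simulate = {
      sc <- cfg$sc_config
      if (is.null(sc)) sc <- sc_sim_config(seed = cfg$seed)
      sim <- simulate_sc_counts(sc)
      write_mtx_triplet(sim$matrix, file.path(od, "raw"))
      utils::write.csv(sim$matrix$cell_meta, file.path(od, "cell_meta.csv"))
      jsonlite::write_json(sim["de_genes"], file.path(od, "truth.json"),
                           auto_unbox = TRUE)
      utils::write.csv(sim$truth, file.path(od, "truth_cells.csv"),
                       row.names = FALSE)
      rc <- cfg$rhythm_cfg
      if (is.null(rc)) rc <- rhythm_config(seed = cfg$seed)
      write_trace_csv(simulate_biolum_trace(rc), file.path(od, "trace.csv"))
      .write_manifest(.manifest(cfg, stage, list(), list(
        raw = file.path(od, "raw"), trace = file.path(od, "trace.csv"))), od,
        stage)
      sim
    },
    qc = {
      .require_artifact(file.path(od, "raw", "matrix.mtx"), "simulate")
      meta <- utils::read.csv(file.path(od, "cell_meta.csv"), row.names = 1)
      m <- read_mtx_triplet(file.path(od, "raw"), cell_meta = meta)
      fl <- filter_cells_and_genes(m, thresholds = cfg$qc)
      write_mtx_triplet(fl$matrix, file.path(od, "filtered"))
      write_qc_report(fl$cell_report, file.path(od, "qc_report.csv"))
      utils::write.csv(fl$matrix$cell_meta,
                       file.path(od, "cell_meta_filtered.csv"))
      .write_manifest(.manifest(cfg, stage, list(raw = file.path(od, "raw")),
                                list(filtered = file.path(od, "filtered")),
                                cfg$qc), od, stage)
      fl
    },
    cluster = {
      .require_artifact(file.path(od, "filtered", "matrix.mtx"), "qc")
      meta <- utils::read.csv(file.path(od, "cell_meta_filtered.csv"),
                              row.names = 1)
      m <- read_mtx_triplet(file.path(od, "filtered"), cell_meta = meta)
      norm <- normalize_counts(m, cfg$scale_factor)
      assign <- cluster_cells(norm, k = cfg$k, method = cfg$cluster_method,
                              seed = cfg$seed)
      cov <- condition_coverage(assign, m$cell_meta$condition)
      utils::write.csv(data.frame(barcode = names(assign$labels),
                                  cluster = assign$labels),
                       file.path(od, "clusters.csv"), row.names = FALSE)
      utils::write.csv(cov, file.path(od, "cluster_coverage.csv"),
                       row.names = FALSE)
      .write_manifest(.manifest(cfg, stage,
                                list(filtered = file.path(od, "filtered")),
                                list(clusters = file.path(od, "clusters.csv")),
                                list(k = cfg$k, method = cfg$cluster_method)),
                      od, stage)
      list(assignment = assign, coverage = cov)
    },
    de = {
      .require_artifact(file.path(od, "filtered", "matrix.mtx"), "qc")
      meta <- utils::read.csv(file.path(od, "cell_meta_filtered.csv"),
                              row.names = 1)
      m <- read_mtx_triplet(file.path(od, "filtered"), cell_meta = meta)
      conds <- unique(m$cell_meta$condition)
      if (length(conds) != 2)
        stop("day/night DE requires exactly 2 conditions, found ",
             length(conds))
      de <- nb_exact_test(m, which(m$cell_meta$condition == conds[1]),
                          which(m$cell_meta$condition == conds[2]))
      utils::write.csv(de, file.path(od, "de_results.csv"), row.names = FALSE)
      .write_manifest(.manifest(cfg, stage,
                                list(filtered = file.path(od, "filtered")),
                                list(de = file.path(od, "de_results.csv")),
                                list(group_a = conds[1], group_b = conds[2],
                                     alpha = cfg$de_alpha)), od, stage)
      de
    },
    topology = {
      .require_artifact(file.path(od, "clusters.csv"), "cluster")
      meta <- utils::read.csv(file.path(od, "cell_meta_filtered.csv"),
                              row.names = 1)
      m <- read_mtx_triplet(file.path(od, "filtered"), cell_meta = meta)
      cl <- utils::read.csv(file.path(od, "clusters.csv"))
      labels <- cl$cluster
      names(labels) <- cl$barcode
      conds <- sort(unique(m$cell_meta$condition))
      nets <- list()
      for (ax in cfg$axes) {
        if (!all(c(ax$ligand_gene, ax$receptor_gene) %in% gene_names(m)))
          next
        per_cond <- lapply(conds, function(cc) {
          sel <- m$cell_meta$condition == cc
          sub <- m[, sel]
          a <- structure(list(labels = as.integer(factor(labels[sel])),
                              k = length(unique(labels[sel])),
                              method = cfg$cluster_method, seed = cfg$seed),
                         class = "cluster_assignment")
          axis_network(sub, a, ax, condition = cc)
        })
        names(per_cond) <- conds
        if (length(conds) == 2) {
          cmp <- compare_networks(per_cond[[1]], per_cond[[2]])
          per_cond <- list(cmp$day, cmp$night)
          names(per_cond) <- conds
        }
        for (cc in conds)
          export_network(per_cond[[cc]],
                         graphml = file.path(od, sprintf("net_%s_%s.graphml",
                                                         ax$name, cc)),
                         json = file.path(od, sprintf("net_%s_%s.json",
                                                      ax$name, cc)))
        nets[[ax$name]] <- per_cond
      }
      .write_manifest(.manifest(cfg, stage,
                                list(clusters = file.path(od, "clusters.csv")),
                                list(networks = names(nets))), od, stage)
      nets
    },
    rhythm = {
      .require_artifact(file.path(od, "trace.csv"), "simulate")
      tr <- read_trace_csv(file.path(od, "trace.csv"))
      fit <- fit_rhythm(detrend_and_smooth(tr, cfg$baseline_window_h,
                                           cfg$smooth_window_h))
      res <- data.frame(period_h = fit$period_h, phase_h = fit$phase_h,
                        amplitude = fit$amplitude, rae = fit$rae,
                        gof = fit$gof, initiated = fit$initiated)
      utils::write.csv(res, file.path(od, "rhythm_fit.csv"),
                       row.names = FALSE)
      .write_manifest(.manifest(cfg, stage,
                                list(trace = file.path(od, "trace.csv")),
                                list(fit = file.path(od, "rhythm_fit.csv")),
                                list(smooth_window_h = cfg$smooth_window_h,
                                     baseline_window_h = cfg$baseline_window_h,
                                     period_range = cfg$period_range,
                                     rae_max = cfg$rae_max)), od, stage)
      fit
    })
  invisible(result)
}
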