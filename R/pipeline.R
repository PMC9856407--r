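#' Default run configuration
#'
#' Assembles the shipped scenario, panel, gating tree, default geometry and
#' zones, ROI and statistics settings, and the hotspot populations
#' (cytotoxic N1 neutrophils and galectin-3-positive cells) into a run
#' configuration for [run_pipeline()].
#'
#' @param master_seed Master seed; every stage derives its own sub-seed from
#'   it. Default 1.
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function(master_seed = 1) {
  structure(list(
    master_seed = as.integer(master_seed),
    scenario = default_scenario(),
    panel = default_marker_panel(),
    gating_tree = default_gating_tree(),
    geometry = device_geometry(),
    zones = zone_config(),
    rois = list(n_per_zone = 6, diameter_range = c(110, 220),
                zones = c("proximal", "border", "distal", "remote")),
    stats = list(tails = "one", reporting_threshold = 0.01, bh_adjust = FALSE),
    cluster = list(d_list = c(30, 50, 75), min_cells = 10,
                   populations = list(
                     list(name = "n1_neutrophil", cell_type = "n1_neutrophil"),
                     list(name = "Gal3_positive", flag = "Gal3")))
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' File paths inside the YAML (`scenario`, `panel`, `gating_tree`,
#' `cell_table`) are resolved relative to the YAML file. Omitted components
#' fall back to the shipped defaults.
#'
#' @param path Path to a YAML run configuration.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  dir <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p) || file.exists(p)) p else file.path(dir, p)
  cfg <- default_run_config(raw$master_seed %||% 1)
  if (!is.null(raw$scenario)) cfg$scenario <- read_scenario(resolve(raw$scenario))
  if (!is.null(raw$panel)) cfg$panel <- read_marker_panel(resolve(raw$panel))
  if (!is.null(raw$gating_tree))
    cfg$gating_tree <- read_gating_tree(resolve(raw$gating_tree), cfg$panel)
  if (!is.null(raw$cell_table)) cfg$cell_table <- resolve(raw$cell_table)
  if (!is.null(raw$geometry))
    cfg$geometry <- do.call(device_geometry, lapply(raw$geometry, unlist))
  if (!is.null(raw$zones))
    cfg$zones <- zone_config(unlist(raw$zones$names), unlist(raw$zones$boundaries))
  for (f in intersect(names(raw), c("rois", "stats", "cluster")))
    cfg[[f]] <- utils::modifyList(cfg[[f]], raw[[f]])
  cfg
}

#' Validate a run configuration
#'
#' Schema check of all nested components; returns a human-readable list of
#' problems rather than stopping at the first.
#'
#' @param config A `run_config` list, or a path to a YAML run configuration.
#' @return Character vector of diagnostics; empty when the config is valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) return(sprintf("config file '%s' not found", config))
    config <- tryCatch(read_run_config(config), error = function(e) e)
    if (inherits(config, "error"))
      return(sprintf("config failed to load: %s", conditionMessage(config)))
  }
  errs <- character()
  errs <- c(errs, validate_scenario(config$scenario))
  zb <- config$zones$boundaries
  if (is.null(zb) || any(diff(zb) <= 0))
    errs <- c(errs, "ZoneConfig: zone boundaries must be strictly increasing")
  if (length(config$zones$names) + 1 != length(zb))
    errs <- c(errs, "ZoneConfig: need one more boundary than zone names")
  tr <- tryCatch({ as_gating_tree(unclass(config$gating_tree), config$panel); NULL },
                 error = function(e) conditionMessage(e))
  if (!is.null(tr)) errs <- c(errs, tr)
  dr <- config$rois$diameter_range
  if (length(dr) != 2 || dr[1] > dr[2] || dr[1] <= 0)
    errs <- c(errs, "rois$diameter_range must be two increasing positive lengths")
  if (any(diff(config$cluster$d_list) <= 0))
    errs <- c(errs, "cluster$d_list must be strictly increasing")
  if (config$cluster$min_cells < 2)
    errs <- c(errs, "cluster$min_cells must be >= 2")
  if (!is.null(config$cell_table) && !file.exists(config$cell_table))
    errs <- c(errs, sprintf("cell_table '%s' not found", config$cell_table))
  errs
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate (or load) -> gate -> classify -> zone -> ROI
#' enrichment vs matched control -> multi-scale hotspot clustering with
#' treatment-specificity verdicts, all randomness derived from the master
#' seed. No stage mutates an earlier stage's table; each stage output is a
#' new object, and all tables can be written to `out_dir`.
#'
#' @param config A `run_config` (see [default_run_config()],
#'   [read_run_config()]).
#' @param out_dir Optional output directory; created if missing. Writes
#'   `cells.csv`, `control_cells.csv`, `enrichment.csv`, `zone_rates.csv`
#'   (heatmap-ready combination x zone matrix), `clusters_<pop>.csv`, and
#'   `report.json`.
#' @return A list of class `run_report`: configuration echo, seeds, per-stage
#'   counts, enrichment table, cluster summaries and specificity verdicts.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  errs <- validate_config(config)
  if (length(errs)) stopf("invalid run config: %s", paste(errs, collapse = "; "))
  seed <- as.integer(config$master_seed)
  seeds <- list(generate = seed, control = seed + 1L, roi_base = seed + 100L,
                labels = seed + 900L)

  # stage: synthetic scene (or user cell table) + matched control
  scene <- generate_scene(config$scenario, config$geometry, config$zones,
                          config$panel, seed = seeds$generate)
  ctrl <- generate_control_region(config$scenario, config$geometry, config$zones,
                                  config$panel, seed = seeds$control,
                                  n_cells = nrow(scene$cells))

  # stage: gating and classification
  assay <- classify(compute_positivity(scene$cells, config$panel),
                    config$gating_tree, config$panel)
  control <- classify(compute_positivity(ctrl$cells, config$panel),
                      config$gating_tree, config$panel)
  control$zone <- "control"

  # stage: zonal stratification
  assay <- assign_zones(assay, config$geometry, config$zones)

  # stage: combination rates and reportable set
  combos <- enumerate_combinations(config$panel,
                                   gating_tree_types(config$gating_tree))
  zone_rates <- combination_rates(assay, combos, by = "zone")
  reportable <- filter_reportable(zone_rates, config$stats$reporting_threshold)

  # stage: paired ROI enrichment per zone
  enrich <- list()
  for (zi in seq_along(config$rois$zones)) {
    z <- config$rois$zones[zi]
    rep_z <- reportable[reportable$zone == z, , drop = FALSE]
    if (!nrow(rep_z)) next
    cz <- tibble::tibble(marker = rep_z$marker, cell_type = rep_z$cell_type)
    a_roi <- sample_rois(z, config$rois$n_per_zone, config$rois$diameter_range,
                         seed = seeds$roi_base + 2L * zi,
                         geometry = config$geometry, zones = config$zones)
    c_roi <- sample_rois("control", config$rois$n_per_zone,
                         config$rois$diameter_range,
                         seed = seeds$roi_base + 2L * zi + 1L,
                         geometry = config$geometry, zones = config$zones)
    ar <- roi_rates(assay, a_roi, cz)
    cr <- roi_rates(control, c_roi, cz)
    for (j in seq_len(nrow(cz))) {
      sel <- function(tb) tb$rate[tb$marker %in% cz$marker[j] &
                                    tb$cell_type == cz$cell_type[j]]
      ht <- suppressWarnings(enrichment_test(sel(ar), sel(cr),
                                             tails = config$stats$tails))
      enrich[[length(enrich) + 1L]] <- data.frame(
        zone = z, marker = cz$marker[j], cell_type = cz$cell_type[j],
        assay_rate = mean(sel(ar)), control_rate = mean(sel(cr)),
        t = ht$t %||% NA_real_, p = ht$p, stringsAsFactors = FALSE)
    }
  }
  enrich <- tibble::as_tibble(do.call(rbind, enrich))
  if (isTRUE(config$stats$bh_adjust) && nrow(enrich))
    enrich$p_adj <- stats::p.adjust(enrich$p, method = "BH")

  # stage: multi-scale hotspot clustering per population
  clusters <- list()
  for (pop in config$cluster$populations) {
    sub <- if (!is.null(pop$cell_type)) assay[assay$cell_type == pop$cell_type, ]
           else assay[assay[[flag_col(pop$flag)]], ]
    ms <- multiscale_cluster(sub, config$cluster$d_list,
                             config$cluster$min_cells, label_seed = seeds$labels)
    spec <- lapply(ms$results, cluster_specificity)
    ms$summary$treatment_specific <-
      vapply(spec, function(s) s$treatment_specific, FALSE)
    clusters[[pop$name]] <- list(multiscale = ms, specificity = spec,
                                 n_cells = nrow(sub))
  }

  report <- structure(list(
    package_version = as.character(packageVersion("mimaspat")),
    master_seed = seed, seeds = seeds,
    zone_boundaries = setNames(as.list(config$zones$boundaries),
                               c(config$zones$names, "outer")),
    counts = list(
      assay_cells = nrow(assay), control_cells = nrow(control),
      per_zone = as.list(table(assay$zone)),
      per_type = as.list(table(assay$cell_type))),
    n_combinations = nrow(combos),
    n_reportable = nrow(reportable),
    enrichment = enrich,
    cluster_summary = lapply(clusters, function(cl)
      cbind(population_cells = cl$n_cells, cl$multiscale$summary)),
    treatment_specific = lapply(clusters, function(cl)
      setNames(cl$multiscale$summary$treatment_specific,
               cl$multiscale$summary$d_max))
  ), class = "run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(assay, file.path(out_dir, "cells.csv"), row.names = FALSE)
    write.csv(control, file.path(out_dir, "control_cells.csv"), row.names = FALSE)
    write.csv(enrich, file.path(out_dir, "enrichment.csv"), row.names = FALSE)
    hm <- stats::reshape(as.data.frame(zone_rates[, c("zone", "marker", "cell_type", "rate")]),
                         idvar = c("marker", "cell_type"), timevar = "zone",
                         direction = "wide")
    names(hm) <- sub("^rate\\.", "", names(hm))
    write.csv(hm, file.path(out_dir, "zone_rates.csv"), row.names = FALSE)
    for (nm in names(clusters))
      write.csv(clusters[[nm]]$multiscale$results[[2]]$cells[
        , c("cell_id", "x_um", "y_um", "zone", "cluster_id")],
        file.path(out_dir, paste0("clusters_", nm, ".csv")), row.names = FALSE)
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

report_to_json <- function(report) {
  r <- unclass(report)
  r$enrichment <- as.data.frame(r$enrichment)
  r$cluster_summary <- lapply(r$cluster_summary, as.data.frame)
  r$treatment_specific <- lapply(r$treatment_specific, as.list)
  r
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed %d: %d assay cells / %d control cells\n",
              x$master_seed, x$counts$assay_cells, x$counts$control_cells))
  cat(sprintf("  %d combinations, %d reportable, %d enrichment tests\n",
              x$n_combinations, x$n_reportable, nrow(x$enrichment)))
  for (nm in names(x$treatment_specific))
    cat(sprintf("  hotspots[%s]: treatment-specific at d = {%s}\n", nm,
                paste(names(which(x$treatment_specific[[nm]])), collapse = ", ")))
  invisible(x)
}
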