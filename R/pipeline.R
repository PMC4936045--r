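# End-to-end orchestration: simulate (or load) -> prepare -> home ranges and
# availability -> design table -> candidate ranking -> interaction importance
# -> reports, every stage's output written to the run directory.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline in one object. All thresholds must
#' be positive; the seed drives every random stage and is recorded alongside
#' a configuration hash in the run directory.
#'
#' @param seed Integer master seed.
#' @param truth A [truth_config()] (synthetic mode).
#' @param grid,lconfig Landscape grid and generator configuration.
#' @param season_start Analysis season start ("MM-DD").
#' @param dop_threshold DOP filter cutoff.
#' @param min_days,min_fixes Minimum-data rule thresholds.
#' @param availability_order `"third"` (within MCP) or `"second"` (study
#'   area).
#' @param cluster_min_run,cluster_radius GPS cluster-site parameters.
#' @param candidate_groups Thematic term groups for
#'   [build_candidate_set()].
#' @param vif_cutoff Collinearity cutoff.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            truth = truth_config(),
                            grid = grid_spec(400, 400, cell_size = 25),
                            lconfig = landscape_config(),
                            season_start = "05-01",
                            dop_threshold = 5,
                            min_days = 2, min_fixes = 50,
                            availability_order = "third",
                            cluster_min_run = 3, cluster_radius = 15,
                            candidate_groups = NULL,
                            vif_cutoff = 3) {
  stopifnot(dop_threshold > 0, min_days > 0, min_fixes > 0,
            cluster_min_run > 0, cluster_radius > 0, vif_cutoff > 0)
  structure(list(seed = as.integer(seed), truth = truth, grid = grid,
                 lconfig = lconfig, season_start = season_start,
                 dop_threshold = dop_threshold, min_days = min_days,
                 min_fixes = min_fixes,
                 availability_order = availability_order,
                 cluster_min_run = cluster_min_run,
                 cluster_radius = cluster_radius,
                 candidate_groups = candidate_groups,
                 vif_cutoff = vif_cutoff),
            class = "pipeline_config")
}

config_hash <- function(config) {
  s <- yaml::as.yaml(rapply(unclass(config), function(x)
    if (is.numeric(x)) signif(x, 12) else x, how = "replace"))
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2^31
  sprintf("%08x", h)
}

write_csv_plain <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Run the pipeline end to end
#'
#' Executes simulate -> prepare -> home ranges / availability -> design table
#' -> VIF screen -> candidate ranking -> interaction importance -> reports,
#' writing each stage's tables (CSV), the exclusion log, the coefficient and
#' importance figures (PDF) and a `run_info.yaml` with the seed and a
#' configuration hash. Re-running with the same configuration and seed
#' reproduces every output byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created if missing).
#' @param study Optional pre-built `simulated_study` (otherwise synthetic
#'   data are generated from `config`).
#' @param stop_after Run only up to this stage: one of `"simulate"`,
#'   `"prep"`, `"homerange"`, `"build-table"`, `"select"`, `"report"`.
#' @param write_figures Write PDF figures (default TRUE).
#' @return Invisibly, a list with every stage's object (`study`, `prep`,
#'   `home_ranges`, `table`, `vif`, `selection`, `importance`,
#'   `coefficients`, `summaries`) and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("rsfate_run_"),
                         study = NULL, stop_after = "report",
                         write_figures = TRUE) {
  stages <- c("simulate", "prep", "homerange", "build-table", "select", "report")
  stop_after <- match.arg(stop_after, stages)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  info <- list(seed = config$seed, config_hash = config_hash(config))
  yaml::write_yaml(info, file.path(out_dir, "run_info.yaml"))
  res <- list(out_dir = out_dir)
  done <- function(stage) match(stage, stages) >= match(stop_after, stages)

  message("[simulate] generating synthetic study (seed ", config$seed, ")")
  if (is.null(study))
    study <- simulate_study(truth = config$truth, grid = config$grid,
                            lconfig = config$lconfig, seed = config$seed)
  res$study <- study
  write_csv_plain(telemetry_table(study$bear_years),
                  file.path(out_dir, "telemetry.csv"))
  write_csv_plain(fate_table(study$bear_years),
                  file.path(out_dir, "fates.csv"))
  if (done("simulate")) return(invisible(res))

  message("[prep] DOP filter, end dates, truncation")
  prep <- prepare_study(study$bear_years, season_start = config$season_start,
                        dop_threshold = config$dop_threshold,
                        min_days = config$min_days,
                        min_fixes = config$min_fixes,
                        seed = config$seed + 1L)
  res$prep <- prep
  write_csv_plain(prep$exclusions, file.path(out_dir, "exclusions.csv"))
  counts <- tibble::tibble(
    bear_id = vapply(prep$bear_years, function(b) b$bear_id, ""),
    year = vapply(prep$bear_years, function(b) b$year, 1L),
    fate = vapply(prep$bear_years, function(b) b$fate, ""),
    n_fixes = vapply(prep$bear_years, function(b) nrow(b$relocations), 0L),
    fix_rate = vapply(prep$bear_years, function(b) b$fix_rate, 0))
  write_csv_plain(counts, file.path(out_dir, "bear_year_counts.csv"))
  if (done("prep")) return(invisible(res))

  message("[homerange] 100% MCP and matched availability")
  # annual MCP: hull over the DOP-filtered fixes of the whole monitoring
  # window, not only the truncated season
  annual <- study$bear_years
  for (i in seq_along(annual))
    annual[[i]]$relocations <- filter_dop(annual[[i]]$relocations,
                                          config$dop_threshold)
  keys_kept <- vapply(prep$bear_years, function(b)
    paste0(b$bear_id, "/", b$year), "")
  annual <- Filter(function(b)
    paste0(b$bear_id, "/", b$year) %in% keys_kept, annual)
  hr <- mcp_home_ranges(annual)
  avail <- sample_study_availability(prep$bear_years, hr,
                                    order = config$availability_order,
                                    seed = config$seed + 2L)
  res$home_ranges <- hr
  res$availability <- avail
  write_geojson_polygons(hr, file.path(out_dir, "home_ranges.geojson"))
  if (done("homerange")) return(invisible(res))

  message("[build-table] covariate extraction and standardization")
  tab <- build_use_avail_table(prep$bear_years, avail, study$landscape)
  res$table <- tab
  write_csv_plain(tab, file.path(out_dir, "use_avail_table.csv"))
  yaml::write_yaml(as.list(attr(tab, "standardization")),
                   file.path(out_dir, "standardization.yaml"))
  if (done("build-table")) return(invisible(res))

  message("[select] VIF screen, candidate ranking, interaction importance")
  # VIF screen over the continuous landscape covariates; dummy indicators of
  # the single land-cover factor are mutually correlated by construction and
  # are not screened against each other
  predictors <- intersect(continuous_covariates(), colnames(tab))
  vif <- compute_vif(tab, predictors)
  res$vif <- vif
  write_csv_plain(tibble::tibble(term = names(vif), vif = as.numeric(vif)),
                  file.path(out_dir, "vif.csv"))
  cset <- if (is.null(config$candidate_groups))
    build_candidate_set(vif = vif, vif_cutoff = config$vif_cutoff)
  else build_candidate_set(groups = config$candidate_groups, vif = vif,
                           vif_cutoff = config$vif_cutoff)
  sel <- rank_models(tab, cset)
  res$selection <- sel
  write_csv_plain(sel, file.path(out_dir, "selection.csv"))
  best_label <- sel$label[1]
  best_spec <- Filter(function(s) s$label == best_label, cset)[[1]]
  best_fit <- attr(sel, "fits")[[best_label]]
  res$best_fit <- best_fit
  if (length(best_spec$interaction_terms)) {
    imp <- interaction_importance(tab, best_spec, full_fit = best_fit)
    res$importance <- imp
    write_csv_plain(imp, file.path(out_dir, "importance.csv"))
  }
  write_csv_plain(coef_table(best_fit), file.path(out_dir, "coefficients.csv"))
  if (done("select")) return(invisible(res))

  message("[report] figures and habitat-use summaries")
  cr <- report_coefficients(best_fit)
  res$coefficients <- cr$table
  write_csv_plain(cr$table, file.path(out_dir, "coefficients_by_group.csv"))
  summaries <- use_summaries(tab)
  res$summaries <- summaries
  write_csv_plain(summaries, file.path(out_dir, "use_summaries.csv"))
  if (write_figures) {
    grDevices::pdf(file.path(out_dir, "fig_coefficients.pdf"), 7, 5)
    print(cr$plot)
    grDevices::dev.off()
    if (!is.null(res$importance)) {
      ir <- report_importance(res$importance)
      grDevices::pdf(file.path(out_dir, "fig_importance.pdf"), 7, 5)
      print(ir$plot)
      grDevices::dev.off()
    }
  }
  invisible(res)
}
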