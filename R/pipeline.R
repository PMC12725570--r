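#' Prepare the HUC-12 predictor table for the forest stage
#'
#' Numeric cleaning between the linkage and modelling stages: id columns
#' are dropped; percent-change columns undefined because a class was absent
#' historically are imputed to zero (the paired presence-change column
#' carries the gain signal); class columns absent from a HUC-12's pair of
#' networks altogether are zero (no change); rows with remaining missing
#' condition values are dropped with a logged count.
#'
#' @param huc_table output of [build_huc12_table()]
#' @return list: `x` (numeric predictor data frame), `huc12_id` (kept rows)
#' @export
prepare_rf_predictors <- function(huc_table) {
  id_cols <- c("huc12_id", "ecoregion_id", "hist_fcn_id", "curr_fcn_id")
  x <- huc_table[setdiff(names(huc_table), id_cols)]
  for (nm in grep("_km_pctchg$|_presence_chg$", names(x), value = TRUE)) {
    x[[nm]][is.na(x[[nm]])] <- 0
  }
  ok <- stats::complete.cases(x)
  if (any(!ok)) {
    message(sum(!ok), " HUC-12 row(s) dropped for missing condition values")
  }
  list(x = x[ok, , drop = FALSE], huc12_id = huc_table$huc12_id[ok])
}

#' Run the full analysis pipeline on a dataset
#'
#' Executes every stage in order: network validation and small-reach
#' filtering, barrier-scenario delineation (historical and current),
#' habitat classification and per-FCN richness/rarity metrics (grouped by
#' ecoregion), HUC-12 linkage, per-site temporal beta-diversity with
#' permutation significance, the loss/gain dominance test, per-species
#' paired tests, and the spatial random-forest attribution stage. Stage
#' outputs are written as CSV under `out_dir` as each stage completes;
#' a structured JSON report closes the run. All randomness derives from
#' `seed`; a rerun with the same inputs and seed is identical.
#'
#' @param net a `river_network` (already loaded/validated)
#' @param barriers a validated barrier data frame
#' @param communities a [community_pair()] whose sites are HUC-12 ids
#' @param centroids data frame `huc12_id`, `x`, `y` (planar units)
#' @param schema a [habitat_schema()]
#' @param out_dir output directory (created if needed), or `NULL` to skip
#'   writing files
#' @param min_area_km2 drainage-area floor for [filter_small_reaches()]
#' @param n_perm permutations for the TBI and species tests
#' @param alpha significance level
#' @param correction multiple-testing correction for the species tests
#' @param rf_runs repeated final forest fits
#' @param rf_thresholds distance thresholds (`NULL` = distance quartiles)
#' @param seed integer seed
#' @param run_species_tests run the per-species permutation tests (the
#'   slowest optional stage)
#' @return a `fcnflow_report` list with all stage outputs
#' @export
run_pipeline <- function(net, barriers, communities, centroids,
                         schema = habitat_schema(pass_through = character(0)),
                         out_dir = NULL, min_area_km2 = 2.5, n_perm = 999,
                         alpha = 0.05, correction = "holm", rf_runs = 30,
                         rf_thresholds = NULL, seed = 1,
                         run_species_tests = FALSE) {
  stopifnot(inherits(net, "river_network"),
            inherits(communities, "community_pair"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE, na = "")
    }
  }

  net <- filter_small_reaches(net, min_area_km2)
  barriers <- barriers[barriers$reach_id %in% net$reaches$reach_id, ,
                       drop = FALSE]

  parts <- list(
    historical = delineate_fcns(
      net, select_barriers(barriers, scenario("historical")), "historical"),
    current = delineate_fcns(
      net, select_barriers(barriers, scenario("current")), "current"))
  fcn_summary <- do.call(rbind, lapply(names(parts), function(nm) {
    s <- summarize_fcns(parts[[nm]])
    s$scenario <- nm
    s
  }))
  emit(fcn_summary, "fcn_summary")
  emit(rbind(cbind(parts$historical$membership, scenario = "historical"),
             cbind(parts$current$membership, scenario = "current")),
       "fcn_membership")

  classes <- classify_reaches(net, schema)
  habs <- lapply(parts, function(p) {
    h <- habitat_presence(p, net, classes, schema)
    eco <- p$fcns$ecoregion_id[match(h$fcn_id, p$fcns$fcn_id)]
    h <- rarity_weighted_richness(h, groups = eco)
    h$rwr_z <- zscore_by_group(h$rwr, eco)
    h
  })
  emit(rbind(habs$historical, habs$current), "fcn_habitat")

  huc_table <- build_huc12_table(net, parts$historical, parts$current,
                                 habs$historical, habs$current, schema)
  emit(huc_table, "huc12_predictors")

  tbi <- tbi_permutation_test(communities, n_perm = n_perm, seed = seed,
                              alpha = alpha)
  emit(tbi, "tbi_results")
  dominance <- dominance_test(tbi, n_perm = n_perm, seed = seed + 1,
                              alpha = alpha)
  species <- if (run_species_tests) {
    species_paired_tests(communities, n_perm = n_perm, seed = seed + 2,
                         correction = correction)
  } else {
    occupancy_change(communities)
  }
  emit(species, "species_change")

  prep <- prepare_rf_predictors(huc_table)
  common <- intersect(intersect(prep$huc12_id, tbi$site[!is.na(tbi$D)]),
                      centroids$huc12_id)
  xi <- prep$x[match(common, prep$huc12_id), , drop = FALSE]
  yi <- tbi$D[match(common, tbi$site)]
  ci <- as.matrix(centroids[match(common, centroids$huc12_id), c("x", "y")])
  pruned <- prune_predictors(xi, yi, preference = "total_km_pctchg")
  runset <- fit_spatial_rf(xi[pruned$kept], yi, ci,
                           thresholds = rf_thresholds, n_runs = rf_runs,
                           seed = seed + 3)
  ranking <- importance_ranking(runset)
  emit(ranking, "rf_importance")
  emit(runset$residual_moran, "rf_residual_moran")

  report <- structure(list(
    stages = c("validate", "delineate", "habitat", "link", "tbi", "rf"),
    n_reaches = nrow(net$reaches),
    fcn_summary = fcn_summary,
    tbi = list(mean_D = mean(tbi$D, na.rm = TRUE),
               mean_B = dominance$mean_B, mean_C = dominance$mean_C,
               n_significant = sum(tbi$significant, na.rm = TRUE),
               dominance = dominance),
    rf = list(oob_r2_median = stats::median(runset$oob_r2),
              oob_r2_mad = stats::mad(runset$oob_r2),
              spatial_predictors = runset$spatial_predictors_used,
              top_predictors = utils::head(ranking, 8)),
    pruned_out = pruned$removed,
    seed = seed),
    class = "fcnflow_report")
  if (!is.null(out_dir)) {
    write_report(report, file.path(out_dir, "report.json"))
  }
  out <- list(net = net, parts = parts, habitat = habs,
              huc_table = huc_table, tbi = tbi, dominance = dominance,
              species = species, runset = runset, ranking = ranking,
              report = report)
  invisible(out)
}

#' Serialize a pipeline report to JSON
#'
#' @param report a `fcnflow_report`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass_deep_(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null",
                       dataframe = "rows")
  invisible(path)
}

unclass_deep_ <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    lapply(unclass(x), unclass_deep_)
  } else {
    x
  }
}
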