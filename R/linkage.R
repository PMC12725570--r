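#' Longest FCN intersecting each HUC-12
#'
#' Several FCNs can cross one HUC-12 subwatershed; the subwatershed is
#' characterized by the longest one (total stream km, not reach count).
#' Length ties break to the smallest `fcn_id` and are logged.
#'
#' @param part a `fcn_partition`
#' @param net the `river_network` carrying `huc12_id` per reach
#' @return data frame `huc12_id`, `fcn_id`, `fcn_length_km`
#' @export
longest_fcn_per_huc12 <- function(part, net) {
  stopifnot(inherits(part, "fcn_partition"), inherits(net, "river_network"))
  m <- merge(part$membership, net$reaches[c("reach_id", "huc12_id")],
             by = "reach_id")
  cand <- unique(m[c("huc12_id", "fcn_id")])
  cand$fcn_length_km <-
    part$fcns$total_length_km[match(cand$fcn_id, part$fcns$fcn_id)]
  # order so the first row per huc12 is the longest, ties to smallest fcn_id
  cand <- cand[order(cand$huc12_id, -cand$fcn_length_km, cand$fcn_id), ]
  dup <- duplicated(cand$huc12_id)
  ties <- tapply(cand$fcn_length_km, cand$huc12_id,
                 function(x) length(x) > 1 && x[1] == x[2])
  if (any(ties)) {
    message(sum(ties), " HUC-12(s) with tied longest-FCN lengths; ",
            "smallest fcn_id kept")
  }
  out <- cand[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Historic-to-current habitat change predictors
#'
#' For a pair of FCN habitat summaries (the longest historical and current
#' FCN of one HUC-12): per habitat class, the percent change in class
#' length (negative = loss from the historic network), defined only when
#' the class had positive historic length; a presence change in
#' \{-1, 0, +1\}; the percent change in total network length
#' (`total_km_pctchg`, the fragmentation measure); and the change in the
#' rarity-weighted-richness z-score when both are supplied.
#'
#' @param hist_lengths named numeric, historic class lengths (km)
#' @param curr_lengths named numeric, current class lengths (km)
#' @param hist_presence,curr_presence character vectors of present classes
#' @param hist_total,curr_total total FCN lengths (km)
#' @param hist_rwr_z,curr_rwr_z optional RWR z-scores
#' @return named list of predictors: `<class>_km_pctchg`,
#'   `<class>_presence_chg`, `total_km_pctchg`, and optionally `rwr_z_chg`.
#'   A class absent historically but present currently has an undefined
#'   percent change (`NA`, logged); its `+1` presence change carries the
#'   signal.
#' @export
habitat_change_predictors <- function(hist_lengths, curr_lengths,
                                      hist_presence, curr_presence,
                                      hist_total, curr_total,
                                      hist_rwr_z = NULL, curr_rwr_z = NULL) {
  classes <- sort(union(names(hist_lengths), names(curr_lengths)))
  h <- ifelse(classes %in% names(hist_lengths),
              as.numeric(hist_lengths[classes]), 0)
  k <- ifelse(classes %in% names(curr_lengths),
              as.numeric(curr_lengths[classes]), 0)
  pct <- ifelse(h > 0, 100 * (k - h) / h, NA_real_)
  n_undef <- sum(h == 0 & k > 0)
  if (n_undef > 0L) {
    message(n_undef, " class(es) gained from zero historic length; ",
            "percent change undefined (presence change carries the signal)")
  }
  pres <- as.integer(classes %in% curr_presence) -
    as.integer(classes %in% hist_presence)
  out <- c(stats::setNames(as.list(pct), paste0(classes, "_km_pctchg")),
           stats::setNames(as.list(pres), paste0(classes, "_presence_chg")),
           list(total_km_pctchg = 100 * (curr_total - hist_total) / hist_total))
  if (!is.null(hist_rwr_z) && !is.null(curr_rwr_z)) {
    out$rwr_z_chg <- curr_rwr_z - hist_rwr_z
  }
  out
}

#' Length-weighted condition summaries per HUC-12
#'
#' Length-weighted average of reach-scale condition scores (habitat
#' condition index `hwi`, local hydrologic regulation `local_hydro_reg`)
#' over the reaches of one HUC-12. Missing values are skipped and weights
#' renormalized; all-missing gives `NA` with a warning.
#'
#' @param net a `river_network`
#' @param huc12_id a HUC-12 id present in the network
#' @param vars condition columns to summarize
#' @return named numeric vector
#' @export
length_weighted_condition <- function(net, huc12_id,
                                      vars = c("hwi", "local_hydro_reg")) {
  r <- net$reaches[net$reaches$huc12_id == huc12_id, , drop = FALSE]
  if (nrow(r) == 0L) stop("no reaches in HUC-12 ", huc12_id, call. = FALSE)
  vapply(vars, function(v) {
    if (!v %in% names(r)) return(NA_real_)
    x <- r[[v]]; w <- r$length_km
    ok <- !is.na(x)
    if (!any(ok)) {
      warning("all '", v, "' values missing in HUC-12 ", huc12_id,
              call. = FALSE)
      return(NA_real_)
    }
    sum(x[ok] * w[ok]) / sum(w[ok])
  }, numeric(1))
}

#' Outlet (largest drainage area) metrics per HUC-12
#'
#' Upstream-accumulated metrics (dam density, dam storage) are taken from
#' the HUC-12 outlet: the member reach with the largest drainage area, ties
#' to the smallest reach id.
#'
#' @param net a `river_network`
#' @param huc12_id a HUC-12 id present in the network
#' @param vars outlet columns to extract
#' @return named numeric vector
#' @export
outlet_upstream_metrics <- function(net, huc12_id,
                                    vars = c("upstream_dam_density",
                                             "upstream_dam_storage")) {
  r <- net$reaches[net$reaches$huc12_id == huc12_id, , drop = FALSE]
  if (nrow(r) == 0L) stop("no reaches in HUC-12 ", huc12_id, call. = FALSE)
  r <- r[order(-r$drainage_area_km2, r$reach_id), , drop = FALSE]
  vapply(vars, function(v) {
    if (!v %in% names(r)) NA_real_ else as.numeric(r[[v]][1])
  }, numeric(1))
}

#' Assemble the HUC-12 predictor table
#'
#' Runs the full linkage stage: longest historical and current FCN per
#' HUC-12, habitat-change predictors from their habitat summaries, RWR
#' z-score change, and current condition summaries (length-weighted `hwi`
#' and `local_hydro_reg`, outlet dam density/storage). HUC-12s whose
#' longest current FCN has no historical counterpart summary are dropped
#' with a logged count.
#'
#' @param net a `river_network`
#' @param part_hist,part_curr historical and current `fcn_partition`s
#' @param hab_hist,hab_curr [habitat_presence()] summaries (with `rwr`
#'   filled) for the two partitions
#' @param schema the [habitat_schema()] used
#' @return data frame, one row per HUC-12: ids, `ecoregion_id`,
#'   `hist_fcn_id`, `curr_fcn_id`, predictor columns, condition columns.
#'   `NA` percent changes (class absent historically) are retained; the
#'   modelling stage imputes or drops them explicitly.
#' @export
build_huc12_table <- function(net, part_hist, part_curr, hab_hist, hab_curr,
                              schema = habitat_schema()) {
  lh <- longest_fcn_per_huc12(part_hist, net)
  lc <- longest_fcn_per_huc12(part_curr, net)
  both <- merge(lh, lc, by = "huc12_id", suffixes = c("_hist", "_curr"))
  missing_h <- !(both$fcn_id_hist %in% hab_hist$fcn_id)
  missing_c <- !(both$fcn_id_curr %in% hab_curr$fcn_id)
  if (any(missing_h | missing_c)) {
    message(sum(missing_h | missing_c),
            " HUC-12(s) dropped: no habitat summary for longest FCN")
    both <- both[!(missing_h | missing_c), , drop = FALSE]
  }
  cl_h <- attr(hab_hist, "class_lengths"); pr_h <- attr(hab_hist, "presence")
  cl_c <- attr(hab_curr, "class_lengths"); pr_c <- attr(hab_curr, "presence")
  have_z <- !is.null(hab_hist$rwr_z) && !is.null(hab_curr$rwr_z)
  z_h <- if (have_z) stats::setNames(hab_hist$rwr_z, hab_hist$fcn_id)
  z_c <- if (have_z) stats::setNames(hab_curr$rwr_z, hab_curr$fcn_id)

  rows <- lapply(seq_len(nrow(both)), function(i) {
    fh <- both$fcn_id_hist[i]; fc <- both$fcn_id_curr[i]
    pred <- habitat_change_predictors(
      cl_h[[fh]], cl_c[[fc]], pr_h[[fh]], pr_c[[fc]],
      both$fcn_length_km_hist[i], both$fcn_length_km_curr[i],
      if (have_z) z_h[[fh]], if (have_z) z_c[[fc]])
    cond <- length_weighted_condition(net, both$huc12_id[i])
    outl <- outlet_upstream_metrics(net, both$huc12_id[i])
    c(pred, as.list(cond), as.list(outl))
  })
  all_names <- unique(unlist(lapply(rows, names)))
  pred_mat <- do.call(rbind, lapply(rows, function(p) {
    vapply(all_names, function(nm)
      if (is.null(p[[nm]])) NA_real_ else as.numeric(p[[nm]]), numeric(1))
  }))
  eco <- net$reaches$ecoregion_id[match(both$huc12_id,
                                        net$reaches$huc12_id)]
  out <- data.frame(huc12_id = both$huc12_id,
                    ecoregion_id = as.character(eco),
                    hist_fcn_id = both$fcn_id_hist,
                    curr_fcn_id = both$fcn_id_curr,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(pred_mat))
}
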