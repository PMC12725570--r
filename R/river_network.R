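REACH_REQUIRED_COLS <- c("reach_id", "downstream_id", "length_km",
                         "drainage_area_km2", "ecoregion_id", "huc12_id")
REACH_OPTIONAL_COLS <- c("aug_temp_c", "gradient_class", "flow_class",
                         "confinement_class", "waterbody_type", "hwi",
                         "local_hydro_reg", "upstream_dam_density",
                         "upstream_dam_storage")
WATERBODY_TYPES <- c("none", "ocean_estuary", "natural_lake", "artificial_lake")

#' Construct a dendritic river network from a reach table
#'
#' A river network is a forest of in-trees: each confluence-to-confluence
#' reach points to at most one downstream reach; reaches with no downstream
#' neighbour are network termini (ocean outlets or hydrologic disconnects).
#' Confluences are implicit (two or more reaches sharing a downstream
#' neighbour).
#'
#' @param reaches data frame with columns `reach_id`, `downstream_id`
#'   (`NA` or `""` marks a terminus), `length_km`, `drainage_area_km2`,
#'   `ecoregion_id`, `huc12_id`, and optionally `aug_temp_c`,
#'   `gradient_class`, `flow_class`, `confinement_class`, `waterbody_type`,
#'   `hwi`, `local_hydro_reg`, `upstream_dam_density`, `upstream_dam_storage`.
#'   Extra columns are dropped with a notice.
#' @return An object of class `river_network`: a list with the validated
#'   reach table (`$reaches`) and the terminus reach ids (`$terminus_ids`).
#'   Row order of the input does not affect the result (rows are sorted by
#'   `reach_id`).
#' @details Validation failures are signalled as classed conditions:
#'   `fcnflow_duplicate_reach` (repeated `reach_id`),
#'   `fcnflow_dangling_downstream` (`downstream_id` not in the table),
#'   `fcnflow_cycle` (the downstream pointers form a cycle), and
#'   `fcnflow_bad_measure` (non-positive length or drainage area).
#'   Drainage area decreasing in the downstream direction is a warning, not
#'   an error, since real hydrography contains divergences.
#' @export
river_network <- function(reaches) {
  stopifnot(is.data.frame(reaches))
  missing_cols <- setdiff(REACH_REQUIRED_COLS, names(reaches))
  if (length(missing_cols) > 0L) {
    stop("reach table is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keep <- intersect(c(REACH_REQUIRED_COLS, REACH_OPTIONAL_COLS), names(reaches))
  extra <- setdiff(names(reaches), keep)
  if (length(extra) > 0L) {
    message("ignoring ", length(extra), " extra reach column(s): ",
            paste(extra, collapse = ", "))
  }
  reaches <- reaches[keep]
  reaches$reach_id <- as.character(reaches$reach_id)
  reaches$downstream_id <- as.character(reaches$downstream_id)
  reaches$downstream_id[!is.na(reaches$downstream_id) &
                          reaches$downstream_id == ""] <- NA_character_

  if (anyDuplicated(reaches$reach_id)) {
    dup <- unique(reaches$reach_id[duplicated(reaches$reach_id)])
    stop(condition_(
      "fcnflow_duplicate_reach",
      paste0("duplicate reach_id: ", paste(dup, collapse = ", "))))
  }
  bad_len <- !is.finite(reaches$length_km) | reaches$length_km <= 0
  bad_area <- !is.finite(reaches$drainage_area_km2) |
    reaches$drainage_area_km2 <= 0
  if (any(bad_len) || any(bad_area)) {
    stop(condition_(
      "fcnflow_bad_measure",
      paste0("non-positive length or drainage area for reach(es): ",
             paste(reaches$reach_id[bad_len | bad_area], collapse = ", "))))
  }
  if ("waterbody_type" %in% names(reaches)) {
    wb <- reaches$waterbody_type
    if (!all(wb %in% WATERBODY_TYPES | is.na(wb))) {
      stop("waterbody_type must be one of ",
           paste(WATERBODY_TYPES, collapse = ", "), call. = FALSE)
    }
  } else {
    reaches$waterbody_type <- "none"
  }

  down_idx <- match(reaches$downstream_id, reaches$reach_id)
  dangling <- !is.na(reaches$downstream_id) & is.na(down_idx)
  if (any(dangling)) {
    stop(condition_(
      "fcnflow_dangling_downstream",
      paste0("downstream_id not present in table for reach(es): ",
             paste(reaches$reach_id[dangling], collapse = ", "))))
  }
  check_acyclic_(reaches$reach_id, down_idx)

  # permissive on monotone drainage area: warn, keep
  has_down <- !is.na(down_idx)
  shrink <- has_down & reaches$drainage_area_km2 >
    reaches$drainage_area_km2[down_idx] + 1e-9
  if (any(shrink)) {
    warning(sprintf(
      "drainage area decreases downstream of %d reach(es) (kept as-is)",
      sum(shrink)), call. = FALSE)
  }

  reaches <- reaches[order(reaches$reach_id), , drop = FALSE]
  rownames(reaches) <- NULL
  structure(
    list(reaches = reaches,
         terminus_ids = reaches$reach_id[is.na(reaches$downstream_id)]),
    class = "river_network")
}

condition_ <- function(class, msg) {
  structure(class = c(class, "error", "condition"),
            list(message = msg, call = NULL))
}

# Walk downstream pointers with a three-colour marking; each reach has at
# most one out-edge so every walk either reaches a terminus/closed reach or
# revisits the current path (a cycle).
check_acyclic_ <- function(ids, down_idx) {
  n <- length(ids)
  state <- integer(n) # 0 unseen, 1 on current path, 2 closed
  for (start in seq_len(n)) {
    if (state[start] != 0L) next
    path <- integer(0)
    v <- start
    while (!is.na(v) && state[v] == 0L) {
      state[v] <- 1L
      path <- c(path, v)
      v <- down_idx[v]
    }
    if (!is.na(v) && state[v] == 1L) {
      stop(condition_(
        "fcnflow_cycle",
        paste0("cycle in downstream pointers involving reach ", ids[v])))
    }
    state[path] <- 2L
  }
  invisible(TRUE)
}

#' @export
print.river_network <- function(x, ...) {
  cat(sprintf(
    "<river_network> %d reaches, %d terminus reach(es), %.1f km total\n",
    nrow(x$reaches), length(x$terminus_ids), sum(x$reaches$length_km)))
  invisible(x)
}

#' Read a reach table from CSV and validate it
#'
#' @param path path to a CSV file with the columns documented in
#'   [river_network()]. An empty string or missing `downstream_id` denotes a
#'   network terminus.
#' @return a validated [river_network()]
#' @export
load_reach_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(reach_id = "character",
                                        downstream_id = "character"))
  river_network(tab)
}

#' Write a reach table to CSV
#'
#' Inverse of [load_reach_table()]: `load_reach_table(write_reach_table(net))`
#' reproduces `net` field for field.
#'
#' @param net a `river_network`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_reach_table <- function(net, path) {
  stopifnot(inherits(net, "river_network"))
  utils::write.csv(net$reaches, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Drop reaches below a minimum drainage area
#'
#' Small headwater reaches are excluded to even out variable drainage density
#' in the source hydrography. Because drainage area accumulates downstream,
#' the removed set is upstream-closed in well-formed data; if a retained
#' reach would be left pointing at a removed one (possible only when the
#' monotonicity warning fired at load), its downstream pointer is cleared and
#' it becomes a terminus, with a warning.
#'
#' @param net a `river_network`
#' @param min_area_km2 minimum drainage area retained, km^2 (default 2.5)
#' @return the filtered `river_network`
#' @export
filter_small_reaches <- function(net, min_area_km2 = 2.5) {
  stopifnot(inherits(net, "river_network"))
  keep <- net$reaches$drainage_area_km2 >= min_area_km2
  if (!any(keep)) {
    stop(condition_("fcnflow_empty_network",
                    "filtering would remove every reach"))
  }
  out <- net$reaches[keep, , drop = FALSE]
  orphan <- !is.na(out$downstream_id) &
    !(out$downstream_id %in% out$reach_id)
  if (any(orphan)) {
    warning(sprintf(
      "%d retained reach(es) pointed at removed reaches; made termini",
      sum(orphan)), call. = FALSE)
    out$downstream_id[orphan] <- NA_character_
  }
  river_network(out)
}

#' All reaches draining through a given reach
#'
#' @param net a `river_network`
#' @param reach_id a reach id present in `net`
#' @return character vector of reach ids whose downstream path passes
#'   through `reach_id`, including `reach_id` itself
#' @export
upstream_set <- function(net, reach_id) {
  stopifnot(inherits(net, "river_network"))
  ids <- net$reaches$reach_id
  if (!reach_id %in% ids) stop("unknown reach_id: ", reach_id, call. = FALSE)
  kids <- children_index_(net)
  acc <- character(0)
  frontier <- reach_id
  while (length(frontier) > 0L) {
    acc <- c(acc, frontier)
    frontier <- unlist(kids[frontier], use.names = FALSE)
  }
  sort(acc)
}

# reach_id -> character vector of immediate upstream reach ids
children_index_ <- function(net) {
  r <- net$reaches
  has_down <- !is.na(r$downstream_id)
  split(r$reach_id[has_down], factor(r$downstream_id[has_down],
                                     levels = r$reach_id))
}
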