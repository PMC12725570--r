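BARRIER_TYPES <- c("waterfall", "dam")
PASSABILITY_LEVELS <- c("complete", "partial", "unknown")

#' Validate a barrier table
#'
#' @param barriers data frame with columns `barrier_id`, `reach_id`,
#'   `barrier_type` (`waterfall` or `dam`), `passability` (`complete`,
#'   `partial` or `unknown`), and logical (or 0/1) flags `removed`,
#'   `off_network`, `anadromous_upstream`.
#' @return the validated data frame with flags coerced to logical
#' @export
barrier_set <- function(barriers) {
  stopifnot(is.data.frame(barriers))
  req <- c("barrier_id", "reach_id", "barrier_type", "passability",
           "removed", "off_network", "anadromous_upstream")
  miss <- setdiff(req, names(barriers))
  if (length(miss) > 0L) {
    stop("barrier table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  barriers$barrier_id <- as.character(barriers$barrier_id)
  barriers$reach_id <- as.character(barriers$reach_id)
  if (!all(barriers$barrier_type %in% BARRIER_TYPES)) {
    stop("barrier_type must be one of ", paste(BARRIER_TYPES, collapse = ", "),
         call. = FALSE)
  }
  if (!all(barriers$passability %in% PASSABILITY_LEVELS)) {
    stop("passability must be one of ",
         paste(PASSABILITY_LEVELS, collapse = ", "), call. = FALSE)
  }
  for (fl in c("removed", "off_network", "anadromous_upstream")) {
    barriers[[fl]] <- as.logical(barriers[[fl]])
  }
  barriers
}

#' Read a barrier table from CSV
#'
#' Boolean flags may be coded 0/1.
#'
#' @param path CSV path with the columns of [barrier_set()]
#' @return validated barrier data frame
#' @export
load_barrier_table <- function(path) {
  barrier_set(utils::read.csv(path, stringsAsFactors = FALSE,
                              colClasses = c(barrier_id = "character",
                                             reach_id = "character")))
}

#' Barrier scenario definitions
#'
#' The historical scenario fragments the network with natural barriers only:
#' waterfalls that are complete barriers to fish passage. The current
#' scenario adds dams of any passability class (complete, partial or
#' unknown). Both exclude barriers flagged as removed, off the routed
#' network, or with observed anadromous fish distribution upstream.
#'
#' @param name `"historical"` or `"current"`
#' @param exclusion_flags flag columns that disqualify a barrier
#' @return a `fcn_scenario` list
#' @export
scenario <- function(name = c("historical", "current"),
                     exclusion_flags = c("removed", "off_network",
                                         "anadromous_upstream")) {
  name <- match.arg(name)
  include_types <- if (name == "historical") "waterfall" else
    c("waterfall", "dam")
  structure(list(name = name, include_types = include_types,
                 exclusion_flags = exclusion_flags),
            class = "fcn_scenario")
}

#' Select the barriers active under a scenario
#'
#' @param barriers validated barrier data frame ([barrier_set()])
#' @param scen a [scenario()]
#' @return the subset of rows active under the scenario (possibly empty).
#'   Waterfalls count only when they are complete barriers; dams count at
#'   any passability.
#' @export
select_barriers <- function(barriers, scen) {
  barriers <- barrier_set(barriers)
  stopifnot(inherits(scen, "fcn_scenario"))
  keep <- barriers$barrier_type %in% scen$include_types
  keep <- keep & !(barriers$barrier_type == "waterfall" &
                     barriers$passability != "complete")
  for (fl in scen$exclusion_flags) {
    keep <- keep & !barriers[[fl]]
  }
  barriers[keep, , drop = FALSE]
}

#' Partition a river network into functionally connected networks
#'
#' A functionally connected network (FCN) is a maximal set of reaches
#' mutually reachable without crossing a passage barrier or a network
#' terminus. A barrier on reach `r` severs the connection between `r` and
#' its downstream neighbour; the barrier reach itself belongs to the
#' upstream patch. A barrier on a terminus reach has no downstream edge to
#' cut and is a logged no-op; multiple barriers on one reach collapse to a
#' single cut.
#'
#' @param net a `river_network`
#' @param active data frame of active barriers (from [select_barriers()]),
#'   or `NULL`/empty for an unfragmented network
#' @param scenario_name label stored on the result
#' @return a `fcn_partition`: list with `$membership` (data frame
#'   `reach_id`, `fcn_id`) and `$fcns` (data frame `fcn_id`, `n_reaches`,
#'   `total_length_km`, `ecoregion_id`). FCN ids are
#'   `"<scenario>_<smallest member reach_id>"`, so the labelling is
#'   deterministic and independent of reach iteration order.
#' @export
delineate_fcns <- function(net, active = NULL, scenario_name = "current") {
  stopifnot(inherits(net, "river_network"))
  r <- net$reaches
  n <- nrow(r)
  if (!is.null(active) && nrow(active) > 0L) {
    unknown <- setdiff(active$reach_id, r$reach_id)
    if (length(unknown) > 0L) {
      bad <- active$barrier_id[active$reach_id %in% unknown]
      stop("barrier(s) on unknown reach: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cut_ids <- unique(active$reach_id)
  } else {
    cut_ids <- character(0)
  }
  n_noop <- sum(cut_ids %in% net$terminus_ids)
  if (n_noop > 0L) {
    message(n_noop, " barrier(s) on terminus reaches do not cut any edge")
  }

  down_idx <- match(r$downstream_id, r$reach_id)
  keep_edge <- !is.na(down_idx) & !(r$reach_id %in% cut_ids)
  comp <- union_find_components_(n, which(keep_edge), down_idx[keep_edge])

  # deterministic id: smallest member reach_id (rows are sorted by reach_id)
  first_row <- match(unique(comp), comp)
  label <- paste0(scenario_name, "_", r$reach_id[first_row])
  fcn_id <- label[match(comp, comp[first_row])]

  membership <- data.frame(reach_id = r$reach_id, fcn_id = fcn_id,
                           stringsAsFactors = FALSE)
  f <- factor(fcn_id, levels = sort(unique(fcn_id)))
  fcns <- data.frame(
    fcn_id = levels(f),
    n_reaches = as.integer(tabulate(f)),
    total_length_km = as.numeric(tapply(r$length_km, f, sum)),
    ecoregion_id = as.character(tapply(as.character(r$ecoregion_id), f,
                                       modal_value_)),
    stringsAsFactors = FALSE)
  rownames(fcns) <- NULL
  structure(list(membership = membership, fcns = fcns,
                 scenario = scenario_name),
            class = "fcn_partition")
}

# most frequent value, ties to the smallest label
modal_value_ <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  names(tab)[tab == tab[1]][1]
}

# union-find with path halving over the retained reach->downstream edges
union_find_components_ <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(from)) {
    a <- find(from[k]); b <- find(to[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  vapply(seq_len(n), find, integer(1))
}

#' @export
print.fcn_partition <- function(x, ...) {
  cat(sprintf("<fcn_partition> scenario=%s, %d FCNs over %d reaches\n",
              x$scenario, nrow(x$fcns), nrow(x$membership)))
  invisible(x)
}

#' Summarize FCN counts and mean lengths
#'
#' Reproduces the shape of an FCN characterization table: per ecoregion, the
#' number of networks and their average total length, plus an all-groups row.
#'
#' @param part a `fcn_partition`
#' @return data frame with columns `ecoregion_id`, `n_fcn`,
#'   `mean_length_km`, `total_length_km`; last row is `"all"`.
#' @export
summarize_fcns <- function(part) {
  stopifnot(inherits(part, "fcn_partition"))
  f <- part$fcns
  if (nrow(f) == 0L) {
    return(data.frame(ecoregion_id = character(0), n_fcn = integer(0),
                      mean_length_km = numeric(0),
                      total_length_km = numeric(0)))
  }
  g <- factor(f$ecoregion_id)
  out <- data.frame(
    ecoregion_id = levels(g),
    n_fcn = as.integer(tabulate(g)),
    mean_length_km = as.numeric(tapply(f$total_length_km, g, mean)),
    total_length_km = as.numeric(tapply(f$total_length_km, g, sum)),
    stringsAsFactors = FALSE)
  rbind(out, data.frame(ecoregion_id = "all", n_fcn = nrow(f),
                        mean_length_km = mean(f$total_length_km),
                        total_length_km = sum(f$total_length_km)))
}

#' Percent change between two period values
#'
#' @param historical baseline value (nonzero)
#' @param current comparison value
#' @param digits if not `NULL`, round the result half away from zero to this
#'   many decimal places (reporting convention)
#' @return `100 * (current - historical) / historical`
#' @export
percent_change <- function(historical, current, digits = NULL) {
  if (any(historical == 0)) {
    stop("percent change undefined for a zero baseline", call. = FALSE)
  }
  pc <- 100 * (current - historical) / historical
  if (!is.null(digits)) pc <- round_half_away(pc, digits)
  pc
}

#' Round half away from zero
#'
#' Reporting convention for printed percent changes (base `round()` rounds
#' half to even).
#'
#' @param x numeric
#' @param digits decimal places
#' @return rounded numeric
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
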