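#' Habitat classification schema
#'
#' Reaches are classified into composite physical habitat classes built from
#' a configurable set of dimensions: stream size (drainage-area breaks),
#' thermal regime (August temperature breaks), and pass-through categorical
#' attributes (gradient, flow regime, valley confinement). Waterbody classes
#' (ocean/estuary, natural lake, artificial lake) are standalone: a reach in
#' a waterbody contributes that class by mere presence, with no minimum
#' length. The break values ship as editable defaults; they are inputs, not
#' constants of the method.
#'
#' @param size_breaks named numeric vector of upper drainage-area bounds
#'   (km^2), strictly increasing; the last entry may be `Inf`
#' @param temp_breaks named numeric vector of upper August-temperature
#'   bounds (deg C), strictly increasing, or `NULL` to disable the
#'   temperature dimension
#' @param pass_through reach columns used verbatim as class dimensions
#' @param min_presence_km minimum total class length (km) for a class to
#'   count as present in an FCN (inclusive bound)
#' @return a `habitat_schema` list
#' @export
habitat_schema <- function(
    size_breaks = c(headwater = 25, creek = 100, small_river = 1000,
                    medium_river = 10000, large_river = Inf),
    temp_breaks = c(cold = 12, cool = 18, warm = Inf),
    pass_through = c("gradient_class", "flow_class", "confinement_class"),
    min_presence_km = 1.0) {
  check_breaks <- function(b, what) {
    if (is.null(b)) return(invisible(NULL))
    if (is.null(names(b)) || anyDuplicated(names(b)) ||
        is.unsorted(b, strictly = TRUE)) {
      stop(what, " breaks must be strictly increasing with unique labels",
           call. = FALSE)
    }
  }
  check_breaks(size_breaks, "size")
  check_breaks(temp_breaks, "temperature")
  structure(list(size_breaks = size_breaks, temp_breaks = temp_breaks,
                 pass_through = pass_through,
                 min_presence_km = min_presence_km),
            class = "habitat_schema")
}

break_label_ <- function(x, breaks) {
  lab <- names(breaks)[findInterval(x, breaks, left.open = TRUE) + 1L]
  lab[is.na(x)] <- NA_character_
  lab
}

#' Classify reaches into physical habitat classes
#'
#' Classification is pure row-wise lookup: the same attributes always yield
#' the same class, independent of network context. Reaches with a missing
#' attribute in any enabled dimension get the sentinel class
#' `"unclassified"` and are counted in a message.
#'
#' @param net a `river_network`
#' @param schema a [habitat_schema()]
#' @return data frame `reach_id`, `habitat_class` (composite label,
#'   dimensions joined by `"."`), `waterbody_class` (`NA` when the reach is
#'   not a waterbody)
#' @export
classify_reaches <- function(net, schema = habitat_schema()) {
  stopifnot(inherits(net, "river_network"), inherits(schema, "habitat_schema"))
  r <- net$reaches
  parts <- list(size = break_label_(r$drainage_area_km2, schema$size_breaks))
  if (!is.null(schema$temp_breaks)) {
    if (!"aug_temp_c" %in% names(r)) {
      stop("temperature dimension enabled but aug_temp_c column is absent",
           call. = FALSE)
    }
    parts$temp <- break_label_(r$aug_temp_c, schema$temp_breaks)
  }
  for (col in schema$pass_through) {
    if (col %in% names(r)) parts[[col]] <- as.character(r[[col]])
  }
  m <- do.call(cbind, parts)
  cls <- apply(m, 1L, function(row) {
    if (anyNA(row)) "unclassified" else paste(row, collapse = ".")
  })
  n_missing <- sum(cls == "unclassified")
  if (n_missing > 0L) {
    message(n_missing, " reach(es) with missing attributes -> 'unclassified'")
  }
  wb <- as.character(r$waterbody_type)
  wb[is.na(wb) | wb == "none"] <- NA_character_
  data.frame(reach_id = r$reach_id, habitat_class = cls,
             waterbody_class = wb, stringsAsFactors = FALSE)
}

#' Per-FCN habitat lengths, presence and richness
#'
#' Sums member reach length by habitat class within each FCN. A stream class
#' is present when its total length is at least `min_presence_km`
#' (inclusive); a waterbody class is present whenever any member reach
#' carries it. Richness is the number of present classes.
#'
#' @param part a `fcn_partition`
#' @param net the `river_network` the partition was built from
#' @param classes output of [classify_reaches()]
#' @param schema the [habitat_schema()] used
#' @return data frame with one row per FCN: `fcn_id`, `richness`, `rwr`
#'   (`NA` until [rarity_weighted_richness()]), plus attribute
#'   `"class_lengths"` (named list fcn_id -> named numeric km by class) and
#'   `"presence"` (named list fcn_id -> character vector of present classes)
#' @export
habitat_presence <- function(part, net, classes, schema = habitat_schema()) {
  stopifnot(inherits(part, "fcn_partition"))
  m <- merge(part$membership, classes, by = "reach_id")
  m <- merge(m, net$reaches[c("reach_id", "length_km")], by = "reach_id")
  by_fcn <- split(m, m$fcn_id)
  class_lengths <- lapply(by_fcn, function(d) {
    tapply(d$length_km, d$habitat_class, sum)
  })
  presence <- Map(function(d, cl) {
    stream <- names(cl)[cl >= schema$min_presence_km]
    wb <- unique(d$waterbody_class[!is.na(d$waterbody_class)])
    sort(union(stream, wb))
  }, by_fcn, class_lengths)
  out <- data.frame(fcn_id = names(by_fcn),
                    richness = vapply(presence, length, integer(1)),
                    rwr = NA_real_, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "class_lengths") <- class_lengths
  attr(out, "presence") <- presence
  out
}

#' Rarity-weighted habitat richness
#'
#' For each FCN, the sum over its present habitat classes of the inverse of
#' the number of FCNs (in the same scenario and ecoregion group) containing
#' that class: rare classes contribute close to 1, ubiquitous classes close
#' to 1/n. Summed over all FCNs in a group, RWR equals the number of
#' distinct classes present anywhere in the group.
#'
#' @param summaries output of [habitat_presence()] for one scenario
#' @param groups optional group labels (e.g. ecoregion), one per row of
#'   `summaries`; the class counts `n_h` are then taken within each group
#'   (the paper-scale convention: one scenario x ecoregion at a time)
#' @return `summaries` with the `rwr` column filled
#' @export
rarity_weighted_richness <- function(summaries, groups = NULL) {
  presence <- attr(summaries, "presence")
  if (nrow(summaries) == 0L) return(summaries)
  if (is.null(groups)) groups <- rep("all", nrow(summaries))
  stopifnot(length(groups) == nrow(summaries))
  for (g in unique(groups)) {
    rows <- which(groups == g)
    pres_g <- presence[summaries$fcn_id[rows]]
    counts <- table(unlist(pres_g, use.names = FALSE))
    summaries$rwr[rows] <- vapply(pres_g, function(p) {
      if (length(p) == 0L) 0 else sum(1 / as.numeric(counts[p]))
    }, numeric(1))
  }
  summaries
}

#' Group-wise z-scores
#'
#' Standardizes values within each group to mean 0 and sample (n-1)
#' standard deviation 1. RWR values are z-scored within ecoregion so that
#' the two periods (with different network counts) are comparable. A group
#' with zero spread gets z = 0 with a warning.
#'
#' @param values numeric vector
#' @param groups group labels, same length
#' @return numeric vector of z-scores
#' @export
zscore_by_group <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  out <- numeric(length(values))
  for (g in unique(groups)) {
    i <- which(groups == g)
    s <- stats::sd(values[i])
    if (length(i) < 2L || !is.finite(s) || s == 0) {
      warning("group '", g, "' has no spread; z-scores set to 0",
              call. = FALSE)
      out[i] <- 0
    } else {
      out[i] <- (values[i] - mean(values[i])) / s
    }
  }
  out
}
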