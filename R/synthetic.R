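#' Configuration for the synthetic dataset generator
#'
#' The generator emulates the structure of the study inputs: a dendritic
#' reach network with physical and condition attributes, natural and
#' artificial barriers, a HUC-12 partition with planar centroids, and
#' two-period fish presence-absence communities in which losses concentrate
#' in fragmented, low-condition watersheds. The defaults give roughly 500
#' HUC-12 sites over a 4,000-reach network — large enough for the spatial
#' forest stage, small enough to regenerate in seconds.
#'
#' Current occupancy is historical occupancy thinned by a site-level
#' logistic loss model: a historically present species is lost with
#' probability `plogis(b0 + b1 * frag + b2 * cond)`, where `frag` is the
#' site's fractional loss of longest-network length between the two
#' barrier scenarios and `cond` its length-weighted habitat condition
#' (HWI). Losses only, by default, with an optional gain rate for testing
#' the gain branch of the dominance test.
#'
#' @param n_reaches number of reaches
#' @param n_waterfalls,n_dams barrier counts
#' @param dam_size_bias exponent of the drainage-area preference when
#'   placing dams (0 = uniform)
#' @param n_species number of fish species
#' @param richness_gradient exponent shaping species' minimum-network-length
#'   requirements; 1 spreads requirements over the observed length
#'   distribution
#' @param loss_intercept,loss_frag_coef,loss_condition_coef logistic loss
#'   model coefficients (`b0`, `b1`, `b2`)
#' @param gain_rate per-cell probability of a spurious gain (default 0)
#' @param n_huc12 target number of HUC-12 subwatersheds
#' @param n_ecoregions number of ecoregion blocks
#' @param seed integer seed; every downstream draw derives from it
#' @return a `synth_config` list
#' @export
synth_config <- function(n_reaches = 4000, n_waterfalls = 110, n_dams = 66,
                         dam_size_bias = 0.5, n_species = 40,
                         richness_gradient = 1, loss_intercept = -3.2,
                         loss_frag_coef = 3.5, loss_condition_coef = -1.5,
                         gain_rate = 0, n_huc12 = 500, n_ecoregions = 4,
                         seed = 1) {
  stopifnot(n_reaches > 2, n_waterfalls >= 0, n_dams >= 0,
            n_waterfalls + n_dams < n_reaches, n_species > 0, n_huc12 > 0)
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a random dendritic river network
#'
#' Builds a random recursive in-tree (each new reach attaches downstream to
#' an existing one), draws log-normal reach lengths (median ~2 km) and
#' incremental drainage areas, accumulates drainage area downstream (so
#' monotonicity holds by construction), embeds the tree in the plane with
#' gently meandering branches, and attaches attributes: August temperature
#' decreasing and gradient class increasing with distance from the outlet,
#' categorical flow and confinement draws, occasional waterbodies, and
#' spatially structured condition scores. HUC-12 ids are carved as
#' contiguous subtree blocks (so several FCNs can intersect one HUC-12) and
#' ecoregions as contiguous blocks of HUC-12s.
#'
#' @param cfg a [synth_config()]
#' @return a validated [river_network()]; reach positions and HUC-12
#'   centroids are attached as attributes `"positions"` and `"centroids"`
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_reaches
  parent <- c(NA_integer_,
              vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  length_km <- stats::rlnorm(n, meanlog = log(2), sdlog = 0.5)
  own_area <- stats::rlnorm(n, meanlog = log(3), sdlog = 0.7)

  area <- own_area
  for (i in n:2) area[parent[i]] <- area[parent[i]] + area[i]

  depth <- integer(n)
  for (i in 2:n) depth[i] <- depth[parent[i]] + 1L

  theta <- numeric(n); pos <- matrix(0, n, 2)
  theta[1] <- stats::runif(1, 0, 2 * pi)
  for (i in 2:n) {
    theta[i] <- theta[parent[i]] + stats::rnorm(1, 0, 0.7)
    pos[i, ] <- pos[parent[i], ] +
      length_km[i] * c(cos(theta[i]), sin(theta[i]))
  }

  aug_temp_c <- pmin(pmax(24 - 0.6 * depth + stats::rnorm(n, 0, 1.5), 2), 28)
  grad_score <- depth + stats::rnorm(n, 0, 3)
  gradient_class <- cut(grad_score,
                        breaks = stats::quantile(grad_score,
                                                 c(0, 1 / 3, 2 / 3, 1)),
                        labels = c("low", "moderate", "high"),
                        include.lowest = TRUE)
  flow_class <- sample(c("perennial", "intermittent", "snowmelt"), n,
                       replace = TRUE, prob = c(0.5, 0.3, 0.2))
  confinement_class <- sample(c("confined", "unconfined"), n, replace = TRUE)
  waterbody_type <- sample(c("none", "natural_lake", "artificial_lake"), n,
                           replace = TRUE, prob = c(0.96, 0.02, 0.02))
  waterbody_type[1] <- "ocean_estuary" # the outlet reach
  sx <- as.numeric(scale(pos[, 1] + pos[, 2]))
  hwi <- stats::pnorm(0.8 * sx + stats::rnorm(n, 0, 0.8))
  local_hydro_reg <- stats::pnorm(-0.5 * sx + stats::rnorm(n, 0, 1))

  # the greedy carve overshoots its size target by ~40%; shrink the target
  # so the realized block count lands near n_huc12
  huc <- carve_huc12_blocks_(parent,
                             max(2L, round(n / cfg$n_huc12 / 1.4)))
  n_blocks <- max(huc)
  eco_of_huc <- cut(seq_len(n_blocks), breaks = cfg$n_ecoregions,
                    labels = paste0("eco", seq_len(cfg$n_ecoregions)))
  centroids <- data.frame(
    huc12_id = paste0("huc", formatC(seq_len(n_blocks), width = 4,
                                     flag = "0")),
    x = as.numeric(tapply(pos[, 1], huc, mean)),
    y = as.numeric(tapply(pos[, 2], huc, mean)))

  ids <- paste0("r", formatC(seq_len(n), width = 5, flag = "0"))
  reaches <- data.frame(
    reach_id = ids,
    downstream_id = ifelse(is.na(parent), NA_character_, ids[parent]),
    length_km = length_km, drainage_area_km2 = area,
    ecoregion_id = as.character(eco_of_huc[huc]),
    huc12_id = centroids$huc12_id[huc],
    aug_temp_c = aug_temp_c,
    gradient_class = as.character(gradient_class),
    flow_class = flow_class, confinement_class = confinement_class,
    waterbody_type = waterbody_type, hwi = hwi,
    local_hydro_reg = local_hydro_reg,
    upstream_dam_density = 0, upstream_dam_storage = 0,
    stringsAsFactors = FALSE)
  net <- river_network(reaches)
  attr(net, "positions") <- data.frame(reach_id = ids, x = pos[, 1],
                                       y = pos[, 2])
  attr(net, "centroids") <- centroids
  net
}

# Greedy subtree partition: walking children-before-parents, carve a new
# block whenever the pending (unassigned) subtree at a node reaches the
# target size; the root sweeps up the remainder.
carve_huc12_blocks_ <- function(parent, target) {
  n <- length(parent)
  kids <- split(seq_len(n)[-1], parent[-1])
  pend <- rep(1L, n)
  block <- integer(n)
  next_block <- 0L
  carve <- function(v, id) {
    stack <- v
    while (length(stack) > 0L) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (block[u] != 0L) next
      block[u] <<- id
      stack <- c(stack, kids[[as.character(u)]])
    }
  }
  for (v in n:1) {
    if (pend[v] >= target || v == 1L) {
      next_block <- next_block + 1L
      carve(v, next_block)
    } else {
      pend[parent[v]] <- pend[parent[v]] + pend[v]
    }
  }
  block
}

#' Place synthetic barriers on a network
#'
#' Waterfalls are placed uniformly over non-terminus reaches; dams are
#' sampled with probability proportional to drainage area raised to
#' `dam_size_bias` (real dams sit on larger rivers). No two barriers share
#' a reach; all exclusion flags start false. Waterfalls are complete
#' barriers; dam passability is drawn from complete/partial/unknown.
#'
#' @param net a `river_network`
#' @param cfg a [synth_config()]
#' @return a validated barrier data frame ([barrier_set()])
#' @export
place_barriers <- function(net, cfg) {
  stopifnot(inherits(net, "river_network"), inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 1L)
  r <- net$reaches
  candidates <- r$reach_id[!is.na(r$downstream_id)]
  need <- cfg$n_waterfalls + cfg$n_dams
  if (length(candidates) < need) {
    stop("not enough non-terminus reaches for the requested barrier counts",
         call. = FALSE)
  }
  wf <- sample(candidates, cfg$n_waterfalls)
  rest <- setdiff(candidates, wf)
  wts <- r$drainage_area_km2[match(rest, r$reach_id)]^cfg$dam_size_bias
  dm <- if (cfg$n_dams > 0) sample(rest, cfg$n_dams, prob = wts) else
    character(0)
  barrier_set(data.frame(
    barrier_id = paste0("b", seq_len(need)),
    reach_id = c(wf, dm),
    barrier_type = rep(c("waterfall", "dam"), c(cfg$n_waterfalls,
                                                cfg$n_dams)),
    passability = c(rep("complete", cfg$n_waterfalls),
                    sample(c("complete", "partial", "unknown"), cfg$n_dams,
                           replace = TRUE, prob = c(0.5, 0.3, 0.2))),
    removed = FALSE, off_network = FALSE, anadromous_upstream = FALSE,
    stringsAsFactors = FALSE))
}

# dam-derived upstream metrics: accumulated dam count and storage per
# drainage area at each reach
add_upstream_dam_metrics_ <- function(net, barriers, seed) {
  set.seed(seed)
  r <- net$reaches
  n <- nrow(r)
  dams <- barriers[barriers$barrier_type == "dam", , drop = FALSE]
  cnt <- numeric(n); sto <- numeric(n)
  idx <- match(dams$reach_id, r$reach_id)
  cnt[idx] <- 1
  sto[idx] <- stats::rlnorm(nrow(dams), meanlog = log(50), sdlog = 1)
  down <- match(r$downstream_id, r$reach_id)
  # accumulate towards the outlet: process reaches deepest-first
  ord <- order(-upstream_depth_(down))
  for (i in ord) {
    if (!is.na(down[i])) {
      cnt[down[i]] <- cnt[down[i]] + cnt[i]
      sto[down[i]] <- sto[down[i]] + sto[i]
    }
  }
  net$reaches$upstream_dam_density <- 100 * cnt / r$drainage_area_km2
  net$reaches$upstream_dam_storage <- sto / r$drainage_area_km2
  net
}

upstream_depth_ <- function(down) {
  n <- length(down)
  depth <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    path <- integer(0); v <- i
    while (!is.na(v) && is.na(depth[v])) {
      path <- c(path, v); v <- down[v]
    }
    base <- if (is.na(v)) 0L else depth[v]
    depth[rev(path)] <- base + seq_along(path)
  }
  depth
}

#' Simulate two-period fish communities over a fragmented network
#'
#' Each species draws a minimum network-length requirement from the
#' empirical distribution of longest-historical-FCN lengths (so longer
#' networks host more species). Historical occupancy fills HUC-12s whose
#' longest historical FCN meets the requirement, thinned by a 0.9
#' observation rate. Current occupancy retains each historically present
#' species unless it is lost with probability
#' `plogis(b0 + b1 * frag + b2 * cond)`; with the default `gain_rate = 0`
#' no gains occur, matching loss-dominated community change.
#'
#' @param net a `river_network`
#' @param part_hist,part_curr historical and current `fcn_partition`s
#' @param cfg a [synth_config()]
#' @return a [community_pair()] with attribute `"truth"`: a data frame of
#'   per-site fractional network-length loss (`frag`), condition (`cond`)
#'   and the longest-FCN lengths used
#' @export
simulate_communities <- function(net, part_hist, part_curr, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 2L)
  lh <- longest_fcn_per_huc12(part_hist, net)
  lc <- longest_fcn_per_huc12(part_curr, net)
  sites <- merge(lh[c("huc12_id", "fcn_length_km")],
                 lc[c("huc12_id", "fcn_length_km")],
                 by = "huc12_id", suffixes = c("_hist", "_curr"))
  sites <- sites[order(sites$huc12_id), ]
  frag <- pmax(0, (sites$fcn_length_km_hist - sites$fcn_length_km_curr) /
                 sites$fcn_length_km_hist)
  cond <- vapply(sites$huc12_id, function(h)
    length_weighted_condition(net, h, "hwi")[["hwi"]], numeric(1))

  ns <- nrow(sites); np <- cfg$n_species
  req <- stats::quantile(
    sites$fcn_length_km_hist,
    probs = stats::runif(np)^cfg$richness_gradient, names = FALSE)
  t1 <- matrix(0L, ns, np,
               dimnames = list(sites$huc12_id,
                               paste0("sp", formatC(seq_len(np), width = 3,
                                                    flag = "0"))))
  for (j in seq_len(np)) {
    t1[, j] <- as.integer(sites$fcn_length_km_hist >= req[j] &
                            stats::runif(ns) < 0.9)
  }
  p_loss <- stats::plogis(cfg$loss_intercept + cfg$loss_frag_coef * frag +
                            cfg$loss_condition_coef * cond)
  keep <- matrix(stats::runif(ns * np), ns, np) >= p_loss
  t2 <- t1 * (keep * 1L)
  if (cfg$gain_rate > 0) {
    gains <- matrix(stats::runif(ns * np), ns, np) < cfg$gain_rate & t1 == 0L
    t2[gains] <- 1L
  }
  storage.mode(t2) <- "integer"
  pair <- community_pair(t1, t2)
  attr(pair, "truth") <- data.frame(
    huc12_id = sites$huc12_id, frag = frag, cond = cond,
    longest_hist_km = sites$fcn_length_km_hist,
    longest_curr_km = sites$fcn_length_km_curr,
    stringsAsFactors = FALSE)
  pair
}

#' Generate a complete synthetic dataset
#'
#' Runs the generator end to end: network, barriers, dam-derived upstream
#' metrics, historical and current FCN partitions, communities, centroids.
#'
#' @param cfg a [synth_config()]
#' @return a `synth_dataset` list: `$network`, `$barriers`, `$part_hist`,
#'   `$part_curr`, `$communities`, `$centroids`, `$truth` (the generating
#'   parameters plus the per-site fragmentation table)
#' @export
generate_dataset <- function(cfg = synth_config()) {
  net <- generate_network(cfg)
  barriers <- place_barriers(net, cfg)
  centroids <- attr(net, "centroids")
  net <- add_upstream_dam_metrics_(net, barriers, cfg$seed + 3L)
  part_hist <- delineate_fcns(net, select_barriers(barriers,
                                                   scenario("historical")),
                              "historical")
  part_curr <- delineate_fcns(net, select_barriers(barriers,
                                                   scenario("current")),
                              "current")
  communities <- simulate_communities(net, part_hist, part_curr, cfg)
  structure(list(network = net, barriers = barriers,
                 part_hist = part_hist, part_curr = part_curr,
                 communities = communities, centroids = centroids,
                 truth = list(config = unclass(cfg),
                              sites = attr(communities, "truth"))),
            class = "synth_dataset")
}
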