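# Small fixture builders and independent oracles shared across tests.

# A linear chain r1 -> r2 -> ... -> rn (rn is the terminus).
make_chain <- function(n, lengths = rep(1, n), areas = seq_len(n) * 10) {
  ids <- paste0("r", seq_len(n))
  data.frame(reach_id = ids,
             downstream_id = c(ids[-1], NA),
             length_km = lengths, drainage_area_km2 = areas,
             ecoregion_id = "e1", huc12_id = "h1",
             stringsAsFactors = FALSE)
}

# A random in-tree reach table: node i (i > 1) drains to a uniformly chosen
# earlier node; drainage areas accumulate so monotonicity holds.
make_random_tree <- function(n, seed = 1) {
  set.seed(seed)
  parent <- c(NA, vapply(seq_len(n - 1) + 1L,
                         function(i) sample.int(i - 1L, 1L), integer(1)))
  own <- runif(n, 0.5, 5)
  area <- own
  for (i in n:2) area[parent[i]] <- area[parent[i]] + area[i]
  ids <- sprintf("r%04d", seq_len(n))
  data.frame(reach_id = ids,
             downstream_id = ifelse(is.na(parent), NA, ids[parent]),
             length_km = runif(n, 0.2, 5),
             drainage_area_km2 = area,
             ecoregion_id = sample(c("e1", "e2"), n, replace = TRUE),
             huc12_id = paste0("h", 1 + (seq_len(n) - 1) %/% 10),
             stringsAsFactors = FALSE)
}

# Reflexive-transitive closure oracle: reachability by repeated boolean
# matrix multiplication over the reach -> downstream adjacency.
closure_upstream_oracle <- function(reaches, reach_id) {
  ids <- reaches$reach_id
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  has_down <- !is.na(reaches$downstream_id)
  adj[cbind(reaches$reach_id[has_down], reaches$downstream_id[has_down])] <- TRUE
  reach <- diag(n) > 0
  dimnames(reach) <- list(ids, ids)
  repeat {
    nxt <- reach | (reach %*% adj > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  sort(ids[reach[, reach_id]])
}

# Connected-components oracle for FCN delineation: undirected reach graph
# with barrier->downstream edges deleted, via igraph.
igraph_fcn_oracle <- function(reaches, barrier_reach_ids) {
  has_down <- !is.na(reaches$downstream_id) &
    !(reaches$reach_id %in% barrier_reach_ids)
  g <- igraph::graph_from_data_frame(
    data.frame(from = reaches$reach_id[has_down],
               to = reaches$downstream_id[has_down]),
    directed = FALSE,
    vertices = data.frame(name = reaches$reach_id))
  comp <- igraph::components(g)$membership
  split(names(comp), comp)
}

# Barrier table row builder with all flags off by default.
make_barriers <- function(reach_ids, types,
                          passability = rep("complete", length(reach_ids)),
                          removed = FALSE, off_network = FALSE,
                          anadromous_upstream = FALSE) {
  barrier_set(data.frame(
    barrier_id = paste0("b", seq_along(reach_ids)),
    reach_id = reach_ids, barrier_type = types, passability = passability,
    removed = removed, off_network = off_network,
    anadromous_upstream = anadromous_upstream, stringsAsFactors = FALSE))
}

# Habitat summaries object with a hand-specified presence structure, for
# exercising rarity-weighted richness without a network.
make_presence_summaries <- function(presence_list) {
  out <- data.frame(fcn_id = names(presence_list),
                    richness = vapply(presence_list, length, integer(1)),
                    rwr = NA_real_, stringsAsFactors = FALSE)
  attr(out, "presence") <- presence_list
  out
}

# A small community pair with known counts.
make_pair <- function(t1, t2, sites = NULL, species = NULL) {
  if (!is.null(sites)) rownames(t1) <- rownames(t2) <- sites
  if (!is.null(species)) colnames(t1) <- colnames(t2) <- species
  community_pair(t1, t2)
}
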