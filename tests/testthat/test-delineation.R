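test_that("scenario selection keeps the right barrier classes", {
  b <- make_barriers(c("r1", "r2"), c("waterfall", "dam"),
                     passability = c("complete", "partial"))
  hist <- select_barriers(b, scenario("historical"))
  expect_equal(hist$barrier_type, "waterfall")
  curr <- select_barriers(b, scenario("current"))
  expect_setequal(curr$barrier_type, c("waterfall", "dam"))

  # a partially passable waterfall never counts; a partial dam does
  b2 <- make_barriers("r1", "waterfall", passability = "partial")
  expect_equal(nrow(select_barriers(b2, scenario("historical"))), 0)
  expect_equal(nrow(select_barriers(b2, scenario("current"))), 0)
})

test_that("exclusion flags disqualify barriers", {
  removed_dam <- make_barriers("r2", "dam", passability = "unknown",
                               removed = TRUE)
  expect_equal(nrow(select_barriers(removed_dam, scenario("current"))), 0)
  anad <- make_barriers("r2", "dam", anadromous_upstream = TRUE)
  expect_equal(nrow(select_barriers(anad, scenario("current"))), 0)
  off <- make_barriers("r2", "waterfall", off_network = TRUE)
  expect_equal(nrow(select_barriers(off, scenario("historical"))), 0)
})

test_that("an unfragmented single-outlet network is one FCN", {
  net <- river_network(make_random_tree(30, seed = 2))
  part <- delineate_fcns(net, NULL, "historical")
  expect_equal(nrow(part$fcns), 1)
  expect_equal(part$fcns$total_length_km, sum(net$reaches$length_km))
})

test_that("two waterfalls make three patches; one more dam makes four", {
  # a small branching watershed with a single outlet
  tab <- make_random_tree(25, seed = 5)
  net <- river_network(tab)
  non_term <- setdiff(tab$reach_id, tab$reach_id[is.na(tab$downstream_id)])
  wf <- make_barriers(non_term[c(3, 10)], c("waterfall", "waterfall"))
  hist <- delineate_fcns(net, select_barriers(wf, scenario("historical")),
                         "historical")
  expect_equal(nrow(hist$fcns), 3)

  all_b <- rbind(wf, make_barriers(non_term[17], "dam"))
  all_b$barrier_id <- paste0("b", seq_len(nrow(all_b)))
  curr <- delineate_fcns(net, select_barriers(all_b, scenario("current")),
                         "current")
  expect_equal(nrow(curr$fcns), 4)
})

test_that("delineation matches the connected-components oracle", {
  skip_if_not_installed("igraph")
  for (seed in 1:10) {
    tab <- make_random_tree(50, seed = seed)
    net <- river_network(tab)
    non_term <- setdiff(tab$reach_id, tab$reach_id[is.na(tab$downstream_id)])
    set.seed(seed + 100)
    cut_ids <- sample(non_term, 5)
    part <- delineate_fcns(net, make_barriers(cut_ids, rep("dam", 5)))
    ours <- split(part$membership$reach_id, part$membership$fcn_id)
    oracle <- igraph_fcn_oracle(tab, cut_ids)
    norm <- function(blocks) {
      blocks <- lapply(blocks, sort)
      unname(blocks[order(vapply(blocks, `[`, "", 1))])
    }
    expect_identical(norm(ours), norm(oracle))
  }
})

test_that("FCNs partition the reaches and k cuts give k+1 patches", {
  for (seed in 1:8) {
    n <- 40 + seed
    tab <- make_random_tree(n, seed = seed)
    net <- river_network(tab)
    non_term <- setdiff(tab$reach_id, tab$reach_id[is.na(tab$downstream_id)])
    set.seed(seed)
    k <- sample(0:6, 1)
    part <- delineate_fcns(net,
                           if (k > 0) make_barriers(sample(non_term, k),
                                                    rep("waterfall", k),
                                                    rep("complete", k)))
    expect_setequal(part$membership$reach_id, tab$reach_id)
    expect_false(anyDuplicated(part$membership$reach_id) > 0)
    expect_equal(sum(part$fcns$n_reaches), n)
    expect_equal(nrow(part$fcns), k + 1)
  }
})

test_that("adding a barrier never decreases count nor grows the max patch", {
  tab <- make_random_tree(60, seed = 3)
  net <- river_network(tab)
  non_term <- setdiff(tab$reach_id, tab$reach_id[is.na(tab$downstream_id)])
  set.seed(42)
  picks <- sample(non_term, 8)
  prev_n <- 0; prev_max <- Inf
  for (k in seq_along(picks)) {
    part <- delineate_fcns(net, make_barriers(picks[1:k], rep("dam", k)))
    expect_gte(nrow(part$fcns), prev_n)
    expect_lte(max(part$fcns$total_length_km), prev_max)
    prev_n <- nrow(part$fcns); prev_max <- max(part$fcns$total_length_km)
  }
})

test_that("terminus barriers are no-ops and co-located barriers collapse", {
  tab <- make_chain(4)
  net <- river_network(tab)
  term_b <- make_barriers("r4", "dam")
  expect_message(part <- delineate_fcns(net, term_b), "terminus")
  expect_equal(nrow(part$fcns), 1)

  two_same <- make_barriers(c("r2", "r2"), c("waterfall", "dam"))
  expect_equal(nrow(delineate_fcns(net, two_same)$fcns), 2)

  bad <- make_barriers("zz", "dam")
  expect_error(delineate_fcns(net, bad), "unknown reach")
})

test_that("delineation is invariant to reach row order", {
  tab <- make_random_tree(50, seed = 8)
  non_term <- setdiff(tab$reach_id, tab$reach_id[is.na(tab$downstream_id)])
  b <- make_barriers(non_term[c(2, 9, 21)], rep("dam", 3))
  p1 <- delineate_fcns(river_network(tab), b)
  p2 <- delineate_fcns(river_network(tab[rev(seq_len(nrow(tab))), ]), b)
  expect_identical(p1$membership, p2$membership)
  expect_identical(p1$fcns, p2$fcns)
})

test_that("FCN summaries aggregate counts and mean lengths", {
  tab <- make_chain(2, lengths = c(10, 30))
  tab$downstream_id <- NA # two disconnected one-reach drainages
  part <- delineate_fcns(river_network(tab), NULL)
  s <- summarize_fcns(part)
  all_row <- s[s$ecoregion_id == "all", ]
  expect_equal(all_row$n_fcn, 2)
  expect_equal(all_row$mean_length_km, 20)

  # group means recombine to the overall mean through the counts
  tab2 <- make_random_tree(80, seed = 6)
  part2 <- delineate_fcns(river_network(tab2),
                          make_barriers(tab2$reach_id[c(5, 20, 40)],
                                        rep("dam", 3)))
  s2 <- summarize_fcns(part2)
  grp <- s2[s2$ecoregion_id != "all", ]
  expect_equal(sum(grp$n_fcn * grp$mean_length_km) / sum(grp$n_fcn),
               s2$mean_length_km[s2$ecoregion_id == "all"])
})

test_that("percent change follows the reporting arithmetic", {
  expect_equal(percent_change(2711, 4321, digits = 0), 59)
  expect_equal(percent_change(84.4, 52.9, digits = 0), -37)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 10), "zero baseline")
  # reporting rounds half away from zero
  expect_equal(round_half_away(c(0.5, -0.5)), c(1, -1))
  expect_equal(round_half_away(-81.25, 1), -81.3)
})
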