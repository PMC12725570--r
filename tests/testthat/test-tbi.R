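test_that("the Sorensen decomposition counts losses and gains per site", {
  t1 <- rbind(c(1, 1, 1, 0), c(1, 0, 1, 0), c(1, 1, 0, 0), c(0, 0, 0, 0))
  t2 <- rbind(c(1, 0, 0, 1), c(1, 0, 1, 0), c(0, 0, 1, 1), c(0, 0, 0, 0))
  pair <- make_pair(t1, t2, sites = paste0("s", 1:4))
  res <- tbi_components(pair)
  expect_equal(res$a[1], 1); expect_equal(res$b[1], 2); expect_equal(res$c[1], 1)
  expect_equal(res$D[1], 0.6)
  expect_equal(res$B[1], 0.4)
  expect_equal(res$C[1], 0.2)
  expect_equal(res$D[2], 0) # unchanged site
  expect_true(is.na(res$D[4])) # empty in both periods
  # disjoint nonempty rows are maximally dissimilar
  dis <- tbi_components(make_pair(rbind(c(1, 0)), rbind(c(0, 1))))
  expect_equal(dis$D, 1)
})

test_that("identities D = B + C and richness margins hold on random data", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(3:30, 1); p <- sample(2:15, 1)
    t1 <- matrix(rbinom(n * p, 1, runif(1, 0.2, 0.8)), n, p)
    t2 <- matrix(rbinom(n * p, 1, runif(1, 0.2, 0.8)), n, p)
    res <- tbi_components(community_pair(t1, t2))
    ok <- !is.na(res$D)
    expect_equal(res$D[ok], res$B[ok] + res$C[ok])
    expect_true(all(res$D[ok] >= 0 & res$D[ok] <= 1))
    expect_true(all(res$B[ok] >= 0 & res$C[ok] >= 0))
    expect_equal(res$a + res$b, as.integer(rowSums(t1)))
    expect_equal(res$a + res$c, as.integer(rowSums(t2)))
  }
})

test_that("unchanged sites get permutation p = 1", {
  t1 <- matrix(rbinom(40, 1, 0.5), 8, 5)
  pair <- community_pair(t1, t1)
  res <- tbi_permutation_test(pair, n_perm = 99, seed = 3)
  ok <- !is.na(res$D)
  expect_true(all(res$p_value[ok] == 1))
})

test_that("permutation p matches the exact column-null tail probability", {
  # Under independent column permutation the entries landing in one site's
  # row are independent draws from each column's values, so the exact tail
  # P(D_perm >= D_obs) is a small enumeration over 0/1 row patterns.
  exact_tail <- function(t1, t2, site) {
    p <- ncol(t1)
    m1 <- colMeans(t1); m2 <- colMeans(t2)
    tail_p <- 0
    obs <- tbi_components(community_pair(t1, t2))$D[site]
    grid <- expand.grid(rep(list(0:1), 2 * p))
    for (g in seq_len(nrow(grid))) {
      r1 <- as.integer(grid[g, 1:p]); r2 <- as.integer(grid[g, p + 1:p])
      pr <- prod(ifelse(r1 == 1, m1, 1 - m1)) *
        prod(ifelse(r2 == 1, m2, 1 - m2))
      a <- sum(r1 & r2); b <- sum(r1 & !r2); cc <- sum(!r1 & r2)
      d <- if (2 * a + b + cc == 0) NA else (b + cc) / (2 * a + b + cc)
      if (!is.na(d) && d >= obs) tail_p <- tail_p + pr
    }
    tail_p
  }
  set.seed(5)
  t1 <- matrix(c(1, 1, 0, 0, 1, 0, 1, 0), 4, 2)
  t2 <- matrix(c(1, 0, 0, 1, 0, 0, 1, 1), 4, 2)
  pair <- community_pair(t1, t2)
  res <- tbi_permutation_test(pair, n_perm = 4999, seed = 11)
  for (site in 1:4) {
    tau <- exact_tail(t1, t2, site)
    expect_equal(res$p_value[site], (1 + 4999 * tau) / (1 + 4999),
                 tolerance = 0.06)
  }
})

test_that("permutation p-values are reproducible given the seed", {
  set.seed(2)
  t1 <- matrix(rbinom(60, 1, 0.5), 10, 6)
  t2 <- matrix(rbinom(60, 1, 0.4), 10, 6)
  pair <- community_pair(t1, t2)
  a <- tbi_permutation_test(pair, n_perm = 199, seed = 7)
  b <- tbi_permutation_test(pair, n_perm = 199, seed = 7)
  expect_identical(a, b)
  c_ <- tbi_permutation_test(pair, n_perm = 199, seed = 8)
  expect_false(identical(a$p_value, c_$p_value))
})

test_that("the joint site permutation scheme is also available", {
  set.seed(4)
  t1 <- matrix(rbinom(60, 1, 0.5), 10, 6)
  t2 <- matrix(rbinom(60, 1, 0.4), 10, 6)
  res <- tbi_permutation_test(community_pair(t1, t2), n_perm = 99, seed = 1,
                              scheme = "sites")
  expect_true(all(res$p_value > 0 & res$p_value <= 1, na.rm = TRUE))
})

test_that("dominance test recognizes loss-only change and symmetry", {
  t1 <- matrix(1L, 10, 4)
  t2 <- t1; t2[, 1] <- 0L # every site loses species 1, gains none
  res <- tbi_components(community_pair(t1, t2))
  dom <- dominance_test(res, n_perm = 999, seed = 2)
  expect_equal(dom$direction, "loss")
  expect_equal(dom$mean_C, 0)
  expect_lte(dom$p, 0.05)

  # perfectly balanced loss and gain components cannot be significant
  t2b <- t1; t2b[, 1] <- 0L; t2b <- cbind(t2b, rep(1L, 10)) # gain col
  t1b <- cbind(t1, rep(0L, 10))
  resb <- tbi_components(community_pair(t1b, t2b))
  expect_equal(resb$B, resb$C)
  domb <- dominance_test(resb, n_perm = 999, seed = 2)
  expect_equal(domb$direction, "none")
})

test_that("dominance recovers an injected loss bias across replicates", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    t1 <- matrix(rbinom(200, 1, 0.6), 20, 10)
    keep <- matrix(runif(200) > 0.25, 20, 10)
    t2 <- t1 * (keep * 1L) # 25% loss rate, no gains
    res <- tbi_components(community_pair(t1, t2))
    dom <- dominance_test(res, n_perm = 199, seed = s)
    if (dom$direction == "loss") hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("per-species paired tests flag consistent losses only", {
  set.seed(10)
  n <- 12
  t1 <- cbind(rep(1L, n), rbinom(n, 1, 0.6), rep(1L, n))
  t2 <- cbind(rep(0L, n), t1[, 2], rep(1L, n))
  pair <- make_pair(t1, t2, species = c("lost", "noisy", "stable"))
  res <- species_paired_tests(pair, n_perm = 1999, seed = 5)
  # exhaustive sign-flip oracle: only the all-plus and all-minus flips of a
  # constant difference vector reach |t| = Inf, so the exact tail is 2/2^12
  tau <- 2 / 2^n
  expect_equal(res$p_raw[res$species == "lost"],
               (1 + 1999 * tau) / (1 + 1999), tolerance = 0.05)
  expect_equal(res$p_raw[res$species == "stable"], 1)
  expect_equal(res$p_adj, p.adjust(res$p_raw, "holm"))
  expect_error(species_paired_tests(make_pair(t1[1, , drop = FALSE],
                                              t2[1, , drop = FALSE])),
               "two sites")
})

test_that("occupancy change reproduces the reporting arithmetic", {
  counts <- data.frame(h = c(55, 756, 315, 128, 10),
                       c = c(16, 109, 63, 24, 0))
  n <- max(counts$h)
  t1 <- sapply(counts$h, function(k) rep(c(1L, 0L), c(k, n - k)))
  t2 <- sapply(counts$c, function(k) rep(c(1L, 0L), c(k, n - k)))
  pair <- community_pair(t1, t2)
  oc <- occupancy_change(pair)
  expect_equal(oc$n_hist, counts$h)
  expect_equal(oc$delta, counts$c - counts$h)
  expect_equal(oc$pct_change, c(-70.9, -85.6, -80.0, -81.3, -100))

  # conservation: shared + lost species over sites equals all t1 presences
  res <- tbi_components(pair)
  expect_equal(sum(res$a + res$b), sum(t1))
})

test_that("range types join onto the species table", {
  t1 <- matrix(rbinom(30, 1, 0.5), 10, 3,
               dimnames = list(NULL, c("s1", "s2", "s3")))
  pair <- community_pair(t1, t1)
  oc <- occupancy_change(pair, range_types = c(s1 = "anadromous",
                                               s2 = "narrow", s3 = "wide"))
  expect_equal(oc$range_type, c("anadromous", "narrow", "wide"))
})
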