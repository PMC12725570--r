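grid_coords <- function(n_side) {
  as.matrix(expand.grid(x = seq_len(n_side), y = seq_len(n_side)))
}

test_that("spatial weights are inverse-distance, thresholded, row-normed", {
  co <- grid_coords(3)
  w <- spatial_weights(co, threshold = 1.2)
  expect_equal(unname(diag(w$A)), rep(0, 9))
  expect_equal(w$A, t(w$A))
  # only rook neighbours at distance 1 survive a 1.2 threshold
  expect_equal(w$A[1, 2], 1)
  expect_equal(w$A[1, 5], 0) # diagonal neighbour at sqrt(2) is cut
  expect_true(all(abs(rowSums(w$W) - 1) < 1e-12))
})

test_that("sites without neighbours are flagged as islands", {
  co <- rbind(c(0, 0), c(1, 0), c(100, 100))
  expect_message(w <- spatial_weights(co, 2), "no neighbour")
  expect_equal(unname(w$islands), 3L)
  expect_equal(unname(rowSums(w$W)[3]), 0)
})

test_that("Moran's I equals the closed-form double sum on a hand case", {
  co <- rbind(c(0, 0), c(1, 0), c(2, 0), c(0, 1), c(1, 1))
  x <- c(1, 3, 2, 5, 4)
  w <- spatial_weights(co, threshold = 1.2)
  m <- morans_i(x, w, n_perm = 99, seed = 1)
  # independent recomputation of the statistic, written out longhand
  z <- x - mean(x)
  num <- 0
  for (i in 1:5) for (j in 1:5) num <- num + w$W[i, j] * z[i] * z[j]
  oracle <- (5 / sum(w$W)) * num / sum(z^2)
  expect_equal(m$I, oracle)
  expect_equal(m$expected_I, -1 / 4)
})

test_that("Moran's I agrees with an independent implementation", {
  skip_if_not_installed("ape")
  set.seed(6)
  co <- matrix(runif(40), 20, 2)
  x <- rnorm(20)
  w <- spatial_weights(co, threshold = 0.5)
  ours <- morans_i(x, w, n_perm = 49, seed = 1)
  theirs <- ape::Moran.I(x, w$W, scaled = FALSE)
  expect_equal(ours$I, theirs$observed, tolerance = 1e-10)
})

test_that("the permutation null centres on -1/(n-1)", {
  set.seed(12)
  n <- 20
  co <- matrix(runif(2 * n), n, 2)
  w <- spatial_weights(co, threshold = 0.6)
  x <- rnorm(n)
  z <- x - mean(x)
  i_of <- function(xx) {
    zz <- xx - mean(xx)
    (n / sum(w$W)) * as.numeric(zz %*% w$W %*% zz) / sum(zz^2)
  }
  perm_mean <- mean(replicate(3000, i_of(sample(x))))
  expect_lt(abs(perm_mean - (-1 / (n - 1))), 0.01)
})

test_that("a linear gradient is detected as positive autocorrelation", {
  co <- cbind(seq_len(25), 0)
  w <- spatial_weights(co, threshold = 1.5)
  m <- morans_i(seq_len(25) + rnorm(25, 0, 0.01), w, n_perm = 199, seed = 2)
  expect_gt(m$I, 0)
  expect_lte(m$p_value, 0.05)
})

test_that("zero-variance input gives an undefined Moran's I", {
  w <- spatial_weights(grid_coords(2), 1.5)
  expect_warning(m <- morans_i(rep(1, 4), w, n_perm = 9), "zero variance")
  expect_true(is.na(m$I))
})

test_that("MEM eigenvectors are orthogonal and Moran-ordered", {
  set.seed(3)
  co <- matrix(runif(30), 15, 2)
  w <- spatial_weights(co, threshold = 0.7)
  mem <- mem_spatial_predictors(w)
  g <- crossprod(mem)
  expect_equal(g, diag(ncol(mem)), tolerance = 1e-8, ignore_attr = TRUE)
  # the leading eigenvector has the largest Moran's I of the set
  ivals <- apply(mem, 2, function(v) morans_i(v, w, n_perm = 9, seed = 1)$I)
  expect_equal(unname(which.max(ivals)), 1L)
  expect_true(all(diff(attr(mem, "eigenvalues")) <= 1e-9))
  # eigenvalues agree with a direct dense eigensolve of the centred matrix
  n <- nrow(w$A)
  h <- diag(n) - matrix(1 / n, n, n)
  ev <- eigen(h %*% w$A %*% h, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(attr(mem, "eigenvalues"),
               ev[seq_len(ncol(mem))], tolerance = 1e-9)
})

test_that("orthogonal predictors survive pruning untouched", {
  set.seed(9)
  x <- data.frame(a = rnorm(100), b = rnorm(100))
  y <- rnorm(100)
  out <- prune_predictors(x, y)
  expect_setequal(out$kept, c("a", "b"))
  expect_equal(nrow(out$removed), 0)
})

test_that("duplicate and constant columns are removed with reasons", {
  set.seed(10)
  a <- rnorm(60)
  x <- data.frame(a = a, dup = a, z = rep(1, 60), b = rnorm(60))
  y <- a + rnorm(60, 0, 0.1)
  out <- prune_predictors(x, y)
  expect_true("ZV" %in% out$removed$reason[out$removed$predictor == "z"])
  expect_equal(sum(c("a", "dup") %in% out$kept), 1)
})

test_that("pruned output respects both thresholds and the greedy oracle", {
  greedy_oracle <- function(x, y, ct, vt) {
    repeat {
      if (ncol(x) < 2) break
      cm <- abs(cor(x)); diag(cm) <- 0
      if (max(cm) <= ct) break
      ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      pair <- colnames(cm)[ij]
      rel <- sapply(pair, function(nm)
        abs(cor(x[[nm]], y, method = "spearman")))
      x[[pair[which.min(rel)]]] <- NULL
    }
    repeat {
      if (ncol(x) < 2) break
      v <- sapply(names(x), function(nm)
        1 / (1 - summary(lm(x[[nm]] ~ ., x[setdiff(names(x), nm)]))$r.squared))
      if (max(v) <= vt) break
      x[[names(which.max(v))]] <- NULL
    }
    names(x)
  }
  set.seed(77)
  base <- matrix(rnorm(300), 50, 6)
  x <- as.data.frame(base)
  x$V2 <- x$V1 * 0.95 + rnorm(50, 0, 0.1)
  x$V4 <- x$V3 + x$V5 + rnorm(50, 0, 0.05)
  y <- x$V1 + rnorm(50)
  out <- prune_predictors(x, y)
  kept <- out$kept
  cm <- abs(cor(x[kept])); diag(cm) <- 0
  expect_lte(max(cm), 0.75)
  v <- sapply(kept, function(nm)
    1 / (1 - summary(lm(x[[nm]] ~ ., x[setdiff(kept, nm)]))$r.squared))
  expect_lte(max(v), 5)
  expect_setequal(kept, greedy_oracle(x, y, 0.75, 5))
})

test_that("a protected predictor is never dropped for its proxy", {
  set.seed(21)
  a <- rnorm(80)
  x <- data.frame(total = a, proxy = a + rnorm(80, 0, 0.05),
                  other = rnorm(80))
  y <- a + rnorm(80, 0, 0.2)
  out <- prune_predictors(x, y, preference = "total")
  expect_true("total" %in% out$kept)
  expect_false("proxy" %in% out$kept)
})
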