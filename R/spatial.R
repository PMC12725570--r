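#' Inverse-distance spatial weights with a distance threshold
#'
#' Pairs closer than the threshold get weight `1/d_ij`; others (and the
#' diagonal) get zero. The symmetric matrix is kept for eigenvector
#' (MEM) construction; a row-normalized copy is used in Moran's I. Sites
#' with no neighbour inside the threshold are flagged.
#'
#' @param coords two-column matrix of planar site coordinates
#' @param threshold distance threshold, same units as `coords`
#' @return a `spatial_weights` list: `$threshold`, `$W` (row-normalized),
#'   `$A` (symmetric, unnormalized), `$islands` (row indices with no
#'   neighbours)
#' @export
spatial_weights <- function(coords, threshold) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, threshold > 0)
  d <- as.matrix(stats::dist(coords))
  a <- ifelse(d > 0 & d <= threshold, 1 / d, 0)
  diag(a) <- 0
  rs <- rowSums(a)
  islands <- which(rs == 0)
  if (length(islands) > 0L) {
    message(length(islands), " site(s) with no neighbour within threshold ",
            format(threshold))
  }
  w <- a / ifelse(rs > 0, rs, 1)
  structure(list(threshold = threshold, W = w, A = a, islands = islands),
            class = "spatial_weights")
}

#' Moran's I with permutation significance
#'
#' Global spatial autocorrelation
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the centred
#' values and `S0` the sum of weights; expectation `-1/(n-1)` under the
#' permutation null. Significance comes from randomly permuting the values
#' over sites (one-sided for positive autocorrelation by default, the
#' direction relevant to residual diagnostics).
#'
#' @param x numeric values, one per site
#' @param w a [spatial_weights()]
#' @param n_perm number of permutations
#' @param seed integer seed
#' @param alternative `"greater"` (default) or `"two.sided"`
#' @return list: `I`, `expected_I`, `p_value`, `n`
#' @export
morans_i <- function(x, w, n_perm = 499, seed = 1,
                     alternative = c("greater", "two.sided")) {
  stopifnot(inherits(w, "spatial_weights"))
  alternative <- match.arg(alternative)
  n <- length(x)
  stopifnot(n >= 3, n == nrow(w$W))
  if (stats::sd(x) == 0) {
    warning("zero variance; Moran's I undefined", call. = FALSE)
    return(list(I = NA_real_, expected_I = -1 / (n - 1), p_value = NA_real_,
                n = n))
  }
  i_of <- function(z) {
    z <- z - mean(z)
    (n / sum(w$W)) * as.numeric(z %*% w$W %*% z) / sum(z^2)
  }
  i_obs <- i_of(x)
  set.seed(seed)
  exceed <- 0L
  for (k in seq_len(n_perm)) {
    ip <- i_of(x[sample.int(n)])
    hit <- if (alternative == "greater") ip >= i_obs else
      abs(ip + 1 / (n - 1)) >= abs(i_obs + 1 / (n - 1))
    if (hit) exceed <- exceed + 1L
  }
  list(I = i_obs, expected_I = -1 / (n - 1),
       p_value = (1 + exceed) / (1 + n_perm), n = n)
}

#' Moran eigenvector maps
#'
#' Eigenvectors of the double-centred symmetric weight matrix
#' `(I - 11'/n) A (I - 11'/n)` with positive eigenvalues, in decreasing
#' eigenvalue order — eigenvalue order is Moran's-I order, so the first
#' column is the smoothest, most positively autocorrelated spatial
#' pattern. These serve as spatial predictor candidates for the
#' random-forest stage.
#'
#' @param w a [spatial_weights()]
#' @param tol eigenvalues below `tol * max(eigenvalue)` are dropped
#' @return matrix with columns `MEM1`, `MEM2`, ...
#' @export
mem_spatial_predictors <- function(w, tol = 1e-9) {
  stopifnot(inherits(w, "spatial_weights"))
  a <- w$A
  n <- nrow(a)
  if (n < 3L) stop("too few sites for MEM construction", call. = FALSE)
  h <- diag(n) - matrix(1 / n, n, n)
  e <- eigen(h %*% a %*% h, symmetric = TRUE)
  pos <- which(e$values > tol * max(abs(e$values)))
  if (length(pos) == 0L) stop("no positive eigenvalues", call. = FALSE)
  v <- e$vectors[, pos, drop = FALSE]
  colnames(v) <- paste0("MEM", seq_along(pos))
  attr(v, "eigenvalues") <- e$values[pos]
  v
}

#' Prune collinear predictors
#'
#' Drops zero-variance predictors, then iteratively resolves pairwise
#' correlations above `cor_threshold` (within a violating pair, the
#' predictor less rank-correlated with the response is dropped), then drops
#' the worst-VIF predictor until every variance inflation factor is at most
#' `vif_threshold`.
#'
#' @param x numeric predictor data frame (no missing values)
#' @param y numeric response
#' @param cor_threshold maximum allowed pairwise |Pearson r|
#' @param vif_threshold maximum allowed VIF
#' @param preference predictors protected from dropping (a preference
#'   order, as collinearity filters in spatial-RF tooling support): in a
#'   violating pair the unprotected member is dropped, so a hypothesis
#'   variable is never replaced by a collinear proxy
#' @return list: `kept` (names), `removed` (data frame `predictor`,
#'   `reason` in \{"ZV", "Cor", "VIF"\})
#' @export
prune_predictors <- function(x, y, cor_threshold = 0.75, vif_threshold = 5,
                             preference = NULL) {
  x <- as.data.frame(x)
  stopifnot(ncol(x) >= 2, nrow(x) == length(y), !anyNA(x))
  removed <- data.frame(predictor = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  drop_one <- function(nm, why) {
    removed <<- rbind(removed, data.frame(predictor = nm, reason = why,
                                          stringsAsFactors = FALSE))
    x[[nm]] <<- NULL
  }
  for (nm in names(x)) {
    if (stats::sd(x[[nm]]) == 0) drop_one(nm, "ZV")
  }
  if (ncol(x) == 0L) stop("all predictors removed", call. = FALSE)
  relevance <- function(nm) abs(stats::cor(x[[nm]], y, method = "spearman"))
  repeat {
    if (ncol(x) < 2L) break
    cm <- abs(stats::cor(x))
    diag(cm) <- 0
    if (max(cm) <= cor_threshold) break
    ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    pair <- colnames(cm)[ij]
    prot <- pair %in% preference
    loser <- if (sum(prot) == 1L) pair[!prot] else
      pair[which.min(vapply(pair, relevance, numeric(1)))]
    drop_one(loser, "Cor")
  }
  vif_of <- function() {
    vapply(names(x), function(nm) {
      r2 <- summary(stats::lm(x[[nm]] ~ ., data = x[setdiff(names(x), nm)])
                    )$r.squared
      if (r2 >= 1) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  while (ncol(x) >= 2L) {
    v <- vif_of()
    if (max(v) <= vif_threshold) break
    cand <- v[!names(v) %in% preference]
    if (length(cand) == 0L) cand <- v
    drop_one(names(cand)[which.max(cand)], "VIF")
  }
  if (ncol(x) == 0L) stop("all predictors removed", call. = FALSE)
  list(kept = names(x), removed = removed)
}
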