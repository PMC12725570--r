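#' Two-period community pair
#'
#' Aligned site-by-species binary occupancy matrices for a historical and a
#' current period.
#'
#' @param t1,t2 binary matrices (or data frames) with identical dimnames:
#'   rows are sites (HUC-12s), columns are species; entries in \{0, 1\}
#' @return a `community_pair` list with integer matrices `$t1`, `$t2`
#' @export
community_pair <- function(t1, t2) {
  t1 <- as.matrix(t1); t2 <- as.matrix(t2)
  if (!identical(dim(t1), dim(t2))) {
    stop("the two community matrices must have the same shape", call. = FALSE)
  }
  if (!is.null(rownames(t1)) && !identical(rownames(t1), rownames(t2))) {
    stop("site labels differ between periods", call. = FALSE)
  }
  if (!is.null(colnames(t1)) && !identical(colnames(t1), colnames(t2))) {
    stop("species labels differ between periods", call. = FALSE)
  }
  if (!all(t1 %in% c(0, 1)) || !all(t2 %in% c(0, 1))) {
    stop("community matrices must be binary", call. = FALSE)
  }
  storage.mode(t1) <- "integer"; storage.mode(t2) <- "integer"
  structure(list(t1 = t1, t2 = t2), class = "community_pair")
}

tbi_abc_ <- function(t1, t2) {
  a <- as.integer(rowSums(t1 == 1L & t2 == 1L))
  b <- as.integer(rowSums(t1 == 1L & t2 == 0L))
  c_ <- as.integer(rowSums(t1 == 0L & t2 == 1L))
  denom <- 2L * a + b + c_
  list(a = a, b = b, c = c_, denom = denom,
       B = ifelse(denom > 0, b / denom, NA_real_),
       C = ifelse(denom > 0, c_ / denom, NA_real_),
       D = ifelse(denom > 0, (b + c_) / denom, NA_real_))
}

#' Temporal beta-diversity decomposition per site
#'
#' For each site, counts species shared between the two periods (`a`), lost
#' (`b`, present only historically) and gained (`c`, present only
#' currently), and decomposes the Sorensen dissimilarity
#' `D = (b + c) / (2a + b + c)` into a loss component `B = b / (2a+b+c)`
#' and a gain component `C = c / (2a+b+c)`, so `D = B + C` exactly. Sites
#' empty in both periods have an undefined index (`NA`).
#'
#' @param pair a [community_pair()]
#' @return data frame: `site`, `a`, `b`, `c`, `denom`, `B`, `C`, `D`,
#'   `p_value` (`NA` until [tbi_permutation_test()]), `significant`
#' @export
tbi_components <- function(pair) {
  stopifnot(inherits(pair, "community_pair"))
  k <- tbi_abc_(pair$t1, pair$t2)
  sites <- rownames(pair$t1)
  if (is.null(sites)) sites <- as.character(seq_len(nrow(pair$t1)))
  data.frame(site = sites, a = k$a, b = k$b, c = k$c, denom = k$denom,
             B = k$B, C = k$C, D = k$D, p_value = NA_real_,
             significant = NA, stringsAsFactors = FALSE)
}

#' Permutation test of per-site temporal change
#'
#' Tests, for each site, the null hypothesis that the site is not
#' exceptionally different between the two periods relative to randomly
#' generated assemblages that could have been observed there. The default
#' scheme (`"columns"`) permutes each species column independently across
#' sites, separately in each period's matrix, and recomputes every site's
#' dissimilarity each round; the alternative (`"sites"`) applies one common
#' row permutation to both matrices jointly, preserving within-site species
#' associations. P-values use the add-one estimator
#' `(1 + #\{D_perm >= D_obs\}) / (1 + n_perm)` so they are never zero, and
#' permuted values tied with the observed one count as exceedances.
#'
#' @param pair a [community_pair()]
#' @param n_perm number of permutations (default 9999)
#' @param seed integer seed; results are reproducible bit-for-bit given
#'   `(seed, n_perm, scheme)`
#' @param alpha significance level for the `significant` flag
#' @param scheme `"columns"` (default) or `"sites"`
#' @return the [tbi_components()] data frame with `p_value` and
#'   `significant` filled (undefined sites stay `NA`)
#' @export
tbi_permutation_test <- function(pair, n_perm = 9999, seed = 1,
                                 alpha = 0.05,
                                 scheme = c("columns", "sites")) {
  stopifnot(inherits(pair, "community_pair"), n_perm >= 1)
  scheme <- match.arg(scheme)
  res <- tbi_components(pair)
  n <- nrow(pair$t1)
  d_obs <- res$D
  set.seed(seed)
  if (scheme == "columns") {
    exceed <- tbi_perm_exceed(pair$t1, pair$t2, d_obs, as.integer(n_perm))
  } else {
    exceed <- integer(n)
    for (k in seq_len(n_perm)) {
      p1 <- pair$t1[sample.int(n), , drop = FALSE]
      p2 <- pair$t2[sample.int(n), , drop = FALSE]
      d_perm <- tbi_abc_(p1, p2)$D
      hit <- !is.na(d_perm) & !is.na(d_obs) & d_perm >= d_obs
      exceed[hit] <- exceed[hit] + 1L
    }
  }
  res$p_value <- ifelse(is.na(d_obs), NA_real_,
                        (1 + exceed) / (1 + n_perm))
  res$significant <- res$p_value <= alpha
  res
}

#' Loss/gain dominance across sites
#'
#' Paired comparison of the loss (`B`) and gain (`C`) components across
#' sites by sign-flip permutation of the per-site differences `B - C`.
#' Undefined sites are excluded with a logged count.
#'
#' @param results a [tbi_components()] data frame
#' @param n_perm number of sign-flip permutations
#' @param seed integer seed
#' @param alpha significance level
#' @return list: `direction` (`"loss"`, `"gain"` or `"none"`), `mean_B`,
#'   `mean_C`, `p` (two-sided)
#' @export
dominance_test <- function(results, n_perm = 9999, seed = 1, alpha = 0.05) {
  ok <- !is.na(results$D)
  if (sum(ok) < 2L) stop("need at least two defined sites", call. = FALSE)
  n_drop <- sum(!ok)
  if (n_drop > 0L) message(n_drop, " undefined site(s) excluded")
  d <- results$B[ok] - results$C[ok]
  obs <- mean(d)
  set.seed(seed)
  exceed <- 0L
  for (k in seq_len(n_perm)) {
    flip <- sample(c(-1, 1), length(d), replace = TRUE)
    if (abs(mean(flip * d)) >= abs(obs)) exceed <- exceed + 1L
  }
  p <- (1 + exceed) / (1 + n_perm)
  direction <- if (p > alpha || obs == 0) "none" else
    if (obs > 0) "loss" else "gain"
  list(direction = direction, mean_B = mean(results$B[ok]),
       mean_C = mean(results$C[ok]), p = p)
}

#' Per-species paired permutation tests
#'
#' For each species, a paired t statistic on the site-wise occupancy
#' differences (current minus historical), with significance from sign-flip
#' permutation of the differences (two-sided, add-one estimator) and a
#' multiple-testing correction across species. A species unchanged at every
#' site has p = 1; a species changed identically at every occupied site has
#' an infinite t statistic and attains the minimum permutation p.
#'
#' @param pair a [community_pair()]
#' @param n_perm number of sign-flip permutations
#' @param seed integer seed
#' @param correction p-adjustment method: `"holm"` (default),
#'   `"bonferroni"` or `"BH"`
#' @param range_types optional named character vector, species id ->
#'   range type (`anadromous`, `narrow`, `wide`)
#' @return data frame: `species`, `range_type`, `n_hist`, `n_curr`,
#'   `delta`, `pct_change`, `t_stat`, `p_raw`, `p_adj`
#' @export
species_paired_tests <- function(pair, n_perm = 9999, seed = 1,
                                 correction = c("holm", "bonferroni", "BH"),
                                 range_types = NULL) {
  stopifnot(inherits(pair, "community_pair"))
  correction <- match.arg(correction)
  n <- nrow(pair$t1)
  if (n < 2L) stop("need at least two sites", call. = FALSE)
  diffs <- pair$t2 - pair$t1
  t_of <- function(d) {
    s <- stats::sd(d)
    if (s == 0) {
      if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    } else {
      mean(d) / (s / sqrt(length(d)))
    }
  }
  p_raw <- numeric(ncol(diffs))
  t_obs <- apply(diffs, 2L, t_of)
  set.seed(seed)
  for (j in seq_len(ncol(diffs))) {
    d <- diffs[, j]
    if (all(d == 0)) {
      p_raw[j] <- 1
      next
    }
    exceed <- 0L
    for (k in seq_len(n_perm)) {
      tp <- t_of(sample(c(-1, 1), n, replace = TRUE) * d)
      if (abs(tp) >= abs(t_obs[j])) exceed <- exceed + 1L
    }
    p_raw[j] <- (1 + exceed) / (1 + n_perm)
  }
  occ <- occupancy_change(pair, range_types)
  occ$t_stat <- as.numeric(t_obs)
  occ$p_raw <- p_raw
  occ$p_adj <- stats::p.adjust(p_raw, method = correction)
  occ
}

#' Species occupancy change between periods
#'
#' Column sums of the two occupancy matrices, their difference, and the
#' percent change from the historical count (rounded half away from zero to
#' one decimal, the reporting convention for occupancy tables).
#'
#' @param pair a [community_pair()]
#' @param range_types optional named character vector, species id ->
#'   range type
#' @return data frame: `species`, `range_type`, `n_hist`, `n_curr`,
#'   `delta`, `pct_change`
#' @export
occupancy_change <- function(pair, range_types = NULL) {
  stopifnot(inherits(pair, "community_pair"))
  sp <- colnames(pair$t1)
  if (is.null(sp)) sp <- as.character(seq_len(ncol(pair$t1)))
  n_hist <- as.integer(colSums(pair$t1))
  n_curr <- as.integer(colSums(pair$t2))
  pct <- ifelse(n_hist > 0,
                round_half_away(100 * (n_curr - n_hist) / n_hist, 1),
                NA_real_)
  rt <- if (is.null(range_types)) NA_character_ else
    as.character(range_types[sp])
  data.frame(species = sp, range_type = rt, n_hist = n_hist,
             n_curr = n_curr, delta = n_curr - n_hist, pct_change = pct,
             stringsAsFactors = FALSE)
}
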