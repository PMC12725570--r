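#' Spatial random forest with Moran-eigenvector augmentation
#'
#' Fits a random forest of the response (per-site temporal beta-diversity)
#' on habitat-change and condition predictors, checks the out-of-bag
#' residuals for spatial autocorrelation (Moran's I with permutation
#' significance at each distance threshold), and — if any threshold is
#' significant — adds Moran eigenvector map (MEM) columns one at a time, in
#' decreasing eigenvalue order, until the residuals are non-significant at
#' every threshold or the candidates are exhausted (then a warning). The
#' final model is then refit `n_runs` times under different seeds to obtain
#' the distribution of out-of-bag R-squared and permutation importances.
#' Forest hyperparameters are the library defaults.
#'
#' @param x numeric predictor data frame (already pruned, no missing values)
#' @param y numeric response, one value per row of `x`
#' @param coords two-column matrix of site coordinates
#' @param thresholds distance thresholds for the residual diagnostics;
#'   `NULL` uses the quartiles (25/50/75%) of the pairwise distances
#' @param n_runs number of repeated final fits (default 30)
#' @param seed integer seed governing every random step
#' @param n_perm permutations for each Moran test
#' @param alpha residual-significance level
#' @param max_mem maximum number of MEM columns considered
#' @param min_sites minimum number of sites (default 30)
#' @return an `rf_runset` list: `$oob_r2` (length `n_runs`), `$importance`
#'   (runs x predictors matrix), `$residual_moran` (data frame per
#'   threshold for the final model), `$spatial_predictors_used`, `$models`
#'   (the `n_runs` ranger fits), `$data` (the augmented predictor frame),
#'   `$thresholds`
#' @export
fit_spatial_rf <- function(x, y, coords, thresholds = NULL, n_runs = 30,
                           seed = 1, n_perm = 199, alpha = 0.05,
                           max_mem = 20, min_sites = 30) {
  x <- as.data.frame(x)
  coords <- as.matrix(coords)
  n <- nrow(x)
  stopifnot(length(y) == n, nrow(coords) == n)
  if (n < min_sites) {
    stop("need at least ", min_sites, " sites for the forest stage",
         call. = FALSE)
  }
  if (is.null(thresholds)) {
    dd <- as.numeric(stats::dist(coords))
    thresholds <- as.numeric(stats::quantile(dd, c(0.25, 0.5, 0.75)))
  }
  wlist <- lapply(thresholds, function(th) spatial_weights(coords, th))

  fit_once <- function(dat, s) {
    ranger::ranger(y = y, x = dat, importance = "permutation",
                   seed = s, num.threads = 1)
  }
  resid_moran <- function(fit, s) {
    res <- y - fit$predictions # out-of-bag residuals
    out <- lapply(seq_along(wlist), function(i) {
      m <- morans_i(res, wlist[[i]], n_perm = n_perm, seed = s + i)
      data.frame(threshold = thresholds[i], I = m$I,
                 expected_I = m$expected_I, p_value = m$p_value)
    })
    do.call(rbind, out)
  }

  dat <- x
  fit <- fit_once(dat, seed)
  rm_tab <- resid_moran(fit, seed)
  mem_used <- character(0)
  if (any(rm_tab$p_value <= alpha, na.rm = TRUE)) {
    # candidates from the threshold with the strongest residual structure
    w_star <- wlist[[which.min(rm_tab$p_value)]]
    mems <- mem_spatial_predictors(w_star)
    mems <- mems[, seq_len(min(ncol(mems), max_mem)), drop = FALSE]
    for (j in seq_len(ncol(mems))) {
      dat[[colnames(mems)[j]]] <- mems[, j]
      mem_used <- c(mem_used, colnames(mems)[j])
      fit <- fit_once(dat, seed + j)
      rm_tab <- resid_moran(fit, seed + j)
      if (all(rm_tab$p_value > alpha, na.rm = TRUE)) break
    }
    if (any(rm_tab$p_value <= alpha, na.rm = TRUE)) {
      warning("residual spatial autocorrelation remains after ",
              length(mem_used), " MEM predictors", call. = FALSE)
    }
  }

  run_seeds <- seed + 1000L + seq_len(n_runs)
  models <- lapply(run_seeds, function(s) fit_once(dat, s))
  oob_r2 <- vapply(models, function(m) m$r.squared, numeric(1))
  importance <- t(vapply(models, function(m) m$variable.importance,
                         numeric(ncol(dat))))
  rownames(importance) <- paste0("run", seq_len(n_runs))
  structure(list(oob_r2 = oob_r2, importance = importance,
                 residual_moran = rm_tab,
                 spatial_predictors_used = mem_used,
                 models = models, data = dat, response = y,
                 thresholds = thresholds),
            class = "rf_runset")
}

#' @export
print.rf_runset <- function(x, ...) {
  cat(sprintf(
    "<rf_runset> %d runs, median OOB R^2 = %.3f, %d spatial predictor(s)\n",
    length(x$oob_r2), stats::median(x$oob_r2),
    length(x$spatial_predictors_used)))
  invisible(x)
}

#' Median importance ranking over repeated runs
#'
#' @param runset an `rf_runset`
#' @param include_spatial include the MEM columns in the ranking
#' @return data frame `predictor`, `median_importance`, `rank` (1 = most
#'   important), sorted by rank
#' @export
importance_ranking <- function(runset, include_spatial = FALSE) {
  stopifnot(inherits(runset, "rf_runset"))
  med <- apply(runset$importance, 2L, stats::median)
  if (!include_spatial) {
    med <- med[!names(med) %in% runset$spatial_predictors_used]
  }
  out <- data.frame(predictor = names(med), median_importance = as.numeric(med),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$median_importance), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Partial dependence of the response on one predictor
#'
#' Evaluates the fitted forests over a grid of the predictor's observed
#' range while every other predictor (including any spatial columns) is
#' held at its 0.5 quantile, averaging predictions across all repeated
#' runs.
#'
#' @param runset an `rf_runset`
#' @param predictor name of a fitted predictor
#' @param grid_size number of grid points
#' @return data frame `value`, `prediction`
#' @export
partial_dependence <- function(runset, predictor, grid_size = 25) {
  stopifnot(inherits(runset, "rf_runset"))
  dat <- runset$data
  if (!predictor %in% names(dat)) {
    stop("unknown predictor: ", predictor, call. = FALSE)
  }
  grid <- seq(min(dat[[predictor]]), max(dat[[predictor]]),
              length.out = grid_size)
  base <- as.data.frame(lapply(dat, function(col) stats::median(col)))
  newdata <- base[rep(1L, grid_size), , drop = FALSE]
  newdata[[predictor]] <- grid
  preds <- vapply(runset$models, function(m) {
    stats::predict(m, data = newdata, num.threads = 1)$predictions
  }, numeric(grid_size))
  data.frame(value = grid, prediction = rowMeans(preds))
}

#' Spearman screening of predictors against the response
#'
#' Reporting helper: rank correlation of each predictor with the response,
#' with test p-values. Used for exploration, never for selection.
#'
#' @param x predictor data frame
#' @param y response
#' @return data frame `predictor`, `rho`, `p_value`, sorted by |rho|
#' @export
spearman_screen <- function(x, y) {
  x <- as.data.frame(x)
  out <- do.call(rbind, lapply(names(x), function(nm) {
    ct <- suppressWarnings(
      stats::cor.test(x[[nm]], y, method = "spearman", exact = FALSE))
    data.frame(predictor = nm, rho = unname(ct$estimate),
               p_value = ct$p.value, stringsAsFactors = FALSE)
  }))
  out[order(-abs(out$rho)), ]
}
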