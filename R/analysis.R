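#' Perceived shock intensity of one cell
#'
#' Time-averaged relative reduction of cellular volume (or projected size)
#' following shocks: for each shock whose pre- and post-onset windows are
#' covered by the trace, the drop is `(V_pre - V_post) / V_pre` with
#' `V_pre` the mean over the `pre_window_min` before onset and `V_post` the
#' minimum within `post_window_min` after onset; the cell's perceived shock
#' intensity is the mean drop over those shocks.
#'
#' @param times,values the volume/size trace (minutes, arbitrary units).
#' @param schedule the [shock_schedule()].
#' @param post_window_min window after shock onset searched for the
#'   minimum.
#' @param pre_window_min averaging window before onset.
#' @return scalar fraction, or `NA` if the trace covers no shock.
#' @export
perceived_shock <- function(times, values, schedule, post_window_min = 12,
                            pre_window_min = 6) {
  drops <- c()
  for (j in seq_len(nrow(schedule$intervals))) {
    s <- schedule$intervals[j, 1]
    pre <- values[times >= s - pre_window_min & times < s]
    post <- values[times >= s & times <= s + post_window_min]
    if (length(pre) == 0 || length(post) == 0) next
    v_pre <- mean(pre)
    drops <- c(drops, (v_pre - min(post)) / v_pre)
  }
  if (length(drops) == 0) return(NA_real_)
  mean(drops)
}

# internal: Spearman rho + two-tailed p with pairwise-complete dropping
spearman_pair <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(rho = NA_real_, p = NA_real_, n = length(x)))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  c(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Spearman correlations between parameters and features
#'
#' Rank correlation of every parameter column against every feature
#' column, with two-tailed p-values; missing entries are dropped pairwise
#' and constant columns reported as `NA`.
#'
#' @param params data frame with `cell_id` and parameter columns (any of
#'   `k_m, g_m, k_p, g_p, k_mp`).
#' @param features data frame with `cell_id` and numeric feature columns.
#' @return list of matrices `rho`, `p`, `n` (parameters x features).
#' @export
correlate_features <- function(params, features) {
  mg <- merge(params, features, by = "cell_id")
  if (nrow(mg) < 10) stop("argument error: fewer than 10 paired rows")
  pcols <- intersect(c("k_m", "g_m", "k_p", "g_p", "k_mp"), names(params))
  fcols <- setdiff(names(features)[vapply(features, is.numeric,
                                          logical(1))], "cell_id")
  rho <- p <- nmat <- matrix(NA_real_, length(pcols), length(fcols),
                             dimnames = list(pcols, fcols))
  for (a in pcols) for (b in fcols) {
    r <- spearman_pair(mg[[a]], mg[[b]])
    rho[a, b] <- r["rho"]; p[a, b] <- r["p"]; nmat[a, b] <- r["n"]
  }
  list(rho = rho, p = p, n = nmat)
}

#' PCA of single-cell parameters and weighted feature ranking
#'
#' Principal component analysis of the standardized log-parameters. Each
#' feature is then scored by its weighted average rank correlation with the
#' components, the weights being the components' variance fractions:
#' `score(f) = sum_c varfrac_c * |rho(PC_c, f)|`. Features are ranked by
#' this score, which summarizes how strongly a feature tracks the overall
#' parameter variability rather than any single parameter.
#'
#' @param params data frame with `cell_id` and at least two of
#'   `k_m, g_m, k_p, g_p, k_mp` (log taken internally; defaults to the four
#'   natural rates when all are present).
#' @param features data frame with `cell_id` and numeric features.
#' @param param_cols which parameter columns to analyze.
#' @return list of class `pca_summary`: `loadings`, `variance_fractions`,
#'   `pc_feature_rho`, `pc_feature_p`, `feature_scores` (sorted), `scores`
#'   (cell x component).
#' @export
pca_rank <- function(params, features,
                     param_cols = intersect(c("k_m", "g_m", "k_p", "g_p"),
                                            names(params))) {
  if (length(param_cols) < 2)
    stop("argument error: need at least two parameter columns")
  mg <- merge(params, features, by = "cell_id")
  if (nrow(mg) < 10) stop("argument error: fewer than 10 cells")
  Z <- log(as.matrix(mg[, param_cols]))
  pc <- stats::prcomp(Z, center = TRUE, scale. = TRUE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  fcols <- setdiff(names(features)[vapply(features, is.numeric,
                                          logical(1))], "cell_id")
  k <- length(vf)
  rho <- p <- matrix(NA_real_, k, length(fcols),
                     dimnames = list(paste0("PC", seq_len(k)), fcols))
  for (c_ in seq_len(k)) for (b in fcols) {
    r <- spearman_pair(pc$x[, c_], mg[[b]])
    rho[c_, b] <- r["rho"]; p[c_, b] <- r["p"]
  }
  scores <- colSums(vf * abs(ifelse(is.na(rho), 0, rho)))
  names(vf) <- paste0("PC", seq_len(k))
  structure(list(loadings = pc$rotation, variance_fractions = vf,
                 pc_feature_rho = rho, pc_feature_p = p,
                 feature_scores = sort(scores, decreasing = TRUE),
                 scores = pc$x),
            class = "pca_summary")
}

#' Bootstrap test of mother/daughter parameter inheritance
#'
#' Compares, per parameter, the distance `|ln theta_daughter - ln
#' theta_mother|` between related mother/daughter (MD) pairs and
#' non-related mother/daughter (nMD) pairs — a mother paired with another
#' mother's daughter from the same dataset. For each of `n_boot` bootstrap
#' resamples, `n_pairs` MD pairs are drawn with replacement and `n_pairs`
#' distinct nMD pairs without replacement; the one-sided p-value is the
#' fraction of resamples in which the mean MD distance is at least the mean
#' nMD distance. The relative closeness is `1 - mean(MD) / mean(nMD)` over
#' the full pair pools.
#'
#' @param params data frame with `cell_id` and parameter columns.
#' @param lineage data frame with `daughter_id`, `mother_id`.
#' @param n_pairs pairs per resample (at least this many MD pairs must
#'   exist).
#' @param n_boot bootstrap resamples.
#' @param seed optional seed.
#' @param param_cols parameters tested.
#' @return list of class `inheritance_report`: `table` (data frame with
#'   `parameter, mean_md, mean_nmd, closeness_pct, p_value`), `n_pairs`,
#'   `n_boot`, `n_md_available`.
#' @export
inheritance_test <- function(params, lineage, n_pairs = 40,
                             n_boot = 50000, seed = NULL,
                             param_cols = intersect(c("k_mp", "g_m", "g_p",
                                                      "k_m", "k_p"),
                                                    names(params))) {
  if (!is.null(seed)) set.seed(seed)
  pl <- lineage[lineage$daughter_id %in% params$cell_id &
                lineage$mother_id %in% params$cell_id, , drop = FALSE]
  if (nrow(pl) < n_pairs)
    stop("test error: fewer than ", n_pairs, " mother/daughter pairs")
  idx <- function(ids) match(ids, params$cell_id)
  mom_of <- stats::setNames(pl$mother_id, pl$daughter_id)
  mothers <- unique(pl$mother_id)
  daughters <- pl$daughter_id
  # all (mother, daughter) combinations that are NOT related
  combos <- expand.grid(m = mothers, d = daughters,
                        stringsAsFactors = FALSE)
  combos <- combos[mom_of[combos$d] != combos$m, , drop = FALSE]
  rows <- list()
  for (pc in param_cols) {
    v <- log(params[[pc]])
    d_md <- abs(v[idx(pl$daughter_id)] - v[idx(pl$mother_id)])
    d_nmd <- abs(v[idx(combos$d)] - v[idx(combos$m)])
    md_means <- rowMeans(matrix(sample(d_md, n_pairs * n_boot,
                                       replace = TRUE), n_boot))
    nmd_means <- vapply(seq_len(n_boot), function(b)
      mean(d_nmd[sample.int(length(d_nmd), n_pairs)]), numeric(1))
    rows[[pc]] <- data.frame(
      parameter = pc,
      mean_md = mean(d_md),
      mean_nmd = mean(d_nmd),
      closeness_pct = 100 * (1 - mean(d_md) / mean(d_nmd)),
      p_value = mean(md_means >= nmd_means),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, n_pairs = n_pairs, n_boot = n_boot,
                 n_md_available = nrow(pl)),
            class = "inheritance_report")
}

#' @export
print.inheritance_report <- function(x, ...) {
  cat("Mother/daughter inheritance bootstrap (", x$n_md_available,
      " MD pairs, ", x$n_boot, " resamples of ", x$n_pairs, ")\n",
      sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Mother vs daughter comparison of a single-cell feature
#'
#' Mean relative daughter-minus-mother difference of a feature and the
#' rank correlation between mothers' and daughters' values (a negative
#' correlation indicates anti-inheritance: extreme mothers have
#' opposite-extreme daughters).
#'
#' @param features data frame with `cell_id` and the feature.
#' @param lineage data frame with `daughter_id`, `mother_id`.
#' @param feature feature column name.
#' @return list: `mean_rel_diff`, `rho`, `p`, `n_pairs`.
#' @export
md_feature_comparison <- function(features, lineage,
                                  feature = "perceived_shock") {
  fm <- features[[feature]][match(lineage$mother_id, features$cell_id)]
  fd <- features[[feature]][match(lineage$daughter_id, features$cell_id)]
  ok <- is.finite(fm) & is.finite(fd)
  if (any(ok & fm == 0)) {
    warning("dropping ", sum(ok & fm == 0),
            " pair(s) with zero-valued mother feature")
    ok <- ok & fm != 0
  }
  fm <- fm[ok]; fd <- fd[ok]
  if (length(fm) < 10)
    stop("argument error: fewer than 10 mother/daughter feature pairs")
  r <- spearman_pair(fm, fd)
  list(mean_rel_diff = mean((fd - fm) / fm),
       rho = unname(r["rho"]), p = unname(r["p"]), n_pairs = length(fm))
}
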