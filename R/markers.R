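#' Univariate biomarker screening
#'
#' Tests every feature for abundance differences across sample groups:
#' Wilcoxon rank-sum for two groups (exact enumeration when both groups have
#' at most 10 samples and there are no ties, normal approximation with tie
#' correction otherwise), Kruskal-Wallis for more. P-values are
#' Benjamini-Hochberg adjusted across features; candidates are features with
#' `q <= q_max`.
#'
#' @param table an [abundance_table()]
#' @param groups group label per sample (>= 2 groups, each of size >= 2)
#' @param q_max FDR cut for candidate markers (default 0.05)
#' @return data.frame with feature_id, test, statistic, p, q, candidate
#' @export
candidate_markers <- function(table, groups, q_max = 0.05) {
  stopifnot(inherits(table, "abundance_table"))
  groups <- as.character(groups)
  if (length(groups) != length(table$sample_ids))
    stop("one group label per sample required")
  sizes <- table(groups)
  if (length(sizes) < 2L || any(sizes < 2L))
    stop("need >= 2 groups, each with >= 2 samples")
  two <- length(sizes) == 2L
  lev <- names(sizes)
  rows <- lapply(table$feature_ids, function(f) {
    x <- table$values[, f]
    if (length(unique(x)) == 1L)
      return(data.frame(feature_id = f,
                        test = if (two) "wilcoxon" else "kruskal_wallis",
                        statistic = NA_real_, p = 1, stringsAsFactors = FALSE))
    if (two) {
      x1 <- x[groups == lev[1]]; x2 <- x[groups == lev[2]]
      exact <- length(x1) <= 10 && length(x2) <= 10 &&
        !anyDuplicated(c(x1, x2))
      wt <- suppressWarnings(wilcox.test(x1, x2, exact = exact,
                                         correct = !exact))
      data.frame(feature_id = f, test = "wilcoxon",
                 statistic = unname(wt$statistic), p = wt$p.value,
                 stringsAsFactors = FALSE)
    } else {
      kt <- suppressWarnings(kruskal.test(x, factor(groups)))
      data.frame(feature_id = f, test = "kruskal_wallis",
                 statistic = unname(kt$statistic), p = kt$p.value,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$candidate <- out$q <= q_max
  out[order(out$p, out$feature_id), ]
}

#' Rank candidate markers by random-forest permutation importance
#'
#' Fits a random forest of `n_trees` randomized trees on the candidate
#' features and measures each feature's contribution as the mean
#' out-of-bag-style accuracy drop over 10 random shuffles of that feature
#' (seeded, hence deterministic). Features are ranked by decreasing
#' importance. A single candidate trivially gets rank 1.
#'
#' @param table an [abundance_table()]
#' @param groups group label per sample
#' @param candidates character vector of candidate feature IDs
#' @param n_trees forest size (default 500)
#' @param n_shuffles shuffles per feature for permutation importance
#' @param seed RNG seed
#' @return data.frame with feature_id, rf_importance, rf_rank
#' @export
rank_markers_rf <- function(table, groups, candidates, n_trees = 500,
                            n_shuffles = 10, seed = 1) {
  stopifnot(inherits(table, "abundance_table"))
  candidates <- intersect(candidates, table$feature_ids)
  if (length(candidates) == 0L) stop("no candidate features to rank")
  if (length(table$sample_ids) < 4L) stop("need >= 4 samples")
  if (length(candidates) == 1L)
    return(data.frame(feature_id = candidates, rf_importance = NA_real_,
                      rf_rank = 1L, stringsAsFactors = FALSE))
  X <- as.data.frame(table$values[, candidates, drop = FALSE])
  colnames(X) <- make.names(candidates)
  y <- factor(as.character(groups))
  imp <- with_seed(seed, {
    fit <- ranger::ranger(x = X, y = y, num.trees = n_trees,
                          num.threads = 1, seed = child_seed(seed, "rf"))
    base_acc <- mean(predict(fit, X, num.threads = 1)$predictions == y)
    vapply(seq_along(candidates), function(j) {
      drops <- vapply(seq_len(n_shuffles), function(s) {
        Xp <- X
        Xp[[j]] <- sample(Xp[[j]])
        base_acc - mean(predict(fit, Xp, num.threads = 1)$predictions == y)
      }, numeric(1))
      mean(drops)
    }, numeric(1))
  })
  ord <- order(-imp, candidates)
  data.frame(feature_id = candidates[ord], rf_importance = imp[ord],
             rf_rank = seq_along(candidates), stringsAsFactors = FALSE)
}

#' Full marker report: univariate screen plus random-forest ranking
#'
#' @inheritParams candidate_markers
#' @inheritParams rank_markers_rf
#' @return the [candidate_markers()] table with rf_importance and rf_rank
#'   filled in for candidates
#' @export
marker_report <- function(table, groups, q_max = 0.05, n_trees = 500,
                          seed = 1) {
  screen <- candidate_markers(table, groups, q_max = q_max)
  screen$rf_importance <- NA_real_
  screen$rf_rank <- NA_integer_
  cand <- screen$feature_id[screen$candidate]
  if (length(cand) >= 1L && length(table$sample_ids) >= 4L) {
    rf <- rank_markers_rf(table, groups, cand, n_trees = n_trees, seed = seed)
    idx <- match(rf$feature_id, screen$feature_id)
    screen$rf_importance[idx] <- rf$rf_importance
    screen$rf_rank[idx] <- rf$rf_rank
  }
  screen
}
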