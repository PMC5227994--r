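#' Alpha diversity index of one sample
#'
#' `observed` = number of features with positive abundance; `shannon` =
#' `-sum p_i ln p_i` (natural log); `simpson` = Gini-Simpson `1 - sum p_i^2`;
#' `chao1` = bias-corrected `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` with F1/F2
#' the singleton/doubleton counts (integer counts required).
#'
#' @param x non-negative abundance vector with positive sum
#' @param which index name
#' @return index value
#' @export
alpha_index <- function(x, which = c("observed", "shannon", "simpson", "chao1")) {
  which <- match.arg(which)
  if (any(x < 0)) stop("abundances must be non-negative")
  total <- sum(x)
  if (total <= 0) stop("alpha diversity undefined for an all-zero sample")
  if (which == "observed") return(sum(x > 0))
  if (which == "chao1") {
    if (any(x != round(x))) stop("chao1 requires integer counts")
    s_obs <- sum(x > 0)
    f1 <- sum(x == 1)
    f2 <- sum(x == 2)
    return(s_obs + f1 * (f1 - 1) / (2 * (f2 + 1)))
  }
  p <- x[x > 0] / total
  if (which == "shannon") -sum(p * log(p)) else 1 - sum(p^2)
}

#' Alpha diversity summary for every sample of a count table
#'
#' @param table an [abundance_table()]; chao1 is reported only for count
#'   tables
#' @return data.frame with sample_id, observed_otus, shannon, simpson, chao1
#' @export
alpha_table <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  rows <- lapply(table$sample_ids, function(s) {
    x <- table$values[s, ]
    if (sum(x) <= 0)
      return(data.frame(sample_id = s, observed_otus = 0, shannon = NA_real_,
                        simpson = NA_real_, chao1 = NA_real_))
    data.frame(sample_id = s,
               observed_otus = alpha_index(x, "observed"),
               shannon = alpha_index(x, "shannon"),
               simpson = alpha_index(x, "simpson"),
               chao1 = if (table$kind == "count") alpha_index(x, "chao1")
                       else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bootstrapped rarefaction curve of one sample
#'
#' At each depth, `B` rarefied count vectors are drawn without replacement;
#' the index is evaluated on the per-OTU mean of the `B` draws (so the curve
#' reflects the bootstrap-averaged community, not the average index).
#'
#' @param counts integer OTU count vector
#' @param depths strictly increasing depths, all `<= sum(counts)`
#' @param B bootstrap replicates per depth (default 20)
#' @param index `"observed"` or `"shannon"`
#' @param seed RNG seed
#' @return data.frame with columns depth and value; attribute `B`
#' @export
rarefaction_curve <- function(counts, depths, B = 20,
                              index = c("observed", "shannon"), seed = 1) {
  index <- match.arg(index)
  if (length(depths) == 0L) stop("empty depth grid")
  if (any(diff(depths) <= 0)) stop("depths must be strictly increasing")
  if (B < 1) stop("B must be >= 1")
  if (max(depths) > sum(counts))
    stop("depths exceed the sample total ", sum(counts))
  values <- with_seed(seed, vapply(depths, function(d) {
    draws <- vapply(seq_len(B), function(b)
      rarefy_unseeded(counts, d), numeric(length(counts)))
    mean_vec <- rowMeans(draws)
    alpha_index(mean_vec, index)
  }, numeric(1)))
  structure(data.frame(depth = as.integer(depths), value = values),
            B = as.integer(B), index = index)
}

# In-stream rarefaction (caller manages the seed).
rarefy_unseeded <- function(counts, depth) {
  total <- sum(counts)
  if (depth == total) return(as.numeric(counts))
  idx <- rep.int(seq_along(counts), counts)
  as.numeric(tabulate(sample(idx, depth, replace = FALSE),
                      nbins = length(counts)))
}

#' Association between alpha diversity and metadata factors
#'
#' Categorical factors: Kruskal-Wallis across groups, with an exact
#' permutation p-value (full enumeration of group assignments) when the
#' number of distinct assignments is small, otherwise the chi-square
#' approximation. Numeric factors: Spearman rho with a seeded permutation
#' p-value. Single-valued factors are skipped with a warning.
#'
#' @param alpha data.frame from [alpha_table()]
#' @param metadata data.frame from [read_metadata()] (rownames = sample IDs)
#' @param value column of `alpha` to test (default `"shannon"`)
#' @param n_perm permutations for numeric factors (default 10000)
#' @param seed RNG seed
#' @param exact_max enumerate the Kruskal-Wallis null exactly when the number
#'   of distinct assignments is at most this (default 5000)
#' @return data.frame with factor, type, statistic, p
#' @export
alpha_factor_stats <- function(alpha, metadata, value = "shannon",
                               n_perm = 10000, seed = 1, exact_max = 5000) {
  y <- alpha[[value]][match(rownames(metadata), alpha$sample_id)]
  ok <- !is.na(y)
  rows <- lapply(names(metadata), function(f) {
    v <- metadata[[f]][ok]
    yy <- y[ok]
    if (length(unique(v)) < 2L) {
      warning("factor '", f, "' is single-valued; skipped")
      return(NULL)
    }
    if (is.numeric(v)) {
      if (length(yy) < 4L) {
        warning("factor '", f, "': too few samples for a numeric test; skipped")
        return(NULL)
      }
      rho <- suppressWarnings(cor(yy, v, method = "spearman"))
      perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
        suppressWarnings(cor(yy, sample(v), method = "spearman")),
        numeric(1)))
      p <- (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (1 + n_perm)
      data.frame(factor = f, type = "numeric", statistic = rho, p = p,
                 stringsAsFactors = FALSE)
    } else {
      g <- factor(v)
      if (any(table(g) < 1L) || nlevels(g) < 2L) return(NULL)
      h_obs <- suppressWarnings(kruskal.test(yy, g)$statistic)
      n_arr <- n_distinct_arrangements(table(g))
      if (n_arr <= exact_max) {
        perms <- distinct_label_arrangements(as.character(g))
        h_all <- apply(perms, 2, function(lab)
          suppressWarnings(kruskal.test(yy, factor(lab))$statistic))
        p <- mean(h_all >= h_obs - 1e-12)
      } else {
        p <- suppressWarnings(kruskal.test(yy, g)$p.value)
      }
      data.frame(factor = f, type = "categorical", statistic = unname(h_obs),
                 p = p, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(factor = character(), type = character(),
                               statistic = numeric(), p = numeric())
  else out
}

n_distinct_arrangements <- function(sizes) {
  exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
}

# All distinct arrangements of a label multiset, one column each.
distinct_label_arrangements <- function(labels) {
  rec <- function(remaining) {
    m <- length(remaining)
    if (length(unique(remaining)) == 1L)
      return(matrix(remaining[1], nrow = m, ncol = 1))
    first <- remaining[1]
    k <- sum(remaining == first)
    picks <- combn(m, k)
    cols <- lapply(seq_len(ncol(picks)), function(j) {
      sub <- rec(remaining[remaining != first])
      out <- matrix(first, nrow = m, ncol = ncol(sub))
      out[-picks[, j], ] <- sub
      out
    })
    do.call(cbind, cols)
  }
  rec(sort(labels))
}
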