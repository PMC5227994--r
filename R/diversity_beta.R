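#' Phylogeny-aware similarity between two community profiles
#'
#' A tree-traversal similarity in the Meta-Storms spirit: shared abundance
#' matches at the leaves score in full, and unmatched residual mass is
#' propagated toward the root, decaying by `exp(-beta * branch_length)` on
#' every edge it crosses, where it can still match mass from the other
#' sample at deeper nodes. The result lies in \[0, 1\]; as `beta` grows it
#' converges to the plain leaf overlap `sum min(A_i, B_i)`.
#'
#' @param tree rooted `ape::phylo` with branch lengths; leaves = OTU IDs
#' @param A,B non-negative abundance vectors named by (a subset of) the tree
#'   leaves, each summing to 1 within 1e-9
#' @param beta decay rate per unit branch length (> 0, default 1)
#' @return similarity S in \[0, 1\]
#' @export
metastorms_similarity <- function(tree, A, B, beta = 1.0) {
  stopifnot(inherits(tree, "phylo"))
  if (beta <= 0) stop("beta must be > 0")
  leaves <- tree$tip.label
  a <- stats::setNames(numeric(length(leaves)), leaves)
  b <- a
  check_mass <- function(x, nm) {
    if (any(x < 0)) stop(nm, " has negative abundances")
    if (length(x) && is.null(names(x))) stop(nm, " must be named by tree leaves")
    if (!all(names(x) %in% leaves))
      stop(nm, " has non-leaf entries: ",
           paste(setdiff(names(x), leaves), collapse = ", "))
    if (abs(sum(x) - 1) > 1e-9)
      stop(nm, " must sum to 1 (got ", format(sum(x)), ")")
  }
  check_mass(A, "A"); check_mass(B, "B")
  a[names(A)] <- A
  b[names(B)] <- B

  # leaf matching
  m <- pmin(a, b)
  S <- sum(m)
  ra_leaf <- a - m
  rb_leaf <- b - m

  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(leaves)
  n_node <- n_tip + tr$Nnode
  ra <- numeric(n_node)
  rb <- numeric(n_node)
  ra[seq_len(n_tip)] <- ra_leaf[tr$tip.label]
  rb[seq_len(n_tip)] <- rb_leaf[tr$tip.label]

  # postorder edges: children are finished before their parent appears
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]
    child <- tr$edge[e, 2]
    decay <- exp(-beta * tr$edge.length[e])
    ra[parent] <- ra[parent] + ra[child] * decay
    rb[parent] <- rb[parent] + rb[child] * decay
    # once all edges into this parent are processed, match residuals there
    if (e == max(which(tr$edge[, 1] == parent))) {
      mm <- min(ra[parent], rb[parent])
      S <- S + mm
      ra[parent] <- ra[parent] - mm
      rb[parent] <- rb[parent] - mm
    }
  }
  min(1, max(0, S))
}

#' Pairwise phylogeny-aware distance matrix
#'
#' `D[i, j] = 1 - S(i, j)` from [metastorms_similarity()].
#'
#' @param profiles named list (or samples-by-leaves matrix) of abundance
#'   vectors, each summing to 1
#' @param tree rooted `ape::phylo`
#' @param beta decay rate (default 1)
#' @return a [sample_dist()]
#' @export
distance_matrix <- function(profiles, tree, beta = 1.0) {
  if (is.matrix(profiles))
    profiles <- stats::setNames(
      lapply(seq_len(nrow(profiles)), function(i) profiles[i, ]),
      rownames(profiles))
  ids <- names(profiles)
  if (length(ids) < 2L) stop("need >= 2 samples")
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- metastorms_similarity(tree, profiles[[i]], profiles[[j]], beta)
    D[i, j] <- D[j, i] <- 1 - s
  }
  sample_dist(D)
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Gower-centres `-0.5 * J D^2 J`, eigendecomposes, and scales eigenvectors
#' by the square roots of the positive eigenvalues. Negative eigenvalues are
#' reported but excluded from the coordinates. Axis signs are fixed by
#' making the largest-magnitude loading of each axis positive.
#'
#' @param D a [sample_dist()] (or symmetric matrix)
#' @param n_axes number of axes to keep (truncated with a warning when fewer
#'   positive eigenvalues exist)
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all),
#'   `explained` (fraction of positive-eigenvalue variance per kept axis)
#' @export
pcoa <- function(D, n_axes = 2) {
  if (inherits(D, "sample_dist")) D <- D$D
  if (n_axes < 1) stop("n_axes must be >= 1")
  n <- nrow(D)
  fit <- suppressWarnings(cmdscale(stats::as.dist(D), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > 1e-10)
  if (length(pos) == 0L) {
    coords <- matrix(0, n, n_axes,
                     dimnames = list(rownames(D), paste0("PCo", seq_len(n_axes))))
    return(list(coordinates = coords, eigenvalues = eig,
                explained = rep(0, n_axes)))
  }
  if (n_axes > length(pos)) {
    warning("only ", length(pos), " positive eigenvalues; axes truncated")
    n_axes <- length(pos)
  }
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  coords <- fix_axis_signs(coords)
  colnames(coords) <- paste0("PCo", seq_len(n_axes))
  rownames(coords) <- rownames(D)
  list(coordinates = coords, eigenvalues = eig,
       explained = eig[seq_len(n_axes)] / sum(eig[pos]))
}

#' Principal component analysis of an abundance table
#'
#' Column-centred singular value decomposition; the same axis-sign
#' convention as [pcoa()].
#'
#' @param table an [abundance_table()]
#' @param n_axes axes to keep
#' @return list with `coordinates`, `eigenvalues` (variances per component),
#'   `explained`
#' @export
pca <- function(table, n_axes = 2) {
  stopifnot(inherits(table, "abundance_table"))
  X <- table$values
  if (nrow(X) < 2L) stop("need >= 2 samples")
  fit <- prcomp(X, center = TRUE, scale. = FALSE)
  vars <- fit$sdev^2
  keep <- seq_len(min(n_axes, ncol(fit$x)))
  coords <- fix_axis_signs(fit$x[, keep, drop = FALSE])
  colnames(coords) <- paste0("PC", keep)
  total <- sum(vars)
  list(coordinates = coords, eigenvalues = vars,
       explained = if (total > 0) vars[keep] / total else vars[keep] * 0)
}

fix_axis_signs <- function(coords) {
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (length(i) && coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  coords
}

#' UPGMA (average-linkage) dendrogram of a distance matrix as Newick
#'
#' Agglomerates the closest pair at each step (ties: the lexicographically
#' smallest pair), with cluster heights equal to half the merge distance so
#' leaf-to-root path lengths are ultrametric.
#'
#' @param D a [sample_dist()] (or symmetric matrix)
#' @return Newick string (with branch lengths, terminated by `;`)
#' @export
upgma <- function(D) {
  if (inherits(D, "sample_dist")) D <- D$D
  n <- nrow(D)
  if (n < 2L) stop("need >= 2 samples")
  ids <- rownames(D)
  active <- lapply(seq_len(n), function(i)
    list(label = ids[i], newick = ids[i], size = 1L, height = 0))
  names(active) <- ids
  Dc <- D
  while (length(active) > 1L) {
    labs <- names(active)
    best <- NULL
    for (i in seq_len(length(labs) - 1)) for (j in (i + 1):length(labs)) {
      pair <- sort(c(labs[i], labs[j]))
      d <- Dc[labs[i], labs[j]]
      if (is.null(best) || d < best$d - 1e-12 ||
          (abs(d - best$d) <= 1e-12 &&
           (pair[1] < best$pair[1] ||
            (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
        best <- list(d = d, pair = pair)
      }
    }
    u <- active[[best$pair[1]]]; v <- active[[best$pair[2]]]
    h <- best$d / 2
    merged <- list(
      label = best$pair[1],
      newick = sprintf("(%s:%s,%s:%s)", u$newick,
                       format(h - u$height, digits = 15),
                       v$newick, format(h - v$height, digits = 15)),
      size = u$size + v$size, height = h)
    # average-linkage update
    others <- setdiff(names(active), best$pair)
    newD <- matrix(0, length(others) + 1, length(others) + 1,
                   dimnames = list(c(others, best$pair[1]),
                                   c(others, best$pair[1])))
    if (length(others)) {
      newD[others, others] <- Dc[others, others]
      for (o in others) {
        d_new <- (u$size * Dc[o, best$pair[1]] + v$size * Dc[o, best$pair[2]]) /
          (u$size + v$size)
        newD[o, best$pair[1]] <- newD[best$pair[1], o] <- d_new
      }
    }
    Dc <- newD
    active[[best$pair[2]]] <- NULL
    active[[best$pair[1]]] <- merged
  }
  paste0(active[[1]]$newick, ";")
}

#' PERMANOVA-style permutation test on a distance matrix
#'
#' Pseudo-F from squared distances: `SS_total = sum_{i<j} d_ij^2 / n`,
#' `SS_within = sum over groups of within-group pair sums / group size`,
#' `F = (SS_between / (g - 1)) / (SS_within / (n - g))`. The null is label
#' permutation: when the number of distinct relabelings is small enough the
#' test enumerates them all (`p = #{F_perm >= F_obs} / total`, identity
#' included); otherwise `n_perm` seeded Monte-Carlo permutations with
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#'
#' @param D a [sample_dist()] (or symmetric matrix)
#' @param labels group label per sample (each group needs >= 2 members)
#' @param n_perm Monte-Carlo permutations (default 10000)
#' @param seed RNG seed
#' @param exact_max enumerate exhaustively when the number of distinct
#'   relabelings is at most this (default 5000)
#' @return list with `pseudo_F`, `p`, `n_perm_used`, `exact`
#' @export
permutation_group_test <- function(D, labels, n_perm = 10000, seed = 1,
                                   exact_max = 5000) {
  if (inherits(D, "sample_dist")) D <- D$D
  labels <- as.character(labels)
  n <- nrow(D)
  if (length(labels) != n) stop("one label per sample required")
  sizes <- table(labels)
  if (length(sizes) < 2L) stop("need >= 2 groups")
  if (any(sizes < 2L)) stop("every group needs >= 2 samples")
  D2 <- D^2
  f_obs <- pseudo_f(D2, labels)
  n_arr <- n_distinct_arrangements(sizes)
  if (n_arr <= exact_max) {
    perms <- distinct_label_arrangements(labels)
    f_all <- apply(perms, 2, function(lab) pseudo_f(D2, lab))
    p <- mean(f_all >= f_obs - 1e-12)
    list(pseudo_F = f_obs, p = p, n_perm_used = ncol(perms), exact = TRUE)
  } else {
    f_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      pseudo_f(D2, sample(labels)), numeric(1)))
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
    list(pseudo_F = f_obs, p = p, n_perm_used = n_perm, exact = FALSE)
  }
}

pseudo_f <- function(D2, labels) {
  n <- nrow(D2)
  g <- length(unique(labels))
  ss_total <- sum(D2[upper.tri(D2)]) / n
  ss_within <- 0
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    sub <- D2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  (ss_between / (g - 1)) / (ss_within / (n - g))
}
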