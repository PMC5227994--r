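test_that("alpha indices match closed forms", {
  u4 <- c(5, 5, 5, 5)
  expect_equal(alpha_index(u4, "shannon"), log(4), tolerance = 1e-12)
  expect_equal(alpha_index(u4, "simpson"), 0.75, tolerance = 1e-12)
  expect_equal(alpha_index(u4, "observed"), 4)
  single <- c(9, 0, 0)
  expect_equal(alpha_index(single, "shannon"), 0)
  expect_equal(alpha_index(single, "simpson"), 0)
  # chao1 hand example: F1 = 2 singletons, F2 = 0 doubletons
  expect_equal(alpha_index(c(5, 3, 1, 1), "chao1"), 5)
  expect_error(alpha_index(c(1.5, 2), "chao1"), "integer")
  expect_error(alpha_index(c(0, 0), "shannon"), "all-zero")
})

test_that("chao1 never falls below observed richness", {
  with_seed_test(61, {
    for (i in 1:1000) {
      x <- rpois(sample(3:30, 1), sample(1:5, 1))
      if (sum(x) == 0) next
      expect_gte(alpha_index(x, "chao1"), alpha_index(x, "observed"))
    }
  })
})

test_that("rarefaction curves honour the bootstrap-mean rule", {
  counts <- c(40, 30, 20, 10)
  # full depth: every draw is the sample itself, any B
  rc <- rarefaction_curve(counts, depths = c(50, 100), B = 5, index = "shannon",
                          seed = 3)
  expect_equal(rc$value[2], alpha_index(counts, "shannon"), tolerance = 1e-12)
  expect_equal(attr(rarefaction_curve(counts, 10, index = "observed",
                                      seed = 1), "B"), 20L)  # default B
  expect_error(rarefaction_curve(counts, integer(0)), "empty")
  expect_error(rarefaction_curve(counts, c(10, 10)), "increasing")
  expect_identical(rarefaction_curve(counts, c(20, 60), seed = 9),
                   rarefaction_curve(counts, c(20, 60), seed = 9))
})

test_that("observed-OTU curves rise with depth on bootstrap means", {
  counts <- c(100, 40, 10, 4, 2, 1, 1)
  rc <- rarefaction_curve(counts, depths = c(10, 40, 100, 158), B = 200,
                          index = "observed", seed = 7)
  expect_true(all(diff(rc$value) >= 0))
})

test_that("factor association handles categorical, numeric, degenerate factors", {
  alpha <- data.frame(sample_id = sprintf("S%d", 1:4),
                      shannon = c(1, 2, 3, 4))
  meta <- data.frame(group = c("A", "A", "B", "B"),
                     ph = c(5.0, 5.5, 6.0, 6.5),
                     site = c("x", "x", "x", "x"),
                     row.names = alpha$sample_id, stringsAsFactors = FALSE)
  expect_warning(res <- alpha_factor_stats(alpha, meta, n_perm = 500, seed = 2),
                 "single-valued")
  kw <- res[res$factor == "group", ]
  # perfect separation of (1,2) vs (3,4): 2 of the 6 distinct assignments
  # reach the maximal H, so the exact permutation p is 1/3
  expect_equal(kw$p, 1 / 3, tolerance = 1e-12)
  sp <- res[res$factor == "ph", ]
  expect_equal(sp$statistic, 1)   # perfectly rank-correlated
  expect_false("site" %in% res$factor)
})

test_that("tree similarity is 1 on identical profiles and symmetric", {
  with_seed_test(62, {
    for (rep in 1:100) {
      n <- sample(4:16, 1)
      tree <- ape::rtree(n, br = function(k) rexp(k, 10))
      a <- rgamma(n, 1); a <- stats::setNames(a / sum(a), tree$tip.label)
      b <- rgamma(n, 1); b <- stats::setNames(b / sum(b), tree$tip.label)
      expect_equal(metastorms_similarity(tree, a, a), 1, tolerance = 1e-12)
      sab <- metastorms_similarity(tree, a, b)
      expect_equal(sab, metastorms_similarity(tree, b, a), tolerance = 1e-12)
      expect_gte(sab, 0); expect_lte(sab, 1)
    }
  })
})

test_that("two-leaf similarity matches the closed form", {
  tree <- ape::read.tree(text = "(L1:0.5,L2:0.5);")
  s <- metastorms_similarity(tree, c(L1 = 1, L2 = 0), c(L1 = 0, L2 = 1),
                             beta = 1)
  expect_equal(s, exp(-0.5), tolerance = 1e-12)
  # no leaf overlap, both residuals decay by e^-L before matching at the root
  s2 <- metastorms_similarity(tree, c(L1 = 1, L2 = 0), c(L1 = 0, L2 = 1),
                              beta = 2)
  expect_equal(s2, exp(-1), tolerance = 1e-12)
})

test_that("similarity on a star tree matches the hand formula", {
  tree <- ape::read.tree(text = "(X:0.2,Y:0.2,Z:0.2);")
  A <- c(X = 0.6, Y = 0.4, Z = 0)
  B <- c(X = 0.1, Y = 0.4, Z = 0.5)
  # leaf overlap 0.1 + 0.4; residuals (0.5, 0, 0) vs (0, 0, 0.5) decay by
  # e^-0.2 each and match min(0.5, 0.5) * e^-0.2 at the root
  expect_equal(metastorms_similarity(tree, A, B, beta = 1),
               0.5 + 0.5 * exp(-0.2), tolerance = 1e-12)
})

test_that("similarity decreases in beta toward pure leaf overlap", {
  tree <- ref9()$db$tree
  with_seed_test(63, {
    a <- rgamma(9, 1); a <- stats::setNames(a / sum(a), tree$tip.label)
    b <- rgamma(9, 1); b <- stats::setNames(b / sum(b), tree$tip.label)
  })
  s <- vapply(c(0.5, 1, 2, 5, 50), function(bb)
    metastorms_similarity(tree, a, b, beta = bb), numeric(1))
  expect_true(all(diff(s) <= 1e-12))
  overlap <- sum(pmin(a, b))
  expect_equal(metastorms_similarity(tree, a, b, beta = 500), overlap,
               tolerance = 1e-6)
  expect_gte(s[1], overlap)
  expect_error(metastorms_similarity(tree, a, b, beta = 0), "beta")
  expect_error(metastorms_similarity(tree, a * 2, b), "sum to 1")
})

test_that("distance matrices are symmetric with zero self-distance", {
  db <- ref9()$db
  with_seed_test(64, {
    profs <- lapply(1:4, function(i) {
      a <- rgamma(9, 1); stats::setNames(a / sum(a), db$tree$tip.label)
    })
  })
  names(profs) <- sprintf("S%d", 1:4)
  profs$S4 <- profs$S1   # duplicated sample
  dm <- distance_matrix(profs, db$tree)
  expect_equal(dm$D["S1", "S4"], 0, tolerance = 1e-12)
  expect_equal(dm$D, t(dm$D))
  expect_true(all(diag(dm$D) == 0))
})

test_that("PCoA recovers collinear and planar Euclidean configurations", {
  x <- c(0, 1, 2)
  D <- abs(outer(x, x, "-"))   # plain matrix: configuration-scale distances
  dimnames(D) <- list(letters[1:3], letters[1:3])
  ord <- pcoa(D, n_axes = 1)
  gaps <- as.vector(dist(ord$coordinates[, 1]))
  expect_equal(sort(gaps), c(1, 1, 2), tolerance = 1e-8)
  expect_equal(sum(ord$eigenvalues > 1e-8), 1L)

  with_seed_test(65, {
    P <- matrix(runif(12), ncol = 2)
  })
  D2 <- as.matrix(dist(P)); D2 <- D2 / max(D2)
  dimnames(D2) <- list(sprintf("s%d", 1:6), sprintf("s%d", 1:6))
  ord2 <- pcoa(sample_dist(D2), n_axes = 2)
  got <- as.matrix(dist(ord2$coordinates))
  expect_equal(unname(got), unname(D2), tolerance = 1e-8)
})

test_that("degenerate distance matrices give zero coordinates", {
  D <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  ord <- suppressWarnings(pcoa(sample_dist(D), n_axes = 2))
  expect_true(all(ord$coordinates == 0))
  expect_true(all(abs(ord$eigenvalues) < 1e-10))
})

test_that("PCA separates clusters and reports bounded explained variance", {
  m <- rbind(matrix(c(10, 0), 3, 2, byrow = TRUE),
             matrix(c(0, 10), 3, 2, byrow = TRUE))
  m <- m + matrix(seq(0, 0.5, length.out = 12), 6, 2)
  tab <- make_table(m)
  ord <- pca(tab, n_axes = 2)
  s1 <- ord$coordinates[1:3, 1]; s2 <- ord$coordinates[4:6, 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
  expect_lte(sum(ord$explained), 1 + 1e-12)
  ident <- make_table(matrix(5, 3, 4))
  ord0 <- pca(ident, n_axes = 2)
  expect_true(all(abs(ord0$coordinates) < 1e-10))
})

test_that("UPGMA reproduces the hand example and merge-height monotonicity", {
  D <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  nwk <- upgma(D)
  expect_equal(nwk, "((a:1,b:1):2,c:3);")
  tr <- ape::read.tree(text = nwk)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))

  with_seed_test(66, {
    for (rep in 1:10) {
      n <- sample(4:8, 1)
      P <- matrix(runif(2 * n), ncol = 2)
      D <- as.matrix(dist(P)); D <- D / max(D)
      dimnames(D) <- list(sprintf("s%d", 1:n), sprintf("s%d", 1:n))
      tr <- ape::read.tree(text = upgma(sample_dist(D)))
      if (is.null(tr)) next
      depths <- ape::node.depth.edgelength(tr)
      # ultrametric: all leaves at the same depth (= final merge height / 1)
      expect_lt(diff(range(depths[seq_len(n)])), 1e-8)
    }
  })
})

test_that("duplicated samples merge first, ties resolve deterministically", {
  D <- matrix(0.4, 4, 4); diag(D) <- 0
  dimnames(D) <- list(c("d", "b", "c", "a"), c("d", "b", "c", "a"))
  # all distances equal: the tie rule must merge a,b first
  nwk <- upgma(sample_dist(D))
  expect_match(nwk, "\\(a:0.2,b:0.2\\)")
  D2 <- D; D2["c", "d"] <- D2["d", "c"] <- 0
  nwk2 <- upgma(sample_dist(D2))
  expect_match(nwk2, "\\(c:0,d:0\\)")
})

test_that("the permutation group test is exact on the separated 3+3 case", {
  D <- matrix(1, 6, 6); diag(D) <- 0
  D[1:3, 1:3] <- 0; D[4:6, 4:6] <- 0
  dimnames(D) <- list(sprintf("s%d", 1:6), sprintf("s%d", 1:6))
  res <- permutation_group_test(sample_dist(D), rep(c("g1", "g2"), each = 3))
  expect_true(res$exact)
  expect_equal(res$n_perm_used, 20L)   # 6!/(3!3!) distinct relabelings
  expect_equal(res$p, 2 / 20, tolerance = 1e-12)
  expect_error(permutation_group_test(sample_dist(D), c(rep("a", 5), "b")),
               ">= 2")
})

test_that("the permutation test matches an independent PERMANOVA oracle", {
  skip_if_not_installed("vegan")
  with_seed_test(67, {
    P <- rbind(matrix(rnorm(14, 0), ncol = 2), matrix(rnorm(14, 2), ncol = 2))
  })
  D <- as.matrix(dist(P)); D <- D / max(D)
  ids <- sprintf("s%d", 1:14)
  dimnames(D) <- list(ids, ids)
  labels <- rep(c("a", "b"), each = 7)
  res <- permutation_group_test(sample_dist(D), labels, n_perm = 999, seed = 5)
  fit <- vegan::adonis2(stats::as.dist(D) ~ g,
                        data = data.frame(g = labels), permutations = 999)
  expect_equal(res$pseudo_F, fit$F[1], tolerance = 1e-9)
})

test_that("the permutation test holds its nominal type-I error", {
  n <- 12
  ids <- sprintf("s%d", 1:n)
  labels <- rep(c("a", "b"), each = n / 2)
  pvals <- with_seed_test(68, vapply(1:200, function(r) {
    P <- matrix(rnorm(2 * n), ncol = 2)
    D <- as.matrix(dist(P)); D <- D / max(D)
    dimnames(D) <- list(ids, ids)
    permutation_group_test(sample_dist(D), labels, n_perm = 400,
                           seed = r, exact_max = 400)$p
  }, numeric(1)))
  expect_lt(abs(mean(pvals <= 0.05) - 0.05), 0.03)
})
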