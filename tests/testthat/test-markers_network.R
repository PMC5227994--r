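# Exact two-sided Wilcoxon rank-sum p by full enumeration of group splits.
oracle_wilcoxon <- function(x1, x2) {
  pooled <- c(x1, x2)
  n1 <- length(x1)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- combn(length(pooled), n1)
  w_all <- apply(splits, 2, function(idx)
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(x2) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

test_that("perfectly separated features get the exact extreme p-value", {
  m <- matrix(0, 8, 2, dimnames = list(sprintf("s%d", 1:8), c("hit", "flat")))
  m[, "hit"] <- c(1, 2, 3, 4, 10, 11, 12, 13)
  m[, "flat"] <- 5
  tab <- abundance_table(m, kind = "count")
  groups <- rep(c("a", "b"), each = 4)
  res <- candidate_markers(tab, groups, q_max = 0.1)
  hit <- res[res$feature_id == "hit", ]
  expect_equal(hit$test, "wilcoxon")
  expect_equal(hit$p, 2 / 70, tolerance = 1e-12)  # 2 of C(8,4) splits
  expect_equal(hit$q, 2 * 2 / 70, tolerance = 1e-12)  # BH over 2 features
  flat <- res[res$feature_id == "flat", ]
  expect_equal(flat$p, 1)
  expect_false(flat$candidate)
  expect_true(hit$candidate)
})

test_that("exact Wilcoxon matches full enumeration for small groups", {
  with_seed_test(71, {
    for (rep in 1:25) {
      n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
      x <- round(rlnorm(n1 + n2), 3)
      if (anyDuplicated(x)) next
      m <- matrix(x, ncol = 1, dimnames = list(sprintf("s%d", 1:(n1 + n2)), "f"))
      res <- candidate_markers(abundance_table(m, kind = "count"),
                               rep(c("a", "b"), c(n1, n2)))
      expect_equal(res$p, oracle_wilcoxon(x[1:n1], x[(n1 + 1):(n1 + n2)]),
                   tolerance = 1e-9, label = sprintf("rep %d", rep))
    }
  })
})

test_that("more than two groups fall back to Kruskal-Wallis and BH is monotone", {
  with_seed_test(72, {
    m <- matrix(rlnorm(15 * 8), 15, 8,
                dimnames = list(sprintf("s%d", 1:15), sprintf("f%d", 1:8)))
    m[1:5, 1] <- m[1:5, 1] + 50   # one structured feature
  })
  groups <- rep(c("a", "b", "c"), each = 5)
  res <- candidate_markers(abundance_table(m, kind = "count"), groups)
  expect_true(all(res$test == "kruskal_wallis"))
  expect_true(all(res$q >= res$p - 1e-12))
  expect_true(all(diff(res$q[order(res$p)]) >= -1e-12))
  expect_error(candidate_markers(abundance_table(m, kind = "count"),
                                 rep("a", 15)), ">= 2")
})

test_that("a global null yields few false candidates", {
  frac <- with_seed_test(73, vapply(1:20, function(r) {
    m <- matrix(rlnorm(20 * 25), 20, 25,
                dimnames = list(sprintf("s%d", 1:20), sprintf("f%d", 1:25)))
    res <- candidate_markers(abundance_table(m, kind = "count"),
                             rep(c("a", "b"), each = 10))
    mean(res$candidate)
  }, numeric(1)))
  expect_lte(mean(frac), 0.05)
})

test_that("random forest ranks the informative feature first, reproducibly", {
  with_seed_test(74, {
    n <- 40
    m <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(sprintf("s%d", 1:n), sprintf("f%d", 1:10)))
    groups <- rep(c("a", "b"), each = n / 2)
    m[groups == "b", 4] <- m[groups == "b", 4] + 5   # 5-SD shift
  })
  tab <- abundance_table(m - min(m), kind = "count")
  rf <- rank_markers_rf(tab, groups, sprintf("f%d", 1:10), seed = 9)
  expect_equal(rf$feature_id[1], "f4")
  expect_gt(rf$rf_importance[1], max(rf$rf_importance[-1]))
  rf2 <- rank_markers_rf(tab, groups, sprintf("f%d", 1:10), seed = 9)
  expect_identical(rf, rf2)
  # permuting sample order does not change the ranking
  perm <- with_seed_test(75, sample(n))
  tab_p <- abundance_table(tab$values[perm, ], kind = "count")
  rf3 <- rank_markers_rf(tab_p, groups[perm], sprintf("f%d", 1:10), seed = 9)
  expect_equal(rf3$feature_id[1], "f4")
  # single candidate needs no model
  one <- rank_markers_rf(tab, groups, "f4", seed = 1)
  expect_equal(one$rf_rank, 1L)
})

test_that("marker reports attach RF ranks only to candidates", {
  with_seed_test(76, {
    m <- matrix(rlnorm(12 * 6), 12, 6,
                dimnames = list(sprintf("s%d", 1:12), sprintf("f%d", 1:6)))
    groups <- rep(c("a", "b"), each = 6)
    m[groups == "b", 2] <- m[groups == "b", 2] * 40
  })
  rep_ <- marker_report(abundance_table(m, kind = "count"), groups, seed = 4)
  expect_true(all(is.na(rep_$rf_rank[!rep_$candidate])))
  if (any(rep_$candidate)) expect_false(any(is.na(rep_$rf_rank[rep_$candidate])))
})

test_that("network edges require strong, significant correlations", {
  with_seed_test(77, {
    base <- cumsum(runif(10, 0.5, 1.5))
    m <- cbind(twin1 = base, twin2 = base * 2,          # rho = 1
               anti = max(base) - base + 0.1,           # rho = -1 with base
               noise = sample(base))                    # decorrelated
    rownames(m) <- sprintf("s%d", 1:10)
  })
  tab <- abundance_table(m, kind = "count")
  net <- build_network(tab, rho_min = 0.6, q_max = 0.05)
  key <- paste(net$edges$u, net$edges$v)
  expect_true("twin1 twin2" %in% key)
  e <- net$edges[net$edges$u == "twin1" & net$edges$v == "twin2", ]
  expect_equal(e$rho, 1)
  expect_equal(e$sign, "co-occurrence")
  anti <- net$edges[net$edges$v == "anti" | net$edges$u == "anti", ]
  expect_true(all(anti$sign == "co-exclusion"))
  expect_error(build_network(abundance_table(m[1:4, ], kind = "count")), "5")
})

test_that("weak correlations and rare features stay out of the network", {
  with_seed_test(78, {
    m <- matrix(rlnorm(10 * 4), 10, 4,
                dimnames = list(sprintf("s%d", 1:10), sprintf("f%d", 1:4)))
    m[, 4] <- 0; m[1, 4] <- 1   # present in 10% of samples only
  })
  rho <- suppressWarnings(cor(m[, 1], m[, 2], method = "spearman"))
  net <- build_network(abundance_table(m, kind = "count"),
                       rho_min = max(0.6, abs(rho) + 0.01),
                       prevalence_min = 0.2)
  expect_false("f4" %in% net$nodes)
  key <- paste(net$edges$u, net$edges$v)
  expect_false("f1 f2" %in% key)
})

test_that("null data produce false edges at no more than the FDR budget", {
  rates <- with_seed_test(79, vapply(1:30, function(r) {
    m <- matrix(rlnorm(10 * 12), 10, 12,
                dimnames = list(sprintf("s%d", 1:10), sprintf("f%d", 1:12)))
    net <- build_network(abundance_table(m, kind = "count"),
                         rho_min = 0, q_max = 0.05)
    nrow(net$edges) / choose(12, 2)
  }, numeric(1)))
  expect_lte(mean(rates), 0.05)
})

test_that("topology statistics match hand examples", {
  tri <- structure(list(nodes = c("a", "b", "c"),
                        edges = data.frame(u = c("a", "a", "b"),
                                           v = c("b", "c", "c"),
                                           rho = 1, q = 0, sign = "co-occurrence",
                                           stringsAsFactors = FALSE)),
                   class = "interaction_network")
  t1 <- network_topology(tri)
  expect_equal(unlist(t1[c("density", "n_islands", "diameter", "radius",
                           "centralization")]),
               c(density = 1, n_islands = 1, diameter = 1, radius = 1,
                 centralization = 0))

  path <- structure(list(nodes = c("a", "b", "c"),
                         edges = data.frame(u = c("a", "b"), v = c("b", "c"),
                                            rho = 1, q = 0,
                                            sign = "co-occurrence",
                                            stringsAsFactors = FALSE)),
                    class = "interaction_network")
  t2 <- network_topology(path)
  expect_equal(t2$density, 2 / 3)
  expect_equal(t2$diameter, 2)
  expect_equal(t2$radius, 1)
  expect_equal(t2$centralization, 1)   # degrees (1,2,1): (1+0+1)/(2*1)

  isolated <- structure(list(nodes = letters[1:5],
                             edges = data.frame(u = character(),
                                                v = character(),
                                                rho = numeric(), q = numeric(),
                                                sign = character())),
                        class = "interaction_network")
  t3 <- network_topology(isolated)
  expect_equal(unlist(t3[c("n_islands", "density", "diameter", "radius")]),
               c(n_islands = 5, density = 0, diameter = 0, radius = 0))
})

# Plain BFS oracle for components / eccentricities on an edge list.
oracle_graph_stats <- function(nodes, edges) {
  adj <- stats::setNames(lapply(nodes, function(x) character()), nodes)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$u[i]]] <- c(adj[[edges$u[i]]], edges$v[i])
    adj[[edges$v[i]]] <- c(adj[[edges$v[i]]], edges$u[i])
  }
  bfs_dist <- function(s) {
    d <- stats::setNames(rep(Inf, length(nodes)), nodes)
    d[s] <- 0; q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (!is.finite(d[w])) { d[w] <- d[v] + 1; q <- c(q, w) }
    }
    d
  }
  dists <- vapply(nodes, bfs_dist, numeric(length(nodes)))
  comp_key <- apply(dists, 2, function(d)
    paste(sort(names(d)[is.finite(d)]), collapse = ","))
  comps <- strsplit(unique(comp_key), ",")
  sizes <- lengths(comps)
  big <- comps[[which.max(sizes)]]
  ecc <- vapply(big, function(v) max(dists[big, v]), numeric(1))
  list(components = length(comps),
       largest_tied = sum(sizes == max(sizes)) > 1,
       diameter = if (nrow(edges)) max(ecc) else 0,
       radius = if (nrow(edges)) min(ecc) else 0)
}

test_that("topology agrees with a BFS brute force on random graphs", {
  with_seed_test(80, {
    for (rep in 1:20) {
      n <- sample(4:12, 1)
      nodes <- sprintf("n%02d", seq_len(n))
      pairs <- combn(nodes, 2)
      pick <- runif(ncol(pairs)) < 0.25
      edges <- if (any(pick)) {
        data.frame(u = pairs[1, pick], v = pairs[2, pick],
                   rho = 1, q = 0, sign = "co-occurrence",
                   stringsAsFactors = FALSE)
      } else {
        data.frame(u = character(), v = character(), rho = numeric(),
                   q = numeric(), sign = character(), stringsAsFactors = FALSE)
      }
      net <- structure(list(nodes = nodes, edges = edges),
                       class = "interaction_network")
      got <- network_topology(net)
      want <- oracle_graph_stats(nodes, edges)
      expect_equal(got$n_islands, want$components, label = sprintf("rep %d", rep))
      if (!want$largest_tied) {   # tie-broken largest component is arbitrary
        expect_equal(got$diameter, want$diameter, label = sprintf("rep %d", rep))
        expect_equal(got$radius, want$radius, label = sprintf("rep %d", rep))
      }
    }
  })
})

test_that("adding an edge never splits islands nor lowers density", {
  with_seed_test(81, {
    nodes <- sprintf("n%d", 1:8)
    pairs <- combn(nodes, 2)
    ord <- sample(ncol(pairs))
    edges <- data.frame(u = character(), v = character(), rho = numeric(),
                        q = numeric(), sign = character(),
                        stringsAsFactors = FALSE)
    prev <- network_topology(structure(list(nodes = nodes, edges = edges),
                                       class = "interaction_network"))
    for (j in ord[1:12]) {
      edges <- rbind(edges, data.frame(u = pairs[1, j], v = pairs[2, j],
                                       rho = 1, q = 0, sign = "co-occurrence",
                                       stringsAsFactors = FALSE))
      cur <- network_topology(structure(list(nodes = nodes, edges = edges),
                                        class = "interaction_network"))
      expect_lte(cur$n_islands, prev$n_islands)
      expect_gte(cur$density, prev$density)
      prev <- cur
    }
  })
})
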