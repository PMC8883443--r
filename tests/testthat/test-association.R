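test_that("per-gene F-tests match a sum-of-squares oracle via aov", {
  set.seed(81)
  labels <- rep(1:4, each = 15)
  expr <- matrix(rnorm(20 * 60), 20, 60,
                 dimnames = list(paste0("g", 1:20), paste0("c", 1:60)))
  expr[1, ] <- expr[1, ] + labels          # real signal
  expr[2, ] <- 3                           # constant
  res <- cluster_association_ftest(expr, labels)
  for (g in c("g1", "g5", "g12")) {
    sm <- summary(aov(expr[g, ] ~ factor(labels)))[[1]]
    expect_equal(res$f_stat[res$gene == g], sm[["F value"]][1],
                 tolerance = 1e-10)
    expect_equal(res$p[res$gene == g], sm[["Pr(>F)"]][1], tolerance = 1e-10)
  }
  expect_equal(res$f_stat[res$gene == "g2"], 0)
  expect_equal(res$p[res$gene == "g2"], 1)
  # perfect separation: no within-cluster variance
  sep <- rbind(s = as.numeric(labels))
  res_sep <- cluster_association_ftest(sep, labels)
  expect_equal(res_sep$p, 0)
  expect_error(cluster_association_ftest(expr, rep(1, 60)), "one cluster")
  expect_error(cluster_association_ftest(expr[, 1:16], rep(1:4, c(14, 1, 1, 0))[1:16]),
               "fewer than 2")
})

test_that("F-test p-values are uniform under the null", {
  set.seed(82)
  labels <- rep(1:5, each = 12)
  expr <- matrix(rnorm(600 * 60), 600, 60,
                 dimnames = list(paste0("g", 1:600), NULL))
  res <- cluster_association_ftest(expr, labels)
  expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
})

test_that("class Fisher test matches enumeration and handles degenerate cuts", {
  # class = exactly the significant genes, equal-sized complement
  res <- data.frame(gene = paste0("g", 1:12),
                    f_stat = 1, p = c(rep(0.001, 6), rep(0.9, 6)),
                    p_adj = c(rep(0.002, 6), rep(0.9, 6)))
  cls <- list(myclass = paste0("g", 1:6))
  got <- class_association_fisher(res, cls, alpha = 0.05)
  want <- fisher.test(matrix(c(6, 0, 0, 6), 2))$p.value
  expect_equal(got$fisher_p, want)
  expect_equal(want, 2 / choose(12, 6))   # closed-form two-sided tail
  # everything significant: no association possible
  all_sig <- class_association_fisher(res, cls, alpha = 1)
  expect_equal(all_sig$fisher_p, 1)
  expect_error(class_association_fisher(res, list(none = "zzz")), "empty")
})

test_that("Fisher p-values are uniform when class and significance are independent", {
  set.seed(83)
  ps <- replicate(200, {
    p <- runif(40)
    res <- data.frame(gene = paste0("g", 1:40), f_stat = 1, p = p,
                      p_adj = p)
    cls <- list(cl = paste0("g", sample(40, 15)))
    class_association_fisher(res, cls, alpha = 0.3)$fisher_p
  })
  # discrete and conservative; must not pile up near 0
  expect_lte(mean(ps < 0.05), 0.07)
})

test_that("Ig-by-cluster map aggregates means and medians correctly", {
  expr <- matrix(c(2, 2, 2, 8, 8, 8), 1, 6,
                 dimnames = list("ig1", paste0("c", 1:6)))
  labels <- setNames(rep(1:2, each = 3), colnames(expr))
  map <- ig_cluster_map(expr, labels, "ig1")
  expect_equal(map$mean_expr, c(2, 8))
  expect_equal(map$median_expr, c(2, 8))
  # single cluster reproduces the grand statistics
  one <- ig_cluster_map(expr, setNames(rep(1, 6), colnames(expr)), "ig1")
  expect_equal(one$mean_expr, mean(expr))
  # cell order does not matter
  perm <- sample(6)
  map2 <- ig_cluster_map(expr[, perm, drop = FALSE], labels[perm], "ig1")
  expect_equal(map2, map)
  expect_warning(ig_cluster_map(expr, labels, c("ig1", "nope")), "not in")
  empty <- ig_cluster_map(expr, labels, character(0))
  expect_equal(nrow(empty), 0L)
})

test_that("planted Ig programs surface in the cluster map and the F-test", {
  sim <- simulate_homeo_population(4L, 30L, n_homeobox = 10L, n_ig = 20L,
                                   link_strength = 4, seed = 84L)
  lognorm <- log1p(sim$counts$counts)
  labels <- sim$truth$cluster_labels
  map <- ig_cluster_map(lognorm, labels, sim$counts$gene_classes$ig)
  for (k in 1:4) {
    for (g in sim$truth$linked_ig[[k]]) {
      in_cl <- map$mean_expr[map$cluster == k & map$gene == g]
      grand <- mean(lognorm[g, ])
      raw_in <- mean(sim$counts$counts[g, labels == k])
      expect_gte(raw_in, 2 * mean(sim$counts$counts[g, ]) * 0.5)
      expect_gt(in_cl, grand)
    }
  }
})

test_that("hypergeometric overlap equals exhaustive enumeration", {
  expect_equal(overlap_hypergeometric(paste0("g", 1:5), paste0("g", 1:5),
                                      universe_size = 5L)$p, 1)
  expect_equal(overlap_hypergeometric(paste0("g", 1:5), paste0("g", 1:5),
                                      universe_size = 10L)$p, 1 / choose(10, 5))
  # enumeration oracle on a 15-gene universe
  set.seed(85)
  a <- paste0("g", sample(15, 6)); b <- paste0("g", sample(15, 7))
  got <- overlap_hypergeometric(a, b, universe_size = 15L)
  draws <- combn(15, 7)
  a_idx <- as.integer(sub("g", "", a))
  enum <- mean(apply(draws, 2, function(d)
    length(intersect(d, a_idx)) >= got$overlap))
  expect_equal(got$p, enum, tolerance = 1e-12)
  expect_error(overlap_hypergeometric(paste0("g", 1:30), "g1",
                                      universe_size = 20L), "larger")
})
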