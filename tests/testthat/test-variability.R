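test_that("size factors respect symmetry, scaling and the median-of-ratios oracle", {
  two <- count_matrix(matrix(c(5, 3, 8, 5, 3, 8), 3, 2,
                             dimnames = list(paste0("g", 1:3), c("A", "B"))))
  expect_equal(unname(size_factors(two)), c(1, 1))
  dbl <- count_matrix(matrix(c(5, 3, 8, 10, 6, 16), 3, 2,
                             dimnames = list(paste0("g", 1:3), c("A", "B"))))
  sf <- size_factors(dbl)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(exp(mean(log(sf))), 1)
  # independent brute-force median-of-ratios on a random fixture
  m <- random_count_matrix(50L, 8L, lambda = 20, seed = 3L)
  got <- size_factors(m)
  allpos <- apply(m$counts > 0, 1, all)
  ref <- exp(rowMeans(log(m$counts[allpos, ])))
  brute <- apply(m$counts[allpos, ], 2, function(col) median(col / ref))
  brute <- brute / exp(mean(log(brute)))
  expect_equal(unname(got), unname(brute), tolerance = 1e-12)
  expect_error(size_factors(count_matrix(matrix(0L, 2, 2))), "all-zero")
})

test_that("pure Poisson data recover the CV^2 = 1/mu technical trend", {
  set.seed(21)
  mu <- exp(runif(1000, log(0.5), log(200)))
  counts <- matrix(rpois(1000 * 200, mu), 1000, 200,
                   dimnames = list(paste0("g", 1:1000), paste0("c", 1:200)))
  fit <- fit_technical_noise(count_matrix(counts),
                             sf = setNames(rep(1, 200), paste0("c", 1:200)))
  expect_lt(abs(fit$a1 - 1), 0.2)
  expect_lt(abs(fit$a0), 0.05)
})

test_that("planted overdispersion is recovered in the asymptotic CV^2 offset", {
  set.seed(22)
  mu <- exp(runif(2000, log(1), log(200)))
  # gamma-Poisson mixture with squared biological CV 0.2
  lam <- mu * rgamma(2000 * 100, shape = 5, rate = 5)
  counts <- matrix(rpois(2000 * 100, lam), 2000, 100,
                   dimnames = list(paste0("g", 1:2000), paste0("c", 1:100)))
  fit <- fit_technical_noise(count_matrix(counts),
                             sf = setNames(rep(1, 100), paste0("c", 1:100)))
  expect_lt(abs(fit$a0 - 0.2) / 0.2, 0.5)
})

test_that("excess-variance test: degenerate genes, type-I control, power", {
  set.seed(23)
  n_cells <- 100L
  mu <- exp(runif(500, log(1), log(100)))
  counts <- matrix(rpois(500 * n_cells, mu), 500, n_cells,
                   dimnames = list(paste0("g", 1:500),
                                   paste0("c", seq_len(n_cells))))
  counts[1, ] <- 5L  # constant gene
  m <- count_matrix(counts)
  fit <- fit_technical_noise(m, sf = setNames(rep(1, n_cells),
                                              colnames(counts)))
  hvg <- test_variable_genes(m, fit, fdr = 0.1)
  expect_equal(hvg$p[1], 1)
  expect_false(hvg$is_variable[1])
  expect_lt(mean(hvg$is_variable), 0.15)  # null-dominated simulation
  # planted high-variance genes among Poisson null genes
  set.seed(24)
  extra <- matrix(rpois(50 * n_cells,
                        10 * rgamma(50 * n_cells, 1, 1)), 50, n_cells,
                  dimnames = list(paste0("hv", 1:50),
                                  paste0("c", seq_len(n_cells))))
  m2 <- count_matrix(rbind(counts[-1, ], extra))
  fit2 <- fit_technical_noise(m2, sf = setNames(rep(1, n_cells),
                                                colnames(counts)))
  hvg2 <- test_variable_genes(m2, fit2, fdr = 0.1)
  power <- mean(hvg2$is_variable[grepl("^hv", hvg2$gene)])
  expect_gte(power, 0.8)
})

test_that("BH adjustment is monotone and bounded by the raw p-values", {
  m <- random_count_matrix(100L, 30L, lambda = 10, seed = 5L)
  fit <- fit_technical_noise(m)
  hvg <- test_variable_genes(m, fit)
  expect_true(all(hvg$p_adj >= hvg$p - 1e-15))
  ord <- order(hvg$p)
  expect_true(all(diff(hvg$p_adj[ord]) >= -1e-15))
  expect_true(all(hvg$p >= 0 & hvg$p <= 1))
})

test_that("the variance test is invariant to joint rescaling of counts and size factors", {
  m <- random_count_matrix(80L, 40L, lambda = 8, seed = 6L)
  fit <- fit_technical_noise(m)
  hvg <- test_variable_genes(m, fit)
  m4 <- count_matrix(m$counts * 4L)
  fit4 <- fit
  fit4$size_factors <- fit$size_factors * 4
  hvg4 <- test_variable_genes(m4, fit4)
  expect_equal(hvg4$p, hvg$p, tolerance = 1e-12)
})

test_that("class enrichment equals exhaustive enumeration on small universes", {
  # closed form: universe 10, class 5, variable 5, overlap 5
  universe <- paste0("g", 1:10)
  res <- class_enrichment_hypergeometric(universe[1:5],
                                         list(cl = universe[1:5]), universe)
  expect_equal(res$p, 1 / choose(10, 5))
  # exhaustive enumeration oracle on a 12-gene universe
  universe <- paste0("g", 1:12)
  class_set <- universe[1:5]
  variable <- universe[c(1, 2, 3, 6, 7, 8)]
  ov <- length(intersect(variable, class_set))
  draws <- combn(12, length(variable))
  in_class <- seq_len(12) %in% 1:5
  enum <- mean(apply(draws, 2, function(d) sum(in_class[d]) >= ov))
  got <- class_enrichment_hypergeometric(variable, list(cl = class_set),
                                         universe)
  expect_equal(got$p, enum, tolerance = 1e-12)
  # zero overlap: upper tail includes 0, so p is large
  none <- class_enrichment_hypergeometric(universe[6:8],
                                          list(cl = universe[1:3]), universe)
  expect_gte(none$p, 0.5)
  expect_error(class_enrichment_hypergeometric("g1", list(a = "g1"),
                                               character(0)), "empty")
})

test_that("scaled expression matches an independent formula evaluation", {
  m <- random_count_matrix(60L, 25L, lambda = 10, seed = 9L)
  m$counts[1, ] <- 7  # constant gene scales to zero (unit size factors)
  fit <- fit_technical_noise(m, sf = setNames(rep(1, 25), colnames(m$counts)))
  scaled <- scale_expression(m, fit)
  expect_equal(unname(scaled[1, ]), rep(0, 25L))
  norm <- sweep(m$counts, 2, fit$size_factors, `/`)
  g <- "g17"
  mu <- mean(norm[g, ]); v_obs <- var(norm[g, ])
  v_tech <- max(fit$a1 * mu + fit$a0 * mu^2, 0)
  denom <- sqrt(v_tech + max(v_obs - v_tech, 0)) / (1 + mu)
  want <- (log1p(norm[g, ]) - mean(log1p(norm[g, ]))) / denom
  expect_equal(scaled[g, ], want, tolerance = 1e-12)
})
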