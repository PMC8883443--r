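test_that("r_g is the mean expression over expressing cells", {
  m <- count_matrix(matrix(c(0, 0, 2, 4), 1, 4,
                           dimnames = list("g", paste0("c", 1:4))))
  expect_equal(unname(estimate_rg(m, "g")), 3)
  single <- count_matrix(matrix(5, 1, 1, dimnames = list("g", "c1")))
  expect_equal(unname(estimate_rg(single, "g")), 5)
  zero <- count_matrix(matrix(0L, 1, 3, dimnames = list("g", NULL)))
  expect_error(estimate_rg(zero, "g"), "zero expressing")
  # Monte-Carlo: boxcar covering 30% of the axis, lambda = 0
  ref <- make_reference(list(stripe_spec("g", 0.5, 0.3, "boxcar")),
                        grid_size = 201L)
  sim <- simulate_cells(ref, 4000L, r = 20, lambda_bg = 0, seed = 13L)
  rg <- estimate_rg(sim$counts, "g")
  expect_lt(abs(rg - 20) / 20, 0.05)
})

test_that("log-likelihood profiles equal a brute-force double loop", {
  set.seed(51)
  for (rep in 1:10) {
    grid <- seq(0, 1, length.out = 21L)
    curves <- matrix(runif(5 * 21), 5, 21,
                     dimnames = list(paste0("g", 1:5), NULL))
    curves[sample(length(curves), 30)] <- 0   # zero-support territory
    ref <- reference_map(grid, curves)
    params <- mapping_params(setNames(runif(5, 1, 30), paste0("g", 1:5)),
                             lambda_bg = 0.1)
    d <- setNames(rpois(5, 5), paste0("g", 1:5))
    got <- cell_log_likelihood(d, ref, params)
    brute <- numeric(21)
    for (x in 1:21) {
      s <- 0
      for (g in 1:5) {
        y <- curves[g, x]
        mu <- if (y > 0) params$r[g] * y else 0.1
        s <- s + dpois(d[[g]], mu, log = TRUE)
      }
      brute[x] <- s
    }
    expect_equal(got, brute, tolerance = 1e-9)
  }
})

test_that("profiles behave sensibly in the single-gene limits", {
  ref <- make_reference(list(stripe_spec("g", 0.5, 0.2, "boxcar")),
                        grid_size = 101L)
  params <- mapping_params(c(g = 5), lambda_bg = 0.1)
  # zero counts: likelihood is maximal outside the stripe (r*Y > lambda)
  ll0 <- cell_log_likelihood(c(g = 0), ref, params)
  outside <- ref$grid < 0.4 | ref$grid > 0.6
  expect_true(max(ll0[outside]) > max(ll0[!outside]))
  # a count at the gene's unique peak pulls the argmax there
  gauss <- make_reference(list(stripe_spec("g", 0.5, 0.2, "gaussian")),
                          grid_size = 101L)
  ll7 <- cell_log_likelihood(c(g = 7), gauss, mapping_params(c(g = 7), 0.1))
  expect_equal(gauss$grid[which.max(ll7)], 0.5)
  # lambda = 0 with a positive count in zero territory: -Inf, never NaN
  ll_inf <- cell_log_likelihood(c(g = 3), ref, mapping_params(c(g = 5), 0))
  expect_true(all(is.nan(ll_inf) == FALSE))
  expect_true(any(ll_inf == -Inf))
})

test_that("position mapping breaks plateau ties at the stripe midpoint", {
  ref <- make_reference(list(stripe_spec("g", 0.5, 0.2, "boxcar")),
                        grid_size = 101L)
  m <- count_matrix(matrix(5L, 1, 1, dimnames = list("g", "c1")))
  est <- map_position(m, ref, mapping_params(c(g = 5), lambda_bg = 0.1))
  expect_equal(est$x_hat, 0.5)
  expect_equal(est$n_ties, sum(ref$grid >= 0.4 & ref$grid <= 0.6))
  # a cell with no reads in any mapped gene cannot be placed
  m0 <- count_matrix(matrix(0L, 1, 1, dimnames = list("g", "c1")))
  est0 <- map_position(m0, ref, mapping_params(c(g = 5), 0.1))
  expect_false(est0$mapped)
  expect_true(is.na(est0$x_hat))
  est0b <- map_position(m0, ref, mapping_params(c(g = 5), 0.1),
                        require_hox = FALSE)
  expect_true(est0b$mapped)
})

test_that("positions are recovered on the default seven-gene simulation", {
  sim <- default_mapping_sim(n_cells = 500L, r = 20, lambda = 0.1)
  est <- map_position(sim$counts, sim$ref,
                      mapping_params(estimate_rg(sim$counts), 0.1))
  ok <- est$mapped
  truth <- sim$truth$positions[est$cell[ok]]
  expect_gte(cor(est$x_hat[ok], truth), 0.9)
  widest <- max(vapply(default_hox_specs(), `[[`, numeric(1), "width"))
  expect_lte(median(abs(est$x_hat[ok] - truth)), widest / 2)
})

test_that("the profile is gene-order invariant and attraction is monotone", {
  gauss <- make_reference(list(stripe_spec("a", 0.3, 0.2, "gaussian"),
                               stripe_spec("b", 0.7, 0.2, "gaussian")),
                          grid_size = 101L)
  params <- mapping_params(c(a = 10, b = 10), 0.1)
  d <- c(a = 4, b = 1)
  ll1 <- cell_log_likelihood(d, gauss, params)
  ll2 <- cell_log_likelihood(d[c("b", "a")], gauss, params)
  expect_equal(ll1, ll2)
  # raising gene a's count (count <= r) never moves x_hat away from 0.3
  prev_dist <- Inf
  for (cnt in c(1, 3, 6, 10)) {
    m <- count_matrix(matrix(c(cnt, 0), 2, 1,
                             dimnames = list(c("a", "b"), "c1")))
    est <- map_position(m, gauss, params)
    dist <- abs(est$x_hat - 0.3)
    expect_lte(dist, prev_dist)
    prev_dist <- dist
  }
})

test_that("Latin hypercube robustness scan: design and degenerate range", {
  sim <- default_mapping_sim(n_cells = 120L, seed = 15L)
  rb <- robustness_lhs(sim$counts, sim$ref, n_draws = 5L,
                       lambda_range = c(0.1, 0.1),
                       r_scale_range = c(1, 1), seed = 2L)
  expect_true(all(rb$spearman == 1))
  # LHS: each marginal stratum sampled exactly once
  rb2 <- robustness_lhs(sim$counts, sim$ref, n_draws = 8L,
                        lambda_range = c(0.01, 1),
                        r_scale_range = c(0.2, 5), seed = 3L)
  lam_u <- (log(rb2$design$lambda) - log(0.01)) / (log(1) - log(0.01))
  expect_setequal(floor(lam_u * 8), 0:7)
  rs_u <- (log(rb2$design$r_scale) - log(0.2)) / (log(5) - log(0.2))
  expect_setequal(floor(rs_u * 8), 0:7)
})
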