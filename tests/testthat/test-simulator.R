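test_that("sinusoid factor trajectories evaluate exactly", {
  s <- sin_factor(10, 1, 10, 0)
  expect_equal(s[1], 0)                       # phase 0 at t = 0
  expect_lte(max(abs(s)), 1)                  # amplitude bound
  # period = T completes one cycle: wrapped value matches the start
  s2 <- sin_factor(20, 0.7, 20, 0.3)
  expect_equal(0.7 * sin(2 * pi * 20 / 20 + 0.3), s2[1], tolerance = 1e-9)
  expect_error(sin_factor(2, 1, 10), "T >= 3")
})

test_that("noise-free simulation is deterministic and matches the model", {
  net <- benchmark_grn()
  d1 <- simulate(net, T = 30)
  d2 <- simulate(net, T = 30)
  expect_identical(d1$values, d2$values)
  # manual recursion oracle for the first two steps of one gene
  Fs <- tanhnet:::factor_series_matrix(net, 30)
  g <- "g04"
  regs <- net$edges[net$edges$target == g, ]
  state <- c(net$init, F1 = unname(Fs[1, "F1"]), F2 = unname(Fs[1, "F2"]))
  u <- sum(regs$weight * state[regs$regulator]) - net$beta[[g]]
  expect_equal(d1$values[g, 2],
               net$init[[g]] + net$alpha[[g]] * tanh(u), tolerance = 1e-12)
})

test_that("seeded noisy simulation is reproducible, seeds differ", {
  net <- benchmark_grn()
  a <- simulate(net, seed = 4, snr = 10)
  b <- simulate(net, seed = 4, snr = 10)
  c2 <- simulate(net, seed = 5, snr = 10)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c2$values))
})

test_that("injected noise has variance Var(g)/c and zero mean", {
  net <- benchmark_grn()
  free <- simulate(net, T = 59)
  nsim <- 50000
  sims <- simulate(net, nsim = nsim, seed = 9, T = 59, snr = 10)
  # the first transition's deviation from the noise-free path is the
  # raw injected noise (no feedback yet); g04 has no factor parent, so
  # the factor rows' observation noise cannot enter its first step
  g <- "g04"
  dev <- vapply(seq_len(nsim), function(s) sims[[s]]$values[g, 2], 0) -
    free$values[g, 2]
  v_target <- var(free$values[g, ]) / 10
  expect_equal(var(dev), v_target, tolerance = 0.02 * v_target + 0.02)
  expect_equal(mean(dev), 0, tolerance = 3 * sqrt(v_target / nsim) + 1e-3)
})

test_that("replicate mean converges to the noise-free path", {
  # noise feeds back through the tanh, so the replicate mean carries an
  # O(noise variance) nonlinearity bias; at a mild noise level the law
  # of large numbers dominates and the mean tracks the noise-free path
  net <- benchmark_grn()
  free <- simulate(net, T = 20)
  sims <- simulate(net, nsim = 4000, seed = 2, T = 20, snr = 100)
  for (tt in c(2, 5, 10)) {
    avg <- rowMeans(vapply(sims, function(s) s$values[net$genes, tt],
                           numeric(11)))
    expect_equal(unname(avg), unname(free$values[net$genes, tt]),
                 tolerance = 0.05)
  }
})

test_that("random sparse networks respect degree constraints", {
  net <- random_grn(11, 2, n_links = 26, l_max = 4, seed = 1)
  expect_equal(nrow(net$edges), 26)
  expect_equal(n_candidate_links(net) - nrow(net$edges), 117)
  deg <- in_degrees(net)
  expect_true(all(deg[net$genes] <= 4))
  expect_true(all(deg[net$factors] == 0))
  # empty network: constant noise-free trajectories when beta = 0
  net0 <- random_grn(4, 0, n_links = 0, l_max = 2, seed = 2)
  net0$beta[] <- 0
  d0 <- simulate(net0, T = 10)
  expect_true(all(apply(d0$values, 1, function(r) diff(range(r))) == 0))
  expect_error(random_grn(3, 0, n_links = 50, l_max = 2), "infeasible")
})

test_that("power-law degree sampling shows the k^-gamma slope", {
  set.seed(6)
  p <- powerlaw_indegree_probs(2.5, 4)
  draws <- sample(1:4, 1e4, replace = TRUE, prob = p)
  h <- tabulate(draws, 4)
  slope <- coef(lm(log(h) ~ log(1:4)))[2]
  expect_lt(abs(slope - (-2.5)), 0.2)
  # random_grn honours the law
  net <- random_grn(200, 0, l_max = 4, gamma = 2.5, seed = 3)
  expect_true(all(in_degrees(net)[net$genes] <= 4))
  expect_error(random_grn(5, 0, l_max = 3, gamma = 3.5), "gamma")
})

test_that("packaged benchmark has the published topology counts", {
  net <- benchmark_grn()
  expect_equal(length(net$genes), 11L)
  expect_equal(length(net$factors), 2L)
  expect_equal(nrow(net$edges), 26L)
  expect_equal(n_candidate_links(net), 143L)
  expect_equal(n_candidate_links(net) - nrow(net$edges), 117L)
  expect_true(all(in_degrees(net)[net$factors] == 0))
  expect_true(all(in_degrees(net, count_self = FALSE)[net$genes] <= 4))
  # noise-free trajectories are finite, bounded, and clearly non-constant
  d <- simulate(net, T = 59)
  expect_true(all(is.finite(d$values)))
  rng <- apply(d$values[net$genes, ], 1, function(r) diff(range(r)))
  expect_true(all(rng > 0.1 * abs(net$alpha)))
})
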