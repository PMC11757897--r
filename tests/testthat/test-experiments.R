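# Sweep drivers and region maps (scaled-down problem sizes).

test_that("alpha sweep steps the extended network from 9 equilibria to 1", {
  net <- build_extended_triangle(fixture_spec(beta = 1.025))
  sw <- alpha_sweep(net, range = c(0.05, 3),
                    grid = c(0.05, 0.3, 0.6, 1.5, 3.0),
                    n_starts = 250, seed = 1)
  counts <- sw$counts$n
  expect_equal(counts[1], 9L)
  expect_equal(counts[length(counts)], 1L)
  expect_true(all(diff(counts) <= 0))          # non-increasing in alpha
  expect_true(all(counts %% 2L == 1L))         # odd everywhere (fold pairs)
  # count transitions only across detected folds
  f <- sw$fold_values
  for (i in seq_len(length(counts) - 1L)) {
    if (counts[i + 1L] < counts[i]) {
      expect_true(any(f > sw$counts$alpha[i] & f < sw$counts$alpha[i + 1L]))
    }
  }
})

test_that("multi-equilibria area of the (alpha, beta) plane grows with inlet haematocrit", {
  alphas <- seq(0.05, 0.6, length.out = 7)
  betas <- seq(0.85, 1.15, length.out = 7)
  areas <- sapply(c(0.35, 0.45), function(h) {
    net <- build_triangle(fixture_spec(h_in = h))
    rm <- region_map_alpha_beta(net, alphas, betas, n_starts = 40, seed = 2)
    expect_true(all(rm$counts %% 2L == 1L))
    expect_true(all(rm$counts <= equilibrium_upper_bound(net)))
    rm$multi_area
  })
  expect_gt(areas[2], areas[1])
})

test_that("strong asymmetry leaves a unique equilibrium", {
  for (b in c(0.4, 2.2)) {
    net <- build_triangle(fixture_spec(alpha = 0.5, beta = b))
    expect_length(enumerate_equilibria(net, n_starts = 150, seed = 3), 1L)
  }
})

test_that("the degenerate proportional rule agrees between compiled and R paths", {
  register_splitting_rule("proportional_r",
                          function(r, H, Dp, Dd, Ds) r)
  net <- ext_default()
  eq_cpp <- enumerate_equilibria(net, n_starts = 150, seed = 5,
                                 rule = "proportional")
  eq_r <- enumerate_equilibria(net, n_starts = 150, seed = 5,
                               rule = "proportional_r")
  expect_equal(length(eq_cpp), length(eq_r))
  k1 <- sort(vapply(eq_cpp, function(s) s$qhat[["4->5"]], numeric(1)))
  k2 <- sort(vapply(eq_r, function(s) s$qhat[["4->5"]], numeric(1)))
  expect_equal(k1, k2, tolerance = 1e-8)
  # with psi = r the daughter haematocrit equals the parent's: no phase
  # separation, so every vessel carries the inlet haematocrit
  for (s in eq_cpp) {
    hs <- s$haematocrits[abs(s$qhat[names(s$haematocrits)]) > 1e-6]
    expect_true(all(abs(hs - 0.45) < 1e-8))
  }
})

test_that("inlet-pressure sweep traces verified branches with paired folds", {
  net <- ext_default()
  sw <- inlet_pressure_sweep(net, range = c(0.42, 0.58), n_starts = 200,
                             seed = 6, ds_max = 0.02)
  expect_length(sw$equilibria, 9L)
  expect_true(all(sw$fold_values >= 0.42 & sw$fold_values <= 0.58))
  br <- sw$branches[[1]]
  n <- br$n_unknown
  i <- nrow(br$points) %/% 2L
  net_i <- set_network_parameter(net, "p1", br$points[i, n + 1])
  expect_lt(max(abs(assemble_residual(net_i, br$points[i, 1:n]))), 1e-10)
})
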