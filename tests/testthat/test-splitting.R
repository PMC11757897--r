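# Pries-1990 plasma-skimming rule and the pluggable rule interface.

test_that("coefficients follow the printed formulas", {
  co <- pries1990_coefficients(10, 10, 10, 0.45)
  expect_equal(co$X0, 0.04)
  expect_equal(co$rho, 1 + 6.98 * 0.55 / 10)
  expect_equal(co$A, 0)                      # equal daughters: log(1) = 0
  # A is antisymmetric under daughter <-> sibling
  a1 <- pries1990_coefficients(10, 8, 12, 0.3)$A
  a2 <- pries1990_coefficients(10, 12, 8, 0.3)$A
  expect_equal(a1, -a2, tolerance = 1e-14)
  expect_error(pries1990_coefficients(0.79, 10, 10, 0.4), "X0")
})

test_that("psi is piecewise with hard thresholds and symmetric midpoint", {
  co <- pries1990_coefficients(10, 10, 10, 0.45)
  expect_equal(psi(0.02, co), 0)             # below X0 = 0.04
  expect_equal(psi(0.98, co), 1)             # above 1 - X0
  expect_equal(psi(0.5, co), 0.5)            # A = 0, symmetric bifurcation
  expect_error(psi(-0.01, co), "ratio")
  expect_error(psi(1.01, co), "ratio")
})

test_that("psi partitions unity between the two daughters", {
  set.seed(42)
  for (k in 1:25) {
    Dp <- runif(1, 5, 60)
    Dd <- runif(1, 5, 60)
    Ds <- runif(1, 5, 60)
    H <- runif(1, 0, 0.8)
    cd <- pries1990_coefficients(Dp, Dd, Ds, H)
    cs <- pries1990_coefficients(Dp, Ds, Dd, H)
    r <- seq(0, 1, length.out = 101)
    expect_lt(max(abs(psi(r, cd) + psi(1 - r, cs) - 1)), 1e-12)
  }
})

test_that("psi is non-decreasing and continuous at the thresholds", {
  set.seed(7)
  for (k in 1:10) {
    co <- pries1990_coefficients(runif(1, 2, 50), runif(1, 2, 50),
                                 runif(1, 2, 50), runif(1, 0, 0.8))
    r <- seq(0, 1, length.out = 2001)
    p <- psi(r, co)
    expect_true(all(diff(p) >= -1e-12))
    # continuity: limits at the kinks equal the piecewise values
    eps <- 1e-10
    expect_lt(abs(psi(min(co$X0 + eps, 1), co) - 0), 1e-6)
    expect_lt(abs(psi(max(1 - co$X0 - eps, 0), co) - 1), 1e-6)
  }
})

test_that("daughter haematocrit defect captures the steady-state balance", {
  # psi = 1 branch: everything goes to this daughter
  expect_equal(daughter_haematocrit_defect(1, 0.45, 0.99, 0.45 / 0.99,
                                           10, 10, 10), 0, tolerance = 1e-12)
  # symmetric split: zero defect iff daughter inherits the parent haematocrit
  expect_equal(daughter_haematocrit_defect(1, 0.45, 0.5, 0.45, 10, 10, 10), 0,
               tolerance = 1e-12)
  expect_gt(abs(daughter_haematocrit_defect(1, 0.45, 0.5, 0.3, 10, 10, 10)), 0)
  # below threshold: zero defect iff the daughter carries no red cells
  expect_equal(daughter_haematocrit_defect(1, 0.45, 0.02, 0, 10, 10, 10), 0)
  expect_gt(abs(daughter_haematocrit_defect(1, 0.45, 0.02, 0.2, 10, 10, 10)), 0)
  # scale invariance under uniform flow rescaling
  d1 <- daughter_haematocrit_defect(1, 0.4, 0.3, 0.35, 12, 9, 11)
  d2 <- daughter_haematocrit_defect(10, 0.4, 3, 0.35, 12, 9, 11)
  expect_equal(d2, 10 * d1, tolerance = 1e-12)
  expect_error(daughter_haematocrit_defect(1e-15, 0.4, 0, 0, 10, 10, 10),
               "degenerate")
})

test_that("rule registry exposes built-ins and accepts new rules", {
  expect_equal(splitting_rule("pries1990")$name, "pries1990")
  expect_equal(splitting_rule("proportional")$psi(0.3, 0.4, 10, 10, 10), 0.3)
  expect_error(splitting_rule("nope"), "unknown splitting rule")
  register_splitting_rule("test_constant", function(r, H, Dp, Dd, Ds) 0.5)
  expect_equal(splitting_rule("test_constant")$psi(0.9, 0, 1, 1, 1), 0.5)
})
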