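# Assembly and Newton solution of the steady-state network equations.

test_that("zero-haematocrit solve matches symmetry and the linear oracle", {
  net <- tri_default(h_in = 0)
  st <- solve_zero_haematocrit(net)
  q <- signed_flows(net, st)
  expect_equal(unname(q[c("1->4", "2->5", "4->5", "6->3")]),
               c(0.5, 0.5, 0, 1), tolerance = 1e-12)
  expect_lt(max(abs(assemble_residual(net, st))), 1e-12)

  # asymmetric triangle against an independently assembled dense solve
  net2 <- tri_default(beta = 2, h_in = 0)
  st2 <- solve_zero_haematocrit(net2)
  oracle <- kirchhoff_oracle(net2, H = 0)
  expect_equal(unname(st2$pressures[names(oracle)]), unname(oracle),
               tolerance = 1e-12)
  expect_lt(max(abs(assemble_residual(net2, st2))), 1e-12)
})

test_that("normalised inlet flows always sum to one", {
  net <- ext_default()
  st <- solve_zero_haematocrit(net)
  q <- signed_flows(net, st)
  expect_equal(unname(q[["1->7"]] + q[["2->8"]]), 1, tolerance = 1e-12)
  # also for an arbitrary (non-equilibrium) state with finite flows
  x <- hemonet::state_x(st) + 0.01
  q2 <- signed_flows(net, x)
  expect_equal(unname(q2[["1->7"]] + q2[["2->8"]]), 1, tolerance = 1e-12)
  expect_true(all(is.finite(assemble_residual(net, x))))
})

test_that("compiled and R residual assemblies agree", {
  set.seed(3)
  for (net in list(tri_default(), ext_default())) {
    cn <- hemonet:::compile_network(net)
    st <- solve_zero_haematocrit(net)
    for (k in 1:10) {
      x <- hemonet::state_x(st) + runif(cn$n_unknown, -0.05, 0.2)
      rc <- hemonet:::.residual_kernel(x, cn, 0L, 0)
      rr <- hemonet:::residual_r(x, cn, 0L, 0)
      expect_equal(rc, rr, tolerance = 1e-13)
    }
  }
})

test_that("residuals are invariant under node relabelling", {
  net <- tri_default()
  st <- solve_zero_haematocrit(net)
  r1 <- unname(sort(abs(assemble_residual(net, st))))
  map <- setNames(c(11L, 22L, 33L, 44L, 55L, 66L), net$nodes$id)
  net2 <- vascular_network(
    transform(net$nodes, id = map[as.character(id)]),
    transform(net$vessels, from = map[as.character(from)],
              to = map[as.character(to)]))
  st2 <- solve_zero_haematocrit(net2)
  expect_equal(unname(sort(abs(assemble_residual(net2, st2)))), r1,
               tolerance = 1e-12)
})

test_that("finite differencing recovers exact derivatives of a quadratic", {
  f <- function(x) c(x[1]^2 + 2 * x[2], x[1] * x[2] - 3)
  J <- hemonet:::jac_fd(f, c(0.7, -0.2))
  expect_equal(J, rbind(c(1.4, 2), c(-0.2, 0.7)), tolerance = 1e-8)
})

test_that("Newton converges instantly from an equilibrium and flags bad input", {
  net <- tri_default()
  eq <- enumerate_equilibria(net, n_starts = 60, seed = 1)[[1]]
  res <- newton_solve(net, eq)
  expect_true(res$converged)
  expect_lte(res$iterations, 2L)
  bad <- newton_solve(net, rep(NaN, length(hemonet::state_x(eq))))
  expect_false(bad$converged)
})

test_that("Newton reaches a true equilibrium from the homotopy base", {
  net <- tri_default()
  start <- solve_zero_haematocrit(net)
  res <- newton_solve(net, start)
  expect_true(res$converged)
  expect_lt(res$residual_norm, 1e-11)
  eq <- enumerate_equilibria(net, n_starts = 60, seed = 1)
  d <- vapply(eq, function(s) max(abs(s$x - res$state$x)), numeric(1))
  expect_lt(min(d), 1e-6)     # lands on a member of the equilibrium set
})

test_that("equilibria conserve blood and red cells at every node", {
  for (net in list(tri_default(), ext_default())) {
    eq <- enumerate_equilibria(net, n_starts = 150, seed = 2)
    red <- find_redundant_vessels(net)
    h_in <- 0.45
    for (s in eq) {
      expect_lt(max(abs(assemble_residual(net, s))), 1e-10)
      q <- s$qhat
      # global RBC balance: outlet flux equals inlet flux
      hin_vessels <- names(q)[grepl("^1->|^2->", names(q))]
      out_vessel <- names(q)[grepl("->3$", names(q))]
      influx <- sum(q[hin_vessels] * h_in)
      outflux <- q[[out_vessel]] * s$haematocrits[[out_vessel]]
      expect_equal(outflux, influx, tolerance = 1e-10)
    }
  }
})

test_that("equilibria are invariant to viscosity, length and pressure scales", {
  base <- enumerate_equilibria(tri_default(), n_starts = 80, seed = 4)
  ref <- sort(vapply(base, function(s) s$qhat[["4->5"]], numeric(1)))
  refH <- sort(vapply(base, function(s) s$haematocrits[["4->6"]], numeric(1)))

  # plasma viscosity
  eq1 <- enumerate_equilibria(tri_default(), n_starts = 80, seed = 4,
                              params = rheology_params(mu_p = 7.3))
  expect_equal(sort(vapply(eq1, function(s) s$qhat[["4->5"]], numeric(1))),
               ref, tolerance = 1e-10)

  # reference length (all lengths scaled together)
  net_L <- tri_default()
  net_L$vessels$length <- net_L$vessels$length * 3.7
  eq2 <- enumerate_equilibria(net_L, n_starts = 80, seed = 4)
  expect_equal(sort(vapply(eq2, function(s) s$qhat[["4->5"]], numeric(1))),
               ref, tolerance = 1e-10)

  # uniform rescaling of the boundary-pressure span
  net_P <- build_triangle(fixture_spec(p1 = 1.5, p2 = 1.5, p3 = 0))
  eq3 <- enumerate_equilibria(net_P, n_starts = 80, seed = 4)
  expect_equal(sort(vapply(eq3, function(s) s$qhat[["4->5"]], numeric(1))),
               ref, tolerance = 1e-10)
  expect_equal(sort(vapply(eq3, function(s) s$haematocrits[["4->6"]],
                           numeric(1))), refH, tolerance = 1e-10)
})

test_that("signed_flows rejects states with reversed total inflow", {
  net <- tri_default()
  cn <- hemonet:::compile_network(net)
  x <- c(rep(5, 3), rep(0.2, 4))   # interior pressures far above the inlets
  expect_error(signed_flows(net, x), "Q_in")
})
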