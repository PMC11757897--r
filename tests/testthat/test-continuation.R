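# Homotopy start, branch continuation, fold refinement, classification.

test_that("homotopy start solves the linear problem when no red cells enter", {
  net <- tri_default(h_in = 0)
  st <- homotopy_initial_solve(net)
  expect_equal(unname(st$pressures), unname(solve_zero_haematocrit(net)$pressures),
               tolerance = 1e-10)
})

test_that("homotopy start lands on a verified equilibrium at defaults", {
  for (net in list(tri_default(), ext_default())) {
    st <- homotopy_initial_solve(net)
    expect_lt(max(abs(assemble_residual(net, st))), 1e-10)
    eq <- enumerate_equilibria(net, n_starts = 150, seed = 1)
    d <- vapply(eq, function(s) max(abs(s$x - st$x)), numeric(1))
    expect_lt(min(d), 1e-6)
  }
})

test_that("triangle admits exactly the three labelled equilibria at beta = 1", {
  net <- tri_default()
  eq <- enumerate_equilibria(net, n_starts = 100, seed = 1)
  expect_length(eq, 3L)
  labs <- classify_flow_state(net, eq)
  expect_setequal(as.vector(labs), c("-", "0", "+"))
  # the intermediate equilibrium has exactly zero cross flow at beta = 1
  mid <- eq[[which(labs == "0")]]
  expect_lt(abs(mid$qhat[["4->5"]]), 1e-9)
  expect_lt(mid$haematocrits[["4->5"]], 0.01)
  # asymmetric haematocrit distribution of the (+) equilibrium
  plus <- eq[[which(labs == "+")]]
  expect_gt(plus$haematocrits[["4->6"]], 0.45)
  expect_lt(plus$haematocrits[["5->6"]], 0.45)
  # mirror closure at beta = 1: the mirrored set is the set itself
  for (s in eq) {
    xm <- mirror_state(net, s)
    d <- vapply(eq, function(o) max(abs(o$x - xm)), numeric(1))
    expect_lt(min(d), 1e-8)
  }
})

test_that("triangle beta branch has two machine-consistent folds", {
  net <- tri_default()
  eq <- enumerate_equilibria(net, n_starts = 100, seed = 1)
  labs <- classify_flow_state(net, eq)
  folds <- lapply(eq, function(s) {
    br <- continue_branch(net, "beta", c(0.5, 1.5), s, ds_max = 0.02)
    sort(br$folds$param)
  })
  for (f in folds) {
    expect_length(f, 2L)
    expect_equal(f, folds[[1]], tolerance = 1e-6)  # same curve, same folds
  }
  f <- folds[[1]]
  expect_true(f[1] < 1 && f[2] > 1)
  # every recorded branch point is a verified equilibrium
  br <- continue_branch(net, "beta", c(0.5, 1.5), eq[[1]], ds_max = 0.02)
  n <- br$n_unknown
  for (i in round(seq(1, nrow(br$points), length.out = 15))) {
    net_i <- set_network_parameter(net, "beta", br$points[i, n + 1])
    expect_lt(max(abs(assemble_residual(net_i, br$points[i, 1:n]))), 1e-10)
  }
})

test_that("state-space Jacobian is near-singular at a refined fold", {
  net <- tri_default()
  eq <- enumerate_equilibria(net, n_starts = 100, seed = 1)
  br <- continue_branch(net, "beta", c(0.5, 1.5), eq[[1]], ds_max = 0.02)
  k <- which.max(br$folds$param)
  xf <- attr(br$folds, "states")[[k]]
  net_f <- set_network_parameter(net, "beta", br$folds$param[k])
  J <- jacobian(net_f, xf)
  sv <- svd(J)$d
  expect_lt(sv[length(sv)] / sv[1], 1e-5)
})

test_that("a fold-free linear problem yields a monotone branch", {
  net <- tri_default(h_in = 0)
  st <- solve_zero_haematocrit(net)
  br <- continue_branch(net, "beta", c(0.5, 1.5), st, ds_max = 0.02)
  expect_equal(nrow(br$folds), 0L)
  n <- br$n_unknown
  expect_true(all(diff(br$points[, n + 1]) > 0) ||
                all(diff(br$points[, n + 1]) < 0))
})

test_that("extended triangle carries nine distinct flow-state tuples", {
  net <- ext_default()
  eq <- enumerate_equilibria(net, n_starts = 250, seed = 1)
  expect_length(eq, 9L)
  tuples <- label_tuples(net, eq)
  expect_length(unique(tuples), 9L)
  expect_setequal(tuples, c("-,-", "-,0", "-,+", "0,-", "0,0", "0,+",
                            "+,-", "+,0", "+,+"))
  # intermediate-labelled redundant vessels carry (almost) no red cells
  labs <- classify_flow_state(net, eq)
  for (i in seq_along(eq)) {
    if (labs[i, "7->8"] == "0") expect_lt(eq[[i]]$haematocrits[["7->8"]], 0.01)
    if (labs[i, "4->5"] == "0") expect_lt(eq[[i]]$haematocrits[["4->5"]], 0.01)
  }
})

test_that("classification handles coexisting sets per the flow ordering", {
  # a straddling triple labels its middle member intermediate
  expect_equal(hemonet:::label_flows(c(-0.05, 0.01, 0.06)), c("-", "0", "+"))
  # two coexisting equilibria are labelled by sign
  expect_equal(hemonet:::label_flows(c(-0.05, 0.06)), c("-", "+"))
  # singletons: by sign, intermediate only at numerical zero
  expect_equal(hemonet:::label_flows(0.03), "+")
  expect_equal(hemonet:::label_flows(1e-12), "0")
  # nine flows in three separated groups
  set.seed(11)
  v <- sample(c(-0.06, -0.058, -0.055, -0.002, 0, 0.002, 0.055, 0.058, 0.06))
  expect_equal(hemonet:::label_flows(v),
               c("-", "0", "+")[cut(v, c(-1, -0.03, 0.03, 1), labels = FALSE)],
               ignore_attr = TRUE)
})
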