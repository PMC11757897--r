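# Benchmark fixtures and the random-network generator.

test_that("triangle fixture matches its blueprint", {
  net <- tri_default()
  expect_equal(nrow(net$nodes), 6L)
  expect_equal(nrow(net$vessels), 6L)
  expect_silent(validate_network(net))
  v <- net$vessels
  expect_equal(v$length[v$from == 4 & v$to == 5], 0.1)   # alpha L
  expect_equal(v$length[v$from == 4 & v$to == 6], 1)     # beta L
  expect_true(all(v$diameter == 10))
  expect_equal(sum(is.finite(v$inlet_haematocrit)), 2L)
  expect_equal(length(find_redundant_vessels(net)), 1L)
  # alpha and beta land on the annotated vessels
  net2 <- build_triangle(fixture_spec(alpha = 0.25, beta = 1.7))
  expect_equal(net2$vessels$length[3], 0.25)
  expect_equal(net2$vessels$length[4], 1.7)
})

test_that("extended-triangle fixture matches its blueprint", {
  net <- ext_default()
  expect_equal(nrow(net$nodes), 8L)
  expect_equal(nrow(net$vessels), 9L)
  expect_silent(validate_network(net))
  v <- net$vessels
  expect_equal(v$length[v$from == 7 & v$to == 8], 0.1)
  expect_equal(v$length[v$from == 4 & v$to == 5], 0.1)
  expect_equal(v$length[v$from == 4 & v$to == 6], 1)
  # inlet haematocrits attach to (1,7) and (2,8)
  hv <- v[is.finite(v$inlet_haematocrit), c("from", "to")]
  expect_setequal(paste(hv$from, hv$to), c("1 7", "2 8"))
  expect_equal(length(find_redundant_vessels(net)), 2L)
})

test_that("beta = 1 networks are mirror-symmetric by construction", {
  for (net in list(tri_default(), ext_default())) {
    M <- net$meta$mirror
    v <- net$vessels
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    k1 <- key(v$from, v$to)
    mf <- M[as.character(v$from)]
    mt <- M[as.character(v$to)]
    for (e in seq_len(nrow(v))) {
      em <- which(k1 == key(mf[e], mt[e]))
      expect_equal(v$length[em], v$length[e])
      expect_equal(v$diameter[em], v$diameter[e])
    }
  }
})

test_that("fixture parameter updates rebuild the right entries", {
  net <- set_network_parameter(ext_default(), "beta", 2.2)
  expect_equal(net$vessels$length[7], 2.2)
  net <- set_network_parameter(net, "alpha", 0.3)
  expect_equal(net$vessels$length[c(3, 6)], c(0.3, 0.3))
  net <- set_network_parameter(net, "h_in", 0.2)
  expect_equal(net$vessels$inlet_haematocrit[1:2], c(0.2, 0.2))
  net <- set_network_parameter(net, "D", 40)
  expect_true(all(net$vessels$diameter == 40))
  net <- set_network_parameter(net, "p1", 0.8)
  expect_equal(net$nodes$pressure[1], 0.8)
  expect_error(set_network_parameter(net, "gamma", 1), "unknown")
})

test_that("random networks are reproducible, valid and feasible", {
  for (seed in 1:8) {
    a <- random_network(seed)
    b <- random_network(seed)
    expect_identical(a, b)
    expect_silent(validate_network(a))
    expect_gte(length(enumerate_feasible_orientations(a)), 1L)
  }
  expect_false(identical(random_network(1), random_network(2)))
  # the generator must not disturb the global RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(random_network(3)); after <- runif(1)
  expect_identical(before, after)
  # small budgets force the Y topology, which has no redundant vessel
  y <- random_network(5, node_budget = 4L)
  expect_equal(length(find_redundant_vessels(y)), 0L)
})

test_that("network validation reports specific violations", {
  net <- tri_default()
  bad <- net$nodes; bad$pressure[1] <- NA
  expect_error(vascular_network(bad, net$vessels), "node.* 1")
  bad2 <- net$vessels; bad2$diameter[1] <- 1.0
  expect_error(vascular_network(net$nodes, bad2), "diameter")
  bad3 <- net$nodes; bad3$pressure[3] <- 0.9   # outlet above inlets
  expect_error(vascular_network(bad3, net$vessels), "inlet pressure")
  bad4 <- net$vessels; bad4$inlet_haematocrit[1] <- NA
  expect_error(vascular_network(net$nodes, bad4), "inlet vessel")
})
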