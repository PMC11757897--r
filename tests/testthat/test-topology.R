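# Feasible flow orientations and redundant vessels.

y_network <- function() {
  vascular_network(
    nodes = data.frame(id = 1:4,
                       kind = c("inlet", "interior", "outlet", "outlet"),
                       pressure = c(1, NA, 0, 0.1)),
    vessels = data.frame(from = c(1, 2, 2), to = c(2, 3, 4),
                         length = 1, diameter = 10,
                         inlet_haematocrit = c(0.45, NA, NA)))
}

test_that("orientation counts match exhaustive expectations", {
  # triangle: the cross vessel is the only free direction
  ors <- enumerate_feasible_orientations(tri_default())
  expect_length(ors, 2L)
  d <- do.call(rbind, ors)
  flips <- apply(d, 2, function(col) length(unique(col)) > 1)
  expect_identical(names(which(flips)), "4->5")
  # extended triangle: both cross vessels are free
  expect_length(enumerate_feasible_orientations(ext_default()), 4L)
  # Y bifurcation: fully forced
  expect_length(enumerate_feasible_orientations(y_network()), 1L)
})

test_that("every returned orientation passes an independent acyclicity check", {
  for (net in list(tri_default(), ext_default(), y_network())) {
    for (o in enumerate_feasible_orientations(net)) {
      expect_true(is_acyclic_kahn(net, o))
    }
  }
})

test_that("redundant vessels are the direction-ambiguous ones", {
  expect_identical(names(find_redundant_vessels(tri_default())), "4->5")
  expect_identical(sort(names(find_redundant_vessels(ext_default()))),
                   c("4->5", "7->8"))
  expect_length(find_redundant_vessels(y_network()), 0L)
  expect_equal(equilibrium_upper_bound(tri_default()), 3L)
  expect_equal(equilibrium_upper_bound(ext_default()), 9L)
  expect_equal(equilibrium_upper_bound(y_network()), 1L)
})

test_that("redundancy is invariant under node relabelling", {
  for (seed in 1:6) {
    net <- random_network(seed)
    r1 <- length(find_redundant_vessels(net))
    # relabel nodes with a fresh permutation
    perm <- sample(1000:2000, nrow(net$nodes))
    map <- setNames(perm, net$nodes$id)
    nodes2 <- transform(net$nodes, id = map[as.character(id)])
    vessels2 <- transform(net$vessels,
                          from = map[as.character(from)],
                          to = map[as.character(to)])
    net2 <- vascular_network(nodes2, vessels2)
    expect_equal(length(find_redundant_vessels(net2)), r1)
  }
})

test_that("the search guard and infeasibility are reported", {
  expect_error(enumerate_feasible_orientations(tri_default(), max_vessels = 3),
               "guard")
  # three inlets all forced into one junction leave it without an outflow
  bad <- vascular_network(
    data.frame(id = 1:4, kind = c("inlet", "inlet", "inlet", "interior"),
               pressure = c(1, 1, 1, NA)),
    data.frame(from = 1:3, to = 4, length = 1, diameter = 10,
               inlet_haematocrit = 0.4),
    validate = FALSE)
  expect_error(enumerate_feasible_orientations(bad), "no feasible")
})

test_that("equilibrium orientations are members of the feasible set", {
  net <- tri_default()
  ors <- enumerate_feasible_orientations(net)
  for (s in enumerate_equilibria(net, n_starts = 60, seed = 1)) {
    expect_true(orientation_member(net, s, ors))
  }
})
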