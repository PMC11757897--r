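# Benchmark network fixtures and a random small-network generator.
#
# The triangle network has two inlets (nodes 1, 2), one outlet (node 3) and a
# triangular interior (nodes 4, 5, 6) whose cross vessel <4,5> is its single
# redundant vessel. The extended-triangle network inserts one more cross
# vessel <7,8> between the inlets and the triangle, giving two redundant
# vessels. Length ratios: alpha scales the redundant vessels, beta scales
# vessel (4,6) and controls the asymmetry; all other vessels have the
# reference length L = 1 (dimensionless flows are independent of L).

#' Fixture parameter set
#'
#' Parameters of the benchmark networks. Defaults: symmetric inlet pressures
#' `P1 = P2 = 0.5` with outlet `P3 = 0` (already normalised), common diameter
#' `D = 10` um, redundant-vessel length ratio `alpha = 0.1`, asymmetry ratio
#' `beta = 1`, inlet haematocrit `h_in = 0.45`.
#'
#' @param alpha Redundant-vessel length ratio (> 0).
#' @param beta Length ratio of vessel (4,6) (> 0); `beta = 1` is the
#'   symmetric network.
#' @param D Common vessel diameter in micrometres (> 1.1).
#' @param p1,p2 Inlet pressures (> `p3`).
#' @param p3 Outlet pressure.
#' @param h_in Inlet haematocrit fraction in `[0, 1)`.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(alpha = 0.1, beta = 1, D = 10,
                         p1 = 0.5, p2 = 0.5, p3 = 0, h_in = 0.45) {
  stopifnot(alpha > 0, beta > 0, D > 1.1, p1 > p3, p2 > p3,
            h_in >= 0, h_in < 1)
  structure(list(alpha = alpha, beta = beta, D = D,
                 p1 = p1, p2 = p2, p3 = p3, h_in = h_in),
            class = "fixture_spec")
}

#' Build the triangle benchmark network
#'
#' Six nodes (inlets 1, 2; outlet 3; interior 4, 5, 6) and six vessels
#' (1,4), (2,5), <4,5>, (4,6), (5,6), (6,3). Vessel <4,5> has length
#' `alpha * L`, vessel (4,6) has length `beta * L`, all others length `L`;
#' all diameters equal `D`. With `beta = 1` the network is mirror-symmetric
#' under the node swap (1<->2, 4<->5).
#'
#' @param spec A [fixture_spec()].
#' @return A [vascular_network()] with fixture annotations in `meta`
#'   (redundant-vessel rows, parameter-tagged vessels, the mirror node map).
#' @export
build_triangle <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  nodes <- data.frame(
    id = 1:6,
    kind = c("inlet", "inlet", "outlet", "interior", "interior", "interior"),
    pressure = c(spec$p1, spec$p2, spec$p3, NA, NA, NA)
  )
  vessels <- data.frame(
    from = c(1, 2, 4, 4, 5, 6),
    to   = c(4, 5, 5, 6, 6, 3),
    length = c(1, 1, spec$alpha, spec$beta, 1, 1),
    diameter = spec$D,
    inlet_haematocrit = c(spec$h_in, spec$h_in, NA, NA, NA, NA)
  )
  vascular_network(nodes, vessels, meta = list(
    fixture = "triangle", spec = unclass(spec),
    redundant_rows = 3L, alpha_rows = 3L, beta_rows = 4L,
    mirror = c(`1` = 2L, `2` = 1L, `3` = 3L, `4` = 5L, `5` = 4L, `6` = 6L)
  ))
}

#' Build the extended-triangle benchmark network
#'
#' Eight nodes (inlets 1, 2; outlet 3; interior 4..8) and nine vessels
#' (1,7), (2,8), <7,8>, (7,4), (8,5), <4,5>, (4,6), (5,6), (6,3). The two
#' cross vessels <7,8> and <4,5> have length `alpha * L`, vessel (4,6) has
#' length `beta * L`, the rest length `L`; all diameters equal `D`. Inlet
#' haematocrits attach to (1,7) and (2,8).
#'
#' @inheritParams build_triangle
#' @return A [vascular_network()] with fixture annotations in `meta`.
#' @export
build_extended_triangle <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  nodes <- data.frame(
    id = 1:8,
    kind = c("inlet", "inlet", "outlet", rep("interior", 5)),
    pressure = c(spec$p1, spec$p2, spec$p3, rep(NA, 5))
  )
  vessels <- data.frame(
    from = c(1, 2, 7, 7, 8, 4, 4, 5, 6),
    to   = c(7, 8, 8, 4, 5, 5, 6, 6, 3),
    length = c(1, 1, spec$alpha, 1, 1, spec$alpha, spec$beta, 1, 1),
    diameter = spec$D,
    inlet_haematocrit = c(spec$h_in, spec$h_in, rep(NA, 7))
  )
  vascular_network(nodes, vessels, meta = list(
    fixture = "extended_triangle", spec = unclass(spec),
    redundant_rows = c(3L, 6L), alpha_rows = c(3L, 6L), beta_rows = 7L,
    mirror = c(`1` = 2L, `2` = 1L, `3` = 3L, `4` = 5L, `5` = 4L, `6` = 6L,
               `7` = 8L, `8` = 7L)
  ))
}

#' Update a sweep parameter of a fixture network
#'
#' Rebuilds the annotated vessel/node entries of a fixture network for a new
#' value of one of its parameters. Used by the continuation and sweep
#' drivers.
#'
#' @param network A fixture network (from [build_triangle()] or
#'   [build_extended_triangle()]).
#' @param param One of `"beta"`, `"alpha"`, `"h_in"`, `"D"`, `"p1"`, `"p2"`.
#' @param value New parameter value.
#' @return The updated network.
#' @export
set_network_parameter <- function(network, param, value) {
  v <- network$vessels
  n <- network$nodes
  meta <- network$meta
  switch(param,
    beta = { v$length[meta$beta_rows] <- value },
    alpha = { v$length[meta$alpha_rows] <- value },
    h_in = {
      v$inlet_haematocrit[is.finite(v$inlet_haematocrit)] <- value
      meta$spec$h_in <- value
    },
    D = { v$diameter[] <- value },
    p1 = { n$pressure[which(n$kind == "inlet")[1L]] <- value },
    p2 = { n$pressure[which(n$kind == "inlet")[2L]] <- value },
    stop(sprintf("unknown sweep parameter '%s'", param), call. = FALSE)
  )
  if (param %in% c("beta", "alpha")) meta$spec[[param]] <- value
  if (param == "D") meta$spec$D <- value
  vascular_network(n, v, meta = meta)
}

#' Mirror image of a state under a fixture's reflection map
#'
#' The fixture networks carry a node permutation (`meta$mirror`) that swaps
#' the two inlet-side halves. Applying it to a state swaps the left/right
#' pressures and haematocrits and negates the flow in every redundant
#' vessel. For a symmetric network (`beta = 1`, equal inlet conditions) the
#' equilibrium set is closed under this map.
#'
#' @inheritParams signed_flows
#' @return The mirrored unknown vector (not polished; feed to
#'   [newton_solve()] if an exact equilibrium is required).
#' @export
mirror_state <- function(network, state) {
  M <- network$meta$mirror
  if (is.null(M)) stop("network has no mirror annotation", call. = FALSE)
  cn <- compile_network(network)
  x <- state_x(state)
  n_int <- length(cn$int0)
  ids <- network$nodes$id
  out <- x
  # pressures: value at node v moves to node M[v]
  for (j in seq_len(n_int)) {
    v <- ids[cn$int0[j] + 1L]
    jm <- which(ids[cn$int0 + 1L] == M[[as.character(v)]])
    out[jm] <- x[j]
  }
  # haematocrits: vessel (u,v) maps to vessel (M u, M v) (either order)
  key <- paste(pmin(ids[cn$from0 + 1L], ids[cn$to0 + 1L]),
               pmax(ids[cn$from0 + 1L], ids[cn$to0 + 1L]))
  for (e in seq_along(cn$from0)) {
    if (cn$h_idx[e] < 0) next
    mu <- M[[as.character(ids[cn$from0[e] + 1L])]]
    mv <- M[[as.character(ids[cn$to0[e] + 1L])]]
    em <- which(key == paste(min(mu, mv), max(mu, mv)))
    out[n_int + cn$h_idx[em] + 1L] <- x[n_int + cn$h_idx[e] + 1L]
  }
  out
}

#' Random small network for property tests
#'
#' Draws a feasible degree-3 topology (single Y bifurcation, double Y tree,
#' triangle or extended triangle, subject to the node budget), randomises all
#' vessel lengths (`[0.05, 3] L`), diameters (`[5, 50]` um), boundary
#' pressures (inlets above outlets) and the inlet haematocrit (`[0, 0.6]`),
#' and randomly relabels the nodes. Reproducible from `seed`; every draw has
#' at least one feasible flow orientation by construction.
#'
#' @param seed Integer seed.
#' @param node_budget Maximum number of nodes (4..12).
#' @return A [vascular_network()].
#' @export
random_network <- function(seed, node_budget = 12L) {
  stopifnot(node_budget >= 4L, node_budget <= 12L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)

  templates <- list(
    y = list(nodes = data.frame(id = 1:4,
                                kind = c("inlet", "interior", "outlet", "outlet")),
             edges = rbind(c(1, 2), c(2, 3), c(2, 4))),
    double_y = list(nodes = data.frame(
                      id = 1:8,
                      kind = c("inlet", "interior", "interior", "interior",
                               "outlet", "outlet", "outlet", "outlet")),
                    edges = rbind(c(1, 2), c(2, 3), c(2, 4),
                                  c(3, 5), c(3, 6), c(4, 7), c(4, 8))),
    triangle = list(nodes = data.frame(
                      id = 1:6,
                      kind = c("inlet", "inlet", "outlet",
                               "interior", "interior", "interior")),
                    edges = rbind(c(1, 4), c(2, 5), c(4, 5),
                                  c(4, 6), c(5, 6), c(6, 3))),
    extended_triangle = list(nodes = data.frame(
                      id = 1:8,
                      kind = c("inlet", "inlet", "outlet", rep("interior", 5))),
                    edges = rbind(c(1, 7), c(2, 8), c(7, 8), c(7, 4), c(8, 5),
                                  c(4, 5), c(4, 6), c(5, 6), c(6, 3)))
  )
  ok <- vapply(templates, function(t) nrow(t$nodes) <= node_budget, logical(1))
  tpl <- templates[[sample(which(ok), 1L)]]

  n <- nrow(tpl$nodes)
  m <- nrow(tpl$edges)
  pin <- runif(sum(tpl$nodes$kind == "inlet"), 0.6, 1.2)
  pout <- runif(sum(tpl$nodes$kind == "outlet"), 0, 0.3)
  pressure <- rep(NA_real_, n)
  pressure[tpl$nodes$kind == "inlet"] <- pin
  pressure[tpl$nodes$kind == "outlet"] <- pout
  h_in <- runif(1, 0, 0.6)

  perm <- sample.int(n)  # random node ids
  nodes <- data.frame(id = perm, kind = tpl$nodes$kind, pressure = pressure)
  inlet_ids <- nodes$id[nodes$kind == "inlet"]
  vessels <- data.frame(
    from = perm[tpl$edges[, 1]],
    to = perm[tpl$edges[, 2]],
    length = runif(m, 0.05, 3),
    diameter = runif(m, 5, 50)
  )
  vessels$inlet_haematocrit <-
    ifelse(vessels$from %in% inlet_ids | vessels$to %in% inlet_ids,
           h_in, NA_real_)
  vascular_network(nodes, vessels, meta = list(seed = seed))
}
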