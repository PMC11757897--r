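#' Construct a vascular network
#'
#' A vascular network is an undirected graph of nodes (vessel junctions,
#' inlets, outlets) and vessels. Boundary nodes (inlets and outlets) have
#' degree one and a prescribed pressure; interior nodes have degree three
#' (the splitting rules used here are defined for three-vessel junctions).
#' Each vessel carries a length (in multiples of a reference length), a
#' diameter in micrometres, and -- if it is attached to an inlet node -- a
#' prescribed inlet haematocrit. The `from`/`to` order of a vessel is its
#' reference orientation: a positive signed flow runs from `from` to `to`.
#'
#' @param nodes Data frame with columns `id` (integer), `kind` (one of
#'   `"inlet"`, `"outlet"`, `"interior"`) and `pressure` (prescribed boundary
#'   pressure; `NA` for interior nodes).
#' @param vessels Data frame with columns `from`, `to` (node ids), `length`,
#'   `diameter` and optionally `inlet_haematocrit` (`NA` except for vessels
#'   attached to an inlet node).
#' @param meta Optional list of annotations (kept through JSON round trips).
#' @param validate Check the network invariants (default `TRUE`).
#' @return An object of class `vascular_network`.
#' @export
vascular_network <- function(nodes, vessels, meta = list(), validate = TRUE) {
  nodes <- as.data.frame(nodes)
  vessels <- as.data.frame(vessels)
  if (is.null(vessels$inlet_haematocrit)) vessels$inlet_haematocrit <- NA_real_
  nodes$id <- as.integer(nodes$id)
  vessels$from <- as.integer(vessels$from)
  vessels$to <- as.integer(vessels$to)
  net <- structure(list(nodes = nodes, vessels = vessels, meta = meta),
                   class = "vascular_network")
  if (validate) validate_network(net)
  net
}

#' Validate the vascular-network invariants
#'
#' Checks: unique node ids; known node kinds; finite prescribed pressures on
#' boundary nodes; degree 1 at boundary nodes and degree 3 at interior nodes;
#' a connected graph with at least one inlet and one outlet; strictly
#' positive lengths and diameters (> 1.1 um, the singular diameter of the
#' viscosity law); every inlet pressure above every outlet pressure; and an
#' inlet haematocrit in `[0, 1)` on every inlet vessel (and only there).
#'
#' @param net A `vascular_network`.
#' @return `net`, invisibly; stops with an informative error otherwise.
#' @export
validate_network <- function(net) {
  nodes <- net$nodes
  vessels <- net$vessels
  fail <- function(...) stop(sprintf(...), call. = FALSE)

  if (anyDuplicated(nodes$id)) fail("duplicate node ids")
  if (!all(nodes$kind %in% c("inlet", "outlet", "interior"))) {
    fail("node kind must be inlet, outlet or interior")
  }
  boundary <- nodes$kind != "interior"
  if (any(!is.finite(nodes$pressure[boundary]))) {
    bad <- nodes$id[boundary & !is.finite(nodes$pressure)]
    fail("boundary node(s) %s missing a prescribed pressure",
         paste(bad, collapse = ", "))
  }
  if (!any(nodes$kind == "inlet")) fail("network has no inlet node")
  if (!any(nodes$kind == "outlet")) fail("network has no outlet node")
  if (!all(c(vessels$from, vessels$to) %in% nodes$id)) {
    fail("vessel endpoint references an unknown node id")
  }
  if (any(vessels$from == vessels$to)) fail("self-loop vessel")

  deg <- table(factor(c(vessels$from, vessels$to), levels = nodes$id))
  if (any(deg[boundary] != 1L)) {
    fail("inlet/outlet node(s) %s must have degree exactly 1",
         paste(nodes$id[boundary][deg[boundary] != 1L], collapse = ", "))
  }
  if (any(deg[!boundary] != 3L)) {
    fail("interior node(s) %s must have degree exactly 3",
         paste(nodes$id[!boundary][deg[!boundary] != 3L], collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(vessels[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes$id))
  if (!igraph::is_connected(g)) fail("network graph is not connected")

  if (any(!is.finite(vessels$length)) || any(vessels$length <= 0)) {
    fail("vessel lengths must be strictly positive")
  }
  if (any(!is.finite(vessels$diameter)) || any(vessels$diameter <= 1.1)) {
    fail("vessel diameters must exceed 1.1 micrometres")
  }
  pin <- nodes$pressure[nodes$kind == "inlet"]
  pout <- nodes$pressure[nodes$kind == "outlet"]
  if (min(pin) <= max(pout)) {
    fail("every inlet pressure must exceed every outlet pressure")
  }

  inlet_ids <- nodes$id[nodes$kind == "inlet"]
  is_inlet_vessel <- vessels$from %in% inlet_ids | vessels$to %in% inlet_ids
  h <- vessels$inlet_haematocrit
  if (any(is_inlet_vessel & (!is.finite(h) | h < 0 | h >= 1))) {
    fail("every inlet vessel needs an inlet haematocrit in [0, 1)")
  }
  if (any(!is_inlet_vessel & is.finite(h))) {
    fail("inlet haematocrit given on a non-inlet vessel")
  }
  invisible(net)
}

#' @export
print.vascular_network <- function(x, ...) {
  n <- x$nodes; v <- x$vessels
  cat(sprintf("<vascular_network> %d nodes (%d inlet, %d outlet), %d vessels\n",
              nrow(n), sum(n$kind == "inlet"), sum(n$kind == "outlet"), nrow(v)))
  invisible(x)
}

# ---- compiled form ---------------------------------------------------------
# Flat integer/double arrays consumed by the C++ residual kernel. Node order
# follows net$nodes; unknown vector layout is [interior pressures, then one
# haematocrit per non-inlet vessel, in vessel order].
compile_network <- function(net, rule = "pries1990",
                            params = rheology_params()) {
  nodes <- net$nodes
  vessels <- net$vessels
  nid <- nodes$id
  kind <- match(nodes$kind, c("inlet", "outlet", "interior")) - 1L
  from0 <- match(vessels$from, nid) - 1L
  to0 <- match(vessels$to, nid) - 1L

  inlet_vessel <- kind[from0 + 1L] == 0L | kind[to0 + 1L] == 0L
  # orient inlet vessels away from the inlet node so their reference flow
  # is positive when blood enters the network
  flip <- inlet_vessel & kind[to0 + 1L] == 0L
  tmp <- from0[flip]; from0[flip] <- to0[flip]; to0[flip] <- tmp
  # orient outlet vessels toward the outlet node
  outlet_vessel <- kind[from0 + 1L] == 1L | kind[to0 + 1L] == 1L
  flip2 <- outlet_vessel & kind[from0 + 1L] == 1L
  tmp <- from0[flip2]; from0[flip2] <- to0[flip2]; to0[flip2] <- tmp

  h_idx <- rep(-1L, nrow(vessels))
  h_idx[!inlet_vessel] <- seq_len(sum(!inlet_vessel)) - 1L
  p_idx <- rep(-1L, nrow(nodes))
  p_idx[kind == 2L] <- seq_len(sum(kind == 2L)) - 1L

  int0 <- which(kind == 2L) - 1L
  incid <- matrix(-1L, nrow = 3L, ncol = length(int0))
  sgn <- matrix(0L, nrow = 3L, ncol = length(int0))
  for (j in seq_along(int0)) {
    v <- int0[j]
    e <- which(from0 == v | to0 == v)
    stopifnot(length(e) == 3L)
    incid[, j] <- e - 1L
    sgn[, j] <- ifelse(to0[e] == v, 1L, -1L)  # +1: reference flow enters node
  }

  rl <- splitting_rule(rule)
  D <- vessels$diameter
  Cv <- coeff_C(D)
  list(
    kind = kind,
    p_bound = ifelse(is.finite(nodes$pressure), nodes$pressure, 0),
    from0 = from0, to0 = to0,
    len = vessels$length, diam = D,
    hfix = ifelse(inlet_vessel, vessels$inlet_haematocrit, -1),
    inlet_vessel = inlet_vessel,
    h_idx = h_idx, p_idx = p_idx,
    int0 = int0, incid = incid, sgn = sgn,
    n_unknown = length(int0) + sum(!inlet_vessel),
    # diameter-only viscosity and splitting terms, precompiled once
    mu45v = mu_45(D), Cv = Cv, wallv = (D / (D - 1.1))^2,
    denomv = 0.55^Cv - 1,
    rpre = 128 * vessels$length / (pi * D^4),
    x0v = 0.4 / D, logD = log(D),
    mu_p = params$mu_p,
    rule = rl$name,
    rule_code = if (is.na(rl$code)) -1L else rl$code,
    psi_fn = rl$psi
  )
}

#' Number of unknowns of the steady-state system
#'
#' Interior nodal pressures plus one haematocrit per non-inlet vessel.
#'
#' @param net A [vascular_network()].
#' @return Integer problem size.
#' @export
n_unknowns <- function(net) {
  compile_network(net)$n_unknown
}
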