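# Flow orientations and redundant vessels.
#
# A feasible orientation assigns a direction to every vessel such that the
# directed graph is acyclic (flow loops would contradict pressure-driven
# flow), inlets feed the network, outlets drain it, and every interior node
# has at least one inflow and one outflow. Vessels whose direction differs
# between feasible orientations are "redundant"; they are where coexisting
# equilibria can differ.

#' Enumerate all feasible flow orientations of a network
#'
#' Exhaustive search over the free (non-boundary) vessels, after forcing
#' inlet vessels away from their inlet and outlet vessels toward their
#' outlet. An assignment is kept when every interior node has in- and
#' out-degree at least one and the directed graph is acyclic.
#'
#' @param network A [vascular_network()].
#' @param max_vessels Guard on the exhaustive search (default 25).
#' @return A list of orientations; each is an integer vector with one entry
#'   per vessel, `+1` meaning flow along the vessel's `from -> to` reference
#'   orientation and `-1` the reverse, named `"from->to"`.
#' @export
enumerate_feasible_orientations <- function(network, max_vessels = 25L) {
  v <- network$vessels
  n <- network$nodes
  m <- nrow(v)
  if (m > max_vessels) {
    stop(sprintf("network has %d vessels; exhaustive orientation search is guarded at %d",
                 m, max_vessels), call. = FALSE)
  }
  inlet_ids <- n$id[n$kind == "inlet"]
  outlet_ids <- n$id[n$kind == "outlet"]
  dir <- rep(NA_integer_, m)
  dir[v$from %in% inlet_ids] <- 1L
  dir[v$to %in% inlet_ids] <- -1L
  dir[v$to %in% outlet_ids] <- 1L
  dir[v$from %in% outlet_ids] <- -1L
  free <- which(is.na(dir))

  interior_ids <- n$id[n$kind == "interior"]
  check <- function(d) {
    heads <- ifelse(d > 0, v$to, v$from)   # node receiving flow
    tails <- ifelse(d > 0, v$from, v$to)
    indeg <- table(factor(heads, levels = interior_ids))
    outdeg <- table(factor(tails, levels = interior_ids))
    if (any(indeg == 0L) || any(outdeg == 0L)) return(FALSE)
    g <- igraph::graph_from_data_frame(
      data.frame(from = tails, to = heads), directed = TRUE,
      vertices = data.frame(name = n$id))
    igraph::is_dag(g)
  }

  out <- list()
  for (bits in 0:(2^length(free) - 1L)) {
    d <- dir
    if (length(free)) {
      d[free] <- ifelse(bitwAnd(bits, 2^(seq_along(free) - 1L)) > 0, 1L, -1L)
    }
    if (check(d)) {
      names(d) <- paste0(v$from, "->", v$to)
      out[[length(out) + 1L]] <- d
    }
    if (!length(free)) break
  }
  if (!length(out)) {
    stop("no feasible flow orientation: malformed boundary assignment",
         call. = FALSE)
  }
  out
}

#' Identify the redundant vessels of a network
#'
#' A vessel is redundant when its flow direction differs between at least two
#' feasible orientations; all other vessels are fixed vessels.
#'
#' @inheritParams enumerate_feasible_orientations
#' @return Integer vector of vessel row indices (into `network$vessels`),
#'   named by vessel label.
#' @export
find_redundant_vessels <- function(network, max_vessels = 25L) {
  ors <- enumerate_feasible_orientations(network, max_vessels)
  dirs <- do.call(rbind, ors)
  idx <- which(apply(dirs, 2, function(col) length(unique(col)) > 1L))
  stats::setNames(as.integer(idx), colnames(dirs)[idx])
}

#' Upper bound on the number of equilibria
#'
#' Coexisting equilibria are distinguished by the flow state (negative,
#' intermediate or positive) in each redundant vessel, so a network with `r`
#' redundant vessels admits at most `3^r` equilibria.
#'
#' @inheritParams enumerate_feasible_orientations
#' @return Integer `3^r`.
#' @export
equilibrium_upper_bound <- function(network, max_vessels = 25L) {
  3L^length(find_redundant_vessels(network, max_vessels))
}

#' Flow orientation induced by a state
#'
#' Signs each vessel by its flow direction; vessels with `|Qhat|` below `tol`
#' get 0 (direction undefined at zero flow).
#'
#' @inheritParams signed_flows
#' @param tol Zero-flow tolerance on normalised flows.
#' @return Integer vector in `{-1, 0, 1}` per vessel, named by label.
#' @export
induced_orientation <- function(network, state, tol = 1e-9,
                                rule = "pries1990",
                                params = rheology_params()) {
  q <- signed_flows(network, state, rule, params)
  # labels follow the compiled reference orientation (inlet vessels flipped
  # into the network); map back to the raw vessel order
  v <- network$vessels
  raw <- paste0(v$from, "->", v$to)
  rev <- paste0(v$to, "->", v$from)
  out <- integer(nrow(v))
  for (e in seq_len(nrow(v))) {
    val <- if (raw[e] %in% names(q)) q[[raw[e]]] else -q[[rev[e]]]
    out[e] <- if (abs(val) < tol) 0L else if (val > 0) 1L else -1L
  }
  stats::setNames(out, raw)
}
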