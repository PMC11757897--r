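# Shared fixtures and small independent oracles for the test suite.

tri_default <- function(...) build_triangle(fixture_spec(...))
ext_default <- function(...) build_extended_triangle(fixture_spec(...))

# independent dense Kirchhoff solve (constant per-vessel viscosity), built
# from first principles: nodal conductance balance at interior nodes
kirchhoff_oracle <- function(network, H = 0) {
  v <- network$vessels
  n <- network$nodes
  mu <- sapply(seq_len(nrow(v)), function(e)
    apparent_viscosity(H, v$diameter[e]))
  g <- pi * v$diameter^4 / (128 * v$length * mu)
  interior <- n$id[n$kind == "interior"]
  A <- matrix(0, length(interior), length(interior))
  b <- numeric(length(interior))
  for (j in seq_along(interior)) {
    vid <- interior[j]
    touching <- which(v$from == vid | v$to == vid)
    for (e in touching) {
      other <- if (v$from[e] == vid) v$to[e] else v$from[e]
      A[j, j] <- A[j, j] + g[e]
      jo <- match(other, interior)
      if (!is.na(jo)) A[j, jo] <- A[j, jo] - g[e]
      else b[j] <- b[j] + g[e] * n$pressure[n$id == other]
    }
  }
  setNames(solve(A, b), interior)
}

# Kahn topological sort, written independently of igraph, as an acyclicity
# check for orientations
is_acyclic_kahn <- function(network, orientation) {
  v <- network$vessels
  heads <- ifelse(orientation > 0, v$to, v$from)
  tails <- ifelse(orientation > 0, v$from, v$to)
  ids <- network$nodes$id
  edges <- data.frame(tails, heads)
  repeat {
    indeg <- table(factor(edges$heads, levels = ids))
    src <- ids[indeg == 0]
    src <- setdiff(src, setdiff(ids, c(edges$tails, edges$heads)))
    if (!length(src)) break
    keep <- !(edges$tails %in% src)
    edges <- edges[keep, , drop = FALSE]
    ids <- setdiff(ids, src)
    if (!nrow(edges)) return(TRUE)
  }
  nrow(edges) == 0L
}

# membership of a state's induced orientation in a set of feasible
# orientations (zero-flow vessels are direction-free)
orientation_member <- function(network, state, orientations, tol = 1e-9) {
  ind <- induced_orientation(network, state, tol = tol)
  any(vapply(orientations, function(o) {
    all(ind == 0L | ind == o)
  }, logical(1)))
}

label_tuples <- function(network, states) {
  apply(classify_flow_state(network, states), 1, paste, collapse = ",")
}

# flows of a state keyed by unordered vessel, for set comparisons
qhat_of <- function(state, lab) state$qhat[[lab]]
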