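# Network JSON format, result writers and a DOT export.
#
# Document layout:
# {
#   "meta":    { "format": "hemonet-network", "version": 1, ... },
#   "nodes":   [ { "id": 1, "kind": "inlet", "pressure": 0.5 }, ... ],
#   "vessels": [ { "from": 1, "to": 4, "length": 1.0, "diameter": 10,
#                  "inlet_haematocrit": 0.45 }, ... ]
# }
# Lengths are multiples of the reference vessel length; diameters are in
# micrometres; pressures may be raw or pre-normalised (equilibrium flows and
# haematocrits do not depend on the pressure scale).

#' Read a vascular network from JSON
#'
#' Parses and validates a network document; all [vascular_network()]
#' invariants are checked on read. Validation errors name the offending
#' node or field.
#'
#' @param path File path.
#' @return A [vascular_network()].
#' @export
read_network <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  for (field in c("nodes", "vessels")) {
    if (is.null(doc[[field]])) {
      stop(sprintf("network document missing '%s' (at /%s)", field, field),
           call. = FALSE)
    }
  }
  nodes <- as.data.frame(doc$nodes)
  vessels <- as.data.frame(doc$vessels)
  for (col in c("id", "kind")) {
    if (is.null(nodes[[col]])) {
      stop(sprintf("node entries need '%s' (at /nodes/*/%s)", col, col),
           call. = FALSE)
    }
  }
  if (is.null(nodes$pressure)) nodes$pressure <- NA_real_
  for (col in c("from", "to", "length", "diameter")) {
    if (is.null(vessels[[col]])) {
      stop(sprintf("vessel entries need '%s' (at /vessels/*/%s)", col, col),
           call. = FALSE)
    }
  }
  meta <- if (is.null(doc$meta)) list() else doc$meta
  vascular_network(nodes, vessels, meta = meta)
}

#' Write a vascular network to JSON
#'
#' Deterministic output (fixed key order, fixed precision) so identical
#' networks produce identical files; `meta` entries are passed through, so
#' `write_network()` then [read_network()] round-trips the document.
#'
#' @param network A [vascular_network()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  meta <- network$meta
  meta$format <- "hemonet-network"
  meta$version <- 1L
  meta$units <- list(length = "multiples of reference length L",
                     diameter = "micrometres")
  doc <- list(meta = meta,
              nodes = network$nodes,
              vessels = network$vessels)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write sweep results to tidy CSV
#'
#' One row per branch point (`kind = "point"`) and one per fold
#' (`kind = "fold"`), with the swept parameter, the normalised flow and
#' haematocrit of every vessel, the interior pressures and the branch label.
#' A comment header records the solver tolerances and the seed.
#'
#' @param sweep A sweep result (e.g. from [beta_sweep()]).
#' @param network The swept network.
#' @param path Output file.
#' @param seed Seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_results <- function(sweep, network, path, seed = 0L) {
  brs <- sweep$branches
  if (!length(brs) || !nrow(brs[[1]]$points)) {
    stop("empty sweep result; nothing to write", call. = FALSE)
  }
  rows <- list()
  for (i in seq_along(brs)) {
    br <- brs[[i]]
    n <- br$n_unknown
    lab <- if (!is.null(sweep$labels)) sweep$labels[i] else NA_character_
    for (k in seq_len(nrow(br$points))) {
      val <- br$points[k, n + 1L]
      net_k <- set_network_parameter(network, sweep$param, val)
      cn <- compile_network(net_k, br$rule, br$params)
      st <- make_state(net_k, cn, br$points[k, seq_len(n)])
      q <- setNames(st$qhat, paste0("Q_", names(st$qhat)))
      h <- setNames(st$haematocrits, paste0("H_", names(st$haematocrits)))
      p <- setNames(st$pressures_norm, paste0("P_", names(st$pressures_norm)))
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "point", branch = i, label = lab,
        param = sweep$param, value = val,
        t(q), t(h), t(p), check.names = FALSE)
    }
  }
  pts <- do.call(rbind, rows)
  fold_rows <- if (nrow(sweep$folds)) {
    data.frame(kind = "fold", branch = sweep$folds$branch,
               label = sweep$folds$label, param = sweep$param,
               value = sweep$folds$param)
  } else NULL
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# hemonet sweep: parameter %s over [%g, %g]", sweep$param,
            sweep$range[1], sweep$range[2]),
    sprintf("# solver tolerance %g, branch tolerance %g, seed %d",
            SOLVER_TOL, BRANCH_TOL, seed),
    "# columns: Q* are flows normalised by total inflow; P* normalised pressures"
  ), con)
  utils::write.csv(merge_all(pts, fold_rows), con, row.names = FALSE)
  invisible(path)
}

merge_all <- function(a, b) {
  if (is.null(b)) return(a)
  for (col in setdiff(names(a), names(b))) b[[col]] <- NA
  rbind(a, b[, names(a)])
}

#' Export a network as Graphviz DOT (for visual checks)
#'
#' @param network A [vascular_network()].
#' @return A character string in DOT syntax.
#' @export
as_dot <- function(network) {
  n <- network$nodes
  v <- network$vessels
  shape <- c(inlet = "invtriangle", outlet = "triangle", interior = "circle")
  nl <- sprintf("  %d [shape=%s, label=\"%d%s\"];", n$id, shape[n$kind], n$id,
                ifelse(is.finite(n$pressure),
                       sprintf("\\nP=%.3g", n$pressure), ""))
  el <- sprintf("  %d -- %d [label=\"L=%.3g D=%.3g\"];", v$from, v$to,
                v$length, v$diameter)
  paste(c("graph hemonet {", nl, el, "}"), collapse = "\n")
}
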