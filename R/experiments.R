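# Sweep drivers: bifurcation studies over vessel-length ratios, diameter,
# inlet haematocrit and inlet pressure, and equilibrium-count region maps.

# merge fold locations that coincide up to tol (same fold reached from
# different starting equilibria; refined folds agree to ~1e-8, while
# genuinely distinct folds can sit ~4e-4 apart)
merge_folds <- function(values, tol = 2e-5) {
  if (!length(values)) return(numeric(0))
  v <- sort(values)
  v[c(TRUE, diff(v) > tol)]
}

# trace branches in `param` from every equilibrium in `states`, collecting
# the merged fold set and the per-branch fold lists
sweep_branches <- function(network, param, range, states, labels = NULL,
                           ds_max = 0.01, max_points = 4000L,
                           rule = "pries1990", params = rheology_params()) {
  branches <- list()
  folds <- data.frame(param = numeric(0), branch = integer(0),
                      label = character(0))
  for (i in seq_along(states)) {
    br <- continue_branch(network, param, range, states[[i]], ds_max = ds_max,
                          max_points = max_points, rule = rule,
                          params = params)
    branches[[i]] <- br
    if (nrow(br$folds)) {
      folds <- rbind(folds, data.frame(
        param = br$folds$param, branch = i,
        label = if (is.null(labels)) NA_character_ else labels[i]))
    }
  }
  list(param = param, range = range, branches = branches,
       folds = folds, fold_values = merge_folds(folds$param),
       labels = labels)
}

#' Bifurcation sweep in the asymmetry ratio beta
#'
#' Enumerates the equilibria at the network's current `beta`, then traces
#' every equilibrium branch across `range` by pseudo-arclength continuation,
#' collecting fold bifurcations (merged across branches) and flow-state
#' labels. For the triangle network at default parameters this produces the
#' S-shaped structure with two folds near 0.96 and 1.04; for the
#' extended-triangle network, eight folds (two outer, six inner).
#'
#' @inheritParams signed_flows
#' @param range Beta interval to sweep.
#' @param n_starts,seed Multistart budget for the initial enumeration.
#' @param ds_max Maximum arclength step (unit-scaled parameter).
#' @return List with `branches`, `folds` (per-branch data frame),
#'   `fold_values` (merged), `equilibria` and `labels` at the anchor point.
#' @export
beta_sweep <- function(network, range = c(0.5, 1.5), n_starts = 300L,
                       seed = 0L, ds_max = 0.01, rule = "pries1990",
                       params = rheology_params()) {
  eq <- enumerate_equilibria(network, n_starts = n_starts, seed = seed,
                             rule = rule, params = params)
  labs <- apply(classify_flow_state(network, eq), 1, paste, collapse = ",")
  out <- sweep_branches(network, "beta", range, eq, labs, ds_max = ds_max,
                        rule = rule, params = params)
  out$equilibria <- eq
  out
}

#' Bifurcation sweep in the redundant-vessel length ratio alpha
#'
#' Traces equilibrium branches in `alpha` and tabulates the equilibrium
#' count on a grid (warm-started enumeration per grid point). Increasing
#' `alpha` raises the redundant-vessel resistance; equilibria are destroyed
#' pairwise at folds until a unique equilibrium remains.
#'
#' @inheritParams beta_sweep
#' @param range Alpha interval.
#' @param grid Alpha values at which to count equilibria.
#' @return List with `branches`, `folds`, `fold_values`, and `counts`
#'   (data frame `alpha`, `n`).
#' @export
alpha_sweep <- function(network, range = c(0.02, 2), grid = NULL,
                        n_starts = 300L, seed = 0L, ds_max = 0.01,
                        rule = "pries1990", params = rheology_params()) {
  if (is.null(grid)) grid <- seq(range[1], range[2], length.out = 9L)
  eq <- enumerate_equilibria(network, n_starts = n_starts, seed = seed,
                             rule = rule, params = params)
  labs <- apply(classify_flow_state(network, eq), 1, paste, collapse = ",")
  out <- sweep_branches(network, "alpha", range, eq, labs, ds_max = ds_max,
                        rule = rule, params = params)
  counts <- count_on_grid(network, "alpha", grid, seed = seed,
                          rule = rule, params = params)
  out$counts <- data.frame(alpha = grid, n = counts)
  out$equilibria <- eq
  out
}

# warm-started equilibrium counts along a parameter grid
count_on_grid <- function(network, param, grid, n_starts = 60L, seed = 0L,
                          rule = "pries1990", params = rheology_params()) {
  warm <- list()
  counts <- integer(length(grid))
  for (i in seq_along(grid)) {
    net_i <- set_network_parameter(network, param, grid[i])
    eq <- tryCatch(
      enumerate_equilibria(net_i, n_starts = n_starts, seed = seed + i,
                           extra_seeds = warm, structured = TRUE,
                           homotopy = FALSE, rule = rule, params = params),
      error = function(e) list())
    counts[i] <- length(eq)
    warm <- eq
  }
  counts
}

#' Equilibrium-count map over the (alpha, beta) plane
#'
#' Counts equilibria (warm-started multistart enumeration) at every cell
#' centre of an `alpha` x `beta` grid and reports the area of the
#' multiple-equilibria region per count level (cell count times cell area).
#'
#' @inheritParams beta_sweep
#' @param alphas,betas Grid values (cell centres).
#' @param n_starts Multistart budget per cell.
#' @return List of class `region_map`: `alphas`, `betas`, `counts` matrix
#'   (alpha rows, beta columns), `areas` (named by count level) and
#'   `multi_area` (total area with more than one equilibrium).
#' @export
region_map_alpha_beta <- function(network, alphas = seq(0.05, 1, length.out = 21),
                                  betas = seq(0.3, 2.5, length.out = 21),
                                  n_starts = 60L, seed = 0L,
                                  rule = "pries1990",
                                  params = rheology_params()) {
  counts <- matrix(0L, length(alphas), length(betas))
  for (ib in seq_along(betas)) {
    net_b <- set_network_parameter(network, "beta", betas[ib])
    warm <- list()
    for (ia in seq_along(alphas)) {
      net_ab <- set_network_parameter(net_b, "alpha", alphas[ia])
      eq <- tryCatch(
        enumerate_equilibria(net_ab, n_starts = n_starts,
                             seed = seed + ia * 1000L + ib,
                             extra_seeds = warm, homotopy = FALSE,
                             rule = rule, params = params),
        error = function(e) list())
      counts[ia, ib] <- length(eq)
      warm <- eq
    }
  }
  cell <- mean(diff(alphas)) * mean(diff(betas))
  lv <- sort(unique(as.vector(counts)))
  areas <- vapply(lv, function(l) sum(counts == l) * cell, numeric(1))
  structure(list(alphas = alphas, betas = betas, counts = counts,
                 areas = setNames(areas, lv),
                 multi_area = sum(counts > 1L) * cell),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region_map> %d x %d cells; multi-equilibria area %.4g\n",
              length(x$alphas), length(x$betas), x$multi_area))
  print(x$areas)
  invisible(x)
}

#' Bifurcation sweep in the inlet haematocrit
#'
#' Continues every equilibrium at the anchor inlet haematocrit down towards
#' zero, collecting the fold bifurcations at which equilibria are created as
#' the inlet haematocrit increases (critical haematocrit values). The
#' smallest fold is the critical value at which the network first admits
#' more than the base equilibrium. Fold labels are inherited from the
#' flow-state tuple of the branch's anchor equilibrium.
#'
#' @inheritParams beta_sweep
#' @param range Inlet-haematocrit interval (anchor at `range[2]`).
#' @param grid Optional haematocrit values at which to count equilibria.
#' @return List with `branches`, `folds` (with branch labels),
#'   `fold_values`, `critical` (smallest fold), `counts` (if `grid` given)
#'   and the anchor `equilibria`/`labels`.
#' @export
haematocrit_sweep <- function(network, range = c(0, 0.45), grid = NULL,
                              n_starts = 300L, seed = 0L, ds_max = 0.01,
                              rule = "pries1990",
                              params = rheology_params()) {
  net_a <- set_network_parameter(network, "h_in", range[2])
  eq <- enumerate_equilibria(net_a, n_starts = n_starts, seed = seed,
                             rule = rule, params = params)
  labs <- apply(classify_flow_state(net_a, eq), 1, paste, collapse = ",")
  out <- sweep_branches(net_a, "h_in", range, eq, labs, ds_max = ds_max,
                        rule = rule, params = params)
  out$critical <- if (length(out$fold_values)) min(out$fold_values) else NA_real_
  if (!is.null(grid)) {
    out$counts <- data.frame(h_in = grid,
                             n = count_on_grid(network, "h_in", grid,
                                               seed = seed, rule = rule,
                                               params = params))
  }
  out$equilibria <- eq
  out$labels <- labs
  out
}

#' Critical-haematocrit curves over vessel diameter
#'
#' For each diameter on a grid, runs the inlet-haematocrit fold analysis of
#' [haematocrit_sweep()] (warm-starting the anchor equilibria from the
#' previous diameter) and records the fold values with their branch labels.
#' The first critical value `h3(D)` is the smallest fold; the diameter at
#' which `h3` peaks is located by a parabolic refinement through the best
#' grid points.
#'
#' @inheritParams beta_sweep
#' @param Ds Diameter grid in micrometres (default 20 points, log-spaced
#'   over 10..200).
#' @param h_anchor Anchor inlet haematocrit (must exceed every critical
#'   value of interest; default 0.6).
#' @param trace_labels Restrict branch tracing to equilibria with these
#'   flow-state tuples (default: the all-positive and all-negative
#'   extremes, whose shared fold is the first critical value `h3`); `NULL`
#'   traces every branch.
#' @return List with `Ds`, `h3` (first critical per diameter), `folds`
#'   (long data frame `D`, `h`, `label`) and `D_h3_max` (refined argmax).
#' @export
region_map_D_H <- function(network, Ds = exp(seq(log(10), log(200),
                                                 length.out = 20L)),
                           h_anchor = 0.6, n_starts = 200L, seed = 0L,
                           ds_max = 0.01, trace_labels = c("+,+", "-,-"),
                           rule = "pries1990",
                           params = rheology_params()) {
  h3 <- rep(NA_real_, length(Ds))
  folds_all <- data.frame(D = numeric(0), h = numeric(0),
                          label = character(0))
  warm <- list()
  for (i in seq_along(Ds)) {
    net_D <- set_network_parameter(network, "D", Ds[i])
    net_D <- set_network_parameter(net_D, "h_in", h_anchor)
    eq <- tryCatch(
      enumerate_equilibria(net_D, n_starts = n_starts, seed = seed + i,
                           extra_seeds = warm, homotopy = FALSE,
                           rule = rule, params = params),
      error = function(e) list())
    if (!length(eq)) next
    warm <- eq
    labs <- apply(classify_flow_state(net_D, eq), 1, paste, collapse = ",")
    keep <- if (is.null(trace_labels)) seq_along(eq) else which(labs %in% trace_labels)
    if (!length(keep)) next
    sw <- sweep_branches(net_D, "h_in", c(0, h_anchor), eq[keep], labs[keep],
                         ds_max = ds_max, rule = rule, params = params)
    if (nrow(sw$folds)) {
      folds_all <- rbind(folds_all,
                         data.frame(D = Ds[i], h = sw$folds$param,
                                    label = sw$folds$label))
      h3[i] <- min(sw$folds$param)
    }
  }
  D_max <- refine_argmax(Ds, h3)
  list(Ds = Ds, h3 = h3, folds = folds_all, D_h3_max = D_max)
}

# parabolic refinement (in log D) of the maximum of a gridded curve
refine_argmax <- function(x, y) {
  ok <- which(is.finite(y))
  if (length(ok) < 3L) return(x[ok][which.max(y[ok])])
  i <- ok[which.max(y[ok])]
  if (i == 1L || i == length(x) || !all(is.finite(y[(i - 1L):(i + 1L)]))) {
    return(x[i])
  }
  lx <- log(x[(i - 1L):(i + 1L)])
  yy <- y[(i - 1L):(i + 1L)]
  den <- yy[1] - 2 * yy[2] + yy[3]
  if (abs(den) < 1e-14) return(x[i])
  exp(lx[2] - (lx[3] - lx[1]) / 2 * (yy[3] - yy[1]) / (2 * den))
}

#' Bifurcation sweep in one inlet pressure
#'
#' Traces equilibrium branches as one inlet pressure varies, with the other
#' boundary pressures fixed, under any registered splitting rule. Equilibria
#' emerge and vanish pairwise at folds, in sets distinguished by the flow in
#' one of the redundant vessels.
#'
#' @inheritParams beta_sweep
#' @param range Inlet-pressure interval for the varied inlet.
#' @param which_inlet `"p1"` or `"p2"`.
#' @return Same shape as [beta_sweep()].
#' @export
inlet_pressure_sweep <- function(network, range, which_inlet = "p1",
                                 n_starts = 300L, seed = 0L, ds_max = 0.01,
                                 rule = "pries1990",
                                 params = rheology_params()) {
  eq <- enumerate_equilibria(network, n_starts = n_starts, seed = seed,
                             rule = rule, params = params)
  labs <- apply(classify_flow_state(network, eq), 1, paste, collapse = ",")
  out <- sweep_branches(network, which_inlet, range, eq, labs,
                        ds_max = ds_max, rule = rule, params = params)
  out$equilibria <- eq
  out
}
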