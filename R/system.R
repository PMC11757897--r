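# Assembly and solution of the dimensionless steady-state network equations.
#
# Unknown vector layout (shared with the compiled kernel):
#   x = [pressures at interior nodes, haematocrits of non-inlet vessels]
# Inlet-vessel haematocrits and boundary pressures are parameters.

SOLVER_TOL <- 1e-11      # Newton acceptance, residual infinity norm
BRANCH_TOL <- 1e-10      # verification tolerance for continuation points

# residual closure over a compiled network; uses the C++ kernel for built-in
# rules and the R assembly for user-registered ones
resid_fun <- function(cn, mode = 0L, hfreeze = 0) {
  if (cn$rule_code >= 0L) {
    function(x) .residual_kernel(x, cn, mode, hfreeze)
  } else {
    function(x) residual_r(x, cn, mode, hfreeze)
  }
}

# homotopy residual h(x, lambda) = (1 - lambda) F(x) + lambda G(x)
homotopy_fun <- function(cn, hfreeze) {
  f <- resid_fun(cn, 0L)
  g <- resid_fun(cn, 1L, hfreeze)
  function(x, lambda) (1 - lambda) * f(x) + lambda * g(x)
}

# ---- pure-R residual assembly (general splitting rules) --------------------
residual_r <- function(x, cn, mode = 0L, hfreeze = 0) {
  n_int <- length(cn$int0)
  m <- length(cn$from0)
  P <- cn$p_bound
  sel_p <- cn$p_idx >= 0
  P[sel_p] <- x[cn$p_idx[sel_p] + 1L]
  H <- cn$hfix
  sel_h <- cn$h_idx >= 0
  H[sel_h] <- x[n_int + cn$h_idx[sel_h] + 1L]
  Hv <- if (mode == 1L) rep(hfreeze, m) else pmin(pmax(H, -0.5), 0.995)
  mu <- cn$mu_p * (1 + (cn$mu45v - 1) *
                     ((1 - Hv)^cn$Cv - 1) / cn$denomv * cn$wallv) * cn$wallv
  Q <- (P[cn$from0 + 1L] - P[cn$to0 + 1L]) / (cn$rpre * mu)
  Qin <- sum(Q[cn$h_idx < 0])
  floor_q <- max(1e-8 * max(abs(Q)), EPS_Q)
  scale <- if (Qin > floor_q) Qin else max(max(abs(Q)), EPS_Q)
  Q <- Q / scale

  int_col <- rep(-1L, length(cn$kind))
  int_col[cn$int0 + 1L] <- seq_len(n_int)

  res <- numeric(cn$n_unknown)
  for (j in seq_len(n_int)) {
    res[j] <- sum(cn$sgn[, j] * Q[cn$incid[, j] + 1L])
  }
  for (e in seq_len(m)) {
    if (cn$h_idx[e] < 0) next
    row <- n_int + cn$h_idx[e] + 1L
    if (mode == 1L) { res[row] <- H[e] - hfreeze; next }
    u <- if (Q[e] >= 0) cn$from0[e] else cn$to0[e]
    j <- int_col[u + 1L]
    if (j < 0) {
      w <- if (u == cn$from0[e]) cn$to0[e] else cn$from0[e]
      j <- int_col[w + 1L]
      if (j < 0) { res[row] <- H[e]; next }
      ek <- cn$incid[, j] + 1L
      res[row] <- sum(cn$sgn[, j] * Q[ek] * H[ek])
      next
    }
    ek <- cn$incid[, j] + 1L
    f <- cn$sgn[, j] * Q[ek]                      # positive = into node u
    parent <- ek[f > EPS_Q]
    outs <- ek[f < -EPS_Q]
    if (length(parent) == 1L && length(outs) == 2L &&
        abs(Q[parent]) > EPS_Q) {
      sib <- outs[outs != e]
      qp <- abs(Q[parent]); qd <- abs(Q[e])
      r <- min(max(qd / qp, 0), 1)
      Hp <- min(max(H[parent], 0), 0.9999)   # clamp out-of-range iterates
      p <- cn$psi_fn(r, Hp, cn$diam[parent], cn$diam[e], cn$diam[sib])
      res[row] <- p * qp * H[parent] - qd * H[e]
    } else {
      res[row] <- sum(cn$sgn[, j] * Q[ek] * H[ek])
    }
  }
  res
}

# ---- exported surface ------------------------------------------------------

#' Signed normalised flows of a network state
#'
#' Computes the signed volumetric flow in every vessel from the pressure
#' differences and haematocrit-dependent resistances of a state, then divides
#' by the total inflow `Q_in` (the sum over inlet vessels), so `|Q|` is at
#' most 1 at an equilibrium. Flow is positive along the vessel's reference
#' orientation (inlet vessels point into the network, outlet vessels toward
#' the outlet).
#'
#' @param network A [vascular_network()].
#' @param state A state as returned by the solvers, or a bare unknown vector.
#' @param rule Splitting rule name (resistances do not depend on it, but the
#'   compiled form carries it).
#' @param params [rheology_params()].
#' @return Named vector of normalised flows (one per vessel, named
#'   `"from->to"`), with the unnormalised total inflow in attribute `"Qin"`.
#' @export
signed_flows <- function(network, state, rule = "pries1990",
                         params = rheology_params()) {
  cn <- compile_network(network, rule, params)
  x <- state_x(state)
  Q <- .flows_kernel(x, cn, 0L, 0)
  Qin <- attr(Q, "Qin")
  if (Qin <= 0) stop("total inflow Q_in <= 0: state outside the valid flow region",
                     call. = FALSE)
  out <- as.numeric(Q) / Qin
  names(out) <- vessel_labels(network, cn)
  attr(out, "Qin") <- Qin
  out
}

#' Assemble the steady-state residual of a network state
#'
#' One residual entry per interior node (flow conservation) and one per
#' non-inlet vessel (RBC conservation at a convergence, or the splitting-rule
#' equation at a bifurcation, chosen from the signs of the current flows).
#' All entries are dimensionless; the residual vanishes exactly at an
#' equilibrium.
#'
#' @inheritParams signed_flows
#' @return Named residual vector of length
#'   `#interior nodes + #non-inlet vessels`.
#' @export
assemble_residual <- function(network, state, rule = "pries1990",
                              params = rheology_params()) {
  cn <- compile_network(network, rule, params)
  r <- resid_fun(cn)(state_x(state))
  names(r) <- residual_labels(network, cn)
  r
}

#' Finite-difference Jacobian of the residual
#'
#' Central differences with steps scaled to the magnitude of each unknown.
#' Warns when the differencing stencil straddles a junction-type switch or a
#' splitting-rule threshold (the residual is only piecewise smooth there).
#'
#' @inheritParams signed_flows
#' @return Square matrix of partial derivatives of the residual with respect
#'   to the unknowns.
#' @export
jacobian <- function(network, state, rule = "pries1990",
                     params = rheology_params()) {
  cn <- compile_network(network, rule, params)
  x <- state_x(state)
  f <- resid_fun(cn)
  J <- jac_fd(f, x)
  if (!identical(junction_signature(cn, x, -1), junction_signature(cn, x, +1))) {
    warning("finite-difference stencil straddles a junction-type switch or splitting-rule kink",
            call. = FALSE)
  }
  J
}

# flow-sign / psi-zone signature used to flag non-smooth differencing
junction_signature <- function(cn, x, side) {
  h <- fd_steps(x)
  xs <- x + side * h
  Q <- .flows_kernel(xs, cn, 0L, 0)
  Qin <- attr(Q, "Qin")
  s <- if (abs(Qin) > EPS_Q) as.numeric(Q) / Qin else as.numeric(Q)
  sgn <- ifelse(s > EPS_Q, 1L, ifelse(s < -EPS_Q, -1L, 0L))
  zone <- integer(length(s))
  for (e in seq_along(s)) {
    u <- if (s[e] >= 0) cn$from0[e] else cn$to0[e]
    j <- which(cn$int0 == u)
    if (length(j) != 1L) next
    ek <- cn$incid[, j] + 1L
    f <- cn$sgn[, j] * s[ek]
    parent <- ek[f > EPS_Q]
    if (length(parent) == 1L && abs(s[parent]) > EPS_Q) {
      r <- abs(s[e]) / abs(s[parent])
      x0 <- cn$x0v[parent]
      zone[e] <- if (r < x0) 1L else if (r > 1 - x0) 3L else 2L
    }
  }
  list(sgn = sgn, zone = zone)
}

# distance of the closest bifurcation flow ratio to a splitting-rule
# threshold (X0 or 1 - X0); small values mean the state sits at a psi kink
kink_distance <- function(cn, x) {
  Q <- .flows_kernel(x, cn, 0L, 0)
  Qin <- attr(Q, "Qin")
  q <- if (abs(Qin) > EPS_Q) as.numeric(Q) / Qin else as.numeric(Q)
  dmin <- Inf
  for (j in seq_along(cn$int0)) {
    ek <- cn$incid[, j] + 1L
    f <- cn$sgn[, j] * q[ek]
    parent <- ek[f > EPS_Q]
    outs <- ek[f < -EPS_Q]
    if (length(parent) == 1L && length(outs) == 2L) {
      x0 <- cn$x0v[parent]
      for (e in outs) {
        r <- abs(q[e]) / abs(q[parent])
        dmin <- min(dmin, abs(r - x0), abs(r - (1 - x0)))
      }
    }
  }
  dmin
}

fd_steps <- function(x) {
  .Machine$double.eps^(1 / 3) * pmax(abs(x), 0.1)
}

# central-difference Jacobian of f at x
jac_fd <- function(f, x) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  h <- fd_steps(x)
  for (i in seq_len(n)) {
    xp <- x; xp[i] <- x[i] + h[i]
    xm <- x; xm[i] <- x[i] - h[i]
    J[, i] <- (f(xp) - f(xm)) / (2 * h[i])
  }
  J
}

# ---- linear solves ---------------------------------------------------------

# interior pressures for a fixed haematocrit field (linear Kirchhoff solve);
# hfreeze may be a scalar or a per-vessel vector
solve_frozen_pressures <- function(cn, hfreeze) {
  Hv <- pmin(pmax(hfreeze, 0), 0.995)
  mu <- cn$mu_p * (1 + (cn$mu45v - 1) *
                     ((1 - Hv)^cn$Cv - 1) / cn$denomv * cn$wallv) * cn$wallv
  g <- 1 / (cn$rpre * mu)  # conductance per vessel
  n_int <- length(cn$int0)
  A <- matrix(0, n_int, n_int)
  b <- numeric(n_int)
  int_col <- rep(-1L, length(cn$kind))
  int_col[cn$int0 + 1L] <- seq_len(n_int)
  for (j in seq_len(n_int)) {
    for (k in 1:3) {
      e <- cn$incid[k, j] + 1L
      other <- if (cn$sgn[k, j] > 0) cn$from0[e] else cn$to0[e]
      A[j, j] <- A[j, j] + g[e]
      jo <- int_col[other + 1L]
      if (jo > 0) A[j, jo] <- A[j, jo] - g[e]
      else b[j] <- b[j] + g[e] * cn$p_bound[other + 1L]
    }
  }
  tryCatch(solve(A, b),
           error = function(e) stop("singular conductance system: network disconnected or ill-posed",
                                    call. = FALSE))
}

#' Zero-haematocrit (linear) equilibrium
#'
#' With no red cells anywhere the viscosity is constant per vessel and the
#' network equations reduce to a linear conductance system with a unique
#' solution. This state is the natural starting point for continuation in the
#' inlet haematocrit and a building block of the homotopy start.
#'
#' @inheritParams signed_flows
#' @return A `network_state` with `H = 0` in every non-inlet vessel.
#' @export
solve_zero_haematocrit <- function(network, rule = "pries1990",
                                   params = rheology_params()) {
  cn <- compile_network(network, rule, params)
  p <- solve_frozen_pressures(cn, 0)
  make_state(network, cn, c(p, numeric(cn$n_unknown - length(p))))
}

# ---- Newton ----------------------------------------------------------------

# damped Newton on a residual closure; haematocrit entries are clipped to
# [0, 0.999] during iteration (final acceptance is on the unclipped residual)
newton_core <- function(f, x0, n_int, tol = SOLVER_TOL, maxit = 50L) {
  n <- length(x0)
  hcols <- if (n > n_int) (n_int + 1L):n else integer(0)
  clip <- function(x) {
    x[hcols] <- pmin(pmax(x[hcols], 0), 0.999)
    x
  }
  x <- x0
  if (any(!is.finite(x))) {
    return(list(converged = FALSE, x = x0, norm = Inf, iterations = 0L))
  }
  fx <- f(x)
  if (any(!is.finite(fx))) {
    return(list(converged = FALSE, x = x0, norm = Inf, iterations = 0L))
  }
  nrm <- max(abs(fx))
  for (it in seq_len(maxit)) {
    if (nrm < tol) {
      return(list(converged = TRUE, x = x, norm = nrm, iterations = it - 1L))
    }
    J <- jac_fd(f, x)
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      step <- tryCatch(qr.solve(J + diag(1e-10, n), -fx),
                       error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
    }
    t <- 1
    improved <- FALSE
    for (half in 0:20) {
      xn <- clip(x + t * step)
      fn <- f(xn)
      if (all(is.finite(fn)) && max(abs(fn)) < nrm) {
        x <- xn; fx <- fn; nrm <- max(abs(fn)); improved <- TRUE
        break
      }
      t <- t / 2
    }
    if (!improved) break
  }
  list(converged = nrm < tol, x = x, norm = nrm, iterations = maxit)
}

#' Damped Newton solve of the network equations
#'
#' Newton iteration with backtracking line search on the full nonlinear
#' system, re-assembling the residual (and hence the junction typing) at
#' every step. Haematocrit iterates are clipped to `[0, 0.999]` during the
#' iteration; acceptance requires the unclipped residual below `tol`.
#' Non-convergence is reported as a result, not an error.
#'
#' @inheritParams signed_flows
#' @param initial A state or bare unknown vector to start from.
#' @param tol Residual infinity-norm for acceptance (default `1e-11`).
#' @param maxit Maximum Newton iterations (default 50).
#' @return A list with `converged`, `state` (a `network_state`, only if
#'   converged), `residual_norm` and `iterations`.
#' @export
newton_solve <- function(network, initial, tol = SOLVER_TOL, maxit = 50L,
                         rule = "pries1990", params = rheology_params()) {
  cn <- compile_network(network, rule, params)
  res <- newton_core(resid_fun(cn), state_x(initial), length(cn$int0),
                     tol = tol, maxit = maxit)
  out <- list(converged = res$converged, residual_norm = res$norm,
              iterations = res$iterations)
  if (res$converged) out$state <- make_state(network, cn, res$x)
  out
}

# ---- state helpers ---------------------------------------------------------

vessel_labels <- function(network, cn) {
  ids <- network$nodes$id
  paste0(ids[cn$from0 + 1L], "->", ids[cn$to0 + 1L])
}

residual_labels <- function(network, cn) {
  ids <- network$nodes$id
  c(paste0("node_", ids[cn$int0 + 1L]),
    paste0("H_", vessel_labels(network, cn)[cn$h_idx >= 0]))
}

#' @rdname newton_solve
#' @param x Bare unknown vector.
#' @export
state_x <- function(x) {
  if (inherits(x, "network_state")) x$x else as.numeric(x)
}

# wrap an unknown vector as a reportable state: raw + normalised pressures,
# haematocrits, normalised signed flows
make_state <- function(network, cn, x) {
  n_int <- length(cn$int0)
  p <- x[seq_len(n_int)]
  names(p) <- network$nodes$id[cn$int0 + 1L]
  h <- x[n_int + seq_len(cn$n_unknown - n_int)]
  names(h) <- vessel_labels(network, cn)[cn$h_idx >= 0]
  Q <- .flows_kernel(x, cn, 0L, 0)
  Qin <- attr(Q, "Qin")
  qn <- if (abs(Qin) > EPS_Q) as.numeric(Q) / Qin else as.numeric(Q)
  names(qn) <- vessel_labels(network, cn)
  ref <- min(cn$p_bound[cn$kind == 1L])
  span <- sum(cn$p_bound[cn$kind == 0L] - ref)
  structure(list(x = x, pressures = p,
                 pressures_norm = (p - ref) / span,
                 haematocrits = h, qhat = qn, Qin = Qin),
            class = "network_state")
}

#' @export
print.network_state <- function(x, ...) {
  cat("<network_state>\n  P:", paste(sprintf("%s=%.4g", names(x$pressures), x$pressures),
                                     collapse = " "), "\n")
  cat("  H:", paste(sprintf("%s=%.4g", names(x$haematocrits), x$haematocrits),
                    collapse = " "), "\n")
  cat("  Qhat:", paste(sprintf("%s=%.4g", names(x$qhat), x$qhat),
                       collapse = " "), "\n")
  invisible(x)
}

# dedup metric: infinity norm over normalised pressures and haematocrits
state_distance <- function(a, b) {
  max(abs(c(a$pressures_norm - b$pressures_norm,
            a$haematocrits - b$haematocrits)))
}
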