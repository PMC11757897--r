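# Homotopy and pseudo-arclength continuation.
#
# An initial equilibrium is found by deforming a starting system G (frozen
# viscosity, haematocrit pinned at the inlet value) into the full network
# equations F along h = (1-lambda) F + lambda G, tracking the solution from
# lambda = 1 to 0. Equilibrium branches in a network parameter are traced by
# a secant-tangent predictor / orthogonal Newton corrector, which passes
# through fold bifurcations; folds are located from sign changes of the
# tangent's parameter component and refined on a bordered (Moore) system.

# plain (unclipped) Newton used by the corrector and the fold refiner
newton_plain <- function(f, x0, tol = SOLVER_TOL, maxit = 12L) {
  x <- x0
  fx <- f(x)
  if (any(!is.finite(fx))) return(list(converged = FALSE, x = x0, norm = Inf))
  nrm <- max(abs(fx))
  for (it in seq_len(maxit)) {
    if (nrm < tol) return(list(converged = TRUE, x = x, norm = nrm))
    J <- jac_fd(f, x)
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      return(list(converged = FALSE, x = x, norm = nrm))
    }
    t <- 1
    repeat {
      xn <- x + t * step
      fn <- f(xn)
      if (all(is.finite(fn)) && max(abs(fn)) < nrm) break
      t <- t / 2
      if (t < 1e-6) return(list(converged = FALSE, x = x, norm = nrm))
    }
    x <- xn; fx <- fn; nrm <- max(abs(fn))
  }
  list(converged = nrm < tol, x = x, norm = nrm)
}

# fast parameter update of a compiled network (vectors only; topology fixed)
update_compiled <- function(cn, param, value, meta) {
  switch(param,
    beta = { cn$len[meta$beta_rows] <- value
             cn$rpre <- 128 * cn$len / (pi * cn$diam^4) },
    alpha = { cn$len[meta$alpha_rows] <- value
              cn$rpre <- 128 * cn$len / (pi * cn$diam^4) },
    h_in = { cn$hfix[cn$hfix >= 0] <- value },
    D = { D <- rep(value, length(cn$diam))
          cn$diam <- D
          Cv <- coeff_C(D)
          cn$mu45v <- mu_45(D); cn$Cv <- Cv
          cn$wallv <- (D / (D - 1.1))^2
          cn$denomv <- 0.55^Cv - 1
          cn$rpre <- 128 * cn$len / (pi * D^4)
          cn$x0v <- 0.4 / D; cn$logD <- log(D) },
    p1 = { cn$p_bound[which(cn$kind == 0L)[1L]] <- value },
    p2 = { cn$p_bound[which(cn$kind == 0L)[2L]] <- value },
    stop(sprintf("unknown sweep parameter '%s'", param), call. = FALSE)
  )
  cn
}

# residual closure F(x, lam) for a swept parameter
param_fun <- function(network, param, rule = "pries1990",
                      params = rheology_params()) {
  cn0 <- compile_network(network, rule, params)
  meta <- network$meta
  use_cpp <- cn0$rule_code >= 0L
  function(x, lam) {
    cn <- update_compiled(cn0, param, lam, meta)
    if (use_cpp) .residual_kernel(x, cn, 0L, 0) else residual_r(x, cn, 0L, 0)
  }
}

# current value of a sweep parameter of a fixture network
network_parameter <- function(network, param) {
  sp <- network$meta$spec
  switch(param,
    beta = sp$beta, alpha = sp$alpha, D = sp$D,
    h_in = {
      h <- network$vessels$inlet_haematocrit
      h[is.finite(h)][1L]
    },
    p1 = network$nodes$pressure[which(network$nodes$kind == "inlet")[1L]],
    p2 = network$nodes$pressure[which(network$nodes$kind == "inlet")[2L]],
    stop(sprintf("unknown sweep parameter '%s'", param), call. = FALSE)
  )
}

# ---- generic arclength tracer ---------------------------------------------
# fun(x, lam_unit) with lam_unit in [0, 1]; returns matrix of (x, lam_unit)
# rows plus a status string
trace_path <- function(fun, x0, lam0, dir = +1,
                       ds0 = 5e-3, ds_min = 1e-9, ds_max = 0.03,
                       max_points = 3000L, tol = SOLVER_TOL) {
  n <- length(x0)
  Fext <- function(u) fun(u[seq_len(n)], u[n + 1L])
  u <- c(x0, lam0)

  J <- jac_fd(Fext, u)
  tv <- svd(J, nu = 0, nv = n + 1L)$v[, n + 1L]
  if (abs(tv[n + 1L]) > 1e-12) tv <- tv * sign(tv[n + 1L]) * sign(dir)

  pts <- matrix(NA_real_, max_points, n + 1L)
  pts[1L, ] <- u
  np <- 1L
  ds <- ds0
  status <- "max_points"
  while (np < max_points) {
    pred <- u + ds * tv
    corr <- newton_plain(function(w) c(Fext(w), sum((w - u) * tv) - ds),
                         pred, tol = tol, maxit = 10L)
    if (!corr$converged) {
      ds <- ds / 2
      if (ds < ds_min) { status <- "step_underflow"; break }
      next
    }
    un <- corr$x
    if (un[n + 1L] < 0 || un[n + 1L] > 1) {
      # land exactly on the range boundary
      lb <- if (un[n + 1L] < 0) 0 else 1
      end <- newton_plain(function(w) Fext(c(w, lb)), u[seq_len(n)],
                          tol = tol, maxit = 20L)
      if (end$converged) {
        np <- np + 1L
        pts[np, ] <- c(end$x, lb)
      }
      status <- "range_boundary"
      break
    }
    tv <- (un - u) / sqrt(sum((un - u)^2))
    u <- un
    np <- np + 1L
    pts[np, ] <- u
    ds <- min(ds * 1.4, ds_max)
  }
  list(points = pts[seq_len(np), , drop = FALSE], status = status)
}

# fold refinement: Newton on the bordered system
#   [ F(x, lam); J_x(x, lam) v; |v|^2 - 1 ] = 0
# seeded from the bracketing branch points; returns lam at the fold (unit
# scale) and the fold state, or NULL on failure
refine_fold <- function(fun, u_lo, u_hi) {
  n <- length(u_lo) - 1L
  u0 <- (u_lo + u_hi) / 2
  x0 <- u0[seq_len(n)]; l0 <- u0[n + 1L]
  Fx <- function(x, lam) fun(x, lam)
  # null-vector seed: x-direction of the secant between the bracket points
  v0 <- (u_hi - u_lo)[seq_len(n)]
  nv <- sqrt(sum(v0^2))
  if (nv < 1e-14) return(NULL)
  v0 <- v0 / nv
  dirder <- function(x, lam, v) {
    h <- 1e-6
    (Fx(x + h * v, lam) - Fx(x - h * v, lam)) / (2 * h)
  }
  G <- function(y) {
    x <- y[seq_len(n)]; lam <- y[n + 1L]; v <- y[n + 1L + seq_len(n)]
    c(Fx(x, lam), dirder(x, lam, v), sum(v^2) - 1)
  }
  res <- newton_plain(G, c(x0, l0, v0), tol = 1e-9, maxit = 25L)
  if (!res$converged) return(NULL)
  lam <- res$x[n + 1L]
  lo <- min(u_lo[n + 1L], u_hi[n + 1L]); hi <- max(u_lo[n + 1L], u_hi[n + 1L])
  pad <- 10 * (hi - lo) + 1e-5
  if (lam < lo - pad || lam > hi + pad) return(NULL)  # wandered off
  list(x = res$x[seq_len(n)], lam = lam, v = res$x[n + 1L + seq_len(n)])
}

# ---- exported operations ---------------------------------------------------

#' Initial equilibrium by homotopy continuation
#'
#' Deforms a starting system with a known unique solution (viscosity frozen
#' at the inlet haematocrit; every vessel haematocrit pinned to it) into the
#' full network equations along the convex homotopy, tracking the solution
#' path by pseudo-arclength from the frozen system to the full one, then
#' polishing with Newton.
#'
#' @inheritParams signed_flows
#' @return A `network_state` equilibrium of the full equations.
#' @export
homotopy_initial_solve <- function(network, rule = "pries1990",
                                   params = rheology_params()) {
  cn <- compile_network(network, rule, params)
  h <- cn$hfix[cn$hfix >= 0]
  hfreeze <- if (length(h)) mean(h) else 0
  n_int <- length(cn$int0)
  x1 <- c(solve_frozen_pressures(cn, hfreeze),
          rep(hfreeze, cn$n_unknown - n_int))
  hf <- homotopy_fun(cn, hfreeze)
  if (hfreeze == 0) {
    res <- newton_core(resid_fun(cn), x1, n_int)
    if (!res$converged) stop("homotopy solve failed at zero haematocrit",
                             call. = FALSE)
    return(make_state(network, cn, res$x))
  }
  tr <- trace_path(hf, x1, 1, dir = -1)
  endl <- tr$points[nrow(tr$points), length(x1) + 1L]
  if (endl > 1e-8) {
    stop(sprintf("homotopy tracking stalled at lambda = %.3g", endl),
         call. = FALSE)
  }
  res <- newton_core(resid_fun(cn), tr$points[nrow(tr$points), seq_along(x1)],
                     n_int)
  if (!res$converged) stop("homotopy endpoint failed Newton polish",
                           call. = FALSE)
  x <- canonical_zero_flow(cn, res$x)
  if (!identical(x, res$x)) {
    res2 <- newton_core(resid_fun(cn), x, n_int)
    if (res2$converged) res$x <- canonical_zero_flow(cn, res2$x)
  }
  make_state(network, cn, res$x)
}

#' Trace an equilibrium branch in a network parameter
#'
#' Pseudo-arclength predictor-corrector continuation of the steady-state
#' equations in one of the fixture sweep parameters (`"beta"`, `"alpha"`,
#' `"h_in"`, `"D"`, `"p1"`, `"p2"`). The trace passes through folds (turning
#' back in the parameter); it ends at a range boundary, after `max_points`,
#' or when the step underflows. Every recorded point is a verified
#' equilibrium. Folds are detected from sign changes of the parameter
#' component of the secant tangent and refined on a bordered system whose
#' solution has a singular state-space Jacobian.
#'
#' @inheritParams signed_flows
#' @param param Sweep parameter name.
#' @param range Numeric length-2 parameter interval.
#' @param start A `network_state` equilibrium at `start_value`.
#' @param start_value Parameter value of `start` (default: the network's
#'   current value).
#' @param directions Trace towards larger values (`+1`), smaller (`-1`) or
#'   both (default).
#' @param ds_max Maximum arclength step on the unit-scaled parameter range.
#' @param max_points Cap on recorded points per direction.
#' @return An object of class `branch`: list with `param`, `points` (one row
#'   per branch point: unknowns then the parameter value), `folds` (data
#'   frame with the refined fold parameter values and states) and `status`.
#' @export
continue_branch <- function(network, param, range, start, start_value = NULL,
                            directions = c(-1, 1), ds_max = 0.03,
                            max_points = 3000L, rule = "pries1990",
                            params = rheology_params()) {
  stopifnot(length(range) == 2L, range[1] < range[2])
  if (is.null(start_value)) start_value <- network_parameter(network, param)
  span <- range[2] - range[1]
  l2u <- function(l) (l - range[1]) / span
  fun <- param_fun(network, param, rule, params)
  funu <- function(x, lu) fun(x, range[1] + lu * span)
  x0 <- state_x(start)
  n <- length(x0)

  segs <- list()
  for (d in directions) {
    tr <- trace_path(funu, x0, l2u(start_value), dir = d,
                     ds_max = ds_max, max_points = max_points)
    segs[[length(segs) + 1L]] <- tr
  }
  pts <- if (length(segs) == 2L) {
    rbind(segs[[1]]$points[rev(seq_len(nrow(segs[[1]]$points))), , drop = FALSE],
          segs[[2]]$points[-1L, , drop = FALSE])
  } else segs[[1]]$points
  pts[, n + 1L] <- range[1] + pts[, n + 1L] * span

  br <- structure(list(param = param, range = range, points = pts,
                       n_unknown = n, fun = fun, network = network,
                       rule = rule, params = params,
                       status = vapply(segs, `[[`, "", "status")),
                  class = "branch")
  br$folds <- detect_folds(br)

  # border-collision folds: a trace that stalls (step underflow) on a psi
  # kink has reached a fold located at the threshold itself, where the
  # residual is only piecewise smooth and the corrector cannot turn
  ends <- if (length(segs) == 2L) c(1L, nrow(pts)) else nrow(pts)
  for (k in seq_along(segs)) {
    if (segs[[k]]$status != "step_underflow") next
    ui <- ends[k]
    xk <- pts[ui, seq_len(n)]
    lamk <- pts[ui, n + 1L]
    netk <- set_network_parameter(network, param, lamk)
    cnk <- compile_network(netk, rule, params)
    if (kink_distance(cnk, xk) < 1e-3) {
      st <- attr(br$folds, "states")
      br$folds <- rbind(br$folds,
                        data.frame(param = lamk, index = ui))
      attr(br$folds, "states") <- c(st, list(xk))
    }
  }
  br
}

#' @export
print.branch <- function(x, ...) {
  cat(sprintf("<branch> parameter '%s' over [%g, %g]: %d points, %d fold(s)\n",
              x$param, x$range[1], x$range[2], nrow(x$points),
              nrow(x$folds)))
  invisible(x)
}

#' Locate fold bifurcations on a branch
#'
#' Scans consecutive branch points for a sign change in the parameter
#' increment (the parameter component of the secant tangent) and refines each
#' candidate with Newton on the bordered fold system. Fold states satisfy a
#' near-singular state-Jacobian check by construction.
#'
#' @param branch A `branch` from [continue_branch()].
#' @return Data frame with columns `param` (fold location) and `index`
#'   (bracketing point), plus the fold states in attribute `"states"`.
#' @export
detect_folds <- function(branch) {
  pts <- branch$points
  n <- branch$n_unknown
  empty <- data.frame(param = numeric(0), index = integer(0))
  if (nrow(pts) < 3L) { attr(empty, "states") <- list(); return(empty) }
  dl <- diff(pts[, n + 1L])
  sgn <- sign(dl)
  sgn[sgn == 0] <- NA
  idx <- which(!is.na(sgn[-1]) & !is.na(sgn[-length(sgn)]) &
                 sgn[-1] * sgn[-length(sgn)] < 0)
  span <- branch$range[2] - branch$range[1]
  funu <- function(x, lu) branch$fun(x, branch$range[1] + lu * span)
  Fext <- function(u) funu(u[seq_len(n)], u[n + 1L])
  out <- data.frame(param = numeric(0), index = integer(0))
  states <- list()
  for (i in idx) {
    u0 <- pts[i, ]; u2 <- pts[i + 2L, ]
    u0[n + 1L] <- (u0[n + 1L] - branch$range[1]) / span
    u2[n + 1L] <- (u2[n + 1L] - branch$range[1]) / span
    maximum <- pts[i + 1L, n + 1L] > pts[i, n + 1L]
    loc <- brent_fold(Fext, u0, u2, maximum)
    if (is.null(loc)) next
    lam <- loc$u[n + 1L]
    xf <- loc$u[seq_len(n)]
    # polish on the bordered system (machine-accurate fold)
    rf <- refine_fold(funu, loc$u - 1e-4 * loc$t, loc$u + 1e-4 * loc$t)
    if (!is.null(rf) && abs(rf$lam - lam) < 1e-5) {
      lam <- rf$lam
      xf <- rf$x
    }
    out <- rbind(out, data.frame(param = branch$range[1] + lam * span,
                                 index = i + 1L))
    states[[length(states) + 1L]] <- xf
  }
  attr(out, "states") <- states
  out
}

# locate the parameter extremum between two branch points by Brent search
# along the chord: each evaluation projects onto the hyperplane orthogonal
# to the chord with a Newton corrector
brent_fold <- function(Fext, u0, u2, maximum) {
  n <- length(u0) - 1L
  chord <- u2 - u0
  S <- sqrt(sum(chord^2))
  if (S < 1e-14) return(NULL)
  t0 <- chord / S
  last <- NULL
  g <- function(ds) {
    pred <- u0 + ds * t0
    corr <- newton_plain(function(w) c(Fext(w), sum((w - u0) * t0) - ds),
                         pred, tol = SOLVER_TOL, maxit = 12L)
    if (!corr$converged) return(NA_real_)
    last <<- corr$x
    corr$x[n + 1L]
  }
  opt <- tryCatch(
    stats::optimize(function(ds) {
      v <- g(ds)
      if (is.na(v)) (if (maximum) -1 else 1) * 1e6 else v
    }, c(0, S), maximum = maximum, tol = 1e-10),
    error = function(e) NULL)
  if (is.null(opt)) return(NULL)
  ds_star <- if (maximum) opt$maximum else opt$minimum
  val <- g(ds_star)
  if (is.na(val) || is.null(last)) return(NULL)
  # local tangent (state-space direction of the curve at the fold)
  tx <- t0
  tx[n + 1L] <- 0
  nt <- sqrt(sum(tx^2))
  if (nt > 1e-14) tx <- tx / nt
  list(u = last, t = tx)
}

#' All equilibria of a network at one parameter point
#'
#' Collects equilibria from (a) the homotopy start, (b) Newton from the
#' frozen-viscosity and zero-haematocrit base states, (c) one structured
#' seed per flow-state pattern of the redundant vessels (pressures biased to
#' drive the corresponding flow directions, haematocrit zeroed in
#' "intermediate" vessels), and (d) seeded low-discrepancy (Latin hypercube)
#' multistart Newton. Candidates are accepted when the residual is below
#' `1e-11`, the total inflow is positive with all inlet vessels feeding the
#' network, normalised flows are bounded by 1 and haematocrits are
#' non-negative (values above 1 are flagged with a warning); duplicates are
#' merged at state distance `1e-6`.
#'
#' @inheritParams signed_flows
#' @param n_starts Number of random multistart seeds (default 300).
#' @param seed RNG seed for the multistart sample (default 0).
#' @param extra_seeds Optional list of additional starting vectors/states
#'   (e.g. warm starts from a neighbouring parameter point).
#' @param structured Use the flow-state-pattern seeds (default TRUE).
#' @param homotopy Include the homotopy start (default TRUE).
#' @return List of `network_state` equilibria (possibly of length 1).
#' @export
enumerate_equilibria <- function(network, n_starts = 300L, seed = 0L,
                                 extra_seeds = list(), structured = TRUE,
                                 homotopy = TRUE, rule = "pries1990",
                                 params = rheology_params()) {
  cn <- compile_network(network, rule, params)
  n_int <- length(cn$int0)
  n <- cn$n_unknown
  f <- resid_fun(cn)
  h_in <- cn$hfix[cn$hfix >= 0][1L]
  if (!is.finite(h_in)) h_in <- 0

  seeds <- lapply(extra_seeds, state_x)
  base <- tryCatch(c(solve_frozen_pressures(cn, h_in), rep(h_in, n - n_int)),
                   error = function(e) NULL)
  if (!is.null(base)) seeds <- c(seeds, list(base))
  seeds <- c(seeds, list(c(solve_frozen_pressures(cn, 0), rep(0, n - n_int))))
  if (homotopy) {
    hs <- tryCatch(homotopy_initial_solve(network, rule, params),
                   error = function(e) NULL)
    if (!is.null(hs)) seeds <- c(seeds, list(hs$x))
  }

  if (structured && !is.null(base)) {
    red <- tryCatch(find_redundant_vessels(network), error = function(e) integer(0))
    if (length(red) > 0 && length(red) <= 4) {
      span <- diff(range(cn$p_bound[cn$kind != 2L]))
      delta <- 0.05 * span
      pats <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), length(red))))
      for (k in seq_len(nrow(pats))) {
        x <- base
        for (j in seq_along(red)) {
          e <- red[j]           # row index; interior-interior, order preserved
          hrow <- n_int + cn$h_idx[e] + 1L
          s <- pats[k, j]
          x[hrow] <- if (s == 0L) 0 else h_in
          if (s != 0L) {
            pf <- cn$p_idx[cn$from0[e] + 1L]
            pt <- cn$p_idx[cn$to0[e] + 1L]
            if (pf >= 0) x[pf + 1L] <- x[pf + 1L] + s * delta
            if (pt >= 0) x[pt + 1L] <- x[pt + 1L] - s * delta
          }
        }
        seeds <- c(seeds, list(x))
      }
    }
  }

  if (n_starts > 0) {
    # haematocrit-first sampling: draw a haematocrit field, then start from
    # the pressures of the linear system consistent with that field
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    m <- length(cn$from0)
    U <- lhs::randomLHS(as.integer(n_starts), m)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    for (k in seq_len(nrow(U))) {
      hfield <- U[k, ] * 0.7
      hfield[cn$hfix >= 0] <- cn$hfix[cn$hfix >= 0]
      p <- tryCatch(solve_frozen_pressures(cn, hfield),
                    error = function(e) NULL)
      if (is.null(p)) next
      x <- numeric(n)
      x[seq_len(n_int)] <- p
      x[(n_int + 1L):n] <- hfield[cn$h_idx >= 0]
      seeds <- c(seeds, list(x))
    }
  }

  found <- list()
  warned_h <- FALSE
  for (x0 in seeds) {
    res <- newton_core(f, x0, n_int)
    if (!res$converged || res$norm > BRANCH_TOL) next
    x <- canonical_zero_flow(cn, res$x)
    if (!identical(x, res$x)) {
      res <- newton_core(f, x, n_int)
      if (!res$converged || res$norm > BRANCH_TOL) next
      res$x <- canonical_zero_flow(cn, res$x)
      if (max(abs(f(res$x))) > BRANCH_TOL) next
    }
    st <- make_state(network, cn, res$x)
    if (!is_valid_equilibrium(st, cn)) next
    if (!warned_h && any(st$haematocrits > 1 + 1e-9)) {
      warning("equilibrium with haematocrit above 1", call. = FALSE)
      warned_h <- TRUE
    }
    if (!any(vapply(found, function(s) state_distance(s, st) < 1e-6,
                    logical(1)))) {
      found[[length(found) + 1L]] <- st
    }
  }
  # mirror closure: mirrored images of found equilibria as extra seeds
  # (exact symmetry at beta = 1; a cheap targeted seed otherwise)
  if (!is.null(network$meta$mirror) && length(found)) {
    for (pass in 1:2) {
      added <- FALSE
      for (s in found) {
        xm <- tryCatch(mirror_state(network, s), error = function(e) NULL)
        if (is.null(xm)) break
        if (any(vapply(found, function(o) max(abs(o$x - xm)) < 1e-6,
                       logical(1)))) next
        res <- newton_core(f, xm, n_int)
        if (!res$converged || res$norm > BRANCH_TOL) next
        res$x <- canonical_zero_flow(cn, res$x)
        if (max(abs(f(res$x))) > BRANCH_TOL) next
        st <- make_state(network, cn, res$x)
        if (!is_valid_equilibrium(st, cn)) next
        if (!any(vapply(found, function(o) state_distance(o, st) < 1e-6,
                        logical(1)))) {
          found[[length(found) + 1L]] <- st
          added <- TRUE
        }
      }
      if (!added) break
    }
  }
  if (!length(found)) stop("no equilibrium found", call. = FALSE)
  key <- vapply(found, function(s) paste(sprintf("%.7f", s$x), collapse = ","),
                character(1))
  found[order(key)]
}

# At zero flow a vessel's haematocrit is unidentifiable (its splitting-rule
# equation is vacuous); the canonical representative carries H = 0 there,
# consistent with the threshold behaviour of the splitting rule.
canonical_zero_flow <- function(cn, x, tol = 1e-8) {
  n_int <- length(cn$int0)
  Q <- .flows_kernel(x, cn, 0L, 0)
  Qin <- attr(Q, "Qin")
  q <- if (abs(Qin) > EPS_Q) as.numeric(Q) / Qin else as.numeric(Q)
  for (e in seq_along(q)) {
    if (cn$h_idx[e] >= 0 && abs(q[e]) < tol) {
      x[n_int + cn$h_idx[e] + 1L] <- 0
    }
  }
  x
}

# physical-validity filter for accepted equilibria
is_valid_equilibrium <- function(st, cn) {
  if (!is.finite(st$Qin) || st$Qin <= 0) return(FALSE)
  qin_vessels <- st$qhat[cn$h_idx < 0]
  if (any(qin_vessels <= 0)) return(FALSE)
  if (any(abs(st$qhat) > 1 + 1e-6)) return(FALSE)
  if (any(st$haematocrits < -1e-9)) return(FALSE)
  TRUE
}

#' Classify equilibria by redundant-vessel flow state
#'
#' Labels each equilibrium of a coexisting set, per redundant vessel, as
#' having negative (`"-"`), intermediate (`"0"`) or positive (`"+"`) flow.
#' For each vessel the flows across the set are grouped by the largest gaps
#' into at most three ordered clusters; when the set straddles zero with
#' three clusters the middle one is the intermediate state, otherwise labels
#' follow the flow sign (a single equilibrium is intermediate only when its
#' flow is numerically zero). A warning flags ambiguous configurations
#' (duplicate label tuples).
#'
#' @inheritParams signed_flows
#' @param states List of `network_state` equilibria at one parameter point.
#' @param redundant Redundant-vessel rows from [find_redundant_vessels()]
#'   (computed if omitted).
#' @param tol Zero-flow tolerance.
#' @return Character matrix, one row per equilibrium, one column per
#'   redundant vessel (named by vessel label).
#' @export
classify_flow_state <- function(network, states, redundant = NULL,
                                tol = 1e-9) {
  if (is.null(redundant)) redundant <- find_redundant_vessels(network)
  v <- network$vessels
  labels <- matrix("", length(states), length(redundant),
                   dimnames = list(NULL, names(redundant)))
  for (j in seq_along(redundant)) {
    e <- redundant[j]
    lab <- paste0(v$from[e], "->", v$to[e])
    vals <- vapply(states, function(s) {
      if (lab %in% names(s$qhat)) s$qhat[[lab]] else -s$qhat[[paste0(v$to[e], "->", v$from[e])]]
    }, numeric(1))
    labels[, j] <- label_flows(vals, tol)
  }
  if (nrow(labels) > 1L) {
    tup <- apply(labels, 1, paste, collapse = ",")
    if (anyDuplicated(tup)) {
      warning("ambiguous flow-state classification: duplicate label tuples",
              call. = FALSE)
    }
  }
  labels
}

# gap-cluster a set of coexisting flows in one redundant vessel into labels
label_flows <- function(vals, tol = 1e-9) {
  nlab <- function(x) if (abs(x) < tol) "0" else if (x > 0) "+" else "-"
  ns <- length(vals)
  if (ns == 1L) return(nlab(vals))
  straddle <- min(vals) < -tol && max(vals) > tol
  if (!straddle) return(vapply(vals, nlab, character(1)))
  o <- order(vals)
  sv <- vals[o]
  gaps <- diff(sv)
  k <- min(3L, ns)
  cuts <- sort(order(gaps, decreasing = TRUE)[seq_len(k - 1L)])
  grp <- integer(ns)
  start <- 1L
  gi <- 1L
  for (c in c(cuts, ns)) {
    grp[o[start:c]] <- gi
    gi <- gi + 1L
    start <- c + 1L
  }
  if (max(grp) == 3L) {
    c("-", "0", "+")[grp]
  } else {
    # two clusters: label each by the sign of its mean
    means <- tapply(vals, grp, mean)
    lab <- vapply(as.numeric(means), nlab, character(1))
    lab[grp]
  }
}
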