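# Phase-separation (plasma skimming) rules at flow bifurcations.
#
# At a diverging junction the red-cell flux splits disproportionately between
# the daughters. A splitting rule gives the fraction psi of the parent RBC
# flux entering one daughter as a function of that daughter's fractional
# blood flow r = Q_daughter / Q_parent.

# Flow floor (normalised units) below which a parent flow is treated as zero;
# the flow ratio r is undefined at Q_parent = 0.
EPS_Q <- 1e-14

#' Pries 1990 splitting-rule coefficients
#'
#' Coefficients of the logit-form phase-separation rule:
#' skew `A = -(6.96 / D_parent) * log(D_daughter / D_sibling)` (natural log),
#' exponent `rho = 1 + 6.98 (1 - H_parent) / D_parent`, and threshold flow
#' fraction `X0 = 0.4 / D_parent`. `A` is antisymmetric under swapping the
#' daughter with its sibling; `rho` and `X0` are shared by both daughters.
#'
#' @param D_parent,D_daughter,D_sibling Vessel diameters in micrometres,
#'   all `> 0.8` (so that `X0 < 0.5`).
#' @param H_parent Parent-vessel haematocrit fraction in `[0, 1)`.
#' @return A list of class `split_coefficients` with entries `A`, `rho`, `X0`.
#' @export
pries1990_coefficients <- function(D_parent, D_daughter, D_sibling, H_parent) {
  stopifnot(D_parent > 0, D_daughter > 0, D_sibling > 0,
            H_parent >= 0, H_parent < 1)
  X0 <- 0.4 / D_parent
  if (X0 >= 0.5) {
    stop("parent vessel too narrow for the Pries 1990 rule (X0 >= 0.5)",
         call. = FALSE)
  }
  structure(list(
    A   = -6.96 / D_parent * log(D_daughter / D_sibling),
    rho = 1 + 6.98 * (1 - H_parent) / D_parent,
    X0  = X0
  ), class = "split_coefficients")
}

#' RBC flux fraction entering a daughter vessel
#'
#' Piecewise logit-form splitting rule: no red cells enter the daughter when
#' its fractional blood flow `r` is below the threshold `X0`; all of them do
#' when the fraction exceeds `1 - X0`; in between
#' \deqn{\psi(r) = \frac{e^A (r - X_0)^\rho}
#'   {e^A (r - X_0)^\rho + (1 - r - X_0)^\rho}.}
#' The exponent is applied to `max(r - X0, 0)` so that round-off just below a
#' threshold cannot produce complex powers.
#'
#' @param r Daughter flow fraction in `[0, 1]` (vectorised).
#' @param coeffs A `split_coefficients` object, e.g. from
#'   [pries1990_coefficients()].
#' @return RBC flux fraction in `[0, 1]`.
#' @export
psi <- function(r, coeffs) {
  if (any(!is.finite(r)) || any(r < 0) || any(r > 1)) {
    stop("flow ratio r must lie in [0, 1]", call. = FALSE)
  }
  a <- exp(coeffs$A) * pmax(r - coeffs$X0, 0)^coeffs$rho
  b <- pmax(1 - r - coeffs$X0, 0)^coeffs$rho
  out <- ifelse(r < coeffs$X0, 0, ifelse(r > 1 - coeffs$X0, 1, a / (a + b)))
  as.numeric(out)
}

#' Residual of the daughter-haematocrit equation at a bifurcation
#'
#' Steady-state RBC bookkeeping for one daughter of a diverging junction:
#' `psi(r) * Q_parent * H_parent - Q_daughter * H_daughter`, which vanishes
#' exactly when the splitting rule is satisfied. The residual is invariant
#' under a uniform rescaling of all flows, since `r` is a ratio and the
#' product terms are homogeneous of degree one.
#'
#' @param Q_parent,Q_daughter Flow magnitudes (in the direction of flow);
#'   `Q_parent` must exceed the zero-flow floor `1e-14` in normalised units.
#' @param H_parent,H_daughter Haematocrit fractions.
#' @param D_parent,D_daughter,D_sibling Diameters passed to the rule.
#' @param rule Splitting rule name, see [splitting_rule()].
#' @return Scalar residual.
#' @export
daughter_haematocrit_defect <- function(Q_parent, H_parent, Q_daughter, H_daughter,
                                        D_parent, D_daughter, D_sibling,
                                        rule = "pries1990") {
  if (!is.finite(Q_parent) || abs(Q_parent) < EPS_Q) {
    stop("degenerate junction: parent flow below the zero-flow floor",
         call. = FALSE)
  }
  rl <- splitting_rule(rule)
  r <- min(max(Q_daughter / Q_parent, 0), 1)
  p <- rl$psi(r, H_parent, D_parent, D_daughter, D_sibling)
  p * Q_parent * H_parent - Q_daughter * H_daughter
}

#' Splitting-rule registry
#'
#' Phase-separation rules are pluggable: a rule is a name plus a function
#' `psi(r, H_parent, D_parent, D_daughter, D_sibling)` returning the RBC flux
#' fraction for the daughter with flow fraction `r`. Built-in rules:
#' `"pries1990"` (default; the empirical logit rule above) and
#' `"proportional"` (`psi = r`, i.e. no phase separation -- a degenerate rule
#' useful for testing, under which the haematocrit equations become linear at
#' fixed flows). Additional rules can be registered with
#' `register_splitting_rule()`; they use the general (R-level) residual
#' assembly path.
#'
#' @param name Rule name.
#' @return A list with entries `name`, `psi` and `code` (internal integer code
#'   for compiled rules, `NA` for user-registered ones).
#' @export
splitting_rule <- function(name = "pries1990") {
  rl <- .rule_registry[[name]]
  if (is.null(rl)) {
    stop(sprintf("unknown splitting rule '%s'; registered: %s", name,
                 paste(names(.rule_registry), collapse = ", ")), call. = FALSE)
  }
  rl
}

#' @rdname splitting_rule
#' @param psi_fn Function `(r, H_parent, D_parent, D_daughter, D_sibling)`
#'   returning the RBC flux fraction. It must satisfy the partition of unity
#'   `psi(r) + psi_sibling(1 - r) = 1` for RBC conservation.
#' @export
register_splitting_rule <- function(name, psi_fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(psi_fn))
  assign(name, list(name = name, psi = psi_fn, code = NA_integer_),
         envir = .rule_registry)
  invisible(name)
}

.rule_registry <- new.env(parent = emptyenv())

.init_rules <- function() {
  assign("pries1990", list(
    name = "pries1990",
    psi = function(r, H_parent, D_parent, D_daughter, D_sibling) {
      psi(r, pries1990_coefficients(D_parent, D_daughter, D_sibling, H_parent))
    },
    code = 0L
  ), envir = .rule_registry)
  assign("proportional", list(
    name = "proportional",
    psi = function(r, H_parent, D_parent, D_daughter, D_sibling) r,
    code = 1L
  ), envir = .rule_registry)
}
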