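#' Effective oxygen diffusivity in the mycelial network
#'
#' Hindered-diffusion power law: the bulk diffusion coefficient reduced by
#' the local hyphal volume fraction, `D_eff = D_bulk * (1 - ch)^a`.
#'
#' @param ch local hyphal volume fraction, in \[0, 1).
#' @param p a [kinetic_params()] object.
#' @return effective diffusivity, m^2 h^-1 (vectorised over `ch`).
#' @export
#' @examples
#' effective_diffusion(0.2, kinetic_params())
effective_diffusion <- function(ch, p) {
  stopifnot(inherits(p, "kinetic_params"))
  if (any(ch < 0) || any(ch >= 1))
    stop_pellet("hyphal fraction must lie in [0, 1) for a positive diffusivity")
  p$d_bulk * (1 - ch)^p$a
}

#' Volumetric oxygen consumption: growth term
#'
#' Monod-limited oxygen consumption for the formation of new biomass:
#' `q = (rho_h / Y_X/O2) * c/(K_XO + c) * mu_max * ch`, in kg m^-3 h^-1.
#' Negative concentrations (transient solver overshoot) are clamped to 0.
#'
#' @param c local oxygen concentration, kg m^-3 (vectorised).
#' @param ch local hyphal volume fraction (scalar or same length as `c`).
#' @param p a [kinetic_params()] object; `y_xo2`, `k_xo`, `mu_max`, `rho_h`
#'   may be complex for complex-step differentiation.
#' @return consumption rate, kg m^-3 h^-1.
#' @export
q_growth <- function(c, ch, p) {
  if (identical(p$y_xo2, 0)) stop_pellet("y_xo2 must be nonzero")
  cc <- pmax(c, 0)
  (p$rho_h / p$y_xo2) * (cc / (p$k_xo + cc)) * p$mu_max * ch
}

#' Volumetric oxygen consumption: growth plus maintenance
#'
#' Adds maintenance metabolism to the growth term and floors the
#' growth-linked driving force at zero below the critical concentration:
#' `q = (rho_h/Y) * max(c - c_crit, 0)/(K_XO + c) * mu_max * ch
#'    + m_O2,max * rho_h * c/(K_MO + c) * ch`.
#' Without the floor the printed growth term would turn negative for
#' `c < c_crit`, i.e. oxygen production; non-negativity is enforced.
#'
#' @inheritParams q_growth
#' @return consumption rate, kg m^-3 h^-1.
#' @export
q_maintenance_variant <- function(c, ch, p) {
  cc <- pmax(c, 0)
  grow <- (p$rho_h / p$y_xo2) * (pmax(cc - p$c_crit, 0) / (p$k_xo + cc)) *
    p$mu_max * ch
  maint <- p$m_o2_max * p$rho_h * (cc / (p$k_mo + cc)) * ch
  grow + maint
}

# Variant dispatch and its derivative with respect to concentration.
q_oxygen <- function(c, ch, p) {
  if (p$variant == "growth_only") q_growth(c, ch, p)
  else q_maintenance_variant(c, ch, p)
}

q_oxygen_dc <- function(c, ch, p) {
  cc <- pmax(c, 0)
  if (p$variant == "growth_only") {
    (p$rho_h / p$y_xo2) * p$mu_max * ch * p$k_xo / (p$k_xo + cc)^2
  } else {
    grow <- ifelse(cc > p$c_crit,
                   (p$rho_h / p$y_xo2) * p$mu_max * ch *
                     (p$k_xo + p$c_crit) / (p$k_xo + cc)^2,
                   0)
    maint <- p$m_o2_max * p$rho_h * ch * p$k_mo / (p$k_mo + cc)^2
    grow + maint
  }
}

#' Interpolate a shell profile onto a uniform simulation grid
#'
#' Shell fractions, anchored at the bin mid-radii (flat below the innermost
#' anchor), are interpolated piecewise-linearly onto `n_nodes` equidistant
#' nodes on \[0, r_max\]. Values are clamped to \[0, 0.999\] so the
#' effective diffusivity stays positive; clamping at the top triggers a
#' warning.
#'
#' @param shells a [shell_profile()].
#' @param n_nodes number of grid nodes (default 100).
#' @param r_max outer grid radius, um; must not exceed the outermost shell
#'   radius.
#' @return numeric vector of hyphal fractions per node.
#' @export
fraction_to_grid <- function(shells, n_nodes = 100, r_max) {
  stopifnot(inherits(shells, "shell_profile"), n_nodes >= 3)
  if (r_max > max(shells$shell_outer_radii) + 1e-9)
    stop_pellet("r_max (%g um) exceeds the outermost shell radius (%g um)",
                r_max, max(shells$shell_outer_radii))
  r <- seq(0, r_max, length.out = n_nodes)
  ch <- ch_interpolant(shells)(r)
  if (any(ch > 0.999)) {
    warn_pellet("hyphal fraction clamped to 0.999 on %d node(s)", sum(ch > 0.999))
    ch <- pmin(ch, 0.999)
  }
  ch
}

# Conservative finite-volume diffusion operator for the spherical Laplacian
# div(D r^2 grad c)/r^2 on a uniform grid r_i = (i-1)*dr, i = 1..n.
# D is evaluated at cell faces from the mean of adjacent node fractions.
# Row 1 uses the symmetry control volume [0, dr/2] (centre limit of the
# spherical Laplacian); row n is left empty (Dirichlet node).
# Units: r_max in m, entries in h^-1.
fv_operator <- function(ch, r_max, p, n) {
  dr <- r_max / (n - 1)
  r <- (seq_len(n) - 1) * dr
  ch_face <- (ch[-n] + ch[-1]) / 2
  d_face <- p$d_bulk * (1 - ch_face)^p$a          # faces i+1/2, i = 1..n-1
  r_face <- (r[-n] + r[-1]) / 2
  lower <- numeric(n - 1); upper <- numeric(n - 1); dg <- numeric(n)
  i <- 2:(n - 1)
  alpha <- r_face[i - 1]^2 * d_face[i - 1] / (r[i]^2 * dr^2)
  beta  <- r_face[i]^2     * d_face[i]     / (r[i]^2 * dr^2)
  lower[i - 1] <- alpha
  upper[i] <- beta
  dg[i] <- -(alpha + beta)
  # centre node: dc/dt = 6 D_{1/2->3/2} (c2 - c1) / dr^2
  dg[1] <- -6 * d_face[1] / dr^2
  upper[1] <- 6 * d_face[1] / dr^2
  list(lower = lower, diag = dg, upper = upper, dr = dr, r = r)
}

tri_mult <- function(op, x) {
  n <- length(x)
  y <- op$diag * x
  y[-1] <- y[-1] + op$lower * x[-n]
  y[-n] <- y[-n] + op$upper * x[-1]
  y
}

#' Steady-state oxygen profile by transient integration (method of lines)
#'
#' Discretises the 1D spherical diffusion-consumption balance
#' `dc/dt = (1/r^2) d/dr(D_eff r^2 dc/dr) - q(c)` on `n_nodes` equidistant
#' nodes with a conservative second-order finite-volume scheme, a symmetry
#' (zero-flux) condition at the centre and a Dirichlet condition
#' `c(r_max) = c_surface` at the pellet border, and integrates from the
#' uniform initial condition `c = c_surface` with a stiff solver until the
#' steady-state criterion holds: maximum relative concentration change
#' below `steady_tol` per simulated millisecond (relative to `c_surface`).
#' The first time the criterion is met is recorded as `time_to_steady`.
#'
#' With the default literature kinetics the approach to steady state is
#' governed by the zero-order drain of the initially saturated interior
#' (roughly `c_surface / q_max`, tens of seconds), so the default
#' integration cap is generous; see the package vignette.
#'
#' @param ch hyphal fraction per node (length `n_nodes`), or a
#'   [shell_profile()] to be interpolated via [fraction_to_grid()].
#' @param p a [kinetic_params()] object.
#' @param c_surface oxygen concentration held at the border, kg m^-3.
#' @param r_max pellet border radius, m.
#' @param n_nodes number of radial nodes (default 100).
#' @param steady_tol steady-state criterion, relative change per simulated
#'   millisecond (default 1e-6).
#' @param t_max integration cap in simulated seconds (default 300).
#' @param rtol,atol_frac integrator tolerances; absolute tolerance is
#'   `atol_frac * c_surface`.
#' @return object of class `sim_result`: `radii` (m), `c_o2` (kg m^-3),
#'   `ch`, `c_surface`, `converged`, `time_to_steady` (s).
#' @export
steady_state_profile <- function(ch, p, c_surface, r_max, n_nodes = 100,
                                 steady_tol = 1e-6, t_max = 300,
                                 rtol = 1e-6, atol_frac = 1e-9) {
  stopifnot(inherits(p, "kinetic_params"), c_surface > 0, r_max > 0)
  if (inherits(ch, "shell_profile"))
    ch <- fraction_to_grid(ch, n_nodes, r_max / UM_TO_M)
  n <- length(ch)
  if (n < 3) stop_pellet("need at least 3 grid nodes")
  op <- fv_operator(ch, r_max, p, n)
  deriv <- function(t, y, parms) {
    dy <- tri_mult(op, y) - q_oxygen(y, ch, p)
    dy[n] <- 0
    list(dy)
  }
  ms_h <- 1e-3 / 3600                      # one millisecond in hours
  crit <- function(y) max(abs(deriv(0, y, NULL)[[1]])) * ms_h / c_surface

  y <- rep(c_surface, n)
  t_now <- 0
  time_to_steady <- NA_real_
  # The profile is integrated past the first crossing of `steady_tol` until
  # the residual drift is three decades smaller, so the returned state is a
  # fully settled steady profile while `time_to_steady` reports the honest
  # first crossing of the criterion.
  tail_tol <- steady_tol * 1e-3
  # fine resolution over the first 2 s, coarser afterwards
  plan <- list(c(2, 0.01), c(8, 0.05), c(t_max - 10, 0.1))
  done <- FALSE
  for (stage in plan) {
    if (t_now >= t_max || done) break
    t_end <- min(t_now + stage[1], t_max)
    times_s <- seq(t_now, t_end, by = stage[2])
    sol <- deSolve::ode(y = y, times = times_s / 3600, func = deriv,
                        parms = NULL, method = "lsoda",
                        jactype = "bandint", bandup = 1, banddown = 1,
                        rtol = rtol, atol = atol_frac * c_surface)
    states <- sol[, -1, drop = FALSE]
    crits <- apply(states, 1, crit)
    if (is.na(time_to_steady)) {
      hit <- which(crits < steady_tol)
      hit <- hit[hit > 1]                  # ignore the (repeated) start row
      if (length(hit) > 0) time_to_steady <- times_s[min(hit)]
    }
    tail_hit <- which(crits < tail_tol)
    tail_hit <- tail_hit[tail_hit > 1]
    if (length(tail_hit) > 0) {
      y <- states[min(tail_hit), ]
      done <- TRUE
    } else {
      y <- states[nrow(states), ]
      t_now <- t_end
    }
  }
  converged <- !is.na(time_to_steady)
  if (!converged)
    warn_pellet("steady-state criterion not met within %g s of simulated time", t_max)
  if (min(y) < -1e-9 * c_surface)
    stop_pellet("negative concentrations beyond tolerance (min %g)", min(y))
  y <- unname(pmax(y, 0))
  structure(list(radii = op$r, c_o2 = y, ch = ch, c_surface = c_surface,
                 converged = converged, time_to_steady = time_to_steady,
                 n_nodes = n),
            class = "sim_result")
}

#' Steady-state oxygen profile by damped Newton iteration
#'
#' Solves the steady-state system `L c = q(c)` of the same finite-volume
#' discretisation as [steady_state_profile()] directly, using
#' pseudo-transient continuation (implicit Euler with a growing step) that
#' turns into full Newton iteration as the step grows; the Jacobian is
#' tridiagonal. This is the fast path used by the parameter-estimation
#' routines; it is cross-checked against the transient integration in the
#' package tests.
#'
#' @inheritParams steady_state_profile
#' @param tol convergence tolerance on the scaled residual.
#' @param max_iter iteration cap.
#' @return a `sim_result` (with `time_to_steady = NA`).
#' @export
steady_state_newton <- function(ch, p, c_surface, r_max, n_nodes = 100,
                                tol = 1e-12, max_iter = 200) {
  stopifnot(inherits(p, "kinetic_params"), c_surface > 0, r_max > 0)
  if (inherits(ch, "shell_profile"))
    ch <- fraction_to_grid(ch, n_nodes, r_max / UM_TO_M)
  n <- length(ch)
  op <- fv_operator(ch, r_max, p, n)
  scale <- c_surface * max(abs(op$diag))
  resid <- function(y) {
    f <- tri_mult(op, y) - q_oxygen(y, ch, p)
    f[n] <- 0                              # Dirichlet node held exactly
    f
  }
  y <- rep(c_surface, n)
  dt <- 1e-7                               # pseudo-time step, h
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    f <- resid(y)
    if (max(abs(f)) / scale < tol) { converged <- TRUE; break }
    qp <- q_oxygen_dc(y, ch, p)
    # (I/dt - (L - diag(q'))) delta = F ; Dirichlet row: delta_n = 0
    dg <- 1 / dt - (op$diag - qp)
    lo <- -op$lower
    up <- -op$upper
    dg[n] <- 1; lo[n - 1] <- 0; f[n] <- 0
    delta <- solve_tridiag(lo, dg, up, f)
    y <- pmin(pmax(y + delta, 0), c_surface)
    dt <- min(dt * 4, 1e8)
  }
  if (!converged)
    stop_pellet("steady-state Newton iteration did not converge (%d iterations)",
                max_iter)
  structure(list(radii = op$r, c_o2 = y, ch = ch, c_surface = c_surface,
                 converged = TRUE, time_to_steady = NA_real_, n_nodes = n),
            class = "sim_result")
}

# Parameter sensitivity of the steady state: solves (L - diag(dq/dc)) s =
# dq/dp at the converged state. `dqdp` is the vector of consumption-rate
# derivatives with respect to the parameter (computed by complex step on
# the kinetics). Returns dc/dp per node.
steady_state_sensitivity <- function(sim, p, dqdp) {
  n <- sim$n_nodes
  op <- fv_operator(sim$ch, max(sim$radii), p, n)
  qp <- q_oxygen_dc(sim$c_o2, sim$ch, p)
  dg <- op$diag - qp
  lo <- op$lower
  up <- op$upper
  dg[n] <- 1; lo[n - 1] <- 0
  rhs <- dqdp
  rhs[n] <- 0
  solve_tridiag(lo, dg, up, rhs)
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Steady-state oxygen profile: %d nodes, r_max %.0f um\n",
              x$n_nodes, max(x$radii) / UM_TO_M))
  cat(sprintf("  surface %.3g mg/L, centre %.3g mg/L, converged: %s",
              x$c_surface / MGL_TO_KGM3, x$c_o2[1] / MGL_TO_KGM3, x$converged))
  if (!is.na(x$time_to_steady))
    cat(sprintf(", steady after %.2f s", x$time_to_steady))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.sim_result <- function(x, ...) {
  data.frame(radius_um = x$radii / UM_TO_M, ch = x$ch,
             o2_mg_per_l = x$c_o2 / MGL_TO_KGM3)
}

#' Characteristic time scales of the pellet oxygen balance
#'
#' Order-of-magnitude estimates supporting the pseudo-steady-state
#' assumption: biomass doubling (`ln 2 / mu_max`), diffusion across a
#' length scale (`L^2 / D_eff`), and consumption of a reference
#' concentration (`c_ref / q_growth(c_ref)`). Growth is hours; transport
#' and consumption are seconds to minutes, so the hyphal fraction can be
#' held constant while the oxygen field equilibrates.
#'
#' @param p a [kinetic_params()] object.
#' @param length_scale diffusion length scale, m.
#' @param c_ref reference oxygen concentration, kg m^-3.
#' @param ch_ref reference hyphal fraction.
#' @return list with `t_doubling`, `t_diffusion`, `t_reaction`, all in
#'   hours (Inf when the corresponding rate is zero).
#' @export
characteristic_times <- function(p, length_scale, c_ref, ch_ref) {
  stopifnot(inherits(p, "kinetic_params"),
            length_scale > 0, c_ref > 0, ch_ref >= 0)
  t_doubling <- if (p$mu_max > 0) log(2) / p$mu_max else Inf
  t_diffusion <- length_scale^2 / effective_diffusion(ch_ref, p)
  q <- q_growth(c_ref, ch_ref, p)
  t_reaction <- if (q > 0) c_ref / q else Inf
  list(t_doubling = t_doubling, t_diffusion = t_diffusion,
       t_reaction = t_reaction)
}
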