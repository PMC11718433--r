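#' Default parameter bounds for the kinetic fit
#'
#' Brackets the literature values by at least an order of magnitude:
#' y_xo2 in \[0.1, 30\] kg/kg, m_o2_max in \[1e-5, 0.1\] kg/kg/h, k_xo and
#' k_mo in \[1e-7, 1e-3\] kg/m^3, c_crit in \[0, 1e-4\] kg/m^3.
#'
#' @return named list of `c(lower, upper)` pairs.
#' @export
default_fit_bounds <- function() {
  list(y_xo2 = c(0.1, 30),
       m_o2_max = c(1e-5, 0.1),
       k_xo = c(1e-7, 1e-3),
       k_mo = c(1e-7, 1e-3),
       c_crit = c(0, 1e-4))
}

#' Specification of a per-pellet parameter fit
#'
#' @param free character vector of free parameters, a subset of
#'   `y_xo2`, `m_o2_max`, `k_xo`, `k_mo`, `c_crit`.
#' @param variant consumption model variant, see [kinetic_params()].
#' @param bounds named list of `c(lower, upper)` per free parameter.
#' @param n_starts number of multistart initial points (default 50).
#' @param seed integer seed for start sampling.
#' @param jacobian_mode `"auto"`, `"complex_step"` or
#'   `"finite_difference"`. Complex-step sensitivities require an analytic
#'   forward map; the maintenance variant's growth floor and `c_crit`
#'   introduce kinks, so `"auto"` falls back to finite differences there.
#' @return object of class `fit_spec`.
#' @export
fit_spec <- function(free = "y_xo2",
                     variant = c("growth_only", "growth_plus_maintenance"),
                     bounds = default_fit_bounds(),
                     n_starts = 50, seed = 1L,
                     jacobian_mode = c("auto", "complex_step", "finite_difference")) {
  variant <- match.arg(variant)
  jacobian_mode <- match.arg(jacobian_mode)
  allowed <- c("y_xo2", "m_o2_max", "k_xo", "k_mo", "c_crit")
  if (length(free) == 0 || !all(free %in% allowed))
    stop_pellet("free parameters must be a non-empty subset of {%s}",
                paste(allowed, collapse = ", "))
  for (f in free) {
    b <- bounds[[f]]
    if (is.null(b) || length(b) != 2 || any(!is.finite(b)) || b[1] > b[2] || b[2] <= 0)
      stop_pellet("invalid bounds for %s", f)
  }
  if (jacobian_mode == "auto")
    jacobian_mode <- if (variant == "growth_only" && !("c_crit" %in% free))
      "complex_step" else "finite_difference"
  structure(list(free = free, variant = variant, bounds = bounds,
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 jacobian_mode = jacobian_mode),
            class = "fit_spec")
}

apply_free <- function(p, free_values, variant = NULL) {
  q <- unclass(p)
  for (nm in names(free_values)) q[[nm]] <- unname(free_values[nm])
  if (!is.null(variant)) q$variant <- variant
  structure(q, class = "kinetic_params")
}

#' Residuals of the simulated oxygen profile against measurements
#'
#' Simulates the steady-state oxygen profile on the pellet's radial grid
#' (hyphal fraction from the aligned shell profile, Dirichlet value at the
#' per-pellet maximum concentration) and returns the residuals
#' `y_exp - y_sim` (mg L^-1) at each in-pellet measurement radius. A
#' solver failure yields large penalty residuals flagged with attribute
#' `"failed"`, keeping multistart optimisation robust.
#'
#' @param a an [aligned_pellet()].
#' @param p a [kinetic_params()] object (fixed parameters and variant).
#' @param free_values named numeric vector overriding parameters of `p`.
#' @param n_nodes simulation grid nodes.
#' @return residual vector, mg L^-1.
#' @export
residual_objective <- function(a, p, free_values = NULL, n_nodes = 100) {
  stopifnot(inherits(a, "aligned_pellet"))
  r <- a$radii[a$in_pellet]
  y <- a$c_o2[a$in_pellet]
  if (length(r) < 3) stop_pellet("need at least 3 in-pellet points")
  p2 <- apply_free(p, free_values)
  sim <- tryCatch(
    steady_state_newton(a$shells, p2, a$c_max * MGL_TO_KGM3,
                        a$border_radius * UM_TO_M, n_nodes = n_nodes),
    error = function(e) NULL)
  if (is.null(sim)) {
    res <- rep(1e3, length(r))
    attr(res, "failed") <- TRUE
    return(res)
  }
  y_sim <- interp1(sim$radii / UM_TO_M, sim$c_o2 / MGL_TO_KGM3, r)
  y - y_sim
}

# Jacobian of the residual vector with respect to the free parameters via
# complex-step kinetics sensitivities through the steady state.
residual_jacobian_cs <- function(a, p, free_values, n_nodes = 100, h = 1e-20) {
  r <- a$radii[a$in_pellet]
  p2 <- apply_free(p, free_values)
  sim <- steady_state_newton(a$shells, p2, a$c_max * MGL_TO_KGM3,
                             a$border_radius * UM_TO_M, n_nodes = n_nodes)
  J <- matrix(0, length(r), length(free_values))
  for (j in seq_along(free_values)) {
    nm <- names(free_values)[j]
    pc <- unclass(p2)
    pc[[nm]] <- pc[[nm]] + 1i * h * max(abs(pc[[nm]]), 1e-30)
    hh <- h * max(abs(unclass(p2)[[nm]]), 1e-30)
    dqdp <- Im(q_oxygen(sim$c_o2, sim$ch, structure(pc, class = "kinetic_params"))) / hh
    s <- steady_state_sensitivity(sim, p2, dqdp)
    J[, j] <- -interp1(sim$radii / UM_TO_M, s / MGL_TO_KGM3, r)
  }
  J
}

#' Mean absolute error between measured and simulated profiles
#'
#' @param exp,sim equal-length numeric vectors, mg L^-1.
#' @return MAE, mg L^-1.
#' @export
mean_absolute_error <- function(exp, sim) {
  if (length(exp) == 0 || length(exp) != length(sim))
    stop_pellet("series must be non-empty and of equal length")
  mean(abs(exp - sim))
}

#' Corrected Akaike information criterion for least-squares fits
#'
#' `AICc = n ln(RSS/n) + 2k + 2k(k+1)/(n-k-1)` with `k = n_free + 1` (the
#' residual variance counts as an additional parameter). Intended for the
#' small per-pellet sample sizes (n < 40) of microelectrode profiles.
#'
#' @param rss residual sum of squares.
#' @param n number of data points.
#' @param n_free number of fitted model parameters.
#' @return AICc value.
#' @export
aicc <- function(rss, n, n_free) {
  k <- n_free + 1
  if (n <= k + 1) stop_pellet("sample too small for AICc (n = %d, k = %d)", n, k)
  if (rss < 0) stop_pellet("rss must be nonnegative")
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit kinetic parameters to a pellet's oxygen profile
#'
#' Bounded least squares (Levenberg-Marquardt) from `n_starts` initial
#' points sampled log-uniformly within the bounds (linear-uniformly for
#' `c_crit`, whose lower bound is 0); the best of all starts is returned
#' together with the per-start objective record. Gradients use
#' complex-step steady-state sensitivities when the forward map is
#' analytic in the free parameters, central finite differences otherwise.
#'
#' @param a an [aligned_pellet()].
#' @param p a [kinetic_params()] object holding the fixed parameters.
#' @param spec a [fit_spec()].
#' @param n_nodes simulation grid nodes.
#' @return object of class `fit_result`: `estimates`, `rss` ((mg/L)^2),
#'   `mae` (mg/L), `aicc`, `n_points`, `k_effective`, `start_records`,
#'   `best_start_index`, `jacobian_mode`.
#' @export
fit_parameters <- function(a, p, spec = fit_spec(), n_nodes = 100) {
  stopifnot(inherits(a, "aligned_pellet"), inherits(p, "kinetic_params"),
            inherits(spec, "fit_spec"))
  p <- apply_free(p, NULL, variant = spec$variant)
  lower <- vapply(spec$free, function(f) spec$bounds[[f]][1], 0)
  upper <- vapply(spec$free, function(f) spec$bounds[[f]][2], 0)
  names(lower) <- names(upper) <- spec$free

  starts <- with_seed(spec$seed, {
    m <- sapply(spec$free, function(f) {
      b <- spec$bounds[[f]]
      if (f == "c_crit" || b[1] <= 0)
        stats::runif(spec$n_starts, b[1], b[2])
      else exp(stats::runif(spec$n_starts, log(b[1]), log(b[2])))
    })
    matrix(m, nrow = spec$n_starts,
           dimnames = list(NULL, spec$free))
  })

  fn <- function(par) {
    names(par) <- spec$free
    residual_objective(a, p, par, n_nodes = n_nodes)
  }
  jac <- if (spec$jacobian_mode == "complex_step") {
    function(par) {
      names(par) <- spec$free
      residual_jacobian_cs(a, p, par, n_nodes = n_nodes)
    }
  } else NULL

  results <- vector("list", spec$n_starts)
  objectives <- rep(NA_real_, spec$n_starts)
  for (s in seq_len(spec$n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[s, ], lower = lower, upper = upper,
                         fn = fn, jac = jac,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 100, ftol = 1e-12, ptol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      results[[s]] <- fit
      objectives[s] <- fit$deviance
    }
  }
  if (all(is.na(objectives)))
    stop_pellet("all %d starts failed", spec$n_starts)
  best <- which.min(objectives)
  bf <- results[[best]]
  est <- bf$par
  names(est) <- spec$free

  res <- fn(est)
  rss <- sum(res^2)
  n_pts <- length(res)
  structure(list(estimates = est, rss = rss,
                 mae = mean(abs(res)),
                 aicc = aicc(rss, n_pts, length(spec$free)),
                 n_points = n_pts,
                 k_effective = length(spec$free) + 1L,
                 start_records = objectives,
                 best_start_index = best,
                 jacobian_mode = spec$jacobian_mode,
                 variant = spec$variant,
                 free = spec$free),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit (%s; free: %s)\n", x$variant, paste(x$free, collapse = ", ")))
  for (nm in names(x$estimates))
    cat(sprintf("  %-9s %.4g\n", nm, x$estimates[nm]))
  cat(sprintf("  RSS %.4g, MAE %.4g mg/L, AICc %.2f (n = %d, best start %d/%d)\n",
              x$rss, x$mae, x$aicc, x$n_points, x$best_start_index,
              length(x$start_records)))
  invisible(x)
}

#' Default model-selection candidates
#'
#' Growth-only and growth-plus-maintenance variants with increasing free
#' parameter sets, from the single-yield fit to the full five-parameter
#' kinetics.
#'
#' @param n_starts,seed passed to each [fit_spec()].
#' @return named list of `fit_spec`s.
#' @export
default_fit_candidates <- function(n_starts = 50, seed = 1L) {
  list(
    growth_y = fit_spec("y_xo2", "growth_only", n_starts = n_starts, seed = seed),
    maint_ym = fit_spec(c("y_xo2", "m_o2_max"), "growth_plus_maintenance",
                        n_starts = n_starts, seed = seed),
    growth_kxo = fit_spec("k_xo", "growth_only", n_starts = n_starts, seed = seed),
    maint_monod = fit_spec(c("k_xo", "k_mo", "c_crit"), "growth_plus_maintenance",
                           n_starts = n_starts, seed = seed),
    maint_full = fit_spec(c("y_xo2", "m_o2_max", "k_xo", "k_mo", "c_crit"),
                          "growth_plus_maintenance", n_starts = n_starts,
                          seed = seed))
}

#' Select the consumption model by AICc
#'
#' Fits every candidate specification and ranks them by AICc (ascending);
#' ties are broken in favour of fewer free parameters. Candidates whose
#' fit fails are dropped from the ranking with a warning.
#'
#' @param a an [aligned_pellet()].
#' @param p a [kinetic_params()] object.
#' @param candidates list of [fit_spec()]s (default
#'   [default_fit_candidates()]).
#' @param n_nodes simulation grid nodes.
#' @return object of class `model_selection`: ranked `fits` plus a summary
#'   `table` with AICc and delta-AICc.
#' @export
select_model <- function(a, p, candidates = default_fit_candidates(),
                         n_nodes = 100) {
  if (length(candidates) < 1) stop_pellet("need at least one candidate")
  if (is.null(names(candidates)))
    names(candidates) <- paste0("candidate_", seq_along(candidates))
  fits <- lapply(names(candidates), function(nm) {
    tryCatch(fit_parameters(a, p, candidates[[nm]], n_nodes = n_nodes),
             error = function(e) {
               warn_pellet("candidate %s failed: %s", nm, conditionMessage(e))
               NULL
             })
  })
  names(fits) <- names(candidates)
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) stop_pellet("all candidates failed")
  fits <- fits[ok]
  aiccs <- vapply(fits, function(f) f$aicc, 0)
  kfree <- vapply(fits, function(f) length(f$free), 0L)
  ord <- order(aiccs, kfree)
  fits <- fits[ord]
  tab <- data.frame(candidate = names(fits),
                    variant = vapply(fits, function(f) f$variant, ""),
                    n_free = vapply(fits, function(f) length(f$free), 0L),
                    rss = vapply(fits, function(f) f$rss, 0),
                    mae = vapply(fits, function(f) f$mae, 0),
                    aicc = vapply(fits, function(f) f$aicc, 0),
                    row.names = NULL)
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  structure(list(fits = fits, table = tab, best = names(fits)[1]),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Model selection by AICc (best first):\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Classic one-way analysis of variance
#'
#' Between/within decomposition with the p-value from the F distribution
#' (significance conventionally at alpha = 0.05). Degenerate input with
#' zero within-group variance and equal means returns F = 0, p = 1.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return list with `F` and `p`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2 || any(vapply(groups, length, 0L) < 2))
    stop_pellet("need >= 2 groups with >= 2 values each")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  ssw <- sum(unlist(lapply(groups, function(x) (x - mean(x))^2)))
  means <- vapply(groups, mean, 0)
  if (ssw == 0) {
    if (max(means) - min(means) == 0) return(list(F = 0, p = 1))
    return(list(F = Inf, p = 0))
  }
  tt <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(tt$statistic), p = unname(tt$p.value))
}
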