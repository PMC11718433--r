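#' Run the per-pellet analysis workflow
#'
#' Composes the full single-pellet chain: (optional) binarisation and
#' shell-wise morphometry of a 3D image, replicate averaging and border
#' alignment of the oxygen profile, oxygen-supply metrics, and the kinetic
#' parameter fit. All randomness derives from `seed` through fixed
#' per-stage child seeds, so a rerun is bit-identical.
#'
#' @param input a binary or grayscale [voxel_image()], or a
#'   [shell_profile()] directly (synthetic pellets are spherical by
#'   construction, so shape metrics are skipped and the pellet counts as
#'   spherical).
#' @param o2 an [oxygen_profile()].
#' @param params a [kinetic_params()] object.
#' @param pellet_id identifier, conventionally
#'   "cultivation-time.index" (e.g. `"H-28.2"`).
#' @param strain `"R"` or `"H"`.
#' @param fit a [fit_spec()]; default single free yield coefficient.
#' @param zero_threshold penetration-depth threshold, mg L^-1.
#' @param border_depth optional known oxygen-border depth, um (ground
#'   truth of synthetic profiles); detected from the profile when omitted.
#' @param seed run-level seed.
#' @param n_nodes simulation grid nodes.
#' @return object of class `pellet_record`.
#' @export
run_pellet <- function(input, o2, params, pellet_id = "pellet-1",
                       strain = c("R", "H"), fit = NULL,
                       zero_threshold = 0.05, border_depth = NULL,
                       seed = 1L, n_nodes = 100) {
  strain <- match.arg(strain)
  stage <- "input"
  rec <- tryCatch({
    if (inherits(input, "voxel_image")) {
      stage <- "morphometry"
      img <- if (is_binary_image(input)) input else binarize_otsu(input)
      shells <- shell_hyphal_fraction(img)
      shape <- shape_metrics_3d(img, shells)
      spherical <- shape$is_spherical
    } else if (inherits(input, "shell_profile")) {
      shells <- input
      shape <- NULL
      spherical <- TRUE
    } else stop_pellet("input must be a voxel_image or shell_profile")

    stage <- "alignment"
    aligned <- align_profiles(o2, shells, border_depth = border_depth)
    stage <- "supply metrics"
    metrics <- supply_metrics(aligned, zero_threshold)
    stage <- "parameter fit"
    if (is.null(fit)) fit <- fit_spec(seed = child_seed(seed, 7L))
    fitres <- fit_parameters(aligned, params, fit, n_nodes = n_nodes)

    list(pellet_id = pellet_id, strain = strain, shells = shells,
         shape = shape, is_spherical = spherical, aligned = aligned,
         metrics = metrics, fit = fitres, seed = seed)
  }, error = function(e) {
    stop_pellet("pellet %s failed at stage '%s': %s",
                pellet_id, stage, conditionMessage(e))
  })
  structure(rec, class = "pellet_record")
}

#' @export
print.pellet_record <- function(x, ...) {
  cat(sprintf("Pellet %s (strain %s, %s)\n", x$pellet_id, x$strain,
              if (x$is_spherical) "spherical" else "nonspherical"))
  print(x$metrics)
  print(x$fit)
  invisible(x)
}

# Simulated oxygen concentrations (mg/L) at the in-pellet measurement
# radii of a record, for an arbitrary parameter set and hyphal fraction
# source ("own" shells or a constant value).
record_sim_at_radii <- function(rec, params, y_value, ch_constant = NULL,
                                n_nodes = 100) {
  a <- rec$aligned
  p2 <- apply_free(params, c(y_xo2 = unname(y_value)))
  ch <- if (is.null(ch_constant))
    fraction_to_grid(a$shells, n_nodes, a$border_radius)
  else rep(min(ch_constant, 0.999), n_nodes)
  sim <- steady_state_newton(ch, p2, a$c_max * MGL_TO_KGM3,
                             a$border_radius * UM_TO_M, n_nodes = n_nodes)
  interp1(sim$radii / UM_TO_M, sim$c_o2 / MGL_TO_KGM3, a$radii[a$in_pellet])
}

# Pellet-mean hyphal fraction: total hyphal volume over border-sphere
# volume.
record_mean_ch <- function(rec) {
  R <- rec$aligned$border_radius
  3 * integrate_ch_r2(rec$shells, 0, R) / R^3
}

#' Cohort-level summary over a set of pellet records
#'
#' Reproduces the cohort analysis: only spherical pellets enter the mean
#' values; per-strain and overall means of penetration depth, APP and the
#' fitted yield coefficient; one-way ANOVA between strains; and the
#' per-pellet mean absolute error of the simulated oxygen profile under
#' three evaluation modes: (1) the pellet's individually estimated yield,
#' (2) the cohort-mean yield, (3) the cohort-mean yield combined with a
#' constant, strain-averaged hyphal fraction.
#'
#' @param records list of [run_pellet()] results.
#' @param params a [kinetic_params()] object (fixed parameters for the
#'   evaluation-mode simulations).
#' @param n_nodes simulation grid nodes.
#' @return object of class `cohort_summary`: per-pellet `table`,
#'   per-group `means`, `anova` p-values, and the mode MAEs.
#' @export
cohort_summary <- function(records, params, n_nodes = 100) {
  stopifnot(length(records) >= 1)
  spherical <- vapply(records, function(r) isTRUE(r$is_spherical), TRUE)
  if (!any(spherical)) stop_pellet("no spherical pellets after filtering")
  sph <- records[spherical]

  y_hat <- vapply(records, function(r) unname(r$fit$estimates["y_xo2"]), 0)
  y_mean <- mean(y_hat[spherical])
  strains <- vapply(records, function(r) r$strain, "")
  mean_ch_strain <- tapply(vapply(sph, record_mean_ch, 0),
                           strains[spherical], mean)

  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    yexp <- r$aligned$c_o2[r$aligned$in_pellet]
    mae1 <- r$fit$mae
    mae2 <- mean_absolute_error(
      yexp, record_sim_at_radii(r, params, y_mean, n_nodes = n_nodes))
    chbar <- mean_ch_strain[[r$strain]]
    if (is.null(chbar) || is.na(chbar)) chbar <- mean(vapply(sph, record_mean_ch, 0))
    mae3 <- mean_absolute_error(
      yexp, record_sim_at_radii(r, params, y_mean, ch_constant = chbar,
                                n_nodes = n_nodes))
    data.frame(pellet_id = r$pellet_id, strain = r$strain,
               is_spherical = r$is_spherical,
               penetration_depth_um = r$metrics$penetration_depth,
               app_percent = r$metrics$app,
               y_xo2 = unname(r$fit$estimates["y_xo2"]),
               mae_individual = mae1, mae_mean_parameter = mae2,
               mae_mean_ch = mae3)
  })
  tab <- do.call(rbind, rows)

  sph_tab <- tab[tab$is_spherical, ]
  grp_stats <- function(d) c(
    depth_mean = mean(d$penetration_depth_um), depth_sd = stats::sd(d$penetration_depth_um),
    app_mean = mean(d$app_percent), app_sd = stats::sd(d$app_percent),
    y_mean = mean(d$y_xo2), y_sd = stats::sd(d$y_xo2))
  means <- list(overall = grp_stats(sph_tab))
  for (s in unique(sph_tab$strain)) means[[s]] <- grp_stats(sph_tab[sph_tab$strain == s, ])

  anv <- list()
  if (length(unique(sph_tab$strain)) == 2 &&
      all(table(sph_tab$strain) >= 2)) {
    by_strain <- split(sph_tab, sph_tab$strain)
    anv <- list(
      depth = one_way_anova(lapply(by_strain, `[[`, "penetration_depth_um"))$p,
      app = one_way_anova(lapply(by_strain, `[[`, "app_percent"))$p,
      y_xo2 = one_way_anova(lapply(by_strain, `[[`, "y_xo2"))$p)
  }
  structure(list(table = tab, means = means, anova_p = anv,
                 y_mean = y_mean, mean_ch_strain = mean_ch_strain),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  n_sph <- sum(x$table$is_spherical)
  cat(sprintf("Cohort: %d pellets (%d spherical)\n", nrow(x$table), n_sph))
  ov <- x$means$overall
  cat(sprintf("  penetration %.0f +/- %.0f um, APP %.1f +/- %.1f %%, Y_X/O2 %.2f +/- %.2f\n",
              ov["depth_mean"], ov["depth_sd"], ov["app_mean"], ov["app_sd"],
              ov["y_mean"], ov["y_sd"]))
  if (length(x$anova_p))
    cat(sprintf("  strain ANOVA p: depth %.3g, APP %.3g, Y %.3g\n",
                x$anova_p$depth, x$anova_p$app, x$anova_p$y_xo2))
  cat(sprintf("  MAE: individual %.3g, mean-parameter %.3g, mean-ch %.3g mg/L\n",
              mean(x$table$mae_individual), mean(x$table$mae_mean_parameter),
              mean(x$table$mae_mean_ch)))
  invisible(x)
}
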