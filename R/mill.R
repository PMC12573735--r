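#' Fit the wall-force ball-milling model to a reaction step
#'
#' The central modelling function of the package. Given the reactant (or
#' pre-reactive adduct) and transition-state geometries of a reaction step
#' and an impact pressure, it predicts the mechanically induced change in
#' the activation energy, \eqn{\Delta E_{a,mec}}, for every impact
#' orientation and its isotropic (spherical) average
#' \eqn{\langle\Delta E_{a,mec}\rangle}.
#'
#' The model idealises one milling-ball collision as two rigid walls
#' compressing the molecule along a direction \eqn{\hat n(\theta,\phi)}.
#' The total compressive force is the impact pressure acting on the
#' molecular cross-section, \eqn{F_{mec} = P\,\pi R(\theta,\phi)^2}; it is
#' split uniformly over the atoms, each pushed toward the dividing plane.
#' The work these forces perform along the straight-line displacement from
#' reactant to transition state (after mass-weighted Kabsch superposition)
#' lowers the barrier: \eqn{\Delta E_{a,mec} = -W_{mec}}. Averaging over a
#' uniform angular grid emulates the random impact orientations of ball
#' milling.
#'
#' @param reactant Reactant/minimum geometry: a [molecular_structure()] or
#'   a path to an XYZ file.
#' @param ts Transition-state geometry, same form; atom order must match
#'   the reactant index-by-index.
#' @param pressure Impact pressure in GPa.
#' @param grid_n Polar grid size N (2N^2 directions are sampled).
#' @param delta_mode,delta_constant,radius_mode,weight_scheme See
#'   [milling_config()].
#' @param ea Optional baseline activation energy E_a (kcal/mol, from
#'   electronic-structure calculations); when given, the mechanically
#'   modified barrier \eqn{E_{a,mec} = E_a + \langle\Delta E_{a,mec}\rangle}
#'   is reported.
#' @param label Optional label for printing.
#' @return An object of class `mill`: list with `endpoints`, `config`,
#'   `alignment`, `map` (the [sweep_directions()] result), `average`
#'   (\eqn{\langle\Delta E_{a,mec}\rangle}, kcal/mol), `extrema`, `ea`,
#'   `ea_mec`, `label`, `call`.
#' @seealso [sweep_directions()], [pressure_scan()], [compare_pathways()]
#' @export
#' @examples
#' ep <- make_contraction_pair(n_atoms = 12, factor = 0.9, seed = 1)
#' fit <- mill(ep$reactant, ep$transition, pressure = 1, grid_n = 40)
#' fit
#' coef(fit)
#' predict(fit, pressure = c(1, 2, 4))
mill <- function(reactant, ts, pressure = 1, grid_n = 100,
                 delta_mode = c("vdw", "none", "constant"),
                 delta_constant = NULL,
                 radius_mode = c("directional", "global"),
                 weight_scheme = "uniform",
                 ea = NULL, label = NULL) {
  cl <- match.call()
  inputs <- c(reactant = if (is.character(reactant)) reactant else NA,
              ts = if (is.character(ts)) ts else NA)
  if (is.character(reactant)) reactant <- read_xyz(reactant)
  if (is.character(ts)) ts <- read_xyz(ts)
  endpoints <- reaction_endpoints(reactant, ts, baseline_barrier = ea)
  config <- milling_config(pressure = pressure, grid_n = grid_n,
                           delta_mode = delta_mode,
                           delta_constant = delta_constant,
                           radius_mode = radius_mode,
                           weight_scheme = weight_scheme)
  new_mill(endpoints, config, call = cl, label = label, inputs = inputs)
}

# Internal constructor shared by mill() and pressure_scan().
new_mill <- function(endpoints, config, path = NULL, call = NULL,
                     label = NULL, inputs = NULL) {
  map <- sweep_directions(endpoints, config, path = path)
  ea <- endpoints$baseline_barrier
  structure(
    list(endpoints = endpoints, config = config, alignment = map$alignment,
         map = map, average = map$average, extrema = map$extrema,
         ea = ea, ea_mec = if (!is.null(ea)) ea + map$average,
         label = label, inputs = inputs, call = call,
         version = as.character(utils::packageVersion("ballmill"))),
    class = "mill")
}

#' @export
print.mill <- function(x, digits = 4, ...) {
  cat("Wall-force ball-milling model",
      if (!is.null(x$label)) paste0("-- ", x$label), "\n")
  cat(sprintf("  %d atoms, P = %g GPa, N = %d (%d directions), delta = %s, radius = %s\n",
              n_atoms(x$endpoints$reactant), x$config$pressure,
              x$config$grid_n, 2L * x$config$grid_n^2, x$config$delta_mode,
              x$config$radius_mode))
  cat(sprintf("  <dEa,mec> = %+.*f kcal/mol  (range %+.*f to %+.*f)\n",
              digits, x$average, digits, x$extrema$min$value, digits,
              x$extrema$max$value))
  if (!is.null(x$ea)) {
    cat(sprintf("  Ea = %.*f -> Ea,mec = %.*f kcal/mol\n", digits, x$ea,
                digits, x$ea_mec))
  }
  invisible(x)
}

#' @export
summary.mill <- function(object, ...) {
  structure(list(fit = object), class = "summary.mill")
}

#' @export
print.summary.mill <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat("\nAlignment\n")
  cat(sprintf("  mass-weighted RMSD     : %.6f Angstrom\n",
              f$alignment$mw_rmsd))
  cat(sprintf("  residual net translation: %.2e amu Angstrom\n",
              f$alignment$residual_linear))
  cat(sprintf("  residual net rotation   : %.2e amu Angstrom^2\n",
              f$alignment$residual_angular))
  r <- f$map$radius
  cat("\nMolecular radius R(theta, phi)\n")
  if (length(r) == 1L) {
    cat(sprintf("  global R = %.4f Angstrom\n", r))
  } else {
    cat(sprintf("  min %.4f / mean %.4f / max %.4f Angstrom\n",
                min(r), mean(r), max(r)))
  }
  cat("\nMost favourable impact direction\n")
  cat(sprintf("  dEa,mec = %+.*f kcal/mol at theta = %.3f, phi = %.3f rad\n",
              digits, f$extrema$min$value, f$extrema$min$theta,
              f$extrema$min$phi))
  invisible(x)
}

#' @export
coef.mill <- function(object, ...) {
  out <- c(delta_ea_avg = object$average,
           delta_ea_min = object$extrema$min$value,
           delta_ea_max = object$extrema$max$value)
  if (!is.null(object$ea)) {
    out <- c(out, ea = object$ea, ea_mec = object$ea_mec)
  }
  out
}

#' Predict the average barrier change at other pressures
#'
#' The wall forces, and hence the mechanical work, are exactly linear in
#' the impact pressure, so the fitted average rescales as
#' \eqn{\langle\Delta E_{a,mec}\rangle(P) =
#' (P/P_0)\,\langle\Delta E_{a,mec}\rangle(P_0)} without re-sweeping the
#' grid. Use [pressure_scan()] to recompute full maps instead.
#'
#' @param object A fitted [mill()] model.
#' @param pressure Numeric vector of pressures in GPa.
#' @param ... Unused.
#' @return data.frame with columns `pressure`, `delta_ea_avg` and (when a
#'   baseline barrier is set) `ea_mec`.
#' @export
predict.mill <- function(object, pressure = object$config$pressure, ...) {
  stopifnot(all(pressure >= 0))
  p0 <- object$config$pressure
  if (p0 == 0) {
    avg <- ifelse(pressure == 0, 0, NA_real_)
    if (anyNA(avg)) {
      stop("cannot extrapolate from a zero-pressure fit; refit at P > 0")
    }
  } else {
    avg <- object$average * pressure / p0
  }
  out <- data.frame(pressure = pressure, delta_ea_avg = avg)
  if (!is.null(object$ea)) out$ea_mec <- object$ea + avg
  out
}

#' Plot the directional map of the barrier change
#'
#' Image of \eqn{\Delta E_{a,mec}(\theta, \phi)} over the angular grid with
#' a diverging palette centered at zero (blue: barrier lowered, i.e.
#' mechanically promoted directions).
#'
#' @param x A fitted [mill()] model or a `directional_map`.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.mill <- function(x, ...) {
  plot(x$map, main = x$label, ...)
  invisible(x)
}

#' @export
plot.directional_map <- function(x, main = NULL, ...) {
  z <- t(x$delta_ea)   # x axis: phi, y axis: theta
  lim <- max(abs(z), 1e-12)
  graphics::image(x$phis, x$thetas, z, zlim = c(-lim, lim),
                  col = grDevices::hcl.colors(64, "Blue-Red 2", rev = TRUE),
                  xlab = expression(phi ~ "(rad)"),
                  ylab = expression(theta ~ "(rad)"),
                  main = main %||%
                    sprintf("dEa,mec (kcal/mol), <avg> = %+.3f", x$average),
                  ...)
  invisible(x)
}

#' Scan a reaction over several impact pressures
#'
#' Shares one alignment across pressures and re-sweeps the grid at each
#' pressure (each pressure is computed independently, not rescaled).
#'
#' @param endpoints A [reaction_endpoints()] pair.
#' @param pressures Numeric vector of pressures in GPa (possibly empty).
#' @param config A [milling_config()]; its pressure field is overridden by
#'   each scan value.
#' @return An object of class `milling_scan`: list of [mill()]-class
#'   results, one per pressure.
#' @export
pressure_scan <- function(endpoints, pressures,
                          config = milling_config()) {
  stopifnot(inherits(endpoints, "reaction_endpoints"),
            all(pressures >= 0))
  path <- align_endpoints(endpoints)
  results <- lapply(pressures, function(p) {
    cfg <- config
    cfg$pressure <- p
    new_mill(endpoints, cfg, path = path)
  })
  structure(list(pressures = as.numeric(pressures), results = results),
            class = "milling_scan")
}

#' @export
print.milling_scan <- function(x, ...) {
  cat("Pressure scan:", length(x$pressures), "pressures\n")
  if (length(x$pressures)) print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.milling_scan <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  data.frame(pressure_gpa = x$pressures,
             delta_ea_avg = vapply(x$results, `[[`, numeric(1), "average"),
             delta_ea_min = vapply(x$results,
                                   function(r) r$extrema$min$value,
                                   numeric(1)),
             delta_ea_max = vapply(x$results,
                                   function(r) r$extrema$max$value,
                                   numeric(1)))
}

#' Compare the mechanical activation of two reaction pathways
#'
#' Reports the average and extremal barrier changes of two fitted models
#' computed under identical milling configurations, their difference, and
#' which pathway is mechanically favoured (the more negative average, i.e.
#' the larger barrier lowering). Typical uses: endo vs exo cycloaddition
#' pathways, or forward vs reverse reaction of an equilibrium (a "hot" vs
#' "cold" mechanochemical pair).
#'
#' @param a,b Fitted [mill()] models.
#' @param labels Length-2 character vector naming the pathways.
#' @param tol Averages closer than this (kcal/mol) are reported as no
#'   preference.
#' @return An object of class `milling_comparison`.
#' @export
compare_pathways <- function(a, b,
                             labels = c(a$label %||% "a", b$label %||% "b"),
                             tol = 0) {
  stopifnot(inherits(a, "mill"), inherits(b, "mill"))
  keys <- c("pressure", "grid_n", "delta_mode", "delta_constant",
            "radius_mode", "weight_scheme")
  if (!identical(a$config[keys], b$config[keys])) {
    stop("pathways were computed with different milling configurations; ",
         "refit with identical pressure/grid/delta/radius settings")
  }
  side <- function(x, lab) {
    list(label = lab, average = x$average,
         min = x$extrema$min$value, max = x$extrema$max$value,
         ea = x$ea, ea_mec = x$ea_mec)
  }
  diff <- a$average - b$average
  favored <- if (abs(diff) <= tol) "none" else if (diff < 0) labels[1L]
             else labels[2L]
  structure(list(a = side(a, labels[1L]), b = side(b, labels[2L]),
                 difference = diff, favored = favored,
                 config = a$config),
            class = "milling_comparison")
}

#' @export
print.milling_comparison <- function(x, digits = 4, ...) {
  cat("Pathway comparison at P =", x$config$pressure, "GPa\n")
  tab <- data.frame(
    pathway = c(x$a$label, x$b$label),
    delta_ea_avg = c(x$a$average, x$b$average),
    delta_ea_min = c(x$a$min, x$b$min),
    delta_ea_max = c(x$a$max, x$b$max))
  print(format(tab, digits = digits), row.names = FALSE)
  cat(sprintf("  difference (%s - %s): %+.*f kcal/mol\n", x$a$label,
              x$b$label, digits, x$difference))
  cat("  mechanically favored:",
      if (x$favored == "none") "no preference" else x$favored, "\n")
  invisible(x)
}
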