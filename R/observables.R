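#' Spatial profiles derived from a converged solution
#'
#' Evaluates every derived field of the model on the converged potential:
#' ion number densities, ionic and headgroup charge densities, and the
#' headgroup probability density (set to zero beyond x = D, outside its
#' support).
#'
#' @param state a converged `mlpb_solution`.
#' @param params parameters (defaults to those stored in `state`).
#' @return Object of class `mlpb_profiles` (a data frame, SI units):
#'   columns `x` (m), `phi` (V), `eps_r`, `n_plus`, `n_minus` (1/m^3),
#'   `rho_ions`, `rho_zw` (C/m^3), `prob_density`. Solver metadata
#'   (`params`, `lambda`, `iterations`, `residual`) is carried in
#'   attributes.
#' @export
extract_profiles <- function(state, params = state$params) {
  stopifnot(inherits(state, "mlpb_solution"))
  if (!isTRUE(state$converged))
    stop("profiles require a converged solution", call. = FALSE)
  x <- state$grid$x
  ions <- ion_number_densities(state$phi, params)
  prob <- numeric(length(x))
  rho_zw <- numeric(length(x))
  if (state$headgroup) {
    di <- state$grid$d_index
    p_hg <- headgroup_probability(x[seq_len(di)], state$phi[seq_len(di)],
                                  params)
    prob[seq_len(di)] <- as.numeric(p_hg)
    rho_zw <- headgroup_charge_density(prob, x, params)
  }
  out <- data.frame(
    x = x, phi = state$phi, eps_r = state$eps_r,
    n_plus = ions$n_plus, n_minus = ions$n_minus,
    rho_ions = ion_charge_density(state$phi, params),
    rho_zw = rho_zw, prob_density = prob
  )
  structure(out,
            class = c("mlpb_profiles", "data.frame"),
            params = params, lambda = state$lambda,
            iterations = state$iterations, residual = state$residual)
}

#' Average headgroup dipole orientation angle
#'
#' The headgroup dipole has fixed charge separation D, its negative charge
#' in the x = 0 plane and its positive charge at projected distance x, so
#' the angle to the membrane normal is `omega(x) = acos(x/D)`. Averaging
#' over the probability density with the same measure as its normalization
#' gives `<omega> = (1/D) int_0^D P(x) acos(x/D) dx`, reported in degrees.
#' A uniform density gives exactly 1 radian (57.2958 deg); densities piled
#' up near the plane (the usual case: the positive charge is attracted to
#' the negative plane) give larger angles, i.e. headgroups lying flatter.
#'
#' @param state a converged `mlpb_solution`.
#' @param params parameters (defaults to those stored in `state`).
#' @param form `"boltzmann"` (default) uses the point-like density even when
#'   `params$alpha` is set — the reference observable of the model —
#'   `"lattice"` uses the finite-volume form (requires `alpha`).
#' @param convention `"mean-angle"` (default) averages `omega(x)` directly;
#'   `"angle-of-mean-cosine"` averages `cos(omega) = x/D` first and returns
#'   `acos` of the mean, an alternative reduction of the same density.
#' @return Angle in degrees, in \[0, 90\].
#' @export
average_orientation_angle <- function(state, params = state$params,
                                      form = c("boltzmann", "lattice"),
                                      convention = c("mean-angle",
                                                     "angle-of-mean-cosine")) {
  stopifnot(inherits(state, "mlpb_solution"))
  if (!isTRUE(state$converged))
    stop("orientation angle requires a converged solution", call. = FALSE)
  form <- match.arg(form)
  convention <- match.arg(convention)
  di <- state$grid$d_index
  xs <- state$grid$x[seq_len(di)]
  alpha <- if (form == "lattice") {
    if (is.null(params$alpha))
      stop("form = 'lattice' requires params$alpha", call. = FALSE)
    params$alpha
  } else NULL
  prob <- headgroup_probability(xs, state$phi[seq_len(di)], params,
                                alpha = alpha)
  u <- pmin(xs / params$D, 1)
  if (convention == "mean-angle") {
    ang <- pracma::trapz(xs, as.numeric(prob) * acos(u)) / params$D
  } else {
    mean_cos <- pracma::trapz(xs, as.numeric(prob) * u) / params$D
    ang <- acos(min(max(mean_cos, 0), 1))
  }
  ang * 180 / pi
}

#' Temperature sweep across the DPPC phase transition
#'
#' Solves the model at each temperature with the area per lipid set by the
#' DPPC phase rule (gel a0 = 0.48 nm^2 below 314 K, liquid-crystalline
#' a0 = 0.60 nm^2 above; 314 K itself is excluded because the model has no
#' phase-transition physics) and records the scalar observables. Within a
#' phase the average orientation angle is essentially temperature
#' independent; the jump between phases comes entirely from the change in
#' area per lipid.
#'
#' @param base an [mlpb_parameters()] object supplying everything except T
#'   and a0.
#' @param T_values temperatures (K), none equal to 314.
#' @param n_nodes grid size per solve.
#' @param opts [solver_options()].
#' @return Object of class `mlpb_sweep` (a data frame): columns `T` (K),
#'   `a0_nm2`, `phase` ("gel"/"liquid"), `omega_deg`, `phi0_mV`,
#'   `eps_surface`, `eps_far`.
#' @export
temperature_sweep <- function(base, T_values, n_nodes = 4000,
                              opts = solver_options()) {
  stopifnot(inherits(base, "mlpb_params"), is.numeric(T_values),
            length(T_values) >= 1L)
  rows <- lapply(T_values, function(Tk) {
    a0 <- dppc_phase_area(Tk)  # errors at the 314 K transition gap
    p <- mlpb_parameters(T = Tk, a0 = a0, D = base$D * 1e9,
                         p0 = base$p0 / mlpb_constants()$debye,
                         salt = base$n0 / (1e3 * mlpb_constants()$N_A),
                         water = base$n0w / (1e3 * mlpb_constants()$N_A),
                         n_refr = base$n_refr, alpha = base$alpha,
                         L = base$L * 1e9)
    sol <- solve_mlpb(p, grid = build_grid(p, n_nodes), opts = opts)
    data.frame(
      T = Tk, a0_nm2 = a0,
      phase = if (Tk < 314) "gel" else "liquid",
      omega_deg = average_orientation_angle(sol),
      phi0_mV = sol$phi[1] * 1e3,
      eps_surface = sol$eps_r[1],
      eps_far = sol$eps_r[length(sol$eps_r)]
    )
  })
  structure(do.call(rbind, rows), class = c("mlpb_sweep", "data.frame"))
}

#' Headgroup probability density for a family of lattice parameters
#'
#' Evaluates the point-like Boltzmann density and one finite-volume lattice
#' density per requested `alpha` on the converged potential, all normalized
#' to unit mean over \[0, D\]. Small `alpha` reproduces the Boltzmann curve;
#' large `alpha` (close packing) flattens the density to 1. The spread
#' (max - min) therefore decreases monotonically with `alpha`.
#'
#' @param state a converged `mlpb_solution`.
#' @param alphas positive lattice parameters.
#' @param params parameters (defaults to those stored in `state`).
#' @return Data frame in long form: `x` (m), `curve` ("boltzmann" or
#'   "alpha=<value>"), `alpha` (NA for the Boltzmann curve), `prob_density`.
#' @export
probability_density_comparison <- function(state, alphas,
                                           params = state$params) {
  stopifnot(inherits(state, "mlpb_solution"), is.numeric(alphas),
            length(alphas) >= 1L)
  if (any(alphas <= 0)) stop("all alphas must be positive", call. = FALSE)
  if (!isTRUE(state$converged))
    stop("probability densities require a converged solution", call. = FALSE)
  di <- state$grid$d_index
  xs <- state$grid$x[seq_len(di)]
  phis <- state$phi[seq_len(di)]
  base <- data.frame(
    x = xs, curve = "boltzmann", alpha = NA_real_,
    prob_density = as.numeric(headgroup_probability(xs, phis, params,
                                                    alpha = NULL)))
  rows <- lapply(alphas, function(a) {
    data.frame(x = xs, curve = sprintf("alpha=%g", a), alpha = a,
               prob_density = as.numeric(headgroup_probability(xs, phis,
                                                               params,
                                                               alpha = a)))
  })
  do.call(rbind, c(list(base), rows))
}
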