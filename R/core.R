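#' Langevin function
#'
#' `L(u) = coth(u) - 1/u`, the mean alignment of a classical dipole of energy
#' `-p E cos(theta)` in thermal equilibrium. Odd, strictly increasing, and
#' bounded in (-1, 1). `coth(u) - 1/u` cancels catastrophically near zero, so
#' for |u| < 1e-2 the Taylor series `u/3 - u^3/45 + 2u^5/945 - u^7/4725` is
#' used: at the switch point its truncation error is below machine precision
#' while the naive difference has already lost about six digits.
#'
#' @param u dimensionless argument, any finite numeric vector.
#' @return Numeric vector of the same length, values in (-1, 1).
#' @examples
#' langevin(0)   # 0
#' langevin(1)   # 0.3130353
#' @export
langevin <- function(u) {
  stopifnot(is.numeric(u), all(is.finite(u)))
  out <- numeric(length(u))
  small <- abs(u) < 1e-2
  us <- u[small]
  out[small] <- us / 3 - us^3 / 45 + 2 * us^5 / 945 - us^7 / 4725
  ub <- u[!small]
  out[!small] <- 1 / tanh(ub) - 1 / ub
  out
}

#' Langevin ratio L(u)/u
#'
#' The ratio that enters the field-dependent permittivity; its u -> 0 limit is
#' 1/3 (the Onsager zero-field value). Series branch for |u| < 1e-2:
#' `1/3 - u^2/45 + 2u^4/945 - u^6/4725`.
#'
#' @param u dimensionless argument, finite numeric vector.
#' @return `langevin(u)/u` with the limit 1/3 at u = 0; strictly decreasing
#'   in |u|.
#' @export
langevin_ratio <- function(u) {
  stopifnot(is.numeric(u), all(is.finite(u)))
  out <- numeric(length(u))
  small <- abs(u) < 1e-2
  us <- u[small]
  out[small] <- 1 / 3 - us^2 / 45 + 2 * us^4 / 945 - us^6 / 4725
  ub <- u[!small]
  out[!small] <- (1 / tanh(ub) - 1 / ub) / ub
  out
}

#' Cavity-field factor gamma
#'
#' `gamma = (3/2) * (2 + n^2)/3`: the product of the Onsager cavity-field
#' enhancement `(2 + n^2)/3` for a dipole embedded in a sphere of permittivity
#' `n^2` and the 3/2 factor of the saturation regime.
#'
#' @param n_refr optical refractive index of water (>= 1).
#' @return Dimensionless factor.
#' @export
gamma_factor <- function(n_refr) {
  stopifnot(is.numeric(n_refr), all(n_refr >= 1))
  (3 / 2) * (2 + n_refr^2) / 3
}

#' Water polarization magnitude
#'
#' `P(E) = n0w * ((2 + n^2)/3) * p0 * L(gamma * p0 * E * beta)`: orientational
#' polarization of point-like water dipoles with the cavity-field correction.
#' Monotonically increasing in E, saturating at `n0w * ((2+n^2)/3) * p0`.
#'
#' @param E electric field magnitude (V/m), non-negative numeric vector.
#' @param params an [mlpb_parameters()] object.
#' @return Polarization magnitude (C/m^2).
#' @export
polarization <- function(E, params) {
  stopifnot(inherits(params, "mlpb_params"), all(E >= 0))
  g <- gamma_factor(params$n_refr)
  u <- g * params$p0 * E * params$beta
  params$n0w * ((2 + params$n_refr^2) / 3) * params$p0 * langevin(u)
}

#' Field-dependent relative permittivity of water
#'
#' The MLPB permittivity
#' `eps_r(E) = n^2 + (3/2) * ((2+n^2)/3)^2 * (n0w p0^2 beta / eps0) * L(u)/u`
#' with `u = gamma * p0 * E * beta`. Strictly decreasing in E: strong fields
#' saturate the dipole orientation (dielectric saturation) and the
#' permittivity falls toward the electronic contribution `n^2`. At E = 0 the
#' ratio L(u)/u takes its limit 1/3 and the expression reduces exactly to
#' [onsager_permittivity()].
#'
#' @param E electric field magnitude (V/m), non-negative numeric vector.
#' @param params an [mlpb_parameters()] object.
#' @return Dimensionless permittivity, bounded below by `n^2`.
#' @examples
#' p <- mlpb_parameters(T = 298)
#' relative_permittivity(0, p) # 78.5, bulk water at room temperature
#' @export
relative_permittivity <- function(E, params) {
  stopifnot(inherits(params, "mlpb_params"), all(E >= 0))
  g <- gamma_factor(params$n_refr)
  u <- g * params$p0 * E * params$beta
  cst <- mlpb_constants()
  params$n_refr^2 + (3 / 2) * ((2 + params$n_refr^2) / 3)^2 *
    params$n0w * params$p0^2 * params$beta / cst$eps0 * langevin_ratio(u)
}

#' Zero-field (Onsager) permittivity
#'
#' `eps = n^2 + ((2+n^2)/3)^2 * n0w * p0^2 * beta / (2 eps0)`: the bulk
#' dielectric constant of the model electrolyte, i.e. the E -> 0 limit of
#' [relative_permittivity()]. With p0 = 3.1 Debye, 55 mol/l water and
#' n = 1.33 it gives 78.5 at 298 K.
#'
#' @param params an [mlpb_parameters()] object.
#' @return Dimensionless permittivity.
#' @export
onsager_permittivity <- function(params) {
  stopifnot(inherits(params, "mlpb_params"))
  relative_permittivity(0, params)
}

#' Boltzmann ion number densities
#'
#' `n+ = n0 exp(-e0 phi beta)`, `n- = n0 exp(+e0 phi beta)` for a monovalent
#' symmetric electrolyte; the product is n0^2 for any potential.
#'
#' @param phi electric potential (V), finite numeric vector.
#' @param params an [mlpb_parameters()] object.
#' @return List with components `n_plus` and `n_minus` (1/m^3).
#' @export
ion_number_densities <- function(phi, params) {
  stopifnot(inherits(params, "mlpb_params"), is.numeric(phi),
            all(is.finite(phi)))
  u <- mlpb_constants()$e0 * phi * params$beta
  if (any(abs(u) > 700))
    stop("|e0*phi*beta| > 700: Boltzmann factor overflow, the solver state ",
         "producing this potential has diverged", call. = FALSE)
  list(n_plus = params$n0 * exp(-u), n_minus = params$n0 * exp(u))
}

#' Net ionic charge density
#'
#' `rho_ions = e0 (n+ - n-) = -2 e0 n0 sinh(e0 phi beta)`: odd in phi and of
#' opposite sign, so counter-ions dominate wherever the potential is nonzero.
#'
#' @inheritParams ion_number_densities
#' @return Charge density (C/m^3).
#' @export
ion_charge_density <- function(phi, params) {
  stopifnot(inherits(params, "mlpb_params"), is.numeric(phi),
            all(is.finite(phi)))
  cst <- mlpb_constants()
  u <- cst$e0 * phi * params$beta
  if (any(abs(u) > 700))
    stop("|e0*phi*beta| > 700: Boltzmann factor overflow, the solver state ",
         "producing this potential has diverged", call. = FALSE)
  -2 * cst$e0 * params$n0 * sinh(u)
}

#' Headgroup positive-charge probability density
#'
#' Probability density that the positive (choline) charge of a headgroup
#' dipole sits at projected distance x from the charged plane, normalized so
#' that its mean over the headgroup region is one: `(1/D) int_0^D P dx = 1`.
#'
#' Two forms are available. The point-like Boltzmann form
#' `P(x) = Lambda exp(-e0 phi beta)` ignores the headgroup volume; the
#' lattice-statistics form
#' `P(x) = Lambda * alpha exp(-e0 phi beta) / (alpha exp(-e0 phi beta) + 1)`
#' accounts for the finite headgroup volume through the ratio `alpha` and
#' saturates where the Boltzmann form diverges. As alpha -> 0 the lattice
#' form recovers the Boltzmann form; as alpha -> infinity (all lattice sites
#' occupied) it flattens to P = 1. In both cases the normalization constant
#' Lambda follows from the unit-mean condition by trapezoidal quadrature on
#' the supplied grid.
#'
#' @param x positions (m), increasing, spanning exactly \[0, D\].
#' @param phi electric potential at `x` (V), finite.
#' @param params an [mlpb_parameters()] object.
#' @param alpha overrides `params$alpha`; `NULL` and `params$alpha = NULL`
#'   select the Boltzmann form.
#' @return Numeric vector `P(x) >= 0` with attribute `"lambda"` holding the
#'   normalization constant.
#' @export
headgroup_probability <- function(x, phi, params, alpha = params$alpha) {
  stopifnot(inherits(params, "mlpb_params"), is.numeric(x), is.numeric(phi),
            length(x) == length(phi), length(x) >= 2L)
  if (!all(is.finite(phi))) stop("non-finite potential values", call. = FALSE)
  if (params$D <= 0) stop("D must be positive", call. = FALSE)
  D <- params$D
  if (abs(x[1]) > 1e-15 * D || abs(x[length(x)] - D) > 1e-9 * D)
    stop("x must span [0, D]", call. = FALSE)
  bf <- exp(-mlpb_constants()$e0 * phi * params$beta)
  if (is.null(alpha)) {
    shape <- bf
  } else {
    if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
    shape <- alpha * bf / (alpha * bf + 1)
  }
  lambda <- D / pracma::trapz(x, shape)
  structure(lambda * shape, lambda = lambda)
}

#' Headgroup volume charge density
#'
#' Smears the single positive charge e0 of each headgroup over the region
#' `0 < x <= D` according to the probability density:
#' `rho_Zw = e0 * P(x) / (D a0)` there and exactly zero beyond D. Its
#' integral over \[0, D\] is `e0/a0 = -sigma`, so the headgroup layer exactly
#' compensates the phosphate plane.
#'
#' @param prob probability density `P` evaluated at `x` (values beyond D are
#'   ignored).
#' @param x positions (m), `0 <= x <= L`.
#' @param params an [mlpb_parameters()] object.
#' @return Charge density (C/m^3) at each `x`.
#' @export
headgroup_charge_density <- function(prob, x, params) {
  stopifnot(inherits(params, "mlpb_params"), is.numeric(prob), is.numeric(x),
            length(prob) == length(x), all(x >= 0), all(x <= params$L))
  out <- numeric(length(x))
  inside <- x <= params$D
  out[inside] <- mlpb_constants()$e0 * prob[inside] / (params$D * params$a0)
  out
}
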