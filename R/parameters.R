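#' Model parameters for the MLPB headgroup-layer problem
#'
#' Collects all physical inputs of the modified Langevin-Poisson-Boltzmann
#' (MLPB) model of a planar zwitterionic lipid headgroup layer. Arguments are
#' given in the units experimentalists use (K, nm^2, nm, Debye, mol/l); the
#' returned object stores everything in SI, which is what every other function
#' in the package consumes.
#'
#' The negative phosphate charges of the headgroups form a charged plane at
#' x = 0 with surface charge density `sigma = -e0/a0`; the positive choline
#' charge of each headgroup is distributed over `0 < x <= D` by a probability
#' density (Boltzmann by default, finite-volume lattice form when `alpha` is
#' set).
#'
#' @param T temperature (K).
#' @param a0 area per lipid (nm^2). DPPC: 0.48 in the gel phase (T < 314 K),
#'   0.60 in the liquid-crystalline phase (T > 314 K).
#' @param D headgroup charge separation, i.e. P-N distance (nm).
#' @param p0 water dipole moment (Debye).
#' @param salt bulk salt concentration (mol/l), monovalent symmetric.
#' @param water bulk water concentration (mol/l).
#' @param n_refr optical refractive index of water (dimensionless).
#' @param alpha optional lattice-statistics volume-ratio parameter
#'   (dimensionless, > 0): ratio of the average headgroup volume to the
#'   average solution volume in the headgroup region. `NULL` (default)
#'   selects the point-like Boltzmann probability density.
#' @param L domain length (nm); the far boundary where the field vanishes.
#'
#' @return Object of class `mlpb_params`: list with SI fields `T`, `beta`
#'   (1/J), `a0` (m^2), `D` (m), `p0` (C m), `n0`, `n0w` (1/m^3), `n_refr`,
#'   `alpha`, `L` (m), and `sigma` (C/m^2).
#' @seealso [mlpb_preset()] for the DPPC parameter sets, [solve_mlpb()].
#' @examples
#' p <- mlpb_parameters(T = 310, a0 = 0.48)
#' p$sigma # about -0.33 C/m^2
#' @export
mlpb_parameters <- function(T = 310, a0 = 0.48, D = 0.42, p0 = 3.1,
                            salt = 0.1, water = 55, n_refr = 1.33,
                            alpha = NULL, L = 12) {
  for (nm in c("T", "a0", "D", "p0", "salt", "water", "n_refr", "L")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  if (T <= 0) stop("parameter 'T' must be positive (kelvin)", call. = FALSE)
  if (T < 200) warning("T = ", T, " K is outside the plausible range for ",
                       "aqueous electrolytes", call. = FALSE)
  if (a0 <= 0) stop("parameter 'a0' must be positive", call. = FALSE)
  if (D <= 0) stop("parameter 'D' must be positive", call. = FALSE)
  if (p0 <= 0) stop("parameter 'p0' must be positive", call. = FALSE)
  if (salt < 0) stop("parameter 'salt' must be non-negative", call. = FALSE)
  if (water <= 0) stop("parameter 'water' must be positive", call. = FALSE)
  if (n_refr < 1) stop("parameter 'n_refr' must be >= 1", call. = FALSE)
  if (L <= D) stop("domain length 'L' must exceed the charge separation 'D'",
                   call. = FALSE)
  if (!is.null(alpha)) {
    if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
        alpha <= 0)
      stop("parameter 'alpha' must be a single positive number or NULL",
           call. = FALSE)
  }
  cst <- mlpb_constants()
  structure(list(
    T      = T,
    beta   = 1 / (cst$kB * T),
    a0     = a0 * 1e-18,
    D      = D * 1e-9,
    p0     = p0 * cst$debye,
    n0     = .mol_per_l_to_m3(salt),
    n0w    = .mol_per_l_to_m3(water),
    n_refr = n_refr,
    alpha  = alpha,
    L      = L * 1e-9,
    sigma  = -cst$e0 / (a0 * 1e-18)
  ), class = "mlpb_params")
}

#' DPPC parameter presets
#'
#' The two reference parameter sets for a DPPC lipid layer: gel phase
#' (T = 310 K, a0 = 0.48 nm^2) and liquid-crystalline phase (T = 323 K,
#' a0 = 0.60 nm^2), both with D = 0.42 nm, p0 = 3.1 Debye, 0.1 mol/l salt,
#' 55 mol/l water, n = 1.33, L = 12 nm.
#'
#' @param name `"dppc-gel"` or `"dppc-liquid"`.
#' @param ... overrides passed on to [mlpb_parameters()] (e.g. `alpha`).
#' @return An `mlpb_params` object.
#' @examples
#' mlpb_preset("dppc-liquid")$T
#' @export
mlpb_preset <- function(name = c("dppc-gel", "dppc-liquid"), ...) {
  name <- match.arg(name)
  if (name == "dppc-gel") mlpb_parameters(T = 310, a0 = 0.48, ...)
  else mlpb_parameters(T = 323, a0 = 0.60, ...)
}

#' Area per lipid from the DPPC phase rule
#'
#' DPPC is in the gel phase below the main transition at 314 K (a0 = 0.48
#' nm^2) and in the liquid-crystalline phase above it (a0 = 0.60 nm^2). The
#' transition temperature itself is excluded: the model contains no phase
#' transition physics, so no single parameter set applies there.
#'
#' @param T temperature (K), scalar.
#' @return Area per lipid in nm^2.
#' @export
dppc_phase_area <- function(T) {
  stopifnot(is.numeric(T), length(T) == 1L, is.finite(T))
  if (T == 314)
    stop("T = 314 K is the DPPC gel/liquid transition temperature; ",
         "the model excludes the transition point (choose T < 314 or T > 314)",
         call. = FALSE)
  if (T < 314) 0.48 else 0.60
}

#' @export
print.mlpb_params <- function(x, ...) {
  cat("MLPB model parameters\n")
  cat(sprintf("  T      = %g K\n", x$T))
  cat(sprintf("  a0     = %g nm^2   (sigma = %.4g C/m^2)\n",
              x$a0 * 1e18, x$sigma))
  cat(sprintf("  D      = %g nm\n", x$D * 1e9))
  cat(sprintf("  p0     = %g Debye\n", x$p0 / mlpb_constants()$debye))
  cat(sprintf("  salt   = %g mol/l, water = %g mol/l\n",
              x$n0 / (1e3 * mlpb_constants()$N_A),
              x$n0w / (1e3 * mlpb_constants()$N_A)))
  cat(sprintf("  n      = %g, L = %g nm\n", x$n_refr, x$L * 1e9))
  if (!is.null(x$alpha))
    cat(sprintf("  alpha  = %g (lattice headgroup statistics)\n", x$alpha))
  invisible(x)
}
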