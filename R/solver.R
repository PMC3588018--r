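#' Solver options for the MLPB fixed-point iteration
#'
#' @param max_iter outer iteration cap.
#' @param damping relaxation factor in (0, 1] applied to each update; 0.25 is
#'   robust for all the DPPC parameter sets, larger values converge faster
#'   but can overshoot in the saturation regime.
#' @param tol convergence criterion: maximum node-wise potential update per
#'   sweep (V).
#' @param verbose print the residual every 25 sweeps.
#' @return Object of class `mlpb_solver_options`.
#' @export
solver_options <- function(max_iter = 10000L, damping = 0.25, tol = 1e-9,
                           verbose = FALSE) {
  stopifnot(max_iter >= 1, damping > 0, damping <= 1, tol > 0)
  structure(list(max_iter = as.integer(max_iter), damping = damping,
                 tol = tol, verbose = isTRUE(verbose)),
            class = "mlpb_solver_options")
}

#' Solve the MLPB boundary-value problem
#'
#' Solves the nonlinear Poisson problem
#' `d/dx[eps0 eps_r(E) dphi/dx] = 2 e0 n0 sinh(e0 phi beta) - rho_Zw(phi)`
#' on \[0, L\] with the surface-charge flux condition
#' `eps0 eps_r(0) phi'(0) = -sigma` at the phosphate plane and `phi'(L) = 0`
#' at the far boundary. The permittivity `eps_r` depends on the local field
#' through Langevin dielectric saturation, and the headgroup source term
#' `rho_Zw = e0 P(x)/(D a0)` depends on `phi` through the normalized
#' probability density, so the problem is solved self-consistently:
#'
#' * conservative finite-volume discretization with `eps_r` evaluated at
#'   cell faces (flux continuity at x = D holds by construction);
#' * damped Picard outer iteration: each sweep freezes `eps_r(E)` and the
#'   normalization `Lambda` at the current iterate, Newton-linearizes the
#'   `sinh` term, and solves the resulting tridiagonal system (sparse LU);
#' * the flux boundary condition enters as the known boundary flux `-sigma`,
#'   so the field-dependent `eps_r(0)` is implicit and needs no special
#'   treatment.
#'
#' The iteration starts from `phi = 0` (so `eps_r` starts at the Onsager
#' value and `Lambda = 1`) and stops when the largest node update falls
#' below `opts$tol`. Everything is deterministic: identical inputs give
#' bit-identical output.
#'
#' @param params an [mlpb_parameters()] object. If `params$alpha` is set the
#'   lattice-statistics headgroup density is used in the source term.
#' @param grid an [build_grid()] grid (defaults to 4000 nodes).
#' @param opts a [solver_options()] object.
#' @param headgroup logical; `FALSE` removes the headgroup source term
#'   (pure salt screening of the bare charged plane).
#' @param freeze_permittivity optional number; when given, `eps_r` is held
#'   constant at this value (classical Poisson-Boltzmann), used for
#'   validation against the Gouy-Chapman closed form.
#' @param sigma optional surface charge density override (C/m^2); defaults
#'   to `params$sigma = -e0/a0`.
#' @return Object of class `mlpb_solution`: list with `grid`, `phi` (V),
#'   `efield` (V/m, node values of |phi'|), `eps_r` (node values),
#'   `lambda` (headgroup normalization constant), `converged`, `iterations`,
#'   `residual` (final max |delta phi|, V), `residual_history`, and the
#'   echoed `params`, `opts`, `headgroup`, `sigma`.
#' @examples
#' \donttest{
#' sol <- solve_mlpb(mlpb_preset("dppc-gel"))
#' round(sol$eps_r[1])        # 44: strong dielectric saturation at the plane
#' round(sol$phi[1] * 1e3)    # about -60 mV
#' }
#' @export
solve_mlpb <- function(params, grid = build_grid(params),
                       opts = solver_options(), headgroup = TRUE,
                       freeze_permittivity = NULL, sigma = NULL) {
  stopifnot(inherits(params, "mlpb_params"), inherits(grid, "mlpb_grid"),
            inherits(opts, "mlpb_solver_options"))
  cst <- mlpb_constants()
  x <- grid$x
  N <- length(x)
  if (is.null(sigma)) sigma <- params$sigma
  h <- diff(x)                                   # face spacings, length N-1
  w <- c(h[1] / 2, (h[-1] + h[-(N - 1)]) / 2, h[N - 1] / 2)  # control volumes
  di <- grid$d_index
  idx_hg <- seq_len(di)                          # nodes in [0, D]
  x_hg <- x[idx_hg]
  eb <- cst$e0 * params$beta
  phi <- numeric(N)
  lambda <- 1
  hist <- numeric(0)
  converged <- FALSE
  delta_max <- NA_real_

  for (it in seq_len(opts$max_iter)) {
    if (any(abs(eb * phi) > 700))
      stop("Boltzmann factor overflow during iteration ", it,
           ": the fixed point diverged; reduce 'damping'", call. = FALSE)
    e_face <- abs(diff(phi)) / h
    eps_face <- if (is.null(freeze_permittivity))
      relative_permittivity(e_face, params)
    else rep.int(freeze_permittivity, N - 1L)
    a <- cst$eps0 * eps_face / h                 # face conductances

    s  <- 2 * cst$e0 * params$n0 * sinh(eb * phi)
    ds <- 2 * cst$e0 * params$n0 * eb * cosh(eb * phi)
    rhs_hg <- numeric(N)
    if (headgroup) {
      prob <- headgroup_probability(x_hg, phi[idx_hg], params)
      lambda <- attr(prob, "lambda")
      rhs_hg[idx_hg] <- -cst$e0 * prob / (params$D * params$a0)
    }

    # tridiagonal rows: a_lo*phi[i-1] + a_di*phi[i] + a_up*phi[i+1] = b
    a_lo <- c(0, a)
    a_up <- c(a, 0)
    a_di <- -(a_lo + a_up) - w * ds
    b <- w * (s - ds * phi + rhs_hg)
    b[1] <- b[1] - sigma                         # boundary flux at x = 0
    # (far boundary flux is zero: nothing to add at row N)

    A <- Matrix::bandSparse(N, N, k = -1:1,
                            diagonals = list(a_lo[-1], a_di, a_up[-N]))
    phi_new <- as.numeric(Matrix::solve(A, b))
    delta <- phi_new - phi
    delta_max <- max(abs(delta))
    hist <- c(hist, delta_max)
    phi <- phi + opts$damping * delta
    if (opts$verbose && it %% 25L == 0L)
      message(sprintf("sweep %4d: max |delta phi| = %.3e V", it, delta_max))
    if (delta_max < opts$tol) { converged <- TRUE; break }
  }
  if (!converged) {
    tail_res <- paste(sprintf("%.3e", utils::tail(hist, 5)), collapse = ", ")
    stop("MLPB fixed point did not converge in ", opts$max_iter,
         " sweeps; last residuals (V): ", tail_res,
         ". Try stronger damping or a better-conditioned parameter set.",
         call. = FALSE)
  }

  e_face <- abs(diff(phi)) / h
  efield <- c(e_face[1], (e_face[-1] + e_face[-(N - 1)]) / 2,
              e_face[N - 1])
  eps_r <- if (is.null(freeze_permittivity)) relative_permittivity(efield, params)
           else rep.int(freeze_permittivity, N)
  if (headgroup) {
    prob <- headgroup_probability(x_hg, phi[idx_hg], params)
    lambda <- attr(prob, "lambda")
  }
  structure(list(
    grid = grid, phi = phi, efield = efield, eps_r = eps_r,
    lambda = lambda, converged = converged, iterations = length(hist),
    residual = delta_max, residual_history = hist,
    params = params, opts = opts, headgroup = headgroup, sigma = sigma,
    freeze_permittivity = freeze_permittivity
  ), class = "mlpb_solution")
}

#' @export
print.mlpb_solution <- function(x, ...) {
  cat("MLPB solution\n")
  cat(sprintf("  %d nodes, %d sweeps, final max |delta phi| = %.2e V\n",
              x$grid$n_nodes, x$iterations, x$residual))
  cat(sprintf("  phi(0)   = %.2f mV\n", x$phi[1] * 1e3))
  cat(sprintf("  eps_r(0) = %.2f,  eps_r(L) = %.2f\n",
              x$eps_r[1], x$eps_r[length(x$eps_r)]))
  cat(sprintf("  Lambda   = %.4f\n", x$lambda))
  invisible(x)
}

#' Gouy-Chapman reference potential
#'
#' Closed-form potential of the classical constant-permittivity
#' Poisson-Boltzmann problem for a bare charged plane in a monovalent
#' symmetric electrolyte:
#' `phi(x) = (2 kT / e0) log[(1 + g exp(-kappa x)) / (1 - g exp(-kappa x))]`
#' with `kappa` the inverse Debye length and `g = tanh(e0 phi0 beta / 4)`,
#' where the surface potential `phi0` follows from the Grahame equation
#' `sigma = sqrt(8 n0 eps eps0 kT) sinh(e0 phi0 beta / 2)`. Used as the
#' analytic oracle for the solver with the permittivity frozen and the
#' headgroup term off.
#'
#' @param params an [mlpb_parameters()] object (supplies T, n0, sigma).
#' @param eps_const the constant relative permittivity.
#' @param x positions at which to evaluate (m).
#' @param sigma optional surface charge density override (C/m^2).
#' @return Potential (V) at `x`.
#' @export
gouy_chapman_reference <- function(params, eps_const, x, sigma = NULL) {
  stopifnot(inherits(params, "mlpb_params"), eps_const > 0, all(x >= 0))
  cst <- mlpb_constants()
  if (is.null(sigma)) sigma <- params$sigma
  if (sigma == 0) return(numeric(length(x)))
  eb <- cst$e0 * params$beta
  kappa <- sqrt(2 * params$n0 * cst$e0^2 * params$beta / (eps_const * cst$eps0))
  phi0 <- (2 / eb) * asinh(sigma /
            sqrt(8 * params$n0 * eps_const * cst$eps0 / params$beta))
  g <- tanh(eb * phi0 / 4)
  (2 / eb) * log((1 + g * exp(-kappa * x)) / (1 - g * exp(-kappa * x)))
}

#' Debye screening length
#'
#' `lambda_D = sqrt(eps eps0 kT / (2 n0 e0^2))` for a monovalent symmetric
#' electrolyte.
#'
#' @param params an [mlpb_parameters()] object.
#' @param eps_const relative permittivity to use (defaults to the Onsager
#'   bulk value for the parameter set).
#' @return Debye length (m).
#' @export
debye_length <- function(params, eps_const = onsager_permittivity(params)) {
  cst <- mlpb_constants()
  sqrt(eps_const * cst$eps0 / (2 * params$n0 * cst$e0^2 * params$beta))
}

#' Residual diagnostics of a converged solution
#'
#' Re-evaluates the discrete equations at the converged potential and
#' reports how well the solution satisfies them:
#'
#' * `max_residual`: largest control-volume imbalance of the discrete
#'   divergence equation, normalized by the boundary flux |sigma| (so it is
#'   the fraction of the surface charge unaccounted for in the worst cell);
#' * `flux_jump_at_D`: relative mismatch of the dielectric displacement
#'   across the headgroup boundary node;
#' * `bc_mismatch_surface`: relative error of
#'   `eps0 eps_r(0) phi'(0) + sigma = 0` with the converged `eps_r(0)`;
#' * `bc_mismatch_far`: |phi'(L)| * L / |phi(0)|, the far-boundary flux
#'   relative to the solution scale;
#' * `charge_balance`: `|sigma + int (rho_Zw + rho_ions) dx| / |sigma|`,
#'   the global electroneutrality defect (Gauss's law forces this to cancel
#'   exactly in the continuum).
#'
#' @param state an `mlpb_solution`.
#' @param params parameters (defaults to those stored in `state`).
#' @return Named list of diagnostics (all dimensionless).
#' @export
residual_diagnostics <- function(state, params = state$params) {
  stopifnot(inherits(state, "mlpb_solution"))
  cst <- mlpb_constants()
  x <- state$grid$x; phi <- state$phi; N <- length(x)
  h <- diff(x)
  sigma <- state$sigma
  e_face <- abs(diff(phi)) / h
  eps_face <- if (is.null(state$freeze_permittivity))
    relative_permittivity(e_face, params)
  else rep.int(state$freeze_permittivity, N - 1L)
  flux <- cst$eps0 * eps_face * diff(phi) / h    # signed face fluxes
  rho_ions <- ion_charge_density(phi, params)
  rho_zw <- numeric(N)
  if (state$headgroup) {
    di <- state$grid$d_index
    prob <- headgroup_probability(x[seq_len(di)], phi[seq_len(di)], params)
    rho_zw[seq_len(di)] <- cst$e0 * prob / (params$D * params$a0)
  }
  rhs <- -rho_ions - rho_zw                      # d/dx[eps0 eps_r phi'] = -rho
  w <- c(h[1] / 2, (h[-1] + h[-(N - 1)]) / 2, h[N - 1] / 2)
  div <- (c(flux, 0) - c(-sigma, flux)) / w      # boundary fluxes inserted
  resid <- div - rhs                             # C/m^3 imbalance per cell
  scale <- max(abs(sigma), .Machine$double.eps)
  net_charge <- pracma::trapz(x, rho_ions + rho_zw)
  list(
    max_residual = max(abs(resid * w)) / scale,
    flux_jump_at_D = {
      di <- state$grid$d_index
      abs(flux[di] - flux[di - 1L]) / max(abs(flux[di - 1L]), scale)
    },
    bc_mismatch_surface = abs(cst$eps0 * state$eps_r[1] *
                                (phi[2] - phi[1]) / h[1] + sigma) / scale,
    bc_mismatch_far = abs((phi[N] - phi[N - 1]) / h[N - 1]) * params$L /
      max(abs(phi[1]), .Machine$double.eps),
    charge_balance = abs(sigma + net_charge) / scale
  )
}
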