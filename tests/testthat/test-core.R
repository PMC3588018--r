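# Pointwise physics: Langevin saturation, permittivity, ion statistics,
# headgroup probability density.

test_that("langevin matches high-precision values and stays stable near 0", {
  expect_identical(langevin(0), 0)
  # mpmath, 30 digits
  expect_equal(langevin(1), 0.313035285499331, tolerance = 1e-14)
  expect_equal(langevin(10), 0.900000004122307, tolerance = 1e-14)
  # agreement with the naive formula away from the cancellation region
  u <- c(seq(1e-3, 1, length.out = 50), seq(1, 50, length.out = 50))
  expect_true(max(abs(langevin(u) - (1 / tanh(u) - 1 / u))) < 1e-12)
  # continuity across the series/closed-form switch at |u| = 1e-2
  lo <- langevin(1e-2 * (1 - 1e-9))
  hi <- langevin(1e-2 * (1 + 1e-9))
  expect_equal(lo, hi, tolerance = 1e-8)
})

test_that("langevin is odd, increasing, and bounded in (-1, 1)", {
  u <- seq(-40, 40, length.out = 401)
  lv <- langevin(u)
  expect_equal(lv, -langevin(-u), tolerance = 1e-15)
  expect_true(all(diff(lv) > 0))
  expect_true(all(abs(lv) < 1))
  # ratio limit
  expect_equal(langevin_ratio(0), 1 / 3, tolerance = 1e-15)
  expect_true(all(diff(langevin_ratio(seq(0, 30, length.out = 100))) < 0))
})

test_that("cavity-field factor", {
  expect_equal(gamma_factor(1.33), 1.884450, tolerance = 1e-6)
  expect_equal(gamma_factor(1), 1.5)
  expect_equal(gamma_factor(sqrt(7)), 4.5)
})

test_that("polarization saturates and matches scalar high-precision check", {
  p <- mlpb_parameters(T = 298)
  expect_identical(polarization(0, p), 0)
  E <- 10^seq(5, 10, length.out = 30)
  P <- polarization(E, p)
  expect_true(all(diff(P) > 0))
  sat <- p$n0w * ((2 + p$n_refr^2) / 3) * p$p0
  expect_lt(P[length(P)], sat)
  expect_equal(polarization(1e12, p) / sat, 1, tolerance = 1e-3)
  # mpmath evaluation of the closed form at E = 1e8 V/m, 298 K
  expect_equal(polarization(1e8, p), 0.0669339881331281, tolerance = 1e-12)
})

test_that("field-dependent permittivity: Onsager limit, saturation, bounds", {
  p298 <- mlpb_parameters(T = 298)
  # zero-field value is the bulk dielectric constant of water
  expect_equal(relative_permittivity(0, p298), 78.5, tolerance = 7e-4)
  expect_identical(relative_permittivity(0, p298), onsager_permittivity(p298))
  # mpmath: Onsager values at the three study temperatures
  expect_equal(onsager_permittivity(p298), 78.4880483328255, tolerance = 1e-12)
  expect_equal(onsager_permittivity(mlpb_parameters(T = 310)),
               75.5182748489742, tolerance = 1e-12)
  expect_equal(onsager_permittivity(mlpb_parameters(T = 323, a0 = 0.60)),
               72.5500337559815, tolerance = 1e-12)
  # mpmath evaluation of the full expression at E = 1e7 V/m, 310 K
  expect_equal(relative_permittivity(1e7, mlpb_parameters(T = 310)),
               75.5080855952337, tolerance = 1e-12)
  # huge fields strip the orientational part, leaving n^2
  expect_equal(relative_permittivity(1e15, p298), p298$n_refr^2,
               tolerance = 1e-3)
  # strictly decreasing, bounded below by n^2
  E <- 10^seq(4, 11, length.out = 200)
  er <- relative_permittivity(E, p298)
  expect_true(all(diff(er) < 0))
  expect_true(all(er > p298$n_refr^2))
  # vanishing dipole moment leaves only the electronic response
  tiny <- mlpb_parameters(T = 298, p0 = 1e-6)
  expect_equal(onsager_permittivity(tiny), tiny$n_refr^2, tolerance = 1e-9)
  # continuity at the series switch point of L(u)/u
  p <- p298
  E_switch <- 1e-2 / (gamma_factor(p$n_refr) * p$p0 * p$beta)
  lo <- relative_permittivity(E_switch * (1 - 1e-9), p)
  hi <- relative_permittivity(E_switch * (1 + 1e-9), p)
  expect_equal(lo, hi, tolerance = 1e-9)
})

test_that("Boltzmann ion densities: product invariant and scalar checks", {
  p <- mlpb_parameters(T = 310)
  d0 <- ion_number_densities(0, p)
  expect_identical(d0$n_plus, p$n0)
  expect_identical(d0$n_minus, p$n0)
  cst <- mlpb_constants()
  kT_over_e <- 1 / (cst$e0 * p$beta)
  d1 <- ion_number_densities(-kT_over_e, p)
  expect_equal(d1$n_plus, p$n0 * exp(1), tolerance = 1e-14)
  expect_equal(d1$n_minus, p$n0 / exp(1), tolerance = 1e-14)
  # e0 * 0.060 / (kB * 310), evaluated with mpmath
  d2 <- ion_number_densities(-0.060, p)
  expect_equal(d2$n_plus / p$n0, exp(2.24603576546131), tolerance = 1e-12)
  # n+ n- = n0^2 for any potential
  phi <- seq(-0.2, 0.2, length.out = 101)
  dd <- ion_number_densities(phi, p)
  expect_equal(dd$n_plus * dd$n_minus, rep(p$n0^2, 101), tolerance = 1e-14)
  expect_error(ion_number_densities(1e6, p), "overflow")
})

test_that("ionic charge density is odd and linearizes to Debye-Huckel", {
  p <- mlpb_parameters(T = 310)
  expect_identical(ion_charge_density(0, p), 0)
  phi <- seq(-0.1, 0.1, length.out = 41)
  expect_equal(ion_charge_density(phi, p), -ion_charge_density(-phi, p),
               tolerance = 1e-14)
  expect_true(all(ion_charge_density(phi[phi < 0], p) > 0))
  cst <- mlpb_constants()
  # small potentials: rho ~ -2 e0 n0 (e0 phi beta), error O(u^2) relative
  phis <- 1e-2 / (cst$e0 * p$beta)  # u = 0.01
  lin <- -2 * cst$e0 * p$n0 * cst$e0 * phis * p$beta
  expect_equal(ion_charge_density(phis, p) / lin, 1, tolerance = 1e-4)
})

test_that("headgroup probability density normalizes and matches closed form", {
  p <- mlpb_preset("dppc-gel")
  x <- seq(0, p$D, length.out = 2001)
  # flat potential: uniform density with Lambda = 1 (both forms)
  pr0 <- headgroup_probability(x, rep(0, length(x)), p)
  expect_equal(as.numeric(pr0), rep(1, length(x)), tolerance = 1e-14)
  expect_equal(attr(pr0, "lambda"), 1, tolerance = 1e-14)
  pr0a <- headgroup_probability(x, rep(0, length(x)), p, alpha = 2)
  expect_equal(as.numeric(pr0a), rep(1, length(x)), tolerance = 1e-14)
  # linear potential: analytic exponential normalization
  cst <- mlpb_constants()
  c_slope <- -0.05 / p$D                 # phi = c*x, -50 mV across D
  k <- cst$e0 * c_slope * p$beta
  pr <- headgroup_probability(x, c_slope * x, p)
  lambda_exact <- p$D * k / (1 - exp(-k * p$D))
  expect_equal(attr(pr, "lambda"), lambda_exact, tolerance = 1e-6)
  expect_equal(as.numeric(pr), lambda_exact * exp(-k * x), tolerance = 1e-6)
})

test_that("probability density properties hold for arbitrary potentials", {
  p <- mlpb_preset("dppc-gel")
  x <- seq(0, p$D, length.out = 1501)
  for (phi in random_phi_profiles(x)) {
    for (a in list(NULL, 0.5, 5)) {
      pr <- headgroup_probability(x, phi, p, alpha = a)
      expect_true(all(pr >= 0))
      expect_equal(pracma::trapz(x, as.numeric(pr)) / p$D, 1,
                   tolerance = 1e-8)
    }
    # lattice form recovers the Boltzmann form as alpha -> 0
    pb <- as.numeric(headgroup_probability(x, phi, p, alpha = NULL))
    pl <- as.numeric(headgroup_probability(x, phi, p, alpha = 1e-8))
    expect_equal(pl, pb, tolerance = 1e-6)
    # and flattens to 1 as alpha -> infinity
    pf <- as.numeric(headgroup_probability(x, phi, p, alpha = 1e8))
    expect_equal(pf, rep(1, length(x)), tolerance = 1e-6)
  }
  expect_error(headgroup_probability(x, x * NA_real_, p), "non-finite")
  expect_error(headgroup_probability(x, numeric(length(x)), p, alpha = -1),
               "alpha")
})

test_that("headgroup charge density smears e0 per lipid over [0, D]", {
  p <- mlpb_preset("dppc-gel")
  cst <- mlpb_constants()
  x <- seq(0, p$L, length.out = 3001)
  uniform <- as.numeric(x <= p$D)
  rho <- headgroup_charge_density(uniform, x, p)
  expect_equal(rho[x <= p$D & x > 0][1], cst$e0 / (p$D * p$a0),
               tolerance = 1e-14)
  expect_true(all(rho[x > p$D] == 0))
  # any normalized density integrates to e0/a0 = -sigma
  xs <- seq(0, p$D, length.out = 2001)
  phi <- -0.06 * exp(-xs / (0.3 * p$D))
  pr <- headgroup_probability(xs, phi, p)
  rho_hg <- headgroup_charge_density(as.numeric(pr), xs, p)
  expect_equal(pracma::trapz(xs, rho_hg), cst$e0 / p$a0, tolerance = 1e-8)
  expect_equal(pracma::trapz(xs, rho_hg), -p$sigma, tolerance = 1e-8)
})
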