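test_that("energy and stress vanish in the undeformed, undamaged reference", {
  p <- table1_params()
  expect_equal(strain_energy(p, diag(3)), 0, tolerance = 1e-12)
  expect_equal(max(abs(cauchy_stress(p, diag(3)))), 0, tolerance = 1e-12)
})

test_that("non-positive Jacobians are rejected", {
  p <- table1_params()
  expect_error(deformation_point(diag(c(-1, 1, 1)), p), "det\\(F\\)")
  expect_error(strain_energy(p, diag(c(1, 0, 1))), "det\\(F\\)")
})

test_that("energy matches an independently written evaluation", {
  p <- table1_params()
  # equibiaxial stretch, isochoric
  lam <- 1.05
  Feb <- diag(c(lam, lam, 1 / lam^2))
  expect_equal(strain_energy(p, Feb), oracle_energy(Feb, p),
               tolerance = 1e-12)
  # frozen value from the oracle (independent arithmetic, Table 1, D = 0)
  expect_equal(strain_energy(p, Feb), 18.9029532, tolerance = 1e-6)
  # a handful of random deformations, with and without damage
  set.seed(42)
  for (k in 1:5) {
    Fr <- diag(3) + matrix(rnorm(9, sd = 0.06), 3)
    if (det(Fr) <= 0) next
    D <- runif(2, 0, 0.5)
    st <- damage_state(D = D, beta_hist = c(1, 1))
    expect_equal(strain_energy(p, Fr, st), oracle_energy(Fr, p, D),
                 tolerance = 1e-10)
  }
})

test_that("raising damage strictly lowers the energy when fibers are loaded", {
  p <- table1_params()
  Fs <- diag(c(1.1, 1, 1 / 1.1))
  psi0 <- strain_energy(p, Fs, damage_state())
  psi1 <- strain_energy(p, Fs, damage_state(D = c(p$D_inf, p$D_inf),
                                            beta_hist = c(10, 10)))
  expect_lt(psi1, psi0)
})

test_that("Cauchy stress is the push-forward derivative of the energy", {
  p <- table1_params()
  set.seed(7)
  for (k in 1:4) {
    Fr <- diag(3) + matrix(rnorm(9, sd = 0.05), 3)
    if (det(Fr) <= 0) next
    st <- damage_state(D = c(0.1, 0.25), beta_hist = c(2, 4))
    sig <- cauchy_stress(p, Fr, st)
    expect_equal(sig, t(sig), tolerance = 1e-12)
    # central finite differences of psi wrt F give the 1st PK stress
    P <- matrix(0, 3, 3)
    h <- 1e-6
    for (i in 1:3) for (j in 1:3) {
      Fp <- Fr; Fp[i, j] <- Fp[i, j] + h
      Fm <- Fr; Fm[i, j] <- Fm[i, j] - h
      P[i, j] <- (strain_energy(p, Fp, st) - strain_energy(p, Fm, st)) / (2 * h)
    }
    sig_fd <- P %*% t(Fr) / det(Fr)
    sig_fd <- (sig_fd + t(sig_fd)) / 2
    expect_equal(sig, sig_fd, tolerance = 1e-5)
  }
})

test_that("fiber-free incompressible uniaxial stress matches Neo-Hooke", {
  # alpha1 ~ 0 removes the fibers; solve the lateral stretch so the lateral
  # stress vanishes, then sigma_axial = 2*c1*(lam^2 - 1/lam)
  pn <- material_params(c1 = 9.02, eps1 = 499.8, eps2 = 2.4, alpha1 = 1e-12,
                        alpha2 = 2.2, kappa = 1e-8, beta_f = 39.87,
                        D_inf = 0, gamma_inf = 11, beta_s = 0.06)
  lam <- 1.1
  lat <- uniroot(function(l) cauchy_stress(pn, diag(c(lam, l, l)))[2, 2],
                 c(0.8, 1.05), tol = 1e-14)$root
  sig <- cauchy_stress(pn, diag(c(lam, lat, lat)))
  expect_equal(sig[1, 1], 2 * 9.02 * (lam^2 - 1 / lam), tolerance = 5e-3)
  expect_equal(sig[1, 1], 5.43, tolerance = 2e-3)
})

test_that("kappa -> 0 reduces the dispersed invariant to the aligned one", {
  p0 <- table1_params()                       # kappa = 1e-8, effectively aligned
  Fs <- diag(c(1.08, 0.99, 1 / (1.08 * 0.99)))
  d <- deformation_point(Fs, p0)
  expect_equal(d$E, d$I4 - 1, tolerance = 1e-6)
})

test_that("damage is irreversible, bounded by D_inf and history-driven", {
  p <- table1_params()
  st <- damage_state()
  lams <- c(seq(1, 1.15, length.out = 30), seq(1.15, 1, length.out = 30))
  D_trace <- numeric(0)
  for (lam in lams) {
    st <- update_damage(p, diag(c(lam, 1, 1 / lam)), st)
    D_trace <- c(D_trace, st$D[1])
  }
  expect_true(all(diff(D_trace) >= -1e-15))          # non-decreasing
  expect_true(all(D_trace <= p$D_inf + 1e-12))       # bounded
  expect_lte(max(D_trace), 0.96)
  # unloaded reference leaves the virgin state untouched
  st0 <- update_damage(p, diag(3), damage_state())
  expect_identical(st0$D, c(0, 0))
  # a second identical cycle adds nothing (no new history maximum)
  st2 <- st
  for (lam in lams) st2 <- update_damage(p, diag(c(lam, 1, 1 / lam)), st2)
  expect_equal(st2$D, st$D, tolerance = 1e-15)
  expect_equal(st2$beta_hist, st$beta_hist, tolerance = 1e-15)
})

test_that("higher gamma_inf gives lower damage under identical loading", {
  lam_peak <- 1.1
  defo <- diag(c(lam_peak, 1, 1 / lam_peak))
  st18 <- update_damage(table1_params(18), defo)
  st11 <- update_damage(table1_params(11), defo)
  expect_lt(st18$D[1], st11$D[1])
  expect_lt(st18$D[2], st11$D[2])
})

test_that("cyclic protocol shows stress softening that saturates", {
  p <- table1_params(18)
  stretch <- function(t) 1 + 0.08 * sin(pi * t)^2   # periodic on [0, 1]
  out <- run_cyclic_protocol(p, stretch, n_cycles = 5, n_steps = 60)
  peaks <- vapply(split(out$stress_kPa, out$cycle), max, numeric(1))
  expect_true(all(diff(peaks) <= 1e-10))            # non-increasing
  expect_lt(peaks[2], peaks[1])                     # strict first-cycle drop
  # history maximum saturates: cycles 4 and 5 coincide
  c4 <- out$stress_kPa[out$cycle == 4]
  c5 <- out$stress_kPa[out$cycle == 5]
  expect_equal(c5, c4, tolerance = 1e-8)
  # damage trace non-decreasing and bounded
  expect_true(all(diff(out$D_family1) >= -1e-15))
  expect_lte(max(out$D_family1), p$D_inf)
})

test_that("with damage disabled all cycles coincide", {
  p0 <- material_params(c1 = 9.02, eps1 = 499.8, eps2 = 2.4, alpha1 = 1400,
                        alpha2 = 2.2, kappa = 1e-8, beta_f = 39.87,
                        D_inf = 0, gamma_inf = 18, beta_s = 0.06)
  out <- run_cyclic_protocol(p0, function(t) 1 + 0.08 * sin(pi * t)^2,
                             n_cycles = 2, n_steps = 40)
  expect_equal(out$stress_kPa[out$cycle == 2],
               out$stress_kPa[out$cycle == 1], tolerance = 1e-12)
  expect_true(all(out$D_family1 == 0))
})

test_that("non-periodic stretch programs are rejected", {
  expect_error(run_cyclic_protocol(table1_params(), function(t) 1 + 0.1 * t),
               "not periodic")
})

test_that("parameter presets and config round-trip", {
  p11 <- aneurysm_params("aneurysm_gamma11")
  p18 <- aneurysm_params("aneurysm_gamma18")
  expect_equal(p11$gamma_inf, 11)
  expect_equal(p18$gamma_inf, 18)
  expect_equal(p11$c1, 9.02)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_material_config(p18, path)
  expect_equal(read_material_config(path), p18)
})

test_that("cycle-curve CSV writer emits the contract columns", {
  out <- run_cyclic_protocol(table1_params(), function(t) 1 + 0.05 * sin(pi * t)^2,
                             n_cycles = 1, n_steps = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cycle_curves(out, path)
  got <- read.csv(path)
  expect_named(got, c("cycle", "stretch", "stress_kPa", "D_family1",
                      "D_family2"))
  expect_equal(nrow(got), nrow(out))
})
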