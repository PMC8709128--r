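# shared fixtures, all built in code

table1_params <- function(gamma_inf = 11) {
  material_params(c1 = 9.02, eps1 = 499.8, eps2 = 2.4, alpha1 = 1400,
                  alpha2 = 2.2, kappa = 1e-8, beta_f = 39.87, D_inf = 0.96,
                  gamma_inf = gamma_inf, beta_s = 0.06)
}

# single-node "mesh" for metric unit tests
point_mesh <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
               rbind(c(1L, 2L, 3L)))
}

# single-node series with a prescribed vector profile tau(t) (n x 3)
one_node_series <- function(times, tau_mat, period) {
  mesh <- point_mesh()
  tau <- array(0, dim = c(length(times), 3L, 3L))
  tau[, 1, ] <- tau_mat
  wss_series(mesh, times, tau, period)
}

# independent evaluation of the strain energy written as plain arithmetic
# (kept deliberately separate from the package internals)
oracle_energy <- function(Fm, pars, D = c(0, 0)) {
  C <- t(Fm) %*% Fm
  I1 <- sum(diag(C)); I3 <- det(C)
  b <- pars$beta_f * pi / 180
  psi <- pars$c1 * (I1 * I3^(-1 / 3) - 3) +
    pars$eps1 * (I3^pars$eps2 + I3^(-pars$eps2) - 2)
  for (s in c(1, -1)) {
    a <- c(cos(b), s * sin(b), 0)
    I4 <- drop(a %*% C %*% a)
    E <- pars$kappa * I1 + (1 - 3 * pars$kappa) * I4 - 1
    fam <- if (s == 1) 1L else 2L
    if (E > 0) psi <- psi + (1 - D[fam]) * pars$alpha1 * E^pars$alpha2
  }
  psi
}

tube_fig2_spec <- function(gamma_inf = 18, h = 0.04, n_cycles = 5) {
  wf <- make_waveform(period = 0.8)
  tube_spec(D0 = 0.41, h = h, material = table1_params(gamma_inf),
            pressure_program = pressure_program_from_waveform(wf, 8.7, 20),
            period = 0.8, n_cycles = n_cycles)
}
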