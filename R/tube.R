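#' Specify a compliant straight-tube inflation experiment
#'
#' Reduced-order surrogate for a fluid-structure-interaction test of a
#' straight compliant vessel: a quasi-static thin-walled (membrane) cylinder
#' under cyclic transmural pressure, with anchored ends (fixed axial stretch
#' `lambda_z = 1`) and isochoric wall thinning (`lambda_r = 1/lambda_theta`).
#' Fluid inertia and axial wave propagation are outside the model.
#'
#' @param D0 Unloaded inner diameter, cm.
#' @param h Wall thickness, cm. A warning is issued outside the thin-wall
#'   regime (`h/D0 > 0.2`).
#' @param material A `material_params` (damage model) or `elastic_params`
#'   (small-strain linear wall) object.
#' @param pressure_program Function of time returning transmural pressure in
#'   kPa over one cycle (treated as periodic with period `period`).
#' @param period Cycle duration, s.
#' @param n_cycles Number of cycles to run (>= 1; 5 recommended so damage
#'   saturates).
#' @return An object of class `tube_spec`.
#' @export
tube_spec <- function(D0 = 0.41, h = 0.04, material = aneurysm_params(),
                      pressure_program, period = 0.8, n_cycles = 5) {
  stopifnot(D0 > 0, h > 0, is.function(pressure_program),
            period > 0, n_cycles >= 1)
  if (h / D0 > 0.2) {
    warning("h/D0 = ", signif(h / D0, 3),
            " is outside the thin-wall regime (> 0.2)", call. = FALSE)
  }
  structure(list(D0 = D0, h = h, material = material,
                 pressure_program = pressure_program, period = period,
                 n_cycles = n_cycles),
            class = "tube_spec")
}

# membrane hoop stress difference sigma_11 - sigma_33 (kPa) at hoop stretch
# lam, frame (circumferential, axial, radial), F = diag(lam, 1, 1/lam)
tube_hoop_stress <- function(material, lam, state) {
  if (inherits(material, "elastic_params")) {
    # plane-strain small-strain hoop law: eps_z = 0 => E_eff = E/(1-nu^2)
    return(material$E / (1 - material$nu^2) * (lam - 1))
  }
  defo <- deformation_point(diag(c(lam, 1, 1 / lam)), material)
  sig <- cauchy_stress(material, defo, state)
  sig[1, 1] - sig[3, 3]
}

#' Solve one quasi-static inflation step of the membrane tube
#'
#' Finds the hoop stretch `lambda` satisfying thin-wall (Laplace) equilibrium
#' `sigma_theta(lambda) * h = P * r` with current wall thickness
#' `h = h0 / lambda` and current radius `r = lambda * r0`, i.e. the residual
#' `sigma_theta(lambda) * h0 / lambda - P * lambda * r0 = 0`. The damage state
#' is held fixed during the solve.
#'
#' @param spec A [tube_spec()].
#' @param P Transmural pressure, kPa (>= 0).
#' @param state A `damage_state` (ignored for `elastic_params` walls).
#' @param solver `"brent"` (default, [stats::uniroot]) or `"newton"`
#'   (damped Newton with numeric derivative); both converge to the same root.
#' @param lambda_max Upper bracket for the hoop stretch.
#' @return List with `radius` (cm), `stretch`, `stress_kPa` (hoop stress
#'   difference) and the achieved `residual`.
#' @export
solve_inflation_step <- function(spec, P, state = damage_state(),
                                 solver = c("brent", "newton"),
                                 lambda_max = 3) {
  solver <- match.arg(solver)
  stopifnot(P >= 0)
  r0 <- spec$D0 / 2
  if (P == 0) {
    return(list(radius = r0, stretch = 1, stress_kPa = 0, residual = 0))
  }
  resid <- function(lam) {
    tube_hoop_stress(spec$material, lam, state) * spec$h / lam - P * lam * r0
  }
  lo <- 1 + 1e-12
  if (resid(lambda_max) > 0) {
    # fine; root below lambda_max
  } else {
    stop("inflation step diverged at P = ", signif(P, 4),
         " kPa: no equilibrium radius with stretch <= ", lambda_max,
         " (material too soft for this load)", call. = FALSE)
  }
  lam <- if (solver == "brent") {
    stats::uniroot(resid, c(lo, lambda_max), tol = 1e-14)$root
  } else {
    x <- 1.05
    for (it in 1:100) {
      fx <- resid(x)
      dfx <- (resid(x + 1e-7) - resid(x - 1e-7)) / 2e-7
      step <- fx / dfx
      x_new <- x - step
      if (x_new <= lo || x_new >= lambda_max) x_new <- x - sign(step) * 0.1 * (x - lo)
      x <- x_new
      if (abs(step) < 1e-13) break
    }
    x
  }
  scale <- abs(P * lam * r0)
  list(radius = lam * r0, stretch = lam,
       stress_kPa = tube_hoop_stress(spec$material, lam, state),
       residual = abs(resid(lam)) / scale)
}

# one pressure step with damage evolution: staggered fixed point between the
# equilibrium solve and the history-maximum damage update (saturating, so the
# iteration is contractive)
tube_step_with_damage <- function(spec, P, state, damage_on = TRUE) {
  lam_prev <- -Inf
  sol <- solve_inflation_step(spec, P, state)
  if (damage_on && inherits(spec$material, "material_params") &&
      spec$material$D_inf > 0) {
    for (it in 1:50) {
      defo <- deformation_point(diag(c(sol$stretch, 1, 1 / sol$stretch)),
                                spec$material)
      state_new <- update_damage(spec$material, defo, state)
      if (identical(state_new$beta_hist, state$beta_hist) &&
          abs(sol$stretch - lam_prev) < 1e-13) break
      lam_prev <- sol$stretch
      state <- state_new
      sol <- solve_inflation_step(spec, P, state)
      if (abs(sol$stretch - lam_prev) < 1e-13) break
    }
  }
  list(sol = sol, state = state)
}

#' Run the paired (non-degraded / degraded) tube inflation experiment
#'
#' Runs the identical cyclic pressure program twice — once with the damage
#' model active and once with damage frozen at zero — and returns both radius
#' / radial-strain traces. The time grid of each cycle is augmented with the
#' exact in-cycle argmax of the pressure program so peak quantities are
#' resolution-independent (quasi-static path independence).
#'
#' @param spec A [tube_spec()].
#' @param n_steps Time samples per cycle.
#' @return List of class `tube_experiment` with tibbles `degraded` and
#'   `non_degraded` (columns `time`, `cycle`, `pressure_kPa`, `radius`,
#'   `strain`, `D_family1`, `D_family2`) and the peak final-cycle strains
#'   `eps_d_peak`, `eps_nd_peak`.
#' @export
run_tube_experiment <- function(spec, n_steps = 64) {
  r0 <- spec$D0 / 2
  # in-cycle grid, augmented with the program's argmax
  tt <- seq(0, spec$period, length.out = n_steps + 1L)[-(n_steps + 1L)]
  tfine <- seq(0, spec$period, length.out = 4096L)
  t_peak <- tfine[which.max(spec$pressure_program(tfine))]
  opt <- stats::optimize(spec$pressure_program,
                         interval = c(max(0, t_peak - spec$period / 100),
                                      min(spec$period, t_peak + spec$period / 100)),
                         maximum = TRUE, tol = 1e-12)
  tt <- sort(unique(c(tt, opt$maximum)))

  run_once <- function(damage_on) {
    state <- damage_state()
    rows <- vector("list", spec$n_cycles)
    for (cyc in seq_len(spec$n_cycles)) {
      n <- length(tt)
      radius <- numeric(n); D1 <- numeric(n); D2 <- numeric(n)
      Pv <- spec$pressure_program(tt)
      for (i in seq_len(n)) {
        st <- tube_step_with_damage(spec, Pv[i], state, damage_on)
        state <- st$state
        radius[i] <- st$sol$radius
        D1[i] <- state$D[1]; D2[i] <- state$D[2]
      }
      rows[[cyc]] <- tibble::tibble(
        time = (cyc - 1) * spec$period + tt, cycle = cyc, pressure_kPa = Pv,
        radius = radius, strain = (radius - r0) / r0,
        D_family1 = D1, D_family2 = D2
      )
    }
    do.call(rbind, rows)
  }

  d <- run_once(TRUE)
  nd <- run_once(FALSE)
  last <- function(tr) tr[tr$cycle == spec$n_cycles, ]
  structure(list(
    degraded = d, non_degraded = nd,
    eps_d_peak = max(last(d)$strain), eps_nd_peak = max(last(nd)$strain)
  ), class = "tube_experiment")
}

#' Degradation-induced relative change in peak radial strain
#'
#' The per-run scalar: the relative change in final-cycle peak radial strain
#' between the non-degraded and degraded twins,
#' `(eps_nd - eps_d) / eps_nd * 100` by default (the softened wall inflates
#' more, so the default is <= 0).
#'
#' @param exp_out A `tube_experiment`.
#' @param reference `"nd"` (default) normalizes by the non-degraded strain;
#'   `"d"` by the degraded strain.
#' @return Scalar percent change.
#' @export
strain_rel_change <- function(exp_out, reference = c("nd", "d")) {
  reference <- match.arg(reference)
  e_nd <- exp_out$eps_nd_peak; e_d <- exp_out$eps_d_peak
  den <- if (reference == "nd") e_nd else e_d
  (e_nd - e_d) / den * 100
}

#' Wall-thickness sensitivity sweep of the degradation effect
#'
#' Repeats the paired tube experiment at each wall thickness and reports the
#' degradation-induced relative strain change per thickness together with its
#' relative spread across the sweep, `(max - min) / |mean| * 100`. A small
#' spread means the degradation effect on strain is insensitive to the
#' (uncertain) wall thickness.
#'
#' @param base A [tube_spec()]; its `h` is replaced by each sweep value.
#' @param thicknesses Numeric vector of wall thicknesses, cm (>= 2 values for
#'   a meaningful spread; a single repeated value gives spread 0).
#' @param n_steps Time samples per cycle.
#' @param reference Passed to [strain_rel_change()].
#' @return List with `table` (tibble: `thickness_cm`,
#'   `rel_strain_change_pct`) and `spread_pct`.
#' @export
thickness_sweep <- function(base, thicknesses = c(0.02, 0.04, 0.06),
                            n_steps = 64, reference = "nd") {
  stopifnot(length(thicknesses) >= 1, all(thicknesses > 0))
  vals <- vapply(thicknesses, function(h) {
    spec_h <- base
    spec_h$h <- h
    strain_rel_change(run_tube_experiment(spec_h, n_steps = n_steps),
                      reference = reference)
  }, numeric(1))
  spread <- if (max(abs(vals)) == 0 || diff(range(vals)) == 0) {
    0
  } else {
    diff(range(vals)) / abs(mean(vals)) * 100
  }
  list(
    table = tibble::tibble(thickness_cm = thicknesses,
                           rel_strain_change_pct = vals),
    spread_pct = spread
  )
}
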