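#' Constitutive parameters of the aneurysmal wall
#'
#' The aneurysm wall is modelled as a nearly incompressible, fiber-reinforced
#' hyperelastic solid with irreversible, saturating damage acting on the
#' collagen-fiber contribution (Mullins-type stress softening). The strain
#' energy density is
#' \deqn{\psi = c_1 (I_1 I_3^{-1/3} - 3)
#'       + \epsilon_1 (I_3^{\epsilon_2} + I_3^{-\epsilon_2} - 2)
#'       + \sum_{a=1,2} (1 - D_a)\, \alpha_1 \langle E_a \rangle^{\alpha_2},}
#' with \eqn{E_a = \kappa I_1 + (1 - 3\kappa) I_{4,a} - 1} the generalized
#' (dispersed) fiber invariant of family \eqn{a}, and two symmetric fiber
#' families at \eqn{\pm\beta_f} from the circumferential direction in the
#' wall tangent plane. Fibers only contribute in tension
#' (\eqn{\langle x\rangle = \max(x, 0)}).
#'
#' Damage per family follows the saturation law
#' \deqn{D_a = D_\infty \left[1 -
#'       \exp(-\beta_a / \gamma_\infty)\right]^{\beta_s},}
#' where \eqn{\beta_a} is the running maximum over the loading history of the
#' effective (undamaged) fiber energy \eqn{\alpha_1\langle E_a\rangle^{\alpha_2}}
#' (kPa). \eqn{\gamma_\infty} (kPa) scales the driving energy, so a *larger*
#' \eqn{\gamma_\infty} means *less* damage under identical loading (lower
#' damage intensity); the small shape exponent \eqn{\beta_s} makes damage
#' activate readily once fibers load and then saturate, nearly independently
#' of the load level.
#'
#' @param c1 Ground-matrix (isotropic) stiffness, kPa.
#' @param eps1 Volumetric penalty stiffness, kPa.
#' @param eps2 Volumetric penalty exponent (>= 1), dimensionless.
#' @param alpha1 Fiber stiffness, kPa.
#' @param alpha2 Fiber exponent (>= 1), dimensionless.
#' @param kappa Fiber dispersion in `[0, 1/3]`; 0 = perfectly aligned,
#'   1/3 = isotropic.
#' @param beta_f Fiber angle from the circumferential direction, degrees in
#'   `[0, 90]`.
#' @param D_inf Damage saturation value in `[0, 1)`; `0` disables damage.
#' @param gamma_inf Damage saturation rate parameter, kPa (> 0).
#' @param beta_s Damage shape parameter in `(0, 1)`: fraction of `D_inf`
#'   reached when the driving history variable equals `gamma_inf`.
#' @return An object of class `material_params`.
#' @seealso [aneurysm_params()] for the published parameter presets,
#'   [strain_energy()], [cauchy_stress()], [update_damage()].
#' @export
material_params <- function(c1, eps1, eps2, alpha1, alpha2, kappa, beta_f,
                            D_inf, gamma_inf, beta_s) {
  stopifnot(
    c1 > 0, eps1 > 0, gamma_inf > 0, alpha1 >= 0,
    alpha2 >= 1, eps2 >= 1,
    kappa >= 0, kappa <= 1 / 3,
    D_inf >= 0, D_inf < 1,
    beta_f >= 0, beta_f <= 90,
    beta_s > 0, beta_s < 1
  )
  structure(
    list(c1 = c1, eps1 = eps1, eps2 = eps2, alpha1 = alpha1, alpha2 = alpha2,
         kappa = kappa, beta_f = beta_f, D_inf = D_inf, gamma_inf = gamma_inf,
         beta_s = beta_s),
    class = "material_params"
  )
}

#' Published aneurysm-wall parameter presets
#'
#' Returns the aneurysm-region parameter set used throughout the package
#' (c1 = 9.02 kPa, eps1 = 499.8 kPa, eps2 = 2.4, alpha1 = 1400 kPa,
#' alpha2 = 2.2, kappa = 1e-8, beta_f = 39.87 deg, D_inf = 0.96,
#' beta_s = 0.06), in two damage-intensity variants distinguished by
#' `gamma_inf`: 11 kPa (higher damage intensity) or 18 kPa (lower).
#'
#' @param preset `"aneurysm_gamma11"` or `"aneurysm_gamma18"`.
#' @return A `material_params` object.
#' @export
aneurysm_params <- function(preset = c("aneurysm_gamma11", "aneurysm_gamma18")) {
  preset <- match.arg(preset)
  gamma_inf <- switch(preset, aneurysm_gamma11 = 11, aneurysm_gamma18 = 18)
  material_params(
    c1 = 9.02, eps1 = 499.8, eps2 = 2.4, alpha1 = 1400, alpha2 = 2.2,
    kappa = 1e-8, beta_f = 39.87, D_inf = 0.96, gamma_inf = gamma_inf,
    beta_s = 0.06
  )
}

#' Read / write material parameter configs
#'
#' YAML (or JSON) configs use the field names of [material_params()]. A config
#' may instead name a preset via a single `preset:` key.
#'
#' @param path File path.
#' @param params A `material_params` object (for writing).
#' @return `read_material_config()` returns a `material_params` object.
#' @export
read_material_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$preset)) return(aneurysm_params(cfg$preset))
  do.call(material_params, cfg[names(formals(material_params))])
}

#' @rdname read_material_config
#' @export
write_material_config <- function(params, path) {
  stopifnot(inherits(params, "material_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' Linear-elastic wall parameters (non-aneurysmal vessel)
#'
#' The parent and branch vessels outside the aneurysm are modelled as a simple
#' elastic (Neo-Hookean at small strain) material with modulus `E` and Poisson
#' ratio `nu`; defaults are E = 1000 kPa, nu = 0.49.
#'
#' @param E Elastic modulus, kPa.
#' @param nu Poisson ratio in `[0, 0.5)`.
#' @return An object of class `elastic_params`.
#' @export
elastic_params <- function(E = 1000, nu = 0.49) {
  stopifnot(E > 0, nu >= 0, nu < 0.5)
  structure(list(E = E, nu = nu), class = "elastic_params")
}

#' Per-family damage state
#'
#' Internal variables of the damage model: the per-family damage `D` and the
#' per-family history variable `beta_hist` (kPa), the running maximum of the
#' effective fiber energy. Both are non-decreasing along any loading path.
#'
#' @param D Numeric length-2, damage per fiber family, each in `[0, 1)`.
#' @param beta_hist Numeric length-2, accumulated damage-driving history
#'   (kPa), each >= 0.
#' @return An object of class `damage_state`.
#' @export
damage_state <- function(D = c(0, 0), beta_hist = c(0, 0)) {
  stopifnot(length(D) == 2L, length(beta_hist) == 2L,
            all(D >= 0), all(D < 1), all(beta_hist >= 0))
  structure(list(D = as.numeric(D), beta_hist = as.numeric(beta_hist)),
            class = "damage_state")
}

#' Kinematic point: deformation gradient and its invariants
#'
#' Carries a deformation gradient `F` together with the invariants the
#' constitutive law needs: `I1 = tr(C)`, `I3 = det(C)` with `C = t(F) %*% F`,
#' and the per-family generalized fiber invariants
#' `E_a = kappa*I1 + (1-3*kappa)*I4_a - 1` built from the material's dispersion
#' and fiber angle. The local frame convention is
#' (e1, e2, e3) = (circumferential, axial, radial); the fiber families lie in
#' the e1–e2 tangent plane at +/- `beta_f` from e1.
#'
#' @param F 3x3 deformation gradient with `det(F) > 0`.
#' @param params A `material_params` object (supplies `kappa`, `beta_f`).
#' @return An object of class `deformation_point` with elements `F`, `J`,
#'   `C`, `I1`, `I3`, `I4` (length 2), `E` (length 2), `a` (2-list of fiber
#'   direction vectors).
#' @export
deformation_point <- function(F, params) {
  stopifnot(is.matrix(F), all(dim(F) == c(3L, 3L)))
  J <- det(F)
  if (!is.finite(J) || J <= 0) {
    stop("invalid deformation: det(F) = ", format(J), " must be > 0",
         call. = FALSE)
  }
  C <- crossprod(F) # t(F) %*% F
  I1 <- sum(diag(C))
  I3 <- det(C)
  a <- fiber_directions(params$beta_f)
  I4 <- vapply(a, function(ai) drop(ai %*% C %*% ai), numeric(1))
  E <- params$kappa * I1 + (1 - 3 * params$kappa) * I4 - 1
  structure(list(F = F, J = J, C = C, I1 = I1, I3 = I3, I4 = I4, E = E, a = a),
            class = "deformation_point")
}

# unit fiber direction vectors at +/- beta_f (degrees) from e1 in the e1-e2 plane
fiber_directions <- function(beta_f) {
  b <- beta_f * pi / 180
  list(c(cos(b),  sin(b), 0),
       c(cos(b), -sin(b), 0))
}

# effective (undamaged) fiber energy per family, kPa; tension-only
fiber_energy0 <- function(params, defo) {
  Epos <- pmax(defo$E, 0)
  params$alpha1 * Epos^params$alpha2
}

#' Strain energy density of the damaged wall model
#'
#' Evaluates the strain energy (kPa) at a deformation point given the current
#' damage state. The damage state is held fixed (no evolution here); use
#' [update_damage()] to evolve it.
#'
#' @param params A `material_params` object.
#' @param defo A `deformation_point` (or a 3x3 deformation gradient, which is
#'   promoted via [deformation_point()]).
#' @param state A `damage_state`; defaults to the virgin state.
#' @return Scalar energy density, kPa. Zero at the identity deformation with
#'   zero damage.
#' @export
strain_energy <- function(params, defo, state = damage_state()) {
  if (is.matrix(defo)) defo <- deformation_point(defo, params)
  psi_iso <- params$c1 * (defo$I1 * defo$I3^(-1 / 3) - 3)
  psi_vol <- params$eps1 * (defo$I3^params$eps2 + defo$I3^(-params$eps2) - 2)
  psi_fib <- sum((1 - state$D) * fiber_energy0(params, defo))
  psi_iso + psi_vol + psi_fib
}

#' Cauchy stress of the damaged wall model
#'
#' Analytic push-forward of the second Piola-Kirchhoff stress
#' `S = 2 d(psi)/d(C)`: `sigma = F S t(F) / J`. Symmetric by construction;
#' zero at the identity with zero damage. Consistent with finite differences
#' of [strain_energy()].
#'
#' @inheritParams strain_energy
#' @return Symmetric 3x3 Cauchy stress tensor, kPa.
#' @export
cauchy_stress <- function(params, defo, state = damage_state()) {
  if (is.matrix(defo)) defo <- deformation_point(defo, params)
  Cinv <- solve(defo$C)
  I <- diag(3)
  # d(psi_iso)/dC = c1 * (I3^-1/3 * I - (1/3) I1 I3^-1/3 * Cinv)
  dpsi <- params$c1 * defo$I3^(-1 / 3) * (I - (defo$I1 / 3) * Cinv)
  # d(psi_vol)/dC = eps1*eps2*(I3^eps2 - I3^-eps2) * Cinv
  dpsi <- dpsi + params$eps1 * params$eps2 *
    (defo$I3^params$eps2 - defo$I3^(-params$eps2)) * Cinv
  # fiber families, tension-only
  for (a in 1:2) {
    if (defo$E[a] > 0) {
      dE <- params$kappa * I +
        (1 - 3 * params$kappa) * tcrossprod(defo$a[[a]])
      dpsi <- dpsi + (1 - state$D[a]) * params$alpha1 * params$alpha2 *
        defo$E[a]^(params$alpha2 - 1) * dE
    }
  }
  S <- 2 * dpsi
  sig <- defo$F %*% S %*% t(defo$F) / defo$J
  (sig + t(sig)) / 2 # symmetrize against round-off
}

#' Evolve the damage state at a deformation point
#'
#' Updates the per-family history variable to the running maximum of the
#' effective fiber energy and re-evaluates the saturation law
#' `D = D_inf * (1 - exp(log(1 - beta_s) * beta_hist / gamma_inf))`.
#' Damage is irreversible: unloading, or re-loading below the historical
#' maximum, leaves the state unchanged.
#'
#' @inheritParams strain_energy
#' @return A new `damage_state`.
#' @export
update_damage <- function(params, defo, state = damage_state()) {
  if (is.matrix(defo)) defo <- deformation_point(defo, params)
  beta_new <- pmax(state$beta_hist, fiber_energy0(params, defo))
  D_new <- damage_from_beta(params, beta_new)
  # irreversibility guard (the saturation law is monotone in beta anyway)
  damage_state(D = pmax(state$D, D_new), beta_hist = beta_new)
}

# saturation law D(beta); D_inf = 0 disables damage. The small shape
# exponent beta_s makes damage activate readily and then be nearly
# insensitive to the load level (steep rise, flat saturation).
damage_from_beta <- function(params, beta) {
  params$D_inf * (1 - exp(-beta / params$gamma_inf))^params$beta_s
}

#' Run a stretch-controlled cyclic loading protocol at a material point
#'
#' Drives a material point through `n_cycles` of a periodic circumferential
#' stretch program under membrane kinematics
#' (`F = diag(lambda, 1, 1/lambda)`: fixed axial stretch, isochoric thinning)
#' and records the membrane stress difference
#' `sigma_theta = sigma_11 - sigma_33` together with the damage trace. With
#' damage active the model exhibits Mullins-type stress softening: the peak
#' stress at a repeated peak stretch is non-increasing across cycles, and the
#' response converges once the history maximum saturates.
#'
#' @param params A `material_params` object.
#' @param stretch Either a function of time mapping `[0, T]` to stretch
#'   (must be periodic: `stretch(0) == stretch(T)`), or a numeric vector of
#'   stretch samples over one cycle (first and last must agree).
#' @param n_cycles Number of cycles (>= 1).
#' @param n_steps Samples per cycle when `stretch` is a function.
#' @param period Cycle duration (s), only used for the time column.
#' @return A [tibble::tibble] with columns `cycle`, `time`, `stretch`,
#'   `stress_kPa`, `D_family1`, `D_family2`.
#' @export
run_cyclic_protocol <- function(params, stretch, n_cycles = 5,
                                n_steps = 100, period = 1) {
  stopifnot(n_cycles >= 1)
  if (is.function(stretch)) {
    tt <- seq(0, period, length.out = n_steps + 1L)
    lam <- stretch(tt)
    if (abs(lam[1] - lam[length(lam)]) > 1e-9 * max(abs(lam))) {
      stop("stretch program is not periodic over one cycle", call. = FALSE)
    }
  } else {
    lam <- as.numeric(stretch)
    if (length(lam) < 3L ||
        abs(lam[1] - lam[length(lam)]) > 1e-9 * max(abs(lam))) {
      stop("stretch program is not periodic over one cycle", call. = FALSE)
    }
    tt <- seq(0, period, length.out = length(lam))
  }
  state <- damage_state()
  n <- length(lam)
  out <- vector("list", n_cycles)
  for (cyc in seq_len(n_cycles)) {
    stress <- numeric(n); D1 <- numeric(n); D2 <- numeric(n)
    for (i in seq_len(n)) {
      defo <- deformation_point(diag(c(lam[i], 1, 1 / lam[i])), params)
      # explicit ordering: stress with the state accumulated so far, then
      # evolve the state — first-cycle loading is the virgin response
      sig <- cauchy_stress(params, defo, state)
      state <- update_damage(params, defo, state)
      stress[i] <- sig[1, 1] - sig[3, 3]
      D1[i] <- state$D[1]; D2[i] <- state$D[2]
    }
    out[[cyc]] <- tibble::tibble(
      cycle = cyc, time = (cyc - 1) * period + tt, stretch = lam,
      stress_kPa = stress, D_family1 = D1, D_family2 = D2
    )
  }
  res <- do.call(rbind, out)
  attr(res, "final_state") <- state
  res
}

#' Write cyclic stress-stretch curves to CSV
#'
#' @param curves Output of [run_cyclic_protocol()].
#' @param path CSV file path.
#' @export
write_cycle_curves <- function(curves, path) {
  utils::write.csv(
    curves[, c("cycle", "stretch", "stress_kPa", "D_family1", "D_family2")],
    path, row.names = FALSE
  )
  invisible(path)
}
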