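#' Parametric pulsatile waveform
#'
#' Generates a smooth T-periodic waveform on a uniform grid: a raised-cosine
#' systolic bump over the first `systolic_fraction` of the cycle on a flat
#' diastolic baseline, rescaled so the peak-to-trough amplitude is
#' `amplitude` and the (cyclic-trapezoid) mean is exactly `mean_level`.
#' Optional seeded Gaussian jitter supports robustness tests; with
#' `noise_sd = 0` the waveform is fully deterministic.
#'
#' @param period Period `T`, s.
#' @param mean_level Cycle mean (flow in cm^3/s, or pressure in kPa when used
#'   as a pressure-program shape).
#' @param amplitude Peak-to-trough amplitude (>= 0).
#' @param systolic_fraction Fraction of the cycle occupied by the systolic
#'   bump, in (0, 1).
#' @param n_samples Samples per period (uniform grid on `[0, T)`).
#' @param noise_sd Standard deviation of additive jitter (0 = none).
#' @param seed Integer seed for the jitter.
#' @param require_positive Error if any sample is <= 0 (an inflow must be
#'   strictly positive).
#' @return A [flow_waveform()].
#' @export
make_waveform <- function(period = 0.8, mean_level = 2.0, amplitude = 3.0,
                          systolic_fraction = 0.36, n_samples = 200,
                          noise_sd = 0, seed = 1L, require_positive = TRUE) {
  stopifnot(period > 0, amplitude >= 0, n_samples >= 8,
            systolic_fraction > 0, systolic_fraction < 1)
  tt <- seq(0, period, length.out = n_samples + 1L)[-(n_samples + 1L)]
  ts <- systolic_fraction * period
  shape <- ifelse(tt < ts, 0.5 * (1 - cos(2 * pi * tt / ts)), 0)
  if (noise_sd > 0) {
    set.seed(seed)
    shape <- shape + stats::rnorm(n_samples, sd = noise_sd)
  }
  rng <- diff(range(shape))
  Q <- if (rng > 0 && amplitude > 0) shape * amplitude / rng else rep(0, n_samples)
  # exact mean normalization under the cyclic trapezoid (uniform grid: the
  # plain mean)
  w <- cyclic_trapezoid_weights(tt, period)
  Q <- Q - sum(w * Q) / period + mean_level
  if (require_positive && any(Q <= 0)) {
    stop("waveform is not strictly positive (min = ", signif(min(Q), 3),
         "); reduce amplitude or raise mean_level", call. = FALSE)
  }
  flow_waveform(tt, Q, period)
}

#' Rescale a waveform shape to a pressure program
#'
#' Maps a [flow_waveform()]'s shape linearly onto `[P_min, P_max]` and
#' returns a periodic function of time (kPa), e.g. the 8.7-20 kPa cyclic
#' load of the tube experiment.
#'
#' @param wf A [flow_waveform()].
#' @param P_min,P_max Load range, kPa.
#' @return Function `P(t)` (kPa), `wf$period`-periodic.
#' @export
pressure_program_from_waveform <- function(wf, P_min = 8.7, P_max = 20) {
  stopifnot(P_max > P_min)
  qf <- waveform_fun(wf)
  q_lo <- min(wf$Q); q_rng <- diff(range(wf$Q))
  if (q_rng == 0) return(function(t) rep((P_min + P_max) / 2, length(t)))
  function(t) P_min + (qf(t) - q_lo) / q_rng * (P_max - P_min)
}

#' Idealized dome-on-vessel surface mesh
#'
#' Builds a watertight triangulated shell of a spherical aneurysm sac
#' (`"dome"`) joined at its neck to a cylindrical parent-vessel stub
#' (`"parent"`): sphere of diameter `dome_diameter` centred at the origin,
#' truncated where its cross-section equals the vessel radius, with the
#' cylinder attached at the shared neck ring. Region labels partition the
#' nodes.
#'
#' @param resolution Azimuthal segment count (>= 8); node count grows ~
#'   quadratically, triangle count ~ x4 per doubling.
#' @param dome_diameter Inner diameter of the sac, cm.
#' @param vessel_diameter Inner diameter of the parent vessel, cm (must be
#'   smaller than `dome_diameter`).
#' @param neck_length Length of the parent stub, cm.
#' @return A [surface_mesh()] with labels `"dome"` / `"parent"`.
#' @export
make_dome_mesh <- function(resolution = 24, dome_diameter = 1.0,
                           vessel_diameter = 0.41,
                           neck_length = vessel_diameter) {
  stopifnot(dome_diameter > 0, vessel_diameter > 0,
            vessel_diameter < dome_diameter, resolution >= 8)
  Rd <- dome_diameter / 2
  rv <- vessel_diameter / 2
  phi_neck <- pi - asin(rv / Rd)          # polar angle of the neck ring
  n_th <- as.integer(resolution)
  n_phi <- max(4L, as.integer(ceiling(resolution * phi_neck / (2 * pi) * 2)))
  n_z <- max(3L, as.integer(round(resolution / 6)))
  th <- seq(0, 2 * pi, length.out = n_th + 1L)[-(n_th + 1L)]
  phi <- seq(0, phi_neck, length.out = n_phi + 1L)[-1L] # rings below the pole

  nodes <- rbind(c(0, 0, Rd)) # pole
  labels <- "dome"
  ring_ids <- list()
  for (j in seq_along(phi)) {
    ring <- cbind(Rd * sin(phi[j]) * cos(th), Rd * sin(phi[j]) * sin(th),
                  Rd * cos(phi[j]))
    ring_ids[[j]] <- nrow(nodes) + seq_len(n_th)
    nodes <- rbind(nodes, ring)
    labels <- c(labels, rep("dome", n_th))
  }
  z_neck <- Rd * cos(phi_neck)
  zz <- seq(z_neck, z_neck - neck_length, length.out = n_z + 1L)[-1L]
  for (k in seq_along(zz)) {
    ring <- cbind(rv * cos(th), rv * sin(th), rep(zz[k], n_th))
    ring_ids[[length(ring_ids) + 1L]] <- nrow(nodes) + seq_len(n_th)
    nodes <- rbind(nodes, ring)
    labels <- c(labels, rep("parent", n_th))
  }
  if (nrow(nodes) < 100L) {
    stop("resolution too coarse: only ", nrow(nodes),
         " nodes (< 100); increase `resolution`", call. = FALSE)
  }
  tri <- list()
  r1 <- ring_ids[[1]]
  for (i in seq_len(n_th)) { # pole fan
    tri[[length(tri) + 1L]] <- c(1L, r1[i], r1[if (i < n_th) i + 1L else 1L])
  }
  for (j in seq_len(length(ring_ids) - 1L)) { # ring-to-ring quads
    a <- ring_ids[[j]]; b <- ring_ids[[j + 1L]]
    for (i in seq_len(n_th)) {
      ip <- if (i < n_th) i + 1L else 1L
      tri[[length(tri) + 1L]] <- c(a[i], b[i], b[ip])
      tri[[length(tri) + 1L]] <- c(a[i], b[ip], a[ip])
    }
  }
  surface_mesh(nodes, do.call(rbind, tri), labels)
}

#' Specification of a paired synthetic WSS dataset
#'
#' Parameters of the synthetic flow-impingement pattern the generator
#' emulates: a patch of high, (near-)unidirectional shear where the inflow
#' jet strikes the dome, and low, direction-oscillating shear elsewhere, in
#' paired non-degraded/degraded variants with opposite-signed TAWSS/OSI
#' shifts in the low-shear region (the degradation signature) and
#' same-signed shifts in the impingement patch.
#'
#' OSI is set by the reversal-fraction construction: a node with reversal
#' fraction `rho` carries a constant-magnitude shear vector flipped by 180
#' degrees for the last `round(rho * n_time)` samples, giving OSI =
#' `k/n_time` in closed form. TAWSS effects are multiplicative magnitude
#' scalings; OSI effects are reversal-count shifts (rounded to the sample
#' grid; the *applied* per-node effects are returned as ground truth).
#'
#' @param impingement_center Unit direction of the impingement patch centre
#'   (from the dome centre).
#' @param impingement_width Angular radius of the patch, radians.
#' @param tawss_high,tawss_low Shear magnitudes (dyn/cm^2) inside/outside the
#'   patch.
#' @param rev_frac_high,rev_frac_low Reversal fractions (OSI targets, in
#'   `[0, 0.5]`) inside/outside the patch.
#' @param dtawss_low_pct,dosi_low_pct Degradation effect sizes (percent) in
#'   the low-shear region (opposite-signed by default: TAWSS down, OSI up).
#' @param dtawss_high_pct,dosi_high_pct Effect sizes in the impingement patch
#'   (same-signed by default: positive correlation).
#' @param n_time Time samples per cycle.
#' @param noise_sd SD of additive Gaussian noise on every vector component
#'   (dyn/cm^2); 0 = noise-free.
#' @param seed Integer seed (runs are bit-for-bit reproducible).
#' @return Object of class `synthetic_field_spec`.
#' @export
synthetic_field_spec <- function(impingement_center = c(0, 0, 1),
                                 impingement_width = 0.7,
                                 tawss_high = 40, tawss_low = 8,
                                 rev_frac_high = 0.05, rev_frac_low = 0.25,
                                 dtawss_low_pct = -20, dosi_low_pct = 30,
                                 dtawss_high_pct = 25, dosi_high_pct = 25,
                                 n_time = 80, noise_sd = 0, seed = 1L) {
  stopifnot(tawss_high > 0, tawss_low > 0,
            rev_frac_high >= 0, rev_frac_high <= 0.5,
            rev_frac_low >= 0, rev_frac_low <= 0.5,
            n_time >= 8, noise_sd >= 0,
            all(is.finite(c(dtawss_low_pct, dosi_low_pct,
                            dtawss_high_pct, dosi_high_pct))))
  if (1 + dtawss_low_pct / 100 <= 0 || 1 + dtawss_high_pct / 100 <= 0) {
    stop("TAWSS effect size would produce non-positive magnitudes",
         call. = FALSE)
  }
  structure(list(
    impingement_center = impingement_center / sqrt(sum(impingement_center^2)),
    impingement_width = impingement_width,
    tawss_high = tawss_high, tawss_low = tawss_low,
    rev_frac_high = rev_frac_high, rev_frac_low = rev_frac_low,
    dtawss_low_pct = dtawss_low_pct, dosi_low_pct = dosi_low_pct,
    dtawss_high_pct = dtawss_high_pct, dosi_high_pct = dosi_high_pct,
    n_time = as.integer(n_time), noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "synthetic_field_spec")
}

# reversal sign pattern: -1 on the last k of n samples
reversal_signs <- function(n, k) c(rep(1, n - k), rep(-1, k))

#' Generate a paired non-degraded / degraded WSS time series
#'
#' Builds the two series of [synthetic_field_spec()] on a mesh, plus the
#' ground truth needed for recovery tests: patch masks and the *applied*
#' per-node effect sizes (OSI shifts are quantized to the sample grid, so
#' the applied values — exact by construction — can differ slightly from the
#' requested ones).
#'
#' @param mesh A [surface_mesh()] (dome/parent labels used for the patch
#'   geometry; parent nodes are treated as low-shear).
#' @param spec A [synthetic_field_spec()].
#' @param waveform Optional [flow_waveform()] whose shape modulates the
#'   magnitude of purely unidirectional nodes (`rev_frac = 0`); oscillating
#'   nodes use constant magnitude so their OSI stays in closed form.
#' @return List with `nd`, `d` (both [wss_series()]) and `truth`: logical
#'   `impingement_mask`, per-node `tawss_nd`, `osi_nd`, `dtawss_pct`,
#'   `dosi_pct` (applied values).
#' @export
make_paired_wss_series <- function(mesh, spec = synthetic_field_spec(),
                                   waveform = NULL) {
  n_node <- nrow(mesh$nodes)
  n <- spec$n_time
  period <- if (is.null(waveform)) 0.8 else waveform$period
  times <- seq(0, period, length.out = n + 1L)[-(n + 1L)]

  # patch geometry: angular distance of each node direction from the centre
  dirs <- mesh$nodes / pmax(sqrt(rowSums(mesh$nodes^2)), 1e-12)
  ang <- acos(pmin(pmax(dirs %*% spec$impingement_center, -1), 1))
  imp <- as.vector(ang < spec$impingement_width)
  if (!is.null(mesh$labels)) imp <- imp & mesh$labels == "dome"

  # per-node tangential unit direction (any consistent tangent will do)
  ref <- c(1, 0, 0)
  e <- t(vapply(seq_len(n_node), function(i) {
    v <- c(dirs[i, 2] * ref[3] - dirs[i, 3] * ref[2],
           dirs[i, 3] * ref[1] - dirs[i, 1] * ref[3],
           dirs[i, 1] * ref[2] - dirs[i, 2] * ref[1])
    if (sum(v^2) < 1e-12) v <- c(0, 1, 0)
    v / sqrt(sum(v^2))
  }, numeric(3)))

  A_nd <- ifelse(imp, spec$tawss_high, spec$tawss_low)
  A_d <- A_nd * ifelse(imp, 1 + spec$dtawss_high_pct / 100,
                       1 + spec$dtawss_low_pct / 100)
  k_nd <- round(ifelse(imp, spec$rev_frac_high, spec$rev_frac_low) * n)
  k_d <- round(k_nd * ifelse(imp, 1 + spec$dosi_high_pct / 100,
                             1 + spec$dosi_low_pct / 100))
  if (any(k_d > n / 2) || any(k_nd > n / 2)) {
    stop("OSI effect sizes would exceed the 0.5 bound", call. = FALSE)
  }
  osi_nd <- k_nd / n
  dosi_applied <- ifelse(k_nd > 0, (k_d / pmax(k_nd, 1) - 1) * 100,
                         ifelse(k_d > 0, Inf, 0))
  dtawss_applied <- (A_d / A_nd - 1) * 100

  m_t <- rep(1, n)
  if (!is.null(waveform)) {
    qf <- waveform_fun(waveform)
    m_t <- qf(times)
    m_t <- m_t / (sum(cyclic_trapezoid_weights(times, period) * m_t) / period)
    if (any(m_t <= 0)) stop("waveform modulation must stay positive", call. = FALSE)
  }

  build <- function(A, k) {
    tau <- array(0, dim = c(n, n_node, 3))
    for (i in seq_len(n_node)) {
      prof <- if (k[i] == 0L) A[i] * m_t else A[i] * reversal_signs(n, k[i])
      for (cmp in 1:3) tau[, i, cmp] <- prof * e[i, cmp]
    }
    tau
  }
  tau_nd <- build(A_nd, k_nd)
  tau_d <- build(A_d, k_d)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    tau_nd <- tau_nd + stats::rnorm(length(tau_nd), sd = spec$noise_sd)
    tau_d <- tau_d + stats::rnorm(length(tau_d), sd = spec$noise_sd)
  }
  list(
    nd = wss_series(mesh, times, tau_nd, period),
    d = wss_series(mesh, times, tau_d, period),
    truth = list(
      impingement_mask = imp,
      tawss_nd = A_nd, osi_nd = osi_nd,
      dtawss_pct = dtawss_applied, dosi_pct = dosi_applied
    )
  )
}
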