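# cyclic trapezoid weights for T-periodic samples t_1 < ... < t_n in [0, T):
# w_i = (t_{i+1} - t_{i-1})/2 with wrap-around closure; sum(w) = T exactly
cyclic_trapezoid_weights <- function(t, period) {
  n <- length(t)
  t_next <- c(t[-1], t[1] + period)
  t_prev <- c(t[n] - period, t[-n])
  (t_next - t_prev) / 2
}

#' Triangulated surface mesh
#'
#' Minimal surface-mesh container for the metric stack: node coordinates,
#' triangle connectivity and optional per-node region labels (e.g. `"dome"`
#' vs `"parent"`, used to restrict comparisons to the aneurysm region).
#'
#' @param nodes Numeric `n x 3` matrix of coordinates, cm.
#' @param triangles Integer `m x 3` matrix of 1-based node indices.
#' @param labels Optional character vector of length `n`.
#' @return Object of class `surface_mesh`.
#' @export
surface_mesh <- function(nodes, triangles, labels = NULL) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  triangles <- as.matrix(triangles); storage.mode(triangles) <- "integer"
  stopifnot(ncol(nodes) == 3L, ncol(triangles) == 3L)
  if (min(triangles) < 1L || max(triangles) > nrow(nodes)) {
    stop("triangle indices out of range", call. = FALSE)
  }
  if (any(triangles[, 1] == triangles[, 2] |
          triangles[, 1] == triangles[, 3] |
          triangles[, 2] == triangles[, 3])) {
    stop("degenerate triangles (repeated vertex)", call. = FALSE)
  }
  if (!is.null(labels)) stopifnot(length(labels) == nrow(nodes))
  structure(list(nodes = nodes, triangles = triangles, labels = labels),
            class = "surface_mesh")
}

# per-node area weights: one third of each incident triangle's area
node_areas <- function(mesh) {
  v <- mesh$nodes
  tr <- mesh$triangles
  e1 <- v[tr[, 2], ] - v[tr[, 1], ]
  e2 <- v[tr[, 3], ] - v[tr[, 1], ]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- 0.5 * sqrt(rowSums(cr^2))
  w <- numeric(nrow(v))
  for (k in 1:3) {
    acc <- tapply(area / 3, tr[, k], sum)
    w[as.integer(names(acc))] <- w[as.integer(names(acc))] + acc
  }
  w
}

#' Time-resolved wall-shear-stress series on a surface mesh
#'
#' Per-node WSS vectors sampled over one (post-transient) cardiac cycle.
#' Sample times must be strictly increasing within `[0, T)` and are treated
#' as `T`-periodic; any warm-up transient must already have been discarded by
#' the caller.
#'
#' @param mesh A [surface_mesh()].
#' @param times Sample instants, s, strictly increasing within `[0, period)`.
#' @param tau Numeric array `n_time x n_node x 3` of WSS vectors, dyn/cm^2.
#' @param period Cycle duration `T`, s.
#' @return Object of class `wss_series`.
#' @export
wss_series <- function(mesh, times, tau, period) {
  stopifnot(inherits(mesh, "surface_mesh"), period > 0)
  times <- as.numeric(times)
  if (length(times) < 3L) stop("need at least 3 time samples", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (min(times) < 0 || max(times) >= period) {
    stop("times must lie in [0, period)", call. = FALSE)
  }
  gaps <- diff(c(times, times[1] + period))
  if (max(gaps) > period / 2) {
    stop("incomplete cycle: samples leave a gap of ", signif(max(gaps), 3),
         " s in a period of ", period, " s", call. = FALSE)
  }
  stopifnot(length(dim(tau)) == 3L,
            dim(tau)[1] == length(times),
            dim(tau)[2] == nrow(mesh$nodes),
            dim(tau)[3] == 3L)
  structure(list(mesh = mesh, times = times, tau = tau, period = period),
            class = "wss_series")
}

#' Time-averaged wall shear stress (TAWSS)
#'
#' Per node, the cycle average of the WSS magnitude,
#' `TAWSS(x) = (1/T) * integral over one cycle of |tau_w(x, t)| dt`,
#' computed by cyclic (wrap-around) trapezoidal quadrature. Non-negative by
#' construction.
#'
#' @param series A [wss_series()].
#' @return Numeric per-node vector, dyn/cm^2.
#' @export
compute_tawss <- function(series) {
  w <- cyclic_trapezoid_weights(series$times, series$period)
  mag <- sqrt(series$tau[, , 1]^2 + series$tau[, , 2]^2 + series$tau[, , 3]^2)
  drop(crossprod(mag, w)) / series$period
}

#' Oscillatory shear index (OSI)
#'
#' Per node, `OSI = 0.5 * (1 - |cycle-mean tau_w| / TAWSS)`: 0 for a
#' uni-directional shear vector, 0.5 for a symmetric 180-degree reversal.
#' Nodes whose TAWSS falls below `floor` are *undefined* (returned as `NA`,
#' not 0) and carry that mask downstream. Values are clipped to `[0, 0.5]`
#' only against round-off; the total clip amount is recorded in the
#' `"clipped"` attribute.
#'
#' @param series A [wss_series()].
#' @param tawss Optional precomputed [compute_tawss()] result.
#' @param floor TAWSS floor (dyn/cm^2) below which OSI is undefined.
#' @return Numeric per-node vector in `[0, 0.5]` with `NA` where undefined;
#'   attributes `"clipped"` (summed round-off clip) and `"n_undefined"`.
#' @export
compute_osi <- function(series, tawss = compute_tawss(series), floor = 1e-6) {
  w <- cyclic_trapezoid_weights(series$times, series$period)
  mean_vec <- vapply(1:3, function(k) drop(crossprod(series$tau[, , k], w)),
                     numeric(dim(series$tau)[2])) / series$period
  if (is.null(dim(mean_vec))) mean_vec <- matrix(mean_vec, nrow = 1L)
  mag_mean <- sqrt(rowSums(mean_vec^2))
  osi <- 0.5 * (1 - mag_mean / tawss)
  undefined <- tawss < floor
  osi[undefined] <- NA_real_
  clip <- sum(pmax(osi - 0.5, 0), na.rm = TRUE) + sum(pmax(-osi, 0), na.rm = TRUE)
  osi <- pmin(pmax(osi, 0), 0.5)
  attr(osi, "clipped") <- clip
  attr(osi, "n_undefined") <- sum(undefined)
  osi
}

#' Endothelial cell activation potential (ECAP)
#'
#' `ECAP = OSI / TAWSS` per node (cm^2/dyn); high values flag
#' low-and-oscillatory shear. Nodes with TAWSS below the floor — or already
#' undefined OSI — are `NA`, never infinite.
#'
#' @param tawss,osi Per-node vectors.
#' @param floor TAWSS floor, dyn/cm^2.
#' @return Numeric per-node vector with `NA` where undefined.
#' @export
compute_ecap <- function(tawss, osi, floor = 1e-6) {
  stopifnot(length(tawss) == length(osi))
  out <- ifelse(tawss < floor, NA_real_, osi / tawss)
  out[is.na(osi)] <- NA_real_
  out
}

#' Full per-node hemodynamic metric stack
#'
#' Convenience wrapper computing TAWSS, OSI and ECAP for one simulation
#' condition. The `defined` column is the common validity mask (nodes with
#' TAWSS below the floor are undefined for OSI and ECAP).
#'
#' @param series A [wss_series()].
#' @param floor TAWSS floor for OSI/ECAP definedness, dyn/cm^2.
#' @return Tibble of class `hemodynamic_fields` with columns `node`, `tawss`,
#'   `osi`, `ecap`, `defined`, plus the mesh in attribute `"mesh"`.
#' @export
hemodynamic_fields <- function(series, floor = 1e-6) {
  tawss <- compute_tawss(series)
  osi <- compute_osi(series, tawss, floor = floor)
  ecap <- compute_ecap(tawss, as.numeric(osi), floor = floor)
  out <- tibble::tibble(
    node = seq_along(tawss), tawss = tawss, osi = as.numeric(osi),
    ecap = ecap, defined = !is.na(osi)
  )
  attr(out, "mesh") <- series$mesh
  attr(out, "osi_clipped") <- attr(osi, "clipped")
  class(out) <- c("hemodynamic_fields", class(out))
  out
}
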