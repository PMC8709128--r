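#' Convert between the unit systems used in vascular mechanics
#'
#' The package works internally in CGS (cm, g, s; stress in dyn/cm^2) because
#' published Windkessel resistances and capacitances are CGS, while material
#' parameters are quoted in kPa and clinical pressures in mmHg. All
#' conversions are exact constant factors (1 kPa = 1e4 dyn/cm^2,
#' 1 mmHg = 1333.22 dyn/cm^2), so round trips are lossless.
#'
#' Supported units: pressure/stress `"dyn/cm2"`, `"Pa"`, `"kPa"`, `"mmHg"`;
#' length `"cm"`, `"mm"`; volumetric flow `"cm3/s"`, `"mL/min"`.
#'
#' @param x Numeric vector of values to convert.
#' @param from,to Unit names (see above). `from` and `to` must belong to the
#'   same dimension.
#' @return Numeric vector in the target unit.
#' @examples
#' convert_units(1, "kPa", "dyn/cm2")    # 1e4
#' convert_units(100, "mmHg", "kPa")     # 13.3322
#' @export
convert_units <- function(x, from, to) {
  stopifnot(is.numeric(x), length(from) == 1L, length(to) == 1L)
  # factors to the CGS base unit of each dimension
  tab <- list(
    pressure = c("dyn/cm2" = 1, "Pa" = 10, "kPa" = 1e4, "mmHg" = 1333.22),
    length   = c("cm" = 1, "mm" = 0.1),
    flow     = c("cm3/s" = 1, "mL/min" = 1 / 60)
  )
  dim_of <- function(u) {
    hit <- vapply(tab, function(f) u %in% names(f), logical(1))
    if (!any(hit)) {
      stop("unknown unit '", u, "'; supported: ",
           paste(unlist(lapply(tab, names)), collapse = ", "), call. = FALSE)
    }
    names(tab)[hit][1]
  }
  df <- dim_of(from); dt <- dim_of(to)
  if (df != dt) {
    stop("cannot convert ", from, " (", df, ") to ", to, " (", dt, ")",
         call. = FALSE)
  }
  f <- tab[[df]]
  x * unname(f[from] / f[to])
}

#' @rdname convert_units
#' @details `mmHg_per_dyncm2()` exposes the conversion constant used
#'   throughout (1 mmHg = 1333.22 dyn/cm^2).
#' @export
mmHg_per_dyncm2 <- function() 1333.22

#' Number of discrete time steps per cardiac cycle
#'
#' Bookkeeping helper used by the pipeline provenance records: the number of
#' solver steps per cycle for a period `T_s` resolved at time step `dt_s`
#' (e.g. `T = 0.8` s at `dt = 1e-4` s gives 8000 steps).
#'
#' @param T_s Cycle duration (s).
#' @param dt_s Time-step size (s).
#' @return Integer step count `round(T_s / dt_s)`.
#' @export
steps_per_cycle <- function(T_s, dt_s) {
  stopifnot(T_s > 0, dt_s > 0, dt_s <= T_s)
  as.integer(round(T_s / dt_s))
}
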