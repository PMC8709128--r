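#' Per-node relative percentage change between conditions
#'
#' `delta_f = (f_d - f_nd) / f_nd * 100` for a field `f` evaluated in the
#' degraded (`f_d`) and non-degraded (`f_nd`) conditions. Nodes where the
#' reference `|f_nd|` falls below `floor`, or where either input is already
#' undefined (`NA`), are undefined in the output; the number of newly masked
#' nodes is recorded in the `"n_masked"` attribute.
#'
#' @param f_nd,f_d Per-node numeric vectors on the same mesh/mask.
#' @param floor Reference floor below which the change is undefined.
#' @return Per-node percent change with `NA` where undefined.
#' @export
relative_change <- function(f_nd, f_d, floor = 1e-12) {
  if (length(f_nd) != length(f_d)) {
    stop("field length mismatch: ", length(f_nd), " vs ", length(f_d),
         " nodes (conditions must share the mesh)", call. = FALSE)
  }
  out <- (f_d - f_nd) / f_nd * 100
  newmask <- !is.na(f_nd) & abs(f_nd) < floor
  out[newmask] <- NA_real_
  attr(out, "n_masked") <- sum(newmask)
  out
}

#' Correlation product of the TAWSS and OSI degradation responses
#'
#' Per node, the product of the fractional (degradation-induced) changes in
#' TAWSS and OSI, scaled by 100:
#' `C = (dTAWSS/100) * (dOSI/100) * 100 = dTAWSS * dOSI / 100` (percent).
#' A negative `C` flags a node where degradation moved TAWSS and OSI in
#' opposite directions (the inverse-correlation signature); masks propagate.
#'
#' @param dtawss,dosi Per-node relative changes, percent.
#' @return Per-node correlation product, percent.
#' @export
correlation_product <- function(dtawss, dosi) {
  stopifnot(length(dtawss) == length(dosi))
  as.numeric(dtawss) * as.numeric(dosi) / 100
}

#' Digitize the correlation product to -1 / 0 / +1
#'
#' Nodes with `|C| > threshold` map to `sign(C)`; sub-threshold nodes keep an
#' explicit 0 class (the inequality is strict, so `C == threshold` maps to
#' 0); masked nodes stay masked.
#'
#' @param C Per-node correlation product, percent.
#' @param threshold Magnitude threshold, percent (default 5, >= 0).
#' @return Per-node values in `{-1, 0, 1}` with `NA` preserved.
#' @export
digitize_correlation <- function(C, threshold = 5) {
  if (length(threshold) != 1L || !is.finite(threshold) || threshold < 0) {
    stop("digitization threshold must be a single non-negative number",
         call. = FALSE)
  }
  ifelse(is.na(C), NA_real_, ifelse(abs(C) > threshold, sign(C), 0))
}

#' Classify nodes into low/high TAWSS x low/high OSI regimes
#'
#' "High" is strict: TAWSS > `tawss_threshold` (default 25 dyn/cm^2) and
#' OSI > `osi_threshold` (default 0.15); values exactly at a threshold are
#' classified "low". Nodes with undefined OSI get `NA`.
#'
#' @param fields A [hemodynamic_fields()] tibble (or any data frame with
#'   `tawss` and `osi` columns).
#' @param tawss_threshold TAWSS threshold, dyn/cm^2.
#' @param osi_threshold OSI threshold.
#' @return Factor with levels `lowT_lowO`, `lowT_highO`, `highT_lowO`,
#'   `highT_highO`.
#' @export
classify_regimes <- function(fields, tawss_threshold = 25,
                             osi_threshold = 0.15) {
  stopifnot(tawss_threshold > 0, osi_threshold > 0)
  hiT <- fields$tawss > tawss_threshold
  hiO <- fields$osi > osi_threshold
  lab <- ifelse(is.na(hiO), NA_character_,
                paste0(ifelse(hiT, "highT", "lowT"), "_",
                       ifelse(hiO, "highO", "lowO")))
  factor(lab, levels = c("lowT_lowO", "lowT_highO", "highT_lowO",
                         "highT_highO"))
}

#' Compare hemodynamics between non-degraded and degraded conditions
#'
#' Assembles the full comparison layer for a paired run: per-node relative
#' changes of TAWSS, OSI and ECAP, the correlation product `C`, its
#' digitization, and regime labels (classified on the *non-degraded* fields,
#' the pre-degradation baseline). Comparisons are restricted to
#' `region`-labelled nodes when the mesh carries labels (default `"dome"`,
#' the aneurysm region, where the degradation model acts); pass
#' `region = NULL` for the full mesh.
#'
#' @param nd,d [hemodynamic_fields()] for the non-degraded and degraded
#'   conditions, on the same mesh.
#' @param tawss_threshold,osi_threshold Regime thresholds (see
#'   [classify_regimes()]).
#' @param digitize_threshold Digitization magnitude threshold, percent.
#' @param region Region label to restrict to, or `NULL` for all nodes.
#' @return Object of class `degradation_comparison`: a tibble with columns
#'   `node`, `region`, `tawss_nd`, `osi_nd`, `dTAWSS_pct`, `dOSI_pct`,
#'   `dECAP_pct`, `C_corr`, `C_digitized`, `regime`, plus threshold metadata
#'   in attributes.
#' @export
compare_degradation <- function(nd, d, tawss_threshold = 25,
                                osi_threshold = 0.15,
                                digitize_threshold = 5, region = "dome") {
  if (nrow(nd) != nrow(d)) {
    stop("field length mismatch: conditions must share the mesh", call. = FALSE)
  }
  mesh <- attr(nd, "mesh")
  keep <- rep(TRUE, nrow(nd))
  reg <- rep(NA_character_, nrow(nd))
  if (!is.null(mesh) && !is.null(mesh$labels)) {
    reg <- mesh$labels
    if (!is.null(region)) keep <- mesh$labels %in% region
  }
  dtawss <- relative_change(nd$tawss, d$tawss)
  dosi <- relative_change(nd$osi, d$osi)
  decap <- relative_change(nd$ecap, d$ecap)
  Cc <- correlation_product(dtawss, dosi)
  out <- tibble::tibble(
    node = nd$node, region = reg,
    tawss_nd = nd$tawss, osi_nd = nd$osi,
    dTAWSS_pct = as.numeric(dtawss), dOSI_pct = as.numeric(dosi),
    dECAP_pct = as.numeric(decap),
    C_corr = Cc,
    C_digitized = digitize_correlation(Cc, digitize_threshold),
    regime = classify_regimes(nd, tawss_threshold, osi_threshold)
  )[keep, ]
  attr(out, "thresholds") <- list(tawss = tawss_threshold, osi = osi_threshold,
                                  digitize = digitize_threshold)
  attr(out, "mesh") <- mesh
  class(out) <- c("degradation_comparison", class(out))
  out
}

#' Per-regime summary of a degradation comparison
#'
#' One row per low/high TAWSS x OSI regime: node count, area fraction (when
#' the mesh is available), mean relative changes and the digitized class
#' composition.
#'
#' @param cmp A [compare_degradation()] result.
#' @return Tibble with one row per non-empty regime.
#' @export
summarize_regimes <- function(cmp) {
  mesh <- attr(cmp, "mesh")
  aw <- if (!is.null(mesh)) node_areas(mesh)[cmp$node] else rep(1, nrow(cmp))
  total_area <- sum(aw)
  split_idx <- split(seq_len(nrow(cmp)), cmp$regime, drop = TRUE)
  rows <- lapply(names(split_idx), function(lv) {
    i <- split_idx[[lv]]
    dig <- cmp$C_digitized[i]
    tibble::tibble(
      regime = lv, n_nodes = length(i),
      area_fraction = sum(aw[i]) / total_area,
      mean_dTAWSS_pct = mean(cmp$dTAWSS_pct[i], na.rm = TRUE),
      mean_dOSI_pct = mean(cmp$dOSI_pct[i], na.rm = TRUE),
      mean_dECAP_pct = mean(cmp$dECAP_pct[i], na.rm = TRUE),
      frac_dig_neg = mean(dig == -1, na.rm = TRUE),
      frac_dig_zero = mean(dig == 0, na.rm = TRUE),
      frac_dig_pos = mean(dig == 1, na.rm = TRUE)
    )
  })
  do.call(rbind, rows)
}

#' Inverse-correlation summary statistics
#'
#' Quantifies how often degradation moved TAWSS and OSI in opposite
#' directions: overall and per regime, the fraction of unmasked,
#' digitized-nonzero nodes with `C_digitized == -1`, plus the mean relative
#' ECAP change in the low-TAWSS/high-OSI regime (the rupture-prone corner).
#' Empty regimes are reported as absent (`NA`), not zero.
#'
#' @param cmp A [compare_degradation()] result.
#' @return List with `overall_inverse_fraction`, `by_regime` (tibble:
#'   `regime`, `n_digitized_nonzero`, `inverse_fraction`),
#'   `mean_dECAP_lowT_highO`, and node bookkeeping counts.
#' @export
inverse_correlation_report <- function(cmp) {
  nz <- !is.na(cmp$C_digitized) & cmp$C_digitized != 0
  overall <- if (any(nz)) mean(cmp$C_digitized[nz] == -1) else NA_real_
  by_reg <- lapply(levels(cmp$regime), function(lv) {
    i <- which(cmp$regime == lv & nz)
    tibble::tibble(
      regime = lv, n_digitized_nonzero = length(i),
      inverse_fraction = if (length(i)) mean(cmp$C_digitized[i] == -1)
                         else NA_real_
    )
  })
  lowhigh <- cmp$regime == "lowT_highO" & !is.na(cmp$dECAP_pct)
  list(
    overall_inverse_fraction = overall,
    by_regime = do.call(rbind, by_reg),
    mean_dECAP_lowT_highO = if (any(lowhigh, na.rm = TRUE))
      mean(cmp$dECAP_pct[which(lowhigh)]) else NA_real_,
    n_nodes = nrow(cmp),
    n_masked = sum(is.na(cmp$C_digitized)),
    n_digitized_nonzero = sum(nz)
  )
}
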