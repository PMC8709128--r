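test_that("waveform normalization and determinism contracts hold", {
  wf <- make_waveform(period = 0.8, mean_level = 2, amplitude = 3)
  w <- aneuflow:::cyclic_trapezoid_weights(wf$t, wf$period)
  expect_equal(sum(w * wf$Q) / wf$period, 2, tolerance = 1e-10)
  expect_equal(diff(range(wf$Q)), 3, tolerance = 1e-12)
  # amplitude 0 -> constant at the mean
  flat <- make_waveform(amplitude = 0, mean_level = 1.5)
  expect_true(all(flat$Q == 1.5))
  # same seed -> identical samples (with jitter active)
  a <- make_waveform(noise_sd = 0.05, seed = 9)
  b <- make_waveform(noise_sd = 0.05, seed = 9)
  expect_identical(a$Q, b$Q)
  # an inflow must stay positive
  expect_error(make_waveform(mean_level = 0.5, amplitude = 3), "positive")
})

test_that("dome mesh honors the requested geometry and labelling", {
  mesh <- make_dome_mesh(24, dome_diameter = 1.0, vessel_diameter = 0.41)
  dome <- mesh$labels == "dome"
  r <- sqrt(rowSums(mesh$nodes^2))
  expect_true(all(abs(r[dome] - 0.5) < 1e-12))       # on the 0.5 cm sphere
  rho <- sqrt(rowSums(mesh$nodes[!dome, 1:2]^2))
  expect_true(all(abs(rho - 0.205) < 1e-12))         # on the 0.205 cm cylinder
  expect_setequal(unique(mesh$labels), c("dome", "parent"))
  expect_length(mesh$labels, nrow(mesh$nodes))       # labels partition nodes
  # refinement doubling multiplies triangle count by ~4
  mesh2 <- make_dome_mesh(48)
  expect_equal(nrow(mesh2$triangles) / nrow(mesh$triangles), 4,
               tolerance = 0.15)
  expect_error(make_dome_mesh(8), "resolution too coarse")
})

test_that("zero effects and zero noise give identical paired series", {
  mesh <- make_dome_mesh(16)
  spec <- synthetic_field_spec(dtawss_low_pct = 0, dosi_low_pct = 0,
                               dtawss_high_pct = 0, dosi_high_pct = 0,
                               n_time = 20)
  pair <- make_paired_wss_series(mesh, spec)
  expect_identical(pair$d$tau, pair$nd$tau)
  cmp <- compare_degradation(hemodynamic_fields(pair$nd),
                             hemodynamic_fields(pair$d))
  expect_true(all(cmp$C_corr[!is.na(cmp$C_corr)] == 0))
})

test_that("pipeline recovers the designed effect sizes exactly (no noise)", {
  mesh <- make_dome_mesh(20)
  spec <- synthetic_field_spec(dtawss_low_pct = -20, dosi_low_pct = 30,
                               n_time = 80)
  pair <- make_paired_wss_series(mesh, spec, make_waveform(period = 0.8))
  f_nd <- hemodynamic_fields(pair$nd)
  f_d <- hemodynamic_fields(pair$d)
  cmp <- compare_degradation(f_nd, f_d)
  low <- !pair$truth$impingement_mask[cmp$node]
  expect_equal(cmp$dTAWSS_pct[low], rep(-20, sum(low)), tolerance = 1e-10)
  expect_equal(cmp$dOSI_pct[low], rep(30, sum(low)), tolerance = 1e-10)
  expect_true(all(cmp$C_digitized[low] == -1))
  # measured baseline fields equal the generator's ground truth
  expect_equal(f_nd$tawss, pair$truth$tawss_nd, tolerance = 1e-12)
  expect_equal(f_nd$osi, pair$truth$osi_nd, tolerance = 1e-12)
})

test_that("recovery degrades gracefully but stays close under noise", {
  mesh <- make_dome_mesh(16)
  spec <- synthetic_field_spec(noise_sd = 0.2, n_time = 80, seed = 21)
  pair <- make_paired_wss_series(mesh, spec)
  cmp <- compare_degradation(hemodynamic_fields(pair$nd),
                             hemodynamic_fields(pair$d))
  low <- !pair$truth$impingement_mask[cmp$node]
  # noise_sd = 0.2 dyn/cm2 on an 8 dyn/cm2 field: mean recovery within ~1%
  expect_equal(mean(cmp$dTAWSS_pct[low]), -20, tolerance = 0.05)
  expect_equal(mean(cmp$dOSI_pct[low]), 30, tolerance = 0.05)
})

test_that("seeded generation is bit-for-bit reproducible", {
  mesh <- make_dome_mesh(16)
  spec <- synthetic_field_spec(noise_sd = 0.1, seed = 33, n_time = 24)
  p1 <- make_paired_wss_series(mesh, spec)
  p2 <- make_paired_wss_series(mesh, spec)
  expect_identical(p1$nd$tau, p2$nd$tau)
  expect_identical(p1$d$tau, p2$d$tau)
})

test_that("reversal-fraction construction sweeps OSI across [0, 0.5]", {
  mesh <- make_dome_mesh(16)
  n_time <- 80
  for (rho in c(0, 0.1, 0.25, 0.4, 0.5)) {
    spec <- synthetic_field_spec(rev_frac_low = rho, rev_frac_high = rho,
                                 dosi_low_pct = 0, dosi_high_pct = 0,
                                 n_time = n_time)
    pair <- make_paired_wss_series(mesh, spec)
    osi <- compute_osi(pair$nd)
    k <- round(rho * n_time)
    if (k == 0) {
      expect_true(all(abs(osi) < 1e-12, na.rm = TRUE))
    } else {
      # closed-form square-wave OSI = k/n at every node
      expect_equal(as.numeric(osi), rep(k / n_time, length(osi)),
                   tolerance = 1e-12)
    }
  }
})

test_that("infeasible effect sizes are rejected", {
  expect_error(synthetic_field_spec(dtawss_low_pct = -120),
               "non-positive magnitudes")
  mesh <- make_dome_mesh(16)
  spec <- synthetic_field_spec(rev_frac_low = 0.4, dosi_low_pct = 60)
  expect_error(make_paired_wss_series(mesh, spec), "0.5 bound")
})
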