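test_that("relative change implements (f_d - f_nd)/f_nd * 100 with masking", {
  expect_equal(relative_change(10, 12), 20, ignore_attr = TRUE)
  expect_equal(relative_change(c(5, 5), c(5, 5)), c(0, 0), ignore_attr = TRUE)
  d <- relative_change(c(10, 0, NA), c(12, 1, 2))
  expect_true(is.na(d[2]) && is.na(d[3]))
  expect_identical(attr(d, "n_masked"), 1L)
  expect_error(relative_change(1:3, 1:4), "mismatch")
})

test_that("correlation product matches the element-wise oracle", {
  expect_equal(correlation_product(-20, 30), -6)
  expect_equal(correlation_product(0, 30), 0)
  set.seed(5)
  a <- rnorm(50, sd = 20); b <- rnorm(50, sd = 20)
  expect_equal(correlation_product(a, b), a * b / 100)  # one-line oracle
})

test_that("digitization is strict at the threshold and keeps a 0 class", {
  expect_identical(digitize_correlation(-6, 5), -1)
  expect_identical(digitize_correlation(4.9, 5), 0)
  expect_identical(digitize_correlation(5, 5), 0)    # strict ">"
  expect_identical(digitize_correlation(-5, 5), 0)
  expect_true(is.na(digitize_correlation(NA_real_, 5)))
  expect_error(digitize_correlation(1, -2), "non-negative")
})

test_that("digitized sign equals the product of the delta signs", {
  set.seed(6)
  dt <- rnorm(200, sd = 30); do <- rnorm(200, sd = 30)
  C <- correlation_product(dt, do)
  dig <- digitize_correlation(C, 5)
  nz <- dig != 0
  expect_true(all(dig[nz] == sign(dt[nz]) * sign(do[nz])))
  # threshold monotonicity: the nonzero set shrinks as the threshold grows
  n_nz <- vapply(c(0, 2, 5, 10, 20),
                 function(th) sum(digitize_correlation(C, th) != 0),
                 numeric(1))
  expect_true(all(diff(n_nz) <= 0))
})

test_that("regime classification thresholds are strict for 'high'", {
  f <- tibble::tibble(tawss = c(30, 25, 24, 30), osi = c(0.1, 0.15, 0.2, NA))
  lab <- classify_regimes(f)
  expect_equal(as.character(lab),
               c("highT_lowO", "lowT_lowO", "lowT_highO", NA))
})

test_that("masks are conserved through the full comparison pipeline", {
  mesh <- make_dome_mesh(16)
  spec <- synthetic_field_spec(rev_frac_high = 0, n_time = 40)  # OSI = 0 patch
  pair <- make_paired_wss_series(mesh, spec)
  f_nd <- hemodynamic_fields(pair$nd)
  f_d <- hemodynamic_fields(pair$d)
  cmp <- compare_degradation(f_nd, f_d)
  # the impingement patch has OSI = 0 in both conditions: dOSI undefined there
  imp <- pair$truth$impingement_mask[cmp$node]
  expect_true(all(is.na(cmp$dOSI_pct[imp])))
  expect_true(all(is.na(cmp$C_corr[imp])))
  expect_true(all(is.na(cmp$C_digitized[imp])))
  # a node undefined upstream is undefined in all downstream maps
  na_chain <- is.na(cmp$dOSI_pct)
  expect_true(all(is.na(cmp$C_corr[na_chain])))
  expect_true(all(is.na(cmp$C_digitized[na_chain])))
  # unmasked counts are monotone non-increasing along the pipeline
  n_defined <- c(sum(!is.na(cmp$dTAWSS_pct)), sum(!is.na(cmp$C_corr)),
                 sum(!is.na(cmp$C_digitized)))
  expect_true(all(diff(n_defined) <= 0))
})

test_that("comparison recovers the generator's designed regime structure", {
  mesh <- make_dome_mesh(20)
  pair <- make_paired_wss_series(mesh, synthetic_field_spec())
  f_nd <- hemodynamic_fields(pair$nd)
  cmp <- compare_degradation(f_nd, hemodynamic_fields(pair$d))
  imp <- pair$truth$impingement_mask[cmp$node]
  # designed low-TAWSS/high-OSI patch classifies as such, impingement as
  # high-TAWSS/low-OSI (TAWSS 40 vs 8 around the 25 dyn/cm2 threshold,
  # OSI 0.25 vs 0.05 around 0.15)
  expect_true(all(cmp$regime[!imp] == "lowT_highO"))
  expect_true(all(cmp$regime[imp] == "highT_lowO"))
  summ <- summarize_regimes(cmp)
  expect_setequal(summ$regime, c("lowT_highO", "highT_lowO"))
  expect_equal(sum(summ$n_nodes), nrow(cmp))
  expect_equal(sum(summ$area_fraction), 1, tolerance = 1e-12)
})

test_that("inverse-correlation report orders regimes as designed", {
  mesh <- make_dome_mesh(20)
  pair <- make_paired_wss_series(mesh, synthetic_field_spec())
  cmp <- compare_degradation(hemodynamic_fields(pair$nd),
                             hemodynamic_fields(pair$d))
  rep <- inverse_correlation_report(cmp)
  br <- rep$by_regime
  inv_low <- br$inverse_fraction[br$regime == "lowT_highO"]
  inv_high <- br$inverse_fraction[br$regime == "highT_lowO"]
  expect_gt(inv_low, inv_high)   # inverse coupling concentrated at low WSS
  expect_equal(inv_low, 1)
  expect_equal(inv_high, 0)
  # empty regimes are reported absent, not zero
  expect_true(is.na(br$inverse_fraction[br$regime == "lowT_lowO"]))
  # all-negative / balanced sanity checks on the digitized fractions
  all_neg <- tibble::tibble(C_digitized = rep(-1, 10),
                            regime = factor(rep("lowT_highO", 10),
                                            levels = levels(cmp$regime)),
                            dECAP_pct = 1)
  expect_equal(inverse_correlation_report(all_neg)$overall_inverse_fraction, 1)
  balanced <- tibble::tibble(C_digitized = rep(c(-1, 1), 5),
                             regime = factor(rep("lowT_highO", 10),
                                             levels = levels(cmp$regime)),
                             dECAP_pct = 1)
  expect_equal(inverse_correlation_report(balanced)$overall_inverse_fraction,
               0.5)
})
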