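test_that("the analytic plan delivers the prescription at the PTV surface", {
  plan <- reference_plan()
  expect_equal(plan$d_max_gy, 60)            # 48 Gy at the 80% isodose
  expect_equal(dose_profile(plan, plan$ptv_radius_mm), 48, tolerance = 5e-3)
  expect_equal(dose_profile(plan, 0), 60, tolerance = 1e-3)
  r <- seq(0, 40, by = 0.5)
  expect_true(all(diff(dose_profile(plan, r)) <= 0))
})

test_that("the reference dose grid is spherically symmetric", {
  ref <- build_reference_dose(reference_plan(), spacing_mm = 2,
                              n_voxels = 41)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(1, 3, 2)))
    expect_equal(max(abs(ref$dose_gy - aperm(ref$dose_gy, perm))), 0)
  expect_error(build_reference_dose(reference_plan(), spacing_mm = 1,
                                    n_voxels = 21), "grid too small")
})

test_that("position PDFs are normalized histograms around the plan position", {
  tr <- stationary_trace(duration_s = 30)
  pa <- assign_phase(tr)
  m <- compute_gating_mask(pa, gating_window("phase", "expiration"))
  for (d in c("ap", "cc", "lr")) {
    pdf <- build_position_pdf(tr, m, pa, d)
    expect_equal(sum(pdf$mass), 1, tolerance = 1e-9)
    expect_true(all(pdf$mass >= 0))
    expect_true(!is.unsorted(pdf$bin_edges_mm, strictly = TRUE))
  }
  # a direction with no motion concentrates in a single bin
  flat <- resp_trace(tr$time_s, tr$pos[, "ap"], tr$pos[, "cc"],
                     rep(2.2, length(tr$time_s)))
  pdf_lr <- build_position_pdf(flat, m, pa, "lr")
  expect_identical(sum(pdf_lr$mass > 0), 1L)
  expect_equal(max(pdf_lr$mass), 1)
  # PDF support tracks the gated residual range
  res <- compute_residual_motion(tr, m, pa)
  pdf_cc <- build_position_pdf(tr, m, pa, "cc")
  occupied <- range(which(pdf_cc$mass > 0))
  width <- diff(pdf_cc$bin_edges_mm[c(occupied[1], occupied[2] + 1L)])
  expect_lt(abs(width - res$mean_mm["cc"]), 1.5)
  off <- m
  off$on[] <- FALSE
  expect_error(build_position_pdf(tr, off, pa, "cc"), "beam-on")
})

test_that("probability integration pro-rates partial bins", {
  unif <- structure(list(direction = "cc", bin_edges_mm = 0:10,
                         mass = rep(0.1, 10), planned_mm = 0),
                    class = "position_pdf")
  expect_equal(compute_pctv(unif, 0, 3), 0.3)
  expect_equal(compute_pctv(unif, 0.25, 0.75), 0.05)
  expect_equal(compute_pctv(unif, -5, 15), 1)
  expect_equal(compute_pctv(unif, -5, -1), 0)
  expect_error(compute_pctv(unif, 3, 3), "a_lower_mm")
  # disjoint exhaustive partition sums to one
  cuts <- c(-Inf, 2.5, 5, 7.25, Inf)
  parts <- vapply(seq_len(4), function(i)
    compute_pctv(unif, cuts[i], cuts[i + 1]), numeric(1))
  expect_equal(sum(parts), 1, tolerance = 1e-12)
})

test_that("delta kernels reproduce identity and pure translation", {
  ref <- build_reference_dose(reference_plan(), spacing_mm = 1,
                              n_voxels = 91)
  same <- convolve_dose(ref, list(cc = delta_pdf(0)))
  expect_equal(same$dose_gy, ref$dose_gy, tolerance = 1e-12)
  # translation on a compact blob whose support clears the kernel width
  n <- 31
  co <- seq_len(n) - (n + 1) / 2
  r <- sqrt(outer(outer(co^2, co^2, `+`), co^2, `+`))
  blob <- dose_grid(array(60 * (r <= 3), dim = c(n, n, n)), 1,
                    rep(-(n - 1) / 2, 3))
  shifted <- convolve_dose(blob, list(cc = delta_pdf(5)))
  expect_equal(shifted$dose_gy[, 6:n, ], blob$dose_gy[, 1:(n - 5), ],
               tolerance = 1e-12)
  expect_equal(max(abs(shifted$dose_gy[, 1:5, ])), 0)
})

test_that("separable convolution matches direct 3-D convolution", {
  # compact spherical dose blob so that the boundary carries no dose
  n <- 31
  co <- (seq_len(n) - (n + 1) / 2)
  r <- sqrt(outer(outer(co^2, co^2, `+`), co^2, `+`))
  blob <- dose_grid(array(60 * (r <= 3), dim = c(n, n, n)), 1,
                    rep(-(n - 1) / 2, 3))
  pdfs <- list(lr = gaussian_pdf(3, 7, direction = "lr"),
               cc = gaussian_pdf(3, 7, direction = "cc", shift_mm = 2),
               ap = gaussian_pdf(3, 7, direction = "ap"))
  sep <- convolve_dose(blob, pdfs)
  kernels <- lapply(pdfs, function(p) respgate:::pdf_to_kernel(p, 1))
  direct <- oracle_convolve3d(blob$dose_gy,
                              kernels[c("lr", "cc", "ap")])
  expect_lt(max(abs(sep$dose_gy - direct)), 1e-8 * 60)
  expect_lt(abs(sum(sep$dose_gy) - sum(blob$dose_gy)),
            1e-6 * sum(blob$dose_gy))
  expect_true(all(sep$dose_gy >= 0))
})

test_that("convolution refuses to push dose off the grid", {
  ref <- build_reference_dose(reference_plan(), spacing_mm = 1,
                              n_voxels = 81)
  expect_error(convolve_dose(ref, list(cc = delta_pdf(30))),
               "insufficient padding")
})

test_that("DVH metrics follow the empirical dose distribution", {
  # uniform dose: D2 = D98 = D50, HI = 0
  unif <- dose_grid(array(60, dim = c(31, 31, 31)), 1, rep(-15, 3))
  dvh <- compute_dvh(unif, ctv_diameter_mm = 20)
  expect_equal(dvh$metrics$D2, 60)
  expect_equal(dvh$metrics$D98, 60)
  expect_equal(dvh$metrics$HI, 0)
  expect_true(all(diff(dvh$volume_fraction) <= 0))
  expect_error(compute_dvh(unif, ctv_center_mm = c(12, 0, 0),
                           ctv_diameter_mm = 20), "outside")

  # graded dose field: metrics match the voxel-exhaustive oracle
  co <- (seq_len(31) - 16)
  grad <- dose_grid(array(rep(50 + co, each = 31 * 31),
                          dim = c(31, 31, 31)), 1, rep(-15, 3))
  dvh_g <- compute_dvh(grad, ctv_diameter_mm = 16)
  orac <- oracle_dvh_metrics(grad, c(0, 0, 0), 16)
  expect_equal(dvh_g$n_voxels, orac$n)
  expect_equal(dvh_g$metrics$D2, orac$D2, tolerance = 1e-9)
  expect_equal(dvh_g$metrics$D98, orac$D98, tolerance = 1e-9)
  expect_equal(dvh_g$metrics$D50, orac$D50, tolerance = 1e-9)
  expect_equal(dvh_g$metrics$HI,
               (orac$D2 - orac$D98) / orac$D50, tolerance = 1e-9)
  # D98 <= D50 <= D2 ordering
  expect_true(dvh_g$metrics$D98 <= dvh_g$metrics$D50)
  expect_true(dvh_g$metrics$D50 <= dvh_g$metrics$D2)
})

test_that("blurring never sharpens the target dose", {
  ref <- build_reference_dose(reference_plan(), spacing_mm = 2,
                              n_voxels = 61)
  hi_ref <- compute_dvh(ref)$metrics$HI
  blur <- convolve_dose(ref, list(cc = gaussian_pdf(3, 7, bin_width_mm = 2),
                                  ap = gaussian_pdf(2, 6, bin_width_mm = 2,
                                                    direction = "ap")))
  hi_blur <- compute_dvh(blur)$metrics$HI
  expect_gt(hi_blur, hi_ref)
})

test_that("gated dose analysis composes the stages coherently", {
  tr <- drifting_trace(drift_cc = -0.3, duration_s = 60)
  g <- gated_dose_analysis(tr, "phase", "expiration", spacing_mm = 2)
  expect_s3_class(g$dvh, "dvh_curve")
  expect_true(g$hi > g$reference_hi)
  expect_true(g$p_ctv >= 0 && g$p_ctv <= 1)
  # a stationary trace barely blurs the plan
  ts <- stationary_trace(duration_s = 30)
  gs <- gated_dose_analysis(ts, "phase", "expiration", spacing_mm = 2)
  expect_lt(gs$hi, g$hi)
  tab <- gated_dose_table(list(ts), spacing_mm = 2)
  expect_identical(nrow(tab), 6L)
  expect_true(all(is.finite(tab$HI)))
})
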