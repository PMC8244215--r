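make_gpd <- function(xi = 0, sigma = 500) {
  structure(list(xi = xi, sigma = sigma, fallback = FALSE,
                 loglik = NA_real_), class = "gpd_params")
}

test_that("used composition averages the 3x3 window and renormalises", {
  cm <- matrix(1L, 9, 9)          # all class A
  cm[5, 5:7] <- 2L                # 3 of the 9 window cells are class B
  st <- stack_from_classes(cm)
  comp <- extract_used_composition(list(x = 5.5, y = 3.5), st)
  expect_equal(unname(comp["class_B"]), 3 / 9)
  expect_equal(sum(comp), 1)

  # homogeneous window
  hom <- extract_used_composition(list(x = 1.5, y = 7.5), st)
  expect_equal(unname(hom["class_A"]), 1)

  # corner fix: 4-cell window, still sums to 1
  corner <- extract_used_composition(list(x = 0.5, y = 8.5), st)
  expect_equal(sum(corner), 1)
})

test_that("available composition weights near cells more than far ones", {
  # class B on two rings of equal cell count, near (d1) vs far (d2)
  cm <- matrix(1L, 21, 21)
  cm[11, c(9, 13)] <- 2L          # near ring, distance 2
  cm2 <- matrix(1L, 21, 21)
  cm2[11, c(3, 19)] <- 2L         # far ring, distance 8
  fix <- list(x = 10.5, y = 10.5)
  gpd <- make_gpd(0, 2)
  near <- extract_available_composition(fix, stack_from_classes(cm),
                                        radius = 10, gpd = gpd)
  far <- extract_available_composition(fix, stack_from_classes(cm2),
                                       radius = 10, gpd = gpd)
  expect_gt(near["class_B"], far["class_B"])
  expect_equal(sum(near), 1)

  # homogeneous landscape: composition is the single class, any gpd
  hom <- extract_available_composition(fix, stack_from_classes(
    matrix(1L, 21, 21), classes = "class_A"), radius = 6, gpd = gpd)
  expect_equal(unname(hom), 1)

  # symmetric half-planes around a centred fix: about half each
  hp <- matrix(1L, 21, 20)
  hp[, 11:20] <- 2L
  half <- extract_available_composition(list(x = 10, y = 10.5),
                                        stack_from_classes(hp),
                                        radius = 8, gpd = gpd)
  expect_equal(unname(half["class_A"]), 0.5, tolerance = 0.02)
})

test_that("psf fit is null under no selection and antisymmetric to swaps", {
  set.seed(5)
  st <- generate_landscape(40, 40, 3, 3, seed = 5)
  gpd <- make_gpd(0, 5 * 125)
  # null: used cells drawn like available cells (beta = 0)
  tab <- simulate_psf_strata(st, c(class_B = 0, class_C = 0), "class_A",
                             n_strata = 400, radius = 1000, gpd = gpd,
                             seed = 7)
  m0 <- fit_psf(tab, "class_A")
  expect_true(all(abs(m0$coef) < 0.35))

  # swapping roles flips coefficient signs
  rows <- tab$rows
  rows$role <- ifelse(rows$role == "used", "available", "used")
  # swapped table has >1 used rows per stratum; collapse to 1 per stratum
  keep <- !duplicated(paste(rows$stratum, rows$role)) |
    rows$role == "available"
  swapped <- used_available_table(rows[keep, ], tab$classes)
  m1 <- fit_psf(swapped, "class_A")
  expect_lt(max(abs(m1$coef + m0$coef)), 0.2)
})

test_that("psf recovers known selection strengths from synthetic strata", {
  st <- generate_landscape(50, 50, 3, 4, seed = 2)
  beta <- c(class_B = 2, class_C = -1)

  # shared availability (radius covering the landscape): the pooled
  # logistic contrast is an exact exponential tilt and recovers beta
  flat_gpd <- make_gpd(0, 1e6)
  tab_g <- simulate_psf_strata(st, beta, "class_A", n_strata = 800,
                               radius = 1e4, gpd = flat_gpd, seed = 3)
  fit_g <- fit_psf(tab_g, "class_A")
  expect_lt(max(abs(fit_g$coef[names(beta)] - beta)), 0.3)
  expect_true(all(fit_g$se > 0))

  # local availability disks: the stratum-conditional likelihood stays
  # consistent where the pooled contrast attenuates
  gpd <- make_gpd(0, 5 * 125)
  tab_l <- simulate_psf_strata(st, beta, "class_A", n_strata = 800,
                               radius = 1500, gpd = gpd, seed = 3)
  cfit <- fit_psf(tab_l, "class_A", method = "conditional")
  expect_lt(max(abs(cfit$coef[names(beta)] - beta)), 0.3)

  # coefficient table is shaped like a report table with an NA reference
  tab2 <- psf_coefficients(fit_g)
  expect_true(is.na(tab2$estimate[tab2$class == "class_A"]))
})

test_that("cross-validated AUC separates signal from null", {
  st <- generate_landscape(50, 50, 3, 4, seed = 8)
  gpd <- make_gpd(0, 5 * 125)
  strong <- simulate_psf_strata(st, c(class_B = 3, class_C = -3),
                                "class_A", n_strata = 300, radius = 3000,
                                gpd = gpd, seed = 4)
  auc_strong <- crossvalidate_psf(strong, k = 5, seed = 1)
  expect_gt(auc_strong, 0.8)

  null <- simulate_psf_strata(st, c(class_B = 0, class_C = 0), "class_A",
                              n_strata = 300, radius = 3000, gpd = gpd,
                              seed = 5)
  auc_null <- crossvalidate_psf(null, k = 5, seed = 1)
  expect_lt(abs(auc_null - 0.5), 0.08)

  # spatial fold assignment also runs and scores
  auc_sp <- crossvalidate_psf(strong, k = 5, spatial = TRUE, seed = 1)
  expect_gt(auc_sp, 0.7)

  # fixed seed, fixed folds: stable
  expect_identical(auc_strong, crossvalidate_psf(strong, k = 5, seed = 1))
})

test_that("predicted conductance matches the generating formula exactly", {
  st <- generate_landscape(30, 30, 3, 3, seed = 6)
  beta <- c(class_B = 1.4, class_C = -0.6)
  truth <- conductance_from_truth(st, beta, "class_A")
  model <- structure(list(coef = beta, se = beta * 0, reference = "class_A",
                          loglik = NA_real_, method = "pooled",
                          separation = FALSE), class = "psf_model")
  pred <- predict_conductance(model, st)
  expect_equal(pred$values, truth$values, tolerance = 1e-12)
  expect_true(all(pred$values > 0 & pred$values < 1))

  # road-scale avoidance: essentially impassable but never exactly 0
  road <- structure(list(coef = c(class_B = -29.68), se = c(class_B = 0),
                         reference = "class_A", loglik = NA_real_,
                         method = "pooled", separation = FALSE),
                    class = "psf_model")
  two <- stack_from_classes(matrix(2L, 3, 3), classes = c("class_B"))
  two$classes <- c("class_B")
  v <- predict_conductance(road, two)$values[1, 1]
  expect_lt(v, 1e-12)
  expect_gt(v, 0)

  # reference-class-only cell scores 0.5
  refonly <- stack_from_classes(matrix(1L, 2, 2), classes = "class_A")
  m2 <- structure(list(coef = c(class_B = 3), se = c(class_B = 0),
                       reference = "class_A", loglik = NA_real_,
                       method = "pooled", separation = FALSE),
                  class = "psf_model")
  expect_equal(predict_conductance(m2, refonly)$values[1, 1], 0.5)
})
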