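test_that("absolute activity follows %ID/g x ID/100 x mass x exp(-kt)", {
  expect_equal(activity_at(10, 1e6, 1, cu64, 0), 1e5)
  expect_equal(activity_at(10, 1e6, 1, cu64, 45720), 5e4)
  lam <- cu64$decay_constant
  expect_equal(activity_at(14.9, 1e6, 0.5, cu64, 86400),
               74500 * exp(-lam * 86400))
  expect_equal(activity_at(14.9, 1e6, 0.5, cu64, 86400), 2.01e4,
               tolerance = 1e-3)
  # decay can be switched off for non-decay-corrected tables
  expect_equal(activity_at(10, 1e6, 2, cu64, 86400, decay = FALSE), 2e5)
  expect_error(activity_at(10, 1e6, NA, cu64, 0), class = "mirdose_missing_mass")
  expect_error(activity_at(-1, 1e6, 1, cu64, 0), class = "mirdose_invalid_argument")
})

test_that("trapezoidal AUC handles boundary rules and hand-computed curves", {
  const <- time_activity_curve("blood", cu64, c(0, 1000), c(100, 100))
  expect_equal(integrate_to_T(const, 1000), 1e5)
  tri <- time_activity_curve("blood", cu64, c(0, 100), c(0, 100))
  expect_equal(integrate_to_T(tri, 100), 5000)

  # piecewise trapezoid by hand with the plateau rule on [0, 6 h]
  pw <- time_activity_curve("liver", cu64, c(21600, 86400, 172800),
                            c(1000, 500, 250), boundary_rule = "plateau")
  expect_equal(integrate_to_T(pw, 172800), 21.6e6 + 48.6e6 + 32.4e6)

  pw0 <- time_activity_curve("liver", cu64, c(21600, 86400, 172800),
                             c(1000, 500, 250), boundary_rule = "zero")
  expect_equal(integrate_to_T(pw0, 172800), 10.8e6 + 48.6e6 + 32.4e6)

  # linear back-extrapolation: slope (500-1000)/64800, A(0) = 1166.67
  pwl <- time_activity_curve("liver", cu64, c(21600, 86400, 172800),
                             c(1000, 500, 250), boundary_rule = "linear")
  a0 <- 1000 + 500 / 64800 * 21600
  expect_equal(integrate_to_T(pwl, 172800),
               (a0 + 1000) / 2 * 21600 + 48.6e6 + 32.4e6)

  # linear rule floors at zero for steeply rising curves
  rise <- time_activity_curve("tumour", cu64, c(100, 200), c(10, 1000),
                              boundary_rule = "linear")
  expect_equal(integrate_to_T(rise, 200), 10 / 2 * 100 + (10 + 1000) / 2 * 100)

  # integration limit inside the observation window interpolates at T
  expect_equal(integrate_to_T(tri, 50), 50 * 50 / 2)
  expect_error(integrate_to_T(pw, 1000), class = "mirdose_invalid_argument")
})

test_that("tail integral is A(T)/lambda", {
  expect_equal(tail_integral(1000, 1e-5), 1e8)
  expect_equal(tail_integral(0, cu64), 0)
  expect_equal(tail_integral(500, cu64), 500 / cu64$decay_constant)
  expect_equal(tail_integral(500, cu64), 3.298e7, tolerance = 1e-3)
  expect_error(tail_integral(-1, cu64), class = "mirdose_invalid_argument")
})

test_that("single-point TIA is rectangle plus tail; linearity in ID is exact", {
  bd <- data.frame(subject_id = "m1", group_id = "g", organ = "liver",
                   time_h = 48, pct_id_per_g = 10)
  tia <- time_integrated_activity(bd, cu64, 1e6, 1, T_h = 48)
  A <- activity_at(10, 1e6, 1, cu64, hours_to_seconds(48))
  expect_equal(tia$auc_0_T_Bq_s, A * hours_to_seconds(48))
  expect_equal(tia$tail_Bq_s, A / cu64$decay_constant)
  expect_equal(tia$total_Bq_s, tia$auc_0_T_Bq_s + tia$tail_Bq_s)

  tia2 <- time_integrated_activity(bd, cu64, 2e6, 1, T_h = 48)
  expect_equal(tia2$total_Bq_s, 2 * tia$total_Bq_s)
})

test_that("pure-decay curves recover the closed form A0/lambda", {
  # decay-corrected %ID/g constant => A(t) = A0 exp(-lambda t)
  lam <- cu64$decay_constant
  A0 <- 1e5
  bd <- make_biodist(organs = "liver", times_h = c(6, 24, 48), n = 1,
                     pct = function(o, t) 10)
  tia <- time_integrated_activity(bd, cu64, 1e6, 1, T_h = 48)
  closed <- A0 / lam
  expect_lt(abs(tia$total_Bq_s - closed) / closed, 0.02)
  # with the origin observed, trapezoid >= true integral on a convex curve
  bd0 <- make_biodist(organs = "liver", times_h = c(0, 6, 24, 48), n = 1,
                      pct = function(o, t) 10)
  tia0 <- time_integrated_activity(bd0, cu64, 1e6, 1, T_h = 48)
  expect_gte(tia0$total_Bq_s,
             A0 * (1 - exp(-lam * hours_to_seconds(48))) / lam + tia0$tail_Bq_s)

  # convergence: denser sampling approaches the closed form
  dense <- make_biodist(organs = "liver", times_h = seq(0, 48, by = 1), n = 1,
                        pct = function(o, t) 10)
  tia_d <- time_integrated_activity(dense, cu64, 1e6, 1, T_h = 48)
  expect_lt(abs(tia_d$total_Bq_s - closed), abs(tia$total_Bq_s - closed))
  expect_lt(abs(tia_d$total_Bq_s - closed) / closed, 1e-3)
})

test_that("TIA tables cover organs, demand masses, and warn on early tails", {
  bd <- make_biodist(organs = c("liver", "kidneys"), n = 2,
                     pct = function(o, t) if (o == "liver") 8 else 5)
  masses <- c(liver = 1.5, kidneys = 0.4)
  tt <- tia_table(bd, lu177, 6.5e6, masses)
  expect_setequal(tt$organ, c("liver", "kidneys"))
  expect_true(all(tt$total_Bq_s == tt$auc_Bq_s + tt$tail_Bq_s))
  expect_true(all(tt$total_Bq_s >= tt$tail_Bq_s & tt$total_Bq_s >= tt$auc_Bq_s))
  expect_error(tia_table(bd, lu177, 6.5e6, c(liver = 1.5)),
               class = "mirdose_missing_mass")
  expect_warning(
    time_integrated_activity(bd[bd$organ == "liver" & bd$time_h <= 24, ],
                             lu177, 6.5e6, 1.5, T_h = 48),
    class = "mirdose_early_tail")
})

test_that("organ-mass registry ships documented mouse defaults", {
  m <- organ_mass_registry()
  expect_true(all(c("liver", "blood", "whole_body") %in% names(m)))
  expect_true(all(m > 0))
  expect_equal(unname(m["whole_body"]), 30)
  expect_error(organ_mass_registry("rat"), class = "mirdose_missing_data")
})
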