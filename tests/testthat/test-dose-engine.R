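make_tias <- function(...) {
  v <- c(...)
  data.frame(organ = names(v), auc_Bq_s = v * 0.8, tail_Bq_s = v * 0.2,
             total_Bq_s = v, T_s = 172800)
}

self_table <- function(S) {
  svalue_table(data.frame(source = names(S), target = names(S),
                          S_Gy_per_Bq_s = unname(S)),
               nuclide_name = "Lu-177", phantom_id = "test")
}

test_that("equivalent dose is A_s x S x W_R with source additivity", {
  tias <- make_tias(liver = 1e8)
  rep <- equivalent_dose(tias, self_table(c(liver = 1e-9)), injected_MBq = 1)
  expect_equal(rep$dose_Sv, 0.1)
  expect_equal(rep$dose_Sv_per_MBq, 0.1)

  # zero activity everywhere gives zero dose
  rep0 <- equivalent_dose(make_tias(liver = 0, kidneys = 0),
                          self_table(c(liver = 1e-9, kidneys = 2e-9)))
  expect_true(all(rep0$dose_Sv == 0))

  # cross-organ contributions add: 0.05 + 0.02 Sv to one target
  cross <- svalue_table(data.frame(
    source = c("liver", "kidneys", "kidneys"),
    target = c("liver", "liver", "kidneys"),
    S_Gy_per_Bq_s = c(5e-10, 2e-10, 1e-9)))
  rep2 <- equivalent_dose(make_tias(liver = 1e8, kidneys = 1e8), cross)
  expect_equal(rep2$dose_Sv[rep2$target == "liver"], 0.05 + 0.02)

  # cross_organ = FALSE keeps self terms only
  rep3 <- equivalent_dose(make_tias(liver = 1e8, kidneys = 1e8), cross,
                          cross_organ = FALSE)
  expect_equal(rep3$dose_Sv[rep3$target == "liver"], 0.05)

  # W_R scales linearly
  repw <- equivalent_dose(tias, self_table(c(liver = 1e-9)), w_r = 2)
  expect_equal(repw$dose_Sv, 0.2)

  expect_error(equivalent_dose(make_tias(liver = 1, spleen = 1),
                               self_table(c(liver = 1e-9))),
               class = "mirdose_missing_svalue")
})

test_that("sphere S-values interpolate log-log, exactly at nodes", {
  curve <- sphere_svalue_curve(c(1, 10), c(1e-9, 1e-10))
  expect_equal(sphere_s_value(1, curve), 1e-9)
  expect_equal(sphere_s_value(10, curve), 1e-10)
  # geometric midpoint in log-log space
  expect_equal(sphere_s_value(10^0.5, curve), 10^-9.5)
  expect_equal(sphere_s_value(3.1623, curve), 3.1623e-10, tolerance = 1e-4)

  expect_error(sphere_s_value(0.5, curve), class = "mirdose_range_error")
  expect_error(sphere_s_value(20, curve), class = "mirdose_range_error")
  expect_warning(s <- sphere_s_value(20, curve, clamp = TRUE),
                 class = "mirdose_clamped")
  expect_equal(s, 1e-10)

  # 2 cm unit-density sphere weighs (4/3) pi r^3
  expect_equal(sphere_mass_g(2), 4 / 3 * pi)
  expect_equal(sphere_mass_g(2), 4.19, tolerance = 1e-3)

  expect_error(sphere_svalue_curve(c(1, 10), c(1e-10, 1e-9)),
               class = "mirdose_schema_error")  # must decrease with mass
  expect_error(sphere_svalue_curve(1, 1e-9), class = "mirdose_schema_error")
})

test_that("sphere interpolation is monotone and S*m is constant for 1/m curves", {
  masses <- exp(seq(log(0.2), log(15), length.out = 10))
  k <- 3.2e-10
  curve <- sphere_svalue_curve(masses, k / masses)
  q <- exp(seq(log(0.2), log(15), length.out = 57))
  s <- vapply(q, sphere_s_value, numeric(1), curve = curve)
  expect_true(all(diff(s) < 0))
  expect_equal(s * q, rep(k, length(q)), tolerance = 1e-9)
})

test_that("whole-body TIA supports measured-row and sum-of-sources modes", {
  tias <- make_tias(liver = 1e8, kidneys = 2e8)
  wb <- whole_body_tia(tias, "sum_of_sources")
  expect_equal(wb$total_Bq_s, 3e8)
  expect_error(whole_body_tia(tias, "measured_row"),
               class = "mirdose_missing_data")
  tias_wb <- rbind(tias, make_tias(whole_body = 5e8))
  expect_equal(whole_body_tia(tias_wb, "measured_row")$total_Bq_s, 5e8)
  # sum mode excludes the measured whole-body row itself
  expect_equal(whole_body_tia(tias_wb, "sum_of_sources")$total_Bq_s, 3e8)
  expect_equal(whole_body_tia(make_tias(liver = 1e8)[0, ],
                              "sum_of_sources")$total_Bq_s, 0)
})

test_that("E_mean/m fixtures reproduce the energy-deposition oracle exactly", {
  masses <- c(liver = 1.5, kidneys = 0.4, spleen = 0.1, blood = 1.8)
  e_mev <- 0.147  # mean beta energy scale for Lu-177
  fx <- make_s_value_fixture(lu177, masses, e_mev)
  tias <- make_tias(liver = 3e8, kidneys = 8e7, spleen = 2e7, blood = 5e8)
  rep <- equivalent_dose(tias, fx$s_table, injected_MBq = 6.5)
  for (o in names(masses)) {
    oracle <- energy_deposition_dose(tias$total_Bq_s[tias$organ == o],
                                     e_mev, masses[[o]])
    expect_equal(rep$dose_Sv[rep$target == o], oracle, tolerance = 1e-9)
  }
})

test_that("tumour doses flow through the sphere model only", {
  masses <- c(liver = 1.5)
  fx <- make_s_value_fixture(lu177, masses, 0.147)
  tias <- rbind(make_tias(liver = 1e8), make_tias(tumour = 2e8))
  rep <- equivalent_dose(tias, fx$s_table, sphere_curve = fx$sphere,
                         tumour_mass_g = 0.35, injected_MBq = 6.5)
  oracle <- energy_deposition_dose(2e8, 0.147, 0.35)
  expect_equal(rep$dose_Sv[rep$target == "tumour"], oracle, tolerance = 1e-6)
  expect_error(equivalent_dose(tias, fx$s_table, tumour_mass_g = 0.35),
               class = "mirdose_missing_svalue")
  expect_error(equivalent_dose(tias, fx$s_table, sphere_curve = fx$sphere),
               class = "mirdose_missing_mass")
})

test_that("S-value tables round-trip through their text format", {
  fx <- make_s_value_fixture(lu177, c(liver = 1.5, kidneys = 0.4), 0.147)
  path <- withr::local_tempfile(fileext = ".csv")
  e <- fx$s_table$entries
  utils::write.table(cbind(nuclide = "Lu-177", phantom_id = "synthetic", e),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  back <- read_svalue_table(path)
  expect_equal(back$entries$S_Gy_per_Bq_s, e$S_Gy_per_Bq_s)
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(data.frame(nuclide = "Lu-177",
                                mass_g = fx$sphere$mass_g,
                                S_Gy_per_Bq_s = fx$sphere$S_Gy_per_Bq_s),
                     path2, sep = ",", row.names = FALSE, quote = FALSE)
  sph <- read_sphere_curve(path2)
  expect_equal(sph$S_Gy_per_Bq_s, fx$sphere$S_Gy_per_Bq_s)
})
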