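test_that("kinetic specs validate their parameters", {
  expect_error(organ_kinetic_spec("blood", "biexponential_decline",
                                  list(A1 = 1, k1 = 0)),
               class = "mirdose_invalid_argument")
  expect_error(organ_kinetic_spec("tumour", "uptake_washout",
                                  list(A = 10, k_up = 0.01, k_wash = 0.05)),
               class = "mirdose_invalid_argument")
  expect_error(organ_kinetic_spec("nonsense_organ", "uptake_washout",
                                  list(A = 10, k_up = 0.1, k_wash = 0.02)),
               class = "mirdose_invalid_argument")
  spec <- organ_kinetic_spec("tumour", "uptake_washout",
                             list(A = 31.5, k_up = 0.08, k_wash = 0.02))
  # uptake-washout peaks at ln(ku/kw)/(ku-kw), here near 24 h
  t_peak <- log(0.08 / 0.02) / (0.08 - 0.02)
  grid <- seq(1, 48, by = 0.5)
  expect_equal(grid[which.max(kinetic_value(spec, grid))], t_peak,
               tolerance = 0.03)
})

test_that("zero-noise simulation reproduces the model curve exactly", {
  specs <- paper_like_kinetics(noise_cv = 0)
  sim <- simulate_biodist(specs, seed = 1, n_per_group = 2)
  for (o in c("blood", "tumour", "liver")) {
    for (t in c(6, 24, 48)) {
      v <- sim$pct_id_per_g[sim$organ == o & sim$time_h == t]
      expect_equal(v, rep(kinetic_value(specs[[o]], t), 2))
    }
  }
})

test_that("the generator is a pure function of (spec, seed)", {
  specs <- paper_like_kinetics()
  s1 <- simulate_biodist(specs, seed = 99)
  s2 <- simulate_biodist(specs, seed = 99)
  expect_identical(s1, s2)
  s3 <- simulate_biodist(specs, seed = 100)
  expect_false(identical(s1$pct_id_per_g, s3$pct_id_per_g))
  expect_error(simulate_biodist(specs), class = "mirdose_invalid_argument")
  # destructive sampling: subject ids are distinct across time points
  expect_equal(length(unique(s1$subject_id)), 3 * 4)
  expect_true(all(table(s1$subject_id, s1$time_h) %in% c(0, length(specs))))
})

test_that("default kinetics hit the stated blood anchors (law of large numbers)", {
  specs <- paper_like_kinetics(noise_cv = 0.10)
  sim <- simulate_biodist(specs, times_h = c(6, 48), n_per_group = 50, seed = 7)
  m6 <- mean(sim$pct_id_per_g[sim$organ == "blood" & sim$time_h == 6])
  m48 <- mean(sim$pct_id_per_g[sim$organ == "blood" & sim$time_h == 48])
  expect_lt(abs(m6 - 10.6) / 10.6, 0.05)
  expect_lt(abs(m48 - 1.9) / 1.9, 0.05)
  # tumour peaks near 24 h in the noise-free curve
  tum <- specs$tumour
  expect_gt(kinetic_value(tum, 24), kinetic_value(tum, 6))
  expect_gt(kinetic_value(tum, 24), kinetic_value(tum, 48))
})

test_that("binding-assay simulation matches the model in the noiseless limit", {
  d <- simulate_binding_assay(2.9, 1.83, 0.002, noise_cv = 0, seed = 1)
  sb <- d$total_bound_pmol - d$nonspecific_bound_pmol
  f <- d$free_conc_nM
  expect_equal(sb, 1.83 * f / (2.9 + f))
  # saturation: SB at F = 1000 Kd is within 0.1% of Bmax
  d_sat <- simulate_binding_assay(2.9, 1.83, 0, series = 2900, noise_cv = 0,
                                  n_replicates = 1, seed = 1)
  expect_equal(d_sat$total_bound_pmol, 1.83, tolerance = 1e-3)
  # duplicates and determinism
  expect_equal(sum(d$replicate == 1), sum(d$replicate == 2))
  expect_identical(simulate_binding_assay(2.9, 1.83, seed = 4),
                   simulate_binding_assay(2.9, 1.83, seed = 4))
})

test_that("E_mean/m fixture construction is the stated unit conversion", {
  fx <- make_s_value_fixture(lu177, c(liver = 1), 1)  # 1 g, 1 MeV
  expect_equal(fx$s_table$entries$S_Gy_per_Bq_s, 1.602176634e-10)
  fx2 <- make_s_value_fixture(lu177, c(liver = 2), 1)
  expect_equal(fx2$s_table$entries$S_Gy_per_Bq_s,
               fx$s_table$entries$S_Gy_per_Bq_s / 2)
  expect_true(all(diff(fx$sphere$S_Gy_per_Bq_s) < 0))
  expect_equal(fx$s_table$phantom_id, "synthetic_emean_over_m")
})

test_that("end-to-end: zero-noise pipeline equals the analytic dose oracle", {
  masses <- organ_mass_registry()
  specs <- paper_like_kinetics(noise_cv = 0)
  sim <- simulate_biodist(specs, seed = 3, injected_MBq = 6.5)
  e_mev <- 0.147
  fx <- make_s_value_fixture(lu177, masses, e_mev)
  organs <- setdiff(unique(sim$organ), "tumour")
  tias <- tia_table(sim, lu177, 6.5e6, masses, organs = organs)
  rep <- equivalent_dose(tias, fx$s_table, injected_MBq = 6.5)
  for (o in organs) {
    oracle <- energy_deposition_dose(tias$total_Bq_s[tias$organ == o],
                                     e_mev, masses[[o]])
    expect_equal(rep$dose_Sv[rep$target == o], oracle, tolerance = 1e-9)
  }
  # dose per MBq is invariant to the injected activity
  sim2 <- sim
  sim2$injected_activity_MBq <- 13
  tias2 <- tia_table(sim2, lu177, 13e6, masses, organs = organs)
  rep2 <- equivalent_dose(tias2, fx$s_table, injected_MBq = 13)
  expect_equal(rep2$dose_Sv_per_MBq, rep$dose_Sv_per_MBq, tolerance = 1e-12)
})
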