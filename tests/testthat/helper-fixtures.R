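# Shared fixtures, built in code at test time.

cu64 <- nuclide("Cu-64", 45720)
lu177 <- nuclide("Lu-177", 578880)

# a minimal valid per-animal biodistribution data.frame
make_biodist <- function(organs = c("tumour", "blood", "liver"),
                         times_h = c(6, 24, 48), n = 3,
                         pct = function(organ, t) 5,
                         group_id = "g1", injected_MBq = 6.5) {
  rows <- expand.grid(i = seq_len(n), organ = organs, time_h = times_h,
                      stringsAsFactors = FALSE)
  data.frame(
    subject_id = sprintf("%s_t%g_m%d", group_id, rows$time_h, rows$i),
    group_id = group_id, organ = rows$organ, time_h = rows$time_h,
    pct_id_per_g = mapply(pct, rows$organ, rows$time_h),
    injected_activity_MBq = injected_MBq)
}

# per-animal table with exactly the requested group means (constant values)
biodist_with_means <- function(means, time_h = 24, n = 4, group_id = "g1") {
  do.call(rbind, lapply(names(means), function(o) {
    data.frame(subject_id = sprintf("%s_m%d", group_id, seq_len(n)),
               group_id = group_id, organ = o, time_h = time_h,
               pct_id_per_g = rep(means[[o]], n))
  }))
}

# noiseless one-site binding data on the standard series
noiseless_assay <- function(kd = 2.9, bmax = 1.83, ns = 0.002,
                            series = binding_series()) {
  f <- rep(series, each = 2)
  data.frame(free_conc_nM = f,
             total_bound_pmol = bmax * f / (kd + f) + ns * f,
             nonspecific_bound_pmol = ns * f,
             n_cells = 1e6, volume_L = 200e-6)
}
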