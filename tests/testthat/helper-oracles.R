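# Independent oracles, deliberately implemented along different paths than
# the package code they check.

# Brute-force exact two-sided rank-sum p-value: enumerate every assignment of
# the pooled values to group A and compute U directly from pairwise
# comparisons (no ranks).
brute_force_rank_sum <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a); n <- length(pooled)
  u_pairwise <- function(x, y) {
    sum(outer(x, y, function(p, q) (p > q) + 0.5 * (p == q)))
  }
  centre <- na * (n - na) / 2
  dev_obs <- abs(u_pairwise(a, b) - centre)
  combos <- utils::combn(n, na)
  devs <- apply(combos, 2, function(idx) {
    abs(u_pairwise(pooled[idx], pooled[-idx]) - centre)
  })
  mean(devs >= dev_obs - 1e-9)
}

# Energy-deposition self-dose oracle for E_mean/m fixtures:
# dose [Gy] = decays x energy per decay [J] / mass [kg]
energy_deposition_dose <- function(tia_Bq_s, e_mean_MeV, mass_g) {
  tia_Bq_s * e_mean_MeV * 1.602176634e-13 / (mass_g / 1000)
}
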