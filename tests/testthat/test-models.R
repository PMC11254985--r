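# Deterministic PK and PK/PD kernels against independent RK4 oracles and
# their own closed-form identities.

grid <- time_grid()

test_that("SC plasma profile matches the Bateman closed form's peak and an RK4 oracle", {
  pk <- sc_pk_params()
  cp <- sc_plasma_profile(pk, 1, grid)
  expect_equal(cp$value[1], 0)

  kel <- pk$cl / pk$v
  tmax_min <- log(pk$ka / kel) / (pk$ka - kel) * 60
  cmax <- 1e6 / (pk$v * 1000) * pk$ka / (pk$ka - kel) *
    (exp(-kel * tmax_min / 60) - exp(-pk$ka * tmax_min / 60))
  expect_equal(tmax_min, 10.8977, tolerance = 1e-4)
  expect_equal(cmax, 5.2100, tolerance = 1e-4)
  em <- exposure_metrics(cp)
  expect_lt(abs(em$tmax - tmax_min), 0.25)       # within one grid step
  expect_equal(em$cmax, cmax, tolerance = 1e-4)  # curvature loss < 1e-4 rel

  orc <- sc_ode_oracle(pk, ke0 = 5.36, dose_mg = 1, grid)
  expect_lt(max_rel_err(cp$value, orc$cp), 1e-6)
})

test_that("SC solution agrees with the oracle across perturbed parameter sets", {
  for (set in perturbed_sets("sc")) {
    cp <- sc_plasma_profile(set$pk, 2, grid)
    prof <- subject_profiles("sc", 2, pk = set$pk,
                             pd = pd_params(ke0 = set$ke0))
    orc <- sc_ode_oracle(set$pk, set$ke0, 2, grid)
    expect_lt(max_rel_err(cp$value, orc$cp), 1e-6)
    expect_lt(max_rel_err(prof$ce, orc$ce), 1e-6)
  }
})

test_that("dose proportionality is exact for both formulations", {
  cp1 <- sc_plasma_profile(sc_pk_params(), 1, grid)$value
  cp2 <- sc_plasma_profile(sc_pk_params(), 2, grid)$value
  expect_equal(cp2, 2 * cp1, tolerance = 1e-12)
  sl1 <- sl_plasma_profile(sl_pk_params(), 10, grid)$value
  sl3 <- sl_plasma_profile(sl_pk_params(), 30, grid)$value
  expect_equal(sl3, 3 * sl1, tolerance = 1e-10)
})

test_that("ka = kel degeneracy switches to the continuous limit form", {
  # cl chosen so kel == ka exactly
  pk_eq <- sc_pk_params(cl = 14.9 * 153, v = 153, ka = 14.9)
  cp_eq <- sc_plasma_profile(pk_eq, 1, grid)
  t_h <- grid / 60
  limit <- 1e6 / (153 * 1000) * 14.9 * t_h * exp(-14.9 * t_h)
  expect_equal(cp_eq$value, limit, tolerance = 1e-12)
  # continuity: a nearby non-degenerate kel gives nearly the same profile
  pk_near <- sc_pk_params(cl = 14.9 * 153 * (1 + 1e-7), v = 153, ka = 14.9)
  cp_near <- sc_plasma_profile(pk_near, 1, grid)
  expect_lt(max_rel_err(cp_near$value, cp_eq$value), 1e-6)
  # oracle confirms the degenerate profile
  orc <- sc_ode_oracle(pk_eq, 5.36, 1, grid)
  expect_lt(max_rel_err(cp_eq$value, orc$cp), 1e-6)
})

test_that("SL solution matches the RK4 oracle and peaks in the 30-60 min range", {
  pk <- sl_pk_params()
  cp <- sl_plasma_profile(pk, 30, grid)
  expect_equal(cp$value[1], 0)
  expect_true(all(cp$value >= 0))
  orc <- sl_ode_oracle(pk, 5.36, 30, grid)
  expect_lt(max_rel_err(cp$value, orc$cp), 1e-6)
  tmax <- cp$time_min[which.max(cp$value)]
  expect_gte(tmax, 30)
  expect_lte(tmax, 60)
  for (set in perturbed_sets("sl", k = 3)) {
    prof <- subject_profiles("sl", 30, pk = set$pk,
                             pd = pd_params(ke0 = set$ke0))
    o <- sl_ode_oracle(set$pk, set$ke0, 30, grid)
    expect_lt(max_rel_err(prof$cp, o$cp), 1e-6)
    expect_lt(max_rel_err(prof$ce, o$ce), 1e-6)
  }
})

test_that("SL mass balance closes at every grid point", {
  pk <- sl_pk_params()
  dose_ng <- 30 * 1e6 * pk$f
  # production route with an elimination accumulator state appended
  A <- sl_rate_matrix(pk, elim = TRUE)
  X <- apopkpd:::lin_ode_states(A, c(dose_ng, rep(0, 5)), grid)
  total <- colSums(X)
  expect_lt(max(abs(total - dose_ng)) / dose_ng, 1e-6)
  # and the independent oracle agrees
  orc <- sl_ode_oracle(pk, 5.36, 30, grid)
  expect_lt(max(abs(orc$amounts + orc$eliminated - dose_ng)) / dose_ng, 1e-6)
})

test_that("the SL rate matrix guards its compartmental sign structure", {
  pk <- sl_pk_params()
  A <- sl_rate_matrix(pk, ke0 = 5.36, elim = TRUE)
  expect_identical(dim(A), c(7L, 7L))
  core <- A[1:5, 1:5]
  expect_true(all(core[row(core) != col(core)] >= 0))
  expect_true(all(colSums(core) <= 1e-12))
  pk$k21 <- -0.01   # corrupt past the constructor
  expect_error(sl_rate_matrix(pk), "mass must leave only via elimination")
})

test_that("effect-site link reproduces first-order step response and the SC closed form", {
  ke0 <- 5.36
  const <- time_profile(grid, rep(4, length(grid)))
  ce <- effect_site_profile(const, ke0)
  expect_equal(ce$value, 4 * (1 - exp(-ke0 * grid / 60)), tolerance = 1e-12)
  zero <- time_profile(grid, rep(0, length(grid)))
  expect_true(all(effect_site_profile(zero, ke0)$value == 0))

  # on a sampled SC plasma curve the piecewise-linear step update tracks the
  # exact triple-exponential convolution to the Cp-interpolation error
  cp <- sc_plasma_profile(sc_pk_params(), 1, grid)
  ce_link <- effect_site_profile(cp, ke0)
  ce_exact <- subject_profiles("sc", 1)$ce
  expect_lt(max_rel_err(ce_link$value, ce_exact), 5e-4)
  expect_equal(max(ce_exact), 4.1164, tolerance = 1e-3)
  tpeak <- grid[which.max(ce_exact)]
  expect_gt(tpeak, 25); expect_lt(tpeak, 27)
})

test_that("the effect-site peak lies on the plasma curve (crossing identity)", {
  for (f in c("sc", "sl")) {
    prof <- subject_profiles(f, if (f == "sc") 2 else 30)
    i <- which.max(prof$ce)
    # dCe/dt = 0 at the peak forces Ce = Cp there, up to grid resolution
    slope <- abs(diff(prof$cp[c(i - 1, i + 1)])) / 0.5  # ng/mL per min
    expect_lt(abs(prof$ce[i] - prof$cp[i]), max(0.5 * slope, 1e-3))
  }
})

test_that("sigmoid-Emax change is half-maximal at EC50 and bounded", {
  pd <- pd_params()
  ce <- time_profile(c(0, 1, 2), c(pd$ec50, pd$ec50, 0))
  d <- updrs_change_profile(ce, pd)
  expect_equal(d$value[1], -pd$b0 * pd$emax / 2)  # -12.15 points
  expect_equal(d$value[3], 0)
  big <- time_profile(c(0, 1), c(0, 1e6))
  expect_equal(updrs_change_profile(big, pd)$value[2], -24.3, tolerance = 1e-6)
  # pointwise monotone decreasing in Ce, bounded in [-b0*emax, 0]
  ce_inc <- time_profile(seq(0, 50, by = 1), seq(0, 50, by = 1))
  d_inc <- updrs_change_profile(ce_inc, pd)$value
  expect_true(all(diff(d_inc) <= 0))
  expect_true(all(d_inc <= 0 & d_inc >= -pd$b0 * pd$emax))
})

test_that("invalid inputs are rejected", {
  expect_error(sc_plasma_profile(sc_pk_params(), 0), "positive")
  expect_error(sc_plasma_profile(sc_pk_params(), -1), "positive")
  expect_error(effect_site_profile(sc_plasma_profile(sc_pk_params(), 1), 0),
               "ke0")
  expect_error(sc_pk_params(cl = -5), "strictly positive")
  expect_error(sl_pk_params(k21 = 0), "strictly positive")
  expect_error(pd_params(mcic = 30), "mcic")
  expect_error(time_profile(c(1, 2), c(0, 0)), "start at 0")
  expect_error(time_profile(c(0, 0.5, 0.25), c(0, 1, 1)), "increasing")
})
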