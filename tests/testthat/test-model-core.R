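test_that("euthermic line is determined by its two anchor points", {
  p <- thermo_params(m_tnz = 1, t_lc = 30, t_be = 38, t_bt = 2,
                     tmr = 0.05, m_r = 0.8)
  line <- derive_euthermic_line(p)
  expect_equal(unname(line["beta_e"]), -0.125)
  expect_equal(unname(line["alpha_e"]), 4.75)
  # anchor conditions to machine precision
  expect_equal(predict_euthermic(p$t_lc, p), p$m_tnz)
  expect_equal(predict_euthermic(p$t_be, p), 0)
  # interior point cross-checked with a two-anchor interpolation oracle
  expect_equal(predict_euthermic(22, p), (38 - 22) / (38 - 30) * 1.0)
})

test_that("degenerate euthermic geometry is rejected", {
  expect_error(thermo_params(m_tnz = 1, t_lc = 30, t_be = 30, t_bt = 2,
                             tmr = 0.05, m_r = 0.8),
               "t_be must exceed t_lc")
  expect_error(thermo_params(m_tnz = 1, t_lc = 30, t_be = 38, t_bt = 2,
                             tmr = 0.9, m_r = 0.95),
               "tmr")
  expect_error(thermo_params(m_tnz = 1, t_lc = 30, t_be = 38, t_bt = -6,
                             tmr = 0.05, m_r = 0.8),
               "t_bt")
})

test_that("threshold temperature matches the bisection oracle", {
  p <- thermo_params(m_tnz = 1, t_lc = 30, t_be = 38, t_bt = 2,
                     tmr = 0.05, m_r = 0.8)
  expect_equal(derive_tt(p), 1.6)
  # second worked case: slope -0.1, zero-crossing 10, minimum 1.0
  p2 <- thermo_params(m_tnz = 2, t_lc = 25, t_be = 45, t_bt = 10,
                      tmr = 1.0, m_r = 1.4)
  expect_equal(p2$beta_r, -0.1)
  expect_equal(derive_tt(p2), 0.0)
  for (p in random_thermo_params(200, seed = 42)) {
    expect_lt(abs(derive_tt(p) - tt_bisection_oracle(p)), 1e-6)
    expect_lt(derive_tt(p), p$t_bt)
  }
})

test_that("torpor curve is continuous at t_t and anchored at t_lc", {
  p <- thermo_params(m_tnz = 1, t_lc = 30, t_be = 38, t_bt = 2,
                     tmr = 0.05, m_r = 0.8)
  eps <- 1e-9
  expect_lt(abs(predict_torpor(p$t_t - eps, p) -
                  predict_torpor(p$t_t + eps, p)), 1e-8)
  expect_equal(predict_torpor(p$t_lc, p), p$m_r)
  # conforming value at ta = 15: log-linear interpolation between the two
  # anchors (t_t, tmr) and (t_lc, m_r) is the independent oracle
  loglin <- exp(log(0.05) + (15 - p$t_t) / (p$t_lc - p$t_t) *
                  (log(0.8) - log(0.05)))
  expect_equal(predict_torpor(15, p), loglin, tolerance = 1e-9)
  expect_equal(predict_torpor(15, p), 0.184974, tolerance = 1e-5)
})

test_that("q10 follows the conforming exponent", {
  p <- thermo_params(m_tnz = 1, t_lc = 30, t_be = 38, t_bt = 2,
                     tmr = 0.05, m_r = 0.8)
  # ratio of conforming predictions 10 degrees apart is the oracle
  expect_equal(q10_conforming(p),
               predict_torpor(25, p) / predict_torpor(15, p))
  expect_equal(q10_conforming(p), 2.654519, tolerance = 1e-5)
  # flat conforming segment: m_r = tmr gives q10 exactly 1
  pf <- thermo_params(m_tnz = 1, t_lc = 30, t_be = 38, t_bt = 2,
                      tmr = 0.05, m_r = 0.05)
  expect_equal(q10_conforming(pf), 1)
})

test_that("curve algebra holds over random admissible parameter sets", {
  for (p in random_thermo_params(1000, seed = 7)) {
    expect_equal(predict_euthermic(p$t_lc, p), p$m_tnz, tolerance = 1e-12)
    expect_equal(predict_torpor(p$t_lc, p), p$m_r, tolerance = 1e-10)
    tt <- derive_tt(p)
    expect_lt(abs((p$alpha_r + p$beta_r * tt) - p$tmr), 1e-8)
    expect_lt(abs(p$alpha_c * exp(p$beta_c * tt) - p$tmr), 1e-8)
    expect_lte(q10_conforming(p), 5 + 1e-9)
  }
})

test_that("curves are monotone and ordered below the thermoneutral zone", {
  for (p in random_thermo_params(100, seed = 3)) {
    ta <- seq(p$t_bt - 3, p$t_lc, length.out = 50)
    me <- predict_euthermic(ta, p)
    mt <- predict_torpor(ta, p)
    expect_true(all(diff(me) < 0))
    expect_true(all(diff(mt[ta < p$t_t]) <= 0))
    conf <- mt[ta >= p$t_t]
    if (p$m_r > p$tmr) expect_true(all(diff(conf) > 0))
    # euthermic curve sits above the torpor curve away from t_lc
    expect_true(all(me[ta < p$t_lc - 1e-6] >= mt[ta < p$t_lc - 1e-6]))
  }
})
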