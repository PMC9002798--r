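# Build a fake sampler result with constant curve parameters and scripted
# state-indicator draws, so the assignment arithmetic can be checked exactly.
fake_run <- function(s_draws, n_draws = 2000,
                     tbe = 38, tbt = 2, tmr = 0.05, mr = 0.8) {
  n_rec <- ncol(s_draws)
  m <- cbind(matrix(rep(c(tbe, tbt, tmr, mr), each = n_draws), n_draws),
             s_draws)
  colnames(m) <- c("Tbe", "Tbt", "TMR", "Mr", paste0("s[", seq_len(n_rec), "]"))
  list(samples = coda::mcmc.list(coda::mcmc(m)))
}

test_that("membership probabilities are draw frequencies", {
  p <- thermo_params(m_tnz = 1, t_lc = 30, t_be = 38, t_bt = 2,
                     tmr = 0.05, m_r = 0.8)
  # three in-between records: mostly-torpor, mostly-euthermy, balanced-ish
  ta <- c(15, 20, 25)
  m <- (predict_euthermic(ta, p) + predict_torpor(ta, p)) / 2
  s <- cbind(rep(c(1L, 2L), c(1900, 100)),
             rep(c(1L, 2L), c(200, 1800)),
             rep(c(1L, 2L), c(900, 1100)))
  tab <- preassign(data.frame(ta = ta, m = m), fake_run(s),
                   tlc = 30, m_tnz_norm = 1, m_mean = 1)
  expect_equal(tab$membership_torpor, c(0.95, 0.10, 0.45))
  expect_equal(tab$state, c("torpor", "euthermy", "euthermy"))
  expect_equal(tab$membership, c(0.95, 0.90, 0.55))
  expect_false(any(tab$auto))
})

test_that("automatic overrides fix records outside the predicted curves", {
  p <- thermo_params(m_tnz = 1, t_lc = 30, t_be = 38, t_bt = 2,
                     tmr = 0.05, m_r = 0.8)
  ta <- c(15, 15, 15, 35)
  m <- c(predict_euthermic(15, p) + 0.5,     # above the euthermic curve
         predict_torpor(15, p) - 0.05,       # below the torpor curve
         (predict_euthermic(15, p) + predict_torpor(15, p)) / 2,
         1.02)                               # thermoneutral record
  s <- cbind(rep(c(1L, 2L), c(400, 1600)),   # model leaned euthermy...
             rep(c(1L, 2L), c(1200, 800)),   # ...and torpor: overrides flip
             rep(c(1L, 2L), c(1000, 1000)))
  tab <- preassign(data.frame(ta = ta, m = m), fake_run(s),
                   tlc = 30, m_tnz_norm = 1, m_mean = 1)
  expect_equal(tab$state, c("euthermy", "torpor", "euthermy", "tnz"))
  expect_equal(tab$membership[c(1, 2, 4)], c(1, 1, 1))
  expect_true(all(tab$auto[c(1, 2, 4)]))
  expect_false(tab$auto[3])
})

test_that("overrides are skipped when no record is assigned to torpor", {
  p <- thermo_params(m_tnz = 1, t_lc = 30, t_be = 38, t_bt = 2,
                     tmr = 0.05, m_r = 0.8)
  ta <- c(15, 20)
  m <- c(predict_euthermic(15, p) + 0.5,     # would trip the override
         predict_euthermic(20, p))
  s <- cbind(rep(2L, 2000), rep(2L, 2000))   # nobody in torpor
  tab <- preassign(data.frame(ta = ta, m = m), fake_run(s),
                   tlc = 30, m_tnz_norm = 1, m_mean = 1)
  expect_false(any(tab$auto))
  expect_lt(max(tab$membership_torpor), 1e-12)
})

test_that("confidence is the membership times the t_lc side probability", {
  tlc_draws <- seq(29, 31, length.out = 1000)
  # all draws below ta: a thermoneutral record is certain
  expect_equal(assignment_confidence(32, "tnz", 1, tlc_draws), 1)
  # membership 0.9 and side probability 0.9
  ta_q90 <- unname(quantile(tlc_draws, 0.9, type = 1))
  conf <- assignment_confidence(ta_q90, "tnz", 0.9, tlc_draws)
  expect_equal(conf, 0.9 * mean(tlc_draws <= ta_q90))
  expect_equal(conf, 0.81, tolerance = 0.01)
  # at the posterior median the side probability is one half
  med <- 30.001001                     # midpoint record: exactly half below
  expect_lte(assignment_confidence(med, "euthermy", 1, tlc_draws), 0.5 + 1e-9)
  expect_lte(assignment_confidence(med, "tnz", 1, tlc_draws), 0.51)
})

test_that("validity follows the one-sided binomial test", {
  expect_true(assignment_validity(1.0, 6000))
  expect_false(assignment_validity(0.5, 6000))
  expect_false(assignment_validity(0.8, 6000))   # at the null boundary
  expect_error(assignment_validity(0.9, 0), "positive count")
  # raising the threshold never increases the number of valid records
  conf <- seq(0, 1, by = 0.01)
  n_valid <- vapply(c(0.7, 0.8, 0.9),
                    function(th) sum(assignment_validity(conf, 6000,
                                                         threshold = th)),
                    numeric(1))
  expect_true(all(diff(n_valid) <= 0))
})
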