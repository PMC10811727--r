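# Phase segmentation, nitrogen balance, electron ledger, DNRA rate.

test_that("the phase boundary is the first sample below threshold that stays below", {
  ts <- make_ts(0:3, no3 = c(2, 1, 0.05, 0), alkane = c(1, 0.9, 0.8, 0.7))
  expect_equal(segment_phases(ts, 0.1)$boundary_index, 3)
  # a transient dip does not end Phase 1
  ts2 <- make_ts(0:4, no3 = c(2, 0.04, 1, 0.04, 0),
                 alkane = c(1, 0.9, 0.8, 0.7, 0.6))
  expect_equal(segment_phases(ts2, 0.1)$boundary_index, 4)
  # nitrate never depleted: everything is Phase 1
  ts3 <- make_ts(0:3, no3 = c(2, 1.8, 1.5, 1.2), alkane = c(1, 1, 1, 1))
  expect_equal(segment_phases(ts3, 0.1)$boundary_index, 5)
  expect_true(is.na(segment_phases(ts3, 0.1)$boundary_time_h))
  expect_error(reactor_timeseries(numeric(0), numeric(0), numeric(0),
                                  numeric(0), numeric(0), numeric(0),
                                  numeric(0),
                                  vessel_geometry(1, 1, 308), 2),
               "empty")
})

test_that("nitrogen recovery is produced over consumed, with N2 converted to the liquid basis", {
  ts <- make_ts(0:2, no3 = c(1, 0.5, 0), nh4 = c(0, 0.1, 0.2),
                n2 = c(0, 0.4, 0.8), alkane = c(1, 0.95, 0.9))
  nb <- nitrogen_balance(ts)
  expect_equal(nb$n_produced, 1.0)
  expect_equal(nb$n_consumed, 1.0)
  expect_equal(nb$n_recovery, 1.0)
  # N2 measured vessel-total: halving v_liq doubles its per-litre weight
  ts2 <- make_ts(0:2, no3 = c(1, 0.5, 0), nh4 = c(0, 0.1, 0.2),
                 n2 = c(0, 0.2, 0.4), alkane = c(1, 0.95, 0.9), v_liq = 0.5)
  expect_equal(nitrogen_balance(ts2)$n_recovery, 1.0)
  expect_error(nitrogen_balance(
    make_ts(0:1, no3 = c(1, 1), alkane = c(1, 0.9))), "consumption")
})

test_that("nitrogen balance at the published batch-test scale gives recovery about 1.12", {
  # produced 2.21 (NH4+ + N2-N), consumed 1.98 mmol N/l
  ts <- make_ts(c(0, 100, 200), no3 = c(1.98, 1.0, 0),
                nh4 = c(0, 0.2, 0.5), n2 = c(0, 0.8, 1.71),
                alkane = c(13, 12.6, 12.2))
  expect_equal(nitrogen_balance(ts)$n_recovery, 2.21 / 1.98)
  expect_equal(round(nitrogen_balance(ts)$n_recovery, 2), 1.12)
})

test_that("nitrite-only nitrate reduction against measured ethane drawdown gives the hand-computed electron fraction", {
  # 1.0 mmol NO3- all accumulated as NO2-; 0.15 mmol ethane consumed
  ts <- make_ts(0:2, no3 = c(1, 0.5, 0), no2 = c(0, 0.5, 1),
                alkane = c(0.5, 0.42, 0.35))
  b <- electron_balance(ts)
  expect_equal(b$e_denit, 0)
  expect_equal(b$e_dnra, 0)
  expect_equal(b$e_residual_no2, 2.0)
  expect_equal(b$e_max, 14 * 0.15)
  expect_equal(b$e_fraction, 2.0 / 2.1, tolerance = 1e-12)
  expect_error(electron_balance(
    make_ts(0:1, no3 = c(1, 0), no2 = c(0, 1), alkane = c(1, 1))),
    "drawdown")
})

test_that("the pathway decomposition matches an independent per-timestep electron ledger", {
  # mixed two-phase run, constructed by hand (v_liq = 1 l):
  # Phase 1 (t 0-3): NO3 2 -> 0 producing NO2 1.2, N2-N 0.8
  # Phase 2 (t 3-8): NO2 1.2 -> 0.1 producing NH4 0.5, N2-N 0.6
  ts <- make_ts(0:8,
                no3 = c(2, 1.4, 0.6, 0, 0, 0, 0, 0, 0),
                no2 = c(0, 0.36, 0.84, 1.2, 1.0, 0.75, 0.5, 0.3, 0.1),
                nh4 = c(0, 0, 0, 0, 0.1, 0.2, 0.3, 0.4, 0.5),
                n2 = c(0, 0.24, 0.56, 0.8, 0.9, 1.05, 1.2, 1.3, 1.4),
                alkane = c(2, 1.9, 1.8, 1.66, 1.6, 1.5, 1.43, 1.36, 1.3))
  b <- electron_balance(ts, segment_phases(ts, 0.05))
  total <- b$e_denit + b$e_dnra + b$e_residual_no2
  expect_equal(total, oracle_electron_ledger(ts), tolerance = 1e-12)
  # and the declared pathway split on endpoints
  expect_equal(b$e_denit, 5 * 1.4)
  expect_equal(b$e_dnra, 8 * 0.5)
  expect_equal(b$e_residual_no2, 2 * 0.1)
  expect_true(all(c(b$e_denit, b$e_dnra, b$e_residual_no2) >= 0))
})

test_that("balances are endpoint-determined: inserting or removing interior samples changes nothing", {
  p <- scenario_library()[["ethane-like"]]
  p$noise_sd[] <- 0
  ts <- simulate_reactor(p)$timeseries
  thin <- ts[c(1, seq(3, nrow(ts) - 2, by = 3), nrow(ts)), ]
  ts2 <- reactor_timeseries(thin$time_h, thin$no3_mmolN_l, thin$no2_mmolN_l,
                            thin$nh4_mmolN_l, thin$n2_mmolN_total,
                            thin$alkane_mmol_total, thin$co2_mmol_total,
                            attr(ts, "geometry"), attr(ts, "n_carbons"))
  b1 <- electron_balance(ts)
  b2 <- electron_balance(ts2)
  for (f in c("n_recovery", "e_denit", "e_dnra", "e_residual_no2",
              "e_max", "e_fraction"))
    expect_equal(b2[[f]], b1[[f]], tolerance = 1e-12, info = f)
})

test_that("no ammonium means no DNRA electrons and a zero DNRA rate", {
  ts <- make_ts(0:5, no3 = c(2, 1, 0, 0, 0, 0),
                no2 = c(0, 1, 2, 1.5, 1.0, 0.5),
                n2 = c(0, 0, 0, 0.5, 1.0, 1.5),
                alkane = c(2, 1.9, 1.8, 1.7, 1.6, 1.5))
  b <- electron_balance(ts)
  expect_equal(b$e_dnra, 0)
  expect_equal(b$dnra_rate, 0)
})

test_that("the DNRA rate is the Phase-2 ammonium slope in per-day units", {
  # NH4+ rising 0.2 mmol N/l over 6 h -> 0.8 mmol N/l/day; series begins in
  # Phase 2 (nitrate already depleted)
  ts <- make_ts(0:6, no3 = rep(0, 7), no2 = seq(1.2, 0.6, by = -0.1),
                nh4 = seq(0, 0.2, length.out = 7),
                alkane = seq(1, 0.94, by = -0.01))
  expect_equal(dnra_rate(ts), 0.8, tolerance = 1e-12)
  flat <- make_ts(0:6, no3 = rep(0, 7), nh4 = rep(0.3, 7),
                  alkane = seq(1, 0.94, by = -0.01))
  expect_equal(dnra_rate(flat), 0)
  # fewer than two usable Phase-2 samples
  short <- make_ts(0:2, no3 = c(2, 1, 0), nh4 = c(0, 0, 0),
                   alkane = c(1, 0.9, 0.8))
  expect_error(dnra_rate(short), "fewer than two")
})
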