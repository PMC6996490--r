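test_that("monotone growth has no retractions; repeated collapse has two", {
  expect_equal(nrow(detect_retractions(seq(0, 40, length.out = 50))), 0)
  len <- c(seq(0, 20, length.out = 10), seq(20, 1, length.out = 10),
           seq(1, 20, length.out = 10), seq(20, 1, length.out = 10))
  expect_equal(nrow(detect_retractions(len)), 2)
  expect_error(detect_retractions(c(5, -1, 10)), "negative")
})

test_that("failed control axons retract twice, as in their ground truth", {
  for (s in 1:20) {
    sim <- simulate_axon("dmso", 300 + s)
    r <- detect_retractions(sim$trace$length_um)
    expect_equal(nrow(r), 2) # initial + post-DREZ collapse
    expect_length(sim$truth$retraction_times_min, 2)
  }
  # a reentered axon only retracts once
  sim2 <- simulate_axon("ca_src_taxol", 5)
  expect_equal(nrow(detect_retractions(sim2$trace$length_um)), 1)
})

test_that("velocity_during matches the hand-computed worked example", {
  tr <- make_manual_trace(rep(100, 3), position = c(0, 0.5, 1.0))
  ev <- tibble::tibble(start_frame = 0L, end_frame = 2L,
                       duration_min = 15, initiation_min = 0)
  expect_equal(velocity_during(tr, ev), 0.1)
})

test_that("velocity_during is undefined without a usable event", {
  tr <- make_manual_trace(rep(100, 10))
  v <- velocity_during(tr, detect_peaks(tr))
  expect_true(is.na(v))
  expect_true(attr(v, "undefined"))
  # single-frame events carry no increments
  ev1 <- tibble::tibble(start_frame = 3L, end_frame = 3L,
                        duration_min = 5, initiation_min = 15)
  expect_true(is.na(velocity_during(tr, ev1)))
})

test_that("velocity sign convention round-trips the generator parameter", {
  # a noise-free constructed event moving at +0.2 um/min toward the cord
  pos <- c(rep(-3, 5), -3 + 0.2 * 5 * (0:9), rep(NA, 0))
  tr <- make_manual_trace(rep(100, length(pos)), position = pos)
  ev <- tibble::tibble(start_frame = 5L, end_frame = 14L,
                       duration_min = 50, initiation_min = 25)
  expect_equal(velocity_during(tr, ev), 0.2)
  # and the simulated dmso preset yields negative axon-level values on average
  vs <- sapply(1:30, function(s) {
    sim <- simulate_axon("dmso", 900 + s, noise_sd = 0)
    as.numeric(velocity_during(sim$trace, detect_peaks(sim$trace)))
  })
  expect_lt(mean(vs, na.rm = TRUE), 0)
})

test_that("call_reentry applies the persistence rule", {
  # never inside, with regrowth -> failed_retracted
  len <- c(seq(38, 1, length.out = 12), seq(1, 39, length.out = 20),
           rep(39, 20))
  tr <- make_manual_trace(rep(100, 52), position = len - 40, length_um = len)
  expect_equal(call_reentry(tr)$outcome, "failed_retracted")
  # inside deeper than 1 um for 5 consecutive frames -> reentered
  pos <- c(len - 40, rep(2, 5))
  tr2 <- make_manual_trace(rep(100, 57), position = pos,
                           length_um = pos + 40)
  cr <- call_reentry(tr2)
  expect_equal(cr$outcome, "reentered")
  expect_equal(cr$crossing_time_min, 52 * 5)
  # all-absent trace -> no_regrowth
  tr3 <- make_manual_trace(rep(NA_real_, 10), present = rep(FALSE, 10))
  expect_equal(call_reentry(tr3)$outcome, "no_regrowth")
})

test_that("stricter epsilon or persistence never converts failed to reentered", {
  # full retraction, regrowth, 3 frames at 1.5 um inside, then collapse
  pos <- c(rep(-35, 3), rep(-5, 7), rep(1.5, 3), rep(-5, 10))
  tr <- make_manual_trace(rep(100, 23), position = pos,
                          length_um = pos + 40)
  expect_equal(call_reentry(tr, epsilon_um = 1, m_frames = 3)$outcome,
               "reentered")
  expect_equal(call_reentry(tr, epsilon_um = 1, m_frames = 4)$outcome,
               "failed_retracted")
  expect_equal(call_reentry(tr, epsilon_um = 2, m_frames = 3)$outcome,
               "failed_retracted")
})

test_that("re-entry calls agree with generator truth on noise-free traces", {
  conds <- c("dmso", "taxol", "ca_src", "ca_src_taxol")
  for (s in 1:40) {
    sim <- simulate_axon(conds[(s %% 4) + 1], 1100 + s, noise_sd = 0)
    cr <- call_reentry(sim$trace)
    expect_equal(cr$outcome, sim$truth$outcome)
    expect_equal(cr$crossing_time_min, sim$truth$crossing_time_min)
  }
})

test_that("outcome_summary returns per-condition fractions summing to one", {
  calls <- tibble::tibble(
    condition = c(rep("a", 5), rep("b", 10)),
    outcome = c(rep("reentered", 5),
                rep("reentered", 4), rep("failed_retracted", 6)))
  os <- outcome_summary(calls)
  expect_equal(os$fraction[os$condition == "a" & os$outcome == "reentered"], 1)
  expect_equal(os$fraction[os$condition == "b" & os$outcome == "reentered"],
               0.4)
  expect_equal(sum(os$fraction[os$condition == "b"]), 1)
  expect_equal(nrow(os), 6) # all three outcomes tabulated per condition
})

test_that("taxol re-entry sits between the control and forced extremes", {
  outs <- sapply(1:60, function(s)
    call_reentry(simulate_axon("taxol", 1500 + s)$trace)$outcome)
  frac <- mean(outs == "reentered")
  expect_gt(frac, 0)
  expect_lte(frac, 1)
  dmso <- sapply(1:20, function(s)
    call_reentry(simulate_axon("dmso", 1500 + s)$trace)$outcome)
  expect_gte(frac, mean(dmso == "reentered"))
})
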