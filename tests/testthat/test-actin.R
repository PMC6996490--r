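test_that("a constant trace yields no peaks", {
  tr <- make_manual_trace(rep(100, 50))
  expect_equal(nrow(detect_peaks(tr)), 0)
})

test_that("a single 22-frame elevated run is one 110-min event", {
  tr <- make_step_trace(100, elevated = 40:61)
  ev <- detect_peaks(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_frame, 40)
  expect_equal(ev$end_frame, 61)
  expect_equal(ev$duration_min, 110)
  expect_equal(ev$initiation_min, 200)
})

test_that("runs separated by one sub-threshold frame merge, two do not", {
  tr1 <- make_step_trace(100, elevated = c(40:44, 46:50))
  ev1 <- detect_peaks(tr1, merge_gap = 1)
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$duration_min, 55)
  tr2 <- make_step_trace(100, elevated = c(40:44, 47:51))
  ev2 <- detect_peaks(tr2, merge_gap = 1)
  expect_equal(nrow(ev2), 2)
  expect_equal(detect_peaks(tr2, merge_gap = 2)$duration_min, 60)
})

test_that("detect_peaks equals the brute-force scanner on simulated traces", {
  conds <- c("untreated", "dmso", "taxol", "ca_src")
  for (s in 1:40) {
    cond <- conds[(s %% 4) + 1]
    for (ns in c(0, 1.5)) {
      tr <- simulate_axon(cond, 4000 + s, noise_sd = ns)$trace
      ev <- detect_peaks(tr)
      bf <- brute_force_peaks(tr)
      expect_identical(ev$start_frame, bf$start_frame)
      expect_identical(ev$end_frame, bf$end_frame)
    }
  }
})

test_that("noise-free detection recovers truth intervals exactly", {
  for (s in 1:50) {
    sim <- simulate_axon("dmso", 5000 + s, noise_sd = 0)
    ev <- detect_peaks(sim$trace)
    expect_identical(ev$start_frame, sim$truth$events$start_frame)
    expect_identical(ev$end_frame, sim$truth$events$end_frame)
    expect_equal(ev$duration_min, sim$truth$events$duration_min)
  }
})

test_that("detected durations are positive multiples of the frame interval", {
  for (s in 1:10) {
    ev <- detect_peaks(simulate_axon("taxol", 600 + s)$trace)
    expect_true(all(ev$duration_min >= 5))
    expect_true(all(ev$duration_min %% 5 == 0))
  }
})

test_that("peak_stats pools durations across axons and counts zero-event axons", {
  ev <- tibble::tibble(
    axon_id = c("a", "a", "b"),
    start_frame = c(10, 30, 12), end_frame = c(15, 39, 19),
    duration_min = c(30, 50, 40), initiation_min = c(50, 150, 60))
  st <- peak_stats(ev, axon_ids = c("a", "b"))
  expect_equal(st$duration_mean, 40) # pooled over {30, 50} and {40}
  expect_equal(st$count_mean, 1.5)
  expect_equal(st$initiation_mean, mean(c(50, 60)))
  st0 <- peak_stats(ev, axon_ids = c("a", "b", "c", "d"))
  expect_equal(st0$count_mean, 0.75)
  expect_equal(st0$duration_mean, 40) # pooled mean unaffected by empty axons
})

test_that("peak_stats flags the no-events-anywhere case", {
  empty <- tibble::tibble(axon_id = character(), start_frame = integer(),
                          end_frame = integer(), duration_min = numeric(),
                          initiation_min = numeric())
  st <- peak_stats(empty, axon_ids = c("a", "b"))
  expect_false(st$duration_defined)
  expect_true(is.na(st$duration_mean))
  expect_equal(st$count_mean, 0)
})

test_that("classify_frames labels concentrates, transitions, and the rest", {
  tr <- make_step_trace(30, elevated = 10:12)
  ev <- detect_peaks(tr)
  cl <- classify_frames(tr, ev, w = 1)
  st <- cl$states$state
  expect_equal(which(st == "concentrate") - 1L, 10:12)
  expect_equal(which(st == "transition") - 1L, c(9L, 13L))
  expect_true(all(st[-(10:14)] == "dispersed"))
  expect_equal(sum(cl$fractions), 1)
  expect_equal(unname(cl$fractions["concentrate"]), 3 / 30)
})

test_that("classify_frames with no events gives all-dispersed", {
  tr <- make_manual_trace(rep(100, 20))
  cl <- classify_frames(tr, detect_peaks(tr))
  expect_equal(unname(cl$fractions["concentrate"]), 0)
  expect_equal(unname(cl$fractions["transition"]), 0)
  expect_equal(unname(cl$fractions["dispersed"]), 1)
})

test_that("classify_frames rejects events outside the trace range", {
  tr <- make_manual_trace(rep(100, 20))
  bad <- tibble::tibble(start_frame = 30L, end_frame = 35L,
                        duration_min = 30, initiation_min = 150)
  expect_error(classify_frames(tr, bad), "outside")
})

test_that("stabilized presets navigate more with concentrates+transitions", {
  # fractions over the navigation window (up to spinal entry, where reached)
  frac_ct <- function(cond) {
    mean(sapply(1:30, function(s) {
      tr <- simulate_axon(cond, 7000 + s)$trace
      cr <- call_reentry(tr)
      if (!is.na(cr$crossing_time_min))
        tr <- tr[tr$time_min < cr$crossing_time_min, ]
      f <- classify_frames(tr, detect_peaks(tr))$fractions
      f["concentrate"] + f["transition"]
    }))
  }
  expect_gt(frac_ct("taxol"), frac_ct("dmso"))
})

test_that("scatter_table has one row per present frame, states attached", {
  sim <- simulate_axon("dmso", 21, noise_sd = 0)
  ev <- detect_peaks(sim$trace)
  cl <- classify_frames(sim$trace, ev)
  sc <- scatter_table(sim$trace, cl$states)
  expect_equal(nrow(sc), sum(sim$trace$present))
  expect_false(any(is.na(sc$area_um2)))
  # concentrates are compact: smaller than the typical growth cone
  expect_lt(mean(sc$area_um2[sc$state == "concentrate"]),
            median(sc$area_um2))
})
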