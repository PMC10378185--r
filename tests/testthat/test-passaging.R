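test_that("outcome metric follows the signed-magnitude formula", {
  expect_equal(outcome_metric(500, 500), 0)          # sgn(0) = 0
  expect_equal(outcome_metric(1e3, 1e6), 6)          # K clone wins at 10^6
  expect_equal(outcome_metric(1e6, 1e3), -6)         # r clone wins
  expect_warning(z <- outcome_metric(0, 0), "undefined")
  expect_equal(z, 0)
  expect_error(outcome_metric(-1, 10), "non-negative")
})

test_that("schedules validate and reseeding preserves totals and ratios", {
  expect_error(passage_schedule(0, 1), "positive")
  sys <- clone_system(c("A", "B"), r = c(1, 0.6), K = c(1e6, 3e6))

  # 0 passages: the outcome is the seeded state
  out0 <- run_passage_series(sys, passage_schedule(2e3, 3, 0), c(0.3, 0.7))
  expect_equal(sum(out0$seeded), 2e3 * 25)
  expect_equal(out0$seeded / sum(out0$seeded), c(0.3, 0.7))
  expect_equal(nrow(out0$sizes), 0)

  # dilution correctness at every passage: seeded total = density * area,
  # clone ratios preserved exactly by reseeding
  out <- run_passage_series(sys, passage_schedule(2e3, 3, 8), c(0.5, 0.5))
  expect_equal(max(abs(rowSums(out$frequencies) - 1)), 0, tolerance = 1e-9)
  for (p in 1:7) {
    reseed <- 2e3 * 25 * out$frequencies[p, ]
    expect_equal(sum(reseed), 2e3 * 25, tolerance = 1e-9)
    expect_equal(reseed / sum(reseed), out$frequencies[p, ],
                 tolerance = 1e-12)
  }

  expect_error(run_passage_series(sys, passage_schedule(2e3, 3, 5),
                                  c(0.6, 0.6)), "sum to 1")
  # seeding at/above the capacity surface is rejected
  expect_error(run_passage_series(sys, passage_schedule(1e5, 1, 5),
                                  c(0.5, 0.5)), "capacity surface")
})

test_that("identical clones stay at constant frequency for 30 passages", {
  sys <- clone_system(c("A", "B"), r = c(0.8, 0.8), K = c(2e6, 2e6))
  out <- run_passage_series(sys, passage_schedule(5e3, 2, 30), c(0.5, 0.5))
  drift <- max(abs(out$frequencies - 0.5))
  expect_lt(drift, 1e-6)
  expect_true(is.na(crossing_passage(out, "A", "B")))  # never strictly above
})

test_that("passage dynamics match the fixed-step RK4 oracle", {
  # r-specialist vs K-specialist under a permissive schedule: the
  # r-clone's frequency rises monotonically and overtakes at the same
  # passage as the oracle
  r <- c(1.0, 0.6); K <- c(1e6, 3e6)
  sys <- clone_system(c("fast", "dense"), r = r, K = K)
  sched <- passage_schedule(2e3, 7, 10)
  f0 <- c(0.2, 0.8)
  out <- run_passage_series(sys, sched, f0)
  oracle <- passage_oracle(r, K, 2e3, 7, 10, f0)
  expect_equal(unname(out$sizes), oracle$sizes, tolerance = 1e-6)
  expect_true(all(diff(out$frequencies[, "fast"]) > 0))

  cross <- crossing_passage(out, "fast", "dense")
  cross_oracle <- which(oracle$frequencies[, 1] > oracle$frequencies[, 2])[1]
  expect_false(is.na(cross))
  expect_equal(cross, cross_oracle)

  # a later crossing under a tighter schedule, still matching the oracle
  sched2 <- passage_schedule(1.5e4, 2, 12)
  out2 <- run_passage_series(sys, sched2, c(0.1, 0.9))
  oracle2 <- passage_oracle(r, K, 1.5e4, 2, 12, c(0.1, 0.9))
  expect_equal(crossing_passage(out2, "fast", "dense"),
               which(oracle2$frequencies[, 1] > oracle2$frequencies[, 2])[1])
  expect_error(crossing_passage(out2, "fast", "nope"), "present")
})

test_that("steering heatmaps separate r- from K-selecting schedules", {
  r <- c(1.0, 0.6); K <- c(1e6, 3e6)
  sys <- clone_system(c("fast", "dense"), r = r, K = K)

  # identical clones: metric exactly 0 everywhere
  neutral <- clone_system(c("a", "b"), r = c(0.8, 0.8), K = c(2e6, 2e6))
  hm0 <- steering_heatmap(neutral, "a", "b", densities = c(1e3, 1e4),
                          intervals = c(2, 6), n_passages = 10)
  expect_true(all(hm0$metric == 0))

  # 1x1 grid equals a direct run + metric call
  hm1 <- steering_heatmap(sys, "fast", "dense", densities = 5e3,
                          intervals = 4, n_passages = 8,
                          initial_frequencies = c(0.5, 0.5))
  direct <- run_passage_series(sys, passage_schedule(5e3, 4, 8), c(0.5, 0.5))
  expect_equal(unname(hm1$metric[1, 1]),
               unname(outcome_metric(direct$sizes[8, "fast"],
                                     direct$sizes[8, "dense"])))

  # with the K-clone seeded dominant, permissive schedules hand the win to
  # the r-clone (negative) while near-confluent, fast-split schedules keep
  # the K-clone on top (positive)
  dens <- c(1e3, 1e4, 1e5)  # up to ~92% occupancy at seeding
  hm <- steering_heatmap(sys, "fast", "dense", densities = dens,
                         intervals = c(1, 7), n_passages = 30,
                         initial_frequencies = c(0.05, 0.95))
  expect_lt(hm$metric[2, 1], 0)   # interval 7 d, 1e3 cells/cm^2
  expect_gt(hm$metric[1, 3], 0)   # interval 1 d, 1e5 cells/cm^2

  # with equal seeding the r-clone always harvests more, and the winning
  # size grows with density: metric non-increasing along each short row
  hm_eq <- steering_heatmap(sys, "fast", "dense",
                            densities = c(1e3, 4e3, 1.6e4, 4e4),
                            intervals = c(1, 2), n_passages = 20,
                            initial_frequencies = c(0.5, 0.5))
  expect_true(all(is.finite(hm_eq$metric)))
  expect_true(all(diff(hm_eq$metric[1, ]) <= 1e-9))
  expect_true(all(diff(hm_eq$metric[2, ]) <= 1e-9))

  # infeasible cells (seeding above the capacity surface) are NA, not fatal
  hm_na <- steering_heatmap(sys, "fast", "dense",
                            densities = c(5e3, 9e5), intervals = 2,
                            n_passages = 3)
  expect_false(is.na(hm_na$metric[1, 1]))
  expect_true(is.na(hm_na$metric[1, 2]))
})
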