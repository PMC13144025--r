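# Spark engine: trials, episode detection, classification, morphology.

fake_record <- function(t, ryr, ip3r = 0 * ryr, i = 0 * t,
                        cds = NULL) {
  data.frame(t_ms = t, n_open_ryr = ryr, n_open_ip3r = ip3r,
             i_total_pA = i,
             cds_mean_uM = cds %||% rep(0.1, length(t)),
             cds_max_uM = cds %||% rep(0.1, length(t)),
             cjsr_min_uM = rep(850, length(t)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("episodes are maximal positive runs with correct peaks", {
  expect_equal(nrow(detect_episodes(fake_record(0:5, rep(0, 6)))), 0L)
  rec <- fake_record(0:6, c(0, 1, 3, 0, 0, 2, 0))
  ep <- detect_episodes(rec)
  expect_equal(nrow(ep), 2L)
  expect_equal(ep$peak, c(3, 2))
  expect_equal(ep$start_ms, c(1, 5))
  expect_equal(ep$end_ms, c(2, 5))
  # IP3R openings count toward the total
  ep2 <- detect_episodes(fake_record(0:2, c(0, 1, 0), c(1, 0, 0)))
  expect_equal(nrow(ep2), 1L)

  # property: boundaries match a brute-force run-length scan
  set.seed(5)
  for (rep in 1:25) {
    tot <- sample(0:3, 40, replace = TRUE, prob = c(0.55, 0.2, 0.15, 0.1))
    rec <- fake_record(seq_along(tot), tot)
    ep <- detect_episodes(rec)
    # oracle: explicit scan
    runs <- list(); cur <- NULL
    for (k in seq_along(tot)) {
      if (tot[k] > 0) {
        cur <- c(cur, k)
      } else if (!is.null(cur)) { runs <- c(runs, list(cur)); cur <- NULL }
    }
    if (!is.null(cur)) runs <- c(runs, list(cur))
    expect_equal(nrow(ep), length(runs))
    for (k in seq_along(runs)) {
      expect_equal(ep$peak[k], max(tot[runs[[k]]]))
      expect_equal(c(ep$start_ms[k], ep$end_ms[k]), range(runs[[k]]))
    }
  }
})

test_that("spark classification applies the peak threshold rule", {
  ep <- function(peaks) data.frame(start_ms = seq_along(peaks),
                                   end_ms = seq_along(peaks), peak = peaks)
  expect_false(classify_spark(ep(5))$is_spark)   # peak 5 is not a spark
  expect_true(classify_spark(ep(6))$is_spark)    # peak 6 is
  expect_true(classify_spark(ep(5), rule = "ge5")$is_spark)
  none <- classify_spark(ep(numeric(0)))
  expect_false(none$is_spark); expect_equal(none$n_sparks, 0L)
  multi <- classify_spark(ep(c(7, 3, 8)))
  expect_true(multi$is_spark)
  expect_equal(multi$n_sparks, 2L)
  expect_true(multi$is_multispark)
  # n_sparks never exceeds the episode count
  set.seed(2)
  for (rep in 1:20) {
    peaks <- sample(0:10, sample(0:6, 1), replace = TRUE)
    expect_lte(classify_spark(ep(peaks))$n_sparks, length(peaks))
  }
})

test_that("Ca2+ mass is the trapezoidal area under the current", {
  expect_equal(ca_mass(fake_record(seq(0, 10, 0.5), 0 * seq(0, 10, 0.5))), 0)
  # rectangular 0.16-pA, 10-ms pulse = 1.6 fC
  t <- seq(0, 10, 0.01)
  expect_equal(ca_mass(fake_record(t, 0 * t, i = rep(0.16, length(t)))),
               1.6, tolerance = 1e-12)
  # piecewise-linear trace vs an independent fine-grid Riemann sum
  set.seed(8)
  t <- sort(runif(30, 0, 50))
  y <- runif(30, 0, 2)
  rec <- fake_record(t, 0 * t, i = y)
  tf <- seq(min(t), max(t), length.out = 200001)
  riemann <- mean(approx(t, y, tf)$y) * (max(t) - min(t))
  expect_equal(ca_mass(rec), riemann, tolerance = 1e-6)
})

test_that("spark duration interpolates the 10%-of-max crossings", {
  t <- seq(0, 30, 0.5)
  flat <- fake_record(t, 0 * t, cds = rep(0.1, length(t)))
  expect_equal(spark_duration(flat), 0)
  # triangle rising 0 -> 100 over 10 ms and back: crossings at 10 uM
  tri <- c(seq(0, 100, length.out = 21), seq(95, 0, length.out = 20))
  rec <- fake_record(seq(0, 20, 0.5), numeric(41), cds = tri)
  expect_equal(spark_duration(rec), 18, tolerance = 1e-10)
  # scale invariance of the relative threshold
  rec2 <- rec; rec2$cds_mean_uM <- rec$cds_mean_uM * 37.5
  expect_equal(spark_duration(rec2), spark_duration(rec), tolerance = 1e-10)
})

test_that("max open count equals a brute-force scan", {
  expect_equal(max_n_open(fake_record(0:3, rep(0, 4))), 0L)
  rec <- fake_record(0:5, c(0, 4, 15, 7, 1, 0), c(0, 0, 0, 2, 0, 0))
  expect_equal(max_n_open(rec), 15L)
  set.seed(3)
  for (rep in 1:10) {
    a <- sample(0:20, 30, TRUE); b <- sample(0:5, 30, TRUE)
    expect_equal(max_n_open(fake_record(1:30, a, b)), max(a + b))
  }
})

test_that("a frozen-gating trial keeps the forced channel open throughout", {
  p <- frozen_ryr_params()
  g <- make_checkerboard(1, margin = 5)
  rec <- run_trial(g, trial_config(duration = 10, seed = 1, ip3 = 0), p)
  expect_true(all(rec$n_open_ryr == 1))
  expect_true(all(rec$n_open_ip3r == 0))
  expect_gt(max(rec$cds_max_uM), 1)  # it is actually releasing
})

test_that("trials are bit-reproducible from the seed", {
  g <- place_ip3rs(make_checkerboard(20), 3, seed = 2)
  cfg <- trial_config(duration = 15, seed = 77, ip3 = 1)
  r1 <- run_trial(g, cfg)
  r2 <- run_trial(g, cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- run_trial(g, trial_config(duration = 15, seed = 78, ip3 = 1))
  expect_false(identical(as.data.frame(r1), as.data.frame(r3)))
})

test_that("forced-site policies resolve as documented", {
  g <- make_checkerboard(9, margin = 4)
  ry <- g$sites[g$sites$kind == "RYR", ]
  # explicit site must exist
  expect_error(run_trial(g, trial_config(duration = 1,
                                         forced = c(1, 1))), "forced site")
  # centermost choice is deterministic: open count starts at 1
  rec <- run_trial(g, trial_config(duration = 1, seed = 1, ip3 = 0),
                   frozen_ryr_params())
  expect_equal(rec$n_open_ryr[1], 1L)
  # no forcing leaves a resting CRU quiescent
  rec0 <- run_trial(g, trial_config(duration = 20, seed = 1, ip3 = 0,
                                    forced = "none"))
  expect_true(all(rec0$n_open_ryr == 0))
  expect_equal(max_n_open(rec0), 0L)
})

test_that("a 50-RyR checkerboard produces sparks in a nonzero trial fraction", {
  tab <- trend_sweep()
  base <- tab[tab$n_ip3r == 0, ]
  expect_gt(base$fidelity, 0)        # some seeds recruit >= 6 channels
  expect_lt(base$fidelity, 1)        # and some do not
  expect_equal(base$n_sparks, base$fidelity * base$n_trials)
})
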