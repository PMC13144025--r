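# Six-state park/drive IP3R2 gating.

test_that("intermodal rates follow the stated closed forms and limits", {
  p <- default_params()$ip3r
  # saturation limit: gates pushed to m24*h24 = 1 leave only a24
  psat <- p; psat$k_m24 <- 1e-9; psat$k_h24 <- 1e9
  gt <- ip3r_modal_gates(1, 1, psat)
  expect_equal(gt$m24 * gt$h24, 1, tolerance = 1e-12)
  expect_equal(intermodal_rates(1, 1, psat)$q24, gt$a24, tolerance = 1e-9)
  # vanishing-drive limit: no Ca2+ -> m42*h42 = 0 -> q42 = a42
  q0 <- intermodal_rates(0, 1, p)
  expect_equal(q0$q42, ip3r_modal_gates(0, 1, p)$a42)
  # general identity against the gate pieces
  gt1 <- ip3r_modal_gates(3, 2, p)
  q1 <- intermodal_rates(3, 2, p)
  expect_equal(q1$q24, gt1$a24 + gt1$v24 * (1 - gt1$m24 * gt1$h24))
  expect_equal(q1$q42, gt1$a42 + p$v42 * gt1$m42 * gt1$h42)
  expect_true(q1$q24 >= 0 && q1$q42 >= 0)
})

test_that("intermodal rates at (1 uM Ca, 1 uM IP3) match the frozen fixture", {
  # hand evaluation of the closed forms:
  # a24 = 45/2, m24 = 1/2, h24 = 2500/2501 -> q24 = 22.5 + 40(1 - 1250/2501)
  # a42 = 0.8/1.0081, g = 1/2, m42 = 1/4, h42 = 6400/6401
  q <- intermodal_rates(1, 1, default_params()$ip3r)
  expect_equal(q$q24, 22.5 + 40 * (1 - 0.5 * 2500 / 2501), tolerance = 1e-12)
  expect_equal(q$q42, 0.8 / 1.0081 + 100 * 0.25 * 6400 / 6401,
               tolerance = 1e-12)
  expect_equal(q$q24, 42.5079968, tolerance = 1e-7)
  expect_equal(q$q42, 25.7896664, tolerance = 1e-7)
})

test_that("R and compiled intermodal rates agree exactly", {
  p <- default_params()$ip3r
  for (c_ds in c(0, 0.1, 1, 10, 300)) {
    for (ip3 in c(0, 0.1, 1, 10)) {
      r <- intermodal_rates(c_ds, ip3, p)
      cpp <- cruspark:::ip3r_rates_cpp(c_ds, ip3, p)
      expect_equal(unname(cpp["q24"]), r$q24, tolerance = 1e-14)
      expect_equal(unname(cpp["q42"]), r$q42, tolerance = 1e-14)
    }
  }
})

test_that("the generator carries the fixed-rate table on the tree", {
  p <- default_params()$ip3r
  q <- intermodal_rates(0.1, 1, p)
  Q <- build_generator(q$q24, q$q42, p)
  expect_equal(rowSums(Q), rep(0, 6), tolerance = 1e-12)
  expect_equal(Q[1, 2], 1.14)       # q_12
  expect_equal(Q[2, 6], 10.1)       # q_26
  expect_equal(Q[4, 5], 4.14e-3)    # q_45
  expect_equal(Q[5, 4], 3.42)       # q_54
  # only tree edges populated
  off <- Q; diag(off) <- 0
  edges <- rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2), c(2, 6), c(6, 2),
                 c(2, 4), c(4, 2), c(4, 5), c(5, 4))
  mask <- matrix(FALSE, 6, 6); mask[edges] <- TRUE
  expect_true(all(off[!mask] == 0))
  expect_error(build_generator(-1, 1, p), "rates")
})

test_that("stationary distribution matches closed forms and the null space", {
  p <- default_params()$ip3r
  # symmetric toy chain: all rates equal -> uniform distribution
  psym <- p
  for (nm in c("q12", "q21", "q23", "q32", "q26", "q62", "q45", "q54")) {
    psym[[nm]] <- 1
  }
  expect_equal(stationary_distribution(build_generator(1, 1, psym)),
               rep(1 / 6, 6), tolerance = 1e-12)

  # mode-restricted closed forms from detailed-balance products
  r1 <- 0.0958 / 1.14; r3 <- 4.75e-3 / 0.0119; r6 <- 10.1 / 3.27
  drive_p6 <- r6 / (1 + r1 + r3 + r6)
  w <- 4.14e-3 / 3.42
  park_p5 <- w / (1 + w)
  expect_warning(pi_drive <- stationary_distribution(build_generator(0, 1, p)),
                 "drive")
  expect_equal(pi_drive[6], drive_p6, tolerance = 1e-12)
  expect_equal(sum(pi_drive[c(4, 5)]), 0)
  expect_warning(pi_park <- stationary_distribution(build_generator(1, 0, p)),
                 "park")
  expect_equal(pi_park[5], park_p5, tolerance = 1e-12)

  # detailed-balance solution equals the null-space solution to 1e-10
  for (c_ds in c(0.05, 0.5, 5, 50, 500)) {
    for (ip3 in c(0.1, 1, 10)) {
      Q <- cruspark:::ip3r_generator(c_ds, ip3, p)
      pi_db <- stationary_distribution(Q)
      ns <- svd(t(Q))$v[, 6]
      pi_ns <- ns / sum(ns)
      expect_equal(pi_db, pi_ns, tolerance = 1e-10)
      expect_equal(sum(pi_db), 1, tolerance = 1e-12)
      # edge-by-edge detailed balance on the tree
      for (e in list(c(1, 2), c(2, 3), c(2, 6), c(2, 4), c(4, 5))) {
        expect_equal(pi_db[e[1]] * Q[e[1], e[2]], pi_db[e[2]] * Q[e[2], e[1]],
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("fixed-dt stepping reproduces matrix-exponential occupancies", {
  skip_if_not_installed("Matrix")
  p <- default_params()$ip3r
  Q <- cruspark:::ip3r_generator(5, 1, p)   # moderate rates at this point
  horizon <- 10
  dt <- 0.9 * 0.1 / max(-diag(Q))
  expected <- as.matrix(Matrix::expm(Q * horizon))[2, ]  # start in state 2
  n <- 20000
  states <- rep(2L, n)
  set.seed(17)
  for (s in seq_len(ceiling(horizon / dt))) states <- step_ip3r(states, Q, dt)
  occ <- tabulate(states, 6) / n
  for (k in 1:6) {
    se <- sqrt(expected[k] * (1 - expected[k]) / n)
    expect_lt(abs(occ[k] - expected[k]), 3 * se + 0.005)
  }
  expect_error(step_ip3r(2L, Q, 1), "guard")
})

test_that("open-probability curve is biphasic with the expected peaks", {
  ca <- 10^seq(-2, 3, length.out = 51)
  po1 <- po_curve(ca, ip3 = 1)
  po10 <- po_curve(ca, ip3 = 10)
  pk1 <- ca[which.max(po1$po)]
  pk10 <- ca[which.max(po10$po)]
  # biphasic: both tails well below the peak
  expect_lt(po1$po[1], 0.2 * max(po1$po))
  expect_lt(po1$po[51], 0.2 * max(po1$po))
  expect_lt(po10$po[1], 0.2 * max(po10$po))
  expect_lt(po10$po[51], 0.2 * max(po10$po))
  # peak locations and IP3 ordering
  expect_gte(pk1, 1); expect_lte(pk1, 10)
  expect_lte(pk10, 100)
  expect_gt(max(po10$po), max(po1$po))
  # no IP3, no opening, anywhere on the curve
  expect_equal(po_curve(ca, ip3 = 0)$po, rep(0, 51))
})

test_that("time-averaged simulated P_O agrees with the stationary solve", {
  ca <- c(0.1, 5, 100)
  po_s <- po_curve(ca, ip3 = 1, mode = "stationary")$po
  po_m <- po_curve(ca, ip3 = 1, duration = 1500, mode = "simulated",
                   seed = 4)$po
  expect_equal(po_m, po_s, tolerance = 0.12)     # relative
  expect_true(all(abs(po_m - po_s) < 0.06))      # absolute band
})
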