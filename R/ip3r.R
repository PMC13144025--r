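# Six-state park/drive IP3R2 gating.
#
# States 1..6 on a tree: 1-2-3 and 2-6 form the high-open-probability
# "drive" mode (open state 6), 4-5 the low-open-probability "park" mode
# (open state 5). The intermodal edge 2-4 carries the Ca2+/IP3-dependent
# rates q24 (drive -> park) and q42 (park -> drive); all other rates are
# fixed. Open states: {5, 6}. IP3 is required for the channel to open and
# conduct: at [IP3] = 0 the drive mode is unreachable and the park open
# transition is disabled, so the channel stays closed.

IP3R_OPEN_STATES <- c(5L, 6L)
IP3R_PARK_STATES <- c(4L, 5L)
IP3R_DRIVE_STATES <- c(1L, 2L, 3L, 6L)

#' Ca2+/IP3-dependent gates of the intermodal transition
#'
#' The modal gates are Hill functions:
#' `m24 = c^2/(c^2 + k_m24^2)`, `h24 = k_h24^2/(c^2 + k_h24^2)` (and the
#' 42-direction analogues, with the drive-recruitment gate
#' `g = ip3^2/(ip3^2 + k_g^2)` folded into `m42`), and the IP3-only rates
#' `a24 = a24_max * k_a24^2/(k_a24^2 + ip3^2)` (parking, falls with IP3),
#' `a42 = a42_max * ip3^2/(ip3^2 + k_a42^2)` (recruitment, rises with
#' IP3). Together these make drive-mode occupancy — and hence open
#' probability — biphasic in Ca2+ and increasing in IP3.
#'
#' @param c_ds dyadic \[Ca2+\], uM.
#' @param ip3 \[IP3\], uM.
#' @param params `ip3r` section of [default_params()].
#' @return list with `m24`, `h24`, `m42`, `h42`, `a24`, `a42`, `v24`.
#' @export
ip3r_modal_gates <- function(c_ds, ip3, params) {
  stopifnot(all(c_ds >= 0), all(ip3 >= 0))
  c2 <- c_ds^2
  i2 <- ip3^2
  i4 <- i2^2
  # drive recruitment and a42 are quartic in IP3: the drive mode must be
  # essentially inaccessible at trace [IP3] yet fully recruited by 10 uM
  g <- i4 / (i4 + params$k_g^4)
  list(
    m24 = c2 / (c2 + params$k_m24^2),
    h24 = params$k_h24^2 / (c2 + params$k_h24^2),
    m42 = g * c2 / (c2 + params$k_m42^2),
    h42 = params$k_h42^2 / (c2 + params$k_h42^2),
    a24 = params$a24_max * params$k_a24^2 / (params$k_a24^2 + i2),
    a42 = params$a42_max * i4 / (i4 + params$k_a42^4),
    v24 = params$v24
  )
}

#' Intermodal transition rates q24 and q42
#'
#' `q24 = a24 + v24 * (1 - m24 * h24)` (drive -> park) and
#' `q42 = a42 + v42 * m42 * h42` (park -> drive), with the modal gates of
#' [ip3r_modal_gates()] and the fixed rate `v42`.
#'
#' @inheritParams ip3r_modal_gates
#' @return list with `q24`, `q42` (ms^-1).
#' @export
#' @examples
#' intermodal_rates(1, 1, default_params()$ip3r)
intermodal_rates <- function(c_ds, ip3, params) {
  gt <- ip3r_modal_gates(c_ds, ip3, params)
  list(q24 = gt$a24 + gt$v24 * (1 - gt$m24 * gt$h24),
       q42 = gt$a42 + params$v42 * gt$m42 * gt$h42)
}

#' Assemble the six-state generator matrix
#'
#' 6x6 continuous-time Markov generator (ms^-1) on the tree
#' 1-2, 2-3, 2-6, 2-4, 4-5; rows sum to zero, off-diagonals only on tree
#' edges.
#'
#' @param q24,q42 intermodal rates, ms^-1 (>= 0).
#' @param params `ip3r` parameter list (fixed rates).
#' @return 6x6 numeric matrix.
#' @export
build_generator <- function(q24, q42, params) {
  if (q24 < 0 || q42 < 0) stop_arg("intermodal rates must be >= 0")
  Q <- matrix(0, 6, 6)
  Q[1, 2] <- params$q12; Q[2, 1] <- params$q21
  Q[2, 3] <- params$q23; Q[3, 2] <- params$q32
  Q[2, 6] <- params$q26; Q[6, 2] <- params$q62
  Q[2, 4] <- q24;        Q[4, 2] <- q42
  Q[4, 5] <- params$q45; Q[5, 4] <- params$q54
  diag(Q) <- -rowSums(Q)
  Q
}

# Convenience: generator at given (c, ip3).
ip3r_generator <- function(c_ds, ip3, params) {
  q <- intermodal_rates(c_ds, ip3, params)
  build_generator(q$q24, q$q42, params)
}

#' Stationary distribution of the six-state chain
#'
#' Because the transition graph is a tree, the stationary distribution
#' satisfies detailed balance edge by edge and is computed exactly by
#' edge-ratio products. If the intermodal edge is cut (`q24` or `q42`
#' zero, e.g. at \[IP3\] = 0) the chain is reducible: with a warning, the
#' distribution restricted to the reachable mode is returned (park if the
#' drive mode drains into it, i.e. `q42 = 0`; drive if `q24 = 0`).
#'
#' @param gen 6x6 generator from [build_generator()].
#' @return probability vector of length 6.
#' @export
stationary_distribution <- function(gen) {
  stopifnot(is.matrix(gen), all(dim(gen) == c(6, 6)))
  q24 <- gen[2, 4]; q42 <- gen[4, 2]
  w <- rep(0, 6)
  w[2] <- 1
  w[1] <- gen[2, 1] / gen[1, 2]
  w[3] <- gen[2, 3] / gen[3, 2]
  w[6] <- gen[2, 6] / gen[6, 2]
  if (q24 > 0 && q42 > 0) {
    w[4] <- q24 / q42
    w[5] <- w[4] * gen[4, 5] / gen[5, 4]
  } else if (q42 == 0 && q24 > 0) {
    warning("reducible chain (q42 = 0): returning park-mode distribution",
            call. = FALSE)
    w <- rep(0, 6)
    w[4] <- 1
    w[5] <- gen[4, 5] / gen[5, 4]
  } else if (q24 == 0 && q42 > 0) {
    warning("reducible chain (q24 = 0): returning drive-mode distribution",
            call. = FALSE)
    # w already drive-only
  } else {
    warning("reducible chain (q24 = q42 = 0): returning park-mode distribution",
            call. = FALSE)
    w <- rep(0, 6)
    w[4] <- 1
    w[5] <- gen[4, 5] / gen[5, 4]
  }
  w / sum(w)
}

#' One fixed-dt stochastic step of IP3R2 states
#'
#' Each channel moves from state `i` to neighbour `j` with probability
#' `dt * q_ij`, else stays; one uniform draw per channel. Errors if the
#' total exit probability of any state could exceed 0.1.
#'
#' @param states integer vector of states in 1..6.
#' @param gen 6x6 generator.
#' @param dt time step, ms.
#' @return updated integer vector.
#' @export
step_ip3r <- function(states, gen, dt) {
  stopifnot(all(states %in% 1:6), dt > 0)
  exit <- -diag(gen)
  if (dt * max(exit) > 0.1) {
    stop_arg(sprintf(
      "dt = %g ms violates the gating guard (max exit p = %.3g > 0.1); use dt <= %.3g",
      dt, dt * max(exit), 0.1 / max(exit)))
  }
  P <- dt * gen
  diag(P) <- 0
  cum <- t(apply(P, 1, cumsum))
  u <- runif(length(states))
  out <- states
  for (s in 1:6) {
    idx <- which(states == s)
    if (!length(idx)) next
    # first state j with u < cum[s, j]; u beyond the total -> stay
    j <- findInterval(u[idx], cum[s, ]) + 1L
    move <- j <= 6L & u[idx] < cum[s, 6]
    out[idx[move]] <- j[move]
  }
  out
}

#' Open-probability curve of a single IP3R2
#'
#' For each Ca2+ level: `"stationary"` returns `pi_5 + pi_6` of the exact
#' stationary distribution; `"simulated"` runs a free single channel for
#' `duration` ms at clamped fields (no RyR2s, no IP3R2 flux, so \[Ca2+\]
#' does not change) and reports the fraction of time spent open.
#'
#' @param ca_grid Ca2+ concentrations, uM.
#' @param ip3 \[IP3\], uM.
#' @param duration simulated duration per concentration, ms.
#' @param mode `"stationary"` or `"simulated"`.
#' @param seed integer seed (simulated mode).
#' @param params `ip3r` parameter list.
#' @return data.frame with columns `ca_uM`, `po`.
#' @export
#' @examples
#' po <- po_curve(c(0.1, 3, 100), ip3 = 1)
#' po$po
po_curve <- function(ca_grid, ip3, duration = 1000,
                     mode = c("stationary", "simulated"), seed = 1,
                     params = default_params()$ip3r) {
  mode <- match.arg(mode)
  stopifnot(all(ca_grid >= 0), ip3 >= 0, duration > 0)
  po <- vapply(seq_along(ca_grid), function(i) {
    c_ds <- ca_grid[i]
    if (ip3 == 0) return(0)  # cannot open without IP3
    if (mode == "stationary") {
      pi <- stationary_distribution(ip3r_generator(c_ds, ip3, params))
      sum(pi[IP3R_OPEN_STATES])
    } else {
      dt <- 0.9 * 0.1 / max_ip3r_exit_rate(params)
      ip3r_po_sim_cpp(c_ds, ip3, duration, dt,
                      derive_seed(seed, i), params)
    }
  }, numeric(1))
  data.frame(ca_uM = ca_grid, po = po)
}

# Upper bound on the total exit rate over all states and all (c, ip3):
# state 2 can exit at q21+q23+q26 + (a24_max + v24); state 4 at
# q45 + (a42_max + v42). Used to derive the gating dt guard.
max_ip3r_exit_rate <- function(params) {
  max(params$q12,
      params$q21 + params$q23 + params$q26 + params$a24_max + params$v24,
      params$q32,
      params$q45 + params$a42_max + params$v42,
      params$q54,
      params$q62)
}
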