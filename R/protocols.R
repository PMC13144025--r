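# Batch experiment protocols: fidelity sweep over (N_IP3R, [IP3]) and the
# control-vs-heart-failure comparison. Per-trial seeds derive from
# (base seed, condition index, trial index); spark morphology statistics
# are computed over spark trials only, fidelity over all trials.

run_condition <- function(geom_fun, n_ip3r, ip3, n_trials, cond_idx,
                          base_seed, duration, params, rule,
                          reseed_placement = TRUE) {
  res <- vector("list", n_trials)
  geom_fixed <- NULL
  for (k in seq_len(n_trials)) {
    seed <- derive_seed(base_seed, cond_idx, k)
    g <- if (reseed_placement || is.null(geom_fixed)) {
      gg <- geom_fun()
      if (n_ip3r > 0) gg <- place_ip3rs(gg, n_ip3r,
                                        seed = derive_seed(seed, 3L))
      if (!reseed_placement) geom_fixed <- gg
      gg
    } else geom_fixed
    rec <- run_trial(g, trial_config(duration = duration, seed = seed,
                                     ip3 = ip3, spark_rule = rule),
                     params)
    res[[k]] <- summarize_trial(rec, rule)
  }
  res
}

condition_row <- function(label, n_ryr, n_ip3r, ip3, summaries) {
  n <- length(summaries)
  is_spark <- vapply(summaries, `[[`, logical(1), "is_spark")
  fid <- mean(is_spark)
  sp <- summaries[is_spark]
  stat <- function(field) {
    v <- vapply(sp, `[[`, numeric(1), field)
    c(mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) > 1) sd(v) else NA_real_)
  }
  mass <- stat("ca_mass_fC"); dur <- stat("duration_ms")
  mno <- stat("max_n_open")
  data.frame(
    condition = label, n_ryr = n_ryr, n_ip3r = n_ip3r, ip3_uM = ip3,
    n_trials = n, n_sparks = sum(is_spark),
    fidelity = fid, fidelity_se = sqrt(fid * (1 - fid) / n),
    mass_mean_fC = mass["mean"], mass_sd_fC = mass["sd"],
    duration_mean_ms = dur["mean"], duration_sd_ms = dur["sd"],
    max_n_open_mean = mno["mean"], max_n_open_sd = mno["sd"],
    n_multispark = sum(vapply(summaries, `[[`, logical(1),
                              "is_multispark")),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Spark-fidelity sweep over IP3R2 count and IP3 concentration
#'
#' For each combination of `n_ip3r` and `ip3`, runs `n_trials` trials on
#' an `n_ryr`-channel checkerboard with IP3R2s re-placed at random for
#' every trial (the default; set `reseed_placement = FALSE` to fix one
#' placement per condition), forcing one RyR2 open at t = 0, and reports
#' spark fidelity (qualifying trials / all trials) with its binomial
#' standard error plus morphology statistics over spark trials.
#'
#' The standard protocol is `n_ip3r = 0:10`, `ip3 = c(0, 0.1, 1, 10)`,
#' `n_trials = 100`; reduced grids run proportionally faster.
#'
#' @param n_ip3r integer vector of IP3R2 counts.
#' @param ip3 numeric vector of \[IP3\] values, uM.
#' @param n_trials trials per condition.
#' @param n_ryr checkerboard RyR2 count.
#' @param duration trial length, ms.
#' @param base_seed integer; per-trial seeds derive from it.
#' @param params full parameter list.
#' @param rule spark classification rule.
#' @param reseed_placement re-randomize IP3R2 placement each trial.
#' @param progress print one line per condition.
#' @return data.frame, one row per condition.
#' @export
run_fidelity_sweep <- function(n_ip3r = 0:10, ip3 = c(0, 0.1, 1, 10),
                               n_trials = 100, n_ryr = 50, duration = 200,
                               base_seed = 1, params = default_params(),
                               rule = "gt5", reseed_placement = TRUE,
                               progress = FALSE) {
  stopifnot(n_trials >= 1, length(n_ip3r) >= 1, length(ip3) >= 1)
  grid <- expand.grid(n_ip3r = n_ip3r, ip3 = ip3)
  rows <- vector("list", nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    ni <- grid$n_ip3r[ci]; ii <- grid$ip3[ci]
    if (progress) {
      message(sprintf("condition %d/%d: N_IP3R=%d, [IP3]=%g uM",
                      ci, nrow(grid), ni, ii))
    }
    sm <- run_condition(function() make_checkerboard(n_ryr), ni, ii,
                        n_trials, ci, base_seed, duration, params, rule,
                        reseed_placement)
    rows[[ci]] <- condition_row(sprintf("checkerboard N_IP3R=%d IP3=%g",
                                        ni, ii),
                                n_ryr, ni, ii, sm)
  }
  do.call(rbind, rows)
}

#' Control versus heart-failure spark comparison
#'
#' Control conditions: `n_ryr` checkerboard with `ctrl_n_ip3r` IP3R2s
#' (default 0 and 1). Heart-failure conditions: fragmented/dispersed
#' clusters with `hf_frac * n_ryr` IP3R2s (rounded half-up; default 0%,
#' 25%, 50% and 100%). \[IP3\] is held at `ip3` (0.1 uM standard). The
#' HF geometry is generated once per run from the base seed (emulating a
#' fixed imaged CRU); IP3R2 placements re-randomize per trial.
#'
#' @param n_trials trials per condition (standard protocol: 500).
#' @param ip3 \[IP3\], uM.
#' @param n_ryr RyR2 count per CRU.
#' @param ctrl_n_ip3r IP3R2 counts for the control CRU.
#' @param hf_frac IP3R2 expression as a fraction of `n_ryr` for the HF
#'   CRU.
#' @param duration trial length, ms.
#' @param base_seed integer seed.
#' @param params full parameter list.
#' @param rule spark classification rule.
#' @param progress print one line per condition.
#' @return data.frame, one row per condition (see
#'   [run_fidelity_sweep()]).
#' @export
run_ctrl_vs_hf <- function(n_trials = 500, ip3 = 0.1, n_ryr = 50,
                           ctrl_n_ip3r = c(0, 1),
                           hf_frac = c(0, 0.25, 0.5, 1),
                           duration = 200, base_seed = 1,
                           params = default_params(), rule = "gt5",
                           progress = FALSE) {
  stopifnot(n_trials >= 1)
  hf_geom <- geometry_preset("hf", seed = derive_seed(base_seed, 99L),
                             n_ryr = n_ryr)
  conds <- c(
    lapply(ctrl_n_ip3r, function(n) {
      list(label = sprintf("CTRL N_IP3R=%d", n), hf = FALSE,
           n_ip3r = as.integer(n))
    }),
    lapply(hf_frac, function(f) {
      n <- as.integer(round_half_up(f * n_ryr))
      list(label = sprintf("HF N_IP3R=%d (%.0f%% N_RyR)", n, 100 * f),
           hf = TRUE, n_ip3r = n)
    })
  )
  rows <- vector("list", length(conds))
  for (ci in seq_along(conds)) {
    cd <- conds[[ci]]
    if (progress) message(sprintf("condition %d/%d: %s", ci, length(conds),
                                  cd$label))
    gf <- if (cd$hf) function() hf_geom else function() make_checkerboard(n_ryr)
    sm <- run_condition(gf, cd$n_ip3r, ip3, n_trials, ci, base_seed,
                        duration, params, rule)
    rows[[ci]] <- condition_row(cd$label, n_ryr, cd$n_ip3r, ip3, sm)
  }
  do.call(rbind, rows)
}
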