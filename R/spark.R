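# Spark engine: single stochastic trials, spark detection and morphology.

#' Trial configuration
#'
#' @param duration trial length, ms (the standard protocol uses 200 ms).
#' @param dt time step, ms; `NULL` derives the largest step allowed by
#'   [dt_stability()].
#' @param seed integer trial seed; everything stochastic in the trial
#'   (gating streams, initial IP3R2 states) derives from it.
#' @param ip3 \[IP3\], uM (held constant; 0.1 uM in the standard
#'   protocols).
#' @param forced which RyR2 is set open at t = 0: `"center"` (the RyR2
#'   closest to the RyR2 centroid; deterministic), `"random"`, `"none"`,
#'   or an explicit `c(ix, iy)` lattice position.
#' @param record_stride steps between saved samples; `NULL` targets a
#'   0.05-ms sampling interval.
#' @param spark_rule episode peak rule for spark classification:
#'   `"gt5"` (peak simultaneous open count > 5, the default) or `"ge5"`
#'   (>= 5), reflecting the two readings of "at least 4 other channels".
#' @param boundary_ds dyadic boundary condition (`"dirichlet"` rim held at
#'   `c_rest`, or `"noflux"` for closed-system tests).
#' @param refill logical; JSR refill from the NSR on (default) or off.
#' @return list of class `trial_config`.
#' @export
trial_config <- function(duration = 200, dt = NULL, seed = 1, ip3 = 0.1,
                         forced = "center", record_stride = NULL,
                         spark_rule = c("gt5", "ge5"),
                         boundary_ds = c("dirichlet", "noflux"),
                         refill = TRUE) {
  stopifnot(duration > 0, ip3 >= 0)
  structure(list(duration = duration, dt = dt, seed = as.integer(seed),
                 ip3 = ip3, forced = forced, record_stride = record_stride,
                 spark_rule = match.arg(spark_rule),
                 boundary_ds = match.arg(boundary_ds), refill = refill),
            class = "trial_config")
}

cell_index <- function(geom, ix, iy) (ix - 1L) + (iy - 1L) * geom$nx

resolve_forced <- function(geom, forced, seed) {
  ry <- ryr_sites(geom)
  if (identical(forced, "none")) return(-1L)
  if (!nrow(ry)) stop_arg("geometry has no RyR2 to force open")
  if (identical(forced, "center")) {
    cx <- mean(ry$ix); cy <- mean(ry$iy)
    d2 <- (ry$ix - cx)^2 + (ry$iy - cy)^2
    return(which.min(d2) - 1L)
  }
  if (identical(forced, "random")) {
    return(with_seed(derive_seed(seed, 11L),
                     sample.int(nrow(ry), 1L)) - 1L)
  }
  if (is.numeric(forced) && length(forced) == 2L) {
    hit <- which(ry$ix == forced[1] & ry$iy == forced[2])
    if (!length(hit)) {
      stop_arg(sprintf("no RyR2 at explicit forced site (%d,%d)",
                       forced[1], forced[2]))
    }
    return(hit[1] - 1L)
  }
  stop_arg("`forced` must be \"center\", \"random\", \"none\" or c(ix, iy)")
}

#' Run one stochastic spark trial
#'
#' Initial state: dyadic \[Ca2+\] at `c_rest`, JSR at `ca_nsr`, buffers at
#' equilibrium, all RyR2s closed, IP3R2 states drawn from their stationary
#' distribution at (`c_rest`, `ip3`). At t = 0 the forced RyR2 is set open
#' and thereafter gates freely; channels and fields advance on the same
#' fixed dt. Fully reproducible from (seed, config, geometry): the RyR2
#' and IP3R2 gating streams are seeded separately from the trial seed.
#'
#' @param geom a `cru_geometry` with at least one RyR2 (unless
#'   `forced = "none"`).
#' @param cfg a [trial_config()].
#' @param params full parameter list ([default_params()]).
#' @return a `trial_record`: data.frame of sampled series (`t_ms`,
#'   `n_open_ryr`, `n_open_ip3r`, `i_total_pA`, `cds_mean_uM`,
#'   `cds_max_uM`, `cjsr_min_uM`, `ca_total`) with the configuration,
#'   seed, dt and final fields attached as attributes.
#' @export
#' @examples
#' g <- make_checkerboard(8, margin = 4)
#' rec <- run_trial(g, trial_config(duration = 5, seed = 1))
#' max_n_open(rec)
run_trial <- function(geom, cfg = trial_config(), params = default_params()) {
  stopifnot(inherits(geom, "cru_geometry"), inherits(cfg, "trial_config"))
  ry <- ryr_sites(geom)
  ip <- ip3r_sites(geom)
  if (!nrow(ry) && !identical(cfg$forced, "none")) {
    stop_arg("geometry has no RyR2 channels")
  }
  bounds <- dt_stability(params, geom$pitch_nm)
  dt <- cfg$dt %||% bounds$dt
  if (dt > bounds$dt + 1e-15) {
    stop_arg(sprintf(
      "dt = %g ms violates the stability/gating bound %.4g ms", dt,
      bounds$dt))
  }
  nsteps <- ceiling(cfg$duration / dt)
  stride <- cfg$record_stride %||% max(1L, round(0.05 / dt))

  tp <- params$transport
  tp$p_ryr <- calibrate_permeability(tp$i_ryr_pA, tp$calib_dc_uM)
  tp$p_ip3r <- calibrate_permeability(tp$i_ip3r_pA, tp$calib_dc_uM)
  tp$pitch_nm <- geom$pitch_nm

  fields <- new_field_state(geom, params)
  pi0 <- if (nrow(ip) && cfg$ip3 > 0) {
    stationary_distribution(ip3r_generator(tp$c_rest, cfg$ip3, params$ip3r))
  } else rep(0, 6)

  nbrs0 <- lapply(ryr_neighbor_list(geom), function(v) as.integer(v - 1L))
  forced <- resolve_forced(geom, cfg$forced, cfg$seed)

  out <- run_trial_cpp(
    geom$nx, geom$ny,
    cell_index(geom, ry$ix, ry$iy), nbrs0,
    cell_index(geom, ip$ix, ip$iy),
    forced,
    cfg$duration, dt, as.integer(stride),
    derive_seed(cfg$seed, 1L), derive_seed(cfg$seed, 2L),
    params$ryr, params$ip3r, tp, params$buffers,
    cfg$ip3,
    cfg$boundary_ds == "dirichlet", cfg$refill, tp$beta,
    as.numeric(fields$c_ds), as.numeric(fields$c_jsr),
    lapply(fields$b_free, as.numeric), pi0)

  rec <- data.frame(t_ms = out$t, n_open_ryr = out$n_open_ryr,
                    n_open_ip3r = out$n_open_ip3r,
                    i_total_pA = out$i_total_pA,
                    cds_mean_uM = out$cds_mean, cds_max_uM = out$cds_max,
                    cjsr_min_uM = out$cjsr_min, ca_total = out$ca_total)
  structure(rec, class = c("trial_record", "data.frame"),
            seed = cfg$seed, dt = dt, config = cfg,
            final_fields = list(
              c_ds = matrix(out$final_cds, geom$nx, geom$ny),
              c_jsr = matrix(out$final_cjsr, geom$nx, geom$ny),
              b_free = lapply(out$final_b,
                              function(v) matrix(v, geom$nx, geom$ny))))
}

#' Release episodes of a trial
#'
#' Episodes are maximal intervals of the sampled series during which the
#' total open-channel count (RyR2 + IP3R2) is positive, each annotated
#' with its peak simultaneous open count.
#'
#' @param rec a `trial_record` (or any data.frame with `t_ms`,
#'   `n_open_ryr`, `n_open_ip3r`).
#' @return data.frame with `start_ms`, `end_ms`, `peak`.
#' @export
detect_episodes <- function(rec) {
  tot <- rec$n_open_ryr + rec$n_open_ip3r
  on <- tot > 0
  if (!any(on)) {
    return(data.frame(start_ms = numeric(), end_ms = numeric(),
                      peak = integer()))
  }
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(
    start_ms = rec$t_ms[starts[keep]],
    end_ms = rec$t_ms[ends[keep]],
    peak = vapply(keep, function(k) {
      max(tot[starts[k]:ends[k]])
    }, numeric(1))
  )
}

#' Classify sparks among episodes
#'
#' An episode qualifies as a Ca2+ spark when its peak simultaneous open
#' count exceeds 5 (`"gt5"`, i.e. the trigger recruited at least 5 more
#' channels) or reaches 5 (`"ge5"`). A trial is a spark trial when at
#' least one episode qualifies; two or more qualifying episodes make a
#' multi-spark.
#'
#' @param episodes output of [detect_episodes()].
#' @param rule `"gt5"` (default) or `"ge5"`.
#' @return list with `is_spark`, `n_sparks`, `is_multispark`.
#' @export
classify_spark <- function(episodes, rule = c("gt5", "ge5")) {
  rule <- match.arg(rule)
  qual <- if (rule == "gt5") episodes$peak > 5 else episodes$peak >= 5
  n <- sum(qual)
  list(is_spark = n >= 1L, n_sparks = as.integer(n),
       is_multispark = n >= 2L)
}

#' Total Ca2+ mass released during a trial
#'
#' Trapezoidal area under the total release current (pA) versus time
#' (ms); pA * ms = fC.
#'
#' @param rec a `trial_record` (needs `t_ms`, `i_total_pA`).
#' @return charge, fC.
#' @export
ca_mass <- function(rec) trapz_int(rec$t_ms, rec$i_total_pA)

#' Spark duration from the dyadic Ca2+ trace
#'
#' Time between the first up-crossing and the last down-crossing of 10%
#' of the maximum of the spatially averaged dyadic \[Ca2+\] (crossings
#' linearly interpolated; baseline subtracted at the first sample so the
#' resting level does not count as signal). 0 when the trace never rises
#' above threshold after the first sample.
#'
#' @param rec a `trial_record` (needs `t_ms` and the concentration trace).
#' @param trace which dyadic summary to use: `"mean"` (fluorescence-like
#'   spatial average, default) or `"max"`.
#' @return duration, ms.
#' @export
spark_duration <- function(rec, trace = c("mean", "max")) {
  trace <- match.arg(trace)
  y <- if (trace == "mean") rec$cds_mean_uM else rec$cds_max_uM
  t <- rec$t_ms
  y <- y - y[1]
  m <- max(y)
  if (m <= 0) return(0)
  thr <- 0.1 * m
  above <- y > thr
  if (!any(above)) return(0)
  i1 <- which(above)[1]
  i2 <- tail(which(above), 1)
  cross <- function(ia, ib) {
    # linear interpolation of the threshold crossing between samples
    if (ia < 1) return(t[ib])
    t[ia] + (thr - y[ia]) * (t[ib] - t[ia]) / (y[ib] - y[ia])
  }
  t_up <- if (i1 == 1) t[1] else cross(i1 - 1, i1)
  t_dn <- if (i2 == length(y)) t[i2] else cross(i2 + 1, i2)
  t_dn - t_up
}

#' Maximum simultaneous open-channel count
#'
#' @param rec a `trial_record`.
#' @return integer.
#' @export
max_n_open <- function(rec) {
  if (!nrow(rec)) return(0L)
  as.integer(max(rec$n_open_ryr + rec$n_open_ip3r))
}

#' Summarize a trial into spark metrics
#'
#' @param rec a `trial_record`.
#' @param rule spark classification rule (see [classify_spark()]).
#' @return list of class `spark_summary`: `is_spark`, `n_sparks`,
#'   `is_multispark`, `n_episodes`, `ca_mass_fC`, `duration_ms`,
#'   `max_n_open`.
#' @export
summarize_trial <- function(rec, rule = c("gt5", "ge5")) {
  rule <- match.arg(rule)
  ep <- detect_episodes(rec)
  cls <- classify_spark(ep, rule)
  structure(list(
    is_spark = cls$is_spark, n_sparks = cls$n_sparks,
    is_multispark = cls$is_multispark, n_episodes = nrow(ep),
    ca_mass_fC = ca_mass(rec), duration_ms = spark_duration(rec),
    max_n_open = max_n_open(rec)
  ), class = "spark_summary")
}

#' @export
print.spark_summary <- function(x, ...) {
  cat(sprintf(
    "<spark_summary> spark: %s (%d qualifying / %d episodes)\n  mass %.3g fC, duration %.3g ms, max n_open %d\n",
    x$is_spark, x$n_sparks, x$n_episodes, x$ca_mass_fC, x$duration_ms,
    x$max_n_open))
  invisible(x)
}

#' Write a trial time series as CSV
#'
#' @param rec a `trial_record`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(rec, path) {
  write.csv(as.data.frame(rec)[c("t_ms", "n_open_ryr", "n_open_ip3r",
                                 "i_total_pA", "cds_mean_uM", "cds_max_uM",
                                 "cjsr_min_uM")],
            path, row.names = FALSE)
  invisible(path)
}
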