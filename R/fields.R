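# Dyadic / JSR reaction-diffusion fields.
#
# Explicit-Euler update on the geometry's lattice: dyadic [Ca2+] gains
# 5-point-Laplacian diffusion (D_myo), channel fluxes and net buffer
# release; JSR [Ca2+] gains beta * (refill + Laplacian diffusion (D_JSR)
# - channel fluxes). Dyadic boundary is Dirichlet at c_rest (escape to
# bulk cytosol), JSR boundary no-flux. Sub-volumes of the two compartments
# are matched, with beta absorbing luminal rapid buffering.

#' Calibrate a single-channel permeability from its current
#'
#' `P = i / (2 F dC)`: the volume flow (L/ms) such that one open channel
#' at a JSR-to-dyad gradient `dC` carries current `i` of divalent Ca2+.
#' [channel_current()] is the exact inverse map.
#'
#' @param i_single single-channel current, pA.
#' @param delta_c calibration gradient, uM.
#' @return permeability, L/ms.
#' @export
#' @examples
#' p <- calibrate_permeability(0.16, 850)
#' channel_current(p, 850)  # 0.16 pA again
calibrate_permeability <- function(i_single, delta_c) {
  i_single <- check_pos(i_single, "i_single")
  delta_c <- check_pos(delta_c, "delta_c")
  # pA = 1e-12 C/s; uM * L = 1e-6 umol = 1e-12 mol... work in SI:
  # mol/s = i[A] / (2F); P[L/s] = (mol/s) / (delta_c [mol/L]); ms scale.
  (i_single * 1e-12) / (2 * .FARADAY * delta_c * 1e-6) / 1000
}

#' @rdname calibrate_permeability
#' @param p permeability, L/ms.
#' @return current, pA.
#' @export
channel_current <- function(p, delta_c) {
  2 * .FARADAY * p * 1000 * delta_c * 1e-6 * 1e12
}

#' Channel Ca2+ fluxes into the dyadic sub-volume
#'
#' `J = n_open * P * (c_jsr - c_ds) / v_ds` in uM/ms; the sign follows the
#' gradient. `flux_ryr()` uses the RyR2 permeability, `flux_ip3r()` the
#' IP3R2 permeability (calibrated from `i_ryr_pA` / `i_ip3r_pA` at
#' `calib_dc_uM`).
#'
#' @param n_open number of open channels at the site.
#' @param c_jsr,c_ds local JSR and dyadic \[Ca2+\], uM.
#' @param params `transport` parameter list.
#' @return flux, uM/ms (vectorised).
#' @export
flux_ryr <- function(n_open, c_jsr, c_ds, params) {
  p <- calibrate_permeability(params$i_ryr_pA, params$calib_dc_uM)
  n_open * p * (c_jsr - c_ds) / params$v_ds_L
}

#' @rdname flux_ryr
#' @export
flux_ip3r <- function(n_open, c_jsr, c_ds, params) {
  p <- calibrate_permeability(params$i_ip3r_pA, params$calib_dc_uM)
  n_open * p * (c_jsr - c_ds) / params$v_ds_L
}

#' JSR refill flux from the bulk NSR store
#'
#' `J_refill = (ca_nsr - c_jsr) / tau_refill`, uM/ms: first-order
#' relaxation to the fixed network-SR concentration.
#'
#' @param c_jsr JSR \[Ca2+\], uM (vectorised).
#' @param params `transport` parameter list.
#' @return flux, uM/ms.
#' @export
#' @examples
#' refill_flux(850, default_params()$transport)  # 0 at full load
refill_flux <- function(c_jsr, params) {
  (params$ca_nsr - c_jsr) / params$tau_refill
}

# Equilibrium free-buffer concentration at dyadic Ca2+ level c.
buffer_equilibrium <- function(c, buf) {
  buf$b_total * buf$k_off / (buf$k_off + buf$k_on * c)
}

#' One explicit-Euler step of the three dyadic buffers
#'
#' Per buffer, the net free-Ca2+ release is
#' `j_i = k_off * (b_total - b) - k_on * b * c_ds` (negative when binding
#' removes Ca2+), and the free-buffer pool moves by the same amount:
#' `b <- b + dt * j_i`. Free + bound buffer is conserved exactly.
#'
#' @param b_free list (or single matrix) of free-buffer grids, uM.
#' @param c_ds dyadic \[Ca2+\] grid, uM.
#' @param dt time step, ms.
#' @param params `buffers` parameter list.
#' @return list with `b_free` (updated grids) and `j_total` (net Ca2+
#'   release rate, uM/ms, the buffer term of the dyadic update).
#' @export
buffer_step <- function(b_free, c_ds, dt, params) {
  stopifnot(dt > 0)
  j_total <- 0
  out <- b_free
  for (nm in names(params)) {
    buf <- params[[nm]]
    b <- b_free[[nm]]
    j <- buf$k_off * (buf$b_total - b) - buf$k_on * b * c_ds
    b_new <- b + dt * j
    if (any(b_new < 0) || any(b_new > buf$b_total)) {
      warning(sprintf("buffer `%s` clamped to [0, b_total]; dt may be too large",
                      nm), call. = FALSE)
      b_new <- pmin(pmax(b_new, 0), buf$b_total)
    }
    out[[nm]] <- b_new
    j_total <- j_total + j
  }
  list(b_free = out, j_total = j_total)
}

#' Explicit-scheme stability bound on the time step
#'
#' `dt <= 0.5 * dx^2 / (4 * max(d_myo, beta * d_jsr))` for the 5-point
#' diffusion update (the JSR Laplacian enters scaled by `beta`), combined
#' with the gating guards (per-channel transition probability <= 0.1).
#'
#' @param params full parameter list ([default_params()]).
#' @param pitch_nm lattice pitch, nm.
#' @return list with `dt_fields`, `dt_ryr`, `dt_ip3r`, `dt` (the overall
#'   bound), all in ms.
#' @export
dt_stability <- function(params = default_params(),
                         pitch_nm = CRU_PITCH_NM) {
  dx_um <- pitch_nm / 1000
  d_eff <- max(params$transport$d_myo,
               params$transport$beta * params$transport$d_jsr)
  dt_fields <- 0.5 * dx_um^2 / (4 * d_eff)
  dt_ryr <- 0.1 / (max(params$ryr$kplus_max, params$ryr$kminus) *
                     exp(4 * abs(params$ryr$ej)))
  dt_ip3r <- 0.1 / max_ip3r_exit_rate(params$ip3r)
  list(dt_fields = dt_fields, dt_ryr = dt_ryr, dt_ip3r = dt_ip3r,
       dt = min(dt_fields, dt_ryr, dt_ip3r))
}

#' Initial field state for a geometry
#'
#' Dyadic \[Ca2+\] at `c_rest` everywhere, JSR at `ca_nsr`, the three
#' buffers at binding equilibrium with `c_rest`.
#'
#' @param geom a `cru_geometry`.
#' @param params full parameter list.
#' @return list of grids (`nx` x `ny` matrices): `c_ds`, `c_jsr`, and
#'   `b_free` (named list of three).
#' @export
new_field_state <- function(geom, params = default_params()) {
  tp <- params$transport
  grid <- function(v) matrix(v, geom$nx, geom$ny)
  list(
    c_ds  = grid(tp$c_rest),
    c_jsr = grid(tp$ca_nsr),
    b_free = lapply(params$buffers, function(b) {
      grid(buffer_equilibrium(tp$c_rest, b))
    })
  )
}

# 5-point Laplacian (1/dx^2 units applied by caller) with configurable
# ghost cells: "dirichlet" pads with `bc_value`, "noflux" replicates edges.
lap5 <- function(m, boundary = c("dirichlet", "noflux"), bc_value = 0) {
  boundary <- match.arg(boundary)
  nx <- nrow(m); ny <- ncol(m)
  pad <- matrix(if (boundary == "dirichlet") bc_value else 0,
                nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- m
  if (boundary == "noflux") {
    pad[1, 2:(ny + 1)] <- m[1, ]; pad[nx + 2, 2:(ny + 1)] <- m[nx, ]
    pad[2:(nx + 1), 1] <- m[, 1]; pad[2:(nx + 1), ny + 2] <- m[, ny]
  }
  pad[1:nx, 2:(ny + 1)] + pad[3:(nx + 2), 2:(ny + 1)] +
    pad[2:(nx + 1), 1:ny] + pad[2:(nx + 1), 3:(ny + 2)] - 4 * m
}

#' One explicit-Euler step of the dyadic and JSR fields
#'
#' Reference (pure-R) implementation of the coupled update; [run_trial()]
#' uses an equivalent compiled path. `n_open_ryr` / `n_open_ip3r` are
#' per-site open-channel counts (matrices, or NULL for none).
#'
#' @param fields field state from [new_field_state()].
#' @param dt time step, ms (checked against [dt_stability()]).
#' @param params full parameter list.
#' @param n_open_ryr,n_open_ip3r open-channel count grids or NULL.
#' @param boundary_ds dyadic boundary: `"dirichlet"` (held at `c_rest`,
#'   default) or `"noflux"` (closed test configuration).
#' @param refill logical; include the NSR refill term.
#' @param beta luminal buffering factor override (default from params).
#' @param pitch_nm lattice pitch, nm.
#' @return updated field state.
#' @export
step_fields <- function(fields, dt, params = default_params(),
                        n_open_ryr = NULL, n_open_ip3r = NULL,
                        boundary_ds = c("dirichlet", "noflux"),
                        refill = TRUE, beta = NULL,
                        pitch_nm = CRU_PITCH_NM) {
  boundary_ds <- match.arg(boundary_ds)
  tp <- params$transport
  beta <- beta %||% tp$beta
  dx_um <- pitch_nm / 1000
  d_eff <- max(tp$d_myo, beta * tp$d_jsr)
  if (dt > 0.5 * dx_um^2 / (4 * d_eff) + 1e-15) {
    stop_arg(sprintf(
      "dt = %g ms violates the diffusion stability bound %.4g ms",
      dt, 0.5 * dx_um^2 / (4 * d_eff)))
  }
  c_ds <- fields$c_ds; c_jsr <- fields$c_jsr
  j_ryr <- if (is.null(n_open_ryr)) 0 else
    flux_ryr(n_open_ryr, c_jsr, c_ds, tp)
  j_ip3r <- if (is.null(n_open_ip3r)) 0 else
    flux_ip3r(n_open_ip3r, c_jsr, c_ds, tp)
  bs <- buffer_step(fields$b_free, c_ds, dt, params$buffers)
  lap_ds <- lap5(c_ds, boundary_ds, tp$c_rest) / dx_um^2
  lap_jsr <- lap5(c_jsr, "noflux") / dx_um^2
  j_ref <- if (refill) refill_flux(c_jsr, tp) else 0
  new_ds <- c_ds + dt * (tp$d_myo * lap_ds + j_ryr + j_ip3r + bs$j_total)
  new_jsr <- c_jsr + dt * beta * (j_ref + tp$d_jsr * lap_jsr - j_ryr - j_ip3r)
  fields$c_ds <- pmax(new_ds, 0)
  fields$c_jsr <- pmax(new_jsr, 0)
  fields$b_free <- bs$b_free
  fields
}

# Total Ca2+ content (uM * site, matched sub-volumes): free dyadic +
# buffer-bound + JSR. Conserved in the closed test configuration.
total_calcium <- function(fields, params = default_params()) {
  bound <- 0
  for (nm in names(params$buffers)) {
    bound <- bound + sum(params$buffers[[nm]]$b_total - fields$b_free[[nm]])
  }
  sum(fields$c_ds) + sum(fields$c_jsr) + bound
}
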