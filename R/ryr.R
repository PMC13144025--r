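# Two-state stochastic RyR2 gating.
#
# Opening is Hill-type in dyadic [Ca2+] against a threshold K_r that falls
# linearly with local JSR load (luminal regulation), and both opening and
# closing probabilities are modulated by exp(EJ * num_net), the allosteric
# coupling to edge-sharing neighbours.

#' RyR2 activation threshold under luminal regulation
#'
#' `K_r(x,y) = max(k_r_max - alpha_r * c_jsr, k_r_floor)` in uM. A loaded
#' JSR lowers the threshold (channels easier to open); depletion during a
#' spark raises it again, which is the main termination mechanism. The
#' floor keeps the linear form positive at high load.
#'
#' @param c_jsr local JSR \[Ca2+\], uM (vectorised).
#' @param params `ryr` section of [default_params()].
#' @return threshold concentration(s), uM.
#' @export
#' @examples
#' activation_threshold(850, default_params()$ryr)
activation_threshold <- function(c_jsr, params) {
  stopifnot(all(c_jsr >= 0))
  pmax(params$k_r_max - params$alpha_r * c_jsr, params$k_r_floor)
}

#' RyR2 opening rate (Hill activation by dyadic Ca2+)
#'
#' `k+ = kplus_max * c_ds^hill / (c_ds^hill + k_r^hill)`, bounded in
#' `[0, kplus_max]`.
#'
#' @param c_ds dyadic \[Ca2+\], uM (vectorised).
#' @param k_r activation threshold from [activation_threshold()], uM.
#' @param params `ryr` parameter list.
#' @return opening rate(s), ms^-1.
#' @export
opening_rate <- function(c_ds, k_r, params) {
  stopifnot(all(c_ds >= 0), all(k_r > 0))
  ch <- c_ds^params$hill
  params$kplus_max * ch / (ch + k_r^params$hill)
}

#' Allosteric coupling factor
#'
#' `exp(ej * num_net)`: transition probabilities of a channel are scaled by
#' the exponential of the coupling energy times the net neighbour state.
#'
#' @param num_net integer net neighbour count (see [count_num_net()]).
#' @param params `ryr` parameter list.
#' @return dimensionless factor(s).
#' @export
coupling_factor <- function(num_net, params) exp(params$ej * num_net)

# Adjacency among RyR sites: indices (into the RyR site table) of
# edge-sharing (Manhattan distance 1) RyR neighbours.
ryr_neighbor_list <- function(geom) {
  ry <- ryr_sites(geom)
  n <- nrow(ry)
  key <- paste(ry$ix, ry$iy)
  lapply(seq_len(n), function(i) {
    nb <- paste(c(ry$ix[i] + 1L, ry$ix[i] - 1L, ry$ix[i], ry$ix[i]),
                c(ry$iy[i], ry$iy[i], ry$iy[i] + 1L, ry$iy[i] - 1L))
    which(key %in% nb)
  })
}

#' Net neighbour state of an RyR2
#'
#' Neighbours are RyR2s at Manhattan distance 1 (edge-sharing at the 30-nm
#' pitch). For an opening transition `num_net` is (open neighbours) -
#' (closed neighbours); for a closing transition the negation, so coupling
#' always favours conformity with the neighbourhood. Bounded in \[-4, 4\].
#'
#' @param i index of the channel in the RyR site table of `geom`.
#' @param open logical vector of per-RyR open flags.
#' @param geom a `cru_geometry` (or a precomputed neighbour list from it).
#' @param direction `"opening"` or `"closing"`.
#' @return integer in \[-4, 4\].
#' @export
count_num_net <- function(i, open, geom, direction = c("opening", "closing")) {
  direction <- match.arg(direction)
  nbrs <- if (is.list(geom) && !inherits(geom, "cru_geometry")) geom
          else ryr_neighbor_list(geom)
  nb <- nbrs[[i]]
  net <- sum(open[nb]) - sum(!open[nb])
  if (direction == "closing") net <- -net
  as.integer(net)
}

#' One fixed-dt stochastic step of all RyR2s
#'
#' Each closed channel opens with probability
#' `dt * k+ * exp(ej * num_net)` and each open channel closes with
#' probability `dt * k- * exp(ej * num_net)`, with `num_net` evaluated
#' from the pre-step state and one independent uniform draw per channel.
#' Errors if any per-channel probability could exceed 0.1 (use a smaller
#' `dt`).
#'
#' @param open logical vector of open flags (one per RyR2 site).
#' @param c_ds,c_jsr local dyadic and JSR \[Ca2+\] at each RyR2 site, uM.
#' @param dt time step, ms.
#' @param params `ryr` parameter list.
#' @param geom a `cru_geometry`, or a precomputed neighbour list.
#' @return updated logical vector.
#' @export
step_ryr <- function(open, c_ds, c_jsr, dt, params, geom) {
  stopifnot(dt > 0, length(c_ds) == length(open),
            length(c_jsr) == length(open))
  pmax_rate <- max(params$kplus_max, params$kminus) *
    exp(4 * abs(params$ej))
  if (dt * pmax_rate > 0.1) {
    stop_arg(sprintf(
      "dt = %g ms violates the gating guard (worst-case p = %.3g > 0.1); use dt <= %.3g",
      dt, dt * pmax_rate, 0.1 / pmax_rate))
  }
  nbrs <- if (is.list(geom) && !inherits(geom, "cru_geometry")) geom
          else ryr_neighbor_list(geom)
  n <- length(open)
  if (n == 0L) return(open)
  k_r <- activation_threshold(c_jsr, params)
  kp <- opening_rate(c_ds, k_r, params)
  p <- numeric(n)
  for (i in seq_len(n)) {
    dir <- if (open[i]) "closing" else "opening"
    net <- count_num_net(i, open, nbrs, dir)
    rate <- if (open[i]) params$kminus else kp[i]
    p[i] <- dt * rate * coupling_factor(net, params)
  }
  u <- runif(n)
  xor(open, u < p)
}
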