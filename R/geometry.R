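# CRU geometries: lattice arrangements of RyR2 and IP3R2 channels.
#
# A geometry is a grid of 30 x 30 nm sites, each empty or holding exactly
# one channel. Control CRUs are checkerboards (no two RyR2s share an edge,
# as seen in healthy ventricular myocytes); heart-failure-like CRUs are
# fragmented into several smaller, dispersed clusters; IP3R2s are
# interspersed at random free sites among the RyR2s.

CRU_PITCH_NM <- 30

new_cru_geometry <- function(nx, ny, sites, pitch_nm = CRU_PITCH_NM) {
  stopifnot(nx >= 1, ny >= 1)
  sites <- data.frame(kind = as.character(sites$kind),
                      ix = as.integer(sites$ix), iy = as.integer(sites$iy),
                      stringsAsFactors = FALSE)
  g <- structure(list(nx = as.integer(nx), ny = as.integer(ny),
                      pitch_nm = pitch_nm, sites = sites),
                 class = "cru_geometry")
  validate_geometry(g)
}

#' @export
print.cru_geometry <- function(x, ...) {
  s <- compute_stats(x)
  cat(sprintf("<cru_geometry> %d x %d sites (pitch %g nm): %d RyR2, %d IP3R2\n",
              x$nx, x$ny, x$pitch_nm, s$n_ryr, s$n_ip3r))
  invisible(x)
}

validate_geometry <- function(g) {
  s <- g$sites
  if (nrow(s)) {
    if (!all(s$kind %in% c("RYR", "IP3R"))) {
      stop_arg("geometry contains unknown channel kind")
    }
    if (any(s$ix < 1L | s$ix > g$nx | s$iy < 1L | s$iy > g$ny)) {
      stop_arg("geometry has sites outside the grid")
    }
    if (anyDuplicated(s[c("ix", "iy")])) {
      stop_arg("geometry has two channels on one lattice cell")
    }
  }
  g
}

ryr_sites <- function(g) g$sites[g$sites$kind == "RYR", , drop = FALSE]
ip3r_sites <- function(g) g$sites[g$sites$kind == "IP3R", , drop = FALSE]

#' Checkerboard control CRU geometry
#'
#' Places `n_ryr` RyR2s on alternating cells of a centred square block so
#' that no two RyR2s share a lattice edge (nearest neighbours sit on the
#' 42.4-nm diagonal), the arrangement typical of healthy ventricular
#' myocytes. The grid is the occupied block plus `margin` empty border
#' sites on every side, which gives released Ca2+ room to diffuse to the
#' open (bulk cytosol) boundary.
#'
#' @param n_ryr number of RyR2 channels (>= 0).
#' @param margin empty border width in sites.
#' @param seed unused; accepted so all constructors share one signature
#'   (the checkerboard is deterministic).
#' @return a `cru_geometry`.
#' @export
#' @examples
#' g <- make_checkerboard(50)
#' compute_stats(g)$n_ryr
make_checkerboard <- function(n_ryr = 50, margin = 10, seed = NULL) {
  n_ryr <- check_count(n_ryr, "n_ryr")
  margin <- check_count(margin, "margin")
  if (n_ryr == 0L) {
    side <- max(1L, 2L * margin)
    return(new_cru_geometry(side, side,
                            data.frame(kind = character(), ix = integer(),
                                       iy = integer())))
  }
  # smallest k x k block whose checkerboard holds n_ryr channels
  k <- 1L
  while (ceiling(k^2 / 2) < n_ryr) k <- k + 1L
  cells <- expand.grid(ix = seq_len(k), iy = seq_len(k))
  cells <- cells[(cells$ix + cells$iy) %% 2L == 0L, ]
  cells <- cells[order(cells$iy, cells$ix), ][seq_len(n_ryr), ]
  sites <- data.frame(kind = "RYR",
                      ix = cells$ix + margin, iy = cells$iy + margin)
  new_cru_geometry(k + 2L * margin, k + 2L * margin, sites)
}

#' Fragmented heart-failure-like CRU geometry
#'
#' Emulates the fragmentation and dispersion of RyR2 clusters seen in
#' failing myocytes by super-resolution imaging: `n_ryr` channels are
#' split over `n_clusters` compact 4-connected blobs grown from seed
#' points whose spacing is controlled by `spread`. Clusters keep a minimum
#' exclusion gap of `min_gap` sites so they remain distinct under the
#' default cluster linking radius of [compute_stats()].
#'
#' @param n_ryr total RyR2 count (>= n_clusters).
#' @param n_clusters number of clusters (>= 1).
#' @param spread target centre-to-centre cluster spacing in nm.
#' @param seed integer seed; a fixed seed is bit-reproducible.
#' @param margin empty border width in sites.
#' @param min_gap minimum gap between sites of different clusters, in
#'   sites (default 4 sites = 120 nm).
#' @param max_retries placement restarts before a capacity error.
#' @return a `cru_geometry`.
#' @export
#' @examples
#' g <- make_fragmented(50, 5, seed = 1)
#' compute_stats(g)$n_clusters
make_fragmented <- function(n_ryr, n_clusters, spread = 250, seed = NULL,
                            margin = 10, min_gap = 4, max_retries = 200) {
  n_ryr <- check_count(n_ryr, "n_ryr")
  n_clusters <- check_count(n_clusters, "n_clusters", min = 1L)
  if (n_ryr < n_clusters) stop_arg("`n_ryr` must be >= `n_clusters`")
  spread_sites <- max(1, spread / CRU_PITCH_NM)

  quota <- rep(n_ryr %/% n_clusters, n_clusters)
  extra <- n_ryr %% n_clusters
  if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L

  grow_all <- function() {
    # cluster seed points: sequential placement, each a distance ~spread
    # from a previously placed centre, all pairs >= 0.8 * spread apart
    centers <- matrix(0, n_clusters, 2)
    if (n_clusters > 1) {
      for (k in 2:n_clusters) {
        for (att in seq_len(50)) {
          ref <- centers[sample.int(k - 1L, 1L), ]
          ang <- runif(1, 0, 2 * pi)
          rad <- spread_sites * runif(1, 0.9, 1.3)
          cand <- round(ref + rad * c(cos(ang), sin(ang)))
          d <- sqrt(rowSums((centers[seq_len(k - 1L), , drop = FALSE] -
                               matrix(cand, k - 1L, 2, byrow = TRUE))^2))
          if (all(d >= 0.8 * spread_sites)) break
          cand <- NULL
        }
        if (is.null(cand)) return(NULL)
        centers[k, ] <- cand
      }
    }
    occupied <- list()   # per-cluster matrices of cells
    for (k in seq_len(n_clusters)) {
      blob <- matrix(centers[k, ], 1, 2)
      while (nrow(blob) < quota[k]) {
        # candidate free 4-neighbours of the blob, outside other clusters'
        # exclusion zone
        nb <- unique(rbind(
          cbind(blob[, 1] + 1L, blob[, 2]), cbind(blob[, 1] - 1L, blob[, 2]),
          cbind(blob[, 1], blob[, 2] + 1L), cbind(blob[, 1], blob[, 2] - 1L)))
        key <- paste(nb[, 1], nb[, 2])
        nb <- nb[!key %in% paste(blob[, 1], blob[, 2]), , drop = FALSE]
        if (length(occupied)) {
          other <- do.call(rbind, occupied)
          keep <- vapply(seq_len(nrow(nb)), function(i) {
            min(sqrt((other[, 1] - nb[i, 1])^2 +
                       (other[, 2] - nb[i, 2])^2)) >= min_gap
          }, logical(1))
          nb <- nb[keep, , drop = FALSE]
        }
        if (!nrow(nb)) return(NULL)
        blob <- rbind(blob, nb[sample.int(nrow(nb), 1L), ])
      }
      occupied[[k]] <- blob
    }
    do.call(rbind, occupied)
  }

  cells <- with_seed(seed, {
    out <- NULL
    for (try in seq_len(max_retries)) {
      out <- grow_all()
      if (!is.null(out)) break
    }
    out
  })
  if (is.null(cells)) {
    stop_arg("could not pack the requested clusters (capacity error); ",
             "increase `spread` or reduce `n_clusters`")
  }
  cells[, 1] <- cells[, 1] - min(cells[, 1]) + 1L + margin
  cells[, 2] <- cells[, 2] - min(cells[, 2]) + 1L + margin
  sites <- data.frame(kind = "RYR", ix = cells[, 1], iy = cells[, 2])
  new_cru_geometry(max(cells[, 1]) + margin, max(cells[, 2]) + margin, sites)
}

#' Intersperse IP3R2s among the RyR2s of a CRU
#'
#' Adds `n_ip3r` IP3R2s drawn uniformly without replacement from the
#' unoccupied sites inside the bounding box of the existing RyR2s expanded
#' by one site ("within the CRU"). Existing channels are never displaced.
#'
#' @param geom a `cru_geometry` with at least one RyR2 (unless
#'   `n_ip3r = 0`).
#' @param n_ip3r number of IP3R2s to add.
#' @param seed integer seed; fixed seed gives a fixed placement.
#' @return a new `cru_geometry`.
#' @export
#' @examples
#' g <- place_ip3rs(make_checkerboard(50), 5, seed = 42)
#' compute_stats(g)$n_ip3r
place_ip3rs <- function(geom, n_ip3r, seed = NULL) {
  stopifnot(inherits(geom, "cru_geometry"))
  n_ip3r <- check_count(n_ip3r, "n_ip3r")
  if (n_ip3r == 0L) return(geom)
  ry <- ryr_sites(geom)
  if (!nrow(ry)) stop_arg("geometry has no RyR2s to intersperse among")
  x0 <- max(1L, min(ry$ix) - 1L); x1 <- min(geom$nx, max(ry$ix) + 1L)
  y0 <- max(1L, min(ry$iy) - 1L); y1 <- min(geom$ny, max(ry$iy) + 1L)
  box <- expand.grid(ix = x0:x1, iy = y0:y1)
  occ <- paste(geom$sites$ix, geom$sites$iy)
  free <- box[!paste(box$ix, box$iy) %in% occ, , drop = FALSE]
  if (nrow(free) < n_ip3r) {
    stop_arg(sprintf(
      "capacity error: %d free sites in the CRU region, %d IP3R2s requested",
      nrow(free), n_ip3r))
  }
  pick <- with_seed(seed, free[sample.int(nrow(free), n_ip3r), , drop = FALSE])
  sites <- rbind(geom$sites,
                 data.frame(kind = "IP3R", ix = pick$ix, iy = pick$iy))
  new_cru_geometry(geom$nx, geom$ny, sites, geom$pitch_nm)
}

#' Geometry summary statistics
#'
#' Clusters are connected components of the RyR2 sites under
#' centre-to-centre distance `link_radius`. Reported are channel counts,
#' cluster count, mean RyR2s per cluster, the mean nearest-neighbour
#' distance between RyR2 channels (nm) and between cluster centroids (nm,
#' `NA` when fewer than two clusters).
#'
#' @param geom a `cru_geometry`.
#' @param link_radius cluster linking distance in nm (default 100 nm, a
#'   common edge criterion for RyR2 cluster definitions).
#' @return list with `n_ryr`, `n_ip3r`, `n_clusters`,
#'   `mean_ryr_per_cluster`, `mean_nn_distance` (channel level, nm),
#'   `mean_cluster_nn_distance` (nm), `cluster_id` (per RyR2 site).
#' @export
compute_stats <- function(geom, link_radius = 100) {
  stopifnot(inherits(geom, "cru_geometry"))
  ry <- ryr_sites(geom)
  n <- nrow(ry)
  out <- list(n_ryr = n, n_ip3r = nrow(ip3r_sites(geom)),
              n_clusters = 0L, mean_ryr_per_cluster = NA_real_,
              mean_nn_distance = NA_real_,
              mean_cluster_nn_distance = NA_real_, cluster_id = integer())
  if (n == 0L) return(out)
  xy <- cbind(ry$ix, ry$iy) * geom$pitch_nm
  d <- as.matrix(stats::dist(xy))
  # union-find over pairs within link_radius
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (d[i, j] <= link_radius) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  cl <- match(roots, unique(roots))
  out$cluster_id <- cl
  out$n_clusters <- length(unique(cl))
  out$mean_ryr_per_cluster <- n / out$n_clusters
  if (n > 1) {
    diag(d) <- Inf
    out$mean_nn_distance <- mean(apply(d, 1, min))
  }
  if (out$n_clusters > 1) {
    cent <- t(vapply(seq_len(out$n_clusters), function(k) {
      colMeans(xy[cl == k, , drop = FALSE])
    }, numeric(2)))
    dc <- as.matrix(stats::dist(cent)); diag(dc) <- Inf
    out$mean_cluster_nn_distance <- mean(apply(dc, 1, min))
  }
  out
}

#' Preset geometries for the control / heart-failure comparison
#'
#' `"ctrl"` is a 50-RyR2 checkerboard (single compact cluster); `"hf"` is
#' a fragmented arrangement of 50 RyR2s over 5 dispersed clusters,
#' emulating the fewer-channels-per-cluster, shorter-distance statistics
#' reported for failing myocytes.
#'
#' @param name `"ctrl"` or `"hf"`.
#' @param seed seed for the stochastic HF generator.
#' @param n_ryr total RyR2 count.
#' @return a `cru_geometry`.
#' @export
geometry_preset <- function(name = c("ctrl", "hf"), seed = 1, n_ryr = 50) {
  name <- match.arg(name)
  switch(name,
         ctrl = make_checkerboard(n_ryr),
         hf   = make_fragmented(n_ryr, n_clusters = 5, spread = 250,
                                seed = seed))
}

#' Write / read a CRU geometry as CSV
#'
#' Plain-text interchange format: comment lines starting with `#` carry
#' pitch and grid-size metadata, then a `kind,ix,iy` table with 1-based
#' integer lattice indices and kind `RYR` or `IP3R`. `read_geometry()` of
#' a written file reproduces the geometry exactly.
#'
#' @param geom a `cru_geometry`.
#' @param path file path.
#' @return `read_geometry()` returns a `cru_geometry`;
#'   `write_geometry()` returns `path` invisibly.
#' @export
write_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "cru_geometry"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# cruspark geometry v1",
               sprintf("# pitch_nm: %g", geom$pitch_nm),
               sprintf("# nx: %d", geom$nx),
               sprintf("# ny: %d", geom$ny),
               "kind,ix,iy"), con)
  if (nrow(geom$sites)) {
    writeLines(sprintf("%s,%d,%d", geom$sites$kind, geom$sites$ix,
                       geom$sites$iy), con)
  }
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) stop_arg(sprintf("geometry file not found: %s", path))
  lines <- readLines(path)
  meta_val <- function(key, default) {
    hit <- grep(sprintf("^#\\s*%s:", key), lines, value = TRUE)
    if (!length(hit)) return(default)
    as.numeric(sub(sprintf("^#\\s*%s:\\s*", key), "", hit[1]))
  }
  body_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(body_idx) ||
      !identical(trimws(lines[body_idx[1]]), "kind,ix,iy")) {
    stop_arg("geometry file must have header line `kind,ix,iy`")
  }
  hdr_line <- body_idx[1]
  rows <- body_idx[-1]
  sites <- data.frame(kind = character(), ix = integer(), iy = integer())
  if (length(rows)) {
    parts <- strsplit(trimws(lines[rows]), ",")
    bad <- which(lengths(parts) != 3L)
    if (length(bad)) {
      stop_arg(sprintf("geometry file row %d (line %d): expected 3 fields",
                       bad[1], rows[bad[1]]))
    }
    m <- do.call(rbind, parts)
    ix <- suppressWarnings(as.integer(m[, 2]))
    iy <- suppressWarnings(as.integer(m[, 3]))
    kind <- trimws(m[, 1])
    for (r in seq_along(rows)) {
      if (!kind[r] %in% c("RYR", "IP3R")) {
        stop_arg(sprintf("geometry file row %d (line %d): unknown kind \"%s\"",
                         r, rows[r], kind[r]))
      }
      if (is.na(ix[r]) || is.na(iy[r])) {
        stop_arg(sprintf("geometry file row %d (line %d): non-integer index",
                         r, rows[r]))
      }
    }
    sites <- data.frame(kind = kind, ix = ix, iy = iy)
  }
  nx <- meta_val("nx", if (nrow(sites)) max(sites$ix) + 10 else 20)
  ny <- meta_val("ny", if (nrow(sites)) max(sites$iy) + 10 else 20)
  pitch <- meta_val("pitch_nm", CRU_PITCH_NM)
  if (nrow(sites)) {
    if (any(sites$ix < 1 | sites$ix > nx | sites$iy < 1 | sites$iy > ny)) {
      r <- which(sites$ix < 1 | sites$ix > nx |
                   sites$iy < 1 | sites$iy > ny)[1]
      stop_arg(sprintf("geometry file row %d: index outside %d x %d grid",
                       r, nx, ny))
    }
    dup <- which(duplicated(sites[c("ix", "iy")]))
    if (length(dup)) {
      stop_arg(sprintf("geometry file row %d: duplicate cell (%d,%d)",
                       dup[1], sites$ix[dup[1]], sites$iy[dup[1]]))
    }
  }
  new_cru_geometry(nx, ny, sites, pitch)
}
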