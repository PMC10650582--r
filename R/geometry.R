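#' @section Phantom geometry:
#' Randomized layered label maps emulate the variety of anatomical
#' structures: inside a random ellipsoidal foreground, geometric primitives
#' (ellipses, axis-aligned rectangles, random convex polygons) are stamped
#' iteratively, later shapes overwriting earlier ones; a morphological
#' closing and small-object removal smooth the outlines.
#' @name phantom-geometry
NULL

# --- binary morphology on logical matrices ------------------------------

shift_mat <- function(m, di, dj) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  si <- max(1, 1 + di):min(H, H + di)
  sj <- max(1, 1 + dj):min(W, W + dj)
  out[si, sj] <- m[si - di, sj - dj]
  out
}

disk_offsets <- function(r) {
  g <- expand.grid(di = -r:r, dj = -r:r)
  g[g$di^2 + g$dj^2 <= r^2, , drop = FALSE]
}

binary_dilate <- function(m, r = 2) {
  off <- disk_offsets(r)
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (k in seq_len(nrow(off)))
    out <- out | shift_mat(m, off$di[k], off$dj[k])
  out
}

binary_erode <- function(m, r = 2) !binary_dilate(!m, r)

binary_close <- function(m, r = 2) binary_erode(binary_dilate(m, r), r)

# --- primitive rasterizers (logical H x W) ------------------------------

raster_ellipse <- function(H, W, ci, cj, a, b, theta) {
  i <- matrix(seq_len(H), H, W) - ci
  j <- matrix(seq_len(W), H, W, byrow = TRUE) - cj
  u <- i * cos(theta) + j * sin(theta)
  v <- -i * sin(theta) + j * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

raster_rect <- function(H, W, ci, cj, hh, hw) {
  i <- matrix(seq_len(H), H, W)
  j <- matrix(seq_len(W), H, W, byrow = TRUE)
  abs(i - ci) <= hh & abs(j - cj) <= hw
}

raster_convex_polygon <- function(H, W, ci, cj, radius, n_vertices) {
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  rad <- stats::runif(n_vertices, 0.5, 1) * radius
  vi <- ci + rad * cos(ang)
  vj <- cj + rad * sin(ang)
  i <- matrix(seq_len(H), H, W)
  j <- matrix(seq_len(W), H, W, byrow = TRUE)
  inside <- matrix(TRUE, H, W)
  for (k in seq_len(n_vertices)) {
    k2 <- if (k == n_vertices) 1L else k + 1L
    # vertices are in CCW angular order: keep the left side of each edge
    cross <- (vi[k2] - vi[k]) * (j - vj[k]) - (vj[k2] - vj[k]) * (i - vi[k])
    inside <- inside & cross >= 0
  }
  inside
}

# --- label map sampling -------------------------------------------------

#' Sample a randomized layered label map
#'
#' Builds a 2D digital phantom geometry: an ellipsoidal foreground (region
#' label 1) into which `n_layers` random primitives are stamped, each
#' receiving a fresh label and overwriting whatever it covers (painter's
#' algorithm). Outlines are then smoothed by a binary closing (disk radius
#' 2) applied per label in stamping order, and connected components
#' smaller than 16 px are absorbed into the base region. Labels are
#' finally renumbered compactly `1..K`.
#'
#' @param rng_seed integer seed; identical seeds give bit-identical maps.
#' @param grid `c(H, W)` image size, both at least 16.
#' @param n_layers number of primitives stamped (the full-scale phantom
#'   generator uses 2000).
#' @return an object of class `cest_label_map`: a list with integer matrix
#'   `labels` (0 = background) and logical matrix `foreground`.
#' @examples
#' lm <- sample_label_map(1, grid = c(64, 64), n_layers = 40)
#' table(lm$labels[lm$foreground])
#' @export
sample_label_map <- function(rng_seed, grid = c(128L, 128L),
                             n_layers = 2000L) {
  H <- grid[1]; W <- grid[2]
  if (H < 16 || W < 16)
    stop("grid must be at least 16 x 16 to contain the minimum primitive")
  stopifnot(n_layers >= 1)
  with_seed(rng_seed, {
    theta <- stats::runif(1, 0, pi)
    fg <- raster_ellipse(H, W,
                         ci = H / 2 + stats::runif(1, -0.04, 0.04) * H,
                         cj = W / 2 + stats::runif(1, -0.04, 0.04) * W,
                         a = stats::runif(1, 0.65, 0.9) * H / 2,
                         b = stats::runif(1, 0.65, 0.9) * W / 2,
                         theta = theta)
    labels <- matrix(0L, H, W)
    labels[fg] <- 1L
    fg_idx <- which(fg)
    nxt <- 2L
    for (l in seq_len(n_layers)) {
      type <- sample(c("ellipse", "rect", "poly"), 1)
      s <- stats::runif(1, 4, H / 3)
      ctr <- fg_idx[sample.int(length(fg_idx), 1)]
      ci <- (ctr - 1) %% H + 1
      cj <- (ctr - 1) %/% H + 1
      prim <- switch(type,
        ellipse = raster_ellipse(H, W, ci, cj, a = s / 2,
                                 b = stats::runif(1, 0.4, 1) * s / 2,
                                 theta = stats::runif(1, 0, pi)),
        rect = raster_rect(H, W, ci, cj, hh = s / 2,
                           hw = stats::runif(1, 0.4, 1) * s / 2),
        poly = raster_convex_polygon(H, W, ci, cj, radius = s / 2,
                                     n_vertices = sample(3:6, 1)))
      prim <- prim & fg
      if (any(prim)) {
        labels[prim] <- nxt
        nxt <- nxt + 1L
      }
    }
    # morphological smoothing, painter order
    for (l in sort(unique(labels[labels > 1L]))) {
      cl <- binary_close(labels == l, r = 2) & fg
      labels[cl] <- l
    }
    # absorb sub-16-px fragments into the base region
    for (l in sort(unique(labels[labels > 1L]))) {
      comp <- cpp_label_components(labels == l)
      sizes <- tabulate(comp[comp > 0])
      small <- which(sizes < 16)
      if (length(small)) labels[comp %in% small] <- 1L
    }
    keep <- sort(unique(labels[labels > 0L]))
    relab <- integer(max(keep))
    relab[keep] <- seq_along(keep)
    labels[labels > 0L] <- relab[labels[labels > 0L]]
    structure(list(labels = labels, foreground = fg),
              class = "cest_label_map")
  })
}

#' @export
print.cest_label_map <- function(x, ...) {
  cat(sprintf("label map: %d x %d, %d regions, %d foreground px\n",
              nrow(x$labels), ncol(x$labels), max(x$labels), sum(x$foreground)))
  invisible(x)
}

#' Wrap a user-supplied integer label map
#'
#' Accepts any integer matrix (for example an anatomical tissue-class
#' slice) as phantom geometry; nonzero labels become regions.
#'
#' @param labels integer matrix, 0 = background.
#' @return a `cest_label_map`.
#' @export
as_label_map <- function(labels) {
  stopifnot(is.matrix(labels), all(labels >= 0))
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  structure(list(labels = labels, foreground = labels > 0L),
            class = "cest_label_map")
}

#' Assign pool parameters to every label region
#'
#' Each region of the label map receives one uniform draw of a 2--5 pool
#' system from the stated parameter ranges: the water pool (present on the
#' whole foreground) plus 1--4 metabolite pools. Regions are internally
#' homogeneous (one draw per region, not per voxel).
#'
#' @param label_map a `cest_label_map` from [sample_label_map()] or
#'   [as_label_map()].
#' @param ranges parameter intervals, see [protocol_ranges()].
#' @param rng_seed integer seed.
#' @return an object of class `cest_phantom`: list with `label_map`,
#'   `regions` (per-region list of [pool_params()]), `n_pools` (integer
#'   grid) and `pool_maps` (per pool, per field `H x W` grids, `NA` where
#'   a pool is absent).
#' @export
sample_pool_maps <- function(label_map, ranges = protocol_ranges(), rng_seed) {
  stopifnot(inherits(label_map, "cest_label_map"))
  labs <- label_map$labels
  if (!any(labs > 0L)) stop("label map has an empty foreground")
  region_ids <- sort(unique(labs[labs > 0L]))
  with_seed(rng_seed, {
    regions <- lapply(region_ids, function(id) {
      n_pools <- sample(2:5, 1)
      pools <- c(list(sample_water_pool(ranges)),
                 replicate(n_pools - 1, sample_metabolite_pool(ranges),
                           simplify = FALSE))
      list(id = id, n_pools = n_pools, pools = pools)
    })
    build_phantom(label_map, regions)
  })
}

#' Assemble a phantom from explicit per-region pool systems
#'
#' Lower-level companion of [sample_pool_maps()] for fully specified
#' (non-random) phantoms, e.g. concentration-ladder fixtures.
#'
#' @param label_map a `cest_label_map`.
#' @param regions list of `list(id =, pools = list(<pool_params>, ...))`,
#'   water pool first in each `pools` list.
#' @return a `cest_phantom`.
#' @export
build_phantom <- function(label_map, regions) {
  labs <- label_map$labels
  H <- nrow(labs); W <- ncol(labs)
  fields <- c("t1_s", "t2_ms", "delta_ppm", "k_hz", "conc_mM")
  max_pools <- max(vapply(regions, function(r) length(r$pools), 1L))
  pool_maps <- lapply(seq_len(max_pools), function(p)
    stats::setNames(lapply(fields, function(f) matrix(NA_real_, H, W)), fields))
  n_pools <- matrix(0L, H, W)
  for (r in regions) {
    r$n_pools <- r$n_pools %||% length(r$pools)
    idx <- labs == r$id
    n_pools[idx] <- length(r$pools)
    for (p in seq_along(r$pools))
      for (f in fields)
        pool_maps[[p]][[f]][idx] <- r$pools[[p]][[f]]
  }
  structure(list(label_map = label_map, regions = regions,
                 n_pools = n_pools, pool_maps = pool_maps),
            class = "cest_phantom")
}

#' @export
print.cest_phantom <- function(x, ...) {
  cat(sprintf("CEST phantom: %d regions, pool systems of size %s\n",
              length(x$regions),
              paste(sort(unique(vapply(x$regions, function(r) length(r$pools), 1L))),
                    collapse = "/")))
  invisible(x)
}
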