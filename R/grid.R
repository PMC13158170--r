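#' Voxel grid
#'
#' Regular axis-aligned voxel grid.  Voxel (i, j, k) (1-based array
#' indices) has its center at \code{origin + (c(i,j,k) - 0.5) * spacing};
#' masks are stored as logical arrays over this grid.
#'
#' @param shape integer vector of length 3, each >= 8.
#' @param spacing voxel size in mm, scalar (isotropic) or length 3.
#' @param origin grid corner in mm, length 3.
#' @return object of class \code{voxel_grid}.
#' @export
voxel_grid <- function(shape, spacing = 1, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(length(shape) == 3, length(origin) == 3, length(spacing) == 3)
  if (any(shape < 8L)) stop("voxel grid shape must be at least 8 along every axis")
  if (any(spacing <= 0)) stop("voxel spacing must be positive")
  structure(list(shape = shape, spacing = as.double(spacing),
                 origin = as.double(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel grid %d x %d x %d, spacing %s mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(signif(x$spacing, 4), collapse = " x ")))
  invisible(x)
}

#' Voxel volume in mm^3
#' @param grid a \code{voxel_grid}.
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

# Voxel-center coordinate (mm) of linear voxel indices.
voxel_centers <- function(grid, idx) {
  a <- arrayInd(idx, grid$shape)
  sweep(sweep(a - 0.5, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

# Linear voxel index containing each point (N x 3, mm); NA outside grid.
point_voxel <- function(grid, pts) {
  ijk <- floor(sweep(sweep(pts, 2, grid$origin, "-"), 2, grid$spacing, "/")) + 1
  bad <- ijk < 1 | sweep(ijk, 2, grid$shape, ">")
  idx <- (ijk[, 3] - 1) * grid$shape[1] * grid$shape[2] +
    (ijk[, 2] - 1) * grid$shape[1] + ijk[, 1]
  idx[rowSums(bad) > 0] <- NA_integer_
  as.integer(idx)
}

#' Euclidean distance transform of a mask
#'
#' Distance in mm from every voxel center to the nearest voxel of the
#' mask (0 inside the mask, +Inf if the mask is empty).
#'
#' @param grid a \code{voxel_grid}.
#' @param mask logical array with \code{grid$shape} dims.
#' @return numeric array of distances (mm).
#' @export
mask_distance <- function(grid, mask) {
  stopifnot(identical(dim(mask), grid$shape))
  edt_cpp(as.logical(mask), grid$shape, grid$spacing)
}

# Boundary voxels of a mask: mask voxels with at least one 6-neighbour
# outside the mask (or on the array edge).
mask_boundary <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  shift_ok <- function(ax, by) {
    out <- array(FALSE, d)
    n <- d[ax]
    src <- seq_len(n) + by
    keep <- src >= 1 & src <= n
    idx_to <- which(keep); idx_from <- src[keep]
    if (ax == 1) out[idx_to, , ] <- mask[idx_from, , ]
    if (ax == 2) out[, idx_to, ] <- mask[, idx_from, ]
    if (ax == 3) out[, , idx_to] <- mask[, , idx_from]
    out
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) interior <- interior & shift_ok(ax, by)
  mask & !interior
}

# Uniform jitter of voxel centers within their voxel.
jitter_in_voxel <- function(grid, idx) {
  ctr <- voxel_centers(grid, idx)
  n <- length(idx)
  ctr + cbind(runif(n, -0.5, 0.5) * grid$spacing[1],
              runif(n, -0.5, 0.5) * grid$spacing[2],
              runif(n, -0.5, 0.5) * grid$spacing[3])
}
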