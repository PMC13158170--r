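#' First-pass low-dose volume
#'
#' Geometric expansion of the target(s): the band of tissue between an
#' inner and an outer margin beyond each target surface, scaled to the
#' target's effective radius, chosen to encompass approximately the
#' region where the dose is expected to be near the low-dose threshold.
#' Excludes the targets and OARs; clipped to the skull.  Identical for
#' every weight vector.
#'
#' @param case a \code{gk_case}.
#' @param margins inner and outer margins as fractions of the effective
#'   radius (default c(0.2, 0.6)).
#' @return list: \code{mask} (logical array), \code{measure} (mm^3),
#'   \code{pass = "first"}.
#' @export
first_pass_ld_volume <- function(case, margins = c(0.2, 0.6)) {
  if (margins[1] >= margins[2]) stop("inverted low-dose margins: inner >= outer")
  grid <- case$grid
  band <- array(FALSE, grid$shape)
  for (k in seq_along(case$targets)) {
    r_eff <- effective_radius(grid, case$targets[[k]])
    d <- mask_distance(grid, case$targets[[k]])
    band <- band | (d > margins[1] * r_eff & d <= margins[2] * r_eff)
  }
  outside <- band & !case$skull
  if (any(outside))
    warning("low-dose expansion exits the skull; clipped")
  band <- band & case$skull & !target_union(case) & !oar_union(case)
  list(mask = band, measure = sum(band) * voxel_volume(grid), pass = "first")
}

# voxel region on which doses are reconstructed: skull voxels within a
# radius-scaled margin of the targets (covers the low-dose band and the
# half-prescription isodose used by the gradient index)
dose_region <- function(case, margin = NULL) {
  grid <- case$grid
  if (is.null(margin)) {
    r_max <- max(vapply(case$targets, function(m) effective_radius(grid, m), 0))
    margin <- max(12, 1.4 * r_max)
  }
  d <- mask_distance(grid, target_union(case))
  which(d <= margin & case$skull)
}

#' Second-pass low-dose volumes
#'
#' One volume per weight vector: the voxels (outside the targets) whose
#' first-pass dose lies in the band [d_ld, d_ld + delta).  An instance
#' whose band is empty falls back to the first-pass geometric volume.
#'
#' @param case a \code{gk_case}.
#' @param dose matrix of first-pass doses (region voxels x K).
#' @param region_idx voxel indices the dose rows refer to.
#' @param delta band width in Gy (default 0.15 * d_ld).
#' @return list of K integer voxel-index vectors.
#' @export
second_pass_ld_volumes <- function(case, dose, region_idx, delta = NULL) {
  if (is.null(delta)) delta <- 0.15 * case$d_ld
  stopifnot(delta > 0, nrow(dose) == length(region_idx))
  tu <- target_union(case)
  ok <- !tu[region_idx]
  out <- vector("list", ncol(dose))
  fb <- NULL
  for (j in seq_len(ncol(dose))) {
    inband <- ok & dose[, j] >= case$d_ld & dose[, j] < case$d_ld + delta
    v <- region_idx[inband]
    if (length(v) == 0) {
      warning("instance ", j, ": empty second-pass low-dose band; ",
              "falling back to the first-pass volume")
      if (is.null(fb)) fb <- which(first_pass_ld_volume(case)$mask)
      v <- fb
    }
    out[[j]] <- v
  }
  out
}

#' Non-redundant sampling of overlapping low-dose volumes
#'
#' Samples the per-instance low-dose point sets so that overlapping
#' volumes share points: volumes are visited in order of non-increasing
#' target density; at each step the running point union is thinned to
#' the current density, thinned points falling inside the current volume
#' are reused, and only the volume's not-yet-covered part receives fresh
#' points.  Every instance keeps (in expectation) its desired density
#' while the union of all points stays minimal.
#'
#' @param volumes list of voxel-index vectors (one per instance).
#' @param n_points desired point count per volume.
#' @param grid the \code{voxel_grid}.
#' @param seed integer seed.
#' @return object of class \code{sampling_plan}: \code{points} (matrix,
#'   the union P), \code{voxel}, \code{member} (list of logical vectors
#'   over P, in the original instance order), \code{omega},
#'   \code{order}, \code{n_desired}, \code{n_realized}.
#' @export
overlap_sample <- function(volumes, n_points, grid, seed = 1) {
  m <- length(volumes)
  stopifnot(length(n_points) == m, m >= 1)
  vv <- voxel_volume(grid)
  sizes <- vapply(volumes, length, 0L) * vv        # |V_j| in mm^3
  if (any(sizes == 0)) stop("empty low-dose volume")
  omega <- n_points / sizes                        # points per mm^3
  if (any(omega * vv > 8))
    stop("requested sampling density exceeds the voxel resolution")
  ord <- order(-omega)                             # stable in ties

  set.seed(derive_seed(seed, "overlap_sample"))
  nvox <- prod(grid$shape)
  in_union <- logical(nvox)
  # master point table; p-union and p_j are index vectors into it
  pt_vox <- integer(0)
  p_union <- integer(0)
  members <- vector("list", m)

  for (j in ord) {
    vj <- volumes[[j]]
    in_vj <- logical(nvox)
    in_vj[vj] <- TRUE
    union_mm3 <- sum(in_union) * vv

    n_sel <- round(omega[j] * union_mm3)
    sel <- if (length(p_union) > 0 && n_sel > 0)
      p_union[sample.int(length(p_union), min(n_sel, length(p_union)))]
    else integer(0)
    p_in <- sel[in_vj[pt_vox[sel]]]

    new_vox <- vj[!in_union[vj]]
    n_out <- round(omega[j] * length(new_vox) * vv)
    p_out <- integer(0)
    if (n_out > 0 && length(new_vox) > 0) {
      take <- new_vox[sample.int(length(new_vox), n_out, replace = TRUE)]
      p_out <- length(pt_vox) + seq_along(take)
      pt_vox <- c(pt_vox, take)
    }

    members[[j]] <- c(p_in, p_out)
    p_union <- c(sel, p_out)
    in_union[vj] <- TRUE
  }

  keep <- sort(unique(unlist(members)))
  remap <- integer(length(pt_vox))
  remap[keep] <- seq_along(keep)
  member_log <- lapply(members, function(ids) {
    v <- logical(length(keep))
    v[remap[ids]] <- TRUE
    v
  })
  coords <- jitter_in_voxel(grid, pt_vox[keep])
  structure(list(points = coords, voxel = pt_vox[keep],
                 member = member_log, omega = omega, order = ord,
                 n_desired = n_points,
                 n_realized = vapply(members, length, 0L)),
            class = "sampling_plan")
}

#' Two-pass Pareto sweep of a planning case
#'
#' Full pipeline: first-pass points (shared, weight-independent low-dose
#' volume from geometric expansion), batched ADMM solve for every weight
#' vector, dose reconstruction near the targets, per-instance second-pass
#' low-dose volumes from the first-pass dose band, non-redundant overlap
#' sampling into one shared point union, second batched solve with
#' per-instance low-dose bounds, final doses and clinical metrics.
#'
#' @param case a \code{gk_case}.
#' @param sliders slider grid spec ("3x3", c(3, 3), or a
#'   \code{\link{slider_grid}} data frame).
#' @param n_iter iterations per pass (scalar or length 2; default 3000).
#' @param precision "single" or "double" (ADMM iterations only; the
#'   Schur inversions are always double).
#' @param seed run seed; per-stage seeds are derived from it.
#' @param delta second-pass dose-band width (Gy); default 0.15 * d_ld.
#' @param densities,caps dose-point sampling overrides.
#' @param trace_stride residual trace stride.
#' @return object of class \code{gk_sweep}: plans and fits per pass,
#'   LPs, doses over the evaluation region, the sampling plan, and a
#'   metrics data frame (one row per weight vector).
#' @export
run_two_pass <- function(case, sliders = "3x3", n_iter = 3000,
                         precision = c("single", "double"),
                         seed = case$seed, delta = NULL,
                         densities = NULL, caps = NULL, trace_stride = 10) {
  precision <- match.arg(precision)
  n_iter <- rep_len(n_iter, 2)
  grid_w <- if (is.data.frame(sliders)) sliders else slider_grid(sliders)
  K <- nrow(grid_w)

  # ---- pass 1: shared low-dose volume from geometric expansion
  pts1 <- sample_case_points(case, seed = derive_seed(seed, "pass1_pts"),
                             densities = densities, caps = caps)
  lp1 <- build_case_lp(case, pts1)
  fit1 <- solve_batch(lp1, grid_w, n_iter = n_iter[1], precision = precision,
                      trace_stride = trace_stride)
  plans1 <- recover_primal(fit1, lp1)

  region_idx <- dose_region(case)
  reg_coords <- voxel_centers(case$grid, region_idx)
  dose1 <- compute_dose(case, plans1, reg_coords)

  # ---- pass 2: per-instance dose-band volumes, shared point union
  vols2 <- second_pass_ld_volumes(case, dose1, region_idx, delta = delta)
  dens <- default_point_densities()
  if (!is.null(densities)) dens[names(densities)] <- densities
  cp <- default_point_caps()
  if (!is.null(caps)) cp[names(caps)] <- caps
  vv <- voxel_volume(case$grid)
  n_des <- vapply(vols2, function(v)
    min(max(round(dens[["low-dose"]] * length(v) * vv), cp[["low-dose"]][1]),
        cp[["low-dose"]][2]), 0)
  sp <- overlap_sample(vols2, n_des, case$grid,
                       seed = derive_seed(seed, "pass2_ld"))

  pts2 <- pts1
  pts2$ld <- structure(list(category = "low-dose", coords = sp$points,
                            voxel = sp$voxel, owner = rep(NA_integer_, nrow(sp$points)),
                            level = rep(case$d_ld, nrow(sp$points)),
                            n = nrow(sp$points)), class = "dose_points")
  lp2 <- build_case_lp(case, pts2)
  fit2 <- solve_batch(lp2, grid_w, n_iter = n_iter[2], precision = precision,
                      trace_stride = trace_stride, ld_members = sp$member)
  plans2 <- recover_primal(fit2, lp2)
  dose2 <- compute_dose(case, plans2, reg_coords)

  metrics <- plan_metrics(case, dose2, region_idx, plans2)
  metrics$s_ld <- grid_w$s_ld
  metrics$s_bot <- grid_w$s_bot
  metrics <- metrics[, c("s_ld", "s_bot", setdiff(names(metrics),
                                                  c("s_ld", "s_bot")))]

  structure(list(case_name = case$name, sliders = grid_w,
                 pts1 = pts1, lp1 = lp1, fit1 = fit1, plans1 = plans1,
                 dose1 = dose1, vols2 = vols2, sampling = sp,
                 pts2 = pts2, lp2 = lp2, fit2 = fit2, plans2 = plans2,
                 dose2 = dose2, region_idx = region_idx,
                 metrics = metrics, seed = seed, precision = precision,
                 n_iter = n_iter), class = "gk_sweep")
}

#' @export
print.gk_sweep <- function(x, ...) {
  cat(sprintf("gk_sweep '%s': %d weight vectors, two passes of %s iterations (%s precision)\n",
              x$case_name, nrow(x$sliders),
              paste(x$n_iter, collapse = "/"), x$precision))
  print(x$metrics, digits = 4)
  invisible(x)
}
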