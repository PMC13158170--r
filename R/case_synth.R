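#' Phantom specification
#'
#' Describes a synthetic planning case: spherical target(s) inside an
#' ellipsoidal skull, optional small spherical organs at risk (OARs)
#' placed 2-10 mm from a target surface, and per-structure dose levels.
#'
#' @param target_volumes_mm3 numeric vector of requested target volumes
#'   (mm^3); total must lie in [500, 55000].
#' @param n_oars number of OARs (>= 0).
#' @param d_presc prescription dose(s) in Gy, scalar or one per target.
#' @param d_oar_max maximum OAR dose(s) in Gy, scalar or one per OAR.
#' @param spacing isotropic voxel size in mm.
#' @param seed integer seed; the case is fully deterministic given
#'   (spec, seed).
#' @param name optional case label.
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(target_volumes_mm3, n_oars = 1, d_presc = 20,
                         d_oar_max = 10, spacing = 1, seed = 1,
                         name = "case") {
  stopifnot(all(target_volumes_mm3 > 0), n_oars >= 0, all(d_presc > 0),
            all(d_oar_max > 0), spacing > 0)
  nt <- length(target_volumes_mm3)
  if (nt < 1 || nt > 9) stop("between 1 and 9 targets are supported")
  tot <- sum(target_volumes_mm3)
  if (tot < 500 || tot > 55000)
    stop("total target volume must lie within 0.5-55 cm^3")
  d_presc <- rep_len(d_presc, nt)
  if (n_oars > 0) d_oar_max <- rep_len(d_oar_max, n_oars)
  radii <- (3 * target_volumes_mm3 / (4 * pi))^(1 / 3)
  if (any(radii < 2 * spacing))
    stop("target radii must be at least twice the voxel spacing")
  structure(list(target_volumes_mm3 = as.double(target_volumes_mm3),
                 radii = radii, n_oars = as.integer(n_oars),
                 d_presc = as.double(d_presc),
                 d_oar_max = if (n_oars > 0) as.double(d_oar_max) else double(0),
                 spacing = as.double(spacing), seed = as.integer(seed),
                 oar_radius = 4, name = name),
            class = "phantom_spec")
}

sphere_mask <- function(grid, center, radius, axes = c(1, 1, 1)) {
  cx <- (seq_len(grid$shape[1]) - 0.5) * grid$spacing[1] + grid$origin[1]
  cy <- (seq_len(grid$shape[2]) - 0.5) * grid$spacing[2] + grid$origin[2]
  cz <- (seq_len(grid$shape[3]) - 0.5) * grid$spacing[3] + grid$origin[3]
  dx2 <- ((cx - center[1]) / axes[1])^2
  dy2 <- ((cy - center[2]) / axes[2])^2
  dz2 <- ((cz - center[3]) / axes[3])^2
  q <- outer(outer(dx2, dy2, "+"), dz2, "+")
  array(q <= radius^2, grid$shape)
}

# Sector axis directions: 8 unit vectors tilted 65 degrees from the
# grid z axis at 45-degree azimuthal steps (a stand-in for the source
# sector geometry; only a fixed, distinct set of directions matters).
sector_directions <- function() {
  s <- 0:7
  th <- 65 * pi / 180
  ph <- (s * 45 + 22.5) * pi / 180
  cbind(cos(ph) * sin(th), sin(ph) * sin(th), rep(cos(th), 8))
}

#' Default synthetic kernel bank parameters
#'
#' Anisotropic Gaussian dose-rate kernels, one per (isocenter, sector,
#' collimator) triple.  Collimator Gaussian widths are half the nominal
#' 4/8/16 mm collimator sizes; peak amplitudes rise with collimator size
#' and are normalized so that all 24 sectors at the largest collimator
#' deliver the calibration dose rate (3 Gy/min) at the isocenter.
#'
#' @param rate_cal calibration dose rate in Gy/min.
#' @return list with fields \code{sigma}, \code{amp}, \code{dirs},
#'   \code{kappa}, \code{rate_cal}.
#' @export
kernel_bank <- function(rate_cal = 3) {
  list(sigma = c(2, 4, 8), amp = rate_cal / 24 * c(0.55, 0.8, 1.0),
       dirs = sector_directions(), kappa = 1 / 3, rate_cal = rate_cal)
}

#' Generate a synthetic planning case
#'
#' Builds the voxel phantom described by a \code{\link{phantom_spec}}:
#' skull, targets, OARs, Gaussian kernel bank, and isocenters placed by
#' \code{\link{place_isocenters}}.  Deterministic given the spec (which
#' includes the seed).
#'
#' @param spec a \code{phantom_spec}.
#' @param place_iso place isocenters immediately (default TRUE).
#' @return object of class \code{gk_case}.
#' @export
make_phantom <- function(spec, place_iso = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(derive_seed(spec$seed, "phantom"))
  nt <- length(spec$radii)
  r <- spec$radii
  h <- spec$spacing

  # target centers along x, separated so masks stay disjoint
  cx <- numeric(nt)
  for (k in seq_len(nt)[-1])
    cx[k] <- cx[k - 1] + r[k - 1] + r[k] + max(4, 0.4 * (r[k - 1] + r[k]))
  jit <- if (nt > 1) matrix(runif(2 * nt, -2, 2), nt) else matrix(0, 1, 2)
  centers <- cbind(cx, jit)

  pad <- max(18, 0.9 * max(r)) + spec$oar_radius
  lo <- apply(centers, 2, min) - max(r) - pad
  hi <- apply(centers, 2, max) + max(r) + pad
  shape <- pmax(ceiling((hi - lo) / h) + 2L, 8L)
  grid <- voxel_grid(shape, h, origin = lo - h)

  skull_c <- (lo + hi) / 2
  skull_semi <- (hi - lo) / 2 + spec$oar_radius / 2
  skull <- sphere_mask(grid, skull_c, 1, axes = skull_semi)

  targets <- vector("list", nt)
  for (k in seq_len(nt)) {
    # correct the radius for voxelization so the discrete volume matches;
    # volumes move in whole-voxel steps, so track the best radius seen
    rk <- r[k]
    best <- c(r = rk, dev = Inf)
    for (it in 1:10) {
      vol <- sum(sphere_mask(grid, centers[k, ], rk)) * voxel_volume(grid)
      dev <- abs(vol - spec$target_volumes_mm3[k]) / spec$target_volumes_mm3[k]
      if (dev < best["dev"]) best <- c(r = rk, dev = dev)
      if (dev <= 0.01) break
      rk <- rk * (spec$target_volumes_mm3[k] / vol)^(1 / 3)
    }
    targets[[k]] <- sphere_mask(grid, centers[k, ], best[["r"]])
    if (any(targets[[k]] & !skull))
      stop("infeasible phantom spec: target ", k, " does not fit inside the skull")
    vol <- sum(targets[[k]]) * voxel_volume(grid)
    if (abs(vol - spec$target_volumes_mm3[k]) > 0.05 * spec$target_volumes_mm3[k])
      stop("voxelized target ", k, " volume deviates more than 5% from request")
  }

  oars <- list()
  oar_centers <- NULL
  if (spec$n_oars > 0) {
    dirs26 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    dirs26 <- dirs26[rowSums(abs(dirs26)) > 0, ]
    dirs26 <- dirs26 / sqrt(rowSums(dirs26^2))
    for (o in seq_len(spec$n_oars)) {
      k <- (o - 1) %% nt + 1
      gap <- runif(1, 2, 10)
      ord <- sample.int(nrow(dirs26))
      placed <- FALSE
      for (d in ord) {
        ctr <- centers[k, ] + dirs26[d, ] * (r[k] + gap + spec$oar_radius)
        # inside skull (with an OAR-radius margin) and clear of all targets
        e <- sum(((ctr - skull_c) / pmax(skull_semi - spec$oar_radius, 1))^2)
        clear <- all(sqrt(rowSums(sweep(centers, 2, ctr)^2)) >=
                       r + spec$oar_radius + 1)
        if (e <= 1 && clear) {
          oars[[o]] <- sphere_mask(grid, ctr, spec$oar_radius)
          oar_centers <- rbind(oar_centers, ctr)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("infeasible phantom spec: could not place OAR ", o)
    }
  }

  case <- structure(list(
    grid = grid, skull = skull, targets = targets, oars = oars,
    target_centers = centers, oar_centers = oar_centers,
    d_presc = spec$d_presc, d_oar_max = spec$d_oar_max,
    d_ld = 0.5 * min(spec$d_presc),
    kernels = kernel_bank(), iso = NULL, iso_target = NULL,
    seed = spec$seed, spec = spec, name = spec$name,
    schema_version = 1L), class = "gk_case")
  if (place_iso) {
    ip <- place_isocenters(case)
    case$iso <- ip$positions
    case$iso_target <- ip$target
  }
  case
}

#' @export
print.gk_case <- function(x, ...) {
  cat(sprintf("gk_case '%s': %d target(s), total %.0f mm^3, %d OAR(s), %s isocenters\n",
              x$name, length(x$targets),
              sum(vapply(x$targets, sum, 0)) * voxel_volume(x$grid),
              length(x$oars),
              if (is.null(x$iso)) "no" else nrow(x$iso)))
  invisible(x)
}

# effective (volume-equivalent sphere) radius of a mask, mm
effective_radius <- function(grid, mask) {
  (3 * sum(mask) * voxel_volume(grid) / (4 * pi))^(1 / 3)
}

#' Place isocenters inside the targets
#'
#' Deterministic greedy lattice fill of each target interior: candidate
#' positions on a cubic lattice centered at the target centroid are kept
#' when they fall inside the target and outside every OAR.  The default
#' lattice step grows with the target's effective radius
#' (\code{max(2.5, 1.32 * r_eff^0.56)} mm), so isocenter counts across
#' the clinical volume envelope fall in the clinically reported range.
#'
#' @param case a \code{gk_case}.
#' @param min_spacing lattice step in mm (scalar or per target); must be
#'   at least the voxel spacing.  Default: radius-scaled rule above.
#' @return list with \code{positions} (n x 3 mm) and \code{target}
#'   (owning target index per isocenter).
#' @export
place_isocenters <- function(case, min_spacing = NULL) {
  grid <- case$grid
  nt <- length(case$targets)
  pos <- NULL
  owner <- integer(0)
  oar_any <- Reduce(`|`, case$oars, array(FALSE, grid$shape))
  for (k in seq_len(nt)) {
    m <- case$targets[[k]]
    if (!any(m)) stop("target ", k, " is empty; cannot host an isocenter")
    r_eff <- effective_radius(grid, m)
    h <- if (is.null(min_spacing)) max(2.5, 1.32 * r_eff^0.56)
         else rep_len(min_spacing, nt)[k]
    if (h < max(grid$spacing))
      stop("isocenter spacing must be at least the voxel spacing")
    ctr <- colMeans(voxel_centers(grid, which(m)))
    ext <- r_eff + h
    ax <- lapply(1:3, function(a) ctr[a] + seq(-floor(ext / h), floor(ext / h)) * h)
    cand <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
    cand <- cand[order(cand[, 3], cand[, 2], cand[, 1]), , drop = FALSE]
    vox <- point_voxel(grid, cand)
    ok <- !is.na(vox) & m[vox] & !oar_any[vox]
    kept <- cand[ok, , drop = FALSE]
    if (nrow(kept) == 0) {
      # tiny target: single isocenter at the in-target voxel nearest the centroid
      tv <- which(m)
      cc <- voxel_centers(grid, tv)
      kept <- cc[which.min(rowSums(sweep(cc, 2, ctr)^2)), , drop = FALSE]
      if (oar_any[point_voxel(grid, kept)])
        stop("target ", k, " has no isocenter position outside the OARs")
    }
    pos <- rbind(pos, kept)
    owner <- c(owner, rep(k, nrow(kept)))
  }
  dimnames(pos) <- NULL
  list(positions = pos, target = owner)
}

#' Default per-category dose-point count caps
#'
#' Minimum and maximum numbers of sampled dose points per category,
#' defaulting to the envelope observed across the clinical test set
#' (low-dose: 250-5000 in the first pass).
#' @return named list of c(min, max) pairs.
#' @export
default_point_caps <- function() {
  list(`target-surface` = c(468, 9151), `target-interior` = c(264, 20957),
       shell = c(200, 3893), oar = c(211, 5286), `low-dose` = c(250, 5000))
}

#' Default per-category sampling densities
#'
#' Points per mm^2 for surface categories (target surface, OAR surface)
#' and per mm^3 for volumetric categories (interior, shell, low-dose).
#' @return named numeric vector.
#' @export
default_point_densities <- function() {
  c(`target-surface` = 0.12, `target-interior` = 0.015, shell = 0.025,
    oar = 0.5, `low-dose` = 0.015)
}

target_union <- function(case) Reduce(`|`, case$targets)
oar_union <- function(case) Reduce(`|`, case$oars, array(FALSE, case$grid$shape))

# band of voxels just outside the target(s): the selectivity shell
shell_mask <- function(case, width = 2) {
  d <- mask_distance(case$grid, target_union(case))
  m <- d > 0 & d <= width & case$skull & !oar_union(case)
  array(m, case$grid$shape)
}

category_mask <- function(case, category, ld_mask = NULL) {
  switch(category,
    "target-surface" = mask_boundary(target_union(case)),
    "target-interior" = {
      tu <- target_union(case)
      ti <- tu & !mask_boundary(tu)
      if (!any(ti)) tu else ti
    },
    "shell" = shell_mask(case),
    "low-dose" = {
      if (is.null(ld_mask)) ld_mask <- first_pass_ld_volume(case)$mask
      ld_mask
    },
    "oar" = {
      if (length(case$oars) == 0) stop("case has no OARs")
      mask_boundary(oar_union(case))
    },
    stop("unknown dose-point category: ", category))
}

#' Sample dose points from a structure category
#'
#' The number of points is \code{clip(round(density * measure), min,
#' max)}, where the measure is the structure volume (mm^3) for
#' volumetric categories and the boundary-voxel area (mm^2) for surface
#' categories.  Points are voxel centers jittered uniformly within their
#' voxel; reproducible given the seed.
#'
#' @param case a \code{gk_case}.
#' @param category one of "target-surface", "target-interior", "shell",
#'   "low-dose", "oar".
#' @param density points per mm^3 (volumetric) or mm^2 (surface).
#' @param min_count,max_count category count caps.
#' @param seed integer seed.
#' @param ld_mask low-dose volume mask (for category "low-dose"); default
#'   is the first-pass geometric expansion.
#' @return object of class \code{dose_points}: coords (n x 3 mm), voxel
#'   indices, per-point owner structure and dose level, counts.
#' @export
sample_dose_points <- function(case, category, density = NULL,
                               min_count = NULL, max_count = NULL,
                               seed = case$seed, ld_mask = NULL) {
  caps <- default_point_caps()[[category]]
  if (is.null(min_count)) min_count <- caps[1]
  if (is.null(max_count)) max_count <- caps[2]
  if (is.null(density)) density <- default_point_densities()[[category]]
  if (!is.numeric(density) || density <= 0) stop("density must be positive")
  grid <- case$grid

  mask <- category_mask(case, category, ld_mask)
  idx <- which(mask)
  if (length(idx) == 0) stop("cannot sample dose points from an empty structure (",
                             category, ")")
  surface <- category %in% c("target-surface", "oar")
  measure <- if (surface) length(idx) * grid$spacing[1] * grid$spacing[2]
             else length(idx) * voxel_volume(grid)
  n <- min(max(round(density * measure), min_count), max_count)

  set.seed(derive_seed(seed, paste0("pts_", category)))
  take <- idx[sample.int(length(idx), n, replace = TRUE)]
  coords <- jitter_in_voxel(grid, take)

  owner <- rep(NA_integer_, n)
  level <- rep(NA_real_, n)
  if (category %in% c("target-surface", "target-interior")) {
    for (k in seq_along(case$targets)) {
      ink <- case$targets[[k]][take]
      owner[ink] <- k
    }
    level <- case$d_presc[owner]
  } else if (category == "shell") {
    dt <- lapply(case$targets, function(m) mask_distance(grid, m))
    dmat <- vapply(dt, function(d) d[take], numeric(n))
    owner <- if (length(case$targets) == 1) rep(1L, n)
             else max.col(-matrix(dmat, n), ties.method = "first")
    level <- case$d_presc[owner]
  } else if (category == "oar") {
    for (k in seq_along(case$oars)) {
      ink <- case$oars[[k]][take]
      owner[ink] <- k
    }
    level <- case$d_oar_max[owner]
  } else {
    level <- rep(case$d_ld, n)
  }

  structure(list(category = category, coords = coords, voxel = take,
                 owner = owner, level = level, n = n, measure = measure,
                 density = density, caps = c(min_count, max_count)),
            class = "dose_points")
}

#' Sample the full first-pass dose-point set of a case
#'
#' @param case a \code{gk_case}.
#' @param seed integer seed (per-category streams are derived from it).
#' @param densities,caps optional overrides, as in
#'   \code{\link{default_point_densities}} / \code{\link{default_point_caps}}.
#' @param ld_mask low-dose mask override.
#' @return named list of \code{dose_points} (oar entry NULL when absent).
#' @export
sample_case_points <- function(case, seed = case$seed, densities = NULL,
                               caps = NULL, ld_mask = NULL) {
  dens <- default_point_densities()
  if (!is.null(densities)) dens[names(densities)] <- densities
  cp <- default_point_caps()
  if (!is.null(caps)) cp[names(caps)] <- caps
  cats <- c("target-surface", "target-interior", "shell", "low-dose")
  pts <- lapply(cats, function(cc)
    sample_dose_points(case, cc, dens[[cc]], cp[[cc]][1], cp[[cc]][2],
                       seed = seed, ld_mask = ld_mask))
  names(pts) <- c("ts", "ti", "shell", "ld")
  pts$oar <- if (length(case$oars) > 0)
    sample_dose_points(case, "oar", dens[["oar"]], cp[["oar"]][1],
                       cp[["oar"]][2], seed = seed) else NULL
  pts
}

#' Influence (dose-rate) matrix for a set of points
#'
#' Rows are points, columns are (isocenter, sector, collimator) triples
#' in isocenter-major order (sector next, collimator innermost).  Entry
#' (j, (i,s,c)) is the dose rate in Gy/min delivered at point j by
#' kernel (i,s,c) at unit time.
#'
#' @param case a \code{gk_case} with isocenters placed.
#' @param points a \code{dose_points} object or an n x 3 coordinate
#'   matrix (mm).
#' @return numeric matrix (n_points x 24 * n_iso).
#' @export
build_influence <- function(case, points) {
  if (inherits(points, "dose_points")) points <- points$coords
  if (is.null(case$iso)) stop("case has no isocenters; run place_isocenters()")
  k <- case$kernels
  influence_cpp(points, case$iso, k$dirs, k$sigma, k$amp, k$kappa)
}
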