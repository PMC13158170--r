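#' Reconstruct dose from a plan
#'
#' Dose at a point is the sum of the precalculated dose-rate kernels
#' weighted by the plan's sector times; evaluated for one or several
#' plans at arbitrary points (Gy; times in minutes, rates in Gy/min).
#'
#' @param case a \code{gk_case}.
#' @param plans a single plan or a list of plans (shared kernel bank).
#' @param points n x 3 coordinate matrix (mm), or a \code{dose_points}
#'   object, or a logical region mask over the grid.
#' @return numeric matrix (n_points x K).
#' @export
compute_dose <- function(case, plans, points) {
  if (inherits(plans, "gk_plan")) plans <- list(plans)
  if (inherits(points, "dose_points")) points <- points$coords
  if (is.logical(points)) points <- voxel_centers(case$grid, which(points))
  T <- vapply(plans, function(p) p$t, numeric(length(plans[[1]]$t)))
  T <- matrix(T, ncol = length(plans))
  if (any(!is.finite(T)) || any(T < 0)) stop("plan times must be finite and >= 0")
  k <- case$kernels
  dose_accumulate_cpp(points, case$iso, k$dirs, k$sigma, k$amp, k$kappa, T)
}

#' Clinical plan metrics
#'
#' Coverage (fraction of target volume at or above its prescription),
#' selectivity (fraction of the prescription isodose volume inside the
#' target), gradient index (half-prescription isodose volume over the
#' prescription isodose volume) and beam-on time (minutes, at the
#' calibration dose rate built into the kernels).  Metrics that are not
#' well defined are reported as NA with a reason code: the gradient
#' index and selectivity when prescriptions differ between targets, the
#' selectivity and gradient index when the prescription isodose volume
#' is empty.
#'
#' @param case a \code{gk_case}.
#' @param dose dose matrix (region voxels x K) from
#'   \code{\link{compute_dose}}.
#' @param region_idx voxel indices of the dose rows; must cover the
#'   targets and the surrounding fall-off region.
#' @param plans list of K plans (for the beam-on time).
#' @return data.frame with one row per plan: coverage, selectivity, gi,
#'   bot, sel_reason, gi_reason.
#' @export
plan_metrics <- function(case, dose, region_idx, plans) {
  if (inherits(plans, "gk_plan")) plans <- list(plans)
  dose <- matrix(dose, nrow = length(region_idx))
  K <- ncol(dose)
  tu <- target_union(case)
  if (!any(tu)) stop("case has no target voxels")
  n_tv <- sum(tu)
  in_target <- tu[region_idx]
  equal_presc <- length(unique(case$d_presc)) == 1
  # per-region-voxel prescription threshold (its owning target's, for coverage)
  owner <- rep(NA_integer_, length(region_idx))
  for (k in seq_along(case$targets)) {
    ink <- case$targets[[k]][region_idx]
    owner[ink] <- k
  }

  out <- lapply(seq_len(K), function(j) {
    d <- dose[, j]
    cov <- sum(in_target & d >= case$d_presc[owner], na.rm = TRUE) / n_tv
    sel <- NA_real_; gi <- NA_real_
    sel_reason <- ""; gi_reason <- ""
    if (!equal_presc) {
      sel_reason <- gi_reason <- "differing prescriptions"
    } else {
      p <- case$d_presc[1]
      piv <- sum(d >= p)
      if (piv == 0) {
        sel_reason <- gi_reason <- "empty prescription isodose volume"
      } else {
        sel <- sum(in_target & d >= p) / piv
        gi <- sum(d >= p / 2) / piv
      }
    }
    data.frame(coverage = cov, selectivity = sel, gi = gi,
               bot = plans[[j]]$bot, sel_reason = sel_reason,
               gi_reason = gi_reason)
  })
  do.call(rbind, out)
}

#' Pareto table of a metric sweep
#'
#' Flags plans dominated in (coverage up, selectivity up, gradient index
#' down, beam-on time down) space.  Metrics undefined for any plan are
#' left out of the dominance comparison.
#'
#' @param metrics data.frame from \code{\link{plan_metrics}} (with
#'   slider columns if available).
#' @return the table with a logical \code{dominated} column appended.
#' @export
pareto_table <- function(metrics) {
  stopifnot(nrow(metrics) >= 1)
  dirs <- c(coverage = 1, selectivity = 1, gi = -1, bot = -1)
  use <- names(dirs)[names(dirs) %in% names(metrics)]
  use <- use[vapply(use, function(nm) !anyNA(metrics[[nm]]), TRUE)]
  M <- as.matrix(metrics[, use, drop = FALSE]) %*% diag(dirs[use], length(use))
  n <- nrow(M)
  dominated <- vapply(seq_len(n), function(i) {
    any(vapply(seq_len(n)[-i], function(k)
      all(M[k, ] >= M[i, ]) && any(M[k, ] > M[i, ]), TRUE))
  }, TRUE)
  metrics$dominated <- if (n == 1) FALSE else dominated
  metrics
}
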