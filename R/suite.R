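#' Synthetic validation suite
#'
#' Five phantom specifications emulating the attributes of clinical
#' Gamma Knife cases across indications: a small vestibular-schwannoma-
#' like case with two OARs, small and mid-size meningioma-like cases,
#' a two-target metastases-like case, and a larger single-target case.
#' Total target volumes span 0.66-8 cm^3 and isocenter counts fall in
#' the clinically reported 17-214 range.  Deterministic given the seed.
#'
#' @param seed base seed; each case derives its own stream from it.
#' @return named list of \code{phantom_spec}s.
#' @export
validation_suite <- function(seed = 1) {
  list(
    vs_small = phantom_spec(663, n_oars = 2, d_presc = 13, d_oar_max = 8,
                            seed = derive_seed(seed, "case_vs_small"),
                            name = "vs_small"),
    me_small = phantom_spec(1400, n_oars = 1, d_presc = 20, d_oar_max = 10,
                            seed = derive_seed(seed, "case_me_small"),
                            name = "me_small"),
    mm_two = phantom_spec(c(900, 1500), n_oars = 0, d_presc = 20,
                          seed = derive_seed(seed, "case_mm_two"),
                          name = "mm_two"),
    me_mid = phantom_spec(5000, n_oars = 1, d_presc = 18, d_oar_max = 10,
                          seed = derive_seed(seed, "case_me_mid"),
                          name = "me_mid"),
    me_large = phantom_spec(8000, n_oars = 1, d_presc = 20, d_oar_max = 12,
                            seed = derive_seed(seed, "case_me_large"),
                            name = "me_large"))
}

#' Full solver validation of one case
#'
#' Merged evaluation used by the validation suite: builds the two-pass
#' problems once, compares single-precision ADMM at each iteration
#' budget against the exact LP oracle on the first-pass instances
#' (higher budgets continue the same iteration stream, which is exactly
#' equivalent to a longer fresh run), and runs the single-versus-double
#' dose criterion of \code{\link{precision_policy_report}} on both
#' passes with shared problem instances.
#'
#' @param case a \code{gk_case} (or \code{phantom_spec}).
#' @param sliders slider grid (default "3x3").
#' @param n_iter ascending iteration budgets for the quality comparison;
#'   the largest is also used for the precision comparison.
#' @param seed sampling seed.
#' @return list: \code{quality} (data frame as
#'   \code{\link{admm_quality_report}}), \code{precision} (list as
#'   \code{\link{precision_policy_report}}).
#' @export
case_validation <- function(case, sliders = "3x3", n_iter = c(2000, 3000),
                            seed = NULL) {
  if (inherits(case, "phantom_spec")) case <- make_phantom(case)
  if (is.null(seed)) seed <- case$seed
  n_iter <- sort(n_iter)
  grid_w <- if (is.data.frame(sliders)) sliders else slider_grid(sliders)
  region_idx <- dose_region(case)
  reg_coords <- voxel_centers(case$grid, region_idx)

  # pass 1 problem, shared by everything below
  pts1 <- sample_case_points(case, seed = derive_seed(seed, "pass1_pts"))
  lp1 <- build_case_lp(case, pts1)
  sch1 <- precompute_schur(lp1$A)
  oracle <- solve_lp_exact(lp1, grid_w)

  qual <- list()
  fit_s <- NULL
  done <- 0
  for (ni in n_iter) {
    fit_s <- solve_batch(lp1, grid_w, n_iter = ni - done, precision = "single",
                         schur = sch1, trace_stride = 0, state = fit_s)
    done <- ni
    cmp <- compare_to_oracle(lp1, recover_primal(fit_s, lp1), oracle)
    qual[[as.character(ni)]] <- cbind(case = case$name, n_iter = ni, cmp)
  }
  quality <- do.call(rbind, qual)
  rownames(quality) <- NULL
  attr(quality, "lp_dim") <- c(m = lp1$m, n = lp1$n)
  attr(quality, "schur_cond") <- sch1$cond

  ni_max <- max(n_iter)
  fit_d <- solve_batch(lp1, grid_w, n_iter = ni_max, precision = "double",
                       schur = sch1, trace_stride = 0)
  d1 <- list(single = compute_dose(case, recover_primal(fit_s, lp1), reg_coords),
             double = compute_dose(case, recover_primal(fit_d, lp1), reg_coords))

  # pass 2 instances from the double-precision reference dose
  vols2 <- second_pass_ld_volumes(case, d1$double, region_idx)
  dens <- default_point_densities()
  cp <- default_point_caps()
  vv <- voxel_volume(case$grid)
  n_des <- vapply(vols2, function(v)
    min(max(round(dens[["low-dose"]] * length(v) * vv), cp[["low-dose"]][1]),
        cp[["low-dose"]][2]), 0)
  sp <- overlap_sample(vols2, n_des, case$grid,
                       seed = derive_seed(seed, "pass2_ld"))
  pts2 <- pts1
  pts2$ld <- structure(list(category = "low-dose", coords = sp$points,
                            voxel = sp$voxel,
                            owner = rep(NA_integer_, nrow(sp$points)),
                            level = rep(case$d_ld, nrow(sp$points)),
                            n = nrow(sp$points)), class = "dose_points")
  lp2 <- build_case_lp(case, pts2)
  sch2 <- precompute_schur(lp2$A)
  f2 <- lapply(c(single = "single", double = "double"), function(p)
    solve_batch(lp2, grid_w, n_iter = ni_max, precision = p, schur = sch2,
                trace_stride = 0, ld_members = sp$member))
  d2 <- lapply(f2, function(f) compute_dose(case, recover_primal(f, lp2),
                                            reg_coords))

  ds <- cbind(d1$single, d2$single)
  dd <- cbind(d1$double, d2$double)
  adev <- abs(ds - dd)
  rel <- adev / pmax(abs(dd), .Machine$double.eps)
  abs_fail <- adev > 0.05
  precision <- list(
    n_points = length(adev), n_abs_fail = sum(abs_fail),
    max_rel_among_abs_fail = if (any(abs_fail)) 100 * max(rel[abs_fail]) else 0,
    all_within = all(!abs_fail | rel <= 0.005),
    max_abs = max(adev), max_rel_pct = 100 * max(rel))

  list(quality = quality, precision = precision)
}

#' ADMM-versus-oracle quality report for one case
#'
#' Builds the first-pass LP of a case, solves every weight vector of the
#' slider grid with the batched ADMM solver (fixed iteration count, row
#' normalization, BOT column scaling and the per-instance step-size
#' heuristic applied) and with the exact LP oracle on the identical
#' instances, and reports per-instance relative deviations of the total
#' primal objective and its BOT term.
#'
#' @param case a \code{gk_case} (or \code{phantom_spec}).
#' @param sliders slider grid (default "3x3", nine weight vectors).
#' @param n_iter ADMM iteration count(s); one report per entry.
#' @param precision iteration precision.
#' @param seed sampling seed.
#' @param oracle optional precomputed oracle results (reused across
#'   iteration counts).
#' @return data.frame with columns case, n_iter, instance, sliders,
#'   objective values and percent errors.
#' @export
admm_quality_report <- function(case, sliders = "3x3", n_iter = c(2000, 3000),
                                precision = "single", seed = NULL,
                                oracle = NULL) {
  if (inherits(case, "phantom_spec")) case <- make_phantom(case)
  if (is.null(seed)) seed <- case$seed
  grid_w <- if (is.data.frame(sliders)) sliders else slider_grid(sliders)
  pts <- sample_case_points(case, seed = derive_seed(seed, "pass1_pts"))
  lp <- build_case_lp(case, pts)
  schur <- precompute_schur(lp$A)
  if (is.null(oracle)) oracle <- solve_lp_exact(lp, grid_w)
  out <- lapply(n_iter, function(ni) {
    fit <- solve_batch(lp, grid_w, n_iter = ni, precision = precision,
                       schur = schur, trace_stride = 0)
    cmp <- compare_to_oracle(lp, recover_primal(fit, lp), oracle)
    cbind(case = case$name, n_iter = ni, cmp)
  })
  out <- do.call(rbind, out)
  attr(out, "lp_dim") <- c(m = lp$m, n = lp$n)
  attr(out, "schur_cond") <- schur$cond
  out
}

#' Single- versus double-precision dose comparison for one case
#'
#' Runs the full two-pass optimization twice with identical seeds, once
#' with single-precision and once with double-precision ADMM iterations
#' (Schur inversions always double), reconstructs the dose of every plan
#' at every evaluation point after each pass, and summarizes the
#' per-dose-point disagreement: a point passes when its relative
#' deviation is within \code{rel_tol} or its absolute deviation within
#' \code{abs_tol} Gy.
#'
#' The optimization problems of both passes are built once (the
#' second-pass low-dose volumes are derived from the double-precision
#' reference doses), so both precisions solve the exact same problem
#' instances and only the iteration arithmetic differs.
#'
#' @param case a \code{gk_case} (or \code{phantom_spec}).
#' @param sliders slider grid.
#' @param n_iter iterations per pass.
#' @param seed run seed (shared by both precisions).
#' @param rel_tol,abs_tol acceptance thresholds (0.5\% / 0.05 Gy).
#' @return list: \code{n_points} compared, \code{n_abs_fail} (points
#'   beyond abs_tol), \code{max_rel_among_abs_fail} (percent; 0 when no
#'   point fails the absolute criterion), \code{all_within} (logical),
#'   \code{max_abs}, \code{max_rel_pct}.
#' @export
precision_policy_report <- function(case, sliders = "3x3", n_iter = 3000,
                                    seed = NULL, rel_tol = 0.005,
                                    abs_tol = 0.05) {
  if (inherits(case, "phantom_spec")) case <- make_phantom(case)
  if (is.null(seed)) seed <- case$seed
  n_iter <- rep_len(n_iter, 2)
  grid_w <- if (is.data.frame(sliders)) sliders else slider_grid(sliders)
  region_idx <- dose_region(case)
  reg_coords <- voxel_centers(case$grid, region_idx)

  # pass 1: one LP, solved in both precisions
  pts1 <- sample_case_points(case, seed = derive_seed(seed, "pass1_pts"))
  lp1 <- build_case_lp(case, pts1)
  sch1 <- precompute_schur(lp1$A)
  f1 <- lapply(c(single = "single", double = "double"), function(p)
    solve_batch(lp1, grid_w, n_iter = n_iter[1], precision = p,
                schur = sch1, trace_stride = 0))
  d1 <- lapply(f1, function(f) compute_dose(case, recover_primal(f, lp1),
                                            reg_coords))

  # pass 2: instances fixed from the double-precision reference dose
  vols2 <- second_pass_ld_volumes(case, d1$double, region_idx)
  dens <- default_point_densities()
  cp <- default_point_caps()
  vv <- voxel_volume(case$grid)
  n_des <- vapply(vols2, function(v)
    min(max(round(dens[["low-dose"]] * length(v) * vv), cp[["low-dose"]][1]),
        cp[["low-dose"]][2]), 0)
  sp <- overlap_sample(vols2, n_des, case$grid,
                       seed = derive_seed(seed, "pass2_ld"))
  pts2 <- pts1
  pts2$ld <- structure(list(category = "low-dose", coords = sp$points,
                            voxel = sp$voxel,
                            owner = rep(NA_integer_, nrow(sp$points)),
                            level = rep(case$d_ld, nrow(sp$points)),
                            n = nrow(sp$points)), class = "dose_points")
  lp2 <- build_case_lp(case, pts2)
  sch2 <- precompute_schur(lp2$A)
  f2 <- lapply(c(single = "single", double = "double"), function(p)
    solve_batch(lp2, grid_w, n_iter = n_iter[2], precision = p,
                schur = sch2, trace_stride = 0, ld_members = sp$member))
  d2 <- lapply(f2, function(f) compute_dose(case, recover_primal(f, lp2),
                                            reg_coords))

  ds <- cbind(d1$single, d2$single)
  dd <- cbind(d1$double, d2$double)
  adev <- abs(ds - dd)
  rel <- adev / pmax(abs(dd), .Machine$double.eps)
  abs_fail <- adev > abs_tol
  list(n_points = length(adev),
       n_abs_fail = sum(abs_fail),
       max_rel_among_abs_fail = if (any(abs_fail))
         100 * max(rel[abs_fail]) else 0,
       all_within = all(!abs_fail | rel <= rel_tol),
       max_abs = max(adev), max_rel_pct = 100 * max(rel))
}
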