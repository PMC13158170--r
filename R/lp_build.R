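#' Map slider positions to objective weights
#'
#' The planner's two sliders (low-dose and beam-on time, both in [0,1])
#' are mapped log-linearly onto the corresponding primal weights, with
#' the target and shell weights fixed at one.  The lower end of the BOT
#' range is the lowest allowed BOT weight \code{w0_bot} used by the
#' step-size heuristic \code{\link{rho_heuristic}}.
#'
#' @param s_ld,s_bot slider positions in [0, 1].
#' @param w_ld_range,w_bot_range positive (min, max) weight ranges.
#' @return object of class \code{weight_vector} with fields \code{w_t},
#'   \code{w_s}, \code{w_ld}, \code{w_bot}, \code{w0_bot}, \code{s_ld},
#'   \code{s_bot}.
#' @export
sliders_to_weights <- function(s_ld, s_bot, w_ld_range = c(0.05, 2),
                               w_bot_range = c(5, 150)) {
  if (s_ld < 0 || s_ld > 1 || s_bot < 0 || s_bot > 1)
    stop("slider values must lie in [0, 1]")
  stopifnot(all(w_ld_range > 0), all(w_bot_range > 0),
            diff(w_ld_range) >= 0, diff(w_bot_range) >= 0)
  loglin <- function(s, rng) {
    if (s <= 0) return(rng[1])
    if (s >= 1) return(rng[2])
    exp(log(rng[1]) + s * (log(rng[2]) - log(rng[1])))
  }
  structure(list(w_t = 1, w_s = 1,
                 w_ld = loglin(s_ld, w_ld_range),
                 w_bot = loglin(s_bot, w_bot_range),
                 w0_bot = w_bot_range[1],
                 s_ld = s_ld, s_bot = s_bot),
            class = "weight_vector")
}

#' Uniform slider grid
#'
#' Parses a grid size such as \code{"3x3"} or \code{"21x21"} (or a
#' numeric pair) into all combinations of equally spaced slider values
#' over [0, 1]; a 21x21 grid corresponds to steps of 0.05 and 441 weight
#' vectors.
#'
#' @param grid character "AxB" or integer vector of length 2.
#' @param ... passed to \code{\link{sliders_to_weights}}.
#' @return data.frame with columns \code{s_ld}, \code{s_bot} and a list
#'   column \code{w} of \code{weight_vector}s.
#' @export
slider_grid <- function(grid = "3x3", ...) {
  if (is.character(grid))
    grid <- as.integer(strsplit(grid, "x", fixed = TRUE)[[1]])
  stopifnot(length(grid) == 2, all(grid >= 1))
  vals <- function(n) if (n == 1) 0.5 else seq(0, 1, length.out = n)
  g <- expand.grid(s_ld = vals(grid[1]), s_bot = vals(grid[2]))
  g$w <- lapply(seq_len(nrow(g)),
                function(i) sliders_to_weights(g$s_ld[i], g$s_bot[i], ...))
  g
}

#' Step-size heuristic for the batched ADMM solver
#'
#' One augmented-Lagrangian parameter per weight vector:
#' \code{rho = 2.5e-3 * w0_bot / w_bot}, decreasing with the beam-on-time
#' weight, as calibrated on row-normalized planning problems.
#'
#' @param w_bot beam-on-time weight (>= \code{w0_bot}).
#' @param w0_bot lowest allowed beam-on-time weight (> 0).
#' @return positive scalar rho.
#' @export
rho_heuristic <- function(w_bot, w0_bot) {
  if (any(w0_bot <= 0) || any(w_bot <= 0))
    stop("weights must be strictly positive")
  if (any(w_bot < w0_bot))
    stop("w_bot must be at least the lowest allowed BOT weight w0_bot")
  2.5e-3 * w0_bot / w_bot
}

#' Beam-on-time column scaling factor
#'
#' The relative influence of the BOT columns of the constraint matrix
#' shrinks as the number of dose points grows, so those columns are
#' rescaled by \code{beta = (total number of non-OAR dose points) / 2000}
#' (OAR points carry no objective term and are excluded).
#'
#' @param counts numeric vector of non-OAR dose-point counts (target
#'   surface, target interior, shell, low-dose block(s)).
#' @return positive scalar beta.
#' @export
bot_column_scaling <- function(counts) {
  stopifnot(all(counts >= 0))
  sum(counts) / 2000
}

#' Assemble the dual linear program of weighted-sum inverse planning
#'
#' The primal problem penalizes target underdose, shell overdose,
#' low-dose-band excess and total beam-on time, with hard OAR maximum
#' doses and per-(isocenter, sector) collimator-time/shot-time coupling.
#' Its dual is \code{min c'x  s.t.  Ax <= b, 0 <= x <= u}, with one dual
#' variable per dose point (alpha: target, beta: shell, gamma: low-dose,
#' delta: OAR) plus eight sector variables mu per isocenter, and 25 rows
#' per isocenter (24 collimator-time rows plus one shot-time row).  The
#' objective weights enter only through b (BOT weight, shot-time rows)
#' and u (per-category weight over point count); the physics enters
#' through A via the influence matrices.
#'
#' Row order: per isocenter, the 24 (sector, collimator) rows (sector
#' major, collimator innermost) then the shot-time row.  Column order:
#' target points (surface then interior), shell, low-dose, OAR, then the
#' mu columns (isocenter major).
#'
#' @param phi named list of influence blocks (rows = points, columns =
#'   kernel triples): \code{ts}, \code{ti}, \code{shell}, \code{ld},
#'   optionally \code{oar} (NULL allowed).
#' @param levels named list of per-point dose levels (Gy), same names.
#' @param n_iso number of isocenters.
#' @param d_ld low-dose threshold (Gy), recorded for objective evaluation.
#' @return object of class \code{dual_lp} (unnormalized; see
#'   \code{\link{normalize_rows}} and \code{\link{apply_bot_scaling}}).
#' @export
assemble_dual_lp <- function(phi, levels, n_iso, d_ld = NULL) {
  if (n_iso < 1) stop("at least one isocenter is required")
  blocks <- c("ts", "ti", "shell", "ld", "oar")
  phi <- phi[blocks]
  names(phi) <- blocks
  counts <- vapply(phi, function(p) if (is.null(p)) 0L else nrow(p), 0L)
  if (counts["ts"] + counts["ti"] == 0) stop("at least one target dose point is required")
  ncol_k <- 24 * n_iso
  for (b in blocks) if (!is.null(phi[[b]]) && ncol(phi[[b]]) != ncol_k)
    stop("influence block '", b, "' has wrong number of kernel columns")

  n_pts <- sum(counts)
  m <- 25L * n_iso
  n <- n_pts + 8L * n_iso

  # row bookkeeping: per isocenter, 24 t rows then 1 tau row
  row_iso <- rep(seq_len(n_iso), each = 25L)
  row_kind <- rep(c(rep("t", 24L), "tau"), n_iso)
  t_rows <- which(row_kind == "t")      # in kernel-column (i,s,c) order
  tau_rows <- which(row_kind == "tau")

  col_cat <- rep(c("target", "target", "shell", "ld", "oar"), counts)
  col_cat <- c(col_cat, rep("mu", 8L * n_iso))
  mu_cols <- n_pts + seq_len(8L * n_iso)

  A <- matrix(0, m, n)
  sign_of <- c(ts = 1, ti = 1, shell = -1, ld = -1, oar = -1)
  off <- 0L
  for (b in blocks) {
    if (counts[b] == 0) next
    A[t_rows, off + seq_len(counts[b])] <- sign_of[b] * t(phi[[b]])
    off <- off + counts[b]
  }
  # mu columns: -1 on the matching (i,s,c) t rows, +1 on the tau row
  for (i in seq_len(n_iso)) {
    for (s in 1:8) {
      mc <- n_pts + (i - 1L) * 8L + s
      rows_t <- (i - 1L) * 25L + (s - 1L) * 3L + 1:3
      A[rows_t, mc] <- -1
      A[(i - 1L) * 25L + 25L, mc] <- 1
    }
  }

  lev <- unlist(lapply(blocks, function(b) levels[[b]]), use.names = FALSE)
  stopifnot(length(lev) == n_pts)
  cvec <- c(ifelse(col_cat[seq_len(n_pts)] == "target", -lev, lev),
            rep(0, 8L * n_iso))

  structure(list(
    c = cvec, A = A, m = m, n = n, n_iso = n_iso,
    counts = c(ts = unname(counts["ts"]), ti = unname(counts["ti"]),
               shell = unname(counts["shell"]), ld = unname(counts["ld"]),
               oar = unname(counts["oar"])),
    col_cat = col_cat, mu_cols = mu_cols,
    row_iso = row_iso, row_kind = row_kind,
    t_rows = t_rows, tau_rows = tau_rows,
    levels = lev, d_ld = d_ld,
    phi = phi,
    row_norms = rep(1, m), beta = 1), class = "dual_lp")
}

#' @export
print.dual_lp <- function(x, ...) {
  cat(sprintf("dual_lp: A is %d x %d (%d isocenters; points: %s)\n",
              x$m, x$n, x$n_iso,
              paste(names(x$counts), x$counts, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Normalize the rows of the constraint matrix
#'
#' Scales every row of A to unit Euclidean norm (recording the norms for
#' solution recovery), which makes the diagonal of the Schur complement
#' S = AA' + I equal to two and its off-diagonal entries lie in [-1, 1].
#' The b entries are scaled identically, so the problem is equivalent.
#'
#' @param lp a \code{dual_lp}.
#' @return the row-normalized \code{dual_lp}.
#' @export
normalize_rows <- function(lp) {
  nr <- sqrt(rowSums(lp$A^2))
  if (any(nr == 0)) {
    bad <- which(nr == 0)[1]
    stop(sprintf("row %d of A (isocenter %d, kind %s) has zero norm",
                 bad, lp$row_iso[bad], lp$row_kind[bad]))
  }
  lp$A <- lp$A / nr
  lp$row_norms <- lp$row_norms * nr
  lp
}

#' Apply the BOT column scaling
#'
#' Multiplies the mu (BOT) columns of A by beta (an exact change of
#' variables mu' = mu/beta; the recovered sector and shot times are
#' unchanged).  Applied after \code{\link{normalize_rows}}.
#'
#' @param lp a \code{dual_lp}.
#' @param beta positive scale, e.g. from \code{\link{bot_column_scaling}}.
#' @return the scaled \code{dual_lp}.
#' @export
apply_bot_scaling <- function(lp, beta) {
  stopifnot(beta > 0)
  lp$A[, lp$mu_cols] <- lp$A[, lp$mu_cols] * beta
  lp$beta <- lp$beta * beta
  lp
}

#' Per-weight-vector bound columns
#'
#' For one weight vector, builds the b and u columns of the dual LP.
#' The objective weights are per-point, per-Gy penalty rates on summed
#' slacks, so they enter the dual bounds directly: u is \code{w_t} on
#' target columns, \code{w_s} on shell columns, \code{w_ld} on low-dose
#' columns and +Inf on OAR and mu columns; b is zero on collimator-time
#' rows and the (row-scaled) BOT weight on shot-time rows.  In the
#' second pass, a 0/1 membership vector over the shared low-dose points
#' gives weight only to that instance's own points (zero upper bound
#' elsewhere).
#'
#' @param lp a \code{dual_lp}.
#' @param w a \code{weight_vector}.
#' @param ld_member optional logical vector over LD columns; points
#'   outside the instance's low-dose set get a zero upper bound.
#' @return list with \code{b} (length m) and \code{u} (length n).
#' @export
weights_to_bounds <- function(lp, w, ld_member = NULL) {
  if (any(unlist(w[c("w_t", "w_s", "w_ld", "w_bot")]) <= 0))
    stop("all objective weights must be strictly positive")
  if (lp$counts[["ts"]] + lp$counts[["ti"]] == 0) stop("no target points")
  u <- rep(Inf, lp$n)
  u[lp$col_cat == "target"] <- w$w_t
  u[lp$col_cat == "shell"] <- w$w_s
  if (lp$counts[["ld"]] > 0) {
    if (is.null(ld_member)) {
      u[lp$col_cat == "ld"] <- w$w_ld
    } else {
      stopifnot(length(ld_member) == lp$counts[["ld"]])
      if (!any(ld_member)) stop("instance has no low-dose points")
      u[lp$col_cat == "ld"] <- ifelse(ld_member, w$w_ld, 0)
    }
  }
  b <- rep(0, lp$m)
  b[lp$tau_rows] <- w$w_bot / lp$row_norms[lp$tau_rows]
  list(b = b, u = u)
}

#' Assemble, precondition and package the LP of a synthetic case
#'
#' Convenience wrapper: influence matrices for every sampled point
#' category, dual-LP assembly, row normalization, and BOT column scaling
#' with beta from the non-OAR point total.
#'
#' @param case a \code{gk_case}.
#' @param points point set from \code{\link{sample_case_points}}.
#' @return a preconditioned \code{dual_lp}.
#' @export
build_case_lp <- function(case, points) {
  phi <- list(ts = build_influence(case, points$ts),
              ti = build_influence(case, points$ti),
              shell = build_influence(case, points$shell),
              ld = build_influence(case, points$ld),
              oar = if (!is.null(points$oar)) build_influence(case, points$oar))
  levels <- list(ts = points$ts$level, ti = points$ti$level,
                 shell = points$shell$level, ld = points$ld$level,
                 oar = if (!is.null(points$oar)) points$oar$level)
  lp <- assemble_dual_lp(phi, levels, nrow(case$iso), d_ld = case$d_ld)
  lp <- normalize_rows(lp)
  beta <- bot_column_scaling(lp$counts[c("ts", "ti", "shell", "ld")])
  apply_bot_scaling(lp, beta)
}
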