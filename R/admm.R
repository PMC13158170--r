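#' Precompute the Schur-complement operator
#'
#' Builds S = AA' + I and its explicit inverse in double precision (the
#' inverse is later cast to the working precision of the iterations).
#' S is symmetric positive definite by construction; the inverse is
#' validated by a residual check at build time.
#'
#' @param A constraint matrix (m x n).
#' @return object of class \code{schur_op}: \code{Sinv}, \code{m},
#'   \code{cond} (1-norm condition estimate of S), \code{diag_range}.
#' @export
precompute_schur <- function(A) {
  if (!all(is.finite(A))) stop("A must be finite to build the Schur operator")
  S <- tcrossprod(A)
  diag(S) <- diag(S) + 1
  ch <- tryCatch(chol(S), error = function(e)
    stop("Schur complement is numerically singular: ", conditionMessage(e)))
  Sinv <- chol2inv(ch)
  res <- max(abs(S %*% Sinv - diag(nrow(S))))
  if (res >= 1e-8)
    stop(sprintf("Schur inverse residual %.2e exceeds 1e-8", res))
  structure(list(Sinv = Sinv, m = nrow(S),
                 cond = norm(S, "1") * norm(Sinv, "1"),
                 diag_range = range(diag(S)), residual = res),
            class = "schur_op")
}

as_weight_list <- function(weights) {
  if (inherits(weights, "weight_vector")) return(list(weights))
  if (is.data.frame(weights)) return(weights$w)
  weights
}

#' Solve a batch of weight-vector instances with ADMM
#'
#' Runs a fixed number of scaled-form ADMM iterations on
#' \code{min c'x  s.t.  Ax <= b, 0 <= x <= u} for all K weight vectors
#' simultaneously: the x-update reduces to products with the cached
#' Schur inverse, the z-update to element-wise clipping against the
#' per-instance bound columns B and U, and the y-update to a dual
#' ascent step with per-instance step size rho.  Iterates start at zero.
#' No early stopping is used; residuals are recorded every
#' \code{trace_stride} iterations.
#'
#' @param lp a preconditioned \code{dual_lp}.
#' @param weights a \code{weight_vector}, a list of them, or a
#'   \code{\link{slider_grid}} data frame.
#' @param n_iter fixed iteration count (default 3000 per pass).
#' @param precision "single" (default; iterations in IEEE float32, the
#'   Schur inversion always double) or "double".
#' @param rho per-instance step sizes; default
#'   \code{rho_scale * rho_heuristic(w_bot, w0_bot)}.
#' @param rho_scale formulation-scale factor applied to the step-size
#'   heuristic (default 5600, calibrated once on validation phantoms;
#'   the heuristic's base constant is tied to the clinical
#'   formulation's unit conventions, so this package's dose/time/weight
#'   scales require one overall recalibration; see the methods
#'   vignette).
#' @param trace_stride residual recording stride (0 disables).
#' @param schur optional precomputed \code{schur_op} (reused across
#'   batches and passes at fixed A).
#' @param ld_members optional list of per-instance logical LD membership
#'   vectors (second pass).
#' @param state optional warm-start state (list Z1, Z2, Y1, Y2).
#' @return object of class \code{admm_fit}: final Z1 (solution
#'   estimates), Y2 (scaled duals for plan recovery), rho, residual
#'   traces, weights, flags.
#' @export
solve_batch <- function(lp, weights, n_iter = 3000, precision = c("single", "double"),
                        rho = NULL, rho_scale = 5600, trace_stride = 10,
                        schur = NULL, ld_members = NULL, state = NULL) {
  precision <- match.arg(precision)
  stopifnot(n_iter >= 1)
  wl <- as_weight_list(weights)
  K <- length(wl)
  if (is.null(rho))
    rho <- vapply(wl, function(w)
      rho_scale * rho_heuristic(w$w_bot, w$w0_bot), 0)
  rho <- rep_len(rho, K)
  if (is.null(schur)) schur <- precompute_schur(lp$A)

  B <- matrix(0, lp$m, K)
  U <- matrix(0, lp$n, K)
  for (j in seq_len(K)) {
    bu <- weights_to_bounds(lp, wl[[j]],
                            ld_member = if (!is.null(ld_members)) ld_members[[j]])
    B[, j] <- bu$b
    U[, j] <- bu$u
  }
  L <- matrix(0, lp$n, K)
  if (is.null(state))
    state <- list(Z1 = matrix(0, lp$n, K), Z2 = matrix(0, lp$m, K),
                  Y1 = matrix(0, lp$n, K), Y2 = matrix(0, lp$m, K))

  out <- admm_iterate_cpp(lp$A, schur$Sinv, lp$c, rho, B, U, L,
                          state$Z1, state$Z2, state$Y1, state$Y2,
                          as.integer(n_iter), precision == "single",
                          as.integer(trace_stride))
  if (out$diverged)
    warning("ADMM iterates diverged (non-finite) at iteration ", out$iterations,
            "; partial trace returned")
  structure(list(Z1 = out$Z1, Z2 = out$Z2, Y1 = out$Y1, Y2 = out$Y2,
                 rho = rho, weights = wl, precision = precision,
                 iterations = out$iterations, diverged = out$diverged,
                 trace = list(iter = out$trace_iter,
                              primal = out$primal_res, dual = out$dual_res),
                 schur = schur, ld_members = ld_members),
            class = "admm_fit")
}

#' One ADMM cycle
#'
#' Runs a single (x, z, y) update on an existing state, for inspection
#' and testing; equivalent to \code{solve_batch(..., n_iter = 1)} with a
#' warm start.
#'
#' @inheritParams solve_batch
#' @param state state list (Z1, Z2, Y1, Y2), e.g. from a previous fit.
#' @return updated \code{admm_fit}.
#' @export
admm_step <- function(lp, weights, state, rho = NULL,
                      precision = "double", schur = NULL, ld_members = NULL) {
  solve_batch(lp, weights, n_iter = 1, precision = precision, rho = rho,
              trace_stride = 0, schur = schur, ld_members = ld_members,
              state = state)
}

#' Recover treatment plans from converged dual variables
#'
#' The primal solution of instance j is rho_j times the converged scaled
#' dual variable of the Ax <= b block, un-scaled by the recorded row
#' norms: its collimator-time rows give the sector times t(i,s,c) (in
#' the influence-column order) and its shot-time rows the per-isocenter
#' times tau_i; beam-on time is the sum of the tau_i (minutes).  Small
#' negative entries are clipped to zero; larger ones trigger a warning.
#'
#' @param fit an \code{admm_fit} (or a Y2 matrix).
#' @param lp the \code{dual_lp} that was solved.
#' @param rho per-column step sizes (taken from the fit when given).
#' @param neg_tol relative tolerance for negative entries (fraction of
#'   the column maximum).
#' @return list of plans; each has \code{t} (length 24 n_iso),
#'   \code{tau} (length n_iso), \code{bot} and the instance's weights.
#' @export
recover_primal <- function(fit, lp, rho = NULL, neg_tol = 1e-3) {
  if (inherits(fit, "admm_fit")) {
    Y2 <- fit$Y2
    if (is.null(rho)) rho <- fit$rho
    wl <- fit$weights
  } else {
    Y2 <- as.matrix(fit)
    wl <- NULL
  }
  stopifnot(!is.null(rho), nrow(Y2) == lp$m)
  K <- ncol(Y2)
  plans <- vector("list", K)
  for (j in seq_len(K)) {
    y <- Y2[, j] * rho[j] / lp$row_norms
    tol <- max(neg_tol * max(abs(y)), 1e-6)
    n_neg <- sum(y < -tol)
    if (n_neg > 0)
      warning(sprintf("instance %d: %d recovered entries below -%.1e clipped to zero",
                      j, n_neg, tol))
    y <- pmax(y, 0)
    plans[[j]] <- structure(list(t = y[lp$t_rows], tau = y[lp$tau_rows],
                                 bot = sum(y[lp$tau_rows]),
                                 w = if (!is.null(wl)) wl[[j]]),
                            class = "gk_plan")
  }
  plans
}

#' @export
print.gk_plan <- function(x, ...) {
  cat(sprintf("gk_plan: %d active of %d kernels, BOT %.2f min\n",
              sum(x$t > 0), length(x$t), x$bot))
  invisible(x)
}

#' Primal objective terms of a recovered plan
#'
#' Evaluates the four weighted-sum objective terms (summed target
#' underdose, summed shell overdose, summed low-dose excess, beam-on
#' time) of a plan on the dose points of an LP instance, using the
#' stored (unnormalized) influence blocks.
#'
#' @param lp a \code{dual_lp}.
#' @param plan a plan from \code{\link{recover_primal}} (or an oracle).
#' @param w a \code{weight_vector} (default: the plan's own).
#' @param ld_member optional logical LD membership (second pass).
#' @return named numeric: target, shell, ld, bot, total.
#' @export
primal_objective <- function(lp, plan, w = plan$w, ld_member = NULL) {
  stopifnot(!is.null(w))
  tvec <- plan$t
  d_t <- c(if (lp$counts[["ts"]] > 0) lp$phi$ts %*% tvec,
           if (lp$counts[["ti"]] > 0) lp$phi$ti %*% tvec)
  lev_t <- lp$levels[lp$col_cat[seq_along(lp$levels)] == "target"]
  term_t <- w$w_t * sum(pmax(lev_t - d_t, 0))

  term_s <- 0
  if (lp$counts[["shell"]] > 0) {
    d_s <- as.vector(lp$phi$shell %*% tvec)
    lev_s <- lp$levels[lp$col_cat[seq_along(lp$levels)] == "shell"]
    term_s <- w$w_s * sum(pmax(d_s - lev_s, 0))
  }

  term_ld <- 0
  if (lp$counts[["ld"]] > 0) {
    d_ld <- as.vector(lp$phi$ld %*% tvec)
    exc <- pmax(d_ld - lp$d_ld, 0)
    term_ld <- if (is.null(ld_member)) w$w_ld * sum(exc)
               else w$w_ld * sum(exc[ld_member])
  }

  term_bot <- w$w_bot * sum(plan$tau)
  c(target = term_t, shell = term_s, ld = term_ld, bot = term_bot,
    total = term_t + term_s + term_ld + term_bot)
}
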