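python_binary <- function() {
  py <- getOption("gkpareto.python", "")
  if (nzchar(py)) return(py)
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stop("no python interpreter found for the exact LP oracle")
}

#' Solve linear programs exactly (reference oracle)
#'
#' Solves \code{min c'x s.t. Ax <= b, l <= x <= u} to optimality with
#' the HiGHS solver (via the bundled python bridge), one instance per
#' column of B/U.  Used as the ground-truth reference against which the
#' ADMM solutions are validated; it plays no part in plan generation.
#'
#' @param cvec objective (length n).
#' @param A constraint matrix (m x n).
#' @param B right-hand sides, m x K.
#' @param L lower bounds (length n).
#' @param U upper bounds, n x K (may contain +Inf).
#' @return list of K results: \code{status} (0 = optimal),
#'   \code{objective}, \code{x}, \code{marginals} (of the Ax <= b rows).
#' @export
lp_oracle <- function(cvec, A, B, L, U) {
  m <- nrow(A); n <- ncol(A)
  B <- matrix(B, nrow = m); U <- matrix(U, nrow = n)
  K <- ncol(B)
  stopifnot(length(cvec) == n, length(L) == n, ncol(U) == K)
  enc <- function(x) {
    x <- as.double(x)
    x[x == Inf] <- 1e300
    x[x == -Inf] <- -1e300
    x
  }
  prefix <- tempfile("lp_oracle_")
  jsonlite::write_json(list(m = m, n = n, K = K),
                       paste0(prefix, "_meta.json"), auto_unbox = TRUE)
  con <- file(paste0(prefix, "_in.bin"), "wb")
  writeBin(enc(c(cvec, A, B, L, U)), con, size = 8, endian = "little")
  close(con)
  on.exit(unlink(paste0(prefix, c("_meta.json", "_in.bin", "_out.bin"))))

  script <- system.file("python", "lp_oracle.py", package = "gkpareto")
  status <- system2(python_binary(), c(shQuote(script), shQuote(prefix)),
                    stdout = TRUE, stderr = TRUE)
  outfile <- paste0(prefix, "_out.bin")
  if (!file.exists(outfile))
    stop("LP oracle failed: ", paste(status, collapse = "\n"))
  con <- file(outfile, "rb")
  raw <- readBin(con, what = "double", n = K * (2 + n + m), size = 8,
                 endian = "little")
  close(con)
  lapply(seq_len(K), function(j) {
    off <- (j - 1) * (2 + n + m)
    list(status = as.integer(raw[off + 1]), objective = raw[off + 2],
         x = raw[off + 2 + seq_len(n)],
         marginals = raw[off + 2 + n + seq_len(m)])
  })
}

#' Exact solution of a planning LP instance
#'
#' Solves one (or K) weight-vector instances of a \code{dual_lp} with
#' the exact LP oracle and recovers the primal treatment plan from the
#' dual values of the inequality rows, passed through the same row
#' un-scaling as the ADMM recovery.
#'
#' @param lp a preconditioned \code{dual_lp}.
#' @param weights a \code{weight_vector}, list, or \code{slider_grid}
#'   data frame.
#' @param ld_members optional per-instance LD membership (second pass).
#' @return list of \code{oracle_result}s: \code{status},
#'   \code{objective} (dual LP optimum), \code{x}, \code{plan}
#'   (recovered primal plan), \code{w}.
#' @export
solve_lp_exact <- function(lp, weights, ld_members = NULL) {
  wl <- as_weight_list(weights)
  K <- length(wl)
  B <- matrix(0, lp$m, K); U <- matrix(0, lp$n, K)
  for (j in seq_len(K)) {
    bu <- weights_to_bounds(lp, wl[[j]],
                            ld_member = if (!is.null(ld_members)) ld_members[[j]])
    B[, j] <- bu$b; U[, j] <- bu$u
  }
  res <- lp_oracle(lp$c, lp$A, B, rep(0, lp$n), U)
  lapply(seq_len(K), function(j) {
    r <- res[[j]]
    if (r$status != 0)
      stop("oracle reports non-optimal status ", r$status,
           " for instance ", j, " (planning LPs are bounded and feasible)")
    y <- -r$marginals / lp$row_norms   # primal plan = multipliers of Ax <= b
    y <- pmax(y, 0)
    plan <- structure(list(t = y[lp$t_rows], tau = y[lp$tau_rows],
                           bot = sum(y[lp$tau_rows]), w = wl[[j]]),
                      class = "gk_plan")
    structure(list(status = r$status, objective = r$objective, x = r$x,
                   marginals = r$marginals, plan = plan, w = wl[[j]]),
              class = "oracle_result")
  })
}

#' Compare ADMM plans with exact-oracle plans
#'
#' Per instance, evaluates the primal objective terms of the ADMM and
#' oracle plans on the identical LP instance and reports relative
#' deviations (of the total objective and of the BOT term) in percent.
#'
#' @param lp the shared \code{dual_lp}.
#' @param admm_plans plans from \code{\link{recover_primal}}.
#' @param oracle_results from \code{\link{solve_lp_exact}} on the same
#'   instance and points.
#' @param ld_members optional per-instance LD membership (second pass).
#' @return data.frame: per-instance objective terms and percent errors.
#' @export
compare_to_oracle <- function(lp, admm_plans, oracle_results,
                              ld_members = NULL) {
  K <- length(admm_plans)
  stopifnot(length(oracle_results) == K)
  rows <- lapply(seq_len(K), function(j) {
    mem <- if (!is.null(ld_members)) ld_members[[j]]
    w <- admm_plans[[j]]$w
    oa <- primal_objective(lp, admm_plans[[j]], w, ld_member = mem)
    oo <- primal_objective(lp, oracle_results[[j]]$plan, w, ld_member = mem)
    data.frame(instance = j, s_ld = w$s_ld, s_bot = w$s_bot,
               admm_total = oa[["total"]], oracle_total = oo[["total"]],
               admm_bot = oa[["bot"]], oracle_bot = oo[["bot"]],
               err_total_pct = 100 * abs(oa[["total"]] - oo[["total"]]) /
                 abs(oo[["total"]]),
               err_bot_pct = 100 * abs(oa[["bot"]] - oo[["bot"]]) /
                 abs(oo[["bot"]]))
  })
  do.call(rbind, rows)
}
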