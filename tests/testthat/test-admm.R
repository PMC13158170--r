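toy_lp <- function() {
  # min -x s.t. x <= 1, 0 <= x <= 2: optimum x* = 1, objective -1
  structure(list(c = -1, A = matrix(1, 1, 1), m = 1L, n = 1L,
                 row_norms = 1, t_rows = 1L, tau_rows = integer(0),
                 col_cat = "target", counts = c(ts = 1L, ti = 0L, shell = 0L,
                                                ld = 0L, oar = 0L)),
            class = "dual_lp")
}

toy_solve <- function(n_iter, rho = 0.1, precision = FALSE, K = 1) {
  lp <- toy_lp()
  sch <- precompute_schur(lp$A)
  gkpareto:::admm_iterate_cpp(lp$A, sch$Sinv, lp$c, rep(rho, K),
                              matrix(1, 1, K), matrix(2, 1, K),
                              matrix(0, 1, K), matrix(0, 1, K),
                              matrix(0, 1, K), matrix(0, 1, K),
                              matrix(0, 1, K), as.integer(n_iter), precision,
                              0L)
}

test_that("Schur operator is built and validated in double precision", {
  s0 <- precompute_schur(matrix(0, 3, 4))
  expect_equal(s0$Sinv, diag(3))
  expect_equal(s0$cond, 1)
  expect_equal(precompute_schur(matrix(c(0.6, 0.8), 1, 2))$Sinv, matrix(0.5))
  set.seed(2)
  A <- matrix(rnorm(300), 10, 30)
  sch <- precompute_schur(A)
  S <- tcrossprod(A) + diag(10)
  expect_lt(max(abs(S %*% sch$Sinv - diag(10))), 1e-10)
  expect_error(precompute_schur(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("ADMM solves the closed-form toy bound problem", {
  out <- toy_solve(2000)
  expect_lt(abs(out$Z1[1, 1] - 1), 1e-4)
  out3 <- toy_solve(3000)
  expect_lt(abs(-out3$Z1[1, 1] - (-1)) / 1, 1e-3)   # objective c'z vs optimum
  # primal recovery: rho * y2 equals the multiplier of x <= 1 (which is 1)
  expect_lt(abs(out3$Y2[1, 1] * 0.1 - 1), 1e-3)
})

test_that("batched columns evolve independently and identically", {
  out <- toy_solve(500, K = 3)
  expect_identical(out$Z1[, 1], out$Z1[, 2])
  expect_identical(out$Y2[, 1], out$Y2[, 3])

  lp <- random_planning_lp(seed = 3)
  w1 <- sliders_to_weights(0, 0.5)
  w2 <- sliders_to_weights(1, 0.2)
  sch <- precompute_schur(lp$A)
  fb <- solve_batch(lp, list(w1, w2), n_iter = 400, precision = "double",
                    schur = sch, trace_stride = 0)
  f1 <- solve_batch(lp, list(w1), n_iter = 400, precision = "double",
                    schur = sch, trace_stride = 0)
  expect_equal(fb$Z1[, 1], f1$Z1[, 1], tolerance = 1e-10)
  expect_equal(fb$Y2[, 1], f1$Y2[, 1], tolerance = 1e-10)
})

test_that("box projection is element-wise clipping and idempotent", {
  set.seed(4)
  x <- rnorm(50)
  l <- rep(0, 50); u <- runif(50, 0.1, 2)
  clip <- function(v) pmin(pmax(v, l), u)
  expect_identical(clip(clip(x)), clip(x))
  expect_true(all(clip(x) >= l & clip(x) <= u))
})

test_that("primal recovery unscales, clips and splits the dual variable", {
  lp <- random_planning_lp(seed = 5)
  K <- 2
  Y2 <- matrix(0, lp$m, K)
  plans0 <- recover_primal(Y2, lp, rho = c(1, 2))
  expect_equal(plans0[[1]]$bot, 0)
  expect_true(all(plans0[[2]]$t == 0))

  set.seed(6)
  Y2 <- matrix(abs(rnorm(lp$m * K)), lp$m, K)
  p1 <- recover_primal(Y2, lp, rho = c(2, 2))
  p2 <- recover_primal(2 * Y2, lp, rho = c(1, 1))
  expect_equal(p1[[1]]$t, p2[[1]]$t)
  expect_equal(p1[[2]]$tau, p2[[2]]$tau)
  expect_equal(length(p1[[1]]$t), 24 * lp$n_iso)
  expect_equal(length(p1[[1]]$tau), lp$n_iso)
  expect_warning(recover_primal(matrix(-1, lp$m, 1), lp, rho = 1), "clipped")
})

test_that("3000-iteration ADMM matches the exact oracle on random planning LPs", {
  errs <- c()
  for (seed in 1:20) {
    lp <- random_planning_lp(seed = seed, n_iso = 2, n_ts = 60, n_ti = 40,
                             n_sh = 40, n_ld = 50)
    w <- sliders_to_weights(runif(1), runif(1))
    orc <- solve_lp_exact(lp, w)[[1]]
    fit <- solve_batch(lp, w, n_iter = 3000, precision = "double",
                       trace_stride = 0)
    pa <- primal_objective(lp, recover_primal(fit, lp)[[1]], w)
    po <- primal_objective(lp, orc$plan, w)
    errs <- c(errs, abs(pa[["total"]] - po[["total"]]) / po[["total"]])
  }
  expect_lt(max(errs), 0.01)
})

test_that("the converged plan is insensitive to the step size near the rule", {
  lp <- random_planning_lp(seed = 30)
  w <- sliders_to_weights(0.5, 0.5)
  base <- 5600 * rho_heuristic(w$w_bot, w$w0_bot)
  objs <- vapply(c(0.1, 1, 10), function(f) {
    fit <- solve_batch(lp, w, n_iter = 3000, precision = "double",
                       rho = f * base, trace_stride = 0)
    primal_objective(lp, recover_primal(fit, lp)[[1]], w)[["total"]]
  }, 0)
  expect_lt(diff(range(objs)) / mean(objs), 0.02)
})

test_that("residuals decay to feasibility at convergence", {
  lp <- random_planning_lp(seed = 12)
  w <- sliders_to_weights(0.5, 0.5)
  fit <- solve_batch(lp, w, n_iter = 3000, precision = "single",
                     trace_stride = 10)
  tr <- fit$trace
  expect_identical(tr$iter[1], 10L)
  expect_identical(length(tr$iter), 300L)
  # final normalized primal residual small; decreased vs early iterations
  expect_lt(tr$primal[300, 1], 1e-3)
  expect_lt(tr$primal[300, 1], tr$primal[1, 1] / 10)
  bu <- weights_to_bounds(lp, w)
  viol <- max(0, max(lp$A %*% fit$Z1[, 1] - bu$b))
  expect_lt(viol / max(abs(bu$b)), 1e-3)
})

test_that("single-precision iterates track double precision on the same LP", {
  lp <- random_planning_lp(seed = 21)
  w <- sliders_to_weights(0.5, 0.5)
  sch <- precompute_schur(lp$A)
  fs <- solve_batch(lp, w, n_iter = 2000, precision = "single", schur = sch,
                    trace_stride = 0)
  fd <- solve_batch(lp, w, n_iter = 2000, precision = "double", schur = sch,
                    trace_stride = 0)
  ps <- primal_objective(lp, recover_primal(fs, lp)[[1]], w)
  pd <- primal_objective(lp, recover_primal(fd, lp)[[1]], w)
  expect_lt(abs(ps[["total"]] - pd[["total"]]) / pd[["total"]], 0.005)
})

test_that("a warm-started single step equals one more batch iteration", {
  lp <- random_planning_lp(seed = 9)
  w <- sliders_to_weights(0.2, 0.8)
  sch <- precompute_schur(lp$A)
  f100 <- solve_batch(lp, w, n_iter = 100, precision = "double", schur = sch,
                      trace_stride = 0)
  f101 <- solve_batch(lp, w, n_iter = 101, precision = "double", schur = sch,
                      trace_stride = 0)
  stp <- admm_step(lp, w, state = f100, schur = sch)
  expect_equal(stp$Z1, f101$Z1, tolerance = 1e-12)
  expect_equal(stp$Y2, f101$Y2, tolerance = 1e-12)
})
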