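test_that("dual LP dimensions follow the 25-rows / 8-extra-columns law", {
  # clinical-size check: 53 isocenters and 4123 dose points -> 1325 x 4547
  n_iso <- 53; n_pts <- 4123
  n_ts <- 2000; n_ti <- n_pts - n_ts
  nk <- 24 * n_iso
  phi <- list(ts = matrix(0.1, n_ts, nk), ti = matrix(0.1, n_ti, nk),
              shell = NULL, ld = NULL, oar = NULL)
  levels <- list(ts = rep(20, n_ts), ti = rep(20, n_ti))
  lp <- assemble_dual_lp(phi, levels, n_iso, d_ld = 10)
  expect_identical(dim(lp$A), c(1325L, 4547L))

  # smallest clinical case: 17 isocenters, 3910 points -> 425 x 4046
  n_pts <- 4046 - 8 * 17
  phi <- list(ts = matrix(0.1, n_pts, 24 * 17), ti = NULL, shell = NULL,
              ld = NULL, oar = NULL)
  lp2 <- assemble_dual_lp(phi, list(ts = rep(20, n_pts)), 17, d_ld = 10)
  expect_identical(dim(lp2$A), c(425L, 4046L))

  # degenerate single-isocenter, single-point problem
  lp3 <- assemble_dual_lp(list(ts = matrix(1, 1, 24)), list(ts = 20), 1)
  expect_identical(dim(lp3$A), c(25L, 9L))

  expect_error(assemble_dual_lp(list(ts = matrix(1, 1, 24)), list(ts = 20), 0),
               "isocenter")
  expect_error(assemble_dual_lp(list(shell = matrix(1, 5, 24)),
                                list(shell = rep(20, 5)), 1), "target")
})

test_that("objective and bound structure matches the dualization", {
  lp <- random_planning_lp(seed = 2)
  # c: -D_presc on target, +D_presc on shell, +D_LD on low-dose, 0 on mu
  expect_true(all(lp$c[lp$col_cat == "target"] == -20))
  expect_true(all(lp$c[lp$col_cat == "shell"] == 20))
  expect_true(all(lp$c[lp$col_cat == "ld"] == 10))
  expect_true(all(lp$c[lp$col_cat == "mu"] == 0))
  w <- sliders_to_weights(0.5, 0.5)
  bu <- weights_to_bounds(lp, w)
  expect_true(all(bu$u[lp$col_cat == "target"] == w$w_t))
  expect_true(all(bu$u[lp$col_cat == "shell"] == w$w_s))
  expect_true(all(bu$u[lp$col_cat == "ld"] == w$w_ld))
  expect_true(all(is.infinite(bu$u[lp$col_cat == "mu"])))
  expect_true(all(bu$b[lp$t_rows] == 0))
  expect_true(all(bu$b[lp$tau_rows] > 0))
  # second-pass membership zeroes the foreign low-dose bounds
  mem <- rep(c(TRUE, FALSE), length.out = lp$counts[["ld"]])
  bu2 <- weights_to_bounds(lp, w, ld_member = mem)
  expect_equal(unname(bu2$u[lp$col_cat == "ld"]), ifelse(mem, w$w_ld, 0))
  w0 <- w; w0$w_ld <- 0
  expect_error(weights_to_bounds(lp, w0), "strictly positive")
})

test_that("slider map hits its endpoints and is monotone", {
  w00 <- sliders_to_weights(0, 0)
  w11 <- sliders_to_weights(1, 1)
  expect_equal(w00$w_t, 1)
  expect_equal(w00$w_s, 1)
  expect_equal(w00$w_ld, 0.05)
  expect_equal(w00$w_bot, w00$w0_bot)
  expect_equal(w11$w_ld, 2)
  expect_equal(w11$w_bot, 150)
  wb <- vapply(seq(0, 1, 0.1), function(s) sliders_to_weights(0, s)$w_bot, 0)
  expect_true(all(diff(wb) > 0))
  expect_error(sliders_to_weights(-0.1, 0), "0, 1")
  expect_error(sliders_to_weights(0, 1.1), "0, 1")
  g <- slider_grid("21x21")
  expect_identical(nrow(g), 441L)
  expect_equal(sort(unique(g$s_ld)), seq(0, 1, 0.05))
})

test_that("row normalization gives unit rows and a Schur diagonal of two", {
  lp0 <- list(A = matrix(c(3, 4), 1, 2), m = 1L, n = 2L,
              row_iso = 1L, row_kind = "t", row_norms = 1, b = 0)
  class(lp0) <- "dual_lp"
  lpn <- normalize_rows(lp0)
  expect_equal(lpn$A, matrix(c(0.6, 0.8), 1, 2))
  expect_equal(tcrossprod(lpn$A) + 1, matrix(2))

  # planning LP before BOT column scaling: diag(S) = 2, off-diag in [-1, 1]
  case <- tiny_case()
  pts <- tiny_lp()$pts
  phi <- list(ts = build_influence(case, pts$ts),
              ti = build_influence(case, pts$ti),
              shell = build_influence(case, pts$shell),
              ld = build_influence(case, pts$ld),
              oar = build_influence(case, pts$oar))
  levels <- list(ts = pts$ts$level, ti = pts$ti$level, shell = pts$shell$level,
                 ld = pts$ld$level, oar = pts$oar$level)
  lp <- normalize_rows(assemble_dual_lp(phi, levels, nrow(case$iso),
                                        d_ld = case$d_ld))
  S <- tcrossprod(lp$A) + diag(lp$m)
  expect_equal(diag(S), rep(2, lp$m), tolerance = 1e-12)
  off <- S - diag(diag(S))
  expect_true(all(off >= -1 - 1e-12 & off <= 1 + 1e-12))

  lp0$A <- matrix(0, 1, 2)
  expect_error(normalize_rows(lp0), "zero norm")
})

test_that("BOT column scale and step-size heuristic follow their closed forms", {
  expect_equal(bot_column_scaling(c(800, 600, 300, 200, 100)), 1)
  expect_equal(bot_column_scaling(rep(10000, 4)), 20)
  expect_equal(bot_column_scaling(1000), 0.5)
  expect_equal(rho_heuristic(0.01, 0.01), 2.5e-3)
  expect_equal(rho_heuristic(0.02, 0.01), 1.25e-3)
  expect_equal(rho_heuristic(0.1, 0.01), 2.5e-4)
  expect_error(rho_heuristic(1, -1), "positive")
  expect_error(rho_heuristic(0.5, 1), "lowest allowed")
})

test_that("preconditioning is an equivalence transform of the planning LP", {
  lp <- random_planning_lp(seed = 4)
  w <- sliders_to_weights(0.5, 0.5)
  # undo the beta scaling to get the unscaled (but row-normalized) LP
  lp_raw <- lp
  lp_raw$A[, lp_raw$mu_cols] <- lp_raw$A[, lp_raw$mu_cols] / lp_raw$beta
  lp_raw$beta <- 1
  o1 <- solve_lp_exact(lp, w)[[1]]
  o2 <- solve_lp_exact(lp_raw, w)[[1]]
  p1 <- primal_objective(lp, o1$plan, w)
  p2 <- primal_objective(lp_raw, o2$plan, w)
  expect_equal(p1, p2, tolerance = 1e-5)
  expect_equal(o1$plan$bot, o2$plan$bot, tolerance = 1e-5)
})

test_that("strong duality holds against an independently built primal LP", {
  lp <- random_planning_lp(seed = 6, n_iso = 2, n_ts = 30, n_ti = 20,
                           n_sh = 20, n_ld = 25)
  for (s in list(c(0, 0), c(0.5, 0.5), c(1, 1))) {
    w <- sliders_to_weights(s[1], s[2])
    dual <- solve_lp_exact(lp, w)[[1]]
    prim <- primal_planning_lp(lp, w)
    po <- lp_oracle(prim$c, prim$A, matrix(prim$b), prim$l, matrix(prim$u))[[1]]
    expect_equal(po$objective, -dual$objective,
                 tolerance = 1e-6 * max(1, abs(po$objective)))
    # the recovered plan attains the same primal objective
    expect_equal(unname(primal_objective(lp, dual$plan, w)[["total"]]),
                 po$objective, tolerance = 1e-6 * max(1, abs(po$objective)))
  }
})

test_that("scaling all weights scales the optimum but not the plan", {
  lp <- random_planning_lp(seed = 8, n_iso = 2, n_ts = 30, n_ti = 20,
                           n_sh = 20, n_ld = 25)
  w <- sliders_to_weights(0.5, 0.5)
  lam <- 3
  wl <- w
  wl[c("w_t", "w_s", "w_ld", "w_bot")] <-
    lapply(w[c("w_t", "w_s", "w_ld", "w_bot")], function(x) lam * x)
  o1 <- solve_lp_exact(lp, w)[[1]]
  o2 <- solve_lp_exact(lp, wl)[[1]]
  expect_equal(o2$objective, lam * o1$objective, tolerance = 1e-6)
  expect_equal(o2$plan$bot, o1$plan$bot, tolerance = 1e-4 * max(1, o1$plan$bot))
})
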