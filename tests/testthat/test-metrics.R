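test_that("dose reconstruction is the time-weighted kernel sum", {
  case <- tiny_case()
  nk <- 24 * nrow(case$iso)
  pts <- sample_dose_points(case, "target-interior", seed = 3,
                            min_count = 40, max_count = 40)
  zero <- structure(list(t = rep(0, nk), tau = rep(0, nrow(case$iso)),
                         bot = 0, w = NULL), class = "gk_plan")
  expect_true(all(compute_dose(case, zero, pts) == 0))

  # a single active kernel reproduces that kernel's field
  one <- zero; one$t[37] <- 1
  phi <- build_influence(case, pts)
  expect_equal(as.vector(compute_dose(case, one, pts)), phi[, 37])

  # restriction consistency: region dose equals full dose on the region
  set.seed(8)
  pl <- zero; pl$t <- runif(nk)
  d_all <- compute_dose(case, pl, pts$coords)
  d_sub <- compute_dose(case, pl, pts$coords[1:10, , drop = FALSE])
  expect_equal(d_all[1:10, 1], d_sub[, 1])
})

test_that("coverage, selectivity and gradient index follow their definitions", {
  case <- make_phantom(phantom_spec(4189, n_oars = 0, seed = 3, name = "r10"),
                       place_iso = FALSE)
  region_idx <- which(case$skull)
  coords <- gkpareto:::voxel_centers(case$grid, region_idx)
  ctr <- colMeans(gkpareto:::voxel_centers(case$grid, which(case$targets[[1]])))
  rad <- sqrt(rowSums(sweep(coords, 2, ctr)^2))
  plan <- structure(list(t = 0, tau = 0, bot = 12.5, w = NULL),
                    class = "gk_plan")

  # ideal plan: exactly the prescription inside the target, nothing outside
  d <- ifelse(case$targets[[1]][region_idx], case$d_presc[1], 0)
  m <- plan_metrics(case, matrix(d, ncol = 1), region_idx, list(plan))
  expect_equal(m$coverage, 1)
  expect_equal(m$selectivity, 1)
  expect_equal(m$bot, 12.5)

  # spherical fall-off: 100% isodose at r1, 50% at r2 -> GI = (r2/r1)^3
  r1 <- 10; r2 <- 14
  dose <- case$d_presc[1] * 2^(-(rad - r1) / (r2 - r1))
  m2 <- plan_metrics(case, matrix(dose, ncol = 1), region_idx, list(plan))
  expect_equal(m2$gi, (r2 / r1)^3, tolerance = 0.05)
  expect_equal(m2$coverage, 1)

  # no dose: zero coverage, undefined selectivity with a reason
  m0 <- plan_metrics(case, matrix(0, length(region_idx)), region_idx,
                     list(plan))
  expect_equal(m0$coverage, 0)
  expect_true(is.na(m0$selectivity))
  expect_match(m0$sel_reason, "empty")

  # differing prescriptions leave the gradient index undefined
  case2 <- make_phantom(phantom_spec(c(900, 1200), n_oars = 0,
                                     d_presc = c(18, 22), seed = 5,
                                     name = "mt"), place_iso = FALSE)
  reg2 <- which(case2$skull)
  m3 <- plan_metrics(case2, matrix(20, length(reg2)), reg2, list(plan))
  expect_true(is.na(m3$gi))
  expect_match(m3$gi_reason, "prescriptions")
})

test_that("the exact oracle solves the toy LP and matches vertex enumeration", {
  res <- lp_oracle(-1, matrix(1, 1, 1), matrix(1), 0, matrix(2))[[1]]
  expect_identical(res$status, 0L)
  expect_equal(res$x, 1)
  expect_equal(res$objective, -1)
  expect_equal(res$marginals, -1)

  set.seed(31)
  for (rep in 1:12) {
    m <- 3; n <- 4
    A <- matrix(rnorm(m * n), m)
    cvec <- rnorm(n)
    b <- runif(m, 0.5, 1.5)
    u <- runif(n, 0.5, 2)
    got <- lp_oracle(cvec, A, matrix(b), rep(0, n), matrix(u))[[1]]
    ref <- brute_lp(cvec, A, b, rep(0, n), u)
    expect_equal(got$objective, ref$objective, tolerance = 1e-7)
  }
})

test_that("oracle plans satisfy the LP bounds and beat ADMM iterates", {
  lp <- random_planning_lp(seed = 14)
  w <- sliders_to_weights(0.3, 0.7)
  orc <- solve_lp_exact(lp, w)[[1]]
  bu <- weights_to_bounds(lp, w)
  expect_true(all(lp$A %*% orc$x <= bu$b + 1e-8))
  expect_true(all(orc$x >= -1e-8 & orc$x <= bu$u + 1e-8))
  fit <- solve_batch(lp, w, n_iter = 500, precision = "double",
                     trace_stride = 0)
  # minimization bound: the exact optimum is below any projected iterate
  z <- pmin(pmax(fit$Z1[, 1], 0), bu$u)
  expect_lte(orc$objective, sum(lp$c * z) + 1e-8)
})

test_that("identical plans compare with zero error", {
  lp <- random_planning_lp(seed = 15)
  w <- sliders_to_weights(0.5, 0.5)
  orc <- solve_lp_exact(lp, w)
  cmp <- compare_to_oracle(lp, list(orc[[1]]$plan), orc)
  expect_equal(cmp$err_total_pct, 0)
  expect_equal(cmp$err_bot_pct, 0)
})

test_that("the BOT objective term decreases as its weight grows", {
  lp <- random_planning_lp(seed = 16, n_iso = 2, n_ts = 40, n_ti = 30,
                           n_sh = 30, n_ld = 30)
  bots <- vapply(c(0, 0.5, 1), function(s) {
    w <- sliders_to_weights(0.5, s)
    orc <- solve_lp_exact(lp, w)[[1]]
    unname(primal_objective(lp, orc$plan, w)[["bot"]] / w$w_bot)  # raw BOT
  }, 0)
  expect_true(all(diff(bots) <= 1e-8))
})

test_that("pareto table flags dominated plans only", {
  m1 <- data.frame(coverage = 0.95, selectivity = 0.9, gi = 2.8, bot = 40)
  expect_false(pareto_table(m1)$dominated)
  m2 <- data.frame(coverage = c(0.95, 0.80), selectivity = c(0.9, 0.85),
                   gi = c(2.8, 3.5), bot = c(40, 55))
  expect_identical(pareto_table(m2)$dominated, c(FALSE, TRUE))
  # undefined metrics are excluded from the dominance comparison
  m3 <- m2; m3$gi <- c(NA, NA)
  expect_identical(pareto_table(m3)$dominated, c(FALSE, TRUE))
})

test_that("ADMM metric sampling noise mirrors the oracle's", {
  # re-sample the dose points of one small case repeatedly and compare the
  # spread of the resulting beam-on times between solvers
  case <- tiny_case()
  w <- sliders_to_weights(0.5, 0.5)
  bot_admm <- bot_orc <- numeric(12)
  for (r in seq_len(12)) {
    pts <- sample_case_points(case, seed = 1000 + r, caps = tiny_caps)
    lp <- build_case_lp(case, pts)
    fit <- solve_batch(lp, w, n_iter = 2000, precision = "single",
                       trace_stride = 0)
    bot_admm[r] <- recover_primal(fit, lp)[[1]]$bot
    bot_orc[r] <- solve_lp_exact(lp, w)[[1]]$plan$bot
  }
  # same mean and statistically indistinguishable dispersion (alpha = 0.01)
  expect_lt(abs(mean(bot_admm) - mean(bot_orc)) / mean(bot_orc), 0.05)
  av <- stats::ansari.test(bot_admm - median(bot_admm),
                           bot_orc - median(bot_orc))
  expect_gt(av$p.value, 0.01)
})
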