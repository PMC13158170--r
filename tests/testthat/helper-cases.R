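# Small fixtures shared across test files.  Everything is generated in
# code from seeds; caps are shrunk so unit tests stay fast.

tiny_caps <- list(`target-surface` = c(60, 60), `target-interior` = c(40, 40),
                  shell = c(40, 40), `low-dose` = c(60, 60), oar = c(30, 30))

.case_cache <- new.env(parent = emptyenv())

tiny_case <- function() {
  if (is.null(.case_cache$tiny))
    .case_cache$tiny <- make_phantom(phantom_spec(900, n_oars = 1,
                                                  d_presc = 20, seed = 101,
                                                  name = "tiny"))
  .case_cache$tiny
}

tiny_lp <- function(seed = 5) {
  key <- paste0("lp", seed)
  if (is.null(.case_cache[[key]])) {
    pts <- sample_case_points(tiny_case(), seed = seed, caps = tiny_caps)
    .case_cache[[key]] <- list(pts = pts, lp = build_case_lp(tiny_case(), pts))
  }
  .case_cache[[key]]
}

# Random planning-structured LP (random nonnegative influence), small
# enough for fast ADMM and oracle runs.
random_planning_lp <- function(n_iso = 2, n_ts = 60, n_ti = 40, n_sh = 40,
                               n_ld = 50, seed = 1, d_presc = 20, d_ld = 10) {
  set.seed(seed)
  nk <- 24 * n_iso
  ph <- function(n) matrix(abs(rnorm(n * nk, sd = 0.1)), n, nk)
  phi <- list(ts = ph(n_ts), ti = ph(n_ti), shell = ph(n_sh), ld = ph(n_ld),
              oar = NULL)
  levels <- list(ts = rep(d_presc, n_ts), ti = rep(d_presc, n_ti),
                 shell = rep(d_presc, n_sh), ld = rep(d_ld, n_ld), oar = NULL)
  lp <- assemble_dual_lp(phi, levels, n_iso, d_ld = d_ld)
  lp <- normalize_rows(lp)
  apply_bot_scaling(lp, bot_column_scaling(c(n_ts, n_ti, n_sh, n_ld)))
}

# Brute-force LP oracle by vertex enumeration, independent of the HiGHS
# bridge: enumerates all active sets of n constraints among the rows of
# A and the box faces, solves each square system, and keeps the best
# feasible point.
brute_lp <- function(cvec, A, b, l, u, tol = 1e-9) {
  n <- ncol(A)
  G <- rbind(A, diag(n), -diag(n))
  h <- c(b, u, -l)
  combos <- utils::combn(nrow(G), n)
  best <- Inf
  xbest <- NULL
  for (j in seq_len(ncol(combos))) {
    idx <- combos[, j]
    M <- G[idx, , drop = FALSE]
    if (abs(det(M)) < 1e-10) next
    x <- solve(M, h[idx])
    if (all(G %*% x <= h + tol)) {
      ob <- sum(cvec * x)
      if (ob < best - 1e-12) {
        best <- ob
        xbest <- x
      }
    }
  }
  list(objective = best, x = xbest)
}

# Primal weighted-sum planning LP assembled independently of the
# package's dual construction, for strong-duality audits.  Variables:
# [t (24 n_iso), tau (n_iso), underdose slacks, shell slacks, LD slacks].
primal_planning_lp <- function(lp, w) {
  nk <- 24 * lp$n_iso
  ni <- lp$n_iso
  n1 <- lp$counts[["ts"]] + lp$counts[["ti"]]
  n2 <- lp$counts[["shell"]]
  n3 <- lp$counts[["ld"]]
  n4 <- lp$counts[["oar"]]
  phi_t <- rbind(lp$phi$ts, lp$phi$ti)
  lev <- lp$levels
  lev_t <- lev[seq_len(n1)]
  lev_sh <- lev[n1 + seq_len(n2)]
  lev_oar <- if (n4 > 0) lev[n1 + n2 + n3 + seq_len(n4)]
  nv <- nk + ni + n1 + n2 + n3
  zeros <- function(nr) matrix(0, nr, nv)
  blocks <- list()
  rhs <- c()
  # -phi_t t - s_u <= -D_presc
  Bk <- zeros(n1); Bk[, seq_len(nk)] <- -phi_t
  Bk[cbind(seq_len(n1), nk + ni + seq_len(n1))] <- -1
  blocks$tgt <- Bk; rhs <- c(rhs, -lev_t)
  # phi_sh t - s_o <= D_presc
  Bk <- zeros(n2); Bk[, seq_len(nk)] <- lp$phi$shell
  Bk[cbind(seq_len(n2), nk + ni + n1 + seq_len(n2))] <- -1
  blocks$sh <- Bk; rhs <- c(rhs, lev_sh)
  # phi_ld t - s_l <= D_LD
  Bk <- zeros(n3); Bk[, seq_len(nk)] <- lp$phi$ld
  Bk[cbind(seq_len(n3), nk + ni + n1 + n2 + seq_len(n3))] <- -1
  blocks$ld <- Bk; rhs <- c(rhs, rep(lp$d_ld, n3))
  # phi_oar t <= D_OARmax (hard)
  if (n4 > 0) {
    Bk <- zeros(n4); Bk[, seq_len(nk)] <- lp$phi$oar
    blocks$oar <- Bk; rhs <- c(rhs, lev_oar)
  }
  # sum_c t(i,s,c) - tau_i <= 0
  Bk <- zeros(8 * ni)
  for (i in seq_len(ni)) for (s in 1:8) {
    r <- (i - 1) * 8 + s
    Bk[r, (i - 1) * 24 + (s - 1) * 3 + 1:3] <- 1
    Bk[r, nk + i] <- -1
  }
  blocks$sec <- Bk; rhs <- c(rhs, rep(0, 8 * ni))
  cvec <- c(rep(0, nk), rep(w$w_bot, ni), rep(w$w_t, n1), rep(w$w_s, n2),
            rep(w$w_ld, n3))
  list(c = cvec, A = do.call(rbind, blocks), b = rhs,
       l = rep(0, nv), u = rep(Inf, nv))
}
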