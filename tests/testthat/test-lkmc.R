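test_that("motion rates combine symmetric diffusion with upwind convection", {
  p <- lkmc_params()
  dx <- 6
  Ddx2 <- p$D_p * 100 / (dx / 1000)^2
  r0 <- motion_rates(c(0, 0), dx, p)
  expect_equal(unname(r0), rep(Ddx2, 4))
  r1 <- motion_rates(c(2, 0), dx, p)
  expect_equal(r1[["+x"]], Ddx2 + 2 / (dx / 1000))
  expect_equal(r1[["-x"]], Ddx2)
  expect_equal(r1[["+y"]], Ddx2)
  # fully caged platelet has zero motion rates
  rc <- motion_rates(c(2, 1), dx, p, blocked = rep(TRUE, 4))
  expect_true(all(rc == 0))
})

test_that("random-walk statistics recover the Einstein relation", {
  set.seed(101)
  p <- lkmc_params()
  dx_mm <- 6e-3
  db <- rate_database(motion_rates(c(0, 0), 6, p))
  M <- 2500L
  nhop <- 20L
  r2 <- numeric(M)
  tt <- numeric(M)
  step <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  for (m in seq_len(M)) {
    pos <- c(0, 0); t <- 0
    for (k in seq_len(nhop)) {
      ev <- select_execute(db)
      pos <- pos + step[ev$event, ]
      t <- t + ev$dt
    }
    r2[m] <- sum((pos * dx_mm)^2)
    tt[m] <- t
  }
  D_hat <- mean(r2) / (4 * mean(tt))        # 2 d D, d = 2
  expect_lt(abs(D_hat - p$D_p * 100) / (p$D_p * 100), 0.05)
})

test_that("a convected walker drifts at the fluid speed", {
  set.seed(7)
  p <- lkmc_params()
  u <- 1.5                                   # mm/s
  db <- rate_database(motion_rates(c(u, 0), 6, p))
  x <- 0; t <- 0
  step <- c(1, -1, 0, 0)
  for (k in seq_len(10000L)) {
    ev <- select_execute(db)
    x <- x + step[ev$event]
    t <- t + ev$dt
  }
  drift <- x * 6e-3 / t
  expect_lt(abs(drift - u) / u, 0.05)
})

test_that("rejection-free selection reproduces rate-weighted statistics", {
  set.seed(11)
  db <- rate_database(c(a = 1, b = 3))
  n <- 1e5L
  picks <- integer(n)
  dts <- numeric(n)
  for (i in seq_len(n)) {
    ev <- select_execute(db)
    picks[i] <- ev$event
    dts[i] <- ev$dt
  }
  # selection frequencies 0.25/0.75 within 3 sigma
  ph <- mean(picks == 2L)
  expect_lt(abs(ph - 0.75), 3 * sqrt(0.75 * 0.25 / n))
  # waiting times are exponential with mean 1/R_tot
  expect_lt(abs(mean(dts) - 1 / 4) / (1 / 4), 0.02)
  # quiescent database signals Inf waiting time
  q <- select_execute(rate_database(c(a = 0)))
  expect_true(is.na(q$event) && is.infinite(q$dt))
})

test_that("two-state attach/detach chain matches the analytic occupancy", {
  set.seed(5)
  katt <- 2; kdet <- 1
  bound <- FALSE; t_bound <- 0; t_tot <- 0
  for (i in seq_len(20000L)) {
    db <- rate_database(if (bound) c(detach = kdet) else c(attach = katt))
    ev <- select_execute(db)
    if (bound) t_bound <- t_bound + ev$dt
    t_tot <- t_tot + ev$dt
    bound <- !bound
  }
  expect_lt(abs(t_bound / t_tot - katt / (katt + kdet)), 0.02)
})

test_that("bond rates follow the slip-bond and vWF forms", {
  p <- lkmc_params()
  hp <- hill_params()
  b0 <- bond_rates(hp$alpha_min, 0, collagen = FALSE, p)
  # at zero shear the vWF factor is exactly 1: bare baseline rates
  expect_equal(b0$attach, p$k_att0 * hp$alpha_min)
  expect_equal(b0$detach, p$k_det0 / hp$alpha_min)
  bc <- bond_rates(0.5, 0, collagen = TRUE, p)
  expect_equal(bc$attach, p$k_att0_col * 0.5 * vwf_enhancement(0, p))
  expect_equal(bc$detach, p$k_det0_col / 0.5)
  expect_error(bond_rates(2, 100), "alpha")
  # vWF enhancement: >= 1, non-decreasing, midpoint inside 3000-8000/s
  g <- seq(0, 12000, by = 50)
  W <- vwf_enhancement(g, p)
  expect_true(all(W >= 1))
  expect_true(all(diff(W) >= 0))
  mid <- g[which.min(abs(W - (1 + p$W_max) / 2))]
  expect_gte(mid, 3000)
  expect_lte(mid, 8000)
  # shear loads break bonds: detach grows with gamma
  d1 <- bond_rates(0.5, 1000, params = p)$detach
  d2 <- bond_rates(0.5, 6000, params = p)$detach
  expect_gt(d2, d1)
})

test_that("the event engine is bit-reproducible and excludes double occupancy", {
  g <- build_cylinder(domain_spec("cylinder", spacing_um = 12, dim = 2))
  n <- prod(g$dims)
  vel <- uniform_velocity(g, 1)
  gam <- rep(200, n)
  run_once <- function() {
    set.seed(99)
    arr <- insert_inlet_platelets(g, vel, dt = 2, t0 = 0)
    np <- length(arr$time)
    lkmc_run_cpp(as.integer(g$flags), as.integer(g$dims), g$dim,
                 g$spacing / 1000, vel$u, gam,
                 rep(-1L, np), rep(0L, np),
                 rep(hill_params()$alpha_min, np), rep(FALSE, np),
                 arr$time, as.integer(arr$node), seq_len(np),
                 0, 2, thrombosim:::.lkmc_cpp_params(lkmc_params()), TRUE)
  }
  r1 <- run_once()
  r2 <- run_once()
  expect_identical(r1$ev_time, r2$ev_time)
  expect_identical(r1$ev_type, r2$ev_type)
  expect_identical(r1$pnode, r2$pnode)
  occ_nodes <- r1$pnode[r1$pnode >= 0]
  expect_false(any(duplicated(occ_nodes)))
})

test_that("inlet insertion recovers the configured mixing-cup concentration", {
  g <- build_cylinder(domain_spec("cylinder", spacing_um = 6, dim = 2))
  fl <- solve_flow(g, NULL, inlet_wall_shear = 200)
  p <- lkmc_params()
  set.seed(3)
  arr <- insert_inlet_platelets(g, fl$velocity, dt = 1, t0 = 0, p)
  expect_gt(arr$rate, 0)
  # dt = 0 -> no insertions
  a0 <- insert_inlet_platelets(g, fl$velocity, dt = 0, t0 = 0, p)
  expect_length(a0$time, 0)
  # uniform limit E = 1: rate equals C_bulk * Q exactly
  p1 <- lkmc_params(margination_E = 1)
  a1 <- insert_inlet_platelets(g, fl$velocity, dt = 1, t0 = 0, p1)
  face <- thrombosim:::.inlet_face(g, fl$velocity)
  Q_um3 <- sum(pmax(face$u, 0) * 1000) * g$spacing^2
  expect_equal(a1$rate, p$C_bulk / 1e9 * Q_um3, tolerance = 1e-12)
  # margination shifts arrivals toward the walls but leaves the rate alone
  expect_equal(arr$rate, a1$rate, tolerance = 1e-12)
})

test_that("empirical long-run mixing-cup concentration is within 3%", {
  g <- build_cylinder(domain_spec("cylinder", spacing_um = 6, dim = 2))
  fl <- solve_flow(g, NULL, inlet_wall_shear = 200)
  p <- lkmc_params()
  set.seed(10)
  lam <- insert_inlet_platelets(g, fl$velocity, dt = 1e-6, t0 = 0, p)$rate
  T_total <- 1e5 / lam
  n <- 0
  for (w in seq_len(100)) {
    n <- n + length(insert_inlet_platelets(g, fl$velocity,
                                           dt = T_total / 100, 0, p)$time)
  }
  face <- thrombosim:::.inlet_face(g, fl$velocity)
  Q_um3 <- sum(pmax(face$u, 0) * 1000) * g$spacing^2
  c_hat <- n / (Q_um3 * T_total) * 1e9      # back to 1/uL
  expect_lt(abs(c_hat - p$C_bulk) / p$C_bulk, 0.03)
})
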