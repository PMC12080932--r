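test_that("mass is conserved to machine precision in a closed box", {
  g <- make_channel_grid(30, 20, closed = TRUE)
  cf <- concentration_field(g)
  set.seed(1)
  open <- g$flags == flag_codes()[["fluid"]]
  cf$species$ADP[open] <- runif(sum(open))
  m0 <- total_mass(cf)[["ADP"]]
  cf2 <- step_cdr(cf, NULL, NULL, dt = cdr_stable_dt(NULL, g), g, nsub = 500L)
  expect_lt(abs(total_mass(cf2)[["ADP"]] - m0) / m0, 1e-12)
  expect_gte(min(cf2$species$ADP[open]), 0)
})

test_that("a point source deposits exactly q*T of mass in quiescent fluid", {
  g <- make_channel_grid(30, 20, closed = TRUE)
  p <- transport_params()
  cf <- concentration_field(g, p)
  pl <- data.frame(node = 305L, bound = TRUE, released = TRUE,
                   release_time = 0, id = 1L)
  src <- release_sources(pl, t_now = 0, g, p)
  q <- src$species$ADP[305]
  expect_gt(q, 0)
  dt <- cdr_stable_dt(NULL, g, p)
  cf2 <- step_cdr(cf, NULL, src, dt, g, p, nsub = 200L)
  expect_equal(total_mass(cf2)[["ADP"]], q * dt * 200, tolerance = 1e-12)
})

test_that("a pulse advects at the fluid speed with sub-cell centroid error", {
  p <- transport_params(D_ADP = 1e-12, D_TXA2 = 1e-12)
  g <- make_channel_grid(100, 9, spacing_um = 3)
  cf <- concentration_field(g, p)
  cf$species$ADP[20, 2:8] <- 1
  vel <- uniform_velocity(g, 2)
  dt <- 5e-4
  n <- 100L
  cf2 <- step_cdr(cf, vel, NULL, dt, g, p, nsub = n)
  centroid <- sum(seq_len(100) * rowSums(cf2$species$ADP)) /
    sum(cf2$species$ADP)
  expected <- 20 + 2 * dt * n / (g$spacing / 1000)
  expect_lt(abs(centroid - expected), 1)
  expect_equal(sum(cf2$species$ADP), 7, tolerance = 1e-12)
})

test_that("time steps violating the stability bound are rejected with the admissible dt", {
  g <- make_channel_grid(30, 9)
  vel <- uniform_velocity(g, 5)
  cf <- concentration_field(g)
  dt_ok <- cdr_stable_dt(vel, g)
  err <- expect_error(step_cdr(cf, vel, NULL, dt = dt_ok * 5, g),
                      "stability bound")
  expect_match(conditionMessage(err), "use dt <=")
})

test_that("per-step global balance closes: d(mass) = sources - outflow", {
  g <- make_channel_grid(60, 11)
  p <- transport_params()
  cf <- concentration_field(g, p)
  vel <- uniform_velocity(g, 1.5)
  pl <- data.frame(node = 300L, bound = TRUE, released = TRUE,
                   release_time = 0, id = 1L)
  src <- release_sources(pl, t_now = 2, g, p)
  dt <- cdr_stable_dt(vel, g, p)
  m0 <- total_mass(cf)[["ADP"]]
  for (i in 1:5) {
    cf <- step_cdr(cf, vel, src, dt, g, p, nsub = 50L)
    m1 <- total_mass(cf)[["ADP"]]
    bal <- (m1 - m0) -
      (attr(cf, "source_mass")[["ADP"]] - attr(cf, "outflow_mass")[["ADP"]])
    expect_lt(abs(bal), 1e-8 * max(m1, 1e-30))
    m0 <- m1
  }
  expect_gte(min(cf$species$ADP), 0)
})

test_that("release kinetics: first-order ADP bolus and constant TXA2 synthesis", {
  g <- make_channel_grid(20, 9)
  p <- transport_params()
  # no platelet above threshold -> all-zero source field
  none <- release_sources(data.frame(node = integer(0), bound = logical(0),
                                     released = logical(0),
                                     release_time = numeric(0),
                                     id = integer(0)), 10, g, p)
  expect_true(all(none$species$ADP == 0) && all(none$species$TXA2 == 0))
  # cumulative ADP release follows Q (1 - exp(-k t)); integrate the rate
  pl <- data.frame(node = 50L, bound = TRUE, released = TRUE,
                   release_time = 3, id = 1L)
  tt <- seq(3, 43, by = 0.01)
  rates <- vapply(tt, function(t)
    release_sources(pl, t, g, p)$species$ADP[50], numeric(1))
  cum <- sum(rates) * 0.01
  closed <- p$Q_ADP_uM * (1 - exp(-p$k_rel * 40))
  expect_equal(cum, closed, tolerance = 1e-3)
  # TXA2 rate is constant while bound and activated
  expect_equal(release_sources(pl, 5, g, p)$species$TXA2[50],
               release_sources(pl, 500, g, p)$species$TXA2[50])
  # additivity over platelets
  pl2 <- rbind(pl, data.frame(node = 51L, bound = TRUE, released = TRUE,
                              release_time = 7, id = 2L))
  s2 <- release_sources(pl2, 9, g, p)
  s1a <- release_sources(pl, 9, g, p)
  s1b <- release_sources(pl2[2, ], 9, g, p)
  expect_equal(s2$species$ADP, s1a$species$ADP + s1b$species$ADP)
})
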