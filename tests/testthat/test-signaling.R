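test_that("agonist input assembly applies the collagen and TXA2 equivalences", {
  A <- assemble_agonist_inputs(adp_uM = c(0, 5), txa2_uM = c(2, 0),
                               collagen_contact = c(TRUE, FALSE))
  expect_equal(A[1, "u46619"], c(u46619 = 30))       # 15 x [TXA2]
  expect_equal(A[1, "convulxin"], c(convulxin = 10)) # collagen contact
  expect_equal(A[2, "convulxin"], c(convulxin = 0))
  expect_equal(A[2, "adp"], c(adp = 5))
  expect_equal(unname(A[, "thrombin"]), c(0, 0))     # thrombin only under tf
})

test_that("scenario transforms zero or inject the right inputs", {
  mk <- function(sc) assemble_agonist_inputs(5, 1, TRUE, thrombin_nM = 7,
                                             scenario = sc)
  expect_equal(mk("no-adp")[1, "adp"], c(adp = 0))
  expect_equal(mk("no-adp")[1, "u46619"], c(u46619 = 15))
  expect_equal(mk("no-txa2")[1, "u46619"], c(u46619 = 0))
  expect_equal(mk("no-txa2")[1, "adp"], c(adp = 5))
  expect_equal(unname(mk("no-both")[1, c("adp", "u46619")]), c(0, 0))
  sp <- scenario_params()
  expect_equal(mk("gsno")[1, "gsno"], c(gsno = sp$gsno_uM))
  expect_equal(mk("iloprost")[1, "iloprost"], c(iloprost = sp$iloprost_nM))
  expect_equal(mk("tf")[1, "thrombin"], c(thrombin = 7))
  expect_equal(mk("control")[1, "thrombin"], c(thrombin = 0))
  expect_error(mk("aspirin"), "unknown scenario")
})

test_that("Hill adhesiveness satisfies its anchor identities and bounds", {
  hp <- hill_params(alpha_min = 0.01, alpha_max = 1, n = 2, xi50 = 20)
  expect_equal(hill_adhesiveness(0, hp), 0.01)
  expect_equal(hill_adhesiveness(hp$xi50, hp), (0.01 + 1) / 2)
  xi <- seq(0, 200, by = 0.5)
  F <- hill_adhesiveness(xi, hp)
  expect_true(all(diff(F) >= 0))
  expect_true(all(F >= hp$alpha_min - 1e-12 & F <= hp$alpha_max + 1e-12))
  # negative excursions of xi are treated as zero activation
  expect_equal(hill_adhesiveness(-5, hp), hp$alpha_min)
})

test_that("activation integrates supra-basal calcium exactly as written", {
  hp <- hill_params(xi50 = 10, xi_crit = 10)
  # constant supra-basal level c for T seconds gives xi = c T
  # (binary-exact increment so the crossing time is unambiguous)
  xi <- 0; rel <- FALSE; rt <- NA_real_
  for (t in 1:100) {
    u <- update_activation(xi, rel, rt, ca = 0.05 + 0.25, ca0 = 0.05,
                           dt = 1, t_now = t, pars = hp)
    xi <- u$xi; rel <- u$released; rt <- u$release_time
  }
  expect_equal(xi, 0.25 * 100)
  expect_true(rel)
  expect_equal(rt, 40)                     # 0.25 * 40 = 10 = xi_crit
  # basal calcium leaves xi at zero and F at alpha_min
  u0 <- update_activation(0, FALSE, NA_real_, 0.05, 0.05, 1, 1, hp)
  expect_equal(u0$xi, 0)
  expect_equal(u0$F, hp$alpha_min)
  # sub-basal excursions subtract (no rectification) but release is monotone
  u1 <- update_activation(12, TRUE, 3, ca = 0.01, ca0 = 0.05, dt = 1,
                          t_now = 60, pars = hp)
  expect_equal(u1$xi, 12 - 0.04)
  expect_true(u1$released)
  expect_equal(u1$release_time, 3)
})

test_that("the reduced thrombin curve has lag, monotone rise and TF scaling", {
  expect_equal(thrombin_curve(c(0, 10, 100), 0), c(0, 0, 0))
  expect_equal(thrombin_curve(0, 1), 0)
  tt <- seq(0, 600, by = 5)
  for (tf in c(0.25, 1, 4)) {
    th <- thrombin_curve(tt, tf)
    expect_true(all(diff(th) >= -1e-12))
  }
  # non-decreasing in TF density at fixed times
  sweep_tf <- seq(0, 5, by = 0.25)
  for (t in c(60, 180, 400)) {
    th <- vapply(sweep_tf, function(x) thrombin_curve(t, x), numeric(1))
    expect_true(all(diff(th) >= -1e-12))
  }
  expect_error(thrombin_curve(10, -1), "non-negative")
})

test_that("calcium prediction is a pure deterministic function of its inputs", {
  co <- get_test_cohort()
  m <- co$models[[1]]
  lag <- matrix(m$ca0, 3, 8)
  ag <- assemble_agonist_inputs(c(0, 1, 0), c(0, 0, 0.5),
                                c(TRUE, FALSE, FALSE))
  p1 <- predict_calcium(m, lag, ag)
  p2 <- predict_calcium(m, lag, ag)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0))
  bad <- m; bad$net <- NULL
  expect_error(predict_calcium(bad, lag, ag), "untrained")
})

test_that("rollouts pad lags with basal calcium before platelet entry", {
  co <- get_test_cohort()
  m <- co$models[[1]]
  tr <- rollout_calcium(m, rep(0, 6), 40)
  # resting platelet stays at the basal fixed point
  expect_true(all(abs(tr - m$ca0) < 0.2 * m$ca0))
})
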