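test_that("donor parameter draws are deterministic and seed-sensitive", {
  cfg <- cohort_config()
  d1 <- generate_donor(cfg, seed = 5)
  d2 <- generate_donor(cfg, seed = 5)
  d3 <- generate_donor(cfg, seed = 6)
  expect_identical(d1$amplitude, d2$amplitude)
  expect_identical(d1$synergy, d2$synergy)
  expect_false(identical(d1$amplitude, d3$amplitude))
  expect_true(all(unlist(d1[c("amplitude", "ec50", "tau_rise",
                              "tau_decay")]) > 0))
})

test_that("the cohort spans weak-to-strong collagen responders by construction", {
  cfg <- cohort_config()
  co <- generate_cohort(cfg, seed = 1)
  expect_length(co, cfg$n_donors)
  acvx <- vapply(co, function(d) d$amplitude[["convulxin"]], numeric(1))
  expect_gte(max(acvx) / min(acvx), 3)
})

test_that("generator traces obey their closed-form anchors", {
  cfg <- cohort_config()
  d <- generate_donor(cfg, seed = 9)
  # all doses zero -> flat basal trace
  z <- generator_trace(d, stats::setNames(as.list(rep(0, 6)),
                                          c("adp", "convulxin", "thrombin",
                                            "u46619", "iloprost", "gsno")))
  expect_true(all(z == d$ca0))
  # single agonist at its EC50 with no synergy: peak supra-basal = A/2
  d0 <- d
  d0$synergy[] <- 0
  dose <- list(adp = d0$ec50[["adp"]], convulxin = 0, thrombin = 0,
               u46619 = 0, iloprost = 0, gsno = 0)
  tr <- generator_trace(d0, dose)
  expect_equal(max(tr) - d0$ca0, d0$amplitude[["adp"]] / 2,
               tolerance = 1e-10)
  # saturating iloprost quenches any agonist mix
  dose$iloprost <- 1e5
  dose$convulxin <- 50
  tri <- generator_trace(d0, dose)
  expect_lt(max(tri) - d0$ca0, 1e-3)
  expect_error(generator_trace(d, list(adp = -1, convulxin = 0, thrombin = 0,
                                       u46619 = 0, iloprost = 0, gsno = 0)),
               "negative dose")
})

test_that("PAS panel covers basal, singles and all pairwise dose combinations", {
  cfg <- cohort_config()
  cond <- pas_conditions(cfg)
  expect_equal(sum(cond$type == "basal"), 1)
  expect_equal(sum(cond$type == "single"), 6 * length(cfg$dose_factors))
  expect_equal(sum(cond$type == "pair"),
               choose(6, 2) * length(cfg$dose_factors)^2)
  d <- generate_donor(cfg, seed = 3)
  pas <- simulate_pas_traces(d, cond, cfg, seed = 3)
  expect_equal(dim(pas$traces), c(nrow(cond), cfg$trace_len))
  expect_true(all(pas$traces >= 0))
  basal <- pas$traces[cond$type == "basal", ]
  expect_lt(max(abs(basal - d$ca0)), 5 * cfg$noise_sd)
})

test_that("training is bit-deterministic given its seed", {
  cfg <- cohort_config()
  d <- generate_donor(cfg, seed = 21)
  pas <- simulate_pas_traces(d, NULL, cfg, seed = 21)
  m1 <- train_donor_nn(pas, training_seed = 4, epochs = 150L)
  m2 <- train_donor_nn(pas, training_seed = 4, epochs = 150L)
  expect_identical(m1$net$W, m2$net$W)
  expect_identical(m1$provenance$holdout, m2$provenance$holdout)
})

test_that("trained surrogates are faithful on held-out pairwise conditions", {
  co <- get_test_cohort()
  nr <- vapply(co$models, function(m) mean(m$validation$holdout_nrmse),
               numeric(1))
  # cohort-level closed-loop fidelity; individual worst conditions
  # (agonist x intermediate-dose inhibitor interactions) run higher
  expect_lt(mean(nr), 0.15)
  expect_true(all(nr < 0.3))
  # resting platelet is a trained fixed point for every donor
  for (m in co$models) {
    r <- rollout_calcium(m, rep(0, 6), 60)
    expect_lt(max(abs(r - m$ca0)), 0.5 * m$ca0)
  }
})

test_that("threshold calibration hits the fast-donor anchor and spreads the cohort", {
  co <- get_test_cohort()
  tau <- co$cal$tau_crit
  expect_true(all(is.finite(tau)))          # every donor crosses by 360 s
  expect_gte(min(tau), 45)
  expect_lte(min(tau), 80)
  expect_gte(max(tau) / min(tau), 2)        # constructed heterogeneity
  # doubling xi_crit strictly delays every donor's crossing
  tau2 <- vapply(co$cal$xi_trajectories, function(xi) {
    i <- which(xi >= 2 * co$cal$xi_crit)
    if (length(i) == 0) NA_real_ else i[1]
  }, numeric(1))
  ok <- is.finite(tau2)
  expect_true(all(tau2[ok] > tau[ok]))
})

test_that("donor models survive a JSON round trip", {
  co <- get_test_cohort()
  m <- co$models[[2]]
  f <- tempfile(fileext = ".json")
  save_donor_model(m, f)
  m2 <- load_donor_model(f)
  lag <- matrix(m$ca0, 2, 8)
  ag <- assemble_agonist_inputs(c(1, 0), c(0, 0.3), c(FALSE, TRUE))
  expect_equal(predict_calcium(m, lag, ag), predict_calcium(m2, lag, ag),
               tolerance = 1e-12)
  unlink(f)
})
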