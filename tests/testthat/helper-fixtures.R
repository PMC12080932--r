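# Shared fixtures. Heavy artifacts (the trained synthetic cohort and the
# scenario matrix) are built once per test session and cached in this
# environment so several test files can share them.

.fixture_env <- new.env(parent = emptyenv())

# a bare rectangular lattice for solver unit tests: walls top/bottom,
# inlet/outlet open (or fully closed box)
make_channel_grid <- function(nx, ny, spacing_um = 6, closed = FALSE) {
  fl <- matrix(flag_codes()[["fluid"]], nx, ny)
  fl[, 1] <- flag_codes()[["wall"]]
  fl[, ny] <- flag_codes()[["wall"]]
  if (closed) {
    fl[1, ] <- flag_codes()[["wall"]]
    fl[nx, ] <- flag_codes()[["wall"]]
  } else {
    fl[1, 2:(ny - 1)] <- flag_codes()[["inlet"]]
    fl[nx, 2:(ny - 1)] <- flag_codes()[["outlet"]]
  }
  structure(list(flags = fl, spacing = spacing_um, dim = 2L,
                 dims = c(nx, ny),
                 spec = list(shape = "channel",
                             inlet_diameter_mm = (ny - 1) * spacing_um / 1000)),
            class = "lattice_grid")
}

uniform_velocity <- function(grid, ux_mms, uy_mms = 0) {
  n <- prod(grid$dims)
  structure(list(u = cbind(rep(ux_mms, n), rep(uy_mms, n)),
                 dims = grid$dims, spacing = grid$spacing, dim = grid$dim,
                 units = "mm/s"),
            class = "velocity_field")
}

# cohort configuration used by the calibration / scenario acceptance tests;
# these ARE the study conditions (10 donors, default generator medians)
test_cohort_config <- function() cohort_config()

# trained synthetic cohort (10 donors) + threshold calibration, built once
get_test_cohort <- function() {
  if (!is.null(.fixture_env$cohort)) return(.fixture_env$cohort)
  cfg <- test_cohort_config()
  donors <- generate_cohort(cfg, seed = 2024L)
  models <- lapply(donors, function(d) {
    pas <- simulate_pas_traces(d, NULL, cfg, seed = d$seed)
    train_donor_nn(pas, training_seed = d$seed)
  })
  cal <- calibrate_thresholds(models)
  models <- lapply(models, function(m) { m$hill <- cal$hill; m })
  .fixture_env$cohort <- list(config = cfg, donors = donors,
                              models = models, cal = cal)
  .fixture_env$cohort
}

# venous scenario-matrix configuration (reduced duration, coarse lattice;
# problem sizes documented in the methods vignette)
matrix_base_config <- function(hill) {
  simulation_config(domain_spec("cylinder", spacing_um = 12, dim = 2),
                    inlet_wall_shear = 200, donor = NULL,
                    scenario = "control", duration = 180, seed = 1L,
                    lkmc = lkmc_params(insert_window = 0.5),
                    hill = hill, max_transport_substeps = 3000L)
}

# full donor x scenario matrix over the calibrated cohort, built once
get_test_matrix <- function() {
  if (!is.null(.fixture_env$matrix)) return(.fixture_env$matrix)
  co <- get_test_cohort()
  base <- matrix_base_config(co$cal$hill)
  models <- co$models
  names(models) <- paste0("donor", seq_along(models))
  tab <- run_scenario_matrix(base, models,
                             scenarios = c("control", "no-txa2", "no-adp",
                                           "no-both", "gsno", "iloprost",
                                           "tf"),
                             seed = 77L)
  .fixture_env$matrix <- tab
  tab
}
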