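# Donor-specific platelet signaling: agonist input assembly, neural-network
# calcium prediction with lagged feedback, activation-state integration,
# Hill-function adhesiveness, and the reduced intra-clot thrombin curve.

# feedback lags (seconds before the current time) used by the calcium net
.CA_LAGS <- c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L)

# fixed scenario vocabulary
.SCENARIOS <- c("control", "no-adp", "no-txa2", "no-both", "gsno",
                "iloprost", "tf")

#' Scenario names understood by the simulator
#' @return Character vector of valid scenario identifiers.
#' @export
scenario_names <- function() .SCENARIOS

#' Hill-function platelet adhesiveness
#'
#' Maps the integrated activation state `xi` to the bond-formation propensity
#' `F(xi) = alpha_min + (alpha_max - alpha_min) xi^n / (xi^n + xi50^n)`,
#' where `n` controls the sharpness of the response and `xi50` is the
#' half-activation point.
#'
#' @param xi Activation state (uM s), any non-negative vector. Negative
#'   values (possible because supra-basal excursions are integrated without
#'   rectification) are treated as zero activation.
#' @param pars A [hill_params()].
#' @return Adhesiveness in `[alpha_min, alpha_max]`.
#' @export
hill_adhesiveness <- function(xi, pars = hill_params()) {
  x <- pmax(xi, 0)
  pars$alpha_min + (pars$alpha_max - pars$alpha_min) *
    x^pars$n / (x^pars$n + pars$xi50^pars$n)
}

#' Parameters of the adhesiveness Hill function and release threshold
#'
#' @param alpha_min,alpha_max Bounds of the adhesiveness (dimensionless).
#' @param n Hill coefficient (sharpness).
#' @param xi50 Half-activation state (uM s); typically set by
#'   [calibrate_thresholds()].
#' @param xi_crit Dense-granule release threshold (uM s); typically set by
#'   [calibrate_thresholds()].
#' @return A list of class `hill_params`.
#' @export
hill_params <- function(alpha_min = 0.01, alpha_max = 1.0, n = 2,
                        xi50 = 25, xi_crit = 25) {
  structure(list(alpha_min = alpha_min, alpha_max = alpha_max, n = n,
                 xi50 = xi50, xi_crit = xi_crit),
            class = "hill_params")
}

#' Assemble the six agonist inputs for the calcium network
#'
#' Maps the local simulation state to the network's input vector
#' (ADP uM, convulxin nM, thrombin nM, U46619 uM-equivalents, iloprost nM,
#' GSNO uM). Collagen contact is represented by the effective GPVI-activator
#' concentration convulxin = 10 nM; local TXA2 enters as U46619 = 15 x
#' [TXA2]. The scenario transform is applied last: agonist-inhibition
#' scenarios zero the corresponding input, antagonist scenarios add the
#' configured constant dose, and the tissue-factor scenario supplies the
#' intra-clot thrombin level (otherwise thrombin is zero).
#'
#' @param adp_uM,txa2_uM Local soluble agonist concentrations (uM), vectors.
#' @param collagen_contact Logical vector: platelet bound directly to a
#'   collagen node.
#' @param thrombin_nM Intra-clot thrombin (nM), scalar or vector; only used
#'   under the `tf` scenario.
#' @param scenario One of [scenario_names()].
#' @param pars A [scenario_params()].
#' @return Matrix with one row per platelet and columns
#'   `adp, convulxin, thrombin, u46619, iloprost, gsno`.
#' @export
assemble_agonist_inputs <- function(adp_uM, txa2_uM, collagen_contact,
                                    thrombin_nM = 0,
                                    scenario = "control",
                                    pars = scenario_params()) {
  if (!scenario %in% .SCENARIOS)
    stop("unknown scenario: ", scenario, call. = FALSE)
  n <- length(adp_uM)
  A <- cbind(adp = pmax(adp_uM, 0),
             convulxin = ifelse(collagen_contact, 10, 0),
             thrombin = 0,
             u46619 = 15 * pmax(txa2_uM, 0),
             iloprost = 0,
             gsno = 0)
  if (scenario %in% c("no-adp", "no-both")) A[, "adp"] <- 0
  if (scenario %in% c("no-txa2", "no-both")) A[, "u46619"] <- 0
  if (scenario == "gsno") A[, "gsno"] <- pars$gsno_uM
  if (scenario == "iloprost") A[, "iloprost"] <- pars$iloprost_nM
  if (scenario == "tf") A[, "thrombin"] <- rep(thrombin_nM, length.out = n)
  A
}

#' Constant antagonist doses and TF settings used by scenarios
#'
#' @param gsno_uM Constant GSNO exposure in the `gsno` scenario (uM).
#' @param iloprost_nM Constant iloprost exposure in the `iloprost` scenario
#'   (nM).
#' @param tf_density Wall tissue-factor density (molecules/um^2) driving the
#'   reduced thrombin curve in the `tf` scenario.
#' @return A list of class `scenario_params`.
#' @export
scenario_params <- function(gsno_uM = 2, iloprost_nM = 20, tf_density = 1) {
  structure(list(gsno_uM = gsno_uM, iloprost_nM = iloprost_nM,
                 tf_density = tf_density), class = "scenario_params")
}

# build the scaled 14-column design matrix from agonists and calcium lags;
# doses enter through the saturating receptor-occupancy transform c/(c+ref),
# which maps each input to [0, 1) on its own EC50-like scale
.nn_design <- function(model, agonists, lag_mat) {
  stopifnot(ncol(agonists) == 6, ncol(lag_mat) == length(.CA_LAGS))
  occ <- agonists / (agonists +
                       matrix(model$input_refs, nrow(agonists), 6, byrow = TRUE))
  occ[agonists == 0] <- 0
  cbind(occ, (lag_mat - model$ca0) / model$ca_ref)
}

#' Predict the next-second intracellular calcium for a set of platelets
#'
#' Evaluates the donor-specific feed-forward network on the 14-dimensional
#' input (six agonist concentrations at time t; calcium at t-1, t-2, t-4,
#' t-8, t-16, t-32, t-64, t-128 s, basal-padded before platelet entry) and
#' returns calcium at t + 1 s, clamped at zero. A pure function of its
#' inputs.
#'
#' @param model A trained `donor_model` (see [train_donor_nn()]).
#' @param lag_mat Matrix (platelets x 8) of lagged calcium values (uM).
#' @param agonists Matrix (platelets x 6) from [assemble_agonist_inputs()].
#' @return Numeric vector of predicted calcium (uM) at the next second.
#' @export
predict_calcium <- function(model, lag_mat, agonists) {
  if (is.null(model$net)) stop("donor model is untrained", call. = FALSE)
  X <- .nn_design(model, agonists, lag_mat)
  pmax(0, model$ca0 + model$ca_ref * as.numeric(nn_forward(model$net, X)))
}

#' Closed-loop calcium rollout under constant agonist exposure
#'
#' Iterates [predict_calcium()] from a basal trace: lag lookups before entry
#' return the basal level.
#'
#' @param model A `donor_model`.
#' @param agonists Length-6 agonist vector (constant exposure), or a
#'   `t_end` x 6 matrix for time-varying input.
#' @param t_end Number of seconds to roll out.
#' @return Numeric vector of calcium values at t = 1..t_end (uM).
#' @export
rollout_calcium <- function(model, agonists, t_end = 256L) {
  if (is.null(dim(agonists))) {
    as.numeric(rollout_panel(model, matrix(agonists, 1), t_end))
  } else {
    maxlag <- max(.CA_LAGS)
    tr <- rep(model$ca0, maxlag + t_end)
    for (t in seq_len(t_end)) {
      lags <- matrix(tr[maxlag + t - .CA_LAGS], 1)
      tr[maxlag + t] <- predict_calcium(model, lags,
                                        agonists[t, , drop = FALSE])
    }
    tr[(maxlag + 1):(maxlag + t_end)]
  }
}

#' Closed-loop rollouts for a panel of constant conditions
#'
#' Vectorized counterpart of [rollout_calcium()]: all conditions advance in
#' lockstep, one batched network evaluation per second.
#'
#' @param model A `donor_model`.
#' @param doses Matrix (conditions x 6) of constant agonist exposures.
#' @param t_end Number of seconds to roll out.
#' @return Matrix (conditions x t_end) of calcium values (uM).
#' @export
rollout_panel <- function(model, doses, t_end = 256L) {
  nc <- nrow(doses)
  maxlag <- max(.CA_LAGS)
  tr <- matrix(model$ca0, nc, maxlag + t_end)
  for (t in seq_len(t_end)) {
    lags <- tr[, maxlag + t - .CA_LAGS, drop = FALSE]
    tr[, maxlag + t] <- predict_calcium(model, lags, doses)
  }
  tr[, (maxlag + 1):(maxlag + t_end), drop = FALSE]
}

#' Integrate calcium into the activation state and adhesiveness
#'
#' Advances `xi` by `(Ca - Ca0) dt` exactly as written - negative supra-basal
#' excursions subtract; there is no rectification. Sets the (monotone)
#' released flag the first time `xi >= xi_crit` and recomputes the Hill
#' adhesiveness.
#'
#' @param xi Current activation states (uM s).
#' @param released Current release flags (logical).
#' @param release_time Current first-crossing times (s; NA if not crossed).
#' @param ca Calcium at this step (uM).
#' @param ca0 Basal calcium (uM), scalar or vector.
#' @param dt Signaling time step (s), nominally 1.
#' @param t_now Current time (s), recorded at first crossing.
#' @param pars A [hill_params()] carrying `xi50` and `xi_crit`.
#' @return List with updated `xi`, `F`, `released`, `release_time`.
#' @export
update_activation <- function(xi, released, release_time, ca, ca0, dt, t_now,
                              pars = hill_params()) {
  xi <- xi + (ca - ca0) * dt
  newly <- !released & xi >= pars$xi_crit
  released <- released | newly
  release_time[newly] <- t_now
  list(xi = xi, F = hill_adhesiveness(xi, pars), released = released,
       release_time = release_time)
}

#' Reduced intra-clot thrombin generation curve
#'
#' Spatially uniform thrombin concentration prescribed inside the clot under
#' the tissue-factor scenario: a lag phase of duration `t_lag(tf)` followed
#' by a smooth monotone rise to a plateau `T_max(tf)`, with the plateau
#' increasing and the lag shortening as the wall TF density grows, and
#' `T_max(0) = 0`. A parameterized surrogate for a reduced ODE description
#' of thrombin generation under venous flow.
#'
#' @param t Time since the start of the simulation (s), vector.
#' @param tf_density Wall TF density (molecules/um^2), non-negative.
#' @param T_plateau Saturating plateau scale (nM).
#' @param K_tf TF density giving half-maximal plateau (molecules/um^2).
#' @param t_lag0 Lag duration at vanishing TF (s).
#' @param tau_rise Rise time constant after the lag (s).
#' @return Thrombin concentration (nM) at each `t`.
#' @export
thrombin_curve <- function(t, tf_density, T_plateau = 6, K_tf = 0.5,
                           t_lag0 = 120, tau_rise = 60) {
  if (tf_density < 0) stop("tf_density must be non-negative", call. = FALSE)
  stopifnot(all(t >= 0))
  if (tf_density == 0) return(rep(0, length(t)))
  Tmax <- T_plateau * tf_density / (tf_density + K_tf)
  t_lag <- t_lag0 / (1 + tf_density / K_tf)
  s <- pmax(0, t - t_lag) / tau_rise
  Tmax * tanh(s)^2
}
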