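# Synthetic donor cohort: a stand-in for human pairwise-agonist-scanning
# (PAS) measurements. Each donor is a parameter set for a phenomenological
# calcium-response generator (dose-dependent amplitude, first-order rise and
# decay kinetics, pairwise synergy, multiplicative inhibitor suppression).
# Donor-specific neural networks are trained on the generated traces; the
# generator itself then serves as the independent oracle for the surrogate.

.AGONISTS <- c("adp", "convulxin", "thrombin", "u46619")
.INHIBITORS <- c("iloprost", "gsno")
.INPUTS <- c("adp", "convulxin", "thrombin", "u46619", "iloprost", "gsno")

#' Cohort-level configuration of the synthetic PAS generator
#'
#' Median parameters from which individual donors are drawn log-normally.
#' Amplitudes are supra-basal calcium peaks (uM); EC50s are in the native
#' input units (ADP uM, convulxin nM, thrombin nM, U46619 uM-equivalents,
#' iloprost nM, GSNO uM). The convulxin amplitude is additionally stratified
#' geometrically across the cohort (ratio `cvx_spread` between the strongest
#' and weakest collagen responder), which reproduces the wide spread of
#' collagen-driven activation times seen across healthy donors.
#'
#' @param n_donors Cohort size.
#' @param amplitude,ec50,hill_slope,tau_rise,tau_decay Named per-agonist
#'   medians (see defaults).
#' @param synergy_median Median pairwise synergy coefficient between
#'   excitatory agonists.
#' @param ic50,inhib_slope Named per-inhibitor medians.
#' @param ca0 Basal intracellular calcium (uM).
#' @param sigma_log Log-normal spread of most donor parameters.
#' @param sigma_log_gsno Larger spread of the GSNO IC50 (donor-to-donor
#'   nitric-oxide sensitivity varies strongly).
#' @param cvx_spread Constructed strongest/weakest convulxin amplitude ratio.
#' @param noise_sd Additive Gaussian measurement noise on traces (uM).
#' @param dose_factors Dose grid, as multiples of the cohort-median EC50
#'   (a fixed instrument panel shared by all donors).
#' @param trace_len Trace length (s) at 1 s resolution.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_donors = 10L,
                          amplitude = c(adp = 0.45, convulxin = 0.9,
                                        thrombin = 0.6, u46619 = 0.22),
                          ec50 = c(adp = 1, convulxin = 5, thrombin = 5,
                                   u46619 = 1),
                          hill_slope = c(adp = 1.5, convulxin = 1.5,
                                         thrombin = 1.5, u46619 = 1.5),
                          tau_rise = c(adp = 5, convulxin = 15, thrombin = 8,
                                       u46619 = 10),
                          tau_decay = c(adp = 150, convulxin = 250,
                                        thrombin = 90, u46619 = 60),
                          synergy_median = 0.25,
                          ic50 = c(iloprost = 2, gsno = 2),
                          inhib_slope = c(iloprost = 2, gsno = 2),
                          ca0 = 0.05, sigma_log = 0.25, sigma_log_gsno = 0.5,
                          cvx_spread = 4, noise_sd = 0.005,
                          dose_factors = c(0.1, 1, 10), trace_len = 256L) {
  structure(as.list(environment()), class = "cohort_config")
}

#' Draw one synthetic donor parameter set
#'
#' Deterministic given the seed: all kinetic constants are drawn log-normally
#' around the cohort medians. `cvx_multiplier` applies the cohort's
#' constructed collagen-responder stratification (see [generate_cohort()]).
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed for this donor.
#' @param cvx_multiplier Multiplier on the convulxin amplitude.
#' @param donor_id Identifier stored in the provenance block.
#' @return A list of class `synthetic_donor_params`.
#' @export
generate_donor <- function(config = cohort_config(), seed = 1L,
                           cvx_multiplier = 1, donor_id = seed) {
  set.seed(seed)
  ln <- function(med, sl = config$sigma_log)
    med * exp(rnorm(length(med), 0, sl))
  A <- ln(config$amplitude)
  A[["convulxin"]] <- A[["convulxin"]] * cvx_multiplier
  pairs <- utils::combn(.AGONISTS, 2)
  S <- stats::setNames(ln(rep(config$synergy_median, ncol(pairs))),
                       paste(pairs[1, ], pairs[2, ], sep = ":"))
  ic50 <- c(iloprost = ln(config$ic50[["iloprost"]]),
            gsno = ln(config$ic50[["gsno"]], config$sigma_log_gsno))
  structure(list(
    amplitude = A, ec50 = ln(config$ec50),
    hill_slope = ln(config$hill_slope, config$sigma_log / 2),
    tau_rise = ln(config$tau_rise), tau_decay = ln(config$tau_decay),
    synergy = S, ic50 = ic50, inhib_slope = config$inhib_slope,
    ca0 = config$ca0, donor_id = donor_id, seed = seed,
    cvx_multiplier = cvx_multiplier),
    class = "synthetic_donor_params")
}

#' Generate the synthetic donor cohort
#'
#' Donor i receives convulxin-amplitude multiplier
#' `cvx_spread^((i-1)/(n-1) - 1/2)` times a log-normal jitter, so the cohort
#' spans weak-to-strong collagen responders by construction.
#'
#' @param config A [cohort_config()].
#' @param seed Master seed.
#' @return List of `synthetic_donor_params`, length `n_donors`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  n <- config$n_donors
  lapply(seq_len(n), function(i) {
    mult <- config$cvx_spread^((i - 1) / (n - 1) - 0.5)
    generate_donor(config, seed = (seed * 1000L + i) %% 2147483647L,
                   cvx_multiplier = mult, donor_id = i)
  })
}

#' The PAS condition panel
#'
#' Single exposures of all six inputs at each dose factor, all pairwise
#' combinations of two inputs over the full dose-factor product, and one
#' basal (no agonist) record. Doses are multiples of the cohort-median EC50s
#' (the same instrument panel for every donor).
#'
#' @param config A [cohort_config()].
#' @return Data frame with one row per condition: columns `id`, `type`
#'   (`basal`/`single`/`pair`) and one dose column per input.
#' @export
pas_conditions <- function(config = cohort_config()) {
  ref <- c(config$ec50, config$ic50)[.INPUTS]
  rows <- list(c(id = 0, type = "basal",
                 stats::setNames(rep(0, 6), .INPUTS)))
  out <- data.frame(matrix(0, 0, 6, dimnames = list(NULL, .INPUTS)))
  doses <- expand.grid(a = .INPUTS, f = config$dose_factors,
                       stringsAsFactors = FALSE)
  singles <- do.call(rbind, lapply(seq_len(nrow(doses)), function(r) {
    v <- stats::setNames(rep(0, 6), .INPUTS)
    v[doses$a[r]] <- doses$f[r] * ref[[doses$a[r]]]
    v
  }))
  pr <- utils::combn(.INPUTS, 2)
  pairsl <- list()
  for (p in seq_len(ncol(pr))) {
    for (fa in config$dose_factors) for (fb in config$dose_factors) {
      v <- stats::setNames(rep(0, 6), .INPUTS)
      v[pr[1, p]] <- fa * ref[[pr[1, p]]]
      v[pr[2, p]] <- fb * ref[[pr[2, p]]]
      pairsl[[length(pairsl) + 1]] <- v
    }
  }
  basal <- stats::setNames(rep(0, 6), .INPUTS)
  m <- rbind(basal, singles, do.call(rbind, pairsl))
  df <- as.data.frame(m, row.names = FALSE)
  df$type <- c("basal", rep("single", nrow(singles)),
               rep("pair", length(pairsl)))
  df$id <- seq_len(nrow(df))
  df
}

# dose-response amplitude R_a and inhibitor factor for one condition
.generator_response <- function(donor, dose) {
  R <- vapply(.AGONISTS, function(a) {
    c <- dose[[a]]
    if (c <= 0) return(0)
    h <- donor$hill_slope[[a]]
    donor$amplitude[[a]] * c^h / (c^h + donor$ec50[[a]]^h)
  }, numeric(1))
  inhib <- 1
  for (i in .INHIBITORS) {
    c <- dose[[i]]
    if (c > 0) {
      s <- donor$inhib_slope[[i]]
      ic <- donor$ic50[[i]]
      inhib <- inhib * ic^s / (ic^s + c^s)
    }
  }
  list(R = R, inhib = inhib)
}

# rise-decay kernel normalized to unit peak on the standard discrete
# 0..255 s grid (the PAS trace grid), regardless of the evaluation times
.generator_kernel_peak <- function(tr, td) {
  g <- (1 - exp(-(0:255) / tr)) * exp(-(0:255) / td)
  max(g)
}

.generator_kernel <- function(tr, td, tt) {
  g <- (1 - exp(-tt / tr)) * exp(-tt / td)
  m <- .generator_kernel_peak(tr, td)
  if (m > 0) g / m else g
}

#' Generator calcium trace for one agonist condition
#'
#' The deterministic (noise-free) synthetic calcium response:
#' `Ca(t) = Ca0 + inhib * (sum_a R_a g_a(t) + sum_{a<b} S_ab min(R_a, R_b)
#' g_ab(t))`, where `R_a` is the Hill-type dose response, `g_a` a unit-peak
#' rise-decay kernel, `g_ab` the pair kernel (faster rise, slower decay of
#' the pair), and `inhib` the product of inhibitor Hill factors.
#'
#' @param donor A `synthetic_donor_params`.
#' @param dose Named length-6 dose vector (see [pas_conditions()] columns).
#' @param trace_len Trace length (s).
#' @return Numeric vector of calcium (uM) at t = 0..trace_len-1.
#' @export
generator_trace <- function(donor, dose, trace_len = 256L) {
  if (any(unlist(dose[.INPUTS]) < 0)) stop("negative dose", call. = FALSE)
  tt <- seq_len(trace_len) - 1
  resp <- .generator_response(donor, dose)
  total <- numeric(trace_len)
  for (a in .AGONISTS) {
    if (resp$R[[a]] > 0)
      total <- total + resp$R[[a]] *
        .generator_kernel(donor$tau_rise[[a]], donor$tau_decay[[a]], tt)
  }
  pr <- utils::combn(.AGONISTS, 2)
  for (p in seq_len(ncol(pr))) {
    a <- pr[1, p]; b <- pr[2, p]
    lo <- min(resp$R[[a]], resp$R[[b]])
    if (lo > 0) {
      S <- donor$synergy[[paste(a, b, sep = ":")]]
      g <- .generator_kernel(min(donor$tau_rise[[a]], donor$tau_rise[[b]]),
                             max(donor$tau_decay[[a]], donor$tau_decay[[b]]),
                             tt)
      total <- total + S * lo * g
    }
  }
  donor$ca0 + resp$inhib * total
}

#' Simulate a synthetic PAS dataset for one donor
#'
#' @param donor A `synthetic_donor_params`.
#' @param conditions Condition panel from [pas_conditions()].
#' @param config A [cohort_config()] (for noise and trace length).
#' @param seed Seed for the measurement noise.
#' @return A `pas_dataset`: list with the `conditions` data frame and a
#'   `traces` matrix (conditions x trace_len, uM, floored at zero).
#' @export
simulate_pas_traces <- function(donor, conditions = NULL,
                                config = cohort_config(), seed = 1L) {
  if (is.null(conditions)) conditions <- pas_conditions(config)
  stopifnot(nrow(conditions) > 0)
  set.seed(seed)
  tl <- config$trace_len
  traces <- matrix(0, nrow(conditions), tl)
  for (r in seq_len(nrow(conditions))) {
    tr <- generator_trace(donor, as.list(conditions[r, .INPUTS]), tl)
    if (config$noise_sd > 0)
      tr <- tr + rnorm(tl, 0, config$noise_sd)
    traces[r, ] <- pmax(tr, 0)
  }
  structure(list(conditions = conditions, traces = traces,
                 ca0 = donor$ca0, donor_id = donor$donor_id,
                 donor_seed = donor$seed),
            class = "pas_dataset")
}

# design matrix (agonists at t, calcium lags, basal-padded) and targets for
# supervised next-second prediction from a PAS dataset
.pas_design <- function(pas, input_refs, ca_ref) {
  tl <- ncol(pas$traces)
  nt <- tl - 1                         # predict t+1 for t = 0..tl-2
  nc <- nrow(pas$conditions)
  X <- matrix(0, nc * nt, 14)
  y <- numeric(nc * nt)
  cond_id <- integer(nc * nt)
  doses <- as.matrix(pas$conditions[, .INPUTS])
  for (r in seq_len(nc)) {
    tr <- pas$traces[r, ]
    rows <- (r - 1) * nt + seq_len(nt)
    occ <- doses[r, ] / (doses[r, ] + input_refs)
    occ[doses[r, ] == 0] <- 0
    ag <- matrix(occ, nt, 6, byrow = TRUE)
    lag <- matrix(pas$ca0, nt, length(.CA_LAGS))
    for (li in seq_along(.CA_LAGS)) {
      l <- .CA_LAGS[li]
      tcur <- seq_len(nt) - 1           # current times t
      src <- tcur - l                   # lag times
      ok <- src >= 0
      lag[ok, li] <- tr[src[ok] + 1]
    }
    X[rows, ] <- cbind(ag, (lag - pas$ca0) / ca_ref)
    y[rows] <- (tr[2:tl] - pas$ca0) / ca_ref
    cond_id[rows] <- r
  }
  list(X = X, y = y, cond_id = cond_id)
}

# normalized RMSE: RMSE over the dynamic range of the reference trace; for
# near-flat traces the range is floored at `floor_rng` (by default callers
# pass 10% of the donor's full-panel dynamic range) so fidelity on
# low-response conditions is judged against the instrument scale
.nrmse <- function(pred, truth, floor_rng) {
  rng <- max(diff(range(truth)), floor_rng)
  sqrt(mean((pred - truth)^2)) / rng
}

#' Train a donor-specific calcium network on a PAS dataset
#'
#' Feed-forward net with input = 6 agonist doses + 8 lagged calcium values,
#' two tanh processing layers of 12 nodes (a single-hidden-layer reading of
#' the architecture is available via `hidden`), linear scalar output:
#' calcium at the next second. Training is full-batch Adam with fixed epochs
#' and seed, hence bit-deterministic. 20% of the pairwise conditions are
#' held out (split by condition) and the model's closed-loop rollout NRMSE
#' on them is stored in `$validation`.
#'
#' @param pas A `pas_dataset` (must include the basal record).
#' @param hidden Hidden layer sizes; default `c(12, 12)`.
#' @param training_seed Seed controlling initialization and the holdout
#'   split.
#' @param epochs,lr Adam schedule.
#' @param input_refs Fixed per-input scale divisors (native units); default
#'   is the cohort-median EC50 panel.
#' @param ca_ref Calcium scale divisor (uM).
#' @return A `donor_model`: network weights, basal level, scales, Hill/
#'   threshold parameters (filled by [calibrate_thresholds()]), provenance.
#' @export
train_donor_nn <- function(pas, hidden = c(12, 12), training_seed = 1L,
                           epochs = 6000L, lr = 8e-3,
                           input_refs = c(adp = 1, convulxin = 5,
                                          thrombin = 5, u46619 = 1,
                                          iloprost = 2, gsno = 2),
                           ca_ref = 0.5) {
  stopifnot(inherits(pas, "pas_dataset"))
  if (!any(pas$conditions$type == "basal"))
    stop("PAS dataset must include a basal record", call. = FALSE)
  set.seed(training_seed)
  des <- .pas_design(pas, input_refs, ca_ref)
  pair_ids <- pas$conditions$id[pas$conditions$type == "pair"]
  n_hold <- floor(0.2 * length(pair_ids))
  hold <- sort(sample(pair_ids, n_hold))
  train_rows <- !(des$cond_id %in% hold)
  # emphasize the basal record so the resting state is a trained fixed point
  w <- rep(1, sum(train_rows))
  basal_id <- pas$conditions$id[pas$conditions$type == "basal"][1]
  w[des$cond_id[train_rows] == basal_id] <- 20
  net <- nn_init(14L, hidden)
  net <- nn_train(net, des$X[train_rows, , drop = FALSE],
                  des$y[train_rows], epochs = epochs, lr = lr, sample_w = w,
                  noise_cols = 7:14, noise_sd = 0.12, batch_size = 2048L)
  if (!all(is.finite(net$loss)))
    stop("training diverged; loss history attached", call. = FALSE)
  model <- structure(list(net = net, ca0 = pas$ca0, ca_ref = ca_ref,
                          input_refs = input_refs, type = "nn",
                          hill = hill_params(),
                          provenance = list(donor_id = pas$donor_id,
                                            donor_seed = pas$donor_seed,
                                            training_seed = training_seed,
                                            hidden = hidden,
                                            epochs = epochs, lr = lr,
                                            holdout = hold)),
                     class = "donor_model")
  # closed-loop rollout fidelity on the held-out pairwise conditions
  tl <- ncol(pas$traces)
  floor_rng <- 0.1 * diff(range(pas$traces))
  hrows <- match(hold, pas$conditions$id)
  preds <- rollout_panel(model, as.matrix(pas$conditions[hrows, .INPUTS]), tl)
  nr <- vapply(seq_along(hold), function(i) {
    .nrmse(preds[i, -tl], pas$traces[hrows[i], -1], floor_rng)
  }, numeric(1))
  model$validation <- list(holdout_nrmse = nr,
                           final_loss = tail(net$loss, 1))
  model
}

#' Calibrate the cohort-wide activation thresholds
#'
#' Chooses a single `(xi50, xi_crit)` for the whole cohort by bisection on
#' `xi_crit` so that, under constant collagen stimulation (convulxin 10 nM,
#' everything else basal), the fastest donor's first dense-granule release
#' time is ~60 s; the constructed cohort heterogeneity then spreads the
#' remaining donors' crossing times up to the several-minute scale. `xi50`
#' is tied to `xi_crit/3`: integrin activation (adhesiveness) precedes
#' dense-granule secretion, so a platelet is already strongly adhesive when
#' it starts releasing. Donors that never cross within `t_max` are reported.
#'
#' @param models List of trained `donor_model`s.
#' @param t_fast Target first-crossing time of the fastest donor (s).
#' @param t_max Simulation horizon for the calibration rollout (s).
#' @param hill A [hill_params()] supplying `alpha_min`, `alpha_max`, `n`.
#' @return List with `xi50`, `xi_crit`, `tau_crit` (per donor, NA if no
#'   crossing), and the per-donor activation integrals.
#' @export
calibrate_thresholds <- function(models, t_fast = 60, t_max = 360,
                                 hill = hill_params()) {
  stim <- c(adp = 0, convulxin = 10, thrombin = 0, u46619 = 0,
            iloprost = 0, gsno = 0)
  xi_traj <- lapply(models, function(m) {
    ca <- as.numeric(rollout_panel(m, matrix(stim, 1), t_max))
    cumsum(ca - m$ca0)
  })
  tau_of <- function(xi, xc) {
    i <- which(xi >= xc)
    if (length(i) == 0) NA_real_ else i[1]
  }
  xi_hi <- max(vapply(xi_traj, max, numeric(1)))
  if (xi_hi <= 0) stop("no donor exceeds basal calcium under collagen",
                       call. = FALSE)
  lo <- 0; hi <- xi_hi
  for (it in seq_len(60)) {
    mid <- (lo + hi) / 2
    tmin <- min(vapply(xi_traj, tau_of, numeric(1), xc = mid), na.rm = TRUE)
    if (is.finite(tmin) && tmin < t_fast) lo <- mid else hi <- mid
  }
  xi_crit <- (lo + hi) / 2
  tau <- vapply(xi_traj, tau_of, numeric(1), xc = xi_crit)
  if (all(is.na(tau)))
    stop(sprintf("unattainable span: no donor crosses within %d s", t_max),
         call. = FALSE)
  if (any(is.na(tau)))
    warning(sprintf("%d donor(s) never cross xi_crit within %d s; reported as non-crossing",
                    sum(is.na(tau)), t_max))
  list(xi50 = xi_crit / 3, xi_crit = xi_crit, tau_crit = tau,
       xi_trajectories = xi_traj,
       hill = hill_params(hill$alpha_min, hill$alpha_max, hill$n,
                          xi50 = xi_crit / 3, xi_crit = xi_crit))
}

#' Serialize a donor model to JSON
#'
#' Writes the named weight arrays, basal level, scales, Hill/threshold
#' parameters and provenance block to a portable JSON file.
#'
#' @param model A `donor_model`.
#' @param path Output file path.
#' @export
save_donor_model <- function(model, path) {
  obj <- list(W = lapply(model$net$W, unclass),
              b = model$net$b, sizes = model$net$sizes,
              ca0 = model$ca0, ca_ref = model$ca_ref,
              input_refs = as.list(model$input_refs),
              hill = unclass(model$hill), type = model$type,
              provenance = model$provenance)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a donor model from JSON
#'
#' @param path File written by [save_donor_model()].
#' @return A `donor_model`.
#' @export
load_donor_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- list(W = lapply(obj$W, as.matrix), b = lapply(obj$b, as.numeric),
              sizes = obj$sizes)
  structure(list(net = net, ca0 = obj$ca0, ca_ref = obj$ca_ref,
                 input_refs = unlist(obj$input_refs),
                 hill = do.call(hill_params, as.list(obj$hill)),
                 type = obj$type, provenance = obj$provenance),
            class = "donor_model")
}
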