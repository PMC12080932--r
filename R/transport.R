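# Soluble agonist transport: coupled convection-diffusion-reaction equations
# for ADP and TXA2 with sources at sufficiently activated bound platelets.
# Bound-platelet nodes are treated as zero-velocity pore cells, so released
# agonist accumulates inside the porous clot; only vessel walls are no-flux.

#' Transport parameters for the agonist CDR solver
#'
#' @param D_ADP,D_TXA2 Species diffusivities (cm^2/s). Literature small-
#'   molecule values are used by default.
#' @param Q_ADP_uM Total releasable dense-granule ADP of one bound platelet
#'   voxel, expressed as the concentration it would produce released into
#'   its own lattice cell (uM). A voxel stands for a platelet-rich volume
#'   element, so this parametrization keeps local signaling concentrations
#'   invariant under lattice coarsening.
#' @param k_rel First-order ADP release rate after the activation threshold is
#'   crossed (1/s).
#' @param q_TXA2_uMs Constant TXA2 synthesis rate of a bound, activated
#'   platelet voxel, as local cell concentration per second (uM/s).
#' @param cfl Safety factor applied to the explicit stability bound.
#' @param u_cap_mms Advective face velocities are capped at this magnitude
#'   (mm/s). Regions above the cap are concentration-free jet cores where
#'   washout is effectively instantaneous at either speed; the cap keeps
#'   the explicit CFL bound (and hence the substep count) set by the
#'   signaling-relevant near-wall flow rather than by the stenotic jet.
#' @return A list of class `transport_params`.
#' @export
transport_params <- function(D_ADP = 2.4e-6, D_TXA2 = 2.1e-6,
                             Q_ADP_uM = 100, k_rel = 0.05,
                             q_TXA2_uMs = 0.1, cfl = 0.9, u_cap_mms = 25) {
  structure(list(D = c(ADP = D_ADP, TXA2 = D_TXA2),
                 Q_ADP_uM = Q_ADP_uM, k_rel = k_rel,
                 q_TXA2_uMs = q_TXA2_uMs, cfl = cfl, u_cap_mms = u_cap_mms),
            class = "transport_params")
}

#' Create an all-zero concentration field
#'
#' @param grid A `lattice_grid`.
#' @param params A [transport_params()].
#' @return A `concentration_field` holding one array (uM) per species.
#' @export
concentration_field <- function(grid, params = transport_params()) {
  stopifnot(inherits(grid, "lattice_grid"))
  structure(list(species = list(ADP = array(0, grid$dims),
                                TXA2 = array(0, grid$dims)),
                 D = params$D, dims = grid$dims, spacing = grid$spacing,
                 dim = grid$dim),
            class = "concentration_field")
}

# solid mask for transport: walls and collagen only (clot is porous)
.transport_flags <- function(grid) {
  fl <- grid$flags
  fl[fl == .FLAG[["collagen"]]] <- .FLAG[["wall"]]
  fl
}

#' Largest stable explicit time step for the CDR scheme
#'
#' Minimum over species of the advective CFL bound (sum over axes of
#' `|u_a|/dx <= 1/dt`) and the diffusive bound `dx^2 / (2 d D)`, scaled by
#' the configured safety factor.
#'
#' @param velocity A `velocity_field` (mm/s), or NULL for pure diffusion.
#' @param grid A `lattice_grid`.
#' @param params A [transport_params()].
#' @return Stable dt in seconds.
#' @export
cdr_stable_dt <- function(velocity, grid, params = transport_params()) {
  dx <- grid$spacing / 1000                       # mm
  Dmax <- max(params$D) * 100                     # cm^2/s -> mm^2/s
  dt_diff <- dx^2 / (2 * grid$dim * Dmax)
  dt_adv <- Inf
  if (!is.null(velocity)) {
    cap <- params$u_cap_mms %||% Inf
    u <- pmin(pmax(velocity$u, -cap), cap)
    s <- rowSums(abs(u)) / dx                     # sum_a |u_a|/dx per node
    if (max(s) > 0) dt_adv <- 1 / max(s)
  }
  params$cfl * min(dt_diff, dt_adv)
}

#' Advance the agonist concentration fields by one time step
#'
#' One explicit finite-volume step of
#' `dc/dt + div(u c) = D laplacian(c) + S` for every species, with
#' first-order upwind advection, no-flux walls, zero concentration at the
#' inlet and convective outflow at the outlet. The flux-form update is
#' exactly conservative and positivity-preserving under the stability bound.
#'
#' @param conc A `concentration_field`.
#' @param velocity A `velocity_field` (mm/s) or NULL (quiescent fluid).
#' @param src A source field from [release_sources()], or NULL.
#' @param dt Time step (s); must satisfy the stability bound of
#'   [cdr_stable_dt()] (with safety factor 1), else an error names the
#'   admissible step.
#' @param grid The `lattice_grid`.
#' @param params A [transport_params()].
#' @param nsub Number of identical substeps of length `dt` to take.
#' @return The updated `concentration_field`, with attributes
#'   `outflow_mass` and `source_mass` (uM x cell volume units, per species).
#' @export
step_cdr <- function(conc, velocity, src = NULL, dt, grid,
                     params = transport_params(), nsub = 1L) {
  stopifnot(inherits(conc, "concentration_field"))
  p1 <- params; p1$cfl <- 1
  dt_max <- cdr_stable_dt(velocity, grid, p1)
  if (dt > dt_max * (1 + 1e-9))
    stop(sprintf("dt = %.3g s violates the explicit stability bound; use dt <= %.3g s",
                 dt, dt_max), call. = FALSE)
  fl <- .transport_flags(grid)
  n <- prod(grid$dims)
  zero <- numeric(n)
  u <- if (is.null(velocity)) NULL else {
    cap <- params$u_cap_mms %||% Inf
    pmin(pmax(velocity$u, -cap), cap)
  }
  ux <- if (is.null(u)) zero else u[, 1]
  uy <- if (is.null(u)) zero else u[, 2]
  uz <- if (!is.null(u) && grid$dim == 3L) u[, 3] else zero
  outm <- srcm <- c(ADP = 0, TXA2 = 0)
  for (sp in names(conc$species)) {
    D_mm <- conc$D[[sp]] * 100
    s <- if (is.null(src)) zero else as.numeric(src$species[[sp]])
    res <- cdr_steps_cpp(as.numeric(conc$species[[sp]]), as.integer(fl),
                         ux, uy, uz, as.integer(grid$dims), grid$dim,
                         grid$spacing / 1000, D_mm, s, dt, as.integer(nsub))
    conc$species[[sp]] <- array(res$conc, grid$dims)
    outm[sp] <- res$outflow_mass
    srcm[sp] <- res$source_mass
  }
  attr(conc, "outflow_mass") <- outm
  attr(conc, "source_mass") <- srcm
  conc
}

#' Total dissolved mass per species
#'
#' @param conc A `concentration_field`.
#' @return Named numeric vector, in uM x cell-volume units (divide by the
#'   number of cells for the mean concentration).
#' @export
total_mass <- function(conc) {
  vapply(conc$species, sum, numeric(1))
}

#' Agonist source field from the current platelet population
#'
#' Platelets whose activation state has crossed the release threshold act as
#' point sources at their lattice node: ADP leaves the dense granules by
#' first-order kinetics from the crossing time (cumulative release
#' `Q_ADP (1 - exp(-k_rel (t - t0)))`), while TXA2 is synthesized at a
#' constant rate for as long as the platelet remains bound and activated.
#'
#' @param platelets Data frame with columns `node` (linear node index),
#'   `bound` (logical), `released` (logical) and `release_time` (s, NA if
#'   never crossed).
#' @param t_now Current simulation time (s).
#' @param grid The `lattice_grid`.
#' @param params A [transport_params()].
#' @return A `source_field`: per-species arrays of release rates (uM/s) plus
#'   a `provenance` data frame tagging each source node with its platelet.
#' @export
release_sources <- function(platelets, t_now, grid,
                            params = transport_params()) {
  adp <- array(0, grid$dims)
  txa2 <- array(0, grid$dims)
  act <- which(platelets$bound & platelets$released)
  if (length(act) > 0) {
    nodes <- platelets$node[act]
    dt0 <- pmax(0, t_now - platelets$release_time[act])
    r_adp <- params$Q_ADP_uM * params$k_rel * exp(-params$k_rel * dt0)
    for (ii in seq_along(act)) {
      adp[nodes[ii]] <- adp[nodes[ii]] + r_adp[ii]
      txa2[nodes[ii]] <- txa2[nodes[ii]] + params$q_TXA2_uMs
    }
  }
  structure(list(species = list(ADP = adp, TXA2 = txa2),
                 provenance = data.frame(
                   node = if (length(act)) platelets$node[act] else integer(0),
                   platelet = if (length(act)) platelets$id[act] else integer(0))),
            class = "source_field")
}
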