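# Lattice kinetic Monte Carlo platelet dynamics: motion rates from diffusion
# plus upwind convection, activation- and shear-dependent bond rates with the
# vWF high-shear enhancement, rejection-free event selection, and
# flux-matched inlet insertion with a near-wall (marginated) excess.

#' Parameters of the platelet LKMC model
#'
#' @param D_p Platelet effective diffusivity (cm^2/s); RBC-augmented value.
#' @param k_att0 Baseline platelet-platelet attachment rate prefactor (1/s).
#' @param k_att0_col Baseline platelet-collagen attachment prefactor (1/s);
#'   collagen (GPVI/vWF) capture is much faster than aggregate growth.
#' @param k_det0 Baseline platelet-platelet detachment prefactor (1/s).
#' @param k_det0_col Baseline platelet-collagen detachment prefactor (1/s).
#' @param gamma_c Slip-bond shear scale (1/s): detachment grows as
#'   `exp(gamma/gamma_c)`.
#' @param W_max Maximal vWF attachment enhancement at pathological shear.
#' @param gamma_vwf Midpoint of the vWF conformational switch (1/s), within
#'   the 3000-8000 1/s window.
#' @param s_vwf Width of the switch (1/s).
#' @param C_bulk Bulk platelet concentration (1/uL).
#' @param margination_E Near-wall excess factor of the inlet concentration.
#' @param margination_delta Near-wall excess boundary-layer thickness (um).
#' @param insert_window Fraction of the inlet cross-section, measured from
#'   the reactive (bottom) wall, in which platelets are actually inserted
#'   (2D). At the simulated Peclet numbers platelets starting beyond a few
#'   tens of microns from the reactive wall can never reach it within their
#'   transit time, so restricting insertion to a window is an exact
#'   importance restriction that only removes pass-through events. 1 = full
#'   cross-section.
#' @export
lkmc_params <- function(D_p = 2.5e-7, k_att0 = 2, k_att0_col = 500,
                        k_det0 = 2e-4, k_det0_col = 1e-5,
                        gamma_c = 1200, W_max = 20, gamma_vwf = 3500,
                        s_vwf = 500, C_bulk = 1.5e5,
                        margination_E = 4, margination_delta = 10,
                        insert_window = 1) {
  structure(list(D_p = D_p, k_att0 = k_att0, k_att0_col = k_att0_col,
                 k_det0 = k_det0, k_det0_col = k_det0_col,
                 gamma_c = gamma_c, W_max = W_max, gamma_vwf = gamma_vwf,
                 s_vwf = s_vwf, C_bulk = C_bulk,
                 margination_E = margination_E,
                 margination_delta = margination_delta,
                 insert_window = insert_window),
            class = "lkmc_params")
}

# parameter list handed to the C++ engine
.lkmc_cpp_params <- function(params) {
  list(D_p_mm2s = params$D_p * 100, k_att0 = params$k_att0,
       k_att0_col = params$k_att0_col, k_det0 = params$k_det0,
       k_det0_col = params$k_det0_col, gamma_c = params$gamma_c,
       W_max = params$W_max, gamma_vwf = params$gamma_vwf,
       s_vwf = params$s_vwf)
}

#' vWF shear enhancement factor
#'
#' Smooth sigmoidal switch rising from exactly 1 at zero shear to `W_max`
#' across the 3000-8000 1/s window where vWF elongates (a logistic in
#' `gamma`, baseline-normalized so quiescent fluid carries no enhancement).
#'
#' @param gamma Local shear rate (1/s), vectorized.
#' @param params An [lkmc_params()].
#' @return Enhancement factor `>= 1`, non-decreasing in `gamma`.
#' @export
vwf_enhancement <- function(gamma, params = lkmc_params()) {
  s0 <- stats::plogis(-params$gamma_vwf / params$s_vwf)
  s <- stats::plogis((gamma - params$gamma_vwf) / params$s_vwf)
  1 + (params$W_max - 1) * pmax(0, s - s0) / (1 - s0)
}

#' Directional motion rates of a mobile platelet
#'
#' Upwind convection added to symmetric diffusion:
#' `rate(+e) = D_p/dx^2 + max(0, u.e)/dx`; rates into walls or occupied
#' nodes are zero.
#'
#' @param u Local fluid velocity (mm/s), length-`d` vector.
#' @param dx_um Lattice spacing (um).
#' @param params An [lkmc_params()].
#' @param blocked Logical vector of length `2d` (+x, -x, +y, -y, ...) marking
#'   directions whose target node is a wall or occupied.
#' @return Named rate vector (1/s), one entry per direction.
#' @export
motion_rates <- function(u, dx_um, params = lkmc_params(),
                         blocked = rep(FALSE, 2 * length(u))) {
  d <- length(u)
  dx <- dx_um / 1000                    # mm
  Dd <- params$D_p * 100 / dx^2         # cm^2/s -> mm^2/s
  r <- numeric(2 * d)
  for (a in seq_len(d)) {
    r[2 * a - 1] <- Dd + max(0, u[a]) / dx
    r[2 * a] <- Dd + max(0, -u[a]) / dx
  }
  r[blocked] <- 0
  axes <- c("x", "y", "z")[seq_len(d)]
  names(r) <- as.vector(rbind(paste0("+", axes), paste0("-", axes)))
  r
}

#' Attachment and detachment rates of a platelet
#'
#' `attach = k_att0 * F * W(gamma)` (with the larger collagen prefactor for
#' collagen bonds) and `detach = k_det0 * (1/F) * exp(gamma/gamma_c) /
#' W(gamma)`: activation strengthens bonds, shear loads break them
#' (slip-bond exponential, saturated at eight shear scales), and elongated
#' vWF both boosts capture and stabilizes existing bonds across the same
#' 3000-8000 1/s conformational switch. For bound platelets the engine
#' evaluates `gamma` as the surface traction (the largest shear rate over
#' adjacent fluid nodes), since the platelet's own node is a no-slip solid.
#'
#' @param F Platelet adhesiveness from the Hill map, in
#'   `[alpha_min, alpha_max]`.
#' @param gamma Local shear rate (1/s).
#' @param collagen Logical: is this a platelet-collagen bond?
#' @param params An [lkmc_params()].
#' @param alpha_min,alpha_max Admissible adhesiveness bounds.
#' @return List with `attach` and `detach` rates (1/s), vectorized over `F`
#'   and `gamma`.
#' @export
bond_rates <- function(F, gamma, collagen = FALSE, params = lkmc_params(),
                       alpha_min = 0.01, alpha_max = 1.0) {
  if (any(F < alpha_min - 1e-12 | F > alpha_max + 1e-12))
    stop("F outside [alpha_min, alpha_max]", call. = FALSE)
  W <- vwf_enhancement(gamma, params)
  katt <- if (collagen) params$k_att0_col else params$k_att0
  kdet <- if (collagen) params$k_det0_col else params$k_det0
  list(attach = katt * F * W,
       detach = kdet * (1 / F) * exp(pmin(gamma / params$gamma_c, 8)) / W)
}

#' Construct a rate database
#'
#' Event catalog for rejection-free selection: every possible event with its
#' current rate. The engine-internal database uses a Fenwick tree over
#' platelets; this R-level object serves the same selection contract for
#' small systems and statistical verification.
#'
#' @param rates Named numeric vector of non-negative event rates (1/s).
#' @return A `rate_database` with elements `rates` and `total`.
#' @export
rate_database <- function(rates) {
  stopifnot(is.numeric(rates), all(rates >= 0))
  structure(list(rates = rates, total = sum(rates)), class = "rate_database")
}

#' Select and clock the next event (rejection-free KMC step)
#'
#' Chooses an event with probability `rate/R_tot` and advances the clock by
#' an exponential waiting time `dt = -log(r)/R_tot`.
#'
#' @param db A [rate_database()].
#' @return List with `event` (index), `name`, `dt` (s), and `rate`. If the
#'   total rate is zero, returns `event = NA` and `dt = Inf` (quiescent:
#'   advance to the next scheduled insertion).
#' @export
select_execute <- function(db) {
  stopifnot(inherits(db, "rate_database"))
  if (db$total <= 0)
    return(list(event = NA_integer_, name = NA_character_, dt = Inf,
                rate = 0))
  i <- findInterval(stats::runif(1) * db$total, cumsum(db$rates)) + 1L
  i <- min(i, length(db$rates))
  dt <- -log(stats::runif(1)) / db$total
  list(event = i, name = names(db$rates)[i], dt = dt, rate = db$rates[[i]])
}

# open (insertable) nodes of the first fluid column, their linear indices
# and the axial velocity (mm/s) they see
.inlet_face <- function(grid, velocity) {
  ux <- array(velocity$u[, 1], grid$dims)
  if (grid$dim == 2L) {
    j <- which(grid$flags[2, ] != .FLAG[["wall"]] &
                 grid$flags[2, ] != .FLAG[["collagen"]])
    list(node = 2L + (j - 1L) * grid$dims[1],
         u = ux[cbind(2L, j)],
         pos = cbind(y = (j - 1) * grid$spacing))
  } else {
    jk <- which(grid$flags[2, , ] != .FLAG[["wall"]] &
                  grid$flags[2, , ] != .FLAG[["collagen"]], arr.ind = TRUE)
    node <- 2L + (jk[, 1] - 1L) * grid$dims[1] +
      (jk[, 2] - 1L) * grid$dims[1] * grid$dims[2]
    list(node = node, u = ux[cbind(2L, jk)],
         pos = cbind(y = (jk[, 1] - 1) * grid$spacing,
                     z = (jk[, 2] - 1) * grid$spacing))
  }
}

# near-wall excess weight profile over the inlet face (unnormalized)
.margination_weight <- function(grid, face, params) {
  E <- params$margination_E
  delta <- params$margination_delta
  if (grid$dim == 2L) {
    y <- face$pos[, "y"]
    dwall <- pmin(y - (min(y) - grid$spacing / 2),
                  (max(y) + grid$spacing / 2) - y)
  } else {
    cy <- grid$spec$inlet_diameter_mm * 1000 / 2
    r <- sqrt((face$pos[, "y"] - cy)^2 + (face$pos[, "z"] - cy)^2)
    dwall <- pmax(max(r) + grid$spacing / 2 - r, 0)
  }
  1 + (E - 1) * exp(-dwall / delta)
}

#' Draw inlet platelet arrivals for a time window
#'
#' The insertion rate matches the platelet flux through the inlet: a Poisson
#' number of arrivals with mean `integral C(r) u(r) dA * dt`, where the
#' near-wall excess profile `C(r) = C_norm [1 + (E-1) exp(-d_wall/delta)]`
#' is normalized so its mixing-cup (flux-weighted) average equals `C_bulk`.
#' Radial positions are sampled from the flux-weighted density `C(r) u(r)`.
#'
#' @param grid A `lattice_grid`.
#' @param velocity A `velocity_field` (mm/s).
#' @param dt Window length (s).
#' @param t0 Window start time (s); arrival times are uniform in
#'   `[t0, t0 + dt)`.
#' @param params An [lkmc_params()].
#' @return List with sorted `time` (s), `node` (linear index into the first
#'   fluid column), and the deterministic `rate` (1/s).
#' @export
insert_inlet_platelets <- function(grid, velocity, dt, t0 = 0,
                                   params = lkmc_params()) {
  face <- .inlet_face(grid, velocity)
  w <- .margination_weight(grid, face, params)
  u_um <- pmax(face$u, 0) * 1000                 # um/s
  dA <- grid$spacing^2                           # node area (2D: slab depth)
  C_bulk_um3 <- params$C_bulk / 1e9              # 1/uL -> 1/um^3
  flux_w <- w * u_um
  if (sum(flux_w) <= 0 || dt <= 0)
    return(list(time = numeric(0), node = integer(0), rate = 0))
  # normalize over the FULL face: mixing-cup of C equals C_bulk
  C_norm <- C_bulk_um3 * sum(u_um) / sum(flux_w)
  # optional insertion window: realize only the flux entering within
  # `insert_window` of the span above the reactive wall (2D)
  win <- params$insert_window %||% 1
  if (win < 1 && grid$dim == 2L) {
    y <- face$pos[, "y"]
    keep <- y - min(y) <= win * (max(y) - min(y)) + 1e-9
    face$node <- face$node[keep]
    flux_w <- flux_w[keep]
  }
  lambda <- C_norm * sum(flux_w) * dA            # = C_bulk * Q (full window)
  n <- stats::rpois(1, lambda * dt)
  if (n == 0)
    return(list(time = numeric(0), node = integer(0), rate = lambda))
  idx <- sample.int(length(face$node), n, replace = TRUE,
                    prob = flux_w / sum(flux_w))
  list(time = t0 + sort(stats::runif(n, 0, dt)),
       node = face$node[idx], rate = lambda)
}
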