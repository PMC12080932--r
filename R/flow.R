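# Quasi-static incompressible Newtonian flow on the shared lattice.
# Single-relaxation-time BGK; full-way bounce-back on walls and bound
# platelets; prescribed parabolic/Poiseuille profile at the inlet whose wall
# shear rate equals the configured value; zero-gradient outlet.

#' Control parameters for the lattice Boltzmann flow solver
#'
#' @param tau Relaxation time (lattice units), must exceed 0.5. Sets the time
#'   step via `nu_lattice = (tau - 0.5)/3`.
#' @param viscosity_cm2s Kinematic viscosity of blood (cm^2/s). Newtonian
#'   default 3.1e-2 cm^2/s (3.1e-6 m^2/s).
#' @param max_iter Iteration cap before the solver reports non-convergence.
#' @param check_every Residual check cadence (iterations).
#' @param tol Convergence threshold: relative L2 velocity change per
#'   `check_every` iterations.
#' @param u_lattice_max Target maximal lattice velocity (Mach control). For
#'   these steady, low-Reynolds flows the time step is chosen so the fastest
#'   expected velocity maps to this lattice speed; this solves the flow at a
#'   reduced effective viscosity (Reynolds number of order one instead of
#'   order 0.1), which leaves the steady velocity field essentially
#'   unchanged while cutting the wash-out time of transients by orders of
#'   magnitude. Set to `NA` to use the physical viscosity scaling.
#' @param occlusion_headroom Factor by which local velocities may grow as
#'   the clot occludes the vessel before the Mach cap is reached (the time
#'   step stays fixed over a run so warm restarts remain exact).
#' @return A list of class `lb_control`.
#' @export
lb_control <- function(tau = 1.0, viscosity_cm2s = 3.1e-2,
                       max_iter = 200000L, check_every = 100L, tol = 1e-6,
                       u_lattice_max = 0.12, occlusion_headroom = 1.5,
                       max_iter_warm = 400L, strict = TRUE) {
  if (tau <= 0.5) stop("tau must exceed 0.5", call. = FALSE)
  structure(list(tau = tau, viscosity_cm2s = viscosity_cm2s,
                 max_iter = as.integer(max_iter),
                 check_every = as.integer(check_every), tol = tol,
                 u_lattice_max = u_lattice_max,
                 occlusion_headroom = occlusion_headroom,
                 max_iter_warm = as.integer(max_iter_warm),
                 strict = strict),
            class = "lb_control")
}

# effective solid mask: walls, collagen and bound-platelet nodes
.effective_flags <- function(grid, occupancy) {
  fl <- grid$flags
  fl[fl == .FLAG[["collagen"]]] <- .FLAG[["wall"]]
  if (!is.null(occupancy)) fl[occupancy == 1L] <- .FLAG[["wall"]]
  fl
}

# prescribed axial inlet velocity (um/s) per node; wall shear rate gamma_w
# maps to u_max = gamma_w * h / 2 over the effective half-width h (the
# bounce-back wall sits half a lattice link beyond the last fluid node)
.inlet_profile <- function(grid, flags_eff, inlet_wall_shear) {
  dx <- grid$spacing
  u <- numeric(length(flags_eff))
  if (grid$dim == 2L) {
    ny <- grid$dims[2]
    jopen <- which(flags_eff[1, ] == .FLAG[["inlet"]])
    if (length(jopen) == 0) return(u)
    y <- (jopen - 1) * dx
    ylo <- min(y) - dx / 2
    yhi <- max(y) + dx / 2
    h <- (yhi - ylo) / 2
    yc <- (yhi + ylo) / 2
    umax <- inlet_wall_shear * h / 2
    idx <- 1 + (jopen - 1) * grid$dims[1]
    u[idx] <- umax * (1 - ((y - yc) / h)^2)
  } else {
    open <- which(flags_eff == .FLAG[["inlet"]])
    ai <- arrayInd(open, grid$dims)
    cy <- grid$spec$inlet_diameter_mm * 1000 / 2
    r <- sqrt(((ai[, 2] - 1) * dx - cy)^2 + ((ai[, 3] - 1) * dx - cy)^2)
    reff <- max(r) + dx / 2
    umax <- inlet_wall_shear * reff / 2
    u[open] <- umax * pmax(0, 1 - (r / reff)^2)
  }
  u
}

#' Solve the quasi-static flow field
#'
#' Runs the BGK lattice Boltzmann solver to a steady state on the grid, with
#' no-slip on walls and on bound-platelet nodes, a prescribed parabolic (2D) /
#' Poiseuille (3D) inlet profile whose wall shear rate equals
#' `inlet_wall_shear`, and a zero-gradient outlet. Pass the previous `state`
#' to warm-start the quasi-static re-solve after the deposit has grown.
#'
#' @param grid A `lattice_grid`.
#' @param occupancy Optional occupancy field (see [occupancy_field()]); bound
#'   platelet nodes act as bounce-back solids.
#' @param inlet_wall_shear Imposed inlet wall shear rate (1/s), positive.
#' @param state Optional previous `lb_state` for warm starting.
#' @param control An [lb_control()].
#' @return List with `state` (an `lb_state`) and `velocity` (a
#'   `velocity_field`, mm/s).
#' @export
solve_flow <- function(grid, occupancy = NULL, inlet_wall_shear,
                       state = NULL, control = lb_control()) {
  stopifnot(inherits(grid, "lattice_grid"), inlet_wall_shear > 0)
  if (control$tau <= 0.5) stop("tau must exceed 0.5", call. = FALSE)
  flags_eff <- .effective_flags(grid, occupancy)
  dx <- grid$spacing
  u_in <- .inlet_profile(grid, flags_eff, inlet_wall_shear)
  if (!is.null(state)) {
    # warm restart keeps the time step so populations remain consistent;
    # if occlusion has outgrown the Mach headroom, fall back to a cold
    # restart with a freshly scaled step
    prof <- apply(flags_eff != .FLAG[["wall"]], 1, sum)
    amp <- prof[1] / max(min(prof), 1)
    if (max(u_in) * amp * state$dt / dx > 0.25) state <- NULL
  }
  if (!is.null(state)) {
    dt <- state$dt
  } else if (is.finite(control$u_lattice_max %||% NA)) {
    # Mach-targeted scaling: fastest expected velocity (inlet peak amplified
    # by the narrowest open cross-section, with occlusion headroom) maps to
    # u_lattice_max; effective viscosity is reduced accordingly (Re ~ 1)
    prof <- apply(flags_eff != .FLAG[["wall"]], 1, sum)
    amp <- prof[1] / max(min(prof), 1)
    u_est <- max(u_in) * amp * control$occlusion_headroom
    dt <- control$u_lattice_max * dx / u_est
  } else {
    nu <- control$viscosity_cm2s * 1e8          # cm^2/s -> um^2/s
    dt <- (control$tau - 0.5) / 3 * dx^2 / nu   # physical seconds per step
  }
  u_in_l <- u_in * dt / dx
  if (max(u_in_l) > 0.3)
    stop("inlet lattice velocity too large; reduce spacing, shear or u_lattice_max",
         call. = FALSE)
  f_init <- if (!is.null(state)) state$f else numeric(0)
  # quasi-static warm updates get a bounded iteration budget; the field
  # keeps re-converging across successive updates
  iter_cap <- if (!is.null(state)) control$max_iter_warm else control$max_iter
  res <- lb_solve_cpp(as.integer(flags_eff), as.integer(grid$dims), grid$dim,
                      u_in_l, control$tau, f_init,
                      iter_cap, control$check_every, control$tol)
  if (!all(is.finite(res$ux)) && !is.null(state)) {
    # warm state destabilized (e.g. geometry changed too much): cold restart
    return(solve_flow(grid, occupancy, inlet_wall_shear, state = NULL,
                      control = control))
  }
  if (!all(is.finite(res$ux)))
    stop("flow solver diverged (non-finite velocities)", call. = FALSE)
  if (!res$converged && (control$strict %||% TRUE) && is.null(state)) {
    cond <- structure(class = c("thrombosim_convergence_error", "error",
                                "condition"),
                      list(message = sprintf(
                        "flow solver did not converge in %d iterations (last residual %.3e)",
                        res$iterations, utils::tail(res$residuals, 1)),
                        call = sys.call(), residuals = res$residuals))
    stop(cond)
  }
  conv <- dx / dt / 1000                        # lattice units -> mm/s
  d <- grid$dim
  umat <- cbind(res$ux, res$uy, if (d == 3) res$uz)[, seq_len(d), drop = FALSE] * conv
  st <- structure(list(f = res$f, flags_eff = flags_eff, dims = grid$dims,
                       ndim = d, tau = control$tau, dx = dx, dt = dt,
                       gamma_l = res$gamma_l, rho = res$rho,
                       iterations = res$iterations,
                       residuals = res$residuals,
                       inlet_wall_shear = inlet_wall_shear,
                       control = control),
                  class = "lb_state")
  vel <- structure(list(u = umat, dims = grid$dims, spacing = dx, dim = d,
                        units = "mm/s"),
                   class = "velocity_field")
  list(state = st, velocity = vel)
}

#' Local shear rate field from the converged LB state
#'
#' The shear-rate magnitude `gamma = sqrt(2 S:S)` is computed locally from the
#' LB non-equilibrium moments (strain-rate tensor), not by differencing the
#' velocity field; a centered finite-difference estimate is used only as an
#' independent cross-check in the test suite.
#'
#' @param state An `lb_state` from [solve_flow()].
#' @param grid The `lattice_grid` the state was solved on.
#' @return A `shear_field`: list with `gamma` (array, 1/s) over the grid.
#' @export
wall_shear <- function(state, grid) {
  stopifnot(inherits(state, "lb_state"), inherits(grid, "lattice_grid"))
  g <- array(state$gamma_l / state$dt, grid$dims)
  structure(list(gamma = g, dims = grid$dims, spacing = grid$spacing,
                 dim = grid$dim, units = "1/s"),
            class = "shear_field")
}

#' Wall shear rate along the bottom wall, extrapolated to the wall plane
#'
#' For each axial column, linearly extrapolates the shear-rate magnitude from
#' the two near-wall fluid nodes to the effective (half-link) wall position.
#' Exact for the linear shear profile of fully developed channel flow.
#'
#' @param shear A `shear_field`.
#' @param grid The `lattice_grid`.
#' @return Numeric vector of wall shear rates (1/s), one per axial column
#'   (NA where fewer than two open nodes exist).
#' @export
wall_shear_profile <- function(shear, grid) {
  stopifnot(inherits(shear, "shear_field"))
  gm <- if (grid$dim == 2L) shear$gamma else shear$gamma[, , (grid$dims[3] + 1) %/% 2]
  open <- if (grid$dim == 2L) {
    grid$flags != .FLAG[["wall"]] & grid$flags != .FLAG[["collagen"]]
  } else {
    k <- (grid$dims[3] + 1) %/% 2
    grid$flags[, , k] != .FLAG[["wall"]] & grid$flags[, , k] != .FLAG[["collagen"]]
  }
  nx <- grid$dims[1]
  out <- rep(NA_real_, nx)
  for (i in seq_len(nx)) {
    j <- which(open[i, ])
    if (length(j) < 2) next
    j0 <- j[1]; j1 <- j[2]
    out[i] <- 1.5 * gm[i, j0] - 0.5 * gm[i, j1]
  }
  out
}

#' Update the flow state after an occupancy change
#'
#' Marks newly bound platelet nodes as bounce-back solids and re-initializes
#' nodes freed by detachment at equilibrium with the local interpolated
#' velocity. If the occupancy is unchanged, the state is returned as is.
#' The returned state must be re-converged via [solve_flow()] (warm start).
#'
#' @param state An `lb_state`.
#' @param grid The `lattice_grid`.
#' @param occupancy Current occupancy field.
#' @return An updated `lb_state`.
#' @export
update_noslip <- function(state, grid, occupancy) {
  stopifnot(inherits(state, "lb_state"))
  flags_new <- .effective_flags(grid, occupancy)
  if (identical(flags_new, state$flags_eff)) return(state)
  q <- if (state$ndim == 2L) 9L else 19L
  freed <- which(state$flags_eff == .FLAG[["wall"]] & flags_new != .FLAG[["wall"]])
  if (length(freed) > 0) {
    n <- prod(state$dims)
    fm <- matrix(state$f, nrow = q)            # q x n
    d <- state$ndim
    # macroscopic velocity of current fluid nodes (lattice units)
    L <- .lb_lattice(d)
    rho <- colSums(fm)
    for (k in freed) {
      nbrs <- .face_neighbors(k, state$dims)
      nbrs <- nbrs[state$flags_eff[nbrs] != .FLAG[["wall"]] &
                     flags_new[nbrs] != .FLAG[["wall"]]]
      uvec <- rep(0, 3)
      if (length(nbrs) > 0) {
        for (a in seq_len(d)) {
          ca <- L$c[, a]
          uvec[a] <- mean(colSums(fm[, nbrs, drop = FALSE] * ca) /
                            rho[nbrs])
        }
      }
      fm[, k] <- lb_equilibrium_cpp(d, 1.0, uvec)
    }
    state$f <- as.numeric(fm)
  }
  state$flags_eff <- flags_new
  state
}

# face-neighbor linear indices of node k (column-major, within bounds)
.face_neighbors <- function(k, dims) {
  ai <- arrayInd(k, dims)[1, ]
  d <- length(dims)
  out <- integer(0)
  for (a in seq_len(d)) {
    for (s in c(-1L, 1L)) {
      p <- ai
      p[a] <- p[a] + s
      if (p[a] >= 1 && p[a] <= dims[a]) {
        lin <- p[1]
        mult <- 1
        for (b in seq_len(d - 1)) {
          mult <- mult * dims[b]
          lin <- lin + (p[b + 1] - 1) * mult
        }
        out <- c(out, lin)
      }
    }
  }
  out
}

# lattice velocity sets mirrored on the R side (row = direction)
.lb_lattice <- function(ndim) {
  if (ndim == 2L) {
    c2 <- rbind(c(0,0,0), c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                c(1,1,0), c(-1,-1,0), c(1,-1,0), c(-1,1,0))
    list(c = c2, q = 9L)
  } else {
    c3 <- rbind(c(0,0,0),
                c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1),
                c(1,1,0), c(-1,-1,0), c(1,-1,0), c(-1,1,0),
                c(1,0,1), c(-1,0,-1), c(1,0,-1), c(-1,0,1),
                c(0,1,1), c(0,-1,-1), c(0,1,-1), c(0,-1,1))
    list(c = c3, q = 19L)
  }
}

#' Volumetric flux through an axial cross-section
#'
#' @param velocity A `velocity_field` (mm/s).
#' @param grid The `lattice_grid`.
#' @param i Axial column index (1-based); defaults to the outlet column.
#' @return Flux in mm^3/s (3D) or mm^2/s per unit depth (2D).
#' @export
section_flux <- function(velocity, grid, i = grid$dims[1]) {
  stopifnot(inherits(velocity, "velocity_field"))
  d <- grid$dim
  dx_mm <- grid$spacing / 1000
  ux <- array(velocity$u[, 1], grid$dims)
  if (d == 2L) sum(ux[i, ]) * dx_mm else sum(ux[i, , ]) * dx_mm^2
}
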