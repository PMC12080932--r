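# Lattice conventions shared by every module:
#   - 0-based physical coordinates, node-centered: node i sits at (i-1)*spacing um
#   - flow along +x; inlet face at x = 0, outlet face at x = L
#   - flag codes: 0 fluid, 1 wall, 2 inlet, 3 outlet, 4 collagen (collagen is wall)

.FLAG <- c(fluid = 0L, wall = 1L, inlet = 2L, outlet = 3L, collagen = 4L)

#' Node flag codes used by the lattice grid
#'
#' @return Named integer vector mapping flag names (`fluid`, `wall`, `inlet`,
#'   `outlet`, `collagen`) to the integer codes stored in `grid$flags`.
#' @export
flag_codes <- function() .FLAG

#' Specify a simulation domain
#'
#' Describes one of the two vessel geometries: a straight cylindrical (venous)
#' vessel with a centered reactive collagen patch, or a stenotic (arterial)
#' vessel whose central constriction expresses collagen. In 2D mode the domain
#' is the axial-radial center plane of the 3D vessel, so a 75% area reduction
#' appears as a halving of the local gap width.
#'
#' @param shape `"cylinder"` or `"stenosis"`.
#' @param length_mm Domain length along the flow axis (mm).
#' @param inlet_diameter_mm Inlet diameter (mm).
#' @param area_reduction Fractional reduction of cross-sectional flow area at
#'   the stenosis apex, strictly within (0, 1). Stenosis only.
#' @param constriction_length_mm Axial extent of the constriction (mm),
#'   centered in the domain. Stenosis only.
#' @param patch_length_mm Axial length of the collagen patch (mm). For the
#'   stenosis the patch defaults to the constricted region itself.
#' @param circumference_fraction Fraction of the circumference covered by
#'   collagen, measured from the bottom of the vessel (0.5 = semicylindrical).
#'   In 2D any positive fraction places collagen on the bottom wall.
#' @param spacing_um Lattice spacing (um). One platelet occupies one node.
#' @param dim 2 (center plane) or 3.
#' @return A `domain_spec` object.
#' @export
domain_spec <- function(shape = c("cylinder", "stenosis"),
                        length_mm = if (shape == "stenosis") 1.0 else 0.5,
                        inlet_diameter_mm = 0.12,
                        area_reduction = 0.75,
                        constriction_length_mm = 0.5,
                        patch_length_mm = if (shape == "stenosis") constriction_length_mm else 0.25,
                        circumference_fraction = 0.5,
                        spacing_um = 3,
                        dim = 2) {
  shape <- match.arg(shape)
  stopifnot(length_mm > 0, inlet_diameter_mm > 0, spacing_um > 0,
            dim %in% c(2L, 3L), circumference_fraction >= 0,
            circumference_fraction <= 1, patch_length_mm >= 0)
  if (patch_length_mm > length_mm + 1e-12)
    stop("collagen patch longer than the domain", call. = FALSE)
  if (shape == "stenosis") {
    if (!(area_reduction > 0 && area_reduction < 1))
      stop("area_reduction must lie strictly within (0, 1)", call. = FALSE)
    if (constriction_length_mm <= 0 || constriction_length_mm > length_mm)
      stop("constriction_length_mm must lie in (0, length_mm]", call. = FALSE)
  }
  structure(list(shape = shape, length_mm = length_mm,
                 inlet_diameter_mm = inlet_diameter_mm,
                 area_reduction = area_reduction,
                 constriction_length_mm = constriction_length_mm,
                 patch_length_mm = patch_length_mm,
                 circumference_fraction = circumference_fraction,
                 spacing_um = spacing_um, dim = as.integer(dim)),
            class = "domain_spec")
}

# number of nodes spanning a physical length: floor(L/dx) + 1 (node-centered)
.n_nodes <- function(length_um, spacing_um)
  as.integer(floor(length_um / spacing_um + 1e-9)) + 1L

# local vessel radius (um) along x for a spec; vectorized over x_um
.local_radius <- function(spec, x_um) {
  r_in <- spec$inlet_diameter_mm * 1000 / 2
  if (spec$shape == "cylinder") return(rep(r_in, length(x_um)))
  r_apex <- r_in * sqrt(1 - spec$area_reduction)
  xc <- spec$length_mm * 1000 / 2
  lc <- spec$constriction_length_mm * 1000
  r <- rep(r_in, length(x_um))
  inside <- abs(x_um - xc) <= lc / 2
  # C1-smooth cosine bump: R = R_in at the shoulders, R_apex at the throat
  r[inside] <- r_in - (r_in - r_apex) * 0.5 * (1 + cos(2 * pi * (x_um[inside] - xc) / lc))
  r
}

#' Build the voxelized lattice grid for a domain
#'
#' Voxelizes the vessel described by a [domain_spec()] onto a regular lattice.
#' A node is fluid when its center lies inside the nominal vessel boundary;
#' all other nodes are wall. Fluid nodes on the x = 0 / x = L faces are
#' flagged inlet / outlet. Collagen is assigned to wall nodes adjacent to
#' fluid, within the patch span and circumferential coverage.
#'
#' @param spec A [domain_spec()].
#' @return A `lattice_grid`: list with `flags` (integer array, see
#'   [flag_codes()]), `spacing` (um), `dim`, `dims`, and the originating `spec`.
#' @export
build_domain <- function(spec) {
  stopifnot(inherits(spec, "domain_spec"))
  if (spec$shape == "cylinder") build_cylinder(spec) else build_stenosis(spec)
}

#' @rdname build_domain
#' @export
build_cylinder <- function(spec) {
  stopifnot(inherits(spec, "domain_spec"), spec$shape == "cylinder")
  .build_grid(spec)
}

#' @rdname build_domain
#' @export
build_stenosis <- function(spec) {
  stopifnot(inherits(spec, "domain_spec"), spec$shape == "stenosis")
  if (!(spec$area_reduction > 0 && spec$area_reduction < 1))
    stop("area_reduction must lie strictly within (0, 1)", call. = FALSE)
  .build_grid(spec)
}

.build_grid <- function(spec) {
  dx <- spec$spacing_um
  L <- spec$length_mm * 1000
  D <- spec$inlet_diameter_mm * 1000
  nx <- .n_nodes(L, dx)
  ny <- .n_nodes(D, dx)
  x <- (seq_len(nx) - 1) * dx
  y <- (seq_len(ny) - 1) * dx
  cy <- D / 2
  rx <- .local_radius(spec, x)

  if (spec$dim == 2L) {
    flags <- matrix(.FLAG[["wall"]], nx, ny)
    # node is fluid iff its center lies strictly inside the nominal boundary;
    # boundary nodes become bounce-back walls (effective wall half a link in)
    fluid <- outer(seq_len(nx), seq_len(ny),
                   function(i, j) abs(y[j] - cy) < rx[i] - 1e-9)
    flags[fluid] <- .FLAG[["fluid"]]
    flags[1, ][fluid[1, ]] <- .FLAG[["inlet"]]
    flags[nx, ][fluid[nx, ]] <- .FLAG[["outlet"]]
    dims <- c(nx, ny)
    storage.mode(dims) <- "integer"
  } else {
    nz <- ny
    z <- y
    cz <- cy
    flags <- array(.FLAG[["wall"]], c(nx, ny, nz))
    r2 <- outer((y - cy)^2, (z - cz)^2, `+`)   # ny x nz
    for (i in seq_len(nx)) {
      sl <- flags[i, , ]
      sl[r2 < rx[i]^2 - 1e-9] <- .FLAG[["fluid"]]
      flags[i, , ] <- sl
    }
    flags[1, , ][flags[1, , ] == .FLAG[["fluid"]]] <- .FLAG[["inlet"]]
    flags[nx, , ][flags[nx, , ] == .FLAG[["fluid"]]] <- .FLAG[["outlet"]]
    dims <- c(nx, ny, nz)
    storage.mode(dims) <- "integer"
  }

  grid <- structure(list(flags = flags, spacing = dx, dim = spec$dim,
                         dims = dims, spec = spec),
                    class = "lattice_grid")
  .assign_collagen(grid)
}

# collagen: wall nodes adjacent (face neighbors) to fluid, inside the patch
# span, within the circumferential coverage measured from the vessel bottom
.assign_collagen <- function(grid) {
  spec <- grid$spec
  if (spec$patch_length_mm <= 0 || spec$circumference_fraction <= 0) return(grid)
  dx <- grid$spacing
  L <- spec$length_mm * 1000
  D <- spec$inlet_diameter_mm * 1000
  cy <- D / 2
  if (spec$shape == "cylinder") {
    xc <- L / 2
    span <- c(xc - spec$patch_length_mm * 1000 / 2, xc + spec$patch_length_mm * 1000 / 2)
  } else {
    xc <- L / 2
    lc <- min(spec$patch_length_mm, spec$constriction_length_mm) * 1000
    span <- c(xc - lc / 2, xc + lc / 2)
  }
  flags <- grid$flags
  wallish <- flags == .FLAG[["wall"]]
  open <- flags != .FLAG[["wall"]]   # fluid, inlet, outlet
  adj <- .adjacent_to(open, grid$dim)
  if (grid$dim == 2L) {
    nx <- grid$dims[1]; ny <- grid$dims[2]
    xmat <- matrix((seq_len(nx) - 1) * dx, nx, ny)
    ymat <- matrix((seq_len(ny) - 1) * dx, nx, ny, byrow = TRUE)
    inspan <- xmat >= span[1] - 1e-9 & xmat <= span[2] + 1e-9
    bottom <- ymat < cy   # 2D: one wall side of the patch span
    col <- wallish & adj & inspan & bottom
  } else {
    nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
    idx <- which(wallish & adj, arr.ind = TRUE)
    xv <- (idx[, 1] - 1) * dx
    dy <- (idx[, 2] - 1) * dx - cy
    dz <- (idx[, 3] - 1) * dx - cy
    r <- sqrt(dy^2 + dz^2)
    theta <- acos(pmin(1, pmax(-1, -dy / pmax(r, 1e-12))))  # 0 at bottom
    keep <- xv >= span[1] - 1e-9 & xv <= span[2] + 1e-9 &
      theta <= spec$circumference_fraction * pi + 1e-9
    col <- array(FALSE, grid$dims)
    col[idx[keep, , drop = FALSE]] <- TRUE
  }
  flags[col] <- .FLAG[["collagen"]]
  grid$flags <- flags
  grid
}

# logical array: node has a face neighbor for which `mask` is TRUE
.adjacent_to <- function(mask, dim) {
  out <- array(FALSE, dim(mask))
  shift <- function(m, axis, by) {
    res <- array(FALSE, dim(m))
    n <- dim(m)[axis]
    if (abs(by) >= n) return(res)
    src <- if (by > 0) 1:(n - by) else (1 - by):n
    dst <- if (by > 0) (1 + by):n else 1:(n + by)
    if (length(dim(m)) == 2) {
      if (axis == 1) res[dst, ] <- m[src, ] else res[, dst] <- m[, src]
    } else {
      if (axis == 1) res[dst, , ] <- m[src, , ]
      else if (axis == 2) res[, dst, ] <- m[, src, ]
      else res[, , dst] <- m[, , src]
    }
    res
  }
  for (axis in seq_len(dim)) {
    out <- out | shift(mask, axis, 1L) | shift(mask, axis, -1L)
  }
  out
}

#' Reactive collagen surface mask
#'
#' @param grid A `lattice_grid`.
#' @return Integer vector of linear node indices flagged as collagen, in
#'   deterministic lexicographic (column-major) order.
#' @export
reactive_surface_mask <- function(grid) {
  stopifnot(inherits(grid, "lattice_grid"))
  which(grid$flags == .FLAG[["collagen"]])
}

#' Open cross-sectional area profile along the flow axis
#'
#' Counts non-wall nodes in each x = const cross-section; multiplied by the
#' node cross-section (spacing^(dim-1)) this is the discrete flow area.
#'
#' @param grid A `lattice_grid`.
#' @return Integer vector of open-node counts, one per axial column.
#' @export
cross_section_profile <- function(grid) {
  stopifnot(inherits(grid, "lattice_grid"))
  open <- grid$flags != .FLAG[["wall"]] & grid$flags != .FLAG[["collagen"]]
  apply(open, 1, sum)
}

#' Apex-to-inlet flow area ratio of a built grid
#'
#' @param grid A `lattice_grid`.
#' @return Ratio of the minimal open cross-section (node count) to the inlet
#'   cross-section.
#' @export
apex_area_ratio <- function(grid) {
  prof <- cross_section_profile(grid)
  min(prof) / prof[1]
}

#' Create an empty occupancy field
#'
#' Per-node platelet occupancy read by the flow solver: 0 open, 1 bound
#' platelet. Updated by the LKMC engine; each bound platelet occupies one
#' lattice node (the configured platelet footprint).
#'
#' @param grid A `lattice_grid`.
#' @return Integer array with the grid's dimensions, all zero.
#' @export
occupancy_field <- function(grid) {
  stopifnot(inherits(grid, "lattice_grid"))
  array(0L, grid$dims)
}

#' @export
print.lattice_grid <- function(x, ...) {
  cat("lattice_grid:", x$spec$shape, paste(x$dims, collapse = " x "),
      "nodes @", x$spacing, "um,", x$dim, "D\n")
  tab <- table(factor(x$flags, levels = .FLAG, labels = names(.FLAG)))
  print(tab)
  invisible(x)
}
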