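# Flow-solver verification on the venous channel at a slightly coarser
# lattice than the reference runs (identical physics, faster convergence);
# the acceptance suite re-checks the reference resolutions.
#
# Quantitative solver checks use the physical-viscosity time-step scaling
# (u_lattice_max = NA): the Mach-targeted scaling used inside coupled runs
# trades a few percent of compressibility error for far faster transients,
# which is documented and fine there but not what these assertions test.
lb_physical <- function(...) lb_control(u_lattice_max = NA, ...)

flow_fixture <- function() {
  if (!is.null(.fixture_env$flow)) return(.fixture_env$flow)
  g <- build_cylinder(domain_spec("cylinder", spacing_um = 6, dim = 2))
  fl <- solve_flow(g, NULL, inlet_wall_shear = 200, control = lb_physical())
  .fixture_env$flow <- list(g = g, fl = fl)
  .fixture_env$flow
}

test_that("an empty venous channel reproduces plane Poiseuille flow", {
  fx <- flow_fixture()
  g <- fx$g; fl <- fx$fl
  ux <- array(fl$velocity$u[, 1], g$dims)
  mid <- round(g$dims[1] / 2)
  jc <- (g$dims[2] + 1) %/% 2
  # discretization-consistent Poiseuille: the bounce-back wall sits half a
  # link beyond the last fluid node, so u_max = gamma_w * h_eff / 2 with
  # h_eff the effective half-width; the solver must hit that within 2%
  # (the nominal-radius comparison at reference spacing lives in the
  # acceptance suite)
  open_j <- which(g$flags[mid, ] == flag_codes()[["fluid"]])
  h_eff <- (diff(range(open_j)) / 2 + 0.5) * g$spacing / 1000   # mm
  u_ref <- 200 * h_eff / 2
  expect_lt(abs(ux[mid, jc] - u_ref) / u_ref, 0.02)
  sh <- wall_shear(fl$state, g)
  wp <- wall_shear_profile(sh, g)
  expect_lt(abs(wp[mid] - 200) / 200, 0.05)
  # incompressibility proxy: density deviation under 1%
  expect_lt(max(abs(fl$state$rho[fl$state$flags_eff == 0] - 1)), 0.01)
  # mass conservation between inlet and outlet sections
  q_in <- section_flux(fl$velocity, g, 2)
  q_out <- section_flux(fl$velocity, g)
  expect_lt(abs(q_in - q_out) / q_in, 0.01)
})

test_that("LB shear field matches a centered finite-difference oracle", {
  fx <- flow_fixture()
  g <- fx$g; fl <- fx$fl
  sh <- wall_shear(fl$state, g)
  ux <- array(fl$velocity$u[, 1], g$dims)
  uy <- array(fl$velocity$u[, 2], g$dims)
  dx <- g$spacing / 1000
  i <- round(g$dims[1] / 2)
  for (j in 4:(g$dims[2] - 3)) {
    dudy <- (ux[i, j + 1] - ux[i, j - 1]) / (2 * dx)
    dudx <- (ux[i + 1, j] - ux[i - 1, j]) / (2 * dx)
    dvdy <- (uy[i, j + 1] - uy[i, j - 1]) / (2 * dx)
    dvdx <- (uy[i + 1, j] - uy[i - 1, j]) / (2 * dx)
    s11 <- dudx; s22 <- dvdy; s12 <- 0.5 * (dudy + dvdx)
    g_fd <- sqrt(2 * (s11^2 + s22^2 + 2 * s12^2))
    if (g_fd > 20)
      expect_lt(abs(sh$gamma[i, j] - g_fd) / g_fd, 0.02)
  }
})

test_that("gradient-free flow has vanishing shear (channel centerline symmetry)", {
  fx <- flow_fixture()
  sh <- wall_shear(fx$fl$state, fx$g)
  jc <- (fx$g$dims[2] + 1) %/% 2
  mid <- round(fx$g$dims[1] / 2)
  # the centerline of fully developed channel flow is a zero-gradient line
  expect_lt(sh$gamma[mid, jc], 0.02 * max(sh$gamma[mid, ]))
})

test_that("warm-started quasi-static re-solves agree with cold starts", {
  fx <- flow_fixture()
  g <- fx$g; fl <- fx$fl
  occ <- occupancy_field(g)
  occ[80:84, 2:4] <- 1L                       # a small mural deposit
  ctl <- lb_physical(max_iter_warm = 200000L)
  warm <- solve_flow(g, occ, 200, state = update_noslip(fl$state, g, occ),
                     control = ctl)
  cold <- solve_flow(g, occ, 200, control = ctl)
  rel <- sqrt(sum((warm$velocity$u - cold$velocity$u)^2) /
                sum(cold$velocity$u^2))
  expect_lt(rel, 1e-4)
  # no-slip on the deposit
  uocc <- warm$velocity$u[which(occ == 1L), ]
  expect_true(all(abs(uocc) < 1e-12))
})

test_that("update_noslip is the identity when occupancy is unchanged", {
  fx <- flow_fixture()
  g <- fx$g; fl <- fx$fl
  occ <- occupancy_field(g)
  expect_identical(update_noslip(fl$state, g, occ), fl$state)
})

test_that("a fully occluded cross-section carries no outlet flux", {
  g <- build_cylinder(domain_spec("cylinder", length_mm = 0.2,
                                  patch_length_mm = 0.1, spacing_um = 12))
  occ <- occupancy_field(g)
  occ[17, ] <- 1L                             # plug the mid cross-section
  fl <- solve_flow(g, occ, 200)
  q_out <- section_flux(fl$velocity, g)
  q_ref <- section_flux(solve_flow(g, NULL, 200)$velocity, g)
  expect_lt(abs(q_out), 0.02 * q_ref)
})

test_that("partial occlusion accelerates the jet through the gap (continuity)", {
  g <- build_cylinder(domain_spec("cylinder", length_mm = 0.25,
                                  patch_length_mm = 0.1, spacing_um = 12))
  base <- solve_flow(g, NULL, 200)
  occ <- occupancy_field(g)
  occ[11:13, 2:6] <- 1L                       # block half the lumen
  part <- solve_flow(g, occ, 200, state = update_noslip(base$state, g, occ))
  ux_b <- array(base$velocity$u[, 1], g$dims)
  ux_p <- array(part$velocity$u[, 1], g$dims)
  expect_gt(max(ux_p[12, ]), 1.3 * max(ux_b[12, ]))
})

test_that("a relaxation time at or below 1/2 is rejected", {
  expect_error(lb_control(tau = 0.5), "exceed 0.5")
  expect_error(lb_control(tau = 0.3), "exceed 0.5")
})

test_that("3D Poiseuille pipe flow matches continuity and the profile shape", {
  g <- build_cylinder(domain_spec("cylinder", length_mm = 0.25,
                                  patch_length_mm = 0.1, spacing_um = 12,
                                  dim = 3))
  fl <- solve_flow(g, NULL, inlet_wall_shear = 200,
                   control = lb_physical())
  ux <- array(fl$velocity$u[, 1], g$dims)
  jc <- (g$dims[2] + 1) %/% 2
  mid <- round(g$dims[1] / 2)
  umax <- ux[mid, jc, jc]
  # coarse pipe: centerline within 15% of gamma_w R / 2
  expect_lt(abs(umax - 200 * 0.06 / 2) / (200 * 0.06 / 2), 0.15)
  q_in <- section_flux(fl$velocity, g, 2)
  q_out <- section_flux(fl$velocity, g)
  expect_lt(abs(q_in - q_out) / q_in, 0.02)
})
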