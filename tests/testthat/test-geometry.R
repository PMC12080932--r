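test_that("cylinder voxelization follows the stated node and patch conventions", {
  spec <- domain_spec("cylinder", spacing_um = 3, dim = 2)
  g <- build_cylinder(spec)
  # floor(L/dx) + 1 node-centered columns: floor(500/3) + 1
  expect_identical(g$dims[1], 167L)
  expect_identical(g$dims[2], 41L)
  m <- reactive_surface_mask(g)
  expect_gt(length(m), 0)
  ai <- arrayInd(m, g$dims)
  xs <- (ai[, 1] - 1) * g$spacing
  # centered 0.25 mm patch spans [125, 375] um (node centers inside it)
  expect_gte(min(xs), 125)
  expect_lte(max(xs), 375)
  expect_gte(min(xs), 125 - g$spacing)
  expect_true(all(ai[, 2] == 1))          # 2D: one wall side
  # collagen nodes are wall nodes adjacent to open fluid
  expect_true(all(g$flags[m] == flag_codes()[["collagen"]]))
})

test_that("empty patch and patch-too-long cases behave as specified", {
  g0 <- build_cylinder(domain_spec("cylinder", patch_length_mm = 0))
  expect_length(reactive_surface_mask(g0), 0)
  expect_error(domain_spec("cylinder", patch_length_mm = 0.6),
               "longer than the domain")
})

test_that("stenosis area reduction is honored in 3D and on the center plane", {
  g3 <- build_stenosis(domain_spec("stenosis", dim = 3, spacing_um = 3))
  prof <- cross_section_profile(g3)
  ratio <- min(prof) / prof[1]
  # one voxel ring at the apex: 2*pi*r_apex/dx nodes
  ring <- 2 * pi * 30 / 3
  tol <- 2 * ring / prof[1]
  expect_lt(abs(ratio - 0.25), tol)
  # 2D center plane: gap ratio sqrt(1 - 0.75) = 0.5 (+- one node each wall)
  g2 <- build_stenosis(domain_spec("stenosis", dim = 2, spacing_um = 3))
  p2 <- cross_section_profile(g2)
  expect_lt(abs(min(p2) / p2[1] - 0.5), 2 / p2[1] + 0.05)
})

test_that("vanishing constriction recovers the straight vessel", {
  sp <- domain_spec("stenosis", area_reduction = 1e-12, length_mm = 0.5,
                    patch_length_mm = 0.25, spacing_um = 6)
  gs <- build_stenosis(sp)
  prof <- cross_section_profile(gs)
  expect_true(all(prof == prof[1]))
})

test_that("invalid constriction fractions are rejected", {
  expect_error(domain_spec("stenosis", area_reduction = 0), "strictly within")
  expect_error(domain_spec("stenosis", area_reduction = 1), "strictly within")
  expect_error(domain_spec("stenosis", area_reduction = 1.2), "strictly within")
})

test_that("reactive surface mask equals a brute-force flag scan, deterministically", {
  for (shape in c("cylinder", "stenosis")) {
    g <- build_domain(domain_spec(shape, spacing_um = 6,
                                  dim = if (shape == "cylinder") 3 else 2))
    m <- reactive_surface_mask(g)
    brute <- which(as.vector(g$flags) == flag_codes()[["collagen"]])
    expect_identical(m, brute)
    expect_true(!is.unsorted(m))
    # rebuild invariance: bitwise identical flags
    g2 <- build_domain(g$spec)
    expect_identical(g$flags, g2$flags)
  }
})

test_that("stenosis with zero collagen coverage has an empty mask", {
  g <- build_stenosis(domain_spec("stenosis", circumference_fraction = 0,
                                  spacing_um = 6))
  expect_length(reactive_surface_mask(g), 0)
})

test_that("every collagen node is a wall-adjacent-to-fluid node", {
  g <- build_cylinder(domain_spec("cylinder", dim = 3, spacing_um = 6))
  m <- reactive_surface_mask(g)
  open <- g$flags != flag_codes()[["wall"]] &
    g$flags != flag_codes()[["collagen"]]
  adj <- thrombosim:::.adjacent_to(open, g$dim)
  expect_true(all(adj[m]))
})

test_that("occupancy fields start empty with the grid's shape", {
  g <- build_cylinder(domain_spec("cylinder", spacing_um = 6))
  occ <- occupancy_field(g)
  expect_identical(dim(occ), dim(g$flags))
  expect_true(all(occ == 0L))
})
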