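# builds one TRI reference molecule (optionally rotated rigidly) plus point
# partners at given lab-frame positions
make_sdf_fixture <- function(partner_pos, rot = diag(3), origin = c(15, 15, 15),
                             box = c(30, 30, 30), n_frames = 1) {
  n_p <- nrow(partner_pos)
  top <- system_topology(list(tri_species(), point_sp()), c(1L, n_p))
  coords <- array(NA_real_, dim = c(3 + n_p, 3, n_frames))
  for (f in seq_len(n_frames)) {
    coords[1:3, , f] <- t(rot %*% t(tri_local_coords())) +
      matrix(origin, 3, 3, byrow = TRUE)
    coords[-(1:3), , f] <- partner_pos
  }
  trajectory(coords, box, top)
}

test_that("a partner at fixed local coordinates fills exactly one voxel", {
  # partner at local (2.1, 0, 0): on the anchor1->anchor2 axis
  traj <- make_sdf_fixture(matrix(c(15 + 2.1, 15, 15), 1), n_frames = 4)
  grid <- compute_sdf(traj, "TRI", c("A1", "A2", "A3"), "PNT", voxel = 0.5,
                      extent = 4)
  vals <- attr(grid, "values")
  expect_equal(sum(vals > 0), 1L)
  expect_equal(nrow(grid), 1L)
  expect_equal(grid$x, 2.25)  # voxel center containing local x = 2.1
  expect_equal(grid$y, 0.25)
  expect_equal(grid$z, 0.25)
  # density = 1 partner / voxel volume
  expect_equal(grid$density, 1 / 0.5^3)

  # rigid rotation of the reference molecule leaves the local frame fixed
  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  pos <- t(rot %*% c(2.1, 0, 0)) + c(15, 15, 15)
  traj2 <- make_sdf_fixture(pos, rot = rot)
  grid2 <- compute_sdf(traj2, "TRI", c("A1", "A2", "A3"), "PNT", voxel = 0.5,
                       extent = 4)
  expect_equal(grid2$x, 2.25)
  expect_equal(grid2$y, 0.25)
  expect_equal(grid2$z, 0.25)
})

test_that("uniform partners give bulk density and exact mass conservation", {
  n_p <- 300
  n_f <- 25
  top <- system_topology(list(tri_species(), point_sp()), c(1L, n_p))
  box <- c(24, 24, 24)
  coords <- withr::with_seed(41, {
    out <- array(NA_real_, dim = c(3 + n_p, 3, n_f))
    for (f in seq_len(n_f)) {
      out[1:3, , f] <- tri_local_coords() + matrix(12, 3, 3)
      out[-(1:3), , f] <- matrix(runif(n_p * 3) * 24, ncol = 3)
    }
    out
  })
  traj <- trajectory(coords, box, top)
  grid <- compute_sdf(traj, "TRI", c("A1", "A2", "A3"), "PNT", voxel = 1,
                      extent = 3)
  vals <- attr(grid, "values")
  # bulk density within sampling error
  expect_equal(mean(vals), n_p / prod(box), tolerance = 0.1)
  # grid mass: direct count oracle with an independent frame construction
  direct <- vapply(seq_len(n_f), function(f) {
    a1 <- coords[1, , f]; a2 <- coords[2, , f]; a3 <- coords[3, , f]
    ex <- (a2 - a1) / sqrt(sum((a2 - a1)^2))
    v3 <- a3 - a1
    ez <- c(ex[2] * v3[3] - ex[3] * v3[2], ex[3] * v3[1] - ex[1] * v3[3],
            ex[1] * v3[2] - ex[2] * v3[1])
    ez <- ez / sqrt(sum(ez^2))
    ey <- c(ez[2] * ex[3] - ez[3] * ex[2], ez[3] * ex[1] - ez[1] * ex[3],
            ez[1] * ex[2] - ez[2] * ex[1])
    inreg <- 0
    for (j in (3 + 1):(3 + n_p)) {
      d <- coords[j, , f] - a1
      d <- d - box * round(d / box)
      loc <- c(sum(d * ex), sum(d * ey), sum(d * ez))
      if (all(loc >= -3 & loc < 3)) inreg <- inreg + 1
    }
    inreg
  }, numeric(1))
  expect_equal(sum(vals) * 1^3, mean(direct), tolerance = 1e-6)
})

test_that("collinear anchors are rejected with molecule and frame named", {
  lin <- species_topology("LIN", tibble::tibble(
    label = c("B1", "B2", "B3"), element = c("C", "C", "C"),
    mass = c(12, 12, 12), charge = c(0, 0, 0),
    lj_epsilon = c(0.1, 0.1, 0.1), lj_rmin_half = c(2, 2, 2)))
  top <- system_topology(list(lin, point_sp()), c(1L, 1L))
  coords <- array(0, dim = c(4, 3, 1))
  coords[1, , 1] <- c(10, 10, 10)
  coords[2, , 1] <- c(11, 10, 10)
  coords[3, , 1] <- c(12, 10, 10)   # collinear with the first two
  coords[4, , 1] <- c(13, 10, 10)
  traj <- trajectory(coords, c(20, 20, 20), top)
  expect_error(compute_sdf(traj, "LIN", c("B1", "B2", "B3"), "PNT"),
               "collinear.*molecule 1.*frame 1")
})

test_that("Dens is the particle density at the first minimum", {
  # constructed profile: g has first-minimum value 0.5; rho_partner = 0.5
  r <- seq(0.025, 6, by = 0.05)
  g <- 1 + 2 * exp(-(r - 2)^2 / 0.1) - 0.5 * exp(-(r - 3)^2 / 0.02)
  g_at_3 <- 1 + 2 * exp(-1^2 / 0.1) - 0.5  # ~ 0.5 at the minimum
  prof <- structure(tibble::tibble(r = r, g = g, count = g),
                    bin_edges = seq(0, 6, by = 0.05), rho = 0.5,
                    class = c("mix_rdf", class(tibble::tibble())))
  dp <- dens_profile(prof, smooth_window = 1)
  expect_lt(abs(dp$r_min - 3.0), 0.05 + 1e-9)
  expect_equal(dp$dens, 0.5 * g_at_3, tolerance = 0.05)
  expect_equal(dp$dens, 0.25, tolerance = 0.05)

  # ideal gas has no solvation shell
  ig <- gen_ideal_gas(200, 15, n_frames = 10, seed = 42)
  expect_error(dens_profile(ig, "GAS", "GAS", bin_width = 0.25), "no solvation")

  # compositional oracle on the LJ fluid
  lj <- gen_lj_fluid(n = 125, rho_star = 0.8, T_star = 1.0, n_frames = 12,
                     n_equil_sweeps = 400, sweeps_per_sample = 5, seed = 43)
  prof_lj <- compute_rdf(lj, "LJ", "LJ", bin_width = 0.05)
  dp_lj <- dens_profile(prof_lj)
  rmin <- find_first_minimum(prof_lj)
  expect_equal(dp_lj$r_min, rmin)
  expect_equal(dp_lj$dens,
               attr(prof_lj, "rho") * prof_lj$g[match(rmin, prof_lj$r)])
})

test_that("density grids serialize to Gaussian cube text", {
  traj <- make_sdf_fixture(matrix(c(15 + 2.1, 15, 15), 1))
  grid <- compute_sdf(traj, "TRI", c("A1", "A2", "A3"), "PNT", voxel = 1,
                      extent = 2)
  path <- withr::local_tempfile(fileext = ".cube")
  write_cube(grid, path)
  lines <- readLines(path)
  n_side <- dim(attr(grid, "values"))[1]
  expect_equal(as.integer(strsplit(trimws(lines[4]), "\\s+")[[1]][1]), n_side)
  # voxel vector in bohr
  expect_equal(as.numeric(strsplit(trimws(lines[4]), "\\s+")[[1]][2]),
               1 * 1.8897259886, tolerance = 1e-6)
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:7)]), "\\s+")))
  expect_equal(sum(vals), sum(attr(grid, "values")), tolerance = 1e-6)
})
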