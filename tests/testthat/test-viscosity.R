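test_that("the kinetic pressure term matches a hand computation", {
  sp <- species_topology("P", tibble::tibble(
    label = "X", element = "H", mass = 1, charge = 0,
    lj_epsilon = 0, lj_rmin_half = 1))
  top <- system_topology(sp, 1L)
  coords <- array(c(5, 5, 5), dim = c(1, 3, 3))
  vel <- array(rep(c(1, 1, 0), 3), dim = c(1, 3, 3))
  traj <- trajectory(coords, c(10, 10, 10), top, velocities = vel,
                     unwrapped = TRUE)
  ps <- compute_pressure_tensor(traj, cutoff = 4)
  # P_xy = m v_x v_y / (418.4 V) in kcal/(mol A^3)
  expect_equal(ps$Pxy, rep(1 * 1 * 1 / 418.4 / 1000, 3), tolerance = 1e-12)
  expect_equal(ps$Pyz, rep(0, 3))
  expect_equal(ps$Pxx, ps$Pyy, tolerance = 1e-12)
  # temperature from equipartition: (1/2) m v^2 = (3/2) kB T
  expect_equal(attr(ps, "temperature"), 2 / (3 * 0.0019872041) / 418.4,
               tolerance = 1e-9)
})

test_that("zero velocities and no interactions give the zero tensor", {
  sp <- species_topology("P", tibble::tibble(
    label = "X", element = "He", mass = 4, charge = 0,
    lj_epsilon = 0, lj_rmin_half = 1))
  top <- system_topology(sp, 3L)
  coords <- array(runif(9, 1, 9), dim = c(3, 3, 2))
  vel <- array(0, dim = c(3, 3, 2))
  traj <- trajectory(coords, c(10, 10, 10), top, velocities = vel)
  ps <- compute_pressure_tensor(traj, cutoff = 4, temperature = 300)
  expect_true(all(as.matrix(ps[, c("Pxy", "Pxz", "Pyz", "Pxx", "Pyy", "Pzz")]) == 0))
  # missing velocities are an error
  traj$velocities <- NULL
  expect_error(compute_pressure_tensor(traj, cutoff = 4), "velocities")
})

test_that("two LJ atoms on the x axis load only the diagonal", {
  sp <- species_topology("LJ2", tibble::tibble(
    label = "X", element = "Ar", mass = 40, charge = 0,
    lj_epsilon = 0.5, lj_rmin_half = 1.2))
  top <- system_topology(sp, 2L)
  coords <- array(0, dim = c(2, 3, 1))
  coords[1, , 1] <- c(4, 5, 5); coords[2, , 1] <- c(6.5, 5, 5)
  vel <- array(0, dim = c(2, 3, 1))
  traj <- trajectory(coords, c(12, 12, 12), top, velocities = vel)
  ps <- compute_pressure_tensor(traj, cutoff = 5, temperature = 300)
  expect_equal(ps$Pxy, 0)
  expect_equal(ps$Pxz, 0)
  expect_true(abs(ps$Pxx) > 0)
  expect_equal(ps$Pyy, 0)   # virial r_y F_y = 0 on the x axis
})

test_that("the ACF at lag zero is the series variance", {
  ou <- gen_ou_pressure(n_steps = 5000, dt = 0.05, sigma_P = 30, tau_c = 0.5,
                        seed = 91)
  gv <- green_kubo_viscosity(ou)
  x <- ou$Pxy - mean(ou$Pxy)
  v3 <- mean(vapply(c("Pxy", "Pxz", "Pyz"), function(k) {
    y <- ou[[k]] - mean(ou[[k]]); sum(y^2) / length(y)
  }, numeric(1)))
  expect_equal(gv$acf$acf[1], v3, tolerance = 1e-12)
})

test_that("viscosity is invariant under sign flip and component permutation", {
  ou <- gen_ou_pressure(n_steps = 2e4, dt = 0.05, sigma_P = 40, tau_c = 1,
                        seed = 92)
  base <- green_kubo_viscosity(ou)
  flip <- ou
  flip$Pxy <- -flip$Pxy; flip$Pxz <- -flip$Pxz; flip$Pyz <- -flip$Pyz
  flip <- pressure_series(flip, attr(ou, "volume"), attr(ou, "temperature"),
                          attr(ou, "units"))
  expect_equal(green_kubo_viscosity(flip)$eta, base$eta)
  perm <- ou
  tmp <- perm$Pxy; perm$Pxy <- perm$Pyz; perm$Pyz <- perm$Pxz; perm$Pxz <- tmp
  perm <- pressure_series(perm, attr(ou, "volume"), attr(ou, "temperature"),
                          attr(ou, "units"))
  expect_equal(green_kubo_viscosity(perm)$eta, base$eta)
})

test_that("the OU fixture recovers the closed-form viscosity and units chain", {
  V <- 1.3e4; Temp <- 323; sigma <- 120; tau <- 1
  ou <- gen_ou_pressure(n_steps = 4e5, dt = 0.05, sigma_P = sigma, tau_c = tau,
                        volume = V, temperature = Temp, units = "atm",
                        seed = 93)
  gv <- green_kubo_viscosity(ou)
  # independent conversion: eta = (V / kB T) sigma^2 tau in SI, to mPa s
  eta_expected <- (V * 1e-30) / (1.380649e-23 * Temp) *
    (sigma * 101325)^2 * (tau * 1e-12) * 1e3
  expect_lt(abs(gv$eta - eta_expected) / eta_expected, 0.1)

  # same numbers declared in internal units scale by the squared unit ratio
  ou2 <- pressure_series(tibble::as_tibble(ou), V, Temp,
                         units = "kcal/mol/A3")
  gv2 <- green_kubo_viscosity(ou2)
  ratio <- (mix_constants()$kcal_mol_a3_to_pa / mix_constants()$atm_to_pa)^2
  expect_equal(gv2$eta / gv$eta, ratio, tolerance = 1e-9)
})

test_that("white noise integrates to the half-weight plateau", {
  n <- 5e4; dt <- 0.1; sigma <- 25; V <- 8000; Temp <- 300
  comps <- withr::with_seed(94, replicate(3, rnorm(n, sd = sigma)))
  ser <- pressure_series(tibble::tibble(time = (seq_len(n) - 1) * dt,
                                        Pxy = comps[, 1], Pxz = comps[, 2],
                                        Pyz = comps[, 3]),
                         volume = V, temperature = Temp, units = "atm")
  gv <- green_kubo_viscosity(ser)
  pref <- (V * 1e-30) / (1.380649e-23 * Temp) * 101325^2 * 1e-12 * 1e3
  # discrete-sum oracle: trapezoid gives ACF(0) * dt / 2
  expected <- pref * sigma^2 * dt / 2
  expect_lt(abs(gv$eta - expected) / expected, 0.05)
})

test_that("averaging three components cuts the estimator variance about 3x", {
  V <- 1e4; Temp <- 300
  etas3 <- numeric(20); etas1 <- numeric(20)
  for (s in 1:20) {
    ou <- gen_ou_pressure(n_steps = 2e4, dt = 0.05, sigma_P = 50, tau_c = 1,
                          volume = V, temperature = Temp, seed = 200 + s)
    etas3[s] <- green_kubo_viscosity(ou, max_lag = 200,
                                     truncation_policy = "fixed")$eta
    tb <- tibble::as_tibble(ou)
    tb$Pxz <- tb$Pxy; tb$Pyz <- tb$Pxy
    solo <- pressure_series(tb, V, Temp, "atm")
    etas1[s] <- green_kubo_viscosity(solo, max_lag = 200,
                                     truncation_policy = "fixed")$eta
  }
  expect_gt(var(etas1) / var(etas3), 1.8)
})

test_that("pressure series round-trip through CSV with their metadata", {
  ou <- gen_ou_pressure(n_steps = 500, dt = 0.05, sigma_P = 10, tau_c = 0.5,
                        volume = 5e3, temperature = 310, seed = 95)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pressure_series(ou, path)
  back <- read_pressure_series(path)
  expect_equal(back$Pxy, ou$Pxy, tolerance = 1e-12)
  expect_equal(attr(back, "volume"), 5e3)
  expect_equal(attr(back, "temperature"), 310)
  expect_equal(attr(back, "units"), "atm")
})
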