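test_that("MSD handles static, ballistic and Brownian motion", {
  top <- system_topology(point_sp(), 4L)
  coords <- array(rep(runif(12), 10), dim = c(4, 3, 10))
  st <- trajectory(coords, c(10, 10, 10), top, unwrapped = TRUE)
  expect_true(all(compute_msd(st)$msd == 0))

  bl <- gen_ballistic(30, 20, speed = 1.5, dt = 0.1, n_frames = 60, seed = 61)
  m <- compute_msd(bl)
  expect_equal(m$msd, 1.5^2 * m$lag^2, tolerance = 1e-10)

  b <- gen_brownian(200, 30, D = 1, dt = 0.1, n_frames = 400, seed = 62)
  mb <- compute_msd(b)
  mid <- mb$lag > 1 & mb$lag < 10
  expect_lt(max(abs(mb$msd[mid] / (6 * mb$lag[mid]) - 1)), 0.1)
})

test_that("FFT and direct MSD paths agree to 1e-8 relative", {
  for (seed in c(63, 64)) {
    b <- gen_brownian(25, 15, D = 0.7, dt = 0.05, n_frames = 180, seed = seed)
    f <- compute_msd(b, method = "fft")
    d <- compute_msd(b, method = "direct")
    expect_equal(f$msd, d$msd, tolerance = 1e-8)
    expect_equal(f$n_samples, d$n_samples)
  }
})

test_that("wrapped input is rejected with a pointer to unwrap", {
  b <- gen_brownian(30, 6, D = 1, dt = 0.5, n_frames = 80, seed = 65)
  w <- wrap(b)
  expect_error(compute_msd(w), "unwrap")
  expect_silent(compute_msd(unwrap(w)))
})

test_that("beta recovers exact power-law exponents", {
  mk_msd <- function(lag, msd) {
    structure(tibble::tibble(lag = lag, msd = msd,
                             n_samples = rep(1, length(lag))),
              dt = lag[2] - lag[1],
              class = c("mix_msd", class(tibble::tibble())))
  }
  t <- seq(0, 20, by = 0.1)
  expect_lt(max(abs(compute_beta(mk_msd(t, 6 * 2 * t))$beta - 1), na.rm = TRUE), 1e-6)
  expect_lt(max(abs(compute_beta(mk_msd(t, 3 * t^2))$beta - 2), na.rm = TRUE), 1e-6)
  expect_lt(max(abs(compute_beta(mk_msd(t, 0.4 * t^1.5))$beta - 1.5), na.rm = TRUE), 1e-6)
  expect_error(compute_beta(mk_msd(t, rep(0, length(t)))), "positive")
})

test_that("beta traces the ballistic-to-diffusive crossover", {
  # Langevin closed form: MSD = 6 D (t - tau (1 - exp(-t/tau)))
  tau <- 1; D <- 0.5
  t <- seq(0, 50, by = 0.02)
  msd <- 6 * D * (t - tau * (1 - exp(-t / tau)))
  obj <- structure(tibble::tibble(lag = t, msd = msd, n_samples = rep(1, length(t))),
                   dt = 0.02, class = c("mix_msd", class(tibble::tibble())))
  beta <- compute_beta(obj)
  early <- beta$beta[beta$lag < 0.05]
  late <- beta$beta[beta$lag > 30]
  expect_true(all(abs(early - 2) < 0.05, na.rm = TRUE))
  expect_true(all(abs(late - 1) < 0.05, na.rm = TRUE))
  expect_true(all(diff(beta$beta[!is.na(beta$beta)]) < 1e-8))  # monotone descent
})

test_that("Einstein estimator recovers the generator diffusion coefficient", {
  b <- gen_brownian(300, 40, D = 1, dt = 0.1, n_frames = 600, seed = 66)
  est <- estimate_diffusion(compute_msd(b))
  expect_lt(abs(est$D - 1), 0.05)
  expect_gt(est$D_A2_ns, 900)
  # bias shrinks as the ensemble grows
  small <- estimate_diffusion(compute_msd(
    gen_brownian(75, 40, D = 1, dt = 0.1, n_frames = 600, seed = 66)))
  expect_lte(abs(est$D - 1), abs(small$D - 1) + 0.02)
})

test_that("non-diffusive trajectories refuse an Einstein fit", {
  bl <- gen_ballistic(40, 20, speed = 1, dt = 0.1, n_frames = 80, seed = 67)
  err <- tryCatch(estimate_diffusion(compute_msd(bl)), condition = identity)
  expect_s3_class(err, "mix_no_diffusive_regime")
  expect_s3_class(err$beta, "mix_beta")   # beta profile attached
  st <- trajectory(array(1, dim = c(2, 3, 30)), c(10, 10, 10),
                   system_topology(point_sp(), 2L), unwrapped = TRUE)
  expect_error(estimate_diffusion(compute_msd(st)))
})

test_that("a fixed window override mimics a tail-decade fit", {
  b <- gen_brownian(300, 40, D = 1, dt = 0.1, n_frames = 600, seed = 68)
  est <- estimate_diffusion(compute_msd(b), window = c(24, 30))
  expect_equal(est$window, c(24, 30))
  # few independent origins survive at tail lags; the estimate is noisier
  expect_lt(abs(est$D - 1), 0.2)
})

test_that("bond vectors are extracted and normalized per molecule", {
  d <- gen_hbond_dimers(5, n_frames = 2, seed = 69)
  v <- vectors_from_bond(d, "DON", c("OD", "HD"))
  expect_equal(dim(v$vectors), c(5, 3, 2))
  nrm <- sqrt(v$vectors[, 1, ]^2 + v$vectors[, 2, ]^2 + v$vectors[, 3, ]^2)
  expect_equal(as.vector(nrm), rep(1, 10), tolerance = 1e-12)
  # hand oracle on a two-frame fixture
  o <- select_atoms(d$topology, "DON:OD")[2]
  h <- select_atoms(d$topology, "DON:HD")[2]
  hand <- d$coords[h, , 1] - d$coords[o, , 1]
  hand <- hand / sqrt(sum(hand^2))
  expect_equal(v$vectors[2, , 1], hand, tolerance = 1e-12)
  # rigid translation leaves vectors constant
  d2 <- d
  d2$coords[, , 2] <- d2$coords[, , 1] + 1.5
  v2 <- vectors_from_bond(d2, "DON", c("OD", "HD"))
  expect_equal(v2$vectors[, , 2], v2$vectors[, , 1])
  expect_error(vectors_from_bond(d, "DON", c("OD", "XX")), "missing")
})

test_that("VRD is 1 for frozen vectors and 0 for i.i.d. resampled ones", {
  frz <- gen_rotor(50, D_r = 0, n_frames = 40, seed = 70)
  C <- compute_vrd(frz)
  expect_equal(C$C, rep(1, nrow(C)), tolerance = 1e-12)
  iid <- gen_rotor(400, D_r = 0, n_frames = 40, seed = 71)
  iid$vectors <- withr::with_seed(72, {
    v <- array(rnorm(400 * 3 * 40), dim = c(400, 3, 40))
    nr <- sqrt(v[, 1, ]^2 + v[, 2, ]^2 + v[, 3, ]^2)
    for (f in 1:40) v[, , f] <- v[, , f] / nr[, f]
    v
  })
  Ci <- compute_vrd(iid)
  n_samp <- 400 * (40 - seq_len(nrow(Ci) - 1))
  expect_true(all(abs(Ci$C[-1]) <= 3 / sqrt(n_samp)))
})

test_that("rotor VRD matches exp(-2 D_r tau) pointwise", {
  rot <- gen_rotor(1000, D_r = 0.05, dt = 0.05, n_frames = 300, seed = 73)
  C <- compute_vrd(rot, max_lag_fraction = 0.5)
  keep <- C$lag <= 3 / (2 * 0.05)
  expected <- exp(-2 * 0.05 * C$lag[keep])
  n_samp <- 1000 * (300 - C$lag[keep] / 0.05)
  se <- 1 / sqrt(n_samp)
  expect_true(all(abs(C$C[keep] - expected) <= pmax(3 * se, 0.02)))
  fit <- fit_vrd_decay(C)
  expect_lt(abs(fit$rate - 0.1) / 0.1, 0.1)
})
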