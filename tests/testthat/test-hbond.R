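test_that("dimer fixtures are detected perfectly inside the criteria", {
  d <- gen_hbond_dimers(12, n_frames = 10, r0 = 2.0, theta0 = 150, seed = 51)
  det <- detect_hbonds(d, hbond_criteria(2.5, 130))
  expect_equal(nrow(det), 12L * 10L)     # all pairs, all frames
  expect_true(all(det$r <= 2.5))
  expect_true(all(det$angle >= 130))
  # geometry strictly outside the distance criterion: zero detections
  far <- gen_hbond_dimers(12, n_frames = 5, r0 = 3.5, theta0 = 150, seed = 51)
  expect_equal(nrow(detect_hbonds(far, hbond_criteria(2.5, 130))), 0L)
})

test_that("criteria boundaries are closed", {
  # hand-built: D at origin, H at +1 x, A exactly at r_max beyond H (angle 180)
  don <- species_topology("DON", tibble::tibble(
    label = c("OD", "HD"), element = c("O", "H"), mass = c(16, 1),
    charge = c(-0.4, 0.4), lj_epsilon = c(0.2, 0.05),
    lj_rmin_half = c(1.8, 0.2)), bonds = rbind(c(1L, 2L)),
    donors = tibble::tibble(heavy = "OD", hydrogen = "HD"))
  acc <- species_topology("ACC", tibble::tibble(
    label = "OA", element = "O", mass = 16, charge = -0.3,
    lj_epsilon = 0.2, lj_rmin_half = 1.8), acceptors = "OA")
  top <- system_topology(list(don, acc), c(1L, 1L))
  coords <- array(0, dim = c(3, 3, 1))
  coords[1, , 1] <- c(5, 5, 5)
  coords[2, , 1] <- c(6, 5, 5)
  coords[3, , 1] <- c(8.5, 5, 5)   # r(H...A) = 2.5 exactly, angle = 180 exactly
  traj <- trajectory(coords, c(20, 20, 20), top)
  det <- detect_hbonds(traj, hbond_criteria(2.5, 130))
  expect_equal(nrow(det), 1L)
  expect_equal(det$r, 2.5)
  expect_equal(det$angle, 180)
  # angle exactly at the threshold also counts: reuse the measured angle of
  # a bent geometry as the criterion
  coords[3, , 1] <- c(6 + 2 * cos(pi / 5), 5 + 2 * sin(pi / 5), 5)
  traj2 <- trajectory(coords, c(20, 20, 20), top)
  th <- detect_hbonds(traj2, hbond_criteria(2.5, 0))$angle
  expect_equal(nrow(detect_hbonds(traj2, hbond_criteria(2.5, th))), 1L)
  expect_equal(nrow(detect_hbonds(traj2, hbond_criteria(2.5 - 1e-9, th + 1e-9))), 0L)
})

test_that("detection equals the exhaustive all-triples oracle on random frames", {
  withr::with_seed(52, {
    for (rep in 1:5) {
      d <- gen_hbond_dimers(8, n_frames = 1, r0 = runif(1, 1.6, 3.2),
                            theta0 = runif(1, 120, 175),
                            jitter_r = 0.4, jitter_theta = 15,
                            seed = sample(1e6, 1))
      # perturb coordinates so geometries scatter across the criteria
      d$coords <- d$coords + array(rnorm(length(d$coords), sd = 0.3),
                                   dim = dim(d$coords))
      det <- detect_hbonds(d, hbond_criteria(2.5, 130))
      oracle <- bf_detect_hbonds(d$coords[, , 1], d$box[1, ], d$topology,
                                 2.5, 130)
      got <- det[order(det$h), c("donor", "h", "acceptor")]
      expect_equal(nrow(det), nrow(oracle))
      if (nrow(oracle)) {
        oracle <- oracle[order(oracle[, 2]), , drop = FALSE]
        expect_equal(unname(as.matrix(got)), unname(oracle))
      }
    }
  })
})

test_that("detection F1 is 1.0 against embedded ground truth with margin jitter", {
  d <- gen_hbond_dimers(20, n_frames = 25, r0 = 2.0, theta0 = 155,
                        jitter_r = 0.3, jitter_theta = 15, occupancy = 0.6,
                        seed = 53)
  det <- detect_hbonds(d, hbond_criteria(2.5, 130))
  truth <- d$metadata$hbond_truth
  h <- select_atoms(d$topology, "DON:HD")
  pred <- matrix(FALSE, 20, 25)
  for (row in seq_len(nrow(det))) {
    k <- match(det$h[row], h)
    pred[k, det$frame[row]] <- TRUE
  }
  tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  f1 <- 2 * tp / (2 * tp + fp + fn)
  expect_equal(f1, 1.0)
})

test_that("count series follows the schedule and ignores molecule numbering", {
  sched <- matrix(FALSE, 6, 12)
  withr::with_seed(54, {
    for (k in 1:6) sched[k, sample(12, 7)] <- TRUE
  })
  d <- gen_hbond_dimers(6, n_frames = 12, occupancy = sched, seed = 55)
  s <- count_series(d, hbond_criteria(2.5, 130))
  expect_equal(s$n_bonds, colSums(sched))
  # relabeling oracle: reverse the dimer order (both species blocks)
  perm <- c(rbind(rev(seq(1, 11, 2)), rev(seq(2, 12, 2))),
            12 + c(rbind(rev(seq(1, 11, 2)), rev(seq(2, 12, 2)))))
  d2 <- d
  d2$coords <- d$coords[perm, , , drop = FALSE]
  s2 <- count_series(d2, hbond_criteria(2.5, 130))
  expect_equal(sort(s2$n_bonds), sort(s$n_bonds))
  # empty criteria match gives the all-zero series
  none <- count_series(d, hbond_criteria(0.5, 170))
  expect_true(all(none$n_bonds == 0))
})

test_that("occupancy reports schedule fractions and excludes never-bonded pairs", {
  sched <- matrix(FALSE, 3, 100)
  sched[1, 1:37] <- TRUE     # 37 percent
  sched[2, ] <- TRUE         # always bonded
  d <- gen_hbond_dimers(3, n_frames = 100, occupancy = sched, seed = 56)
  occ <- percent_occupancy(count_series(d, hbond_criteria(2.5, 130)))
  expect_equal(nrow(occ), 2L)           # the never-bonded pair is excluded
  expect_equal(sort(occ$occupancy), c(37.0, 100.0))
  expect_equal(attr(occ, "class_mean"), mean(c(37, 100)))
  # occupancy is frame-order invariant
  d2 <- gen_hbond_dimers(3, n_frames = 100,
                         occupancy = sched[, c(51:100, 1:50)], seed = 56)
  occ2 <- percent_occupancy(count_series(d2, hbond_criteria(2.5, 130)))
  expect_equal(sort(occ2$occupancy), sort(occ$occupancy))
})

test_that("the Gaussian fit recovers histogram and sampling parameters", {
  # exact discretized Gaussian: parameters recovered to 1e-6
  X <- seq(150, 250)
  dens <- 1 / (10 * sqrt(2 * pi)) * exp(-(X - 200)^2 / (2 * 10^2))
  fit <- fit_gaussian(data.frame(X = X, density = dens))
  expect_equal(fit$mean, 200, tolerance = 1e-6)
  expect_equal(fit$sd, 10, tolerance = 1e-6)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)

  # near-Gaussian sampled counts
  counts <- withr::with_seed(57, round(rnorm(5000, 200, 10)))
  fit2 <- fit_gaussian(counts)
  expect_lt(abs(fit2$mean - 200), 1)
  expect_lt(abs(fit2$sd - 10) / 10, 0.1)
  # the fitted mean tracks the sample mean for unimodal histograms
  expect_lt(abs(fit2$mean - mean(counts)) / mean(counts), 0.02)

  # binomial bond counts: n_pairs = 100, p = 0.37
  counts3 <- withr::with_seed(58, rbinom(5000, 100, 0.37))
  fit3 <- fit_gaussian(counts3)
  expect_lt(abs(fit3$mean - 37) / 37, 0.02)

  expect_error(fit_gaussian(rep(5, 100)), "degenerate")
})
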