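# Synthetic trajectories with analytically known structure and dynamics.
# Each generator is a pure function of its seed (identical arguments give
# bit-identical output) and embeds its ground truth in trajectory metadata
# so tests cannot pair data with the wrong truth.

point_species <- function(name = "GAS", element = "Ar", mass = 39.948,
                          charge = 0, lj_epsilon = 0, lj_rmin_half = 1.0) {
  species_topology(name, tibble(
    label = "X1", element = element, mass = mass, charge = charge,
    lj_epsilon = lj_epsilon, lj_rmin_half = lj_rmin_half))
}

#' Ideal-gas trajectory: i.i.d. uniform positions each frame
#'
#' Null model for structural estimators: a structureless fluid whose radial
#' distribution function is identically 1.
#'
#' @param n Number of particles.
#' @param box Length-3 box (A) or scalar (cubic).
#' @param n_frames Number of frames.
#' @param dt Timestep (ps).
#' @param seed RNG seed (recorded in metadata).
#' @return A `mix_traj` of single-atom molecules.
#' @export
gen_ideal_gas <- function(n, box, n_frames = 100, dt = 1, seed = 1) {
  if (length(box) == 1L) box <- rep(box, 3)
  coords <- withr::with_seed(seed, {
    array(runif(n * 3 * n_frames) * rep(box, each = n), dim = c(n, 3, n_frames))
  })
  top <- system_topology(list(point_species()), n)
  trajectory(coords, box, top, dt = dt,
             metadata = list(kind = "ideal_gas", seed = seed))
}

#' Brownian trajectory with known diffusion coefficient
#'
#' Free diffusion: per-axis increments are i.i.d. normal with variance
#' `2 D dt`, so the ensemble mean-square displacement is `6 D t` exactly in
#' expectation. Coordinates are stored unwrapped (continuous); a wrapped
#' copy is obtainable with [wrap()].
#'
#' @param n Number of particles.
#' @param box Box (A); starting positions are uniform inside it.
#' @param D Diffusion coefficient (A^2/ps), >= 0.
#' @param dt Timestep (ps), > 0.
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @return Unwrapped `mix_traj`; `metadata$D` carries the ground truth.
#' @export
gen_brownian <- function(n, box, D = 1, dt = 0.1, n_frames = 1000, seed = 1) {
  stopifnot(D >= 0, dt > 0)
  if (length(box) == 1L) box <- rep(box, 3)
  coords <- withr::with_seed(seed, {
    x0 <- matrix(runif(n * 3) * rep(box, each = n), ncol = 3)
    steps <- array(rnorm(n * 3 * (n_frames - 1), sd = sqrt(2 * D * dt)),
                   dim = c(n, 3, n_frames - 1))
    out <- array(NA_real_, dim = c(n, 3, n_frames))
    out[, , 1] <- x0
    for (f in seq_len(n_frames - 1)) out[, , f + 1] <- out[, , f] + steps[, , f]
    out
  })
  top <- system_topology(list(point_species()), n)
  trajectory(coords, box, top, dt = dt, unwrapped = TRUE,
             metadata = list(kind = "brownian", seed = seed, D = D))
}

#' Ballistic trajectory: constant random velocities
#'
#' Every particle moves in a straight line, so the ensemble MSD is
#' `<v^2> t^2` and the log-log slope (beta parameter) is exactly 2.
#'
#' @param n Number of particles.
#' @param box Box (A).
#' @param speed Particle speed (A/ps); either a scalar (all speeds equal)
#'   or a length-`n` vector.
#' @param dt Timestep (ps).
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @return Unwrapped `mix_traj` with velocities;
#'   `metadata$mean_sq_speed` carries `<v^2>`.
#' @export
gen_ballistic <- function(n, box, speed = 1, dt = 0.1, n_frames = 100, seed = 1) {
  if (length(box) == 1L) box <- rep(box, 3)
  speed <- rep_len(speed, n)
  res <- withr::with_seed(seed, {
    x0 <- matrix(runif(n * 3) * rep(box, each = n), ncol = 3)
    u <- matrix(rnorm(n * 3), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    v <- u * speed
    list(x0 = x0, v = v)
  })
  coords <- array(NA_real_, dim = c(n, 3, n_frames))
  vels <- array(NA_real_, dim = c(n, 3, n_frames))
  for (f in seq_len(n_frames)) {
    coords[, , f] <- res$x0 + res$v * (f - 1) * dt
    vels[, , f] <- res$v
  }
  top <- system_topology(list(point_species()), n)
  trajectory(coords, box, top, dt = dt, velocities = vels, unwrapped = TRUE,
             metadata = list(kind = "ballistic", seed = seed,
                             mean_sq_speed = mean(speed^2)))
}

#' Rotationally diffusing unit vectors
#'
#' Each vector performs isotropic angular diffusion: per step it rotates by
#' an angle drawn with variance `4 D_r dt` about a random axis perpendicular
#' to itself, then is renormalized. The first-rank orientational
#' correlation of such a vector decays as `exp(-2 D_r tau)`.
#'
#' @param n Number of rotors.
#' @param D_r Rotational diffusion coefficient (1/ps), >= 0. The small-step
#'   regime `D_r dt << 1` is assumed.
#' @param dt Timestep (ps).
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @return A `mix_vectors` object (array `n x 3 x n_frames` of unit
#'   vectors with times and metadata; `metadata$D_r` is the ground truth).
#' @export
gen_rotor <- function(n, D_r = 0.05, dt = 0.01, n_frames = 500, seed = 1) {
  stopifnot(D_r >= 0, dt > 0)
  vecs <- withr::with_seed(seed, {
    u <- matrix(rnorm(n * 3), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    out <- array(NA_real_, dim = c(n, 3, n_frames))
    out[, , 1] <- u
    if (n_frames > 1L) {
      for (f in 2:n_frames) {
        if (D_r > 0) {
          theta <- rnorm(n, sd = sqrt(4 * D_r * dt))
          # random perpendicular axis per rotor
          raw <- matrix(rnorm(n * 3), ncol = 3)
          proj <- rowSums(raw * u)
          ax <- raw - u * proj
          ax <- ax / sqrt(rowSums(ax^2))
          # Rodrigues rotation of u about ax by theta (u is perpendicular to ax)
          cosv <- cos(theta); sinv <- sin(theta)
          cr <- cbind(ax[, 2] * u[, 3] - ax[, 3] * u[, 2],
                      ax[, 3] * u[, 1] - ax[, 1] * u[, 3],
                      ax[, 1] * u[, 2] - ax[, 2] * u[, 1])
          u <- u * cosv + cr * sinv
          u <- u / sqrt(rowSums(u^2))
        }
        out[, , f] <- u
      }
    }
    out
  })
  structure(
    list(vectors = vecs, times = (seq_len(n_frames) - 1) * dt, dt = dt,
         definition = "synthetic rotor",
         metadata = list(kind = "rotor", seed = seed, D_r = D_r)),
    class = "mix_vectors"
  )
}

#' @export
print.mix_vectors <- function(x, ...) {
  cat(sprintf("<mix_vectors> %d vectors x %d frames, dt = %g ps (%s)\n",
              dim(x$vectors)[1], dim(x$vectors)[3], x$dt, x$definition))
  invisible(x)
}

#' Donor-H...acceptor dimer trajectory with controlled geometry
#'
#' Places isolated donor/acceptor molecule pairs on a cubic lattice with
#' spacing large enough that dimers never cross-talk (separation beyond
#' twice the detection distance). In bonded frames the H...acceptor
#' distance is `r0 +/- jitter_r` and the donor-H...acceptor angle is
#' `theta0 +/- jitter_theta`; in broken frames (per the occupancy schedule)
#' the acceptor is displaced beyond `2 * criteria_r_max`. The exact
#' per-frame bond labels are stored in `metadata$hbond_truth`.
#'
#' The donor species `DON` has atoms `OD` (heavy) and `HD` (donor H); the
#' acceptor species `ACC` has atoms `OA` (acceptor) and a bonded carbon
#' `CA`, so both the donor-H...A and the H...A-X angle conventions are
#' exercised.
#'
#' @param n_dimers Number of donor/acceptor pairs.
#' @param n_frames Number of frames.
#' @param r0 Target H...acceptor distance (A).
#' @param theta0 Target donor-H...acceptor angle (degrees).
#' @param jitter_r Half-width of uniform jitter on the distance (A).
#' @param jitter_theta Half-width of uniform jitter on the angle (degrees).
#' @param occupancy Logical matrix `n_dimers x n_frames` (TRUE = bonded),
#'   or a single fraction in `[0, 1]`: the first `round(f * n_frames)`
#'   frames of every pair are bonded.
#' @param criteria_r_max Detection distance the fixture is built around
#'   (controls lattice spacing and the broken displacement).
#' @param dt Timestep (ps).
#' @param seed RNG seed.
#' @return A `mix_traj`; ground truth in `metadata`.
#' @export
gen_hbond_dimers <- function(n_dimers, n_frames = 100, r0 = 2.0, theta0 = 150,
                             jitter_r = 0, jitter_theta = 0, occupancy = 1,
                             criteria_r_max = 2.5, dt = 1, seed = 1) {
  if (is.matrix(occupancy)) {
    stopifnot(nrow(occupancy) == n_dimers, ncol(occupancy) == n_frames)
    sched <- occupancy
  } else {
    stopifnot(occupancy >= 0, occupancy <= 1)
    k <- round(occupancy * n_frames)
    sched <- matrix(FALSE, n_dimers, n_frames)
    if (k > 0) sched[, seq_len(k)] <- TRUE
  }
  r_broken <- 2 * criteria_r_max + 1 + r0
  spacing <- 2 * (r_broken + jitter_r) + 4
  n_side <- ceiling(n_dimers^(1 / 3))
  box <- rep(n_side * spacing, 3)
  grid <- as.matrix(expand.grid(x = seq_len(n_side), y = seq_len(n_side),
                                z = seq_len(n_side)))[seq_len(n_dimers), , drop = FALSE]
  centers <- (grid - 0.5) * spacing
  l_oh <- 1.0
  l_ca <- 1.2
  don <- species_topology("DON", tibble(
    label = c("OD", "HD"), element = c("O", "H"),
    mass = c(15.999, 1.008), charge = c(-0.4, 0.4),
    lj_epsilon = c(0.21, 0.046), lj_rmin_half = c(1.77, 0.2245)),
    bonds = rbind(c(1L, 2L)),
    donors = tibble(heavy = "OD", hydrogen = "HD"))
  acc <- species_topology("ACC", tibble(
    label = c("OA", "CA"), element = c("O", "C"),
    mass = c(15.999, 12.011), charge = c(-0.3, 0.3),
    lj_epsilon = c(0.21, 0.07), lj_rmin_half = c(1.77, 2.0)),
    bonds = rbind(c(1L, 2L)),
    acceptors = "OA")
  # atom order must match topology block structure: all DON molecules then
  # all ACC molecules, molecules contiguous
  top <- system_topology(list(don, acc), c(n_dimers, n_dimers))
  n_at <- 4L * n_dimers
  coords <- withr::with_seed(seed, {
    out <- array(NA_real_, dim = c(n_at, 3, n_frames))
    for (f in seq_len(n_frames)) {
      u <- matrix(rnorm(n_dimers * 3), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      raw <- matrix(rnorm(n_dimers * 3), ncol = 3)
      p <- raw - u * rowSums(raw * u)
      p <- p / sqrt(rowSums(p^2))
      th <- (theta0 + runif(n_dimers, -jitter_theta, jitter_theta)) * pi / 180
      r <- r0 + runif(n_dimers, -jitter_r, jitter_r)
      r[!sched[, f]] <- r_broken
      d_pos <- centers
      h_pos <- centers + u * l_oh
      w <- -u * cos(th) + p * sin(th)   # unit vector at angle theta to H->D
      a_pos <- h_pos + w * r
      c_pos <- a_pos + w * l_ca
      for (m in seq_len(n_dimers)) {
        out[2L * (m - 1L) + 1L, , f] <- d_pos[m, ]
        out[2L * (m - 1L) + 2L, , f] <- h_pos[m, ]
        out[2L * n_dimers + 2L * (m - 1L) + 1L, , f] <- a_pos[m, ]
        out[2L * n_dimers + 2L * (m - 1L) + 2L, , f] <- c_pos[m, ]
      }
    }
    out
  })
  trajectory(coords, box, top, dt = dt,
             metadata = list(kind = "hbond_dimers", seed = seed,
                             r0 = r0, theta0 = theta0, jitter_r = jitter_r,
                             jitter_theta = jitter_theta,
                             criteria_r_max = criteria_r_max,
                             hbond_truth = sched))
}

#' Equilibrated Lennard-Jones fluid configurations (Metropolis Monte Carlo)
#'
#' A structured-liquid fixture: at liquid-like reduced density and
#' temperature the radial distribution function shows the first peak,
#' shoulder and first minimum that solvation-shell analyses assume.
#' The pair potential is the same R_min-form 12-6 used by the energetics
#' module (`eps [ (R0/r)^12 - 2 (R0/r)^6 ]` with `R0 = 2^(1/6) sigma`),
#' with a plain cutoff, so configuration energies cross-check exactly.
#'
#' @param n Number of particles (<= 500 keeps equilibration fast).
#' @param rho_star Reduced density `n sigma^3 / V`.
#' @param T_star Reduced temperature `kB T / eps`.
#' @param sigma LJ sigma (A).
#' @param epsilon LJ well depth (kcal/mol).
#' @param n_frames Configurations to sample.
#' @param n_equil_sweeps Equilibration sweeps before sampling.
#' @param sweeps_per_sample Decorrelation sweeps between samples.
#' @param cutoff Pair cutoff (A); default `min(3 sigma, L/2)`.
#' @param seed RNG seed.
#' @return A `mix_traj`; `metadata` records energies, acceptance ratio and
#'   the potential parameters.
#' @export
gen_lj_fluid <- function(n = 200, rho_star = 0.8, T_star = 1.0, sigma = 1.0,
                         epsilon = 1.0, n_frames = 50, n_equil_sweeps = 1500,
                         sweeps_per_sample = 10, cutoff = NULL, seed = 1) {
  stopifnot(n <= 500)
  L <- (n / rho_star)^(1 / 3) * sigma
  box <- rep(L, 3)
  if (is.null(cutoff)) cutoff <- min(3 * sigma, L / 2)
  r0 <- 2^(1 / 6) * sigma
  # beta in reduced units; with no well depth every move is accepted
  beta <- if (epsilon > 0) 1 / (T_star * epsilon) else 0
  res <- withr::with_seed(seed, {
    # start from a perturbed cubic lattice to avoid overlaps
    n_side <- ceiling(n^(1 / 3))
    g <- as.matrix(expand.grid(seq_len(n_side), seq_len(n_side),
                               seq_len(n_side)))[seq_len(n), ]
    init <- (g - 0.5) * (L / n_side) +
      matrix(runif(n * 3, -0.05, 0.05) * sigma, ncol = 3)
    init <- init - box[1] * floor(init / box[1])
    lj_mc_cpp(init, box, epsilon, r0, beta, cutoff, 0.25 * sigma,
              as.integer(n_equil_sweeps), as.integer(n_frames),
              as.integer(sweeps_per_sample))
  })
  energies <- res$energies
  if (n_frames >= 10) {
    # crude convergence check: first and second production halves should
    # agree within a few standard errors
    h1 <- energies[seq_len(floor(n_frames / 2))]
    h2 <- energies[(floor(n_frames / 2) + 1):n_frames]
    pooled_se <- sqrt(var(h1) / length(h1) + var(h2) / length(h2))
    if (pooled_se > 0 && abs(mean(h1) - mean(h2)) > 6 * pooled_se) {
      abort("gen_lj_fluid: energy drift test failed; increase n_equil_sweeps")
    }
  }
  coords <- array(unlist(res$frames), dim = c(n, 3, n_frames))
  top <- system_topology(list(point_species(
    name = "LJ", element = "Ar", mass = 39.948, charge = 0,
    lj_epsilon = epsilon, lj_rmin_half = r0 / 2)), n)
  trajectory(coords, box, top, dt = 1,
             metadata = list(kind = "lj_fluid", seed = seed, sigma = sigma,
                             epsilon = epsilon, rho_star = rho_star,
                             T_star = T_star, cutoff = cutoff,
                             energies = energies, acceptance = res$acceptance))
}

#' Construct a pressure-tensor series object
#'
#' @param data Data frame with columns `time` (ps), `Pxy`, `Pxz`, `Pyz`
#'   (and optionally `Pxx`, `Pyy`, `Pzz`).
#' @param volume Box volume (A^3), > 0.
#' @param temperature Temperature (K), > 0.
#' @param units Pressure units of the components: `"atm"` or
#'   `"kcal/mol/A3"`.
#' @param metadata Free-form list.
#' @return Tibble subclass `mix_pressure_series`.
#' @export
pressure_series <- function(data, volume, temperature, units = "atm",
                            metadata = list()) {
  data <- as_tibble(data)
  stopifnot(all(c("time", "Pxy", "Pxz", "Pyz") %in% names(data)),
            volume > 0, temperature > 0)
  if (nrow(data) > 1L) {
    d <- diff(data$time)
    if ((max(d) - min(d)) > 1e-9 * max(abs(d))) {
      abort("pressure series must be uniformly spaced in time")
    }
  }
  if (any(!is.finite(as.matrix(data[, c("Pxy", "Pxz", "Pyz")])))) {
    abort("pressure components must be finite")
  }
  units <- match.arg(units, c("atm", "kcal/mol/A3"))
  structure(data,
            volume = volume, temperature = temperature, units = units,
            metadata = metadata,
            class = c("mix_pressure_series", class(data)))
}

#' Ornstein-Uhlenbeck off-diagonal pressure-tensor series
#'
#' Three independent OU components (xy, xz, yz) with stationary standard
#' deviation `sigma_P` and correlation time `tau_c`, discretized exactly as
#' an AR(1) process with coefficient `exp(-dt/tau_c)`. For such a series
#' the Green-Kubo integral has the closed form
#' `eta = (V / kB T) sigma_P^2 tau_c`, making it the oracle for
#' [green_kubo_viscosity()].
#'
#' @param n_steps Series length.
#' @param dt Sampling interval (ps); should satisfy `dt << tau_c`.
#' @param sigma_P Stationary standard deviation of each component.
#' @param tau_c Correlation time (ps).
#' @param volume Box volume (A^3).
#' @param temperature Temperature (K).
#' @param units Pressure units of `sigma_P` (`"atm"` or `"kcal/mol/A3"`).
#' @param seed RNG seed.
#' @return A `mix_pressure_series`; metadata carries `sigma_P`, `tau_c` and
#'   the seed.
#' @export
gen_ou_pressure <- function(n_steps = 1e5, dt = 0.05, sigma_P = 100,
                            tau_c = 1, volume = 1e4, temperature = 323,
                            units = "atm", seed = 1) {
  stopifnot(dt > 0, tau_c > 0, sigma_P >= 0)
  phi <- exp(-dt / tau_c)
  comps <- withr::with_seed(seed, {
    lapply(1:3, function(k) {
      if (sigma_P == 0) return(rep(0, n_steps))
      innov <- rnorm(n_steps, sd = sigma_P * sqrt(1 - phi^2))
      innov[1] <- rnorm(1, sd = sigma_P)
      as.numeric(stats::filter(innov, phi, method = "recursive"))
    })
  })
  pressure_series(
    tibble(time = (seq_len(n_steps) - 1) * dt,
           Pxy = comps[[1]], Pxz = comps[[2]], Pyz = comps[[3]]),
    volume = volume, temperature = temperature, units = units,
    metadata = list(kind = "ou_pressure", seed = seed, sigma_P = sigma_P,
                    tau_c = tau_c))
}
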