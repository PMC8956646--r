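#' Virial pressure tensor from a trajectory with velocities
#'
#' `P_ab = (1/V) [ sum_i m_i v_ia v_ib + sum_{i<j} r_ij,a F_ij,b ]` with
#' the kinetic term from per-atom momenta and the virial term from the
#' pairwise Lennard-Jones + Coulomb forces of the energetics parameters,
#' under minimum image and a plain cutoff. Off-diagonal components feed
#' the Green-Kubo viscosity integral; diagonal components are retained for
#' diagnostics. Components are in internal units kcal/(mol A^3).
#'
#' @param traj A `mix_traj` carrying velocities (A/ps).
#' @param cutoff Pair cutoff (A), at most `min(box)/2`.
#' @param temperature Temperature (K) recorded on the series; default is
#'   estimated from the kinetic energy by equipartition.
#' @param include_intramolecular Include 1-4+ intramolecular pairs.
#' @param frames Optional frame subset.
#' @return A `mix_pressure_series` with columns `time`, `Pxy`, `Pxz`,
#'   `Pyz`, `Pxx`, `Pyy`, `Pzz`.
#' @export
compute_pressure_tensor <- function(traj, cutoff = 12, temperature = NULL,
                                    include_intramolecular = FALSE,
                                    frames = NULL) {
  stopifnot(inherits(traj, "mix_traj"))
  if (is.null(traj$velocities)) {
    abort("trajectory carries no velocities; the kinetic term requires them")
  }
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  if (cutoff > min(traj$box[frames, ]) / 2 + 1e-9) {
    abort(sprintf("cutoff %g exceeds min(box)/2", cutoff))
  }
  at <- traj$topology$atoms
  excl <- exclusion_pairs(traj$topology)
  comp <- matrix(NA_real_, length(frames), 6)
  for (k in seq_along(frames)) {
    f <- frames[k]
    vel <- traj$velocities[, , f, drop = FALSE]; dim(vel) <- dim(vel)[1:2]
    P <- virial_frame_cpp(frame_coords(traj, f), vel, traj$box[f, ],
                          at$charge, at$lj_epsilon, at$lj_rmin_half,
                          at$mass, at$molecule, cutoff,
                          include_intramolecular, excl, .COULOMB_K,
                          .KE_TO_KCAL) / prod(traj$box[f, ])
    comp[k, ] <- c(P[1, 2], P[1, 3], P[2, 3], P[1, 1], P[2, 2], P[3, 3])
  }
  if (is.null(temperature)) {
    ke <- mean(vapply(frames, function(f) {
      vel <- traj$velocities[, , f, drop = FALSE]; dim(vel) <- dim(vel)[1:2]
      0.5 * sum(at$mass * rowSums(vel^2)) * .KE_TO_KCAL
    }, numeric(1)))
    temperature <- 2 * ke / (3 * nrow(at) * .KB_KCAL)
  }
  pressure_series(
    tibble(time = traj$times[frames],
           Pxy = comp[, 1], Pxz = comp[, 2], Pyz = comp[, 3],
           Pxx = comp[, 4], Pyy = comp[, 5], Pzz = comp[, 6]),
    volume = mean(apply(traj$box[frames, , drop = FALSE], 1, prod)),
    temperature = temperature, units = "kcal/mol/A3",
    metadata = list(cutoff = cutoff))
}

# unnormalized all-origins autocorrelation C(L) = sum_t x_t x_{t+L} / (N - L)
acf_unnormalized <- function(x, max_lag) {
  n <- length(x)
  x <- x - mean(x)
  nfft <- 2^ceiling(log2(2 * n))
  fx <- fft(c(x, rep(0, nfft - n)))
  ac <- Re(fft(fx * Conj(fx), inverse = TRUE))[1:(max_lag + 1L)] / nfft
  ac / (n - 0:max_lag)
}

#' Green-Kubo shear viscosity from the pressure-tensor autocorrelation
#'
#' `eta = (V / kB T) integral_0^inf < P_xy(0) P_xy(t) > dt`. The
#' unnormalized autocorrelation is computed with all time origins for each
#' off-diagonal component, the three components are averaged (a standard
#' noise reduction; recorded in the result), and the running integral is
#' accumulated by the trapezoid rule. The plateau estimate is read at the
#' first zero crossing of the averaged ACF (beyond it the tail of a finite
#' series is noise-dominated); if no crossing occurs within `max_lag` a
#' warning is issued and the fixed-lag value at `max_lag` is reported.
#'
#' @param series A `mix_pressure_series` (units `"atm"` or
#'   `"kcal/mol/A3"`; volume in A^3, temperature in K).
#' @param max_lag Maximum lag in steps (default: a fifth of the series).
#' @param truncation_policy `"zero-crossing"` or `"fixed"` (report at
#'   `max_lag`).
#' @return Object of class `mix_viscosity`: `eta` (mPa s),
#'   `truncation_lag` (ps), `acf` (tibble `lag`, `acf`; input pressure
#'   units squared), `running` (tibble `lag`, `eta`), plus the `V`, `T`
#'   and unit bookkeeping used.
#' @export
green_kubo_viscosity <- function(series, max_lag = NULL,
                                 truncation_policy = c("zero-crossing", "fixed")) {
  stopifnot(inherits(series, "mix_pressure_series"))
  truncation_policy <- match.arg(truncation_policy)
  n <- nrow(series)
  if (n < 10L) abort("pressure series too short")
  if (is.null(max_lag)) max_lag <- max(10L, floor(n / 5))
  max_lag <- min(max_lag, n - 2L)
  dt <- series$time[2] - series$time[1]
  comps <- cbind(series$Pxy, series$Pxz, series$Pyz)
  if (all(comps == 0)) {
    acf_avg <- rep(0, max_lag + 1L)
  } else {
    acf_avg <- rowMeans(vapply(1:3, function(k) {
      acf_unnormalized(comps[, k], max_lag)
    }, numeric(max_lag + 1L)))
  }
  V <- attr(series, "volume")
  Temp <- attr(series, "temperature")
  u <- switch(attr(series, "units"),
              "atm" = .ATM_TO_PA,
              "kcal/mol/A3" = .KCAL_MOL_A3_TO_PA)
  # (V[m^3] / kB T) * ACF[Pa^2] * dt[s] -> Pa s; report mPa s
  pref <- (V * 1e-30) / (.KB_J * Temp) * u^2 * 1e-12 * 1e3
  run <- pref * c(0, pracma::cumtrapz(seq(0, by = dt, length.out = max_lag + 1L),
                                      acf_avg)[-1])
  crossing <- which(acf_avg < 0)[1]
  if (truncation_policy == "zero-crossing" && !is.na(crossing)) {
    trunc_idx <- crossing
  } else {
    if (truncation_policy == "zero-crossing" && any(acf_avg != 0)) {
      warn("ACF has no zero crossing within max_lag; falling back to the fixed-lag value")
    }
    trunc_idx <- max_lag + 1L
  }
  lags <- seq(0, by = dt, length.out = max_lag + 1L)
  structure(list(eta = run[trunc_idx], truncation_lag = lags[trunc_idx],
                 policy = truncation_policy,
                 acf = tibble(lag = lags, acf = acf_avg),
                 running = tibble(lag = lags, eta = run),
                 volume = V, temperature = Temp,
                 units = attr(series, "units"),
                 components_averaged = 3L),
            class = "mix_viscosity")
}

#' @export
print.mix_viscosity <- function(x, ...) {
  cat(sprintf("<viscosity> eta = %.4g mPa s (truncated at %g ps, %s; 3 components averaged)\n",
              x$eta, x$truncation_lag, x$policy))
  invisible(x)
}

#' @export
glance.mix_viscosity <- function(x, ...) {
  tibble(eta_mPas = x$eta, truncation_lag_ps = x$truncation_lag,
         policy = x$policy, volume_A3 = x$volume, temperature_K = x$temperature)
}

#' @export
tidy.mix_viscosity <- function(x, ...) {
  left_join(x$acf, x$running, by = "lag")
}

#' @export
autoplot.mix_viscosity <- function(object, ...) {
  df <- object$running
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag, y = .data$eta)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$truncation_lag,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = object$eta, linetype = "dotted",
                        colour = "firebrick") +
    ggplot2::labs(x = "upper integration limit (ps)",
                  y = expression(eta(t) ~ (mPa %.% s)))
}

#' @export
autoplot.mix_pressure_series <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object)[, c("time", "Pxy", "Pxz", "Pyz")],
                            -"time", names_to = "component",
                            values_to = "P")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$P,
                                   colour = .data$component)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "time (ps)",
                  y = sprintf("pressure (%s)", attr(object, "units")))
}
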