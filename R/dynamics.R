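#' Mean-square displacement of molecular centers of mass
#'
#' `MSD(tau) = (1/N) < sum_i | r_i^COM(t + tau) - r_i^COM(t) |^2 >`,
#' averaged over all molecules of the species and all time origins
#' (stride 1). Centers of mass are mass-weighted with hydrogens included.
#' Requires unwrapped (continuous) coordinates: wrapped input -- any
#' inter-frame minimum-image jump at the half-box limit, or an explicit
#' `unwrapped = FALSE` trajectory showing such jumps -- is rejected with a
#' pointer to [unwrap()].
#'
#' Two equivalent evaluation paths exist: an FFT-accelerated one (default)
#' and a direct double loop; they agree to 1e-8 relative and the direct
#' path serves as the oracle in the test-suite.
#'
#' @param traj An unwrapped `mix_traj`.
#' @param species Optional species restriction.
#' @param max_lag_fraction Largest lag as a fraction of the trajectory
#'   length (default 0.5: longer lags average too few origins).
#' @param method `"fft"` or `"direct"`.
#' @return Tibble subclass `mix_msd` with columns `lag` (ps), `msd` (A^2),
#'   `n_samples` (origin-molecule pairs per lag).
#' @export
compute_msd <- function(traj, species = NULL, max_lag_fraction = 0.5,
                        method = c("fft", "direct")) {
  stopifnot(inherits(traj, "mix_traj"))
  method <- match.arg(method)
  if (!traj$unwrapped) {
    # wrapped-coordinate heuristic: any inter-frame jump at the box scale
    nf <- n_frames(traj)
    if (nf > 1L) {
      for (f in 2:nf) {
        jump <- abs(traj$coords[, , f] - traj$coords[, , f - 1])
        lim <- matrix(traj$box[f, ] / 2, nrow(jump), 3, byrow = TRUE)
        if (any(jump >= lim)) {
          abort("trajectory looks wrapped (inter-frame jump >= box/2); run unwrap() first")
        }
      }
    }
  }
  com <- com_coords(traj, species)
  n_mol <- dim(com)[1]
  nf <- dim(com)[3]
  max_lag <- max(1L, floor(max_lag_fraction * (nf - 1L)))
  msd <- if (method == "fft") msd_fft(com, max_lag) else msd_direct(com, max_lag)
  out <- tibble(lag = (0:max_lag) * traj$dt, msd = msd,
                n_samples = (nf - 0:max_lag) * n_mol)
  structure(out, species = species, dt = traj$dt, n_molecules = n_mol,
            class = c("mix_msd", class(out)))
}

msd_direct <- function(com, max_lag) {
  nf <- dim(com)[3]
  vapply(0:max_lag, function(L) {
    if (L == 0) return(0)
    d <- com[, , (1 + L):nf, drop = FALSE] - com[, , 1:(nf - L), drop = FALSE]
    mean(apply(d^2, c(1, 3), sum))
  }, numeric(1))
}

msd_fft <- function(com, max_lag) {
  # per molecule and axis: MSD_L = S1(L) - 2 S2(L), S2 by FFT autocorrelation
  n_mol <- dim(com)[1]; nf <- dim(com)[3]
  nfft <- 2^ceiling(log2(2 * nf))
  # stack all (molecule, axis) series as columns
  xm <- matrix(0, nfft, n_mol * 3)
  for (d in 1:3) {
    xm[1:nf, (d - 1) * n_mol + seq_len(n_mol)] <- t(com[, d, , drop = FALSE][, 1, ])
  }
  fx <- mvfft(xm)
  ac <- Re(mvfft(fx * Conj(fx), inverse = TRUE))[1:nf, , drop = FALSE] / nfft
  x2 <- xm[1:nf, , drop = FALSE]^2
  # recursive S1: sum_t (x_t^2 + x_{t+L}^2) over valid origins
  msd_cols <- matrix(0, max_lag + 1L, ncol(xm))
  q <- 2 * colSums(x2)
  for (L in 0:max_lag) {
    if (L > 0) q <- q - x2[L, ] - x2[nf - L + 1L, ]
    msd_cols[L + 1L, ] <- q / (nf - L) - 2 * ac[L + 1L, ] / (nf - L)
  }
  # sum axes, average molecules
  out <- numeric(max_lag + 1L)
  for (d in 1:3) {
    out <- out + rowMeans(msd_cols[, (d - 1) * n_mol + seq_len(n_mol), drop = FALSE])
  }
  out[1] <- 0
  # the S1 - 2 S2 cancellation leaves O(eps * x^2) residue on static input
  out[abs(out) < 1e-10 * max(mean(x2), 1e-300)] <- 0
  pmax(out, 0)
}

#' Logarithmic MSD slope (beta parameter)
#'
#' `beta(t) = d log10 MSD / d log10 t`, evaluated by centered finite
#' differences on a (optionally smoothed) MSD series. `beta = 2` marks
#' ballistic motion, `beta = 1` the diffusive regime in which Einstein
#' fits are valid.
#'
#' @param msd A `mix_msd`.
#' @param smooth_window Moving-average window on the MSD before
#'   differencing (default 1 = none).
#' @return Tibble subclass `mix_beta` with columns `lag`, `beta`.
#' @export
compute_beta <- function(msd, smooth_window = 1) {
  stopifnot(inherits(msd, "mix_msd"))
  keep <- msd$lag > 0 & msd$msd > 0
  t <- msd$lag[keep]; m <- smooth_ma(msd$msd[keep], smooth_window)
  if (length(t) < 3L) abort("fewer than 3 positive MSD lags; cannot form beta")
  lt <- log10(t); lm <- log10(m)
  n <- length(t)
  beta <- rep(NA_real_, n)
  beta[2:(n - 1)] <- (lm[3:n] - lm[1:(n - 2)]) / (lt[3:n] - lt[1:(n - 2)])
  out <- tibble(lag = t, beta = beta)
  structure(out, smooth_window = smooth_window,
            class = c("mix_beta", class(out)))
}

#' Einstein self-diffusion coefficient from the diffusive regime
#'
#' Fits `MSD = 6 D t + c` by ordinary least squares over the diffusive
#' window and reports `D = slope / 6`. By default the window is the
#' longest contiguous run of lags with `|beta - 1| <= beta_tol`
#' (default 0.1); alternatively a fixed time window (e.g. the tail decade
#' of a long trajectory) can be imposed.
#'
#' @param msd A `mix_msd`.
#' @param beta Optional precomputed `mix_beta` (computed if `NULL` and no
#'   window given).
#' @param window Optional fixed `c(t_lo, t_hi)` window (ps) overriding the
#'   beta policy.
#' @param beta_tol Tolerance defining "diffusive" (default 0.1).
#' @param beta_smooth Smoothing window passed to [compute_beta()].
#' @return Object of class `mix_diffusion`: `D` (A^2/ps), `D_A2_ns`
#'   (A^2/ns), `se` (standard error of D), `window`, `beta_mean`.
#' @export
estimate_diffusion <- function(msd, beta = NULL, window = NULL,
                               beta_tol = 0.1, beta_smooth = 5) {
  stopifnot(inherits(msd, "mix_msd"))
  if (is.null(window)) {
    if (is.null(beta)) beta <- compute_beta(msd, smooth_window = beta_smooth)
    ok <- !is.na(beta$beta) & abs(beta$beta - 1) <= beta_tol
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    # a run shorter than 3 lags is smoothing noise, not a diffusive regime
    if (!length(runs) || max(r$lengths[runs]) < 3L) {
      cnd <- rlang::error_cnd(
        "mix_no_diffusive_regime",
        message = "no diffusive regime (|beta - 1| <= tol nowhere): subdiffusive or insufficient sampling",
        beta = beta)
      stop(cnd)
    }
    best <- runs[which.max(r$lengths[runs])]
    window <- c(beta$lag[starts[best]], beta$lag[ends[best]])
  }
  sel <- msd$lag >= window[1] & msd$lag <= window[2] & msd$lag > 0
  if (sum(sel) < 2L) abort("diffusive window contains fewer than 2 lags")
  fit <- lm(msd ~ lag, data = msd[sel, ])
  sl <- summary(fit)$coefficients["lag", ]
  bmean <- if (!is.null(beta)) {
    mean(beta$beta[beta$lag >= window[1] & beta$lag <= window[2]], na.rm = TRUE)
  } else NA_real_
  structure(list(D = unname(sl["Estimate"]) / 6,
                 D_A2_ns = unname(sl["Estimate"]) / 6 * 1000,
                 se = unname(sl["Std. Error"]) / 6,
                 window = window, beta_mean = bmean, fit = fit,
                 species = attr(msd, "species")),
            class = "mix_diffusion")
}

#' @export
print.mix_diffusion <- function(x, ...) {
  cat(sprintf(
    "<diffusion> D = %.4g A^2/ps (%.4g A^2/ns) +/- %.2g, window [%g, %g] ps\n",
    x$D, x$D_A2_ns, x$se, x$window[1], x$window[2]))
  invisible(x)
}

#' @export
glance.mix_diffusion <- function(x, ...) {
  tibble(D_A2_ps = x$D, D_A2_ns = x$D_A2_ns, se_A2_ps = x$se,
         t_lo = x$window[1], t_hi = x$window[2], beta_mean = x$beta_mean)
}

#' Per-molecule bond unit vectors from a trajectory
#'
#' The normalized minimum-image vector from atom `bond[1]` to atom
#' `bond[2]` within each molecule of the species, per frame -- the input
#' to vector-reorientation analysis (e.g. the hydroxyl O-H bond).
#'
#' @param traj A `mix_traj`.
#' @param species Species name.
#' @param bond Character vector of two atom labels `(from, to)`.
#' @return A `mix_vectors` object.
#' @export
vectors_from_bond <- function(traj, species, bond) {
  stopifnot(inherits(traj, "mix_traj"), length(bond) == 2L)
  top <- traj$topology
  atoms <- top$atoms[top$atoms$species == species, ]
  if (!nrow(atoms)) abort(sprintf("no species '%s'", species))
  mols <- unique(atoms$molecule)
  ia <- vapply(mols, function(m) {
    sub <- atoms[atoms$molecule == m, ]
    i <- sub$index[match(bond[1], sub$label)]
    if (is.na(i)) abort(sprintf("label '%s' missing in species '%s'", bond[1], species))
    i
  }, integer(1))
  ib <- vapply(mols, function(m) {
    sub <- atoms[atoms$molecule == m, ]
    i <- sub$index[match(bond[2], sub$label)]
    if (is.na(i)) abort(sprintf("label '%s' missing in species '%s'", bond[2], species))
    i
  }, integer(1))
  nf <- n_frames(traj)
  out <- array(NA_real_, dim = c(length(mols), 3, nf))
  for (f in seq_len(nf)) {
    v <- minimum_image(traj$coords[ib, , f, drop = FALSE][, , 1] -
                         traj$coords[ia, , f, drop = FALSE][, , 1], traj$box[f, ])
    if (is.null(dim(v))) v <- matrix(v, ncol = 3)
    nrm <- sqrt(rowSums(v^2))
    if (any(nrm == 0)) abort(sprintf("zero-length %s-%s bond at frame %d",
                                     bond[1], bond[2], f))
    out[, , f] <- v / nrm
  }
  structure(list(vectors = out, times = traj$times, dt = traj$dt,
                 definition = paste(species, paste(bond, collapse = "-")),
                 metadata = list()),
            class = "mix_vectors")
}

#' Vector reorientation dynamics (first-rank orientational correlation)
#'
#' `C(tau) = < u_i(t) . u_i(t + tau) >` over molecules and all time
#' origins, normalized so `C(0) = 1`. For a vector undergoing isotropic
#' rotational diffusion with coefficient `D_r`, `C(tau) = exp(-2 D_r tau)`.
#' Vectors deviating from unit norm by more than 1e-6 are renormalized
#' with a warning; zero-length vectors exclude their molecule (logged in
#' the `n_excluded` attribute).
#'
#' @param vectors A `mix_vectors` (from [gen_rotor()] or
#'   [vectors_from_bond()]).
#' @param max_lag_fraction Largest lag as a fraction of the series length.
#' @return Tibble subclass `mix_vrd` with columns `lag` (ps), `C`.
#' @export
compute_vrd <- function(vectors, max_lag_fraction = 0.5) {
  stopifnot(inherits(vectors, "mix_vectors"))
  u <- vectors$vectors
  nrm <- sqrt(u[, 1, , drop = FALSE]^2 + u[, 2, , drop = FALSE]^2 +
                u[, 3, , drop = FALSE]^2)[, 1, ]
  if (is.null(dim(nrm))) nrm <- matrix(nrm, nrow = dim(u)[1])
  zero <- apply(nrm == 0, 1, any)
  n_excluded <- sum(zero)
  if (n_excluded) {
    u <- u[!zero, , , drop = FALSE]
    nrm <- nrm[!zero, , drop = FALSE]
  }
  if (max(abs(nrm - 1)) > 1e-6) {
    warn("vectors deviate from unit norm by more than 1e-6; renormalizing")
  }
  for (f in seq_len(dim(u)[3])) u[, , f] <- u[, , f] / nrm[, f]
  nf <- dim(u)[3]
  max_lag <- max(1L, floor(max_lag_fraction * (nf - 1L)))
  C <- numeric(max_lag + 1L)
  C[1] <- 1
  for (L in seq_len(max_lag)) {
    s <- u[, 1, (1 + L):nf] * u[, 1, 1:(nf - L)] +
      u[, 2, (1 + L):nf] * u[, 2, 1:(nf - L)] +
      u[, 3, (1 + L):nf] * u[, 3, 1:(nf - L)]
    C[L + 1L] <- mean(s)
  }
  out <- tibble(lag = (0:max_lag) * vectors$dt, C = C)
  structure(out, definition = vectors$definition, n_excluded = n_excluded,
            n_vectors = dim(u)[1],
            class = c("mix_vrd", class(out)))
}

#' Exponential decay rate of a reorientation correlation
#'
#' Fits `C(tau) = exp(-k tau)` by nonlinear least squares (initialized
#' from a log-linear fit over `C >= c_min`). For rotational diffusion the
#' rate `k` estimates `2 D_r`.
#'
#' @param vrd A `mix_vrd`.
#' @param c_min Correlation floor defining the fit range (default 0.1;
#'   below it the tail is noise-dominated).
#' @return List with `rate` (1/ps), `tau_r = 1/rate` (ps) and the lag
#'   range used.
#' @export
fit_vrd_decay <- function(vrd, c_min = 0.1) {
  stopifnot(inherits(vrd, "mix_vrd"))
  keep <- vrd$lag > 0 & vrd$C >= c_min
  if (sum(keep) < 3L) abort("too few points above c_min to fit a decay")
  t <- vrd$lag[keep]; C <- vrd$C[keep]
  k0 <- -sum(t * log(C)) / sum(t^2)
  fit <- minpack.lm::nlsLM(C ~ exp(-k * t), data = tibble(t = t, C = C),
                           start = list(k = k0))
  k <- unname(coef(fit)["k"])
  list(rate = k, tau_r = 1 / k, lag_range = range(t))
}

#' @export
tidy.mix_msd <- function(x, ...) as_tibble(unclass_profile(x))
#' @export
tidy.mix_beta <- function(x, ...) as_tibble(unclass_profile(x))
#' @export
tidy.mix_vrd <- function(x, ...) as_tibble(unclass_profile(x))

#' @export
autoplot.mix_msd <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(tidy(object), .data$lag > 0),
                  ggplot2::aes(x = .data$lag, y = .data$msd)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag (ps)", y = expression(MSD ~ (ring(A)^2)))
}

#' @export
autoplot.mix_beta <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$lag, y = .data$beta)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "lag (ps)", y = expression(beta))
}

#' @export
autoplot.mix_vrd <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$lag, y = .data$C)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(tau ~ (ps)), y = expression(C(tau)),
                  title = attr(object, "definition"))
}
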