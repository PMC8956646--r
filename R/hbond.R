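#' Geometric hydrogen-bond criteria
#'
#' A hydrogen bond is declared when the H...acceptor minimum-image distance
#' is at most `r_max` AND the bonding angle is at least `angle_min`
#' (two separate criteria, one distance and one angle, read off combined
#' distribution plots). Both boundaries are closed: a geometry exactly at a
#' threshold counts. Two angle conventions are supported: the
#' donor-H...acceptor angle at the hydrogen (`"dha"`, 180 = linear) and the
#' H...acceptor-X angle at the acceptor (`"hax"`, X = the acceptor's
#' bonded heavy atom).
#'
#' Named presets carry per-pair criteria typical of menthol/fatty-acid
#' site pairs; presets are data, not code:
#' `"men_fa"` (2.0 A, 150 deg), `"fa_fa"` (2.0 A, 135 deg),
#' `"men_men"` (2.25 A, 150 deg).
#'
#' @param r_max Maximum H...acceptor distance (A), > 0.
#' @param angle_min Minimum angle (degrees) in `[0, 180]`.
#' @param convention `"dha"` or `"hax"`.
#' @param preset Optional preset name overriding `r_max`/`angle_min`.
#' @return Object of class `mix_hbond_criteria`.
#' @export
hbond_criteria <- function(r_max = 2.5, angle_min = 130,
                           convention = c("dha", "hax"), preset = NULL) {
  convention <- match.arg(convention)
  if (!is.null(preset)) {
    presets <- list(men_fa = c(2.0, 150), fa_fa = c(2.0, 135),
                    men_men = c(2.25, 150))
    if (!preset %in% names(presets)) {
      abort(sprintf("unknown preset '%s' (have: %s)", preset,
                    paste(names(presets), collapse = ", ")))
    }
    r_max <- presets[[preset]][1]
    angle_min <- presets[[preset]][2]
  }
  stopifnot(r_max > 0, angle_min >= 0, angle_min <= 180)
  structure(list(r_max = r_max, angle_min = angle_min,
                 convention = convention, preset = preset),
            class = "mix_hbond_criteria")
}

#' @export
print.mix_hbond_criteria <- function(x, ...) {
  cat(sprintf("<hbond criteria> r <= %.2f A, angle >= %.0f deg (%s)%s\n",
              x$r_max, x$angle_min, x$convention,
              if (!is.null(x$preset)) paste0(" [", x$preset, "]") else ""))
  invisible(x)
}

#' Detect hydrogen bonds frame by frame
#'
#' Applies the geometric criteria to every donor-H/acceptor combination
#' from the topology (donor and acceptor on different molecules unless
#' `include_intramolecular`), using minimum-image distances. Returns
#' exactly the triples satisfying both criteria.
#'
#' @param traj A `mix_traj` whose topology declares donors and acceptors.
#' @param criteria A [hbond_criteria()].
#' @param frames Frame indices to scan (default all).
#' @param include_intramolecular Allow donor and acceptor on the same
#'   molecule.
#' @return Tibble with one row per detected bond: `frame`, `donor`, `h`,
#'   `acceptor` (global atom indices), `donor_molecule`,
#'   `acceptor_molecule`, `r` (A), `angle` (degrees).
#' @export
detect_hbonds <- function(traj, criteria = hbond_criteria(), frames = NULL,
                          include_intramolecular = FALSE) {
  stopifnot(inherits(traj, "mix_traj"), inherits(criteria, "mix_hbond_criteria"))
  top <- traj$topology
  don <- top$donors
  acc <- top$acceptors
  if (!nrow(don)) abort("topology declares no donor sites")
  if (!length(acc)) abort("topology declares no acceptor sites")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  mol <- top$atoms$molecule
  if (criteria$convention == "hax") {
    x_of_a <- vapply(acc, function(a) {
      nb <- bonded_neighbors(top, a)
      if (!length(nb)) abort(sprintf(
        "acceptor atom %d has no bonded heavy atom (needed for the hax angle)", a))
      nb[1]
    }, integer(1))
  }
  rows <- list()
  for (f in frames) {
    x <- frame_coords(traj, f)
    box <- traj$box[f, ]
    for (k in seq_len(nrow(don))) {
      h <- don$hydrogen[k]; dheavy <- don$heavy[k]
      d <- minimum_image(x[acc, , drop = FALSE] -
                           matrix(x[h, ], length(acc), 3, byrow = TRUE), box)
      r <- row_norm3(d)
      ok <- which(r <= criteria$r_max & acc != h & acc != dheavy &
                    (include_intramolecular | mol[acc] != mol[h]))
      if (!length(ok)) next
      if (criteria$convention == "dha") {
        vd <- minimum_image(matrix(x[dheavy, ] - x[h, ], length(ok), 3,
                                   byrow = TRUE), box)
        th <- angle_deg(vd, d[ok, , drop = FALSE])
      } else {
        a_idx <- acc[ok]
        va_h <- -d[ok, , drop = FALSE]
        va_x <- minimum_image(x[x_of_a[ok], , drop = FALSE] -
                                x[a_idx, , drop = FALSE], box)
        th <- angle_deg(va_h, va_x)
      }
      pass <- th >= criteria$angle_min
      if (!any(pass)) next
      sel <- ok[pass]
      rows[[length(rows) + 1L]] <- tibble(
        frame = f, donor = dheavy, h = h, acceptor = acc[sel],
        donor_molecule = mol[h], acceptor_molecule = mol[acc[sel]],
        r = r[sel], angle = th[pass])
    }
  }
  if (!length(rows)) {
    return(tibble(frame = integer(0), donor = integer(0), h = integer(0),
                  acceptor = integer(0), donor_molecule = integer(0),
                  acceptor_molecule = integer(0), r = numeric(0),
                  angle = numeric(0)))
  }
  bind_rows(rows)
}

#' Hydrogen-bond count time series
#'
#' Runs [detect_hbonds()] on every frame and aggregates the total bond
#' count per frame; the full per-bond detections are retained for
#' occupancy analysis.
#'
#' @inheritParams detect_hbonds
#' @return Tibble subclass `mix_hbond_series` with columns `frame`, `time`
#'   (ps), `n_bonds`; the detections tibble is in attribute `detections`,
#'   the criteria in `criteria`.
#' @export
count_series <- function(traj, criteria = hbond_criteria(), frames = NULL,
                         include_intramolecular = FALSE) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  det <- detect_hbonds(traj, criteria, frames, include_intramolecular)
  counts <- vapply(frames, function(f) sum(det$frame == f), numeric(1))
  out <- tibble(frame = frames, time = traj$times[frames], n_bonds = counts)
  structure(out, detections = det, criteria = criteria,
            n_frames = length(frames),
            class = c("mix_hbond_series", class(out)))
}

#' Gaussian fit of the hydrogen-bond count distribution
#'
#' Least-squares fit of
#' `F(X) = a / (sigma sqrt(2 pi)) * exp(-(X - Xbar)^2 / (2 sigma^2))`
#' to the normalized histogram of per-frame bond counts, initialized at the
#' sample mean and standard deviation. The fitted `Xbar` is reported as the
#' average hydrogen-bond number; the amplitude `a` is reported but unused
#' downstream.
#'
#' @param x A `mix_hbond_series`, or a numeric vector of per-frame counts.
#' @param ... Unused.
#' @return Object of class `mix_gaussfit` with elements `amplitude`,
#'   `mean`, `sd`, `residual` (sum of squared histogram residuals) and
#'   `histogram`.
#' @export
fit_gaussian <- function(x, ...) UseMethod("fit_gaussian")

#' @export
fit_gaussian.mix_hbond_series <- function(x, ...) fit_gaussian(x$n_bonds, ...)

#' @export
fit_gaussian.numeric <- function(x, ...) {
  if (length(x) < 3L || var(x) == 0) {
    abort(sprintf(
      "degenerate count distribution (variance 0); report the constant %g instead",
      x[1]))
  }
  lev <- seq(floor(min(x)), ceiling(max(x)))
  freq <- vapply(lev, function(v) sum(round(x) == v), numeric(1))
  dens <- freq / length(x)   # unit bin width: histogram mass per count
  fit_gaussian(tibble(X = lev, density = dens),
               start = list(a = 1, m = mean(x), s = sd(x)))
}

#' @rdname fit_gaussian
#' @param start Optional start values `list(a, m, s)` (data-frame method);
#'   defaults to moments of the histogram.
#' @export
fit_gaussian.data.frame <- function(x, start = NULL, ...) {
  stopifnot(all(c("X", "density") %in% names(x)))
  if (is.null(start)) {
    m0 <- sum(x$X * x$density) / sum(x$density)
    s0 <- sqrt(sum((x$X - m0)^2 * x$density) / sum(x$density))
    start <- list(a = sum(x$density), m = m0, s = s0)
  }
  fit <- minpack.lm::nlsLM(
    density ~ a / (s * sqrt(2 * pi)) * exp(-(X - m)^2 / (2 * s^2)),
    data = x, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  structure(list(amplitude = unname(cf["a"]), mean = unname(cf["m"]),
                 sd = abs(unname(cf["s"])),
                 residual = sum(stats::resid(fit)^2),
                 histogram = as_tibble(x[, c("X", "density")])),
            class = "mix_gaussfit")
}

#' @export
print.mix_gaussfit <- function(x, ...) {
  cat(sprintf("<gaussian fit> mean = %.3f, sd = %.3f, amplitude = %.3f\n",
              x$mean, x$sd, x$amplitude))
  invisible(x)
}

#' @export
glance.mix_gaussfit <- function(x, ...) {
  tibble(mean = x$mean, sd = x$sd, amplitude = x$amplitude,
         residual = x$residual)
}

#' Percent occupancy of donor-acceptor pairs
#'
#' For each (donor site, acceptor site) pair of molecules that bonds in at
#' least one frame, the occupancy is `100 * frames_bonded / n_frames`: the
#' fraction of trajectory time the pair satisfies the criteria. The
#' class-level summary is the mean over ever-bonded pairs (pairs never
#' observed bonded are excluded; this aggregation is recorded in the
#' output).
#'
#' @param series A `mix_hbond_series` from [count_series()].
#' @return Tibble with one row per ever-bonded pair: `donor`, `h`,
#'   `acceptor`, `donor_molecule`, `acceptor_molecule`, `frames_bonded`,
#'   `occupancy` (percent); the class mean is attribute `class_mean` and
#'   in `summary`.
#' @export
percent_occupancy <- function(series) {
  stopifnot(inherits(series, "mix_hbond_series"))
  det <- attr(series, "detections")
  nf <- attr(series, "n_frames")
  if (!nrow(det)) {
    out <- tibble(donor = integer(0), h = integer(0), acceptor = integer(0),
                  donor_molecule = integer(0), acceptor_molecule = integer(0),
                  frames_bonded = integer(0), occupancy = numeric(0))
    return(structure(out, class_mean = NA_real_,
                     aggregation = "mean over ever-bonded pairs",
                     class = c("mix_occupancy", class(out))))
  }
  out <- det %>%
    dplyr::distinct(.data$frame, .data$donor, .data$h, .data$acceptor,
                    .data$donor_molecule, .data$acceptor_molecule) %>%
    group_by(.data$donor, .data$h, .data$acceptor,
             .data$donor_molecule, .data$acceptor_molecule) %>%
    summarise(frames_bonded = n(), .groups = "drop") %>%
    mutate(occupancy = 100 * .data$frames_bonded / nf) %>%
    arrange(dplyr::desc(.data$occupancy))
  structure(out, class_mean = mean(out$occupancy),
            aggregation = "mean over ever-bonded pairs",
            class = c("mix_occupancy", class(out)))
}

#' @export
tidy.mix_hbond_series <- function(x, ...) as_tibble(unclass_profile(x))

#' @export
glance.mix_hbond_series <- function(x, ...) {
  tibble(n_frames = attr(x, "n_frames"), mean_bonds = mean(x$n_bonds),
         sd_bonds = sd(x$n_bonds), max_bonds = max(x$n_bonds))
}

#' @export
autoplot.mix_hbond_series <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$time, y = .data$n_bonds)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)", y = "hydrogen bonds per frame")
}

#' @export
autoplot.mix_gaussfit <- function(object, ...) {
  h <- object$histogram
  h$fit <- object$amplitude / (object$sd * sqrt(2 * pi)) *
    exp(-(h$X - object$mean)^2 / (2 * object$sd^2))
  ggplot2::ggplot(h, ggplot2::aes(x = .data$X)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$density), fill = "grey75") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), colour = "firebrick") +
    ggplot2::labs(x = "hydrogen bonds per frame", y = "probability mass")
}
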