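#' Site-site radial distribution function g(r)
#'
#' Histogram of reference-partner minimum-image distances, normalized by
#' the uncorrelated-fluid expectation so that an ideal gas gives
#' `g(r) = 1`: counts are divided by `n_frames * n_ref * rho * V_shell(k)`
#' where `rho` is the partner number density available to each reference
#' atom and the shell volumes are the exact spherical shells
#' `(4/3) pi (r_{k+1}^3 - r_k^3)` (not `4 pi r^2 dr`), which removes the
#' small-r discretization bias.
#'
#' Intramolecular pairs are excluded by default: the analyses this package
#' targets are intermolecular site-site correlations. Self pairs are always
#' excluded.
#'
#' @param traj A `mix_traj` (coordinates treated as wrapped).
#' @param ref,partner Selections (expression string, `mix_selection`, or
#'   index vector).
#' @param bin_width Bin width (A). Default 0.05 A resolves the 2 A peak vs
#'   3 A shoulder structure typical of hydrogen-bonded liquids.
#' @param r_max Histogram range (A); must not exceed half the smallest box
#'   length (minimum image validity). Default `min(box)/2`.
#' @param exclude_intramolecular Exclude pairs within one molecule.
#' @param frames Optional frame subset.
#' @return Tibble subclass `mix_rdf` with columns `r` (bin centers), `g`,
#'   `count`, and attributes `bin_edges`, `rho`, `n_ref`, `n_partner`,
#'   `n_frames`.
#' @export
compute_rdf <- function(traj, ref, partner, bin_width = 0.05, r_max = NULL,
                        exclude_intramolecular = TRUE, frames = NULL) {
  stopifnot(inherits(traj, "mix_traj"))
  top <- traj$topology
  ref <- as_selection(top, ref)
  partner <- as_selection(top, partner)
  if (!length(ref) || !length(partner)) abort("empty selection")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  min_half <- min(traj$box[frames, ]) / 2
  if (is.null(r_max)) r_max <- min_half
  if (r_max > min_half + 1e-9) {
    abort(sprintf("r_max = %g exceeds min(box)/2 = %g (minimum image invalid)",
                  r_max, min_half))
  }
  nbins <- ceiling(r_max / bin_width - 1e-9)
  mol <- top$atoms$molecule
  counts <- numeric(nbins)
  vols <- numeric(length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    counts <- counts + rdf_hist_cpp(frame_coords(traj, f), traj$box[f, ],
                                    ref - 1L, partner - 1L, mol,
                                    bin_width, nbins, exclude_intramolecular)
    vols[k] <- prod(traj$box[f, ])
  }
  # partner density available to a reference atom: excluded partners
  # (self and, optionally, same-molecule) do not contribute
  excl_per_ref <- vapply(ref, function(i) {
    if (exclude_intramolecular) sum(mol[partner] == mol[i]) else sum(partner == i)
  }, numeric(1))
  rho <- (length(partner) - mean(excl_per_ref)) / mean(vols)
  edges <- seq(0, by = bin_width, length.out = nbins + 1L)
  shell <- (4 / 3) * pi * diff(edges^3)
  g <- counts / (length(frames) * length(ref) * rho * shell)
  out <- tibble(r = (edges[-1] + edges[-length(edges)]) / 2, g = g,
                count = counts)
  structure(out,
            bin_edges = edges, rho = rho, n_ref = length(ref),
            n_partner = length(partner), n_frames = length(frames),
            ref_expr = attr(ref, "expr"), partner_expr = attr(partner, "expr"),
            exclude_intramolecular = exclude_intramolecular,
            class = c("mix_rdf", class(out)))
}

# centered moving average; shrinks the window symmetrically at the edges
smooth_ma <- function(x, window) {
  if (window <= 1L) return(x)
  half <- floor(window / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Locate the first minimum of a radial profile (solvation-shell boundary)
#'
#' Finds the first local minimum after the first local maximum with
#' `g > min_peak`, on a moving-average-smoothed copy of the profile (raw
#' histograms are noisy at modest sampling). Ties are broken toward
#' smaller r. The peak threshold (default 1.05) keeps statistical ripples
#' of a structureless fluid from being mistaken for a solvation shell.
#'
#' @param profile A `mix_rdf` (or any tibble with `r` and `g` columns).
#' @param smooth_window Moving-average window in bins (default 5).
#' @param min_peak Minimum height for a maximum to count as a shell peak.
#' @return The bin-center radius of the first minimum (A).
#' @export
find_first_minimum <- function(profile, smooth_window = 5, min_peak = 1.05) {
  r <- profile$r
  g <- smooth_ma(profile$g, smooth_window)
  n <- length(g)
  if (n < 3L) abort("no solvation shell: profile too short")
  peak <- NA_integer_
  for (i in 2:(n - 1)) {
    if (g[i] > min_peak && g[i] > g[i - 1] && g[i] >= g[i + 1]) { peak <- i; break }
  }
  if (is.na(peak)) abort("no solvation shell: no maximum with g > 1")
  if (peak + 1L >= n) abort("no solvation shell: maximum at profile edge")
  for (j in (peak + 1L):(n - 1L)) {
    if (g[j] <= g[j - 1] && g[j] < g[j + 1]) return(r[j])
  }
  abort("no solvation shell: no minimum after the first maximum")
}

#' Coordination number from a radial profile
#'
#' Mean number of partner atoms within `r_shell` of a reference atom,
#' `N = 4 pi rho integral_0^r_shell r^2 g(r) dr`, evaluated by the
#' trapezoid rule on bin centers (with the endpoint value interpolated).
#' `r_shell` is conventionally the first RDF minimum
#' ([find_first_minimum()]).
#'
#' @param profile A `mix_rdf`.
#' @param r_shell Shell radius (A), within the profile range.
#' @param rho Partner density override (A^-3); defaults to the profile's.
#' @return Coordination number (dimensionless count).
#' @export
coordination_number <- function(profile, r_shell, rho = NULL) {
  if (is.null(rho)) rho <- attr(profile, "rho")
  r <- profile$r
  g <- profile$g
  if (r_shell > max(attr(profile, "bin_edges"))) {
    abort("r_shell beyond the profile range")
  }
  keep <- r <= r_shell
  rr <- r[keep]; gg <- g[keep]
  if (!length(rr) || max(rr) < r_shell) {
    g_end <- approx(r, g, xout = r_shell, rule = 2)$y
    rr <- c(rr, r_shell); gg <- c(gg, g_end)
  }
  # integrand -> 0 at r = 0
  rr <- c(0, rr); gg <- c(gg[1], gg)
  4 * pi * rho * pracma::trapz(rr, rr^2 * gg)
}

#' @export
tidy.mix_rdf <- function(x, ...) as_tibble(unclass_profile(x))

unclass_profile <- function(x) {
  class(x) <- setdiff(class(x), c("mix_rdf", "mix_adf", "mix_msd", "mix_beta",
                                  "mix_vrd", "mix_hbond_series", "mix_energy"))
  x
}

#' @export
autoplot.mix_rdf <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (Å)", y = "g(r)",
                  title = sprintf("RDF: %s around %s",
                                  attr(object, "partner_expr"),
                                  attr(object, "ref_expr")))
}
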