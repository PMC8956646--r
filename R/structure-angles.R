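# Euclidean norms per row with plain double accumulation (x^2 + y^2 + z^2
# left to right). rowSums would accumulate in extended precision and can
# land 1 ulp away from the C++ histogram kernels at exact bin edges.
row_norm3 <- function(m) sqrt(m[, 1]^2 + m[, 2]^2 + m[, 3]^2)

angle_deg <- function(v1, v2) {
  # angle between row vectors of two n x 3 matrices, in degrees
  n1 <- sqrt(rowSums(v1^2)); n2 <- sqrt(rowSums(v2^2))
  cosv <- rowSums(v1 * v2) / (n1 * n2)
  acos(pmin(1, pmax(-1, cosv))) * 180 / pi
}

bonded_neighbors <- function(topology, i) {
  b <- topology$bonds
  c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])
}

#' Angular distribution function over gated triples
#'
#' Histogram of the angle at the middle atom of (a, vertex, c) triples,
#' where `a` and `c` are partner atoms within `r_gate` of the vertex
#' (minimum image). If the two flank selections are identical each
#' unordered pair is counted once. Frequencies are normalized to unit mass.
#' Triples with a zero-length arm are skipped and counted in the
#' `n_skipped` attribute.
#'
#' @param traj A `mix_traj`.
#' @param sel_a,sel_vertex,sel_c Selections for the two flanks and the
#'   vertex.
#' @param bin_width Angular bin width in degrees (default 2).
#' @param r_gate Neighbor-shell gate distance (A).
#' @param exclude_intramolecular Require flank atoms on different molecules
#'   than the vertex.
#' @param frames Optional frame subset.
#' @return Tibble subclass `mix_adf` with columns `theta` (bin centers,
#'   degrees), `frequency`, `count`.
#' @export
compute_adf <- function(traj, sel_a, sel_vertex, sel_c, bin_width = 2,
                        r_gate, exclude_intramolecular = TRUE, frames = NULL) {
  stopifnot(inherits(traj, "mix_traj"))
  top <- traj$topology
  sel_a <- as_selection(top, sel_a)
  sel_vertex <- as_selection(top, sel_vertex)
  sel_c <- as_selection(top, sel_c)
  same_flanks <- identical(as.integer(sel_a), as.integer(sel_c))
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  nbins <- ceiling(180 / bin_width)
  edges <- seq(0, by = bin_width, length.out = nbins + 1L)
  counts <- numeric(nbins)
  n_skipped <- 0L
  mol <- top$atoms$molecule
  for (f in frames) {
    x <- frame_coords(traj, f)
    box <- traj$box[f, ]
    for (v in sel_vertex) {
      da <- minimum_image(x[sel_a, , drop = FALSE] -
                            matrix(x[v, ], length(sel_a), 3, byrow = TRUE), box)
      dc <- minimum_image(x[sel_c, , drop = FALSE] -
                            matrix(x[v, ], length(sel_c), 3, byrow = TRUE), box)
      ra <- row_norm3(da); rc <- row_norm3(dc)
      ok_a <- which(ra <= r_gate & sel_a != v &
                      (!exclude_intramolecular | mol[sel_a] != mol[v]))
      ok_c <- which(rc <= r_gate & sel_c != v &
                      (!exclude_intramolecular | mol[sel_c] != mol[v]))
      for (ia in ok_a) {
        for (ic in ok_c) {
          if (sel_a[ia] == sel_c[ic]) next
          if (same_flanks && sel_a[ia] > sel_c[ic]) next
          if (ra[ia] == 0 || rc[ic] == 0) { n_skipped <- n_skipped + 1L; next }
          th <- angle_deg(da[ia, , drop = FALSE], dc[ic, , drop = FALSE])
          bin <- min(nbins, floor(th / bin_width) + 1L)
          counts[bin] <- counts[bin] + 1
        }
      }
    }
  }
  total <- sum(counts)
  out <- tibble(theta = (edges[-1] + edges[-length(edges)]) / 2,
                frequency = if (total > 0) counts / total else counts,
                count = counts)
  structure(out, bin_edges = edges, n_skipped = n_skipped, n_obs = total,
            class = c("mix_adf", class(out)))
}

#' @export
tidy.mix_adf <- function(x, ...) as_tibble(unclass_profile(x))

#' @export
autoplot.mix_adf <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$theta, y = .data$frequency)) +
    ggplot2::geom_col(width = diff(attr(object, "bin_edges"))[1]) +
    ggplot2::labs(x = "angle (degrees)", y = "frequency")
}

new_cdf <- function(counts, x_edges, y_edges, axes, extra = list()) {
  xc <- (x_edges[-1] + x_edges[-length(x_edges)]) / 2
  yc <- (y_edges[-1] + y_edges[-length(y_edges)]) / 2
  out <- as_tibble(expand.grid(x = xc, y = yc))
  out$count <- as.vector(counts)
  structure(out, counts = counts, x_edges = x_edges, y_edges = y_edges,
            axes = axes, extra = extra,
            class = c("mix_cdf", class(out)))
}

cdf_pair_observations <- function(traj, h_sel, acceptor_sel,
                                  angle_convention, r_max,
                                  exclude_intramolecular, frames) {
  top <- traj$topology
  mol <- top$atoms$molecule
  obs_r <- list(); obs_a <- list()
  # resolve the third atom per H (covalent heavy partner) or per acceptor
  heavy_of_h <- vapply(as.integer(h_sel), function(h) {
    nb <- bonded_neighbors(top, h)
    if (!length(nb)) abort(sprintf(
      "atom %d has no covalent partner; cannot define the donor-H...A angle", h))
    nb[1]
  }, integer(1))
  if (angle_convention == "hax") {
    x_of_a <- vapply(as.integer(acceptor_sel), function(a) {
      nb <- bonded_neighbors(top, a)
      if (!length(nb)) abort(sprintf(
        "acceptor atom %d has no bonded heavy atom; cannot define the H...A-X angle", a))
      nb[1]
    }, integer(1))
  }
  for (f in frames) {
    x <- frame_coords(traj, f)
    box <- traj$box[f, ]
    for (hi in seq_along(h_sel)) {
      h <- h_sel[hi]
      d <- minimum_image(x[acceptor_sel, , drop = FALSE] -
                           matrix(x[h, ], length(acceptor_sel), 3, byrow = TRUE), box)
      r <- row_norm3(d)
      ok <- which(r < r_max & acceptor_sel != h &
                    (!exclude_intramolecular | mol[acceptor_sel] != mol[h]))
      if (!length(ok)) next
      if (angle_convention == "dha") {
        vd <- minimum_image(matrix(x[heavy_of_h[hi], ] - x[h, ],
                                   length(ok), 3, byrow = TRUE), box)
        th <- angle_deg(vd, d[ok, , drop = FALSE])
      } else {
        a_idx <- acceptor_sel[ok]
        xx <- x[x_of_a[ok], , drop = FALSE]
        va_h <- minimum_image(matrix(x[h, ], length(ok), 3, byrow = TRUE) -
                                x[a_idx, , drop = FALSE], box)
        va_x <- minimum_image(xx - x[a_idx, , drop = FALSE], box)
        th <- angle_deg(va_h, va_x)
      }
      obs_r[[length(obs_r) + 1L]] <- r[ok]
      obs_a[[length(obs_a) + 1L]] <- th
    }
  }
  tibble(r = unlist(obs_r) %||% numeric(0),
         angle = unlist(obs_a) %||% numeric(0))
}

#' Combined radial/angular distribution function
#'
#' Two-dimensional histogram over the H...acceptor distance and a bonding
#' angle, the standard plot from which geometric hydrogen-bond criteria are
#' read off. The angle is defined through the topology: either the
#' donor-H...acceptor angle at the hydrogen (`"dha"`, using H's covalent
#' heavy-atom partner) or the H...acceptor-X angle at the acceptor
#' (`"hax"`, using the acceptor's bonded heavy atom). The raw-count
#' marginals of the result equal the 1D distance and angle histograms of
#' the same gated pair set exactly.
#'
#' @param traj A `mix_traj`.
#' @param h_sel Selection of (donor) hydrogen atoms.
#' @param acceptor_sel Selection of acceptor atoms.
#' @param angle_convention `"dha"` or `"hax"`; recorded in the result.
#' @param r_bin_width,r_max Distance binning (A).
#' @param angle_bin_width Angle binning (degrees).
#' @param exclude_intramolecular Only count pairs on different molecules.
#' @param frames Optional frame subset.
#' @return Tibble subclass `mix_cdf` (columns `x` = distance, `y` = angle,
#'   `count`) with attributes `counts` (matrix), `x_edges`, `y_edges`.
#' @export
compute_cdf_rad_ang <- function(traj, h_sel, acceptor_sel,
                                angle_convention = c("dha", "hax"),
                                r_bin_width = 0.05, r_max = NULL,
                                angle_bin_width = 2,
                                exclude_intramolecular = TRUE, frames = NULL) {
  stopifnot(inherits(traj, "mix_traj"))
  angle_convention <- match.arg(angle_convention)
  top <- traj$topology
  h_sel <- as_selection(top, h_sel)
  acceptor_sel <- as_selection(top, acceptor_sel)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  if (is.null(r_max)) r_max <- min(traj$box[frames, ]) / 2
  obs <- cdf_pair_observations(traj, h_sel, acceptor_sel, angle_convention,
                               r_max, exclude_intramolecular, frames)
  nbr <- ceiling(r_max / r_bin_width - 1e-9)
  nba <- ceiling(180 / angle_bin_width)
  x_edges <- seq(0, by = r_bin_width, length.out = nbr + 1L)
  y_edges <- seq(0, by = angle_bin_width, length.out = nba + 1L)
  counts <- matrix(0, nbr, nba)
  if (nrow(obs)) {
    bi <- pmin(nbr, floor(obs$r / r_bin_width) + 1L)
    bj <- pmin(nba, floor(obs$angle / angle_bin_width) + 1L)
    for (k in seq_along(bi)) counts[bi[k], bj[k]] <- counts[bi[k], bj[k]] + 1
  }
  new_cdf(counts, x_edges, y_edges, axes = c("distance", "angle"),
          extra = list(angle_convention = angle_convention,
                       n_frames = length(frames)))
}

#' Fraction of combined-distribution counts inside a criteria region
#'
#' Shares of observations with distance at most `r_max` and angle at least
#' `angle_min` -- the geometric hydrogen-bond region of a radial/angular
#' combined distribution.
#'
#' @param cdf A distance-angle `mix_cdf`.
#' @param r_max,angle_min Criteria bounds; must fall on bin edges for an
#'   exact region.
#' @return Fraction in `[0, 1]`.
#' @export
cdf_region_fraction <- function(cdf, r_max, angle_min) {
  stopifnot(inherits(cdf, "mix_cdf"),
            identical(attr(cdf, "axes"), c("distance", "angle")))
  counts <- attr(cdf, "counts")
  xe <- attr(cdf, "x_edges"); ye <- attr(cdf, "y_edges")
  xi <- which(xe[-1] <= r_max + 1e-9)
  yi <- which(ye[-length(ye)] >= angle_min - 1e-9)
  total <- sum(counts)
  if (total == 0) return(0)
  sum(counts[xi, yi, drop = FALSE]) / total
}

#' Combined radial/radial distribution for bridge motifs
#'
#' Quantifies three-molecule bridge motifs (e.g. menthol...fatty
#' acid...menthol): for each bridge atom, the first axis is the minimum-image
#' distance to its nearest qualifying partner from `partner1` on another
#' molecule, and the second axis the distance to the nearest `partner2`
#' atom on a molecule different from both. A bridge atom with no qualifying
#' partner on either axis contributes nothing (counted in `n_unpaired`).
#'
#' @param traj A `mix_traj`.
#' @param bridge Selection of bridge-site atoms (one entry per bridge
#'   molecule is typical).
#' @param partner1,partner2 Selections for the two contact axes.
#' @param bin_width Distance bin width (A).
#' @param r_max Histogram range (A); default `min(box)/2`.
#' @param frames Optional frame subset.
#' @return Tibble subclass `mix_cdf` with axes `("distance", "distance")`.
#' @export
compute_cdf_rad_rad <- function(traj, bridge, partner1, partner2,
                                bin_width = 0.05, r_max = NULL,
                                frames = NULL) {
  stopifnot(inherits(traj, "mix_traj"))
  top <- traj$topology
  bridge <- as_selection(top, bridge)
  partner1 <- as_selection(top, partner1)
  partner2 <- as_selection(top, partner2)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  if (is.null(r_max)) r_max <- min(traj$box[frames, ]) / 2
  mol <- top$atoms$molecule
  nb <- ceiling(r_max / bin_width - 1e-9)
  edges <- seq(0, by = bin_width, length.out = nb + 1L)
  counts <- matrix(0, nb, nb)
  n_unpaired <- 0L
  for (f in frames) {
    x <- frame_coords(traj, f)
    box <- traj$box[f, ]
    for (b in bridge) {
      d1 <- minimum_image(x[partner1, , drop = FALSE] -
                            matrix(x[b, ], length(partner1), 3, byrow = TRUE), box)
      r1 <- row_norm3(d1)
      ok1 <- which(mol[partner1] != mol[b] & r1 < r_max)
      if (!length(ok1)) { n_unpaired <- n_unpaired + 1L; next }
      i1 <- ok1[which.min(r1[ok1])]
      d2 <- minimum_image(x[partner2, , drop = FALSE] -
                            matrix(x[b, ], length(partner2), 3, byrow = TRUE), box)
      r2 <- row_norm3(d2)
      ok2 <- which(mol[partner2] != mol[b] &
                     mol[partner2] != mol[partner1[i1]] & r2 < r_max)
      if (!length(ok2)) { n_unpaired <- n_unpaired + 1L; next }
      i2 <- ok2[which.min(r2[ok2])]
      bi <- floor(r1[i1] / bin_width) + 1L
      bj <- floor(r2[i2] / bin_width) + 1L
      counts[bi, bj] <- counts[bi, bj] + 1
    }
  }
  new_cdf(counts, edges, edges, axes = c("distance", "distance"),
          extra = list(n_unpaired = n_unpaired, n_frames = length(frames)))
}

#' @export
tidy.mix_cdf <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "mix_cdf")
  out
}

#' @export
autoplot.mix_cdf <- function(object, ...) {
  axes <- attr(object, "axes")
  labs <- ifelse(axes == "distance", "distance (Å)", "angle (degrees)")
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$x, y = .data$y, fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = labs[1], y = labs[2], fill = "counts")
}
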