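#' Spatial distribution function in a reference molecule's local frame
#'
#' For every reference molecule and frame, partner atoms are mapped into a
#' body-fixed frame defined by three anchor atoms -- origin at anchor 1,
#' x-axis toward anchor 2, xy-plane containing anchor 3, right-handed --
#' and accumulated on a cubic voxel grid spanning `[-extent, extent]^3`.
#' Values are number densities (A^-3): raw counts divided by
#' `n_frames * n_ref * voxel^3`, so the grid mass
#' `sum(values) * voxel^3` equals the mean number of in-region partner
#' atoms per frame per reference molecule.
#'
#' @param traj A `mix_traj`.
#' @param ref_species Species name of the reference molecules.
#' @param anchors Character vector of three atom labels within the
#'   reference species; must be non-collinear in every frame (cross-product
#'   norm tolerance 1e-6).
#' @param partner Selection of partner atoms (atoms on the reference
#'   molecule itself are skipped).
#' @param voxel Voxel edge (A).
#' @param extent Half-width of the grid (A).
#' @param frames Optional frame subset.
#' @return Object of class `mix_sdf`: tibble of occupied voxels
#'   (`x`, `y`, `z` centers, `density`) with the full array in attribute
#'   `values`, plus `voxel`, `origin`, `edges`, `n_ref`, `n_frames` and an
#'   `isovalue` suggestion (half the grid maximum).
#' @export
compute_sdf <- function(traj, ref_species, anchors, partner, voxel = 0.5,
                        extent = 5, frames = NULL) {
  stopifnot(inherits(traj, "mix_traj"), length(anchors) == 3L)
  top <- traj$topology
  partner <- as_selection(top, partner)
  atoms <- top$atoms
  ref_atoms <- atoms[atoms$species == ref_species, ]
  if (!nrow(ref_atoms)) abort(sprintf("no species '%s' in topology", ref_species))
  mols <- unique(ref_atoms$molecule)
  anchor_idx <- lapply(mols, function(m) {
    sub <- ref_atoms[ref_atoms$molecule == m, ]
    idx <- sub$index[match(anchors, sub$label)]
    if (anyNA(idx)) abort(sprintf("anchor label(s) missing in species '%s'", ref_species))
    idx
  })
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  n_side <- 2L * ceiling(extent / voxel)
  half <- n_side / 2
  vals <- array(0, dim = c(n_side, n_side, n_side))
  mol <- atoms$molecule
  for (f in frames) {
    x <- frame_coords(traj, f)
    box <- traj$box[f, ]
    for (k in seq_along(mols)) {
      ai <- anchor_idx[[k]]
      o <- x[ai[1], ]
      v2 <- as.numeric(minimum_image(x[ai[2], ] - o, box))
      v3 <- as.numeric(minimum_image(x[ai[3], ] - o, box))
      ex <- v2 / sqrt(sum(v2^2))
      cz <- c(ex[2] * v3[3] - ex[3] * v3[2],
              ex[3] * v3[1] - ex[1] * v3[3],
              ex[1] * v3[2] - ex[2] * v3[1])
      ncz <- sqrt(sum(cz^2))
      if (!is.finite(ncz) || ncz < 1e-6) {
        abort(sprintf("collinear anchors in molecule %d at frame %d", mols[k], f))
      }
      ez <- cz / ncz
      ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
              ez[3] * ex[1] - ez[1] * ex[3],
              ez[1] * ex[2] - ez[2] * ex[1])
      keep <- partner[mol[partner] != mols[k]]
      if (!length(keep)) next
      d <- minimum_image(x[keep, , drop = FALSE] -
                           matrix(o, length(keep), 3, byrow = TRUE), box)
      loc <- cbind(d %*% ex, d %*% ey, d %*% ez)
      ii <- floor(loc / voxel) + half + 1L
      inside <- ii[, 1] >= 1 & ii[, 1] <= n_side &
        ii[, 2] >= 1 & ii[, 2] <= n_side &
        ii[, 3] >= 1 & ii[, 3] <= n_side
      ii <- ii[inside, , drop = FALSE]
      for (r in seq_len(nrow(ii))) {
        vals[ii[r, 1], ii[r, 2], ii[r, 3]] <- vals[ii[r, 1], ii[r, 2], ii[r, 3]] + 1
      }
    }
  }
  vals <- vals / (length(frames) * length(mols) * voxel^3)
  centers <- (seq_len(n_side) - half - 0.5) * voxel
  occ <- which(vals > 0, arr.ind = TRUE)
  out <- tibble(x = centers[occ[, 1]], y = centers[occ[, 2]],
                z = centers[occ[, 3]], density = vals[occ])
  structure(out, values = vals, voxel = voxel,
            origin = rep(-half * voxel + voxel / 2, 3), centers = centers,
            n_ref = length(mols), n_frames = length(frames),
            isovalue = max(vals) / 2, anchors = anchors,
            class = c("mix_sdf", class(out)))
}

#' @export
tidy.mix_sdf <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "mix_sdf")
  out
}

#' Radial particle-density curve and Dens value
#'
#' The particle-density curve is `rho(r) = g(r) * rho_partner`, the
#' absolute partner number density at distance r from the reference site;
#' the `Dens` value is this density at the curve's first minimum (the first
#' solvation-shell boundary), located with the same detector as
#' [find_first_minimum()].
#'
#' @param x A `mix_rdf` profile, or a `mix_traj` (with `ref`/`partner`
#'   selections passed on to [compute_rdf()]).
#' @param ... For the trajectory method, arguments to [compute_rdf()].
#' @param smooth_window Moving-average window for minimum detection.
#' @return Object of class `mix_dens`: list with `curve` (tibble `r`,
#'   `density`), `r_min` (A) and `dens` (A^-3).
#' @export
dens_profile <- function(x, ..., smooth_window = 5) {
  UseMethod("dens_profile")
}

#' @export
dens_profile.mix_rdf <- function(x, ..., smooth_window = 5) {
  rho <- attr(x, "rho")
  curve <- tibble(r = x$r, density = x$g * rho)
  r_min <- find_first_minimum(x, smooth_window = smooth_window)
  dens <- curve$density[match(r_min, curve$r)]
  structure(list(curve = curve, r_min = r_min, dens = dens,
                 rho_partner = rho),
            class = "mix_dens")
}

#' @export
dens_profile.mix_traj <- function(x, ref, partner, ..., smooth_window = 5) {
  prof <- compute_rdf(x, ref, partner, ...)
  dens_profile(prof, smooth_window = smooth_window)
}

#' @export
print.mix_dens <- function(x, ...) {
  cat(sprintf("<mix_dens> first minimum at r = %.3f A, Dens = %.4g A^-3\n",
              x$r_min, x$dens))
  invisible(x)
}

#' @export
glance.mix_dens <- function(x, ...) {
  tibble(r_min = x$r_min, dens = x$dens, rho_partner = x$rho_partner)
}

#' @export
autoplot.mix_sdf <- function(object, ...) {
  # z-integrated projection of the local-frame density
  vals <- attr(object, "values")
  centers <- attr(object, "centers")
  proj <- apply(vals, c(1, 2), sum) * attr(object, "voxel")
  df <- as_tibble(expand.grid(x = centers, y = centers))
  df$density <- as.vector(proj)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "local x (Å)", y = "local y (Å)",
                  fill = expression(rho ~ (ring(A)^-2)),
                  title = "SDF, z-projected local-frame density")
}
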