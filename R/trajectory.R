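#' Construct a trajectory object
#'
#' Frames of atomic coordinates (Angstrom) in an orthorhombic periodic box,
#' bound to a [system_topology()]. Times must be strictly increasing and
#' uniformly spaced (within 1e-9 relative); the atom count is constant
#' across frames.
#'
#' @param coords Numeric array `n_atoms x 3 x n_frames`.
#' @param box Length-3 vector (constant box) or `n_frames x 3` matrix, in
#'   Angstrom; all lengths > 0.
#' @param topology A `mix_topology` whose atom count matches `coords`.
#' @param times Frame times in ps; defaults to `0, dt, 2 dt, ...`.
#' @param dt Timestep in ps (used when `times` is `NULL`).
#' @param velocities Optional array `n_atoms x 3 x n_frames` in A/ps.
#' @param unwrapped Logical: are the coordinates continuous (not wrapped
#'   back into the box)? Dynamics analyses require unwrapped coordinates;
#'   structural analyses treat coordinates as wrapped.
#' @param metadata Free-form list (generators record seeds and ground truth
#'   here).
#' @return Object of class `mix_traj`.
#' @export
trajectory <- function(coords, box, topology, times = NULL, dt = 1,
                       velocities = NULL, unwrapped = FALSE,
                       metadata = list()) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  n_atoms <- dim(coords)[1]
  n_frames <- dim(coords)[3]
  if (!is.null(topology) && n_atoms != n_atoms_topology(topology)) {
    abort(sprintf("coords have %d atoms but topology implies %d",
                  n_atoms, n_atoms_topology(topology)))
  }
  if (any(!is.finite(coords))) abort("coordinates must be finite")
  if (is.null(dim(box))) {
    stopifnot(length(box) == 3L)
    box <- matrix(rep(as.numeric(box), each = n_frames), nrow = n_frames)
  }
  box <- as.matrix(box)
  stopifnot(nrow(box) == n_frames, ncol(box) == 3L)
  if (any(box <= 0)) abort("box lengths must be > 0")
  if (is.null(times)) times <- (seq_len(n_frames) - 1) * dt
  stopifnot(length(times) == n_frames)
  if (n_frames > 1L) {
    d <- diff(times)
    if (any(d <= 0)) abort("frame times must be strictly increasing")
    if ((max(d) - min(d)) > 1e-9 * max(abs(d))) {
      abort("frame times must be uniformly spaced (1e-9 relative)")
    }
    dt <- d[1]
  }
  if (!is.null(velocities)) {
    stopifnot(identical(dim(velocities), dim(coords)))
  }
  structure(
    list(coords = coords, box = box, times = as.numeric(times), dt = dt,
         topology = topology, velocities = velocities,
         unwrapped = isTRUE(unwrapped), metadata = metadata),
    class = "mix_traj"
  )
}

#' @export
print.mix_traj <- function(x, ...) {
  cat(sprintf(
    "<mix_traj> %d atoms x %d frames, dt = %g ps, box ~ (%.2f, %.2f, %.2f) A%s\n",
    n_atoms(x), n_frames(x), x$dt, x$box[1, 1], x$box[1, 2], x$box[1, 3],
    if (x$unwrapped) ", unwrapped" else ""))
  invisible(x)
}

#' Trajectory dimensions
#' @param traj A `mix_traj`.
#' @return Integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

frame_coords <- function(traj, i) {
  x <- traj$coords[, , i, drop = FALSE]
  dim(x) <- dim(x)[1:2]   # keep the n x 3 matrix even for a single atom
  x
}

#' Minimum-image convention displacement
#'
#' Maps each displacement component into `[-L/2, L/2)` for an orthorhombic
#' box, i.e. returns the displacement to the nearest periodic image. The
#' result is invariant under adding any integer multiple of the box length
#' to the input.
#'
#' @param delta Numeric 3-vector or `n x 3` matrix of displacements (A).
#' @param box Length-3 box vector (A), all entries > 0.
#' @return Same shape as `delta`.
#' @export
#' @examples
#' minimum_image(c(9, 0, 0), c(10, 10, 10))  # -> (-1, 0, 0)
minimum_image <- function(delta, box) {
  stopifnot(all(box > 0))
  if (is.matrix(delta)) {
    b <- matrix(box, nrow = nrow(delta), ncol = 3, byrow = TRUE)
  } else {
    stopifnot(length(delta) == 3L)
    b <- box
  }
  delta - b * floor(delta / b + 0.5)
}

#' Wrap coordinates into the primary box
#'
#' @param traj A `mix_traj`.
#' @return A `mix_traj` with all coordinates in `[0, L)` and
#'   `unwrapped = FALSE`.
#' @export
wrap <- function(traj) {
  stopifnot(inherits(traj, "mix_traj"))
  out <- traj
  for (f in seq_len(n_frames(traj))) {
    b <- matrix(traj$box[f, ], nrow = n_atoms(traj), ncol = 3, byrow = TRUE)
    x <- out$coords[, , f]
    out$coords[, , f] <- x - b * floor(x / b)
  }
  out$unwrapped <- FALSE
  out
}

#' Unwrap periodic-boundary jumps into continuous coordinates
#'
#' Accumulates minimum-image inter-frame displacements so that particle
#' paths are continuous across box boundaries; required before any
#' mean-square-displacement analysis. Assumes the sampling is fine enough
#' that no atom moves half a box length between frames; a displacement at
#' that limit triggers a warning naming the frame and atom.
#'
#' @param traj A `mix_traj` (wrapped coordinates).
#' @return A `mix_traj` with continuous coordinates and `unwrapped = TRUE`.
#'   Wrapping the result reproduces the wrapped input exactly.
#' @export
unwrap <- function(traj) {
  stopifnot(inherits(traj, "mix_traj"))
  out <- traj
  nf <- n_frames(traj)
  if (nf < 2L) {
    out$unwrapped <- TRUE
    return(out)
  }
  prev_w <- frame_coords(traj, 1)
  prev_u <- prev_w
  for (f in 2:nf) {
    box <- traj$box[f, ]
    cur <- frame_coords(traj, f)
    disp <- minimum_image(cur - prev_w, box)
    lim <- matrix(box / 2, nrow = nrow(disp), ncol = 3, byrow = TRUE)
    bad <- which(abs(disp) >= lim * (1 - 1e-9), arr.ind = TRUE)
    if (nrow(bad)) {
      warn(sprintf(
        "unwrap: displacement >= box/2 at frame %d, atom %d; sampling too coarse",
        f, bad[1, 1]))
    }
    prev_u <- prev_u + disp
    out$coords[, , f] <- prev_u
    prev_w <- cur
  }
  out$unwrapped <- TRUE
  out
}

#' Subset trajectory frames
#' @param traj A `mix_traj`.
#' @param frames Integer frame indices to keep (in order).
#' @return A `mix_traj`.
#' @export
subset_frames <- function(traj, frames) {
  stopifnot(inherits(traj, "mix_traj"))
  out <- traj
  out$coords <- traj$coords[, , frames, drop = FALSE]
  out$box <- traj$box[frames, , drop = FALSE]
  out$times <- traj$times[frames]
  if (!is.null(traj$velocities)) {
    out$velocities <- traj$velocities[, , frames, drop = FALSE]
  }
  out
}

#' Per-molecule center-of-mass coordinates
#'
#' Mass-weighted molecular centers of mass (hydrogens included), computed
#' on the coordinates as stored; unwrap first for dynamics.
#'
#' @param traj A `mix_traj` with a topology.
#' @param species Optional species name to restrict to.
#' @return Array `n_molecules x 3 x n_frames`, with molecule ids as
#'   `dimnames` on the first margin.
#' @export
com_coords <- function(traj, species = NULL) {
  top <- traj$topology
  if (is.null(top)) abort("trajectory has no topology")
  atoms <- top$atoms
  keep <- if (is.null(species)) rep(TRUE, nrow(atoms)) else atoms$species == species
  if (!any(keep)) abort(sprintf("no atoms for species '%s'", species))
  idx <- atoms$index[keep]
  mol <- atoms$molecule[keep]
  mass <- atoms$mass[keep]
  mols <- sort(unique(mol))
  grp <- match(mol, mols)
  msum <- as.numeric(rowsum(mass, grp))
  nf <- n_frames(traj)
  out <- array(NA_real_, dim = c(length(mols), 3, nf),
               dimnames = list(as.character(mols), NULL, NULL))
  for (f in seq_len(nf)) {
    x <- traj$coords[idx, , f, drop = FALSE][, , 1, drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, ncol = 3)
    out[, , f] <- rowsum(x * mass, grp) / msum
  }
  out
}
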