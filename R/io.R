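#' Read a trajectory from XYZ, PDB or DCD
#'
#' Supported formats:
#' \describe{
#'   \item{xyz}{Extended XYZ dialect whose comment line must contain
#'     `box Lx Ly Lz` (Angstrom) and may contain `time t` (ps).}
#'   \item{pdb}{Multi-MODEL PDB; the box is taken from the CRYST1 record.
#'     Any cell angle differing from 90 degrees is rejected (orthorhombic
#'     boxes only).}
#'   \item{dcd}{CHARMM-style binary DCD with a unit-cell block (read via
#'     bio3d).}
#' }
#' The declared atom count must match the topology-implied count.
#'
#' @param path File path.
#' @param topology A `mix_topology` for the file.
#' @param format One of `"xyz"`, `"pdb"`, `"dcd"`; default guesses from the
#'   file extension.
#' @param dt Timestep in ps used when the file carries no time information.
#' @return A `mix_traj`.
#' @export
read_trajectory <- function(path, topology, format = NULL, dt = 1) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  format <- match.arg(format, c("xyz", "pdb", "dcd"))
  switch(format,
         xyz = read_xyz(path, topology, dt),
         pdb = read_pdb_traj(path, topology, dt),
         dcd = read_dcd_traj(path, topology, dt))
}

read_xyz <- function(path, topology, dt = 1) {
  lines <- readLines(path)
  n_expected <- n_atoms_topology(topology)
  pos <- 1L
  coords <- list()
  boxes <- list()
  times <- numeric(0)
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    na <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(na)) abort(sprintf("xyz: expected atom count at line %d", pos))
    if (na != n_expected) {
      abort(sprintf("xyz: frame declares %d atoms but topology implies %d",
                    na, n_expected))
    }
    comment <- lines[pos + 1L]
    m <- regmatches(comment, regexec(
      "box\\s+([-0-9.eE+]+)\\s+([-0-9.eE+]+)\\s+([-0-9.eE+]+)", comment))[[1]]
    if (length(m) != 4L) {
      abort(sprintf("xyz: comment line of frame at line %d lacks 'box Lx Ly Lz'", pos))
    }
    box <- as.numeric(m[2:4])
    tm <- regmatches(comment, regexec("time\\s+([-0-9.eE+]+)", comment))[[1]]
    times <- c(times, if (length(tm) == 2L) as.numeric(tm[2]) else NA_real_)
    block <- lines[(pos + 2L):(pos + 1L + na)]
    fields <- strsplit(trimws(block), "\\s+")
    xyz <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
    coords[[length(coords) + 1L]] <- xyz
    boxes[[length(boxes) + 1L]] <- box
    pos <- pos + 2L + na
  }
  if (!length(coords)) abort("xyz: no frames found")
  arr <- array(unlist(coords), dim = c(n_expected, 3, length(coords)))
  if (anyNA(times)) times <- NULL
  trajectory(arr, do.call(rbind, boxes), topology, times = times, dt = dt)
}

#' Write a trajectory as XYZ
#'
#' Writes the package's XYZ dialect: per frame, the atom count, a comment
#' line `box Lx Ly Lz time t`, then `element x y z` records at 1e-6 A
#' precision.
#'
#' @param traj A `mix_traj`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "mix_traj"))
  el <- if (!is.null(traj$topology)) traj$topology$atoms$element else rep("X", n_atoms(traj))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(as.character(n_atoms(traj)), con)
    writeLines(sprintf("box %.8f %.8f %.8f time %.8f",
                       traj$box[f, 1], traj$box[f, 2], traj$box[f, 3],
                       traj$times[f]), con)
    x <- frame_coords(traj, f)
    writeLines(sprintf("%s %.8f %.8f %.8f", el, x[, 1], x[, 2], x[, 3]), con)
  }
  invisible(path)
}

read_pdb_traj <- function(path, topology, dt = 1) {
  lines <- readLines(path)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cr)) abort("pdb: no CRYST1 record; box is required")
  cr <- cr[1]
  box <- as.numeric(c(substr(cr, 7, 15), substr(cr, 16, 24), substr(cr, 25, 33)))
  ang <- as.numeric(c(substr(cr, 34, 40), substr(cr, 41, 47), substr(cr, 48, 54)))
  if (any(abs(ang - 90) > 1e-6)) {
    abort(sprintf(
      "pdb: non-orthorhombic cell (angles %.2f %.2f %.2f); only orthorhombic boxes are supported",
      ang[1], ang[2], ang[3]))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  na <- ncol(xyz) / 3
  if (na != n_atoms_topology(topology)) {
    abort(sprintf("pdb: file has %d atoms but topology implies %d",
                  na, n_atoms_topology(topology)))
  }
  nf <- nrow(xyz)
  arr <- array(NA_real_, dim = c(na, 3, nf))
  for (f in seq_len(nf)) {
    arr[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  trajectory(arr, box, topology, dt = dt)
}

read_dcd_traj <- function(path, topology, dt = 1) {
  xyz <- bio3d::read.dcd(path, cell = FALSE, verbose = FALSE)
  cell <- tryCatch(bio3d::read.dcd(path, cell = TRUE, verbose = FALSE),
                   error = function(e) NULL)
  if (is.null(cell)) abort("dcd: file carries no unit-cell block; box is required")
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  cell <- as.matrix(cell)
  if (is.null(dim(cell)) || ncol(cell) < 6) cell <- matrix(cell, ncol = 6)
  ang <- cell[, 4:6, drop = FALSE]
  if (any(abs(ang - 90) > 1e-4)) {
    abort("dcd: non-orthorhombic cell; only orthorhombic boxes are supported")
  }
  na <- ncol(xyz) / 3
  if (na != n_atoms_topology(topology)) {
    abort(sprintf("dcd: file has %d atoms but topology implies %d",
                  na, n_atoms_topology(topology)))
  }
  nf <- nrow(xyz)
  arr <- array(NA_real_, dim = c(na, 3, nf))
  for (f in seq_len(nf)) arr[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  trajectory(arr, cell[, 1:3, drop = FALSE], topology, dt = dt)
}

#' Write a tibble as CSV with a JSON metadata header
#'
#' The metadata (selections, bins, frame counts, generator seeds, units) is
#' serialized as a single JSON object on a leading `#` comment line, so the
#' file stays valid CSV for any reader that skips comments.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param meta Named list of metadata.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @return `read_table_csv()` returns a list with elements `data` (tibble)
#'   and `meta` (list).
#' @export
read_table_csv <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- if (length(hdr)) jsonlite::fromJSON(sub("^#\\s*", "", hdr[1])) else list()
  data <- as_tibble(utils::read.csv(path, comment.char = "#"))
  list(data = data, meta = meta)
}

#' Write / read an off-diagonal pressure-tensor series as CSV
#'
#' Columns `time, Pxy, Pxz, Pyz` with a JSON header line carrying the box
#' volume (A^3), temperature (K) and pressure units (`"atm"` or
#' `"kcal/mol/A3"`), so MD-engine output can be fed to
#' [green_kubo_viscosity()] without the package's own virial evaluator.
#'
#' @param series A `mix_pressure_series`.
#' @param path File path.
#' @return `read_pressure_series()` returns a `mix_pressure_series`.
#' @export
write_pressure_series <- function(series, path) {
  stopifnot(inherits(series, "mix_pressure_series"))
  meta <- list(volume_A3 = attr(series, "volume"),
               temperature_K = attr(series, "temperature"),
               units = attr(series, "units"))
  md <- attr(series, "metadata")
  if (length(md)) meta <- c(meta, md[vapply(md, is.atomic, logical(1))])
  write_table_csv(as_tibble(series)[, c("time", "Pxy", "Pxz", "Pyz")],
                  path, meta)
}

#' @rdname write_pressure_series
#' @export
read_pressure_series <- function(path) {
  x <- read_table_csv(path)
  need <- c("time", "Pxy", "Pxz", "Pyz")
  if (!all(need %in% names(x$data))) {
    abort("pressure series CSV must have columns time, Pxy, Pxz, Pyz")
  }
  pressure_series(x$data[need],
                  volume = x$meta$volume_A3,
                  temperature = x$meta$temperature_K,
                  units = x$meta$units %||% "atm",
                  metadata = x$meta)
}

#' Write a spatial density grid in Gaussian cube format
#'
#' Voxel vectors are converted from Angstrom to bohr as the cube standard
#' requires; values stay in particles per cubic Angstrom. A single dummy
#' atom marks the local-frame origin.
#'
#' @param grid A `mix_sdf` density grid.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(grid, path) {
  stopifnot(inherits(grid, "mix_sdf"))
  vals <- attr(grid, "values")
  origin <- attr(grid, "origin") * .BOHR_PER_ANGSTROM
  voxel <- attr(grid, "voxel") * .BOHR_PER_ANGSTROM
  n <- dim(vals)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("mixanalyze spatial distribution grid (density in A^-3)", con)
  writeLines("local molecular frame: origin anchor1, x toward anchor2, xy-plane through anchor3", con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", 1L, origin[1], origin[2], origin[3]), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", n[1], voxel, 0, 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", n[2], 0, voxel, 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", n[3], 0, 0, voxel), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", 1L, 0, 0, 0, 0), con)
  for (i in seq_len(n[1])) {
    for (j in seq_len(n[2])) {
      v <- vals[i, j, ]
      chunks <- split(v, ceiling(seq_along(v) / 6))
      writeLines(vapply(chunks, function(ch) paste(sprintf("%13.5e", ch), collapse = " "),
                        character(1)), con)
    }
  }
  invisible(path)
}
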