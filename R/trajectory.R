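#' Construct a trajectory object
#'
#' A trajectory couples per-frame coordinates with a topology structure whose
#' atom order defines the coordinate order.
#'
#' @param coords Numeric array `frames x atoms x 3` (Angstrom).
#' @param times Numeric vector of frame times in picoseconds.
#' @param topology A `gpcr_structure` with the same atom count.
#' @param source Free-text provenance.
#' @return An object of class `gpcr_trajectory`.
#' @export
new_trajectory <- function(coords, times, topology, source = "memory") {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L,
            inherits(topology, "gpcr_structure"),
            dim(coords)[2] == nrow(topology$atoms),
            length(times) == dim(coords)[1])
  structure(list(coords = coords, times = as.numeric(times),
                 topology = topology, source = source),
            class = "gpcr_trajectory")
}

#' @export
print.gpcr_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, t = %.1f..%.1f ps (source: %s)\n",
              n_frames(x), dim(x$coords)[2],
              if (n_frames(x)) min(x$times) else NA,
              if (n_frames(x)) max(x$times) else NA, x$source))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory A `gpcr_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[1]

#' Extract one frame as a structure
#'
#' @param trajectory A `gpcr_trajectory`.
#' @param i Frame index (1-based).
#' @return A `gpcr_structure` with the topology's atoms at frame `i`'s
#'   coordinates.
#' @export
frame_structure <- function(trajectory, i) {
  if (i < 1L || i > n_frames(trajectory))
    gpcr_abort(sprintf("frame index %d out of range 1..%d", i,
                       n_frames(trajectory)), "gpcrstates_validation_error")
  s <- trajectory$topology
  s$atoms$x <- trajectory$coords[i, , 1]
  s$atoms$y <- trajectory$coords[i, , 2]
  s$atoms$z <- trajectory$coords[i, , 3]
  s$source <- sprintf("%s[frame %d]", trajectory$source, i)
  s
}

#' Read a multi-model PDB file as a trajectory
#'
#' Frame times default to `interval_ps * model_index`.
#'
#' @param path Path to a multi-MODEL PDB file.
#' @param interval_ps Time between consecutive models, in ps.
#' @return A `gpcr_trajectory`.
#' @export
read_pdb_trajectory <- function(path, interval_ps = 100) {
  lines <- readLines(path, warn = FALSE)
  models <- split_models(lines)
  frames <- lapply(models, parse_atom_lines)
  nat <- unname(vapply(frames, nrow, integer(1)))
  if (length(unique(nat)) != 1L)
    gpcr_abort("models differ in atom count", "gpcrstates_io_error")
  coords <- array(0, dim = c(length(frames), nat[1], 3))
  for (i in seq_along(frames))
    coords[i, , ] <- as.matrix(frames[[i]][, c("x", "y", "z")])
  new_trajectory(coords, interval_ps * seq_along(frames),
                 new_structure(frames[[1]], source = path), source = path)
}

# ---- DCD binary trajectory format ------------------------------------------
# CHARMM/NAMD layout: Fortran record markers, "CORD" header with a 20-int
# control block, title block, atom-count block, then per frame three float
# records (x, y, z). Convention note: this writer stores the snapshot
# interval directly in ps in the header delta field (not AKMA units);
# read_dcd() inverts the same convention, so third-party DCDs load with
# times in AKMA-scaled units unless `interval_ps` is given.

#' Write a trajectory to a DCD file
#'
#' @param trajectory A `gpcr_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(trajectory, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nfr <- n_frames(trajectory)
  nat <- dim(trajectory$coords)[2]
  dt <- if (nfr > 1) diff(trajectory$times)[1] else trajectory$times[1]
  rec <- function(writer) {
    # Fortran sequential record: length marker, payload, length marker
    raw <- writer()
    writeBin(length(raw), con, size = 4, endian = "little")
    writeBin(raw, con)
    writeBin(length(raw), con, size = 4, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- nfr   # NSET
  icntrl[2] <- 1L    # ISTART
  icntrl[3] <- 1L    # NSAVC
  icntrl[20] <- 24L  # version
  rec(function() {
    c(charToRaw("CORD"),
      writeBin(icntrl[1:9], raw(), size = 4, endian = "little"),
      writeBin(as.numeric(dt), raw(), size = 4, endian = "little"),
      writeBin(icntrl[11:20], raw(), size = 4, endian = "little"))
  })
  title <- sprintf("%-80s", "Created by gpcrstates")
  rec(function() c(writeBin(1L, raw(), size = 4, endian = "little"),
                   charToRaw(title)))
  rec(function() writeBin(as.integer(nat), raw(), size = 4, endian = "little"))
  for (i in seq_len(nfr)) {
    for (d in 1:3) {
      rec(local({ di <- d; ii <- i; function()
        writeBin(as.numeric(trajectory$coords[ii, , di]), raw(), size = 4,
                 endian = "little") }))
    }
  }
  invisible(path)
}

#' Read a DCD trajectory
#'
#' @param path Path to a DCD file.
#' @param topology A `gpcr_structure` providing atom identities (the PDB
#'   topology written alongside the trajectory).
#' @param interval_ps Optional override of the frame interval in ps; by
#'   default the header delta field is interpreted as ps (see [write_dcd()]).
#' @return A `gpcr_trajectory`.
#' @export
read_dcd <- function(path, topology, interval_ps = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rec <- function() {
    n <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(n) == 0L) return(NULL)
    payload <- readBin(con, "raw", n)
    n2 <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (!identical(n, n2))
      gpcr_abort("corrupt DCD record markers", "gpcrstates_io_error")
    payload
  }
  hdr <- rec()
  if (is.null(hdr) || rawToChar(hdr[1:4]) != "CORD")
    gpcr_abort(sprintf("not a DCD file: %s", path), "gpcrstates_io_error")
  nset <- readBin(hdr[5:8], "integer", 1, size = 4, endian = "little")
  istart <- readBin(hdr[9:12], "integer", 1, size = 4, endian = "little")
  nsavc <- readBin(hdr[13:16], "integer", 1, size = 4, endian = "little")
  delta <- readBin(hdr[41:44], "numeric", 1, size = 4, endian = "little")
  rec() # title block, ignored
  nat <- readBin(rec(), "integer", 1, size = 4, endian = "little")
  if (nat != nrow(topology$atoms))
    gpcr_abort(sprintf("DCD atom count (%d) does not match topology (%d)",
                       nat, nrow(topology$atoms)), "gpcrstates_validation_error")
  coords <- array(NA_real_, dim = c(nset, nat, 3))
  for (i in seq_len(nset)) {
    for (d in 1:3) {
      payload <- rec()
      if (is.null(payload))
        gpcr_abort(sprintf("DCD truncated at frame %d", i), "gpcrstates_io_error")
      coords[i, , d] <- readBin(payload, "numeric", nat, size = 4,
                                endian = "little")
    }
  }
  dt <- interval_ps %||% delta
  times <- (istart + (seq_len(nset) - 1L) * nsavc) * dt
  new_trajectory(coords, times, topology, source = path)
}

# ---- frame sampling ---------------------------------------------------------

#' Define a frame sampling plan
#'
#' The default plan mirrors short production runs used for state-labelled
#' training data: 20 ns of dynamics sampled every 100 ps, i.e. 200 frames
#' per trajectory. Snapshots are taken at t = interval, 2*interval, ...,
#' length (the t = 0 starting structure is not a snapshot), so the expected
#' frame count is `floor(length_ns * 1000 / interval_ps)`.
#'
#' @param length_ns Trajectory length in nanoseconds.
#' @param interval_ps Sampling interval in picoseconds.
#' @return An object of class `gpcr_sampling_plan` with fields `length_ns`,
#'   `interval_ps`, `n_frames`.
#' @examples
#' sampling_plan()          # 200 frames
#' sampling_plan(1, 100)    # 10 frames
#' @export
sampling_plan <- function(length_ns = 20, interval_ps = 100) {
  stopifnot(length_ns > 0, interval_ps > 0)
  structure(list(length_ns = length_ns, interval_ps = interval_ps,
                 n_frames = as.integer(floor(length_ns * 1000 / interval_ps))),
            class = "gpcr_sampling_plan")
}

#' @export
print.gpcr_sampling_plan <- function(x, ...) {
  cat(sprintf("<sampling plan> %g ns / %g ps -> %d frames\n",
              x$length_ns, x$interval_ps, x$n_frames))
  invisible(x)
}

#' Extract evenly spaced frames according to a sampling plan
#'
#' Picks the trajectory frame nearest each target time t = interval,
#' 2*interval, ..., length. The trajectory must span the plan length
#' (within one interval of tolerance).
#'
#' @param trajectory A `gpcr_trajectory`.
#' @param plan A `gpcr_sampling_plan`.
#' @return The subsampled `gpcr_trajectory`, with an attribute
#'   `frame_index` recording the source frame of each snapshot.
#' @export
extract_frames <- function(trajectory, plan = sampling_plan()) {
  span <- max(trajectory$times)
  want <- plan$length_ns * 1000
  if (span < want - plan$interval_ps)
    gpcr_abort(sprintf("trajectory spans %.0f ps but the plan requires %.0f ps",
                       span, want), "gpcrstates_validation_error")
  targets <- plan$interval_ps * seq_len(plan$n_frames)
  idx <- vapply(targets, function(t) which.min(abs(trajectory$times - t)),
                integer(1))
  out <- new_trajectory(trajectory$coords[idx, , , drop = FALSE],
                        trajectory$times[idx], trajectory$topology,
                        source = trajectory$source)
  attr(out, "frame_index") <- idx
  out
}
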