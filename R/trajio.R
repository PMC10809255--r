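#' Read a topology from a PDB file plus a sidecar table
#'
#' PDB records carry atom identities and frame-0 coordinates but no masses or
#' partial charges, so those are supplied through a sidecar TSV with columns
#' \code{particle_id}, \code{mass}, \code{charge} and \code{groups}
#' (semicolon-separated group names per particle; empty for none). No
#' element-based guessing is performed: a missing sidecar entry is an error,
#' since silently guessed charges would corrupt every dipole downstream.
#'
#' @param path path to the PDB file.
#' @param sidecar path to the sidecar TSV; defaults to \code{<path>.tsv}.
#' @return a [Topology-class].
#' @seealso [writeTopology()], [readTrajectory()]
#' @export
readTopology <- function(path, sidecar = paste0(path, ".tsv")) {
  if (!file.exists(path)) stop(sprintf("topology file not found: %s", path))
  if (!file.exists(sidecar)) stop(sprintf("sidecar file not found: %s", sidecar))
  pdb <- bio3d::read.pdb(path)
  nAtoms <- nrow(pdb$atom)
  sc <- utils::read.delim(sidecar, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(particle_id = "integer",
                                         mass = "numeric", charge = "numeric",
                                         groups = "character"))
  need <- c("particle_id", "mass", "charge", "groups")
  if (!all(need %in% names(sc)))
    stop("sidecar must have columns particle_id, mass, charge, groups")
  if (anyDuplicated(sc$particle_id))
    stop("duplicate particle ids in sidecar")
  if (nrow(sc) != nAtoms)
    stop(sprintf("sidecar has %d particles but PDB has %d atoms",
                 nrow(sc), nAtoms))
  sc <- sc[order(sc$particle_id), ]
  if (!identical(sc$particle_id, 0:(nAtoms - 1L)))
    stop("sidecar particle ids must be contiguous from 0")
  memberships <- strsplit(sc$groups, ";", fixed = TRUE)
  groups <- list()
  for (i in seq_len(nAtoms)) {
    for (g in memberships[[i]]) {
      if (!nzchar(g)) next
      groups[[g]] <- c(groups[[g]], sc$particle_id[i])
    }
  }
  topology(sc$particle_id, sc$mass, sc$charge, groups)
}

#' Write a topology as PDB plus sidecar table
#'
#' @param topology a [Topology-class].
#' @param coords frame-0 coordinates, nParticles x 3 matrix (Angstrom).
#' @param path output PDB path; the sidecar is written to \code{<path>.tsv}.
#' @return invisibly, the PDB path.
#' @export
writeTopology <- function(topology, coords, path) {
  n <- nParticles(topology)
  stopifnot(nrow(coords) == n, ncol(coords) == 3)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(coords)),
                   resno = rep(1L, n), resid = rep("MOL", n),
                   eleno = seq_len(n), elety = rep("C", n))
  membership <- rep("", n)
  for (g in groupNames(topology)) {
    ids <- groupMembers(topology, g) + 1L
    membership[ids] <- ifelse(nzchar(membership[ids]),
                              paste(membership[ids], g, sep = ";"), g)
  }
  sc <- data.frame(particle_id = topology@particleId,
                   mass = sprintf("%.4f", topology@mass),
                   charge = sprintf("%.6f", topology@charge),
                   groups = membership)
  utils::write.table(sc, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a trajectory table
#'
#' The canonical on-disk trajectory dialect is a diffable TSV with one row
#' per particle per frame: \code{frame  time_ns  particle_id  x  y  z}
#' (coordinates in Angstrom at fixed precision). Malformed input is
#' rejected, never repaired.
#'
#' @param path path to the trajectory TSV.
#' @param topology the matching [Topology-class].
#' @return a [Trajectory-class].
#' @seealso [writeTrajectory()]
#' @export
readTrajectory <- function(path, topology) {
  if (!file.exists(path)) stop(sprintf("trajectory file not found: %s", path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("frame", "time_ns", "particle_id", "x", "y", "z")
  if (!all(need %in% names(dt)))
    stop("trajectory table must have columns frame, time_ns, particle_id, x, y, z")
  if (nrow(dt) == 0) stop("trajectory table is empty")
  n <- nParticles(topology)
  data.table::setorderv(dt, c("frame", "particle_id"))
  frameRle <- rle(dt$frame)
  frames <- frameRle$values
  counts <- frameRle$lengths
  if (any(counts != n))
    stop(sprintf("particle count per frame does not match topology (%d)", n))
  times <- dt$time_ns[match(frames, dt$frame)]
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (!identical(as.integer(sort(unique(dt$particle_id))), 0:(n - 1L)))
    stop("particle ids do not match the topology")
  coords <- array(NA_real_, dim = c(n, 3, length(frames)))
  xyz <- as.matrix(dt[, c("x", "y", "z")])
  for (f in seq_along(frames)) {
    rows <- ((f - 1L) * n + 1L):(f * n)
    coords[, , f] <- xyz[rows, ]
  }
  trajectory(times, coords, topology)
}

#' Write a trajectory table
#'
#' Coordinates are written at fixed 4-decimal precision, times at 6; a file
#' written from coordinates already rounded to that precision round-trips
#' bit-identically through \code{writeTrajectory} and [readTrajectory()].
#'
#' @param traj a [Trajectory-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeTrajectory <- function(traj, path) {
  n <- nParticles(traj)
  nf <- nFrames(traj)
  frame <- rep(seq_len(nf) - 1L, each = n)
  dt <- data.table::data.table(
    frame = frame,
    time_ns = sprintf("%.6f", rep(frameTimes(traj), each = n)),
    particle_id = rep(0:(n - 1L), nf),
    x = sprintf("%.4f", as.numeric(traj@coords[, 1, ])),
    y = sprintf("%.4f", as.numeric(traj@coords[, 2, ])),
    z = sprintf("%.4f", as.numeric(traj@coords[, 3, ]))
  )
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# Registered result schemas: deterministic column order and float formats.
.tableSchemas <- list(
  metrics = list(
    columns = c("time_ns", "dye", "np", "surface_dist_A",
                "parallel_angle_deg", "theta_deg"),
    formats = c(time_ns = "%.6f", surface_dist_A = "%.4f",
                parallel_angle_deg = "%.3f", theta_deg = "%.3f")
  ),
  segments = list(
    columns = c("dye", "np", "label", "start_ns", "end_ns",
                "mean_surface_distance_A", "parallel_fraction",
                "mean_theta_deg", "flagged"),
    formats = c(start_ns = "%.4f", end_ns = "%.4f",
                mean_surface_distance_A = "%.4f", parallel_fraction = "%.4f",
                mean_theta_deg = "%.3f")
  ),
  dimer_events = list(
    columns = c("dye_a", "dye_b", "start_ns", "end_ns", "location",
                "end_reason"),
    formats = c(start_ns = "%.4f", end_ns = "%.4f")
  ),
  trimer_intervals = list(
    columns = c("dye_a", "dye_b", "dye_c", "start_ns", "end_ns", "transient"),
    formats = c(start_ns = "%.4f", end_ns = "%.4f")
  ),
  transitions = list(
    columns = c("t_peak_ps", "t_end_ps", "f_end_pN", "dF_pN", "dE_eV"),
    formats = c(t_peak_ps = "%.3f", t_end_ps = "%.3f", f_end_pN = "%.3f",
                dF_pN = "%.3f", dE_eV = "%.6f")
  ),
  adsorption_summary = list(columns = NULL, formats = c(), average_row = TRUE),
  dimer_summary = list(
    columns = c("system", "mean_dimer_count", "total_time_ns",
                "mean_lifetime_ns"),
    formats = c(mean_dimer_count = "%.4f", total_time_ns = "%.4f",
                mean_lifetime_ns = "%.4f")
  ),
  characterization = list(columns = NULL, formats = c())
)

#' Write a result table in a registered schema
#'
#' All tabular outputs share one dialect: TSV with header, UTF-8, '.'
#' decimal separator, deterministic column order, floats at fixed per-column
#' precision. The \code{adsorption_summary} schema (one row per repetition,
#' one column per system) additionally appends an \code{"average"} row
#' computed with [averageOverRepetitions()], matching how per-repetition
#' adsorbed-time percentages are reported.
#'
#' @param rows a data.frame of result records.
#' @param path output path.
#' @param schema one of \code{names(dyetraj:::.tableSchemas)}.
#' @return invisibly, the path.
#' @seealso [readResultTable()]
#' @export
writeResultTable <- function(rows, path, schema) {
  if (!schema %in% names(.tableSchemas))
    stop(sprintf("unregistered schema '%s'", schema))
  sc <- .tableSchemas[[schema]]
  df <- as.data.frame(rows)
  if (!is.null(sc$columns)) {
    missing <- setdiff(sc$columns, names(df))
    if (nrow(df) == 0 && length(missing)) {
      for (m in missing) df[[m]] <- character(0)
      missing <- character(0)
    }
    if (length(missing))
      stop(sprintf("schema '%s' requires columns: %s", schema,
                   paste(missing, collapse = ", ")))
    df <- df[, sc$columns, drop = FALSE]
  }
  if (isTRUE(sc$average_row) && nrow(df) > 0) {
    numcols <- vapply(df, is.numeric, logical(1))
    avg <- df[1, , drop = FALSE]
    for (cn in names(df)) {
      if (numcols[[cn]] && cn != "repetition") {
        avg[[cn]] <- averageOverRepetitions(df[[cn]])
        df[[cn]] <- sprintf("%.4f", df[[cn]])
      } else {
        df[[cn]] <- as.character(df[[cn]])
        avg[[cn]] <- "average"
      }
    }
    df <- rbind(df, avg)
  }
  for (cn in names(sc$formats)) {
    if (cn %in% names(df) && nrow(df) > 0)
      df[[cn]] <- sprintf(sc$formats[[cn]], as.numeric(df[[cn]]))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a result table written by [writeResultTable()]
#'
#' @param path path to the TSV.
#' @return a data.frame.
#' @export
readResultTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("table not found: %s", path))
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
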