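#' Fluorophore trajectory tables
#'
#' A sample trajectory is the simulator's ground-truth input: one row per
#' molecule per frame with columns `time_s`, `molecule_id`, `species`,
#' `x_um`, `y_um`, `z_um`. Coordinates are object-space micrometres in a
#' right-handed frame with z = 0 at the coverslip and z increasing into the
#' sample (this orientation fixes the evanescent-decay direction). Invariants:
#' times strictly increasing; every molecule present at one frame is present
#' at all frames; all coordinates finite with z >= 0.
#'
#' @param df A data frame with the six columns above.
#' @return A validated `sample_trajectory` (a data frame subclass).
#' @seealso [generate_surface_plate()], [generate_solution_box()],
#'   [generate_hemisphere_cell()], [read_trajectory()]
#' @export
sample_trajectory <- function(df) {
  cols <- c("time_s", "molecule_id", "species", "x_um", "y_um", "z_um")
  if (!is.data.frame(df) || !all(cols %in% names(df)))
    stop_arg("trajectory needs columns: ", paste(cols, collapse = ", "))
  df <- df[cols]
  df$molecule_id <- as.integer(df$molecule_id)
  df$species <- as.character(df$species)
  for (v in c("time_s", "x_um", "y_um", "z_um")) df[[v]] <- as.numeric(df[[v]])
  if (nrow(df) == 0L)
    return(structure(df, class = c("sample_trajectory", "data.frame")))
  num <- df[c("time_s", "x_um", "y_um", "z_um")]
  if (!all(vapply(num, function(v) all(is.finite(v)), logical(1))))
    stop_arg("trajectory contains non-finite values")
  if (any(df$z_um < 0))
    stop_arg("trajectory contains z < 0 (z is measured from the coverslip)")
  times <- unique(df$time_s)
  if (is.unsorted(times, strictly = TRUE))
    stop_arg("frame times must be strictly increasing")
  ids0 <- sort(df$molecule_id[df$time_s == times[1L]])
  if (anyDuplicated(ids0))
    stop_arg("duplicate molecule_id within a frame")
  for (t in times[-1L]) {
    ids <- sort(df$molecule_id[df$time_s == t])
    if (length(ids) != length(ids0) || any(ids != ids0))
      stop_arg("molecule set differs between frames (no birth/death allowed)")
  }
  df <- df[order(df$time_s, df$molecule_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("sample_trajectory", "data.frame"))
}

#' @export
print.sample_trajectory <- function(x, ...) {
  times <- traj_times(x)
  cat(sprintf("<sample_trajectory> %d molecule(s) x %d frame(s)\n",
              if (length(times)) sum(x$time_s == times[1L]) else 0L,
              length(times)))
  if (length(times))
    cat(sprintf("  t: %g .. %g s;  species: %s\n", min(times), max(times),
                paste(unique(x$species), collapse = ", ")))
  if (nrow(x)) {
    cat("  head:\n")
    print(utils::head(as.data.frame(x), 4L))
  }
  invisible(x)
}

#' Frame times of a trajectory
#' @param traj A `sample_trajectory`.
#' @return Numeric vector of frame times in seconds.
#' @export
traj_times <- function(traj) unique(traj$time_s)

#' Extract one frame of a trajectory
#' @param traj A `sample_trajectory`.
#' @param which Frame index (1-based) or, with `time =`, an exact frame time.
#' @param time Frame time in seconds (overrides `which`).
#' @return A `sample_trajectory` containing a single time point.
#' @export
traj_frame <- function(traj, which = 1L, time = NULL) {
  times <- traj_times(traj)
  t0 <- if (!is.null(time)) time else times[which]
  if (is.na(t0) || !t0 %in% times) stop_arg("no such frame")
  out <- traj[traj$time_s == t0, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("sample_trajectory", "data.frame"))
}

#' Write / read trajectory CSV
#'
#' The CSV dialect: header `time_s,molecule_id,species,x_um,y_um,z_um`, UTF-8,
#' '.' decimal separator, one row per molecule per frame. Numeric fields are
#' written with 17 significant digits so a round trip reproduces the doubles
#' exactly.
#'
#' @param traj A `sample_trajectory`.
#' @param path Output file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a validated `sample_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  traj <- sample_trajectory(traj)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("time_s,molecule_id,species,x_um,y_um,z_um", con)
  if (nrow(traj)) {
    lines <- sprintf("%.17g,%d,%s,%.17g,%.17g,%.17g",
                     traj$time_s, traj$molecule_id, traj$species,
                     traj$x_um, traj$y_um, traj$z_um)
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop_arg("trajectory file not found: ", path)
  header <- readLines(path, n = 1L)
  if (!identical(header, "time_s,molecule_id,species,x_um,y_um,z_um"))
    stop_arg("line 1: unexpected header '", header, "'")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("numeric", "integer", "character",
                                       "numeric", "numeric", "numeric"))
  if (nrow(df)) {
    bad <- which(!stats::complete.cases(df[c("time_s", "molecule_id",
                                             "x_um", "y_um", "z_um")]))
    if (length(bad))
      stop_arg("line ", bad[1L] + 1L, ": malformed row")
    dec <- which(diff(df$time_s) < 0)
    if (length(dec))
      stop_arg("line ", dec[1L] + 2L, ": time_s decreases")
  }
  sample_trajectory(df)
}
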