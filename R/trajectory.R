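#' Trajectory frames
#'
#' A frame holds the timestamped atom records of one MD snapshot; a trajectory
#' is an ordered sequence of frames with constant atom count.  Molecule
#' membership is assigned by contiguous index blocks (`molecule_id =
#' (global_index - 1) %/% molecule_size`, zero based), matching the
#' duplicated-molecule layout that system-builder tools emit.
#'
#' @param step integer MD step.
#' @param time time in ps.
#' @param cl an [cell()] object.
#' @param atoms data.frame with columns `label`, `index`, `molecule`, `x`,
#'   `y`, `z` and optionally `mass`, `charge`.
#' @return `md_frame` / `md_trajectory` objects.
#' @export
frame <- function(step, time, cl, atoms) {
  stopifnot(inherits(cl, "md_cell"), is.data.frame(atoms))
  need <- c("label", "index", "molecule", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(atoms$index))
    stop("atom global indices must be unique within a frame")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom positions must be finite")
  structure(list(step = as.integer(step), time = as.numeric(time),
                 cell = cl, atoms = atoms),
            class = "md_frame")
}

#' @rdname frame
#' @param frames list of `md_frame` objects.
#' @param source free-text provenance.
#' @export
trajectory <- function(frames, source = "constructed") {
  stopifnot(length(frames) >= 1L,
            all(vapply(frames, inherits, logical(1), "md_frame")))
  n <- vapply(frames, function(f) nrow(f$atoms), integer(1))
  if (length(unique(n)) != 1L)
    stop("atom count must be constant across frames")
  tm <- vapply(frames, `[[`, numeric(1), "time")
  if (length(tm) > 1L && any(diff(tm) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(frames = frames, source = source), class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d frame(s), %d atoms, source: %s\n",
              length(x$frames), nrow(x$frames[[1]]$atoms), x$source))
  invisible(x)
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("<md_frame> step %d, t = %g ps, %d atoms (%s cell)\n",
              x$step, x$time, nrow(x$atoms), x$cell$periodic))
  invisible(x)
}

.assign_molecules <- function(n_atoms, molecule_size, where = "trajectory") {
  molecule_size <- as.integer(molecule_size)
  if (molecule_size < 1L) stop("molecule_size must be a positive integer")
  if (n_atoms %% molecule_size != 0L)
    stop(sprintf("%s: atom count %d is not divisible by molecule_size %d",
                 where, n_atoms, molecule_size))
  (seq_len(n_atoms) - 1L) %/% molecule_size
}

.imcon_to_periodic <- function(imcon) {
  switch(as.character(imcon), "1" = "cubic", "2" = "orthorhombic",
         "3" = "parallelepiped",
         stop("unsupported imcon value ", imcon, " (accepted: 1, 2, 3)"))
}

.periodic_to_imcon <- function(periodic) {
  switch(periodic, cubic = 1L, orthorhombic = 2L, parallelepiped = 3L,
         stop("cannot write a non-periodic cell to HISTORY"))
}

.num <- function(tok, lineno, what) {
  v <- suppressWarnings(as.numeric(tok))
  if (any(is.na(v)))
    stop(sprintf("line %d: non-numeric %s: '%s'", lineno, what,
                 paste(tok[is.na(v)], collapse = " ")))
  v
}

#' Read a DL_POLY-style HISTORY trajectory
#'
#' Parses the HISTORY text dialect (plain or gzip-compressed): a title line;
#' a header line `levcfg imcon natms [...]`; then per frame a
#' `timestep <step> <natms> <levcfg> <imcon> <dt> <time>` line, three cell
#' rows, and per atom a `label index [mass charge ...]` line followed by an
#' `x y z` line (velocity/force lines are skipped according to `levcfg`).
#'
#' @param path file path (text or `.gz`).
#' @param molecule_size atoms per molecule for block molecule assignment
#'   (8 for all-atom HFA-134a, 2 for the reduced two-center dimers).
#' @return An [trajectory()] object; positions in Angstrom, time in ps.
#' @export
read_history <- function(path, molecule_size) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  # tolerate trailing blank lines
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (length(lines) < 2L) stop("structural error: HISTORY file has no header")
  hdr <- strsplit(trimws(lines[2L]), "\\s+")[[1]]
  if (length(hdr) < 2L || length(hdr) > 5L)
    stop("line 2: header must carry 2-5 integers (levcfg imcon natms ...)")
  hdr <- .num(hdr, 2L, "header field")
  hdr_natms <- if (length(hdr) >= 3L) as.integer(hdr[3L]) else NA_integer_

  i <- 3L
  frames <- list()
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (tolower(tok[1L]) != "timestep" || length(tok) < 5L)
      stop(sprintf("line %d: malformed timestep record: '%s'", i, lines[i]))
    vals <- .num(tok[-1L], i, "timestep field")
    step <- as.integer(vals[1L]); natms <- as.integer(vals[2L])
    levcfg <- as.integer(vals[3L]); imcon <- as.integer(vals[4L])
    tm <- if (length(vals) >= 6L) vals[6L] else vals[1L] * vals[5L]
    if (!levcfg %in% 0:2)
      stop(sprintf("line %d: unsupported levcfg %d (accepted: 0, 1, 2)",
                   i, levcfg))
    per <- .imcon_to_periodic(imcon)
    if (!is.na(hdr_natms) && natms != hdr_natms)
      stop(sprintf("structural error: frame at line %d declares %d atoms, header says %d",
                   i, natms, hdr_natms))
    if (i + 3L > length(lines))
      stop(sprintf("line %d: truncated frame: missing cell rows", i))
    cm <- t(vapply(1:3, function(k) {
      r <- strsplit(trimws(lines[i + k]), "\\s+")[[1]]
      if (length(r) != 3L)
        stop(sprintf("line %d: cell row must have 3 components", i + k))
      .num(r, i + k, "cell component")
    }, numeric(3)))
    cl <- cell(cm, per)
    j <- i + 4L
    per_atom <- 2L + levcfg
    if (j + natms * per_atom - 1L > length(lines))
      stop(sprintf("structural error: frame at line %d truncated (expected %d atoms)",
                   i, natms))
    lab <- character(natms); idx <- integer(natms)
    mass <- rep(NA_real_, natms); chg <- rep(NA_real_, natms)
    pos <- matrix(0, natms, 3L)
    for (a in seq_len(natms)) {
      at <- j + (a - 1L) * per_atom
      rec <- strsplit(trimws(lines[at]), "\\s+")[[1]]
      if (length(rec) < 2L)
        stop(sprintf("line %d: atom record needs at least 'label index'", at))
      lab[a] <- rec[1L]
      idx[a] <- as.integer(.num(rec[2L], at, "atom index"))
      if (length(rec) >= 3L) mass[a] <- .num(rec[3L], at, "mass")
      if (length(rec) >= 4L) chg[a] <- .num(rec[4L], at, "charge")
      xyz <- strsplit(trimws(lines[at + 1L]), "\\s+")[[1]]
      if (length(xyz) != 3L)
        stop(sprintf("line %d: coordinate record must have 3 components", at + 1L))
      pos[a, ] <- .num(xyz, at + 1L, "coordinate")
    }
    mol <- .assign_molecules(natms, molecule_size,
                             sprintf("frame at line %d", i))
    atoms <- data.frame(label = lab, index = idx, molecule = mol,
                        x = pos[, 1], y = pos[, 2], z = pos[, 3],
                        mass = mass, charge = chg)
    frames[[length(frames) + 1L]] <- frame(step, tm, cl, atoms)
    i <- j + natms * per_atom
  }
  if (!length(frames)) stop("structural error: no frames in HISTORY file")
  trajectory(frames, source = path)
}

#' Write a trajectory in the HISTORY dialect
#'
#' Emits text accepted by [read_history()]; positions are written with 10
#' decimals so a read/write round trip preserves them to well over 6
#' significant digits.
#'
#' @param traj an [trajectory()] object.
#' @param path output file path (a `.gz` suffix triggers gzip compression).
#' @export
write_history <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"), length(traj$frames) >= 1L)
  fr <- traj$frames
  natms <- nrow(fr[[1L]]$atoms)
  imcon <- .periodic_to_imcon(fr[[1L]]$cell$periodic)
  dt <- if (length(fr) > 1L) fr[[2L]]$time - fr[[1L]]$time else 0
  out <- c("HISTORY written by the danai package",
           sprintf("%d %d %d %d", 0L, imcon, natms, length(fr)))
  for (f in fr) {
    out <- c(out,
             sprintf("timestep %d %d %d %d %.6f %.6f",
                     f$step, natms, 0L, .periodic_to_imcon(f$cell$periodic),
                     dt, f$time),
             apply(f$cell$matrix, 1L,
                   function(r) sprintf("%18.10f %18.10f %18.10f",
                                       r[1], r[2], r[3])))
    a <- f$atoms
    mass <- ifelse(is.na(a$mass), 0, a$mass)
    chg <- ifelse(is.na(a$charge), 0, a$charge)
    rec <- sprintf("%-8s %d %.6f %.6f", a$label, a$index, mass, chg)
    xyz <- sprintf("%18.10f %18.10f %18.10f", a$x, a$y, a$z)
    out <- c(out, as.vector(rbind(rec, xyz)))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' Standard XYZ layout: an atom-count line, a comment line, then one
#' `label x y z` record per atom.  XYZ carries no cell, so one is supplied
#' externally.  The frame time is taken from a `time = <t>` (or `t= <t>`)
#' field on the comment line when present, else the zero-based frame index.
#'
#' @inheritParams read_history
#' @param cl the periodic [cell()] shared by all frames.
#' @export
read_xyz <- function(path, cl, molecule_size) {
  if (!file.exists(path)) stop("no such file: ", path)
  stopifnot(inherits(cl, "md_cell"))
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (!length(lines)) stop("structural error: empty XYZ file")
  i <- 1L; k <- 0L; frames <- list()
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n <= 0L)
      stop(sprintf("line %d: expected an atom count, got '%s'", i, lines[i]))
    if (i + 1L + n > length(lines))
      stop(sprintf("structural error: frame at line %d declares %d atoms but file ends early",
                   i, n))
    comment <- lines[i + 1L]
    m <- regmatches(comment,
                    regexec("t(?:ime)?\\s*=\\s*([-+0-9.eE]+)", comment))[[1L]]
    tm <- if (length(m) == 2L) as.numeric(m[2L]) else as.numeric(k)
    step <- k
    sm <- regmatches(comment, regexec("step\\s*=?\\s*([0-9]+)", comment))[[1L]]
    if (length(sm) == 2L) step <- as.integer(sm[2L])
    lab <- character(n); pos <- matrix(0, n, 3L)
    for (a in seq_len(n)) {
      at <- i + 1L + a
      rec <- strsplit(trimws(lines[at]), "\\s+")[[1]]
      if (length(rec) < 4L)
        stop(sprintf("line %d: XYZ record must be 'label x y z'", at))
      lab[a] <- rec[1L]
      pos[a, ] <- .num(rec[2:4], at, "coordinate")
    }
    mol <- .assign_molecules(n, molecule_size, sprintf("frame %d", k))
    atoms <- data.frame(label = lab, index = seq_len(n), molecule = mol,
                        x = pos[, 1], y = pos[, 2], z = pos[, 3],
                        mass = NA_real_, charge = NA_real_)
    frames[[length(frames) + 1L]] <- frame(step, tm, cl, atoms)
    i <- i + 2L + n
    k <- k + 1L
  }
  trajectory(frames, source = path)
}

#' @rdname read_xyz
#' @param traj an [trajectory()] object.
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  out <- character(0)
  for (f in traj$frames) {
    a <- f$atoms
    out <- c(out, as.character(nrow(a)),
             sprintf("step = %d time = %.6f ps", f$step, f$time),
             sprintf("%-8s %16.8f %16.8f %16.8f", a$label, a$x, a$y, a$z))
  }
  writeLines(out, path)
  invisible(path)
}
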