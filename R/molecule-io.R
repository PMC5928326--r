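## Readers/writers for the external formats the toolkit consumes:
## GRO / XYZ coordinates, a GROMOS ITP topology subset, XVG-like observable
## tables, and CSV site reports. Coordinates are stored in nm throughout.

#' Construct a trajectory frame
#'
#' @param time Frame time in ps.
#' @param coordinates Numeric N x 3 matrix of positions, nm.
#' @param box Length-3 numeric vector of orthorhombic box edges, nm.
#' @return An object of class `trajectory_frame`.
#' @export
trajectory_frame <- function(time, coordinates, box) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L)
    stop("coordinates must be an N x 3 matrix")
  if (!all(is.finite(coordinates)))
    stop("coordinates must be finite")
  if (length(box) != 3L || any(box <= 0))
    stop("box must be 3 positive edge lengths (orthorhombic)")
  structure(list(time = time, coordinates = coordinates, box = as.numeric(box)),
            class = "trajectory_frame")
}

#' Read multi-frame coordinates from a GRO or XYZ file
#'
#' GRO positions are read as nm; XYZ positions are read as Angstrom and
#' converted to nm. Only orthorhombic boxes are supported: a GRO box line
#' with non-zero off-diagonal components is rejected.
#'
#' @param path Path to the coordinate file.
#' @param format Either `"gro"` or `"xyz"`.
#' @return A list of [trajectory_frame()] objects, in file order.
#' @export
read_coordinates <- function(path, format = c("gro", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  frames <- switch(format, gro = parse_gro(lines), xyz = parse_xyz(lines))
  n <- vapply(frames, function(f) nrow(f$coordinates), integer(1))
  if (length(unique(n)) > 1L)
    stop("inconsistent atom count across frames: ", paste(unique(n), collapse = ", "))
  frames
}

parse_gro <- function(lines) {
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    if (i + 1L > length(lines)) stop("truncated GRO file at line ", i)
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat < 1L)
      stop("GRO parse error at line ", i + 1L, ": expected atom count")
    if (i + 1L + nat + 1L > length(lines))
      stop("truncated GRO frame starting at line ", i)
    atom_lines <- lines[(i + 2L):(i + 1L + nat)]
    coords <- matrix(NA_real_, nat, 3L)
    for (k in seq_len(nat)) {
      ln <- atom_lines[k]
      if (nchar(ln) < 44L)
        stop("GRO parse error at line ", i + 1L + k, ": line too short")
      xyz <- suppressWarnings(as.numeric(c(substr(ln, 21, 28),
                                           substr(ln, 29, 36),
                                           substr(ln, 37, 44))))
      if (anyNA(xyz))
        stop("GRO parse error at line ", i + 1L + k, ": non-numeric coordinate")
      coords[k, ] <- xyz
    }
    box_fields <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 2L + nat]),
                                                       "\\s+")[[1]]))
    if (anyNA(box_fields) || !(length(box_fields) %in% c(3L, 9L)))
      stop("GRO parse error at line ", i + 2L + nat, ": malformed box line")
    if (length(box_fields) == 9L && any(abs(box_fields[4:9]) > 1e-12))
      stop("triclinic boxes are not supported")
    time <- gro_title_time(title)
    frames[[length(frames) + 1L]] <-
      trajectory_frame(time, coords, box_fields[1:3])
    i <- i + nat + 3L
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (!length(frames)) stop("no frames found in GRO input")
  frames
}

gro_title_time <- function(title) {
  m <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
  if (length(m) == 2L) as.numeric(m[2]) else 0
}

parse_xyz <- function(lines) {
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L)
      stop("XYZ parse error at line ", i, ": expected atom count")
    if (i + 1L + nat > length(lines)) stop("truncated XYZ frame at line ", i)
    coords <- matrix(NA_real_, nat, 3L)
    for (k in seq_len(nat)) {
      f <- strsplit(trimws(lines[i + 1L + k]), "\\s+")[[1]]
      if (length(f) < 4L)
        stop("XYZ parse error at line ", i + 1L + k, ": expected element + 3 coordinates")
      xyz <- suppressWarnings(as.numeric(f[2:4]))
      if (anyNA(xyz))
        stop("XYZ parse error at line ", i + 1L + k, ": non-numeric coordinate")
      coords[k, ] <- xyz / 10  # Angstrom -> nm
    }
    ## XYZ carries no box; a generous bounding cube keeps downstream code valid
    ext <- apply(coords, 2, function(v) diff(range(v)))
    box <- pmax(ext + 2, 2)
    frames[[length(frames) + 1L]] <- trajectory_frame(0, coords, box)
    i <- i + nat + 2L
  }
  if (!length(frames)) stop("no frames found in XYZ input")
  frames
}

#' Write frames to a GRO or XYZ file
#'
#' Inverse of [read_coordinates()] (round-trips within format precision;
#' GRO stores 3 decimals in nm, XYZ is written at full precision in Angstrom).
#'
#' @param frames List of [trajectory_frame()] objects.
#' @param path Output path.
#' @param format `"gro"` or `"xyz"`.
#' @param atom_names Optional character vector of atom names (GRO) or
#'   element symbols (XYZ); recycled defaults are used otherwise.
#' @export
write_coordinates <- function(frames, path, format = c("gro", "xyz"),
                              atom_names = NULL) {
  format <- match.arg(format)
  if (inherits(frames, "trajectory_frame")) frames <- list(frames)
  out <- character(0)
  for (fr in frames) {
    nat <- nrow(fr$coordinates)
    nm <- if (is.null(atom_names)) rep("X", nat) else rep_len(atom_names, nat)
    if (format == "gro") {
      hdr <- sprintf("frame t= %.4f", fr$time)
      body <- vapply(seq_len(nat), function(k)
        sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1L, "MOL", nm[k],
                k %% 100000L, fr$coordinates[k, 1],
                fr$coordinates[k, 2], fr$coordinates[k, 3]),
        character(1))
      box <- sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3])
      out <- c(out, hdr, as.character(nat), body, box)
    } else {
      body <- vapply(seq_len(nat), function(k)
        sprintf("%s %.8f %.8f %.8f", nm[k], 10 * fr$coordinates[k, 1],
                10 * fr$coordinates[k, 2], 10 * fr$coordinates[k, 3]),
        character(1))
      out <- c(out, as.character(nat), sprintf("t= %.4f", fr$time), body)
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Construct a molecular topology
#'
#' Atoms carry 1-based indices, partial charges (e), charge-group ids and
#' masses (u); positions (nm) are optional until coordinates are attached.
#' Charge-sum invariants (total charge equal to `net_charge`, each charge
#' group summing to an integer, both within 1e-6 e) are checked and reported
#' as warnings so that mid-fit, non-integral inputs can still be handled.
#'
#' @param name Molecule name.
#' @param atoms data.frame with columns `index`, `name`, `charge`,
#'   `charge_group`, `mass`, and optionally `x`, `y`, `z` (nm).
#' @param bonds Two-column matrix of 1-based atom indices (may be empty).
#' @param dihedrals data.frame with columns `ai`, `aj`, `ak`, `al` and
#'   optionally `param_id` (may be empty).
#' @param net_charge Integer net charge in e.
#' @return An object of class `molecule_topology`.
#' @export
molecule_topology <- function(name, atoms, bonds = NULL, dihedrals = NULL,
                              net_charge = 0L) {
  atoms <- as.data.frame(atoms)
  req <- c("index", "name", "charge", "charge_group", "mass")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$index)) stop("atom indices must be unique")
  if (!is.null(bonds) && length(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2L)
    if (!all(bonds %in% atoms$index))
      stop("bond indices reference non-existent atoms")
  } else bonds <- matrix(integer(0), ncol = 2L)
  if (is.null(dihedrals))
    dihedrals <- data.frame(ai = integer(0), aj = integer(0),
                            ak = integer(0), al = integer(0))
  qtot <- sum(atoms$charge)
  if (abs(qtot - net_charge) > 1e-6)
    warning(sprintf("total charge %.6f differs from declared net charge %d",
                    qtot, net_charge))
  gs <- tapply(atoms$charge, atoms$charge_group, sum)
  off <- abs(gs - round(gs)) > 1e-6
  if (any(off))
    warning("charge group(s) not summing to an integer: ",
            paste(names(gs)[off], collapse = ", "))
  structure(list(name = name, atoms = atoms, bonds = bonds,
                 dihedrals = as.data.frame(dihedrals),
                 net_charge = as.integer(net_charge)),
            class = "molecule_topology")
}

#' @export
print.molecule_topology <- function(x, ...) {
  cat(sprintf("molecule_topology '%s': %d atoms, %d bonds, %d dihedrals, net charge %+d e\n",
              x$name, nrow(x$atoms), nrow(x$bonds), nrow(x$dihedrals),
              x$net_charge))
  cat(sprintf("  charge groups: %d\n", length(unique(x$atoms$charge_group))))
  invisible(x)
}

#' Attach coordinates from a trajectory frame to a topology
#'
#' @param molecule A [molecule_topology()].
#' @param frame A [trajectory_frame()] with one row per atom.
#' @return The topology with `x`, `y`, `z` columns (nm) filled in.
#' @export
set_coordinates <- function(molecule, frame) {
  if (nrow(frame$coordinates) != nrow(molecule$atoms))
    stop("frame has ", nrow(frame$coordinates), " atoms but topology has ",
         nrow(molecule$atoms))
  molecule$atoms[, c("x", "y", "z")] <- frame$coordinates
  molecule
}

#' Read a GROMOS-style ITP topology subset
#'
#' Parses the `[atoms]` (with the charge-group `cgnr` column), `[bonds]` and
#' `[dihedrals]` sections; everything else is ignored. Charge-sum invariant
#' violations are warnings, not errors.
#'
#' @param path Path to the ITP file.
#' @return A [molecule_topology()].
#' @export
read_topology_subset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- sub(";.*$", "", readLines(path))
  sec <- NA_character_
  name <- sub("\\.itp$", "", basename(path))
  atoms <- list(); bonds <- list(); dihedrals <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    m <- regmatches(ln, regexec("^\\[\\s*([A-Za-z]+)\\s*\\]$", ln))[[1]]
    if (length(m) == 2L) { sec <- tolower(m[2]); next }
    f <- strsplit(ln, "\\s+")[[1]]
    if (is.na(sec)) next
    if (sec == "moleculetype") {
      name <- f[1]
    } else if (sec == "atoms") {
      if (length(f) < 8L)
        stop("ITP parse error at line ", i, ": [atoms] needs 8 fields ",
             "(nr type resnr residue atom cgnr charge mass)")
      atoms[[length(atoms) + 1L]] <- data.frame(
        index = as.integer(f[1]), type = f[2], name = f[5],
        charge_group = as.integer(f[6]), charge = as.numeric(f[7]),
        mass = as.numeric(f[8]))
    } else if (sec == "bonds") {
      bonds[[length(bonds) + 1L]] <- as.integer(f[1:2])
    } else if (sec == "dihedrals") {
      if (length(f) < 4L)
        stop("ITP parse error at line ", i, ": [dihedrals] needs 4 atom indices")
      dihedrals[[length(dihedrals) + 1L]] <- data.frame(
        ai = as.integer(f[1]), aj = as.integer(f[2]),
        ak = as.integer(f[3]), al = as.integer(f[4]),
        param_id = if (length(f) >= 5L) f[5] else NA_character_)
    }
  }
  if (!length(atoms)) stop("ITP format error: missing [atoms] section")
  atoms <- do.call(rbind, atoms)
  bonds <- if (length(bonds)) do.call(rbind, bonds) else NULL
  dihedrals <- if (length(dihedrals)) do.call(rbind, dihedrals) else NULL
  molecule_topology(name, atoms, bonds, dihedrals,
                    net_charge = round(sum(atoms$charge)))
}

#' Write the ITP subset understood by [read_topology_subset()]
#'
#' @param molecule A [molecule_topology()].
#' @param path Output path.
#' @export
write_topology_subset <- function(molecule, path) {
  a <- molecule$atoms
  type <- if ("type" %in% names(a)) a$type else a$name
  out <- c("[ moleculetype ]",
           sprintf("%s 3", molecule$name),
           "", "[ atoms ]",
           ";  nr type resnr residue atom cgnr    charge      mass",
           sprintf("%4d %-5s 1 MOL %-5s %4d %10.6f %9.4f",
                   a$index, type, a$name, a$charge_group, a$charge, a$mass))
  if (nrow(molecule$bonds)) {
    out <- c(out, "", "[ bonds ]",
             sprintf("%4d %4d 2", molecule$bonds[, 1], molecule$bonds[, 2]))
  }
  if (nrow(molecule$dihedrals)) {
    d <- molecule$dihedrals
    pid <- if ("param_id" %in% names(d)) ifelse(is.na(d$param_id), "", d$param_id) else ""
    out <- c(out, "", "[ dihedrals ]",
             trimws(sprintf("%4d %4d %4d %4d %s", d$ai, d$aj, d$ak, d$al, pid)))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read an XVG-like observable table
#'
#' Lines starting with `#` or `@` are skipped; remaining lines are parsed as
#' whitespace-separated numeric columns, the first being time (ps). Ragged
#' rows raise an error; every data row in the file appears in the output.
#'
#' @param path Path to the file.
#' @param col_names Optional column names (first column is time).
#' @return A data.frame of class `observable_table` whose first column is
#'   `time`.
#' @export
read_observable_table <- function(path, col_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  data_lines <- lines[keep]
  if (!length(data_lines)) stop("empty data section in ", path)
  rows <- strsplit(trimws(data_lines), "\\s+")
  ncols <- lengths(rows)
  if (length(unique(ncols)) > 1L) {
    bad <- which(keep)[which(ncols != ncols[1])[1]]
    stop("ragged row at line ", bad, ": expected ", ncols[1], " fields")
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) stop("non-numeric value in data section of ", path)
  tab <- as.data.frame(matrix(vals, ncol = ncols[1], byrow = TRUE))
  if (is.null(col_names)) col_names <- c("time", paste0("V", seq_len(ncols[1] - 1L)))
  names(tab) <- rep_len(col_names, ncols[1])
  if (is.unsorted(tab[[1]])) stop("rows are not time-ordered")
  class(tab) <- c("observable_table", "data.frame")
  tab
}

#' Write an observable table in XVG-like form
#'
#' @param tab A data.frame (first column time, ps).
#' @param path Output path.
#' @param title Optional title written as an `@` comment.
#' @export
write_observable_table <- function(tab, path, title = NULL) {
  out <- character(0)
  if (!is.null(title)) out <- sprintf("@ title \"%s\"", title)
  body <- apply(as.data.frame(tab), 1L,
                function(r) paste(sprintf("%.10g", as.numeric(r)), collapse = "  "))
  writeLines(c(out, body), path)
  invisible(path)
}

## Column order of the per-site hydration report (Tables-style layout).
report_columns <- c("Molecule", "Atom", "Aver_HB", "Aver_HB_sd", "tau_HB",
                    "tau_HB_sd", "lifetime_HB", "dG_HB", "dG_HB_sd",
                    "Percent", "CN", "CN_sd", "OBD_HB", "OBD_HB_sd",
                    "Orientation")

#' Write / read a per-site hydration report as CSV
#'
#' Column layout follows the standard per-site summary: molecule, site atom,
#' mean H-bond count, residence time tau (ps), lifetime (1/ps), breakage free
#' energy (kJ/mol), occupancy percent, coordination number, optimal binding
#' distance (nm) and water orientation class. Sites with insufficient
#' sampling carry `NA` in the kinetic columns (rendered as empty cells).
#'
#' @param rows data.frame with (a subset of) the report columns.
#' @param path Output path.
#' @export
write_report <- function(rows, path) {
  rows <- as.data.frame(rows)
  for (cn in setdiff(report_columns, names(rows))) rows[[cn]] <- NA
  utils::write.csv(rows[, report_columns], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_report
#' @return `read_report()` returns the report as a data.frame.
#' @export
read_report <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
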