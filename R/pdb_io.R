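# Fixed-column PDB and GRO coordinate I/O.  The reader keeps names exactly
# as found (dialect is detected, not silently normalized); the writer can
# emit either dialect.  Coordinates are Angstrom internally; GRO files are
# nanometre and are converted on read.

.parse_pdb_atoms <- function(lines, lineno, path = "") {
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (!length(lines))
    return(NULL)
  num <- function(txt, what) {
    out <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(out) & nzchar(trimws(txt)))
    if (!length(bad)) bad <- which(is.na(out))
    if (length(bad))
      stop("malformed ATOM record (bad ", what, ") at line ",
           lineno[bad[1]], if (nzchar(path)) paste0(" of ", path))
    out
  }
  atoms <- data.frame(
    serial = as.integer(num(substr(lines, 7, 11), "serial")),
    name = trimws(substr(lines, 13, 16)),
    alt = trimws(substr(lines, 17, 17)),
    resid = trimws(substr(lines, 18, 21)),
    chain = substr(lines, 22, 22),
    resno = as.integer(num(substr(lines, 23, 26), "residue number")),
    ins = trimws(substr(lines, 27, 27)),
    x = num(substr(lines, 31, 38), "x"),
    y = num(substr(lines, 39, 46), "y"),
    z = num(substr(lines, 47, 54), "z"),
    element = trimws(substr(lines, 77, 78)),
    stringsAsFactors = FALSE)
  drop <- !(atoms$alt %in% c("", "A"))
  if (any(drop)) {
    warning("dropping ", sum(drop), " atom(s) with alternate location other ",
            "than blank/'A'")
    atoms <- atoms[!drop, , drop = FALSE]
  }
  atoms$alt <- NULL
  blank <- !nzchar(atoms$element)
  atoms$element[blank] <- derive_element(atoms$name[blank])
  atoms
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records from the fixed PDB columns.  Only the first
#' MODEL of a multi-model file is read (use [read_trajectory] for frame
#' series).  Alternate-location indicators other than blank or `'A'` are
#' dropped with a warning; insertion codes are retained.
#'
#' @param path path to a PDB file.
#' @param dialect `"auto"` (detect from the names found), `"pdbv3"` or
#'   `"pdbv2"`; when a concrete dialect is given the structure is
#'   normalized to it after reading.
#' @return a [nuc_structure].
#' @export
read_pdb <- function(path, dialect = c("auto", "pdbv3", "pdbv2")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  endmdl <- which(substr(lines, 1, 6) == "ENDMDL")
  if (length(endmdl)) {
    lines <- lines[seq_len(endmdl[1])]
    lineno <- lineno[seq_len(endmdl[1])]
  }
  title <- trimws(sub("^TITLE ", "",
                      lines[substr(lines, 1, 6) == "TITLE "][1] %||% ""))
  if (is.na(title)) title <- ""
  atoms <- .parse_pdb_atoms(lines, lineno, path)
  if (is.null(atoms))
    stop("no ATOM/HETATM records in ", path)
  s <- nuc_structure(atoms, title = title, dialect = "pdbv3")
  s$dialect <- detect_dialect(s)
  if (dialect != "auto" && dialect != s$dialect)
    s <- as_dialect(s, dialect)
  s
}

.format_atom_name <- function(name) {
  # element symbols of one letter start in column 14; 4-character names
  # use the full field
  ifelse(nchar(name) >= 4, substr(name, 1, 4),
         sprintf(" %-3s", name))
}

.pdb_atom_lines <- function(atoms) {
  sprintf("ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$serial %% 100000L,
          .format_atom_name(atoms$name),
          atoms$resid, atoms$chain, atoms$resno,
          ifelse(nzchar(atoms$ins), atoms$ins, " "),
          atoms$x, atoms$y, atoms$z, 1, 0, atoms$element)
}

.pdb_body <- function(s) {
  a <- s$atoms
  out <- character(0)
  serial <- 0L
  for (ch in unique(a$chain)) {
    sub <- a[a$chain == ch, , drop = FALSE]
    sub$serial <- serial + seq_len(nrow(sub))
    serial <- serial + nrow(sub) + 1L
    last <- sub[nrow(sub), ]
    ter <- sprintf("TER   %5d      %-3s %1s%4d", serial, last$resid,
                   last$chain, last$resno)
    out <- c(out, .pdb_atom_lines(sub), ter)
  }
  out
}

#' Write a structure to a PDB file
#'
#' Emits standard fixed-column ATOM records with a TER record per chain and
#' a terminating END.  Coordinates round-trip at PDB precision (3 decimal
#' places).
#'
#' @param s a non-empty [nuc_structure].
#' @param path output file path.
#' @param dialect target naming dialect (default: the structure's own).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path, dialect = NULL) {
  stopifnot(inherits(s, "nuc_structure"))
  if (n_atoms(s) == 0L) stop("refusing to write an empty structure")
  if (!is.null(dialect) && dialect != s$dialect) s <- as_dialect(s, dialect)
  if (any(nchar(s$atoms$name) > 4))
    stop("atom name longer than 4 characters: ",
         s$atoms$name[which(nchar(s$atoms$name) > 4)[1]])
  lines <- c(if (nzchar(s$title)) sprintf("TITLE     %s", s$title),
             .pdb_body(s), "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame; frame times (ns) are recorded in
#' `REMARK` lines that [read_trajectory] understands.
#'
#' @param traj a [nuc_trajectory].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "nuc_trajectory"))
  s <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  if (nzchar(s$title)) writeLines(sprintf("TITLE     %s", s$title), con)
  for (i in seq_len(n_frames(traj))) {
    coords(s) <- frame_coords(traj, i)
    writeLines(c(sprintf("MODEL     %4d", i),
                 sprintf("REMARK    time= %.6f ns", traj$times[i]),
                 .pdb_body(s), "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

# extract a time stamp (ns) from header lines of one model/frame block;
# understands "time= <x> ns" remarks and GROMACS-style "t= <x>" (ps)
.header_time <- function(lines) {
  m <- regmatches(lines, regexpr("time= *[-0-9.eE+]+", lines))
  if (length(m)) return(as.numeric(sub("time= *", "", m[1])))
  m <- regmatches(lines, regexpr("t= *[-0-9.eE+]+", lines))
  if (length(m)) return(as.numeric(sub("t= *", "", m[1])) / 1000)  # ps -> ns
  NA_real_
}

#' Read a GRO coordinate file
#'
#' Reads the first frame of a GROMACS .gro file.  Coordinates are converted
#' from nanometre to Angstrom.
#'
#' @param path path to a .gro file.
#' @return a [nuc_structure].
#' @export
read_gro <- function(path) {
  fr <- .read_gro_frames(path, first_only = TRUE)
  fr$structures[[1]]
}

.read_gro_frames <- function(path, first_only = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  structures <- list()
  times <- numeric(0)
  i <- 1L
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    title <- lines[i]
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat)) stop("malformed GRO atom count at line ", i + 1L)
    if (i + 1L + nat + 1L > length(lines))
      stop("truncated GRO frame starting at line ", i)
    al <- lines[i + 1L + seq_len(nat)]
    atoms <- data.frame(
      serial = as.integer(substr(al, 16, 20)),
      name = trimws(substr(al, 11, 15)),
      resid = trimws(substr(al, 6, 10)),
      chain = "A",
      resno = as.integer(substr(al, 1, 5)),
      ins = "",
      x = as.numeric(substr(al, 21, 28)) * 10,
      y = as.numeric(substr(al, 29, 36)) * 10,
      z = as.numeric(substr(al, 37, 44)) * 10,
      stringsAsFactors = FALSE)
    if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z))
      stop("malformed GRO coordinate line in frame starting at line ", i)
    atoms$element <- derive_element(atoms$name)
    s <- nuc_structure(atoms, title = trimws(title), dialect = "pdbv3")
    s$dialect <- detect_dialect(s)
    structures[[length(structures) + 1L]] <- s
    times <- c(times, .header_time(title))
    i <- i + 1L + nat + 2L  # title + count + atoms + box line
    if (first_only) break
  }
  if (!length(structures)) stop("no frames found in ", path)
  list(structures = structures, times = times)
}

#' Read a trajectory from a multi-model PDB or concatenated GRO file
#'
#' The topology file provides atom identities; the trajectory file provides
#' one coordinate frame per MODEL block (PDB) or per concatenated frame
#' (GRO, nm converted to Angstrom).  Frame times are taken from header
#' remarks when present (`time= <ns>` or GROMACS `t= <ps>`), otherwise the
#' frame index (0, 1, 2, ... ns) is used.
#'
#' @param topology_path PDB file defining the topology.
#' @param traj_path multi-model PDB or GRO file; format chosen by file
#'   extension (`.gro`) or content.
#' @return a [nuc_trajectory].
#' @export
read_trajectory <- function(topology_path, traj_path) {
  topo <- read_pdb(topology_path)
  nat <- n_atoms(topo)
  if (grepl("\\.gro$", traj_path, ignore.case = TRUE)) {
    fr <- .read_gro_frames(traj_path)
    mats <- lapply(fr$structures, coords)
    counts <- vapply(mats, nrow, integer(1))
    bad <- which(counts != nat)
    if (length(bad))
      stop("frame ", bad[1], " has ", counts[bad[1]], " atoms; topology has ", nat)
    times <- fr$times
  } else {
    lines <- readLines(traj_path, warn = FALSE)
    starts <- which(substr(lines, 1, 5) == "MODEL")
    ends <- which(substr(lines, 1, 6) == "ENDMDL")
    if (length(starts) == 0L) {
      starts <- 1L
      ends <- length(lines)
    }
    if (length(starts) != length(ends))
      stop("unbalanced MODEL/ENDMDL records in ", traj_path)
    mats <- vector("list", length(starts))
    times <- rep(NA_real_, length(starts))
    for (k in seq_along(starts)) {
      block <- lines[starts[k]:ends[k]]
      blockno <- starts[k]:ends[k]
      atoms <- .parse_pdb_atoms(block, blockno, traj_path)
      if (is.null(atoms) || nrow(atoms) != nat)
        stop("frame ", k, " has ", if (is.null(atoms)) 0 else nrow(atoms),
             " atoms; topology has ", nat)
      mats[[k]] <- as.matrix(atoms[, c("x", "y", "z")])
      times[k] <- .header_time(block)
    }
  }
  if (anyNA(times)) times <- seq_along(mats) - 1
  arr <- array(NA_real_, dim = c(length(mats), nat, 3))
  for (k in seq_along(mats)) arr[k, , ] <- mats[[k]]
  nuc_trajectory(topo, arr, times)
}
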