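# Hierarchical coordinate model: a structure is a flat atom table (one row
# per atom) carrying chain / residue grouping, plus a title and the active
# atom-naming dialect.  This mirrors how single-stranded aptamer models are
# exchanged in practice (single-chain PDB files, heavy atoms with or
# without hydrogens).

#' Construct a nucleic-acid structure
#'
#' @param atoms data frame with columns `serial` (integer, unique),
#'   `name` (PDB atom name), `element` (symbol), `resid` (residue code),
#'   `chain` (single character), `resno` (integer residue number), `ins`
#'   (insertion code, `""` when absent), and coordinates `x`, `y`, `z` in
#'   Angstrom.
#' @param title free-text title.
#' @param dialect atom-naming dialect, `"pdbv3"` or `"pdbv2"`.
#' @return an object of class `nuc_structure`.
#' @details Invariants enforced: finite coordinates, unique atom serials,
#'   unique atom names within each residue, and strictly increasing residue
#'   numbers within each chain.
#' @export
nuc_structure <- function(atoms, title = "", dialect = "pdbv3") {
  need <- c("serial", "name", "element", "resid", "chain", "resno",
            "ins", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms)[need]
  atoms$serial <- as.integer(atoms$serial)
  atoms$resno <- as.integer(atoms$resno)
  if (nrow(atoms)) {
    if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
      stop("non-finite coordinates in atom table")
    if (anyDuplicated(atoms$serial))
      stop("atom serials are not unique")
    key <- residue_key(atoms)
    if (anyDuplicated(paste(key, atoms$name)))
      stop("duplicated atom name within a residue")
    for (ch in unique(atoms$chain)) {
      rn <- atoms$resno[atoms$chain == ch]
      rn <- rn[c(TRUE, diff(rn) != 0)]
      if (any(diff(unique(rn)) <= 0) || any(diff(rn) < 0))
        stop("residue numbers not strictly increasing within chain ", ch)
    }
  }
  structure(list(atoms = atoms, title = title, dialect = dialect),
            class = "nuc_structure")
}

residue_key <- function(atoms) paste(atoms$chain, atoms$resno, atoms$ins)

#' Number of atoms in a structure
#' @param s a [nuc_structure].
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Number of residues in a structure
#' @param s a [nuc_structure].
#' @export
n_residues <- function(s) length(unique(residue_key(s$atoms)))

#' Coordinates of a structure as an N x 3 matrix (Angstrom)
#' @param s a [nuc_structure].
#' @export
coords <- function(s) {
  unname(as.matrix(s$atoms[, c("x", "y", "z")]))
}

`coords<-` <- function(s, value) {
  stopifnot(nrow(value) == nrow(s$atoms), ncol(value) == 3)
  s$atoms$x <- value[, 1]
  s$atoms$y <- value[, 2]
  s$atoms$z <- value[, 3]
  s
}

# split atom row indices by residue, preserving file order
residue_indices <- function(atoms) {
  key <- residue_key(atoms)
  split(seq_len(nrow(atoms)), factor(key, levels = unique(key)))
}

# one row per residue: code, chain, resno, ins
residue_table <- function(s) {
  a <- s$atoms
  idx <- vapply(residue_indices(a), `[`, integer(1), 1L)
  data.frame(resid = a$resid[idx], chain = a$chain[idx],
             resno = a$resno[idx], ins = a$ins[idx],
             stringsAsFactors = FALSE)
}

.base_kind_map <- c(A = "adenine", DA = "adenine",
                    C = "cytosine", DC = "cytosine",
                    G = "guanine", DG = "guanine",
                    U = "uracil",
                    T = "thymine", DT = "thymine")

#' Base identity of a residue code
#'
#' @param code residue code(s) in either dialect (`A`, `U`, `DT`, ...).
#' @return one of `"adenine"`, `"cytosine"`, `"guanine"`, `"uracil"`,
#'   `"thymine"`, or `NA` for unknown codes.
#' @export
base_kind <- function(code) {
  unname(.base_kind_map[code])
}

.seq_letter <- c(A = "A", DA = "A", C = "C", DC = "C", G = "G", DG = "G",
                 U = "U", T = "T", DT = "T")

#' Nucleotide sequence of a structure
#'
#' Returns the 5'-to-3' single-letter sequence, using `U` for uracil and
#' `T` for thymine regardless of the naming dialect.
#'
#' @param s a [nuc_structure].
#' @return a single character string (empty for an empty structure).
#' @export
sequence_of <- function(s) {
  stopifnot(inherits(s, "nuc_structure"))
  if (n_atoms(s) == 0L) return("")
  codes <- residue_table(s)$resid
  letters <- .seq_letter[codes]
  if (anyNA(letters)) {
    bad <- unique(codes[is.na(letters)])
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  }
  paste(letters, collapse = "")
}

# renumber serials 1..N after editing operations
renumber_serials <- function(s) {
  s$atoms$serial <- seq_len(nrow(s$atoms))
  s
}

#' @export
print.nuc_structure <- function(x, ...) {
  a <- x$atoms
  cat("nuc_structure:", n_atoms(x), "atoms,", n_residues(x), "residues,",
      length(unique(a$chain)), "chain(s), dialect", x$dialect, "\n")
  if (nzchar(x$title)) cat("  title:", x$title, "\n")
  if (n_atoms(x)) {
    sq <- tryCatch(sequence_of(x), error = function(e) NULL)
    if (!is.null(sq) && nzchar(sq))
      cat("  sequence: ",
          if (nchar(sq) > 60) paste0(substr(sq, 1, 60), "...") else sq,
          "\n", sep = "")
    cat("  hydrogens:", if (any(a$element == "H")) "present" else "absent",
        "\n")
  }
  invisible(x)
}

#' Construct a trajectory
#'
#' @param topology a [nuc_structure] shared by all frames.
#' @param coords numeric array of dimension `n_frames x n_atoms x 3`
#'   (Angstrom), atom ordering as in the topology.
#' @param times frame times in nanoseconds, strictly increasing,
#'   non-negative.
#' @return an object of class `nuc_trajectory`.
#' @export
nuc_trajectory <- function(topology, coords, times) {
  stopifnot(inherits(topology, "nuc_structure"))
  if (length(dim(coords)) != 3 || dim(coords)[2] != n_atoms(topology) ||
      dim(coords)[3] != 3)
    stop("coords must be an n_frames x n_atoms x 3 array matching the topology")
  if (length(times) != dim(coords)[1])
    stop("times length must equal the number of frames")
  if (any(times < 0) || any(diff(times) <= 0) && length(times) > 1)
    stop("frame times must be non-negative and strictly increasing")
  structure(list(topology = topology, coords = coords, times = as.numeric(times)),
            class = "nuc_trajectory")
}

#' Number of frames in a trajectory
#' @param traj a [nuc_trajectory].
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

# coordinates of frame i as an N x 3 matrix
frame_coords <- function(traj, i) {
  matrix(traj$coords[i, , ], ncol = 3)
}

#' @export
print.nuc_trajectory <- function(x, ...) {
  cat("nuc_trajectory:", n_frames(x), "frames x", n_atoms(x$topology),
      "atoms; time", min(x$times), "-", max(x$times), "ns\n")
  invisible(x)
}

#' Printed aptamer sequences used as in-package fixtures
#'
#' The two parent ssRNA aptamer sequences (A6, A11; 60 nt each, selected
#' against PC-3 prostate-cancer cells) and their published ssDNA versions
#' (LN-A6, LN-A11).  Note that the published LN-A11 string has 57 nt: it
#' omits the `CCT` triplet that a strict per-residue U-to-T substitution of
#' A11 produces.  This package performs strict substitution and never
#' deletes residues, so `convert_sequence(aptamer_sequences()["A11"])`
#' differs from the published LN-A11 at that triplet.
#'
#' @return named character vector with elements `A6`, `A11`, `LN_A6`,
#'   `LN_A11`.
#' @examples
#' convert_sequence(aptamer_sequences()[["A6"]]) == aptamer_sequences()[["LN_A6"]]
#' @export
aptamer_sequences <- function() {
  c(A6     = "CCGCAUCGUCCCAAGCCGAUUUUGGCGAGCAGCAGACAGGUUCCGGGGCGAGCAGCAGAC",
    A11    = "CGAUGCGGAAUAGGGGCCAGGCGUAUCUGAGCUCCUAUUCUCUUUGUCCCGUCUGCUGCU",
    LN_A6  = "CCGCATCGTCCCAAGCCGATTTTGGCGAGCAGCAGACAGGTTCCGGGGCGAGCAGCAGAC",
    LN_A11 = "CGATGCGGAATAGGGGCCAGGCGTATCTGAGCTATTCTCTTTGTCCCGTCTGCTGCT")
}
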