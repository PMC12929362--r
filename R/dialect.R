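# Atom/residue naming dialects.  Modern PDB (v3) names sugar atoms with a
# prime ("O2'") and phosphate oxygens OP1/OP2, and uses two-letter DNA
# residue codes (DA/DC/DG/DT).  The legacy dialect (v2, still emitted by
# several modelling tools) uses an asterisk ("O2*"), O1P/O2P, and
# single-letter residue codes for both RNA and DNA.  The mapping below is a
# bijection on the covered names; anything outside it passes through
# unchanged (with a warning for unrecognized residue codes).

.op_v3_to_v2 <- c("OP1" = "O1P", "OP2" = "O2P", "OP3" = "O3P")

#' Translate PDB atom names between naming dialects
#'
#' @param name character vector of atom names.
#' @param to target dialect, `"pdbv3"` or `"pdbv2"`.
#' @return character vector of translated names.
#' @examples
#' atom_name_to_dialect(c("O2'", "OP1"), "pdbv2")
#' @export
atom_name_to_dialect <- function(name, to = c("pdbv3", "pdbv2")) {
  to <- match.arg(to)
  if (to == "pdbv2") {
    hit <- name %in% names(.op_v3_to_v2)
    name[hit] <- .op_v3_to_v2[name[hit]]
    gsub("'", "*", name, fixed = TRUE)
  } else {
    v2 <- names(.op_v3_to_v2)
    names(v2) <- unname(.op_v3_to_v2)
    hit <- name %in% names(v2)
    name[hit] <- v2[name[hit]]
    gsub("*", "'", name, fixed = TRUE)
  }
}

# Residue code translation.  v2 -> v3 needs to know whether an ambiguous
# single-letter code is DNA; the caller passes `is_dna` per residue
# (typically inferred from the absence of an O2'/O2* atom).
residue_code_to_dialect <- function(code, to = c("pdbv3", "pdbv2"),
                                    is_dna = NULL) {
  to <- match.arg(to)
  if (to == "pdbv2") {
    map <- c(DA = "A", DC = "C", DG = "G", DT = "T")
    hit <- code %in% names(map)
    code[hit] <- map[code[hit]]
    code
  } else {
    if (is.null(is_dna)) is_dna <- rep(FALSE, length(code))
    out <- code
    out[code == "T"] <- "DT"
    amb <- code %in% c("A", "C", "G") & is_dna
    out[amb] <- paste0("D", code[amb])
    out
  }
}

.known_residues <- c("A", "C", "G", "U", "T", "DA", "DC", "DG", "DT")

#' Detect the atom-naming dialect of a structure
#'
#' A structure is classed legacy (`"pdbv2"`) if any atom name contains an
#' asterisk or any residue uses the bare code `T`; otherwise `"pdbv3"`.
#'
#' @param s a [nuc_structure].
#' @return `"pdbv3"` or `"pdbv2"`.
#' @export
detect_dialect <- function(s) {
  a <- s$atoms
  if (any(grepl("*", a$name, fixed = TRUE)) || any(a$resid == "T"))
    "pdbv2"
  else
    "pdbv3"
}

#' Convert a structure to a naming dialect
#'
#' Translates atom names and residue codes; names outside the dialect
#' tables pass through unchanged (unknown residue codes trigger a warning).
#' The mapping is involutive on the covered name set.
#'
#' @param s a [nuc_structure].
#' @param to `"pdbv3"` or `"pdbv2"`.
#' @return the structure, renamed, with its `dialect` field updated.
#' @export
as_dialect <- function(s, to = c("pdbv3", "pdbv2")) {
  to <- match.arg(to)
  stopifnot(inherits(s, "nuc_structure"))
  a <- s$atoms
  unknown <- setdiff(unique(a$resid), .known_residues)
  if (length(unknown))
    warning("unrecognized residue code(s) pass through unchanged: ",
            paste(unknown, collapse = ", "))
  a$name <- atom_name_to_dialect(a$name, to)
  if (to == "pdbv3") {
    # a residue is DNA when it lacks a 2'-oxygen
    key <- residue_key(a)
    has_o2 <- tapply(a$name %in% c("O2'", "O2*"), key, any)
    a$resid <- residue_code_to_dialect(a$resid, "pdbv3",
                                       is_dna = !as.vector(has_o2[key]))
  } else {
    a$resid <- residue_code_to_dialect(a$resid, "pdbv2")
  }
  s$atoms <- a
  s$dialect <- to
  s
}
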