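# The ssRNA -> ssDNA conversion algorithm: three sequential edits that
# preserve the parent conformation exactly.  (I) delete the ribose
# 2'-hydroxyl (O2' and its hydroxyl hydrogen) to obtain deoxyribose;
# (II) replace the uracil H5 with a methyl carbon C7 built in the base
# plane at the exterior position H5 occupied, turning uracil into
# thymine; (III) rename residues to standard DNA codes.  No retained atom
# ever moves, so the superposition RMSD between parent and product over
# shared atoms is exactly zero.

#' Methyl-construction geometry parameters
#'
#' Geometry used when building the thymine methyl group: the C5-C7 bond
#' length, the C-H bond length of the three methyl hydrogens, the H-C-H
#' tetrahedral angle, and the tolerance beyond which a uracil ring is
#' flagged non-planar (the methyl is then placed using the best-fit ring
#' plane).
#'
#' @param c5_c7_bond C5-C7 bond length, Angstrom (default 1.50, the
#'   standard thymine value).
#' @param c_h_bond methyl C-H bond length, Angstrom (default 1.09).
#' @param hch_angle H-C-H angle, degrees (default 109.5).
#' @param coplanarity_tol maximum out-of-plane ring deviation tolerated
#'   without warning, Angstrom (default 0.15).
#' @return an object of class `methyl_geometry`.
#' @export
methyl_geometry <- function(c5_c7_bond = 1.50, c_h_bond = 1.09,
                            hch_angle = 109.5, coplanarity_tol = 0.15) {
  stopifnot(c5_c7_bond > 0, c_h_bond > 0,
            hch_angle > 90, hch_angle < 120, coplanarity_tol > 0)
  structure(list(c5_c7_bond = c5_c7_bond, c_h_bond = c_h_bond,
                 hch_angle = hch_angle, coplanarity_tol = coplanarity_tol),
            class = "methyl_geometry")
}

.empty_fragment <- function() {
  list(removed_atoms = data.frame(residue = character(0), atom = character(0)),
       added_atoms = data.frame(residue = character(0), atom = character(0)),
       renamed_residues = data.frame(residue = character(0),
                                     old = character(0), new = character(0)))
}

.residue_id <- function(chain, resno, ins = "") {
  paste0(chain, ":", resno, ifelse(nzchar(ins), ins, ""))
}

#' Remove the 2'-hydroxyl from every ribose
#'
#' Deletes the `O2'` atom (and its hydroxyl hydrogen `HO2'`/`HO'2`/`2HO'`,
#' when present) from every residue, converting ribose to deoxyribose.
#' All other atoms keep bit-identical coordinates.  Residues that already
#' lack `O2'` are left untouched and logged as already-deoxy.
#'
#' @param s a [nuc_structure].
#' @return list with elements `structure` (edited [nuc_structure]) and
#'   `fragment` (removal ledger).
#' @export
strip_2prime_hydroxyl <- function(s) {
  stopifnot(inherits(s, "nuc_structure"))
  a <- s$atoms
  nm_v3 <- atom_name_to_dialect(a$name, "pdbv3")
  frag <- .empty_fragment()
  key <- residue_key(a)
  o2_rows <- which(nm_v3 == "O2'")
  ho2_rows <- which(nm_v3 %in% c("HO2'", "HO'2", "2HO'") &
                      key %in% key[o2_rows])
  drop <- c(o2_rows, ho2_rows)
  if (length(drop)) {
    frag$removed_atoms <- data.frame(
      residue = .residue_id(a$chain[drop], a$resno[drop], a$ins[drop]),
      atom = nm_v3[drop])
    s$atoms <- a[-drop, , drop = FALSE]
    s <- renumber_serials(s)
  } else {
    warning("no 2'-hydroxyl found; structure appears to be already DNA")
  }
  list(structure = s, fragment = frag)
}

# best-fit pyrimidine ring plane from the ring atoms present
.uracil_ring_atoms <- c("N1", "C2", "N3", "C4", "C5", "C6")

#' Methylate every uracil at C5
#'
#' For each uracil residue: the `H5` hydrogen is deleted when present, and
#' a methyl carbon `C7` is constructed at `geom$c5_c7_bond` from C5, in
#' the base plane, along the exterior bisector of C4-C5-C6 (the position
#' H5 occupied).  The construction uses heavy atoms only (C4, C5, C6), so
#' hydrogen-free models convert identically.  When the parent residue
#' carries hydrogens, three methyl hydrogens `H71`/`H72`/`H73` are added
#' with tetrahedral geometry, staggered relative to the C5-C4 bond.  No
#' other atom moves.
#'
#' @param s a [nuc_structure].
#' @param geom a [methyl_geometry].
#' @return list with elements `structure` and `fragment`.
#' @export
methylate_uracil <- function(s, geom = methyl_geometry()) {
  stopifnot(inherits(s, "nuc_structure"), inherits(geom, "methyl_geometry"))
  a <- s$atoms
  a$name <- atom_name_to_dialect(a$name, "pdbv3")
  frag <- .empty_fragment()
  idx_by_res <- residue_indices(a)
  removed <- list(); added <- list()
  new_rows <- list()
  drop_rows <- integer(0)
  for (ri in seq_along(idx_by_res)) {
    rows <- idx_by_res[[ri]]
    code <- a$resid[rows[1]]
    if (!identical(base_kind(code), "uracil")) next
    rid <- .residue_id(a$chain[rows[1]], a$resno[rows[1]], a$ins[rows[1]])
    nm <- a$name[rows]
    need <- c("C4", "C5", "C6")
    if (!all(need %in% nm))
      stop("uracil residue ", rid, " lacks ring atom(s): ",
           paste(setdiff(need, nm), collapse = ", "))
    get <- function(x) unlist(a[rows[match(x, nm)], c("x", "y", "z")],
                              use.names = FALSE)
    c4 <- get("C4"); c5 <- get("C5"); c6 <- get("C6")
    ring_present <- intersect(.uracil_ring_atoms, nm)
    ring_xyz <- do.call(rbind, lapply(ring_present, get))
    u <- -(unitv(c4 - c5) + unitv(c6 - c5))
    if (nrow(ring_xyz) >= 3) {
      pl <- best_fit_plane(ring_xyz)
      if (pl$max_dev > geom$coplanarity_tol)
        warning("uracil ring ", rid, " deviates ",
                format(round(pl$max_dev, 3)),
                " Angstrom from planarity; using best-fit ring plane")
      u <- u - sum(u * pl$normal) * pl$normal  # project into ring plane
    }
    c7 <- c5 + geom$c5_c7_bond * unitv(u)
    h5_row <- rows[which(nm == "H5")]
    if (length(h5_row)) {
      drop_rows <- c(drop_rows, h5_row)
      removed[[length(removed) + 1L]] <- data.frame(residue = rid, atom = "H5")
    }
    add <- data.frame(serial = NA_integer_, name = "C7", element = "C",
                      resid = code, chain = a$chain[rows[1]],
                      resno = a$resno[rows[1]], ins = a$ins[rows[1]],
                      x = c7[1], y = c7[2], z = c7[3])
    has_h <- any(a$element[rows] == "H")
    if (has_h) {
      tors <- c(180, 60, -60)  # staggered relative to C5-C4
      hname <- c("H71", "H72", "H73")
      for (k in 1:3) {
        hp <- place_atom(c4, c5, c7, geom$c_h_bond, geom$hch_angle, tors[k])
        add <- rbind(add, data.frame(serial = NA_integer_, name = hname[k],
                                     element = "H", resid = code,
                                     chain = a$chain[rows[1]],
                                     resno = a$resno[rows[1]],
                                     ins = a$ins[rows[1]],
                                     x = hp[1], y = hp[2], z = hp[3]))
      }
    }
    new_rows[[length(new_rows) + 1L]] <- list(after = max(rows), rows = add)
    added[[length(added) + 1L]] <-
      data.frame(residue = rid, atom = add$name)
  }
  if (length(new_rows) || length(drop_rows)) {
    pieces <- list()
    cut <- c(0L, vapply(new_rows, function(z) z$after, integer(1)), nrow(a))
    for (k in seq_len(length(cut) - 1L)) {
      if (cut[k + 1L] > cut[k]) {
        seg <- a[setdiff(seq.int(cut[k] + 1L, cut[k + 1L]), drop_rows), ,
                 drop = FALSE]
        pieces[[length(pieces) + 1L]] <- seg
      }
      if (k <= length(new_rows))
        pieces[[length(pieces) + 1L]] <- new_rows[[k]]$rows
    }
    s$atoms <- do.call(rbind, pieces)
    s <- renumber_serials(s)
  }
  frag$removed_atoms <- if (length(removed)) do.call(rbind, removed) else
    frag$removed_atoms
  frag$added_atoms <- if (length(added)) do.call(rbind, added) else
    frag$added_atoms
  list(structure = s, fragment = frag)
}

#' Rename residues to DNA codes
#'
#' Maps residue codes A/C/G/U to DA/DC/DG/DT (modern PDB convention);
#' already-DNA codes are left unchanged.  Refuses to rename any residue
#' that still carries a 2'-oxygen, since that would mislabel a
#' ribonucleotide as DNA.
#'
#' @param s a [nuc_structure] whose ribose stripping (and uracil
#'   methylation) has already been applied.
#' @return list with elements `structure` and `fragment`.
#' @export
rename_to_dna <- function(s) {
  stopifnot(inherits(s, "nuc_structure"))
  a <- s$atoms
  nm_v3 <- atom_name_to_dialect(a$name, "pdbv3")
  bad <- which(nm_v3 == "O2'")
  if (length(bad)) {
    rid <- .residue_id(a$chain[bad], a$resno[bad], a$ins[bad])
    stop("residue(s) still contain a 2'-oxygen (run strip_2prime_hydroxyl ",
         "first): ", paste(unique(rid), collapse = ", "))
  }
  map <- c(A = "DA", C = "DC", G = "DG", U = "DT", T = "DT")
  frag <- .empty_fragment()
  hit <- a$resid %in% names(map)
  if (any(hit)) {
    key <- residue_key(a)
    first <- !duplicated(key) & hit
    frag$renamed_residues <- data.frame(
      residue = .residue_id(a$chain[first], a$resno[first], a$ins[first]),
      old = a$resid[first], new = unname(map[a$resid[first]]))
    a$resid[hit] <- map[a$resid[hit]]
    s$atoms <- a
  }
  s$dialect <- "pdbv3"
  list(structure = s, fragment = frag)
}

.merge_fragments <- function(...) {
  frags <- list(...)
  out <- .empty_fragment()
  for (f in frags) {
    out$removed_atoms <- rbind(out$removed_atoms, f$removed_atoms)
    out$added_atoms <- rbind(out$added_atoms, f$added_atoms)
    out$renamed_residues <- rbind(out$renamed_residues, f$renamed_residues)
  }
  out
}

#' Convert an ssRNA structure to ssDNA
#'
#' Applies [strip_2prime_hydroxyl], [methylate_uracil] and [rename_to_dna]
#' in that order, then validates the product against the DNA residue
#' templates.  Coordinates of every atom present in both input and output
#' are bit-identical, so the conformation of the parent model is preserved
#' exactly.  Applying the conversion to an already-converted structure is
#' the identity (the report shows zero removals and additions).
#'
#' @param s a [nuc_structure] (an ssRNA model; already-DNA structures pass
#'   through unchanged).
#' @param geom a [methyl_geometry].
#' @param strict when `TRUE`, validation failures raise an error instead
#'   of being reported.
#' @return list with elements `structure` (the ssDNA [nuc_structure]) and
#'   `report` (a `conversion_report`: ledger of removed/added/renamed
#'   entries plus validation findings).
#' @examples
#' rna <- build_helix("ACGU")
#' out <- convert_structure(rna)
#' sequence_of(out$structure)  # "ACGT"
#' out$report
#' @export
convert_structure <- function(s, geom = methyl_geometry(), strict = FALSE) {
  stopifnot(inherits(s, "nuc_structure"))
  already_dna <- !any(atom_name_to_dialect(s$atoms$name, "pdbv3") == "O2'")
  step1 <- if (already_dna) {
    list(structure = s, fragment = .empty_fragment())
  } else {
    strip_2prime_hydroxyl(s)
  }
  step2 <- methylate_uracil(step1$structure, geom)
  step3 <- rename_to_dna(step2$structure)
  frag <- .merge_fragments(step1$fragment, step2$fragment, step3$fragment)
  validation <- validate_dna(step3$structure)
  report <- structure(c(frag, list(validation = validation)),
                      class = "conversion_report")
  if (strict && any(!validation$pass))
    stop("validation failed:\n",
         paste(validation$detail[!validation$pass], collapse = "\n"))
  list(structure = step3$structure, report = report)
}

#' @export
print.conversion_report <- function(x, ...) {
  cat("conversion report:\n")
  cat("  removed atoms: ", nrow(x$removed_atoms),
      " (", sum(x$removed_atoms$atom == "O2'"), " O2')\n", sep = "")
  cat("  added atoms:   ", nrow(x$added_atoms),
      " (", sum(x$added_atoms$atom == "C7"), " C7)\n", sep = "")
  cat("  renamed residues:", nrow(x$renamed_residues), "\n")
  v <- x$validation
  cat("  validation: ", sum(v$pass), "/", nrow(v), " checks passed\n",
      sep = "")
  if (any(!v$pass))
    cat(paste("   FAIL:", v$detail[!v$pass], collapse = "\n"), "\n")
  invisible(x)
}

#' Serialize a conversion report as JSON
#'
#' @param report a `conversion_report`.
#' @param path optional output file; when omitted the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "conversion_report"))
  js <- jsonlite::toJSON(
    list(removed = report$removed_atoms, added = report$added_atoms,
         renamed = report$renamed_residues, validation = report$validation),
    dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Validate a structure against the DNA residue templates
#'
#' Per-residue checks: the heavy-atom inventory equals the DNA template
#' (5'-terminal residues may lack the phosphate group); no residue
#' contains a 2'-oxygen; every thymine has a C7 with C5-C7 distance in
#' (1.3, 1.7) Angstrom; intra-residue bond lengths are within +/- 0.25
#' Angstrom of the idealized template values; and consecutive residues
#' are connected with an O3'-P distance in (1.4, 1.9) Angstrom.
#'
#' @param s a [nuc_structure] (DNA codes expected).
#' @param templates a [residue_templates()] table.
#' @return data frame with columns `check`, `residue`, `pass`, `detail`.
#' @export
validate_dna <- function(s, templates = residue_templates()) {
  stopifnot(inherits(s, "nuc_structure"))
  a <- s$atoms
  a$name <- atom_name_to_dialect(a$name, "pdbv3")
  idx_by_res <- residue_indices(a)
  res <- character(0); chk <- character(0); ok <- logical(0); det <- character(0)
  note <- function(check, rid, pass, detail = "") {
    chk <<- c(chk, check); res <<- c(res, rid)
    ok <<- c(ok, pass); det <<- c(det, detail)
  }
  prev <- NULL  # (chain, o3 coords) of previous residue
  for (ri in seq_along(idx_by_res)) {
    rows <- idx_by_res[[ri]]
    code <- a$resid[rows[1]]
    rid <- .residue_id(a$chain[rows[1]], a$resno[rows[1]], a$ins[rows[1]])
    nm <- a$name[rows]
    heavy <- nm[a$element[rows] != "H"]
    get <- function(x) unlist(a[rows[match(x, nm)], c("x", "y", "z")],
                              use.names = FALSE)
    # no 2'-oxygen anywhere
    note("no_o2prime", rid, !("O2'" %in% nm),
         if ("O2'" %in% nm) paste0(rid, ": residue retains O2'") else "")
    tmpl <- templates[[code]]
    if (is.null(tmpl)) {
      note("template_inventory", rid, FALSE,
           paste0(rid, ": no DNA template for residue code ", code))
      prev <- NULL
      next
    }
    expect <- tmpl$atoms
    is_5prime <- ri == 1L ||
      a$chain[rows[1]] != a$chain[idx_by_res[[ri - 1L]][1]]
    expect_sets <- list(expect)
    if (is_5prime)
      expect_sets <- c(expect_sets,
                       list(setdiff(expect, c("P", "OP1", "OP2"))))
    inv_ok <- any(vapply(expect_sets, function(e) setequal(heavy, e),
                         logical(1)))
    note("template_inventory", rid, inv_ok,
         if (!inv_ok) paste0(rid, ": heavy atoms {",
                             paste(sort(heavy), collapse = ","),
                             "} do not match the ", code, " template") else "")
    # thymine methyl bond
    if (code == "DT") {
      d <- if (all(c("C5", "C7") %in% nm)) vnorm(get("C5") - get("C7")) else NA
      pass <- !is.na(d) && d > 1.3 && d < 1.7
      note("c5_c7_bond", rid, pass,
           if (!pass) paste0(rid, ": C5-C7 distance ",
                             if (is.na(d)) "missing" else round(d, 3)) else "")
    }
    # template bond lengths
    bad <- character(0)
    for (bi in seq_len(nrow(tmpl$bonds))) {
      an <- tmpl$bonds$a[bi]; bn <- tmpl$bonds$b[bi]
      if (!(an %in% nm && bn %in% nm)) next
      d <- vnorm(get(an) - get(bn))
      if (abs(d - tmpl$bonds$length[bi]) > 0.25)
        bad <- c(bad, paste0(an, "-", bn, "=", round(d, 2)))
    }
    note("bond_lengths", rid, length(bad) == 0L,
         if (length(bad)) paste0(rid, ": bond(s) outside template +/-0.25: ",
                                 paste(bad, collapse = ", ")) else "")
    # backbone connectivity to the previous residue
    if (!is.null(prev) && prev$chain == a$chain[rows[1]] && "P" %in% nm) {
      d <- vnorm(prev$o3 - get("P"))
      pass <- d > 1.4 && d < 1.9
      note("backbone_link", rid, pass,
           if (!pass) paste0(rid, ": O3'(prev)-P distance ",
                             round(d, 3)) else "")
    }
    prev <- if ("O3'" %in% nm)
      list(chain = a$chain[rows[1]], o3 = get("O3'")) else NULL
  }
  data.frame(check = chk, residue = res, pass = ok, detail = det,
             stringsAsFactors = FALSE)
}

#' Convert an RNA sequence string to DNA
#'
#' Replaces every uracil letter `U` by thymine `T`; all other characters
#' are unchanged.  Whitespace is ignored; case is preserved in the sense
#' that input is upper-cased before substitution.
#'
#' @param rna_seq character string over the alphabet `A`, `C`, `G`, `U`
#'   (case-insensitive; whitespace allowed and removed).
#' @return the same-length DNA sequence string.
#' @examples
#' convert_sequence("CCG CAU CGU")  # "CCGCATCGT"
#' @export
convert_sequence <- function(rna_seq) {
  stopifnot(is.character(rna_seq), length(rna_seq) == 1L)
  sq <- toupper(gsub("[[:space:]]", "", rna_seq))
  if (!nzchar(sq)) return("")
  ch <- strsplit(sq, "")[[1]]
  bad <- which(!(ch %in% c("A", "C", "G", "U")))
  if (length(bad))
    stop("invalid character '", ch[bad[1]], "' at position ", bad[1],
         " (alphabet is A, C, G, U)")
  gsub("U", "T", sq, fixed = TRUE)
}
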