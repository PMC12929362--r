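# Idealized nucleotide monomer geometry.  Templates are built in code from
# standard bond lengths, ring angles and sugar-pucker torsions (C3'-endo
# for ribose, C2'-endo for deoxyribose; planar bases as regular polygons).
# They provide (i) the monomers the helix fixture generator stamps along a
# helical axis, (ii) the reference atom inventories and bond lengths used
# by chemical validation, and (iii) donor/acceptor classifications for
# hydrogen-bond counting on heavy-atom-only models.  The geometry aims at
# chemical plausibility and self-consistency, not crystallographic
# accuracy.

# ---- planar base templates (2D) ---------------------------------------

# exterior bisector substituent placement on a ring vertex
.sub2d <- function(xy, at, n1, n2, len) {
  r <- xy[at, ]
  u <- (r - xy[n1, ]) / vnorm(r - xy[n1, ]) +
       (r - xy[n2, ]) / vnorm(r - xy[n2, ])
  r + len * u / vnorm(u)
}

# two sp2 amino hydrogens on an exocyclic nitrogen
.amino_h2d <- function(xy, n, c_parent, len = 1.01) {
  u <- (xy[n, ] - xy[c_parent, ]) / vnorm(xy[n, ] - xy[c_parent, ])
  rot <- function(v, th) {
    t <- th * pi / 180
    c(cos(t) * v[1] - sin(t) * v[2], sin(t) * v[1] + cos(t) * v[2])
  }
  rbind(xy[n, ] + len * rot(u, 60), xy[n, ] + len * rot(u, -60))
}

.hexagon2d <- function(labels, side = 1.38) {
  xy <- matrix(0, 6, 2, dimnames = list(labels, NULL))
  pos <- c(0, 0)
  for (k in 1:6) {
    xy[k, ] <- pos
    th <- (k - 1) * 60 * pi / 180
    pos <- pos + side * c(cos(th), sin(th))
  }
  xy
}

# planar base template in 2D; returns coords, the glycosidic attach atom,
# the atom defining the chi torsion, and the intra-base bond list
.base_template_2d <- function(base, hydrogens = FALSE) {
  side <- 1.38
  bonds <- NULL
  add_bond <- function(a, b) bonds <<- rbind(bonds, data.frame(a = a, b = b))
  if (base %in% c("uracil", "thymine", "cytosine")) {
    ring <- c("N1", "C2", "N3", "C4", "C5", "C6")
    xy <- .hexagon2d(ring, side)
    for (k in 1:6) add_bond(ring[k], ring[k %% 6 + 1])
    sub <- function(at, n1, n2, nm, len) {
      xy <<- rbind(xy, setNames(t(.sub2d(xy, at, n1, n2, len)), NULL))
      rownames(xy)[nrow(xy)] <<- nm
      add_bond(at, nm)
    }
    sub("C2", "N1", "N3", "O2", 1.22)
    if (base == "cytosine") {
      sub("C4", "N3", "C5", "N4", 1.34)
      if (hydrogens) {
        h <- .amino_h2d(xy, "N4", "C4")
        xy <- rbind(xy, H41 = h[1, ], H42 = h[2, ])
        add_bond("N4", "H41"); add_bond("N4", "H42")
      }
    } else {
      sub("C4", "N3", "C5", "O4", 1.22)
      if (hydrogens) sub("N3", "C2", "C4", "H3", 1.01)
    }
    if (base == "thymine") sub("C5", "C4", "C6", "C7", 1.50)
    if (hydrogens) {
      if (base != "thymine") sub("C5", "C4", "C6", "H5", 1.08)
      sub("C6", "C5", "N1", "H6", 1.08)
    }
    list(xy = xy, attach = "N1", chi_atom = "C2", bonds = bonds)
  } else {
    # purine: hexagon N1 C2 N3 C4 C5 C6 fused with pentagon C4 N9 C8 N7 C5
    ring6 <- c("N1", "C2", "N3", "C4", "C5", "C6")
    xy <- .hexagon2d(ring6, side)
    for (k in 1:6) add_bond(ring6[k], ring6[k %% 6 + 1])
    # pentagon built on the C5->C4 edge, outside the hexagon
    p <- matrix(0, 3, 2, dimnames = list(c("N9", "C8", "N7"), NULL))
    pos <- xy["C4", ]
    dir <- (xy["C4", ] - xy["C5", ]) / vnorm(xy["C4", ] - xy["C5", ])
    rot <- function(v, th) {
      t <- th * pi / 180
      c(cos(t) * v[1] - sin(t) * v[2], sin(t) * v[1] + cos(t) * v[2])
    }
    for (k in 1:3) {
      dir <- rot(dir, 72)
      pos <- pos + side * dir
      p[k, ] <- pos
    }
    xy <- rbind(xy, p)
    add_bond("C4", "N9"); add_bond("N9", "C8")
    add_bond("C8", "N7"); add_bond("N7", "C5")
    sub <- function(at, n1, n2, nm, len) {
      xy <<- rbind(xy, setNames(t(.sub2d(xy, at, n1, n2, len)), NULL))
      rownames(xy)[nrow(xy)] <<- nm
      add_bond(at, nm)
    }
    if (base == "adenine") {
      sub("C6", "N1", "C5", "N6", 1.34)
      if (hydrogens) {
        h <- .amino_h2d(xy, "N6", "C6")
        xy <- rbind(xy, H61 = h[1, ], H62 = h[2, ])
        add_bond("N6", "H61"); add_bond("N6", "H62")
        sub("C2", "N1", "N3", "H2", 1.08)
        sub("C8", "N9", "N7", "H8", 1.08)
      }
    } else {
      sub("C6", "N1", "C5", "O6", 1.22)
      sub("C2", "N1", "N3", "N2", 1.34)
      if (hydrogens) {
        sub("N1", "C2", "C6", "H1", 1.01)
        h <- .amino_h2d(xy, "N2", "C2")
        xy <- rbind(xy, H21 = h[1, ], H22 = h[2, ])
        add_bond("N2", "H21"); add_bond("N2", "H22")
        sub("C8", "N9", "N7", "H8", 1.08)
      }
    }
    list(xy = xy, attach = "N9", chi_atom = "C4", bonds = bonds)
  }
}

# ---- sugar + backbone (3D, torsion-driven) ----------------------------

# branch-placement signs and reference torsions, frozen after numerical
# verification of ring closure, chirality and helix connectivity
.geom_const <- list(
  # sugar ring internal angles (deg)
  ang_o4_c1_c2 = 106.1, ang_c1_c2_c3 = 101.5, ang_c2_c3_c4 = 102.6,
  # pucker torsions nu0..nu4 (deg)
  nu_ribose = c(0.0, -22.3, 36.1, -36.1, 22.3),
  nu_deoxy  = c(-22.3, 36.1, -36.1, 22.3, 0.0),
  # exocyclic branches: torsion offsets (deg) from the in-ring neighbour
  o3_branch = 120, o2_branch = 120, c5_branch = -120, n_branch = -120,
  # backbone torsions (deg), A-form-like
  gamma = 54, beta = 178, chi = -158,
  # bond lengths (Angstrom)
  b_c1_o4 = 1.414, b_c1_c2 = 1.528, b_c2_c3 = 1.525, b_c3_c4 = 1.528,
  b_c3_o3 = 1.423, b_c2_o2 = 1.413, b_c4_c5 = 1.510, b_c5_o5 = 1.440,
  b_o5_p = 1.593, b_p_op = 1.485, b_c1_n = 1.470,
  # angles (deg)
  ang_c2_c3_o3 = 110.6, ang_c1_c2_o2 = 110.0, ang_c3_c4_c5 = 115.5,
  ang_c4_c5_o5 = 110.2, ang_c5_o5_p = 120.9, ang_o5_p_op = 108.1,
  ang_o4_c1_n = 108.2, ang_c1_n_chi_pur = 126.3, ang_c1_n_chi_pyr = 117.5
)

.sugar_backbone <- function(sugar = c("ribose", "deoxyribose")) {
  sugar <- match.arg(sugar)
  g <- .geom_const
  nu <- if (sugar == "ribose") g$nu_ribose else g$nu_deoxy
  at <- list()
  at[["C1'"]] <- c(0, 0, 0)
  at[["O4'"]] <- c(g$b_c1_o4, 0, 0)
  a <- g$ang_o4_c1_c2 * pi / 180
  at[["C2'"]] <- c(g$b_c1_c2 * cos(a), g$b_c1_c2 * sin(a), 0)
  at[["C3'"]] <- place_atom(at[["O4'"]], at[["C1'"]], at[["C2'"]],
                            g$b_c2_c3, g$ang_c1_c2_c3, nu[2])
  at[["C4'"]] <- place_atom(at[["C1'"]], at[["C2'"]], at[["C3'"]],
                            g$b_c3_c4, g$ang_c2_c3_c4, nu[3])
  at[["O3'"]] <- place_atom(at[["C1'"]], at[["C2'"]], at[["C3'"]],
                            g$b_c3_o3, g$ang_c2_c3_o3, nu[3] + g$o3_branch)
  if (sugar == "ribose")
    at[["O2'"]] <- place_atom(at[["O4'"]], at[["C1'"]], at[["C2'"]],
                              g$b_c2_o2, g$ang_c1_c2_o2, nu[2] + g$o2_branch)
  at[["C5'"]] <- place_atom(at[["C2'"]], at[["C3'"]], at[["C4'"]],
                            g$b_c4_c5, g$ang_c3_c4_c5, nu[4] + g$c5_branch)
  at[["O5'"]] <- place_atom(at[["C3'"]], at[["C4'"]], at[["C5'"]],
                            g$b_c5_o5, g$ang_c4_c5_o5, g$gamma)
  at[["P"]]   <- place_atom(at[["C4'"]], at[["C5'"]], at[["O5'"]],
                            g$b_o5_p, g$ang_c5_o5_p, g$beta)
  at[["OP1"]] <- place_atom(at[["C5'"]], at[["O5'"]], at[["P"]],
                            g$b_p_op, g$ang_o5_p_op, 52)
  at[["OP2"]] <- place_atom(at[["C5'"]], at[["O5'"]], at[["P"]],
                            g$b_p_op, g$ang_o5_p_op, 172)
  do.call(rbind, at)
}

# embed a 2D base template into 3D at the glycosidic position
.embed_base <- function(bb, base2d, purine) {
  g <- .geom_const
  c1 <- bb["C1'", ]; o4 <- bb["O4'", ]; c4s <- bb["C4'", ]
  nu0 <- if ("O2'" %in% rownames(bb)) g$nu_ribose[1] else g$nu_deoxy[1]
  npos <- place_atom(c4s, o4, c1, g$b_c1_n, g$ang_o4_c1_n,
                     nu0 + g$n_branch)
  ang <- if (purine) g$ang_c1_n_chi_pur else g$ang_c1_n_chi_pyr
  chipos <- place_atom(o4, c1, npos, 1.38, ang, g$chi)
  ex <- unitv(chipos - npos)
  ez <- unitv(cross3(ex, unitv(c1 - npos)))
  ey <- cross3(ez, ex)
  xy <- base2d$xy
  ta <- xy[base2d$attach, ]; tb <- xy[base2d$chi_atom, ]
  tx <- (tb - ta) / vnorm(tb - ta)
  ty <- c(-tx[2], tx[1])
  # ring interior side in the template vs required side of C1'
  other <- if (purine) "C8" else "C6"
  s_tmpl <- sign(sum((xy[other, ] - ta) * ty))
  c1_loc <- c1 - npos
  if (sign(sum(c1_loc * ey)) == s_tmpl) ey <- -ey
  out <- matrix(0, nrow(xy), 3, dimnames = list(rownames(xy), NULL))
  for (k in seq_len(nrow(xy))) {
    q <- xy[k, ] - ta
    out[k, ] <- npos + sum(q * tx) * ex + sum(q * ty) * ey
  }
  out
}

# tetrahedral hydrogen completion on a carbon with two heavy neighbours
.ch2_hydrogens <- function(cpos, n1, n2, len = 1.09) {
  u <- unitv(unitv(cpos - n1) + unitv(cpos - n2))
  w <- unitv(cross3(n1 - cpos, n2 - cpos))
  half <- 54.75 * pi / 180
  rbind(cpos + len * (u * cos(half) + w * sin(half)),
        cpos + len * (u * cos(half) - w * sin(half)))
}

.ch1_hydrogen <- function(cpos, nbrs, len = 1.09) {
  u <- -rowSums(vapply(seq_len(nrow(nbrs)),
                       function(i) unitv(nbrs[i, ] - cpos), numeric(3)))
  # vapply returns 3 x n; rowSums over columns
  cpos + len * unitv(u)
}

.code_info <- function(code) {
  switch(code,
    A = list(base = "adenine", sugar = "ribose"),
    C = list(base = "cytosine", sugar = "ribose"),
    G = list(base = "guanine", sugar = "ribose"),
    U = list(base = "uracil", sugar = "ribose"),
    DA = list(base = "adenine", sugar = "deoxyribose"),
    DC = list(base = "cytosine", sugar = "deoxyribose"),
    DG = list(base = "guanine", sugar = "deoxyribose"),
    DT = list(base = "thymine", sugar = "deoxyribose"),
    stop("unknown residue code: ", code))
}

.backbone_order <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
                     "C3'", "O3'", "C2'", "O2'", "C1'")

# full monomer template for one residue code; coords in a residue-local
# frame, rownames are PDBv3 atom names
.build_monomer <- function(code, hydrogens = FALSE) {
  info <- .code_info(code)
  purine <- info$base %in% c("adenine", "guanine")
  bb <- .sugar_backbone(info$sugar)
  b2 <- .base_template_2d(info$base, hydrogens = hydrogens)
  base3 <- .embed_base(bb, b2, purine)
  bonds <- rbind(
    data.frame(a = c("P", "P", "P", "O5'", "C5'", "C4'", "C4'", "C3'",
                     "C3'", "C2'", "O4'"),
               b = c("OP1", "OP2", "O5'", "C5'", "C4'", "C3'", "O4'",
                     "O3'", "C2'", "C1'", "C1'")),
    data.frame(a = "C1'", b = b2$attach),
    b2$bonds)
  if (info$sugar == "ribose")
    bonds <- rbind(bonds, data.frame(a = "C2'", b = "O2'"))
  xyz <- rbind(bb, base3)
  if (hydrogens) {
    h <- rbind(
      "H5'"  = .ch2_hydrogens(bb["C5'", ], bb["C4'", ], bb["O5'", ])[1, ],
      "H5''" = .ch2_hydrogens(bb["C5'", ], bb["C4'", ], bb["O5'", ])[2, ],
      "H4'"  = .ch1_hydrogen(bb["C4'", ], bb[c("C3'", "C5'", "O4'"), ]),
      "H3'"  = .ch1_hydrogen(bb["C3'", ], bb[c("C2'", "C4'", "O3'"), ]),
      "H1'"  = .ch1_hydrogen(bb["C1'", ],
                             rbind(bb[c("C2'", "O4'"), ], base3[b2$attach, ])))
    hb <- data.frame(a = c("C5'", "C5'", "C4'", "C3'", "C1'"),
                     b = c("H5'", "H5''", "H4'", "H3'", "H1'"))
    if (info$sugar == "ribose") {
      h <- rbind(h,
        "H2'"  = .ch1_hydrogen(bb["C2'", ], bb[c("C1'", "C3'", "O2'"), ]),
        "HO2'" = place_atom(bb["C1'", ], bb["C2'", ], bb["O2'", ],
                            0.96, 109.5, 180))
      hb <- rbind(hb, data.frame(a = c("C2'", "O2'"), b = c("H2'", "HO2'")))
    } else {
      h2 <- .ch2_hydrogens(bb["C2'", ], bb["C1'", ], bb["C3'", ])
      h <- rbind(h, "H2'" = h2[1, ], "H2''" = h2[2, ])
      hb <- rbind(hb, data.frame(a = c("C2'", "C2'"), b = c("H2'", "H2''")))
    }
    xyz <- rbind(xyz, h)
    bonds <- rbind(bonds, hb)
  }
  # canonical atom order: backbone 5'->3', then base, then hydrogens
  heavy <- rownames(xyz)[!grepl("^H|^[0-9]H", rownames(xyz))]
  ord <- c(intersect(.backbone_order, heavy),
           setdiff(heavy, .backbone_order),
           setdiff(rownames(xyz), heavy))
  xyz <- xyz[ord, , drop = FALSE]
  list(code = code, xyz = xyz, bonds = bonds, base = info$base,
       sugar = info$sugar)
}

.template_env <- new.env(parent = emptyenv())

get_monomer <- function(code, hydrogens = FALSE) {
  key <- paste0(code, if (hydrogens) "_H")
  if (is.null(.template_env[[key]]))
    .template_env[[key]] <- .build_monomer(code, hydrogens)
  .template_env[[key]]
}

.heavy_donors <- list(
  A = "N6", C = "N4", G = c("N1", "N2"), U = "N3", T = "N3",
  DA = "N6", DC = "N4", DG = c("N1", "N2"), DT = "N3")

#' Residue template table
#'
#' Idealized per-residue reference data for the eight canonical
#' ribo/deoxyribo-nucleotides: heavy-atom name inventory, expected heavy
#' atom count, intra-residue bond list with idealized lengths (Angstrom),
#' and heavy-atom donor/acceptor classification for hydrogen-bond
#' analysis.  The DNA template of each base equals the RNA template minus
#' the 2'-oxygen (plus the C7 methyl carbon for thymine).
#'
#' @return named list, one element per residue code (`A`, `C`, `G`, `U`,
#'   `DA`, `DC`, `DG`, `DT`), each with components `atoms`,
#'   `heavy_count`, `bonds` (data frame `a`, `b`, `length`), `donors`,
#'   `acceptors`.
#' @export
residue_templates <- function() {
  codes <- c("A", "C", "G", "U", "DA", "DC", "DG", "DT")
  out <- lapply(codes, function(code) {
    m <- get_monomer(code)
    xyz <- m$xyz
    bonds <- m$bonds
    bonds$length <- vapply(seq_len(nrow(bonds)), function(i)
      vnorm(xyz[bonds$a[i], ] - xyz[bonds$b[i], ]), numeric(1))
    el <- derive_element(rownames(xyz))
    base_letter <- sub("^D", "", code)
    donors <- intersect(.heavy_donors[[code]], rownames(xyz))
    if (m$sugar == "ribose") donors <- c(donors, "O2'")
    list(atoms = rownames(xyz), heavy_count = nrow(xyz),
         bonds = bonds, donors = donors,
         acceptors = rownames(xyz)[el %in% c("N", "O")])
  })
  names(out) <- codes
  out
}
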