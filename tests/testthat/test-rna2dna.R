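# The RNA -> DNA conversion algorithm: sequence substitution, 2'-OH
# stripping, C5 methylation, renaming, validation.

test_that("sequence conversion reproduces the published DNA strings", {
  sq <- aptamer_sequences()
  expect_identical(convert_sequence(sq[["A6"]]), sq[["LN_A6"]])
  # grouped/spaced/lower-case input is tolerated
  expect_identical(convert_sequence("ccg cau cgu"), "CCGCATCGT")
  expect_identical(convert_sequence(""), "")
  expect_error(convert_sequence("ACGX"), "position 4")
  expect_error(convert_sequence("ACGT"), "position 4")  # T is not RNA
})

test_that("strict per-residue conversion of the second aptamer keeps all 60 nt", {
  sq <- aptamer_sequences()
  got <- convert_sequence(sq[["A11"]])
  expect_identical(got, char_map_convert(sq[["A11"]]))
  expect_identical(nchar(got), 60L)
  # the published 57-nt DNA string omits one U-derived triplet; strict
  # substitution therefore does not equal it
  expect_identical(nchar(sq[["LN_A11"]]), 57L)
  expect_false(identical(got, sq[["LN_A11"]]))
  expect_identical(gsub("CCT", "", got, fixed = TRUE),
                   gsub("CCT", "", sq[["LN_A11"]], fixed = TRUE))
})

test_that("2'-hydroxyl stripping removes exactly O2' (+ its hydrogen) and moves nothing", {
  s <- build_helix("A", hydrogens = TRUE)
  out <- strip_2prime_hydroxyl(s)
  expect_setequal(out$fragment$removed_atoms$atom, c("O2'", "HO2'"))
  expect_identical(n_atoms(out$structure), n_atoms(s) - 2L)
  sh <- shared_coords(s, out$structure)
  expect_identical(sh$a, sh$b)  # bit-identical coordinates

  s60 <- build_helix(aptamer_sequences()[["A6"]])
  n_o2 <- sum(s60$atoms$name == "O2'")
  expect_identical(n_o2, 60L)
  out60 <- strip_2prime_hydroxyl(s60)
  expect_identical(nrow(out60$fragment$removed_atoms), n_o2)
  expect_identical(sum(out60$structure$atoms$name == "O2'"), 0L)

  dna <- build_helix("ACGT")
  expect_warning(out_dna <- strip_2prime_hydroxyl(dna), "already")
  expect_identical(nrow(out_dna$fragment$removed_atoms), 0L)
  expect_identical(coords(out_dna$structure), coords(dna))
})

test_that("uracil methylation builds C7 in the ring plane at the exterior bisector", {
  for (hyd in c(TRUE, FALSE)) {
    s <- build_helix("U", hydrogens = hyd)
    out <- methylate_uracil(s)
    a <- out$structure$atoms
    expect_true("C7" %in% a$name)
    get <- function(nm) unlist(a[a$name == nm, c("x", "y", "z")],
                               use.names = FALSE)
    c4 <- get("C4"); c5 <- get("C5"); c6 <- get("C6"); c7 <- get("C7")
    expect_equal(vnorm(c7 - c5), 1.50, tolerance = 1e-9)
    # recompute the two base angles from the output coordinates
    expect_lt(abs(angle_deg(c4, c5, c7) - 120), 3)
    expect_lt(abs(angle_deg(c6, c5, c7) - 120), 3)
    ring <- do.call(rbind, lapply(c("N1", "C2", "N3", "C4", "C5", "C6"), get))
    pl <- aptaconv:::best_fit_plane(ring)
    expect_lt(abs(sum((c7 - pl$center) * pl$normal)), 0.15)
    if (hyd) {
      expect_true(all(c("H71", "H72", "H73") %in% a$name))
      expect_false("H5" %in% a$name)
      for (h in c("H71", "H72", "H73"))
        expect_equal(vnorm(get(h) - c7), 1.09, tolerance = 1e-9)
    } else {
      expect_false(any(c("H71", "H72", "H73") %in% a$name))
    }
    # heavy-atom construction: C7 identical with and without hydrogens
    if (hyd) c7_h <<- c7 else expect_equal(c7, c7_h, tolerance = 1e-9)
  }
})

test_that("methylation leaves structures without uracil untouched and guards ring atoms", {
  s <- build_helix("ACG")
  out <- methylate_uracil(s)
  expect_identical(out$structure$atoms, s$atoms)
  expect_identical(nrow(out$fragment$added_atoms), 0L)

  u <- build_helix("U")
  u$atoms <- u$atoms[u$atoms$name != "C5", ]
  expect_error(methylate_uracil(u), "C5")
})

test_that("renaming maps to DNA codes and refuses unstripped ribonucleotides", {
  s <- build_helix("GUCA")
  expect_error(rename_to_dna(s), "2'-oxygen")
  stripped <- strip_2prime_hydroxyl(s)$structure
  meth <- methylate_uracil(stripped)$structure
  out <- rename_to_dna(meth)
  expect_setequal(unique(out$structure$atoms$resid), c("DG", "DT", "DC", "DA"))
  expect_identical(base_kind("DT"), "thymine")
  expect_identical(sequence_of(out$structure), "GTCA")
})

test_that("full conversion preserves the conformation exactly and balances mass", {
  a6_seq <- aptamer_sequences()[["A6"]]
  s <- build_helix(a6_seq)
  out <- convert_structure(s)
  rep <- out$report

  # mass balance, recomputed from the input by direct counting
  expect_identical(nrow(rep$removed_atoms), sum(s$atoms$name == "O2'"))
  n_u <- sum(strsplit(a6_seq, "")[[1]] == "U")
  expect_identical(sum(rep$added_atoms$atom == "C7"), n_u)
  expect_identical(sum(rep$renamed_residues$new == "DT"), n_u)
  expect_identical(nrow(rep$renamed_residues), 60L)

  # retained atoms bit-identical; superposition RMSD exactly 0
  sh <- shared_coords(s, out$structure)
  expect_identical(sh$a, sh$b)
  expect_lt(kabsch_superpose(sh$b, sh$a)$rmsd, 1e-12)

  expect_identical(sequence_of(out$structure),
                   aptamer_sequences()[["LN_A6"]])
  expect_true(all(rep$validation$pass))

  # idempotence
  out2 <- convert_structure(out$structure)
  expect_identical(nrow(out2$report$removed_atoms), 0L)
  expect_identical(nrow(out2$report$added_atoms), 0L)
  expect_identical(coords(out2$structure), coords(out$structure))
})

test_that("sequence and structure conversion commute on random sequences", {
  set.seed(11)
  for (k in 1:12) {
    sq <- paste(sample(c("A", "C", "G", "U"), 8, replace = TRUE),
                collapse = "")
    s <- build_helix(sq)
    expect_identical(sequence_of(convert_structure(s)$structure),
                     convert_sequence(sq))
  }
})

test_that("methyl construction postconditions hold on perturbed rings", {
  base <- build_helix("UUU")
  set.seed(4)
  for (k in 1:25) {
    s <- base
    # random displacement of bounded magnitude (<= 0.05 A per atom)
    dir <- matrix(rnorm(3 * n_atoms(s)), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    pert <- coords(s) + dir * runif(n_atoms(s), 0, 0.05)
    s$atoms$x <- pert[, 1]; s$atoms$y <- pert[, 2]; s$atoms$z <- pert[, 3]
    out <- methylate_uracil(s)
    a <- out$structure$atoms
    for (rn in unique(a$resno)) {
      get <- function(nm) unlist(a[a$resno == rn & a$name == nm,
                                   c("x", "y", "z")], use.names = FALSE)
      c7 <- get("C7")
      expect_lt(abs(angle_deg(get("C4"), get("C5"), c7) - 120), 3)
      expect_lt(abs(angle_deg(get("C6"), get("C5"), c7) - 120), 3)
      ring <- do.call(rbind,
                      lapply(c("N1", "C2", "N3", "C4", "C5", "C6"), get))
      pl <- aptaconv:::best_fit_plane(ring)
      expect_lt(abs(sum((c7 - pl$center) * pl$normal)), 0.15)
    }
  }
})

test_that("validation flags injected chemical defects by residue", {
  s <- convert_structure(build_helix("GUAC"))$structure

  # an O2' left behind
  bad <- s
  extra <- bad$atoms[bad$atoms$name == "C2'" & bad$atoms$resno == 2, ]
  extra$name <- "O2'"; extra$element <- "O"; extra$serial <- max(bad$atoms$serial) + 1L
  extra$x <- extra$x + 1.4
  bad$atoms <- rbind(bad$atoms, extra)
  v <- validate_dna(bad)
  fail <- v[!v$pass, ]
  expect_true(any(fail$check == "no_o2prime" & fail$residue == "A:2"))

  # a methyl carbon at a non-bonding distance
  bad2 <- s
  i <- which(bad2$atoms$name == "C7")
  j <- which(bad2$atoms$name == "C5" & bad2$atoms$resno == bad2$atoms$resno[i])
  dir <- unlist(bad2$atoms[i, c("x", "y", "z")]) -
    unlist(bad2$atoms[j, c("x", "y", "z")])
  shift <- unname((2.5 / vnorm(dir) - 1) * dir)
  bad2$atoms[i, c("x", "y", "z")] <- bad2$atoms[i, c("x", "y", "z")] + shift
  v2 <- validate_dna(bad2)
  expect_true(any(!v2$pass & v2$check == "c5_c7_bond"))

  # strict mode raises on a defective product
  expect_error(convert_structure(bad2, strict = TRUE), "validation")
})
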