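# Structure container, naming dialects, PDB/GRO I/O.

test_that("PDB write/read round-trips names, numbering, sequence and coordinates", {
  for (case in list(list(seq = "GACGUACGUA", hyd = FALSE),
                    list(seq = "ACGT", hyd = FALSE),
                    list(seq = "UGAC", hyd = TRUE))) {
    s <- build_helix(case$seq, hydrogens = case$hyd)
    f <- withr::local_tempfile(fileext = ".pdb")
    write_pdb(s, f)
    rt <- read_pdb(f)
    expect_identical(rt$atoms$name, s$atoms$name)
    expect_identical(rt$atoms$resid, s$atoms$resid)
    expect_identical(rt$atoms$resno, s$atoms$resno)
    expect_identical(sequence_of(rt), sequence_of(s))
    expect_lt(max(abs(coords(rt) - coords(s))), 0.001 + 1e-9)
  }
})

test_that("written PDB agrees with an independent reader (bio3d)", {
  skip_if_not_installed("bio3d")
  s <- build_helix("GCAU")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  b <- bio3d::read.pdb(f)
  expect_equal(matrix(b$xyz, ncol = 3, byrow = TRUE), round(coords(s), 3),
               tolerance = 1e-9)
  expect_identical(trimws(b$atom$elety), s$atoms$name)
  expect_identical(trimws(b$atom$resid), s$atoms$resid)
})

test_that("the 60-residue helix of the parent aptamer sequence round-trips", {
  a6 <- aptamer_sequences()[["A6"]]
  s <- build_helix(a6)
  expect_identical(n_residues(s), 60L)
  expect_identical(sequence_of(s), a6)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  expect_identical(sequence_of(read_pdb(f)), a6)
})

test_that("legacy (pdbv2) names are detected and normalization is involutive", {
  s <- build_helix("ACGU")
  v2 <- as_dialect(s, "pdbv2")
  expect_true(any(v2$atoms$name == "O2*"))
  expect_true(any(v2$atoms$name == "O1P"))
  expect_identical(v2$dialect, "pdbv2")
  back <- as_dialect(v2, "pdbv3")
  expect_identical(back$atoms$name, s$atoms$name)
  expect_identical(back$atoms$resid, s$atoms$resid)

  # DNA residue codes collapse to single letters in v2 and are recovered
  d <- convert_structure(s)$structure
  d2 <- as_dialect(d, "pdbv2")
  expect_setequal(unique(d2$atoms$resid), c("A", "C", "G", "T"))
  d3 <- as_dialect(d2, "pdbv3")
  expect_identical(d3$atoms$resid, d$atoms$resid)

  # a v2 file on disk is auto-detected and normalized on request
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f, dialect = "pdbv2")
  rt_auto <- read_pdb(f)
  expect_identical(rt_auto$dialect, "pdbv2")
  rt_norm <- read_pdb(f, dialect = "pdbv3")
  expect_identical(rt_norm$atoms$name, s$atoms$name)
})

test_that("unknown residue codes pass through dialect mapping with a warning", {
  s <- build_helix("ACGU")
  s$atoms$resid[s$atoms$resno == 2] <- "XYZ"
  expect_warning(v2 <- as_dialect(s, "pdbv2"), "XYZ")
  expect_true(any(v2$atoms$resid == "XYZ"))
  expect_error(sequence_of(s), "XYZ")
})

test_that("multi-model PDB trajectories round-trip with frame times", {
  ref <- build_helix("GAUC")
  traj <- make_noise_trajectory(ref, noise_spec(sigma = 0.3, n_frames = 5,
                                                seed = 7, dt = 0.5))
  ftop <- withr::local_tempfile(fileext = ".pdb")
  ftrj <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ref, ftop)
  write_trajectory(traj, ftrj)
  rt <- read_trajectory(ftop, ftrj)
  expect_identical(n_frames(rt), 5L)
  expect_equal(rt$times, traj$times)
  expect_lt(max(abs(rt$coords - traj$coords)), 0.001 + 1e-9)

  # five identical models -> five identical frames
  still <- make_noise_trajectory(ref, noise_spec(0, 5, seed = 1))
  write_trajectory(still, ftrj)
  rt2 <- read_trajectory(ftop, ftrj)
  for (i in 2:5)
    expect_identical(rt2$coords[i, , ], rt2$coords[1, , ])
})

test_that("GRO coordinates are converted from nm to Angstrom", {
  f <- withr::local_tempfile(fileext = ".gro")
  lines <- c("hand-built frame t= 100.0",
             "    3",
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1L, "U", "P", 1L, 0.1, 0.2, 0.3),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1L, "U", "O5'", 2L, 0.4, -0.5, 0.6),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1L, "U", "C5'", 3L, 0.0, 0.0, 1.234),
             "   5.0   5.0   5.0")
  writeLines(lines, f)
  s <- read_gro(f)
  expect_identical(n_atoms(s), 3L)
  # hand conversion of one atom line: 0.1 nm -> 1.0 A etc.
  expect_equal(unname(coords(s)[1, ]), c(1.0, 2.0, 3.0))
  expect_equal(unname(coords(s)[2, ]), c(4.0, -5.0, 6.0))

  # two concatenated frames with GROMACS-style ps time stamps
  writeLines(c(lines, sub("t= 100.0", "t= 200.0", lines)), f)
  ftop <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, ftop)
  traj <- read_trajectory(ftop, f)
  expect_identical(n_frames(traj), 2L)
  expect_equal(traj$times, c(0.1, 0.2))  # ps -> ns
})

test_that("parse and consistency errors name the offending location", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("TITLE     broken",
               "ATOM      1  P     U A   1      bad.000   0.000   0.000",
               "END"), f)
  expect_error(read_pdb(f), "line 2")
  writeLines(c("TITLE     empty", "END"), f)
  expect_error(read_pdb(f), "no ATOM")
  expect_error(read_pdb(file.path(tempdir(), "nope.pdb")), "not found")

  # frame atom-count mismatch names the frame
  ref <- build_helix("GAUC")
  traj <- make_noise_trajectory(ref, noise_spec(0, 2, seed = 1))
  ftop <- withr::local_tempfile(fileext = ".pdb")
  ftrj <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ref, ftop)
  write_trajectory(traj, ftrj)
  lines <- readLines(ftrj)
  atom_lines <- which(startsWith(lines, "ATOM"))
  writeLines(lines[-atom_lines[n_atoms(ref) + 1]], ftrj)  # drop one atom of frame 2
  expect_error(read_trajectory(ftop, ftrj), "frame 2")
})

test_that("altloc handling keeps blank/'A' and drops others with a warning", {
  s <- build_helix("AC")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  lines <- readLines(f)
  i <- which(startsWith(lines, "ATOM"))[1]
  dup <- lines[i]
  substr(lines[i], 17, 17) <- "A"
  substr(dup, 17, 17) <- "B"
  writeLines(append(lines, dup, after = i), f)
  expect_warning(rt <- read_pdb(f), "alternate location")
  expect_identical(n_atoms(rt), n_atoms(s))
})

test_that("structure invariants are enforced at construction", {
  s <- build_helix("ACGU")
  a <- s$atoms
  a$serial[2] <- a$serial[1]
  expect_error(nuc_structure(a), "serial")
  a <- s$atoms
  a$name[2] <- a$name[1]
  expect_error(nuc_structure(a), "duplicated atom name")
  a <- s$atoms
  a$x[1] <- NaN
  expect_error(nuc_structure(a), "finite")
  a <- s$atoms
  a$resno[a$resno == 2L] <- 0L  # 1, 0, 3, 4 is not increasing
  expect_error(nuc_structure(a), "increasing")
  expect_error(write_pdb(nuc_structure(s$atoms[0, ]), tempfile()), "empty")
  expect_identical(sequence_of(nuc_structure(s$atoms[0, ])), "")
})
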