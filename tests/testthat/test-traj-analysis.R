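# MD descriptors: Kabsch superposition RMSD, hydrogen bonds, summaries,
# plateau detection.

test_that("Kabsch superposition recovers rigid transforms and matches the quaternion oracle", {
  set.seed(2)
  x <- matrix(rnorm(30), 10, 3)

  r0 <- kabsch_superpose(x, x)
  expect_lt(r0$rmsd, 1e-12)
  expect_equal(r0$rotation, diag(3), tolerance = 1e-9)

  # rigid invariance: rotated + translated copy superposes exactly
  for (k in 1:20) {
    tr <- random_rigid()
    y <- sweep(x %*% tr$rotation, 2, tr$translation, "+")
    expect_lt(kabsch_superpose(y, x)$rmsd, 1e-9)
    expect_lt(kabsch_superpose(x, y)$rmsd, 1e-9)
  }

  # symmetry with uniform weights
  y <- x + matrix(rnorm(30, sd = 0.4), 10, 3)
  expect_equal(kabsch_superpose(x, y)$rmsd, kabsch_superpose(y, x)$rmsd,
               tolerance = 1e-12)

  # 1000 random instances against the independent quaternion oracle
  worst <- 0
  for (k in 1:1000) {
    n <- sample(10:100, 1)
    a <- matrix(rnorm(3 * n, sd = 3), n, 3)
    b <- matrix(rnorm(3 * n, sd = 3), n, 3)
    w <- if (k %% 3 == 0) runif(n, 0.5, 2) else NULL
    worst <- max(worst, abs(kabsch_superpose(a, b, w)$rmsd -
                              quaternion_rmsd(a, b, w)))
  }
  expect_lt(worst, 1e-6)
})

test_that("degenerate superposition inputs are rejected", {
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "N >= 3")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
  x <- matrix(rnorm(30), 10, 3)
  expect_error(kabsch_superpose(x, x, weights = rep(-1, 10)), "positive")
})

test_that("RMSD series is zero for identical frames and under pure rigid motion", {
  ref <- build_helix("GACU")
  still <- make_noise_trajectory(ref, noise_spec(0, 4, seed = 1))
  expect_equal(rmsd_series(still)$values, rep(0, 4), tolerance = 1e-12)

  drift <- function(i) list(rotation = rot_axis(c(1, 2, 3), 10 * i),
                            translation = c(2 * i, -i, 0.5 * i))
  moving <- make_noise_trajectory(ref, noise_spec(0, 6, seed = 1,
                                                  drift = drift))
  raw_disp <- sqrt(mean((frame_coords_of(moving, 6) - coords(ref))^2))
  expect_gt(raw_disp, 1)  # large raw displacement...
  expect_lt(max(rmsd_series(moving)$values), 1e-9)  # ...fully removed by the fit
})

test_that("RMSD of seeded Gaussian noise matches the analytic expectation", {
  ref <- build_helix(aptamer_sequences()[["A6"]])  # ~1300 atoms
  sigma <- 0.5
  traj <- make_noise_trajectory(ref, noise_spec(sigma, 60, seed = 42))
  series <- rmsd_series(traj, mass_weighted = FALSE)
  n <- n_atoms(ref)
  analytic_nm <- sigma * sqrt(3) * sqrt(1 - 6 / (3 * n)) / 10
  expect_lt(abs(mean(series$values) / analytic_nm - 1), 0.05)

  # per-frame agreement with the quaternion oracle on the same frames
  for (i in c(1, 30, 60)) {
    q <- quaternion_rmsd(frame_coords_of(traj, i), coords(ref)) / 10
    expect_equal(series$values[i], q, tolerance = 1e-9)
  }
})

test_that("hydrogen-bond detection honours both geometric cutoffs", {
  mk <- function(da, hangle_offset = 0) {
    # donor O with H pointing at acceptor O at distance da (Angstrom)
    h <- c(0.96 * cos(hangle_offset * pi / 180),
           0.96 * sin(hangle_offset * pi / 180), 0)
    atoms <- data.frame(
      serial = 1:3, name = c("O1X", "H1X", "O2X"),
      element = c("O", "H", "O"), resid = c("X", "X", "Y"),
      chain = "A", resno = c(1L, 1L, 2L), ins = "",
      x = c(0, h[1], da), y = c(0, h[2], 0), z = 0)
    nuc_structure(atoms)
  }
  expect_identical(nrow(find_hbonds(mk(3.0))), 1L)       # inside both cutoffs
  expect_identical(nrow(find_hbonds(mk(3.6))), 0L)       # distance cutoff
  expect_identical(nrow(find_hbonds(mk(3.0, 45))), 0L)   # angle cutoff
  expect_identical(nrow(find_hbonds(mk(3.0, 25))), 1L)
})

test_that("the idealized Watson-Crick G-C pair shows exactly three bonds", {
  gc <- build_gc_pair()
  hb <- find_hbonds(gc)
  expect_identical(nrow(hb), 3L)
  expect_setequal(paste(hb$donor_name, hb$acceptor_name),
                  c("N4 O6", "N1 N3", "N2 O2"))
  # manual distance/angle verification straight from the coordinates
  xyz <- coords(gc)
  for (r in seq_len(nrow(hb))) {
    expect_lt(hb$distance_nm[r], 0.35)
    expect_lt(angle_deg(xyz[hb$hydrogen[r], ], xyz[hb$donor[r], ],
                        xyz[hb$acceptor[r], ]), 30)
  }
})

test_that("H-bond counts are rigid-invariant and monotone in the thresholds", {
  gc <- build_gc_pair()
  set.seed(9)
  for (k in 1:5) {
    tr <- random_rigid()
    moved <- gc
    newxyz <- sweep(coords(gc) %*% tr$rotation, 2, tr$translation, "+")
    moved$atoms$x <- newxyz[, 1]; moved$atoms$y <- newxyz[, 2]
    moved$atoms$z <- newxyz[, 3]
    expect_identical(nrow(find_hbonds(moved)), 3L)
  }
  counts_d <- vapply(c(0.35, 0.32, 0.30, 0.28, 0.25), function(d)
    nrow(find_hbonds(gc, hbond_criteria(max_da_dist = d))), integer(1))
  expect_true(all(diff(counts_d) <= 0))
  counts_a <- vapply(c(30, 20, 10, 5, 1, 0.5), function(a)
    nrow(find_hbonds(gc, hbond_criteria(max_hda_angle = a))), integer(1))
  expect_true(all(diff(counts_a) <= 0))
})

test_that("H-bond series follows separation events and warns without donors", {
  gc <- build_gc_pair()
  # frames 0..5; from frame 3 on, shift the cytosine 10 A away
  n <- n_atoms(gc)
  arr <- array(rep(coords(gc), each = 6), dim = c(6, n, 3))
  cyt <- gc$atoms$resid == "C"
  for (i in 4:6) arr[i, cyt, 1] <- arr[i, cyt, 1] + 10
  traj <- nuc_trajectory(gc, arr, times = 0:5)
  series <- hbond_series(traj)
  expect_identical(series$values, c(3, 3, 3, 0, 0, 0))

  # no donors: carbon-only structure
  atoms <- data.frame(serial = 1:3, name = c("C1X", "C2X", "C3X"),
                      element = "C", resid = "X", chain = "A",
                      resno = 1L, ins = "", x = c(0, 2, 4), y = 0, z = 0)
  s <- nuc_structure(atoms)
  expect_warning(hb <- find_hbonds(s), "donors")
  expect_identical(nrow(hb), 0L)
})

test_that("heavy-atom proxy mode counts template donors without hydrogens", {
  s <- build_helix("GCAU")  # no hydrogens anywhere
  crit <- hbond_criteria(heavy_only_mode = TRUE)
  hb <- find_hbonds(s, crit)
  expect_true(all(is.na(hb$hydrogen)))
  expect_true(all(hb$distance_nm <= 0.32 + 1e-12))
  traj <- make_noise_trajectory(s, noise_spec(0, 3, seed = 1))
  series <- hbond_series(traj, crit)
  expect_match(series$label, "proxy")
  expect_identical(length(unique(series$values)), 1L)
})

test_that("series summaries reproduce closed-form values", {
  s <- aptamer_series(0:2, c(1, 2, 3), units = "nm")
  sm <- summarize_series(s)
  expect_identical(sm$mean, 2)
  expect_identical(sm$sd, 1)
  expect_identical(sm$n, 3L)

  const <- aptamer_series(0:9, rep(4.2, 10), units = "count")
  smc <- summarize_series(const)
  expect_identical(smc$mean, 4.2)
  expect_identical(smc$sd, 0)

  # arithmetic sequence: exact closed form for mean and SD
  v <- seq(1, 21, by = 2)  # 11 terms, mean 11
  sma <- summarize_series(aptamer_series(seq_along(v), v, units = "count"))
  expect_equal(sma$mean, 11)
  expect_equal(sma$sd, sqrt(4 * sum((seq_along(v) - 6)^2) / 10))

  # discard_before drops the equilibration prefix
  sm2 <- summarize_series(aptamer_series(0:9, c(rep(100, 5), rep(2, 5))),
                          discard_before = 5)
  expect_identical(sm2$mean, 2)
  expect_identical(sm2$n, 5L)
  expect_error(summarize_series(aptamer_series(0:9, 0:9),
                                discard_before = 9.5), "fewer than 2")

  # sd of seeded noise recovers the generator sigma within 10%
  noise <- make_plateau_series(1, 1000, pre_slope = 0, noise_sd = 0.05,
                               seed = 3, baseline = 5)
  expect_lt(abs(summarize_series(noise)$sd / 0.05 - 1), 0.1)
})

test_that("plateau detection matches the exhaustive window-scan oracle", {
  cases <- list(
    make_plateau_series(75, 200, pre_slope = 0.01, noise_sd = 0),
    make_plateau_series(100, 200, pre_slope = 0.02, noise_sd = 0.01, seed = 5),
    make_plateau_series(40, 200, pre_slope = 0.05, noise_sd = 0),
    aptamer_series(0:200, rep(1, 201)),          # constant
    aptamer_series(0:200, 0.01 * (0:200)),        # monotone ramp
    make_plateau_series(199, 200, pre_slope = 0.05))  # onset = total - dt
  expected_none <- c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  for (i in seq_along(cases)) {
    got <- detect_plateau(cases[[i]])$onset_time
    oracle <- plateau_scan_oracle(cases[[i]], 20, 0.005, 0.1)
    expect_identical(is.na(got), expected_none[i])
    expect_identical(got, oracle)
  }
  # the 75-ns-onset scenario is recovered within one window
  on75 <- detect_plateau(cases[[1]])$onset_time
  expect_lte(abs(on75 - 75), 20)
  # constant series: onset at the first time point
  expect_identical(detect_plateau(cases[[4]])$onset_time, 0)
  expect_error(detect_plateau(aptamer_series(0:30, rep(1, 31))),
               "2 \\* window")
})

test_that("comparison grids arrange runs by molecule and metric", {
  mk <- function(mean, sd, units, label)
    structure(list(mean = mean, sd = sd, n = 100L, units = units,
                   label = label), class = "series_summary")
  sums <- list(mk(79.85, 5.02, "count", "A6 (300 K)"),
               mk(0.56, 0.11, "nm", "A6 (300 K)"),
               mk(59.15, 3.99, "count", "LN-A6 (300 K)"),
               mk(0.99, 0.12, "nm", "LN-A6 (300 K)"))
  tab <- compare_runs(sums)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$hb_mean, c(79.85, 59.15))
  expect_identical(tab$rmsd_sd, c(0.11, 0.12))

  expect_identical(nrow(compare_runs(sums[1])), 1L)
  expect_error(compare_runs(sums[c(1, 1)]), "duplicate")
  bad <- sums
  bad[[2]]$units <- "angstrom"
  expect_error(compare_runs(bad), "unit mismatch")
})
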