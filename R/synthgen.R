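# Fixture generation: idealized single-stranded helices built by stamping
# the residue templates along a helical axis, synthetic trajectories with
# known noise/drift ground truth, and piecewise plateau series.  These
# stand in for externally modelled aptamer structures and MD output, so
# every analysis path is testable with known answers.

#' Helical placement parameters
#'
#' @param form helix family: `"A"` (RNA-like; twist 32.7 deg/residue,
#'   rise 2.81 A) or `"B"` (DNA-like; twist 36.0, rise 3.38).
#' @param twist,rise override the per-residue twist (degrees, in (0, 60))
#'   and rise (Angstrom, > 0).
#' @param seed integer kept for interface stability; the builder is
#'   deterministic.
#' @return an object of class `helix_params`.
#' @export
helix_params <- function(form = c("A", "B"), twist = NULL, rise = NULL,
                         seed = 1L) {
  form <- match.arg(form)
  twist <- twist %||% if (form == "A") 32.7 else 36.0
  rise <- rise %||% if (form == "A") 2.81 else 3.38
  stopifnot(twist > 0, twist < 60, rise > 0)
  structure(list(form = form, twist = twist, rise = rise,
                 seed = as.integer(seed)), class = "helix_params")
}

# Rigid placement of the monomer template relative to the helix axis (z),
# chosen so that applying the helical symmetry operation (rotate by
# `twist`, rise along z) to the phosphorus of the next residue puts it at
# bond distance from O3'.  Solved once per (sugar, twist, rise) by
# direct numerical optimization over the 5 effective rigid degrees of
# freedom, then cached.
.helix_placement <- function(sugar, twist, rise) {
  key <- sprintf("place_%s_%.4f_%.4f", sugar, twist, rise)
  if (!is.null(.template_env[[key]])) return(.template_env[[key]])
  probe <- get_monomer(if (sugar == "ribose") "G" else "DG")$xyz
  nm <- rownames(probe)
  sym <- function(X) sweep(X %*% t(rot_z(twist)), 2, c(0, 0, rise), "+")
  # pairs across the backbone link excluded from the clash term (bonded
  # or separated by two bonds through the new O3'-P bond)
  link_excl <- rbind(
    cbind("O3'", c("P", "OP1", "OP2", "O5'")),
    cbind(c("C3'", "C2'", "C4'"), "P"))
  objective <- function(p) {
    R <- rot_axis(c(1, 0, 0), p[1]) %*% rot_axis(c(0, 1, 0), p[2]) %*%
      rot_z(p[3])
    X <- sweep(probe %*% t(R), 2, c(p[4], p[5], 0), "+")
    Y <- sym(X)
    dlink <- vnorm(Y[match("P", nm), ] - X[match("O3'", nm), ])
    obj <- 200 * (dlink - 1.60)^2
    a1 <- angle_deg(X[match("C3'", nm), ], X[match("O3'", nm), ],
                    Y[match("P", nm), ])
    a2 <- angle_deg(X[match("O3'", nm), ], Y[match("P", nm), ],
                    Y[match("O5'", nm), ])
    obj <- obj + 0.002 * ((a1 - 120)^2 + (a2 - 104)^2)
    for (Ynb in list(Y, sym(Y))) {
      dmat <- sqrt(pmax(0, outer(rowSums(X^2), rowSums(Ynb^2), "+") -
                          2 * X %*% t(Ynb)))
      if (identical(Ynb, Y)) {
        ii <- match(link_excl[, 1], nm)
        jj <- match(link_excl[, 2], nm)
        dmat[cbind(ii, jj)] <- 99
      }
      viol <- pmin(dmat, 2.7) - 2.7
      obj <- obj + 2 * sum(viol^2)
    }
    obj
  }
  best <- NULL
  for (rz0 in c(0, 90, 180, 270)) for (tx0 in c(4, 7, 10)) {
    p0 <- c(0, 0, rz0, tx0, 0)
    fit <- stats::optim(p0, objective, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  fit <- stats::optim(best$par, objective, method = "BFGS",
                      control = list(maxit = 500))
  if (fit$value < best$value) best <- fit
  p <- best$par
  R <- rot_axis(c(1, 0, 0), p[1]) %*% rot_axis(c(0, 1, 0), p[2]) %*%
    rot_z(p[3])
  place <- function(X) sweep(X %*% t(R), 2, c(p[4], p[5], 0), "+")
  X <- place(probe)
  Y <- sym(X)
  dlink <- vnorm(Y[match("P", nm), ] - X[match("O3'", nm), ])
  if (dlink < 1.45 || dlink > 1.75)
    stop("helix placement failed for twist ", twist, ", rise ", rise,
         ": O3'-P link ", round(dlink, 2), " Angstrom")
  out <- list(R = R, t = c(p[4], p[5], 0), link = dlink)
  .template_env[[key]] <- out
  out
}

.letter_to_code <- function(letters, dna) {
  map <- if (dna) c(A = "DA", C = "DC", G = "DG", T = "DT")
         else c(A = "A", C = "C", G = "G", U = "U")
  unname(map[letters])
}

#' Build an idealized single-stranded helix
#'
#' Stamps idealized nucleotide templates (C3'-endo ribose for RNA,
#' C2'-endo deoxyribose for DNA, planar bases) along a helical axis with
#' the given per-residue twist and rise.  The resulting strand has
#' consecutive O3'-P distances at bonding range and passes the residue
#' template validation; `sequence_of()` of the result round-trips the
#' input sequence.  Single-stranded only: no base pairing is modelled.
#'
#' @param seq sequence string over `A`,`C`,`G`,`U` (RNA) or `A`,`C`,`G`,`T`
#'   (DNA); mixing `U` and `T` is an error.  A sequence without `U`/`T`
#'   is built as RNA unless `params$form` is `"B"`.
#' @param params a [helix_params]; default: A-form for RNA, B-form for
#'   DNA.
#' @param hydrogens also place idealized hydrogens (default `FALSE`:
#'   heavy atoms only, as structure-prediction servers typically emit).
#' @param chain chain identifier.
#' @return a [nuc_structure] (all phosphates present, including 5').
#' @examples
#' s <- build_helix("ACGU")
#' sequence_of(s)
#' @export
build_helix <- function(seq, params = NULL, hydrogens = FALSE,
                        chain = "A") {
  stopifnot(is.character(seq), length(seq) == 1L)
  sq <- toupper(gsub("[[:space:]]", "", seq))
  if (!nzchar(sq)) stop("empty sequence")
  ch <- strsplit(sq, "")[[1]]
  bad <- setdiff(unique(ch), c("A", "C", "G", "U", "T"))
  if (length(bad))
    stop("invalid sequence character(s): ", paste(bad, collapse = ", "))
  if (all(c("U", "T") %in% ch))
    stop("sequence mixes U and T; build either RNA or DNA")
  dna <- "T" %in% ch || (!("U" %in% ch) && !is.null(params) &&
                           params$form == "B")
  params <- params %||% helix_params(if (dna) "B" else "A")
  codes <- .letter_to_code(ch, dna)
  sugar <- if (dna) "deoxyribose" else "ribose"
  pl <- .helix_placement(sugar, params$twist, params$rise)
  rows <- list()
  for (i in seq_along(codes)) {
    mono <- get_monomer(codes[i], hydrogens = hydrogens)
    X <- sweep(mono$xyz %*% t(pl$R), 2, pl$t, "+")
    X <- sweep(X %*% t(rot_z(params$twist * (i - 1))), 2,
               c(0, 0, params$rise * (i - 1)), "+")
    rownames(X) <- NULL
    rows[[i]] <- data.frame(
      serial = NA_integer_, name = rownames(mono$xyz),
      element = derive_element(rownames(mono$xyz)),
      resid = codes[i], chain = chain, resno = i, ins = "",
      x = X[, 1], y = X[, 2], z = X[, 3])
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  nuc_structure(atoms,
                title = sprintf("idealized %s-form single-stranded %s helix",
                                params$form, if (dna) "DNA" else "RNA"),
                dialect = "pdbv3")
}

#' Synthetic-trajectory noise specification
#'
#' @param sigma Gaussian noise standard deviation per coordinate,
#'   Angstrom (>= 0).
#' @param n_frames number of frames.
#' @param seed RNG seed; generation is bit-reproducible under a fixed
#'   seed.
#' @param drift optional per-frame rigid motion: `function(i)` returning
#'   `list(rotation = 3x3, translation = length-3)` applied to frame `i`
#'   (0-based) as `xyz %*% rotation + translation`.
#' @param dt frame spacing in ns (default 1; frame times are
#'   `0, dt, 2 dt, ...`).
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(sigma, n_frames, seed = 1L, drift = NULL, dt = 1) {
  stopifnot(sigma >= 0, n_frames >= 1, dt > 0)
  structure(list(sigma = sigma, n_frames = as.integer(n_frames),
                 seed = as.integer(seed), drift = drift, dt = dt),
            class = "noise_spec")
}

# run code with a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic noisy trajectory around a reference structure
#'
#' Frame i is the reference coordinates plus i.i.d. Gaussian noise of
#' standard deviation `spec$sigma` per coordinate, optionally composed
#' with a per-frame rigid drift.  Ground truth for testing RMSD recovery:
#' after superposition the expected mean square deviation per atom is
#' close to `3 sigma^2 (1 - 2/N)` (six rigid degrees of freedom are
#' absorbed by the fit).
#'
#' @param ref a [nuc_structure].
#' @param spec a [noise_spec].
#' @return a [nuc_trajectory] with frame times `0, dt, ...` ns.
#' @export
make_noise_trajectory <- function(ref, spec) {
  stopifnot(inherits(ref, "nuc_structure"), inherits(spec, "noise_spec"))
  base <- coords(ref)
  n <- nrow(base)
  arr <- array(NA_real_, dim = c(spec$n_frames, n, 3))
  .with_seed(spec$seed, {
    for (i in seq_len(spec$n_frames)) {
      X <- base + matrix(stats::rnorm(3 * n, sd = spec$sigma), n, 3)
      if (!is.null(spec$drift)) {
        d <- spec$drift(i - 1L)
        X <- sweep(X %*% d$rotation, 2, d$translation, "+")
      }
      arr[i, , ] <- X
    }
  })
  nuc_trajectory(ref, arr, times = (seq_len(spec$n_frames) - 1L) * spec$dt)
}

#' Generate a ramp-then-plateau series with known onset
#'
#' Linear ramp of slope `pre_slope` until `t_onset`, constant thereafter,
#' plus seeded Gaussian noise: the ground-truth scenario for plateau
#' detection.
#'
#' @param t_onset plateau onset time, ns, in (0, total).
#' @param total series length, ns.
#' @param dt sampling interval, ns (> 0).
#' @param pre_slope ramp slope before onset, units/ns (default 0.01).
#' @param noise_sd Gaussian noise SD (default 0).
#' @param seed RNG seed.
#' @param baseline value at time 0 (default 0.5).
#' @return an [aptamer_series] (units `"nm"`).
#' @export
make_plateau_series <- function(t_onset, total, dt = 1, pre_slope = 0.01,
                                noise_sd = 0, seed = 1L, baseline = 0.5) {
  if (dt <= 0) stop("dt must be positive")
  if (t_onset <= 0 || t_onset >= total)
    stop("t_onset must lie strictly inside (0, total)")
  tt <- seq(0, total, by = dt)
  vv <- baseline + pre_slope * pmin(tt, t_onset)
  if (noise_sd > 0)
    vv <- vv + .with_seed(seed, stats::rnorm(length(tt), sd = noise_sd))
  aptamer_series(tt, pmax(vv, 0), units = "nm",
                 label = sprintf("synthetic plateau (onset %g ns)", t_onset))
}

#' Idealized Watson-Crick G-C base-pair fixture
#'
#' Two planar bases (guanine and cytosine, with their polar hydrogens)
#' placed at standard Watson-Crick geometry: the cytosine is positioned
#' by least squares so that the three canonical hydrogen bonds
#' (O6...H41-N4, N1-H1...N3, N2-H21...O2) have the standard
#' donor-acceptor distances (2.91, 2.95, 2.86 Angstrom) with near-linear
#' hydrogen geometry.  A synthetic construct for exercising hydrogen-bond
#' detection; no sugars or backbone are included.
#'
#' @return a [nuc_structure] with two residues (G, C) in one chain.
#' @export
build_gc_pair <- function() {
  if (!is.null(.template_env[["gc_pair"]])) return(.template_env[["gc_pair"]])
  g2 <- .base_template_2d("guanine", hydrogens = TRUE)$xy
  c2 <- .base_template_2d("cytosine", hydrogens = TRUE)$xy
  targets <- list(  # donor res, donor, hydrogen, acceptor res, acceptor, D-A dist
    list("C", "N4", c("H41", "H42"), "G", "O6", 2.91),
    list("G", "N1", "H1", "C", "N3", 2.95),
    list("G", "N2", c("H21", "H22"), "C", "O2", 2.86))
  rot2 <- function(v, th) {
    t <- th * pi / 180
    cbind(cos(t) * v[, 1] - sin(t) * v[, 2],
          sin(t) * v[, 1] + cos(t) * v[, 2])
  }
  objective <- function(p) {
    cc <- sweep(rot2(c2, p[1]), 2, p[2:3], "+")
    rownames(cc) <- rownames(c2)
    obj <- 0
    for (tg in targets) {
      dxy <- if (tg[[1]] == "G") g2[tg[[2]], ] else cc[tg[[2]], ]
      axy <- if (tg[[4]] == "G") g2[tg[[5]], ] else cc[tg[[5]], ]
      obj <- obj + 50 * (vnorm(dxy - axy) - tg[[6]])^2
      angs <- vapply(tg[[3]], function(h) {
        hxy <- if (tg[[1]] == "G") g2[h, ] else cc[h, ]
        angle_deg(c(hxy, 0), c(dxy, 0), c(axy, 0))
      }, numeric(1))
      obj <- obj + 0.01 * min(angs)^2
    }
    # keep the two bases from overlapping
    dmat <- sqrt(pmax(0, outer(rowSums(g2^2), rowSums(cc^2), "+") -
                        2 * g2 %*% t(cc)))
    obj + 5 * sum((pmin(dmat, 2.6) - 2.6)^2)
  }
  best <- NULL
  for (th in seq(0, 330, by = 30)) {
    fit <- stats::optim(c(th, 6, 0), objective, method = "Nelder-Mead",
                        control = list(maxit = 3000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  cc <- sweep(rot2(c2, best$par[1]), 2, best$par[2:3], "+")
  rownames(cc) <- rownames(c2)
  mk <- function(xy, code, resno) {
    data.frame(serial = NA_integer_, name = rownames(xy),
               element = derive_element(rownames(xy)), resid = code,
               chain = "A", resno = resno, ins = "",
               x = xy[, 1], y = xy[, 2], z = 0)
  }
  atoms <- rbind(mk(g2, "G", 1L), mk(cc, "C", 2L))
  atoms$serial <- seq_len(nrow(atoms))
  s <- nuc_structure(atoms, title = "idealized Watson-Crick G-C pair (synthetic)")
  .template_env[["gc_pair"]] <- s
  s
}
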