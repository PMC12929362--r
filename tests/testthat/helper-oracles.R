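# Independent oracles used to cross-check the package's own algorithms.
# These deliberately use different mathematics than the implementation
# (quaternion eigen-decomposition vs SVD Kabsch; brute-force window scan
# vs incremental plateau search; per-character lookup vs regex).

# Quaternion-method optimal superposition RMSD (Horn's closed form): the
# optimal rotation maximizes the largest eigenvalue of the 4x4 key matrix.
quaternion_rmsd <- function(mobile, reference, weights = NULL) {
  n <- nrow(mobile)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  m <- sweep(mobile, 2, colSums(mobile * w))
  r <- sweep(reference, 2, colSums(reference * w))
  S <- t(m * w) %*% r
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- sum(w * rowSums(m^2)) + sum(w * rowSums(r^2)) - 2 * lambda
  sqrt(max(0, msd))
}

# Exhaustive plateau-onset scan: for every candidate start index, check
# every window (quadratic; no early exit logic shared with the package).
plateau_scan_oracle <- function(series, window, slope_tol, fluctuation_tol) {
  tt <- series$times; vv <- series$values
  starts <- which(tt + window <= max(tt) + 1e-9)
  ok <- vapply(starts, function(j) {
    sel <- which(tt >= tt[j] - 1e-9 & tt <= tt[j] + window + 1e-9)
    if (length(sel) < 2) return(TRUE)
    fit <- stats::lm(vv[sel] ~ tt[sel])
    abs(stats::coef(fit)[2]) <= slope_tol &&
      stats::sd(vv[sel]) <= fluctuation_tol
  }, logical(1))
  for (i in seq_along(tt)) {
    cand <- which(starts >= i)
    if (!length(cand)) return(NA_real_)
    if (all(ok[cand])) return(tt[i])
  }
  NA_real_
}

# Per-character U->T map, independent of the implementation's regex path.
char_map_convert <- function(s) {
  ch <- strsplit(gsub("[[:space:]]", "", toupper(s)), "")[[1]]
  paste(vapply(ch, function(x) if (x == "U") "T" else x, character(1)),
        collapse = "")
}

# internal geometry helpers reused by the tests
vnorm <- aptaconv:::vnorm
angle_deg <- aptaconv:::angle_deg
frame_coords_of <- aptaconv:::frame_coords

# random rigid transform (proper rotation + translation)
random_rigid <- function() {
  ax <- stats::rnorm(3)
  list(rotation = rot_axis(ax, stats::runif(1, 0, 360)),
       translation = stats::rnorm(3, sd = 10))
}

# shared-atom coordinate pairing between two structures, keyed by
# chain/residue/atom name
shared_coords <- function(s1, s2) {
  k1 <- paste(s1$atoms$chain, s1$atoms$resno, s1$atoms$name)
  k2 <- paste(s2$atoms$chain, s2$atoms$resno, s2$atoms$name)
  shared <- intersect(k1, k2)
  list(a = coords(s1)[match(shared, k1), , drop = FALSE],
       b = coords(s2)[match(shared, k2), , drop = FALSE],
       keys = shared)
}
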