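# Small 3D geometry kernel shared by the structure-editing and analysis code.
# All coordinates are Cartesian, in Angstrom, stored as plain numeric vectors
# or N x 3 matrices.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle at vertex b of the triple a-b-c, in degrees
#' @noRd
angle_deg <- function(a, b, c) {
  u <- unitv(a - b)
  v <- unitv(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Dihedral a-b-c-d in degrees, IUPAC sign convention
#' @noRd
dihedral_deg <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Natural extension reference frame placement: position atom D given
# positions of A, B, C, the bond length C-D, the angle B-C-D (deg) and the
# torsion A-B-C-D (deg).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  c + bc * d2[1] + m * d2[2] + n * d2[3]
}

rot_z <- function(theta_deg) {
  t <- theta_deg * pi / 180
  matrix(c(cos(t), -sin(t), 0,
           sin(t),  cos(t), 0,
           0,       0,      1), 3, 3, byrow = TRUE)
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis length-3 axis vector (need not be unit length).
#' @param theta_deg rotation angle in degrees.
#' @return 3 x 3 proper rotation matrix (apply as `xyz %*% rot_axis(...)`).
#' @export
rot_axis <- function(axis, theta_deg) {
  u <- unitv(axis)
  t <- theta_deg * pi / 180
  ct <- cos(t); st <- sin(t)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), 3, 3, byrow = TRUE)
}

# Best-fit plane through a point cloud (>= 3 points).  Returns the centroid,
# unit normal, and per-point out-of-plane deviations.
best_fit_plane <- function(xyz) {
  stopifnot(nrow(xyz) >= 3)
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  normal <- sv$v[, 3]
  dev <- as.vector(sweep(xyz, 2, ctr) %*% normal)
  list(center = ctr, normal = normal, dev = dev,
       max_dev = max(abs(dev)), rms_dev = sqrt(mean(dev^2)))
}

# Standard atomic masses (u) for the elements that occur in nucleic acids.
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     P = 30.974, S = 32.06, NA_ = 22.990, CL = 35.45,
                     MG = 24.305, K = 39.098)

element_mass <- function(element) {
  el <- toupper(element)
  el[el == "NA"] <- "NA_"
  m <- .element_masses[el]
  m[is.na(m)] <- 12.011  # unknown elements treated as carbon-like
  unname(m)
}

# Derive the chemical element from a PDB atom name when the element column
# is absent.  Nucleic-acid names start with the element letter, optionally
# preceded by a digit in old hydrogen names like "1H5'".
derive_element <- function(name) {
  vapply(name, function(nm) {
    nm <- gsub("[*']", "", nm)
    nm <- sub("^[0-9]+", "", nm)
    if (nchar(nm) == 0L) return("X")
    toupper(substr(nm, 1L, 1L))
  }, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
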