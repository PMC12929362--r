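# Optimal rigid-body superposition (Kabsch) and RMSD time series.  The
# superposition solves the weighted least-squares problem for the proper
# rotation (reflections excluded by determinant correction) and reports
# the post-fit weighted RMSD, the descriptor used to follow aptamer
# conformational drift along a trajectory.

#' Kabsch superposition of two coordinate sets
#'
#' Finds the weighted least-squares optimal rigid transform (proper
#' rotation plus translation) superposing `mobile` onto `reference`, and
#' the post-fit weighted RMSD.  Reflections are excluded via the
#' determinant correction, so the returned rotation is always proper.
#'
#' @param mobile,reference N x 3 coordinate matrices (N >= 3), same atom
#'   ordering.
#' @param weights per-atom positive weights (e.g. masses); uniform when
#'   omitted.
#' @return list with `rotation` (3 x 3), `translation` (length 3; the
#'   fitted coordinates are `mobile %*% rotation + translation`), and
#'   `rmsd` (same length units as the input).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(30), 10, 3)
#' r <- kabsch_superpose(x %*% rot_axis(c(1, 1, 0), 40) + 5, x)
#' r$rmsd  # ~0
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n < 3 || nrow(reference) != n || ncol(mobile) != 3 ||
      ncol(reference) != 3)
    stop("need matching N x 3 coordinate sets with N >= 3")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights <= 0))
    stop("weights must be positive, one per atom")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  m <- sweep(mobile, 2, cm)
  r <- sweep(reference, 2, cr)
  # degenerate (collinear or coincident) point sets have rank < 2
  span <- svd(m * sqrt(w))$d
  if (span[2] < max(span[1], 1e-8) * 1e-8)
    stop("degenerate (collinear) coordinates: rotation is not determined")
  cov <- t(m * w) %*% r
  sv <- svd(cov)
  d <- sign(det(sv$v %*% t(sv$u)))
  corr <- diag(c(1, 1, d))
  rot <- sv$u %*% corr %*% t(sv$v)
  fitted <- m %*% rot
  rmsd <- sqrt(sum(w * rowSums((fitted - r)^2)))
  list(rotation = rot, translation = as.vector(cr - cm %*% rot), rmsd = rmsd)
}

# resolve an atom selection against an atom table: NULL (all), logical,
# integer indices, or a predicate function(atoms) -> logical
resolve_selection <- function(atoms, selection) {
  if (is.null(selection)) return(seq_len(nrow(atoms)))
  if (is.function(selection)) selection <- selection(atoms)
  if (is.logical(selection)) {
    stopifnot(length(selection) == nrow(atoms))
    return(which(selection))
  }
  as.integer(selection)
}

#' RMSD time series of a trajectory against a reference structure
#'
#' Each frame is superposed onto the fixed reference over the selected
#' atoms ([kabsch_superpose]) and the post-fit RMSD recorded.  The default
#' is a mass-weighted fit and mass-weighted RMSD over all atoms, the
#' common convention of MD analysis tools; output is in nanometres.
#'
#' @param traj a [nuc_trajectory].
#' @param reference a [nuc_structure] with the same atom ordering as the
#'   trajectory topology (defaults to the topology itself).
#' @param selection `NULL` (all atoms), a logical/integer vector over the
#'   topology atoms, or a predicate `function(atoms)` returning a logical
#'   vector.  Must resolve to at least 3 atoms.
#' @param mass_weighted use atomic masses as fit/RMSD weights (default
#'   `TRUE`).
#' @return an [aptamer_series] with units `"nm"`.
#' @export
rmsd_series <- function(traj, reference = NULL, selection = NULL,
                        mass_weighted = TRUE) {
  stopifnot(inherits(traj, "nuc_trajectory"))
  topo <- traj$topology
  if (is.null(reference)) reference <- topo
  stopifnot(inherits(reference, "nuc_structure"))
  sel <- resolve_selection(topo$atoms, selection)
  if (length(sel) < 3)
    stop("selection resolves to fewer than 3 atoms")
  if (n_atoms(reference) != n_atoms(topo))
    stop("reference and topology atom counts differ (",
         n_atoms(reference), " vs ", n_atoms(topo), ")")
  refxyz <- coords(reference)[sel, , drop = FALSE]
  wts <- if (mass_weighted) element_mass(topo$atoms$element[sel]) else NULL
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    kabsch_superpose(frame_coords(traj, i)[sel, , drop = FALSE],
                     refxyz, wts)$rmsd
  }, numeric(1))
  aptamer_series(traj$times, vals / 10, units = "nm",
                 label = "RMSD vs reference")
}
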