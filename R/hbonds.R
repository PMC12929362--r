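# Geometric intramolecular hydrogen-bond detection.  The default criteria
# follow the common MD-analysis convention: donor-acceptor distance at
# most 0.35 nm and hydrogen-donor-acceptor angle at most 30 degrees,
# donors being N/O atoms carrying a hydrogen and acceptors any N/O.  For
# heavy-atom-only models a distance-only proxy is provided (donors taken
# from the residue-template classification), clearly labelled as such.

#' Hydrogen-bond detection criteria
#'
#' @param max_da_dist maximum donor-acceptor distance, nm (default 0.35).
#' @param max_hda_angle maximum hydrogen-donor-acceptor angle, degrees
#'   (default 30).
#' @param heavy_only_mode for hydrogen-free models: count donor-acceptor
#'   pairs at most `heavy_da_dist` apart with no angle term, donors taken
#'   from the residue template classification.  This proxy count is not
#'   comparable to hydrogen-aware counts.
#' @param heavy_da_dist distance cutoff used in heavy-only mode, nm
#'   (default 0.32).
#' @return an object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_da_dist = 0.35, max_hda_angle = 30,
                           heavy_only_mode = FALSE, heavy_da_dist = 0.32) {
  stopifnot(max_da_dist > 0, max_hda_angle > 0, max_hda_angle <= 90,
            heavy_da_dist > 0)
  structure(list(max_da_dist = max_da_dist, max_hda_angle = max_hda_angle,
                 heavy_only_mode = heavy_only_mode,
                 heavy_da_dist = heavy_da_dist),
            class = "hbond_criteria")
}

# Covalent bond inference by interatomic distance: heavy-heavy pairs
# within 1.8 A, hydrogen-heavy within 1.25 A.  Returns a 2-column index
# matrix.  O(N^2) but computed once per topology.
infer_bonds <- function(xyz, element) {
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), 0, 2))
  d <- as.matrix(stats::dist(xyz))
  ish <- element == "H"
  cut <- matrix(1.8, n, n)
  cut[ish, ] <- 1.25
  cut[, ish] <- 1.25
  cut[ish, ish] <- 0  # no H-H bonds
  hit <- which(d < cut & upper.tri(d), arr.ind = TRUE)
  unname(as.matrix(hit))
}

# adjacency list from a bond index matrix
.adjacency <- function(bonds, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# per-topology donor/acceptor tables, computed once and reused per frame
hbond_topology <- function(s, criteria) {
  a <- s$atoms
  nm <- atom_name_to_dialect(a$name, "pdbv3")
  el <- a$element
  xyz <- coords(s)
  bonds <- infer_bonds(xyz, el)
  adj <- .adjacency(bonds, nrow(a))
  acceptors <- which(el %in% c("N", "O"))
  if (criteria$heavy_only_mode) {
    tmpl <- residue_templates()
    donors <- which(vapply(seq_len(nrow(a)), function(i) {
      t <- tmpl[[a$resid[i]]]
      !is.null(t) && nm[i] %in% t$donors
    }, logical(1)))
    dh <- data.frame(donor = donors, hydrogen = NA_integer_)
  } else {
    no <- which(el %in% c("N", "O"))
    dh <- do.call(rbind, lapply(no, function(i) {
      hs <- adj[[i]][el[adj[[i]]] == "H"]
      if (length(hs)) data.frame(donor = i, hydrogen = hs) else NULL
    }))
    if (is.null(dh))
      dh <- data.frame(donor = integer(0), hydrogen = integer(0))
  }
  # exclusion: partners within <= 2 covalent bonds of the donor
  excl <- lapply(seq_len(nrow(a)), function(i) {
    n1 <- adj[[i]]
    unique(c(i, n1, unlist(adj[n1])))
  })
  list(dh = dh, acceptors = acceptors, excl = excl, names = nm,
       resno = a$resno, chain = a$chain)
}

#' Find intramolecular hydrogen bonds in one structure/frame
#'
#' Applies the geometric criteria to all donor/acceptor pairs: donors are
#' N/O atoms with a covalently attached hydrogen (or template-classified
#' donors in heavy-only mode), acceptors any N/O; pairs closer than three
#' covalent bonds are excluded; the list is deduplicated per
#' donor/hydrogen/acceptor triple.
#'
#' @param s a [nuc_structure] (topology + one frame of coordinates).
#' @param criteria an [hbond_criteria].
#' @param topology_info cached result of the internal topology scan; when
#'   analysing many frames of one topology pass the same object to avoid
#'   recomputation (see [hbond_series]).
#' @return data frame with columns `donor`, `hydrogen` (`NA` in
#'   heavy-only mode), `acceptor` (atom indices), plus `donor_name`,
#'   `acceptor_name`, `distance_nm`, `angle_deg`.
#' @export
find_hbonds <- function(s, criteria = hbond_criteria(),
                        topology_info = NULL) {
  stopifnot(inherits(s, "nuc_structure"))
  info <- topology_info %||% hbond_topology(s, criteria)
  xyz <- coords(s)
  .find_hbonds_xyz(xyz, info, criteria, warn = TRUE)
}

.find_hbonds_xyz <- function(xyz, info, criteria, warn = FALSE) {
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), donor_name = character(0),
                      acceptor_name = character(0),
                      distance_nm = numeric(0), angle_deg = numeric(0))
  if (nrow(info$dh) == 0L || length(info$acceptors) == 0L) {
    if (warn) warning("no donors or no acceptors found; empty bond list")
    return(empty)
  }
  cut_a <- (if (criteria$heavy_only_mode) criteria$heavy_da_dist
            else criteria$max_da_dist) * 10  # nm -> Angstrom
  dunique <- unique(info$dh$donor)
  dxyz <- xyz[dunique, , drop = FALSE]
  axyz <- xyz[info$acceptors, , drop = FALSE]
  # donor-acceptor distance matrix
  dd <- outer(rowSums(dxyz^2), rowSums(axyz^2), "+") -
    2 * dxyz %*% t(axyz)
  dd[dd < 0] <- 0
  dd <- sqrt(dd)
  res <- list()
  for (di in seq_along(dunique)) {
    d <- dunique[di]
    ok <- which(dd[di, ] <= cut_a)
    acc <- info$acceptors[ok]
    acc <- setdiff(acc, info$excl[[d]])
    if (!length(acc)) next
    if (criteria$heavy_only_mode) {
      res[[length(res) + 1L]] <- data.frame(
        donor = d, hydrogen = NA_integer_, acceptor = acc,
        distance_nm = dd[di, match(acc, info$acceptors)] / 10,
        angle_deg = NA_real_)
    } else {
      hs <- info$dh$hydrogen[info$dh$donor == d]
      for (h in hs) {
        ang <- vapply(acc, function(a2)
          angle_deg(xyz[h, ], xyz[d, ], xyz[a2, ]), numeric(1))
        keep <- ang <= criteria$max_hda_angle
        if (any(keep))
          res[[length(res) + 1L]] <- data.frame(
            donor = d, hydrogen = h, acceptor = acc[keep],
            distance_nm = dd[di, match(acc[keep], info$acceptors)] / 10,
            angle_deg = ang[keep])
      }
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[!duplicated(out[, c("donor", "hydrogen", "acceptor")]), ,
             drop = FALSE]
  out$donor_name <- info$names[out$donor]
  out$acceptor_name <- info$names[out$acceptor]
  rownames(out) <- NULL
  out[, c("donor", "hydrogen", "acceptor", "donor_name", "acceptor_name",
          "distance_nm", "angle_deg")]
}

#' Hydrogen-bond count time series over a trajectory
#'
#' Counts [find_hbonds] results per frame.  The covalent topology and
#' donor/acceptor classification are derived once from the topology
#' structure and reused for every frame.
#'
#' @param traj a [nuc_trajectory].
#' @param criteria an [hbond_criteria].
#' @return an [aptamer_series] with units `"count"` (label marks the
#'   heavy-only proxy mode when active).
#' @export
hbond_series <- function(traj, criteria = hbond_criteria()) {
  stopifnot(inherits(traj, "nuc_trajectory"))
  topo <- traj$topology
  info <- hbond_topology(topo, criteria)
  if (nrow(info$dh) == 0L || length(info$acceptors) == 0L)
    warning("no donors or no acceptors in topology; all counts are zero")
  vals <- vapply(seq_len(n_frames(traj)), function(i)
    nrow(.find_hbonds_xyz(frame_coords(traj, i), info, criteria)),
    numeric(1))
  aptamer_series(traj$times, vals, units = "count",
                 label = if (criteria$heavy_only_mode)
                   "intramolecular H-bonds (heavy-atom proxy)"
                 else "intramolecular H-bonds")
}
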