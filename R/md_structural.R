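#' Ordered coordinate frames with atom metadata
#'
#' Container for trajectory post-processing: a list of per-frame coordinate
#' matrices (n_atoms x 3, Angstrom) plus an atom table carrying residue
#' number, residue name, atom name and chain, as found in PDB records.
#'
#' @param coords List of n_atoms x 3 numeric matrices, one per frame, all
#'   with the same atom count.
#' @param atoms Data frame with columns `resno`, `resid` (residue name),
#'   `elety` (atom name) and optionally `chain`, one row per atom.
#' @param frame_interval Time between frames in ns (metadata only).
#' @return An object of class `frame_series`.
#' @export
frame_series <- function(coords, atoms, frame_interval = NA_real_) {
  stopifnot(is.list(coords), length(coords) >= 1, is.data.frame(atoms),
            all(c("resno", "resid", "elety") %in% names(atoms)))
  n_atoms <- nrow(atoms)
  ok <- vapply(coords, function(m) {
    is.matrix(m) && nrow(m) == n_atoms && ncol(m) == 3 && all(is.finite(m))
  }, logical(1))
  if (!all(ok)) stop("all frames must be finite n_atoms x 3 matrices")
  if (!"chain" %in% names(atoms)) atoms$chain <- "A"
  structure(list(coords = coords, atoms = atoms,
                 frame_interval = frame_interval),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("Frame series: %d frames x %d atoms (%d residues)\n",
              length(x$coords), nrow(x$atoms), length(unique(x$atoms$resno))))
  invisible(x)
}

#' Drop the equilibration portion of a trajectory
#'
#' Removes the leading fraction of frames before analysis - the usual
#' treatment of the equilibration phase of an MD replicate (e.g. the first
#' 50 ns of a 350 ns run is fraction 1/7). Expressed as a fraction because
#' frame intervals differ between datasets.
#'
#' @param traj A [frame_series].
#' @param fraction Fraction of initial frames to discard, in \[0, 1).
#' @return A [frame_series] with the remaining frames.
#' @export
discard_equilibration <- function(traj, fraction = 1 / 7) {
  stopifnot(inherits(traj, "frame_series"),
            is.numeric(fraction), fraction >= 0, fraction < 1)
  n <- length(traj$coords)
  drop <- floor(n * fraction)
  if (n - drop < 1) stop("discarding would leave no frames")
  traj$coords <- traj$coords[(drop + 1):n]
  traj
}

#' Select atoms with a small selection language
#'
#' Supports conjunctions of clauses joined by `and`, each clause being a
#' keyword followed by one or more values: `resid` (residue numbers),
#' `name` (atom names), `chain` (chain identifiers), e.g.
#' `"resid 160 and name OD1 OD2 CG"`.
#'
#' @param traj A [frame_series].
#' @param selection Selection string, or a numeric vector of atom indices
#'   (returned unchanged after validation).
#' @return Integer vector of atom indices.
#' @export
select_atoms <- function(traj, selection) {
  stopifnot(inherits(traj, "frame_series"))
  n <- nrow(traj$atoms)
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
    if (any(idx < 1 | idx > n)) stop("atom index out of range")
    return(idx)
  }
  stopifnot(is.character(selection), length(selection) == 1)
  keep <- rep(TRUE, n)
  for (clause in strsplit(selection, "\\s+and\\s+")[[1]]) {
    tok <- strsplit(trimws(clause), "\\s+")[[1]]
    if (length(tok) < 2) stop(sprintf("malformed selection clause: '%s'", clause))
    key <- tok[1]; vals <- tok[-1]
    keep <- keep & switch(key,
      resid = traj$atoms$resno %in% as.integer(vals),
      name = traj$atoms$elety %in% vals,
      chain = traj$atoms$chain %in% vals,
      stop(sprintf("unknown selection keyword '%s'", key))
    )
  }
  idx <- which(keep)
  if (length(idx) == 0) stop(sprintf("selection '%s' matches no atoms", selection))
  idx
}

# Center of mass of a selection in one frame (unit masses by default).
.com <- function(xyz, idx, masses = NULL) {
  m <- if (is.null(masses)) rep(1, length(idx)) else masses[idx]
  colSums(xyz[idx, , drop = FALSE] * m) / sum(m)
}

#' Per-frame distance between centers of mass of two atom groups
#'
#' The standard operational definition of a salt-bridge coordinate: the
#' distance between the centers of mass of the two charged moieties (e.g.
#' the Asp carboxylate OD1/OD2/CG and the Arg guanidinium NH1/NH2/NE/CZ),
#' with unit atom masses unless masses are supplied.
#'
#' @param traj A [frame_series].
#' @param sel_a,sel_b Selections (see [select_atoms()]).
#' @param masses Optional per-atom masses.
#' @return Numeric vector of distances (Angstrom), one per frame.
#' @export
group_distance_series <- function(traj, sel_a, sel_b, masses = NULL) {
  ia <- select_atoms(traj, sel_a)
  ib <- select_atoms(traj, sel_b)
  vapply(traj$coords, function(xyz) {
    sqrt(sum((.com(xyz, ia, masses) - .com(xyz, ib, masses))^2))
  }, numeric(1))
}

#' Normalised distance distribution
#'
#' Histogram of a distance series with fixed bin width; bin masses sum
#' to 1.
#'
#' @param series Distance series (Angstrom).
#' @param bin_width Bin width in Angstrom.
#' @return Data frame with `mid` (bin centre, Angstrom) and `p` (bin
#'   probability mass).
#' @export
distance_distribution <- function(series, bin_width = 0.25) {
  stopifnot(is.numeric(series), length(series) >= 10, bin_width > 0)
  lo <- floor(min(series) / bin_width) * bin_width
  breaks <- seq(lo, max(series) + bin_width, by = bin_width)
  h <- graphics::hist(series, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, p = h$counts / length(series))
}

#' Salt-bridge occupancy
#'
#' Fraction of frames in which the group-group distance is at or below a
#' contact threshold; 4 Angstrom is the conventional cutoff for a formed
#' salt bridge between side-chain charge centers.
#'
#' @param series Distance series (Angstrom).
#' @param threshold Contact threshold (Angstrom).
#' @return Fraction in \[0, 1\].
#' @export
salt_bridge_occupancy <- function(series, threshold = 4.0) {
  stopifnot(is.numeric(series), length(series) >= 1, threshold > 0)
  mean(series <= threshold)
}

#' Time-averaged density profile along the membrane normal
#'
#' Histogram of the z coordinates of a selection pooled over frames,
#' normalised to a peak of 1 - the usual way to visualise how far S4
#' arginines sit along the membrane normal in different activation states.
#' The membrane normal is assumed to be the z axis.
#'
#' @param traj A [frame_series].
#' @param selection Atom selection.
#' @param bin_width Bin width in Angstrom.
#' @return Data frame with `z` (bin centre) and `density` (peak-normalised).
#' @export
z_density_profile <- function(traj, selection, bin_width = 0.5) {
  idx <- select_atoms(traj, selection)
  zs <- unlist(lapply(traj$coords, function(xyz) xyz[idx, 3]))
  lo <- floor(min(zs) / bin_width) * bin_width
  breaks <- seq(lo, max(zs) + bin_width, by = bin_width)
  h <- graphics::hist(zs, breaks = breaks, plot = FALSE)
  data.frame(z = h$mids, density = h$counts / max(h$counts))
}

#' Time-averaged screened Coulomb energy of a charged pair
#'
#' `E = k_C q_a q_b / (eps_r r)` averaged over frames, with
#' `k_C = 332.0637 kcal Angstrom / (mol e0^2)`. This is a deliberately
#' simple point-charge estimate of salt-bridge strength; the relative
#' dielectric `eps_r` must be chosen explicitly by the caller.
#'
#' @param distance_series Per-frame distances (Angstrom), all positive.
#' @param q_a,q_b Group charges in elementary charges.
#' @param epsilon_r Relative dielectric constant (> 0).
#' @return Mean energy in kcal/mol.
#' @examples
#' coulomb_energy(4, q_a = 1, q_b = -1, epsilon_r = 1)  # about -83.0
#' @export
coulomb_energy <- function(distance_series, q_a, q_b, epsilon_r) {
  stopifnot(is.numeric(distance_series), length(distance_series) >= 1,
            is.numeric(epsilon_r), epsilon_r > 0)
  if (any(distance_series <= 0)) {
    stop("singular frame: zero or negative pair distance")
  }
  mean(.coulomb_const_kcalA * q_a * q_b / (epsilon_r * distance_series))
}

#' Triad interaction energy for one state and variant
#'
#' Bundles the three pairwise Coulomb terms of the
#' D160-R258 / D160-R261 / R261-R258 triad for one structural state (A_I
#' or A_F) of one variant; the total is their sum.
#'
#' @param pair_energies Named numeric vector of the three pair energies
#'   (kcal/mol).
#' @param state `"A_I"` or `"A_F"`.
#' @param variant Variant label (e.g. `"WT"`, `"N264R"`).
#' @return An object of class `triad_energy`.
#' @export
triad_energy <- function(pair_energies, state, variant) {
  stopifnot(is.numeric(pair_energies), length(pair_energies) == 3,
            state %in% c("A_I", "A_F"))
  structure(list(pair_energies = pair_energies,
                 total = sum(pair_energies),
                 state = state, variant = variant),
            class = "triad_energy")
}

#' Thermodynamic-cycle energy difference between activation states
#'
#' Given triad energies for the intermediate-active (A_I) and fully-active
#' (A_F) states of a variant and of a reference, computes the transition
#' energy `dE = E(A_I) - E(A_F)` per construct and the cycle difference
#' `ddE = dE_variant - dE_reference`. A positive `ddE` means the variant
#' pays extra electrostatic energy to leave the intermediate state - the
#' signature of salt-bridge-mediated trapping.
#'
#' @param variant_ai,variant_af,reference_ai,reference_af [triad_energy]
#'   objects for the four corners of the cycle.
#' @return List with `de_variant`, `de_reference`, `dde` (kcal/mol).
#' @export
cycle_energy <- function(variant_ai, variant_af, reference_ai, reference_af) {
  tri <- list(variant_ai, variant_af, reference_ai, reference_af)
  if (!all(vapply(tri, inherits, logical(1), "triad_energy"))) {
    stop("all four corners of the cycle must be triad_energy objects")
  }
  if (variant_ai$state != "A_I" || reference_ai$state != "A_I" ||
      variant_af$state != "A_F" || reference_af$state != "A_F") {
    stop("state labels do not match cycle corners")
  }
  de_v <- variant_ai$total - variant_af$total
  de_r <- reference_ai$total - reference_af$total
  list(de_variant = de_v, de_reference = de_r, dde = de_v - de_r)
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares superposition of one coordinate set onto another over a
#' selection, returning the rotation, translation and minimal RMSD. The
#' rotation is constrained to be proper (determinant +1).
#'
#' @param frame_a,frame_b n x 3 coordinate matrices (mobile, reference).
#' @param idx Optional atom indices over which to superpose (default all).
#' @return List with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `frame_a %*% rotation + translation`), and `rmsd`
#'   (Angstrom over the selection).
#' @export
kabsch_superpose <- function(frame_a, frame_b, idx = NULL) {
  stopifnot(is.matrix(frame_a), is.matrix(frame_b),
            ncol(frame_a) == 3, ncol(frame_b) == 3,
            nrow(frame_a) == nrow(frame_b))
  if (is.null(idx)) idx <- seq_len(nrow(frame_a))
  A <- frame_a[idx, , drop = FALSE]
  B <- frame_b[idx, , drop = FALSE]
  if (nrow(A) < 3) stop("need at least 3 atoms for a superposition")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  if (qr(A0)$rank < 2) stop("degenerate geometry: selection is collinear")
  H <- crossprod(A0, B0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  R <- t(R)  # so that row-vector coordinates transform as x %*% R
  tr <- cb - as.vector(ca %*% R)
  moved <- sweep(A %*% R, 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

#' Cluster trajectory frames by conformation
#'
#' Superposes every frame onto the first frame over the C-alpha atoms
#' (removing global rotation/translation), then runs k-means on the
#' flattened C-alpha coordinates - Euclidean distance in that space is
#' proportional to C-alpha RMSD. Each cluster is represented by the frame
#' closest to its mean. Deterministic under a fixed seed.
#'
#' @param traj A [frame_series].
#' @param k Number of clusters (1 <= k <= n_frames).
#' @param seed Integer seed for the k-means initialisation.
#' @param selection Atom selection used as the clustering coordinate set
#'   (default `"name CA"`).
#' @return List with `labels` (cluster id per frame), `centroid_frames`
#'   (representative frame index per cluster), `sizes`.
#' @export
cluster_frames <- function(traj, k, seed = 1, selection = "name CA") {
  stopifnot(inherits(traj, "frame_series"), k >= 1)
  n <- length(traj$coords)
  if (k > n) stop("k exceeds the number of frames")
  idx <- select_atoms(traj, selection)
  ref <- traj$coords[[1]]
  X <- t(vapply(traj$coords, function(xyz) {
    fit <- kabsch_superpose(xyz, ref, idx)
    as.vector(sweep(xyz[idx, , drop = FALSE] %*% fit$rotation, 2,
                    fit$translation, "+"))
  }, numeric(3 * length(idx))))
  km <- withr::with_seed(seed,
    stats::kmeans(X, centers = min(k, nrow(unique(X))), nstart = 10))
  labels <- km$cluster
  centroid_frames <- vapply(seq_len(max(labels)), function(cl) {
    members <- which(labels == cl)
    d2 <- rowSums((X[members, , drop = FALSE] -
                     matrix(km$centers[cl, ], length(members),
                            ncol(X), byrow = TRUE))^2)
    members[which.min(d2)]
  }, integer(1))
  list(labels = labels, centroid_frames = centroid_frames,
       sizes = as.vector(km$size))
}
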