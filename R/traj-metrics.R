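# Trajectory statistics: rigid-body superposition, RMSD/RMSF, backbone
# distance patterns, geometric hydrogen-bond detection and interaction
# distance classification.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation + translation of `mobile` onto `reference` over a
#' matched atom selection. The rotation is constrained to be proper
#' (det = +1), so mirror solutions are never returned.
#'
#' @param mobile,reference one-frame `md_traj` objects.
#' @param selection passed to [select_atoms()]; default `"backbone"`. The
#'   selections must map 1:1 between the two frames (same atom count and
#'   names, in order) and contain at least 3 non-collinear atoms.
#' @return list with `frame` (the whole mobile frame, transformed) and
#'   `rmsd` (Angstrom, over the selection).
#' @export
superpose <- function(mobile, reference, selection = "backbone") {
  stopifnot(inherits(mobile, "md_traj"), inherits(reference, "md_traj"),
            n_frames(mobile) == 1L, n_frames(reference) == 1L)
  im <- select_atoms(mobile, selection)
  ir <- select_atoms(reference, selection)
  if (length(im) != length(ir) || length(im) < 3L ||
      !all(mobile$atoms$elety[im] == reference$atoms$elety[ir])) {
    stop("selections do not map 1:1 between mobile and reference",
         call. = FALSE)
  }
  P <- frame_coords(mobile)[im, , drop = FALSE]
  Q <- frame_coords(reference)[ir, , drop = FALSE]
  k <- kabsch(P, Q)
  all_xyz <- frame_coords(mobile)
  moved <- sweep(all_xyz, 2L, k$center_mobile) %*% k$rotation
  moved <- sweep(moved, 2L, k$center_reference, `+`)
  out <- set_frame_coords(mobile, 1L, moved)
  list(frame = out, rmsd = k$rmsd)
}

# Closed-form Kabsch solution for paired point sets (n x 3).
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3L, ncol(Q) == 3L)
  cp <- colMeans(P)
  cq <- colMeans(Q)
  P0 <- sweep(P, 2L, cp)
  Q0 <- sweep(Q, 2L, cq)
  if (qr(P0)$rank < 2L) {
    stop("degenerate (collinear) atom set: superposition ill-defined",
         call. = FALSE)
  }
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  dev <- P0 %*% R - Q0
  list(rotation = R, center_mobile = cp, center_reference = cq,
       rmsd = sqrt(mean(rowSums(dev^2))))
}

#' Align every frame of a trajectory onto a reference
#'
#' @inheritParams superpose
#' @param traj an `md_traj`.
#' @return the trajectory with every frame superposed onto `reference` over
#'   `selection`.
#' @export
align_trajectory <- function(traj, reference, selection = "backbone") {
  for (f in seq_len(n_frames(traj))) {
    traj <- set_frame_coords(traj, f,
      frame_coords(superpose(get_frame(traj, f), reference, selection)$frame))
  }
  traj
}

#' Per-frame RMSD from a reference structure
#'
#' Each frame is optimally superposed onto the reference over `selection`
#' and the post-fit RMSD recorded. The mean and standard deviation over the
#' analysis window are attached as attributes, together with an
#' `acceptable` flag marking whether the windowed mean is below the
#' conventional 3 Angstrom stability bound (a quality marker, not an
#' error).
#'
#' @inheritParams align_trajectory
#' @param window frame indices for the summary; default
#'   [analysis_window()] of the trajectory.
#' @return numeric vector, one RMSD (Angstrom) per frame, with attributes
#'   `mean`, `sd`, `window`, `acceptable`.
#' @export
rmsd_series <- function(traj, reference, selection = "backbone",
                        window = NULL) {
  window <- resolve_window(traj, window)
  r <- vapply(seq_len(n_frames(traj)), function(f) {
    superpose(get_frame(traj, f), reference, selection)$rmsd
  }, 0)
  structure(r, mean = mean(r[window]), sd = stats::sd(r[window]),
            window = window, acceptable = mean(r[window]) < 3)
}

#' Time-dependent per-residue RMSD
#'
#' After a global backbone superposition of each frame onto the reference,
#' the backbone RMSD of every residue is computed per frame. Residues
#' lacking any of the four backbone atoms are excluded and reported in the
#' `excluded` attribute.
#'
#' @inheritParams rmsd_series
#' @return numeric matrix, residues x frames (Angstrom), with rownames
#'   `chain:resno` and attribute `residues` (the residue table) and
#'   `excluded`.
#' @export
per_residue_rmsd <- function(traj, reference) {
  aligned <- align_trajectory(traj, reference, "backbone")
  res <- residue_table(aligned)
  ref_xyz <- frame_coords(reference)
  keep <- logical(nrow(res))
  idx_list <- vector("list", nrow(res))
  ref_list <- vector("list", nrow(res))
  for (i in seq_len(nrow(res))) {
    ia <- select_atoms(aligned, "backbone", resno = res$resno[i],
                       chain = res$chain[i])
    ir <- select_atoms(reference, "backbone", resno = res$resno[i],
                       chain = res$chain[i])
    if (length(ia) == 4L && length(ir) == 4L) {
      keep[i] <- TRUE
      idx_list[[i]] <- ia
      ref_list[[i]] <- ref_xyz[ir, , drop = FALSE]
    }
  }
  out <- matrix(NA_real_, sum(keep), n_frames(aligned))
  rownames(out) <- paste0(res$chain, ":", res$resno)[keep]
  ki <- which(keep)
  for (f in seq_len(n_frames(aligned))) {
    xyz <- frame_coords(aligned, f)
    for (j in seq_along(ki)) {
      dev <- xyz[idx_list[[ki[j]]], , drop = FALSE] - ref_list[[ki[j]]]
      out[j, f] <- sqrt(mean(rowSums(dev^2)))
    }
  }
  structure(out, residues = res[keep, , drop = FALSE],
            excluded = res[!keep, , drop = FALSE])
}

#' Root-mean-square fluctuation per residue
#'
#' `RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2)` over the analysis window,
#' for one selected atom per residue (default C-alpha). The trajectory is
#' assumed to be aligned already (see [align_trajectory()]); fluctuations
#' otherwise include global motion.
#'
#' @inheritParams rmsd_series
#' @param selection atom selection, default `"calpha"`.
#' @return data frame `chain`, `resno`, `resid`, `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, selection = "calpha", window = NULL) {
  window <- resolve_window(traj, window)
  idx <- select_atoms(traj, selection)
  if (length(idx) == 0L) stop("empty atom selection", call. = FALSE)
  a <- traj$atoms[idx, , drop = FALSE]
  vals <- vapply(seq_along(idx), function(j) {
    cols <- xyz_index(idx[j])
    xyz <- traj$xyz[window, cols, drop = FALSE]
    mu <- colMeans(xyz)
    sqrt(mean(rowSums(sweep(xyz, 2L, mu)^2)))
  }, 0)
  data.frame(chain = a$chain, resno = a$resno, resid = a$resid, rmsf = vals,
             stringsAsFactors = FALSE)
}

#' Backbone distance pattern
#'
#' Per residue, the mean (over the analysis window) distance of the
#' geometric center of the four backbone atoms (N, C, CA, O) from the
#' coordinate origin, after aligning every frame onto the reference
#' backbone. A conformational-drift fingerprint: identical folds give
#' identical patterns regardless of where the trajectory drifted.
#'
#' @inheritParams rmsd_series
#' @return data frame `chain`, `resno`, `resid`, `mean_dist` (Angstrom);
#'   residues missing backbone atoms are dropped and reported in the
#'   `excluded` attribute.
#' @export
distance_pattern <- function(traj, reference, window = NULL) {
  window <- resolve_window(traj, window)
  aligned <- align_trajectory(traj, reference, "backbone")
  res <- residue_table(aligned)
  keep <- logical(nrow(res))
  dist_mean <- numeric(nrow(res))
  idx_list <- lapply(seq_len(nrow(res)), function(i) {
    select_atoms(aligned, "backbone", resno = res$resno[i],
                 chain = res$chain[i])
  })
  keep <- lengths(idx_list) == 4L
  for (i in which(keep)) {
    d <- vapply(window, function(f) {
      ctr <- colMeans(frame_coords(aligned, f)[idx_list[[i]], , drop = FALSE])
      sqrt(sum(ctr^2))
    }, 0)
    dist_mean[i] <- mean(d)
  }
  out <- data.frame(chain = res$chain, resno = res$resno, resid = res$resid,
                    mean_dist = dist_mean, stringsAsFactors = FALSE)
  structure(out[keep, , drop = FALSE],
            excluded = res[!keep, , drop = FALSE])
}

#' Geometric criteria containers
#'
#' `hbond_criteria`: a hydrogen bond requires donor-acceptor distance
#' `<= d_max` (default 3.5 Angstrom) and donor-hydrogen-acceptor angle
#' `>= angle_min` (default 150 degrees; 180 is linear, measured at the
#' hydrogen). `contact_criteria`: electrostatic and pi interactions count
#' as within-range at `<= electro_pi_max` (default 5, with the `<=
#' strong_max = 4` subset flagged separately), long-range electrostatics at
#' `> longrange_min` (default 6) up to a reporting cap `longrange_max`
#' (default 10).
#'
#' @param d_max,angle_min,electro_pi_max,strong_max,longrange_min,longrange_max
#'   numeric cutoffs as above (Angstrom / degrees).
#' @return a named list of criteria.
#' @export
hbond_criteria <- function(d_max = 3.5, angle_min = 150) {
  stopifnot(d_max > 0, angle_min > 0, angle_min <= 180)
  list(d_max = d_max, angle_min = angle_min)
}

#' @rdname hbond_criteria
#' @export
contact_criteria <- function(electro_pi_max = 5.0, strong_max = 4.0,
                             longrange_min = 6.0, longrange_max = 10.0) {
  stopifnot(electro_pi_max < longrange_min, strong_max <= electro_pi_max,
            longrange_min < longrange_max)
  list(electro_pi_max = electro_pi_max, strong_max = strong_max,
       longrange_min = longrange_min, longrange_max = longrange_max)
}

# Covalent donor-hydrogen pairs: N/O heavy atoms with an H within d_covalent.
donor_hydrogen_pairs <- function(frame, d_covalent = 1.2) {
  xyz <- frame_coords(frame)
  is_h <- frame$atoms$elesy == "H"
  if (!any(is_h)) {
    stop("no hydrogens in structure; add hydrogens (protonate) before ",
         "hydrogen-bond analysis", call. = FALSE)
  }
  heavy <- which(frame$atoms$elesy %in% c("N", "O"))
  hyd <- which(is_h)
  pairs <- NULL
  for (h in hyd) {
    d2 <- rowSums(sweep(xyz[heavy, , drop = FALSE], 2L, xyz[h, ])^2)
    j <- which(d2 < d_covalent^2)
    if (length(j)) {
      j <- j[which.min(d2[j])]  # closest heavy atom owns the hydrogen
      pairs <- rbind(pairs, c(donor = heavy[j], hydrogen = h))
    }
  }
  pairs
}

#' Detect hydrogen bonds in a frame
#'
#' Purely geometric detection: donors are N/O atoms with a covalently bound
#' hydrogen (inferred as any H within 1.2 Angstrom when no topology is
#' given), acceptors are N/O atoms. A donor-hydrogen-acceptor triple is a
#' hydrogen bond when the donor-acceptor distance and the angle at the
#' hydrogen satisfy `criteria`. The acceptor may be any N/O other than the
#' donor itself; restrict `chain` to count intra-molecular bonds only.
#'
#' @param frame one-frame `md_traj` containing hydrogens.
#' @param criteria a [hbond_criteria()] list.
#' @param chain optional chain identifier to restrict both partners to.
#' @return data frame `donor`, `hydrogen`, `acceptor` (atom indices),
#'   `distance` (Angstrom), `angle` (degrees), sorted by donor then
#'   acceptor.
#' @export
detect_hbonds <- function(frame, criteria = hbond_criteria(), chain = NULL) {
  stopifnot(n_frames(frame) == 1L)
  xyz <- frame_coords(frame)
  dh <- donor_hydrogen_pairs(frame)
  acceptors <- which(frame$atoms$elesy %in% c("N", "O"))
  if (!is.null(chain)) {
    acceptors <- acceptors[frame$atoms$chain[acceptors] %in% chain]
    if (!is.null(dh)) {
      dh <- dh[frame$atoms$chain[dh[, "donor"]] %in% chain, , drop = FALSE]
    }
  }
  out <- NULL
  for (k in seq_len(NROW(dh))) {
    d <- dh[k, "donor"]
    h <- dh[k, "hydrogen"]
    for (a in acceptors) {
      if (a == d) next
      dda <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
      if (dda > criteria$d_max) next
      u <- xyz[d, ] - xyz[h, ]
      v <- xyz[a, ] - xyz[h, ]
      cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang < criteria$angle_min) next
      out <- rbind(out, data.frame(donor = d, hydrogen = h, acceptor = a,
                                   distance = dda, angle = ang))
    }
  }
  if (is.null(out)) {
    out <- data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric())
  }
  out[order(out$donor, out$acceptor), , drop = FALSE]
}

#' Mean hydrogen-bond count over a trajectory window
#'
#' @inheritParams detect_hbonds
#' @param traj an `md_traj` with hydrogens.
#' @param window frame indices; default [analysis_window()].
#' @return mean number of hydrogen bonds per frame (full precision; round
#'   to integer for table-style reporting), with attribute `per_frame`.
#' @export
mean_hbond_count <- function(traj, criteria = hbond_criteria(),
                             window = NULL, chain = NULL) {
  window <- resolve_window(traj, window)
  counts <- vapply(window, function(f) {
    nrow(detect_hbonds(get_frame(traj, f), criteria, chain = chain))
  }, 0L)
  structure(mean(counts), per_frame = counts)
}

AROMATIC_RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

CHARGED_GROUP_ATOMS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  LYS = "NZ", ARG = "CZ",
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

#' Interaction-group centroid of a residue
#'
#' For `role = "charged"`: carboxylate O midpoint (Asp/Glu), Lys NZ, Arg CZ
#' or His ring centroid — standard salt-bridge conventions. For
#' `role = "ring"`: aromatic ring centroid (Phe/Tyr six-ring, Trp six-ring,
#' His imidazole).
#'
#' @param frame one-frame `md_traj`.
#' @param resno,chain residue address.
#' @param role `"charged"` or `"ring"`.
#' @return length-3 coordinate (Angstrom).
#' @export
group_centroid <- function(frame, resno, chain = NULL,
                           role = c("charged", "ring")) {
  role <- match.arg(role)
  idx <- select_atoms(frame, "all", resno = resno, chain = chain)
  if (!length(idx)) stop("residue ", resno, " not found", call. = FALSE)
  resname <- frame$atoms$resid[idx[1L]]
  atoms <- if (role == "charged") CHARGED_GROUP_ATOMS[[resname]]
           else AROMATIC_RING_ATOMS[[resname]]
  if (is.null(atoms)) {
    stop(resname, resno, " has no ", role,
         " interaction group", call. = FALSE)
  }
  sub <- idx[frame$atoms$elety[idx] %in% atoms]
  if (length(sub) != length(atoms)) {
    stop(resname, resno, " is missing ", role, "-group atoms", call. = FALSE)
  }
  colMeans(frame_coords(frame)[sub, , drop = FALSE])
}

#' Interaction distance time series with class labels
#'
#' Per frame, the distance between the interaction-group centroids of two
#' residues, classified against [contact_criteria()]: `"within"` when
#' `<= electro_pi_max` (with `strong = TRUE` when also `<= strong_max`),
#' `"long-range"` when `> longrange_min`, otherwise `"neither"`. For
#' `"anion_pi"`/`"cation_pi"` the second residue supplies the aromatic ring
#' centroid; for `"electrostatic"` both partners use their charged-group
#' centroids.
#'
#' @param traj an `md_traj`.
#' @param res_a,res_b residue indices (with optional `chain_a`, `chain_b`).
#' @param type `"electrostatic"`, `"anion_pi"` or `"cation_pi"`.
#' @param criteria a [contact_criteria()] list.
#' @param chain_a,chain_b optional chains.
#' @return data frame `frame`, `time`, `distance`, `class`, `strong`.
#' @export
contact_timeseries <- function(traj, res_a, res_b,
                               type = c("electrostatic", "anion_pi",
                                        "cation_pi"),
                               criteria = contact_criteria(),
                               chain_a = NULL, chain_b = NULL) {
  type <- match.arg(type)
  role_b <- if (type == "electrostatic") "charged" else "ring"
  d <- vapply(seq_len(n_frames(traj)), function(f) {
    fr <- get_frame(traj, f)
    pa <- group_centroid(fr, res_a, chain_a, "charged")
    pb <- group_centroid(fr, res_b, chain_b, role_b)
    sqrt(sum((pa - pb)^2))
  }, 0)
  cls <- ifelse(d <= criteria$electro_pi_max, "within",
                ifelse(d > criteria$longrange_min, "long-range", "neither"))
  data.frame(frame = seq_along(d), time = traj$time, distance = d,
             class = cls, strong = d <= criteria$strong_max,
             stringsAsFactors = FALSE)
}
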