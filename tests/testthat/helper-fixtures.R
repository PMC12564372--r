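# Small in-code fixtures shared across test files.

# One-frame structure from an n x 3 coordinate matrix; one residue per atom
# unless resno is given.
make_frame <- function(coords, elety = NULL, resno = NULL, resid = "GLY",
                       chain = "A") {
  n <- nrow(coords)
  if (is.null(elety)) elety <- rep("CA", n)
  if (is.null(resno)) resno <- seq_len(n)
  atoms <- data.frame(elety = elety, resid = resid, chain = chain,
                      resno = resno, stringsAsFactors = FALSE)
  md_traj(atoms, as.numeric(t(coords)))
}

# A compact folded-ish backbone reference: n_res residues, four backbone
# atoms each, arranged on a coarse helix so superposition is well-posed.
make_backbone_ref <- function(n_res = 20) {
  atoms <- NULL
  xyz <- NULL
  for (i in seq_len(n_res)) {
    t0 <- i * 100 * pi / 180
    base <- c(8 * cos(t0), 8 * sin(t0), 1.5 * i)
    atoms <- rbind(atoms, data.frame(
      elety = c("N", "CA", "C", "O"), resid = "ALA", chain = "A",
      resno = i, stringsAsFactors = FALSE))
    xyz <- rbind(xyz,
                 base + c(0, 0, 0), base + c(1.2, 0.8, 0.2),
                 base + c(2.4, 0.3, 0.5), base + c(3.0, 1.2, 0.9))
  }
  md_traj(atoms, as.numeric(t(xyz)))
}

# Random rigid transform of an n x 3 matrix (uses current RNG state).
rigid_transform <- function(coords, angle = NULL, axis = NULL, shift = NULL) {
  if (is.null(angle)) angle <- runif(1, 0, 2 * pi)
  if (is.null(axis)) axis <- rnorm(3)
  if (is.null(shift)) shift <- runif(3, -10, 10)
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  sweep(coords %*% R, 2, shift, `+`)
}

# Independent O(n^3) hydrogen-bond oracle: enumerate every
# (heavy, hydrogen, heavy) triple directly from coordinates.
hbond_oracle <- function(frame, d_max = 3.5, angle_min = 150,
                         d_covalent = 1.2) {
  xyz <- frame_coords(frame)
  el <- frame$atoms$elesy
  no <- which(el %in% c("N", "O"))
  hs <- which(el == "H")
  hits <- NULL
  for (h in hs) {
    # hydrogen belongs to its nearest covalently bonded N/O, if any
    dcov <- sqrt(rowSums(sweep(xyz[no, , drop = FALSE], 2, xyz[h, ])^2))
    if (!any(dcov < d_covalent)) next
    d <- no[which.min(dcov)]
    for (a in no) {
      if (a == d) next
      dda <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
      u <- xyz[d, ] - xyz[h, ]
      v <- xyz[a, ] - xyz[h, ]
      ang <- acos(max(-1, min(1, sum(u * v) /
                                sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
      if (dda <= d_max && ang >= angle_min) {
        hits <- rbind(hits, c(d, h, a))
      }
    }
  }
  if (is.null(hits)) return(matrix(integer(), ncol = 3))
  hits[order(hits[, 1], hits[, 3]), , drop = FALSE]
}

# Brute-force rigid superposition: best RMSD over a sampled set of
# rotations (after centroid match). A lower bound check for Kabsch.
grid_min_rmsd <- function(P, Q, n_rot = 4000) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  best <- Inf
  for (i in seq_len(n_rot)) {
    q <- rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                  2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                  2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
                3, 3, byrow = TRUE)
    r <- sqrt(mean(rowSums((P0 %*% R - Q0)^2)))
    if (r < best) best <- r
  }
  best
}

# Closed-form OLS oracle, independent of lm().
ols_oracle <- function(x, y) {
  sx <- x - mean(x)
  slope <- sum(sx * (y - mean(y))) / sum(sx^2)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}
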