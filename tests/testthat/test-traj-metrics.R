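test_that("Kabsch superposition nails identity, rigid copies and the grid oracle", {
  ref <- make_backbone_ref(10)

  # identity
  s <- superpose(ref, ref)
  expect_equal(s$rmsd, 0, tolerance = 1e-12)

  # a rigidly moved copy superposes back to numerical zero
  set.seed(5)
  moved <- set_frame_coords(ref, 1, rigid_transform(frame_coords(ref)))
  s2 <- superpose(moved, ref)
  expect_lt(s2$rmsd, 1e-6)
  expect_equal(frame_coords(s2$frame), frame_coords(ref), tolerance = 1e-6)

  # 4-atom toy with one displaced atom: Kabsch <= sampled-rotation minimum
  P <- matrix(c(0, 0, 0, 1.5, 0, 0, 0, 1.5, 0, 0.4, 0.3, 1.8), 4, 3,
              byrow = TRUE)
  Q <- P
  Q[4, ] <- Q[4, ] + c(0.6, -0.4, 0.3)
  fr_p <- make_frame(P, elety = c("N", "CA", "C", "O"), resno = rep(1, 4))
  fr_q <- make_frame(Q, elety = c("N", "CA", "C", "O"), resno = rep(1, 4))
  k_rmsd <- superpose(fr_p, fr_q, selection = "backbone")$rmsd
  set.seed(11)
  g_rmsd <- grid_min_rmsd(P, Q, n_rot = 5000)
  expect_lte(k_rmsd, g_rmsd + 1e-3)   # closed form never beaten by sampling
  expect_lte(g_rmsd - k_rmsd, 0.05)   # and sampling converges towards it

  # collinear selections are rejected
  L <- cbind(seq(0, 3, length.out = 4), 0, 0)
  fr_l <- make_frame(L, elety = c("N", "CA", "C", "O"), resno = rep(1, 4))
  expect_error(superpose(fr_l, fr_l), "collinear")
  expect_error(superpose(ref, make_backbone_ref(9)), "1:1")
})

test_that("superposition agrees with bio3d's least-squares fit", {
  ref <- make_backbone_ref(12)
  set.seed(8)
  tr <- gen_trajectory(ref, n_frames = 5, amplitude = 0.6,
                       rigid_motion = TRUE, seed = 8)
  ours <- rmsd_series(tr, ref, window = 1:5)
  sel <- select_atoms(ref, "backbone")
  cols <- as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel))
  theirs <- bio3d::rmsd(ref$xyz[1, ], tr$xyz, a.inds = cols, b.inds = cols,
                        fit = TRUE)
  # bio3d reports RMSD rounded to 3 decimals
  expect_equal(as.numeric(ours), as.numeric(theirs), tolerance = 1e-3)
})

test_that("RMSD series is zero for static/translated copies and tracks jitter", {
  ref <- make_backbone_ref(15)
  static <- gen_trajectory(ref, n_frames = 8, amplitude = 0, seed = 1)
  expect_equal(as.numeric(rmsd_series(static, ref)), rep(0, 8),
               tolerance = 1e-12)

  # pure translations vanish after alignment
  shifted <- static
  for (f in 1:8) {
    shifted <- set_frame_coords(shifted, f,
      sweep(frame_coords(shifted, f), 2, c(f, -2 * f, 0.5 * f), `+`))
  }
  expect_lt(max(rmsd_series(shifted, ref)), 1e-9)

  # isotropic Gaussian jitter: mean RMSD within 10% of sqrt(3)*sigma
  sigma <- 0.4
  jit <- gen_trajectory(ref, n_frames = 500, amplitude = sigma, seed = 2)
  m <- attr(rmsd_series(jit, ref, window = 1:500), "mean")
  expect_lt(abs(m - sqrt(3) * sigma) / (sqrt(3) * sigma), 0.10)
  expect_true(attr(rmsd_series(jit, ref), "acceptable"))

  # window arithmetic: last 40% by default
  expect_equal(attr(rmsd_series(static, ref), "window"), 5:8)
  expect_equal(analysis_window(2500), 1501:2500)
})

test_that("per-residue RMSD is zero when static and localizes planted motion", {
  ref <- make_backbone_ref(20)
  static <- gen_trajectory(ref, n_frames = 4, amplitude = 0, seed = 1)
  m0 <- per_residue_rmsd(static, ref)
  expect_equal(max(abs(m0)), 0, tolerance = 1e-12)
  expect_equal(dim(m0), c(20L, 4L))

  # jitter confined to residues 12-14: those rows dominate
  tr <- gen_trajectory(ref, n_frames = 60, amplitude = 1e-3,
                       loop_region = 12:14, loop_amplitude_factor = 400,
                       seed = 6)
  m <- per_residue_rmsd(tr, ref)
  hot <- rowMeans(m)[rownames(m) %in% paste0("A:", 12:14)]
  cold <- rowMeans(m)[!rownames(m) %in% paste0("A:", 12:14)]
  expect_gt(min(hot), 3 * max(cold))

  # single frame decomposes the global backbone RMSD
  one <- get_frame(tr, 1)
  pr <- per_residue_rmsd(one, ref)
  expect_equal(sqrt(mean(pr^2)),
               superpose(one, ref)$rmsd, tolerance = 1e-9)

  # residues missing backbone atoms are flagged and excluded
  broken <- ref
  drop <- which(broken$atoms$resno == 5 & broken$atoms$elety == "O")
  broken$atoms <- broken$atoms[-drop, ]
  broken$xyz <- broken$xyz[, -xyz_index(drop), drop = FALSE]
  mb <- per_residue_rmsd(broken, broken)
  expect_false("A:5" %in% rownames(mb))
  expect_equal(attr(mb, "excluded")$resno, 5L)
})

test_that("RMSF matches the isotropic analytic limit and finds the planted loop", {
  ref <- make_backbone_ref(30)
  static <- gen_trajectory(ref, n_frames = 10, amplitude = 0, seed = 1)
  expect_equal(rmsf(static, window = 1:10)$rmsf, rep(0, 30),
               tolerance = 1e-12)

  sigma <- 0.5
  tr <- gen_trajectory(ref, n_frames = 1000, amplitude = sigma, seed = 3)
  r <- rmsf(tr, window = 1:1000)
  expect_equal(mean(r$rmsf), sqrt(3) * sigma, tolerance = 0.05)

  # elevated-amplitude loop recovered as the argmax
  trl <- gen_trajectory(ref, n_frames = 300, amplitude = 0.2,
                        loop_region = 21:27, loop_amplitude_factor = 3,
                        seed = 4)
  rl <- rmsf(trl, window = 1:300)
  expect_true(rl$resno[which.max(rl$rmsf)] %in% 21:27)

  expect_error(rmsf(tr, window = integer()), "out of bounds")
})

test_that("summed squared RMSF equals the trace of total fluctuation", {
  ref <- make_backbone_ref(12)
  tr <- gen_trajectory(ref, n_frames = 40, amplitude = 0.4, seed = 9)
  r <- rmsf(tr, window = 1:40)
  # direct trace computation over the same CA coordinates
  idx <- select_atoms(tr, "calpha")
  total <- 0
  for (j in idx) {
    cols <- c(3 * j - 2, 3 * j - 1, 3 * j)
    xyz <- tr$xyz[, cols]
    total <- total + sum(apply(xyz, 2, function(c) mean((c - mean(c))^2)))
  }
  expect_equal(sum(r$rmsf^2), total, tolerance = 1e-9)
})

test_that("distance pattern matches hand geometry and a naive oracle", {
  # one residue whose backbone atoms are symmetric about (3,4,0): 3-4-5
  coords <- rbind(c(3, 4, 1), c(3, 4, -1), c(2, 4, 0), c(4, 4, 0))
  fr <- make_frame(coords, elety = c("N", "CA", "C", "O"),
                   resno = rep(1, 4))
  dp <- distance_pattern(fr, fr, window = 1)
  expect_equal(dp$mean_dist, 5.0, tolerance = 1e-12)

  # static trajectory equals the single-frame pattern
  ref <- make_backbone_ref(10)
  static <- gen_trajectory(ref, n_frames = 6, amplitude = 0, seed = 1)
  expect_equal(distance_pattern(static, ref, window = 1:6)$mean_dist,
               distance_pattern(ref, ref, window = 1)$mean_dist,
               tolerance = 1e-9)

  # random 10-residue 50-frame toy vs an independent two-loop recomputation
  tr <- gen_trajectory(ref, n_frames = 50, amplitude = 0.3, seed = 12)
  got <- distance_pattern(tr, ref, window = 1:50)
  aligned <- align_trajectory(tr, ref)
  manual <- numeric(10)
  for (res in 1:10) {
    idx <- select_atoms(aligned, "backbone", resno = res)
    acc <- 0
    for (f in 1:50) {
      ctr <- colMeans(frame_coords(aligned, f)[idx, ])
      acc <- acc + sqrt(sum(ctr^2))
    }
    manual[res] <- acc / 50
  }
  expect_equal(got$mean_dist, manual, tolerance = 1e-9)
})

test_that("hydrogen-bond detection honors both geometric criteria", {
  # N-H...O triples built directly at stated geometry
  place <- function(d, angle) {
    gen_toy_structure(4, hbond_distance = d, hbond_angle = angle)
  }
  expect_equal(nrow(detect_hbonds(place(2.9, 175))), 1L)
  expect_equal(nrow(detect_hbonds(place(3.6, 180))), 0L)  # distance fails
  expect_equal(nrow(detect_hbonds(place(3.0, 149))), 0L)  # angle fails
  expect_equal(nrow(detect_hbonds(place(3.0, 150.5))), 1L)

  # both criteria are inclusive: an exactly representable linear triple at
  # the 3.5 A donor-acceptor cutoff is detected
  tri <- make_frame(rbind(c(0, 0, 0), c(0, 1, 0), c(0, 3.5, 0)),
                    elety = c("N", "H", "O"), resno = c(1, 1, 2))
  hb <- detect_hbonds(tri)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 3.5)
  expect_equal(hb$angle, 180)

  # structures without hydrogens are an instructive error
  ref <- make_backbone_ref(5)
  expect_error(detect_hbonds(ref), "protonate")
})

test_that("hydrogen-bond sets are identical to the exhaustive all-triples oracle", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- 30
    coords <- matrix(runif(3 * n, 0, 12), n, 3)
    elety <- sample(c("N", "O", "C", "H"), n, replace = TRUE)
    fr <- make_frame(coords, elety = elety, resno = seq_len(n))
    got <- detect_hbonds(fr)
    want <- hbond_oracle(fr)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(unname(as.matrix(got[, c("donor", "hydrogen", "acceptor")])),
                   unname(want))
    }
  }
})

test_that("mean H-bond counts honor the analysis window", {
  toy <- gen_toy_structure(6)                       # exactly one engineered bond
  static <- gen_trajectory(toy, n_frames = 10, amplitude = 0, seed = 1)
  expect_equal(as.numeric(mean_hbond_count(static, window = 1:10)), 1)

  # toggling the bond off on alternate frames halves the mean
  toggled <- static
  o_idx <- which(toggled$atoms$resno == attr(toy, "acceptor_res") &
                   toggled$atoms$elety == "O")
  for (f in seq(2, 10, by = 2)) {
    xyz <- frame_coords(toggled, f)
    xyz[o_idx, ] <- xyz[o_idx, ] + c(0, 10, 0)
    toggled <- set_frame_coords(toggled, f, xyz)
  }
  expect_equal(as.numeric(mean_hbond_count(toggled, window = 1:10)), 0.5)

  # explicit windows are honored exactly
  expect_equal(as.numeric(mean_hbond_count(toggled, window = seq(1, 9, 2))), 1)
  expect_equal(length(attr(mean_hbond_count(toggled, window = 3:10),
                           "per_frame")), 8L)
})

test_that("contact classification and group centroids follow convention", {
  # ideal hexagon ring: centroid is the vertex mean
  ang <- seq(0, 300, by = 60) * pi / 180
  ring <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  phe <- make_frame(ring, elety = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                    resno = rep(1, 6), resid = "PHE")
  expect_equal(group_centroid(phe, 1, role = "ring"), colMeans(ring),
               tolerance = 1e-12)

  # ion pair at 3.5 A -> within; 7.0 A -> long-range; 5.5 A -> neither
  make_pair <- function(d) {
    atoms <- data.frame(elety = c("NZ", "OD1", "OD2"),
                        resid = c("LYS", "ASP", "ASP"), chain = "A",
                        resno = c(1, 2, 2), stringsAsFactors = FALSE)
    md_traj(atoms, as.numeric(t(rbind(c(0, 0, 0), c(d, 0.5, 0),
                                      c(d, -0.5, 0)))))
  }
  ts <- contact_timeseries(make_pair(3.5), 1, 2, "electrostatic")
  expect_equal(ts$class, "within")
  expect_equal(ts$distance, 3.5, tolerance = 1e-12)
  expect_equal(contact_timeseries(make_pair(7), 1, 2, "electrostatic")$class,
               "long-range")
  expect_equal(contact_timeseries(make_pair(5.5), 1, 2,
                                  "electrostatic")$class, "neither")
  expect_true(contact_timeseries(make_pair(3.9), 1, 2,
                                 "electrostatic")$strong)
  expect_false(contact_timeseries(make_pair(4.5), 1, 2,
                                  "electrostatic")$strong)

  # requesting a pi partner without a ring is an error
  expect_error(contact_timeseries(make_pair(4), 1, 2, "cation_pi"),
               "no ring")
})

test_that("metrics are invariant under a global rigid transform of all frames", {
  ref <- make_backbone_ref(15)
  tr <- gen_trajectory(ref, n_frames = 30, amplitude = 0.3,
                       loop_region = 6:8, loop_amplitude_factor = 2,
                       seed = 14)
  set.seed(15)
  moved <- tr
  R <- il18design:::random_rotation()
  shift <- runif(3, -8, 8)
  for (f in 1:30) {
    moved <- set_frame_coords(moved, f,
      sweep(frame_coords(moved, f) %*% R, 2, shift, `+`))
  }
  expect_equal(as.numeric(rmsd_series(moved, ref, window = 1:30)),
               as.numeric(rmsd_series(tr, ref, window = 1:30)),
               tolerance = 1e-9)
  expect_equal(distance_pattern(moved, ref, window = 1:30)$mean_dist,
               distance_pattern(tr, ref, window = 1:30)$mean_dist,
               tolerance = 1e-9)
  expect_equal(per_residue_rmsd(moved, ref), per_residue_rmsd(tr, ref),
               tolerance = 1e-9)
})
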