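test_that("all generators are deterministic per seed and leave the RNG alone", {
  set.seed(123)
  before <- .Random.seed
  a <- gen_validation_set(seed = 7)
  expect_identical(.Random.seed, before)
  b <- gen_validation_set(seed = 7)
  expect_identical(a, b)
  expect_false(identical(a$ddg, gen_validation_set(seed = 8)$ddg))

  sites <- data.frame(wt_res = c("E", "K"), position = c(6, 129))
  expect_identical(gen_ddg_landscape(sites, seed = 3),
                   gen_ddg_landscape(sites, seed = 3))
  ref <- gen_toy_structure(8)
  expect_identical(gen_trajectory(ref, n_frames = 5, seed = 2),
                   gen_trajectory(ref, n_frames = 5, seed = 2))
})

test_that("validation sets embed the planted linear relation", {
  # zero noise: fits recover the planted lines to numerical precision
  vs <- gen_validation_set(n_mutants = 17, noise_sd = 0, seed = 1)
  x <- log(vs$panel$activity_pct)
  for (k in 1:3) {
    f <- fit_ddg_activity(x, vs$ddg[[k + 1L]])
    expect_equal(f$slope, vs$truth$slopes[k], tolerance = 1e-9)
    expect_equal(f$intercept, vs$truth$intercepts[k], tolerance = 1e-9)
    expect_equal(abs(f$pearson_r), 1, tolerance = 1e-9)
  }
  # default slopes are all negative: r -> -1 in the zero-noise limit
  expect_lt(fit_ddg_activity(x, vs$ddg$ddg_binding)$pearson_r, 0)

  # degenerate activities are refused
  expect_error(gen_validation_set(n_mutants = 5,
                                  activity_pct = rep(100, 5), seed = 1),
               "degenerate")

  # variant labels are parseable
  expect_silent(lapply(vs$panel$variant, parse_variant))
})

test_that("slope recovery over repeated seeds is unbiased within 2 SE", {
  slopes <- vapply(1:200, function(s) {
    vs <- gen_validation_set(n_mutants = 17, noise_sd = 0.5, seed = s)
    fit_ddg_activity(log(vs$panel$activity_pct), vs$ddg$ddg_binding)$slope
  }, 0)
  planted <- il18_published_calibration()$lines$slope[1]
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - planted), 2 * se + 1e-12)
})

test_that("ddG landscapes are additive at zero epistasis and scoring-ready", {
  sites <- data.frame(wt_res = c("E", "N", "K", "R"),
                      position = c(6, 111, 129, 131))
  ls <- gen_ddg_landscape(sites, epistasis_sd = 0, seed = 5)
  expect_equal(ls$table, ls$truth$additive, tolerance = 1e-12)

  # combination rows equal the sum of their singles
  combo <- ls$table[grepl("\\+", ls$table$variant), ]
  for (i in seq_len(min(5, nrow(combo)))) {
    v <- parse_variant(combo$variant[i])
    tr <- additive_ddg(v, ls$singles)
    expect_equal(as.numeric(tr),
                 as.numeric(combo[i, c("ddg_binding", "ddg_fold_complex",
                                       "ddg_fold_ligand")]),
                 tolerance = 1e-9)
  }

  # output feeds candidate_scoring unchanged
  w <- il18_published_calibration()$weights
  ranked <- rank_variants(score_variants(ls$table, w))
  expect_equal(ranked$variant[1], ls$truth$best_variant)
})

test_that("ranking recovers the planted best variant under low epistasis", {
  sites <- data.frame(wt_res = c("E", "N", "K"), position = c(6, 111, 129))
  w <- il18_published_calibration()$weights
  hit <- vapply(1:100, function(s) {
    ls <- gen_ddg_landscape(sites, epistasis_sd = 0.01, seed = s)
    rank_variants(score_variants(ls$table, w))$variant[1] ==
      ls$truth$best_variant
  }, TRUE)
  expect_gte(mean(hit), 0.95)
})

test_that("toy structures carry exactly the engineered hydrogen bond", {
  toy <- gen_toy_structure(10, hbond_distance = 2.9, hbond_angle = 170)
  hb <- detect_hbonds(toy)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 2.9, tolerance = 1e-9)
  expect_equal(hb$angle, 170, tolerance = 1e-6)
  expect_equal(toy$atoms$resno[hb$donor], attr(toy, "donor_res"))
  expect_equal(toy$atoms$resno[hb$acceptor], attr(toy, "acceptor_res"))

  # near-miss geometry is not detected
  expect_equal(nrow(detect_hbonds(gen_toy_structure(10, 3.6, 170))), 0L)

  # PDB round-trip to the format's 3-decimal precision
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_traj(toy, f)
  back <- read_pdb_traj(f)
  expect_equal(back$xyz, toy$xyz, tolerance = 1e-3)
  expect_equal(back$atoms$elety, toy$atoms$elety)
  expect_equal(back$atoms$resno, toy$atoms$resno)
})

test_that("synthetic trajectories express the requested fluctuation field", {
  ref <- gen_toy_structure(118)  # covers the 106-112 loop analogue
  # zero amplitude: static, RMSF identically zero
  st <- gen_trajectory(ref, n_frames = 5, amplitude = 0, seed = 1)
  expect_equal(max(rmsf(st, window = 1:5)$rmsf), 0, tolerance = 1e-12)

  # uniform 0.5 A amplitude: RMSF within 5% of the sqrt(3)*sigma limit
  tr <- gen_trajectory(ref, n_frames = 600, amplitude = 0.5,
                       loop_amplitude_factor = 1, seed = 2)
  expect_equal(mean(rmsf(tr, window = 1:600)$rmsf), sqrt(3) * 0.5,
               tolerance = 0.05)

  # amplified loop (default residues 106-112): RMSF argmax inside it
  trl <- gen_trajectory(ref, n_frames = 300, amplitude = 0.2,
                        loop_amplitude_factor = 3, seed = 3)
  rl <- rmsf(trl, window = 1:300)
  expect_true(rl$resno[which.max(rl$rmsf)] %in% 106:112)

  # multi-model PDB round trip preserves frame count and coordinates
  f <- withr::local_tempfile(fileext = ".pdb")
  small <- gen_trajectory(gen_toy_structure(6), n_frames = 7,
                          amplitude = 0.4, seed = 4)
  write_pdb_traj(small, f)
  back <- read_pdb_traj(f)
  expect_equal(n_frames(back), 7L)
  expect_equal(back$xyz, small$xyz, tolerance = 1e-3)
})

test_that("the full synthetic pipeline recovers its own planted design", {
  # validation panel -> fits -> weights -> landscape -> rank
  vs <- gen_validation_set(n_mutants = 17, noise_sd = 0.05, seed = 31)
  x <- log(vs$panel$activity_pct)
  fits <- lapply(2:4, function(k) fit_ddg_activity(x, vs$ddg[[k]]))
  w <- derive_weights(fits)
  # weights close to planted correlations (near -1 at this noise): negative
  expect_true(all(w < -0.9))
  sites <- data.frame(wt_res = c("E", "N", "K"), position = c(6, 111, 129))
  ls <- gen_ddg_landscape(sites, weights = w, epistasis_sd = 0.02, seed = 31)
  ranked <- rank_variants(score_variants(ls$table, w))
  expect_equal(ranked$variant[1], ls$truth$best_variant)
})
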