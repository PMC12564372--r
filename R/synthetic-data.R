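# Seeded synthetic-data generators. These stand in for the external
# force-field, docking and simulation engines: every downstream stage of the
# pipeline can be exercised against planted ground truth, offline. All
# generators are deterministic for a fixed seed and leave the session RNG
# state untouched.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a per-residue interface energy table with planted labels
#'
#' Draws residue contributions by class — key in `[-5, -1]` kcal/mol,
#' favorable-but-not-key in `(-1, 0)`, unfavorable in `(0, 2.5]` — and a
#' decomposition in which electrostatics and van der Waals terms are
#' favorable and desolvation opposes them, the qualitative signature of a
#' protein-protein interface. The planted class of every row is returned so
#' classification can be checked for exact recovery.
#'
#' @param n_residues number of interface residues.
#' @param frac_unfavorable,frac_key class proportions (remainder is
#'   favorable-not-key).
#' @param seed integer seed; fixed seed gives identical output.
#' @return list with `table` (a [load_residue_energies()]-shaped data
#'   frame) and `labels` (planted class per row: `key`, `favorable`,
#'   `unfavorable`).
#' @export
gen_energy_table <- function(n_residues = 30, frac_unfavorable = 0.35,
                             frac_key = 0.4, seed = 1) {
  stopifnot(n_residues >= 1, frac_unfavorable >= 0, frac_key >= 0,
            frac_unfavorable + frac_key <= 1)
  with_seed(seed, {
    n_unf <- round(n_residues * frac_unfavorable)
    n_key <- round(n_residues * frac_key)
    n_fav <- n_residues - n_unf - n_key
    labels <- sample(rep(c("key", "favorable", "unfavorable"),
                         c(n_key, n_fav, n_unf)))
    e_total <- numeric(n_residues)
    e_total[labels == "key"] <- stats::runif(sum(labels == "key"), -5, -1)
    e_total[labels == "favorable"] <-
      stats::runif(sum(labels == "favorable"), -0.95, -0.01)
    e_total[labels == "unfavorable"] <-
      stats::runif(sum(labels == "unfavorable"), 0.01, 2.5)
    desolv <- abs(stats::rnorm(n_residues, 0.5, 0.2))
    elec <- (e_total - desolv) * stats::runif(n_residues, 0.3, 0.7)
    vdw <- e_total - desolv - elec
    tab <- data.frame(
      chain = "A",
      res_name = sample(AA3, n_residues, replace = TRUE),
      res_index = sort(sample.int(160, n_residues)),
      e_total = e_total, e_elec = elec, e_vdw = vdw, e_desolv = desolv,
      site = sample(c("I", "II", "III"), n_residues, replace = TRUE),
      stringsAsFactors = FALSE
    )
    list(table = tab, labels = labels)
  })
}

#' Generate a mutant validation panel with a planted linear calibration
#'
#' Emulates the statistical structure of a mutant activity panel: percent
#' activities spread log-uniformly around the wild-type standard, and each
#' ddG type generated as
#' `ddg = slope * ln(activity_pct) + intercept + N(0, noise_sd)`. Default
#' slopes and intercepts are the published calibration lines, so the
#' generator reproduces the study's conditions (a higher ddG means less
#' activity); the defaults for panel size (17) and noise (0.5 kcal/mol) are
#' stated in the methods vignette.
#'
#' @param n_mutants panel size (>= 3).
#' @param slopes,intercepts numeric length-3 (binding, fold-complex,
#'   fold-ligand); defaults from [il18_published_calibration()].
#' @param noise_sd Gaussian noise on each ddG, kcal/mol.
#' @param activity_range percent-activity range sampled log-uniformly.
#' @param activity_pct optional explicit activities (must not be all
#'   identical — the regression predictor would be degenerate).
#' @param seed integer seed.
#' @return list with `panel` (`variant`, `activity_pct`), `ddg` (`variant`,
#'   three `ddg_*` columns) and `truth` (planted slopes/intercepts/noise).
#' @export
gen_validation_set <- function(n_mutants = 17, slopes = NULL,
                               intercepts = NULL, noise_sd = 0.5,
                               activity_range = c(2, 400),
                               activity_pct = NULL, seed = 1) {
  stopifnot(n_mutants >= 3, noise_sd >= 0)
  cal <- il18_published_calibration()$lines
  if (is.null(slopes)) slopes <- cal$slope
  if (is.null(intercepts)) intercepts <- cal$intercept
  stopifnot(length(slopes) == 3L, length(intercepts) == 3L)
  with_seed(seed, {
    if (is.null(activity_pct)) {
      activity_pct <- exp(stats::runif(n_mutants, log(activity_range[1L]),
                                       log(activity_range[2L])))
    }
    stopifnot(length(activity_pct) == n_mutants, all(activity_pct > 0))
    if (stats::var(activity_pct) == 0) {
      stop("degenerate panel: all activities identical", call. = FALSE)
    }
    pos <- sample.int(157, n_mutants)
    wt <- sample(AA1, n_mutants, replace = TRUE)
    mut <- vapply(wt, function(w) sample(setdiff(AA1, w), 1L), "")
    labels <- paste0(wt, pos, mut)
    x <- log(activity_pct)
    ddg <- vapply(1:3, function(k) {
      slopes[k] * x + intercepts[k] + stats::rnorm(n_mutants, 0, noise_sd)
    }, numeric(n_mutants))
    ddg <- as.data.frame(ddg)
    names(ddg) <- c("ddg_binding", "ddg_fold_complex", "ddg_fold_ligand")
    list(panel = data.frame(variant = labels, activity_pct = activity_pct,
                            stringsAsFactors = FALSE),
         ddg = cbind(data.frame(variant = labels, stringsAsFactors = FALSE),
                     ddg),
         truth = list(slopes = slopes, intercepts = intercepts,
                      noise_sd = noise_sd))
  })
}

#' Generate an additive-plus-epistatic ddG landscape over mutable sites
#'
#' Single-mutant ddG triples are drawn i.i.d. Gaussian with means chosen so
#' that roughly a third of substitutions improve binding (matching the
#' proportions seen in saturation scans of unfavorable interface residues).
#' The most promising singles are then combined into double/triple/quadruple
#' variants whose triples are the sum of their constituents plus a Gaussian
#' epistatic (synergistic) deviation per component. The additive part is the
#' ground truth: the best variant by additive score is recorded for
#' recovery tests.
#'
#' @param sites data frame `wt_res`, `position` of mutable sites.
#' @param weights scoring weights (default published calibration).
#' @param n_combination_singles how many top singles feed combinations.
#' @param max_k largest combination size (default 4).
#' @param epistasis_sd kcal/mol sd of the per-component epistatic deviation.
#' @param single_mean,single_sd length-3 mean/sd of the single-mutant ddG
#'   components.
#' @param seed integer seed.
#' @return list with `table` (all singles + combinations, scoring-ready),
#'   `singles` (singles only), and `truth` (`best_variant`, additive table,
#'   epistasis_sd).
#' @export
gen_ddg_landscape <- function(sites, weights = NULL,
                              n_combination_singles = 5, max_k = 4,
                              epistasis_sd = 0.3,
                              single_mean = c(0.6, 0.8, 0.7),
                              single_sd = c(1.6, 1.5, 1.3),
                              seed = 1) {
  stopifnot(nrow(sites) >= 1)
  if (is.null(weights)) weights <- il18_published_calibration()$weights
  singles <- saturate(sites)
  with_seed(seed, {
    n <- length(singles)
    stab <- data.frame(
      variant = vapply(singles, variant_label, ""),
      ddg_binding = stats::rnorm(n, single_mean[1L], single_sd[1L]),
      ddg_fold_complex = stats::rnorm(n, single_mean[2L], single_sd[2L]),
      ddg_fold_ligand = stats::rnorm(n, single_mean[3L], single_sd[3L]),
      stringsAsFactors = FALSE
    )
    ranked_singles <- rank_variants(score_variants(stab, weights))
    top <- utils::head(ranked_singles$variant, n_combination_singles)
    top_v <- lapply(top, parse_variant)
    combos <- list()
    for (k in 2:max_k) combos <- c(combos, combine_variants(top_v, k))
    add_rows <- lapply(combos, function(v) {
      tr <- additive_ddg(v, stab)
      data.frame(variant = variant_label(v), ddg_binding = tr[[1L]],
                 ddg_fold_complex = tr[[2L]], ddg_fold_ligand = tr[[3L]],
                 stringsAsFactors = FALSE)
    })
    additive <- rbind(stab, do.call(rbind, add_rows))
    observed <- additive
    if (length(combos)) {
      ci <- seq.int(nrow(stab) + 1L, nrow(additive))
      for (col in c("ddg_binding", "ddg_fold_complex", "ddg_fold_ligand")) {
        observed[ci, col] <- observed[ci, col] +
          stats::rnorm(length(ci), 0, epistasis_sd)
      }
    }
    best <- rank_variants(score_variants(additive, weights))$variant[1L]
    list(table = observed, singles = stab,
         truth = list(best_variant = best, additive = additive,
                      epistasis_sd = epistasis_sd))
  })
}

#' Generate an idealized toy structure with an engineered hydrogen bond
#'
#' An extended chain (7 Angstrom residue spacing, so chain neighbours never
#' satisfy hydrogen-bond geometry) of backbone atoms (N, CA, C, O) plus the
#' amide hydrogen. The carbonyl oxygen of the last residue is repositioned
#' near the first residue's amide group so that exactly one
#' donor-hydrogen-acceptor triple has the requested donor-acceptor distance
#' and angle — a constructed fixture for hydrogen-bond detection.
#'
#' @param n_res number of residues (>= 2).
#' @param hbond_distance engineered donor-acceptor distance, Angstrom.
#' @param hbond_angle engineered donor-hydrogen-acceptor angle, degrees.
#' @return one-frame `md_traj`; attributes `donor_res` (1) and
#'   `acceptor_res` (`n_res`) record the engineered pair.
#' @export
gen_toy_structure <- function(n_res = 10, hbond_distance = 2.9,
                              hbond_angle = 170) {
  stopifnot(n_res >= 2, hbond_distance > 0,
            hbond_angle > 90, hbond_angle <= 180)
  spacing <- 7
  atoms <- NULL
  xyz <- NULL
  for (i in seq_len(n_res)) {
    x0 <- spacing * (i - 1L)
    res_atoms <- data.frame(
      elety = c("N", "H", "CA", "C", "O"),
      resid = "GLY", chain = "A", resno = i,
      elesy = c("N", "H", "C", "C", "O"), stringsAsFactors = FALSE)
    res_xyz <- rbind(c(x0, 0, 0), c(x0, 1.01, 0), c(x0 + 1.5, 0, 0),
                     c(x0 + 2.9, 0, 0), c(x0 + 2.9, -1.2, 0))
    atoms <- rbind(atoms, res_atoms)
    xyz <- rbind(xyz, res_xyz)
  }
  # engineered acceptor: solve for the O position giving the requested
  # D-A distance and D-H-A angle at the hydrogen of residue 1
  N <- xyz[1L, ]
  H <- xyz[2L, ]
  theta <- (180 - hbond_angle) * pi / 180  # deviation from linear
  dir <- c(sin(theta), cos(theta), 0)      # H->A; H->D is (0,-1,0)
  dh <- sqrt(sum((N - H)^2))
  tt <- (-2 * dh * cos(pi - hbond_angle * pi / 180) +
         sqrt((2 * dh * cos(pi - hbond_angle * pi / 180))^2 -
              4 * (dh^2 - hbond_distance^2))) / 2
  acceptor_row <- which(atoms$resno == n_res & atoms$elety == "O")
  xyz[acceptor_row, ] <- H + tt * dir
  traj <- md_traj(atoms, as.numeric(t(xyz)))
  attr(traj, "donor_res") <- 1L
  attr(traj, "acceptor_res") <- n_res
  traj
}

#' Generate a synthetic trajectory of harmonic positional fluctuations
#'
#' Each frame displaces every atom of the reference by isotropic Gaussian
#' noise whose standard deviation per coordinate is `amplitude`, multiplied
#' by `loop_amplitude_factor` for residues inside `loop_region` — an
#' elevated-mobility loop planted into an otherwise uniformly fluctuating
#' structure (by default residues 106-112, the flexible hairpin-loop
#' analogue). Optionally each frame also receives a global random rigid
#' rotation + translation, which downstream alignment must remove.
#'
#' @param reference one-frame `md_traj` with backbone atoms.
#' @param n_frames number of frames.
#' @param amplitude per-coordinate fluctuation sd, Angstrom.
#' @param loop_region residue indices with elevated amplitude.
#' @param loop_amplitude_factor multiplier inside `loop_region`.
#' @param rigid_motion logical; add a random global rigid transform per
#'   frame.
#' @param time_step ns between frames.
#' @param seed integer seed.
#' @return an `md_traj` with `n_frames` frames.
#' @export
gen_trajectory <- function(reference, n_frames = 100, amplitude = 0.3,
                           loop_region = 106:112,
                           loop_amplitude_factor = 1,
                           rigid_motion = FALSE, time_step = 0.06,
                           seed = 1) {
  stopifnot(inherits(reference, "md_traj"), n_frames >= 1, amplitude >= 0,
            loop_amplitude_factor >= 0)
  ref_xyz <- frame_coords(reference)
  n_atoms <- nrow(ref_xyz)
  amp <- rep(amplitude, n_atoms)
  amp[reference$atoms$resno %in% loop_region] <-
    amplitude * loop_amplitude_factor
  with_seed(seed, {
    frames <- matrix(NA_real_, n_frames, 3L * n_atoms)
    for (f in seq_len(n_frames)) {
      xyz <- ref_xyz + matrix(stats::rnorm(3L * n_atoms, 0, amp),
                              ncol = 3L)  # amp recycles per coordinate row
      if (rigid_motion) {
        xyz <- xyz %*% random_rotation() +
          matrix(stats::runif(3, -5, 5), n_atoms, 3L, byrow = TRUE)
      }
      frames[f, ] <- as.numeric(t(xyz))
    }
    md_traj(reference$atoms, frames, time = (seq_len(n_frames) - 1) *
              time_step)
  })
}

# Uniform random proper rotation (quaternion method).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}
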