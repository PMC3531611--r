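# Synthetic-data generators.  These replace the two inputs the pipeline
# cannot regenerate at the desk: replicate plate fluorescence and solvated
# zipper trajectories.  Both are seeded and reproducible, and both return
# their ground truth alongside the data so every downstream operation can
# be tested against known values.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Parameters for simulated ThT replicate sets
#'
#' Defaults emulate one plate condition of the aggregation assay: 40
#' replicate wells, sigmoidal growth with well-to-well variation in both
#' half-time and plateau, white detector noise at about 1% of the plateau,
#' and a constant dye blank.  The default half-time scale (10 +/- 1 s) is
#' in the few-second regime the fast-aggregation conditions occupy; time
#' sampling (121 points to 3x the mean half-time) resolves the transition
#' well.
#'
#' @param n_replicates Wells per condition (default 40; >= 5).
#' @param true_t50_mean,true_t50_sd Ground-truth half-time distribution,
#'   seconds (default 10, 1).
#' @param steepness Logistic growth rate k in 1/s (default 1).
#' @param lag_shape Sigmoid family: `"logistic"` (default) or `"gompertz"`
#'   (asymmetric, for lag-robustness tests).
#' @param plateau_mean,plateau_cv Plateau amplitude distribution, arbitrary
#'   units (default 100, 0.1).  `plateau_mean = 0` yields non-aggregating
#'   wells.
#' @param noise_sd White-noise SD in the same units (default 1).
#' @param blank_level Constant dye background added to every well
#'   (default 50).
#' @param t_max,dt Time grid `seq(0, t_max, by = dt)` in seconds (defaults
#'   `3 * true_t50_mean` and `t_max / 120`).
#' @param seed RNG seed.
#' @return An object of class `tht_sim_params`.
#' @export
tht_sim_params <- function(n_replicates = 40, true_t50_mean = 10,
                           true_t50_sd = 1, steepness = 1,
                           lag_shape = c("logistic", "gompertz"),
                           plateau_mean = 100, plateau_cv = 0.1,
                           noise_sd = 1, blank_level = 50,
                           t_max = NULL, dt = NULL, seed = 1) {
  lag_shape <- match.arg(lag_shape)
  stopifnot(n_replicates >= 5, true_t50_mean > 0, true_t50_sd >= 0,
            steepness > 0, plateau_mean >= 0, plateau_cv >= 0,
            noise_sd >= 0, blank_level >= 0)
  t_max <- t_max %||% (3 * true_t50_mean)
  dt <- dt %||% (t_max / 120)
  structure(list(n_replicates = as.integer(n_replicates),
                 true_t50_mean = true_t50_mean, true_t50_sd = true_t50_sd,
                 steepness = steepness, lag_shape = lag_shape,
                 plateau_mean = plateau_mean, plateau_cv = plateau_cv,
                 noise_sd = noise_sd, blank_level = blank_level,
                 t_max = t_max, dt = dt, seed = seed),
            class = "tht_sim_params")
}

#' Preset for a condition with too broad a rate spread for a single t50
#'
#' Emulates the double phosphovariant's behaviour at acid pH: wells span a
#' wide range of half-times, so the replicate histogram is too broad for a
#' meaningful single summary value.
#'
#' @param ... Overrides passed to [tht_sim_params()].
#' @return A `tht_sim_params` with `true_t50_sd` at half the mean.
#' @export
tht_sim_params_wide_spread <- function(...) {
  defaults <- list(true_t50_mean = 20, true_t50_sd = 10, t_max = 80)
  args <- utils::modifyList(defaults, list(...))
  do.call(tht_sim_params, args)
}

#' Simulate a replicate set of ThT curves
#'
#' Each replicate well i is `blank_level + A_i * L(t; tau_i, k) + eps(t)`
#' with L a logistic (or Gompertz) sigmoid, `tau_i ~ Normal(mean, sd)`
#' amplitude `A_i ~ Normal(plateau_mean, cv * plateau_mean)` and white
#' noise eps.  The blank well carries the same background and noise with
#' no signal.  The returned [replicate_set()] has the per-well ground
#' truth attached as `attr(, "truth")`: `tau` (sigmoid midpoint), `A`, and
#' `true_t50` (the time the noiseless curve crosses half its plateau --
#' equal to tau for the logistic, offset by `log(log(2)) / k` for the
#' Gompertz).
#'
#' @param params A [tht_sim_params()].
#' @param variant,pH Labels stored on the set.
#' @return A [replicate_set()] with a `truth` attribute.
#' @export
simulate_tht_replicates <- function(params = tht_sim_params(),
                                    variant = "synthetic", pH = NA_real_) {
  stopifnot(inherits(params, "tht_sim_params"))
  if (params$plateau_mean < 0) stop("plateau_mean implies negative plateau")
  times <- seq(0, params$t_max, by = params$dt)
  with_seed(params$seed, {
    tau <- stats::rnorm(params$n_replicates, params$true_t50_mean,
                        params$true_t50_sd)
    A <- stats::rnorm(params$n_replicates, params$plateau_mean,
                      params$plateau_cv * params$plateau_mean)
    A <- pmax(A, 0)
    sig <- function(t, tau) switch(params$lag_shape,
                                   logistic = stats::plogis(params$steepness * (t - tau)),
                                   gompertz = exp(-exp(-params$steepness * (t - tau))))
    curves <- lapply(seq_len(params$n_replicates), function(i) {
      y <- params$blank_level + A[i] * sig(times, tau[i]) +
        stats::rnorm(length(times), 0, params$noise_sd)
      kinetic_curve(times, y, sprintf("W%02d", i))
    })
    blank <- kinetic_curve(times,
                           params$blank_level +
                             stats::rnorm(length(times), 0, params$noise_sd),
                           "blank")
    set <- replicate_set(curves, blank, variant = variant, pH = pH)
    true_t50 <- switch(params$lag_shape,
                       logistic = tau,
                       gompertz = tau - log(log(2)) / params$steepness)
    attr(set, "truth") <- data.frame(tau = tau, A = A, true_t50 = true_t50)
    set
  })
}

#' Parameters for simulated zipper trajectories
#'
#' @param base_model Two-sheet [fibril_model()] (with sheet provenance).
#' @param n_frames Number of frames.
#' @param interior Per-frame counts of waters planted strictly inside the
#'   interface region (length `n_frames`, recycled from length 1).
#' @param exterior Per-frame counts of waters planted outside the region
#'   (recycled likewise; default 50).
#' @param jitter_sd Coordinate jitter SD in Angstrom applied to the
#'   peptide before water placement (default 0.3).
#' @param inset,threshold Region/verdict parameters matching the analysis
#'   defaults.
#' @param times Frame times in ns (default 0, 1, 2, ...).
#' @param seed RNG seed.
#' @return An object of class `traj_sim_params`.
#' @export
traj_sim_params <- function(base_model, n_frames = 11, interior = 0,
                            exterior = 50, jitter_sd = 0.3, inset = 1.0,
                            threshold = 5, times = NULL, seed = 1) {
  stopifnot(inherits(base_model, "fibril_model"), n_frames >= 1,
            jitter_sd >= 0)
  if (is.null(attr(base_model, "sheet_of_chain")))
    stop("base model needs two-sheet provenance")
  interior <- rep_len(as.integer(interior), n_frames)
  exterior <- rep_len(as.integer(exterior), n_frames)
  stopifnot(all(interior >= 0), all(exterior >= 0))
  times <- times %||% (seq_len(n_frames) - 1)
  stopifnot(length(times) == n_frames)
  structure(list(base_model = base_model, n_frames = as.integer(n_frames),
                 interior = interior, exterior = exterior,
                 jitter_sd = jitter_sd, inset = inset, threshold = threshold,
                 times = times, seed = seed),
            class = "traj_sim_params")
}

#' Narrative water-count presets for trajectory simulations
#'
#' Plateau interior water counts emulating the qualitative behaviour
#' classes of solvated zipper simulations of the phosphovariants: a
#' protonated (neutral) phosphate leaves the interface dry; a mono-anionic
#' phosphate floods position-5 and position-8 zippers (roughly 60 and 20
#' waters) but not position 9; a di-anionic phosphate floods all three
#' (roughly 55, 35 and 35).  These are generator presets for synthetic
#' tests, not reproductions of any simulation.
#'
#' @return Named list of named numeric vectors (`protonated`,
#'   `mono_anionic`, `di_anionic`).
#' @export
traj_water_presets <- function() {
  list(protonated = c(p5Y = 0, p8Y = 0, p9Y = 0),
       mono_anionic = c(p5Y = 60, p8Y = 20, p9Y = 0),
       di_anionic = c(p5Y = 55, p8Y = 35, p9Y = 35))
}

#' Simulate a zipper trajectory with planted interface waters
#'
#' Each frame is a jittered copy of the base model; the interface region
#' is then recomputed on the jittered coordinates and exactly the
#' scheduled number of interior waters is placed uniformly inside it
#' (rejection sampling with a 2.8 Angstrom water-water exclusion), plus
#' the scheduled exterior waters outside it.  Because waters are placed
#' after the jitter, the interior count of every frame equals the schedule
#' exactly, which is the generator's ground truth
#' (`attr(, "truth")$interior`).
#'
#' @param params A [traj_sim_params()].
#' @return List of [trajectory_frame()] objects with a `truth` attribute.
#' @export
simulate_zipper_trajectory <- function(params) {
  stopifnot(inherits(params, "traj_sim_params"))
  with_seed(params$seed, {
    frames <- vector("list", params$n_frames)
    for (f in seq_len(params$n_frames)) {
      pep <- params$base_model
      if (params$jitter_sd > 0) {
        pep$x <- pep$x + stats::rnorm(nrow(pep), 0, params$jitter_sd)
        pep$y <- pep$y + stats::rnorm(nrow(pep), 0, params$jitter_sd)
        pep$z <- pep$z + stats::rnorm(nrow(pep), 0, params$jitter_sd)
      }
      region <- define_interface_region(pep, inset = params$inset)
      wat_in <- place_waters(region, params$interior[f], inside = TRUE)
      wat_out <- place_waters(region, params$exterior[f], inside = FALSE)
      frames[[f]] <- trajectory_frame(params$times[f], pep,
                                      waters = rbind(wat_in, wat_out))
    }
    attr(frames, "truth") <- data.frame(time = params$times,
                                        interior = params$interior,
                                        exterior = params$exterior)
    frames
  })
}

# rejection-sample water oxygens inside (or outside) the region prism,
# with a 2.8 A exclusion between placed interior waters
place_waters <- function(region, n, inside, exclusion = 2.8,
                         max_tries = 20000L) {
  if (n == 0L) return(matrix(numeric(), 0, 3))
  hr <- range(region$hull[, 1]); vr <- range(region$hull[, 2])
  pad <- region$dilate + if (inside) 0 else 10
  placed <- matrix(NA_real_, n, 3)
  got <- 0L
  for (try in seq_len(max_tries)) {
    w <- if (inside) stats::runif(1, region$lo, region$hi)
    else stats::runif(1, region$lo - 8, region$hi + 8)
    uv <- c(stats::runif(1, hr[1] - pad, hr[2] + pad),
            stats::runif(1, vr[1] - pad, vr[2] + pad))
    p <- region$origin + w * region$normal + region$basis %*% uv
    ok <- points_in_region(matrix(p, 1, 3), region)
    if (ok != inside) next
    if (inside && got > 0L) {
      d2 <- colSums((t(placed[seq_len(got), , drop = FALSE]) - c(p))^2)
      if (min(d2) < exclusion^2) next
    }
    got <- got + 1L
    placed[got, ] <- p
    if (got == n) return(placed)
  }
  stop("water schedule exceeds region capacity at ", exclusion,
       " A exclusion (placed ", got, " of ", n, ")")
}
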