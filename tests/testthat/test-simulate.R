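test_that("simulations are seed-reproducible and seed-sensitive", {
  s1 <- simulate_tht_replicates(tht_sim_params(seed = 17))
  s2 <- simulate_tht_replicates(tht_sim_params(seed = 17))
  s3 <- simulate_tht_replicates(tht_sim_params(seed = 18))
  expect_identical(s1$curves[[1]]$intensities, s2$curves[[1]]$intensities)
  expect_identical(attr(s1, "truth"), attr(s2, "truth"))
  expect_false(identical(s1$curves[[1]]$intensities, s3$curves[[1]]$intensities))

  m7 <- default_zipper(7)
  t1 <- simulate_zipper_trajectory(traj_sim_params(m7, n_frames = 2,
                                                   interior = 3, seed = 5))
  t2 <- simulate_zipper_trajectory(traj_sim_params(m7, n_frames = 2,
                                                   interior = 3, seed = 5))
  expect_identical(t1[[1]]$waters, t2[[1]]$waters)
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99); a <- rnorm(1)
  set.seed(99); invisible(simulate_tht_replicates(tht_sim_params(seed = 1)))
  b <- rnorm(1)
  expect_identical(a, b)
})

test_that("the noiseless limit recovers the true half-time exactly", {
  p <- tht_sim_params(noise_sd = 0, true_t50_sd = 0, plateau_cv = 0, seed = 1)
  set <- simulate_tht_replicates(p)
  out <- process_replicates(set)
  # interpolation on a smooth sigmoid: error far below the sampling step
  expect_equal(out$summary$mean_t50, 10, tolerance = 1e-3)
  expect_equal(out$summary$sd_t50, 0, tolerance = 1e-6)
})

test_that("zero plateau wells are called non-aggregating", {
  set <- simulate_tht_replicates(tht_sim_params(plateau_mean = 0, seed = 2))
  call <- classify_assembly(subtract_blank(set))
  expect_identical(call$outcome, "no_fibrils")
})

test_that("generator ground truth matches the sigmoid midpoint family", {
  pg <- tht_sim_params(lag_shape = "gompertz", noise_sd = 0, true_t50_sd = 0,
                       plateau_cv = 0, seed = 3)
  set <- simulate_tht_replicates(pg)
  truth <- attr(set, "truth")
  # gompertz midpoint is offset from tau by -log(log 2) / k
  expect_equal(truth$true_t50[1], truth$tau[1] - log(log(2)), tolerance = 1e-12)
  out <- process_replicates(set)
  expect_equal(out$summary$mean_t50, truth$true_t50[1], tolerance = 2e-2)
})

test_that("the wide-spread preset defeats a single t50 summary", {
  narrow <- simulate_tht_replicates(tht_sim_params(seed = 8))
  wide <- simulate_tht_replicates(tht_sim_params_wide_spread(seed = 8))
  sd_n <- sd(attr(narrow, "truth")$true_t50)
  sd_w <- sd(attr(wide, "truth")$true_t50)
  expect_gt(sd_w, 4 * sd_n)
})

test_that("planted water schedules are honoured exactly, with jitter", {
  m7 <- default_zipper(7)
  for (js in c(0, 0.3)) {
    sched <- c(0, 5, 12)
    traj <- simulate_zipper_trajectory(
      traj_sim_params(m7, n_frames = 3, interior = sched, exterior = 30,
                      jitter_sd = js, seed = 11))
    ps <- penetration_series(traj)
    expect_identical(ps$n_waters, as.integer(sched))
    truth <- attr(traj, "truth")
    expect_identical(truth$interior, as.integer(sched))
  }
})

test_that("planted interior waters respect the exclusion distance", {
  m7 <- default_zipper(7)
  traj <- simulate_zipper_trajectory(
    traj_sim_params(m7, n_frames = 1, interior = 25, exterior = 0,
                    jitter_sd = 0, seed = 14))
  W <- traj[[1]]$waters
  d <- as.matrix(dist(W))
  diag(d) <- Inf
  expect_gte(min(d), 2.8)
})

test_that("impossible schedules hit the capacity error", {
  m7 <- default_zipper(7)
  expect_error(simulate_zipper_trajectory(
    traj_sim_params(m7, n_frames = 1, interior = 5000, seed = 1)),
    "capacity")
})

test_that("all-dry and flooded schedules map to the verdict classes", {
  m7 <- default_zipper(7)
  dry <- simulate_zipper_trajectory(
    traj_sim_params(m7, n_frames = 5, interior = 0, seed = 3))
  expect_identical(attr(penetration_series(dry), "verdict"), "stable")
  presets <- traj_water_presets()
  flooded <- simulate_zipper_trajectory(
    traj_sim_params(m7, n_frames = 5,
                    interior = round(seq(0, presets$mono_anionic[["p5Y"]],
                                         length.out = 5)),
                    seed = 3))
  expect_identical(attr(penetration_series(flooded), "verdict"), "dissolved")
})

test_that("the transcribed outcome fixture matches the observed pattern", {
  oc <- strand_e_outcomes()
  pick <- function(v, ph) oc[oc$variant == v & abs(oc$pH - ph) < 1e-9, ]
  expect_identical(pick("p5Y", 3.6)$outcome, "no_fibrils")
  expect_identical(pick("p8Y", 3.6)$outcome, "no_fibrils")
  expect_identical(pick("p3S10T", 3.6)$outcome, "no_fibrils")
  expect_identical(pick("p9Y", 3.6)$outcome, "fibrils")
  expect_identical(pick("p9Y", 7.5)$outcome, "no_fibrils")
  expect_identical(pick("control", 7.5)$outcome, "fibrils")
  expect_true(all(pick("control", 1.1)$outcome == "fibrils"))
  expect_identical(sum(oc$outcome == "no_fibrils" & oc$pH == 7.5), 7L)
  expect_true(all(oc$outcome == "fibrils" | oc$pH > 1.2))
  # censoring bookkeeping: censored iff no fibrils
  expect_true(all(is.na(oc$censored_at) == (oc$outcome == "fibrils")))
  # the double variant carries no t50 at acid pH (spread too wide)
  expect_true(is.na(pick("p3S10T", 1.1)$t50))
})

test_that("outcome matrices survive a TSV round-trip", {
  oc <- strand_e_outcomes()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_outcomes(oc[, c("variant", "pH", "outcome", "t50")], path)
  back <- read_outcomes(path)
  expect_identical(back$variant, oc$variant)
  expect_identical(back$outcome, oc$outcome)
  expect_equal(back$t50, oc$t50)
})

test_that("plate files round-trip through wide and long readers", {
  set <- simulate_tht_replicates(tht_sim_params(n_replicates = 5, seed = 20))
  t <- set$curves[[1]]$times
  wide <- data.frame(time = t)
  for (cv in set$curves) wide[[cv$well_id]] <- cv$intensities
  wide$BLK <- set$blank$intensities
  pw <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(wide, pw, row.names = FALSE)
  curves <- read_plate_wide(pw)
  expect_length(curves, 6L)
  expect_equal(curves$W01$intensities, set$curves[[1]]$intensities)

  long <- do.call(rbind, lapply(names(curves), function(w)
    data.frame(well = w, time = t, intensity = curves[[w]]$intensities)))
  pl <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(long, pl, sep = "\t", row.names = FALSE, quote = FALSE)
  curves2 <- read_plate_long(pl)
  expect_equal(curves2$W03$intensities, curves$W03$intensities)

  map <- read_plate_map(text = "
W01: {variant: control, pH: 1.1}
W02: {variant: control, pH: 1.1}
W03: {variant: control, pH: 1.1}
W04: {variant: p9Y, pH: 1.1}
W05: {variant: p9Y, pH: 1.1}
BLK: blank
")
  sets <- assemble_plate(curves, map)
  expect_length(sets, 2L)
  expect_identical(sets$`control@1.1`$variant, "control")
  expect_length(sets$`control@1.1`$curves, 3L)
  expect_length(sets$`p9Y@1.1`$curves, 2L)
})
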