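test_that("the interface slab spans the inter-plane gap minus the insets", {
  m7 <- default_zipper(7)
  region <- define_interface_region(m7, inset = 1)
  expect_equal(region$separation, 12, tolerance = 1e-6)
  expect_equal(region$hi - region$lo, 12 - 2, tolerance = 1e-6)
  expect_error(define_interface_region(m7, inset = 6), "degenerate slab")
})

test_that("models without provenance need an explicit sheet partition", {
  m7 <- default_zipper(7)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_model(m7, path)
  back <- read_model(path)
  expect_error(define_interface_region(back), "sheet partition")
  region <- define_interface_region(back, sheets = "A-H,I-P")
  expect_equal(region$separation, 12, tolerance = 1e-3)
})

test_that("water counting matches planted ground truth exactly", {
  m7 <- default_zipper(7)
  sched <- c(0, 2, 7, 4)
  traj <- simulate_zipper_trajectory(
    traj_sim_params(m7, n_frames = 4, interior = sched, exterior = 50,
                    jitter_sd = 0, seed = 9))
  counts <- vapply(traj, function(fr)
    count_interface_waters(fr, define_interface_region(fr$peptide)), 1L)
  expect_identical(counts, as.integer(sched))
  # empty water list counts zero
  empty <- trajectory_frame(0, m7)
  expect_identical(count_interface_waters(empty, define_interface_region(m7)), 0L)
})

test_that("boundary waters are excluded by the strict inequality", {
  m7 <- default_zipper(7)
  region <- define_interface_region(m7)
  ctr_uv <- colMeans(region$hull)
  at_w <- function(w) c(region$origin + w * region$normal +
                          region$basis %*% ctr_uv)
  # straddle the lower bounding plane: only the interior point counts
  fr <- trajectory_frame(0, m7, waters = rbind(at_w(region$lo - 1e-6),
                                               at_w(region$lo + 1e-6)))
  expect_identical(count_interface_waters(fr, region), 1L)
  # and symmetrically at the upper plane
  fr2 <- trajectory_frame(0, m7, waters = rbind(at_w(region$hi - 1e-6),
                                                at_w(region$hi + 1e-6)))
  expect_identical(count_interface_waters(fr2, region), 1L)
})

test_that("counting equals a brute-force point-in-prism oracle", {
  skip_if_not_installed("mgcv")
  m7 <- default_zipper(7)
  region <- define_interface_region(m7)
  set.seed(21)
  # scatter waters over a box covering the model and then some
  W <- cbind(runif(400, min(m7$x) - 10, max(m7$x) + 10),
             runif(400, min(m7$y) - 10, max(m7$y) + 10),
             runif(400, min(m7$z) - 10, max(m7$z) + 10))
  fr <- trajectory_frame(0, m7, waters = W)
  got <- count_interface_waters(fr, region)

  # independent oracle: slab test along the normal plus dilated-hull test
  # via mgcv's point-in-polygon and a direct segment-distance scan
  rel <- W - matrix(region$origin, nrow(W), 3, byrow = TRUE)
  w <- rel %*% region$normal
  uv <- rel %*% region$basis
  hull <- region$hull
  inside_poly <- mgcv::in.out(rbind(hull, hull[1, ]), uv)
  seg_dist <- function(p) {
    n <- nrow(hull); d <- Inf
    for (i in seq_len(n)) {
      a <- hull[i, ]; b <- hull[if (i == n) 1 else i + 1, ]
      t <- sum((p - a) * (b - a)) / sum((b - a)^2)
      t <- min(1, max(0, t))
      d <- min(d, sqrt(sum((p - (a + t * (b - a)))^2)))
    }
    d
  }
  near_poly <- apply(uv, 1, seg_dist) < region$dilate
  oracle <- sum(w > region$lo & w < region$hi & (inside_poly | near_poly))
  expect_identical(got, as.integer(oracle))
  expect_gt(got, 0)   # the box does cover the interface
})

test_that("counts are invariant under joint rigid motion", {
  m7 <- default_zipper(7)
  traj <- simulate_zipper_trajectory(
    traj_sim_params(m7, n_frames = 1, interior = 11, exterior = 60,
                    jitter_sd = 0, seed = 4))
  fr <- traj[[1]]
  moved_pep <- rigid_move(fr$peptide)
  Rm <- attr(moved_pep, "rigid_R"); tr <- attr(moved_pep, "rigid_t")
  moved <- trajectory_frame(fr$time, moved_pep,
                            waters = fr$waters %*% t(Rm) +
                              matrix(tr, nrow(fr$waters), 3, byrow = TRUE))
  c0 <- count_interface_waters(fr, define_interface_region(fr$peptide))
  c1 <- count_interface_waters(moved, define_interface_region(moved_pep))
  expect_identical(c0, 11L)
  expect_identical(c1, c0)
})

test_that("the verdict is monotone in threshold and inset", {
  m7 <- default_zipper(7)
  traj <- simulate_zipper_trajectory(
    traj_sim_params(m7, n_frames = 3, interior = c(0, 3, 3), jitter_sd = 0,
                    seed = 2))
  expect_identical(attr(penetration_series(traj, threshold = 5), "verdict"),
                   "stable")
  expect_identical(attr(penetration_series(traj, threshold = 3), "verdict"),
                   "dissolved")
  expect_identical(attr(penetration_series(traj, threshold = 1), "verdict"),
                   "dissolved")
  # larger inset shrinks the region: counts cannot increase
  for (fr in traj) {
    c1 <- count_interface_waters(fr, define_interface_region(fr$peptide, inset = 1))
    c3 <- count_interface_waters(fr, define_interface_region(fr$peptide, inset = 3))
    expect_lte(c3, c1)
  }
})

test_that("a ramp of planted waters dissolves the zipper", {
  m7 <- default_zipper(7)
  ramp <- round(seq(0, 60, length.out = 7))
  traj <- simulate_zipper_trajectory(
    traj_sim_params(m7, n_frames = 7, interior = ramp, jitter_sd = 0.3,
                    seed = 6))
  ps <- penetration_series(traj)
  expect_identical(attr(ps, "verdict"), "dissolved")
  expect_identical(max(ps$n_waters), 60L)
  expect_identical(ps$n_waters, as.integer(ramp))
})

test_that("sheet separation beyond twice the initial gap forces dissolution", {
  m7 <- default_zipper(7)
  soc <- attr(m7, "sheet_of_chain")
  blown <- m7
  sel <- blown$chain %in% names(soc)[soc == 2L]
  blown$z[sel] <- blown$z[sel] + 18    # gap 12 -> 30 > 2 x 12
  frames <- list(trajectory_frame(0, m7), trajectory_frame(1, blown))
  ps <- penetration_series(frames)
  expect_identical(attr(ps, "verdict"), "dissolved")
  expect_true(attr(ps, "collapsed"))
  expect_true(all(ps$n_waters == 0))
})

test_that("frames with missing peptide atoms are named in the error", {
  m7 <- default_zipper(7)
  good <- trajectory_frame(0, m7)
  bad <- good
  bad$peptide <- m7[0, ]
  expect_error(penetration_series(list(good, bad)), "frame 2")
})

test_that("trajectory PDB round-trip preserves counts", {
  m7 <- default_zipper(7)
  traj <- simulate_zipper_trajectory(
    traj_sim_params(m7, n_frames = 3, interior = c(1, 4, 2), exterior = 20,
                    jitter_sd = 0, seed = 13))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_length(back, 3L)
  counts <- vapply(back, function(fr)
    count_interface_waters(fr, define_interface_region(fr$peptide,
                                                       sheets = "A-H,I-P")), 1L)
  expect_identical(counts, c(1L, 4L, 2L))
  expect_identical(nrow(back[[2]]$waters), 4L + 20L)
})
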