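test_that("ideal strand geometry matches textbook beta-strand values", {
  st <- build_ideal_strand("AA")
  ca <- st[st$elety == "CA", ]
  d <- sqrt(sum((ca[2, c("x", "y", "z")] - ca[1, c("x", "y", "z")])^2))
  expect_equal(d, 3.8, tolerance = 0.02)        # trans-peptide CA-CA spacing

  st13 <- build_ideal_strand(SEQ_E)
  ca13 <- st13[st13$elety == "CA", ]
  rise <- attr(st13, "rise")
  expect_equal(max(ca13$x) - min(ca13$x), 12 * rise, tolerance = 1e-9)
  expect_gt(rise, 3.2); expect_lt(rise, 3.6)    # extended-strand axial rise

  # glycine emits no CB
  stg <- build_ideal_strand("AGA")
  expect_identical(nrow(stg[stg$elety == "CB" & stg$resno == 2, ]), 0L)
  expect_identical(nrow(stg[stg$elety == "CB", ]), 2L)

  expect_error(build_ideal_strand("AXA"), "unknown residue")
})

test_that("side-chain pleat alternates across the sheet plane", {
  st <- build_ideal_strand(SEQ_E)
  cb <- st[st$elety == "CB", ]
  ca <- st[st$elety == "CA", ]
  dz <- cb$z - ca$z[match(cb$resno, ca$resno)]
  expect_true(all(abs(dz) > 0.5))
  expect_true(all(diff(sign(dz)) != 0))          # strict alternation
})

test_that("sheet registries realise the pairing rules", {
  st <- build_ideal_strand(SEQ_E)
  ca_x <- function(sheet, chain, resno) {
    a <- sheet[sheet$elety == "CA" & sheet$chain == chain & sheet$resno == resno, ]
    a$x
  }
  # antiparallel in-register: residue i faces residue 14 - i
  shr <- build_sheet(st, strand_arrangement("antiparallel_in_register"))
  expect_equal(ca_x(shr, "B", 9), ca_x(shr, "A", 5), tolerance = 0.35)
  expect_equal(ca_x(shr, "B", 5), ca_x(shr, "A", 9), tolerance = 0.35)
  # antiparallel shifted (s = -1): residue i faces residue 13 - i
  shs <- build_sheet(st, strand_arrangement("antiparallel_shifted"))
  expect_equal(ca_x(shs, "B", 8), ca_x(shs, "A", 5), tolerance = 0.35)
  expect_equal(ca_x(shs, "B", 4), ca_x(shs, "A", 9), tolerance = 0.35)
  # parallel: residue i directly above residue i
  shp <- build_sheet(st, strand_arrangement("parallel_in_register"))
  expect_equal(ca_x(shp, "B", 5), ca_x(shp, "A", 5))
  # strand spacing along the fibril axis is the hydrogen-bond repeat
  yA <- mean(shs$y[shs$chain == "A"]); yB <- mean(shs$y[shs$chain == "B"])
  expect_equal(abs(yB - yA), 4.8, tolerance = 0.2)
})

test_that("excessive registry shifts are rejected", {
  st <- build_ideal_strand(SEQ_E)
  expect_error(build_sheet(st, strand_arrangement("antiparallel_shifted",
                                                  registry_shift = -10)),
               "fewer than 4 residues")
  expect_error(strand_arrangement("parallel_in_register", registry_shift = 2),
               "must be 0")
})

test_that("in-register sheets are hydrogen-bond compatible", {
  st <- build_ideal_strand(SEQ_E)
  for (kind in c("antiparallel_in_register", "antiparallel_shifted",
                 "parallel_in_register")) {
    hb <- hbond_distances(build_sheet(st, strand_arrangement(kind)))
    # no overclose contacts, and the bonded alternation of residue pairs
    # sits in the canonical N...O band between every adjacent strand pair
    expect_gt(min(hb$d_NO), 2.6)
    frac <- tapply(hb$d_NO >= 2.7 & hb$d_NO <= 3.3,
                   paste(hb$chain1, hb$chain2), mean)
    expect_true(all(frac >= 0.4), info = kind)
  }
})

test_that("the zipper taxonomy enumerates 8 distinct classes", {
  cls <- enumerate_zipper_classes()
  expect_length(cls, 8L)
  expect_identical(vapply(cls, `[[`, 1L, "class_id"), 1:8)
  keys <- vapply(cls, function(d) paste(d$strand_orientation,
                                        d$sheet_face_packing,
                                        d$sheet_polarity), "")
  expect_identical(anyDuplicated(keys), 0L)
  anti <- vapply(cls, function(d) d$strand_orientation == "antiparallel", TRUE)
  expect_identical(sum(anti), 4L)
})

test_that("the shifted registry admits exactly classes 7 and 8", {
  ids <- function(cl) vapply(cl, `[[`, 1L, "class_id")
  sh <- shifted_compatible_classes()
  expect_identical(ids(sh), c(7L, 8L))
  expect_length(sh, 2L)
  # 7 and 8 share strand symmetry and differ only in face packing
  expect_identical(sh[[1]]$sheet_polarity, sh[[2]]$sheet_polarity)
  expect_false(sh[[1]]$sheet_face_packing == sh[[2]]$sheet_face_packing)
  par <- shifted_compatible_classes(arrangement =
                                      strand_arrangement("parallel_in_register"))
  expect_identical(ids(par), 1:4)
  reg <- shifted_compatible_classes(arrangement =
                                      strand_arrangement("antiparallel_in_register"))
  expect_identical(ids(reg), c(5L, 6L))
})

test_that("all eight classes build clash-free at default parameters", {
  for (cid in 1:8) {
    m <- build_class_zipper(SEQ_E, cid)
    expect_s3_class(m, "fibril_model")
    soc <- attr(m, "sheet_of_chain")
    expect_identical(sum(soc == 1L), 8L)
    expect_identical(sum(soc == 2L), 8L)
  }
})

test_that("inter-sheet separation is the mean-plane gap and scales", {
  gap <- function(m) {
    soc <- attr(m, "sheet_of_chain")
    abs(mean(m$z[m$chain %in% names(soc)[soc == 2]]) -
          mean(m$z[m$chain %in% names(soc)[soc == 1]]))
  }
  m12 <- default_zipper(7)
  m24 <- build_class_zipper(SEQ_E, 7,
                            params = build_params(inter_sheet_separation = 24))
  expect_equal(gap(m12), 12, tolerance = 1e-6)
  expect_equal(gap(m24), 24, tolerance = 1e-6)
})

test_that("class 7 and class 8 share their first sheet exactly", {
  strip <- function(m) {
    d <- as.data.frame(m)[m$chain %in% LETTERS[1:8],
                          c("chain", "resno", "elety", "x", "y", "z")]
    rownames(d) <- NULL
    d
  }
  expect_identical(strip(default_zipper(7)), strip(default_zipper(8)))
})

test_that("nearest-pair CB averaging matches a brute-force oracle", {
  # two chains, one CB pair 10 A apart across the interface
  mk_atom <- function(chain, resno, elety, x, y, z)
    data.frame(chain = chain, resno = resno, resid = "TYR", elety = elety,
               x = x, y = y, z = z)
  toy <- fibril_model(rbind(
    mk_atom("A", 1, "CA", 0, 0, 0), mk_atom("A", 1, "CB", 0, 0, 1),
    mk_atom("B", 1, "CA", 0, 0, 12), mk_atom("B", 1, "CB", 0, 0, 11)),
    sheet_of_chain = c(A = 1L, B = 2L))
  expect_equal(average_cb_distance(toy, 1), 10)

  # 4-chain toy with scattered CBs: oracle scans all cross-sheet pairs
  set.seed(3)
  rows <- list()
  for (k in 1:4) {
    sheet <- if (k <= 2) 1 else 2
    for (r in 1:3) {
      base_z <- if (sheet == 1) 0 else 12
      caz <- base_z
      cbz <- base_z + (if (sheet == 1) 1 else -1) * runif(1, 0.5, 2)
      xx <- runif(1, 0, 20); yy <- runif(1, 0, 10)
      rows[[length(rows) + 1L]] <- rbind(
        mk_atom(LETTERS[k], r, "CA", xx, yy, caz),
        mk_atom(LETTERS[k], r, "CB", xx, yy, cbz))
    }
  }
  toy4 <- fibril_model(do.call(rbind, rows),
                       sheet_of_chain = c(A = 1L, B = 1L, C = 2L, D = 2L))
  for (pos in 1:3) {
    cb <- toy4[toy4$elety == "CB" & toy4$resno == pos, ]
    P1 <- as.matrix(cb[cb$chain %in% c("A", "B"), c("x", "y", "z")])
    P2 <- as.matrix(cb[cb$chain %in% c("C", "D"), c("x", "y", "z")])
    D <- as.matrix(dist(rbind(P1, P2)))[seq_len(nrow(P1)),
                                        nrow(P1) + seq_len(nrow(P2)), drop = FALSE]
    oracle <- mean(c(apply(D, 1, min), apply(D, 2, min)))
    expect_equal(average_cb_distance(toy4, pos), oracle)
  }
})

test_that("CB distances are invariant under rigid motion of the model", {
  m7 <- default_zipper(7)
  moved <- rigid_move(m7)
  for (pos in c(5, 8, 9))
    expect_equal(average_cb_distance(moved, pos),
                 average_cb_distance(m7, pos), tolerance = 1e-9)
})

test_that("positions 5 and 8 pair symmetrically in both class builds", {
  for (cid in c(7, 8)) {
    m <- default_zipper(cid)
    expect_lt(abs(average_cb_distance(m, 5) - average_cb_distance(m, 8)), 0.5)
  }
})

test_that("glycine positions cannot be measured", {
  m <- build_class_zipper("DWGFYLLYYTEFT", 7)
  expect_error(average_cb_distance(m, 3), "CB missing")
})

test_that("PDB round-trip preserves the model", {
  m7 <- default_zipper(7)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_model(m7, path)
  lines <- readLines(path)
  expect_identical(sum(startsWith(lines, "TER")), 16L)
  expect_identical(tail(lines, 1), "END")
  back <- read_model(path)
  expect_identical(nrow(back), nrow(m7))
  expect_identical(back$elety, m7$elety)
  expect_identical(back$chain, m7$chain)
  expect_equal(back$x, m7$x, tolerance = 5e-4)
  expect_equal(back$z, m7$z, tolerance = 5e-4)
})

test_that("coordinates outside the PDB field width are rejected", {
  st <- build_ideal_strand("AA")
  st$x <- st$x + 1e5
  expect_error(write_model(st, withr::local_tempfile(fileext = ".pdb")),
               "fixed-width")
})

test_that("malformed PDB files fail with a line number", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_model(build_ideal_strand("A"), path)
  lines <- readLines(path)
  lines[2] <- substr(lines[2], 1, 40)   # truncate the CA record
  writeLines(lines, path)
  expect_error(read_model(path), "line 2")
})
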