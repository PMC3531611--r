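#' Strand-strand arrangement within a beta-sheet
#'
#' The three ways neighbouring beta-strands can associate in a sheet:
#' `parallel_in_register` (every strand identical, stacked along the fibril
#' axis), `antiparallel_in_register` (alternate strands reversed, residue i
#' pairing with residue N+1-i of its neighbour) and `antiparallel_shifted`
#' (reversed and translated along the strand axis by `registry_shift`
#' residues, so residue i pairs with residue N+1-i+s).  With the default
#' shift s = -1 on a 13-mer, residue 5 lies opposite residue 8 and residue
#' 9 opposite residue 4 of its neighbours -- the registry that aligns the
#' aromatic core and pairs Tyr5 with Tyr8' while isolating Tyr9.
#'
#' @param kind One of `"parallel_in_register"`, `"antiparallel_in_register"`,
#'   `"antiparallel_shifted"`.
#' @param registry_shift Integer shift s in residues; must be 0 unless the
#'   kind is `antiparallel_shifted` (default -1 there).
#' @return An object of class `strand_arrangement`.
#' @export
strand_arrangement <- function(kind = c("antiparallel_shifted",
                                        "parallel_in_register",
                                        "antiparallel_in_register"),
                               registry_shift = NULL) {
  kind <- match.arg(kind)
  if (is.null(registry_shift))
    registry_shift <- if (kind == "antiparallel_shifted") -1L else 0L
  registry_shift <- as.integer(registry_shift)
  if (kind != "antiparallel_shifted" && registry_shift != 0L)
    stop("registry_shift must be 0 for in-register arrangements")
  structure(list(kind = kind, registry_shift = registry_shift),
            class = "strand_arrangement")
}

#' @export
print.strand_arrangement <- function(x, ...) {
  cat(sprintf("<strand_arrangement> %s (shift %d)\n", x$kind, x$registry_shift))
  invisible(x)
}

#' Residue pairing rule of an arrangement
#'
#' For each residue position of a strand, the position of the residue that
#' lies directly opposite on an adjacent strand: `i` itself when parallel
#' in-register, `N+1-i` when antiparallel in-register and `N+1-i+s` when
#' antiparallel shifted (positions falling outside `1..n_res` pair with
#' nothing and are returned as `NA`).
#'
#' @param arrangement A [strand_arrangement()].
#' @param n_res Strand length.
#' @return Integer vector of partner positions (with `NA` for overhangs).
#' @examples
#' pairing_rule(strand_arrangement("antiparallel_in_register"), 13)[5] # 9
#' pairing_rule(strand_arrangement("antiparallel_shifted"), 13)[5]     # 8
#' @export
pairing_rule <- function(arrangement, n_res) {
  i <- seq_len(n_res)
  p <- switch(arrangement$kind,
              parallel_in_register = i,
              antiparallel_in_register = n_res + 1L - i,
              antiparallel_shifted = n_res + 1L - i + arrangement$registry_shift)
  p[p < 1L | p > n_res] <- NA_integer_
  p
}

#' Geometry parameters for sheet and zipper construction
#'
#' @param n_strands_per_sheet Strands per sheet (default 8).
#' @param n_sheets Number of sheets (default 2).
#' @param intra_sheet_spacing Strand-to-strand spacing along the fibril
#'   axis, Angstrom (default 4.8, the cross-beta hydrogen-bond repeat).
#' @param inter_sheet_separation Distance between the mean planes of the
#'   two sheets, Angstrom (default 12).
#' @param dihedrals Backbone `c(phi, psi)` for the ideal strand.
#' @return An object of class `build_params`.
#' @export
build_params <- function(n_strands_per_sheet = 8, n_sheets = 2,
                         intra_sheet_spacing = 4.8,
                         inter_sheet_separation = 12,
                         dihedrals = c(phi = -139, psi = 135)) {
  stopifnot(n_strands_per_sheet >= 2, n_sheets %in% c(1, 2),
            intra_sheet_spacing > 0, inter_sheet_separation > 0)
  structure(list(n_strands_per_sheet = as.integer(n_strands_per_sheet),
                 n_sheets = as.integer(n_sheets),
                 intra_sheet_spacing = intra_sheet_spacing,
                 inter_sheet_separation = inter_sheet_separation,
                 dihedrals = dihedrals),
            class = "build_params")
}

#' Stack an ideal strand into a beta-sheet
#'
#' Stacks `n_strands_per_sheet` copies of the strand at
#' `intra_sheet_spacing` along the fibril axis y.  For antiparallel
#' arrangements alternate strands are reversed by a 180-degree rotation
#' (about the sheet normal z for the in-register pairing, which preserves
#' side-chain faces, and about the hydrogen-bond axis y for the shifted
#' pairing, which swaps them) and translated along x so the arrangement's
#' [pairing_rule()] holds exactly.  Chains are lettered A, B, C, ... in
#' stacking order.
#'
#' @param strand Single-chain [fibril_model()] from [build_ideal_strand()].
#' @param arrangement A [strand_arrangement()].
#' @param params A [build_params()].
#' @return A single-sheet [fibril_model()] with arrangement provenance.
#' @export
build_sheet <- function(strand, arrangement = strand_arrangement(),
                        params = build_params()) {
  stopifnot(inherits(strand, "fibril_model"))
  if (length(unique(strand$chain)) != 1L)
    stop("build_sheet expects a single-strand input")
  n_res <- length(unique(strand$resno))
  s <- arrangement$registry_shift
  if (arrangement$kind == "antiparallel_shifted") {
    overlap <- n_res - abs(s)
    if (overlap < 4L)
      stop("registry shift leaves fewer than 4 residues of strand overlap")
  }
  ca <- model_atoms(strand, elety = "CA")
  rise <- (ca$x[n_res] - ca$x[1]) / (n_res - 1)
  x1 <- ca$x[1]
  flipped <- switch(arrangement$kind,
                    parallel_in_register = NULL,
                    antiparallel_in_register =
                      transform_model(strand, ROT180$z,
                                      c(2 * x1 + (n_res - 1) * rise, 0, 0)),
                    antiparallel_shifted =
                      transform_model(strand, ROT180$y,
                                      c(2 * x1 + (n_res + s - 1) * rise, 0, 0)))
  chains <- vector("list", params$n_strands_per_sheet)
  for (k in seq_len(params$n_strands_per_sheet)) {
    src <- if (k %% 2L == 1L || is.null(flipped)) strand else flipped
    ch <- transform_model(src, diag(3), c(0, (k - 1) * params$intra_sheet_spacing, 0))
    ch$chain <- LETTERS[k]
    chains[[k]] <- ch
  }
  atoms <- do.call(rbind, lapply(chains, as.data.frame))
  m <- fibril_model(atoms, arrangement = arrangement, params = params)
  attr(m, "rise") <- rise
  m
}

# ---- zipper-class taxonomy -------------------------------------------------
#
# The eight steric-zipper classes are the distinct combinations of three
# binary symmetry choices: strand orientation within a sheet, which faces of
# the two sheets meet at the dry interface, and the relative polarity of the
# sheets.  The id assignment below records this package's mapping onto the
# published 1-8 numbering; ids 7 and 8 (the two classes whose strand
# symmetry admits the shifted antiparallel registry) are anchored by their
# published inter-sheet distance patterns: the face-to-back packing
# (generated by pure translation along the sheet normal) reproduces the
# class 7 pattern and the face-to-face packing (180-degree rotation about
# the strand axis) the class 8 pattern.  The `op` column is the rigid
# motion generating sheet 2 from sheet 1.
ZIPPER_CLASSES <- data.frame(
  class_id = 1:8,
  strand_orientation = rep(c("parallel", "antiparallel"), each = 4),
  sheet_face_packing = c("face_to_face", "face_to_back", "face_to_face",
                         "face_to_back", "face_to_face", "face_to_back",
                         "face_to_back", "face_to_face"),
  sheet_polarity = c("up_up", "up_up", "up_down", "up_down",
                     "up_up", "up_up", "up_down", "up_down"),
  op = c("rot_y", "translate", "rot_x", "rot_z",
         "rot_y", "rot_z", "translate", "rot_x"),
  shifted_compatible = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
  stringsAsFactors = FALSE
)

#' Enumerate the eight steric-zipper classes
#'
#' Returns descriptors for the limiting set of eight arrangements of
#' beta-strands and beta-sheets in a cross-beta steric zipper: the cross
#' product of strand orientation (parallel/antiparallel), sheet face
#' packing (face-to-face/face-to-back) and sheet polarity (up-up/up-down),
#' numbered 1-8 per the published taxonomy.
#'
#' @return List of 8 objects of class `zipper_class`, each with fields
#'   `class_id`, `strand_orientation`, `sheet_face_packing`,
#'   `sheet_polarity`, `op` (the generating rigid motion) and
#'   `shifted_compatible`.
#' @examples
#' length(enumerate_zipper_classes()) # 8
#' @export
enumerate_zipper_classes <- function() {
  lapply(seq_len(nrow(ZIPPER_CLASSES)), function(i) {
    d <- as.list(ZIPPER_CLASSES[i, ])
    structure(d, class = "zipper_class")
  })
}

#' @export
print.zipper_class <- function(x, ...) {
  cat(sprintf("<zipper_class %d> %s strands, %s sheets, polarity %s\n",
              x$class_id, x$strand_orientation, x$sheet_face_packing,
              x$sheet_polarity))
  invisible(x)
}

#' Zipper classes compatible with a strand arrangement
#'
#' Filters class descriptors to those whose strand-level symmetry admits
#' the given sheet arrangement.  The shifted antiparallel registry is
#' compatible with exactly two of the eight classes -- 7 and 8, which share
#' that strand symmetry and differ only in which sheet faces meet at the
#' interface.  In-register antiparallel sheets match classes 5 and 6, and
#' parallel sheets the four parallel classes 1-4.
#'
#' @param classes List of `zipper_class` descriptors
#'   (default [enumerate_zipper_classes()]).
#' @param arrangement A [strand_arrangement()].
#' @return Filtered list of `zipper_class` descriptors.
#' @examples
#' ids <- vapply(shifted_compatible_classes(), `[[`, 1, "class_id")
#' ids # 7 8
#' @export
shifted_compatible_classes <- function(classes = enumerate_zipper_classes(),
                                       arrangement = strand_arrangement()) {
  keep <- switch(arrangement$kind,
                 antiparallel_shifted =
                   vapply(classes, function(d) isTRUE(d$shifted_compatible), TRUE),
                 antiparallel_in_register =
                   vapply(classes, function(d)
                     d$strand_orientation == "antiparallel" &&
                       !isTRUE(d$shifted_compatible), TRUE),
                 parallel_in_register =
                   vapply(classes, function(d)
                     d$strand_orientation == "parallel", TRUE))
  classes[keep]
}

#' Pack two beta-sheets into a steric zipper
#'
#' Duplicates the sheet, applies the class's symmetry operation (recorded
#' in the taxonomy table: pure translation for face-to-back class 7,
#' 180-degree rotation about the strand axis for face-to-face class 8, and
#' analogous motions for the remaining classes) and separates the two
#' sheets so their mean planes lie `inter_sheet_separation` apart.  A
#' steric sanity check rejects any placement bringing atoms of different
#' sheets closer than 2.2 Angstrom.
#'
#' @param sheet Single-sheet [fibril_model()] from [build_sheet()].
#' @param zclass A `zipper_class` descriptor.
#' @param params A [build_params()].
#' @return A two-sheet [fibril_model()]; chains of sheet 2 continue the
#'   letter sequence and `attr(, "sheet_of_chain")` records the partition.
#' @export
build_zipper <- function(sheet, zclass, params = build_params()) {
  stopifnot(inherits(sheet, "fibril_model"))
  if (!is.null(attr(sheet, "sheet_of_chain")))
    stop("build_zipper expects a single-sheet input")
  n_ch <- length(unique(sheet$chain))
  ymax <- (n_ch - 1) * params$intra_sheet_spacing
  ca <- model_atoms(sheet, elety = "CA", chain = unique(sheet$chain)[1])
  n_res <- nrow(ca)
  rise <- attr(sheet, "rise") %||% ((ca$x[n_res] - ca$x[1]) / (n_res - 1))
  recenter_x <- 2 * ca$x[1] + (n_res - 1) * rise

  s2 <- switch(zclass$op,
               translate = sheet,
               rot_x = transform_model(sheet, ROT180$x, c(0, ymax, 0)),
               rot_y = transform_model(sheet, ROT180$y, c(recenter_x, 0, 0)),
               rot_z = transform_model(sheet, ROT180$z, c(recenter_x, ymax, 0)))
  dz <- params$inter_sheet_separation - (mean(s2$z) - mean(sheet$z))
  s2 <- transform_model(s2, diag(3), c(0, 0, dz))
  s2$chain <- LETTERS[match(s2$chain, LETTERS) + n_ch]

  xyz1 <- as.matrix(sheet[, c("x", "y", "z")])
  xyz2 <- as.matrix(s2[, c("x", "y", "z")])
  dmin <- min_cross_distance(xyz1, xyz2)
  if (dmin$d < 2.2)
    stop(sprintf("steric clash between sheets: atoms %d and %d are %.2f A apart",
                 dmin$i, dmin$j, dmin$d))

  atoms <- rbind(as.data.frame(sheet), as.data.frame(s2))
  soc <- c(stats::setNames(rep(1L, n_ch), unique(sheet$chain)),
           stats::setNames(rep(2L, n_ch), unique(s2$chain)))
  m <- fibril_model(atoms, arrangement = attr(sheet, "arrangement"),
                    zclass = zclass, params = params, sheet_of_chain = soc)
  attr(m, "rise") <- rise
  m
}

# nearest pair between two coordinate sets (blocked to bound memory)
min_cross_distance <- function(A, B, block = 2000L) {
  best <- list(d = Inf, i = NA_integer_, j = NA_integer_)
  for (s in seq(1L, nrow(A), by = block)) {
    e <- min(s + block - 1L, nrow(A))
    d2 <- outer(rowSums(A[s:e, , drop = FALSE]^2), rowSums(B^2), "+") -
      2 * A[s:e, , drop = FALSE] %*% t(B)
    k <- arrayInd(which.min(d2), dim(d2))
    d <- sqrt(max(d2[k], 0))
    if (d < best$d) best <- list(d = d, i = s + k[1] - 1L, j = k[2])
  }
  best
}

#' Convenience constructor for a full zipper model
#'
#' Chains [build_ideal_strand()], [build_sheet()] and [build_zipper()] for
#' one class id.
#'
#' @param sequence Peptide one-letter sequence.
#' @param class_id Zipper class 1-8.
#' @param arrangement Sheet arrangement; defaults to the natural
#'   arrangement for the class (shifted antiparallel for 7/8, in-register
#'   antiparallel for 5/6, parallel for 1-4).
#' @param params A [build_params()].
#' @return A two-sheet [fibril_model()].
#' @examples
#' \donttest{
#' m7 <- build_class_zipper("DWSFYLLYYTEFT", 7)
#' average_cb_distance(m7, 9)
#' }
#' @export
build_class_zipper <- function(sequence, class_id, arrangement = NULL,
                               params = build_params()) {
  zc <- enumerate_zipper_classes()[[class_id]]
  if (is.null(arrangement)) {
    arrangement <- if (zc$shifted_compatible) strand_arrangement("antiparallel_shifted")
    else if (zc$strand_orientation == "antiparallel")
      strand_arrangement("antiparallel_in_register")
    else strand_arrangement("parallel_in_register")
  }
  st <- build_ideal_strand(sequence, params$dihedrals)
  sh <- build_sheet(st, arrangement, params)
  build_zipper(sh, zc, params)
}

#' Average inter-sheet CB-CB distance at a residue position
#'
#' For a two-sheet zipper model, measures how far apart the side chains at
#' one sequence position sit across the dry interface: for every chain
#' whose CB at that position points into the interface (the side-chain
#' pleat directed toward the opposite sheet), the nearest interface-facing
#' CB at the same position on the opposite sheet is found, and the mean of
#' those nearest-pair distances is returned.  Restricting to
#' interface-facing side chains makes the measure position-dependent: side
#' chains on the outer faces are common to every packing and do not report
#' on the interface.  Set `interface_only = FALSE` for the unrestricted
#' nearest-pair mean over all chains.
#'
#' @param model Two-sheet [fibril_model()].
#' @param residue_position 1-based sequence position; its CB must exist in
#'   every chain (i.e. not glycine).
#' @param interface_only Restrict to interface-facing CB atoms (default).
#' @return Mean nearest-pair CB-CB distance in Angstrom.
#' @export
average_cb_distance <- function(model, residue_position, interface_only = TRUE) {
  soc <- attr(model, "sheet_of_chain")
  if (is.null(soc)) stop("model has no two-sheet provenance")
  cb <- model_atoms(model, elety = "CB", resno = residue_position)
  ca <- model_atoms(model, elety = "CA", resno = residue_position)
  all_ch <- unique(model$chain)
  if (!all(all_ch %in% cb$chain))
    stop("CB missing at position ", residue_position,
         " in chain(s) ", paste(setdiff(all_ch, cb$chain), collapse = ","),
         " (glycine?)")
  # sheet-normal axis from the sheet centroids, so the facing test is
  # independent of the model's orientation in space
  X1 <- model_xyz(model, chain = names(soc)[soc == 1L])
  X2 <- model_xyz(model, chain = names(soc)[soc == 2L])
  n <- unit(colMeans(X2) - colMeans(X1))
  pick <- function(sheet_no) {
    ch <- names(soc)[soc == sheet_no]
    b <- cb[cb$chain %in% ch, ]
    a <- ca[match(b$chain, ca$chain), ]
    if (interface_only) {
      inward <- if (sheet_no == 1L) 1 else -1
      w <- (as.matrix(b[, c("x", "y", "z")]) -
              as.matrix(a[, c("x", "y", "z")])) %*% n
      b <- b[w * inward > 0, , drop = FALSE]
    }
    as.matrix(b[, c("x", "y", "z")])
  }
  P1 <- pick(1L); P2 <- pick(2L)
  if (!nrow(P1) || !nrow(P2))
    stop("no interface-facing CB at position ", residue_position,
         " on one of the sheets")
  nearest <- function(A, B)
    apply(A, 1, function(p) sqrt(min(colSums((t(B) - p)^2))))
  mean(c(nearest(P1, P2), nearest(P2, P1)))
}

#' Hydrogen-bond registry distances of a sheet
#'
#' Diagnostic for the builder's sheet geometry: for each pair of adjacent
#' strands, the nearest backbone N...O contact of every residue.  An
#' in-register ideal sheet should place these in the canonical
#' hydrogen-bond band (2.7-3.3 Angstrom) for the bonded alternation of
#' residue pairs.
#'
#' @param sheet Single-sheet [fibril_model()].
#' @return Data frame with columns `chain1`, `chain2`, `resno`, `d_NO`
#'   (nearest N-to-O distance from that residue's N to any O of the
#'   neighbouring strand).
#' @export
hbond_distances <- function(sheet) {
  chains <- unique(sheet$chain)
  rows <- list()
  for (k in seq_len(length(chains) - 1L)) {
    a <- chains[k]; b <- chains[k + 1L]
    Nxyz <- model_xyz(sheet, elety = "N", chain = a)
    Oxyz <- model_xyz(sheet, elety = "O", chain = b)
    resa <- model_atoms(sheet, elety = "N", chain = a)$resno
    d <- apply(Nxyz, 1, function(p) sqrt(min(colSums((t(Oxyz) - p)^2))))
    rows[[k]] <- data.frame(chain1 = a, chain2 = b, resno = resa, d_NO = d)
  }
  do.call(rbind, rows)
}
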