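# Parametric cross-beta geometry.
#
# Coordinate convention (right-handed, Angstrom units, residues 1-based):
#   x = strand axis, y = sheet stacking / hydrogen-bond (fibril) axis,
#   z = sheet normal / inter-sheet separation.
#
# Models are deterministic ideal geometry: fixed bond lengths and angles,
# backbone dihedrals supplied by the caller, no force field.

# 3-vector cross product
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

unit <- function(v) v / sqrt(sum(v^2))

# Natural extension reference frame: position of atom d given the chain
# a-b-c, the bond length |c-d|, the angle b-c-d and the torsion a-b-c-d.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  tor <- dihedral * pi / 180
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  c(m %*% d2) + c
}

# ideal backbone geometry (lengths in Angstrom, angles in degrees)
IDEAL_GEOM <- list(
  b_NCa = 1.458, b_CaC = 1.525, b_CN = 1.329, b_CO = 1.231, b_CaCb = 1.530,
  a_NCaC = 111.0, a_CaCN = 116.6, a_CNCa = 121.7, a_OCN = 120.5,
  a_NCaCb = 110.5, tor_Cb = -122.0
)

#' Construct a fibril model from an atom table
#'
#' `fibril_model` is the coordinate container used throughout the zipper
#' builder: a data frame of atoms (`chain`, `resno`, `resid`, `elety`,
#' `x`, `y`, `z`) plus provenance attributes recording how the model was
#' built (`arrangement`, `zclass`, `params`) and, for two-sheet models, the
#' assignment of chains to sheets (`sheet_of_chain`).
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`.
#' @param arrangement Optional [strand_arrangement()] provenance.
#' @param zclass Optional zipper-class descriptor provenance.
#' @param params Optional [build_params()] provenance.
#' @param sheet_of_chain Optional named integer vector mapping chain ids to
#'   sheet number (1 or 2).
#' @return An object of class `fibril_model`.
#' @export
fibril_model <- function(atoms, arrangement = NULL, zclass = NULL,
                         params = NULL, sheet_of_chain = NULL) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atom table needs columns: ", paste(need, collapse = ", "))
  atoms <- atoms[, need]
  structure(atoms,
            class = c("fibril_model", "data.frame"),
            arrangement = arrangement, zclass = zclass, params = params,
            sheet_of_chain = sheet_of_chain)
}

#' @export
print.fibril_model <- function(x, ...) {
  ch <- unique(x$chain)
  zc <- attr(x, "zclass")
  cat(sprintf("<fibril_model> %d atoms, %d chain(s) [%s]%s\n",
              nrow(x), length(ch), paste(ch, collapse = ""),
              if (!is.null(zc)) paste0(", zipper class ", zc$class_id) else ""))
  invisible(x)
}

#' Build an ideal extended beta-strand
#'
#' Places backbone N, CA, C, O plus CB for every non-glycine residue with
#' ideal bond lengths/angles and uniform backbone dihedrals (default
#' phi = -139 deg, psi = +135 deg, the textbook antiparallel beta-strand
#' conformation).  CB is placed tetrahedrally; side chains beyond CB are
#' not modelled.  The strand is oriented with its axis along x, carbonyls
#' along the hydrogen-bond axis y and the side-chain pleat along the sheet
#' normal z; residue 1 sits at the low-x end.
#'
#' @param sequence One-letter amino-acid string.
#' @param dihedrals Numeric `c(phi, psi)` in degrees.
#' @param chain Chain identifier for the emitted atoms.
#' @return A single-chain [fibril_model()].  The attribute `rise` records
#'   the per-residue advance along x (Angstrom).
#' @examples
#' st <- build_ideal_strand("AA")
#' @export
build_ideal_strand <- function(sequence, dihedrals = c(phi = -139, psi = 135),
                               chain = "A") {
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, AA1)
  if (length(bad))
    stop("invalid sequence: unknown residue letter(s) ", paste(unique(bad), collapse = ", "))
  phi <- dihedrals[[1]]; psi <- dihedrals[[2]]; omega <- 180
  g <- IDEAL_GEOM
  n_res <- length(aa)

  res <- vector("list", n_res)
  N1 <- c(0, 0, 0); Ca1 <- c(g$b_NCa, 0, 0)
  C1 <- place_atom(c(0, 1, 0), N1, Ca1, g$b_CaC, g$a_NCaC, psi + 180)
  res[[1]] <- list(N = N1, CA = Ca1, C = C1)
  if (n_res > 1) for (i in 2:n_res) {
    p <- res[[i - 1]]
    Ni <- place_atom(p$N, p$CA, p$C, g$b_CN, g$a_CaCN, psi)
    Cai <- place_atom(p$CA, p$C, Ni, g$b_NCa, g$a_CNCa, omega)
    Ci <- place_atom(p$C, Ni, Cai, g$b_CaC, g$a_NCaC, phi)
    res[[i]] <- list(N = Ni, CA = Cai, C = Ci)
  }
  for (i in seq_len(n_res)) {
    r <- res[[i]]
    r$O <- place_atom(r$N, r$CA, r$C, g$b_CO, g$a_OCN, psi + 180)
    if (aa[i] != "G")
      r$CB <- place_atom(r$C, r$N, r$CA, g$b_CaCb, g$a_NCaCb, g$tor_Cb)
    res[[i]] <- r
  }

  res <- orient_strand(res)

  rows <- list()
  for (i in seq_len(n_res)) {
    for (at in c("N", "CA", "C", "O", "CB")) {
      if (is.null(res[[i]][[at]])) next
      xyz <- res[[i]][[at]]
      rows[[length(rows) + 1L]] <-
        data.frame(chain = chain, resno = i, resid = bio3d::aa123(aa[i]),
                   elety = at, x = xyz[1], y = xyz[2], z = xyz[3])
    }
  }
  atoms <- do.call(rbind, rows)
  m <- fibril_model(atoms)
  ca <- atoms[atoms$elety == "CA", ]
  attr(m, "rise") <- if (n_res > 1) (ca$x[n_res] - ca$x[1]) / (n_res - 1) else NA_real_
  m
}

# Rotate/translate a residue list so the strand axis lies along +x (residue 1
# at low x), the mean carbonyl direction along y and the pleat along z.
orient_strand <- function(res) {
  ca <- t(vapply(res, function(r) r$CA, numeric(3)))
  n <- nrow(ca)
  if (n == 1L) return(res)
  dirv <- stats::prcomp(ca)$rotation[, 1]
  if (sum(dirv * (ca[n, ] - ca[1, ])) < 0) dirv <- -dirv
  ref <- if (abs(dirv[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  v3 <- unit(cross3(dirv, ref))
  v2 <- cross3(v3, dirv)
  Rm <- rbind(dirv, v2, v3)
  ctr <- colMeans(ca)
  res <- lapply(res, function(r) lapply(r, function(p) c(Rm %*% (p - ctr))))
  # roll about x so carbonyls (which alternate sign residue to residue) lie
  # in the xy plane, pointing along the hydrogen-bond axis
  co <- t(vapply(res, function(r) r$O - r$C, numeric(3)))
  co <- co * rep_len(c(1, -1), nrow(co))
  ang <- atan2(mean(co[, 3]), mean(co[, 2]))
  ca_rot <- rbind(c(1, 0, 0),
                  c(0, cos(-ang), -sin(-ang)),
                  c(0, sin(-ang), cos(-ang)))
  lapply(res, function(r) lapply(r, function(p) c(ca_rot %*% p)))
}

# Apply a rigid motion (rotation matrix + translation) to a model's coords.
transform_model <- function(model, Rm = diag(3), tr = c(0, 0, 0)) {
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(Rm)
  model$x <- xyz[, 1] + tr[1]
  model$y <- xyz[, 2] + tr[2]
  model$z <- xyz[, 3] + tr[3]
  model
}

# 180-degree rotations about the coordinate axes
ROT180 <- list(x = diag(c(1, -1, -1)),
               y = diag(c(-1, 1, -1)),
               z = diag(c(-1, -1, 1)))

model_atoms <- function(model, elety = NULL, chain = NULL, resno = NULL) {
  sel <- rep(TRUE, nrow(model))
  if (!is.null(elety)) sel <- sel & model$elety %in% elety
  if (!is.null(chain)) sel <- sel & model$chain %in% chain
  if (!is.null(resno)) sel <- sel & model$resno %in% resno
  model[sel, , drop = FALSE]
}

model_xyz <- function(model, ...) {
  a <- model_atoms(model, ...)
  as.matrix(a[, c("x", "y", "z")])
}
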