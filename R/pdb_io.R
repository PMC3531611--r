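# PDB v3.3 coordinate I/O.  Reading goes through bio3d; writing uses a
# fixed-width formatter so each chain is TER-terminated (the installed
# writer omits TER records).

format_atom_line <- function(eleno, elety, resid, chain, resno, x, y, z) {
  if (any(abs(c(x, y, z)) >= 10000) || any(c(x, y, z) <= -1000))
    stop("coordinate out of PDB fixed-width range (-999.999 .. 9999.999)")
  # PDB columns: atom names of <4 chars start in column 14; column 17 is
  # the (blank) altLoc, resName 18-20, chainID 22, resSeq 23-26, x from 31
  name <- ifelse(nchar(elety) < 4L, paste0(" ", elety), elety)
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          eleno, name, resid, chain, resno, x, y, z)
}

model_pdb_lines <- function(model, eleno_start = 1L) {
  lines <- character()
  eleno <- eleno_start
  for (ch in unique(model$chain)) {
    sub <- model[model$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      lines <- c(lines, format_atom_line(eleno, sub$elety[i], sub$resid[i],
                                         ch, sub$resno[i],
                                         sub$x[i], sub$y[i], sub$z[i]))
      eleno <- eleno + 1L
    }
    last <- sub[nrow(sub), ]
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d",
                              eleno, last$resid, ch, last$resno))
    eleno <- eleno + 1L
  }
  list(lines = lines, eleno = eleno)
}

#' Write a fibril model to a PDB file
#'
#' Emits standard ATOM records with one TER record per chain and a closing
#' END.  Coordinates are written at the PDB's 3-decimal precision;
#' coordinates outside the fixed-width field range raise an error.
#'
#' @param model A [fibril_model()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "fibril_model"))
  out <- model_pdb_lines(model)
  writeLines(c(out$lines, "END"), path)
  invisible(path)
}

#' Read a fibril model from a PDB file
#'
#' Parses ATOM records (via bio3d) into a [fibril_model()].  Build
#' provenance is not stored in PDB, so two-sheet models read back from disk
#' need their chain-to-sheet partition re-supplied (see the `sheets`
#' argument of [penetration_series()] / [define_interface_region()]).
#'
#' @param path PDB file path.
#' @return A [fibril_model()].
#' @export
read_model <- function(path) {
  check_pdb_lines(path)
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  fibril_model(data.frame(chain = a$chain, resno = a$resno, resid = a$resid,
                          elety = a$elety, x = a$x, y = a$y, z = a$z))
}

# cheap structural pre-scan so malformed files fail with a line number
check_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  atom <- grep("^(ATOM  |HETATM)", lines)
  for (i in atom) {
    ln <- lines[i]
    if (nchar(ln) < 54 ||
        is.na(suppressWarnings(as.numeric(substr(ln, 31, 38)))) ||
        is.na(suppressWarnings(as.numeric(substr(ln, 39, 46)))) ||
        is.na(suppressWarnings(as.numeric(substr(ln, 47, 54)))))
      stop("malformed PDB record at line ", i, ": ", substr(ln, 1, 40))
  }
  invisible(TRUE)
}

#' A single frame of a zipper trajectory
#'
#' @param time Frame time in nanoseconds.
#' @param peptide A [fibril_model()] holding the peptide atoms.
#' @param waters Numeric matrix (n x 3) of water oxygen coordinates
#'   (hydrogens are not tracked), or `NULL`.
#' @param ions Numeric matrix (n x 3) of counter-ion coordinates, or `NULL`.
#' @return An object of class `trajectory_frame`.
#' @export
trajectory_frame <- function(time, peptide, waters = NULL, ions = NULL) {
  stopifnot(inherits(peptide, "fibril_model"))
  fix <- function(m) {
    if (is.null(m) || !length(m)) return(matrix(numeric(), 0, 3))
    m <- as.matrix(m); stopifnot(ncol(m) == 3); m
  }
  structure(list(time = as.numeric(time), peptide = peptide,
                 waters = fix(waters), ions = fix(ions)),
            class = "trajectory_frame")
}

#' @export
print.trajectory_frame <- function(x, ...) {
  cat(sprintf("<trajectory_frame> t = %g ns: %d peptide atoms, %d waters, %d ions\n",
              x$time, nrow(x$peptide), nrow(x$waters), nrow(x$ions)))
  invisible(x)
}

#' Write a trajectory as a multi-MODEL PDB
#'
#' Each frame becomes a MODEL/ENDMDL block holding the peptide chains
#' (TER-delimited), water oxygens as HOH `O` HETATM-style ATOM records on
#' chain W and ions as NA records on chain I.
#'
#' @param frames List of [trajectory_frame()] objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(frames, path) {
  stopifnot(length(frames) >= 1L,
            all(vapply(frames, inherits, TRUE, "trajectory_frame")))
  out <- character()
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    out <- c(out, sprintf("MODEL     %4d", f))
    pl <- model_pdb_lines(fr$peptide)
    out <- c(out, pl$lines)
    eleno <- pl$eleno
    if (nrow(fr$waters)) for (i in seq_len(nrow(fr$waters))) {
      out <- c(out, format_atom_line(eleno, "O", "HOH", "W", i,
                                     fr$waters[i, 1], fr$waters[i, 2], fr$waters[i, 3]))
      eleno <- eleno + 1L
    }
    if (nrow(fr$ions)) for (i in seq_len(nrow(fr$ions))) {
      out <- c(out, format_atom_line(eleno, "NA", "NA ", "I", i,
                                     fr$ions[i, 1], fr$ions[i, 2], fr$ions[i, 3]))
      eleno <- eleno + 1L
    }
    out <- c(out, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Read a multi-MODEL PDB trajectory
#'
#' Waters are recognised as HOH/WAT/TIP3 residues (their oxygen atoms) and
#' ions as NA/NA+/SOD residues; everything else is peptide.  Frame times
#' default to the frame index in nanoseconds unless supplied.
#'
#' @param path Multi-MODEL PDB path.
#' @param times Optional numeric vector of frame times (ns).
#' @return List of [trajectory_frame()] objects.
#' @export
read_trajectory <- function(path, times = NULL) {
  check_pdb_lines(path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  blocks <- if (length(starts)) {
    if (length(starts) != length(ends))
      stop("unbalanced MODEL/ENDMDL records")
    Map(function(s, e) lines[(s + 1L):(e - 1L)], starts, ends)
  } else list(lines)   # single-model file
  n_frames <- length(blocks)
  if (is.null(times)) times <- seq_len(n_frames)
  stopifnot(length(times) == n_frames)
  # frames may hold different water counts, so each block is parsed on its
  # own rather than through a fixed-width multi-model container
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  lapply(seq_len(n_frames), function(f) {
    writeLines(c(blocks[[f]], "END"), tmp)
    pdb <- bio3d::read.pdb(tmp)
    a <- pdb$atom
    wat <- a$resid %in% c("HOH", "WAT", "TIP3") & a$elety %in% c("O", "OW", "OH2")
    ion <- a$resid %in% c("NA", "NA+", "SOD")
    pep <- !(a$resid %in% c("HOH", "WAT", "TIP3")) & !ion
    pepm <- fibril_model(data.frame(chain = a$chain[pep], resno = a$resno[pep],
                                    resid = a$resid[pep], elety = a$elety[pep],
                                    x = a$x[pep], y = a$y[pep], z = a$z[pep]))
    trajectory_frame(times[f], pepm,
                     waters = cbind(a$x[wat], a$y[wat], a$z[wat]),
                     ions = cbind(a$x[ion], a$y[ion], a$z[ion]))
  })
}
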