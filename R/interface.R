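# Dry-interface geometry and water-penetration counting.
#
# The interface region of a two-sheet zipper is a slab-bounded prism: along
# the sheet normal it spans the gap between the two sheets' mean planes,
# inset by a margin on each side; in the plane it is the convex hull of the
# interface-facing CB projections, dilated by 2 Angstrom.  All geometry is
# computed in the model's own frame (normal = the axis joining the sheet
# centroids), so counts are invariant under rigid motion of the system.

#' Define the dry inter-sheet interface region of a zipper model
#'
#' @param model Two-sheet [fibril_model()] (build provenance supplies the
#'   chain-to-sheet partition; otherwise pass `sheets`).
#' @param inset Margin in Angstrom by which the slab is inset from each
#'   sheet's mean plane (default 1.0).
#' @param sheets Optional chain partition when the model carries none:
#'   either a named integer vector (chain -> 1/2), a list of two chain
#'   vectors, or a compact string like `"A-H,I-P"`.
#' @param dilate Footprint dilation around the CB hull in Angstrom
#'   (default 2).
#' @return An object of class `interface_region`: fields `origin`,
#'   `normal`, `basis` (3 x 2 in-plane basis), `lo`/`hi` (slab bounds along
#'   the normal, relative to `origin`), `hull` (footprint polygon vertices
#'   in basis coordinates), `dilate`, `separation` (mean-plane distance).
#' @export
define_interface_region <- function(model, inset = 1.0, sheets = NULL,
                                    dilate = 2.0) {
  soc <- attr(model, "sheet_of_chain") %||% parse_sheet_spec(sheets, unique(model$chain))
  if (is.null(soc)) stop("model has no sheet partition; supply `sheets`")
  ch1 <- names(soc)[soc == 1L]; ch2 <- names(soc)[soc == 2L]
  if (!length(ch1) || !length(ch2)) stop("sheets are not separable")
  X1 <- model_xyz(model, chain = ch1); X2 <- model_xyz(model, chain = ch2)
  c1 <- colMeans(X1); c2 <- colMeans(X2)
  n <- c2 - c1
  sep <- sqrt(sum(n^2))
  if (sep < 1e-6) stop("sheets are not separable (coincident centroids)")
  n <- n / sep
  origin <- (c1 + c2) / 2
  m1 <- mean((X1 - matrix(origin, nrow(X1), 3, byrow = TRUE)) %*% n)
  m2 <- mean((X2 - matrix(origin, nrow(X2), 3, byrow = TRUE)) %*% n)
  lo <- min(m1, m2) + inset
  hi <- max(m1, m2) - inset
  if (hi - lo <= 0)
    stop(sprintf("degenerate slab: inset %.2f A leaves no interior (mean-plane gap %.2f A)",
                 inset, abs(m2 - m1)))
  # in-plane basis
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit(cross3(n, ref)); v <- cross3(n, u)
  B <- cbind(u, v)
  # footprint: interface-facing CBs of both sheets, projected in-plane
  uv <- interface_cb_uv(model, soc, origin, n, B)
  if (nrow(uv) < 3L) stop("too few interface-facing CB atoms for a footprint")
  hull <- uv[grDevices::chull(uv), , drop = FALSE]
  structure(list(origin = origin, normal = n, basis = B, lo = lo, hi = hi,
                 hull = hull, dilate = dilate,
                 separation = abs(m2 - m1)),
            class = "interface_region")
}

interface_cb_uv <- function(model, soc, origin, n, B) {
  cb <- model_atoms(model, elety = "CB")
  ca <- model_atoms(model, elety = "CA")
  key <- paste(cb$chain, cb$resno); keyca <- paste(ca$chain, ca$resno)
  ca <- ca[match(key, keyca), , drop = FALSE]
  sheet <- soc[cb$chain]
  zcb <- (as.matrix(cb[, c("x", "y", "z")]) -
            matrix(origin, nrow(cb), 3, byrow = TRUE)) %*% n
  zca <- (as.matrix(ca[, c("x", "y", "z")]) -
            matrix(origin, nrow(ca), 3, byrow = TRUE)) %*% n
  inward <- ifelse(sheet == 1L, 1, -1) * sign(mean(zcb[sheet == 2L]) - mean(zcb[sheet == 1L]))
  facing <- (zcb - zca) * inward > 0
  P <- as.matrix(cb[facing, c("x", "y", "z"), drop = FALSE])
  (P - matrix(origin, nrow(P), 3, byrow = TRUE)) %*% B
}

#' @export
print.interface_region <- function(x, ...) {
  cat(sprintf("<interface_region> slab thickness %.2f A (mean-plane gap %.2f A), footprint %d-gon +%.1f A\n",
              x$hi - x$lo, x$separation, nrow(x$hull), x$dilate))
  invisible(x)
}

# strictly-inside test for the dilated prism
points_in_region <- function(P, region) {
  if (!nrow(P)) return(logical(0))
  rel <- P - matrix(region$origin, nrow(P), 3, byrow = TRUE)
  w <- rel %*% region$normal
  in_slab <- w > region$lo & w < region$hi
  uv <- rel %*% region$basis
  in_slab & in_dilated_hull(uv, region$hull, region$dilate)
}

# point strictly within `r` of a convex polygon (inside counts as distance 0)
in_dilated_hull <- function(uv, hull, r) {
  inside <- point_in_poly(uv, hull)
  d <- dist_to_poly(uv, hull)
  inside | d < r
}

point_in_poly <- function(uv, poly) {
  n <- nrow(poly)
  res <- rep(FALSE, nrow(uv))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- (uv[, 2] < yi) != (uv[, 2] < yj)
    xint <- xi + (uv[cross, 2] - yi) / (yj - yi) * (xj - xi)
    res[cross] <- xor(res[cross], uv[cross, 1] < xint)
    j <- i
  }
  res
}

dist_to_poly <- function(uv, poly) {
  n <- nrow(poly)
  d2 <- rep(Inf, nrow(uv))
  j <- n
  for (i in seq_len(n)) {
    a <- poly[j, ]; b <- poly[i, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 > 0) pmin(1, pmax(0, ((uv[, 1] - a[1]) * ab[1] +
                                          (uv[, 2] - a[2]) * ab[2]) / len2)) else 0
    dx <- uv[, 1] - (a[1] + t * ab[1]); dy <- uv[, 2] - (a[2] + t * ab[2])
    d2 <- pmin(d2, dx^2 + dy^2)
    j <- i
  }
  sqrt(d2)
}

parse_sheet_spec <- function(sheets, chains) {
  if (is.null(sheets)) return(NULL)
  if (is.numeric(sheets) && !is.null(names(sheets)))
    return(vapply(sheets, as.integer, 1L))
  if (is.character(sheets) && length(sheets) == 1L) {
    parts <- strsplit(sheets, ",", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("sheet spec must have two comma-separated ranges")
    expand <- function(rng) {
      ab <- strsplit(rng, "-", fixed = TRUE)[[1]]
      if (length(ab) == 1L) return(ab)
      LETTERS[match(ab[1], LETTERS):match(ab[2], LETTERS)]
    }
    sheets <- list(expand(parts[1]), expand(parts[2]))
  }
  if (is.list(sheets) && length(sheets) == 2L) {
    soc <- c(stats::setNames(rep(1L, length(sheets[[1]])), sheets[[1]]),
             stats::setNames(rep(2L, length(sheets[[2]])), sheets[[2]]))
    missing <- setdiff(chains, names(soc))
    if (length(missing)) stop("chains not covered by sheet spec: ",
                              paste(missing, collapse = ","))
    return(soc)
  }
  stop("cannot interpret sheet specification")
}

#' Count waters inside the dry interface of one frame
#'
#' Number of water oxygens strictly inside the slab-and-footprint prism.
#' Boundary points (exactly on a bounding plane or on the dilated footprint
#' edge) are excluded.
#'
#' @param frame A [trajectory_frame()].
#' @param region An [define_interface_region()] result computed on this
#'   frame's peptide coordinates.
#' @return Integer count (0 for an empty water list).
#' @export
count_interface_waters <- function(frame, region) {
  stopifnot(inherits(frame, "trajectory_frame"),
            inherits(region, "interface_region"))
  sum(points_in_region(frame$waters, region))
}

#' Water penetration over a trajectory and the stability verdict
#'
#' For each frame the interface region is recomputed from the current
#' peptide coordinates (so sheet drift naturally enlarges or degrades the
#' slab) and the interior waters are counted.  The zipper is `stable` only
#' if every frame stays below `threshold` waters (default 5: a dry zipper
#' admits fewer than five waters over a trajectory); otherwise
#' `dissolved`.  As a structural-collapse shortcut, a frame whose
#' mean-plane gap exceeds twice the first frame's gap marks the trajectory
#' dissolved regardless of count.  Ions are counted separately and
#' reported but do not enter the verdict.
#'
#' @param frames List of [trajectory_frame()] objects (>= 1).
#' @param inset Slab inset in Angstrom (default 1.0).
#' @param threshold Water-count threshold (default 5).
#' @param sheets Chain partition passed to [define_interface_region()]
#'   when the frames' peptide models carry no provenance.
#' @return An object of class `penetration_series`: data frame of `time`,
#'   `n_waters`, `n_ions`, `separation` plus attributes `threshold`,
#'   `verdict` (`"stable"`/`"dissolved"`) and `collapsed` (logical).
#' @export
penetration_series <- function(frames, inset = 1.0, threshold = 5,
                               sheets = NULL) {
  stopifnot(length(frames) >= 1L)
  rows <- vector("list", length(frames))
  sep0 <- NULL
  collapsed <- FALSE
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    if (!inherits(fr, "trajectory_frame") || !nrow(fr$peptide))
      stop("frame ", f, " has missing peptide atoms")
    region <- define_interface_region(fr$peptide, inset = inset, sheets = sheets)
    if (is.null(sep0)) sep0 <- region$separation
    if (region$separation > 2 * sep0) collapsed <- TRUE
    rows[[f]] <- data.frame(
      time = fr$time,
      n_waters = count_interface_waters(fr, region),
      n_ions = sum(points_in_region(fr$ions, region)),
      separation = region$separation)
  }
  df <- do.call(rbind, rows)
  verdict <- if (!collapsed && all(df$n_waters < threshold)) "stable" else "dissolved"
  structure(df, class = c("penetration_series", "data.frame"),
            threshold = threshold, verdict = verdict, collapsed = collapsed)
}

#' @export
print.penetration_series <- function(x, ...) {
  cat(sprintf("<penetration_series> %d frames, max %d waters (threshold %d): %s%s\n",
              nrow(x), max(x$n_waters), attr(x, "threshold"), attr(x, "verdict"),
              if (attr(x, "collapsed")) " [structural collapse]" else ""))
  invisible(x)
}
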