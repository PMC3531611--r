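#' Phosphosite separation score of a variant in an arrangement or model
#'
#' The quantity the architecture screen compares: how close the phosphate
#' groups of a variant would sit in a candidate fibril organisation.
#'
#' For a schematic [strand_arrangement()] the score is the registry offset
#' (in residues) between a phosphosite on one strand and the same site on
#' its nearest neighbouring strand, `|2p - (N+1) - s|` for antiparallel
#' pairings and 0 for parallel in-register (every site stacks on itself).
#'
#' For a built two-sheet [fibril_model()] the score is in Angstrom:
#' single-site variants use [average_cb_distance()] at the phosphosite
#' (inter-sheet, interface-facing); multi-site variants take the minimum
#' over all site pairs, where unequal positions are scored by the nearest
#' CB-CB contact between distinct chains anywhere in the assembly (a
#' cross-site contact between neighbouring strands of one sheet is a real
#' phosphate-phosphate clash that same-position scores cannot see).
#'
#' @param x A [strand_arrangement()] or a two-sheet [fibril_model()].
#' @param variant A [peptide_variant()] with at least one phosphosite.
#' @param n_res Strand length (schematic case; default from the variant).
#' @return Numeric separation score (residue offset or Angstrom).
#' @export
phosphosite_separation <- function(x, variant, n_res = nchar(variant$sequence)) {
  stopifnot(inherits(variant, "peptide_variant"))
  sites <- variant$phosphosites
  if (!length(sites)) stop("variant ", variant$name, " has no phosphosite")
  if (inherits(x, "strand_arrangement")) {
    partner <- function(i) switch(x$kind,
                                  parallel_in_register = i,
                                  antiparallel_in_register = n_res + 1L - i,
                                  antiparallel_shifted = n_res + 1L - i + x$registry_shift)
    offs <- outer(sites, sites, function(p, q) abs(p - partner(q)))
    as.numeric(min(offs))
  } else if (inherits(x, "fibril_model")) {
    if (length(sites) == 1L) return(average_cb_distance(x, sites))
    score <- Inf
    for (i in seq_along(sites)) for (j in i:length(sites)) {
      p <- sites[i]; q <- sites[j]
      d <- if (p == q) average_cb_distance(x, p) else min_cross_site(x, p, q)
      score <- min(score, d)
    }
    score
  } else stop("x must be a strand_arrangement or a fibril_model")
}

# nearest CB-CB contact between residue positions p and q on distinct chains
min_cross_site <- function(model, p, q) {
  A <- model_atoms(model, elety = "CB", resno = p)
  B <- model_atoms(model, elety = "CB", resno = q)
  if (!nrow(A) || !nrow(B)) stop("CB missing at position ", p, " or ", q)
  best <- Inf
  for (i in seq_len(nrow(A))) {
    keep <- B$chain != A$chain[i]
    if (!any(keep)) next
    d2 <- (B$x[keep] - A$x[i])^2 + (B$y[keep] - A$y[i])^2 + (B$z[keep] - A$z[i])^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

#' @keywords internal
consistency_report <- function(candidate, verdict, reason, separations) {
  if (verdict == "eliminated" && !nzchar(reason))
    stop("eliminated candidates need a reason")
  structure(list(candidate = candidate, verdict = verdict, reason = reason,
                 separations = separations),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("<consistency_report> %s: %s%s\n", x$candidate, x$verdict,
              if (nzchar(x$reason)) paste0(" -- ", x$reason) else ""))
  if (length(x$separations))
    cat("  separations: ",
        paste(sprintf("%s=%.3g", names(x$separations), x$separations),
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

# variants with outcomes at the query pH, split by outcome; control (no
# phosphosite) carries no proximity constraint and is dropped
screen_inputs <- function(outcomes, pH, variants) {
  sel <- outcomes[abs(outcomes$pH - pH) < 1e-9, , drop = FALSE]
  sel <- sel[!duplicated(sel$variant), , drop = FALSE]
  sel <- sel[sel$variant %in% names(variants), , drop = FALSE]
  has_site <- vapply(sel$variant,
                     function(v) length(variants[[v]]$phosphosites) > 0L, TRUE)
  sel <- sel[has_site, , drop = FALSE]
  if (!nrow(sel)) stop("no phosphovariant outcomes at pH ", pH)
  list(agg = sel$variant[sel$outcome == "fibrils"],
       non = sel$variant[sel$outcome == "no_fibrils"])
}

# Shared elimination rule: a candidate survives only if every aggregating
# variant's phosphosites are farther apart than every non-aggregating
# variant's, by at least `margin`.  The schematic arrangement screen uses
# strict inequality (equal spacing cannot explain different outcomes); the
# model screen's margin subsumes strictness, so margin = 0 is vacuous there.
screen_candidate <- function(label, seps, agg, non, margin = 0, strict = FALSE) {
  if (!length(agg) || !length(non))
    return(consistency_report(label, "consistent",
                              "indeterminate: outcomes impose no constraint", seps))
  worst_non <- max(seps[non]); best_agg <- min(seps[agg])
  if (best_agg - worst_non >= margin && (!strict || best_agg > worst_non))
    consistency_report(label, "consistent", "", seps)
  else
    consistency_report(label, "eliminated",
                       sprintf(paste0("non-aggregating %s separation (%.3g) is not ",
                                      "exceeded by aggregating %s (%.3g) by the ",
                                      "required margin %.3g"),
                               names(which.max(seps[non])), worst_non,
                               names(which.min(seps[agg])), best_agg, margin),
                       seps)
}

#' Screen strand arrangements against aggregation outcomes
#'
#' Tests the three strand-strand arrangements against the variant-by-pH
#' outcome matrix under the electrostatic-repulsion reading: if charge
#' proximity blocks assembly, every variant that fails to aggregate must
#' place its phosphates closer together than every variant that does.  An
#' arrangement in which a non-aggregating variant's separation is greater
#' than or equal to an aggregating variant's is eliminated.  With the
#' observed pH 3.6 outcomes (p5Y/p8Y blocked, p9Y and the rest
#' aggregating) only the antiparallel shifted organisation survives.
#'
#' @param outcomes An `outcome_matrix` (see [strand_e_outcomes()]).
#' @param pH Query pH (default 3.6, where outcomes differ most).
#' @param variants Named list of [peptide_variant()]s
#'   (default [strand_e_variants()]).
#' @param registry_shift Shift for the shifted arrangement (default -1).
#' @return List of `consistency_report`, one per arrangement, with an
#'   `indeterminate` attribute when the outcomes impose no constraint.
#' @export
screen_strand_arrangements <- function(outcomes, pH = 3.6,
                                       variants = strand_e_variants(),
                                       registry_shift = -1) {
  inp <- screen_inputs(outcomes, pH, variants)
  arrs <- list(
    parallel_in_register = strand_arrangement("parallel_in_register"),
    antiparallel_in_register = strand_arrangement("antiparallel_in_register"),
    antiparallel_shifted = strand_arrangement("antiparallel_shifted",
                                              registry_shift))
  used <- c(inp$agg, inp$non)
  reports <- lapply(names(arrs), function(nm) {
    seps <- vapply(used, function(v)
      phosphosite_separation(arrs[[nm]], variants[[v]]), 1)
    names(seps) <- used
    screen_candidate(nm, seps, inp$agg, inp$non, margin = 0, strict = TRUE)
  })
  names(reports) <- names(arrs)
  attr(reports, "indeterminate") <- !length(inp$agg) || !length(inp$non)
  reports
}

#' Screen zipper classes against aggregation outcomes
#'
#' Applies the same repulsion-monotonicity rule to built zipper models,
#' with separations measured in Angstrom by [phosphosite_separation()].  A
#' class is consistent only when every aggregating variant's separation
#' exceeds every non-aggregating variant's by at least `margin` (default
#' 3 Angstrom, about the distance gap the class 7 geometry opens between
#' the isolated position 9 and the paired positions 5/8).
#'
#' @param outcomes An `outcome_matrix`.
#' @param models Named list of two-sheet [fibril_model()]s; names are class
#'   ids (e.g. `"7"`, `"8"`).
#' @param pH Query pH (default 3.6).
#' @param margin Required separation gap in Angstrom (default 3).
#' @param variants Named list of [peptide_variant()]s.
#' @return List of `consistency_report`, one per class.
#' @export
screen_zipper_classes <- function(outcomes, models, pH = 3.6, margin = 3,
                                  variants = strand_e_variants()) {
  stopifnot(length(models) >= 1L, !is.null(names(models)))
  inp <- screen_inputs(outcomes, pH, variants)
  used <- c(inp$agg, inp$non)
  reports <- lapply(names(models), function(id) {
    m <- models[[id]]
    if (!inherits(m, "fibril_model")) stop("missing model for class ", id)
    seps <- vapply(used, function(v) phosphosite_separation(m, variants[[v]]), 1)
    names(seps) <- used
    screen_candidate(paste0("class ", id), seps, inp$agg, inp$non, margin)
  })
  names(reports) <- names(models)
  attr(reports, "indeterminate") <- !length(inp$agg) || !length(inp$non)
  reports
}

#' End-to-end architecture inference
#'
#' Composes the two screens into the full elimination chain: the three
#' strand arrangements are screened against the outcomes; if a unique
#' arrangement survives, the zipper classes compatible with it are built
#' as idealized models and screened in turn; the winning class id (if
#' unique) is returned with the full audit trail.  On the transcribed
#' strand E outcomes at pH 3.6 the chain is 3 arrangements -> 1
#' (antiparallel shifted) -> 2 candidate classes (7, 8) -> class 7.
#'
#' The screen assumes all variants assemble into a common fibril
#' morphology; the report carries this assumption in its header field.
#'
#' @param outcomes An `outcome_matrix`.
#' @param params A [build_params()] for the candidate models.
#' @param pH Query pH (default 3.6).
#' @param margin Class-screen margin in Angstrom (default 3).
#' @param variants Named list of [peptide_variant()]s.
#' @param sequence Sequence to build models from (default the control's).
#' @return An object of class `architecture_inference`: list with
#'   `assumption`, `arrangement_reports`, `winning_arrangement` (or `NA`),
#'   `class_reports` (or `NULL`), `winner` (class id integer, or
#'   `NA_integer_` when no unique consistent class exists).
#' @export
infer_architecture <- function(outcomes, params = build_params(), pH = 3.6,
                               margin = 3, variants = strand_e_variants(),
                               sequence = NULL) {
  sequence <- sequence %||% variants[[1]]$sequence
  arr_reports <- screen_strand_arrangements(outcomes, pH, variants)
  consistent <- names(arr_reports)[vapply(arr_reports, function(r)
    r$verdict == "consistent", TRUE)]
  out <- list(assumption = paste("assumes all variants share a common fibril",
                                 "morphology; consistency, not proof"),
              arrangement_reports = arr_reports,
              winning_arrangement = NA_character_,
              class_reports = NULL, winner = NA_integer_)
  class(out) <- "architecture_inference"
  if (length(consistent) != 1L || attr(arr_reports, "indeterminate"))
    return(out)
  out$winning_arrangement <- consistent
  arrangement <- strand_arrangement(consistent)
  cand <- shifted_compatible_classes(enumerate_zipper_classes(), arrangement)
  strand <- build_ideal_strand(sequence, params$dihedrals)
  sheet <- build_sheet(strand, arrangement, params)
  models <- lapply(cand, function(zc) build_zipper(sheet, zc, params))
  names(models) <- vapply(cand, function(zc) as.character(zc$class_id), "")
  cls_reports <- screen_zipper_classes(outcomes, models, pH, margin, variants)
  out$class_reports <- cls_reports
  ok <- names(cls_reports)[vapply(cls_reports, function(r)
    r$verdict == "consistent", TRUE)]
  if (length(ok) == 1L) out$winner <- as.integer(ok)
  out
}

#' @export
print.architecture_inference <- function(x, ...) {
  cat("<architecture_inference>\n")
  cat("  note:", x$assumption, "\n")
  cat("  arrangements:", paste(sprintf("%s[%s]", names(x$arrangement_reports),
                                       vapply(x$arrangement_reports, `[[`, "", "verdict")),
                               collapse = ", "), "\n")
  if (!is.null(x$class_reports))
    cat("  classes:", paste(sprintf("%s[%s]", names(x$class_reports),
                                    vapply(x$class_reports, `[[`, "", "verdict")),
                            collapse = ", "), "\n")
  cat("  winner:", if (is.na(x$winner)) "none (indeterminate)" else
    paste("class", x$winner), "\n")
  invisible(x)
}
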