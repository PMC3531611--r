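#' Site pKa model for peptide charge calculations
#'
#' Collects the acid-dissociation constants used to assign residue and
#' phosphate charges as a function of pH.  The side-chain carboxylates of
#' Asp and Glu are taken as pKa 4.0.  A phosphomonoester on Ser/Thr/Tyr
#' titrates twice: the first deprotonation (neutral to mono-anionic) at
#' `pKa_phos1` and the second (mono- to di-anionic) at `pKa_phos2`.  The
#' defaults 2.1 and 6.7 place the three dominant phosphate species at the
#' three working pH values of the assay: fully protonated (0) at pH 1.1,
#' mono-anionic (-1) at pH 3.6 and di-anionic (-2) at pH 7.5.
#'
#' Basic and thiol side chains (His, Lys, Arg, Cys) are carried in an
#' extensible table so sequences containing them still receive standard
#' charges; they are absent from strand E.  Capped termini contribute no
#' charge, and terminal pKa values are ignored for capped peptides.
#'
#' @param pKa_asp,pKa_glu Carboxylate pKa values (default 4.0).
#' @param pKa_phos1,pKa_phos2 First and second phosphate pKa (2.1, 6.7).
#' @param extra Named numeric vector of additional side-chain pKa values,
#'   `c(K = 10.5, R = 12.5, H = 6.0, C = 8.3)` by default.
#' @return An object of class `charge_model`.
#' @examples
#' phosphate_charge_state(3.6)$phosphate_charge # -1
#' @export
charge_model <- function(pKa_asp = 4.0, pKa_glu = 4.0,
                         pKa_phos1 = 2.1, pKa_phos2 = 6.7,
                         extra = c(K = 10.5, R = 12.5, H = 6.0, C = 8.3)) {
  stopifnot(is.finite(pKa_asp), is.finite(pKa_glu),
            is.finite(pKa_phos1), is.finite(pKa_phos2))
  if (!(pKa_phos1 < pKa_phos2))
    stop("phosphate pKa1 must be below pKa2")
  structure(list(pKa_asp = pKa_asp, pKa_glu = pKa_glu,
                 pKa_phos1 = pKa_phos1, pKa_phos2 = pKa_phos2,
                 extra = extra),
            class = "charge_model")
}

# dominant-species charge of a single acid group: 0 at/below pKa, -1 above.
# The tie at pH == pKa deliberately resolves to the protonated (less charged)
# species so the assignment is deterministic at the boundary.
acid_dominant <- function(pH, pKa) ifelse(pH > pKa, -1, 0)
acid_fraction <- function(pH, pKa) -1 / (1 + 10^(pKa - pH))
base_dominant <- function(pH, pKa) ifelse(pH > pKa, 0, 1)
base_fraction <- function(pH, pKa) 1 / (1 + 10^(pH - pKa))

# diprotic phosphate speciation at a given pH
phos_fractions <- function(pH, model) {
  a1 <- 10^(pH - model$pKa_phos1)
  a2 <- 10^(2 * pH - model$pKa_phos1 - model$pKa_phos2)
  z <- 1 + a1 + a2
  c(h2 = 1 / z, h1 = a1 / z, h0 = a2 / z)
}

#' Dominant phosphate protonation state at a pH
#'
#' Returns the dominant charge of a phosphomonoester group (0, -1 or -2)
#' under the Henderson-Hasselbalch model, together with the species
#' fractions.  With the default model the three assay pH values 1.1, 3.6 and
#' 7.5 map to charges 0, -1 and -2 respectively.  Ties at a pKa resolve
#' toward the more protonated state.
#'
#' @param pH Numeric pH in (0, 14).
#' @param model A [charge_model()].
#' @return An object of class `protonation_state` with elements
#'   `phosphate_charge` (integer in `{0, -1, -2}`), `fractions` (species
#'   probabilities) and `pH`.
#' @examples
#' phosphate_charge_state(1.1)$phosphate_charge # 0
#' phosphate_charge_state(7.5)$phosphate_charge # -2
#' @export
phosphate_charge_state <- function(pH, model = charge_model()) {
  stopifnot(pH > 0, pH < 14)
  ch <- if (pH <= model$pKa_phos1) 0L else if (pH <= model$pKa_phos2) -1L else -2L
  structure(list(phosphate_charge = ch, fractions = phos_fractions(pH, model),
                 pH = pH),
            class = "protonation_state")
}

#' @export
print.protonation_state <- function(x, ...) {
  cat(sprintf("<protonation_state> pH %.2f: dominant phosphate charge %d (fractions 0/-1/-2: %.3f/%.3f/%.3f)\n",
              x$pH, x$phosphate_charge, x$fractions["h2"], x$fractions["h1"], x$fractions["h0"]))
  invisible(x)
}

#' Net charge of a peptide variant at a pH
#'
#' Sums per-site charges over the ionisable groups of the peptide: Asp and
#' Glu carboxylates, any phosphate groups at the variant's phosphosites, and
#' (if present in the sequence) His/Lys/Arg/Cys via the model's extensible
#' pKa table.  Capped termini contribute nothing.  In `"dominant"` mode each
#' site contributes the integer charge of its dominant Henderson-Hasselbalch
#' species (ties at a pKa resolve toward the protonated species); in
#' `"fractional"` mode each site contributes its expected charge, so the
#' result is continuous in pH.
#'
#' For the capped strand E control this gives 0 at pH 1.1 and -2 at pH 7.5
#' (the two carboxylates); each phosphate adds its 0/-1/-2 state on top.
#'
#' @param variant A [peptide_variant()].
#' @param pH Numeric pH in (0, 14).
#' @param model A [charge_model()].
#' @param mode `"dominant"` (integer result) or `"fractional"`.
#' @return Net charge (length-1 numeric; integer-valued in dominant mode).
#' @examples
#' ctrl <- strand_e_variants()$control
#' net_charge(ctrl, 1.1) #  0
#' net_charge(ctrl, 7.5) # -2
#' @export
net_charge <- function(variant, pH, model = charge_model(),
                       mode = c("dominant", "fractional")) {
  mode <- match.arg(mode)
  stopifnot(inherits(variant, "peptide_variant"), pH > 0, pH < 14)
  aa <- strsplit(variant$sequence, "")[[1]]
  dom <- mode == "dominant"
  qacid <- if (dom) acid_dominant else acid_fraction
  qbase <- if (dom) base_dominant else base_fraction

  q <- 0
  q <- q + sum(qacid(pH, model$pKa_asp)[rep(1, sum(aa == "D"))])
  q <- q + sum(qacid(pH, model$pKa_glu)[rep(1, sum(aa == "E"))])
  for (res in intersect(names(model$extra), aa)) {
    n <- sum(aa == res)
    q <- q + n * (if (res %in% c("K", "R", "H")) qbase(pH, model$extra[[res]])
                  else qacid(pH, model$extra[[res]]))
  }
  if (length(variant$phosphosites)) {
    if (dom) {
      q <- q + length(variant$phosphosites) *
        phosphate_charge_state(pH, model)$phosphate_charge
    } else {
      fr <- phos_fractions(pH, model)
      q <- q + length(variant$phosphosites) * (-fr[["h1"]] - 2 * fr[["h0"]])
    }
  }
  if (!variant$n_term_acetylated) q <- q + qbase(pH, 9.0)
  if (!variant$c_term_amidated) q <- q + qacid(pH, 3.1)
  unname(q)
}

#' Per-site protonation table for a variant
#'
#' Expands [net_charge()] into its per-residue contributions, which is
#' useful for inspecting which groups drive the titration.
#'
#' @inheritParams net_charge
#' @return Data frame with columns `position`, `residue`, `group`, `charge`.
#' @export
site_charges <- function(variant, pH, model = charge_model(),
                         mode = c("dominant", "fractional")) {
  mode <- match.arg(mode)
  aa <- strsplit(variant$sequence, "")[[1]]
  rows <- list()
  for (i in seq_along(aa)) {
    res <- aa[i]
    qr <- if (res == "D") acid_val(pH, model$pKa_asp, mode)
    else if (res == "E") acid_val(pH, model$pKa_glu, mode)
    else if (res %in% names(model$extra)) {
      if (res %in% c("K", "R", "H")) base_val(pH, model$extra[[res]], mode)
      else acid_val(pH, model$extra[[res]], mode)
    } else 0
    if (qr != 0)
      rows[[length(rows) + 1L]] <- data.frame(position = i, residue = res,
                                              group = "side chain", charge = qr)
    if (i %in% variant$phosphosites) {
      qp <- if (mode == "dominant")
        phosphate_charge_state(pH, model)$phosphate_charge
      else { fr <- phos_fractions(pH, model); -fr[["h1"]] - 2 * fr[["h0"]] }
      rows[[length(rows) + 1L]] <- data.frame(position = i, residue = res,
                                              group = "phosphate", charge = qp)
    }
  }
  if (!length(rows))
    return(data.frame(position = integer(), residue = character(),
                      group = character(), charge = numeric()))
  do.call(rbind, rows)
}

acid_val <- function(pH, pKa, mode)
  if (mode == "dominant") acid_dominant(pH, pKa) else acid_fraction(pH, pKa)
base_val <- function(pH, pKa, mode)
  if (mode == "dominant") base_dominant(pH, pKa) else base_fraction(pH, pKa)
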