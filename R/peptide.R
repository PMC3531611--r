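#' Peptide variant with optional phosphosites
#'
#' A `peptide_variant` describes one peptide in a phospho-scanning series: a
#' one-letter sequence, the set of phosphorylated residue positions, and the
#' capping state of its termini.  The model peptide used throughout this
#' package is strand E of beta-2-microglobulin (residues 59-71,
#' `DWSFYLLYYTEFT`), synthesised with an acetylated N terminus and an
#' amidated C terminus, so both termini default to capped.
#'
#' @param name Short label, e.g. `"p9Y"` for the variant phosphorylated at
#'   Tyr9, or `"control"` for the unmodified peptide.
#' @param sequence One-letter amino-acid string (standard 20 codes).
#' @param phosphosites Integer vector of 1-based residue indices carrying a
#'   phosphate group.  Every index must point at Ser, Thr or Tyr.
#' @param n_term_acetylated,c_term_amidated Logical; capped termini carry no
#'   ionisable terminal group.
#'
#' @return An object of class `peptide_variant`.
#' @examples
#' p9Y <- peptide_variant("p9Y", "DWSFYLLYYTEFT", phosphosites = 9)
#' count_phosphorylatable_sites(p9Y)
#' @export
peptide_variant <- function(name, sequence, phosphosites = integer(),
                            n_term_acetylated = TRUE, c_term_amidated = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) >= 1L)
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, AA1)
  if (length(bad))
    stop("invalid sequence: unknown residue letter(s) ", paste(unique(bad), collapse = ", "))
  phosphosites <- sort(unique(as.integer(phosphosites)))
  if (length(phosphosites)) {
    if (any(phosphosites < 1L | phosphosites > length(aa)))
      stop("phosphosite index out of range 1..", length(aa))
    not_sty <- phosphosites[!aa[phosphosites] %in% c("S", "T", "Y")]
    if (length(not_sty))
      stop("phosphosite on non-phosphorylatable residue at position ",
           paste(not_sty, collapse = ", "), " (", paste(aa[not_sty], collapse = ","),
           "); only S, T and Y accept a phosphate")
  }
  structure(
    list(name = as.character(name), sequence = sequence,
         phosphosites = phosphosites,
         n_term_acetylated = isTRUE(n_term_acetylated),
         c_term_amidated = isTRUE(c_term_amidated)),
    class = "peptide_variant"
  )
}

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")

#' @export
print.peptide_variant <- function(x, ...) {
  ph <- if (length(x$phosphosites)) paste(x$phosphosites, collapse = ",") else "none"
  cat(sprintf("<peptide_variant> %s  %s  phosphosites: %s  caps: %s/%s\n",
              x$name, x$sequence, ph,
              if (x$n_term_acetylated) "Ac" else "H3N+",
              if (x$c_term_amidated) "NH2" else "COO-"))
  invisible(x)
}

#' Parse a compact variant definition string
#'
#' Accepts definitions of the form `"NAME=SEQUENCE"` or
#' `"NAME=SEQUENCE;phos=3,10"`.
#'
#' @param x Character vector of definitions.
#' @return A list of [peptide_variant()] objects (a single object for
#'   length-1 input).
#' @examples
#' parse_variant("p3S10T=DWSFYLLYYTEFT;phos=3,10")
#' @export
parse_variant <- function(x) {
  parse1 <- function(s) {
    s <- gsub("[[:space:]]", "", s)
    main <- strsplit(s, ";", fixed = TRUE)[[1]]
    nv <- strsplit(main[1], "=", fixed = TRUE)[[1]]
    if (length(nv) != 2L) stop("cannot parse variant definition: ", s)
    phos <- integer()
    for (opt in main[-1]) {
      kv <- strsplit(opt, "=", fixed = TRUE)[[1]]
      if (length(kv) == 2L && kv[1] == "phos")
        phos <- as.integer(strsplit(kv[2], ",", fixed = TRUE)[[1]])
      else stop("unknown option in variant definition: ", opt)
    }
    peptide_variant(nv[1], nv[2], phos)
  }
  out <- lapply(x, parse1)
  if (length(out) == 1L) out[[1]] else out
}

#' Read variant definitions from a YAML block or file
#'
#' The YAML maps variant names to either a sequence string or a mapping with
#' `sequence:` and optional `phosphosites:` entries.
#'
#' @param file Path to a YAML file, or `NULL` when `text` is given.
#' @param text YAML text.
#' @return Named list of [peptide_variant()] objects.
#' @export
read_variants_yaml <- function(file = NULL, text = NULL) {
  y <- if (is.null(text)) yaml::read_yaml(file) else yaml::read_yaml(text = text)
  out <- lapply(names(y), function(nm) {
    v <- y[[nm]]
    if (is.character(v)) peptide_variant(nm, v)
    else peptide_variant(nm, v$sequence, v$phosphosites %||% integer())
  })
  names(out) <- names(y)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The strand E phospho-scanning variant series
#'
#' The built-in eight-member series for strand E (`DWSFYLLYYTEFT`): the
#' non-phosphorylated control, six single-site variants covering every
#' phosphorylatable residue class (p3S, p5Y, p8Y, p9Y, p10T, p13T) and the
#' double variant p3S10T.  All peptides are N-acetylated and C-amidated.
#'
#' @return Named list of [peptide_variant()] objects.
#' @examples
#' names(strand_e_variants())
#' @export
strand_e_variants <- function() {
  seqE <- "DWSFYLLYYTEFT"
  defs <- list(control = integer(), p13T = 13L, p10T = 10L, p9Y = 9L,
               p8Y = 8L, p5Y = 5L, p3S = 3L, p3S10T = c(3L, 10L))
  out <- lapply(names(defs), function(nm) peptide_variant(nm, seqE, defs[[nm]]))
  names(out) <- names(defs)
  out
}

#' Count phosphorylatable residues in a peptide
#'
#' Counts the serine, threonine and tyrosine residues in the sequence --
#' the positions at which a phosphate group can be installed reversibly.
#'
#' @param variant A [peptide_variant()] or a plain sequence string.
#' @return Integer count of S, T and Y residues.
#' @examples
#' count_phosphorylatable_sites("DWSFYLLYYTEFT") # 6
#' @export
count_phosphorylatable_sites <- function(variant) {
  seq <- if (inherits(variant, "peptide_variant")) variant$sequence else variant
  aa <- strsplit(seq, "")[[1]]
  bad <- setdiff(aa, AA1)
  if (length(bad))
    stop("invalid sequence: unknown residue letter(s) ", paste(unique(bad), collapse = ", "))
  sum(aa %in% c("S", "T", "Y"))
}
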