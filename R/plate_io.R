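#' Read plate fluorescence data in wide format
#'
#' Wide layout: first column is time in seconds, every other column is one
#' well, with well ids as column names.  Delimiter is inferred from the
#' file extension (`.csv` vs `.tsv`/`.txt`) unless given.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` to infer from the extension.
#' @return Named list of [kinetic_curve()] objects.
#' @export
read_plate_wide <- function(path, sep = NULL) {
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (ncol(df) < 2L) stop("wide plate file needs a time column plus wells")
  times <- df[[1]]
  out <- lapply(names(df)[-1], function(w) kinetic_curve(times, df[[w]], w))
  names(out) <- names(df)[-1]
  out
}

#' Read plate fluorescence data in long format
#'
#' Long layout: columns `well`, `time`, `intensity` (header required).
#'
#' @inheritParams read_plate_wide
#' @return Named list of [kinetic_curve()] objects.
#' @export
read_plate_long <- function(path, sep = NULL) {
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  need <- c("well", "time", "intensity")
  if (!all(need %in% names(df)))
    stop("long plate file needs columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$well), function(d) {
    d <- d[order(d$time), ]
    kinetic_curve(d$time, d$intensity, d$well[1])
  })
  out[order(names(out))]
}

#' Read a plate map assigning wells to conditions
#'
#' YAML mapping of well id to either the string `"blank"` or a mapping with
#' `variant:` and `pH:` entries, e.g.
#' ```yaml
#' A1: {variant: control, pH: 1.1}
#' H12: blank
#' ```
#'
#' @param file YAML file path, or `NULL` with `text`.
#' @param text YAML text.
#' @return Data frame with columns `well`, `variant`, `pH`, `blank`.
#' @export
read_plate_map <- function(file = NULL, text = NULL) {
  y <- if (is.null(text)) yaml::read_yaml(file) else yaml::read_yaml(text = text)
  rows <- lapply(names(y), function(w) {
    v <- y[[w]]
    if (identical(v, "blank"))
      data.frame(well = w, variant = NA_character_, pH = NA_real_, blank = TRUE)
    else
      data.frame(well = w, variant = v$variant, pH = as.numeric(v$pH), blank = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble replicate sets from curves and a plate map
#'
#' Groups the mapped wells by (variant, pH) and attaches the blank wells
#' (averaged when several) to every set.
#'
#' @param curves Named list of [kinetic_curve()] (names are well ids).
#' @param map Data frame from [read_plate_map()].
#' @return Named list of [replicate_set()] objects (`variant@pH` names).
#' @export
assemble_plate <- function(curves, map) {
  blanks <- curves[map$well[map$blank]]
  if (!length(blanks)) stop("plate map contains no blank wells")
  cond <- map[!map$blank, , drop = FALSE]
  keys <- paste0(cond$variant, "@", cond$pH)
  out <- lapply(split(cond, keys), function(d)
    replicate_set(curves[d$well], blanks, variant = d$variant[1], pH = d$pH[1]))
  out
}

#' Read or write a variant-by-pH aggregation outcome matrix
#'
#' Tab-separated table with columns `variant`, `pH`, `outcome`
#' (`fibrils`/`no_fibrils`) and optional `t50` (mean seconds, `NA` when not
#' determined).
#'
#' @param path File path.
#' @return `read_outcomes()`: an `outcome_matrix` data frame.
#' @export
read_outcomes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("variant", "pH", "outcome")
  if (!all(need %in% names(df)))
    stop("outcome table needs columns: ", paste(need, collapse = ", "))
  if (!"t50" %in% names(df)) df$t50 <- NA_real_
  as_outcome_matrix(df)
}

#' @param outcomes An `outcome_matrix` data frame.
#' @rdname read_outcomes
#' @export
write_outcomes <- function(outcomes, path) {
  utils::write.table(outcomes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

as_outcome_matrix <- function(df) {
  bad <- setdiff(unique(df$outcome), c("fibrils", "no_fibrils"))
  if (length(bad)) stop("outcomes must be fibrils/no_fibrils, got: ",
                        paste(bad, collapse = ", "))
  df$pH <- as.numeric(df$pH)
  class(df) <- c("outcome_matrix", "data.frame")
  df
}
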