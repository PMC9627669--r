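TREATMENTS <- c("etoposide", "tnfa", "vehicle")

#' A single 384-well plate measurement
#'
#' Holds one plate's raw relative luminescence units (RLU) and, when the
#' assay included the TOX viability channel, the per-well viability
#' fluorescence, together with plate identity.
#'
#' @param plate_id plate identifier (text).
#' @param replicate_id replicate identifier, e.g. "R1".
#' @param treatment one of `"etoposide"`, `"tnfa"`, `"vehicle"`.
#' @param rlu named numeric vector of non-negative luminescence values;
#'   names are well addresses. Wells absent from `rlu` are stored as `NA`
#'   (permitted only for EMPTY wells of the layout in later stages).
#' @param viability optional named numeric vector of non-negative
#'   viability values over the same wells.
#' @return an object of class `plate_read`.
#' @export
plate_read <- function(plate_id, replicate_id, treatment, rlu,
                       viability = NULL) {
  treatment <- match.arg(treatment, TREATMENTS)
  full <- fill_wells(rlu, "rlu")
  v <- if (!is.null(viability)) fill_wells(viability, "viability")
  structure(list(plate_id = as.character(plate_id),
                 replicate_id = as.character(replicate_id),
                 treatment = treatment, rlu = full, viability = v),
            class = "plate_read")
}

fill_wells <- function(x, what) {
  if (is.null(names(x))) {
    screen_abort(sprintf("%s values must be named by well address", what),
                 "rnaiscreen_format_error")
  }
  wells <- canonical_well(names(x))
  x <- as.numeric(x)
  neg <- !is.na(x) & x < 0
  if (any(neg)) {
    screen_abort(sprintf("negative %s value at well %s", what,
                         paste(wells[neg], collapse = ", ")),
                 "rnaiscreen_value_error")
  }
  full <- setNames(rep(NA_real_, 384L), plate_wells())
  full[wells] <- x
  full
}

#' @export
print.plate_read <- function(x, ...) {
  n <- sum(!is.na(x$rlu))
  cat(sprintf("plate_read %s / %s (%s): %d measured wells, RLU median %.4g%s\n",
              x$plate_id, x$replicate_id, x$treatment, n,
              median(x$rlu, na.rm = TRUE),
              if (!is.null(x$viability)) ", with viability" else ""))
  invisible(x)
}

#' Read a plate-matrix CSV (one plate per file)
#'
#' The file is a 16 x 24 matrix with row headers A--P in the first column
#' and column headers 1--24, one cell per well.
#'
#' @param path path to the CSV file.
#' @param plate_id,replicate_id,treatment plate identity (not stored in
#'   the matrix dialect, so supplied by the caller).
#' @return a `plate_read` covering all 384 wells.
#' @export
parse_plate_matrix <- function(path, plate_id, replicate_id = "R1",
                               treatment = "etoposide") {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) != 16L) {
    screen_abort(sprintf("expected 16 rows, found %d in %s", nrow(raw), path),
                 "rnaiscreen_format_error")
  }
  if (ncol(raw) != 25L) {
    screen_abort(sprintf("expected 24 data columns, found %d in %s",
                         ncol(raw) - 1L, path),
                 "rnaiscreen_format_error")
  }
  rows <- toupper(as.character(raw[[1L]]))
  if (!identical(sort(rows), LETTERS[1:16])) {
    screen_abort(sprintf("row headers must be A-P; offending row(s): %s",
                         paste(setdiff(rows, LETTERS[1:16]), collapse = ", ")),
                 "rnaiscreen_format_error")
  }
  vals <- as.matrix(raw[, -1L])
  rlu <- setNames(rep(NA_real_, 384L), plate_wells())
  for (i in seq_len(16L)) {
    for (j in seq_len(24L)) {
      v <- suppressWarnings(as.numeric(vals[i, j]))
      w <- format_well(rows[i], j)
      if (is.na(v) && !is.na(vals[i, j]) && vals[i, j] != "") {
        screen_abort(sprintf("non-numeric value at well %s", w),
                     "rnaiscreen_value_error")
      }
      if (!is.na(v) && v < 0) {
        screen_abort(sprintf("negative value at well %s", w),
                     "rnaiscreen_value_error")
      }
      rlu[w] <- v
    }
  }
  plate_read(plate_id, replicate_id, treatment, rlu)
}

#' Write a plate as a matrix CSV
#'
#' Inverse of [parse_plate_matrix()]; round-trips cell-for-cell.
#'
#' @param plate a `plate_read`.
#' @param path output path.
#' @export
write_plate_matrix <- function(plate, path) {
  m <- matrix(fmt_num(plate$rlu[plate_wells()]), nrow = 16L, ncol = 24L,
              byrow = TRUE)
  df <- data.frame(row = LETTERS[1:16], m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("row", as.character(1:24))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## full double precision so parse(write(x)) round-trips bit-for-bit
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Read a long-table screen CSV (many plates per file)
#'
#' The long dialect is the pipeline's canonical format: one row per well
#' with columns `plate_id`, `replicate_id`, `treatment`, `well`, `rlu`
#' and optionally `viability`.
#'
#' @param path path to the CSV file.
#' @return a list of `plate_read` objects, one per distinct
#'   (plate_id, replicate_id, treatment).
#' @export
parse_long_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "replicate_id", "treatment", "well", "rlu")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    screen_abort(sprintf("long table missing column(s): %s",
                         paste(miss, collapse = ", ")),
                 "rnaiscreen_format_error")
  }
  df$well <- canonical_well(df$well)
  key <- paste(df$plate_id, df$replicate_id, df$treatment, df$well, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    screen_abort(sprintf("duplicate row for plate %s replicate %s well %s",
                         d$plate_id, d$replicate_id, d$well),
                 "rnaiscreen_duplication_error")
  }
  grp <- interaction(df$plate_id, df$replicate_id, df$treatment, drop = TRUE)
  lapply(split(df, grp), function(g) {
    plate_read(g$plate_id[1L], g$replicate_id[1L], g$treatment[1L],
               rlu = setNames(g$rlu, g$well),
               viability = if ("viability" %in% names(g) &&
                               !all(is.na(g$viability)))
                 setNames(g$viability, g$well))
  })
}

#' Write plates as a canonical long-table CSV
#'
#' @param plates a `plate_read` or list of them.
#' @param path output path.
#' @export
write_long_table <- function(plates, path) {
  if (inherits(plates, "plate_read")) plates <- list(plates)
  rows <- lapply(plates, function(p) {
    keep <- !is.na(p$rlu)
    out <- data.frame(plate_id = p$plate_id, replicate_id = p$replicate_id,
                      treatment = p$treatment, well = names(p$rlu)[keep],
                      rlu = fmt_num(unname(p$rlu[keep])),
                      stringsAsFactors = FALSE)
    if (!is.null(p$viability)) out$viability <- fmt_num(unname(p$viability[keep]))
    out
  })
  has_v <- vapply(rows, function(r) "viability" %in% names(r), logical(1))
  if (any(has_v) && !all(has_v)) {
    rows <- lapply(rows, function(r) {
      if (!"viability" %in% names(r)) r$viability <- rep("NA", nrow(r))
      r
    })
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-screen siRNA library annotation
#'
#' Validates the screen-wide annotation table mapping each sample well of
#' each plate to its siRNA and gene (one siRNA per well; the emulated
#' library carries three siRNAs per gene).
#'
#' @param df data.frame with columns `gene_id`, `sirna_id`, `plate_id`,
#'   `well`.
#' @return the validated data.frame, class `library_annotation`.
#' @export
library_annotation <- function(df) {
  need <- c("gene_id", "sirna_id", "plate_id", "well")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    screen_abort(sprintf("annotation missing column(s): %s",
                         paste(miss, collapse = ", ")),
                 "rnaiscreen_annotation_error")
  }
  df$well <- canonical_well(df$well)
  if (anyDuplicated(df$sirna_id)) {
    screen_abort("each sirna_id must occur once in the annotation",
                 "rnaiscreen_annotation_error")
  }
  class(df) <- c("library_annotation", "data.frame")
  df
}
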