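#' Plate-wise robust Z-score
#'
#' Scores every sample well of a plate as
#' \deqn{z = \frac{x - \mathrm{median}(x_{subset})}{\mathrm{mad}(x_{subset})}}
#' where \eqn{x} is the well's luminescence value and the subset is all
#' sample wells of the same plate. The MAD is the median absolute
#' deviation from the subset median, scaled by `mad_constant`
#' (1.4826 for consistency with the normal SD; set 1 for the unscaled
#' MAD). Control wells are never part of the subset and carry no Z-score;
#' their raw values are retained for QC.
#'
#' A plate whose sample wells are constant (MAD = 0) cannot be scored and
#' raises a degenerate-plate condition rather than producing infinite
#' scores; [normalize_screen()] catches it, excludes the plate and logs
#' the exclusion.
#'
#' @param plate a [plate_read()].
#' @param layout a [plate_layout()] giving the plate's sample wells.
#' @param mad_constant MAD scale factor (default 1.4826).
#' @return an object of class `normalized_plate`: the plate identity, the
#'   per-sample-well `z`, the carried-through raw `rlu`, and normalization
#'   metadata (`median`, `mad` = scaled MAD, `mad_raw`, `n`).
#' @examples
#' lay <- default_layout()
#' rlu <- setNames(rlnorm(384, log(1000), 0.2), plate_wells())
#' p <- plate_read("P1", "R1", "etoposide", rlu)
#' np <- robust_zscore_plate(p, lay)
#' median(np$z)  # 0 by construction
#' @export
robust_zscore_plate <- function(plate, layout, mad_constant = 1.4826) {
  sw <- layout_wells(layout, "SAMPLE")
  x <- plate$rlu[sw]
  x <- x[!is.na(x)]
  if (length(x) < 2L) {
    screen_abort(sprintf("plate %s: fewer than 2 measured sample wells",
                         plate$plate_id),
                 "rnaiscreen_layout_error")
  }
  med <- median(x)
  mad_raw <- median(abs(x - med))
  if (mad_raw == 0) {
    screen_abort(sprintf("plate %s: MAD of sample wells is 0 (degenerate plate)",
                         plate$plate_id),
                 "rnaiscreen_degenerate_plate_error")
  }
  mad_scaled <- mad_constant * mad_raw
  z <- (x - med) / mad_scaled
  structure(list(plate_id = plate$plate_id,
                 replicate_id = plate$replicate_id,
                 treatment = plate$treatment,
                 z = z, rlu = plate$rlu,
                 stats = list(median = med, mad = mad_scaled,
                              mad_raw = mad_raw,
                              mad_constant = mad_constant,
                              n = length(x))),
            class = "normalized_plate")
}

#' @export
print.normalized_plate <- function(x, ...) {
  cat(sprintf("normalized_plate %s / %s: %d sample wells, median %.4g, scaled MAD %.4g\n",
              x$plate_id, x$replicate_id, x$stats$n, x$stats$median, x$stats$mad))
  invisible(x)
}

#' Normalize luminescence to the viability channel
#'
#' Divides every well's RLU by its TOX viability fluorescence, so the
#' reporter signal reflects per-viable-cell activity rather than well
#' cell number. Identity and treatment are unchanged. Plates without a
#' viability channel fail fast; no imputation is attempted.
#'
#' @param plate a [plate_read()] with a viability map.
#' @return a [plate_read()] whose `rlu` is the viability-normalized signal.
#' @export
viability_normalize <- function(plate) {
  if (is.null(plate$viability)) {
    screen_abort(sprintf("plate %s has no viability channel", plate$plate_id),
                 "rnaiscreen_configuration_error")
  }
  scored <- !is.na(plate$rlu)
  v <- plate$viability
  bad <- scored & (is.na(v) | v == 0)
  if (any(bad)) {
    screen_abort(sprintf("zero or missing viability at well %s",
                         paste(names(v)[bad], collapse = ", ")),
                 "rnaiscreen_division_error")
  }
  out <- plate
  out$rlu[scored] <- plate$rlu[scored] / v[scored]
  out
}

#' Normalize a whole screen to plate-wise robust Z-scores
#'
#' Applies [robust_zscore_plate()] to every plate and joins the scores to
#' the siRNA library annotation. Degenerate plates (MAD = 0) are excluded
#' from the result and listed in the `excluded_plates` attribute, never
#' silently scored.
#'
#' @param plates list of [plate_read()] objects.
#' @param layout a [plate_layout()], or a named list of layouts keyed by
#'   `plate_id` when plates differ (e.g. a partially filled final plate).
#' @param annotation a [library_annotation()] table; may be `NULL` for
#'   un-annotated scoring (gene/siRNA columns are then `NA`).
#' @param mad_constant MAD scale factor, see [robust_zscore_plate()].
#' @return an object of class `normalized_screen`: a data.frame with
#'   columns `gene_id`, `sirna_id`, `plate_id`, `replicate_id`,
#'   `treatment`, `well`, `rlu`, `z`, plus attributes `plate_stats`
#'   (per-plate normalization metadata) and `excluded_plates`.
#' @export
normalize_screen <- function(plates, layout, annotation = NULL,
                             mad_constant = 1.4826) {
  if (inherits(plates, "plate_read")) plates <- list(plates)
  get_layout <- function(pid) {
    if (inherits(layout, "plate_layout")) return(layout)
    l <- layout[[pid]]
    if (is.null(l)) {
      screen_abort(sprintf("no layout for plate %s", pid),
                   "rnaiscreen_layout_error")
    }
    l
  }
  rows <- list(); stats <- list(); excluded <- list()
  for (p in plates) {
    lay <- get_layout(p$plate_id)
    np <- tryCatch(robust_zscore_plate(p, lay, mad_constant),
                   rnaiscreen_degenerate_plate_error = function(e) e)
    if (inherits(np, "condition")) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(plate_id = p$plate_id, replicate_id = p$replicate_id,
                   reason = conditionMessage(np), stringsAsFactors = FALSE)
      next
    }
    wells <- names(np$z)
    rows[[length(rows) + 1L]] <-
      data.frame(plate_id = p$plate_id, replicate_id = p$replicate_id,
                 treatment = p$treatment, well = wells,
                 rlu = unname(p$rlu[wells]), z = unname(np$z),
                 stringsAsFactors = FALSE)
    stats[[length(stats) + 1L]] <-
      data.frame(plate_id = p$plate_id, replicate_id = p$replicate_id,
                 median = np$stats$median, mad = np$stats$mad,
                 n = np$stats$n, stringsAsFactors = FALSE)
  }
  scr <- if (length(rows)) do.call(rbind, rows) else
    data.frame(plate_id = character(0), replicate_id = character(0),
               treatment = character(0), well = character(0),
               rlu = numeric(0), z = numeric(0))
  if (!is.null(annotation)) {
    idx <- match(paste(scr$plate_id, scr$well, sep = "\r"),
                 paste(annotation$plate_id, annotation$well, sep = "\r"))
    if (anyNA(idx) && nrow(scr)) {
      m <- scr[is.na(idx), , drop = FALSE][1L, ]
      screen_abort(sprintf("no annotation for sample well %s on plate %s",
                           m$well, m$plate_id),
                   "rnaiscreen_annotation_error")
    }
    scr$gene_id <- annotation$gene_id[idx]
    scr$sirna_id <- annotation$sirna_id[idx]
  } else {
    scr$gene_id <- rep(NA_character_, nrow(scr))
    scr$sirna_id <- rep(NA_character_, nrow(scr))
  }
  scr <- scr[, c("gene_id", "sirna_id", "plate_id", "replicate_id",
                 "treatment", "well", "rlu", "z")]
  rownames(scr) <- NULL
  structure(scr,
            plate_stats = if (length(stats)) do.call(rbind, stats) else NULL,
            excluded_plates = if (length(excluded)) do.call(rbind, excluded)
                              else NULL,
            mad_constant = mad_constant,
            class = c("normalized_screen", "data.frame"))
}

#' @export
print.normalized_screen <- function(x, ...) {
  excl <- attr(x, "excluded_plates")
  cat(sprintf("normalized_screen: %d scored wells on %d plates (%d excluded)\n",
              nrow(x), length(unique(paste(x$plate_id, x$replicate_id))),
              if (is.null(excl)) 0L else nrow(excl)))
  if (!is.null(excl)) {
    for (i in seq_len(nrow(excl))) cat("  excluded:", excl$reason[i], "\n")
  }
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
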