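#' Z'-factor assay quality statistic
#'
#' \deqn{Z' = 1 - \frac{3(\sigma_p + \sigma_n)}{|\mu_p - \mu_n|}}
#' over positive- and negative-control well values, with sample
#' (n - 1 denominator) standard deviations. Z' is at most 1; values of
#' 0.5 and above denote an excellent assay window; the screening cutoff
#' used here for plate acceptance defaults to 0.1.
#'
#' @param pos numeric vector of positive-control values (at least 2).
#' @param neg numeric vector of negative-control values (at least 2).
#' @return the Z'-factor, a single number \eqn{\le 1}.
#' @examples
#' z_factor(c(900, 1000, 1100), c(90, 100, 110))  # 0.6333...
#' @export
z_factor <- function(pos, neg) {
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  if (length(pos) < 2L || length(neg) < 2L) {
    screen_abort("need at least 2 values in each control arm",
                 "rnaiscreen_insufficient_controls_error")
  }
  mp <- mean(pos); mn <- mean(neg)
  if (mp == mn) {
    screen_abort("control means are equal: Z'-factor separation undefined",
                 "rnaiscreen_undefined_separation_error")
  }
  1 - 3 * (sd(pos) + sd(neg)) / abs(mp - mn)
}

#' Per-plate Z'-factor quality control
#'
#' Computes one Z'-factor per plate from designated control wells on the
#' raw RLU scale. Following the screen design, the positive controls are
#' the stimulated nontargeting-siRNA wells (full reporter induction) and
#' the negative controls are the DMSO vehicle-column wells (no
#' induction); both role choices are configurable because plate designs
#' vary. Plates below the acceptance cutoff are flagged for repetition,
#' not dropped. The report also tallies plates below / at-or-above a
#' reporting threshold (conventionally 0.5, the excellent-assay mark) and
#' the mean Z' across plates, and, when replicate plates are present,
#' per-pair Spearman reproducibility over sample wells.
#'
#' @param plates list of [plate_read()] objects.
#' @param layout a [plate_layout()] or named list keyed by `plate_id`.
#' @param cutoff plate acceptance cutoff on Z' (default 0.1).
#' @param report_threshold reporting threshold for the quality tally
#'   (default 0.5).
#' @param positive_role,negative_role layout roles providing the control
#'   arms.
#' @return an object of class `qc_report`: a data.frame with one row per
#'   plate (`plate_id`, `replicate_id`, `z_factor`, `n_pos`, `n_neg`,
#'   `pass`, `note`), with attributes `mean_z_factor`, `n_below`,
#'   `n_at_or_above`, `cutoff`, `report_threshold` and `replicate_rho`.
#' @export
plate_qc <- function(plates, layout, cutoff = 0.1, report_threshold = 0.5,
                     positive_role = "NONTARGETING_CTRL",
                     negative_role = "VEHICLE_CTRL") {
  if (inherits(plates, "plate_read")) plates <- list(plates)
  get_layout <- function(pid) {
    if (inherits(layout, "plate_layout")) layout else layout[[pid]]
  }
  rows <- lapply(plates, function(p) {
    lay <- get_layout(p$plate_id)
    pos <- p$rlu[layout_wells(lay, positive_role)]
    neg <- p$rlu[layout_wells(lay, negative_role)]
    zf <- tryCatch(z_factor(pos, neg), rnaiscreen_error = function(e) e)
    note <- ""
    if (inherits(zf, "condition")) {
      note <- conditionMessage(zf)
      zf <- NA_real_
    }
    data.frame(plate_id = p$plate_id, replicate_id = p$replicate_id,
               z_factor = zf, n_pos = sum(!is.na(pos)),
               n_neg = sum(!is.na(neg)),
               pass = !is.na(zf) && zf >= cutoff, note = note,
               stringsAsFactors = FALSE)
  })
  qc <- do.call(rbind, rows)
  rownames(qc) <- NULL
  zf <- qc$z_factor[!is.na(qc$z_factor)]
  structure(qc,
            mean_z_factor = if (length(zf)) mean(zf) else NA_real_,
            n_below = sum(zf < report_threshold),
            n_at_or_above = sum(zf >= report_threshold),
            cutoff = cutoff, report_threshold = report_threshold,
            replicate_rho = replicate_correlations(plates, layout),
            class = c("qc_report", "data.frame"))
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d plates, mean Z' = %.3f; %d below %.2g, %d at/above; cutoff %.2g (%d pass)\n",
              nrow(x), attr(x, "mean_z_factor"), attr(x, "n_below"),
              attr(x, "report_threshold"), attr(x, "n_at_or_above"),
              attr(x, "cutoff"), sum(x$pass)))
  rho <- attr(x, "replicate_rho")
  if (!is.null(rho) && nrow(rho)) {
    cat(sprintf("  replicate Spearman rho: median %.3f over %d plate pairs\n",
                median(rho$rho), nrow(rho)))
  }
  invisible(x)
}

#' Spearman rank correlation between two replicate plates
#'
#' Reproducibility statistic for replicated screening plates: Spearman's
#' rho over the shared wells, with ties resolved by average ranks.
#'
#' @param r1,r2 named numeric vectors of per-well values from the two
#'   replicates; the well sets must match.
#' @return Spearman's rho in \[-1, 1\].
#' @export
replicate_spearman <- function(r1, r2) {
  if (is.null(names(r1)) || is.null(names(r2)) ||
      !setequal(names(r1), names(r2))) {
    screen_abort("replicates must cover the same well set",
                 "rnaiscreen_alignment_error")
  }
  r2 <- r2[names(r1)]
  keep <- !is.na(r1) & !is.na(r2)
  if (sum(keep) < 3L) {
    screen_abort("need at least 3 shared measured wells",
                 "rnaiscreen_alignment_error")
  }
  cor(r1[keep], r2[keep], method = "spearman")
}

## All replicate pairs of the same physical plate (plate_id + treatment),
## correlated over sample-well raw RLU.
replicate_correlations <- function(plates, layout) {
  get_layout <- function(pid) {
    if (inherits(layout, "plate_layout")) layout else layout[[pid]]
  }
  key <- vapply(plates, function(p) paste(p$plate_id, p$treatment), character(1))
  out <- list()
  for (k in unique(key)) {
    grp <- plates[key == k]
    if (length(grp) < 2L) next
    sw <- layout_wells(get_layout(grp[[1L]]$plate_id), "SAMPLE")
    for (i in seq_len(length(grp) - 1L)) {
      for (j in seq(i + 1L, length(grp))) {
        out[[length(out) + 1L]] <- data.frame(
          plate_id = grp[[i]]$plate_id,
          rep1 = grp[[i]]$replicate_id, rep2 = grp[[j]]$replicate_id,
          rho = replicate_spearman(grp[[i]]$rlu[sw], grp[[j]]$rlu[sw]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(plate_id = character(0), rep1 = character(0),
               rep2 = character(0), rho = numeric(0))
}

#' Resolve repeated plates before scoring
#'
#' Screens often re-run low-quality plates. Given several replicates of
#' the same plate/treatment, keep either the latest replicate (by
#' replicate id order, the default) or the one with the best Z'-factor.
#'
#' @param plates list of [plate_read()] objects.
#' @param qc optional [plate_qc()] report, required for `"keep_best"`.
#' @param policy `"keep_latest"` or `"keep_best"`.
#' @return the reduced list of plates, one per (plate_id, treatment).
#' @export
resolve_repeats <- function(plates, qc = NULL,
                            policy = c("keep_latest", "keep_best")) {
  policy <- match.arg(policy)
  key <- vapply(plates, function(p) paste(p$plate_id, p$treatment), character(1))
  picked <- lapply(unique(key), function(k) {
    grp <- plates[key == k]
    if (length(grp) == 1L) return(grp[[1L]])
    if (policy == "keep_latest") {
      reps <- vapply(grp, `[[`, character(1), "replicate_id")
      grp[[order(reps, decreasing = TRUE)[1L]]]
    } else {
      if (is.null(qc)) {
        screen_abort("keep_best policy requires a qc report",
                     "rnaiscreen_configuration_error")
      }
      zf <- vapply(grp, function(p) {
        i <- which(qc$plate_id == p$plate_id &
                   qc$replicate_id == p$replicate_id)[1L]
        if (is.na(i)) -Inf else qc$z_factor[i]
      }, numeric(1))
      grp[[which.max(zf)]]
    }
  })
  picked
}
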