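#' Counter-screen input table with treatment-control references
#'
#' Bundles per-gene mean reporter RLU under the DNA-damage stimulus
#' (etoposide) and under TNFa with the two reference levels the
#' classification needs: the etoposide treatment-control RLU (the
#' "red line" of the etoposide arm) and the siTRAF6 RLU under TNFa
#' (the arbitrary TNFa threshold, chosen because TRAF6 is required for
#' the DNA-damage pathway but has no prominent role in TNFa signaling).
#'
#' @param data data.frame with columns `gene_id`, `rlu_eto`, `rlu_tnfa`
#'   (NA for a missing arm).
#' @param theta_eto etoposide treatment-control reference RLU (> 0).
#' @param theta_tnf siTRAF6 TNFa reference RLU (> 0).
#' @return an object of class `counter_screen_input`.
#' @seealso [counter_references()] to derive the references from control
#'   wells, [classify_groups()].
#' @export
counter_screen_input <- function(data, theta_eto, theta_tnf) {
  need <- c("gene_id", "rlu_eto", "rlu_tnfa")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    screen_abort(sprintf("counter-screen table missing column(s): %s",
                         paste(miss, collapse = ", ")),
                 "rnaiscreen_format_error")
  }
  if (!is.numeric(theta_eto) || !is.numeric(theta_tnf) ||
      theta_eto <= 0 || theta_tnf <= 0) {
    screen_abort("references theta_eto and theta_tnf must be strictly positive",
                 "rnaiscreen_configuration_error")
  }
  neg <- (!is.na(data$rlu_eto) & data$rlu_eto < 0) |
         (!is.na(data$rlu_tnfa) & data$rlu_tnfa < 0)
  if (any(neg)) {
    screen_abort("negative RLU in counter-screen table",
                 "rnaiscreen_value_error")
  }
  structure(data.frame(gene_id = as.character(data$gene_id),
                       rlu_eto = data$rlu_eto, rlu_tnfa = data$rlu_tnfa,
                       stringsAsFactors = FALSE),
            theta_eto = theta_eto, theta_tnf = theta_tnf,
            class = c("counter_screen_input", "data.frame"))
}

#' Derive counter-screen references from control-well values
#'
#' @param controls data.frame with columns `role`, `treatment`, `rlu`;
#'   the etoposide reference is the mean RLU of `treatment_ctrl` rows
#'   under `etoposide`, the TNFa reference the mean RLU of `sitraf6`
#'   rows under `tnfa`. Replicate rows are averaged.
#' @return list with `theta_eto` and `theta_tnf`.
#' @export
counter_references <- function(controls) {
  need <- c("role", "treatment", "rlu")
  if (!all(need %in% names(controls))) {
    screen_abort("controls table needs columns role, treatment, rlu",
                 "rnaiscreen_format_error")
  }
  pick <- function(role, treatment) {
    v <- controls$rlu[controls$role == role & controls$treatment == treatment]
    if (!length(v)) {
      screen_abort(sprintf("no %s control rows under %s", role, treatment),
                   "rnaiscreen_configuration_error")
    }
    mean(v)
  }
  list(theta_eto = pick("treatment_ctrl", "etoposide"),
       theta_tnf = pick("sitraf6", "tnfa"))
}

#' Dual-stimulus counter-screen classification
#'
#' Classifies each pre-selected hit by the two-arm rule: group I if the
#' gene's knockdown abrogated the etoposide-induced reporter signal
#' (RLU_eto strictly below `f_eto` times the etoposide treatment-control
#' reference); group II if its TNFa-induced signal stayed strictly above
#' `f_tnf` times the siTRAF6 reference (i.e. the gene is not required for
#' TNFa-driven activation). The intersection — genes required for the
#' DNA-damage arm but dispensable for the TNFa arm — are the
#' DNA-damage-selective positive regulators. Genes at exactly a threshold
#' are non-members (strict inequalities), and signed margins
#' (RLU - threshold) are recorded per arm so any re-thresholding is
#' auditable. Genes missing either arm are unclassifiable.
#'
#' @param input a [counter_screen_input()].
#' @param f_eto,f_tnf threshold multipliers applied to the two references
#'   (defaults 1.0).
#' @return an object of class `counter_result`: a data.frame with columns
#'   `gene_id`, `rlu_eto`, `rlu_tnfa`, `margin_eto`, `margin_tnf`,
#'   `group1`, `group2`, `selective` (logical, NA when unclassifiable),
#'   with the thresholds in attributes.
#' @export
classify_groups <- function(input, f_eto = 1.0, f_tnf = 1.0) {
  if (!inherits(input, "counter_screen_input")) {
    screen_abort("input must be a counter_screen_input",
                 "rnaiscreen_configuration_error")
  }
  th_e <- f_eto * attr(input, "theta_eto")
  th_t <- f_tnf * attr(input, "theta_tnf")
  out <- as.data.frame(input)
  out$margin_eto <- out$rlu_eto - th_e
  out$margin_tnf <- out$rlu_tnfa - th_t
  out$group1 <- out$rlu_eto < th_e
  out$group2 <- out$rlu_tnfa > th_t
  miss <- is.na(out$rlu_eto) | is.na(out$rlu_tnfa)
  out$group1[miss] <- NA
  out$group2[miss] <- NA
  out$selective <- out$group1 & out$group2
  structure(out, theta_eto = attr(input, "theta_eto"),
            theta_tnf = attr(input, "theta_tnf"),
            f_eto = f_eto, f_tnf = f_tnf,
            class = c("counter_result", "data.frame"))
}

#' Summary counts of a counter-screen classification
#'
#' @param result a [classify_groups()] result.
#' @return list with counts `group1`, `group2`, `selective`,
#'   `unclassifiable` and `n` (all classified genes).
#' @export
count_selective <- function(result) {
  un <- is.na(result$group1) | is.na(result$group2)
  list(group1 = sum(result$group1[!un]),
       group2 = sum(result$group2[!un]),
       selective = sum(result$selective[!un]),
       unclassifiable = sum(un),
       n = sum(!un))
}

#' @export
print.counter_result <- function(x, ...) {
  cts <- count_selective(x)
  cat(sprintf("counter_result: %d genes classified (thresholds: eto < %.4g, tnfa > %.4g)\n",
              cts$n, attr(x, "f_eto") * attr(x, "theta_eto"),
              attr(x, "f_tnf") * attr(x, "theta_tnf")))
  cat(sprintf("  group I (etoposide response abrogated): %d\n", cts$group1))
  cat(sprintf("  group II (TNFa response retained):      %d\n", cts$group2))
  cat(sprintf("  selective (I and II):                   %d\n", cts$selective))
  if (cts$unclassifiable) cat(sprintf("  unclassifiable: %d\n", cts$unclassifiable))
  invisible(x)
}

#' Two-arm RLU plot of a counter screen
#'
#' Per-gene RLU in the etoposide and TNFa arms with the reference
#' thresholds drawn as red lines; selective genes highlighted.
#'
#' @param x a `counter_result`.
#' @param ... passed to plotting functions.
#' @export
plot.counter_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  sel <- !is.na(x$selective) & x$selective
  for (arm in c("eto", "tnfa")) {
    v <- if (arm == "eto") x$rlu_eto else x$rlu_tnfa
    th <- if (arm == "eto") attr(x, "f_eto") * attr(x, "theta_eto")
          else attr(x, "f_tnf") * attr(x, "theta_tnf")
    ord <- order(v)
    graphics::plot(seq_along(v), v[ord], pch = 16, cex = 0.6,
                   col = ifelse(sel[ord], "firebrick", "grey40"),
                   xlab = "gene (ranked)", ylab = "RLU",
                   main = if (arm == "eto") "etoposide" else "TNFa", ...)
    graphics::abline(h = th, col = "red", lwd = 2)
  }
  invisible(x)
}
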