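#' Aggregate siRNA-level Z-scores to gene level
#'
#' Each gene is screened with several independent siRNAs (three in the
#' emulated library); the gene-level score in each direction is the
#' best-scoring siRNA: the signed minimum Z for the activator direction
#' (knockdown abrogates reporter induction) and the signed maximum Z for
#' the suppressor direction (knockdown unleashes the reporter). A
#' stricter two-of-three variant uses the second-best siRNA in each
#' direction instead.
#'
#' Ranks are deterministic: activator rank orders by ascending
#' `best_activator_z`, suppressor rank by descending `best_suppressor_z`;
#' exact ties are broken lexicographically on `gene_id`.
#'
#' @param screen a [normalize_screen()] result (or any data.frame with
#'   `gene_id` and `z` columns).
#' @param annotation optional [library_annotation()]; genes present in
#'   the annotation but with no scored siRNA (all their plates excluded)
#'   are reported in the `unscored` attribute rather than ranked.
#' @param method `"best"` (default) or `"second_best"`.
#' @return an object of class `gene_scores`: a data.frame sorted by
#'   `gene_id` with columns `gene_id`, `n_sirnas`, `best_activator_z`,
#'   `best_suppressor_z`, `activator_rank`, `suppressor_rank`, and flag
#'   columns `activator_candidate`, `suppressor_candidate`, `excluded`,
#'   `excluded_reason` (flags set by [select_hits()] /
#'   [apply_exclusion()]); attribute `unscored` lists unscorable genes.
#' @export
aggregate_gene_scores <- function(screen, annotation = NULL,
                                  method = c("best", "second_best")) {
  method <- match.arg(method)
  if (anyNA(screen$gene_id)) {
    screen_abort("every scored well must carry a gene_id",
                 "rnaiscreen_annotation_error")
  }
  zs <- split(screen$z, screen$gene_id)
  kth <- function(v, k, decreasing) {
    v <- sort(v, decreasing = decreasing)
    v[min(k, length(v))]    # singleton genes fall back to their only value
  }
  k <- if (method == "best") 1L else 2L
  tab <- data.frame(
    gene_id = names(zs),
    n_sirnas = vapply(zs, length, integer(1)),
    best_activator_z = vapply(zs, kth, numeric(1), k = k, decreasing = FALSE),
    best_suppressor_z = vapply(zs, kth, numeric(1), k = k, decreasing = TRUE),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$gene_id), , drop = FALSE]
  n <- nrow(tab)
  ord_act <- order(tab$best_activator_z, tab$gene_id)
  ord_sup <- order(-tab$best_suppressor_z, tab$gene_id)
  tab$activator_rank <- rep(NA_integer_, n)
  tab$suppressor_rank <- rep(NA_integer_, n)
  tab$activator_rank[ord_act] <- seq_len(n)
  tab$suppressor_rank[ord_sup] <- seq_len(n)
  tab$activator_candidate <- rep(FALSE, n)
  tab$suppressor_candidate <- rep(FALSE, n)
  tab$excluded <- rep(FALSE, n)
  tab$excluded_reason <- rep(NA_character_, n)
  rownames(tab) <- NULL
  unscored <- character(0)
  if (!is.null(annotation)) {
    unscored <- sort(setdiff(unique(annotation$gene_id), tab$gene_id))
  }
  structure(tab, unscored = unscored, method = method,
            class = c("gene_scores", "data.frame"))
}

#' Flag top-ranked activator and suppressor candidates
#'
#' Rank-count selection, mirroring the screen's hit rule: the
#' `n_activators` genes with the smallest best-activator Z become
#' activator candidates and the `n_suppressors` genes with the largest
#' best-suppressor Z become suppressor candidates. These are counts, not
#' Z thresholds. Ties at a selection boundary resolve deterministically
#' (equal Z, then lexicographically smaller `gene_id` first).
#'
#' @param table a [aggregate_gene_scores()] result.
#' @param n_activators,n_suppressors selection sizes (defaults 1000/100).
#' @return the table with candidate flags set.
#' @export
select_hits <- function(table, n_activators = 1000L, n_suppressors = 100L) {
  g <- nrow(table)
  if (g == 0L) {
    screen_abort("empty gene score table", "rnaiscreen_configuration_error")
  }
  if (n_activators > g || n_suppressors > g) {
    screen_warn(sprintf("selection size exceeds %d genes; bounded", g),
                "rnaiscreen_selection_bounded_warning")
    n_activators <- min(n_activators, g)
    n_suppressors <- min(n_suppressors, g)
  }
  table$activator_candidate <- table$activator_rank <= n_activators
  table$suppressor_candidate <- table$suppressor_rank <= n_suppressors
  ## flags never survive on previously excluded genes
  table$activator_candidate[table$excluded] <- FALSE
  table$suppressor_candidate[table$excluded] <- FALSE
  attr(table, "n_activators") <- n_activators
  attr(table, "n_suppressors") <- n_suppressors
  table
}

#' Remove candidates in generally-required machinery categories
#'
#' Genes encoding general transcription or RNA-processing machinery, the
#' proteasome and the ribosome are required for any reporter expression
#' and so are uninformative as pathway hits; a user-supplied exclusion
#' table removes their candidate flags while recording the category.
#'
#' @param table a [aggregate_gene_scores()] / [select_hits()] result.
#' @param exclusion data.frame with columns `gene_id`, `category`.
#' @return the table with `excluded` / `excluded_reason` set and
#'   candidate flags removed from excluded genes; exclusion-list genes
#'   absent from the table are recorded in the `not_found` attribute.
#' @export
apply_exclusion <- function(table, exclusion) {
  if (is.null(exclusion) || nrow(exclusion) == 0L) return(table)
  if (!all(c("gene_id", "category") %in% names(exclusion))) {
    screen_abort("exclusion table needs columns gene_id, category",
                 "rnaiscreen_configuration_error")
  }
  idx <- match(table$gene_id, exclusion$gene_id)
  hit <- !is.na(idx)
  table$excluded[hit] <- TRUE
  table$excluded_reason[hit] <- exclusion$category[idx[hit]]
  table$activator_candidate[hit] <- FALSE
  table$suppressor_candidate[hit] <- FALSE
  attr(table, "not_found") <-
    sort(setdiff(exclusion$gene_id, table$gene_id))
  table
}

#' @export
print.gene_scores <- function(x, ...) {
  cat(sprintf("gene_scores: %d genes (best-siRNA aggregation: %s)\n",
              nrow(x), attr(x, "method")))
  cat(sprintf("  activator candidates: %d, suppressor candidates: %d, excluded: %d\n",
              sum(x$activator_candidate), sum(x$suppressor_candidate),
              sum(x$excluded)))
  if (length(attr(x, "unscored"))) {
    cat(sprintf("  unscored genes: %d\n", length(attr(x, "unscored"))))
  }
  top <- as.data.frame(x)[order(x$activator_rank), ]
  print(utils::head(top[, c("gene_id", "best_activator_z", "best_suppressor_z",
                            "activator_rank", "suppressor_rank")], 5L))
  invisible(x)
}

#' Ranked Z-score curve of a screen
#'
#' Plots genes by activator rank against their best-activator Z (the
#' screen's cumulative hit curve): candidate activators sit in the low-Z
#' tail, suppressors in the high-Z tail.
#'
#' @param x a `gene_scores` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gene_scores <- function(x, ...) {
  ord <- order(x$best_activator_z)
  z <- x$best_activator_z[ord]
  col <- ifelse(x$activator_candidate[ord], "firebrick",
                ifelse(x$suppressor_candidate[ord], "steelblue", "grey50"))
  graphics::plot(seq_along(z), z, col = col, pch = 16, cex = 0.4,
                 xlab = "gene rank (activator direction)",
                 ylab = "best-scoring siRNA Z", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
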