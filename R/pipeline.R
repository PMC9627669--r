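#' Configuration for a full screen analysis run
#'
#' Collects every stage parameter with defaults matching the screening
#' workflow: MAD scale 1.4826, Z'-factor plate cutoff 0.1, reporting
#' threshold 0.5, 1000 activator and 100 suppressor candidates, and
#' strict unit threshold multipliers for the counter screen.
#'
#' @param sim a [sim_config()] (used when `plates` is NULL), or NULL.
#' @param plates,layout,annotation pre-loaded screen data; when NULL the
#'   screen is simulated from `sim`.
#' @param mad_constant MAD scale factor for normalization.
#' @param zfactor_cutoff plate-acceptance Z' cutoff.
#' @param report_threshold Z' reporting threshold.
#' @param n_activators,n_suppressors hit-selection sizes.
#' @param exclusion optional exclusion table (`gene_id`, `category`).
#' @param f_eto,f_tnf counter-screen threshold multipliers.
#' @param run_counter run the counter-screen stage.
#' @param viability_normalize divide RLU by the viability channel before
#'   scoring.
#' @param repeat_policy how replicate plates of the same physical plate
#'   are resolved before scoring: `"keep_latest"`, `"keep_best"` (by
#'   Z'), or `"keep_all"`.
#' @param aggregate_method gene aggregation rule, see
#'   [aggregate_gene_scores()].
#' @return a list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), plates = NULL, layout = NULL,
                       annotation = NULL,
                       mad_constant = 1.4826,
                       zfactor_cutoff = 0.1, report_threshold = 0.5,
                       n_activators = 1000L, n_suppressors = 100L,
                       exclusion = NULL,
                       f_eto = 1.0, f_tnf = 1.0,
                       run_counter = TRUE,
                       viability_normalize = FALSE,
                       repeat_policy = c("keep_latest", "keep_best", "keep_all"),
                       aggregate_method = c("best", "second_best")) {
  repeat_policy <- match.arg(repeat_policy)
  aggregate_method <- match.arg(aggregate_method)
  structure(as.list(environment()), class = "run_config")
}

#' Run the whole screen analysis
#'
#' Orchestrates simulate (or load) -> viability normalization (optional)
#' -> Z'-factor QC -> plate-wise robust Z normalization -> gene-level hit
#' calling with optional category exclusion -> dual-stimulus counter
#' screen, and returns everything as one classed object with print,
#' summary and plot methods. A run is fully deterministic given its
#' configuration (including the simulation seed).
#'
#' @param config a [run_config()].
#' @return an object of class `screen_run` with elements `config`, `sim`
#'   (when simulated), `qc`, `screen`, `gene_scores`, `counter`,
#'   `counter_counts` and `summary`.
#' @examples
#' run <- run_screen(run_config(sim = sim_config(n_genes = 200, seed = 7),
#'                              n_activators = 30, n_suppressors = 10))
#' run
#' summary(run)
#' @export
run_screen <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, rnaiscreen_error = function(e) {
      screen_abort(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                   class(e)[1L])
    })
  }
  sim <- NULL
  if (is.null(config$plates)) {
    sim <- stage("simulate", simulate_primary_screen(config$sim))
    plates <- sim$plates
    layout <- sim$layouts
    annotation <- sim$annotation
  } else {
    plates <- config$plates
    layout <- config$layout
    annotation <- config$annotation
  }
  if (config$viability_normalize) {
    plates <- stage("viability", lapply(plates, viability_normalize))
  }
  qc <- stage("qc", plate_qc(plates, layout, cutoff = config$zfactor_cutoff,
                             report_threshold = config$report_threshold))
  if (config$repeat_policy != "keep_all") {
    pol <- if (config$repeat_policy == "keep_latest") "keep_latest" else "keep_best"
    plates <- resolve_repeats(plates, qc = qc, policy = pol)
  }
  screen <- stage("normalize",
                  normalize_screen(plates, layout, annotation,
                                   mad_constant = config$mad_constant))
  scores <- stage("hit_calling", {
    tab <- aggregate_gene_scores(screen, annotation,
                                 method = config$aggregate_method)
    tab <- select_hits(tab, config$n_activators, config$n_suppressors)
    apply_exclusion(tab, config$exclusion)
  })
  counter <- NULL; counter_counts <- NULL
  if (config$run_counter && !is.null(sim)) {
    counter <- stage("counter", {
      cands <- scores$gene_id[scores$activator_candidate]
      classify_groups(simulate_counter_screen(sim, genes = cands),
                      f_eto = config$f_eto, f_tnf = config$f_tnf)
    })
    counter_counts <- count_selective(counter)
  }
  excl <- attr(screen, "excluded_plates")
  summary <- list(
    seed = if (!is.null(sim)) config$sim$seed else NA_integer_,
    parameters = list(mad_constant = config$mad_constant,
                      zfactor_cutoff = config$zfactor_cutoff,
                      n_activators = attr(scores, "n_activators"),
                      n_suppressors = attr(scores, "n_suppressors"),
                      f_eto = config$f_eto, f_tnf = config$f_tnf,
                      repeat_policy = config$repeat_policy,
                      aggregate_method = config$aggregate_method),
    n_plates_scored = length(unique(paste(screen$plate_id,
                                          screen$replicate_id))),
    n_plates_excluded = if (is.null(excl)) 0L else nrow(excl),
    excluded_plates = if (is.null(excl)) character(0) else excl$plate_id,
    n_genes = nrow(scores),
    mean_z_factor = attr(qc, "mean_z_factor"),
    n_qc_pass = sum(qc$pass),
    n_activator_candidates = sum(scores$activator_candidate),
    n_suppressor_candidates = sum(scores$suppressor_candidate),
    n_excluded_genes = sum(scores$excluded),
    counter = counter_counts)
  structure(list(config = config, sim = sim, qc = qc, screen = screen,
                 gene_scores = scores, counter = counter,
                 counter_counts = counter_counts, summary = summary),
            class = "screen_run")
}

#' @export
print.screen_run <- function(x, ...) {
  s <- x$summary
  cat("screen_run\n")
  cat(sprintf("  %d genes on %d plates (%d excluded as degenerate)\n",
              s$n_genes, s$n_plates_scored, s$n_plates_excluded))
  cat(sprintf("  QC: mean Z' %.3f, %d/%d plates pass cutoff %.2g\n",
              s$mean_z_factor, s$n_qc_pass, nrow(x$qc),
              s$parameters$zfactor_cutoff))
  cat(sprintf("  hits: %d activator + %d suppressor candidates (%d excluded)\n",
              s$n_activator_candidates, s$n_suppressor_candidates,
              s$n_excluded_genes))
  if (!is.null(s$counter)) {
    cat(sprintf("  counter screen: %d group I, %d group II, %d selective\n",
                s$counter$group1, s$counter$group2, s$counter$selective))
  }
  invisible(x)
}

#' @export
summary.screen_run <- function(object, ...) {
  object$summary
}

#' @export
plot.screen_run <- function(x, which = c("scores", "qc", "counter"), ...) {
  which <- match.arg(which)
  switch(which,
         scores = plot(x$gene_scores, ...),
         qc = {
           graphics::plot(seq_len(nrow(x$qc)), x$qc$z_factor, pch = 16,
                          xlab = "plate", ylab = "Z'-factor", ...)
           graphics::abline(h = attr(x$qc, "cutoff"), col = "red", lty = 2)
           graphics::abline(h = attr(x$qc, "report_threshold"),
                            col = "grey40", lty = 3)
         },
         counter = {
           if (is.null(x$counter)) {
             screen_abort("run has no counter-screen stage",
                          "rnaiscreen_configuration_error")
           }
           plot(x$counter, ...)
         })
  invisible(x)
}

#' Write all stage outputs of a run to a directory
#'
#' Writes `z.csv` (normalized screen), `qc.csv` + `qc_report.json`,
#' `hits.csv`, `unscored.csv`, `counter_result.csv` (when present) and
#' `summary.json`. Existing files are only replaced with
#' `overwrite = TRUE`.
#'
#' @param run a [run_screen()] result.
#' @param dir output directory (created if missing).
#' @param overwrite replace existing files.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir, overwrite = FALSE) {
  stopifnot(inherits(run, "screen_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- function(name) {
    p <- file.path(dir, name)
    if (file.exists(p) && !overwrite) {
      screen_abort(sprintf("%s exists; use overwrite = TRUE", p),
                   "rnaiscreen_configuration_error")
    }
    p
  }
  write.csv(as.data.frame(run$screen), out("z.csv"), row.names = FALSE)
  write.csv(as.data.frame(run$qc), out("qc.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(mean_z_factor = attr(run$qc, "mean_z_factor"),
         n_below = attr(run$qc, "n_below"),
         n_at_or_above = attr(run$qc, "n_at_or_above"),
         cutoff = attr(run$qc, "cutoff"),
         plates = as.data.frame(run$qc),
         replicate_rho = attr(run$qc, "replicate_rho")),
    out("qc_report.json"), auto_unbox = TRUE, digits = NA)
  write.csv(as.data.frame(run$gene_scores), out("hits.csv"),
            row.names = FALSE)
  unscored <- attr(run$gene_scores, "unscored")
  write.csv(data.frame(gene_id = unscored), out("unscored.csv"),
            row.names = FALSE)
  if (!is.null(run$counter)) {
    write.csv(as.data.frame(run$counter), out("counter_result.csv"),
              row.names = FALSE)
  }
  jsonlite::write_json(run$summary, out("summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
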