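#' Configuration of a synthetic arrayed reporter screen
#'
#' Defines the generative model for a seeded synthetic screen with known
#' ground truth. Each well's signal is
#' \deqn{RLU = p \cdot B \cdot (1 + (F - 1) m) \cdot e^{\varepsilon}}
#' with plate effect \eqn{p} log-normal (sd `plate_effect_sdlog` on the
#' log scale), baseline reporter activity \eqn{B}, stimulus induction
#' fold \eqn{F} (1 for vehicle wells), and log-normal well noise
#' \eqn{\varepsilon \sim N(0, \sigma)} with
#' \eqn{\sigma = \sqrt{\ln(1 + CV^2)}}. Knockdown acts only on the
#' induced component: the remaining induced fraction is
#' \eqn{m = 1 - e (1 - \kappa)} where \eqn{\kappa} is the gene-class
#' multiplier (activators \eqn{< 1}, suppressors \eqn{> 1}, neutral 1)
#' and \eqn{e \in [0, 1]} the per-siRNA knockdown efficacy. An siRNA is
#' fully effective (\eqn{e = 1}) with probability `p_effective` and
#' otherwise partially effective, \eqn{e \sim U(0,} `partial_efficacy_max`).
#'
#' Gene classes are assigned in exact proportions (rounded counts,
#' shuffled); a configured fraction of the activators is DNA-damage
#' selective (their knockdown does not touch the TNFa arm of the counter
#' screen), the remainder shared between both stimuli.
#'
#' @param n_genes number of library genes.
#' @param sirnas_per_gene independent siRNAs per gene (library default 3).
#' @param prop_activator,prop_suppressor gene-class proportions (the rest
#'   are neutral).
#' @param activator_multiplier induced-signal fraction remaining after a
#'   fully effective activator knockdown (0.1 = 90% signal loss).
#' @param suppressor_multiplier induced-signal factor for suppressor
#'   knockdown (> 1).
#' @param pathway_ctrl_multiplier multiplier of the siIKBKG-like pathway
#'   control wells (strong activator knockdown).
#' @param p_effective probability an siRNA is fully effective.
#' @param partial_efficacy_max upper bound of the partial-efficacy draw.
#' @param baseline_rlu unstimulated reporter baseline (RLU).
#' @param induction_eto,induction_tnf stimulus induction folds.
#' @param noise_cv well-noise coefficient of variation.
#' @param plate_effect_sdlog log-scale SD of the multiplicative plate
#'   effect.
#' @param death_kill_fraction signal fraction remaining in cell-death
#'   control wells.
#' @param prop_selective fraction of activators that are DNA-damage
#'   selective.
#' @param sitraf6_tnf_multiplier induced-fraction remaining in
#'   siTRAF6-transfected wells under TNFa (sets the group-II reference
#'   just below the full response).
#' @param n_replicates technical replicates of every plate.
#' @param counter_replicates replicate measurements averaged per arm in
#'   the counter screen.
#' @param simulate_viability also generate a TOX viability channel.
#' @param viability_cv CV of the viability channel.
#' @param column_gradient optional spatial artifact for robustness
#'   testing: fractional linear signal drift from the left to the right
#'   plate edge (0, the default, means no gradient — the pipeline applies
#'   no spatial correction).
#' @param seed integer seed; the whole screen is deterministic given it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000L, sirnas_per_gene = 3L,
                       prop_activator = 0.10, prop_suppressor = 0.05,
                       activator_multiplier = 0.1,
                       suppressor_multiplier = 3,
                       pathway_ctrl_multiplier = 0.05,
                       p_effective = 0.8, partial_efficacy_max = 0.3,
                       baseline_rlu = 100, induction_eto = 10,
                       induction_tnf = 8,
                       noise_cv = 0.15, plate_effect_sdlog = 0.1,
                       death_kill_fraction = 0.05,
                       prop_selective = 0.5,
                       sitraf6_tnf_multiplier = 0.8,
                       n_replicates = 1L, counter_replicates = 3L,
                       simulate_viability = FALSE, viability_cv = 0.1,
                       column_gradient = 0, seed = 1L) {
  cfg <- as.list(environment())
  if (prop_activator + prop_suppressor > 1) {
    screen_abort("class proportions must sum to at most 1",
                 "rnaiscreen_configuration_error")
  }
  stopifnot(activator_multiplier > 0, suppressor_multiplier > 0,
            noise_cv >= 0, plate_effect_sdlog >= 0,
            p_effective >= 0, p_effective <= 1,
            baseline_rlu > 0, induction_eto >= 1, induction_tnf >= 1,
            n_genes >= 1, sirnas_per_gene >= 1)
  structure(cfg, class = "sim_config")
}

cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

## exact-count class assignment, deterministically shuffled under the seed
assign_classes <- function(cfg) {
  g <- cfg$n_genes
  n_act <- round(cfg$prop_activator * g)
  n_sup <- round(cfg$prop_suppressor * g)
  cls <- sample(rep(c("activator", "suppressor", "neutral"),
                    c(n_act, n_sup, g - n_act - n_sup)))
  sel <- rep(FALSE, g)
  act_idx <- which(cls == "activator")
  n_sel <- round(cfg$prop_selective * length(act_idx))
  if (n_sel > 0L) sel[sample(act_idx, n_sel)] <- TRUE
  data.frame(gene_id = sprintf("G%05d", seq_len(g)), class = cls,
             selective = sel, stringsAsFactors = FALSE)
}

class_multiplier <- function(class, cfg) {
  ifelse(class == "activator", cfg$activator_multiplier,
         ifelse(class == "suppressor", cfg$suppressor_multiplier, 1))
}

#' Simulate the primary arrayed screen
#'
#' Lays the library out on as many 384-well plates as needed (352 sample
#' wells per plate, trailing unused wells EMPTY), draws gene classes and
#' per-siRNA efficacies, and generates etoposide-stimulated plates under
#' the generative model of [sim_config()]. Control wells follow their
#' roles: vehicle-column wells lack induction, nontargeting wells show
#' the full induced signal, pathway-control wells behave as a strong
#' activator knockdown, and death-control wells are scaled by the kill
#' fraction.
#'
#' @param config a [sim_config()].
#' @return a list of class `screen_sim` with elements `plates` (list of
#'   [plate_read()]), `layouts` (named list of per-plate layouts),
#'   `annotation` (a [library_annotation()]), `truth` (list of `genes`
#'   and `sirnas` ground-truth tables) and `config`.
#' @export
simulate_primary_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- assign_classes(config)
  n_sirna <- config$n_genes * config$sirnas_per_gene
  sirnas <- data.frame(
    sirna_id = sprintf("s%05d_%d",
                       rep(seq_len(config$n_genes), each = config$sirnas_per_gene),
                       rep(seq_len(config$sirnas_per_gene), config$n_genes)),
    gene_id = rep(genes$gene_id, each = config$sirnas_per_gene),
    stringsAsFactors = FALSE)
  full <- runif(n_sirna) < config$p_effective
  sirnas$efficacy <- ifelse(full, 1, runif(n_sirna, 0, config$partial_efficacy_max))

  template <- default_layout()
  sample_wells <- layout_wells(template, "SAMPLE")
  wells_per_plate <- length(sample_wells)        # 352
  n_plates <- ceiling(n_sirna / wells_per_plate)
  sirnas$plate_id <- sprintf("P%03d", (seq_len(n_sirna) - 1L) %/% wells_per_plate + 1L)
  sirnas$well <- sample_wells[(seq_len(n_sirna) - 1L) %% wells_per_plate + 1L]

  layouts <- list()
  plates <- list()
  cls_mult <- setNames(class_multiplier(genes$class, config), genes$gene_id)
  sdlog <- cv_to_sdlog(config$noise_cv)
  for (i in seq_len(n_plates)) {
    pid <- sprintf("P%03d", i)
    on_plate <- sirnas[sirnas$plate_id == pid, , drop = FALSE]
    n_empty <- wells_per_plate - nrow(on_plate)
    lay <- if (n_empty > 0L) default_layout(n_empty = n_empty) else template
    layouts[[pid]] <- lay
    ## induced-fraction multiplier per well
    m <- setNames(rep(NA_real_, 384L), plate_wells())
    m[on_plate$well] <- 1 - on_plate$efficacy *
      (1 - cls_mult[on_plate$gene_id])
    m[layout_wells(lay, "NONTARGETING_CTRL")] <- 1
    m[layout_wells(lay, "PATHWAY_CTRL")] <- config$pathway_ctrl_multiplier
    m[layout_wells(lay, "DEATH_CTRL")] <- 1
    m[layout_wells(lay, "VEHICLE_CTRL")] <- 1
    kill <- setNames(rep(1, 384L), plate_wells())
    kill[layout_wells(lay, "DEATH_CTRL")] <- config$death_kill_fraction
    fold <- setNames(rep(config$induction_eto, 384L), plate_wells())
    fold[layout_wells(lay, "VEHICLE_CTRL")] <- 1
    measured <- plate_wells()[!is.na(m)]
    grad <- 1 + config$column_gradient * (well_col(measured) - 12.5) / 23
    for (r in seq_len(config$n_replicates)) {
      pe <- exp(rnorm(1L, 0, config$plate_effect_sdlog))
      noise <- if (sdlog > 0) exp(rnorm(length(measured), 0, sdlog)) else
        rep(1, length(measured))
      rlu <- pe * config$baseline_rlu * grad *
        (1 + (fold[measured] - 1) * m[measured]) * kill[measured] * noise
      viability <- NULL
      if (config$simulate_viability) {
        v_sdlog <- cv_to_sdlog(config$viability_cv)
        v_noise <- if (v_sdlog > 0) exp(rnorm(length(measured), 0, v_sdlog)) else
          rep(1, length(measured))
        viability <- setNames(1000 * kill[measured] * v_noise, measured)
      }
      plates[[length(plates) + 1L]] <-
        plate_read(pid, sprintf("R%d", r), "etoposide",
                   rlu = setNames(rlu, measured), viability = viability)
    }
  }
  annotation <- library_annotation(
    sirnas[, c("gene_id", "sirna_id", "plate_id", "well")])
  structure(list(plates = plates, layouts = layouts, annotation = annotation,
                 truth = list(genes = genes,
                              sirnas = sirnas[, c("sirna_id", "gene_id",
                                                  "efficacy")]),
                 config = config),
            class = "screen_sim")
}

#' @export
print.screen_sim <- function(x, ...) {
  cat(sprintf("screen_sim: %d genes x %d siRNAs on %d plates (%d plate reads), seed %d\n",
              x$config$n_genes, x$config$sirnas_per_gene, length(x$layouts),
              length(x$plates), x$config$seed))
  print(table(x$truth$genes$class))
  invisible(x)
}

#' Simulate the dual-stimulus counter screen
#'
#' Generates per-gene mean RLU for the etoposide and TNFa arms of a
#' counter screen over the queried genes, using the recorded ground
#' truth: gene-level knockdown is driven by the gene's best siRNA; all
#' activator knockdowns suppress the etoposide arm, but only shared
#' (non-selective) activators also suppress the TNFa arm. References are
#' generated from simulated control wells: the etoposide
#' treatment-control (full induction) and siTRAF6 under TNFa (induced
#' fraction `sitraf6_tnf_multiplier`).
#'
#' @param sim a `screen_sim` (or its `truth` element plus `config` given
#'   separately).
#' @param genes gene ids to assay; defaults to all genes.
#' @param config a [sim_config()]; defaults to `sim$config`.
#' @return a [counter_screen_input()] carrying the generated references;
#'   the ground truth is attached as attribute `truth`.
#' @export
simulate_counter_screen <- function(sim, genes = NULL, config = NULL) {
  truth <- if (inherits(sim, "screen_sim")) sim$truth else sim
  config <- if (is.null(config)) sim$config else config
  set.seed(config$seed + 1L)
  gt <- truth$genes
  if (is.null(genes)) genes <- gt$gene_id
  unknown <- setdiff(genes, gt$gene_id)
  if (length(unknown)) {
    screen_abort(sprintf("no ground truth for gene(s): %s",
                         paste(head(unknown, 5L), collapse = ", ")),
                 "rnaiscreen_alignment_error")
  }
  gt <- gt[match(genes, gt$gene_id), , drop = FALSE]
  eff <- vapply(split(truth$sirnas$efficacy, truth$sirnas$gene_id), max,
                numeric(1))[genes]
  kappa <- class_multiplier(gt$class, config)
  m_eto <- 1 - eff * (1 - kappa)
  ## selective activators leave the TNFa arm untouched
  kappa_tnf <- ifelse(gt$class == "activator" & gt$selective, 1, kappa)
  m_tnf <- 1 - eff * (1 - kappa_tnf)
  sdlog <- cv_to_sdlog(config$noise_cv)
  arm_mean <- function(m, fold) {
    det <- config$baseline_rlu * (1 + (fold - 1) * m)
    if (sdlog == 0) return(det)
    noise <- matrix(exp(rnorm(length(det) * config$counter_replicates, 0, sdlog)),
                    nrow = length(det))
    det * rowMeans(noise)
  }
  rlu_eto <- arm_mean(m_eto, config$induction_eto)
  rlu_tnf <- arm_mean(m_tnf, config$induction_tnf)
  theta_eto <- mean(arm_mean(rep(1, config$counter_replicates),
                             config$induction_eto))
  theta_tnf <- mean(arm_mean(rep(config$sitraf6_tnf_multiplier,
                                 config$counter_replicates),
                             config$induction_tnf))
  out <- counter_screen_input(
    data.frame(gene_id = genes, rlu_eto = rlu_eto, rlu_tnfa = rlu_tnf,
               stringsAsFactors = FALSE),
    theta_eto = theta_eto, theta_tnf = theta_tnf)
  attr(out, "truth") <- gt
  out
}

#' Recovery metrics of called hits against simulation ground truth
#'
#' Compares a flagged [select_hits()] table (activator or suppressor
#' direction) or a [classify_groups()] result (selective flags) with the
#' recorded ground truth and reports precision, recall and the rank of
#' every true hit. With no flagged genes, recall is 0 and precision is
#' undefined (reported as `NA` with TP = FP = 0).
#'
#' @param hits a `gene_scores` or `counter_result` object.
#' @param truth the `genes` ground-truth table of a `screen_sim` (or the
#'   `screen_sim` itself).
#' @param direction for `gene_scores`: `"activator"` or `"suppressor"`.
#' @return list with `precision`, `recall`, `tp`, `fp`, `fn` and `ranks`
#'   (data.frame of true hits and, where available, their ranks).
#' @export
evaluate_recovery <- function(hits, truth,
                              direction = c("activator", "suppressor")) {
  direction <- match.arg(direction)
  if (inherits(truth, "screen_sim")) truth <- truth$truth$genes
  if (inherits(hits, "counter_result")) {
    flagged <- hits$gene_id[!is.na(hits$selective) & hits$selective]
    true_set <- truth$gene_id[truth$class == "activator" & truth$selective]
    ranks <- data.frame(gene_id = true_set, rank = NA_integer_)
    universe <- hits$gene_id
  } else {
    flag_col <- paste0(direction, "_candidate")
    rank_col <- paste0(direction, "_rank")
    flagged <- hits$gene_id[hits[[flag_col]]]
    true_set <- truth$gene_id[truth$class == direction]
    ranks <- data.frame(gene_id = true_set,
                        rank = hits[[rank_col]][match(true_set, hits$gene_id)])
    universe <- hits$gene_id
  }
  miss <- setdiff(true_set, universe)
  if (length(miss) && length(miss) == length(true_set)) {
    screen_abort("no ground-truth gene appears in the hit table: id mismatch",
                 "rnaiscreen_alignment_error")
  }
  tp <- length(intersect(flagged, true_set))
  fp <- length(setdiff(flagged, true_set))
  fn <- length(setdiff(true_set, flagged))
  list(precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
       recall = if (tp + fn == 0L) NA_real_ else tp / (tp + fn),
       tp = tp, fp = fp, fn = fn, ranks = ranks)
}
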