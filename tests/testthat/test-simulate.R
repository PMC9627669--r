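test_that("simulation is deterministic given config and seed", {
  cfg <- sim_config(n_genes = 120, seed = 21)
  a <- simulate_primary_screen(cfg)
  b <- simulate_primary_screen(cfg)
  expect_identical(lapply(a$plates, `[[`, "rlu"),
                   lapply(b$plates, `[[`, "rlu"))
  expect_identical(a$truth, b$truth)
  c <- simulate_primary_screen(sim_config(n_genes = 120, seed = 22))
  expect_false(identical(a$plates[[1]]$rlu, c$plates[[1]]$rlu))
})

test_that("noise-free neutral screens follow the closed-form signal model", {
  cfg <- sim_config(n_genes = 117, prop_activator = 0, prop_suppressor = 0,
                    noise_cv = 0, plate_effect_sdlog = 0,
                    induction_eto = 10, baseline_rlu = 100, seed = 5)
  sim <- simulate_primary_screen(cfg)
  p <- sim$plates[[1]]
  lay <- sim$layouts[[p$plate_id]]
  sw <- names(lay$roles)[lay$roles == "SAMPLE"]
  # every sample well: plate_effect (=1) x baseline x induction
  expect_equal(unname(p$rlu[sw]), rep(1000, length(sw)))
  # vehicle column lacks induction
  vw <- names(lay$roles)[lay$roles == "VEHICLE_CTRL"]
  expect_equal(unname(p$rlu[vw]), rep(100, length(vw)))
  # nontargeting wells show the full induced signal
  nw <- names(lay$roles)[lay$roles == "NONTARGETING_CTRL"]
  expect_equal(unname(p$rlu[nw]), rep(1000, length(nw)))
  # pathway control behaves as strong activator knockdown
  pw <- names(lay$roles)[lay$roles == "PATHWAY_CTRL"]
  expect_equal(unname(p$rlu[pw]),
               rep(100 * (1 + 9 * cfg$pathway_ctrl_multiplier), length(pw)))
  # death-control wells are scaled by the kill fraction
  dw <- names(lay$roles)[lay$roles == "DEATH_CTRL"]
  expect_equal(unname(p$rlu[dw]),
               rep(1000 * cfg$death_kill_fraction, length(dw)))

  # with plate effects on, the within-plate signal is plate-constant scaled
  cfg2 <- sim_config(n_genes = 117, prop_activator = 0, prop_suppressor = 0,
                     noise_cv = 0, plate_effect_sdlog = 0.3, seed = 5)
  p2 <- simulate_primary_screen(cfg2)$plates[[1]]
  expect_equal(unname(p2$rlu[sw] / p2$rlu[sw][1]), rep(1, length(sw)))
})

test_that("library size maps to the expected plate count and layout", {
  sim <- simulate_primary_screen(sim_config(n_genes = 2000, seed = 2))
  expect_length(sim$layouts, ceiling(6000 / 352))   # 18 plates
  expect_equal(nrow(sim$annotation), 6000L)
  # trailing wells of the final plate are EMPTY, never silently scored
  last <- sim$layouts[[length(sim$layouts)]]
  expect_equal(sum(last$roles == "SAMPLE"), 6000L - 17L * 352L)
  expect_equal(sum(last$roles == "EMPTY"), 352L - (6000L - 17L * 352L))
  # gene classes drawn in exact proportions
  expect_equal(sum(sim$truth$genes$class == "activator"), 200L)
  expect_equal(sum(sim$truth$genes$class == "suppressor"), 100L)
})

test_that("viability channel is generated and usable for normalization", {
  cfg <- sim_config(n_genes = 117, simulate_viability = TRUE, seed = 8)
  sim <- simulate_primary_screen(cfg)
  p <- sim$plates[[1]]
  expect_false(is.null(p$viability))
  out <- viability_normalize(p)
  expect_true(all(out$rlu[!is.na(out$rlu)] > 0))
})

test_that("noise-free counter screen reflects the selectivity map", {
  cfg <- sim_config(n_genes = 60, p_effective = 1, noise_cv = 0,
                    prop_activator = 0.5, prop_selective = 0.5, seed = 31)
  sim <- simulate_primary_screen(cfg)
  inp <- simulate_counter_screen(sim)
  truth <- attr(inp, "truth")
  th_e <- attr(inp, "theta_eto")
  # selective activator: etoposide arm below reference, TNFa arm untouched
  sel <- truth$class == "activator" & truth$selective
  expect_true(all(inp$rlu_eto[sel] < th_e))
  expect_equal(inp$rlu_tnfa[sel],
               rep(cfg$baseline_rlu * cfg$induction_tnf, sum(sel)))
  # neutral genes sit exactly at the treatment reference: not group I
  neu <- truth$class == "neutral"
  expect_equal(inp$rlu_eto[neu], rep(th_e, sum(neu)))
  res <- classify_groups(inp)
  expect_false(any(res$group1[neu]))
  expect_error(simulate_counter_screen(sim, genes = "NOPE"),
               class = "rnaiscreen_alignment_error")
})

test_that("recovery metrics match their definitions and conventions", {
  truth <- data.frame(gene_id = sprintf("G%02d", 1:20),
                      class = rep(c("activator", "neutral"), c(5, 15)),
                      selective = FALSE)
  scr <- toy_screen(setNames(as.list(c(rnorm(5, -6, 0.1), rnorm(15, 0, 0.1))),
                             truth$gene_id))
  tab <- select_hits(aggregate_gene_scores(scr), 5, 0)
  perfect <- evaluate_recovery(tab, truth, "activator")
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_true(all(perfect$ranks$rank <= 5))

  none <- evaluate_recovery(select_hits(tab, 0, 0), truth, "activator")
  expect_equal(none$recall, 0)
  expect_true(is.na(none$precision))
  expect_equal(none$tp + none$fp, 0L)

  # random flags on a 50/50 truth give precision ~ 0.5 by Monte Carlo
  set.seed(17)
  truth2 <- data.frame(gene_id = sprintf("G%03d", 1:100),
                       class = rep(c("activator", "neutral"), 50),
                       selective = FALSE)
  prec <- replicate(200, {
    fake <- data.frame(gene_id = truth2$gene_id,
                       activator_candidate = FALSE,
                       activator_rank = seq_len(100))
    fake$activator_candidate[sample(100, 30)] <- TRUE
    evaluate_recovery(fake, truth2, "activator")$precision
  })
  expect_equal(mean(prec), 0.5, tolerance = 0.05)
})

test_that("optional column gradient tilts signal left to right", {
  base <- sim_config(n_genes = 117, prop_activator = 0, prop_suppressor = 0,
                     noise_cv = 0, plate_effect_sdlog = 0, seed = 4)
  flat <- simulate_primary_screen(base)$plates[[1]]
  tilted_cfg <- base; tilted_cfg$column_gradient <- 0.4
  tilted <- simulate_primary_screen(tilted_cfg)$plates[[1]]
  col <- as.integer(substr(names(tilted$rlu), 2, 3))
  sw <- !is.na(tilted$rlu) & col <= 22
  ratio <- tilted$rlu[sw] / flat$rlu[sw]
  expect_true(all(diff(tapply(ratio, col[sw], mean)) > 0))
  expect_equal(unname(flat$rlu[sw]), unname((tilted$rlu / (1 + 0.4 * (col - 12.5) / 23))[sw]))
})

test_that("null screens select genes without positional plate bias", {
  # all-neutral screens with plate effects on: which plate a gene sits on
  # must not influence its selection odds
  tally <- integer(0)
  expected <- integer(0)
  for (s in 1:50) {
    sim <- simulate_primary_screen(
      sim_config(n_genes = 468, prop_activator = 0, prop_suppressor = 0,
                 plate_effect_sdlog = 0.2, seed = 1000 + s))
    scr <- normalize_screen(sim$plates, sim$layouts, sim$annotation)
    tab <- select_hits(aggregate_gene_scores(scr), 50, 0)
    ann <- sim$annotation
    gene_plate <- tapply(ann$plate_id, ann$gene_id, `[`, 1L)
    sel_plates <- gene_plate[tab$gene_id[tab$activator_candidate]]
    tally <- c(tally, sel_plates)
    if (s == 1) expected <- table(gene_plate)
  }
  obs <- table(factor(tally, levels = names(expected)))
  p <- suppressWarnings(stats::chisq.test(obs, p = as.numeric(expected) /
                                            sum(expected))$p.value)
  expect_gt(p, 0.001)
})
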