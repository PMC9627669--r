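test_that("gene aggregation takes the signed extremum per direction", {
  scr <- toy_screen(list(GA = c(-3.2, -0.5, 0.4), GB = 1.7,
                         GC = c(0.1, 0.2, -0.1)))
  tab <- aggregate_gene_scores(scr)
  expect_equal(tab$best_activator_z[tab$gene_id == "GA"], -3.2)
  expect_equal(tab$best_suppressor_z[tab$gene_id == "GA"], 0.4)
  # singleton gene: both extrema are its only value
  expect_equal(tab$best_activator_z[tab$gene_id == "GB"], 1.7)
  expect_equal(tab$best_suppressor_z[tab$gene_id == "GB"], 1.7)
  expect_equal(tab$n_sirnas, c(3L, 1L, 3L))
})

test_that("aggregation agrees with an exhaustive scan on random screens", {
  set.seed(55)
  zs <- setNames(lapply(1:10, function(i) rnorm(3)), sprintf("G%02d", 1:10))
  tab <- aggregate_gene_scores(toy_screen(zs))
  expect_equal(nrow(tab), 10L)
  for (g in names(zs)) {
    lo <- hi <- zs[[g]][1]
    for (v in zs[[g]]) { if (v < lo) lo <- v; if (v > hi) hi <- v }
    expect_equal(tab$best_activator_z[tab$gene_id == g], lo)
    expect_equal(tab$best_suppressor_z[tab$gene_id == g], hi)
  }
})

test_that("second-best aggregation demands two supporting siRNAs", {
  scr <- toy_screen(list(GA = c(-5, -1, 0), GB = c(-4, 3, 2)))
  tab <- aggregate_gene_scores(scr, method = "second_best")
  expect_equal(tab$best_activator_z, c(-1, 2))
  expect_equal(tab$best_suppressor_z, c(-1, 2))
})

test_that("hit selection flags exact counts with a deterministic tie rule", {
  scr <- toy_screen(setNames(lapply(c(-5, -4, -3, -2, -1, 0, 1, 2, 3, 4),
                                    function(v) v),
                             sprintf("G%02d", 1:10)))
  tab <- select_hits(aggregate_gene_scores(scr), n_activators = 3,
                     n_suppressors = 2)
  expect_equal(sum(tab$activator_candidate), 3L)
  expect_equal(sort(tab$gene_id[tab$activator_candidate]),
               c("G01", "G02", "G03"))
  expect_equal(sum(tab$suppressor_candidate), 2L)
  expect_equal(sort(tab$gene_id[tab$suppressor_candidate]),
               c("G09", "G10"))

  # empty selection
  tab0 <- select_hits(aggregate_gene_scores(scr), 0, 0)
  expect_false(any(tab0$activator_candidate))

  # boundary tie: equal z resolves to the lexicographically smaller id
  scr2 <- toy_screen(list(GB = -2.0, GA = -2.0, GC = -5, GD = 1))
  tab2 <- select_hits(aggregate_gene_scores(scr2), 2, 0)
  expect_identical(sort(tab2$gene_id[tab2$activator_candidate]),
                   c("GA", "GC"))

  # oversized request bounds with a warning
  expect_warning(tab3 <- select_hits(aggregate_gene_scores(scr), 100, 100),
                 class = "rnaiscreen_selection_bounded_warning")
  expect_true(all(tab3$activator_candidate))
})

test_that("selection is invariant to input row order", {
  set.seed(77)
  zs <- setNames(lapply(1:50, function(i) rnorm(3)), sprintf("G%02d", 1:50))
  scr <- toy_screen(zs)
  tab1 <- select_hits(aggregate_gene_scores(scr), 10, 5)
  scr_shuf <- scr[sample(nrow(scr)), ]
  class(scr_shuf) <- class(scr)
  tab2 <- select_hits(aggregate_gene_scores(scr_shuf), 10, 5)
  expect_identical(tab1$gene_id, tab2$gene_id)
  expect_identical(tab1$activator_candidate, tab2$activator_candidate)
  expect_identical(tab1$suppressor_candidate, tab2$suppressor_candidate)
})

test_that("selected activators dominate unselected genes up to the tie rule", {
  set.seed(88)
  zs <- setNames(lapply(1:40, function(i) rnorm(3)), sprintf("G%02d", 1:40))
  tab <- select_hits(aggregate_gene_scores(toy_screen(zs)), 12, 0)
  sel_max <- max(tab$best_activator_z[tab$activator_candidate])
  unsel_min <- min(tab$best_activator_z[!tab$activator_candidate])
  expect_lte(sel_max, unsel_min)
})

test_that("category exclusion strips flags and records reasons", {
  scr <- toy_screen(list(GA = -4, GB = -3, GC = -2, GD = 5))
  tab <- select_hits(aggregate_gene_scores(scr), 2, 1)
  excl <- data.frame(gene_id = c("GA", "GZ"),
                     category = c("ribosome", "proteasome"))
  out <- apply_exclusion(tab, excl)
  expect_false(out$activator_candidate[out$gene_id == "GA"])
  expect_true(out$excluded[out$gene_id == "GA"])
  expect_identical(out$excluded_reason[out$gene_id == "GA"], "ribosome")
  # untouched genes keep their flags
  expect_true(out$activator_candidate[out$gene_id == "GB"])
  expect_identical(attr(out, "not_found"), "GZ")
  # empty exclusion is the identity
  expect_identical(apply_exclusion(tab, NULL), tab)

  # constructed 1100-candidate / 780-overlap refinement leaves 320
  set.seed(99)
  zsbig <- setNames(as.list(rnorm(3000)), sprintf("G%04d", 1:3000))
  big <- select_hits(aggregate_gene_scores(toy_screen(zsbig)), 1000, 100)
  cand <- big$gene_id[big$activator_candidate | big$suppressor_candidate]
  expect_equal(length(cand), 1100L)
  excl_big <- data.frame(gene_id = cand[seq_len(780)], category = "machinery")
  refined <- apply_exclusion(big, excl_big)
  expect_equal(sum(refined$activator_candidate | refined$suppressor_candidate),
               320L)
})

test_that("genes with no scored siRNA are listed unscored, not ranked", {
  scr <- toy_screen(list(GA = c(-1, 0), GB = 2))
  ann <- library_annotation(data.frame(
    gene_id = c("GA", "GA", "GB", "GC"),
    sirna_id = paste0("s", 1:4), plate_id = "P1",
    well = c("A01", "A02", "A03", "A04")))
  tab <- aggregate_gene_scores(scr, annotation = ann)
  expect_identical(attr(tab, "unscored"), "GC")
  expect_false("GC" %in% tab$gene_id)
})
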