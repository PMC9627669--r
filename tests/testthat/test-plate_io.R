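test_that("well addresses parse, canonicalize and round-trip", {
  p <- parse_well(c("A1", "B07", "b7", "P24"))
  expect_equal(p$well, c("A01", "B07", "B07", "P24"))
  expect_equal(p$row, c("A", "B", "B", "P"))
  expect_equal(p$column, c(1L, 7L, 7L, 24L))
  # parse(format(a)) = a over the whole plate
  all_wells <- plate_wells()
  expect_identical(canonical_well(all_wells), all_wells)
  expect_identical(format_well(well_row <- substr(all_wells, 1, 1),
                               as.integer(substr(all_wells, 2, 3))),
                   all_wells)
  expect_error(parse_well("Q1"), class = "rnaiscreen_address_error")
  expect_error(parse_well("A25"), class = "rnaiscreen_address_error")
  expect_error(parse_well("A0"), class = "rnaiscreen_address_error")
  expect_error(format_well("A", 25), class = "rnaiscreen_address_error")
})

test_that("plate-matrix files parse, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  m <- data.frame(row = LETTERS[1:16],
                  matrix(100.0, 16, 24), check.names = FALSE)
  names(m) <- c("row", as.character(1:24))
  write.csv(m, path, row.names = FALSE, quote = FALSE)
  p <- parse_plate_matrix(path, "P1", "R1", "etoposide")
  expect_equal(sum(!is.na(p$rlu)), 384L)
  expect_equal(unname(p$rlu[["A01"]]), 100.0)

  # round-trip cell-for-cell
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_plate_matrix(p, path2)
  p2 <- parse_plate_matrix(path2, "P1", "R1", "etoposide")
  expect_identical(p2$rlu, p$rlu)

  # dimension and value errors
  write.csv(m[1:15, ], path, row.names = FALSE, quote = FALSE)
  expect_error(parse_plate_matrix(path, "P1"), "expected 16 rows",
               class = "rnaiscreen_format_error")
  m2 <- m; m2[3, "7"] <- -5
  write.csv(m2, path, row.names = FALSE, quote = FALSE)
  expect_error(parse_plate_matrix(path, "P1"), "C07",
               class = "rnaiscreen_value_error")
})

test_that("long tables parse per plate/replicate/treatment and round-trip", {
  set.seed(42)
  plates <- list(random_plate(1, "P1"), random_plate(2, "P2"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_long_table(plates, path)
  got <- parse_long_table(path)
  expect_length(got, 2L)
  expect_true(all(vapply(got, function(p) sum(!is.na(p$rlu)), numeric(1)) == 384))
  key <- vapply(got, `[[`, character(1), "plate_id")
  expect_identical(got[[which(key == "P1")]]$rlu, plates[[1]]$rlu)

  # matrix -> long -> parse is the identity
  mpath <- withr::local_tempfile(fileext = ".csv")
  write_plate_matrix(plates[[1]], mpath)
  pm <- parse_plate_matrix(mpath, "P1", "R1", "etoposide")
  lpath <- withr::local_tempfile(fileext = ".csv")
  write_long_table(pm, lpath)
  expect_equal(parse_long_table(lpath)[[1]]$rlu, pm$rlu)

  df <- data.frame(plate_id = "P1", replicate_id = "R1",
                   treatment = "etoposide", well = c("A1", "A1"),
                   rlu = c(1, 2))
  write.csv(df, path, row.names = FALSE)
  expect_error(parse_long_table(path), class = "rnaiscreen_duplication_error")
  df$well <- c("Q1", "A2")
  write.csv(df, path, row.names = FALSE)
  expect_error(parse_long_table(path), class = "rnaiscreen_address_error")
})

test_that("layouts enforce coverage, uniqueness and role bookkeeping", {
  lay <- default_layout()
  counts <- table(lay$roles)
  expect_equal(unname(counts[["SAMPLE"]]), 352L)
  expect_equal(unname(counts[["VEHICLE_CTRL"]]), 16L)
  expect_equal(unname(counts[["NONTARGETING_CTRL"]]), 8L)
  expect_equal(unname(counts[["DEATH_CTRL"]]), 4L)
  expect_equal(unname(counts[["PATHWAY_CTRL"]]), 4L)
  expect_equal(sum(counts), 384L)
  # DMSO column is column 24 throughout
  expect_true(all(substr(layout_wells <- names(lay$roles)[lay$roles == "VEHICLE_CTRL"],
                         2, 3) == "24"))

  roles <- setNames(rep("SAMPLE", 384L), plate_wells())
  expect_error(plate_layout(roles[-1]), "A01",
               class = "rnaiscreen_layout_coverage_error")
  dup <- c(roles, setNames("PATHWAY_CTRL", "A01"))
  expect_error(plate_layout(dup), class = "rnaiscreen_layout_conflict_error")

  # library map must sit exactly on SAMPLE wells, one siRNA each
  lib <- data.frame(well = "A24", sirna_id = "s1", gene_id = "G1")
  expect_error(plate_layout(names_ok <- lay$roles, library = lib),
               class = "rnaiscreen_layout_error")
})

test_that("YAML layout configs load with conflicts and coverage checked", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "controls:",
    "  vehicle_ctrl:      {columns: [24]}",
    "  nontargeting_ctrl: {wells: [A23, B23, C23, D23, E23, F23, G23, H23]}",
    "  death_ctrl:        {wells: [I23, J23, K23, L23]}",
    "  pathway_ctrl:      {wells: [M23, N23, O23, P23]}"), path)
  lay <- load_layout(path)
  expect_s3_class(lay, "plate_layout")
  expect_equal(sum(lay$roles == "SAMPLE"), 352L)
  expect_identical(unname(lay$roles[["A24"]]), "VEHICLE_CTRL")

  writeLines(c(
    "controls:",
    "  vehicle_ctrl: {columns: [24]}",
    "  pathway_ctrl: {wells: [A24]}"), path)
  expect_error(load_layout(path), class = "rnaiscreen_layout_conflict_error")

  # explicit samples block turns on full-coverage checking
  writeLines(c(
    "controls:",
    "  vehicle_ctrl: {columns: [24]}",
    "samples:",
    "  columns: [1, 2, 3]"), path)
  expect_error(load_layout(path), class = "rnaiscreen_layout_coverage_error")
})

test_that("library annotation validates columns and siRNA uniqueness", {
  ann <- data.frame(gene_id = c("G1", "G1", "G2"),
                    sirna_id = c("s1", "s2", "s3"),
                    plate_id = "P1", well = c("A1", "A2", "A3"))
  out <- library_annotation(ann)
  expect_identical(out$well, c("A01", "A02", "A03"))
  ann$sirna_id <- c("s1", "s1", "s3")
  expect_error(library_annotation(ann), class = "rnaiscreen_annotation_error")
  expect_error(library_annotation(ann[, -1]),
               class = "rnaiscreen_annotation_error")
})
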