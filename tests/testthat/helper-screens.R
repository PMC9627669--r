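# Shared fixtures and independent oracles. The oracles deliberately avoid
# the code paths (and where possible the base helpers) they are used to
# check: medians are computed from explicit sort order, Spearman from the
# average-rank closed form plus the Pearson product-moment formula.

# sort-based order-statistic median
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}

oracle_mad <- function(x, constant = 1.4826) {
  constant * oracle_median(abs(x - oracle_median(x)))
}

oracle_zscores <- function(x, constant = 1.4826) {
  (x - oracle_median(x)) / oracle_mad(x, constant)
}

# average ranks via the counting formula, then Pearson by hand
oracle_rank <- function(v) {
  vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
}

oracle_spearman <- function(x, y) {
  rx <- oracle_rank(x); ry <- oracle_rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

oracle_z_factor <- function(pos, neg) {
  n1 <- length(pos); n2 <- length(neg)
  s1 <- sqrt(sum((pos - mean(pos))^2) / (n1 - 1))
  s2 <- sqrt(sum((neg - mean(neg))^2) / (n2 - 1))
  1 - 3 * (s1 + s2) / abs(mean(pos) - mean(neg))
}

# a layout whose only SAMPLE wells are the given ones (rest EMPTY)
tiny_layout <- function(sample_wells) {
  roles <- stats::setNames(rep("EMPTY", 384L), plate_wells())
  roles[canonical_well(sample_wells)] <- "SAMPLE"
  plate_layout(roles)
}

# a full random plate under the default layout
random_plate <- function(seed, plate_id = "P1", replicate_id = "R1",
                         meanlog = log(1000), sdlog = 0.4) {
  set.seed(seed)
  plate_read(plate_id, replicate_id, "etoposide",
             rlu = stats::setNames(stats::rlnorm(384, meanlog, sdlog),
                                   plate_wells()))
}

# screen table for hit-calling tests without running the simulator
toy_screen <- function(z_by_gene) {
  rows <- lapply(names(z_by_gene), function(g) {
    z <- z_by_gene[[g]]
    data.frame(gene_id = g, sirna_id = paste0(g, "_", seq_along(z)),
               plate_id = "P1", replicate_id = "R1",
               treatment = "etoposide",
               well = plate_wells()[seq_along(z)],
               rlu = NA_real_, z = z, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("normalized_screen", "data.frame"))
}
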