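#' @importFrom stats median sd cor runif rnorm setNames aggregate
#' @importFrom utils read.csv write.csv head
NULL

WELL_ROLES <- c("SAMPLE", "NONTARGETING_CTRL", "DEATH_CTRL",
                "PATHWAY_CTRL", "VEHICLE_CTRL", "EMPTY")

#' Construct a 384-well plate layout
#'
#' A layout maps every one of the 384 wells to exactly one role (sample or
#' one of the control classes) and, optionally, maps the sample wells to
#' the siRNA/gene library. Roles follow the arrayed-screen design: a
#' nontargeting siRNA control, a cell-death-inducing siRNA mixture, a
#' pathway-abolishing siRNA (siIKBKG) as positive knockdown control, and a
#' DMSO vehicle column left unstimulated.
#'
#' @param roles named character vector; names are well addresses (any
#'   accepted spelling), values one of `SAMPLE`, `NONTARGETING_CTRL`,
#'   `DEATH_CTRL`, `PATHWAY_CTRL`, `VEHICLE_CTRL`, `EMPTY`. All 384 wells
#'   must be covered exactly once.
#' @param library optional data.frame with columns `well`, `sirna_id`,
#'   `gene_id` defined exactly on the SAMPLE wells; no `sirna_id` may
#'   repeat within the plate.
#' @return an object of class `plate_layout`.
#' @seealso [default_layout()], [load_layout()]
#' @export
plate_layout <- function(roles, library = NULL) {
  wells <- canonical_well(names(roles))
  if (anyDuplicated(wells)) {
    dup <- unique(wells[duplicated(wells)])
    screen_abort(sprintf("well(s) assigned more than one role: %s",
                         paste(dup, collapse = ", ")),
                 "rnaiscreen_layout_conflict_error")
  }
  missing <- setdiff(plate_wells(), wells)
  if (length(missing)) {
    screen_abort(sprintf("layout does not cover well(s): %s",
                         paste(head(missing, 8L), collapse = ", ")),
                 "rnaiscreen_layout_coverage_error")
  }
  vals <- toupper(as.character(roles))
  if (!all(vals %in% WELL_ROLES)) {
    screen_abort(sprintf("unknown role(s): %s",
                         paste(unique(setdiff(vals, WELL_ROLES)), collapse = ", ")),
                 "rnaiscreen_layout_error")
  }
  role_map <- setNames(vals, wells)[plate_wells()]
  if (!is.null(library)) {
    need <- c("well", "sirna_id", "gene_id")
    if (!all(need %in% names(library))) {
      screen_abort("library map needs columns well, sirna_id, gene_id",
                   "rnaiscreen_layout_error")
    }
    library <- data.frame(well = canonical_well(library$well),
                          sirna_id = as.character(library$sirna_id),
                          gene_id = as.character(library$gene_id),
                          stringsAsFactors = FALSE)
    sample_wells <- names(role_map)[role_map == "SAMPLE"]
    extra <- setdiff(library$well, sample_wells)
    if (length(extra)) {
      screen_abort(sprintf("library map covers non-SAMPLE well(s): %s",
                           paste(head(extra, 8L), collapse = ", ")),
                   "rnaiscreen_layout_error")
    }
    uncov <- setdiff(sample_wells, library$well)
    if (length(uncov)) {
      screen_abort(sprintf("SAMPLE well(s) missing from library map: %s",
                           paste(head(uncov, 8L), collapse = ", ")),
                   "rnaiscreen_layout_coverage_error")
    }
    if (anyDuplicated(library$sirna_id)) {
      screen_abort("an sirna_id appears twice in one plate",
                   "rnaiscreen_layout_error")
    }
  }
  structure(list(roles = role_map, library = library), class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat("384-well plate layout\n")
  tab <- table(factor(x$roles, levels = WELL_ROLES))
  for (r in names(tab)) if (tab[[r]] > 0L) cat(sprintf("  %-18s %3d wells\n", r, tab[[r]]))
  if (!is.null(x$library)) {
    cat(sprintf("  library: %d siRNAs, %d genes\n",
                nrow(x$library), length(unique(x$library$gene_id))))
  }
  invisible(x)
}

layout_wells <- function(layout, role) {
  names(layout$roles)[layout$roles == role]
}

#' Default screening-plate layout template
#'
#' Emulates the screen's plate design: columns 1--22 carry one library
#' siRNA per well (352 sample wells), column 24 is the DMSO vehicle
#' column, and column 23 holds the transfection controls (8 nontargeting
#' wells in rows A--H, 4 cell-death wells in rows I--L, 4 siIKBKG pathway
#' wells in rows M--P).
#'
#' @param n_empty number of trailing sample wells (row-major from P22
#'   backwards) to mark EMPTY, for partially filled final plates.
#' @return a `plate_layout` without a library map.
#' @export
default_layout <- function(n_empty = 0L) {
  roles <- setNames(rep("SAMPLE", 384L), plate_wells())
  roles[sprintf("%s24", LETTERS[1:16])] <- "VEHICLE_CTRL"
  roles[sprintf("%s23", LETTERS[1:8])] <- "NONTARGETING_CTRL"
  roles[sprintf("%s23", LETTERS[9:12])] <- "DEATH_CTRL"
  roles[sprintf("%s23", LETTERS[13:16])] <- "PATHWAY_CTRL"
  if (n_empty > 0L) {
    sample_wells <- names(roles)[roles == "SAMPLE"]
    roles[utils::tail(sample_wells, n_empty)] <- "EMPTY"
  }
  plate_layout(roles)
}

#' Read a plate layout from a YAML configuration
#'
#' The configuration declares control blocks as well lists or whole
#' columns, plus (optionally) the library map, e.g.:
#' \preformatted{
#' controls:
#'   vehicle_ctrl:      {columns: [24]}
#'   nontargeting_ctrl: {wells: [A23, B23, C23, D23, E23, F23, G23, H23]}
#'   death_ctrl:        {wells: [I23, J23, K23, L23]}
#'   pathway_ctrl:      {wells: [M23, N23, O23, P23]}
#' empty: {wells: []}
#' library: {file: library.csv}   # columns well, sirna_id, gene_id
#' }
#' Wells not claimed by any block are SAMPLE wells. A well claimed by two
#' blocks is a conflict error.
#'
#' @param path path to the YAML file.
#' @return a `plate_layout`.
#' @export
load_layout <- function(path) {
  cfg <- yaml::read_yaml(path)
  roles <- setNames(rep("SAMPLE", 384L), plate_wells())
  claimed <- character(0)
  claim <- function(block, role) {
    wells <- character(0)
    if (!is.null(block$wells) && length(block$wells)) {
      wells <- canonical_well(unlist(block$wells))
    }
    if (!is.null(block$columns)) {
      for (cc in unlist(block$columns)) {
        wells <- c(wells, format_well(LETTERS[1:16], rep(as.integer(cc), 16L)))
      }
    }
    dup <- intersect(wells, claimed)
    if (length(dup)) {
      screen_abort(sprintf("well(s) assigned more than one role: %s",
                           paste(dup, collapse = ", ")),
                   "rnaiscreen_layout_conflict_error")
    }
    claimed <<- c(claimed, wells)
    roles[wells] <<- role
    invisible(NULL)
  }
  ctrl <- cfg$controls
  if (!is.null(ctrl)) {
    for (nm in names(ctrl)) {
      role <- toupper(nm)
      if (!role %in% WELL_ROLES) {
        screen_abort(sprintf("unknown control role in layout config: %s", nm),
                     "rnaiscreen_layout_error")
      }
      claim(ctrl[[nm]], role)
    }
  }
  if (!is.null(cfg$empty)) claim(cfg$empty, "EMPTY")
  ## An explicit samples block switches coverage checking on: every well
  ## must then be claimed by some block.
  if (!is.null(cfg$samples)) {
    claim(cfg$samples, "SAMPLE")
    missing <- setdiff(plate_wells(), claimed)
    if (length(missing)) {
      screen_abort(sprintf("layout does not cover well(s): %s",
                           paste(head(missing, 8L), collapse = ", ")),
                   "rnaiscreen_layout_coverage_error")
    }
  }
  lib <- NULL
  if (!is.null(cfg$library)) {
    if (!is.null(cfg$library$file)) {
      lib_path <- cfg$library$file
      if (!file.exists(lib_path)) {
        lib_path <- file.path(dirname(path), cfg$library$file)
      }
      lib <- read.csv(lib_path, stringsAsFactors = FALSE)
    } else if (!is.null(cfg$library$records)) {
      lib <- do.call(rbind, lapply(cfg$library$records, as.data.frame))
    }
  }
  plate_layout(roles, library = lib)
}
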