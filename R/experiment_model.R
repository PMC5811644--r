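#' Species pool of the default mesocosm design
#'
#' Four native submerged macrophytes in two functional groups plus the
#' introduced rooted invader. Rooted species draw nutrients mainly from the
#' sediment, non-rooted species from the water column.
#'
#' @return A data.frame with columns `code`, `name`, `functional_group`
#'   (`"rooted"` or `"non_rooted"`) and `native` (logical).
#' @export
species_table <- function() {
  data.frame(
    code = c("M", "P", "C", "U", "L"),
    name = c("Myriophyllum spicatum", "Potamogeton perfoliatus",
             "Ceratophyllum demersum", "Utricularia vulgaris",
             "Lagarosiphon major"),
    functional_group = c("rooted", "rooted", "non_rooted", "non_rooted",
                         "rooted"),
    native = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

NATIVE_CODES <- c("M", "P", "C", "U")
YIELD_COLS <- paste0("yield_", NATIVE_CODES)
TOTAL_SHOOTS <- 8L

#' Functional-group label of a species composition
#'
#' @param composition Character vector of native species codes (may be empty).
#' @param species Species table as returned by [species_table()].
#' @return `"bare"`, `"rooted"`, `"non_rooted"` or `"mixture"`.
#' @export
group_label <- function(composition, species = species_table()) {
  if (length(composition) == 0) return("bare")
  fg <- unique(species$functional_group[match(composition, species$code)])
  if (anyNA(fg)) stop("unknown species code in composition")
  if (length(fg) > 1) "mixture" else fg
}

#' Build the default 12-treatment x 6-block experimental design
#'
#' The layout of the substitutive mesocosm experiment: one bare-sediment
#' control, four monocultures, one rooted pair (M+P), one non-rooted pair
#' (C+U), the four rooted/non-rooted two-species mixtures, and the
#' four-species mixture; each replicated in 6 blocks (72 units). Planting
#' density is constant at 8 shoots per mesocosm, divided equally among the
#' composition members.
#'
#' @param blocks Number of blocks (default 6).
#' @return An object of class `experiment_design`: a list with `species`
#'   (data.frame), `treatments` (data.frame with `id`, `composition` as a
#'   list-column, `richness`, `group_label`, `shoots_per_species`) and
#'   `blocks`.
#' @export
build_default_design <- function(blocks = 6L) {
  comps <- list(
    character(0),
    "M", "P", "C", "U",
    c("M", "P"), c("C", "U"),
    c("M", "C"), c("M", "U"), c("P", "C"), c("P", "U"),
    c("M", "P", "C", "U")
  )
  sp <- species_table()
  tr <- data.frame(
    id = seq_along(comps),
    richness = vapply(comps, length, integer(1))
  )
  tr$composition <- comps
  tr$group_label <- vapply(comps, group_label, character(1), species = sp)
  tr$shoots_per_species <- ifelse(tr$richness > 0,
                                  TOTAL_SHOOTS %/% pmax(tr$richness, 1L), 0L)
  design <- list(species = sp, treatments = tr, blocks = as.integer(blocks))
  class(design) <- "experiment_design"
  design
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("Experiment design: %d treatments x %d blocks = %d units\n",
              nrow(x$treatments), x$blocks, nrow(x$treatments) * x$blocks))
  comp <- vapply(x$treatments$composition, function(cc)
    if (length(cc)) paste(cc, collapse = "+") else "bare", character(1))
  print(data.frame(id = x$treatments$id, composition = comp,
                   group = x$treatments$group_label,
                   richness = x$treatments$richness))
  invisible(x)
}

design_composition <- function(design, treatment_id) {
  i <- match(treatment_id, design$treatments$id)
  if (is.na(i)) stop("unknown treatment id: ", treatment_id)
  design$treatments$composition[[i]]
}

#' Validate a table of mesocosm records
#'
#' Checks the structural invariants of the tidy data model against a design:
#' known treatment ids and blocks, per-species yields present exactly for the
#' treatment's composition, non-negative masses, positive initial mass and
#' duration, and logical colonization indicator.
#'
#' @param records Data.frame as returned by [read_mesocosm_csv()] or
#'   [simulate_experiment()].
#' @param design An `experiment_design` (default [build_default_design()]).
#' @return A data.frame with columns `row`, `field`, `message`; zero rows iff
#'   the table is valid. Attribute `n_checked` holds the record count.
#' @export
validate_table <- function(records, design = build_default_design()) {
  viol <- list()
  add <- function(row, field, message) {
    viol[[length(viol) + 1L]] <<- data.frame(row = row, field = field,
                                             message = message,
                                             stringsAsFactors = FALSE)
  }
  req <- c("block", "treatment_id", YIELD_COLS, "invader_root",
           "invader_shoot", "colonized", "invader_initial", "duration_days")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (r in seq_len(nrow(records))) {
    rec <- records[r, ]
    if (!rec$block %in% seq_len(design$blocks))
      add(r, "block", sprintf("block %s outside 1..%d", rec$block,
                              design$blocks))
    if (!rec$treatment_id %in% design$treatments$id) {
      add(r, "treatment_id", sprintf("unknown treatment id %s",
                                     rec$treatment_id))
      next
    }
    comp <- design_composition(design, rec$treatment_id)
    for (sp in NATIVE_CODES) {
      y <- rec[[paste0("yield_", sp)]]
      if (sp %in% comp) {
        if (is.na(y))
          add(r, paste0("yield_", sp),
              sprintf("species %s in treatment but yield missing", sp))
        else if (y < 0)
          add(r, paste0("yield_", sp), "negative biomass")
      } else if (!is.na(y)) {
        add(r, paste0("yield_", sp),
            sprintf("yield for species %s not in treatment composition", sp))
      }
    }
    for (f in c("invader_root", "invader_shoot", "invader_initial")) {
      if (is.na(rec[[f]]) || rec[[f]] < 0) add(r, f, "negative or missing mass")
    }
    if (!is.na(rec$invader_initial) && rec$invader_initial == 0)
      add(r, "invader_initial", "initial fragment mass must be positive")
    if (is.na(rec$duration_days) || rec$duration_days < 1)
      add(r, "duration_days", "duration must be a positive number of days")
    if (!is.logical(rec$colonized) || is.na(rec$colonized))
      add(r, "colonized", "colonized must be TRUE/FALSE")
  }
  out <- if (length(viol)) do.call(rbind, viol) else
    data.frame(row = integer(0), field = character(0),
               message = character(0), stringsAsFactors = FALSE)
  attr(out, "n_checked") <- nrow(records)
  out
}

#' Read a mesocosm table from CSV
#'
#' Long format, one row per mesocosm, wide per-species yield columns
#' `yield_M`, `yield_P`, `yield_C`, `yield_U` (empty cells for species absent
#' from the treatment). All masses in grams dry weight.
#'
#' @param path Path to a CSV file with a header row.
#' @return Data.frame of mesocosm records.
#' @export
read_mesocosm_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("parse error reading ", path, ": ",
                             conditionMessage(e))
  )
  req <- c("block", "treatment_id", YIELD_COLS, "invader_root",
           "invader_shoot", "colonized", "invader_initial", "duration_days")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("schema error in ", path, ": missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (cc in c("block", "treatment_id", "duration_days"))
    df[[cc]] <- as.integer(df[[cc]])
  for (cc in c(YIELD_COLS, "invader_root", "invader_shoot", "invader_initial"))
    df[[cc]] <- as.numeric(df[[cc]])
  df$colonized <- as.logical(df$colonized)
  df[, req]
}

#' Write a mesocosm table to CSV
#'
#' @param records Data.frame of mesocosm records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @rdname read_mesocosm_csv
#' @export
write_mesocosm_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Long per-species export of native yields (for plotting)
#'
#' @param records Mesocosm records.
#' @return Data.frame with `block`, `treatment_id`, `species`, `yield_g`;
#'   one row per present species per mesocosm.
#' @export
native_yields_long <- function(records) {
  out <- do.call(rbind, lapply(NATIVE_CODES, function(sp) {
    y <- records[[paste0("yield_", sp)]]
    keep <- !is.na(y)
    data.frame(block = records$block[keep],
               treatment_id = records$treatment_id[keep],
               species = sp, yield_g = y[keep], stringsAsFactors = FALSE)
  }))
  out[order(out$block, out$treatment_id, out$species), , drop = FALSE]
}

#' Total native biomass per mesocosm (g DW)
#'
#' @param records Mesocosm records.
#' @return Numeric vector, zero for bare-sediment units.
#' @export
total_native_biomass <- function(records) {
  m <- as.matrix(records[, YIELD_COLS])
  rowSums(m, na.rm = TRUE)
}

#' Serialize / read an experiment design as YAML
#'
#' @param design An `experiment_design`.
#' @param path File path.
#' @return `design_to_yaml()` returns `path` invisibly;
#'   `design_from_yaml()` returns an `experiment_design`.
#' @export
design_to_yaml <- function(design, path) {
  obj <- list(
    blocks = design$blocks,
    species = lapply(seq_len(nrow(design$species)), function(i)
      as.list(design$species[i, ])),
    treatments = lapply(seq_len(nrow(design$treatments)), function(i) {
      tr <- design$treatments[i, ]
      list(id = tr$id, composition = as.list(tr$composition[[1]]),
           richness = tr$richness, group_label = tr$group_label,
           shoots_per_species = tr$shoots_per_species)
    })
  )
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname design_to_yaml
#' @export
design_from_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  sp <- do.call(rbind, lapply(obj$species, function(s)
    data.frame(s, stringsAsFactors = FALSE)))
  tr <- data.frame(
    id = vapply(obj$treatments, function(t) as.integer(t$id), integer(1)),
    richness = vapply(obj$treatments, function(t) as.integer(t$richness),
                      integer(1))
  )
  tr$composition <- lapply(obj$treatments, function(t)
    as.character(unlist(t$composition)))
  tr$group_label <- vapply(obj$treatments, function(t) t$group_label,
                           character(1))
  tr$shoots_per_species <- vapply(obj$treatments, function(t)
    as.integer(t$shoots_per_species), integer(1))
  design <- list(species = sp, treatments = tr,
                 blocks = as.integer(obj$blocks))
  class(design) <- "experiment_design"
  design
}
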