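# Closed set of macro-categories used by the region ontology.
REGION_CATEGORIES <- c(
  "Isocortex", "Olfactory areas", "Hippocampal formation",
  "Claustrum + amygdala", "Striatum + pallidum", "Thalamus",
  "Hypothalamus", "Midbrain + pons", "Medulla", "Cerebellum", "Fiber tracts"
)

COHORT_STAGES <- c("raw", "thresholded", "volume_normalized", "unit_mean")

#' Construct a cohort table
#'
#' A cohort table bundles an animals-by-regions projection-fraction matrix
#' with per-animal metadata, the region ontology, and a processing-stage tag.
#' The projection fraction of a region is the fraction of its voxels carrying
#' detected axonal signal, so raw values live in \code{[0, 1]}; after
#' injection-volume normalization values may exceed 1, and after unit-mean
#' normalization every region column averages exactly 1 across animals.
#'
#' @param values numeric matrix, animals in rows, regions in columns. Row
#'   names must be animal ids and column names region abbreviations.
#' @param animals data frame with columns \code{animal_id}, \code{condition}
#'   (+1 control, -1 sleep-restricted), \code{sex} ("M"/"F"),
#'   \code{injection_volume} (> 0, in \code{volume_unit}), and injection
#'   centroid distances \code{ml_um} (from midline), \code{ap_um} (from the
#'   anterior commissure), \code{dv_um} (from the pia), all in micrometres.
#' @param regions data frame with columns \code{region_id},
#'   \code{abbreviation}, \code{name}, \code{category}; one row per column
#'   of \code{values}, in column order.
#' @param hemisphere "ipsilateral" or "contralateral".
#' @param stage processing stage tag, one of \code{"raw"},
#'   \code{"thresholded"}, \code{"volume_normalized"}, \code{"unit_mean"}.
#' @param volume_unit free-text unit of \code{injection_volume}, carried
#'   through unchanged.
#' @return an object of class \code{cohort_table}.
#' @export
cohort_table <- function(values, animals, regions,
                         hemisphere = c("ipsilateral", "contralateral"),
                         stage = "raw", volume_unit = "arbitrary") {
  hemisphere <- match.arg(hemisphere)
  stopifnot(is.matrix(values), is.numeric(values))
  storage.mode(values) <- "double"
  animals <- as.data.frame(animals, stringsAsFactors = FALSE)
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  obj <- structure(
    list(values = values, animals = animals, regions = regions,
         hemisphere = hemisphere, stage = stage,
         volume_unit = as.character(volume_unit)),
    class = "cohort_table")
  validate_cohort(obj)
  obj
}

#' Validate a cohort table
#'
#' Checks all structural invariants: shape consistency, unique ids, the
#' closed category set, condition coding, positive injection volumes,
#' non-negative centroid distances, value-range rules per stage, and the
#' unit-mean property at stage \code{"unit_mean"}.
#'
#' @param cohort a \code{cohort_table}.
#' @return the cohort, invisibly; errors describe the offending entry.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  v <- cohort$values
  an <- cohort$animals
  rg <- cohort$regions

  need_an <- c("animal_id", "condition", "sex", "injection_volume",
               "ml_um", "ap_um", "dv_um")
  miss <- setdiff(need_an, names(an))
  if (length(miss) > 0L)
    stop("animal metadata lacks column(s): ", paste(miss, collapse = ", "))
  need_rg <- c("region_id", "abbreviation", "name", "category")
  miss <- setdiff(need_rg, names(rg))
  if (length(miss) > 0L)
    stop("region ontology lacks column(s): ", paste(miss, collapse = ", "))

  if (nrow(v) != nrow(an))
    stop("value matrix has ", nrow(v), " rows but metadata describes ",
         nrow(an), " animals")
  if (ncol(v) != nrow(rg))
    stop("value matrix has ", ncol(v), " columns but ontology describes ",
         nrow(rg), " regions")
  if (anyDuplicated(an$animal_id))
    stop("duplicate animal_id: ",
         paste(unique(an$animal_id[duplicated(an$animal_id)]), collapse = ", "))
  if (anyDuplicated(rg$abbreviation))
    stop("duplicate region abbreviation: ",
         paste(unique(rg$abbreviation[duplicated(rg$abbreviation)]), collapse = ", "))
  if (anyDuplicated(rg$region_id))
    stop("duplicate region_id: ",
         paste(unique(rg$region_id[duplicated(rg$region_id)]), collapse = ", "))
  if (nrow(v) > 0L && !identical(rownames(v), as.character(an$animal_id)))
    stop("row names of the value matrix must equal animals$animal_id, in order")
  if (ncol(v) > 0L && !identical(colnames(v), as.character(rg$abbreviation)))
    stop("column names of the value matrix must equal regions$abbreviation, in order")

  bad_cat <- setdiff(unique(rg$category), REGION_CATEGORIES)
  if (length(bad_cat) > 0L)
    stop("unknown region category: ", paste(bad_cat, collapse = ", "))
  if (nrow(rg) > 0L && any(rg$region_id <= 0))
    stop("region_id must be a positive integer; offending: ",
         paste(rg$abbreviation[rg$region_id <= 0], collapse = ", "))

  if (!all(an$condition %in% c(-1, 1)))
    stop("condition must be coded +1 (control) or -1 (CSR); offending animal: ",
         paste(an$animal_id[!an$condition %in% c(-1, 1)], collapse = ", "))
  if (!all(an$sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'; offending animal: ",
         paste(an$animal_id[!an$sex %in% c("M", "F")], collapse = ", "))
  if (any(!is.finite(an$injection_volume)) || any(an$injection_volume <= 0))
    stop("injection_volume must be positive; offending animal: ",
         paste(an$animal_id[!(is.finite(an$injection_volume) & an$injection_volume > 0)],
               collapse = ", "))
  for (col in c("ml_um", "ap_um", "dv_um")) {
    if (any(!is.finite(an[[col]])) || any(an[[col]] < 0))
      stop(col, " must be a non-negative distance in µm; offending animal: ",
           paste(an$animal_id[!(is.finite(an[[col]]) & an[[col]] >= 0)], collapse = ", "))
  }

  if (!cohort$stage %in% COHORT_STAGES)
    stop("unknown stage '", cohort$stage, "'")
  if (anyNA(v))
    stop("missing values are not supported; first NA at ", first_bad_cell(v, is.na(v)))
  if (any(v < 0))
    stop("negative projection fraction at ", first_bad_cell(v, v < 0))
  if (cohort$stage == "raw" && any(v > 1))
    stop("projection fraction > 1 at stage=raw: ", first_bad_cell(v, v > 1))
  if (cohort$stage == "unit_mean" && nrow(v) > 0L) {
    cm <- colMeans(v)
    off <- which(abs(cm - 1) > 1e-12)
    if (length(off) > 0L)
      stop("stage=unit_mean but column mean != 1 for region ",
           paste(colnames(v)[off[seq_len(min(3, length(off)))]], collapse = ", "))
  }
  invisible(cohort)
}

first_bad_cell <- function(v, mask) {
  idx <- which(mask, arr.ind = TRUE)[1L, , drop = TRUE]
  paste0("animal '", rownames(v)[idx[1L]], "', region '",
         colnames(v)[idx[2L]], "' (value ", format(v[idx[1L], idx[2L]]), ")")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d animals x %d regions, %s hemisphere, stage=%s\n",
              nrow(x$values), ncol(x$values), x$hemisphere, x$stage))
  if (nrow(x$animals) > 0L) {
    cat(sprintf("  conditions: %d control / %d CSR; sexes: %d M / %d F\n",
                sum(x$animals$condition == 1), sum(x$animals$condition == -1),
                sum(x$animals$sex == "M"), sum(x$animals$sex == "F")))
  }
  invisible(x)
}

require_stage <- function(cohort, stage) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!identical(cohort$stage, stage))
    stop("expected a cohort at stage '", stage, "' but got stage '",
         cohort$stage, "' (the canonical chain is raw -> thresholded -> ",
         "volume_normalized -> unit_mean)")
  invisible(cohort)
}

#' Load a cohort from its three on-disk files
#'
#' Reads the comma-separated values table (animals x regions, header row of
#' region abbreviations, first column of animal ids), the JSON metadata
#' document, and the region-ontology CSV, and assembles a validated
#' \code{cohort_table}. Row and column order follow the files.
#'
#' @param values_path CSV of projection fractions.
#' @param metadata_path JSON object with fields \code{stage},
#'   \code{hemisphere}, \code{volume_unit} and an \code{animals} array of
#'   animal records.
#' @param ontology_path CSV with columns \code{region_id},
#'   \code{abbreviation}, \code{name}, \code{category}.
#' @return a \code{cohort_table}.
#' @export
load_cohort <- function(values_path, metadata_path, ontology_path) {
  raw <- utils::read.csv(values_path, check.names = FALSE,
                         colClasses = "character")
  if (ncol(raw) < 1L) stop("values file has no columns: ", values_path)
  ids <- raw[[1L]]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids

  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  if (is.null(meta$animals))
    stop("metadata file lacks an 'animals' array: ", metadata_path)
  an <- as.data.frame(meta$animals, stringsAsFactors = FALSE)

  rg <- utils::read.csv(ontology_path, check.names = FALSE,
                        stringsAsFactors = FALSE)

  missing_meta <- setdiff(rownames(vals), an$animal_id)
  if (length(missing_meta) > 0L)
    stop("animal(s) in values file missing from metadata: ",
         paste(missing_meta, collapse = ", "))
  an <- an[match(rownames(vals), an$animal_id), , drop = FALSE]
  rownames(an) <- NULL

  missing_ont <- setdiff(colnames(vals), rg$abbreviation)
  if (length(missing_ont) > 0L)
    stop("region column(s) absent from ontology: ",
         paste(missing_ont, collapse = ", "))
  rg <- rg[match(colnames(vals), rg$abbreviation), , drop = FALSE]
  rownames(rg) <- NULL

  cohort_table(vals, an, rg,
               hemisphere = meta$hemisphere %||% "ipsilateral",
               stage = meta$stage %||% "raw",
               volume_unit = meta$volume_unit %||% "arbitrary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort to disk
#'
#' Emits three files readable by \code{\link{load_cohort}}:
#' \code{<prefix>_values.csv}, \code{<prefix>_metadata.json},
#' \code{<prefix>_ontology.csv}. Numeric values are written with 17
#' significant digits so the round trip is value-exact; repeated writes of
#' the same cohort are byte-identical.
#'
#' @param cohort a valid \code{cohort_table}.
#' @param out_prefix path prefix for the three files.
#' @return invisibly, the character vector of paths written.
#' @export
write_cohort <- function(cohort, out_prefix) {
  validate_cohort(cohort)
  paths <- paste0(out_prefix, c("_values.csv", "_metadata.json", "_ontology.csv"))

  v <- cohort$values
  con <- file(paths[1L], open = "wb")
  on.exit(close(con), add = TRUE)
  header <- paste(c("animal_id", colnames(v)), collapse = ",")
  rows <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], formatC(v[i, ], digits = 17, format = "g")),
          collapse = ",")
  }, character(1L))
  writeLines(c(header, rows), con = con, sep = "\n")

  meta <- list(stage = cohort$stage, hemisphere = cohort$hemisphere,
               volume_unit = cohort$volume_unit, animals = cohort$animals)
  jsonlite::write_json(meta, paths[2L], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)

  ont <- cohort$regions[, c("region_id", "abbreviation", "name", "category")]
  con2 <- file(paths[3L], open = "wb")
  on.exit(close(con2), add = TRUE)
  esc <- function(x) {
    x <- as.character(x)
    needs <- grepl('[",\n]', x)
    x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
    x
  }
  lines <- c(paste(names(ont), collapse = ","),
             vapply(seq_len(nrow(ont)), function(i)
               paste(esc(unlist(ont[i, ], use.names = FALSE)), collapse = ","),
               character(1L)))
  writeLines(lines, con = con2, sep = "\n")

  invisible(paths)
}

#' Restrict a cohort to animals matching a predicate
#'
#' Used e.g. for the sex-stratified reanalysis: the same pipeline is run on
#' males and females separately. Retained rows are copied bitwise; regions
#' and the stage tag are unchanged.
#'
#' @param cohort a \code{cohort_table}.
#' @param animal_filter a function taking one row of the animal metadata (a
#'   one-row data frame) and returning \code{TRUE} to keep the animal.
#' @return the filtered \code{cohort_table}.
#' @export
subset_cohort <- function(cohort, animal_filter) {
  validate_cohort(cohort)
  stopifnot(is.function(animal_filter))
  keep <- vapply(seq_len(nrow(cohort$animals)), function(i) {
    res <- animal_filter(cohort$animals[i, , drop = FALSE])
    if (!is.logical(res) || length(res) != 1L || is.na(res))
      stop("animal_filter must return a single TRUE/FALSE for animal '",
           cohort$animals$animal_id[i], "'")
    res
  }, logical(1L))
  if (!any(keep))
    stop("animal_filter matched no animals; downstream fits are undefined ",
         "on an empty cohort")
  out <- cohort
  out$values <- cohort$values[keep, , drop = FALSE]
  out$animals <- cohort$animals[keep, , drop = FALSE]
  rownames(out$animals) <- NULL
  validate_cohort(out)
  out
}
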