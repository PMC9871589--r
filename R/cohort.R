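#' Subject cohorts
#'
#' A cohort is a tibble with one row per subject: identifiers, diagnosis
#' (`EP` = positive class, `HC`), gender, ethnicity, age, the six MCCB-like
#' cognition scores (`psp`, `vig`, `wme`, `vel`, `vil`, `pso`; `NA` marks a
#' missing assessment), and a `volume` list-column of two-channel input
#' arrays (see [stack_channels()]).
#'
#' @param data a data frame with the columns above.
#' @param provenance free-text note on where the cohort came from.
#' @return a tibble of class `epcog_cohort`.
#' @export
cohort <- function(data, provenance = "unspecified") {
  data <- as_tibble(data)
  required <- c("subject_id", "diagnosis", "gender", COG_DIMS)
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("cohort is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "epcog_schema_error")
  }
  if (anyDuplicated(data$subject_id)) {
    abort("subject_id values must be unique", class = "epcog_schema_error")
  }
  data$subject_id <- as.character(data$subject_id)
  data$diagnosis <- factor(as.character(data$diagnosis), levels = c("HC", "EP"))
  if (anyNA(data$diagnosis)) {
    abort("diagnosis must be 'EP' or 'HC' for every subject",
          class = "epcog_schema_error")
  }
  g <- as.character(data$gender)
  g[g == "M"] <- "male"
  g[g == "F"] <- "female"
  data$gender <- factor(g, levels = c("male", "female"))
  if (anyNA(data$gender)) {
    abort("gender must be 'male'/'female' (or 'M'/'F')",
          class = "epcog_schema_error")
  }
  if (!"ethnicity" %in% names(data)) data$ethnicity <- NA_character_
  if (!"age" %in% names(data)) data$age <- NA_real_
  for (d in COG_DIMS) data[[d]] <- as.numeric(data[[d]])
  structure(data, class = c("epcog_cohort", class(tibble())),
            provenance = provenance)
}

#' Score matrix of a cohort
#'
#' @param x an `epcog_cohort`.
#' @return numeric matrix subjects x 6 (rownames = subject ids, `NA` =
#'   missing), columns in the canonical dimension order.
#' @export
score_table <- function(x) {
  m <- as.matrix(as.data.frame(x)[, COG_DIMS])
  rownames(m) <- x$subject_id
  m
}

#' Load a cohort from a metadata CSV plus a directory of volumes
#'
#' The CSV must contain columns `subject_id`, `diagnosis` (`EP`/`HC`),
#' `gender` (`M`/`F`), and the six score columns (blank = missing);
#' `ethnicity` and `age` are optional. Volumes are searched as
#' `<subject_id>_gm.nii(.gz)` and `<subject_id>_wm.nii(.gz)`; a subject
#' with only one tissue has that map replicated into both channels, and
#' subjects with neither are reported together in a single error.
#'
#' Missing cognition cells are flagged (`NA`), never imputed here:
#' imputation is a modelling step fitted on a training split (see
#' [impute_missing()]).
#'
#' @param metadata_csv path to the metadata table.
#' @param volume_dir directory holding per-subject NIfTI files.
#' @return an [cohort()] with populated `volume` column.
#' @export
load_cohort <- function(metadata_csv, volume_dir) {
  if (!file.exists(metadata_csv)) {
    abort(sprintf("metadata file not found: %s", metadata_csv),
          class = "epcog_io_error")
  }
  meta <- utils::read.csv(metadata_csv, stringsAsFactors = FALSE)
  required <- c("subject_id", "diagnosis", "gender", COG_DIMS)
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    abort(sprintf("metadata is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "epcog_schema_error")
  }
  find_vol <- function(id, tissue) {
    for (ext in c(".nii.gz", ".nii")) {
      p <- file.path(volume_dir, paste0(id, "_", tolower(tissue), ext))
      if (file.exists(p)) return(p)
    }
    NULL
  }
  vols <- vector("list", nrow(meta))
  orphans <- character()
  for (i in seq_len(nrow(meta))) {
    id <- meta$subject_id[i]
    gm_path <- find_vol(id, "GM")
    wm_path <- find_vol(id, "WM")
    if (is.null(gm_path) && is.null(wm_path)) {
      orphans <- c(orphans, id)
      next
    }
    gm <- if (!is.null(gm_path)) load_probability_map(gm_path, "GM")
    wm <- if (!is.null(wm_path)) load_probability_map(wm_path, "WM")
    vols[[i]] <- stack_channels(gm, wm)
  }
  if (length(orphans) > 0) {
    abort(sprintf("no volume file found for subject(s): %s",
                  paste(orphans, collapse = ", ")),
          class = "epcog_io_error")
  }
  meta$volume <- vols
  cohort(meta, provenance = sprintf("loaded from %s", metadata_csv))
}

#' Write a cohort to the standard on-disk layout
#'
#' Inverse of [load_cohort()]: a metadata CSV plus per-subject
#' `<id>_gm.nii.gz` / `<id>_wm.nii.gz` files.
#'
#' @param x an `epcog_cohort` with volumes.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- as.data.frame(x)[, c("subject_id", "diagnosis", "gender",
                               "ethnicity", "age", COG_DIMS)]
  meta$gender <- ifelse(meta$gender == "male", "M", "F")
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE,
                   na = "")
  for (i in seq_len(nrow(x))) {
    v <- x$volume[[i]]
    if (is.null(v)) next
    id <- x$subject_id[i]
    write_probability_map(v[, , , 1L], file.path(dir, paste0(id, "_gm.nii.gz")),
                          affine = attr(v, "affine"))
    write_probability_map(v[, , , 2L], file.path(dir, paste0(id, "_wm.nii.gz")),
                          affine = attr(v, "affine"))
  }
  invisible(dir)
}
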