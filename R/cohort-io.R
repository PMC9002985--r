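#' Column-name schema for cohort files
#'
#' Maps the canonical variable names used throughout the package to the column
#' names found in a delimited file. Override entries to read files with other
#' headers; the mapping can also be loaded from a YAML/JSON file via
#' [read_cohort()]'s `schema` argument.
#'
#' @param ... named overrides, e.g. `height_cm = "height"`.
#' @return named character vector (canonical name -> file column name).
#' @export
cohort_schema <- function(...) {
  schema <- setNames(COHORT_COLUMNS, COHORT_COLUMNS)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), COHORT_COLUMNS)
    if (length(bad)) abort(paste0("unknown schema entries: ", toString(bad)))
    schema[names(dots)] <- unlist(dots)
  }
  schema
}

mandatory_cols <- function() {
  setdiff(COHORT_COLUMNS, c("fev1_post_ml", "fvc_post_ml"))
}

#' Validate and type a cohort table
#'
#' Applies the record-level plausibility rules: age >= 18, height in
#' (120, 230) cm, FEV1 and FVC in (500, 9000) mL, post-bronchodilator values
#' present either both or neither, complete exposure/mediator/covariate
#' information, unique offspring ids, and a single line per parent. Rows
#' failing completeness or plausibility are dropped with one logged count per
#' reason; structural violations (duplicate ids, parent in two lines) are
#' errors.
#'
#' @param data data frame with canonical cohort columns.
#' @return validated tibble (class `cohort_tbl`) in canonical column order.
#' @export
validate_cohort <- function(data) {
  data <- as_tibble(data)
  missing_cols <- setdiff(mandatory_cols(), names(data))
  if (length(missing_cols))
    abort(paste0("missing mandatory columns: ", toString(missing_cols)))
  for (col in c("fev1_post_ml", "fvc_post_ml"))
    if (!col %in% names(data)) data[[col]] <- NA_real_

  data <- data |>
    mutate(
      offspring_id = as.character(.data$offspring_id),
      parent_id = as.character(.data$parent_id),
      line = as.character(.data$line),
      sex = as.character(.data$sex),
      age = as.numeric(.data$age),
      ever_smoker = as_flag(.data$ever_smoker),
      m1_overweight_prepuberty = as_flag(.data$m1_overweight_prepuberty),
      height_cm = as.numeric(.data$height_cm),
      fev1_ml = as.numeric(.data$fev1_ml),
      fvc_ml = as.numeric(.data$fvc_ml),
      fev1_post_ml = as.numeric(.data$fev1_post_ml),
      fvc_post_ml = as.numeric(.data$fvc_post_ml),
      parent_edu_low = as_flag(.data$parent_edu_low),
      parent_exposure = as.character(.data$parent_exposure)
    )

  if (anyDuplicated(data$offspring_id))
    abort("duplicate offspring_id values")
  if (any(!data$line %in% LINE_LEVELS))
    abort("`line` must be 'paternal' or 'maternal'")
  if (any(!data$sex %in% SEX_LEVELS))
    abort("`sex` must be 'son' or 'daughter'")
  lines_per_parent <- data |>
    distinct(.data$parent_id, .data$line) |>
    count(.data$parent_id)
  if (any(lines_per_parent$n > 1))
    abort("a parent_id maps to more than one line")
  if (any(!is.na(data$parent_exposure) &
          !data$parent_exposure %in% EXPOSURE_LEVELS))
    abort("invalid parent_exposure value")

  # completeness then plausibility, one logged count per reason
  keep <- rep(TRUE, nrow(data))
  drop_reason <- function(bad, reason) {
    bad <- bad & keep
    drop_log(reason, sum(bad))
    keep[bad] <<- FALSE
  }
  key <- c("age", "ever_smoker", "m1_overweight_prepuberty", "height_cm",
           "fev1_ml", "fvc_ml", "parent_edu_low", "parent_exposure")
  for (col in key)
    drop_reason(is.na(data[[col]]), paste("missing", col))
  drop_reason(!is.na(data$age) & data$age < 18, "age below 18")
  drop_reason(!is.na(data$height_cm) &
                (data$height_cm <= 120 | data$height_cm >= 230),
              "implausible height")
  for (col in c("fev1_ml", "fvc_ml"))
    drop_reason(!is.na(data[[col]]) &
                  (data[[col]] <= 500 | data[[col]] >= 9000),
                paste("implausible", col))
  post_one <- xor(is.na(data$fev1_post_ml), is.na(data$fvc_post_ml))
  drop_reason(post_one, "post-bronchodilator values incomplete")

  out <- data[keep, COHORT_COLUMNS]
  out$parent_exposure <- factor(out$parent_exposure, levels = EXPOSURE_LEVELS)
  out$sex <- factor(out$sex, levels = SEX_LEVELS)
  class(out) <- c("cohort_tbl", class(out))
  out
}

#' Read a cohort file
#'
#' Reads a delimited offspring-level table, renames columns through the
#' schema, and validates it (see [validate_cohort()]). If silhouette-score
#' columns (`silhouette_age8`, `silhouette_puberty`, `silhouette_age30` for
#' the parent, `silhouette_offspring_age8`/`_puberty` for the offspring) are
#' present, exposure and mediator flags are derived from them; pre-coded
#' flags take precedence with a warning when both are supplied.
#'
#' @param path file path (CSV, or TSV when the name ends in `.tsv`).
#' @param schema mapping from [cohort_schema()], or a path to a YAML/JSON
#'   file holding one.
#' @return validated `cohort_tbl` tibble with a `provenance` attribute.
#' @export
read_cohort <- function(path, schema = cohort_schema()) {
  if (is.character(schema) && length(schema) == 1 && file.exists(schema)) {
    raw <- if (grepl("\\.json$", schema)) jsonlite::read_json(schema, simplifyVector = TRUE)
           else yaml::read_yaml(schema)
    schema <- do.call(cohort_schema, as.list(raw))
  }
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  data <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
  if (nrow(data) == 0) abort("empty cohort file")

  # silhouette-derived coding where flag columns are absent (or both present)
  parent_sil <- c("silhouette_age8", "silhouette_puberty", "silhouette_age30")
  if (all(parent_sil %in% names(data))) {
    if (schema[["parent_exposure"]] %in% names(data)) {
      warn("both silhouette scores and parent_exposure present; flags win")
    } else {
      sx <- ifelse(data$line == "maternal", "female", "male")
      ow <- lapply(parent_sil, function(cl)
        code_overweight_from_silhouette(sx, data[[cl]]))
      data$parent_exposure <- derive_exposure_category(ow[[1]], ow[[2]], ow[[3]])
    }
  }
  off_sil <- c("silhouette_offspring_age8", "silhouette_offspring_puberty")
  if (all(off_sil %in% names(data))) {
    if (schema[["m1_overweight_prepuberty"]] %in% names(data)) {
      warn("both silhouette scores and m1_overweight_prepuberty present; flags win")
    } else {
      sx <- ifelse(data$sex == "daughter", "female", "male")
      ow8 <- code_overweight_from_silhouette(sx, data[[off_sil[1]]])
      owp <- code_overweight_from_silhouette(sx, data[[off_sil[2]]])
      data$m1_overweight_prepuberty <- ow8 | owp
    }
  }

  present <- schema[schema %in% names(data)]
  data <- rename(data, !!!setNames(as.list(unname(present)), names(present)))
  out <- validate_cohort(data)
  attr(out, "provenance") <- paste0("file:", path)
  out
}

#' Write a cohort file
#'
#' Serialises a cohort table so that `read_cohort(write_cohort(x))` is the
#' identity on values: booleans as 0/1, enums as lowercase strings, optional
#' post-bronchodilator values as empty fields, columns in the canonical
#' schema order.
#'
#' @param data cohort tibble.
#' @param path output path (CSV, or TSV when the name ends in `.tsv`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  out <- as_tibble(data)[, COHORT_COLUMNS] |>
    mutate(across(where(is.logical), as.integer),
           across(where(is.factor), as.character))
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}
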