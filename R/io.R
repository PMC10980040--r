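tac_schema <- c("subject_id", "region", "frame_start_min", "frame_dur_min",
                "conc")
blood_schema <- c("subject_id", "time_min", "parent_plasma", "whole_plasma")
subject_schema <- c("subject_id", "group", "age", "sex", "fP_measured",
                    "scan_date")
param_schema <- c("subject_id", "region", "model", "mode", "parameter",
                  "estimate", "se", "converged")

read_tsv_checked <- function(path, schema, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(schema, names(df))
  if (length(missing_cols)) {
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[, schema]
  for (cc in numeric_cols) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        stop("non-numeric value in column '", cc, "' of ", basename(path),
             " at line ", bad[1] + 1L) # +1 for header
      }
      df[[cc]] <- vn
    }
  }
  df
}

#' Read and validate the tabular data files
#'
#' Tab-separated tables with exact headers, UTF-8, '.' decimal. The TAC
#' table has one row per subject x region x frame (`subject_id`, `region`,
#' `frame_start_min`, `frame_dur_min`, `conc`); the blood table one row per
#' sample (`subject_id`, `time_min`, `parent_plasma`, `whole_plasma`), with
#' strictly increasing times per subject; the subject table one row per
#' subject. Malformed rows are reported with their line number.
#'
#' @param path File path.
#' @return A validated tibble (with internal column names `frame_start`,
#'   `frame_dur` for the TAC table).
#' @export
read_tac_table <- function(path) {
  df <- read_tsv_checked(path, tac_schema,
                         c("frame_start_min", "frame_dur_min", "conc"))
  key <- paste(df$subject_id, df$region, df$frame_start_min)
  if (anyDuplicated(key)) {
    stop("duplicate subject x region x frame at line ",
         which(duplicated(key))[1] + 1L)
  }
  if (any(df$frame_dur_min <= 0)) {
    stop("non-positive frame duration at line ",
         which(df$frame_dur_min <= 0)[1] + 1L)
  }
  tibble::tibble(subject_id = as.character(df$subject_id),
                 region = as.character(df$region),
                 frame_start = df$frame_start_min,
                 frame_dur = df$frame_dur_min, conc = df$conc)
}

#' @rdname read_tac_table
#' @export
read_blood_table <- function(path) {
  df <- read_tsv_checked(path, blood_schema,
                         c("time_min", "parent_plasma", "whole_plasma"))
  for (id in unique(df$subject_id)) {
    tt <- df$time_min[df$subject_id == id]
    if (is.unsorted(tt, strictly = TRUE)) {
      bad <- which(df$subject_id == id)[which(diff(tt) <= 0)[1] + 1L]
      stop("time not increasing for subject ", id, " at line ", bad + 1L)
    }
  }
  tibble::as_tibble(df)
}

#' @rdname read_tac_table
#' @export
read_subject_table <- function(path) {
  df <- read_tsv_checked(path, subject_schema,
                         c("age", "fP_measured", "scan_date"))
  if (any(df$fP_measured <= 0 | df$fP_measured >= 1)) {
    stop("fP_measured must lie in (0, 1); offending line ",
         which(df$fP_measured <= 0 | df$fP_measured >= 1)[1] + 1L)
  }
  tibble::as_tibble(df)
}

#' @rdname read_tac_table
#' @export
read_param_table <- function(path) {
  df <- read_tsv_checked(path, param_schema, c("estimate", "se"))
  df$converged <- as.logical(df$converged)
  tibble::as_tibble(df)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' Write a cohort to a directory of TSV tables
#'
#' Writes `subjects.tsv`, `tacs.tsv` and `blood.tsv` in the package's
#' exchange schemas, plus `manifest.json` recording the seed and group
#' sizes, sufficient to identify the generating configuration.
#'
#' @param cohort A `pet_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subj <- cohort$subjects[, c("subject_id", "group", "age", "sex",
                              "fP_measured", "scan_date")]
  write_tsv(subj, file.path(dir, "subjects.tsv"))
  tt <- cohort$tacs
  write_tsv(data.frame(subject_id = tt$subject_id, region = tt$region,
                       frame_start_min = tt$frame_start,
                       frame_dur_min = tt$frame_dur, conc = tt$conc),
            file.path(dir, "tacs.tsv"))
  blood <- do.call(rbind, lapply(names(cohort$inputs), function(id) {
    inp <- cohort$inputs[[id]]
    data.frame(subject_id = id, time_min = inp$time,
               parent_plasma = inp$parent_plasma,
               whole_plasma = inp$whole_plasma)
  }))
  write_tsv(blood, file.path(dir, "blood.tsv"))
  manifest <- list(seed = cohort$truth$seed,
                   n = as.list(table(cohort$subjects$group)),
                   regions = unique(tt$region),
                   package_version = as.character(utils::packageVersion("hbpet")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Rebuilds a `pet_cohort`-shaped object (without ground truth) from
#' `subjects.tsv`, `tacs.tsv` and `blood.tsv`.
#'
#' @param dir Directory path.
#' @param half_life Radionuclide half-life in minutes.
#' @return A list of class `pet_cohort`.
#' @export
read_cohort <- function(dir, half_life = 20.364) {
  subjects <- read_subject_table(file.path(dir, "subjects.tsv"))
  tacs <- read_tac_table(file.path(dir, "tacs.tsv"))
  blood <- read_blood_table(file.path(dir, "blood.tsv"))
  first <- tacs[tacs$subject_id == tacs$subject_id[1] &
                  tacs$region == tacs$region[1], ]
  sch <- frame_schedule(first$frame_start, first$frame_dur)
  inputs <- lapply(split(blood, blood$subject_id), function(b) {
    input_function(b$time_min, b$parent_plasma, b$whole_plasma)
  })
  inputs <- inputs[unique(subjects$subject_id)]
  structure(list(subjects = subjects, inputs = inputs, tacs = tacs,
                 truth = NULL,
                 config = list(schedule = sch, half_life = half_life,
                               regions = unique(tacs$region))),
            class = "pet_cohort")
}
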