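#' Dipstick haematuria categories
#'
#' Canonical category strings for the semi-quantitative erythrocyte dipstick
#' (Multistix-style colour scheme). The four highest categories are read as
#' positive haematuria, the rest as negative; haematuria serves as a marker
#' for catheterisation-induced microtrauma.
#'
#' @format Character vector of the seven categories, ordered from negative
#'   upwards.
#' @export
dipstick_categories <- c(
  "negative",
  "non-haemolysed 10 (+/-)",
  "haemolysed 10 (+/-)",
  "haemolysed 25 (1+)",
  "haemolysed 80 (2+)",
  "non-haemolysed 80 (2+)",
  "haemolysed 200 (3+)"
)

dipstick_positive_set <- c(
  "haemolysed 25 (1+)",
  "haemolysed 80 (2+)",
  "non-haemolysed 80 (2+)",
  "haemolysed 200 (3+)"
)

#' Dichotomise a dipstick haematuria reading
#'
#' @param category One of [dipstick_categories] (vectorised).
#' @return Logical: `TRUE` for a positive haematuria assessment (the 1+, 2+
#'   and 3+ categories), `FALSE` for negative and the trace (+/-) categories.
#' @examples
#' classify_dipstick("haemolysed 25 (1+)")     # TRUE
#' classify_dipstick("non-haemolysed 10 (+/-)") # FALSE
#' @export
classify_dipstick <- function(category) {
  bad <- !category %in% dipstick_categories
  if (any(bad))
    cf_data_error(sprintf("unknown dipstick category: %s",
                          paste(shQuote(unique(category[bad])), collapse = ", ")))
  category %in% dipstick_positive_set
}

#' Summarise a triplicate bladder scan
#'
#' Pre- and post-catheterisation bladder volumes are taken as the arithmetic
#' mean of three ultrasound scans. Eligibility for catheterisation requires a
#' pre-void volume of at least 150 mL in *all three* measurements, not just
#' on average.
#'
#' @param triplet Numeric vector of exactly 3 non-negative volumes (mL).
#' @return List with `mean_volume` (mL) and `all_at_or_above_150` (logical).
#' @examples
#' summarize_scan(c(160, 155, 170))  # eligible
#' summarize_scan(c(160, 149, 170))  # not eligible: one scan below 150
#' @export
summarize_scan <- function(triplet) {
  triplet <- as.numeric(triplet)
  if (length(triplet) != 3L || anyNA(triplet))
    cf_data_error("a scan triplet must hold exactly 3 volumes")
  if (any(triplet < 0))
    cf_data_error("scan volumes must be non-negative")
  list(mean_volume = mean(triplet),
       all_at_or_above_150 = all(triplet >= 150))
}

#' Per-visit clinical record
#'
#' Non-trace measurements taken at one test visit: triplicate pre- and
#' post-catheterisation bladder scans, the dipstick haematuria category, and
#' the subject's bladder-dysfunction history.
#'
#' @param subject_id Subject identifier.
#' @param visit Visit number (1 or 2).
#' @param device `"MHZC"` or `"CEC"`.
#' @param prevoid_scan,postvoid_scan Numeric triplets (mL).
#' @param dipstick One of [dipstick_categories].
#' @param medical_history `"neurogenic"` or `"non-neurogenic"`.
#' @return A `clinical_record` list with the scan summaries attached as
#'   `prevoid` and `postvoid`.
#' @export
clinical_record <- function(subject_id, visit, device, prevoid_scan,
                            postvoid_scan, dipstick = "negative",
                            medical_history = c("non-neurogenic",
                                                "neurogenic")) {
  check_device(device)
  if (!visit %in% c(1L, 2L)) cf_data_error("`visit` must be 1 or 2")
  medical_history <- match.arg(medical_history)
  pre <- summarize_scan(prevoid_scan)
  post <- summarize_scan(postvoid_scan)
  classify_dipstick(dipstick)  # validates the category
  structure(list(subject_id = as.character(subject_id),
                 visit = as.integer(visit), device = device,
                 prevoid_scan = as.numeric(prevoid_scan),
                 postvoid_scan = as.numeric(postvoid_scan),
                 prevoid = pre, postvoid = post,
                 dipstick = dipstick, medical_history = medical_history),
            class = "clinical_record")
}

#' Read and write per-visit clinical records
#'
#' One CSV row per subject-visit with columns `subject_id`, `visit`,
#' `device`, `prevoid_1..3`, `postvoid_1..3`, `dipstick`, `medical_history`.
#'
#' @param path CSV path.
#' @return `read_clinical_records()`: a list of [clinical_record()] objects.
#' @export
read_clinical_records <- function(path) {
  if (!file.exists(path)) cf_format_error(sprintf("no such file: %s", path))
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("subject_id", "visit", "device",
            paste0("prevoid_", 1:3), paste0("postvoid_", 1:3),
            "dipstick", "medical_history")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    cf_format_error(sprintf("clinical-record CSV lacks column(s): %s",
                            paste(missing, collapse = ", ")))
  lapply(seq_len(nrow(df)), function(i) {
    clinical_record(df$subject_id[i], df$visit[i], df$device[i],
                    as.numeric(df[i, paste0("prevoid_", 1:3)]),
                    as.numeric(df[i, paste0("postvoid_", 1:3)]),
                    df$dipstick[i], df$medical_history[i])
  })
}

#' @rdname read_clinical_records
#' @param records List of [clinical_record()] objects.
#' @export
write_clinical_records <- function(records, path) {
  rows <- lapply(records, function(r) {
    out <- data.frame(subject_id = r$subject_id, visit = r$visit,
                      device = r$device)
    out[paste0("prevoid_", 1:3)] <- as.list(r$prevoid_scan)
    out[paste0("postvoid_", 1:3)] <- as.list(r$postvoid_scan)
    out$dipstick <- r$dipstick
    out$medical_history <- r$medical_history
    out
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
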