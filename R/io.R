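# Plain-text image and table I/O.
#
# Images cross the file boundary as ASCII PGM (P2, 8-bit) or CSV matrices;
# in memory every image is a numeric matrix in [0, 1] with rows = depth
# (B-scans) or rows = y (en-face images).

#' Write a grayscale image as ASCII PGM (P2)
#'
#' Values are clipped to \[0, 1\] and quantized to 8 bits.
#'
#' @param img numeric matrix in \[0, 1\].
#' @param path output file path (conventionally `.pgm`).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path) {
  stopifnot(is.matrix(img), is.numeric(img))
  q <- round(clip01(img) * 255)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(q), nrow(q)), "255"), con)
  # one image row per line
  writeLines(apply(q, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Read an ASCII PGM (P2) grayscale image
#'
#' @param path file path.
#' @return numeric matrix scaled to \[0, 1\].
#' @export
read_pgm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^\\s*#", txt)]
  assert_that(trimws(txt[1]) == "P2", "not an ASCII PGM (P2) file")
  tokens <- scan(text = paste(txt[-1], collapse = "\n"), what = numeric(),
                 quiet = TRUE)
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  px <- tokens[-(1:3)]
  assert_that(length(px) == w * h, "PGM pixel count mismatch")
  matrix(px, nrow = h, ncol = w, byrow = TRUE) / maxval
}

#' Read/write a float image as a headerless CSV matrix
#'
#' Lossless float round-trip used for phantom fixtures.
#'
#' @param img numeric matrix.
#' @param path file path.
#' @return `write_matrix_csv`: `path` invisibly; `read_matrix_csv`: matrix.
#' @export
write_matrix_csv <- function(img, path) {
  utils::write.table(img, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  as.matrix(utils::read.csv(path, header = FALSE))
}

#' Read an image file by extension
#'
#' Dispatches on extension: `.pgm` (8-bit ASCII PGM) or `.csv` (float matrix).
#'
#' @param path file path.
#' @return numeric matrix in \[0, 1\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    pgm = read_pgm(path),
    csv = clip01(read_matrix_csv(path)),
    stop("unsupported image format: .", ext, " (use .pgm or .csv)")
  )
}

# Canonical eye-table column set (cohort CSV contract).
cohort_columns <- function() {
  c("subject_id", "eye", "group", "age", "dm_duration", "etdrs_level",
    "vd_srcp", "vd_drcp", "faz_area_mm2", "rnfl_um", "gcl_ipl_um",
    "inl_um", "opl_um", "total_um", "bcva_logmar")
}

#' Read and write eye-level cohort tables
#'
#' The cohort CSV has one row per eye with columns
#' `subject_id, eye (OD/OS), group, age, dm_duration, etdrs_level, vd_srcp,
#' vd_drcp, faz_area_mm2, rnfl_um, gcl_ipl_um, inl_um, opl_um, total_um,
#' bcva_logmar`.
#'
#' @param records data.frame of eye records.
#' @param path file path.
#' @return `read_cohort_csv`: a validated data.frame.
#' @export
write_cohort_csv <- function(records, path) {
  missing_cols <- setdiff(cohort_columns(), names(records))
  assert_that(length(missing_cols) == 0,
              paste("cohort table missing columns:",
                    paste(missing_cols, collapse = ", ")))
  utils::write.csv(records[, union(cohort_columns(), names(records))], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_columns(), names(df))
  assert_that(length(missing_cols) == 0,
              paste("cohort CSV missing columns:",
                    paste(missing_cols, collapse = ", ")))
  assert_that(all(df$eye %in% c("OD", "OS")), "eye must be OD or OS")
  assert_that(all(is.finite(df$bcva_logmar)), "bcva_logmar must be finite")
  df
}
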