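#' Read / write a feature quantification table CSV
#'
#' The on-disk layout mirrors a peak picker's export: a header row
#' `feature_id, mz, rt` followed by one column per sample; cells are peak
#' areas with 0 meaning "not detected" (no NAs on disk). Writing then
#' reading reproduces all values to better than 1e-9 relative error.
#'
#' @param path CSV file path.
#' @return [read_feature_table()] returns a [feature_table()];
#'   `write_feature_table` invisibly returns `path`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("feature_id", "mz", "rt")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("feature table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  sample_cols <- setdiff(names(df), required)
  if (!length(sample_cols)) stop("feature table has no sample columns")
  areas <- as.matrix(df[sample_cols])
  if (!is.numeric(areas)) {
    bad <- sample_cols[which(!vapply(df[sample_cols], is.numeric, logical(1)))[1]]
    stop("non-numeric areas in column ", bad)
  }
  if (anyNA(areas)) {
    bad <- which(is.na(areas), arr.ind = TRUE)[1, ]
    stop("missing area at row ", bad[1], ", column ", sample_cols[bad[2]],
         " (use 0 for non-detected)")
  }
  if (any(areas < 0)) {
    bad <- which(areas < 0, arr.ind = TRUE)[1, ]
    stop("negative area at feature ", df$feature_id[bad[1]], ", sample ",
         sample_cols[bad[2]])
  }
  if (anyDuplicated(df$feature_id))
    stop("duplicate feature_id in ", path, ": ",
         df$feature_id[duplicated(df$feature_id)][1])
  feature_table(df[required], areas, sample_cols)
}

#' @rdname read_feature_table
#' @param table a [feature_table()] on the raw area scale.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  if (table$values != "areas")
    stop("only raw area tables are written to disk (got values = '",
         table$values, "')")
  df <- cbind(table$features[c("feature_id", "mz", "rt")],
              as.data.frame(table$areas, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata CSV
#'
#' Columns: sample_id, participant_id, visit, age, sex, education, is_blank.
#' Blank samples carry no participant; every non-blank sample must map to a
#' participant, and (participant, visit) pairs are unique.
#'
#' @param path CSV path.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "participant_id", "visit", "age", "is_blank")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("metadata lacks column(s): ", paste(missing, collapse = ", "))
  df$is_blank <- as.logical(df$is_blank)
  df$participant_id[df$participant_id %in% c("", "NA")] <- NA_character_
  if (any(!df$is_blank & is.na(df$participant_id)))
    stop("non-blank sample without participant: ",
         df$sample_id[which(!df$is_blank & is.na(df$participant_id))[1]])
  pv <- df[!df$is_blank, c("participant_id", "visit")]
  if (anyDuplicated(pv))
    stop("duplicate (participant, visit) pair: ",
         paste(pv[duplicated(pv), ][1, ], collapse = "/"))
  df
}

#' @rdname read_metadata
#' @param metadata sample metadata data.frame.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE)
  invisible(path)
}

#' Read an MGF (Mascot Generic Format) spectrum file
#'
#' Parses standard `BEGIN IONS`/`END IONS` blocks honoring `PEPMASS`,
#' `RTINSECONDS` (converted to minutes on read) and `TITLE`. Sample
#' occurrences and an optional feature link travel in TITLE-embedded
#' `KEY=value` tokens (`SAMPLES=` semicolon-separated, `FEATURE=`). Peaks
#' are returned sorted by m/z; round-tripping through [write_mgf()]
#' preserves precursor m/z and peak lists to 1e-6 Da.
#'
#' @param path MGF file path.
#' @return list of spectrum records (spectrum_id, feature_id, precursor_mz,
#'   rt minutes, peaks matrix, samples).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  spectra <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (line == "BEGIN IONS") {
      start <- i
      rec <- list(spectrum_id = NA_character_, feature_id = NA_character_,
                  precursor_mz = NA_real_, rt = NA_real_,
                  samples = character(0))
      mzs <- numeric(0); ints <- numeric(0)
      i <- i + 1L
      closed <- FALSE
      while (i <= n) {
        l <- trimws(lines[i])
        if (l == "END IONS") { closed <- TRUE; break }
        if (l == "BEGIN IONS") stop("unterminated BEGIN IONS block at line ", start)
        if (grepl("^PEPMASS=", l)) {
          rec$precursor_mz <- as.numeric(strsplit(sub("^PEPMASS=", "", l), "[ \t]")[[1]][1])
        } else if (grepl("^RTINSECONDS=", l)) {
          rec$rt <- as.numeric(sub("^RTINSECONDS=", "", l)) / 60
        } else if (grepl("^TITLE=", l)) {
          title <- sub("^TITLE=", "", l)
          toks <- strsplit(title, "[ \t]+")[[1]]
          rec$spectrum_id <- toks[1]
          for (tk in toks[-1]) {
            if (grepl("^SAMPLES=", tk))
              rec$samples <- strsplit(sub("^SAMPLES=", "", tk), ";")[[1]]
            if (grepl("^FEATURE=", tk))
              rec$feature_id <- sub("^FEATURE=", "", tk)
          }
        } else if (grepl("^[A-Z]+=", l) || l == "") {
          # other headers ignored
        } else {
          parts <- strsplit(l, "[ \t]+")[[1]]
          vals <- suppressWarnings(as.numeric(parts))
          if (length(vals) < 2 || anyNA(vals[1:2]))
            stop("non-numeric peak line at line ", i, ": '", l, "'")
          mzs <- c(mzs, vals[1]); ints <- c(ints, vals[2])
        }
        i <- i + 1L
      }
      if (!closed) stop("unterminated BEGIN IONS block at line ", start)
      if (is.na(rec$spectrum_id))
        rec$spectrum_id <- sprintf("spectrum_%d", length(spectra) + 1L)
      ord <- order(mzs)
      rec$peaks <- cbind(mz = mzs[ord], intensity = ints[ord])
      spectra[[length(spectra) + 1L]] <- rec
    }
    i <- i + 1L
  }
  spectra
}

#' @rdname read_mgf
#' @param spectra list of spectrum records.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    title <- sp$spectrum_id
    if (!is.null(sp$feature_id) && !is.na(sp$feature_id))
      title <- paste0(title, " FEATURE=", sp$feature_id)
    if (length(sp$samples))
      title <- paste0(title, " SAMPLES=", paste(sp$samples, collapse = ";"))
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", title),
                 sprintf("PEPMASS=%.6f", sp$precursor_mz),
                 if (!is.null(sp$rt) && !is.na(sp$rt))
                   sprintf("RTINSECONDS=%.4f", sp$rt * 60),
                 sprintf("%.6f %.4f", sp$peaks[, "mz"], sp$peaks[, "intensity"]),
                 "END IONS", ""), con)
  }
  invisible(path)
}

#' Write / read the generator's ground-truth sidecar
#'
#' JSON serialization of the planted structure labels so that recovery
#' analyses can run against files on disk.
#'
#' @param truth the `truth` list produced by the generators.
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  # named vectors become JSON objects so participant/feature names survive
  for (f in c("true_random_slopes", "true_random_intercepts",
              "resilience_signs", "age_signs"))
    if (!is.null(truth[[f]])) truth[[f]] <- as.list(truth[[f]])
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null", na = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("true_random_slopes", "true_random_intercepts",
              "resilience_signs", "age_signs"))
    if (!is.null(tr[[f]])) tr[[f]] <- unlist(tr[[f]])
  if (!is.null(tr$spectrum_labels))
    tr$spectrum_labels <- as.data.frame(tr$spectrum_labels,
                                        stringsAsFactors = FALSE)
  tr
}
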