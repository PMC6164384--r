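# Readers/writers for the plain-text interchange formats:
# peak-list CSV/TSV, JCAMP-DX peak tables, descriptor-matrix CSV,
# activity CSV.

#' Read peak lists from a CSV/TSV file
#'
#' Expects a header with columns `sample_id`, `nucleus` (`1H`|`13C`),
#' `shift_ppm` and (optionally) `intensity`.  The delimiter is inferred
#' from the file extension (`.tsv` -> tab) unless given.
#'
#' @param path File path.
#' @param sep Field separator; default inferred from extension.
#' @return A named list of [peak_list()] objects, in order of first
#'   appearance of each sample id.
#' @export
read_peaklist_csv <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("sample_id", "nucleus", "shift_ppm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("peak-list file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$intensity)) df$intensity <- 1
  ids <- unique(df$sample_id)
  out <- lapply(ids, function(id) {
    d <- df[df$sample_id == id, , drop = FALSE]
    peak_list(as.character(id), d$nucleus, d$shift_ppm, d$intensity)
  })
  names(out) <- ids
  out
}

#' Write peak lists to CSV
#'
#' @param peaklists List of [peak_list()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peaklist_csv <- function(peaklists, path) {
  rows <- lapply(peaklists, function(p) {
    if (!nrow(p$peaks)) return(NULL)
    data.frame(sample_id = p$sample_id, nucleus = p$peaks$nucleus,
               shift_ppm = p$peaks$shift, intensity = p$peaks$intensity)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(sample_id = character(), nucleus = character(),
                     shift_ppm = numeric(), intensity = numeric())
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a JCAMP-DX peak table
#'
#' Minimal reader for the peak-table form (`##PEAK TABLE=(XY..XY)` or
#' `##PEAKTABLE=`): pairs of chemical shift and intensity separated by
#' commas and/or whitespace, one file per nucleus per sample.  Compound
#' JCAMP-DX, NTUPLES and full-spectrum (XYDATA) records are out of scope.
#'
#' @param path JCAMP-DX file path.
#' @param sample_id Sample identifier; defaults to the `##TITLE=` record.
#' @param nucleus `"1H"` or `"13C"`; defaults to a parse of
#'   `##.OBSERVE NUCLEUS=` (`^1H` / `^13C`).
#' @return A [peak_list()].
#' @export
read_jcampdx <- function(path, sample_id = NULL, nucleus = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  if (is.null(sample_id)) {
    t <- grep("^##TITLE=", lines, value = TRUE)
    sample_id <- if (length(t)) trimws(sub("^##TITLE=", "", t[1])) else
      sub("\\.[^.]*$", "", basename(path))
  }
  if (is.null(nucleus)) {
    o <- grep("NUCLEUS=", lines, value = TRUE, ignore.case = TRUE)
    nucleus <- if (length(o) && grepl("13C", o[1])) "13C" else
      if (length(o) && grepl("1H", o[1])) "1H" else
        stop("nucleus not given and no ##.OBSERVE NUCLEUS= record",
             call. = FALSE)
  }
  start <- grep("^##PEAK ?TABLE=", lines)
  if (!length(start)) stop("no ##PEAK TABLE= record in ", path, call. = FALSE)
  body <- lines[(start[1] + 1L):length(lines)]
  stop_at <- grep("^##", body)
  if (length(stop_at)) body <- body[seq_len(stop_at[1] - 1L)]
  tokens <- unlist(strsplit(paste(body, collapse = " "), "[,;[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  vals <- suppressWarnings(as.numeric(tokens))
  if (any(is.na(vals)) || length(vals) %% 2L != 0L) {
    stop("malformed peak table in ", path, call. = FALSE)
  }
  shift <- vals[seq(1, length(vals), by = 2)]
  intensity <- vals[seq(2, length(vals), by = 2)]
  peak_list(sample_id, rep(nucleus, length(shift)), shift, intensity)
}

#' Write a descriptor matrix to CSV
#'
#' First column `sample_id`, remaining columns the joint descriptor names
#' (`H_0014[1.3019,1.4019)` style).
#'
#' @param dm A `descriptor_matrix` from [build_matrix()], or a plain
#'   numeric matrix with dimnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(dm, path) {
  values <- if (inherits(dm, "descriptor_matrix")) dm$values else dm
  df <- data.frame(sample_id = rownames(values), values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a descriptor matrix from CSV
#'
#' Inverse of [write_matrix_csv()]: returns the numeric matrix with sample
#' ids as row names and descriptor names as column names.
#'
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id") {
    stop("descriptor CSV must start with a sample_id column", call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$sample_id
  m
}

#' Read an activity table from CSV
#'
#' Columns: `sample_id`, `ic50`, `units` (`uM` or `ug/mL`; the micro sign
#' is accepted), optional `censored` (logical; assay gave no IC50 within
#' the tested range).  Censored records may leave `ic50` empty.
#'
#' @param path File path.
#' @return A data.frame with normalized `units` and logical `censored`.
#' @export
read_activity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("sample_id", "ic50", "units")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("activity file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  units <- gsub("µ", "u", df$units)
  ok <- units %in% c("uM", "ug/mL")
  if (any(!ok)) {
    stop("unknown units: ", paste(unique(units[!ok]), collapse = ", "),
         " (use uM or ug/mL)", call. = FALSE)
  }
  df$units <- units
  df$censored <- if (is.null(df$censored)) FALSE else as.logical(df$censored)
  df$ic50 <- as.numeric(df$ic50)
  bad <- !df$censored & (is.na(df$ic50) | df$ic50 <= 0)
  if (any(bad)) {
    stop("non-positive or missing ic50 for uncensored sample(s): ",
         paste(df$sample_id[bad], collapse = ", "), call. = FALSE)
  }
  df
}
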