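#' One scan's ROI time series
#'
#' A single scan: a T x R numeric matrix (timepoints in rows, regions in
#' columns) plus identifying metadata. Values are whatever signal units the
#' upstream extraction produced; the model never rescales them.
#'
#' @param matrix numeric T x R matrix, no missing values.
#' @param participant_id,scan_id character identifiers.
#' @param group group label, `"mindfulness"` or `"control"`.
#' @param tr_seconds sampling interval in seconds (default 2).
#' @param region_names character vector of R unique region names; defaults to
#'   `"R1".."Rn"`.
#' @return An object of class `scan_series`.
#' @export
scan_series <- function(matrix, participant_id = "p1", scan_id = "s1",
                        group = c("mindfulness", "control"), tr_seconds = 2,
                        region_names = NULL) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "double"
  group <- match.arg(group)
  if (is.null(region_names)) region_names <- paste0("R", seq_len(ncol(m)))
  obj <- structure(list(
    participant_id = as.character(participant_id),
    scan_id = as.character(scan_id),
    group = group,
    matrix = m,
    tr_seconds = as.numeric(tr_seconds),
    region_names = as.character(region_names)
  ), class = "scan_series")
  validate_scan_series(obj)
  obj
}

validate_scan_series <- function(s) {
  stopifnot(inherits(s, "scan_series"))
  m <- s$matrix
  if (nrow(m) < 2L) stop("scan must have at least 2 timepoints")
  if (ncol(m) < 2L) stop("scan must have at least 2 regions")
  if (anyNA(m)) stop("scan matrix contains missing values")
  if (s$tr_seconds <= 0) stop("tr_seconds must be positive")
  if (length(s$region_names) != ncol(m)) stop("region_names length mismatch")
  if (anyDuplicated(s$region_names)) stop("region_names must be unique")
  invisible(s)
}

#' @export
print.scan_series <- function(x, ...) {
  cat(sprintf("scan_series: %s/%s (%s), %d timepoints x %d regions, TR = %gs\n",
              x$participant_id, x$scan_id, x$group,
              nrow(x$matrix), ncol(x$matrix), x$tr_seconds))
  invisible(x)
}

normalize_group <- function(g) {
  g <- tolower(trimws(as.character(g)))
  bad <- !(g %in% c("mindfulness", "control"))
  if (any(bad))
    stop("unknown group label(s): ", paste(unique(g[bad]), collapse = ", "))
  g
}

#' Read a cohort manifest
#'
#' Reads a delimited text file (CSV or TSV, detected from the extension) with
#' columns `participant_id`, `scan_id`, `group`, `stress_score`, `avg_drinks`,
#' `path`, and validates the cohort invariants: each (participant, scan) pair
#' is unique and every participant belongs to exactly one group.
#'
#' @param path file path.
#' @return A `data.frame` of class `cohort_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  as_manifest(df)
}

#' Coerce a data frame to a validated cohort manifest
#'
#' @param df data frame with the manifest columns (see [read_manifest()]).
#' @return A `data.frame` of class `cohort_manifest`.
#' @export
as_manifest <- function(df) {
  if (nrow(df) == 0L) stop("no scans in manifest")
  need <- c("participant_id", "scan_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("manifest missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"stress_score" %in% names(df)) df$stress_score <- NA_real_
  if (!"avg_drinks" %in% names(df)) df$avg_drinks <- NA_real_
  if (!"path" %in% names(df)) df$path <- NA_character_
  df$participant_id <- as.character(df$participant_id)
  df$scan_id <- as.character(df$scan_id)
  df$group <- normalize_group(df$group)
  key <- paste(df$participant_id, df$scan_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (participant_id, scan_id) pair(s) in manifest")
  gmap <- tapply(df$group, df$participant_id,
                 function(g) length(unique(g)))
  if (any(gmap > 1L))
    stop("participant(s) assigned to more than one group: ",
         paste(names(gmap)[gmap > 1L], collapse = ", "))
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' Write a cohort manifest to delimited text
#'
#' @param manifest a `cohort_manifest`.
#' @param path output path; `.tsv`/`.txt` writes tab-delimited, else CSV.
#' @export
write_manifest <- function(manifest, path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(manifest, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read one scan's time-series matrix
#'
#' Reads a delimited numeric matrix (timepoints x regions, no header row) and
#' attaches the metadata from one manifest row. Values are left untouched.
#' Non-numeric cells raise an error naming the row and column.
#'
#' @param path file path (CSV or TSV by extension).
#' @param meta one-row data frame or list with `participant_id`, `scan_id`,
#'   `group`, optionally `tr_seconds`; may be `NULL` for anonymous reads.
#' @param region_names optional region names to attach (and validate against
#'   the column count).
#' @return A [scan_series()].
#' @export
read_scan <- function(path, meta = NULL, region_names = NULL) {
  if (!file.exists(path)) stop("scan file not found: ", path)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = FALSE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  m <- suppressWarnings(vapply(raw, as.numeric, numeric(nrow(raw))))
  m <- matrix(as.numeric(m), nrow = nrow(raw))
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at row %d, column %d of %s",
                 idx[1L], idx[2L], path))
  }
  if (is.null(meta)) meta <- list(participant_id = "p1", scan_id = "s1",
                                  group = "control")
  tr <- if (!is.null(meta$tr_seconds)) meta$tr_seconds else 2
  scan_series(m,
              participant_id = meta$participant_id,
              scan_id = meta$scan_id,
              group = normalize_group(meta$group),
              tr_seconds = tr,
              region_names = region_names)
}

#' Write one scan's matrix to delimited text
#'
#' @param scan a `scan_series` or bare numeric matrix.
#' @param path output path (CSV or TSV by extension).
#' @export
write_scan <- function(scan, path) {
  m <- if (inherits(scan, "scan_series")) scan$matrix else as.matrix(scan)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(m, path, sep = sep, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a whole cohort (manifest plus scan matrices)
#'
#' Region order is taken from `region_names` (or the first scan) and must
#' match across scans; a column-count mismatch is an error, never a silent
#' reorder.
#'
#' @param manifest_path manifest file path; relative scan paths are resolved
#'   against the manifest's directory.
#' @param region_names optional region names shared by all scans.
#' @return list with `manifest` and `scans` (list of [scan_series()]).
#' @export
read_cohort <- function(manifest_path, region_names = NULL) {
  manifest <- read_manifest(manifest_path)
  base <- dirname(manifest_path)
  scans <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$path[i]
    if (!file.exists(p)) p <- file.path(base, manifest$path[i])
    scans[[i]] <- read_scan(p, meta = manifest[i, ], region_names = region_names)
    if (i > 1L && ncol(scans[[i]]$matrix) != ncol(scans[[1L]]$matrix))
      stop("region count mismatch between scans ", manifest$scan_id[1L],
           " and ", manifest$scan_id[i])
  }
  list(manifest = manifest, scans = scans)
}

#' Trim a scan's time series
#'
#' Removes `trim_leading` volumes from the start (steady-state settling),
#' then `trim_edges` timepoints from each end (band-pass edge effects). The
#' defaults (10 and 3) reduce a 297-volume scan to 281 usable timepoints.
#'
#' @param s a [scan_series()].
#' @param trim_leading nonnegative integer, leading volumes to drop first.
#' @param trim_edges nonnegative integer, timepoints to drop from each end
#'   after the leading trim.
#' @return The trimmed `scan_series`.
#' @export
trim_series <- function(s, trim_leading = 10L, trim_edges = 3L) {
  stopifnot(inherits(s, "scan_series"))
  trim_leading <- as.integer(trim_leading)
  trim_edges <- as.integer(trim_edges)
  if (trim_leading < 0L || trim_edges < 0L)
    stop("trim amounts must be nonnegative")
  T_ <- nrow(s$matrix)
  newT <- T_ - trim_leading - 2L * trim_edges
  if (newT < 2L)
    stop(sprintf("trimming leaves %d timepoints (need >= 2): T=%d, leading=%d, edges=%d",
                 newT, T_, trim_leading, trim_edges))
  keep <- seq.int(trim_leading + trim_edges + 1L, T_ - trim_edges)
  s$matrix <- s$matrix[keep, , drop = FALSE]
  s
}

#' Write fitted HSMM parameters to JSON
#'
#' The on-disk representation round-trips losslessly (full double precision).
#'
#' @param params an [hsmm_params()] object.
#' @param path output path.
#' @export
write_params <- function(params, path) {
  validate_hsmm_params(params)
  obj <- list(
    K = params$K, R = params$R, mu = params$mu,
    sigma = params$sigma, trans = params$trans, init = params$init,
    dwell = params$dwell, max_dwell = params$max_dwell,
    region_names = params$region_names
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Read HSMM parameters from JSON
#'
#' @param path a file written by [write_params()].
#' @return An [hsmm_params()] object.
#' @export
read_params <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  sigma <- o$sigma
  if (is.array(sigma) && length(dim(sigma)) == 3L) {
    sigma <- lapply(seq_len(dim(sigma)[1L]), function(k) sigma[k, , ])
  } else if (is.matrix(sigma)) {
    sigma <- list(sigma)
  }
  sigma <- lapply(sigma, as.matrix)
  mu <- matrix(as.numeric(o$mu), nrow = o$K)
  trans <- matrix(as.numeric(o$trans), nrow = o$K)
  dwell <- o$dwell
  if (identical(dwell$family, "nonparametric"))
    dwell$pmf <- matrix(as.numeric(dwell$pmf), nrow = o$K)
  hsmm_params(mu = mu, sigma = sigma, trans = trans, init = o$init,
              dwell = dwell, max_dwell = o$max_dwell,
              region_names = o$region_names)
}

#' Write a stage result to disk
#'
#' Data frames are written as delimited text; everything else as JSON with
#' full precision.
#'
#' @param results a data frame or list.
#' @param path output path; extension decides the format for data frames.
#' @export
write_results <- function(results, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  if (file.access(dir, 2L) != 0L) stop("output directory not writable: ", dir)
  if (is.data.frame(results)) {
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
    utils::write.table(results, path, sep = sep, row.names = FALSE,
                       quote = FALSE)
  } else {
    jsonlite::write_json(results, path, digits = I(17), auto_unbox = TRUE,
                         null = "null", force = TRUE)
  }
  invisible(path)
}
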