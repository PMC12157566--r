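# full-precision numeric formatting for all tabular output
.fmt <- function(x) sprintf("%.17g", x)

#' Write / read a run time series as TSV
#'
#' The TSV has one row per region: first column `region`, then one column
#' per time point, values at full precision. A sidecar JSON
#' (`<path>.json`) carries TR, subject and run identifiers. Reading back
#' restores bitwise-equal values.
#'
#' @param ts a `run_timeseries`.
#' @param path TSV file path.
#' @param scheme optional `parcellation_scheme` to re-attach on read.
#' @return `write_timeseries` returns `path` invisibly; `read_timeseries`
#'   returns a `run_timeseries`.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "run_timeseries"))
  m <- unclass(ts)
  df <- data.frame(region = rownames(m),
                   apply(m, 2, .fmt), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("region", sprintf("t%d", seq_len(ncol(m))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(TR = attr(ts, "TR"), subject_id = attr(ts, "subject_id"),
         run_id = attr(ts, "run_id")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path, scheme = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(df$region, NULL)
  meta <- list(TR = 1, subject_id = "", run_id = "")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    got <- jsonlite::fromJSON(sidecar)
    meta[names(got)] <- got
  }
  ts <- run_timeseries(m, TR = meta$TR, scheme = scheme,
                       subject_id = meta$subject_id, run_id = meta$run_id)
  if (is.null(scheme)) rownames(ts) <- df$region
  ts
}

#' Write / read a named square matrix as TSV
#'
#' Used for FC matrices, identifiability matrices and ICC maps: region (or
#' subject) names as header row and first column, full numeric precision.
#'
#' @param m numeric matrix with dimnames.
#' @param path file path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` a matrix.
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- sprintf("r%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%d", seq_len(ncol(m)))
  df <- data.frame(name = rownames(m), apply(m, 2, .fmt),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("name", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$name
  m
}

#' Read a two-run manifest
#'
#' A manifest is a TSV with columns `subject_id`, `run_id`, `path` (and
#' optionally `scheme_name`) listing one time-series file per subject-run.
#' Every subject must have exactly two runs; paths are resolved relative
#' to the manifest's directory.
#'
#' @param path manifest TSV path.
#' @return data.frame with resolved paths, ordered by subject then run.
#' @export
read_manifest <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (!all(c("subject_id", "run_id", "path") %in% names(df)))
    stop("manifest needs columns subject_id, run_id, path")
  counts <- table(df$subject_id)
  bad <- names(counts)[counts != 2L]
  if (length(bad))
    stop("subject(s) without exactly 2 runs: ", paste(bad, collapse = ", "))
  df$path <- ifelse(grepl("^/", df$path), df$path,
                    file.path(dirname(path), df$path))
  missing <- df$path[!file.exists(df$path)]
  if (length(missing))
    stop("manifest path(s) do not resolve: ", paste(missing, collapse = ", "))
  df[order(df$subject_id, df$run_id), , drop = FALSE]
}

#' Load all runs listed in a manifest
#'
#' @param manifest data.frame from [read_manifest()] (or a manifest path).
#' @param scheme optional `parcellation_scheme` applied to every run.
#' @return list of per-subject lists of two `run_timeseries`.
#' @export
load_manifest_runs <- function(manifest, scheme = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  subjects <- unique(manifest$subject_id)
  lapply(subjects, function(s) {
    rows <- manifest[manifest$subject_id == s, , drop = FALSE]
    lapply(seq_len(nrow(rows)), function(r) {
      ts <- read_timeseries(rows$path[r], scheme = scheme)
      attr(ts, "subject_id") <- rows$subject_id[r]
      attr(ts, "run_id") <- rows$run_id[r]
      ts
    })
  })
}

#' Write / read an analysis report as JSON
#'
#' Reports are plain nested lists of scalars, vectors and small matrices;
#' serialization keeps full numeric precision so a written report re-reads
#' to equal values.
#'
#' @param report a list (class `analysis_report` tolerated).
#' @param path JSON file path.
#' @return `write_report` returns `path` invisibly; `read_report` a list.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
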