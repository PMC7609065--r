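#' Read intensity traces from plain-text files
#'
#' Reads whitespace- or tab-delimited ASCII trace files of the kind
#' exported by common TIRF analysis software. Leading lines that do not
#' parse as data (comments starting with `#`, free-text headers) are kept
#' as metadata; a column-name row is honored when present. Data columns
#' are, in order: frame index (0-based), DD, DA, optionally AA, and
#' optionally a ground-truth label column. Files with two intensity
#' columns produce non-ALEX traces (stoichiometry undefined), files with
#' three produce ALEX traces.
#'
#' @param path A file, a directory (all `*.txt`/`*.tsv` files within), or a
#'   character vector of files.
#' @param dialect Reserved for explicit dialect selection; `"auto"` sniffs
#'   column count and headers.
#' @return A list of [fret_trace()] objects. Any label column is attached
#'   as attribute `"labels"` on the trace and the source path is stored in
#'   `meta$source`.
#' @export
read_traces <- function(path, dialect = c("auto", "ismslike", "simple")) {
  dialect <- match.arg(dialect)
  files <- if (length(path) == 1L && dir.exists(path)) {
    list.files(path, pattern = "\\.(txt|tsv|dat)$", full.names = TRUE)
  } else {
    path
  }
  if (length(files) == 0L) stop("no trace files found at ", path)
  lapply(files, read_one_trace)
}

read_one_trace <- function(file) {
  lines <- readLines(file, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    stop("empty trace file: ", file)
  }
  is_data_line <- function(x) {
    tok <- strsplit(trimws(x), "\\s+")[[1]]
    length(tok) >= 2L && !is.na(suppressWarnings(as.numeric(tok[1])))
  }
  first_data <- which(vapply(lines, is_data_line, logical(1)))[1]
  if (is.na(first_data)) stop("no numeric data block in ", file)
  header_lines <- if (first_data > 1L) lines[seq_len(first_data - 1L)] else
    character(0)
  col_names <- NULL
  if (length(header_lines)) {
    cand <- trimws(sub("^#", "", header_lines[length(header_lines)]))
    tok <- strsplit(cand, "\\s+")[[1]]
    if (length(tok) >= 3L && all(is.na(suppressWarnings(as.numeric(tok))))) {
      col_names <- tok
    }
  }
  dat <- tryCatch(
    read.table(text = lines[first_data:length(lines)], header = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) {
      stop("parse error in ", file, " (data starts at line ", first_data,
           "): ", conditionMessage(e), call. = FALSE)
    }
  )
  is_num <- vapply(dat, is.numeric, logical(1))
  # trailing non-numeric column = label column
  labels <- NULL
  if (!is_num[length(is_num)]) {
    lab <- as.character(dat[[length(is_num)]])
    if (!all(lab %in% FRET_CLASSES)) {
      bad <- which(!is_num)[1]
      stop("non-numeric cells in data block of ", file, " (column ", bad,
           ", first at line ", first_data, ")", call. = FALSE)
    }
    labels <- lab
    dat <- dat[, -length(is_num), drop = FALSE]
    is_num <- is_num[-length(is_num)]
  }
  if (!all(is_num)) {
    stop("non-numeric cells in data block of ", file, " (column ",
         which(!is_num)[1], ", data starting line ", first_data, ")",
         call. = FALSE)
  }
  nc <- ncol(dat)
  if (nc < 3L) stop("expected at least frame, DD, DA columns in ", file)
  frames <- dat[[1]]
  if (any(diff(frames) != 1)) {
    stop("frame indices must be contiguous in ", file)
  }
  tr <- fret_trace(dd = dat[[2]], da = dat[[3]],
                   aa = if (nc >= 4L) dat[[4]] else NULL,
                   meta = list(source = file, header = header_lines,
                               col_names = col_names))
  if (!is.null(labels)) attr(tr, "labels") <- labels
  tr
}

#' Write traces to plain-text files
#'
#' One file per trace with a commented header and a column-name row;
#' columns are frame (0-based), DD, DA, AA (ALEX only) and, when
#' requested and available, the ground-truth label. Values are written at
#' full precision so a read/write round trip is the identity.
#'
#' @param traces A list of [fret_trace()] or `labeled_trace` objects.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; files are named
#'   `<prefix>_<index>.txt` with zero-padded indices.
#' @param include_labels Write the label column for labelled traces?
#' @return Invisibly, the vector of files written.
#' @export
write_traces <- function(traces, dir, prefix = "trace",
                         include_labels = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (length(traces) == 0L) return(invisible(character(0)))
  width <- max(4L, nchar(as.character(length(traces))))
  files <- character(length(traces))
  for (i in seq_along(traces)) {
    obj <- traces[[i]]
    labels <- NULL
    if (inherits(obj, "labeled_trace")) {
      labels <- as.character(obj$labels)
      tr <- obj$trace
    } else {
      tr <- obj
      labels <- attr(tr, "labels")
    }
    stopifnot(inherits(tr, "fret_trace"))
    df <- data.frame(frame = seq_len(tr$n_frames) - 1L, DD = tr$dd,
                     DA = tr$da)
    if (!is.null(tr$aa)) df$AA <- tr$aa
    if (include_labels && !is.null(labels)) df$label <- labels
    f <- file.path(dir, sprintf("%s_%0*d.txt", prefix, width, i))
    con <- file(f, "w")
    writeLines(c("# exported intensity trace",
                 paste0("# ", paste(names(df), collapse = "\t"))), con)
    write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    close(con)
    files[i] <- f
  }
  invisible(files)
}

#' Write the simulation manifest of a dataset
#'
#' Records the per-trace generative configuration (class, states, noise,
#' bleach times, ...) of a simulated dataset as JSON, next to the exported
#' trace files, so any trace can be audited or regenerated.
#'
#' @param dataset A [generate_dataset()] result.
#' @param path Output JSON file.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(dataset, path) {
  stopifnot(inherits(dataset, "fret_dataset"))
  manifest <- list(seed = dataset$seed, params = unclass(dataset$params),
                   traces = dataset$summary)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
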