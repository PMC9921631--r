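#' Read intensity traces from CSV
#'
#' Expects columns `frame` and `value`, plus optionally `trace` (or
#' `region_id`) to distinguish several traces in one file.
#'
#' @param path CSV file path.
#' @return A `trace_set` tibble with columns `trace`, `frame`, `value`.
#' @export
read_traces <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("region_id" %in% names(tb) && !"trace" %in% names(tb)) {
    tb$trace <- tb$region_id
  }
  missing <- setdiff(c("frame", "value"), names(tb))
  if (length(missing)) {
    stop("trace file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"trace" %in% names(tb)) tb$trace <- 1L
  bad <- which(!is.finite(tb$frame) | !is.finite(tb$value))
  if (length(bad)) {
    stop("malformed trace rows (non-numeric frame/value) at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), call. = FALSE)
  }
  new_trace_set(tibble::tibble(trace = tb$trace,
                               frame = as.integer(tb$frame),
                               value = as.numeric(tb$value)))
}

#' Write intensity traces to CSV
#'
#' @param traces A `trace_set` tibble (columns `trace`, `frame`, `value`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  stopifnot(all(c("trace", "frame", "value") %in% names(traces)))
  readr::write_csv(traces[, c("trace", "frame", "value")], path)
  invisible(path)
}

#' Write a movie as multi-page 16-bit TIFF
#'
#' Detector units are clipped to `[0, 65535]` and rounded; one page per
#' frame.
#'
#' @param movie A `synthetic_movie` or `height x width x n_frames` array.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  frames <- if (inherits(movie, "synthetic_movie")) movie$frames else movie
  stopifnot(length(dim(frames)) == 3)
  pages <- lapply(seq_len(dim(frames)[3]), function(t) {
    img <- pmin(pmax(round(frames[, , t]), 0), 65535)
    img / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF stack as a frame array
#'
#' @param path TIFF file path.
#' @return `height x width x n_frames` array in detector units (16-bit
#'   values).
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  out <- array(0, dim = c(H, W, length(pages)))
  for (t in seq_along(pages)) out[, , t] <- pages[[t]] * 65535
  out
}

#' Write a counting report as JSON
#'
#' @param report A `count_report` ([run_pipeline()]) or any list.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$estimates <- if (!is.null(out$estimates)) {
    as.data.frame(out$estimates)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows", force = TRUE)
  invisible(path)
}

#' Read a pipeline configuration from JSON or YAML
#'
#' @param path Path ending in `.json`, `.yaml` or `.yml`.
#' @return The configuration list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configs",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    stop("unsupported config format: .", ext, call. = FALSE)
  }
}
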