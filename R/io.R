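#' Read and write phase tables and keypress traces
#'
#' The package's on-disk dialects are plain CSV. Phase tables are long,
#' with header `subject,delta_i_db,repetition,percept,onset_s,`
#' `duration_s,censored` (percept SIM/AM, onsets in seconds from trial
#' start, 0-based). Traces have header `time_s,left_key,right_key` at
#' the configured sampling rate.
#'
#' @param phases,trace Tibbles to write.
#' @param path File path.
#' @return The tibble read, or (for writers) the input invisibly.
#' @name rivalry_io
NULL

#' @rdname rivalry_io
#' @export
write_phase_table <- function(phases, path) {
  assert_phase_table(phases)
  readr::write_csv(phases, path)
  invisible(phases)
}

#' @rdname rivalry_io
#' @export
read_phase_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           percept = readr::col_character(),
                           onset_s = readr::col_double(),
                           duration_s = readr::col_double(),
                           censored = readr::col_logical(),
                           .default = readr::col_guess()
                         ))
  assert_phase_table(out)
  out
}

#' @rdname rivalry_io
#' @export
write_trace <- function(trace, path) {
  if (!all(c("time_s", "left_key", "right_key") %in% names(trace))) {
    abort("`trace` needs `time_s`, `left_key`, `right_key` columns.")
  }
  readr::write_csv(trace, path)
  invisible(trace)
}

#' @rdname rivalry_io
#' @export
read_trace <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = "dii")
  if (!all(c("time_s", "left_key", "right_key") %in% names(out))) {
    abort(paste0("file ", path, " is not a trace CSV (expected header ",
                 "time_s,left_key,right_key)."))
  }
  out
}

#' Load a directory of rivalry data files
#'
#' Auto-detects the dialect of every CSV file in a directory: files
#' whose header matches the phase-table dialect are stacked into one
#' phase table, trace files are returned as a named list. Files with
#' an unrecognized header are reported in an error, never guessed
#' silently. Intended as the entry point for externally deposited
#' datasets that follow (or are converted to) these dialects.
#'
#' @param dir Directory containing `.csv` files.
#' @return List with `phases` (one stacked tibble or `NULL`) and
#'   `traces` (named list of trace tibbles).
#' @export
read_rivalry_dir <- function(dir) {
  if (!dir.exists(dir)) abort(paste0("directory not found: ", dir))
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) abort(paste0("no .csv files in ", dir))
  phase_tabs <- list()
  traces <- list()
  bad <- character()
  for (f in files) {
    hdr <- names(readr::read_csv(f, n_max = 0, show_col_types = FALSE))
    if (all(c("percept", "onset_s", "duration_s") %in% hdr)) {
      phase_tabs[[f]] <- read_phase_table(f)
    } else if (all(c("time_s", "left_key", "right_key") %in% hdr)) {
      traces[[basename(f)]] <- read_trace(f)
    } else {
      bad <- c(bad, basename(f))
    }
  }
  if (length(bad)) {
    abort(paste0("unrecognized header in file(s): ", paste(bad, collapse = ", "),
                 "; expected the phase-table or trace dialect."))
  }
  list(
    phases = if (length(phase_tabs)) dplyr::bind_rows(phase_tabs) else NULL,
    traces = traces
  )
}
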