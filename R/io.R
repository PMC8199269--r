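#' Write a cohort to CSV with a JSON sidecar
#'
#' One row per subject; the `episodes` list-column is serialised as a JSON
#' array (objects with `start_offset` and `duration`, seconds) in a single
#' column. The generating [cohort_spec()] (including the seed), when present,
#' is written to `<path>.spec.json` so every file is traceable to its
#' parameters.
#'
#' @param cohort A cohort `data.frame` from [generate_cohort()] (or the same
#'   layout read from disk).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  if (!is.null(out$episodes)) {
    out$episodes <- vapply(
      out$episodes,
      function(e) as.character(jsonlite::toJSON(e, digits = NA)),
      character(1)
    )
  }
  utils::write.csv(out, path, row.names = FALSE)
  spec <- attr(cohort, "cohort_spec")
  if (!is.null(spec)) {
    jsonlite::write_json(unclass(spec), paste0(path, ".spec.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort()]
#'
#' @param path CSV path; a `<path>.spec.json` sidecar, if present, is
#'   re-attached as the `"cohort_spec"` attribute.
#' @return A cohort `data.frame` with the `episodes` list-column restored.
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(cohort$episodes)) {
    cohort$episodes <- lapply(cohort$episodes, function(s) {
      e <- jsonlite::fromJSON(s)
      if (!length(e)) {
        data.frame(start_offset = numeric(0), duration = numeric(0))
      } else {
        as.data.frame(e)
      }
    })
  }
  sidecar <- paste0(path, ".spec.json")
  if (file.exists(sidecar)) {
    raw <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(cohort, "cohort_spec") <- raw
  }
  cohort
}
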