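# Cohort-table I/O: comma-separated person-level table (header row, UTF-8,
# empty cells for missing values) plus a JSON sidecar holding the column
# metadata, the generating specifications and the simulation truth, so a
# written cohort round-trips losslessly.

#' Write a cohort table (and its metadata sidecar) to disk
#'
#' @param sim either the list returned by [generate_cohort()] or a bare
#'   `cohort_table`.
#' @param path path of the CSV file to create; the sidecar is written next
#'   to it as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(sim, path) {
  tab <- if (is.data.frame(sim)) sim else sim$table
  truth <- if (is.data.frame(sim)) NULL else sim$truth
  meta <- attr(tab, "outcome_meta")
  columns <- lapply(tab, function(col) {
    if (is.factor(col)) {
      list(type = if (is.ordered(col)) "ordered" else "factor",
           levels = levels(col))
    } else if (is.logical(col)) {
      list(type = "logical")
    } else {
      list(type = "numeric")
    }
  })
  utils::write.csv(tab, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  sidecar <- list(columns = columns,
                  confounders = attr(tab, "confounders"),
                  outcome_meta = meta,
                  truth = truth)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a cohort table written by [write_cohort()]
#'
#' @param path path of the CSV file; the `<path>.json` sidecar must exist.
#' @return A list with `table` (a `cohort_table`) and `truth` (data frame or
#'   `NULL`).
#' @export
read_cohort <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- utils::read.csv(path, na.strings = "", fileEncoding = "UTF-8",
                         stringsAsFactors = FALSE)
  for (nm in names(sidecar$columns)) {
    info <- sidecar$columns[[nm]]
    if (info$type %in% c("factor", "ordered")) {
      tab[[nm]] <- factor(tab[[nm]], levels = info$levels,
                          ordered = info$type == "ordered")
    } else if (info$type == "logical") {
      tab[[nm]] <- as.logical(tab[[nm]])
    }
  }
  meta <- sidecar$outcome_meta
  # JSON round-trip turns bound pairs into plain vectors; keep them numeric
  meta <- lapply(meta, function(m) {
    m$bounds <- as.numeric(m$bounds)
    m
  })
  attr(tab, "confounders") <- sidecar$confounders
  attr(tab, "outcome_meta") <- meta
  class(tab) <- c("cohort_table", "data.frame")
  truth <- sidecar$truth
  if (!is.null(truth)) truth <- as.data.frame(truth)
  list(table = tab, truth = truth)
}
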