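#' Write a stage result with a JSON parameter sidecar
#'
#' Tabular results are written as TSV; a JSON sidecar (same path with a
#' `.json` extension) records the parameters, the seed, and the package
#' version, with alphabetically ordered fields so reruns are byte-comparable.
#' Non-tabular results (named lists of scalars) are written as a one-row TSV.
#'
#' @param result data frame, or a named list of scalar values.
#' @param path output TSV path.
#' @param params named list of parameters to record (an [analysis_config]
#'   is accepted directly).
#' @param seed seed to record, or `NULL`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, params = list(), seed = NULL) {
  if (inherits(params, "analysis_config")) params <- unclass(params)
  if (!is.data.frame(result)) {
    if (!is.list(result) || is.null(names(result))) {
      stop("result must be a data frame or a named list", call. = FALSE)
    }
    scalars <- result[vapply(result, function(x)
      is.atomic(x) && length(x) == 1L, logical(1))]
    result <- as.data.frame(scalars, stringsAsFactors = FALSE)
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ok <- tryCatch({
    utils::write.table(result, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) {
    stop("cannot write report to '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (length(params)) params <- params[order(names(params))]
  meta <- list(
    parameters = params,
    seed = seed,
    software = paste0("biomepipe ",
                      as.character(utils::packageVersion("biomepipe")))
  )
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read back the JSON sidecar of a report
#'
#' @param path the TSV path passed to [write_report].
#' @return The sidecar contents as a list.
#' @export
read_report_sidecar <- function(path) {
  jsonlite::read_json(paste0(tools::file_path_sans_ext(path), ".json"),
                      simplifyVector = TRUE)
}
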