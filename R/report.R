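#' Serialize a result to JSON
#'
#' Writes a versioned JSON report for a `selection_result`, an
#' `eval_report`, or a fitted `csadt` object, with the resolved
#' configuration and history arrays embedded so a saved report documents
#' the run that produced it. Identical runs write byte-identical files.
#'
#' @param result A `selection_result`, `eval_report`, or `csadt` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  obj <- as_report(result)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#'
#' @param path Path to the report.
#' @return A list mirroring the JSON structure.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

as_report <- function(result) UseMethod("as_report")

#' @export
as_report.selection_result <- function(result) {
  list(schema = "csadt-report/1", type = "selection",
       mask = result$mask$bits,
       n_selected = result$mask$n_selected,
       selected = as.list(result$selected),
       fitness = list(total = result$fitness$total,
                      error_rate = result$fitness$error_rate,
                      subset_ratio = result$fitness$subset_ratio),
       history = result$history,
       n_evals = result$n_evals,
       config = list(csa = unclass(result$csa_config),
                     fitness = unclass(result$fitness_config),
                     classifier = list(name = result$classifier$name,
                                       seed = result$classifier$seed,
                                       params = result$classifier$params),
                     direction = result$direction))
}

#' @export
as_report.eval_report <- function(result) {
  list(schema = "csadt-report/1", type = "evaluation",
       counts = list(tp = result$counts$tp, tn = result$counts$tn,
                     fp = result$counts$fp, fn = result$counts$fn),
       accuracy = result$accuracy, precision = result$precision,
       recall = result$recall, f1 = result$f1,
       undefined = as.list(result$undefined),
       positive_label = result$positive)
}

#' @export
as_report.csadt <- function(result) {
  list(schema = "csadt-report/1", type = "csadt_fit",
       seed = result$seed,
       n_samples = result$n_samples,
       n_features = length(result$feature_names),
       selection = as_report(result$selection),
       evaluation = as_report(result$report),
       positive_label = result$positive)
}
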