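#' Write a classification report as JSON
#'
#' Serializes a leave-one-out classification result together with the ranked
#' feature-class correlations into a single JSON report: confusion matrix,
#' accuracy (as a percentage), per-dyad predictions, and the feature table
#' ordered by decreasing \code{|r|} with its p-values. Regenerating the
#' report from the same inputs yields a byte-identical file.
#'
#' @param result A \code{classification_result} from [loo_evaluate()].
#' @param correlations Data frame from [feature_class_correlations()] (may
#'   have zero rows).
#' @param path Output JSON file.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(result, correlations, path) {
  stopifnot(inherits(result, "classification_result"))
  corr <- correlations
  if (is.null(corr) || nrow(corr) == 0) {
    corr <- data.frame(feature = character(), modality = character(),
                       r = numeric(), p = numeric())
  }
  corr <- corr[order(-abs(corr$r)), , drop = FALSE]
  rownames(corr) <- NULL
  payload <- list(
    classes = result$classes,
    confusion = result$confusion,
    n = sum(result$confusion),
    accuracy = result$accuracy,
    accuracy_pct = accuracy_from_counts(
      sum(result$confusion),
      sum(result$confusion) - sum(diag(result$confusion))),
    predictions = data.frame(dyad_id = result$dyad_id,
                             truth = result$truth,
                             predicted = result$predicted),
    features = corr
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read back a JSON classification report
#'
#' @param path Report file written by [write_report()].
#' @return A list with the report fields; \code{confusion} is a 2x2 matrix.
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep$confusion <- matrix(as.numeric(rep$confusion), nrow = 2,
                          dimnames = list(rep$classes, rep$classes))
  rep
}
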