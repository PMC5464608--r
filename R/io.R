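# Plain-text serialization of pipeline artifacts.

#' Write shadow-ranked features as TSV
#'
#' Columns: feature id, FWER, mean importance, rank.
#'
#' @param ranked a [compute_fwer()] result.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_ranked_features <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_features"))
  utils::write.table(ranked$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write ensemble predictions as TSV
#'
#' Columns: sample id, votes, probability, label.
#'
#' @param prediction an [predict.icap_ensemble()] result.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_predictions <- function(prediction, path) {
  stopifnot(inherits(prediction, "icap_prediction"))
  utils::write.table(prediction$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an active-learning transcript as JSON
#'
#' One record per iteration: the chosen sample, the committed probability
#' and prediction, the revealed label and the chained hash.
#'
#' @param transcript an [active_loop()] result.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_transcript <- function(transcript, path) {
  stopifnot(inherits(transcript, "active_transcript"))
  jsonlite::write_json(transcript$transcript, path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
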