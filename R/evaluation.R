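# Average precision and MAP over TREC-style runs and qrels.
# Relevance is binary: any grade >= 1 counts as relevant, and AP is
# normalized by the total number of relevant documents even when the run
# retrieves fewer (trec_eval convention).

#' Average precision of one ranking
#'
#' `AP = (1/R) * sum over relevant retrieved docs of precision at their
#' rank`, with `R` the total number of relevant documents. Relevant
#' documents absent from the ranking contribute 0.
#'
#' @param ranked Character vector of doc ids, best first, duplicate-free.
#' @param relevant Character vector (or set) of relevant doc ids.
#' @return AP in `[0, 1]`, or `NA` when `R = 0` (such topics are skipped,
#'   not scored 0).
#' @examples
#' average_precision(c("B", "A"), "A") # 0.5
#' @export
average_precision <- function(ranked, relevant) {
  ranked <- as.character(ranked)
  relevant <- unique(as.character(relevant))
  if (anyDuplicated(ranked)) {
    stop(sprintf("ranking contains duplicate doc id: %s",
                 ranked[duplicated(ranked)][1]))
  }
  if (!length(relevant)) return(NA_real_)
  hits <- ranked %in% relevant
  if (!any(hits)) return(0)
  sum(cumsum(hits)[hits] / seq_along(hits)[hits]) / length(relevant)
}

#' Evaluate a run against qrels
#'
#' Computes per-topic average precision and its mean (MAP) over all topics
#' that have at least one relevant document in the qrels. Topics judged in
#' the qrels but missing from the run score `AP = 0`; topics with no
#' relevant documents are skipped.
#'
#' @param run Either a data.frame as returned by [read_run()] (columns
#'   `topic`, `doc_id`, `rank`) or a named list mapping topic id to a
#'   ranking data.frame with a `doc_id` column, best first.
#' @param qrels Data.frame with columns `topic`, `doc_id`, `grade` (see
#'   [read_qrels()]).
#' @return An `eval_report`: list with `per_topic` (named AP vector),
#'   `map`, `n_evaluated`, `n_skipped`.
#' @export
evaluate_run <- function(run, qrels) {
  rankings <- if (is.data.frame(run)) {
    run <- run[order(run$topic, run$rank), , drop = FALSE]
    split(run$doc_id, run$topic)
  } else {
    lapply(run, function(df) df$doc_id)
  }
  topics <- sort(unique(qrels$topic))
  ap <- numeric()
  skipped <- 0L
  for (t in topics) {
    rel <- qrels$doc_id[qrels$topic == t & qrels$grade >= 1L]
    if (!length(rel)) {
      skipped <- skipped + 1L
      next
    }
    ranked <- rankings[[t]]
    if (is.null(ranked)) ranked <- character()
    ap[[t]] <- average_precision(ranked, rel)
  }
  structure(list(per_topic = ap,
                 map = if (length(ap)) mean(ap) else NA_real_,
                 n_evaluated = length(ap), n_skipped = skipped),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("MAP %.4f over %d topic(s) (%d skipped, no relevant docs)\n",
              x$map, x$n_evaluated, x$n_skipped))
  invisible(x)
}
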