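#' Predict the match winner from the momentum differential
#'
#' Forms one match-level momentum score per player from the series
#' according to `params$prediction_mode` — `"mean"` (mean momentum over the
#' match, the default), `"final"` (last point's momentum) or
#' `"cumulative"` (sum over points) — adds the break-point set adjustments
#' (summed over sets), and predicts the player with the higher score.
#' Ties break to the player with more total points won, then to player 1,
#' so predictions are deterministic.
#'
#' @param series a `momentum_series`.
#' @param m the `match_record` the series came from (supplies the actual
#'   winner when derivable from `set_victor`).
#' @param params a [momentum_params()] object.
#' @return An object of class `prediction_result`: list with `match_id`,
#'   `predicted_winner`, `momentum_differential` (score 1 minus score 2),
#'   `scores`, `actual_winner` (NA when underivable), `correct`,
#'   `set_scores`.
#' @export
predict_winner <- function(series, m, params = momentum_params()) {
  stopifnot(inherits(series, "momentum_series"))
  n <- nrow(series$M)
  if (n == 0L) stop("empty momentum series", call. = FALSE)
  ss <- series$set_scores
  score <- numeric(2)
  for (x in 1:2) {
    adj <- params$w_bp_created * sum(ss[[paste0("bp_created_", x)]]) +
      params$w_bp_converted * sum(ss[[paste0("bp_converted_", x)]])
    base <- switch(params$prediction_mode,
                   final = series$M[n, x],
                   mean = mean(series$M[, x]),
                   cumulative = sum(series$M[, x]))
    score[x] <- base + adj
  }
  pred <- if (score[1] > score[2]) 1L else if (score[2] > score[1]) 2L else {
    tot <- c(sum(m$points$point_victor == 1), sum(m$points$point_victor == 2))
    if (tot[1] >= tot[2]) 1L else 2L
  }
  actual <- actual_winner(m)
  out <- list(match_id = series$match_id, predicted_winner = pred,
              momentum_differential = score[1] - score[2], scores = score,
              actual_winner = actual,
              correct = if (is.na(actual)) NA else pred == actual,
              set_scores = ss)
  class(out) <- "prediction_result"
  out
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction> %s: predicts player %d (differential %+0.4f)%s\n",
              x$match_id, x$predicted_winner, x$momentum_differential,
              if (is.na(x$actual_winner)) "" else
                sprintf("; actual %d [%s]", x$actual_winner,
                        if (x$correct) "correct" else "wrong")))
  invisible(x)
}

# Actual winner: explicit simulator annotation wins; otherwise the player
# with more set victories.
actual_winner <- function(m) {
  if (!is.null(m$meta$winner) && !is.na(m$meta$winner))
    return(as.integer(m$meta$winner))
  sv <- m$points$set_victor
  sv <- sv[!is.na(sv) & sv != 0]
  if (!length(sv)) return(NA_integer_)
  s1 <- sum(sv == 1); s2 <- sum(sv == 2)
  if (s1 == s2) NA_integer_ else if (s1 > s2) 1L else 2L
}

#' Evaluate prediction accuracy over a corpus
#'
#' Runs the full pipeline (event extraction, momentum series, prediction)
#' on every match, compares against the actual winner, and reports the
#' fraction predicted correctly. Matches whose winner cannot be derived
#' are skipped with a warning and counted in `n_skipped`.
#'
#' @param corpus a `match_corpus`.
#' @param params a [momentum_params()] object.
#' @param modes prediction modes to evaluate; defaults to
#'   `params$prediction_mode`. The first is the headline accuracy.
#' @return List with `accuracy` (headline mode), `accuracy_by_mode`,
#'   `results` (per-match data frame sorted by match_id), `n_skipped`.
#' @export
evaluate_corpus <- function(corpus, params = momentum_params(),
                            modes = params$prediction_mode) {
  stopifnot(inherits(corpus, "match_corpus"))
  rows <- list()
  skipped <- 0L
  for (m in corpus) {
    if (is.na(actual_winner(m))) {
      warning("match ", m$match_id, " has no derivable winner; skipped",
              call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    fl <- extract_flags(m, params)
    ser <- momentum_series(m, fl, params)
    for (mode in modes) {
      pm <- params; pm$prediction_mode <- mode
      pr <- predict_winner(ser, m, pm)
      rows[[length(rows) + 1L]] <- data.frame(
        match_id = pr$match_id, mode = mode,
        predicted_winner = pr$predicted_winner,
        actual_winner = pr$actual_winner,
        momentum_differential = pr$momentum_differential,
        correct = pr$correct, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no evaluable matches in corpus", call. = FALSE)
  res <- do.call(rbind, rows)
  res <- res[order(res$match_id), , drop = FALSE]
  rownames(res) <- NULL
  acc <- vapply(modes, function(md) mean(res$correct[res$mode == md]),
                numeric(1))
  list(accuracy = unname(acc[1L]),
       accuracy_by_mode = acc,
       results = res, n_skipped = skipped)
}
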