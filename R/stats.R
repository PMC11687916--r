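#' Pearson chi-square test of independence on a contingency table
#'
#' Computes the Pearson statistic \eqn{\sum (O - E)^2 / E} with expected
#' counts from the row/column marginals, `df = (r-1)(c-1)`, and the p-value
#' from the chi-square upper tail. No continuity correction is applied by
#' default; the Yates correction (2x2 tables only) is available via
#' `correction = TRUE`. A reported p-value of 0 is floored at `1e-300`
#' ("significance 0.00" is read as p below working precision, never a
#' literal zero).
#'
#' @param tab matrix of nonnegative counts, at least 2x2.
#' @param correction apply the Yates continuity correction (2x2 only).
#' @return An object of class `chi_square_result`: list with `statistic`,
#'   `df`, `p_value`, `expected`.
#' @examples
#' chi_square(matrix(c(20, 10, 10, 20), 2))  # statistic 20/3
#' @export
chi_square <- function(tab, correction = FALSE) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("contingency table must be at least 2x2", call. = FALSE)
  if (any(tab < 0) || any(!is.finite(tab)))
    stop("counts must be finite and nonnegative", call. = FALSE)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("zero marginal: chi-square test invalid", call. = FALSE)
  E <- outer(rs, cs) / sum(tab)
  d <- abs(tab - E)
  if (correction) {
    if (!all(dim(tab) == c(2L, 2L)))
      stop("continuity correction applies to 2x2 tables only", call. = FALSE)
    d <- pmax(0, d - 0.5)
  }
  stat <- sum(d^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  out <- list(statistic = stat, df = df, p_value = max(p, 1e-300),
              expected = E)
  class(out) <- "chi_square_result"
  out
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square = %.4f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Server-versus-game-winner contingency table and hold rate
#'
#' Tallies every completed game of a corpus (points with nonzero
#' `game_victor`) into a 2x2 table of server identity against game winner,
#' and reports the server game-win ("hold") rate — the quantity observed
#' empirically at 0.84 in Grand Slam play.
#'
#' @param corpus a `match_corpus` or single `match_record`.
#' @return List with `table` (2x2 counts), `rate` (P(game winner ==
#'   server)), and `n_games`.
#' @export
server_outcome_table <- function(corpus) {
  if (inherits(corpus, "match_record")) corpus <- new_corpus(list(corpus))
  stopifnot(inherits(corpus, "match_corpus"))
  servers <- winners <- integer(0)
  for (m in corpus) {
    g <- m$points$game_victor
    keep <- !is.na(g) & g != 0
    servers <- c(servers, m$points$server[keep])
    winners <- c(winners, g[keep])
  }
  if (!length(servers)) stop("no completed games in corpus", call. = FALSE)
  tab <- table(factor(servers, 1:2, c("server=1", "server=2")),
               factor(winners, 1:2, c("winner=1", "winner=2")))
  list(table = unclass(tab), rate = mean(servers == winners),
       n_games = length(servers))
}

# Corpus-level summary of one indicator: the mean value (a rate for binary
# flags, per service point where serve-conditioned) plus the range of the
# underlying observations, used for pooled normalization.
indicator_value <- function(corpus, indicator) {
  num <- den <- 0
  lo <- Inf; hi <- -Inf
  for (m in corpus) {
    pts <- m$points
    fl <- suppressWarnings(extract_flags(m))
    sv1 <- sum(fl$serving_1); sv2 <- sum(fl$serving_2)
    obs <- switch(indicator,
      distance_run = c(pts$distance_run_1, pts$distance_run_2),
      serve_speed = pts$serve_speed,
      rally_count = pts$rally_count,
      double_fault = c(fl$n1_1[fl$serving_1 == 1], fl$n1_2[fl$serving_2 == 1]),
      unforced_error = c(fl$n2_1, fl$n2_2),
      ace = c(fl$p1_1[fl$serving_1 == 1], fl$p1_2[fl$serving_2 == 1]),
      winning_shot = c(fl$p2_1, fl$p2_2),
      three_consecutive_wins = c(fl$p3_1, fl$p3_2),
      three_consecutive_losses = c(fl$n3_1, fl$n3_2),
      stop("unknown indicator: ", indicator, call. = FALSE))
    obs <- obs[!is.na(obs)]
    num <- num + sum(obs); den <- den + length(obs)
    if (length(obs)) {
      lo <- min(lo, min(obs)); hi <- max(hi, max(obs))
    }
  }
  if (den == 0) c(value = NA_real_, lo = NA_real_, hi = NA_real_)
  else c(value = num / den, lo = lo, hi = hi)
}

#' Court-type variance summary of match indicators
#'
#' For each indicator, computes its corpus-level value (mean or rate) per
#' court type, scales the values to `[0, 1]` by the pooled min-max range of
#' the indicator's underlying observations across all courts (binary rates
#' are already on `[0, 1]`), and reports the population variance of the
#' normalized values across court types — small variance marks an
#' indicator stable across surfaces (hence usable in a surface-agnostic
#' momentum model), large variance a surface-sensitive one (serve speed,
#' rally count, aces).
#'
#' @param corpora named list of `match_corpus` objects, one per court type;
#'   at least two types.
#' @param indicators character vector of indicator names (see defaults).
#' @return Data frame: one row per indicator with the per-court normalized
#'   values and their population `variance`. Indicators missing for any
#'   court type are excluded with a warning.
#' @export
court_type_summary <- function(corpora,
                               indicators = c("distance_run", "serve_speed",
                                              "rally_count", "double_fault",
                                              "unforced_error", "ace",
                                              "winning_shot",
                                              "three_consecutive_wins",
                                              "three_consecutive_losses")) {
  stopifnot(is.list(corpora), length(corpora) >= 2L,
            !is.null(names(corpora)))
  rows <- list()
  for (ind in indicators) {
    res <- vapply(corpora, indicator_value, numeric(3), indicator = ind)
    vals <- res["value", ]
    if (any(is.na(vals))) {
      warning("indicator '", ind, "' missing for court type(s) ",
              paste(names(vals)[is.na(vals)], collapse = ", "),
              "; excluded", call. = FALSE)
      next
    }
    lo <- min(res["lo", ]); hi <- max(res["hi", ])
    norm <- if (hi == lo) rep(0, length(vals)) else (vals - lo) / (hi - lo)
    row <- as.data.frame(as.list(stats::setNames(norm, names(corpora))))
    row <- cbind(data.frame(indicator = ind), row,
                 data.frame(variance = mean((norm - mean(norm))^2)))
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}

#' Correlation matrix of the twelve event-flag streams
#'
#' Pearson correlation (equivalently the phi coefficient on binary
#' streams) between the six event flags of both players, with all points
#' of the corpus stacked. Structural identities of the two-player game show
#' up exactly: one player's three-win stream is the other's three-loss
#' stream, so those entries are +1.
#'
#' @param flags_list a list of [extract_flags()] outputs (or one).
#' @return A 12x12 symmetric matrix with unit diagonal, `NA` for streams
#'   with zero variance (reported with a warning).
#' @export
event_correlation <- function(flags_list) {
  if (inherits(flags_list, "event_flags")) flags_list <- list(flags_list)
  cols <- as.vector(outer(c("p1", "p2", "p3", "n1", "n2", "n3"), 1:2,
                          paste, sep = "_"))
  stacked <- do.call(rbind, lapply(flags_list, function(fl)
    as.matrix(fl[, cols])))
  if (nrow(stacked) < 2L) stop("need at least 2 points", call. = FALSE)
  sds <- apply(stacked, 2L, stats::sd)
  if (any(sds == 0))
    warning("zero-variance stream(s): ",
            paste(cols[sds == 0], collapse = ", "),
            "; correlations undefined (NA)", call. = FALSE)
  suppressWarnings(stats::cor(stacked))
}

#' Cumulative points / games / sets time series of a match
#'
#' Three nondecreasing step functions per player over the point index; the
#' final sets values identify the match winner.
#'
#' @param m a `match_record`.
#' @return Data frame with columns `point_no`, `points_1`, `points_2`,
#'   `games_1`, `games_2`, `sets_1`, `sets_2`.
#' @export
score_time_series <- function(m) {
  stopifnot(inherits(m, "match_record"))
  pts <- m$points
  gv <- ifelse(is.na(pts$game_victor), 0, pts$game_victor)
  sv <- ifelse(is.na(pts$set_victor), 0, pts$set_victor)
  data.frame(point_no = pts$point_no,
             points_1 = cumsum(pts$point_victor == 1),
             points_2 = cumsum(pts$point_victor == 2),
             games_1 = cumsum(gv == 1), games_2 = cumsum(gv == 2),
             sets_1 = cumsum(sv == 1), sets_2 = cumsum(sv == 2))
}

#' Plot the cumulative score time series of a match
#'
#' @param m a `match_record`.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the [score_time_series()] data frame.
#' @export
plot_score_series <- function(m, ...) {
  ts <- score_time_series(m)
  graphics::par(mfrow = c(3, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(mfrow = c(1, 1)))
  for (what in c("points", "games", "sets")) {
    y1 <- ts[[paste0(what, "_1")]]; y2 <- ts[[paste0(what, "_2")]]
    graphics::plot(ts$point_no, y1, type = "s", col = "#1b6ca8",
                   ylim = range(0, y1, y2), xlab = "point", ylab = what, ...)
    graphics::lines(ts$point_no, y2, type = "s", col = "#c23b22")
  }
  invisible(ts)
}
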