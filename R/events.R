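#' Detect k-point winning streaks
#'
#' Returns, for each point, whether `player` has won the last `k` points
#' ending at that point (inclusive). A flag therefore fires on the k-th and
#' every subsequent point of a longer run: a 5-point run with `k = 3` yields
#' flags on points 3, 4 and 5.
#'
#' @param victors integer sequence of point winners, values in `{1, 2}`.
#' @param k streak length, `>= 2`.
#' @param player 1 or 2.
#' @return A binary vector the same length as `victors`.
#' @examples
#' detect_streaks(c(1, 1, 1, 2, 1), k = 3, player = 1)  # 0 0 1 0 0
#' @export
detect_streaks <- function(victors, k = 3L, player) {
  if (k < 2L) stop("streak length k must be >= 2", call. = FALSE)
  stopifnot(player %in% c(1L, 2L), all(victors %in% c(1L, 2L)))
  n <- length(victors)
  if (n < k) return(integer(n))
  win <- as.integer(victors == player)
  cs <- c(0L, cumsum(win))
  flag <- integer(n)
  idx <- k:n
  flag[idx] <- as.integer(cs[idx + 1L] - cs[idx + 1L - k] == k)
  flag
}

#' Reconstruct break-point context for every point
#'
#' A break point is a point on the opponent's serve which, if won by the
#' receiver, wins the receiver the game. When the record carries raw
#' `break_pt_*` columns they are trusted; otherwise the game score is
#' replayed from `point_victor` within each `(set_no, game_no)` group.
#' Tiebreak games (entered when both players have won six games in a set,
#' tracked via `game_victor`) carry no break points.
#'
#' @param m a `match_record`.
#' @return Data frame with per-player columns `break_pt_1`, `break_pt_won_1`,
#'   `break_pt_2`, `break_pt_won_2` (1 = that player, as receiver, holds /
#'   converts a break point on this point).
#' @export
detect_break_points <- function(m) {
  stopifnot(inherits(m, "match_record"))
  pts <- m$points
  n <- nrow(pts)
  raw_ok <- all(c("break_pt_1", "break_pt_2") %in% names(pts)) &&
    !all(is.na(pts$break_pt_1)) && !all(is.na(pts$break_pt_2))
  if (raw_ok) {
    won1 <- pts$break_pt_won_1
    won2 <- pts$break_pt_won_2
    if (all(is.na(won1))) won1 <- ifelse(pts$break_pt_1 == 1 &
                                           pts$point_victor == 1, 1, 0)
    if (all(is.na(won2))) won2 <- ifelse(pts$break_pt_2 == 1 &
                                           pts$point_victor == 2, 1, 0)
    return(data.frame(break_pt_1 = ifelse(is.na(pts$break_pt_1), 0, pts$break_pt_1),
                      break_pt_won_1 = ifelse(is.na(won1), 0, won1),
                      break_pt_2 = ifelse(is.na(pts$break_pt_2), 0, pts$break_pt_2),
                      break_pt_won_2 = ifelse(is.na(won2), 0, won2)))
  }
  if (any(is.na(pts$set_no)) || any(is.na(pts$game_no)) ||
      any(is.na(pts$server))) {
    warning("break points not reconstructible (missing set/game/server); ",
            "flags absent", call. = FALSE)
    na <- rep(NA_real_, n)
    return(data.frame(break_pt_1 = na, break_pt_won_1 = na,
                      break_pt_2 = na, break_pt_won_2 = na))
  }
  bp1 <- bpw1 <- bp2 <- bpw2 <- numeric(n)
  games <- c(0L, 0L)       # games won in current set
  gpts <- c(0L, 0L)        # points won in current game
  cur_set <- pts$set_no[1L]
  cur_game <- pts$game_no[1L]
  for (i in seq_len(n)) {
    if (pts$set_no[i] != cur_set) {
      cur_set <- pts$set_no[i]; games <- c(0L, 0L); gpts <- c(0L, 0L)
      cur_game <- pts$game_no[i]
    } else if (pts$game_no[i] != cur_game) {
      cur_game <- pts$game_no[i]; gpts <- c(0L, 0L)
    }
    s <- pts$server[i]; r <- 3L - s
    tiebreak <- games[1L] >= 6L && games[2L] >= 6L
    if (!tiebreak && gpts[r] >= 3L && gpts[r] - gpts[s] >= 1L) {
      if (r == 1L) bp1[i] <- 1 else bp2[i] <- 1
      if (pts$point_victor[i] == r) {
        if (r == 1L) bpw1[i] <- 1 else bpw2[i] <- 1
      }
    }
    w <- pts$point_victor[i]
    gpts[w] <- gpts[w] + 1L
    gv <- pts$game_victor[i]
    if (!is.na(gv) && gv != 0) games[gv] <- games[gv] + 1L
  }
  data.frame(break_pt_1 = bp1, break_pt_won_1 = bpw1,
             break_pt_2 = bp2, break_pt_won_2 = bpw2)
}

#' Extract the six momentum-event flags per player per point
#'
#' Derives, for every point and both players, the binary flags driving the
#' momentum increment: `p1` winning serve (ace, or ace/untouched serve
#' winner depending on `params$p1_definition`), `p2` winning shot, `p3`
#' three consecutive points won, `n1` double fault, `n2` unforced error,
#' `n3` three consecutive points lost; plus serving and break-point context.
#'
#' Precedence rules: a winning serve suppresses the generic winning-shot
#' flag (one point contributes one gain event), and a double fault
#' suppresses the generic unforced-error flag. An opponent's unforced error
#' sets no positive flag for the scorer — only active winning situations
#' count. Absent raw indicator columns yield zero flags with one warning.
#'
#' @param m a `match_record` (violations allowed; see [validate_match()]).
#' @param params a [momentum_params()] object (only `p1_definition` is
#'   used here).
#' @return An `event_flags` data frame, one row per point, with columns
#'   `point_no`, `set_no`, and for each player `x`: `p1_x, p2_x, p3_x,
#'   n1_x, n2_x, n3_x, serving_x, break_pt_x, break_pt_won_x`.
#' @export
extract_flags <- function(m, params = momentum_params()) {
  stopifnot(inherits(m, "match_record"))
  pts <- m$points
  n <- nrow(pts)
  col0 <- function(name) {
    v <- pts[[name]]
    if (is.null(v) || all(is.na(v))) {
      warning("indicator column '", name, "' absent; contributing 0 flags",
              call. = FALSE)
      numeric(n)
    } else ifelse(is.na(v), 0, v)
  }
  bp <- detect_break_points(m)
  out <- data.frame(point_no = pts$point_no, set_no = pts$set_no)
  victors <- pts$point_victor
  for (x in 1:2) {
    serving <- as.integer(pts$server == x)
    ace <- col0(paste0("ace_", x))
    p1 <- serving * ace
    if (params$p1_definition == "ace_or_serve_winner") {
      sw <- col0(paste0("serve_winner_", x))
      p1 <- pmin(1, p1 + serving * sw)
    }
    winner <- col0(paste0("winner_", x))
    p2 <- as.integer(winner == 1 & p1 == 0)
    dfault <- col0(paste0("double_fault_", x))
    n1 <- serving * dfault
    unf <- col0(paste0("unf_err_", x))
    n2 <- as.integer(unf == 1 & n1 == 0)
    p3 <- detect_streaks(victors, 3L, x)
    n3 <- detect_streaks(victors, 3L, 3L - x)
    out[[paste0("p1_", x)]] <- as.numeric(p1)
    out[[paste0("p2_", x)]] <- as.numeric(p2)
    out[[paste0("p3_", x)]] <- as.numeric(p3)
    out[[paste0("n1_", x)]] <- as.numeric(n1)
    out[[paste0("n2_", x)]] <- as.numeric(n2)
    out[[paste0("n3_", x)]] <- as.numeric(n3)
    out[[paste0("serving_", x)]] <- serving
    out[[paste0("break_pt_", x)]] <-
      ifelse(is.na(bp[[paste0("break_pt_", x)]]), 0,
             bp[[paste0("break_pt_", x)]])
    out[[paste0("break_pt_won_", x)]] <-
      ifelse(is.na(bp[[paste0("break_pt_won_", x)]]), 0,
             bp[[paste0("break_pt_won_", x)]])
  }
  class(out) <- c("event_flags", "data.frame")
  out
}

#' Tally events per player over a match
#'
#' Column sums of the event flags in the shape of a winners/losers event
#' table: per-service-point rates for winning serves and double faults,
#' raw counts for winning shots, three-point runs, unforced errors and
#' three-point slumps, plus net-point and distance bookkeeping from the raw
#' columns.
#'
#' @param m a `match_record`.
#' @param flags output of [extract_flags()] for `m`.
#' @return Data frame with one row per player and columns
#'   `rate_winning_serve`, `n_winning_shots`, `n_three_consecutive_wins`,
#'   `rate_double_fault`, `n_unforced_errors`, `n_three_consecutive_losses`,
#'   `n_net_points`, `n_net_points_won`, `total_distance_run`.
#' @export
tally_events <- function(m, flags = extract_flags(m)) {
  stopifnot(inherits(m, "match_record"), nrow(flags) == nrow(m$points))
  pts <- m$points
  row_for <- function(x) {
    sv <- sum(flags[[paste0("serving_", x)]])
    rate <- function(cnt) if (sv > 0) cnt / sv else NA_real_
    data.frame(
      player = x,
      rate_winning_serve = rate(sum(flags[[paste0("p1_", x)]])),
      n_winning_shots = sum(flags[[paste0("p2_", x)]]),
      n_three_consecutive_wins = sum(flags[[paste0("p3_", x)]]),
      rate_double_fault = rate(sum(flags[[paste0("n1_", x)]])),
      n_unforced_errors = sum(flags[[paste0("n2_", x)]]),
      n_three_consecutive_losses = sum(flags[[paste0("n3_", x)]]),
      n_net_points = sum(pts[[paste0("net_pt_", x)]], na.rm = TRUE),
      n_net_points_won = sum(pts[[paste0("net_pt_won_", x)]], na.rm = TRUE),
      total_distance_run = sum(pts[[paste0("distance_run_", x)]], na.rm = TRUE)
    )
  }
  rbind(row_for(1L), row_for(2L))
}
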