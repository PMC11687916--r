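#' Create a fresh tennis scoring state
#'
#' Standard rules: games to 4 points win-by-2 with deuce continuation, sets
#' to 6 games win-by-2, a 7-point (win-by-2) tiebreak at six games all,
#' best-of-3 or best-of-5 sets. Serve alternates by game; within a tiebreak
#' the serve follows the 1-2-2-... pattern and the player who received
#' first in the tiebreak serves first in the next set.
#'
#' @param best_of 3 or 5.
#' @param server player serving the first game (1 or 2).
#' @param final_set_tiebreak play a tiebreak at 6-6 in the deciding set
#'   (default TRUE).
#' @return A `scoring_state` list.
#' @seealso [advance()]
#' @export
scoring_state <- function(best_of = 5L, server = 1L,
                          final_set_tiebreak = TRUE) {
  stopifnot(best_of %in% c(3L, 5L), server %in% c(1L, 2L))
  st <- list(points = c(0L, 0L), games = c(0L, 0L), sets = c(0L, 0L),
             server = as.integer(server), best_of = as.integer(best_of),
             tiebreak = FALSE, tb_points = c(0L, 0L), tb_played = 0L,
             set_no = 1L, game_no = 1L, point_no = 0L,
             final_set_tiebreak = isTRUE(final_set_tiebreak),
             finished = FALSE, winner = NA_integer_,
             game_victor = 0L, set_victor = 0L)
  class(st) <- "scoring_state"
  st
}

#' Advance the scoring state by one point
#'
#' Applies one point won by `point_winner` and returns the legal successor
#' state. The fields `game_victor` and `set_victor` of the returned state
#' report whether this point concluded a game and/or set (0 otherwise);
#' `finished`/`winner` report match completion.
#'
#' @param state a `scoring_state`.
#' @param point_winner 1 or 2.
#' @return The successor `scoring_state`.
#' @export
advance <- function(state, point_winner) {
  if (state$finished) stop("match already finished", call. = FALSE)
  w <- as.integer(point_winner); l <- 3L - w
  stopifnot(w %in% c(1L, 2L))
  st <- state
  st$point_no <- st$point_no + 1L
  st$game_victor <- 0L; st$set_victor <- 0L
  game_won <- FALSE
  if (st$tiebreak) {
    st$tb_points[w] <- st$tb_points[w] + 1L
    st$tb_played <- st$tb_played + 1L
    if (st$tb_points[w] >= 7L && st$tb_points[w] - st$tb_points[l] >= 2L) {
      game_won <- TRUE
    } else if (st$tb_played %% 2L == 1L) {
      # serve changes after point 1, then every two points
      st$server <- 3L - st$server
    }
  } else {
    st$points[w] <- st$points[w] + 1L
    if (st$points[w] >= 4L && st$points[w] - st$points[l] >= 2L)
      game_won <- TRUE
  }
  if (game_won) {
    st$games[w] <- st$games[w] + 1L
    st$game_victor <- w
    st$points <- c(0L, 0L)
    if (st$tiebreak) {
      # next-set server: whoever received the first point of the tiebreak
      st$server <- 3L - st$tb_first_server
      st$tiebreak <- FALSE
      st$tb_points <- c(0L, 0L); st$tb_played <- 0L
      set_won <- TRUE                       # tiebreak always decides the set
    } else {
      st$server <- 3L - st$server
      g <- st$games
      set_won <- g[w] >= 6L && g[w] - g[l] >= 2L
    }
    if (set_won) {
      st$sets[w] <- st$sets[w] + 1L
      st$set_victor <- w
      st$games <- c(0L, 0L)
      need <- st$best_of %/% 2L + 1L
      if (st$sets[w] >= need) {
        st$finished <- TRUE
        st$winner <- w
      } else {
        st$set_no <- st$set_no + 1L
        st$game_no <- 1L
      }
    } else {
      st$game_no <- st$game_no + 1L
      deciding <- sum(st$sets) == st$best_of - 1L
      if (st$games[1L] == 6L && st$games[2L] == 6L &&
          (st$final_set_tiebreak || !deciding)) {
        st$tiebreak <- TRUE
        st$tb_points <- c(0L, 0L); st$tb_played <- 0L
        st$tb_first_server <- st$server
      }
    }
  }
  st
}

#' Closed-form probability that the server wins a standard game
#'
#' For per-point server win probability `p` (points i.i.d.), the chance of
#' holding serve is
#' \deqn{p^4 (1 + 4q + 10q^2) + 20 p^3 q^3 \frac{p^2}{1 - 2pq}, \quad q = 1 - p,}
#' the first term covering wins to love/15/30 and the second the deuce
#' continuation (win by two from 3-3).
#'
#' @param p per-point probability the server wins, in `[0, 1]` (vectorised).
#' @return Probability the server wins the game.
#' @export
game_win_probability <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  q <- 1 - p
  deuce <- ifelse(p %in% c(0, 1), p, p^2 / (1 - 2 * p * q))
  p^4 * (1 + 4 * q + 10 * q^2) + 20 * p^3 * q^3 * deuce
}

#' Calibrate the per-point probability to a target game-win rate
#'
#' Inverts [game_win_probability()] by bisection, e.g. to find the per-point
#' serve-win probability whose game-level hold rate equals an empirically
#' observed value such as 0.84.
#'
#' @param target_game_prob desired probability of holding serve, in (0, 1).
#' @param tol residual tolerance (default 1e-12; the root satisfies
#'   `|game_win_probability(p*) - target| < 1e-10` comfortably).
#' @return The per-point probability `p*`.
#' @export
calibrate_point_prob <- function(target_game_prob, tol = 1e-12) {
  if (!(target_game_prob > 0 && target_game_prob < 1))
    stop("target game probability must be in (0, 1)", call. = FALSE)
  lo <- 0; hi <- 1
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (game_win_probability(mid) < target_game_prob) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Monte-Carlo simulation of independent service games
#'
#' Simulates `n` i.i.d. standard games at per-point server win probability
#' `p` and returns the fraction held by the server. Vectorised: a game
#' reaches deuce iff the server takes exactly 3 of the first 6 points
#' (otherwise whichever player has 4 of the 6 already won it at the moment
#' they reached 4); the deuce continuation is resolved in point pairs.
#' Serves as the independent stochastic oracle for
#' [game_win_probability()].
#'
#' @param n number of games.
#' @param p per-point server win probability.
#' @return Fraction of the `n` games won by the server.
#' @export
simulate_games <- function(n, p) {
  stopifnot(n >= 1, p >= 0, p <= 1)
  k <- stats::rbinom(n, 6L, p)           # server points among the first six
  won <- k >= 4L
  open <- which(k == 3L)                 # 3-3: deuce
  while (length(open)) {
    a <- stats::rbinom(length(open), 1L, p)
    b <- stats::rbinom(length(open), 1L, p)
    won[open[a == 1L & b == 1L]] <- TRUE
    decided <- a == b                    # 2-0 server or 0-2 receiver
    open <- open[!decided]
  }
  mean(won)
}
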