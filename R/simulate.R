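# Court-type effects enter only where cross-court variance is empirically
# large: serve speed, rally length and ace probability. Double-fault and
# unforced-error rates stay court-invariant.
court_profiles <- function() {
  list(
    grass = list(ace_given_won = 0.18, serve_speed_mean = 185,
                 rally_lambda = 3.0),
    hard  = list(ace_given_won = 0.15, serve_speed_mean = 195,
                 rally_lambda = 4.0),
    clay  = list(ace_given_won = 0.08, serve_speed_mean = 172,
                 rally_lambda = 5.2)
  )
}

#' Configuration of the stochastic point simulator
#'
#' The generative model emits one row per point with every raw indicator of
#' the canonical schema filled in a mutually consistent way: each point's
#' end is explained by exactly one of ace / untouched serve winner / rally
#' winner / unforced error / double fault. Net approaches are drawn so that
#' the long-run net-point success rate equals `net_success_prob` (default
#' 0.82, the empirically observed rate). Inter-point gaps are exponential
#' with mean 40 s, truncated to 15-180 s, so the forgetting coefficient is
#' exercised over its whole range.
#'
#' @param best_of 3 or 5 sets.
#' @param court_type `"hard"`, `"grass"` or `"clay"`; shifts serve speed,
#'   rally length and ace probability only.
#' @param p_serve length-2: per-point win probability of each player on
#'   their own serve. The default is calibrated so the game-level hold rate
#'   is the empirically observed 0.84 (see [calibrate_point_prob()]).
#' @param p_serve_winner probability a server-won non-ace point was an
#'   untouched serve winner.
#' @param p_double_fault probability a server-lost point was a double fault.
#' @param p_winner_shot probability a rally-ended point was finished by the
#'   winner's winning shot (otherwise the loser's unforced error).
#' @param net_approach_rate mean per-point probability that either player
#'   approaches the net.
#' @param net_success_prob long-run fraction of net approaches that win the
#'   point (default 0.82).
#' @param gap_mean_seconds,gap_range mean and truncation bounds of the
#'   inter-point gap distribution.
#' @param first_server player serving the first game.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(best_of = 5L, court_type = "hard",
                              p_serve = NULL,
                              p_serve_winner = 0.08,
                              p_double_fault = 0.12,
                              p_winner_shot = 0.45,
                              net_approach_rate = 0.25,
                              net_success_prob = 0.82,
                              gap_mean_seconds = 40,
                              gap_range = c(15, 180),
                              first_server = 1L) {
  court_type <- match.arg(court_type, c("hard", "grass", "clay"))
  if (is.null(p_serve))
    p_serve <- rep(calibrate_point_prob(0.84), 2L)
  cfg <- list(best_of = as.integer(best_of), court_type = court_type,
              p_serve = as.numeric(p_serve),
              p_serve_winner = p_serve_winner,
              p_double_fault = p_double_fault,
              p_winner_shot = p_winner_shot,
              net_approach_rate = net_approach_rate,
              net_success_prob = net_success_prob,
              gap_mean_seconds = gap_mean_seconds,
              gap_range = as.numeric(gap_range),
              first_server = as.integer(first_server),
              court = court_profiles()[[court_type]])
  probs <- c(cfg$p_serve, p_serve_winner, p_double_fault, p_winner_shot,
             net_approach_rate, net_success_prob)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  stopifnot(best_of %in% c(3L, 5L), gap_range[1] < gap_range[2])
  class(cfg) <- "simulation_config"
  cfg
}

# Inverse-CDF draw from Exponential(mean) truncated to [lo, hi]; one
# uniform per draw keeps the RNG stream length deterministic.
rgap <- function(n, mean, lo, hi) {
  rate <- 1 / mean
  plo <- stats::pexp(lo, rate); phi <- stats::pexp(hi, rate)
  stats::qexp(plo + stats::runif(n) * (phi - plo), rate)
}

#' Simulate one complete match
#'
#' Plays a full match through the scoring state machine ([advance()]) with
#' the stochastic event model of [simulation_config()], producing a
#' schema-valid `match_record` (zero [validate_match()] violations) whose
#' raw indicator columns are all filled. Ground-truth annotations for
#' oracle testing — the true event flags (including streaks computed by an
#' online run counter), break-point context from the state machine, and the
#' drawn inter-point gaps — are attached as `m$truth`.
#'
#' @param cfg a [simulation_config()].
#' @param seed integer seed; identical seeds give identical records.
#' @param match_id identifier stamped on every point.
#' @return A `match_record` with an extra `truth` element (data frame).
#' @export
simulate_match <- function(cfg = simulation_config(), seed = 1L,
                           match_id = sprintf("sim-%06d", seed)) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(seed)
  st <- scoring_state(cfg$best_of, cfg$first_server)
  cap <- 512L
  blank <- function() numeric(cap)
  col <- list(
    set_no = blank(), game_no = blank(), point_no = blank(),
    elapsed = blank(), server = blank(), victor = blank(),
    game_victor = blank(), set_victor = blank(),
    ace_1 = blank(), ace_2 = blank(), sw_1 = blank(), sw_2 = blank(),
    win_1 = blank(), win_2 = blank(), df_1 = blank(), df_2 = blank(),
    ue_1 = blank(), ue_2 = blank(), np_1 = blank(), np_2 = blank(),
    npw_1 = blank(), npw_2 = blank(), bp_1 = blank(), bp_2 = blank(),
    bpw_1 = blank(), bpw_2 = blank(), dist_1 = blank(), dist_2 = blank(),
    rally = blank(), speed = blank(),
    p3_1 = blank(), p3_2 = blank(), n3_1 = blank(), n3_2 = blank(),
    gap = blank()
  )
  grow <- function() {
    cap <<- cap * 2L
    col <<- lapply(col, function(v) c(v, numeric(length(v))))
  }
  # net approaches biased towards the point winner so that the success rate
  # among approaches is net_success_prob while the mean rate stays at
  # net_approach_rate
  a_win <- 2 * cfg$net_approach_rate * cfg$net_success_prob
  a_lose <- 2 * cfg$net_approach_rate * (1 - cfg$net_success_prob)
  elapsed <- 0
  run <- c(0L, 0L)   # current consecutive-points-won runs
  i <- 0L
  while (!st$finished) {
    i <- i + 1L
    if (i > cap) grow()
    s <- st$server; r <- 3L - s
    set_no <- st$set_no; game_no <- st$game_no
    bp_rec <- !st$tiebreak && st$points[r] >= 3L &&
      st$points[r] - st$points[s] >= 1L
    w <- if (stats::runif(1) < cfg$p_serve[s]) s else r
    l <- 3L - w
    # exactly one point-ending explanation
    ace <- sw <- dfault <- FALSE; winner_shot <- unf <- FALSE
    if (w == s) {
      u <- stats::runif(1)
      if (u < cfg$court$ace_given_won) ace <- TRUE
      else if (u < cfg$court$ace_given_won + cfg$p_serve_winner) sw <- TRUE
      else winner_shot <- stats::runif(1) < cfg$p_winner_shot
      if (!ace && !sw && !winner_shot) unf <- TRUE      # loser's error
    } else {
      if (stats::runif(1) < cfg$p_double_fault) dfault <- TRUE
      else winner_shot <- stats::runif(1) < cfg$p_winner_shot
      if (!dfault && !winner_shot) unf <- TRUE
    }
    rally <- if (ace) 1 else if (sw) 2 else if (dfault) 0 else
      3 + stats::rpois(1, cfg$court$rally_lambda)
    net_w <- stats::runif(1) < a_win
    net_l <- stats::runif(1) < a_lose
    speed <- stats::rnorm(1, cfg$court$serve_speed_mean, 8)
    d1 <- max(0, stats::rnorm(1, rally * 1.7, 1))
    d2 <- max(0, stats::rnorm(1, rally * 1.7, 1))
    gap <- rgap(1, cfg$gap_mean_seconds, cfg$gap_range[1], cfg$gap_range[2])
    elapsed <- elapsed + gap
    run[w] <- run[w] + 1L; run[l] <- 0L
    st <- advance(st, w)
    col$set_no[i] <- set_no; col$game_no[i] <- game_no; col$point_no[i] <- i
    col$elapsed[i] <- elapsed; col$server[i] <- s; col$victor[i] <- w
    col$game_victor[i] <- st$game_victor; col$set_victor[i] <- st$set_victor
    col$ace_1[i] <- as.numeric(ace && w == 1); col$ace_2[i] <- as.numeric(ace && w == 2)
    col$sw_1[i] <- as.numeric(sw && w == 1); col$sw_2[i] <- as.numeric(sw && w == 2)
    col$win_1[i] <- as.numeric(winner_shot && w == 1)
    col$win_2[i] <- as.numeric(winner_shot && w == 2)
    col$df_1[i] <- as.numeric(dfault && l == 1); col$df_2[i] <- as.numeric(dfault && l == 2)
    col$ue_1[i] <- as.numeric(unf && l == 1); col$ue_2[i] <- as.numeric(unf && l == 2)
    col$np_1[i] <- as.numeric((w == 1 && net_w) || (l == 1 && net_l))
    col$np_2[i] <- as.numeric((w == 2 && net_w) || (l == 2 && net_l))
    col$npw_1[i] <- as.numeric(w == 1 && net_w)
    col$npw_2[i] <- as.numeric(w == 2 && net_w)
    col$bp_1[i] <- as.numeric(bp_rec && r == 1)
    col$bp_2[i] <- as.numeric(bp_rec && r == 2)
    col$bpw_1[i] <- as.numeric(bp_rec && r == 1 && w == 1)
    col$bpw_2[i] <- as.numeric(bp_rec && r == 2 && w == 2)
    col$dist_1[i] <- d1; col$dist_2[i] <- d2
    col$rally[i] <- rally; col$speed[i] <- speed
    col$p3_1[i] <- as.numeric(run[1] >= 3L); col$p3_2[i] <- as.numeric(run[2] >= 3L)
    col$n3_1[i] <- as.numeric(run[2] >= 3L); col$n3_2[i] <- as.numeric(run[1] >= 3L)
    col$gap[i] <- gap
  }
  idx <- seq_len(i)
  pts <- data.frame(
    match_id = match_id,
    point_no = col$point_no[idx], set_no = col$set_no[idx],
    game_no = col$game_no[idx], elapsed_seconds = col$elapsed[idx],
    server = col$server[idx], point_victor = col$victor[idx],
    game_victor = col$game_victor[idx], set_victor = col$set_victor[idx],
    ace_1 = col$ace_1[idx], ace_2 = col$ace_2[idx],
    serve_winner_1 = col$sw_1[idx], serve_winner_2 = col$sw_2[idx],
    winner_1 = col$win_1[idx], winner_2 = col$win_2[idx],
    double_fault_1 = col$df_1[idx], double_fault_2 = col$df_2[idx],
    unf_err_1 = col$ue_1[idx], unf_err_2 = col$ue_2[idx],
    net_pt_1 = col$np_1[idx], net_pt_2 = col$np_2[idx],
    net_pt_won_1 = col$npw_1[idx], net_pt_won_2 = col$npw_2[idx],
    break_pt_1 = col$bp_1[idx], break_pt_2 = col$bp_2[idx],
    break_pt_won_1 = col$bpw_1[idx], break_pt_won_2 = col$bpw_2[idx],
    distance_run_1 = col$dist_1[idx], distance_run_2 = col$dist_2[idx],
    rally_count = col$rally[idx], serve_speed = col$speed[idx],
    stringsAsFactors = FALSE
  )
  m <- match_record(pts, court_type = cfg$court_type, best_of = cfg$best_of)
  m$meta$winner <- st$winner
  m$truth <- data.frame(
    point_no = col$point_no[idx],
    p3_1 = col$p3_1[idx], p3_2 = col$p3_2[idx],
    n3_1 = col$n3_1[idx], n3_2 = col$n3_2[idx],
    break_pt_1 = col$bp_1[idx], break_pt_2 = col$bp_2[idx],
    break_pt_won_1 = col$bpw_1[idx], break_pt_won_2 = col$bpw_2[idx],
    gap_seconds = col$gap[idx]
  )
  m
}

#' Simulate a corpus of matches
#'
#' Per-match seeds are `seed + 1, ..., seed + n`, so corpora are
#' reproducible and individual matches can be regenerated in isolation.
#'
#' @param n number of matches.
#' @param cfg a [simulation_config()] shared by all matches.
#' @param seed base integer seed.
#' @param id_prefix match_id prefix.
#' @return A `match_corpus`.
#' @export
simulate_corpus <- function(n, cfg = simulation_config(), seed = 1L,
                            id_prefix = "sim") {
  new_corpus(lapply(seq_len(n), function(i)
    simulate_match(cfg, seed = seed + i,
                   match_id = sprintf("%s-%06d", id_prefix, seed + i))))
}

#' Simulate a corpus with a configured skill gap
#'
#' Player 1 serves at `base + delta/2`, player 2 at `base - delta/2`; with
#' `delta = 0` the corpus is exactly symmetric (a null for prediction
#' accuracy), and growing `delta` makes player 1 increasingly dominant.
#'
#' @param n matches.
#' @param delta skill gap in per-point serve-win probability.
#' @param base baseline serve-win probability (default the 0.84-hold
#'   calibration, about 0.673).
#' @param seed base seed.
#' @param best_of sets format (default 3 to keep corpora cheap).
#' @return A `match_corpus`.
#' @export
simulate_skill_corpus <- function(n, delta, base = calibrate_point_prob(0.84),
                                  seed = 1L, best_of = 3L) {
  cfg <- simulation_config(best_of = best_of,
                           p_serve = c(base + delta / 2, base - delta / 2))
  simulate_corpus(n, cfg, seed = seed,
                  id_prefix = sprintf("skill%03.0f", delta * 1000))
}
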