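# Hand-built fixtures used across test files. All fixtures are constructed
# in code; nothing is read from disk.

# Minimal canonical points table: victors + servers only, one game per
# `game_len` points (server alternates by game).
tiny_points <- function(victors, servers = NULL, match_id = "t-0001",
                        game_len = 4L) {
  n <- length(victors)
  game <- (seq_len(n) - 1L) %/% game_len + 1L
  if (is.null(servers)) servers <- ifelse(game %% 2L == 1L, 1L, 2L)
  data.frame(match_id = match_id, point_no = seq_len(n), set_no = 1L,
             game_no = game, server = servers, point_victor = victors,
             stringsAsFactors = FALSE)
}

tiny_match <- function(...) match_record(tiny_points(...), best_of = 3)

# Independent brute-force streak oracle: explicit sliding window.
streak_oracle <- function(victors, k, player) {
  n <- length(victors)
  out <- integer(n)
  for (i in seq_len(n)) {
    if (i >= k && all(victors[(i - k + 1L):i] == player)) out[i] <- 1L
  }
  out
}

# Independent unrolled momentum oracle: M_n = sum_i (prod_{j>i} f_j) dM_i.
unrolled_momentum <- function(f, dM) {
  n <- length(f)
  M <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(i)) {
      w <- 1
      if (j < i) for (t in (j + 1L):i) w <- w * f[t]
      acc <- acc + w * dM[j]
    }
    M[i] <- acc
  }
  M
}

# Random seeded event-flags table (not from a match) for recursion tests.
random_flags <- function(n, seed) {
  set.seed(seed)
  fl <- data.frame(point_no = seq_len(n), set_no = 1L)
  victors <- sample(1:2, n, replace = TRUE)
  serving <- sample(1:2, n, replace = TRUE)
  for (x in 1:2) {
    fl[[paste0("p1_", x)]] <- as.numeric(serving == x &
                                           stats::runif(n) < 0.1)
    fl[[paste0("p2_", x)]] <- as.numeric(fl[[paste0("p1_", x)]] == 0 &
                                           stats::runif(n) < 0.2)
    fl[[paste0("p3_", x)]] <- detect_streaks(victors, 3L, x)
    fl[[paste0("n1_", x)]] <- as.numeric(serving == x &
                                           stats::runif(n) < 0.05)
    fl[[paste0("n2_", x)]] <- as.numeric(fl[[paste0("n1_", x)]] == 0 &
                                           stats::runif(n) < 0.15)
    fl[[paste0("n3_", x)]] <- detect_streaks(victors, 3L, 3L - x)
    fl[[paste0("serving_", x)]] <- as.integer(serving == x)
    fl[[paste0("break_pt_", x)]] <- 0
    fl[[paste0("break_pt_won_", x)]] <- 0
  }
  class(fl) <- c("event_flags", "data.frame")
  fl
}

# Attach a synthetic monotone clock so momentum_series has real gaps.
with_clock <- function(m, gaps) {
  m$points$elapsed_seconds <- cumsum(gaps)
  m
}

quick_cfg <- function(...) simulation_config(best_of = 3L, ...)
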