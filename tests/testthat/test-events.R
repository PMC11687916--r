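test_that("detect_streaks matches its definition on small cases", {
  expect_equal(detect_streaks(c(1, 2, 1, 2), 3, 1), rep(0L, 4))
  expect_equal(detect_streaks(c(1, 1, 1), 3, 1), c(0L, 0L, 1L))
  # a 5-run fires on the 3rd and every later point
  expect_equal(detect_streaks(rep(1, 5), 3, 1), c(0L, 0L, 1L, 1L, 1L))
  expect_equal(detect_streaks(c(1, 1, 1, 1), 3, 2), rep(0L, 4))
  expect_error(detect_streaks(c(1, 2), 1, 1), "k")
})

test_that("detect_streaks equals the sliding-window brute force (property)", {
  set.seed(42)
  for (rep in 1:25) {
    v <- sample(1:2, 200, replace = TRUE)
    k <- sample(2:5, 1)
    for (pl in 1:2)
      expect_equal(detect_streaks(v, k, pl), streak_oracle(v, k, pl))
  }
})

test_that("extract_flags encodes the event definitions", {
  pts <- tiny_points(victors = c(1, 2, 2, 1), servers = c(1, 1, 2, 2))
  pts$ace_1 <- c(1, 0, 0, 0)
  pts$double_fault_2 <- c(0, 0, 1, 0)
  pts$winner_2 <- c(0, 1, 0, 0)
  pts$unf_err_2 <- c(0, 0, 1, 0)        # double fault also logged as UE
  pts$winner_1 <- c(1, 0, 0, 0)         # same point as the ace
  m <- match_record(pts)
  fl <- suppressWarnings(extract_flags(m))
  # serving ace -> p1 for player 1 only; co-occurring winner suppressed
  expect_equal(fl$p1_1, c(1, 0, 0, 0))
  expect_equal(fl$p2_1, c(0, 0, 0, 0))
  expect_equal(fl$p1_2, rep(0, 4))
  # receiver's winner shot is p2
  expect_equal(fl$p2_2, c(0, 1, 0, 0))
  # server's double fault -> n1 for server, no positive flag for opponent;
  # co-occurring unforced error suppressed by the double fault
  expect_equal(fl$n1_2, c(0, 0, 1, 0))
  expect_equal(fl$n2_2, c(0, 0, 0, 0))
  expect_equal(fl$p2_1[3], 0)
  expect_equal(fl$serving_1, c(1, 1, 0, 0))
})

test_that("p1 definition toggles between ace-only and ace-or-serve-winner", {
  pts <- tiny_points(victors = c(1, 1), servers = c(1, 1))
  pts$ace_1 <- c(1, 0)
  pts$serve_winner_1 <- c(0, 1)
  m <- match_record(pts)
  both <- suppressWarnings(extract_flags(m, momentum_params()))
  ace_only <- suppressWarnings(
    extract_flags(m, momentum_params(p1_definition = "ace")))
  expect_equal(both$p1_1, c(1, 1))
  expect_equal(ace_only$p1_1, c(1, 0))
})

test_that("absent indicator columns give zero flags with a warning", {
  m <- tiny_match(victors = c(1, 2, 1))
  w <- capture_warnings(fl <- extract_flags(m))
  expect_true(all(grepl("absent", w)))
  expect_gt(length(w), 0)
  expect_equal(fl$p1_1, rep(0, 3))
  expect_equal(fl$n2_2, rep(0, 3))
})

test_that("streak flags and exclusivity invariants hold on simulated play", {
  m <- simulate_match(quick_cfg(), seed = 5)
  fl <- extract_flags(m)
  v <- m$points$point_victor
  for (x in 1:2) {
    expect_equal(fl[[paste0("p3_", x)]], as.numeric(streak_oracle(v, 3, x)))
    # p3 and n3 never both fire for the same player
    expect_true(all(fl[[paste0("p3_", x)]] + fl[[paste0("n3_", x)]] <= 1))
    # p1/n1 imply serving; at most one of p1, p2
    expect_true(all(fl[[paste0("p1_", x)]] <= fl[[paste0("serving_", x)]]))
    expect_true(all(fl[[paste0("n1_", x)]] <= fl[[paste0("serving_", x)]]))
    expect_true(all(fl[[paste0("p1_", x)]] + fl[[paste0("p2_", x)]] <= 1))
  }
  # A's three-wins stream is identically B's three-losses stream
  expect_equal(fl$p3_1, fl$n3_2)
  expect_equal(fl$p3_2, fl$n3_1)
})

test_that("relabeling players swaps the two flag streams exactly", {
  m <- simulate_match(quick_cfg(), seed = 9)
  sw <- m
  pts <- sw$points
  pts$server <- 3 - pts$server
  pts$point_victor <- 3 - pts$point_victor
  pts$game_victor <- ifelse(pts$game_victor == 0, 0, 3 - pts$game_victor)
  pts$set_victor <- ifelse(pts$set_victor == 0, 0, 3 - pts$set_victor)
  for (base in c("ace", "serve_winner", "winner", "double_fault", "unf_err",
                 "net_pt", "net_pt_won", "break_pt", "break_pt_won",
                 "distance_run")) {
    a <- pts[[paste0(base, "_1")]]
    pts[[paste0(base, "_1")]] <- pts[[paste0(base, "_2")]]
    pts[[paste0(base, "_2")]] <- a
  }
  sw$points <- pts
  f1 <- extract_flags(m); f2 <- extract_flags(sw)
  for (cl in c("p1", "p2", "p3", "n1", "n2", "n3", "serving", "break_pt",
               "break_pt_won")) {
    expect_equal(f1[[paste0(cl, "_1")]], f2[[paste0(cl, "_2")]], info = cl)
    expect_equal(f1[[paste0(cl, "_2")]], f2[[paste0(cl, "_1")]], info = cl)
  }
})

test_that("break points: textbook scores and reconstruction vs simulator", {
  # 30-40 with player 1 serving is a break point for player 2
  v <- c(1, 1, 2, 2, 2, 2)     # after 5 points: 30-40, point 6 converts
  pts <- tiny_points(victors = v, servers = rep(1L, 6), game_len = 6L)
  m <- match_record(pts)
  bp <- detect_break_points(m)
  expect_equal(bp$break_pt_2, c(0, 0, 0, 0, 0, 1))
  expect_equal(bp$break_pt_won_2, c(0, 0, 0, 0, 0, 1))
  expect_equal(bp$break_pt_1, rep(0, 6))

  # advantage receiver after deuce is a break point: points 8 (AD-R after
  # 40-40) and 10 (AD-R again) for the receiver
  v2 <- c(1, 1, 1, 2, 2, 2, 2, 1, 2, 2)
  pts2 <- tiny_points(victors = v2, servers = rep(1L, 10), game_len = 10L)
  bp2 <- detect_break_points(match_record(pts2))
  expect_equal(which(bp2$break_pt_2 == 1), c(8, 10))
  expect_equal(which(bp2$break_pt_won_2 == 1), 10)

  # reconstruction equals the simulator's ground truth (raw columns removed)
  m3 <- simulate_match(quick_cfg(), seed = 31)
  stripped <- m3
  stripped$points$break_pt_1 <- stripped$points$break_pt_2 <- NA
  stripped$points$break_pt_won_1 <- stripped$points$break_pt_won_2 <- NA
  bp3 <- detect_break_points(stripped)
  expect_equal(bp3$break_pt_1, m3$truth$break_pt_1)
  expect_equal(bp3$break_pt_2, m3$truth$break_pt_2)
  expect_equal(bp3$break_pt_won_1, m3$truth$break_pt_won_1)
  expect_equal(bp3$break_pt_won_2, m3$truth$break_pt_won_2)
})

test_that("tally_events sums flags and computes service-point rates", {
  pts <- tiny_points(victors = c(1, 2, 1, 1, 2, 2, 1, 1, 1, 1),
                     servers = c(rep(1L, 5), rep(2L, 5)), game_len = 5L)
  pts$winner_1 <- c(0, 0, 1, 0, 0, 0, 1, 0, 0, 0)
  pts$double_fault_1 <- c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0)
  m <- match_record(pts)
  fl <- suppressWarnings(extract_flags(m))
  tl <- tally_events(m, fl)
  expect_equal(tl$n_winning_shots[1], 2)
  expect_equal(tl$rate_double_fault[1], 1 / 5)   # 5 service points
  expect_equal(tl$n_three_consecutive_wins[1], sum(streak_oracle(
    pts$point_victor, 3, 1)))
  expect_equal(tl$n_three_consecutive_losses[2],
               tl$n_three_consecutive_wins[1])
})

test_that("tallies on a simulated corpus agree with raw-column bookkeeping", {
  corpus <- simulate_corpus(3, quick_cfg(), seed = 77)
  for (m in corpus) {
    fl <- extract_flags(m)
    tl <- tally_events(m, fl)
    for (x in 1:2) {
      pts <- m$points
      sv <- sum(pts$server == x)
      expect_equal(tl$rate_winning_serve[x],
                   sum(pts[[paste0("ace_", x)]] +
                         pts[[paste0("serve_winner_", x)]]) / sv)
      expect_equal(tl$n_unforced_errors[x], sum(pts[[paste0("unf_err_", x)]]))
      expect_equal(tl$n_net_points_won[x],
                   sum(pts[[paste0("net_pt_won_", x)]]))
    }
  }
})
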