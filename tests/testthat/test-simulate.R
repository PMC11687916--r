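test_that("advance: game, deuce, tiebreak and match transitions", {
  st <- scoring_state(best_of = 3)
  # server takes the game to love
  for (i in 1:4) st <- advance(st, 1)
  expect_equal(st$games, c(1L, 0L))
  expect_equal(st$game_victor, 1L)
  expect_equal(st$server, 2L)           # serve alternates by game
  expect_equal(st$points, c(0L, 0L))

  # deuce: 3-3 then win-by-two
  st2 <- scoring_state(best_of = 3)
  for (w in c(1, 1, 1, 2, 2, 2)) st2 <- advance(st2, w)
  expect_equal(st2$points, c(3L, 3L))
  st2 <- advance(st2, 1)                 # AD-1
  expect_equal(st2$game_victor, 0L)
  st2 <- advance(st2, 2)                 # back to deuce
  st2 <- advance(st2, 2); st2 <- advance(st2, 2)
  expect_equal(st2$games, c(0L, 1L))

  # 6-6 in games enters a tiebreak; 7-0 takes set 7-6
  st3 <- scoring_state(best_of = 3)
  for (g in 1:12) {
    w <- if (g %% 2 == 1) 1 else 2      # trade games to 6-6
    for (i in 1:4) st3 <- advance(st3, w)
  }
  expect_true(st3$tiebreak)
  tb_server <- st3$server
  st3 <- advance(st3, 1)
  expect_equal(st3$server, 3L - tb_server)   # serve flips after TB point 1
  for (i in 1:6) st3 <- advance(st3, 1)
  expect_false(st3$tiebreak)
  expect_equal(st3$sets, c(1L, 0L))
  expect_equal(st3$set_victor, 1L)

  # advancing a finished match errors
  st4 <- scoring_state(best_of = 3)
  while (!st4$finished) st4 <- advance(st4, 1)
  expect_equal(st4$winner, 1L)
  expect_error(advance(st4, 1), "finished")
})

test_that("random playouts satisfy the conservation laws (property)", {
  for (seed in c(2, 13, 57, 101)) {
    set.seed(seed)
    st <- scoring_state(best_of = if (seed %% 2) 3 else 5)
    total <- 0L
    sets_won <- c(0L, 0L)
    while (!st$finished) {
      st <- advance(st, sample(1:2, 1))
      total <- total + 1L
      if (st$set_victor != 0) sets_won[st$set_victor] <-
          sets_won[st$set_victor] + 1L
    }
    expect_equal(st$point_no, total)
    expect_equal(sets_won[st$winner], st$best_of %/% 2L + 1L)
    expect_lt(sets_won[3L - st$winner], st$best_of %/% 2L + 1L)
  }
})

test_that("closed-form game probability: symmetry, endpoints, MC anchor", {
  expect_equal(game_win_probability(0.5), 0.5)
  expect_equal(game_win_probability(1), 1)
  expect_equal(game_win_probability(0), 0)
  expect_true(all(diff(game_win_probability(seq(0.05, 0.95, 0.05))) > 0))
  set.seed(99)
  n <- 2e5
  mc <- simulate_games(n, 0.6)
  exact <- game_win_probability(0.6)
  expect_lt(abs(mc - exact), 3 * sqrt(exact * (1 - exact) / n))
})

test_that("calibration inverts the closed form (property)", {
  expect_equal(calibrate_point_prob(0.5), 0.5, tolerance = 1e-10)
  for (t in seq(0.2, 0.95, by = 0.15)) {
    p <- calibrate_point_prob(t)
    expect_lt(abs(game_win_probability(p) - t), 1e-10)
  }
  expect_error(calibrate_point_prob(1.2), "0, 1")
})

test_that("simulate_match is deterministic in the seed", {
  cfg <- quick_cfg()
  m1 <- simulate_match(cfg, seed = 42)
  m2 <- simulate_match(cfg, seed = 42)
  expect_identical(m1$points, m2$points)
  expect_identical(m1$truth, m2$truth)
  m3 <- simulate_match(cfg, seed = 43)
  expect_false(identical(m1$points$point_victor, m3$points$point_victor))
})

test_that("a certain player wins a best-of-3 in the minimal 48 points", {
  cfg <- quick_cfg(p_serve = c(1, 0))   # player 1 wins every point
  m <- simulate_match(cfg, seed = 1)
  expect_equal(m$meta$winner, 1L)
  expect_true(all(m$points$point_victor == 1))
  # 4 points per game, 6 games per set, 2 sets to win best-of-3
  expect_equal(nrow(m$points), 48L)
  expect_equal(sum(m$points$set_victor == 1), 2L)
})

test_that("simulated matches are schema-valid with consistent attribution", {
  for (seed in c(3, 44)) {
    m <- simulate_match(quick_cfg(), seed = seed)
    expect_equal(nrow(validate_match(m)), 0L)
    pts <- m$points
    # each point's end explained by exactly one of ace / serve winner /
    # winner shot / double fault / unforced error
    expl <- pts$ace_1 + pts$ace_2 + pts$serve_winner_1 + pts$serve_winner_2 +
      pts$winner_1 + pts$winner_2 + pts$double_fault_1 + pts$double_fault_2 +
      pts$unf_err_1 + pts$unf_err_2
    expect_true(all(expl == 1))
    # aces on server-won points only; double faults on server-lost only
    for (x in 1:2) {
      ace <- pts[[paste0("ace_", x)]] == 1
      expect_true(all(pts$server[ace] == x & pts$point_victor[ace] == x))
      dfl <- pts[[paste0("double_fault_", x)]] == 1
      expect_true(all(pts$server[dfl] == x & pts$point_victor[dfl] != x))
    }
    # clock strictly increasing, gaps within the truncation bounds
    gaps <- diff(c(0, pts$elapsed_seconds))
    expect_true(all(gaps >= 15 & gaps <= 180))
  }
})

test_that("extract_flags reproduces the simulator's ground truth exactly", {
  for (seed in c(8, 70)) {
    m <- simulate_match(quick_cfg(), seed = seed)
    fl <- extract_flags(m)
    expect_equal(fl$p3_1, m$truth$p3_1)
    expect_equal(fl$p3_2, m$truth$p3_2)
    expect_equal(fl$n3_1, m$truth$n3_1)
    expect_equal(fl$n3_2, m$truth$n3_2)
    expect_equal(fl$break_pt_1, m$truth$break_pt_1)
    expect_equal(fl$break_pt_won_2, m$truth$break_pt_won_2)
  }
})

test_that("net-point success frequency converges to the configured 0.82", {
  corpus <- simulate_corpus(60, quick_cfg(), seed = 500)
  won <- app <- 0
  for (m in corpus) {
    app <- app + sum(m$points$net_pt_1) + sum(m$points$net_pt_2)
    won <- won + sum(m$points$net_pt_won_1) + sum(m$points$net_pt_won_2)
  }
  expect_gt(app, 1000)
  expect_lt(abs(won / app - 0.82), 3 * sqrt(0.82 * 0.18 / app))
})

test_that("invalid simulation configs are rejected", {
  expect_error(simulation_config(p_serve = c(1.2, 0.5)), "probabilities")
  expect_error(simulation_config(best_of = 4))
  expect_error(simulation_config(gap_range = c(100, 50)))
})
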