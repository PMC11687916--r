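#' Forgetting coefficient
#'
#' Multiplicative decay applied to the previous momentum value:
#' \deqn{f(\Delta t) = f_{floor} + f_{scale}\, e^{-\lambda \Delta t}}
#' with the shipped constants \eqn{0.6 + 0.4 e^{-\lambda \Delta t}}. Since
#' `f_floor + f_scale = 1`, `f(0) = 1` exactly; as the inter-point gap grows
#' the coefficient decreases strictly and monotonically towards the floor
#' 0.6, mirroring how the psychological carry-over of the previous point
#' fades with time but never vanishes entirely within a match.
#'
#' @param dt_seconds nonnegative gap(s) since the previous point, seconds.
#'   `NA` entries are replaced by `params$default_dt_seconds`.
#' @param params a [momentum_params()] object.
#' @return Numeric vector of coefficients in `(f_floor, 1]`.
#' @export
forgetting_coefficient <- function(dt_seconds, params = momentum_params()) {
  dt_seconds[is.na(dt_seconds)] <- params$default_dt_seconds
  if (any(dt_seconds < 0))
    stop("inter-point gap must be nonnegative", call. = FALSE)
  params$f_floor + params$f_scale * exp(-params$lambda_decay * dt_seconds)
}

#' Momentum increment for one point
#'
#' Linear weighted sum of the event flags:
#' \deqn{\Delta M = \alpha \sum_k w_{pk}\,flag_{pk} - \beta \sum_j w_{nj}\,flag_{nj}}
#' where \eqn{\alpha} is the positive modifier (1.2 when serving, 1
#' otherwise) and \eqn{\beta} the negative modifier (1 when serving, 1.2
#' otherwise). Negative events enter with an explicit minus so that they
#' lower momentum; the weights themselves stay nonnegative.
#'
#' @param pos length-3 binary vector (winning serve, winning shot,
#'   three-point run) or a matrix with 3 columns for many points.
#' @param neg length-3 binary vector (double fault, unforced error,
#'   three-point slump) or matching matrix.
#' @param serving logical (scalar or vector): is this player serving.
#' @param params a [momentum_params()] object.
#' @return Numeric increment(s) \eqn{\Delta M}.
#' @examples
#' p <- momentum_params()
#' momentum_increment(c(1, 0, 0), c(0, 0, 0), serving = TRUE, p)   # 0.36
#' momentum_increment(c(0, 0, 0), c(0, 0, 1), serving = FALSE, p)  # -0.504
#' @export
momentum_increment <- function(pos, neg, serving, params = momentum_params()) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3L)
  if (is.null(dim(neg))) neg <- matrix(neg, ncol = 3L)
  stopifnot(ncol(pos) == 3L, ncol(neg) == 3L, nrow(pos) == nrow(neg))
  alpha <- ifelse(serving, params$alpha_serve, params$alpha_recv)
  beta <- ifelse(serving, params$beta_serve, params$beta_recv)
  drop(alpha * (pos %*% params$w_p) - beta * (neg %*% params$w_n))
}

#' Compute the momentum series for both players
#'
#' Runs the first-order difference equation
#' \deqn{M_i = f(\Delta t_i)\, M_{i-1} + \Delta M_i, \qquad M_0 = 0}
#' independently per player over the point sequence. The inter-point gaps
#' \eqn{\Delta t_i} are successive differences of the cumulative match
#' clock; missing or non-positive gaps fall back to
#' `params$default_dt_seconds`.
#'
#' @param m a `match_record`.
#' @param flags output of [extract_flags()] for `m`.
#' @param params a [momentum_params()] object.
#' @return An object of class `momentum_series`: list with `M` (n x 2
#'   matrix of momentum values), `dM` (n x 2 increments), `f` (length-n
#'   forgetting coefficients), `dt` (gaps used), `set_no`, `point_no`, and
#'   `set_scores` (see [set_scores()]).
#' @export
momentum_series <- function(m, flags = extract_flags(m),
                            params = momentum_params()) {
  stopifnot(inherits(m, "match_record"))
  n <- nrow(m$points)
  if (nrow(flags) != n)
    stop("flags not aligned to points (", nrow(flags), " vs ", n, ")",
         call. = FALSE)
  el <- m$points$elapsed_seconds
  dt <- if (all(is.na(el))) rep(params$default_dt_seconds, n) else
    c(NA, diff(el))
  dt[is.na(dt) | dt <= 0] <- params$default_dt_seconds
  f <- forgetting_coefficient(dt, params)
  M <- dM <- matrix(0, n, 2L)
  for (x in 1:2) {
    dM[, x] <- momentum_increment(
      as.matrix(flags[paste0(c("p1_", "p2_", "p3_"), x)]),
      as.matrix(flags[paste0(c("n1_", "n2_", "n3_"), x)]),
      flags[[paste0("serving_", x)]] == 1, params)
    prev <- 0
    for (i in seq_len(n)) {
      prev <- f[i] * prev + dM[i, x]
      M[i, x] <- prev
    }
  }
  out <- list(M = M, dM = dM, f = f, dt = dt,
              set_no = flags$set_no, point_no = flags$point_no,
              match_id = m$match_id)
  class(out) <- "momentum_series"
  out$set_scores <- set_scores(out, m, flags, params)
  out
}

#' @export
print.momentum_series <- function(x, ...) {
  n <- nrow(x$M)
  cat(sprintf("<momentum_series> %s: %d points; final M = (%.3f, %.3f)\n",
              x$match_id, n, x$M[n, 1], x$M[n, 2]))
  invisible(x)
}

#' Per-set momentum scores with break-point adjustment
#'
#' Summarises each set by the mean momentum over its points, then rewards
#' break-point pressure: each break point a player creates adds
#' `w_bp_created` and each conversion adds `w_bp_converted` to that
#' player's set score. With both weights zero the scores reduce to plain
#' set means.
#'
#' @param series a `momentum_series` (its `M` and `set_no` are used).
#' @param m the `match_record` the series was computed from.
#' @param flags aligned [extract_flags()] output (supplies break-point
#'   context).
#' @param params a [momentum_params()] object.
#' @return Data frame with one row per set: `set_no`, `n_points`, and per
#'   player `score_x`, `bp_created_x`, `bp_converted_x`.
#' @export
set_scores <- function(series, m, flags = extract_flags(m),
                       params = momentum_params()) {
  sets <- unique(series$set_no)
  rows <- lapply(sets, function(s) {
    idx <- which(series$set_no == s)
    row <- data.frame(set_no = s, n_points = length(idx))
    for (x in 1:2) {
      bpc <- sum(flags[[paste0("break_pt_", x)]][idx])
      bpv <- sum(flags[[paste0("break_pt_won_", x)]][idx])
      row[[paste0("score_", x)]] <- mean(series$M[idx, x]) +
        params$w_bp_created * bpc + params$w_bp_converted * bpv
      row[[paste0("bp_created_", x)]] <- bpc
      row[[paste0("bp_converted_", x)]] <- bpv
    }
    row
  })
  do.call(rbind, rows)
}

#' Plot the two momentum curves of a match
#'
#' @param series a `momentum_series`.
#' @param labels length-2 player labels.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `series`.
#' @export
plot_momentum <- function(series, labels = c("player 1", "player 2"), ...) {
  i <- seq_len(nrow(series$M))
  graphics::plot(i, series$M[, 1], type = "l", col = "#1b6ca8",
                 xlab = "point", ylab = "momentum M", ...)
  graphics::lines(i, series$M[, 2], col = "#c23b22")
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topleft", legend = labels, lty = 1,
                   col = c("#1b6ca8", "#c23b22"), bty = "n")
  invisible(series)
}
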