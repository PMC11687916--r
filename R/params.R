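#' Momentum model parameters
#'
#' Bundles every constant of the momentum chain model: the forgetting
#' coefficient \eqn{f(\Delta t) = f_{floor} + f_{scale} e^{-\lambda \Delta t}},
#' the server/receiver modifiers \eqn{\alpha} and \eqn{\beta}, the linear
#' event weights for the three positive (winning serve, winning shot,
#' three-point run) and three negative (double fault, unforced error,
#' three-point slump) events, and the break-point adjustment applied to
#' per-set scores.
#'
#' Shipped defaults are the published model constants: `w_p = (0.30, 0.32,
#' 0.38)`, `w_n = (0.32, 0.26, 0.42)`, `alpha = 1.2` when serving else `1`,
#' `beta = 1` when serving else `1.2`, and `f = 0.6 + 0.4 exp(-lambda dt)`.
#' The decay rate `lambda` is not part of the published constants; the
#' default `log(2)/40` halves the transient memory component over a typical
#' 40-second inter-point gap. The break-point set-score weights are likewise
#' package extrapolations (see the methods vignette) and default to 0.05 per
#' break point created and 0.10 per break point converted.
#'
#' @param lambda_decay exponential decay rate of the forgetting coefficient,
#'   per second (> 0).
#' @param f_floor,f_scale floor and transient scale of the forgetting
#'   coefficient; must sum to 1 so that `f(0) = 1`.
#' @param alpha_serve,alpha_recv positive-event modifier when the player is
#'   serving / receiving.
#' @param beta_serve,beta_recv negative-event modifier when serving /
#'   receiving.
#' @param w_p length-3 nonnegative weights of the positive events
#'   (winning serve, winning shot, three consecutive points won); must sum
#'   to 1.
#' @param w_n length-3 nonnegative weights of the negative events
#'   (double fault, unforced error, three consecutive points lost); must sum
#'   to 1.
#' @param w_bp_created,w_bp_converted per-set score adjustment per break
#'   point created / converted.
#' @param default_dt_seconds fallback inter-point gap (seconds) used when
#'   the match clock is missing or non-increasing.
#' @param prediction_mode how the match-level score is formed from the
#'   momentum series: `"mean"` (default), `"final"` or `"cumulative"`.
#' @param p1_definition what counts as a "winning serve" event: aces plus
#'   untouched serve winners (`"ace_or_serve_winner"`, default) or aces only
#'   (`"ace"`).
#'
#' @return An object of class `momentum_params` (a validated named list).
#' @examples
#' p <- momentum_params()
#' forgetting_coefficient(0, p)    # 1 exactly
#' forgetting_coefficient(1e9, p)  # the floor, 0.6
#' @export
momentum_params <- function(lambda_decay = log(2) / 40,
                            f_floor = 0.6,
                            f_scale = 0.4,
                            alpha_serve = 1.2,
                            alpha_recv = 1.0,
                            beta_serve = 1.0,
                            beta_recv = 1.2,
                            w_p = c(0.30, 0.32, 0.38),
                            w_n = c(0.32, 0.26, 0.42),
                            w_bp_created = 0.05,
                            w_bp_converted = 0.10,
                            default_dt_seconds = 40,
                            prediction_mode = c("mean", "final", "cumulative"),
                            p1_definition = c("ace_or_serve_winner", "ace")) {
  prediction_mode <- match.arg(prediction_mode)
  p1_definition <- match.arg(p1_definition)
  p <- list(
    lambda_decay = lambda_decay, f_floor = f_floor, f_scale = f_scale,
    alpha_serve = alpha_serve, alpha_recv = alpha_recv,
    beta_serve = beta_serve, beta_recv = beta_recv,
    w_p = as.numeric(w_p), w_n = as.numeric(w_n),
    w_bp_created = w_bp_created, w_bp_converted = w_bp_converted,
    default_dt_seconds = default_dt_seconds,
    prediction_mode = prediction_mode,
    p1_definition = p1_definition
  )
  class(p) <- "momentum_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(
    inherits(p, "momentum_params"),
    p$lambda_decay > 0,
    length(p$w_p) == 3L, length(p$w_n) == 3L,
    all(p$w_p >= 0), all(p$w_n >= 0),
    p$alpha_serve >= 0, p$alpha_recv >= 0,
    p$beta_serve >= 0, p$beta_recv >= 0,
    p$w_bp_created >= 0, p$w_bp_converted >= 0,
    p$default_dt_seconds > 0
  )
  if (abs(p$f_floor + p$f_scale - 1) > 1e-12)
    stop("f_floor + f_scale must equal 1 so that f(0) = 1", call. = FALSE)
  if (abs(sum(p$w_p) - 1) > 1e-12 || abs(sum(p$w_n) - 1) > 1e-12)
    stop("w_p and w_n must each sum to 1", call. = FALSE)
  invisible(p)
}

#' @export
print.momentum_params <- function(x, ...) {
  cat("Momentum chain parameters\n")
  cat(sprintf("  f(dt) = %.2f + %.2f * exp(-%.5f * dt)\n",
              x$f_floor, x$f_scale, x$lambda_decay))
  cat(sprintf("  alpha (serve/recv) = %.2f / %.2f ; beta = %.2f / %.2f\n",
              x$alpha_serve, x$alpha_recv, x$beta_serve, x$beta_recv))
  cat(sprintf("  w_p = (%s) ; w_n = (%s)\n",
              paste(format(x$w_p), collapse = ", "),
              paste(format(x$w_n), collapse = ", ")))
  cat(sprintf("  break-point set adjustment: %.2f created, %.2f converted\n",
              x$w_bp_created, x$w_bp_converted))
  cat(sprintf("  default dt = %gs ; prediction mode = %s ; p1 = %s\n",
              x$default_dt_seconds, x$prediction_mode, x$p1_definition))
  invisible(x)
}

#' Read momentum parameters from a JSON config file
#'
#' Any field of [momentum_params()] may appear in the file; omitted fields
#' keep their defaults.
#'
#' @param path path to a JSON file.
#' @return A `momentum_params` object.
#' @export
read_params <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(momentum_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown parameter field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(momentum_params, cfg)
}
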