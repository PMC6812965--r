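#' Four-parameter feedback-contingent choice parameters
#'
#' Bundle of the four parameters governing a player's switch probability in
#' the fox/rabbit game:
#'
#' * `ms` -- model strength: log-odds slope linking the player's switch
#'   propensity to the opponent's switch-rate log-odds on post-win trials.
#'   `ms = 1` is direct probability matching; `ms > 1` a maximizing tendency.
#' * `sm` -- strategy mix: change of the model-based slope on post-loss
#'   trials. Negative values mean the internal model of the opponent is
#'   suppressed after losses; `sm = -ms` wipes it out entirely.
#' * `pe` -- perseveration: unconditional log-odds bias towards repeating
#'   the previously executed rule (positive = repeat).
#' * `ss` -- win-stay/lose-shift: log-odds bias to repeat after wins and
#'   abandon after losses (positive = classic win-stay/lose-shift).
#'
#' @param ms,sm,pe,ss Finite numeric scalars (log-odds units).
#' @return An object of class `"choice_params"`: a named numeric vector with
#'   elements `ms`, `sm`, `pe`, `ss`.
#' @examples
#' choice_params(ms = 0.48, sm = -0.38, pe = 0.21, ss = 0.20)
#' @export
choice_params <- function(ms = 0, sm = 0, pe = 0, ss = 0) {
  p <- c(ms = as.numeric(ms), sm = as.numeric(sm),
         pe = as.numeric(pe), ss = as.numeric(ss))
  if (length(p) != 4L || anyNA(p) || any(!is.finite(p)))
    stop("all four choice parameters (ms, sm, pe, ss) must be finite scalars",
         call. = FALSE)
  structure(p, class = "choice_params")
}

#' @method print choice_params
#' @export
print.choice_params <- function(x, digits = 3, ...) {
  cat("choice parameters (log-odds units):\n")
  print(round(unclass(x), digits))
  sl <- feedback_slopes(x)
  cat(sprintf("model slope post-win: %.3f; post-loss (reversed-label): %.3f\n",
              sl[["post_win"]], sl[["post_loss"]]))
  invisible(x)
}

as_choice_params <- function(x) {
  if (inherits(x, "choice_params")) return(x)
  x <- unlist(x)
  if (!all(c("ms", "sm", "pe", "ss") %in% names(x)))
    x <- stats::setNames(as.numeric(x)[1:4], c("ms", "sm", "pe", "ss"))
  choice_params(x[["ms"]], x[["sm"]], x[["pe"]], x[["ss"]])
}

#' Model-based slopes implied by choice parameters
#'
#' The log-odds slope of the switch propensity against the opponent
#' switch-rate log-odds, separately after wins and after losses. The
#' post-loss slope is expressed on the reversed-label axis (opponent rate
#' `p` relabelled `1 - p`), on which model-conform behaviour has a positive
#' slope in both feedback conditions: `ms` post-win and `ms + sm` post-loss.
#'
#' @param params A [choice_params()] object.
#' @return Named numeric vector `c(post_win, post_loss)`.
#' @export
feedback_slopes <- function(params) {
  params <- as_choice_params(params)
  c(post_win = params[["ms"]], post_loss = params[["ms"]] + params[["sm"]])
}

#' Log-odds of an opponent switch rate
#'
#' @param p_os Opponent switch rate(s), strictly inside (0, 1).
#' @return `log(p_os / (1 - p_os))`.
#' @export
opponent_logodds <- function(p_os) {
  bad <- !is.finite(p_os) | p_os <= 0 | p_os >= 1
  if (any(bad))
    stop("opponent switch rate must lie strictly inside (0, 1); got: ",
         paste(format(p_os[bad]), collapse = ", "), call. = FALSE)
  log(p_os / (1 - p_os))
}

check_wl <- function(wl) {
  if (any(!wl %in% c(-1, 1)))
    stop("feedback code `wl` must be +1 (post-win) or -1 (post-loss)",
         call. = FALSE)
  as.numeric(wl)
}
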