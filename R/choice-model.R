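#' Switch propensity on the log-odds scale
#'
#' Evaluates the feedback-contingent choice model. With `os` the log-odds of
#' the opponent's switch rate and `wl` coding the previous trial's feedback
#' (+1 win, -1 loss, action errors counting as losses), the log-odds of a
#' switch is
#'
#' \deqn{wl \cdot os \cdot (ms + sm(1 - wl)/2) - pe - wl \cdot ss.}
#'
#' On post-win trials the model slope is `ms`; on post-loss trials the slope
#' on the reversed-label axis is `ms + sm`, so `sm < 0` expresses
#' loss-contingent suppression of the opponent model.
#'
#' @param params A [choice_params()] object (or coercible).
#' @param p_os Opponent switch rate(s) strictly in (0, 1).
#' @param wl Feedback code(s), +1 post-win or -1 post-loss.
#' @return Numeric vector of switch log-odds (recycled over `p_os`, `wl`).
#' @seealso [switch_probability()], [predict_condition_grid()]
#' @export
switch_logit <- function(params, p_os, wl) {
  params <- as_choice_params(params)
  os <- opponent_logodds(p_os)
  wl <- check_wl(wl)
  slope <- params[["ms"]] + params[["sm"]] * (1 - wl) / 2
  wl * os * slope - params[["pe"]] - wl * params[["ss"]]
}

#' Switch probability under the choice model
#'
#' Logistic transform of [switch_logit()]; always strictly inside (0, 1).
#'
#' @inheritParams switch_logit
#' @return Numeric vector of switch probabilities.
#' @examples
#' switch_probability(choice_params(ms = 1), p_os = 0.8, wl = 1)  # 0.8
#' @export
switch_probability <- function(params, p_os, wl) {
  stats::plogis(switch_logit(params, p_os, wl))
}

#' Model-predicted condition grid
#'
#' Predicted mean switch rate for every combination of opponent switch rate
#' and previous feedback, the condition-average surface the model is fitted
#' to.
#'
#' @inheritParams switch_logit
#' @param p_os_list Opponent switch rates, each strictly in (0, 1).
#' @return A `condition_grid` data frame with columns `p_os`, `wl`
#'   (+1/-1), `switch_rate`, `n_trials` (NA for predictions).
#' @export
predict_condition_grid <- function(params, p_os_list) {
  if (length(p_os_list) < 1L)
    stop("`p_os_list` must contain at least one opponent switch rate",
         call. = FALSE)
  grid <- expand.grid(p_os = sort(unique(as.numeric(p_os_list))),
                      wl = c(1, -1), KEEP.OUT.ATTRS = FALSE)
  grid$switch_rate <- switch_probability(params, grid$p_os, grid$wl)
  grid$n_trials <- NA_real_
  class(grid) <- c("condition_grid", "data.frame")
  grid
}

as_condition_grid <- function(x) {
  need <- c("p_os", "wl", "switch_rate")
  if (!all(need %in% names(x)))
    stop("a condition grid needs columns p_os, wl, switch_rate", call. = FALSE)
  if (is.null(x$n_trials)) x$n_trials <- NA_real_
  if (anyDuplicated(x[c("p_os", "wl")]))
    stop("each (p_os, wl) cell may appear at most once", call. = FALSE)
  if (any(x$switch_rate < 0 | x$switch_rate > 1, na.rm = TRUE))
    stop("switch rates must lie in [0, 1]", call. = FALSE)
  class(x) <- unique(c("condition_grid", class(x)))
  x
}

## Sum-of-squares objective for condition-average fits; `w` are cell weights.
condition_ss <- function(theta, grid, w) {
  slope <- theta[1] + theta[2] * (1 - grid$wl) / 2
  pred <- stats::plogis(grid$wl * grid$os * slope - theta[3] - grid$wl * theta[4])
  sum(w * (pred - grid$switch_rate)^2)
}

## One optimisation pass: simplex from `start`, then a quasi-Newton polish.
fit_grid_once <- function(grid, w, start, reltol = 1e-10) {
  nm <- stats::optim(start, condition_ss, grid = grid, w = w,
                     method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = reltol))
  bf <- tryCatch(
    stats::optim(nm$par, condition_ss, grid = grid, w = w, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) nm)
  if (bf$value <= nm$value) bf else nm
}

#' Fit the choice model to condition-average switch rates
#'
#' Least-squares fit of the four-parameter model to a grid of mean switch
#' rates over (opponent switch rate x post-win/post-loss) cells. The
#' optimiser is a Nelder-Mead simplex started from `init` plus jittered
#' restarts (best objective wins), followed by a quasi-Newton polish.
#' Parameter uncertainty comes from a seeded residual bootstrap.
#'
#' @param observed A condition grid: data frame with columns `p_os`, `wl`
#'   (+1/-1), `switch_rate` and optionally `n_trials`.
#' @param init Optional starting [choice_params()]; default
#'   `(0.5, -0.3, 0.1, 0.2)`.
#' @param weights `"none"` (default; cells are near-balanced by design) or
#'   `"n"` to weight cells by trial counts.
#' @param n_restarts Number of jittered restarts around `init`.
#' @param ci `"bootstrap"` for residual-bootstrap 95% intervals or `"none"`.
#' @param n_boot Bootstrap resamples (default 199).
#' @param seed Integer seed fixing both the restart jitter and the bootstrap.
#' @return A `fit_result` list: `params` ([choice_params()]), `estimates`,
#'   `ci` (2 x 4 matrix or NULL), `r2`, `objective` (residual sum of
#'   squares), `converged`, `method = "condition_LS"`, `n_cells`,
#'   `fitted` grid.
#' @export
fit_condition_averages <- function(observed, init = NULL,
                                   weights = c("none", "n"),
                                   n_restarts = 5,
                                   ci = c("bootstrap", "none"),
                                   n_boot = 199, seed = 171L) {
  observed <- as_condition_grid(observed)
  weights <- match.arg(weights)
  ci <- match.arg(ci)
  observed <- observed[is.finite(observed$switch_rate), , drop = FALSE]
  n_cells <- nrow(observed)
  if (n_cells < 4L)
    stop("need at least 4 distinct (p_os, wl) cells to identify 4 parameters; got ",
         n_cells, call. = FALSE)
  grid <- observed
  grid$os <- opponent_logodds(grid$p_os)
  check_wl(grid$wl)
  w <- if (weights == "n") {
    if (anyNA(grid$n_trials)) stop("weights = \"n\" requires n_trials",
                                   call. = FALSE)
    grid$n_trials / mean(grid$n_trials)
  } else rep(1, n_cells)

  start <- if (is.null(init)) c(0.5, -0.3, 0.1, 0.2) else
    as.numeric(as_choice_params(init))
  fits <- withr_seed(seed, {
    starts <- c(list(start),
                lapply(seq_len(n_restarts),
                       function(i) start + stats::rnorm(4, 0, 0.25)))
    lapply(starts, function(s) fit_grid_once(grid, w, s))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  est <- stats::setNames(best$par, c("ms", "sm", "pe", "ss"))

  pred <- switch_probability(est, grid$p_os, grid$wl)
  ss_res <- sum(w * (grid$switch_rate - pred)^2)
  ss_tot <- sum(w * (grid$switch_rate - stats::weighted.mean(grid$switch_rate, w))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_

  ci_mat <- NULL
  if (ci == "bootstrap") {
    ## centre and inflate residuals by the degrees-of-freedom factor
    ## sqrt(n/(n-p)): raw residuals from a 4-parameter fit to few cells
    ## under-disperse, which would make the intervals anti-conservative
    resid <- grid$switch_rate - pred
    resid <- (resid - mean(resid)) * sqrt(n_cells / max(1, n_cells - 4))
    boot <- withr_seed(seed + 1L, {
      vapply(seq_len(n_boot), function(b) {
        g <- grid
        g$switch_rate <- pmin(1, pmax(0, pred + sample(resid, n_cells,
                                                       replace = TRUE)))
        fit_grid_once(g, w, best$par, reltol = 1e-8)$par
      }, numeric(4))
    })
    ci_mat <- apply(boot, 1, stats::quantile, probs = c(0.025, 0.975))
    colnames(ci_mat) <- c("ms", "sm", "pe", "ss")
  }

  out <- list(params = choice_params(est[1], est[2], est[3], est[4]),
              estimates = est, ci = ci_mat, se = NULL, r2 = r2,
              objective = best$value,
              converged = best$convergence == 0,
              method = "condition_LS", n_cells = n_cells,
              fitted = data.frame(grid[c("p_os", "wl", "switch_rate")],
                                  fitted = pred))
  class(out) <- "fit_result"
  if (!out$converged)
    warning("condition-average fit did not converge; treat estimates with care",
            call. = FALSE)
  out
}

#' Running estimate of an opponent's switch rate
#'
#' Trial-by-trial estimate of the partner's switch rate for play against
#' human (or otherwise non-stationary) opponents, as used by the
#' trial-by-trial model fit. For trial `t` of a block only switch events
#' *before* `t` enter. Blocks start from the previous block's final value
#' (0.5 for the first block), carried over as a single pseudo-observation,
#' and a symmetric smoothing count (default 0.5 successes / 0.5 failures)
#' keeps the estimate strictly inside (0, 1) so its log-odds stays finite:
#'
#' `estimate = (smoothing + prior + switches_so_far) / (2 * smoothing + 1 + trials_so_far)`
#'
#' @param switches 0/1 vector of the opponent's switch events, in play
#'   order. The first trial of each block has no defined switch and may be
#'   `NA` (ignored as an event).
#' @param block Block index per trial (same length as `switches`).
#' @param carryover Carry the final estimate of block n-1 into block n
#'   (default TRUE); otherwise every block restarts at 0.5.
#' @param smoothing Symmetric pseudo-count added to successes and failures.
#' @return Numeric vector: the estimate available *at* each trial.
#' @export
running_opponent_switch_rate <- function(switches, block = NULL,
                                         carryover = TRUE, smoothing = 0.5) {
  n <- length(switches)
  if (n == 0L) return(numeric(0))
  if (is.null(block)) block <- rep(1L, n)
  if (length(block) != n) stop("`block` must match `switches` in length",
                               call. = FALSE)
  out <- numeric(n)
  prior <- 0.5
  for (b in unique(block)) {
    idx <- which(block == b)
    s <- 0; k <- 0
    for (i in idx) {
      out[i] <- (smoothing + prior + s) / (2 * smoothing + 1 + k)
      ev <- switches[i]
      if (!is.na(ev)) { s <- s + ev; k <- k + 1 }
    }
    prior <- if (carryover) (smoothing + prior + s) / (2 * smoothing + 1 + k)
             else 0.5
  }
  out
}

#' Fit the choice model to trial-by-trial choices
#'
#' Maximum-likelihood fit of the four-parameter model to a player's observed
#' switch/repeat sequence. The model is linear in (ms, sm, pe, ss) on the
#' log-odds scale, so the Bernoulli likelihood is maximised exactly by a
#' binomial GLM on the design columns `wl*os`, `wl*os*(1-wl)/2`, `-1`,
#' `-wl`; Wald standard errors come from the observed information. First
#' trials of each block (no defined feedback or switch) are excluded.
#'
#' @param trials A session log (one player): data frame with columns
#'   `block`, `trial_in_block`, `player_switch`, `opponent_switch`,
#'   `outcome` (`"win"`/`"loss"`), and `opponent_rate` (programmed rate)
#'   when `p_os = "programmed"`.
#' @param p_os `"programmed"` to use the known per-block opponent rate
#'   (simulated opponents) or `"running"` to use
#'   [running_opponent_switch_rate()] of the partner's observed switches
#'   (dyads).
#' @param init Unused (the GLM needs no starting value); kept for interface
#'   symmetry with [fit_condition_averages()].
#' @return A `fit_result` list with `params`, `estimates`, `se`, `ci`
#'   (Wald 95%), `objective` (maximised log-likelihood), `converged`,
#'   `rank_deficient`, `boundary` flags, `method = "trialwise_ML"`,
#'   `n_trials`.
#' @export
fit_trialwise <- function(trials, p_os = c("programmed", "running"),
                          init = NULL) {
  p_os <- match.arg(p_os)
  mf <- trialwise_frame(trials, p_os)
  n <- nrow(mf)
  if (n < 8L) stop("too few usable trials (", n, ") for a trial-by-trial fit",
                   call. = FALSE)
  boundary <- length(unique(mf$y)) < 2L
  if (boundary)
    warning("degenerate choice sequence (all switch or all repeat); ",
            "estimates lie on the boundary", call. = FALSE)
  X <- cbind(ms = mf$wl * mf$os,
             sm = mf$wl * mf$os * (1 - mf$wl) / 2,
             pe = -1,
             ss = -mf$wl)
  rank_deficient <- qr(X)$rank < 4L
  if (rank_deficient)
    warning("design is rank deficient (no variation in feedback and/or ",
            "opponent rate); some parameters are unidentified", call. = FALSE)
  fit <- suppressWarnings(
    stats::glm.fit(X, mf$y, family = stats::binomial(), intercept = FALSE))
  cf <- stats::setNames(fit$coefficients, colnames(X))
  ## observed information from the final IRLS weights
  keep <- !is.na(cf)
  se <- rep(NA_real_, 4); names(se) <- colnames(X)
  if (any(keep)) {
    W <- fit$weights
    info <- crossprod(X[, keep, drop = FALSE] * sqrt(W))
    v <- tryCatch(diag(solve(info)), error = function(e) rep(NA_real_, sum(keep)))
    se[keep] <- sqrt(v)
  }
  est <- ifelse(is.na(cf), 0, cf)
  ll <- sum(stats::dbinom(mf$y, 1, fit$fitted.values, log = TRUE))
  ci <- rbind(`2.5%` = est + stats::qnorm(0.025) * se,
              `97.5%` = est + stats::qnorm(0.975) * se)
  out <- list(params = choice_params(est[1], est[2], est[3], est[4]),
              estimates = est, se = se, ci = ci, r2 = NA_real_,
              objective = ll, converged = fit$converged && !boundary,
              rank_deficient = rank_deficient, boundary = boundary,
              method = "trialwise_ML", n_trials = n)
  class(out) <- "fit_result"
  out
}

## Assemble the trialwise model frame: y, wl, os per usable trial.
trialwise_frame <- function(trials, p_os) {
  need <- c("block", "trial_in_block", "player_switch", "outcome")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trial log lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  ord <- order(trials$block, trials$trial_in_block)
  trials <- trials[ord, , drop = FALSE]
  prev_out <- ave(as.character(trials$outcome), trials$block,
                  FUN = function(x) c(NA, x[-length(x)]))
  wl <- ifelse(prev_out == "win", 1, -1)
  rate <- switch(p_os,
    programmed = {
      if (is.null(trials$opponent_rate))
        stop("p_os = \"programmed\" requires an `opponent_rate` column",
             call. = FALSE)
      trials$opponent_rate
    },
    running = running_opponent_switch_rate(trials$opponent_switch,
                                           trials$block))
  keep <- trials$trial_in_block > 1 & !is.na(trials$player_switch) &
    !is.na(wl) & is.finite(rate)
  data.frame(y = as.integer(trials$player_switch[keep]),
             wl = as.numeric(wl[keep]),
             os = opponent_logodds(rate[keep]))
}

#' @method print fit_result
#' @export
print.fit_result <- function(x, digits = 3, ...) {
  cat(sprintf("choice-model fit (%s), %s\n", x$method,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  est <- round(x$estimates, digits)
  print(est)
  if (!is.null(x$ci)) {
    cat("95% interval:\n")
    print(round(x$ci, digits))
  }
  if (!is.na(x$r2)) cat("R^2 =", round(x$r2, 4), "\n")
  if (identical(x$method, "trialwise_ML"))
    cat("log-likelihood =", round(x$objective, 2), "on", x$n_trials, "trials\n")
  invisible(x)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
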