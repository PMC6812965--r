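#' Baseline-correct feedback-locked epochs
#'
#' Subtracts each trial's mean signal over the pre-feedback interval.
#'
#' @param epochs An `epoch_set` (list with `values`, `times_ms`, `design`).
#' @param window Baseline window in ms, default `c(-200, 0)` (half-open).
#' @return The `epoch_set` with baselined `values`.
#' @export
baseline_epochs <- function(epochs, window = c(-200, 0)) {
  idx <- which(epochs$times_ms >= window[1] & epochs$times_ms < window[2])
  if (!length(idx)) stop("baseline window contains no time points",
                         call. = FALSE)
  epochs$values <- epochs$values -
    rowMeans(epochs$values[, idx, drop = FALSE])
  epochs$baselined <- TRUE
  epochs
}

#' Optional pre-whitening of user-supplied epochs
#'
#' Removes per-trial linear and quadratic trends across the trial sequence
#' (per time point). Synthetic epochs do not need this; it is provided for
#' recorded signals that carry slow drifts.
#'
#' @param epochs An `epoch_set`.
#' @return The detrended `epoch_set`.
#' @export
prewhiten_epochs <- function(epochs) {
  n <- nrow(epochs$values)
  tr <- seq_len(n)
  X <- cbind(1, zscore(tr), zscore(tr)^2)
  epochs$values <- stats::lm.fit(X, epochs$values)$residuals
  epochs
}

#' Time-point-wise context regression of feedback-locked signals
#'
#' For each time point and feedback condition (post-win / post-loss), the
#' trial-to-trial signal is regressed on the four context variables `A`
#' (opponent overall switch rate), `B` (opponent lag-1 switch), `C` (player
#' lag-1 switch) and `AB`, via a two-level model (trials within subjects,
#' random intercept) or a pooled regression. With
#' `reverse_labels = TRUE` the opponent-related predictors (`A`, `B`, and
#' hence `AB`) are sign-flipped on post-loss rows so coefficient magnitudes
#' are directly comparable across feedback conditions; the signed variant is
#' obtained with `reverse_labels = FALSE`.
#'
#' @param epochs An `epoch_set`; baselined automatically unless already
#'   flagged.
#' @param standardize Z-score the signal (per time point, within feedback
#'   condition) and predictors before fitting, so coefficients are
#'   standardized (default TRUE).
#' @param method `"lmer"` (needs >= 2 subjects) or `"pooled"` (ordinary
#'   least squares, subject-blind).
#' @param reverse_labels Apply the post-loss label reversal (default TRUE).
#' @return A `coef_timecourse` data frame: `time_ms`, `predictor`, `wl`,
#'   `beta`, `se`, `p`.
#' @export
timepoint_context_regression <- function(epochs,
                                         standardize = TRUE,
                                         method = c("lmer", "pooled"),
                                         reverse_labels = TRUE) {
  method <- match.arg(method)
  if (!isTRUE(epochs$baselined)) epochs <- baseline_epochs(epochs)
  design <- epochs$design
  if (method == "lmer" && length(unique(design$subject_id)) < 2L)
    stop("the two-level regression needs at least 2 subjects; ",
         "use method = \"pooled\" for single-subject data", call. = FALSE)
  out <- list()
  for (w in c(1, -1)) {
    rows <- which(design$wl == w)
    X <- design[rows, c("A", "B", "C", "AB")]
    if (reverse_labels && w == -1) {
      X$A <- -X$A; X$B <- -X$B; X$AB <- X$A * X$B
    }
    if (standardize) X[] <- lapply(X, zscore)
    dat <- data.frame(X, subject_id = design$subject_id[rows])
    for (j in seq_along(epochs$times_ms)) {
      y <- epochs$values[rows, j]
      dat$y <- if (standardize) zscore(y) else y
      co <- if (method == "lmer") {
        m <- suppressMessages(suppressWarnings(
          lme4::lmer(y ~ A + B + C + AB + (1 | subject_id), data = dat,
                     REML = FALSE)))
        summary(m)$coefficients
      } else {
        summary(stats::lm(y ~ A + B + C + AB, data = dat))$coefficients
      }
      co <- co[c("A", "B", "C", "AB"), , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        time_ms = epochs$times_ms[j], predictor = rownames(co),
        wl = w, beta = co[, 1], se = co[, 2],
        p = 2 * stats::pnorm(-abs(co[, 1] / co[, 2])), row.names = NULL)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("coef_timecourse", "data.frame")
  res
}

#' Average an epoch over a time window
#'
#' Arithmetic mean of each trial's signal over `[lo, hi)`; the default
#' 300-700 ms window is the a-priori feedback interval used for the PPI and
#' individual-difference analyses.
#'
#' @param epochs An `epoch_set` (or a trials x time matrix plus `times_ms`).
#' @param lo,hi Window bounds in ms (half-open).
#' @param times_ms Time grid when `epochs` is a bare matrix.
#' @return Numeric vector, one scalar per trial.
#' @export
window_average <- function(epochs, lo = 300, hi = 700, times_ms = NULL) {
  if (is.list(epochs)) {
    times_ms <- epochs$times_ms
    values <- epochs$values
  } else values <- epochs
  if (hi <= lo) stop("`hi` must exceed `lo`", call. = FALSE)
  idx <- which(times_ms >= lo & times_ms < hi)
  if (!length(idx)) stop("window [", lo, ", ", hi, ") contains no time points",
                         call. = FALSE)
  rowMeans(values[, idx, drop = FALSE])
}

#' PPI analysis: does residual signal modulate upcoming choices?
#'
#' Two-step psychophysiological-interaction analysis, split by feedback.
#' Step 1 regresses the window-averaged signal on the four context
#' variables (two-level, random intercept per subject) and retains the
#' residuals `D`, finally projected onto the orthogonal complement of the
#' step-1 fixed-effect design so `D` is exactly uncorrelated with `A`, `B`,
#' `C`, `AB` in the fitting subset. Step 2 fits a multilevel logistic model
#' of the *next* trial's switch on `A`, `B`, `C`, `AB`, `D` and the four
#' `D x` interactions.
#'
#' @param epochs An `epoch_set` (baselined automatically); its `design`
#'   must carry `switch_next`.
#' @param lo,hi Window bounds in ms for the step-1 signal (default
#'   300-700).
#' @param method `"glmer"` (random intercept per subject) or `"glm"`.
#' @param reverse_labels Sign-flip opponent predictors on post-loss rows
#'   (default TRUE, matching the slope analyses).
#' @return A `ppi_result` data frame: `wl`, `term`, `estimate`, `se`, `z`,
#'   `p`, with attribute `"residual_sd"` (per feedback condition).
#' @export
ppi_analysis <- function(epochs, lo = 300, hi = 700,
                         method = c("glmer", "glm"),
                         reverse_labels = TRUE) {
  method <- match.arg(method)
  if (!isTRUE(epochs$baselined)) epochs <- baseline_epochs(epochs)
  design <- epochs$design
  sig <- window_average(epochs, lo, hi)
  out <- list(); rsd <- c()
  for (w in c(1, -1)) {
    rows <- which(design$wl == w & !is.na(design$switch_next))
    if (length(rows) < 20L) next
    d <- design[rows, c("A", "B", "C", "AB", "subject_id", "switch_next")]
    if (reverse_labels && w == -1) {
      d$A <- -d$A; d$B <- -d$B; d$AB <- d$A * d$B
    }
    d[c("A", "B", "C", "AB")] <- lapply(d[c("A", "B", "C", "AB")], zscore)
    d$sig <- zscore(sig[rows])
    ## step 1: two-level context regression of the window signal
    step1 <- if (method == "glmer" && length(unique(d$subject_id)) > 1L)
      suppressMessages(suppressWarnings(
        lme4::lmer(sig ~ A + B + C + AB + (1 | subject_id), data = d,
                   REML = FALSE)))
    else stats::lm(sig ~ A + B + C + AB, data = d)
    res <- stats::residuals(step1)
    ## exact orthogonalisation against the fixed-effect design
    res <- stats::lm.fit(cbind(1, as.matrix(d[c("A", "B", "C", "AB")])),
                         res)$residuals
    rsd[as.character(w)] <- stats::sd(res)
    if (stats::sd(res) < 1e-10) {
      message("residual variance ~ 0 for wl = ", w,
              "; interaction terms dropped")
      next
    }
    d$D <- zscore(res)
    f <- switch_next ~ A + B + C + AB + D + D:A + D:B + D:C + D:AB
    co <- if (method == "glmer") {
      m <- tryCatch(suppressMessages(suppressWarnings(
        lme4::glmer(stats::update(f, . ~ . + (1 | subject_id)), data = d,
                    family = stats::binomial(), nAGQ = 0L))),
        error = function(e) NULL)
      if (is.null(m)) {
        message("multilevel logistic fit failed; falling back to glm")
        summary(stats::glm(f, data = d, family = stats::binomial()))$coefficients
      } else summary(m)$coefficients
    } else summary(stats::glm(f, data = d, family = stats::binomial()))$coefficients
    keep <- setdiff(rownames(co), "(Intercept)")
    out[[length(out) + 1L]] <- data.frame(
      wl = w, term = keep, estimate = co[keep, 1], se = co[keep, 2],
      z = co[keep, 3], p = 2 * stats::pnorm(-abs(co[keep, 3])),
      row.names = NULL)
  }
  res_df <- do.call(rbind, out)
  attr(res_df, "residual_sd") <- rsd
  class(res_df) <- c("ppi_result", "data.frame")
  res_df
}

#' Per-subject window coefficients for individual-difference analyses
#'
#' For each subject and feedback condition, regresses the window-averaged
#' (300-700 ms by default) signal on the four context variables within that
#' subject, z-scoring signal and predictors within the subset, and returns
#' the standardized coefficients.
#'
#' @inheritParams ppi_analysis
#' @return Data frame: `subject_id`, `wl`, `predictor`, `coef`.
#' @export
subject_window_coefficients <- function(epochs, lo = 300, hi = 700,
                                        reverse_labels = TRUE) {
  if (!isTRUE(epochs$baselined)) epochs <- baseline_epochs(epochs)
  design <- epochs$design
  sig <- window_average(epochs, lo, hi)
  combos <- expand.grid(subject_id = unique(design$subject_id),
                        wl = c(1, -1))
  out <- lapply(seq_len(nrow(combos)), function(i) {
    rows <- which(design$subject_id == combos$subject_id[i] &
                    design$wl == combos$wl[i])
    d <- design[rows, c("A", "B", "C", "AB")]
    if (reverse_labels && combos$wl[i] == -1) {
      d$A <- -d$A; d$B <- -d$B; d$AB <- d$A * d$B
    }
    d[] <- lapply(d, zscore)
    d$y <- zscore(sig[rows])
    cf <- stats::coef(stats::lm(y ~ A + B + C + AB, data = d))
    data.frame(subject_id = combos$subject_id[i], wl = combos$wl[i],
               predictor = c("A", "B", "C", "AB"),
               coef = unname(cf[c("A", "B", "C", "AB")]))
  })
  do.call(rbind, out)
}

#' Correlate per-subject signal coefficients with behaviour
#'
#' Pearson correlations between each subject's window coefficients (per
#' context predictor and feedback condition) and (1) the subject's
#' reversed-label switch-rate slope in the matching feedback condition, and
#' (2) the subject's overall win rate. The post-win vs post-loss contrast
#' per predictor is tested with a z test for dependent correlations sharing
#' one variable (Meng-Rosenthal-Rubin).
#'
#' @param subject_coefs Output of [subject_window_coefficients()].
#' @param subject_slopes `subject_slopes` from [reversed_label_slopes()]
#'   (columns `subject_id`, `wl`, `slope`).
#' @param win_rates Data frame `subject_id`, `win_rate`.
#' @return List with `correlations` (predictor, measure, wl, r, n, p) and
#'   `contrasts` (predictor, measure, z, p). Zero-variance inputs yield NA
#'   correlations.
#' @export
individual_difference_correlations <- function(subject_coefs, subject_slopes,
                                               win_rates) {
  n_sub <- length(unique(subject_coefs$subject_id))
  if (n_sub < 10L)
    warning("only ", n_sub, " subjects; individual-difference correlations ",
            "are unstable below 10", call. = FALSE)
  safe_cor <- function(x, y) {
    if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) return(NA_real_)
    stats::cor(x, y)
  }
  preds <- unique(subject_coefs$predictor)
  cors <- list(); ctr <- list()
  for (pr in preds) {
    for (measure in c("slope", "win_rate")) {
      vals <- list()
      for (w in c(1, -1)) {
        cf <- subject_coefs[subject_coefs$predictor == pr &
                              subject_coefs$wl == w, ]
        beh <- if (measure == "slope")
          merge(cf, subject_slopes[subject_slopes$wl == w,
                                   c("subject_id", "slope")],
                by = "subject_id")
        else merge(cf, win_rates, by = "subject_id")
        names(beh)[names(beh) %in% c("slope", "win_rate")] <- "m"
        beh <- beh[order(beh$subject_id), ]
        r <- safe_cor(beh$coef, beh$m)
        n <- nrow(beh)
        p <- if (is.na(r) || n < 4) NA_real_ else {
          tt <- r * sqrt((n - 2) / (1 - r^2))
          2 * stats::pt(-abs(tt), n - 2)
        }
        cors[[length(cors) + 1L]] <- data.frame(
          predictor = pr, measure = measure, wl = w, r = r, n = n, p = p)
        vals[[as.character(w)]] <- beh
      }
      bw <- merge(vals[["1"]], vals[["-1"]], by = "subject_id",
                  suffixes = c("_w", "_l"))
      z <- dependent_cor_z(safe_cor(bw$coef_w, bw$m_w),
                           safe_cor(bw$coef_l, bw$m_l),
                           safe_cor(bw$coef_w, bw$coef_l), nrow(bw))
      ctr[[length(ctr) + 1L]] <- data.frame(
        predictor = pr, measure = measure, z = z,
        p = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)))
    }
  }
  list(correlations = do.call(rbind, cors), contrasts = do.call(rbind, ctr))
}

## z test for the difference of two dependent correlations r1 = cor(x1, m),
## r2 = cor(x2, m) sharing the variable m, with r12 = cor(x1, x2)
## (Meng, Rosenthal & Rubin 1992).
dependent_cor_z <- function(r1, r2, r12, n) {
  if (anyNA(c(r1, r2, r12)) || n < 4) return(NA_real_)
  rbar2 <- (r1^2 + r2^2) / 2
  f <- min(1, (1 - r12) / (2 * (1 - rbar2)))
  h <- (1 - f * rbar2) / (1 - rbar2)
  (atanh(r1) - atanh(r2)) * sqrt((n - 3) / (2 * (1 - r12) * h))
}
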