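#' Write a trial log to CSV
#'
#' One row per trial, comma-separated, UTF-8, '.' decimal, empty fields for
#' missing values, header mandatory -- the dialect all package readers
#' expect.
#'
#' @param trials A trial log data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

trial_log_columns <- c("block", "trial_in_block", "role", "player_rule",
                       "opponent_rule", "player_switch", "opponent_switch",
                       "outcome", "action_error")

#' Read and validate a trial log
#'
#' Reads a CSV trial log (the simulator dialect, or arbitrary column names
#' remapped via `column_map`) and validates the game's bookkeeping
#' invariants: every trial has a win/loss outcome, action errors always
#' coincide with losses, and on error-free trials the outcome matches the
#' zero-sum rule (fox wins exactly when the rules match, rabbit when they
#' differ). Violations are reported with their row numbers.
#'
#' @param path CSV file path.
#' @param column_map Optional named character vector mapping file column
#'   names to canonical names, e.g. `c(blk = "block", resp = "player_rule")`.
#' @param validate_outcomes Check the zero-sum outcome rule (default TRUE;
#'   disable for logs with randomised feedback).
#' @return Validated trial-log data frame.
#' @export
read_trial_log <- function(path, column_map = NULL, validate_outcomes = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    hit <- names(d) %in% names(column_map)
    names(d)[hit] <- unname(column_map[names(d)[hit]])
  }
  miss <- setdiff(trial_log_columns, names(d))
  if (length(miss))
    stop("trial log is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!d$outcome %in% c("win", "loss"))
  if (length(bad))
    stop("invalid outcome value(s) at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  bad <- which(d$action_error == 1 & d$outcome == "win")
  if (length(bad))
    stop("action errors must be losses; violated at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  if (validate_outcomes) {
    match_rules <- d$player_rule == d$opponent_rule
    expect_win <- ifelse(d$role == "fox", match_rules, !match_rules)
    # a partner's action error hands the player the win regardless of rules
    opp_err <- if (is.null(d$opponent_action_error)) rep(0L, nrow(d))
               else d$opponent_action_error
    expect_win <- expect_win & opp_err == 0 | opp_err == 1
    bad <- which(d$action_error == 0 &
                   (d$outcome == "win") != expect_win)
    if (length(bad))
      stop("outcome inconsistent with the zero-sum rule at row(s): ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  d
}

#' Write signal epochs to CSV (wide) with a time-grid sidecar
#'
#' `<prefix>_epochs.csv` holds one row per trial (the design columns, then
#' one column per time point); `<prefix>_times.csv` holds the grid.
#'
#' @param epochs An `epoch_set`.
#' @param prefix Path prefix.
#' @return The two paths, invisibly.
#' @export
write_epochs <- function(epochs, prefix) {
  wide <- cbind(epochs$design,
                stats::setNames(as.data.frame(epochs$values),
                                paste0("t", epochs$times_ms)))
  p1 <- paste0(prefix, "_epochs.csv")
  p2 <- paste0(prefix, "_times.csv")
  utils::write.csv(wide, p1, row.names = FALSE, na = "")
  utils::write.csv(data.frame(time_ms = epochs$times_ms), p2,
                   row.names = FALSE)
  invisible(c(p1, p2))
}

#' Read signal epochs written by [write_epochs()]
#'
#' @param prefix Path prefix used when writing.
#' @return An `epoch_set`.
#' @export
read_epochs <- function(prefix) {
  wide <- utils::read.csv(paste0(prefix, "_epochs.csv"),
                          stringsAsFactors = FALSE, check.names = FALSE)
  times <- utils::read.csv(paste0(prefix, "_times.csv"))$time_ms
  tcols <- paste0("t", times)
  miss <- setdiff(tcols, names(wide))
  if (length(miss)) stop("epoch file does not match its time grid",
                         call. = FALSE)
  structure(list(values = as.matrix(wide[tcols]),
                 times_ms = times,
                 design = wide[setdiff(names(wide), tcols)]),
            class = "epoch_set")
}

#' Read choice parameters from a config file
#'
#' Accepts either JSON (`{"ms": 0.48, ...}`) or flat `key=value` lines with
#' fields `ms`, `sm`, `pe`, `ss`.
#'
#' @param path File path.
#' @return A [choice_params()] object.
#' @export
read_choice_params <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vals <- if (grepl("^\\s*\\{", txt[1]))
    unlist(jsonlite::fromJSON(paste(txt, collapse = "\n")))
  else {
    kv <- strsplit(trimws(txt[nzchar(trimws(txt))]), "\\s*=\\s*")
    stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                    vapply(kv, `[`, "", 1))
  }
  miss <- setdiff(c("ms", "sm", "pe", "ss"), names(vals))
  if (length(miss)) stop("parameter file lacks field(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  choice_params(vals[["ms"]], vals[["sm"]], vals[["pe"]], vals[["ss"]])
}

#' Serialize a fit result to delimited text
#'
#' Header lines (`# key: value`) carry method, objective, R^2 and the
#' convergence flag; the body is a CSV table with one row per parameter and
#' its 95% interval.
#'
#' @param fit A `fit_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  lo <- hi <- rep(NA_real_, 4)
  if (!is.null(fit$ci)) { lo <- fit$ci[1, ]; hi <- fit$ci[2, ] }
  tab <- data.frame(parameter = names(fit$estimates),
                    estimate = unname(fit$estimates), lo95 = lo, hi95 = hi)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# method: %s", fit$method),
               sprintf("# objective: %.10g", fit$objective),
               sprintf("# r2: %s", format(fit$r2, digits = 10)),
               sprintf("# converged: %s", fit$converged)), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' Read a fit result written by [write_fit_result()]
#'
#' @param path File path.
#' @return A `fit_result`-like list (`estimates`, `ci`, `r2`, `objective`,
#'   `converged`, `method`).
#' @export
read_fit_result <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(paste0("^# ", key, ": "), "",
                           grep(paste0("^# ", key, ":"), hdr, value = TRUE))
  tab <- utils::read.csv(text = lines[!grepl("^#", lines)])
  est <- stats::setNames(tab$estimate, tab$parameter)
  ci <- if (all(is.na(tab$lo95))) NULL else
    rbind(`2.5%` = stats::setNames(tab$lo95, tab$parameter),
          `97.5%` = stats::setNames(tab$hi95, tab$parameter))
  out <- list(params = as_choice_params(est), estimates = est, ci = ci,
              r2 = suppressWarnings(as.numeric(get("r2"))),
              objective = as.numeric(get("objective")),
              converged = as.logical(get("converged")),
              method = get("method"))
  class(out) <- "fit_result"
  out
}

#' Condition-average benchmark fits from a local copy of the study deposit
#'
#' Given a directory containing per-experiment trial logs of real fox/rabbit
#' play (fetched manually; no downloader is provided), reads every log,
#' pools the group condition grid and fits the choice model, returning one
#' row of parameter estimates and R^2 per experiment subdirectory or file.
#'
#' @param dir Directory with trial-log CSVs (optionally in per-experiment
#'   subdirectories).
#' @param column_map Optional column remapping passed to
#'   [read_trial_log()].
#' @return Data frame: `experiment`, `ms`, `sm`, `pe`, `ss`, `r2`.
#' @export
fit_osf_benchmark <- function(dir, column_map = NULL) {
  if (!dir.exists(dir))
    stop("deposit directory not found: ", dir,
         " (fetch the study data manually and point `dir` at it)",
         call. = FALSE)
  subs <- list.dirs(dir, recursive = FALSE)
  units <- if (length(subs)) subs else dir
  out <- lapply(units, function(u) {
    files <- list.files(u, pattern = "\\.csv$", full.names = TRUE)
    if (!length(files)) return(NULL)
    logs <- lapply(files, read_trial_log, column_map = column_map)
    for (i in seq_along(logs))
      if (is.null(logs[[i]]$subject_id)) logs[[i]]$subject_id <- i
    trials <- do.call(rbind, logs)
    fit <- fit_condition_averages(condition_switch_rates(trials), ci = "none")
    data.frame(experiment = basename(u), t(fit$estimates), r2 = fit$r2)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no trial-log CSVs found under ", dir, call. = FALSE)
  rownames(res) <- NULL
  res
}
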