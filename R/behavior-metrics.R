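#' Per-day reward rate normalized to the habituation median
#'
#' Computes, per mouse and day, the reward rate (rewards per non-timeout
#' trial) and its percent change relative to that mouse's median rate over
#' habituation days. The first block of every session (re-acquaintance with
#' the task) and timeout trials are excluded.
#'
#' @param logs Stacked session-log data frame (one or many mice).
#' @return Data frame with columns `mouse_id, epoch, day, n_trials,
#'   n_rewards, rate, pct_change`.
#' @export
normalized_reward_rate <- function(logs) {
  keep <- logs$choice != "timeout" & logs$block_idx > 0L
  df <- as.data.frame(logs)[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop("no eligible trials", call. = FALSE)
  agg <- stats::aggregate(rewarded ~ mouse_id + epoch + day, data = df,
                          FUN = function(x) c(n = length(x), r = sum(x)))
  out <- data.frame(mouse_id = agg$mouse_id, epoch = agg$epoch,
                    day = agg$day,
                    n_trials = agg$rewarded[, "n"],
                    n_rewards = agg$rewarded[, "r"],
                    stringsAsFactors = FALSE)
  out$rate <- out$n_rewards / out$n_trials
  out <- out[order(out$mouse_id, out$epoch, out$day), , drop = FALSE]
  res <- lapply(split(out, out$mouse_id), function(m) {
    hab <- m$rate[m$epoch == "habituation"]
    if (length(hab) == 0L) {
      stop("mouse ", m$mouse_id[1], " has no habituation days", call. = FALSE)
    }
    m$pct_change <- 100 * (m$rate / stats::median(hab) - 1)
    m
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' p(high) as a function of trial position around block transitions
#'
#' For every block transition in the logs, trials at offsets relative to the
#' transition (offset 0 = first trial of the new block) are scored against
#' the contemporaneous high spout: negative offsets against the old high
#' spout, nonnegative against the new one. Offsets are restricted to within
#' the adjacent blocks so neighboring transitions never contaminate the
#' curve. Timeouts are excluded. Offsets with zero eligible trials are
#' reported as `NA`, never fabricated.
#'
#' @param logs Stacked session-log data frame.
#' @param window Integer vector of offsets, e.g. `-5:15`.
#' @return Data frame `offset, p_high, n` of class `transition_curve`.
#' @export
p_high_curve <- function(logs, window = -5:15) {
  window <- sort(unique(as.integer(window)))
  hit <- stats::setNames(numeric(length(window)), window)
  n <- stats::setNames(numeric(length(window)), window)
  for (s in split_sessions(logs)) {
    bidx <- s$block_idx
    starts <- which(c(FALSE, diff(bidx) != 0))  # row index of offset 0
    for (st in starts) {
      for (k in seq_along(window)) {
        off <- window[k]
        i <- st + off
        if (i < 1L || i > nrow(s)) next
        # stay inside the block the offset refers to
        if (off >= 0L && bidx[i] != bidx[st]) next
        if (off < 0L && bidx[i] != bidx[st - 1L]) next
        if (s$choice[i] == "timeout") next
        n[k] <- n[k] + 1
        hit[k] <- hit[k] + (s$choice[i] == s$high_spout[i])
      }
    }
  }
  out <- data.frame(offset = window,
                    p_high = ifelse(n > 0, hit / n, NA_real_),
                    n = as.integer(n))
  class(out) <- c("transition_curve", "data.frame")
  out
}

#' Exponential recovery fit after the block transition
#'
#' Fits `p(n) = A - (A - p0) * exp(-n / tau)` by unweighted least squares
#' over post-transition offsets `n >= 0` with defined values. All three
#' parameters (asymptote `A`, intercept `p0`, time constant `tau`) are free.
#' Non-recovering (near-constant) curves and fits with nonpositive `tau`
#' are flagged invalid.
#'
#' @param curve A [p_high_curve()] result (or data frame with `offset`,
#'   `p_high`).
#' @return List of class `transition_fit`: `tau`, `asymptote`, `intercept`,
#'   `rss`, `valid`, `message`.
#' @export
fit_transition_tau <- function(curve) {
  d <- curve[curve$offset >= 0 & is.finite(curve$p_high), , drop = FALSE]
  invalid <- function(msg) {
    structure(list(tau = NA_real_, asymptote = NA_real_,
                   intercept = NA_real_, rss = NA_real_,
                   valid = FALSE, message = msg),
              class = "transition_fit")
  }
  if (nrow(d) < 4L) return(invalid("fewer than 4 post-transition offsets"))
  x <- as.numeric(d$offset); y <- d$p_high
  if (stats::sd(y) < 1e-8) return(invalid("constant curve: no recovery dynamics"))
  rss_fun <- function(par) {
    A <- par[1]; p0 <- par[2]; tau <- exp(par[3])
    sum((y - (A - (A - p0) * exp(-x / tau)))^2)
  }
  A0 <- max(y); p00 <- y[1]
  best <- NULL
  for (tau0 in c(1, 3, 10)) {
    o <- stats::optim(c(A0, p00, log(tau0)), rss_fun, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
    # Nelder-Mead polish guards against BFGS stalling on flat regions
    o <- stats::optim(o$par, rss_fun,
                      control = list(maxit = 5000, reltol = 1e-15))
    if (is.null(best) || o$value < best$value) best <- o
  }
  tau <- exp(best$par[3])
  if (!is.finite(tau) || tau <= 0 || tau > 1e6) {
    return(invalid("fit did not converge to a positive finite tau"))
  }
  structure(list(tau = tau, asymptote = best$par[1],
                 intercept = best$par[2], rss = best$value,
                 valid = TRUE, message = "ok"),
            class = "transition_fit")
}

#' Conditional switch probabilities after two-trial histories
#'
#' A history is two consecutive non-timeout trials on the same spout with an
#' outcome pair in \{RR, RU, UR, UU\} (ordered older to newer; R = rewarded,
#' U = unrewarded). The outcome event is the next non-timeout trial
#' (timeouts are transparent); a switch means choosing the other spout.
#' Histories are counted per mouse within sessions, and a history must occur
#' strictly more than `min_count` times for that mouse to be reported as
#' included.
#'
#' @param logs Stacked session-log data frame.
#' @param min_count Exclusion threshold: histories with count
#'   `<= min_count` are marked excluded. Default 50.
#' @return Data frame `mouse_id, history, n, p_switch, included`.
#' @export
conditional_switch_probs <- function(logs, min_count = 50L) {
  rows <- list()
  for (s in split_sessions(logs)) {
    s <- s[s$choice != "timeout", , drop = FALSE]
    n <- nrow(s)
    if (n < 3L) next
    t <- seq_len(n - 2L)
    same <- s$choice[t] == s$choice[t + 1L]
    if (!any(same)) next
    t <- t[same]
    rows[[length(rows) + 1L]] <- data.frame(
      mouse_id = s$mouse_id[1],
      history = paste0(ifelse(s$rewarded[t], "R", "U"),
                       ifelse(s$rewarded[t + 1L], "R", "U")),
      switch = s$choice[t + 2L] != s$choice[t + 1L],
      stringsAsFactors = FALSE)
  }
  grid <- expand.grid(mouse_id = unique(logs$mouse_id),
                      history = c("RR", "RU", "UR", "UU"),
                      stringsAsFactors = FALSE)
  if (length(rows) == 0L) {
    grid$n <- 0L; grid$p_switch <- NA_real_; grid$included <- FALSE
    return(grid[order(grid$mouse_id, grid$history), ])
  }
  ev <- do.call(rbind, rows)
  out <- grid
  out$n <- 0L; out$p_switch <- NA_real_
  for (i in seq_len(nrow(out))) {
    sel <- ev$mouse_id == out$mouse_id[i] & ev$history == out$history[i]
    out$n[i] <- sum(sel)
    if (out$n[i] > 0L) out$p_switch[i] <- mean(ev$switch[sel])
  }
  out$included <- out$n > min_count
  out[order(out$mouse_id, out$history), ]
}

#' Training performance criterion
#'
#' Met when any contiguous window of `window` days has mean daily p(high)
#' strictly above `threshold`.
#'
#' @param daily_p_high Numeric vector of per-day p(high), in day order.
#' @param window Window length in days (default 5).
#' @param threshold Strict lower bound on the window mean (default 0.6).
#' @return `TRUE`/`FALSE`, or `NA` when fewer than `window` days are
#'   available (not evaluable, distinct from failure).
#' @export
performance_criterion <- function(daily_p_high, window = 5L, threshold = 0.6) {
  n <- length(daily_p_high)
  if (n < window) return(NA)
  means <- vapply(seq_len(n - window + 1L),
                  function(i) mean(daily_p_high[i:(i + window - 1L)]), 0)
  any(means > threshold)
}

#' Write tidy behavioral metric tables
#'
#' @param df A tidy metric data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
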