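#' Block-length scheme for the two-armed bandit task
#'
#' Describes how block lengths (the number of trials between uncued reward
#' reversals) are drawn. Two kinds are supported: a fixed length for every
#' block, or a discrete distribution over lengths. The task variants used in
#' practice are a fixed length of 20 trials, and a variable scheme drawing
#' 20, 30 or 40 trials with probabilities 0.43, 0.32 and 0.25.
#'
#' @param kind `"fixed"` or `"variable"`.
#' @param fixed_length Positive integer block length (used when
#'   `kind = "fixed"`).
#' @param lengths Integer vector of candidate block lengths (variable kind).
#' @param probs Numeric vector of probabilities, same length as `lengths`,
#'   summing to 1 (within 1e-12).
#' @return An object of class `block_scheme`.
#' @examples
#' block_scheme("fixed", fixed_length = 20)
#' block_scheme("variable", lengths = c(20, 30, 40), probs = c(0.43, 0.32, 0.25))
#' @export
block_scheme <- function(kind = c("fixed", "variable"), fixed_length = 20L,
                         lengths = NULL, probs = NULL) {
  kind <- match.arg(kind)
  if (kind == "fixed") {
    if (length(fixed_length) != 1L || !is.finite(fixed_length) ||
        fixed_length < 1 || fixed_length != round(fixed_length)) {
      stop("`fixed_length` must be a single positive integer", call. = FALSE)
    }
    out <- list(kind = "fixed", fixed_length = as.integer(fixed_length))
  } else {
    if (is.null(lengths) || is.null(probs) || length(lengths) != length(probs) ||
        length(lengths) == 0L) {
      stop("variable scheme needs `lengths` and `probs` of equal positive length",
           call. = FALSE)
    }
    if (any(!is.finite(lengths)) || any(lengths < 1) ||
        any(lengths != round(lengths))) {
      stop("block lengths must be positive integers", call. = FALSE)
    }
    if (any(!is.finite(probs)) || any(probs < 0) ||
        abs(sum(probs) - 1) > 1e-12) {
      stop("`probs` must be nonnegative and sum to 1 within 1e-12",
           call. = FALSE)
    }
    out <- list(kind = "variable", lengths = as.integer(lengths),
                probs = as.numeric(probs))
  }
  structure(out, class = "block_scheme")
}

#' @export
print.block_scheme <- function(x, ...) {
  if (x$kind == "fixed") {
    cat("<block_scheme> fixed, length", x$fixed_length, "trials\n")
  } else {
    cat("<block_scheme> variable:",
        paste0(x$lengths, " (p=", format(x$probs), ")", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Task configuration for the two-armed bandit
#'
#' Reward contingencies and session structure. On each trial one spout (the
#' "high" spout) rewards a choice with probability `p_high` and the other
#' with `p_low`; the high-spout identity reverses at every block boundary.
#' The standard probabilistic task uses 0.8 / 0.2.
#'
#' @param p_high Reward probability at the currently favorable spout.
#' @param p_low Reward probability at the other spout; `p_low <= p_high`.
#' @param scheme A [block_scheme()].
#' @param n_trials Trials per session.
#' @return An object of class `task_config`.
#' @export
task_config <- function(p_high = 0.8, p_low = 0.2,
                        scheme = block_scheme("fixed", 20L),
                        n_trials = 300L) {
  stopifnot(inherits(scheme, "block_scheme"))
  if (!is.finite(p_high) || !is.finite(p_low) ||
      p_low < 0 || p_high > 1 || p_low > p_high) {
    stop("need 0 <= p_low <= p_high <= 1", call. = FALSE)
  }
  if (n_trials < 1 || n_trials != round(n_trials)) {
    stop("`n_trials` must be a positive integer", call. = FALSE)
  }
  structure(list(p_high = p_high, p_low = p_low, scheme = scheme,
                 n_trials = as.integer(n_trials)),
            class = "task_config")
}

#' Sample one block length from a scheme
#'
#' Uses the current R random stream; seed with `set.seed()` for
#' reproducibility.
#'
#' @param scheme A [block_scheme()].
#' @return A single positive integer in the scheme's support.
#' @export
sample_block_length <- function(scheme) {
  stopifnot(inherits(scheme, "block_scheme"))
  if (scheme$kind == "fixed") return(scheme$fixed_length)
  scheme$lengths[sample.int(length(scheme$lengths), 1L, prob = scheme$probs)]
}

#' Run one bandit session under an arbitrary policy
#'
#' Simulates the task environment trial by trial. The policy is a function
#' `policy(info)` returning `"L"`, `"R"` or `"timeout"`, where `info` is a
#' list with `trial_idx` (0-based), `prev_choice` and `prev_rewarded` (the
#' preceding trial's outcome, `NA` on the first trial), and `high_spout`
#' (the hidden contemporaneous high spout, available so oracle policies can
#' be written; a realistic agent must ignore it and track its own history).
#' Rewards are Bernoulli draws at `p_high` for the contemporaneous high
#' spout and `p_low` otherwise; timeouts are never rewarded and are
#' produced only if the policy emits them. The initial high spout is drawn
#' uniformly at random. A session may end mid-block; the partial final
#' block keeps its true sampled length.
#'
#' @param config A [task_config()].
#' @param policy Function of the per-trial `info` list returning a choice
#'   symbol.
#' @param mouse_id,session_id,epoch,day Session annotations carried into the
#'   log.
#' @return A `session_log` data frame with columns `mouse_id, session_id,
#'   epoch, day, trial_idx, block_idx, trial_in_block, high_spout, choice,
#'   rewarded` and an attribute `block_lengths` holding every sampled length
#'   (including the possibly unfinished final block).
#' @export
run_session <- function(config, policy, mouse_id = "m0", session_id = "s0",
                        epoch = "habituation", day = 0L) {
  stopifnot(inherits(config, "task_config"), is.function(policy))
  n <- config$n_trials
  high <- character(n); choice <- character(n); rewarded <- logical(n)
  block_idx <- integer(n); trial_in_block <- integer(n)
  cur_high <- if (stats::runif(1) < 0.5) "L" else "R"
  blk_len <- sample_block_length(config$scheme)
  block_lengths <- blk_len
  blk <- 0L; tib <- 0L
  for (t in seq_len(n)) {
    ch <- policy(list(
      trial_idx = t - 1L,
      prev_choice = if (t > 1L) choice[t - 1L] else NA_character_,
      prev_rewarded = if (t > 1L) rewarded[t - 1L] else NA,
      high_spout = cur_high))
    if (!is.character(ch) || length(ch) != 1L ||
        !ch %in% c("L", "R", "timeout")) {
      stop("policy must return 'L', 'R' or 'timeout'", call. = FALSE)
    }
    rew <- FALSE
    if (ch != "timeout") {
      p <- if (ch == cur_high) config$p_high else config$p_low
      rew <- stats::runif(1) < p
    }
    high[t] <- cur_high; choice[t] <- ch; rewarded[t] <- rew
    block_idx[t] <- blk; trial_in_block[t] <- tib
    tib <- tib + 1L
    if (tib >= blk_len && t < n) {
      cur_high <- if (cur_high == "L") "R" else "L"
      blk <- blk + 1L; tib <- 0L
      blk_len <- sample_block_length(config$scheme)
      block_lengths <- c(block_lengths, blk_len)
    }
  }
  log <- data.frame(
    mouse_id = mouse_id, session_id = session_id, epoch = epoch,
    day = as.integer(day), trial_idx = seq_len(n) - 1L,
    block_idx = block_idx, trial_in_block = trial_in_block,
    high_spout = high, choice = choice, rewarded = rewarded,
    stringsAsFactors = FALSE)
  attr(log, "block_lengths") <- block_lengths
  class(log) <- c("session_log", "data.frame")
  log
}

#' Read / write session logs
#'
#' The session-log CSV dialect is shared by all behavioral functions:
#' columns `mouse_id,session_id,epoch,day,trial_idx,block_idx,
#' trial_in_block,high_spout,choice,rewarded`, with `choice` in
#' `{L, R, timeout}` and `rewarded` in `{0, 1}`.
#'
#' @param logs A session-log data frame (one or many sessions stacked).
#' @param path File path.
#' @return `read_session_log()` returns the data frame;
#'   `write_session_log()` returns `path` invisibly.
#' @export
write_session_log <- function(logs, path) {
  cols <- c("mouse_id", "session_id", "epoch", "day", "trial_idx",
            "block_idx", "trial_in_block", "high_spout", "choice", "rewarded")
  stopifnot(all(cols %in% names(logs)))
  out <- logs[, cols]
  out$rewarded <- as.integer(out$rewarded)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$rewarded <- as.logical(df$rewarded)
  class(df) <- c("session_log", "data.frame")
  df
}

# Split a stacked log into a list of single-session data frames, preserving
# trial order within each session.
split_sessions <- function(logs) {
  key <- paste(logs$mouse_id, logs$session_id, sep = "\r")
  out <- split(as.data.frame(logs), key)
  lapply(out, function(s) s[order(s$trial_idx), , drop = FALSE])
}
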