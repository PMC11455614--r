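make_logs <- function(...) {
  out <- rbind(...)
  class(out) <- c("session_log", "data.frame")
  out
}

test_that("normalized_reward_rate excludes first blocks and normalizes to habituation", {
  tc <- task_config(n_trials = 200, scheme = block_scheme("fixed", 20))
  mk <- function(day, epoch, seed, sid) {
    set.seed(seed)
    log <- run_session(tc, function(info) info$high_spout,
                       mouse_id = "m1", session_id = sid, epoch = epoch,
                       day = day)
    log
  }
  logs <- make_logs(mk(0, "habituation", 1, "h0"), mk(1, "habituation", 2, "h1"),
                    mk(2, "habituation", 3, "h2"), mk(3, "treatment", 4, "t0"))
  rs <- normalized_reward_rate(logs)
  expect_equal(nrow(rs), 4)
  # manual recomputation for one day
  d0 <- logs[logs$day == 0 & logs$block_idx > 0 & logs$choice != "timeout", ]
  expect_equal(rs$rate[rs$day == 0], mean(d0$rewarded))
  hab_med <- median(rs$rate[rs$epoch == "habituation"])
  expect_equal(rs$pct_change, 100 * (rs$rate / hab_med - 1))
  # derived arithmetic: 0.66 vs habituation median 0.60 is +10%
  expect_equal(100 * (0.66 / 0.60 - 1), 10, tolerance = 1e-12)
  # duplicating sessions (scale invariance) leaves percent change unchanged
  dup <- logs
  dup$session_id <- paste0(dup$session_id, "_dup")
  rs2 <- normalized_reward_rate(make_logs(logs, dup))
  expect_equal(rs2$pct_change, rs$pct_change)
  # a mouse with no habituation days errors
  tr_only <- logs[logs$epoch == "treatment", ]
  expect_error(normalized_reward_rate(tr_only), "habituation")
})

test_that("p_high_curve equals the brute-force tally oracle on simulated agents", {
  tc <- task_config(scheme = block_scheme("variable",
                                          lengths = c(20L, 30L, 40L),
                                          probs = c(0.43, 0.32, 0.25)),
                    n_trials = 300)
  logs <- do.call(rbind, lapply(1:10, function(i) {
    simulate_agent(q_params(0.6, 0.3, 3, 0), tc, seed = i,
                   mouse_id = sprintf("m%02d", i))
  }))
  window <- -5:15
  curve <- p_high_curve(logs, window)
  expect_equal(curve$p_high, unname(oracle_p_high(logs, window)))
  expect_true(all(curve$p_high >= 0 & curve$p_high <= 1, na.rm = TRUE))
})

test_that("p_high_curve handles perseverating agents and missing offsets", {
  # an agent that always picks the block-0 high spout: 1 before the first
  # transition, 0 after it
  tc <- task_config(p_high = 1, p_low = 0,
                    scheme = block_scheme("fixed", 10), n_trials = 20)
  set.seed(2)
  first_high <- NULL
  log <- run_session(tc, function(info) {
    if (is.null(first_high)) first_high <<- info$high_spout
    first_high
  })
  curve <- p_high_curve(log, -3:3)
  expect_equal(curve$p_high[curve$offset < 0], rep(1, 3))
  expect_equal(curve$p_high[curve$offset >= 0], rep(0, 4))
  # offsets beyond any block are NA with zero counts, not zero
  far <- p_high_curve(log, 90:92)
  expect_true(all(is.na(far$p_high)))
  expect_true(all(far$n == 0))
})

test_that("L/R relabeling symmetry leaves the curve unchanged", {
  tc <- task_config(n_trials = 300)
  logs <- simulate_agent(q_params(0.6, 0.3, 3, 0), tc, n_sessions = 5,
                         seed = 77)
  flip <- function(x) ifelse(x == "L", "R", ifelse(x == "R", "L", x))
  mirrored <- logs
  mirrored$choice <- flip(mirrored$choice)
  mirrored$high_spout <- flip(mirrored$high_spout)
  expect_equal(p_high_curve(logs, -4:10)$p_high,
               p_high_curve(mirrored, -4:10)$p_high)
})

test_that("fit_transition_tau recovers a noiseless exponential exactly", {
  tau <- 3.0; A <- 0.85; p0 <- 0.2
  offs <- 0:19
  curve <- data.frame(offset = offs,
                      p_high = A - (A - p0) * exp(-offs / tau),
                      n = 100L)
  fit <- fit_transition_tau(curve)
  expect_true(fit$valid)
  expect_equal(fit$tau, tau, tolerance = 1e-6)
  expect_equal(fit$asymptote, A, tolerance = 1e-6)
  expect_equal(fit$intercept, p0, tolerance = 1e-6)
})

test_that("fit_transition_tau flags degenerate curves", {
  const <- data.frame(offset = 0:9, p_high = rep(0.7, 10), n = 50L)
  expect_false(fit_transition_tau(const)$valid)
  short <- data.frame(offset = 0:2, p_high = c(0.2, 0.5, 0.6), n = 50L)
  expect_false(fit_transition_tau(short)$valid)
})

test_that("smaller beta gives smaller fitted tau (monotone trend)", {
  tc <- task_config(scheme = block_scheme("fixed", 30), n_trials = 300)
  taus <- vapply(c(1, 2, 4), function(beta) {
    logs <- do.call(rbind, lapply(1:12, function(i) {
      simulate_agent(q_params(0.6, 0.3, beta, 0), tc, seed = 1000 * beta + i,
                     mouse_id = sprintf("m%02d", i))
    }))
    fit_transition_tau(p_high_curve(logs, 0:25))$tau
  }, 0)
  expect_true(all(diff(taus) > 0))
})

test_that("conditional_switch_probs equals exhaustive enumeration on the hand-written log", {
  log <- handwritten_session()
  tab <- conditional_switch_probs(log, min_count = 0)
  orc <- oracle_switch(log)
  for (h in c("RR", "RU", "UR", "UU")) {
    sub <- orc[orc$history == h, ]
    row <- tab[tab$history == h, ]
    expect_equal(row$n, nrow(sub))
    if (nrow(sub) > 0) expect_equal(row$p_switch, mean(sub$switch))
  }
  # spot-checked by hand: RR histories at pairs (1,2) and (9,10), both
  # followed by a stay; UU once at (7,8), followed by a switch
  expect_equal(tab$n[tab$history == "RR"], 2L)
  expect_equal(tab$p_switch[tab$history == "RR"], 0)
  expect_equal(tab$n[tab$history == "UU"], 1L)
  expect_equal(tab$p_switch[tab$history == "UU"], 1)
})

test_that("win-stay / lose-shift agent gives P(switch|UU)=1 and P(switch|RR)=0", {
  tc <- task_config(n_trials = 400)
  set.seed(12)
  last <- "L"
  log <- run_session(tc, function(info) {
    if (!is.na(info$prev_choice)) {
      last <<- if (info$prev_rewarded) info$prev_choice else
        setdiff(c("L", "R"), info$prev_choice)
    }
    last
  })
  tab <- conditional_switch_probs(log, min_count = 5)
  expect_equal(tab$p_switch[tab$history == "RR"], 0)
  # a deterministic WSLS agent switches immediately after any failure, so a
  # same-spout history starting with U can never arise: UU is unobserved
  # (vacuously P(switch | UU) = 1 in the limit), while RU is always
  # followed by a switch
  expect_equal(tab$n[tab$history == "UU"], 0L)
  expect_equal(tab$p_switch[tab$history == "RU"], 1)
})

test_that("the >50 occurrence threshold is strict", {
  # history occurring exactly 50 times is excluded at the default threshold
  block <- data.frame(
    mouse_id = "m1", session_id = "s1", epoch = "habituation", day = 0L,
    trial_idx = 0:149,
    block_idx = 0L, trial_in_block = 0:149, high_spout = "L",
    choice = "L", rewarded = TRUE, stringsAsFactors = FALSE)
  # 150 rewarded L-trials: 148 RR histories; truncate to exactly 52 trials
  # so that RR occurs 50 times
  b <- block[1:52, ]
  tab <- conditional_switch_probs(b, min_count = 50)
  expect_equal(tab$n[tab$history == "RR"], 50L)
  expect_false(tab$included[tab$history == "RR"])
  tab2 <- conditional_switch_probs(block[1:53, ], min_count = 50)
  expect_true(tab2$included[tab2$history == "RR"])
})

test_that("timeouts are transparent to switch histories", {
  log <- handwritten_session()
  # insert a timeout between trials: shifts indices but not the filtered
  # event stream
  extra <- log[1, ]
  extra$trial_idx <- 3.5; extra$choice <- "timeout"; extra$rewarded <- FALSE
  aug <- rbind(log[1:4, ], extra, log[5:12, ])
  expect_equal(conditional_switch_probs(aug, min_count = 0)$p_switch,
               conditional_switch_probs(log, min_count = 0)$p_switch)
})

test_that("performance_criterion applies a strict window mean", {
  expect_true(performance_criterion(rep(0.7, 5)))
  expect_false(performance_criterion(rep(0.6, 5)))  # strict inequality
  expect_true(is.na(performance_criterion(rep(0.9, 4))))
  expect_true(performance_criterion(c(0.2, 0.2, rep(0.65, 5))))
})
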