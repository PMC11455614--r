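# Independent oracles used across the suite. Each re-derives a quantity by
# the most literal route available (plain loops, enumeration, closed forms)
# and must stay independent of the package code paths it checks.

# Literal R re-simulation of the Q-value recursion and per-trial likelihood
# over a stacked log: the oracle for session_nll / qlearn_forward.
oracle_nll <- function(logs, params) {
  total <- 0; n <- 0
  for (s in split(as.data.frame(logs),
                  paste(logs$mouse_id, logs$session_id))) {
    s <- s[order(s$trial_idx), ]
    qL <- 0; qR <- 0
    for (i in seq_len(nrow(s))) {
      if (s$choice[i] == "timeout") next
      p_right <- 1 / (1 + exp(-(params$beta * (qR - qL) + params$bias)))
      p_obs <- if (s$choice[i] == "R") p_right else 1 - p_right
      total <- total - log(p_obs)
      n <- n + 1
      R <- as.numeric(s$rewarded[i])
      if (s$choice[i] == "R") {
        qR <- qR + params$alpha * (R - qR)
        qL <- (1 - params$zeta) * qL
      } else {
        qL <- qL + params$alpha * (R - qL)
        qR <- (1 - params$zeta) * qR
      }
    }
  }
  total / n
}

# Brute-force per-offset p(high) tally around block transitions, restricted
# to the adjacent blocks, mirroring the documented curve semantics.
oracle_p_high <- function(logs, window) {
  hit <- setNames(numeric(length(window)), window)
  n <- setNames(numeric(length(window)), window)
  for (s in split(as.data.frame(logs),
                  paste(logs$mouse_id, logs$session_id))) {
    s <- s[order(s$trial_idx), ]
    starts <- which(c(FALSE, diff(s$block_idx) != 0))
    for (st in starts) {
      for (k in seq_along(window)) {
        i <- st + window[k]
        if (i < 1 || i > nrow(s)) next
        ref_block <- if (window[k] >= 0) s$block_idx[st] else
          s$block_idx[st - 1]
        if (s$block_idx[i] != ref_block) next
        if (s$choice[i] == "timeout") next
        n[k] <- n[k] + 1
        hit[k] <- hit[k] + (s$choice[i] == s$high_spout[i])
      }
    }
  }
  ifelse(n > 0, hit / n, NA_real_)
}

# Exhaustive enumeration of two-trial same-spout histories and the switch
# outcome on the following trial (timeout-filtered stream).
oracle_switch <- function(logs) {
  out <- list()
  for (s in split(as.data.frame(logs),
                  paste(logs$mouse_id, logs$session_id))) {
    s <- s[order(s$trial_idx), ]
    s <- s[s$choice != "timeout", ]
    if (nrow(s) < 3) next
    for (t in 1:(nrow(s) - 2)) {
      if (s$choice[t] != s$choice[t + 1]) next
      h <- paste0(ifelse(s$rewarded[t], "R", "U"),
                  ifelse(s$rewarded[t + 1], "R", "U"))
      out[[length(out) + 1]] <- c(h, s$choice[t + 2] != s$choice[t + 1])
    }
  }
  if (length(out) == 0) return(NULL)
  m <- do.call(rbind, out)
  data.frame(history = m[, 1], switch = as.logical(m[, 2]),
             stringsAsFactors = FALSE)
}

# Step-up Benjamini-Hochberg by its textbook definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  adj[o] <- p[o] * m / seq_len(m)
  adj[o] <- rev(cummin(rev(adj[o])))
  pmin(adj, 1)
}

# Spearman correlation as rank-then-Pearson with average ranks.
oracle_spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  stats::cor(rank(x[ok]), rank(y[ok]))
}

# Brute-force Ward (ward.D2) agglomeration returning sorted merge heights.
# Lance-Williams on squared Euclidean distances; heights are square roots.
oracle_ward_heights <- function(X) {
  d2 <- as.matrix(stats::dist(X))^2
  active <- seq_len(nrow(X))
  sizes <- rep(1, nrow(X))
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bestv <- Inf
    for (a in seq_along(active)) {
      for (b in seq_len(a - 1)) {
        v <- d2[active[a], active[b]]
        if (v < bestv) { bestv <- v; best <- c(active[a], active[b]) }
      }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(bestv))
    ni <- sizes[i]; nj <- sizes[j]
    for (k in active) {
      if (k == i || k == j) next
      nk <- sizes[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * bestv) /
        (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  sort(heights)
}

# Per-gene ordinary least squares t-statistic for the condition column,
# via lm(), the oracle for the unmoderated route.
oracle_lm_t <- function(y, cond, covars) {
  apply(y, 1, function(v) {
    df <- data.frame(v = v, cond = cond, covars)
    fit <- stats::lm(v ~ ., data = df)
    stats::coef(summary(fit))["cond", "t value"]
  })
}

# A hand-written 12-trial single-session log with known history structure.
# choices:  L L L R R L L L R R R R
# rewarded: 1 1 0 0 1 1 0 0 1 1 0 1
handwritten_session <- function() {
  data.frame(
    mouse_id = "hw", session_id = "s1", epoch = "habituation", day = 0L,
    trial_idx = 0:11,
    block_idx = c(rep(0L, 6), rep(1L, 6)),
    trial_in_block = c(0:5, 0:5),
    high_spout = c(rep("L", 6), rep("R", 6)),
    choice = c("L", "L", "L", "R", "R", "L", "L", "L", "R", "R", "R", "R"),
    rewarded = as.logical(c(1, 1, 0, 0, 1, 1, 0, 0, 1, 1, 0, 1)),
    stringsAsFactors = FALSE)
}

# Tiny deterministic nucleus-count fixture: `n` nuclei split over samples
# and conditions with Poisson-ish structured counts.
tiny_nuclei <- function(n_genes = 60, samples = c("a", "b", "c", "d"),
                        conds = c("control", "control", "T3", "T3"),
                        nuclei_per_sample = 40, seed = 99) {
  set.seed(seed)
  base <- stats::rgamma(n_genes, 1, 1) + 0.05
  cols <- list(); meta <- list()
  for (i in seq_along(samples)) {
    mu <- outer(base, stats::rlnorm(nuclei_per_sample, log(20), 0.2) / sum(base))
    cnt <- matrix(stats::rpois(length(mu), mu), nrow = n_genes)
    cols[[i]] <- cnt
    meta[[i]] <- data.frame(cell_type = "typeA", sample_id = samples[i],
                            condition = conds[i], cre_status = "n/a",
                            pct_mt = stats::runif(nuclei_per_sample, 1, 5),
                            stringsAsFactors = FALSE)
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- sprintf("g%03d", seq_len(n_genes))
  md <- do.call(rbind, meta)
  md$n_genes <- colSums(counts > 0)
  nucleus_counts(counts, md)
}
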