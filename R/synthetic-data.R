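#' Cohort specification for synthetic bandit experiments
#'
#' Describes a simulated cohort of mice run through habituation and
#' treatment epochs of the bandit task. Per-mouse Q-learning parameters are
#' drawn from uniform priors chosen to span the range of well-trained
#' performers (documented in the methods vignette); the treatment epoch
#' multiplies each mouse's inverse temperature by `beta_factor`, emulating
#' a T3-like shift toward exploration when `beta_factor < 1`.
#'
#' @param n_mice Number of mice (default 12, matching a typical cohort).
#' @param sessions_per_epoch Sessions per epoch (default 4).
#' @param trials_per_session Trials per session (default 350).
#' @param alpha_range,zeta_range,beta_range,bias_sd Parameter priors:
#'   uniform ranges for the learning rate, forgetting rate and inverse
#'   temperature, and a normal sd for the bias.
#' @param beta_factor Multiplicative treatment effect on beta (default 0.7).
#' @param task A [task_config()].
#' @param seed Integer seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mice = 12L, sessions_per_epoch = 4L,
                        trials_per_session = 350L,
                        alpha_range = c(0.4, 0.8), zeta_range = c(0.1, 0.5),
                        beta_range = c(2, 5), bias_sd = 0.1,
                        beta_factor = 0.7,
                        task = task_config(
                          p_high = 0.8, p_low = 0.2,
                          scheme = block_scheme("variable",
                                                lengths = c(20L, 30L, 40L),
                                                probs = c(0.43, 0.32, 0.25)),
                          n_trials = 350L),
                        seed = 1L) {
  stopifnot(beta_factor > 0, n_mice >= 1,
            all(alpha_range >= 0), all(alpha_range <= 1),
            all(zeta_range >= 0), all(zeta_range <= 1), all(beta_range >= 0))
  structure(list(n_mice = as.integer(n_mice),
                 sessions_per_epoch = as.integer(sessions_per_epoch),
                 trials_per_session = as.integer(trials_per_session),
                 alpha_range = alpha_range, zeta_range = zeta_range,
                 beta_range = beta_range, bias_sd = bias_sd,
                 beta_factor = beta_factor, task = task,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws per-mouse parameters from the spec's priors, simulates habituation
#' sessions, applies the multiplicative beta treatment effect, and simulates
#' treatment sessions, all via [simulate_agent()] on the spec's task.
#'
#' @param spec A [cohort_spec()].
#' @return List: `logs` (stacked session-log data frame over both epochs)
#'   and `truth` (data frame of per-mouse true parameters per epoch).
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  mice <- sprintf("m%02d", seq_len(spec$n_mice))
  truth <- data.frame(
    mouse_id = mice,
    alpha = stats::runif(spec$n_mice, spec$alpha_range[1], spec$alpha_range[2]),
    zeta = stats::runif(spec$n_mice, spec$zeta_range[1], spec$zeta_range[2]),
    beta_hab = stats::runif(spec$n_mice, spec$beta_range[1], spec$beta_range[2]),
    bias = stats::rnorm(spec$n_mice, 0, spec$bias_sd),
    stringsAsFactors = FALSE)
  truth$beta_treat <- truth$beta_hab * spec$beta_factor
  task <- spec$task
  task$n_trials <- spec$trials_per_session
  # child seeds drawn up-front so each mouse/epoch is independently rerunnable
  child <- matrix(sample.int(.Machine$integer.max, 2L * spec$n_mice),
                  ncol = 2L)
  logs <- vector("list", 2L * spec$n_mice)
  for (i in seq_len(spec$n_mice)) {
    hab <- simulate_agent(
      q_params(truth$alpha[i], truth$zeta[i], truth$beta_hab[i], truth$bias[i]),
      task, n_sessions = spec$sessions_per_epoch, seed = child[i, 1],
      mouse_id = mice[i], epoch = "habituation", first_day = 0L)
    trt <- simulate_agent(
      q_params(truth$alpha[i], truth$zeta[i], truth$beta_treat[i],
               truth$bias[i]),
      task, n_sessions = spec$sessions_per_epoch, seed = child[i, 2],
      mouse_id = mice[i], epoch = "treatment",
      first_day = spec$sessions_per_epoch)
    logs[[2L * i - 1L]] <- hab
    logs[[2L * i]] <- trt
  }
  out <- do.call(rbind, logs)
  class(out) <- c("session_log", "data.frame")
  list(logs = out, truth = truth)
}

#' Specification for synthetic single-nucleus counts
#'
#' Negative-binomial gene x nucleus counts with per-sample random
#' intercepts, a log-normal library-size distribution, and a fraction of
#' genes "spiked" with a known condition (T3 vs control) log2 fold-change.
#' Per-nucleus percent-mitochondrial values carry mild gene-specific
#' covariate loadings. Scales default well below a real dataset so a full
#' differential-expression run stays under a minute.
#'
#' @param n_genes Number of genes (default 5000).
#' @param n_samples_per_cond Samples per condition (default 4).
#' @param nuclei_per_sample Nuclei per sample (default 250).
#' @param lib_size_meanlog,lib_size_sdlog Log-normal library-size
#'   parameters (defaults log(2500), 0.3).
#' @param dispersion NB dispersion (1/size; default 0.15).
#' @param sample_sdlog SD of per-sample, per-gene log-normal intercepts
#'   (default 0.1).
#' @param spike_fraction Fraction of genes spiked (default 0.04, i.e. 200
#'   of 5000).
#' @param spike_lfc_range Absolute log2FC range for spikes (default 1 to 2;
#'   signs random).
#' @param mt_effect_sd SD of gene-specific loadings on scaled percent-MT
#'   (default 0.05).
#' @param cell_type Cell-type label assigned to every nucleus.
#' @param seed Integer seed.
#' @return List of class `counts_spec`.
#' @export
counts_spec <- function(n_genes = 5000L, n_samples_per_cond = 4L,
                        nuclei_per_sample = 250L,
                        lib_size_meanlog = log(2500), lib_size_sdlog = 0.3,
                        dispersion = 0.15, sample_sdlog = 0.1,
                        spike_fraction = 0.04, spike_lfc_range = c(1, 2),
                        mt_effect_sd = 0.05, cell_type = "L2.3.IT",
                        seed = 1L) {
  stopifnot(spike_fraction >= 0, spike_fraction <= 1, dispersion > 0)
  structure(list(n_genes = as.integer(n_genes),
                 n_samples_per_cond = as.integer(n_samples_per_cond),
                 nuclei_per_sample = as.integer(nuclei_per_sample),
                 lib_size_meanlog = lib_size_meanlog,
                 lib_size_sdlog = lib_size_sdlog,
                 dispersion = dispersion, sample_sdlog = sample_sdlog,
                 spike_fraction = spike_fraction,
                 spike_lfc_range = spike_lfc_range,
                 mt_effect_sd = mt_effect_sd, cell_type = cell_type,
                 seed = as.integer(seed)),
            class = "counts_spec")
}

#' Generate synthetic nucleus counts with a spike-in truth table
#'
#' @param spec A [counts_spec()].
#' @return List: `nuclei` (a [nucleus_counts()]) and `truth` (data frame
#'   `gene, spiked, log2fc` on the generative scale).
#' @export
gen_counts <- function(spec) {
  stopifnot(inherits(spec, "counts_spec"))
  set.seed(spec$seed)
  G <- spec$n_genes
  genes <- sprintf("g%05d", seq_len(G))
  # relative abundance profile: heavy-tailed, as in real UMI data
  rel <- stats::rgamma(G, shape = 0.4, rate = 1)
  rel <- rel / sum(rel)
  n_spike <- round(spec$spike_fraction * G)
  spiked <- sample.int(G, n_spike)
  lfc <- numeric(G)
  lfc[spiked] <- sample(c(-1, 1), n_spike, replace = TRUE) *
    stats::runif(n_spike, spec$spike_lfc_range[1], spec$spike_lfc_range[2])
  mt_load <- stats::rnorm(G, 0, spec$mt_effect_sd)

  samples <- c(sprintf("ctrl%d", seq_len(spec$n_samples_per_cond)),
               sprintf("t3_%d", seq_len(spec$n_samples_per_cond)))
  conds <- rep(c("control", "T3"), each = spec$n_samples_per_cond)
  blocks <- vector("list", length(samples))
  meta <- vector("list", length(samples))
  size <- 1 / spec$dispersion
  for (s in seq_along(samples)) {
    ncell <- spec$nuclei_per_sample
    # per-sample per-gene random intercept (biological sample variability)
    samp_fac <- exp(stats::rnorm(G, 0, spec$sample_sdlog))
    cond_fac <- if (conds[s] == "T3") 2^lfc else rep(1, G)
    lib <- stats::rlnorm(ncell, spec$lib_size_meanlog, spec$lib_size_sdlog)
    pct_mt <- pmax(stats::rnorm(ncell, 3, 1.2), 0.1)
    mt_scaled <- (pct_mt - 3) / 1.2
    base <- rel * samp_fac * cond_fac
    mu <- outer(base, lib) * exp(outer(mt_load, mt_scaled))
    cnt <- matrix(stats::rnbinom(G * ncell, mu = mu, size = size),
                  nrow = G)
    blocks[[s]] <- Matrix::Matrix(cnt, sparse = TRUE)
    meta[[s]] <- data.frame(
      cell_type = spec$cell_type, sample_id = samples[s],
      condition = conds[s], cre_status = "n/a", pct_mt = pct_mt,
      stringsAsFactors = FALSE)
  }
  counts <- do.call(cbind, blocks)
  rownames(counts) <- genes
  md <- do.call(rbind, meta)
  md$n_genes <- Matrix::colSums(counts > 0)
  truth <- data.frame(gene = genes, spiked = seq_len(G) %in% spiked,
                      log2fc = lfc, stringsAsFactors = FALSE)
  list(nuclei = nucleus_counts(counts, md), truth = truth)
}

#' Generate synthetic laser-power sweeps with true sigmoid parameters
#'
#' Hill curves per cell with log-normal per-cell jitter around condition
#' means and multiplicative Gaussian measurement noise. T3-like condition
#' effects scale the saturation amplitude and the half-maximum power.
#'
#' @param n_cells_per_cond Cells per condition (default 20).
#' @param powers Laser powers (mW); default 8 log-spaced values over
#'   0.03 to 4.
#' @param amp_mean,half_mean,slope_mean Control-condition geometric means
#'   (defaults 2.0 pC/pF, 0.5 mW, 1.8).
#' @param cell_sdlog Per-cell log-normal jitter of all three parameters
#'   (default 0.15).
#' @param amp_factor,half_factor Multiplicative T3 effects (defaults 1.5
#'   and 0.7).
#' @param noise_cv Multiplicative measurement noise CV (default 0.05).
#' @param cm_pf Membrane capacitance metadata (pF).
#' @param seed Integer seed.
#' @return List: `sweeps` (data frame in the power-sweep CSV dialect) and
#'   `truth` (per-cell true parameters).
#' @export
gen_psc_sweeps <- function(n_cells_per_cond = 20L,
                           powers = exp(seq(log(0.03), log(4), length.out = 8)),
                           amp_mean = 2.0, half_mean = 0.5, slope_mean = 1.8,
                           cell_sdlog = 0.15, amp_factor = 1.5,
                           half_factor = 0.7, noise_cv = 0.05, cm_pf = 120,
                           seed = 1L) {
  set.seed(seed)
  rows <- list(); tr <- list()
  for (cond in c("control", "T3")) {
    a_mu <- amp_mean * if (cond == "T3") amp_factor else 1
    h_mu <- half_mean * if (cond == "T3") half_factor else 1
    for (i in seq_len(n_cells_per_cond)) {
      id <- sprintf("%s_c%02d", cond, i)
      amp <- a_mu * stats::rlnorm(1, 0, cell_sdlog)
      half <- h_mu * stats::rlnorm(1, 0, cell_sdlog)
      slope <- slope_mean * stats::rlnorm(1, 0, cell_sdlog)
      y <- amp / (1 + (half / powers)^slope)
      if (noise_cv > 0) y <- y * (1 + stats::rnorm(length(y), 0, noise_cv))
      rows[[id]] <- data.frame(cell_id = id, condition = cond, cm_pf = cm_pf,
                               power_mw = powers, charge_pc_per_pf = y,
                               stringsAsFactors = FALSE)
      tr[[id]] <- data.frame(cell_id = id, condition = cond, amp = amp,
                             half_power = half, hill_slope = slope,
                             stringsAsFactors = FALSE)
    }
  }
  list(sweeps = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(tr, list(make.row.names = FALSE))))
}

#' Generate first-order Markov syllable streams with known transitions
#'
#' Builds a transition matrix over `n_syllables` states as a mixture of a
#' deterministic cycle and the uniform no-self-transition distribution
#' (`stochasticity` = 0 gives the pure cycle, 1 the uniform chain), with
#' geometric run lengths of mean `mean_run` frames, then emits frame-level
#' label streams.
#'
#' @param n_sessions Number of sessions (default 4).
#' @param n_frames Frames per session (default 20000).
#' @param n_syllables Number of syllables (default 20).
#' @param stochasticity Mixture weight in \[0, 1\] (default 0.5).
#' @param mean_run Mean run length in frames (default 12, roughly
#'   sub-second at 30 Hz).
#' @param seed Integer seed.
#' @return List: `streams` (named list of integer frame vectors) and
#'   `transition` (the true instance-level transition matrix, zero
#'   diagonal).
#' @export
gen_syllable_streams <- function(n_sessions = 4L, n_frames = 20000L,
                                 n_syllables = 20L, stochasticity = 0.5,
                                 mean_run = 12, seed = 1L) {
  stopifnot(stochasticity >= 0, stochasticity <= 1, n_syllables >= 2)
  set.seed(seed)
  K <- n_syllables
  cyc <- matrix(0, K, K)
  cyc[cbind(seq_len(K), c(seq_len(K)[-1], 1L))] <- 1
  unif <- matrix(1 / (K - 1), K, K); diag(unif) <- 0
  P <- (1 - stochasticity) * cyc + stochasticity * unif
  streams <- list()
  for (s in seq_len(n_sessions)) {
    frames <- integer(0)
    cur <- sample.int(K, 1L)
    while (length(frames) < n_frames) {
      run <- 1L + stats::rgeom(1L, 1 / mean_run)
      frames <- c(frames, rep(cur, run))
      cur <- sample.int(K, 1L, prob = P[cur, ])
    }
    streams[[sprintf("sess%02d", s)]] <- frames[seq_len(n_frames)]
  }
  list(streams = streams, transition = P)
}
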