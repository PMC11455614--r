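#' Baseline-subtracted integrated charge of an evoked current
#'
#' Integrates the current trace (trapezoidal rule) over a window after
#' stimulus onset, after subtracting the mean baseline current estimated
#' over `baseline` seconds preceding onset, and divides by the membrane
#' capacitance. With current in pA, time in seconds and `cm` in pF the
#' result is in pC/pF (pA.s = pC).
#'
#' @param time Sample times (s), strictly increasing.
#' @param current Current samples (pA), same length as `time`.
#' @param onset Stimulus onset time (s).
#' @param window Integration window (s), default 0.010 (10 ms).
#' @param cm Membrane capacitance (pF).
#' @param baseline Baseline-estimation span preceding onset (s),
#'   default 0.1.
#' @return Normalized charge (pC/pF).
#' @export
integrate_charge <- function(time, current, onset, window = 0.010, cm,
                             baseline = 0.1) {
  stopifnot(length(time) == length(current), cm > 0)
  if (onset + window > max(time)) {
    stop("integration window exceeds the trace", call. = FALSE)
  }
  base_sel <- time >= onset - baseline & time < onset
  base <- if (any(base_sel)) mean(current[base_sel]) else 0
  sel <- time >= onset & time <= onset + window
  if (sum(sel) < 2L) stop("too few samples in the window", call. = FALSE)
  tt <- time[sel]; yy <- current[sel] - base
  q <- sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
  q / cm
}

#' Fit a Hill sigmoid to a laser-power response profile
#'
#' Nonlinear least squares of
#' `charge(x) = amp / (1 + (half_power / x)^hill_slope)` over the sweep's
#' (power, charge) points, optimized in log-parameter space with a 3 x 3
#' multi-start grid over initial half-power and slope (best residual wins;
#' ties broken by the smaller slope). By construction the fitted curve
#' passes through `amp / 2` at `x = half_power`. The fit is
#' scale-equivariant: scaling all charges by k scales `amp` by k and leaves
#' the other coefficients unchanged.
#'
#' @param power Laser powers (mW), positive, at least 5 distinct values.
#' @param charge Normalized charges (pC/pF), same length.
#' @return List of class `sigmoid_fit`: `amp`, `half_power`, `hill_slope`,
#'   `rss`, `valid`, `message`.
#' @export
fit_sigmoid <- function(power, charge) {
  stopifnot(length(power) == length(charge))
  if (any(power <= 0)) stop("powers must be positive", call. = FALSE)
  if (length(unique(power)) < 5L) {
    stop("need at least 5 distinct powers", call. = FALSE)
  }
  lx <- log(power)
  rss_fun <- function(par) {
    amp <- exp(par[1]); lb <- par[2]; slope <- exp(par[3])
    pred <- amp / (1 + exp(-slope * (lx - lb)))  # Hill form in log space
    sum((charge - pred)^2)
  }
  amp0 <- max(abs(charge))
  if (amp0 <= 0) amp0 <- 1
  b_grid <- stats::quantile(lx, c(0.25, 0.5, 0.75))
  s_grid <- c(0.5, 1.5, 3)
  best <- NULL
  for (b0 in b_grid) {
    for (s0 in s_grid) {
      o <- try(stats::optim(c(log(amp0), b0, log(s0)), rss_fun,
                            method = "BFGS",
                            control = list(maxit = 2000, reltol = 1e-15)),
               silent = TRUE)
      if (inherits(o, "try-error")) next
      o2 <- stats::optim(o$par, rss_fun,
                         control = list(maxit = 5000, reltol = 1e-15))
      if (o2$value < o$value) o <- o2
      if (is.null(best) || o$value < best$value - 1e-12 ||
          (abs(o$value - best$value) <= 1e-12 &&
           exp(o$par[3]) < exp(best$par[3]))) {
        best <- o
      }
    }
  }
  if (is.null(best) || !all(is.finite(best$par))) {
    return(structure(list(amp = NA_real_, half_power = NA_real_,
                          hill_slope = NA_real_, rss = NA_real_,
                          valid = FALSE, message = "did not converge"),
                     class = "sigmoid_fit"))
  }
  structure(list(amp = exp(best$par[1]), half_power = exp(best$par[2]),
                 hill_slope = exp(best$par[3]), rss = best$value,
                 valid = TRUE, message = "ok"),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> amp=%.4g half_power=%.4g mW slope=%.4g rss=%.3g (%s)\n",
              x$amp, x$half_power, x$hill_slope, x$rss, x$message))
  invisible(x)
}

#' Evaluate a fitted Hill sigmoid
#'
#' @param fit A `sigmoid_fit`.
#' @param power Powers (mW) at which to evaluate.
#' @return Predicted charges.
#' @export
predict_sigmoid <- function(fit, power) {
  fit$amp / (1 + (fit$half_power / power)^fit$hill_slope)
}

#' Per-cell log2 fold-changes of sigmoid coefficients vs the control median
#'
#' For each coefficient (`amp`, `half_power`, `hill_slope`), reports
#' `log2(coef / median over control cells)` per cell. Cells with
#' nonpositive coefficients are excluded with a notice.
#'
#' @param fits Data frame with columns `cell_id`, `amp`, `half_power`,
#'   `hill_slope` (e.g. one row per cell in the treated group).
#' @param control_fits Same-format data frame for control cells (used for
#'   the medians).
#' @return Data frame `cell_id, amp_lfc, half_power_lfc, hill_slope_lfc`.
#' @export
param_fold_changes <- function(fits, control_fits) {
  cols <- c("amp", "half_power", "hill_slope")
  stopifnot(all(cols %in% names(fits)), all(cols %in% names(control_fits)),
            nrow(control_fits) >= 1L)
  med <- vapply(cols, function(cc) stats::median(control_fits[[cc]]), 0)
  if (any(med <= 0)) stop("control medians must be positive", call. = FALSE)
  bad <- rowSums(sapply(cols, function(cc) fits[[cc]] <= 0)) > 0
  if (any(bad)) {
    message(sum(bad), " cell(s) with nonpositive coefficients excluded")
    fits <- fits[!bad, , drop = FALSE]
  }
  out <- data.frame(cell_id = fits$cell_id, stringsAsFactors = FALSE)
  for (cc in cols) out[[paste0(cc, "_lfc")]] <- log2(fits[[cc]] / med[[cc]])
  out
}

#' Paired-pulse ratio with single-pulse subtraction
#'
#' The first-pulse charge is integrated from the paired trace at the first
#' stimulus; the second-pulse charge is integrated after subtracting the
#' averaged single-pulse trace from the paired trace (isolating the second
#' response from the decaying tail of the first). PPR = second / first.
#'
#' @param time Sample times (s), shared by both traces.
#' @param paired Current trace (pA) with two stimuli `inter_pulse` apart.
#' @param single Averaged current trace (pA) from the single-pulse stimulus.
#' @param onset First-stimulus onset (s).
#' @param inter_pulse Inter-pulse interval (s), default 0.05.
#' @param window Charge integration window (s), default 0.010.
#' @param cm Membrane capacitance (pF).
#' @param baseline Baseline span (s).
#' @return List: `ppr`, `q1`, `q2`, `valid` (FALSE when the first-pulse
#'   charge is numerically zero).
#' @export
paired_pulse_ratio <- function(time, paired, single, onset, inter_pulse = 0.05,
                window = 0.010, cm, baseline = 0.1) {
  q1 <- integrate_charge(time, paired, onset, window, cm, baseline)
  residual <- paired - single
  q2 <- integrate_charge(time, residual, onset + inter_pulse, window, cm,
                         baseline)
  if (abs(q1) < 1e-12) {
    return(list(ppr = NA_real_, q1 = q1, q2 = q2, valid = FALSE))
  }
  list(ppr = q2 / q1, q1 = q1, q2 = q2, valid = TRUE)
}

#' Whole-cell recording quality control
#'
#' Pass requires all configured criteria: membrane-resistance variation
#' between recordings below `rm_var_max` (%), holding current at -70 mV not
#' more negative than `ih_min` (pA), series-resistance variation below
#' `rs_var_max` (%), and peak saturating current above `peak_min` (pA).
#'
#' @param record List or data frame row with `rm_var_pct`, `holding_pa`,
#'   `rs_var_pct`, `peak_pa`.
#' @param rm_var_max,ih_min,rs_var_max,peak_min Thresholds (defaults 20,
#'   -400, 25, 250).
#' @return List: `pass` (logical) and `failed` (character vector naming the
#'   violated criteria, empty on pass).
#' @export
qc_pass <- function(record, rm_var_max = 20, ih_min = -400,
                    rs_var_max = 25, peak_min = 250) {
  failed <- character(0)
  if (!(record$rm_var_pct < rm_var_max)) {
    failed <- c(failed, sprintf("Rm variation %.3g%% >= %g%%",
                                record$rm_var_pct, rm_var_max))
  }
  if (!(record$holding_pa > ih_min)) {
    failed <- c(failed, sprintf("holding current %.4g pA <= %g pA",
                                record$holding_pa, ih_min))
  }
  if (!(record$rs_var_pct < rs_var_max)) {
    failed <- c(failed, sprintf("Rs variation %.3g%% >= %g%%",
                                record$rs_var_pct, rs_var_max))
  }
  if (!(record$peak_pa > peak_min)) {
    failed <- c(failed, sprintf("peak current %.4g pA <= %g pA",
                                record$peak_pa, peak_min))
  }
  list(pass = length(failed) == 0L, failed = failed)
}

#' Read / write power sweeps
#'
#' CSV dialect: `cell_id,condition,cm_pf,power_mw,charge_pc_per_pf`.
#'
#' @param sweeps Data frame in the dialect above.
#' @param path File path.
#' @return `read_power_sweeps()` returns the data frame.
#' @export
write_power_sweeps <- function(sweeps, path) {
  cols <- c("cell_id", "condition", "cm_pf", "power_mw", "charge_pc_per_pf")
  stopifnot(all(cols %in% names(sweeps)))
  utils::write.csv(sweeps[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_power_sweeps
#' @export
read_power_sweeps <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Fit every cell in a sweep table
#'
#' @param sweeps Power-sweep data frame (see [write_power_sweeps()]).
#' @return Data frame `cell_id, condition, amp, half_power, hill_slope,
#'   rss, valid`.
#' @export
fit_all_sweeps <- function(sweeps) {
  out <- lapply(split(sweeps, sweeps$cell_id), function(d) {
    f <- fit_sigmoid(d$power_mw, d$charge_pc_per_pf)
    data.frame(cell_id = d$cell_id[1], condition = d$condition[1],
               amp = f$amp, half_power = f$half_power,
               hill_slope = f$hill_slope, rss = f$rss, valid = f$valid,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
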