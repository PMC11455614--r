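#' Nucleus-level count container
#'
#' A light wrapper pairing a sparse gene x nucleus count matrix with
#' per-nucleus metadata. Metadata must contain `cell_type`, `sample_id`,
#' `condition` (`"T3"` or `"control"`), and may contain `cre_status`
#' (`"pos"`, `"neg"` or `"n/a"`), `pct_mt` and `n_genes`; missing `pct_mt`
#' and `n_genes` are derived from the matrix (`n_genes` = genes detected per
#' nucleus, `pct_mt` defaults to 0 when no MT genes are annotated).
#'
#' @param counts A `dgCMatrix` (or coercible matrix), genes in rows, with
#'   rownames (gene ids) and one column per nucleus.
#' @param meta Data frame with one row per column of `counts`.
#' @return An object of class `nucleus_counts`.
#' @export
nucleus_counts <- function(counts, meta) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (min(counts@x, 0) < 0) stop("counts must be nonnegative", call. = FALSE)
  stopifnot(nrow(meta) == ncol(counts))
  need <- c("cell_type", "sample_id", "condition")
  if (!all(need %in% names(meta))) {
    stop("metadata must contain ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(meta$condition %in% c("T3", "control"))) {
    stop("condition must be 'T3' or 'control'", call. = FALSE)
  }
  if (is.null(meta$cre_status)) meta$cre_status <- "n/a"
  if (is.null(meta$n_genes)) meta$n_genes <- Matrix::colSums(counts > 0)
  if (is.null(meta$pct_mt)) meta$pct_mt <- 0
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%05d", seq_len(nrow(counts)))
  }
  structure(list(counts = counts, meta = as.data.frame(meta)),
            class = "nucleus_counts")
}

#' @export
print.nucleus_counts <- function(x, ...) {
  cat(sprintf("<nucleus_counts> %d genes x %d nuclei; %d cell type(s), %d sample(s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$meta$cell_type)),
              length(unique(x$meta$sample_id))))
  invisible(x)
}

#' Read nucleus counts from MTX + TSV files
#'
#' Expects a MatrixMarket sparse matrix (genes x nuclei), a one-column gene
#' TSV (no header) and a per-nucleus metadata TSV (header, one row per
#' nucleus).
#'
#' @param mtx,genes_tsv,meta_tsv File paths.
#' @return A [nucleus_counts()] object.
#' @export
read_nucleus_counts <- function(mtx, genes_tsv, meta_tsv) {
  m <- Matrix::readMM(mtx)
  genes <- utils::read.table(genes_tsv, sep = "\t",
                             stringsAsFactors = FALSE)[[1]]
  meta <- utils::read.delim(meta_tsv, stringsAsFactors = FALSE)
  rownames(m) <- genes
  nucleus_counts(m, meta)
}

#' Write nucleus counts as MTX + TSV
#'
#' @param nuclei A [nucleus_counts()].
#' @param dir Output directory (created if needed); files
#'   `matrix.mtx`, `genes.tsv`, `meta.tsv`.
#' @return `dir`, invisibly.
#' @export
write_nucleus_counts <- function(nuclei, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(nuclei$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(rownames(nuclei$counts), file.path(dir, "genes.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(nuclei$meta, file.path(dir, "meta.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Build pseudocells for one cell type
#'
#' Within each (sample, condition\[, cre_status\]) stratum, nuclei are
#' randomly shuffled and partitioned into `floor(n / target_size)` groups
#' (at least one when `n >= min_nuclei`), each of at least `min_nuclei`
#' members, and raw UMI counts are summed per group. Strata with fewer than
#' `min_nuclei` nuclei are dropped; a cell type with fewer than `min_nuclei`
#' total nuclei or fewer than `min_pseudocells` constructed pseudocells is
#' excluded (an outcome, not an error). The `cre_status` field enters the
#' stratification only when the cell type contains both "pos" and "neg"
#' nuclei.
#'
#' Pseudocell `pct_mt` is the count-weighted mean of member-nucleus values;
#' `n_genes` is the number of genes detected in the aggregate.
#'
#' @param nuclei A [nucleus_counts()].
#' @param cell_type Cell type to aggregate.
#' @param target_size Average nuclei per pseudocell (default 30).
#' @param min_nuclei Minimum nuclei per pseudocell (default 15).
#' @param min_pseudocells Minimum pseudocells for the cell type to be kept
#'   (default 6).
#' @param seed Integer seed for the random partition.
#' @return An object of class `pseudocell_matrix`: `counts` (gene x
#'   pseudocell), `meta` (per pseudocell), `excluded` flag and `reason`, and
#'   `membership` (list of nucleus column indices per pseudocell).
#' @export
build_pseudocells <- function(nuclei, cell_type, target_size = 30L,
                              min_nuclei = 15L, min_pseudocells = 6L,
                              seed = 1L) {
  stopifnot(inherits(nuclei, "nucleus_counts"))
  sel <- which(nuclei$meta$cell_type == cell_type)
  excluded <- function(reason) {
    structure(list(counts = NULL, meta = NULL, membership = NULL,
                   cell_type = cell_type, excluded = TRUE, reason = reason),
              class = "pseudocell_matrix")
  }
  if (length(sel) < min_nuclei) {
    return(excluded(sprintf("only %d nuclei (< %d)", length(sel), min_nuclei)))
  }
  meta <- nuclei$meta[sel, , drop = FALSE]
  use_cre <- all(c("pos", "neg") %in% meta$cre_status)
  strat <- if (use_cre) {
    paste(meta$sample_id, meta$condition, meta$cre_status, sep = "\r")
  } else {
    paste(meta$sample_id, meta$condition, sep = "\r")
  }
  set.seed(seed)
  groups <- list()
  for (key in unique(strat)) {
    idx <- sel[strat == key]
    n <- length(idx)
    if (n < min_nuclei) next
    idx <- idx[sample.int(n)]
    k <- max(1L, n %/% as.integer(target_size))
    # chunk with remainder spread over the first groups
    sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    bounds <- cumsum(c(0L, sizes))
    for (g in seq_len(k)) {
      groups[[length(groups) + 1L]] <- idx[(bounds[g] + 1L):bounds[g + 1L]]
    }
  }
  if (length(groups) < min_pseudocells) {
    return(excluded(sprintf("only %d pseudocells (< %d)",
                            length(groups), min_pseudocells)))
  }
  cm <- nuclei$counts
  agg <- vapply(groups, function(g) {
    as.numeric(Matrix::rowSums(cm[, g, drop = FALSE]))
  }, numeric(nrow(cm)))
  rownames(agg) <- rownames(cm)
  colnames(agg) <- sprintf("pc%03d", seq_along(groups))
  pmeta <- do.call(rbind, lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    w <- Matrix::colSums(cm[, g, drop = FALSE])
    data.frame(
      pseudocell_id = sprintf("pc%03d", i),
      sample_id = nuclei$meta$sample_id[g[1]],
      condition = nuclei$meta$condition[g[1]],
      cre_status = nuclei$meta$cre_status[g[1]],
      n_member_nuclei = length(g),
      pct_mt = if (sum(w) > 0) sum(nuclei$meta$pct_mt[g] * w) / sum(w)
               else mean(nuclei$meta$pct_mt[g]),
      n_genes = sum(agg[, i] > 0),
      stringsAsFactors = FALSE)
  }))
  structure(list(counts = agg, meta = pmeta, membership = groups,
                 cell_type = cell_type, excluded = FALSE, reason = "ok"),
            class = "pseudocell_matrix")
}

#' @export
print.pseudocell_matrix <- function(x, ...) {
  if (x$excluded) {
    cat(sprintf("<pseudocell_matrix> '%s' EXCLUDED: %s\n",
                x$cell_type, x$reason))
  } else {
    cat(sprintf("<pseudocell_matrix> '%s': %d genes x %d pseudocells\n",
                x$cell_type, nrow(x$counts), ncol(x$counts)))
  }
  invisible(x)
}

#' Background gene set for one cell type
#'
#' Genes detected (nonzero counts) in strictly more than `min_fraction` of
#' the subtype's nuclei.
#'
#' @param nuclei A [nucleus_counts()].
#' @param cell_type Cell type defining the cell universe.
#' @param min_fraction Strict detection-fraction threshold (default 0.01).
#' @return Character vector of gene ids (possibly empty).
#' @export
background_genes <- function(nuclei, cell_type, min_fraction = 0.01) {
  sel <- nuclei$meta$cell_type == cell_type
  if (!any(sel)) return(character(0))
  m <- nuclei$counts[, sel, drop = FALSE]
  frac <- Matrix::rowSums(m > 0) / ncol(m)
  rownames(m)[frac > min_fraction]
}

#' Normalize counts to log2 counts-per-100k
#'
#' `log2(1e5 * count / column_total + 1)`. The CP100k scale follows the
#' convention of the differential-expression procedure; the pseudocount of
#' 1 is this package's documented choice.
#'
#' @param counts Gene x column matrix of nonnegative counts.
#' @return Dense numeric matrix, same dimensions.
#' @export
normalize_cp100k <- function(counts) {
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  tot[tot == 0] <- 1
  log2(sweep(counts, 2, tot, "/") * 1e5 + 1)
}

# Intra-block (within-sample) correlation of expression residuals,
# estimated per gene by a one-way ANOVA moment method, then stabilized by a
# lowess trend on mean expression (counting noise dilutes the ICC for
# low-expression genes, so the correlation rises with expression). Used when
# sample is nested in condition, where a fixed sample factor would alias the
# contrast. Returns the per-gene trended rho and the trimmed-mean consensus.
.rho_trend <- function(y, block, groups, mean_expr) {
  blocks <- unique(block)
  zero <- list(rho_gene = rep(0, nrow(y)), consensus = 0)
  if (length(blocks) == length(block)) return(zero)
  icc <- apply(y, 1, function(v) {
    # center within condition, then decompose across samples
    v <- v - stats::ave(v, groups)
    msb_num <- 0; msw_num <- 0; dfb <- 0; dfw <- 0; ksum <- 0
    for (b in blocks) {
      vb <- v[block == b]
      k <- length(vb)
      ksum <- ksum + k
      msb_num <- msb_num + k * mean(vb)^2
      msw_num <- msw_num + sum((vb - mean(vb))^2)
      dfw <- dfw + (k - 1)
    }
    dfb <- length(blocks) - length(unique(groups))
    if (dfb < 1 || dfw < 1) return(NA_real_)
    msb <- msb_num / dfb; msw <- msw_num / dfw
    k0 <- ksum / length(blocks)
    sb2 <- (msb - msw) / k0
    if (!is.finite(sb2)) return(NA_real_)
    sb2 / (sb2 + msw + 1e-12)
  })
  ok <- is.finite(icc)
  if (!any(ok)) return(zero)
  z <- atanh(pmin(pmax(icc, -0.3), 0.99))
  consensus <- min(max(tanh(mean(z[ok], trim = 0.15)), 0), 0.99)
  lo <- stats::lowess(mean_expr[ok], z[ok], f = 0.3)
  rho_gene <- tanh(stats::approx(lo$x, lo$y, xout = mean_expr, rule = 2,
                                 ties = mean)$y)
  rho_gene[!is.finite(rho_gene)] <- consensus
  list(rho_gene = pmin(pmax(rho_gene, 0), 0.95), consensus = consensus)
}

# Whitening transform for the equicorrelated random-sample model
# V = (1 - rho) I + rho J within each block: returns M such that rows of
# M %*% cbind(y, X) are decorrelated.
.block_whitener <- function(block, rho) {
  n <- length(block)
  M <- diag(n) / sqrt(1 - rho)
  for (b in unique(block)) {
    idx <- which(block == b)
    k <- length(idx)
    adj <- (1 / sqrt(1 - rho + k * rho) - 1 / sqrt(1 - rho)) / k
    M[idx, idx] <- M[idx, idx] + adj
  }
  M
}

# Solve trigamma(x) = y for x > 0 (y > 0), used by the moments estimator of
# the prior degrees of freedom.
.trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  # Newton iterations on 1/trigamma, as in standard eB variance shrinkage
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

#' Moderated-t differential expression on pseudocells
#'
#' Fits, per gene, a linear model of log2 CP100k expression on condition
#' (T3 vs control) plus pseudocell-level covariates (`pct_mt` and
#' `log2(n_genes)` by default). Per-gene residual variances are shrunk
#' toward a mean-expression-dependent trend by an empirical-Bayes rule:
#' `s2_post = (d0 * s0^2(g) + d * s2_g) / (d0 + d)` with the trend `s0^2(g)`
#' from a lowess fit of log variance on mean expression and `d0` estimated
#' by moments from the spread of log variances (solving
#' `trigamma(d0/2) = var(log s2 - log s0^2) - trigamma(d/2)`). The moderated
#' t is the condition coefficient over its posterior standard error, with
#' `d0 + d` degrees of freedom; p-values are Benjamini-Hochberg adjusted
#' within the supplied background set.
#'
#' Pseudocells from one sample share that sample's biological state, so
#' sample id enters the model "where applicable": as a fixed blocking factor
#' when every sample contains pseudocells of both conditions, or — in the
#' usual nested design where each sample sits in one condition and a fixed
#' factor would alias the contrast — as an equicorrelated random effect, via
#' a consensus intra-sample correlation estimated across genes and
#' generalized least squares (the duplicate-correlation device). How sample
#' id was handled is reported in the `blocking` attribute.
#'
#' @param pseudocells A non-excluded [build_pseudocells()] result.
#' @param background Optional character vector restricting genes (e.g. from
#'   [background_genes()]).
#' @param covariates Character vector among `"pct_mt"`, `"log2_n_genes"`.
#' @param d0 `NULL` to estimate the prior degrees of freedom (default);
#'   `0` disables shrinkage, giving ordinary per-gene t-tests.
#' @param groups Optional factor overriding the contrast grouping
#'   (level 2 vs level 1); by default `condition` with control as baseline.
#' @param block_method `"auto"` (fixed factor when estimable, else random
#'   effect, else none), `"fixed"`, `"random"` or `"none"`.
#' @return A `de_table` data frame: `gene, mean_expr, log2fc, t_mod, p,
#'   fdr`, with attributes `d0`, `df_residual`, `blocking`, `rho`,
#'   `dropped`.
#' @export
moderated_t_de <- function(pseudocells, background = NULL,
                           covariates = c("pct_mt", "log2_n_genes"),
                           d0 = NULL, groups = NULL,
                           block_method = c("auto", "fixed", "random",
                                            "none")) {
  block_method <- match.arg(block_method)
  stopifnot(inherits(pseudocells, "pseudocell_matrix"))
  if (pseudocells$excluded) {
    stop("cell type was excluded: ", pseudocells$reason, call. = FALSE)
  }
  meta <- pseudocells$meta
  if (is.null(groups)) {
    groups <- factor(meta$condition, levels = c("control", "T3"))
  } else {
    groups <- as.factor(groups)
    stopifnot(nlevels(groups) == 2L, length(groups) == nrow(meta))
  }
  if (min(table(groups)) < 2L) {
    stop("need at least 2 pseudocells per condition", call. = FALSE)
  }
  y <- normalize_cp100k(pseudocells$counts)
  if (!is.null(background)) {
    y <- y[rownames(y) %in% background, , drop = FALSE]
  }
  nonzero <- rowSums(pseudocells$counts[rownames(y), , drop = FALSE]) > 0
  dropped <- rownames(y)[!nonzero]
  if (length(dropped) > 0) {
    message(length(dropped), " all-zero gene row(s) dropped")
    y <- y[nonzero, , drop = FALSE]
  }
  if (nrow(y) == 0L) stop("no genes to test", call. = FALSE)

  X <- cbind(intercept = 1, cond = as.numeric(groups) - 1)
  cov_map <- list(pct_mt = meta$pct_mt, log2_n_genes = log2(meta$n_genes))
  for (cv in covariates) {
    v <- cov_map[[cv]]
    if (is.null(v)) stop("unknown covariate: ", cv, call. = FALSE)
    if (stats::sd(v) < 1e-12) {
      message("covariate '", cv, "' is constant; dropped")
      next
    }
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  sample_by_cond <- table(meta$sample_id, groups)
  fixed_ok <- nrow(sample_by_cond) > 1L && all(sample_by_cond > 0)
  blocking <- "none"
  if (block_method %in% c("auto", "fixed") && fixed_ok) {
    S <- stats::model.matrix(~ factor(meta$sample_id))[, -1, drop = FALSE]
    colnames(S) <- paste0("sample", seq_len(ncol(S)))
    X <- cbind(X, S)
    blocking <- "fixed"
  } else if (block_method == "fixed") {
    stop("fixed sample blocking would alias the condition contrast",
         call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X); d <- n - p
  if (d < 1L) stop("no residual degrees of freedom", call. = FALSE)

  mean_expr <- rowMeans(y)
  rho <- 0
  rho_gene <- rep(0, nrow(y))
  if (blocking == "none" && block_method %in% c("auto", "random") &&
      nrow(sample_by_cond) > length(unique(groups))) {
    rt <- .rho_trend(y, meta$sample_id, groups, mean_expr)
    rho <- rt$consensus
    rho_gene <- rt$rho_gene
    if (any(rho_gene > 0)) blocking <- "random"
  }

  # fit gene-wise least squares, whitening per trended-rho bin when the
  # sample random effect is active
  lfc <- s2 <- v_cond <- rep(NA_real_, nrow(y))
  rho_bin <- round(rho_gene / 0.02) * 0.02
  for (rb in unique(rho_bin)) {
    sel <- rho_bin == rb
    if (rb > 0) {
      W <- .block_whitener(meta$sample_id, rb)
      Xw <- W %*% X
      Yw <- y[sel, , drop = FALSE] %*% t(W)
    } else {
      Xw <- X
      Yw <- y[sel, , drop = FALSE]
    }
    qrW <- qr(Xw)
    cf <- t(qr.coef(qrW, t(Yw)))
    res <- Yw - cf %*% t(Xw)
    lfc[sel] <- cf[, 2]
    s2[sel] <- rowSums(res^2) / d
    v_cond[sel] <- solve(crossprod(Xw))[2, 2]
  }
  s2_floor <- pmax(s2, 1e-12)
  if (is.null(d0)) {
    lo <- stats::lowess(mean_expr, log(s2_floor), f = 0.5)
    s0 <- exp(stats::approx(lo$x, lo$y, xout = mean_expr, rule = 2,
                            ties = mean)$y)
    z <- log(s2_floor) - log(s0)
    spread <- stats::var(z) - trigamma(d / 2)
    d0_hat <- if (spread <= 0) Inf else 2 * .trigamma_inverse(spread)
  } else if (d0 == 0) {
    s0 <- s2_floor
    d0_hat <- 0
  } else {
    lo <- stats::lowess(mean_expr, log(s2_floor), f = 0.5)
    s0 <- exp(stats::approx(lo$x, lo$y, xout = mean_expr, rule = 2,
                            ties = mean)$y)
    d0_hat <- d0
  }
  s2_post <- if (is.infinite(d0_hat)) s0 else
    (d0_hat * s0 + d * s2) / (d0_hat + d)
  df_total <- d0_hat + d
  t_mod <- lfc / sqrt(s2_post * v_cond)
  pval <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- data.frame(gene = rownames(y), mean_expr = mean_expr,
                    log2fc = lfc, t_mod = t_mod, p = pval,
                    fdr = stats::p.adjust(pval, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- d0_hat
  attr(out, "df_residual") <- d
  attr(out, "blocking") <- blocking
  attr(out, "rho") <- rho
  attr(out, "dropped") <- dropped
  class(out) <- c("de_table", "data.frame")
  out
}

#' Robustness scores over cross-condition sample pairs
#'
#' For each gene, over all (T3 sample, control sample) pairs of per-sample
#' summaries, the score is `(n_up - n_down) / n_pairs`, where "up" means the
#' T3 member strictly exceeds the control member; ties contribute zero.
#' Swapping condition labels negates the score exactly. With 4 vs 4 samples
#' an absolute score of 0.5 corresponds to concordance in 12 of 16 pairs
#' (75%).
#'
#' @param summary_mat Gene x sample matrix of per-sample summaries (mean
#'   normalized expression for `robScore_logFC`; percent nonzero for
#'   `robScore_pct`).
#' @param condition Character/factor vector over columns, values `"T3"` or
#'   `"control"`.
#' @return Named numeric vector of per-gene scores in \[-1, 1\].
#' @export
rob_scores <- function(summary_mat, condition) {
  summary_mat <- as.matrix(summary_mat)
  stopifnot(ncol(summary_mat) == length(condition))
  t3 <- which(condition == "T3"); ct <- which(condition == "control")
  if (length(t3) == 0L || length(ct) == 0L) {
    stop("both conditions need at least one sample", call. = FALSE)
  }
  n_pairs <- length(t3) * length(ct)
  score <- numeric(nrow(summary_mat))
  for (i in t3) {
    for (j in ct) {
      dlt <- summary_mat[, i] - summary_mat[, j]
      score <- score + sign(dlt)
    }
  }
  stats::setNames(score / n_pairs, rownames(summary_mat))
}

#' Per-sample summaries feeding the robustness scores
#'
#' Computes, per gene and sample: the mean log2 CP100k expression across the
#' sample's pseudocells, and the percent of the sample's nuclei with nonzero
#' counts (from `nuclei` when supplied, else the mean nonzero fraction over
#' member nuclei is unavailable and pseudocell-level detection is used).
#'
#' @param pseudocells A [build_pseudocells()] result.
#' @param nuclei Optional originating [nucleus_counts()] for nucleus-level
#'   percent-nonzero summaries.
#' @return List with `mean_expr` and `pct_nonzero` gene x sample matrices
#'   plus `condition` per sample.
#' @export
sample_summaries <- function(pseudocells, nuclei = NULL) {
  meta <- pseudocells$meta
  samples <- unique(meta$sample_id)
  y <- normalize_cp100k(pseudocells$counts)
  mean_expr <- vapply(samples, function(s) {
    rowMeans(y[, meta$sample_id == s, drop = FALSE])
  }, numeric(nrow(y)))
  if (!is.null(nuclei)) {
    pct <- vapply(samples, function(s) {
      cols <- unlist(pseudocells$membership[meta$sample_id == s])
      as.numeric(Matrix::rowSums(nuclei$counts[rownames(y), cols,
                                               drop = FALSE] > 0)) /
        length(cols)
    }, numeric(nrow(y)))
  } else {
    pct <- vapply(samples, function(s) {
      rowMeans(pseudocells$counts[, meta$sample_id == s, drop = FALSE] > 0)
    }, numeric(nrow(y)))
  }
  rownames(pct) <- rownames(y)
  condition <- vapply(samples, function(s) {
    meta$condition[match(s, meta$sample_id)]
  }, "")
  list(mean_expr = mean_expr, pct_nonzero = 100 * pct, condition = condition)
}

#' Call thyroid-responsive genes (TRGs)
#'
#' Flags as TRG every gene with FDR-adjusted p < `fdr_cut` and
#' `|robScore_logFC| >= rob_cut` (i.e. concordant direction in at least 75%
#' of cross-condition sample pairs at the default 0.5 cutoff). Also returns
#' the non-TRG reference set: among the `n_top` most-expressed genes, those
#' with FDR > `fdr_cut`, `robScore_logFC == 0` and `robScore_pct == 0`.
#'
#' @param de A `de_table` from [moderated_t_de()].
#' @param robscore_logfc,robscore_pct Named per-gene scores from
#'   [rob_scores()].
#' @param fdr_cut,rob_cut TRG thresholds (defaults 0.05 and 0.5).
#' @param n_top Expression rank cutoff for the non-TRG universe
#'   (default 10000).
#' @return The `de_table` with columns `robscore_logfc`, `robscore_pct`,
#'   `is_trg` added, and attribute `non_trgs` (character vector).
#' @export
call_trgs <- function(de, robscore_logfc, robscore_pct,
                      fdr_cut = 0.05, rob_cut = 0.5, n_top = 10000L) {
  de$robscore_logfc <- unname(robscore_logfc[de$gene])
  de$robscore_pct <- unname(robscore_pct[de$gene])
  de$is_trg <- de$fdr < fdr_cut & abs(de$robscore_logfc) >= rob_cut
  top <- de$gene[order(-de$mean_expr)][seq_len(min(n_top, nrow(de)))]
  sel <- de$gene %in% top & de$fdr > fdr_cut &
    de$robscore_logfc == 0 & de$robscore_pct == 0
  attr(de, "non_trgs") <- de$gene[sel]
  de
}

#' Write a DE table as TSV
#'
#' Stable column order:
#' `gene, log2fc, t_mod, p, fdr, robscore_logfc, robscore_pct, is_trg`.
#'
#' @param de A `de_table` (after [call_trgs()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  cols <- c("gene", "log2fc", "t_mod", "p", "fdr",
            "robscore_logfc", "robscore_pct", "is_trg")
  cols <- cols[cols %in% names(de)]
  utils::write.table(de[, cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Cross-cell-type TRG correlation and clustering
#'
#' Pairwise Spearman correlations of per-cell-type log2 fold-changes over
#' the union of TRGs (average ranks for ties, pairwise-complete
#' observations), followed by hierarchical clustering of the correlation
#' matrix rows on Euclidean distances with Ward's criterion ("ward.D2").
#' Cell types with no finite values over the TRG union are excluded with a
#' notice.
#'
#' @param lfc_mat Gene (TRG union) x cell-type matrix of log2 fold-changes;
#'   `NA` where a gene was not testable in a cell type.
#' @return List: `cor` (correlation matrix), `hclust`, `order` (cell types
#'   in dendrogram order).
#' @export
trg_correlation <- function(lfc_mat) {
  lfc_mat <- as.matrix(lfc_mat)
  cover <- colSums(is.finite(lfc_mat)) > 0
  if (any(!cover)) {
    message("excluding cell type(s) with no TRG-union coverage: ",
            paste(colnames(lfc_mat)[!cover], collapse = ", "))
    lfc_mat <- lfc_mat[, cover, drop = FALSE]
  }
  if (ncol(lfc_mat) < 2L) {
    stop("need at least 2 cell types with TRGs", call. = FALSE)
  }
  cm <- stats::cor(lfc_mat, method = "spearman",
                   use = "pairwise.complete.obs")
  hc <- stats::hclust(stats::dist(cm), method = "ward.D2")
  list(cor = cm, hclust = hc, order = colnames(cm)[hc$order])
}

#' Regression of manipulation-induced expression change on the TRG program
#'
#' Ordinary least squares of the change in log2 fold-change caused by a
#' receptor manipulation (e.g. Cre+ DN-THR vs Cre- cells under T3) on the
#' original TRG log2 fold-change. A slope near -1 with high R-squared is the
#' signature of full program reversal by a dominant-negative receptor. The
#' disrupted set comprises genes with contrast FDR < `fdr_cut` and absolute
#' fractional expression change of at least `frac_cut` (25%:
#' `|2^delta - 1| >= 0.25`).
#'
#' @param original_lfc Named numeric: TRG log2FC in the unmanipulated
#'   contrast.
#' @param delta_lfc Named numeric: log2FC of the manipulated vs
#'   unmanipulated contrast, same genes.
#' @param contrast_fdr Named numeric: FDR of the manipulated-vs-unmanipulated
#'   contrast (optional; without it the disrupted set is empty).
#' @param fdr_cut,frac_cut Disruption thresholds (0.05, 0.25).
#' @return List of class `disruption_result`: `slope`, `intercept`,
#'   `r_squared`, `disrupted` (character vector), `n_genes`.
#' @export
disruption_regression <- function(original_lfc, delta_lfc,
                                  contrast_fdr = NULL,
                                  fdr_cut = 0.05, frac_cut = 0.25) {
  genes <- intersect(names(original_lfc), names(delta_lfc))
  if (length(genes) < 3L) stop("need at least 3 aligned genes", call. = FALSE)
  x <- original_lfc[genes]; yv <- delta_lfc[genes]
  fit <- stats::lm(yv ~ x)
  tss <- sum((yv - mean(yv))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  disrupted <- character(0)
  if (!is.null(contrast_fdr)) {
    fdr <- contrast_fdr[genes]
    frac <- abs(2^yv - 1)
    disrupted <- genes[!is.na(fdr) & fdr < fdr_cut & frac >= frac_cut]
  }
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, disrupted = disrupted,
                 n_genes = length(genes)),
            class = "disruption_result")
}

#' Full per-cell-type DE pipeline
#'
#' Convenience wrapper: background filter, pseudocell construction,
#' moderated-t DE, robustness scores (mean expression and nucleus-level
#' percent nonzero), TRG calling.
#'
#' @inheritParams build_pseudocells
#' @inheritParams moderated_t_de
#' @param min_fraction Background detection threshold.
#' @return A `de_table` with TRG flags, or `NULL` (with a message) when the
#'   cell type is excluded.
#' @export
pseudocell_de_pipeline <- function(nuclei, cell_type, target_size = 30L,
                                   min_nuclei = 15L, min_pseudocells = 6L,
                                   min_fraction = 0.01,
                                   covariates = c("pct_mt", "log2_n_genes"),
                                   d0 = NULL, seed = 1L) {
  pc <- build_pseudocells(nuclei, cell_type, target_size, min_nuclei,
                          min_pseudocells, seed)
  if (pc$excluded) {
    message("cell type '", cell_type, "' excluded: ", pc$reason)
    return(NULL)
  }
  bg <- background_genes(nuclei, cell_type, min_fraction)
  de <- moderated_t_de(pc, background = bg, covariates = covariates, d0 = d0)
  ss <- sample_summaries(pc, nuclei)
  rs_lfc <- rob_scores(ss$mean_expr[de$gene, , drop = FALSE], ss$condition)
  rs_pct <- rob_scores(ss$pct_nonzero[de$gene, , drop = FALSE], ss$condition)
  call_trgs(de, rs_lfc, rs_pct)
}
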