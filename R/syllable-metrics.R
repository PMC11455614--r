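#' Syllable usage distributions with a global 1% filter
#'
#' Collapses each frame-level label stream to syllable instances (maximal
#' runs of identical labels), computes the pooled instance distribution
#' across all sessions, retains only syllables making up strictly more than
#' `min_fraction` of pooled occurrences, and returns per-session usage
#' fractions over the retained set, renormalized.
#'
#' @param streams List of integer vectors (frame-level syllable labels, one
#'   per session), or a data frame with columns `session_id`, `frame_idx`,
#'   `syllable`.
#' @param min_fraction Strict pooled-usage threshold (default 0.01).
#' @return List: `retained` (sorted syllable ids), `usage` (named list of
#'   per-session usage vectors over retained syllables), `pooled`
#'   (pre-filter pooled fractions), `instances` (per-session run-length
#'   encoded instance label vectors).
#' @export
usage_stats <- function(streams, min_fraction = 0.01) {
  if (is.data.frame(streams)) {
    streams <- lapply(split(streams, streams$session_id), function(d) {
      d$syllable[order(d$frame_idx)]
    })
  }
  if (length(streams) == 0L) stop("no streams supplied", call. = FALSE)
  inst <- lapply(streams, function(s) {
    if (length(s) == 0L) stop("empty stream", call. = FALSE)
    rle(as.integer(s))$values
  })
  pooled_counts <- table(unlist(inst, use.names = FALSE))
  pooled <- pooled_counts / sum(pooled_counts)
  retained <- sort(as.integer(names(pooled)[pooled > min_fraction]))
  usage <- lapply(inst, function(v) {
    v <- v[v %in% retained]
    cnt <- table(factor(v, levels = retained))
    tot <- sum(cnt)
    if (tot == 0L) return(stats::setNames(rep(NA_real_, length(retained)),
                                          retained))
    stats::setNames(as.numeric(cnt) / tot, retained)
  })
  list(retained = retained, usage = usage,
       pooled = stats::setNames(as.numeric(pooled), names(pooled)),
       instances = inst)
}

#' Shannon entropy of a usage distribution
#'
#' `H = -sum(p * log2(p))` in bits, with `0 * log 0 = 0`. A uniform
#' distribution over 4 syllables gives 2 bits; a single syllable gives 0.
#'
#' @param usage Numeric vector of usage fractions (should sum to 1).
#' @return Entropy in bits.
#' @export
usage_entropy <- function(usage) {
  p <- usage[is.finite(usage) & usage > 0]
  -sum(p * log2(p))
}

#' Outgoing-transition entropies per syllable
#'
#' For each retained syllable, the Shannon entropy (bits) of the empirical
#' distribution over the *next* instance's syllable. Transitions are counted
#' only between originally consecutive instances that are both retained, so
#' the run-length construction guarantees no self-transitions. The session
#' value is the unweighted mean over syllables with at least one outgoing
#' transition.
#'
#' @param stream Integer vector of frame-level labels (one session), or a
#'   precomputed instance vector with `instances = TRUE`.
#' @param retained Integer vector of retained syllable ids (from
#'   [usage_stats()]); `NULL` keeps every syllable.
#' @param instances Set `TRUE` when `stream` is already instance-level.
#' @return List: `per_syllable` (named entropies, bits) and `session_mean`.
#' @export
outgoing_entropy <- function(stream, retained = NULL, instances = FALSE) {
  inst <- if (instances) as.integer(stream) else rle(as.integer(stream))$values
  if (length(inst) < 2L) stop("need at least 2 instances", call. = FALSE)
  from <- inst[-length(inst)]
  to <- inst[-1L]
  if (!is.null(retained)) {
    keep <- from %in% retained & to %in% retained
    from <- from[keep]; to <- to[keep]
  }
  sylls <- sort(unique(from))
  ent <- vapply(sylls, function(s) {
    p <- table(to[from == s])
    usage_entropy(as.numeric(p) / sum(p))
  }, 0)
  names(ent) <- sylls
  list(per_syllable = ent,
       session_mean = if (length(ent) > 0) mean(ent) else NA_real_)
}

#' Read / write frame-level syllable streams
#'
#' CSV dialect: `session_id,frame_idx,syllable`.
#'
#' @param streams Named list of integer label vectors.
#' @param path File path.
#' @return `read_syllable_streams()` returns a named list of integer
#'   vectors.
#' @export
write_syllable_streams <- function(streams, path) {
  df <- do.call(rbind, lapply(names(streams), function(id) {
    data.frame(session_id = id,
               frame_idx = seq_along(streams[[id]]) - 1L,
               syllable = as.integer(streams[[id]]))
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_syllable_streams
#' @export
read_syllable_streams <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$session_id), function(d) {
    as.integer(d$syllable[order(d$frame_idx)])
  })
}

#' Session-level entropy table
#'
#' Applies the 1% pooled filter, then computes per-session usage entropy and
#' mean outgoing entropy.
#'
#' @param streams As in [usage_stats()].
#' @param min_fraction Pooled retention threshold.
#' @return Tidy data frame `session_id, usage_entropy, outgoing_entropy`.
#' @export
syllable_entropy_table <- function(streams, min_fraction = 0.01) {
  us <- usage_stats(streams, min_fraction)
  ids <- names(us$usage)
  if (is.null(ids)) ids <- as.character(seq_along(us$usage))
  data.frame(
    session_id = ids,
    usage_entropy = vapply(us$usage, usage_entropy, 0),
    outgoing_entropy = vapply(us$instances, function(v) {
      outgoing_entropy(v, retained = us$retained,
                       instances = TRUE)$session_mean
    }, 0),
    row.names = NULL, stringsAsFactors = FALSE)
}
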