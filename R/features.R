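#' Betti-1 curve of a persistence diagram
#'
#' The number of independent 1-cycles alive at each filtration value:
#' `B1(t) = #\{intervals of dimension 1 with birth <= t < death\}`. Returned
#' as a right-continuous step function given by its breakpoints.
#'
#' @param diagram A `persistence_diagram` (or data frame with columns
#'   `dimension`, `birth`, `death`).
#' @return A `betti_curve`: data frame with columns `t` (breakpoints) and
#'   `count` (value on `[t_i, t_{i+1})`), with attribute `max` = peak count.
#'   An empty dimension-1 diagram gives the identically-zero curve.
#' @examples
#' dg <- data.frame(dimension = 1, birth = c(1, 2), death = c(3, 4))
#' attr(betti1_curve(dg), "max") # 2: the intervals overlap on [2, 3)
#' @export
betti1_curve <- function(diagram) {
  d1 <- as.data.frame(diagram)
  d1 <- d1[d1$dimension == 1, , drop = FALSE]
  if (nrow(d1) == 0) {
    out <- data.frame(t = 0, count = 0L)
    attr(out, "max") <- 0L
    class(out) <- c("betti_curve", "data.frame")
    return(out)
  }
  steps <- rbind(data.frame(t = d1$birth, delta = 1L),
                 data.frame(t = d1$death[is.finite(d1$death)], delta = -1L))
  t <- sort(unique(steps$t))
  agg <- rowsum(steps$delta, match(steps$t, t))  # exact-value grouping
  count <- cumsum(as.integer(agg))
  out <- data.frame(t = t, count = count)
  attr(out, "max") <- max(count)
  class(out) <- c("betti_curve", "data.frame")
  out
}

#' Evaluate a Betti curve at filtration values
#'
#' @param curve A `betti_curve`.
#' @param t Numeric vector of filtration values.
#' @return Integer counts of alive 1-cycles at each `t`.
#' @export
betti_at <- function(curve, t) {
  idx <- findInterval(t, curve$t)
  ifelse(idx == 0, 0L, curve$count[pmax(idx, 1)])
}

#' The six scalar topological features of a diagram
#'
#' From the dimension-1 intervals with lifetimes
#' \eqn{\ell_i = death_i - birth_i} and \eqn{L = \sum \ell_i}:
#' \describe{
#'   \item{total_cycles}{number of dimension-1 intervals.}
#'   \item{max_cycles}{peak of the Betti-1 curve (most cycles alive at once).}
#'   \item{max_persistence}{\eqn{\max \ell_i}.}
#'   \item{npe}{normalized persistence entropy
#'     \eqn{-\sum (\ell_i/L) \log(\ell_i/L) / \log(total\_cycles)}; defined
#'     as 0 when there are at most one cycle.}
#'   \item{max_persistence_ratio, median_persistence_ratio}{maximum and
#'     median of the per-cycle dimensionless ratios
#'     \eqn{r_i = death_i / birth_i}.}
#' }
#' With no cycles, all six features are 0. The count, entropy and ratio
#' features are invariant to a global rescaling of the point cloud;
#' `max_persistence` scales linearly with it.
#'
#' @param diagram A `persistence_diagram`.
#' @return Named numeric vector of the six features.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
#' compute_features(rips_diagram(sq))
#' @export
compute_features <- function(diagram) {
  d1 <- as.data.frame(diagram)
  d1 <- d1[d1$dimension == 1 & is.finite(d1$death), , drop = FALSE]
  k <- nrow(d1)
  if (k == 0)
    return(c(total_cycles = 0, max_cycles = 0, max_persistence = 0,
             npe = 0, max_persistence_ratio = 0, median_persistence_ratio = 0))
  life <- d1$death - d1$birth
  npe <- if (k <= 1) 0 else {
    p <- life / sum(life)
    -sum(p * log(p)) / log(k)
  }
  ratio <- d1$death / d1$birth
  c(total_cycles = k,
    max_cycles = attr(betti1_curve(d1), "max"),
    max_persistence = max(life),
    npe = npe,
    max_persistence_ratio = max(ratio),
    median_persistence_ratio = median(ratio))
}

#' Names of the six topological feature columns
#' @return Character vector.
#' @export
tda_feature_names <- function() {
  c("total_cycles", "max_cycles", "max_persistence", "npe",
    "max_persistence_ratio", "median_persistence_ratio")
}

#' Extract the per-epoch topological feature table
#'
#' For every epoch: embed the multichannel segment as a point cloud in
#' channel space, compute its Vietoris-Rips persistence diagram, and reduce
#' it to the six scalar features. Subject metadata is carried along so the
#' result rows are ready for group statistics and machine learning.
#'
#' @param epoch_set An `epoch_set` (see [segment_epochs()]).
#' @param meta Optional named list or one-row data frame with `group` and
#'   `moca` for the subject.
#' @param zscore Per-channel z-scoring of the point cloud (default off; the
#'   raw microvolt geometry defines the filtration).
#' @return Data frame: `subject_id`, `group`, `moca`, `condition`,
#'   `session`, plus the six feature columns, one row per epoch.
#' @export
extract_features <- function(epoch_set, meta = NULL, zscore = FALSE) {
  stopifnot(inherits(epoch_set, "epoch_set"))
  n <- length(epoch_set$epochs)
  feats <- matrix(0, nrow = n, ncol = 6,
                  dimnames = list(NULL, tda_feature_names()))
  for (i in seq_len(n)) {
    epc <- build_point_cloud(epoch_set$epochs[[i]], zscore = zscore)
    feats[i, ] <- compute_features(rips_diagram(epc))
  }
  data.frame(subject_id = rep(epoch_set$subject_id, n),
             group = rep(if (is.null(meta$group)) NA_character_ else
               meta$group, n),
             moca = rep(if (is.null(meta$moca)) NA_integer_ else
               as.integer(meta$moca), n),
             condition = as.character(epoch_set$condition),
             session = epoch_set$session,
             feats,
             stringsAsFactors = FALSE)
}

#' Feature table for a whole study
#'
#' Runs the preprocessing chain ([preprocess_recording()]) and
#' [extract_features()] over every subject of a synthetic study.
#'
#' @param study An `eeg_study` from [generate_study()].
#' @param low_hz,high_hz,epoch_length_s,threshold_uv,emd,zscore Passed to
#'   the preprocessing and feature stages.
#' @return The study-wide feature table (one row per epoch).
#' @export
study_features <- function(study, low_hz = 1, high_hz = 40,
                           epoch_length_s = 2, threshold_uv = 100,
                           emd = TRUE, zscore = FALSE) {
  stopifnot(inherits(study, "eeg_study"))
  rows <- vector("list", nrow(study$participants))
  for (i in seq_len(nrow(study$participants))) {
    meta <- study$participants[i, ]
    es <- preprocess_recording(study$recordings[[meta$subject_id]],
                               low_hz = low_hz, high_hz = high_hz,
                               epoch_length_s = epoch_length_s,
                               threshold_uv = threshold_uv, emd = emd,
                               cue_as = study$config$cue_as_target)
    rows[[i]] <- extract_features(es, meta = meta, zscore = zscore)
  }
  do.call(rbind, rows)
}
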