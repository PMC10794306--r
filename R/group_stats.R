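#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided Mann-Whitney test of `x` versus `y` with midrank tie handling;
#' the p-value uses the normal approximation with tie and continuity
#' correction. The returned `U` counts x-over-y wins plus half-ties, so
#' `0 <= U <= length(x) * length(y)`.
#'
#' @param x,y Nonempty numeric samples.
#' @return List with elements `U` and `p`.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("samples must be nonempty")
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Common-language effect size
#'
#' `P(X > Y) + 0.5 * P(X = Y)` over all pairs. Computed by exhaustive pair
#' counting for moderate samples and by the algebraically identical midrank
#' formula for large ones.
#'
#' @param x,y Nonempty numeric samples.
#' @return Number in `[0, 1]`; equals the Mann-Whitney U divided by
#'   `length(x) * length(y)` and the ROC AUC of `x` as the positive class.
#' @export
cles <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) stop("samples must be nonempty")
  if (as.numeric(nx) * ny <= 4e6) {
    (sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))) / (nx * ny)
  } else {
    r <- rank(c(x, y))
    (sum(r[seq_len(nx)]) - nx * (nx + 1) / 2) / (as.numeric(nx) * ny)
  }
}

#' Single-feature ROC AUC
#'
#' Area under the ROC curve of the ranking classifier that scores class
#' membership by the feature value itself; positive cases are expected to
#' score higher. Numerically identical to [cles()] of positive versus
#' negative values.
#'
#' @param values_pos,values_neg Feature values of the positive and negative
#'   class (both nonempty).
#' @return AUC in `[0, 1]`.
#' @export
feature_auc <- function(values_pos, values_neg) {
  if (length(values_pos) == 0 || length(values_neg) == 0)
    stop("both classes must be nonempty")
  r <- pROC::roc(controls = values_neg, cases = values_pos,
                 direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

# deterministic subsample for the normality gate (Shapiro-Wilk needs
# 3 <= n <= 5000; we cap at `cap` evenly spaced values)
shapiro_p <- function(v, cap = 500) {
  v <- v[is.finite(v)]
  n <- length(v)
  if (n < 3) return(NA_real_)
  if (n > cap) v <- v[round(seq(1, n, length.out = cap))]
  out <- tryCatch(shapiro.test(v)$p.value, error = function(e) NA_real_)
  out
}

#' Group comparison panel over features and conditions
#'
#' For each topological feature and each stimulus condition (`TGT`, `IGN`
#' and `ALL` = their union), compares the healthy and MCI distributions with
#' the Wilcoxon rank-sum test and reports the U statistic, two-sided
#' p-value, common-language effect size, single-feature ROC AUC, and a
#' Shapiro-Wilk normality p-value per group (on at most `normality_cap`
#' evenly spaced values). All quantities are oriented as healthy versus MCI.
#'
#' Tests are run at epoch level by default, matching the per-epoch feature
#' table; note that epochs within a subject are not independent, so these
#' p-values describe the epoch distributions rather than a subject-level
#' inference. Use `aggregate = "subject"` for per-subject medians. No
#' multiple-testing correction is applied across the 18 panels.
#'
#' @param features Feature table from [study_features()] with both groups.
#' @param aggregate `"epoch"` (default) or `"subject"` (median per subject).
#' @param normality_cap Sample-size cap for the Shapiro-Wilk gate.
#' @return Data frame with 18 rows (6 features x 3 conditions) and columns
#'   `feature`, `condition`, `n_healthy`, `n_mci`, `U`, `p_r`, `cles`,
#'   `auc`, `p_n_healthy`, `p_n_mci`.
#' @export
compare_all <- function(features, aggregate = c("epoch", "subject"),
                        normality_cap = 500) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.data.frame(features))
  if (!all(c("healthy", "mci") %in% features$group))
    stop("feature table must contain both groups")
  rows <- list()
  for (cond in c("TGT", "IGN", "ALL")) {
    sub <- if (cond == "ALL") features else
      features[features$condition == cond, , drop = FALSE]
    for (f in tda_feature_names()) {
      if (aggregate == "subject") {
        agg <- tapply(sub[[f]], sub$subject_id, median)
        grp <- tapply(sub$group, sub$subject_id, `[`, 1)
        h <- agg[grp == "healthy"]; m <- agg[grp == "mci"]
      } else {
        h <- sub[[f]][sub$group == "healthy"]
        m <- sub[[f]][sub$group == "mci"]
      }
      rs <- rank_sum_test(h, m)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, condition = cond,
        n_healthy = length(h), n_mci = length(m),
        U = rs$U, p_r = rs$p,
        cles = cles(h, m),
        auc = feature_auc(h, m),
        p_n_healthy = shapiro_p(h, normality_cap),
        p_n_mci = shapiro_p(m, normality_cap),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
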