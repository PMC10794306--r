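#' Two-dimensional manifold projection of the feature table
#'
#' Unsupervised 2-D embedding (UMAP or t-SNE) of the six topological
#' features, per stimulus condition. Only the feature columns reach the
#' projector -- group labels and MoCA scores are returned alongside for
#' plotting but never passed in, so the embedding is strictly unsupervised.
#' Features are z-scored per column first (counts and entropies live on
#' very different scales). Deterministic given `seed`.
#'
#' @param features Feature table from [study_features()].
#' @param method `"umap"` (default) or `"tsne"`.
#' @param condition `"TGT"`, `"IGN"` or `"ALL"` (union).
#' @param seed Integer seed.
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @param perplexity t-SNE perplexity (requires roughly `3 * perplexity`
#'   epochs).
#' @return A `projection2d`: list with `coordinates` (n x 2 matrix),
#'   `method`, `condition`, `seed`, and `meta` (subject_id, group, moca per
#'   row).
#' @export
project_features <- function(features, method = c("umap", "tsne"),
                             condition = "ALL", seed = 1L,
                             n_neighbors = 15, min_dist = 0.1,
                             perplexity = 30) {
  method <- match.arg(method)
  stopifnot(condition %in% c("TGT", "IGN", "ALL"))
  sub <- if (condition == "ALL") features else
    features[features$condition == condition, , drop = FALSE]
  x <- as.matrix(sub[, tda_feature_names()])
  if (nrow(x) < 4) stop("too few epochs to project")
  x <- scale(x)
  x[, attr(x, "scaled:scale") == 0] <- 0  # constant features carry nothing

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  coords <- if (method == "umap") {
    nn <- min(n_neighbors, nrow(x) - 1)
    uwot::umap(x, n_neighbors = nn, min_dist = min_dist, n_threads = 1,
               n_sgd_threads = 0)
  } else {
    px <- min(perplexity, floor((nrow(x) - 1) / 3))
    if (px < 1) stop("too few epochs for t-SNE")
    Rtsne::Rtsne(x, perplexity = px, check_duplicates = FALSE,
                 num_threads = 1)$Y
  }
  if (!all(is.finite(coords))) stop("projection produced non-finite coordinates")
  structure(list(coordinates = unname(as.matrix(coords)),
                 method = method, condition = condition, seed = seed,
                 meta = sub[, c("subject_id", "group", "moca")]),
            class = "projection2d")
}

#' @export
print.projection2d <- function(x, ...) {
  cat(sprintf("%s projection (%s): %d epochs -> 2-D, seed %d\n",
              toupper(x$method), x$condition, nrow(x$coordinates), x$seed))
  invisible(x)
}

#' Mean silhouette width of labels on a 2-D projection
#'
#' Small helper used to quantify how well the unsupervised embedding
#' separates the cohorts: the average silhouette width of the given labels
#' on the Euclidean 2-D coordinates.
#'
#' @param projection A `projection2d`.
#' @param labels Factor-like vector, one per projected epoch (defaults to
#'   the stored group labels).
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
projection_silhouette <- function(projection,
                                  labels = projection$meta$group) {
  co <- projection$coordinates
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(co))
  d <- as.matrix(dist(co))
  n <- nrow(co)
  sil <- numeric(n)
  for (i in seq_len(n)) {
    same <- labels == labels[i]; same[i] <- FALSE
    other <- labels != labels[i]
    if (!any(same) || !any(other)) { sil[i] <- 0; next }
    a <- mean(d[i, same])
    b <- min(tapply(d[i, other], labels[other], mean))
    sil[i] <- (b - a) / max(a, b)
  }
  mean(sil)
}
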