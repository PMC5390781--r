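feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    need <- c("c_w", "c_c", "c_p")
    miss <- setdiff(need, names(features))
    if (length(miss))
      stop("features data.frame lacks column(s): ", paste(miss, collapse = ", "))
    M <- as.matrix(features[, need])
  } else if (is.list(features) &&
             all(vapply(features, inherits, logical(1L), "feature_vector"))) {
    M <- t(vapply(features, function(f) c(f$c_w, f$c_c, f$c_p), numeric(3L)))
    colnames(M) <- c("c_w", "c_c", "c_p")
  } else if (is.matrix(features) && ncol(features) == 3L) {
    M <- features
    colnames(M) <- c("c_w", "c_c", "c_p")
  } else stop("features must be a data.frame, matrix, or list of feature_vector")
  if (!all(is.finite(M))) stop("features contain non-finite values")
  M
}

#' Fit a group model for Mahalanobis classification
#'
#' Estimates the mean vector and sample covariance (denominator `n - 1`) of
#' one group's concentration feature vectors. An optional ridge `eps * I`
#' can be added to the covariance for near-singular groups; by default none
#' is, and a singular covariance is an error.
#'
#' @param features feature vectors of one group: a data.frame with columns
#'   `c_w`, `c_c`, `c_p`, a 3-column matrix, or a list of `feature_vector`.
#' @param label group label stored in the model.
#' @param ridge non-negative ridge added to the covariance diagonal
#'   (default 0).
#' @return An object of class `group_model`: list with `label`, `mu`
#'   (3-vector), `S` (3x3 covariance), `chol_S` (upper Cholesky factor),
#'   `n`.
#' @export
fit_group_model <- function(features, label, ridge = 0) {
  M <- feature_matrix(features)
  n <- nrow(M)
  if (n < 4L) stop("need at least 4 samples per group, got ", n)
  mu <- colMeans(M)
  S <- stats::cov(M) + diag(ridge, 3L)
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R) || any(diag(R) < sqrt(.Machine$double.eps) * max(diag(R), 1))) {
    vr <- diag(stats::cov(M))
    worst <- names(vr)[which.min(vr)]
    stop("covariance of group '", label, "' is singular or near-singular ",
         "(deficient direction dominated by '", worst,
         "'); add a ridge or more varied samples")
  }
  structure(list(label = as.character(label), mu = mu, S = S, chol_S = R, n = n),
            class = "group_model")
}

#' @export
print.group_model <- function(x, ...) {
  cat(sprintf("<group_model> '%s' (n = %d): mu = (%.4f, %.4f, %.4f)\n",
              x$label, x$n, x$mu[1L], x$mu[2L], x$mu[3L]))
  invisible(x)
}

#' Squared Mahalanobis distance to a group
#'
#' Computes `D^2 = (x - mu)' S^-1 (x - mu)` through the Cholesky factor of
#' the group covariance (a triangular solve, no explicit inversion). `D^2`
#' is invariant under any common invertible linear transformation of the
#' feature space -- in particular under the common scaling an unknown
#' optical path length applies to all concentration estimates.
#'
#' @param x a 3-vector, 3-column matrix of feature vectors, `feature_vector`,
#'   or features data.frame.
#' @param g a [fit_group_model()] object.
#' @return Numeric vector of squared distances, one per row of `x`.
#' @export
mahalanobis_d2 <- function(x, g) {
  stopifnot(inherits(g, "group_model"))
  M <- if (is.numeric(x) && is.null(dim(x)) && length(x) == 3L)
    matrix(x, 1L) else feature_matrix(x)
  Z <- backsolve(g$chol_S, t(M) - g$mu, transpose = TRUE)
  colSums(Z * Z)
}

#' Classify feature vectors by minimal Mahalanobis distance
#'
#' Each sample is assigned to the group whose Mahalanobis distance is
#' smallest. Ties are broken toward the `"normal"` (non-degraded) group
#' with a warning. When true labels are available a confusion summary is
#' computed with *degraded as the positive class*: a false positive is a
#' normal sample labelled degraded, a false negative a degraded sample
#' labelled normal; percentages use the grand total of classified samples.
#'
#' @param features feature vectors (data.frame, matrix, or list of
#'   `feature_vector`).
#' @param models list of exactly two `group_model` objects, one of which
#'   must be labelled `"degraded"` for confusion reporting.
#' @param truth optional character vector of true labels (or taken from a
#'   `group` column of `features` when present).
#' @return An object of class `classification_result`: data.frame `samples`
#'   (per-sample `D2` to each group and `predicted`), and -- when truth is
#'   known -- `false_pos`, `false_neg`, `total`, `accuracy`, and the
#'   corresponding percentages.
#' @export
classify <- function(features, models, truth = NULL) {
  if (!is.list(models) || length(models) != 2L ||
      !all(vapply(models, inherits, logical(1L), "group_model")))
    stop("`models` must be a list of exactly two group_model objects")
  labs <- vapply(models, `[[`, character(1L), "label")
  if (anyDuplicated(labs)) stop("the two group models must have distinct labels")
  M <- feature_matrix(features)
  if (is.null(truth) && is.data.frame(features) && "group" %in% names(features))
    truth <- features$group
  D2 <- vapply(models, function(g) mahalanobis_d2(M, g), numeric(nrow(M)))
  if (nrow(M) == 1L) D2 <- matrix(D2, 1L)
  colnames(D2) <- labs

  pick <- max.col(-D2, ties.method = "first")
  ties <- abs(D2[, 1L] - D2[, 2L]) == 0
  if (any(ties)) {
    to_normal <- if ("normal" %in% labs) which(labs == "normal") else 1L
    pick[ties] <- to_normal
    warning(sum(ties), " tie(s) in Mahalanobis distance broken toward '",
            labs[to_normal], "'")
  }
  predicted <- labs[pick]
  samples <- data.frame(D2, predicted = predicted, stringsAsFactors = FALSE)

  out <- list(samples = samples, labels = labs)
  if (!is.null(truth) && !all(is.na(truth))) {
    if (length(truth) != nrow(M))
      stop("`truth` must supply one label per sample")
    if (!"degraded" %in% labs)
      stop("confusion reporting expects one model labelled 'degraded'")
    pos <- "degraded"
    neg <- setdiff(labs, pos)
    fp <- sum(truth == neg & predicted == pos)
    fn <- sum(truth == pos & predicted == neg)
    n <- sum(truth %in% labs)
    out$false_pos <- fp
    out$false_neg <- fn
    out$total <- n
    out$false_pos_pct <- 100 * fp / n
    out$false_neg_pct <- 100 * fn / n
    out$accuracy <- 1 - (fp + fn) / n
  }
  structure(out, class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification_result> ", nrow(x$samples), " samples (",
      paste(x$labels, collapse = " vs "), ")\n", sep = "")
  if (!is.null(x$total))
    cat(sprintf("  false pos %d (%.2f%%), false neg %d (%.2f%%), accuracy %.4f\n",
                x$false_pos, x$false_pos_pct, x$false_neg, x$false_neg_pct,
                x$accuracy))
  invisible(x)
}

#' Leave-one-out Mahalanobis classification
#'
#' Scores each sample against group models refitted with that sample held
#' out (the model of its own group loses one observation; the other group's
#' model is unchanged), then classifies by minimal distance. This avoids
#' the optimistic bias of resubstitution when the same samples define the
#' group means and covariances.
#'
#' @param features feature data.frame with a `group` column, or any
#'   accepted feature container plus an explicit `labels` vector.
#' @param labels true group labels (exactly two distinct values).
#' @param ridge ridge passed to [fit_group_model()].
#' @return A `classification_result` (see [classify()]).
#' @export
classify_loo <- function(features, labels = NULL, ridge = 0) {
  M <- feature_matrix(features)
  if (is.null(labels) && is.data.frame(features) && "group" %in% names(features))
    labels <- features$group
  if (is.null(labels)) stop("leave-one-out classification needs true labels")
  labels <- as.character(labels)
  labs <- sort(unique(labels))
  if (length(labs) != 2L) stop("need exactly two groups, got ", length(labs))
  n <- nrow(M)
  D2 <- matrix(NA_real_, n, 2L, dimnames = list(NULL, labs))
  full <- lapply(labs, function(l) fit_group_model(M[labels == l, , drop = FALSE], l))
  names(full) <- labs
  for (i in seq_len(n)) {
    gi <- labels[i]
    own <- fit_group_model(M[labels == gi & seq_len(n) != i, , drop = FALSE], gi)
    other <- full[[setdiff(labs, gi)]]
    D2[i, gi] <- mahalanobis_d2(M[i, ], own)
    D2[i, setdiff(labs, gi)] <- mahalanobis_d2(M[i, ], other)
  }
  pick <- max.col(-D2, ties.method = "first")
  ties <- abs(D2[, 1L] - D2[, 2L]) == 0
  if (any(ties)) {
    to_normal <- if ("normal" %in% labs) which(labs == "normal") else 1L
    pick[ties] <- to_normal
    warning(sum(ties), " tie(s) broken toward '", labs[to_normal], "'")
  }
  predicted <- labs[pick]
  samples <- data.frame(D2, predicted = predicted, stringsAsFactors = FALSE)
  out <- list(samples = samples, labels = labs)
  if ("degraded" %in% labs) {
    pos <- "degraded"; neg <- setdiff(labs, pos)
    fp <- sum(labels == neg & predicted == pos)
    fn <- sum(labels == pos & predicted == neg)
    out$false_pos <- fp; out$false_neg <- fn; out$total <- n
    out$false_pos_pct <- 100 * fp / n
    out$false_neg_pct <- 100 * fn / n
    out$accuracy <- 1 - (fp + fn) / n
  }
  structure(out, class = "classification_result")
}
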