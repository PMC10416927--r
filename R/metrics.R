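#' Per-output area under the ROC curve
#'
#' For each output column, the probability that a randomly chosen positive
#' sample receives a higher score than a randomly chosen negative one
#' (ties count one half), computed from midranks.  Columns with no
#' positive or no negative labels are undefined and returned as
#' \code{NA}.
#'
#' @param preds numeric score matrix, samples x outputs.
#' @param y binary label matrix of the same shape.
#' @return numeric vector of per-column AUROC values (\code{NA} where
#'   undefined).
#' @export
auroc_per_output <- function(preds, y) {
  if (!identical(dim(preds), dim(y))) stop("shape mismatch between 'preds' and 'y'")
  vapply(seq_len(ncol(y)), function(j) {
    lab <- y[, j]; np <- sum(lab == 1); nn <- sum(lab == 0)
    if (np == 0L || nn == 0L) return(NA_real_)
    r <- rank(preds[, j], ties.method = "average")
    (sum(r[lab == 1]) - np * (np + 1) / 2) / (np * nn)
  }, numeric(1))
}

#' Per-output area under the precision-recall curve
#'
#' Average precision: the step-wise integral of precision over recall,
#' sweeping a descending score threshold with tied scores grouped into a
#' single step.  Columns with no positive labels are undefined
#' (\code{NA}).
#'
#' @inheritParams auroc_per_output
#' @return numeric vector of per-column average-precision values.
#' @export
aupr_per_output <- function(preds, y) {
  if (!identical(dim(preds), dim(y))) stop("shape mismatch between 'preds' and 'y'")
  vapply(seq_len(ncol(y)), function(j) {
    lab <- y[, j]; P <- sum(lab == 1)
    if (P == 0L) return(NA_real_)
    s <- preds[, j]
    o <- order(s, decreasing = TRUE)
    s <- s[o]; lab <- lab[o]
    # group tied scores: evaluate precision only at the end of each group
    ends <- c(which(diff(s) != 0), length(s))
    cum_tp <- cumsum(lab)[ends]
    cum_n <- ends
    tp_step <- diff(c(0, cum_tp))
    sum(tp_step / P * (cum_tp / cum_n))
  }, numeric(1))
}

#' Compute the full metric bundle for one prediction matrix
#'
#' @inheritParams auroc_per_output
#' @param provenance free-form identifier recorded in the result.
#' @return list of class \code{metric_bundle} with the mean cross-entropy
#'   (nats), per-output and mean AUROC/AUPR.
#' @export
metric_bundle <- function(preds, y, provenance = "") {
  p <- pmin(pmax(preds, 1e-12), 1 - 1e-12)
  cel <- -mean(y * log(p) + (1 - y) * log(1 - p))
  auroc <- auroc_per_output(preds, y)
  aupr <- aupr_per_output(preds, y)
  structure(list(cel = cel, auroc_per_deg = auroc, aupr_per_deg = aupr,
                 auroc_mean = mean(auroc, na.rm = TRUE),
                 aupr_mean = mean(aupr, na.rm = TRUE),
                 provenance = provenance),
            class = "metric_bundle")
}

#' @export
print.metric_bundle <- function(x, ...) {
  cat(sprintf("Metrics%s: cross-entropy %.4f nats, mean AUROC %.4f, mean AUPR %.4f (%d outputs, %d undefined)\n",
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else "",
              x$cel, x$auroc_mean, x$aupr_mean, length(x$auroc_per_deg),
              sum(is.na(x$auroc_per_deg))))
  invisible(x)
}

#' Aggregate metric bundles over cross-validation folds
#'
#' Per-DEG AUROC/AUPR are averaged over the folds in which they are
#' defined; DEGs undefined in every fold are excluded from the grand mean
#' and reported.  Scalar metrics are summarized as mean and standard
#' deviation across folds.
#'
#' @param per_fold list of [metric_bundle()] objects.
#' @return list with per-metric \code{mean}/\code{sd}, the per-DEG
#'   fold-averaged vectors, and \code{n_undefined}.
#' @export
summarize_over_folds <- function(per_fold) {
  if (!length(per_fold)) stop("no folds to summarize")
  sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
  auroc_mat <- sapply(per_fold, function(b) b$auroc_per_deg)
  aupr_mat <- sapply(per_fold, function(b) b$aupr_per_deg)
  if (is.null(dim(auroc_mat))) {
    auroc_mat <- matrix(auroc_mat, ncol = length(per_fold))
    aupr_mat <- matrix(aupr_mat, ncol = length(per_fold))
  }
  auroc_deg <- rowMeans(auroc_mat, na.rm = TRUE)
  aupr_deg <- rowMeans(aupr_mat, na.rm = TRUE)
  undef <- !is.finite(auroc_deg)
  cels <- vapply(per_fold, `[[`, numeric(1), "cel")
  aurocs <- vapply(per_fold, `[[`, numeric(1), "auroc_mean")
  auprs <- vapply(per_fold, `[[`, numeric(1), "aupr_mean")
  list(cel_mean = mean(cels), cel_sd = sd0(cels),
       auroc_mean = mean(aurocs), auroc_sd = sd0(aurocs),
       aupr_mean = mean(auprs), aupr_sd = sd0(auprs),
       auroc_per_deg = ifelse(undef, NA_real_, auroc_deg),
       aupr_per_deg = ifelse(is.finite(aupr_deg), aupr_deg, NA_real_),
       n_undefined = sum(undef))
}

#' Uniform-random prediction baseline
#'
#' Samples predictions iid from U[0, 1) and evaluates them against the
#' labels.  Analytically, the expected cross-entropy of a uniform score
#' against any binary label is exactly 1 nat and the expected AUROC is
#' 0.5; the expected average precision equals the column prevalence.
#'
#' @param y binary label matrix.
#' @param seed integer seed.
#' @return a [metric_bundle()].
#' @export
random_baseline <- function(y, seed = 1L) {
  stopifnot(length(y) > 0)
  preds <- with_seed(seed, matrix(stats::runif(length(y)), nrow(y)))
  metric_bundle(preds, y, provenance = sprintf("random baseline (seed %d)", seed))
}

#' k-nearest-neighbor baseline over cross-validation folds
#'
#' For each validation tumor, finds the \code{k} nearest training tumors
#' by distance between binary SGA vectors and predicts each DEG's
#' probability as the fraction of those neighbors carrying the DEG.
#' Neighbors are weighted uniformly; distance ties are broken by
#' ascending training-set index.  The Jaccard distance of two all-zero
#' vectors is defined as 0 (identical).
#'
#' @param data an [rinn_data()] object.
#' @param plan a [make_cv_splits()] fold plan for \code{data}.
#' @param k number of neighbors.
#' @param metric \code{"euclidean"} or \code{"jaccard"}.
#' @return list of per-fold [metric_bundle()]s plus their
#'   [summarize_over_folds()] summary.
#' @export
knn_baseline <- function(data, plan, k = 21, metric = c("euclidean", "jaccard")) {
  metric <- match.arg(metric)
  if (k < 1L) stop("'k' must be positive")
  bundles <- lapply(plan$used, function(f) {
    val <- which(plan$fold == f); tr <- which(plan$fold != f)
    if (k > length(tr)) stop("'k' exceeds the training split size")
    Xv <- data$sga[val, , drop = FALSE]; Xt <- data$sga[tr, , drop = FALSE]
    common <- Xv %*% t(Xt)
    rv <- rowSums(Xv); rt <- rowSums(Xt)
    if (metric == "euclidean") {
      D <- sqrt(pmax(outer(rv, rt, "+") - 2 * common, 0))
    } else {
      un <- outer(rv, rt, "+") - common
      D <- ifelse(un == 0, 0, 1 - common / ifelse(un == 0, 1, un))
    }
    preds <- t(apply(D, 1L, function(d) {
      nb <- order(d, seq_along(d))[seq_len(k)]
      colMeans(data$deg[tr[nb], , drop = FALSE])
    }))
    metric_bundle(preds, data$deg[val, , drop = FALSE],
                  provenance = sprintf("kNN k=%d %s, fold %d", k, metric, f))
  })
  list(folds = bundles, summary = summarize_over_folds(bundles))
}
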