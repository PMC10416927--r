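#' Build a cross-validation fold plan
#'
#' Partitions the samples into \code{k} folds of near-equal size by a
#' seeded permutation; the first \code{folds_used} folds are the
#' validation sets actually evaluated (3 folds of 10-fold
#' cross-validation by default, so each evaluation trains on 90\% of the
#' data and validates on 10\%).
#'
#' @param n_samples number of samples.
#' @param k number of folds.
#' @param folds_used how many folds serve as validation sets.
#' @param seed integer seed.
#' @return list of class \code{fold_plan}: \code{fold} (fold id per
#'   sample), \code{used}, \code{k}, \code{seed}.
#' @export
make_cv_splits <- function(n_samples, k = 10, folds_used = 3, seed = 1L) {
  if (n_samples < k) stop("'n_samples' must be at least 'k'")
  if (folds_used > k) stop("'folds_used' cannot exceed 'k'")
  fold <- integer(n_samples)
  with_seed(seed, {
    fold[sample.int(n_samples)] <- rep_len(seq_len(k), n_samples)
  })
  structure(list(fold = fold, used = seq_len(folds_used), k = as.integer(k),
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Sample hyperparameter configurations from a search space
#'
#' Combined random/grid search: list elements of the space that are plain
#' vectors are treated as grids and sampled uniformly from their values;
#' elements of the form \code{list(min =, max =)} are sampled log-uniformly
#' (set \code{log = FALSE} for linear sampling); integer-valued ranges are
#' rounded.  The default space mirrors the hyperparameter ranges that
#' full-scale model selection explored: learning rate 1e-4--1e-3, L1 rate
#' 4.5e-6--6.4e-6, 100--800 epochs, batch sizes 30--170, hidden sizes
#' 50--650, activations relu/softplus/sigmoid.
#'
#' @param space named list of grids/ranges for \code{learning_rate},
#'   \code{l1}, \code{epochs}, \code{batch_size}, \code{hidden_sizes},
#'   \code{activation}.
#' @param n number of configurations to draw.
#' @param seed integer seed.
#' @param architecture \code{"RINN"} or \code{"DNN"}; DNN configurations
#'   also sample \code{n_hidden_layers} (grid 1--8 by default).
#' @return list of [rinn_hp()] objects.
#' @export
sample_hyperparameters <- function(space = default_search_space(), n = 10,
                                   seed = 1L, architecture = "RINN") {
  architecture <- match.arg(architecture, c("RINN", "DNN"))
  if (!length(space)) stop("empty search space")
  draw <- function(field) {
    v <- space[[field]]
    if (is.null(v)) stop(sprintf("search space lacks field '%s'", field))
    if (is.list(v)) {
      if (is.null(v$min) || is.null(v$max) || v$min > v$max || length(v$min) != 1L) {
        stop(sprintf("invalid range for field '%s'", field))
      }
      log_scale <- v$log %||% TRUE
      x <- if (log_scale) exp(stats::runif(1, log(v$min), log(v$max)))
           else stats::runif(1, v$min, v$max)
      if (isTRUE(v$integer)) x <- as.integer(round(x))
      x
    } else {
      if (!length(v)) stop(sprintf("empty grid for field '%s'", field))
      v[[sample.int(length(v), 1L)]]
    }
  }
  with_seed(seed, {
    lapply(seq_len(max(n, 0L)), function(i) {
      hs <- draw("hidden_sizes")
      if (architecture == "DNN") {
        nh <- if (!is.null(space$n_hidden_layers)) draw("n_hidden_layers")
              else sample.int(8L, 1L)
        hs <- rep(hs, length.out = nh)
      }
      rinn_hp(learning_rate = draw("learning_rate"), l1 = draw("l1"),
              epochs = draw("epochs"), batch_size = draw("batch_size"),
              activation = draw("activation"), hidden_sizes = hs,
              architecture = architecture)
    })
  })
}

#' @rdname sample_hyperparameters
#' @export
default_search_space <- function() {
  list(learning_rate = list(min = 1e-4, max = 1e-3),
       l1 = list(min = 4.5e-6, max = 6.4e-6),
       epochs = list(min = 100, max = 800, log = FALSE, integer = TRUE),
       batch_size = list(min = 30, max = 170, log = FALSE, integer = TRUE),
       hidden_sizes = list(min = 50, max = 650, log = FALSE, integer = TRUE),
       activation = c("relu", "softplus", "sigmoid"))
}

#' Desk-scale search space for synthetic studies
#'
#' A reduced search space sized for the package's synthetic datasets
#' (hundreds of samples, tens of SGAs, nets with ~10^3--10^4
#' parameters): SGD learning rates 0.4--0.6, L1 rates 5e-5--3e-4
#' (log-uniform), 200--300 epochs, batches of 48--64, hidden sizes
#' 6--10, softplus activation (the activation full-scale selection
#' overwhelmingly favored).  Small nets trained on hundreds of samples
#' tolerate and need far larger SGD steps than the full-scale nets'
#' 1e-4--1e-3 range; the narrow hidden layers impose the capacity
#' pressure that makes functionally equivalent inputs share hidden
#' nodes.
#'
#' @export
desk_search_space <- function() {
  list(learning_rate = list(min = 0.4, max = 0.6),
       l1 = list(min = 5e-5, max = 3e-4),
       epochs = list(min = 200, max = 300, log = FALSE, integer = TRUE),
       batch_size = list(min = 48, max = 64, log = FALSE, integer = TRUE),
       hidden_sizes = list(min = 6, max = 10, log = FALSE, integer = TRUE),
       activation = "softplus")
}

#' Evaluate one hyperparameter configuration under a fold plan
#'
#' Trains one network per used fold on that fold's 90\% training split
#' and records validation cross-entropy, mean AUROC, mean AUPR and the
#' total absolute weight, aggregated as mean and standard deviation over
#' folds.  Training failures are caught and flagged rather than aborting
#' a sweep.  Per-fold training seeds derive deterministically from
#' \code{(seed, candidate_index, fold)}.
#'
#' @param data an [rinn_data()] object.
#' @param architecture \code{"RINN"} or \code{"DNN"}.
#' @param hp an [rinn_hp()] object.
#' @param plan a [make_cv_splits()] plan for \code{data}.
#' @param seed sweep-level integer seed.
#' @param candidate_index index of this candidate within its sweep.
#' @return list of class \code{model_record}.
#' @export
evaluate_candidate <- function(data, architecture, hp, plan, seed = 1L,
                               candidate_index = 0L) {
  if (length(plan$fold) != nrow(data$sga)) {
    stop("fold plan was built for a different sample count")
  }
  sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
  rec <- tryCatch({
    folds <- lapply(plan$used, function(f) {
      tr <- which(plan$fold != f); val <- which(plan$fold == f)
      sub <- list(sga = data$sga[tr, , drop = FALSE],
                  deg = data$deg[tr, , drop = FALSE])
      fit <- train_network(sub, architecture, hp,
                           seed = derive_seed(seed, candidate_index, f))
      preds <- network_forward(fit$weights, data$sga[val, , drop = FALSE])
      b <- metric_bundle(preds, data$deg[val, , drop = FALSE],
                         provenance = sprintf("candidate %d, fold %d",
                                              candidate_index, f))
      sw <- sum(vapply(fit$weights$W, function(w) sum(abs(w)), numeric(1)))
      list(bundle = b, sum_abs_w = sw)
    })
    cels <- vapply(folds, function(f) f$bundle$cel, numeric(1))
    aurocs <- vapply(folds, function(f) f$bundle$auroc_mean, numeric(1))
    auprs <- vapply(folds, function(f) f$bundle$aupr_mean, numeric(1))
    sws <- vapply(folds, function(f) f$sum_abs_w, numeric(1))
    list(hp = hp, architecture = architecture, failed = FALSE, error = NULL,
         fold_cel = cels, fold_auroc = aurocs, fold_aupr = auprs,
         fold_sum_abs_w = sws,
         cel = mean(cels), cel_sd = sd0(cels),
         auroc = mean(aurocs), auroc_sd = sd0(aurocs),
         aupr = mean(auprs), aupr_sd = sd0(auprs),
         sum_abs_w = mean(sws), sum_abs_w_sd = sd0(sws),
         dx = NA_real_, candidate_index = candidate_index)
  }, error = function(e) {
    list(hp = hp, architecture = architecture, failed = TRUE,
         error = conditionMessage(e), dx = NA_real_,
         candidate_index = candidate_index)
  })
  class(rec) <- "model_record"
  rec
}

#' Sparsity-versus-error distance from the origin
#'
#' The model-selection score: the Euclidean distance from the origin in
#' the plane spanned by total absolute weight and validation
#' cross-entropy, \eqn{d_x = \sqrt{(\sum|w|)^2 + L^2}}.  In
#' \code{"minmax"} mode (the default used for ranking) both axes are
#' first rescaled to [0, 1] over the candidate population, since the raw
#' distance is dominated by the weight axis, whose magnitude is orders of
#' magnitude larger than the loss.
#'
#' @param cel validation cross-entropy (nats).
#' @param sum_abs_weights total absolute weight.
#' @param mode \code{"minmax"} or \code{"raw"}.
#' @param population for minmax mode: a two-column matrix or list of
#'   \code{(cel, sum_abs_weights)} pairs defining the rescaling.
#' @return nonnegative distance (vectorized over \code{cel}).
#' @export
compute_dx <- function(cel, sum_abs_weights, mode = c("minmax", "raw"),
                       population = NULL) {
  mode <- match.arg(mode)
  if (mode == "raw") return(sqrt(sum_abs_weights^2 + cel^2))
  if (is.list(population)) population <- do.call(rbind, lapply(population, unlist))
  if (is.null(population) || nrow(population) < 2L) {
    stop("minmax mode needs a population of at least 2 (cel, sum|w|) pairs")
  }
  rng_c <- range(population[, 1L]); rng_w <- range(population[, 2L])
  if (diff(rng_c) == 0 || diff(rng_w) == 0) {
    stop("degenerate population: an axis has no spread")
  }
  sqrt(((cel - rng_c[1L]) / diff(rng_c))^2 +
       ((sum_abs_weights - rng_w[1L]) / diff(rng_w))^2)
}

#' Rank evaluated models by distance from the origin
#'
#' Computes \code{dx} for every successful record (minmax-normalized over
#' the successful population by default) and orders ascending; ties break
#' by lower cross-entropy, then lower total weight, then insertion
#' order.  Failed records are excluded.
#'
#' @param records list of [evaluate_candidate()] records.
#' @param mode passed to [compute_dx()].
#' @return the successful records, ordered, each with \code{dx} and
#'   \code{rank} filled in.
#' @export
rank_models <- function(records, mode = c("minmax", "raw")) {
  mode <- match.arg(mode)
  ok <- !vapply(records, `[[`, logical(1), "failed")
  if (!any(ok)) stop("all model records failed")
  recs <- records[ok]
  cel <- vapply(recs, `[[`, numeric(1), "cel")
  sw <- vapply(recs, `[[`, numeric(1), "sum_abs_w")
  dx <- if (mode == "raw") compute_dx(cel, sw, "raw")
        else if (length(recs) >= 2L && diff(range(cel)) > 0 && diff(range(sw)) > 0)
          compute_dx(cel, sw, "minmax", population = cbind(cel, sw))
        else compute_dx(cel, sw, "raw")
  o <- order(dx, cel, sw, seq_along(recs))
  recs <- recs[o]
  for (i in seq_along(recs)) {
    recs[[i]]$dx <- dx[o[i]]
    recs[[i]]$rank <- i
  }
  recs
}

#' Run a hyperparameter sweep with cross-validation
#'
#' Draws \code{n_candidates} configurations from the search space,
#' evaluates each under the fold plan and returns the ranked records
#' together with a one-row-per-candidate ledger.
#'
#' @param data an [rinn_data()] object.
#' @param n_candidates number of configurations.
#' @param architecture \code{"RINN"} or \code{"DNN"}.
#' @param space search space (see [sample_hyperparameters()]); defaults
#'   to [desk_search_space()] sized for synthetic data.
#' @param k,folds_used cross-validation setup.
#' @param seed integer seed for sampling, fold assignment and training.
#' @param mode dx mode for ranking.
#' @return object of class \code{rinn_sweep}: \code{records} (ranked),
#'   \code{all_records}, \code{ledger} (data frame), \code{plan}.
#' @export
rinn_select <- function(data, n_candidates = 50, architecture = "RINN",
                        space = desk_search_space(), k = 10, folds_used = 3,
                        seed = 1L, mode = "minmax") {
  plan <- make_cv_splits(nrow(data$sga), k = k, folds_used = folds_used,
                         seed = derive_seed(seed, 0L, 0L))
  hps <- sample_hyperparameters(space, n_candidates, seed = derive_seed(seed, 0L, 1L),
                                architecture = architecture)
  records <- lapply(seq_along(hps), function(i) {
    evaluate_candidate(data, architecture, hps[[i]], plan, seed = seed,
                       candidate_index = i)
  })
  ranked <- rank_models(records, mode = mode)
  structure(list(records = ranked, all_records = records,
                 ledger = sweep_ledger(ranked), plan = plan,
                 seed = as.integer(seed), mode = mode),
            class = "rinn_sweep")
}

#' @export
print.rinn_sweep <- function(x, ...) {
  n_fail <- sum(vapply(x$all_records, `[[`, logical(1), "failed"))
  cat(sprintf("Hyperparameter sweep: %d candidates (%d failed), %d-fold CV on %d folds\n",
              length(x$all_records), n_fail, x$plan$k, length(x$plan$used)))
  cat("Top models by dx:\n")
  print(utils::head(x$ledger[, c("rank", "dx", "cel", "auroc", "sum_abs_w",
                                 "learning_rate", "l1", "epochs")], 5L),
        row.names = FALSE)
  invisible(x)
}

# one row per ranked record
sweep_ledger <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(rank = r$rank, candidate = r$candidate_index,
               architecture = r$architecture,
               learning_rate = r$hp$learning_rate, l1 = r$hp$l1,
               epochs = r$hp$epochs, batch_size = r$hp$batch_size,
               activation = r$hp$activation,
               hidden = paste(r$hp$hidden_sizes, collapse = "-"),
               cel = r$cel, cel_sd = r$cel_sd, auroc = r$auroc,
               auroc_sd = r$auroc_sd, aupr = r$aupr, aupr_sd = r$aupr_sd,
               sum_abs_w = r$sum_abs_w, sum_abs_w_sd = r$sum_abs_w_sd,
               dx = r$dx)
  }))
}

#' Retrain a configuration on all samples
#'
#' After model selection, the chosen configurations are retrained on
#' 100\% of the data for analysis of the learned weights.
#'
#' @param data an [rinn_data()] object.
#' @param architecture,hp,seed as in [rinn()].
#' @return a fitted \code{rinn} object.
#' @export
retrain_full <- function(data, architecture, hp, seed = 1L) {
  rinn(data, architecture = architecture, hidden_sizes = hp$hidden_sizes,
       activation = hp$activation, learning_rate = hp$learning_rate,
       l1 = hp$l1, epochs = hp$epochs, batch_size = hp$batch_size,
       seed = seed)
}
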