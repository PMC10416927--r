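#' Candidate edges for a causal graph
#'
#' All edges eligible for the thresholded causal graph of a trained RINN
#' restricted to an SGA set: every SGA-to-hidden edge originating from
#' the set (any layer, via the redundant-input rows) plus every
#' hidden-to-hidden edge between consecutive layers.  Output-head weights
#' (\code{W9}) are never candidates.
#'
#' @param weights an \code{rinn_weights} RINN object or fitted [rinn()]
#'   model.
#' @param sga_set character vector of SGA ids (subset of the model's
#'   inputs).
#' @return data frame with columns \code{from}, \code{to}, \code{layer}
#'   (destination layer), \code{type} (\code{"sga"} or \code{"hidden"}),
#'   \code{weight}, \code{abs_w}.  Hidden nodes are named
#'   \code{h<layer>_<index>} with layer 1 adjacent to the SGAs.
#' @export
candidate_edges <- function(weights, sga_set = character()) {
  sga_ids <- NULL
  if (inherits(weights, "rinn")) {
    sga_ids <- weights$sga_ids
    weights <- weights$weights
  }
  stopifnot(inherits(weights, "rinn_weights"))
  if (weights$architecture != "RINN") stop("causal graphs require RINN weights")
  m <- weights$n_inputs
  h <- weights$hidden_sizes
  sga_ids <- sga_ids %||% sprintf("SGA%02d", seq_len(m))
  unknown <- setdiff(sga_set, sga_ids)
  if (length(unknown)) {
    stop(sprintf("unknown gene id(s): %s", paste(unknown, collapse = ", ")))
  }
  sel <- match(sga_set, sga_ids)
  hid <- function(l, idx) sprintf("h%d_%d", l, idx)

  out <- list()
  for (l in seq_len(8L)) {
    wl <- if (l == 1L) weights$W[[1L]]
          else weights$W[[l]][(nrow(weights$W[[l]]) - m + 1L):nrow(weights$W[[l]]), ,
                              drop = FALSE]
    if (length(sel)) {
      block <- wl[sel, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        from = rep(sga_set, times = h[l]),
        to = rep(hid(l, seq_len(h[l])), each = length(sel)),
        layer = l, type = "sga",
        weight = as.vector(block), stringsAsFactors = FALSE)
    }
    if (l >= 2L) {
      core <- weights$W[[l]][seq_len(h[l - 1L]), , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        from = rep(hid(l - 1L, seq_len(h[l - 1L])), times = h[l]),
        to = rep(hid(l, seq_len(h[l])), each = h[l - 1L]),
        layer = l, type = "hidden",
        weight = as.vector(core), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out$abs_w <- abs(out$weight)
  out
}

# edges kept at a threshold under the reachability rule; cand from
# candidate_edges()
retained_edges <- function(cand, threshold) {
  keep <- cand[cand$abs_w >= threshold, , drop = FALSE]
  sga_e <- keep[keep$type == "sga", , drop = FALSE]
  hid_e <- keep[keep$type == "hidden", , drop = FALSE]
  reached <- unique(sga_e$to)
  if (nrow(hid_e)) {
    # edges run layer l-1 -> l, so one ascending pass settles reachability
    keep_h <- logical(nrow(hid_e))
    for (l in sort(unique(hid_e$layer))) {
      at <- which(hid_e$layer == l)
      ok <- hid_e$from[at] %in% reached
      keep_h[at] <- ok
      reached <- union(reached, hid_e$to[at][ok])
    }
    hid_e <- hid_e[keep_h, , drop = FALSE]
  }
  rbind(sga_e, hid_e)
}

#' Find the weight threshold yielding a target edge count
#'
#' Binary-searches the distinct absolute weights of the candidate edges
#' for the threshold at which the causal graph (SGA-origin edges with
#' \code{|w| >= t}, plus hidden-to-hidden edges with \code{|w| >= t} that
#' are reachable from a kept SGA edge) retains \code{target_edges}
#' edges.  When ties or reachability jumps make the exact count
#' unattainable, the smallest threshold yielding at most
#' \code{target_edges} is returned and the realized count reported.
#'
#' @param weights RINN weights or fitted model, or a
#'   [candidate_edges()] data frame.
#' @param sga_set SGA ids (ignored when \code{weights} is already a
#'   candidate table).
#' @param target_edges desired total number of retained edges.
#' @return list with \code{threshold} and the realized \code{n_edges}.
#' @export
find_edge_threshold <- function(weights, sga_set = character(),
                                target_edges = 300) {
  cand <- if (is.data.frame(weights)) weights else candidate_edges(weights, sga_set)
  if (target_edges > nrow(cand)) stop("fewer candidate edges than 'target_edges'")
  vals <- sort(unique(cand$abs_w))  # ascending; count(t) non-increasing in t
  count_at <- function(t) nrow(retained_edges(cand, t))
  lo <- 1L; hi <- length(vals)
  # find the smallest threshold value with count <= target
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (count_at(vals[mid]) <= target_edges) hi <- mid else lo <- mid + 1L
  }
  thr <- vals[lo]
  n <- count_at(thr)
  if (n > target_edges) {
    # only possible when ties at the maximum weight exceed the target:
    # no finite threshold yields <= target, so keep nothing
    thr <- vals[length(vals)] * (1 + 1e-9) + 1e-12
    n <- count_at(thr)
  }
  list(threshold = thr, n_edges = n)
}

#' Build a thresholded causal graph from RINN weights
#'
#' Keeps SGA-origin edges from the given SGA set with absolute weight at
#' least the threshold, and hidden-to-hidden edges above the threshold
#' that are reachable (by a directed path) from a kept SGA-origin edge;
#' hidden nodes not incident to any kept edge are pruned.  The layer
#' ordering makes the graph acyclic by construction.
#'
#' @param weights RINN weights or fitted [rinn()] model.
#' @param sga_set character vector of SGA ids forming set \emph{j}.
#' @param threshold nonnegative absolute-weight cutoff.
#' @param model_id optional identifier stored on the graph.
#' @return object of class \code{causal_graph}: \code{edges} (data
#'   frame), \code{hidden_nodes}, \code{sga_set}, \code{threshold},
#'   \code{model_id}.
#' @export
build_causal_graph <- function(weights, sga_set, threshold, model_id = NA) {
  stopifnot(threshold >= 0)
  cand <- candidate_edges(weights, sga_set)
  edges <- retained_edges(cand, threshold)
  hidden <- sort(unique(c(edges$to, edges$from[edges$type == "hidden"])))
  structure(list(edges = edges, hidden_nodes = hidden,
                 sga_set = sga_set, threshold = threshold,
                 model_id = model_id),
            class = "causal_graph")
}

#' @export
print.causal_graph <- function(x, ...) {
  cat(sprintf("Causal graph%s: %d SGAs, %d hidden nodes, %d edges (threshold %.4g)\n",
              if (!is.na(x$model_id)) sprintf(" [model %s]", x$model_id) else "",
              length(x$sga_set), length(x$hidden_nodes), nrow(x$edges),
              x$threshold))
  invisible(x)
}

#' Ancestor SGAs of a node in a causal graph
#'
#' All SGAs with a directed path to the node, found by memoized
#' recursion over parent edges (the layered structure guarantees
#' termination).
#'
#' @param graph a [build_causal_graph()] object.
#' @param node a hidden-node or SGA id present in the graph.
#' @return character vector of ancestor SGA ids (sorted).
#' @export
ancestor_sgas <- function(graph, node) {
  known <- c(graph$hidden_nodes, graph$sga_set)
  if (!(node %in% known)) stop(sprintf("unknown node '%s'", node))
  memo <- new.env(parent = emptyenv())
  rec <- function(v) {
    if (v %in% graph$sga_set) return(v)
    if (!is.null(memo[[v]])) return(memo[[v]])
    parents <- graph$edges$from[graph$edges$to == v]
    anc <- sort(unique(unlist(lapply(parents, rec))))
    memo[[v]] <- anc %||% character()
    memo[[v]]
  }
  res <- rec(node)
  if (is.null(res)) character() else res
}

#' Label every hidden node by its ancestor SGA set
#'
#' @param graph a [build_causal_graph()] object.
#' @return named list: for each hidden node with a nonempty ancestor
#'   set, the sorted character vector of ancestor SGAs.
#' @export
label_hidden_nodes <- function(graph) {
  labels <- lapply(graph$hidden_nodes, function(v) ancestor_sgas(graph, v))
  names(labels) <- graph$hidden_nodes
  labels[vapply(labels, length, integer(1)) > 0L]
}

#' Hidden-node labels shared across models
#'
#' Given causal graphs for the same SGA set from several models, tabulates
#' every ancestor-label set that appears in any model together with the
#' models containing at least one hidden node carrying exactly that
#' label.
#'
#' @param graphs list of [build_causal_graph()] objects with identical
#'   \code{sga_set}.
#' @param pathway optional name recorded in the output.
#' @return data frame with columns \code{label} (comma-joined SGA set),
#'   \code{n_sga}, \code{n_models}, \code{models}.
#' @export
shared_nodes_across_models <- function(graphs, pathway = NA_character_) {
  if (length(graphs) < 2L) stop("need at least 2 graphs")
  sets <- lapply(graphs, function(g) sort(g$sga_set))
  if (!all(vapply(sets, identical, logical(1), sets[[1L]]))) {
    stop("graphs were built with different SGA sets")
  }
  per_model <- lapply(graphs, function(g) {
    unique(vapply(label_hidden_nodes(g), paste, character(1), collapse = ","))
  })
  labels <- sort(unique(unlist(per_model)))
  if (!length(labels)) {
    return(data.frame(pathway = character(), label = character(),
                      n_sga = integer(), n_models = integer(),
                      models = character()))
  }
  rows <- lapply(labels, function(lb) {
    inm <- which(vapply(per_model, function(p) lb %in% p, logical(1)))
    data.frame(pathway = pathway, label = lb,
               n_sga = length(strsplit(lb, ",", fixed = TRUE)[[1L]]),
               n_models = length(inm),
               models = paste(inm - 1L, collapse = ","),  # models numbered from 0
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$n_sga, -out$n_models, out$label), , drop = FALSE]
}

#' Random-SGA control for shared hidden-node counts
#'
#' Repeatedly draws a random SGA set of the pathway's size from a pool
#' disjoint from the evaluated pathway genes, builds the thresholded
#' causal graph for every model, and records, for each label
#' cardinality \code{n}, the maximum number of models sharing any
#' \code{n}-SGA label.  Reports mean and standard deviation over
#' replicates.
#'
#' @param models list of fitted [rinn()] models (or weight objects).
#' @param group_size size \emph{m} of the random SGA sets.
#' @param pool character vector of SGA ids to draw from.
#' @param target_edges per-model edge budget for thresholding.
#' @param replicates number of random draws.
#' @param seed integer seed.
#' @return data frame with columns \code{n}, \code{mean}, \code{sd} of
#'   the max-shared-model counts.
#' @export
random_label_control <- function(models, group_size, pool, target_edges = 300,
                                 replicates = 30, seed = 1L) {
  if (group_size > length(pool)) stop("'pool' is smaller than 'group_size'")
  counts <- with_seed(seed, {
    vapply(seq_len(replicates), function(r) {
      j <- sample(pool, group_size)
      per_model <- lapply(models, function(mod) {
        thr <- find_edge_threshold(mod, j, target_edges = target_edges)
        unique(vapply(label_hidden_nodes(
          build_causal_graph(mod, j, thr$threshold)),
          paste, character(1), collapse = ","))
      })
      vapply(seq_len(group_size), function(n) {
        labs <- unique(unlist(per_model))
        labs <- labs[vapply(strsplit(labs, ",", fixed = TRUE), length,
                            integer(1)) == n]
        if (!length(labs)) return(0L)
        max(vapply(labs, function(lb) {
          sum(vapply(per_model, function(p) lb %in% p, logical(1)))
        }, integer(1)))
      }, integer(1))
    }, integer(group_size))
  })
  counts <- matrix(counts, nrow = group_size)
  data.frame(n = seq_len(group_size),
             mean = apply(counts, 1L, mean),
             sd = apply(counts, 1L, stats::sd))
}

#' Score recovery of planted structure on synthetic data
#'
#' Measures how well a set of trained models recovers the pathway groups
#' planted in a synthetic ground-truth structure: (a) mean within-group
#' versus between-group signature cosine similarity; (b) per planted
#' group, the number of models whose thresholded causal graph contains a
#' hidden node labeled by the full group, and the fraction of groups
#' where at least half the models do; (c) the [random_label_control()]
#' for each group size.
#'
#' @param models list of fitted [rinn()] models trained on data from
#'   \code{truth}.
#' @param truth the [build_ground_truth()] object.
#' @param target_edges per-model edge budget for causal graphs.
#' @param control_replicates replicates for the random control (0 skips
#'   it).
#' @param seed integer seed for the control.
#' @return list of class \code{recovery_report}.
#' @export
score_recovery <- function(models, truth, target_edges = 30,
                           control_replicates = 30, seed = 1L) {
  stopifnot(inherits(truth, "rinn_dag"), length(models) >= 1L)
  groups <- truth$pathway_groups
  if (!length(groups)) stop("ground truth has no planted pathway groups")
  sga_ids <- truth$sga_ids
  bad <- vapply(models, function(m) {
    ids <- if (inherits(m, "rinn")) m$sga_ids else NULL
    !is.null(ids) && !identical(ids, sga_ids)
  }, logical(1))
  if (any(bad)) stop("model SGA ids do not match the ground truth")

  # (a) signature similarity within vs between planted groups
  sims <- lapply(models, function(m) cosine_similarity_matrix(extract_signatures(m)))
  grouped <- unlist(groups, use.names = FALSE)
  within <- c(); between <- c()
  for (s in sims) {
    for (g in groups) {
      pairs <- t(utils::combn(g, 2L))
      within <- c(within, s[pairs])
      # members of the other planted groups; for a single planted group,
      # fall back to all non-group SGAs
      other <- setdiff(grouped, g)
      if (!length(other)) other <- setdiff(sga_ids, g)
      between <- c(between, as.vector(s[g, other]))
    }
  }
  # (b) full planted label recovered per group
  shared <- lapply(names(groups), function(gn) {
    j <- groups[[gn]]
    full <- paste(sort(j), collapse = ",")
    n_with <- sum(vapply(models, function(mod) {
      thr <- find_edge_threshold(mod, j, target_edges = target_edges)
      labs <- vapply(label_hidden_nodes(build_causal_graph(mod, j, thr$threshold)),
                     paste, character(1), collapse = ",")
      full %in% labs
    }, logical(1)))
    list(group = gn, size = length(j), models_with_full_label = n_with)
  })
  n_models <- length(models)
  frac_recovered <- mean(vapply(shared, function(s) {
    s$models_with_full_label >= ceiling(n_models / 2)
  }, logical(1)))

  controls <- NULL
  if (control_replicates > 0L) {
    pool <- setdiff(sga_ids, grouped)
    controls <- lapply(unique(vapply(shared, `[[`, integer(1), "size")),
                       function(m) {
      ctl <- random_label_control(models, m, pool, target_edges = target_edges,
                                  replicates = control_replicates,
                                  seed = derive_seed(seed, m, 0L))
      ctl$group_size <- m
      ctl
    })
    controls <- do.call(rbind, controls)
  }
  structure(list(within_mean = mean(within), between_mean = mean(between),
                 gap = mean(within) - mean(between),
                 shared = shared, n_models = n_models,
                 frac_groups_recovered = frac_recovered,
                 control = controls, target_edges = target_edges),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Planted-structure recovery report\n")
  cat(sprintf("  signature cosine similarity: within %.3f, between %.3f (gap %.3f)\n",
              x$within_mean, x$between_mean, x$gap))
  for (s in x$shared) {
    cat(sprintf("  %s (size %d): full label in %d/%d models\n",
                s$group, s$size, s$models_with_full_label, x$n_models))
  }
  cat(sprintf("  groups recovered by >= half the models: %.0f%%\n",
              100 * x$frac_groups_recovered))
  if (!is.null(x$control)) {
    full <- x$control[x$control$n == x$control$group_size, , drop = FALSE]
    for (i in seq_len(nrow(full))) {
      cat(sprintf("  random control (m=%d, full label): %.2f +/- %.2f models\n",
                  full$group_size[i], full$mean[i], full$sd[i]))
    }
  }
  invisible(x)
}
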