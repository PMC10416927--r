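# Independent brute-force oracles used to validate the package's
# implementations on small instances.

# AUROC by exhaustive enumeration of positive-negative pairs.
brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# Average precision by explicit descending threshold sweep over the
# distinct score values (ties grouped at each threshold).
brute_ap <- function(scores, labels) {
  P <- sum(labels == 1)
  if (P == 0) return(NA_real_)
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0; prev_recall <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    recall <- tp / P
    precision <- tp / sum(sel)
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# Ancestor SGAs by exhaustive path enumeration over an edge data frame
# (columns from/to), with no memoization.
brute_ancestors <- function(edges, node, sga_ids) {
  anc <- character()
  walk <- function(v) {
    parents <- edges$from[edges$to == v]
    for (p in parents) {
      if (p %in% sga_ids) anc <<- c(anc, p) else walk(p)
    }
  }
  walk(node)
  sort(unique(anc))
}

# Small random layered DAG over SGA and hidden nodes, as an edge frame.
random_layered_edges <- function(n_sga, layer_sizes, p_edge = 0.4) {
  sga_ids <- sprintf("S%d", seq_len(n_sga))
  layers <- lapply(seq_along(layer_sizes), function(l) {
    sprintf("h%d_%d", l, seq_len(layer_sizes[l]))
  })
  edges <- list()
  for (l in seq_along(layers)) {
    for (s in sga_ids) for (h in layers[[l]]) {
      if (stats::runif(1) < p_edge / length(layer_sizes)) {
        edges[[length(edges) + 1L]] <- data.frame(from = s, to = h)
      }
    }
    if (l > 1L) {
      for (a in layers[[l - 1L]]) for (b in layers[[l]]) {
        if (stats::runif(1) < p_edge) {
          edges[[length(edges) + 1L]] <- data.frame(from = a, to = b)
        }
      }
    }
  }
  list(edges = if (length(edges)) do.call(rbind, edges)
               else data.frame(from = character(), to = character()),
       sga_ids = sga_ids, hidden = unlist(layers))
}

# Tiny paired dataset for smoke tests.
tiny_dataset <- function(n = 60, m = 6, p = 12, seed = 1) {
  dag <- build_ground_truth(n_sga = m, pathway_sizes = c(2), layer_sizes = c(3, 3),
                            n_deg = p, seed = seed)
  simulate_binary_dataset(dag, n, seed = seed + 1)
}

# Hand-built fold plan (bypasses the seeded constructor).
manual_plan <- function(fold, used) {
  structure(list(fold = fold, used = used, k = max(fold), seed = NA_integer_),
            class = "fold_plan")
}
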