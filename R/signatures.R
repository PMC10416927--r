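#' Extract SGA weight signatures from a trained network
#'
#' An SGA's weight signature is the concatenation of all weights running
#' from that SGA to hidden nodes: for an RINN, its row of \code{W1}
#' followed by its redundant-input rows of \code{W2}..\code{W8} (columns
#' ordered layer 1 to 8, then node index within the layer); for a DNN,
#' only its row of \code{W1}, as those are the only weights specific to
#' an individual input.
#'
#' @param weights an \code{rinn_weights} object, or a fitted [rinn()]
#'   model.
#' @param sga_ids optional row names.
#' @return numeric matrix, SGAs x hidden nodes, with columns named
#'   \code{h<layer>_<index>}; raw signed weights.
#' @export
extract_signatures <- function(weights, sga_ids = NULL) {
  if (inherits(weights, "rinn")) {
    sga_ids <- sga_ids %||% weights$sga_ids
    weights <- weights$weights
  }
  stopifnot(inherits(weights, "rinn_weights"))
  m <- weights$n_inputs
  h <- weights$hidden_sizes
  if (weights$architecture == "RINN") {
    blocks <- vector("list", 8L)
    blocks[[1L]] <- weights$W[[1L]]
    for (i in 2:8) {
      wi <- weights$W[[i]]
      blocks[[i]] <- wi[(nrow(wi) - m + 1L):nrow(wi), , drop = FALSE]
    }
    S <- do.call(cbind, blocks)
    colnames(S) <- unlist(lapply(seq_len(8L), function(l) {
      sprintf("h%d_%d", l, seq_len(h[l]))
    }))
  } else {
    S <- weights$W[[1L]]
    colnames(S) <- sprintf("h1_%d", seq_len(h[1L]))
  }
  rownames(S) <- sga_ids %||% sprintf("SGA%02d", seq_len(m))
  S
}

#' Cosine similarity between SGA weight signatures
#'
#' @param S signature matrix from [extract_signatures()].
#' @return symmetric matrix in [-1, 1] with unit diagonal for nonzero
#'   rows.  Rows with an all-zero signature get similarity 0 to
#'   everything (including themselves) and are listed in the
#'   \code{"zero_rows"} attribute.
#' @export
cosine_similarity_matrix <- function(S) {
  if (nrow(S) < 2L) stop("need at least 2 signature rows")
  nrm <- sqrt(rowSums(S^2))
  zero <- nrm == 0
  safe <- ifelse(zero, 1, nrm)
  C <- tcrossprod(S / safe)
  C[zero, ] <- 0; C[, zero] <- 0
  C <- pmin(pmax(C, -1), 1)
  diag(C)[!zero] <- 1
  dimnames(C) <- list(rownames(S), rownames(S))
  attr(C, "zero_rows") <- rownames(S)[zero] %||% which(zero)
  C
}

#' Table of each SGA's most similar SGAs
#'
#' For each query SGA, lists the \code{k} highest off-diagonal cosine
#' similarities (ties broken by descending similarity then ascending
#' gene name) and flags neighbors that share at least one pathway with
#' the query.  When a list of similarity matrices from several models is
#' supplied, per-pair similarities are first averaged over the models
#' (mean and standard deviation reported) and the top \code{k} are taken
#' on the mean.
#'
#' @param sim similarity matrix, or list of similarity matrices with
#'   identical dimnames.
#' @param k neighbors per query.
#' @param pathways optional [read_pathways()] table (columns
#'   \code{pathway}, \code{gene}) used for the same-pathway flag.
#' @return data frame with columns \code{query}, \code{rank},
#'   \code{neighbor}, \code{similarity}, \code{similarity_sd},
#'   \code{same_pathway}; the total flag count is attached as attribute
#'   \code{"n_same_pathway"}.
#' @export
top_k_table <- function(sim, k = 3, pathways = NULL) {
  if (is.list(sim)) {
    arr <- simplify2array(sim)
    sd_mat <- apply(arr, c(1L, 2L), stats::sd)
    sim_m <- apply(arr, c(1L, 2L), mean)
    zero <- Reduce(union, lapply(sim, attr, "zero_rows"))
  } else {
    sim_m <- sim
    sd_mat <- matrix(NA_real_, nrow(sim), ncol(sim))
    zero <- attr(sim, "zero_rows")
  }
  ids <- rownames(sim_m)
  if (k >= nrow(sim_m)) stop("'k' must be smaller than the number of SGAs")
  keep <- setdiff(ids, zero)
  share <- pathway_membership_fn(pathways)
  rows <- lapply(keep, function(q) {
    cand <- setdiff(keep, q)
    o <- order(-sim_m[q, cand], cand)
    nb <- cand[o][seq_len(k)]
    data.frame(query = q, rank = seq_len(k), neighbor = nb,
               similarity = sim_m[q, nb],
               similarity_sd = sd_mat[match(q, ids), match(nb, ids)],
               same_pathway = vapply(nb, share, logical(1), q = q),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_same_pathway") <- sum(out$same_pathway)
  out
}

# returns function(neighbor, q) -> do the two genes share >= 1 pathway
pathway_membership_fn <- function(pathways) {
  if (is.null(pathways)) return(function(nb, q) FALSE)
  split_pw <- split(pathways$pathway, pathways$gene)
  function(nb, q) {
    a <- split_pw[[q]]; b <- split_pw[[nb]]
    !is.null(a) && !is.null(b) && length(intersect(a, b)) > 0L
  }
}

#' Directed similarity graph over SGAs
#'
#' One edge from each SGA to each of its \code{k} most similar SGAs,
#' weighted by cosine similarity; mutual top-k pairs are marked
#' bidirected.
#'
#' @param sim similarity matrix.
#' @param k 1 or 3 (any positive count below the SGA number works).
#' @return an \pkg{igraph} directed graph with edge attributes
#'   \code{weight} and \code{bidirected} and vertex attribute
#'   \code{degree}.
#' @export
build_similarity_graph <- function(sim, k = 1) {
  tab <- top_k_table(sim, k = k)
  g <- igraph::graph_from_data_frame(
    data.frame(from = tab$query, to = tab$neighbor, weight = tab$similarity),
    directed = TRUE)
  el <- igraph::as_edgelist(g)
  keys <- paste(el[, 1L], el[, 2L]); rev_keys <- paste(el[, 2L], el[, 1L])
  igraph::E(g)$bidirected <- keys %in% intersect(keys, rev_keys) & rev_keys %in% keys
  igraph::V(g)$degree <- igraph::degree(g, mode = "all")
  g
}

#' Louvain community detection on the similarity graph
#'
#' Runs Louvain modularity maximization on the undirected weighted
#' projection of the similarity graph (edge weight = the larger of the
#' two directed weights).  Deterministic for a fixed seed.
#'
#' @param graph a [build_similarity_graph()] result.
#' @param resolution Louvain resolution parameter.
#' @param seed integer seed.
#' @return list with \code{membership} (named community id per SGA),
#'   \code{modularity}, and the undirected \code{graph} used.
#' @export
detect_communities <- function(graph, resolution = 1.0, seed = 1L) {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  und <- igraph::as_undirected(graph, mode = "collapse",
                               edge.attr.comb = list(weight = "max", "ignore"))
  # Louvain needs nonnegative weights; cosine similarities can dip below 0
  w <- pmax(igraph::E(und)$weight, 0)
  cl <- with_seed(seed, igraph::cluster_louvain(und, weights = w,
                                                resolution = resolution))
  membership <- igraph::membership(cl)
  list(membership = structure(as.integer(membership), names = names(membership)),
       modularity = igraph::modularity(und, membership, weights = w),
       graph = und)
}

#' Hierarchical clustering of SGA weight signatures
#'
#' Agglomerative clustering with distance one-minus-cosine-similarity and
#' average linkage, as used to order signature heatmaps.
#'
#' @param S signature matrix.
#' @param k optional number of flat clusters to cut.
#' @return list with the \code{hclust} tree, the leaf \code{order}
#'   (heatmap-ready), and \code{clusters} (when \code{k} given).
#' @export
cluster_signatures <- function(S, k = NULL) {
  if (nrow(S) < 2L) stop("need at least 2 signature rows")
  d <- stats::as.dist(1 - cosine_similarity_matrix(S))
  hc <- stats::hclust(d, method = "average")
  out <- list(hclust = hc, order = hc$order,
              labels = rownames(S)[hc$order])
  if (!is.null(k)) out$clusters <- stats::cutree(hc, k = k)
  out
}
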