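#' Build a ground-truth layered causal structure
#'
#' Constructs a random layered DAG in which binary somatic genomic
#' alterations (SGAs) act on latent "signaling" nodes arranged in
#' successive layers, and the deepest latent layer drives binary
#' differential-expression (DEG) outputs.  Groups of SGAs designated as
#' pathways attach to a shared latent node in the first layer, emulating
#' drivers that perturb a common signaling protein; remaining SGAs attach
#' to latent nodes uniformly at random.  Edges only run from lower to
#' strictly higher layers, so the structure is acyclic by construction.
#'
#' @param n_sga number of SGA input variables.
#' @param pathway_sizes integer vector; sizes of the planted pathway
#'   groups.  Their sum must not exceed \code{n_sga}.
#' @param layer_sizes integer vector (length 1--8); sizes of the latent
#'   layers.
#' @param n_deg number of DEG output variables.
#' @param edge_density probability in (0, 1] that any admissible
#'   latent-to-latent or latent-to-DEG edge is present (connectivity is
#'   repaired afterwards so every latent node lies on an SGA-to-DEG path).
#' @param weight_range length-2 numeric; absolute edge weights are drawn
#'   uniformly from this interval.
#' @param pathway_weight_range length-2 numeric; absolute weights of the
#'   pathway-to-shared-node attachments.  Defaults to twice
#'   \code{weight_range}: planted pathway effects are deliberately strong
#'   so that the shared signal is identifiable at desk scale.
#' @param pathway_private_rate probability that a pathway member also
#'   receives a private attachment deeper in the hierarchy; defaults to
#'   \code{edge_density}.  Zero makes members act purely through their
#'   shared node.
#' @param seed integer seed; the construction is deterministic given the
#'   seed.
#' @return An object of class \code{rinn_dag} with components
#'   \code{sga_weights} (per-layer SGA attachment matrices),
#'   \code{latent_weights} (between consecutive latent layers),
#'   \code{deg_weights}, \code{pathway_groups} (named list of SGA ids) and
#'   \code{shared_targets} (the latent node shared by each group).
#' @seealso [simulate_binary_dataset()] to draw data through the structure.
#' @export
build_ground_truth <- function(n_sga, pathway_sizes = integer(), layer_sizes,
                               n_deg, edge_density = 0.3,
                               weight_range = c(0.5, 2),
                               pathway_weight_range = 2 * weight_range,
                               pathway_private_rate = edge_density,
                               seed = 1L) {
  stopifnot(n_sga >= 1, n_deg >= 1)
  layer_sizes <- as.integer(layer_sizes)
  if (!length(layer_sizes) || any(layer_sizes < 1L)) {
    stop("'layer_sizes' must be a non-empty vector of positive counts")
  }
  if (length(layer_sizes) > 8L) stop("at most 8 latent layers are supported")
  pathway_sizes <- as.integer(pathway_sizes)
  if (any(pathway_sizes < 1L)) stop("pathway sizes must be positive")
  if (sum(pathway_sizes) > n_sga) stop("sum(pathway_sizes) exceeds n_sga")
  if (length(pathway_sizes) > layer_sizes[1L]) {
    stop("more pathway groups than first-layer latent nodes")
  }
  if (!(edge_density > 0 && edge_density <= 1)) {
    stop("'edge_density' must lie in (0, 1]")
  }
  stopifnot(length(weight_range) == 2L, all(weight_range > 0),
            weight_range[1L] <= weight_range[2L])
  stopifnot(length(pathway_weight_range) == 2L, all(pathway_weight_range > 0),
            pathway_weight_range[1L] <= pathway_weight_range[2L])

  L <- length(layer_sizes)
  sga_ids <- sprintf("SGA%02d", seq_len(n_sga))
  deg_ids <- sprintf("DEG%03d", seq_len(n_deg))

  with_seed(seed, {
    rw <- function(n) {  # signed weight magnitudes, mostly activating
      mag <- stats::runif(n, weight_range[1L], weight_range[2L])
      mag * ifelse(stats::runif(n) < 0.8, 1, -1)
    }
    pos <- function(n) stats::runif(n, pathway_weight_range[1L], pathway_weight_range[2L])

    sga_w <- lapply(layer_sizes, function(h) {
      matrix(0, n_sga, h, dimnames = list(sga_ids, NULL))
    })

    # Pathway groups: consecutive blocks of SGA indices, each attached with
    # positive weights to its own shared first-layer node.
    groups <- list(); shared <- character()
    if (length(pathway_sizes)) {
      stops <- cumsum(pathway_sizes)
      starts <- c(1L, head(stops, -1L) + 1L)
      for (g in seq_along(pathway_sizes)) {
        members <- starts[g]:stops[g]
        groups[[sprintf("PW%d", g)]] <- sga_ids[members]
        sga_w[[1L]][members, g] <- pos(length(members))
        shared[sprintf("PW%d", g)] <- sprintf("L1_%d", g)
        # optional private attachments deeper in the hierarchy
        for (m in members) {
          if (stats::runif(1) < pathway_private_rate && L >= 2L) {
            l <- sample(2:L, 1L)
            sga_w[[l]][m, sample.int(layer_sizes[l], 1L)] <- rw(1)
          }
        }
      }
    }

    # Non-pathway SGAs: one attachment uniformly at random over all latent
    # nodes, plus extras at rate edge_density.
    free <- setdiff(seq_len(n_sga), unlist(lapply(groups, match, sga_ids)))
    node_layer <- rep(seq_len(L), layer_sizes)
    node_index <- unlist(lapply(layer_sizes, seq_len))
    for (m in free) {
      n_att <- 1L + stats::rbinom(1L, 2L, edge_density)
      pick <- sample.int(length(node_layer), n_att)
      for (p in pick) sga_w[[node_layer[p]]][m, node_index[p]] <- rw(1)
    }

    # Latent-to-latent edges between consecutive layers.
    lat_w <- NULL
    if (L >= 2L) {
      lat_w <- lapply(seq_len(L - 1L), function(l) {
        w <- matrix(0, layer_sizes[l], layer_sizes[l + 1L])
        on <- stats::runif(length(w)) < edge_density
        w[on] <- rw(sum(on))
        w
      })
      # every node in layer l+1 needs an upstream edge or an SGA attachment;
      # every node in layer l needs a downstream edge
      for (l in seq_len(L - 1L)) {
        for (j in seq_len(layer_sizes[l + 1L])) {
          if (all(lat_w[[l]][, j] == 0) && all(sga_w[[l + 1L]][, j] == 0)) {
            lat_w[[l]][sample.int(layer_sizes[l], 1L), j] <- rw(1)
          }
        }
        for (i in seq_len(layer_sizes[l])) {
          if (all(lat_w[[l]][i, ] == 0)) {
            lat_w[[l]][i, sample.int(layer_sizes[l + 1L], 1L)] <- rw(1)
          }
        }
      }
    }

    # every first-layer node needs an SGA parent
    for (j in seq_len(layer_sizes[1L])) {
      if (all(sga_w[[1L]][, j] == 0)) {
        sga_w[[1L]][sample.int(n_sga, 1L), j] <- rw(1)
      }
    }

    # DEG attachments from the deepest layer; every DEG needs a parent and
    # every deep node a child.
    deg_w <- matrix(0, layer_sizes[L], n_deg, dimnames = list(NULL, deg_ids))
    on <- stats::runif(length(deg_w)) < edge_density
    deg_w[on] <- rw(sum(on))
    for (j in seq_len(n_deg)) {
      if (all(deg_w[, j] == 0)) deg_w[sample.int(layer_sizes[L], 1L), j] <- rw(1)
    }
    for (i in seq_len(layer_sizes[L])) {
      if (all(deg_w[i, ] == 0)) deg_w[i, sample.int(n_deg, 1L)] <- rw(1)
    }

    structure(list(layer_sizes = layer_sizes, n_sga = n_sga, n_deg = n_deg,
                   sga_weights = sga_w, latent_weights = lat_w,
                   deg_weights = deg_w, pathway_groups = groups,
                   shared_targets = shared, sga_ids = sga_ids,
                   deg_ids = deg_ids, seed = as.integer(seed)),
              class = "rinn_dag")
  })
}

#' @export
print.rinn_dag <- function(x, ...) {
  cat("Ground-truth layered causal structure\n")
  cat(sprintf("  SGAs: %d  latent layers: %s  DEGs: %d\n",
              x$n_sga, paste(x$layer_sizes, collapse = "-"), x$n_deg))
  if (length(x$pathway_groups)) {
    for (g in names(x$pathway_groups)) {
      cat(sprintf("  %s (shared node %s): %s\n", g, x$shared_targets[[g]],
                  paste(x$pathway_groups[[g]], collapse = ", ")))
    }
  }
  invisible(x)
}

# Deterministic signal propagation through the DAG: tanh squashing at
# latent nodes, raw linear combination at the DEG layer.
propagate_dag <- function(dag, X) {
  L <- length(dag$layer_sizes)
  H <- tanh(X %*% dag$sga_weights[[1L]])
  if (L >= 2L) {
    for (l in 2:L) {
      H <- tanh(H %*% dag$latent_weights[[l - 1L]] + X %*% dag$sga_weights[[l]])
    }
  }
  H %*% dag$deg_weights
}

#' Simulate a paired binary SGA/DEG dataset from a ground-truth structure
#'
#' SGA entries are iid Bernoulli; each sample's signal is propagated
#' through the signed, tanh-squashed layered structure, thresholded at
#' zero to give noise-free DEG calls, and finally each call is flipped
#' independently with probability \code{flip_noise}.
#'
#' @param dag a [build_ground_truth()] object.
#' @param n_samples number of tumors to simulate.
#' @param sga_prevalence per-entry probability that an SGA is present.
#' @param flip_noise per-entry probability in [0, 0.5) that a DEG call is
#'   flipped after thresholding.
#' @param seed integer seed.
#' @return An object of class \code{rinn_data}: a list with binary integer
#'   matrices \code{sga} (samples x SGAs) and \code{deg} (samples x DEGs),
#'   carrying sample and gene identifiers as dimnames.
#' @export
simulate_binary_dataset <- function(dag, n_samples, sga_prevalence = 0.1,
                                    flip_noise = 0.05, seed = 1L) {
  stopifnot(inherits(dag, "rinn_dag"))
  if (n_samples < 1L) stop("'n_samples' must be positive")
  if (!(sga_prevalence > 0 && sga_prevalence < 1)) {
    stop("'sga_prevalence' must lie in (0, 1)")
  }
  if (!(flip_noise >= 0 && flip_noise < 0.5)) {
    stop("'flip_noise' must lie in [0, 0.5)")
  }
  with_seed(seed, {
    X <- matrix(stats::rbinom(n_samples * dag$n_sga, 1L, sga_prevalence),
                n_samples, dag$n_sga)
    signal <- propagate_dag(dag, X)
    Y <- (signal > 0) + 0L
    if (flip_noise > 0) {
      flips <- matrix(stats::rbinom(length(Y), 1L, flip_noise), nrow(Y))
      Y <- (Y + flips) %% 2L
    }
    rinn_data(X, Y,
              sample_ids = sprintf("S%04d", seq_len(n_samples)),
              sga_ids = dag$sga_ids, deg_ids = dag$deg_ids)
  })
}

#' Construct a paired SGA/DEG dataset object
#'
#' @param sga,deg binary matrices with equal row counts (samples).
#' @param sample_ids,sga_ids,deg_ids identifier vectors; taken from the
#'   matrices' dimnames when omitted.
#' @return An object of class \code{rinn_data}.
#' @export
rinn_data <- function(sga, deg, sample_ids = NULL, sga_ids = NULL,
                      deg_ids = NULL) {
  sga <- as.matrix(sga); deg <- as.matrix(deg)
  check_binary_matrix(sga, "sga"); check_binary_matrix(deg, "deg")
  if (nrow(sga) != nrow(deg)) stop("'sga' and 'deg' must have equal row counts")
  sample_ids <- sample_ids %||% rownames(sga) %||% sprintf("S%04d", seq_len(nrow(sga)))
  sga_ids <- sga_ids %||% colnames(sga) %||% sprintf("SGA%02d", seq_len(ncol(sga)))
  deg_ids <- deg_ids %||% colnames(deg) %||% sprintf("DEG%03d", seq_len(ncol(deg)))
  for (ids in list(sample_ids, sga_ids, deg_ids)) {
    if (anyDuplicated(ids)) stop("identifiers must be unique")
  }
  storage.mode(sga) <- "integer"; storage.mode(deg) <- "integer"
  dimnames(sga) <- list(sample_ids, sga_ids)
  dimnames(deg) <- list(sample_ids, deg_ids)
  structure(list(sga = sga, deg = deg), class = "rinn_data")
}

#' @export
print.rinn_data <- function(x, ...) {
  cat(sprintf("Paired binary dataset: %d samples, %d SGAs (prevalence %.3f), %d DEGs (prevalence %.3f)\n",
              nrow(x$sga), ncol(x$sga), mean(x$sga), ncol(x$deg), mean(x$deg)))
  invisible(x)
}

#' @export
dim.rinn_data <- function(x) c(nrow(x$sga), ncol(x$sga), ncol(x$deg))

#' Binarize a tumor expression profile against matched normals
#'
#' A gene is called differentially expressed in a tumor when its value
#' falls outside the central quantile band of that gene's distribution
#' across normal samples (by default, beyond the 2.5\% tail on either
#' side).  Quantiles use linear interpolation between order statistics
#' (\code{stats::quantile} type 7).
#'
#' @param tumor_values numeric vector of one tumor's per-gene expression.
#' @param normal_values numeric matrix, normal samples x genes.
#' @param tail tail mass in (0, 0.5) excluded on each side; default 0.025.
#' @return integer vector of 0/1 DEG calls, one per gene.
#' @export
binarize_deg_profile <- function(tumor_values, normal_values, tail = 0.025) {
  if (!(tail > 0 && tail < 0.5)) stop("'tail' must lie in (0, 0.5)")
  normal_values <- as.matrix(normal_values)
  if (nrow(normal_values) < 2L) stop("need at least 2 normal samples per gene")
  if (length(tumor_values) != ncol(normal_values)) {
    stop("'tumor_values' length must equal the number of genes in 'normal_values'")
  }
  lo <- apply(normal_values, 2L, stats::quantile, probs = tail, type = 7, names = FALSE)
  hi <- apply(normal_values, 2L, stats::quantile, probs = 1 - tail, type = 7, names = FALSE)
  as.integer(tumor_values < lo | tumor_values > hi)
}

#' Combine mutation and copy-number calls into one SGA matrix
#'
#' A gene is called altered in a tumor when it carries a non-synonymous
#' mutation/indel or a somatic copy-number alteration: the elementwise
#' logical OR of the two binary indicator matrices.
#'
#' @param mutation,cnv binary matrices of identical shape and dimnames.
#' @return binary integer matrix of SGA calls.
#' @export
combine_alteration_calls <- function(mutation, cnv) {
  mutation <- as.matrix(mutation); cnv <- as.matrix(cnv)
  if (!identical(dim(mutation), dim(cnv))) stop("shape mismatch between 'mutation' and 'cnv'")
  if (!identical(dimnames(mutation), dimnames(cnv))) {
    stop("identifier mismatch between 'mutation' and 'cnv'")
  }
  check_binary_matrix(mutation, "mutation"); check_binary_matrix(cnv, "cnv")
  out <- (mutation | cnv) + 0L
  dimnames(out) <- dimnames(mutation)
  out
}
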