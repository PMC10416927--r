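#' Read and write paired SGA/DEG datasets
#'
#' Two on-disk encodings are supported.  \code{"tsv"}: one tab-separated
#' file per matrix with a header row of gene ids and the sample id in the
#' first column.  \code{"mtx"}: MatrixMarket sparse files with two
#' plain-text identifier sidecars (\code{*_rows.txt}, \code{*_cols.txt})
#' each.  Values are validated as binary on read, with the offending row
#' and column named otherwise.
#'
#' @param data an [rinn_data()] object.
#' @param dir directory to write into (created if needed).
#' @param format \code{"tsv"} or \code{"mtx"}.
#' @param prefix file-name prefix.
#' @return \code{write_rinn_data} returns the directory invisibly;
#'   \code{read_rinn_data} returns an \code{rinn_data} object.
#' @export
write_rinn_data <- function(data, dir, format = c("tsv", "mtx"),
                            prefix = "dataset") {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (part in c("sga", "deg")) {
    M <- data[[part]]
    base <- file.path(dir, paste0(prefix, "_", part))
    if (format == "tsv") {
      df <- data.frame(sample_id = rownames(M), M, check.names = FALSE)
      utils::write.table(df, paste0(base, ".tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    } else {
      Matrix::writeMM(Matrix::Matrix(M * 1, sparse = TRUE), paste0(base, ".mtx"))
      writeLines(rownames(M), paste0(base, "_rows.txt"))
      writeLines(colnames(M), paste0(base, "_cols.txt"))
    }
  }
  invisible(dir)
}

#' @rdname write_rinn_data
#' @export
read_rinn_data <- function(dir, format = c("tsv", "mtx"), prefix = "dataset") {
  format <- match.arg(format)
  read_part <- function(part) {
    base <- file.path(dir, paste0(prefix, "_", part))
    if (format == "tsv") {
      path <- paste0(base, ".tsv")
      if (!file.exists(path)) stop(sprintf("missing file '%s'", path))
      df <- utils::read.table(path, sep = "\t", header = TRUE,
                              check.names = FALSE, colClasses = NA)
      M <- as.matrix(df[, -1L, drop = FALSE])
      rownames(M) <- df[[1L]]
    } else {
      path <- paste0(base, ".mtx")
      if (!file.exists(path)) stop(sprintf("missing file '%s'", path))
      M <- as.matrix(Matrix::readMM(path))
      rownames(M) <- readLines(paste0(base, "_rows.txt"))
      colnames(M) <- readLines(paste0(base, "_cols.txt"))
    }
    bad <- which(!(M %in% c(0, 1)))
    if (length(bad)) {
      i <- arrayInd(bad[1L], dim(M))
      stop(sprintf("non-binary entry in '%s' at sample '%s', gene '%s'",
                   part, rownames(M)[i[1L]], colnames(M)[i[2L]]))
    }
    storage.mode(M) <- "integer"
    M
  }
  sga <- read_part("sga"); deg <- read_part("deg")
  rinn_data(sga, deg)
}

#' Read the packaged cancer-pathway membership table
#'
#' A two-column TSV mapping nine named signaling pathways to their member
#' genes (35 distinct genes; CDKN2A belongs to both the p53 and
#' Cell-cycle pathways).  This is the silver-standard table used to flag
#' same-pathway similarity neighbors and to choose the SGA sets of causal
#' graphs.
#'
#' @param path optional path to an alternative two-column TSV.
#' @return data frame with columns \code{pathway} and \code{gene}.
#' @export
read_pathways <- function(path = NULL) {
  path <- path %||% system.file("extdata", "cancer_pathways.tsv",
                                package = "rinn", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("pathway", "gene") %in% names(df))) {
    stop("pathway table needs columns 'pathway' and 'gene'")
  }
  df
}

#' Export a ground-truth structure as JSON
#'
#' Latent nodes are named \code{L<layer>_<index>}; edges are written as
#' explicit from/to/weight records.
#'
#' @param dag a [build_ground_truth()] object.
#' @param path output file.
#' @export
write_dag_json <- function(dag, path) {
  nm <- function(l, i) sprintf("L%d_%d", l, i)
  edges <- list()
  add <- function(from, to, w) {
    edges[[length(edges) + 1L]] <<- list(from = from, to = to, weight = w)
  }
  for (l in seq_along(dag$sga_weights)) {
    w <- dag$sga_weights[[l]]
    nz <- which(w != 0, arr.ind = TRUE)
    for (r in seq_len(nrow(nz))) {
      add(dag$sga_ids[nz[r, 1L]], nm(l, nz[r, 2L]), w[nz[r, , drop = FALSE]])
    }
  }
  for (l in seq_along(dag$latent_weights)) {
    w <- dag$latent_weights[[l]]
    nz <- which(w != 0, arr.ind = TRUE)
    for (r in seq_len(nrow(nz))) {
      add(nm(l, nz[r, 1L]), nm(l + 1L, nz[r, 2L]), w[nz[r, , drop = FALSE]])
    }
  }
  w <- dag$deg_weights
  nz <- which(w != 0, arr.ind = TRUE)
  L <- length(dag$layer_sizes)
  for (r in seq_len(nrow(nz))) {
    add(nm(L, nz[r, 1L]), dag$deg_ids[nz[r, 2L]], w[nz[r, , drop = FALSE]])
  }
  jsonlite::write_json(
    list(layer_sizes = dag$layer_sizes,
         sga_ids = dag$sga_ids, deg_ids = dag$deg_ids,
         pathway_groups = dag$pathway_groups,
         shared_targets = as.list(dag$shared_targets),
         edges = edges),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Archive trained weights as portable text
#'
#' Writes one TSV per weight matrix plus a JSON manifest (architecture,
#' activation, layer sizes, biases, training history and seed), and reads
#' the archive back.
#'
#' @param fit a fitted [rinn()] model or \code{rinn_weights} object.
#' @param dir archive directory.
#' @export
write_weights <- function(fit, dir) {
  w <- if (inherits(fit, "rinn")) fit$weights else fit
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(w$W)) {
    utils::write.table(w$W[[i]], file.path(dir, sprintf("W%d.tsv", i)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  manifest <- list(architecture = w$architecture, activation = w$activation,
                   n_inputs = w$n_inputs, n_outputs = w$n_outputs,
                   hidden_sizes = w$hidden_sizes,
                   biases = lapply(w$b, as.numeric),
                   n_matrices = length(w$W))
  if (inherits(fit, "rinn")) {
    manifest$hp <- unclass(fit$hp)
    manifest$seed <- fit$seed
    manifest$history <- fit$history
    manifest$sga_ids <- fit$sga_ids
    manifest$deg_ids <- fit$deg_ids
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_weights
#' @export
read_weights <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  W <- lapply(seq_len(manifest$n_matrices), function(i) {
    as.matrix(utils::read.table(file.path(dir, sprintf("W%d.tsv", i)),
                                sep = "\t", header = FALSE))
  })
  W <- lapply(W, function(m) { dimnames(m) <- NULL; m })
  b <- manifest$biases
  if (is.matrix(b)) b <- lapply(seq_len(nrow(b)), function(i) b[i, ])
  structure(list(architecture = manifest$architecture,
                 activation = manifest$activation, W = W, b = b,
                 n_inputs = as.integer(manifest$n_inputs),
                 n_outputs = as.integer(manifest$n_outputs),
                 hidden_sizes = as.integer(manifest$hidden_sizes)),
            class = "rinn_weights")
}

#' Export a causal or similarity graph
#'
#' Writes GraphML and/or DOT via \pkg{igraph}.  Causal graphs carry node
#' attributes \code{kind} (sga/hidden), \code{layer} and \code{label}
#' (comma-joined ancestor set) and edge attributes \code{weight} and
#' \code{abs_weight}.
#'
#' @param graph a \code{causal_graph} or an \pkg{igraph} object.
#' @param path output file; the extension picks the format
#'   (\code{.graphml} or \code{.dot}/\code{.gv}).
#' @export
write_graph_file <- function(graph, path) {
  if (inherits(graph, "causal_graph")) graph <- as_igraph(graph)
  fmt <- if (grepl("\\.graphml$", path)) "graphml" else "dot"
  igraph::write_graph(graph, path, format = fmt)
  invisible(path)
}

#' Convert a causal graph to an igraph object
#'
#' @param graph a [build_causal_graph()] object.
#' @return a directed \pkg{igraph} graph.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "causal_graph"))
  used_sgas <- unique(graph$edges$from[graph$edges$type == "sga"])
  verts <- data.frame(
    name = c(used_sgas, graph$hidden_nodes),
    kind = c(rep("sga", length(used_sgas)),
             rep("hidden", length(graph$hidden_nodes))),
    stringsAsFactors = FALSE)
  verts$layer <- 0L
  hid <- verts$kind == "hidden"
  verts$layer[hid] <- as.integer(sub("^h(\\d+)_.*$", "\\1", verts$name[hid]))
  labels <- label_hidden_nodes(graph)
  verts$label <- vapply(verts$name, function(v) {
    if (!is.null(labels[[v]])) paste(labels[[v]], collapse = ",") else v
  }, character(1))
  g <- igraph::graph_from_data_frame(
    data.frame(from = graph$edges$from, to = graph$edges$to,
               weight = graph$edges$weight, abs_weight = graph$edges$abs_w),
    directed = TRUE, vertices = verts)
  g
}

#' Export a signature dendrogram as Newick
#'
#' @param clust a [cluster_signatures()] result (or \code{hclust}).
#' @param path output file.
#' @export
write_dendrogram <- function(clust, path) {
  hc <- if (inherits(clust, "hclust")) clust else clust$hclust
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Export a per-DEG AUROC histogram as TSV
#'
#' Bins the per-output AUROC values of a metric bundle into fixed-width
#' bins and writes bin edges and counts, for histogram-style comparison
#' of models and baselines.
#'
#' @param bundle a [metric_bundle()] (or numeric vector of AUROCs).
#' @param path output TSV.
#' @param breaks histogram breaks over [0, 1].
#' @export
write_auroc_histogram <- function(bundle, path, breaks = seq(0, 1, by = 0.05)) {
  v <- if (is.numeric(bundle)) bundle else bundle$auroc_per_deg
  h <- graphics::hist(v[is.finite(v)], breaks = breaks, plot = FALSE)
  utils::write.table(data.frame(bin_lo = utils::head(h$breaks, -1L),
                                bin_hi = h$breaks[-1L], count = h$counts),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
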