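test_that("RINN signatures concatenate the input rows of all eight layers", {
  w <- init_network("RINN", 3, 4, rinn_hp(hidden_sizes = 2), seed = 1)
  S <- extract_signatures(w, sga_ids = c("A", "B", "C"))
  expect_identical(dim(S), c(3L, 16L))
  expect_identical(colnames(S)[1:2], c("h1_1", "h1_2"))
  expect_identical(colnames(S)[15:16], c("h8_1", "h8_2"))
  # manual concatenation for SGA 2: row 2 of W1, then redundant row of W2..W8
  manual <- c(w$W[[1]][2, ],
              unlist(lapply(2:8, function(i) w$W[[i]][nrow(w$W[[i]]) - 3 + 2, ])))
  expect_equal(unname(S[2, ]), unname(manual))
})

test_that("DNN signatures use only the first weight matrix", {
  w <- init_network("DNN", 4, 3, rinn_hp(hidden_sizes = c(50, 10),
                                         architecture = "DNN"), seed = 2)
  S <- extract_signatures(w)
  expect_identical(dim(S), c(4L, 50L))
  expect_equal(unname(S), unname(w$W[[1]]))
})

test_that("cosine similarity has unit diagonal, symmetry and known values", {
  S <- rbind(a = c(1, 0, 1), b = c(1, 1, 0), c = c(2, 0, 2), z = c(0, 0, 0))
  C <- cosine_similarity_matrix(S)
  expect_equal(C["a", "b"], 0.5)
  expect_equal(C["a", "c"], 1)      # scale invariance of a duplicate direction
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)[1:3]), rep(1, 3))
  expect_true(all(C["z", ] == 0))   # zero signature flagged, similarity 0
  expect_identical(attr(C, "zero_rows"), "z")
  expect_true(all(abs(C) <= 1 + 1e-12))
})

test_that("similarity is invariant to positive rescaling of signature rows", {
  withr::with_seed(3, {
    S <- matrix(rnorm(40), 5, 8, dimnames = list(letters[1:5], NULL))
    C1 <- cosine_similarity_matrix(S)
    S2 <- S * matrix(runif(5, 0.1, 10), 5, 8)
    expect_equal(cosine_similarity_matrix(S2), C1, tolerance = 1e-12)
  })
})

test_that("top-k neighbor tables match an exhaustive sort", {
  withr::with_seed(4, {
    S <- matrix(rnorm(48), 6, 8,
                dimnames = list(paste0("G", 1:6), NULL))
    C <- cosine_similarity_matrix(S)
    tab <- top_k_table(C, k = 3)
    for (q in rownames(C)) {
      cand <- setdiff(rownames(C), q)
      best <- cand[order(-C[q, cand], cand)][1:3]
      expect_identical(tab$neighbor[tab$query == q], best)
    }
  })
  # 2 SGAs are each other's single neighbor
  S2 <- rbind(x = c(1, 0), y = c(1, 1))
  t2 <- top_k_table(cosine_similarity_matrix(S2), k = 1)
  expect_identical(t2$neighbor, c("y", "x"))
})

test_that("pathway flags mark shared membership and count the bold entries", {
  pw <- data.frame(pathway = c("P1", "P1", "P2"), gene = c("A", "B", "C"))
  S <- rbind(A = c(1, 0.9, 0), B = c(1, 1, 0), C = c(0, 0.1, 1))
  tab <- top_k_table(cosine_similarity_matrix(S), k = 1, pathways = pw)
  expect_true(tab$same_pathway[tab$query == "A"])   # A's top neighbor is B
  expect_false(tab$same_pathway[tab$query == "C"])
  expect_identical(attr(tab, "n_same_pathway"), sum(tab$same_pathway))
  # query not in any pathway never flags
  pw2 <- data.frame(pathway = "P9", gene = "ZZZ")
  tab2 <- top_k_table(cosine_similarity_matrix(S), k = 2, pathways = pw2)
  expect_false(any(tab2$same_pathway))
})

test_that("aggregated neighbor tables average similarities across models", {
  S1 <- rbind(A = c(1, 0), B = c(1, 0.2), C = c(0, 1))
  S2 <- rbind(A = c(1, 0.1), B = c(1, 0), C = c(0.1, 1))
  sims <- list(cosine_similarity_matrix(S1), cosine_similarity_matrix(S2))
  tab <- top_k_table(sims, k = 1)
  mean_ab <- mean(c(sims[[1]]["A", "B"], sims[[2]]["A", "B"]))
  expect_equal(tab$similarity[tab$query == "A"], mean_ab)
  expect_equal(tab$similarity_sd[tab$query == "A"],
               sd(c(sims[[1]]["A", "B"], sims[[2]]["A", "B"])))
})

test_that("similarity graphs have one edge per query per k with mutual marking", {
  withr::with_seed(5, {
    S <- matrix(rnorm(80), 10, 8, dimnames = list(paste0("G", 1:10), NULL))
    C <- cosine_similarity_matrix(S)
    g1 <- build_similarity_graph(C, k = 1)
    expect_equal(igraph::ecount(g1), 10L)
    g3 <- build_similarity_graph(C, k = 3)
    expect_equal(igraph::ecount(g3), 30L)
  })
  S2 <- rbind(x = c(1, 0), y = c(1, 0.2))
  g <- build_similarity_graph(cosine_similarity_matrix(S2), k = 1)
  expect_true(all(igraph::E(g)$bidirected))
})

test_that("community detection separates disconnected cliques deterministically", {
  # two disconnected triangles embedded as block-structured signatures
  S <- rbind(a1 = c(1, 0.9, 0.8, 0, 0, 0), a2 = c(0.9, 1, 0.7, 0, 0, 0),
             a3 = c(0.8, 0.9, 1, 0, 0, 0), b1 = c(0, 0, 0, 1, 0.9, 0.8),
             b2 = c(0, 0, 0, 0.9, 1, 0.7), b3 = c(0, 0, 0, 0.8, 0.9, 1))
  g <- build_similarity_graph(cosine_similarity_matrix(S), k = 2)
  com <- detect_communities(g, seed = 1)
  expect_equal(length(unique(com$membership)), 2L)
  expect_length(unique(com$membership[c("a1", "a2", "a3")]), 1L)
  expect_length(unique(com$membership[c("b1", "b2", "b3")]), 1L)
  expect_gt(com$modularity, 0.3)
  # permuting node order relabels but does not change the partition
  perm <- c(4, 1, 5, 2, 6, 3)
  com2 <- detect_communities(
    build_similarity_graph(cosine_similarity_matrix(S[perm, ]), k = 2), seed = 1)
  tab <- table(com$membership[names(com2$membership)], com2$membership)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("hierarchical clustering of signatures uses 1 - cosine with average linkage", {
  S <- rbind(a = c(1, 0), a2 = c(2, 0), b = c(0, 1), b2 = c(0, 3))
  cl <- cluster_signatures(S, k = 2)
  # duplicates (same direction) merge at height 0
  expect_equal(min(cl$hclust$height), 0)
  # orthogonal groups merge last at height 1
  expect_equal(max(cl$hclust$height), 1)
  expect_identical(cl$clusters[["a"]], cl$clusters[["a2"]])
  expect_false(cl$clusters[["a"]] == cl$clusters[["b"]])
  # three-point fixture traced by hand: d(a,b)=0, then average linkage to c
  S3 <- rbind(a = c(1, 0), b = c(1, 0), c = c(1, 1))
  hc <- cluster_signatures(S3)$hclust
  d_ac <- 1 - cosine_similarity_matrix(S3)["a", "c"]
  expect_equal(sort(hc$height), sort(c(0, d_ac)), tolerance = 1e-12)
  # dendrogram exports as Newick
  tmp <- tempfile(fileext = ".nwk")
  write_dendrogram(cluster_signatures(S), tmp)
  expect_match(readLines(tmp), "^\\(")
})
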