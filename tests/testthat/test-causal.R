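toy_weights <- function(m = 2, h = 2, p = 2, seed = 1) {
  w <- init_network("RINN", m, p, rinn_hp(hidden_sizes = h), seed = seed)
  w$W <- lapply(w$W, function(x) x * 0)
  w
}

test_that("candidate edges enumerate SGA-origin and hidden-hidden weights only", {
  w <- toy_weights(m = 1, h = 2)
  cand <- candidate_edges(w, "SGA01")
  # 2 nodes per layer x 8 layers of SGA-origin candidates
  expect_equal(sum(cand$type == "sga"), 16L)
  # hidden-to-hidden: 2x2 between each of the 7 consecutive layer pairs
  expect_equal(sum(cand$type == "hidden"), 28L)
  expect_true(all(cand$abs_w == 0))
  # empty SGA set leaves only hidden-hidden candidates
  cand0 <- candidate_edges(w, character())
  expect_true(all(cand0$type == "hidden"))
  expect_error(candidate_edges(w, "NOPE"), "unknown gene")
})

test_that("edge threshold reproduces order statistics on distinct weights", {
  w <- toy_weights(m = 1, h = 1)
  # chain: SGA -> h1 (0.9); h1->h2 (0.8); h2->h3 (0.7); h3->h4 (0.6); h4->h5 (0.5)
  w$W[[1]][1, 1] <- 0.9
  for (i in 2:5) w$W[[i]][1, 1] <- 1.0 - 0.1 * i
  res <- find_edge_threshold(w, "SGA01", target_edges = 3)
  expect_equal(res$threshold, 0.7)
  expect_equal(res$n_edges, 3L)
  # target = all candidates with nonzero weight support
  res_all <- find_edge_threshold(candidate_edges(w, "SGA01")[
    candidate_edges(w, "SGA01")$abs_w > 0, ], target_edges = 5)
  expect_equal(res_all$threshold, 0.5)
  expect_error(find_edge_threshold(w, "SGA01", target_edges = 1e6), "fewer")
})

test_that("graphs keep only above-threshold edges reachable from the SGA set", {
  w <- toy_weights(m = 1, h = 4)
  w$W[[1]][1, 1] <- 0.9          # SGA -> h1_1
  w$W[[2]][1, 2] <- 0.8          # h1_1 -> h2_2 (reachable)
  w$W[[2]][3, 4] <- 0.95         # h1_3 -> h2_4 (above threshold, unreachable)
  g <- build_causal_graph(w, "SGA01", threshold = 0.7)
  expect_equal(nrow(g$edges), 2L)
  expect_false(any(g$edges$from == "h1_3"))
  expect_setequal(g$hidden_nodes, c("h1_1", "h2_2"))
  # threshold above every weight leaves an empty edge set
  g2 <- build_causal_graph(w, "SGA01", threshold = 2)
  expect_equal(nrow(g2$edges), 0L)
  # threshold 0 keeps every reachable candidate
  g3 <- build_causal_graph(w, "SGA01", threshold = 0)
  cand <- candidate_edges(w, "SGA01")
  expect_equal(nrow(g3$edges), nrow(rinn:::retained_edges(cand, 0)))
})

test_that("ancestor queries walk chains, colliders and diamonds", {
  w <- toy_weights(m = 2, h = 2)
  # chain from SGA01 and a collider with SGA02 at h2_1:
  # SGA01 -> h1_1 -> h2_1 <- SGA02 (direct redundant-input edge into layer 2)
  w$W[[1]][1, 1] <- 1
  w$W[[2]][1, 1] <- 1      # h1_1 -> h2_1
  w$W[[2]][3, 1] <- 1      # redundant row of SGA01... row h+1 = SGA01
  w$W[[2]][4, 1] <- 1      # redundant row SGA02 -> h2_1
  g <- build_causal_graph(w, c("SGA01", "SGA02"), threshold = 0.5)
  expect_identical(ancestor_sgas(g, "h1_1"), "SGA01")
  expect_identical(ancestor_sgas(g, "h2_1"), c("SGA01", "SGA02"))
  expect_error(ancestor_sgas(g, "h9_9"), "unknown node")
  labs <- label_hidden_nodes(g)
  expect_identical(labs[["h2_1"]], c("SGA01", "SGA02"))
  # diamond: two paths from SGA01 merge; SGA02 joins one branch
  w2 <- toy_weights(m = 2, h = 2)
  w2$W[[1]][1, 1] <- 1; w2$W[[1]][1, 2] <- 1; w2$W[[1]][2, 2] <- 1
  w2$W[[2]][1, 1] <- 1; w2$W[[2]][2, 1] <- 1
  g2 <- build_causal_graph(w2, c("SGA01", "SGA02"), threshold = 0.5)
  expect_identical(ancestor_sgas(g2, "h2_1"), c("SGA01", "SGA02"))
})

test_that("a node's label is the union of its parents' labels and direct SGA parents", {
  withr::with_seed(21, {
    for (rep in 1:60) {
      rl <- random_layered_edges(n_sga = sample(2:5, 1),
                                 layer_sizes = sample(2:4, sample(2:3, 1), TRUE))
      g <- structure(list(edges = data.frame(rl$edges,
                                             type = ifelse(grepl("^S", rl$edges$from),
                                                           "sga", "hidden"),
                                             weight = 1, abs_w = 1),
                          hidden_nodes = rl$hidden, sga_set = rl$sga_ids,
                          threshold = 0, model_id = NA),
                     class = "causal_graph")
      for (v in rl$hidden) {
        expect_identical(ancestor_sgas(g, v),
                         brute_ancestors(rl$edges, v, rl$sga_ids))
      }
    }
  })
})

test_that("identically labeled hidden nodes are counted across models", {
  w1 <- toy_weights(m = 2, h = 2)
  w1$W[[1]][1, 1] <- 1; w1$W[[2]][3, 1] <- 1; w1$W[[2]][4, 1] <- 1
  w1$W[[2]][1, 1] <- 1
  w2 <- toy_weights(m = 2, h = 2, seed = 2)
  w2$W[[1]][1, 2] <- 1; w2$W[[2]][2, 2] <- 1; w2$W[[2]][4, 2] <- 1
  j <- c("SGA01", "SGA02")
  g1 <- build_causal_graph(w1, j, 0.5)
  g2 <- build_causal_graph(w2, j, 0.5)
  tab <- shared_nodes_across_models(list(g1, g2), pathway = "toy")
  pair <- tab[tab$label == "SGA01,SGA02", ]
  expect_equal(pair$n_models, 2L)
  expect_equal(pair$models, "0,1")
  # a label present in no model is absent
  expect_false("SGA02,SGA02" %in% tab$label)
  # mismatched SGA sets are rejected
  g3 <- build_causal_graph(w2, "SGA01", 0.5)
  expect_error(shared_nodes_across_models(list(g1, g3)), "different SGA sets")
})

test_that("edge-free models give zero shared-label counts in the control", {
  mods <- list(toy_weights(m = 6, h = 2), toy_weights(m = 6, h = 2, seed = 2))
  # all-zero weights: thresholding keeps nothing
  ctl <- random_label_control(mods, group_size = 2,
                              pool = sprintf("SGA%02d", 3:6),
                              target_edges = 0, replicates = 3, seed = 1)
  expect_true(all(ctl$mean == 0))
  expect_true(all(ctl$sd == 0))
  expect_error(random_label_control(mods, group_size = 9,
                                    pool = sprintf("SGA%02d", 3:6)), "smaller")
})

test_that("threshold search on real weight tables matches a linear-scan oracle", {
  withr::with_seed(13, {
    for (rep in 1:50) {
      n_sga <- sample(2:4, 1); h <- sample(2:3, 1)
      w <- toy_weights(m = n_sga, h = h, seed = rep)
      # distinct |w| everywhere: a random permutation of distinct magnitudes
      tot <- 0
      for (i in seq_along(w$W)) tot <- tot + length(w$W[[i]])
      vals <- sample(seq(0.01, 50, length.out = tot))
      k <- 0
      for (i in seq_along(w$W)) {
        nw <- length(w$W[[i]])
        w$W[[i]][] <- vals[(k + 1):(k + nw)] * sample(c(-1, 1), nw, TRUE)
        k <- k + nw
      }
      sga_set <- sprintf("SGA%02d", seq_len(n_sga))
      cand <- candidate_edges(w, sga_set)
      # attainable counts under the reachability rule, by exhaustive scan
      achievable <- sort(unique(vapply(unique(cand$abs_w), function(t) {
        nrow(rinn:::retained_edges(cand, t))
      }, numeric(1))))
      target <- sample.int(min(40L, max(achievable)), 1)
      res <- find_edge_threshold(cand, target_edges = target)
      if (target %in% achievable) {
        expect_equal(res$n_edges, target)
      } else {
        # reachability can make counts jump; the rule is then <= target
        expect_equal(res$n_edges, max(achievable[achievable <= target]))
      }
      g <- build_causal_graph(w, sga_set, res$threshold)
      expect_equal(nrow(g$edges), res$n_edges)
    }
  })
})

test_that("built graphs are acyclic and fully SGA-reachable", {
  withr::with_seed(17, {
    dat <- tiny_dataset(n = 60, m = 6, p = 10, seed = 30)
    fit <- rinn(dat, hidden_sizes = 4, epochs = 15, learning_rate = 0.3,
                l1 = 1e-3, seed = 3)
    j <- colnames(dat$sga)[1:3]
    thr <- find_edge_threshold(fit, j, target_edges = 12)
    g <- build_causal_graph(fit, j, thr$threshold)
    ig <- as_igraph(g)
    expect_true(igraph::is_dag(ig))
    hid <- g$hidden_nodes
    d <- igraph::distances(ig, v = intersect(j, igraph::V(ig)$name), to = hid,
                           mode = "out")
    expect_true(all(is.finite(apply(d, 2, min))))
    # graph exports round-trip through GraphML
    tmp <- tempfile(fileext = ".graphml")
    write_graph_file(g, tmp)
    g_in <- igraph::read_graph(tmp, format = "graphml")
    expect_equal(igraph::ecount(g_in), nrow(g$edges))
  })
})
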