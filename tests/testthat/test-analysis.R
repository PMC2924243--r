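fx_small <- make_planted_fixture(n = 250, module_sizes = c(12, 12),
                                 seed = 13)
res_small <- netwalk(fx_small$net, fx_small$ws[[1]], walk_config())

test_that("subnetwork extraction is deterministic and shuffle-stable", {
  ef <- res_small$edges
  expect_equal(nrow(extract_subnetwork(ef, "top_k", 0)$edges), 0)

  top <- extract_subnetwork(ef, "top_k", 40)
  expect_equal(nrow(top$edges), 40)
  # induced nodes all touch a selected edge
  expect_setequal(top$nodes, unique(c(top$edges$source, top$edges$target)))
  # provenance
  expect_identical(top$rule, list(rule = "top_k", value = 40))

  # stable under row shuffling of the input table
  set.seed(1)
  shuf <- ef[sample(nrow(ef)), , drop = FALSE]
  top2 <- extract_subnetwork(shuf, "top_k", 40)
  expect_identical(top$edges, top2$edges)
  # idempotent: re-extracting from the selection returns the selection
  expect_identical(extract_subnetwork(top$edges, "top_k", 40)$edges,
                   top$edges)

  # s_ge at the maximum keeps exactly the argmax edge(s)
  mx <- extract_subnetwork(ef, "s_ge", max(ef$s))
  expect_equal(nrow(mx$edges), sum(ef$s == max(ef$s)))

  expect_warning(all_e <- extract_subnetwork(ef, "top_k", nrow(ef) + 50),
                 "exceeds")
  expect_equal(nrow(all_e$edges), nrow(ef))

  # boundary ties break lexicographically, reproducibly
  tied <- data.frame(source = c("B", "A", "C", "D"),
                     target = c("X", "X", "X", "X"),
                     directed = FALSE, itype = "PPI",
                     s = c(1, 1, 1, 0))
  expect_message(sel <- extract_subnetwork(tied, "top_k", 2), "tie")
  expect_identical(sel$edges$source, c("A", "B"))
})

test_that("coherence report gives boxplot statistics of node values", {
  w2 <- data_vector(setNames(rep(2, 10), sprintf("n%02d", 1:10)))
  sub <- list(nodes = names(w2), edges = data.frame())
  rep2 <- coherence_report(sub, w2)
  expect_equal(rep2$median, 2)
  expect_equal(rep2$q3 - rep2$q1, 0)
  expect_equal(rep2$frac_above_1, 1)

  # top and bottom networks on the planted fixture straddle no-change
  k <- 30
  top <- extract_subnetwork(res_small$edges, "top_k", k)
  bot <- extract_subnetwork(res_small$edges, "bottom_k", k)
  w <- fx_small$ws[[1]]
  expect_gt(coherence_report(top, w)$median, 1)
  expect_lt(coherence_report(bot, w)$median, 1)

  # single-edge subnetwork and empty subnetwork degenerate gracefully
  one <- extract_subnetwork(res_small$edges, "top_k", 1)
  expect_lte(coherence_report(one, w)$n_nodes, 2)
  none <- extract_subnetwork(res_small$edges, "top_k", 0)
  expect_equal(coherence_report(none, w)$n_nodes, 0)
})

test_that("EF matrices stack conditions and demand aligned edge sets", {
  ef <- res_small$edges
  m1 <- build_ef_matrix(list(c1 = ef))
  expect_equal(ncol(m1), 1)
  expect_equal(nrow(m1), nrow(ef))

  m2 <- build_ef_matrix(list(c1 = ef, c2 = ef))
  expect_identical(m2[, 1], m2[, 2])

  # column-stacking oracle on 3 conditions
  fx3 <- make_planted_fixture(n = 150, module_sizes = c(8, 8),
                              n_conditions = 3, seed = 29)
  runs <- lapply(fx3$ws, function(w) netwalk(fx3$net, w, walk_config()))
  names(runs) <- vapply(fx3$ws, condition_of, character(1))
  efm <- build_ef_matrix(runs)
  expect_identical(colnames(efm), names(runs))
  for (j in 1:3) {
    ref <- setNames(runs[[j]]$edges$s, edge_keys(runs[[j]]$edges))
    expect_equal(efm[, j], ref[rownames(efm)])
  }

  other <- netwalk(fx3$net, fx3$ws[[1]], walk_config())
  trimmed <- other$edges[-1, ]
  expect_error(build_ef_matrix(list(a = runs[[1]]$edges, b = trimmed)),
               "edge sets differ")
})

test_that("Ward clustering separates modules active in disjoint conditions", {
  act <- rbind(c(TRUE, TRUE, FALSE, FALSE),
               c(FALSE, FALSE, TRUE, TRUE))
  fx <- make_planted_fixture(n = 250, module_sizes = c(12, 12),
                             n_conditions = 4, activation = act, seed = 3)
  runs <- lapply(fx$ws, function(w) netwalk(fx$net, w, walk_config()))
  names(runs) <- vapply(fx$ws, condition_of, character(1))
  efm <- build_ef_matrix(runs)
  cl <- cluster_ef(efm, k_select = nrow(fx$truth$high_edges),
                   n_clusters = 2)
  hi <- cl$clusters[cl$selected %in% edge_keys(fx$truth$high_edges)]
  lo <- cl$clusters[cl$selected %in% edge_keys(fx$truth$low_edges)]
  expect_gt(length(hi), 0)
  expect_gt(length(lo), 0)
  expect_length(unique(hi), 1)
  expect_length(unique(lo), 1)
  expect_false(unique(hi) == unique(lo))

  # invariance to row and column permutation, up to relabeling
  set.seed(4)
  perm <- efm[sample(nrow(efm)), sample(ncol(efm))]
  class(perm) <- class(efm)
  cl2 <- cluster_ef(perm, k_select = nrow(fx$truth$high_edges),
                    n_clusters = 2)
  expect_setequal(cl2$selected, cl$selected)
  agree <- table(cl$clusters[cl$selected], cl2$clusters[cl$selected])
  expect_equal(sum(agree > 0), 2)  # one-to-one label correspondence

  # degenerate all-equal matrix collapses to one cluster with a warning
  flat <- matrix(0.5, nrow = 5, ncol = 2,
                 dimnames = list(paste0("e", 1:5), c("a", "b")))
  expect_warning(cf <- cluster_ef(flat, k_select = 5, n_clusters = 2),
                 "equal")
  expect_equal(unname(cf$clusters), rep(1L, 5))
})

test_that("zero perturbation reproduces the reference run exactly", {
  fx <- fx_small
  r0 <- robustness_experiment(fx$net, fx$ws[[1]], walk_config(),
                              kind = "data_deletion", levels = 0,
                              n_reps = 2, seed = 5)
  expect_equal(r0$statistic, c(1, 1), tolerance = 1e-12)
  f2 <- robustness_experiment(fx$net, fx$ws[[1]], walk_config(),
                              kind = "expansion_factor", levels = 2,
                              top_k = 50, seed = 5)
  expect_equal(f2$statistic, 1)

  # reproducibility: same seed, same table
  ra <- robustness_experiment(fx$net, fx$ws[[1]], walk_config(),
                              kind = "edge_deletion", levels = c(0.3),
                              n_reps = 2, seed = 11)
  rb <- robustness_experiment(fx$net, fx$ws[[1]], walk_config(),
                              kind = "edge_deletion", levels = c(0.3),
                              n_reps = 2, seed = 11)
  expect_identical(ra, rb)
  expect_error(robustness_experiment(fx$net, fx$ws[[1]], walk_config(),
                                     kind = "data_deletion", levels = 1.5),
               "fractions")
  expect_error(robustness_experiment(fx$net, fx$ws[[1]], walk_config(),
                                     kind = "expansion_factor", levels = 0.5),
               "> 1")
})
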