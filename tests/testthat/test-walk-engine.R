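test_that("transition probabilities follow the neighbour-value rule", {
  # A -> B and A -> C directed, w_B = 3, w_C = 1: p = 3/4 and 1/4
  net <- interaction_network(data.frame(
    source = c("A", "A"), target = c("B", "C"), directed = TRUE,
    itype = "SIGNALING"), quiet = TRUE)
  w <- impute_missing(net, data_vector(c(B = 3, C = 1)), quiet = TRUE)
  tm <- build_transition_matrix(net, w)
  P <- as.matrix(tm$P)
  dimnames(P) <- list(tm$nodes, tm$nodes)
  expect_equal(P["A", "B"], 3 / 4)
  expect_equal(P["A", "C"], 1 / 4)
  # B and C have no downstream neighbours: dangling
  expect_identical(tm$dangling, c(FALSE, TRUE, TRUE))

  # all w = 1 reduces to the uniform walk
  case <- random_walk_case(40, seed = 8)
  ones <- impute_missing(case$net, data_vector(setNames(1, case$net$nodes[1])),
                         quiet = TRUE)
  tmu <- build_transition_matrix(case$net, ones)
  Pu <- as.matrix(tmu$P)
  for (i in which(!tmu$dangling)) {
    nz <- Pu[i, ] > 0
    expect_equal(unname(Pu[i, nz]), rep(1 / sum(nz), sum(nz)))
  }

  expect_error(build_transition_matrix(interaction_network(quiet = TRUE),
                                       data_vector(c(a = 1))), "empty")
  bad <- setNames(rep(NA_real_, n_nodes(net)), net$nodes)
  expect_error(build_transition_matrix(net, bad), "cover")
})

test_that("every transition row sums to 1 within 1e-12", {
  for (seed in c(2, 21, 33)) {
    case <- random_walk_case(60, seed = seed)
    w <- impute_missing(case$net, case$w, quiet = TRUE)
    tm <- build_transition_matrix(case$net, w)
    rs <- Matrix::rowSums(tm$P)
    expect_true(all(abs(rs[!tm$dangling] - 1) <= 1e-12))
    # dangling rows are implicit uniform rows: stored part is all zero
    expect_true(all(rs[tm$dangling] == 0))
  }
})

test_that("restart vector is data-proportional or uniform", {
  w <- data_vector(c(a = 1, b = 1, c = 1, d = 1))
  expect_equal(as.numeric(restart_vector(w, walk_config(bias_restart = TRUE))),
               rep(0.25, 4))
  w2 <- data_vector(c(a = 5, b = 2, c = 2, d = 1))
  expect_equal(as.numeric(restart_vector(w2)), c(0.5, 0.2, 0.2, 0.1))
  w10 <- data_vector(setNames(2 ^ rnorm(10), letters[1:10]))
  expect_equal(as.numeric(restart_vector(
    w10, walk_config(bias_restart = FALSE))), rep(0.1, 10))
})

test_that("stationary limits: symmetric two-node case and q = 1", {
  pair <- interaction_network(data.frame(
    source = "A", target = "B", directed = FALSE, itype = "PPI"),
    quiet = TRUE)
  w <- impute_missing(pair, data_vector(c(A = 1)), quiet = TRUE)
  tm <- build_transition_matrix(pair, w)
  cfg0 <- walk_config(q = 0)
  expect_warning(g0 <- stationary_distribution(tm, restart_vector(w, cfg0),
                                               cfg0), "unique")
  expect_equal(as.numeric(g0), c(0.5, 0.5), tolerance = 1e-10)

  # q = 1: the walker only restarts, so g = r
  case <- random_walk_case(30, seed = 4)
  wq <- impute_missing(case$net, case$w, quiet = TRUE)
  cfg1 <- walk_config(q = 1)
  tmq <- build_transition_matrix(case$net, wq)
  r <- restart_vector(wq, cfg1)
  g1 <- stationary_distribution(tmq, r, cfg1)
  expect_equal(as.numeric(g1), as.numeric(r), tolerance = 1e-12)
})

test_that("power iteration agrees with the dense direct solve", {
  qs <- c(0.01, 0.1, 0.5)
  for (k in 1:10) {
    case <- random_walk_case(20 + 12 * k, seed = 100 + k)
    q <- qs[(k %% 3) + 1]
    cfg <- walk_config(q = q)
    w <- impute_missing(case$net, case$w, quiet = TRUE)
    tm <- build_transition_matrix(case$net, w)
    r <- restart_vector(w, cfg)
    g <- stationary_distribution(tm, r, cfg)
    expect_true(attr(g, "converged"))
    oracle <- dense_oracle_g(case$net, w, q)
    expect_lt(max(abs(as.numeric(g) - oracle[tm$nodes])), 1e-10)
    # fixed-point residual
    step <- as.numeric(Matrix::t(tm$P) %*% as.numeric(g)) +
      sum(g[tm$dangling]) / length(g)
    resid <- sum(abs(as.numeric(g) - ((1 - q) * step + q * as.numeric(r))))
    expect_lt(resid, 10 * cfg$tol)
  }
})

test_that("visitation mass is conserved and backgrounds are positive", {
  for (seed in c(11, 12)) {
    case <- random_walk_case(80, seed = seed)
    vis <- run_walk(case$net, case$w, walk_config())
    expect_equal(sum(vis$g), 1, tolerance = 1e-10)
    expect_equal(sum(vis$g_r), 1, tolerance = 1e-10)
    expect_true(all(vis$g >= 0))
    expect_true(all(vis$g_r > 0))   # q > 0 restart reaches every node
    expect_true(all(is.finite(vis$g_rel)))
  }
})

test_that("uniform data gives g identical to the background", {
  case <- random_walk_case(50, seed = 9)
  ones <- data_vector(setNames(rep(1, 50), case$net$nodes))
  vis <- run_walk(case$net, ones, walk_config())
  expect_true(all(abs(vis$g - vis$g_r) <= 1e-12))
  expect_equal(vis$g_rel, rep(1, 50), tolerance = 1e-10)
})

test_that("raising a node's data value never lowers its visitation", {
  # empirical monotonicity over randomized small instances
  for (seed in c(41, 42, 43)) {
    case <- random_walk_case(25, seed = seed)
    w <- impute_missing(case$net, case$w, quiet = TRUE)
    base <- run_walk(case$net, w, walk_config())
    set.seed(seed)
    for (target in sample(case$net$nodes, 3)) {
      w_up <- w
      w_up[[target]] <- w_up[[target]] * 4
      up <- run_walk(case$net, data_vector(w_up), walk_config())
      i <- match(target, base$nodes)
      expect_gte(up$g[i], base$g[i] - 1e-12)
    }
  }
})

test_that("non-convergence within max_iter warns and flags the result", {
  case <- random_walk_case(40, seed = 6)
  w <- impute_missing(case$net, case$w, quiet = TRUE)
  cfg <- walk_config(q = 0.01, max_iter = 2)
  tm <- build_transition_matrix(case$net, w)
  expect_warning(g <- stationary_distribution(tm, restart_vector(w, cfg),
                                              cfg), "converge")
  expect_false(attr(g, "converged"))
})
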