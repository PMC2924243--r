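# Independent dense oracle for the walk engine.  Deliberately shares no
# code with the package internals: the transition matrix is built
# elementwise by looping over edge records, dangling rows are materialized
# as full 1/n rows, and the stationary distribution comes from a direct
# linear solve of g (I - (1-q) P) = q r instead of power iteration.

dense_transition_matrix <- function(net, w) {
  nodes <- net$nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- net$edges
  for (k in seq_len(nrow(e))) {
    src <- e$source[k]
    tgt <- e$target[k]
    A[src, tgt] <- w[[tgt]]
    if (!e$directed[k]) A[tgt, src] <- w[[src]]
  }
  P <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n)) {
    rs <- sum(A[i, ])
    P[i, ] <- if (rs == 0) rep(1 / n, n) else A[i, ] / rs
  }
  P
}

dense_oracle_g <- function(net, w, q, bias_restart = TRUE) {
  P <- dense_transition_matrix(net, w)
  n <- length(net$nodes)
  wv <- as.numeric(w[net$nodes])
  r <- if (bias_restart) wv / sum(wv) else rep(1 / n, n)
  g <- solve(t(diag(n) - (1 - q) * P), q * r)
  stats::setNames(as.numeric(g), net$nodes)
}

# random mixed directed/undirected test network with positive random data;
# isolated node forced in so dangling rows occur
random_walk_case <- function(n, seed, p_edge = 2.5 / n) {
  set.seed(seed)
  ids <- sprintf("n%03d", seq_len(n))
  pairs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) < 2) return(random_walk_case(n, seed + 1000, p_edge * 2))
  directed <- stats::runif(nrow(pairs)) < 0.4
  itype <- sample(c("PPI", "SIGNALING", "FS"), nrow(pairs), replace = TRUE)
  net <- interaction_network(
    data.frame(source = pairs[, 1], target = pairs[, 2],
               directed = directed, itype = itype,
               stringsAsFactors = FALSE),
    nodes = ids, quiet = TRUE)
  w <- data_vector(stats::setNames(2 ^ stats::rnorm(n, 0, 1), ids),
                   condition = paste0("case", seed))
  list(net = net, w = w)
}

node_degree <- function(net) {
  d <- table(c(net$edges$source, net$edges$target))
  out <- stats::setNames(rep(0, length(net$nodes)), net$nodes)
  out[names(d)] <- as.numeric(d)
  out
}
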