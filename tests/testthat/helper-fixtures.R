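# Shared fixtures and independent oracles used across the test files.
# Everything is generated in code; nothing is read from disk except the
# package's own extdata fixtures.

random_rotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# a small template atlas reused by the semilandmark tests (cached per session)
small_atlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_template(n_fixed = 6L, curve_counts = c(8L, 8L),
                              n_surface = 16L, seed = 77L)
    cache
  }
})

# UV-sphere mesh (poles + regular grid), used for analytic projection tests
uv_sphere <- function(r = 1, n_phi = 20L, n_theta = 20L) {
  phis <- seq(0, pi, length.out = n_phi + 2L)[-c(1L, n_phi + 2L)]
  thetas <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  V <- rbind(c(0, 0, r), c(0, 0, -r))
  for (p in phis) for (t in thetas)
    V <- rbind(V, r * c(sin(p) * cos(t), sin(p) * sin(t), cos(p)))
  idx <- function(i, j) 2L + (i - 1L) * n_theta + j
  Fc <- list()
  for (j in seq_len(n_theta)) {
    jn <- if (j == n_theta) 1L else j + 1L
    Fc[[length(Fc) + 1L]] <- c(1L, idx(1L, j), idx(1L, jn))
    Fc[[length(Fc) + 1L]] <- c(2L, idx(n_phi, jn), idx(n_phi, j))
  }
  for (i in seq_len(n_phi - 1L)) for (j in seq_len(n_theta)) {
    jn <- if (j == n_theta) 1L else j + 1L
    Fc[[length(Fc) + 1L]] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, jn))
    Fc[[length(Fc) + 1L]] <- c(idx(i, j), idx(i + 1L, jn), idx(i, jn))
  }
  surface_mesh(V, do.call(rbind, Fc))
}

# effectively-star binary tree (tiny internal branches), for reductions that
# need a bifurcating tree but star-like covariance
near_star <- function(n, pendant = 1) {
  tr <- ape::stree(n, "left")   # binary ladder; tiny internal edges
  tr$edge.length <- rep(1e-9, nrow(tr$edge))
  dep <- ape::node.depth.edgelength(tr)
  tips <- tr$edge[, 2L] <= n
  tr$edge.length[tips] <- pendant + max(dep) - dep[tr$edge[tips, 2L]]
  tr
}

# --- independent oracles -------------------------------------------------

# ordinary Procrustes by numerical minimization over a quaternion rotation
opa_oracle <- function(X, Y, allow_scale = TRUE) {
  X0 <- sweep(X, 2L, colMeans(X))
  Y0 <- sweep(Y, 2L, colMeans(Y))
  rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3L, 3L, byrow = TRUE)
  }
  # given the rotation, the optimal uniform scale has the closed form
  # s = max(0, <X0 R, Y0> / ||X0||^2); the rotation itself is found
  # numerically over quaternions
  obj <- function(q) {
    R <- rot(q)
    s <- if (allow_scale) max(0, sum((X0 %*% R) * Y0) / sum(X0^2)) else 1
    sum((s * X0 %*% R - Y0)^2)
  }
  best <- Inf
  for (try in 1:30) {
    o <- stats::optim(stats::rnorm(4L), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  sqrt(best)
}

# Blomberg's K written directly from the formula, independent of k_mult()
blomberg_k_oracle <- function(tree, y) {
  C <- ape::vcv.phylo(tree)
  y <- y[rownames(C)]
  n <- length(y)
  Cinv <- solve(C)
  ones <- rep(1, n)
  ahat <- sum(Cinv %*% y) / sum(Cinv)
  d <- y - ahat
  observed <- drop(crossprod(d)) / drop(t(d) %*% Cinv %*% d)
  expected <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  observed / expected
}

# exact parsimony by enumerating all internal-node labelings (small trees)
parsimony_enumeration <- function(tree, states) {
  lev <- sort(unique(as.character(states)))
  ntip <- length(tree$tip.label)
  tipstate <- match(as.character(states)[match(tree$tip.label,
                                               names(states))], lev)
  nnode <- tree$Nnode
  combos <- expand.grid(rep(list(seq_along(lev)), nnode))
  best <- Inf
  node_sets <- vector("list", nnode)
  for (r in seq_len(nrow(combos))) {
    lab <- c(tipstate, as.integer(combos[r, ]))
    cost <- sum(lab[tree$edge[, 1L]] != lab[tree$edge[, 2L]])
    if (cost < best) {
      best <- cost
      node_sets <- lapply(seq_len(nnode), function(i)
        as.integer(combos[r, i]))
    } else if (cost == best) {
      node_sets <- lapply(seq_len(nnode), function(i)
        union(node_sets[[i]], as.integer(combos[r, i])))
    }
  }
  list(score = best,
       mpr = lapply(node_sets, function(s) lev[sort(s)]))
}

# marginal node posteriors of the 2-state equal-rates Mk model by joint
# enumeration; the transition probability has the closed form
# P(same) = (1 + exp(-2qt))/2, P(different) = (1 - exp(-2qt))/2
mk_marginals_enumeration <- function(tree, states, q, lev,
                                     root_prior = c(0.5, 0.5)) {
  ntip <- length(tree$tip.label)
  tipstate <- match(as.character(states)[match(tree$tip.label,
                                               names(states))], lev)
  nnode <- tree$Nnode
  P <- lapply(tree$edge.length, function(t) {
    e <- exp(-2 * q * t)
    matrix(c((1 + e) / 2, (1 - e) / 2, (1 - e) / 2, (1 + e) / 2), 2L)
  })
  combos <- expand.grid(rep(list(seq_along(lev)), nnode))
  w <- numeric(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    lab <- c(tipstate, as.integer(combos[r, ]))
    pr <- root_prior[lab[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge)))
      pr <- pr * P[[e]][lab[tree$edge[e, 1L]], lab[tree$edge[e, 2L]]]
    w[r] <- pr
  }
  w <- w / sum(w)
  post <- matrix(0, nnode, length(lev), dimnames =
                   list((ntip + 1L):(ntip + nnode), lev))
  for (r in seq_len(nrow(combos)))
    for (i in seq_len(nnode))
      post[i, as.integer(combos[r, i])] <-
        post[i, as.integer(combos[r, i])] + w[r]
  post
}

# Brownian tip data on a tree (independent of the package's generator)
bm_tips <- function(tree, sigma2 = 1, d = 1L) {
  L <- t(chol(ape::vcv.phylo(tree)))
  Y <- L %*% matrix(stats::rnorm(length(tree$tip.label) * d),
                    length(tree$tip.label)) * sqrt(sigma2)
  rownames(Y) <- tree$tip.label
  Y
}

# deterministic 30-tip ultrametric tree containing one 6-tip clade,
# assembled from two coalescent subtrees of fixed seed and equal height
tree_with_6clade <- function(seed = 101L) {
  set.seed(seed)
  a <- ape::rcoal(6L, tip.label = paste0("c", 1:6))
  b <- ape::rcoal(24L, tip.label = paste0("t", 1:24))
  scale_to <- function(tr, h) {
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * h
    tr
  }
  a <- scale_to(a, 4); b <- scale_to(b, 8)
  na <- sub(";$", ":6", ape::write.tree(a))
  nb <- sub(";$", ":2", ape::write.tree(b))
  validate_phylo(ape::read.tree(text = paste0("(", na, ",", nb, ");")))
}
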