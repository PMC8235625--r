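#' Brownian-motion covariance of a tree
#'
#' The n x n matrix of shared root-to-MRCA path lengths among tips; the
#' covariance of tip values under Brownian motion with unit rate.
#'
#' @param tree a `phylo`.
#' @return symmetric positive semidefinite matrix with tip depths on the
#'   diagonal.
#' @export
phylo_vcv <- function(tree) ape::vcv.phylo(validate_phylo_loose(tree))

# tree with positive lengths and unique labels; polytomies (including a
# star phylogeny, the canonical K = 1 case) are allowed here because the
# covariance-based statistics only need the shared-path-length matrix
validate_phylo_loose <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a `phylo` object", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels", call. = FALSE)
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0))
    stop("all branch lengths must be positive", call. = FALSE)
  tree
}

align_trait <- function(tree, trait) {
  if (is.null(names(trait))) stop("trait must be named by tip", call. = FALSE)
  y <- trait[tree$tip.label]
  if (anyNA(y)) stop("trait is missing for some tips", call. = FALSE)
  y
}

align_matrix <- function(tree, Y) {
  Y <- as.matrix(Y)
  if (is.null(rownames(Y)))
    stop("shape matrix must have species rownames", call. = FALSE)
  Y <- Y[tree$tip.label, , drop = FALSE]
  if (anyNA(Y)) stop("data missing for some tips", call. = FALSE)
  Y
}

# shared machinery of K and Kmult: observed/expected ratio of ordinary to
# phylogenetically transformed deviations from the phylogenetic mean
k_ratio <- function(Cinv, ones_Cinv, sum_Cinv, expected, Y) {
  a <- drop(ones_Cinv %*% Y) / sum_Cinv
  dev <- sweep(Y, 2L, a)
  num <- sum(dev^2)
  den <- sum(dev * (Cinv %*% dev))
  (num / den) / expected
}

#' Blomberg's K: phylogenetic signal of a univariate trait
#'
#' K is the ratio of the observed mean squared deviation from the
#' phylogenetic (GLS) mean to the phylogenetically corrected one, divided by
#' its expectation under Brownian motion, so Brownian evolution expects
#' K = 1 and a star phylogeny gives exactly 1. Significance comes from
#' permuting trait values across tips (add-one rule).
#'
#' @param tree a `phylo`.
#' @param trait named numeric vector over tips, non-constant.
#' @param n_perm number of permutations (0 skips the test).
#' @param seed RNG seed.
#' @return list with `K`, `p` and `n_perm`.
#' @export
blomberg_k <- function(tree, trait, n_perm = 10000L, seed = 1L) {
  tree <- validate_phylo_loose(tree)
  y <- align_trait(tree, trait)
  if (stats::var(y) < 1e-300)
    stop("trait is constant: phylogenetic signal undefined", call. = FALSE)
  k_mult(tree, matrix(y, ncol = 1L, dimnames = list(names(y), NULL)),
         n_perm = n_perm, seed = seed, .label = "K")
}

#' Multivariate phylogenetic signal (Kmult)
#'
#' The multivariate generalization of Blomberg's K for landmark shape data:
#' squared deviations are summed over all trait dimensions (Euclidean
#' distances from the multivariate phylogenetic mean), normalized by the
#' Brownian expectation. With one column it reduces exactly to Blomberg's K.
#'
#' @param tree a `phylo`.
#' @param Y matrix with species rownames (one row per tip), e.g. flattened
#'   Procrustes shapes.
#' @inheritParams blomberg_k
#' @return list with `K`, `p` and `n_perm`.
#' @export
k_mult <- function(tree, Y, n_perm = 10000L, seed = 1L, .label = "Kmult") {
  tree <- validate_phylo_loose(tree)
  Y <- align_matrix(tree, Y)
  n <- nrow(Y)
  if (n < 3L) stop("need at least 3 species", call. = FALSE)
  C <- ape::vcv.phylo(tree)
  Cinv <- solve(C)
  ones_Cinv <- rep(1, n) %*% Cinv
  sum_Cinv <- sum(Cinv)
  expected <- (sum(diag(C)) - n / sum_Cinv) / (n - 1)
  K_obs <- k_ratio(Cinv, ones_Cinv, sum_Cinv, expected, Y)
  p <- NA_real_
  if (n_perm > 0L) {
    set.seed(seed)
    K_perm <- vapply(seq_len(n_perm), function(i)
      k_ratio(Cinv, ones_Cinv, sum_Cinv, expected,
              Y[sample.int(n), , drop = FALSE]), 0)
    p <- (sum(K_perm >= K_obs) + 1) / (n_perm + 1)
  }
  out <- list(K = unname(K_obs), p = p, n_perm = n_perm)
  names(out)[1L] <- "K"
  attr(out, "statistic") <- .label
  out
}

anova_f <- function(y, g) {
  gm <- tapply(y, g, mean)
  n_j <- tabulate(g)
  grand <- mean(y)
  ssb <- sum(n_j * (gm - grand)^2)
  ssw <- sum((y - gm[as.integer(g)])^2)
  df1 <- nlevels(g) - 1L
  df2 <- length(y) - nlevels(g)
  (ssb / df1) / (ssw / df2)
}

#' Phylogenetic ANOVA by Brownian simulation
#'
#' The standard one-way ANOVA F statistic is computed on the tip data, and
#' its null distribution is obtained by simulating Brownian motion on the
#' tree (rate estimated from the data via phylogenetically independent
#' contrasts) and recomputing F with the group labels held fixed. Reported
#' alongside the ordinary parametric p-value.
#'
#' @param tree a `phylo`.
#' @param groups named factor/character over tips (two or more levels).
#' @param trait named numeric vector over tips.
#' @param n_sim number of Brownian simulations.
#' @param seed RNG seed.
#' @return list with `F`, `p_phylo` (simulation, add-one rule),
#'   `p_standard` (parametric) and `sigma2` (contrasts rate estimate).
#' @export
phyl_anova <- function(tree, groups, trait, n_sim = 1000L, seed = 1L) {
  tree <- validate_phylo(tree)
  y <- align_trait(tree, trait)
  g <- factor(as.character(align_trait(tree, groups)))
  if (nlevels(g) < 2L)
    stop("need at least two groups", call. = FALSE)
  F_obs <- anova_f(y, g)
  df1 <- nlevels(g) - 1L
  df2 <- length(y) - nlevels(g)
  p_standard <- stats::pf(F_obs, df1, df2, lower.tail = FALSE)
  sigma2 <- mean(ape::pic(y, tree)^2)
  set.seed(seed)
  L <- t(chol(ape::vcv.phylo(tree)))
  Z <- L %*% matrix(stats::rnorm(length(y) * n_sim), length(y)) *
    sqrt(sigma2)
  gi <- as.integer(g)
  n_j <- tabulate(gi)
  # vectorized F over simulated columns
  gm <- rowsum(Z, gi) / n_j
  grand <- colMeans(Z)
  ssb <- colSums(n_j * sweep(gm, 2L, grand)^2)
  ssw <- colSums((Z - gm[gi, , drop = FALSE])^2)
  F_sim <- (ssb / df1) / (ssw / df2)
  list(F = F_obs,
       p_phylo = (sum(F_sim >= F_obs) + 1) / (n_sim + 1),
       p_standard = p_standard, sigma2 = sigma2, n_sim = n_sim)
}

#' Retain principal components up to a cumulative variance threshold
#'
#' Centered PCA of the data; returns the scores on the smallest leading axis
#' set whose cumulative variance reaches the threshold (95% by default, the
#' reduction used before MANCOVA).
#'
#' @param Y data matrix (rows = specimens/species).
#' @param threshold cumulative variance fraction to reach.
#' @return list with `scores`, `n_axes`, `variance_fraction` (all axes) and
#'   `cumulative` (fraction covered by the retained set).
#' @export
retain_pcs <- function(Y, threshold = 0.95) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 2L) stop("need at least 2 rows", call. = FALSE)
  pc <- stats::prcomp(Y, center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  n_axes <- which(cumsum(vf) >= threshold - 1e-12)[1L]
  list(scores = pc$x[, seq_len(n_axes), drop = FALSE], n_axes = n_axes,
       variance_fraction = vf, cumulative = sum(vf[seq_len(n_axes)]))
}

pillai_f <- function(H, E, df_h, df_res) {
  p <- ncol(E)
  eig <- Re(eigen(solve(E, H), only.values = TRUE)$values)
  V <- sum(eig / (1 + eig))
  s <- min(p, df_h)
  m <- 0.5 * (abs(p - df_h) - 1)
  n2 <- 0.5 * (df_res - p - 1)
  tmp1 <- 2 * m + s + 1
  tmp2 <- 2 * n2 + s + 1
  Fstat <- (tmp2 / tmp1 * V) / (s - V)
  c(Pillai = V, approx_F = Fstat, num_Df = s * tmp1, den_Df = s * tmp2)
}

#' MANCOVA of shape scores on size, group and their interaction
#'
#' Sequential (Type I) multivariate linear model `scores ~ size + group +
#' size:group`, in that order, with Pillai's trace and Rao's F approximation
#' per term, all terms tested against the full-model residual SSCP — the
#' layout of the published allometry/locomotion table.
#'
#' @param scores numeric matrix (n x q) of retained PC scores (a single
#'   column is allowed, in which case Pillai's F equals the sequential
#'   univariate ANCOVA F).
#' @param log_size numeric covariate (log centroid size).
#' @param groups factor/character of group membership.
#' @return a data.frame with rows size, locomotion, interaction, residuals
#'   and columns Df, Pillai, approx_F, num_Df, den_Df, p_value.
#' @export
mancova_pillai <- function(scores, log_size, groups) {
  Y <- as.matrix(scores)
  n <- nrow(Y); q <- ncol(Y)
  g <- factor(as.character(groups))
  if (length(log_size) != n || length(g) != n)
    stop("size/group length mismatch", call. = FALSE)
  if (n <= q + 3L)
    stop("too few cases for ", q, " response axes (need n > q + 3)",
         call. = FALSE)
  size <- as.numeric(log_size)
  Xg <- stats::model.matrix(~g)[, -1L, drop = FALSE]
  blocks <- list(intercept = matrix(1, n, 1L),
                 size = matrix(size, n, 1L),
                 locomotion = Xg,
                 interaction = Xg * size)
  X <- do.call(cbind, blocks)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    # identify the first term block whose addition does not raise the rank
    r_prev <- 0L; bad <- "design"
    Xacc <- NULL
    for (b in names(blocks)) {
      Xacc <- cbind(Xacc, blocks[[b]])
      r <- qr(Xacc)$rank
      if (r < r_prev + ncol(blocks[[b]])) { bad <- b; break }
      r_prev <- r
    }
    stop("rank-deficient design: term '", bad, "' is aliased",
         call. = FALSE)
  }
  sscp_fit <- function(cols) {
    fit <- qr.fitted(qr(X[, seq_len(cols), drop = FALSE]), Y)
    crossprod(fit)
  }
  ncum <- cumsum(vapply(blocks, ncol, 1L))
  P0 <- sscp_fit(ncum[1L])
  P1 <- sscp_fit(ncum[2L])
  P2 <- sscp_fit(ncum[3L])
  P3 <- sscp_fit(ncum[4L])
  E <- crossprod(Y - qr.fitted(qrX, Y))
  df_res <- n - ncol(X)
  terms <- list(size = list(H = P1 - P0, df = 1L),
                locomotion = list(H = P2 - P1, df = ncol(Xg)),
                interaction = list(H = P3 - P2, df = ncol(Xg)))
  rows <- lapply(names(terms), function(nm) {
    tr <- terms[[nm]]
    st <- pillai_f(tr$H, E, tr$df, df_res)
    data.frame(term = nm, Df = tr$df, Pillai = st[["Pillai"]],
               approx_F = st[["approx_F"]], num_Df = st[["num_Df"]],
               den_Df = st[["den_Df"]],
               p_value = stats::pf(st[["approx_F"]], st[["num_Df"]],
                                   st[["den_Df"]], lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(term = "residuals", Df = df_res, Pillai = NA,
                               approx_F = NA, num_Df = NA, den_Df = NA,
                               p_value = NA))
  rownames(out) <- out$term
  out
}

tip_branch_design <- function(tree) {
  n <- length(tree$tip.label)
  X <- matrix(0, n, nrow(tree$edge),
              dimnames = list(tree$tip.label, NULL))
  parent_of <- integer(max(tree$edge))
  edge_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  edge_of[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  root <- n + 1L
  for (i in seq_len(n)) {
    v <- i
    while (v != root) {
      e <- edge_of[v]
      X[i, e] <- tree$edge.length[e]
      v <- parent_of[v]
    }
  }
  X
}

#' Per-branch evolutionary rates by phylogenetic ridge regression
#'
#' Regresses the (root-centered) tip phenotypes on the design of root-to-tip
#' branch paths: entry (i, j) of the design is the length of branch j if it
#' lies on tip i's path from the root, else 0. The ridge coefficient of a
#' branch, per trait dimension, is its evolutionary rate vector; the
#' magnitude is the Euclidean norm across dimensions. The root estimate is
#' the phylogenetic GLS mean. When `lambda` is not supplied it is chosen by
#' golden-section search on log-lambda minimizing the leave-one-out tip
#' prediction error.
#'
#' @param tree a `phylo`.
#' @param Y named vector or matrix (rows = tips) of tip phenotypes.
#' @param lambda optional ridge penalty (>= 0 relative scale applied as-is).
#' @return a `rate_field`: list with `rates` (per-branch magnitudes, one per
#'   edge of the tree), `beta` (branches x dimensions), `lambda`,
#'   `root_estimate`, `fitted` and `tree`.
#' @export
rr_rates <- function(tree, Y, lambda = NULL) {
  tree <- validate_phylo(tree)
  if (is.null(dim(Y)))
    Y <- matrix(Y, ncol = 1L, dimnames = list(names(Y), NULL))
  Y <- align_matrix(tree, Y)
  n <- nrow(Y)
  C <- ape::vcv.phylo(tree)
  Cinv <- solve(C)
  a <- drop(rep(1, n) %*% Cinv %*% Y) / sum(Cinv)
  Yc <- sweep(Y, 2L, a)
  X <- tip_branch_design(tree)
  sv <- svd(X)
  d <- sv$d
  UtY <- crossprod(sv$u, Yc)
  loo_sse <- function(lam) {
    shrink <- d^2 / (d^2 + lam)
    hat <- rowSums(sweep(sv$u^2, 2L, shrink, "*"))
    resid <- Yc - sv$u %*% (shrink * UtY)
    sum((resid / pmax(1 - hat, 1e-12))^2)
  }
  if (is.null(lambda)) {
    scale0 <- mean(d^2)
    opt <- stats::optimize(function(u) loo_sse(10^u * scale0),
                           interval = c(-8, 3), tol = 1e-4)
    lambda <- 10^opt$minimum * scale0
  }
  beta <- sv$v %*% ((d / (d^2 + lambda)) * UtY)
  fitted <- sweep(X %*% beta, 2L, a, "+")
  structure(list(rates = sqrt(rowSums(beta^2)), beta = beta,
                 lambda = lambda, root_estimate = a, fitted = fitted,
                 tree = tree),
            class = "rate_field")
}

#' @export
print.rate_field <- function(x, ...) {
  cat("<rate_field> ", length(x$rates), " branches; lambda = ",
      signif(x$lambda, 4), "; mean rate magnitude = ",
      signif(mean(x$rates), 4), "\n", sep = "")
  invisible(x)
}

#' Randomization test for clade-level evolutionary rate shifts
#'
#' For every clade with between 2 and n/2 tips, the mean rate magnitude of
#' the clade's branches (including the clade's stem branch) is compared with
#' the mean over all remaining branches. The null distribution of the
#' difference is built by shuffling rate magnitudes across branches; the
#' two-tailed add-one p-value and a direction flag (higher / lower at
#' alpha = 0.05, else ns) are reported per clade, with an optional
#' Benjamini-Hochberg column (per-clade significance is reported raw).
#'
#' By default (`standardize = TRUE`) magnitudes are multiplied by the square
#' root of their branch length before the comparison: under Brownian motion
#' a branch's rate estimate has standard deviation proportional to
#' 1/sqrt(t), so raw magnitudes are systematically larger on short branches
#' and a global shuffle of raw magnitudes over-flags short-branch clades.
#' The standardized statistic is calibrated near the nominal level while a
#' genuine sigma-squared multiplier still scales it uniformly.
#'
#' @param tree a `phylo` (must be the tree the rates were computed on).
#' @param rates a `rate_field` from [rr_rates] (or a bare vector with one
#'   magnitude per edge).
#' @param n_rand number of randomizations.
#' @param seed RNG seed.
#' @param alpha significance level for the direction flag.
#' @param standardize length-standardize magnitudes (see Details).
#' @return a data.frame (class `clade_shift_report`) with one row per
#'   tested clade: `node`, `n_tips`, `tips`, `mean_clade`, `mean_rest`,
#'   `diff`, `p`, `p_adj`, `direction`.
#' @export
search_shift_clades <- function(tree, rates, n_rand = 1000L, seed = 1L,
                                alpha = 0.05, standardize = TRUE) {
  tree <- validate_phylo(tree)
  mags <- if (inherits(rates, "rate_field")) rates$rates else as.numeric(rates)
  m <- nrow(tree$edge)
  if (length(mags) != m)
    stop("rate field does not match the tree's branches", call. = FALSE)
  if (standardize) mags <- mags * sqrt(tree$edge.length)
  ntip <- length(tree$tip.label)
  nodes <- (ntip + 2L):(ntip + tree$Nnode)   # all non-root internal nodes
  keep <- list()
  for (v in nodes) {
    tips <- ape::extract.clade(tree, v)$tip.label
    if (length(tips) >= 2L && length(tips) <= ntip / 2)
      keep[[as.character(v)]] <- tips
  }
  if (!length(keep))
    stop("no clades within the allowed size range", call. = FALSE)
  # membership: edges of the subtree plus the stem edge of the clade node
  M <- matrix(FALSE, length(keep), m)
  for (i in seq_along(keep)) {
    v <- as.integer(names(keep)[i])
    desc <- descendant_nodes(tree, v)
    M[i, ] <- tree$edge[, 2L] %in% c(v, desc)
  }
  size_in <- rowSums(M)
  mean_in <- (M %*% mags) / size_in
  mean_out <- ((sum(mags) - M %*% mags)) / (m - size_in)
  obs <- drop(mean_in - mean_out)
  set.seed(seed)
  exceed <- numeric(length(obs))
  for (r in seq_len(n_rand)) {
    perm <- sample(mags)
    din <- (M %*% perm) / size_in
    dout <- (sum(perm) - M %*% perm) / (m - size_in)
    exceed <- exceed + (abs(din - dout) >= abs(obs) - 1e-15)
  }
  p <- (exceed + 1) / (n_rand + 1)
  direction <- ifelse(p <= alpha, ifelse(obs > 0, "higher", "lower"), "ns")
  out <- data.frame(node = as.integer(names(keep)),
                    n_tips = vapply(keep, length, 1L),
                    tips = vapply(keep, paste, "", collapse = ","),
                    mean_clade = drop(mean_in), mean_rest = drop(mean_out),
                    diff = obs, p = p,
                    p_adj = stats::p.adjust(p, "BH"),
                    direction = direction, row.names = NULL)
  class(out) <- c("clade_shift_report", "data.frame")
  out
}

descendant_nodes <- function(tree, node) {
  E <- tree$edge
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    ch <- E[E[, 1L] == v, 2L]
    out <- c(out, ch)
    stack <- c(stack, ch[ch > length(tree$tip.label)])
  }
  out
}

#' Size comparison between locomotor groups, with and without phylogeny
#'
#' Welch's two-sided t-test on log centroid size plus the simulation-based
#' phylogenetic ANOVA on the same data, reported together: the typical
#' pattern for clade-confounded size differences is a significant t-test
#' whose signal disappears once phylogeny is accounted for.
#'
#' @param log_cs named numeric vector of log centroid sizes over tips.
#' @param groups named factor/character over tips.
#' @param tree a `phylo`.
#' @param n_sim,seed passed to [phyl_anova].
#' @return list with `t_p`, `t_statistic`, `group_means`, `phyl_anova`.
#' @export
size_comparison <- function(log_cs, groups, tree, n_sim = 1000L, seed = 1L) {
  tree <- validate_phylo(tree)
  y <- align_trait(tree, log_cs)
  g <- factor(as.character(align_trait(tree, groups)))
  tt <- stats::t.test(y ~ g)
  pa <- phyl_anova(tree, groups, log_cs, n_sim = n_sim, seed = seed)
  list(t_p = tt$p.value, t_statistic = unname(tt$statistic),
       group_means = tapply(y, g, mean), phyl_anova = pa)
}
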