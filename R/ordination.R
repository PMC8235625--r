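flip_axes <- function(rotation, scores) {
  for (j in seq_len(ncol(rotation))) {
    i <- which.max(abs(rotation[, j]))
    if (rotation[i, j] < 0) {
      rotation[, j] <- -rotation[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(rotation = rotation, scores = scores)
}

#' Principal component analysis of shape data
#'
#' Centered PCA of flattened Procrustes shapes with a deterministic sign
#' convention (the largest-magnitude loading of every axis is positive).
#'
#' @param Y numeric matrix, one row per specimen/species.
#' @return an `ordination`: list with `scores`, `axes` (columns are unit
#'   loading vectors), `variance_fraction` (non-increasing, sums to 1),
#'   `center`.
#' @export
shape_pca <- function(Y) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 2L) stop("need at least 2 rows", call. = FALSE)
  pc <- stats::prcomp(Y, center = TRUE, scale. = FALSE)
  fl <- flip_axes(pc$rotation, pc$x)
  structure(list(scores = fl$scores, axes = fl$rotation,
                 variance_fraction = pc$sdev^2 / sum(pc$sdev^2),
                 center = pc$center),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat("<ordination> ", nrow(x$scores), " observations x ",
      ncol(x$scores), " axes; leading variance fractions: ",
      paste(signif(utils::head(x$variance_fraction, 3L), 3),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Project a phylogeny into an ordination (phylomorphospace)
#'
#' Estimates the score of every internal node on every axis by
#' maximum-likelihood Brownian ancestral-state reconstruction and attaches
#' the node scores plus the tree's edge list, ready for plotting tip scores
#' with branches drawn between them.
#'
#' @param tree a `phylo` whose tips are (a subset of) the score rows.
#' @param ordination an `ordination` with species rownames on `scores`, or
#'   a bare score matrix.
#' @return the ordination with `node_scores` (internal nodes x axes, rownames
#'   are ape node numbers) and `edges` added.
#' @export
phylomorphospace <- function(tree, ordination) {
  tree <- validate_phylo(tree)
  ord <- if (inherits(ordination, "ordination")) ordination
         else structure(list(scores = as.matrix(ordination)),
                        class = "ordination")
  S <- align_matrix(tree, ord$scores)
  node_scores <- vapply(seq_len(ncol(S)), function(j)
    unname(phytools::fastAnc(tree, stats::setNames(S[, j], rownames(S)))),
    numeric(tree$Nnode))
  node_scores <- matrix(node_scores, tree$Nnode, ncol(S))
  ntip <- length(tree$tip.label)
  dimnames(node_scores) <- list((ntip + 1L):(ntip + tree$Nnode),
                                colnames(S))
  ord$node_scores <- node_scores
  ord$edges <- tree$edge
  ord
}

#' Between-group principal component analysis
#'
#' Eigenanalysis of the covariance of the group mean vectors (equal group
#' weights), with every specimen projected onto the resulting axes. With two
#' groups there is exactly one axis, collinear with the difference of the
#' group means.
#'
#' @param Y data matrix (rows = specimens).
#' @param groups factor/character of group membership.
#' @return an `ordination` with `scores`, `axes`, `variance_fraction`
#'   (among group means), `center` (grand mean of group means),
#'   `group_means` and `groups`.
#' @export
between_group_pca <- function(Y, groups) {
  Y <- as.matrix(Y)
  g <- factor(as.character(groups))
  if (nlevels(g) < 2L)
    stop("between-group PCA needs at least two groups", call. = FALSE)
  means <- rowsum(Y, g) / as.vector(table(g))
  center <- colMeans(means)
  Mc <- sweep(means, 2L, center)
  if (sum(Mc^2) < 1e-24)
    stop("groups have identical means: no between-group variance",
         call. = FALSE)
  eg <- eigen(crossprod(Mc) / (nlevels(g) - 1L), symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  axes <- eg$vectors[, pos, drop = FALSE]
  scores <- sweep(Y, 2L, center) %*% axes
  fl <- flip_axes(axes, scores)
  colnames(fl$scores) <- paste0("bgPC", seq_len(ncol(fl$scores)))
  rownames(fl$scores) <- rownames(Y)
  structure(list(scores = fl$scores, axes = fl$rotation,
                 variance_fraction = eg$values[pos] / sum(eg$values[pos]),
                 center = center, group_means = means, groups = g),
            class = "ordination")
}

wilson_typicality <- function(d2, N, p) {
  if (N <= p) return(NA_real_)
  f <- (N * (N - p)) / (p * (N + 1) * (N - 1)) * d2
  stats::pf(f, p, N - p, lower.tail = FALSE)
}

#' Typicality-probability classification with small-sample correction
#'
#' Each specimen's squared Mahalanobis distance to every group mean (pooled
#' within-group covariance) is converted into a typicality probability by
#' the small-sample F transformation; the specimen is assigned to the group
#' with the highest probability. With `cross_validate = TRUE` the evaluated
#' specimen is excluded from its own group's mean and from the pooled
#' covariance, the leave-one-out scheme appropriate for small samples.
#' Specimens whose best typicality falls below `atypical_below` are flagged
#' but still assigned by argmax.
#'
#' @param scores numeric matrix (n x p), e.g. between-group PC scores.
#' @param groups factor/character of true group membership.
#' @param cross_validate leave-one-out evaluation (default TRUE).
#' @param atypical_below flag threshold for the best typicality.
#' @return a `classification_report`: list with `table` (per specimen:
#'   true group, assigned group, typicality per group, atypical flag) and
#'   `accuracy` (percent correctly classified).
#' @export
classify_typicality <- function(scores, groups, cross_validate = TRUE,
                                atypical_below = 0.05) {
  X <- as.matrix(scores)
  n <- nrow(X); p <- ncol(X)
  g <- factor(as.character(groups))
  n_j <- table(g)
  if (any(n_j <= p + cross_validate))
    stop("group sizes must exceed the score dimensionality (",
         p, "); reduce the number of axes first", call. = FALSE)
  lev <- levels(g)
  pooled <- function(exclude = 0L) {
    S <- matrix(0, p, p)
    df <- 0L
    for (l in lev) {
      idx <- setdiff(which(g == l), exclude)
      Xi <- X[idx, , drop = FALSE]
      S <- S + crossprod(sweep(Xi, 2L, colMeans(Xi)))
      df <- df + length(idx) - 1L
    }
    S / df
  }
  probs <- matrix(NA_real_, n, length(lev), dimnames = list(rownames(X), lev))
  for (i in seq_len(n)) {
    excl <- if (cross_validate) i else 0L
    S <- pooled(excl)
    Sinv <- tryCatch(solve(S), error = function(e)
      stop("singular pooled covariance; reduce the score dimensionality",
           call. = FALSE))
    for (l in lev) {
      idx <- setdiff(which(g == l), excl)
      mu <- colMeans(X[idx, , drop = FALSE])
      d2 <- drop(t(X[i, ] - mu) %*% Sinv %*% (X[i, ] - mu))
      probs[i, l] <- wilson_typicality(d2, length(idx), p)
    }
  }
  assigned <- lev[max.col(probs, ties.method = "first")]
  tab <- data.frame(specimen = if (!is.null(rownames(X))) rownames(X)
                    else paste0("specimen_", seq_len(n)),
                    group = as.character(g), assigned = assigned,
                    atypical = apply(probs, 1L, max) < atypical_below,
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(probs))
  structure(list(table = tab,
                 accuracy = 100 * mean(assigned == as.character(g)),
                 cross_validated = cross_validate),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report> accuracy ", round(x$accuracy, 1), "% (",
      if (x$cross_validated) "cross-validated" else "resubstitution",
      ", n = ", nrow(x$table), ")\n", sep = "")
  invisible(x)
}

#' Between-group PCA classification with full cross-validation
#'
#' Combines [between_group_pca] and [classify_typicality]. With
#' `cross_validate = TRUE` the *entire* chain is left-one-out: for every
#' specimen the between-group axes are recomputed without it, the specimen
#' is projected onto those axes, and its typicality is evaluated against
#' group statistics that exclude it. This removes the well-known
#' between-group-PCA overfitting artifact (axes computed from all labels
#' leak group information), so shuffled labels yield chance-level accuracy.
#'
#' @param Y data matrix (rows = specimens), e.g. retained PC scores.
#' @param groups factor/character of group membership.
#' @param cross_validate leave-one-out over axes and classifier (default).
#' @return a `classification_report` (see [classify_typicality]) with the
#'   full-sample `ordination` attached as `$ordination`.
#' @export
bg_classify <- function(Y, groups, cross_validate = TRUE) {
  Y <- as.matrix(Y)
  g <- factor(as.character(groups))
  ord <- between_group_pca(Y, g)
  if (!cross_validate) {
    rep <- classify_typicality(ord$scores, g, cross_validate = FALSE)
    rep$ordination <- ord
    return(rep)
  }
  n <- nrow(Y)
  lev <- levels(g)
  probs <- matrix(NA_real_, n, length(lev),
                  dimnames = list(rownames(Y), lev))
  for (i in seq_len(n)) {
    ord_i <- between_group_pca(Y[-i, , drop = FALSE], g[-i])
    s_i <- drop((Y[i, ] - ord_i$center) %*% ord_i$axes)
    S_train <- ord_i$scores
    p <- ncol(S_train)
    # pooled within-group covariance of the training scores
    Sp <- matrix(0, p, p); df <- 0L
    for (l in lev) {
      Xi <- S_train[g[-i] == l, , drop = FALSE]
      Sp <- Sp + crossprod(sweep(Xi, 2L, colMeans(Xi)))
      df <- df + nrow(Xi) - 1L
    }
    Sp <- Sp / df
    Sinv <- solve(Sp)
    for (l in lev) {
      Xi <- S_train[g[-i] == l, , drop = FALSE]
      mu <- colMeans(Xi)
      d2 <- drop(t(s_i - mu) %*% Sinv %*% (s_i - mu))
      probs[i, l] <- wilson_typicality(d2, nrow(Xi), p)
    }
  }
  assigned <- lev[max.col(probs, ties.method = "first")]
  tab <- data.frame(specimen = if (!is.null(rownames(Y))) rownames(Y)
                    else paste0("specimen_", seq_len(n)),
                    group = as.character(g), assigned = assigned,
                    atypical = apply(probs, 1L, max) < 0.05,
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(probs))
  structure(list(table = tab,
                 accuracy = 100 * mean(assigned == as.character(g)),
                 cross_validated = TRUE, ordination = ord),
            class = "classification_report")
}

#' Permutation test of the distance between group mean shapes
#'
#' Observed Euclidean distance between the two group mean vectors, tested by
#' randomly permuting group labels (group sizes preserved); the p-value is
#' one-tailed (large distances indicate separation) with the add-one rule.
#'
#' @param Y data matrix (rows = specimens/species).
#' @param groups factor/character with exactly two levels.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list with `distance`, `p`, `n_perm`.
#' @export
permutation_group_distance <- function(Y, groups, n_perm = 10000L,
                                       seed = 1L) {
  Y <- as.matrix(Y)
  g <- factor(as.character(groups))
  if (nlevels(g) != 2L) stop("exactly two groups required", call. = FALSE)
  dist_between <- function(gg) {
    m <- rowsum(Y, gg) / as.vector(table(gg))
    sqrt(sum((m[1L, ] - m[2L, ])^2))
  }
  obs <- dist_between(g)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) dist_between(sample(g)), 0)
  list(distance = obs, p = (sum(perm >= obs - 1e-15) + 1) / (n_perm + 1),
       n_perm = n_perm)
}

#' Landmark configurations at the extremes of an ordination axis
#'
#' Reconstructs the shape at chosen score quantiles of one axis:
#' `center + score * axis`, reshaped to k x 3 landmarks — the endpoint
#' shapes used to visualize what an axis (e.g. the between-group axis)
#' means anatomically. If the ordination lives in a reduced PC space, pass
#' the PC `basis` (list with `center` and `rotation`) to map back to shape
#' space.
#'
#' @param ordination an `ordination`.
#' @param axis axis index.
#' @param quantiles two score quantiles (default the observed extremes).
#' @param basis optional list(center, rotation) mapping the ordination's
#'   space back to flattened shape space.
#' @param mesh optional reference `surface_mesh` digitized in consensus
#'   shape space; if supplied, TPS-warped copies matching each endpoint are
#'   returned.
#' @param reference optional k x 3 consensus landmarks for the mesh warp.
#' @return list with `low`, `high` (k x 3 matrices), `scores` used, and
#'   optionally `mesh_low`, `mesh_high`.
#' @export
axis_endpoint_shapes <- function(ordination, axis = 1L,
                                 quantiles = c(0, 1), basis = NULL,
                                 mesh = NULL, reference = NULL) {
  stopifnot(inherits(ordination, "ordination"))
  if (axis > ncol(ordination$axes)) stop("invalid axis index", call. = FALSE)
  s <- stats::quantile(ordination$scores[, axis], quantiles, names = FALSE)
  vecs <- lapply(s, function(si)
    ordination$center + si * ordination$axes[, axis])
  if (!is.null(basis))
    vecs <- lapply(vecs, function(v)
      basis$center + drop(basis$rotation %*% v))
  to_config <- function(v) matrix(v, ncol = 3L)
  out <- list(low = to_config(vecs[[1L]]), high = to_config(vecs[[2L]]),
              scores = s)
  if (!is.null(mesh)) {
    if (is.null(reference))
      stop("mesh warping needs the consensus `reference`", call. = FALSE)
    tps <- tps_build(reference)
    for (side in c("low", "high")) {
      w <- mesh
      w$vertices <- tps_warp(reference, out[[side]], mesh$vertices,
                             tps = tps)
      out[[paste0("mesh_", side)]] <- w
    }
  }
  out
}
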