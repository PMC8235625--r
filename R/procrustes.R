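#' Ordinary Procrustes superimposition of two configurations
#'
#' Least-squares rigid (optionally scaled) superimposition of `source` onto
#' `target`. Only proper rotations are allowed (determinant +1): left/right
#' structures are never mirrored implicitly.
#'
#' @param source,target k x 3 matrices with matching landmark order.
#' @param allow_scale if `TRUE` a uniform scale factor is also fitted.
#' @return a list with `rotation` (3 x 3), `scale`, `translation`,
#'   `residual` (root summed squared distances after fitting) and `aligned`
#'   (the transformed source). The fitted map is
#'   `aligned = scale * (source - centroid_s) %*% rotation + centroid_t`.
#' @export
ordinary_procrustes <- function(source, target, allow_scale = TRUE) {
  X <- as_points_matrix(source)
  Y <- as_points_matrix(target)
  if (!identical(dim(X), dim(Y)))
    stop("source and target must have the same dimensions", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(Y)))
    stop("non-finite coordinates", call. = FALSE)
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2L, cx); Y0 <- sweep(Y, 2L, cy)
  nx <- sqrt(sum(X0^2))
  if (nx < 1e-12 || sqrt(sum(Y0^2)) < 1e-12)
    stop("degenerate configuration: all points coincident", call. = FALSE)
  M <- crossprod(X0, Y0)
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  s <- if (allow_scale) sum(diag(D) * sv$d) / sum(X0^2) else 1
  aligned <- s * X0 %*% R
  aligned <- sweep(aligned, 2L, cy, "+")
  res <- sqrt(sum((aligned - Y)^2))
  list(rotation = R, scale = s, translation = cy - s * drop(cx %*% R),
       residual = res, aligned = aligned)
}

scale_to_unit_cs <- function(m) {
  m <- sweep(m, 2L, colMeans(m))
  m / sqrt(sum(m^2))
}

#' Generalized Procrustes analysis
#'
#' Iterative full-Procrustes superimposition: every configuration is
#' centered, scaled to unit centroid size, and rotated to the running
#' consensus; the consensus is re-estimated (and itself re-scaled to unit
#' centroid size) until it changes by less than `tol` or `max_iter` is hit.
#' Raw centroid sizes are recorded before scaling.
#'
#' @param configs a list of [landmark_config] (identical landmark layout) or
#'   an n x k x 3 array.
#' @param tol convergence tolerance on the root-summed-squared change of the
#'   consensus between iterations.
#' @param max_iter iteration cap.
#' @return an `aligned_sample`: list with `shapes` (n x k x 3 array, each
#'   centered with centroid size 1), `centroid_sizes`, `consensus` (k x 3,
#'   unit centroid size), `converged`, `iterations`, and the input ids.
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 100L) {
  arr <- configs_to_array(configs)
  n <- dim(arr)[1L]; k <- dim(arr)[2L]
  if (n < 1L) stop("need at least one configuration", call. = FALSE)
  cs <- apply(arr, 1L, function(m) centroid_size(m))
  shapes <- array(0, dim(arr), dimnames = dimnames(arr))
  for (i in seq_len(n)) shapes[i, , ] <- scale_to_unit_cs(arr[i, , ])
  consensus <- scale_to_unit_cs(shapes[1L, , ])
  iterations <- 0L; converged <- FALSE
  if (n == 1L) {
    converged <- TRUE
  } else {
    for (it in seq_len(max_iter)) {
      for (i in seq_len(n)) {
        fit <- ordinary_procrustes(shapes[i, , ], consensus,
                                   allow_scale = FALSE)
        shapes[i, , ] <- scale_to_unit_cs(fit$aligned)
      }
      new_cons <- scale_to_unit_cs(apply(shapes, c(2L, 3L), mean))
      delta <- sqrt(sum((new_cons - consensus)^2))
      consensus <- new_cons
      iterations <- it
      if (delta < tol) { converged <- TRUE; break }
    }
  }
  structure(list(shapes = shapes, centroid_sizes = cs,
                 consensus = consensus, converged = converged,
                 iterations = iterations,
                 specimen_id = rownames_or(arr, "specimen"),
                 meta = attr(arr, "meta")),
            class = "aligned_sample")
}

#' @export
print.aligned_sample <- function(x, ...) {
  cat("<aligned_sample> ", dim(x$shapes)[1L], " shapes x ",
      dim(x$shapes)[2L], " landmarks; ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$iterations, " iterations\n", sep = "")
  invisible(x)
}

configs_to_array <- function(configs) {
  if (is.array(configs) && length(dim(configs)) == 3L) {
    arr <- configs
    storage.mode(arr) <- "double"
    return(arr)
  }
  if (inherits(configs, "landmark_config")) configs <- list(configs)
  k <- unname(vapply(configs, function(cf) nrow(as_points_matrix(cf)), 1L))
  if (length(unique(k)) != 1L)
    stop("configurations have mismatched landmark counts: ",
         paste(unique(k), collapse = ", "), call. = FALSE)
  n <- length(configs)
  arr <- array(0, c(n, k[1L], 3L))
  ids <- character(n)
  for (i in seq_len(n)) {
    arr[i, , ] <- as_points_matrix(configs[[i]])
    ids[i] <- if (inherits(configs[[i]], "landmark_config"))
      configs[[i]]$specimen_id else paste0("specimen_", i)
  }
  dimnames(arr) <- list(ids, NULL, c("x", "y", "z"))
  if (inherits(configs[[1L]], "landmark_config"))
    attr(arr, "meta") <- configs[[1L]][c("roles", "curve_id", "order_index")]
  arr
}

rownames_or <- function(arr, prefix) {
  if (!is.null(dimnames(arr)[[1L]])) dimnames(arr)[[1L]]
  else paste0(prefix, "_", seq_len(dim(arr)[1L]))
}

#' Species mean forms
#'
#' For every species, the specimens are superimposed by [gpa] and the mean
#' form is the Procrustes consensus multiplied by the arithmetic mean of the
#' specimens' raw centroid sizes; the mean centroid size is reported
#' alongside.
#'
#' @param configs list of [landmark_config] (their `species_id` fields group
#'   them), or an n x k x 3 array plus a `species` vector.
#' @param species optional character vector overriding the species grouping.
#' @return a `species_mean_set`: named list with one entry per species,
#'   each a list `mean_form` (k x 3, centroid size = mean_cs), `mean_cs`,
#'   `n_specimens`.
#' @export
species_mean_forms <- function(configs, species = NULL) {
  if (is.null(species)) {
    if (is.array(configs))
      stop("`species` is required when `configs` is an array", call. = FALSE)
    species <- vapply(configs, function(cf) cf$species_id, "")
  }
  arr <- configs_to_array(configs)
  out <- lapply(split(seq_along(species), species), function(idx) {
    sub <- arr[idx, , , drop = FALSE]
    fit <- gpa(sub)
    mean_cs <- mean(fit$centroid_sizes)
    list(mean_form = fit$consensus * mean_cs, mean_cs = mean_cs,
         n_specimens = length(idx))
  })
  structure(out, class = "species_mean_set")
}

#' Flatten species mean shapes into a species x (3k) matrix
#'
#' Superimposes the mean forms of a `species_mean_set` by [gpa] and returns
#' the aligned shapes as row vectors (x-block, y-block, z-block), the usual
#' input for the comparative analyses.
#'
#' @param means a `species_mean_set`.
#' @return list with `shapes` (matrix, one row per species), `log_cs`
#'   (named vector of log mean centroid sizes) and `consensus`.
#' @export
flatten_species_means <- function(means) {
  stopifnot(inherits(means, "species_mean_set"))
  arr <- array(0, c(length(means), nrow(means[[1L]]$mean_form), 3L))
  for (i in seq_along(means)) arr[i, , ] <- means[[i]]$mean_form
  dimnames(arr) <- list(names(means), NULL, c("x", "y", "z"))
  fit <- gpa(arr)
  Y <- t(apply(fit$shapes, 1L, as.vector))
  rownames(Y) <- names(means)
  list(shapes = Y,
       log_cs = stats::setNames(log(vapply(means, `[[`, 1, "mean_cs")),
                                names(means)),
       consensus = fit$consensus)
}
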