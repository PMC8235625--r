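#' Build a 3D thin-plate spline from a reference configuration
#'
#' Sets up the bordered TPS kernel system for the 3D kernel phi(r) = -r (the
#' sign convention under which bending energy is non-negative) and returns
#' both the interpolation machinery and the bending-energy matrix.
#' The bending-energy matrix is the landmark block of the inverse bordered
#' system; its rows and columns annihilate affine configurations, so any
#' affine deformation of the reference has bending energy zero. Eigenvalues
#' in [-1e-10, 0) arising from roundoff are clipped to 0 so the matrix is
#' positive semidefinite.
#'
#' @param reference k x 3 matrix (k >= 4, spanning 3 dimensions).
#' @return an object of class `tps3d` with elements `reference`,
#'   `bending_energy` (k x k) and the inverse bordered system used by
#'   [tps_warp] and [bending_energy].
#' @export
tps_build <- function(reference) {
  X <- as_points_matrix(reference)
  k <- nrow(X)
  if (k < 4L) stop("TPS needs at least 4 landmarks", call. = FALSE)
  if (!all(is.finite(X))) stop("non-finite coordinates", call. = FALSE)
  P <- cbind(1, X)
  if (qr(P)$rank < 4L)
    stop("singular kernel: reference landmarks are coplanar or collinear",
         call. = FALSE)
  # 3D kernel phi(r) = -r: the sign that makes the landmark block of the
  # inverse bordered system positive semidefinite (with +r the same block is
  # negative semidefinite and the interpolant is unchanged)
  K <- -as.matrix(stats::dist(X))
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4L, 4L)))
  Linv <- tryCatch(solve(L), error = function(e)
    stop("singular kernel system: ", conditionMessage(e), call. = FALSE))
  Lb <- Linv[seq_len(k), seq_len(k), drop = FALSE]
  Lb <- (Lb + t(Lb)) / 2
  eg <- eigen(Lb, symmetric = TRUE)
  vals <- eg$values
  neg <- vals < 0
  if (any(vals < -1e-10 * max(abs(vals))))
    warning("bending-energy matrix has substantially negative eigenvalues; ",
            "clipping to PSD")
  vals[neg] <- 0
  Lb <- eg$vectors %*% (vals * t(eg$vectors))
  Lb <- (Lb + t(Lb)) / 2
  structure(list(reference = X, k = k, Linv = Linv, bending_energy = Lb),
            class = "tps3d")
}

#' Bending energy of a target configuration
#'
#' The non-affine deformation energy of mapping the spline's reference onto
#' `target`: the quadratic form `t(y) %*% Lb %*% y` summed over the three
#' coordinate axes, with `Lb` the bending-energy matrix of the reference.
#'
#' @param tps a `tps3d` object from [tps_build] (or a bare k x k
#'   bending-energy matrix).
#' @param target k x 3 matrix.
#' @return a non-negative scalar.
#' @export
bending_energy <- function(tps, target) {
  Lb <- if (inherits(tps, "tps3d")) tps$bending_energy else as.matrix(tps)
  Y <- as_points_matrix(target)
  sum(vapply(1:3, function(j) drop(crossprod(Y[, j], Lb %*% Y[, j])), 0))
}

#' Warp arbitrary points with a thin-plate spline
#'
#' Builds the TPS interpolant taking `reference` exactly onto `target` and
#' evaluates it at `query_points` — used for surface-patch transfer and for
#' warping meshes to reconstructed landmark configurations.
#'
#' @param reference,target k x 3 matrices; `tps_warp` maps reference
#'   landmarks exactly to the target landmarks.
#' @param query_points m x 3 matrix of points to deform.
#' @param tps optionally a prebuilt `tps3d` for `reference`.
#' @return m x 3 matrix of warped points.
#' @export
tps_warp <- function(reference, target, query_points, tps = NULL) {
  if (is.null(tps)) tps <- tps_build(reference)
  Y <- as_points_matrix(target)
  if (nrow(Y) != tps$k)
    stop("target must match the reference landmark count", call. = FALSE)
  Q <- as_points_matrix(query_points)
  rhs <- rbind(Y, matrix(0, 4L, 3L))
  coefs <- tps$Linv %*% rhs               # k weights + 4 affine rows, per axis
  W <- coefs[seq_len(tps$k), , drop = FALSE]
  A <- coefs[tps$k + 1:4, , drop = FALSE]
  # distances from every query point to every reference landmark
  D2 <- outer(rowSums(Q^2), rep(1, tps$k)) +
    outer(rep(1, nrow(Q)), rowSums(tps$reference^2)) -
    2 * Q %*% t(tps$reference)
  D2[D2 < 0 | is.nan(D2)] <- 0
  cbind(1, Q) %*% A - sqrt(D2) %*% W      # kernel phi(r) = -r
}
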