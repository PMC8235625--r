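#' Resample a polyline to equally spaced points
#'
#' Places `n` points at equal arc-length spacing along the piecewise-linear
#' curve through the input points; the first and last points are preserved
#' exactly. This is the resampling applied to every digitized curve before
#' sliding.
#'
#' @param polyline ordered m x 3 matrix (m >= 2).
#' @param n number of output points (n >= 2).
#' @return n x 3 matrix.
#' @export
resample_curve <- function(polyline, n) {
  P <- as_points_matrix(polyline)
  if (nrow(P) < 2L || n < 2L)
    stop("need at least 2 input and 2 output points", call. = FALSE)
  seg <- sqrt(rowSums(diff(P)^2))
  if (sum(seg) < 1e-300)
    stop("degenerate curve: zero total length", call. = FALSE)
  s <- c(0, cumsum(seg))
  targets <- seq(0, s[length(s)], length.out = n)
  out <- matrix(0, n, 3L)
  out[1L, ] <- P[1L, ]
  out[n, ] <- P[nrow(P), ]
  for (i in seq(2L, n - 1L)) {
    j <- findInterval(targets[i], s, rightmost.closed = TRUE)
    w <- (targets[i] - s[j]) / (s[j + 1L] - s[j])
    out[i, ] <- (1 - w) * P[j, ] + w * P[j + 1L, ]
  }
  out
}

project_to_polyline <- function(points, polyline) {
  P <- as_points_matrix(points)
  L <- as_points_matrix(polyline)
  A <- L[-nrow(L), , drop = FALSE]
  B <- L[-1L, , drop = FALSE]
  AB <- B - A
  len2 <- rowSums(AB^2)
  len2[len2 < 1e-300] <- 1e-300
  out <- P
  for (i in seq_len(nrow(P))) {
    t <- pmin(1, pmax(0, rowSums(sweep(-A, 2L, P[i, ], "+") * AB) / len2))
    cand <- A + t * AB
    j <- which.min(rowSums(sweep(cand, 2L, P[i, ])^2))
    out[i, ] <- cand[j, ]
  }
  out
}

#' Template atlas for semilandmark patching
#'
#' Bundles the fully digitized template specimen (fixed landmarks, resampled
#' curves, surface semilandmarks) with its triangulated mesh; used by
#' [place_patch] to transfer surface semilandmarks to every other specimen.
#'
#' @param config the template [landmark_config] (all three roles present).
#' @param mesh the template `surface_mesh`.
#' @return an object of class `template_atlas`.
#' @export
template_atlas <- function(config, mesh) {
  stopifnot(inherits(config, "landmark_config"),
            inherits(mesh, "surface_mesh"))
  if (!any(config$roles == "surface"))
    stop("template must carry surface semilandmarks", call. = FALSE)
  curve_counts <- table(config$curve_id[config$roles == "curve"])
  structure(list(config = config, mesh = mesh,
                 curve_counts = curve_counts,
                 surface_count = sum(config$roles == "surface")),
            class = "template_atlas")
}

#' Sliding plan: tangent bases for every semilandmark
#'
#' Curve semilandmarks slide along one tangent vector, the normalized chord
#' between their neighbours on the same curve (one-sided at curve ends).
#' Surface semilandmarks slide in the tangent plane of the specimen mesh,
#' spanned by two orthonormal vectors orthogonal to the nearest vertex
#' normal. Fixed landmarks do not slide.
#'
#' @param config a [landmark_config].
#' @param mesh the specimen `surface_mesh` (required if surface points are
#'   present).
#' @return list with `t1`, `t2` (k x 3 matrices, zero rows where a direction
#'   does not apply) and `n_par` (number of sliding parameters).
#' @export
sliding_plan <- function(config, mesh = NULL) {
  pts <- config$points
  k <- nrow(pts)
  t1 <- matrix(0, k, 3L)
  t2 <- matrix(0, k, 3L)
  is_curve <- config$roles == "curve"
  for (cid in unique(config$curve_id[is_curve])) {
    idx <- which(is_curve & config$curve_id == cid)
    idx <- idx[order(config$order_index[idx])]
    m <- length(idx)
    for (j in seq_len(m)) {
      lo <- idx[max(1L, j - 1L)]
      hi <- idx[min(m, j + 1L)]
      v <- pts[hi, ] - pts[lo, ]
      nv <- sqrt(sum(v^2))
      if (nv > 1e-300) t1[idx[j], ] <- v / nv
    }
  }
  is_surf <- config$roles == "surface"
  if (any(is_surf)) {
    if (is.null(mesh))
      stop("surface semilandmarks need the specimen mesh", call. = FALSE)
    VN <- vertex_normals(mesh)
    for (i in which(is_surf)) {
      d2 <- rowSums(sweep(mesh$vertices, 2L, pts[i, ])^2)
      n <- VN[which.min(d2), ]
      # orthonormal complement of the normal
      ref <- if (abs(n[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      u <- ref - sum(ref * n) * n
      u <- u / sqrt(sum(u^2))
      w <- c(n[2L] * u[3L] - n[3L] * u[2L],
             n[3L] * u[1L] - n[1L] * u[3L],
             n[1L] * u[2L] - n[2L] * u[1L])
      t1[i, ] <- u
      t2[i, ] <- w / sqrt(sum(w^2))
    }
  }
  list(t1 = t1, t2 = t2,
       n_par = sum(is_curve) + 2L * sum(is_surf))
}

#' Patch surface semilandmarks from a template onto a specimen
#'
#' Warps the template's surface semilandmarks to the specimen with a
#' thin-plate spline built on the fixed + curve correspondences, then
#' projects every warped point onto the specimen mesh, so all surface points
#' lie on the specimen surface.
#'
#' @param atlas a [template_atlas].
#' @param specimen a [landmark_config] with all fixed and curve points
#'   digitized; its surface rows (if present) are replaced, otherwise
#'   surface rows are appended in template order.
#' @param mesh the specimen's `surface_mesh`.
#' @return the specimen [landmark_config] with surface points filled in.
#' @export
place_patch <- function(atlas, specimen, mesh) {
  stopifnot(inherits(atlas, "template_atlas"))
  if (is.null(mesh)) stop("specimen mesh is required", call. = FALSE)
  tc <- atlas$config
  scaffold_t <- tc$roles != "surface"
  scaffold_s <- specimen$roles != "surface"
  if (sum(scaffold_t) != sum(scaffold_s))
    stop("specimen fixed+curve layout does not match the template",
         call. = FALSE)
  warped <- tps_warp(tc$points[scaffold_t, , drop = FALSE],
                     specimen$points[scaffold_s, , drop = FALSE],
                     tc$points[!scaffold_t, , drop = FALSE])
  proj <- mesh_closest_points(mesh, warped)
  if (any(specimen$roles == "surface")) {
    pts <- specimen$points
    pts[specimen$roles == "surface", ] <- proj$points
    cfg <- specimen
    cfg$points <- pts
  } else {
    cfg <- landmark_config(
      points = rbind(specimen$points, proj$points),
      roles = c(specimen$roles, rep("surface", nrow(proj$points))),
      specimen_id = specimen$specimen_id, species_id = specimen$species_id,
      curve_id = c(specimen$curve_id, rep(NA_integer_, nrow(proj$points))),
      order_index = c(specimen$order_index,
                      rep(NA_integer_, nrow(proj$points))),
      mesh = mesh)
  }
  cfg$mesh <- mesh
  cfg
}

#' One bending-energy sliding (relaxation) step
#'
#' Slides the specimen's semilandmarks along their tangent directions to
#' minimize the thin-plate-spline bending energy between the reference and
#' the specimen. With `y` the stacked specimen coordinates, `x` the stacked
#' reference (superimposed on the specimen), `U` the block tangent-basis
#' matrix and `B` the three-axis block-diagonal bending-energy form of the
#' reference, the sliding amplitudes are the exact generalized-least-squares
#' minimizer `t* = -(U'BU)^-1 U'B (y - x)`. Slid curve points are then
#' re-projected onto the specimen's curve polylines and surface points onto
#' the specimen mesh; fixed landmarks are untouched.
#'
#' @param specimen a [landmark_config].
#' @param reference k x 3 matrix (template or consensus), same layout.
#' @param mesh specimen `surface_mesh` (for surface projection).
#' @param slide_curves slide curve semilandmarks too (default) or only
#'   surface points.
#' @param project re-project onto curve/mesh after sliding (default TRUE).
#' @return list with `config` (slid [landmark_config]), `energy_before`,
#'   `energy_after`, and the amplitude vector `t`.
#' @export
relax_once <- function(specimen, reference, mesh = specimen$mesh,
                       slide_curves = TRUE, project = TRUE) {
  ref <- as_points_matrix(reference)
  pts <- specimen$points
  k <- nrow(pts)
  if (nrow(ref) != k) stop("reference layout mismatch", call. = FALSE)
  fit <- ordinary_procrustes(ref, pts, allow_scale = TRUE)
  x <- fit$aligned
  tps <- tps_build(x)
  B <- tps$bending_energy
  plan <- sliding_plan(specimen, mesh)
  slide1 <- if (slide_curves) specimen$roles %in% c("curve", "surface") else
    specimen$roles == "surface"
  slide2 <- specimen$roles == "surface"
  cols <- sum(slide1) + sum(slide2)
  e_before <- bending_energy(B, pts)
  if (cols == 0L)
    return(list(config = specimen, energy_before = e_before,
                energy_after = e_before, t = numeric(0)))
  # stacked order: all x, all y, all z;  B3 = blockdiag(B, B, B)
  U <- matrix(0, 3L * k, cols)
  key <- integer(cols)   # landmark index per column
  j <- 0L
  for (i in which(slide1)) {
    j <- j + 1L
    U[c(i, k + i, 2L * k + i), j] <- plan$t1[i, ]
    key[j] <- i
  }
  for (i in which(slide2)) {
    j <- j + 1L
    U[c(i, k + i, 2L * k + i), j] <- plan$t2[i, ]
    key[j] <- i
  }
  d <- as.vector(pts - x)               # y - x, stacked column-major
  BU <- rbind(B %*% U[seq_len(k), , drop = FALSE],
              B %*% U[k + seq_len(k), , drop = FALSE],
              B %*% U[2L * k + seq_len(k), , drop = FALSE])
  M <- crossprod(U, BU)
  rhs <- -crossprod(BU, d)
  tt <- tryCatch(solve(M, rhs), error = function(e) {
    warning("singular sliding system; using ridge-regularized solve")
    solve(M + diag(1e-8 * mean(diag(M)) + 1e-300, ncol(M)), rhs)
  })
  ynew <- d + as.vector(x) + U %*% tt
  newpts <- matrix(ynew, k, 3L)
  newpts[specimen$roles == "fixed", ] <- pts[specimen$roles == "fixed", ]
  if (project) {
    is_curve <- specimen$roles == "curve"
    if (slide_curves && any(is_curve)) {
      for (cid in unique(specimen$curve_id[is_curve])) {
        idx <- which(is_curve & specimen$curve_id == cid)
        idx <- idx[order(specimen$order_index[idx])]
        newpts[idx, ] <- project_to_polyline(newpts[idx, , drop = FALSE],
                                             pts[idx, , drop = FALSE])
      }
    }
    is_surf <- specimen$roles == "surface"
    if (any(is_surf)) {
      if (!is.null(mesh)) {
        proj <- mesh_closest_points(mesh, newpts[is_surf, , drop = FALSE])
        newpts[is_surf, ] <- proj$points
      }
    }
  }
  cfg <- specimen
  cfg$points <- newpts
  list(config = cfg, energy_before = e_before,
       energy_after = bending_energy(B, newpts), t = drop(tt))
}

#' Iterative relaxation against the Procrustes consensus
#'
#' Repeats (GPA of all specimens -> consensus -> one bending-energy sliding
#' step of every specimen against the consensus) for `iterations` rounds,
#' the final sliding stage of the semilandmark workflow.
#'
#' @param configs list of patched [landmark_config].
#' @param meshes optional list of specimen meshes (defaults to each
#'   config's `mesh` field).
#' @param iterations number of relaxation rounds (default 3).
#' @param slide_curves passed to [relax_once].
#' @param trace_file optional path: the per-iteration total bending energy is
#'   written there as JSON.
#' @return list with `configs` (slid configurations) and `trace` (total
#'   bending energy: initial value, then one entry after each iteration).
#' @export
relax_to_consensus <- function(configs, meshes = NULL, iterations = 3L,
                               slide_curves = TRUE, trace_file = NULL) {
  n <- length(configs)
  if (is.null(meshes)) meshes <- lapply(configs, function(cf) cf$mesh)
  total_energy <- function(cfgs, consensus) {
    sum(vapply(cfgs, function(cf) {
      al <- ordinary_procrustes(consensus, cf$points)$aligned
      bending_energy(tps_build(al), cf$points)
    }, 0))
  }
  fit <- gpa(configs)
  trace <- total_energy(configs, fit$consensus)
  for (it in seq_len(iterations)) {
    cons <- fit$consensus
    for (i in seq_len(n)) {
      configs[[i]] <- relax_once(configs[[i]], cons, mesh = meshes[[i]],
                                 slide_curves = slide_curves)$config
    }
    fit <- gpa(configs)
    trace <- c(trace, total_energy(configs, fit$consensus))
  }
  if (!is.null(trace_file))
    jsonlite::write_json(list(total_bending_energy = trace), trace_file,
                         auto_unbox = FALSE, digits = NA)
  list(configs = configs, trace = trace)
}

#' Average two replicate digitizations of one specimen
#'
#' Aligns the second digitization onto the first by ordinary Procrustes
#' superimposition (rotation + translation only, so the specimen's scale is
#' kept) and averages the coordinates, reducing digitization error before
#' patching.
#'
#' @param a,b two [landmark_config] of the same specimen and layout.
#' @return a [landmark_config] with averaged coordinates.
#' @export
average_replicates <- function(a, b) {
  if (!identical(dim(a$points), dim(b$points)))
    stop("replicates have different landmark layouts", call. = FALSE)
  fit <- ordinary_procrustes(b$points, a$points, allow_scale = FALSE)
  out <- a
  out$points <- (a$points + fit$aligned) / 2
  out
}
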