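#' Triangulated surface mesh
#'
#' A minimal container for triangulated surfaces: `vertices` (V x 3, mm) and
#' `faces` (F x 3 integer, 1-based vertex indices).
#'
#' @param vertices numeric V x 3 matrix.
#' @param faces integer F x 3 matrix of vertex indices.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("vertices and faces must each have 3 columns", call. = FALSE)
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range", call. = FALSE)
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " triangles\n", sep = "")
  invisible(x)
}

#' Read / write triangulated meshes (ASCII PLY and OBJ)
#'
#' Plain-text subsets of the two formats: PLY with `vertex` x/y/z and
#' triangular `face` elements, OBJ with `v` and triangular `f` records
#' (attribute suffixes like `f 1/1/1` are accepted and stripped).
#'
#' @param path file path; `read_mesh` dispatches on the extension.
#' @return a `surface_mesh`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         obj = read_obj(path),
         stop("unsupported mesh format: ", ext, call. = FALSE))
}

#' @rdname read_mesh
#' @export
read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1L], "ply")) stop("not a PLY file", call. = FALSE)
  if (!any(grepl("format ascii", lines[seq_len(5L)])))
    stop("only ASCII PLY is supported", call. = FALSE)
  endh <- match("end_header", trimws(lines))
  nv <- as.integer(sub(".*vertex\\s+", "",
                       grep("element vertex", lines, value = TRUE)[1L]))
  nf <- as.integer(sub(".*face\\s+", "",
                       grep("element face", lines, value = TRUE)[1L]))
  body <- lines[(endh + 1L):length(lines)]
  vrows <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  V <- do.call(rbind, lapply(vrows, function(r) as.numeric(r[1:3])))
  frows <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  Fc <- do.call(rbind, lapply(frows, function(r) {
    if (as.integer(r[1L]) != 3L)
      stop("non-triangular face in PLY", call. = FALSE)
    as.integer(r[2:4]) + 1L
  }))
  surface_mesh(V, Fc)
}

#' @rdname read_mesh
#' @export
read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  V <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                             function(r) as.numeric(r[2:4])))
  Fc <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(r) {
    idx <- unname(vapply(r[-1L], function(tok)
      as.integer(strsplit(tok, "/")[[1L]][1L]), 1L))
    if (length(idx) != 3L)
      stop("non-triangular face in OBJ", call. = FALSE)
    idx
  }))
  surface_mesh(V, Fc)
}

#' @param mesh a `surface_mesh`.
#' @rdname read_mesh
#' @export
write_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(format(mesh$vertices, digits = 9, trim = TRUE,
                          scientific = FALSE), 1L, paste, collapse = " "),
             con)
  writeLines(paste(3L, mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L,
                   mesh$faces[, 3L] - 1L), con)
  invisible(path)
}

#' @rdname read_mesh
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("v", mesh$vertices[, 1L], mesh$vertices[, 2L],
                   mesh$vertices[, 3L]), con)
  writeLines(paste("f", mesh$faces[, 1L], mesh$faces[, 2L],
                   mesh$faces[, 3L]), con)
  invisible(path)
}

#' Closest points on a triangulated mesh
#'
#' Exact point-to-triangle projection (Voronoi-region case analysis) over
#' all triangles, returning for each query point its closest point on the
#' mesh surface, the distance, and the triangle hit.
#'
#' @param mesh a `surface_mesh`.
#' @param points m x 3 matrix of query points.
#' @return list with `points` (m x 3 projected), `distance` (length m) and
#'   `face` (triangle index).
#' @export
mesh_closest_points <- function(mesh, points) {
  P <- as_points_matrix(points)
  V <- mesh$vertices; Fc <- mesh$faces
  A <- V[Fc[, 1L], , drop = FALSE]
  B <- V[Fc[, 2L], , drop = FALSE]
  C <- V[Fc[, 3L], , drop = FALSE]
  AB <- B - A; AC <- C - A; BC <- C - B
  m <- nrow(P)
  out <- matrix(0, m, 3L)
  dist <- numeric(m)
  face <- integer(m)
  for (i in seq_len(m)) {
    p <- P[i, ]
    AP <- sweep(-A, 2L, p, "+")
    BP <- sweep(-B, 2L, p, "+")
    CP <- sweep(-C, 2L, p, "+")
    d1 <- rowSums(AB * AP); d2 <- rowSums(AC * AP)
    d3 <- rowSums(AB * BP); d4 <- rowSums(AC * BP)
    d5 <- rowSums(AB * CP); d6 <- rowSums(AC * CP)
    va <- d3 * d6 - d5 * d4
    vb <- d5 * d2 - d1 * d6
    vc <- d1 * d4 - d3 * d2
    cand <- A   # default: vertex A region
    done <- d1 <= 0 & d2 <= 0
    reg <- !done & d3 >= 0 & d4 <= d3                     # vertex B
    cand[reg, ] <- B[reg, , drop = FALSE]; done <- done | reg
    reg <- !done & d6 >= 0 & d5 <= d6                     # vertex C
    cand[reg, ] <- C[reg, , drop = FALSE]; done <- done | reg
    reg <- !done & vc <= 0 & d1 >= 0 & d3 <= 0            # edge AB
    if (any(reg)) {
      v <- d1[reg] / (d1[reg] - d3[reg])
      cand[reg, ] <- A[reg, , drop = FALSE] + v * AB[reg, , drop = FALSE]
    }
    done <- done | reg
    reg <- !done & vb <= 0 & d2 >= 0 & d6 <= 0            # edge AC
    if (any(reg)) {
      w <- d2[reg] / (d2[reg] - d6[reg])
      cand[reg, ] <- A[reg, , drop = FALSE] + w * AC[reg, , drop = FALSE]
    }
    done <- done | reg
    reg <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0   # edge BC
    if (any(reg)) {
      w <- (d4[reg] - d3[reg]) / ((d4[reg] - d3[reg]) + (d5[reg] - d6[reg]))
      cand[reg, ] <- B[reg, , drop = FALSE] + w * BC[reg, , drop = FALSE]
    }
    done <- done | reg
    if (any(!done)) {                                     # interior
      denom <- 1 / (va[!done] + vb[!done] + vc[!done])
      v <- vb[!done] * denom; w <- vc[!done] * denom
      cand[!done, ] <- A[!done, , drop = FALSE] +
        v * AB[!done, , drop = FALSE] + w * AC[!done, , drop = FALSE]
    }
    d2all <- rowSums(sweep(cand, 2L, p)^2)
    j <- which.min(d2all)
    out[i, ] <- cand[j, ]
    dist[i] <- sqrt(d2all[j])
    face[i] <- j
  }
  list(points = out, distance = dist, face = face)
}

#' Area-weighted vertex normals of a mesh
#'
#' @param mesh a `surface_mesh`.
#' @return V x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  V <- mesh$vertices; Fc <- mesh$faces
  A <- V[Fc[, 1L], ]; B <- V[Fc[, 2L], ]; C <- V[Fc[, 3L], ]
  e1 <- B - A; e2 <- C - A
  fn <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  N <- matrix(0, nrow(V), 3L)
  for (c in 1:3) {
    for (ax in 1:3)
      N[, ax] <- N[, ax] + unname(tapply(fn[, ax], factor(Fc[, c],
                 levels = seq_len(nrow(V))), sum, default = 0))
  }
  N[is.na(N)] <- 0
  len <- sqrt(rowSums(N^2))
  len[len < 1e-300] <- 1
  N / len
}

bbox_diagonal <- function(mesh) {
  rng <- apply(mesh$vertices, 2L, range)
  sqrt(sum((rng[2L, ] - rng[1L, ])^2))
}
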