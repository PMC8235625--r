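#' Landmark configuration for one specimen
#'
#' A `landmark_config` holds one specimen's k x 3 landmark coordinates (in
#' mm) together with the role of every point. Three roles are distinguished:
#' `"fixed"` anatomical landmarks, `"curve"` semilandmarks (ordered points
#' along a digitized curve, identified by `curve_id` and `order_index`), and
#' `"surface"` semilandmarks (points spread over a surface patch, free to
#' slide in two directions).
#'
#' @param points numeric k x 3 matrix of coordinates (mm).
#' @param roles character vector of length k with values `"fixed"`,
#'   `"curve"` or `"surface"`.
#' @param specimen_id,species_id identifiers.
#' @param curve_id integer vector of length k; `NA` except for curve points.
#' @param order_index integer vector of length k; `NA` except for curve
#'   points, consecutive and unique within one `curve_id`.
#' @param mesh optional `surface_mesh` the specimen's surface points lie on,
#'   or a path to one.
#'
#' @return an object of class `landmark_config`.
#' @export
landmark_config <- function(points, roles, specimen_id = "specimen",
                            species_id = "species", curve_id = NULL,
                            order_index = NULL, mesh = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L)
    stop("`points` must be a k x 3 matrix", call. = FALSE)
  k <- nrow(points)
  if (!all(is.finite(points)))
    stop("non-finite landmark coordinates", call. = FALSE)
  roles <- match.arg(roles, c("fixed", "curve", "surface"),
                     several.ok = TRUE)
  if (length(roles) == 1L) roles <- rep(roles, k)
  if (length(roles) != k)
    stop("`roles` must have one entry per landmark", call. = FALSE)
  if (is.null(curve_id)) curve_id <- rep(NA_integer_, k)
  if (is.null(order_index)) order_index <- rep(NA_integer_, k)
  curve_id <- as.integer(curve_id)
  order_index <- as.integer(order_index)
  is_curve <- roles == "curve"
  if (any(is_curve & is.na(curve_id)))
    stop("curve landmarks need a `curve_id`", call. = FALSE)
  if (any(is_curve & is.na(order_index)))
    stop("curve landmarks need an `order_index`", call. = FALSE)
  for (cid in unique(curve_id[is_curve])) {
    oi <- sort(order_index[is_curve & curve_id == cid])
    if (anyDuplicated(oi) || !all(diff(oi) == 1L))
      stop("order_index within curve ", cid,
           " must be consecutive and unique", call. = FALSE)
  }
  structure(list(specimen_id = as.character(specimen_id),
                 species_id = as.character(species_id),
                 points = points, roles = roles,
                 curve_id = curve_id, order_index = order_index,
                 mesh = mesh),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("<landmark_config> ", x$specimen_id, " (", x$species_id, "): ",
      nrow(x$points), " landmarks [",
      sum(x$roles == "fixed"), " fixed, ",
      sum(x$roles == "curve"), " curve, ",
      sum(x$roles == "surface"), " surface]\n", sep = "")
  invisible(x)
}

as_points_matrix <- function(x) {
  if (inherits(x, "landmark_config")) x$points else {
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    m
  }
}

#' Centroid size of a landmark configuration
#'
#' The standard geometric-morphometric size measure: the square root of the
#' summed squared distances of all landmarks from their centroid. Scaling
#' the coordinates by a factor c scales the centroid size by c.
#'
#' @param x a `landmark_config` or a k x 3 coordinate matrix.
#' @return a positive scalar, in the unit of the coordinates (mm).
#' @export
centroid_size <- function(x) {
  m <- as_points_matrix(x)
  if (nrow(m) < 2L) stop("need at least 2 landmarks", call. = FALSE)
  if (!all(is.finite(m))) stop("non-finite coordinates", call. = FALSE)
  ctr <- colMeans(m)
  sqrt(sum(sweep(m, 2L, ctr)^2))
}

#' Read / write the per-landmark CSV dialect
#'
#' One row per landmark with columns `specimen_id, species_id, landmark_id,
#' role, curve_id, order_index, x, y, z` (UTF-8, '.' decimal separator).
#' Rows belonging to one `specimen_id` become one [landmark_config];
#' landmarks are ordered by `landmark_id` within specimen.
#'
#' @param path file path.
#' @return `read_landmark_csv`: a named list of [landmark_config].
#' @export
read_landmark_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "species_id", "landmark_id", "role",
            "curve_id", "order_index", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("landmark CSV is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- lapply(split(df, df$specimen_id), function(d) {
    d <- d[order(d$landmark_id), ]
    landmark_config(points = as.matrix(d[, c("x", "y", "z")]),
                    roles = d$role,
                    specimen_id = d$specimen_id[1L],
                    species_id = d$species_id[1L],
                    curve_id = suppressWarnings(as.integer(d$curve_id)),
                    order_index = suppressWarnings(as.integer(d$order_index)))
  })
  out[order(names(out))]
}

#' @param configs a list of [landmark_config] (or a single one).
#' @rdname read_landmark_csv
#' @export
write_landmark_csv <- function(configs, path) {
  if (inherits(configs, "landmark_config")) configs <- list(configs)
  rows <- lapply(configs, function(cf) {
    data.frame(specimen_id = cf$specimen_id, species_id = cf$species_id,
               landmark_id = seq_len(nrow(cf$points)), role = cf$roles,
               curve_id = cf$curve_id, order_index = cf$order_index,
               x = cf$points[, 1L], y = cf$points[, 2L], z = cf$points[, 3L])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Read a classic TPS text file with 3D landmark blocks
#'
#' Parses `LM3=` blocks (one per specimen) with optional `ID=` lines into
#' [landmark_config] objects. All points are imported with role `"fixed"`;
#' curve/surface roles are a property of this pipeline's CSV dialect, not of
#' the TPS format.
#'
#' @param path file path.
#' @return a list of [landmark_config].
#' @export
read_tps3 <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM3\\s*=", lines, ignore.case = TRUE)
  if (!length(starts)) stop("no LM3= blocks found in ", path, call. = FALSE)
  out <- list()
  for (i in seq_along(starts)) {
    s <- starts[i]
    k <- as.integer(sub("^LM3\\s*=\\s*", "", lines[s], ignore.case = TRUE))
    coords <- lines[(s + 1L):(s + k)]
    m <- do.call(rbind, lapply(strsplit(coords, "\\s+"), as.numeric))
    if (ncol(m) != 3L || any(!is.finite(m)))
      stop("malformed coordinate block at LM3 line ", s, call. = FALSE)
    stop_at <- if (i < length(starts)) starts[i + 1L] - 1L else length(lines)
    trailer <- lines[seq.int(min(s + k + 1L, stop_at), stop_at)]
    idl <- grep("^ID\\s*=", trailer, ignore.case = TRUE, value = TRUE)
    id <- if (length(idl)) sub("^ID\\s*=\\s*", "", idl[1L],
                               ignore.case = TRUE) else paste0("tps_", i)
    out[[id]] <- landmark_config(m, "fixed", specimen_id = id)
  }
  out
}
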