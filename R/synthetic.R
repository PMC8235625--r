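#' Parametric bone-like template atlas
#'
#' Builds a watertight triangulated "long bone" (a cylindrical shaft with
#' two bulging epiphyses, meshed as a deformed sphere of revolution with a
#' small seeded asymmetry) and digitizes it: fixed landmarks at analytic
#' feature points (poles, epiphysis bulges), curve semilandmarks resampled
#' along two opposite ridgelines, and surface semilandmarks spread over the
#' epiphyses at mesh vertices.
#'
#' @param n_fixed number of fixed landmarks (>= 6).
#' @param curve_counts integer vector, resampled point count per ridgeline
#'   curve (length gives the number of curves, at most 4).
#' @param n_surface number of surface semilandmarks.
#' @param seed RNG seed (shapes the asymmetry).
#' @param n_phi,n_theta mesh resolution.
#' @return a [template_atlas].
#' @export
make_template <- function(n_fixed = 8L, curve_counts = c(10L, 10L),
                          n_surface = 40L, seed = 1L,
                          n_phi = 28L, n_theta = 26L) {
  if (n_fixed < 6L) stop("need at least 6 fixed landmarks", call. = FALSE)
  if (length(curve_counts) > 4L) stop("at most 4 ridgeline curves",
                                      call. = FALSE)
  set.seed(seed)
  half_len <- 6
  bulge <- stats::runif(2L, 1.6, 2.2)      # epiphysis radii
  waist <- stats::runif(1L, 0.8, 1.1)      # shaft radius
  asym <- stats::runif(1L, 0.03, 0.08)
  phase <- stats::runif(1L, 0, 2 * pi)
  radius <- function(phi, theta) {
    z <- cos(phi)                           # -1..1 along the bone axis
    g <- waist + (bulge[1L] - waist) * exp(-((z - 0.72) / 0.22)^2) +
      (bulge[2L] - waist) * exp(-((z + 0.72) / 0.22)^2)
    g * (1 + asym * sin(2 * theta + phase) * sin(phi)^2)
  }
  phis <- seq(0, pi, length.out = n_phi + 2L)[-c(1L, n_phi + 2L)]
  thetas <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  V <- matrix(0, 2L + n_phi * n_theta, 3L)
  V[1L, ] <- c(0, 0, half_len)
  V[2L, ] <- c(0, 0, -half_len)
  idx <- function(i, j) 2L + (i - 1L) * n_theta + j    # i over phi, j theta
  for (i in seq_len(n_phi)) for (j in seq_len(n_theta)) {
    r <- radius(phis[i], thetas[j]) * sin(phis[i])
    V[idx(i, j), ] <- c(r * cos(thetas[j]), r * sin(thetas[j]),
                        half_len * cos(phis[i]))
  }
  faces <- list()
  for (j in seq_len(n_theta)) {                        # top/bottom fans
    jn <- if (j == n_theta) 1L else j + 1L
    faces[[length(faces) + 1L]] <- c(1L, idx(1L, j), idx(1L, jn))
    faces[[length(faces) + 1L]] <- c(2L, idx(n_phi, jn), idx(n_phi, j))
  }
  for (i in seq_len(n_phi - 1L)) for (j in seq_len(n_theta)) {
    jn <- if (j == n_theta) 1L else j + 1L
    faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1L, j),
                                     idx(i + 1L, jn))
    faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1L, jn), idx(i, jn))
  }
  mesh <- surface_mesh(V, do.call(rbind, faces))
  # ridgeline curves: meridians at opposite angles, poles excluded
  curve_thetas <- c(1L, 1L + n_theta %/% 2L,
                    1L + n_theta %/% 4L, 1L + (3L * n_theta) %/% 4L)
  used_thetas <- curve_thetas[seq_along(curve_counts)]
  curve_pts <- list()
  for (ci in seq_along(curve_counts)) {
    mer <- V[vapply(seq_len(n_phi), function(i)
      idx(i, curve_thetas[ci]), 1L), , drop = FALSE]
    curve_pts[[ci]] <- resample_curve(mer, curve_counts[ci])
  }
  # fixed landmarks: the two poles, then epiphysis-bulge vertices off the
  # curve meridians
  ring_hi <- which.min(abs(half_len * cos(phis) - 0.72 * half_len))
  ring_lo <- which.min(abs(half_len * cos(phis) + 0.72 * half_len))
  free_thetas <- setdiff(seq_len(n_theta), used_thetas)
  slots <- free_thetas[round(seq(1L, length(free_thetas),
                                 length.out = ceiling((n_fixed - 2L) / 2)))]
  fixed_idx <- c(1L, 2L,
                 idx(ring_hi, slots),
                 idx(ring_lo, slots))[seq_len(n_fixed)]
  fixed_pts <- V[fixed_idx, , drop = FALSE]
  # surface semilandmarks: epiphysis vertices, away from the curve meridians
  # and the polar rings, evenly by index
  ring_of <- rep(seq_len(n_phi), each = n_theta)
  theta_of <- rep(seq_len(n_theta), n_phi)
  all_idx <- seq_len(nrow(V))
  cand <- which(abs(V[, 3L]) > 0.45 * half_len & all_idx > 2L &
                  !(all_idx %in% fixed_idx) &
                  !(theta_of[pmax(all_idx - 2L, 1L)] %in% used_thetas) &
                  !(ring_of[pmax(all_idx - 2L, 1L)] %in%
                      c(1L, 2L, n_phi - 1L, n_phi)))
  if (length(cand) < n_surface)
    stop("mesh too coarse for ", n_surface, " surface points", call. = FALSE)
  surf_idx <- cand[round(seq(1L, length(cand), length.out = n_surface))]
  surf_pts <- V[surf_idx, , drop = FALSE]
  pts <- rbind(fixed_pts, do.call(rbind, curve_pts), surf_pts)
  if (min(stats::dist(pts)) < 1e-8)
    stop("degenerate template: coincident landmarks", call. = FALSE)
  roles <- c(rep("fixed", n_fixed),
             rep("curve", sum(curve_counts)),
             rep("surface", n_surface))
  curve_id <- c(rep(NA_integer_, n_fixed),
                rep(seq_along(curve_counts), curve_counts),
                rep(NA_integer_, n_surface))
  order_index <- c(rep(NA_integer_, n_fixed),
                   unlist(lapply(curve_counts, seq_len)),
                   rep(NA_integer_, n_surface))
  cfg <- landmark_config(pts, roles, specimen_id = "template",
                         species_id = "template", curve_id = curve_id,
                         order_index = order_index, mesh = mesh)
  template_atlas(cfg, mesh)
}

#' Simulation recipe: the ground-truth generating model
#'
#' Collects every parameter of the synthetic study design: the tree, the
#' Brownian base rate of shape evolution, optional clade-specific rate
#' multipliers, the locomotor group map and group mean-shape offset, the
#' allometric shape component, specimen-level noise, and the seed.
#' Defaults emulate the study conditions: the 25-species callitrichid
#' fixture tree with its VCL/HL coding, Brownian shape evolution, a small
#' VCL group offset, allometry tied to log centroid size, and up to three
#' specimens per species.
#'
#' @param tree a `phylo` (default [callitrichid_tree()]).
#' @param group_map named character over tips (default
#'   [callitrichid_locomotion()]).
#' @param base_rate Brownian rate of shape evolution, squared Procrustes
#'   units per My per coordinate.
#' @param clade_rate_multipliers list of `list(tips = c(...), multiplier)`:
#'   all branches of the clade spanned by `tips` (including its stem) evolve
#'   at `base_rate * multiplier`.
#' @param group_offset_magnitude Procrustes-distance magnitude of the mean
#'   shape offset added to every VCL tip (direction drawn from the seed).
#' @param allometry_slope shape change (Procrustes units) per unit log
#'   centroid size along a seeded unit direction.
#' @param size_base_log,size_rate log centroid size at the root (log mm) and
#'   its Brownian rate (per My).
#' @param specimen_noise_sd isotropic per-coordinate landmark noise (shape
#'   units) added independently to every specimen.
#' @param specimen_size_sd within-species sd of specimen log centroid size.
#' @param n_specimens specimens sampled per species.
#' @param seed mandatory RNG seed.
#' @return a `simulation_recipe` (validated list).
#' @export
simulation_recipe <- function(tree = callitrichid_tree(),
                              group_map = callitrichid_locomotion(),
                              base_rate = 1e-4,
                              clade_rate_multipliers = list(),
                              group_offset_magnitude = 0.02,
                              allometry_slope = 0.02,
                              size_base_log = 4.0,
                              size_rate = 0.002,
                              specimen_noise_sd = 0.002,
                              specimen_size_sd = 0.02,
                              n_specimens = 3L,
                              seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  tree <- validate_phylo(tree)
  stopifnot(base_rate > 0, specimen_noise_sd >= 0, specimen_size_sd >= 0,
            n_specimens >= 1L)
  for (cl in clade_rate_multipliers)
    if (!is.list(cl) || is.null(cl$tips) || is.null(cl$multiplier) ||
        cl$multiplier <= 0)
      stop("each rate multiplier needs `tips` and a positive `multiplier`",
           call. = FALSE)
  structure(list(tree = tree, group_map = group_map, base_rate = base_rate,
                 clade_rate_multipliers = clade_rate_multipliers,
                 group_offset_magnitude = group_offset_magnitude,
                 allometry_slope = allometry_slope,
                 size_base_log = size_base_log, size_rate = size_rate,
                 specimen_noise_sd = specimen_noise_sd,
                 specimen_size_sd = specimen_size_sd,
                 n_specimens = as.integer(n_specimens),
                 seed = as.integer(seed)),
            class = "simulation_recipe")
}

edge_multipliers <- function(tree, clade_rate_multipliers) {
  mult <- rep(1, nrow(tree$edge))
  for (cl in clade_rate_multipliers) {
    v <- if (length(cl$tips) == 1L) match(cl$tips, tree$tip.label)
         else ape::getMRCA(tree, cl$tips)
    members <- c(v, descendant_nodes(tree, v))
    mult[tree$edge[, 2L] %in% members] <- cl$multiplier
  }
  mult
}

#' Simulate species mean shapes by Brownian motion on the tree
#'
#' Multivariate Brownian motion of a flattened shape vector along every
#' branch, with rate `base_rate * multiplier(branch)` per dimension; the
#' locomotor group offset is added to every VCL tip. Deterministic given the
#' recipe seed.
#'
#' @param recipe a [simulation_recipe].
#' @param root_shape numeric vector: the shape at the root (e.g. a flattened
#'   unit-size template configuration).
#' @param rng_offset integer added to the recipe seed (used by callers that
#'   need several independent draws).
#' @return matrix (tips x dimensions) of species mean shape vectors, with
#'   attributes `node_values` (internal-node shapes), `group_offset` and
#'   `edge_rates` (the true per-branch rates).
#' @export
simulate_bm_shapes <- function(recipe, root_shape, rng_offset = 0L) {
  tree <- recipe$tree
  d <- length(root_shape)
  set.seed(recipe$seed + rng_offset)
  # seeded directions drawn first so they are stable across rng offsets
  offset_dir <- stats::rnorm(d)
  offset_dir <- offset_dir / sqrt(sum(offset_dir^2))
  mult <- edge_multipliers(tree, recipe$clade_rate_multipliers)
  ntip <- length(tree$tip.label)
  vals <- matrix(0, ntip + tree$Nnode, d)
  vals[ntip + 1L, ] <- root_shape
  E <- ape::reorder.phylo(tree, "postorder")$edge
  lens <- ape::reorder.phylo(tree, "postorder")$edge.length
  for (e in rev(seq_len(nrow(E)))) {     # preorder: parents before children
    sd_e <- sqrt(recipe$base_rate * mult[match_edge(tree, E[e, ])] * lens[e])
    vals[E[e, 2L], ] <- vals[E[e, 1L], ] + stats::rnorm(d, 0, sd_e)
  }
  tips <- vals[seq_len(ntip), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  is_vcl <- recipe$group_map[tree$tip.label] == "VCL"
  offset <- recipe$group_offset_magnitude * offset_dir
  tips[is_vcl, ] <- sweep(tips[is_vcl, , drop = FALSE], 2L, offset, "+")
  attr(tips, "node_values") <- vals[(ntip + 1L):(ntip + tree$Nnode), ,
                                    drop = FALSE]
  attr(tips, "group_offset") <- offset
  attr(tips, "edge_rates") <- recipe$base_rate * mult
  tips
}

match_edge <- function(tree, edge_row) {
  which(tree$edge[, 1L] == edge_row[1L] & tree$edge[, 2L] == edge_row[2L])
}

#' Realize specimen landmark configurations from species mean shapes
#'
#' Per specimen: the species mean shape gets an allometric deformation
#' proportional to the drawn log centroid size, independent isotropic
#' landmark noise, is scaled to its centroid size (mm) and embedded on a
#' TPS-warped copy of the template mesh (surface semilandmarks re-projected
#' onto that mesh), and finally receives a random rigid motion.
#'
#' @param species_shapes tips x d matrix from [simulate_bm_shapes] (unit
#'   centroid-size flattened shapes).
#' @param recipe a [simulation_recipe].
#' @param atlas a [template_atlas] providing roles and the mesh to warp.
#' @param log_sizes optional named species log centroid sizes; by default
#'   they are simulated as Brownian motion on the recipe tree.
#' @param with_meshes warp and attach a mesh per specimen (slower); without
#'   meshes, surface points are kept as generated and no projection is done.
#' @return a `synthetic_dataset`: list with `configs` (list of
#'   [landmark_config]), `traits` (species_id -> category), `tree`,
#'   `log_sizes`, `recipe` and `truth` (per-specimen ground-truth record).
#' @export
realize_specimens <- function(species_shapes, recipe, atlas,
                              log_sizes = NULL, with_meshes = TRUE) {
  tree <- recipe$tree
  tc <- atlas$config
  k <- nrow(tc$points)
  d <- 3L * k
  if (ncol(species_shapes) != d)
    stop("species shapes do not match the template layout", call. = FALSE)
  set.seed(recipe$seed + 211L)
  allom_dir <- stats::rnorm(d)
  allom_dir <- allom_dir / sqrt(sum(allom_dir^2))
  if (is.null(log_sizes)) {
    mult <- rep(1, nrow(tree$edge))
    ntip <- length(tree$tip.label)
    vals <- numeric(ntip + tree$Nnode)
    vals[ntip + 1L] <- recipe$size_base_log
    E <- ape::reorder.phylo(tree, "postorder")$edge
    lens <- ape::reorder.phylo(tree, "postorder")$edge.length
    for (e in rev(seq_len(nrow(E))))
      vals[E[e, 2L]] <- vals[E[e, 1L]] +
        stats::rnorm(1L, 0, sqrt(recipe$size_rate * lens[e]))
    log_sizes <- stats::setNames(vals[seq_len(ntip)], tree$tip.label)
  }
  template_unit <- scale_to_unit_cs(tc$points)
  configs <- list()
  truth <- list()
  for (sp in rownames(species_shapes)) {
    for (r in seq_len(recipe$n_specimens)) {
      lcs <- log_sizes[[sp]] + stats::rnorm(1L, 0, recipe$specimen_size_sd)
      v <- species_shapes[sp, ] +
        allom_dir * recipe$allometry_slope * (lcs - recipe$size_base_log) +
        stats::rnorm(d, 0, recipe$specimen_noise_sd)
      shp <- matrix(v, k, 3L)
      pts <- scale_to_unit_cs(shp) * exp(lcs)
      mesh <- NULL
      if (with_meshes) {
        ref <- template_unit * exp(lcs)
        mesh <- atlas$mesh
        mesh$vertices <- tps_warp(ref, pts,
                                  mesh$vertices * exp(lcs) /
                                    centroid_size(tc$points))
        proj <- mesh_closest_points(mesh,
                                    pts[tc$roles == "surface", , drop = FALSE])
        pts[tc$roles == "surface", ] <- proj$points
      }
      # random rigid motion
      Q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
      if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
      tr <- stats::runif(3L, -20, 20)
      pts <- sweep(pts %*% Q, 2L, tr, "+")
      if (!is.null(mesh))
        mesh$vertices <- sweep(mesh$vertices %*% Q, 2L, tr, "+")
      id <- paste0(sp, "_", r)
      configs[[id]] <- landmark_config(pts, tc$roles, specimen_id = id,
                                       species_id = sp,
                                       curve_id = tc$curve_id,
                                       order_index = tc$order_index,
                                       mesh = mesh)
      truth[[id]] <- list(log_cs = lcs, species = sp)
    }
  }
  structure(list(configs = configs,
                 traits = recipe$group_map[rownames(species_shapes)],
                 tree = tree, log_sizes = log_sizes,
                 allometry = allom_dir * recipe$allometry_slope,
                 recipe = recipe, truth = truth),
            class = "synthetic_dataset")
}

#' Generate a complete synthetic dataset from a recipe
#'
#' Template -> Brownian species mean shapes -> specimen realizations, the
#' full ground-truth test bed for the pipeline.
#'
#' @param recipe a [simulation_recipe].
#' @param atlas optional [template_atlas]; by default one is built from the
#'   recipe seed.
#' @param with_meshes passed to [realize_specimens].
#' @return a `synthetic_dataset` (see [realize_specimens]); the atlas and
#'   the species mean shapes are attached as `atlas` and `species_shapes`.
#' @export
simulate_dataset <- function(recipe, atlas = NULL, with_meshes = TRUE) {
  if (is.null(atlas)) atlas <- make_template(seed = recipe$seed)
  root <- as.vector(scale_to_unit_cs(atlas$config$points))
  shapes <- simulate_bm_shapes(recipe, root)
  ds <- realize_specimens(shapes, recipe, atlas, with_meshes = with_meshes)
  ds$atlas <- atlas
  ds$species_shapes <- shapes
  ds
}

#' Write a synthetic dataset in the pipeline's input formats
#'
#' Emits the landmark CSV, one ASCII PLY mesh per specimen (if present), the
#' Newick tree, the trait CSV and the recipe as YAML, into `dir`.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_landmark_csv(dataset$configs, file.path(dir, "landmarks.csv"))
  write_newick(dataset$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(data.frame(species_id = names(dataset$traits),
                              category = unname(dataset$traits)),
                   file.path(dir, "traits.csv"), row.names = FALSE,
                   quote = FALSE)
  for (id in names(dataset$configs)) {
    m <- dataset$configs[[id]]$mesh
    if (!is.null(m))
      write_ply(m, file.path(dir, paste0(id, ".ply")))
  }
  rec <- dataset$recipe
  rec$tree <- ape::write.tree(rec$tree)
  rec$group_map <- as.list(rec$group_map)
  yaml::write_yaml(unclass(rec), file.path(dir, "recipe.yaml"))
  invisible(dir)
}
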