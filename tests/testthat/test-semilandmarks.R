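test_that("curve resampling spaces points by arc length", {
  seg <- rbind(c(0, 0, 0), c(10, 0, 0))
  out <- resample_curve(seg, 6L)
  expect_equal(out[, 1L], seq(0, 10, by = 2))
  expect_equal(out[, 2:3], matrix(0, 6L, 2L))

  # endpoints preserved exactly on any polyline
  set.seed(1)
  poly <- apply(matrix(rnorm(30, sd = .5), 10L), 2L, cumsum)
  out2 <- resample_curve(poly, 7L)
  expect_identical(out2[1L, ], poly[1L, ])
  expect_identical(out2[7L, ], poly[10L, ])

  # dense semicircle: equal arc-length gaps
  t <- seq(0, pi, length.out = 2000L)
  semi <- cbind(cos(t), sin(t), 0)
  out3 <- resample_curve(semi, 11L)
  gaps <- sqrt(rowSums(diff(out3)^2))
  # chord of a pi/10 arc; all gaps equal within 1e-3 of arc/10
  expect_lt(max(abs(gaps - mean(gaps))), 1e-3 * pi / 10)

  expect_error(resample_curve(rbind(c(1, 1, 1), c(1, 1, 1)), 5L),
               "degenerate")
})

test_that("surface patching transfers the template patch through TPS", {
  at <- small_atlas()
  tc <- at$config
  scaffold <- tc$roles != "surface"
  strip <- function(cfg) {
    landmark_config(cfg$points[scaffold, ], cfg$roles[scaffold],
                    specimen_id = "spec", species_id = "sp",
                    curve_id = cfg$curve_id[scaffold],
                    order_index = cfg$order_index[scaffold])
  }
  # specimen identical to the template
  same <- place_patch(at, strip(tc), at$mesh)
  expect_equal(same$points[same$roles == "surface", ],
               tc$points[tc$roles == "surface", ], tolerance = 1e-6)

  # rigidly moved template
  set.seed(2)
  R <- random_rotation(); b <- c(4, -2, 7)
  moved <- tc
  moved$points <- sweep(tc$points %*% R, 2L, b, "+")
  mesh_m <- at$mesh
  mesh_m$vertices <- sweep(mesh_m$vertices %*% R, 2L, b, "+")
  got <- place_patch(at, strip(moved), mesh_m)
  expect_equal(got$points[got$roles == "surface", ],
               moved$points[moved$roles == "surface", ], tolerance = 1e-6)
})

test_that("patched points land on an ellipsoid when the target is one", {
  # template: sphere with a fixed+curve scaffold; specimen: ellipsoid
  sph <- uv_sphere(1, 30L, 30L)
  pick <- c(1L, 2L, 40L, 205L, 363L, 521L, 684L, 842L)
  scaffold_roles <- rep("fixed", length(pick))
  surf_pick <- setdiff(seq(10L, nrow(sph$vertices), by = 37L), pick)
  template <- landmark_config(rbind(sph$vertices[pick, ],
                                    sph$vertices[surf_pick, ]),
                              c(scaffold_roles,
                                rep("surface", length(surf_pick))))
  atlas <- template_atlas(template, sph)
  ax <- c(1.6, 1.0, 0.7)
  ell <- sph
  ell$vertices <- sweep(sph$vertices, 2L, ax, "*")
  spec <- landmark_config(sweep(sph$vertices[pick, ], 2L, ax, "*"),
                          scaffold_roles)
  got <- place_patch(atlas, spec, ell)
  S <- got$points[got$roles == "surface", ]
  # implicit ellipsoid equation satisfied up to mesh faceting
  val <- rowSums(sweep(S, 2L, ax, "/")^2)
  expect_lt(max(abs(val - 1)), 0.05)
  expect_lt(max(mesh_closest_points(ell, S)$distance), 1e-3 * 2 * max(ax))
  # neighbour structure preserved: nearest surface neighbour unchanged
  tpl_surf <- template$points[template$roles == "surface", ]
  nn <- function(M) apply(as.matrix(dist(M)) + diag(Inf, nrow(M)), 1L,
                          which.min)
  expect_gt(mean(nn(S) == nn(sweep(tpl_surf, 2L, ax, "*"))), 0.8)
})

test_that("one sliding step is the exact minimizer of bending energy", {
  at <- small_atlas()
  tc <- at$config
  set.seed(3)
  plan <- sliding_plan(tc, at$mesh)
  spec <- tc
  spec$points <- tc$points + plan$t1 * rnorm(nrow(tc$points), 0, .05) +
    plan$t2 * rnorm(nrow(tc$points), 0, .05)
  res <- relax_once(spec, tc$points, mesh = at$mesh, project = FALSE)
  # oracle: numeric minimization of the same quadratic objective
  k <- nrow(tc$points)
  fit <- ordinary_procrustes(tc$points, spec$points)
  x <- fit$aligned
  B <- tps_build(x)$bending_energy
  plan2 <- sliding_plan(spec, at$mesh)
  slide1 <- spec$roles %in% c("curve", "surface")
  slide2 <- spec$roles == "surface"
  U <- matrix(0, 3L * k, sum(slide1) + sum(slide2))
  j <- 0L
  for (i in which(slide1)) { j <- j + 1L
    U[c(i, k + i, 2L * k + i), j] <- plan2$t1[i, ] }
  for (i in which(slide2)) { j <- j + 1L
    U[c(i, k + i, 2L * k + i), j] <- plan2$t2[i, ] }
  B3 <- function(v) { m <- matrix(v, k, 3L)
    as.vector(B %*% m) }
  dvec <- as.vector(spec$points - x)
  obj <- function(t) { y <- dvec + drop(U %*% t)
    sum(y * B3(y)) }
  grad <- function(t) 2 * drop(crossprod(U, B3(dvec + drop(U %*% t))))
  o <- optim(rep(0, ncol(U)), obj, grad, method = "BFGS",
             control = list(maxit = 1000, reltol = 1e-15))
  expect_equal(res$energy_after, o$value, tolerance = 1e-6)
  expect_lte(res$energy_after, res$energy_before + 1e-10)
})

test_that("sliding leaves a specimen equal to the reference untouched", {
  at <- small_atlas()
  res <- relax_once(at$config, at$config$points, mesh = at$mesh)
  expect_lt(max(abs(res$t)), 1e-9)
  expect_equal(res$config$points, at$config$points, tolerance = 1e-9)
})

test_that("a tangential displacement is recovered by sliding", {
  at <- small_atlas()
  tc <- at$config
  plan <- sliding_plan(tc, at$mesh)
  i <- which(tc$roles == "curve")[4L]
  spec <- tc
  spec$points[i, ] <- tc$points[i, ] + 0.05 * plan$t1[i, ]
  e0 <- bending_energy(tps_build(tc$points), tc$points)  # undisplaced: 0ish
  res <- relax_once(spec, tc$points, mesh = at$mesh)
  expect_lt(res$energy_after, 1e-6 + e0)
  expect_lt(res$energy_after, res$energy_before)
})

test_that("sliding keeps fixed points bit-identical and surface on mesh", {
  at <- small_atlas()
  tc <- at$config
  set.seed(4)
  plan <- sliding_plan(tc, at$mesh)
  spec <- tc
  spec$points <- tc$points + plan$t1 * rnorm(nrow(tc$points), 0, .06)
  res <- relax_once(spec, tc$points, mesh = at$mesh)
  fx <- tc$roles == "fixed"
  expect_identical(res$config$points[fx, ], spec$points[fx, ])
  d <- mesh_closest_points(at$mesh,
                           res$config$points[tc$roles == "surface", ])$distance
  expect_lt(max(d), 1e-6 * bbox_diagonal(at$mesh))
})

test_that("sliding commutes with rigid motion of the specimen", {
  at <- small_atlas()
  tc <- at$config
  set.seed(5)
  plan <- sliding_plan(tc, at$mesh)
  spec <- tc
  spec$points <- tc$points + plan$t1 * rnorm(nrow(tc$points), 0, .05)
  res1 <- relax_once(spec, tc$points, mesh = at$mesh)
  R <- random_rotation(); b <- c(3, 1, -2)
  spec2 <- spec
  spec2$points <- sweep(spec$points %*% R, 2L, b, "+")
  mesh2 <- at$mesh
  mesh2$vertices <- sweep(at$mesh$vertices %*% R, 2L, b, "+")
  spec2$mesh <- mesh2
  res2 <- relax_once(spec2, tc$points, mesh = mesh2)
  back <- sweep(res2$config$points, 2L, b) %*% t(R)
  expect_equal(back, res1$config$points, tolerance = 1e-6)
})

test_that("relaxing identical specimens against their consensus is a no-op", {
  at <- small_atlas()
  cfgs <- lapply(1:3, function(i) {
    cf <- at$config
    cf$specimen_id <- paste0("s", i)
    cf$mesh <- at$mesh
    cf
  })
  out <- relax_to_consensus(cfgs, iterations = 3L)
  for (i in 1:3)
    expect_equal(out$configs[[i]]$points, at$config$points,
                 tolerance = 1e-6)
})

test_that("total bending energy is non-increasing across relax iterations", {
  at <- small_atlas()
  tc <- at$config
  set.seed(6)
  plan <- sliding_plan(tc, at$mesh)
  cfgs <- lapply(1:5, function(i) {
    cf <- tc
    cf$specimen_id <- paste0("s", i)
    cf$points <- tc$points + plan$t1 * rnorm(nrow(tc$points), 0, .05) +
      plan$t2 * rnorm(nrow(tc$points), 0, .05)
    cf$mesh <- at$mesh
    cf
  })
  trace_file <- withr::local_tempfile(fileext = ".json")
  out <- suppressWarnings(
    relax_to_consensus(cfgs, iterations = 3L, trace_file = trace_file))
  expect_length(out$trace, 4L)
  expect_true(all(diff(out$trace) <= 1e-6 * out$trace[1L]))
  logged <- jsonlite::read_json(trace_file, simplifyVector = TRUE)
  expect_equal(logged$total_bending_energy, out$trace, tolerance = 1e-12)
})

test_that("replicate digitizations are averaged after rigid alignment", {
  at <- small_atlas()
  tc <- at$config
  set.seed(7)
  R <- random_rotation()
  rep2 <- tc
  rep2$points <- sweep((tc$points +
                          matrix(rnorm(length(tc$points), 0, .01),
                                 nrow(tc$points))) %*% R, 2L, c(1, 2, 3), "+")
  avg <- average_replicates(tc, rep2)
  # stays close to the first digitization, scale untouched
  expect_lt(max(abs(avg$points - tc$points)), 0.02)
  expect_equal(centroid_size(avg$points), centroid_size(tc$points),
               tolerance = 1e-2)
})
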