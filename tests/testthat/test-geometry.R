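test_that("centroid size matches its definition and is scale-equivariant", {
  square <- rbind(c(.5, .5, 0), c(-.5, .5, 0), c(-.5, -.5, 0), c(.5, -.5, 0))
  expect_equal(centroid_size(square), sqrt(2))

  set.seed(1)
  for (rep in 1:3) {
    P <- matrix(rnorm(150), 50L)
    ctr <- colMeans(P)
    brute <- 0
    for (i in 1:50) brute <- brute + sum((P[i, ] - ctr)^2)  # direct loop
    expect_equal(centroid_size(P), sqrt(brute))
    expect_equal(centroid_size(3 * P), 3 * centroid_size(P))
  }
  expect_error(centroid_size(matrix(c(0, 0, 0), 1L)), "at least 2")
  P[2, 1] <- NA
  expect_error(centroid_size(P), "finite")
})

test_that("landmark configurations validate their role structure", {
  pts <- matrix(rnorm(18), 6L)
  cf <- landmark_config(pts, c("fixed", "fixed", "curve", "curve", "curve",
                               "surface"),
                        curve_id = c(NA, NA, 1, 1, 1, NA),
                        order_index = c(NA, NA, 1, 2, 3, NA))
  expect_s3_class(cf, "landmark_config")
  expect_error(landmark_config(pts, "curve"), "curve_id")
  expect_error(landmark_config(pts, c("fixed", "fixed", "curve", "curve",
                                      "curve", "surface"),
                               curve_id = c(NA, NA, 1, 1, 1, NA),
                               order_index = c(NA, NA, 1, 3, 5, NA)),
               "consecutive")
  pts[1, 1] <- Inf
  expect_error(landmark_config(pts, "fixed"), "non-finite")
})

test_that("landmark CSV and TPS-format readers round-trip", {
  at <- small_atlas()
  cf <- at$config
  cf2 <- cf; cf2$specimen_id <- "other"; cf2$points <- cf$points + 1
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmark_csv(list(cf, cf2), path)
  back <- read_landmark_csv(path)
  expect_named(back, c("other", "template"))
  expect_equal(back$template$points, cf$points, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(back$template$roles, cf$roles)
  expect_equal(back$template$curve_id, cf$curve_id)

  tpsf <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM3=3", "0 0 0", "1 0 0", "0 1 1", "ID=spec_a",
               "LM3=3", "2 0 0", "1 5 0", "0 1 3", "ID=spec_b"), tpsf)
  tps <- read_tps3(tpsf)
  expect_named(tps, c("spec_a", "spec_b"))
  expect_equal(tps$spec_b$points[2, ], c(1, 5, 0))
})

test_that("ordinary Procrustes recovers rigid+scale transforms exactly", {
  set.seed(2)
  X <- matrix(rnorm(36), 12L)
  fit0 <- ordinary_procrustes(X, X)
  expect_lt(fit0$residual, 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)

  for (rep in 1:5) {
    R <- random_rotation()
    s <- runif(1, .3, 3)
    b <- rnorm(3)
    Y <- s * X %*% R + matrix(b, 12L, 3L, byrow = TRUE)
    fit <- ordinary_procrustes(X, Y)
    expect_lt(fit$residual, 1e-10)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    expect_equal(fit$scale, s, tolerance = 1e-9)
  }
  expect_error(ordinary_procrustes(matrix(1, 5L, 3L), X[1:5, ]),
               "degenerate")
})

test_that("ordinary Procrustes residual matches a quaternion optimizer", {
  set.seed(3)
  for (rep in 1:3) {
    X <- matrix(rnorm(24), 8L)
    Y <- matrix(rnorm(24), 8L)
    fit <- ordinary_procrustes(X, Y)
    expect_equal(fit$residual, opa_oracle(X, Y), tolerance = 1e-6)
  }
})

test_that("reflections are never used even when they fit better", {
  set.seed(4)
  X <- matrix(rnorm(30), 10L)
  Y <- X %*% diag(c(1, 1, -1))          # mirrored copy
  fit <- ordinary_procrustes(X, Y)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_gt(fit$residual, 0.1)
})

test_that("GPA aligns rigid copies to identical unit-size shapes", {
  set.seed(5)
  X <- matrix(rnorm(30), 10L)
  arr <- array(0, c(4L, 10L, 3L))
  for (i in 1:4) {
    s <- runif(1, .5, 2)
    arr[i, , ] <- s * X %*% random_rotation() +
      matrix(rnorm(3), 10L, 3L, byrow = TRUE)
  }
  fit <- gpa(arr)
  expect_true(fit$converged)
  for (i in 1:4) {
    expect_equal(centroid_size(fit$shapes[i, , ]), 1, tolerance = 1e-9)
    expect_equal(colMeans(fit$shapes[i, , ]), rep(0, 3), tolerance = 1e-9)
    expect_equal(fit$shapes[i, , ], fit$shapes[1, , ], tolerance = 1e-8)
  }
  expect_equal(fit$consensus, fit$shapes[1, , ], tolerance = 1e-8)
})

test_that("GPA output is invariant to rigid motion of any input", {
  set.seed(6)
  arr <- array(rnorm(5 * 8 * 3, sd = 1), c(5L, 8L, 3L))
  fit1 <- gpa(arr)
  arr2 <- arr
  arr2[3, , ] <- 1.7 * arr[3, , ] %*% random_rotation() +
    matrix(rnorm(3), 8L, 3L, byrow = TRUE)
  fit2 <- gpa(arr2)
  expect_equal(fit1$consensus, fit2$consensus, tolerance = 1e-7)
  expect_equal(fit1$shapes[3, , ], fit2$shapes[3, , ], tolerance = 1e-7)
})

test_that("GPA consensus minimizes summed squared distance over rotations", {
  set.seed(7)
  base <- matrix(rnorm(18), 6L)
  arr <- array(0, c(5L, 6L, 3L))
  for (i in 1:5) arr[i, , ] <- base + matrix(rnorm(18, sd = .05), 6L)
  fit <- gpa(arr)
  gpa_obj <- sum(vapply(1:5, function(i)
    sum((fit$shapes[i, , ] - apply(fit$shapes, c(2, 3), mean))^2), 0))
  # oracle: joint optimization of per-shape Euler rotations
  unitized <- lapply(1:5, function(i) {
    m <- sweep(arr[i, , ], 2, colMeans(arr[i, , ]))
    m / sqrt(sum(m^2))
  })
  euler <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3)
  }
  obj <- function(par) {
    rots <- lapply(1:5, function(i) euler(par[(3 * i - 2):(3 * i)]))
    shapes <- lapply(1:5, function(i) unitized[[i]] %*% rots[[i]])
    mean_shape <- Reduce(`+`, shapes) / 5
    sum(vapply(shapes, function(s) sum((s - mean_shape)^2), 0))
  }
  o <- optim(rep(0, 15), obj, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(gpa_obj, o$value, tolerance = 1e-5)
})

test_that("species mean forms follow the consensus-times-mean-size rule", {
  set.seed(8)
  X <- matrix(rnorm(21), 7L)
  Xu <- X - matrix(colMeans(X), 7L, 3L, byrow = TRUE)
  Xu <- Xu / centroid_size(Xu)
  mk <- function(s, id) landmark_config(s * Xu %*% random_rotation(),
                                        "fixed", specimen_id = id,
                                        species_id = "sp")
  means <- species_mean_forms(list(mk(2, "a"), mk(4, "b")))
  expect_equal(means$sp$mean_cs, 3)
  expect_equal(means$sp$n_specimens, 2L)
  expect_equal(centroid_size(means$sp$mean_form), 3, tolerance = 1e-9)
  # mean form = unit consensus x 3: compare up to rotation
  fit <- ordinary_procrustes(means$sp$mean_form, 3 * Xu, allow_scale = FALSE)
  expect_lt(fit$residual, 1e-8)

  # single specimen: itself up to centering/rotation, mean_cs = its size
  one <- mk(1.5, "solo")
  m1 <- species_mean_forms(list(one))
  expect_equal(m1$sp$mean_cs, centroid_size(one$points))

  # two-path computation on perturbed specimens
  specs <- lapply(1:3, function(i)
    landmark_config(X + matrix(rnorm(21, sd = .03), 7L), "fixed",
                    specimen_id = paste0("s", i), species_id = "sp"))
  m3 <- species_mean_forms(specs)$sp
  fit3 <- gpa(specs)
  expect_equal(m3$mean_form, fit3$consensus * mean(fit3$centroid_sizes),
               tolerance = 1e-10)
})

test_that("TPS interpolates exactly and assigns zero energy to affine maps", {
  set.seed(9)
  ref <- matrix(rnorm(30), 10L)
  tps <- tps_build(ref)

  # bending-energy matrix annihilates the affine null space
  expect_lt(max(abs(tps$bending_energy %*% cbind(1, ref))), 1e-8)
  eigs <- eigen(tps$bending_energy, symmetric = TRUE,
                only.values = TRUE)$values
  expect_gte(min(eigs), -1e-12 * max(eigs))

  for (rep in 1:5) {
    A <- matrix(rnorm(9), 3L)
    b <- rnorm(3)
    tgt <- ref %*% A + matrix(b, 10L, 3L, byrow = TRUE)
    expect_lt(abs(bending_energy(tps, tgt)), 1e-8)
    # exact interpolation at the landmarks
    expect_lt(max(abs(tps_warp(ref, tgt, ref, tps = tps) - tgt)), 1e-9)
    # affine targets act on arbitrary points as that same affine map
    q <- matrix(rnorm(21), 7L)
    expect_equal(tps_warp(ref, tgt, q, tps = tps),
                 q %*% A + matrix(b, 7L, 3L, byrow = TRUE),
                 tolerance = 1e-8)
  }
  # identity deformation leaves query points unchanged
  q <- matrix(rnorm(15), 5L)
  expect_equal(tps_warp(ref, ref, q), q, tolerance = 1e-9)
})

test_that("bending energy equals the explicitly inverted bordered system", {
  set.seed(10)
  ref <- matrix(rnorm(24), 8L)
  tgt <- ref + matrix(rnorm(24, sd = .05), 8L)
  K <- -as.matrix(dist(ref))
  P <- cbind(1, ref)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4L, 4L)))
  Lb <- solve(L)[1:8, 1:8]
  oracle <- sum(vapply(1:3, function(j)
    drop(t(tgt[, j]) %*% Lb %*% tgt[, j]), 0))
  expect_equal(bending_energy(tps_build(ref), tgt), oracle,
               tolerance = 1e-10)
})

test_that("TPS warp composed with its inverse problem is near-identity", {
  set.seed(11)
  ref <- matrix(rnorm(30), 10L)
  tgt <- ref + matrix(rnorm(30, sd = 2e-4), 10L)
  q <- matrix(rnorm(24), 8L)
  there <- tps_warp(ref, tgt, q)
  back <- tps_warp(tgt, ref, there)
  expect_lt(max(abs(back - q)), 1e-6)
})

test_that("degenerate references are rejected", {
  flat <- cbind(matrix(rnorm(12), 6L, 2L), 0)    # coplanar
  expect_error(tps_build(flat), "singular kernel")
  expect_error(tps_build(matrix(rnorm(9), 3L)), "at least 4")
})
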