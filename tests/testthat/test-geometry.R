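test_that("GPA exactly superimposes similarity-transformed copies", {
  set.seed(101)
  K <- 10L
  base <- matrix(rnorm(K * 3L), K, 3L)
  arr <- array(NA_real_, dim = c(6L, K, 3L))
  for (i in 1:6) arr[i, , ] <- random_similarity(base)
  sp <- gpa(as_landmark_array(arr))
  d <- as.matrix(dist(sp$aligned))
  expect_lt(max(d), 1e-8)
  # aligned configurations are centered with unit centroid size
  for (i in 1:6) {
    X <- matrix(sp$aligned[i, ], ncol = 3L, byrow = TRUE)
    expect_lt(max(abs(colMeans(X))), 1e-10)
    expect_equal(sum(X^2), 1, tolerance = 1e-10)
  }
})

test_that("GPA mean of two specimens is the midpoint of the aligned pair", {
  set.seed(102)
  arr <- array(rnorm(2L * 8L * 3L), dim = c(2L, 8L, 3L))
  sp <- gpa(as_landmark_array(arr))
  expect_equal(sp$mean_shape, colMeans(sp$aligned), tolerance = 1e-12)
  expect_equal(sp$mean_shape, (sp$aligned[1L, ] + sp$aligned[2L, ]) / 2,
               tolerance = 1e-12)
})

test_that("every aligned configuration is an OPA fixed point of the mean", {
  skip_if_not_installed("vegan")
  set.seed(103)
  arr <- array(rnorm(10L * 9L * 3L), dim = c(10L, 9L, 3L))
  sp <- gpa(as_landmark_array(arr))
  Mu <- matrix(sp$mean_shape, ncol = 3L, byrow = TRUE)
  for (i in 1:10) {
    X <- matrix(sp$aligned[i, ], ncol = 3L, byrow = TRUE)
    # independent ordinary-Procrustes oracle: no further rotation helps
    ss_ours <- sum((X - Mu)^2)
    ss_opa <- vegan::procrustes(Mu, X, scale = FALSE, symmetric = FALSE)$ss
    expect_equal(ss_ours, ss_opa, tolerance = 1e-6)
  }
})

test_that("GPA output is invariant to specimen order and input transforms", {
  set.seed(104)
  n <- 8L; K <- 9L
  arr <- array(rnorm(n * K * 3L), dim = c(n, K, 3L))
  sp1 <- gpa(as_landmark_array(arr))
  perm <- sample(n)
  sp2 <- gpa(as_landmark_array(arr[perm, , ]))
  expect_lt(max(abs(sp2$aligned[order(perm), ] - sp1$aligned)), 1e-8)
  arr3 <- arr
  for (i in seq_len(n)) arr3[i, , ] <- random_similarity(arr[i, , ])
  sp3 <- gpa(as_landmark_array(arr3))
  expect_lt(max(abs(sp3$aligned - sp1$aligned)), 1e-8)
})

test_that("GPA rejects degenerate configurations by specimen", {
  arr <- array(rnorm(3L * 5L * 3L), dim = c(3L, 5L, 3L))
  arr[2L, , ] <- cbind(1:5, 0, 0)    # collinear: rank 1
  expect_error(gpa(as_landmark_array(arr,
                                     specimen_ids = c("a", "bad", "c"))),
               "bad")
})

test_that("symmetry decomposition is exact, idempotent, and flags planted asymmetry", {
  set.seed(105)
  K <- 14L
  pairing <- make_symmetric_pairing(K)
  tmpl <- make_template(K, pairing)
  # perfectly symmetric input: asymmetric component vanishes
  arr <- array(NA_real_, dim = c(4L, K, 3L))
  for (i in 1:4) arr[i, , ] <- tmpl * (0.9 + 0.05 * i)
  sp <- symmetrize(as_landmark_array(arr), pairing)
  expect_lt(max(abs(sp$asymmetric)), 1e-8)
  # decomposition identity holds exactly as stored
  lm <- noisy_shapes(6L, K)
  sp2 <- symmetrize(lm, pairing)
  expect_equal(sp2$symmetric + sp2$asymmetric, sp2$aligned, tolerance = 1e-14)
  # idempotence: re-symmetrizing the symmetric shapes changes nothing,
  # up to (a) per-configuration renormalization to unit centroid size
  # and (b) a drift of higher order in the sample's asymmetry (the
  # symmetric average of optimally rotated copies is itself optimally
  # rotated only to leading order); near the symmetric manifold the
  # component is reproduced below 1e-8
  unit_rows <- function(M) t(apply(M, 1L, function(v) v / sqrt(sum(v^2))))
  sp3 <- symmetrize(as_landmark_array(sp2$symmetric), pairing)
  expect_lt(max(abs(unit_rows(sp3$symmetric) - unit_rows(sp2$symmetric))),
            1e-5)
  lm_low <- noisy_shapes(6L, K, sd = 0.001)
  lo1 <- symmetrize(lm_low, pairing)
  lo2 <- symmetrize(as_landmark_array(lo1$symmetric), pairing)
  expect_lt(max(abs(unit_rows(lo2$symmetric) - unit_rows(lo1$symmetric))),
            1e-8)
  # a planted asymmetric perturbation orthogonal to the similarity
  # transforms is recovered as the mean asymmetric field; a plain
  # single-landmark shift additionally loads the landmark's pair most
  # heavily (superimposition redistributes its rigid component)
  arr4 <- array(NA_real_, dim = c(5L, K, 3L))
  for (i in 1:5) arr4[i, , ] <- tmpl
  lm_idx <- pairing$pairs[1L, 1L]
  arr4[, lm_idx, 1L] <- arr4[, lm_idx, 1L] + 0.05
  sp4 <- symmetrize(as_landmark_array(arr4), pairing)
  A <- matrix(colMeans(sp4$asymmetric), ncol = 3L, byrow = TRUE)
  pair_rows <- pairing$pairs[1L, ]
  per_lm <- rowSums(A^2)
  expect_setequal(order(per_lm, decreasing = TRUE)[1:2], pair_rows)
  # mirror antisymmetry of the asymmetric field
  expect_lt(max(abs(mirror_config(A, pairing) + A)), 1e-6)
  # similarity-orthogonal planted field: recovered almost exactly
  planted <- matrix(0, K, 3L)
  planted[lm_idx, 1L] <- 0.05
  anti <- (planted - mirror_config(planted, pairing)) / 2
  sim_basis <- cbind(
    rep(c(1, 0, 0), K), rep(c(0, 1, 0), K), rep(c(0, 0, 1), K),
    as.vector(t(tmpl)),
    as.vector(t(cbind(0, -tmpl[, 3L], tmpl[, 2L]))),
    as.vector(t(cbind(tmpl[, 3L], 0, -tmpl[, 1L]))),
    as.vector(t(cbind(-tmpl[, 2L], tmpl[, 1L], 0))))
  B <- qr.Q(qr(sim_basis))
  af <- as.vector(t(anti))
  af <- af - B %*% crossprod(B, af)
  field <- matrix(af, K, 3L, byrow = TRUE)
  arr5 <- array(NA_real_, dim = c(5L, K, 3L))
  for (i in 1:5) arr5[i, , ] <- tmpl + field
  sp5 <- symmetrize(as_landmark_array(arr5), pairing)
  A5 <- colMeans(sp5$asymmetric)
  # express the planted field in the output frame (the canonical
  # orientation may rotate the solution relative to the input)
  Mu <- matrix(sp5$mean_shape, ncol = 3L, byrow = TRUE)
  sv <- svd(crossprod(tmpl, Mu))
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) { u <- sv$u; u[, 3L] <- -u[, 3L]; R <- u %*% t(sv$v) }
  af_rot <- as.vector(t(matrix(af, K, 3L, byrow = TRUE) %*% R))
  expect_gt(abs(cor(A5, af_rot)), 0.99)
})

test_that("directional asymmetry test degenerates without FA and detects planted DA", {
  K <- 14L
  pairing <- make_symmetric_pairing(K)
  tmpl <- make_template(K, pairing)
  arr <- array(NA_real_, dim = c(4L, K, 3L))
  for (i in 1:4) arr[i, , ] <- tmpl
  sp <- symmetrize(as_landmark_array(arr), pairing)
  expect_true(directional_asymmetry_test(sp)$degenerate)
  # planted antisymmetric mean field at 3 coordinate SDs: strong signal
  set.seed(106)
  raw <- matrix(rnorm(K * 3L), K, 3L)
  anti <- (raw - mirror_config(raw, pairing)) / 2
  field <- as.vector(t(anti))
  field <- field / sqrt(mean(field^2)) * 0.03
  n <- 8L
  flat <- matrix(as.vector(t(tmpl)), n, 3L * K, byrow = TRUE) +
    matrix(field, n, 3L * K, byrow = TRUE) +
    matrix(rnorm(n * 3L * K, sd = 0.01), n, 3L * K)
  spd <- symmetrize(as_landmark_array(flat), pairing)
  res <- directional_asymmetry_test(spd)
  expect_false(res$degenerate)
  expect_lt(res$p, 0.01)
  expect_equal(res$df2, (n - 1L) * res$df1)
})

test_that("residualization removes group means, preserves the grand mean, and is orthogonal to the design", {
  set.seed(107)
  K <- 14L
  pairing <- make_symmetric_pairing(K)
  lm <- noisy_shapes(50L, K)
  sp <- symmetrize(lm, pairing)
  # null design: output equals input
  cov0 <- data.frame(generation = rep("G1", 50L), sex = rep("F", 50L))
  sp0 <- residualize_shape(sp, cov0)
  expect_equal(sp0$symmetric, sp$symmetric)
  # balanced two-group difference vanishes after residualization
  spb <- sp
  grp <- rep(c("A", "B"), each = 25L)
  delta <- rnorm(3L * K, sd = 0.02)
  spb$symmetric[grp == "B", ] <- sweep(spb$symmetric[grp == "B", ], 2L,
                                       delta, "+")
  spr <- residualize_shape(spb, data.frame(generation = grp))
  gm <- colMeans(spr$symmetric[grp == "A", ]) -
    colMeans(spr$symmetric[grp == "B", ])
  expect_lt(sqrt(sum(gm^2)), 1e-10)
  # random design: residual component orthogonal to design columns
  cov <- data.frame(generation = sample(c("G9", "G15", "G21"), 50L, TRUE),
                    sex = sample(c("F", "M"), 50L, TRUE))
  spx <- residualize_shape(sp, cov)
  design <- model.matrix(~ ., cov)
  resid <- sweep(spx$symmetric, 2L, colMeans(spx$symmetric))
  expect_lt(max(abs(crossprod(design[, -1L], resid))), 1e-8)
  # grand mean preserved
  expect_equal(colMeans(spx$symmetric), colMeans(sp$symmetric),
               tolerance = 1e-10)
  # confounded factors are rejected with the aliased levels named
  cov_bad <- data.frame(generation = grp, dup = grp)
  expect_error(residualize_shape(sp, cov_bad), "aliased")
})

test_that("landmark CSV and pairing files round-trip", {
  set.seed(108)
  lm <- noisy_shapes(5L, 14L)
  path <- tempfile(fileext = ".csv")
  write_landmarks(lm, path)
  back <- read_landmarks(path)
  expect_equal(unclass(back), unclass(lm), tolerance = 1e-9)
  pairing <- make_symmetric_pairing(14L)
  pp <- tempfile(fileext = ".csv")
  write_pairing(pairing, pp)
  back_p <- read_pairing(pp)
  expect_equal(back_p$pairs, pairing$pairs)
  expect_equal(back_p$midline, pairing$midline)
})
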