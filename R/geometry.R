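# Landmark geometry: Generalized Procrustes Analysis, object-symmetry
# decomposition, directional-asymmetry Procrustes ANOVA, and covariate
# residualization of shape.
#
# Conventions: landmark configurations are K x 3; samples are n x K x 3
# arrays; flattened shapes are length 3K ordered L1_x, L1_y, L1_z, L2_x,
# ... GPA removes translation and scales every configuration to unit
# centroid size; rotations are proper (no reflection). Tangent-space
# projection is not applied; analyses operate on aligned coordinates.

#' Coerce to a landmark array
#'
#' @param x an `n x K x 3` array, or an `n x 3K` matrix of flattened
#'   configurations (landmark-major order).
#' @param specimen_ids optional specimen ids.
#' @return An `n x K x 3` array of class `landmark_array`.
#' @export
as_landmark_array <- function(x, specimen_ids = NULL) {
  if (is.matrix(x)) {
    if (ncol(x) %% 3L != 0L) stop_mgp("flat landmark matrix must have 3K columns")
    K <- ncol(x) %/% 3L
    arr <- array(NA_real_, dim = c(nrow(x), K, 3L))
    for (a in 1:3) arr[, , a] <- x[, seq(a, by = 3L, length.out = K)]
    if (is.null(specimen_ids)) specimen_ids <- rownames(x)
    x <- arr
  }
  if (length(dim(x)) != 3L || dim(x)[3L] != 3L) {
    stop_mgp("landmarks must be an n x K x 3 array")
  }
  if (anyNA(x)) stop_mgp("missing landmark coordinates are not supported")
  if (is.null(specimen_ids)) specimen_ids <- dimnames(x)[[1L]]
  if (is.null(specimen_ids)) specimen_ids <- sprintf("s%04d", seq_len(dim(x)[1L]))
  dimnames(x) <- list(specimen_ids, NULL, c("x", "y", "z"))
  structure(x, class = c("landmark_array", "array"))
}

#' Flatten a landmark array to an n x 3K matrix
#'
#' Landmark-major order (`L1_x, L1_y, L1_z, L2_x, ...`), the layout
#' used by all flattened shape matrices in the package.
#'
#' @param arr an `n x K x 3` landmark array.
#' @return n x 3K numeric matrix with coordinate column names.
#' @export
flatten_landmarks <- function(arr) flatten_shapes(as_landmark_array(arr))

# Flatten n x K x 3 -> n x 3K (landmark-major) and back.
flatten_shapes <- function(arr) {
  d <- dim(arr)
  flat <- matrix(NA_real_, d[1L], d[2L] * 3L)
  for (a in 1:3) flat[, seq(a, by = 3L, length.out = d[2L])] <- arr[, , a]
  colnames(flat) <- paste0("L", rep(seq_len(d[2L]), each = 3L), "_",
                           rep(c("x", "y", "z"), times = d[2L]))
  rownames(flat) <- dimnames(arr)[[1L]]
  flat
}

unflatten_shape <- function(v) {
  matrix(v, ncol = 3L, byrow = TRUE)
}

#' Read landmarks from CSV
#'
#' Expects a header `specimen, L1_x, L1_y, L1_z, L2_x, ...`.
#'
#' @param path CSV path.
#' @return A `landmark_array`.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "specimen") stop_mgp("first column must be 'specimen'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$specimen
  as_landmark_array(m)
}

#' Write landmarks to CSV
#'
#' @param landmarks a `landmark_array` (or coercible).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  arr <- as_landmark_array(landmarks)
  flat <- flatten_shapes(arr)
  df <- data.frame(specimen = rownames(flat), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(flat))) df[[colnames(flat)[j]]] <- sprintf("%.10g", flat[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bilateral symmetry pairing
#'
#' CSV with columns `left,right` (1-based landmark indices) followed by
#' a `midline` section: rows where `right` is empty/NA list unpaired
#' midline landmarks in the `left` column.
#'
#' @param path CSV path.
#' @param K total number of landmarks (for validation).
#' @return A `symmetry_pairing` list with `pairs` (P x 2 matrix) and
#'   `midline` (integer vector).
#' @export
read_pairing <- function(path, K = NULL) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  is_mid <- is.na(df$right)
  symmetry_pairing(cbind(df$left[!is_mid], df$right[!is_mid]),
                   df$left[is_mid], K = K)
}

#' Construct a symmetry pairing
#'
#' @param pairs P x 2 matrix of (left, right) 1-based indices.
#' @param midline integer vector of unpaired midline indices.
#' @param K total landmark count; defaults to the maximum index seen.
#' @return A `symmetry_pairing` list.
#' @export
symmetry_pairing <- function(pairs, midline = integer(0), K = NULL) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  midline <- as.integer(midline)
  all_idx <- c(pairs, midline)
  if (is.null(K)) K <- max(all_idx)
  if (any(pairs[, 1L] == pairs[, 2L])) stop_mgp("left index equals right index")
  if (anyDuplicated(all_idx) || !setequal(all_idx, seq_len(K))) {
    stop_mgp("pairing indices must jointly cover 1..K without repeats")
  }
  structure(list(pairs = pairs, midline = midline, K = K),
            class = "symmetry_pairing")
}

#' Write a pairing to CSV
#' @param pairing a `symmetry_pairing`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pairing <- function(pairing, path) {
  df <- data.frame(left = c(pairing$pairs[, 1L], pairing$midline),
                   right = c(pairing$pairs[, 2L],
                             rep(NA_integer_, length(pairing$midline))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Centroid-center a K x 3 configuration and return unit-centroid-size
# version plus the size.
center_scale_config <- function(X) {
  X <- sweep(X, 2L, colMeans(X), "-")
  cs <- sqrt(sum(X^2))
  if (cs <= 0) stop_mgp("degenerate configuration: zero centroid size")
  list(X = X / cs, size = cs)
}

# Optimal proper rotation of centered X onto centered M (both K x 3):
# maximizes tr(R' X' M) subject to det(R) = +1.
opa_rotation <- function(X, M) {
  s <- svd(crossprod(X, M))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, 3L] <- -u[, 3L]
    R <- u %*% t(s$v)
  }
  R
}

#' Generalized Procrustes Analysis
#'
#' Iterative superimposition: every configuration is centered, scaled to
#' unit centroid size, and rotated (proper rotations only) to the
#' current mean; the mean is re-estimated until its change drops below
#' `tol` or `max_iter` iterations. The stored mean shape is the plain
#' average of the aligned configurations.
#'
#' @param landmarks a `landmark_array` (n >= 2, K >= 3).
#' @param tol convergence tolerance on the mean update (default 1e-10).
#' @param max_iter iteration cap (default 200).
#' @param canonical rotate the converged solution into the principal
#'   axes of the mean shape (sign-fixed, proper), so the output is
#'   invariant to specimen order and to rigid pre-transformations of
#'   the inputs. [symmetrize()] disables this to keep the reflection
#'   axis of the input frame.
#' @return A `shape_space` list: `aligned` (n x 3K), `centroid_sizes`,
#'   `mean_shape` (length 3K), `specimen_ids`, `K`; `symmetric` and
#'   `asymmetric` are `NULL` (see [symmetrize()]).
#' @export
gpa <- function(landmarks, tol = 1e-10, max_iter = 200L, canonical = TRUE) {
  arr <- as_landmark_array(landmarks)
  n <- dim(arr)[1L]; K <- dim(arr)[2L]
  if (n < 2L) stop_mgp("GPA needs at least 2 specimens")
  if (K < 3L) stop_mgp("GPA needs at least 3 landmarks")
  configs <- vector("list", n)
  sizes <- numeric(n)
  for (i in seq_len(n)) {
    cs <- tryCatch(center_scale_config(arr[i, , ]),
                   error = function(e) stop_mgp(
                     "degenerate configuration for specimen ",
                     dimnames(arr)[[1L]][i]))
    if (sum(svd(cs$X)$d > 1e-12) < 2L) {
      stop_mgp("degenerate (rank < 2) configuration for specimen ",
               dimnames(arr)[[1L]][i])
    }
    configs[[i]] <- cs$X
    sizes[i] <- cs$size
  }
  ref <- configs[[1L]]
  for (iter in seq_len(max_iter)) {
    aligned <- lapply(configs, function(X) X %*% opa_rotation(X, ref))
    newref <- Reduce(`+`, aligned) / n
    newref <- center_scale_config(newref)$X
    delta <- sqrt(sum((newref - ref)^2))
    ref <- newref
    if (delta < tol) break
  }
  aligned <- lapply(configs, function(X) X %*% opa_rotation(X, ref))
  if (canonical) {
    # rotate the solution so the mean shape sits in its principal axes
    # (sign-fixed, proper), making the output invariant to specimen
    # order and to arbitrary pre-rotation of the inputs
    M <- Reduce(`+`, aligned) / n
    R <- svd(M)$v
    if (det(R) < 0) R[, 3L] <- -R[, 3L]
    A <- M %*% R
    for (j in 1:2) {
      i_max <- which.max(abs(A[, j]))
      if (A[i_max, j] < 0) R[, j] <- -R[, j]
    }
    if (det(R) < 0) R[, 3L] <- -R[, 3L]
    aligned <- lapply(aligned, function(X) X %*% R)
  }
  arr_out <- array(NA_real_, dim = c(n, K, 3L))
  for (i in seq_len(n)) arr_out[i, , ] <- aligned[[i]]
  dimnames(arr_out) <- dimnames(arr)
  flat <- flatten_shapes(arr_out)
  structure(list(aligned = flat,
                 centroid_sizes = stats::setNames(sizes, dimnames(arr)[[1L]]),
                 mean_shape = colMeans(flat),
                 symmetric = NULL, asymmetric = NULL,
                 specimen_ids = dimnames(arr)[[1L]], K = K),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat(sprintf("<shape_space> %d specimens, %d landmarks (%d coordinates)%s\n",
              length(x$specimen_ids), x$K, 3L * x$K,
              if (!is.null(x$symmetric)) ", symmetrized" else ""))
  invisible(x)
}

# Reflect a K x 3 configuration through the yz-plane and swap paired
# landmark labels; midline landmarks keep their row.
reflect_relabel <- function(X, pairing) {
  Y <- X
  Y[, 1L] <- -Y[, 1L]
  swapped <- Y
  swapped[pairing$pairs[, 1L], ] <- Y[pairing$pairs[, 2L], ]
  swapped[pairing$pairs[, 2L], ] <- Y[pairing$pairs[, 1L], ]
  swapped
}

#' Object-symmetry decomposition
#'
#' Each configuration is joined with its reflected-and-relabeled copy
#' (mirror the x axis, swap left/right labels) and GPA is run over the
#' doubled sample. The symmetric component of a specimen is the average
#' of its aligned original and aligned reflected copy; the asymmetric
#' component is the aligned original minus the symmetric component, so
#' `symmetric + asymmetric = aligned` exactly.
#'
#' @param landmarks a `landmark_array`.
#' @param pairing a `symmetry_pairing` covering all K landmarks.
#' @param tol,max_iter passed to [gpa()].
#' @return A `shape_space` with `symmetric` and `asymmetric` filled;
#'   `mean_shape` is the (symmetric) mean over the doubled sample.
#' @export
symmetrize <- function(landmarks, pairing, tol = 1e-10, max_iter = 200L) {
  arr <- as_landmark_array(landmarks)
  n <- dim(arr)[1L]; K <- dim(arr)[2L]
  if (pairing$K != K) stop_mgp("pairing covers ", pairing$K,
                               " landmarks but data have ", K)
  doubled <- array(NA_real_, dim = c(2L * n, K, 3L))
  doubled[seq_len(n), , ] <- arr
  for (i in seq_len(n)) doubled[n + i, , ] <- reflect_relabel(arr[i, , ], pairing)
  ids <- dimnames(arr)[[1L]]
  dimnames(doubled) <- list(c(ids, paste0(ids, ".reflected")), NULL, NULL)
  space2 <- gpa(doubled, tol = tol, max_iter = max_iter, canonical = FALSE)
  # rotate the joint solution so the symmetry plane is exactly x = 0:
  # align the doubled-sample mean onto its own mirror-symmetrized
  # version until the rotation converges to the identity
  M <- unflatten_shape(space2$mean_shape)
  Rtot <- diag(3L)
  for (it in 1:100) {
    Msym <- (M + reflect_relabel(M, pairing)) / 2
    R <- opa_rotation(M, Msym)
    M <- M %*% R
    Rtot <- Rtot %*% R
    if (max(abs(R - diag(3L))) < 1e-14) break
  }
  # the in-plane rotation (about x) is still free: pin it by putting
  # the mean's y-z coordinates into their principal axes, sign-fixed
  R2 <- svd(M[, 2:3])$v
  if (det(R2) < 0) R2[, 2L] <- -R2[, 2L]
  A2 <- M[, 2:3] %*% R2
  if (A2[which.max(abs(A2[, 1L])), 1L] < 0) R2 <- -R2  # proper in 2D
  R3 <- diag(3L)
  R3[2:3, 2:3] <- R2
  Rtot <- Rtot %*% R3
  rot_flat <- function(flat) {
    for (l in seq_len(K)) {
      idx <- (l - 1L) * 3L + 1:3
      flat[, idx] <- flat[, idx, drop = FALSE] %*% Rtot
    }
    flat
  }
  space2$aligned <- rot_flat(space2$aligned)
  space2$mean_shape <- colMeans(space2$aligned)
  orig <- space2$aligned[seq_len(n), , drop = FALSE]
  refl <- space2$aligned[n + seq_len(n), , drop = FALSE]
  sym <- (orig + refl) / 2
  asym <- orig - sym
  rownames(orig) <- rownames(sym) <- rownames(asym) <- ids
  structure(list(aligned = orig,
                 centroid_sizes = space2$centroid_sizes[seq_len(n)],
                 mean_shape = space2$mean_shape,
                 symmetric = sym, asymmetric = asym,
                 specimen_ids = ids, K = K, pairing = pairing),
            class = "shape_space")
}

#' Procrustes ANOVA test for directional asymmetry
#'
#' Tests whether the mean asymmetric component differs from zero against
#' fluctuating asymmetry. With asymmetric components `a_i`,
#' `SS_DA = n * ||mean(a)||^2` and `SS_FA = sum ||a_i - mean(a)||^2`;
#' `F = (SS_DA / df1) / (SS_FA / df2)` with `df1` the empirical rank of
#' the centered asymmetric matrix and `df2 = (n - 1) * df1`. The p-value
#' comes from the F distribution.
#'
#' @param space a symmetrized `shape_space`.
#' @param rank_tol relative singular-value tolerance for the rank.
#' @return A list of class `da_test`: `F`, `df1`, `df2`, `p`, `ss_da`,
#'   `ss_fa`, `degenerate`.
#' @export
directional_asymmetry_test <- function(space, rank_tol = 1e-8) {
  if (is.null(space$asymmetric)) stop_mgp("space has no asymmetric component; run symmetrize()")
  A <- space$asymmetric
  n <- nrow(A)
  if (n < 3L) stop_mgp("directional asymmetry test needs n >= 3")
  abar <- colMeans(A)
  ss_da <- n * sum(abar^2)
  Ac <- sweep(A, 2L, abar, "-")
  ss_fa <- sum(Ac^2)
  if (ss_fa <= .Machine$double.eps * max(1, ss_da)) {
    return(structure(list(F = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                          p = NA_real_, ss_da = ss_da, ss_fa = ss_fa,
                          degenerate = TRUE), class = "da_test"))
  }
  d <- svd(Ac, nu = 0L, nv = 0L)$d
  df1 <- sum(d > rank_tol * d[1L])
  df2 <- (n - 1L) * df1
  Fval <- (ss_da / df1) / (ss_fa / df2)
  p <- stats::pf(Fval, df1, df2, lower.tail = FALSE)
  structure(list(F = Fval, df1 = df1, df2 = df2, p = p,
                 ss_da = ss_da, ss_fa = ss_fa, degenerate = FALSE),
            class = "da_test")
}

#' @export
print.da_test <- function(x, ...) {
  if (x$degenerate) {
    cat("<da_test> degenerate: no fluctuating-asymmetry variation\n")
  } else {
    cat(sprintf("<da_test> F = %.4g on (%d, %d) df, p = %.3g\n",
                x$F, x$df1, x$df2, x$p))
  }
  invisible(x)
}

#' Residualize shape on covariates
#'
#' Regresses each shape coordinate on dummy-coded covariates (typically
#' breeding generation and sex) and replaces the shapes with residuals
#' plus the grand mean, removing between-group mean differences while
#' preserving the overall mean shape. Operates on the symmetric
#' component when present, otherwise on the aligned coordinates.
#'
#' @param space a `shape_space`.
#' @param covariates a `data.frame` with one row per specimen (matched
#'   to `space$specimen_ids` by a `specimen` column if present,
#'   otherwise by position); all columns are treated as factors.
#' @return The `shape_space` with the target component replaced;
#'   fitted coefficients are attached as attribute `coefficients`.
#' @export
residualize_shape <- function(space, covariates) {
  comp <- if (!is.null(space$symmetric)) "symmetric" else "aligned"
  Y <- space[[comp]]
  cov <- as.data.frame(covariates)
  if ("specimen" %in% names(cov)) {
    idx <- match(space$specimen_ids, cov$specimen)
    if (anyNA(idx)) stop_mgp("covariates missing for specimen(s): ",
                             paste(space$specimen_ids[is.na(idx)][1:5],
                                   collapse = ", "))
    cov <- cov[idx, setdiff(names(cov), "specimen"), drop = FALSE]
  }
  if (nrow(cov) != nrow(Y)) stop_mgp("covariate rows do not match specimens")
  cov[] <- lapply(cov, function(col) factor(col))
  keep <- vapply(cov, function(col) nlevels(col) > 1L, logical(1L))
  grand <- colMeans(Y)
  if (!any(keep)) {
    # null design: nothing to remove
    attr(space, "coefficients") <- NULL
    return(space)
  }
  design <- stats::model.matrix(~ ., data = cov[, keep, drop = FALSE])
  qrD <- qr(design)
  if (qrD$rank < ncol(design)) {
    aliased <- colnames(design)[qrD$pivot[(qrD$rank + 1L):ncol(design)]]
    stop_mgp("rank-deficient covariate design; aliased: ",
             paste(aliased, collapse = ", "))
  }
  fit <- stats::lm.fit(design, Y)
  out <- fit$residuals + matrix(grand, nrow(Y), ncol(Y), byrow = TRUE)
  dimnames(out) <- dimnames(Y)
  space[[comp]] <- out
  coefs <- fit$coefficients
  attr(space, "coefficients") <- coefs
  space
}
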