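# Mutant effect directions: joint registration of reference and mutant
# samples, two-group contrast vectors, and projection of process
# effects into the pooled principal-component morphospace.

#' Jointly register reference and mutant landmark sets
#'
#' Pools the two samples (same K and landmark order required) and runs
#' GPA over the union, with size removed; when a pairing is given the
#' pooled sample is additionally decomposed into symmetric and
#' asymmetric components. Group membership is preserved in the
#' `groups` attribute.
#'
#' @param reference a `landmark_array` of reference (e.g. outbred)
#'   specimens.
#' @param mutants a `landmark_array` of mutant specimens.
#' @param pairing optional `symmetry_pairing`; when supplied,
#'   [symmetrize()] is used instead of plain [gpa()].
#' @return A `shape_space` over the pooled sample with attribute
#'   `groups` (factor `reference` / `mutant` per specimen).
#' @export
joint_registration <- function(reference, mutants, pairing = NULL) {
  ref <- as_landmark_array(reference)
  mut <- as_landmark_array(mutants)
  if (dim(ref)[2L] != dim(mut)[2L]) {
    stop_mgp("landmark count mismatch: ", dim(ref)[2L], " vs ", dim(mut)[2L])
  }
  n_ref <- dim(ref)[1L]; n_mut <- dim(mut)[1L]
  pooled <- array(NA_real_, dim = c(n_ref + n_mut, dim(ref)[2L], 3L))
  pooled[seq_len(n_ref), , ] <- ref
  pooled[n_ref + seq_len(n_mut), , ] <- mut
  ids <- c(dimnames(ref)[[1L]], dimnames(mut)[[1L]])
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  dimnames(pooled) <- list(ids, NULL, NULL)
  space <- if (is.null(pairing)) gpa(pooled) else symmetrize(pooled, pairing)
  attr(space, "groups") <- factor(rep(c("reference", "mutant"),
                                      c(n_ref, n_mut)),
                                  levels = c("reference", "mutant"))
  space
}

# Pick the working coordinate matrix of a shape space: the symmetric
# component when present, else the aligned coordinates.
space_coords <- function(space) {
  if (!is.null(space$symmetric)) space$symmetric else space$aligned
}

#' Mutant effect direction (two-group contrast)
#'
#' The per-coordinate difference between the mutant group mean and the
#' reference group mean: exactly the group-coded coefficient vector of
#' a two-group multivariate linear model (the MANOVA contrast
#' direction), used as a shape direction, not as a test statistic.
#'
#' @param space a jointly registered `shape_space`.
#' @param reference_ids,mutant_ids specimen ids (or logical/integer
#'   indices into `space$specimen_ids`) of the two groups.
#' @param label label for the resulting effect vector.
#' @return A list of class `effect_vector`: `values` (length 3K),
#'   `label`, `kind = "mutant"`, `n_mutant`, `n_reference`.
#' @export
mutant_direction <- function(space, reference_ids, mutant_ids,
                             label = "mutant") {
  M <- space_coords(space)
  pick <- function(ids) {
    if (is.character(ids)) {
      idx <- match(ids, space$specimen_ids)
      if (anyNA(idx)) stop_mgp("unknown specimen id(s)")
      idx
    } else if (is.logical(ids)) {
      which(ids)
    } else {
      as.integer(ids)
    }
  }
  ri <- pick(reference_ids); mi <- pick(mutant_ids)
  if (!length(ri) || !length(mi)) stop_mgp("empty group")
  dir <- colMeans(M[mi, , drop = FALSE]) - colMeans(M[ri, , drop = FALSE])
  structure(list(values = unname(dir), label = label, kind = "mutant",
                 n_mutant = length(mi), n_reference = length(ri)),
            class = "effect_vector")
}

#' Construct an effect vector
#'
#' @param values numeric shape direction (length 3K).
#' @param label display label.
#' @param kind one of `"process"`, `"mutant"`, `"pc"`.
#' @return An `effect_vector` list.
#' @export
effect_vector <- function(values, label = "", kind = c("process", "mutant", "pc")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop_mgp("effect vector must be finite")
  structure(list(values = values, label = label, kind = kind),
            class = "effect_vector")
}

#' @export
print.effect_vector <- function(x, ...) {
  cat(sprintf("<effect_vector> '%s' (%s), length %d, norm %.4g\n",
              x$label, x$kind, length(x$values), sqrt(sum(x$values^2))))
  invisible(x)
}

#' Project effect vectors onto the pooled morphospace
#'
#' Runs a PCA of the registered coordinates and draws each effect as a
#' vector from the reference mean shape, magnified by `magnify`, with
#' its tip projected onto PCs 1-2. Also returns per-specimen PC scores,
#' the per-PC variance fractions, and the normal-theory 95% data
#' ellipse of the reference group on PCs 1-2 (chi-square quantile,
#' 2 df).
#'
#' @param space a `shape_space` (pooled reference + mutants).
#' @param effects a list of `effect_vector`s (or plain length-3K
#'   vectors).
#' @param magnify magnification factor for effect vectors (default 4, a
#'   display convention for small process effects).
#' @param reference_ids optional ids of the reference group; defaults
#'   to the `groups` attribute's `reference` level, else all specimens.
#' @return A list of class `morphospace`: `scores` (n x 2), `tips`
#'   (effects x 2), `origin` (reference mean in PC coordinates),
#'   `variance_fractions`, `ellipse` (list: `center`, `axes`, `radii`),
#'   `magnify`.
#' @export
project_onto_morphospace <- function(space, effects, magnify = 4,
                                     reference_ids = NULL) {
  M <- space_coords(space)
  if (nrow(M) < 3L) stop_mgp("morphospace projection needs n >= 3")
  if (is.null(reference_ids)) {
    grp <- attr(space, "groups")
    ref_idx <- if (!is.null(grp)) which(grp == "reference") else seq_len(nrow(M))
  } else {
    ref_idx <- match(reference_ids, space$specimen_ids)
    if (anyNA(ref_idx)) stop_mgp("unknown reference specimen id(s)")
  }
  pca <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  rot <- pca$rotation[, 1:2, drop = FALSE]
  scores <- pca$x[, 1:2, drop = FALSE]
  ref_mean <- colMeans(M[ref_idx, , drop = FALSE])
  origin <- as.vector(crossprod(rot, ref_mean - pca$center))
  vals <- lapply(effects, function(e) if (inherits(e, "effect_vector")) e$values else as.numeric(e))
  labs <- if (!is.null(names(effects))) names(effects) else
    vapply(seq_along(effects), function(i) {
      e <- effects[[i]]
      if (inherits(e, "effect_vector") && nzchar(e$label)) e$label else paste0("effect", i)
    }, character(1L))
  tips <- t(vapply(vals, function(v) {
    if (length(v) != ncol(M)) stop_mgp("effect length does not match space")
    as.vector(crossprod(rot, ref_mean + magnify * v - pca$center))
  }, numeric(2L)))
  dimnames(tips) <- list(labs, c("PC1", "PC2"))
  varfrac <- pca$sdev^2 / sum(pca$sdev^2)
  S <- stats::cov(scores[ref_idx, , drop = FALSE])
  eg <- eigen(S, symmetric = TRUE)
  radii <- sqrt(eg$values * stats::qchisq(0.95, df = 2))
  structure(list(scores = scores,
                 tips = tips,
                 origin = origin,
                 variance_fractions = varfrac,
                 ellipse = list(center = colMeans(scores[ref_idx, , drop = FALSE]),
                                axes = eg$vectors, radii = radii),
                 magnify = magnify),
            class = "morphospace")
}
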