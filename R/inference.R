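# Inference over fitted process effects: LD-matched permutation null
# for variance explained, vector correlations, gene-drop sensitivity,
# pairwise process comparison, and clustering stability.

#' Vector correlation between two effect directions
#'
#' Pearson product-moment correlation between two shape-effect vectors
#' (e.g. PLS1 phenotypic loadings, mutant contrasts), with the usual
#' t test on `df = L - 2` where `L` is the vector length (optionally a
#' landmark subset, e.g. palate-only coordinates).
#'
#' @param a,b numeric vectors of equal length `L >= 3`.
#' @param subset optional integer index vector restricting the
#'   comparison to a coordinate subset.
#' @return A list of class `vec_cor`: `r`, `t`, `df`, `p`.
#' @export
vector_correlation <- function(a, b, subset = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop_mgp("vectors differ in length")
  if (!is.null(subset)) { a <- a[subset]; b <- b[subset] }
  L <- length(a)
  if (L < 3L) stop_mgp("vector correlation needs length >= 3")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop_mgp("vector correlation undefined: zero variance",
             class = "mgp_degenerate")
  }
  r <- stats::cor(a, b)
  df <- L - 2L
  tstat <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(r = r, t = tstat, df = df, p = p), class = "vec_cor")
}

#' @export
print.vec_cor <- function(x, ...) {
  cat(sprintf("<vec_cor> r = %.3f (t = %.3g, df = %d, p = %.3g)\n",
              x$r, x$t, x$df, x$p))
  invisible(x)
}

# Precompute per-gene standardized blocks, gene-level LD, and shape
# pieces shared across many refits on the same data.
perm_engine <- function(catalog, probs, map, Y) {
  genes_ok <- catalog$chrom %in% unique(map$chrom)
  cat_use <- catalog[genes_ok, , drop = FALSE]
  blocks <- vector("list", nrow(cat_use))
  names(blocks) <- cat_use$gene
  for (i in seq_len(nrow(cat_use))) {
    fl <- select_flanking_markers(cat_use[i, , drop = FALSE], map)
    blocks[[i]] <- gene_probability_block(probs, fl[["upstream"]],
                                          fl[["downstream"]])
  }
  std_blocks <- lapply(blocks, function(b) std_cols(b)$X)
  y_ctr <- colMeans(Y)
  Yc <- sweep(Y, 2L, y_ctr, "-")
  y_tr <- sum(colSums(Yc^2) / max(1L, nrow(Yc) - 1L))
  list(catalog = cat_use, blocks = blocks, std_blocks = std_blocks,
       ld = gene_ld_matrix(blocks), Yc = Yc, Ys = Yc_std(Yc), y_tr = y_tr,
       n = nrow(Y))
}

engine_fit <- function(eng, gene_idx, lambda) {
  Xs <- do.call(cbind, eng$std_blocks[gene_idx])
  C <- crossprod(Xs, eng$Ys) / (eng$n - 1L)
  fit_core(Xs, eng$Yc, eng$y_tr, lambda, C = C)
}

mean_set_ld <- function(ld, idx) {
  if (length(idx) < 2L) return(0)
  sub <- ld[idx, idx]
  mean(sub[lower.tri(sub)])
}

#' LD-matched permutation null for variance explained
#'
#' Compares the observed R^2 of a gene-set model against R^2 values
#' from random gene sets of the same size drawn from the catalog, fit
#' with the identical `lambda`. Draws are constrained to match the
#' observed set's mean within-set LD (gene-level `max`-over-founders
#' squared track correlation) within `ld_tol`; after 50 rejected draws
#' the closest-matching candidate is accepted. The one-sided p-value
#' uses the add-one estimator
#' `p = (1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @param gene_set the observed `gene_set`.
#' @param catalog gene catalog to draw from (must be larger than the
#'   gene set).
#' @param probs `founder_probs` array.
#' @param map marker map.
#' @param Y shape matrix used for the observed fit.
#' @param lambda regularization, held fixed across permutations.
#' @param n_perm number of permutations (default 10000).
#' @param ld_tol tolerance on mean within-set LD (default 0.05).
#' @param seed integer seed; the null is bit-reproducible under it.
#' @return An object of class `mgp_null`: `observed_r2`, `null_r2`,
#'   `p_value`, `n_permutations`, `ld_tolerance`, `seed`,
#'   `observed_ld`.
#' @export
permutation_null <- function(gene_set, catalog, probs, map, Y, lambda = 0.06,
                             n_perm = 10000L, ld_tol = 0.05, seed = 1L) {
  genes <- if (inherits(gene_set, "gene_set")) gene_set$genes else gene_set
  eng <- perm_engine(catalog, probs, map, Y)
  obs_idx <- match(genes$gene, eng$catalog$gene)
  obs_idx <- obs_idx[!is.na(obs_idx)]
  m <- length(obs_idx)
  if (m < 1L) stop_mgp("gene set has no genes usable with this catalog/map")
  if (nrow(eng$catalog) <= m) stop_mgp("catalog not larger than the gene set")
  obs_fit <- engine_fit(eng, obs_idx, lambda)
  obs_ld <- mean_set_ld(eng$ld, obs_idx)
  null_r2 <- numeric(n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      best_idx <- NULL
      best_gap <- Inf
      for (try in seq_len(51L)) {
        idx <- sample.int(nrow(eng$catalog), m)
        gap <- abs(mean_set_ld(eng$ld, idx) - obs_ld)
        if (gap < best_gap) { best_gap <- gap; best_idx <- idx }
        if (gap <= ld_tol) break
      }
      null_r2[b] <- engine_fit(eng, best_idx, lambda)$r2
    }
  })
  p <- (1 + sum(null_r2 >= obs_fit$r2)) / (1 + n_perm)
  structure(list(observed_r2 = obs_fit$r2, null_r2 = null_r2, p_value = p,
                 n_permutations = n_perm, ld_tolerance = ld_tol, seed = seed,
                 observed_ld = obs_ld),
            class = "mgp_null")
}

#' @export
print.mgp_null <- function(x, ...) {
  cat(sprintf("<mgp_null> observed R^2 = %.4g vs %d permutations; p = %.4g\n",
              x$observed_r2, x$n_permutations, x$p_value))
  invisible(x)
}

#' Gene-drop sensitivity test
#'
#' Ranks genes by the Euclidean norm of their 8 founder loadings in the
#' full fit, then cumulatively removes the most heavily loaded genes,
#' refitting with the same `lambda` after each removal. Reports, per
#' number of genes removed, the variance explained and the absolute
#' vector correlation of the refit phenotypic loadings with the
#' full-model loadings. A refit that saturates to zero records a
#' correlation of 0 and is flagged.
#'
#' @param gene_set the `gene_set` under study.
#' @param probs `founder_probs` array.
#' @param map marker map.
#' @param Y shape matrix.
#' @param lambda regularization, fixed across refits.
#' @param max_drop maximum genes to remove (`<` number of genes).
#' @return A `data.frame` with columns `k_removed`, `gene_removed`,
#'   `r2`, `corr_with_full`, `saturated`.
#' @export
gene_drop <- function(gene_set, probs, map, Y, lambda = 0.06, max_drop = 5L) {
  genes <- if (inherits(gene_set, "gene_set")) gene_set$genes else gene_set
  eng <- perm_engine(genes, probs, map, Y)
  m <- nrow(eng$catalog)
  if (max_drop >= m) stop_mgp("max_drop must be smaller than the gene set")
  full_idx <- seq_len(m)
  full <- engine_fit(eng, full_idx, lambda)
  norms <- sqrt(colSums(matrix(full$u, nrow = 8L)^2))
  order_drop <- order(norms, decreasing = TRUE)
  out <- data.frame(k_removed = 0:max_drop,
                    gene_removed = c(NA_character_,
                                     eng$catalog$gene[order_drop[seq_len(max_drop)]]),
                    r2 = NA_real_, corr_with_full = NA_real_,
                    saturated = FALSE, stringsAsFactors = FALSE)
  out$r2[1L] <- full$r2
  out$corr_with_full[1L] <- 1
  for (k in seq_len(max_drop)) {
    keep <- full_idx[!(full_idx %in% order_drop[seq_len(k)])]
    fk <- engine_fit(eng, keep, lambda)
    out$r2[k + 1L] <- fk$r2
    if (fk$d == 0 || stats::sd(fk$v) == 0) {
      out$corr_with_full[k + 1L] <- 0
      out$saturated[k + 1L] <- TRUE
    } else {
      out$corr_with_full[k + 1L] <- abs(stats::cor(fk$v, full$v))
    }
  }
  attr(out, "loading_norms") <- stats::setNames(norms, eng$catalog$gene)
  out
}

#' Pairwise process-effect correlation matrix
#'
#' Absolute vector correlations between every pair of effect vectors
#' (diagonal 1); invariant to sign flips of any effect.
#'
#' @param effects a named list of numeric vectors of equal length (at
#'   least 2).
#' @return Symmetric matrix of `|r|` with unit diagonal.
#' @export
pairwise_process_matrix <- function(effects) {
  if (length(effects) < 2L) stop_mgp("need at least 2 effect vectors")
  L <- unique(vapply(effects, length, integer(1L)))
  if (length(L) != 1L) stop_mgp("effect vectors differ in length")
  m <- length(effects)
  labs <- names(effects)
  if (is.null(labs)) labs <- paste0("effect", seq_len(m))
  M <- diag(1, m)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      M[i, j] <- M[j, i] <- abs(vector_correlation(effects[[i]],
                                                   effects[[j]])$r)
    }
  }
  dimnames(M) <- list(labs, labs)
  M
}

#' Cluster process effects and measure cophenetic stability
#'
#' Converts a pairwise `|r|` matrix to distances `1 - |r|`, builds an
#' agglomerative dendrogram, and correlates the dendrogram-implied
#' (cophenetic) distances with the original distances over the strictly
#' lower-triangle pairs. For `m` processes there are `m (m - 1) / 2`
#' pairs and the t test has `df = n_pairs - 2`.
#'
#' @param corr square symmetric matrix with unit diagonal.
#' @param linkage one of `"complete"` (default), `"single"`,
#'   `"average"`.
#' @return A list of class `mgp_clust`: `hclust`, `cophenetic` (full
#'   matrix), `cophenetic_r`, `t`, `df`, `p`, `distance`.
#' @export
cluster_and_cophenetic <- function(corr,
                                   linkage = c("complete", "single", "average")) {
  linkage <- match.arg(linkage)
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) || max(abs(corr - t(corr))) > 1e-8) {
    stop_mgp("correlation matrix must be square and symmetric")
  }
  D <- stats::as.dist(1 - abs(corr))
  hc <- stats::hclust(D, method = linkage)
  coph <- stats::cophenetic(hc)
  vc <- vector_correlation(as.vector(coph), as.vector(D))
  coph_m <- as.matrix(coph)
  dimnames(coph_m) <- dimnames(corr)
  structure(list(hclust = hc, cophenetic = coph_m,
                 cophenetic_r = vc$r, t = vc$t, df = vc$df, p = vc$p,
                 distance = as.matrix(D)),
            class = "mgp_clust")
}

#' @export
print.mgp_clust <- function(x, ...) {
  cat(sprintf("<mgp_clust> %d processes; cophenetic r = %.3f (t = %.3g, df = %d, p = %.3g)\n",
              nrow(x$cophenetic), x$cophenetic_r, x$t, x$df, x$p))
  invisible(x)
}

#' Export a process dendrogram as Newick text
#'
#' @param clust an `mgp_clust` result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(clust, path) {
  phy <- ape::as.phylo(clust$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
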