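# Founder-probability genotypes: marker maps, flanking-marker selection,
# per-gene probability blocks, linkage-disequilibrium and kinship
# summaries. Founder labels are fixed A..H in input column order.

FOUNDERS <- LETTERS[1:8]

#' Read a marker map
#'
#' Reads a 3-column tab-separated file (`marker`, `chrom`, `pos`) with a
#' header. Positions must be strictly increasing within each chromosome
#' and marker ids unique.
#'
#' @param path path to the marker map TSV.
#' @return A `data.frame` with columns `marker`, `chrom`, `pos`.
#' @export
read_marker_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(df))) {
    stop_mgp("marker map must have columns: ", paste(need, collapse = ", "))
  }
  df$marker <- as.character(df$marker)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.numeric(df$pos)
  validate_marker_map(df)
  df[need]
}

validate_marker_map <- function(map) {
  if (anyDuplicated(map$marker)) stop_mgp("duplicate marker ids in map")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop_mgp("marker positions not strictly increasing on chromosome ", ch)
    }
  }
  invisible(map)
}

#' Construct a founder-probability array
#'
#' Wraps an `n_specimens x n_markers x 8` array of diplotype founder
#' contributions. Each (specimen, marker) 8-vector must be non-negative
#' and sum to 1 within 1e-6.
#'
#' @param probs numeric 3-d array; third dimension length 8.
#' @param specimen_ids,marker_ids optional dimnames; taken from `probs`
#'   if absent.
#' @return An object of class `founder_probs` (the validated array).
#' @export
founder_probs <- function(probs, specimen_ids = NULL, marker_ids = NULL) {
  if (length(dim(probs)) != 3L || dim(probs)[3L] != 8L) {
    stop_mgp("probs must be an n x m x 8 array")
  }
  if (is.null(specimen_ids)) specimen_ids <- dimnames(probs)[[1L]]
  if (is.null(marker_ids)) marker_ids <- dimnames(probs)[[2L]]
  if (is.null(specimen_ids)) specimen_ids <- sprintf("s%04d", seq_len(dim(probs)[1L]))
  if (is.null(marker_ids)) stop_mgp("marker ids are required")
  dimnames(probs) <- list(specimen_ids, marker_ids, FOUNDERS)
  if (any(probs < -1e-9)) stop_mgp("negative founder probabilities")
  sums <- rowSums(probs, dims = 2L)
  if (any(abs(sums - 1) > 1e-6)) {
    stop_mgp("founder probabilities must sum to 1 per (specimen, marker)")
  }
  structure(probs, class = "founder_probs")
}

#' Read founder probabilities from a long-format table
#'
#' Expects tab-separated columns
#' `specimen, marker, pA, pB, ..., pH` with a header (gzip transparent).
#'
#' @param path path to the long-format TSV.
#' @param map optional marker map used to order markers; defaults to
#'   first-appearance order.
#' @return A `founder_probs` array.
#' @export
read_founder_probs <- function(path, map = NULL) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  pcols <- paste0("p", FOUNDERS)
  need <- c("specimen", "marker", pcols)
  if (!all(need %in% names(df))) {
    stop_mgp("founder probability table must have columns: ",
             paste(need, collapse = ", "))
  }
  specs <- unique(df$specimen)
  marks <- if (is.null(map)) unique(df$marker) else map$marker
  arr <- array(NA_real_, dim = c(length(specs), length(marks), 8L),
               dimnames = list(specs, marks, FOUNDERS))
  i <- match(df$specimen, specs)
  j <- match(df$marker, marks)
  if (anyNA(j)) stop_mgp("probability table contains markers absent from map")
  for (f in 1:8) {
    arr[cbind(i, j, f)] <- df[[pcols[f]]]
  }
  if (anyNA(arr)) stop_mgp("missing (specimen, marker) combinations in table")
  founder_probs(arr)
}

#' Write founder probabilities to a long-format table
#'
#' Inverse of [read_founder_probs()].
#'
#' @param probs a `founder_probs` array.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_founder_probs <- function(probs, path) {
  d <- dim(probs)
  specs <- rep(dimnames(probs)[[1L]], times = d[2L])
  marks <- rep(dimnames(probs)[[2L]], each = d[1L])
  flat <- matrix(probs, nrow = d[1L] * d[2L], ncol = 8L)
  df <- data.frame(specimen = specs, marker = marks,
                   stringsAsFactors = FALSE)
  for (f in 1:8) df[[paste0("p", FOUNDERS[f])]] <- sprintf("%.10g", flat[, f])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select the flanking markers for a gene
#'
#' The gene center is `floor((start + end) / 2)`. The upstream marker is
#' the one with the largest position `<=` center on the gene's
#' chromosome; the downstream marker has the smallest position `>`
#' center. Genes whose center lies before the first (after the last)
#' marker get that terminal marker for both slots. Upstream/downstream
#' is in base-pair coordinates, not strand-relative.
#'
#' @param gene a single-row gene record (from a catalog) with `gene`,
#'   `chrom`, `start`, `end`.
#' @param map marker map.
#' @return Named character vector `c(upstream = ..., downstream = ...)`.
#' @export
select_flanking_markers <- function(gene, map) {
  chrom_rows <- map[map$chrom == gene$chrom, , drop = FALSE]
  if (!nrow(chrom_rows)) {
    stop_mgp("no markers on chromosome ", gene$chrom, " for gene ", gene$gene)
  }
  ctr <- floor((gene$start + gene$end) / 2)
  at <- which(chrom_rows$pos == ctr)
  if (length(at)) {
    # a marker exactly at the gene center serves as both flanks
    return(c(upstream = chrom_rows$marker[at[1L]],
             downstream = chrom_rows$marker[at[1L]]))
  }
  below <- chrom_rows$pos <= ctr
  up <- if (any(below)) chrom_rows$marker[max(which(below))] else chrom_rows$marker[1L]
  above <- chrom_rows$pos > ctr
  down <- if (any(above)) chrom_rows$marker[min(which(above))] else chrom_rows$marker[nrow(chrom_rows)]
  if (!any(below)) down <- chrom_rows$marker[1L]   # center before first marker
  if (!any(above)) up <- chrom_rows$marker[nrow(chrom_rows)]
  c(upstream = up, downstream = down)
}

#' Average founder probabilities of two flanking markers
#'
#' Returns the elementwise mean of the two markers' founder-probability
#' 8-vectors for every specimen; rows remain on the simplex.
#'
#' @param probs a `founder_probs` array.
#' @param up,down marker ids (equal ids give that marker's block).
#' @return An `n x 8` matrix with founder column names.
#' @export
gene_probability_block <- function(probs, up, down) {
  marks <- dimnames(probs)[[2L]]
  if (!(up %in% marks) || !(down %in% marks)) {
    stop_mgp("unknown marker id: ", paste(setdiff(c(up, down), marks),
                                          collapse = ", "))
  }
  blk <- (probs[, up, ] + probs[, down, ]) / 2
  colnames(blk) <- FOUNDERS
  blk
}

#' Assemble the per-gene genotype block for a gene set
#'
#' For each gene, flanking markers are selected and their founder
#' probabilities averaged; the per-gene 8-column blocks are concatenated
#' in gene order. Genes on chromosomes without markers are dropped with
#' a warning. Identical flanking pairs across genes are retained
#' per-gene, since loadings are reported per gene.
#'
#' @param gene_set a `gene_set` from [resolve_gene_set()], or a catalog
#'   `data.frame` subset.
#' @param probs a `founder_probs` array.
#' @param map marker map.
#' @return An object of class `genotype_block`: an `n x (8 m)` matrix
#'   with columns named `gene.founder`, plus attributes `genes` and
#'   `gene_to_markers`.
#' @export
assemble_genotype_block <- function(gene_set, probs, map) {
  genes <- if (inherits(gene_set, "gene_set")) gene_set$genes else gene_set
  if (!nrow(genes)) stop_mgp("empty gene set")
  blocks <- vector("list", nrow(genes))
  flank <- vector("list", nrow(genes))
  kept <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, , drop = FALSE]
    if (!any(map$chrom == g$chrom)) next
    fl <- select_flanking_markers(g, map)
    blocks[[i]] <- gene_probability_block(probs, fl[["upstream"]],
                                          fl[["downstream"]])
    flank[[i]] <- fl
    kept[i] <- TRUE
  }
  if (!any(kept)) stop_mgp("all genes dropped: no chromosome has markers")
  if (any(!kept)) {
    warning(sprintf("%d gene(s) dropped (no markers on their chromosome): %s",
                    sum(!kept), paste(genes$gene[!kept], collapse = ", ")),
            call. = FALSE)
  }
  X <- do.call(cbind, blocks[kept])
  gk <- genes$gene[kept]
  colnames(X) <- paste(rep(gk, each = 8L), rep(FOUNDERS, times = length(gk)),
                       sep = ".")
  rownames(X) <- dimnames(probs)[[1L]]
  g2m <- do.call(rbind, flank[kept])
  rownames(g2m) <- gk
  structure(X, class = c("genotype_block", "matrix", "array"),
            genes = gk, gene_to_markers = g2m)
}

#' Linkage disequilibrium between two founder-probability tracks
#'
#' The 8-founder probability block of a marker (or gene) has no single
#' allele dosage; instead each founder's probability track is treated as
#' a dosage, and LD between two blocks is the maximum over founders of
#' the squared Pearson correlation of matching tracks. Founders with
#' zero variance in either block are skipped; if no founder is usable
#' the value is undefined and `NA` is returned with a warning.
#'
#' @param block_a,block_b `n x 8` founder-probability matrices (from
#'   [gene_probability_block()]) for the same specimens.
#' @return Squared correlation in `[0, 1]`, or `NA` when undefined.
#' @export
ld_r2 <- function(block_a, block_b) {
  block_a <- as.matrix(block_a); block_b <- as.matrix(block_b)
  if (!all(dim(block_a) == dim(block_b)) || ncol(block_a) != 8L) {
    stop_mgp("ld_r2 expects two n x 8 blocks of equal size")
  }
  if (nrow(block_a) < 3L) stop_mgp("ld_r2 needs at least 3 specimens")
  va <- col_vars(block_a); vb <- col_vars(block_b)
  ok <- va > 0 & vb > 0
  if (!any(ok)) {
    warning("ld_r2 undefined: zero variance in all founder tracks",
            call. = FALSE)
    return(NA_real_)
  }
  r <- vapply(which(ok), function(f) {
    stats::cor(block_a[, f], block_b[, f])
  }, numeric(1L))
  max(r^2)
}

# Pairwise gene-level LD matrix over a list of n x 8 gene blocks.
# Entry (i, j) = max over founders of squared correlation of the
# founder's tracks. Used by the permutation engine for LD matching.
gene_ld_matrix <- function(blocks) {
  m <- length(blocks)
  n <- nrow(blocks[[1L]])
  best <- matrix(0, m, m)
  for (f in 1:8) {
    tracks <- vapply(blocks, function(b) b[, f], numeric(n))
    sds <- sqrt(col_vars(tracks))
    ok <- sds > 0
    if (sum(ok) < 2L) next
    r2 <- matrix(0, m, m)
    r2[ok, ok] <- suppressWarnings(stats::cor(tracks[, ok, drop = FALSE]))^2
    r2[is.na(r2)] <- 0
    best <- pmax(best, r2)
  }
  diag(best) <- 1
  best
}

#' Genotype-correlation kinship matrix
#'
#' Pearson correlation between specimens' flattened, column-centered
#' founder-probability vectors: a fast relatedness screen for deciding
#' whether a kinship adjustment is warranted. Also reports the mean and
#' standard deviation of the off-diagonal entries.
#'
#' @param probs a `founder_probs` array with at least 2 specimens.
#' @return A list of class `kinship` with elements `K` (n x n symmetric
#'   correlation matrix, unit diagonal), `offdiag_mean`, `offdiag_sd`.
#' @export
kinship_matrix <- function(probs) {
  d <- dim(probs)
  if (d[1L] < 2L) stop_mgp("kinship needs at least 2 specimens")
  flat <- matrix(probs, nrow = d[1L])           # n x (m*8)
  flat <- sweep(flat, 2L, colMeans(flat), "-")  # column-center
  K <- suppressWarnings(stats::cor(t(flat)))
  K[is.na(K)] <- 0
  diag(K) <- 1
  dimnames(K) <- list(dimnames(probs)[[1L]], dimnames(probs)[[1L]])
  off <- K[lower.tri(K)]
  structure(list(K = K, offdiag_mean = mean(off),
                 offdiag_sd = stats::sd(off)),
            class = "kinship")
}

#' @export
print.kinship <- function(x, ...) {
  cat(sprintf("<kinship> %d specimens; off-diagonal mean %.4f, sd %.4f\n",
              nrow(x$K), x$offdiag_mean, x$offdiag_sd))
  invisible(x)
}
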