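test_that("flanking-marker selection follows the center rule and boundaries", {
  map <- data.frame(marker = c("m1", "m2"), chrom = "1", pos = c(40, 70),
                    stringsAsFactors = FALSE)
  g <- data.frame(gene = "g", chrom = "1", start = 45, end = 55)
  expect_equal(unname(select_flanking_markers(g, map)), c("m1", "m2"))
  # marker exactly at the center serves as both flanks
  map2 <- data.frame(marker = c("m1", "m2", "m3"), chrom = "1",
                     pos = c(20, 50, 70), stringsAsFactors = FALSE)
  fl <- select_flanking_markers(g, map2)
  expect_equal(unname(fl), c("m2", "m2"))
  # beyond the terminal markers: clamp to the nearest single marker
  g_lo <- data.frame(gene = "g", chrom = "1", start = 1, end = 10)
  expect_equal(unname(select_flanking_markers(g_lo, map)), c("m1", "m1"))
  g_hi <- data.frame(gene = "g", chrom = "1", start = 100, end = 120)
  expect_equal(unname(select_flanking_markers(g_hi, map)), c("m2", "m2"))
  expect_error(select_flanking_markers(
    data.frame(gene = "g", chrom = "X", start = 1, end = 2), map),
    "no markers")
})

test_that("flanking selection matches a brute-force nearest-position scan", {
  set.seed(11)
  n_mark <- 1000L
  map <- data.frame(marker = sprintf("m%04d", 1:n_mark),
                    chrom = as.character(rep(1:5, each = 200L)),
                    pos = rep(sort(sample.int(1e6, 200L)), 5L),
                    stringsAsFactors = FALSE)
  # per-chromosome strictly increasing positions
  for (ch in unique(map$chrom)) {
    idx <- map$chrom == ch
    map$pos[idx] <- sort(sample.int(1e6, sum(idx)))
  }
  for (i in 1:200) {
    ch <- sample(unique(map$chrom), 1L)
    st <- sample.int(9e5, 1L)
    g <- data.frame(gene = "g", chrom = ch, start = st, end = st + 1000L)
    got <- select_flanking_markers(g, map)
    ctr <- floor((g$start + g$end) / 2)
    sub <- map[map$chrom == ch, ]
    at <- sub$marker[sub$pos == ctr]
    if (length(at)) {
      expect_equal(unname(got), c(at, at))
    } else {
      up <- sub$marker[sub$pos <= ctr]
      dn <- sub$marker[sub$pos > ctr]
      exp_up <- if (length(up)) up[length(up)] else sub$marker[1L]
      exp_dn <- if (length(dn)) dn[1L] else sub$marker[nrow(sub)]
      if (!length(up)) exp_dn <- sub$marker[1L]
      if (!length(dn)) exp_up <- sub$marker[nrow(sub)]
      expect_equal(unname(got), c(exp_up, exp_dn))
    }
  }
})

test_that("gene probability block is the flanking-marker mean on the simplex", {
  set.seed(3)
  probs <- random_probs(20L, c("mA", "mB"))
  blk <- gene_probability_block(probs, "mA", "mA")
  expect_equal(unname(blk), unname(probs[, "mA", ]))
  # two pure indicator markers -> half/half
  arr <- array(0, dim = c(2L, 2L, 8L))
  arr[, 1L, 1L] <- 1; arr[, 2L, 2L] <- 1
  p2 <- founder_probs(arr, marker_ids = c("x", "y"))
  blk2 <- gene_probability_block(p2, "x", "y")
  expect_equal(unname(blk2[1L, ]), c(0.5, 0.5, rep(0, 6L)))
  # random oracle: independent recomputation
  blk3 <- gene_probability_block(probs, "mA", "mB")
  expect_equal(blk3, (probs[, "mA", ] + probs[, "mB", ]) / 2)
  expect_equal(unname(rowSums(blk3)), rep(1, 20L))
  expect_error(gene_probability_block(probs, "mA", "nope"), "unknown marker")
})

test_that("genotype block has 8 columns per gene and unit per-gene row sums", {
  set.seed(5)
  cfg <- tiny_config(seed = 2)
  gm <- simulate_founder_mosaic(cfg)
  ann <- simulate_annotation(cfg, gm$map)
  gs <- resolve_gene_set(ann$causal_term, ann$ontology, ann$catalog)
  X <- assemble_genotype_block(gs, gm$probs, gm$map)
  m <- nrow(gs$genes)
  expect_equal(ncol(X), 8L * m)
  expect_equal(unname(rowSums(X)), rep(m, nrow(X)))   # each 8-block sums to 1
  # per-gene blocks equal the direct computation
  g1 <- gs$genes[1L, ]
  fl <- select_flanking_markers(g1, gm$map)
  expect_equal(unname(X[, paste0(g1$gene, ".", LETTERS[1:8])]),
               unname(gene_probability_block(gm$probs, fl[["upstream"]],
                                             fl[["downstream"]])))
  # genes on chromosomes without markers are dropped with a warning
  genes2 <- rbind(gs$genes,
                  data.frame(gene = "offmap", chrom = "99", start = 1L,
                             end = 2L, tx_length = 2L, strand = "+"))
  expect_warning(X2 <- assemble_genotype_block(genes2, gm$probs, gm$map),
                 "dropped")
  expect_equal(ncol(X2), 8L * m)
  expect_error(suppressWarnings(assemble_genotype_block(
    genes2[genes2$gene == "offmap", ], gm$probs, gm$map)), "all genes dropped")
})

test_that("20 genes give 160 genotype coefficients", {
  cfg <- sim_config(n_specimens = 40L, n_chromosomes = 5L,
                    markers_per_chromosome = 20L, n_genes = 40L,
                    term_size = 20L, K = 14L, seed = 9L)
  gm <- simulate_founder_mosaic(cfg)
  ann <- simulate_annotation(cfg, gm$map)
  gs <- resolve_gene_set(ann$causal_term, ann$ontology, ann$catalog)
  X <- assemble_genotype_block(gs, gm$probs, gm$map)
  expect_equal(ncol(X), 160L)
})

test_that("LD is 1 for identical blocks, low across chromosomes, high under tight linkage", {
  set.seed(21)
  blk <- random_simplex(500L)
  expect_equal(ld_r2(blk, blk), 1)
  # independent markers
  expect_lt(ld_r2(blk, random_simplex(500L)), 0.05)
  # tight linkage: adjacent markers of a slow-switching mosaic
  cfg <- sim_config(n_specimens = 500L, n_chromosomes = 1L,
                    markers_per_chromosome = 4L, switch_prob = 0.02,
                    prob_softening = 0, K = 14L, seed = 4L)
  gm <- simulate_founder_mosaic(cfg)
  expect_gt(ld_r2(gm$probs[, 1L, ], gm$probs[, 2L, ]), 0.8)
  # cross-chromosome markers of the same mosaic are unlinked
  cfg2 <- sim_config(n_specimens = 500L, n_chromosomes = 2L,
                     markers_per_chromosome = 2L, switch_prob = 0.02,
                     prob_softening = 0, K = 14L, seed = 4L)
  gm2 <- simulate_founder_mosaic(cfg2)
  expect_lt(ld_r2(gm2$probs[, 1L, ], gm2$probs[, 3L, ]), 0.05)
  # zero variance signaled distinctly
  const <- matrix(rep(1 / 8, 8L * 10L), 10L)
  expect_warning(out <- ld_r2(const, const), "zero variance")
  expect_true(is.na(out))
})

test_that("kinship matrix matches pairwise correlation and screens relatedness", {
  set.seed(31)
  probs <- random_probs(4L, sprintf("m%d", 1:6))
  # duplicate a specimen
  arr <- unclass(probs)
  arr[2L, , ] <- arr[1L, , ]
  probs2 <- founder_probs(arr, marker_ids = sprintf("m%d", 1:6))
  k2 <- kinship_matrix(probs2)
  expect_equal(k2$K[1L, 2L], 1, tolerance = 1e-10)
  # brute-force oracle on 4 specimens
  k <- kinship_matrix(probs)
  flat <- matrix(unclass(probs), nrow = 4L)
  flat <- sweep(flat, 2L, colMeans(flat))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(k$K[i, j], cor(flat[i, ], flat[j, ]), tolerance = 1e-12)
  }
  expect_equal(k$K, t(k$K))
  # unrelated mosaic sample: off-diagonal mean near zero, PSD up to ridge
  cfg <- sim_config(n_specimens = 200L, K = 14L, seed = 8L)
  gm <- simulate_founder_mosaic(cfg)
  kk <- kinship_matrix(gm$probs)
  expect_lt(abs(kk$offdiag_mean), 0.02)
  ev <- eigen(kk$K + diag(1e-10, nrow(kk$K)), symmetric = TRUE,
              only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("founder probability tables round-trip through the long format", {
  set.seed(13)
  probs <- random_probs(6L, c("mk1", "mk2", "mk3"))
  path <- tempfile(fileext = ".tsv")
  write_founder_probs(probs, path)
  back <- read_founder_probs(path)
  expect_equal(unclass(back), unclass(probs), tolerance = 1e-9)
  expect_identical(dimnames(back), dimnames(probs))
})
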