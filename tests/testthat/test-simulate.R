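test_that("founder mosaics respect the switch model and the simplex", {
  # no switching: constant probabilities along each chromosome
  cfg0 <- sim_config(n_specimens = 10L, n_chromosomes = 2L,
                     markers_per_chromosome = 6L, switch_prob = 0,
                     prob_softening = 0, K = 14L, seed = 3L)
  gm0 <- simulate_founder_mosaic(cfg0)
  for (ch in c(1:6, 7:12)) {
    expect_equal(unname(gm0$probs[, ch, ]),
                 unname(gm0$probs[, ifelse(ch <= 6L, 1L, 7L), ]))
  }
  # unsoftened diplotypes live on {0, 0.5, 1} and rows sum to one
  expect_true(all(gm0$probs %in% c(0, 0.5, 1)))
  sums <- rowSums(unclass(gm0$probs), dims = 2L)
  expect_equal(unname(sums), matrix(1, 10L, 12L))
  # empirical switch frequency matches the nominal rate within 3 SE
  cfg1 <- sim_config(n_specimens = 50L, n_chromosomes = 1L,
                     markers_per_chromosome = 200L, switch_prob = 0.02,
                     prob_softening = 0, K = 14L, seed = 10L)
  gm1 <- simulate_founder_mosaic(cfg1)
  # diplotype changes underestimate chain switches; count via both
  # haplotype indicator halves: a change in the 8-vector marks >=1 switch
  changed <- 0L; total <- 0L
  P <- unclass(gm1$probs)
  for (j in 2:200) {
    changed <- changed + sum(rowSums(abs(P[, j, ] - P[, j - 1L, ])) > 0)
    total <- total + 50L
  }
  # two chains, each switching at 0.02: P(any) = 1 - 0.98^2
  p_any <- 1 - 0.98^2
  se <- sqrt(p_any * (1 - p_any) / total)
  expect_lt(abs(changed / total - p_any), 3 * se)
  expect_error(sim_config(switch_prob = 1.5), "switch_prob")
})

test_that("annotation fixtures contain the causal term and round-trip", {
  cfg <- tiny_config(seed = 12L)
  gm <- simulate_founder_mosaic(cfg)
  ann <- simulate_annotation(cfg, gm$map)
  ont <- ann$ontology
  causal_members <- ont$gene[ont$go_id == ann$causal_term]
  expect_true(all(cfg$causal_genes %in% causal_members))
  expect_equal(length(causal_members), cfg$term_size)
  expect_equal(length(setdiff(causal_members, cfg$causal_genes)),
               cfg$term_size - length(cfg$causal_genes))
  # all genes on chromosomes present in the map
  expect_true(all(ann$catalog$chrom %in% unique(gm$map$chrom)))
  # serialization identity through the catalog reader
  path <- tempfile(fileext = ".tsv")
  writeLines(ann$catalog_lines, path)
  expect_identical(load_gene_catalog(path), ann$catalog)
  # genes do not overlap within a chromosome
  for (ch in unique(ann$catalog$chrom)) {
    sub <- ann$catalog[ann$catalog$chrom == ch, ]
    if (nrow(sub) > 1L) {
      sub <- sub[order(sub$start), ]
      expect_true(all(sub$start[-1L] > sub$end[-nrow(sub)]))
    }
  }
})

test_that("a null generator yields no genetic effect and a noiseless one is exactly recoverable", {
  cfg0 <- tiny_config(seed = 21L, effect_size = 0)
  ds0 <- simulate_dataset(cfg0)
  expect_equal(ds0$truth$a, 0)
  expect_equal(ds0$truth$genetic_var, 0)
  tmpl_flat <- as.vector(t(ds0$truth$template))
  resid <- sweep(flatten_landmarks(ds0$landmarks), 2L, tmpl_flat)
  # only sex effect and noise remain
  expect_lt(max(abs(colMeans(resid))), 4 * cfg0$noise_sd)

  # noiseless single-gene architecture: the shape regression of the
  # unpenalized fit recovers the planted direction exactly (the
  # standardized loadings v keep only its sign pattern, since without
  # noise every coordinate's scale is proportional to the effect)
  cfg1 <- tiny_config(seed = 22L, effect_size = 0.5, noise_sd = 0,
                      sex_effect = 0, causal_genes = "sim01",
                      n_specimens = 120L)
  ds1 <- simulate_dataset(cfg1)
  gs <- resolve_gene_set(ds1$causal_term, ds1$ontology, ds1$catalog)
  X <- assemble_genotype_block(gs, ds1$probs, ds1$map)
  Y <- flatten_landmarks(ds1$landmarks)
  fit <- fit_spls(X, Y, lambda = 0)
  expect_gt(abs(cor(fit$b, ds1$truth$w)), 0.999)
  # with noise-dominated coordinates (the shape-data regime) the
  # phenotypic loadings themselves recover the direction
  cfg2 <- tiny_config(seed = 23L, effect_size = 0.1, sex_effect = 0,
                      causal_genes = "sim01", n_specimens = 600L)
  ds2 <- simulate_dataset(cfg2)
  gs2 <- resolve_gene_set(ds2$causal_term, ds2$ontology, ds2$catalog)
  X2 <- assemble_genotype_block(gs2, ds2$probs, ds2$map)
  Y2 <- flatten_landmarks(ds2$landmarks)
  fit2 <- fit_spls(X2, Y2, lambda = 0)
  expect_gt(abs(cor(fit2$v, ds2$truth$w)), 0.95)
})

test_that("the analytic variance share matches a Monte-Carlo decomposition", {
  cfg <- sim_config(n_specimens = 2000L, n_chromosomes = 6L,
                    markers_per_chromosome = 20L, n_genes = 40L,
                    term_size = 10L, K = 14L, effect_size = 0.05,
                    seed = 31L)
  ds <- simulate_dataset(cfg)
  tr <- ds$truth
  expect_equal(tr$realized_share, 0.05, tolerance = 1e-12)
  # Monte-Carlo: decompose realized coordinate variance
  flat <- flatten_landmarks(ds$landmarks)
  total_var <- sum(apply(flat, 2L, var))
  genetic <- var(tr$scores)
  expect_equal(genetic, tr$genetic_var, tolerance = 1e-12)
  # realized total variance agrees with the generator's bookkeeping;
  # at n = 2000 the trace fluctuation is well under 5% relative
  expected_total <- tr$genetic_var + tr$noise_var + tr$sex_var
  expect_lt(abs(total_var - expected_total) / expected_total, 0.05)
})

test_that("the target R^2 is realized in the fitted model at moderate n", {
  # architecture with a 5% raw-coordinate genetic share: the fitted
  # trace-ratio R^2 on GPA-aligned coordinates should sit near the
  # target, averaged over generator seeds
  r2s <- vapply(1:6, function(s) {
    cfg <- sim_config(n_specimens = 400L, K = 24L, seed = 100L + s)
    ds <- simulate_dataset(cfg)
    sp <- gpa(ds$landmarks)
    gs <- resolve_gene_set(ds$causal_term, ds$ontology, ds$catalog)
    X <- assemble_genotype_block(gs, ds$probs, ds$map)
    fit_spls(X, sp$aligned, 0.06)$r2
  }, numeric(1L))
  expect_lt(abs(mean(r2s) - 0.05), 0.02)
})

test_that("fixture bundles are byte-identical under a fixed seed and carry truth", {
  cfg <- tiny_config(seed = 33L)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  p1 <- make_fixture(cfg, d1)
  p2 <- make_fixture(cfg, d2)
  for (nm in names(p1)) {
    expect_identical(readBin(p1[[nm]], "raw", file.size(p1[[nm]])),
                     readBin(p2[[nm]], "raw", file.size(p2[[nm]])),
                     label = nm)
  }
  truth <- jsonlite::read_json(p1[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$seed, 33L)
  expect_equal(truth$causal_genes, cfg$causal_genes)
  expect_equal(length(truth$w), 3L * cfg$K)
  # bundle is readable by the package's own readers
  lm <- read_landmarks(p1[["landmarks"]])
  expect_equal(dim(lm)[1L], cfg$n_specimens)
  mp <- read_marker_map(p1[["map"]])
  pr <- read_founder_probs(p1[["probs"]], mp)
  expect_equal(dim(pr)[2L], nrow(mp))
  unlink(c(d1, d2), recursive = TRUE)
})
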