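# Synthetic multiparental data generator. Emulates the statistical
# structure the mapping method assumes: 8-founder diplotype mosaics
# with linkage along chromosomes, a gene catalog + ontology with one
# causal process term, a bilaterally symmetric landmark template, and
# sparse additive genetic effects on shape with isotropic noise. All
# generators are deterministic given the config seed.

#' Simulation configuration
#'
#' Collects the generator's parameters with defaults chosen to mimic a
#' moderately sized multiparental mapping study: 800 specimens, 20
#' chromosomes x 50 evenly spaced markers, a founder switch probability
#' of 0.15 per marker interval and haplotype (so linkage disequilibrium
#' decays over a few megabases), mild probability softening
#' (reconstruction uncertainty), a 200-gene catalog with a 20-gene
#' causal-process term
#' of which 2 genes are causal, a 5% target genetic variance share, and
#' a 54-landmark bilaterally symmetric configuration.
#'
#' @param n_specimens sample size.
#' @param n_chromosomes number of chromosomes.
#' @param markers_per_chromosome markers per chromosome (evenly spaced).
#' @param marker_spacing_bp base pairs between adjacent markers.
#' @param switch_prob per-interval founder switch probability of each
#'   haplotype chain, in `[0, 1]`.
#' @param prob_softening mixing weight toward the uniform simplex, in
#'   `[0, 1)`; emulates haplotype-reconstruction uncertainty.
#' @param n_genes genes in the catalog.
#' @param term_size genes in the causal-process term (causal + decoys).
#' @param decoy_term_size genes per decoy term.
#' @param n_decoy_terms number of decoy terms.
#' @param causal_genes symbols of the causal genes (must be simulated
#'   symbols `sim01`, `sim02`, ...).
#' @param effect_direction_seed seed for the shared effect direction and
#'   per-gene founder coefficients.
#' @param effect_size target genetic variance share of the raw
#'   coordinates, in `[0, 1)`.
#' @param noise_sd isotropic landmark noise SD (same units as the
#'   template, whose centroid size is near 1).
#' @param sex_effect magnitude of a fixed symmetric sex-dimorphism
#'   direction added to male specimens (0 disables).
#' @param K number of landmarks.
#' @param pairing optional `symmetry_pairing`; defaults to
#'   [make_symmetric_pairing()]`(K)`.
#' @param seed master seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_specimens = 800L,
                       n_chromosomes = 20L,
                       markers_per_chromosome = 50L,
                       marker_spacing_bp = 1e6,
                       switch_prob = 0.15,
                       prob_softening = 0.05,
                       n_genes = 200L,
                       term_size = 20L,
                       decoy_term_size = 8L,
                       n_decoy_terms = 5L,
                       causal_genes = c("sim01", "sim02"),
                       effect_direction_seed = 42L,
                       effect_size = 0.05,
                       noise_sd = 0.005,
                       sex_effect = 0.0025,
                       K = 54L,
                       pairing = NULL,
                       seed = 1L) {
  if (switch_prob < 0 || switch_prob > 1) stop_mgp("switch_prob must be in [0, 1]")
  if (prob_softening < 0 || prob_softening >= 1) stop_mgp("prob_softening must be in [0, 1)")
  if (effect_size < 0 || effect_size >= 1) stop_mgp("effect_size must be in [0, 1)")
  if (is.null(pairing)) pairing <- make_symmetric_pairing(K)
  all_syms <- sprintf("sim%02d", seq_len(n_genes))
  if (!all(causal_genes %in% all_syms) && length(causal_genes)) {
    stop_mgp("causal_genes must be among the simulated symbols ",
             all_syms[1L], "..", all_syms[n_genes])
  }
  if (term_size < length(causal_genes) || term_size > n_genes) {
    stop_mgp("term_size must be between the causal count and n_genes")
  }
  structure(list(n_specimens = as.integer(n_specimens),
                 n_chromosomes = as.integer(n_chromosomes),
                 markers_per_chromosome = as.integer(markers_per_chromosome),
                 marker_spacing_bp = marker_spacing_bp,
                 switch_prob = switch_prob,
                 prob_softening = prob_softening,
                 n_genes = as.integer(n_genes),
                 term_size = as.integer(term_size),
                 decoy_term_size = as.integer(decoy_term_size),
                 n_decoy_terms = as.integer(n_decoy_terms),
                 causal_genes = causal_genes,
                 effect_direction_seed = as.integer(effect_direction_seed),
                 effect_size = effect_size,
                 noise_sd = noise_sd,
                 sex_effect = sex_effect,
                 K = as.integer(K),
                 pairing = pairing,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default bilateral pairing for K landmarks
#'
#' Splits K into left/right pairs plus a midline set (roughly one
#' midline landmark per five, parity-adjusted). For the reference
#' K = 54 this gives 22 pairs and 10 midline landmarks. Landmarks
#' `1..P` are left, `P+1..2P` right, the rest midline.
#'
#' @param K total landmark count (>= 4).
#' @return A `symmetry_pairing`.
#' @export
make_symmetric_pairing <- function(K) {
  if (K < 4L) stop_mgp("need at least 4 landmarks")
  n_mid <- max(2L, round(K / 5))
  if ((K - n_mid) %% 2L != 0L) n_mid <- n_mid + 1L
  P <- (K - n_mid) %/% 2L
  symmetry_pairing(cbind(seq_len(P), P + seq_len(P)),
                   midline = 2L * P + seq_len(n_mid), K = K)
}

#' Deterministic symmetric landmark template
#'
#' A smooth, vaguely cranium-like closed form: paired landmarks sit at
#' mirrored x offsets along a parameterized arc, midline landmarks on
#' the x = 0 plane. Fully deterministic in `K` and the pairing; scaled
#' to unit centroid size.
#'
#' @param K landmark count.
#' @param pairing a `symmetry_pairing` (defaults to
#'   [make_symmetric_pairing()]).
#' @return K x 3 matrix.
#' @export
make_template <- function(K, pairing = make_symmetric_pairing(K)) {
  X <- matrix(NA_real_, K, 3L)
  P <- nrow(pairing$pairs)
  th <- pi * (seq_len(P) - 0.5) / P
  left <- cbind(-0.6 * sin(th) - 0.05, cos(th), 0.35 * sin(2 * th))
  right <- left; right[, 1L] <- -left[, 1L]
  X[pairing$pairs[, 1L], ] <- left
  X[pairing$pairs[, 2L], ] <- right
  nm <- length(pairing$midline)
  ph <- pi * (seq_len(nm) - 0.5) / nm
  X[pairing$midline, ] <- cbind(0, 0.9 * cos(ph), 0.55 * sin(ph) + 0.15)
  X <- sweep(X, 2L, colMeans(X), "-")
  # pre-rotate the y-z block into its principal axes with the same
  # conventions the symmetrized shape space uses, so template-based
  # samples come out of the alignment in the template's own frame
  R2 <- svd(X[, 2:3])$v
  if (det(R2) < 0) R2[, 2L] <- -R2[, 2L]
  A2 <- X[, 2:3] %*% R2
  if (A2[which.max(abs(A2[, 1L])), 1L] < 0) R2 <- -R2
  X[, 2:3] <- X[, 2:3] %*% R2
  X / sqrt(sum(X^2))
}

# Simulate founder states of one haplotype chain along one chromosome
# for n specimens: uniform initial founder; per interval, switch to a
# uniformly chosen *other* founder with probability switch_prob.
sim_chain <- function(n, n_mark, switch_prob) {
  st <- matrix(0L, n, n_mark)
  st[, 1L] <- sample.int(8L, n, replace = TRUE)
  if (n_mark > 1L) {
    for (j in 2:n_mark) {
      cur <- st[, j - 1L]
      sw <- stats::runif(n) < switch_prob
      jump <- sample.int(7L, n, replace = TRUE)
      jump <- jump + (jump >= cur)
      st[, j] <- ifelse(sw, jump, cur)
    }
  }
  st
}

#' Simulate a founder-mosaic genotype sample
#'
#' Per specimen and chromosome, two independent founder-state Markov
#' chains are run along the marker grid; the diplotype probability
#' 8-vector at a marker is the average of the two haplotype indicator
#' vectors (entries in {0, 0.5, 1}), optionally mixed with the uniform
#' simplex by `prob_softening`. Marker positions are evenly spaced.
#'
#' @param config a `sim_config`.
#' @return A list with `probs` (a `founder_probs` array) and `map`
#'   (marker map `data.frame`).
#' @export
simulate_founder_mosaic <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_specimens
  mpc <- config$markers_per_chromosome
  n_mark <- config$n_chromosomes * mpc
  map <- data.frame(
    marker = sprintf("m%04d", seq_len(n_mark)),
    chrom = as.character(rep(seq_len(config$n_chromosomes), each = mpc)),
    pos = rep(config$marker_spacing_bp * seq_len(mpc),
              times = config$n_chromosomes),
    stringsAsFactors = FALSE)
  arr <- array(NA_real_, dim = c(n, n_mark, 8L))
  with_seed(child_seed(config$seed, 101L), {
    for (ch in seq_len(config$n_chromosomes)) {
      h1 <- sim_chain(n, mpc, config$switch_prob)
      h2 <- sim_chain(n, mpc, config$switch_prob)
      cols <- (ch - 1L) * mpc + seq_len(mpc)
      for (f in 1:8) {
        arr[, cols, f] <- ((h1 == f) + (h2 == f)) / 2
      }
    }
  })
  s <- config$prob_softening
  if (s > 0) arr <- (1 - s) * arr + s / 8
  probs <- founder_probs(arr,
                         specimen_ids = sprintf("s%04d", seq_len(n)),
                         marker_ids = map$marker)
  list(probs = probs, map = map)
}

#' Simulate the gene catalog and ontology fixtures
#'
#' Places `n_genes` genes at random non-overlapping intervals within
#' the marker span; every fourth gene carries a second, shorter
#' transcript so the longest-transcript rule is exercised on re-read.
#' The ontology contains one `causal process (synthetic)` term holding
#' the causal genes plus decoys up to `term_size`, and `n_decoy_terms`
#' decoy terms over the remaining genes.
#'
#' @param config a `sim_config`.
#' @param map marker map from [simulate_founder_mosaic()].
#' @return A list with `catalog_lines` and `ontology_lines` (TSV text,
#'   header included), plus parsed `catalog` and `ontology` frames and
#'   `causal_term` (its GO id).
#' @export
simulate_annotation <- function(config, map) {
  stopifnot(inherits(config, "sim_config"))
  syms <- sprintf("sim%02d", seq_len(config$n_genes))
  chroms <- unique(map$chrom)
  placed <- with_seed(child_seed(config$seed, 202L), {
    res <- vector("list", config$n_genes)
    occupied <- stats::setNames(vector("list", length(chroms)), chroms)
    for (i in seq_len(config$n_genes)) {
      ok <- FALSE
      for (try in 1:1000) {
        ch <- chroms[[sample.int(length(chroms), 1L)]]
        span <- range(map$pos[map$chrom == ch])
        len <- round(stats::runif(1L, 5e3, 2e5))
        start <- round(stats::runif(1L, span[1L], span[2L] - len))
        end <- start + len
        ivs <- occupied[[ch]]
        clash <- any(vapply(ivs, function(iv) start <= iv[2L] && end >= iv[1L],
                            logical(1L)))
        if (!clash) {
          occupied[[ch]] <- c(ivs, list(c(start, end)))
          res[[i]] <- list(gene = syms[i], chrom = ch, start = start, end = end)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop_mgp("could not place gene ", syms[i],
                        " without overlap after 1000 tries")
    }
    res
  })
  cat_lines <- c("gene\ttranscript\tchrom\tstart\tend\tstrand")
  for (i in seq_along(placed)) {
    g <- placed[[i]]
    strand <- if (i %% 2L == 0L) "-" else "+"
    cat_lines <- c(cat_lines, sprintf("%s\t%s-201\t%s\t%d\t%d\t%s",
                                      g$gene, g$gene, g$chrom,
                                      g$start, g$end, strand))
    if (i %% 4L == 0L) {
      # shorter second transcript nested in the first
      off <- max(1L, round((g$end - g$start) / 4))
      cat_lines <- c(cat_lines, sprintf("%s\t%s-202\t%s\t%d\t%d\t%s",
                                        g$gene, g$gene, g$chrom,
                                        g$start + off, g$end - off, strand))
    }
  }
  causal <- config$causal_genes
  n_decoy_in_term <- config$term_size - length(causal)
  noncausal <- setdiff(syms, causal)
  term_decoys <- with_seed(child_seed(config$seed, 203L),
                           sample(noncausal, n_decoy_in_term))
  ont <- data.frame(go_id = character(0), term = character(0),
                    gene = character(0), stringsAsFactors = FALSE)
  causal_id <- "GO:9000001"
  ont <- rbind(ont, data.frame(go_id = causal_id,
                               term = "causal process (synthetic)",
                               gene = c(causal, term_decoys),
                               stringsAsFactors = FALSE))
  decoy_rows <- with_seed(child_seed(config$seed, 204L), {
    rows <- vector("list", config$n_decoy_terms)
    for (t in seq_len(config$n_decoy_terms)) {
      take <- sample(syms, min(config$decoy_term_size, length(syms)))
      rows[[t]] <- data.frame(go_id = sprintf("GO:9000%03d", t + 1L),
                              term = sprintf("decoy process %02d", t),
                              gene = take, stringsAsFactors = FALSE)
    }
    rows
  })
  ont <- do.call(rbind, c(list(ont), decoy_rows))
  ont_lines <- c("go_id\tterm\tgene",
                 sprintf("%s\t%s\t%s", ont$go_id, ont$term, ont$gene))
  tmp <- tempfile(fileext = ".tsv")
  writeLines(cat_lines, tmp)
  catalog <- load_gene_catalog(tmp)
  unlink(tmp)
  list(catalog_lines = cat_lines, ontology_lines = ont_lines,
       catalog = catalog, ontology = ont, causal_term = causal_id)
}

# Symmetrize a flat 3K vector under the pairing (average with its
# reflected-relabeled copy) and remove components along the similarity
# transforms (translations, rotations, scaling) of the template, so the
# direction lives in shape space.
shape_direction <- function(raw, template, pairing) {
  K <- nrow(template)
  Xr <- unflatten_shape(raw)
  sym <- (Xr + reflect_relabel(Xr, pairing)) / 2
  v <- as.vector(t(sym))
  # similarity basis at the template
  tx <- as.vector(t(cbind(1, 0, 0)[rep(1L, K), ]))
  ty <- as.vector(t(cbind(0, 1, 0)[rep(1L, K), ]))
  tz <- as.vector(t(cbind(0, 0, 1)[rep(1L, K), ]))
  sc <- as.vector(t(template))
  rx <- as.vector(t(cbind(0, -template[, 3L], template[, 2L])))
  ry <- as.vector(t(cbind(template[, 3L], 0, -template[, 1L])))
  rz <- as.vector(t(cbind(-template[, 2L], template[, 1L], 0)))
  B <- qr.Q(qr(cbind(tx, ty, tz, sc, rx, ry, rz)))
  v <- v - B %*% crossprod(B, v)
  v <- as.vector(v)
  v / sqrt(sum(v^2))
}

#' Simulate landmark shapes under a sparse additive genetic model
#'
#' Shape of specimen i = symmetric template
#' `+ a * sum_g (P_g[i, ] . c_g) * w + sex + noise`, where `P_g` is the
#' gene's averaged founder-probability block, `c_g` a seeded zero-sum
#' founder coefficient vector (effects are contrasts among founders),
#' and `w` a unit direction respecting the symmetry pairing and
#' orthogonal to the template's similarity transforms. The scalar `a`
#' is calibrated so the genetic share of the total coordinate variance
#' (genetic + sex + noise, computed from the generator's own
#' components) equals `effect_size`.
#'
#' @param config a `sim_config`.
#' @param probs `founder_probs` from [simulate_founder_mosaic()].
#' @param catalog gene catalog from [simulate_annotation()].
#' @param map marker map.
#' @return A list with `landmarks` (a `landmark_array`), `covariates`
#'   (`specimen`, `generation`, `sex`), and `truth`: `w`, `a`,
#'   `causal_genes`, `genetic_var`, `noise_var`, `sex_var`,
#'   `realized_share`, `template`, `scores`.
#' @export
simulate_shapes <- function(config, probs, catalog, map) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_specimens
  K <- config$K
  template <- make_template(K, config$pairing)
  tflat <- as.vector(t(template))
  dirs <- with_seed(config$effect_direction_seed, {
    w <- shape_direction(stats::rnorm(3L * K), template, config$pairing)
    coefs <- lapply(seq_along(config$causal_genes), function(i) {
      cc <- stats::rnorm(8L)
      cc - mean(cc)
    })
    sexdir <- shape_direction(stats::rnorm(3L * K), template, config$pairing)
    list(w = w, coefs = coefs, sexdir = sexdir)
  })
  score <- rep(0, n)
  if (length(config$causal_genes) && config$effect_size > 0) {
    for (i in seq_along(config$causal_genes)) {
      g <- catalog[catalog$gene == config$causal_genes[i], , drop = FALSE]
      if (!nrow(g)) stop_mgp("causal gene ", config$causal_genes[i],
                             " not in catalog")
      fl <- select_flanking_markers(g, map)
      P <- gene_probability_block(probs, fl[["upstream"]], fl[["downstream"]])
      score <- score + as.vector(P %*% dirs$coefs[[i]])
    }
  }
  gvar_unit <- stats::var(score)           # variance of the raw genetic score
  noise_var_total <- 3 * K * config$noise_sd^2
  cov_sex <- with_seed(child_seed(config$seed, 301L), {
    data.frame(specimen = sprintf("s%04d", seq_len(n)),
               generation = sample(c("G9", "G15", "G21", "G27"), n,
                                   replace = TRUE),
               sex = sample(c("F", "M"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  sex_ind <- as.numeric(cov_sex$sex == "M")
  sex_var_total <- stats::var(sex_ind) * config$sex_effect^2
  a <- 0
  if (config$effect_size > 0 && gvar_unit > 0) {
    if (noise_var_total + sex_var_total > 0) {
      # solve a^2 gvar / (a^2 gvar + sex + noise) = effect_size
      a <- sqrt(config$effect_size * (noise_var_total + sex_var_total) /
                  ((1 - config$effect_size) * gvar_unit))
    } else {
      # no noise: scale is arbitrary, genetic share is 1
      a <- 1
    }
  }
  E <- with_seed(child_seed(config$seed, 302L),
                 matrix(stats::rnorm(n * 3L * K, sd = config$noise_sd),
                        n, 3L * K))
  flat <- matrix(tflat, n, 3L * K, byrow = TRUE) +
    outer(a * score, dirs$w) +
    outer(config$sex_effect * sex_ind, dirs$sexdir) +
    E
  rownames(flat) <- cov_sex$specimen
  genetic_var <- a^2 * gvar_unit
  realized <- if (genetic_var + sex_var_total + noise_var_total > 0) {
    genetic_var / (genetic_var + sex_var_total + noise_var_total)
  } else 0
  list(landmarks = as_landmark_array(flat, specimen_ids = cov_sex$specimen),
       covariates = cov_sex,
       truth = list(w = dirs$w, a = a, causal_genes = config$causal_genes,
                    founder_coefs = dirs$coefs,
                    genetic_var = genetic_var,
                    noise_var = noise_var_total,
                    sex_var = sex_var_total,
                    realized_share = realized,
                    template = template,
                    scores = a * score))
}

#' Simulate a complete dataset
#'
#' Convenience wrapper chaining [simulate_founder_mosaic()],
#' [simulate_annotation()] and [simulate_shapes()].
#'
#' @param config a `sim_config`.
#' @return A list: `probs`, `map`, `catalog`, `ontology`,
#'   `causal_term`, `landmarks`, `covariates`, `truth`, `config`, plus
#'   the raw `catalog_lines` / `ontology_lines`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  gm <- simulate_founder_mosaic(config)
  ann <- simulate_annotation(config, gm$map)
  sh <- simulate_shapes(config, gm$probs, ann$catalog, gm$map)
  c(gm, ann, sh, list(config = config))
}

#' Write a fixture bundle to disk
#'
#' Writes landmark CSV, long-format founder probabilities, marker map,
#' gene catalog, ontology, pairing, covariates, and a `truth.json`
#' holding the generating direction, causal genes, variance shares and
#' seed. Byte-identical across runs with the same config.
#'
#' @param config a `sim_config`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
make_fixture <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- simulate_dataset(config)
  paths <- c(landmarks = file.path(out_dir, "landmarks.csv"),
             probs = file.path(out_dir, "founder_probs.tsv"),
             map = file.path(out_dir, "marker_map.tsv"),
             catalog = file.path(out_dir, "gene_catalog.tsv"),
             ontology = file.path(out_dir, "ontology.tsv"),
             pairing = file.path(out_dir, "pairing.csv"),
             covariates = file.path(out_dir, "covariates.csv"),
             truth = file.path(out_dir, "truth.json"))
  write_landmarks(ds$landmarks, paths[["landmarks"]])
  write_founder_probs(ds$probs, paths[["probs"]])
  utils::write.table(ds$map, paths[["map"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(ds$catalog_lines, paths[["catalog"]])
  writeLines(ds$ontology_lines, paths[["ontology"]])
  write_pairing(ds$config$pairing, paths[["pairing"]])
  utils::write.csv(ds$covariates, paths[["covariates"]], row.names = FALSE,
                   quote = FALSE)
  truth <- ds$truth
  truth$template <- NULL
  truth$scores <- NULL
  truth$seed <- config$seed
  truth$causal_term <- ds$causal_term
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
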