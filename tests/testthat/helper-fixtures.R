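# Shared fixture builders. Everything is generated in code; no stored
# data files.

# A small catalog TSV written to a temp file; returns the path.
write_catalog_tsv <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene\ttranscript\tchrom\tstart\tend\tstrand", rows), path)
  path
}

write_ontology_tsv <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("go_id\tterm\tgene", rows), path)
  path
}

# Random rows on the 8-simplex.
random_simplex <- function(n) {
  m <- matrix(stats::rexp(n * 8L), n, 8L)
  m / rowSums(m)
}

# A founder_probs array with random simplex entries.
random_probs <- function(n, marker_ids) {
  arr <- array(NA_real_, dim = c(n, length(marker_ids), 8L))
  for (j in seq_along(marker_ids)) arr[, j, ] <- random_simplex(n)
  founder_probs(arr, specimen_ids = sprintf("s%03d", seq_len(n)),
                marker_ids = marker_ids)
}

# Small, fast simulation settings for unit tests; defaults elsewhere.
tiny_config <- function(...) {
  args <- list(n_specimens = 80L, n_chromosomes = 4L,
               markers_per_chromosome = 12L, n_genes = 24L,
               term_size = 6L, decoy_term_size = 5L, n_decoy_terms = 3L,
               K = 14L)
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

# Random landmark sample: template + iid noise (K from pairing).
noisy_shapes <- function(n, K, sd = 0.01, pairing = make_symmetric_pairing(K)) {
  tmpl <- make_template(K, pairing)
  flat <- matrix(as.vector(t(tmpl)), n, 3L * K, byrow = TRUE) +
    matrix(stats::rnorm(n * 3L * K, sd = sd), n, 3L * K)
  as_landmark_array(flat)
}

# Mirror a K x 3 configuration under a pairing (used to build
# antisymmetric fields in geometry tests).
mirror_config <- function(X, pairing) {
  Y <- X
  Y[, 1L] <- -Y[, 1L]
  S <- Y
  S[pairing$pairs[, 1L], ] <- Y[pairing$pairs[, 2L], ]
  S[pairing$pairs[, 2L], ] <- Y[pairing$pairs[, 1L], ]
  S
}

# Apply a random rigid transform (+ scale) to a K x 3 configuration.
random_similarity <- function(X) {
  q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  s <- stats::runif(1L, 0.5, 2)
  shift <- stats::rnorm(3L, sd = 5)
  sweep(s * X %*% q, 2L, shift, "+")
}
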