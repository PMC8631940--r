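# End-to-end pipeline: resolve a process query to a gene set, assemble
# the genotype block, preprocess landmarks (GPA, object symmetry,
# covariate residualization), fit the regularized PLS, and write
# machine-readable artifacts plus an HTML report.

#' Run a process mapping analysis end to end
#'
#' Stages: (1) resolve the query (or explicit GO ids) to a gene set;
#' (2) GPA + object-symmetry decomposition of the landmarks, covariate
#' residualization when covariates are given; (3) per-gene genotype
#' block assembly; (4) regularized PLS fit, with `lambda` either fixed
#' or chosen by 10-fold cross-validation (`lambda = "cv"`); (5)
#' optional mutant comparison via joint registration. Inputs may be
#' file paths (the formats of the respective readers) or pre-built
#' objects.
#'
#' @param landmarks landmark CSV path or `landmark_array`.
#' @param probs founder-probability TSV path or `founder_probs`.
#' @param map marker-map TSV path or `data.frame`.
#' @param catalog catalog TSV path or catalog `data.frame`.
#' @param ontology ontology TSV path or `data.frame`.
#' @param pairing pairing CSV path or `symmetry_pairing`; `NULL` skips
#'   the symmetry decomposition.
#' @param covariates covariate CSV path or `data.frame`; `NULL` skips
#'   residualization.
#' @param query text query resolved with [filter_terms()] (all matching
#'   terms are used); ignored when `go_ids` is given.
#' @param go_ids explicit GO identifiers.
#' @param lambda numeric regularization, or `"cv"` for cross-validated
#'   choice over `cv_grid`.
#' @param cv_grid lambda grid for cross-validation.
#' @param seed seed for the CV fold shuffle.
#' @param compare optional mutant landmark CSV (a `genotype` column
#'   marks groups) or `landmark_array`; adds a mutant-direction
#'   comparison.
#' @param out_dir when non-`NULL`, artifacts are written there:
#'   `fit.json`, `loadings.csv`, `effect.csv`, `report.html`, and
#'   `cv.csv` when CV ran.
#' @return A list of class `mgp_run`: `gene_set`, `space`, `block`,
#'   `fit`, `cv` (or `NULL`), `lambda_source`, `effect`
#'   (`effect_vector`), `comparison` (or `NULL`), `files`.
#' @export
run_mgp <- function(landmarks, probs, map, catalog, ontology,
                    pairing = NULL, covariates = NULL,
                    query = NULL, go_ids = NULL,
                    lambda = 0.06, cv_grid = seq(0.01, 0.20, by = 0.01),
                    seed = 1L, compare = NULL, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_mgp("[", name, "] ", conditionMessage(e))
    })
  }
  landmarks <- stage("landmarks", if (is.character(landmarks))
    read_landmarks(landmarks) else as_landmark_array(landmarks))
  map <- stage("map", if (is.character(map)) read_marker_map(map) else map)
  probs <- stage("genotypes", if (is.character(probs))
    read_founder_probs(probs, map) else probs)
  catalog <- stage("catalog", if (is.character(catalog))
    load_gene_catalog(catalog) else catalog)
  ontology <- stage("ontology", if (is.character(ontology))
    load_ontology(ontology) else ontology)
  if (is.character(pairing)) pairing <- stage("pairing", read_pairing(pairing))
  if (is.character(covariates)) {
    covariates <- stage("covariates",
                        utils::read.csv(covariates, stringsAsFactors = FALSE))
  }

  gene_set <- stage("resolve", {
    if (is.null(go_ids)) {
      if (is.null(query)) stop_mgp("either query or go_ids is required")
      hits <- filter_terms(query, ontology)
      if (!nrow(hits)) stop_mgp("query '", query, "' matched no terms")
      go_ids <- hits$go_id
    }
    resolve_gene_set(go_ids, ontology, catalog,
                     query = if (is.null(query)) "" else query)
  })

  space <- stage("geometry", {
    sp <- if (is.null(pairing)) gpa(landmarks) else symmetrize(landmarks, pairing)
    if (!is.null(covariates)) sp <- residualize_shape(sp, covariates)
    sp
  })
  Y <- space_coords(space)

  block <- stage("genotype block", {
    b <- assemble_genotype_block(gene_set, probs, map)
    idx <- match(space$specimen_ids, rownames(b))
    if (anyNA(idx)) stop_mgp("specimens missing from genotype data: ",
                             paste(space$specimen_ids[is.na(idx)][1:5],
                                   collapse = ", "))
    b[idx, , drop = FALSE]
  })
  # row subsetting drops attributes; restore per-gene structure
  attr(block, "genes") <- unique(sub("\\.[A-H]$", "", colnames(block)))

  cv <- NULL
  lambda_source <- "fixed"
  if (identical(lambda, "cv")) {
    cv <- stage("cross-validation",
                cross_validate(block, Y, cv_grid, seed = seed))
    lambda <- cv$chosen_lambda
    lambda_source <- "cv"
  }
  fit <- stage("pls fit", fit_spls(block, Y, lambda))
  effect <- effect_vector(fit$v, label = if (!is.null(query) && nzchar(query))
    query else paste(gene_set$go_ids, collapse = "+"), kind = "process")

  comparison <- NULL
  if (!is.null(compare)) {
    comparison <- stage("mutant comparison", {
      mut <- if (is.character(compare)) read_landmarks(compare) else
        as_landmark_array(compare)
      jr <- joint_registration(landmarks, mut, pairing = pairing)
      grp <- attr(jr, "groups")
      mdir <- mutant_direction(jr, which(grp == "reference"),
                               which(grp == "mutant"))
      vc <- vector_correlation(effect$values, mdir$values)
      list(direction = mdir, vc = vc)
    })
  }

  run <- structure(list(gene_set = gene_set, space = space, block = block,
                        fit = fit, cv = cv, lambda_source = lambda_source,
                        effect = effect, comparison = comparison,
                        seed = seed, files = NULL),
                   class = "mgp_run")
  if (!is.null(out_dir)) run$files <- write_run_artifacts(run, out_dir)
  run
}

#' @export
print.mgp_run <- function(x, ...) {
  cat(sprintf("<mgp_run> %d genes, n = %d; lambda = %.4g (%s); R^2 = %.4g\n",
              nrow(x$gene_set$genes), nrow(x$block), x$fit$lambda,
              x$lambda_source, x$fit$r2))
  if (!is.null(x$comparison)) {
    cat(sprintf("  mutant comparison: r = %.3f (t = %.3g, df = %d, p = %.3g)\n",
                x$comparison$vc$r, x$comparison$vc$t, x$comparison$vc$df,
                x$comparison$vc$p))
  }
  invisible(x)
}

#' Serialize a PLS fit to JSON
#'
#' @param fit an `mgp_pls`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(lambda = fit$lambda, d = fit$d, r2 = fit$r2,
              u = fit$u, v = fit$v, b = fit$b, scores = fit$scores,
              x_center = fit$x_center, x_scale = fit$x_scale,
              y_center = fit$y_center, y_scale = fit$y_scale,
              x_labels = fit$x_labels, genes = fit$genes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a PLS fit from JSON
#'
#' @param path path written by [write_fit_json()].
#' @return An `mgp_pls` object.
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "mgp_pls")
}

# Per-gene x founder loading table from a fit.
loading_table <- function(fit) {
  genes <- fit$genes
  if (is.null(genes)) genes <- unique(sub("\\.[A-H]$", "", fit$x_labels))
  U <- matrix(fit$u, nrow = 8L)
  df <- data.frame(gene = genes, t(U), stringsAsFactors = FALSE)
  names(df)[-1L] <- FOUNDERS
  df$norm <- sqrt(colSums(U^2))
  df[order(df$norm, decreasing = TRUE), , drop = FALSE]
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(fit = file.path(out_dir, "fit.json"),
             loadings = file.path(out_dir, "loadings.csv"),
             effect = file.path(out_dir, "effect.csv"),
             report = file.path(out_dir, "report.html"))
  write_fit_json(run$fit, files[["fit"]])
  lt <- loading_table(run$fit)
  num <- vapply(lt, is.numeric, logical(1L))
  lt[num] <- lapply(lt[num], function(x) sprintf("%.10g", x))
  utils::write.csv(lt, files[["loadings"]], row.names = FALSE, quote = FALSE)
  K <- length(run$effect$values) %/% 3L
  eff <- data.frame(landmark = rep(seq_len(K), each = 3L),
                    axis = rep(c("x", "y", "z"), K),
                    loading = sprintf("%.10g", run$effect$values))
  utils::write.csv(eff, files[["effect"]], row.names = FALSE, quote = FALSE)
  if (!is.null(run$cv)) {
    files[["cv"]] <- file.path(out_dir, "cv.csv")
    cvdf <- data.frame(lambda = run$cv$lambda_grid,
                       mean_error = sprintf("%.10g", run$cv$mean_error))
    utils::write.csv(cvdf, files[["cv"]], row.names = FALSE, quote = FALSE)
  }
  sums <- tools::md5sum(files[names(files) != "report"])
  write_html_report(run, files[["report"]],
                    checksums = stats::setNames(unname(sums),
                                                basename(names(sums))))
  files
}

# Minimal static HTML report: provenance, gene loadings, effect
# summary, optional mutant comparison.
write_html_report <- function(run, path, checksums = NULL) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lt <- loading_table(run$fit)
  rows <- apply(lt, 1L, function(r) {
    paste0("<tr><td>", paste(esc(format(r)), collapse = "</td><td>"),
           "</td></tr>")
  })
  cmp <- ""
  if (!is.null(run$comparison)) {
    vc <- run$comparison$vc
    cmp <- sprintf(
      "<h2>Mutant comparison</h2><p>vector correlation r = %.3f (t = %.3g, df = %d, p = %.3g)</p>",
      vc$r, vc$t, vc$df, vc$p)
  }
  cvp <- if (is.null(run$cv)) "" else sprintf(
    "<p>lambda chosen by %d-fold cross-validation over [%g, %g].</p>",
    nrow(run$cv$fold_errors), min(run$cv$lambda_grid), max(run$cv$lambda_grid))
  html <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>Process MGP report</title>",
    "<style>body{font-family:sans-serif;margin:2em}table{border-collapse:collapse}td,th{border:1px solid #999;padding:2px 8px}</style>",
    "</head><body>",
    "<h1>Process MGP analysis</h1>",
    sprintf("<p>Gene set: %d genes from terms %s%s</p>",
            nrow(run$gene_set$genes),
            esc(paste(run$gene_set$go_ids, collapse = ", ")),
            if (nzchar(run$gene_set$query))
              paste0(" (query: ", esc(run$gene_set$query), ")") else ""),
    sprintf("<p>n = %d specimens; lambda = %.4g (%s); singular value d = %.4g; R<sup>2</sup> = %.4g (%.2f%% of shape variance)</p>",
            nrow(run$block), run$fit$lambda, run$lambda_source, run$fit$d,
            run$fit$r2, 100 * run$fit$r2),
    cvp,
    "<h2>Per-gene founder loadings (PLS1)</h2>",
    "<table><tr><th>gene</th>",
    paste0("<th>", FOUNDERS, "</th>", collapse = ""),
    "<th>norm</th></tr>",
    rows,
    "</table>",
    cmp,
    sprintf("<p>seed %s</p>", run$seed),
    if (!is.null(checksums)) sprintf(
      "<p>artifact md5: %s</p>",
      esc(paste(sprintf("%s=%s", names(checksums), checksums),
                collapse = "; "))) else "",
    "</body></html>")
  writeLines(html, path)
  invisible(path)
}
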