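# Gene catalog and ontology handling: resolve text queries against a
# flat-file GO-style annotation snapshot into gene sets with genomic
# intervals, the unit of marker selection.

#' Load a gene catalog from a transcript-level interval file
#'
#' Reads a tab-separated snapshot with columns
#' `gene, transcript, chrom, start, end, strand` (header required; the
#' file may be gzip-compressed) and collapses transcripts to one record
#' per gene symbol. Among multiple transcripts of a gene the longest
#' (`end - start` maximal) is retained; ties are broken by the smallest
#' start position. Coordinates are 1-based and inclusive.
#'
#' Gene identity is keyed on the symbol. The same symbol appearing on two
#' different chromosomes is rejected, since downstream marker selection
#' and plots would be ambiguous.
#'
#' @param path path to the catalog TSV (optionally gzipped).
#' @return A `data.frame` with columns `gene`, `chrom`, `start`, `end`,
#'   `tx_length` (`end - start + 1`), `strand`, one row per gene, ordered
#'   by chromosome then start.
#' @export
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ttranscript\tchrom\tstart\tend\tstrand",
#'              "Bmpr1b\tBmpr1b-201\t3\t100\t500\t+",
#'              "Bmpr1b\tBmpr1b-202\t3\t100\t900\t+"), tsv)
#' load_gene_catalog(tsv)
load_gene_catalog <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("gene", "transcript", "chrom", "start", "end", "strand")
  if (!all(need %in% names(df))) {
    stop_mgp("gene catalog must have columns: ", paste(need, collapse = ", "))
  }
  start <- suppressWarnings(as.integer(df$start))
  end <- suppressWarnings(as.integer(df$end))
  bad <- which(is.na(start) | is.na(end) | !nzchar(df$gene) | !nzchar(df$chrom))
  if (length(bad)) {
    stop_mgp("malformed catalog row at data line ", bad[1L],
             " of ", basename(path))
  }
  rev_iv <- which(start > end)
  if (length(rev_iv)) {
    stop_mgp("start > end at data line ", rev_iv[1L], " (gene ",
             df$gene[rev_iv[1L]], ")")
  }
  df$start <- start
  df$end <- end
  # longest transcript per gene; ties -> smallest start
  len <- end - start
  ord <- order(df$gene, -len, start)
  df <- df[ord, , drop = FALSE]
  keep <- df[!duplicated(df$gene), , drop = FALSE]
  dup_chr <- tapply(df$chrom, df$gene, function(x) length(unique(x)))
  if (any(dup_chr > 1L)) {
    stop_mgp("gene symbol(s) on multiple chromosomes: ",
             paste(names(dup_chr)[dup_chr > 1L], collapse = ", "))
  }
  out <- data.frame(gene = keep$gene, chrom = keep$chrom,
                    start = keep$start, end = keep$end,
                    tx_length = keep$end - keep$start + 1L,
                    strand = keep$strand, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load a gene-ontology annotation map
#'
#' Reads a 3-column tab-separated file (`go_id`, `term`, `gene`),
#' optionally gzipped. Duplicate (`go_id`, `gene`) pairs are collapsed.
#'
#' @param path path to the ontology TSV.
#' @return A `data.frame` with columns `go_id`, `term`, `gene`.
#' @export
load_ontology <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("go_id", "term", "gene")
  if (!all(need %in% names(df))) {
    stop_mgp("ontology must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[!duplicated(df[c("go_id", "gene")]), need, drop = FALSE]
  if (!nrow(df)) stop_mgp("ontology file is empty")
  rownames(df) <- NULL
  df
}

#' Filter ontology terms by a text query
#'
#' Returns terms whose name contains the query as a case-insensitive
#' substring. A `|` in the query separates alternatives with union
#' (OR) semantics: `filter_terms("a|b", ont)` is exactly the union of
#' the separate queries.
#'
#' @param query non-empty query string; `|` separates alternatives.
#' @param ontology ontology map from [load_ontology()].
#' @return A `data.frame` with columns `go_id`, `term`, `n_genes`, one
#'   row per matching term (possibly zero rows).
#' @export
filter_terms <- function(query, ontology) {
  if (!is.character(query) || length(query) != 1L || !nzchar(query)) {
    stop_mgp("query must be a single non-empty string")
  }
  terms <- unique(ontology[c("go_id", "term")])
  alts <- strsplit(query, "|", fixed = TRUE)[[1L]]
  alts <- alts[nzchar(alts)]
  hit <- rep(FALSE, nrow(terms))
  for (a in alts) {
    hit <- hit | grepl(a, terms$term, ignore.case = TRUE, fixed = FALSE)
  }
  out <- terms[hit, , drop = FALSE]
  n_genes <- vapply(out$go_id, function(id) {
    length(unique(ontology$gene[ontology$go_id == id]))
  }, integer(1L))
  out$n_genes <- unname(n_genes)
  rownames(out) <- NULL
  out
}

#' Resolve GO identifiers to a gene set with genomic intervals
#'
#' Takes the union of genes annotated to the given terms (direct
#' annotations only; no graph closure) and matches each to its catalog
#' record. Genes absent from the catalog are dropped with a warning that
#' reports the count. Resolution is idempotent and invariant to the
#' order of `go_ids`; the result is ordered genomically.
#'
#' @param go_ids character vector of GO identifiers, all present in the
#'   ontology.
#' @param ontology ontology map from [load_ontology()].
#' @param catalog gene catalog from [load_gene_catalog()].
#' @param query optional query string recorded on the result.
#' @return An object of class `gene_set`: a list with `query`, `go_ids`,
#'   `genes` (catalog rows for the member genes) and `n_unmapped`.
#' @export
resolve_gene_set <- function(go_ids, ontology, catalog, query = "") {
  go_ids <- unique(as.character(go_ids))
  missing_ids <- setdiff(go_ids, ontology$go_id)
  if (length(missing_ids)) {
    stop_mgp("go_id(s) not in ontology: ", paste(missing_ids, collapse = ", "))
  }
  symbols <- unique(ontology$gene[ontology$go_id %in% go_ids])
  in_cat <- symbols %in% catalog$gene
  n_unmapped <- sum(!in_cat)
  if (n_unmapped > 0L) {
    warning(sprintf("%d gene(s) not in catalog were dropped: %s",
                    n_unmapped, paste(symbols[!in_cat], collapse = ", ")),
            call. = FALSE)
  }
  genes <- catalog[catalog$gene %in% symbols, , drop = FALSE]
  if (!nrow(genes)) stop_mgp("no mappable genes for the selected term(s)")
  genes <- genes[order(genes$chrom, genes$start, genes$gene), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(query = query, go_ids = sort(go_ids), genes = genes,
                 n_unmapped = n_unmapped),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %d gene(s) from %d GO term(s)%s\n",
              nrow(x$genes), length(x$go_ids),
              if (nzchar(x$query)) paste0(" [query: ", x$query, "]") else ""))
  cat("  genes:", paste(utils::head(x$genes$gene, 10L), collapse = ", "),
      if (nrow(x$genes) > 10L) "..." else "", "\n")
  invisible(x)
}
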