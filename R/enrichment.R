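# Local over-representation analysis: hypergeometric upper-tail tests per
# annotation term, Benjamini-Hochberg FDR per namespace, top-N selection and
# bubble/chord plot-data exports.

.namespaces <- c("GO_CC", "GO_MF", "GO_BP", "PATHWAY")

#' Upper-tail hypergeometric p-value
#'
#' P\[X >= k\] for X ~ Hypergeometric(N, K, n): drawing `n` genes from a
#' universe of `N` of which `K` carry the annotation, the chance of seeing
#' `k` or more annotated genes. Summed in log space for stability.
#'
#' @param k Observed overlap (0 <= k <= min(K, n)).
#' @param K Term size.
#' @param n Query size (within the universe).
#' @param N Universe size.
#' @return p-value in (0, 1\].
#' @export
#' @examples
#' hypergeom_p(4, 5, 4, 10)  # 5/210
hypergeom_p <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L, length(N) == 1L)
  if (k < 0 || K < 0 || n < 0 || N < 0 || K > N || n > N || k > min(K, n)) {
    stop(sprintf("invalid hypergeometric arguments k=%s K=%s n=%s N=%s",
                 k, K, n, N))
  }
  if (k == 0) return(1)
  lo <- stats::dhyper(seq.int(k, min(K, n)), K, N - K, n, log = TRUE)
  mx <- max(lo)
  min(1, exp(mx + log(sum(exp(lo - mx)))))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Classic step-up adjustment with monotonicity enforcement; adjusted values
#' are returned in the input order and are always >= the raw p-values.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same order.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Construct an annotation table
#'
#' Flat term -> gene-set annotations within one namespace; the background
#' universe is the union of all term members.
#'
#' @param terms Named list of character gene vectors; every term non-empty,
#'   names unique.
#' @param namespace One of `"GO_CC"`, `"GO_MF"`, `"GO_BP"`, `"PATHWAY"`.
#' @return An object of class `annotation_table` with `namespace`, `terms`
#'   (symbols upper-cased, deduplicated) and `universe`.
#' @export
annotation_table <- function(terms, namespace = "PATHWAY") {
  namespace <- match.arg(namespace, .namespaces)
  stopifnot(is.list(terms), length(terms) > 0L)
  nm <- names(terms)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm)) {
    stop("terms must have unique non-empty names")
  }
  terms <- lapply(terms, function(g) unique(toupper(as.character(g))))
  if (any(vapply(terms, length, integer(1)) == 0L)) {
    stop("every term must be non-empty")
  }
  structure(list(namespace = namespace, terms = terms,
                 universe = sort(unique(unlist(terms, use.names = FALSE)))),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf("<annotation_table %s: %d terms, %d universe genes>\n",
              x$namespace, length(x$terms), length(x$universe)))
  invisible(x)
}

#' Over-representation analysis of a query gene set
#'
#' For each annotation term with at least one query overlap (or all terms
#' when `test_all`), computes the upper-tail hypergeometric p-value against
#' the annotation table's own gene universe, then applies
#' Benjamini-Hochberg within each namespace across the tested terms. Query
#' genes outside the universe are excluded from `n` and reported in the
#' `excluded_genes` attribute. Rows are sorted by FDR ascending, then
#' overlap `k` descending, then term name.
#'
#' @param query A [gene_set()] or character vector of symbols.
#' @param annotations An [annotation_table()] or a list of them.
#' @param fdr_cutoff Rows with `fdr < fdr_cutoff` are flagged significant.
#' @param test_all Also test (and count in the BH family) terms with zero
#'   overlap; they get `p_value = 1`.
#' @return Data frame with columns `term, namespace, k, K, n, N, p_value,
#'   fdr, significant, genes` (overlap members, comma-collapsed); attribute
#'   `excluded_genes` lists query genes outside the universe.
#' @export
enrich <- function(query, annotations, fdr_cutoff = 0.05, test_all = FALSE) {
  qg <- if (inherits(query, "gene_set")) query$genes else
    unique(toupper(as.character(query)))
  if (inherits(annotations, "annotation_table")) {
    annotations <- list(annotations)
  }
  stopifnot(all(vapply(annotations, inherits, logical(1), "annotation_table")))
  excluded <- character(0)
  out <- lapply(annotations, function(ann) {
    eff <- intersect(qg, ann$universe)
    excluded <<- unique(c(excluded, setdiff(qg, ann$universe)))
    n <- length(eff)
    if (n == 0L) {
      stop(sprintf("no query gene lies in the %s annotation universe",
                   ann$namespace))
    }
    N <- length(ann$universe)
    hits <- lapply(ann$terms, intersect, eff)
    k <- vapply(hits, length, integer(1))
    keep <- if (test_all) rep(TRUE, length(k)) else k >= 1L
    if (!any(keep)) return(NULL)
    K <- vapply(ann$terms, length, integer(1))[keep]
    kk <- k[keep]
    p <- mapply(hypergeom_p, kk, K, MoreArgs = list(n = n, N = N))
    df <- data.frame(term = names(ann$terms)[keep], namespace = ann$namespace,
                     k = kk, K = K, n = n, N = N, p_value = p,
                     fdr = bh_fdr(p), stringsAsFactors = FALSE)
    df$significant <- df$fdr < fdr_cutoff
    df$genes <- vapply(hits[keep], paste, character(1), collapse = ",")
    df <- df[order(df$fdr, -df$k, df$term, method = "radix"), , drop = FALSE]
    df
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(term = character(0), namespace = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p_value = numeric(0), fdr = numeric(0),
                      significant = logical(0), genes = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  attr(res, "excluded_genes") <- excluded
  res
}

#' Select the top terms per namespace
#'
#' First `top_n` rows per namespace under the enrichment ordering (FDR
#' ascending, overlap `k` descending, term name ascending).
#'
#' @param rows An [enrich()] result.
#' @param top_n Number of rows to keep per namespace (>= 1).
#' @return Subset of `rows`.
#' @export
top_terms <- function(rows, top_n) {
  if (!is.numeric(top_n) || length(top_n) != 1L || top_n < 1) {
    stop("top_n must be a single number >= 1")
  }
  rows <- rows[order(match(rows$namespace, unique(rows$namespace)),
                     rows$fdr, -rows$k, rows$term, method = "radix"), ,
               drop = FALSE]
  out <- do.call(rbind, lapply(split(rows, factor(rows$namespace,
                                                  unique(rows$namespace))),
                               utils::head, n = top_n))
  rownames(out) <- NULL
  out
}

#' Bubble-diagram data
#'
#' One row per term: overlap count and `-log10(fdr)`, the usual bubble
#' size/color pair.
#'
#' @param rows An [enrich()] result.
#' @return Data frame `term, namespace, k, neg_log10_fdr`.
#' @export
bubble_data <- function(rows) {
  data.frame(term = rows$term, namespace = rows$namespace, k = rows$k,
             neg_log10_fdr = -log10(rows$fdr), stringsAsFactors = FALSE)
}

#' Chordal-diagram membership matrix
#'
#' Binary gene x term membership restricted to the overlap genes of the
#' selected terms.
#'
#' @param selected_rows Rows (typically from [top_terms()]) whose `genes`
#'   column holds comma-collapsed overlap members.
#' @return Integer matrix, genes as rows, terms as columns.
#' @export
chord_data <- function(selected_rows) {
  members <- strsplit(selected_rows$genes, ",", fixed = TRUE)
  genes <- unique(unlist(members, use.names = FALSE))
  m <- matrix(0L, nrow = length(genes), ncol = nrow(selected_rows),
              dimnames = list(genes, selected_rows$term))
  for (j in seq_along(members)) m[members[[j]], j] <- 1L
  m
}

#' Read gene sets in GMT format
#'
#' One term per line: name, description, then the member genes,
#' tab-separated.
#'
#' @param path File path.
#' @param namespace Namespace assigned to the resulting table.
#' @return An [annotation_table()].
#' @export
read_gmt <- function(path, namespace = "PATHWAY") {
  con <- file(path, encoding = "UTF-8")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("empty GMT file '%s'", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad)) stop(sprintf("GMT line %d has fewer than 3 fields",
                             which(bad)[1]))
  terms <- lapply(parts, function(p) p[-(1:2)])
  names(terms) <- vapply(parts, `[[`, character(1), 1L)
  annotation_table(terms, namespace)
}

#' Write an annotation table in GMT format
#'
#' @param ann An [annotation_table()].
#' @param path Output path.
#' @param description Description field written for every term.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(ann, path, description = "na") {
  stopifnot(inherits(ann, "annotation_table"))
  lines <- vapply(names(ann$terms), function(nm) {
    paste(c(nm, description, ann$terms[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write enrichment rows as a STRING-style TSV
#'
#' Columns mirror STRING's `enrichment.<Category>.tsv`: term, observed gene
#' count, background gene count, p-value, FDR, matching genes.
#'
#' @param rows An [enrich()] result (single namespace or mixed).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(rows, path) {
  df <- data.frame(term = rows$term,
                   observed_gene_count = rows$k,
                   background_gene_count = rows$K,
                   p_value = rows$p_value,
                   fdr = rows$fdr,
                   matching_genes = rows$genes,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
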