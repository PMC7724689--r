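# Gene-set normalization, union, disease-source integration, Venn overlap.

#' Construct a gene set
#'
#' A `gene_set` is a labelled, ordered collection of unique upper-case gene
#' symbols with per-gene provenance tags. Symbols are trimmed, upper-cased
#' and deduplicated (merging provenance) on construction.
#'
#' @param genes Character vector of symbols (any case).
#' @param label Set label used as the default provenance tag.
#' @param provenance Optional list, parallel to `genes`, of character tag
#'   vectors; defaults to `label` for every gene.
#' @return An object of class `gene_set` with fields `label`, `genes`
#'   (ordered unique symbols) and `provenance` (named list).
#' @export
gene_set <- function(genes = character(0), label = "", provenance = NULL) {
  genes <- as.character(genes)
  if (anyNA(genes) || any(!nzchar(trimws(genes)))) {
    stop("gene symbols must be non-empty and non-missing")
  }
  syms <- toupper(gsub("\\s+", "", genes))
  if (is.null(provenance)) {
    provenance <- rep(list(if (nzchar(label)) label else character(0)),
                      length(syms))
  }
  stopifnot(length(provenance) == length(syms))
  uniq <- unique(syms)
  prov <- lapply(uniq, function(s) {
    sort(unique(unlist(provenance[syms == s], use.names = FALSE)))
  })
  names(prov) <- uniq
  structure(list(label = label, genes = uniq, provenance = prov),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set '%s': %d symbols>\n", x$label, length(x$genes)))
  if (length(x$genes) > 0L) {
    shown <- utils::head(x$genes, 10L)
    cat(" ", paste(shown, collapse = ", "),
        if (length(x$genes) > 10L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Map raw target names to official gene symbols
#'
#' Each raw name is looked up in a caller-supplied mapping table (exact
#' string match on `raw_name`), the mapped symbol upper-cased, and
#' duplicates collapsed with merged provenance (the contributing raw names).
#' Raw names absent from the mapping are returned in `unmapped`, never
#' silently dropped into the set.
#'
#' @param raw_names Character vector of raw protein/target names.
#' @param mapping Data frame with columns `raw_name`, `symbol`.
#' @param label Label for the resulting set.
#' @return A list with `set` (a [gene_set()]) and `unmapped` (character).
#' @export
normalize_genes <- function(raw_names, mapping, label = "") {
  stopifnot(is.data.frame(mapping),
            all(c("raw_name", "symbol") %in% names(mapping)))
  raw_names <- as.character(raw_names)
  if (length(raw_names) == 0L) {
    return(list(set = gene_set(character(0), label), unmapped = character(0)))
  }
  idx <- match(raw_names, mapping$raw_name)
  unmapped <- unique(raw_names[is.na(idx)])
  hit <- !is.na(idx)
  set <- gene_set(mapping$symbol[idx[hit]], label = label,
                  provenance = as.list(raw_names[hit]))
  list(set = set, unmapped = unmapped)
}

#' Union of per-ingredient target sets
#'
#' Set union over already-normalized gene sets, first-seen ordering.
#' Provenance records every contributing set: each symbol's tags are the
#' union of the contributing sets' labels and of their own per-gene tags.
#'
#' @param sets List of [gene_set()] objects.
#' @param label Label for the union set.
#' @return A [gene_set()].
#' @export
union_targets <- function(sets, label = "union") {
  stopifnot(is.list(sets), all(vapply(sets, inherits, logical(1), "gene_set")))
  genes <- character(0)
  prov <- list()
  for (s in sets) {
    for (g in s$genes) {
      tags <- c(s$label[nzchar(s$label)], s$provenance[[g]])
      if (is.null(prov[[g]])) {
        genes <- c(genes, g)
        prov[[g]] <- unique(tags)
      } else {
        prov[[g]] <- unique(c(prov[[g]], tags))
      }
    }
  }
  out <- gene_set(genes, label = label, provenance = prov[genes])
  out
}

#' Integrate two disease-target sources
#'
#' Union of two normalized disease-target sets with per-source provenance
#' retained; a gene found in both sources carries both tags.
#'
#' @param source_a,source_b [gene_set()] objects.
#' @param label Label for the integrated set.
#' @return A [gene_set()].
#' @export
integrate_disease_targets <- function(source_a, source_b,
                                      label = "disease_targets") {
  union_targets(list(source_a, source_b), label = label)
}

#' Venn overlap of drug targets against disease targets
#'
#' Intersection on symbols plus the usual summary counts.
#' `pct_of_b` = 100 * |intersection| / |disease set|, rounded half-up to 2
#' decimals for reporting.
#'
#' @param drug_targets,disease_targets [gene_set()] objects.
#' @return A list of class `venn_summary`: `size_a`, `size_b`,
#'   `size_intersection`, `size_union`, `pct_of_b`, and `overlap` (a
#'   [gene_set()] of the common symbols, provenance merged from both sides).
#' @export
venn <- function(drug_targets, disease_targets) {
  stopifnot(inherits(drug_targets, "gene_set"),
            inherits(disease_targets, "gene_set"))
  if (length(disease_targets$genes) == 0L) {
    stop("disease target set is empty: overlap percentage undefined")
  }
  common <- intersect(drug_targets$genes, disease_targets$genes)
  prov <- lapply(common, function(g) {
    unique(c(drug_targets$provenance[[g]], disease_targets$provenance[[g]]))
  })
  overlap <- gene_set(common, label = "overlap", provenance = prov)
  a <- length(drug_targets$genes)
  b <- length(disease_targets$genes)
  i <- length(common)
  structure(list(size_a = a, size_b = b, size_intersection = i,
                 size_union = a + b - i,
                 pct_of_b = round_half_up(100 * i / b, 2L),
                 overlap = overlap),
            class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat(sprintf(
    "<venn: |A|=%d |B|=%d |A^B|=%d |AvB|=%d (%.2f%% of B)>\n",
    x$size_a, x$size_b, x$size_intersection, x$size_union, x$pct_of_b))
  invisible(x)
}

#' Read a one-symbol-per-line gene list
#'
#' @param path File path; blank lines and `#` comment lines are skipped.
#' @param label Label for the resulting set.
#' @return A [gene_set()].
#' @export
read_gene_list <- function(path, label = basename(path)) {
  con <- file(path, encoding = "UTF-8")
  on.exit(close(con))
  lines <- trimws(readLines(con, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_set(lines, label = label)
}

#' Write a gene set as a one-symbol-per-line list
#'
#' @param set A [gene_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(set, path) {
  stopifnot(inherits(set, "gene_set"))
  writeLines(set$genes, path, useBytes = FALSE)
  invisible(path)
}

#' Write a gene set as TSV with provenance
#'
#' Columns `symbol` and `provenance` (";"-collapsed tags).
#'
#' @param set A [gene_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_set_tsv <- function(set, path) {
  stopifnot(inherits(set, "gene_set"))
  df <- data.frame(
    symbol = set$genes,
    provenance = vapply(set$provenance[set$genes], paste, character(1),
                        collapse = ";"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a raw-name to symbol mapping table
#'
#' Two-column TSV with header `raw_name`, `symbol`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_gene_mapping <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("raw_name", "symbol") %in% names(df))) {
    stop(sprintf("mapping file '%s' must have columns raw_name, symbol", path))
  }
  df
}
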