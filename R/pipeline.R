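# End-to-end orchestration: chem -> target_sets -> ppi_network -> enrichment,
# artifact writing, and the tripartite herb-ingredient-target-disease export.

#' Build a pipeline configuration
#'
#' All screening thresholds default to the conventional values: OB >= 30,
#' Caco-2 >= 0.4, DL >= 0.18; BATMAN score >= 20 with adjusted P < 0.05;
#' PPI combined score >= 0.4 ("medium confidence"); FDR cutoff 0.05; top 25
#' pathways and top 10 GO terms per namespace.
#'
#' @param ingredient_tables List of `list(path=, source=)` entries
#'   (`source` is `"TCMSP"` or `"BATMAN"`).
#' @param target_map Path to the ingredient-target map TSV (`herb_latin,
#'   ingredient, raw_target`).
#' @param disease_a,disease_b Paths to the two disease-target source lists
#'   (one symbol per line).
#' @param ppi_edges Path to a STRING-style `string_interactions.tsv`.
#' @param annotations List of `list(path=, namespace=)` GMT entries.
#' @param gene_mapping Optional path to a `raw_name, symbol` mapping TSV;
#'   when `NULL` raw targets are taken as symbols (identity mapping).
#' @param ob_min,caco2_min,dl_min,score_min,adj_p_max Screening thresholds.
#' @param ppi_score_min PPI combined-score cut.
#' @param drop_isolated Drop PPI nodes with no surviving edge.
#' @param fdr_cutoff Enrichment significance cutoff.
#' @param top_n_pathways,top_n_go Top-N selection sizes.
#' @param seed Seed recorded in the run log.
#' @param out_dir Artifact directory.
#' @param base_dir Directory that relative input paths are resolved
#'   against.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(ingredient_tables, target_map, disease_a,
                            disease_b, ppi_edges, annotations,
                            gene_mapping = NULL,
                            ob_min = 30, caco2_min = 0.4, dl_min = 0.18,
                            score_min = 20, adj_p_max = 0.05,
                            ppi_score_min = 0.4, drop_isolated = FALSE,
                            fdr_cutoff = 0.05, top_n_pathways = 25L,
                            top_n_go = 10L, seed = 1L, out_dir = "results",
                            base_dir = ".") {
  stopifnot(ppi_score_min >= 0, ppi_score_min <= 1,
            fdr_cutoff > 0, fdr_cutoff <= 1,
            top_n_pathways >= 1, top_n_go >= 1)
  structure(list(ingredient_tables = ingredient_tables,
                 target_map = target_map, disease_a = disease_a,
                 disease_b = disease_b, ppi_edges = ppi_edges,
                 annotations = annotations, gene_mapping = gene_mapping,
                 ob_min = ob_min, caco2_min = caco2_min, dl_min = dl_min,
                 score_min = score_min, adj_p_max = adj_p_max,
                 ppi_score_min = ppi_score_min,
                 drop_isolated = drop_isolated, fdr_cutoff = fdr_cutoff,
                 top_n_pathways = top_n_pathways, top_n_go = top_n_go,
                 seed = seed, out_dir = out_dir, base_dir = base_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a flat JSON document
#'
#' Relative paths in the file are resolved against the file's directory.
#'
#' @param path Path to a `config.json` as written by [gen_bundle()].
#' @return A [pipeline_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: '%s'", path))
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  args <- raw
  args$base_dir <- dirname(normalizePath(path))
  args$ingredient_tables <- lapply(raw$ingredient_tables, function(e) {
    list(path = e$path, source = e$source)
  })
  args$annotations <- lapply(raw$annotations, function(e) {
    list(path = e$path, namespace = e$namespace)
  })
  do.call(pipeline_config, args)
}

.resolve <- function(path, base_dir) {
  if (is.null(path)) return(NULL)
  if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(base_dir, path)
}

.require_file <- function(path, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s input not readable: '%s'", what, path))
  }
  path
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Build the tripartite herb-ingredient-target-disease edge list
#'
#' Typed edges: `herb_ingredient` (one per herb carrying a candidate),
#' `ingredient_target` (from the candidate-restricted map), and
#' `target_disease` for overlap members only. The node table marks overlap
#' targets.
#'
#' @param candidates Candidate table from [select_candidates()].
#' @param target_map Data frame `herb_latin, ingredient, raw_target` (or a
#'   `target` column of symbols).
#' @param overlap [gene_set()] of drug-disease overlap symbols.
#' @param disease_label Label of the single disease node.
#' @return A list with `edges` (`source, target, type`) and `nodes`
#'   (`node, role, is_overlap`).
#' @export
build_itd_network <- function(candidates, target_map, overlap,
                              disease_label = "disease") {
  tgt_col <- if ("target" %in% names(target_map)) "target" else "raw_target"
  key <- .name_key(candidates$name)
  map <- target_map[.name_key(target_map$ingredient) %in% key, , drop = FALSE]
  hi <- unique(do.call(rbind, lapply(seq_len(nrow(candidates)), function(i) {
    data.frame(source = strsplit(candidates$herbs[i], ";", fixed = TRUE)[[1]],
               target = candidates$name[i], type = "herb_ingredient",
               stringsAsFactors = FALSE)
  })))
  it <- unique(data.frame(source = map$ingredient,
                          target = toupper(map[[tgt_col]]),
                          type = "ingredient_target", stringsAsFactors = FALSE))
  ov <- overlap$genes
  td <- data.frame(source = ov,
                   target = rep(disease_label, length(ov)),
                   type = rep("target_disease", length(ov)),
                   stringsAsFactors = FALSE)
  edges <- rbind(hi, it, td)
  rownames(edges) <- NULL
  targets <- unique(it$target)
  nodes <- rbind(
    data.frame(node = unique(hi$source), role = "herb",
               stringsAsFactors = FALSE),
    data.frame(node = candidates$name, role = "ingredient",
               stringsAsFactors = FALSE),
    data.frame(node = targets, role = "target", stringsAsFactors = FALSE),
    data.frame(node = disease_label, role = "disease",
               stringsAsFactors = FALSE))
  nodes$is_overlap <- nodes$node %in% ov & nodes$role == "target"
  list(edges = edges, nodes = nodes)
}

#' Run the full analysis pipeline
#'
#' Executes candidate screening, target-set integration, the Venn overlap,
#' PPI construction with topology metrics, and per-namespace
#' over-representation analysis, writing every artifact under the
#' configured output directory. Deterministic: identical inputs and config
#' yield byte-identical artifacts.
#'
#' @param config A [pipeline_config()] or path to a JSON config file.
#' @param stop_after Last stage to execute: `"filter"`, `"targets"`,
#'   `"venn"`, `"network"`, `"enrich"` or `"all"` (default). The run log is
#'   written in every case, covering the executed stages.
#' @return A `pipeline_report` list: `candidates`, `drug_targets`,
#'   `disease_targets`, `venn`, `graph`, `topology`, `summary`,
#'   `enrichment`, `tripartite` and `log` (per-stage counts), invisibly.
#' @export
run_pipeline <- function(config, stop_after = c("all", "filter", "targets",
                                                "venn", "network", "enrich")) {
  stop_after <- match.arg(stop_after)
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  bd <- config$base_dir
  out <- .resolve(config$out_dir, bd)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = config$seed,
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              package_version = as.character(utils::packageVersion("netpharm")))
  report <- structure(list(out_dir = out), class = "pipeline_report")
  finish <- function() {
    jsonlite::write_json(log, file.path(out, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report$log <- log
    invisible(report)
  }

  th <- pk_thresholds(config$ob_min, config$caco2_min, config$dl_min,
                      config$score_min, config$adj_p_max)

  # -- stage 1: ingredient screening -------------------------------------
  candidates <- NULL
  tables <- .stage("filter", {
    lapply(config$ingredient_tables, function(e) {
      read_ingredients(.require_file(.resolve(e$path, bd), "ingredient"),
                       source = e$source)
    })
  })
  candidates <- .stage("filter", select_candidates(tables, th))
  log$ingredients_per_herb <- vapply(tables, nrow, integer(1))
  log$ingredients_total <- sum(log$ingredients_per_herb)
  log$candidates <- nrow(candidates)
  utils::write.table(candidates, file.path(out, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$candidates <- candidates
  if (stop_after == "filter") return(finish())

  # -- stage 2: ingredient targets ---------------------------------------
  drug <- .stage("targets", {
    map <- utils::read.delim(.require_file(.resolve(config$target_map, bd),
                                           "target map"),
                             sep = "\t", stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8")
    map <- map[.name_key(map$ingredient) %in% .name_key(candidates$name), ,
               drop = FALSE]
    mapping <- if (!is.null(config$gene_mapping)) {
      read_gene_mapping(.require_file(.resolve(config$gene_mapping, bd),
                                      "gene mapping"))
    } else {
      data.frame(raw_name = unique(map$raw_target),
                 symbol = unique(map$raw_target), stringsAsFactors = FALSE)
    }
    per_herb <- split(map, factor(map$herb_latin, unique(map$herb_latin)))
    log$raw_targets_per_herb <- vapply(per_herb, function(m)
      length(unique(m$raw_target)), integer(1))
    log$raw_targets_total <- sum(log$raw_targets_per_herb)
    per_ing <- split(map$raw_target, factor(map$ingredient,
                                            unique(map$ingredient)))
    unmapped <- character(0)
    sets <- lapply(names(per_ing), function(ing) {
      nz <- normalize_genes(unique(per_ing[[ing]]), mapping, label = ing)
      unmapped <<- unique(c(unmapped, nz$unmapped))
      nz$set
    })
    log$unmapped_targets <- length(unmapped)
    if (length(unmapped) > 0L) {
      writeLines(sort(unmapped), file.path(out, "unmapped_targets.txt"))
    }
    union_targets(sets, label = "drug_targets")
  })
  log$drug_targets <- length(drug$genes)
  write_gene_set_tsv(drug, file.path(out, "drug_targets.tsv"))
  report$drug_targets <- drug
  if (stop_after == "targets") return(finish())

  # -- stage 3: disease integration + Venn -------------------------------
  vn <- .stage("venn", {
    a <- read_gene_list(.require_file(.resolve(config$disease_a, bd),
                                      "disease source A"), label = "source_a")
    b <- read_gene_list(.require_file(.resolve(config$disease_b, bd),
                                      "disease source B"), label = "source_b")
    log$disease_a <- length(a$genes)
    log$disease_b <- length(b$genes)
    disease <- integrate_disease_targets(a, b)
    log$disease_total <- length(disease$genes)
    write_gene_set_tsv(disease, file.path(out, "disease_targets.tsv"))
    venn(drug, disease)
  })
  log$overlap <- vn$size_intersection
  log$overlap_pct <- vn$pct_of_b
  jsonlite::write_json(list(size_a = vn$size_a, size_b = vn$size_b,
                            size_intersection = vn$size_intersection,
                            size_union = vn$size_union,
                            pct_of_b = vn$pct_of_b,
                            overlap = vn$overlap$genes),
                       file.path(out, "venn.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_gene_list(vn$overlap, file.path(out, "overlap_targets.txt"))
  report$venn <- vn
  if (stop_after == "venn") return(finish())

  # -- stage 4: PPI network ----------------------------------------------
  graph <- .stage("network", {
    edges <- read_string_edges(.require_file(.resolve(config$ppi_edges, bd),
                                             "PPI edges"))
    build_graph(edges, score_threshold = config$ppi_score_min,
                drop_isolated = isTRUE(config$drop_isolated),
                node_universe = vn$overlap)
  })
  topo <- rank_hubs(topology(graph))
  summ <- network_summary(graph)
  log$ppi_nodes <- summ$n_nodes
  log$ppi_edges <- summ$n_edges
  log$ppi_excluded_pairs <- summ$n_excluded_pairs
  utils::write.table(topo, file.path(out, "topology.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  export_graph(graph, file.path(out, "ppi_network.tsv"), "tsv")
  export_graph(graph, file.path(out, "ppi_network.sif"), "sif")
  export_graph(graph, file.path(out, "ppi_network.graphml"), "graphml")
  jsonlite::write_json(unclass(summ), file.path(out, "network_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$graph <- graph
  report$topology <- topo
  report$summary <- summ
  if (stop_after == "network") return(finish())

  # -- stage 5: enrichment -----------------------------------------------
  enr <- .stage("enrich", {
    anns <- lapply(config$annotations, function(e) {
      read_gmt(.require_file(.resolve(e$path, bd), "annotation"),
               namespace = e$namespace)
    })
    rows <- enrich(vn$overlap, anns, fdr_cutoff = config$fdr_cutoff)
    for (ns in unique(rows$namespace)) {
      sub <- rows[rows$namespace == ns, , drop = FALSE]
      write_enrichment_tsv(sub, file.path(out, sprintf("enrichment_%s.tsv",
                                                       tolower(ns))))
      top_n <- if (ns == "PATHWAY") config$top_n_pathways else config$top_n_go
      sel <- top_terms(sub, top_n)
      utils::write.table(bubble_data(sel),
                         file.path(out, sprintf("bubble_%s.tsv",
                                                tolower(ns))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ch <- chord_data(sel)
      utils::write.table(data.frame(gene = rownames(ch), ch,
                                    check.names = FALSE,
                                    stringsAsFactors = FALSE),
                         file.path(out, sprintf("chord_%s.tsv",
                                                tolower(ns))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    rows
  })
  log$enriched_significant <- sum(enr$significant)
  report$enrichment <- enr
  if (stop_after == "enrich") return(finish())

  # -- stage 6: tripartite network ---------------------------------------
  trip <- .stage("tripartite", {
    map <- utils::read.delim(.resolve(config$target_map, bd), sep = "\t",
                             stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    build_itd_network(candidates, map, vn$overlap)
  })
  utils::write.table(trip$edges, file.path(out, "tripartite_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(trip$nodes, file.path(out, "tripartite_nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log$tripartite_target_disease_edges <-
    sum(trip$edges$type == "target_disease")
  report$tripartite <- trip
  finish()
}

#' @export
print.pipeline_report <- function(x, ...) {
  l <- x$log
  cat("<pipeline_report>\n")
  cat(sprintf("  ingredients: %d (%s) -> candidates: %d\n",
              l$ingredients_total,
              paste(l$ingredients_per_herb, collapse = ", "), l$candidates))
  cat(sprintf("  raw targets: %d (%s) -> drug targets: %d\n",
              l$raw_targets_total,
              paste(l$raw_targets_per_herb, collapse = ", "),
              l$drug_targets))
  cat(sprintf("  disease: %d + %d -> %d | overlap: %d (%.2f%%)\n",
              l$disease_a, l$disease_b, l$disease_total, l$overlap,
              l$overlap_pct))
  cat(sprintf("  ppi: %d nodes, %d edges | significant terms: %d\n",
              l$ppi_nodes, l$ppi_edges, l$enriched_significant))
  invisible(x)
}
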