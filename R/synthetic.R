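# Synthetic input generator with planted ground truth.
#
# Every generator is deterministic under (seed, params) and constructs its
# planted counts exactly (memberships are allocated first, random identities
# and field values second), so the downstream pipeline recovers the truth
# record exactly, not approximately.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards; every generator in the package draws through this, so
#' regeneration under the same `(seed, params)` is bit-identical.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

.default_herbs <- function() {
  data.frame(
    herb_latin = c("Radix Scrophulariae", "Bulbus Fritillariae ferganensis",
                   "Concha Ostreae"),
    herb_pinyin = c("XuanShen", "ZheBeiMu", "ShengMuLi"),
    source = c("TCMSP", "TCMSP", "BATMAN"),
    stringsAsFactors = FALSE)
}

# draws inside / outside the passing region of each screening field
.draw_pass_tcmsp <- function(n, th) {
  data.frame(OB = stats::runif(n, th$ob_min, 100),
             caco2 = stats::runif(n, th$caco2_min, 2),
             DL = stats::runif(n, th$dl_min, 1))
}
.draw_pass_batman <- function(n, th) {
  data.frame(score = stats::runif(n, th$score_min, 60),
             adj_p = stats::runif(n, 0, th$adj_p_max))
}

#' Generate per-herb ingredient tables with planted screen outcomes
#'
#' TCMSP rows draw OB ~ U(0, 100), Caco-2 ~ U(-1, 2), DL ~ U(0, 1); BATMAN
#' rows draw score ~ U(0, 60), adjusted P ~ U(0, 0.2). Planted passers have
#' their fields re-drawn from the passing region; every non-passer is forced
#' to fail at least one randomly chosen criterion. `shared_pass_herbs`
#' optionally plants one passing compound under the same name in two herbs,
#' so cross-herb deduplication is exercised.
#'
#' @param per_herb_counts Integer vector, rows per herb (default
#'   `c(47, 17, 10)`).
#' @param pass_counts Integer vector, planted passers per herb (default
#'   `c(3, 2, 5)`).
#' @param herbs Data frame `herb_latin, herb_pinyin, source`; default three
#'   herbs, the first two TCMSP-screened and the third BATMAN-screened.
#' @param shared_pass_herbs Length-2 integer vector of herb indices sharing
#'   one planted passer name, or `NULL` for none. Default `c(1, 2)`.
#' @param thresholds A [pk_thresholds()] list defining the passing regions.
#' @param seed Integer seed.
#' @return A list with `tables` (list of per-herb ingredient data frames)
#'   and `truth` (`planted_pass_names` per herb, expected candidate count
#'   `n_candidates`, seed).
#' @export
gen_ingredients <- function(per_herb_counts = c(47L, 17L, 10L),
                            pass_counts = c(3L, 2L, 5L),
                            herbs = .default_herbs(),
                            shared_pass_herbs = c(1L, 2L),
                            thresholds = pk_thresholds(),
                            seed = 1L) {
  stopifnot(length(per_herb_counts) == nrow(herbs),
            length(pass_counts) == nrow(herbs))
  if (any(pass_counts > per_herb_counts) || any(per_herb_counts < 0)) {
    stop("infeasible counts: pass_counts must not exceed per_herb_counts")
  }
  if (!is.null(shared_pass_herbs)) {
    stopifnot(length(shared_pass_herbs) == 2L)
    if (any(pass_counts[shared_pass_herbs] < 1L)) {
      stop("infeasible shared passer: both herbs need pass_counts >= 1")
    }
  }
  th <- thresholds
  with_seed(seed, {
    id0 <- 0L
    tables <- vector("list", nrow(herbs))
    pass_names <- vector("list", nrow(herbs))
    for (h in seq_len(nrow(herbs))) {
      nh <- per_herb_counts[h]
      np <- pass_counts[h]
      nm <- sprintf("cmpd_h%d_%03d", h, seq_len(nh))
      ids <- sprintf("ID%05d", id0 + seq_len(nh))
      id0 <- id0 + nh
      is_pass <- seq_len(nh) <= np       # planted rows first, shuffled below
      df <- data.frame(herb_latin = herbs$herb_latin[h],
                       herb_pinyin = herbs$herb_pinyin[h],
                       name = nm, compound_id = ids,
                       formula = "C6H12O6",
                       source_rule = herbs$source[h],
                       stringsAsFactors = FALSE)
      if (herbs$source[h] == "TCMSP") {
        df$OB <- stats::runif(nh, 0, 100)
        df$caco2 <- stats::runif(nh, -1, 2)
        df$DL <- stats::runif(nh, 0, 1)
        if (np > 0L) df[is_pass, c("OB", "caco2", "DL")] <-
            .draw_pass_tcmsp(np, th)
        for (i in which(!is_pass)) {
          fld <- sample(c("OB", "caco2", "DL"), 1L)
          df[i, fld] <- switch(fld,
            OB = stats::runif(1, 0, th$ob_min * 0.999),
            caco2 = stats::runif(1, -1, th$caco2_min * 0.999),
            DL = stats::runif(1, 0, th$dl_min * 0.999))
        }
      } else {
        df$score <- stats::runif(nh, 0, 60)
        df$adj_p <- stats::runif(nh, 0, 0.2)
        if (np > 0L) df[is_pass, c("score", "adj_p")] <-
            .draw_pass_batman(np, th)
        for (i in which(!is_pass)) {
          fld <- sample(c("score", "adj_p"), 1L)
          df[i, fld] <- switch(fld,
            score = stats::runif(1, 0, th$score_min * 0.999),
            adj_p = stats::runif(1, th$adj_p_max, 0.2))
        }
      }
      perm <- sample.int(nh)
      df <- df[perm, , drop = FALSE]
      rownames(df) <- NULL
      tables[[h]] <- df
      pass_names[[h]] <- df$name[df$name %in% nm[is_pass]]
    }
    if (!is.null(shared_pass_herbs)) {
      a <- shared_pass_herbs[1]; b <- shared_pass_herbs[2]
      shared <- sprintf("shared_cmpd_%d_%d", a, b)
      for (h in c(a, b)) {
        old <- pass_names[[h]][1]
        tables[[h]]$name[tables[[h]]$name == old] <- shared
        pass_names[[h]][1] <- shared
      }
    }
    names(tables) <- herbs$herb_latin
    names(pass_names) <- herbs$herb_latin
    list(tables = tables,
         truth = list(seed = seed,
                      planted_pass_names = pass_names,
                      n_candidates = length(unique(unlist(pass_names)))))
  })
}

#' Generate ingredient-to-target maps with exact per-herb and union sizes
#'
#' Constructive allocation: a union set of `union_size` symbols is drawn
#' from the universe; every union gene is first assigned one owning herb
#' (quota-respecting, so coverage is exact), then each herb's set is topped
#' up to its exact size with other union genes. Within a herb, every target
#' is attached to at least one of the herb's candidate ingredients and every
#' ingredient receives at least one target when feasible.
#'
#' @param candidates Candidate data frame from [select_candidates()] (needs
#'   `name` and `herbs` columns).
#' @param universe_size Size of the symbol universe targets are drawn from.
#' @param per_herb_target_counts Integer vector, unique targets per herb
#'   (default `c(58, 46, 27)`).
#' @param union_size Exact size of the across-herb union (default 71).
#' @param herb_order Character vector of herb Latin names, aligned with
#'   `per_herb_target_counts`; defaults to the order of appearance in
#'   `candidates$herbs`.
#' @param seed Integer seed.
#' @return A list with `map` (data frame `herb_latin, ingredient,
#'   raw_target`) and `truth` (union symbols, per-herb symbol sets, seed).
#' @export
gen_target_maps <- function(candidates, universe_size = 500L,
                            per_herb_target_counts = c(58L, 46L, 27L),
                            union_size = 71L, herb_order = NULL, seed = 1L) {
  q <- as.integer(per_herb_target_counts)
  if (union_size > sum(q) || union_size < max(q) || union_size > universe_size) {
    stop("infeasible sizes: need max(counts) <= union_size <= sum(counts) <= universe")
  }
  herb_lists <- strsplit(candidates$herbs, ";", fixed = TRUE)
  if (is.null(herb_order)) herb_order <- unique(unlist(herb_lists))
  stopifnot(length(herb_order) == length(q))
  with_seed(seed, {
    pool <- sprintf("T%04d", seq_len(universe_size))
    U <- sample(pool, union_size)
    # base allotment b: sum(b) == union_size, b <= q, every gene owned once
    b <- pmin(q, floor(q * union_size / sum(q)))
    while (sum(b) < union_size) {
      i <- which(b < q)[which.max(q[which(b < q)] - b[which(b < q)])]
      b[i] <- b[i] + 1L
    }
    owner <- rep(seq_along(q), times = b)
    sets <- lapply(seq_along(q), function(h) {
      owned <- U[owner == h]
      extra <- sample(setdiff(U, owned), q[h] - length(owned))
      sample(c(owned, extra))
    })
    names(sets) <- herb_order
    map <- do.call(rbind, lapply(seq_along(q), function(h) {
      ings <- candidates$name[vapply(herb_lists, function(hl)
        herb_order[h] %in% hl, logical(1))]
      if (length(ings) == 0L) {
        stop(sprintf("herb '%s' has no candidate ingredient", herb_order[h]))
      }
      tg <- sets[[h]]
      asg <- sample(ings, length(tg), replace = TRUE)
      # ensure every ingredient of the herb carries >= 1 target
      missing <- setdiff(ings, unique(asg))
      if (length(missing) > 0L && length(tg) >= length(ings)) {
        asg[sample.int(length(tg), length(missing))] <- missing
      }
      data.frame(herb_latin = herb_order[h], ingredient = asg,
                 raw_target = tg, stringsAsFactors = FALSE)
    }))
    rownames(map) <- NULL
    list(map = map,
         truth = list(seed = seed, union_targets = sort(U),
                      union_size = union_size,
                      per_herb_targets = lapply(sets, sort)))
  })
}

#' Generate two disease-target source lists with exact planted overlaps
#'
#' Builds sources A and B with exact sizes and pairwise overlap, and an
#' exact overlap between the drug-target set and the integrated disease
#' union: `drug_overlap` genes are drawn from `drug_set`, the remainder of
#' the union is fresh symbols disjoint from `drug_set`.
#'
#' @param drug_set A [gene_set()] or character vector of drug-target
#'   symbols.
#' @param size_a,size_b Source sizes (defaults 245 and 93).
#' @param ab_overlap Size of the A-B intersection (default 17, so the union
#'   is 321 under the defaults).
#' @param drug_overlap Exact size of the drug-vs-disease overlap (default
#'   29).
#' @param seed Integer seed.
#' @return A list with `source_a`, `source_b` (character vectors) and
#'   `truth` (all planted sizes, the union size and planted overlap
#'   symbols).
#' @export
gen_disease_lists <- function(drug_set, size_a = 245L, size_b = 93L,
                              ab_overlap = 17L, drug_overlap = 29L,
                              seed = 1L) {
  dg <- if (inherits(drug_set, "gene_set")) drug_set$genes
        else unique(toupper(as.character(drug_set)))
  union_size <- size_a + size_b - ab_overlap
  if (ab_overlap > min(size_a, size_b) || ab_overlap < 0) {
    stop("infeasible ab_overlap")
  }
  if (drug_overlap > min(length(dg), union_size)) {
    stop("infeasible drug_overlap: exceeds drug set or disease union size")
  }
  with_seed(seed, {
    in_drug <- sample(dg, drug_overlap)
    fresh <- setdiff(sprintf("D%04d", seq_len(union_size + length(dg))), dg)
    union_genes <- sample(c(in_drug, fresh[seq_len(union_size - drug_overlap)]))
    ab <- sample(union_genes, ab_overlap)
    rest <- setdiff(union_genes, ab)
    a_only <- sample(rest, size_a - ab_overlap)
    b_only <- setdiff(rest, a_only)
    stopifnot(length(b_only) == size_b - ab_overlap)
    list(source_a = sample(c(ab, a_only)),
         source_b = sample(c(ab, b_only)),
         truth = list(seed = seed, size_a = size_a, size_b = size_b,
                      ab_overlap = ab_overlap, union_size = union_size,
                      drug_overlap = drug_overlap,
                      drug_overlap_genes = sort(in_drug)))
  })
}

#' Generate a scored random interaction edge table
#'
#' `gnm` draws exactly `m` distinct non-self edges uniformly among the node
#' pairs; `planted_module` additionally wires a chosen node subset into a
#' clique whose edges score above the confidence cut (so the module survives
#' thresholding), then adds `m` random extra edges. Scores are drawn from
#' `score_range` (clique edges from `[max(0.4, lo), hi]`).
#'
#' @param node_set Character vector (or [gene_set()]) of node labels.
#' @param model `"gnm"` or `"planted_module"`.
#' @param m Number of random edges (default 86).
#' @param module_nodes For `planted_module`: node labels to wire densely;
#'   default the first 5 nodes.
#' @param score_range Combined-score range, default `c(0.15, 0.999)`.
#' @param score_threshold Confidence cut used for the connectivity truth
#'   (default 0.4).
#' @param seed Integer seed.
#' @return A list with `edges` (data frame `node1, node2, combined_score`)
#'   and `truth` (node/edge counts, the connected-node set at the
#'   threshold, module nodes if planted).
#' @export
gen_ppi <- function(node_set, model = c("gnm", "planted_module"), m = 86L,
                    module_nodes = NULL, score_range = c(0.15, 0.999),
                    score_threshold = 0.4, seed = 1L) {
  model <- match.arg(model)
  nodes <- if (inherits(node_set, "gene_set")) node_set$genes
           else as.character(node_set)
  n <- length(nodes)
  npairs <- choose(n, 2L)
  if (m > npairs) stop("infeasible m: more edges than node pairs")
  with_seed(seed, {
    pair_of <- function(idx) {
      # unrank the idx-th unordered pair (1-based, row-major upper triangle)
      i <- findInterval(idx - 1L, cumsum(c(0, (n - 1L):1L)),
                        rightmost.closed = FALSE)
      j <- idx - c(0, cumsum((n - 1L):1L))[i] + i
      cbind(nodes[i], nodes[j + 0L])
    }
    clique <- NULL
    if (model == "planted_module") {
      if (is.null(module_nodes)) module_nodes <- nodes[seq_len(min(5L, n))]
      stopifnot(all(module_nodes %in% nodes))
      cmb <- utils::combn(sort(module_nodes), 2L)
      clique <- data.frame(node1 = cmb[1L, ], node2 = cmb[2L, ],
                           combined_score = stats::runif(
                             ncol(cmb), max(score_threshold, score_range[1]),
                             score_range[2]),
                           stringsAsFactors = FALSE)
    }
    idx <- sample.int(npairs, m)
    pr <- pair_of(idx)
    edges <- data.frame(node1 = pr[, 1L], node2 = pr[, 2L],
                        combined_score = stats::runif(m, score_range[1],
                                                      score_range[2]),
                        stringsAsFactors = FALSE)
    if (!is.null(clique)) edges <- rbind(clique, edges)
    g <- build_graph(edges, score_threshold = score_threshold,
                     node_universe = nodes)
    connected <- sort(unique(c(g$edges$node1, g$edges$node2)))
    list(edges = edges,
         truth = list(seed = seed, n_nodes = n, n_random_edges = m,
                      module_nodes = if (is.null(clique)) NULL
                                     else sort(module_nodes),
                      score_threshold = score_threshold,
                      connected_nodes = connected))
  })
}

#' Generate a GMT annotation table with planted enriched terms
#'
#' Decoy terms sample members uniformly from the universe; planted terms
#' oversample the query genes with sampling weight `enrichment_factor`
#' (factor 1 means no planting: a null table). The truth records the
#' expected overlap `K * f*q / (f*q + (N - q))` for each planted term.
#'
#' @param universe Character vector of background genes.
#' @param n_terms Number of decoy terms (default 19).
#' @param term_size_range Length-2 integer range of term sizes (default
#'   `c(5, 50)`).
#' @param n_planted Number of planted enriched terms (default 1; forced to 0
#'   when `enrichment_factor == 1`).
#' @param enrichment_factor Oversampling weight for query members (>= 1).
#' @param query Character vector (or [gene_set()]) of query genes, required
#'   when planting.
#' @param namespace Namespace for the resulting table.
#' @param seed Integer seed.
#' @return A list with `annotations` (an [annotation_table()]) and `truth`
#'   (planted term names, factor, expected overlap per planted term).
#' @export
gen_annotations <- function(universe, n_terms = 19L,
                            term_size_range = c(5L, 50L), n_planted = 1L,
                            enrichment_factor = 1, query = NULL,
                            namespace = "PATHWAY", seed = 1L) {
  universe <- unique(toupper(as.character(universe)))
  N <- length(universe)
  if (max(term_size_range) > N) stop("term sizes exceed the universe")
  if (enrichment_factor < 1) stop("enrichment_factor must be >= 1")
  if (enrichment_factor == 1) n_planted <- 0L
  qg <- if (inherits(query, "gene_set")) query$genes
        else unique(toupper(as.character(query)))
  if (n_planted > 0L && length(intersect(qg, universe)) == 0L) {
    stop("planting requires query genes inside the universe")
  }
  with_seed(seed, {
    sizes <- sample(seq.int(term_size_range[1], term_size_range[2]),
                    n_terms + n_planted, replace = TRUE)
    w <- ifelse(universe %in% qg, enrichment_factor, 1)
    terms <- list()
    expected <- numeric(0)
    for (i in seq_len(n_planted)) {
      nm <- sprintf("planted_%02d", i)
      terms[[nm]] <- sample(universe, sizes[i], prob = w)
      q <- length(intersect(qg, universe))
      expected[nm] <- sizes[i] * enrichment_factor * q /
        (enrichment_factor * q + (N - q))
    }
    for (i in seq_len(n_terms)) {
      terms[[sprintf("decoy_%03d", i)]] <-
        sample(universe, sizes[n_planted + i])
    }
    list(annotations = annotation_table(terms, namespace),
         truth = list(seed = seed,
                      planted_terms = if (n_planted > 0L)
                        sprintf("planted_%02d", seq_len(n_planted))
                        else character(0),
                      enrichment_factor = enrichment_factor,
                      expected_overlap = expected))
  })
}

#' Write a complete synthetic input bundle to disk
#'
#' Generates every table the pipeline consumes, shaped by default like the
#' worked three-herb study (74 ingredients screening to 9 candidates; 131
#' raw targets collapsing to 71; disease sources 245 and 93 integrating to
#' 321 with a planted drug overlap of 29), and writes them together with a
#' machine-readable truth record and a ready-to-run pipeline config.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed driving every generator.
#' @param params Optional overrides: any of `per_herb_counts`,
#'   `pass_counts`, `per_herb_target_counts`, `union_size`, `size_a`,
#'   `size_b`, `ab_overlap`, `drug_overlap`, `ppi_m`,
#'   `enrichment_factor`, `n_decoy_terms`, `annotation_universe_size`.
#' @return The parsed truth record, invisibly; files written: per-herb
#'   ingredient TSVs, `target_map.tsv`, `gene_mapping.tsv`,
#'   `disease_source_a.txt`, `disease_source_b.txt`,
#'   `string_interactions.tsv`, one GMT per namespace, `truth.json`,
#'   `config.json`.
#' @export
gen_bundle <- function(dir, seed = 1L, params = list()) {
  p <- utils::modifyList(list(
    per_herb_counts = c(47L, 17L, 10L), pass_counts = c(3L, 2L, 5L),
    per_herb_target_counts = c(58L, 46L, 27L), union_size = 71L,
    size_a = 245L, size_b = 93L, ab_overlap = 17L, drug_overlap = 29L,
    ppi_m = 86L, enrichment_factor = 8, n_decoy_terms = 19L,
    annotation_universe_size = 300L), params)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  herbs <- .default_herbs()

  ing <- gen_ingredients(p$per_herb_counts, p$pass_counts, herbs = herbs,
                         seed = seed)
  ing_paths <- character(nrow(herbs))
  for (h in seq_len(nrow(herbs))) {
    ing_paths[h] <- file.path(dir, sprintf("ingredients_%s.tsv",
                                           tolower(herbs$herb_pinyin[h])))
    tb <- ing$tables[[h]]
    utils::write.table(tb[, setdiff(names(tb), "source_rule")], ing_paths[h],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cands <- select_candidates(ing$tables)

  tm <- gen_target_maps(cands, per_herb_target_counts = p$per_herb_target_counts,
                        union_size = p$union_size,
                        herb_order = herbs$herb_latin, seed = seed + 1L)
  utils::write.table(tm$map, file.path(dir, "target_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mapping <- data.frame(raw_name = tm$truth$union_targets,
                        symbol = tm$truth$union_targets,
                        stringsAsFactors = FALSE)
  utils::write.table(mapping, file.path(dir, "gene_mapping.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  drug <- gene_set(tm$truth$union_targets, label = "drug_targets")

  dis <- gen_disease_lists(drug, p$size_a, p$size_b, p$ab_overlap,
                           p$drug_overlap, seed = seed + 2L)
  writeLines(dis$source_a, file.path(dir, "disease_source_a.txt"))
  writeLines(dis$source_b, file.path(dir, "disease_source_b.txt"))

  overlap <- sort(dis$truth$drug_overlap_genes)
  ppi <- gen_ppi(overlap, "gnm", m = p$ppi_m, seed = seed + 3L)
  utils::write.table(ppi$edges, file.path(dir, "string_interactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ann_universe <- unique(c(overlap,
                           sprintf("U%04d", seq_len(p$annotation_universe_size))))
  gmt_paths <- list()
  ann_truth <- list()
  for (i in seq_along(.namespaces)) {
    ns <- .namespaces[i]
    ann <- gen_annotations(ann_universe, n_terms = p$n_decoy_terms,
                           n_planted = 1L,
                           enrichment_factor = p$enrichment_factor,
                           query = overlap, namespace = ns,
                           seed = seed + 10L + i)
    pth <- file.path(dir, sprintf("annotations_%s.gmt", tolower(ns)))
    write_gmt(ann$annotations, pth)
    gmt_paths[[ns]] <- pth
    ann_truth[[ns]] <- ann$truth
  }

  truth <- list(seed = seed,
                ingredients = ing$truth,
                targets = tm$truth,
                disease = dis$truth,
                ppi = ppi$truth,
                annotations = ann_truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  config <- list(
    ingredient_tables = lapply(seq_len(nrow(herbs)), function(h) {
      list(path = basename(ing_paths[h]), source = herbs$source[h])
    }),
    target_map = "target_map.tsv",
    gene_mapping = "gene_mapping.tsv",
    disease_a = "disease_source_a.txt",
    disease_b = "disease_source_b.txt",
    ppi_edges = "string_interactions.tsv",
    annotations = lapply(names(gmt_paths), function(ns) {
      list(path = basename(gmt_paths[[ns]]), namespace = ns)
    }),
    ob_min = 30, caco2_min = 0.4, dl_min = 0.18,
    score_min = 20, adj_p_max = 0.05,
    ppi_score_min = 0.4, drop_isolated = FALSE,
    fdr_cutoff = 0.05, top_n_pathways = 25L, top_n_go = 10L,
    seed = seed, out_dir = "results")
  jsonlite::write_json(config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(truth)
}
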