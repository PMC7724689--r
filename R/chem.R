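# Molecular formulas, masses, and pharmacokinetic candidate screening.

# Embedded atomic weight table. Average weights are the IUPAC 2005-era
# standard atomic weights; monoisotopic masses are principal-isotope masses.
# Immutable at run time: atomic_weights() hands out a copy.
.atomic_weights <- data.frame(
  element = c("H", "C", "N", "O", "Na", "Mg", "Al", "Si", "P", "S",
              "Cl", "K", "Ca", "Fe", "Zn"),
  average = c(1.00794, 12.0107, 14.0067, 15.9994, 22.98976928, 24.3050,
              26.9815386, 28.0855, 30.973762, 32.065,
              35.453, 39.0983, 40.078, 55.845, 65.409),
  monoisotopic = c(1.0078250319, 12, 14.0030740052, 15.9949146221,
                   22.9897692809, 23.9850417, 26.98153863, 27.9769265325,
                   30.97376151, 31.97207069,
                   34.96885271, 38.9637064864, 39.96259098, 55.9349375,
                   63.9291422),
  stringsAsFactors = FALSE
)

#' Embedded atomic weight table
#'
#' Average (abundance-weighted standard) and monoisotopic (principal isotope)
#' atomic masses for the elements the formula parser recognizes. The table is
#' embedded in the package and never fetched at run time.
#'
#' @return A data frame with columns `element`, `average`, `monoisotopic`
#'   (both in Da).
#' @export
#' @examples
#' atomic_weights()
atomic_weights <- function() {
  .atomic_weights
}

#' Parse a molecular formula into element counts
#'
#' Accepts Hill-style formulas (`"C29H50O"`) and the underscore subscript
#' markup used in some database exports (`"C_29_H_50_O"`); underscores are
#' stripped before parsing. An element symbol without a trailing integer has
#' an implicit count of 1.
#'
#' @param formula A single non-empty formula string.
#' @return A named integer vector mapping element symbol to count.
#' @export
#' @examples
#' parse_formula("CCaO_3_")    # C:1 Ca:1 O:3
#' parse_formula("C_29_H_50_O")
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula)) {
    stop("formula must be a single character string")
  }
  f <- gsub("_", "", trimws(formula), fixed = TRUE)
  if (!nzchar(f)) stop("empty formula string")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", f)[[1]]
  tokens <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1]]
  if (m[1] == -1L || paste(tokens, collapse = "") != f) {
    stop(sprintf("garbled formula: '%s'", formula))
  }
  syms <- sub("[0-9]*$", "", tokens)
  unknown <- setdiff(syms, .atomic_weights$element)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown element symbol '%s' in formula '%s'",
                 unknown[1], formula))
  }
  cnts <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", tokens)))
  cnts[is.na(cnts)] <- 1L
  if (any(cnts < 1L)) stop(sprintf("zero element count in formula '%s'", formula))
  out <- tapply(cnts, factor(syms, levels = unique(syms)), sum)
  stats::setNames(as.integer(out), names(out))
}

#' Molecular mass of an element-count multiset
#'
#' Sums `count * weight` over elements using either average atomic weights or
#' monoisotopic (principal-isotope) masses. Full double precision is
#' returned; use [formula_mass()] for the display-rounded value.
#'
#' @param counts Named integer vector as returned by [parse_formula()].
#' @param mode `"average"` or `"monoisotopic"`.
#' @param weights Weight table; defaults to the embedded [atomic_weights()].
#' @return Mass in Da (full precision).
#' @export
molecular_mass <- function(counts, mode = c("average", "monoisotopic"),
                           weights = atomic_weights()) {
  mode <- match.arg(mode)
  if (length(counts) == 0L) stop("empty element counts")
  idx <- match(names(counts), weights$element)
  if (anyNA(idx)) {
    stop(sprintf("element '%s' missing from weight table",
                 names(counts)[which(is.na(idx))[1]]))
  }
  sum(as.numeric(counts) * weights[[mode]][idx])
}

#' Round half-up
#'
#' Decimal rounding with ties away from zero (0.0005 -> 0.001), as used for
#' all displayed masses and percentages. Base `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Parse a formula and report its display mass
#'
#' Convenience wrapper: [parse_formula()] then [molecular_mass()], rounded
#' half-up to `digits` decimals for reporting.
#'
#' @inheritParams molecular_mass
#' @param formula Formula string.
#' @param digits Decimals for display rounding (default 3).
#' @return Rounded mass in Da.
#' @export
#' @examples
#' formula_mass("CCaO_3_")                     # 100.087
#' formula_mass("C_29_H_50_O", "monoisotopic") # 414.386
formula_mass <- function(formula, mode = c("average", "monoisotopic"),
                         digits = 3L, weights = atomic_weights()) {
  round_half_up(molecular_mass(parse_formula(formula), mode, weights), digits)
}

#' Pharmacokinetic screening thresholds
#'
#' Defaults are the standard ADME screen: oral bioavailability OB >= 30
#' (percent), Caco-2 permeability >= 0.4, drug-likeness DL >= 0.18 for
#' TCMSP-style rows; score >= 20 and adjusted P < 0.05 for BATMAN-style
#' rows. OB, Caco-2, DL and score cuts are inclusive; the adjusted-P cut is
#' strict, matching the conventional operators.
#'
#' @param ob_min,caco2_min,dl_min TCMSP-rule lower bounds (inclusive).
#' @param score_min BATMAN score lower bound (inclusive).
#' @param adj_p_max BATMAN adjusted-P upper bound (exclusive).
#' @return A named list of thresholds.
#' @export
pk_thresholds <- function(ob_min = 30, caco2_min = 0.4, dl_min = 0.18,
                          score_min = 20, adj_p_max = 0.05) {
  stopifnot(ob_min >= 0, ob_min <= 100, dl_min >= 0, dl_min <= 1,
            adj_p_max >= 0, adj_p_max <= 1)
  list(ob_min = ob_min, caco2_min = caco2_min, dl_min = dl_min,
       score_min = score_min, adj_p_max = adj_p_max)
}

#' Apply the pharmacokinetic candidate filter
#'
#' Row-wise screen of an ingredient table. Rows with `source_rule == "TCMSP"`
#' must carry non-missing `OB`, `caco2`, `DL`; rows with
#' `source_rule == "BATMAN"` must carry `score`, `adj_p`. A missing required
#' field is an error, never a silent pass or fail.
#'
#' @param ingredients Data frame with a `source_rule` column plus the fields
#'   its rule requires.
#' @param thresholds A [pk_thresholds()] list.
#' @return Logical vector, one element per row.
#' @export
passes_filter <- function(ingredients, thresholds = pk_thresholds()) {
  if (!is.data.frame(ingredients) || !"source_rule" %in% names(ingredients)) {
    stop("ingredients must be a data frame with a 'source_rule' column")
  }
  rule <- as.character(ingredients$source_rule)
  bad <- setdiff(unique(rule), c("TCMSP", "BATMAN"))
  if (length(bad) > 0L) stop(sprintf("unknown source_rule '%s'", bad[1]))
  need <- function(cols, rows, label) {
    for (cl in cols) {
      if (!cl %in% names(ingredients) || anyNA(ingredients[[cl]][rows])) {
        stop(sprintf("missing %s field '%s' required by the %s rule",
                     label, cl, label))
      }
    }
  }
  out <- logical(nrow(ingredients))
  tc <- rule == "TCMSP"
  if (any(tc)) {
    need(c("OB", "caco2", "DL"), tc, "TCMSP")
    if (any(ingredients$OB[tc] < 0 | ingredients$OB[tc] > 100)) {
      stop("OB outside [0, 100]")
    }
    out[tc] <- ingredients$OB[tc] >= thresholds$ob_min &
      ingredients$caco2[tc] >= thresholds$caco2_min &
      ingredients$DL[tc] >= thresholds$dl_min
  }
  bm <- rule == "BATMAN"
  if (any(bm)) {
    need(c("score", "adj_p"), bm, "BATMAN")
    if (any(ingredients$adj_p[bm] < 0 | ingredients$adj_p[bm] > 1)) {
      stop("adj_p outside [0, 1]")
    }
    out[bm] <- ingredients$score[bm] >= thresholds$score_min &
      ingredients$adj_p[bm] < thresholds$adj_p_max
  }
  out
}

# dedup key: case-folded, whitespace-stripped; Greek letters preserved so
# e.g. "Sitosterol" and "beta-sitosterol" variants stay distinct.
.name_key <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Deduplicate candidate ingredients across herbs
#'
#' Collapses rows sharing a normalized name (case-folded,
#' whitespace-stripped) into one candidate that carries the list of herbs
#' containing it. Ordering is deterministic: herb order as supplied, then
#' input row order; the first occurrence supplies the descriptive fields.
#'
#' @param rows Data frame of (already screened) ingredient rows with at
#'   least `herb_latin` and `name` columns.
#' @return Data frame with one row per unique name: `name`, `compound_id`,
#'   `formula` (when present in the input), `herbs` (";"-collapsed Latin
#'   names) and `n_herbs`.
#' @export
dedup_candidates <- function(rows) {
  if (nrow(rows) == 0L) {
    return(data.frame(name = character(0), herbs = character(0),
                      n_herbs = integer(0), stringsAsFactors = FALSE))
  }
  key <- .name_key(rows$name)
  first <- !duplicated(key)
  out <- rows[first, intersect(c("name", "compound_id", "formula"),
                               names(rows)), drop = FALSE]
  herb_by_key <- lapply(split(rows$herb_latin, factor(key, levels = key[first])),
                        unique)
  out$herbs <- vapply(herb_by_key, paste, character(1), collapse = ";")
  out$n_herbs <- vapply(herb_by_key, length, integer(1))
  rownames(out) <- NULL
  out
}

#' Screen per-herb ingredient tables and deduplicate candidates
#'
#' Applies [passes_filter()] to each herb table, then collapses identical
#' compounds appearing in several herbs with [dedup_candidates()], merging
#' provenance. With `prefiltered = TRUE` the screen is skipped and all rows
#' are treated as candidates (for tables that were already filtered
#' upstream).
#'
#' @param tables A list of per-herb ingredient data frames, each carrying
#'   `herb_latin`, `name` and, unless `prefiltered`, the fields its
#'   `source_rule` requires. List order defines the herb order.
#' @param thresholds A [pk_thresholds()] list.
#' @param prefiltered Skip the pharmacokinetic screen.
#' @return Candidate data frame as from [dedup_candidates()].
#' @export
select_candidates <- function(tables, thresholds = pk_thresholds(),
                              prefiltered = FALSE) {
  stopifnot(is.list(tables))
  kept <- lapply(tables, function(tb) {
    if (prefiltered) tb else tb[passes_filter(tb, thresholds), , drop = FALSE]
  })
  common <- Reduce(intersect, lapply(kept, names))
  all_rows <- do.call(rbind, lapply(kept, function(tb) tb[, common, drop = FALSE]))
  dedup_candidates(all_rows)
}

#' Read a TCMSP- or BATMAN-style ingredient table
#'
#' Tab-separated, UTF-8, header required. TCMSP dialect columns:
#' `herb_latin, herb_pinyin, name, compound_id, formula, OB, caco2, DL`;
#' BATMAN dialect replaces the last three with `score, adj_p`. A
#' `source_rule` column is added from `source`.
#'
#' @param path File path.
#' @param source `"TCMSP"` or `"BATMAN"`.
#' @return Ingredient data frame.
#' @export
read_ingredients <- function(path, source = c("TCMSP", "BATMAN")) {
  source <- match.arg(source)
  df <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          check.names = TRUE)
  need <- c("herb_latin", "herb_pinyin", "name", "compound_id",
            if (source == "TCMSP") c("OB", "caco2", "DL") else c("score", "adj_p"))
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing column(s) %s in '%s'", source,
                 paste(missing, collapse = ", "), path))
  }
  df$source_rule <- source
  df
}
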