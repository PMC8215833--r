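# Level-wise Apriori over encoded records with weighted support/confidence.
#
# An item is a (feature, level) pair; the class label is an item on the
# pseudo-feature "class". Weighted support of an itemset Z is
#   wsup(Z) = sup(Z) * mean W(t) over Z's non-class items,
# with class-only itemsets given weight 1, so for class-consequent rules the
# weight factor cancels in Eq-style confidence ratios and confidence stays
# in [0, 1]. Raw support is anti-monotone and bounds wsup from above
# (all W(t) <= 1), so downward-closure pruning uses raw support against the
# weighted threshold and the weighted threshold itself is a post-filter.

#' Mining configuration
#'
#' @param min_wsupport minimum weighted support for an itemset to be kept.
#' @param min_confidence minimum weighted confidence for a rule to be kept.
#' @param max_antecedent maximum number of antecedent items.
#' @param top_k number of rules reported by ranking / the CLI.
#' @param mode `"significant"` (mine over the 8 significant features) or
#'   `"all_features"` (all 13).
#' @return a validated `mining_config` list.
#' @export
mining_config <- function(min_wsupport = 0.005, min_confidence = 0.9,
                          max_antecedent = 6, top_k = 20,
                          mode = c("significant", "all_features")) {
  mode <- match.arg(mode)
  stopifnot(min_wsupport >= 0, min_wsupport <= 1,
            min_confidence >= 0, min_confidence <= 1,
            max_antecedent >= 1, top_k >= 1)
  structure(list(min_wsupport = min_wsupport,
                 min_confidence = min_confidence,
                 max_antecedent = as.integer(max_antecedent),
                 top_k = as.integer(top_k), mode = mode),
            class = "mining_config")
}

match_items <- function(items, dataset) {
  if (length(items) == 0L) return(rep(TRUE, nrow(dataset)))
  unknown <- setdiff(names(items), names(dataset))
  if (length(unknown)) {
    hd_stop("itemset mentions feature(s) absent from dataset: ",
            paste(unknown, collapse = ", "), class = "hdwarm_schema_error")
  }
  hit <- rep(TRUE, nrow(dataset))
  for (f in names(items)) hit <- hit & (dataset[[f]] == items[[f]])
  hit
}

#' Raw support of an itemset
#'
#' Fraction of records containing every item of the set (the class item, if
#' present, must equal the record's class). The empty itemset has support 1.
#'
#' @param items named character vector of (feature = level) items; the class
#'   item uses the name `class`.
#' @param dataset encoded dataset.
#' @return proportion in \[0, 1\].
#' @export
support <- function(items, dataset) {
  if (nrow(dataset) == 0L) {
    hd_stop("empty dataset", class = "hdwarm_domain_error")
  }
  sum(match_items(items, dataset)) / nrow(dataset)
}

#' Aggregate item weight of an itemset
#'
#' Arithmetic mean of W(t) over the non-class items; itemsets containing
#' only class items (or nothing) have weight 1 by convention so weighted
#' and raw support coincide for them.
#'
#' @param items named character vector of items.
#' @param weights a `warm_weights` table covering every non-class item.
#' @return weight in \[0, 1\].
#' @export
itemset_weight <- function(items, weights) {
  plain <- items[names(items) != CLASS_COLUMN]
  if (length(plain) == 0L) return(1)
  mean(vapply(seq_along(plain), function(i) {
    item_weight(weights, names(plain)[i], plain[[i]])
  }, numeric(1)))
}

#' Weighted support
#'
#' `support(items, dataset) * itemset_weight(items, weights)`.
#'
#' @inheritParams itemset_weight
#' @param dataset encoded dataset.
#' @return proportion in \[0, 1\].
#' @export
weighted_support <- function(items, dataset, weights) {
  support(items, dataset) * itemset_weight(items, weights)
}

#' Weighted confidence of a class rule
#'
#' Ratio of the weighted support of antecedent-plus-consequent to the
#' weighted support of the antecedent. For class consequents the aggregate
#' weight factor is identical in numerator and denominator, so the value
#' equals the raw confidence and lies in \[0, 1\].
#'
#' @param antecedent named character vector of non-class items.
#' @param consequent class label (or a named `class = label` item).
#' @inheritParams weighted_support
#' @return proportion in \[0, 1\], or `NA_real_` when the antecedent has
#'   zero weighted support (undefined rule; batch mining skips it).
#' @export
#' @examples
#' # a rule whose antecedent and antecedent-plus-class weighted supports
#' # are equal has confidence 1
weighted_confidence <- function(antecedent, consequent, dataset, weights) {
  if (CLASS_COLUMN %in% names(antecedent)) {
    hd_stop("antecedent must not contain the class item",
            class = "hdwarm_domain_error")
  }
  if (!is.null(names(consequent)) && length(consequent) == 1L &&
      identical(names(consequent), CLASS_COLUMN)) {
    consequent <- unname(consequent)
  }
  if (!consequent %in% CLASS_LEVELS) {
    hd_stop("consequent must be one of: ",
            paste(CLASS_LEVELS, collapse = " / "),
            class = "hdwarm_domain_error")
  }
  denom <- weighted_support(antecedent, dataset, weights)
  if (denom <= 0) return(NA_real_)
  both <- c(antecedent, setNames(consequent, CLASS_COLUMN))
  weighted_support(both, dataset, weights) / denom
}

#' Mine frequent itemsets (level-wise Apriori)
#'
#' Enumerates itemsets of at most `max_antecedent` non-class items plus at
#' most one class item whose weighted support reaches
#' `config$min_wsupport`. Candidates are generated level-wise; pruning uses
#' raw support (anti-monotone upper bound on weighted support) against the
#' weighted threshold, and the weighted threshold is applied as a
#' post-filter at each level. Fully deterministic: items and output are in
#' canonical lexicographic order.
#'
#' @param dataset encoded dataset.
#' @param weights `warm_weights` covering the dataset's features.
#' @param config a [mining_config()].
#' @return data.frame with columns `items` (canonical string), `size`,
#'   `support_count`, `support`, `wsupport`, sorted by (size, items).
#' @export
mine_frequent_itemsets <- function(dataset, weights, config = mining_config()) {
  if (nrow(dataset) == 0L) {
    hd_stop("empty dataset", class = "hdwarm_domain_error")
  }
  n <- nrow(dataset)
  theta <- config$min_wsupport
  feats <- intersect(names(dataset), unique(weights$items$feature))
  feats <- feats[feats != CLASS_COLUMN]

  # item universe: observed (feature, level) pairs plus class items
  univ <- list()
  for (f in feats) {
    for (l in sort(unique(dataset[[f]]), method = "radix")) {
      univ[[length(univ) + 1L]] <- list(feature = f, level = l)
    }
  }
  if (CLASS_COLUMN %in% names(dataset)) {
    for (l in sort(unique(dataset[[CLASS_COLUMN]]), method = "radix")) {
      univ[[length(univ) + 1L]] <- list(feature = CLASS_COLUMN, level = l)
    }
  }
  if (length(univ) == 0L) {
    return(data.frame(items = character(0), size = integer(0),
                      support_count = integer(0), support = numeric(0),
                      wsupport = numeric(0)))
  }
  key <- vapply(univ, function(it) paste0(it$feature, "=", it$level),
                character(1))
  ord <- order(vapply(univ, `[[`, character(1), "feature"),
               vapply(univ, `[[`, character(1), "level"), method = "radix")
  univ <- univ[ord]; key <- key[ord]
  item_feat <- vapply(univ, `[[`, character(1), "feature")
  item_wt <- vapply(seq_along(univ), function(i) {
    if (item_feat[i] == CLASS_COLUMN) NA_real_
    else item_weight(weights, univ[[i]]$feature, univ[[i]]$level)
  }, numeric(1))
  item_match <- lapply(univ, function(it) dataset[[it$feature]] == it$level)
  item_count <- vapply(item_match, sum, numeric(1))

  # a node is an integer vector of item indices (strictly increasing)
  results <- list()
  keep_level <- function(nodes, counts) {
    for (i in seq_along(nodes)) {
      idx <- nodes[[i]]
      plain <- idx[item_feat[idx] != CLASS_COLUMN]
      w <- if (length(plain)) mean(item_wt[plain]) else 1
      ws <- (counts[i] / n) * w
      if (ws >= theta) {
        results[[length(results) + 1L]] <<- list(
          idx = idx, count = counts[i], wsupport = ws)
      }
    }
  }

  frontier_idx <- which(item_count / n >= theta)
  nodes <- lapply(frontier_idx, identity)
  node_match <- item_match[frontier_idx]
  node_count <- item_count[frontier_idx]
  keep_level(nodes, node_count)
  frequent_keys <- new.env(parent = emptyenv())
  for (i in frontier_idx) assign(as.character(i), TRUE, frequent_keys)
  node_key <- function(idx) paste(idx, collapse = ".")
  for (i in seq_along(nodes)) assign(node_key(nodes[[i]]), TRUE, frequent_keys)

  max_plain <- config$max_antecedent
  repeat {
    if (length(nodes) == 0L) break
    new_nodes <- list(); new_match <- list(); new_count <- numeric(0)
    for (i in seq_along(nodes)) {
      idx <- nodes[[i]]
      n_plain <- sum(item_feat[idx] != CLASS_COLUMN)
      has_class <- any(item_feat[idx] == CLASS_COLUMN)
      last <- idx[length(idx)]
      if (last >= length(univ)) next
      for (j in (last + 1L):length(univ)) {
        if (item_feat[j] %in% item_feat[idx]) next
        j_class <- item_feat[j] == CLASS_COLUMN
        if (j_class && has_class) next
        if (!j_class && n_plain + 1L > max_plain) next
        if (j_class && n_plain > max_plain) next
        cand <- c(idx, j)
        # downward closure on raw support: every (k-1)-subset frequent
        ok <- TRUE
        if (length(cand) > 2L) {
          for (d in seq_along(cand)) {
            sub <- cand[-d]
            if (!exists(node_key(sub), frequent_keys, inherits = FALSE)) {
              ok <- FALSE; break
            }
          }
        }
        if (!ok) next
        m <- node_match[[i]] & item_match[[j]]
        cnt <- sum(m)
        if (cnt / n < theta) next
        new_nodes[[length(new_nodes) + 1L]] <- cand
        new_match[[length(new_match) + 1L]] <- m
        new_count <- c(new_count, cnt)
      }
    }
    if (length(new_nodes) == 0L) break
    for (nd in new_nodes) assign(node_key(nd), TRUE, frequent_keys)
    keep_level(new_nodes, new_count)
    nodes <- new_nodes; node_match <- new_match; node_count <- new_count
  }

  if (length(results) == 0L) {
    return(data.frame(items = character(0), size = integer(0),
                      support_count = integer(0), support = numeric(0),
                      wsupport = numeric(0)))
  }
  items_str <- vapply(results, function(r) {
    format_items(setNames(
      vapply(univ[r$idx], `[[`, character(1), "level"),
      item_feat[r$idx]))
  }, character(1))
  out <- data.frame(
    items = items_str,
    size = vapply(results, function(r) length(r$idx), integer(1)),
    support_count = vapply(results, function(r) as.integer(r$count),
                           integer(1)),
    support = vapply(results, function(r) r$count / n, numeric(1)),
    wsupport = vapply(results, function(r) r$wsupport, numeric(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$size, out$items, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate class-association rules from frequent itemsets
#'
#' For every frequent itemset holding exactly one class item and a
#' non-empty antecedent, emits the rule antecedent -> class with weighted
#' confidence, keeping rules whose confidence reaches
#' `config$min_confidence`. Antecedents with zero weighted support are
#' skipped (undefined confidence). Deterministic, duplicate-free.
#'
#' @param itemsets output of [mine_frequent_itemsets()].
#' @inheritParams mine_frequent_itemsets
#' @return a `warm_rules` data.frame with columns antecedent, consequent,
#'   support (of antecedent + consequent), wsupport_antecedent,
#'   wsupport_rule, confidence.
#' @export
generate_class_rules <- function(itemsets, dataset, weights,
                                 config = mining_config()) {
  rows <- list()
  for (i in seq_len(nrow(itemsets))) {
    items <- parse_items(itemsets$items[i])
    if (!CLASS_COLUMN %in% names(items)) next
    antecedent <- items[names(items) != CLASS_COLUMN]
    if (length(antecedent) == 0L) next
    ws_a <- weighted_support(antecedent, dataset, weights)
    if (ws_a <= 0) next
    conf <- itemsets$wsupport[i] / ws_a
    if (conf < config$min_confidence) next
    rows[[length(rows) + 1L]] <- data.frame(
      antecedent = format_items(antecedent),
      consequent = unname(items[[CLASS_COLUMN]]),
      support = itemsets$support[i],
      wsupport_antecedent = ws_a,
      wsupport_rule = itemsets$wsupport[i],
      confidence = conf,
      stringsAsFactors = FALSE
    )
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(setNames(list(character(0), character(0), numeric(0),
                                numeric(0), numeric(0), numeric(0)),
                           RULE_COLUMNS))
  new_warm_rules(df)
}

#' Mine class rules end to end
#'
#' Convenience wrapper: [mine_frequent_itemsets()] then
#' [generate_class_rules()].
#'
#' @inheritParams mine_frequent_itemsets
#' @return a `warm_rules` data.frame (unranked; see [rank_rules()]).
#' @export
mine_class_rules <- function(dataset, weights, config = mining_config()) {
  generate_class_rules(mine_frequent_itemsets(dataset, weights, config),
                       dataset, weights, config)
}
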