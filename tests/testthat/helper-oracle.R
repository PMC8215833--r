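# Brute-force mining oracle: exhaustive powerset enumeration with its own
# support counting and weighting, independent of the package's miner.

oracle_support_count <- function(items, dataset) {
  hits <- 0L
  for (r in seq_len(nrow(dataset))) {
    ok <- TRUE
    for (f in names(items)) {
      if (dataset[[f]][r] != items[[f]]) { ok <- FALSE; break }
    }
    if (ok) hits <- hits + 1L
  }
  hits
}

oracle_item_weight <- function(items, weights) {
  plain <- items[names(items) != "class"]
  if (length(plain) == 0L) return(1)
  w <- numeric(0)
  for (i in seq_along(plain)) {
    row <- weights$items[weights$items$feature == names(plain)[i] &
                           weights$items$level == plain[[i]], ]
    w <- c(w, row$w_t)
  }
  mean(w)
}

oracle_itemsets_key <- function(items) {
  items <- items[order(names(items))]
  paste0(names(items), "=", unname(items), collapse = ",")
}

# Enumerate every itemset (<= 1 item per feature, <= 1 class item, at most
# max_antecedent non-class items) and keep those with weighted support >=
# the threshold: one grid cell per assignment of "absent or a level" to
# each feature plus "absent or a class label". Returns a data.frame keyed
# like the package output.
oracle_mine <- function(dataset, weights, config) {
  n <- nrow(dataset)
  feats <- setdiff(names(dataset), "class")
  choices <- lapply(feats, function(f) c(NA_character_,
                                         unique(dataset[[f]])))
  choices <- c(choices, list(c(NA_character_, unique(dataset$class))))
  names(choices) <- c(feats, "class")
  grid <- expand.grid(choices, stringsAsFactors = FALSE)
  out <- list()
  for (g in seq_len(nrow(grid))) {
    row <- unlist(grid[g, , drop = FALSE])
    items <- row[!is.na(row)]
    if (length(items) == 0L) next
    n_plain <- sum(names(items) != "class")
    if (n_plain > config$max_antecedent) next
    cnt <- oracle_support_count(items, dataset)
    ws <- (cnt / n) * oracle_item_weight(items, weights)
    if (ws < config$min_wsupport) next
    out[[length(out) + 1L]] <- data.frame(
      items = oracle_itemsets_key(items), size = length(items),
      support_count = cnt, support = cnt / n, wsupport = ws,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(items = character(0), size = integer(0),
                      support_count = integer(0), support = numeric(0),
                      wsupport = numeric(0)))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$size, df$items, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Exhaustive class-rule enumeration from the oracle itemsets.
oracle_rules <- function(dataset, weights, config) {
  sets <- oracle_mine(dataset, weights, config)
  n <- nrow(dataset)
  out <- list()
  for (i in seq_len(nrow(sets))) {
    parts <- strsplit(sets$items[i], ",", fixed = TRUE)[[1]]
    kv <- strsplit(parts, "=", fixed = TRUE)
    items <- stats::setNames(vapply(kv, `[[`, character(1), 2),
                             vapply(kv, `[[`, character(1), 1))
    if (!"class" %in% names(items)) next
    ante <- items[names(items) != "class"]
    if (length(ante) == 0L) next
    ws_a <- (oracle_support_count(ante, dataset) / n) *
      oracle_item_weight(ante, weights)
    if (ws_a <= 0) next
    conf <- sets$wsupport[i] / ws_a
    if (conf < config$min_confidence) next
    out[[length(out) + 1L]] <- data.frame(
      antecedent = oracle_itemsets_key(ante),
      consequent = unname(items[["class"]]),
      support = sets$support[i],
      wsupport_antecedent = ws_a,
      wsupport_rule = sets$wsupport[i],
      confidence = conf, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(antecedent = character(0), consequent = character(0),
                      support = numeric(0), wsupport_antecedent = numeric(0),
                      wsupport_rule = numeric(0), confidence = numeric(0)))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$antecedent, df$consequent, method = "radix"), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}
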