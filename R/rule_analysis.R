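# Ranking, sick/healthy partition, feature-frequency summaries, reports.

#' Rank rules and keep the top k
#'
#' Total order: confidence (descending), then raw support (descending),
#' then antecedent size (ascending), then antecedent string
#' (lexicographic). The chain is a total order, so ranking is invariant to
#' the input order.
#'
#' @param rules a `warm_rules` data.frame.
#' @param k how many rules to keep (default: all).
#' @return the top `k` rules, ranked.
#' @export
rank_rules <- function(rules, k = nrow(rules)) {
  stopifnot(k >= 1 || nrow(rules) == 0L)
  if (nrow(rules) == 0L) return(rules)
  size <- vapply(rules$antecedent, function(a) length(parse_items(a)),
                 integer(1), USE.NAMES = FALSE)
  ord <- order(-rules$confidence, -rules$support, size, rules$antecedent,
               method = "radix")
  out <- rules[head(ord, k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition rules into sick and healthy sets
#'
#' @param rules class-consequent rules.
#' @return list with elements `sick` (consequent "Heart Disease") and
#'   `healthy` (consequent "No Heart Disease"); exhaustive and disjoint.
#' @export
partition_rules <- function(rules) {
  bad <- setdiff(unique(rules$consequent), CLASS_LEVELS)
  if (length(bad)) {
    hd_stop("non-class consequent: ", bad[1], class = "hdwarm_domain_error")
  }
  sick <- rules[rules$consequent == "Heart Disease", , drop = FALSE]
  healthy <- rules[rules$consequent == "No Heart Disease", , drop = FALSE]
  rownames(sick) <- rownames(healthy) <- NULL
  list(sick = sick, healthy = healthy)
}

#' Feature frequency across a rule set
#'
#' Counts, for each feature, the number of rules whose antecedent mentions
#' it — the summary used to spot the dominant predictors among the mined
#' rules.
#'
#' @param rules a `warm_rules` data.frame.
#' @param features which features to tabulate (default: every feature seen).
#' @return named integer vector of counts with attribute `total_rules`.
#' @export
feature_frequency <- function(rules, features = NULL) {
  ante <- lapply(rules$antecedent, function(a) names(parse_items(a)))
  seen <- unique(unlist(ante))
  if (is.null(features)) {
    features <- CLEVELAND_FEATURES[CLEVELAND_FEATURES %in% seen]
    features <- c(features, setdiff(seen, CLEVELAND_FEATURES))
  }
  counts <- vapply(features, function(f) {
    sum(vapply(ante, function(x) f %in% x, logical(1)))
  }, integer(1))
  structure(counts, total_rules = nrow(rules))
}

#' Best rule for a given consequent
#'
#' @param rules a `warm_rules` data.frame.
#' @param consequent class label.
#' @return the rank-1 rule with that consequent (1-row data.frame), or
#'   `NULL` when none exists.
#' @export
best_rule <- function(rules, consequent) {
  sub <- rules[rules$consequent == consequent, , drop = FALSE]
  if (nrow(sub) == 0L) return(NULL)
  rank_rules(sub, 1L)
}

#' Render a Markdown mining report
#'
#' Top-k rule table (confidence at 2 decimals, half-up), sick/healthy
#' partition sizes, feature-frequency summary over the sick rules, and a
#' note that printed 2-decimal weights can disagree with full-precision
#' arithmetic (the package always computes at full precision).
#'
#' @param rules mined rules.
#' @param weights the `warm_weights` used.
#' @param config the [mining_config()] used.
#' @return character vector of Markdown lines.
#' @export
render_report <- function(rules, weights, config = mining_config()) {
  top <- rank_rules(rules, min(config$top_k, max(nrow(rules), 1)))
  lines <- c(
    "# WARM mining report",
    "",
    sprintf("Mode: %s | min weighted support: %g | min confidence: %g | top-k: %d",
            config$mode, config$min_wsupport, config$min_confidence,
            config$top_k),
    "",
    sprintf("## Top %d rules", nrow(top)),
    "",
    "| No | Rule | Confidence |",
    "|---:|------|-----------:|"
  )
  if (nrow(top)) {
    pretty <- function(a) gsub(",", " ", a, fixed = TRUE)
    lines <- c(lines, sprintf(
      "| %d | %s ==> class=%s | %.2f |",
      seq_len(nrow(top)), vapply(top$antecedent, pretty, character(1)),
      top$consequent, round_half_up(top$confidence, 2)))
  }
  parts <- partition_rules(top)
  lines <- c(lines, "",
             sprintf("Sick rules: %d | healthy rules: %d of top %d.",
                     nrow(parts$sick), nrow(parts$healthy), nrow(top)),
             "", "## Feature frequency across sick rules", "",
             "| Feature | Rules |", "|---------|------:|")
  freq <- feature_frequency(parts$sick)
  if (length(freq)) {
    lines <- c(lines, sprintf("| %s | %d |", names(freq), freq))
  }
  lines <- c(lines, "", "## Weight table (2 dp display)", "",
             "| Feature | Level | W(n) | W(value) | W(t) |",
             "|---------|-------|-----:|---------:|-----:|",
             sprintf("| %s | %s | %.2f | %.2f | %.4f |",
                     weights$items$feature, weights$items$level,
                     round_half_up(weights$items$w_n, 2),
                     round_half_up(weights$items$w_value, 2),
                     round_half_up(weights$items$w_t, 4)),
             "",
             paste("Note: weights are computed and mined at full floating",
                   "precision; the 2-decimal columns are display rounding",
                   "(half-up) and may disagree with independently rounded",
                   "published tables."))
  lines
}
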