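# Feature weights W(n), value weights W(value), total item weights W(t).

#' Select significant features from occurrence counts
#'
#' A feature is significant when its occurrence count is strictly greater
#' than `threshold` (">" as stated: "appeared more than 10 times").
#'
#' @param counts named occurrence counts from [load_occurrence_table()].
#' @param threshold non-negative integer cut-off (default 10).
#' @return character vector of significant feature names in canonical order.
#' @export
#' @examples
#' select_significant(load_occurrence_table(), 10)
#' # sex cp fbs exang oldpeak slope ca thal
select_significant <- function(counts, threshold = 10) {
  stopifnot(threshold >= 0)
  keep <- names(counts)[counts > threshold]
  CLEVELAND_FEATURES[CLEVELAND_FEATURES %in% keep]
}

#' Normalized feature weight W(n)
#'
#' The weight of a feature is its occurrence count divided by the summed
#' counts of every included feature, so weights over the included set sum
#' to one. Full precision; round only for display.
#'
#' @param counts named occurrence counts.
#' @param included features forming the normalization set.
#' @param feature the feature whose weight is wanted (must be in `included`).
#' @return proportion in \[0, 1\].
#' @export
#' @examples
#' counts <- load_occurrence_table()
#' sig <- select_significant(counts)
#' feature_weight(counts, sig, "sex") # 20/121 = 0.1652893
feature_weight <- function(counts, included, feature) {
  if (!feature %in% included) {
    hd_stop("feature '", feature, "' is not in the included set",
            class = "hdwarm_domain_error")
  }
  total <- sum(counts[included])
  if (!isTRUE(total > 0)) {
    hd_stop("included occurrence counts sum to zero",
            class = "hdwarm_domain_error")
  }
  unname(counts[[feature]] / total)
}

#' Empirical value weight W(value)
#'
#' Fraction of records in which `feature` takes `level`, computed on the
#' cleaned encoded dataset.
#'
#' @param dataset encoded dataset.
#' @param feature feature name (a column of `dataset`).
#' @param level level label.
#' @return proportion in \[0, 1\]; 0 for a level absent from the data.
#' @export
value_weight <- function(dataset, feature, level) {
  if (nrow(dataset) == 0L) {
    hd_stop("empty dataset", class = "hdwarm_domain_error")
  }
  if (!feature %in% names(dataset)) {
    hd_stop("feature '", feature, "' not in dataset",
            class = "hdwarm_domain_error")
  }
  sum(dataset[[feature]] == level) / nrow(dataset)
}

#' Total item weight W(t)
#'
#' The strength score of a (feature, level) item: the product of its
#' feature weight and value weight.
#'
#' @param w_n feature weight in \[0, 1\].
#' @param w_value value weight in \[0, 1\].
#' @return `w_n * w_value` at full precision.
#' @export
#' @examples
#' total_weight(0.14, 0.68) # 0.0952
total_weight <- function(w_n, w_value) {
  stopifnot(w_n >= 0, w_n <= 1, w_value >= 0, w_value <= 1)
  w_n * w_value
}

#' Build the full weight table
#'
#' For every included feature computes W(n) from the occurrence counts, and
#' for every level of that feature observed in `dataset` computes W(value)
#' and the total item weight W(t) = W(n) * W(value).
#'
#' @param counts named occurrence counts.
#' @param included features to include (default: all features named in
#'   `counts`).
#' @param dataset encoded dataset whose columns cover `included`.
#' @return an object of class `warm_weights`: list with `feature_weights`
#'   (named numeric) and `items` (data.frame feature, level, w_n, w_value,
#'   w_t).
#' @export
build_weight_table <- function(counts, included = names(counts), dataset) {
  missing <- setdiff(included, names(dataset))
  if (length(missing)) {
    hd_stop("dataset lacks included feature(s): ",
            paste(missing, collapse = ", "), class = "hdwarm_schema_error")
  }
  included <- names(counts)[names(counts) %in% included]
  w_n <- vapply(included, function(f) feature_weight(counts, included, f),
                numeric(1))
  rows <- lapply(included, function(f) {
    levels <- sort(unique(dataset[[f]]), method = "radix")
    w_value <- vapply(levels, function(l) value_weight(dataset, f, l),
                      numeric(1))
    data.frame(feature = f, level = levels, w_n = w_n[[f]],
               w_value = unname(w_value),
               w_t = total_weight_vec(w_n[[f]], unname(w_value)),
               stringsAsFactors = FALSE)
  })
  items <- do.call(rbind, rows)
  rownames(items) <- NULL
  structure(list(feature_weights = w_n, items = items),
            class = "warm_weights")
}

total_weight_vec <- function(w_n, w_value) w_n * w_value

#' @export
print.warm_weights <- function(x, ...) {
  cat("Weight table over", length(x$feature_weights), "features,",
      nrow(x$items), "items\n")
  shown <- x$items
  shown$w_n_2dp <- round_half_up(shown$w_n, 2)
  shown$w_t_2dp <- round_half_up(shown$w_t, 2)
  print.data.frame(shown, digits = 4)
  invisible(x)
}

#' Look up the total weight of an item
#'
#' @param weights a `warm_weights` object.
#' @param feature,level the item.
#' @return its W(t).
#' @export
item_weight <- function(weights, feature, level) {
  i <- which(weights$items$feature == feature & weights$items$level == level)
  if (length(i) != 1L) {
    hd_stop("unknown item: ", feature, "=", level,
            class = "hdwarm_domain_error")
  }
  weights$items$w_t[i]
}

#' Export a weight table as CSV
#'
#' Full-precision columns plus 2-decimal display columns (half-up
#' rounding), mirroring how the reference tables print.
#'
#' @param weights a `warm_weights` object.
#' @param sink output CSV path.
#' @return `sink`, invisibly.
#' @export
write_weight_table <- function(weights, sink) {
  out <- weights$items
  out$w_n_2dp <- round_half_up(out$w_n, 2)
  out$w_value_2dp <- round_half_up(out$w_value, 2)
  out$w_t_2dp <- round_half_up(out$w_t, 2)
  for (col in c("w_n", "w_value", "w_t")) {
    out[[col]] <- format(out[[col]], digits = 17, scientific = FALSE,
                         trim = TRUE)
  }
  write.csv(out, sink, row.names = FALSE)
  invisible(sink)
}
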