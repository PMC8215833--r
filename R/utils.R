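# Shared vocabulary and small helpers.

# Canonical attribute order; "goal" is the raw class column, "class" the
# encoded one. Single naming authority for every module.
CLEVELAND_FEATURES <- c(
  "age", "sex", "cp", "trestbps", "chol", "fbs", "restecg",
  "thalach", "exang", "oldpeak", "slope", "ca", "thal"
)
CLASS_COLUMN <- "class"
CLASS_LEVELS <- c("No Heart Disease", "Heart Disease")

#' Round half away from zero
#'
#' Decimal rounding with ties going up in absolute value (0.005 -> 0.01),
#' matching how the reference tables round. Used only for display and
#' reporting; all internal arithmetic is full precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(20 / 121, 2) # 0.17
#' round_half_up(0.125, 2)    # 0.13
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

hd_stop <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "hdwarm_error")))
}

# Items are (feature, level) pairs carried as a named character vector,
# e.g. c(cp = "asymptomatic", class = "Heart Disease"). Canonical order is
# lexicographic by feature name; levels never contain "=" or ",".
sort_items <- function(items) {
  items[order(names(items), method = "radix")]
}

format_items <- function(items) {
  if (length(items) == 0L) return("")
  items <- sort_items(items)
  paste0(names(items), "=", unname(items), collapse = ",")
}

parse_items <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  eq <- regexpr("=", parts, fixed = TRUE)
  if (any(eq < 0L)) {
    hd_stop("malformed item string: ", x, class = "hdwarm_parse_error")
  }
  sort_items(setNames(substring(parts, eq + 1L), substring(parts, 1L, eq - 1L)))
}

# Level aliases seen in the literature's rule tables; normalized on read.
LEVEL_ALIASES <- c(
  reversable = "reversible",
  flat = "Flat",
  upsloping = "Upsloping",
  downsloping = "Downsloping"
)

normalize_level <- function(x) {
  hit <- match(x, names(LEVEL_ALIASES))
  x[!is.na(hit)] <- LEVEL_ALIASES[hit[!is.na(hit)]]
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
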