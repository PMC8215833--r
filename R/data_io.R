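# Reading Cleveland-format records and occurrence counts; rule serialization.

#' Read processed Cleveland-format heart disease records
#'
#' Parses the 14-column comma-separated dialect of the processed Cleveland
#' heart disease file: the 13 clinical attributes (age, sex, cp, trestbps,
#' chol, fbs, restecg, thalach, exang, oldpeak, slope, ca, thal) followed by
#' the diagnosis column `goal` (0--4). The literal token `"?"` marks a
#' missing value and becomes `NA`; any other non-numeric token is an error,
#' so corrupt input fails loudly rather than silently becoming missing.
#'
#' @param source path to a file, or a character vector of lines (anything
#'   [readLines()] accepts; a `textConnection` works for in-memory input).
#' @return a `data.frame` with one row per input record, in input order,
#'   numeric columns named by the canonical lowercase feature names plus
#'   `goal`. Missing values are `NA`.
#' @export
#' @examples
#' lines <- c("63,1,1,145,233,1,2,150,0,2.3,3,0,6,0",
#'            "67,1,4,160,286,0,2,108,1,1.5,2,3,3,2")
#' read_cleveland(lines)
read_cleveland <- function(source) {
  lines <- if (is.character(source) && length(source) != 1L) {
    source
  } else if (is.character(source) && !file.exists(source)) {
    # in-memory text: one string, possibly multi-line
    strsplit(source, "\n", fixed = TRUE)[[1]]
  } else {
    readLines(source, warn = FALSE)
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cols <- c(CLEVELAND_FEATURES, "goal")
  if (length(lines) == 0L) {
    empty <- as.data.frame(setNames(rep(list(numeric(0)), 14L), cols))
    return(empty)
  }
  fields <- strsplit(lines, ",", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields != 14L)
  if (length(bad)) {
    hd_stop("row ", bad[1], ": expected 14 comma-separated fields, found ",
            n_fields[bad[1]], class = "hdwarm_parse_error")
  }
  mat <- matrix(trimws(unlist(fields)), ncol = 14L, byrow = TRUE)
  mat[mat == "?"] <- NA_character_
  num <- suppressWarnings(array(as.numeric(mat), dim = dim(mat)))
  bad_tok <- which(is.na(num) & !is.na(mat), arr.ind = TRUE)
  if (nrow(bad_tok)) {
    r <- bad_tok[1, 1]
    hd_stop("row ", r, ": non-numeric token '", mat[r, bad_tok[1, 2]],
            "' (only '?' marks missing)", class = "hdwarm_parse_error")
  }
  df <- as.data.frame(num)
  names(df) <- cols
  goal_ok <- is.na(df$goal) | (df$goal %in% 0:4)
  if (!all(goal_ok)) {
    hd_stop("row ", which(!goal_ok)[1], ": goal must be an integer in 0..4",
            class = "hdwarm_parse_error")
  }
  df
}

#' Load a feature occurrence-count table
#'
#' Occurrence counts summarize how often each of the 13 attributes appeared
#' in the best-performing feature subsets of an upstream feature-selection
#' study; they are the raw material for the normalized feature weights W(n).
#' The bundled table ships with the package (`"bundled"`), or a CSV with
#' columns `feature,count` can be supplied.
#'
#' @param source `"bundled"` for the packaged table, or a path to a CSV.
#' @return named numeric vector of counts, one per feature, in canonical
#'   feature order.
#' @export
#' @examples
#' counts <- load_occurrence_table()
#' counts[["sex"]] # 20
load_occurrence_table <- function(source = "bundled") {
  path <- if (identical(source, "bundled")) {
    system.file("extdata", "occurrence_counts.csv", package = "hdwarm",
                mustWork = TRUE)
  } else {
    source
  }
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("feature", "count") %in% names(tab))) {
    hd_stop("occurrence table needs columns 'feature' and 'count'",
            class = "hdwarm_schema_error")
  }
  tab$feature <- tolower(trimws(tab$feature))
  if (anyDuplicated(tab$feature)) {
    hd_stop("duplicate feature in occurrence table: ",
            tab$feature[duplicated(tab$feature)][1],
            class = "hdwarm_schema_error")
  }
  missing <- setdiff(CLEVELAND_FEATURES, tab$feature)
  if (length(missing)) {
    hd_stop("occurrence table missing feature(s): ",
            paste(missing, collapse = ", "), class = "hdwarm_schema_error")
  }
  extra <- setdiff(tab$feature, CLEVELAND_FEATURES)
  if (length(extra)) {
    hd_stop("unknown feature(s) in occurrence table: ",
            paste(extra, collapse = ", "), class = "hdwarm_schema_error")
  }
  counts <- setNames(as.numeric(tab$count), tab$feature)[CLEVELAND_FEATURES]
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    hd_stop("occurrence counts must be non-negative integers",
            class = "hdwarm_schema_error")
  }
  counts
}

# Internal constructor: validates and canonicalizes a rules data.frame.
RULE_COLUMNS <- c("antecedent", "consequent", "support",
                  "wsupport_antecedent", "wsupport_rule", "confidence")

new_warm_rules <- function(df) {
  if (nrow(df)) {
    df$antecedent <- vapply(df$antecedent,
                            function(a) format_items(parse_items(a)),
                            character(1), USE.NAMES = FALSE)
  }
  df <- df[, RULE_COLUMNS]
  rownames(df) <- NULL
  class(df) <- c("warm_rules", "data.frame")
  df
}

#' Serialize mined rules
#'
#' Writes rules to JSON (one object per rule) or CSV at full floating-point
#' precision, with antecedent items in canonical lexicographic
#' (feature, level) order, so a write/read round trip is the identity.
#'
#' @param rules a rules data.frame as returned by [generate_class_rules()].
#' @param sink output file path.
#' @param format `"json"` or `"csv"`.
#' @return `sink`, invisibly.
#' @seealso [read_rules()]
#' @export
write_rules <- function(rules, sink, format = c("json", "csv")) {
  format <- match.arg(format)
  df <- as.data.frame(rules)[, RULE_COLUMNS, drop = FALSE]
  if (format == "json") {
    # I(17) = 17 significant digits: doubles round-trip exactly
    jsonlite::write_json(df, sink, dataframe = "rows", auto_unbox = TRUE,
                         digits = I(17), na = "null")
  } else {
    out <- df
    for (col in c("support", "wsupport_antecedent", "wsupport_rule",
                  "confidence")) {
      out[[col]] <- format(df[[col]], digits = 17, scientific = FALSE,
                           trim = TRUE)
    }
    write.csv(out, sink, row.names = FALSE)
  }
  invisible(sink)
}

#' Read serialized rules
#'
#' @param source path to a JSON or CSV file written by [write_rules()] (or
#'   hand-written in the same schema). Level aliases such as `reversable`
#'   are normalized to the canonical vocabulary.
#' @param format `"json"`, `"csv"`, or `"auto"` (by file extension).
#' @return a `warm_rules` data.frame.
#' @export
read_rules <- function(source, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", source, ignore.case = TRUE)) "json" else "csv"
  }
  df <- if (format == "json") {
    as.data.frame(jsonlite::read_json(source, simplifyVector = TRUE))
  } else {
    read.csv(source, stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0L) {
    df <- as.data.frame(setNames(
      list(character(0), character(0), numeric(0), numeric(0), numeric(0),
           numeric(0)), RULE_COLUMNS))
    return(new_warm_rules(df))
  }
  missing <- setdiff(RULE_COLUMNS, names(df))
  if (length(missing)) {
    hd_stop("rules file missing column(s): ", paste(missing, collapse = ", "),
            class = "hdwarm_schema_error")
  }
  df$antecedent <- vapply(df$antecedent, function(a) {
    items <- parse_items(a)
    format_items(setNames(normalize_level(unname(items)), names(items)))
  }, character(1), USE.NAMES = FALSE)
  for (col in c("support", "wsupport_antecedent", "wsupport_rule",
                "confidence")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  new_warm_rules(df)
}

#' Write and read encoded (nominal) datasets
#'
#' Encoded datasets are data.frames of level labels with a final `class`
#' column; they round-trip through plain CSV.
#'
#' @param dataset encoded dataset (data.frame of character levels + `class`).
#' @param sink,source file path.
#' @return `write_encoded` returns `sink` invisibly; `read_encoded` the
#'   dataset with level aliases normalized.
#' @export
write_encoded <- function(dataset, sink) {
  write.csv(dataset, sink, row.names = FALSE)
  invisible(sink)
}

#' @rdname write_encoded
#' @export
read_encoded <- function(source) {
  df <- read.csv(source, stringsAsFactors = FALSE, check.names = FALSE)
  if (!CLASS_COLUMN %in% names(df)) {
    hd_stop("encoded dataset must have a 'class' column",
            class = "hdwarm_schema_error")
  }
  for (col in names(df)) df[[col]] <- normalize_level(as.character(df[[col]]))
  bad <- setdiff(unique(df[[CLASS_COLUMN]]), CLASS_LEVELS)
  if (length(bad)) {
    hd_stop("illegal class label: ", bad[1], class = "hdwarm_schema_error")
  }
  df
}
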