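# Cleaning, class binarization, and clinical discretization.

#' Default clinical discretization scheme
#'
#' Maps each raw Cleveland attribute onto the nominal vocabulary used for
#' rule mining. Numeric attributes get fixed clinical bins; coded attributes
#' get name maps. Interval features use half-open `[lo, hi)` bins except
#' where a strict ">" defines the upper category (thalach, oldpeak), and the
#' outermost bins extend to infinity so discretization is total on the reals:
#'
#' * age: `< 41` lessThanForty, `41--64` betweenAge, `>= 65` greaterThanSixtyFour
#' * trestbps (mmHg): `< 120` normal, `[120,140)` unusual, `[140,160)` high,
#'   `>= 160` very_high
#' * chol (mg/dL): `< 200` normal, `[200,240)` borderline_high, `[240,250)`
#'   high, `>= 250` very_high
#' * thalach (bpm): `<= 100` Normal, `> 100` Tachycardia
#' * oldpeak (ST depression): `<= 0` Zero, `> 0` greaterThanZero
#' * sex 1/0 -> Male/Female; cp 1..4 -> typicalAngina, atypicalAngina,
#'   nonAnginalPain, asymptomatic; fbs 1/0 -> TRUE/FALSE; restecg 0/1/2 ->
#'   normal/STTWaveAbnormality/showingProbable; exang 1/0 -> Yes/No;
#'   slope 1/2/3 -> Upsloping/Flat/Downsloping; ca 0..3 ->
#'   zero/one/two/three; thal 3/6/7 -> normal/fixed/reversible
#'
#' @return a named list (one entry per feature) describing interval bins
#'   (`breaks`, `labels`, `right`) or code maps (`map`), with class
#'   `"hdwarm_scheme"`.
#' @export
default_scheme <- function() {
  interval <- function(breaks, labels, right = FALSE) {
    list(kind = "interval", breaks = breaks, labels = labels, right = right)
  }
  codes <- function(...) {
    list(kind = "code", map = c(...))
  }
  scheme <- list(
    age = interval(c(-Inf, 41, 65, Inf),
                   c("lessThanForty", "betweenAge", "greaterThanSixtyFour")),
    sex = codes(`1` = "Male", `0` = "Female"),
    cp = codes(`1` = "typicalAngina", `2` = "atypicalAngina",
               `3` = "nonAnginalPain", `4` = "asymptomatic"),
    trestbps = interval(c(-Inf, 120, 140, 160, Inf),
                        c("normal", "unusual", "high", "very_high")),
    chol = interval(c(-Inf, 200, 240, 250, Inf),
                    c("normal", "borderline_high", "high", "very_high")),
    fbs = codes(`1` = "TRUE", `0` = "FALSE"),
    restecg = codes(`0` = "normal", `1` = "STTWaveAbnormality",
                    `2` = "showingProbable"),
    thalach = interval(c(-Inf, 100, Inf), c("Normal", "Tachycardia"),
                       right = TRUE),
    exang = codes(`1` = "Yes", `0` = "No"),
    oldpeak = interval(c(-Inf, 0, Inf), c("Zero", "greaterThanZero"),
                       right = TRUE),
    slope = codes(`1` = "Upsloping", `2` = "Flat", `3` = "Downsloping"),
    ca = codes(`0` = "zero", `1` = "one", `2` = "two", `3` = "three"),
    thal = codes(`3` = "normal", `6` = "fixed", `7` = "reversible")
  )
  structure(scheme, class = "hdwarm_scheme")
}

#' Legal levels of a feature under a scheme
#'
#' @param scheme a discretization scheme, see [default_scheme()].
#' @param feature feature name, or `NULL` for all features.
#' @return character vector of level labels (a named list over features if
#'   `feature` is `NULL`).
#' @export
scheme_levels <- function(scheme = default_scheme(), feature = NULL) {
  one <- function(entry) {
    if (entry$kind == "interval") entry$labels else unname(entry$map)
  }
  if (is.null(feature)) return(lapply(scheme, one))
  if (!feature %in% names(scheme)) {
    hd_stop("unknown feature: ", feature, class = "hdwarm_schema_error")
  }
  one(scheme[[feature]])
}

#' Drop records with missing values
#'
#' Mirrors the preprocessing step of deleting every record carrying a
#' missing field (no imputation). Idempotent; preserves input order.
#'
#' @param records raw records data.frame from [read_cleveland()].
#' @return the subset of complete records.
#' @export
drop_incomplete <- function(records) {
  records[complete.cases(records), , drop = FALSE]
}

#' Binarize the diagnosis column
#'
#' The raw `goal` codes criticality 0--4; prediction targets presence only,
#' so 1--4 collapse to "Heart Disease" and 0 maps to "No Heart Disease".
#'
#' @param goal integer vector in 0..4.
#' @return character vector of class labels.
#' @export
#' @examples
#' binarize_goal(c(0, 3)) # "No Heart Disease" "Heart Disease"
binarize_goal <- function(goal) {
  if (any(is.na(goal)) || !all(goal %in% 0:4)) {
    hd_stop("goal must be an integer in 0..4",
            class = "hdwarm_domain_error")
  }
  as.character(ifelse(goal == 0, CLASS_LEVELS[1], CLASS_LEVELS[2]))
}

discretize_column <- function(x, feature, entry) {
  if (entry$kind == "interval") {
    as.character(cut(x, breaks = entry$breaks, labels = entry$labels,
                     right = entry$right))
  } else {
    key <- as.character(x)
    out <- unname(entry$map[key])
    if (any(is.na(out) & !is.na(x))) {
      bad <- x[is.na(out) & !is.na(x)][1]
      hd_stop("feature '", feature, "': code ", bad,
              " outside its code map", class = "hdwarm_domain_error")
    }
    out
  }
}

#' Discretize one complete raw record
#'
#' @param record a single complete raw record: a 1-row data.frame or named
#'   list with the 13 attributes and `goal`.
#' @param scheme discretization scheme.
#' @return named character vector of levels plus a `class` entry.
#' @export
#' @examples
#' rec <- read_cleveland("70,1,4,130,322,0,2,109,0,2.4,2,3,3,1")[1, ]
#' discretize_record(rec) # age = "greaterThanSixtyFour", ...
discretize_record <- function(record, scheme = default_scheme()) {
  record <- as.list(record)
  if (any(is.na(unlist(record[CLEVELAND_FEATURES])))) {
    hd_stop("record has missing values; clean with drop_incomplete() first",
            class = "hdwarm_domain_error")
  }
  levels <- vapply(CLEVELAND_FEATURES, function(f) {
    discretize_column(record[[f]], f, scheme[[f]])
  }, character(1))
  c(levels, setNames(binarize_goal(record$goal), CLASS_COLUMN))
}

#' Clean, discretize and project a raw dataset
#'
#' Full preprocessing pipeline: drop incomplete records, discretize every
#' attribute under `scheme`, binarize the class, and keep only
#' `feature_subset` (plus the class column).
#'
#' @param records raw records data.frame from [read_cleveland()].
#' @param scheme discretization scheme.
#' @param feature_subset character vector of features to keep (default all
#'   13). The class is implicit; listing `goal` or `class` is an error.
#' @return encoded dataset: data.frame of character levels with a final
#'   `class` column.
#' @export
encode_dataset <- function(records, scheme = default_scheme(),
                           feature_subset = CLEVELAND_FEATURES) {
  if (any(c("goal", CLASS_COLUMN) %in% feature_subset)) {
    hd_stop("the class label is implicit; do not list 'goal' or 'class' in ",
            "feature_subset", class = "hdwarm_schema_error")
  }
  unknown <- setdiff(feature_subset, CLEVELAND_FEATURES)
  if (length(unknown)) {
    hd_stop("unknown feature(s): ", paste(unknown, collapse = ", "),
            class = "hdwarm_schema_error")
  }
  keep <- CLEVELAND_FEATURES[CLEVELAND_FEATURES %in% feature_subset]
  records <- drop_incomplete(records)
  cols <- lapply(keep, function(f) {
    discretize_column(records[[f]], f, scheme[[f]])
  })
  out <- as.data.frame(setNames(cols, keep), stringsAsFactors = FALSE)
  if (nrow(records) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(keep)), keep))
  }
  out[[CLASS_COLUMN]] <- binarize_goal(records$goal)
  out
}
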