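# Seeded generator for Cleveland-like encoded datasets with planted rules.

#' Specify a synthetic encoded dataset
#'
#' Describes a categorical dataset in the clinical vocabulary: per-feature
#' level marginals, a binary class prevalence, and optional planted
#' antecedent -> class rules. Planting overrides the marginals only on the
#' records that carry a planted antecedent (disjoint blocks of
#' `ceiling(coverage * n)` records, assigned in rule order); everything else
#' is drawn independently, so there are no correlations beyond the planted
#' ones.
#'
#' @param n number of records.
#' @param marginals named list: feature -> named probability vector over its
#'   levels (each sums to 1).
#' @param class_prevalence probability of "Heart Disease".
#' @param planted_rules list of rules, each a list with `antecedent` (named
#'   character vector of (feature = level) items), `class` (label),
#'   `confidence` and `coverage` in \[0, 1\].
#' @param seed integer seed driving the single pseudo-random stream.
#' @return a validated `synthetic_spec` object.
#' @export
synthetic_spec <- function(n, marginals, class_prevalence = 0.5,
                           planted_rules = list(), seed = 1L) {
  stopifnot(n >= 1, class_prevalence >= 0, class_prevalence <= 1)
  for (f in names(marginals)) {
    p <- marginals[[f]]
    if (is.null(names(p)) || any(!nzchar(names(p)))) {
      hd_stop("marginal for '", f, "' must be a named probability vector",
              class = "hdwarm_spec_error")
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      hd_stop("marginal for '", f, "' must be non-negative and sum to 1",
              class = "hdwarm_spec_error")
    }
  }
  total_cov <- 0
  for (r in planted_rules) {
    a <- r$antecedent
    if (anyDuplicated(names(a))) {
      hd_stop("planted rule assigns two levels to feature '",
              names(a)[duplicated(names(a))][1], "'",
              class = "hdwarm_spec_error")
    }
    for (f in names(a)) {
      if (!f %in% names(marginals) || !a[[f]] %in% names(marginals[[f]])) {
        hd_stop("planted antecedent item ", f, "=", a[[f]],
                " is not a legal (feature, level) pair",
                class = "hdwarm_spec_error")
      }
    }
    if (!r$class %in% CLASS_LEVELS ||
        r$confidence < 0 || r$confidence > 1 ||
        r$coverage < 0 || r$coverage > 1) {
      hd_stop("planted rule needs a legal class label and confidence/",
              "coverage in [0, 1]", class = "hdwarm_spec_error")
    }
    total_cov <- total_cov + r$coverage
  }
  if (total_cov > 1 + 1e-8) {
    hd_stop("planted rule coverages sum to more than 1",
            class = "hdwarm_spec_error")
  }
  structure(list(n = as.integer(n), marginals = marginals,
                 class_prevalence = class_prevalence,
                 planted_rules = planted_rules, seed = as.integer(seed)),
            class = "synthetic_spec")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic encoded dataset
#'
#' Draws each feature independently from its marginal and the class from
#' the prevalence, then overwrites disjoint blocks of records with the
#' planted antecedents; every record carrying a planted antecedent (block
#' or chance carrier) then has its class redrawn to equal the rule's label
#' with probability equal to the target confidence, in rule order, so the
#' rule's empirical confidence is binomial around its target. Identical spec
#' and seed give bit-identical output; the global RNG state is restored on
#' exit.
#'
#' @param spec a [synthetic_spec()].
#' @return encoded dataset (data.frame of levels plus `class`).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n
    cols <- lapply(spec$marginals, function(p) {
      sample(names(p), n, replace = TRUE, prob = p)
    })
    df <- as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
    df[[CLASS_COLUMN]] <- ifelse(
      stats::runif(n) < spec$class_prevalence, CLASS_LEVELS[2],
      CLASS_LEVELS[1])
    start <- 1L
    for (r in spec$planted_rules) {
      m <- as.integer(ceiling(r$coverage * n))
      if (m == 0L) next
      idx <- start:(start + m - 1L)
      for (f in names(r$antecedent)) df[[f]][idx] <- r$antecedent[[f]]
      start <- start + m
    }
    # class is drawn for every record carrying a planted antecedent (the
    # block plus chance carriers), so the rule's empirical confidence is
    # binomial around its target rather than diluted by background records
    for (r in spec$planted_rules) {
      carrier <- which(match_items(r$antecedent, df))
      if (length(carrier) == 0L) next
      hit <- stats::runif(length(carrier)) < r$confidence
      other <- setdiff(CLASS_LEVELS, r$class)
      df[[CLASS_COLUMN]][carrier] <- ifelse(hit, r$class, other)
    }
    df
  })
}

#' Default Cleveland-like synthetic specification
#'
#' A packaged stand-in for the cleaned Cleveland encoding: 297 records over
#' the full 13-feature clinical vocabulary, marginals loosely shaped on the
#' real dataset (in particular the 203/297 male split), class prevalence
#' 137/297, and two planted headline rules — a sick rule
#' \{cp=asymptomatic, exang=Yes, oldpeak=greaterThanZero, thal=reversible\}
#' at target confidence 0.98 covering 30% of records, and a healthy rule
#' \{sex=Female, cp=nonAnginalPain, thal=normal\} at confidence 1 covering
#' 10%.
#'
#' @param seed integer seed.
#' @param n number of records (default 297).
#' @return a `synthetic_spec`.
#' @export
cleveland_like_spec <- function(seed = 1L, n = 297L) {
  marginals <- list(
    age = c(lessThanForty = 0.10, betweenAge = 0.75,
            greaterThanSixtyFour = 0.15),
    sex = c(Male = 203 / 297, Female = 94 / 297),
    cp = c(typicalAngina = 0.08, atypicalAngina = 0.17,
           nonAnginalPain = 0.27, asymptomatic = 0.48),
    trestbps = c(normal = 0.35, unusual = 0.38, high = 0.17,
                 very_high = 0.10),
    chol = c(normal = 0.18, borderline_high = 0.33, high = 0.07,
             very_high = 0.42),
    fbs = c(`FALSE` = 0.85, `TRUE` = 0.15),
    restecg = c(normal = 0.50, STTWaveAbnormality = 0.01,
                showingProbable = 0.49),
    thalach = c(Normal = 0.08, Tachycardia = 0.92),
    exang = c(No = 0.67, Yes = 0.33),
    oldpeak = c(Zero = 0.33, greaterThanZero = 0.67),
    slope = c(Upsloping = 0.47, Flat = 0.46, Downsloping = 0.07),
    ca = c(zero = 0.59, one = 0.22, two = 0.13, three = 0.06),
    thal = c(normal = 0.55, fixed = 0.06, reversible = 0.39)
  )
  planted <- list(
    list(antecedent = c(cp = "asymptomatic", exang = "Yes",
                        oldpeak = "greaterThanZero", thal = "reversible"),
         class = "Heart Disease", confidence = 0.98, coverage = 0.30),
    list(antecedent = c(sex = "Female", cp = "nonAnginalPain",
                        thal = "normal"),
         class = "No Heart Disease", confidence = 1.0, coverage = 0.10)
  )
  synthetic_spec(n = n, marginals = marginals,
                 class_prevalence = 137 / 297,
                 planted_rules = planted, seed = seed)
}

# Representative raw values used to re-numerify interval levels when
# writing the Cleveland 14-column dialect.
INTERVAL_REPRESENTATIVES <- list(
  age = c(lessThanForty = 35, betweenAge = 50, greaterThanSixtyFour = 70),
  trestbps = c(normal = 110, unusual = 130, high = 150, very_high = 170),
  chol = c(normal = 180, borderline_high = 220, high = 245,
           very_high = 280),
  thalach = c(Normal = 90, Tachycardia = 150),
  oldpeak = c(Zero = 0, greaterThanZero = 1.5)
)

#' Write an encoded dataset in the Cleveland 14-column dialect
#'
#' Re-numerifies levels through inverse code maps; interval levels become a
#' fixed representative value inside their bin (so encode -> write -> read
#' -> encode is the identity, while raw magnitudes are synthetic). The
#' class column becomes goal 0/1.
#'
#' @param dataset encoded dataset over all 13 features plus `class`.
#' @param sink output path.
#' @param scheme discretization scheme whose code maps are inverted.
#' @return `sink`, invisibly.
#' @export
write_cleveland <- function(dataset, sink, scheme = default_scheme()) {
  missing <- setdiff(c(CLEVELAND_FEATURES, CLASS_COLUMN), names(dataset))
  if (length(missing)) {
    hd_stop("dataset must carry all 13 features plus class; missing: ",
            paste(missing, collapse = ", "), class = "hdwarm_schema_error")
  }
  cols <- lapply(CLEVELAND_FEATURES, function(f) {
    entry <- scheme[[f]]
    lv <- dataset[[f]]
    if (entry$kind == "code") {
      inv <- setNames(names(entry$map), unname(entry$map))
      out <- inv[lv]
    } else {
      out <- INTERVAL_REPRESENTATIVES[[f]][lv]
    }
    if (any(is.na(out))) {
      hd_stop("illegal level for feature '", f, "': ",
              lv[is.na(out)][1], class = "hdwarm_domain_error")
    }
    unname(out)
  })
  goal <- ifelse(dataset[[CLASS_COLUMN]] == CLASS_LEVELS[2], 1L, 0L)
  lines <- do.call(paste, c(cols, list(goal), sep = ","))
  writeLines(lines, sink)
  invisible(sink)
}
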