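# Fixtures built in code: toy encoded datasets, handcrafted weight tables,
# the published top-20 significant-features rule table, and a random-toy
# generator for oracle comparisons.

fixture_path <- function(name) {
  system.file("extdata", name, package = "hdwarm", mustWork = TRUE)
}

# Four records, {sex=Male} in three of them.
toy4 <- function() {
  data.frame(
    sex = c("Male", "Male", "Male", "Female"),
    ca = c("three", "zero", "three", "zero"),
    class = c("Heart Disease", "Heart Disease", "No Heart Disease",
              "No Heart Disease"),
    stringsAsFactors = FALSE
  )
}

# Handcrafted weight table over the toy vocabulary (w_t chosen directly).
# Includes ca=two, a level no toy4() record carries (support-0 item).
toy_weights <- function(w_male = 0.2, w_female = 0.1, w_three = 0.3,
                        w_zero = 0.05, w_two = 0.15) {
  items <- data.frame(
    feature = c("sex", "sex", "ca", "ca", "ca"),
    level = c("Male", "Female", "three", "zero", "two"),
    w_n = 0.5, w_value = 1,
    w_t = c(w_male, w_female, w_three, w_zero, w_two),
    stringsAsFactors = FALSE
  )
  structure(list(feature_weights = c(sex = 0.5, ca = 0.5), items = items),
            class = "warm_weights")
}

# The published top-20 rules over the 8 significant features (antecedent
# levels as printed, including the 'reversable' spelling in some rows, which
# read/normalization canonicalizes elsewhere; here we build canonically).
table10_rules <- function() {
  A <- function(...) {
    items <- c(...)
    paste0(names(items), "=", items, collapse = ",")
  }
  HD <- "Heart Disease"; NO <- "No Heart Disease"
  spec <- list(
    list(A(sex = "Female", cp = "nonAnginalPain", thal = "normal"), NO, 1),
    list(A(sex = "Female", exang = "No", oldpeak = "greaterThanZero",
           ca = "zero"), NO, 1),
    list(A(cp = "asymptomatic", exang = "Yes",
           oldpeak = "greaterThanZero", thal = "reversible"), HD, 0.98),
    list(A(sex = "Male", cp = "asymptomatic", exang = "Yes",
           oldpeak = "greaterThanZero", thal = "reversible"), HD, 0.97),
    list(A(cp = "asymptomatic", fbs = "FALSE", exang = "Yes",
           oldpeak = "greaterThanZero", thal = "reversible"), HD, 0.97),
    list(A(sex = "Female", cp = "nonAnginalPain"), NO, 0.97),
    list(A(sex = "Female", fbs = "FALSE", exang = "No",
           oldpeak = "greaterThanZero", thal = "normal"), NO, 0.97),
    list(A(sex = "Male", cp = "asymptomatic", ca = "one"), HD, 0.97),
    list(A(sex = "Female", cp = "nonAnginalPain", exang = "No"), NO, 0.97),
    list(A(cp = "asymptomatic", exang = "Yes", slope = "Flat",
           thal = "reversible"), HD, 0.97),
    list(A(cp = "asymptomatic", exang = "Yes",
           oldpeak = "greaterThanZero", slope = "Flat",
           thal = "reversible"), HD, 0.97),
    list(A(sex = "Male", cp = "asymptomatic", fbs = "FALSE",
           exang = "Yes", oldpeak = "greaterThanZero",
           thal = "reversible"), HD, 0.97),
    list(A(sex = "Female", exang = "No", ca = "zero"), NO, 0.96),
    list(A(sex = "Female", exang = "No", ca = "zero", thal = "normal"),
         NO, 0.96),
    list(A(cp = "asymptomatic", slope = "Flat", thal = "reversible"),
         HD, 0.96),
    list(A(sex = "Female", fbs = "FALSE", exang = "No", ca = "zero"),
         NO, 0.96),
    list(A(cp = "asymptomatic", oldpeak = "greaterThanZero",
           slope = "Flat", thal = "reversible"), HD, 0.96),
    list(A(sex = "Female", fbs = "FALSE", exang = "No", ca = "zero",
           thal = "normal"), NO, 0.96),
    list(A(cp = "asymptomatic", fbs = "FALSE", slope = "Flat",
           thal = "reversible"), HD, 0.95),
    list(A(cp = "asymptomatic", fbs = "FALSE",
           oldpeak = "greaterThanZero", slope = "Flat",
           thal = "reversible"), HD, 0.95)
  )
  df <- data.frame(
    antecedent = vapply(spec, `[[`, character(1), 1),
    consequent = vapply(spec, `[[`, character(1), 2),
    confidence = vapply(spec, `[[`, numeric(1), 3),
    stringsAsFactors = FALSE
  )
  # raw/weighted supports are not printed; use placeholders that decrease
  # with row number so ranking ties resolve deterministically
  df$support <- seq(0.40, by = -0.01, length.out = nrow(df))
  df$wsupport_antecedent <- df$support
  df$wsupport_rule <- df$support * df$confidence
  hdwarm:::new_warm_rules(df)
}

# Random small encoded dataset + weight table for oracle comparisons.
random_toy <- function(seed, max_records = 8, max_features = 4) {
  set.seed(seed)
  n_feat <- sample(1:max_features, 1)
  n_rec <- sample(2:max_records, 1)
  feats <- paste0("f", seq_len(n_feat))
  cols <- lapply(feats, function(f) {
    n_lev <- sample(2:3, 1)
    sample(paste0(f, "_v", seq_len(n_lev)), n_rec, replace = TRUE)
  })
  df <- as.data.frame(stats::setNames(cols, feats),
                      stringsAsFactors = FALSE)
  df$class <- sample(c("Heart Disease", "No Heart Disease"), n_rec,
                     replace = TRUE)
  items <- do.call(rbind, lapply(feats, function(f) {
    levels <- sort(unique(df[[f]]))
    data.frame(feature = f, level = levels,
               w_n = 1 / n_feat,
               w_value = 1 / length(levels),
               w_t = stats::runif(length(levels), 0.05, 1),
               stringsAsFactors = FALSE)
  }))
  weights <- structure(
    list(feature_weights = stats::setNames(rep(1 / n_feat, n_feat), feats),
         items = items),
    class = "warm_weights")
  config <- mining_config(
    min_wsupport = stats::runif(1, 0, 0.3),
    min_confidence = stats::runif(1, 0, 1),
    max_antecedent = sample(1:4, 1),
    top_k = 20)
  list(dataset = df, weights = weights, config = config)
}
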