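test_that("raw support counts matching records", {
  d <- toy4()
  expect_equal(support(character(0), d), 1)
  expect_equal(support(c(sex = "Male"), d), 0.75)
  expect_equal(support(c(sex = "Male", ca = "three"), d), 0.5)
  expect_equal(support(c(sex = "Nonbinary"), d), 0)
  expect_equal(support(c(class = "Heart Disease"), d), 0.5)
  expect_error(support(c(sex = "Male"), d[0, ]),
               class = "hdwarm_domain_error")
  expect_error(support(c(bogus = "x"), d), class = "hdwarm_schema_error")
})

test_that("itemset weight is the mean item strength; class items weigh 1", {
  w <- toy_weights(w_male = 0.0952, w_three = 0.3)
  expect_equal(itemset_weight(c(class = "Heart Disease"), w), 1)
  expect_equal(itemset_weight(character(0), w), 1)
  expect_equal(itemset_weight(c(sex = "Male"), w), 0.0952)
  expect_equal(itemset_weight(c(sex = "Male", ca = "three"), w),
               (0.0952 + 0.3) / 2)
  # class item does not enter the mean
  expect_equal(itemset_weight(c(sex = "Male", class = "Heart Disease"), w),
               0.0952)
  expect_error(itemset_weight(c(sex = "Martian"), w),
               class = "hdwarm_domain_error")
})

test_that("weighted support multiplies raw support by the itemset weight", {
  d <- toy4()
  w <- toy_weights(w_male = 0.2)
  expect_equal(weighted_support(c(sex = "Male"), d, w), 0.75 * 0.2)
  # an item known to the weight table but absent from every record
  expect_equal(weighted_support(c(ca = "two"), d, w), 0)
  # class-only itemsets keep their raw support
  expect_equal(weighted_support(c(class = "Heart Disease"), d, w), 0.5)
})

test_that("weighted confidence follows the weighted-support ratio", {
  # deterministic toy where both weighted supports are exactly 0.2
  d <- data.frame(
    sex = rep(c("Male", "Female"), c(4, 6)),
    ca = rep(c("three", "zero"), c(4, 6)),
    class = rep(c("Heart Disease", "No Heart Disease"), c(4, 6)),
    stringsAsFactors = FALSE)
  w <- toy_weights(w_male = 0.6, w_three = 0.4)
  ante <- c(sex = "Male", ca = "three")
  expect_equal(weighted_support(ante, d, w), 0.2)
  expect_equal(weighted_support(c(ante, class = "Heart Disease"), d, w),
               0.2)
  expect_equal(weighted_confidence(ante, "Heart Disease", d, w), 1)
  expect_equal(weighted_confidence(ante, "No Heart Disease", d, w), 0)

  # 6-record toy: antecedent in 4, antecedent & class in 3
  d6 <- data.frame(
    sex = c("Male", "Male", "Male", "Male", "Female", "Female"),
    ca = "zero",
    class = c("Heart Disease", "Heart Disease", "Heart Disease",
              "No Heart Disease", "No Heart Disease", "Heart Disease"),
    stringsAsFactors = FALSE)
  expect_equal(weighted_confidence(c(sex = "Male"), "Heart Disease", d6,
                                   toy_weights()), 0.75)

  expect_true(is.na(weighted_confidence(c(ca = "two"), "Heart Disease",
                                        toy4(), toy_weights())))
  expect_error(weighted_confidence(c(class = "Heart Disease"),
                                   "Heart Disease", d6, toy_weights()),
               class = "hdwarm_domain_error")
  expect_error(weighted_confidence(c(sex = "Male"), "Sick", d6,
                                   toy_weights()),
               class = "hdwarm_domain_error")
})

test_that("weighted confidence of class rules equals raw confidence", {
  # algebraic identity: the antecedent's weight factor cancels
  for (seed in 1:20) {
    toy <- random_toy(seed)
    d <- toy$dataset
    feats <- setdiff(names(d), "class")
    ante <- setNames(vapply(feats, function(f) d[[f]][1], character(1)),
                     feats)
    raw <- support(c(ante, class = "Heart Disease"), d) / support(ante, d)
    expect_equal(weighted_confidence(ante, "Heart Disease", d, toy$weights),
                 raw)
  }
})

test_that("the miner matches brute-force enumeration on random toys", {
  for (seed in 101:140) {
    toy <- random_toy(seed)
    got_sets <- mine_frequent_itemsets(toy$dataset, toy$weights, toy$config)
    want_sets <- oracle_mine(toy$dataset, toy$weights, toy$config)
    expect_equal(got_sets, want_sets, info = paste("seed", seed))

    got_rules <- generate_class_rules(got_sets, toy$dataset, toy$weights,
                                      toy$config)
    got_rules <- as.data.frame(got_rules)
    got_rules <- got_rules[order(got_rules$antecedent,
                                 got_rules$consequent, method = "radix"), ]
    rownames(got_rules) <- NULL
    want_rules <- oracle_rules(toy$dataset, toy$weights, toy$config)
    expect_equal(got_rules, want_rules, info = paste("seed", seed))
  }
})

test_that("mined itemsets satisfy anti-monotonicity of raw support", {
  d <- generate_synthetic(cleveland_like_spec(seed = 9, n = 120))
  counts <- load_occurrence_table()
  sig <- select_significant(counts)
  w <- build_weight_table(counts, sig, d)
  sets <- mine_frequent_itemsets(d[, c(sig, "class")], w,
                                 mining_config(min_wsupport = 0.01,
                                               max_antecedent = 3))
  sup <- setNames(sets$support, sets$items)
  for (i in which(sets$size > 1)) {
    items <- hdwarm:::parse_items(sets$items[i])
    for (drop in seq_along(items)) {
      sub <- items[-drop]
      sub_sup <- support(sub, d)
      expect_gte(sub_sup, sets$support[i])
    }
  }
})

test_that("lowering an item weight never raises weighted support", {
  d <- toy4()
  w_hi <- toy_weights(w_male = 0.4, w_three = 0.3)
  w_lo <- toy_weights(w_male = 0.1, w_three = 0.3)
  for (items in list(c(sex = "Male"), c(sex = "Male", ca = "three"),
                     c(sex = "Male", class = "Heart Disease"))) {
    expect_lte(weighted_support(items, d, w_lo),
               weighted_support(items, d, w_hi))
  }
})

test_that("thresholds gate the output as configured", {
  d <- toy4()
  w <- toy_weights()
  # maximum possible weighted support on mixed-class data is < 1
  empty <- mine_frequent_itemsets(d, w, mining_config(min_wsupport = 1))
  expect_equal(nrow(empty), 0L)

  sets <- mine_frequent_itemsets(d, w, mining_config(min_wsupport = 0))
  # a pair present in every record survives at every level it can appear
  all_rows <- data.frame(f1 = "a", f2 = "b",
                         class = rep("Heart Disease", 3),
                         stringsAsFactors = FALSE)
  w2 <- structure(list(
    feature_weights = c(f1 = 0.5, f2 = 0.5),
    items = data.frame(feature = c("f1", "f2"), level = c("a", "b"),
                       w_n = 0.5, w_value = 1, w_t = c(0.7, 0.2),
                       stringsAsFactors = FALSE)), class = "warm_weights")
  sets2 <- mine_frequent_itemsets(all_rows, w2,
                                  mining_config(min_wsupport = 0.1))
  expect_true("f1=a,f2=b" %in% sets2$items)
  expect_true("class=Heart Disease,f1=a,f2=b" %in% sets2$items)

  rules <- generate_class_rules(sets2, all_rows, w2,
                                mining_config(min_confidence = 1))
  expect_true(all(rules$confidence == 1))
  # deterministic planted rule appears at confidence 1
  expect_true("f1=a,f2=b" %in% rules$antecedent)
})

test_that("mining output is deterministic and order-canonical", {
  d <- generate_synthetic(cleveland_like_spec(seed = 3, n = 80))
  counts <- load_occurrence_table()
  sig <- select_significant(counts)
  w <- build_weight_table(counts, sig, d)
  cfg <- mining_config(min_wsupport = 0.01, max_antecedent = 3)
  a <- mine_class_rules(d[, c(sig, "class")], w, cfg)
  b <- mine_class_rules(d[sample(nrow(d)), c(sig, "class")], w, cfg)
  expect_equal(a[order(a$antecedent, a$consequent), ]$confidence,
               b[order(b$antecedent, b$consequent), ]$confidence)
  expect_equal(sort(a$antecedent), sort(b$antecedent))
})
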