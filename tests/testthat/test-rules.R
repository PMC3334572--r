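test_that("published ruleset carries the printed thresholds, counts and labels", {
  rs <- published_ruleset()
  expect_length(rs, 4)
  r1 <- rs[[1]]
  expect_equal(r1$conditions[[1]]$feature, "f14")
  expect_equal(r1$conditions[[1]]$cmp, "<")
  expect_equal(r1$conditions[[1]]$threshold, 1.2)
  expect_equal(r1$label, "neutral")
  expect_equal(r1$confidence, 0.96)
  r4 <- rs[[4]]
  expect_equal(r4$label, "gene-damaging")
  expect_equal(r4$confidence, 0.86)
  got <- lapply(r4$conditions, function(c) c(c$feature, c$cmp, c$threshold))
  expect_setequal(vapply(got, paste, "", collapse = " "),
                  c("f14 > 6.2", "f18 > 0.9", "f5 > 8.7", "f15 > 6"))
  # rule 2: confidence recomputed from counts (0.91), printed value kept aside
  expect_equal(rs[[2]]$confidence, 0.91)
  expect_equal(rs[[2]]$metadata$printed_confidence, 0.92)
})

test_that("classify applies rules in order with the documented fallback", {
  fv1 <- data.frame(f14 = 0.5, f5 = 50, f18 = 0, f15 = 20)
  expect_equal(classify(fv1), list(label = "neutral", rule_id = "R1",
                                   confidence = 0.96))
  fv4 <- data.frame(f14 = 10, f5 = 60, f18 = 5, f15 = 20)
  expect_equal(classify(fv4), list(label = "gene-damaging", rule_id = "R4",
                                   confidence = 0.86))
  # f14 in the printed gap (4.3, 6.2]: uncovered -> conservative fallback
  fvg <- data.frame(f14 = 5, f5 = 60, f18 = 5, f15 = 20)
  p <- classify(fvg)
  expect_equal(p$label, "gene-damaging")
  expect_equal(p$rule_id, "uncovered")
  expect_true(is.na(p$confidence))
  expect_equal(classify(fvg, fallback = "neutral")$label, "neutral")
  # uncomputable required feature errors, naming the feature
  expect_error(classify(data.frame(f14 = NA, f5 = 1, f18 = 1, f15 = 1)), "f14")
  # pure function: identical input, identical prediction
  expect_identical(classify(fv4), classify(fv4))
})

test_that("classify_all matches row-wise classify", {
  withr::with_seed(31, {
    tab <- data.frame(f14 = runif(200, 0, 100), f5 = runif(200, 0, 100),
                      f18 = runif(200, 0, 100), f15 = sample(0:40, 200, TRUE))
    va <- classify_all(tab)
    for (i in seq_len(50)) {
      p <- classify(tab[i, , drop = FALSE])
      expect_equal(va$label[i], p$label)
      expect_equal(va$rule_id[i], p$rule_id)
    }
  })
})

test_that("rule confidence is count ratio rounded half-up to 2 decimals", {
  expect_equal(rule_confidence(660, 687), 0.96)
  expect_equal(rule_confidence(83, 102), 0.81)
  expect_equal(rule_confidence(1024, 1193), 0.86)
  expect_equal(rule_confidence(118, 129), 0.91)
  expect_error(rule_confidence(1, 0), "positive")
  expect_error(rule_confidence(5, 4), "n_correct")
})

test_that("coverage summaries from counts and from data agree on fixtures", {
  rs <- published_ruleset()
  expect_equal(
    coverage_from_counts(rs, c(neutral = 1292L, `gene-damaging` = 1292L)),
    c(neutral = 66.6, `gene-damaging` = 79.3))
  # labeled data routed through the rules: construct rows hitting known rules
  lab <- rbind(
    data.frame(f14 = 0.5, f5 = 10, f18 = 0, f15 = 10, label = "neutral"),   # R1 ok
    data.frame(f14 = 0.5, f5 = 10, f18 = 0, f15 = 10, label = "gene-damaging"), # R1 wrong class
    data.frame(f14 = 10, f5 = 60, f18 = 5, f15 = 20, label = "gene-damaging"),  # R4 ok
    data.frame(f14 = 5, f5 = 60, f18 = 5, f15 = 20, label = "gene-damaging"))   # uncovered
  cov <- coverage_summary(rs, lab)
  expect_equal(cov[["neutral"]], 100)
  expect_equal(cov[["gene-damaging"]], round(100 * 1 / 3, 1))
  # empty class flagged undefined
  cov2 <- coverage_summary(rs, lab[lab$label == "neutral", , drop = FALSE])
  expect_true("gene-damaging" %in% attr(cov2, "undefined"))
})

test_that("extract_rules covers every training row exactly once", {
  withr::with_seed(8, {
    d <- generate_labeled_features(generator_config(n_per_class = 150, seed = 8))
    tree <- induce_tree(d, features = c("f14", "f5", "f18", "f15"))
    rules <- extract_rules(tree, d)
    expect_equal(sum(vapply(rules, `[[`, 0L, "n_covered")), nrow(d))
    # ordered by coverage, descending
    cov <- vapply(rules, `[[`, 0L, "n_covered")
    expect_true(all(diff(cov) <= 0))
    # rule predictions reproduce the tree's own predictions
    expect_equal(classify_all(d, rules)$label, predict(tree, d))
  })
})

test_that("stump and single-leaf trees extract to the expected rules", {
  d <- data.frame(f14 = c(1, 2, 3, 7, 8, 9),
                  label = rep(c("neutral", "gene-damaging"), each = 3))
  stump <- induce_tree(d, features = "f14", pruning_confidence = NA)
  rules <- extract_rules(stump, d)
  expect_length(rules, 2)
  # one leaf: empty condition set covering everything
  d1 <- data.frame(f14 = 1:5, label = rep("neutral", 5))
  leaf <- induce_tree(d1, features = "f14")
  r1 <- extract_rules(leaf, d1)
  expect_length(r1, 1)
  expect_length(r1[[1]]$conditions, 0)
  expect_equal(r1[[1]]$n_covered, 5)
})

test_that("a tree planted with the published thresholds round-trips through extraction", {
  # hand-built tree encoding R1 at the root and R4's f15 test below
  leaf <- function(lbl) list(type = "leaf", label = lbl,
                             counts = c(`gene-damaging` = 0, neutral = 0))
  planted <- structure(list(
    root = list(type = "node", feature = "f14", threshold = 1.2,
                left = leaf("neutral"),
                right = list(type = "node", feature = "f15", threshold = 6,
                             left = leaf("neutral"),
                             right = leaf("gene-damaging"))),
    features = c("f14", "f15"), pruning_confidence = NA, min_leaf = 2L),
    class = "decision_tree")
  train <- data.frame(f14 = c(0.5, 3, 8), f15 = c(1, 3, 10),
                      label = c("neutral", "neutral", "gene-damaging"))
  rules <- extract_rules(planted, train)
  th <- sort(unique(unlist(lapply(rules, function(r)
    vapply(r$conditions, `[[`, 0, "threshold")))))
  expect_equal(th, c(1.2, 6))
  # note: extraction emits <=/>; the planted splits are recovered exactly
  expect_equal(sum(vapply(rules, `[[`, 0L, "n_covered")), 3L)
})

test_that("ruleset JSON serialization round-trips", {
  rs <- published_ruleset()
  f <- tempfile(fileext = ".json")
  write_ruleset(rs, f)
  rs2 <- read_ruleset(f)
  expect_length(rs2, 4)
  expect_equal(rs2[[4]]$label, rs[[4]]$label)
  expect_equal(rs2[[4]]$confidence, 0.86)
  expect_equal(rs2[[1]]$conditions[[1]]$threshold, 1.2)
  tab <- data.frame(f14 = c(0.1, 50), f5 = c(1, 50), f18 = c(0, 50),
                    f15 = c(0, 50))
  expect_equal(classify_all(tab, rs2)$label, classify_all(tab, rs)$label)
})
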