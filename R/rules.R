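#' Construct a rule condition
#'
#' @param feature feature name (e.g. `"f14"`)
#' @param cmp one of `"<"`, `"<="`, `">"`, `">="`
#' @param threshold numeric threshold on the feature's native scale
#' @return a `rule_condition` list
#' @export
rule_condition <- function(feature, cmp, threshold) {
  if (!cmp %in% c("<", "<=", ">", ">=")) stop("unknown comparator: ", cmp)
  if (!is.finite(threshold)) stop("threshold must be finite")
  structure(list(feature = feature, cmp = cmp, threshold = threshold),
            class = "rule_condition")
}

cond_matches <- function(cond, values) {
  v <- values[[cond$feature]]
  if (is.null(v)) stop("feature not present: ", cond$feature)
  switch(cond$cmp,
         "<"  = v <  cond$threshold,
         "<=" = v <= cond$threshold,
         ">"  = v >  cond$threshold,
         ">=" = v >= cond$threshold)
}

#' Construct a rule path
#'
#' A rule path is a conjunction of threshold conditions with a class label
#' and, when available, coverage counts from the training data. The
#' confidence is the fraction of covered training samples that the label
#' classifies correctly, rounded half-up to two decimals.
#'
#' @param rule_id identifier
#' @param conditions list of [rule_condition()]s
#' @param label `"gene-damaging"` or `"neutral"`
#' @param n_covered,n_correct training-sample counts (optional)
#' @param metadata optional named list kept on the rule
#' @return a `rule_path` list
#' @export
rule_path <- function(rule_id, conditions, label,
                      n_covered = NA_integer_, n_correct = NA_integer_,
                      metadata = list()) {
  if (!label %in% fs_labels()) stop("unknown label: ", label)
  conf <- if (!is.na(n_covered) && n_covered > 0)
    rule_confidence(n_correct, n_covered) else NA_real_
  structure(list(rule_id = rule_id, conditions = conditions, label = label,
                 n_covered = as.integer(n_covered),
                 n_correct = as.integer(n_correct),
                 confidence = conf, metadata = metadata),
            class = "rule_path")
}

#' @export
print.rule_path <- function(x, ...) {
  conds <- if (length(x$conditions) == 0) "TRUE" else
    paste(vapply(x$conditions, function(c)
      sprintf("%s %s %g", c$feature, c$cmp, c$threshold), ""), collapse = " & ")
  cat(sprintf("%s: IF %s THEN %s  [%s/%s, conf %s]\n", x$rule_id, conds,
              x$label, x$n_correct, x$n_covered, format(x$confidence)))
  invisible(x)
}

#' Rule confidence from coverage counts
#'
#' @param n_correct,n_covered integer counts, `0 <= n_correct <= n_covered`
#' @return `n_correct / n_covered` rounded half-up to 2 decimals
#' @export
rule_confidence <- function(n_correct, n_covered) {
  if (n_covered <= 0) stop("n_covered must be positive")
  if (n_correct < 0 || n_correct > n_covered)
    stop("n_correct must lie in [0, n_covered]")
  round_half_up(n_correct / n_covered, 2)
}

#' The published four-rule classifier
#'
#' Returns the four high-coverage, high-confidence rules with their
#' training-sample counts. Confidences are recomputed from the counts;
#' rule 2's printed confidence (0.92) differs from its counts
#' (118/129 = 0.91) and is kept as metadata.
#'
#' Thresholds: `f14` (% conserved DNA bases affected) at 1.2 / 4.3 / 6.2,
#' `f5` (max relative location, %) at 85.5 / 8.7, `f18` (% conserved amino
#' acids lost) at 0.9, `f15` (distance to exon boundary, bp) at 6.
#'
#' @return list of four [rule_path()]s, in matching order R1..R4
#' @export
published_ruleset <- function() {
  list(
    rule_path("R1", list(rule_condition("f14", "<", 1.2)),
              NEUTRAL, n_covered = 687L, n_correct = 660L),
    rule_path("R2", list(rule_condition("f14", "<=", 4.3),
                         rule_condition("f5", "<=", 85.5)),
              NEUTRAL, n_covered = 129L, n_correct = 118L,
              metadata = list(printed_confidence = 0.92)),
    rule_path("R3", list(rule_condition("f14", "<=", 4.3),
                         rule_condition("f18", "<=", 0.9),
                         rule_condition("f5", ">", 85.5)),
              NEUTRAL, n_covered = 102L, n_correct = 83L),
    rule_path("R4", list(rule_condition("f14", ">", 6.2),
                         rule_condition("f18", ">", 0.9),
                         rule_condition("f5", ">", 8.7),
                         rule_condition("f15", ">", 6)),
              DAMAGING, n_covered = 1193L, n_correct = 1024L)
  )
}

#' Classify a feature vector with a rule set
#'
#' Rules are tested in order; the first rule whose conditions all hold
#' determines the label and confidence. The published four rules do not
#' partition feature space, so uncovered vectors fall back to a policy
#' (default `"gene-damaging"`, the conservative choice for a screening
#' tool) with `rule_id = "uncovered"` and no confidence.
#'
#' @param fv one-row data frame (or named list) with the features the rules
#'   test; required features must be non-`NA`
#' @param ruleset list of [rule_path()]s (default: [published_ruleset()])
#' @param fallback label for uncovered vectors
#' @return list with `label`, `rule_id`, `confidence`
#' @export
classify <- function(fv, ruleset = published_ruleset(),
                     fallback = c("gene-damaging", "neutral")) {
  fallback <- match.arg(fallback)
  needed <- unique(unlist(lapply(ruleset, function(r)
    vapply(r$conditions, `[[`, "", "feature"))))
  for (nm in needed) {
    v <- fv[[nm]]
    if (is.null(v) || is.na(v))
      stop("required feature uncomputable or missing: ", nm)
  }
  for (r in ruleset) {
    if (length(r$conditions) == 0 ||
        all(vapply(r$conditions, cond_matches, TRUE, values = fv)))
      return(list(label = r$label, rule_id = r$rule_id,
                  confidence = r$confidence))
  }
  list(label = fallback, rule_id = "uncovered", confidence = NA_real_)
}

#' Classify every row of a feature table
#'
#' Vectorized version of [classify()]: first matching rule (in ruleset
#' order) wins, uncovered rows fall back.
#'
#' @param tab data frame of feature columns
#' @param ruleset list of [rule_path()]s
#' @param fallback label for uncovered rows
#' @return data frame with `label`, `rule_id`, `confidence` (one row per
#'   input row)
#' @export
classify_all <- function(tab, ruleset = published_ruleset(),
                         fallback = c("gene-damaging", "neutral")) {
  fallback <- match.arg(fallback)
  needed <- unique(unlist(lapply(ruleset, function(r)
    vapply(r$conditions, `[[`, "", "feature"))))
  for (nm in needed) {
    if (is.null(tab[[nm]])) stop("required feature missing: ", nm)
    if (anyNA(tab[[nm]]))
      stop("required feature uncomputable or missing: ", nm)
  }
  n <- nrow(tab)
  label <- rep(fallback, n)
  rule_id <- rep("uncovered", n)
  confidence <- rep(NA_real_, n)
  unassigned <- rep(TRUE, n)
  for (r in ruleset) {
    hit <- rep(TRUE, n)
    for (cond in r$conditions) hit <- hit & cond_matches(cond, tab)
    take <- hit & unassigned
    label[take] <- r$label
    rule_id[take] <- r$rule_id
    confidence[take] <- r$confidence
    unassigned <- unassigned & !take
  }
  data.frame(label = label, rule_id = rule_id, confidence = confidence,
             stringsAsFactors = FALSE)
}

#' Per-class rule coverage of a labeled dataset
#'
#' For each class, the percentage of that class's examples whose
#' first-matching rule carries the class's own label (i.e. examples
#' correctly captured by the rules), to one decimal.
#'
#' @param ruleset list of [rule_path()]s
#' @param labeled data frame of feature columns plus `label`
#' @return named numeric vector, one percentage per class (`NA` and flagged
#'   via the `undefined` attribute for empty classes)
#' @export
coverage_summary <- function(ruleset, labeled) {
  if (nrow(labeled) == 0) stop("labeled set is empty")
  out <- setNames(rep(NA_real_, 2), fs_labels())
  undefined <- character()
  for (cls in fs_labels()) {
    rows <- labeled[labeled$label == cls, , drop = FALSE]
    if (nrow(rows) == 0) { undefined <- c(undefined, cls); next }
    p <- classify_all(rows, ruleset)
    hit <- p$rule_id != "uncovered" & p$label == cls
    out[cls] <- round_half_up(100 * mean(hit), 1)
  }
  attr(out, "undefined") <- undefined
  out
}

#' Per-class coverage recomputed from rule counts
#'
#' Uses each rule's stored `n_correct` and a per-class total to reproduce
#' printed coverage percentages without the training data.
#'
#' @param ruleset list of [rule_path()]s with counts
#' @param class_totals named integer vector of per-class totals
#' @return named numeric vector of percentages, one decimal
#' @export
coverage_from_counts <- function(ruleset, class_totals) {
  out <- setNames(rep(NA_real_, length(class_totals)), names(class_totals))
  for (cls in names(class_totals)) {
    correct <- sum(vapply(ruleset, function(r)
      if (identical(r$label, cls)) r$n_correct else 0L, 0L))
    out[cls] <- round_half_up(100 * correct / class_totals[[cls]], 1)
  }
  out
}

#' Extract rules from a decision tree
#'
#' Follows every root-to-leaf path and emits one [rule_path()] per leaf;
#' coverage counts are computed by routing the training examples down the
#' tree (each example reaches exactly one leaf). Rules are ordered by
#' `n_covered`, descending.
#'
#' @param tree a [induce_tree()] decision tree
#' @param training data frame of feature columns plus `label`
#' @return list of [rule_path()]s
#' @export
extract_rules <- function(tree, training) {
  if (is.null(tree)) return(list())
  paths <- list()
  walk <- function(node, conds) {
    if (node$type == "leaf") {
      paths[[length(paths) + 1L]] <<- list(conds = conds, label = node$label)
    } else {
      walk(node$left, c(conds, list(rule_condition(node$feature, "<=", node$threshold))))
      walk(node$right, c(conds, list(rule_condition(node$feature, ">", node$threshold))))
    }
  }
  walk(tree$root, list())
  rules <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    covered <- rep(TRUE, nrow(training))
    for (cond in p$conds) covered <- covered & cond_matches(cond, training)
    n_cov <- sum(covered)
    n_cor <- sum(covered & training$label == p$label)
    rule_path(sprintf("L%d", i), p$conds, p$label,
              n_covered = n_cov,
              n_correct = n_cor)
  })
  rules[order(-vapply(rules, `[[`, 0L, "n_covered"))]
}

#' Serialize a rule set to JSON
#'
#' @param ruleset list of [rule_path()]s
#' @param path output file
#' @return `path`, invisibly
#' @export
write_ruleset <- function(ruleset, path) {
  obj <- lapply(ruleset, function(r) list(
    rule_id = r$rule_id,
    conditions = lapply(r$conditions, function(c)
      list(feature = c$feature, cmp = c$cmp, threshold = c$threshold)),
    label = r$label, n_covered = r$n_covered, n_correct = r$n_correct,
    confidence = r$confidence))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a rule set written by [write_ruleset()]
#'
#' @param path input file
#' @return list of [rule_path()]s
#' @export
read_ruleset <- function(path) {
  obj <- jsonlite::read_json(path)
  lapply(obj, function(r) rule_path(
    r$rule_id,
    lapply(r$conditions, function(c) rule_condition(c$feature, c$cmp, c$threshold)),
    r$label,
    n_covered = r$n_covered %||% NA_integer_,
    n_correct = r$n_correct %||% NA_integer_))
}
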