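#' @name decision_tree
#' @title C4.5-style decision-tree induction
#'
#' @description
#' Binary numeric splits (`<=` left, `>` right) chosen by information-gain
#' maximisation, with C4.5-style post-pruning: a subtree is replaced by a
#' leaf when the leaf's pessimistic error estimate (upper confidence limit
#' of the binomial error at confidence `pruning_confidence`) does not exceed
#' the subtree's. Candidate thresholds are midpoints between consecutive
#' distinct feature values; splits leaving fewer than `min_leaf` rows on a
#' side are not considered. Ties between equal-gain splits go to the
#' earlier feature in `features` order, then the lower threshold.
NULL

entropy_counts <- function(pos, neg) {
  n <- pos + neg
  p <- c(pos, neg) / n
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Best split for one feature: returns c(gain, threshold) or NULL.
best_split_feature <- function(x, y_pos, min_leaf) {
  n <- length(x)
  o <- order(x)
  xs <- x[o]; ys <- y_pos[o]
  cum_pos <- cumsum(ys)
  total_pos <- cum_pos[n]
  i <- seq_len(n - 1L)
  valid <- xs[i] != xs[i + 1L] & i >= min_leaf & (n - i) >= min_leaf
  if (!any(valid)) return(NULL)
  i <- i[valid]
  lp <- cum_pos[i]; ln <- i - lp
  rp <- total_pos - lp; rn <- (n - i) - rp
  h <- function(p, q) {
    t <- p + q
    out <- numeric(length(t))
    nz <- p > 0 & q > 0
    out[nz] <- -(p[nz] / t[nz]) * log2(p[nz] / t[nz]) -
      (q[nz] / t[nz]) * log2(q[nz] / t[nz])
    out
  }
  parent <- entropy_counts(total_pos, n - total_pos)
  gain <- parent - ((i / n) * h(lp, ln) + ((n - i) / n) * h(rp, rn))
  best <- which.max(gain)
  c(gain = gain[best], threshold = (xs[i[best]] + xs[i[best] + 1L]) / 2)
}

node_leaf <- function(labels) {
  pos <- sum(labels == DAMAGING)
  neg <- length(labels) - pos
  label <- if (pos >= neg) DAMAGING else NEUTRAL
  list(type = "leaf", label = label,
       counts = c(`gene-damaging` = pos, neutral = neg))
}

grow_node <- function(data, features, min_leaf) {
  labels <- data$label
  n <- nrow(data)
  if (n < 2L * min_leaf || length(unique(labels)) == 1L)
    return(node_leaf(labels))
  y_pos <- labels == DAMAGING
  best <- NULL; best_f <- NULL
  for (f in features) {
    sp <- best_split_feature(data[[f]], y_pos, min_leaf)
    if (is.null(sp)) next
    if (is.null(best) || sp[["gain"]] > best[["gain"]] + 1e-12) {
      best <- sp; best_f <- f
    }
  }
  if (is.null(best) || best[["gain"]] <= 1e-12) return(node_leaf(labels))
  left <- data[[best_f]] <= best[["threshold"]]
  list(type = "node", feature = best_f, threshold = best[["threshold"]],
       counts = c(`gene-damaging` = sum(y_pos), neutral = sum(!y_pos)),
       left = grow_node(data[left, , drop = FALSE], features, min_leaf),
       right = grow_node(data[!left, , drop = FALSE], features, min_leaf))
}

# C4.5 pessimistic error: N * upper confidence limit of the binomial error
# rate at confidence CF (Clopper-Pearson upper bound).
pessimistic_errors <- function(E, N, cf) {
  if (N == 0) return(0)
  u <- if (E >= N) 1 else qbeta(1 - cf, E + 1, N - E)
  N * u
}

prune_node <- function(node, cf) {
  if (node$type == "leaf") return(node)
  node$left <- prune_node(node$left, cf)
  node$right <- prune_node(node$right, cf)
  subtree_err <- function(nd) {
    if (nd$type == "leaf") {
      N <- sum(nd$counts)
      return(pessimistic_errors(N - max(nd$counts), N, cf))
    }
    subtree_err(nd$left) + subtree_err(nd$right)
  }
  N <- sum(node$counts)
  leaf_err <- pessimistic_errors(N - max(node$counts), N, cf)
  if (leaf_err <= subtree_err(node) + 1e-9) {
    label <- names(node$counts)[which.max(node$counts)]
    return(list(type = "leaf", label = label, counts = node$counts))
  }
  node
}

#' Induce a decision tree
#'
#' @param data data frame with numeric feature columns and a `label` column
#'   (`"gene-damaging"` / `"neutral"`)
#' @param features feature columns to use (default: all non-label numerics)
#' @param pruning_confidence C4.5-style pruning confidence (default 0.25);
#'   `NA` disables pruning
#' @param min_leaf minimum rows per leaf (default 2)
#' @return an object of class `decision_tree`
#' @export
induce_tree <- function(data, features = NULL, pruning_confidence = 0.25,
                        min_leaf = 2L) {
  if (nrow(data) < 1) stop("no training rows")
  if (is.null(features))
    features <- setdiff(names(data)[vapply(data, is.numeric, TRUE)], "label")
  if (length(features) < 1) stop("no features")
  bad <- !features %in% names(data)
  if (any(bad)) stop("unknown feature(s): ", paste(features[bad], collapse = ", "))
  root <- grow_node(data[, c(features, "label"), drop = FALSE], features,
                    as.integer(min_leaf))
  if (!is.na(pruning_confidence)) root <- prune_node(root, pruning_confidence)
  structure(list(root = root, features = features,
                 pruning_confidence = pruning_confidence,
                 min_leaf = as.integer(min_leaf)),
            class = "decision_tree")
}

#' Predict with a decision tree
#'
#' @param object a `decision_tree`
#' @param newdata data frame with the tree's feature columns
#' @param ... unused
#' @return character vector of labels
#' @export
predict.decision_tree <- function(object, newdata, ...) {
  out <- character(nrow(newdata))
  recurse <- function(node, idx) {
    if (length(idx) == 0) return(invisible(NULL))
    if (node$type == "leaf") {
      out[idx] <<- node$label
      return(invisible(NULL))
    }
    left <- newdata[[node$feature]][idx] <= node$threshold
    recurse(node$left, idx[left])
    recurse(node$right, idx[!left])
  }
  recurse(object$root, seq_len(nrow(newdata)))
  out
}

n_leaves <- function(node) {
  if (node$type == "leaf") return(1L)
  n_leaves(node$left) + n_leaves(node$right)
}

#' @export
print.decision_tree <- function(x, ...) {
  cat(sprintf("<decision_tree> %d leaves on features: %s\n",
              n_leaves(x$root), paste(x$features, collapse = ", ")))
  invisible(x)
}

#' Serialize a decision tree to JSON
#'
#' @param tree a `decision_tree`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_tree <- function(tree, path) {
  strip <- function(nd) {
    if (nd$type == "leaf")
      list(type = "leaf", label = nd$label, counts = as.list(nd$counts))
    else list(type = "node", feature = nd$feature, threshold = nd$threshold,
              left = strip(nd$left), right = strip(nd$right))
  }
  jsonlite::write_json(list(features = tree$features,
                            pruning_confidence = tree$pruning_confidence,
                            min_leaf = tree$min_leaf,
                            root = strip(tree$root)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a decision tree written by [write_tree()]
#'
#' @param path input file
#' @return a `decision_tree`
#' @export
read_tree <- function(path) {
  obj <- jsonlite::read_json(path)
  rebuild <- function(nd) {
    if (nd$type == "leaf")
      list(type = "leaf", label = nd$label,
           counts = unlist(nd$counts))
    else list(type = "node", feature = nd$feature, threshold = nd$threshold,
              left = rebuild(nd$left), right = rebuild(nd$right))
  }
  structure(list(root = rebuild(obj$root),
                 features = unlist(obj$features),
                 pruning_confidence = obj$pruning_confidence,
                 min_leaf = obj$min_leaf),
            class = "decision_tree")
}
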