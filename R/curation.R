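#' @name curation
#' @title Dataset-curation filters
#'
#' @description
#' Filters used to build clean training sets from raw indel calls: one
#' indel per gene (with a pseudogene rule for the neutral set), a sequencing
#' quality window, a neighbor-distance rule, and multi-species concordance.
#' Every filter returns its result together with a `filter_report` so that
#' `n_in == n_out + nrow(removed)` always holds.
NULL

filter_report <- function(n_in, n_out, removed) {
  stopifnot(n_in - n_out == nrow(removed))
  structure(list(n_in = n_in, n_out = n_out, removed = removed),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d in, %d out, %d removed\n",
              x$n_in, x$n_out, nrow(x$removed)))
  invisible(x)
}

empty_removed <- function() {
  data.frame(id = character(), reason = character(), stringsAsFactors = FALSE)
}

#' Write a filter report's removal list as TSV
#' @param report a `filter_report`
#' @param path output file
#' @export
write_filter_report <- function(report, path) {
  write.table(report$removed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' One indel per gene
#'
#' Disease mode: keep one uniformly random indel per gene (avoids
#' over-training on heavily reported genes). Neutral mode: a gene (within
#' one species) carrying more than one frameshifting indel is assumed to be
#' a pseudogene and *all* of its indels are removed; genes with a single FS
#' indel keep it.
#'
#' @param indels an [indel_set()] with a `gene_id` column (and `species`
#'   for neutral mode)
#' @param mode `"disease"` or `"neutral"`
#' @param seed integer seed (disease-mode random choice)
#' @return list `(indels, report)`
#' @export
one_per_gene <- function(indels, mode = c("disease", "neutral"), seed = 1L) {
  mode <- match.arg(mode)
  if (!"gene_id" %in% names(indels)) stop("indels need a gene_id column")
  keep <- rep(TRUE, nrow(indels))
  reason <- rep(NA_character_, nrow(indels))
  if (mode == "disease") {
    withr::with_seed(seed, {
      for (g in unique(indels$gene_id)) {
        idx <- which(indels$gene_id == g)
        if (length(idx) > 1) {
          drop <- setdiff(idx, sample(idx, 1))
          keep[drop] <- FALSE
          reason[drop] <- "one-per-gene"
        }
      }
    })
  } else {
    grp <- paste(indels$gene_id,
                 if ("species" %in% names(indels)) indels$species else "",
                 sep = "\r")
    fs <- is_frameshifting(indels)
    for (g in unique(grp)) {
      idx <- which(grp == g)
      if (sum(fs[idx]) > 1) {
        keep[idx] <- FALSE
        reason[idx] <- "pseudogene-multiple-fs"
      }
    }
  }
  removed <- data.frame(id = indels$id[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  list(indels = indels[keep, , drop = FALSE],
       report = filter_report(nrow(indels), sum(keep), removed))
}

#' Sequencing-quality window filter
#'
#' An indel is kept only if every base in a window around it (default 10 bp
#' total, half on each side of the affected interval) has quality at least
#' `min_q`. Missing quality data removes the indel with reason
#' `"no-quality-data"`.
#'
#' @param indels an [indel_set()]
#' @param qualities a [dna_track()]-like object holding per-base integer
#'   qualities (its `threshold` is ignored)
#' @param window total window size in bp (default 10)
#' @param min_q minimum per-base quality (default 9)
#' @return list `(indels, report)`
#' @export
quality_window_filter <- function(indels, qualities, window = 10L, min_q = 9L) {
  half <- as.integer(window) %/% 2L
  iv <- indel_interval(indels)
  keep <- rep(TRUE, nrow(indels))
  reason <- rep(NA_character_, nrow(indels))
  for (i in seq_len(nrow(indels))) {
    pos <- seq.int(iv$start[i] - half, iv$end[i] + half - 1L)
    q <- track_scores(qualities, indels$chrom[i], pos)
    if (anyNA(q)) {
      keep[i] <- FALSE; reason[i] <- "no-quality-data"
    } else if (any(q < min_q)) {
      keep[i] <- FALSE; reason[i] <- "low-quality-window"
    }
  }
  removed <- data.frame(id = indels$id[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  list(indels = indels[keep, , drop = FALSE],
       report = filter_report(nrow(indels), sum(keep), removed))
}

#' Neighbor-distance filter
#'
#' Removes every indel whose nearest neighbor on the same chromosome lies
#' closer than `min_gap` bp (edge-to-edge between affected intervals);
#' removal is symmetric — both members of a close pair go. Used with
#' `min_gap = 30` for the high-confidence neutral set and `min_gap = 5`
#' for the relaxed set.
#'
#' @param indels an [indel_set()]
#' @param min_gap minimum allowed distance in bp
#' @return list `(indels, report)`
#' @export
neighbor_distance_filter <- function(indels, min_gap) {
  n <- nrow(indels)
  keep <- rep(TRUE, n)
  iv <- indel_interval(indels)
  for (chrom in unique(indels$chrom)) {
    idx <- which(indels$chrom == chrom)
    if (length(idx) < 2) next
    o <- idx[order(iv$start[idx])]
    s <- iv$start[o]; e <- iv$end[o]
    m <- length(o)
    for (i in seq_len(m - 1L)) {
      j <- i + 1L
      while (j <= m && s[j] - e[i] < min_gap) {  # edge-to-edge; overlap < 0
        keep[o[c(i, j)]] <- FALSE
        j <- j + 1L
      }
    }
  }
  removed <- data.frame(id = indels$id[!keep],
                        reason = rep("near-neighbor", sum(!keep)),
                        stringsAsFactors = FALSE)
  list(indels = indels[keep, , drop = FALSE],
       report = filter_report(n, sum(keep), removed))
}

#' Multi-species concordance filter
#'
#' Keeps an indel only when an identical call (same chromosome, position,
#' and alleles, after normalization) is observed in at least two species of
#' the same lineage. An indel seen in, say, mouse and rat (both rodents)
#' passes; the same call seen only in mouse and dog does not.
#'
#' @param calls named list: species -> [indel_set()]
#' @param lineages named character vector: species -> lineage
#' @return an [indel_set()] of the surviving unique calls (first occurrence
#'   kept), with a `n_species` column
#' @export
multispecies_concordance_filter <- function(calls, lineages) {
  unknown <- setdiff(names(calls), names(lineages))
  if (length(unknown))
    stop("species without lineage assignment: ", paste(unknown, collapse = ", "))
  rows <- do.call(rbind, lapply(names(calls), function(sp) {
    x <- as.data.frame(calls[[sp]])
    if (nrow(x) == 0) return(NULL)
    x$species <- sp
    x$lineage <- lineages[[sp]]
    x
  }))
  if (is.null(rows)) return(empty_indel_set())
  key <- paste(rows$chrom, rows$pos, rows$ref, rows$alt, sep = "\r")
  keep_key <- vapply(split(rows, key), function(g) {
    any(table(unique(g[, c("species", "lineage")])$lineage) >= 2)
  }, TRUE)
  surv <- rows[key %in% names(keep_key)[keep_key], , drop = FALSE]
  key2 <- paste(surv$chrom, surv$pos, surv$ref, surv$alt, sep = "\r")
  first <- !duplicated(key2)
  out <- indel_set(surv$chrom[first], surv$pos[first], surv$ref[first],
                   surv$alt[first], id = surv$id[first], af = surv$af[first])
  out$n_species <- as.integer(table(key2)[key2[first]])
  out
}
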