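#' Assign each indel to the gene(s) whose transcript span contains it
#'
#' @param indels an [indel_set()]
#' @param db gene-keyed transcript list from [read_transcripts()]
#' @return list (one element per indel row) of gene ids; empty when the
#'   indel overlaps no annotated transcript
#' @export
assign_genes <- function(indels, db) {
  lapply(seq_len(nrow(indels)), function(i) {
    a <- indel_affected_start(indels[i, , drop = FALSE])
    hits <- character()
    for (g in names(db)) {
      for (t in db[[g]]) {
        if (t$chrom != indels$chrom[i]) next
        sp <- transcript_span(t)
        if (a >= sp[1] && a < sp[2]) { hits <- c(hits, g); break }
      }
    }
    unique(hits)
  })
}

#' Feature table for a set of indels
#'
#' Runs [extract_features()] on every frameshifting, coding indel; rows
#' that are out of scope (not frameshifting, no gene, no coding overlap)
#' are reported in the `skipped` attribute with a reason.
#'
#' @param indels an [indel_set()]
#' @param db gene-keyed transcript list
#' @param dna_track,protein_track conservation tracks (or `NULL`)
#' @return data frame `indel_id`, `gene_id`, `f14`, `f5`, `f18`, `f15` plus
#'   registered extras; attribute `skipped`: data frame (`id`, `reason`)
#' @export
extract_feature_table <- function(indels, db, dna_track = NULL,
                                  protein_track = NULL) {
  genes <- assign_genes(indels, db)
  rows <- list()
  skipped <- list()
  for (i in seq_len(nrow(indels))) {
    one <- indels[i, , drop = FALSE]
    if (!is_frameshifting(one)) {
      skipped[[length(skipped) + 1L]] <- c(one$id, "not-frameshifting"); next
    }
    if (length(genes[[i]]) == 0) {
      skipped[[length(skipped) + 1L]] <- c(one$id, "no-gene"); next
    }
    g <- genes[[i]][1]
    fv <- tryCatch(
      extract_features(one, db[[g]], dna_track, protein_track),
      error = function(e) NULL)
    if (is.null(fv)) {
      skipped[[length(skipped) + 1L]] <- c(one$id, "no-coding-overlap"); next
    }
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(indel_id = one$id, gene_id = g, stringsAsFactors = FALSE), fv)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(indel_id = character(), gene_id = character(),
               f14 = numeric(), f5 = numeric(), f18 = numeric(),
               f15 = numeric())
  attr(out, "skipped") <- if (length(skipped))
    data.frame(id = vapply(skipped, `[`, "", 1),
               reason = vapply(skipped, `[`, "", 2), stringsAsFactors = FALSE)
  else data.frame(id = character(), reason = character())
  out
}

#' Allele-frequency spectrum of damaging predictions
#'
#' Bins predictions by allele frequency (half-open bins `[lo, hi)`; the
#' last bin is closed) and reports the fraction predicted gene-damaging in
#' each bin. Empty bins are `NA`, not zero.
#'
#' @param predictions data frame with `af` and `label` columns
#' @param bin_edges increasing numeric vector of bin edges in `[0, 1]`;
#'   the default cut points follow the conventional allele-frequency bands
#'   (rare < 0.05, 0.05-0.10, 0.10-0.20, common > 0.20)
#' @return data frame `bin_lo`, `bin_hi`, `n`, `n_damaging`,
#'   `fraction_damaging`
#' @export
af_spectrum <- function(predictions,
                        bin_edges = c(0, 0.05, 0.10, 0.20, 0.5, 1.0)) {
  af <- predictions$af
  if (anyNA(af) || any(af < 0 | af > 1))
    stop("allele frequencies must be present and in [0, 1]")
  k <- length(bin_edges) - 1L
  rows <- lapply(seq_len(k), function(b) {
    lo <- bin_edges[b]; hi <- bin_edges[b + 1L]
    sel <- af >= lo & (af < hi | (b == k & af == hi))
    n <- sum(sel)
    nd <- sum(predictions$label[sel] == DAMAGING)
    data.frame(bin_lo = lo, bin_hi = hi, n = n, n_damaging = nd,
               fraction_damaging = if (n == 0) NA_real_ else nd / n)
  })
  do.call(rbind, rows)
}
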