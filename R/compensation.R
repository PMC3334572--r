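#' @name compensation
#' @title Compensatory-indel analysis
#'
#' @description
#' A frameshifting indel knocks out the reading frame, but a second nearby
#' frameshifting indel can restore it when the *net* size of the pair (or
#' cluster) is divisible by 3. These functions cluster frameshifting indels
#' by proximity, test each cluster for frame restoration, trace the fraction
#' of restored clusters as a function of window size, and compare exon
#' clusters against intron control regions.
NULL

#' Cluster frameshifting indels by proximity
#'
#' Single-linkage chaining: consecutive indels (sorted by position) at most
#' `window` bp apart join one cluster; singletons are not clusters. When a
#' transcript model is supplied, distances are measured on the transcript
#' (cDNA) coordinate; otherwise genomic positions are used.
#'
#' @param indels an [indel_set()] on one region; all members must be
#'   frameshifting
#' @param window maximum distance (bp) chaining two indels
#' @param transcript optional [transcript_model()] for cDNA distances
#' @param region_id identifier stored on each cluster
#' @return list of `indel_cluster` objects with fields `region_id`,
#'   `members` (row indices into `indels`), `net_size`, `frame_restored`,
#'   `max_pairwise_gap`
#' @export
cluster_indels <- function(indels, window, transcript = NULL,
                           region_id = NA_character_) {
  if (nrow(indels) == 0) return(list())
  if (any(!is_frameshifting(indels)))
    stop("cluster_indels expects frameshifting indels only")
  pos <- if (is.null(transcript)) indels$pos else
    vapply(seq_len(nrow(indels)), function(i) {
      m <- genomic_to_cds(transcript, indel_affected_start(indels[i, , drop = FALSE]))
      if (m$status == "coding") as.numeric(m$offset) else NA_real_
    }, 0)
  o <- order(pos)
  pos <- pos[o]
  gaps <- diff(pos)
  grp <- cumsum(c(1, as.integer(gaps > window)))
  clusters <- list()
  for (g in unique(grp)) {
    members <- o[grp == g]
    if (length(members) < 2) next
    net <- sum(indels$net_length[members])
    clusters[[length(clusters) + 1L]] <- structure(
      list(region_id = region_id, members = members,
           net_size = as.integer(net),
           frame_restored = net %% 3L == 0L,
           max_pairwise_gap = max(diff(pos[grp == g]))),
      class = "indel_cluster")
  }
  clusters
}

#' Frame-restoration curve over window sizes
#'
#' For each window size, clusters all regions and reports the fraction of
#' clusters whose net indel size is divisible by 3.
#'
#' @param regions named list: region id -> [indel_set()] (or a list of
#'   `list(indels=, transcript=)` pairs for cDNA distances)
#' @param windows integer vector of window sizes (bp)
#' @return data frame with `window`, `n_clusters`, `n_restored`,
#'   `fraction_restored` (`NA` when a window yields no clusters)
#' @export
restoration_curve <- function(regions, windows) {
  if (length(regions) == 0)
    return(data.frame(window = integer(), n_clusters = integer(),
                      n_restored = integer(), fraction_restored = numeric()))
  rows <- lapply(windows, function(w) {
    cl <- unlist(lapply(names(regions) %||% seq_along(regions), function(r) {
      reg <- regions[[r]]
      if (inherits(reg, "indel_set") || is.data.frame(reg))
        cluster_indels(reg, w, region_id = as.character(r))
      else cluster_indels(reg$indels, w, transcript = reg$transcript,
                          region_id = as.character(r))
    }), recursive = FALSE)
    n <- length(cl)
    nr <- sum(vapply(cl, `[[`, TRUE, "frame_restored"))
    data.frame(window = w, n_clusters = n, n_restored = nr,
               fraction_restored = if (n == 0) NA_real_ else nr / n)
  })
  do.call(rbind, rows)
}

#' Exon versus intron frame-restoration enrichment
#'
#' Restricted to two-indel clusters: the fraction with net size divisible
#' by 3 is computed for exon pairs and for intron control pairs, and the
#' enrichment is their ratio rounded to two decimals.
#'
#' @param exon_pairs,intron_pairs lists of two-member `indel_cluster`s
#' @return list of class `enrichment_result` with `exon_fraction`,
#'   `intron_fraction`, `enrichment`, `n_exon_pairs`, `n_intron_pairs`;
#'   `enrichment` is `NA` (flagged) when the intron fraction is 0
#' @export
exon_intron_enrichment <- function(exon_pairs, intron_pairs) {
  check_pairs <- function(cl, what) {
    sizes <- vapply(cl, function(c) length(c$members), 0L)
    if (any(sizes != 2L)) stop(what, " must contain only 2-indel clusters")
  }
  check_pairs(exon_pairs, "exon_pairs")
  check_pairs(intron_pairs, "intron_pairs")
  frac <- function(cl)
    if (length(cl) == 0) NA_real_
    else mean(vapply(cl, `[[`, TRUE, "frame_restored"))
  ef <- frac(exon_pairs); int_f <- frac(intron_pairs)
  enr <- if (is.na(ef) || is.na(int_f) || int_f == 0) NA_real_
         else round_half_up(ef / int_f, 2)
  structure(list(exon_fraction = ef, intron_fraction = int_f,
                 enrichment = enr,
                 n_exon_pairs = length(exon_pairs),
                 n_intron_pairs = length(intron_pairs),
                 undefined = is.na(enr)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "exon %.2f (n=%d) vs intron %.2f (n=%d): enrichment %s\n",
    x$exon_fraction, x$n_exon_pairs, x$intron_fraction, x$n_intron_pairs,
    if (is.na(x$enrichment)) "undefined" else format(x$enrichment)))
  invisible(x)
}

#' Tile an intron into fixed-size control regions
#'
#' Control regions for the enrichment analysis: tiles of `tile` bp (default
#' 200) anchored at the intron's 5' end; a trailing partial tile is dropped.
#'
#' @param intron_start,intron_end 0-based half-open intron bounds
#' @param tile tile width in bp
#' @return 2-column matrix of tile bounds
#' @export
tile_intron <- function(intron_start, intron_end, tile = 200L) {
  starts <- seq.int(intron_start, intron_end, by = tile)
  starts <- starts[starts + tile <= intron_end]
  cbind(start = starts, end = starts + tile)
}
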