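#' Generator configuration
#'
#' The stated world for the synthetic-data generator: planted rule
#' thresholds default to the published values, class labels are assigned by
#' the published rules themselves, and an excluded margin band around each
#' threshold (default 10% of the threshold) keeps the planted decision
#' boundary identifiable for recovery tests.
#'
#' @param n_per_class examples per class (default 1292, the size of each
#'   class in the balanced training set)
#' @param noise_rate label-flip probability in `[0, 0.5)`
#' @param margin_frac half-width of the excluded band around each planted
#'   threshold, as a fraction of the threshold (default 0.1)
#' @param n_noise_features number of appended uninformative uniform features
#' @param compensation_p probability that a generated indel pair restores
#'   the frame (default 0.7, the observed rate for indels within 20 bp)
#' @param seed integer seed
#' @return a `generator_config` list
#' @export
generator_config <- function(n_per_class = 1292L, noise_rate = 0.02,
                             margin_frac = 0.1, n_noise_features = 0L,
                             compensation_p = 0.7, seed = 1L) {
  if (noise_rate < 0 || noise_rate >= 0.5) stop("noise_rate must be in [0, 0.5)")
  if (margin_frac <= 0) stop("margin_frac must be positive")
  structure(list(n_per_class = as.integer(n_per_class),
                 noise_rate = noise_rate, margin_frac = margin_frac,
                 n_noise_features = as.integer(n_noise_features),
                 compensation_p = compensation_p, seed = as.integer(seed)),
            class = "generator_config")
}

# thresholds the generator plants, per feature
planted_thresholds <- function() {
  list(f14 = c(1.2, 4.3, 6.2), f5 = c(8.7, 85.5), f18 = c(0.9), f15 = c(6))
}

# uniform draw on [0, hi] avoiding margin bands around each threshold
draw_outside_margins <- function(n, thresholds, margin_frac, hi = 100,
                                 integer_valued = FALSE) {
  lo_band <- thresholds * (1 - margin_frac)
  hi_band <- thresholds * (1 + margin_frac)
  out <- numeric(0)
  while (length(out) < n) {
    x <- runif(2L * n, 0, hi)
    if (integer_valued) x <- floor(x)
    bad <- rep(FALSE, length(x))
    for (k in seq_along(thresholds))
      bad <- bad | (x >= lo_band[k] & x <= hi_band[k])
    out <- c(out, x[!bad])
  }
  out[seq_len(n)]
}

#' Generate labeled feature vectors with rule-structured classes
#'
#' Samples the four features uniformly outside the margin bands around the
#' planted thresholds, assigns the true label by the published rules
#' (vectors in the gap the published rules leave uncovered are labeled
#' gene-damaging and flagged in `fallback_region`), flips each label with
#' probability `noise_rate`, and appends `n_noise_features` uninformative
#' uniform features (`noise1`, `noise2`, ...). Rejection sampling continues
#' until both classes reach `n_per_class` rows. Deterministic given the
#' config seed.
#'
#' @param cfg a [generator_config()]
#' @return data frame with columns `f14`, `f5`, `f18`, `f15`, noise
#'   features, `label`, `true_label` and `fallback_region`
#' @export
generate_labeled_features <- function(cfg) {
  th <- planted_thresholds()
  rules <- published_ruleset()
  withr::with_seed(cfg$seed, {
    per_class <- list()
    per_class[[DAMAGING]] <- list(); per_class[[NEUTRAL]] <- list()
    need <- function(cls) cfg$n_per_class -
      sum(vapply(per_class[[cls]], nrow, 0L))
    while (need(DAMAGING) > 0 || need(NEUTRAL) > 0) {
      m <- max(need(DAMAGING), need(NEUTRAL)) * 4L
      block <- data.frame(
        f14 = draw_outside_margins(m, th$f14, cfg$margin_frac),
        f5 = draw_outside_margins(m, th$f5, cfg$margin_frac),
        f18 = draw_outside_margins(m, th$f18, cfg$margin_frac),
        f15 = draw_outside_margins(m, th$f15, cfg$margin_frac, hi = 50,
                                   integer_valued = TRUE))
      pred <- classify_all(block, rules, fallback = "gene-damaging")
      block$true_label <- pred$label
      block$fallback_region <- pred$rule_id == "uncovered"
      for (cls in fs_labels()) {
        want <- need(cls)
        if (want > 0) {
          rows <- block[block$true_label == cls, , drop = FALSE]
          per_class[[cls]][[length(per_class[[cls]]) + 1L]] <-
            head(rows, want)
        }
      }
    }
    out <- rbind(do.call(rbind, per_class[[DAMAGING]]),
                 do.call(rbind, per_class[[NEUTRAL]]))
    rownames(out) <- NULL
    flip <- runif(nrow(out)) < cfg$noise_rate
    out$label <- ifelse(flip,
                        ifelse(out$true_label == DAMAGING, NEUTRAL, DAMAGING),
                        out$true_label)
    if (cfg$n_noise_features > 0)
      for (j in seq_len(cfg$n_noise_features))
        out[[paste0("noise", j)]] <- runif(nrow(out), 0, 100)
    # column order: features, noise, label bookkeeping last
    out <- out[, c(setdiff(names(out), c("true_label", "fallback_region", "label")),
                   "label", "true_label", "fallback_region")]
    out
  })
}

#' Generate a toy gene with sequence and conservation tracks
#'
#' Builds one (or more) valid transcript models on a synthetic chromosome:
#' exons separated by fixed-length introns, a CDS spanning all exons, a
#' random genome sequence, a DNA conservation track with *exactly*
#' `round(conserved_fraction * cds_length)` conserved coding bases, and a
#' per-residue protein track with the same conserved fraction. Conserved
#' positions score 2.0 and the rest 0.2 against a threshold of 1.5, so the
#' planted counts are unambiguous.
#'
#' @param n_exons number of exons
#' @param cds_length total coding length (must be a multiple of 3)
#' @param conserved_fraction fraction of coding bases planted as conserved
#' @param seed integer seed
#' @param intron_length intron size in bp (default 100)
#' @param flank bp of non-genic sequence on each side (default 50)
#' @param strand transcript strand (default `"+"`)
#' @param chrom chromosome name
#' @return list with `transcripts` (gene-keyed, as [read_transcripts()]),
#'   `genome` ([Biostrings::DNAStringSet]), `dna_track`, `protein_track`
#' @export
generate_toy_gene <- function(n_exons = 2L, cds_length = 300L,
                              conserved_fraction = 0.2, seed = 1L,
                              intron_length = 100L, flank = 50L,
                              strand = "+", chrom = "chrT") {
  if (cds_length %% 3L != 0L) stop("cds_length must be a multiple of 3")
  if (n_exons > cds_length %/% 1L) stop("infeasible exon layout")
  withr::with_seed(seed, {
    # split the CDS into n_exons nonempty chunks
    if (n_exons > 1) {
      cuts <- sort(sample(seq_len(cds_length - 1L), n_exons - 1L))
      lens <- diff(c(0L, cuts, cds_length))
    } else lens <- cds_length
    starts <- integer(n_exons)
    cur <- flank
    exons <- matrix(0L, n_exons, 2)
    for (i in seq_len(n_exons)) {
      exons[i, ] <- c(cur, cur + lens[i])
      cur <- cur + lens[i] + intron_length
    }
    chrom_len <- cur - intron_length + flank
    t <- transcript_model("TX1", "GENE1", chrom, strand, exons,
                          cds_start = exons[1, 1], cds_end = exons[n_exons, 2])
    seq <- paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
                 collapse = "")
    genome <- Biostrings::DNAStringSet(setNames(seq, chrom))

    cpos <- coding_positions(t)            # transcript order
    n_cons <- round(conserved_fraction * cds_length)
    cons_idx <- if (n_cons > 0) sort(sample(seq_along(cpos), n_cons)) else integer()
    scores <- rep(0.2, chrom_len)
    scores[cpos[cons_idx] + 1L] <- 2.0
    dna <- dna_track(chrom, 0L, scores, threshold = 1.5)

    n_res <- cds_length %/% 3L
    n_cons_res <- round(conserved_fraction * n_res)
    res_idx <- if (n_cons_res > 0) sort(sample(n_res, n_cons_res)) else integer()
    pscores <- rep(0.2, n_res)
    pscores[res_idx] <- 2.0
    prot <- protein_track(list(TX1 = pscores), threshold = 1.5)

    list(transcripts = list(GENE1 = list(TX1 = t)), genome = genome,
         dna_track = dna, protein_track = prot)
  })
}

# build a one-row indel at 0-based anchor pos with the requested net length
make_indel <- function(chrom, pos, net, id = NULL) {
  if (net == 0) stop("net length must be nonzero")
  if (net > 0) { ref <- "A"; alt <- paste(rep("A", net + 1L), collapse = "") }
  else { ref <- paste(rep("A", -net + 1L), collapse = ""); alt <- "A" }
  indel_set(chrom, pos, ref, alt, id = id)
}

#' Generate clustered frameshifting indel sets
#'
#' Places one indel pair per region: the first indel at a fixed offset and
#' the second a uniform 1..`window` bp downstream. With probability
#' `compensation_p` the pair's net size is divisible by 3 (a compensatory
#' pair, e.g. -1/-2); otherwise it is not (e.g. -1/-1). All members are
#' individually frameshifting. Deterministic given `seed`.
#'
#' @param n_regions number of regions (one pair each)
#' @param compensation_p probability of a frame-restoring pair
#' @param window maximum gap between pair members (bp)
#' @param seed integer seed
#' @return named list: region id -> [indel_set()]; the planted truth is in
#'   attribute `planted` (logical vector per region)
#' @export
generate_indel_clusters <- function(n_regions, compensation_p = 0.7,
                                    window = 20L, seed = 1L) {
  comp_pairs <- list(c(-1L, -2L), c(-2L, -1L), c(1L, 2L), c(2L, 1L), c(1L, -1L))
  noncomp_pairs <- list(c(-1L, -1L), c(1L, 1L), c(-2L, -2L), c(2L, 2L), c(1L, -2L))
  withr::with_seed(seed, {
    planted <- runif(n_regions) < compensation_p
    regions <- lapply(seq_len(n_regions), function(r) {
      sizes <- if (planted[r]) comp_pairs[[sample.int(length(comp_pairs), 1)]]
               else noncomp_pairs[[sample.int(length(noncomp_pairs), 1)]]
      gap <- sample.int(window, 1)
      p1 <- 100L
      chrom <- sprintf("region_%d", r)
      rbind(make_indel(chrom, p1, sizes[1], id = paste0(chrom, "_a")),
            make_indel(chrom, p1 + gap, sizes[2], id = paste0(chrom, "_b")))
    })
    names(regions) <- sprintf("region_%d", seq_len(n_regions))
    attr(regions, "planted") <- planted
    regions
  })
}
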