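# Fixtures: single-exon 500-bp CDS gene and a two-transcript gene.
single_exon_gene <- function() {
  transcript_model("TX1", "G", "chr1", "+", rbind(c(1000, 1500)), 1000, 1500)
}

test_that("affected region runs from the indel to the end of the CDS", {
  t <- single_exon_gene()
  # frameshift at CDS start: whole CDS
  i0 <- toy_indel("chr1", 999, -1)            # first deleted base = 1000
  expect_equal(affected_cds_region(i0, t), c(first = 0, end = 500))
  # 1-bp deletion at offset 450 of a 500-bp CDS
  i450 <- toy_indel("chr1", 1449, -1)
  expect_equal(affected_cds_region(i450, t), c(first = 450, end = 500))
  # downstream of the stop codon: no coding effect
  expect_null(affected_cds_region(toy_indel("chr1", 1600, -1), t))
})

test_that("f14: fraction of the gene's conserved DNA bases affected", {
  t <- single_exon_gene()
  # 10 conserved bases, exactly 1 downstream of the indel
  scores <- rep(0, 500)
  scores[c(10, 20, 30, 40, 50, 60, 70, 80, 90, 480) + 1] <- 2
  tr <- dna_track("chr1", 1000, scores, threshold = 1.5)
  i <- toy_indel("chr1", 1449, -1)            # affected = [450, 500)
  expect_equal(frac_conserved_dna_affected(i, list(t), tr), 10)
  # at CDS start: all conserved bases affected
  expect_equal(frac_conserved_dna_affected(toy_indel("chr1", 999, -1), list(t), tr), 100)
  # downstream of the last conserved base
  expect_equal(frac_conserved_dna_affected(toy_indel("chr1", 1490, -1), list(t), tr), 0)
  # no conservation data -> uncomputable
  expect_true(is.na(frac_conserved_dna_affected(i, list(t), NULL)))
  # zero conserved bases -> 0, flagged
  tr0 <- dna_track("chr1", 1000, rep(0, 500), threshold = 1.5)
  v <- frac_conserved_dna_affected(i, list(t), tr0)
  expect_equal(as.numeric(v), 0)
  expect_equal(attr(v, "flag"), "no-conserved-bases")
})

test_that("f5: maximum relative location across transcripts", {
  # transcript A: offset 450 of 500; transcript B: offset 300 of 600
  ta <- transcript_model("TA", "G", "chr1", "+", rbind(c(1000, 1500)), 1000, 1500)
  tb <- transcript_model("TB", "G", "chr1", "+", rbind(c(850, 1450)), 850, 1450)
  i <- toy_indel("chr1", 1149, -1)  # first affected base 1150
  expect_equal(max_relative_location(i, list(ta, tb)),
               max(100 * 150 / 500, 100 * 300 / 600))
  i2 <- toy_indel("chr1", 1449, -1) # offset 450 in A; past the end of B's CDS
  expect_equal(max_relative_location(i2, list(ta, tb)), 90)
  # first coding base -> 0
  expect_equal(max_relative_location(toy_indel("chr1", 999, -1), list(ta)), 0)
  # invariant under adding a transcript with no coding overlap
  tc <- transcript_model("TC", "G", "chr1", "+", rbind(c(5000, 5300)), 5000, 5300)
  expect_equal(max_relative_location(i, list(ta, tb, tc)),
               max_relative_location(i, list(ta, tb)))
})

test_that("f18: maximum fraction of conserved amino acids lost", {
  # 300-bp CDS -> 100 residues; 20 conserved; exactly 1 at/after codon k
  t <- transcript_model("TX1", "G", "chr1", "+", rbind(c(0, 300)), 0, 300)
  cons <- rep(0.2, 100)
  cons[c(1:19, 90)] <- 2                      # 20 conserved, one late (codon 89)
  pt <- protein_track(list(TX1 = cons), threshold = 1.5)
  i <- toy_indel("chr1", 149, -1)             # offset 150 -> codon 50
  expect_equal(max_frac_conserved_aa_lost(i, list(t), pt), 5)   # 1/20
  expect_equal(max_frac_conserved_aa_lost(toy_indel("chr1", -1 + 1, -1), list(t), pt), 100)
  pt0 <- protein_track(list(TX1 = rep(0, 100)), threshold = 1.5)
  v <- max_frac_conserved_aa_lost(i, list(t), pt0)
  expect_equal(as.numeric(v), 0)
  expect_equal(attr(v, "flag"), "no-conserved-residues")
  expect_true(is.na(max_frac_conserved_aa_lost(i, list(t), NULL)))
})

test_that("f15: minimum distance to an exon boundary", {
  # indel 3 bp from an acceptor in one transcript, 10 bp in another
  ta <- transcript_model("TA", "G", "chr1", "+", rbind(c(100, 200), c(300, 400)),
                         100, 400)
  tb <- transcript_model("TB", "G", "chr1", "+", rbind(c(293, 400)), 293, 400)
  i <- toy_indel("chr1", 302, -1)             # affected base 303
  expect_equal(min_dist_exon_boundary(i, list(ta)), 3)
  expect_equal(min_dist_exon_boundary(i, list(tb)), 10)
  expect_equal(min_dist_exon_boundary(i, list(ta, tb)), 3)
  # exon edge -> 0
  expect_equal(min_dist_exon_boundary(toy_indel("chr1", 299, -1), list(ta)), 0)
  # mid single exon: min of the two edge distances
  ts <- transcript_model("T", "G", "chr1", "+", rbind(c(0, 100)), 0, 99)
  expect_equal(min_dist_exon_boundary(toy_indel("chr1", 29, -1), list(ts)),
               min(30, 99 - 30))
})

test_that("extract_features composes the four features and rejects 3n indels", {
  g <- generate_toy_gene(n_exons = 2, cds_length = 300, conserved_fraction = 0.2,
                         seed = 5)
  t <- g$transcripts$GENE1$TX1
  pos <- cds_to_genomic(t, 90)
  fv <- extract_features(toy_indel("chrT", pos - 1L, -1), g$transcripts$GENE1,
                         g$dna_track, g$protein_track)
  expect_true(all(!is.na(fv[, c("f14", "f5", "f18", "f15")])))
  expect_equal(fv$f5, 100 * 90 / 300)
  expect_error(extract_features(toy_indel("chrT", pos - 1L, 3),
                                g$transcripts$GENE1), "not frameshifting")
  fv2 <- extract_features(toy_indel("chrT", pos - 1L, -1), g$transcripts$GENE1)
  expect_true(is.na(fv2$f14) && is.na(fv2$f18))
  expect_setequal(names(attr(fv2, "flags")), c("f14", "f18"))
})

test_that("feature registry hooks extra features into extraction", {
  register_feature("indel_size", function(indel, transcripts, tracks)
    abs(indel$net_length))
  on.exit(unregister_feature("indel_size"))
  t <- single_exon_gene()
  fv <- extract_features(toy_indel("chr1", 1200, -2), list(t))
  expect_equal(fv$indel_size, 2)
})

test_that("feature table TSV round-trips with canonical column names", {
  tab <- data.frame(indel_id = "i1", gene_id = "G", f14 = 1.5, f5 = 20,
                    f18 = 0.4, f15 = 8)
  f <- tempfile(fileext = ".tsv")
  write_feature_table(tab, f)
  header <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_true(all(c("f14_frac_cons_dna", "f5_max_rel_loc",
                    "f18_max_frac_cons_aa_lost", "f15_min_dist_exon") %in% header))
  expect_equal(read_feature_table(f), tab)
})

test_that("all four features agree with the brute-force oracle (100 random genes)", {
  withr::with_seed(99, {
    for (trial in 1:100) {
      t <- random_transcript(trial + 1000)
      cpos <- oracle_coding_positions(t$exons, t$cds_start, t$cds_end, t$strand)
      L <- length(cpos)
      # plant conservation
      cons_g <- sample(cpos, max(1, L %/% 5))
      span <- transcript_span(t)
      scores <- rep(0, span[2] + 10)
      scores[cons_g + 1L] <- 2
      tr <- dna_track("chrR", 0, scores, threshold = 1.5)
      nres <- L %/% 3
      cons_r <- seq_len(nres) %in% sample(nres, max(1, nres %/% 4))
      pt <- protein_track(setNames(list(ifelse(cons_r, 2, 0)), t$transcript_id),
                          threshold = 1.5)
      # random exonic indel
      a <- sample(cpos, 1)
      net <- sample(c(-2, -1, 1, 2), 1)
      i <- toy_indel("chrR", a - 1L, net)
      want <- oracle_features(i, t, cons_g, cons_r)
      if (is.null(want)) next
      expect_equal(as.numeric(frac_conserved_dna_affected(i, list(t), tr)),
                   want$f14)
      expect_equal(as.numeric(max_relative_location(i, list(t))), want$f5)
      expect_equal(as.numeric(max_frac_conserved_aa_lost(i, list(t), pt)),
                   want$f18)
      if (!is.na(want$f15))
        expect_equal(min_dist_exon_boundary(i, list(t)), want$f15)
    }
  })
})

test_that("f14 never increases as the indel moves 3' along the CDS", {
  withr::with_seed(7, {
    for (trial in 1:10) {
      t <- random_transcript(trial + 2000)
      cpos <- oracle_coding_positions(t$exons, t$cds_start, t$cds_end, t$strand)
      span <- transcript_span(t)
      scores <- rep(0, span[2] + 10)
      scores[sample(cpos, max(1, length(cpos) %/% 4)) + 1L] <- 2
      tr <- dna_track("chrR", 0, scores, threshold = 1.5)
      vals <- vapply(cpos, function(g)
        as.numeric(frac_conserved_dna_affected(toy_indel("chrR", g - 1L, -1),
                                               list(t), tr)), 0)
      expect_true(all(diff(vals) <= 1e-9))
    }
  })
})
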