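# Haplotype table construction, de novo variant marking and the
# junction-proximity permutation test.

test_that("pileup genotyping follows depth and allele-fraction thresholds", {
    g <- genome_model(c(chrA = strrep("A", 200)))
    mk_prop <- function(n, seqs, start = 50L) data.table(
        mol_id = seq_len(n), chrom_l = "chrA", chrom_r = "chrA",
        pos_l = start, pos_r = start + nchar(seqs[1]) - 1L, cons = seqs)
    # 30 molecules all reference -> hom_ref
    hp <- build_haplotypes(mk_prop(30L, rep(strrep("A", 10), 30)), g,
                           min_depth = 10L)
    expect_true(all(hp$gt == "hom_ref"))
    expect_equal(nrow(hp), 10L)
    # 14 ref + 16 alt at one position -> het
    seqs <- c(rep("AAAAA", 14), rep("AACAA", 16))
    hp2 <- build_haplotypes(mk_prop(30L, seqs), g, min_depth = 10L)
    expect_equal(hp2[pos == 52L, gt], "het")
    expect_setequal(unlist(hp2[pos == 52L, .(a1, a2)]), c("A", "C"))
    # depth below min_depth: position absent
    hp3 <- build_haplotypes(mk_prop(5L, rep("AAAAA", 5)), g, min_depth = 10L)
    expect_equal(nrow(hp3), 0L)
    # three alleles above threshold: uncallable, excluded
    seqs4 <- c(rep("AAAAA", 10), rep("AACAA", 10), rep("AAGAA", 10))
    hp4 <- build_haplotypes(mk_prop(30L, seqs4), g, min_depth = 10L)
    expect_false(52L %in% hp4$pos)
    expect_true(51L %in% hp4$pos)
})

test_that("N-masked consensus columns are skipped in the pileup", {
    g <- genome_model(c(chrA = strrep("A", 100)))
    pm <- data.table(mol_id = 1:12, chrom_l = "chrA", chrom_r = "chrA",
                     pos_l = 10L, pos_r = 14L,
                     cons = rep("AANAA", 12))
    hp <- build_haplotypes(pm, g, min_depth = 10L)
    expect_false(12L %in% hp$pos)
})

test_that("de novo SNVs are those absent from reference and haplotypes", {
    chr <- paste0(strrep("C", 30), strrep("G", 30))
    g <- genome_model(c(chrA = chr))
    # precise deletion-style junction joining pos 20 (L) to pos 45 (R),
    # blunt; consensus carries one variant 5 bases left of the junction
    lf <- svduplex:::left_flank_seq(g, "chrA", 20L, "L", 10L)
    rf <- svduplex:::right_flank_seq(g, "chrA", 45L, "R", 10L)
    cons <- paste0(lf, rf)
    substr(cons, 6, 6) <- "T"   # left flank, distance 5
    sv <- data.table(sv_id = "sv1", chrom1 = "chrA", pos1 = 20L, side1 = "L",
                     chrom2 = "chrA", pos2 = 45L, side2 = "R",
                     imprecise = FALSE, junction_consensus = cons,
                     junction_col = 10L, mh_left = 0L, mh_right = 0L,
                     insert_sequence = "")
    hap <- data.table(chrom = "chrA", pos = c(11:20, 45:54),
                      ref = c(rep("C", 10), rep("G", 10)),
                      a1 = c(rep("C", 10), rep("G", 10)),
                      a2 = c(rep("C", 10), rep("G", 10)),
                      gt = "hom_ref")
    data.table::setkey(hap, chrom, pos)
    dn <- call_denovo(sv, hap, g)
    expect_equal(nrow(dn$variants), 1L)
    expect_equal(dn$variants$dist, 5L)
    expect_equal(dn$variants$flank, "left")
    expect_equal(dn$variants$pos, 16L)
    expect_equal(dn$n_informative, 20L)
    # a consensus base matching a known variant allele is NOT de novo
    hap2 <- copy(hap)
    hap2[pos == 16L, `:=`(a2 = "T", gt = "het")]
    data.table::setkey(hap2, chrom, pos)
    dn2 <- call_denovo(sv, hap2, g)
    expect_equal(nrow(dn2$variants), 0L)
    # N columns are neither informative nor variant
    cons3 <- cons
    substr(cons3, 6, 6) <- "N"
    sv3 <- copy(sv); sv3[, junction_consensus := cons3]
    dn3 <- call_denovo(sv3, hap, g)
    expect_equal(nrow(dn3$variants), 0L)
    expect_equal(dn3$n_informative, 19L)
})

test_that("distances exclude microhomology bases", {
    chr <- paste0(strrep("C", 10), "TAG", strrep("C", 7), "AG", strrep("G", 8))
    g <- genome_model(c(chrM = chr))
    jseq <- paste0(genome_seq(g, "chrM", 4, 13), genome_seq(g, "chrM", 23, 30))
    jm <- svduplex:::junction_metric(g, "chrM", 13L, "L", "chrM", 23L, "R",
                                     jseq, 10L, 11L)
    expect_equal(jm$metric, 2L)
    sv <- data.table(sv_id = "s", chrom1 = "chrM", pos1 = 13L, side1 = "L",
                     chrom2 = "chrM", pos2 = 23L, side2 = "R",
                     imprecise = FALSE, junction_consensus = jseq,
                     junction_col = 10L, mh_left = jm$mh_left,
                     mh_right = jm$mh_right, insert_sequence = "")
    mp <- svduplex:::consensus_flank_map(sv[1])
    # microhomology columns carry no distance
    expect_equal(sum(is.na(mp$dist)), jm$metric)
    # first base beyond the ambiguous stretch is distance 1 on each side
    expect_equal(mp[flank == "left" & dist == 1L, col], 10L - jm$mh_left)
    expect_equal(mp[flank == "right" & dist == 1L, col],
                 11L + jm$mh_right)
})

test_that("permutation test p-values behave at the boundaries", {
    cov <- data.table(dist = 1:150, n = rep(20L, 150))
    # all variants at the minimum covered distance: nothing can be smaller
    expect_equal(junction_proximity_test(rep(1, 5), cov, iterations = 500L,
                                         seed = 2L)$p_value, 0)
    # strongly proximal variants
    pt <- junction_proximity_test(rep(1:10, 2), cov, iterations = 5000L,
                                  seed = 3L)
    expect_lt(pt$p_value, 0.01)
    # reproducible under a fixed seed; finite correction stays in (0, 1]
    a <- junction_proximity_test(c(30, 60, 90), cov, iterations = 1000L,
                                 seed = 9L)
    b <- junction_proximity_test(c(30, 60, 90), cov, iterations = 1000L,
                                 seed = 9L)
    expect_equal(a$p_value, b$p_value)
    cc <- junction_proximity_test(rep(1, 5), cov, iterations = 500L,
                                  seed = 2L, finite_correction = TRUE)
    expect_equal(cc$p_value, 1 / 501)
    expect_error(junction_proximity_test(numeric(0), cov), "no observed")
    expect_error(junction_proximity_test(1, cov[0]), "empty coverage")
})

test_that("distance coverage counts variant-bearing consensuses per distance", {
    inf <- data.table(sv_id = c("a", "a", "a", "b", "b", "c"),
                      col = 1:6,
                      dist = c(1L, 2L, 3L, 1L, 2L, 1L),
                      flank = "left")
    cov <- distance_coverage(inf, c("a", "b"))
    expect_equal(cov[dist == 1L, n], 2L)
    expect_equal(cov[dist == 3L, n], 1L)
    expect_false(any(cov$n > 2L))
})
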