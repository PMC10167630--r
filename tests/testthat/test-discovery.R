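# Cross-molecule SV assembly, duplicate purge, junction characterization,
# outer-clip recovery and target classification.

mk_cand <- function(mol_id, pos1, pos2, chrom1 = "chrA", chrom2 = "chrA",
                    side1 = "L", side2 = "R", evidence = "split",
                    sample = "s1", jseq = NA_character_, jq_l = NA_integer_,
                    jq_r = NA_integer_, pos_l = pos1 - 150L,
                    pos_r = pos2 + 150L, n_pairs = 2L, s1 = 2L, s2 = 0L,
                    duplex = FALSE, shared = FALSE, mapq = 60L) {
    data.table(
        mol_id = mol_id, chrom1 = chrom1, pos1 = pos1, side1 = side1,
        chrom2 = chrom2, pos2 = pos2, side2 = side2,
        sv_type = svduplex:::sv_type_of(chrom1, pos1, side1, chrom2, pos2,
                                        side2),
        evidence = evidence, imprecise = evidence == "gap", jseq = jseq,
        jq_l = jq_l, jq_r = jq_r, mapq1 = mapq, mapq2 = mapq,
        sample = sample, chrom_l = chrom1, pos_l = pos_l, clip_l = 0L,
        chrom_r = chrom2, pos_r = pos_r, clip_r = 0L, strand1_n = s1,
        strand2_n = s2, n_pairs = n_pairs, is_duplex = duplex,
        shared_outer = shared)
}

test_that("molecules with identical inner nodes form one SV set", {
    cands <- rbind(mk_cand(1L, 10000L, 20000L, pos_l = 9800L),
                   mk_cand(2L, 10000L, 20000L, pos_l = 9700L),
                   mk_cand(3L, 10000L, 20000L, pos_l = 9600L))
    sets <- find_sv_sets(cands, 500L)
    expect_equal(nrow(sets$svs), 1L)
    expect_equal(nrow(sets$support), 3L)
})

test_that("distant left nodes split into separate SV sets", {
    cands <- rbind(mk_cand(1L, 10000L, 20000L),
                   mk_cand(2L, 20000L, 30000L))
    sets <- find_sv_sets(cands, 1000L)
    expect_equal(nrow(sets$svs), 2L)
})

test_that("the same junction across samples merges into one cross-sample call", {
    cands <- rbind(mk_cand(1L, 10000L, 20000L, sample = "s1"),
                   mk_cand(2L, 10000L, 20000L, sample = "s2"))
    sets <- find_sv_sets(cands, 500L)
    expect_equal(nrow(sets$svs), 1L)
    expect_equal(data.table::uniqueN(sets$support$sample), 2L)
})

test_that("clustering is invariant to candidate input order", {
    set.seed(8)
    cands <- rbind(
        mk_cand(1L, 10000L, 20000L), mk_cand(2L, 10000L, 20000L),
        mk_cand(3L, 12000L, 22000L), mk_cand(4L, 12000L, 22000L),
        mk_cand(5L, 50000L, 60000L, chrom1 = "chrB", chrom2 = "chrB"))
    part <- function(cc) {
        s <- find_sv_sets(cc, 500L)$support
        unname(split(sort(s$mol_id), s$sv_id)[order(vapply(
            split(s$mol_id, s$sv_id), min, 1L))])
    }
    p1 <- part(cands)
    p2 <- part(cands[sample(.N)])
    expect_equal(p1, p2)
})

test_that("near-duplicate supporters are purged under the strict 5 bp total rule", {
    sup <- rbind(
        mk_cand(1L, 10000L, 20000L, pos_l = 9800L, pos_r = 20200L,
                n_pairs = 5L),
        # offsets (2, 2): total 4 < 5 -> the weaker molecule is removed
        mk_cand(2L, 10000L, 20000L, pos_l = 9802L, pos_r = 20202L,
                n_pairs = 1L),
        # offsets (3, 2): total 5, not < 5 -> kept
        mk_cand(3L, 10000L, 20000L, pos_l = 9803L, pos_r = 20198L,
                n_pairs = 1L))
    kept <- purge_near_duplicates(sup, 5L)
    expect_setequal(kept$mol_id, c(1L, 3L))
    # different samples are never purged against each other
    sup2 <- rbind(mk_cand(1L, 1000L, 2000L, sample = "s1"),
                  mk_cand(2L, 1000L, 2000L, sample = "s2",
                          pos_l = 849L, pos_r = 2151L))
    sup2[, pos_l := c(850L, 851L)]; sup2[, pos_r := c(2150L, 2151L)]
    expect_equal(nrow(purge_near_duplicates(sup2, 5L)), 2L)
})

test_that("gap-only calls reconstruct innermost nominal breakpoints", {
    sup <- rbind(
        mk_cand(1L, 10050L, 19990L, evidence = "gap"),
        mk_cand(2L, 10080L, 19970L, evidence = "gap"))
    gp <- reconstruct_gap_junction(sup)
    expect_equal(gp$pos1, 10080L)
    expect_equal(gp$pos2, 19970L)
})

test_that("junction metric matches hand-built blunt, microhomology and insertion cases", {
    chr <- paste0(strrep("C", 10), "TAG", strrep("C", 7), "AG", strrep("G", 8))
    g <- genome_model(c(chrM = chr))
    # microhomology +2: left flank ...AG, the two bases before the right
    # breakpoint are also AG
    jseq <- paste0(genome_seq(g, "chrM", 4, 13), genome_seq(g, "chrM", 23, 30))
    m <- svduplex:::junction_metric(g, "chrM", 13L, "L", "chrM", 23L, "R",
                                    jseq, 10L, 11L)
    expect_equal(m$metric, 2L)
    o <- junction_metric_oracle(g, "chrM", 13L, "L", "chrM", 23L, "R",
                                jseq, 10L, 11L)
    expect_equal(o$metric, 2L)
    # blunt junction: flanks share nothing
    chr2 <- paste0(strrep("A", 10), "ACGT", strrep("C", 20), "TTAG",
                   strrep("G", 10))
    g2 <- genome_model(c(chrM = chr2))
    jseq2 <- paste0(genome_seq(g2, "chrM", 5, 14), genome_seq(g2, "chrM", 35, 44))
    m2 <- svduplex:::junction_metric(g2, "chrM", 14L, "L", "chrM", 35L, "R",
                                     jseq2, 10L, 11L)
    expect_equal(m2$metric, 0L)
    # de novo insertion TT matching neither flank: metric -2
    jseq3 <- paste0(genome_seq(g2, "chrM", 5, 14), "TT",
                    genome_seq(g2, "chrM", 35, 44))
    m3 <- svduplex:::junction_metric(g2, "chrM", 14L, "L", "chrM", 35L, "R",
                                     jseq3, 10L, 13L)
    expect_equal(m3$metric, -2L)
    expect_equal(m3$insert, "TT")
    o3 <- junction_metric_oracle(g2, "chrM", 14L, "L", "chrM", 35L, "R",
                                 jseq3, 10L, 13L)
    expect_equal(o3$metric, -2L)
    expect_equal(o3$insert, "TT")
})

test_that("extension metric equals the placement-enumeration oracle on random junctions", {
    g <- mk_genome(c(chrA = 60000L, chrB = 60000L), seed = 77L)
    svduplex:::with_seed(99L, {
        n <- 1000L
        agree <- 0L
        for (i in seq_len(n)) {
            c1 <- sample(c("chrA", "chrB"), 1); c2 <- sample(c("chrA", "chrB"), 1)
            p1 <- sample(200:59800, 1); p2 <- sample(200:59800, 1)
            s1 <- sample(c("L", "R"), 1); s2 <- sample(c("L", "R"), 1)
            ins <- paste(sample(c("", "A", "C", "G", "T"), sample(0:2, 1) + 1,
                                replace = TRUE), collapse = "")
            lf <- svduplex:::left_flank_seq(g, c1, p1, s1, 40L)
            rf <- svduplex:::right_flank_seq(g, c2, p2, s2, 40L)
            jseq <- paste0(lf, ins, rf)
            qL <- nchar(lf); qR <- qL + nchar(ins) + 1L
            a <- svduplex:::junction_metric(g, c1, p1, s1, c2, p2, s2,
                                            jseq, qL, qR)
            b <- junction_metric_oracle(g, c1, p1, s1, c2, p2, s2,
                                        jseq, qL, qR)
            if (a$metric == b$metric) agree <- agree + 1L
        }
        expect_equal(agree, n)
    })
})

test_that("outer-clipped proper molecules are recovered when clips match the far flank", {
    g <- mk_genome(c(chrA = 50000L), seed = 5L)
    p1 <- 10000L; p2 <- 20000L
    svs <- data.table(
        sv_id = "sv1", chrom1 = "chrA", pos1 = p1, side1 = "L",
        chrom2 = "chrA", pos2 = p2, side2 = "R", imprecise = FALSE,
        insert_sequence = "")
    mk_prop <- function(id, clip_l, clipseq_l) data.table(
        mol_id = id, sample = "s1", chrom_l = "chrA", pos_l = p2,
        clip_l = clip_l, clipseq_l = clipseq_l, chrom_r = "chrA",
        pos_r = p2 + 300L, clip_r = 0L, clipseq_r = "", n_pairs = 1L)
    leftflank <- svduplex:::left_flank_seq(g, "chrA", p1, "L", 12L)
    good <- mk_prop(1L, 12L, leftflank)
    short <- mk_prop(2L, 3L, substr(leftflank, 10, 12))
    wrong <- mk_prop(3L, 12L, strrep("A", 12))
    rec <- recover_outer_clips(rbind(good, short, wrong), svs, g,
                               min_clip = 5L)
    expect_equal(rec$mol_id, 1L)
    # a trailing-clip molecule ending at the left breakpoint, clip matching
    # the right flank, is also recovered
    rightflank <- svduplex:::right_flank_seq(g, "chrA", p2, "R", 12L)
    tr <- data.table(
        mol_id = 4L, sample = "s1", chrom_l = "chrA", pos_l = p1 - 300L,
        clip_l = 0L, clipseq_l = "", chrom_r = "chrA", pos_r = p1,
        clip_r = 12L, clipseq_r = rightflank, n_pairs = 1L)
    rec2 <- recover_outer_clips(tr, svs, g, min_clip = 5L)
    expect_equal(rec2$mol_id, 4L)
})

test_that("target classes follow the uppercase same-locus convention", {
    bed <- tempfile(fileext = ".bed")
    writeLines(c("chrA\t9999\t20000\tt1", "chrB\t9999\t20000\tt2"), bed)
    tg <- load_targets(bed, adjacent_span = 5000L)
    cls <- classify_sv(
        chrom1 = c("chrA", "chrA", "chrA", "chrA", "chrA"),
        pos1 = c(15000L, 15000L, 15000L, 15000L, 15000L),
        chrom2 = c("chrA", "chrA", "chrB", "chrA", "chrB"),
        pos2 = c(16000L, 22000L, 15000L, 40000L, 22000L),
        targets = tg)
    #   both in t1 | T + own adjacent | two targets | target+nowhere |
    #   target to another locus's adjacent
    expect_equal(cls[1], "TT")
    expect_equal(cls[2], "TA")
    expect_equal(cls[3], "tt")
    expect_equal(cls[4], "t-")
    expect_equal(cls[5], "ta")
})

test_that("conflicting exact split junctions become distinct calls", {
    cands <- rbind(
        mk_cand(1L, 10000L, 20000L), mk_cand(2L, 10000L, 20000L),
        mk_cand(3L, 10004L, 20004L))  # within clustering reach, distinct pair
    sets <- find_sv_sets(cands, 500L)
    expect_equal(nrow(sets$svs), 2L)
})
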