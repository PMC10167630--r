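# UMI matching, source-molecule collation and consensus building.

test_that("match_umi assigns unique within-1-mismatch hits and rejects the rest", {
    expected <- c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG", "ACGTACGT")
    expect_equal(match_umi("CCCCCCCC", expected), 2L)       # exact
    expect_equal(match_umi("CCCCCCCA", expected), 2L)       # one mismatch
    expect_true(is.na(match_umi("TTTTTTTT", expected)))     # far from all
    expect_true(is.na(match_umi("AAAAAAA", expected)))      # length mismatch
    # equidistant between two expected UMIs: ambiguous, rejected
    amb <- c("AAAAAAAA", "AAAAAAAC")
    expect_true(is.na(match_umi("AAAAAAAG", amb)))
    # vectorized
    expect_equal(match_umi(c("AAAAAAAA", "ACGTACGA", NA), expected),
                 c(1L, 4L, NA))
})

test_that("the shipped 96-UMI set supports unambiguous 1-mismatch matching", {
    u <- umi_set()
    expect_length(u, 96L)
    expect_equal(match_umi(u, u), 1:96)
    mutated <- paste0("T", substr(u, 2, 8))
    mutated[substr(u, 1, 1) == "T"] <- paste0("A", substr(u, 2, 8)[substr(u, 1, 1) == "T"])
    expect_equal(match_umi(mutated, u), 1:96)
})

test_that("strand consensus applies the 0.667 fractional threshold per column", {
    # 3 identical pairs: every column called
    cc <- strand_consensus(list(rep("ACGT", 3)))
    expect_equal(cc$strand[[1]], "ACGT")
    # 7 of 11 agreeing is below threshold -> N; 8 of 11 passes
    col7 <- c(rep("A", 7), rep("C", 4))
    col8 <- c(rep("A", 8), rep("C", 3))
    cc7 <- strand_consensus(list(paste0(col7, "G")))  # 11 two-base seqs
    expect_equal(substr(cc7$strand[[1]], 1, 1), "N")
    expect_equal(substr(cc7$strand[[1]], 2, 2), "G")
    cc8 <- strand_consensus(list(paste0(col8, "G")))
    expect_equal(substr(cc8$strand[[1]], 1, 1), "A")
})

test_that("duplex consensus masks strand disagreement", {
    cc <- strand_consensus(list(rep("ACGA", 3), rep("ACGG", 3)))
    expect_equal(cc$duplex, "ACGN")
    # single-strand family yields no duplex consensus
    cc1 <- strand_consensus(list(rep("ACGT", 2)))
    expect_null(cc1$duplex)
})

test_that("family downsampling is deterministic under a fixed seed", {
    seqs <- vapply(1:20, function(i)
        paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = ""),
        "")
    a <- strand_consensus(list(seqs), max_depth = 11L, seed = 42L)
    b <- strand_consensus(list(seqs), max_depth = 11L, seed = 42L)
    expect_identical(a$strand[[1]], b$strand[[1]])
})

test_that("overlapping mates merge with quality-weighted conflict resolution", {
    s1 <- list(chrom = "c", pos = 100L, end = 129L,
               seq = strrep("A", 30), qual = strrep("I", 30))
    s2 <- list(chrom = "c", pos = 120L, end = 149L,
               seq = strrep("A", 30), qual = strrep("I", 30))
    m <- merge_overlapping_mates(s1, s2)
    expect_true(m$merged)
    expect_equal(m$pos, 100L); expect_equal(m$end, 149L)
    expect_equal(m$seq, strrep("A", 50))
    # conflicting base resolves to the higher quality read
    s2b <- s2; s2b$seq <- paste0("G", strrep("A", 29)); s2b$qual <- paste0("!", strrep("I", 29))
    m2 <- merge_overlapping_mates(s1, s2b)
    expect_equal(substr(m2$seq, 21, 21), "A")
    s2c <- s2b; s2c$qual <- strrep("I", 30)  # equal quality: tie -> N
    m3 <- merge_overlapping_mates(s1, s2c)
    expect_equal(substr(m3$seq, 21, 21), "N")
    # disjoint mates stay unmerged
    s3 <- list(chrom = "c", pos = 500L, end = 529L,
               seq = strrep("A", 30), qual = strrep("I", 30))
    expect_false(merge_overlapping_mates(s1, s3)$merged)
})

test_that("mirrored-orientation pairs with swapped UMIs form one duplex molecule", {
    g <- mk_genome()
    u <- umi_set()
    rx1 <- paste0(u[5], "-", u[9])
    rx2 <- paste0(u[9], "-", u[5])   # opposite strand: swapped order
    aln <- rbind(
        mk_pair("p1", "chrA", 1000, 1350, g, rx = rx1, orient = 1L),
        mk_pair("p2", "chrA", 1000, 1350, g, rx = rx2, orient = 2L))
    coll <- collate_molecules(aln, "ligation_duplex")
    expect_equal(nrow(coll$molecules), 1L)
    expect_equal(coll$molecules$strand1_n, 1L)
    expect_equal(coll$molecules$strand2_n, 1L)
    expect_true(coll$molecules$is_duplex)
    expect_equal(coll$molecules$umi1, 5L)
    expect_equal(coll$molecules$umi2, 9L)
})

test_that("same-orientation replicates tally one strand family", {
    g <- mk_genome()
    u <- umi_set()
    rx <- paste0(u[1], "-", u[2])
    aln <- rbind(mk_pair("p1", "chrA", 2000, 2400, g, rx = rx),
                 mk_pair("p2", "chrA", 2000, 2400, g, rx = rx))
    coll <- collate_molecules(aln, "ligation_duplex")
    expect_equal(nrow(coll$molecules), 1L)
    expect_equal(coll$molecules$strand1_n, 2L)
    expect_equal(coll$molecules$strand2_n, 0L)
    expect_false(coll$molecules$is_duplex)
})

test_that("tagmentation treats opposite orientations as distinct molecules", {
    g <- mk_genome()
    aln <- rbind(mk_pair("p1", "chrA", 3000, 3400, g, orient = 1L),
                 mk_pair("p2", "chrA", 3000, 3400, g, orient = 2L))
    coll <- collate_molecules(aln, "tagmentation")
    expect_equal(nrow(coll$molecules), 2L)
})

test_that("the 1 bp allowance bounds endpoint differences per coordinate", {
    g <- mk_genome()
    u <- umi_set(); rx <- paste0(u[1], "-", u[2])
    base <- mk_pair("p1", "chrA", 1000, 1400, g, rx = rx)
    near <- mk_pair("p2", "chrA", 1001, 1401, g, rx = rx)   # within 1 bp
    far <- mk_pair("p3", "chrA", 1002, 1400, g, rx = rx)    # 2 bp off
    coll <- collate_molecules(rbind(base, near), "ligation_duplex")
    expect_equal(nrow(coll$molecules), 1L)
    coll2 <- collate_molecules(rbind(base, far), "ligation_duplex")
    expect_equal(nrow(coll2$molecules), 2L)
})

test_that("reads with unmatched UMIs are discarded and counted", {
    g <- mk_genome()
    u <- umi_set()
    good <- mk_pair("p1", "chrA", 1000, 1400, g,
                    rx = paste0(u[1], "-", u[2]))
    bad <- mk_pair("p2", "chrA", 1000, 1400, g,
                   rx = "NNNNNNNN-NNNNNNNN")
    coll <- collate_molecules(rbind(good, bad), "ligation_duplex")
    expect_equal(nrow(coll$molecules), 1L)
    expect_equal(coll$stats$n_umi_rejected, 1L)
})

test_that("anchored grouping matches brute-force transitive closure when keys are separated", {
    # random well-separated keys (>= 3 bp apart between groups): the greedy
    # anchored pass must reproduce the all-pairs transitive grouping exactly
    for (seed in c(11L, 12L, 13L)) {
        keys <- svduplex:::with_seed(seed, {
            ngrp <- 30L
            anchors <- cumsum(sample(3:50, ngrp, replace = TRUE)) + 1000L
            reps <- sample(1:6, ngrp, replace = TRUE)
            data.table(
                sample = "s1", chrom_l = "chrA", chrom_r = "chrA",
                umi_a = 1L, umi_b = 1L,
                # replicates jitter within the allowance of one another;
                # distinct molecules are >= 3 bp apart (the regime where
                # anchored and transitive grouping provably agree)
                pos_l = unlist(mapply(function(a, r)
                    a + sample(0:1, r, replace = TRUE), anchors, reps)),
                pos_r = unlist(mapply(function(a, r)
                    a + 5000L + sample(0:1, r, replace = TRUE), anchors, reps)),
                clip_l = 0L, clip_r = 0L)
        })
        expect_lte(nrow(keys), 200L)
        oracle <- group_molecules_bruteforce(keys)
        kk <- copy(keys)
        kk[, qname := paste0("q", .I)]
        # drive the production path through collate-internal grouping by
        # constructing equivalent alignment rows
        g <- mk_genome(c(chrA = 200000L))
        u <- umi_set()
        rows <- lapply(seq_len(nrow(kk)), function(i)
            mk_pair(kk$qname[i], "chrA", kk$pos_l[i], kk$pos_r[i], g,
                    rx = paste0(u[1], "-", u[1])))
        coll <- collate_molecules(rbindlist(rows), "ligation_duplex")
        got <- merge(coll$pairs, kk[, .(qname)], by = "qname", sort = FALSE)
        got <- coll$pairs[match(kk$qname, qname), mol_id]
        # identical partitions (up to relabeling)
        expect_equal(as.integer(factor(got, levels = unique(got))),
                     as.integer(factor(oracle, levels = unique(oracle))))
    }
})

test_that("collation partitions read pairs and conserves family counts", {
    fx <- small_lig_sim()
    coll <- fx$coll
    expect_equal(sum(coll$molecules$n_pairs), nrow(coll$pairs))
    expect_equal(coll$molecules[, sum(strand1_n + strand2_n)],
                 nrow(coll$pairs))
    expect_equal(anyDuplicated(coll$pairs$qname), 0L)
})
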