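# Synthetic capture-library generator: determinism, truth completeness and
# the planted artifact-class signatures.

test_that("configuration invariants are enforced", {
    expect_error(sim_config(clones = list(list(fraction = 0.7),
                                          list(fraction = 0.6))),
                 "fractions")
    expect_error(sim_config(ligation_chimera_rate = 1.5), "rates")
    expect_error(sim_config(chrom_len = 10000L, target_span = 3000L,
                            adjacent_span = 10000L), "exceed")
    # foldbacks are a tagmentation phenomenon
    cfg <- sim_config(mode = "ligation_duplex", foldback_rate = 0.5)
    expect_equal(cfg$foldback_rate, 0)
})

test_that("the same configuration reproduces byte-identical outputs", {
    cfg <- sim_config(seed = 5, n_chrom = 2, chrom_len = 30000,
                      target_span = 2000, adjacent_span = 5000,
                      molecule_depth = 30, n_chimera_sites = 20,
                      n_foldback_sites = 0, ligation_chimera_rate = 0.02,
                      chimeric_pcr_rate = 0.02)
    d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
    g1 <- make_genome(cfg, d1); g2 <- make_genome(cfg, d2)
    expect_identical(readLines(file.path(d1, "genome.fa")),
                     readLines(file.path(d2, "genome.fa")))
    expect_identical(readLines(file.path(d1, "targets.bed")),
                     readLines(file.path(d2, "targets.bed")))
    l1 <- simulate_library(g1, d1); l2 <- simulate_library(g2, d2)
    expect_identical(readLines(l1$sam), readLines(l2$sam))
    expect_identical(readLines(l1$truth), readLines(l2$truth))
})

test_that("every emitted read pair appears in the truth table exactly once", {
    fx <- small_lig_sim()
    qn <- unique(fx$coll$reads$qname)
    tt <- fx$lib$truth_table
    expect_equal(anyDuplicated(tt$qname), 0L)
    expect_true(all(qn %in% tt$qname))
    aln_all <- read_alignments(fx$lib$sam, "s1")
    expect_setequal(unique(aln_all$qname), tt$qname)
})

test_that("planted deletion microhomology and insertions are exact", {
    cfg <- sim_config(seed = 9, n_chrom = 1, chrom_len = 40000,
                      target_span = 3000, adjacent_span = 5000,
                      molecule_depth = 10, n_chimera_sites = 0,
                      n_foldback_sites = 0, ligation_chimera_rate = 0,
                      chimeric_pcr_rate = 0)
    for (mh in c(0L, 2L, 4L, 9L)) {
        cfg$clones <- list(list(fraction = 0.5,
                                deletions = place_deletions(cfg, 2L, 300L, mh)))
        simg <- make_genome(cfg)
        expect_equal(simg$clones[[1]]$deletions$metric, rep(mh, 2L))
    }
    cfg$clones <- list(list(
        fraction = 0.5,
        deletions = place_deletions(cfg, 2L, 300L, mh = 0L, insert = "TTG")))
    simg <- make_genome(cfg)
    expect_equal(simg$clones[[1]]$deletions$metric, c(-3L, -3L))
})

test_that("chimeric PCR molecules are single-strand singletons sharing an endpoint", {
    fx <- small_lig_sim()
    tt <- fx$lib$truth_table
    ch <- tt[class == "chimericPCR"]
    expect_gt(nrow(ch), 0L)
    expect_true(all(ch$fam1 == 1L & ch$fam2 == 0L))
    expect_true(all(!is.na(ch$shared_partner)))
    # the partner proper molecule shares the left outer endpoint
    pr <- unique(tt[, .(frag_id, outer1_pos)])
    m <- merge(unique(ch[, .(frag_id, outer1_pos, shared_partner)]),
               pr, by.x = "shared_partner", by.y = "frag_id",
               suffixes = c("", ".partner"))
    expect_true(all(m$outer1_pos == m$outer1_pos.partner))
    # chimera junction microhomology is large (the planted k-mer switch)
    expect_true(all(ch$metric >= 5L))
})

test_that("ligation artifact second endpoints are uniform over the genome", {
    cfg <- sim_config(seed = 13, n_chrom = 2, chrom_len = 400000,
                      target_span = 2500, adjacent_span = 8000,
                      molecule_depth = 70, error_rate = 0,
                      ligation_chimera_rate = 0.75, chimeric_pcr_rate = 0,
                      n_chimera_sites = 0, n_foldback_sites = 0)
    simg <- make_genome(cfg, file.path(tempdir(), "kssim"))
    lib <- simulate_library(simg, file.path(tempdir(), "kssim"))
    lg <- unique(lib$truth_table[class == "ligation",
                                 .(frag_id, chrom2, pos2, metric, insert)])
    expect_gte(nrow(lg), 2000L)
    # pool second endpoints onto a unit interval across chromosomes
    off <- c(sim1 = 0, sim2 = 400000)
    u <- (off[lg$chrom2] + lg$pos2) / 800000
    ks <- suppressWarnings(stats::ks.test(u, "punif"))
    expect_gt(ks$p.value, 0.01)
    # junction profile: blunt or single-base insertions, plus the chance
    # homology any random blunt joint shows (geometric tail), so metrics
    # concentrate at small values far below the chimeric 8-9 peak
    expect_gt(mean(lg$metric %in% -1:2), 0.85)
    expect_true(names(which.max(table(lg$metric))) %in% c("-1", "0"))
    # A/T fraction of the single-base insertions reflects A-tailing
    ins1 <- lg[nchar(insert) == 1L, insert]
    expect_gt(length(ins1), 200L)
    at <- mean(ins1 %in% c("A", "T"))
    expect_lt(abs(at - 0.81), 3 * sqrt(0.81 * 0.19 / length(ins1)))
})

test_that("foldback artifacts are small same-side inversions", {
    cfg <- sim_config(seed = 17, n_chrom = 2, chrom_len = 80000,
                      target_span = 4000, adjacent_span = 8000,
                      mode = "tagmentation", molecule_depth = 60,
                      ligation_chimera_rate = 0, chimeric_pcr_rate = 0,
                      foldback_rate = 0.012, n_chimera_sites = 0,
                      n_foldback_sites = 150)
    simg <- make_genome(cfg, file.path(tempdir(), "fbsim"))
    lib <- simulate_library(simg, file.path(tempdir(), "fbsim"))
    fb <- unique(lib$truth_table[class == "foldback",
                                 .(frag_id, pos1, pos2, side1, side2, metric)])
    expect_gt(nrow(fb), 10L)
    expect_true(all(fb$side1 == "L" & fb$side2 == "L"))
    expect_true(all(abs(fb$pos2 - fb$pos1) < 1000L))
    expect_true(all(fb$metric >= 5L))
})

test_that("true SV supporter counts track the heterozygous clone fraction", {
    fx <- small_lig_sim()
    tt <- fx$lib$truth_table
    sv_mols <- unique(tt[class == "trueSV", .(frag_id, sv_id)])
    n_per_sv <- sv_mols[, .N, by = sv_id]
    # depth 100, clone 0.3, heterozygous: ~15 crossing molecules per SV
    expect_true(all(n_per_sv$N > 3 & n_per_sv$N < 40))
})
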