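# Formats and the capture-target coordinate model.

test_that("BED targets convert to 1-based spans with adjacent flanks", {
    bed <- tempfile(fileext = ".bed")
    writeLines("chr1\t399999\t650000\tlocusA", bed)
    tg <- load_targets(bed, adjacent_span = 250000L)
    expect_equal(GenomicRanges::start(tg$targets), 400000L)
    expect_equal(GenomicRanges::end(tg$targets), 650000L)
    adj <- as.data.frame(tg$adjacent)
    expect_equal(sort(adj$start), c(150000L, 650001L))
    expect_equal(sort(adj$end), c(399999L, 900000L))
})

test_that("adjacent flank at a chromosome start is clipped with a warning", {
    bed <- tempfile(fileext = ".bed")
    writeLines("chr1\t99\t5000", bed)
    expect_warning(tg <- load_targets(bed, adjacent_span = 1000L), "clipped")
    left <- as.data.frame(tg$adjacent)[as.data.frame(tg$adjacent)$side == "left", ]
    expect_equal(left$start, 1L)
    expect_equal(left$end, 99L)
})

test_that("targets on different chromosomes get independent locus ids", {
    bed <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t1000\t2000\ta", "chr2\t1000\t2000\tb"), bed)
    tg <- load_targets(bed, adjacent_span = 500L)
    expect_equal(tg$targets$locus, 1:2)
})

test_that("malformed BED lines raise an error naming the line", {
    bed <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t100\t200", "chr1\tnotanumber\t300"), bed)
    expect_error(load_targets(bed), "line 2")
})

test_that("classify_point partitions positions into T, A and -", {
    bed <- tempfile(fileext = ".bed")
    writeLines("chr1\t10000\t20000\tt1", bed)
    tg <- load_targets(bed, adjacent_span = 5000L)
    res <- classify_point(c("chr1", "chr1", "chr1", "chr9"),
                          c(15000L, 8000L, 1000L, 15000L), tg)
    expect_equal(res$code, c("T", "A", "-", "-"))
    expect_equal(res$locus, c(1L, 1L, NA, NA))
    # every probed base lands in exactly one category
    pos <- seq(1L, 40000L, by = 37L)
    codes <- classify_point(rep("chr1", length(pos)), pos, tg)$code
    expect_true(all(codes %in% c("T", "A", "-")))
    expect_equal(sum(codes == "T"), sum(pos >= 10001 & pos <= 20000))
})

test_that("BED round-trips through the target model", {
    bed <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t5000\t9000\tx", "chr2\t100\t400\ty"), bed)
    tg <- load_targets(bed, adjacent_span = 50L)
    out <- tempfile(fileext = ".bed")
    write_targets_bed(tg, out)
    a <- read.table(bed, sep = "\t")[, 1:3]
    b <- read.table(out, sep = "\t")[, 1:3]
    expect_equal(unname(as.matrix(a)), unname(as.matrix(b)))
})

test_that("alignment grouping keeps templates together and rejects ungrouped input", {
    g <- mk_genome()
    rp <- rbind(
        mk_pair("r1", "chrA", 100, 400, g),
        aln_row("r1", "chrB", 50, "40S60M", strrep("A", 100), supp = TRUE),
        mk_pair("r2", "chrA", 500, 900, g))
    gg <- alignment_groups(copy(rp))
    expect_equal(length(unique(gg$group)), 2L)
    expect_equal(nrow(gg[group == gg[qname == "r1", group[1]]]), 3L)
    bad <- rbind(mk_pair("r1", "chrA", 100, 400, g),
                 mk_pair("r2", "chrA", 500, 900, g),
                 mk_pair("r1", "chrA", 100, 400, g))
    expect_error(alignment_groups(bad), "name-grouped|name-sort")
})

test_that("BND VCF records carry correct bracket grammar and round-trip", {
    skip_if_not_installed("VariantAnnotation")
    g <- mk_genome(c(chr1 = 30000L))
    svs <- data.table(
        sv_id = c("svA", "svB"),
        chrom1 = "chr1", pos1 = c(10100L, 5000L), side1 = c("L", "L"),
        chrom2 = "chr1", pos2 = c(20000L, 8000L), side2 = c("R", "L"),
        sv_type = c("Del", "Inv"), imprecise = FALSE,
        junction_metric = c(2L, 0L), insert_sequence = c("", ""),
        n_molecules = c(3L, 1L), n_split = c(3L, 1L), n_gap = 0L,
        n_outer_clip = 0L, n_read_pairs = c(6L, 2L), n_duplex = c(1L, 0L),
        target_class = c("TT", "tt"), n_samples = 1L, vaf = c(0.01, NA))
    out <- tempfile(fileext = ".vcf")
    write_bnd_vcf(svs, g, out)
    v <- VariantAnnotation::readVcf(out)
    expect_equal(nrow(v), 4L)  # two breakends per SV
    rr <- SummarizedExperiment::rowRanges(v)
    alts <- vapply(rr$ALT, function(x) as.character(x)[1], "")
    names(alts) <- names(rr)
    # deletion: left breakend points right, right breakend points left
    expect_match(alts[["svA_1"]], "^[ACGT]\\[chr1:20000\\[$")
    expect_match(alts[["svA_2"]], "^\\]chr1:10100\\][ACGT]$")
    # inversion: both breakends in the same bracket class
    expect_match(alts[["svB_1"]], "\\]chr1:8000\\]")
    expect_match(alts[["svB_2"]], "\\]chr1:5000\\]")
    # breakend coordinates and INFO keys round-trip
    expect_setequal(GenomicRanges::start(rr),
                    c(10100L, 20000L, 5000L, 8000L))
    info <- VariantAnnotation::info(v)
    expect_equal(unique(as.character(info$SVTYPE)), "BND")
    expect_true(all(c("MATEID", "JXNMETRIC", "MOLECULES", "DUPLEX",
                      "TCLASS", "VAF") %in% colnames(info)))
    # every breakend has exactly one mate, mutually
    mate <- stats::setNames(as.character(unlist(info$MATEID)), rownames(info))
    expect_equal(unname(mate[unname(mate[names(rr)])]), names(rr))
})

test_that("breakends outside contig bounds are skipped with a message", {
    g <- mk_genome(c(chr1 = 1000L))
    sv <- data.table(
        sv_id = "bad", chrom1 = "chr1", pos1 = 100L, side1 = "L",
        chrom2 = "chr1", pos2 = 99999L, side2 = "R", sv_type = "Del",
        imprecise = FALSE, junction_metric = 0L, insert_sequence = "",
        n_molecules = 1L, n_split = 1L, n_gap = 0L, n_outer_clip = 0L,
        n_read_pairs = 1L, n_duplex = 0L, target_class = "tt",
        n_samples = 1L, vaf = NA_real_)
    out <- tempfile(fileext = ".vcf")
    expect_message(write_bnd_vcf(sv, g, out), "outside contig")
    expect_false(any(grepl("^chr1\t", readLines(out)) &
                     !grepl("^#", readLines(out))) &&
                 length(grep("^[^#]", readLines(out))) > 0)
})
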