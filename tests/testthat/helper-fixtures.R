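# Test helpers: hand-built alignment tables, tiny genomes and small
# simulated libraries shared across test files.

suppressMessages({
    library(data.table)
})

clip_of <- function(cigar, lead = TRUE) {
    pat <- if (lead) "^([0-9]+)S" else "([0-9]+)S$"
    m <- regmatches(cigar, regexpr(pat, cigar))
    if (!length(m)) 0L else as.integer(gsub("S", "", m))
}

# one alignment record row with the derived columns read_alignments() adds
aln_row <- function(qname, rname, pos, cigar, seq, read_index = 1L,
                    reverse = FALSE, supp = FALSE, mapq = 60L,
                    rx = NA_character_, qual = NULL, sample = "s1") {
    rw <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
    data.table(
        qname = qname, flag = 0L, rname = rname, pos = as.integer(pos),
        mapq = as.integer(mapq), cigar = cigar, seq = seq,
        qual = qual %||% strrep("I", nchar(seq)), rx = rx,
        sa = NA_character_, sample = sample, is_supp = supp,
        is_reverse = reverse, read_index = as.integer(read_index),
        ref_width = rw, end = as.integer(pos) + rw - 1L,
        lead_clip = clip_of(cigar, TRUE), trail_clip = clip_of(cigar, FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a concordant FR read pair over [start, end] on one chromosome; orient 2
# mirrors the read roles (read 2 forward at the left end)
mk_pair <- function(qname, chrom, start, end, genome = NULL, rlen = 100L,
                    rx = NA_character_, orient = 1L, sample = "s1",
                    lead_clip = 0L, trail_clip = 0L, clip_seq = "") {
    w <- min(rlen, end - start + 1L)
    seqA <- if (!is.null(genome))
        genome_seq(genome, chrom, start, start + w - 1L) else strrep("A", w)
    seqB <- if (!is.null(genome))
        genome_seq(genome, chrom, end - w + 1L, end) else strrep("A", w)
    cigA <- paste0(if (lead_clip > 0) paste0(lead_clip, "S"), w, "M")
    cigB <- paste0(w, "M", if (trail_clip > 0) paste0(trail_clip, "S"))
    if (lead_clip > 0) seqA <- paste0(clip_seq, seqA)
    if (trail_clip > 0) seqB <- paste0(seqB, clip_seq)
    ra <- if (orient == 1L) 1L else 2L
    rb <- if (orient == 1L) 2L else 1L
    rbind(
        aln_row(qname, chrom, start, cigA, seqA, read_index = ra,
                reverse = FALSE, rx = rx, sample = sample),
        aln_row(qname, chrom, end - w + 1L, cigB, seqB, read_index = rb,
                reverse = TRUE, rx = rx, sample = sample))
}

# deterministic random genome for junction-metric tests
mk_genome <- function(lens = c(chrA = 5000L, chrB = 5000L), seed = 404L) {
    svduplex:::with_seed(seed, {
        genome_model(vapply(lens, function(n)
            paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  collapse = ""), ""))
    })
}

# small simulated ligation library used by several integration tests
small_lig_sim <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        cfg <- sim_config(seed = 71, n_chrom = 2, chrom_len = 50000,
                          target_span = 2500, adjacent_span = 6000,
                          molecule_depth = 100, error_rate = 0.002,
                          ligation_chimera_rate = 0.01,
                          chimeric_pcr_rate = 0.01,
                          n_chimera_sites = 80, n_foldback_sites = 0)
        cfg$clones <- list(list(fraction = 0.3,
                                deletions = place_deletions(cfg, 1L, 300L, 2L)))
        dir <- file.path(tempdir(), "small_lig_sim")
        simg <- make_genome(cfg, dir = dir)
        lib <- simulate_library(simg, dir, sample = "s1")
        aln <- alignment_groups(read_alignments(lib$sam, "s1"))
        coll <- collate_molecules(aln, "ligation_duplex")
        ex <- extract_junctions(coll)
        cache <<- list(cfg = cfg, simg = simg, lib = lib, coll = coll, ex = ex)
        cache
    }
})
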