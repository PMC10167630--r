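# seqio: readers/writers for the standard formats the pipeline touches and
# the genomic coordinate / capture-target model shared by all stages.
#
# Internal coordinates are 1-based inclusive (SAM convention); BED I/O
# converts 0-based half-open intervals at the boundary.

## ---- genome model ----------------------------------------------------------

#' Construct a genome model from named sequences
#'
#' A genome model is an ordered set of chromosomes with a random-access
#' sequence accessor. Sequences are held as a [Biostrings::DNAStringSet] and
#' always returned uppercase.
#'
#' @param seqs A named [Biostrings::DNAStringSet] (or named character vector).
#' @return An object of class `GenomeModel`.
#' @export
genome_model <- function(seqs) {
    if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
    nm <- names(seqs)
    if (is.null(nm) || anyDuplicated(nm))
        stop2("genome sequences must have unique names")
    structure(list(seqs = seqs, lengths = stats::setNames(Biostrings::width(seqs), nm)),
              class = "GenomeModel")
}

#' Load a genome model from a FASTA file
#' @param path Path to a FASTA file.
#' @return A `GenomeModel`.
#' @export
load_genome <- function(path) {
    seqs <- Biostrings::readDNAStringSet(path)
    # drop FASTA description after first whitespace
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    genome_model(seqs)
}

#' Write a genome model to FASTA
#' @param genome A `GenomeModel`.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
    Biostrings::writeXStringSet(genome$seqs, path, width = 70L)
    invisible(path)
}

#' @export
print.GenomeModel <- function(x, ...) {
    cat("GenomeModel:", length(x$lengths), "chromosome(s),",
        sum(as.numeric(x$lengths)), "bp total\n")
    invisible(x)
}

#' Extract genomic sequence
#'
#' @param genome A `GenomeModel`.
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive coordinates.
#' @return Uppercase character string.
#' @export
genome_seq <- function(genome, chrom, start, end) {
    len <- genome$lengths[[chrom]]
    if (is.null(len)) stop2("unknown chromosome: ", chrom)
    if (start < 1 || end > len || start > end)
        stop2(sprintf("interval [%d,%d] out of bounds for %s (length %d)",
                      start, end, chrom, len))
    toupper(as.character(Biostrings::subseq(genome$seqs[[chrom]], start, end)))
}

# Flank accessors oriented along the molecule through a junction node
# (chrom, pos, side).  side is the direction the molecule proceeds from pos.
#
# left_flank:  bases approaching the junction, junction-proximal base LAST.
# right_flank: bases leaving the junction, junction-proximal base FIRST.
# Both are clipped at chromosome bounds.
left_flank_seq <- function(genome, chrom, pos, side, width = 150L) {
    len <- genome$lengths[[chrom]]
    if (side == "L") {
        s <- max(1L, pos - width + 1L)
        genome_seq(genome, chrom, s, pos)
    } else {
        e <- min(len, pos + width - 1L)
        revcomp(genome_seq(genome, chrom, pos, e))
    }
}

right_flank_seq <- function(genome, chrom, pos, side, width = 150L) {
    len <- genome$lengths[[chrom]]
    if (side == "R") {
        e <- min(len, pos + width - 1L)
        genome_seq(genome, chrom, pos, e)
    } else {
        s <- max(1L, pos - width + 1L)
        revcomp(genome_seq(genome, chrom, s, pos))
    }
}

## ---- capture targets -------------------------------------------------------

#' Load capture targets from BED with adjacent flanks
#'
#' Reads a BED file of capture spans (0-based half-open) and converts to the
#' internal 1-based inclusive representation, computing the two adjacent
#' regions of `adjacent_span` bases on each side of every target, clipped to
#' chromosome bounds when a genome (or seqlengths) is supplied.
#'
#' @param bed_path Path to a BED file with at least 3 columns.
#' @param adjacent_span Width in bases of each adjacent region
#'   (default 250000, the span used for the capture design this models).
#' @param genome Optional `GenomeModel` used to clip flanks at chromosome ends.
#' @return A `TargetRegionSet`: list with `targets` (GRanges, mcols `name`,
#'   `locus`), `adjacent` (GRanges, mcols `locus`, `side`), `adjacent_span`.
#' @export
load_targets <- function(bed_path, adjacent_span = 250000L, genome = NULL) {
    lines <- readLines(bed_path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
    for (i in which(keep)) {
        f <- strsplit(lines[i], "\t")[[1]]
        if (length(f) < 3 || is.na(suppressWarnings(as.numeric(f[2]))) ||
            is.na(suppressWarnings(as.numeric(f[3]))))
            stop2("malformed BED line ", i, " in ", bed_path, ": ", lines[i])
    }
    if (!any(keep)) stop2("BED file has no records: ", bed_path)
    gr <- rtracklayer::import(bed_path, format = "BED")
    nm <- gr$name
    if (is.null(nm) || any(is.na(nm)) || !length(nm))
        nm <- paste0("target_", seq_along(gr))
    targets_from_granges(GenomicRanges::GRanges(
        GenomeInfoDb::seqnames(gr), IRanges::ranges(gr), name = nm),
        adjacent_span = adjacent_span, genome = genome)
}

#' Build a TargetRegionSet from a GRanges of capture spans
#'
#' @param gr GRanges (1-based) with optional mcol `name`.
#' @inheritParams load_targets
#' @return A `TargetRegionSet`.
#' @export
targets_from_granges <- function(gr, adjacent_span = 250000L, genome = NULL) {
    adjacent_span <- as.integer(adjacent_span)
    if (is.null(gr$name)) gr$name <- paste0("target_", seq_along(gr))
    gr$locus <- seq_along(gr)
    seqlens <- if (!is.null(genome)) genome$lengths else NULL
    st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
    chr <- as.character(GenomeInfoDb::seqnames(gr))
    la_s <- st - adjacent_span; la_e <- st - 1L
    ra_s <- en + 1L; ra_e <- en + adjacent_span
    clipped <- FALSE
    if (any(la_s < 1L)) { clipped <- TRUE; la_s <- pmax(la_s, 1L) }
    if (!is.null(seqlens)) {
        lim <- unname(seqlens[chr])
        if (any(ra_e > lim)) { clipped <- TRUE; ra_e <- pmin(ra_e, lim) }
    }
    if (clipped) warning("adjacent flank(s) clipped at chromosome bounds")
    keepL <- la_e >= la_s; keepR <- ra_e >= ra_s
    adj <- GenomicRanges::GRanges(
        c(chr[keepL], chr[keepR]),
        IRanges::IRanges(c(la_s[keepL], ra_s[keepR]), c(la_e[keepL], ra_e[keepR])),
        locus = c(gr$locus[keepL], gr$locus[keepR]),
        side = c(rep("left", sum(keepL)), rep("right", sum(keepR))))
    full <- c(GenomicRanges::granges(adj), GenomicRanges::granges(gr))
    ol <- GenomicRanges::findOverlaps(full, drop.self = TRUE)
    # distinct loci must not collide after adjacent extension
    obj <- structure(list(targets = gr, adjacent = adj,
                          adjacent_span = adjacent_span),
                     class = "TargetRegionSet")
    if (length(ol) > 0) {
        loci <- c(adj$locus, gr$locus)
        if (any(loci[S4Vectors::queryHits(ol)] != loci[S4Vectors::subjectHits(ol)]))
            warning("targets overlap after adjacent extension across loci")
    }
    obj
}

#' @export
print.TargetRegionSet <- function(x, ...) {
    cat("TargetRegionSet:", length(x$targets), "capture target(s), adjacent span",
        x$adjacent_span, "bp\n")
    invisible(x)
}

#' Write capture targets back to BED (0-based half-open)
#' @param targets A `TargetRegionSet`.
#' @param path Output path.
#' @export
write_targets_bed <- function(targets, path) {
    gr <- targets$targets
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevelsInUse(gr)
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

#' Classify genomic points against capture targets
#'
#' Every base of the genome belongs to exactly one of: `T` (inside a capture
#' span), `A` (inside an adjacent region) or `-` (elsewhere, including unknown
#' chromosomes). `T` beats `A` where regions from distinct loci collide; among
#' equal codes the locus with the nearer capture span wins.
#'
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @param targets A `TargetRegionSet`.
#' @return A data.table with columns `code` ("T"/"A"/"-") and `locus`
#'   (integer or NA).
#' @export
classify_point <- function(chrom, pos, targets) {
    n <- length(pos)
    pts <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    GenomeInfoDb::seqlevels(pts) <- union(GenomeInfoDb::seqlevels(pts),
                                          GenomeInfoDb::seqlevels(targets$targets))
    code <- rep("-", n); locus <- rep(NA_integer_, n)
    olT <- GenomicRanges::findOverlaps(pts, targets$targets)
    if (length(olT)) {
        qh <- S4Vectors::queryHits(olT)
        code[qh] <- "T"
        locus[qh] <- targets$targets$locus[S4Vectors::subjectHits(olT)]
    }
    olA <- GenomicRanges::findOverlaps(pts, targets$adjacent)
    if (length(olA)) {
        qh <- S4Vectors::queryHits(olA); sh <- S4Vectors::subjectHits(olA)
        isA <- code[qh] == "-"
        if (any(!isA)) { qh <- qh[isA]; sh <- sh[isA] }
        if (length(qh)) {
            # nearer capture span wins when a point falls in two flanks
            li <- targets$adjacent$locus[sh]
            tg <- targets$targets[li]
            d <- pmin(abs(pos[qh] - GenomicRanges::start(tg)),
                      abs(pos[qh] - GenomicRanges::end(tg)))
            o <- order(qh, d)
            first <- !duplicated(qh[o])
            code[qh[o][first]] <- "A"
            locus[qh[o][first]] <- li[o][first]
        }
    }
    data.table::data.table(code = code, locus = locus)
}

## ---- alignment input -------------------------------------------------------

SAM_FLAG <- list(paired = 1L, proper = 2L, unmapped = 4L, mate_unmapped = 8L,
                 reverse = 16L, mate_reverse = 32L, read1 = 64L, read2 = 128L,
                 secondary = 256L, qcfail = 512L, dup = 1024L, supp = 2048L)

#' Read aligned records from a SAM or BAM file
#'
#' Loads all mapped records with the tags the pipeline needs (`RX` duplex UMI
#' pair, `SA` supplementary alignment chain) into a data.table, preserving
#' file order so that name-grouping of the input can be verified.
#'
#' @param path SAM or BAM file.
#' @param sample Sample name attached to every record.
#' @return data.table with one row per alignment record.
#' @export
read_alignments <- function(path, sample = "sample1") {
    bam <- path
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
        bam <- tempfile(fileext = ".bam")
        Rsamtools::asBam(path, sub("\\.bam$", "", bam), overwrite = TRUE,
                         indexDestination = FALSE)
    }
    p <- Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
        tag = c("RX", "SA"))
    x <- Rsamtools::scanBam(bam, param = p)[[1]]
    dt <- data.table::data.table(
        qname = x$qname, flag = x$flag, rname = as.character(x$rname),
        pos = x$pos, mapq = x$mapq, cigar = x$cigar,
        seq = as.character(x$seq), qual = as.character(x$qual),
        rx = if (!is.null(x$tag$RX)) x$tag$RX else rep(NA_character_, length(x$qname)),
        sa = if (!is.null(x$tag$SA)) x$tag$SA else rep(NA_character_, length(x$qname)))
    dt <- dt[!is.na(pos) & bitwAnd(flag, SAM_FLAG$unmapped) == 0L]
    dt[, sample := sample]
    dt[, is_supp := bitwAnd(flag, SAM_FLAG$supp) > 0L]
    dt[, is_reverse := bitwAnd(flag, SAM_FLAG$reverse) > 0L]
    dt[, read_index := data.table::fifelse(
        bitwAnd(flag, SAM_FLAG$paired) == 0L, 0L,
        data.table::fifelse(bitwAnd(flag, SAM_FLAG$read2) > 0L, 2L, 1L))]
    # query-consuming and reference-consuming CIGAR widths
    dt[, ref_width := GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)]
    dt[, end := pos + ref_width - 1L]
    cl <- clip_lengths(dt$cigar)
    dt[, lead_clip := cl$lead]
    dt[, trail_clip := cl$trail]
    dt[]
}

clip_lengths <- function(cigar) {
    lead <- suppressWarnings(as.integer(sub("^([0-9]+)S.*$", "\\1", cigar)))
    lead[!grepl("^[0-9]+S", cigar)] <- 0L
    trail <- suppressWarnings(as.integer(sub("^.*?([0-9]+)S$", "\\1", cigar)))
    trail[!grepl("[0-9]+S$", cigar)] <- 0L
    list(lead = lead, trail = trail)
}

#' Group aligned records by read name
#'
#' Verifies that the input stream is name-grouped (all records of one template
#' contiguous) and assigns a group id per template. Primary and supplementary
#' records of both mates travel together.
#'
#' @param aln data.table from [read_alignments()], in file order.
#' @return The same table with an integer `group` column, keyed by group.
#' @export
alignment_groups <- function(aln) {
    g <- data.table::rleid(aln$qname)
    first_grp <- g[!duplicated(aln$qname)]
    if (anyDuplicated(aln$qname[!duplicated(g)]))
        stop2("input is not name-grouped (a read name re-appears after another ",
              "name); name-sort the input, e.g. `samtools sort -n`")
    aln[, group := g]
    data.table::setkey(aln, group)
    aln[]
}

## ---- breakend VCF output ---------------------------------------------------

bnd_alt <- function(ref_base, side_here, mate_chrom, mate_pos, mate_side) {
    m <- paste0(mate_chrom, ":", mate_pos)
    if (side_here == "L") {
        # junction attaches to the right side of this base
        if (mate_side == "R") paste0(ref_base, "[", m, "[")
        else                  paste0(ref_base, "]", m, "]")
    } else {
        # junction attaches to the left side of this base
        if (mate_side == "L") paste0("]", m, "]", ref_base)
        else                  paste0("[", m, "[", ref_base)
    }
}

#' Write SV calls as paired VCF breakend (BND) records
#'
#' Each SV produces two BND records with mutual MATEID. INFO carries the SV
#' type, microhomology/insertion metric, supporting molecule counts by
#' evidence class, duplex count, target class and per-sample VAF.
#'
#' @param svs SV call table as produced by [find_svs()] / [apply_filters()].
#' @param genome A `GenomeModel` (declares contigs; provides REF bases).
#' @param out Output VCF path.
#' @return `out`, invisibly.
#' @export
write_bnd_vcf <- function(svs, genome, out) {
    con <- file(out, "w")
    on.exit(close(con))
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##source=svduplex",
        paste0("##contig=<ID=", names(genome$lengths), ",length=",
               unname(genome$lengths), ">"),
        "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
        "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"ID of mate breakend\">",
        "##INFO=<ID=EVENT,Number=1,Type=String,Description=\"SV event id\">",
        "##INFO=<ID=SVCLASS,Number=1,Type=String,Description=\"Junction class: Del, Dup, Inv or Trans\">",
        "##INFO=<ID=JXNMETRIC,Number=1,Type=Integer,Description=\"Microhomology length (>0), blunt (0) or de novo insertion (<0)\">",
        "##INFO=<ID=INSSEQ,Number=1,Type=String,Description=\"De novo inserted sequence at the junction\">",
        "##INFO=<ID=MOLECULES,Number=1,Type=Integer,Description=\"Supporting source molecules (split+gap+outer clip)\">",
        "##INFO=<ID=SPLITMOL,Number=1,Type=Integer,Description=\"Split-evidence molecules\">",
        "##INFO=<ID=GAPMOL,Number=1,Type=Integer,Description=\"Gap-evidence molecules\">",
        "##INFO=<ID=CLIPMOL,Number=1,Type=Integer,Description=\"Outer-clip evidence molecules\">",
        "##INFO=<ID=READPAIRS,Number=1,Type=Integer,Description=\"Supporting read pairs\">",
        "##INFO=<ID=DUPLEX,Number=1,Type=Integer,Description=\"Duplex supporting molecules\">",
        "##INFO=<ID=TCLASS,Number=1,Type=String,Description=\"Two-letter capture target class\">",
        "##INFO=<ID=NSAMPLES,Number=1,Type=Integer,Description=\"Samples carrying the SV\">",
        "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Supporting molecules over mean on-target molecule coverage\">",
        "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Breakpoints reconstructed from gap evidence only\">",
        "##ALT=<ID=BND,Description=\"Breakend\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    if (nrow(svs) == 0) return(invisible(out))
    recs <- data.table::data.table(chrom = character(), pos = integer(),
                                   id = character(), ref = character(),
                                   alt = character(), info = character())
    for (i in seq_len(nrow(svs))) {
        sv <- svs[i]
        ok <- TRUE
        for (j in 1:2) {
            ch <- if (j == 1) sv$chrom1 else sv$chrom2
            po <- if (j == 1) sv$pos1 else sv$pos2
            len <- genome$lengths[[ch]]
            if (is.null(len) || po < 1 || po > len) {
                message("skipping SV ", sv$sv_id, ": breakend ", ch, ":", po,
                        " outside contig bounds")
                ok <- FALSE
            }
        }
        if (!ok) next
        base1 <- genome_seq(genome, sv$chrom1, sv$pos1, sv$pos1)
        base2 <- genome_seq(genome, sv$chrom2, sv$pos2, sv$pos2)
        ids <- paste0(sv$sv_id, "_", 1:2)
        common <- paste0("SVTYPE=BND;EVENT=", sv$sv_id,
            ";SVCLASS=", sv$sv_type,
            if (!is.na(sv$junction_metric)) paste0(";JXNMETRIC=", sv$junction_metric),
            if (!is.na(sv$insert_sequence) && nzchar(sv$insert_sequence))
                paste0(";INSSEQ=", sv$insert_sequence),
            ";MOLECULES=", sv$n_molecules,
            ";SPLITMOL=", sv$n_split, ";GAPMOL=", sv$n_gap,
            ";CLIPMOL=", sv$n_outer_clip,
            ";READPAIRS=", sv$n_read_pairs, ";DUPLEX=", sv$n_duplex,
            ";TCLASS=", sv$target_class, ";NSAMPLES=", sv$n_samples,
            if (!is.na(sv$vaf)) paste0(";VAF=", signif(sv$vaf, 6)),
            if (isTRUE(sv$imprecise)) ";IMPRECISE")
        recs <- rbind(recs, data.table::data.table(
            chrom = c(sv$chrom1, sv$chrom2), pos = c(sv$pos1, sv$pos2),
            id = ids, ref = c(base1, base2),
            alt = c(bnd_alt(base1, sv$side1, sv$chrom2, sv$pos2, sv$side2),
                    bnd_alt(base2, sv$side2, sv$chrom1, sv$pos1, sv$side1)),
            info = paste0(common, ";MATEID=", rev(ids))))
    }
    if (nrow(recs)) {
        data.table::setorder(recs, chrom, pos)
        writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                           recs$chrom, recs$pos, recs$id, recs$ref, recs$alt,
                           recs$info), con)
    }
    invisible(out)
}
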