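# genotype_stats: unphased biallelic haplotype table from proper molecules,
# de novo SNV/indel marking in SV junction consensuses, and the
# junction-proximity permutation test.

#' Build the unphased biallelic haplotype table
#'
#' Pileup of proper-molecule consensus sequences: positions covered by at
#' least `min_depth` unique molecules are genotyped; alleles reaching
#' `min_allele_fraction` are retained (at most two, by count). Positions
#' with more than two qualifying alleles are uncallable and excluded.
#'
#' @param proper Proper molecule table with consensus sequences (`cons`;
#'   requires [extract_junctions()] with `consensus = "all"`), `chrom_l`,
#'   `pos_l`.
#' @param genome `GenomeModel`.
#' @param regions Optional GRanges restricting the table (e.g. targets plus
#'   adjacent regions); NULL = everywhere covered.
#' @param min_depth Minimum unique molecules covering a position.
#' @param min_allele_fraction Minimum allele fraction retained.
#' @return A `HaplotypeTable`: data.table (chrom, pos, ref, a1, a2, gt) with
#'   gt in hom_ref/het/hom_alt; keyed by (chrom, pos).
#' @export
build_haplotypes <- function(proper, genome, regions = NULL,
                             min_depth = 10L, min_allele_fraction = 0.2) {
    rows <- list()
    pm <- proper[!is.na(cons) & chrom_l == chrom_r]
    for (i in seq_len(nrow(pm))) {
        s <- pm$cons[i]
        w <- nchar(s)
        rows[[length(rows) + 1L]] <- data.table::data.table(
            chrom = pm$chrom_l[i],
            pos = pm$pos_l[i]:(pm$pos_l[i] + w - 1L),
            base = strsplit(s, "")[[1]])
    }
    if (!length(rows))
        return(structure(data.table::data.table(
            chrom = character(0), pos = integer(0), ref = character(0),
            a1 = character(0), a2 = character(0), gt = character(0)),
            class = c("HaplotypeTable", "data.table", "data.frame")))
    pile <- data.table::rbindlist(rows)
    pile <- pile[base %in% c("A", "C", "G", "T")]
    if (!is.null(regions)) {
        gr <- GenomicRanges::GRanges(pile$chrom, IRanges::IRanges(pile$pos,
                                                                  pile$pos))
        GenomeInfoDb::seqlevels(gr) <- union(GenomeInfoDb::seqlevels(gr),
                                             GenomeInfoDb::seqlevels(regions))
        keep <- IRanges::overlapsAny(gr, regions)
        pile <- pile[keep]
    }
    cnt <- pile[, .(n = .N), by = .(chrom, pos, base)]
    tot <- cnt[, .(depth = sum(n)), by = .(chrom, pos)]
    cnt <- merge(cnt, tot, by = c("chrom", "pos"))
    cnt <- cnt[depth >= min_depth]
    cnt[, frac := n / depth]
    cnt <- cnt[frac >= min_allele_fraction]
    data.table::setorder(cnt, chrom, pos, -n, base)
    gt <- cnt[, .(nallele = .N, a1 = base[1],
                  a2 = if (.N >= 2L) base[2] else base[1]),
              by = .(chrom, pos)]
    gt <- gt[nallele <= 2L]
    gt[, ref := vapply(seq_len(.N), function(i)
        genome_seq(genome, chrom[i], pos[i], pos[i]), "")]
    gt[, gt := data.table::fifelse(
        a1 == ref & a2 == ref, "hom_ref",
        data.table::fifelse(a1 != ref & a2 != ref, "hom_alt", "het"))]
    out <- gt[, .(chrom, pos, ref, a1, a2, gt)]
    data.table::setkey(out, chrom, pos)
    structure(out, class = c("HaplotypeTable", class(out)))
}

#' Import known biallelic genotypes from a VCF
#'
#' Alternative to the internal pileup genotyper: loads biallelic SNV
#' genotypes of the source individual from a VCF file.
#'
#' @param path VCF path.
#' @param genome `GenomeModel` (provides reference bases).
#' @return A `HaplotypeTable`.
#' @export
import_haplotypes_vcf <- function(path, genome) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
        stop2("VariantAnnotation is required to import VCF genotypes")
    v <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(v)
    ref <- as.character(rr$REF)
    alt <- vapply(rr$ALT, function(x) as.character(x)[1], "")
    gtm <- VariantAnnotation::geno(v)$GT[, 1]
    chrom <- as.character(GenomeInfoDb::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    keep <- nchar(ref) == 1L & nchar(alt) == 1L & !is.na(gtm)
    a1 <- data.table::fifelse(substr(gtm, 1, 1) == "0", ref, alt)
    a2 <- data.table::fifelse(substr(gtm, 3, 3) == "0", ref, alt)
    out <- data.table::data.table(chrom = chrom[keep], pos = pos[keep],
                                  ref = ref[keep], a1 = a1[keep],
                                  a2 = a2[keep])
    out[, gt := data.table::fifelse(a1 == ref & a2 == ref, "hom_ref",
             data.table::fifelse(a1 != ref & a2 != ref, "hom_alt", "het"))]
    data.table::setkey(out, chrom, pos)
    structure(out, class = c("HaplotypeTable", class(out)))
}

# reference position of each junction-consensus column on its flank;
# returns NA for columns inside the ambiguous microhomology stretch.
# distance convention: distance 1 = first base beyond the microhomology.
consensus_flank_map <- function(sv) {
    n <- nchar(sv$junction_consensus)
    q <- sv$junction_col
    mhl <- sv$mh_left; mhr <- sv$mh_right
    ilen <- if (!is.na(sv$insert_sequence) && nzchar(sv$insert_sequence))
        nchar(sv$insert_sequence) else 0L
    cols <- seq_len(n)
    flank <- rep(NA_character_, n)
    dist <- rep(NA_integer_, n)
    pos <- rep(NA_integer_, n)
    chrom <- rep(NA_character_, n)
    # left flank: columns 1 .. q - mh_left (mh and insert columns excluded)
    lmax <- q - mhl
    if (lmax >= 1L) {
        j <- 1:lmax
        flank[j] <- "left"
        dist[j] <- lmax - j + 1L
        off <- q - j  # distance from junction node along the molecule
        if (sv$side1 == "L") pos[j] <- sv$pos1 - off
        else pos[j] <- sv$pos1 + off
        chrom[j] <- sv$chrom1
    }
    # right flank: columns q + ilen + mh_right + 1 .. n
    rmin <- q + ilen + mhr + 1L
    if (rmin <= n) {
        j <- rmin:n
        flank[j] <- "right"
        dist[j] <- j - rmin + 1L
        off <- j - (q + ilen + 1L)
        if (sv$side2 == "R") pos[j] <- sv$pos2 + off
        else pos[j] <- sv$pos2 - off
        chrom[j] <- sv$chrom2
    }
    data.table::data.table(col = cols, chrom = chrom, pos = pos,
                           flank = flank, dist = dist)
}

#' Mark de novo SNVs in SV junction consensuses
#'
#' A non-N consensus base differing from the reference AND absent from the
#' individual's haplotype allele set at that position is a presumptive de
#' novo SNV created during junction formation. Distances are measured from
#' the first non-microhomology base (distance 1 = adjacent to the junction).
#' Informative positions are non-N consensus columns with a covered
#' haplotype entry.
#'
#' @param svs Precise SV call rows from [find_svs()] (junction consensus
#'   and microhomology annotation present).
#' @param haplotypes A `HaplotypeTable`.
#' @param genome `GenomeModel`.
#' @return list(variants = data.table(sv_id, chrom, pos, base, flank, dist),
#'   informative = data.table(sv_id, col, dist, flank) of informative
#'   positions, n_informative).
#' @export
call_denovo <- function(svs, haplotypes, genome) {
    vars <- list(); info <- list()
    prec <- svs[imprecise == FALSE & !is.na(junction_consensus)]
    for (i in seq_len(nrow(prec))) {
        sv <- prec[i]
        mp <- consensus_flank_map(sv)
        bases <- strsplit(sv$junction_consensus, "")[[1]]
        mp[, base := bases[col]]
        mp <- mp[!is.na(pos) & base %in% c("A", "C", "G", "T")]
        if (!nrow(mp)) next
        hp <- haplotypes[mp[, .(chrom, pos)], on = c("chrom", "pos"),
                         nomatch = NULL]
        mp <- merge(mp, hp, by = c("chrom", "pos"))
        if (!nrow(mp)) next
        info[[length(info) + 1L]] <- data.table::data.table(
            sv_id = sv$sv_id, col = mp$col, dist = mp$dist, flank = mp$flank)
        dn <- mp[base != ref & base != a1 & base != a2]
        if (nrow(dn)) {
            vars[[length(vars) + 1L]] <- data.table::data.table(
                sv_id = sv$sv_id, chrom = dn$chrom, pos = dn$pos,
                type = "SNV", base = dn$base, flank = dn$flank,
                dist = dn$dist)
        }
    }
    variants <- if (length(vars)) data.table::rbindlist(vars)
        else data.table::data.table(sv_id = character(0), chrom = character(0),
                                    pos = integer(0), type = character(0),
                                    base = character(0), flank = character(0),
                                    dist = integer(0))
    informative <- if (length(info)) data.table::rbindlist(info)
        else data.table::data.table(sv_id = character(0), col = integer(0),
                                    dist = integer(0), flank = character(0))
    list(variants = variants, informative = informative,
         n_informative = nrow(informative))
}

#' Coverage-weighted distance distribution of informative positions
#'
#' For the variant-containing SV consensuses, counts how many cross an
#' informative position at each distance from the junction — the expected
#' distance distribution of randomly placed variants.
#'
#' @param informative Informative-position table from [call_denovo()].
#' @param variant_svs SV ids that contain at least one variant.
#' @return data.table(dist, n).
#' @export
distance_coverage <- function(informative, variant_svs) {
    inf <- informative[sv_id %in% variant_svs]
    cov <- unique(inf[, .(sv_id, dist)])[, .(n = .N), by = dist]
    data.table::setorder(cov, dist)
    cov
}

#' Junction-proximity permutation test for de novo variants
#'
#' Draws `|variants|` distances from the coverage-weighted distance
#' distribution per iteration; the p-value is the fraction of iterations
#' whose median distance is strictly less than the observed median. A small
#' p-value indicates variants closer to the junction than expected by
#' chance.
#'
#' @param distances Observed variant distances (>= 1).
#' @param coverage data.table(dist, n) from [distance_coverage()] (or any
#'   weights table).
#' @param iterations Permutation iterations.
#' @param seed RNG seed.
#' @param finite_correction Apply the (k+1)/(N+1) finite-sample correction.
#' @return list(p_value, observed_median, iterations, n_variants).
#' @export
junction_proximity_test <- function(distances, coverage, iterations = 10000L,
                                    seed = 1L, finite_correction = FALSE) {
    if (!length(distances)) stop2("no observed variant distances")
    if (!nrow(coverage) || sum(coverage$n) <= 0)
        stop2("empty coverage distribution")
    obs <- stats::median(distances)
    n <- length(distances)
    meds <- with_seed(seed, {
        draws <- matrix(sample(coverage$dist, n * iterations, replace = TRUE,
                               prob = coverage$n), nrow = n)
        apply(draws, 2L, stats::median)
    })
    k <- sum(meds < obs)
    p <- if (finite_correction) (k + 1) / (iterations + 1) else k / iterations
    list(p_value = p, observed_median = obs, iterations = iterations,
         n_variants = n)
}

#' Mann-Whitney secondary test of variant distances
#'
#' Optional one-sided rank test comparing observed variant distances to the
#' expanded coverage-weighted distances (alternative: observed are smaller).
#'
#' @inheritParams junction_proximity_test
#' @return htest object from [stats::wilcox.test()].
#' @export
junction_proximity_wilcox <- function(distances, coverage) {
    expanded <- rep(coverage$dist, coverage$n)
    suppressWarnings(stats::wilcox.test(distances, expanded,
                                        alternative = "less"))
}
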