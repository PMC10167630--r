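# filtering: error-correction filters separating true SV junctions from
# ligation and chimeric-PCR artifacts, plus molecule coverage and VAF.

#' Construct an SV filter specification
#'
#' Defaults reproduce the headline filter setting used throughout the
#' analyses this package models: MAPQ > 50 per flanking alignment, at least
#' three supporting read pairs, SVs detected in a single co-analyzed sample.
#'
#' @param min_mapq Minimum MAPQ of each flanking alignment (strict >).
#' @param require_duplex Demand at least one duplex supporting molecule.
#' @param min_family_size Minimum of the largest strand family size.
#' @param min_read_pairs Minimum read pairs (summed over strands) of the
#'   best-supported molecule.
#' @param min_molecules,max_molecules Bounds on total supporting molecules
#'   (split + gap + outer clip).
#' @param min_samples,max_samples Bounds on the number of co-analyzed
#'   samples sharing the SV.
#' @param exclude_shared_endpoints Drop SVs whose supporting molecules ALL
#'   share an outer endpoint with a proper molecule.
#' @param min_sv_size,max_sv_size Size bounds (bp, same-chromosome SVs;
#'   translocations always pass size bounds).
#' @param allowed_target_classes Optional set of two-letter target class
#'   codes to keep (NULL = all).
#' @return A `FilterSpec` list.
#' @export
filter_spec <- function(min_mapq = 50L, require_duplex = FALSE,
                        min_family_size = 0L, min_read_pairs = 3L,
                        min_molecules = 1L, max_molecules = Inf,
                        min_samples = 1L, max_samples = 1L,
                        exclude_shared_endpoints = FALSE,
                        min_sv_size = 0L, max_sv_size = Inf,
                        allowed_target_classes = NULL) {
    spec <- as.list(environment())
    if (min_molecules > max_molecules || min_samples > max_samples ||
        min_sv_size > max_sv_size)
        stop2("contradictory filter spec: a minimum exceeds its maximum")
    structure(spec, class = "FilterSpec")
}

#' Apply SV filters with per-predicate attrition accounting
#'
#' Predicates are applied in a fixed order (mapq, size, target class,
#' shared endpoints, family/read pairs, duplex, molecules, samples); an SV
#' survives iff every enabled predicate holds. The attrition table records
#' how many SVs each predicate removed (first failing predicate wins).
#'
#' @param svs SV table from [find_svs()].
#' @param spec A `FilterSpec`.
#' @return list(svs = surviving rows, attrition = data.table(filter, removed)).
#' @export
apply_filters <- function(svs, spec) {
    stopifnot(inherits(spec, "FilterSpec"))
    n0 <- nrow(svs)
    preds <- list(
        mapq = svs$min_flank_mapq > spec$min_mapq,
        size = is.na(svs$size) |
            (svs$size >= spec$min_sv_size & svs$size <= spec$max_sv_size),
        target_class = if (is.null(spec$allowed_target_classes))
            rep(TRUE, n0) else svs$target_class %in% spec$allowed_target_classes,
        shared_endpoints = if (spec$exclude_shared_endpoints)
            !svs$all_shared else rep(TRUE, n0),
        family_read_pairs = svs$max_mol_pairs >= spec$min_read_pairs &
            svs$max_family_size >= spec$min_family_size,
        duplex = if (spec$require_duplex) svs$n_duplex >= 1L
            else rep(TRUE, n0),
        molecules = svs$n_molecules >= spec$min_molecules &
            svs$n_molecules <= spec$max_molecules,
        samples = svs$n_samples >= spec$min_samples &
            svs$n_samples <= spec$max_samples)
    alive <- rep(TRUE, n0)
    attr_rows <- list()
    for (nm in names(preds)) {
        p <- preds[[nm]] %in% TRUE
        removed <- sum(alive & !p)
        attr_rows[[length(attr_rows) + 1L]] <- data.table::data.table(
            filter = nm, removed = removed)
        alive <- alive & p
    }
    list(svs = svs[alive], attrition = data.table::rbindlist(attr_rows))
}

#' Average on-target source molecule coverage
#'
#' Sum of the overlap of each unique source molecule span with the capture
#' spans, divided by the total capture span length. The unit is unique
#' molecules per base, not read pairs.
#'
#' @param proper Molecule table with `chrom_l`, `pos_l`, `pos_r` (proper
#'   molecules; one row per unique source molecule).
#' @param targets `TargetRegionSet`.
#' @return Mean molecule coverage (double).
#' @export
compute_coverage <- function(proper, targets) {
    tl <- sum(GenomicRanges::width(targets$targets))
    if (tl == 0) stop2("capture targets have zero total length")
    if (!nrow(proper)) return(0)
    same <- proper[chrom_l == chrom_r & pos_r >= pos_l]
    if (!nrow(same)) return(0)
    gr <- GenomicRanges::GRanges(same$chrom_l,
                                 IRanges::IRanges(same$pos_l, same$pos_r))
    GenomeInfoDb::seqlevels(gr) <- union(GenomeInfoDb::seqlevels(gr),
                                         GenomeInfoDb::seqlevels(targets$targets))
    ol <- GenomicRanges::findOverlaps(gr, targets$targets)
    if (!length(ol)) return(0)
    ov <- GenomicRanges::pintersect(gr[S4Vectors::queryHits(ol)],
                                    targets$targets[S4Vectors::subjectHits(ol)])
    sum(as.numeric(GenomicRanges::width(ov))) / tl
}

#' Variant allele frequency of an SV
#'
#' Count of total supporting molecules (split + gap + outer clip) divided by
#' the average on-target molecule coverage. For a heterozygous SV carried by
#' a clone, the expectation is half the clone fraction.
#'
#' @param n_support Supporting molecule count(s).
#' @param coverage Average on-target molecule coverage (> 0).
#' @return VAF fraction(s); NA (with a warning) when coverage is not positive.
#' @export
compute_vaf <- function(n_support, coverage) {
    if (is.na(coverage) || coverage <= 0) {
        warning("coverage not positive; VAF undefined")
        return(rep(NA_real_, length(n_support)))
    }
    n_support / coverage
}

#' Attach per-sample VAFs to an SV table
#'
#' @param svres Result of [find_svs()].
#' @param coverage Named numeric vector: average on-target molecule coverage
#'   per sample.
#' @return `svres$svs` with a `vaf` column (mean per-sample VAF over the
#'   samples carrying the SV; equals the per-sample VAF for single-sample
#'   calls) and a long `vaf_by_sample` table attached.
#' @export
add_vaf <- function(svres, coverage) {
    sup <- svres$support[, .(n = .N), by = .(sv_id, sample)]
    if (nrow(svres$clips)) {
        cl <- svres$clips[, .(nc = .N), by = .(sv_id, sample)]
        sup <- merge(sup, cl, by = c("sv_id", "sample"), all = TRUE)
        sup[is.na(n), n := 0L]; sup[is.na(nc), nc := 0L]
        sup[, n := n + nc]; sup[, nc := NULL]
    }
    sup[, vaf := n / coverage[sample]]
    v <- sup[, .(vaf = mean(vaf)), by = sv_id]
    svs <- data.table::copy(svres$svs)
    svs[, vaf := NULL]
    svs <- merge(svs, v, by = "sv_id", all.x = TRUE, sort = FALSE)
    svres$svs <- svs
    svres$vaf_by_sample <- sup
    svres
}
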