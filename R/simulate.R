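# simulate: synthetic capture-library generator.
#
# Emits aligned SAM records plus a per-read-pair ground-truth table for a
# probe-capture library over scaled-down targets, with heterozygous clone
# deletions and the three junction artifact classes relevant to capture SV
# calling: intermolecular ligation chimeras (pre-denaturation, duplex-capable,
# blunt/1-base A-T junctions), chimeric PCR (post-denaturation, single strand,
# family size 1, shared outer endpoint, large microhomology) and tagmentation
# foldback inversions (small span, large microhomology).
#
# Microhomology is planted by copying reference bases so that the measured
# junction ambiguity equals the configured length; the flanking bases are
# forced to differ so the planted value is exact for clone deletions.

#' Simulation configuration
#'
#' Defaults describe a scaled-down duplex capture library: a few small
#' chromosomes each with one central capture target, ~2000-fold source
#' molecule coverage over targets (the nominal depth of the capture design
#' this emulates), 2 x 151 reads from ~300 bp fragments, and modest artifact
#' rates. All randomness derives from `seed`.
#'
#' @param seed Integer master seed.
#' @param n_chrom,chrom_len Number and length (bp) of simulated chromosomes.
#' @param target_span Capture target width (bp), centered per chromosome.
#' @param adjacent_span Width of each adjacent (A) region flanking a target.
#' @param mode `"ligation_duplex"` (Y-adapter duplex UMI library) or
#'   `"tagmentation"` (Tn5; no duplex strand identification).
#' @param molecule_depth Mean unique source-molecule coverage over targets.
#' @param frag_peak,frag_sd Fragment length distribution (normal, bp).
#' @param read_len Read length (bp) of each mate.
#' @param min_align Minimum alignable block; shorter junction-side blocks are
#'   soft-clipped instead of split-aligned.
#' @param error_rate Per-base substitution error rate applied to every read.
#' @param fam_zero,fam_lambda Zero-inflated Poisson strand family sizes:
#'   a strand has 0 read pairs with probability `fam_zero`, else
#'   `1 + rpois(fam_lambda)`.
#' @param a_accept,other_accept Capture acceptance (relative to target = 1)
#'   for fragments in adjacent regions and elsewhere.
#' @param ligation_chimera_rate,chimeric_pcr_rate,foldback_rate Artifact
#'   molecules per proper captured molecule. Foldbacks require tagmentation
#'   mode; ligation chimeras are characteristic of ligation mode but a small
#'   residual rate may be configured in tagmentation mode.
#' @param mh_lengths,mh_weights Microhomology length distribution for
#'   chimeric PCR / foldback junctions (default peaked at 8-9 bp).
#' @param blunt_frac Fraction of ligation junctions that are blunt; the rest
#'   carry a single-base insertion.
#' @param at_frac Fraction of single-base ligation insertions that are A or T
#'   (A-tailing signature).
#' @param n_chimera_sites,n_foldback_sites Size of the planted junction-site
#'   pools artifacts draw from.
#' @param low_mapq_frac,low_mapq Fraction of records emitted with a low MAPQ
#'   and the value used (models ambiguous alignment).
#' @param clones List of clones, each `list(fraction =, deletions =)` where
#'   `deletions` is a data.frame with columns `locus`, `pos1`, `pos2`
#'   (junction nodes: last retained base, first retained base), `mh`
#'   (microhomology length), `insert` (de novo insertion, "" for none) and
#'   optionally `snv_flank` ("left"/"right"/NA) and `snv_dist` (>= 2) for a
#'   de novo SNV injected near the junction on the SV haplotype. Deletions
#'   are heterozygous in their clone.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 3L, chrom_len = 60000L,
                       target_span = 3000L, adjacent_span = 10000L,
                       mode = c("ligation_duplex", "tagmentation"),
                       molecule_depth = 2000,
                       frag_peak = 300L, frag_sd = 50L,
                       read_len = 151L, min_align = 20L,
                       error_rate = 0.002,
                       fam_zero = 0.35, fam_lambda = 0.8,
                       a_accept = 0.3, other_accept = 0.002,
                       ligation_chimera_rate = 0.01,
                       chimeric_pcr_rate = 0.01,
                       foldback_rate = 0.01,
                       mh_lengths = 5:12,
                       mh_weights = c(1, 2, 4, 8, 8, 4, 2, 1),
                       blunt_frac = 0.5, at_frac = 0.81,
                       n_chimera_sites = 400L, n_foldback_sites = 300L,
                       low_mapq_frac = 0, low_mapq = 10L,
                       clones = list()) {
    mode <- match.arg(mode)
    cfg <- as.list(environment())
    fr <- vapply(clones, function(cl) cl$fraction, numeric(1))
    if (length(fr) && sum(fr) > 1) stop2("clone fractions sum to more than 1")
    if (any(c(ligation_chimera_rate, chimeric_pcr_rate, foldback_rate) < 0) ||
        any(c(ligation_chimera_rate, chimeric_pcr_rate, foldback_rate) > 1))
        stop2("artifact rates must lie in [0, 1]")
    if (mode == "ligation_duplex" && foldback_rate > 0)
        cfg$foldback_rate <- 0  # foldbacks arise from Tn5 libraries only
    t_start <- (chrom_len - target_span) %/% 2L + 1L
    if (t_start - adjacent_span < 1L ||
        t_start + target_span - 1L + adjacent_span > chrom_len)
        stop2("target plus adjacent flanks exceed chromosome length")
    structure(cfg, class = "SimConfig")
}

#' Place heterozygous clone deletions across capture targets
#'
#' Convenience constructor for the `deletions` table of a clone: `n_per_target`
#' deletions of size `size`, evenly spaced inside every target, all TT class.
#'
#' @param cfg A `SimConfig`.
#' @param n_per_target Deletions per capture target.
#' @param size Deleted bases per deletion (node distance is `size + 1`).
#' @param mh Planted microhomology length (0 = blunt).
#' @param insert De novo insertion sequence ("" = none); requires `mh = 0`.
#' @param snv_flank,snv_dist Optional de novo SNV spec applied to every
#'   deletion (distance from the junction, microhomology excluded, >= 2).
#' @return data.frame suitable for `sim_config(clones=)`.
#' @export
place_deletions <- function(cfg, n_per_target = 4L, size = 150L, mh = 2L,
                            insert = "", snv_flank = NA, snv_dist = NA) {
    t_start <- (cfg$chrom_len - cfg$target_span) %/% 2L + 1L
    t_end <- t_start + cfg$target_span - 1L
    margin <- cfg$frag_peak + 4L * cfg$frag_sd
    usable <- (t_end - margin) - (t_start + margin) - size
    if (usable < n_per_target * (size + 50L))
        stop2("target too small for ", n_per_target, " deletions of size ", size)
    step <- usable %/% n_per_target
    out <- list()
    for (ch in seq_len(cfg$n_chrom)) {
        p1 <- t_start + margin + (seq_len(n_per_target) - 1L) * step +
            step %/% 2L
        out[[ch]] <- data.frame(locus = ch, pos1 = p1, pos2 = p1 + size + 1L,
                                mh = mh, insert = insert,
                                snv_flank = snv_flank, snv_dist = snv_dist,
                                stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
}

#' Load the fixed duplex UMI reference set
#'
#' The 96 expected 8-mer UMIs shipped with the package (pairwise Hamming
#' distance >= 3, so a single-mismatch match is always unambiguous).
#' @return Character vector of 96 UMI sequences; index = UMI index.
#' @export
umi_set <- function() {
    readLines(system.file("extdata", "umi96.txt", package = "svduplex",
                          mustWork = TRUE))
}

## ---- genome construction ---------------------------------------------------

mutate_differ <- function(base, avoid) {
    cand <- setdiff(c("A", "C", "G", "T"), c(base, avoid))
    cand[1]
}

# Truth-side junction metric from the reference: build the ideal junction
# sequence (w flank bases + insert + w flank bases) and count how far the
# breakpoint can slide while remaining consistent with both flanks.
# Returns list(metric, mh_left, mh_right): mh_left/right are the slide
# extents used downstream to orient de novo variant distances.
truth_junction_metric <- function(genome, chrom1, pos1, side1,
                                  chrom2, pos2, side2, insert = "", w = 60L) {
    f_fwd <- function(i) { # continuation of left flank past the junction
        if (side1 == "L") {
            p <- pos1 + i
            if (p > genome$lengths[[chrom1]]) return(NA_character_)
            genome_seq(genome, chrom1, p, p)
        } else {
            p <- pos1 - i
            if (p < 1) return(NA_character_)
            chartr("ACGT", "TGCA", genome_seq(genome, chrom1, p, p))
        }
    }
    g_back <- function(i) { # continuation of right flank before the junction
        if (side2 == "R") {
            p <- pos2 - i
            if (p < 1) return(NA_character_)
            genome_seq(genome, chrom2, p, p)
        } else {
            p <- pos2 + i
            if (p > genome$lengths[[chrom2]]) return(NA_character_)
            chartr("ACGT", "TGCA", genome_seq(genome, chrom2, p, p))
        }
    }
    g_fwd <- function(i) { # right flank bases after the junction (i >= 0)
        if (side2 == "R") genome_seq(genome, chrom2, pos2 + i, pos2 + i)
        else chartr("ACGT", "TGCA", genome_seq(genome, chrom2, pos2 - i, pos2 - i))
    }
    f_bk <- function(i) { # left flank bases before the junction (i >= 0)
        if (side1 == "L") genome_seq(genome, chrom1, pos1 - i, pos1 - i)
        else chartr("ACGT", "TGCA", genome_seq(genome, chrom1, pos1 + i, pos1 + i))
    }
    ilen <- nchar(insert)
    ins <- if (ilen) strsplit(insert, "")[[1]] else character(0)
    # extend the left flank rightward through insert then right flank
    after <- c(ins, vapply(0:(w - 1L), g_fwd, ""))
    i1 <- 0L
    while (i1 < length(after)) {
        nx <- f_fwd(i1 + 1L)
        if (is.na(nx) || after[i1 + 1L] != nx) break
        i1 <- i1 + 1L
    }
    before <- c(rev(ins), vapply(0:(w - 1L), f_bk, ""))
    i2 <- 0L
    while (i2 < length(before)) {
        nx <- g_back(i2 + 1L)
        if (is.na(nx) || before[i2 + 1L] != nx) break
        i2 <- i2 + 1L
    }
    if (ilen == 0L) {
        list(metric = i1 + i2, mh_left = i2, mh_right = i1)
    } else if (i1 + i2 < ilen) {
        list(metric = -(ilen - i1 - i2), mh_left = 0L, mh_right = 0L)
    } else { # insert fully explained by flank homology
        list(metric = i1 + i2 - ilen, mh_left = min(i2, ilen), mh_right = i1)
    }
}

#' Build the simulated genome, capture targets and planted junction sites
#'
#' Generates random-composition chromosomes with one central capture target
#' each, plants the configured microhomology/insertion signatures for clone
#' deletions (with flanking bases forced so planted values are exact), and
#' plants pools of chimeric-PCR and foldback junction sites. Writes FASTA and
#' BED when `dir` is given. Deterministic under `cfg$seed`.
#'
#' @param cfg A `SimConfig`.
#' @param dir Optional output directory for `genome.fa` and `targets.bed`.
#' @return A `SimGenome`: list(genome, targets, clones, chimera_sites,
#'   foldback_sites, cfg, paths).
#' @export
make_genome <- function(cfg, dir = NULL) {
    with_seed(cfg$seed + 7777L, {
        chroms <- paste0("sim", seq_len(cfg$n_chrom))
        seqs <- vapply(chroms, function(x) random_dna(cfg$chrom_len), "")
        t_start <- (cfg$chrom_len - cfg$target_span) %/% 2L + 1L
        t_end <- t_start + cfg$target_span - 1L
        reserved <- lapply(chroms, function(x) logical(cfg$chrom_len))
        names(reserved) <- chroms

        # normalize clone deletions; plant microhomology / insertion signatures
        clones <- list()
        for (ci in seq_along(cfg$clones)) {
            cl <- cfg$clones[[ci]]
            dels <- NULL
            if (!is.null(cl$deletions) && nrow(cl$deletions)) {
                dels <- data.table::as.data.table(cl$deletions)
                if (is.null(dels$snv_flank)) dels[, snv_flank := NA_character_]
                if (is.null(dels$snv_dist)) dels[, snv_dist := NA_integer_]
                dels[, chrom := chroms[locus]]
                dels[, sv_id := sprintf("clone%d_sv%d", ci, .I)]
                for (k in seq_len(nrow(dels))) {
                    L <- dels$pos1[k]; R <- dels$pos2[k]
                    h <- dels$mh[k]; ins <- dels$insert[k]
                    ch <- dels$chrom[k]
                    if (L < t_start || R > t_end)
                        stop2("clone deletion outside capture target")
                    if (R - L - 1L < h + 3L)
                        stop2("deletion too small for microhomology ", h)
                    if (nzchar(ins) && h > 0)
                        stop2("a junction has either microhomology or insertion")
                    s <- seqs[[ch]]
                    if (h > 0) {
                        substr(s, L + 1L, L + h) <- substr(s, R, R + h - 1L)
                        substr(s, L + h + 1L, L + h + 1L) <-
                            mutate_differ(substr(s, R + h, R + h), NULL)
                    } else if (!nzchar(ins)) {
                        substr(s, L + 1L, L + 1L) <-
                            mutate_differ(substr(s, R, R), NULL)
                    } else {
                        substr(s, L + 1L, L + 1L) <-
                            mutate_differ(substr(ins, 1L, 1L), NULL)
                    }
                    # forbid leftward slide (and insert suffix homology)
                    avoidL <- if (nzchar(ins))
                        substr(ins, nchar(ins), nchar(ins))
                    else substr(s, L, L)
                    substr(s, R - 1L, R - 1L) <- mutate_differ(avoidL, NULL)
                    seqs[[ch]] <- s
                    reserved[[ch]][max(1L, L - 40L):min(cfg$chrom_len, R + 40L)] <- TRUE
                }
            }
            clones[[ci]] <- list(fraction = cl$fraction, deletions = dels)
        }

        pick_free <- function(ch, lo, hi, pad) {
            for (tries in 1:200) {
                p <- sample(lo:hi, 1L)
                win <- max(1L, p - pad):min(cfg$chrom_len, p + pad)
                if (!any(reserved[[ch]][win])) return(p)
            }
            NA_integer_
        }

        # chimeric PCR template-switch sites: k-mer at (chrom1, s) copied to
        # just before (chrom2, r2), so switching at the shared k-mer yields
        # a junction with ~k bases of microhomology
        csites <- data.table::data.table()
        for (i in seq_len(cfg$n_chimera_sites)) {
            k <- sample(cfg$mh_lengths, 1L, prob = cfg$mh_weights)
            c1 <- sample(chroms, 1L)
            c2 <- if (cfg$n_chrom > 1L) sample(setdiff(chroms, c1), 1L) else c1
            s <- pick_free(c1, t_start + 60L, t_end - 60L, k + 4L)
            r2 <- pick_free(c2, t_start + 60L, t_end - 60L, k + 4L)
            if (is.na(s) || is.na(r2) || (c1 == c2 && abs(r2 - s) < 2000L)) next
            substr(seqs[[c2]], r2 - k, r2 - 1L) <- substr(seqs[[c1]], s - k + 1L, s)
            reserved[[c1]][(s - k - 2L):(s + 2L)] <- TRUE
            reserved[[c2]][(r2 - k - 2L):(r2 + 2L)] <- TRUE
            csites <- rbind(csites, data.table::data.table(
                chrom1 = c1, s = s, chrom2 = c2, r2 = r2, k = k))
        }

        # foldback inversion sites: reverse-complement homology planted after
        # the inner breakpoint supports an intramolecular fold at p_outer
        fsites <- data.table::data.table()
        for (i in seq_len(cfg$n_foldback_sites)) {
            k <- sample(cfg$mh_lengths, 1L, prob = cfg$mh_weights)
            ch <- sample(chroms, 1L)
            delta <- sample(80:900, 1L)
            pi_ <- pick_free(ch, t_start + 60L, t_end - 60L - delta, k + 4L)
            if (is.na(pi_)) next
            po <- pi_ + delta
            if (any(reserved[[ch]][(po - k - 2L):(po + 2L)])) next
            substr(seqs[[ch]], pi_ + 1L, pi_ + k) <-
                revcomp(substr(seqs[[ch]], po - k + 1L, po))
            reserved[[ch]][(pi_ - 2L):(pi_ + k + 2L)] <- TRUE
            reserved[[ch]][(po - k - 2L):(po + 2L)] <- TRUE
            fsites <- rbind(fsites, data.table::data.table(
                chrom = ch, p_outer = po, p_inner = pi_, k = k))
        }

        genome <- genome_model(stats::setNames(Biostrings::DNAStringSet(seqs),
                                               chroms))
        targets <- targets_from_granges(
            GenomicRanges::GRanges(chroms,
                                   IRanges::IRanges(t_start, t_end),
                                   name = paste0("locus_", seq_along(chroms))),
            adjacent_span = cfg$adjacent_span, genome = genome)

        # truth metrics and de novo SNV positions for clone deletions
        for (ci in seq_along(clones)) {
            dels <- clones[[ci]]$deletions
            if (is.null(dels)) next
            for (k in seq_len(nrow(dels))) {
                tm <- truth_junction_metric(genome, dels$chrom[k], dels$pos1[k],
                                            "L", dels$chrom[k], dels$pos2[k],
                                            "R", dels$insert[k])
                dels[k, `:=`(metric = tm$metric, mh_left = tm$mh_left,
                             mh_right = tm$mh_right)]
                if (!is.na(dels$snv_flank[k])) {
                    d <- dels$snv_dist[k]
                    if (is.na(d) || d < 2L) stop2("snv_dist must be >= 2")
                    p <- if (dels$snv_flank[k] == "left") dels$pos1[k] - d + 1L
                         else dels$pos2[k] + tm$mh_right + d - 1L
                    ref <- genome_seq(genome, dels$chrom[k], p, p)
                    dels[k, `:=`(snv_pos = p,
                                 snv_base = mutate_differ(ref, NULL))]
                }
            }
            if (is.null(dels$snv_pos)) dels[, `:=`(snv_pos = NA_integer_,
                                                   snv_base = NA_character_)]
            clones[[ci]]$deletions <- dels
        }

        paths <- list()
        if (!is.null(dir)) {
            if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
            paths$fasta <- file.path(dir, "genome.fa")
            paths$bed <- file.path(dir, "targets.bed")
            write_genome_fasta(genome, paths$fasta)
            write_targets_bed(targets, paths$bed)
        }
        structure(list(genome = genome, targets = targets, clones = clones,
                       chimera_sites = csites, foldback_sites = fsites,
                       cfg = cfg, paths = paths),
                  class = "SimGenome")
    })
}

## ---- library simulation ----------------------------------------------------

inject_errors <- function(seqs, rate) {
    if (rate <= 0 || !length(seqs)) return(seqs)
    w <- nchar(seqs)
    total <- sum(w)
    k <- stats::rbinom(1L, total, rate)
    if (k == 0L) return(seqs)
    pos <- sample.int(total, k)
    big <- charToRaw(paste(seqs, collapse = ""))
    bases <- charToRaw("ACGT")
    cur <- match(big[pos], bases)
    cur[is.na(cur)] <- 1L
    new <- (cur - 1L + sample.int(3L, k, replace = TRUE)) %% 4L + 1L
    big[pos] <- bases[new]
    all <- rawToChar(big)
    ends <- cumsum(w)
    substring(all, ends - w + 1L, ends)
}

zip_family <- function(n, p0, lambda) {
    z <- stats::rbinom(n, 1L, 1 - p0)
    z * (1L + stats::rpois(n, lambda))
}

# Build one molecule's sequence from its segment path (+ optional inserts
# between segments); segments carry molecule-coordinates m1/m2.
compose_molecule <- function(chrseqs, segs, inserts) {
    parts <- character(0)
    for (i in seq_len(nrow(segs))) {
        s <- substr(chrseqs[[segs$chrom[i]]], segs$ref_s[i], segs$ref_e[i])
        if (segs$strand[i] == "-") s <- revcomp(s)
        parts <- c(parts, s)
        if (i < nrow(segs) && nzchar(inserts[i])) parts <- c(parts, inserts[i])
    }
    paste(parts, collapse = "")
}

# Emit SAM-record rows for one read pair of a multi-segment molecule.
# segs: data.table(chrom, ref_s, ref_e, strand, m1, m2) in molecule order.
emit_pair_records <- function(molS, segs, qname, flags_base, read_len,
                              min_align, mapq) {
    L <- nchar(molS)
    rl <- min(read_len, L)
    win <- list(A = c(1L, rl), B = c(L - rl + 1L, L))
    recs <- list()
    for (r in c("A", "B")) {
        w1 <- win[[r]][1]; w2 <- win[[r]][2]
        rho <- if (r == "A") "+" else "-"
        rows <- list()
        for (i in seq_len(nrow(segs))) {
            o1 <- max(w1, segs$m1[i]); o2 <- min(w2, segs$m2[i])
            if (o2 - o1 + 1L < min_align) next
            if (segs$strand[i] == "+") {
                rs <- segs$ref_s[i] + (o1 - segs$m1[i])
                re <- segs$ref_s[i] + (o2 - segs$m1[i])
            } else {
                re <- segs$ref_e[i] - (o1 - segs$m1[i])
                rs <- segs$ref_e[i] - (o2 - segs$m1[i])
            }
            leadM <- o1 - w1; trailM <- w2 - o2
            lead <- if (segs$strand[i] == "+") leadM else trailM
            trail <- if (segs$strand[i] == "+") trailM else leadM
            rows[[length(rows) + 1L]] <- data.table::data.table(
                chrom = segs$chrom[i], pos = rs, width = o2 - o1 + 1L,
                strand = segs$strand[i], lead = lead, trail = trail,
                reverse = segs$strand[i] != rho)
        }
        if (!length(rows)) next
        rows <- data.table::rbindlist(rows)
        raw <- substr(molS, w1, w2)  # molecule orientation
        rows[, cigar := paste0(data.table::fifelse(lead > 0, paste0(lead, "S"), ""),
                               width, "M",
                               data.table::fifelse(trail > 0, paste0(trail, "S"), ""))]
        rows[, seq := data.table::fifelse(strand == "+", raw, revcomp(raw))]
        rows[, primary := seq_len(.N) == which.max(width)]
        rows[, read := r]
        recs[[length(recs) + 1L]] <- rows
    }
    if (!length(recs)) return(NULL)
    recs <- data.table::rbindlist(recs)
    recs[, qname := qname]
    recs[, mapq := mapq]
    # SA tags chain the records of one read
    recs[, sa := NA_character_]
    for (r in c("A", "B")) {
        idx <- which(recs$read == r)
        if (length(idx) > 1L) {
            for (i in idx) {
                oth <- setdiff(idx, i)
                recs$sa[i] <- paste0(recs$chrom[oth], ",", recs$pos[oth], ",",
                                     data.table::fifelse(recs$reverse[oth], "-", "+"),
                                     ",", recs$cigar[oth], ",", recs$mapq[oth],
                                     ",0;", collapse = "")
            }
        }
    }
    recs[]
}

#' Simulate an aligned capture library with ground truth
#'
#' Draws capture-enriched fragments from the configured clone mixture,
#' generates artifact molecules per their mechanism (ligation chimeras before
#' strand separation, chimeric PCR per amplified strand with family size 1
#' and a shared outer endpoint, tagmentation foldbacks), replicates molecules
#' into strand families, applies per-base sequencing error, and emits
#' name-grouped SAM records (split junction reads as primary + supplementary
#' with SA tags) plus a per-read-pair truth table.
#'
#' @param simg A `SimGenome` from [make_genome()].
#' @param dir Output directory; `reads.sam`, `truth.tsv` and `config.yaml`
#'   are written there.
#' @param sample Sample name recorded in the truth table.
#' @return list(sam, truth, truth_table, config) with file paths and the
#'   in-memory truth data.table.
#' @export
simulate_library <- function(simg, dir, sample = "sample1") {
    cfg <- simg$cfg
    genome <- simg$genome
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    chrseqs <- lapply(seq_along(genome$seqs),
                      function(i) as.character(genome$seqs[[i]]))
    names(chrseqs) <- names(genome$lengths)
    umis <- umi_set()
    tgt <- simg$targets$targets
    t_start <- GenomicRanges::start(tgt); t_end <- GenomicRanges::end(tgt)
    t_chrom <- as.character(GenomeInfoDb::seqnames(tgt))
    fp <- cfg$frag_peak
    fmax <- cfg$frag_peak + 4L * cfg$frag_sd
    ligation <- cfg$mode == "ligation_duplex"

    with_seed(cfg$seed, {
        frag_len <- function(n) pmax(80L, as.integer(round(
            stats::rnorm(n, fp, cfg$frag_sd))))

        cl_frac <- vapply(simg$clones, function(x) x$fraction, numeric(1))
        probs <- c(1 - sum(cl_frac), cl_frac)

        ## -- proper / clone fragments over target windows ------------------
        mols <- list()   # per-molecule rows
        mseg <- list()   # multi-segment paths, keyed by molecule id
        mid <- 0L
        new_ids <- function(n) { ids <- mid + seq_len(n); mid <<- mid + n; ids }

        for (li in seq_along(tgt)) {
            tlen <- t_end[li] - t_start[li] + 1L
            n <- round(cfg$molecule_depth * (tlen + fp) / fp)
            fl <- frag_len(n)
            cl <- sample.int(length(probs), n, replace = TRUE, prob = probs) - 1L
            hap <- sample.int(2L, n, replace = TRUE)
            # background / hap1 fragments live on reference coordinates
            ids <- new_ids(n)
            base <- data.table::data.table(
                id = ids, chrom = t_chrom[li], fl = fl, clone = cl, hap = hap,
                locus = li)
            # alt-coordinate mapping for clone SV haplotypes
            base[, alt := FALSE]
            for (ci in seq_along(simg$clones)) {
                dels <- simg$clones[[ci]]$deletions
                if (is.null(dels)) next
                dl <- dels[locus == li]
                if (!nrow(dl)) next
                base[clone == ci & hap == 2L, alt := TRUE]
            }
            base[, start := t_start[li] - fl +
                     as.integer(floor(stats::runif(.N) * (tlen + fl)))]
            mols[[length(mols) + 1L]] <- base
        }
        frag <- data.table::rbindlist(mols)

        # resolve alt fragments into segment paths across deletion junctions
        frag[, class := "proper"]
        frag[, sv_id := NA_character_]
        frag[, insert := ""]
        frag[, end := start + fl - 1L]
        seg_paths <- list()
        if (any(frag$alt)) {
            for (ci in seq_along(simg$clones)) {
                dels <- simg$clones[[ci]]$deletions
                if (is.null(dels)) next
                for (k in seq_len(nrow(dels))) {
                    L <- dels$pos1[k]; R <- dels$pos2[k]
                    ins <- dels$insert[k]; dsz <- R - L - 1L
                    idx <- which(frag$alt & frag$clone == ci &
                                 frag$chrom == dels$chrom[k] &
                                 frag$start <= L & frag$end > L)
                    if (!length(idx)) next
                    for (j in idx) {
                        # fragment drawn on ALT coordinates: bases past L
                        # continue at R (deletion skipped)
                        lf <- L - frag$start[j] + 1L       # left block len
                        rest <- frag$fl[j] - lf - nchar(ins)
                        if (rest < 1L) next
                        segs <- data.table::data.table(
                            chrom = frag$chrom[j],
                            ref_s = c(frag$start[j], R),
                            ref_e = c(L, R + rest - 1L),
                            strand = "+")
                        frag$class[j] <- "trueSV"
                        frag$sv_id[j] <- dels$sv_id[k]
                        frag$insert[j] <- ins
                        seg_paths[[as.character(frag$id[j])]] <- segs
                    }
                }
            }
            # shift remaining alt fragments right of a deletion back onto
            # reference coordinates (they sampled ALT space)
            for (ci in seq_along(simg$clones)) {
                dels <- simg$clones[[ci]]$deletions
                if (is.null(dels)) next
                for (k in seq_len(nrow(dels))) {
                    L <- dels$pos1[k]; R <- dels$pos2[k]
                    idx <- which(frag$alt & frag$clone == ci &
                                 frag$chrom == dels$chrom[k] &
                                 frag$class == "proper" & frag$start > L)
                    if (length(idx)) {
                        frag[idx, `:=`(start = start + (R - L - 1L),
                                       end = end + (R - L - 1L))]
                    }
                }
            }
        }

        ## -- adjacent and off-target background fragments -------------------
        adj <- simg$targets$adjacent
        n_adj <- round(cfg$a_accept * cfg$molecule_depth *
                       sum(GenomicRanges::width(adj)) / fp)
        if (n_adj > 0) {
            pick <- sample.int(length(adj), n_adj, replace = TRUE,
                               prob = GenomicRanges::width(adj))
            fl <- frag_len(n_adj)
            st <- GenomicRanges::start(adj)[pick] - fl +
                as.integer(floor(stats::runif(n_adj) *
                                 (GenomicRanges::width(adj)[pick] + fl)))
            st <- pmax(1L, st)
            a <- data.table::data.table(
                id = new_ids(n_adj),
                chrom = as.character(GenomeInfoDb::seqnames(adj))[pick],
                fl = fl, clone = 0L, hap = 1L, locus = adj$locus[pick],
                alt = FALSE, start = st, class = "proper",
                sv_id = NA_character_, insert = "", end = st + fl - 1L)
            frag <- rbind(frag, a)
        }
        glen <- sum(as.numeric(genome$lengths))
        n_off <- round(cfg$other_accept * cfg$molecule_depth * glen / fp)
        if (n_off > 0) {
            ch <- sample(names(genome$lengths), n_off, replace = TRUE,
                         prob = as.numeric(genome$lengths))
            fl <- frag_len(n_off)
            st <- pmax(1L, as.integer(floor(stats::runif(n_off) *
                       (genome$lengths[ch] - fl))) + 1L)
            o <- data.table::data.table(
                id = new_ids(n_off), chrom = ch, fl = fl, clone = 0L,
                hap = 1L, locus = NA_integer_, alt = FALSE, start = st,
                class = "proper", sv_id = NA_character_, insert = "",
                end = st + fl - 1L)
            frag <- rbind(frag, o)
        }
        frag[, end := pmin(end, genome$lengths[chrom])]
        frag[, start := pmax(1L, start)]
        frag[, fl := end - start + 1L]
        n_proper <- sum(frag$class == "proper")

        ## -- artifacts -------------------------------------------------------
        art <- list()
        lig_rate <- if (ligation) cfg$ligation_chimera_rate
                    else cfg$ligation_chimera_rate
        n_lig <- stats::rpois(1L, lig_rate * n_proper)
        for (i in seq_len(n_lig)) {
            li <- sample.int(length(tgt), 1L)
            flA <- frag_len(1L); flB <- frag_len(1L)
            sa_ <- t_start[li] - flA +
                as.integer(floor(stats::runif(1L) *
                                 (t_end[li] - t_start[li] + 1L + flA)))
            sa_ <- max(1L, sa_)
            ea_ <- min(sa_ + flA - 1L, genome$lengths[[t_chrom[li]]])
            cB <- sample(names(genome$lengths), 1L,
                         prob = as.numeric(genome$lengths))
            sb_ <- sample.int(genome$lengths[[cB]] - flB, 1L)
            sigB <- sample(c("+", "-"), 1L)
            ins <- if (stats::runif(1L) < cfg$blunt_frac) "" else {
                if (stats::runif(1L) < cfg$at_frac) sample(c("A", "T"), 1L)
                else sample(c("C", "G"), 1L)
            }
            id <- new_ids(1L)
            segs <- data.table::data.table(
                chrom = c(t_chrom[li], cB),
                ref_s = c(sa_, sb_), ref_e = c(ea_, sb_ + flB - 1L),
                strand = c("+", sigB))
            seg_paths[[as.character(id)]] <- segs
            art[[length(art) + 1L]] <- data.table::data.table(
                id = id, chrom = t_chrom[li], fl = flA + flB + nchar(ins),
                clone = 0L, hap = 1L, locus = li, alt = FALSE, start = sa_,
                class = "ligation", sv_id = paste0("lig", i), insert = ins,
                end = ea_)
        }

        n_chim <- if (nrow(simg$chimera_sites))
            stats::rpois(1L, cfg$chimeric_pcr_rate * n_proper) else 0L
        # template switching is a unique late-PCR event: one junction site
        # per artifact (warn when the planted pool limits the count)
        if (n_chim > nrow(simg$chimera_sites)) {
            warning("chimeric PCR count capped by the planted site pool; ",
                    "raise n_chimera_sites")
            n_chim <- nrow(simg$chimera_sites)
        }
        chim_sites <- if (n_chim > 0L)
            sample.int(nrow(simg$chimera_sites), n_chim) else integer(0)
        chim_partner <- integer(0)
        for (i in seq_len(n_chim)) {
            st_ <- simg$chimera_sites[chim_sites[i]]
            # chimeric PCR products are sequencer-sized molecules: the
            # junction is covered by the reads (split evidence)
            u <- sample(50:110, 1L)
            v <- sample(90:150, 1L)
            a <- st_$s - u
            if (a < 1L) next
            # partner proper molecule sharing the left outer endpoint
            pid <- new_ids(1L)
            flp <- frag_len(1L)
            partner <- data.table::data.table(
                id = pid, chrom = st_$chrom1, fl = flp, clone = 0L, hap = 1L,
                locus = NA_integer_, alt = FALSE, start = a, class = "proper",
                sv_id = NA_character_, insert = "",
                end = min(a + flp - 1L, genome$lengths[[st_$chrom1]]))
            frag <- rbind(frag, partner)
            id <- new_ids(1L)
            segs <- data.table::data.table(
                chrom = c(st_$chrom1, st_$chrom2),
                ref_s = c(a, st_$r2), ref_e = c(st_$s, st_$r2 + v - 1L),
                strand = "+")
            seg_paths[[as.character(id)]] <- segs
            art[[length(art) + 1L]] <- data.table::data.table(
                id = id, chrom = st_$chrom1, fl = u + v, clone = 0L, hap = 1L,
                locus = NA_integer_, alt = FALSE, start = a,
                class = "chimericPCR", sv_id = paste0("chim", i), insert = "",
                end = st_$s)
            chim_partner <- c(chim_partner, pid)
            names(chim_partner)[length(chim_partner)] <- as.character(id)
        }

        n_fb <- if (!ligation && nrow(simg$foldback_sites))
            stats::rpois(1L, cfg$foldback_rate * n_proper) else 0L
        if (n_fb > nrow(simg$foldback_sites)) {
            warning("foldback count capped by the planted site pool; ",
                    "raise n_foldback_sites")
            n_fb <- nrow(simg$foldback_sites)
        }
        fb_sites <- if (n_fb > 0L)
            sample.int(nrow(simg$foldback_sites), n_fb) else integer(0)
        for (i in seq_len(n_fb)) {
            st_ <- simg$foldback_sites[fb_sites[i]]
            u <- sample(120:260, 1L)
            v <- sample((cfg$min_align + 20L):130L, 1L)
            a <- st_$p_outer - u + 1L
            if (a < 1L || st_$p_inner - v + 1L < 1L) next
            id <- new_ids(1L)
            segs <- data.table::data.table(
                chrom = st_$chrom,
                ref_s = c(a, st_$p_inner - v + 1L),
                ref_e = c(st_$p_outer, st_$p_inner),
                strand = c("+", "-"))
            seg_paths[[as.character(id)]] <- segs
            art[[length(art) + 1L]] <- data.table::data.table(
                id = id, chrom = st_$chrom, fl = u + v, clone = 0L, hap = 1L,
                locus = NA_integer_, alt = FALSE, start = a,
                class = "foldback", sv_id = paste0("fb", i), insert = "",
                end = st_$p_outer)
        }
        if (length(art)) frag <- rbind(frag, data.table::rbindlist(art))

        ## -- strand families, UMIs, molecule bookkeeping --------------------
        n <- nrow(frag)
        if (n == 0L) stop2("simulation produced no molecules; raise depth")
        if (ligation) {
            frag[, fam1 := zip_family(.N, cfg$fam_zero, cfg$fam_lambda)]
            frag[, fam2 := zip_family(.N, cfg$fam_zero, cfg$fam_lambda)]
            frag[class == "chimericPCR", `:=`(fam1 = 1L, fam2 = 0L)]
            frag[, umi1 := sample.int(96L, .N, replace = TRUE)]
            frag[, umi2 := sample.int(96L, .N, replace = TRUE)]
            # late-PCR chimeras inherit the UMI pair of their template partner
            if (length(chim_partner)) {
                pm <- match(chim_partner, frag$id)
                am <- match(as.integer(names(chim_partner)), frag$id)
                frag$umi1[am] <- frag$umi1[pm]
                frag$umi2[am] <- frag$umi2[pm]
            }
        } else {
            frag[, fam1 := 1L + stats::rpois(.N, cfg$fam_lambda)]
            frag[, fam2 := 0L]
            frag[, umi1 := NA_integer_]
            frag[, umi2 := NA_integer_]
            # Tn5 molecules are sequenced in one orientation; opposite
            # orientations are independent cleavage products
            frag[, orient := sample.int(2L, .N, replace = TRUE)]
        }
        frag <- frag[fam1 + fam2 > 0L]

        ## -- expand to read pairs and emit records --------------------------
        frag[, multi := as.character(id) %in% names(seg_paths)]
        tot <- frag$fam1 + frag$fam2
        ridx <- rep(seq_len(nrow(frag)), tot)
        within <- sequence(tot)
        pairs <- frag[ridx]
        pairs[, strand := data.table::fifelse(within <= fam1, 1L, 2L)]
        pairs[, rep := data.table::fifelse(strand == 1L, within,
                                           within - fam1)]
        if (!ligation) pairs[, strand := orient]
        pairs[, qname := sprintf("f%07d:s%d:p%02d", id, strand, rep)]

        qual_cache <- new.env()
        qual_str <- function(w) {
            key <- as.character(w)
            if (is.null(qual_cache[[key]]))
                qual_cache[[key]] <- strrep("I", w)
            qual_cache[[key]]
        }

        simple <- pairs[multi == FALSE]
        recs <- list()
        if (nrow(simple)) {
            rl <- cfg$read_len
            simple[, w := pmin(rl, fl)]
            # readA at the left molecule end (+), readB at the right end (-)
            recA <- simple[, .(qname, chrom, pos = start, width = w,
                               reverse = FALSE, read = "A", strand)]
            recB <- simple[, .(qname, chrom, pos = end - w + 1L, width = w,
                               reverse = TRUE, read = "B", strand)]
            ab <- rbind(recA, recB)
            ab[, cigar := paste0(width, "M")]
            ab[, primary := TRUE]
            ab[, sa := NA_character_]
            ab[, mapq := 60L]
            # vectorized sequence extraction per chromosome
            ab[, seq := ""]
            for (ch in unique(ab$chrom)) {
                ii <- which(ab$chrom == ch)
                ab$seq[ii] <- substring(chrseqs[[ch]], ab$pos[ii],
                                        ab$pos[ii] + ab$width[ii] - 1L)
            }
            recs[[length(recs) + 1L]] <- ab
        }
        # de novo SNVs ride on the junction-bearing derivative molecules
        snv_map <- list()
        for (cl in simg$clones) {
            d <- cl$deletions
            if (is.null(d)) next
            for (k in which(!is.na(d$snv_pos)))
                snv_map[[d$sv_id[k]]] <- list(chrom = d$chrom[k],
                                              pos = d$snv_pos[k],
                                              base = d$snv_base[k])
        }
        cx <- pairs[multi == TRUE]
        if (nrow(cx)) {
            for (j in seq_len(nrow(cx))) {
                segs <- data.table::copy(seg_paths[[as.character(cx$id[j])]])
                wids <- segs$ref_e - segs$ref_s + 1L
                ins <- cx$insert[j]
                m1 <- cumsum(c(1L, wids[-length(wids)] +
                               ifelse(nzchar(ins), nchar(ins), 0L)))
                segs[, m1 := m1]
                segs[, m2 := m1 + wids - 1L]
                molS <- compose_molecule(chrseqs, segs,
                                         rep(ins, max(0L, nrow(segs) - 1L)))
                sv <- cx$sv_id[j]
                if (!is.na(sv) && !is.null(snv_map[[sv]])) {
                    vv <- snv_map[[sv]]
                    for (sgi in seq_len(nrow(segs))) {
                        if (segs$chrom[sgi] == vv$chrom &&
                            vv$pos >= segs$ref_s[sgi] &&
                            vv$pos <= segs$ref_e[sgi]) {
                            mc <- if (segs$strand[sgi] == "+")
                                segs$m1[sgi] + (vv$pos - segs$ref_s[sgi])
                            else segs$m1[sgi] + (segs$ref_e[sgi] - vv$pos)
                            bb <- if (segs$strand[sgi] == "+") vv$base
                                  else chartr("ACGT", "TGCA", vv$base)
                            substr(molS, mc, mc) <- bb
                        }
                    }
                }
                rr <- emit_pair_records(molS, segs, cx$qname[j], 0L,
                                        cfg$read_len, cfg$min_align, 60L)
                if (is.null(rr)) next
                rr[, strand := cx$strand[j]]
                recs[[length(recs) + 1L]]  <- rr[, .(qname, chrom, pos, width,
                                                     reverse, read, strand,
                                                     cigar, primary, sa, mapq,
                                                     seq)]
            }
        }
        recs <- data.table::rbindlist(recs, use.names = TRUE)
        # drop pairs where one mate had no alignable block at all
        ok <- recs[primary == TRUE, .(both = length(unique(read)) == 2L),
                   by = qname][both == TRUE, qname]
        recs <- recs[qname %in% ok]
        pairs <- pairs[qname %in% ok]
        recs[, seq := inject_errors(seq, cfg$error_rate)]
        if (cfg$low_mapq_frac > 0) {
            low <- stats::runif(nrow(recs)) < cfg$low_mapq_frac
            recs$mapq[low] <- cfg$low_mapq
        }

        # pair-level SAM fields: mate position/strand from the mate's primary
        prim <- recs[primary == TRUE, .(qname, read, chrom, pos, reverse)]
        mates <- data.table::dcast(prim, qname ~ read,
                                   value.var = c("chrom", "pos", "reverse"))
        recs <- merge(recs, mates, by = "qname", sort = FALSE)
        recs[, mate_chrom := data.table::fifelse(read == "A", chrom_B, chrom_A)]
        recs[, mate_pos := data.table::fifelse(read == "A", pos_B, pos_A)]
        recs[, mate_rev := data.table::fifelse(read == "A", reverse_B, reverse_A)]
        # read1/read2 assignment mirrors the sequenced strand
        recs[, is_r1 := (read == "A") == (strand == 1L)]
        recs[, flag := 1L +
                 16L * as.integer(reverse) + 32L * as.integer(mate_rev) +
                 64L * as.integer(is_r1) + 128L * as.integer(!is_r1) +
                 2048L * as.integer(!primary)]

        # observed UMI pairs (with sequencing error), strand-ordered
        pairs_rx <- NULL
        if (ligation) {
            upairs <- unique(pairs[, .(qname, strand, umi1, umi2)])
            u1s <- inject_errors(umis[upairs$umi1], cfg$error_rate)
            u2s <- inject_errors(umis[upairs$umi2], cfg$error_rate)
            upairs[, rx := data.table::fifelse(strand == 1L,
                                               paste0(u1s, "-", u2s),
                                               paste0(u2s, "-", u1s))]
            recs <- merge(recs, upairs[, .(qname, rx)], by = "qname",
                          sort = FALSE)
        } else recs[, rx := NA_character_]

        recs[, pr := -as.integer(primary)]
        data.table::setorder(recs, qname, pr, read)
        recs[, pr := NULL]
        recs[, qual := vapply(nchar(seq), qual_str, "")]

        ## -- write SAM -------------------------------------------------------
        sam_path <- file.path(dir, "reads.sam")
        hdr <- c("@HD\tVN:1.6\tSO:queryname",
                 paste0("@SQ\tSN:", names(genome$lengths), "\tLN:",
                        unname(genome$lengths)),
                 paste0("@RG\tID:", sample, "\tSM:", sample))
        lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s",
                         recs$qname, recs$flag, recs$chrom, recs$pos,
                         recs$mapq, recs$cigar,
                         data.table::fifelse(recs$mate_chrom == recs$chrom, "=",
                                             recs$mate_chrom),
                         recs$mate_pos, recs$seq, recs$qual)
        tags <- character(nrow(recs))
        has_rx <- !is.na(recs$rx)
        tags[has_rx] <- paste0("\tRX:Z:", recs$rx[has_rx])
        has_sa <- !is.na(recs$sa)
        tags[has_sa] <- paste0(tags[has_sa], "\tSA:Z:", recs$sa[has_sa])
        writeLines(c(hdr, paste0(lines, tags)), sam_path)

        ## -- truth table -----------------------------------------------------
        truth <- pairs[, .(qname, frag_id = id, class, sv_id, strand, rep,
                           fam1, fam2, clone, locus,
                           outer1_chrom = chrom, outer1_pos = start,
                           outer2_pos = end)]
        # junction node truth for non-proper classes
        truth[, `:=`(chrom1 = NA_character_, pos1 = NA_integer_,
                     side1 = NA_character_, chrom2 = NA_character_,
                     pos2 = NA_integer_, side2 = NA_character_,
                     metric = NA_integer_, insert = "",
                     shared_partner = NA_integer_,
                     snv_pos = NA_integer_, snv_base = NA_character_,
                     snv_dist = NA_integer_, snv_flank = NA_character_)]
        jinfo <- list()
        for (ci in seq_along(simg$clones)) {
            dels <- simg$clones[[ci]]$deletions
            if (!is.null(dels))
                jinfo[[length(jinfo) + 1L]] <- dels[, .(
                    sv_id, chrom1 = chrom, pos1, side1 = "L",
                    chrom2 = chrom, pos2, side2 = "R",
                    metric = as.integer(metric), insert,
                    snv_pos, snv_base, snv_dist,
                    snv_flank)]
        }
        fa <- frag[multi == TRUE & class != "trueSV"]
        if (nrow(fa)) {
            arows <- lapply(seq_len(nrow(fa)), function(j) {
                segs <- seg_paths[[as.character(fa$id[j])]]
                n1 <- node_after_segment(segs[1])
                n2 <- node_before_segment(segs[2])
                tm <- truth_junction_metric(genome, n1$chrom, n1$pos, n1$side,
                                            n2$chrom, n2$pos, n2$side,
                                            fa$insert[j])
                data.table::data.table(
                    sv_id = fa$sv_id[j], chrom1 = n1$chrom, pos1 = n1$pos,
                    side1 = n1$side, chrom2 = n2$chrom, pos2 = n2$pos,
                    side2 = n2$side, metric = as.integer(tm$metric),
                    insert = fa$insert[j], snv_pos = NA_integer_,
                    snv_base = NA_character_, snv_dist = NA_integer_,
                    snv_flank = NA_character_)
            })
            jinfo[[length(jinfo) + 1L]] <- data.table::rbindlist(arows)
        }
        if (length(jinfo)) {
            jinfo <- data.table::rbindlist(jinfo)
            truth[jinfo, on = "sv_id", `:=`(
                chrom1 = i.chrom1, pos1 = i.pos1, side1 = i.side1,
                chrom2 = i.chrom2, pos2 = i.pos2, side2 = i.side2,
                metric = i.metric, insert = i.insert, snv_pos = i.snv_pos,
                snv_base = i.snv_base, snv_dist = i.snv_dist,
                snv_flank = i.snv_flank)]
        }
        if (length(chim_partner)) {
            pm <- data.table::data.table(
                frag_id = as.integer(names(chim_partner)),
                partner = unname(chim_partner))
            truth[pm, on = "frag_id", shared_partner := i.partner]
        }
        truth[, sample := sample]
        truth_path <- file.path(dir, "truth.tsv")
        data.table::fwrite(truth, truth_path, sep = "\t")
        cfg_path <- file.path(dir, "config.yaml")
        yaml::write_yaml(cfg[!vapply(cfg, is.list, logical(1))], cfg_path)
        list(sam = sam_path, truth = truth_path, truth_table = truth[],
             config = cfg_path)
    })
}

#' Classify SV calls against simulator ground truth
#'
#' Joins the supporting molecules of each call to the truth table (via their
#' representative read names' fragment ids) and assigns each call the
#' majority class of its supporters (ties break toward the artifact class,
#' the conservative direction for filter validation).
#'
#' @param support Support table from [find_svs()].
#' @param pairs Pair-to-molecule map from [collate_molecules()] (rbind over
#'   samples for co-analysis).
#' @param truth Truth table from [simulate_library()].
#' @return data.table(sv_id, truth_class, n_truth) keyed by sv_id.
#' @export
truth_classify_calls <- function(support, pairs, truth) {
    mp <- merge(pairs, truth[, .(qname, class)], by = "qname")
    mcl <- unique(mp[, .(mol_id, class)])
    sup <- merge(support[, .(sv_id, mol_id)], mcl, by = "mol_id",
                 allow.cartesian = TRUE)
    cnt <- sup[, .(n = .N), by = .(sv_id, class)]
    cnt[, art := class != "proper" & class != "trueSV"]
    data.table::setorder(cnt, sv_id, -n, -art)
    out <- cnt[, .(truth_class = class[1], n_truth = sum(n)), by = sv_id]
    data.table::setkey(out, sv_id)
    out
}

# exit node of a traversed segment / entry node of the next
node_after_segment <- function(seg) {
    if (seg$strand == "+") list(chrom = seg$chrom, pos = seg$ref_e, side = "L")
    else list(chrom = seg$chrom, pos = seg$ref_s, side = "R")
}
node_before_segment <- function(seg) {
    if (seg$strand == "+") list(chrom = seg$chrom, pos = seg$ref_s, side = "R")
    else list(chrom = seg$chrom, pos = seg$ref_e, side = "L")
}
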