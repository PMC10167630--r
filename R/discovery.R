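# discovery: assemble per-molecule junction candidates into SV calls across
# molecules and samples, purge near-duplicate molecules, recover outer-clip
# support, reconstruct gap-only junctions and characterize each junction
# (microhomology / de novo insertion, consensus sequence, target class).

#' Two-pass clustering of junction candidates into SV sets
#'
#' Candidates (all co-analyzed samples together) are sorted by the left node
#' and broken into sets wherever consecutive left nodes are separated by at
#' least the maximum proper insert size (or the chromosome/side changes);
#' each set is re-sorted by the right node and the process repeated. Within
#' a final set, distinct exact split-read node pairs become distinct calls;
#' gap-evidence molecules attach to the nearest compatible split junction,
#' or form an imprecise call of their own.
#'
#' @param candidates Combined candidate table from [extract_junctions()]
#'   (rbind over samples, after [flag_shared_endpoints()]).
#' @param max_proper_insert Set-breaking distance (bp).
#' @return list(svs, support): the SV table and the per-supporting-molecule
#'   table keyed by `sv_id`.
#' @export
find_sv_sets <- function(candidates, max_proper_insert) {
    if (!nrow(candidates)) {
        return(list(svs = empty_svs(), support = empty_support()))
    }
    cand <- data.table::copy(candidates)
    data.table::setorder(cand, chrom1, side1, pos1)
    cand[, brk1 := chrom1 != data.table::shift(chrom1, fill = chrom1[1]) |
             side1 != data.table::shift(side1, fill = side1[1]) |
             (pos1 - data.table::shift(pos1, fill = pos1[1])) >=
                 max_proper_insert]
    cand[, grp1 := cumsum(brk1) + 1L]
    data.table::setorder(cand, grp1, chrom2, side2, pos2)
    cand[, brk2 := chrom2 != data.table::shift(chrom2, fill = chrom2[1]) |
             side2 != data.table::shift(side2, fill = side2[1]) |
             (pos2 - data.table::shift(pos2, fill = pos2[1])) >=
                 max_proper_insert,
         by = grp1]
    cand[, grp2 := cumsum(brk2) + 1L, by = grp1]
    cand[, set_id := .GRP, by = .(grp1, grp2)]

    support <- list()
    svrows <- list()
    svn <- 0L
    for (sid in unique(cand$set_id)) {
        cs <- cand[set_id == sid]
        splits <- cs[evidence == "split"]
        gaps <- cs[evidence == "gap"]
        subs <- list()
        if (nrow(splits)) {
            splits[, key := paste(chrom1, pos1, side1, chrom2, pos2, side2,
                                  sep = "|")]
            for (kk in unique(splits$key)) subs[[kk]] <- splits[key == kk]
        }
        gap_alloc <- rep(NA_character_, nrow(gaps))
        if (nrow(gaps) && length(subs)) {
            for (g in seq_len(nrow(gaps))) {
                best <- NA_character_; bestd <- Inf
                for (kk in names(subs)) {
                    s1 <- subs[[kk]][1]
                    if (s1$chrom1 != gaps$chrom1[g] ||
                        s1$chrom2 != gaps$chrom2[g] ||
                        s1$side1 != gaps$side1[g] ||
                        s1$side2 != gaps$side2[g]) next
                    d1 <- abs(s1$pos1 - gaps$pos1[g])
                    d2 <- abs(s1$pos2 - gaps$pos2[g])
                    if (d1 <= max_proper_insert && d2 <= max_proper_insert &&
                        d1 + d2 < bestd) {
                        bestd <- d1 + d2; best <- kk
                    }
                }
                gap_alloc[g] <- best
            }
        }
        emit <- function(rows, precise) {
            svn <<- svn + 1L
            id <- sprintf("sv%05d", svn)
            rows <- data.table::copy(rows)
            rows[, sv_id := id]
            support[[length(support) + 1L]] <<- rows
            svrows[[length(svrows) + 1L]] <<- data.table::data.table(
                sv_id = id, imprecise = !precise)
        }
        for (kk in names(subs)) {
            rows <- subs[[kk]][, key := NULL]
            if (any(!is.na(gap_alloc) & gap_alloc == kk))
                rows <- rbind(rows, gaps[!is.na(gap_alloc) & gap_alloc == kk])
            emit(rows, precise = TRUE)
        }
        orphan <- gaps[is.na(gap_alloc)]
        if (nrow(orphan)) {
            # single-linkage chaining through candidates that joined split
            # subgroups can bridge unrelated gap molecules; supporters of
            # one gap junction can only spread over the insert window per
            # side, so re-apply the two-pass split within the orphans
            for (og in split_gap_groups(orphan, max_proper_insert))
                emit(og, precise = FALSE)
        }
    }
    support <- data.table::rbindlist(support, fill = TRUE)
    svs <- data.table::rbindlist(svrows)
    list(svs = svs, support = support)
}

# recursive two-pass consecutive-gap clustering of gap-only candidates
split_gap_groups <- function(rows, max_proper_insert) {
    if (nrow(rows) < 2L) return(list(rows))
    r <- data.table::copy(rows)
    data.table::setorder(r, pos1)
    b1 <- cumsum(c(0L, diff(r$pos1) >= max_proper_insert))
    out <- list()
    for (g1 in unique(b1)) {
        rr <- r[b1 == g1]
        data.table::setorder(rr, pos2)
        b2 <- cumsum(c(0L, diff(rr$pos2) >= max_proper_insert))
        for (g2 in unique(b2)) {
            sub <- rr[b2 == g2]
            if (nrow(sub) < nrow(rows)) {
                out <- c(out, split_gap_groups(sub, max_proper_insert))
            } else {
                out <- c(out, list(sub))
            }
        }
    }
    out
}

empty_svs <- function() {
    data.table::data.table(sv_id = character(0), imprecise = logical(0))
}
empty_support <- function() {
    e <- empty_candidates()
    e[, `:=`(mol_id = integer(0), sample = character(0), sv_id = character(0))]
    e
}

#' Purge near-duplicate supporting molecules of one SV
#'
#' Within one sample, two supporters whose outer endpoints lie closer than
#' `total_allowance` bp in total (sum over both ends) are presumed PCR
#' duplicates that escaped collation; the one with the smaller read-pair
#' family is removed, iterated to a fixpoint.
#'
#' @param support Support rows of one SV (with `sample`, `pos_l`, `pos_r`,
#'   `chrom_l`, `chrom_r`, `n_pairs`).
#' @param total_allowance Strict upper bound on the summed endpoint distance.
#' @return The retained support rows.
#' @export
purge_near_duplicates <- function(support, total_allowance = 5L) {
    keep <- rep(TRUE, nrow(support))
    for (sm in unique(support$sample)) {
        idx <- which(support$sample == sm & keep)
        repeat {
            removed <- FALSE
            idx <- idx[keep[idx]]
            if (length(idx) < 2L) break
            for (a in seq_len(length(idx) - 1L)) {
                if (!keep[idx[a]]) next
                for (b in (a + 1L):length(idx)) {
                    i <- idx[a]; j <- idx[b]
                    if (!keep[j] || !keep[i]) next
                    if (support$chrom_l[i] != support$chrom_l[j] ||
                        support$chrom_r[i] != support$chrom_r[j]) next
                    d <- abs(support$pos_l[i] - support$pos_l[j]) +
                         abs(support$pos_r[i] - support$pos_r[j])
                    if (d < total_allowance) {
                        drop <- if (support$n_pairs[i] < support$n_pairs[j]) i
                                else if (support$n_pairs[j] < support$n_pairs[i]) j
                                else max(i, j)
                        keep[drop] <- FALSE
                        removed <- TRUE
                    }
                }
            }
            if (!removed) break
        }
    }
    support[keep]
}

# Extension-based junction metric on a junction-spanning consensus.
# jseq: consensus in canonical junction orientation; qL = last left-flank
# column, qR = first right-flank column (qR - qL - 1 = candidate insertion
# length). I1/I2 are how far the left/right flanks extend past the nominal
# breakpoint along the consensus; valid breakpoint placements number
# I1 + I2 - ilen + 1, so the metric is I1 + I2 - ilen (microhomology when
# positive, blunt at 0, net de novo insertion when negative). N stops
# extension (conservative).
junction_metric <- function(genome, chrom1, pos1, side1, chrom2, pos2, side2,
                            jseq, qL, qR, max_ext = 60L) {
    n <- nchar(jseq)
    at <- function(i) if (i >= 1L && i <= n) substr(jseq, i, i) else ""
    f_fwd <- function(i) { # left flank continued past its junction node
        p <- if (side1 == "L") pos1 + i else pos1 - i
        if (p < 1L || p > genome$lengths[[chrom1]]) return("")
        b <- genome_seq(genome, chrom1, p, p)
        if (side1 == "L") b else chartr("ACGT", "TGCA", b)
    }
    g_back <- function(i) { # right flank continued before its junction node
        p <- if (side2 == "R") pos2 - i else pos2 + i
        if (p < 1L || p > genome$lengths[[chrom2]]) return("")
        b <- genome_seq(genome, chrom2, p, p)
        if (side2 == "R") b else chartr("ACGT", "TGCA", b)
    }
    ilen <- qR - qL - 1L
    I1 <- 0L
    while (I1 < max_ext) {
        b <- at(qL + I1 + 1L)
        if (b == "" || b == "N" || b != f_fwd(I1 + 1L)) break
        I1 <- I1 + 1L
    }
    I2 <- 0L
    while (I2 < max_ext) {
        b <- at(qR - I2 - 1L)
        if (b == "" || b == "N" || b != g_back(I2 + 1L)) break
        I2 <- I2 + 1L
    }
    metric <- I1 + I2 - ilen
    if (metric < 0L)
        return(list(metric = metric,
                    insert = substr(jseq, qL + I1 + 1L, qR - 1L - I2),
                    mh_left = 0L, mh_right = 0L))
    list(metric = metric, insert = "", mh_left = I2, mh_right = I1)
}

#' Brute-force placement-enumeration microhomology oracle
#'
#' The column-to-reference mapping of a junction sequence is fixed (column j
#' belongs to the left flank advanced by j - qL, or to the right flank
#' advanced by j - qR); a breakpoint placement chooses a split point t and is
#' valid iff every column at or left of it matches its left-flank base and
#' every column right of it matches its right-flank base. The metric is
#' (valid placements - 1), or -(insertion length) when no placement exists.
#' Exhaustive over split points (quadratic in the window); the independent
#' check of the extension-based implementation.
#'
#' @inheritParams junction_metric
#' @param max_shift Window of split points enumerated around the nominal
#'   junction.
#' @return list(metric, insert).
#' @export
junction_metric_oracle <- function(genome, chrom1, pos1, side1, chrom2, pos2,
                                   side2, jseq, qL, qR, max_shift = 60L) {
    n <- nchar(jseq)
    base_at <- function(chrom, p, comp) {
        if (p < 1L || p > genome$lengths[[chrom]]) return("")
        b <- genome_seq(genome, chrom, p, p)
        if (comp) chartr("ACGT", "TGCA", b) else b
    }
    jcols <- strsplit(jseq, "")[[1]]
    lo <- max(0L, qL - max_shift); hi <- min(n, qL + max_shift)
    wlo <- max(1L, qL - max_shift); whi <- min(n, qR + max_shift)
    win <- wlo:whi
    wantL <- vapply(win, function(j) {
        p <- if (side1 == "L") pos1 + (j - qL) else pos1 - (j - qL)
        base_at(chrom1, p, side1 == "R")
    }, "")
    wantR <- vapply(win, function(j) {
        p <- if (side2 == "R") pos2 + (j - qR) else pos2 - (j - qR)
        base_at(chrom2, p, side2 == "L")
    }, "")
    jw <- jcols[win]
    okL <- jw != "N" & wantL != "" & jw == wantL
    okR <- jw != "N" & wantR != "" & jw == wantR
    placements <- 0L
    for (t in lo:hi) {
        left_cols <- win <= t
        if (all(okL[left_cols]) && all(okR[!left_cols]))
            placements <- placements + 1L
    }
    if (placements > 0L) return(list(metric = placements - 1L, insert = ""))
    a <- qL
    while (a + 1L <= whi && okL[a + 1L - wlo + 1L]) a <- a + 1L
    b <- qR
    while (b - 1L >= wlo && okR[b - 1L - wlo + 1L]) b <- b - 1L
    ins <- if (b - a >= 2L) substr(jseq, a + 1L, b - 1L) else ""
    list(metric = -nchar(ins), insert = ins)
}

# cross-molecule junction consensus: stack supporters aligned at their
# junction column and vote per column (threshold rule, else N)
junction_consensus <- function(jseqs, qls, threshold = 0.667) {
    lefts <- qls
    rights <- nchar(jseqs) - qls
    maxl <- max(lefts); maxr <- max(rights)
    w <- maxl + maxr
    n <- length(jseqs)
    m <- matrix(charToRaw("."), nrow = w, ncol = n)  # '.' = not covered
    for (i in seq_len(n)) {
        off <- maxl - lefts[i]
        m[(off + 1L):(off + nchar(jseqs[i])), i] <- charToRaw(jseqs[i])
    }
    cov <- rowSums(m != charToRaw("."))
    best <- integer(w)
    call <- rep(charToRaw("N"), w)
    for (b in c("A", "C", "G", "T")) {
        cnt <- rowSums(m == charToRaw(b))
        better <- cnt > best
        best[better] <- cnt[better]
        call[better] <- charToRaw(b)
    }
    call[cov == 0L | best / pmax(cov, 1L) < threshold - 1e-9] <- charToRaw("N")
    list(seq = rawToChar(call), qL = maxl)
}

#' Reconstruct nominal breakpoints for gap-only SV calls
#'
#' With no split-read evidence the junction lies in the unsequenced gaps; the
#' nominal breakpoints are the innermost aligned ends over the supporters
#' (maximum position for an L node, minimum for an R node), flagged
#' imprecise, with no junction metric.
#'
#' @param support Support rows of one gap-only SV.
#' @return list(pos1, pos2) nominal node positions.
#' @export
reconstruct_gap_junction <- function(support) {
    p1 <- if (support$side1[1] == "L") max(support$pos1) else min(support$pos1)
    p2 <- if (support$side2[1] == "R") min(support$pos2) else max(support$pos2)
    list(pos1 = p1, pos2 = p2)
}

#' Recover outer-clipped proper molecules as SV support
#'
#' A proper molecule whose outer endpoint coincides with an SV breakpoint and
#' whose outer soft clip is at least `min_clip` bases, with the clipped bases
#' matching the junction's far-side flank (first `min(clip, 20)` bases exact,
#' N wildcard), is counted as outer-clip evidence.
#'
#' @param proper Proper molecule table (with `clipseq_l`/`clipseq_r`).
#' @param svs,support SV tables from [find_svs()] (precise calls only are
#'   searched).
#' @param genome `GenomeModel` for flank lookup.
#' @param min_clip Minimum clipped bases.
#' @param max_check Maximum clipped bases compared.
#' @return data.table of recovered evidence rows (sv_id, mol_id, sample, end).
#' @export
recover_outer_clips <- function(proper, svs, genome, min_clip = 5L,
                                max_check = 20L) {
    out <- list()
    if (!nrow(svs) || !nrow(proper)) return(data.table::rbindlist(out))
    cl <- proper[clip_l >= min_clip]
    cr <- proper[clip_r >= min_clip]
    match_clip <- function(clipseq, expected, from_end) {
        m <- min(nchar(clipseq), max_check, nchar(expected))
        if (m < min_clip) return(FALSE)
        a <- if (from_end) substr(clipseq, nchar(clipseq) - m + 1L,
                                  nchar(clipseq))
             else substr(clipseq, 1L, m)
        b <- if (from_end) substr(expected, nchar(expected) - m + 1L,
                                  nchar(expected))
             else substr(expected, 1L, m)
        ar <- charToRaw(a); br <- charToRaw(b)
        all(ar == br | ar == charToRaw("N") | br == charToRaw("N"))
    }
    for (i in seq_len(nrow(svs))) {
        sv <- svs[i]
        if (isTRUE(sv$imprecise)) next
        ins <- if (is.na(sv$insert_sequence)) "" else sv$insert_sequence
        # node with side R: molecules starting exactly there, lead-clipped;
        # clipped bases must match the sequence approaching from the far side
        for (endno in 1:2) {
            ch <- if (endno == 1) sv$chrom1 else sv$chrom2
            po <- if (endno == 1) sv$pos1 else sv$pos2
            sd <- if (endno == 1) sv$side1 else sv$side2
            fch <- if (endno == 1) sv$chrom2 else sv$chrom1
            fpo <- if (endno == 1) sv$pos2 else sv$pos1
            fsd <- if (endno == 1) sv$side2 else sv$side1
            if (sd == "R") {
                hits <- cl[chrom_l == ch & pos_l == po]
                if (!nrow(hits)) next
                far <- left_flank_seq(genome, fch, fpo, fsd,
                                      width = max_check + nchar(ins))
                expected <- paste0(far, ins)  # last char adjacent to junction
                okm <- vapply(seq_len(nrow(hits)), function(k)
                    match_clip(hits$clipseq_l[k], expected, from_end = TRUE),
                    logical(1))
            } else {
                hits <- cr[chrom_r == ch & pos_r == po]
                if (!nrow(hits)) next
                far <- right_flank_seq(genome, fch, fpo, fsd,
                                       width = max_check + nchar(ins))
                expected <- paste0(ins, far)  # first char adjacent
                okm <- vapply(seq_len(nrow(hits)), function(k)
                    match_clip(hits$clipseq_r[k], expected, from_end = FALSE),
                    logical(1))
            }
            if (any(okm)) {
                h <- hits[okm]
                out[[length(out) + 1L]] <- data.table::data.table(
                    sv_id = sv$sv_id, mol_id = h$mol_id, sample = h$sample,
                    n_pairs = h$n_pairs, end = endno)
            }
        }
    }
    res <- data.table::rbindlist(out)
    if (nrow(res)) res <- unique(res, by = c("sv_id", "mol_id", "sample"))
    res
}

#' Classify an SV junction against capture targets
#'
#' Each breakend is coded T (capture span), A (adjacent region) or `-`.
#' Uppercase letter pairs mark the expected geometry: both ends belonging to
#' the same target locus; anything else is lowercase (artifact-suspicious).
#'
#' @param chrom1,pos1,chrom2,pos2 Breakend coordinates (vectors).
#' @param targets A `TargetRegionSet`.
#' @return Character vector of two-character class codes.
#' @export
classify_sv <- function(chrom1, pos1, chrom2, pos2, targets) {
    c1 <- classify_point(chrom1, pos1, targets)
    c2 <- classify_point(chrom2, pos2, targets)
    same <- !is.na(c1$locus) & !is.na(c2$locus) & c1$locus == c2$locus
    a <- data.table::fifelse(same, c1$code, tolower(c1$code))
    b <- data.table::fifelse(same, c2$code, tolower(c2$code))
    paste0(a, b)
}

#' Assemble, refine and characterize SV calls across samples
#'
#' Runs the full discovery pass over one or more extracted samples analyzed
#' together: shared-endpoint flagging, two-pass candidate clustering,
#' near-duplicate purging, gap-junction reconstruction, junction consensus
#' and microhomology/insertion characterization, outer-clip recovery and
#' target classification.
#'
#' @param extracted A single `ExtractedSample` or list of them (co-analysis).
#' @param genome `GenomeModel`.
#' @param targets `TargetRegionSet`.
#' @param max_proper_insert Clustering distance; default max over samples.
#' @param total_allowance Duplicate purge threshold (bp, strict).
#' @param min_clip Outer-clip recovery threshold (bp).
#' @param threshold Junction consensus column threshold.
#' @param min_sv_size Imprecise same-chromosome calls whose reconstructed
#'   node distance falls below this are indel-scale and dropped.
#' @return list(svs, support, clips): the SV call table (one row per SV),
#'   junction-molecule support, and recovered outer-clip evidence.
#' @export
find_svs <- function(extracted, genome, targets, max_proper_insert = NULL,
                     total_allowance = 5L, min_clip = 5L, threshold = 0.667,
                     min_sv_size = 50L) {
    if (inherits(extracted, "ExtractedSample")) extracted <- list(extracted)
    mpi <- max_proper_insert %||%
        max(vapply(extracted, `[[`, integer(1), "max_proper_insert"))
    cands <- list(); propers <- list()
    for (ex in extracted) {
        cc <- flag_shared_endpoints(ex$candidates, ex$proper)
        cands[[length(cands) + 1L]] <- cc
        propers[[length(propers) + 1L]] <- ex$proper
    }
    cands <- data.table::rbindlist(cands, fill = TRUE)
    proper <- data.table::rbindlist(propers, fill = TRUE)
    sets <- find_sv_sets(cands, mpi)
    svs <- sets$svs; support <- sets$support
    if (!nrow(svs)) {
        return(list(svs = annotate_empty_svs(), support = support,
                    clips = data.table::data.table()))
    }
    kept <- list()
    rows <- list()
    for (i in seq_len(nrow(svs))) {
        id <- svs$sv_id[i]
        sup <- purge_near_duplicates(support[sv_id == id], total_allowance)
        kept[[length(kept) + 1L]] <- sup
        splits <- sup[evidence == "split"]
        if (nrow(splits)) {
            n1 <- splits[1, .(chrom1, pos1, side1, chrom2, pos2, side2)]
            # reference molecule: most centrally placed junction, ties to the
            # larger family then molecule id
            cent <- abs(splits$jq_l - nchar(splits$jseq) / 2)
            o <- order(cent, -splits$n_pairs, splits$mol_id)
            refmol <- splits$mol_id[o[1]]
            jc <- junction_consensus(splits$jseq, splits$jq_l, threshold)
            ilen <- splits$jq_r[1] - splits$jq_l[1] - 1L
            jm <- junction_metric(genome, n1$chrom1, n1$pos1, n1$side1,
                                  n1$chrom2, n1$pos2, n1$side2,
                                  jc$seq, jc$qL, jc$qL + ilen + 1L)
            rows[[length(rows) + 1L]] <- data.table::data.table(
                sv_id = id, chrom1 = n1$chrom1, pos1 = n1$pos1,
                side1 = n1$side1, chrom2 = n1$chrom2, pos2 = n1$pos2,
                side2 = n1$side2, imprecise = FALSE,
                junction_metric = jm$metric,
                insert_sequence = jm$insert,
                junction_consensus = jc$seq, junction_col = jc$qL,
                mh_left = jm$mh_left, mh_right = jm$mh_right,
                reference_molecule = refmol)
        } else {
            gp <- reconstruct_gap_junction(sup)
            rows[[length(rows) + 1L]] <- data.table::data.table(
                sv_id = id, chrom1 = sup$chrom1[1], pos1 = gp$pos1,
                side1 = sup$side1[1], chrom2 = sup$chrom2[1], pos2 = gp$pos2,
                side2 = sup$side2[1], imprecise = TRUE,
                junction_metric = NA_integer_,
                insert_sequence = NA_character_,
                junction_consensus = NA_character_,
                junction_col = NA_integer_,
                mh_left = NA_integer_, mh_right = NA_integer_,
                reference_molecule = NA_integer_)
        }
    }
    support <- data.table::rbindlist(kept)
    svs <- data.table::rbindlist(rows)
    svs[, sv_type := sv_type_of(chrom1, pos1, side1, chrom2, pos2, side2)]
    svs[, size := data.table::fifelse(chrom1 == chrom2,
                                      abs(pos2 - pos1), NA_integer_)]
    # reconstructed gap-only junctions can collapse to indel scale or to
    # crossed nominal nodes (mutually inconsistent supporters); drop both
    tiny <- svs[imprecise == TRUE &
                ((sv_type %in% c("Del", "Dup") & size < min_sv_size) |
                 (chrom1 == chrom2 & pos1 > pos2)), sv_id]
    if (length(tiny)) {
        svs <- svs[!sv_id %in% tiny]
        support <- support[!sv_id %in% tiny]
    }
    clips <- recover_outer_clips(proper, svs, genome, min_clip)
    agg <- support[, .(
        n_split = sum(evidence == "split"),
        n_gap = sum(evidence == "gap"),
        n_read_pairs = sum(n_pairs),
        max_mol_pairs = max(n_pairs),
        n_duplex = sum(is_duplex),
        max_family_size = max(pmax(strand1_n, strand2_n)),
        shared_endpoint_count = sum(shared_outer),
        all_shared = all(shared_outer),
        min_flank_mapq = min(pmin(mapq1, mapq2)),
        n_samples = data.table::uniqueN(sample)), by = sv_id]
    svs <- merge(svs, agg, by = "sv_id", sort = FALSE)
    if (nrow(clips)) {
        cagg <- clips[, .(n_outer_clip = .N), by = sv_id]
        svs <- merge(svs, cagg, by = "sv_id", all.x = TRUE, sort = FALSE)
        svs[is.na(n_outer_clip), n_outer_clip := 0L]
    } else svs[, n_outer_clip := 0L]
    svs[, n_molecules := n_split + n_gap + n_outer_clip]
    svs[, target_class := classify_sv(chrom1, pos1, chrom2, pos2, targets)]
    svs[, vaf := NA_real_]
    list(svs = svs[], support = support, clips = clips)
}

annotate_empty_svs <- function() {
    data.table::data.table(
        sv_id = character(0), chrom1 = character(0), pos1 = integer(0),
        side1 = character(0), chrom2 = character(0), pos2 = integer(0),
        side2 = character(0), imprecise = logical(0),
        junction_metric = integer(0), insert_sequence = character(0),
        junction_consensus = character(0), junction_col = integer(0),
        mh_left = integer(0), mh_right = integer(0),
        reference_molecule = integer(0), sv_type = character(0),
        size = integer(0), n_split = integer(0), n_gap = integer(0),
        n_read_pairs = integer(0), max_mol_pairs = integer(0),
        n_duplex = integer(0), max_family_size = integer(0),
        shared_endpoint_count = integer(0), all_shared = logical(0),
        min_flank_mapq = integer(0), n_samples = integer(0),
        n_outer_clip = integer(0), n_molecules = integer(0),
        target_class = character(0), vaf = numeric(0))
}
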