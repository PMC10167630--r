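# junction: convert source molecules into junction nodes, detect per-molecule
# SV junction candidates (split and gap evidence), and flag molecules sharing
# outer endpoints with properly paired molecules (chimeric PCR signature).
#
# A molecule is a path of aligned segments. Each segment contributes two
# nodes: for a segment [a,b] traversed on the + strand, (a,R) at entry and
# (b,L) at exit; on the - strand, (b,L) at entry and (a,R) at exit. The side
# is the direction the molecule proceeds from the position. The two path
# extremes are the outer nodes (molecule identity); all others are inner
# nodes (junction evidence).

node_lt <- function(c1, p1, s1, c2, p2, s2) {
    if (c1 != c2) return(c1 < c2)
    if (p1 != p2) return(p1 < p2)
    s1 < s2
}

# ---- per-read-pair path reconstruction -------------------------------------

# Build the molecule alignment path of one read pair from its records
# (primary + supplementary of both mates), in canonical orientation
# (smaller outer node first). Returns NULL if no usable blocks.
# Implemented on plain vectors: it runs once per complex molecule (and per
# family member during consensus), so per-call overhead matters.
pair_path <- function(rp, max_proper_insert = 1000L) {
    n_rec <- nrow(rp)
    if (n_rec == 0L) return(NULL)
    v_read <- rp$read_index; v_rev <- rp$is_reverse
    v_chrom <- rp$rname; v_pos <- rp$pos; v_end <- rp$end
    v_mapq <- rp$mapq; v_seq <- rp$seq; v_qual <- rp$qual
    v_lead <- rp$lead_clip; v_trail <- rp$trail_clip
    v_qw <- nchar(v_seq) - v_lead - v_trail
    v_qs <- ifelse(v_rev, v_trail, v_lead) + 1L
    v_qe <- v_qs + v_qw - 1L

    ord1 <- which(v_read <= 1L); ord1 <- ord1[order(v_qs[ord1])]
    ord2 <- which(v_read == 2L); ord2 <- ord2[order(v_qs[ord2])]
    if (!length(ord1) && !length(ord2)) return(NULL)

    ## equivalence-cluster blocks: read-1 blocks seed the path; read-2
    ## blocks (molecule order = reversed query order, direction flipped)
    ## merge onto overlapping same-direction blocks or append as leftovers
    f_chrom <- character(0); f_s <- integer(0); f_e <- integer(0)
    f_dir <- character(0); f_mapq <- integer(0)
    fmap <- integer(n_rec)
    for (i in ord1) {
        f_chrom <- c(f_chrom, v_chrom[i]); f_s <- c(f_s, v_pos[i])
        f_e <- c(f_e, v_end[i])
        f_dir <- c(f_dir, if (v_rev[i]) "-" else "+")
        f_mapq <- c(f_mapq, v_mapq[i])
        fmap[i] <- length(f_s)
    }
    for (i in rev(ord2)) {
        d <- if (v_rev[i]) "+" else "-"
        hit <- 0L
        for (k in seq_along(f_s)) {
            if (v_chrom[i] == f_chrom[k] && d == f_dir[k] &&
                v_pos[i] <= f_e[k] && v_end[i] >= f_s[k]) { hit <- k; break }
        }
        if (hit > 0L) {
            f_s[hit] <- min(f_s[hit], v_pos[i])
            f_e[hit] <- max(f_e[hit], v_end[i])
            f_mapq[hit] <- max(f_mapq[hit], v_mapq[i])
            fmap[i] <- hit
        } else {
            f_chrom <- c(f_chrom, v_chrom[i]); f_s <- c(f_s, v_pos[i])
            f_e <- c(f_e, v_end[i]); f_dir <- c(f_dir, d)
            f_mapq <- c(f_mapq, v_mapq[i])
            fmap[i] <- length(f_s)
        }
    }
    nf <- length(f_s)

    ## split-evidence marks between query-adjacent blocks within one read
    mk_from <- integer(0); mk_to <- integer(0)
    mk_ilen <- integer(0); mk_ins <- character(0)
    for (rr in list(ord1, ord2)) {
        if (length(rr) < 2L) next
        for (k in seq_len(length(rr) - 1L)) {
            i <- rr[k]; j <- rr[k + 1L]
            b1 <- fmap[i]; b2 <- fmap[j]
            ilen <- max(0L, v_qs[j] - v_qe[i] - 1L)
            ins <- ""
            if (ilen > 0L) {
                raw <- if (v_rev[i]) revcomp(v_seq[i]) else v_seq[i]
                ins <- substr(raw, v_qe[i] + 1L, v_qs[j] - 1L)
            }
            if (v_read[i] == 2L) { # read-2 raw order is molecule-reversed
                tmp <- b1; b1 <- b2; b2 <- tmp
                if (nzchar(ins)) ins <- revcomp(ins)
            }
            mk_from <- c(mk_from, b1); mk_to <- c(mk_to, b2)
            mk_ilen <- c(mk_ilen, ilen); mk_ins <- c(mk_ins, ins)
        }
    }

    ## collapse consecutive unmarked, concordant neighbors (the unsequenced
    ## middle of a non-overlapping proper pair is a hole, not a junction)
    s_chrom <- f_chrom[1]; s_s <- f_s[1]; s_e <- f_e[1]
    s_dir <- f_dir[1]; s_mapq <- f_mapq[1]
    segof_f <- integer(nf); segof_f[1] <- 1L
    jx_after <- integer(0); jx_ev <- character(0)
    jx_ilen <- integer(0); jx_ins <- character(0)
    if (nf > 1L) for (b in 2:nf) {
        cs <- length(s_s)
        # a mark from any member of the current segment to this block
        mi <- which(mk_to == b & segof_f[mk_from] == cs)
        concordant <- !length(mi) && f_chrom[b] == s_chrom[cs] &&
            f_dir[b] == s_dir[cs] &&
            ((f_dir[b] == "+" && f_s[b] >= s_s[cs] &&
              max(f_e[b], s_e[cs]) - s_s[cs] + 1L <= max_proper_insert) ||
             (f_dir[b] == "-" && f_e[b] <= s_e[cs] &&
              s_e[cs] - min(f_s[b], s_s[cs]) + 1L <= max_proper_insert))
        if (concordant) {
            s_s[cs] <- min(s_s[cs], f_s[b]); s_e[cs] <- max(s_e[cs], f_e[b])
            s_mapq[cs] <- max(s_mapq[cs], f_mapq[b])
            segof_f[b] <- cs
        } else {
            jx_after <- c(jx_after, cs)
            jx_ev <- c(jx_ev, if (length(mi)) "split" else "gap")
            jx_ilen <- c(jx_ilen, if (length(mi)) mk_ilen[mi[1]] else 0L)
            jx_ins <- c(jx_ins, if (length(mi)) mk_ins[mi[1]] else "")
            s_chrom <- c(s_chrom, f_chrom[b]); s_s <- c(s_s, f_s[b])
            s_e <- c(s_e, f_e[b]); s_dir <- c(s_dir, f_dir[b])
            s_mapq <- c(s_mapq, f_mapq[b])
            segof_f[b] <- cs + 1L
        }
    }
    ns <- length(s_s)
    seg_of_rec <- segof_f[fmap]

    ## molecule coordinates (inserts occupy space between segments)
    wids <- s_e - s_s + 1L
    m1 <- integer(ns)
    pos <- 1L
    for (i in seq_len(ns)) {
        m1[i] <- pos
        pos <- pos + wids[i]
        ji <- which(jx_after == i)
        if (length(ji)) pos <- pos + jx_ilen[ji[1]]
    }
    m2 <- m1 + wids - 1L
    L <- m2[ns]
    jx_qL <- if (length(jx_after)) m2[jx_after] else integer(0)
    jx_qR <- jx_qL + jx_ilen + 1L

    ## pair sequence in molecule frame (read-1 forward), quality-resolved
    sq <- rep(charToRaw("N"), L)
    ql <- rep(as.raw(33L), L)
    nr <- charToRaw("N"); q0 <- as.raw(33L)
    for (i in seq_len(n_rec)) {
        k <- seg_of_rec[i]
        if (is.na(k) || k == 0L) next
        bs <- v_pos[i]; be <- v_end[i]
        if (s_dir[k] == "+") {
            mi <- m1[k] + (bs - s_s[k]); mj <- m1[k] + (be - s_s[k])
        } else {
            mi <- m1[k] + (s_e[k] - be); mj <- m1[k] + (s_e[k] - bs)
        }
        piece <- substr(v_seq[i], v_lead[i] + 1L, v_lead[i] + v_qw[i])
        pieceq <- substr(v_qual[i], v_lead[i] + 1L, v_lead[i] + v_qw[i])
        if (s_dir[k] == "-") {
            piece <- revcomp(piece)
            pieceq <- paste(rev(strsplit(pieceq, "")[[1]]), collapse = "")
        }
        ps <- charToRaw(piece); pq <- charToRaw(pieceq)
        idx <- mi:mj
        fresh <- sq[idx] == nr & ql[idx] == q0
        conflict <- !fresh & sq[idx] != ps
        take <- fresh | (conflict & pq > ql[idx])
        tie <- conflict & pq == ql[idx]
        sq[idx][take] <- ps[take]; ql[idx][take] <- pq[take]
        sq[idx][tie] <- nr
    }
    if (length(jx_after)) for (j in seq_along(jx_after)) {
        if (jx_ilen[j] > 0L && nzchar(jx_ins[j]))
            sq[(jx_qL[j] + 1L):(jx_qR[j] - 1L)] <- charToRaw(jx_ins[j])
    }

    ## outer nodes and outer clips
    outerA <- if (s_dir[1] == "+")
        list(chrom = s_chrom[1], pos = s_s[1], side = "R")
    else list(chrom = s_chrom[1], pos = s_e[1], side = "L")
    outerB <- if (s_dir[ns] == "+")
        list(chrom = s_chrom[ns], pos = s_e[ns], side = "L")
    else list(chrom = s_chrom[ns], pos = s_s[ns], side = "R")
    oclip <- function(krow, entry) {
        best <- list(len = 0L, seq = "")
        low_side <- (s_dir[krow] == "+") == entry
        for (i in seq_len(n_rec)) {
            k <- seg_of_rec[i]
            if (is.na(k) || k != krow) next
            if (low_side && v_pos[i] == s_s[krow] && v_lead[i] > best$len)
                best <- list(len = v_lead[i],
                             seq = substr(v_seq[i], 1L, v_lead[i]))
            if (!low_side && v_end[i] == s_e[krow] && v_trail[i] > best$len) {
                w <- nchar(v_seq[i])
                best <- list(len = v_trail[i],
                             seq = substr(v_seq[i], w - v_trail[i] + 1L, w))
            }
        }
        # store in molecule orientation (SEQ is reference-oriented)
        if (best$len > 0L && s_dir[krow] == "-") best$seq <- revcomp(best$seq)
        best
    }
    clipA <- oclip(1L, TRUE)
    clipB <- oclip(ns, FALSE)

    flip <- node_lt(outerB$chrom, outerB$pos, outerB$side,
                    outerA$chrom, outerA$pos, outerA$side)
    if (flip) {
        ord <- rev(seq_len(ns))
        s_chrom <- s_chrom[ord]; s_mapq <- s_mapq[ord]
        s_dir <- ifelse(s_dir[ord] == "+", "-", "+")
        om1 <- m1[ord]; om2 <- m2[ord]
        ss <- s_s[ord]; se <- s_e[ord]
        s_s <- ss; s_e <- se
        m1 <- L - om2 + 1L
        m2 <- L - om1 + 1L
        if (length(jx_after)) {
            jord <- rev(seq_along(jx_after))
            jx_after <- ns - jx_after[jord]
            jx_ev <- jx_ev[jord]; jx_ilen <- jx_ilen[jord]
            jx_ins <- vapply(jx_ins[jord], function(x)
                if (nzchar(x)) revcomp(x) else x, "", USE.NAMES = FALSE)
            oqL <- jx_qL[jord]; oqR <- jx_qR[jord]
            jx_qL <- L - oqR + 1L
            jx_qR <- L - oqL + 1L
        }
        sq <- charToRaw(revcomp(rawToChar(sq)))
        ql <- rev(ql)
        tmp <- outerA; outerA <- outerB; outerB <- tmp
        tmp <- clipA; clipA <- clipB; clipB <- tmp
    }
    list(segments = data.table::data.table(chrom = s_chrom, s = s_s,
                                           e = s_e, dir = s_dir,
                                           mapq = s_mapq, m1 = m1, m2 = m2),
         junctions = data.table::data.table(after = jx_after,
                                            evidence = jx_ev,
                                            ilen = jx_ilen, ins = jx_ins,
                                            qL = jx_qL, qR = jx_qR),
         seq = rawToChar(sq), qual = rawToChar(ql),
         outer1 = outerA, outer2 = outerB,
         clip1 = clipA, clip2 = clipB, L = L, flipped = flip)
}

#' Extract junction nodes from a molecule path
#'
#' @param path A path from [pair_path()].
#' @return list(outer = 2-row data.table, inner = data.table of inner nodes
#'   in molecule order).
#' @export
extract_nodes <- function(path) {
    segs <- path$segments
    nodes <- list()
    for (i in seq_len(nrow(segs))) {
        sg <- segs[i]
        if (sg$dir == "+") {
            nodes[[length(nodes) + 1L]] <- data.table::data.table(
                chrom = sg$chrom, pos = c(sg$s, sg$e), side = c("R", "L"))
        } else {
            nodes[[length(nodes) + 1L]] <- data.table::data.table(
                chrom = sg$chrom, pos = c(sg$e, sg$s), side = c("L", "R"))
        }
    }
    nodes <- data.table::rbindlist(nodes)
    list(outer = nodes[c(1L, .N)], inner = if (nrow(nodes) > 2L)
        nodes[2:(.N - 1L)] else nodes[0])
}

sv_type_of <- function(chrom1, pos1, side1, chrom2, pos2, side2) {
    data.table::fifelse(chrom1 != chrom2, "Trans",
        data.table::fifelse(side1 == side2, "Inv",
            data.table::fifelse(side1 == "L", "Del", "Dup")))
}

#' Call per-molecule SV junction candidates
#'
#' Split evidence arises from multi-segment paths (junction sequence spans
#' the breakpoint); gap evidence from discordant mate geometry, with
#' approximate inner nodes at the inner aligned ends. Same-chromosome
#' deletion-type junctions below `min_sv_size` are treated as indels and not
#' reported as SV candidates.
#'
#' @param path A [pair_path()] result.
#' @param min_sv_size Minimum deletion/duplication node distance (bp).
#' @return data.table of candidates (possibly empty): canonical node pair,
#'   type, evidence, junction sequence and junction columns, flank MAPQs.
#' @export
call_candidates <- function(path, min_sv_size = 50L) {
    jx <- path$junctions
    out <- list()
    if (!nrow(jx)) return(empty_candidates())
    segs <- path$segments
    for (j in seq_len(nrow(jx))) {
        i <- jx$after[j]
        sgA <- segs[i]; sgB <- segs[i + 1L]
        n1 <- if (sgA$dir == "+") list(chrom = sgA$chrom, pos = sgA$e, side = "L")
              else list(chrom = sgA$chrom, pos = sgA$s, side = "R")
        n2 <- if (sgB$dir == "+") list(chrom = sgB$chrom, pos = sgB$s, side = "R")
              else list(chrom = sgB$chrom, pos = sgB$e, side = "L")
        swap <- node_lt(n2$chrom, n2$pos, n2$side, n1$chrom, n1$pos, n1$side)
        if (swap) { tmp <- n1; n1 <- n2; n2 <- tmp }
        type <- sv_type_of(n1$chrom, n1$pos, n1$side, n2$chrom, n2$pos, n2$side)
        if (type %in% c("Del", "Dup") && abs(n2$pos - n1$pos) < min_sv_size)
            next
        jseq <- NA_character_; qL <- NA_integer_; qR <- NA_integer_
        if (jx$evidence[j] == "split") {
            if (!swap) {
                jseq <- path$seq; qL <- jx$qL[j]; qR <- jx$qR[j]
            } else {
                jseq <- revcomp(path$seq)
                qL <- path$L - jx$qR[j] + 1L
                qR <- path$L - jx$qL[j] + 1L
            }
        }
        out[[length(out) + 1L]] <- data.table::data.table(
            chrom1 = n1$chrom, pos1 = n1$pos, side1 = n1$side,
            chrom2 = n2$chrom, pos2 = n2$pos, side2 = n2$side,
            sv_type = type, evidence = jx$evidence[j],
            imprecise = jx$evidence[j] == "gap",
            jseq = jseq, jq_l = qL, jq_r = qR,
            mapq1 = sgA$mapq, mapq2 = sgB$mapq)
    }
    if (!length(out)) return(empty_candidates())
    data.table::rbindlist(out)
}

empty_candidates <- function() {
    data.table::data.table(
        chrom1 = character(0), pos1 = integer(0), side1 = character(0),
        chrom2 = character(0), pos2 = integer(0), side2 = character(0),
        sv_type = character(0), evidence = character(0),
        imprecise = logical(0), jseq = character(0), jq_l = integer(0),
        jq_r = integer(0), mapq1 = integer(0), mapq2 = integer(0))
}

#' Flag candidates sharing outer endpoints with proper molecules
#'
#' A junction molecule sharing an outer endpoint (within the grouping
#' allowance) with a properly paired molecule of the same library is likely
#' a chimeric PCR product templated on that molecule.
#'
#' @param candidates Candidate table (with molecule outer endpoint columns
#'   `sample`, `chrom_l`, `pos_l`, `chrom_r`, `pos_r`, `mol_id`).
#' @param proper_molecules Proper molecule table with the same columns.
#' @param allowance Endpoint match tolerance (bp).
#' @return `candidates` with a logical `shared_outer` column.
#' @export
flag_shared_endpoints <- function(candidates, proper_molecules,
                                  allowance = 1L) {
    if (!nrow(candidates)) {
        candidates[, shared_outer := logical(0)]
        return(candidates)
    }
    if (!nrow(proper_molecules)) {
        candidates[, shared_outer := FALSE]
        return(candidates)
    }
    eps <- -allowance:allowance
    idx <- rbind(
        proper_molecules[, .(sample, chrom = chrom_l, pos = pos_l)],
        proper_molecules[, .(sample, chrom = chrom_r, pos = pos_r)])
    idx <- idx[, .(pos = rep(pos, each = length(eps)) +
                       rep(eps, times = .N)), by = .(sample, chrom)]
    idx <- unique(idx)
    idx[, hit := TRUE]
    cand <- data.table::copy(candidates)
    l <- idx[cand[, .(sample, chrom = chrom_l, pos = pos_l)],
             on = c("sample", "chrom", "pos"), hit]
    r <- idx[cand[, .(sample, chrom = chrom_r, pos = pos_r)],
             on = c("sample", "chrom", "pos"), hit]
    cand[, shared_outer := (!is.na(l)) | (!is.na(r))]
    cand
}
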