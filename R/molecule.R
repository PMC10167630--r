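# molecule: UMI demultiplexing, grouping of read pairs into source DNA
# molecules, strand family accounting, and two-step consensus building.

#' Match observed UMIs against the expected set
#'
#' An observed UMI is assigned the index of the unique expected UMI within
#' Hamming distance 1; anything else (distance >= 2 everywhere, ties, or a
#' length mismatch) is rejected.
#'
#' @param observed Character vector of observed UMI sequences.
#' @param expected Character vector of expected UMIs (order defines the
#'   index); defaults to the package's fixed 96-UMI set.
#' @return Integer vector of indices (NA = rejected).
#' @export
match_umi <- function(observed, expected = umi_set()) {
    w <- nchar(expected[1])
    if (any(nchar(expected) != w)) stop2("expected UMIs differ in length")
    out <- rep(NA_integer_, length(observed))
    ok <- which(!is.na(observed) & nchar(observed) == w)
    if (!length(ok)) return(out)
    obs <- matrix(charToRaw(paste(observed[ok], collapse = "")), nrow = w)
    nhit <- integer(length(ok))
    hit <- integer(length(ok))
    for (k in seq_along(expected)) {
        d <- hamming_to(obs, charToRaw(expected[k]))
        m <- d <= 1L
        nhit <- nhit + m
        hit[m] <- k
    }
    out[ok[nhit == 1L]] <- hit[nhit == 1L]
    out
}

# Per-read-pair grouping key: outer endpoints, outer clip lengths, canonical
# orientation and (ligation mode) strand-ordered UMI indices.  Only segments
# with MAPQ > mapq_min contribute endpoints.
pair_keys <- function(aln, mode, mapq_min = 20L, expected_umis = umi_set()) {
    dt <- aln[mapq > mapq_min]
    dropped <- setdiff(unique(aln$qname), unique(dt$qname))
    # left outer endpoint: minimum (chrom, pos); right: maximum (chrom, end)
    data.table::setorder(dt, qname, rname, pos)
    left <- dt[!duplicated(qname),
               .(qname, chrom_l = rname, pos_l = pos, clip_l = lead_clip,
                 left_read = read_index, sample)]
    data.table::setorder(dt, qname, rname, end)
    right <- dt[!duplicated(qname, fromLast = TRUE),
                .(qname, chrom_r = rname, pos_r = end, clip_r = trail_clip)]
    keys <- merge(left, right, by = "qname", sort = FALSE)
    # orientation: read providing the left outer endpoint; when both reads
    # start there (fully overlapping mates), fall back on read-1 strand
    at_left <- merge(dt, keys[, .(qname, chrom_l, pos_l)], by = "qname",
                     sort = FALSE)[rname == chrom_l & pos == pos_l]
    tie <- at_left[, .(tie = data.table::uniqueN(read_index) > 1L), by = qname]
    r1rev <- dt[read_index == 1L & !is_supp][!duplicated(qname),
                .(qname, r1rev = is_reverse)]
    keys <- merge(keys, tie, by = "qname", all.x = TRUE, sort = FALSE)
    keys <- merge(keys, r1rev, by = "qname", all.x = TRUE, sort = FALSE)
    keys[, orient := data.table::fifelse(
        tie %in% TRUE,
        data.table::fifelse(r1rev %in% TRUE, 2L, 1L),
        data.table::fifelse(left_read == 2L, 2L, 1L))]
    keys[, c("tie", "r1rev", "left_read") := NULL]
    n_umi_rejected <- 0L
    if (mode == "ligation_duplex") {
        rx <- aln[!is.na(rx)][!duplicated(qname), .(qname, rx)]
        keys <- merge(keys, rx, by = "qname", all.x = TRUE, sort = FALSE)
        sp <- data.table::tstrsplit(keys$rx, "-", fixed = TRUE)
        u1 <- match_umi(sp[[1]], expected_umis)
        u2 <- if (length(sp) > 1) match_umi(sp[[2]], expected_umis)
              else rep(NA_integer_, nrow(keys))
        # canonical strand order: swap the pair for mirrored orientation
        keys[, umi_a := data.table::fifelse(orient == 1L, u1, u2)]
        keys[, umi_b := data.table::fifelse(orient == 1L, u2, u1)]
        bad <- is.na(keys$umi_a) | is.na(keys$umi_b)
        n_umi_rejected <- sum(bad)
        keys <- keys[!bad]
        keys[, rx := NULL]
    } else {
        keys[, umi_a := NA_integer_]
        keys[, umi_b := NA_integer_]
    }
    list(keys = keys, n_mapq_dropped = length(dropped),
         n_umi_rejected = n_umi_rejected)
}

#' Collate read pairs into source DNA molecules
#'
#' Read pairs sharing the same UMI indices (when applicable) and the same
#' outer endpoints and outer clip lengths within a 1 bp allowance are grouped
#' into one source molecule. In ligation mode, pairs with opposite strand
#' orientations (mirrored read roles, swapped UMI order) are the two strands
#' of one molecule; in tagmentation mode opposite orientations with identical
#' endpoints arise from independent Tn5 cleavage events and remain distinct
#' molecules. Grouping is single-pass and anchored on the first-seen key.
#'
#' @param aln Name-grouped alignment table from [read_alignments()] +
#'   [alignment_groups()].
#' @param mode `"ligation_duplex"` or `"tagmentation"`.
#' @param mapq_min Segments at or below this MAPQ do not nominate endpoints.
#' @param allowance Per-coordinate grouping allowance in bp.
#' @param expected_umis Expected UMI list (ligation mode).
#' @return A `CollatedSample` list: `molecules` (one row per source molecule
#'   with strand family sizes and duplex flag), `pairs` (read pair to
#'   molecule map), `reads` (the alignment table), `stats`.
#' @export
collate_molecules <- function(aln, mode = c("ligation_duplex", "tagmentation"),
                              mapq_min = 20L, allowance = 1L,
                              expected_umis = umi_set()) {
    mode <- match.arg(mode)
    pk <- pair_keys(aln, mode, mapq_min, expected_umis)
    keys <- pk$keys
    if (!nrow(keys)) stop2("no read pairs passed MAPQ/UMI screening")
    grpcols <- c("sample", "chrom_l", "chrom_r", "umi_a", "umi_b",
                 if (mode == "tagmentation") "orient")
    # exact-key aggregation, then anchored fuzzy grouping of distinct keys
    keys[, exact := do.call(paste, c(.SD, sep = "|")),
         .SDcols = c(grpcols, "pos_l", "pos_r", "clip_l", "clip_r")]
    uk <- keys[!duplicated(exact),
               c("exact", grpcols, "pos_l", "pos_r", "clip_l", "clip_r"),
               with = FALSE]
    data.table::setorderv(uk, c(grpcols, "pos_l", "pos_r", "clip_l", "clip_r"),
                          na.last = TRUE)
    disc <- do.call(paste, c(uk[, grpcols, with = FALSE], sep = "|"))
    n <- nrow(uk)
    gid <- integer(n)
    cur <- 0L
    a_pl <- a_pr <- a_cl <- a_cr <- 0L
    a_disc <- ""
    pl <- uk$pos_l; pr <- uk$pos_r; cl <- uk$clip_l; cr <- uk$clip_r
    for (i in seq_len(n)) {
        if (cur == 0L || disc[i] != a_disc ||
            abs(pl[i] - a_pl) > allowance || abs(pr[i] - a_pr) > allowance ||
            abs(cl[i] - a_cl) > allowance || abs(cr[i] - a_cr) > allowance) {
            cur <- cur + 1L
            a_pl <- pl[i]; a_pr <- pr[i]; a_cl <- cl[i]; a_cr <- cr[i]
            a_disc <- disc[i]
        }
        gid[i] <- cur
    }
    uk[, mol_id := gid]
    keys <- merge(keys, uk[, .(exact, mol_id)], by = "exact", sort = FALSE)
    if (mode == "ligation_duplex") keys[, strand := orient]
    else keys[, strand := 1L]
    # representative pair: highest summed base quality
    qs <- aln[, .(qsum = sum(qual_sums(qual))), by = qname]
    keys <- merge(keys, qs, by = "qname", sort = FALSE)
    data.table::setorder(keys, mol_id, -qsum, qname)
    mols <- keys[, .(
        sample = sample[1],
        chrom_l = chrom_l[1], pos_l = pos_l[1], clip_l = clip_l[1],
        chrom_r = chrom_r[1], pos_r = pos_r[1], clip_r = clip_r[1],
        umi1 = umi_a[1], umi2 = umi_b[1], orient = orient[1],
        strand1_n = sum(strand == 1L), strand2_n = sum(strand == 2L),
        n_pairs = .N, rep_qname = qname[1]), by = mol_id]
    mols[, is_duplex := mode == "ligation_duplex" & strand1_n > 0L &
             strand2_n > 0L]
    structure(list(molecules = mols,
                   pairs = keys[, .(qname, mol_id, strand, sample)],
                   reads = aln, mode = mode,
                   stats = list(n_pairs = nrow(keys),
                                n_molecules = nrow(mols),
                                n_mapq_dropped = pk$n_mapq_dropped,
                                n_umi_rejected = pk$n_umi_rejected)),
              class = "CollatedSample")
}

#' @export
print.CollatedSample <- function(x, ...) {
    cat("CollatedSample:", x$stats$n_molecules, "source molecules from",
        x$stats$n_pairs, "read pairs (", x$mode, ")\n")
    invisible(x)
}

#' Brute-force reference grouping by transitive closure
#'
#' Independent oracle for [collate_molecules()]: all-pairs comparison under
#' the same key-equality predicate (every coordinate within the allowance),
#' closed transitively. Quadratic; intended for small test instances.
#'
#' @param keys data.table of pair keys (as built internally).
#' @param allowance Per-coordinate allowance in bp.
#' @param grpcols Discrete key columns that must match exactly.
#' @return Integer molecule ids per row of `keys`.
#' @export
group_molecules_bruteforce <- function(keys,
        allowance = 1L,
        grpcols = c("sample", "chrom_l", "chrom_r", "umi_a", "umi_b")) {
    n <- nrow(keys)
    disc <- do.call(paste, c(keys[, grpcols, with = FALSE], sep = "|"))
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        if (disc[i] == disc[j] &&
            abs(keys$pos_l[i] - keys$pos_l[j]) <= allowance &&
            abs(keys$pos_r[i] - keys$pos_r[j]) <= allowance &&
            abs(keys$clip_l[i] - keys$clip_l[j]) <= allowance &&
            abs(keys$clip_r[i] - keys$clip_r[j]) <= allowance) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    match(roots, unique(roots))
}

#' Strand-aware two-step consensus
#'
#' Builds a consensus per strand family and, when both strands are present,
#' a duplex consensus. Families larger than `max_depth` read pairs are
#' downsampled with a seeded RNG. A column is called when the modal base
#' reaches the fractional threshold of the (downsampled) family, else masked
#' N; the duplex consensus keeps only bases on which both strand consensuses
#' agree.
#'
#' @param strand_seqs list of up to two character vectors (aligned, equal
#'   length within a strand) of per-read-pair sequences, one vector per
#'   strand family.
#' @param threshold Fractional agreement required to call a base.
#' @param max_depth Maximum read pairs used per strand.
#' @param seed Seed for downsampling.
#' @return list(strand = list of per-strand consensus strings,
#'   duplex = duplex consensus string or NULL).
#' @export
strand_consensus <- function(strand_seqs, threshold = 0.667, max_depth = 11L,
                             seed = 1L) {
    cons <- vector("list", length(strand_seqs))
    for (s in seq_along(strand_seqs)) {
        seqs <- strand_seqs[[s]]
        if (!length(seqs)) next
        if (length(seqs) > max_depth)
            seqs <- with_seed(seed + s, sample(seqs, max_depth))
        cons[[s]] <- consensus_call(seqs, threshold)
    }
    present <- which(!vapply(cons, is.null, logical(1)))
    duplex <- NULL
    if (length(present) == 2L) {
        a <- charToRaw(cons[[1]]); b <- charToRaw(cons[[2]])
        nr <- charToRaw("N")
        d <- a
        d[a != b | a == nr | b == nr] <- nr
        duplex <- rawToChar(d)
    }
    list(strand = cons, duplex = duplex)
}

# column-wise modal-base call at a fractional threshold (denominator = all
# family members; N never wins)
consensus_call <- function(seqs, threshold) {
    if (length(seqs) == 1L) return(seqs)
    m <- seq_raw_matrix(seqs)
    n <- ncol(m)
    best <- integer(nrow(m))
    call <- rep(charToRaw("N"), nrow(m))
    for (b in c("A", "C", "G", "T")) {
        cnt <- rowSums(m == charToRaw(b))
        better <- cnt > best
        best[better] <- cnt[better]
        call[better] <- charToRaw(b)
    }
    call[best / n < threshold - 1e-9] <- charToRaw("N")
    rawToChar(call)
}

#' Merge overlapping mate reads
#'
#' Alignment-guided merge of a proper read pair whose reference spans
#' overlap: agreeing overlap bases are kept, disagreements resolve to the
#' higher base quality, quality ties are masked N.
#'
#' @param seg1,seg2 Lists or single-row data.tables with fields `chrom`,
#'   `pos`, `end`, `seq` (aligned portion), `qual`.
#' @return list(merged = logical, and when merged: chrom, pos, end, seq,
#'   qual); when not merged (no overlap or inconsistent offsets) the inputs
#'   are returned unchanged under `pair`.
#' @export
merge_overlapping_mates <- function(seg1, seg2) {
    if (seg1$pos > seg2$pos) { tmp <- seg1; seg1 <- seg2; seg2 <- tmp }
    if (seg1$chrom != seg2$chrom || seg2$pos > seg1$end + 0L)
        return(list(merged = FALSE, pair = list(seg1, seg2)))
    if (nchar(seg1$seq) != seg1$end - seg1$pos + 1L ||
        nchar(seg2$seq) != seg2$end - seg2$pos + 1L)
        return(list(merged = FALSE, pair = list(seg1, seg2),
                    reason = "inconsistent overlap"))
    pos <- seg1$pos; end <- max(seg1$end, seg2$end)
    w <- end - pos + 1L
    sq <- rep(charToRaw("N"), w); ql <- rep(as.raw(33L), w)
    i1 <- (seg1$pos - pos + 1L):(seg1$end - pos + 1L)
    sq[i1] <- charToRaw(seg1$seq); ql[i1] <- charToRaw(seg1$qual)
    i2 <- (seg2$pos - pos + 1L):(seg2$end - pos + 1L)
    s2 <- charToRaw(seg2$seq); q2 <- charToRaw(seg2$qual)
    fresh <- sq[i2] == charToRaw("N") & ql[i2] == as.raw(33L)
    conflict <- !fresh & sq[i2] != s2
    take2 <- fresh | (conflict & q2 > ql[i2])
    tie <- conflict & q2 == ql[i2]
    sq[i2][take2] <- s2[take2]; ql[i2][take2] <- q2[take2]
    sq[i2][tie] <- charToRaw("N")
    list(merged = TRUE, chrom = seg1$chrom, pos = pos, end = end,
         seq = rawToChar(sq), qual = rawToChar(ql))
}
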