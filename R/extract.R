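# extract: per-sample driver converting collated molecules into classified
# molecules (proper vs junction candidates) with family consensus sequences.
#
# Molecules whose representative read pair is a concordant FR pair within the
# proper insert limit take a vectorized fast path; everything else is
# reconstructed segment-by-segment via pair_path().

#' Estimate the maximum proper insert size of a library
#'
#' The 99.5th percentile of concordant read-pair spans, the stand-in for the
#' aligner-declared maximum proper insert.
#'
#' @param spans Integer vector of concordant pair reference spans.
#' @param q Quantile used.
#' @return Integer bp.
#' @export
estimate_max_proper_insert <- function(spans, q = 0.995) {
    as.integer(ceiling(stats::quantile(spans, q, names = FALSE)))
}

#' Classify molecules and extract junction candidates for one sample
#'
#' @param collated A `CollatedSample` from [collate_molecules()].
#' @param max_proper_insert Override for the proper-insert limit (bp);
#'   estimated from the library when NULL.
#' @param min_sv_size Minimum Del/Dup node distance called as SV.
#' @param consensus `"candidates"` builds family consensus sequences for
#'   junction molecules only; `"all"` also for proper molecules (needed for
#'   haplotype genotyping).
#' @param threshold,max_depth Consensus parameters (fractional agreement and
#'   read-pair downsampling cap).
#' @param seed Seed for per-molecule consensus downsampling.
#' @return An `ExtractedSample`: list(molecules, candidates, proper,
#'   max_proper_insert, mode, sample).
#' @export
extract_junctions <- function(collated, max_proper_insert = NULL,
                              min_sv_size = 50L,
                              consensus = c("candidates", "all"),
                              threshold = 0.667, max_depth = 11L,
                              seed = 1L) {
    consensus <- match.arg(consensus)
    reads <- collated$reads
    mols <- data.table::copy(collated$molecules)
    pairs <- collated$pairs

    # vectorized per-pair geometry (GForce-friendly aggregations only)
    simple_cig <- "^([0-9]+S)?[0-9]+M([0-9]+S)?$"
    reads[, okcig := grepl(simple_cig, cigar)]
    reads[, posf := data.table::fifelse(is_reverse, NA_real_, as.numeric(pos))]
    reads[, posr := data.table::fifelse(is_reverse, as.numeric(pos), NA_real_)]
    geo <- reads[, .(
        nrec = .N, nsupp = sum(is_supp),
        nchrom = data.table::uniqueN(rname),
        nr1 = sum(read_index == 1L), nr2 = sum(read_index == 2L),
        nfwd = sum(!is_reverse), ncig = sum(okcig),
        minposf = suppressWarnings(min(posf, na.rm = TRUE)),
        minposr = suppressWarnings(min(posr, na.rm = TRUE)),
        span = max(end) - min(pos) + 1L), by = qname]
    geo[, simple := nrec == 2L & nsupp == 0L & nchrom == 1L & nr1 == 1L &
            nr2 == 1L & nfwd == 1L & ncig == 2L & is.finite(minposf) &
            is.finite(minposr) & minposf <= minposr]
    if (is.null(max_proper_insert)) {
        sp <- geo[simple == TRUE, span]
        if (length(sp) < 20L)
            stop2("too few concordant pairs to estimate max proper insert; ",
                  "supply max_proper_insert")
        max_proper_insert <- estimate_max_proper_insert(sp)
    }
    pg <- merge(pairs, geo[, .(qname, simple, span)], by = "qname",
                sort = FALSE)
    magg <- pg[, .(all_simple = all(simple)), by = mol_id]
    mols <- merge(mols, magg, by = "mol_id", sort = FALSE)
    mols[, span := pos_r - pos_l + 1L]
    mols[, fast_proper := all_simple & chrom_l == chrom_r &
             span <= max_proper_insert & span > 0L]
    mols[, class := data.table::fifelse(fast_proper, "proper", NA_character_)]
    mols[, cons := NA_character_]

    data.table::setkey(reads, qname)
    pairs_by_mol <- data.table::copy(pairs)
    data.table::setkey(pairs_by_mol, mol_id)
    cand_rows <- list()
    slow <- which(!mols$fast_proper)
    for (i in slow) {
        rp <- reads[.(mols$rep_qname[i])]
        path <- tryCatch(pair_path(rp, max_proper_insert),
                         error = function(e) NULL)
        if (is.null(path)) { mols$class[i] <- "dropped"; next }
        cands <- call_candidates(path, min_sv_size)
        if (!nrow(cands)) {
            mols$class[i] <- "proper"
            # refresh outer info from the reconstructed path
            mols$pos_l[i] <- path$outer1$pos
            mols$pos_r[i] <- path$outer2$pos
            mols$clip_l[i] <- path$clip1$len
            mols$clip_r[i] <- path$clip2$len
            next
        }
        mols$class[i] <- if (any(cands$evidence == "split")) "sv_candidate"
                         else "gap_candidate"
        # family consensus over all read pairs, aligned on the left outer node
        if (mols$n_pairs[i] > 1L) {
            qn <- pairs_by_mol[.(mols$mol_id[i])]
            stacks <- list(character(0), character(0))
            for (j in seq_len(nrow(qn))) {
                pp <- if (qn$qname[j] == mols$rep_qname[i]) path
                      else tryCatch(pair_path(
                          reads[.(qn$qname[j])],
                          max_proper_insert), error = function(e) NULL)
                if (is.null(pp)) next
                delta <- pp$outer1$pos - path$outer1$pos
                if (path$segments$dir[1] == "-") delta <- -delta
                s <- shift_to_frame(pp$seq, delta, path$L)
                st <- qn$strand[j]
                stacks[[st]] <- c(stacks[[st]], s)
            }
            cc <- strand_consensus(stacks, threshold, max_depth,
                                   derive_seed(seed, mols$rep_qname[i]))
            cons <- cc$duplex %||% cc$strand[[1]] %||% cc$strand[[2]]
            if (!is.null(cons)) {
                path$seq <- cons
                cands <- call_candidates(path, min_sv_size)
                mols$cons[i] <- cons
            }
        } else mols$cons[i] <- path$seq
        if (!nrow(cands)) { mols$class[i] <- "proper"; next }
        cands[, mol_id := mols$mol_id[i]]
        cand_rows[[length(cand_rows) + 1L]] <- cands
    }
    candidates <- if (length(cand_rows)) data.table::rbindlist(cand_rows)
                  else { e <- empty_candidates(); e[, mol_id := integer(0)]; e }
    candidates <- merge(candidates,
                        mols[, .(mol_id, sample, chrom_l, pos_l, clip_l,
                                 chrom_r, pos_r, clip_r, strand1_n, strand2_n,
                                 n_pairs, is_duplex)],
                        by = "mol_id", sort = FALSE)

    proper <- mols[class == "proper"]
    # clipped outer sequences of proper molecules (junction-side evidence)
    proper <- attach_clip_seqs(proper, reads, max_proper_insert)

    if (consensus == "all") {
        prop_idx <- which(mols$class == "proper")
        for (i in prop_idx) {
            qn <- pairs_by_mol[.(mols$mol_id[i])]
            rep_path <- tryCatch(pair_path(
                reads[.(mols$rep_qname[i])],
                max_proper_insert), error = function(e) NULL)
            if (is.null(rep_path)) next
            if (nrow(qn) == 1L) { mols$cons[i] <- rep_path$seq; next }
            stacks <- list(character(0), character(0))
            for (j in seq_len(nrow(qn))) {
                pp <- if (qn$qname[j] == mols$rep_qname[i]) rep_path
                      else tryCatch(pair_path(
                          reads[.(qn$qname[j])],
                          max_proper_insert), error = function(e) NULL)
                if (is.null(pp)) next
                delta <- pp$outer1$pos - rep_path$outer1$pos
                s <- shift_to_frame(pp$seq, delta, rep_path$L)
                stacks[[qn$strand[j]]] <- c(stacks[[qn$strand[j]]], s)
            }
            cc <- strand_consensus(stacks, threshold, max_depth,
                                   derive_seed(seed, mols$rep_qname[i]))
            mols$cons[i] <- cc$duplex %||% cc$strand[[1]] %||% cc$strand[[2]]
        }
        proper <- mols[class == "proper"]
        proper <- attach_clip_seqs(proper, reads, max_proper_insert)
    }

    structure(list(molecules = mols, candidates = candidates, proper = proper,
                   max_proper_insert = max_proper_insert,
                   mode = collated$mode,
                   sample = mols$sample[1]),
              class = "ExtractedSample")
}

#' @export
print.ExtractedSample <- function(x, ...) {
    cat("ExtractedSample:", nrow(x$molecules), "molecules;",
        nrow(x$candidates), "junction candidates; max proper insert",
        x$max_proper_insert, "bp\n")
    invisible(x)
}

# align a pair sequence into the representative frame given a left-edge
# offset delta (pair minus representative), padding with N
shift_to_frame <- function(s, delta, L) {
    if (delta > 0L) s <- paste0(strrep("N", delta), s)
    else if (delta < 0L) s <- substr(s, 1L - delta, nchar(s))
    if (nchar(s) < L) s <- paste0(s, strrep("N", L - nchar(s)))
    substr(s, 1L, L)
}

# pull clipped outer sequences for proper molecules with soft clips from the
# representative pair's terminal records
attach_clip_seqs <- function(proper, reads, max_proper_insert) {
    proper[, clipseq_l := ""]
    proper[, clipseq_r := ""]
    idx <- which(proper$clip_l > 0L | proper$clip_r > 0L)
    for (i in idx) {
        rp <- reads[.(proper$rep_qname[i])]
        path <- tryCatch(pair_path(rp, max_proper_insert),
                         error = function(e) NULL)
        if (is.null(path)) next
        proper$clipseq_l[i] <- path$clip1$seq
        proper$clipseq_r[i] <- path$clip2$seq
        proper$clip_l[i] <- path$clip1$len
        proper$clip_r[i] <- path$clip2$len
    }
    proper
}
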