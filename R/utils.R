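# Shared low-level helpers: seeded RNG scoping, DNA string utilities,
# and small vectorized primitives used across the pipeline stages.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a locally fixed RNG seed
#'
#' Saves and restores the global RNG state so that seeded internal draws
#' (consensus downsampling, permutation tests, simulation) never perturb the
#' caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}

# Deterministic 31-bit sub-seed from a global seed plus a string key
# (e.g. a molecule key), so per-molecule downsampling is reproducible and
# independent of processing order.
derive_seed <- function(seed, key) {
    h <- 0
    for (cc in utf8ToInt(key)) h <- (h * 131 + cc) %% 2147483563L
    as.integer((h + as.numeric(seed)) %% 2147483563L) + 1L
}

# Reverse complement for plain character vectors (A/C/G/T/N alphabet).
# Scalar fast path avoids XStringSet construction in per-record loops.
revcomp <- function(x) {
    if (length(x) == 0L) return(character(0))
    if (length(x) == 1L) {
        if (is.na(x) || !nzchar(x)) return(x)
        return(rawToChar(rev(charToRaw(
            chartr("ACGTNacgtn", "TGCANtgcan", x)))))
    }
    out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
    unname(out)
}

random_dna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Hamming distance between equal-length strings `obs` (vector) and one `ref`.
hamming_to <- function(obs_raw, ref_raw) {
    colSums(obs_raw != ref_raw)
}

# Split a character vector of equal-length strings into a raw-byte matrix
# (nchar x n). Fast path for column-wise consensus voting.
seq_raw_matrix <- function(x) {
    n <- length(x)
    w <- nchar(x[1])
    matrix(charToRaw(paste(x, collapse = "")), nrow = w, ncol = n)
}

raw_to_seq <- function(m) {
    if (is.matrix(m)) apply(m, 2, rawToChar) else rawToChar(m)
}

# Vectorized per-string quality sums (Phred+33 ASCII), batched by width.
qual_sums <- function(qual) {
    w <- nchar(qual)
    out <- numeric(length(qual))
    for (uw in unique(w)) {
        idx <- which(w == uw)
        m <- matrix(as.integer(charToRaw(paste(qual[idx], collapse = ""))),
                    nrow = uw)
        out[idx] <- colSums(m) - 33L * uw
    }
    out
}

stop2 <- function(...) stop(..., call. = FALSE)
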