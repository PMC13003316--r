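.SCORERS <- c(longdust = 0L, sdust = 1L, entropy = 2L)

.scorer_code <- function(scorer) {
    scorer <- match.arg(scorer, names(.SCORERS))
    .SCORERS[[scorer]]
}

# Maximal A/C/G/T runs of a sequence: list of (offset, codes) with 0-based
# offsets. The scan never crosses ambiguous characters; window state is
# implicitly reset at every split.
.segments <- function(seq, k) {
    codes <- .encode(seq)
    if (!length(codes)) return(list())
    ok <- !is.na(codes)
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    out <- list()
    for (z in seq_along(r$values)) {
        if (r$values[z] && r$lengths[z] >= k) {
            out[[length(out) + 1L]] <-
                list(offset = starts[z] - 1L,
                     codes = codes[starts[z]:ends[z]])
        }
    }
    out
}

.empty_intervals <- function(score = TRUE) {
    df <- data.frame(start = integer(0), end = integer(0))
    if (score) df$score <- numeric(0)
    df
}

#' Scan one sequence for good low-complexity intervals (single strand)
#'
#' Applies the candidate search to every position of the forward strand:
#' positions whose terminal k-mer is unique within the context window are
#' skipped; a window-saturated good interval found at the previous position
#' is slid forward by the extension heuristic (when enabled); otherwise the
#' backward/forward candidate search locates the longest good LC interval
#' ending at the position. Ambiguous (non-ACGT) characters split the
#' sequence; no interval spans them. When the model's `xdrop` is set,
#' intervals are X-drop split before merging.
#'
#' @param seq a single DNA string.
#' @param model a [ld_model()] object; heuristic switches are taken from
#'   `model$params`.
#' @param scorer scoring function driving the scan: `"longdust"` (default),
#'   `"sdust"` or `"entropy"`. The entropy score requires `w <= 4^k`.
#' @param merge merge overlapping/adjacent intervals into maximal regions
#'   (default). With `FALSE` the raw good intervals are returned, one per
#'   accepting end position, each at most `w + k - 1` bases long, with the
#'   interval score (NA where the end was grown by the extension heuristic).
#' @return A data frame with columns `start`, `end` (0-based half-open) and,
#'   for `merge = FALSE`, `score` (nats).
#' @examples
#' m <- ld_model(ld_params(k = 5, w = 60, gc = 0.5))
#' ld_scan(strrep("ACGGT", 30), m)
#' @export
ld_scan <- function(seq, model, scorer = "longdust", merge = TRUE) {
    stopifnot(inherits(model, "longdust_model"), length(seq) == 1L)
    sc <- .scorer_code(scorer)
    p <- model$params
    if (sc == .SCORERS[["entropy"]] && p$w > 4^p$k)
        stop("the entropy scorer requires w <= 4^k")
    out <- list()
    for (seg in .segments(seq, p$k)) {
        raw <- .ld_scan_cpp(seg$codes, p$k, p$w, p$threshold, model$f,
                            p$use_extension, p$fast_start, sc)
        if (!length(raw$start)) next
        df <- data.frame(start = raw$start + seg$offset,
                         end = raw$end + seg$offset + 1L,
                         score = raw$score)
        if (!is.null(p$xdrop)) {
            df <- xdrop_filter(df, seq, model, scorer = scorer)
            df$score <- NA_real_  # scores are not recomputed after splitting
        }
        out[[length(out) + 1L]] <- df
    }
    df <- if (length(out)) do.call(rbind, out) else .empty_intervals()
    if (merge) merge_intervals(df) else df
}

#' Backward candidate collection at one end position
#'
#' Scans start positions backwards from `j`, maintaining the suffix score
#' `S(i - k + 1, j)`, and returns the candidate start positions that can
#' head a good LC interval ending at `j`, each with the running suffix score
#' maximum recorded at emission. Low-level surface of the scan, exposed for
#' inspection and testing; positions are 0-based k-mer end indices.
#'
#' @param seq a single ACGT-only DNA string.
#' @param j 0-based position of the interval end (last base), `j >= k - 1`.
#' @param model a [ld_model()] object.
#' @param scorer scoring function (see [ld_scan()]).
#' @return A data frame with columns `pos` (candidate k-mer end positions,
#'   ascending; the interval would start at base `pos - k + 1`) and `vbound`
#'   (suffix score bound, nats; positive).
#' @export
ld_backward <- function(seq, j, model, scorer = "longdust") {
    stopifnot(inherits(model, "longdust_model"))
    codes <- .chk_codes(seq)
    p <- model$params
    .ld_backward_cpp(codes, as.integer(j), p$k, p$w, p$threshold, model$f,
                     .scorer_code(scorer))
}

#' Forward extension from a candidate start
#'
#' Rescans from candidate start `i0` towards `j` with fresh counts and
#' returns the position maximising the prefix score `S(i0 - k + 1, .)`
#' (ties resolved to the latest position). `[i0 - k + 1, j]` is a good LC
#' interval iff the returned argmax equals `j`. Scanning stops early once
#' the score exceeds `vbound` (the candidate's recorded suffix bound).
#'
#' @inheritParams ld_backward
#' @param i0 0-based k-mer end position of the candidate start.
#' @param vbound early-stop score bound in nats (default `Inf`: scan all the
#'   way to `j`).
#' @return A list with `imax` (0-based argmax k-mer end position, or -1 if
#'   the score never reached 0) and `score_at_j` (score of the full
#'   `[i0 - k + 1, j]` interval, NaN if the scan stopped early).
#' @export
ld_forward <- function(seq, i0, j, model, vbound = Inf, scorer = "longdust") {
    stopifnot(inherits(model, "longdust_model"))
    codes <- .chk_codes(seq)
    p <- model$params
    .ld_forward_cpp(codes, as.integer(i0), as.integer(j), vbound, p$k,
                    p$threshold, model$f, .scorer_code(scorer))
}

#' Longest good LC interval ending at a position
#'
#' Runs the backward candidate collection at `j` and extends candidates
#' forward in ascending start order (skipping candidates contained in a
#' previous forward reach) until one reaches `j`.
#'
#' @inheritParams ld_backward
#' @return A one-row data frame with `start`, `end` (0-based half-open base
#'   coordinates of the good interval ending at `j`) and `score`, or a
#'   zero-row data frame if no good LC interval ends at `j`.
#' @export
ld_find_start <- function(seq, j, model, scorer = "longdust") {
    stopifnot(inherits(model, "longdust_model"))
    codes <- .chk_codes(seq)
    p <- model$params
    r <- .ld_find_start_cpp(codes, as.integer(j), p$k, p$w, p$threshold,
                            model$f, p$fast_start, .scorer_code(scorer))
    if (r$start < 0) return(.empty_intervals())
    data.frame(start = r$start - p$k + 1L, end = as.integer(j) + 1L,
               score = r$score)
}

.chk_codes <- function(seq) {
    stopifnot(length(seq) == 1L)
    codes <- .encode(seq)
    if (anyNA(codes))
        stop("this operation requires an ACGT-only sequence")
    codes
}

#' X-drop splitting of reported intervals
#'
#' Recomputes the prefix score profile `v(p) = S(start, p)` across each
#' interval and splits it wherever the running maximum exceeds the current
#' score by more than the model's `xdrop` (in nats): the interval is
#' truncated at the running-max position and scanning restarts, with fresh
#' counts, after the drop position. This trims non-repetitive spacers that
#' were absorbed between two repetitive blocks. With `xdrop` unset (or
#' infinite) the intervals are returned unchanged.
#'
#' @param intervals data frame with `start`/`end` (0-based half-open)
#'   columns, as produced by [ld_scan()].
#' @param seq the DNA string the intervals refer to.
#' @param model a [ld_model()] object (`model$params$xdrop` is the
#'   threshold).
#' @param scorer scoring function (see [ld_scan()]).
#' @return A data frame of sub-intervals with `start`/`end` columns; total
#'   covered length never exceeds the input's.
#' @export
xdrop_filter <- function(intervals, seq, model, scorer = "longdust") {
    stopifnot(inherits(model, "longdust_model"))
    xd <- model$params$xdrop
    if (is.null(xd) || !is.finite(xd)) return(intervals)
    if (!nrow(intervals)) return(.empty_intervals(score = FALSE))
    sc <- .scorer_code(scorer)
    p <- model$params
    codes <- .encode(seq)
    if (!anyNA(codes))
        return(.ld_xdrop_cpp(codes, as.integer(intervals$start),
                             as.integer(intervals$end), p$k, p$threshold,
                             model$f, xd, sc))
    # ambiguous bases elsewhere in the sequence: process interval slices
    pieces <- lapply(seq_len(nrow(intervals)), function(z) {
        s0 <- intervals$start[z]; e0 <- intervals$end[z]
        seg <- codes[(s0 + 1L):e0]
        if (anyNA(seg)) stop("interval spans an ambiguous base")
        d <- .ld_xdrop_cpp(seg, 0L, length(seg), p$k, p$threshold,
                           model$f, xd, sc)
        d$start <- d$start + s0
        d$end <- d$end + s0
        d
    })
    do.call(rbind, pieces)
}

#' Merge intervals into maximal disjoint regions
#'
#' Merges overlapping or directly adjacent (end == start) intervals; the
#' union of good LC intervals is what defines the LC regions of a sequence,
#' and merging across adjacency keeps the output minimal.
#'
#' @param intervals data frame with `start`/`end` (0-based half-open).
#' @return Sorted data frame of disjoint, non-adjacent `start`/`end` rows.
#' @export
merge_intervals <- function(intervals) {
    if (!nrow(intervals)) return(.empty_intervals(score = FALSE))
    o <- order(intervals$start, intervals$end)
    s <- intervals$start[o]; e <- intervals$end[o]
    ms <- s[1]; me <- e[1]
    out_s <- integer(0); out_e <- integer(0)
    for (z in seq_along(s)[-1]) {
        if (s[z] <= me) {
            me <- max(me, e[z])
        } else {
            out_s <- c(out_s, ms); out_e <- c(out_e, me)
            ms <- s[z]; me <- e[z]
        }
    }
    data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Strand-symmetric union of LC calls
#'
#' The scan heuristics are not exactly strand symmetric: a sequence and its
#' reverse complement may yield slightly different good intervals. The
#' default output therefore scans both strands and reports the union: the
#' reverse-complement calls `[s, e)` are mapped back to `[n - e, n - s)` and
#' merged with the forward calls. The result is invariant under reverse
#' complementation of the input.
#'
#' @param seq a single DNA string.
#' @param model a [ld_model()] object.
#' @param scorer scoring function (see [ld_scan()]).
#' @param intervals_fwd optional precomputed forward-strand calls from
#'   [ld_scan()]; computed if `NULL`.
#' @return Merged data frame of `start`/`end` rows (0-based half-open,
#'   forward-strand coordinates).
#' @export
ld_symmetrize <- function(seq, model, scorer = "longdust",
                          intervals_fwd = NULL) {
    if (is.null(intervals_fwd))
        intervals_fwd <- ld_scan(seq, model, scorer = scorer)
    n <- nchar(seq)
    rc <- ld_scan(revcomp(seq), model, scorer = scorer)
    mapped <- data.frame(start = n - rc$end, end = n - rc$start)
    merge_intervals(rbind(intervals_fwd[c("start", "end")], mapped))
}

#' Find low-complexity regions in DNA sequences
#'
#' End-to-end longdust pipeline: builds the frequency model from the
#' genome-wide G+C content (unless overridden), scans every sequence on both
#' strands (by default) and reports the merged union of good LC intervals in
#' BED-style coordinates.
#'
#' @param x input sequences: a (preferably named) character vector, a
#'   `Biostrings::DNAStringSet`, or the path of a (possibly gzipped) FASTA
#'   file.
#' @inheritParams ld_params
#' @param scorer scoring function (see [ld_scan()]).
#' @param params optionally a prebuilt [ld_params()] object, overriding the
#'   individual parameter arguments.
#' @return A data frame with columns `seqid`, `start`, `end` (0-based
#'   half-open), sorted by input order and start; suitable for
#'   [write_bed()].
#' @examples
#' sim <- simulate_genome(3000, repeats = list(list(unit = 20, copies = 8,
#'                        at = 1000)), seed = 1)
#' longdust(c(chr1 = sim$seq), w = 200)
#' @export
longdust <- function(x, k = 7L, w = 5000L, threshold = 0.6, gc = NULL,
                     xdrop = NULL, both_strands = TRUE, use_extension = TRUE,
                     fast_start = FALSE, scorer = "longdust", params = NULL) {
    if (is.null(params))
        params <- ld_params(k = k, w = w, threshold = threshold, gc = gc,
                            xdrop = xdrop, both_strands = both_strands,
                            use_extension = use_extension,
                            fast_start = fast_start)
    stopifnot(inherits(params, "longdust_params"))
    if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
        file.exists(x))
        x <- read_fasta(x)
    if (methods::is(x, "DNAStringSet")) {
        nm <- names(x)
        x <- as.character(x)
        names(x) <- nm
    }
    if (!is.character(x)) stop("'x' must be sequences or a FASTA path")
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    if (is.null(params$gc)) {
        params$gc <- gc_fraction(x)
        if (!is.finite(params$gc) || params$gc <= 0 || params$gc >= 1)
            params$gc <- 0.5  # degenerate input: fall back to uniform
    }
    model <- ld_model(params)
    out <- lapply(seq_along(x), function(z) {
        iv <- if (params$both_strands)
            ld_symmetrize(x[[z]], model, scorer = scorer)
        else
            ld_scan(x[[z]], model, scorer = scorer)
        if (!nrow(iv))
            return(data.frame(seqid = character(0), start = integer(0),
                              end = integer(0)))
        data.frame(seqid = names(x)[z], start = iv$start, end = iv$end)
    })
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    df
}
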