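# Tandem iteron detection in candidate replication origins (oriV).
# Iterons are short (typically 17-22 bp) direct repeats upstream of the rep
# gene that act as binding sites for the Rep initiator protein; small theta
# plasmids typically carry ~4 tandem copies.

#' Build a degenerate consensus from aligned repeat copies
#'
#' Per column, the set of observed bases. A singleton column renders as the
#' base itself; a variable column renders as `(X/Y[...])` with the bases
#' ordered by descending count, ties broken alphabetically — the notation
#' used when quoting imperfect iterons.
#'
#' @param copies Character vector of equal-length DNA strings (>= 2).
#' @return An object of class `DegenerateConsensus`: a list with element
#'   `positions`, one character vector of bases per column (majority
#'   first).
#' @examples
#' render_consensus(build_consensus(c("ACG", "ACG", "ACT")))  # "AC(G/T)"
#' @export
build_consensus <- function(copies) {
  if (length(copies) < 2L) stop("need at least 2 copies")
  copies <- vapply(copies, .check_dna, "", USE.NAMES = FALSE)
  lens <- nchar(copies)
  if (length(unique(lens)) != 1L) stop("copies must have equal length")
  mat <- do.call(rbind, strsplit(copies, "", fixed = TRUE))
  positions <- lapply(seq_len(ncol(mat)), function(j) {
    tab <- sort(table(mat[, j]), decreasing = TRUE)
    # stable: descending count, then alphabetical within equal counts
    ord <- order(-as.integer(tab), names(tab))
    names(tab)[ord]
  })
  structure(list(positions = positions), class = "DegenerateConsensus")
}

#' Render a degenerate consensus in (X/Y) notation
#' @param consensus A `DegenerateConsensus`.
#' @return A single string, e.g. `"CT(A/T)(T/G)ATG..."`.
#' @export
render_consensus <- function(consensus) {
  stopifnot(inherits(consensus, "DegenerateConsensus"))
  paste(vapply(consensus$positions, function(p) {
    if (length(p) == 1L) p else paste0("(", paste(p, collapse = "/"), ")")
  }, ""), collapse = "")
}

#' Parse a degenerate consensus string in (X/Y) notation
#'
#' Inverse of [render_consensus()]: `"AC(G/T)"` becomes a consensus whose
#' third column is the base set \{G, T\} in the given order.
#'
#' @param string Consensus string; 5'-/-3' decorations are stripped.
#' @return A `DegenerateConsensus`.
#' @export
parse_consensus <- function(string) {
  s <- gsub("^5['′]-|-3['′]$", "", trimws(string))
  toks <- regmatches(s, gregexpr("\\([ACGT](/[ACGT])+\\)|[ACGT]", s))[[1]]
  if (paste(toks, collapse = "") != s) {
    stop("cannot parse consensus string: '", string, "'")
  }
  positions <- lapply(toks, function(t) {
    if (startsWith(t, "(")) strsplit(gsub("[()]", "", t), "/", fixed = TRUE)[[1]]
    else t
  })
  structure(list(positions = positions), class = "DegenerateConsensus")
}

#' Expanded length (unit length) of a degenerate consensus
#' @param consensus A `DegenerateConsensus` or a consensus string.
#' @return Number of positions (bp of the repeat unit).
#' @export
consensus_length <- function(consensus) {
  if (is.character(consensus)) consensus <- parse_consensus(consensus)
  length(consensus$positions)
}

#' @export
print.DegenerateConsensus <- function(x, ...) {
  cat("DegenerateConsensus:", render_consensus(x),
      sprintf("(%d bp)\n", consensus_length(x)))
  invisible(x)
}

.majority_base <- function(copies_mat) {
  vapply(seq_len(ncol(copies_mat)), function(j) {
    tab <- sort(table(copies_mat[, j]), decreasing = TRUE)
    ord <- order(-as.integer(tab), names(tab))
    names(tab)[ord][1]
  }, "")
}

.copy_mismatches <- function(copies_mat, majority) {
  rowSums(copies_mat != matrix(majority, nrow(copies_mat),
                               ncol(copies_mat), byrow = TRUE))
}

#' Detect tandem iteron arrays in a DNA sequence
#'
#' Scans for maximal arrays of adjacent (optionally spaced) repeat copies
#' whose per-copy divergence from the column-majority consensus stays below
#' a mismatch budget. Candidate arrays of different unit lengths and
#' offsets that overlap on the sequence are deduplicated, keeping the
#' highest copy count, then the lowest mean mismatch fraction, then the
#' smallest unit, then the leftmost start.
#'
#' Low-complexity units (fewer than 3 distinct bases in the consensus) are
#' suppressed, so homopolymer and dinucleotide tracts are never reported.
#'
#' @param seq DNA string (the candidate oriV region, typically the window
#'   upstream of the rep gene).
#' @param unit_range Length-2 integer vector, the repeat unit lengths to
#'   consider (default `c(18, 24)`, bracketing the 20-22 bp iterons of
#'   small theta plasmids).
#' @param min_copies Minimum copies to report (default 3; canonical
#'   arrays have 4, but degraded arrays should still surface).
#' @param max_mismatch_frac Per-copy mismatch budget as a fraction of the
#'   unit length (default 0.15).
#' @param max_spacer Maximum gap between consecutive copies in bp
#'   (default 0: strictly tandem).
#' @return A list of `IteronArray` objects: `unit_length`, `copy_count`,
#'   `copy_starts` (1-based), `copies`, `consensus`
#'   (`DegenerateConsensus`), `mean_mismatch_frac`, `strand` (`"+"` for
#'   this function).
#' @examples
#' unit <- "CATAAAGCTACGTTTAGCGACC"
#' arr <- find_iteron_arrays(paste0("TTTTT", strrep(unit, 4), "GGGGG"))
#' arr[[1]]$copy_count
#' @export
find_iteron_arrays <- function(seq, unit_range = c(18L, 24L),
                               min_copies = 3L, max_mismatch_frac = 0.15,
                               max_spacer = 0L) {
  seq <- .check_dna(seq)
  if (length(unit_range) != 2L || unit_range[1] > unit_range[2]) {
    stop("unit_range must be c(min, max) with min <= max")
  }
  if (max_spacer < 0L || max_spacer > 10L) {
    stop("max_spacer must be in [0, 10]")
  }
  n <- nchar(seq)
  if (n < 2L * unit_range[1]) return(list())
  x <- strsplit(seq, "", fixed = TRUE)[[1]]

  candidates <- list()
  for (u in seq.int(unit_range[1], unit_range[2])) {
    if (2L * u > n) next
    budget <- floor(max_mismatch_frac * u)
    # O(n) prescreen: Hamming distance between the window at s and the
    # window at s+u; if both copies fit the per-copy budget their pairwise
    # distance is at most 2*budget
    for (spacer in 0L:max_spacer) {
      step <- u + spacer
      if (n < 2L * u + spacer) next
      d <- x[seq_len(n - step)] != x[(step + 1L):n]
      cs <- c(0L, cumsum(d))
      smax <- n - step - u + 1L
      if (smax < 1L) next
      pair_mm <- cs[seq_len(smax) + u] - cs[seq_len(smax)]
      for (s in which(pair_mm <= 2L * budget)) {
        arr <- .grow_array(x, s, u, step, budget, n)
        if (is.null(arr) || arr$copy_count < min_copies) next
        candidates[[length(candidates) + 1L]] <- arr
      }
    }
  }
  if (length(candidates) == 0L) return(list())
  .dedupe_arrays(candidates, min_copies)
}

# Greedily extend an array of copies starting at s rightwards while every
# copy stays within the per-copy mismatch budget of the running majority
# consensus; NULL if even two copies do not qualify.
.grow_array <- function(x, s, u, step, budget, n) {
  starts <- s
  repeat {
    nxt <- starts[length(starts)] + step
    if (nxt + u - 1L > n) break
    trial <- c(starts, nxt)
    mat <- do.call(rbind, lapply(trial, function(p) x[p:(p + u - 1L)]))
    maj <- .majority_base(mat)
    if (any(.copy_mismatches(mat, maj) > budget)) break
    starts <- trial
  }
  if (length(starts) < 2L) return(NULL)
  mat <- do.call(rbind, lapply(starts, function(p) x[p:(p + u - 1L)]))
  maj <- .majority_base(mat)
  mm <- .copy_mismatches(mat, maj)
  if (any(mm > budget)) return(NULL)
  if (length(unique(maj)) < 3L) return(NULL)  # low-complexity guard
  copies <- apply(mat, 1, paste, collapse = "")
  structure(list(unit_length = u, copy_count = length(starts),
                 copy_starts = starts, copies = copies,
                 consensus = build_consensus(copies),
                 mean_mismatch_frac = mean(mm) / u,
                 strand = "+"),
            class = "IteronArray")
}

# Keep, per overlap cluster, the best array: highest copy_count, lowest
# mean mismatch, smallest unit, leftmost. An array is dropped if it
# overlaps an already-accepted better one.
.dedupe_arrays <- function(cands, min_copies) {
  spans <- t(vapply(cands, function(a) {
    c(a$copy_starts[1],
      a$copy_starts[a$copy_count] + a$unit_length - 1L)
  }, integer(2)))
  ord <- order(-vapply(cands, `[[`, 0L, "copy_count"),
               vapply(cands, `[[`, 0, "mean_mismatch_frac"),
               vapply(cands, `[[`, 0L, "unit_length"),
               spans[, 1])
  kept <- list(); kept_spans <- NULL
  for (i in ord) {
    ov <- FALSE
    if (!is.null(kept_spans)) {
      ov <- any(spans[i, 1] <= kept_spans[, 2] &
                spans[i, 2] >= kept_spans[, 1])
    }
    if (!ov) {
      kept[[length(kept) + 1L]] <- cands[[i]]
      kept_spans <- rbind(kept_spans, spans[i, , drop = FALSE])
    }
  }
  kept[order(vapply(kept, function(a) a$copy_starts[1], 0L))]
}

#' @export
print.IteronArray <- function(x, ...) {
  cat(sprintf("IteronArray: %d x %d bp at %d (%s strand), consensus %s\n",
              x$copy_count, x$unit_length, x$copy_starts[1], x$strand,
              render_consensus(x$consensus)))
  invisible(x)
}

#' Extract the window upstream of a rep gene
#'
#' Returns the `window` bp immediately 5' of the start codon on the coding
#' strand, wrapping through the origin of a circular record when needed;
#' for a minus-strand gene the 3' flank is taken and reverse-complemented
#' so the result always reads 5'->3' towards the gene.
#'
#' @param record A `PlasmidRecord`.
#' @param rep_feature One row of `record$features` (data frame or list
#'   with `start`, `end`, `strand`).
#' @param window Window size in bp (default 500). Windows longer than the
#'   plasmid are truncated with a warning.
#' @return DNA string of length `min(window, record$length)`.
#' @export
upstream_window <- function(record, rep_feature, window = 500L) {
  stopifnot(inherits(record, "PlasmidRecord"))
  len <- record$length
  window <- as.integer(window)
  if (window > len) {
    warning("window exceeds plasmid length; truncated to ", len, " bp")
    window <- len
  }
  if (window < 1L) stop("window must be positive")
  if (rep_feature$strand == "+") {
    # window ends just before the start codon
    e <- rep_feature$start - 1L
    if (e < 1L) e <- e + len
    s <- e - window + 1L
    if (s < 1L) s <- s + len
    extract_region(record, s, e)
  } else {
    s <- rep_feature$end + 1L
    if (s > len) s <- s - len
    e <- s + window - 1L
    if (e > len) e <- e - len
    revcomp(extract_region(record, s, e))
  }
}

#' Detect iteron arrays upstream of a rep gene, searching both strands
#'
#' Convenience wrapper: extracts the upstream window of each REP-like
#' feature (or an explicitly given feature), scans both strands with
#' [find_iteron_arrays()], and reports arrays with window-relative
#' coordinates and strand.
#'
#' @param record A `PlasmidRecord`.
#' @param rep_feature Feature row to anchor the window; default the first
#'   feature whose product mentions replication ("rep").
#' @param window Upstream window in bp (default 500).
#' @param ... Passed to [find_iteron_arrays()].
#' @return List of `IteronArray`; `strand` is `"+"` for arrays on the
#'   window as extracted and `"-"` for its reverse complement.
#' @export
detect_iterons <- function(record, rep_feature = NULL, window = 500L, ...) {
  if (is.null(rep_feature)) {
    hit <- grep("rep", record$features$product, ignore.case = TRUE)
    if (length(hit) == 0L) stop("no rep-like feature found on '",
                                record$id, "'")
    rep_feature <- record$features[hit[1], ]
  }
  win <- upstream_window(record, rep_feature, window)
  fwd <- find_iteron_arrays(win, ...)
  rev <- find_iteron_arrays(revcomp(win), ...)
  rev <- lapply(rev, function(a) { a$strand <- "-"; a })
  c(fwd, rev)
}
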