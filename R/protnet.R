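# Reciprocated protein-similarity networks from all-vs-all gapped local
# alignment. A node is a protein; an edge joins two proteins whose directed
# hits BOTH pass the E-value / identity / coverage thresholds; the edge
# weight is the product of alignment identity and coverage. Connected
# components of the network define protein families.

.AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

.check_protein <- function(seq, what = "protein") {
  seq <- toupper(seq)
  bad <- setdiff(unique(strsplit(seq, "", fixed = TRUE)[[1]]), .AA_ALPHABET)
  if (length(bad) > 0L) {
    stop(what, " contains non-standard residues: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (nchar(seq) == 0L) stop("empty ", what)
  seq
}

#' Assemble a protein set with replicon metadata
#'
#' @param id Character vector of protein identifiers (unique).
#' @param sequence Amino-acid strings (20 standard residues + X).
#' @param plasmid_id,strain Optional per-protein metadata.
#' @return Data frame of class `protein_set` with columns `id`,
#'   `sequence`, `plasmid_id`, `strain`, `length`.
#' @export
protein_set <- function(id, sequence, plasmid_id = NA_character_,
                        strain = NA_character_) {
  if (anyDuplicated(id)) stop("protein ids must be unique")
  sequence <- vapply(sequence, .check_protein, "", USE.NAMES = FALSE)
  out <- data.frame(id = as.character(id), sequence = sequence,
                    plasmid_id = as.character(plasmid_id),
                    strain = as.character(strain),
                    length = nchar(sequence), stringsAsFactors = FALSE)
  class(out) <- c("protein_set", "data.frame")
  out
}

.scoring_matrix <- function(matrix = "BLOSUM62") {
  if (is.matrix(matrix)) return(matrix)
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

#' Optimal gapped local alignment of two proteins
#'
#' Smith-Waterman local alignment with affine gap penalties (a gap of
#' length L costs `gap_open + L * gap_extend`), BLOSUM62 by default —
#' the scoring scheme of a standard gapped protein database search.
#' Identity, positives and coverage are computed on the single
#' best-scoring local alignment (the HSP): identity and positives are
#' fractions of alignment columns (gap columns count in the denominator,
#' as in a BLAST hit table), and `coverage` is the fraction of the
#' shorter protein contained in the HSP, with per-side query/subject
#' coverages also reported.
#'
#' @param a,b Amino-acid strings or single rows of a [protein_set()].
#' @param matrix Scoring matrix name from Biostrings (default
#'   `"BLOSUM62"`) or a matrix.
#' @param gap_open,gap_extend Affine gap costs (defaults 11 and 1).
#' @return Object of class `AlignmentHit`: `query_id`, `subject_id`,
#'   `raw_score`, `identity`, `positives`, `coverage`,
#'   `query_coverage`, `subject_coverage`, `align_length`, `evalue`
#'   (filled by the Karlin-Altschul estimate for the two sequence
#'   lengths).
#' @export
local_align <- function(a, b, matrix = "BLOSUM62", gap_open = 11,
                        gap_extend = 1) {
  ida <- idb <- NA_character_
  if (is.list(a) || is.data.frame(a)) { ida <- a$id; a <- a$sequence }
  if (is.list(b) || is.data.frame(b)) { idb <- b$id; b <- b$sequence }
  a <- .check_protein(a, "query"); b <- .check_protein(b, "subject")
  mat <- .scoring_matrix(matrix)

  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ncol_aln <- length(pa)
  nongap <- pa != "-" & pb != "-"
  idents <- sum(pa[nongap] == pb[nongap])
  pos <- sum(mat[cbind(pa[nongap], pb[nongap])] > 0)
  q_span <- sum(pa != "-")
  s_span <- sum(pb != "-")
  shorter <- min(nchar(a), nchar(b))
  cov_short <- (if (nchar(a) <= nchar(b)) q_span else s_span) / shorter
  score <- Biostrings::score(aln)

  structure(list(
    query_id = ida, subject_id = idb, raw_score = score,
    identity = idents / ncol_aln, positives = pos / ncol_aln,
    coverage = cov_short,
    query_coverage = q_span / nchar(a),
    subject_coverage = s_span / nchar(b),
    align_length = ncol_aln,
    evalue = estimate_evalue(score, nchar(a), nchar(b))),
    class = "AlignmentHit")
}

#' @export
print.AlignmentHit <- function(x, ...) {
  cat(sprintf(
    "AlignmentHit %s vs %s: score %.0f, id %.1f%%, pos %.1f%%, cov %.1f%%, E = %.2g\n",
    x$query_id, x$subject_id, x$raw_score, 100 * x$identity,
    100 * x$positives, 100 * x$coverage, x$evalue))
  invisible(x)
}

#' Karlin-Altschul E-value for a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of local
#' alignments scoring at least `S` between a random query of `m` residues
#' and a database of `n` residues. Defaults are the published gapped
#' parameters for BLOSUM62 with gap costs 11/1 (`lambda = 0.267`,
#' `K = 0.041`). Here the E-value serves as a similarity filter, not a
#' statistic of record.
#'
#' @param raw_score Alignment raw score `S`.
#' @param m Query length in residues.
#' @param n Database (subject) length in residues.
#' @param lambda,K Karlin-Altschul parameters for the scoring scheme.
#' @return The expectation `E` (non-negative, monotone decreasing in
#'   `raw_score`).
#' @examples
#' estimate_evalue(40, 100, 100)  # 0.041 * 1e4 * exp(-10.68)
#' @export
estimate_evalue <- function(raw_score, m, n, lambda = 0.267, K = 0.041) {
  if (m <= 0 || n <= 0) stop("sequence lengths must be positive")
  K * m * n * exp(-lambda * raw_score)
}

.hit_passes <- function(hit, evalue_max, identity_min, coverage_min) {
  hit$evalue <= evalue_max && hit$identity >= identity_min &&
    hit$coverage >= coverage_min
}

#' Build a reciprocated protein-similarity network
#'
#' Runs all-vs-all gapped local alignment over the protein set and adds an
#' edge between two proteins only when BOTH directed hits pass all three
#' thresholds (reciprocated similarity). The default thresholds — E-value
#' at most 1e-10, identity at least 30%, HSP coverage at least 90% — are
#' the standard stringent setting for homology networks of plasmid
#' proteomes. The edge weight is the mean over the two directions of
#' identity x coverage, so every edge weight lies in
#' `[identity_min * coverage_min, 1]`. Connected components of the edge
#' set define protein families.
#'
#' @param proteins A [protein_set()].
#' @param evalue_max,identity_min,coverage_min Edge thresholds.
#' @param matrix,gap_open,gap_extend Passed to [local_align()].
#' @return Object of class `SimilarityNetwork`: `graph` (igraph, with
#'   node attributes `plasmid_id`, `strain` and edge attribute `weight`),
#'   `hits` (data frame of all passing directed hits), `components`
#'   (named membership vector), `params`.
#' @export
build_network <- function(proteins, evalue_max = 1e-10,
                          identity_min = 0.30, coverage_min = 0.90,
                          matrix = "BLOSUM62", gap_open = 11,
                          gap_extend = 1) {
  stopifnot(nrow(proteins) >= 1L)
  if (identity_min <= 0 || identity_min > 1 ||
      coverage_min <= 0 || coverage_min > 1 || evalue_max <= 0) {
    stop("thresholds must lie in (0, 1] (identity, coverage) / (0, Inf) (evalue)")
  }
  mat <- .scoring_matrix(matrix)
  n <- nrow(proteins)
  edges <- list()
  hits <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        fwd <- local_align(proteins[i, ], proteins[j, ], mat,
                           gap_open, gap_extend)
        rev <- local_align(proteins[j, ], proteins[i, ], mat,
                           gap_open, gap_extend)
        ok <- .hit_passes(fwd, evalue_max, identity_min, coverage_min) &&
          .hit_passes(rev, evalue_max, identity_min, coverage_min)
        if (ok) {
          w <- mean(c(fwd$identity * fwd$coverage,
                      rev$identity * rev$coverage))
          edges[[length(edges) + 1L]] <- data.frame(
            from = proteins$id[i], to = proteins$id[j], weight = w,
            stringsAsFactors = FALSE)
          hits[[length(hits) + 1L]] <- data.frame(
            query_id = fwd$query_id, subject_id = fwd$subject_id,
            raw_score = fwd$raw_score, identity = fwd$identity,
            positives = fwd$positives, coverage = fwd$coverage,
            evalue = fwd$evalue, stringsAsFactors = FALSE)
        }
      }
    }
  }
  edge_df <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), weight = numeric())
  g <- igraph::graph_from_data_frame(
    edge_df, directed = FALSE,
    vertices = data.frame(name = proteins$id,
                          plasmid_id = proteins$plasmid_id,
                          strain = proteins$strain,
                          stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership
  structure(list(
    graph = g,
    hits = if (length(hits)) do.call(rbind, hits) else NULL,
    components = comp,
    params = list(evalue_max = evalue_max, identity_min = identity_min,
                  coverage_min = coverage_min, gap_open = gap_open,
                  gap_extend = gap_extend)),
    class = "SimilarityNetwork")
}

#' @export
print.SimilarityNetwork <- function(x, ...) {
  cat(sprintf("SimilarityNetwork: %d proteins, %d edges, %d components\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              max(x$components)))
  invisible(x)
}

#' Classify a protein against labeled reference sets
#'
#' Aligns the query against every reference and returns the label of the
#' best-scoring hit passing the E-value threshold (the standard setting
#' for relaxase/replicase/toxin-antitoxin family assignment is 1e-2).
#' Ties on score break by higher identity, then lexicographic reference
#' id. Below threshold the query is `"unclassified"`.
#'
#' @param query Amino-acid string or one row of a [protein_set()].
#' @param references Data frame with columns `id`, `label`, `sequence`
#'   (e.g. Rep_3 / RepA-like / Rep_1 replicases, MOB_P / MOB_Q / MOB_V
#'   relaxases), or a named list of such sets.
#' @param evalue_max E-value threshold (default 1e-2).
#' @param ... Passed to [local_align()].
#' @return List: `label` (`"unclassified"` when nothing passes),
#'   `best_id`, `evalue`, `identity`.
#' @export
classify_protein <- function(query, references, evalue_max = 1e-2, ...) {
  if (is.list(references) && !is.data.frame(references)) {
    references <- do.call(rbind, references)
  }
  if (is.null(references) || nrow(references) == 0L) {
    stop("empty reference set")
  }
  best <- NULL
  for (i in seq_len(nrow(references))) {
    hit <- local_align(query, references$sequence[i], ...)
    if (hit$evalue > evalue_max) next
    better <- is.null(best) ||
      hit$raw_score > best$hit$raw_score ||
      (hit$raw_score == best$hit$raw_score &&
         (hit$identity > best$hit$identity ||
            (hit$identity == best$hit$identity &&
               references$id[i] < best$id)))
    if (better) {
      best <- list(hit = hit, id = references$id[i],
                   label = references$label[i])
    }
  }
  if (is.null(best)) {
    return(list(label = "unclassified", best_id = NA_character_,
                evalue = NA_real_, identity = NA_real_))
  }
  list(label = best$label, best_id = best$id,
       evalue = best$hit$evalue, identity = best$hit$identity)
}

#' Reciprocal similarity report for two proteins
#'
#' Convenience wrapper around [local_align()] in both directions,
#' reporting percent identity and percent positives over the HSP together
#' with per-side coverage — the numbers quoted when two relaxases are
#' said to share, e.g., 74% or 87% similarity.
#'
#' @param a,b Amino-acid strings or [protein_set()] rows.
#' @param ... Passed to [local_align()].
#' @return Data frame with one row per direction: `query`, `subject`,
#'   `identity_pct`, `positives_pct`, `query_coverage_pct`,
#'   `subject_coverage_pct`, `evalue`.
#' @export
reciprocal_similarity <- function(a, b, ...) {
  f <- local_align(a, b, ...)
  r <- local_align(b, a, ...)
  data.frame(
    query = c(f$query_id, r$query_id),
    subject = c(f$subject_id, r$subject_id),
    identity_pct = 100 * c(f$identity, r$identity),
    positives_pct = 100 * c(f$positives, r$positives),
    query_coverage_pct = 100 * c(f$query_coverage, r$query_coverage),
    subject_coverage_pct = 100 * c(f$subject_coverage, r$subject_coverage),
    evalue = c(f$evalue, r$evalue),
    stringsAsFactors = FALSE)
}
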