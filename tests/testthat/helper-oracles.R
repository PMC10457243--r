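# Independent brute-force oracles used to validate the fast paths.
# These deliberately share no code with the package implementation.

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
           "K", "M", "F", "P", "S", "T", "W", "Y", "V")

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

random_protein <- function(n) paste(sample(.AA20, n, TRUE), collapse = "")

# Gotoh affine-gap local alignment score: a gap of length L costs
# open + L * extend. Plain dynamic program, no vectorization tricks.
oracle_local_score <- function(a, b, mat = blosum62, open = 11, extend = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      Ix[i, j] <- max(M[i - 1, j] - open - extend, Ix[i - 1, j] - extend)
      Iy[i, j] <- max(M[i, j - 1] - open - extend, Iy[i, j - 1] - extend)
      M[i, j] <- max(0, max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                            Iy[i - 1, j - 1]) + mat[A[i - 1], B[j - 1]])
      best <- max(best, M[i, j], Ix[i, j], Iy[i, j])
    }
  }
  best
}

# Sliding-window IUPAC matcher on both strands of a (possibly circular)
# sequence, expanding the ambiguity codes by hand.
.IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))

.revcomp_iupac <- function(site) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(site, "")[[1]]]), collapse = "")
}

oracle_scan <- function(seq, site, circular = FALSE) {
  n <- nchar(seq); k <- nchar(site)
  if (k > n) return(integer(0))
  subject <- if (circular) paste0(seq, substr(seq, 1, k - 1)) else seq
  S <- strsplit(subject, "")[[1]]
  hits <- integer(0)
  for (pat in unique(c(site, .revcomp_iupac(site)))) {
    P <- strsplit(pat, "")[[1]]
    for (s in 1:(length(S) - k + 1)) {
      ok <- TRUE
      for (t in 1:k) {
        if (!S[s + t - 1] %in% .IUPAC[[P[t]]]) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, s)
    }
  }
  sort(unique(hits[hits <= n]))
}

# Exact tandem-repeat scan via maximal periodicity runs: for each unit
# length, every maximal stretch with x[i] == x[i + u] defines a repeat
# region whose copy number is floor(length / u). Overlapping reports are
# pruned with the same published preference rule (more copies, smaller
# unit, leftmost), re-implemented from scratch.
oracle_exact_tandem <- function(seq, unit_range = c(18, 24), min_copies = 3) {
  x <- strsplit(seq, "")[[1]]; n <- length(x)
  cand <- list()
  for (u in unit_range[1]:unit_range[2]) {
    if (2 * u > n) next
    match <- x[1:(n - u)] == x[(u + 1):n]
    r <- rle(match)
    stop_at <- cumsum(r$lengths)
    start_at <- stop_at - r$lengths + 1
    for (i in which(r$values)) {
      a <- start_at[i]; L <- r$lengths[i] + u
      k <- floor(L / u)
      if (k < min_copies) next
      if (length(unique(x[a:(a + u - 1)])) < 3) next
      cand[[length(cand) + 1]] <-
        c(start = a, unit = u, copies = k, span_end = a + k * u - 1)
    }
  }
  if (!length(cand)) return(list())
  m <- do.call(rbind, cand)
  ord <- order(-m[, "copies"], m[, "unit"], m[, "start"])
  kept <- NULL
  for (i in ord) {
    if (is.null(kept) ||
        all(m[i, "start"] > kept[, "span_end"] |
            m[i, "span_end"] < kept[, "start"])) {
      kept <- rbind(kept, m[i, , drop = FALSE])
    }
  }
  kept <- kept[order(kept[, "start"]), , drop = FALSE]
  lapply(seq_len(nrow(kept)), function(i) kept[i, 1:3])
}

# Shared fixture: a plasmid record with an iteron array planted upstream
# of a plus-strand rep gene.
make_iteron_plasmid <- function(seed, unit = NULL, copies = 4,
                                sub_prob = 0, len = 1500) {
  modules <- list(rep = list(iteron_unit = unit %||% 21L, copies = copies,
                             sub_prob = sub_prob))
  generate_plasmid(len, 0.40, modules, seed = seed,
                   id = sprintf("syn%d", seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
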