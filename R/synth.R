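# Truth-tracked synthetic data: circular plasmids with planted iteron
# arrays, rep/mob genes and site-free regions, plus protein families with
# controlled within/between-family identity. Every generator takes an
# explicit seed and is fully deterministic given (inputs, seed); no hidden
# global RNG state leaks out.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Random DNA with a target GC content
#' @param n Length in bp.
#' @param gc Target GC fraction (default 0.40, the small-plasmid range).
#' @param seed Optional RNG seed.
#' @return DNA string; bases drawn i.i.d. with P(G) = P(C) = gc/2.
#' @export
random_dna <- function(n, gc = 0.40, seed = NULL) {
  .with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
  })
}

.random_protein <- function(n) {
  aa <- setdiff(.AA_ALPHABET, "X")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

.substitute_bases <- function(seq, prob) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(x)) < prob)
  for (i in hit) {
    x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1L)
  }
  paste(x, collapse = "")
}

# A crude ORF: ATG + random codon-free filler + TAA, sized to aa_len.
.synthetic_orf <- function(aa_len) {
  paste0("ATG", random_dna(3L * aa_len), "TAA")
}

#' Generate a synthetic circular plasmid with planted features
#'
#' Emulates the structure of a small (3-14 kb) plasmid: background DNA at
#' a requested GC content, optionally a rep gene with an upstream array of
#' tandem iterons (perfect or with per-copy substitutions), a mob
#' (relaxase) gene, and a region kept free of the recognition sites of an
#' enzyme panel. The returned truth object fully determines what was
#' planted, so detectors can be scored without access to the generator's
#' internals.
#'
#' @param length Plasmid size in bp (1 kb - 100 kb).
#' @param gc Target GC fraction (realized within about 2 points).
#' @param modules A list with optional entries:
#'   \describe{
#'     \item{rep}{`list(iteron_unit =` DNA string or unit length`,
#'       copies = 4, sub_prob = 0, gap_to_gene = 120, aa_len = 100)` —
#'       plants `copies` tandem iterons followed by a rep ORF
#'       `gap_to_gene` bp downstream.}
#'     \item{mob}{`list(aa_len = 150)` or `TRUE` — plants a relaxase ORF.}
#'     \item{site_free}{`list(start =, end =, enzymes =)` — resamples the
#'       span until no panel site matches (site-free by construction).}
#'   }
#' @param seed RNG seed (required for reproducibility).
#' @param id Record identifier.
#' @return List with `record` (a [plasmid_record()]) and `truth`
#'   (class `SyntheticTruth`: `planted_iterons`, `planted_sites`,
#'   `family_labels`, `seed`).
#' @export
generate_plasmid <- function(length, gc = 0.40, modules = list(),
                             seed = 1L, id = "synthetic_plasmid") {
  if (length < 1000 || length > 100000) {
    stop("plasmid length must be between 1 kb and 100 kb")
  }
  .with_seed(seed, {
    seq <- random_dna(length, gc)
    feats <- NULL
    planted_iterons <- list()
    cursor <- 101L  # leave a small 5' margin

    if (!is.null(modules$rep)) {
      rp <- modules$rep
      unit <- rp$iteron_unit %||% 22L
      if (is.numeric(unit)) unit <- random_dna(as.integer(unit), gc = 0.45)
      unit <- .check_dna(unit)
      copies <- as.integer(rp$copies %||% 4L)
      sub_prob <- rp$sub_prob %||% 0
      gap <- as.integer(rp$gap_to_gene %||% 120L)
      aa_len <- as.integer(rp$aa_len %||% 100L)

      copy_seqs <- vapply(seq_len(copies), function(i) {
        if (sub_prob > 0) .substitute_bases(unit, sub_prob) else unit
      }, "")
      array_seq <- paste(copy_seqs, collapse = "")
      orf <- .synthetic_orf(aa_len)
      block <- paste0(array_seq, random_dna(gap, gc), orf)
      if (cursor + nchar(block) - 1L > length) {
        stop("rep module exceeds plasmid length")
      }
      substr(seq, cursor, cursor + nchar(block) - 1L) <- block
      iter_start <- cursor
      gene_start <- cursor + nchar(array_seq) + gap
      feats <- rbind(feats, data.frame(
        locus_tag = "SYN_rep", start = gene_start,
        end = gene_start + nchar(orf) - 1L, strand = "+",
        product = "replication initiator protein (Rep)",
        translation = "", stringsAsFactors = FALSE))
      planted_iterons[[1]] <- list(
        unit = unit, unit_length = nchar(unit), copy_count = copies,
        copy_starts = iter_start + (seq_len(copies) - 1L) * nchar(unit),
        copies = copy_seqs, sub_prob = sub_prob)
      cursor <- gene_start + nchar(orf) + 200L
    }

    if (isTRUE(modules$mob) || is.list(modules$mob)) {
      mb <- if (is.list(modules$mob)) modules$mob else list()
      aa_len <- as.integer(mb$aa_len %||% 150L)
      orf <- .synthetic_orf(aa_len)
      if (cursor + nchar(orf) - 1L > length) {
        stop("mob module exceeds plasmid length")
      }
      substr(seq, cursor, cursor + nchar(orf) - 1L) <- orf
      feats <- rbind(feats, data.frame(
        locus_tag = "SYN_mob", start = cursor,
        end = cursor + nchar(orf) - 1L, strand = "+",
        product = "mobilization relaxase (MobA)",
        translation = "", stringsAsFactors = FALSE))
      cursor <- cursor + nchar(orf) + 200L
    }

    planted_sites <- list()
    if (!is.null(modules$site_free)) {
      sf <- modules$site_free
      enz <- sf$enzymes %||% default_enzymes()
      s <- as.integer(sf$start); e <- as.integer(sf$end)
      if (s < 1L || e > length) stop("site_free span outside plasmid")
      if (cursor > 101L) {
        # resampling must not overwrite the planted rep/mob block
        covered <- if (s <= e) seq.int(s, e) else c(seq.int(s, length),
                                                    seq.int(1L, e))
        if (any(covered >= 101L & covered < cursor)) {
          stop("site_free region overlaps a planted module; ",
               "choose a non-overlapping span")
        }
      }
      for (attempt in 1:200) {
        frag <- extract_region(seq, s, e, circular = TRUE)
        hits <- unlist(lapply(enz$site, function(st) scan_sites(frag, st)))
        if (length(hits) == 0L) break
        # knock each found site out by resampling its first base region
        repl <- random_dna(.region_length(s, e, length), gc)
        if (s <= e) {
          substr(seq, s, e) <- repl
        } else {
          substr(seq, s, length) <- substr(repl, 1L, length - s + 1L)
          substr(seq, 1L, e) <- substr(repl, length - s + 2L, nchar(repl))
        }
        if (attempt == 200L) stop("could not build a site-free region")
      }
      planted_sites <- setNames(vector("list", nrow(enz)), enz$name)
      for (i in seq_len(nrow(enz))) {
        planted_sites[[i]] <- scan_sites(seq, enz$site[i], circular = TRUE)
      }
    }

    rec <- plasmid_record(id, seq, "circular", feats)
    truth <- structure(list(planted_iterons = planted_iterons,
                            planted_sites = planted_sites,
                            family_labels = NULL, seed = seed),
                       class = "SyntheticTruth")
    list(record = rec, truth = truth)
  })
}

#' Mutate a protein to an approximate target global identity
#'
#' Substitutes residues at `round((1 - target) * L)` distinct positions,
#' each to a uniformly chosen different residue, so the realized global
#' (ungapped, position-wise) identity equals the target up to rounding.
#'
#' @param protein Amino-acid string (length >= 50) or [protein_set()] row.
#' @param target_identity Fraction in (0, 1].
#' @param seed RNG seed.
#' @return The mutated amino-acid string.
#' @export
mutate_to_identity <- function(protein, target_identity, seed = NULL) {
  if (is.list(protein) || is.data.frame(protein)) protein <- protein$sequence
  protein <- .check_protein(protein)
  if (target_identity <= 0 || target_identity > 1) {
    stop("target identity must be in (0, 1]")
  }
  L <- nchar(protein)
  if (L < 50L) stop("protein shorter than 50 residues")
  k <- round((1 - target_identity) * L)
  if (k == 0L) return(protein)
  .with_seed(seed, {
    x <- strsplit(protein, "", fixed = TRUE)[[1]]
    pos <- sample.int(L, k)
    aa <- setdiff(.AA_ALPHABET, "X")
    for (i in pos) x[i] <- sample(setdiff(aa, x[i]), 1L)
    paste(x, collapse = "")
  })
}

#' Generate protein families with controlled identity structure
#'
#' Each family descends from its own ancestor; members are independent
#' mutants of the ancestor at a per-member divergence chosen so that the
#' expected pairwise member-member identity matches `within_identity`
#' (two members mutated independently at fraction p of positions share
#' roughly (1-p)^2 of positions, so p = 1 - sqrt(within)). Family
#' ancestors are mutants of a common root at sqrt(`between_identity`)
#' identity, so ancestor pairs share about `between_identity`; values at
#' or below ~0.2 behave like unrelated random proteins.
#'
#' @param n_families,members_per_family Family structure (e.g. 4 x 5, the
#'   functional-group layout of a plasmid-proteome network figure).
#' @param within_identity,between_identity Target pairwise identities;
#'   `within_identity > between_identity` required.
#' @param length Protein length in residues (default 300).
#' @param seed RNG seed.
#' @return List with `proteins` (a [protein_set()]; ids
#'   `F<f>_M<m>`) and `truth` (`SyntheticTruth` with `family_labels`).
#' @export
generate_protein_families <- function(n_families, members_per_family,
                                      within_identity = 0.85,
                                      between_identity = 0.15,
                                      length = 300L, seed = 1L) {
  if (within_identity <= between_identity) {
    stop("within_identity must exceed between_identity")
  }
  if (within_identity > 1 || between_identity <= 0) {
    stop("identities must lie in (0, 1]")
  }
  .with_seed(seed, {
    root <- .random_protein(length)
    p_member <- 1 - sqrt(within_identity)
    ids <- character(0); seqs <- character(0); labels <- character(0)
    for (f in seq_len(n_families)) {
      # ancestors at sqrt(between) identity to the root, so two ancestors
      # share about `between` pairwise
      anc <- mutate_to_identity(root, sqrt(between_identity))
      for (m in seq_len(members_per_family)) {
        memb <- mutate_to_identity(anc, 1 - p_member)
        ids <- c(ids, sprintf("F%d_M%d", f, m))
        seqs <- c(seqs, memb)
        labels <- c(labels, sprintf("F%d", f))
      }
    }
    prots <- protein_set(ids, seqs, plasmid_id = labels)
    truth <- structure(list(planted_iterons = list(), planted_sites = list(),
                            family_labels = setNames(labels, ids),
                            seed = seed),
                       class = "SyntheticTruth")
    list(proteins = prots, truth = truth)
  })
}

#' Mutate a protein to a target percent-positives similarity
#'
#' "Similarity" figures quoted for relaxase pairs are BLAST positives:
#' the fraction of aligned columns with a positive substitution-matrix
#' score. A random substitution still scores positive with probability
#' p (about 0.11 under BLOSUM62 for uniformly drawn residues), so the
#' identity target that realizes a wanted positives fraction s is
#' (s - p) / (1 - p). The mutation itself is delegated to
#' [mutate_to_identity()] (point substitutions only, so the local
#' alignment of the pair is gap-free and column counts are exact).
#'
#' @param protein Amino-acid string or [protein_set()] row.
#' @param target_positives Wanted positives fraction in (p, 1].
#' @param seed RNG seed.
#' @param matrix Scoring matrix (default `"BLOSUM62"`).
#' @return The mutated amino-acid string.
#' @export
mutate_to_similarity <- function(protein, target_positives, seed = NULL,
                                 matrix = "BLOSUM62") {
  mat <- .scoring_matrix(matrix)
  aa <- setdiff(.AA_ALPHABET, "X")
  sub <- mat[aa, aa]
  diag(sub) <- NA
  p_pos <- mean(sub > 0, na.rm = TRUE)
  if (target_positives <= p_pos || target_positives > 1) {
    stop("target positives must lie in (", round(p_pos, 3), ", 1]")
  }
  mutate_to_identity(protein, (target_positives - p_pos) / (1 - p_pos),
                     seed)
}
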