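#' @importFrom stats setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

.DNA_ALPHABET <- c("A", "C", "G", "T", "N")

.check_dna <- function(seq, what = "sequence") {
  seq <- toupper(seq)
  bad <- setdiff(unique(strsplit(seq, "", fixed = TRUE)[[1]]), .DNA_ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N}: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  seq
}

#' Construct a plasmid record
#'
#' A `PlasmidRecord` is the central container of the package: one circular
#' (or linear) replicon with its DNA sequence and annotated gene features.
#' Coordinates are 1-based inclusive throughout (GenBank convention); on a
#' circular record a feature or region with `start > end` runs forward
#' through the sequence origin.
#'
#' @param id Accession or local name.
#' @param sequence DNA string over \{A,C,G,T,N\}; lowercase is uppercased.
#' @param topology `"circular"` (default, the plasmid case) or `"linear"`.
#' @param features A data frame with columns `locus_tag`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), `product`, `translation` (amino-acid string,
#'   `""` when absent). May be `NULL` for an unannotated record.
#' @return An object of class `PlasmidRecord` with elements `id`,
#'   `sequence`, `length`, `topology`, `features`.
#' @examples
#' rec <- plasmid_record("p1", "ACGTACGT")
#' rec$length
#' @export
plasmid_record <- function(id, sequence, topology = c("circular", "linear"),
                           features = NULL) {
  topology <- match.arg(topology)
  sequence <- .check_dna(sequence, sprintf("record '%s'", id))
  if (nchar(sequence) == 0L) stop("empty sequence for record '", id, "'")
  features <- .normalize_features(features, nchar(sequence), topology, id)
  structure(list(id = as.character(id), sequence = sequence,
                 length = nchar(sequence), topology = topology,
                 features = features),
            class = "PlasmidRecord")
}

.empty_features <- function() {
  data.frame(locus_tag = character(), start = integer(), end = integer(),
             strand = character(), product = character(),
             translation = character(), stringsAsFactors = FALSE)
}

.normalize_features <- function(features, len, topology, id) {
  if (is.null(features) || nrow(features) == 0L) return(.empty_features())
  need <- c("locus_tag", "start", "end", "strand", "product", "translation")
  for (col in setdiff(need, names(features))) {
    features[[col]] <- if (col %in% c("start", "end")) NA_integer_ else ""
  }
  features <- features[, need]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (any(features$start < 1L | features$start > len |
          features$end < 1L | features$end > len)) {
    stop("feature coordinates outside [1, ", len, "] on record '", id, "'")
  }
  wraps <- features$start > features$end
  if (any(wraps) && topology != "circular") {
    stop("origin-wrapping feature on linear record '", id, "'")
  }
  if (!all(features$strand %in% c("+", "-"))) {
    stop("feature strand must be '+' or '-' on record '", id, "'")
  }
  rownames(features) <- NULL
  features
}

#' @export
print.PlasmidRecord <- function(x, ...) {
  cat(sprintf("PlasmidRecord '%s': %s bp, %s, %d feature(s)\n",
              x$id, format(x$length, big.mark = ","), x$topology,
              nrow(x$features)))
  invisible(x)
}

#' Construct a labeled module region on a replicon
#'
#' A coordinate span labeled with its functional role (REP, MOB, ...).
#' `start > end` encodes a region running forward through the origin of a
#' circular replicon, exactly as module coordinates are quoted for
#' deposited plasmid records.
#'
#' @param plasmid_id Identifier of the replicon the region lives on.
#' @param start,end 1-based inclusive coordinates.
#' @param label One of REP, MOB, DPR, GCV, SMR, RM, MSC, MRS, other.
#' @return An object of class `ModuleRegion`.
#' @export
module_region <- function(plasmid_id, start, end,
                          label = c("REP", "MOB", "DPR", "GCV", "SMR",
                                    "RM", "MSC", "MRS", "other")) {
  label <- match.arg(label)
  structure(list(plasmid_id = as.character(plasmid_id),
                 start = as.integer(start), end = as.integer(end),
                 label = label),
            class = "ModuleRegion")
}

#' Extract a (possibly origin-wrapping) region from a replicon
#'
#' If `start <= end` the usual substring `start..end` is returned. On a
#' circular record `start > end` means the region runs forward through the
#' sequence origin: positions `start..length` followed by `1..end`, so the
#' returned length is `(length - start + 1) + end`.
#'
#' @param record A `PlasmidRecord`, or a plain DNA string (then `circular`
#'   controls wrapping).
#' @param start,end 1-based inclusive coordinates within the sequence.
#' @param circular Only used when `record` is a bare string.
#' @return The extracted DNA string.
#' @examples
#' extract_region(plasmid_record("p", "ACGTACGT"), 7, 2)  # "GTAC"
#' @export
extract_region <- function(record, start, end, circular = TRUE) {
  if (inherits(record, "PlasmidRecord")) {
    seq <- record$sequence
    circular <- record$topology == "circular"
  } else {
    seq <- .check_dna(record)
  }
  len <- nchar(seq)
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || start > len || end < 1L || end > len) {
    stop("coordinates (", start, ",", end, ") outside [1, ", len, "]")
  }
  if (start <= end) return(substr(seq, start, end))
  if (!circular) stop("origin-wrapping extraction requested on a linear sequence")
  paste0(substr(seq, start, len), substr(seq, 1L, end))
}

#' Length a region extraction will produce
#' @noRd
.region_length <- function(start, end, len) {
  if (start <= end) end - start + 1L else (len - start + 1L) + end
}

#' GC content of a DNA sequence
#'
#' Percentage of G+C among unambiguous bases; `N` is excluded from both the
#' numerator and the denominator.
#'
#' @param seq DNA string.
#' @param digits Rounding of the reported percentage (default one decimal,
#'   the convention of replicon summary tables).
#' @return GC percentage in `[0, 100]`.
#' @examples
#' gc_content("ATGC")  # 50
#' @export
gc_content <- function(seq, digits = 1) {
  seq <- .check_dna(seq)
  counts <- table(factor(strsplit(seq, "", fixed = TRUE)[[1]],
                         levels = .DNA_ALPHABET))
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0L) stop("GC content undefined: no unambiguous bases")
  round(100 * sum(counts[c("G", "C")]) / denom, digits)
}

#' Reverse complement of a DNA string
#' @param seq DNA string (may contain N).
#' @return The reverse complement.
#' @export
revcomp <- function(seq) {
  seq <- .check_dna(seq)
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Rotate a circular sequence
#'
#' Returns the sequence starting at position `k + 1`, i.e. position
#' `k + 1` of the input becomes position 1 of the output. Useful for
#' rotation-invariance checks of circular-sequence operations.
#' @param seq DNA string.
#' @param k Rotation offset in bp (0 <= k < length).
#' @export
rotate_sequence <- function(seq, k) {
  len <- nchar(seq)
  k <- as.integer(k %% len)
  if (k == 0L) return(seq)
  paste0(substr(seq, k + 1L, len), substr(seq, 1L, k))
}

# ---------------------------------------------------------------------------
# GenBank flat-file IO (minimal: LOCUS/DEFINITION/FEATURES/ORIGIN; CDS and
# gene features with location, locus_tag, product, translation)
# ---------------------------------------------------------------------------

.parse_location <- function(loc) {
  strand <- "+"
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  # join(a..b,c..d): an origin-spanning CDS on a circular record; keep the
  # outer span as start = a, end = d with start > end encoding the wrap
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
    first <- parts[1]; last <- parts[length(parts)]
    start <- as.integer(sub("^[<>]?(\\d+)\\.\\..*$", "\\1", first))
    end <- as.integer(sub("^.*\\.\\.[<>]?(\\d+)$", "\\1", last))
  } else if (grepl("\\.\\.", loc)) {
    start <- as.integer(sub("^[<>]?(\\d+)\\.\\..*$", "\\1", loc))
    end <- as.integer(sub("^.*\\.\\.[<>]?(\\d+)$", "\\1", loc))
  } else {
    start <- end <- as.integer(gsub("[<>]", "", loc))
  }
  if (is.na(start) || is.na(end)) stop("cannot parse feature location: ", loc)
  list(start = start, end = end, strand = strand)
}

#' Read plasmid records from a GenBank flat file
#'
#' A minimal flat-file reader covering the record model used here: one
#' record per LOCUS; topology taken from the LOCUS line (defaulting to
#' circular, the plasmid case); CDS and gene features with their location
#' (including `complement()` and origin-spanning `join()`, stored as
#' `start > end`), `/locus_tag`, `/product` and `/translation`. A CDS
#' without a deposited translation is kept with an empty translation;
#' translations are never recomputed implicitly.
#'
#' @param path Path to a GenBank flat file.
#' @return A list of [plasmid_record()] objects.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^LOCUS", lines)
  if (length(starts) == 0L) {
    stop("malformed GenBank file (no LOCUS line): ", path)
  }
  bounds <- c(starts, length(lines) + 1L)
  lapply(seq_along(starts), function(i) {
    .parse_genbank_record(lines[bounds[i]:(bounds[i + 1L] - 1L)])
  })
}

.parse_genbank_record <- function(lines) {
  locus <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(locus) < 2L) stop("malformed LOCUS line: '", lines[1], "'")
  id <- locus[2]
  topology <- if (any(grepl("\\blinear\\b", lines[1]))) "linear" else "circular"

  feat_at <- grep("^FEATURES", lines)
  orig_at <- grep("^ORIGIN", lines)
  if (length(orig_at) == 0L) stop("record '", id, "' has no ORIGIN section")
  seq_lines <- lines[(orig_at[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[0-9 /]", "", paste(seq_lines, collapse = "")))

  features <- .empty_features()
  if (length(feat_at) > 0L) {
    fl <- lines[(feat_at[1] + 1L):(orig_at[1] - 1L)]
    features <- .parse_feature_table(fl)
  }
  plasmid_record(id, sequence, topology, features)
}

.parse_feature_table <- function(fl) {
  # feature keys start at column 6; qualifiers/continuations at column 22
  key_at <- grep("^ {5}\\S", fl)
  out <- list()
  for (i in seq_along(key_at)) {
    from <- key_at[i]
    to <- if (i < length(key_at)) key_at[i + 1L] - 1L else length(fl)
    key <- sub("^ {5}(\\S+).*$", "\\1", fl[from])
    if (key != "CDS") next
    block <- fl[from:to]
    header <- sub("^ {5}\\S+\\s+", "", block[1])
    # location may continue over lines until the first qualifier
    qual_at <- grep("^\\s+/", block)
    loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(block)
    loc <- paste(trimws(c(header, if (loc_end >= 2L) block[2:loc_end])),
                 collapse = "")
    loc <- sub("/.*$", "", loc)
    pl <- .parse_location(loc)
    quals <- .parse_qualifiers(block, qual_at)
    out[[length(out) + 1L]] <- data.frame(
      locus_tag = quals[["locus_tag"]] %||% "",
      start = pl$start, end = pl$end, strand = pl$strand,
      product = quals[["product"]] %||% "",
      translation = quals[["translation"]] %||% "",
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(.empty_features())
  feats <- do.call(rbind, out)
  rownames(feats) <- NULL
  feats
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_qualifiers <- function(block, qual_at) {
  if (length(qual_at) == 0L) return(list())
  quals <- list()
  bounds <- c(qual_at, length(block) + 1L)
  for (i in seq_along(qual_at)) {
    chunk <- trimws(block[qual_at[i]:(bounds[i + 1L] - 1L)])
    text <- paste(chunk, collapse = "")
    m <- regmatches(text, regexec("^/([A-Za-z_]+)=?\"?([^\"]*)\"?", text))[[1]]
    if (length(m) == 3L) {
      val <- m[3]
      if (m[2] == "translation") val <- gsub("\\s", "", val)
      quals[[m[2]]] <- val
    }
  }
  quals
}

#' Write plasmid records as a GenBank flat file
#'
#' Emits the subset of the format that [read_genbank()] consumes, so a
#' write/read cycle reproduces the record (sequence, topology, feature
#' coordinates, strands, locus tags, products, translations).
#'
#' @param records A `PlasmidRecord` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(records, path) {
  if (inherits(records, "PlasmidRecord")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) .write_genbank_record(rec, con)
  invisible(path)
}

.write_genbank_record <- function(rec, con) {
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   BCT",
                     rec$id, rec$length, rec$topology), con)
  writeLines(sprintf("DEFINITION  %s.", rec$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", rec$length), con)
  fts <- rec$features
  for (i in seq_len(nrow(fts))) {
    loc <- if (fts$start[i] <= fts$end[i]) {
      sprintf("%d..%d", fts$start[i], fts$end[i])
    } else {
      sprintf("join(%d..%d,1..%d)", fts$start[i], rec$length, fts$end[i])
    }
    if (fts$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     CDS             %s", loc), con)
    if (nzchar(fts$locus_tag[i])) {
      writeLines(sprintf("                     /locus_tag=\"%s\"",
                         fts$locus_tag[i]), con)
    }
    if (nzchar(fts$product[i])) {
      writeLines(sprintf("                     /product=\"%s\"",
                         fts$product[i]), con)
    }
    if (nzchar(fts$translation[i])) {
      tr <- fts$translation[i]
      pieces <- substring(tr, seq(1, nchar(tr), 44),
                          pmin(seq(1, nchar(tr), 44) + 43, nchar(tr)))
      pieces[1] <- paste0("/translation=\"", pieces[1])
      pieces[length(pieces)] <- paste0(pieces[length(pieces)], "\"")
      for (p in pieces) {
        writeLines(sprintf("                     %s", p), con)
      }
    }
  }
  writeLines("ORIGIN", con)
  s <- tolower(rec$sequence)
  pos <- seq(1, nchar(s), 60)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59, nchar(s)))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(1, nchar(chunk), 10) + 9, nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(groups, collapse = " ")), con)
  }
  writeLines("//", con)
}

#' Read plasmid sequences from FASTA
#'
#' @param path FASTA file of nucleotide sequences.
#' @param topology Topology to assign to all records (plasmid default
#'   circular).
#' @return List of [plasmid_record()] objects without features.
#' @export
read_fasta_plasmids <- function(path, topology = "circular") {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    plasmid_record(ids[i], as.character(set[[i]]), topology)
  })
}

#' Write a similarity network to GraphML or a tab-separated edge list
#'
#' Node attributes (protein id, plasmid, strain) and edge weights are
#' preserved; re-reading with [read_network()] reproduces the graph.
#'
#' @param net A `SimilarityNetwork` (see [build_network()]) or an igraph
#'   object.
#' @param path Output path.
#' @param format `"graphml"` or `"edge-tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "edge-tsv")) {
  format <- match.arg(format)
  g <- if (inherits(net, "SimilarityNetwork")) net$graph else net
  if (!igraph::is_igraph(g)) stop("not a network")
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(g, what = "edges")
    if (nrow(el) > 0L) el$weight <- sprintf("%.6f", el$weight)
    names(el)[1:2] <- c("source", "target")
    write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a similarity network written by [write_network()]
#' @param path GraphML file.
#' @return An igraph object.
#' @export
read_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
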