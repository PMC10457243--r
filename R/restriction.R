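# Restriction-site availability screening of plasmid genetic modules.
# A module destined for a cloning vector should be poor in the recognition
# sites that populate common multiple-cloning sites (MCS): every enzyme NOT
# cutting inside the module remains usable in the vector's MCS.

#' The default 13-enzyme MCS panel
#'
#' The endonucleases most commonly represented in multiple cloning sites,
#' with their canonical 6-bp recognition sequences: BamHI, EcoRI, EcoRV,
#' HindIII, KpnI, NcoI, NheI, PstI, SacI, SalI, SphI, XbaI, XhoI.
#'
#' @return Data frame with columns `name` and `site` (IUPAC DNA).
#' @export
default_enzymes <- function() {
  data.frame(
    name = c("BamHI", "EcoRI", "EcoRV", "HindIII", "KpnI", "NcoI", "NheI",
             "PstI", "SacI", "SalI", "SphI", "XbaI", "XhoI"),
    site = c("GGATCC", "GAATTC", "GATATC", "AAGCTT", "GGTACC", "CCATGG",
             "GCTAGC", "CTGCAG", "GAGCTC", "GTCGAC", "GCATGC", "TCTAGA",
             "CTCGAG"),
    stringsAsFactors = FALSE)
}

.check_site <- function(site) {
  site <- toupper(site)
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  bad <- setdiff(strsplit(site, "", fixed = TRUE)[[1]], iupac)
  if (length(bad) > 0L) stop("invalid IUPAC site: ", site)
  if (nchar(site) < 4L) stop("recognition site shorter than 4 bp: ", site)
  site
}

#' Scan a sequence for a restriction recognition site
#'
#' Reports every 1-based start position where the (possibly degenerate
#' IUPAC) site matches on either strand. With `circular = TRUE` sites
#' spanning the sequence origin are also found, by matching against the
#' sequence extended with its first `nchar(site) - 1` bases; such hits
#' keep their start position in `1..length`. Hits duplicated by a
#' palindromic site on the two strands are collapsed.
#'
#' @param seq DNA string.
#' @param site IUPAC recognition sequence (e.g. `"GAATTC"`), or a one-row
#'   data frame / list with a `site` element.
#' @param circular Treat the sequence as circular (default `FALSE`).
#' @return Sorted integer vector of match start positions (possibly
#'   empty).
#' @examples
#' scan_sites("GGGAATTCGG", "GAATTC")  # 4
#' @export
scan_sites <- function(seq, site, circular = FALSE) {
  if (is.list(site)) site <- site$site
  site <- .check_site(site)
  seq <- .check_dna(seq)
  k <- nchar(site)
  n <- nchar(seq)
  if (k > n) return(integer(0))
  subject <- if (circular && n > 1L) {
    paste0(seq, substr(seq, 1L, k - 1L))
  } else {
    seq
  }
  subj <- Biostrings::DNAString(subject)
  hits <- integer(0)
  for (pat in c(site, as.character(Biostrings::reverseComplement(
                                     Biostrings::DNAString(site))))) {
    m <- Biostrings::matchPattern(pat, subj, fixed = FALSE)
    hits <- c(hits, BiocGenerics::start(m))
  }
  hits <- hits[hits <= n]  # starts beyond n are rotations of earlier hits
  sort(unique(hits))
}

#' Screen a genetic module for restriction-site availability
#'
#' Extracts the module fragment from its (circular) replicon — wrapping
#' through the origin when `start > end` — and scans every enzyme of the
#' panel. The extracted fragment is treated as linear: a module cloned
#' into a vector is interrupted at its ends, so a site that would only
#' form across the fragment boundary is not a cut. The enzymes partition
#' into `cutting` (with their positions on the fragment, 5'->3' from the
#' region start) and `non_cutting` — the latter being the sites still
#' available for the vector's MCS.
#'
#' @param record A `PlasmidRecord`.
#' @param region A [module_region()] on that record.
#' @param enzymes Data frame with `name` and `site` columns (default the
#'   13-enzyme MCS panel of [default_enzymes()]).
#' @return Object of class `ScreenResult`: `module`, `fragment_length`,
#'   `cutting` (named list of positions), `non_cutting` (character
#'   vector).
#' @export
screen_module <- function(record, region, enzymes = default_enzymes()) {
  stopifnot(inherits(record, "PlasmidRecord"))
  if (inherits(region, "ModuleRegion") &&
      !identical(region$plasmid_id, record$id)) {
    warning("region '", region$plasmid_id, "' screened against record '",
            record$id, "'")
  }
  frag <- extract_region(record, region$start, region$end)
  cutting <- list()
  non_cutting <- character(0)
  for (i in seq_len(nrow(enzymes))) {
    pos <- scan_sites(frag, enzymes$site[i], circular = FALSE)
    if (length(pos) > 0L) {
      cutting[[enzymes$name[i]]] <- pos
    } else {
      non_cutting <- c(non_cutting, enzymes$name[i])
    }
  }
  structure(list(module = region, fragment_length = nchar(frag),
                 cutting = cutting, non_cutting = non_cutting),
            class = "ScreenResult")
}

#' @export
print.ScreenResult <- function(x, ...) {
  cat(sprintf("ScreenResult: %s %d-%d (%d bp), %d cutting / %d available\n",
              x$module$label, x$module$start, x$module$end,
              x$fragment_length, length(x$cutting), length(x$non_cutting)))
  if (length(x$non_cutting)) {
    cat("  not cutting:", paste(x$non_cutting, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tabulate screen results in availability-table form
#'
#' One row per screened module: coordinates, the non-cutting enzyme list,
#' and counts — the layout of a restriction-availability table for vector
#' design.
#'
#' @param results List of `ScreenResult`.
#' @return Data frame with columns `plasmid`, `label`, `start`, `end`,
#'   `n_enzymes`, `n_available`, `non_cutting`.
#' @export
screen_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(plasmid = r$module$plasmid_id, label = r$module$label,
               start = r$module$start, end = r$module$end,
               n_enzymes = length(r$cutting) + length(r$non_cutting),
               n_available = length(r$non_cutting),
               non_cutting = paste(sort(r$non_cutting), collapse = ", "),
               stringsAsFactors = FALSE)
  }))
}
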