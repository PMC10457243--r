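# Accessors for the packaged characterization tables of the Psychrobacter
# sp. ANT_H3 plasmids (deposited as GenBank MN657079-MN657089). The tables
# transcribe published summary data and serve as *inputs*: region
# coordinates for restriction screening, quoted iteron consensus strings
# for the degenerate-notation parser, and per-replicon size/GC/module
# summaries.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "plasmidnet")
  if (path == "") stop("packaged file not found: ", file)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Per-replicon summary of the ANT_H3 plasmids
#'
#' Size, GC content, gene count and predicted genetic modules of the 11
#' plasmids of *Psychrobacter* sp. ANT_H3 (GenBank MN657079-MN657089), as
#' published for the deposited records. Module labels: REP replication,
#' MOB mobilization, DPR DNA-protecting protein, GCV glycine cleavage,
#' SMR multidrug efflux transporter, RM restriction-modification, MSC
#' mechanosensitive channel, MRS multimer resolution system.
#'
#' @return Data frame: `plasmid`, `accession`, `size_bp`, `gc_percent`,
#'   `n_genes`, `modules` (semicolon-separated labels).
#' @export
ant_h3_summary <- function() .extdata("ant_h3_plasmids.tsv")

#' REP-module coordinates and restriction availability of ANT_H3 plasmids
#'
#' The tested REP-module spans (1-based inclusive; `start > end` runs
#' forward through the replicon origin) and the published set of
#' MCS-panel enzymes not cutting within each module.
#'
#' @return Data frame: `plasmid`, `accession`, `start`, `end`, `label`,
#'   `non_cutting` (semicolon-separated enzyme names).
#' @export
ant_h3_rep_regions <- function() .extdata("ant_h3_rep_regions.tsv")

#' Published iteron consensus strings of the ANT_H3 plasmids
#'
#' The quoted oriV iteron consensus of each Rep_3-type ANT_H3 plasmid in
#' degenerate (X/Y) notation: six 22-bp units, one imperfect 21-bp unit
#' (pA3H5) and one 20-bp unit (pA3H11). Parse with [parse_consensus()].
#'
#' @return Data frame: `plasmid`, `unit_group_bp`, `consensus`.
#' @export
ant_h3_iteron_consensi <- function() .extdata("ant_h3_iterons.tsv")
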