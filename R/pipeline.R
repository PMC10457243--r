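# End-to-end orchestration: classify proteins, detect iterons, screen
# restriction availability, build the similarity network, and summarize
# per replicon.

#' Run the full plasmidome characterization over a set of replicons
#'
#' Per replicon: size and GC summary; classification of every translated
#' CDS against the reference sets (when given); iteron detection upstream
#' of rep-like genes; restriction screening of module regions; and a
#' reciprocated protein-similarity network over all translated proteins.
#' Stage failures on an individual replicon are caught, logged into the
#' report, and do not abort the run.
#'
#' @param records List of [plasmid_record()] objects.
#' @param references Optional labeled reference data frame (`id`,
#'   `label`, `sequence`) for REP/MOB family classification.
#' @param enzymes Restriction panel (default [default_enzymes()]).
#' @param regions Optional data frame of module regions (`plasmid`,
#'   `start`, `end`, `label`); when absent, regions are inferred as each
#'   rep-like gene plus `flank` bp on both sides.
#' @param params List of thresholds: `evalue_max` (1e-10),
#'   `identity_min` (0.30), `coverage_min` (0.90), `classify_evalue`
#'   (1e-2), `window` (500), `flank` (300).
#' @return Object of class `ReplicondReport`: `replicons` (data frame:
#'   id, size_bp, gc_percent, n_genes, modules), `screen` (data frame),
#'   `iterons` (data frame), `network` (`SimilarityNetwork` or `NULL`),
#'   `classification` (data frame), `families`, `errors`, `provenance`.
#' @export
run_characterization <- function(records, references = NULL,
                                 enzymes = default_enzymes(),
                                 regions = NULL, params = list()) {
  stopifnot(length(records) >= 1L)
  p <- utils::modifyList(
    list(evalue_max = 1e-10, identity_min = 0.30, coverage_min = 0.90,
         classify_evalue = 1e-2, window = 500L, flank = 300L),
    params)
  errors <- character(0)
  note <- function(stage, id, e) {
    msg <- sprintf("[%s] %s: %s", stage, id, conditionMessage(e))
    errors <<- c(errors, msg)
    NULL
  }

  # --- per-replicon summary -------------------------------------------------
  rep_rows <- lapply(records, function(rec) {
    data.frame(id = rec$id, size_bp = rec$length,
               gc_percent = gc_content(rec$sequence),
               n_genes = nrow(rec$features),
               modules = "", stringsAsFactors = FALSE)
  })
  replicons <- do.call(rbind, rep_rows)

  # --- protein inventory and classification ---------------------------------
  prot_rows <- list()
  for (rec in records) {
    fts <- rec$features
    has_tr <- which(nzchar(fts$translation))
    for (i in has_tr) {
      prot_rows[[length(prot_rows) + 1L]] <- data.frame(
        id = if (nzchar(fts$locus_tag[i])) fts$locus_tag[i] else
          sprintf("%s_cds%d", rec$id, i),
        sequence = fts$translation[i], plasmid_id = rec$id,
        stringsAsFactors = FALSE)
    }
  }
  proteins <- NULL
  classification <- data.frame(protein_id = character(),
                               plasmid_id = character(),
                               family = character(), stringsAsFactors = FALSE)
  if (length(prot_rows) > 0L) {
    pr <- do.call(rbind, prot_rows)
    proteins <- protein_set(make.unique(pr$id), pr$sequence, pr$plasmid_id)
    if (!is.null(references)) {
      cls <- lapply(seq_len(nrow(proteins)), function(i) {
        res <- tryCatch(
          classify_protein(proteins[i, ], references,
                           evalue_max = p$classify_evalue),
          error = function(e) note("classify", proteins$id[i], e))
        data.frame(protein_id = proteins$id[i],
                   plasmid_id = proteins$plasmid_id[i],
                   family = if (is.null(res)) "unclassified" else res$label,
                   stringsAsFactors = FALSE)
      })
      classification <- do.call(rbind, cls)
    }
  }

  # --- iterons upstream of rep-like genes -----------------------------------
  iter_rows <- list()
  for (rec in records) {
    hit <- grep("rep", rec$features$product, ignore.case = TRUE)
    for (i in hit) {
      arrs <- tryCatch(
        detect_iterons(rec, rec$features[i, ], window = p$window),
        error = function(e) note("iterons", rec$id, e))
      for (a in arrs %||% list()) {
        iter_rows[[length(iter_rows) + 1L]] <- data.frame(
          plasmid = rec$id, start = a$copy_starts[1],
          unit_length = a$unit_length, copies = a$copy_count,
          consensus = render_consensus(a$consensus),
          mismatch_frac = a$mean_mismatch_frac, strand = a$strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  iterons <- if (length(iter_rows)) do.call(rbind, iter_rows) else
    data.frame(plasmid = character(), start = integer(),
               unit_length = integer(), copies = integer(),
               consensus = character(), mismatch_frac = numeric(),
               strand = character(), stringsAsFactors = FALSE)

  # --- restriction screen ---------------------------------------------------
  screens <- list()
  by_id <- setNames(records, vapply(records, `[[`, "", "id"))
  if (is.null(regions)) {
    regions <- .infer_regions(records, p$flank)
  }
  for (i in seq_len(nrow(regions %||% data.frame()))) {
    rec <- by_id[[regions$plasmid[i]]]
    if (is.null(rec)) next
    res <- tryCatch(
      screen_module(rec,
                    module_region(regions$plasmid[i], regions$start[i],
                                  regions$end[i],
                                  regions$label[i] %||% "other"),
                    enzymes),
      error = function(e) note("screen", regions$plasmid[i], e))
    if (!is.null(res)) screens[[length(screens) + 1L]] <- res
  }
  screen <- if (length(screens)) screen_table(screens) else NULL

  # --- similarity network ---------------------------------------------------
  network <- NULL
  if (!is.null(proteins) && nrow(proteins) >= 1L) {
    network <- tryCatch(
      build_network(proteins, p$evalue_max, p$identity_min, p$coverage_min),
      error = function(e) note("network", "all", e))
  }

  # --- module labels per replicon -------------------------------------------
  if (nrow(classification) > 0L) {
    lab <- vapply(replicons$id, function(id) {
      fams <- setdiff(unique(
        classification$family[classification$plasmid_id == id]),
        "unclassified")
      paste(sort(fams), collapse = ";")
    }, "")
    replicons$modules <- ifelse(nzchar(lab), lab, "unclassified")
  } else {
    replicons$modules <- "unclassified"
  }

  families <- count_families(network, classification)

  structure(list(
    replicons = replicons, screen = screen, iterons = iterons,
    network = network, classification = classification,
    families = families, errors = errors,
    provenance = list(
      n_records = length(records), params = p,
      tool = paste0("plasmidnet ",
                    as.character(utils::packageVersion("plasmidnet"))))),
    class = "ReplicondReport")
}

.infer_regions <- function(records, flank) {
  rows <- list()
  for (rec in records) {
    hit <- grep("rep", rec$features$product, ignore.case = TRUE)
    for (i in hit) {
      ft <- rec$features[i, ]
      s <- ft$start - flank; e <- ft$end + flank
      len <- rec$length
      if (rec$topology == "circular") {
        s <- ((s - 1L) %% len) + 1L
        e <- ((e - 1L) %% len) + 1L
      } else {
        s <- max(1L, s); e <- min(len, e)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        plasmid = rec$id, start = s, end = e, label = "REP",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Count plasmids per protein family
#'
#' Counts *plasmids*, not proteins: a plasmid appears once per family it
#' carries, so a composite replicon with two different replication
#' systems is counted in both families.
#'
#' @param net A `SimilarityNetwork` (used for its node metadata) or
#'   `NULL`.
#' @param labels Classification data frame (`protein_id`, `plasmid_id`,
#'   `family`), e.g. from [run_characterization()].
#' @return Data frame `family`, `n_plasmids`, sorted by decreasing count
#'   (empty when no labels).
#' @export
count_families <- function(net, labels) {
  if (is.null(labels) || nrow(labels) == 0L) {
    return(data.frame(family = character(), n_plasmids = integer(),
                      stringsAsFactors = FALSE))
  }
  keep <- labels$family != "unclassified"
  pairs <- unique(labels[keep, c("plasmid_id", "family")])
  if (nrow(pairs) == 0L) {
    return(data.frame(family = character(), n_plasmids = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(pairs$family)
  out <- data.frame(family = names(tab), n_plasmids = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$n_plasmids, out$family), , drop = FALSE]
}

#' @export
print.ReplicondReport <- function(x, ...) {
  cat(sprintf("ReplicondReport: %d replicon(s), %d-%d bp\n",
              nrow(x$replicons), min(x$replicons$size_bp),
              max(x$replicons$size_bp)))
  if (!is.null(x$network)) print(x$network)
  if (length(x$errors)) cat(length(x$errors), "stage error(s) logged\n")
  invisible(x)
}

#' Write a characterization report to TSV + JSON
#'
#' @param report A `ReplicondReport`.
#' @param dir Output directory (created if needed). Writes
#'   `report.tsv` (replicon summary), `screen.tsv`, `iterons.tsv`,
#'   `report.json` (everything machine-readable), and
#'   `network.graphml` when a network was built.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ReplicondReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$replicons, file.path(dir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(report$screen)) {
    write.table(report$screen, file.path(dir, "screen.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write.table(report$iterons, file.path(dir, "iterons.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(report$network)) {
    write_network(report$network, file.path(dir, "network.graphml"),
                  "graphml")
  }
  js <- list(replicons = report$replicons, screen = report$screen,
             iterons = report$iterons, families = report$families,
             errors = report$errors, provenance = report$provenance)
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
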