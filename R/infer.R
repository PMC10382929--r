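# Parsimony inference of inter-minichromosomal recombination events
# between an ancestral and a derived karyotype.
#
# Event taxonomy (one record per inferred donor->recipient transfer or
# in-place change):
#   merger               two ancestral minichromosomes' survivors end up
#                        co-resident on one derived minichromosome
#   translocation        a full gene (or adjacent run) moved away from its
#                        ancestral minichromosome
#   duplication_insert   an extra full copy inserted while the original is
#                        retained at its ancestral location
#   partial_duplication  a pseudo gene whose full-length namesake lives on
#                        another minichromosome
#   degeneration_in_place a pseudo gene sitting at the gene's ancestral
#                        location
#   deletion             an ancestral gene with no derived occurrence
#
# The location anchor of an event is the nearest downstream (reading
# direction) full, single-copy gene that is retained at its ancestral
# location; insertions at the cluster end anchor to "none".  Anchoring
# to retained originals (skipping pseudo genes and duplicate copies)
# makes the anchor a stable ancestral coordinate, so independent
# insertions at the head of the same ancestral cluster tally to the
# same location.

.EVENT_COLS <- c("type", "gene", "donor", "recipient",
                 "recipient_ancestral", "location_anchor", "n_genes")

empty_events <- function() {
  data.frame(type = character(), gene = character(), donor = character(),
             recipient = character(), recipient_ancestral = character(),
             location_anchor = character(), n_genes = integer(),
             stringsAsFactors = FALSE)
}

#' Infer recombination-derived events between two karyotypes
#'
#' Classifies every derived gene occurrence and every ancestral gene
#' against a [match_chromosomes()] correspondence, using the most
#' parsimonious single-transfer explanation per occurrence.  Maximal
#' adjacent runs of genes with a common donor are reported as one event
#' (one recombination transfer can carry a multi-gene run).
#'
#' @param ancestral,derived [karyotype()] objects.  The ancestor is a
#'   swappable input (typically an inferred MRCA karyotype fixture).
#' @return A data frame of event records with columns `type`, `gene`
#'   (gene name, or run names joined by `-`), `donor` (ancestral
#'   minichromosome label or `NA`), `recipient` (derived label or `NA`),
#'   `recipient_ancestral` (the recipient's matched ancestral label),
#'   `location_anchor` (gene name or `"none"`), `n_genes`.  The
#'   `accounting` attribute maps every ancestral full-gene occurrence to
#'   its fate (retained / translocated / degenerated / deleted).
#' @export
#' @examples
#' \dontrun{
#' infer_events(load_fixture("MRCA_Linognathus"), load_fixture("L_africanus"))
#' }
infer_events <- function(ancestral, derived) {
  stopifnot(inherits(ancestral, "karyotype"), inherits(derived, "karyotype"))
  anc_ix <- gene_index(ancestral)
  der_ix <- gene_index(derived)
  missing <- setdiff(der_ix$name, anc_ix$name)
  if (length(missing) > 0L) {
    stop("derived gene(s) absent from the ancestral karyotype: ",
         paste(missing, collapse = ", "))
  }

  matching <- match_chromosomes(ancestral, derived)
  primary_anc <- structure(matching$pairs$ancestral,
                           names = matching$pairs$derived)
  anc_sets <- lapply(names(derived$minichromosomes), function(d) {
    c(unname(primary_anc[d]),
      matching$mergers$ancestral[matching$mergers$into == d])
  })
  names(anc_sets) <- names(derived$minichromosomes)

  # pool of ancestral full-gene occurrences, consumed as they are
  # accounted for
  pool <- anc_ix[anc_ix$status == "full", , drop = FALSE]
  pool$fate <- NA_character_
  pool$consumed <- FALSE
  # ancestral pseudo occurrences: a derived pseudo matching one of these
  # in its ancestral context is simply retained, not an event
  ppool <- anc_ix[anc_ix$status == "pseudo", , drop = FALSE]
  ppool$consumed <- rep(FALSE, nrow(ppool))

  der_full <- der_ix[der_ix$status == "full", , drop = FALSE]
  der_full$class <- rep(NA_character_, nrow(der_full))
  der_full$donor <- rep(NA_character_, nrow(der_full))

  consume <- function(name, chroms) {
    # first unconsumed ancestral occurrence of `name`, restricted to
    # `chroms` when non-NULL; returns pool row index or 0
    hit <- which(!pool$consumed & pool$name == name &
                   (if (is.null(chroms)) TRUE else pool$chrom %in% chroms))
    if (length(hit) == 0L) 0L else hit[1L]
  }

  # pass 1: retained occurrences (present in their matched ancestral
  # context, merger partners included)
  for (r in seq_len(nrow(der_full))) {
    ctx <- anc_sets[[der_full$chrom[r]]]
    ctx <- ctx[!is.na(ctx)]
    if (length(ctx) == 0L) next
    i <- consume(der_full$name[r], ctx)
    if (i > 0L) {
      der_full$class[r] <- "retained"
      pool$consumed[i] <- TRUE
      pool$fate[i] <- "retained"
    }
  }

  # pass 2: remaining derived full occurrences are translocations (the
  # ancestral copy is unaccounted for elsewhere) or duplicate insertions
  # (every ancestral copy already retained)
  for (r in which(is.na(der_full$class))) {
    nm <- der_full$name[r]
    i <- consume(nm, NULL)
    if (i > 0L) {
      der_full$class[r] <- "translocation"
      der_full$donor[r] <- pool$chrom[i]
      pool$consumed[i] <- TRUE
      pool$fate[i] <- "translocated"
    } else {
      src <- which(pool$name == nm & pool$fate == "retained")
      if (length(src) == 0L) {
        stop("full gene '", nm,
             "' has no ancestral full-length copy to explain it")
      }
      der_full$class[r] <- "duplication_insert"
      der_full$donor[r] <- pool$chrom[src[1L]]
    }
  }

  # pseudo occurrences: degeneration in place vs partial duplication
  der_pseudo <- der_ix[der_ix$status == "pseudo", , drop = FALSE]
  der_pseudo$class <- rep(NA_character_, nrow(der_pseudo))
  der_pseudo$donor <- rep(NA_character_, nrow(der_pseudo))
  for (r in seq_len(nrow(der_pseudo))) {
    nm <- der_pseudo$name[r]
    ctx <- anc_sets[[der_pseudo$chrom[r]]]
    ctx <- ctx[!is.na(ctx)]
    if (length(ctx)) {
      j <- which(!ppool$consumed & ppool$name == nm & ppool$chrom %in% ctx)
      if (length(j) > 0L) {
        der_pseudo$class[r] <- "retained_pseudo"
        ppool$consumed[j[1L]] <- TRUE
        next
      }
    }
    i <- if (length(ctx)) consume(nm, ctx) else 0L
    if (i > 0L) {
      der_pseudo$class[r] <- "degeneration_in_place"
      pool$consumed[i] <- TRUE
      pool$fate[i] <- "degenerated"
    } else {
      src <- which(pool$name == nm)
      if (length(src) == 0L) {
        stop("pseudo gene 'p", nm,
             "' has no ancestral full-length namesake")
      }
      der_pseudo$class[r] <- "partial_duplication"
      der_pseudo$donor[r] <- pool$chrom[src[1L]]
    }
  }

  pool$fate[!pool$consumed] <- "deleted"

  occ <- rbind(der_full, der_pseudo)
  occ <- occ[order(match(occ$chrom, names(derived$minichromosomes)),
                   occ$position), , drop = FALSE]

  # anchors scan downstream for the nearest retained, full, single-copy
  # gene on the same derived minichromosome
  anchor_after <- function(chrom, pos) {
    cand <- occ[occ$chrom == chrom & occ$position > pos &
                  occ$status == "full" &
                  (is.na(occ$copy) | occ$copy < 2L) &
                  occ$class == "retained", , drop = FALSE]
    if (nrow(cand) == 0L) "none" else cand$name[order(cand$position)][1L]
  }

  events <- list()
  add_event <- function(type, gene, donor, recipient, anchor, n_genes = 1L) {
    events[[length(events) + 1L]] <<- data.frame(
      type = type, gene = gene, donor = donor, recipient = recipient,
      recipient_ancestral = if (!is.na(recipient) &&
                                recipient %in% names(primary_anc))
        unname(primary_anc[recipient]) else NA_character_,
      location_anchor = anchor, n_genes = as.integer(n_genes),
      stringsAsFactors = FALSE)
  }

  # mergers first: one event per absorbed ancestral minichromosome
  for (i in seq_len(nrow(matching$mergers))) {
    add_event("merger", NA_character_,
              matching$mergers$ancestral[i], matching$mergers$into[i],
              "none", n_genes = 0L)
  }

  # insertion-type occurrences, grouped into maximal adjacent runs with
  # a common donor
  run_types <- c("translocation", "duplication_insert",
                 "partial_duplication")
  for (d in names(derived$minichromosomes)) {
    rows <- occ[occ$chrom == d & occ$class %in% run_types, , drop = FALSE]
    if (nrow(rows) == 0L) next
    rows <- rows[order(rows$position), , drop = FALSE]
    run_id <- cumsum(c(TRUE, diff(rows$position) != 1L |
                         rows$class[-1L] != rows$class[-nrow(rows)] |
                         rows$donor[-1L] != rows$donor[-nrow(rows)]))
    for (g in split(seq_len(nrow(rows)), run_id)) {
      run <- rows[g, , drop = FALSE]
      add_event(run$class[1L], paste(run$name, collapse = "-"),
                run$donor[1L], d,
                anchor_after(d, max(run$position)),
                n_genes = nrow(run))
    }
  }

  # in-place degenerations
  dg <- occ[occ$class == "degeneration_in_place", , drop = FALSE]
  for (r in seq_len(nrow(dg))) {
    add_event("degeneration_in_place", dg$name[r], NA_character_,
              dg$chrom[r], anchor_after(dg$chrom[r], dg$position[r]))
  }

  # deletions: anchor at the nearest downstream ancestral gene that is
  # retained on the corresponding derived minichromosome
  matched_derived <- structure(matching$pairs$derived,
                               names = matching$pairs$ancestral)
  del <- pool[pool$fate == "deleted", , drop = FALSE]
  for (r in seq_len(nrow(del))) {
    a <- del$chrom[r]
    d <- if (a %in% names(matched_derived)) unname(matched_derived[a]) else
      NA_character_
    anchor <- "none"
    if (!is.na(d)) {
      downstream <- anc_ix[anc_ix$chrom == a &
                             anc_ix$position > del$position[r] &
                             anc_ix$status == "full", , drop = FALSE]
      downstream <- downstream[order(downstream$position), , drop = FALSE]
      for (nm in downstream$name) {
        hit <- occ[occ$chrom == d & occ$name == nm &
                     occ$class == "retained" & occ$status == "full" &
                     (is.na(occ$copy) | occ$copy < 2L), , drop = FALSE]
        if (nrow(hit) > 0L) { anchor <- nm; break }
      }
    }
    add_event("deletion", del$name[r], NA_character_, d, anchor)
  }

  out <- if (length(events)) do.call(rbind, events) else empty_events()
  rownames(out) <- NULL
  attr(out, "accounting") <- pool[, c("name", "chrom", "position", "fate")]
  attr(out, "classification") <-
    occ[, c("name", "chrom", "position", "status", "copy", "class",
            "donor")]
  out
}

#' Minimum number of recombination events at a location
#'
#' The parsimony lower bound on donor-to-recipient recombination events
#' needed to explain all inferred events anchored at a given location:
#' the number of distinct ancestral donor minichromosomes among them
#' (material arriving from one donor minichromosome can ride on a single
#' recombination event; distinct donors require distinct events).
#'
#' @param events An event data frame from [infer_events()], or several
#'   branches' events row-bound together (all inferred against the same
#'   ancestral karyotype).
#' @param location_anchor A canonical gene name.
#' @param ancestral The ancestral [karyotype()] the events refer to;
#'   donor labels are checked against it.
#' @return A non-negative integer.  Attribute `max_events` holds the
#'   number of donor-bearing events at the anchor (the upper bound), and
#'   attribute `ambiguous` is `TRUE` when distinct events share a donor
#'   minichromosome, so the true count may exceed the lower bound.
#' @export
min_recombination_events <- function(events, location_anchor, ancestral) {
  stopifnot(is.data.frame(events), inherits(ancestral, "karyotype"))
  if (!is.character(location_anchor) || length(location_anchor) != 1L ||
      !is_canonical_gene(location_anchor)) {
    stop("location_anchor must be a canonical gene name")
  }
  at <- events[!is.na(events$location_anchor) &
                 events$location_anchor == location_anchor &
                 !is.na(events$donor), , drop = FALSE]
  unknown <- setdiff(at$donor, names(ancestral$minichromosomes))
  if (length(unknown) > 0L) {
    warning("donor label(s) not present in the supplied ancestral ",
            "karyotype: ", paste(unknown, collapse = ", "))
  }
  donors <- unique(at$donor)
  structure(length(donors),
            max_events = nrow(at),
            ambiguous = nrow(at) > length(donors))
}

#' Tally recombination events per location across branches
#'
#' Counts located events (anchor not `"none"`) per location anchor and
#' per branch, and ranks locations by total count (descending, ties
#' broken lexicographically).  Locations with recurrent independent
#' events across branches are candidate recombination hotspots.
#'
#' @param branch_events A named list of event data frames from
#'   [infer_events()], one per branch.
#' @return An object of class `hotspot_tally`: a data frame with one row
#'   per anchor, one count column per branch, plus `total` and `rank`.
#' @export
hotspot_tally <- function(branch_events) {
  stopifnot(is.list(branch_events), length(branch_events) > 0L)
  if (is.null(names(branch_events)) || any(!nzchar(names(branch_events)))) {
    names(branch_events) <- paste0("branch", seq_along(branch_events))
  }
  located <- lapply(branch_events, function(ev) {
    ev[!is.na(ev$location_anchor) & ev$location_anchor != "none", ,
       drop = FALSE]
  })
  anchors <- sort(unique(unlist(lapply(located, `[[`, "location_anchor"))))
  counts <- vapply(located, function(ev) {
    vapply(anchors, function(a) sum(ev$location_anchor == a), integer(1L))
  }, integer(length(anchors)))
  counts <- matrix(counts, nrow = length(anchors),
                   dimnames = list(anchors, names(branch_events)))
  total <- rowSums(counts)
  ord <- order(-total, anchors)
  out <- data.frame(anchor = anchors, counts, total = as.integer(total),
                    check.names = FALSE, stringsAsFactors = FALSE)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("hotspot_tally", "data.frame")
  out
}

#' Write a hotspot tally as TSV
#'
#' @param tally A `hotspot_tally` from [hotspot_tally()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hotspot_tsv <- function(tally, path) {
  utils::write.table(as.data.frame(tally), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize an event list to JSON
#'
#' @param events An event data frame from [infer_events()].
#' @param path Optional output path.
#' @return JSON string, or `path` invisibly.
#' @export
events_to_json <- function(events, path = NULL) {
  js <- jsonlite::toJSON(events, dataframe = "rows", auto_unbox = TRUE,
                         na = "null", digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname events_to_json
#' @param json A JSON string or file path produced by `events_to_json`.
#' @export
events_from_json <- function(json) {
  out <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  if (length(out) == 0L) return(empty_events())
  out$n_genes <- as.integer(out$n_genes)
  out
}
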