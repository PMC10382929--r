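# Applying recombination events to a synthetic genome, with a
# ground-truth log that replays byte-identically, plus random event
# sampling for recovery simulations.

.TRUTH_COLS <- c(.EVENT_COLS, "insert_pos", "window_start", "window_len")

empty_truth_events <- function() {
  ev <- empty_events()
  ev$insert_pos <- integer()
  ev$window_start <- integer()
  ev$window_len <- integer()
  ev
}

# mutable working state: list of chromosome entries keyed by origin
# label (the label in the input karyotype, stable across edits)
.state_from_karyotype <- function(k) {
  state <- lapply(k$minichromosomes, function(m) {
    list(genes = m$genes, ncr_len = m$ncr_len_bp,
         ncr_seq = m$ncr_sequence, origin = m$label)
  })
  names(state) <- names(k$minichromosomes)
  state
}

.state_to_karyotype <- function(state, species) {
  chroms <- lapply(state, function(ch) {
    g <- ch$genes
    cl_len <- if (anyNA(g$length_bp)) NA_integer_ else sum(g$length_bp)
    ps_len <- if (anyNA(g$length_bp[g$status == "pseudo"])) NA_integer_ else
      sum(g$length_bp[g$status == "pseudo"])
    cl_seq <- if (anyNA(g$sequence)) NA_character_ else
      paste(g$sequence, collapse = "")
    minichromosome(
      g,
      cluster_len_bp = cl_len,
      ncr_len_bp = ch$ncr_len,
      total_len_bp = if (is.na(cl_len) || is.na(ch$ncr_len)) NA_integer_ else
        cl_len + ch$ncr_len,
      pseudo_len_bp = ps_len,
      ncr_sequence = ch$ncr_seq,
      cluster_sequence = cl_seq
    )
  })
  karyotype(unname(chroms), species = species)
}

.insert_rows <- function(genes, row, at) {
  at <- max(1L, min(at, nrow(genes) + 1L))
  if (at == 1L) rbind(row, genes)
  else if (at == nrow(genes) + 1L) rbind(genes, row)
  else rbind(genes[seq_len(at - 1L), ], row,
             genes[seq(at, nrow(genes)), ])
}

.apply_one_event <- function(state, ev) {
  need <- function(label, role) {
    if (is.na(label) || !label %in% names(state)) {
      stop("inapplicable event (", ev$type, " of ", ev$gene, "): ", role,
           " minichromosome '", label, "' not present")
    }
    label
  }
  full_row <- function(label, gene) {
    g <- state[[label]]$genes
    i <- which(g$name == gene & g$status == "full")
    if (length(i) == 0L) {
      stop("inapplicable event (", ev$type, "): no full copy of '", gene,
           "' on ", label)
    }
    i[1L]
  }
  type <- ev$type
  if (type == "merger") {
    a <- need(ev$recipient, "recipient"); b <- need(ev$donor, "donor")
    state[[a]]$genes <- rbind(state[[a]]$genes, state[[b]]$genes)
    state[[b]] <- NULL
  } else if (type == "translocation") {
    d <- need(ev$donor, "donor"); r <- need(ev$recipient, "recipient")
    genes <- strsplit(ev$gene, "-", fixed = TRUE)[[1L]]
    rows <- state[[d]]$genes[vapply(genes, full_row, integer(1L),
                                    label = d), , drop = FALSE]
    keep <- !(seq_len(nrow(state[[d]]$genes)) %in%
                vapply(genes, full_row, integer(1L), label = d))
    state[[d]]$genes <- state[[d]]$genes[keep, , drop = FALSE]
    if (nrow(state[[d]]$genes) == 0L) {
      stop("inapplicable event (translocation): would empty donor ", d)
    }
    state[[r]]$genes <- .insert_rows(state[[r]]$genes, rows, ev$insert_pos)
  } else if (type == "duplication_insert") {
    d <- need(ev$donor, "donor"); r <- need(ev$recipient, "recipient")
    row <- state[[d]]$genes[full_row(d, ev$gene), , drop = FALSE]
    copies <- unlist(lapply(state, function(ch) {
      ch$genes$copy[ch$genes$name == ev$gene]
    }))
    row$copy <- max(c(1L, copies), na.rm = TRUE) + 1L
    state[[r]]$genes <- .insert_rows(state[[r]]$genes, row, ev$insert_pos)
  } else if (type == "partial_duplication") {
    d <- need(ev$donor, "donor"); r <- need(ev$recipient, "recipient")
    src <- state[[d]]$genes[full_row(d, ev$gene), , drop = FALSE]
    len <- ev$window_len
    row <- src
    row$status <- "pseudo"
    row$orientation <- "forward"
    row$copy <- NA_integer_
    row$length_bp <- as.integer(len)
    row$sequence <- if (is.na(src$sequence)) NA_character_ else
      substr(src$sequence, ev$window_start, ev$window_start + len - 1L)
    # a same-name pseudo may already exist; tag the new one to keep
    # serialized labels unambiguous
    prior <- unlist(lapply(state, function(ch) {
      sum(ch$genes$name == ev$gene & ch$genes$status == "pseudo")
    }))
    if (sum(prior) > 0L) row$copy <- sum(prior) + 1L
    state[[r]]$genes <- .insert_rows(state[[r]]$genes, row, ev$insert_pos)
  } else if (type == "degeneration_in_place") {
    r <- need(ev$recipient, "recipient")
    i <- full_row(r, ev$gene)
    state[[r]]$genes$status[i] <- "pseudo"
  } else if (type == "deletion") {
    r <- need(ev$recipient, "recipient")
    i <- full_row(r, ev$gene)
    state[[r]]$genes <- state[[r]]$genes[-i, , drop = FALSE]
    if (nrow(state[[r]]$genes) == 0L) {
      stop("inapplicable event (deletion): would empty ", r)
    }
  } else {
    stop("unknown event type: ", type)
  }
  state
}

# sample one applicable random event against the current state;
# `used_genes`/`used_chroms` keep events independent so that inference
# can recover each one unambiguously
.sample_event <- function(state, used_genes, used_chroms,
                          types, window = c(150L, 450L)) {
  origins <- names(state)
  avail <- setdiff(origins, used_chroms)
  full_genes <- function(label) {
    g <- state[[label]]$genes
    g$name[g$status == "full" & !g$name %in% used_genes]
  }
  n_full <- function(label) sum(state[[label]]$genes$status == "full")
  pick_recipient <- function(donor, gene) {
    cand <- setdiff(avail, donor)
    cand <- cand[vapply(cand, function(r) {
      !gene %in% state[[r]]$genes$name
    }, logical(1L))]
    if (length(cand) == 0L) return(NA_character_)
    sample(cand, 1L)
  }
  for (type in sample(rep(types, length.out = max(length(types), 20L)))) {
    if (type == "merger") {
      if (length(avail) < 2L) next
      ab <- sample(avail, 2L)
      return(data.frame(type = "merger", gene = NA_character_,
                        donor = ab[2L], recipient = ab[1L],
                        recipient_ancestral = ab[1L],
                        location_anchor = NA_character_, n_genes = 0L,
                        insert_pos = NA_integer_,
                        window_start = NA_integer_,
                        window_len = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    if (type %in% c("translocation", "degeneration_in_place", "deletion")) {
      cand <- avail[vapply(avail, n_full, integer(1L)) >= 2L]
      cand <- cand[vapply(cand, function(d) length(full_genes(d)) > 0L,
                          logical(1L))]
      if (length(cand) == 0L) next
      d <- sample(cand, 1L)
      g <- sample(full_genes(d), 1L)
      if (type == "translocation") {
        r <- pick_recipient(d, g)
        if (is.na(r)) next
        pos <- sample.int(nrow(state[[r]]$genes) + 1L, 1L)
        return(data.frame(type = type, gene = g, donor = d, recipient = r,
                          recipient_ancestral = r,
                          location_anchor = NA_character_, n_genes = 1L,
                          insert_pos = pos, window_start = NA_integer_,
                          window_len = NA_integer_,
                          stringsAsFactors = FALSE))
      }
      return(data.frame(type = type, gene = g, donor = NA_character_,
                        recipient = d, recipient_ancestral = d,
                        location_anchor = NA_character_, n_genes = 1L,
                        insert_pos = NA_integer_,
                        window_start = NA_integer_,
                        window_len = NA_integer_, stringsAsFactors = FALSE))
    }
    if (type == "duplication_insert") {
      cand <- avail[vapply(avail, function(d) length(full_genes(d)) > 0L,
                           logical(1L))]
      if (length(cand) == 0L) next
      d <- sample(cand, 1L)
      g <- sample(full_genes(d), 1L)
      r <- pick_recipient(d, g)
      if (is.na(r)) next
      pos <- sample.int(nrow(state[[r]]$genes) + 1L, 1L)
      return(data.frame(type = type, gene = g, donor = d, recipient = r,
                        recipient_ancestral = r,
                        location_anchor = NA_character_, n_genes = 1L,
                        insert_pos = pos, window_start = NA_integer_,
                        window_len = NA_integer_, stringsAsFactors = FALSE))
    }
    if (type == "partial_duplication") {
      cand <- avail[vapply(avail, function(d) {
        g <- state[[d]]$genes
        any(g$status == "full" & !g$name %in% used_genes &
              !is.na(g$length_bp) & g$length_bp >= window[1L])
      }, logical(1L))]
      if (length(cand) == 0L) next
      d <- sample(cand, 1L)
      g_tab <- state[[d]]$genes
      ok <- g_tab$status == "full" & !g_tab$name %in% used_genes &
        !is.na(g_tab$length_bp) & g_tab$length_bp >= window[1L]
      g <- sample(g_tab$name[ok], 1L)
      glen <- g_tab$length_bp[g_tab$name == g & g_tab$status == "full"][1L]
      r <- pick_recipient(d, g)
      if (is.na(r)) next
      wl <- sample(seq(window[1L], min(window[2L], glen)), 1L)
      ws <- sample.int(glen - wl + 1L, 1L)
      pos <- sample.int(nrow(state[[r]]$genes) + 1L, 1L)
      return(data.frame(type = type, gene = g, donor = d, recipient = r,
                        recipient_ancestral = r,
                        location_anchor = NA_character_, n_genes = 1L,
                        insert_pos = pos, window_start = ws,
                        window_len = wl, stringsAsFactors = FALSE))
    }
  }
  NULL
}

#' Apply recombination events to a synthetic genome
#'
#' Applies an explicit event list, or samples `n_events` random events,
#' against a synthetic genome (or a bare karyotype), and returns the
#' derived genome together with a ground-truth log.  Duplicate
#' insertions copy the donor sequence verbatim, so gene copies are
#' sequence-identical; partial duplications copy a random internal
#' window of 150-450 bp of the donor gene (bracketing observed pseudo
#' gene sizes).  Replaying the returned log on the same input
#' reproduces the derived genome byte-identically, because every random
#' choice (insertion position, window coordinates) is recorded in the
#' log.
#'
#' @param genome A `synthetic_genome` from [generate_ancestral_genome()]
#'   or a [karyotype()].
#' @param events An explicit event data frame (the truth-log format;
#'   see Details) applied in row order, or `NULL` to sample randomly.
#' @param n_events Number of random events to sample when `events` is
#'   `NULL`; either a single count or a named vector of counts per
#'   event type.
#' @param types Event types eligible in random mode.
#' @param window Length-2 range of partial-duplication window sizes.
#' @param seed Integer seed for random mode.
#' @return A list with `genome` (same class as the input) and `truth`
#'   (class `truth_log`: `events` data frame, `seed`, `params`).
#' @export
apply_events <- function(genome, events = NULL, n_events = NULL,
                         types = c("translocation", "duplication_insert",
                                   "partial_duplication",
                                   "degeneration_in_place", "deletion",
                                   "merger"),
                         window = c(150L, 450L), seed = 1L) {
  is_sg <- inherits(genome, "synthetic_genome")
  k <- if (is_sg) genome$karyotype else genome
  stopifnot(inherits(k, "karyotype"))
  state <- .state_from_karyotype(k)

  if (is.null(events)) {
    if (is.null(n_events)) stop("give either `events` or `n_events`")
    type_seq <- if (!is.null(names(n_events))) {
      rep(names(n_events), times = n_events)
    } else NULL
    events <- with_seed(seed, {
      total <- if (is.null(type_seq)) as.integer(n_events) else
        length(type_seq)
      if (!is.null(type_seq)) type_seq <- sample(type_seq)
      used_genes <- character(); used_chroms <- character()
      out <- list()
      for (i in seq_len(total)) {
        ev <- .sample_event(state, used_genes, used_chroms,
                            types = if (is.null(type_seq)) types else
                              type_seq[i],
                            window = window)
        if (is.null(ev)) break
        state <- .apply_one_event(state, ev)
        used_genes <- c(used_genes, ev$gene[!is.na(ev$gene)])
        used_chroms <- c(used_chroms, ev$donor[!is.na(ev$donor)],
                         ev$recipient[!is.na(ev$recipient)])
        out[[i]] <- ev
      }
      if (length(out)) do.call(rbind, out) else empty_truth_events()
    })
    # state was mutated inside with_seed's evaluation environment only
    # when sampling; re-apply deterministically below on a fresh state
    state <- .state_from_karyotype(k)
  } else {
    events <- as.data.frame(events, stringsAsFactors = FALSE)
    for (col in .TRUTH_COLS) {
      if (!col %in% names(events)) events[[col]] <- NA
    }
  }

  for (i in seq_len(nrow(events))) {
    state <- .apply_one_event(state, events[i, , drop = FALSE])
  }
  derived_k <- .state_to_karyotype(state, paste0(k$species, " (derived)"))

  derived <- if (is_sg) {
    structure(list(karyotype = derived_k,
                   ncr_sequence = genome$ncr_sequence,
                   motifs = genome$motifs, seed = genome$seed,
                   params = genome$params),
              class = "synthetic_genome")
  } else derived_k

  truth <- structure(list(events = events, seed = seed,
                          params = list(window = window)),
                     class = "truth_log")
  list(genome = derived, truth = truth)
}

#' @export
print.truth_log <- function(x, ...) {
  cat(sprintf("<truth log> %d events (seed %s)\n", nrow(x$events),
              format(x$seed)))
  if (nrow(x$events)) {
    print(x$events[, c("type", "gene", "donor", "recipient")])
  }
  invisible(x)
}

#' Compare an inferred event list with a truth log
#'
#' Canonicalizes both sides to the multiset of
#' `(type, gene, donor, recipient ancestral label)` tuples (merger
#' donor/recipient pairs are order-insensitive) and tests equality.
#' Used by the event-recovery simulations.
#'
#' @param truth A truth-log event data frame (or `truth_log`).
#' @param inferred An event data frame from [infer_events()].
#' @return `TRUE` when the multisets agree.
#' @export
events_match <- function(truth, inferred) {
  if (inherits(truth, "truth_log")) truth <- truth$events
  canon <- function(ev) {
    if (nrow(ev) == 0L) return(character())
    keys <- vapply(seq_len(nrow(ev)), function(i) {
      if (ev$type[i] == "merger") {
        pair <- sort(c(ev$donor[i], ev$recipient_ancestral[i]))
        paste("merger", pair[1L], pair[2L], sep = "|")
      } else {
        paste(ev$type[i], ev$gene[i],
              ifelse(is.na(ev$donor[i]), ".", ev$donor[i]),
              ifelse(is.na(ev$recipient_ancestral[i]), ".",
                     ev$recipient_ancestral[i]), sep = "|")
      }
    }, character(1L))
    sort(keys)
  }
  identical(canon(truth), canon(inferred))
}
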