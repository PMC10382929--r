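# Pairwise karyotype comparison: minichromosome equality,
# identical-minichromosome detection between two karyotypes, and the
# ancestral<->derived chromosome correspondence used by event inference.

#' Test two minichromosomes for equal gene content and arrangement
#'
#' Two minichromosomes are equal when their NCR-anchored ordered gene
#' lists are identical in name and orientation.  Sizes, sequences and
#' duplicate copy tags are ignored.  By default pseudo genes are also
#' ignored, which reproduces the published convention: a minichromosome
#' differing only by a degenerate pseudo copy still has "the same gene
#' content and gene arrangement".  Set `ignore_pseudo = FALSE` for a
#' strict comparison that includes pseudo genes (name + status +
#' orientation).
#'
#' @param m1,m2 [minichromosome()] objects.
#' @param ignore_pseudo Drop pseudo genes before comparing (default
#'   `TRUE`).
#' @return `TRUE` or `FALSE`.
#' @export
chromosomes_equal <- function(m1, m2, ignore_pseudo = TRUE) {
  stopifnot(inherits(m1, "minichromosome"), inherits(m2, "minichromosome"))
  key <- function(m) {
    g <- m$genes
    if (ignore_pseudo) g <- g[g$status == "full", , drop = FALSE]
    paste(g$name, g$status, g$orientation, sep = "/", collapse = "|")
  }
  identical(key(m1), key(m2))
}

# distinct shared full-gene names between two minichromosomes; duplicate
# copies contribute at most one unit per gene name, pseudo genes are
# excluded from the score
.full_gene_set <- function(m) unique(m$genes$name[m$genes$status == "full"])

overlap_score <- function(m1, m2) {
  length(intersect(.full_gene_set(m1), .full_gene_set(m2)))
}

# Greedy maximum-shared-gene matching between two sets of
# minichromosomes.  Repeatedly picks the pair with the largest overlap
# (>= 1), ties broken lexicographically by (label1, label2).  Returns a
# data.frame(label1, label2, overlap).
greedy_matching <- function(chroms1, chroms2) {
  l1 <- names(chroms1); l2 <- names(chroms2)
  if (length(l1) == 0L || length(l2) == 0L) {
    return(data.frame(label1 = character(), label2 = character(),
                      overlap = integer(), stringsAsFactors = FALSE))
  }
  ov <- outer(seq_along(l1), seq_along(l2),
              Vectorize(function(i, j) overlap_score(chroms1[[i]],
                                                     chroms2[[j]])))
  pairs <- list()
  free1 <- rep(TRUE, length(l1)); free2 <- rep(TRUE, length(l2))
  repeat {
    ov_active <- ov
    ov_active[!free1, ] <- -1L
    ov_active[, !free2] <- -1L
    best <- max(ov_active)
    if (best < 1L) break
    cand <- which(ov_active == best, arr.ind = TRUE)
    ord <- order(l1[cand[, 1L]], l2[cand[, 2L]])
    i <- cand[ord[1L], 1L]; j <- cand[ord[1L], 2L]
    pairs[[length(pairs) + 1L]] <- data.frame(
      label1 = l1[i], label2 = l2[j], overlap = as.integer(best),
      stringsAsFactors = FALSE)
    free1[i] <- FALSE; free2[j] <- FALSE
  }
  if (length(pairs) == 0L) {
    return(data.frame(label1 = character(), label2 = character(),
                      overlap = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, pairs)
}

#' Compare two karyotypes minichromosome by minichromosome
#'
#' Matches minichromosomes between the two karyotypes by greedy maximum
#' shared-full-gene overlap (ties broken lexicographically by label),
#' then tests each matched pair for equality with [chromosomes_equal()].
#' The result partitions every minichromosome into `shared` (matched and
#' equal), `differing` (matched but unequal, with per-position diffs) or
#' `unmatched`.
#'
#' @param k1,k2 [karyotype()] objects.
#' @param ignore_pseudo Passed to [chromosomes_equal()].
#' @return An object of class `comparison_report` with elements
#'   `shared` (data frame: `label1`, `label2`), `differing` (data frame:
#'   `label1`, `label2`, `diff`), `unmatched1`, `unmatched2` (character
#'   vectors of labels).
#' @export
#' @examples
#' \dontrun{
#' rep <- compare_karyotypes(load_fixture("L_vituli"),
#'                           load_fixture("L_africanus"))
#' nrow(rep$shared)  # 7
#' }
compare_karyotypes <- function(k1, k2, ignore_pseudo = TRUE) {
  stopifnot(inherits(k1, "karyotype"), inherits(k2, "karyotype"))
  m <- greedy_matching(k1$minichromosomes, k2$minichromosomes)
  eq <- vapply(seq_len(nrow(m)), function(i) {
    chromosomes_equal(k1$minichromosomes[[m$label1[i]]],
                      k2$minichromosomes[[m$label2[i]]],
                      ignore_pseudo = ignore_pseudo)
  }, logical(1L))
  shared <- m[eq, c("label1", "label2"), drop = FALSE]
  diff_rows <- m[!eq, , drop = FALSE]
  differing <- data.frame(
    label1 = diff_rows$label1, label2 = diff_rows$label2,
    diff = vapply(seq_len(nrow(diff_rows)), function(i) {
      describe_diff(k1$minichromosomes[[diff_rows$label1[i]]],
                    k2$minichromosomes[[diff_rows$label2[i]]])
    }, character(1L)),
    stringsAsFactors = FALSE
  )
  rownames(shared) <- rownames(differing) <- NULL
  structure(list(
    species1 = k1$species, species2 = k2$species,
    shared = shared, differing = differing,
    unmatched1 = setdiff(names(k1$minichromosomes), m$label1),
    unmatched2 = setdiff(names(k2$minichromosomes), m$label2)
  ), class = "comparison_report")
}

# terse per-position description of how two matched minichromosomes
# differ (token-level edit summary)
describe_diff <- function(m1, m2) {
  t1 <- strsplit(m1$label, "-", fixed = TRUE)[[1L]]
  t2 <- strsplit(m2$label, "-", fixed = TRUE)[[1L]]
  only1 <- setdiff(t1, t2); only2 <- setdiff(t2, t1)
  parts <- character()
  if (length(only1)) parts <- c(parts, paste0("only in first: ",
                                              paste(only1, collapse = ",")))
  if (length(only2)) parts <- c(parts, paste0("only in second: ",
                                              paste(only2, collapse = ",")))
  if (length(parts) == 0L) parts <- "same tokens, different arrangement"
  paste(parts, collapse = "; ")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison> %s vs %s\n", x$species1, x$species2))
  cat(sprintf("  shared: %d, differing: %d, unmatched: %d + %d\n",
              nrow(x$shared), nrow(x$differing),
              length(x$unmatched1), length(x$unmatched2)))
  invisible(x)
}

#' Write a comparison report as TSV
#'
#' One row per minichromosome pair (or unmatched minichromosome) with a
#' `category` column (`shared`/`differing`/`unmatched`).
#'
#' @param report A `comparison_report` from [compare_karyotypes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_tsv <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  rows <- rbind(
    if (nrow(report$shared))
      data.frame(label1 = report$shared$label1, label2 = report$shared$label2,
                 category = "shared", diff = "", stringsAsFactors = FALSE),
    if (nrow(report$differing))
      data.frame(label1 = report$differing$label1,
                 label2 = report$differing$label2,
                 category = "differing", diff = report$differing$diff,
                 stringsAsFactors = FALSE),
    if (length(report$unmatched1))
      data.frame(label1 = report$unmatched1, label2 = "",
                 category = "unmatched", diff = "", stringsAsFactors = FALSE),
    if (length(report$unmatched2))
      data.frame(label1 = "", label2 = report$unmatched2,
                 category = "unmatched", diff = "", stringsAsFactors = FALSE)
  )
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Match minichromosomes of a derived karyotype to an ancestor
#'
#' Produces the chromosome correspondence used by event inference:
#' pairs are chosen greedily by descending shared-full-gene overlap
#' (duplicate copies count once per name; pseudo genes are excluded from
#' the score), ties broken lexicographically.  An unmatched ancestral
#' minichromosome whose full genes survive on an already-matched derived
#' minichromosome (and nowhere else) is flagged as a merger candidate:
#' two ancestral minichromosomes merged into one derived minichromosome.
#'
#' @param ancestral,derived [karyotype()] objects.
#' @return An object of class `chromosome_matching` with elements
#'   `pairs` (data frame: `ancestral`, `derived`, `overlap`, `merged`),
#'   `mergers` (data frame: `ancestral`, `into`), `unmatched_ancestral`,
#'   `unmatched_derived`.
#' @export
match_chromosomes <- function(ancestral, derived) {
  stopifnot(inherits(ancestral, "karyotype"), inherits(derived, "karyotype"))
  m <- greedy_matching(ancestral$minichromosomes, derived$minichromosomes)
  names(m) <- c("ancestral", "derived", "overlap")
  un_anc <- setdiff(names(ancestral$minichromosomes), m$ancestral)
  un_der <- setdiff(names(derived$minichromosomes), m$derived)
  mergers <- list()
  for (a in un_anc) {
    genes_a <- .full_gene_set(ancestral$minichromosomes[[a]])
    ov <- vapply(m$derived, function(d) {
      overlap_score(ancestral$minichromosomes[[a]],
                    derived$minichromosomes[[d]])
    }, integer(1L))
    if (length(ov) == 0L || max(ov) < 1L) next
    best <- m$derived[order(-ov, m$derived)][1L]
    # survivors only on `best`: the ancestral genes occur full nowhere
    # else in the derived karyotype
    elsewhere <- vapply(setdiff(names(derived$minichromosomes), best),
                        function(d) {
                          length(intersect(
                            genes_a,
                            .full_gene_set(derived$minichromosomes[[d]]))) > 0L
                        }, logical(1L))
    if (!any(elsewhere)) {
      mergers[[length(mergers) + 1L]] <-
        data.frame(ancestral = a, into = best, stringsAsFactors = FALSE)
    }
  }
  mergers <- if (length(mergers)) do.call(rbind, mergers) else
    data.frame(ancestral = character(), into = character(),
               stringsAsFactors = FALSE)
  m$merged <- m$derived %in% mergers$into
  structure(list(
    pairs = m, mergers = mergers,
    unmatched_ancestral = setdiff(un_anc, mergers$ancestral),
    unmatched_derived = un_der
  ), class = "chromosome_matching")
}

#' @export
print.chromosome_matching <- function(x, ...) {
  cat("<chromosome matching>\n")
  for (i in seq_len(nrow(x$pairs))) {
    cat(sprintf("  %s -> %s (overlap %d)%s\n", x$pairs$ancestral[i],
                x$pairs$derived[i], x$pairs$overlap[i],
                if (x$pairs$merged[i]) " [merger]" else ""))
  }
  for (i in seq_len(nrow(x$mergers))) {
    cat(sprintf("  %s => merged into %s\n", x$mergers$ancestral[i],
                x$mergers$into[i]))
  }
  invisible(x)
}

#' Serialize a chromosome matching to JSON
#'
#' @param matching A `chromosome_matching` from [match_chromosomes()].
#' @param path Optional output path.
#' @return JSON string, or `path` invisibly.
#' @export
matching_to_json <- function(matching, path = NULL) {
  stopifnot(inherits(matching, "chromosome_matching"))
  js <- jsonlite::toJSON(unclass(matching), auto_unbox = TRUE,
                         na = "null", digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
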