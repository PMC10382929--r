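# Karyotype data model
#
# A fragmented mitochondrial genome is modelled as a set of circular
# minichromosomes.  Each minichromosome carries one cluster of genes and
# one large non-coding region (NCR).  Gene order is read in the majority
# transcription direction starting immediately downstream of the NCR,
# which linearizes the circle at a natural origin and makes circular
# comparison a plain list comparison.
#
# Compact grammar (one minichromosome per line):
#   token  = ["~"] ["p"] NAME ["#" COPY]
#   line   = token ("-" token)*  ["\t" total ["\t" cluster ["\t" ncr ["\t" pseudo]]]]
# "~" marks reverse orientation relative to the majority transcription
# direction, "p" marks a pseudo gene, and "#2", "#3", ... tag second and
# later copies of a duplicated gene (copies compare equal by name).
# Size columns are in bp.  Lines starting with "#" and blank lines are
# ignored.

# ---- constructors -----------------------------------------------------

# genes: data.frame(name, kind, status, orientation, copy, length_bp, sequence)
new_gene_table <- function(name, status = "full", orientation = "forward",
                           copy = NA_integer_, length_bp = NA_integer_,
                           sequence = NA_character_) {
  n <- length(name)
  df <- data.frame(
    name        = name,
    kind        = gene_kind(name),
    status      = rep_len(status, n),
    orientation = rep_len(orientation, n),
    copy        = as.integer(rep_len(copy, n)),
    length_bp   = as.integer(rep_len(length_bp, n)),
    sequence    = rep_len(as.character(sequence), n),
    stringsAsFactors = FALSE
  )
  bad <- !df$status %in% c("full", "pseudo")
  if (any(bad)) stop("invalid gene status: ", df$status[bad][1L])
  bad <- !df$orientation %in% c("forward", "reverse")
  if (any(bad)) stop("invalid orientation: ", df$orientation[bad][1L])
  ok <- is.na(df$sequence) | is.na(df$length_bp) |
    nchar(df$sequence) == df$length_bp
  if (!all(ok)) stop("sequence length disagrees with length_bp for gene ",
                     df$name[!ok][1L])
  df
}

#' Construct a minichromosome
#'
#' @param genes A gene table as produced by the parser: a data frame with
#'   columns `name`, `kind`, `status` (`"full"`/`"pseudo"`), `orientation`
#'   (`"forward"`/`"reverse"`), `copy` (integer copy tag or `NA`),
#'   `length_bp`, `sequence`.  Gene order is the NCR-anchored reading
#'   order.
#' @param total_len_bp,cluster_len_bp,ncr_len_bp,pseudo_len_bp Optional
#'   sizes in bp.  Sizes are carried verbatim; additivity
#'   (`total = cluster + ncr`) is only asserted for synthetic genomes,
#'   because published size tables contain small unexplained differences
#'   (gene overlap accounting).
#' @param ncr_sequence,cluster_sequence Optional nucleotide sequences.
#' @return An object of class `minichromosome`.  Its `label` is the
#'   serialized gene-cluster string.
#' @export
minichromosome <- function(genes, total_len_bp = NA, cluster_len_bp = NA,
                           ncr_len_bp = NA, pseudo_len_bp = NA,
                           ncr_sequence = NA_character_,
                           cluster_sequence = NA_character_) {
  if (!is.data.frame(genes) || nrow(genes) == 0L) {
    stop("a minichromosome must carry at least one gene")
  }
  m <- structure(
    list(
      genes            = genes,
      total_len_bp     = as.integer(total_len_bp),
      cluster_len_bp   = as.integer(cluster_len_bp),
      ncr_len_bp       = as.integer(ncr_len_bp),
      pseudo_len_bp    = as.integer(pseudo_len_bp),
      ncr_sequence     = as.character(ncr_sequence),
      cluster_sequence = as.character(cluster_sequence)
    ),
    class = "minichromosome"
  )
  m$label <- chrom_label(m)
  m
}

# serialized gene-cluster string, used as the minichromosome label
chrom_label <- function(m) {
  g <- m$genes
  tok <- paste0(
    ifelse(g$orientation == "reverse", "~", ""),
    ifelse(g$status == "pseudo", "p", ""),
    g$name,
    ifelse(!is.na(g$copy) & g$copy >= 2L, paste0("#", g$copy), "")
  )
  paste(tok, collapse = "-")
}

#' Construct a karyotype
#'
#' @param minichromosomes A list of [minichromosome()] objects.
#' @param species Species (or ancestral-state) name.
#' @return An object of class `karyotype`; minichromosomes are kept in
#'   the supplied order and indexed by their labels.
#' @export
karyotype <- function(minichromosomes, species = "unknown") {
  stopifnot(is.list(minichromosomes), length(minichromosomes) > 0L)
  labels <- vapply(minichromosomes, function(m) m$label, character(1L))
  if (anyDuplicated(labels)) {
    stop("duplicate minichromosome labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  names(minichromosomes) <- labels
  structure(list(species = species, minichromosomes = minichromosomes),
            class = "karyotype")
}

# ---- grammar: parse / serialize --------------------------------------

parse_gene_token <- function(token, line_no) {
  raw <- token
  orientation <- "forward"
  if (startsWith(token, "~")) {
    orientation <- "reverse"
    token <- substring(token, 2L)
  }
  copy <- NA_integer_
  tag <- regmatches(token, regexpr("#[0-9]+$", token))
  if (length(tag) == 1L && nzchar(tag)) {
    copy <- as.integer(substring(tag, 2L))
    token <- sub("#[0-9]+$", "", token)
  }
  status <- "full"
  name <- token
  if (!is_canonical_gene(name)) {
    if (startsWith(token, "p") && is_canonical_gene(substring(token, 2L))) {
      status <- "pseudo"
      name <- substring(token, 2L)
    } else {
      stop(sprintf("line %d: unknown gene token '%s'", line_no, raw))
    }
  }
  list(name = name, status = status, orientation = orientation, copy = copy)
}

#' Parse a karyotype grammar document
#'
#' Reads the compact one-minichromosome-per-line gene-order notation
#' (see the package vignette).  Tokens are canonical gene names with an
#' optional `~` prefix (reverse orientation), `p` prefix (pseudo gene)
#' and `#n` suffix (duplicate copy tag).  Up to four optional
#' tab-separated size columns follow the gene string: total, gene
#' cluster, large NCR, and pseudo-gene sizes in bp.
#'
#' @param text A single string (possibly with embedded newlines) or a
#'   character vector of lines.
#' @param species Species name attached to the result.
#' @return A [karyotype()] whose serialization with
#'   [serialize_karyotype()] round-trips byte-identically.
#' @export
#' @examples
#' k <- parse_karyotype("I-cox1\nK-nad4", species = "toy")
#' length(k$minichromosomes)
parse_karyotype <- function(text, species = "unknown") {
  stopifnot(is.character(text))
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty karyotype document")
  chroms <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    line_no <- idx[i]
    fields <- strsplit(lines[line_no], "\t", fixed = TRUE)[[1L]]
    tokens <- strsplit(fields[1L], "-", fixed = TRUE)[[1L]]
    if (length(tokens) == 0L || !all(nzchar(tokens))) {
      stop(sprintf("line %d: malformed gene string '%s'", line_no, fields[1L]))
    }
    parsed <- lapply(tokens, parse_gene_token, line_no = line_no)
    genes <- new_gene_table(
      name        = vapply(parsed, `[[`, character(1L), "name"),
      status      = vapply(parsed, `[[`, character(1L), "status"),
      orientation = vapply(parsed, `[[`, character(1L), "orientation"),
      copy        = vapply(parsed, `[[`, integer(1L), "copy")
    )
    sizes <- rep(NA_integer_, 4L)
    extra <- fields[-1L]
    if (length(extra) > 4L) {
      stop(sprintf("line %d: more than four size columns", line_no))
    }
    if (length(extra) > 0L) {
      num <- suppressWarnings(as.integer(extra))
      if (any(!is.na(extra) & nzchar(extra) & is.na(num))) {
        stop(sprintf("line %d: non-numeric size column", line_no))
      }
      sizes[seq_along(num)] <- num
    }
    chroms[[i]] <- minichromosome(
      genes,
      total_len_bp = sizes[1L], cluster_len_bp = sizes[2L],
      ncr_len_bp = sizes[3L], pseudo_len_bp = sizes[4L]
    )
  }
  karyotype(chroms, species = species)
}

#' Serialize a karyotype to the grammar text
#'
#' Inverse of [parse_karyotype()]: emits one line per minichromosome,
#' with size columns when sizes are present.
#'
#' @param k A [karyotype()].
#' @return A single string (lines joined by newlines, no trailing
#'   newline).
#' @export
serialize_karyotype <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  lines <- vapply(k$minichromosomes, function(m) {
    sizes <- c(m$total_len_bp, m$cluster_len_bp, m$ncr_len_bp,
               m$pseudo_len_bp)
    last <- if (any(!is.na(sizes))) max(which(!is.na(sizes))) else 0L
    if (last == 0L) return(m$label)
    cols <- ifelse(is.na(sizes[seq_len(last)]), "",
                   as.character(sizes[seq_len(last)]))
    paste(c(m$label, cols), collapse = "\t")
  }, character(1L))
  paste(lines, collapse = "\n")
}

#' Read a karyotype grammar file
#'
#' @param path Path to a UTF-8 grammar file.
#' @inheritParams parse_karyotype
#' @return A [karyotype()].
#' @export
read_karyotype <- function(path, species = "unknown") {
  parse_karyotype(readLines(path, warn = FALSE), species = species)
}

#' Write a karyotype grammar file
#'
#' @param k A [karyotype()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_karyotype <- function(k, path) {
  writeLines(serialize_karyotype(k), path)
  invisible(path)
}

# ---- index and summary ------------------------------------------------

#' Index gene occurrences of a karyotype
#'
#' @param k A [karyotype()].
#' @return A data frame with one row per gene occurrence: `name`,
#'   `chrom` (minichromosome label), `position` (1-based within the
#'   NCR-anchored gene order), `status`, `orientation`, `copy`.
#' @export
gene_index <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  out <- lapply(k$minichromosomes, function(m) {
    g <- m$genes
    data.frame(name = g$name, chrom = m$label,
               position = seq_len(nrow(g)), status = g$status,
               orientation = g$orientation, copy = g$copy,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# sum that propagates absence: all-NA -> NA, any-NA -> NA (never zero)
.sum_or_absent <- function(x) {
  if (any(is.na(x))) NA_integer_ else as.integer(sum(x))
}

#' Summarize a karyotype
#'
#' Roll-up statistics of a karyotype: minichromosome count, distinct
#' full genes, duplicate full copies (occurrences beyond the first per
#' gene name), pseudo genes, size column totals, and the range of
#' per-minichromosome full-gene counts.  Missing sizes propagate to
#' `NA` totals (absent, never zero).
#'
#' @param k A [karyotype()].
#' @return An object of class `karyotype_summary` (a list).
#' @export
summarize_karyotype <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  ix <- gene_index(k)
  full <- ix[ix$status == "full", ]
  dup <- sum(pmax(table(full$name) - 1L, 0L))
  counts <- vapply(k$minichromosomes,
                   function(m) sum(m$genes$status == "full"), integer(1L))
  sizes <- function(field) {
    vapply(k$minichromosomes, function(m) m[[field]] %||% NA_integer_,
           integer(1L))
  }
  structure(list(
    species               = k$species,
    n_minichromosomes     = length(k$minichromosomes),
    n_distinct_full_genes = length(unique(full$name)),
    n_duplicate_genes     = as.integer(dup),
    n_pseudo_genes        = sum(ix$status == "pseudo"),
    total_len_bp          = .sum_or_absent(sizes("total_len_bp")),
    cluster_len_bp        = .sum_or_absent(sizes("cluster_len_bp")),
    ncr_len_bp            = .sum_or_absent(sizes("ncr_len_bp")),
    pseudo_len_bp         = .sum_or_absent(sizes("pseudo_len_bp")),
    genes_per_chrom_min   = min(counts),
    genes_per_chrom_max   = max(counts)
  ), class = "karyotype_summary")
}

# ---- packaged fixtures ------------------------------------------------

.FIXTURE_SPECIES <- c(
  L_vituli         = "Linognathus vituli",
  L_africanus      = "Linognathus africanus",
  MRCA_Anoplura    = "MRCA of sucking lice (Anoplura)",
  MRCA_Linognathus = "MRCA of Linognathus spp."
)

#' Load a packaged karyotype fixture
#'
#' The two species karyotypes are transcribed verbatim from the published
#' minichromosome tables and genome maps of the cattle louse
#' *Linognathus vituli* and the goat louse *L. africanus*.  The two
#' ancestral (MRCA) karyotypes are transcribed from the published
#' inferred ancestral minichromosome organizations of sucking lice and
#' of *Linognathus*; all algorithms treat them as swappable inputs, not
#' constants.
#'
#' @param name One of `"L_vituli"`, `"L_africanus"`, `"MRCA_Anoplura"`,
#'   `"MRCA_Linognathus"`.
#' @return A [karyotype()].
#' @export
#' @examples
#' k <- load_fixture("L_vituli")
#' length(k$minichromosomes)  # 10
load_fixture <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(.FIXTURE_SPECIES)) {
    stop("unknown fixture name; expected one of: ",
         paste(names(.FIXTURE_SPECIES), collapse = ", "))
  }
  path <- system.file("extdata", paste0(name, ".txt"),
                      package = "minikaryo", mustWork = TRUE)
  read_karyotype(path, species = .FIXTURE_SPECIES[[name]])
}

# ---- JSON -------------------------------------------------------------

#' Convert a karyotype to/from JSON
#'
#' @param k A [karyotype()].
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return `karyotype_to_json`: a JSON string or `path` invisibly.
#'   `karyotype_from_json`: a [karyotype()].
#' @export
karyotype_to_json <- function(k, path = NULL) {
  stopifnot(inherits(k, "karyotype"))
  obj <- list(
    species = k$species,
    minichromosomes = lapply(unname(k$minichromosomes), function(m) {
      list(label = m$label, genes = m$genes,
           total_len_bp = m$total_len_bp, cluster_len_bp = m$cluster_len_bp,
           ncr_len_bp = m$ncr_len_bp, pseudo_len_bp = m$pseudo_len_bp,
           ncr_sequence = m$ncr_sequence,
           cluster_sequence = m$cluster_sequence)
    })
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, na = "null", digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname karyotype_to_json
#' @param json A JSON string or path to a JSON file produced by
#'   `karyotype_to_json`.
#' @export
karyotype_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  chroms <- lapply(seq_len(nrow(obj$minichromosomes)), function(i) {
    row <- obj$minichromosomes[i, ]
    genes <- row$genes[[1L]]
    genes$copy <- as.integer(genes$copy)
    genes$length_bp <- as.integer(genes$length_bp)
    if (is.null(genes$sequence)) genes$sequence <- NA_character_
    minichromosome(
      genes,
      total_len_bp = row$total_len_bp %||% NA,
      cluster_len_bp = row$cluster_len_bp %||% NA,
      ncr_len_bp = row$ncr_len_bp %||% NA,
      pseudo_len_bp = row$pseudo_len_bp %||% NA,
      ncr_sequence = row$ncr_sequence %||% NA_character_,
      cluster_sequence = row$cluster_sequence %||% NA_character_
    )
  })
  karyotype(chroms, species = obj$species)
}

# ---- print methods ----------------------------------------------------

#' @export
print.minichromosome <- function(x, ...) {
  cat("<minichromosome> ", x$label, "\n", sep = "")
  if (!is.na(x$total_len_bp)) {
    cat(sprintf("  total %d bp (cluster %s, NCR %s, pseudo %s)\n",
                x$total_len_bp,
                ifelse(is.na(x$cluster_len_bp), "?", x$cluster_len_bp),
                ifelse(is.na(x$ncr_len_bp), "?", x$ncr_len_bp),
                ifelse(is.na(x$pseudo_len_bp), "?", x$pseudo_len_bp)))
  }
  invisible(x)
}

#' @export
print.karyotype <- function(x, ...) {
  cat(sprintf("<karyotype> %s: %d minichromosomes\n", x$species,
              length(x$minichromosomes)))
  for (m in x$minichromosomes) cat("  ", m$label, "\n", sep = "")
  invisible(x)
}

#' @export
print.karyotype_summary <- function(x, ...) {
  cat(sprintf("<karyotype summary> %s\n", x$species))
  cat(sprintf("  minichromosomes:     %d\n", x$n_minichromosomes))
  cat(sprintf("  distinct full genes: %d\n", x$n_distinct_full_genes))
  cat(sprintf("  duplicate copies:    %d\n", x$n_duplicate_genes))
  cat(sprintf("  pseudo genes:        %d\n", x$n_pseudo_genes))
  fmt <- function(v) if (is.na(v)) "absent" else format(v, big.mark = ",")
  cat(sprintf("  total / cluster / NCR / pseudo bp: %s / %s / %s / %s\n",
              fmt(x$total_len_bp), fmt(x$cluster_len_bp),
              fmt(x$ncr_len_bp), fmt(x$pseudo_len_bp)))
  cat(sprintf("  full genes per minichromosome: %d-%d\n",
              x$genes_per_chrom_min, x$genes_per_chrom_max))
  invisible(x)
}
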