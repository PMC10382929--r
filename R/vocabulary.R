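# The canonical 37-gene animal mitochondrial vocabulary used throughout:
# 13 protein-coding genes, 22 tRNA genes (single-letter names, numbered
# isoacceptors for Leu and Ser), and 2 rRNA genes.

.PCG_NAMES <- c("atp6", "atp8", "cox1", "cox2", "cox3", "cytb",
                "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6")
.TRNA_NAMES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K",
                 "L1", "L2", "M", "N", "P", "Q", "R", "S1", "S2",
                 "T", "V", "W", "Y")
.RRNA_NAMES <- c("rrnS", "rrnL")

#' The canonical 37-gene mitochondrial vocabulary
#'
#' Returns the standard animal mitochondrial gene complement used by all
#' karyotype operations: 13 protein-coding genes (PCG), 22 tRNA genes
#' named by the single-letter abbreviation of their amino acid (with
#' numbered isoacceptors `L1`, `L2`, `S1`, `S2`), and the two rRNA genes
#' `rrnS` and `rrnL`.
#'
#' @return A data frame with columns `name` and `kind`
#'   (`"PCG"`, `"tRNA"` or `"rRNA"`), 37 rows.
#' @export
#' @examples
#' v <- canonical_vocabulary()
#' nrow(v)            # 37
#' table(v$kind)      # 13 PCG, 22 tRNA, 2 rRNA
canonical_vocabulary <- function() {
  data.frame(
    name = c(.PCG_NAMES, .TRNA_NAMES, .RRNA_NAMES),
    kind = rep(c("PCG", "tRNA", "rRNA"),
               times = c(length(.PCG_NAMES), length(.TRNA_NAMES),
                         length(.RRNA_NAMES))),
    stringsAsFactors = FALSE
  )
}

# kind is a function of the canonical name
gene_kind <- function(name) {
  v <- canonical_vocabulary()
  kind <- v$kind[match(name, v$name)]
  if (anyNA(kind)) {
    stop("unknown gene name(s): ", paste(name[is.na(kind)], collapse = ", "))
  }
  kind
}

is_canonical_gene <- function(name) {
  name %in% canonical_vocabulary()$name
}
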