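# Closed gene vocabulary for a 37-gene metazoan mitogenome plus the control
# region: 13 protein-coding genes, 22 tRNAs (leucine and serine isoacceptors
# disambiguated as trnL1/trnL2 and trnS1/trnS2), 2 rRNAs, and CR.

.PCG_SYMBOLS <- c("cox1", "cox2", "cox3", "nad1", "nad2", "nad3", "nad4",
                  "nad4L", "nad5", "nad6", "cob", "atp6", "atp8")

.TRNA_SYMBOLS <- c("trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH",
                   "trnI", "trnK", "trnL1", "trnL2", "trnM", "trnN", "trnP",
                   "trnQ", "trnR", "trnS1", "trnS2", "trnT", "trnV", "trnW",
                   "trnY")

.RRNA_SYMBOLS <- c("rrnS", "rrnL")

#' Gene vocabulary of the mitogenome model
#'
#' The 38 orderable symbols every function in the package understands:
#' 13 protein-coding genes (PCGs), 22 tRNAs, 2 rRNAs, and the control
#' region `CR`. The vocabulary is closed: unknown symbols are rejected at
#' input rather than silently flowing into the gene-order algebra.
#'
#' @param category optional filter, one or more of `"PCG"`, `"tRNA"`,
#'   `"rRNA"`, `"CR"`.
#' @return character vector of gene symbols.
#' @examples
#' mito_genes("rRNA")
#' length(mito_genes())  # 38
#' @export
mito_genes <- function(category = NULL) {
  all <- c(.PCG_SYMBOLS, .TRNA_SYMBOLS, .RRNA_SYMBOLS, "CR")
  if (is.null(category)) return(all)
  category <- match.arg(category, c("PCG", "tRNA", "rRNA", "CR"),
                        several.ok = TRUE)
  all[gene_category(all) %in% category]
}

#' Category of a gene symbol
#'
#' @param gene character vector of normalized gene symbols.
#' @return character vector with values `"PCG"`, `"tRNA"`, `"rRNA"` or
#'   `"CR"`; `NA` for symbols outside the vocabulary.
#' @examples
#' gene_category(c("cox1", "trnK", "rrnS", "CR"))
#' @export
gene_category <- function(gene) {
  out <- rep(NA_character_, length(gene))
  out[gene %in% .PCG_SYMBOLS] <- "PCG"
  out[gene %in% .TRNA_SYMBOLS] <- "tRNA"
  out[gene %in% .RRNA_SYMBOLS] <- "rRNA"
  out[gene == "CR"] <- "CR"
  out
}

# Synonym map: lower-cased alias -> canonical symbol. Covers the common
# annotation spellings (MITOS, GenBank product names, 12S/16S, D-loop).
.gene_synonyms <- local({
  syn <- c(
    # PCGs
    "co1" = "cox1", "coi" = "cox1", "coxi" = "cox1", "cox-1" = "cox1",
    "co2" = "cox2", "coii" = "cox2", "coxii" = "cox2",
    "co3" = "cox3", "coiii" = "cox3", "coxiii" = "cox3",
    "nd1" = "nad1", "nd2" = "nad2", "nd3" = "nad3", "nd4" = "nad4",
    "nd4l" = "nad4L", "nad4l" = "nad4L", "nd5" = "nad5", "nd6" = "nad6",
    "cytb" = "cob", "cyt b" = "cob", "cob" = "cob",
    "atp6" = "atp6", "atpase6" = "atp6", "atp8" = "atp8", "atpase8" = "atp8",
    # rRNAs
    "12s" = "rrnS", "12s rrna" = "rrnS", "rrns" = "rrnS", "s-rrna" = "rrnS",
    "srrna" = "rrnS", "small subunit ribosomal rna" = "rrnS",
    "16s" = "rrnL", "16s rrna" = "rrnL", "rrnl" = "rrnL", "l-rrna" = "rrnL",
    "lrrna" = "rrnL", "large subunit ribosomal rna" = "rrnL",
    # control region
    "cr" = "CR", "d-loop" = "CR", "dloop" = "CR", "control region" = "CR",
    "a+t rich region" = "CR", "at-rich region" = "CR",
    # tRNA isoacceptor spellings
    "trnl(cun)" = "trnL1", "trnl1(cun)" = "trnL1", "trnl(uur)" = "trnL2",
    "trnl2(uur)" = "trnL2", "trns(agn)" = "trnS1", "trns1(agn)" = "trnS1",
    "trns(ucn)" = "trnS2", "trns2(ucn)" = "trnS2"
  )
  # identity entries for the canonical symbols themselves
  canon <- c(.PCG_SYMBOLS, .TRNA_SYMBOLS, .RRNA_SYMBOLS, "CR")
  names(canon) <- tolower(canon)
  c(syn, canon)
})

#' Normalize gene names to the closed vocabulary
#'
#' Maps common annotation aliases (`12S` -> `rrnS`, `16S` -> `rrnL`,
#' `D-loop` -> `CR`, `ND5` -> `nad5`, `CYTB` -> `cob`, ...) onto the 38
#' canonical symbols. Matching is case-insensitive; normalization is
#' idempotent.
#'
#' @param x character vector of gene names.
#' @param error if `TRUE` (default) unknown names raise an error listing the
#'   accepted vocabulary; if `FALSE` they come back as `NA`.
#' @return character vector of canonical symbols.
#' @examples
#' normalize_gene_names(c("12S", "D-loop", "ND5", "trnL(CUN)"))
#' @export
normalize_gene_names <- function(x, error = TRUE) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(.gene_synonyms[key])
  if (error && anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown gene symbol(s): ", paste(bad, collapse = ", "),
         "\naccepted vocabulary: ", paste(mito_genes(), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Pancrustacean ancestral signed gene order
#'
#' The ancestral ("ground pattern") arrangement of the 37 mitochondrial
#' genes plus control region shared by Pancrustacea, the reference against
#' which derived brachyuran arrangements are compared. A leading minus
#' orientation marks genes encoded on the minus strand.
#'
#' @return a [gene_order] of all 38 symbols.
#' @examples
#' ground_pattern()
#' @export
ground_pattern <- function() {
  spec <- c("cox1", "trnL2", "cox2", "trnK", "trnD", "atp8", "atp6", "cox3",
            "trnG", "nad3", "trnA", "trnR", "trnN", "trnS1", "trnE", "-trnF",
            "-nad5", "-trnH", "-nad4", "-nad4L", "trnT", "-trnP", "nad6",
            "cob", "trnS2", "-nad1", "-trnL1", "-rrnL", "-trnV", "-rrnS",
            "CR", "trnI", "-trnQ", "trnM", "nad2", "trnW", "-trnC", "-trnY")
  parse_signed_symbols(spec, taxon = "pancrustacean")
}
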