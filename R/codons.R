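# Codon usage under the invertebrate mitochondrial genetic code
# (translation table 5): 62 sense codons, TAA/TAG the only stops, ATA = Met,
# AGA/AGG = Ser. Synonymous families are formed by amino acid, so leucine
# has 6 members and serine 8; RSCU of codon i in a family of size k with
# family total N is count_i * k / N, and family RSCU values sum to k.

.genetic_code <- function(table = "5") Biostrings::getGeneticCode(table)

sense_codons <- function(code = .genetic_code()) names(code)[code != "*"]

#' Codon usage of a set of coding sequences
#'
#' Tallies sense-codon counts over in-frame coding sequences. A trailing
#' complete stop codon is excluded from counting, as is a truncated final
#' codon of 1-2 nt (completed by polyadenylation in vivo). Internal stop
#' codons are reported with a warning and skipped, counting continues.
#'
#' @param cds_set character vector (or list) of coding sequences, each on
#'   its coding strand, length >= 3.
#' @param code genetic code table (default: invertebrate mitochondrial,
#'   translation table 5).
#' @return object of class `codon_usage`: data.frame with columns `codon`,
#'   `amino_acid`, `count` over the 62 sense codons (DNA alphabet).
#' @examples
#' codon_usage("ATGTTTTAA")  # 1 Met + 1 Phe, stop excluded
#' @export
codon_usage <- function(cds_set, code = .genetic_code()) {
  cds_set <- toupper(unlist(cds_set))
  if (length(cds_set) == 0L) stop("empty CDS set", call. = FALSE)
  if (any(nchar(cds_set) < 3L))
    stop("coding sequence shorter than one codon", call. = FALSE)
  sense <- sense_codons(code)
  counts <- stats::setNames(integer(length(sense)), sense)
  n_internal_stop <- 0L
  for (s in cds_set) {
    ncod <- nchar(s) %/% 3L
    cods <- substring(s, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
    if (ncod > 0L && code[cods[ncod]] %in% "*") cods <- cods[-ncod]
    is_stop <- !is.na(code[cods]) & code[cods] == "*"
    n_internal_stop <- n_internal_stop + sum(is_stop)
    cods <- cods[!is_stop & cods %in% sense]
    tab <- table(cods)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  if (n_internal_stop > 0L)
    warning(n_internal_stop, " internal stop codon(s) skipped",
            call. = FALSE)
  out <- data.frame(codon = sense, amino_acid = unname(code[sense]),
                    count = unname(counts))
  class(out) <- c("codon_usage", "data.frame")
  out
}

#' Relative synonymous codon usage
#'
#' Adds an `rscu` column to a [codon_usage()] table: each codon's count
#' divided by the mean count of its synonymous family
#' (`rscu_i = count_i * k / N` for family size `k` and family total `N`).
#' Family RSCU values sum to the family size; 1 means no bias. Families with
#' zero total get RSCU 0 for all members and are flagged in the
#' `zero_family` column.
#'
#' @param table a `codon_usage` data.frame.
#' @return the table with `rscu` and `zero_family` columns, same class.
#' @examples
#' u <- codon_usage(c("ATGTTTTTTTTTTTCTAA"))
#' rscu(u)[rscu(u)$amino_acid == "F", ]  # UUU 1.5, UUC 0.5
#' @export
rscu <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("codon", "amino_acid", "count") %in% names(table)))
  fam_total <- tapply(table$count, table$amino_acid, sum)
  fam_size <- tapply(table$count, table$amino_acid, length)
  N <- fam_total[table$amino_acid]
  k <- fam_size[table$amino_acid]
  table$rscu <- ifelse(N > 0, table$count * k / N, 0)
  table$zero_family <- N == 0
  class(table) <- c("codon_usage", "data.frame")
  table
}

#' Classify start and stop codons of a protein-coding gene
#'
#' Extracts the strand-correct coding sequence of a PCG from the genome and
#' reads its terminal codons: the start is the first triplet (flagged when
#' not `ATN`); the stop is the final complete triplet when the coding length
#' is a multiple of 3, otherwise the trailing 1-2 nt are reported in the
#' truncated notation (`T--`, `TA-`) with `complete = FALSE` — such stops
#' are completed to UAA by post-transcriptional polyadenylation.
#'
#' @param ann a [mito_annotation] carrying a sequence.
#' @param gene PCG symbol.
#' @return list of class `codon_call`: `gene`, `start_codon`, `stop_codon`,
#'   `complete` (stop completeness), `canonical_start` (`ATN`?).
#' @export
classify_codons <- function(ann, gene) {
  stopifnot(inherits(ann, "mito_annotation"))
  if (is.null(ann$sequence))
    stop("annotation carries no sequence", call. = FALSE)
  gene <- normalize_gene_names(gene)
  i <- match(gene, ann$records$gene)
  if (is.na(i)) stop("no record for gene ", gene, call. = FALSE)
  if (ann$records$category[i] != "PCG")
    stop(gene, " is not a protein-coding gene", call. = FALSE)
  s <- record_sequence(ann, i, strand_aware = TRUE)
  if (nchar(s) < 6L) stop("coding length < 6 for ", gene, call. = FALSE)

  start <- substr(s, 1L, 3L)
  trail <- nchar(s) %% 3L
  if (trail == 0L) {
    stop_codon <- substr(s, nchar(s) - 2L, nchar(s))
    complete <- TRUE
  } else {
    tail_nt <- substr(s, nchar(s) - trail + 1L, nchar(s))
    stop_codon <- paste0(tail_nt, strrep("-", 3L - trail))
    complete <- FALSE
  }
  structure(list(gene = gene, start_codon = start, stop_codon = stop_codon,
                 complete = complete,
                 canonical_start = grepl("^AT[ACGT]$", start)),
            class = "codon_call")
}

#' @export
print.codon_call <- function(x, ...) {
  cat(sprintf("<codon_call> %s: start %s%s, stop %s%s\n", x$gene,
              x$start_codon,
              if (!x$canonical_start) " (non-canonical)" else "",
              x$stop_codon, if (!x$complete) " (truncated)" else ""))
  invisible(x)
}

#' Write a codon usage / RSCU report
#'
#' Extracts every PCG coding sequence from an annotated genome (minus-strand
#' genes reverse-complemented), tallies codon usage and RSCU, and writes a
#' TSV with columns codon, amino acid, count, RSCU.
#'
#' @param ann a [mito_annotation] with sequence.
#' @param path output TSV path.
#' @return the RSCU table, invisibly.
#' @export
rscu_report <- function(ann, path) {
  stopifnot(inherits(ann, "mito_annotation"))
  pcg <- which(ann$records$category == "PCG")
  if (length(pcg) == 0L) stop("no protein-coding genes", call. = FALSE)
  cds <- vapply(pcg, function(i) record_sequence(ann, i, strand_aware = TRUE),
                character(1L))
  tab <- rscu(codon_usage(cds))
  utils::write.table(tab[, c("codon", "amino_acid", "count", "rscu")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
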