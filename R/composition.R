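#' Base composition and strand skews of a sequence
#'
#' Counts A/T/G/C, computes fractions over the total length, AT and GC
#' content, and the strand-asymmetry skews
#' `AT skew = (A - T)/(A + T)` and `GC skew = (G - C)/(G + C)`.
#' IUPAC ambiguity codes are legal: they count toward the length but are
#' excluded from the four base counts (and hence from the skews), so
#' `at_content + gc_content = 1 - ambiguous fraction`.
#'
#' @param seq non-empty nucleotide string (IUPAC alphabet; `U` counts as
#'   `T`).
#' @return a one-row data.frame of class `composition_profile` with columns
#'   `size`, `A`, `T`, `G`, `C` (counts), `a`, `t`, `g`, `c` (fractions),
#'   `at_content`, `gc_content`, `at_skew`, `gc_skew`. A skew whose
#'   denominator is zero is `NA` (undefined), never a number.
#' @examples
#' base_composition("AAAT")$at_skew  # 0.5
#' @export
base_composition <- function(seq) {
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L || is.na(seq) || nchar(seq) == 0L)
    stop("empty sequence", call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  iupac <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "N")
  bad <- which(!chars %in% iupac)
  if (length(bad) > 0L)
    stop("non-IUPAC character '", chars[bad[1L]], "' at position ", bad[1L],
         call. = FALSE)
  chars[chars == "U"] <- "T"
  n <- length(chars)
  cnt <- c(A = sum(chars == "A"), T = sum(chars == "T"),
           G = sum(chars == "G"), C = sum(chars == "C"))
  out <- data.frame(size = n,
                    A = cnt[["A"]], T = cnt[["T"]], G = cnt[["G"]],
                    C = cnt[["C"]],
                    a = cnt[["A"]] / n, t = cnt[["T"]] / n,
                    g = cnt[["G"]] / n, c = cnt[["C"]] / n)
  out$at_content <- out$a + out$t
  out$gc_content <- out$g + out$c
  out$at_skew <- skew(cnt[["A"]], cnt[["T"]])
  out$gc_skew <- skew(cnt[["G"]], cnt[["C"]])
  class(out) <- c("composition_profile", "data.frame")
  out
}

#' Strand-asymmetry skew
#'
#' `skew(plus, minus) = (plus - minus) / (plus + minus)`; the same value is
#' obtained from counts or from percentages (the statistic is invariant
#' under common scaling). The whole-genome AT skew of a mitogenome with
#' A = 35.5% and T = 38.1% is `skew(35.5, 38.1)` = -0.035.
#'
#' @param plus,minus non-negative counts, fractions or percentages
#'   (vectorized).
#' @return `(plus - minus)/(plus + minus)`, or `NA` where
#'   `plus + minus == 0` (undefined, flagged rather than invented).
#' @examples
#' skew(35.5, 38.1)
#' skew(1, 0)
#' @export
skew <- function(plus, minus) {
  if (any(plus < 0 | minus < 0, na.rm = TRUE))
    stop("skew arguments must be non-negative", call. = FALSE)
  tot <- plus + minus
  ifelse(tot > 0, (plus - minus) / tot, NA_real_)
}

# genome-strand subsequence of one record (handles origin wrap); strand-aware
# mode reverse-complements minus-strand records
record_sequence <- function(ann, i, strand_aware = FALSE) {
  r <- ann$records[i, ]
  s <- if (r$end >= r$start) substr(ann$sequence, r$start, r$end)
  else paste0(substr(ann$sequence, r$start, ann$genome_length),
              substr(ann$sequence, 1L, r$end))
  if (strand_aware && !is.na(r$strand) && r$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Composition profiles over genome partitions
#'
#' Computes one [base_composition()] profile per selected unit, the layout
#' of a published composition-and-skewness table: the whole genome, all
#' protein-coding genes concatenated, each PCG, the tRNAs, the rRNAs, and
#' the control region. By default every unit is profiled as a genome-strand
#' slice (so minus-strand genes show sign-flipped skews relative to their
#' coding strand, as such tables conventionally do); with
#' `strand_aware = TRUE` minus-strand features are reverse-complemented
#' first.
#'
#' @param ann a [mito_annotation] carrying a sequence.
#' @param partition which units to profile: `"table"` (default, the full
#'   table above), `"categories"` (genome/PCGs/tRNAs/rRNAs/CR only), or a
#'   character vector of gene symbols.
#' @param strand_aware reverse-complement minus-strand features before
#'   profiling.
#' @return data.frame with a `unit` column followed by the
#'   [base_composition()] columns.
#' @export
partition_stats <- function(ann, partition = "table", strand_aware = FALSE) {
  stopifnot(inherits(ann, "mito_annotation"))
  if (is.null(ann$sequence))
    stop("annotation carries no sequence", call. = FALSE)
  r <- ann$records

  unit_seq <- function(idx) paste(vapply(idx, function(i)
    record_sequence(ann, i, strand_aware), character(1L)), collapse = "")

  units <- list()
  if (identical(partition, "table") || identical(partition, "categories")) {
    units[["genome"]] <- ann$sequence
    if (any(r$category == "PCG"))
      units[["PCGs"]] <- unit_seq(which(r$category == "PCG"))
    if (identical(partition, "table"))
      for (i in which(r$category == "PCG")) units[[r$gene[i]]] <-
          record_sequence(ann, i, strand_aware)
    if (any(r$category == "tRNA"))
      units[["tRNAs"]] <- unit_seq(which(r$category == "tRNA"))
    if (any(r$category == "rRNA"))
      units[["rRNAs"]] <- unit_seq(which(r$category == "rRNA"))
    if (any(r$category == "CR"))
      units[["CR"]] <- unit_seq(which(r$category == "CR"))
  } else {
    sel <- normalize_gene_names(partition)
    idx <- match(sel, r$gene)
    if (anyNA(idx))
      stop("selector matches no record: ",
           paste(sel[is.na(idx)], collapse = ", "), call. = FALSE)
    for (k in seq_along(sel)) units[[sel[k]]] <-
        record_sequence(ann, idx[k], strand_aware)
  }
  if (length(units) == 0L) stop("selector matches nothing", call. = FALSE)

  out <- do.call(rbind, lapply(units, base_composition))
  out <- cbind(unit = names(units), out)
  rownames(out) <- NULL
  out
}

#' Write a composition report
#'
#' Emits the [partition_stats()] table as TSV shaped like a published
#' composition-and-skewness table: Size, A%, T%, G%, C%, AT%, GC%, AT skew,
#' GC skew per unit (percentages and skews unrounded).
#'
#' @param ann a [mito_annotation] with sequence.
#' @param path output TSV path.
#' @param ... passed to [partition_stats()].
#' @return the report data.frame, invisibly.
#' @export
composition_report <- function(ann, path, ...) {
  p <- partition_stats(ann, ...)
  rep <- data.frame(unit = p$unit, size_bp = p$size,
                    A_pct = 100 * p$a, T_pct = 100 * p$t,
                    G_pct = 100 * p$g, C_pct = 100 * p$c,
                    AT_pct = 100 * p$at_content, GC_pct = 100 * p$gc_content,
                    AT_skew = p$at_skew, GC_skew = p$gc_skew)
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rep)
}
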