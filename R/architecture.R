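#' Pairwise spacers and overlaps around the circular genome
#'
#' One record per genomically adjacent pair, including the origin-spanning
#' pair between the last and first record: the spacer is
#' `downstream start - upstream end - 1` (computed with circular wrap), so a
#' negative value is an overlap of that many bp and 0 means abutting genes.
#'
#' @param ann a [mito_annotation] with at least 2 records.
#' @return data.frame with columns `upstream`, `downstream`, `spacer`
#'   (bp; negative = overlap), `wraps_origin`.
#' @examples
#' tsv <- system.file("extdata", "sinopotamon_chishuiense_table.tsv",
#'                    package = "mitorder")
#' head(pairwise_spacers(read_annotation_table(tsv)))
#' @export
pairwise_spacers <- function(ann) {
  stopifnot(inherits(ann, "mito_annotation"))
  r <- ann$records
  n <- nrow(r)
  if (n < 2L) stop("fewer than 2 records", call. = FALSE)
  up <- seq_len(n)
  down <- c(2:n, 1L)
  spacer <- r$start[down] - r$end[up] - 1L
  wraps <- rep(FALSE, n)
  if (ann$circular) {
    # the last->first pair crosses the origin
    spacer[n] <- spacer[n] + ann$genome_length
    wraps[n] <- TRUE
  } else {
    spacer <- spacer[-n]; up <- up[-n]; down <- down[-n]; wraps <- wraps[-n]
  }
  data.frame(upstream = r$gene[up], downstream = r$gene[down],
             spacer = spacer, wraps_origin = wraps)
}

#' Overlap summary of an annotation
#'
#' Counts genomically adjacent gene pairs with negative spacers, their total
#' overlap in bp, and the longest overlapping pair. Only adjacent pairs are
#' considered (the single-column bookkeeping of published gene tables), so a
#' nested gene counts once against its neighbour.
#'
#' @param ann a [mito_annotation].
#' @return list with `n_pairs`, `total_bp`, `longest` (list `upstream`,
#'   `downstream`, `overlap_bp`; `NULL` when there is no overlap), and
#'   `pairs` (the overlapping subset of [pairwise_spacers()]).
#' @export
overlap_summary <- function(ann) {
  sp <- pairwise_spacers(ann)
  ov <- sp[sp$spacer < 0L, , drop = FALSE]
  ov$overlap_bp <- -ov$spacer
  longest <- NULL
  if (nrow(ov) > 0L) {
    i <- which.max(ov$overlap_bp)
    longest <- list(upstream = ov$upstream[i], downstream = ov$downstream[i],
                    overlap_bp = ov$overlap_bp[i])
  }
  list(n_pairs = nrow(ov), total_bp = sum(ov$overlap_bp),
       longest = longest, pairs = ov[order(-ov$overlap_bp), , drop = FALSE])
}

#' Intergenic (spacer) summary of an annotation
#'
#' Totals the positive spacers between adjacent genes. The origin-spanning
#' gap is reported separately because published per-gene tables leave the
#' first gene's intergenic cell empty and so omit it from their totals.
#'
#' @param ann a [mito_annotation].
#' @return list with `n_regions`, `total_bp`, `range` (smallest/largest
#'   region), all excluding the origin-spanning gap, plus `origin_gap_bp`
#'   (`NA` on linear genomes).
#' @export
intergenic_summary <- function(ann) {
  sp <- pairwise_spacers(ann)
  origin <- sp$spacer[sp$wraps_origin]
  pos <- sp$spacer[sp$spacer > 0L & !sp$wraps_origin]
  list(n_regions = length(pos), total_bp = sum(pos),
       range = if (length(pos) > 0L) range(pos) else c(NA_integer_,
                                                       NA_integer_),
       origin_gap_bp = if (length(origin) == 1L && origin > 0L)
         origin else if (ann$circular) 0L else NA_integer_)
}

#' Strand tally
#'
#' Counts records on the plus and minus strands; the unstranded control
#' region is excluded, so `plus + minus` equals the number of stranded
#' records.
#'
#' @param ann a [mito_annotation].
#' @return named integer vector `c(plus = , minus = )`.
#' @export
strand_tally <- function(ann) {
  stopifnot(inherits(ann, "mito_annotation"))
  s <- ann$records$strand
  c(plus = sum(!is.na(s) & s == "+"), minus = sum(!is.na(s) & s == "-"))
}

#' Per-category record counts and summed lengths
#'
#' Coordinate-derived lengths are used throughout (stated lengths are
#' validation metadata only).
#'
#' @param ann a [mito_annotation].
#' @return data.frame with columns `category`, `n`, `total_bp`, ordered
#'   PCG, tRNA, rRNA, CR.
#' @export
category_totals <- function(ann) {
  stopifnot(inherits(ann, "mito_annotation"))
  len <- record_lengths(ann)
  cat_f <- factor(ann$records$category, levels = c("PCG", "tRNA", "rRNA",
                                                   "CR"))
  out <- data.frame(category = levels(cat_f),
                    n = as.integer(table(cat_f)),
                    total_bp = as.integer(tapply(len, cat_f, sum,
                                                 default = 0L)))
  rownames(out) <- NULL
  out
}

#' Write an architecture report
#'
#' Per-gene TSV (gene, start, end, coordinate length, strand, spacer to the
#' next gene) followed by `#`-prefixed summary lines: strand tally, overlap
#' and intergenic totals, category totals.
#'
#' @param ann a [mito_annotation].
#' @param path output TSV path.
#' @return the per-gene data.frame, invisibly.
#' @export
architecture_report <- function(ann, path) {
  sp <- pairwise_spacers(ann)
  r <- ann$records
  tab <- data.frame(gene = r$gene, start = r$start, end = r$end,
                    length = record_lengths(ann),
                    strand = ifelse(is.na(r$strand), ".", r$strand),
                    spacer_to_next = c(sp$spacer,
                                       rep(NA_integer_,
                                           nrow(r) - nrow(sp))))
  ov <- overlap_summary(ann)
  ig <- intergenic_summary(ann)
  st <- strand_tally(ann)
  ct <- category_totals(ann)
  con <- file(path, "w"); on.exit(close(con))
  suppressWarnings(utils::write.table(tab, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE, na = ""))
  writeLines(c(
    sprintf("# taxon\t%s\tgenome_length\t%d", ann$taxon, ann$genome_length),
    sprintf("# strands\tplus\t%d\tminus\t%d", st["plus"], st["minus"]),
    sprintf("# overlaps\tpairs\t%d\ttotal_bp\t%d\tlongest\t%s",
            ov$n_pairs, ov$total_bp,
            if (is.null(ov$longest)) "none" else
              sprintf("%s/%s:%d", ov$longest$upstream, ov$longest$downstream,
                      ov$longest$overlap_bp)),
    sprintf("# intergenic\tregions\t%d\ttotal_bp\t%d\torigin_gap_bp\t%s",
            ig$n_regions, ig$total_bp, as.character(ig$origin_gap_bp)),
    sprintf("# category\t%s\tn\t%d\ttotal_bp\t%d", ct$category, ct$n,
            ct$total_bp)), con)
  invisible(tab)
}
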