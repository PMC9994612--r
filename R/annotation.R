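#' Construct a mitogenome annotation
#'
#' The central container consumed by every analysis stage: an ordered set of
#' gene records on a (usually circular) mitochondrial genome, with an
#' optional nucleotide sequence. Coordinates are 1-based and inclusive
#' throughout; on a circular genome a record may wrap the origin
#' (`end < start`), in which case it covers `start..genome_length` followed
#' by `1..end`.
#'
#' @param records data.frame with columns `gene`, `start`, `end`, `strand`
#'   (`"+"`, `"-"` or `NA`; `"F"`/`"R"` accepted), and optionally
#'   `start_codon`, `stop_codon`, `stated_length`. Gene names are normalized
#'   against the closed vocabulary ([mito_genes()]) and must be unique.
#' @param genome_length genome size in bp.
#' @param taxon label carried through reports.
#' @param circular logical; circular topology is the default. Wrap-around
#'   records are rejected on linear genomes.
#' @param sequence optional nucleotide string of length `genome_length`.
#' @return an object of class `mito_annotation`: a list with elements
#'   `taxon`, `genome_length`, `circular`, `records` (sorted by `start`),
#'   and `sequence` (`NULL` if absent).
#' @seealso [read_annotation_table()], [validate_annotation()],
#'   [gene_length()]
#' @export
mito_annotation <- function(records, genome_length, taxon = "unknown",
                            circular = TRUE, sequence = NULL) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  need <- c("gene", "start", "end", "strand")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L)
    stop("records lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  records$gene <- normalize_gene_names(records$gene)
  if (anyDuplicated(records$gene))
    stop("duplicate gene name(s): ",
         paste(unique(records$gene[duplicated(records$gene)]), collapse = ", "),
         call. = FALSE)

  records$start <- as.integer(records$start)
  records$end <- as.integer(records$end)
  records$strand <- normalize_strand(records$strand)
  records$category <- gene_category(records$gene)

  for (col in c("start_codon", "stop_codon"))
    if (is.null(records[[col]])) records[[col]] <- NA_character_ else
      records[[col]] <- ifelse(!nzchar(trimws(as.character(records[[col]]))) |
                                 is.na(records[[col]]),
                               NA_character_,
                               trimws(as.character(records[[col]])))
  if (is.null(records$stated_length))
    records$stated_length <- NA_integer_ else
    records$stated_length <- suppressWarnings(as.integer(records$stated_length))

  genome_length <- as.integer(genome_length)
  if (is.na(genome_length) || genome_length < 1L)
    stop("genome_length must be a positive integer", call. = FALSE)
  bad <- records$start < 1L | records$start > genome_length |
    records$end < 1L | records$end > genome_length
  if (any(is.na(bad)))
    stop("missing coordinates in record(s): ",
         paste(records$gene[is.na(bad)], collapse = ", "), call. = FALSE)
  if (!circular && any(records$end < records$start))
    stop("wrap-around record(s) on a linear genome: ",
         paste(records$gene[records$end < records$start], collapse = ", "),
         call. = FALSE)

  records <- records[order(records$start), , drop = FALSE]
  rownames(records) <- NULL
  records <- records[, c("gene", "start", "end", "strand", "category",
                         "start_codon", "stop_codon", "stated_length")]

  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) != genome_length)
      stop("sequence length (", nchar(sequence),
           ") does not equal genome_length (", genome_length, ")",
           call. = FALSE)
  }

  structure(list(taxon = as.character(taxon), genome_length = genome_length,
                 circular = isTRUE(circular), records = records,
                 sequence = sequence),
            class = "mito_annotation")
}

# Accept +/- and the tables' F/R spellings; NA (or "." / "-"-as-dash-cell
# never reaches here: readers map it) means unstranded (control region).
normalize_strand <- function(x) {
  x <- as.character(x)
  out <- rep(NA_character_, length(x))
  out[x %in% c("+", "F", "f")] <- "+"
  out[x %in% c("-", "R", "r")] <- "-"
  bad <- !is.na(x) & is.na(out) & !(x %in% c(".", "", "NA"))
  if (any(bad))
    stop("unrecognized strand value(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  out
}

#' Coordinate-derived gene length on a circular genome
#'
#' `end - start + 1` for ordinary records; records wrapping the origin
#' (`end < start`) cover `genome_length - start + 1 + end` positions.
#'
#' @param start,end 1-based inclusive coordinates (vectorized).
#' @param genome_length genome size in bp.
#' @param circular logical; wrap-around on a linear genome is an error.
#' @return integer vector of lengths in bp.
#' @examples
#' gene_length(5296, 6966, 17311)   # 1671
#' gene_length(17300, 10, 17311)    # 22, wraps the origin
#' @export
gene_length <- function(start, end, genome_length, circular = TRUE) {
  start <- as.integer(start); end <- as.integer(end)
  wrap <- end < start
  if (any(wrap) && !circular)
    stop("wrap-around coordinates on a linear genome", call. = FALSE)
  ifelse(wrap, genome_length - start + 1L + end, end - start + 1L)
}

# lengths of all records of an annotation
record_lengths <- function(ann) {
  gene_length(ann$records$start, ann$records$end, ann$genome_length,
              ann$circular)
}

# genomic positions covered by one record, in 5'->3' genome-strand order
record_positions <- function(start, end, genome_length) {
  if (end >= start) seq.int(start, end)
  else c(seq.int(start, genome_length), seq.int(1L, end))
}

#' Validate an annotation's internal consistency
#'
#' Reports (never throws) one issue per inconsistency: a stated length that
#' disagrees with the coordinate-derived length, an out-of-range coordinate,
#' or a protein-coding gene whose coordinate length is not a multiple of 3
#' without a truncated stop codon (`T--`/`TA-`) to account for the trailing
#' bases. Published tables carry such inconsistencies (a printed tRNA length
#' of 60 against coordinates spanning 66 bp, say); downstream arithmetic in
#' this package always trusts coordinates, and this validator is where the
#' disagreement is surfaced.
#'
#' @param ann a [mito_annotation].
#' @return data.frame with columns `gene`, `issue` (one of
#'   `"length_mismatch"`, `"coordinate_out_of_range"`, `"codon_anomaly"`),
#'   and `detail`; zero rows when the annotation is clean.
#' @export
validate_annotation <- function(ann) {
  stopifnot(inherits(ann, "mito_annotation"))
  r <- ann$records
  len <- record_lengths(ann)
  issues <- list()
  add <- function(gene, issue, detail)
    issues[[length(issues) + 1L]] <<- data.frame(gene = gene, issue = issue,
                                                 detail = detail)

  mism <- !is.na(r$stated_length) & r$stated_length != len
  for (i in which(mism))
    add(r$gene[i], "length_mismatch",
        sprintf("stated length %d but coordinates %d-%d span %d bp",
                r$stated_length[i], r$start[i], r$end[i], len[i]))

  oob <- r$start < 1L | r$start > ann$genome_length |
    r$end < 1L | r$end > ann$genome_length
  for (i in which(oob))
    add(r$gene[i], "coordinate_out_of_range",
        sprintf("coordinates %d-%d outside 1-%d", r$start[i], r$end[i],
                ann$genome_length))

  is_pcg <- r$category == "PCG"
  trail <- len %% 3L
  truncated <- !is.na(r$stop_codon) & r$stop_codon %in% c("T--", "TA-", "T", "TA")
  anom <- is_pcg & trail != 0L & !truncated
  for (i in which(anom))
    add(r$gene[i], "codon_anomaly",
        sprintf("coding length %d is not a multiple of 3 and stop codon '%s' is not truncated",
                len[i], ifelse(is.na(r$stop_codon[i]), "", r$stop_codon[i])))

  if (length(issues) == 0L)
    return(data.frame(gene = character(), issue = character(),
                      detail = character()))
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}

#' @export
print.mito_annotation <- function(x, ...) {
  cat(sprintf("<mito_annotation> %s: %d bp (%s), %d records%s\n",
              x$taxon, x$genome_length,
              if (x$circular) "circular" else "linear",
              nrow(x$records),
              if (is.null(x$sequence)) "" else ", with sequence"))
  counts <- table(factor(x$records$category,
                         levels = c("PCG", "tRNA", "rRNA", "CR")))
  cat("  ", paste(sprintf("%s: %d", names(counts), counts), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::summary
summary.mito_annotation <- function(object, ...) {
  tot <- category_totals(object)
  st <- strand_tally(object)
  cat(sprintf("%s: %d bp, %d records (+%d/-%d stranded genes)\n",
              object$taxon, object$genome_length, nrow(object$records),
              st["plus"], st["minus"]))
  print(tot)
  invisible(tot)
}
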