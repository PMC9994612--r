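#' Read an annotation table
#'
#' Reads the package's TSV annotation dialect: a metadata header line
#' `#taxon=<name> length=<bp> circular=<true|false>` followed by a
#' tab-separated table with columns `gene`, `start`, `end`, `strand`
#' (`F`/`R` or `+`/`-`; `.` for the unstranded control region) and optional
#' `length` (a stated length, kept for validation only), `start_codon`,
#' `stop_codon`. Gene names are normalized (`12S` -> `rrnS`, `D-loop` ->
#' `CR`, ...); records come back sorted by start. If the header carries no
#' `length=`, the genome length is taken from the furthest-reaching record.
#'
#' @param path file path.
#' @return a [mito_annotation].
#' @examples
#' tsv <- system.file("extdata", "sinopotamon_chishuiense_table.tsv",
#'                    package = "mitorder")
#' read_annotation_table(tsv)
#' @export
read_annotation_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2L) stop("no records in ", path, call. = FALSE)

  taxon <- "unknown"; glen <- NA_integer_; circular <- TRUE
  if (length(meta) > 0L) {
    m <- meta[1L]
    pick <- function(key) {
      hit <- regmatches(m, regexpr(paste0(key, "=[^ \t]+"), m))
      if (length(hit) == 0L) NA_character_ else sub(paste0(key, "="), "", hit)
    }
    if (!is.na(pick("taxon"))) taxon <- gsub("_", " ", pick("taxon"))
    if (!is.na(pick("length"))) glen <- as.integer(gsub(",", "", pick("length")))
    if (!is.na(pick("circular"))) circular <- tolower(pick("circular")) == "true"
  }

  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  names(tab) <- tolower(names(tab))
  need <- c("gene", "start", "end", "strand")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L)
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab$strand[!is.na(tab$strand) & tab$strand == "."] <- NA_character_
  if ("length" %in% names(tab)) tab$stated_length <- tab$length
  if (is.na(glen)) glen <- max(tab$end, tab$start)

  mito_annotation(tab, genome_length = glen, taxon = taxon,
                  circular = circular)
}

#' Write an annotation table
#'
#' Emits the TSV dialect read by [read_annotation_table()]; strands are
#' rendered `F`/`R` (`.` for the control region) and the coordinate-derived
#' length is written in the `length` column, so write-then-read round-trips
#' to a record-for-record identical annotation.
#'
#' @param ann a [mito_annotation].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(ann, path) {
  stopifnot(inherits(ann, "mito_annotation"))
  r <- ann$records
  out <- data.frame(gene = r$gene, start = r$start, end = r$end,
                    length = record_lengths(ann),
                    strand = c("+" = "F", "-" = "R")[r$strand],
                    start_codon = r$start_codon, stop_codon = r$stop_codon)
  out$strand[is.na(out$strand)] <- "."
  header <- sprintf("#taxon=%s length=%d circular=%s",
                    gsub(" ", "_", ann$taxon), ann$genome_length,
                    tolower(as.character(ann$circular)))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(header, con)
  suppressWarnings(utils::write.table(out, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE, na = ""))
  invisible(path)
}

#' Read signed gene-order lists
#'
#' One genome per line: `taxon<TAB>cox1,trnL2,...,-trnH,...`, a leading `-`
#' marking the minus strand. Blank lines and `#` comments are skipped.
#'
#' @param path file path.
#' @return list of [gene_order] objects.
#' @export
read_gene_orders <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) == 0L) stop("no gene orders in ", path, call. = FALSE)
  lapply(lines, function(l) {
    parts <- strsplit(l, "\t")[[1L]]
    if (length(parts) != 2L)
      stop("malformed gene-order line: ", l, call. = FALSE)
    syms <- trimws(strsplit(parts[2L], ",")[[1L]])
    parse_signed_symbols(syms, taxon = parts[1L])
  })
}

#' Write signed gene-order lists
#'
#' @param orders a [gene_order] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_orders <- function(orders, path) {
  if (inherits(orders, "gene_order")) orders <- list(orders)
  lines <- vapply(orders, function(o)
    paste0(o$taxon, "\t", paste0(ifelse(o$signs < 0L, "-", ""), o$genes,
                                 collapse = ",")),
    character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
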