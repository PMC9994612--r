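# Minimal GenBank flat-file dialect: LOCUS / FEATURES / ORIGIN, feature keys
# CDS, tRNA, rRNA and D-loop, locations `a..b`, `complement(a..b)` and the
# origin-spanning `join(a..L,1..b)`. Enough to round-trip the annotations
# this package works with; it is not a general GenBank parser.

#' Read a GenBank flat file
#'
#' Parses LOCUS (length, circular/linear topology), the FEATURES table
#' (CDS -> PCG, tRNA, rRNA, D-loop -> CR; gene names from `/gene` or
#' `/product`, normalized to the closed vocabulary) and the ORIGIN sequence.
#' `complement(...)` locations map to the minus strand; an origin-spanning
#' `join(a..length,1..b)` becomes a single wrap-around record, which is
#' rejected when LOCUS declares linear topology.
#'
#' @param path GenBank flat file.
#' @return a [mito_annotation] (with sequence when ORIGIN is present).
#' @seealso [write_genbank()]
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("missing LOCUS line in ", path, call. = FALSE)
  glen <- as.integer(sub("^.*?(\\d+)\\s+bp.*$", "\\1", locus[1L]))
  circular <- grepl("circular", locus[1L], ignore.case = TRUE)
  taxon <- sub("^LOCUS\\s+(\\S+).*$", "\\1", locus[1L])
  def <- grep("^DEFINITION", lines, value = TRUE)
  if (length(def) > 0L)
    taxon <- trimws(sub("^DEFINITION\\s+", "", sub("\\s+mitochondrion.*$", "",
                                                   def[1L])))

  fstart <- grep("^FEATURES", lines)
  if (length(fstart) == 0L) stop("missing FEATURES section in ", path,
                                 call. = FALSE)
  fend <- grep("^(ORIGIN|//)", lines)
  fend <- if (length(fend) > 0L) min(fend[fend > fstart[1L]]) else
    length(lines) + 1L
  feat_lines <- lines[(fstart[1L] + 1L):(fend - 1L)]

  # split into feature blocks: a new feature starts at indent 5 with a key
  key_at <- grepl("^ {5}\\S", feat_lines)
  blocks <- split(feat_lines, cumsum(key_at))
  if (any(!key_at[1L])) blocks <- blocks[-1L]  # leading continuation junk

  recs <- list()
  for (b in blocks) {
    key <- sub("^ {5}(\\S+).*$", "\\1", b[1L])
    if (!key %in% c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature")) next
    loc <- trimws(sub("^ {5}\\S+\\s+", "", b[1L]))
    # location may continue on following lines until a qualifier starts
    i <- 2L
    while (i <= length(b) && !grepl("^\\s+/", b[i])) {
      loc <- paste0(loc, trimws(b[i])); i <- i + 1L
    }
    quals <- b[grepl("^\\s+/", b)]
    getq <- function(name) {
      hit <- grep(paste0("^\\s+/", name, "="), quals, value = TRUE)
      if (length(hit) == 0L) return(NA_character_)
      gsub('"', "", sub(paste0("^\\s+/", name, "="), "", hit[1L]))
    }
    gene <- getq("gene")
    if (is.na(gene)) gene <- getq("product")
    if (is.na(gene) && key == "D-loop") gene <- "CR"
    if (is.na(gene))
      stop("feature without /gene or /product qualifier at location ", loc,
           call. = FALSE)

    p <- parse_gb_location(loc, glen, feature = gene)
    if (p$wraps && !circular)
      stop("origin-spanning location on a linear genome: ", gene,
           call. = FALSE)
    recs[[length(recs) + 1L]] <- data.frame(
      gene = gene, start = p$start, end = p$end,
      strand = if (key %in% c("D-loop", "misc_feature")) NA_character_ else
        p$strand,
      start_codon = NA_character_, stop_codon = NA_character_)
  }
  if (length(recs) == 0L) stop("no usable features in ", path, call. = FALSE)
  records <- do.call(rbind, recs)

  seq <- NULL
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart) > 0L) {
    oend <- grep("^//", lines)
    oend <- if (length(oend) > 0L) min(oend[oend > ostart[1L]]) else
      length(lines) + 1L
    body <- lines[(ostart[1L] + 1L):(oend - 1L)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
    if (!nzchar(seq)) seq <- NULL
  }

  mito_annotation(records, genome_length = glen, taxon = taxon,
                  circular = circular, sequence = seq)
}

parse_gb_location <- function(loc, genome_length, feature = "?") {
  raw <- loc
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",")[[1L]]
    rng <- lapply(parts, parse_gb_range, feature = feature, raw = raw)
    if (length(rng) != 2L || rng[[1L]][2L] != genome_length ||
        rng[[2L]][1L] != 1L)
      stop("unparseable location for feature ", feature, ": ", raw,
           call. = FALSE)
    return(list(start = rng[[1L]][1L], end = rng[[2L]][2L], strand = strand,
                wraps = TRUE))
  }
  rng <- parse_gb_range(loc, feature = feature, raw = raw)
  list(start = rng[1L], end = rng[2L], strand = strand, wraps = FALSE)
}

parse_gb_range <- function(x, feature, raw) {
  x <- gsub("[<>]", "", trimws(x))
  if (!grepl("^\\d+\\.\\.\\d+$", x))
    stop("unparseable location for feature ", feature, ": ", raw,
         call. = FALSE)
  as.integer(strsplit(x, "\\.\\.")[[1L]])
}

#' Write a GenBank flat file
#'
#' Emits the dialect read by [read_genbank()]: LOCUS with length and
#' topology, one feature per record (CDS/tRNA/rRNA/D-loop keyed by
#' category) with `/gene` qualifiers, wrap-around records as
#' `join(a..length,1..b)`, and the sequence as an ORIGIN block when present.
#'
#' @param ann a [mito_annotation].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(ann, path) {
  stopifnot(inherits(ann, "mito_annotation"))
  con <- file(path, "w"); on.exit(close(con))
  name <- gsub(" ", "_", ann$taxon)
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %s MIT",
                     substr(name, 1L, 16L), ann$genome_length,
                     if (ann$circular) "circular" else "linear "), con)
  writeLines(sprintf("DEFINITION  %s mitochondrion.", ann$taxon), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", ann$genome_length), con)

  r <- ann$records
  keys <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", CR = "D-loop")
  for (i in seq_len(nrow(r))) {
    loc <- if (r$end[i] < r$start[i])
      sprintf("join(%d..%d,1..%d)", r$start[i], ann$genome_length, r$end[i])
    else sprintf("%d..%d", r$start[i], r$end[i])
    if (!is.na(r$strand[i]) && r$strand[i] == "-")
      loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-15s %s", keys[[r$category[i]]], loc), con)
    writeLines(sprintf('                     /gene="%s"', r$gene[i]), con)
  }

  if (!is.null(ann$sequence)) {
    writeLines("ORIGIN", con)
    s <- tolower(ann$sequence)
    starts <- seq.int(1L, nchar(s), by = 60L)
    for (st in starts) {
      chunk <- substr(s, st, min(st + 59L, nchar(s)))
      tens <- substring(chunk, seq.int(1L, nchar(chunk), 10L),
                        pmin(seq.int(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
      writeLines(sprintf("%9d %s", st, paste(tens, collapse = " ")), con)
    }
  }
  writeLines("//", con)
  invisible(path)
}
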