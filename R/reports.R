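# Workflow surface tying the stages together: characterize annotated
# genomes, compare gene orders against a reference arrangement, and report
# rearrangement scenarios. All reports are TSV or plain text, byte-identical
# across reruns on identical inputs + seed.

.BUILTIN_REFERENCES <- c("pancrustacean")

# resolve a reference given as a gene_order or a built-in name
.resolve_reference <- function(reference) {
  if (inherits(reference, "gene_order")) return(reference)
  if (is.character(reference) && length(reference) == 1L) {
    if (reference == "pancrustacean") return(ground_pattern())
    stop("unknown reference '", reference, "'; built-ins: ",
         paste(.BUILTIN_REFERENCES, collapse = ", "), call. = FALSE)
  }
  stop("reference must be a gene_order or a built-in name", call. = FALSE)
}

#' Characterize annotated mitogenomes
#'
#' Runs the architecture, composition, codon-usage and validation stages on
#' one or more annotations and writes one report bundle per taxon into
#' `out_dir`: `<taxon>_architecture.tsv`, `<taxon>_validation.tsv`, and —
#' when the annotation carries a sequence — `<taxon>_composition.tsv` and
#' `<taxon>_rscu.tsv`. Without a sequence the composition sections are
#' skipped with a notice (graceful degradation), and the architecture
#' sections are still produced.
#'
#' @param anns a [mito_annotation] or a list of them.
#' @param out_dir output directory (created if absent).
#' @param quiet suppress notices.
#' @return named list (per taxon) of written file paths, invisibly.
#' @export
characterize <- function(anns, out_dir, quiet = FALSE) {
  if (inherits(anns, "mito_annotation")) anns <- list(anns)
  stopifnot(length(anns) >= 1L,
            all(vapply(anns, inherits, logical(1L), "mito_annotation")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  note <- function(...) if (!quiet) message(...)
  out <- list()
  for (ann in anns) {
    tag <- gsub("[^A-Za-z0-9_.-]+", "_", ann$taxon)
    paths <- character(0L)
    p <- file.path(out_dir, paste0(tag, "_architecture.tsv"))
    architecture_report(ann, p); paths <- c(paths, architecture = p)
    p <- file.path(out_dir, paste0(tag, "_validation.tsv"))
    utils::write.table(validate_annotation(ann), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, validation = p)
    if (!is.null(ann$sequence)) {
      p <- file.path(out_dir, paste0(tag, "_composition.tsv"))
      composition_report(ann, p); paths <- c(paths, composition = p)
      if (any(ann$records$category == "PCG")) {
        p <- file.path(out_dir, paste0(tag, "_rscu.tsv"))
        rscu_report(ann, p); paths <- c(paths, rscu = p)
      }
    } else {
      note(ann$taxon, ": no sequence; composition and codon sections skipped")
    }
    out[[ann$taxon]] <- paths
  }
  invisible(out)
}

#' Compare gene orders against a reference arrangement
#'
#' Canonicalizes the orders, groups identical circular arrangements into
#' patterns, and scores each order against the reference with breakpoint
#' distance and a displaced-block decomposition. When `out_dir` is given,
#' writes `patterns.tsv` (taxon, pattern, canonical order) and
#' `distances.tsv` (taxon, shared genes, breakpoint distance, displaced
#' blocks, and the blocks themselves).
#'
#' @param orders list of [gene_order]s.
#' @param reference a [gene_order] or a built-in name
#'   (`"pancrustacean"`, the default).
#' @param out_dir optional output directory.
#' @return list with `patterns` (the [cluster_patterns()] data.frame) and
#'   `distances` (one row per order).
#' @export
compare_orders <- function(orders, reference = "pancrustacean",
                           out_dir = NULL) {
  if (inherits(orders, "gene_order")) orders <- list(orders)
  stopifnot(length(orders) >= 1L,
            all(vapply(orders, inherits, logical(1L), "gene_order")))
  ref <- .resolve_reference(reference)

  pat <- cluster_patterns(orders)
  dist <- do.call(rbind, lapply(orders, function(o) {
    bd <- breakpoint_distance(ref, o)
    blk <- displaced_blocks(ref, o)
    data.frame(taxon = o$taxon,
               n_shared = length(intersect(ref$genes, o$genes)),
               breakpoint_distance = bd,
               n_displaced_blocks = length(blk$displaced),
               displaced_blocks = paste(
                 vapply(blk$displaced, paste, character(1L), collapse = "+"),
                 collapse = ";"),
               exact = blk$exact)
  }))
  rownames(dist) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(pat, file.path(out_dir, "patterns.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(dist, file.path(out_dir, "distances.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(patterns = pat, distances = dist)
}

#' Report rearrangement scenarios between two orders
#'
#' Wraps [infer_scenarios()] and renders each scenario as step-by-step text:
#' the source order, one line per event, and each intermediate order down to
#' the destination. When `out_dir` is given, writes `scenarios.txt`.
#'
#' @param src,dst [gene_order]s over the same gene set.
#' @param out_dir optional output directory.
#' @param ... passed to [infer_scenarios()] (`max_events`, `kinds`,
#'   `max_span`, `max_scenarios`).
#' @return list with `scenarios` (from [infer_scenarios()]) and `text`
#'   (character vector of report lines).
#' @export
infer_report <- function(src, dst, out_dir = NULL, ...) {
  scen <- infer_scenarios(src, dst, ...)
  lines <- c(sprintf("source: %s", paste(format(src), collapse = " ")),
             sprintf("destination: %s", paste(format(dst), collapse = " ")),
             sprintf("scenarios found: %d", length(scen)))
  for (k in seq_along(scen)) {
    sc <- scen[[k]]
    lines <- c(lines, "", sprintf("scenario %d (cost %d):", k, sc$cost))
    for (j in seq_along(sc$events)) {
      lines <- c(lines,
                 sprintf("  step %d: %s", j,
                         format(sc$events[[j]])),
                 sprintf("    -> %s",
                         paste(format(sc$intermediates[[j]]),
                               collapse = " ")))
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(lines, file.path(out_dir, "scenarios.txt"))
  }
  list(scenarios = scen, text = lines)
}
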