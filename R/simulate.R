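# Desk-scale simulator of crab-like mitogenomes: 37 genes + control region
# laid out on a circular genome with realistic lengths, spacers and
# occasional overlaps, sequence drawn i.i.d. from a target base composition,
# and gene orders produced from the pancrustacean ground pattern by a known
# number of sampled rearrangement events. Everything is driven by one seed,
# so identical config + seed gives identical output.

# typical brachyuran PCG lengths (bp) used as the centre of the length model
.PCG_TYPICAL <- c(cox1 = 1539, cox2 = 735, cox3 = 792, nad1 = 930,
                  nad2 = 993, nad3 = 345, nad4 = 1335, nad4L = 276,
                  nad5 = 1671, nad6 = 498, cob = 1137, atp6 = 624,
                  atp8 = 159)

#' Simulation configuration
#'
#' Bundles every tunable of the mitogenome simulator. Defaults emulate a
#' freshwater-crab mitogenome: ~17 kb, strand totals near a real genome's,
#' base composition A 35.5% / T 38.1% / G 9.0% / C 17.5%, tRNAs of
#' 60-75 bp, rRNAs of 800-1400 bp, a 600-1200 bp control region stretched
#' to hit the genome-length target, short intergenic spacers with occasional
#' overlaps up to 47 bp, and rearrangement events drawn mostly from the
#' TDRL mechanism with spans of 2-6 genes.
#'
#' @param seed integer seed driving the single random stream.
#' @param genome_length target genome size in bp.
#' @param base_comp named fractions `c(a=, t=, g=, c=)`; renormalized to
#'   sum to 1, so rounded percentages/100 are accepted as-is.
#' @param codon_weights named non-negative weights over sense codons for
#'   [simulate_cds()] (default uniform).
#' @param n_events number of rearrangement events `k >= 0` for
#'   [simulate_history()].
#' @param event_weights named sampling weights over event kinds.
#' @param span_range min/max genes per event span.
#' @param spacer_range min/max bp of intergenic spacers.
#' @param overlap_prob probability that a junction overlaps instead
#'   (never upstream of a protein-coding gene, whose start codon must
#'   survive); 0 turns overlap sprinkling off.
#' @param overlap_max largest overlap in bp.
#' @param mirror_minus fill minus-strand gene regions with the
#'   complement-mirrored composition (A<->T, G<->C). Off by default so the
#'   whole-genome composition tracks `base_comp` on the genome strand.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, genome_length = 17000L,
                              base_comp = c(a = 0.355, t = 0.381,
                                            g = 0.090, c = 0.175),
                              codon_weights = NULL,
                              n_events = 0L,
                              event_weights = c(tdrl = 0.5,
                                                translocation = 0.3,
                                                inversion = 0.2),
                              span_range = c(2L, 6L),
                              spacer_range = c(0L, 25L),
                              overlap_prob = 0.15, overlap_max = 47L,
                              mirror_minus = FALSE) {
  stopifnot(length(base_comp) == 4L,
            all(c("a", "t", "g", "c") %in% names(base_comp)),
            all(base_comp > 0), abs(sum(base_comp) - 1) < 0.01,
            n_events >= 0L, span_range[1L] >= 1L,
            span_range[2L] >= span_range[1L])
  base_comp <- base_comp / sum(base_comp)
  if (!is.null(codon_weights)) {
    stopifnot(all(codon_weights >= 0))
    if (sum(codon_weights) == 0) stop("zero-weight codon table",
                                      call. = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 base_comp = base_comp[c("a", "t", "g", "c")],
                 codon_weights = codon_weights,
                 n_events = as.integer(n_events),
                 event_weights = event_weights,
                 span_range = as.integer(span_range),
                 spacer_range = as.integer(spacer_range),
                 overlap_prob = overlap_prob,
                 overlap_max = as.integer(overlap_max),
                 mirror_minus = isTRUE(mirror_minus)),
            class = "simulation_config")
}

#' Simulate a rearrangement history
#'
#' Starting from the pancrustacean ground pattern, applies `cfg$n_events`
#' events with kinds sampled by `cfg$event_weights` and uniformly sampled
#' valid parameters (contiguous spans of `cfg$span_range` genes; TDRL loss
#' patterns and translocation destinations resampled until the event
#' actually changes the order). Returns the final order together with the
#' true history, so inference can be scored against the truth.
#'
#' @param cfg a [simulation_config()].
#' @return list with `source` (the ground pattern), `order` (the final
#'   [gene_order]), `events` (list of `rearrangement_event`s).
#' @export
simulate_history <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  src <- ground_pattern()
  cur <- src
  events <- list()
  n <- length(cur$genes)
  for (k in seq_len(cfg$n_events)) {
    kind <- sample(names(cfg$event_weights), 1L,
                   prob = cfg$event_weights)
    for (try in 1:100) {
      l <- sample(seq.int(cfg$span_range[1L], cfg$span_range[2L]), 1L)
      s <- sample.int(n, 1L)
      pos <- ((s - 1L + seq_len(l) - 1L) %% n) + 1L
      span <- cur$genes[pos]
      ev <- switch(kind,
        tdrl = {
          keep1 <- span[sample(c(TRUE, FALSE), l, replace = TRUE)]
          tdrl_event(span, copy1 = keep1)
        },
        inversion = inversion_event(span),
        translocation = {
          after <- sample(setdiff(cur$genes, span), 1L)
          translocation_event(span, after = after)
        })
      nxt <- apply_event(cur, ev)
      if (!order_equal(nxt, cur)) break
      ev <- NULL
    }
    if (is.null(ev)) stop("could not sample an effective event",
                          call. = FALSE)  # unreachable in practice
    events[[k]] <- ev
    cur <- nxt
  }
  cur$taxon <- sprintf("simulated_k%d_seed%d", cfg$n_events, cfg$seed)
  list(source = src, order = cur, events = events)
}

# draw one gene length for the per-category models
.draw_length <- function(gene, category) {
  switch(category,
         PCG = .PCG_TYPICAL[[gene]] + 3L * sample(-10:10, 1L),
         tRNA = sample(60:75, 1L),
         rRNA = if (gene == "rrnL") sample(1200:1400, 1L) else
           sample(800:900, 1L),
         CR = sample(600:1200, 1L))
}

.sample_bases <- function(n, comp) {
  if (n <= 0L) return(character(0L))
  sample(c("A", "T", "G", "C"), n, replace = TRUE, prob = comp)
}

.revcomp_chars <- function(x) rev(chartr("ACGT", "TGCA", x))

#' Simulate an annotated genome with sequence
#'
#' Lays the genes of `order` contiguously on a circular genome: lengths
#' drawn from per-category models (PCG lengths near typical brachyuran
#' values, always multiples of 3), intergenic spacers from
#' `cfg$spacer_range`, and with probability `cfg$overlap_prob` a junction
#' overlaps by up to `cfg$overlap_max` bp (never upstream of a PCG). The
#' control region absorbs the slack so the genome hits
#' `cfg$genome_length`. Sequence bases are drawn i.i.d. from
#' `cfg$base_comp`; each PCG then gets an ATN start and a TAA/TAG stop
#' written on its coding strand and recorded in the annotation, so
#' [validate_annotation()] is clean by construction.
#'
#' @param order a [gene_order]; defaults to the ground pattern.
#' @param cfg a [simulation_config()].
#' @return a [mito_annotation] with sequence.
#' @export
simulate_genome <- function(order = ground_pattern(),
                            cfg = simulation_config()) {
  stopifnot(inherits(order, "gene_order"), inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 1L)
  genes <- order$genes
  cats <- gene_category(genes)
  if (anyNA(cats)) stop("order contains unknown symbols", call. = FALSE)
  ng <- length(genes)

  lens <- vapply(seq_len(ng), function(i) .draw_length(genes[i], cats[i]),
                 numeric(1L))
  spacers <- if (ng > 1L)
    sample(seq.int(cfg$spacer_range[1L], cfg$spacer_range[2L]), ng - 1L,
           replace = TRUE) else integer(0L)
  # overlap sprinkling: junction i sits between gene i and gene i+1
  if (cfg$overlap_prob > 0 && ng > 1L) {
    for (i in seq_len(ng - 1L)) {
      if (cats[i + 1L] != "PCG" && stats::runif(1L) < cfg$overlap_prob) {
        cap <- min(cfg$overlap_max, lens[i] - 1L, lens[i + 1L] - 1L)
        if (cap >= 1L) spacers[i] <- -sample.int(cap, 1L)
      }
    }
  }

  # stretch (or trim) the control region toward the genome-length target
  total <- sum(lens) + sum(spacers)
  cr <- which(cats == "CR")
  if (length(cr) == 1L) {
    adj <- cfg$genome_length - total
    lens[cr] <- max(200L, lens[cr] + adj)
  }

  starts <- 1L + c(0L, cumsum(lens[-ng] + spacers))
  ends <- starts + lens - 1L
  glen <- ends[ng]

  seq_chars <- .sample_bases(glen, cfg$base_comp)
  signs <- order$signs
  if (cfg$mirror_minus) {
    mirr <- cfg$base_comp[c("t", "a", "c", "g")]
    for (i in which(signs < 0L)) {
      idx <- seq.int(starts[i], ends[i])
      seq_chars[idx] <- .sample_bases(length(idx), mirr)
    }
  }

  start_codon <- rep(NA_character_, ng)
  stop_codon <- rep(NA_character_, ng)
  for (i in which(cats == "PCG")) {
    sc <- sample(c("ATG", "ATT", "ATA"), 1L)
    tc <- sample(c("TAA", "TAG"), 1L)
    start_codon[i] <- sc; stop_codon[i] <- tc
    if (signs[i] > 0L) {
      seq_chars[starts[i] + 0:2] <- strsplit(sc, "")[[1L]]
      seq_chars[ends[i] - 2:0] <- strsplit(tc, "")[[1L]]
    } else {
      seq_chars[ends[i] - 2:0] <- .revcomp_chars(strsplit(sc, "")[[1L]])
      seq_chars[starts[i] + 0:2] <- .revcomp_chars(strsplit(tc, "")[[1L]])
    }
  }

  records <- data.frame(gene = genes, start = starts, end = ends,
                        strand = ifelse(cats == "CR", NA_character_,
                                        ifelse(signs < 0L, "-", "+")),
                        start_codon = start_codon, stop_codon = stop_codon)
  mito_annotation(records, genome_length = glen,
                  taxon = order$taxon, circular = TRUE,
                  sequence = paste(seq_chars, collapse = ""))
}

#' Simulate a coding sequence from codon weights
#'
#' `ATG`, then `n_codons` draws from `cfg$codon_weights` over the 62 sense
#' codons of the invertebrate mitochondrial code (uniform when unset), then
#' `TAA`.
#'
#' @param cfg a [simulation_config()].
#' @param n_codons number of weighted codon draws.
#' @return a coding sequence string.
#' @examples
#' simulate_cds(simulation_config(seed = 7), 0)  # "ATGTAA"
#' @export
simulate_cds <- function(cfg = simulation_config(), n_codons) {
  stopifnot(inherits(cfg, "simulation_config"), n_codons >= 0L)
  set.seed(cfg$seed + 2L)
  sense <- sense_codons()
  w <- cfg$codon_weights
  if (is.null(w)) w <- stats::setNames(rep(1, length(sense)), sense)
  w <- w[sense]
  w[is.na(w)] <- 0
  if (sum(w) == 0) stop("zero-weight codon table", call. = FALSE)
  body <- if (n_codons > 0L)
    paste(sample(sense, n_codons, replace = TRUE, prob = w), collapse = "")
  else ""
  paste0("ATG", body, "TAA")
}
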