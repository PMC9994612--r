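# Mechanistic rearrangement events on signed circular gene orders.
#
# TDRL (tandem duplication-random loss): a contiguous span is duplicated
# head-to-tail; from each duplicated gene pair one copy is lost. The
# survivors of copy 1 (in span order) are followed by the survivors of
# copy 2 (in span order), spliced into the span's position; orientations
# never change. Single-TDRL products of a span are therefore exactly the
# span permutations whose index sequence has at most one descent
# (equivalently: the inverse is a two-pile riffle).
#
# Inversion reverses a span and flips every orientation in it; translocation
# (synonym: transposition) excises a span and reinserts it, orientations
# preserved, after a destination gene.

#' Construct rearrangement events
#'
#' Events are described at the gene level so they can be replayed on any
#' order in which the span is contiguous: `span` is the vector of (unsigned)
#' gene symbols of the affected block in pre-event order.
#'
#' @param span character vector of gene symbols, contiguous in the pre-event
#'   order.
#' @param copy1 for TDRL: the span genes retained from the first copy of the
#'   duplicated block (the rest survive in the second copy).
#' @param after for translocation: the gene immediately after which the
#'   excised block is reinserted; must not lie inside the span.
#' @return an object of class `rearrangement_event`.
#' @examples
#' tdrl_event(c("trnE", "trnF", "nad5", "trnH", "nad4"),
#'            copy1 = c("trnE", "trnH"))
#' @name rearrangement_event
NULL

#' @rdname rearrangement_event
#' @export
tdrl_event <- function(span, copy1) {
  span <- normalize_gene_names(span)
  copy1 <- normalize_gene_names(copy1)
  if (length(span) == 0L) stop("empty span", call. = FALSE)
  if (!all(copy1 %in% span))
    stop("copy assignment names gene(s) outside the span: ",
         paste(setdiff(copy1, span), collapse = ", "), call. = FALSE)
  structure(list(kind = "tdrl", span = span, copy1 = copy1),
            class = "rearrangement_event")
}

#' @rdname rearrangement_event
#' @export
inversion_event <- function(span) {
  span <- normalize_gene_names(span)
  if (length(span) == 0L) stop("empty span", call. = FALSE)
  structure(list(kind = "inversion", span = span),
            class = "rearrangement_event")
}

#' @rdname rearrangement_event
#' @export
translocation_event <- function(span, after) {
  span <- normalize_gene_names(span)
  after <- normalize_gene_names(after)
  if (length(span) == 0L) stop("empty span", call. = FALSE)
  stopifnot(length(after) == 1L)
  if (after %in% span)
    stop("destination adjacency lies inside the span", call. = FALSE)
  structure(list(kind = "translocation", span = span, after = after),
            class = "rearrangement_event")
}

#' @exportS3Method base::format
format.rearrangement_event <- function(x, ...) {
  extra <- switch(x$kind,
                  tdrl = paste0(" keep1={", paste(x$copy1, collapse = ","),
                                "}"),
                  translocation = paste0(" -> after ", x$after),
                  "")
  sprintf("<%s> span [%s]%s", x$kind, paste(x$span, collapse = ","), extra)
}

#' @export
print.rearrangement_event <- function(x, ...) {
  cat(format(x), "\n", sep = "")
  invisible(x)
}

# circular positions of a contiguous span of (unsigned) gene names
span_positions <- function(order, span) {
  n <- length(order$genes)
  if (length(span) >= n)
    stop("span must be shorter than the whole order", call. = FALSE)
  i0 <- match(span[1L], order$genes)
  if (is.na(i0))
    stop("span gene absent from order: ", span[1L], call. = FALSE)
  pos <- ((i0 - 1L + seq_along(span) - 1L) %% n) + 1L
  if (!identical(order$genes[pos], span))
    stop("span is not contiguous in the order: ",
         paste(span, collapse = ","), call. = FALSE)
  pos
}

# rebuild a gene_order with span positions replaced by new (signed) content
splice_span <- function(order, pos, genes, signs) {
  g <- order$genes; s <- order$signs
  g[pos] <- genes; s[pos] <- signs
  gene_order(g, s, taxon = order$taxon)
}

#' Apply a tandem duplication-random loss event
#'
#' The span is duplicated head-to-tail and one copy of each gene is lost:
#' the result replaces the span by the `copy1` survivors (in span order)
#' followed by the remaining genes (in span order). Orientations are
#' unchanged. `copy1 = span` (or `character(0)`) is the identity loss
#' pattern.
#'
#' @param order a [gene_order].
#' @param span contiguous block of gene symbols in pre-event order.
#' @param copy1 genes kept from the first copy.
#' @return the rearranged [gene_order].
#' @examples
#' o <- ground_pattern()
#' apply_tdrl(o, c("trnE", "trnF", "nad5", "trnH", "nad4"),
#'            copy1 = c("trnE", "trnH"))
#' @export
apply_tdrl <- function(order, span, copy1) {
  ev <- tdrl_event(span, copy1)
  pos <- span_positions(order, ev$span)
  keep1 <- ev$span %in% ev$copy1
  new_idx <- c(which(keep1), which(!keep1))
  splice_span(order, pos, order$genes[pos][new_idx],
              order$signs[pos][new_idx])
}

#' Apply an inversion
#'
#' The span is reversed in place and every orientation in it is flipped.
#'
#' @inheritParams apply_tdrl
#' @return the rearranged [gene_order].
#' @export
apply_inversion <- function(order, span) {
  ev <- inversion_event(span)
  pos <- span_positions(order, ev$span)
  splice_span(order, pos, rev(order$genes[pos]), -rev(order$signs[pos]))
}

#' Apply a translocation (transposition)
#'
#' The span is excised and reinserted, orientations preserved, immediately
#' after `after` in the remaining order.
#'
#' @inheritParams apply_tdrl
#' @param after destination gene (not inside the span).
#' @return the rearranged [gene_order].
#' @export
apply_translocation <- function(order, span, after) {
  ev <- translocation_event(span, after)
  pos <- span_positions(order, ev$span)
  g <- order$genes[-pos]; s <- order$signs[-pos]
  j <- match(ev$after, g)
  gene_order(append(g, order$genes[pos], after = j),
             append(s, order$signs[pos], after = j),
             taxon = order$taxon)
}

#' Apply any rearrangement event
#'
#' @param order a [gene_order].
#' @param event a `rearrangement_event` from [tdrl_event()],
#'   [inversion_event()] or [translocation_event()].
#' @return the rearranged [gene_order].
#' @export
apply_event <- function(order, event) {
  stopifnot(inherits(event, "rearrangement_event"))
  switch(event$kind,
         tdrl = apply_tdrl(order, event$span, event$copy1),
         inversion = apply_inversion(order, event$span),
         translocation = apply_translocation(order, event$span, event$after),
         stop("unknown event kind: ", event$kind, call. = FALSE))
}

## ---- scenarios -------------------------------------------------------------

#' Construct a rearrangement scenario
#'
#' An ordered list of events carrying a source order into a result order.
#'
#' @param source,result [gene_order] objects.
#' @param events list of `rearrangement_event`s.
#' @param weights optional named numeric cost per event kind (default 1
#'   each).
#' @return object of class `scenario`: `source`, `events`, `result`,
#'   `intermediates` (orders after each event), `cost`.
#' @export
new_scenario <- function(source, events, result = NULL, weights = NULL) {
  cur <- source
  inters <- vector("list", length(events))
  for (i in seq_along(events)) {
    cur <- apply_event(cur, events[[i]])
    inters[[i]] <- cur
  }
  if (is.null(result)) result <- cur
  kinds <- vapply(events, `[[`, character(1L), "kind")
  w <- if (is.null(weights)) rep(1, length(events)) else {
    stopifnot(all(kinds %in% names(weights)))
    unname(weights[kinds])
  }
  structure(list(source = source, events = events, result = result,
                 intermediates = inters, cost = sum(w)),
            class = "scenario")
}

#' Verify that a scenario replays
#'
#' Applies the events in order to the source and tests circular equality of
#' the outcome with the stated result. Never throws: span preconditions
#' broken mid-replay make the scenario invalid, with a diagnostic attached.
#'
#' @param scenario a `scenario`.
#' @return logical; attribute `"detail"` explains a `FALSE`.
#' @export
verify_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  cur <- scenario$source
  for (i in seq_along(scenario$events)) {
    cur <- tryCatch(apply_event(cur, scenario$events[[i]]),
                    error = function(e)
                      structure(NA, detail = sprintf("event %d failed: %s", i,
                                                     conditionMessage(e))))
    if (!inherits(cur, "gene_order"))
      return(structure(FALSE, detail = attr(cur, "detail")))
  }
  ok <- order_equal(cur, scenario$result)
  if (!ok) return(structure(FALSE,
                            detail = "replayed order differs from stated result"))
  TRUE
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s -> %s, %d event(s), cost %g\n",
              x$source$taxon, x$result$taxon, length(x$events), x$cost))
  for (i in seq_along(x$events)) {
    cat(sprintf("  step %d: ", i)); print(x$events[[i]])
    cat("    -> ", format(x$intermediates[[i]]), "\n", sep = "")
  }
  invisible(x)
}

## ---- single-event solvers (exact) ------------------------------------------

# All solvers work on signed integer vectors in a fixed reading direction;
# reflection equivalence is handled by the caller running them against the
# target and its reflection.

rot_to <- function(v, i) if (i == 1L) v else c(v[i:length(v)], v[seq_len(i - 1L)])

# maximal runs of cur whose internal adjacencies all occur (same direction,
# same signs) in dst; `good` is adj_keys(vcur) %in% adj_keys(vdst), with at
# least one FALSE (all TRUE means cur and dst are rotations of each other)
good_runs <- function(good) {
  n <- length(good)
  bad <- which(!good)
  starts <- (bad %% n) + 1L
  ends <- c(bad[-1L], bad[1L] + n)
  ends <- ((ends - 1L) %% n) + 1L
  block_members(starts, ends, n)
}

solve1_tdrl <- function(vcur, vdst, runs) {
  n <- length(vcur)
  for (C in runs[order(-lengths(runs))]) {
    l <- n - length(C)
    if (l < 2L) next
    span_pos <- setdiff(rot_to(seq_len(n), ((C[length(C)]) %% n) + 1L),
                        C)
    span_cur <- vcur[span_pos]
    p <- match(vcur[C[length(C)]], vdst)
    span_dst <- vdst[((p + seq_len(l) - 1L) %% n) + 1L]
    idx <- match(span_dst, span_cur)
    if (anyNA(idx)) next
    d <- which(diff(idx) < 0L)
    if (length(d) != 1L) next
    copy1 <- span_dst[seq_len(d)]
    return(list(kind = "tdrl",
                event = tdrl_event(mito_genes()[abs(span_cur)],
                                   copy1 = mito_genes()[abs(copy1)])))
  }
  NULL
}

solve1_inversion <- function(vcur, vdst) {
  n <- length(vcur)
  scur <- integer(39L); scur[abs(vcur)] <- sign(vcur)
  sdst <- integer(39L); sdst[abs(vdst)] <- sign(vdst)
  flipped <- which(scur != sdst & scur != 0L)
  if (length(flipped) == 0L || length(flipped) >= n) return(NULL)
  pos <- sort(match(flipped, abs(vcur)))
  # contiguity on the circle: either one run, or a run wrapping the origin
  gaps <- diff(pos)
  if (sum(gaps > 1L) > 1L) return(NULL)
  if (any(gaps > 1L)) {  # wraps: rotate so the run is linear
    cut <- pos[which(gaps > 1L) + 1L]
    vc <- rot_to(vcur, cut)
    pos <- sort(match(flipped, abs(vc)))
    if (any(diff(pos) > 1L)) return(NULL)
  } else vc <- vcur
  span_pos <- pos
  product <- vc
  product[span_pos] <- -rev(vc[span_pos])
  # compare product to vdst up to rotation (directed)
  p <- match(product[1L], vdst)
  if (is.na(p)) return(NULL)
  if (!identical(rot_to(vdst, p), product)) return(NULL)
  list(kind = "inversion",
       event = inversion_event(mito_genes()[abs(vc[span_pos])]))
}

solve1_translocation <- function(vcur, vdst, runs) {
  n <- length(vcur)
  for (B in runs[order(lengths(runs))]) {
    if (length(B) >= n - 1L) next
    rcur <- vcur[-B]
    rdst <- vdst[!vdst %in% vcur[B]]
    p <- match(rcur[1L], rdst)
    if (is.na(p)) next
    if (!identical(rot_to(rdst, p), rcur)) next
    q <- match(vcur[B[1L]], vdst)
    after <- vdst[((q - 2L) %% n) + 1L]
    if (after %in% vcur[B]) next
    return(list(kind = "translocation",
                event = translocation_event(mito_genes()[abs(vcur[B])],
                                            after = mito_genes()[abs(after)])))
  }
  NULL
}

# precomputed per-target context: the reading (vdst and its reflection),
# its sorted element multiset, and its adjacency key set
solve1_targets <- function(vdst) {
  lapply(list(vdst, -rev(vdst)), function(v)
    list(v = v, srt = sort.int(v, method = "quick"), adj = adj_keys(v)))
}

# all single events carrying cur onto dst (up to rotation/reflection),
# one representative per kind, in the order kinds are listed; `ctxs` from
# solve1_targets(vdst)
solve1 <- function(vcur, ctxs, kinds) {
  out <- list()
  cadj <- adj_keys(vcur)
  csrt <- sort.int(vcur, method = "quick")
  for (ctx in ctxs) {
    good <- cadj %in% ctx$adj
    if (all(good)) next  # rotation-equal already: no event needed
    same_set <- identical(csrt, ctx$srt)
    runs <- if (same_set) good_runs(good) else NULL
    for (k in kinds) {
      if (!is.null(out[[k]])) next
      sol <- switch(k,
                    tdrl = if (same_set) solve1_tdrl(vcur, ctx$v, runs),
                    inversion = solve1_inversion(vcur, ctx$v),
                    translocation = if (same_set)
                      solve1_translocation(vcur, ctx$v, runs))
      if (!is.null(sol)) out[[k]] <- sol
    }
  }
  unname(out)
}

## ---- move enumeration (intermediate search levels) -------------------------

enumerate_moves <- function(vcur, kinds, max_span) {
  n <- length(vcur)
  names <- mito_genes()
  moves <- list()
  seen <- new.env(hash = TRUE, parent = emptyenv())
  push <- function(ev, prod) {
    key <- paste(canon_ints(prod), collapse = ",")
    if (!is.null(seen[[key]])) return(invisible(NULL))
    seen[[key]] <- TRUE
    moves[[length(moves) + 1L]] <<- list(event = ev, product = prod)
  }
  span_idx <- function(s, l) ((s - 1L + seq_len(l) - 1L) %% n) + 1L
  seen[[paste(canon_ints(vcur), collapse = ",")]] <- TRUE  # never emit identity

  if ("tdrl" %in% kinds) {
    for (l in 2L:min(max_span, n - 1L)) {
      masks <- lapply(seq_len(2L^l - 2L), function(m)
        as.logical(bitwAnd(m, 2L^(seq_len(l) - 1L)) > 0L))
      for (s in seq_len(n)) {
        pos <- span_idx(s, l)
        sp <- vcur[pos]
        for (keep1 in masks) {
          prod <- vcur
          prod[pos] <- c(sp[keep1], sp[!keep1])
          push(list(kind = "tdrl", span = names[abs(sp)],
                    copy1 = names[abs(sp[keep1])]), prod)
        }
      }
    }
  }
  if ("translocation" %in% kinds) {
    for (l in seq_len(min(max_span, n - 2L))) {
      for (s in seq_len(n)) {
        pos <- span_idx(s, l)
        rest <- vcur[-pos]
        m <- length(rest)
        for (j in seq_len(m)) {
          # inserting after rest[j]; j == position just before span is a no-op
          prod <- append(rest, vcur[pos], after = j)
          push(list(kind = "translocation", span = names[abs(vcur[pos])],
                    after = names[abs(rest[j])]), prod)
        }
      }
    }
  }
  if ("inversion" %in% kinds) {
    for (l in seq_len(min(max_span, n - 1L))) {
      for (s in seq_len(n)) {
        pos <- span_idx(s, l)
        prod <- vcur
        prod[pos] <- -rev(vcur[pos])
        push(list(kind = "inversion", span = names[abs(vcur[pos])]), prod)
      }
    }
  }
  moves
}

## ---- scenario inference ----------------------------------------------------

#' Infer rearrangement scenarios between two gene orders
#'
#' Searches for minimal-cost ordered event lists (events counted 1 each)
#' transforming `src` into `dst`, by iterative deepening up to `max_events`.
#' The final step of every path is solved exactly and analytically (a single
#' TDRL, inversion or translocation reaching `dst` is found in polynomial
#' time from the shared-adjacency structure); intermediate steps enumerate
#' candidate events with spans up to `max_span` genes. Scenarios are
#' deduplicated by their event list and intermediate orders (the same
#' product reached by mechanistically different events — a translocation is
#' also a TDRL — yields one scenario per explanation); results are
#' deterministic and invariant under rotation of either input.
#'
#' With `kinds = "tdrl"` and `max_events = 1` the search reproduces the
#' brute-force two-riffle enumeration of single-TDRL products.
#'
#' @param src,dst [gene_order] objects over the same gene set.
#' @param max_events search depth (exhaustive intermediate enumeration is
#'   practical up to 3).
#' @param kinds allowed event kinds, a subset of
#'   `c("tdrl", "inversion", "translocation")` (`"transposition"` is
#'   accepted as a synonym of translocation).
#' @param max_span span-length cap for enumerated intermediate events (the
#'   final step of a path is not capped).
#' @param max_scenarios stop after this many minimal-cost scenarios
#'   (default all).
#' @return list of `scenario` objects of minimal cost (empty when `dst` is
#'   unreachable within `max_events`); `src == dst` yields one empty
#'   scenario of cost 0.
#' @export
infer_scenarios <- function(src, dst, max_events = 3L,
                            kinds = c("tdrl", "inversion", "translocation"),
                            max_span = 6L, max_scenarios = Inf) {
  stopifnot(inherits(src, "gene_order"), inherits(dst, "gene_order"))
  kinds <- tolower(kinds)
  kinds[kinds == "transposition"] <- "translocation"
  bad <- setdiff(kinds, c("tdrl", "inversion", "translocation"))
  if (length(bad) > 0L) stop("unknown event kind(s): ",
                             paste(bad, collapse = ", "), call. = FALSE)
  kinds <- unique(kinds)
  if (!setequal(src$genes, dst$genes))
    stop("gene sets differ; symmetric difference: ",
         paste(c(setdiff(src$genes, dst$genes),
                 setdiff(dst$genes, src$genes)), collapse = ", "),
         call. = FALSE)

  anchor <- min(match(src$genes, mito_genes()))
  vsrc <- canon_ints(ord_encode(src), anchor)
  vdst <- canon_ints(ord_encode(dst), anchor)
  src_c <- ord_decode(vsrc, taxon = src$taxon)
  dst_c <- ord_decode(vdst, taxon = dst$taxon)

  if (identical(vsrc, vdst))
    return(list(new_scenario(src_c, list(), result = dst_c)))

  found <- list()  # keyed by intermediate-sequence string
  n_found <- function() length(found)
  ctxs <- solve1_targets(vdst)

  # intermediate moves travel as plain spec lists; real event objects are
  # built only for the rare paths that reach dst
  build_event <- function(x) {
    if (inherits(x, "rearrangement_event")) return(x)
    switch(x$kind,
           tdrl = tdrl_event(x$span, x$copy1),
           inversion = inversion_event(x$span),
           translocation = translocation_event(x$span, x$after))
  }

  emit <- function(parts) {
    events <- lapply(parts, build_event)
    sc <- tryCatch(new_scenario(src_c, events, result = dst_c),
                   error = function(e) NULL)
    if (is.null(sc)) return(invisible(NULL))
    if (!isTRUE(order_equal(sc$intermediates[[length(sc$intermediates)]],
                            dst_c))) return(invisible(NULL))
    key <- paste(
      paste(vapply(events, format, character(1L)), collapse = "|"),
      paste(vapply(sc$intermediates, function(o)
        paste(canon_ints(ord_encode(o), anchor), collapse = ","),
        character(1L)), collapse = ";"),
      sep = "#")
    if (is.null(found[[key]])) found[[key]] <<- sc
    invisible(NULL)
  }

  search <- function(vcur, budget, parts_so_far) {
    if (n_found() >= max_scenarios) return(invisible(NULL))
    if (budget == 1L) {
      for (sol in solve1(vcur, ctxs, kinds)) {
        emit(c(parts_so_far, list(sol$event)))
        if (n_found() >= max_scenarios) return(invisible(NULL))
      }
      return(invisible(NULL))
    }
    for (mv in enumerate_moves(vcur, kinds, max_span)) {
      if (circ_equal_ints(mv$product, vdst)) next  # shorter path, found earlier
      search(mv$product, budget - 1L, c(parts_so_far, list(mv$event)))
      if (n_found() >= max_scenarios) return(invisible(NULL))
    }
    invisible(NULL)
  }

  for (cost in seq_len(max_events)) {
    search(vsrc, cost, list())
    if (n_found() > 0L) break
  }
  if (length(found) == 0L) return(list())
  out <- found[order(names(found))]
  names(out) <- NULL
  out
}
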