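# Signed circular gene orders. User-facing objects carry gene symbols and
# +/-1 orientations; the algebra below runs on signed integer vectors
# (sign * vocabulary index), with circular equality defined up to rotation
# and reflection (reading the other strand reverses the order and flips
# every orientation — the same molecule).

#' Construct a signed gene order
#'
#' @param genes character vector of gene symbols (normalized against the
#'   closed vocabulary); no duplicates.
#' @param signs integer vector of orientations (`+1`/`-1`), recycled if of
#'   length 1. The control region is conventionally `+1`.
#' @param taxon label.
#' @return object of class `gene_order`: list with `taxon`, `genes`,
#'   `signs`, and `missing` (vocabulary symbols absent from this order).
#' @examples
#' gene_order(c("cox1", "trnL2", "cox2"), c(1, 1, -1))
#' @export
gene_order <- function(genes, signs = 1L, taxon = "unknown") {
  genes <- normalize_gene_names(genes)
  if (anyDuplicated(genes))
    stop("duplicate gene symbol(s) in order: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  signs <- as.integer(rep_len(signs, length(genes)))
  if (!all(signs %in% c(-1L, 1L)))
    stop("signs must be +1 or -1", call. = FALSE)
  structure(list(taxon = as.character(taxon), genes = genes, signs = signs,
                 missing = setdiff(mito_genes(), genes)),
            class = "gene_order")
}

# "-trnH"-style strings -> gene_order
parse_signed_symbols <- function(syms, taxon = "unknown") {
  neg <- grepl("^-", syms)
  gene_order(sub("^-", "", syms), ifelse(neg, -1L, 1L), taxon = taxon)
}

#' @export
print.gene_order <- function(x, ...) {
  cat(sprintf("<gene_order> %s (%d genes%s)\n", x$taxon, length(x$genes),
              if (length(x$missing) > 0L)
                paste0("; absent: ", paste(x$missing, collapse = ","))
              else ""))
  cat("  ", paste0(ifelse(x$signs < 0L, "-", ""), x$genes, collapse = ","),
      "\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::format
format.gene_order <- function(x, ...) {
  paste0(ifelse(x$signs < 0L, "-", ""), x$genes, collapse = ",")
}

## ---- integer encoding ------------------------------------------------------

ord_encode <- function(o) {
  idx <- match(o$genes, mito_genes())
  as.integer(o$signs * idx)
}

ord_decode <- function(v, taxon = "unknown") {
  gene_order(mito_genes()[abs(v)], sign(v), taxon = taxon)
}

# canonical rotation/reflection: anchor = smallest unsigned id present
# (cox1 when present), oriented +, placed first
canon_ints <- function(v, anchor = NULL) {
  if (is.null(anchor)) anchor <- min(abs(v))
  i <- match(anchor, abs(v))
  if (is.na(i)) stop("anchor gene absent from order", call. = FALSE)
  if (v[i] < 0L) {
    v <- -rev(v)
    i <- match(anchor, abs(v))
  }
  if (i > 1L) v <- c(v[i:length(v)], v[seq_len(i - 1L)])
  v
}

# circular equality up to rotation and reflection
circ_equal_ints <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (length(a) == 0L) return(TRUE)
  anchor <- min(abs(a))
  if (!anchor %in% abs(b)) return(FALSE)
  identical(canon_ints(a, anchor), canon_ints(b, anchor))
}

# directed signed adjacency keys of a circular order (u -> v), encoded as
# (u+38)*80 + (v+38); the reflected form of (u,v) is (-v,-u)
adj_keys <- function(v) {
  nxt <- c(v[-1L], v[1L])
  (v + 38L) * 80L + (nxt + 38L)
}

refl_keys <- function(v) {
  nxt <- c(v[-1L], v[1L])
  (-nxt + 38L) * 80L + (-v + 38L)
}

## ---- user-facing operations ------------------------------------------------

#' Extract the signed gene order of an annotation
#'
#' Records are taken in ascending start order (a wrap-around record sits at
#' its start); plus-strand genes get orientation `+1`, minus-strand `-1`,
#' and the unstranded control region `+1`.
#'
#' @param ann a [mito_annotation].
#' @return a [gene_order].
#' @export
extract_order <- function(ann) {
  stopifnot(inherits(ann, "mito_annotation"))
  r <- ann$records  # already sorted by start
  signs <- ifelse(!is.na(r$strand) & r$strand == "-", -1L, 1L)
  gene_order(r$gene, signs, taxon = ann$taxon)
}

#' Canonicalize a signed gene order
#'
#' Rotates the circular order so `cox1` comes first; if `cox1` lies on the
#' minus strand the whole order is reflected (reversed, all orientations
#' flipped) first, so equal circular orders — equal up to rotation and
#' strand of reading — map to identical canonical forms. Idempotent.
#'
#' @param order a [gene_order] containing `cox1`.
#' @return a [gene_order] in canonical form.
#' @export
canonicalize <- function(order) {
  stopifnot(inherits(order, "gene_order"))
  if (!"cox1" %in% order$genes)
    stop("cox1 absent: cannot canonicalize", call. = FALSE)
  ord_decode(canon_ints(ord_encode(order), anchor = 1L), taxon = order$taxon)
}

#' Test two gene orders for circular equality
#'
#' Equality up to rotation and reflection (strand of reading) of the signed
#' circular order.
#'
#' @param a,b [gene_order] objects.
#' @return logical.
#' @export
order_equal <- function(a, b) {
  if (length(a$genes) != length(b$genes)) return(FALSE)
  if (!setequal(a$genes, b$genes)) return(FALSE)
  circ_equal_ints(ord_encode(a), ord_encode(b))
}

#' Group gene orders into arrangement patterns
#'
#' Orders with identical canonical forms share a pattern; patterns are
#' labeled by size-descending roman numerals (ties broken by first member),
#' mirroring how comparative mitogenomics groups taxa by shared
#' arrangements. With `drop_missing = TRUE` (default) the comparison is done
#' on the gene set shared by all members, so incomplete genomes cluster with
#' their complete relatives.
#'
#' @param orders list of [gene_order] objects.
#' @param drop_missing drop genes absent from any member before comparing.
#' @return data.frame with columns `pattern`, `taxon`, `canonical_order`.
#' @export
cluster_patterns <- function(orders, drop_missing = TRUE) {
  if (inherits(orders, "gene_order")) orders <- list(orders)
  stopifnot(length(orders) >= 1L)
  shared <- Reduce(intersect, lapply(orders, `[[`, "genes"))
  if (length(shared) == 0L) stop("orders share no genes", call. = FALSE)
  keys <- vapply(orders, function(o) {
    v <- ord_encode(o)
    if (drop_missing) v <- v[abs(v) %in% match(shared, mito_genes())]
    paste(canon_ints(v), collapse = ",")
  }, character(1L))
  grp <- split(seq_along(orders), keys)
  grp <- grp[order(-lengths(grp), vapply(grp, min, integer(1L)))]
  out <- do.call(rbind, lapply(seq_along(grp), function(i) {
    idx <- grp[[i]]
    data.frame(pattern = as.character(utils::as.roman(i)),
               taxon = vapply(orders[idx], `[[`, character(1L), "taxon"),
               canonical_order = names(grp)[i] |> decode_key())
  }))
  rownames(out) <- NULL
  out
}

decode_key <- function(key) {
  vapply(key, function(k) {
    v <- as.integer(strsplit(k, ",")[[1L]])
    paste0(ifelse(v < 0L, "-", ""), mito_genes()[abs(v)], collapse = ",")
  }, character(1L), USE.NAMES = FALSE)
}

#' Breakpoint distance between two signed circular gene orders
#'
#' The number of signed adjacencies of `a` absent from `b`, where the
#' adjacency `(u, v)` and its reading on the other strand `(-v, -u)` count
#' as the same. A pseudometric on circular signed orders: symmetric, zero
#' exactly when the canonical forms coincide, and obeying the triangle
#' inequality. Orders with different gene sets are compared on the
#' intersection (absent genes deleted, their neighbours joined).
#'
#' @param a,b [gene_order] objects.
#' @return integer count.
#' @examples
#' breakpoint_distance(ground_pattern(), ground_pattern())  # 0
#' @export
breakpoint_distance <- function(a, b) {
  shared <- intersect(a$genes, b$genes)
  if (length(shared) == 0L) stop("orders share no genes", call. = FALSE)
  ids <- match(shared, mito_genes())
  va <- ord_encode(a); va <- va[abs(va) %in% ids]
  vb <- ord_encode(b); vb <- vb[abs(vb) %in% ids]
  if (length(va) == 1L) return(0L)
  bk <- c(adj_keys(vb), refl_keys(vb))
  sum(!(adj_keys(va) %in% bk))
}

## ---- displaced blocks ------------------------------------------------------

# maximal shared blocks of `obs` against `ref`: runs of obs delimited at
# positions where the obs adjacency is absent from ref (up to reflection)
shared_block_bounds <- function(vref, vobs) {
  rk <- c(adj_keys(vref), refl_keys(vref))
  good <- adj_keys(vobs) %in% rk  # good[i]: adjacency obs[i] -> obs[i+1]
  n <- length(vobs)
  if (all(good)) return(list(starts = 1L, ends = n))  # one block, identical
  bad <- which(!good)
  starts <- (bad %% n) + 1L
  ends <- c(bad[-1L], bad[1L] + n)
  ends <- ((ends - 1L) %% n) + 1L
  # blocks in obs order of their start
  o <- order(starts)
  list(starts = starts[o], ends = ends[o])
}

block_members <- function(starts, ends, n) {
  lapply(seq_along(starts), function(i) {
    if (ends[i] >= starts[i]) seq.int(starts[i], ends[i])
    else c(seq.int(starts[i], n), seq.int(1L, ends[i]))
  })
}

#' Decompose the difference between two gene orders into displaced blocks
#'
#' Finds the minimum number of contiguous signed blocks whose excision from
#' both circular orders leaves identical reduced orders — the blocks whose
#' relocation (as units) explains the difference between `reference` and
#' `observed`. Candidate blocks are the maximal shared blocks of the two
#' orders (a block that moved as a unit is delimited by breakpoints on both
#' sides, so it is its own maximal shared block except in degenerate
#' relandings next to a former neighbour). The search over candidate subsets
#' is exact up to `max_blocks` (default 4); beyond that a greedy pass
#' removes the block whose excision most reduces the breakpoint distance and
#' the result is flagged `exact = FALSE`.
#'
#' Ties among equal-cardinality solutions are broken by minimal total
#' displaced-gene count, then lexicographically by first block symbol, so
#' the output is deterministic.
#'
#' @param reference,observed [gene_order] objects (compared on their shared
#'   gene set).
#' @param max_blocks exact-search budget.
#' @return list of class `block_decomposition`: `displaced` (list of
#'   character vectors of signed symbols, in observed order), `shared`
#'   (the remaining blocks), `n_displaced`, `exact`, `budget_exceeded`.
#' @examples
#' displaced_blocks(ground_pattern(), ground_pattern())$n_displaced  # 0
#' @export
displaced_blocks <- function(reference, observed, max_blocks = 4L) {
  shared_genes <- intersect(reference$genes, observed$genes)
  if (length(shared_genes) == 0L) stop("orders share no genes", call. = FALSE)
  ids <- match(shared_genes, mito_genes())
  vref <- ord_encode(reference); vref <- vref[abs(vref) %in% ids]
  vobs <- ord_encode(observed); vobs <- vobs[abs(vobs) %in% ids]
  n <- length(vobs)

  bb <- shared_block_bounds(vref, vobs)
  members <- block_members(bb$starts, bb$ends, n)
  m <- length(members)

  sym <- function(idx) paste0(ifelse(vobs[idx] < 0L, "-", ""),
                              mito_genes()[abs(vobs[idx])])
  as_result <- function(sel, exact, budget_exceeded = FALSE) {
    displaced <- lapply(members[sel], sym)
    kept <- if (length(sel) > 0L) members[-sel] else members
    structure(list(displaced = displaced, shared = lapply(kept, sym),
                   n_displaced = length(displaced), exact = exact,
                   budget_exceeded = budget_exceeded),
              class = "block_decomposition")
  }

  works <- function(sel) {
    drop <- unlist(members[sel])
    ro <- if (length(drop) > 0L) vobs[-drop] else vobs
    rr <- vref[abs(vref) %in% abs(ro)]
    circ_equal_ints(rr, ro)
  }

  if (circ_equal_ints(vref, vobs)) return(as_result(integer(0L), TRUE))

  for (k in seq_len(min(max_blocks, m - 1L))) {
    sels <- utils::combn(m, k, simplify = FALSE)
    ok <- Filter(works, sels)
    if (length(ok) > 0L) {
      sizes <- vapply(ok, function(s) sum(lengths(members[s])), integer(1L))
      first <- vapply(ok, function(s)
        paste(sort(vapply(members[s], function(ix) sym(ix)[1L],
                          character(1L)))[1L]), character(1L))
      best <- ok[[order(sizes, first)[1L]]]
      return(as_result(best, TRUE))
    }
  }

  # greedy fallback: peel off blocks that reduce the breakpoint count most
  sel <- integer(0L)
  repeat {
    if (works(sel)) return(as_result(sel, FALSE, budget_exceeded = TRUE))
    rem <- setdiff(seq_len(m), sel)
    if (length(rem) <= 1L) return(as_result(sel, FALSE, budget_exceeded = TRUE))
    score <- vapply(rem, function(j) {
      drop <- unlist(members[c(sel, j)])
      ro <- vobs[-drop]
      rr <- vref[abs(vref) %in% abs(ro)]
      if (length(ro) <= 1L) 0L else
        sum(!(adj_keys(ro) %in% c(adj_keys(rr), refl_keys(rr))))
    }, integer(1L))
    sel <- c(sel, rem[which.min(score)])
  }
}

#' @export
print.block_decomposition <- function(x, ...) {
  cat(sprintf("<block_decomposition> %d displaced block(s)%s\n",
              x$n_displaced,
              if (!x$exact) " [greedy, block budget exceeded]" else ""))
  for (b in x$displaced) cat("  displaced: ", paste(b, collapse = ","), "\n",
                             sep = "")
  invisible(x)
}
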