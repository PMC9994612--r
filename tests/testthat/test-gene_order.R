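rotate_order <- function(o, k) {
  n <- length(o$genes)
  i <- ((seq_len(n) - 1L + k) %% n) + 1L
  gene_order(o$genes[i], o$signs[i], taxon = o$taxon)
}

reflect_order <- function(o) {
  gene_order(rev(o$genes), -rev(o$signs), taxon = o$taxon)
}

test_that("the ancestral arrangement has 38 signed symbols", {
  gp <- ground_pattern()
  expect_length(gp$genes, 38L)
  expect_identical(sum(gp$signs < 0L), 14L)
  expect_identical(gp$genes[1L], "cox1")
  expect_length(gp$missing, 0L)
})

test_that("orders extracted from annotations follow genomic start order", {
  o <- extract_order(chishuiense())
  expect_length(o$genes, 38L)
  expect_identical(o$genes[1L], "cox1")
  expect_identical(o$signs[o$genes == "nad5"], -1L)
  expect_identical(o$signs[o$genes == "CR"], 1L)
})

test_that("canonicalization is invariant under rotation and reflection", {
  o <- extract_order(chishuiense())
  can <- canonicalize(o)
  expect_identical(can$genes[1L], "cox1")
  expect_identical(can$signs[1L], 1L)
  for (k in c(1L, 7L, 19L)) {
    expect_identical(canonicalize(rotate_order(o, k))$genes, can$genes)
    expect_identical(canonicalize(rotate_order(o, k))$signs, can$signs)
  }
  refl <- canonicalize(reflect_order(o))
  expect_identical(refl$genes, can$genes)
  expect_identical(refl$signs, can$signs)
  expect_identical(canonicalize(can)$genes, can$genes)  # idempotent
  no_cox1 <- gene_order(c("trnK", "trnD"), c(1L, 1L))
  expect_error(canonicalize(no_cox1), "cox1")
})

test_that("circular equality holds up to rotation and reflection only", {
  gp <- ground_pattern()
  expect_true(order_equal(gp, rotate_order(gp, 13L)))
  expect_true(order_equal(gp, reflect_order(gp)))
  flipped <- gp; flipped$signs[2L] <- -flipped$signs[2L]
  expect_false(order_equal(gp, flipped))
  swapped <- rotate_order(gp, 0L)
  swapped$genes[1:2] <- swapped$genes[2:1]
  swapped$signs[1:2] <- swapped$signs[2:1]
  expect_false(order_equal(gp, swapped))
})

test_that("both fixture genomes share one arrangement pattern", {
  orders <- list(extract_order(chishuiense()), extract_order(wushanense()))
  pat <- cluster_patterns(orders)
  expect_identical(unique(pat$pattern), "I")
  # a genuinely different arrangement opens pattern II
  other <- apply_inversion(ground_pattern(), c("trnK", "trnD"))
  pat2 <- cluster_patterns(c(orders, list(other)))
  expect_identical(pat2$pattern[pat2$taxon == "pancrustacean"], "II")
})

test_that("patterns are labeled by size-descending roman numerals", {
  gp <- ground_pattern()
  a <- rotate_order(gp, 3L); a$taxon <- "a"
  b <- reflect_order(gp); b$taxon <- "b"
  c_ <- apply_inversion(gp, c("trnK", "trnD")); c_$taxon <- "c"
  pat <- cluster_patterns(list(c_, a, b))
  expect_identical(pat$pattern[pat$taxon %in% c("a", "b")], c("I", "I"))
  expect_identical(pat$pattern[pat$taxon == "c"], "II")
})

test_that("breakpoint distance is a pseudometric counting lost adjacencies", {
  gp <- ground_pattern()
  obs <- extract_order(chishuiense())
  expect_identical(breakpoint_distance(gp, gp), 0L)
  expect_identical(breakpoint_distance(gp, rotate_order(gp, 9L)), 0L)
  expect_identical(breakpoint_distance(gp, reflect_order(gp)), 0L)
  d <- breakpoint_distance(gp, obs)
  expect_identical(d, breakpoint_distance(obs, gp))
  expect_gt(d, 0L)
  # independent oracle: count adjacencies of gp absent from obs
  adj_set <- function(o) {
    s <- paste0(ifelse(o$signs < 0L, "-", ""), o$genes)
    nxt <- c(s[-1L], s[1L])
    flip <- function(x) ifelse(grepl("^-", x), sub("^-", "", x),
                               paste0("-", x))
    union(paste(s, nxt), paste(flip(nxt), flip(s)))
  }
  s <- paste0(ifelse(gp$signs < 0L, "-", ""), gp$genes)
  own <- paste(s, c(s[-1L], s[1L]))
  expect_identical(d, sum(!own %in% adj_set(obs)))
})

test_that("orders with partial gene sets compare on the intersection", {
  gp <- ground_pattern()
  partial <- extract_order(wushanense())  # lacks trnI
  expect_identical(length(intersect(gp$genes, partial$genes)), 37L)
  d <- breakpoint_distance(gp, partial)
  expect_identical(d, breakpoint_distance(partial, gp))
  # deleting a gene joins its neighbours, so distance to itself is still 0
  expect_identical(breakpoint_distance(partial, partial), 0L)
})

test_that("a single translocated block is recovered as one displaced block", {
  gp <- ground_pattern()
  moved <- apply_translocation(gp, c("trnK", "trnD"), after = "nad3")
  blk <- displaced_blocks(gp, moved)
  expect_identical(blk$n_displaced, 1L)
  expect_identical(blk$displaced[[1L]], c("trnK", "trnD"))
  expect_true(blk$exact)
  same <- displaced_blocks(gp, rotate_order(gp, 5L))
  expect_identical(same$n_displaced, 0L)
})

test_that("ties between decompositions resolve to fewest displaced genes", {
  gp <- ground_pattern()
  obs <- extract_order(chishuiense())
  blk <- displaced_blocks(gp, obs)
  expect_true(blk$exact)
  expect_identical(blk$n_displaced, 3L)
  members <- vapply(blk$displaced, paste, character(1L), collapse = ",")
  expect_true("-trnH" %in% members)
  expect_true("-trnQ" %in% members)
  expect_true("trnM,nad2,trnW,-trnC,-trnY" %in% members)
})

test_that("block decompositions beyond the exact budget are flagged greedy", {
  gp <- ground_pattern()
  scrambled <- gp
  # many independent relocations defeat a 1-block budget
  moves <- list(c("trnK", "nad5"), c("trnG", "rrnS"), c("trnT", "cox2"),
                c("trnV", "nad3"), c("trnW", "trnP"))
  for (m in moves)
    scrambled <- apply_translocation(scrambled, m[1L], after = m[2L])
  blk <- displaced_blocks(gp, scrambled, max_blocks = 1L)
  expect_false(blk$exact)
  expect_true(blk$budget_exceeded)
})
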