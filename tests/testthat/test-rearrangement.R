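test_that("TDRL keeps copy-1 survivors before copy-2 survivors, signs intact", {
  gp <- ground_pattern()
  span <- c("trnE", "trnF", "nad5", "trnH", "nad4")
  out <- apply_tdrl(gp, span, copy1 = c("trnE", "trnH"))
  i <- match("trnE", out$genes)
  expect_identical(out$genes[i:(i + 4L)],
                   c("trnE", "trnH", "trnF", "nad5", "nad4"))
  expect_identical(out$signs[i:(i + 4L)], c(1L, -1L, -1L, -1L, -1L))
  # identity loss patterns leave the order unchanged
  expect_true(order_equal(apply_tdrl(gp, span, copy1 = span), gp))
  expect_true(order_equal(apply_tdrl(gp, span, copy1 = character(0)), gp))
  expect_error(apply_tdrl(gp, span, copy1 = "cox1"), "outside the span")
})

test_that("inversion reverses a span and flips orientations; twice is identity", {
  gp <- ground_pattern()
  out <- apply_inversion(gp, c("trnK", "trnD", "atp8"))
  i <- match("atp8", out$genes)
  expect_identical(out$genes[i:(i + 2L)], c("atp8", "trnD", "trnK"))
  expect_identical(out$signs[i:(i + 2L)], c(-1L, -1L, -1L))
  back <- apply_inversion(out, c("atp8", "trnD", "trnK"))
  expect_true(order_equal(back, gp))
})

test_that("translocation excises a span and reinserts it after the target", {
  gp <- ground_pattern()
  out <- apply_translocation(gp, c("trnK", "trnD"), after = "nad3")
  j <- match("nad3", out$genes)
  expect_identical(out$genes[(j + 1L):(j + 2L)], c("trnK", "trnD"))
  expect_error(apply_translocation(gp, c("trnK", "trnD"), after = "trnD"),
               "inside the span")
  expect_error(apply_tdrl(gp, c("trnK", "atp8"), copy1 = "trnK"),
               "not contiguous")
})

test_that("spans wrap the circular origin transparently", {
  gp <- ground_pattern()
  span <- c("trnY", "cox1", "trnL2")  # last gene joined to the first two
  out <- apply_inversion(gp, span)
  expect_true("cox1" %in% out$genes)
  expect_identical(out$signs[match("cox1", out$genes)], -1L)
  expect_true(order_equal(apply_inversion(out, rev(span)), gp))
})

test_that("scenarios replay their events and verification is honest", {
  gp <- ground_pattern()
  ev <- list(tdrl_event(c("trnE", "trnF", "nad5", "trnH", "nad4"),
                        copy1 = c("trnE", "trnH")),
             translocation_event("trnK", after = "nad3"))
  sc <- new_scenario(gp, ev)
  expect_identical(sc$cost, 2)
  expect_length(sc$intermediates, 2L)
  expect_true(verify_scenario(sc))
  lie <- sc
  lie$result <- gp
  v <- verify_scenario(lie)
  expect_false(v)
  expect_match(attr(v, "detail"), "differs")
})

test_that("a broken span precondition invalidates a scenario without throwing", {
  gp <- ground_pattern()
  # second event's span is no longer contiguous after the first
  sc <- new_scenario(gp, list(translocation_event("trnD", after = "nad3")))
  sc$events <- c(sc$events, list(inversion_event(c("trnK", "trnD"))))
  v <- verify_scenario(sc)
  expect_false(v)
  expect_match(attr(v, "detail"), "event 2")
})

test_that("identical source and destination yield one empty scenario", {
  gp <- ground_pattern()
  sc <- infer_scenarios(gp, gp)
  expect_length(sc, 1L)
  expect_identical(sc[[1L]]$cost, 0)
  expect_length(sc[[1L]]$events, 0L)
})

test_that("single events of every kind are inferred back exactly", {
  gp <- ground_pattern()
  cases <- list(
    tdrl = apply_tdrl(gp, c("trnA", "trnR", "trnN", "trnS1"),
                      copy1 = c("trnR", "trnS1")),
    inversion = apply_inversion(gp, c("trnG", "nad3", "trnA")),
    translocation = apply_translocation(gp, c("trnT", "trnP"),
                                        after = "trnM"))
  for (kind in names(cases)) {
    sc <- infer_scenarios(gp, cases[[kind]], max_events = 1)
    expect_gte(length(sc), 1L)
    kinds_found <- vapply(sc, function(s) s$events[[1L]]$kind, character(1L))
    expect_true(kind %in% kinds_found)
    for (s in sc) expect_true(verify_scenario(s))
  }
})

test_that("inference is invariant under rotation of either input", {
  gp <- ground_pattern()
  dst <- apply_inversion(gp, c("trnG", "nad3", "trnA"))
  rot <- function(o, k) {
    n <- length(o$genes); i <- ((seq_len(n) - 1L + k) %% n) + 1L
    gene_order(o$genes[i], o$signs[i], taxon = o$taxon)
  }
  a <- infer_scenarios(gp, dst, max_events = 1)
  b <- infer_scenarios(rot(gp, 11L), rot(dst, 23L), max_events = 1)
  expect_identical(length(a), length(b))
  expect_identical(lapply(a, function(s) s$events),
                   lapply(b, function(s) s$events))
})

test_that("event kinds can be restricted, with transposition as a synonym", {
  gp <- ground_pattern()
  dst <- apply_translocation(gp, c("trnT", "trnP"), after = "trnM")
  none <- infer_scenarios(gp, dst, max_events = 1, kinds = "inversion")
  expect_length(none, 0L)
  syn <- infer_scenarios(gp, dst, max_events = 1, kinds = "transposition")
  expect_gte(length(syn), 1L)
  expect_identical(syn[[1L]]$events[[1L]]$kind, "translocation")
  expect_error(infer_scenarios(gp, dst, kinds = "fusion"), "unknown event")
})

test_that("gene-set mismatches name the symmetric difference", {
  gp <- ground_pattern()
  partial <- extract_order(wushanense())
  expect_error(infer_scenarios(gp, partial, max_events = 1), "trnI")
})

test_that("two-event histories are found and capped searches stay empty", {
  gp <- ground_pattern()
  mid <- apply_tdrl(gp, c("trnA", "trnR", "trnN"), copy1 = "trnN")
  dst <- apply_inversion(mid, c("cob", "trnS2"))
  sc <- infer_scenarios(gp, dst, max_events = 2, max_scenarios = 1)
  expect_length(sc, 1L)
  expect_identical(sc[[1L]]$cost, 2)
  expect_true(verify_scenario(sc[[1L]]))
  # the same destination is out of reach for a depth-1 search
  expect_length(infer_scenarios(gp, dst, max_events = 1), 0L)
})
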