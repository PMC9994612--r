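test_that("simulation configs validate their inputs", {
  cfg <- simulation_config(seed = 3)
  expect_s3_class(cfg, "simulation_config")
  expect_equal(sum(cfg$base_comp), 1)
  expect_error(simulation_config(base_comp = c(a = .9, t = .4, g = .1,
                                               c = .1)), "base_comp")
  expect_error(simulation_config(codon_weights = c(TTT = 0, TTC = 0)),
               "zero-weight")
  expect_error(simulation_config(n_events = -1), "n_events")
})

test_that("histories are seed-deterministic with exactly k true events", {
  cfg <- simulation_config(seed = 21, n_events = 2)
  h1 <- simulate_history(cfg)
  h2 <- simulate_history(simulation_config(seed = 21, n_events = 2))
  expect_length(h1$events, 2L)
  expect_identical(h1$order$genes, h2$order$genes)
  expect_identical(h1$order$signs, h2$order$signs)
  h3 <- simulate_history(simulation_config(seed = 22, n_events = 2))
  expect_false(identical(h1$order$genes, h3$order$genes) &&
                 identical(h1$order$signs, h3$order$signs))
})

test_that("every sampled event changes the order and replays to the result", {
  for (seed in c(5, 6, 7)) {
    h <- simulate_history(simulation_config(seed = seed, n_events = 3))
    sc <- new_scenario(h$source, h$events)
    expect_true(order_equal(sc$result, h$order))
    cur <- h$source
    for (ev in h$events) {
      nxt <- apply_event(cur, ev)
      expect_false(order_equal(nxt, cur))
      cur <- nxt
    }
  }
})

test_that("simulated genomes hit the length target and validate clean", {
  cfg <- simulation_config(seed = 9)
  g <- simulate_genome(ground_pattern(), cfg)
  expect_identical(g$genome_length, cfg$genome_length)
  expect_identical(nrow(g$records), 38L)
  expect_identical(nrow(validate_annotation(g)), 0L)
  expect_identical(nchar(g$sequence), g$genome_length)
  lens <- with(g$records, end - start + 1L)
  expect_true(all(lens[g$records$category == "PCG"] %% 3L == 0L))
  g2 <- simulate_genome(ground_pattern(), simulation_config(seed = 9))
  expect_identical(g$sequence, g2$sequence)
  expect_identical(g$records, g2$records)
})

test_that("simulated terminal codons are written on the coding strand", {
  g <- simulate_genome(ground_pattern(), simulation_config(seed = 13))
  for (gene in c("cox1", "nad5", "nad4", "atp8")) {  # mixed strands
    cc <- classify_codons(g, gene)
    i <- match(gene, g$records$gene)
    expect_identical(cc$start_codon, g$records$start_codon[i])
    expect_identical(cc$stop_codon, g$records$stop_codon[i])
    expect_true(cc$canonical_start)
    expect_true(cc$complete)
  }
})

test_that("overlaps are sprinkled within the cap and never upstream of a PCG", {
  g <- simulate_genome(ground_pattern(),
                       simulation_config(seed = 17, overlap_prob = 0.6))
  sp <- pairwise_spacers(g)
  ov <- sp[sp$spacer < 0L, ]
  expect_gt(nrow(ov), 0L)
  expect_true(all(-ov$spacer <= 47L))
  down_cat <- gene_category(ov$downstream)
  expect_false(any(down_cat == "PCG"))
  none <- simulate_genome(ground_pattern(),
                          simulation_config(seed = 17, overlap_prob = 0))
  expect_identical(sum(pairwise_spacers(none)$spacer < 0L), 0L)
})

test_that("genome layout follows the requested gene order", {
  h <- simulate_history(simulation_config(seed = 31, n_events = 2))
  g <- simulate_genome(h$order, simulation_config(seed = 31))
  expect_true(order_equal(extract_order(g), h$order))
})

test_that("mirrored minus-strand filling flips the regional composition", {
  comp <- c(a = 0.40, t = 0.30, g = 0.10, c = 0.20)
  cfg_m <- simulation_config(seed = 19, base_comp = comp, mirror_minus = TRUE)
  g <- simulate_genome(ground_pattern(), cfg_m)
  i <- match("rrnL", g$records$gene)  # long minus-strand feature
  slice <- base_composition(substr(g$sequence, g$records$start[i],
                                   g$records$end[i]))
  # mirrored fill puts ~30% A / ~40% T on the genome strand
  expect_lt(slice$a, 0.35)
  expect_gt(slice$t, 0.35)
})

test_that("coding sequences draw sense codons between ATG and TAA", {
  expect_identical(simulate_cds(simulation_config(seed = 7), 0), "ATGTAA")
  s <- simulate_cds(simulation_config(seed = 7), 40)
  expect_identical(nchar(s), 3L * 42L)
  body <- substring(s, seq(4L, nchar(s) - 3L, 3L), seq(6L, nchar(s), 3L))
  body <- body[-length(body)]
  expect_true(all(!body %in% c("TAA", "TAG")))
  # weights concentrate the draw
  w <- stats::setNames(numeric(62), rscu(codon_usage("ATGTAA"))$codon)
  w["GGA"] <- 1
  only <- simulate_cds(simulation_config(seed = 7, codon_weights = w), 10)
  mid <- substring(only, seq(4L, 31L, 3L), seq(6L, 33L, 3L))
  expect_true(all(mid == "GGA"))
})
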