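design <- default_library_design()

wrap <- function(regions) paste0(design$forward_flank, regions, design$reverse_flank)

test_that("trimming extracts the exact random region and counts discards", {
  good <- wrap(strrep("A", 30))
  no_rev <- paste0(design$forward_flank, strrep("A", 30), "TTTTT")
  rs <- read_set(c(good, no_rev), "p")
  out <- trim_to_random_region(rs, design)
  expect_equal(out$reads$sequences, strrep("A", 30))
  expect_equal(out$report$kept, 1L)
  expect_equal(out$report$discarded, 1L)
  expect_equal(out$report$kept + out$report$discarded, out$report$input)

  empty <- trim_to_random_region(read_set(character(), "p"), design)
  expect_equal(empty$report, list(input = 0L, kept = 0L, discarded = 0L))
  expect_length(empty$reads, 0L)
})

test_that("trimming on a generated pool keeps exactly the well-formed reads", {
  sp <- pool_spec("px", 1000L, malformed_fraction = 0.05, seed = 11)
  mp <- make_pool(sp)
  out <- trim_to_random_region(mp$reads, design)
  expect_equal(out$report$kept, mp$manifest$n_wellformed)
  expect_equal(out$report$kept, 950L)
  expect_equal(out$report$discarded, 50L)
})

test_that("mismatch-tolerant flank matching is off by default", {
  region <- strrep("G", 30)
  ff_mut <- sub("^A", "C", design$forward_flank)
  rd <- paste0(ff_mut, region, design$reverse_flank)
  rs <- read_set(rd, "p")
  expect_equal(trim_to_random_region(rs, design)$report$kept, 0L)
  tol <- trim_to_random_region(rs, design, max_mismatch = 1L)
  expect_equal(tol$report$kept, 1L)
  expect_equal(tol$reads$sequences, region)
})

test_that("count_pool collapses duplicates with exact fractions and rpm", {
  rs <- read_set(c("AAA", "AAA", "AAA", "CCC"), "p")
  pc <- count_pool(rs)
  expect_equal(pc$entries$fraction, c(0.75, 0.25))
  expect_equal(pc$entries$rpm, c(750000, 250000))

  one <- count_pool(read_set(rep("ACGT", 5), "p"))
  expect_equal(nrow(one$entries), 1L)
  expect_equal(one$entries$fraction, 1)
  expect_equal(one$entries$rpm, 1e6)

  expect_error(count_pool(read_set(character(), "p")), "empty pool")
})

test_that("count_pool orders by reads descending with lexicographic ties", {
  rs <- read_set(c("TTT", "TTT", "GGG", "GGG", "AAA"), "p")
  pc <- count_pool(rs)
  expect_equal(pc$entries$sequence, c("GGG", "TTT", "AAA"))
  expect_equal(pc$entries$rank, 1:3)
})

test_that("fractions sum to one and rpm is fraction x 1e6 on random pools", {
  for (seed in 1:5) {
    mp <- make_pool(pool_spec("p", 2000L, seed = seed))
    pc <- count_pool(trim_to_random_region(mp$reads, design)$reads)
    expect_equal(sum(pc$entries$fraction), 1, tolerance = 1e-9)
    expect_equal(pc$entries$rpm, pc$entries$fraction * 1e6)
    expect_equal(sum(pc$entries$reads), pc$total_reads)
  }
})

test_that("family_fraction handles trivial and degenerate motifs", {
  pc <- count_pool(read_set(c(strrep("A", 30), strrep("C", 30)), "p"))
  expect_equal(family_fraction(pc, "GGGGG"), 0)

  padded <- paste0(sca21_motif, strrep("A", 10))
  pc1 <- count_pool(read_set(padded, "p"))
  expect_equal(family_fraction(pc1, sca21_motif), 1)
  expect_error(family_fraction(pc1, strrep("A", 31)), "longer than")
})

test_that("family_fraction equals the read-level motif rate (collapse invariance)", {
  mp <- make_pool(pool_spec("p", 5000L,
                            families = list(list(sequence = sca21_motif,
                                                 fraction = 0.2)),
                            seed = 3))
  trimmed <- trim_to_random_region(mp$reads, design)$reads
  pc <- count_pool(trimmed)
  direct <- mean(grepl(sca21_motif, trimmed$sequences, fixed = TRUE))
  expect_equal(family_fraction(pc, sca21_motif), direct)
  # read order does not matter
  shuf <- read_set(sample(trimmed$sequences), "p")
  expect_equal(family_fraction(count_pool(shuf), sca21_motif), direct)
})

test_that("spiked family fractions are recovered within 3 multinomial SD", {
  n <- 1e4
  p_true <- 0.29
  hits <- 0L
  reps <- 100
  for (seed in seq_len(reps)) {
    mp <- make_pool(pool_spec("p", n,
                              families = list(list(sequence = sca21_motif,
                                                   fraction = p_true)),
                              seed = 1000 + seed))
    pc <- count_pool(trim_to_random_region(mp$reads, design)$reads)
    f <- family_fraction(pc, sca21_motif)
    sd3 <- 3 * sqrt(p_true * (1 - p_true) / n)
    if (abs(f - p_true) <= sd3) hits <- hits + 1L
  }
  expect_gte(hits, 99L)
})

# helper: a pool_counts whose family fraction is exact by construction
exact_pool <- function(fam_fraction, id) {
  fam <- paste0(sca21_motif, strrep("A", 10))
  bg <- strrep("C", 30)
  structure(
    list(pool_id = id, total_reads = 1000000L, random_length = 30L,
         entries = data.frame(sequence = c(bg, fam),
                              reads = round(1000000 * c(1 - fam_fraction,
                                                        fam_fraction)),
                              fraction = c(1 - fam_fraction, fam_fraction),
                              rpm = 1e6 * c(1 - fam_fraction, fam_fraction),
                              rank = 1:2)),
    class = "pool_counts")
}

test_that("combine_pools averages fractions by weight", {
  p1 <- count_pool(read_set(c(rep("AAA", 2), rep("CCC", 8)), "a"))  # f(AAA)=0.2
  p2 <- count_pool(read_set(rep("CCC", 10), "b"))                   # f(AAA)=0
  cmb <- combine_pools(list(p1, p2))
  expect_equal(cmb$entries$fraction[cmb$entries$sequence == "AAA"], 0.1)

  first_only <- combine_pools(list(p1, p2), weights = c(1, 0))
  f1 <- first_only$entries[order(first_only$entries$sequence), c("sequence", "fraction")]
  e1 <- p1$entries[order(p1$entries$sequence), c("sequence", "fraction")]
  expect_equal(f1$fraction, e1$fraction)
  expect_equal(f1$sequence, e1$sequence)

  expect_error(combine_pools(list(p1, p2), weights = c(0, 0)), "positive sum")
})

test_that("equimolar combination of the three parallel pools matches the printed family abundance", {
  # family fractions 0.011%, 0%, 0.00095% constructed exactly
  p_but <- exact_pool(0.011 / 100, "butylone_P5")
  p_eth <- exact_pool(0, "ethylone_P5")
  p_pvp <- exact_pool(0.00095 / 100, "aPVP_P9")
  cmb <- combine_pools(list(p_but, p_eth, p_pvp), pool_id = "combined")
  f_pct <- 100 * family_fraction(cmb, sca21_motif)
  expect_equal(f_pct, (0.011 + 0 + 0.00095) / 3, tolerance = 1e-12)
  # agrees with the reported 0.0041% of the combined pool to rounding
  expect_lt(abs(f_pct - 0.0041), 2e-4)
})

test_that("equal-weight combination equals the per-sequence mean fraction", {
  mk <- function(seed) count_pool(
    trim_to_random_region(make_pool(pool_spec("p", 500L, seed = seed))$reads,
                          design)$reads)
  pools <- lapply(1:3, mk)
  cmb <- combine_pools(pools)
  seqs <- cmb$entries$sequence
  per_pool <- sapply(pools, function(p) {
    f <- p$entries$fraction[match(seqs, p$entries$sequence)]
    ifelse(is.na(f), 0, f)
  })
  expect_equal(cmb$entries$fraction, rowMeans(per_pool), tolerance = 1e-12)
})

test_that("pool_summary percentiles match the sort-and-interpolate oracle", {
  combos <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 4)))
  uni <- count_pool(read_set(combos[1:100], "u"))
  s <- pool_summary(uni)
  expect_equal(unname(s$percentiles), rep(0.01, 3))

  tri <- structure(
    list(pool_id = "t", total_reads = 10L, random_length = 3L,
         entries = data.frame(sequence = c("AAA", "CCC", "GGG"),
                              reads = c(5L, 3L, 2L),
                              fraction = c(0.5, 0.3, 0.2),
                              rpm = c(5, 3, 2) * 1e5, rank = 1:3)),
    class = "pool_counts")
  expect_equal(pool_summary(tri)$percentiles[["p50"]], 0.3)

  set.seed(42)
  f <- exp(rnorm(837, sd = 2))
  f <- f / sum(f)
  ln <- structure(
    list(pool_id = "ln", total_reads = length(f), random_length = 30L,
         entries = data.frame(sequence = paste0("s", seq_along(f)),
                              reads = 1L, fraction = f, rpm = f * 1e6,
                              rank = seq_along(f))),
    class = "pool_counts")
  s <- pool_summary(ln)
  expect_equal(unname(s$percentiles),
               oracle_quantile(f, c(0.05, 0.5, 0.95)), tolerance = 1e-14)
  expect_true(s$percentiles[["p5"]] <= s$percentiles[["p50"]])
  expect_true(s$percentiles[["p50"]] <= s$percentiles[["p95"]])
  expect_true(s$percentiles[["p95"]] <= s$max_fraction)
})

test_that("enrichment_trajectory tracks spiked rounds in order", {
  single <- make_pool(pool_spec("r1", 2000L,
                                families = list(list(sequence = sca21_motif,
                                                     fraction = 0.1)),
                                seed = 5))
  pc <- count_pool(trim_to_random_region(single$reads, design)$reads)
  tr <- enrichment_trajectory(list(pc), sca21_motif)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$family_fraction, family_fraction(pc, sca21_motif))

  ser <- make_round_series(c("S0", "S3", "S6"), n_reads = 20000L,
                           motif = sca21_motif,
                           fractions = c(0.004, 0.05, 0.29), seed = 21)
  pcs <- lapply(ser$pools, function(p)
    count_pool(trim_to_random_region(p$reads, design)$reads))
  tr <- enrichment_trajectory(pcs, sca21_motif)
  expect_equal(tr$round_id, c("S0", "S3", "S6"))
  expect_equal(tr$family_fraction, ser$truth$drawn_fraction, tolerance = 1e-12)

  none <- enrichment_trajectory(pcs, strrep("T", 30))
  expect_equal(none$family_fraction, rep(0, 3))
})
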