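test_that("relative gaps follow -ln((d_i - d_{i-1})/d_i) with d_0 = 0", {
  g <- relative_gaps(c(100000, 120000))
  expect_equal(g[1], 0)                       # forced by d_0 = 0
  expect_equal(g[2], 1.791759469, tolerance = 1e-9)  # -ln(20/120) = ln 6
  expect_equal(relative_gaps(c(130000, 3000000))[2], 0.04430026,
               tolerance = 1e-7)
  expect_true(all(relative_gaps(c(1000, 1500, 40000, 41000)) >= 0))
  expect_error(relative_gaps(c(5000, 5000)), "ascending")
})

test_that("gap clamping keeps the logarithm finite", {
  # difference below the clamp is lifted to 1 kb
  g <- relative_gaps(c(100000, 100500, 101000), clamp = 1000)
  expect_true(all(is.finite(g)))
  expect_equal(g[2], -log(1000 / 100500))
})

test_that("gap quantiles are the inclusive empirical CDF of the pool", {
  expect_equal(gap_quantiles(1, c(0, 1, 2)), 2 / 3)
  expect_equal(gap_quantiles(2, c(0, 1, 2)), 1)
  expect_equal(gap_quantiles(c(0.5, 0.5), c(0.5, 0.5, 0.5)), c(1, 1))
  expect_error(gap_quantiles(1, numeric()), "empty")
})

test_that("stripe scores are running quadratic means", {
  expect_equal(stripe_scores(c(0.6, 0.8))[2], sqrt(0.5), tolerance = 1e-9)
  expect_equal(stripe_scores(rep(0.37, 5)), rep(0.37, 5), tolerance = 1e-12)
  expect_equal(stripe_scores(c(0.2, 0.9, 0.95))[3], 0.7643080,
               tolerance = 1e-6)
})

test_that("a stripe ends where the relative gap collapses", {
  g_trim <- relative_gaps(c(100000, 120000, 130000, 3000000))
  expect_lt(g_trim[4], 0.05)
  expect_equal(trim_index(g_trim, 0.05), 3L)
  g_keep <- relative_gaps(c(100000, 120000, 130000, 900000))
  expect_gt(g_keep[4], 0.05)
  expect_equal(trim_index(g_keep, 0.05), 4L)
  expect_equal(trim_index(0), 1L)             # single leaf
  expect_equal(trim_index(c(0, 0.01), 0.05), 1L)
})

test_that("leaf distances are clamped and kept strictly ascending", {
  # sub-kilobase leaf spacing at 200 bp resolution: both distances clamp to
  # 1 kb, the tie is resolved by pushing the second leaf up one clamp unit
  loops <- as_loops(data.frame(
    chrom = "chr1",
    start1 = c(100000, 100000), end1 = c(100200, 100200),
    start2 = c(100400, 100800), end2 = c(100600, 101000), count = 1))
  res <- call_stripes(loops, stripe_call_config(resolution = 200),
                      details = TRUE)
  cand <- res$candidates
  h <- cand[cand$direction == "horizontal", ]
  expect_equal(h$d, c(1000, 2000))
})

test_that("a symmetric two-vertex graph gives cross scores of exactly 1", {
  one <- as_loops(data.frame(chrom = "chr1", start1 = 1e5, end1 = 1.05e5,
                             start2 = 5e5, end2 = 5.05e5, count = 1))
  cand <- call_stripes(one, details = TRUE)$candidates
  expect_equal(cand$cross_score, c(1, 1))
  expect_equal(cand$q, c(1, 1))   # degenerate all-zero pool
})

test_that("pipeline metrics equal the brute-force oracle on random instances", {
  for (seed in 6:9) {
    loops <- random_loops(15, extent = 4e5, seed = seed)
    a <- oracle_stripe_metrics(loops)
    b <- pipeline_metric_table(call_stripes(loops, details = TRUE))
    expect_equal(nrow(a), nrow(b))
    expect_equal(a$d, b$d, tolerance = 1e-12)
    expect_equal(a$g, b$g, tolerance = 1e-12)
    expect_equal(a$q, b$q, tolerance = 1e-12)
    expect_equal(a$stripe_score, b$stripe_score, tolerance = 1e-12)
    expect_equal(a$cross_score, b$cross_score, tolerance = 1e-12)
  }
})

test_that("a clean planted stripe is called at its anchor", {
  fx <- make_stripe_loopset(fixture_spec(n_stripes = 1, leaves_min = 4,
                                         leaves_max = 4, n_noise_loops = 0,
                                         seed = 5))
  expect_equal(nrow(fx$loops), 4)
  st <- call_stripes(fx$loops)
  expect_equal(nrow(st), 1)
  expect_equal(st$direction, fx$truth$direction)
  expect_lte(st$anchor_start, fx$truth$anchor_start)
  expect_gte(st$anchor_end, fx$truth$anchor_end)
  expect_equal(st$n_leaves, 4L)
})

test_that("isolated loop pairs and short stripes are filtered", {
  # every candidate has a single leaf -> min_leaves rejects all
  iso <- as_loops(data.frame(chrom = "chr1",
                             start1 = c(1e5, 9e5), end1 = c(1.05e5, 9.05e5),
                             start2 = c(3e5, 12e5), end2 = c(3.05e5, 12.05e5),
                             count = 1))
  expect_equal(nrow(call_stripes(iso)), 0)

  # two-leaf chains: 15 kb total length rejected, 25 kb accepted
  chain <- function(offs) as_loops(data.frame(
    chrom = "chr1", start1 = 100000, end1 = 105000,
    start2 = 100000 + offs, end2 = 105000 + offs, count = 1))
  expect_equal(nrow(call_stripes(chain(c(10000, 15000)))), 0)
  st <- call_stripes(chain(c(10000, 15000, 25000)))
  expect_equal(nrow(st), 1)
  expect_gte(st$length_bp, 20000)
})

test_that("calling is deterministic and invariant to loop order", {
  fx <- make_stripe_loopset(fixture_spec(n_stripes = 6, seed = 31))
  st1 <- call_stripes(fx$loops)
  set.seed(1)
  st2 <- call_stripes(fx$loops[sample.int(nrow(fx$loops)), ])
  expect_identical(st1, st2)
  expect_identical(st1, call_stripes(fx$loops))
})

test_that("called stripe anchors coincide with graph vertices", {
  fx <- make_stripe_loopset(fixture_spec(n_stripes = 5, seed = 13))
  res <- call_stripes(fx$loops, details = TRUE)
  v <- res$graph$vertices
  key_v <- paste(v$chrom, v$span_start, v$span_end)
  key_s <- paste(res$stripes$chrom, res$stripes$anchor_start,
                 res$stripes$anchor_end)
  expect_true(all(key_s %in% key_v))
})

test_that("planted stripes are recovered in the easy regime", {
  rec <- sapply(1:3, function(seed) {
    fx <- make_stripe_loopset(fixture_spec(seed = seed))
    score_stripe_calls(call_stripes(fx$loops), fx$truth)$recall
  })
  expect_gte(mean(rec), 0.9)
})

test_that("empty input warns and returns an empty table", {
  expect_warning(st <- call_stripes(random_loops(5)[0, ]), "empty")
  expect_equal(nrow(st), 0)
})
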