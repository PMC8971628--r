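members5 <- c("a1", "a2", "h1", "h2", "h3")
groups5 <- structure(list(affected_ids = c("a1", "a2"),
                          healthy_comparator_ids = c("h1", "h2", "h3"),
                          healthy_all_ids = c("h1", "h2", "h3"),
                          exempt_ids = character(), n_d = 2L, n_h = 3L),
                     class = "analysis_groups")

test_that("window assignment follows half-open 1-based tiling", {
  vs <- make_vs(vrow("chr1", 1500000L, c(1L, 0L, 0L, 0L, 0L)),
                members = members5)
  t1 <- window_tally(vs, groups5)
  expect_equal(t1$window_start, 1000001L)
  # exact multiple of the window size stays in the upstream window
  vs2 <- make_vs(vrow("chr1", 1000000L, c(1L, 0L, 0L, 0L, 0L)),
                 vrow("chr1", 1000001L, c(1L, 0L, 0L, 0L, 0L)),
                 members = members5)
  t2 <- window_tally(vs2, groups5)
  expect_equal(sort(t2$window_start), c(1L, 1000001L))
  expect_error(window_tally(vs, groups5, window_size = 0), "positive")
})

test_that("empty variant sets yield empty tallies and landscapes", {
  vs <- subset_variants(fix_sim$variants, integer())
  expect_equal(nrow(window_tally(vs, fix_groups)), 0L)
  expect_equal(nrow(dmd_landscape(vs, fix_groups)), 0L)
})

test_that("per-window variant counts match an independent bucket count", {
  set.seed(31)
  pos <- sample(1:3000000, 10)
  rows <- lapply(pos, function(p)
    vrow("chr2", p, sample(0:1, 5, replace = TRUE)))
  vs <- do.call(make_vs, c(rows, list(members = members5)))
  l <- dmd_landscape(vs, groups5)
  expect_equal(sum(l$n), 10L)
  oracle <- table(((pos - 1) %/% 1000000) * 1000000 + 1)
  expect_equal(l$n[match(as.integer(names(oracle)), l$window_start)],
               as.integer(oracle), ignore_attr = TRUE)
})

test_that("dmd_score reproduces hand-computed values", {
  # one variant, all affected carry, no healthy: +1
  t_all <- data.frame(o_d = 2L, o_h = 0L)
  expect_equal(dmd_score(t_all, 2, 3), 1)
  expect_equal(dmd_score(data.frame(o_d = 0L, o_h = 3L), 2, 3), -1)
  # 40 identical maximal variants
  t40 <- data.frame(o_d = rep(5L, 40), o_h = 0L)
  expect_equal(dmd_score(t40, 5, 12), 40)
  expect_error(dmd_score(data.frame(o_d = 6L, o_h = 0L), 5, 12),
               "exceeds")
})

test_that("landscape matches the brute-force per-variant oracle", {
  vs <- fix_sim$variants
  l <- dmd_landscape(vs, fix_groups)
  oracle <- oracle_dmd(vs, fix_groups, 1000000L)
  got <- setNames(l$dmd, paste(l$chrom, l$window_start))
  expect_equal(got[order(names(got))], oracle, tolerance = 1e-12)
})

test_that("dmd properties: granularity, additivity, label symmetry", {
  vs <- fix_sim$variants
  l <- dmd_landscape(vs, fix_groups)
  # every score is an integer multiple of 1/lcm(5, 12) = 1/60
  expect_true(all(abs(l$dmd * 60 - round(l$dmd * 60)) < 1e-9))

  # additivity over disjoint subsets of one window
  tal <- window_tally(vs, fix_groups)
  w <- names(which.max(table(paste(tal$chrom, tal$window_start))))
  rows <- tal[paste(tal$chrom, tal$window_start) == w, ]
  if (nrow(rows) >= 2) {
    half <- seq_len(nrow(rows) %/% 2)
    expect_equal(dmd_score(rows, 5, 12),
                 dmd_score(rows[half, ], 5, 12) +
                   dmd_score(rows[-half, ], 5, 12))
  }

  # swapping equal-size groups negates the score
  gswap <- groups5
  gswap$affected_ids <- c("h1", "h2")
  gswap$healthy_all_ids <- c("a1", "a2")
  gswap$n_d <- 2L; gswap$n_h <- 2L
  geq <- groups5; geq$healthy_all_ids <- c("h1", "h2"); geq$n_h <- 2L
  set.seed(5)
  vs5 <- do.call(make_vs, c(lapply(1:8, function(i)
    vrow("chr3", i * 100L, sample(0:2, 5, replace = TRUE))),
    list(members = members5)))
  expect_equal(dmd_landscape(vs5, geq)$dmd,
               -dmd_landscape(vs5, gswap)$dmd)
})

test_that("hotspot calling uses a strict threshold and merges neighbors", {
  mk_land <- function(df) structure(df, n_d = 5L, n_h = 12L,
                                    window_size = 1000000L,
                                    class = c("dmd_landscape", "data.frame"))
  flat <- mk_land(data.frame(chrom = "chr1",
                             window_start = c(1L, 1000001L),
                             n = c(30L, 30L), dmd = c(20, 19.9)))
  expect_equal(nrow(call_hotspots(flat)), 0L)  # 20 is not > 20

  one <- mk_land(data.frame(chrom = "chr1", window_start = 1L, n = 40L,
                            dmd = 32.9833))
  h <- call_hotspots(one)
  expect_equal(nrow(h), 1L)
  expect_equal(h$dmd, 32.9833)

  adj <- mk_land(data.frame(chrom = c("chr1", "chr1", "chr2"),
                            window_start = c(1L, 1000001L, 1L),
                            n = c(40L, 40L, 40L), dmd = c(25, 21, 30)))
  h2 <- call_hotspots(adj)
  expect_equal(nrow(h2), 2L)  # two adjacent windows merged, chr2 separate
  m <- h2[h2$chrom == "chr1", ]
  expect_equal(m$n_windows, 2L)
  expect_equal(m$end, 2000000L)

  bands <- data.frame(chrom = "chr2", start = 1L, end = 5000000L,
                      band = "2p25.3")
  h3 <- call_hotspots(adj, bands = bands)
  expect_equal(h3$label[h3$chrom == "chr2"], "2p25.3")
})

test_that("consensus CNV intersects reciprocal-overlap matches", {
  a <- cnv_calls(data.frame(chrom = "chr7", start = 1000L, end = 2000L,
                            copy_state = "deletion", caller = "A",
                            member_id = "m1"))
  # identical call retained unchanged
  b <- a; b$caller <- "B"
  cons <- consensus_cnv(a, b)
  expect_equal(cons$start, 1000L)
  expect_equal(cons$end, 2000L)
  expect_equal(cons$caller, "consensus")

  # disjoint -> empty
  b2 <- b; b2$start <- 5000L; b2$end <- 6000L
  expect_equal(nrow(consensus_cnv(a, b2)), 0L)

  # 60% reciprocal overlap at threshold 0.5: kept, intersected interval
  # a: [1000, 2000] (1001 bp); b: [1400, 2400] (1001 bp);
  # intersection [1400, 2000] = 601 bp = 60.04% of each
  b3 <- b; b3$start <- 1400L; b3$end <- 2400L
  cons3 <- consensus_cnv(a, b3, 0.5)
  expect_equal(cons3$start, 1400L)
  expect_equal(cons3$end, 2000L)
  expect_equal(nrow(consensus_cnv(a, b3, 0.7)), 0L)

  # copy-state and member must match
  b4 <- b; b4$copy_state <- "duplication"
  expect_equal(nrow(consensus_cnv(a, b4)), 0L)
  b5 <- b; b5$member_id <- "m2"
  expect_equal(nrow(consensus_cnv(a, b5)), 0L)
  expect_error(consensus_cnv(a, b, 0), "min_reciprocal_overlap")
})

test_that("differential CNV screen separates group-specific regions", {
  ped <- fix_ped
  g <- fix_groups
  mk <- function(members, chrom = "chr9", start = 1000L, end = 9000L)
    cnv_calls(data.frame(chrom = chrom, start = start, end = end,
                         copy_state = "deletion", caller = "consensus",
                         member_id = members))
  # carried by every member: not differential
  expect_equal(nrow(differential_cnv(mk(ped$id), g)), 0L)
  # 3 affected, 0 comparators: differential
  expect_equal(nrow(differential_cnv(mk(g$affected_ids[1:3]), g)), 3L)
  # affected + a comparator: not differential
  expect_equal(nrow(differential_cnv(
    mk(c(g$affected_ids[1], g$healthy_comparator_ids[1])), g)), 0L)
  # exempt members do not veto
  expect_equal(nrow(differential_cnv(
    mk(c(g$affected_ids[1], g$exempt_ids[1])), g)), 2L)

  # simulated null world: consensus survives, differential screen is empty
  cnv <- simulate_cnv_calls(ped, fix_cfg)
  cons <- consensus_cnv(cnv$xhmm_like, cnv$gatk_like)
  expect_gt(nrow(cons), 0L)
  expect_equal(nrow(differential_cnv(cons, g)), 0L)
})
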