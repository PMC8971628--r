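test_that("differential extraction applies functional and carrier rules", {
  ped <- fix_ped
  g <- fix_groups
  perfect <- rep(0L, 17); names(perfect) <- ped$id
  perfect[g$affected_ids] <- 1L
  everyone <- rep(1L, 17); names(everyone) <- ped$id
  vs <- make_vs(
    vrow("chr1", 100L, perfect, exonic_func = "synonymous"),
    vrow("chr1", 200L, everyone),
    vrow("chr1", 300L, perfect),
    vrow("chr1", 400L, perfect, func = "intronic",
         exonic_func = NA_character_),
    members = ped$id)
  keep <- differential_variants(vs, g)
  expect_equal(keep, c(FALSE, FALSE, TRUE, FALSE))

  # strict rule demands all affected and zero comparators
  partial <- perfect; partial[g$affected_ids[1]] <- 0L
  vs2 <- make_vs(vrow("chr1", 500L, partial), members = ped$id)
  expect_true(differential_variants(vs2, g,
                                    cascade_config(carrier_delta_min = 0.5)))
  expect_false(differential_variants(
    vs2, g, cascade_config(differential_rule = "strict")))
  # the planted driver always survives stage 1
  keys <- variant_keys(fix_sim$variants)
  expect_true(differential_variants(fix_sim$variants, g)[
    keys == fix_sim$truth$driver_key])
})

test_that("rarity filter uses every known reference frequency", {
  mk <- function(...) {
    site <- data.frame(chrom = "chr1", pos = 1L, ref = "A", alt = "G",
                       stringsAsFactors = FALSE)
    for (nm in names(list(...))) site[[nm]] <- list(...)[[nm]]
    variant_set(site, matrix(0L, 1, 1, dimnames = list(NULL, "x")))
  }
  # rs2293239-like profile: max known AF 0.0209 -> kept
  like <- mk(exac_all = 0.0015, exac_eas = 0.0209,
             exac_nonpsych_all = 0.0012, exac_nonpsych_eas = 0.0183,
             g1000_all = 0.0042, g1000_eas = 0.0208)
  expect_true(rarity_filter(like))
  # one common frequency excludes
  expect_false(rarity_filter(mk(exac_all = 0.001, g1000_all = 0.2)))
  # all unknown: kept and flagged
  none <- mk()
  keep <- rarity_filter(none)
  expect_true(keep)
  expect_true(attr(keep, "no_freq_data"))
  # case-control study frequencies are not rarity evidence
  expect_true(rarity_filter(mk(exac_all = 0.01, converge_case = 0.4)))
})

test_that("odds_ratio matches the closed form and clamps boundaries", {
  expect_equal(as.numeric(odds_ratio(0.3, 0.3)), 1)
  expect_equal(as.numeric(odds_ratio(0.5, 0.25)), 3)
  # reciprocal symmetry on interior frequencies
  set.seed(8)
  p1 <- runif(20, 0.01, 0.99); p2 <- runif(20, 0.01, 0.99)
  expect_equal(as.numeric(odds_ratio(p1, p2)) *
                 as.numeric(odds_ratio(p2, p1)), rep(1, 20),
               tolerance = 1e-12)
  # zero clamps to epsilon and is flagged
  r <- odds_ratio(0, 0.01, epsilon = 1e-6)
  expect_equal(as.numeric(r), 1e-6 * 0.99 / (0.01 * (1 - 1e-6)),
               tolerance = 1e-9)
  expect_lt(abs(as.numeric(r) - 1e-4), 2e-6)
  expect_true(attr(r, "boundary"))
  expect_true(is.na(as.numeric(odds_ratio(NA, 0.2))))
})

test_that("enrichment_ratio reproduces published worked examples", {
  pub <- read.table(system.file("extdata", "published_driver_variants.tsv",
                                package = "pedscreen"),
                    header = TRUE, sep = "\t")
  got <- as.numeric(enrichment_ratio(pub$exac_eas, pub$exac_all))
  expect_equal(round(got, 4), pub$exac_eas_over_all)
  expect_equal(as.numeric(enrichment_ratio(0.2, 0.2)), 1)
  r0 <- enrichment_ratio(0.1, 0)
  expect_true(is.na(as.numeric(r0)))
  expect_true(attr(r0, "undefined"))
})

test_that("deleteriousness voting counts calls and thresholded scores", {
  calls <- setNames(rep("tolerated", 13), PREDICTORS)
  calls[1:9] <- "damaging"
  expect_equal(deleteriousness_votes(calls), 9L)
  expect_equal(deleteriousness_votes(setNames(rep("unknown", 13),
                                              PREDICTORS)), 0L)
  # score exactly at threshold counts as damaging (>= convention)
  site <- data.frame(chrom = "chr1", pos = 1L, ref = "A", alt = "G")
  cm <- matrix("unknown", 1, 13, dimnames = list(NULL, PREDICTORS))
  sm <- matrix(NA_real_, 1, 13, dimnames = list(NULL, PREDICTORS))
  sm[1, "CADD"] <- 20; sm[1, "GERP"] <- 1.99
  vs <- variant_set(site, matrix(0L, 1, 1, dimnames = list(NULL, "x")),
                    cm, sm)
  expect_equal(deleteriousness_votes(vs), 1L)
  # a known call takes precedence over the score
  cm[1, "CADD"] <- "tolerated"
  vs2 <- variant_set(site, matrix(0L, 1, 1, dimnames = list(NULL, "x")),
                     cm, sm)
  expect_equal(deleteriousness_votes(vs2), 0L)
})

test_that("run_cascade recovers the planted driver and logs stages", {
  ped <- fix_ped
  rep <- run_cascade(fix_sim$variants, ped)
  expect_equal(rep$candidates$variant_key[1], fix_sim$truth$driver_key)
  expect_equal(rep$candidates$damaging_votes[1], 9L)
  expect_equal(rep$candidates$passed_modes[1], "AD")
  # stage counts chain and never increase
  expect_equal(rep$stages$n_in[1], n_variants(fix_sim$variants))
  expect_equal(rep$stages$n_in[-1], rep$stages$n_out[-4])
  expect_true(all(rep$stages$n_out <= rep$stages$n_in))
  # published-style annotations on the driver row
  expect_equal(rep$candidates$or_converge[1], 1.2626, tolerance = 1e-3)

  # impossible vote threshold empties the report but stays valid
  empty <- run_cascade(fix_sim$variants, ped,
                       cascade_config(min_damaging_votes = 13))
  expect_equal(nrow(empty$candidates), 0L)
  expect_equal(nrow(empty$stages), 4L)
})

test_that("the report is invariant to input variant order", {
  vs <- fix_sim$variants
  set.seed(33)
  shuffled <- subset_variants(vs, sample(n_variants(vs)))
  shuffled <- variant_set(shuffled$sites, shuffled$geno, shuffled$calls)
  r1 <- run_cascade(vs, fix_ped)
  r2 <- run_cascade(shuffled, fix_ped)
  expect_equal(r2$candidates, r1$candidates)
  expect_equal(r2$stages, r1$stages)
})

test_that("dropping the youngest-generation exemption kills the driver", {
  ped <- fix_ped
  strict_groups <- make_groups(ped, policy = "none")
  rep <- run_cascade(fix_sim$variants, ped, groups = strict_groups)
  expect_false(fix_sim$truth$driver_key %in% rep$candidates$variant_key)
  # specifically eliminated at the co-segregation stage: the unaffected
  # carrier youngsters now sit in the comparator group
  seg_row <- rep$stages[rep$stages$stage == "segregation", ]
  drv <- subset_variants(fix_sim$variants,
                         variant_keys(fix_sim$variants) ==
                           fix_sim$truth$driver_key)
  expect_false(cosegregation_filter(drv, strict_groups)$pass)
  expect_true(cosegregation_filter(drv, fix_groups)$pass)
})
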