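test_that("closed-form cases match the peeling likelihood", {
  solo <- pedigree(data.frame(id = "x", father = NA, mother = NA,
                              sex = "male", affected = "unaffected"))
  m <- segregation_model("sporadic", prevalence = 0.5)
  expect_equal(pedigree_likelihood(solo, m), log(0.5))

  # impossible data: affected child, no risk allele, no phenocopies
  trio <- tiny_trio()
  ad0 <- segregation_model("mendelian_AD", q = 0, f_carrier = 0.9,
                           f_noncarrier = 0)
  expect_identical(pedigree_likelihood(trio, ad0), -Inf)

  # q = 0 / q = 1 collapse to the sporadic closed form
  ped <- fix_ped
  naff <- sum(ped$affected == "affected")
  nun <- sum(ped$affected == "unaffected")
  for (qq in c(0, 1)) {
    f <- if (qq == 0) 0.07 else 0.81
    mm <- segregation_model("mendelian_AD", q = qq,
                            f_carrier = if (qq == 0) 0.5 else f,
                            f_noncarrier = if (qq == 0) f else 0.5)
    expect_equal(pedigree_likelihood(ped, mm),
                 naff * log(f) + nun * log(1 - f), tolerance = 1e-12)
  }
})

test_that("peeling equals exhaustive enumeration on small pedigrees", {
  set.seed(17)
  for (shape in c("single", "couple3", "threegen", "twofam")) {
    for (rep in 1:5) {
      ped <- random_small_pedigree(shape)
      m <- segregation_model(sample(c("mendelian_AD", "mendelian_AR"), 1),
                             q = runif(1), f_carrier = runif(1),
                             f_noncarrier = runif(1))
      a <- pedigree_likelihood(ped, m)
      b <- oracle_enum_loglik(ped, m)
      if (is.infinite(a)) expect_true(is.infinite(b))
      else expect_equal(a, b, tolerance = 1e-9)
    }
  }
})

test_that("likelihood is invariant to member ordering", {
  ped <- fix_ped
  m <- segregation_model("mendelian_AD", q = 0.12, f_carrier = 0.85,
                         f_noncarrier = 0.03)
  base <- pedigree_likelihood(ped, m)
  set.seed(2)
  for (i in 1:3) {
    shuf <- as.data.frame(ped)[sample(nrow(ped)), ]
    ped2 <- pedigree(shuf[names(shuf) != "generation"])
    expect_equal(pedigree_likelihood(ped2, m), base, tolerance = 1e-12)
  }
})

test_that("loop pedigrees are rejected by likelihood and fitting", {
  loopy <- pedigree(data.frame(
    id = c("f", "m", "s1", "s2", "kid"),
    father = c(NA, NA, "f", "f", "s1"),
    mother = c(NA, NA, "m", "m", "s2"),
    sex = c("male", "female", "male", "female", "male"),
    affected = "unaffected"))
  m <- segregation_model("mendelian_AD")
  expect_error(pedigree_likelihood(loopy, m), "loop")
  expect_error(fit_models(loopy), "loop")
})

test_that("fit_models maximizes, sorts by AIC and keeps the identity", {
  ped <- simulate_affection(fix_ped, "AD", f_carrier = 1,
                            f_noncarrier = 0, seed = 13)
  fits <- fit_models(ped)
  expect_equal(nrow(fits), 4L)
  expect_true(!is.unsorted(fits$aic))
  expect_equal(fits$neg2lnL, -2 * fits$lnL, tolerance = 1e-12)
  expect_equal(fits$aic, fits$neg2lnL + 2 * fits$k, tolerance = 1e-12)
  expect_true(any(fits$best))
  # the sporadic MLE is the closed-form affected fraction
  p_hat <- mean(ped$affected == "affected")
  sp <- fits[fits$model == "sporadic", ]
  expect_equal(sp$lnL, 17 * (p_hat * log(p_hat) +
                               (1 - p_hat) * log(1 - p_hat)),
               tolerance = 1e-9)
  # fitted Mendelian models can never beat the saturated grid start
  expect_true(all(is.finite(fits$lnL)))
})

test_that("sporadically simulated data keeps the sporadic model in front", {
  close_cnt <- 0L
  for (s in 1:10) {
    ped <- simulate_affection(fix_ped, "sporadic", prevalence = 0.3,
                              seed = 100 + s)
    fits <- fit_models(ped)
    sp <- fits$aic[fits$model == "sporadic"]
    if (sp <= min(fits$aic) + 2) close_cnt <- close_cnt + 1L
  }
  expect_gte(close_cnt, 6L)  # "most replicates"
})

test_that("mendelian_consistency flags impossible transmissions", {
  trio <- tiny_trio()
  g_bad <- c(dad = 0L, mom = 1L, kid = 2L)
  g_ok <- c(dad = 1L, mom = 0L, kid = 1L)
  expect_false(mendelian_consistency(g_bad, trio))
  expect_true(mendelian_consistency(g_ok, trio))
  # missing genotypes marginalized
  g_na <- c(dad = NA, mom = 0L, kid = 2L)
  expect_false(mendelian_consistency(g_na, trio))  # kid needs mom's allele
  g_na2 <- c(dad = NA, mom = 1L, kid = 2L)
  expect_true(mendelian_consistency(g_na2, trio))
  # the planted driver is consistent thanks to the masked founder
  expect_true(mendelian_consistency(
    subset_variants(fix_sim$variants,
                    variant_keys(fix_sim$variants) ==
                      fix_sim$truth$driver_key), fix_ped))
})

test_that("cosegregation_filter implements the AD/AR pattern rules", {
  ped <- fix_ped
  g <- fix_groups
  driver_geno <- rep(0L, 17); names(driver_geno) <- ped$id
  driver_geno[g$affected_ids] <- 1L
  driver_geno[g$exempt_ids[1:4]] <- 1L
  vs <- variant_set(data.frame(chrom = "chr1", pos = 100, ref = "A",
                               alt = "G"),
                    matrix(driver_geno, 1, dimnames = list(NULL, ped$id)))
  r <- cosegregation_filter(vs, g)
  expect_true(r$AD)
  expect_false(r$AR)  # het affected fail the homozygous AR rule
  expect_true(r$pass)
  expect_true(cosegregation_filter(vs, g, mode = "AD")$pass)
  expect_false(cosegregation_filter(vs, g, mode = "AR")$pass)

  # one carrier comparator kills the AD pattern
  bad <- driver_geno; bad[g$healthy_comparator_ids[1]] <- 1L
  vs2 <- variant_set(vs$sites, matrix(bad, 1,
                                      dimnames = list(NULL, ped$id)))
  expect_false(cosegregation_filter(vs2, g, mode = "AD")$pass)

  # missing affected genotype fails; missing comparator passes
  na_aff <- driver_geno; na_aff[g$affected_ids[1]] <- NA
  vs3 <- variant_set(vs$sites, matrix(na_aff, 1,
                                      dimnames = list(NULL, ped$id)))
  expect_false(cosegregation_filter(vs3, g, mode = "AD")$pass)
  na_cmp <- driver_geno; na_cmp[g$healthy_comparator_ids[1]] <- NA
  vs4 <- variant_set(vs$sites, matrix(na_cmp, 1,
                                      dimnames = list(NULL, ped$id)))
  expect_true(cosegregation_filter(vs4, g, mode = "AD")$pass)
})
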