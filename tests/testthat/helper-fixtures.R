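# Shared fixtures, built in code.

tiny_trio <- function(aff = c("unaffected", "unaffected", "affected")) {
  pedigree(data.frame(
    id = c("dad", "mom", "kid"),
    father = c(NA, NA, "dad"), mother = c(NA, NA, "mom"),
    sex = c("male", "female", "male"),
    affected = aff, stringsAsFactors = FALSE))
}

# compact variant-set builder: geno is a members-long vector per variant
make_vs <- function(..., members, calls = NULL) {
  rows <- list(...)
  sites <- do.call(rbind, lapply(rows, `[[`, "site"))
  geno <- do.call(rbind, lapply(rows, `[[`, "geno"))
  colnames(geno) <- members
  variant_set(sites, geno, calls)
}

vrow <- function(chrom, pos, geno, ref = "A", alt = "G", func = "exonic",
                 exonic_func = "nonsynonymous", gene = "GENE1", ...) {
  extra <- list(...)
  site <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                     func = func, exonic_func = exonic_func, gene = gene,
                     stringsAsFactors = FALSE)
  for (nm in names(extra)) site[[nm]] <- extra[[nm]]
  list(site = site, geno = geno)
}

# the default paper-like world, simulated once per test run
fix_ped <- simulate_pedigree()
fix_groups <- make_groups(fix_ped)
fix_cfg <- sim_config(seed = 42, n_background_variants = 200)
fix_sim <- simulate_variant_set(fix_ped, fix_cfg)

# small random pedigrees (<= 6 members) for oracle comparisons
random_small_pedigree <- function(shape = NULL) {
  shapes <- list(
    single = function() data.frame(
      id = "a", father = NA, mother = NA, sex = "male", affected = "x"),
    couple3 = function() data.frame(
      id = c("f", "m", "c1", "c2", "c3"),
      father = c(NA, NA, "f", "f", "f"),
      mother = c(NA, NA, "m", "m", "m"),
      sex = c("male", "female", "male", "female", "male"),
      affected = "x"),
    threegen = function() data.frame(
      id = c("f", "m", "c", "s", "g1", "g2"),
      father = c(NA, NA, "f", NA, "c", "c"),
      mother = c(NA, NA, "m", NA, "s", "s"),
      sex = c("male", "female", "male", "female", "female", "male"),
      affected = "x"),
    twofam = function() data.frame(
      id = c("f", "m", "c1", "s", "g1", "g2"),
      father = c(NA, NA, "f", NA, "c1", "c1"),
      mother = c(NA, NA, "m", NA, "s", "s"),
      sex = c("male", "female", "male", "female", "male", "female"),
      affected = "x"))
  if (is.null(shape)) shape <- sample(names(shapes), 1L)
  df <- shapes[[shape]]()
  df$affected <- sample(c("affected", "unaffected", "unknown"),
                        nrow(df), replace = TRUE,
                        prob = c(0.4, 0.5, 0.1))
  pedigree(df)
}
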