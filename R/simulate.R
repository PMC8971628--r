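# Synthetic pedigree WES world -----------------------------------------------

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator with defaults that
#' emulate the study design the package targets: a three-generation,
#' 17-member family with 5 affected members, an exome-scale background of
#' common and rare variants gene-dropped from founder genotypes, one planted
#' heterozygous autosomal-dominant driver variant that is rare in all
#' reference populations and East-Asian-enriched, and brain-structure volume
#' tables with a configurable group effect.
#'
#' @param pedigree_template `"paper_like_17"` (default) or `"custom"` (build
#'   your own pedigree and pass it to the generators directly).
#' @param n_background_variants number of background records (default 2000;
#'   an exome-scale set scaled down for test runtime).
#' @param fraction_common fraction of background variants with population
#'   AF > 0.05 (default 0.3).
#' @param indel_fraction fraction of background records simulated as InDels
#'   (default 0.12, the SNV/InDel ratio typical of germline exomes).
#' @param driver_af in-family founder allele status is fixed by the carrier
#'   plan; this is the population AF written to the driver's ExAC_ALL-style
#'   annotation (default 0.0015).
#' @param driver_penetrance P(affected | carrier) used to size the carrier
#'   set: the number of carriers is `round(n_affected / penetrance)`
#'   (default 5/9, giving 9 carriers for 5 affected).
#' @param phenocopy_rate P(affected | non-carrier) (default 0).
#' @param driver_damaging_count exact number of damaging predictor calls on
#'   the driver (default 9 of 13).
#' @param predictor_damaging_probs per-predictor probability that a
#'   background nonsynonymous variant is called damaging (default 0.1 each).
#' @param volume_effect named vector of standardized effect sizes d per
#'   structure (default `c("left-amygdala" = 1.5)`).
#' @param volume_effect_group `"affected"` or `"carrier"`: which grouping
#'   carries the volume effect (default `"affected"`).
#' @param volume_cv coefficient of variation of structure volumes
#'   (default 0.07).
#' @param n_cnv_regions shared (non-differential) true CNV regions
#'   (default 8); `cnv_fp_per_caller` caller-private false calls (default 5).
#' @param cnv_fp_per_caller see above.
#' @param seed single integer governing all randomness; stage substreams are
#'   derived from it deterministically.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(pedigree_template = "paper_like_17",
                       n_background_variants = 2000L,
                       fraction_common = 0.3,
                       indel_fraction = 0.12,
                       driver_af = 0.0015,
                       driver_penetrance = 5 / 9,
                       phenocopy_rate = 0,
                       driver_damaging_count = 9L,
                       predictor_damaging_probs = rep(0.1, length(PREDICTORS)),
                       volume_effect = c("left-amygdala" = 1.5),
                       volume_effect_group = c("affected", "carrier"),
                       volume_cv = 0.07,
                       n_cnv_regions = 8L,
                       cnv_fp_per_caller = 5L,
                       seed = 1L) {
  volume_effect_group <- match.arg(volume_effect_group)
  stopifnot(fraction_common >= 0, fraction_common <= 1,
            indel_fraction >= 0, indel_fraction <= 1,
            driver_af >= 0, driver_af <= 1,
            driver_penetrance > 0, driver_penetrance <= 1,
            phenocopy_rate >= 0, phenocopy_rate <= 1,
            driver_damaging_count >= 0,
            driver_damaging_count <= length(PREDICTORS),
            all(predictor_damaging_probs >= 0),
            all(predictor_damaging_probs <= 1),
            volume_cv > 0)
  structure(list(
    pedigree_template = pedigree_template,
    n_background_variants = as.integer(n_background_variants),
    fraction_common = fraction_common,
    indel_fraction = indel_fraction,
    driver_af = driver_af,
    driver_penetrance = driver_penetrance,
    phenocopy_rate = phenocopy_rate,
    driver_damaging_count = as.integer(driver_damaging_count),
    predictor_damaging_probs = predictor_damaging_probs,
    volume_effect = volume_effect,
    volume_effect_group = volume_effect_group,
    volume_cv = volume_cv,
    n_cnv_regions = as.integer(n_cnv_regions),
    cnv_fp_per_caller = as.integer(cnv_fp_per_caller),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a pedigree
#'
#' The `"paper_like_17"` template is a fixed three-generation family of 17
#' members: a founder couple, five second-generation siblings of whom four
#' are affected, four marry-in spouses, and six third-generation children of
#' whom one is affected. Affection status in the template is fixed, not
#' sampled. Data-availability flags mirror a realistic study: one first-
#' generation founder has no exome genotypes (`has_wes = FALSE`) and 13 of
#' 17 members have imaging (`has_mri`).
#'
#' @param config a [sim_config()], or `members` for a custom template.
#' @param members optional member data frame for a custom pedigree (passed
#'   to [pedigree()]); must have at least 3 members.
#' @return a [pedigree()].
#' @export
simulate_pedigree <- function(config = sim_config(), members = NULL) {
  if (!is.null(members) || identical(config$pedigree_template, "custom")) {
    if (is.null(members) || nrow(members) < 3L)
      stop("custom template requires a member table with >= 3 members")
    return(pedigree(members, family_id = "SIM1"))
  }
  m <- function(id, sex, aff, father = NA, mother = NA,
                wes = TRUE, mri = TRUE)
    data.frame(id = id, father = father, mother = mother, sex = sex,
               affected = aff, has_wes = wes, has_mri = mri,
               stringsAsFactors = FALSE)
  members <- rbind(
    m("G1-M-01", "male",   "unaffected", wes = FALSE, mri = FALSE),
    m("G1-F-01", "female", "unaffected", mri = FALSE),
    m("G2-F-01", "female", "affected",   "G1-M-01", "G1-F-01"),
    m("G2-F-02", "female", "affected",   "G1-M-01", "G1-F-01"),
    m("G2-F-03", "female", "affected",   "G1-M-01", "G1-F-01"),
    m("G2-M-01", "male",   "affected",   "G1-M-01", "G1-F-01"),
    m("G2-M-02", "male",   "unaffected", "G1-M-01", "G1-F-01"),
    m("G2-M-03", "male",   "unaffected"),
    m("G2-M-04", "male",   "unaffected", mri = FALSE),
    m("G2-M-05", "male",   "unaffected", mri = FALSE),
    m("G2-F-04", "female", "unaffected"),
    m("G3-F-02", "female", "affected",   "G2-M-03", "G2-F-01"),
    m("G3-M-01", "male",   "unaffected", "G2-M-03", "G2-F-01"),
    m("G3-F-01", "female", "unaffected", "G2-M-04", "G2-F-02"),
    m("G3-M-02", "male",   "unaffected", "G2-M-04", "G2-F-02"),
    m("G3-M-03", "male",   "unaffected", "G2-M-05", "G2-F-03"),
    m("G3-F-03", "female", "unaffected", "G2-M-01", "G2-F-04"))
  pedigree(members, family_id = "FAM_SIM17")
}

#' Gene-drop genotypes down a pedigree
#'
#' Founders are drawn from Hardy-Weinberg proportions at the given allele
#' frequency; every child independently receives one allele from each
#' parent by fair Mendelian transmission (an allele is transmitted with
#' probability g/2 for parental allele count g).
#'
#' @param ped a [pedigree()].
#' @param allele_freq scalar or length-`n` vector of alternate-allele
#'   frequencies in `[0, 1]`.
#' @param n number of independent loci to drop (default
#'   `length(allele_freq)`).
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return integer matrix, `n` x members (member ids as column names), of
#'   alternate-allele counts.
#' @export
gene_drop <- function(ped, allele_freq, n = length(allele_freq),
                      seed = NULL) {
  stopifnot(all(allele_freq >= 0), all(allele_freq <= 1))
  af <- rep_len(allele_freq, n)
  run <- function() {
    geno <- matrix(NA_integer_, n, nrow(ped),
                   dimnames = list(NULL, ped$id))
    for (i in order(ped$generation)) {
      if (is.na(ped$father[i])) {
        geno[, i] <- rbinom(n, 2L, af)
      } else {
        gf <- geno[, ped$father[i]]
        gm <- geno[, ped$mother[i]]
        geno[, i] <- rbinom(n, 1L, gf / 2) + rbinom(n, 1L, gm / 2)
      }
    }
    geno
  }
  if (is.null(seed)) run() else with_substream(seed, 1L, run())
}

#' Plant a heterozygous driver variant
#'
#' Builds the ground-truth driver record: every affected member is a
#' heterozygous carrier; additional unaffected carriers from the youngest
#' generation model incomplete penetrance. The carrier plan is deterministic
#' (test reproducibility): the total carrier count is
#' `round(n_affected / driver_penetrance)` and the extra carriers are the
#' alphabetically first eligible unaffected youngest-generation members with
#' a carrier parent. Founders that must transmit the allele but are not
#' themselves carriers in the plan get a missing genotype (the template's
#' `has_wes = FALSE` founder), which keeps the record Mendelian-consistent
#' without placing a known carrier in the comparator group. The annotation
#' carries rare (all at most 0.05), East-Asian-enriched population
#' frequencies and exactly `driver_damaging_count` damaging predictor calls.
#'
#' @param ped a [pedigree()].
#' @param config a [sim_config()].
#' @return list with elements `variants` (a one-record [variant_set()]) and
#'   `truth` (list: `driver_key`, `carrier_ids`, `masked_ids`, `model`).
#' @export
plant_driver <- function(ped, config = sim_config()) {
  if (config$driver_penetrance <= 0 || config$driver_penetrance > 1)
    stop("driver_penetrance must be in (0, 1]")
  affected <- ped$id[ped$affected == "affected"]
  if (!length(affected)) stop("cannot plant a driver: no affected members")
  n_carrier <- max(length(affected),
                   round(length(affected) / config$driver_penetrance))
  gmax <- max(ped$generation)
  eligible <- sort(ped$id[ped$affected == "unaffected" &
                            ped$generation == gmax &
                            (ped$father %in% affected |
                             ped$mother %in% affected)])
  k <- min(n_carrier - length(affected), length(eligible))
  carriers <- c(affected, head(eligible, k))
  # founders that have a carrier child but no carrier status themselves must
  # be genotype-missing obligate transmitters
  masked <- character()
  for (id in carriers) {
    i <- match(id, ped$id)
    if (is.na(ped$father[i])) next
    if (!(ped$father[i] %in% carriers) && !(ped$mother[i] %in% carriers)) {
      fa <- ped$father[i]
      if (!is.na(ped$father[match(fa, ped$id)]))
        stop("impossible carrier assignment: non-founder parent chain ",
             "cannot transmit the driver Mendelian-consistently")
      masked <- union(masked, fa)
    }
  }
  if ("has_wes" %in% names(ped))
    masked <- union(masked, ped$id[!ped$has_wes])
  geno <- matrix(0L, 1L, nrow(ped), dimnames = list(NULL, ped$id))
  geno[1L, carriers] <- 1L
  geno[1L, masked] <- NA_integer_
  af <- config$driver_af
  sites <- data.frame(
    chrom = "chr5", pos = 1234567L, ref = "A", alt = "G",
    variant_class = "SNV", gene = "DRVR1", func = "exonic",
    exonic_func = "nonsynonymous",
    exac_all = af, exac_eas = min(0.05, round(af * 13.9, 6)),
    exac_nonpsych_all = af * 0.8,
    exac_nonpsych_eas = min(0.05, round(af * 12.2, 6)),
    exac_psych_all = af * 1.4,
    g1000_all = min(0.05, af * 2.8), g1000_eas = min(0.05, af * 13.9),
    converge_case = 0.0141, converge_control = 0.0112,
    stringsAsFactors = FALSE)
  calls <- matrix("tolerated", 1L, length(PREDICTORS),
                  dimnames = list(NULL, PREDICTORS))
  if (config$driver_damaging_count > 0L)
    calls[1L, seq_len(config$driver_damaging_count)] <- "damaging"
  vs <- variant_set(sites, geno, calls)
  list(variants = vs,
       truth = list(driver_key = variant_keys(vs), carrier_ids = carriers,
                    masked_ids = masked, model = "AD"))
}

#' Simulate a full variant set with a planted driver
#'
#' Generates `n_background_variants` background records spread over
#' autosomes (`fraction_common` with AF > 0.05, the rest rare, log-uniform
#' down to 1e-4), gene-drops genotypes at each record's allele frequency,
#' draws functional annotation and predictor calls, and adds the planted
#' driver from [plant_driver()]. Members without exome data (`has_wes =
#' FALSE`) get missing genotypes throughout.
#'
#' @param ped a [pedigree()].
#' @param config a [sim_config()].
#' @return list with elements `variants` (a [variant_set()]) and `truth`.
#' @export
simulate_variant_set <- function(ped, config = sim_config()) {
  planted <- plant_driver(ped, config)
  n <- config$n_background_variants
  if (n == 0L) return(planted)
  with_substream(config$seed, 2L, {
    common <- runif(n) < config$fraction_common
    af <- ifelse(common, runif(n, 0.051, 0.5),
                 10^runif(n, -4, log10(0.05)))
    chrom <- paste0("chr", sample(1:22, n, replace = TRUE,
                                  prob = 23 - (1:22)))
    pos <- sample.int(120000000L, n, replace = TRUE)
    is_indel <- runif(n) < config$indel_fraction
    ref <- ifelse(is_indel, "AT", "A")
    alt <- ifelse(is_indel, "A", "C")
    func <- sample(c("exonic", "intronic", "UTR", "splicing", "intergenic"),
                   n, replace = TRUE, prob = c(0.60, 0.15, 0.10, 0.02, 0.13))
    exonic_func <- rep(NA_character_, n)
    ex <- which(func == "exonic")
    exonic_func[ex] <- ifelse(
      is_indel[ex],
      sample(c("frameshift", "nonframeshift"), length(ex), replace = TRUE,
             prob = c(0.6, 0.4)),
      sample(c("nonsynonymous", "synonymous", "stopgain", "other"),
             length(ex), replace = TRUE, prob = c(0.48, 0.45, 0.02, 0.05)))
    eas_mult <- exp(rnorm(n, 0, 0.5))
    sites <- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      variant_class = ifelse(is_indel, "InDel", "SNV"),
      gene = paste0("BGG", sprintf("%04d", seq_len(n))),
      func = func, exonic_func = exonic_func,
      exac_all = af, exac_eas = pmin(1, af * eas_mult),
      exac_nonpsych_all = af, exac_nonpsych_eas = pmin(1, af * eas_mult),
      exac_psych_all = af,
      g1000_all = af, g1000_eas = pmin(1, af * eas_mult),
      converge_case = NA_real_, converge_control = NA_real_,
      stringsAsFactors = FALSE)
    geno <- gene_drop(ped, af)
    if ("has_wes" %in% names(ped))
      geno[, ped$id[!ped$has_wes]] <- NA_integer_
    calls <- matrix("unknown", n, length(PREDICTORS),
                    dimnames = list(NULL, PREDICTORS))
    scored <- which(func == "exonic" &
                      exonic_func %in% c("nonsynonymous", "stopgain") &
                      !is_indel)
    for (j in seq_along(PREDICTORS))
      calls[scored, j] <- ifelse(
        runif(length(scored)) < config$predictor_damaging_probs[j],
        "damaging", "tolerated")
    # InDels keep conservation-style predictors only
    cons <- match(c("GERP", "PhyloP", "CADD"), PREDICTORS)
    fs <- which(is_indel & func == "exonic")
    for (j in cons)
      calls[fs, j] <- ifelse(
        runif(length(fs)) < config$predictor_damaging_probs[j],
        "damaging", "tolerated")
    bg <- variant_set(sites, geno, calls)
    all_sites <- rbind(bg$sites, planted$variants$sites)
    all_geno <- rbind(bg$geno, planted$variants$geno)
    all_calls <- rbind(bg$calls, planted$variants$calls)
    list(variants = variant_set(all_sites, all_geno, all_calls),
         truth = planted$truth)
  })
}

#' Simulate brain-structure volume tables
#'
#' Per-structure volumes are `baseline * (1 + cv * (d * in_group + z))` with
#' `z` standard normal: realistic mm^3 baselines, multiplicative Gaussian
#' noise with coefficient of variation `volume_cv`, and a standardized group
#' effect `d` ([sim_config()] `volume_effect`) for the affected or carrier
#' group. Only members with imaging (`has_mri`, when present) get rows.
#'
#' @param ped a [pedigree()].
#' @param config a [sim_config()].
#' @param carrier_ids carrier ids, required when `volume_effect_group =
#'   "carrier"`.
#' @return volume table: data frame with `member_id` plus one column per
#'   structure in [VOLUME_STRUCTURES].
#' @export
simulate_volumes <- function(ped, config = sim_config(), carrier_ids = NULL) {
  stopifnot(all(is.finite(config$volume_effect)))
  baselines <- c(
    "left-thalamus" = 7900, "left-caudate" = 3600, "left-putamen" = 4900,
    "left-pallidum" = 1800, "left-hippocampus" = 3900,
    "left-amygdala" = 1300, "left-accumbens-area" = 520,
    "brain-stem" = 21000, "right-thalamus" = 7700, "right-caudate" = 3700,
    "right-putamen" = 4800, "right-pallidum" = 1750,
    "right-hippocampus" = 4000, "right-amygdala" = 1350,
    "right-accumbens-area" = 500, "left-cerebellum" = 140000)
  ids <- if ("has_mri" %in% names(ped)) ped$id[ped$has_mri] else ped$id
  in_group <- if (config$volume_effect_group == "affected") {
    ids %in% ped$id[ped$affected == "affected"]
  } else {
    if (is.null(carrier_ids))
      stop("carrier_ids required for volume_effect_group = 'carrier'")
    ids %in% carrier_ids
  }
  with_substream(config$seed, 3L, {
    out <- data.frame(member_id = ids, stringsAsFactors = FALSE)
    for (s in VOLUME_STRUCTURES) {
      d <- if (s %in% names(config$volume_effect))
        config$volume_effect[[s]] else 0
      b <- baselines[[s]]
      out[[s]] <- b * (1 + config$volume_cv *
                         (d * in_group + rnorm(length(ids))))
    }
    out
  })
}

#' Simulate two-caller CNV call sets
#'
#' Emulates exome CNV calling by two independent tools over a null world
#' with no group-specific events: `n_cnv_regions` true regions are each
#' carried by a random subset of members drawn without regard to affection
#' status, observed by both callers with jittered boundaries (reciprocal
#' overlap around 0.8), plus `cnv_fp_per_caller` caller-private false calls.
#'
#' @param ped a [pedigree()].
#' @param config a [sim_config()].
#' @return list of two `"cnv_calls"` data frames, `xhmm_like` and
#'   `gatk_like`.
#' @export
simulate_cnv_calls <- function(ped, config = sim_config()) {
  with_substream(config$seed, 4L, {
    mk <- function(chrom, start, end, state, caller, member)
      data.frame(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), copy_state = state, caller = caller,
                 member_id = member, stringsAsFactors = FALSE)
    a <- list(); b <- list()
    for (r in seq_len(config$n_cnv_regions)) {
      chrom <- paste0("chr", sample(1:22, 1))
      start <- sample.int(100000000L, 1)
      len <- sample(20000:200000, 1)
      state <- sample(c("deletion", "duplication"), 1)
      # null world: every true region is carried in both groups, so the
      # differential screen has nothing group-specific to find
      grp <- make_groups(ped)
      members <- unique(c(sample(grp$affected_ids, 1),
                          sample(grp$healthy_comparator_ids, 1),
                          sample(ped$id, sample(0:4, 1))))
      for (id in members) {
        j1 <- round(len * runif(2, 0, 0.1))
        j2 <- round(len * runif(2, 0, 0.1))
        a[[length(a) + 1L]] <- mk(chrom, start + j1[1],
                                  start + len - j1[2], state, "callerA", id)
        b[[length(b) + 1L]] <- mk(chrom, start + j2[1],
                                  start + len - j2[2], state, "callerB", id)
      }
    }
    for (k in seq_len(config$cnv_fp_per_caller)) {
      for (side in c("a", "b")) {
        chrom <- paste0("chr", sample(1:22, 1))
        start <- sample.int(100000000L, 1)
        row <- mk(chrom, start, start + sample(10000:50000, 1),
                  sample(c("deletion", "duplication"), 1),
                  if (side == "a") "callerA" else "callerB",
                  sample(ped$id, 1))
        if (side == "a") a[[length(a) + 1L]] <- row
        else b[[length(b) + 1L]] <- row
      }
    }
    list(xhmm_like = cnv_calls(do.call(rbind, a)),
         gatk_like = cnv_calls(do.call(rbind, b)))
  })
}

#' Simulate affection statuses under a segregation model
#'
#' Replaces the pedigree's affection column with phenotypes drawn under a
#' major-locus model: a latent diallelic genotype is gene-dropped at
#' frequency `q` and each member is affected with probability `f_carrier`
#' (carriers) or `f_noncarrier` (non-carriers); the sporadic model draws
#' iid Bernoulli(`prevalence`). Families are ascertained the way segregating
#' pedigrees are collected: draws are repeated until the family shows at
#' least `min_affected` affected and one unaffected member.
#'
#' @param ped a [pedigree()].
#' @param model `"AD"`, `"AR"` or `"sporadic"`.
#' @param q risk-allele frequency (major-locus models).
#' @param f_carrier,f_noncarrier penetrances (carrier defined by the model:
#'   genotype >= 1 under AD, == 2 under AR).
#' @param prevalence sporadic-model affection probability.
#' @param min_affected ascertainment floor (default 2).
#' @param seed integer seed.
#' @return the pedigree with simulated `affected` values.
#' @export
simulate_affection <- function(ped, model = c("AD", "AR", "sporadic"),
                               q = 0.02, f_carrier = 0.9,
                               f_noncarrier = 0.01,
                               prevalence = 0.3, min_affected = 2L,
                               seed = 1L) {
  model <- match.arg(model)
  with_substream(seed, 5L, {
    for (try in 1:2000) {
      if (model == "sporadic") {
        aff <- runif(nrow(ped)) < prevalence
      } else {
        g <- gene_drop(ped, q, n = 1L)[1L, ]
        carrier <- if (model == "AD") g >= 1L else g == 2L
        aff <- runif(nrow(ped)) < ifelse(carrier, f_carrier, f_noncarrier)
      }
      if (sum(aff) >= min_affected && sum(!aff) >= 1L) break
    }
    ped$affected <- ifelse(aff, "affected", "unaffected")
    ped
  })
}

#' Write a complete simulated dataset to disk
#'
#' Emits the PED, VCF, annotation TSV, two CNV call sets and the volume
#' table for one simulated world; all files re-parse through the package
#' readers. Byte-identical for identical configs.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a named list of paths plus the `truth` list.
#' @export
write_simulation <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ped <- simulate_pedigree(config)
  sim <- simulate_variant_set(ped, config)
  vols <- simulate_volumes(ped, config,
                           carrier_ids = sim$truth$carrier_ids)
  cnv <- simulate_cnv_calls(ped, config)
  paths <- list(
    ped = file.path(out_dir, "family.ped"),
    vcf = file.path(out_dir, "variants.vcf"),
    anno = file.path(out_dir, "variants.annotation.tsv"),
    cnv_a = file.path(out_dir, "cnv.callerA.bed.tsv"),
    cnv_b = file.path(out_dir, "cnv.callerB.bed.tsv"),
    volumes = file.path(out_dir, "volumes.tsv"))
  write_pedigree(ped, paths$ped)
  write_variant_fixture(sim$variants, paths$vcf, paths$anno)
  write_cnv_calls(cnv$xhmm_like, paths$cnv_a)
  write_cnv_calls(cnv$gatk_like, paths$cnv_b)
  write_volumes(vols, paths$volumes)
  invisible(c(paths, list(truth = sim$truth)))
}
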