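# Driver-variant prioritization cascade --------------------------------------

#' Cascade configuration
#'
#' @param differential_rule `"carrier_delta"` (default: affected carrier
#'   fraction minus healthy-comparator carrier fraction must reach
#'   `carrier_delta_min`) or `"strict"` (all affected observed carriers and
#'   zero comparator carriers).
#' @param carrier_delta_min minimum carrier-fraction difference
#'   (default 0.5).
#' @param max_af rarity cutoff: every known reference-population frequency
#'   must be at most this (default 0.05).
#' @param min_damaging_votes minimum damaging predictor calls
#'   (default 1).
#' @param coseg_mode inheritance mode(s) for the co-segregation stage
#'   (default `"either"`).
#' @param functional_funcs site classes kept by the functional filter
#'   (default exonic and splicing).
#' @param functional_exonic exonic consequences kept (default
#'   nonsynonymous, stopgain, frameshift).
#' @param predictor_thresholds named thresholds for score-only predictors;
#'   a score at or above its threshold counts as damaging when the
#'   categorical call is unknown.
#' @param or_epsilon clamp for boundary allele frequencies in odds ratios.
#' @return list of class `"cascade_config"`.
#' @export
cascade_config <- function(differential_rule = c("carrier_delta", "strict"),
                           carrier_delta_min = 0.5,
                           max_af = 0.05,
                           min_damaging_votes = 1L,
                           coseg_mode = "either",
                           functional_funcs = c("exonic", "splicing"),
                           functional_exonic = c("nonsynonymous", "stopgain",
                                                 "frameshift"),
                           predictor_thresholds = c(GERP = 2, PhyloP = 1.6,
                                                    CADD = 20),
                           or_epsilon = 1e-6) {
  differential_rule <- match.arg(differential_rule)
  if (max_af <= 0 || max_af >= 1) stop("max_af must be in (0, 1)")
  if (min_damaging_votes < 0 || min_damaging_votes > length(PREDICTORS))
    stop("min_damaging_votes must be in [0, ", length(PREDICTORS), "]")
  structure(list(differential_rule = differential_rule,
                 carrier_delta_min = carrier_delta_min, max_af = max_af,
                 min_damaging_votes = as.integer(min_damaging_votes),
                 coseg_mode = coseg_mode,
                 functional_funcs = functional_funcs,
                 functional_exonic = functional_exonic,
                 predictor_thresholds = predictor_thresholds,
                 or_epsilon = or_epsilon),
            class = "cascade_config")
}

#' Stage 1: differential, functional variant extraction
#'
#' Keeps variants that are functionally relevant (site class in
#' `functional_funcs` and exonic consequence in `functional_exonic`; purely
#' splicing sites pass without an exonic consequence) and whose carrier
#' pattern separates affected members from healthy comparators under the
#' configured rule. Missing genotypes count as non-carrier.
#'
#' @param vs a [variant_set()].
#' @param groups an [make_groups()] result.
#' @param config a [cascade_config()].
#' @return logical vector, `TRUE` for surviving variants.
#' @export
differential_variants <- function(vs, groups, config = cascade_config()) {
  func_ok <- vs$sites$func %in% config$functional_funcs &
    (vs$sites$exonic_func %in% config$functional_exonic |
       (vs$sites$func == "splicing" & is.na(vs$sites$exonic_func)))
  carrier <- !is.na(vs$geno) & vs$geno >= 1L
  f_aff <- rowSums(carrier[, groups$affected_ids, drop = FALSE]) /
    length(groups$affected_ids)
  f_cmp <- rowSums(carrier[, groups$healthy_comparator_ids, drop = FALSE]) /
    length(groups$healthy_comparator_ids)
  diff_ok <- if (config$differential_rule == "strict")
    f_aff == 1 & f_cmp == 0
  else (f_aff - f_cmp) >= config$carrier_delta_min
  func_ok & diff_ok
}

#' Stage 3: population rarity filter
#'
#' Keeps variants whose every known reference-population allele frequency
#' (ExAC subsets and 1000 Genomes) is at most `max_af`. Variants with no
#' known frequency at all are kept as presumed-rare and flagged.
#'
#' @inheritParams differential_variants
#' @return logical vector with attribute `no_freq_data` marking kept
#'   records that had no frequency evidence.
#' @export
rarity_filter <- function(vs, config = cascade_config()) {
  fr <- as.matrix(vs$sites[, RARITY_COLUMNS, drop = FALSE])
  known <- rowSums(!is.na(fr))
  maxf <- suppressWarnings(apply(fr, 1L, max, na.rm = TRUE))
  keep <- known == 0L | maxf <= config$max_af
  structure(keep, no_freq_data = keep & known == 0L)
}

#' Allele-frequency odds ratio
#'
#' `OR = p1 (1 - p2) / (p2 (1 - p1))`. Frequencies at the 0/1 boundary are
#' clamped to `[epsilon, 1 - epsilon]` and the result flagged; an unknown
#' frequency yields `NA` rather than an error.
#'
#' @param p_case,p_control allele frequencies (vectorized).
#' @param epsilon boundary clamp (default 1e-6).
#' @return numeric vector with logical attribute `boundary`.
#' @export
odds_ratio <- function(p_case, p_control, epsilon = 1e-6) {
  boundary <- (!is.na(p_case) & (p_case <= 0 | p_case >= 1)) |
    (!is.na(p_control) & (p_control <= 0 | p_control >= 1))
  p1 <- pmin(pmax(p_case, epsilon), 1 - epsilon)
  p2 <- pmin(pmax(p_control, epsilon), 1 - epsilon)
  structure(p1 * (1 - p2) / (p2 * (1 - p1)), boundary = boundary)
}

#' Subpopulation enrichment ratio
#'
#' Ratio of a subpopulation allele frequency to the overall frequency
#' (e.g. East-Asian over all-population ExAC).
#'
#' @param af_sub,af_all allele frequencies (vectorized).
#' @return numeric vector; `NA` (flagged via attribute `undefined`) where
#'   `af_all` is zero or unknown.
#' @export
enrichment_ratio <- function(af_sub, af_all) {
  undefined <- is.na(af_all) | af_all == 0
  out <- ifelse(undefined, NA_real_, af_sub / af_all)
  structure(out, undefined = undefined)
}

#' Stage 4: deleteriousness-prediction voting
#'
#' Counts predictors calling each variant damaging. Categorical calls use
#' their label; where a call is unknown but a raw score exists for a
#' score-only predictor, the score is compared against its configured
#' threshold (at-or-above counts as damaging). Unknown calls never count.
#'
#' @param vs a [variant_set()], or a character vector of calls for one
#'   variant.
#' @param config a [cascade_config()] (supplies `predictor_thresholds`).
#' @return integer vector of damaging votes per variant.
#' @export
deleteriousness_votes <- function(vs, config = cascade_config()) {
  if (!inherits(vs, "variant_set")) {
    calls <- matrix(vs, 1L, dimnames = list(NULL, names(vs)))
    scores <- NULL
  } else {
    calls <- vs$calls
    scores <- vs$scores
  }
  votes <- rowSums(calls == "damaging")
  if (!is.null(scores)) {
    thr <- config$predictor_thresholds
    for (p in intersect(names(thr), colnames(scores))) {
      use <- calls[, p] == "unknown" & !is.na(scores[, p])
      votes <- votes + (use & scores[, p] >= thr[[p]])
    }
  }
  as.integer(votes)
}

#' Run the four-stage driver-variant cascade
#'
#' Applies, in order: differential/functional extraction, Mendelian
#' consistency plus co-segregation, population rarity, and deleteriousness
#' voting; survivors are ranked by damaging votes (descending), then
#' case-control odds ratio (descending, unknown last), then genomic
#' position.
#'
#' @param vs a [variant_set()].
#' @param ped a [pedigree()].
#' @param config a [cascade_config()].
#' @param groups optional [make_groups()] result (default: built from
#'   `ped` with the youngest-generation exemption policy).
#' @return list of class `"candidate_report"`: `stages` (data frame of
#'   input/surviving counts per stage) and `candidates` (ranked data frame
#'   with `variant_key`, `gene`, `damaging_votes`, `or_exac`,
#'   `or_converge`, `eas_all_ratio`, `passed_modes`).
#' @export
run_cascade <- function(vs, ped, config = cascade_config(),
                        groups = make_groups(ped)) {
  stages <- data.frame(stage = character(), n_in = integer(),
                       n_out = integer(), stringsAsFactors = FALSE)
  log_stage <- function(name, n_in, n_out) {
    ps_info("cascade stage %-14s %5d -> %5d", name, n_in, n_out)
    stages <<- rbind(stages, data.frame(stage = name, n_in = n_in,
                                        n_out = n_out))
  }
  cur <- vs
  s1 <- differential_variants(cur, groups, config)
  log_stage("differential", n_variants(cur), sum(s1))
  cur <- subset_variants(cur, s1)

  mendel <- mendelian_consistency(cur, ped)
  coseg <- cosegregation_filter(cur, groups, config$coseg_mode)
  s2 <- mendel & coseg$pass
  log_stage("segregation", n_variants(cur), sum(s2))
  modes <- paste0(ifelse(coseg$AD, "AD", ""),
                  ifelse(coseg$AD & coseg$AR, "+", ""),
                  ifelse(coseg$AR, "AR", ""))[s2]
  cur <- subset_variants(cur, s2)

  s3 <- rarity_filter(cur, config)
  log_stage("rarity", n_variants(cur), sum(s3))
  modes <- modes[s3]
  cur <- subset_variants(cur, s3)

  votes <- deleteriousness_votes(cur, config)
  s4 <- votes >= config$min_damaging_votes
  log_stage("deleteriousness", n_variants(cur), sum(s4))
  modes <- modes[s4]
  votes <- votes[s4]
  cur <- subset_variants(cur, s4)

  or_exac <- as.numeric(odds_ratio(cur$sites$exac_psych_all,
                                   cur$sites$exac_nonpsych_all,
                                   config$or_epsilon))
  or_conv <- as.numeric(odds_ratio(cur$sites$converge_case,
                                   cur$sites$converge_control,
                                   config$or_epsilon))
  ratio <- as.numeric(enrichment_ratio(cur$sites$exac_eas,
                                       cur$sites$exac_all))
  ord <- order(-votes, -ifelse(is.na(or_conv), -Inf, or_conv),
               cur$sites$chrom, cur$sites$pos)
  candidates <- data.frame(
    variant_key = variant_keys(cur)[ord],
    gene = cur$sites$gene[ord],
    damaging_votes = votes[ord],
    or_exac = or_exac[ord],
    or_converge = or_conv[ord],
    eas_all_ratio = ratio[ord],
    passed_modes = modes[ord],
    stringsAsFactors = FALSE)
  structure(list(stages = stages, candidates = candidates),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("Driver-variant cascade\n")
  for (i in seq_len(nrow(x$stages)))
    cat(sprintf("  %-15s %6d -> %6d\n", x$stages$stage[i],
                x$stages$n_in[i], x$stages$n_out[i]))
  cat(sprintf("%d candidate(s)\n", nrow(x$candidates)))
  if (nrow(x$candidates)) print(head(x$candidates, 10L))
  invisible(x)
}
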