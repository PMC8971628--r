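# Endophenotype volume comparisons -------------------------------------------

pull_volumes <- function(volumes, ids, structure) {
  if (!structure %in% names(volumes))
    stop("unknown structure: ", structure)
  v <- volumes[[structure]][match(ids, volumes$member_id)]
  v[!is.na(v)]
}

two_sample_t <- function(xa, xb, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  na <- length(xa); nb <- length(xb)
  ma <- mean(xa); mb <- mean(xb)
  va <- var(xa); vb <- var(xb)
  if (variant == "student") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- if (se == 0) 0 else (ma - mb) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Two-sample t-test on one structure's volumes
#'
#' Two-sided Student (default, equal variances) or Welch t-test comparing a
#' structure's volumes between two member groups.
#'
#' @param volumes volume table ([read_volumes()] / [simulate_volumes()]).
#' @param group_a_ids,group_b_ids disjoint member id vectors; each needs at
#'   least 2 members with non-missing volumes.
#' @param structure structure column name.
#' @param variant `"student"` or `"welch"`.
#' @return list of class `"group_comparison"`: `structure`, group ids and
#'   sizes, `t_statistic`, `df`, `p_t`.
#' @export
volume_t_test <- function(volumes, group_a_ids, group_b_ids, structure,
                          variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(intersect(group_a_ids, group_b_ids)))
    stop("groups overlap")
  xa <- pull_volumes(volumes, group_a_ids, structure)
  xb <- pull_volumes(volumes, group_b_ids, structure)
  if (length(xa) < 2L || length(xb) < 2L)
    stop("each group needs >= 2 members with volumes")
  tt <- two_sample_t(xa, xb, variant)
  structure(list(structure = structure, group_a_ids = group_a_ids,
                 group_b_ids = group_b_ids, n_a = length(xa),
                 n_b = length(xb), variant = variant, t_statistic = tt$t,
                 df = tt$df, p_t = tt$p),
            class = "group_comparison")
}

#' Label-randomization test on one structure's volumes
#'
#' Permutes group labels and compares permuted `|t|` against the observed
#' `|t|`. When the number of distinct relabelings `choose(n, n_a)` is at
#' most `exact_limit` (default 200,000) every relabeling is enumerated and
#' the p-value is exact (`#{|t*| >= |t|} / N`, which includes the identity
#' relabeling, so p >= 1/N); otherwise `n_permutations` relabelings are
#' sampled uniformly with the given seed and the add-one estimate
#' `(1 + #{|t*| >= |t|}) / (1 + n)` avoids p = 0.
#'
#' @inheritParams volume_t_test
#' @param n_permutations sampled relabelings (default 10000).
#' @param seed RNG seed for sampling (default 1).
#' @param exact_limit enumeration cutoff; set to 0 to force sampling.
#' @return list of class `"group_comparison"` with `p_perm`,
#'   `n_permutations` (relabelings actually used), `exact`, `seed`, plus
#'   the t-test fields.
#' @export
permutation_test <- function(volumes, group_a_ids, group_b_ids, structure,
                             n_permutations = 10000L, seed = 1L,
                             variant = c("student", "welch"),
                             exact_limit = 200000) {
  variant <- match.arg(variant)
  obs <- volume_t_test(volumes, group_a_ids, group_b_ids, structure,
                       variant)
  xa <- pull_volumes(volumes, group_a_ids, structure)
  xb <- pull_volumes(volumes, group_b_ids, structure)
  x <- c(xa, xb)
  na <- length(xa); n <- length(x)
  t_obs <- abs(obs$t_statistic)
  n_exact <- choose(n, na)
  if (n_exact <= exact_limit) {
    idx <- combn(n, na)
    tt <- perm_t_stats(x, idx, variant)
    p <- mean(abs(tt) >= t_obs - 1e-12)
    used <- ncol(idx); exact <- TRUE
  } else {
    idx <- with_substream(seed, 6L,
      vapply(seq_len(n_permutations), function(i) sample.int(n, na),
             integer(na)))
    tt <- perm_t_stats(x, idx, variant)
    p <- (1 + sum(abs(tt) >= t_obs - 1e-12)) / (1 + n_permutations)
    used <- n_permutations; exact <- FALSE
  }
  out <- obs
  out$p_perm <- p
  out$n_permutations <- used
  out$exact <- exact
  out$seed <- seed
  out
}

# |t| for many relabelings at once; idx is an na x K matrix of group-A
# member indices into x.
perm_t_stats <- function(x, idx, variant = "student") {
  na <- nrow(idx); n <- length(x); nb <- n - na
  S <- sum(x); Q <- sum(x^2)
  xa <- matrix(x[idx], nrow = na)
  sa <- colSums(xa); qa <- colSums(xa^2)
  ma <- sa / na; mb <- (S - sa) / nb
  va <- (qa - na * ma^2) / (na - 1)
  vb <- ((Q - qa) - nb * mb^2) / (nb - 1)
  va <- pmax(va, 0); vb <- pmax(vb, 0)
  if (variant == "student") {
    se <- sqrt(((na - 1) * va + (nb - 1) * vb) / (n - 2) *
                 (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
  }
  ifelse(se == 0, 0, (ma - mb) / se)
}

#' Split members into carrier and non-carrier groups for a variant
#'
#' Group A holds carriers (genotype >= 1), group B observed non-carriers;
#' members with missing genotypes are dropped. When a volume table is
#' supplied, both groups are restricted to members with volume rows.
#'
#' @param ped a [pedigree()].
#' @param vs a [variant_set()].
#' @param variant_key `"chrom:pos:ref:alt"` key (default: first variant).
#' @param volumes optional volume table for restriction.
#' @return list with `carrier_ids` and `noncarrier_ids`.
#' @export
carrier_groups <- function(ped, vs, variant_key = NULL, volumes = NULL) {
  keys <- variant_keys(vs)
  i <- if (is.null(variant_key)) 1L else match(variant_key, keys)
  if (is.na(i)) stop("variant not found: ", variant_key)
  g <- vs$geno[i, ped$id]
  carriers <- ped$id[!is.na(g) & g >= 1L]
  noncarriers <- ped$id[!is.na(g) & g == 0L]
  if (!is.null(volumes)) {
    carriers <- intersect(carriers, volumes$member_id)
    noncarriers <- intersect(noncarriers, volumes$member_id)
  }
  if (!length(carriers) || !length(noncarriers))
    stop("all members fall in one genotype class")
  list(carrier_ids = carriers, noncarrier_ids = noncarriers)
}

#' Compare every structure's volumes between two groups
#'
#' Runs the t-test and the randomization test per structure and returns a
#' tidy table. Multiple-testing correction across structures is off by
#' default, matching common single-family practice; `adjust =
#' "bonferroni"` multiplies permutation p-values by the structure count.
#'
#' @inheritParams permutation_test
#' @param structures structure columns to test (default: all non-id
#'   columns).
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return data frame with one row per structure: group sizes, t statistic,
#'   `p_t`, `p_perm`, `p_adj`, `exact`.
#' @export
compare_volumes <- function(volumes, group_a_ids, group_b_ids,
                            structures = NULL, n_permutations = 10000L,
                            seed = 1L, variant = "student",
                            adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (is.null(structures))
    structures <- setdiff(names(volumes), "member_id")
  rows <- lapply(structures, function(s) {
    r <- permutation_test(volumes, group_a_ids, group_b_ids, s,
                          n_permutations, seed, variant)
    data.frame(structure = s, n_a = r$n_a, n_b = r$n_b,
               t_statistic = r$t_statistic, p_t = r$p_t,
               p_perm = r$p_perm, exact = r$exact,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (adjust == "bonferroni")
    pmin(1, out$p_perm * nrow(out)) else out$p_perm
  out
}
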