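# Trait segregation models ---------------------------------------------------

#' Construct a segregation model
#'
#' Four explicit trait models are supported:
#' * `"sporadic"`: affection iid Bernoulli(`prevalence`); 1 free parameter.
#' * `"sporadic_residual"`: sporadic plus a shared nuclear-family latent
#'   binary frailty that multiplies the affection odds of the family's
#'   children (`frailty_prob`, `frailty_or`); 3 free parameters.
#' * `"mendelian_AD"` / `"mendelian_AR"`: major-locus models with
#'   risk-allele frequency `q` (founders in Hardy-Weinberg proportions),
#'   Mendelian transmission, and penetrances `f_carrier` (carrier:
#'   genotype >= 1 under AD, == 2 under AR) and `f_noncarrier`
#'   (phenocopy rate); 3 free parameters.
#'
#' @param kind model kind, see above.
#' @param prevalence,frailty_prob,frailty_or,q,f_carrier,f_noncarrier model
#'   parameters (probabilities in `[0,1]`; `frailty_or > 0`).
#' @return list of class `"segregation_model"` with a `k` free-parameter
#'   count.
#' @export
segregation_model <- function(kind = c("sporadic", "sporadic_residual",
                                       "mendelian_AD", "mendelian_AR"),
                              prevalence = 0.1, frailty_prob = 0.5,
                              frailty_or = 1, q = 0.1, f_carrier = 0.5,
                              f_noncarrier = 0.05) {
  kind <- match.arg(kind)
  probs <- c(prevalence, frailty_prob, q, f_carrier, f_noncarrier)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (frailty_or <= 0) stop("frailty_or must be positive")
  k <- switch(kind, sporadic = 1L, sporadic_residual = 3L,
              mendelian_AD = 3L, mendelian_AR = 3L)
  structure(list(kind = kind, prevalence = prevalence,
                 frailty_prob = frailty_prob, frailty_or = frailty_or,
                 q = q, f_carrier = f_carrier, f_noncarrier = f_noncarrier,
                 k = k),
            class = "segregation_model")
}

# phenotype factor: P(observed affection | affection prob p)
pheno_prob <- function(affected, p) {
  ifelse(affected == "affected", p,
         ifelse(affected == "unaffected", 1 - p, 1))
}

penetrance_by_genotype <- function(model) {
  f1 <- model$f_carrier; f0 <- model$f_noncarrier
  if (model$kind == "mendelian_AD") c(f0, f1, f1) else c(f0, f0, f1)
}

# Mendelian transmission array T[child+1, father+1, mother+1]
transmission_array <- local({
  one <- rbind(c(1, 0), c(0.5, 0.5), c(0, 1))  # P(transmit alt | g)
  arr <- array(0, c(3, 3, 3))
  for (gf in 0:2) for (gm in 0:2) for (af in 0:1) for (am in 0:1)
    arr[af + am + 1L, gf + 1L, gm + 1L] <-
      arr[af + am + 1L, gf + 1L, gm + 1L] +
      one[gf + 1L, af + 1L] * one[gm + 1L, am + 1L]
  arr
})

# --- tiny factor algebra over {0,1,2}-valued member genotypes ---------------

# Expand a factor's value vector to the 3^m cell grid over `vars` by
# vectorized base-3 digit arithmetic (cells vary fastest in vars[1]).
factor_expand <- function(f, vars) {
  m <- length(vars)
  if (identical(f$vars, vars)) return(as.numeric(f$arr))
  cells <- 0:(3L^m - 1L)
  lin <- rep(1L, 3L^m)
  pow <- 1L
  for (j in seq_along(f$vars)) {
    d <- match(f$vars[j], vars)
    lin <- lin + (cells %/% 3L^(d - 1L) %% 3L) * pow
    pow <- pow * 3L
  }
  as.numeric(f$arr)[lin]
}

factor_product <- function(fs) {
  vars <- unique(unlist(lapply(fs, `[[`, "vars")))
  arr <- factor_expand(fs[[1L]], vars)
  for (f in fs[-1L]) arr <- arr * factor_expand(f, vars)
  list(vars = vars, arr = arr)
}

factor_sum_out <- function(f, v) {
  k <- match(v, f$vars)
  vars <- f$vars[-k]
  if (!length(vars))
    return(list(vars = character(), arr = sum(f$arr)))
  perm <- c(seq_along(f$vars)[-k], k)
  arr <- aperm(array(f$arr, rep(3L, length(f$vars))), perm)
  arr <- rowSums(matrix(arr, ncol = 3L))
  list(vars = vars, arr = arr)
}

# Exact likelihood of arbitrary single-locus evidence on a loop-free
# pedigree: founders ~ HW(q), Mendelian transmission, `evid` a members x 3
# matrix of P(member's observed data | genotype).
peel_likelihood <- function(ped, q, evid) {
  hw <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  factors <- list()
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    if (is.na(ped$father[i])) {
      factors[[length(factors) + 1L]] <-
        list(vars = id, arr = hw * evid[i, ])
    } else {
      arr <- transmission_array * rep(evid[i, ], 9L)
      factors[[length(factors) + 1L]] <-
        list(vars = c(id, ped$father[i], ped$mother[i]), arr = arr)
    }
  }
  elim_order <- ped$id[order(-ped$generation, ped$id)]
  const <- 1
  for (v in elim_order) {
    has_v <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (!any(has_v)) next
    prod_f <- factor_product(factors[has_v])
    newf <- factor_sum_out(prod_f, v)
    factors <- factors[!has_v]
    if (!length(newf$vars)) const <- const * newf$arr
    else factors[[length(factors) + 1L]] <- newf
  }
  for (f in factors) const <- const * sum(f$arr)  # defensive; none expected
  const
}

#' Exact pedigree log-likelihood of affection statuses
#'
#' Computes the log-likelihood of the observed affection statuses under a
#' [segregation_model()]. Major-locus models use exact Elston-Stewart-style
#' peeling (variable elimination over latent genotypes, children eliminated
#' before parents), exact up to floating point; the sporadic models have
#' closed forms. Members of unknown status contribute no information.
#' Zero-probability configurations return `-Inf` rather than erroring;
#' pedigrees with marriage or inbreeding loops are rejected.
#'
#' @param ped a [pedigree()].
#' @param model a [segregation_model()].
#' @param check_loops skip the (repeated) loop check when the caller has
#'   already validated the pedigree.
#' @return the log-likelihood (natural log).
#' @export
pedigree_likelihood <- function(ped, model, check_loops = TRUE) {
  if (check_loops && has_loops(ped))
    stop("pedigree contains a loop; exact peeling unsupported")
  y <- ped$affected
  if (model$kind == "sporadic") {
    return(sum(log(pheno_prob(y, model$prevalence))))
  }
  if (model$kind == "sporadic_residual") {
    p <- model$prevalence
    odds <- p / (1 - p)
    odds_hi <- odds * model$frailty_or
    p_hi <- odds_hi / (1 + odds_hi)
    fam <- paste(ped$father, ped$mother)
    is_child <- !is.na(ped$father)
    ll <- sum(log(pheno_prob(y[!is_child], p)))  # founders: baseline
    for (f in unique(fam[is_child])) {
      i <- which(is_child & fam == f)
      l0 <- prod(pheno_prob(y[i], p))
      l1 <- prod(pheno_prob(y[i], p_hi))
      ll <- ll + log((1 - model$frailty_prob) * l0 +
                       model$frailty_prob * l1)
    }
    return(ll)
  }
  pen <- penetrance_by_genotype(model)
  evid <- t(vapply(y, function(yy) pheno_prob(rep(yy, 3L), pen),
                   numeric(3)))
  lik <- peel_likelihood(ped, model$q, evid)
  if (lik <= 0) -Inf else log(lik)
}

#' Summarize a fitted model as likelihood, deviance and AIC
#'
#' @param kind model kind (any label).
#' @param lnL log-likelihood.
#' @param k number of free parameters.
#' @return one-row data frame with `model`, `k`, `lnL`, `neg2lnL`
#'   (`= -2 lnL`) and `aic` (`= -2 lnL + 2k`).
#' @export
segregation_fit <- function(kind, lnL, k) {
  data.frame(model = kind, k = as.integer(k), lnL = lnL,
             neg2lnL = -2 * lnL, aic = -2 * lnL + 2 * k,
             stringsAsFactors = FALSE)
}

#' Fit competing segregation models by maximum likelihood
#'
#' Free parameters are maximized by a deterministic coarse-grid search
#' followed by Nelder-Mead refinement on a logit/log scale; the sporadic
#' model has a closed-form MLE. Fits are returned sorted by AIC; every fit
#' within `tie_margin` of the minimum is flagged as best.
#'
#' @param ped a [pedigree()].
#' @param models character vector of model kinds to fit (default all four).
#' @param tie_margin AIC margin for flagging co-best models (default 0.01).
#' @return data frame of class `"segregation_fits"`: per model `k`,
#'   estimates, `lnL`, `neg2lnL`, `aic`, `converged`, `best`.
#' @export
fit_models <- function(ped, models = c("sporadic", "sporadic_residual",
                                       "mendelian_AD", "mendelian_AR"),
                       tie_margin = 0.01) {
  if (!length(models)) stop("need at least one model")
  if (has_loops(ped))
    stop("pedigree contains a loop; exact peeling unsupported")
  logit <- function(p) log(p / (1 - p))
  expit <- function(x) 1 / (1 + exp(-x))
  known <- ped$affected != "unknown"
  fit_one <- function(kind) {
    if (kind == "sporadic") {
      p <- sum(ped$affected == "affected") / sum(known)
      p <- min(max(p, 1e-12), 1 - 1e-12)
      m <- segregation_model("sporadic", prevalence = p)
      ll <- pedigree_likelihood(ped, m)
      return(cbind(segregation_fit(kind, ll, m$k),
                   prevalence = p, frailty_prob = NA, frailty_or = NA,
                   q = NA, f_carrier = NA, f_noncarrier = NA,
                   converged = TRUE))
    }
    if (kind == "sporadic_residual") {
      make <- function(th) segregation_model(
        "sporadic_residual", prevalence = expit(th[1L]),
        frailty_prob = expit(th[2L]), frailty_or = exp(th[3L]))
      grid <- expand.grid(p = c(0.05, 0.2, 0.4, 0.6),
                          pi = c(0.2, 0.5, 0.8),
                          lor = c(-2, 0, 2))
      starts <- cbind(logit(grid$p), logit(grid$pi), grid$lor)
    } else {
      make <- function(th) segregation_model(
        kind, q = expit(th[1L]), f_carrier = expit(th[2L]),
        f_noncarrier = expit(th[3L]))
      grid <- expand.grid(q = c(0.01, 0.05, 0.1, 0.2, 0.35, 0.5),
                          f1 = c(0.5, 0.7, 0.9, 0.99),
                          f0 = c(0.001, 0.01, 0.05, 0.2))
      starts <- cbind(logit(grid$q), logit(grid$f1), logit(grid$f0))
    }
    nll <- function(th) {
      v <- -pedigree_likelihood(ped, make(th), check_loops = FALSE)
      if (!is.finite(v)) 1e10 else v
    }
    vals <- apply(starts, 1L, nll)
    best <- which.min(vals)
    opt <- tryCatch(
      optim(starts[best, ], nll, method = "Nelder-Mead",
            control = list(maxit = 300, reltol = 1e-8)),
      error = function(e) NULL)
    converged <- !is.null(opt) && opt$convergence == 0L &&
      opt$value < 1e9
    if (is.null(opt) || opt$value > vals[best]) {
      th <- starts[best, ]; val <- vals[best]
    } else {
      th <- opt$par; val <- opt$value
    }
    m <- make(th)
    est <- cbind(segregation_fit(kind, -val, m$k),
                 prevalence = if (kind == "sporadic_residual")
                   m$prevalence else NA,
                 frailty_prob = if (kind == "sporadic_residual")
                   m$frailty_prob else NA,
                 frailty_or = if (kind == "sporadic_residual")
                   m$frailty_or else NA,
                 q = if (grepl("mendelian", kind)) m$q else NA,
                 f_carrier = if (grepl("mendelian", kind))
                   m$f_carrier else NA,
                 f_noncarrier = if (grepl("mendelian", kind))
                   m$f_noncarrier else NA,
                 converged = converged)
    est
  }
  fits <- do.call(rbind, lapply(models, fit_one))
  fits <- fits[order(fits$aic), , drop = FALSE]
  fits$best <- fits$aic <= min(fits$aic) + tie_margin
  rownames(fits) <- NULL
  class(fits) <- c("segregation_fits", "data.frame")
  fits
}

# Variant-level filters -------------------------------------------------------

#' Mendelian consistency of observed genotypes in the pedigree
#'
#' `TRUE` when every non-founder's genotype is compatible with receiving
#' one allele from each parent, marginalizing over missing genotypes
#' (computed as positivity of the exact pedigree likelihood of the observed
#' genotype configuration under an uninformative founder prior).
#'
#' @param vs a [variant_set()] (all variants are checked) or a named
#'   genotype vector for a single variant.
#' @param ped a [pedigree()].
#' @return logical vector, one element per variant.
#' @export
mendelian_consistency <- function(vs, ped) {
  geno <- if (inherits(vs, "variant_set")) vs$geno
  else matrix(vs, 1L, dimnames = list(NULL, names(vs)))
  geno <- geno[, ped$id, drop = FALSE]
  vapply(seq_len(nrow(geno)), function(i) {
    g <- geno[i, ]
    evid <- matrix(1, nrow(ped), 3L)
    obs <- !is.na(g)
    evid[obs, ] <- 0
    evid[cbind(which(obs), g[obs] + 1L)] <- 1
    peel_likelihood(ped, 0.5, evid) > 0
  }, logical(1))
}

#' Co-segregation filter under a stated inheritance mode
#'
#' Tests whether each variant's genotype pattern tracks affection status:
#' under AD every affected member must be an observed carrier (genotype
#' >= 1) and no healthy comparator may carry any alternate allele; under AR
#' affected members must be homozygous alternate and no comparator may be.
#' Exempt members (and missing comparator genotypes) are unconstrained; a
#' missing genotype in an affected member fails the carrier requirement.
#'
#' @param vs a [variant_set()].
#' @param groups an [make_groups()] result.
#' @param mode `"either"` (default: AD or AR passes), `"AD"` or `"AR"`.
#' @return list with logical vectors `pass`, `AD`, `AR`.
#' @export
cosegregation_filter <- function(vs, groups, mode = c("either", "AD", "AR")) {
  mode <- match.arg(mode)
  aff <- vs$geno[, groups$affected_ids, drop = FALSE]
  cmp <- vs$geno[, groups$healthy_comparator_ids, drop = FALSE]
  ad <- rowSums(!is.na(aff) & aff >= 1L) == ncol(aff) &
    rowSums(!is.na(cmp) & cmp >= 1L) == 0L
  ar <- rowSums(!is.na(aff) & aff == 2L) == ncol(aff) &
    rowSums(!is.na(cmp) & cmp == 2L) == 0L
  pass <- switch(mode, either = ad | ar, AD = ad, AR = ar)
  list(pass = pass, AD = ad, AR = ar)
}
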