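# Independent oracles, deliberately brute-force.

# full enumeration over all 3^n genotype vectors
oracle_enum_loglik <- function(ped, model) {
  stopifnot(nrow(ped) <= 7L)
  pen <- if (model$kind == "mendelian_AD")
    c(model$f_noncarrier, model$f_carrier, model$f_carrier)
  else c(model$f_noncarrier, model$f_noncarrier, model$f_carrier)
  q <- model$q
  hw <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  trans <- function(gc, gf, gm) {
    pf <- c(0, 0.5, 1)[gf + 1L]; pm <- c(0, 0.5, 1)[gm + 1L]
    p <- c((1 - pf) * (1 - pm), pf * (1 - pm) + (1 - pf) * pm, pf * pm)
    p[gc + 1L]
  }
  grid <- as.matrix(expand.grid(rep(list(0:2), nrow(ped))))
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    p <- 1
    for (i in seq_len(nrow(ped))) {
      p <- p * if (is.na(ped$father[i])) hw[g[i] + 1L]
      else trans(g[i], g[match(ped$father[i], ped$id)],
                 g[match(ped$mother[i], ped$id)])
      py <- pen[g[i] + 1L]
      p <- p * switch(ped$affected[i], affected = py,
                      unaffected = 1 - py, 1)
    }
    tot <- tot + p
  }
  log(tot)
}

# per-variant sum with an explicit loop and a window dictionary
oracle_dmd <- function(vs, groups, window_size) {
  env <- new.env()
  for (i in seq_len(n_variants(vs))) {
    w <- paste(vs$sites$chrom[i],
               ((vs$sites$pos[i] - 1) %/% window_size) * window_size + 1)
    od <- 0; oh <- 0
    for (id in groups$affected_ids) {
      g <- vs$geno[i, id]
      if (!is.na(g) && g >= 1) od <- od + 1
    }
    for (id in groups$healthy_all_ids) {
      g <- vs$geno[i, id]
      if (!is.na(g) && g >= 1) oh <- oh + 1
    }
    cur <- mget(w, envir = env, ifnotfound = 0)[[1]]
    assign(w, cur + od / groups$n_d - oh / groups$n_h, envir = env)
  }
  out <- unlist(as.list(env))
  out[order(names(out))]
}

# exhaustive relabeling p-value using stats::t.test per relabeling
oracle_perm_p <- function(xa, xb, var_equal = TRUE) {
  x <- c(xa, xb)
  na <- length(xa)
  combos <- combn(length(x), na)
  t_obs <- abs(stats::t.test(xa, xb, var.equal = var_equal)$statistic)
  hits <- 0
  for (j in seq_len(ncol(combos))) {
    a <- x[combos[, j]]; b <- x[-combos[, j]]
    tt <- abs(stats::t.test(a, b, var.equal = var_equal)$statistic)
    if (tt >= t_obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(combos)
}
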