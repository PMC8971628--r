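# Differential mutation density ----------------------------------------------

#' Tally variant carrier occurrences per fixed chromosome window
#'
#' Chromosomes are tiled from position 1 in fixed non-overlapping windows
#' (window `w` covers 1-based positions `[(w-1)*size + 1, w*size]`); a
#' variant belongs to the window containing its position. Occurrence is the
#' number of group members carrying at least one alternate allele; missing
#' genotypes count as non-carrier.
#'
#' @param vs a [variant_set()].
#' @param groups an [make_groups()] result; the affected set and the full
#'   healthy set are tallied.
#' @param window_size window width in bp (default 1e6).
#' @return data frame with one row per variant: `chrom`, `window_start`,
#'   `variant_key`, `o_d`, `o_h`.
#' @export
window_tally <- function(vs, groups, window_size = 1000000L) {
  if (window_size <= 0) stop("window_size must be positive")
  if (n_variants(vs) == 0L)
    return(data.frame(chrom = character(), window_start = integer(),
                      variant_key = character(), o_d = integer(),
                      o_h = integer()))
  carrier <- !is.na(vs$geno) & vs$geno >= 1L
  o_d <- rowSums(carrier[, groups$affected_ids, drop = FALSE])
  o_h <- rowSums(carrier[, groups$healthy_all_ids, drop = FALSE])
  data.frame(
    chrom = vs$sites$chrom,
    window_start = as.integer((vs$sites$pos - 1L) %/% window_size) *
      as.integer(window_size) + 1L,
    variant_key = variant_keys(vs),
    o_d = as.integer(o_d), o_h = as.integer(o_h),
    stringsAsFactors = FALSE)
}

#' Differential mutation density score of one window
#'
#' `DMD = sum_i (O_i,d / N_d - O_i,h / N_h)` over the `n` variants of the
#' window: each variant contributes its affected carrier fraction minus its
#' healthy carrier fraction, so every score is an exact integer multiple of
#' `1 / lcm(N_d, N_h)` and is bounded by `[-n, n]`.
#'
#' @param tally rows of a [window_tally()] table belonging to one window.
#' @param n_d,n_h affected and healthy group sizes (>= 1).
#' @return the DMD score.
#' @export
dmd_score <- function(tally, n_d, n_h) {
  if (n_d < 1L || n_h < 1L) stop("group sizes must be >= 1")
  if (any(tally$o_d > n_d) || any(tally$o_h > n_h))
    stop("occurrence exceeds group size")
  if (any(tally$o_d < 0L) || any(tally$o_h < 0L))
    stop("negative occurrence")
  sum(tally$o_d / n_d - tally$o_h / n_h)
}

#' Differential mutation density landscape
#'
#' Computes the per-window DMD score across the genome represented in the
#' variant set.
#'
#' @inheritParams window_tally
#' @return data frame of class `"dmd_landscape"`: `chrom`, `window_start`,
#'   `n` (variants in window), `dmd`; attributes `n_d`, `n_h`,
#'   `window_size`.
#' @export
dmd_landscape <- function(vs, groups, window_size = 1000000L) {
  tally <- window_tally(vs, groups, window_size)
  n_d <- groups$n_d; n_h <- groups$n_h
  if (!nrow(tally)) {
    out <- data.frame(chrom = character(), window_start = integer(),
                      n = integer(), dmd = numeric())
  } else {
    key <- paste(tally$chrom, tally$window_start)
    contrib <- tally$o_d / n_d - tally$o_h / n_h
    agg <- data.frame(
      chrom = tapply(tally$chrom, key, `[`, 1L),
      window_start = as.integer(tapply(tally$window_start, key, `[`, 1L)),
      n = as.integer(tapply(contrib, key, length)),
      dmd = as.numeric(tapply(contrib, key, sum)),
      stringsAsFactors = FALSE)
    out <- agg[order(agg$chrom, agg$window_start), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, n_d = n_d, n_h = n_h, window_size = as.integer(window_size),
            class = c("dmd_landscape", "data.frame"))
}

#' Call DMD hotspots
#'
#' Windows whose score strictly exceeds the threshold; adjacent qualifying
#' windows on the same chromosome merge into one hotspot. Hotspots are
#' labeled by overlapping cytogenetic bands when a band table is supplied,
#' otherwise `chrom:window_start`.
#'
#' @param landscape a [dmd_landscape()].
#' @param threshold strict lower bound for a hotspot window (default 20).
#' @param vs optional [variant_set()] used to annotate overlapping genes and
#'   variant counts.
#' @param bands optional data frame `chrom`, `start`, `end`, `band`
#'   (1-based inclusive).
#' @return data frame: `label`, `chrom`, `start`, `end`, `dmd` (sum over
#'   merged windows), `n_windows`, `variant_count`, `genes`
#'   (comma-collapsed).
#' @export
call_hotspots <- function(landscape, threshold = 20, vs = NULL,
                          bands = NULL) {
  ws <- attr(landscape, "window_size")
  hot <- landscape[landscape$dmd > threshold, , drop = FALSE]
  empty <- data.frame(label = character(), chrom = character(),
                      start = integer(), end = integer(), dmd = numeric(),
                      n_windows = integer(), variant_count = integer(),
                      genes = character(), stringsAsFactors = FALSE)
  if (!nrow(hot)) return(empty)
  hot <- hot[order(hot$chrom, hot$window_start), , drop = FALSE]
  new_run <- c(TRUE, !(hot$chrom[-1L] == hot$chrom[-nrow(hot)] &
                         hot$window_start[-1L] ==
                           hot$window_start[-nrow(hot)] + ws))
  run <- cumsum(new_run)
  out <- do.call(rbind, lapply(split(seq_len(nrow(hot)), run), function(i) {
    chrom <- hot$chrom[i[1L]]
    start <- min(hot$window_start[i])
    end <- max(hot$window_start[i]) + ws - 1L
    genes <- ""
    vcount <- sum(hot$n[i])
    if (!is.null(vs)) {
      inwin <- vs$sites$chrom == chrom & vs$sites$pos >= start &
        vs$sites$pos <= end
      genes <- paste(sort(unique(stats::na.omit(vs$sites$gene[inwin]))),
                     collapse = ",")
      vcount <- sum(inwin)
    }
    label <- paste0(chrom, ":", start)
    if (!is.null(bands)) {
      hit <- bands$chrom == chrom & bands$start <= end & bands$end >= start
      if (any(hit)) label <- paste(unique(bands$band[hit]), collapse = "/")
    }
    data.frame(label = label, chrom = chrom, start = start, end = end,
               dmd = sum(hot$dmd[i]), n_windows = length(i),
               variant_count = vcount, genes = genes,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write a DMD landscape as BEDGRAPH-style TSV
#'
#' Coordinates convert to the BED convention (0-based half-open) at this
#' boundary.
#'
#' @param landscape a [dmd_landscape()].
#' @param path output path.
#' @export
write_landscape <- function(landscape, path) {
  ws <- attr(landscape, "window_size")
  out <- data.frame(chrom = landscape$chrom,
                    start = landscape$window_start - 1L,
                    end = landscape$window_start - 1L + ws,
                    dmd = landscape$dmd)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Consensus / differential CNV screen ----------------------------------------

#' Consensus CNV calls between two callers
#'
#' Retains calls from set A that have a same-member, same-copy-state call in
#' set B on the same chromosome with reciprocal overlap at least
#' `min_reciprocal_overlap`; the reported interval is the intersection with
#' the best-matching B call. Caller is relabeled `"consensus"`.
#'
#' @param calls_a,calls_b `"cnv_calls"` data frames (1-based inclusive).
#' @param min_reciprocal_overlap required fraction of both intervals
#'   (default 0.5, in `(0, 1]`).
#' @return consensus `"cnv_calls"` data frame.
#' @export
consensus_cnv <- function(calls_a, calls_b, min_reciprocal_overlap = 0.5) {
  if (min_reciprocal_overlap <= 0 || min_reciprocal_overlap > 1)
    stop("min_reciprocal_overlap must be in (0, 1]")
  empty <- cnv_calls(data.frame(chrom = character(), start = integer(),
                                end = integer(), copy_state = character(),
                                caller = character(),
                                member_id = character()))
  if (!nrow(calls_a) || !nrow(calls_b)) return(empty)
  gr <- function(x) GenomicRanges::GRanges(
    paste(x$member_id, x$copy_state, x$chrom, sep = "|"),
    IRanges::IRanges(x$start, x$end))
  ga <- gr(calls_a); gb <- gr(calls_b)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(ga, gb))
  if (!length(hits)) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  inter_s <- pmax(calls_a$start[qi], calls_b$start[si])
  inter_e <- pmin(calls_a$end[qi], calls_b$end[si])
  ov <- inter_e - inter_s + 1L
  recip <- pmin(ov / (calls_a$end[qi] - calls_a$start[qi] + 1L),
                ov / (calls_b$end[si] - calls_b$start[si] + 1L))
  keep <- recip >= min_reciprocal_overlap
  if (!any(keep)) return(empty)
  qi <- qi[keep]; inter_s <- inter_s[keep]; inter_e <- inter_e[keep]
  recip <- recip[keep]
  best <- tapply(seq_along(qi), qi, function(j) j[which.max(recip[j])])
  best <- as.integer(best)
  out <- data.frame(chrom = calls_a$chrom[qi[best]], start = inter_s[best],
                    end = inter_e[best],
                    copy_state = calls_a$copy_state[qi[best]],
                    caller = "consensus",
                    member_id = calls_a$member_id[qi[best]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$member_id), , drop = FALSE]
  rownames(out) <- NULL
  cnv_calls(out)
}

#' Group-differential CNV regions
#'
#' Merges consensus calls into regions (per chromosome and copy state) and
#' keeps regions whose carrier sets separate the groups: carried by at
#' least one affected member and no healthy comparator, or vice versa.
#' Exempt members are unconstrained.
#'
#' @param cnvs consensus `"cnv_calls"`.
#' @param groups an [make_groups()] result.
#' @return `"cnv_calls"` subset of calls lying in differential regions,
#'   with a `region` label column appended.
#' @export
differential_cnv <- function(cnvs, groups) {
  empty <- cbind(cnv_calls(data.frame(chrom = character(),
                                      start = integer(), end = integer(),
                                      copy_state = character(),
                                      caller = character(),
                                      member_id = character())),
                 region = character())
  if (!nrow(cnvs)) return(empty)
  key <- paste(cnvs$chrom, cnvs$copy_state, sep = "|")
  keep <- logical(nrow(cnvs))
  region <- character(nrow(cnvs))
  for (k in unique(key)) {
    i <- which(key == k)
    ir <- IRanges::IRanges(cnvs$start[i], cnvs$end[i])
    red <- IRanges::reduce(ir)
    hit <- IRanges::findOverlaps(ir, red)
    reg_of <- S4Vectors::subjectHits(hit)[match(seq_along(i),
                                                S4Vectors::queryHits(hit))]
    for (r in seq_along(red)) {
      members <- unique(cnvs$member_id[i[reg_of == r]])
      n_aff <- length(intersect(members, groups$affected_ids))
      n_cmp <- length(intersect(members, groups$healthy_comparator_ids))
      if ((n_aff >= 1L && n_cmp == 0L) || (n_aff == 0L && n_cmp >= 1L)) {
        sel <- i[reg_of == r]
        keep[sel] <- TRUE
        region[sel] <- sprintf("%s:%d-%d:%s", cnvs$chrom[i[1L]],
                               IRanges::start(red)[r], IRanges::end(red)[r],
                               cnvs$copy_state[i[1L]])
      }
    }
  }
  out <- cbind(cnvs[keep, , drop = FALSE], region = region[keep])
  rownames(out) <- NULL
  out
}
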