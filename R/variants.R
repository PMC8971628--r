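# Annotated variant sets -----------------------------------------------------

#' Deleteriousness predictor panel
#'
#' The default 13-predictor panel used for deleteriousness voting: twelve
#' dbNSFP-style algorithms (SIFT, both PolyPhen2 models, LRT,
#' MutationTaster, MutationAssessor, FATHMM, PROVEAN, MetaSVM, MetaLR,
#' GERP++, PhyloP) plus CADD as the configurable thirteenth slot.
#' @export
PREDICTORS <- c("SIFT", "Polyphen2_HDIV", "Polyphen2_HVAR", "LRT",
                "MutationTaster", "MutationAssessor", "FATHMM", "PROVEAN",
                "MetaSVM", "MetaLR", "GERP", "PhyloP", "CADD")

# Population-frequency columns recognized in annotation tables, in the
# ANNOVAR-style header dialect, mapped to internal names.
FREQ_COLUMNS <- c(
  ExAC_ALL = "exac_all", ExAC_EAS = "exac_eas",
  ExAC_nonpsych_ALL = "exac_nonpsych_all",
  ExAC_nonpsych_EAS = "exac_nonpsych_eas",
  ExAC_psych_ALL = "exac_psych_all",
  `1000g2015aug_all` = "g1000_all", `1000g2015aug_eas` = "g1000_eas",
  CONVERGE_case = "converge_case", CONVERGE_control = "converge_control")

# Reference-population columns the rarity filter inspects (case/control
# study frequencies are association inputs, not rarity evidence).
RARITY_COLUMNS <- c("exac_all", "exac_eas", "exac_nonpsych_all",
                    "exac_nonpsych_eas", "exac_psych_all",
                    "g1000_all", "g1000_eas")

SITE_COLUMNS <- c("chrom", "pos", "ref", "alt", "variant_class",
                  "gene", "func", "exonic_func", unname(FREQ_COLUMNS))

#' Construct a variant set
#'
#' Container for a table of annotated SNV/InDel records with per-member
#' genotypes. Genotypes are alternate-allele counts (0, 1, 2; `NA` =
#' missing); phase is ignored. One row per (chrom, pos, ref, alt); rows are
#' kept sorted by chromosome then position.
#'
#' @param sites data frame with at least `chrom`, `pos`, `ref`, `alt`;
#'   missing annotation columns (`variant_class`, `gene`, `func`,
#'   `exonic_func`, frequency columns) are filled with `NA`/derived values.
#' @param geno integer matrix, variants x members, member ids as column
#'   names.
#' @param calls character matrix, variants x predictors, entries
#'   `"damaging"`, `"tolerated"` or `"unknown"`; default all-unknown.
#' @param scores optional numeric matrix of raw predictor scores (same
#'   shape as `calls`) for score-only predictors.
#' @return object of class `"variant_set"`: list with elements `sites`,
#'   `geno`, `calls`, `scores`.
#' @export
variant_set <- function(sites, geno, calls = NULL, scores = NULL) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  n <- nrow(sites)
  for (col in c("chrom", "ref", "alt"))
    sites[[col]] <- as.character(sites[[col]])
  sites$pos <- as.integer(sites$pos)
  if (any(sites$pos < 1L, na.rm = TRUE)) stop("positions must be >= 1")
  if (any(sites$ref == sites$alt)) stop("alt allele equal to ref")
  if (is.null(sites$variant_class))
    sites$variant_class <- ifelse(nchar(sites$ref) == nchar(sites$alt),
                                  "SNV", "InDel")
  for (col in setdiff(SITE_COLUMNS, names(sites)))
    sites[[col]] <- if (col %in% unname(FREQ_COLUMNS)) NA_real_ else NA_character_
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != n) stop("geno rows must match sites rows")
  if (is.null(colnames(geno))) stop("geno must have member ids as colnames")
  if (any(geno < 0L | geno > 2L, na.rm = TRUE))
    stop("genotypes must be allele counts in 0..2 or NA")
  if (is.null(calls)) {
    calls <- matrix("unknown", n, length(PREDICTORS),
                    dimnames = list(NULL, PREDICTORS))
  } else {
    calls <- as.matrix(calls)
    if (nrow(calls) != n) stop("calls rows must match sites rows")
    if (!all(calls %in% c("damaging", "tolerated", "unknown")))
      stop("predictor calls must be damaging/tolerated/unknown")
  }
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    if (nrow(scores) != n) stop("scores rows must match sites rows")
  }
  ord <- order(sites$chrom, sites$pos, sites$ref, sites$alt)
  vs <- list(sites = sites[ord, SITE_COLUMNS, drop = FALSE],
             geno = geno[ord, , drop = FALSE],
             calls = calls[ord, , drop = FALSE],
             scores = if (is.null(scores)) NULL else scores[ord, , drop = FALSE])
  rownames(vs$sites) <- NULL
  class(vs) <- "variant_set"
  vs
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d variants (%d SNV, %d InDel) x %d members\n",
              n_variants(x), sum(x$sites$variant_class == "SNV"),
              sum(x$sites$variant_class == "InDel"), ncol(x$geno)))
  invisible(x)
}

#' @rdname variant_set
#' @param vs a variant set.
#' @export
n_variants <- function(vs) nrow(vs$sites)

#' @rdname variant_set
#' @export
variant_keys <- function(vs)
  paste(vs$sites$chrom, vs$sites$pos, vs$sites$ref, vs$sites$alt, sep = ":")

#' @rdname variant_set
#' @param i integer or logical index of variants to keep.
#' @export
subset_variants <- function(vs, i) {
  out <- list(sites = vs$sites[i, , drop = FALSE],
              geno = vs$geno[i, , drop = FALSE],
              calls = vs$calls[i, , drop = FALSE],
              scores = if (is.null(vs$scores)) NULL
                       else vs$scores[i, , drop = FALSE])
  rownames(out$sites) <- NULL
  class(out) <- "variant_set"
  out
}

normalize_exonic_func <- function(x) {
  x <- tolower(as.character(x))
  out <- rep(NA_character_, length(x))
  out[grepl("^nonsynonymous", x)] <- "nonsynonymous"
  out[grepl("^synonymous", x)] <- "synonymous"
  out[grepl("stopgain|stoploss", x)] <- "stopgain"
  out[grepl("^frameshift", x)] <- "frameshift"
  out[grepl("^nonframeshift", x)] <- "nonframeshift"
  out[is.na(out) & !is.na(x) & x != "." & nzchar(x)] <- "other"
  out
}

normalize_func <- function(x) {
  x <- tolower(as.character(x))
  out <- rep(NA_character_, length(x))
  out[grepl("^exonic", x)] <- "exonic"
  out[grepl("splicing", x) & !grepl("^exonic", x)] <- "splicing"
  out[grepl("intronic", x)] <- "intronic"
  out[grepl("utr", x)] <- "UTR"
  out[grepl("intergenic|upstream|downstream", x)] <- "intergenic"
  out[is.na(out) & !is.na(x) & x != "." & nzchar(x)] <- "other"
  out
}

# VCF + annotation reading ----------------------------------------------------

#' Read a multi-sample VCF with an ANNOVAR-style annotation table
#'
#' Parses a VCF 4.x file into a [variant_set()]. Multiallelic rows are split
#' into one record per alternate allele, with genotypes recoded to the count
#' of that allele. An optional tab-separated annotation table (header
#' required; `Chr`/`Start`/`Ref`/`Alt` key columns, Table-3-style frequency
#' headers, predictor call columns `<name>_pred` coded `D`/`T`/`.`) is
#' joined on chrom/pos/ref/alt; records that fail the join keep unknown
#' annotation and raise a warning.
#'
#' @param vcf_path VCF file path.
#' @param anno_path optional annotation TSV path.
#' @param ped optional [pedigree()]; when given, VCF sample ids must match
#'   the member ids exactly (any symmetric difference is an error).
#' @param chrom_style chromosome-name style, see [normalize_chrom()].
#' @return a [variant_set()].
#' @export
read_variants <- function(vcf_path, anno_path = NULL, ped = NULL,
                          chrom_style = "chr") {
  vcf <- VariantAnnotation::readVcf(vcf_path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- normalize_chrom(as.character(GenomicRanges::seqnames(rr)),
                           chrom_style)
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  alt_chr <- lapply(seq_along(alt_list),
                    function(i) as.character(alt_list[[i]]))
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF lacks GT genotype field")
  samples <- colnames(gt)
  if (!is.null(ped)) {
    extra <- setdiff(samples, ped$id)
    missing <- setdiff(ped$id, samples)
    if (length(extra) || length(missing))
      stop("VCF sample ids do not match pedigree member ids; ",
           if (length(extra)) paste0("not in pedigree: ",
                                     paste(extra, collapse = ", "), "; "),
           if (length(missing)) paste0("missing from VCF: ",
                                       paste(missing, collapse = ", ")))
  }
  # split genotype strings once: list of integer allele pairs (NA = '.')
  alle <- lapply(seq_len(nrow(gt)), function(i) {
    parts <- strsplit(gt[i, ], "[/|]")
    lapply(parts, function(p) suppressWarnings(as.integer(p)))
  })
  rows <- list(); genos <- list()
  k <- 0L
  for (i in seq_along(chrom)) {
    for (a in seq_along(alt_chr[[i]])) {
      k <- k + 1L
      rows[[k]] <- data.frame(chrom = chrom[i], pos = pos[i], ref = ref[i],
                              alt = alt_chr[[i]][a],
                              stringsAsFactors = FALSE)
      genos[[k]] <- vapply(alle[[i]], function(p) {
        if (anyNA(p)) NA_integer_ else sum(p == a)
      }, integer(1))
    }
  }
  sites <- do.call(rbind, rows)
  geno <- do.call(rbind, genos)
  colnames(geno) <- samples
  vs <- variant_set(sites, geno)
  if (!is.null(anno_path)) vs <- join_annotation(vs, anno_path, chrom_style)
  ps_info("read %d variant records (%d VCF rows) from %s",
          n_variants(vs), length(chrom), vcf_path)
  vs
}

join_annotation <- function(vs, anno_path, chrom_style = "chr") {
  anno <- data.table::fread(anno_path, sep = "\t", header = TRUE,
                            na.strings = c(".", "", "NA"),
                            data.table = FALSE, check.names = FALSE)
  for (col in c("Chr", "Start", "Ref", "Alt"))
    if (!col %in% names(anno))
      stop("annotation table lacks required column ", col)
  akey <- paste(normalize_chrom(anno$Chr, chrom_style), anno$Start,
                anno$Ref, anno$Alt, sep = ":")
  idx <- match(variant_keys(vs), akey)
  if (anyNA(idx))
    warning(sum(is.na(idx)), " variant(s) had no annotation row; ",
            "kept with unknown annotation")
  pick <- function(col) {
    if (!col %in% names(anno)) return(rep(NA, n_variants(vs)))
    anno[[col]][idx]
  }
  vs$sites$gene <- as.character(pick("Gene.refGene"))
  vs$sites$func <- normalize_func(pick("Func.refGene"))
  vs$sites$exonic_func <- normalize_exonic_func(pick("ExonicFunc.refGene"))
  for (j in seq_along(FREQ_COLUMNS)) {
    v <- suppressWarnings(as.numeric(pick(names(FREQ_COLUMNS)[j])))
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stop("frequency outside [0,1] in column ", names(FREQ_COLUMNS)[j])
    vs$sites[[FREQ_COLUMNS[j]]] <- v
  }
  calls <- matrix("unknown", n_variants(vs), length(PREDICTORS),
                  dimnames = list(NULL, PREDICTORS))
  for (p in PREDICTORS) {
    col <- paste0(p, "_pred")
    if (!col %in% names(anno)) next
    v <- as.character(anno[[col]][idx])
    calls[, p] <- ifelse(is.na(v), "unknown",
                  ifelse(v == "D", "damaging",
                  ifelse(v == "T", "tolerated", "unknown")))
  }
  scores <- NULL
  score_cols <- paste0(PREDICTORS, "_score")
  if (any(score_cols %in% names(anno))) {
    scores <- matrix(NA_real_, n_variants(vs), length(PREDICTORS),
                     dimnames = list(NULL, PREDICTORS))
    for (j in seq_along(PREDICTORS)) {
      col <- score_cols[j]
      if (col %in% names(anno))
        scores[, j] <- suppressWarnings(as.numeric(anno[[col]][idx]))
    }
  }
  vs$calls <- calls
  vs$scores <- scores
  vs
}

# Fixture writers -------------------------------------------------------------

#' Write a variant set as a VCF plus annotation TSV fixture pair
#'
#' Emits a minimal VCF 4.2 (GT-only, one biallelic row per record) and the
#' matching ANNOVAR-style annotation table. Intended for fixtures and
#' simulated data; round-trips through [read_variants()].
#'
#' @param vs a [variant_set()].
#' @param vcf_path,anno_path output paths.
#' @return invisibly, a list of the two paths.
#' @export
write_variant_fixture <- function(vs, vcf_path, anno_path = NULL) {
  members <- colnames(vs$geno)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[vs$geno + 1L], nrow = n_variants(vs))
  gt_str[is.na(vs$geno)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##source=pedscreen",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", members), collapse = "\t"))
  body <- vapply(seq_len(n_variants(vs)), function(i) {
    paste(c(vs$sites$chrom[i], vs$sites$pos[i], ".", vs$sites$ref[i],
            vs$sites$alt[i], ".", "PASS", ".", "GT", gt_str[i, ]),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), vcf_path)
  if (!is.null(anno_path)) {
    fmt <- function(x) ifelse(is.na(x), ".", as.character(x))
    anno <- data.frame(Chr = vs$sites$chrom, Start = vs$sites$pos,
                       End = vs$sites$pos + nchar(vs$sites$ref) - 1L,
                       Ref = vs$sites$ref, Alt = vs$sites$alt,
                       `Func.refGene` = fmt(vs$sites$func),
                       `Gene.refGene` = fmt(vs$sites$gene),
                       `ExonicFunc.refGene` = fmt(recode_exonic_out(
                         vs$sites$exonic_func)),
                       check.names = FALSE, stringsAsFactors = FALSE)
    for (j in seq_along(FREQ_COLUMNS))
      anno[[names(FREQ_COLUMNS)[j]]] <- fmt(vs$sites[[FREQ_COLUMNS[j]]])
    for (p in PREDICTORS)
      anno[[paste0(p, "_pred")]] <-
        c(damaging = "D", tolerated = "T", unknown = ".")[vs$calls[, p]]
    if (!is.null(vs$scores))
      for (p in PREDICTORS)
        if (any(!is.na(vs$scores[, p])))
          anno[[paste0(p, "_score")]] <- fmt(vs$scores[, p])
    write.table(anno, anno_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(vcf = vcf_path, anno = anno_path))
}

recode_exonic_out <- function(x) {
  map <- c(nonsynonymous = "nonsynonymous SNV", synonymous = "synonymous SNV",
           stopgain = "stopgain", frameshift = "frameshift substitution",
           nonframeshift = "nonframeshift substitution", other = "unknown")
  out <- unname(map[x])
  out[is.na(x)] <- NA_character_
  out
}

# CNV + volume IO -------------------------------------------------------------

#' Read / write CNV call sets
#'
#' BED-like tab-separated call sets with header
#' `chrom start end copy_state caller member_id`. On disk coordinates are
#' 0-based half-open (BED convention); in memory they are 1-based inclusive,
#' matching the VCF convention used everywhere else in the package.
#'
#' @param path file path.
#' @return `read_cnv_calls`: data frame of class `"cnv_calls"` with 1-based
#'   inclusive `start`/`end`.
#' @export
read_cnv_calls <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  cnv_calls(data.frame(chrom = x$chrom, start = x$start + 1L, end = x$end,
                       copy_state = x$copy_state, caller = x$caller,
                       member_id = x$member_id, stringsAsFactors = FALSE))
}

#' @rdname read_cnv_calls
#' @param calls a `"cnv_calls"` data frame (1-based inclusive).
#' @export
write_cnv_calls <- function(calls, path) {
  out <- data.frame(chrom = calls$chrom, start = calls$start - 1L,
                    end = calls$end, copy_state = calls$copy_state,
                    caller = calls$caller, member_id = calls$member_id)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_cnv_calls
#' @param df data frame with columns `chrom`, `start`, `end`, `copy_state`
#'   (`"deletion"`/`"duplication"`), `caller`, `member_id`.
#' @export
cnv_calls <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (any(df$start > df$end)) stop("CNV with start > end")
  if (!all(df$copy_state %in% c("deletion", "duplication")))
    stop("copy_state must be 'deletion' or 'duplication'")
  class(df) <- c("cnv_calls", "data.frame")
  df
}

#' Subcortical structures analyzed in volume comparisons
#'
#' Fifteen FSL-FIRST-style subcortical segments plus a cerebellum segment.
#' @export
VOLUME_STRUCTURES <- c(
  "left-thalamus", "left-caudate", "left-putamen", "left-pallidum",
  "left-hippocampus", "left-amygdala", "left-accumbens-area", "brain-stem",
  "right-thalamus", "right-caudate", "right-putamen", "right-pallidum",
  "right-hippocampus", "right-amygdala", "right-accumbens-area",
  "left-cerebellum")

#' Read / write per-member brain-structure volume tables
#'
#' Tab-separated, one row per member: a `member_id` column plus one column
#' per structure, volumes in cubic millimetres (all positive).
#'
#' @param path file path.
#' @return `read_volumes`: data frame with `member_id` and structure
#'   columns.
#' @export
read_volumes <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  if (!"member_id" %in% names(x)) stop("volume table lacks member_id column")
  vols <- x[setdiff(names(x), "member_id")]
  if (any(as.matrix(vols) <= 0, na.rm = TRUE))
    stop("volumes must be positive")
  ps_info("read volumes for %d members, %d structures", nrow(x),
          ncol(vols))
  x
}

#' @rdname read_volumes
#' @param volumes a volume table.
#' @export
write_volumes <- function(volumes, path) {
  write.table(volumes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
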