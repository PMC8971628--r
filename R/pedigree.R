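# Pedigree container ---------------------------------------------------------

#' Construct a pedigree
#'
#' A pedigree is a data frame of members (one row each) carrying parentage,
#' sex, affection status and an inferred generation index, wrapped in the
#' `"pedigree"` S3 class. Founders have both parent ids `NA`; non-founders
#' must have both parents present in the pedigree with the correct sexes,
#' and the parentage graph must be acyclic.
#'
#' @param members data frame with columns `id`, `father`, `mother`
#'   (character; `NA` for founders), `sex` (`"male"`/`"female"`) and
#'   `affected` (`"affected"`/`"unaffected"`/`"unknown"`). Extra columns
#'   (e.g. data-availability flags) are kept.
#' @param family_id single string naming the family.
#' @return object of class `"pedigree"`: the member table with a
#'   `generation` column (founders are generation 1; a child is one past its
#'   deepest parent) and attribute `family_id`.
#' @export
pedigree <- function(members, family_id = "FAM1") {
  members <- as.data.frame(members, stringsAsFactors = FALSE)
  req <- c("id", "father", "mother", "sex", "affected")
  miss <- setdiff(req, names(members))
  if (length(miss))
    stop("pedigree members lack columns: ", paste(miss, collapse = ", "))
  members$id <- as.character(members$id)
  members$father <- as.character(members$father)
  members$mother <- as.character(members$mother)
  if (anyDuplicated(members$id))
    stop("duplicate member ids: ",
         paste(unique(members$id[duplicated(members$id)]), collapse = ", "))
  if (!all(members$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (!all(members$affected %in% c("affected", "unaffected", "unknown")))
    stop("affected must be 'affected', 'unaffected' or 'unknown'")
  one_par <- xor(is.na(members$father), is.na(members$mother))
  if (any(one_par))
    stop("members with exactly one parent recorded: ",
         paste(members$id[one_par], collapse = ", "))
  nf <- !is.na(members$father)
  bad_f <- nf & !(members$father %in% members$id)
  bad_m <- nf & !(members$mother %in% members$id)
  if (any(bad_f | bad_m))
    stop("unknown parent id(s) ",
         paste(unique(c(members$father[bad_f], members$mother[bad_m])),
               collapse = ", "),
         " referenced by member(s): ",
         paste(members$id[bad_f | bad_m], collapse = ", "))
  sex_of <- setNames(members$sex, members$id)
  if (any(nf & sex_of[members$father] != "male"))
    stop("father with non-male sex")
  if (any(nf & sex_of[members$mother] != "female"))
    stop("mother with non-female sex")
  members$generation <- infer_generations(members)  # errors on cycles
  rownames(members) <- NULL
  structure(members, family_id = family_id,
            class = c("pedigree", "data.frame"))
}

# Longest-path generation index; detects cyclic parentage.
infer_generations <- function(members) {
  n <- nrow(members)
  gen <- rep(NA_integer_, n)
  names(gen) <- members$id
  idx <- setNames(seq_len(n), members$id)
  state <- integer(n)  # 0 unvisited, 1 in progress, 2 done
  visit <- function(i) {
    if (state[i] == 1L) stop("cyclic parentage involving member ", members$id[i])
    if (state[i] == 2L) return(gen[i])
    state[i] <<- 1L
    g <- if (is.na(members$father[i])) 1L
    else 1L + max(visit(idx[[members$father[i]]]),
                  visit(idx[[members$mother[i]]]))
    state[i] <<- 2L
    gen[i] <<- g
    g
  }
  for (i in seq_len(n)) visit(i)
  unname(gen)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree '%s': %d members, %d generations, %d affected\n",
              family_id(x), nrow(x), max(x$generation),
              sum(x$affected == "affected")))
  NextMethod()
}

#' @rdname pedigree
#' @param ped a pedigree.
#' @export
family_id <- function(ped) attr(ped, "family_id")

#' @rdname pedigree
#' @export
founders <- function(ped) ped$id[is.na(ped$father)]

#' Detect marriage/inbreeding loops
#'
#' A pedigree is loop-free when the bipartite graph linking individuals to
#' the nuclear families they belong to (as parent or child) is a forest.
#' Exact peeling here supports only loop-free pedigrees.
#'
#' @param ped a pedigree.
#' @return `TRUE` if the pedigree contains a loop.
#' @export
has_loops <- function(ped) {
  nf <- ped[!is.na(ped$father), , drop = FALSE]
  if (!nrow(nf)) return(FALSE)
  fam_key <- paste0("fam:", nf$father, "\r", nf$mother)
  fams <- unique(fam_key)
  par_of <- strsplit(sub("^fam:", "", fams), "\r")
  edges <- unique(rbind(
    cbind(nf$id, fam_key),                               # child -- family
    cbind(vapply(par_of, `[`, "", 1L), fams),            # father -- family
    cbind(vapply(par_of, `[`, "", 2L), fams)))           # mother -- family
  nodes <- unique(c(edges[, 1L], edges[, 2L]))
  parent <- seq_along(nodes)                             # union-find
  root <- function(a) {
    i <- match(a, nodes)
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (k in seq_len(nrow(edges))) {
    ra <- root(edges[k, 1L]); rb <- root(edges[k, 2L])
    if (ra == rb) return(TRUE)
    parent[ra] <- rb
  }
  FALSE
}

# PED IO ----------------------------------------------------------------------

#' Read / write 6-column PED pedigree files
#'
#' Standard pre-makeped PED: family, individual, father, mother, sex
#' (1 = male, 2 = female), phenotype (1 = unaffected, 2 = affected,
#' 0 = unknown). `0` in a parent column means "no parent recorded".
#' Generations are inferred from parentage.
#'
#' @param path file path.
#' @return `read_pedigree`: a [pedigree()]; `write_pedigree`: `path`,
#'   invisibly.
#' @export
read_pedigree <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty PED file: ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(toks) < 6L)
  if (length(bad))
    stop("malformed PED line(s) ", paste(bad, collapse = ", "),
         " in ", path, " (need 6 whitespace-delimited fields)")
  m <- do.call(rbind, lapply(toks, `[`, 1:6))
  sex_code <- m[, 5L]
  phe_code <- m[, 6L]
  badsex <- which(!sex_code %in% c("1", "2"))
  if (length(badsex))
    stop("invalid sex code on PED line(s) ", paste(badsex, collapse = ", "))
  badphe <- which(!phe_code %in% c("0", "1", "2"))
  if (length(badphe))
    stop("invalid phenotype code on PED line(s) ", paste(badphe, collapse = ", "))
  members <- data.frame(
    id = m[, 2L],
    father = ifelse(m[, 3L] == "0", NA_character_, m[, 3L]),
    mother = ifelse(m[, 4L] == "0", NA_character_, m[, 4L]),
    sex = c("1" = "male", "2" = "female")[sex_code],
    affected = c("0" = "unknown", "1" = "unaffected", "2" = "affected")[phe_code],
    stringsAsFactors = FALSE
  )
  ped <- pedigree(members, family_id = m[1L, 1L])
  ps_info("read %d pedigree members from %s", nrow(ped), path)
  ped
}

#' @rdname read_pedigree
#' @param ped a pedigree.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(
    fam = family_id(ped),
    id = ped$id,
    father = ifelse(is.na(ped$father), "0", ped$father),
    mother = ifelse(is.na(ped$mother), "0", ped$mother),
    sex = ifelse(ped$sex == "male", 1L, 2L),
    phe = c(affected = 2L, unaffected = 1L, unknown = 0L)[ped$affected]
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Analysis groups -------------------------------------------------------------

#' Partition pedigree members into analysis groups
#'
#' Builds the member groupings used throughout the pipeline: the affected
#' (case) set, the healthy comparator set used for case-control variant
#' extraction, the full healthy set used for mutation-density denominators,
#' and the set of unaffected members exempt from co-segregation constraints.
#' Under the default `"exclude_g3"` policy, unaffected members of generation
#' `exempt_generation` and beyond are exempt: pre-symptomatic youngsters in
#' the youngest generation may silently carry a risk allele, so their
#' genotypes neither support nor veto a candidate variant. Members of unknown
#' affection status are excluded from every group.
#'
#' @param ped a [pedigree()].
#' @param policy `"exclude_g3"` (default) or `"none"` (no exemptions).
#' @param exempt_generation first generation treated as exempt when
#'   unaffected (default 3).
#' @return object of class `"analysis_groups"`: list with character-vector
#'   elements `affected_ids`, `healthy_comparator_ids`, `healthy_all_ids`,
#'   `exempt_ids`, plus `n_d` and `n_h` group sizes.
#' @export
make_groups <- function(ped, policy = c("exclude_g3", "none"),
                        exempt_generation = 3L) {
  policy <- match.arg(policy)
  affected <- ped$id[ped$affected == "affected"]
  if (!length(affected)) stop("no affected members: cannot form a case group")
  healthy <- ped$id[ped$affected == "unaffected"]
  if (!length(healthy)) stop("no unaffected members: cannot form a control group")
  exempt <- if (policy == "exclude_g3")
    ped$id[ped$affected == "unaffected" & ped$generation >= exempt_generation]
  else character()
  grp <- structure(list(
    affected_ids = affected,
    healthy_comparator_ids = setdiff(healthy, exempt),
    healthy_all_ids = healthy,
    exempt_ids = exempt,
    n_d = length(affected),
    n_h = length(healthy)
  ), class = "analysis_groups")
  grp
}

#' @export
print.analysis_groups <- function(x, ...) {
  cat(sprintf(paste0("Analysis groups: %d affected, %d healthy",
                     " (%d comparators, %d exempt)\n"),
              x$n_d, x$n_h, length(x$healthy_comparator_ids),
              length(x$exempt_ids)))
  invisible(x)
}
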