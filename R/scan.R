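#' Define a target/background species partition
#'
#' The scan compares a polyphyletic target group A (e.g. the vocal learners)
#' against a background group B (every remaining species), optionally setting
#' some taxa aside entirely (e.g. an outgroup excluded from both sets).
#'
#' @param group_a character vector of target taxon labels (non-empty).
#' @param group_b character vector of background taxon labels (non-empty).
#' @param excluded character vector of taxa ignored by the scan.
#' @return an object of class `species_partition`.
#' @export
species_partition <- function(group_a, group_b, excluded = character(0)) {
  group_a <- unique(as.character(group_a))
  group_b <- unique(as.character(group_b))
  excluded <- unique(as.character(excluded))
  if (!length(group_a) || !length(group_b))
    stop("both species groups must be non-empty")
  if (length(intersect(group_a, group_b)) ||
      length(intersect(group_a, excluded)) ||
      length(intersect(group_b, excluded)))
    stop("group_a, group_b and excluded must be pairwise disjoint")
  structure(list(group_a = group_a, group_b = group_b, excluded = excluded),
            class = "species_partition")
}

#' Build a partition from an alignment: chosen targets vs all the rest
#'
#' @param aln a `multiple_alignment` (or character vector of species ids).
#' @param group_a target taxa.
#' @param excluded taxa to ignore.
#' @return a `species_partition` whose background is every other species.
#' @export
partition_from_alignment <- function(aln, group_a, excluded = character(0)) {
  sp <- if (inherits(aln, "multiple_alignment")) alignment_species(aln) else aln
  species_partition(group_a, setdiff(sp, c(group_a, excluded)), excluded)
}

#' @export
print.species_partition <- function(x, ...) {
  cat(sprintf("species_partition: %d target, %d background, %d excluded\n",
              length(x$group_a), length(x$group_b), length(x$excluded)))
  invisible(x)
}

#' Per-site state profiles of the two groups
#'
#' Returns the distinct states observed in group A and group B at one site,
#' at the requested level. For `level = "codon"` the site index addresses
#' codons (1-based) and states are nucleotide triplets. The gap `-` is a
#' state; the ambiguity sentinels (`X` for amino acids, `N` in nucleotides or
#' codons) make the site unscannable because a hidden state could break
#' mutual exclusivity.
#'
#' @param aln a `multiple_alignment`.
#' @param part a `species_partition`; every group member must be a row of
#'   `aln`.
#' @param site 1-based site (codon for `level = "codon"`) index.
#' @param level `"amino_acid"`, `"codon"`, or `"nucleotide"`; defaults to the
#'   alignment's own level.
#' @return a list of class `site_profile_pair` with elements `set_a`,
#'   `set_b`, `level`, `site`, `scannable`.
#' @export
site_profiles <- function(aln, part, site, level = NULL) {
  states <- site_states(aln, site, level %||% alignment_level(aln))
  profile_pair(states, part, level %||% alignment_level(aln), site)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# named per-species state vector at one site of the requested level
site_states <- function(aln, site, level) {
  stopifnot(inherits(aln, "multiple_alignment"))
  if (level %in% c("codon", "nucleotide") &&
      alignment_level(aln) != "nucleotide")
    stop("codon/nucleotide profiles need a nucleotide-level alignment")
  if (level == "amino_acid" && alignment_level(aln) != "amino_acid")
    stop("amino-acid profiles need an amino-acid-level alignment")
  if (level == "codon") {
    if (ncol(aln) %% 3L != 0L) stop("alignment length not divisible by 3")
    n <- ncol(aln) %/% 3L
    if (site < 1L || site > n) stop("codon site out of range")
    j <- 3L * site - 2L
    stats::setNames(paste0(aln[, j], aln[, j + 1L], aln[, j + 2L]),
                    rownames(aln))
  } else {
    if (site < 1L || site > ncol(aln)) stop("site out of range")
    stats::setNames(aln[, site], rownames(aln))
  }
}

profile_pair <- function(states, part, level, site) {
  stopifnot(inherits(part, "species_partition"))
  miss <- setdiff(c(part$group_a, part$group_b), names(states))
  if (length(miss))
    stop("group member(s) absent from alignment: ", paste(miss, collapse = ", "))
  a <- states[part$group_a]
  b <- states[part$group_b]
  amb <- if (level == "amino_acid") function(s) grepl("X", s, fixed = TRUE)
         else function(s) grepl("N", s, fixed = TRUE)
  structure(list(set_a = sort(unique(unname(a))),
                 set_b = sort(unique(unname(b))),
                 level = level, site = site,
                 scannable = !any(amb(a)) && !any(amb(b))),
            class = "site_profile_pair")
}

#' @export
print.site_profile_pair <- function(x, ...) {
  cat(sprintf("site %d [%s]: A={%s} B={%s}%s\n", x$site, x$level,
              paste(x$set_a, collapse = ","), paste(x$set_b, collapse = ","),
              if (x$scannable) "" else " (unscannable)"))
  invisible(x)
}

#' Classify a mutually exclusive site into Types 1-4
#'
#' A site is mutually exclusive when the two groups share no state. Type 1:
#' one state per group (identical substitution on both sides); Type 2: one
#' state in group A, several in group B; Type 3: several in A, one in B;
#' Type 4: several in both. Non-exclusive sites return `NA`.
#'
#' @param profile a `site_profile_pair` from a scannable site.
#' @return integer 1-4, or `NA_integer_` if the sets overlap.
#' @export
classify_site_type <- function(profile) {
  stopifnot(inherits(profile, "site_profile_pair"))
  a <- profile$set_a; b <- profile$set_b
  if (!length(a) || !length(b)) stop("empty state set in profile")
  if (length(intersect(a, b))) return(NA_integer_)
  if (length(a) == 1L) { if (length(b) == 1L) 1L else 2L }
  else { if (length(b) == 1L) 3L else 4L }
}

#' Convergent or divergent label of a variant type
#'
#' Types 1 and 2 (a single, identical state across the target group) are
#' convergent; Types 3 and 4 (different states within the target group) are
#' divergent.
#'
#' @param variant_type integer vector with values in 1-4.
#' @return character vector, `"convergent"` or `"divergent"`.
#' @export
label_con_div <- function(variant_type) {
  if (any(!variant_type %in% 1:4)) stop("variant type must be 1, 2, 3 or 4")
  ifelse(variant_type <= 2L, "convergent", "divergent")
}

#' Synonymy of a codon-level mutually exclusive site
#'
#' Nonsynonymous iff the translated amino-acid profiles are themselves
#' mutually exclusive (disjoint); synonymous otherwise (including the case of
#' the same residue on both sides).
#'
#' @param codon_profile a codon-level `site_profile_pair` whose state sets
#'   are disjoint and contain no ambiguous codon.
#' @return `"synonymous"` or `"nonsynonymous"`.
#' @export
classify_synonymy <- function(codon_profile) {
  stopifnot(inherits(codon_profile, "site_profile_pair"),
            codon_profile$level == "codon")
  aa_a <- translate_codons(codon_profile$set_a)
  aa_b <- translate_codons(codon_profile$set_b)
  if (any(c(aa_a, aa_b) == "X"))
    stop("untranslatable (ambiguous or partially gapped) codon in profile")
  if (length(intersect(aa_a, aa_b))) "synonymous" else "nonsynonymous"
}

#' Nucleotide source of a codon-level mutually exclusive site
#'
#' For each codon position 1-3, the per-position state profile of the two
#' groups is tested for mutual exclusivity. If at least one position is
#' itself mutually exclusive the codon variant is the product of single
#' nucleotide variants (SNV): `"ConSNV"` when group A has exactly one state
#' at the first such position, `"DivSNV"` otherwise. If no single position is
#' exclusive the codon-level exclusivity arises from complex nonexclusive
#' nucleotide variants (`"CNENV"`).
#'
#' @param codon_profile a codon-level `site_profile_pair` with disjoint sets.
#' @return `"ConSNV"`, `"DivSNV"`, or `"CNENV"`.
#' @export
trace_nucleotide_source <- function(codon_profile) {
  stopifnot(inherits(codon_profile, "site_profile_pair"),
            codon_profile$level == "codon")
  for (p in 1:3) {
    a_p <- unique(substr(codon_profile$set_a, p, p))
    b_p <- unique(substr(codon_profile$set_b, p, p))
    if (!length(intersect(a_p, b_p)))
      return(if (length(a_p) == 1L) "ConSNV" else "DivSNV")
  }
  "CNENV"
}

#' Scan an alignment for mutually exclusive variants
#'
#' Walks every site of the alignment at the requested level, computes the
#' group state profiles, and records each scannable, mutually exclusive site
#' as a variant with its Type (1-4) and convergent/divergent label. To focus
#' on point mutations, maximal runs of at least `run_length` adjacent variant
#' sites (adjacency measured in the level's own coordinates) are removed from
#' the variant list and tallied as continuous (putatively structural)
#' variants. At the codon level each retained variant also carries its
#' synonymy and nucleotide-source classification.
#'
#' @param aln a `multiple_alignment` (nucleotide level for `"codon"` or
#'   `"nucleotide"` scans, amino-acid level for `"amino_acid"`).
#' @param part a `species_partition`.
#' @param level scan level; defaults to the alignment's level (a nucleotide
#'   alignment defaults to a codon scan).
#' @param run_length minimum run of adjacent variant sites treated as a
#'   continuous variant and filtered (default 2).
#' @param gene_id optional gene label carried into the report.
#' @return an object of class `scan_report`: list with `variants` (data
#'   frame: gene, site, level, type, con_div, profile_a, profile_b, synonymy,
#'   nt_source, path_class), `counts`, `n_sites`, `n_scanned`,
#'   `n_unscannable`, `n_continuous`.
#' @export
scan_alignment <- function(aln, part, level = NULL, run_length = 2L,
                           gene_id = NA_character_) {
  stopifnot(inherits(aln, "multiple_alignment"))
  if (is.null(level))
    level <- if (alignment_level(aln) == "nucleotide") "codon" else "amino_acid"
  level <- match.arg(level, c("amino_acid", "codon", "nucleotide"))
  n_sites <- switch(level,
                    amino_acid = ncol(aln),
                    nucleotide = ncol(aln),
                    codon = {
                      if (ncol(aln) %% 3L != 0L)
                        stop("alignment length not divisible by 3")
                      ncol(aln) %/% 3L
                    })
  if (n_sites == 0L) stop("empty alignment")

  profs <- vector("list", n_sites)
  type <- rep(NA_integer_, n_sites)
  scannable <- logical(n_sites)
  for (s in seq_len(n_sites)) {
    pr <- site_profiles(aln, part, s, level)
    profs[[s]] <- pr
    scannable[s] <- pr$scannable
    if (pr$scannable) type[s] <- classify_site_type(pr)
  }

  is_var <- !is.na(type)
  continuous <- continuous_run_mask(is_var, run_length)
  keep <- which(is_var & !continuous)

  variants <- data.frame(
    gene = rep(gene_id, length(keep)), site = keep,
    level = rep(level, length(keep)),
    type = type[keep], con_div = if (length(keep))
      label_con_div(type[keep]) else character(0),
    profile_a = vapply(profs[keep], function(p)
      paste(p$set_a, collapse = ","), character(1)),
    profile_b = vapply(profs[keep], function(p)
      paste(p$set_b, collapse = ","), character(1)),
    synonymy = rep(NA_character_, length(keep)),
    nt_source = rep(NA_character_, length(keep)),
    path_class = rep(NA_character_, length(keep)),
    stringsAsFactors = FALSE)
  if (level == "codon" && nrow(variants)) {
    variants$synonymy <- vapply(profs[keep], function(p)
      tryCatch(classify_synonymy(p), error = function(e) NA_character_),
      character(1))
    variants$nt_source <- vapply(profs[keep], trace_nucleotide_source,
                                 character(1))
  }

  counts <- if (nrow(variants))
    as.data.frame(table(type = variants$type, con_div = variants$con_div),
                  stringsAsFactors = FALSE)
  else data.frame(type = integer(0), con_div = character(0), Freq = integer(0))
  counts <- counts[counts$Freq > 0L, , drop = FALSE]

  structure(list(variants = variants, counts = counts, level = level,
                 n_sites = n_sites, n_scanned = sum(scannable),
                 n_unscannable = sum(!scannable),
                 n_continuous = sum(continuous)),
            class = "scan_report")
}

# TRUE for sites inside maximal runs of >= run_length adjacent variant sites
continuous_run_mask <- function(is_var, run_length) {
  out <- logical(length(is_var))
  r <- rle(is_var)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long <- which(r$values & r$lengths >= run_length)
  for (i in long) out[starts[i]:ends[i]] <- TRUE
  out
}

#' @export
print.scan_report <- function(x, ...) {
  cat(sprintf("scan_report [%s]: %d sites (%d scannable, %d ambiguous, %d continuous)\n",
              x$level, x$n_sites, x$n_scanned, x$n_unscannable, x$n_continuous))
  cat(sprintf("  %d mutually exclusive variant site(s)\n", nrow(x$variants)))
  if (nrow(x$counts)) {
    for (i in seq_len(nrow(x$counts)))
      cat(sprintf("  Type %s (%s): %d\n", x$counts$type[i],
                  x$counts$con_div[i], x$counts$Freq[i]))
  }
  invisible(x)
}

#' Per-group state count matrices for logo rendering
#'
#' Tallies, at each requested site, how many species of each group carry each
#' state — the count matrix a sequence-logo renderer consumes.
#'
#' @param aln a `multiple_alignment`.
#' @param part a `species_partition`.
#' @param sites 1-based site indices (level coordinates).
#' @param level scan level (see [scan_alignment()]).
#' @return data frame with columns `site`, `group`, `state`, `count`.
#' @export
logo_counts <- function(aln, part, sites, level = NULL) {
  if (is.null(level))
    level <- if (alignment_level(aln) == "nucleotide") "codon" else "amino_acid"
  out <- list()
  for (s in sites) {
    st <- site_states(aln, s, level)
    for (g in c("a", "b")) {
      grp <- if (g == "a") part$group_a else part$group_b
      tab <- table(st[grp])
      out[[length(out) + 1L]] <- data.frame(
        site = s, group = toupper(g), state = names(tab),
        count = as.integer(tab), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
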