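#' Multiple sequence alignment container
#'
#' A `multiple_alignment` is a species-by-site character matrix with a fixed,
#' stable species order and 1-based site addressing. Two levels exist:
#' `"amino_acid"` (one column per residue) and `"nucleotide"` (one column per
#' base; treated as in-frame codons by downstream codon-level operations, in
#' which case the number of columns must be divisible by 3).
#'
#' Residues are stored uppercase. Ambiguity codes are normalised to a single
#' sentinel per level: amino-acid `B`, `Z`, `J`, `U`, `O` become `X`;
#' nucleotide IUPAC codes other than `A`, `C`, `G`, `T` become `N`. The gap
#' character `-` is retained as a first-class state.
#'
#' @param mat character matrix, one row per species (rownames = species ids),
#'   one column per site.
#' @param level `"amino_acid"` or `"nucleotide"`.
#' @return An object of class `multiple_alignment`: the character matrix with
#'   attributes `level`.
#' @export
multiple_alignment <- function(mat, level = c("amino_acid", "nucleotide")) {
  level <- match.arg(level)
  if (!is.matrix(mat) || !is.character(mat))
    stop("'mat' must be a character matrix")
  if (is.null(rownames(mat)) || anyNA(rownames(mat)))
    stop("alignment rows must be named with species ids")
  if (anyDuplicated(rownames(mat)))
    stop("duplicate species ids in alignment")
  if (ncol(mat) == 0L || nrow(mat) == 0L)
    stop("empty alignment")
  mat[] <- toupper(mat)
  mat[] <- normalize_residues(mat, level)
  structure(mat, level = level, class = c("multiple_alignment", "matrix"))
}

# Collapse ambiguity codes onto one sentinel per level ('X' for amino acids,
# 'N' for nucleotides); unknown characters are an error.
normalize_residues <- function(x, level) {
  if (level == "amino_acid") {
    allowed <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-", "X", "*")
    ambig <- c("B", "Z", "J", "U", "O", "?", ".")
  } else {
    allowed <- c("A", "C", "G", "T", "-", "N")
    ambig <- c("U", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "?", ".")
  }
  x[x %in% ambig] <- if (level == "amino_acid") "X" else "N"
  bad <- setdiff(unique(as.vector(x)), allowed)
  if (length(bad))
    stop("invalid ", sub("_", " ", level), " characters: ",
         paste(bad, collapse = ", "))
  x
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("multiple_alignment [%s]: %d species x %d sites\n",
              alignment_level(x), nrow(x), ncol(x)))
  show <- utils::head(rownames(x), 6L)
  w <- min(ncol(x), 60L)
  for (sp in show)
    cat(sprintf("  %-12s %s%s\n", sp, paste(x[sp, seq_len(w)], collapse = ""),
                if (ncol(x) > w) "..." else ""))
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' Alignment level accessor
#' @param aln a `multiple_alignment`.
#' @return `"amino_acid"` or `"nucleotide"`.
#' @export
alignment_level <- function(aln) attr(aln, "level")

#' Species ids of an alignment
#' @param aln a `multiple_alignment`.
#' @return character vector of taxon labels in stored order.
#' @export
alignment_species <- function(aln) rownames(aln)

#' Read a FASTA alignment
#'
#' Parses an aligned (equal-length, gapped) FASTA file into a
#' [multiple_alignment()]. Record order is preserved; residues are
#' uppercased and ambiguity-normalised.
#'
#' @param path path to a FASTA file.
#' @param level `"amino_acid"` or `"nucleotide"`.
#' @return a `multiple_alignment`.
#' @export
read_fasta_alignment <- function(path, level = c("amino_acid", "nucleotide")) {
  level <- match.arg(level)
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(ids)) stop("duplicate sequence ids in ", path)
  lens <- Biostrings::width(recs)
  if (length(unique(lens)) != 1L)
    stop("records are not aligned (unequal lengths) in ", path)
  mat <- do.call(rbind, strsplit(as.character(recs), ""))
  rownames(mat) <- ids
  multiple_alignment(mat, level)
}

#' Write a FASTA alignment
#'
#' @param aln a `multiple_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  seqs <- Biostrings::BStringSet(apply(aln, 1L, paste, collapse = ""))
  names(seqs) <- rownames(aln)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Translate an in-frame codon alignment to amino acids
#'
#' Codon `i` (nucleotide columns `3i-2 .. 3i`) maps to amino-acid column `i`
#' under the standard genetic code. A fully gapped codon (`---`) translates to
#' the gap state `-`; a codon containing `N` or a partial gap translates to
#' the ambiguity sentinel `X`.
#'
#' @param aln a nucleotide-level `multiple_alignment` whose length is
#'   divisible by 3.
#' @return an amino-acid-level `multiple_alignment` with one third the sites.
#' @export
translate_codon_alignment <- function(aln) {
  stopifnot(inherits(aln, "multiple_alignment"))
  if (alignment_level(aln) != "nucleotide")
    stop("alignment is not at the nucleotide level; cannot translate")
  if (ncol(aln) %% 3L != 0L)
    stop("alignment length ", ncol(aln), " is not divisible by 3 (frame error)")
  codons <- codon_view(aln)
  aa <- matrix(translate_codons(codons), nrow = nrow(codons),
               dimnames = dimnames(codons))
  multiple_alignment(aa, "amino_acid")
}

# species x codon matrix of 3-mers from a nucleotide alignment
codon_view <- function(aln) {
  n_codon <- ncol(aln) %/% 3L
  idx1 <- 3L * seq_len(n_codon) - 2L
  out <- matrix("", nrow = nrow(aln), ncol = n_codon,
                dimnames = list(rownames(aln), NULL))
  for (j in seq_len(n_codon))
    out[, j] <- paste0(aln[, idx1[j]], aln[, idx1[j] + 1L], aln[, idx1[j] + 2L])
  out
}

# vectorised codon -> single amino acid letter, standard code only
translate_codons <- function(codons) {
  out <- unname(Biostrings::GENETIC_CODE[codons])
  out[codons == "---"] <- "-"
  out[is.na(out)] <- "X"   # codons containing N or a partial gap
  out
}

#' Reverse complement of a gapped nucleotide string
#'
#' Gaps are preserved; `N` maps to `N`.
#'
#' @param x character vector of (possibly gapped) nucleotide strings.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-",
            a = "t", c = "g", g = "c", t = "a", n = "n")
  vapply(strsplit(x, ""), function(ch) {
    out <- comp[ch]
    if (anyNA(out)) stop("non-nucleotide character in sequence")
    paste(rev(unname(out)), collapse = "")
  }, character(1))
}
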