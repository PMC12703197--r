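#' Read MAF (multiple alignment format) blocks
#'
#' Parses the `a`/`s` lines of a MAF file into a `maf_block_set`: an ordered
#' list of blocks, each a data frame with one row per species row of the
#' block. Row coordinates follow the MAF standard: `start` is 0-based on the
#' strand given by `strand`, `size` is the ungapped length, `src_size` the
#' full source-sequence length, and `text` the gapped alignment row as
#' printed (all rows of a block align column by column). `i`, `e`, and `q`
#' lines are ignored.
#'
#' @param path path to an uncompressed MAF file.
#' @return a `maf_block_set` (list of data frames with columns `src`,
#'   `species`, `start`, `size`, `strand`, `src_size`, `text`).
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush <- function(cur, blocks) {
    if (!is.null(cur) && length(cur)) {
      df <- do.call(rbind, cur)
      widths <- nchar(df$text)
      if (length(unique(widths)) != 1L)
        stop("MAF block rows have unequal gapped lengths")
      blocks[[length(blocks) + 1L]] <- df
    }
    blocks
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      blocks <- flush(cur, blocks)
      cur <- list()
    } else if (startsWith(ln, "s ")) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) < 7L) stop("malformed MAF 's' line: ", ln)
      text <- toupper(f[7L])
      size <- as.integer(f[4L])
      if (nchar(gsub("-", "", text)) != size)
        stop("MAF row size inconsistent with ungapped text: ", f[2L])
      cur[[length(cur) + 1L]] <- data.frame(
        src = f[2L], species = sub("\\..*$", "", f[2L]),
        start = as.integer(f[3L]), size = size, strand = f[5L],
        src_size = as.integer(f[6L]), text = text,
        stringsAsFactors = FALSE)
    }
  }
  blocks <- flush(cur, blocks)
  if (!length(blocks)) stop("no alignment blocks in ", path)
  structure(blocks, class = "maf_block_set")
}

#' @export
print.maf_block_set <- function(x, ...) {
  cat(sprintf("maf_block_set: %d blocks\n", length(x)))
  invisible(x)
}

#' Extract aligned columns over a reference interval from MAF blocks
#'
#' Selects the alignment columns whose reference (ungapped) positions fall in
#' the 0-based, half-open interval `[ref_start, ref_start + length)` and
#' returns, for every species present in the covering blocks, the aligned
#' text over those columns. Columns belonging to blocks in which a species
#' has no row are reported with the sentinel `.` (absent), which is distinct
#' from the gap character `-` (aligned deletion). With `ref_strand = "-"` the
#' returned texts are reverse-complemented so the reference reads in minus
#' orientation.
#'
#' Block texts already align column-wise as printed (the MAF convention), so
#' minus-strand query rows need no re-orientation; their `strand` flag only
#' affects source-coordinate bookkeeping.
#'
#' @param maf a `maf_block_set` from [read_maf()].
#' @param ref_species species name of the reference rows (the part of `src`
#'   before the first dot).
#' @param ref_start 0-based start on the reference source sequence.
#' @param length number of reference positions to extract (> 0).
#' @param ref_strand `"+"` or `"-"` orientation of the returned texts.
#' @return data frame with columns `species`, `text` (over the selected
#'   columns, in reference-position order), and `missing` (`TRUE` if the
#'   species was absent from at least one covering block).
#' @export
extract_maf_codon <- function(maf, ref_species, ref_start, length,
                              ref_strand = c("+", "-")) {
  ref_strand <- match.arg(ref_strand)
  stopifnot(inherits(maf, "maf_block_set"), length > 0)
  want <- seq.int(ref_start, ref_start + length - 1L)
  has_ref <- vapply(maf, function(b) ref_species %in% b$species, logical(1))
  if (!any(has_ref)) stop("unknown reference species: ", ref_species)

  pieces <- list()   # per covering block: matrix of per-species texts
  covered <- integer(0)
  for (b in maf[has_ref]) {
    r <- which(b$species == ref_species)[1L]
    if (b$strand[r] != "+")
      stop("reference row must be on the + strand")
    chars <- strsplit(b$text[r], "")[[1]]
    refpos <- rep(NA_integer_, length(chars))
    refpos[chars != "-"] <- seq.int(b$start[r], length.out = b$size[r])
    sel <- which(refpos %in% want)
    if (!length(sel)) next
    covered <- c(covered, refpos[sel])
    sub <- vapply(strsplit(b$text, ""),
                  function(ch) paste(ch[sel], collapse = ""), character(1))
    names(sub) <- b$species
    pieces[[length(pieces) + 1L]] <- list(first = min(refpos[sel]),
                                          ncol = length(sel), rows = sub)
  }
  if (!setequal(intersect(covered, want), want))
    stop("reference interval not fully covered by MAF blocks (coverage error)")

  pieces <- pieces[order(vapply(pieces, `[[`, numeric(1), "first"))]
  species <- unique(unlist(lapply(pieces, function(p) names(p$rows))))
  text <- vapply(species, function(sp) {
    paste(vapply(pieces, function(p) {
      if (sp %in% names(p$rows)) p$rows[[sp]] else strrep(".", p$ncol)
    }, character(1)), collapse = "")
  }, character(1))
  missing <- vapply(species, function(sp)
    !all(vapply(pieces, function(p) sp %in% names(p$rows), logical(1))),
    logical(1))
  if (ref_strand == "-") {
    text <- vapply(strsplit(text, ""), function(ch) {
      comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
                `-` = "-", `.` = ".")[ch]
      paste(rev(unname(comp)), collapse = "")
    }, character(1))
  }
  data.frame(species = species, text = unname(text),
             missing = unname(missing), stringsAsFactors = FALSE)
}
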