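#' Scan many genes across many species combinations
#'
#' For every combination, group A is the combination's species and group B is
#' every remaining non-excluded species of the tree (an explicit `group_b`
#' overrides). Each gene is scanned at the requested levels and the per-gene
#' variant tallies are aggregated into one row per combination:
#'
#' * `ConSAV` / `DivSAV` — convergent / divergent amino-acid variants
#'   (`SAV_total` is their sum);
#' * `ConSCV` / `DivSCV` — codon-level variants;
#' * `ConSNV` / `DivSNV` — nucleotide-level variants.
#'
#' Output rows follow the order of `combos` (deterministic). With
#' `checkpoint_dir` set, each combination's row is written to a TSV as soon
#' as it is computed and finished combinations are skipped on re-run, so an
#' interrupted scan resumes to an identical table.
#'
#' @param genes named list of genes; each element is a list with `aa` (an
#'   amino-acid `multiple_alignment`) and/or `codon` (a nucleotide
#'   `multiple_alignment` in frame). `aa` is derived by translation when
#'   only `codon` is given.
#' @param tree rooted `phylo` tree (leaf set must cover all alignments).
#' @param combos list of `species_combination` objects (or character
#'   vectors of species).
#' @param levels subset of `c("amino_acid", "codon", "nucleotide")`.
#' @param excluded taxa excluded from every background group.
#' @param run_length continuous-run filter threshold (see
#'   [scan_alignment()]).
#' @param checkpoint_dir optional directory for per-combination checkpoints.
#' @return data frame with one row per combination: `combo_id`, `species`,
#'   and the count columns above.
#' @export
run_combination_scan <- function(genes, tree,
                                 combos,
                                 levels = c("amino_acid", "codon",
                                            "nucleotide"),
                                 excluded = character(0),
                                 run_length = 2L,
                                 checkpoint_dir = NULL) {
  tree <- validate_tree(tree)
  levels <- match.arg(levels, several.ok = TRUE)
  if (is.null(names(genes)))
    names(genes) <- sprintf("gene%02d", seq_along(genes))
  genes <- lapply(genes, prepare_gene, levels = levels, tree = tree)
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE)

  cols <- c("ConSAV", "DivSAV", "SAV_total", "ConSCV", "DivSCV",
            "ConSNV", "DivSNV")
  rows <- vector("list", length(combos))
  for (i in seq_along(combos)) {
    cb <- combos[[i]]
    sp_a <- if (inherits(cb, "species_combination")) cb$species else sort(cb)
    ckpt <- if (!is.null(checkpoint_dir))
      file.path(checkpoint_dir, sprintf("combo_%05d.tsv", i))
    if (!is.null(ckpt) && file.exists(ckpt)) {
      rows[[i]] <- utils::read.table(ckpt, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE)
      next
    }
    part <- species_partition(sp_a,
                              setdiff(tree$tip.label, c(sp_a, excluded)),
                              excluded)
    counts <- stats::setNames(numeric(length(cols)), cols)
    for (g in genes) {
      if ("amino_acid" %in% levels) {
        rep_aa <- scan_alignment(g$aa, part, "amino_acid", run_length)
        counts["ConSAV"] <- counts["ConSAV"] +
          sum(rep_aa$variants$con_div == "convergent")
        counts["DivSAV"] <- counts["DivSAV"] +
          sum(rep_aa$variants$con_div == "divergent")
      }
      if ("codon" %in% levels && !is.null(g$codon)) {
        rep_c <- scan_alignment(g$codon, part, "codon", run_length)
        counts["ConSCV"] <- counts["ConSCV"] +
          sum(rep_c$variants$con_div == "convergent")
        counts["DivSCV"] <- counts["DivSCV"] +
          sum(rep_c$variants$con_div == "divergent")
      }
      if ("nucleotide" %in% levels && !is.null(g$codon)) {
        rep_n <- scan_alignment(g$codon, part, "nucleotide", run_length)
        counts["ConSNV"] <- counts["ConSNV"] +
          sum(rep_n$variants$con_div == "convergent")
        counts["DivSNV"] <- counts["DivSNV"] +
          sum(rep_n$variants$con_div == "divergent")
      }
    }
    counts["SAV_total"] <- counts["ConSAV"] + counts["DivSAV"]
    row <- cbind(data.frame(combo_id = i,
                            species = paste(sp_a, collapse = ","),
                            stringsAsFactors = FALSE),
                 as.data.frame(as.list(counts)))
    if (!is.null(ckpt))
      utils::write.table(row, ckpt, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

prepare_gene <- function(g, levels, tree) {
  if (is.null(g$aa) && is.null(g$codon))
    stop("each gene needs an 'aa' and/or 'codon' alignment")
  if (is.null(g$aa) && "amino_acid" %in% levels)
    g$aa <- translate_codon_alignment(g$codon)
  for (a in Filter(Negate(is.null), list(g$aa, g$codon)))
    if (!all(tree$tip.label %in% alignment_species(a)))
      stop("alignment is missing tree leaves: ",
           paste(setdiff(tree$tip.label, alignment_species(a)),
                 collapse = ", "))
  g
}

#' Correlate combination variant counts with phylogenetic features
#'
#' Joins a counts table (from [run_combination_scan()]) with a feature table
#' (from [phylo_features_table()]) on `combo_id` and, for each requested
#' (x, y) pair, reports the Spearman rank correlation, the least-squares
#' fit with adjusted R^2, and the Bonferroni outlier test (up to `n_max`
#' outliers). A designated focal combination (e.g. the trait-defined species
#' set) is annotated with whether it is among the outliers.
#'
#' @param counts data frame with `combo_id` and count columns.
#' @param features data frame with `combo_id` and feature columns.
#' @param pairs list of `c(x, y)` column-name pairs, x the predictor.
#' @param focal_id optional `combo_id` of the focal combination.
#' @param n_max,alpha outlier-test parameters (see
#'   [bonferroni_outlier_test()]).
#' @return list with `table` (one row per pair: x, y, n, rho, rho_p, slope,
#'   intercept, adjusted_r2, outliers (comma-joined combo_ids),
#'   focal_is_outlier) and `fits` (named list of `regression_fit`).
#' @export
correlate_features <- function(counts, features, pairs, focal_id = NULL,
                               n_max = 3L, alpha = 0.05) {
  if (!all(counts$combo_id %in% features$combo_id))
    stop("counts and features tables do not join on combo_id")
  merged <- merge(counts, features, by = "combo_id",
                  suffixes = c("", ".feat"))
  merged <- merged[order(merged$combo_id), , drop = FALSE]
  fits <- list()
  rows <- lapply(pairs, function(pr) {
    x_name <- pr[[1L]]; y_name <- pr[[2L]]
    if (!x_name %in% names(merged) || !y_name %in% names(merged))
      stop("unknown column in pair: ", x_name, " / ", y_name)
    x <- merged[[x_name]]; y <- merged[[y_name]]
    sp <- spearman_rho(x, y)
    fit <- fit_linear_regression(x, y)
    out <- bonferroni_outlier_test(fit, n_max = n_max, alpha = alpha)
    out_ids <- merged$combo_id[out$indices]
    fits[[paste(x_name, y_name, sep = "~")]] <<- fit
    data.frame(x = x_name, y = y_name, n = length(x), rho = sp$rho,
               rho_p = sp$p_value, slope = fit$slope,
               intercept = fit$intercept, adjusted_r2 = fit$adjusted_r2,
               outliers = paste(out_ids, collapse = ","),
               focal_is_outlier = if (is.null(focal_id)) NA
                                  else focal_id %in% out_ids,
               stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows), fits = fits)
}
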