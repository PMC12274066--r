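#' Remove insertion-heavy sequences from a gene alignment
#'
#' A column is insertion-derived for a focal sequence when the focal
#' sequence holds a residue there while the majority (> 50%) of the other
#' sequences are gapped: the residue exists only because this sequence
#' inserted it. Sequences whose insertion-derived columns exceed
#' `insertion_frac_max` of their residue count are dropped from the gene.
#'
#' @param alignment A `codon_alignment`.
#' @param cfg A [pipeline_config()] (uses `insertion_frac_max`; strictly
#'   "more than" is removed).
#' @return The alignment without the offending species.
#' @export
filter_insertion_heavy <- function(alignment, cfg = pipeline_config()) {
  seqs <- alignment$sequences
  if (length(seqs) < 2) return(alignment)
  chars <- do.call(rbind, strsplit(seqs, ""))
  is_gap <- chars == "-"
  n <- nrow(chars)
  gap_counts <- colSums(is_gap)
  frac <- vapply(seq_len(n), function(i) {
    res <- !is_gap[i, ]
    if (!any(res)) return(0)
    # majority of the OTHER sequences gapped at this column
    others_gapped <- gap_counts - is_gap[i, ]
    ins <- res & (others_gapped > (n - 1) / 2)
    sum(ins) / sum(res)
  }, numeric(1))
  keep <- frac <= cfg$insertion_frac_max
  if (all(keep)) return(alignment)
  codon_alignment(seqs[keep], gene = alignment$gene)
}

#' Flag genes with too-short terminal branches for a species
#'
#' Genes whose terminal branch for the focal species is shorter than
#' `gene_branch_min` carry too little signal and are excluded from that
#' species' aggregation (boundary kept).
#'
#' @param gene_branch_lengths Named numeric vector, per-gene terminal branch
#'   length for one species (substitutions/site).
#' @param cfg A [pipeline_config()].
#' @return Logical vector (`TRUE` = keep), named by gene.
#' @export
filter_short_branch_genes <- function(gene_branch_lengths,
                                      cfg = pipeline_config()) {
  keep <- gene_branch_lengths >= cfg$gene_branch_min
  names(keep) <- names(gene_branch_lengths)
  keep
}

#' Remove blacklisted genes before aggregation
#'
#' Consumes an externally produced list of deviant genes (e.g. topology
#' outliers) as (clade, gene) pairs.
#'
#' @param genes Character vector of gene ids in the dataset.
#' @param blacklist Data.frame with columns `clade` and `gene`, or a path to
#'   such a TSV; `NULL` means no blacklist.
#' @param clade Clade of the current gene set (matched against the
#'   blacklist; `NA` rows in the blacklist match every clade).
#' @return Character vector of retained gene ids, in input order.
#' @export
apply_gene_blacklist <- function(genes, blacklist = NULL, clade = NA) {
  if (is.null(blacklist)) return(genes)
  if (is.character(blacklist) && length(blacklist) == 1) {
    blacklist <- utils::read.delim(blacklist, sep = "\t",
                                   stringsAsFactors = FALSE)
  }
  stopifnot(all(c("clade", "gene") %in% names(blacklist)))
  rel <- blacklist[is.na(blacklist$clade) | is.na(clade) |
                     blacklist$clade == clade, , drop = FALSE]
  unknown <- setdiff(rel$gene, genes)
  if (length(unknown) > 0) {
    warning("blacklisted gene(s) not in dataset: ",
            paste(unknown, collapse = ", "))
  }
  setdiff(genes, rel$gene)
}

#' Aggregate per-gene substitution records into a species dN/dS
#'
#' Implements the per-species aggregation over the n genes retained for the
#' species: each rate is the summed mapped count divided by the summed
#' branch-length-normalized neutral count,
#' `dN = sum(K_N) / sum(O_N / l)` and `dS = sum(K_S) / sum(O_S / l)`,
#' with `dnds = dN/dS`. The alternative `counts_only` denominator
#' (`sum(O)` without the `1/l` normalization) is exposed for sensitivity
#' checks.
#'
#' @param records Data.frame of per-gene records for one species: columns
#'   `K_N`, `K_S`, `O_N`, `O_S`, `l` (see [map_gene_substitutions()]).
#' @param denominator `"as_printed"` (default) or `"counts_only"`.
#' @return List of class `species_dnds`: `dN`, `dS`, `dnds`, `n_genes`.
#' @export
aggregate_species_dnds <- function(records,
                                   denominator = c("as_printed",
                                                   "counts_only")) {
  denominator <- match.arg(denominator)
  stopifnot(all(c("K_N", "K_S", "O_N", "O_S", "l") %in% names(records)))
  if (nrow(records) < 1) stop("no records to aggregate")
  if (length(unique(records$species)) > 1) {
    stop("records span more than one species")
  }
  if (any(records$l <= 0)) stop("non-positive branch length in records")
  denomN <- if (denominator == "as_printed") {
    sum(records$O_N / records$l)
  } else sum(records$O_N)
  denomS <- if (denominator == "as_printed") {
    sum(records$O_S / records$l)
  } else sum(records$O_S)
  if (denomN <= 0 || denomS <= 0) stop("zero neutral denominator")
  dN <- sum(records$K_N) / denomN
  dS <- sum(records$K_S) / denomS
  if (dS <= 0) stop("dS is zero; dN/dS undefined")
  structure(list(dN = dN, dS = dS, dnds = dN / dS,
                 n_genes = nrow(records)),
            class = "species_dnds")
}

#' Aggregate a full record table into per-species dN/dS
#'
#' Applies the short-branch gene filter then [aggregate_species_dnds()]
#' per species. Species losing every gene are dropped with a warning.
#'
#' @param records Data.frame of [map_gene_substitutions()] rows for many
#'   genes/species.
#' @param cfg A [pipeline_config()].
#' @return Data.frame: `species`, `dN`, `dS`, `dnds`, `n_genes`.
#' @export
aggregate_all_species <- function(records, cfg = pipeline_config()) {
  keep <- records$l >= cfg$gene_branch_min
  records <- records[keep, , drop = FALSE]
  out <- lapply(split(records, records$species), function(d) {
    agg <- aggregate_species_dnds(d, denominator = cfg$denominator)
    data.frame(species = d$species[1], dN = agg$dN, dS = agg$dS,
               dnds = agg$dnds, n_genes = agg$n_genes)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Trim terminal branches outside the reliable length window
#'
#' Species whose terminal branch carries more than `terminal_branch_max` or
#' fewer than `terminal_branch_min` amino-acid substitutions per site are
#' removed (saturation and segregating polymorphism, respectively), and the
#' tree is pruned to the survivors.
#'
#' @param tree Rooted `phylo` over the dN/dS species.
#' @param dnds_table Data.frame with a `species` column (e.g. from
#'   [aggregate_all_species()]).
#' @param aa_lengths Named numeric vector of per-species terminal branch
#'   lengths in amino-acid substitutions per site.
#' @param cfg A [pipeline_config()].
#' @return List: `table` (reduced dN/dS table), `tree` (pruned),
#'   `removed` (character vector of species).
#' @export
trim_terminal_branches <- function(tree, dnds_table, aa_lengths,
                                   cfg = pipeline_config()) {
  sp <- dnds_table$species
  l <- aa_lengths[sp]
  if (any(is.na(l))) stop("missing amino-acid branch length for: ",
                          paste(sp[is.na(l)], collapse = ", "))
  keep <- l >= cfg$terminal_branch_min & l <= cfg$terminal_branch_max
  kept_sp <- sp[keep]
  pruned <- if (length(kept_sp) >= 2) ape::keep.tip(tree, kept_sp) else NULL
  list(table = dnds_table[keep, , drop = FALSE], tree = pruned,
       removed = sp[!keep])
}

#' GC content at third codon positions
#'
#' Per-species fraction of G/C among ungapped, unambiguous third positions,
#' averaged over species.
#'
#' @param alignment A `codon_alignment`.
#' @return Numeric scalar in `[0, 1]`.
#' @export
compute_gc3 <- function(alignment) {
  fracs <- vapply(alignment$sequences, function(s) {
    third <- substring(s, seq(3, nchar(s), by = 3), seq(3, nchar(s), by = 3))
    third <- third[third %in% .nucs]
    if (length(third) == 0) return(NA_real_)
    mean(third %in% c("G", "C"))
  }, numeric(1))
  if (all(is.na(fracs))) stop("no ungapped third positions in gene ",
                              alignment$gene)
  mean(fracs, na.rm = TRUE)
}

#' Select GC3-poor and GC3-rich gene sets
#'
#' Genes represented in at least `gc3_coverage_min` of the clade's species
#' are eligible; the `gc3_set_size` lowest- and highest-GC3 eligible genes
#' form the two sets. Ties are broken lexicographically by gene id so the
#' selection is order-independent.
#'
#' @param gc3 Named numeric vector of per-gene GC3 fractions.
#' @param species_coverage Named numeric vector, fraction of the clade's
#'   species represented in each gene, aligned with `gc3`.
#' @param cfg A [pipeline_config()].
#' @return List with character vectors `poor` and `rich`.
#' @export
select_gc3_genesets <- function(gc3, species_coverage,
                                cfg = pipeline_config()) {
  stopifnot(length(gc3) == length(species_coverage),
            !is.null(names(gc3)))
  eligible <- names(gc3)[species_coverage[names(gc3)] >= cfg$gc3_coverage_min]
  k <- cfg$gc3_set_size
  if (length(eligible) < 2 * k) {
    warning("only ", length(eligible),
            " eligible genes; returning all in both tails")
    k <- max(1, floor(length(eligible) / 2))
  }
  ord <- eligible[order(gc3[eligible], eligible)]
  list(poor = sort(utils::head(ord, k)), rich = sort(utils::tail(ord, k)))
}
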