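#' Pipeline configuration
#'
#' Collects every numeric cutoff the pipeline applies, with the defaults used
#' throughout the analysis: assemblies are kept when contig N50 >= 50 kb and
#' BUSCO completeness >= 70%; gene sequences with more than 10% insertion
#' occupancy are dropped; genes contribute to a species' dN/dS only when the
#' per-gene terminal branch length is >= 0.001 substitutions/site; terminal
#' branches outside [0.01, 1] amino-acid substitutions/site are trimmed in
#' the reduced analysis; "recent" TE copies are those below 5% divergence
#' from their family consensus; species above 30% BUSCO-duplicated are
#' screened out of the reduced comparative set; GC3 gene sets take the 50
#' poorest and 50 richest genes among those covering at least 95% of
#' species; C-values convert at 0.978e9 bp per pg.
#'
#' @param n50_min Minimum contig N50 (bp) to retain an assembly.
#' @param busco_complete_min Minimum complete-BUSCO percentage.
#' @param insertion_frac_max Maximum tolerated insertion fraction per
#'   sequence (strictly above is removed).
#' @param gene_branch_min Minimum per-gene terminal branch length
#'   (substitutions/site) for a gene to enter the aggregation.
#' @param terminal_branch_min,terminal_branch_max Bounds (amino-acid
#'   substitutions/site) outside which terminal branches are trimmed.
#' @param recent_divergence_max Divergence threshold (fraction) below which
#'   TE-annotated reads count as recent (strict `<`).
#' @param duplication_max BUSCO-duplicated percentage above which a species
#'   is excluded from the reduced comparative set (strict `>`).
#' @param gc3_coverage_min Minimum fraction of species a gene must cover to
#'   be eligible for the GC3 sets.
#' @param gc3_set_size Number of genes in each GC3 set.
#' @param pg_to_bp Base pairs per picogram of DNA.
#' @param denominator Either `"as_printed"` (default) or `"counts_only"`;
#'   see [aggregate_species_dnds()].
#' @param seed Integer seed recorded for pipeline runs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n50_min = 50000,
                            busco_complete_min = 70,
                            insertion_frac_max = 0.10,
                            gene_branch_min = 0.001,
                            terminal_branch_min = 0.01,
                            terminal_branch_max = 1.0,
                            recent_divergence_max = 0.05,
                            duplication_max = 30,
                            gc3_coverage_min = 0.95,
                            gc3_set_size = 50,
                            pg_to_bp = 0.978e9,
                            denominator = c("as_printed", "counts_only"),
                            seed = 1L) {
  denominator <- match.arg(denominator)
  cfg <- list(
    n50_min = n50_min, busco_complete_min = busco_complete_min,
    insertion_frac_max = insertion_frac_max,
    gene_branch_min = gene_branch_min,
    terminal_branch_min = terminal_branch_min,
    terminal_branch_max = terminal_branch_max,
    recent_divergence_max = recent_divergence_max,
    duplication_max = duplication_max,
    gc3_coverage_min = gc3_coverage_min, gc3_set_size = gc3_set_size,
    pg_to_bp = pg_to_bp, denominator = denominator, seed = as.integer(seed)
  )
  num <- vapply(cfg[setdiff(names(cfg), c("denominator", "seed"))],
                identity, numeric(1))
  if (any(num <= 0)) stop("all thresholds must be positive")
  if (cfg$terminal_branch_min >= cfg$terminal_branch_max) {
    stop("terminal_branch_min must be < terminal_branch_max")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

# Columns of a species trait table, with the mandatory ones flagged.
.trait_columns <- c(
  species = TRUE, assembly_size = TRUE, cvalue = FALSE, method = FALSE,
  date = FALSE, contig_N50 = FALSE, busco_complete = FALSE,
  busco_duplicated = FALSE, genome_size = FALSE, te_bp = FALSE,
  recent_te_bp = FALSE, dnds = FALSE
)

#' Read a per-species trait table from TSV
#'
#' Expected columns (header names): `species`, `assembly_size` (bp),
#' optionally `cvalue` (pg), `method` (FCM/FD/FIA), `date` (year),
#' `contig_N50` (bp), `busco_complete` (%), `busco_duplicated` (%),
#' `genome_size` (bp), `te_bp`, `recent_te_bp` (bp), `dnds`, plus any
#' further numeric life-history columns. Empty cells are missing values;
#' sentinel strings are not used.
#'
#' @param path TSV file with a header row, tab-separated, `.` decimal.
#' @return A `data.frame` of class `species_traits`.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("trait table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "",
                          check.names = FALSE)
  mandatory <- names(.trait_columns)[.trait_columns]
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0) {
    stop("mandatory column(s) missing: ", paste(missing_cols, collapse = ", "))
  }
  # known numeric columns must parse; unknown extra columns are taken as
  # numeric traits when they parse cleanly, else kept as metadata strings
  character_cols <- c("species", "method")
  known_numeric <- setdiff(names(.trait_columns), character_cols)
  for (col in setdiff(names(df), character_cols)) {
    if (is.character(df[[col]])) {
      bad <- which(!is.na(df[[col]]) &
                     is.na(suppressWarnings(as.numeric(df[[col]]))))
      if (length(bad) > 0) {
        if (col %in% known_numeric) {
          stop("non-numeric value '", df[[col]][bad[1]], "' in column '",
               col, "', row ", bad[1])
        }
        next
      }
    }
    df[[col]] <- as.numeric(df[[col]])
  }
  as_species_traits(df)
}

#' Coerce a data.frame to a validated species trait table
#'
#' @param df A data.frame with at least `species` and `assembly_size`.
#' @return The same data.frame with class `species_traits` prepended.
#' @export
as_species_traits <- function(df) {
  stopifnot(is.data.frame(df))
  if (anyDuplicated(df$species)) {
    stop("duplicate species ids: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  }
  for (col in intersect(c("assembly_size", "contig_N50", "genome_size",
                          "te_bp", "recent_te_bp"), names(df))) {
    if (any(!is.na(df[[col]]) & df[[col]] <= 0)) {
      stop("non-positive values in bp column '", col, "'")
    }
  }
  for (col in intersect(c("busco_complete", "busco_duplicated"), names(df))) {
    v <- df[[col]]
    if (any(!is.na(v) & (v < 0 | v > 100))) {
      stop("percentages out of [0,100] in '", col, "'")
    }
  }
  if (all(c("te_bp", "recent_te_bp") %in% names(df))) {
    both <- !is.na(df$te_bp) & !is.na(df$recent_te_bp)
    if (any(both & df$recent_te_bp > df$te_bp + 1e-9)) {
      stop("recent_te_bp exceeds te_bp for some species")
    }
  }
  if (!inherits(df, "species_traits")) class(df) <- c("species_traits", class(df))
  df
}

#' Write a trait table (or any stage output) to TSV
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Filter assemblies on contiguity and completeness
#'
#' Retains rows with `contig_N50 >= n50_min` and
#' `busco_complete >= busco_complete_min` (thresholds inclusive: exclusion is
#' phrased as "smaller than"). Counts removed per criterion are reported via
#' `message()`.
#'
#' @param table A `species_traits` table with `contig_N50` and
#'   `busco_complete` columns.
#' @param cfg A [pipeline_config()].
#' @return The filtered table, same class and column order.
#' @export
filter_assemblies <- function(table, cfg = pipeline_config()) {
  if (!all(c("contig_N50", "busco_complete") %in% names(table))) {
    stop("filter_assemblies needs contig_N50 and busco_complete columns")
  }
  fail_n50 <- is.na(table$contig_N50) | table$contig_N50 < cfg$n50_min
  fail_busco <- is.na(table$busco_complete) |
    table$busco_complete < cfg$busco_complete_min
  keep <- !fail_n50 & !fail_busco
  message(sprintf(
    "filter_assemblies: removed %d (N50 < %g), %d (BUSCO complete < %g%%); kept %d/%d",
    sum(fail_n50), cfg$n50_min, sum(fail_busco), cfg$busco_complete_min,
    sum(keep), nrow(table)))
  if (!any(keep)) warning("no assemblies pass the quality filters")
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
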