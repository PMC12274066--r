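.te_classes <- c("DNA", "RC", "LTR", "LINE", "SINE", "Other", "Unknown", "none")

#' Validate a TE read-annotation table
#'
#' @param annotations Data.frame with columns `read_id`, `annotated_bp`,
#'   `repeat_class`, `divergence`, `read_bp`.
#' @return The table, invisibly, after checks.
#' @export
validate_te_annotations <- function(annotations) {
  need <- c("read_id", "annotated_bp", "repeat_class", "divergence", "read_bp")
  missing_cols <- setdiff(need, names(annotations))
  if (length(missing_cols) > 0) {
    stop("TE annotation columns missing: ", paste(missing_cols, collapse = ", "))
  }
  with(annotations, {
    if (any(annotated_bp < 0 | annotated_bp > read_bp)) {
      stop("annotated_bp out of [0, read_bp]")
    }
    ann <- annotated_bp > 0
    if (any(!is.na(divergence[ann]) &
            (divergence[ann] < 0 | divergence[ann] > 1))) {
      stop("divergence out of [0, 1]")
    }
  })
  invisible(annotations)
}

#' Summarize overall TE content scaled to genome size
#'
#' The genomic TE fraction is estimated from the sampled reads as
#' `sum(annotated_bp) / sum(read_bp)` and scaled to the genome size
#' estimated by the C-value/WLS stage (not the assembly size). A per-class
#' breakdown is included; classes always sum to the total.
#'
#' @param annotations TE read-annotation table (see
#'   [validate_te_annotations()]).
#' @param genome_size Genome size in bp.
#' @param species Optional species id carried into the summary.
#' @return List of class `te_summary`: `species`, `te_fraction`, `te_bp`,
#'   `sampled_bp`, `by_class` (data.frame: class, bp, fraction).
#' @export
summarize_te_content <- function(annotations, genome_size, species = NA) {
  validate_te_annotations(annotations)
  sampled <- sum(annotations$read_bp)
  if (nrow(annotations) == 0 || sampled <= 0) {
    warning("empty annotation table; TE content set to zero")
    return(structure(list(species = species, te_fraction = 0, te_bp = 0,
                          sampled_bp = sampled,
                          by_class = data.frame(class = character(0),
                                                bp = numeric(0),
                                                fraction = numeric(0))),
                     class = "te_summary"))
  }
  te_fraction <- sum(annotations$annotated_bp) / sampled
  cls <- factor(annotations$repeat_class,
                levels = union(.te_classes, unique(annotations$repeat_class)))
  class_bp <- tapply(annotations$annotated_bp, cls, sum, default = 0)
  class_bp <- class_bp[class_bp > 0 & names(class_bp) != "none"]
  by_class <- data.frame(class = names(class_bp),
                         bp = as.numeric(class_bp) / sampled * genome_size,
                         fraction = as.numeric(class_bp) / sampled,
                         row.names = NULL)
  structure(list(species = species, te_fraction = te_fraction,
                 te_bp = te_fraction * genome_size, sampled_bp = sampled,
                 by_class = by_class),
            class = "te_summary")
}

#' @export
print.te_summary <- function(x, ...) {
  cat(sprintf("TE content%s: %.1f%% of genome (%.4g bp)\n",
              if (is.na(x$species)) "" else paste0(" [", x$species, "]"),
              100 * x$te_fraction, x$te_bp))
  invisible(x)
}

#' Recent TE content (reads below the divergence threshold)
#'
#' Same genome-size scaling as [summarize_te_content()], restricted to
#' annotations strictly below `recent_divergence_max` divergence from their
#' family consensus (a read at exactly the threshold is excluded).
#'
#' @param annotations TE read-annotation table.
#' @param genome_size Genome size in bp.
#' @param cfg A [pipeline_config()].
#' @return Recent TE bp (numeric scalar).
#' @export
recent_te_content <- function(annotations, genome_size,
                              cfg = pipeline_config()) {
  validate_te_annotations(annotations)
  sampled <- sum(annotations$read_bp)
  if (sampled <= 0) return(0)
  recent <- annotations$annotated_bp > 0 & !is.na(annotations$divergence) &
    annotations$divergence < cfg$recent_divergence_max
  sum(annotations$annotated_bp[recent]) / sampled * genome_size
}

#' Divergence landscape histogram
#'
#' Annotated bp mass per divergence bin, bins half-open `[lo, hi)`.
#'
#' @param annotations TE read-annotation table.
#' @param bin_width Bin width in divergence units, in `(0, 0.5]`.
#' @return Data.frame: `bin_lo`, `bin_hi`, `bp`.
#' @export
landscape_histogram <- function(annotations, bin_width = 0.01) {
  validate_te_annotations(annotations)
  if (bin_width <= 0 || bin_width > 0.5) stop("bin_width must be in (0, 0.5]")
  ann <- annotations[annotations$annotated_bp > 0 &
                       !is.na(annotations$divergence), , drop = FALSE]
  breaks <- seq(0, ceiling(1 / bin_width) * bin_width + bin_width,
                by = bin_width)
  idx <- findInterval(ann$divergence, breaks, rightmost.closed = FALSE)
  bp <- tapply(ann$annotated_bp, factor(idx, levels = seq_len(length(breaks) - 1)),
               sum, default = 0)
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                    bp = as.numeric(bp))
  out[out$bp > 0 | out$bin_lo < 1, , drop = FALSE]
}
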