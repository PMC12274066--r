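#' Deduplicate C-value records to one value per species
#'
#' When a species has several C-value records the most recent one is kept;
#' records tied on the most recent date are averaged.
#'
#' @param records Data.frame with columns `species`, `cvalue` (pg), `date`
#'   (numeric year or anything orderable), optionally `method` and
#'   `assembly_size` (carried through from the first retained record).
#' @return Data.frame with one row per species.
#' @export
dedup_cvalues <- function(records) {
  stopifnot(all(c("species", "cvalue", "date") %in% names(records)))
  out <- lapply(split(records, records$species), function(d) {
    newest <- d[d$date == max(d$date), , drop = FALSE]
    res <- newest[1, , drop = FALSE]
    res$cvalue <- mean(newest$cvalue)
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$species), , drop = FALSE]
}

#' Weighted least squares of C-value on assembly size
#'
#' Fits `cvalue_bp = b0 + b1 * assembly_size` by closed-form weighted least
#' squares. The default weights `1/assembly_size^2` encode multiplicative
#' error, matching the growth of C-value scatter with genome size; `equal`
#' weights reduce to ordinary least squares.
#'
#' @param records Data.frame with `assembly_size` (bp) and `cvalue_bp` (bp;
#'   C-values already converted from pg).
#' @param weights `"inv_size_sq"` (default) or `"equal"`.
#' @return An object of class `cvalue_model`: `intercept`, `slope`,
#'   `weights`, `n_records`, `wrss` (weighted residual sum of squares).
#' @export
fit_cvalue_wls <- function(records, weights = c("inv_size_sq", "equal")) {
  weights <- match.arg(weights)
  stopifnot(all(c("assembly_size", "cvalue_bp") %in% names(records)))
  ok <- stats::complete.cases(records[, c("assembly_size", "cvalue_bp")])
  x <- records$assembly_size[ok]; y <- records$cvalue_bp[ok]
  if (length(x) < 3) stop("need at least 3 complete records to fit")
  if (length(unique(x)) < 2) stop("singular design: all assembly sizes equal")
  w <- if (weights == "inv_size_sq") 1 / x^2 else rep(1, length(x))
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swy - slope * swx) / sw
  wrss <- sum(w * (y - intercept - slope * x)^2)
  structure(list(intercept = intercept, slope = slope, weights = weights,
                 n_records = length(x), wrss = wrss),
            class = "cvalue_model")
}

#' @export
print.cvalue_model <- function(x, ...) {
  cat(sprintf(
    "C-value WLS (%s weights, n = %d): cvalue_bp = %.4g + %.4g * assembly_size\n",
    x$weights, x$n_records, x$intercept, x$slope))
  invisible(x)
}

#' Predict an expected C-value (bp) from assembly size
#'
#' Linear prediction floored at the assembly size itself, since an assembly
#' is a lower bound on genome size.
#'
#' @param model A `cvalue_model` from [fit_cvalue_wls()].
#' @param assembly_size Assembly size in bp (> 0), vectorized.
#' @return Predicted genome size(s) in bp.
#' @export
predict_cvalue <- function(model, assembly_size) {
  if (!inherits(model, "cvalue_model")) stop("model is not a fitted cvalue_model")
  if (any(assembly_size <= 0)) stop("assembly_size must be > 0")
  pmax(model$intercept + model$slope * assembly_size, assembly_size)
}

#' Choose the genome size for one species
#'
#' The measured C-value is used when available (converted at `pg_to_bp`);
#' otherwise the C-value predicted from assembly size by the WLS model.
#'
#' @param row One row of a `species_traits` table (needs `assembly_size`,
#'   optionally `cvalue` in pg).
#' @param model A `cvalue_model`, or `NULL` when every species has a
#'   C-value.
#' @param pg_to_bp Conversion constant (bp per pg).
#' @return List with `genome_size` (bp) and `source` (`"cvalue"` or
#'   `"predicted"`).
#' @export
choose_genome_size <- function(row, model = NULL, pg_to_bp = 0.978e9) {
  has_cv <- !is.null(row$cvalue) && length(row$cvalue) == 1 && !is.na(row$cvalue)
  if (has_cv) {
    return(list(genome_size = row$cvalue * pg_to_bp, source = "cvalue"))
  }
  if (is.null(model)) stop("no C-value and no fitted model for species ",
                           row$species)
  if (is.null(row$assembly_size) || is.na(row$assembly_size)) {
    stop("assembly_size missing for species ", row$species)
  }
  list(genome_size = predict_cvalue(model, row$assembly_size),
       source = "predicted")
}

#' Estimate genome sizes for a whole trait table
#'
#' Fits the C-value WLS on the species with measurements and applies the
#' C-value-else-prediction rule to every row.
#'
#' @param table A `species_traits` table with `assembly_size` and (partly
#'   missing) `cvalue` in pg.
#' @param cfg A [pipeline_config()].
#' @param weights Passed to [fit_cvalue_wls()].
#' @return The table with `genome_size` (bp) and `genome_size_source`
#'   columns filled, plus the fitted model as attribute `cvalue_model`.
#' @export
estimate_genome_sizes <- function(table, cfg = pipeline_config(),
                                  weights = "inv_size_sq") {
  has_cv <- !is.na(table$cvalue)
  model <- NULL
  if (sum(has_cv) >= 3 && length(unique(table$assembly_size[has_cv])) >= 2) {
    rec <- data.frame(assembly_size = table$assembly_size[has_cv],
                      cvalue_bp = table$cvalue[has_cv] * cfg$pg_to_bp)
    model <- fit_cvalue_wls(rec, weights = weights)
  } else if (!all(has_cv)) {
    stop("too few C-value records to fit the prediction model")
  }
  res <- lapply(seq_len(nrow(table)), function(i) {
    choose_genome_size(table[i, , drop = FALSE], model, cfg$pg_to_bp)
  })
  table$genome_size <- vapply(res, `[[`, numeric(1), "genome_size")
  table$genome_size_source <- vapply(res, `[[`, character(1), "source")
  attr(table, "cvalue_model") <- model
  table
}
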