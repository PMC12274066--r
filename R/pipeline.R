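#' Run the full analysis end-to-end
#'
#' Composes the stages in analysis order: assembly filtering, genome-size
#' estimation (C-value-else-WLS-prediction), per-gene dN/dS mapping and
#' per-species aggregation, TE summarization scaled to the estimated genome
#' size, and the phylogenetically controlled comparative stage (independent
#' contrasts plus the multivariate Brownian fit). Inputs are either a
#' [generate_scenario()] bundle (`simulate = TRUE`) or user files. All
#' stage tables are written as TSV under `out_dir` together with a JSON run
#' manifest (config snapshot, seed, input digests, per-stage row counts),
#' so identical seeds give identical outputs.
#'
#' @param out_dir Output directory (created if missing).
#' @param cfg A [pipeline_config()].
#' @param simulate Generate all inputs from `scenario` instead of reading
#'   files.
#' @param scenario A [simulation_scenario()] (used when `simulate`).
#' @param tree_file,trait_file,alignment_files,te_files Input paths when
#'   `simulate = FALSE`: newick tree, trait TSV, FASTA gene alignments, and
#'   per-species TE annotation TSVs named by species
#'   (`<species>.tsv`).
#' @param blacklist Optional gene blacklist (see [apply_gene_blacklist()]).
#' @param bootstrap_reps Parametric-bootstrap replicates for the Brownian
#'   support stage (0 skips it).
#' @return The run manifest (list), invisibly; all results are on disk.
#' @export
run_pipeline <- function(out_dir, cfg = pipeline_config(), simulate = FALSE,
                         scenario = simulation_scenario(seed = cfg$seed),
                         tree_file = NULL, trait_file = NULL,
                         alignment_files = NULL, te_files = NULL,
                         blacklist = NULL, bootstrap_reps = 200) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(cfg), seed = cfg$seed,
                   simulate = simulate, stages = list())
  if (simulate) {
    bundle <- generate_scenario(scenario)
    tree <- bundle$tree
    table <- as_species_traits(data.frame(
      species = bundle$traits$species,
      assembly_size = bundle$cvalue_records$assembly_size,
      cvalue = ifelse(seq_len(nrow(bundle$traits)) %% 2 == 1,
                      bundle$cvalue_records$cvalue, NA),
      method = bundle$cvalue_records$method,
      date = bundle$cvalue_records$date,
      contig_N50 = 1e6, busco_complete = 95, busco_duplicated = 5))
    alignments <- bundle$alignments
    te_tables <- lapply(bundle$te, `[[`, "annotations")
    write_newick(tree, file.path(out_dir, "tree.nwk"))
    write_trait_table(bundle$traits, file.path(out_dir, "true_traits.tsv"))
  } else {
    if (is.null(tree_file) || !file.exists(tree_file)) {
      stop("tree file missing: ", tree_file)
    }
    if (is.null(trait_file) || !file.exists(trait_file)) {
      stop("trait file missing: ", trait_file)
    }
    tree <- read_newick(file = tree_file)
    table <- read_trait_table(trait_file)
    alignments <- lapply(alignment_files, read_codon_fasta)
    if (length(alignments) > 0) {
      names(alignments) <- vapply(alignments, `[[`, character(1), "gene")
    }
    te_tables <- lapply(te_files, function(f) {
      utils::read.delim(f, sep = "\t", stringsAsFactors = FALSE)
    })
    if (length(te_tables) > 0 && is.null(names(te_tables))) {
      names(te_tables) <- sub("\\.[^.]*$", "", basename(unlist(te_files)))
    }
    manifest$input_digests <- as.list(tools::md5sum(
      c(tree_file, trait_file, unlist(alignment_files), unlist(te_files))))
  }

  # stage 1: assembly QC filter
  table <- filter_assemblies(table, cfg)
  manifest$stages$filter_assemblies <- list(rows = nrow(table))

  # stage 2: genome size
  table <- estimate_genome_sizes(table, cfg)
  write_trait_table(
    table[, c("species", "genome_size", "genome_size_source")],
    file.path(out_dir, "genome_size.tsv"))
  manifest$stages$genome_size <- list(rows = nrow(table))

  # stage 3-4: dN/dS mapping and aggregation
  dnds_tab <- NULL
  if (length(alignments) > 0) {
    alignments <- lapply(alignments, filter_insertion_heavy, cfg = cfg)
    kept_genes <- apply_gene_blacklist(names(alignments), blacklist)
    alignments <- alignments[kept_genes]
    records <- do.call(rbind, lapply(alignments, function(a) {
      map_gene_substitutions(a, tree)
    }))
    records <- records[records$species %in% table$species, , drop = FALSE]
    write_trait_table(records, file.path(out_dir, "substitution_records.tsv"))
    dnds_tab <- aggregate_all_species(records, cfg)
    write_trait_table(dnds_tab, file.path(out_dir, "dnds.tsv"))
    table$dnds <- dnds_tab$dnds[match(table$species, dnds_tab$species)]
    manifest$stages$dnds <- list(genes = length(alignments),
                                 rows = nrow(dnds_tab))
  }

  # stage 5: TE content scaled to the estimated genome size
  if (length(te_tables) > 0) {
    te_rows <- lapply(names(te_tables), function(sp) {
      gs <- table$genome_size[table$species == sp]
      if (length(gs) != 1 || is.na(gs)) return(NULL)
      summ <- summarize_te_content(te_tables[[sp]], gs, species = sp)
      data.frame(species = sp, te_bp = summ$te_bp,
                 recent_te_bp = recent_te_content(te_tables[[sp]], gs, cfg),
                 te_fraction = summ$te_fraction)
    })
    te_tab <- do.call(rbind, te_rows)
    write_trait_table(te_tab, file.path(out_dir, "te_content.tsv"))
    table$te_bp <- te_tab$te_bp[match(table$species, te_tab$species)]
    table$recent_te_bp <-
      te_tab$recent_te_bp[match(table$species, te_tab$species)]
    manifest$stages$te <- list(rows = nrow(te_tab))
  }

  # stage 6: comparative tests (full and duplication-screened sets)
  comp <- list()
  if (!is.null(dnds_tab) || !is.null(table$te_bp)) {
    sets <- duplication_screen(table, cfg)
    for (set_name in c("full", "reduced")) {
      tab <- sets[[set_name]]
      pairs <- list(c("genome_size", "te_bp"), c("dnds", "genome_size"),
                    c("dnds", "te_bp"), c("dnds", "recent_te_bp"))
      for (pr in pairs) {
        if (!all(pr %in% names(tab))) next
        xv <- stats::setNames(tab[[pr[1]]], tab$species)
        yv <- stats::setNames(tab[[pr[2]]], tab$species)
        ok <- !is.na(xv) & !is.na(yv) & yv > 0 & xv > 0
        if (sum(ok) < 4) next
        cxy <- tryCatch({
          cx <- compute_contrasts(tree, log(xv[ok]))
          cy <- compute_contrasts(tree, log(yv[ok]))
          pic_regression(cx, cy)
        }, error = function(e) NULL)
        if (!is.null(cxy)) {
          comp[[length(comp) + 1]] <- data.frame(
            set = set_name, x = pr[1], y = pr[2], method = "pic",
            slope = cxy$slope, adj_r_squared = cxy$adj_r_squared,
            p_value = cxy$p_value, n = cxy$n)
        }
        ols <- tryCatch(ols_regression(xv[ok], yv[ok], log_x = TRUE,
                                       log_y = TRUE),
                        error = function(e) NULL)
        if (!is.null(ols)) {
          comp[[length(comp) + 1]] <- data.frame(
            set = set_name, x = pr[1], y = pr[2], method = "ols_loglog",
            slope = ols$slope, adj_r_squared = ols$adj_r_squared,
            p_value = ols$p_value, n = ols$n)
        }
      }
    }
  }
  if (length(comp) > 0) {
    comp_tab <- do.call(rbind, comp)
    write_trait_table(comp_tab, file.path(out_dir, "comparative.tsv"))
    manifest$stages$comparative <- list(rows = nrow(comp_tab))
  }

  # Brownian coevolution fit on the trait channels present
  trait_cols <- intersect(c("dnds", "genome_size", "te_bp"), names(table))
  Y <- table[, trait_cols, drop = FALSE]
  for (cl in c("genome_size", "te_bp")) {
    if (cl %in% names(Y)) Y[[cl]] <- log(Y[[cl]])
  }
  rownames(Y) <- table$species
  if (ncol(Y) >= 2 && sum(stats::complete.cases(Y)) >= ncol(Y) + 2) {
    bfit <- fit_brownian_multivariate(tree, as.matrix(Y))
    manifest$stages$brownian <- list(n = bfit$n,
                                     correlation = bfit$correlation)
    if (bootstrap_reps >= 100) {
      supp <- bootstrap_support(bfit, n_reps = bootstrap_reps,
                                seed = cfg$seed)
      write_trait_table(supp, file.path(out_dir, "brownian_support.tsv"))
      manifest$stages$brownian$flagged <-
        paste(supp$trait_x[supp$flagged], supp$trait_y[supp$flagged],
              sep = "~")
    }
    jsonlite::write_json(
      list(R = bfit$R, mu = bfit$mu, correlation = bfit$correlation,
           n = bfit$n, loglik = bfit$loglik),
      file.path(out_dir, "brownian_fit.json"), auto_unbox = TRUE,
      digits = NA, matrix = "rowmajor")
  }

  write_trait_table(table, file.path(out_dir, "species_table.tsv"))
  manifest$outputs <- list.files(out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

#' Recompute headline statistics from deposited source-data tables
#'
#' Given local copies of the per-figure source tables, recomputes the
#' regressions and correlations their captions report: the log-log
#' TE-content/genome-size regression, the Pearson correlation between
#' assembly size and C-value (raw and on logs), the correlation between
#' assembly-based and read-based TE estimates, the correlations between
#' dN/dS variants, and the BUSCO-duplication/genome-size regression.
#' Only the checks whose tables are supplied are run.
#'
#' @param te_vs_size Data.frame or TSV path with `te_bp` and `genome_size`.
#' @param cvalues Data.frame or path with `assembly_size` and `cvalue_bp`
#'   (or `cvalue` in pg).
#' @param te_methods Data.frame or path with two TE estimates per species,
#'   columns `te_a` and `te_b`.
#' @param dnds_pairs Data.frame or path with paired dN/dS columns
#'   `dnds_a` and `dnds_b`.
#' @param duplication Data.frame or path with `busco_duplicated` and
#'   `genome_size`.
#' @param pg_to_bp C-value conversion when only pg values are present.
#' @return Data.frame: `check`, `statistic`, `value`, `n`.
#' @export
reproduce_supplementary <- function(te_vs_size = NULL, cvalues = NULL,
                                    te_methods = NULL, dnds_pairs = NULL,
                                    duplication = NULL, pg_to_bp = 0.978e9) {
  load_tab <- function(x) {
    if (is.character(x)) utils::read.delim(x, sep = "\t",
                                           stringsAsFactors = FALSE) else x
  }
  need <- function(tab, cols, what) {
    miss <- setdiff(cols, names(tab))
    if (length(miss) > 0) stop(what, ": column(s) missing: ",
                               paste(miss, collapse = ", "))
  }
  rows <- list()
  add <- function(check, statistic, value, n) {
    rows[[length(rows) + 1]] <<- data.frame(check = check,
                                            statistic = statistic,
                                            value = value, n = n)
  }
  if (!is.null(te_vs_size)) {
    tab <- load_tab(te_vs_size)
    need(tab, c("te_bp", "genome_size"), "te_vs_size")
    r <- ols_regression(tab$genome_size, tab$te_bp, log_x = TRUE,
                        log_y = TRUE)
    add("te_vs_genome_size_loglog", "slope", r$slope, r$n)
    add("te_vs_genome_size_loglog", "adj_r_squared", r$adj_r_squared, r$n)
  }
  if (!is.null(cvalues)) {
    tab <- load_tab(cvalues)
    if (!"cvalue_bp" %in% names(tab)) {
      need(tab, c("assembly_size", "cvalue"), "cvalues")
      tab$cvalue_bp <- tab$cvalue * pg_to_bp
    }
    ok <- stats::complete.cases(tab$assembly_size, tab$cvalue_bp)
    add("assembly_vs_cvalue", "pearson_r",
        stats::cor(tab$assembly_size[ok], tab$cvalue_bp[ok]), sum(ok))
    add("assembly_vs_cvalue", "pearson_r_log",
        stats::cor(log(tab$assembly_size[ok]), log(tab$cvalue_bp[ok])),
        sum(ok))
  }
  if (!is.null(te_methods)) {
    tab <- load_tab(te_methods)
    need(tab, c("te_a", "te_b"), "te_methods")
    ok <- stats::complete.cases(tab$te_a, tab$te_b)
    add("te_method_agreement", "pearson_r",
        stats::cor(tab$te_a[ok], tab$te_b[ok]), sum(ok))
  }
  if (!is.null(dnds_pairs)) {
    tab <- load_tab(dnds_pairs)
    need(tab, c("dnds_a", "dnds_b"), "dnds_pairs")
    ok <- stats::complete.cases(tab$dnds_a, tab$dnds_b)
    add("dnds_variant_agreement", "pearson_r",
        stats::cor(tab$dnds_a[ok], tab$dnds_b[ok]), sum(ok))
  }
  if (!is.null(duplication)) {
    tab <- load_tab(duplication)
    need(tab, c("busco_duplicated", "genome_size"), "duplication")
    r <- ols_regression(tab$busco_duplicated, tab$genome_size)
    add("duplication_vs_genome_size", "slope", r$slope, r$n)
    add("duplication_vs_genome_size", "adj_r_squared", r$adj_r_squared, r$n)
  }
  if (length(rows) == 0) stop("no input tables supplied")
  do.call(rbind, rows)
}
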