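# End-to-end orchestration: prune the tree to the taxa with karyotype data,
# build the trait table, and run the five analysis stages (signal, trait
# models, rate shifts, chromosome-number CTMC, karyograph SSE), writing
# tabular outputs and a JSON summary when an output directory is given.
# Stage failures are isolated so independent stages still run.

#' Run the full karyotype-evolution analysis
#'
#' @param tree A rooted \code{phylo}, or a path to a Newick file.
#' @param karyotypes "fixture" (the packaged leafcutting-ant compilation), a
#'   record data.frame from [leafcutter_karyotypes()], or a trait table with
#'   columns taxon, n, nm, nsm, nst, nt, fn.
#' @param traits Trait columns to analyse (default all six).
#' @param log_transform Log(x+1)-transform traits for the continuous-trait
#'   stages (default TRUE; discrete stages always use raw counts).
#' @param n_reps Permutations for the signal tests (default 999).
#' @param shift_cutoff AICc cut-off for the rate-shift scan (default 4).
#' @param seed Integer seed for all stochastic steps (default 1).
#' @param karyograph_y_max Optional state-space bound for the karyograph
#'   stage (default: 2 x the largest observed haploid number + 2; smaller
#'   values make exploratory runs much faster).
#' @param out_dir Optional output directory (created if needed); TSV tables
#'   and summary.json are written there.
#' @param stages Subset of c("signal", "models", "shifts", "chromevol",
#'   "karyograph") to run.
#' @return List with elements per stage plus \code{tree} (pruned),
#'   \code{traits}, \code{config}, and \code{errors} (named list of stage
#'   failures, empty on success).
#' @export
run_karyotype_pipeline <- function(tree, karyotypes = "fixture",
                                   traits = c("n", "nm", "nsm", "nst",
                                              "nt", "fn"),
                                   log_transform = TRUE, n_reps = 999L,
                                   shift_cutoff = 4, seed = 1L,
                                   karyograph_y_max = NULL,
                                   out_dir = NULL,
                                   stages = c("signal", "models", "shifts",
                                              "chromevol", "karyograph")) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.character(tree)) tree <- read_newick(file = tree)
  trait_tab <- if (identical(karyotypes, "fixture")) {
    karyotype_trait_table()
  } else if (is.data.frame(karyotypes) && "formula" %in% names(karyotypes)) {
    karyotype_trait_table(karyotypes)
  } else if (is.data.frame(karyotypes)) {
    karyotypes
  } else stop("karyotypes must be 'fixture' or a data.frame")
  bad <- setdiff(traits, setdiff(names(trait_tab), "taxon"))
  if (length(bad))
    stop("unknown trait name(s): ", paste(bad, collapse = ", "))

  shared <- intersect(normalize_taxon_names(tree$tip.label),
                      normalize_taxon_names(trait_tab$taxon))
  if (length(shared) < 4L)
    stop("fewer than 4 taxa shared between tree and karyotype table; ",
         "unmatched tree tips: ",
         paste(setdiff(normalize_taxon_names(tree$tip.label), shared),
               collapse = ", "))
  tree <- prune_to_taxa(tree, shared)
  tree <- resolve_polytomies(tree)
  trait_tab <- trait_tab[normalize_taxon_names(trait_tab$taxon) %in% shared,
                         , drop = FALSE]
  cont <- trait_tab[, c("taxon", traits), drop = FALSE]
  if (log_transform)
    cont[-1L] <- lapply(cont[-1L], function(x) log(x + 1))

  res <- list(tree = tree, traits = trait_tab,
              config = list(traits = traits, log_transform = log_transform,
                            n_reps = n_reps, shift_cutoff = shift_cutoff,
                            seed = seed, stages = stages))
  errors <- list()
  run_stage <- function(name, expr) {
    if (!name %in% stages) return(invisible(NULL))
    r <- tryCatch(expr, error = function(e) e)
    if (inherits(r, "error")) errors[[name]] <<- conditionMessage(r)
    else res[[name]] <<- r
  }

  run_stage("signal", signal_table(tree, cont, n_reps = n_reps, seed = seed))
  run_stage("models", {
    tabs <- lapply(traits, function(tn)
      trait_model_table(tree, stats::setNames(cont[[tn]], cont$taxon)))
    names(tabs) <- traits
    tabs
  })
  run_stage("shifts", {
    sh <- lapply(traits, function(tn)
      scan_rate_shifts(tree, stats::setNames(cont[[tn]], cont$taxon),
                       cutoff = shift_cutoff))
    names(sh) <- traits
    sh
  })
  run_stage("chromevol", {
    y <- stats::setNames(as.integer(trait_tab$n), trait_tab$taxon)
    tab <- chrom_model_table(tree, y)
    bestfit <- attr(tab, "fits")[[which.min(vapply(attr(tab, "fits"),
                                                   `[[`, 0, "AIC"))]]
    list(table = tab, best = bestfit,
         ancestral = chrom_ancestral(tree, y, bestfit))
  })
  run_stage("karyograph", {
    ts <- karyograph_tip_states(trait_tab)
    fits <- fit_m1_m2(tree, ts, y_max = karyograph_y_max)
    best <- if (fits$lrt$p_value < 0.05) fits$m2 else fits$m1
    list(fits = fits, ancestral = ancestral_karyograph(tree, ts, best))
  })

  res$errors <- errors
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  write_newick(res$tree, file.path(out_dir, "pruned_tree.nwk"))
  tsv(res$traits, "traits.tsv")
  if (!is.null(res$signal)) tsv(res$signal, "signal.tsv")
  if (!is.null(res$models))
    for (tn in names(res$models))
      tsv(res$models[[tn]], paste0("models_", tn, ".tsv"))
  if (!is.null(res$shifts))
    for (tn in names(res$shifts))
      tsv(res$shifts[[tn]]$steps, paste0("shifts_", tn, ".tsv"))
  if (!is.null(res$chromevol)) {
    tsv(res$chromevol$table, "chromevol_models.tsv")
    tsv(data.frame(node = rownames(res$chromevol$ancestral$prob),
                   ml_state = res$chromevol$ancestral$ml_state),
        "chromevol_ancestral.tsv")
    write_annotated_newick(res$tree,
                           res$chromevol$ancestral$ml_state,
                           file.path(out_dir, "chromevol_ancestral.nwk"))
  }
  if (!is.null(res$karyograph)) {
    anc <- res$karyograph$ancestral
    tsv(data.frame(node = rownames(anc$prob), mean_y = anc$mean_y,
                   mean_x = anc$mean_x, ml_state = anc$ml_state),
        "karyograph_ancestral.tsv")
  }
  summary <- list(
    n_tips = ape::Ntip(res$tree),
    config = res$config,
    errors = res$errors,
    karyograph = if (!is.null(res$karyograph)) {
      f <- res$karyograph$fits
      list(lnL_m1 = f$m1$lnL, lnL_m2 = f$m2$lnL,
           lrt_statistic = f$lrt$statistic, lrt_p = f$lrt$p_value,
           m1 = f$m1$pars, m2 = f$m2$pars)
    },
    chromevol_best_aic = if (!is.null(res$chromevol))
      min(res$chromevol$table$AIC))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(out_dir)
}
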