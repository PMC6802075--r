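#' Run the full homoplasy-weighing study
#'
#' Orchestrates the stages in their methodological order: allometric
#' regression on the full (unpruned) species set, pruning of the residuals
#' to the study tree, SIC scoring of the six hypothesis models per trait,
#' the specimen-resampling sensitivity filter, the advance rule, and — for
#' traits that advance — pairwise parametric-bootstrap comparison of the
#' focal model against every alternative.  Per-trait failures are isolated
#' and reported; the run is reproducible from `seed`.
#'
#' @param tree Study tree (`phylo`), already pruned to the retained species.
#' @param traits Specimen-level trait table (`species`, `specimen`,
#'   `trait`, `value`), typically covering more species than the tree.
#' @param mass Named ln-body-mass vector covering the trait table's species.
#' @param painting A `regime_painting` of `tree` with two derived regimes.
#' @param focal Focal (homoplasy) model name.
#' @param n_replicates Sensitivity replicates per trait.
#' @param n_sim Simulated datasets per model in each pairwise comparison.
#' @param n_perm Permutation rounds for the allometric significance report.
#' @param specimen_sd Intraspecific SD for the sensitivity stage: `NULL`
#'   (pooled from species with >= 2 specimens, per trait), a single number,
#'   or a named per-trait vector.
#' @param root_policy Root-state policy for the OU models.
#' @param run_pmc Run the pairwise stage for advanced traits?
#' @param seed Master seed (recorded in the report).
#' @return A `study_report`: tibbles `allometry`, `scores`, `sensitivity`,
#'   `advance`, `pmc`, the per-trait fit and comparison objects, and the
#'   configuration echo.
#' @export
run_study <- function(tree, traits, mass, painting, focal = "OU2_shared",
                      n_replicates = 1000, n_sim = 5000, n_perm = 1000,
                      specimen_sd = NULL,
                      root_policy = c("root_regime", "free"),
                      run_pmc = TRUE, seed = 1L) {
  root_policy <- match.arg(root_policy)
  if (!nrow(traits)) stop("empty trait table", call. = FALSE)
  trait_ids <- unique(traits$trait)
  regs <- attr(painting, "regimes"); bg <- attr(painting, "background")
  derived <- setdiff(regs, bg)
  models <- hypothesis_models(bg, derived[1], derived[2],
                              root_policy = root_policy)
  if (!focal %in% names(models))
    stop("unknown focal model '", focal, "'", call. = FALSE)
  set.seed(seed)
  trait_seeds <- sample.int(.Machine$integer.max - 10L, length(trait_ids))

  allom <- list(); score_tabs <- list(); sens_tabs <- list()
  adv_tabs <- list(); pmc_tabs <- list(); pmc_objs <- list()
  fit_objs <- list(); failures <- list()
  for (i in seq_along(trait_ids)) {
    tid <- trait_ids[i]
    res <- tryCatch({
      af <- fit_allometry(traits, mass, tid, n_perm = n_perm,
                          seed = trait_seeds[i])
      x <- residual_matrix(list(af), tree$tip.label)[, 1]
      st <- score_models(tree, painting, x, models, trait = tid)
      sd_i <- if (is.null(specimen_sd)) pooled_specimen_sd(traits, tid)
              else if (length(specimen_sd) > 1) specimen_sd[[tid]]
              else specimen_sd
      sens <- sampling_sensitivity(tree, painting, x, sd = sd_i,
                                   n_replicates = n_replicates,
                                   seed = trait_seeds[i] + 1L,
                                   models = models, trait = tid)
      adv <- advance_rule(st, sens, focal = focal)
      pmc_list <- list()
      if (run_pmc && adv$advance) {
        alts <- setdiff(names(models), focal)
        for (j in seq_along(alts)) {
          pmc_list[[alts[j]]] <- pmc_compare(
            tree, painting, x, models[[focal]], models[[alts[j]]],
            n_sim = n_sim, seed = trait_seeds[i] + 1L + 2L * j)
        }
      }
      list(af = af, st = st, sens = sens, adv = adv, pmc = pmc_list)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[tid]] <- conditionMessage(res)
      warning("trait '", tid, "' failed: ", conditionMessage(res),
              call. = FALSE)
      next
    }
    allom[[tid]] <- glance(res$af)
    score_tabs[[tid]] <- tibble::as_tibble(res$st)
    sens_tabs[[tid]] <- tibble::as_tibble(res$sens)
    adv_tabs[[tid]] <- res$adv
    fit_objs[[tid]] <- attr(res$st, "fits")
    if (length(res$pmc)) {
      pmc_objs[[tid]] <- res$pmc
      pmc_tabs[[tid]] <- dplyr::bind_rows(lapply(res$pmc, glance)) |>
        dplyr::mutate(trait = tid, .before = 1)
    }
  }
  structure(list(
    allometry = dplyr::bind_rows(allom),
    scores = dplyr::bind_rows(score_tabs),
    sensitivity = dplyr::bind_rows(sens_tabs),
    advance = dplyr::bind_rows(adv_tabs),
    pmc = if (length(pmc_tabs)) dplyr::bind_rows(pmc_tabs) else
      tibble::tibble(),
    fits = fit_objs, pmc_results = pmc_objs, failures = failures,
    config = list(focal = focal, n_replicates = n_replicates,
                  n_sim = n_sim, n_perm = n_perm, seed = seed,
                  root_policy = root_policy,
                  n_species = length(tree$tip.label),
                  package_version = as.character(utils::packageVersion(
                    "ouhomoplasy")))),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  nt <- length(unique(x$scores$trait))
  cat("study_report: ", nt, " trait(s) scored on ", x$config$n_species,
      " species (seed ", x$config$seed, ")\n", sep = "")
  if (nrow(x$advance)) {
    adv <- x$advance$trait[x$advance$advance]
    cat("  advanced to pairwise comparison: ",
        if (length(adv)) paste(adv, collapse = ", ") else "none", "\n",
        sep = "")
  }
  if (nrow(x$pmc)) {
    cat("  pairwise classifications:\n")
    print(pmc_symbol_table(x))
  }
  if (length(x$failures))
    cat("  failed trait(s): ", paste(names(x$failures), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Pairwise-comparison summary in +/=/ / notation
#'
#' One row per advanced trait, one column per alternative model: `+` the
#' focal model is favored, `=` both models are plausible, `/` both are
#' implausible, `-` only the alternative is plausible.
#'
#' @param report A `study_report`.
#' @return A tibble.
#' @export
pmc_symbol_table <- function(report) {
  if (!nrow(report$pmc)) return(tibble::tibble())
  sym <- c(focal_favored = "+", both_plausible = "=",
           both_implausible = "/", alternative_favored = "-")
  report$pmc |>
    dplyr::mutate(symbol = sym[.data$classification]) |>
    dplyr::select("trait", "alternative", "symbol") |>
    tidyr::pivot_wider(names_from = "alternative", values_from = "symbol")
}

#' Write a study report to a directory
#'
#' Emits the score and sensitivity tables (the two-panel layout: empirical
#' SIC per model, frequency of lowest SIC among resampled datasets), the
#' advance decisions, the pairwise summary, one JSON record per model fit,
#' and a JSON run log with all seeds and versions.  Everything is plain
#' text.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @param plots Also write one PNG per pairwise comparison (the two ratio
#'   histograms with the empirical ratio marked)?
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir, plots = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wide_sic <- report$scores |>
    dplyr::select("trait", "model", "SIC") |>
    tidyr::pivot_wider(names_from = "model", values_from = "SIC")
  wide_freq <- report$sensitivity |>
    dplyr::select("trait", "model", "freq_lowest_sic") |>
    tidyr::pivot_wider(names_from = "model",
                       values_from = "freq_lowest_sic")
  readr::write_csv(report$allometry, file.path(dir, "allometry.csv"))
  readr::write_csv(wide_sic, file.path(dir, "scores_sic.csv"))
  readr::write_csv(wide_freq, file.path(dir, "sensitivity_freq.csv"))
  readr::write_csv(report$scores, file.path(dir, "scores_long.csv"))
  readr::write_csv(report$advance, file.path(dir, "advance.csv"))
  if (nrow(report$pmc)) {
    readr::write_csv(report$pmc, file.path(dir, "pmc_long.csv"))
    readr::write_csv(pmc_symbol_table(report),
                     file.path(dir, "pmc_summary.csv"))
  }
  if (plots && length(report$pmc_results)) {
    for (tid in names(report$pmc_results))
      for (alt in names(report$pmc_results[[tid]]))
        suppressMessages(ggplot2::ggsave(
          file.path(dir, paste0("pmc_", tid, "_vs_", alt, ".png")),
          autoplot(report$pmc_results[[tid]][[alt]]),
          width = 6, height = 4, dpi = 120))
  }
  for (tid in names(report$fits))
    for (fit in report$fits[[tid]])
      fit_to_json(fit, file.path(dir, paste0("fit_", tid, "_",
                                             fit$spec$name, ".json")))
  writeLines(jsonlite::toJSON(report$config, auto_unbox = TRUE, digits = NA),
             file.path(dir, "run_log.json"))
  invisible(dir)
}
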