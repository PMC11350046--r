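#' Run the full synthetic-cohort analysis pipeline
#'
#' Generates (or reuses) a synthetic cohort, then runs every analysis
#' module: sEPSC detection and waveform statistics per cell, passive /
#' sag / rebound extraction per current-clamp trace, the synapse
#' inclusion filter, per-synapse metrics and nearest-neighbor clustering
#' per vesicle map, and branch / Sholl / spine morphometry per neuron.
#' Group means (+/- SEM), unpaired two-tailed Student t tests with star
#' annotations, and headline percent changes between the first
#' (reference) and second genotype are assembled into a report.
#'
#' When `out_dir` is given, the per-unit feature tables are written as
#' TSV, the group nearest-neighbor mean ECDFs as
#' `nn_ecdf_<group>.tsv`, the report as `report.json`, and a run log
#' (seed, design, package version) as `run_log.json`.
#'
#' @param design a [cohort_design()]; the first genotype is the
#'   reference group for percent changes.
#' @param seed master seed.
#' @param out_dir optional output directory.
#' @param cohort optionally, an existing bundle from
#'   [generate_cohort()]; when supplied, `design`/`seed` describe it.
#' @param min_sv,max_sv synapse inclusion bounds.
#' @return An object of class `tauhcn_report`: list with `features`
#'   (named list of per-unit data.frames: `sepsc`, `passive`,
#'   `synapses`, `morpho`), `nn` (per-group summaries), `tests`,
#'   `effects` (percent changes), `design` and `seed`.
#' @export
run_pipeline <- function(design = cohort_design(), seed = 1,
                         out_dir = NULL, cohort = NULL,
                         min_sv = 10, max_sv = 250) {
  stopifnot(inherits(design, "cohort_design"))
  if (is.null(cohort)) cohort <- generate_cohort(design, seed = seed)

  sepsc_rows <- list(); passive_rows <- list(); syn_rows <- list()
  morpho_rows <- list(); nn_groups <- list()

  for (gname in names(cohort)) {
    grp <- cohort[[gname]]
    genotype <- sub("_.*$", "", gname)
    age <- sub("^.*_", "", gname)

    for (i in seq_along(grp$sepsc)) {
      res <- analyze_sepsc_trace(grp$sepsc[[i]]$trace)
      st <- res$stats
      sepsc_rows[[length(sepsc_rows) + 1L]] <- data.frame(
        group = gname, genotype = genotype, age = age, cell = i,
        frequency_Hz = st$frequency, amplitude_pA = st$amplitude,
        half_width_ms = st$half_width,
        rate_of_rise_pA_per_ms = st$rate_of_rise, n_events = st$n_events)
    }

    for (i in seq_along(grp$cc_traces)) {
      pf <- fit_passive_response(grp$cc_traces[[i]])
      passive_rows[[length(passive_rows) + 1L]] <- data.frame(
        group = gname, genotype = genotype, age = age, cell = i,
        R_in_MOhm = pf$R_in, tau_m_ms = pf$tau_m, sag_sub_pct = pf$sag_sub,
        sag_fit_pct = pf$sag_fit, rebound_mV = pf$rebound)
    }

    included <- filter_synapses(grp$maps, min_sv = min_sv, max_sv = max_sv)
    if (length(included) > 0) {
      sm <- do.call(rbind, lapply(included, synapse_metrics))
      sm <- cbind(data.frame(group = gname, genotype = genotype, age = age),
                  sm)
      syn_rows[[length(syn_rows) + 1L]] <- sm
      nn_groups[[gname]] <-
        group_nn_summary(lapply(included, nn_analysis))
    }

    for (i in seq_along(grp$morphologies)) {
      m <- grp$morphologies[[i]]
      bm <- branch_metrics(m)
      spm <- spine_metrics(m)
      morpho_rows[[length(morpho_rows) + 1L]] <- data.frame(
        group = gname, genotype = genotype, age = age, neuron = i,
        branch_points = bm$branch_points,
        mean_dendrite_length_um = bm$mean_dendrite_length,
        total_length_um = bm$total_length, soma_area_um2 = bm$soma_area,
        spine_density_per_um = spm$density,
        frac_stubby = spm$type_fractions[["stubby"]],
        frac_thin = spm$type_fractions[["thin"]],
        frac_mushroom = spm$type_fractions[["mushroom"]])
    }
  }

  features <- list(sepsc = do.call(rbind, sepsc_rows),
                   passive = do.call(rbind, passive_rows),
                   synapses = do.call(rbind, syn_rows),
                   morpho = do.call(rbind, morpho_rows))

  ref <- design$genotypes[1L]
  tests <- list(); effects <- list()
  if (length(design$genotypes) >= 2L) {
    cmp <- design$genotypes[2L]
    metric_sets <- list(
      sepsc = c("frequency_Hz", "amplitude_pA", "half_width_ms",
                "rate_of_rise_pA_per_ms"),
      passive = c("R_in_MOhm", "sag_sub_pct", "sag_fit_pct", "rebound_mV"),
      synapses = c("sv_count", "presyn_area_um2", "mean_sv_diameter_nm",
                   "docked_pct"),
      morpho = c("branch_points", "mean_dendrite_length_um",
                 "soma_area_um2", "spine_density_per_um"))
    for (tab in names(metric_sets)) {
      df <- features[[tab]]
      if (is.null(df)) next
      for (metric in metric_sets[[tab]]) {
        a <- df[[metric]][df$genotype == ref]
        b <- df[[metric]][df$genotype == cmp]
        if (sum(is.finite(a)) < 2L || sum(is.finite(b)) < 2L) next
        key <- paste(tab, metric, sep = ".")
        tests[[key]] <- group_t_test(a, b, label = key)
        effects[[key]] <- percent_change(mean(a[is.finite(a)]),
                                         mean(b[is.finite(b)]))
      }
    }
    if (length(nn_groups) >= 2L) {
      nn_means <- vapply(nn_groups, `[[`, numeric(1L), "group_mean_nn")
      effects[["nn.group_mean_nn_diff_nm"]] <-
        unname(nn_means[grep(paste0("^", cmp, "_"), names(nn_means))[1L]] -
                 nn_means[grep(paste0("^", ref, "_"), names(nn_means))[1L]])
    }
  }

  report <- structure(
    list(features = features, nn = nn_groups, tests = tests,
         effects = effects, design = design, seed = seed),
    class = "tauhcn_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (tab in names(features)) {
      if (is.null(features[[tab]])) next
      utils::write.table(features[[tab]],
                         file.path(out_dir, paste0(tab, "_features.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    for (gname in names(nn_groups)) {
      utils::write.table(nn_groups[[gname]]$mean_ecdf,
                         file.path(out_dir,
                                   paste0("nn_ecdf_", gname, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    test_df <- do.call(rbind, lapply(names(tests), function(k) {
      tst <- tests[[k]]
      data.frame(metric = k, t = tst$statistic, df = tst$df, p = tst$p,
                 stars = tst$stars,
                 mean_ref = tst$means[1L], sem_ref = tst$sems[1L],
                 mean_cmp = tst$means[2L], sem_cmp = tst$sems[2L])
    }))
    if (!is.null(test_df))
      utils::write.table(test_df, file.path(out_dir, "tests.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(effects_percent_change = effects,
           nn_group_means = lapply(nn_groups, `[[`, "group_mean_nn"),
           note = "no multiple-testing correction across metrics"),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(seed = seed, design = unclass(design),
           package_version = as.character(utils::packageVersion("tauhcn")),
           r_version = R.version.string),
      file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.tauhcn_report <- function(x, ...) {
  cat("<tauhcn_report>\n")
  for (tab in names(x$features))
    if (!is.null(x$features[[tab]]))
      cat(sprintf("  %s: %d rows\n", tab, nrow(x$features[[tab]])))
  if (length(x$effects) > 0) {
    cat("  headline effects (percent change vs reference):\n")
    for (k in names(x$effects))
      cat(sprintf("    %-32s %+.1f\n", k, x$effects[[k]]))
  }
  invisible(x)
}
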