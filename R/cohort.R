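#' Cohort design
#'
#' Describes the synthetic study design: named groups (genotype x age)
#' with the number of cells (patch-clamp recordings), synapses (vesicle
#' maps) and neurons (morphologies) per group.
#'
#' @param genotypes character vector of genotypes
#'   (subset of `c("WT", "Tau35")`).
#' @param age `"4mo"` or `"10mo"`.
#' @param n_cells,n_synapses,n_neurons per-group sample sizes.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(genotypes = c("WT", "Tau35"), age = "10mo",
                          n_cells = 20, n_synapses = 16, n_neurons = 50) {
  if (!all(genotypes %in% c("WT", "Tau35")))
    stop("unknown genotype preset: ",
         paste(setdiff(genotypes, c("WT", "Tau35")), collapse = ", "))
  if (!age %in% c("4mo", "10mo")) stop("unknown age preset: ", age)
  structure(list(genotypes = genotypes, age = age, n_cells = n_cells,
                 n_synapses = n_synapses, n_neurons = n_neurons),
            class = "cohort_design")
}

# deterministic per-item seeds derived from one master seed
derive_seed <- function(seed, stream, i) {
  (seed * 1009L + stream * 101L + i) %% .Machine$integer.max
}

#' Generate a full synthetic cohort
#'
#' For every group in the design, generates sEPSC recordings,
#' current-clamp step responses, vesicle maps and morphologies from the
#' genotype/age presets, each with ground truth attached. The bundle is
#' fully reproducible: the same seed yields identical objects (and
#' identical files when `out_dir` is given).
#'
#' @param design a [cohort_design()].
#' @param seed master integer seed; per-object seeds are derived from it.
#' @param out_dir optional directory; when given, all objects are also
#'   written to `out_dir/<group>/...` in the package's text formats,
#'   along with a `config.json`.
#' @return A named list of groups (`"WT_10mo"`, ...), each holding
#'   `sepsc` (lists from [generate_sepsc_trace()]), `cc_traces`
#'   (current-clamp [ephys_trace()]s), `maps` ([vesicle_map()]s) and
#'   `morphologies` ([neuron_morphology()]s).
#' @export
generate_cohort <- function(design = cohort_design(), seed = 1,
                            out_dir = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  out <- list()
  for (gi in seq_along(design$genotypes)) {
    g <- design$genotypes[gi]
    sp <- default_sepsc_preset(g)
    np <- default_neuron_params(g)
    vp <- default_vesicle_preset(g, design$age)
    mp <- default_morph_preset(g)
    base <- gi * 10L
    grp <- list(
      sepsc = lapply(seq_len(design$n_cells), function(i)
        generate_sepsc_trace(sp, seed = derive_seed(seed, base + 1L, i))),
      cc_traces = lapply(seq_len(design$n_cells), function(i)
        simulate_neuron(np, seed = derive_seed(seed, base + 2L, i))),
      maps = lapply(seq_len(design$n_synapses), function(i)
        generate_vesicle_map(vp, seed = derive_seed(seed, base + 3L, i),
                             synapse_id = sprintf("%s_syn%03d", g, i))),
      morphologies = lapply(seq_len(design$n_neurons), function(i)
        generate_morphology(mp, seed = derive_seed(seed, base + 4L, i)))
    )
    out[[paste(g, design$age, sep = "_")]] <- grp
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(c(unclass(design), list(seed = seed)),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    for (gname in names(out)) {
      gd <- file.path(out_dir, gname)
      for (sub in c("traces", "vesicles", "morphologies"))
        dir.create(file.path(gd, sub), recursive = TRUE,
                   showWarnings = FALSE)
      grp <- out[[gname]]
      for (i in seq_along(grp$sepsc))
        write_trace(grp$sepsc[[i]]$trace,
                    file.path(gd, "traces", sprintf("sepsc_%03d.csv", i)))
      for (i in seq_along(grp$cc_traces))
        write_trace(grp$cc_traces[[i]],
                    file.path(gd, "traces", sprintf("step_%03d.csv", i)))
      for (i in seq_along(grp$maps))
        write_vesicle_map(grp$maps[[i]],
                          file.path(gd, "vesicles",
                                    sprintf("syn_%03d.csv", i)))
      for (i in seq_along(grp$morphologies))
        write_morphology(grp$morphologies[[i]],
                         file.path(gd, "morphologies",
                                   sprintf("neuron_%03d.swc", i)))
    }
  }
  out
}
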