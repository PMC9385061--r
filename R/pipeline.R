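#' Run the full MET analysis pipeline
#'
#' Reads (or simulates) plot-level records and, for each trait, runs the
#' combined ANOVA, the AMMI stage (Gollob tests, stability table, top-k
#' selections, biplot coordinates) and the GGE stage (scores, sector
#' partition, AEA projections, environment diagnostics), writing one TSV
#' per output into `output_dir/<trait>/` plus a `manifest.tsv` listing
#' every file, the seed and the stage that produced it. Numeric output is
#' written at full double precision; rerunning with the same inputs gives
#' byte-identical files.
#'
#' @param input_path CSV of plot records, or `NULL` to simulate.
#' @param sim A [sim_config()] used when `input_path` is `NULL`.
#' @param traits Character vector of trait columns to analyse.
#' @param ammi_components Components to retain in AMMI (`"all"` or integer).
#' @param top_k Genotypes to select per environment (default 4).
#' @param svp_mode SVP mode for the GGE stage.
#' @param output_dir Directory for the report bundle.
#'
#' @return A tibble manifest (`trait`, `stage`, `file`), invisibly also
#'   written to `output_dir/manifest.tsv`.
#' @export
run_pipeline <- function(input_path = NULL, sim = NULL,
                         traits = "yield", ammi_components = "all",
                         top_k = 4, svp_mode = "environment",
                         output_dir) {
  if (is.null(input_path) == is.null(sim)) {
    stop("provide exactly one of input_path or sim", call. = FALSE)
  }
  if (length(traits) == 0) stop("traits must be non-empty", call. = FALSE)
  seed <- if (!is.null(sim)) sim$seed else NA_integer_
  records <- if (!is.null(input_path)) {
    read_met_csv(input_path, traits)
  } else {
    simulate_met(sim)$records
  }
  missing_traits <- setdiff(traits, names(records))
  if (length(missing_traits) > 0) {
    stop("unknown trait(s): ", paste(missing_traits, collapse = ", "),
         call. = FALSE)
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- purrr::map_dfr(traits, function(trait) {
    tdir <- file.path(output_dir, trait)
    dir.create(tdir, showWarnings = FALSE)
    emit <- function(stage, name, df) {
      path <- file.path(tdir, name)
      utils::write.table(df, path, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      tibble::tibble(trait = trait, stage = stage,
                     file = file.path(trait, name))
    }
    step <- function(stage, code) {
      tryCatch(code, error = function(e) {
        stop("stage '", stage, "' failed for trait '", trait, "': ",
             conditionMessage(e), call. = FALSE)
      })
    }

    av <- step("anova", combined_anova(records, trait))
    bart <- step("anova", bartlett_homogeneity(records, trait))
    tab <- step("ammi", cell_means(records, trait))
    fit <- step("ammi", fit_ammi(tab, ammi_components))
    ms_error <- av$ms[av$source == "Error"]
    df_error <- av$df[av$source == "Error"]
    gollob <- step("ammi", gollob_tests(fit, ms_error, df_error))
    stab <- step("ammi", stability_table(fit))
    topk <- step("ammi", top_k_per_environment(fit, top_k))
    gge <- step("gge", fit_gge(tab, svp_mode))
    ww <- step("gge", which_won_where(gge))
    aec <- step("gge", mean_vs_stability(gge))
    ideal <- step("gge", ideal_genotype_distance(gge))
    diag <- step("gge", discriminativeness_representativeness(gge))

    dplyr::bind_rows(
      emit("anova", "anova.tsv", as.data.frame(av)),
      emit("anova", "bartlett.tsv", bart),
      emit("ammi", "ammi_anova.tsv", gollob),
      emit("ammi", "stability.tsv", stab),
      emit("ammi", "top_k.tsv", topk),
      emit("ammi", "coords_ammi1.tsv", ammi_biplot_coords(fit, "AMMI1")),
      emit("ammi", "coords_ammi2.tsv", ammi_biplot_coords(fit, "AMMI2")),
      emit("gge", "gge_scores.tsv", tidy(gge)),
      emit("gge", "sectors.tsv",
           dplyr::left_join(ww$environments, ww$boundaries,
                            by = "sector", suffix = c("", "_boundary"))),
      emit("gge", "aec.tsv",
           dplyr::left_join(aec, ideal, by = "genotype")),
      emit("gge", "env_diag.tsv", diag)
    )
  })
  manifest$seed <- seed
  utils::write.table(manifest, file.path(output_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
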