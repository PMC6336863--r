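#' Configure a synthetic two-genotype cohort
#'
#' Bundles per-genotype generator profiles, cohort size, recording days and a
#' master seed for [run_pipeline()]. Each genotype entry is a named list with
#' any of `spikes` ([sim_profile()]), `calcium` ([calcium_profile()]),
#' `morphology` ([morphology_params()]), `puncta` ([puncta_params()]);
#' missing entries fall back to the defaults. Per-animal, per-day seeds are
#' derived deterministically from the master seed.
#'
#' @param genotypes Named list of genotype profile lists (default two
#'   identical genotypes `wt` and `het`).
#' @param n_animals Animals (wells) per genotype.
#' @param div_days Sorted integer days-in-vitro at which activity is
#'   recorded; serial recordings conventionally start at 8 DIV.
#' @param seed Master integer seed.
#' @param out_dir Optional output directory for CSV tables and the manifest.
#' @param lfp_duration_s,lfp_fs_hz Length and rate of the voltage synthesized
#'   for the LFP stage.
#' @param n_surrogates Surrogates for the calcium stage.
#' @param calcium_duration_s Calcium recording length (s).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(genotypes = list(wt = list(), het = list()),
                          n_animals = 6, div_days = c(8, 11, 14, 17, 21),
                          seed = 1, out_dir = NULL, lfp_duration_s = 60,
                          lfp_fs_hz = 2000, n_surrogates = 200,
                          calcium_duration_s = 300) {
  if (!length(genotypes) || is.null(names(genotypes)) ||
      any(!nzchar(names(genotypes)))) {
    abort("`genotypes` must be a named list.")
  }
  check_scalar(n_animals, "n_animals", min = 1, integer = TRUE)
  if (is.unsorted(div_days)) abort("`div_days` must be sorted.")
  check_scalar(seed, "seed", integer = TRUE)
  genotypes <- purrr::map(genotypes, function(g) {
    list(spikes = g$spikes %||% sim_profile(),
         calcium = g$calcium %||% calcium_profile(),
         morphology = g$morphology %||% morphology_params(),
         puncta = g$puncta %||% puncta_params())
  })
  structure(list(genotypes = genotypes, n_animals = as.integer(n_animals),
                 div_days = as.integer(div_days), seed = as.integer(seed),
                 out_dir = out_dir, lfp_duration_s = lfp_duration_s,
                 lfp_fs_hz = lfp_fs_hz, n_surrogates = n_surrogates,
                 calcium_duration_s = calcium_duration_s),
            class = "cohort_config")
}

# deterministic sub-seed, kept within 32-bit integer range
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  as.integer(strtoi(substr(rlang::hash(key), 1, 7), base = 16L))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Generates the cohort defined by a [cohort_config()] and pushes it through
#' the requested analysis stages: `mea` (spike-train simulation and network
#' activity metrics per animal and day), `lfp` (synthesized voltage, Welch
#' band powers and the day-over-day log10 power-ratio timecourse for the
#' 1-10 Hz and 100-150 Hz bands), `calcium` (correlated-firing ratio per
#' animal) and `morpho` (Sholl, outgrowth, soma area and synaptic-puncta
#' density per animal). A statistics table compares genotypes: pooled t per
#' per-animal endpoint and genotype x DIV two-way ANOVA for longitudinal
#' metrics. Activity metrics are computed on the simulated spike trains
#' directly; synthesized voltage is used by the LFP stage (spike detection
#' from voltage is validated separately).
#'
#' If a stage fails for one animal the error is recorded in the `errors`
#' element and the run continues.
#'
#' @param config A [cohort_config()].
#' @param stages Character subset of `c("mea", "lfp", "calcium", "morpho")`.
#' @return A list of class `pipeline_result` with tibbles `activity`,
#'   `band_power`, `calcium`, `morphology`, `stats`, plus `manifest` and
#'   `errors`. With `config$out_dir` set, tables are written as CSV and the
#'   manifest as JSON.
#' @export
run_pipeline <- function(config,
                         stages = c("mea", "lfp", "calcium", "morpho")) {
  stopifnot(inherits(config, "cohort_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  cfg_hashable <- unclass_deep(config)
  cfg_hashable$out_dir <- NULL   # output location must not change the run hash
  manifest <- list(config = cfg_hashable, stages = stages,
                   package_version = as.character(utils::packageVersion("neurocultr")))
  manifest$hash <- rlang::hash(manifest)
  manifest$out_dir <- config$out_dir
  errors <- list()
  note_error <- function(where, e) {
    errors[[length(errors) + 1L]] <<- list(where = where,
                                           message = conditionMessage(e))
  }
  acc_act <- list(); acc_band <- list(); acc_ca <- list(); acc_morph <- list()

  for (g in names(config$genotypes)) {
    prof <- config$genotypes[[g]]
    for (a in seq_len(config$n_animals)) {
      if ("mea" %in% stages || "lfp" %in% stages) {
        day_power <- list()
        for (d in config$div_days) {
          sd_mea <- derive_seed(config$seed, g, a, d, "mea")
          tryCatch({
            p <- prof$spikes; p$seed <- sd_mea
            sim <- simulate_spike_trains(p)
            if ("mea" %in% stages) {
              acc_act[[length(acc_act) + 1L]] <- dplyr::bind_cols(
                tibble::tibble(genotype = g, animal_id = a, div_day = d),
                activity_summary(sim$spikes))
            }
            if ("lfp" %in% stages) {
              pl <- prof$spikes
              pl$seed <- derive_seed(config$seed, g, a, d, "lfpsim")
              pl$duration_s <- config$lfp_duration_s
              sim_l <- simulate_spike_trains(pl)
              raw <- synthesize_raw(
                sim_l$spikes, fs_hz = config$lfp_fs_hz, spike_amp_sigma = 8,
                oscillations = data.frame(freq_hz = c(4, 120),
                                          amp_uV = c(6, 1.5)),
                noise_sd_uV = 5, one_over_f_exponent = 1,
                div_day = d, well_id = paste0(g, a),
                seed = derive_seed(config$seed, g, a, d, "raw"))
              pw <- vapply(seq_len(nrow(raw$voltage_uV)), function(el) {
                lfp <- extract_lfp(raw, electrode = el)
                psd <- compute_psd(lfp, segment_s = 2)
                c(band_power(psd, 1, 10), band_power(psd, 100, 150))
              }, double(2))
              day_power[[length(day_power) + 1L]] <- tibble::tibble(
                genotype = g, animal_id = a, div_day = d,
                band = c("1-10 Hz", "100-150 Hz"),
                band_lo_hz = c(1, 100), band_hi_hz = c(10, 150),
                power_uV2 = rowMeans(pw))
            }
          }, error = function(e) note_error(sprintf("%s/animal %d/div %d", g, a, d), e))
        }
        if ("lfp" %in% stages && length(day_power)) {
          dp <- dplyr::bind_rows(day_power)
          acc_band[[length(acc_band) + 1L]] <- dplyr::group_modify(
            dplyr::group_by(dp, .data$genotype, .data$animal_id, .data$band,
                            .data$band_lo_hz, .data$band_hi_hz),
            function(df, key) {
              df <- dplyr::arrange(df, .data$div_day)
              dplyr::mutate(df, log10_ratio =
                              log10(.data$power_uV2 / .data$power_uV2[1]))
            }) |> dplyr::ungroup()
        }
      }
      if ("calcium" %in% stages) {
        tryCatch({
          pc <- prof$calcium
          pc$seed <- derive_seed(config$seed, g, a, "ca")
          sim <- simulate_calcium(pc, duration_s = config$calcium_duration_s,
                                  private_event_rate_per_min = 1)
          dff <- delta_f_over_f(sim$F, sim$fs_hz)
          res <- correlated_firing_ratio(
            dff, sim$fs_hz, n_surrogates = config$n_surrogates,
            seed = derive_seed(config$seed, g, a, "casurr"))
          acc_ca[[length(acc_ca) + 1L]] <- dplyr::bind_cols(
            tibble::tibble(genotype = g, animal_id = a), glance(res))
        }, error = function(e) note_error(sprintf("%s/animal %d/calcium", g, a), e))
      }
      if ("morpho" %in% stages) {
        tryCatch({
          pm <- prof$morphology
          pm$seed <- derive_seed(config$seed, g, a, "morph")
          m <- generate_morphology(pm)
          sh <- sholl_profile(m)
          pp <- prof$puncta
          pp$seed <- derive_seed(config$seed, g, a, "puncta")
          fld <- generate_puncta(pp)
          col <- colocalize_and_density(fld$pre, fld$post,
                                        fld$neurite_length_um)
          acc_morph[[length(acc_morph) + 1L]] <- dplyr::bind_cols(
            tibble::tibble(genotype = g, animal_id = a),
            morpho_summary(m),
            tibble::tibble(sholl_sum = sum(sh$intersections),
                           sholl_max = max(sh$intersections)),
            col[c("n_pairs", "density_per_50um")])
        }, error = function(e) note_error(sprintf("%s/animal %d/morpho", g, a), e))
      }
    }
  }

  activity <- dplyr::bind_rows(acc_act)
  band <- dplyr::bind_rows(acc_band)
  calcium <- dplyr::bind_rows(acc_ca)
  morphology <- dplyr::bind_rows(acc_morph)
  stats_tab <- pipeline_stats(activity, band, calcium, morphology,
                              names(config$genotypes))

  res <- structure(list(activity = activity, band_power = band,
                        calcium = calcium, morphology = morphology,
                        stats = stats_tab, manifest = manifest,
                        errors = errors),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(res, config$out_dir)
  res
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

# genotype comparisons across per-animal endpoints
pipeline_stats <- function(activity, band, calcium, morphology, genos) {
  if (length(genos) != 2) return(tibble::tibble())
  rows <- list()
  add_t <- function(endpoint, df, value_col) {
    v1 <- df[[value_col]][df$genotype == genos[1]]
    v2 <- df[[value_col]][df$genotype == genos[2]]
    if (length(v1) >= 2 && length(v2) >= 2 && (sd(v1) > 0 || sd(v2) > 0)) {
      tt <- pooled_t(v1, v2)
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        endpoint = endpoint, test = "pooled t", statistic = tt$statistic,
        df = tt$df, p.value = tt$p.value)
    }
  }
  add_anova <- function(endpoint, df, value_col) {
    ok <- is.finite(df[[value_col]])
    df <- df[ok, ]
    if (dplyr::n_distinct(df$genotype) == 2 &&
        dplyr::n_distinct(df$div_day) >= 2 && stats::sd(df[[value_col]]) > 0) {
      an <- two_way_anova(df, value_col, "genotype", "div_day")
      tab <- an$table[an$table$term == "genotype", ]
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        endpoint = endpoint, test = "2-way ANOVA (genotype)",
        statistic = tab$statistic, df = tab$df, p.value = tab$p.value)
    }
  }
  if (nrow(activity)) {
    per_animal <- dplyr::summarise(
      dplyr::group_by(activity, .data$genotype, .data$animal_id),
      wmfr_hz = mean(.data$wmfr_hz),
      synchrony_index = mean(.data$synchrony_index),
      burst_freq_per_min = mean(.data$burst_freq_per_min), .groups = "drop")
    for (ep in c("wmfr_hz", "synchrony_index", "burst_freq_per_min")) {
      add_t(ep, per_animal, ep)
      add_anova(ep, activity, ep)
    }
  }
  if (nrow(band)) {
    for (b in unique(band$band)) {
      sub <- band[band$band == b & band$log10_ratio != 0, ]
      add_anova(paste0("log10_ratio ", b),
                dplyr::rename(sub, value = "log10_ratio"), "value")
    }
  }
  if (nrow(calcium)) add_t("correlated_firing_ratio", calcium,
                           "correlated_firing_ratio")
  if (nrow(morphology)) {
    for (ep in c("total_outgrowth_um", "soma_area_um2", "sholl_sum",
                 "density_per_50um")) {
      add_t(ep, morphology, ep)
    }
  }
  dplyr::bind_rows(rows)
}

write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("activity", "band_power", "calcium", "morphology", "stats")) {
    df <- res[[nm]]
    if (nrow(df)) {
      df$manifest_hash <- res$manifest$hash
      utils::write.csv(df, file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(sprintf("run hash: %s", res$manifest$hash),
               sprintf("errors: %d", length(res$errors)),
               vapply(res$errors, function(e)
                 sprintf("  %s: %s", e$where, e$message), character(1))),
             file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Recompute published two-group statistics from summary values
#'
#' Runs [pooled_t()] in summary mode on each row of a table of published
#' group summary statistics (mean, SEM, n per group, plus the printed t
#' value) and reports the recomputed statistic next to the printed one with
#' the relative deviation of the magnitudes. The bundled fixture covers the
#' morphology, synapse-density and behavioral endpoints of the Setd5
#' haploinsufficiency study conditions this package models. Residual
#' deviations stem from rounding of the published SEMs.
#'
#' @param fixture Data frame with columns `assay`, `mean1`, `sem1`, `n1`,
#'   `mean2`, `sem2`, `n2`, `printed_t` (and optional labels), or a CSV path;
#'   default is the bundled table.
#' @return Tibble: `assay`, `printed_t`, `recomputed_t`, `rel_deviation`,
#'   `df`, `p.value`. Malformed rows are reported with a warning and skipped.
#' @export
#' @examples
#' recompute_published_stats()
recompute_published_stats <- function(fixture = NULL) {
  if (is.null(fixture)) {
    fixture <- system.file("extdata", "published_group_stats.csv",
                           package = "neurocultr", mustWork = TRUE)
  }
  if (is.character(fixture)) fixture <- utils::read.csv(fixture)
  fixture <- tibble::as_tibble(fixture)
  purrr::map_dfr(seq_len(nrow(fixture)), function(i) {
    row <- fixture[i, ]
    tryCatch({
      tt <- pooled_t(group_summary(row$mean1, row$sem1, row$n1),
                     group_summary(row$mean2, row$sem2, row$n2))
      tibble::tibble(assay = row$assay, printed_t = row$printed_t,
                     recomputed_t = abs(tt$statistic),
                     rel_deviation = abs(abs(tt$statistic) - row$printed_t) /
                       row$printed_t,
                     df = tt$df, p.value = tt$p.value)
    }, error = function(e) {
      warn(sprintf("row %d (%s) skipped: %s", i,
                   row$assay %||% "?", conditionMessage(e)))
      tibble::tibble()
    })
  })
}
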