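#' Configuration of a full scenario-grid run
#'
#' @param variants Names of natural-history variants to run.
#' @param grid A [grid_config()].
#' @param engine `"cohort"` (deterministic solver, the default for property
#'   sweeps), `"microsim"`, or `"both"`.
#' @param n_per_cell Women per cell for the Monte Carlo engine.
#' @param seed Master seed.
#' @param vaccination_coverage Named coverage overrides per birth year
#'   (`NULL` keeps [make_vaccination_profile()] defaults).
#' @param out_dir Output directory for [run()] (created if missing).
#' @return A list of class `run_config`.
#' @export
run_config <- function(variants = names(builtin_variants()),
                       grid = grid_config(),
                       engine = c("cohort", "microsim", "both"),
                       n_per_cell = 2e5,
                       seed = 1L,
                       vaccination_coverage = NULL,
                       out_dir = NULL) {
  engine <- match.arg(engine)
  stopifnot(n_per_cell >= 1, length(variants) >= 1)
  structure(
    list(variants = variants, grid = grid, engine = engine,
         n_per_cell = as.integer(n_per_cell), seed = as.integer(seed),
         vaccination_coverage = vaccination_coverage, out_dir = out_dir),
    class = "run_config"
  )
}

cell_vaccination <- function(birth_year, config) {
  cov <- config$vaccination_coverage[[as.character(birth_year)]]
  make_vaccination_profile(birth_year, coverage = cov)
}

run_one_cell <- function(cell, params, demography, vaccination, config) {
  schedule <- schedule_for_cell(cell, config$grid$policy)
  window <- delay_window_months(schedule)
  rows <- list()
  if (config$engine %in% c("cohort", "both")) {
    sol <- cohort_solve(schedule, params, demography, vaccination)
    rows$cohort <- tibble::tibble(
      engine = "cohort",
      lifetime_risk = lifetime_risk(sol),
      lifetime_risk_se = 0,
      sympt_rate_window = symptomatic_rate_in_window(sol),
      n_simulated = NA_integer_
    )
  }
  if (config$engine %in% c("microsim", "both")) {
    sim <- simulate_cohort(schedule, params, demography, vaccination,
                           n = config$n_per_cell, seed = config$seed)
    rows$microsim <- tibble::tibble(
      engine = "microsim",
      lifetime_risk = lifetime_risk(sim),
      lifetime_risk_se = lifetime_risk_se(sim),
      sympt_rate_window = symptomatic_rate_in_window(sim),
      n_simulated = config$n_per_cell
    )
  }
  dplyr::bind_cols(
    dplyr::bind_rows(
      lapply(rows, function(r) dplyr::bind_cols(cell[rep(1, 1), ], r))
    )
  )
}

#' Execute every cell of the scenario grid
#'
#' Runs the configured engine(s) over the full cohort x frequency x modality x
#' delay cross-product plus the per-cohort no-screening references, for every
#' requested natural-history variant.
#'
#' @param config A [run_config()].
#' @param params_list Optional named list of `nh_params` (defaults to
#'   [make_variant()] for each configured variant name).
#' @param demography A [make_demography()] tibble.
#' @return A tibble with one row per cell x engine: scenario identifiers,
#'   lifetime risk (percent), symptomatic cancer rate in the delay window
#'   (per 100,000), and Monte Carlo metadata. Cells that fail are skipped and
#'   reported in the `failed_cells` attribute.
#' @export
run_scenarios <- function(config = run_config(), params_list = NULL,
                          demography = make_demography()) {
  if (is.null(params_list)) {
    params_list <- stats::setNames(
      lapply(config$variants, function(v) make_variant(v, seed = config$seed,
                                                       demography = demography)),
      config$variants
    )
  }
  grid <- build_grid(config$grid)
  failed <- character()
  out <- purrr::map_dfr(config$variants, function(v) {
    params <- params_list[[v]]
    purrr::map_dfr(seq_len(nrow(grid)), function(i) {
      cell <- grid[i, ]
      vac <- cell_vaccination(cell$birth_year, config)
      res <- tryCatch(
        run_one_cell(cell, params, demography, vac, config),
        error = function(e) {
          failed <<- c(failed, paste0(v, "/", cell$cell_id, ": ", conditionMessage(e)))
          NULL
        }
      )
      if (is.null(res)) return(NULL)
      dplyr::bind_cols(tibble::tibble(variant = v), res)
    })
  })
  attr(out, "failed_cells") <- failed
  attr(out, "config") <- config
  out
}

#' Cohort-averaged outcome table for a scenario run
#'
#' Averages every projection over the three birth cohorts (unweighted, as the
#' analysis defines) and derives the scenario statistics: the short-term rate
#' ratio of symptomatic cancer in the delay window against the same-delay
#' guidelines-compliant comparator (3-yearly for cytology, 5-yearly for
#' primary HPV), the incremental lifetime risk and excess cases per 100,000
#' against the same cell with no delay, and the percent of cancers prevented
#' against the no-screening reference.
#'
#' @param outcomes A [run_scenarios()] tibble.
#' @return A tibble keyed by variant x engine x frequency x modality x delay.
#' @export
summarize_outcomes <- function(outcomes) {
  keys <- c("variant", "engine", "frequency_years", "modality", "delay_years")
  screened <- dplyr::filter(outcomes, .data$screening)
  lr <- average_over_cohorts(
    dplyr::select(screened, dplyr::all_of(c(keys, "birth_year", "lifetime_risk"))),
    lifetime_risk
  )
  rate <- average_over_cohorts(
    dplyr::select(screened, dplyr::all_of(c(keys, "birth_year", "sympt_rate_window"))),
    sympt_rate_window
  )
  noscreen <- outcomes |>
    dplyr::filter(!.data$screening) |>
    dplyr::select("variant", "engine", "birth_year", "lifetime_risk") |>
    average_over_cohorts(lifetime_risk) |>
    dplyr::rename(lifetime_risk_noscreen = "lifetime_risk")

  tab <- dplyr::left_join(lr, rate, by = keys)

  comparator <- tab |>
    dplyr::filter(
      (.data$modality == "CYTOLOGY" & .data$frequency_years == 3) |
        (.data$modality == "HPV_PRIMARY" & .data$frequency_years == 5)
    ) |>
    dplyr::select(dplyr::all_of(setdiff(keys, "frequency_years")),
                  comparator_rate = "sympt_rate_window")
  nodelay <- tab |>
    dplyr::filter(.data$delay_years == 0) |>
    dplyr::select(dplyr::all_of(setdiff(keys, "delay_years")),
                  lifetime_risk_nodelay = "lifetime_risk")

  tab |>
    dplyr::left_join(comparator, by = setdiff(keys, "frequency_years")) |>
    dplyr::left_join(nodelay, by = setdiff(keys, "delay_years")) |>
    dplyr::left_join(noscreen, by = c("variant", "engine")) |>
    dplyr::mutate(
      rate_ratio_vs_compliant = ifelse(
        .data$delay_years == 0, NA_real_,
        short_term_rate_ratio(.data$sympt_rate_window, .data$comparator_rate)
      ),
      incremental_lifetime_risk = .data$lifetime_risk - .data$lifetime_risk_nodelay,
      excess_cases_per_100k = .data$incremental_lifetime_risk * 1000,
      percent_prevented = percent_prevented(.data$lifetime_risk,
                                            .data$lifetime_risk_noscreen)
    )
}

round_risk <- function(x) round(x, 3) # reporting convention: nearest 0.001%

#' Long-term impact table (5-year delay versus none, by screening frequency)
#'
#' @param summary A [summarize_outcomes()] tibble.
#' @param delay Delay arm to report (years).
#' @return One row per variant x modality x measure with one column per
#'   screening frequency; risks rounded to the nearest 0.001 percent and
#'   excess cases to whole cases per 100,000.
#' @export
summarize_table1 <- function(summary, delay = 5) {
  base <- summary |>
    dplyr::filter(.data$delay_years == delay) |>
    dplyr::mutate(
      `Absolute change in lifetime risk (pp)` = round_risk(.data$incremental_lifetime_risk),
      `Excess cases per 100,000` = round(.data$excess_cases_per_100k)
    ) |>
    dplyr::select("variant", "engine", "modality", "frequency_years",
                  dplyr::starts_with("Absolute"), dplyr::starts_with("Excess"))
  base |>
    tidyr::pivot_longer(cols = c(dplyr::starts_with("Absolute"), dplyr::starts_with("Excess")),
                        names_to = "measure", values_to = "value") |>
    tidyr::pivot_wider(names_from = "frequency_years", values_from = "value",
                       names_prefix = "freq_") |>
    dplyr::arrange(.data$modality, .data$variant, .data$measure)
}

#' Short-term rate-ratio table (delay x years-since-last-screen)
#'
#' @param summary A [summarize_outcomes()] tibble.
#' @return RR of symptomatic cancer during the delay window versus the
#'   same-delay guidelines-compliant comparator; no rows for the zero-delay
#'   arm, for which the window rate is not defined.
#' @export
summarize_rate_ratios <- function(summary) {
  summary |>
    dplyr::filter(.data$delay_years > 0) |>
    dplyr::select("variant", "engine", "modality", "delay_years",
                  "frequency_years", "sympt_rate_window",
                  "rate_ratio_vs_compliant") |>
    dplyr::arrange(.data$modality, .data$variant, .data$delay_years,
                   .data$frequency_years)
}

#' Run the full experiment and write a result bundle
#'
#' Executes [run_scenarios()], derives the cohort-averaged outcome table, and
#' writes `outcomes.csv` (per cell), `summary.csv`, `table1.csv`,
#' `rate_ratios.csv`, and `manifest.json` (seed, versions, parameter hashes)
#' to `config$out_dir`. Reruns with the same configuration and seed produce
#' byte-identical files.
#'
#' @param config A [run_config()] with `out_dir` set.
#' @param params_list,demography Passed to [run_scenarios()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the outcome tables and file paths.
#' @export
run <- function(config = run_config(), params_list = NULL,
                demography = make_demography(), quiet = FALSE) {
  stopifnot(!is.null(config$out_dir))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  if (is.null(params_list)) {
    say("generating parameter sets: ", paste(config$variants, collapse = ", "))
    params_list <- stats::setNames(
      lapply(config$variants, function(v) make_variant(v, seed = config$seed,
                                                       demography = demography)),
      config$variants
    )
  }
  say("running ", config$engine, " engine over the scenario grid")
  outcomes <- run_scenarios(config, params_list, demography)
  failed <- attr(outcomes, "failed_cells")
  summary <- summarize_outcomes(outcomes)

  paths <- list(
    outcomes = file.path(config$out_dir, "outcomes.csv"),
    summary = file.path(config$out_dir, "summary.csv"),
    table1 = file.path(config$out_dir, "table1.csv"),
    rate_ratios = file.path(config$out_dir, "rate_ratios.csv"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  utils::write.csv(as.data.frame(outcomes), paths$outcomes, row.names = FALSE)
  utils::write.csv(as.data.frame(summary), paths$summary, row.names = FALSE)
  utils::write.csv(as.data.frame(summarize_table1(summary)), paths$table1,
                   row.names = FALSE)
  utils::write.csv(as.data.frame(summarize_rate_ratios(summary)),
                   paths$rate_ratios, row.names = FALSE)
  manifest <- list(
    seed = config$seed,
    engine = config$engine,
    n_per_cell = config$n_per_cell,
    package_version = as.character(utils::packageVersion("screendelay")),
    parameter_hashes = lapply(params_list, rlang::hash),
    demography_hash = rlang::hash(demography),
    n_cells = nrow(build_grid(config$grid)),
    failed_cells = as.list(failed)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  if (length(failed) > 0) {
    warning("some cells failed and were skipped: ",
            paste(failed, collapse = "; "), call. = FALSE)
  }
  say("wrote ", length(paths), " files to ", config$out_dir)
  invisible(list(outcomes = outcomes, summary = summary, paths = paths,
                 failed_cells = failed))
}
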