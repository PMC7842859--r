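#' Experiment configuration
#'
#' Experiments are driven by a YAML (or JSON) config with keys `profiles`
#' (`"default_mshs"` or a list of site entries), `schema` (`"default"` or a
#' feature list), `outcome_model` (`"default"` or
#' `{base_intercept, coefficients}`), `families`, `strategies`, `balancing`,
#' `train`, `federation`, `bootstrap` and the master `seed`. Every omitted
#' key falls back to [default_experiment_config()]. Configs are validated
#' against the schema shipped at
#' `system.file("extdata/config-schema.json", package = "fedcohort")`
#' before any computation runs.
#'
#' @return `default_experiment_config()`: the default config list.
#' @export
default_experiment_config <- function() {
  list(
    profiles = "default_mshs",
    schema = "default",
    outcome_model = "default",
    families = c("lasso", "mlp"),
    strategies = c("local", "pooled", "federated"),
    balancing = "oversample_minority",
    train = list(learning_rate = 1e-3, batch_size = 32, l1_lambda = 1e-3,
                 optimizer = "adam"),
    federation = list(rounds = NULL, local_epochs = 1, noise_sigma = 0),
    bootstrap = list(n_iterations = 50, test_fraction = 0.30),
    seed = 1
  )
}

#' @rdname default_experiment_config
#' @param path Path to a YAML or JSON config file.
#' @return `read_experiment_config()`: the validated config list with
#'   defaults filled in.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such config file: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort("config must be a YAML/JSON mapping")
  cfg <- modifyList(default_experiment_config(), cfg)
  validate_experiment_config(cfg)
  cfg
}

#' @rdname default_experiment_config
#' @param config A config list.
#' @return `validate_experiment_config()`: the config, invisibly; invalid
#'   configs raise an error naming the offending key.
#' @export
validate_experiment_config <- function(config) {
  schema_path <- system.file("extdata", "config-schema.json",
                             package = "fedcohort")
  schema <- jsonlite::fromJSON(schema_path, simplifyVector = FALSE)
  for (key in schema$required) {
    if (is.null(config[[key]])) abort(sprintf("config error: missing required key `%s`", key))
  }
  check_node <- function(value, spec, where) {
    if (is.null(value)) return(invisible())
    types <- unlist(spec$type)
    r_type <- if (is.null(value)) {
      "null"
    } else if (is.character(value)) {
      "string"
    } else if (is.numeric(value)) {
      "number"
    } else if (!is.null(names(value)) || (is.list(value) && !is.null(spec$properties))) {
      "object"
    } else if (is.list(value) || length(value) > 1) {
      "array"
    } else {
      "other"
    }
    # scalar character/number may also satisfy a declared array type
    ok <- r_type %in% types ||
      ("array" %in% types && r_type %in% c("string", "number")) ||
      ("number" %in% types && r_type == "array" && is.numeric(unlist(value)))
    if (!ok) {
      abort(sprintf("config error: `%s` has type %s, expected %s",
                    where, r_type, paste(types, collapse = "/")))
    }
    vals <- unlist(value)
    if (!is.null(spec$enum) && !all(vals %in% unlist(spec$enum))) {
      abort(sprintf("config error: `%s` must be one of %s", where,
                    paste(unlist(spec$enum), collapse = ", ")))
    }
    if (!is.null(spec$item_enum) && !all(vals %in% unlist(spec$item_enum))) {
      abort(sprintf("config error: `%s` entries must be among %s", where,
                    paste(unlist(spec$item_enum), collapse = ", ")))
    }
    if (is.numeric(vals)) {
      if (!is.null(spec$minimum) && any(vals < spec$minimum)) {
        abort(sprintf("config error: `%s` must be >= %s", where, spec$minimum))
      }
      if (!is.null(spec$exclusiveMinimum) && any(vals <= spec$exclusiveMinimum)) {
        abort(sprintf("config error: `%s` must be > %s", where, spec$exclusiveMinimum))
      }
      if (!is.null(spec$exclusiveMaximum) && any(vals >= spec$exclusiveMaximum)) {
        abort(sprintf("config error: `%s` must be < %s", where, spec$exclusiveMaximum))
      }
    }
    if (!is.null(spec$properties) && is.list(value)) {
      for (k in names(spec$properties)) {
        check_node(value[[k]], spec$properties[[k]], paste(where, k, sep = "."))
      }
    }
    invisible()
  }
  for (k in names(schema$properties)) {
    check_node(config[[k]], schema$properties[[k]], k)
  }
  invisible(config)
}

# Materialize profiles/schema/outcome model from a config.
config_components <- function(config) {
  schema <- if (identical(config$schema, "default")) {
    default_schema()
  } else {
    feature_schema(dplyr::bind_rows(lapply(config$schema, function(f) {
      tibble(name = f$name, kind = f$kind,
             levels = list(unlist(f$levels)), units = f$units %||% NA_character_)
    })))
  }
  profiles <- if (identical(config$profiles, "default_mshs")) {
    default_mshs_profiles()
  } else {
    dplyr::bind_rows(lapply(config$profiles, function(p) {
      site_profile(
        site = p$site, n = p$n, target_prevalence = p$target_prevalence,
        gender_p_male = p$gender_p_male,
        age_median = p$age_median, age_q1 = p$age_q1, age_q3 = p$age_q3,
        category_probs = lapply(p$category_probs, unlist),
        comorbidity_prevalences = unlist(p$comorbidity_prevalences),
        continuous_params = dplyr::bind_rows(lapply(p$continuous_params,
                                                    as_tibble))
      )
    }))
  }
  model <- if (identical(config$outcome_model, "default")) {
    default_outcome_model(schema)
  } else {
    beta <- setNames(rep(0, length(encoded_columns(schema))),
                     encoded_columns(schema))
    user <- unlist(config$outcome_model$coefficients)
    beta[names(user)] <- user
    outcome_model(beta,
                  base_intercept = config$outcome_model$base_intercept %||% -2)
  }
  list(schema = schema, profiles = profiles, model = model)
}

config_train_cfg <- function(config) {
  tr <- config$train
  train_config(learning_rate = tr$learning_rate, batch_size = tr$batch_size,
               l1_lambda = tr$l1_lambda, optimizer = tr$optimizer)
}

config_fed_cfg <- function(config, family, seed) {
  fd <- config$federation
  federation_config(rounds = fd$rounds %||% default_rounds(family),
                    local_epochs = fd$local_epochs,
                    noise_sigma = fd$noise_sigma, seed = seed)
}

write_manifest <- function(out_dir, config, extra = list()) {
  manifest <- c(list(
    package = "fedcohort",
    version = as.character(utils::packageVersion("fedcohort")),
    config = config,
    config_hash = rlang::hash(config)
  ), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
}

#' Simulate cohorts to disk
#'
#' Generates the configured multi-hospital system and writes one cohort CSV
#' per site plus a `manifest.json` recording the master seed, per-site
#' seeds, row counts and a config hash — enough to reproduce the run from
#' the manifest alone.
#'
#' @param config A config list (see [read_experiment_config()]).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the paths of the written cohort files.
#' @export
cmd_simulate <- function(config = default_experiment_config(), out_dir) {
  validate_experiment_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  comp <- config_components(config)
  cohorts <- generate_system(comp$profiles, comp$schema, comp$model,
                             seed = config$seed)
  paths <- vapply(names(cohorts), function(site) {
    path <- file.path(out_dir, sprintf("cohort_%s.csv", site))
    write_cohort_csv(cohorts[[site]], path)
    path
  }, character(1))
  write_manifest(out_dir, config, list(
    master_seed = config$seed,
    site_seeds = setNames(as.list(config$seed + seq_along(cohorts)),
                          names(cohorts)),
    rows = setNames(lapply(cohorts, nrow), names(cohorts)),
    total_rows = sum(vapply(cohorts, nrow, integer(1)))
  ))
  invisible(paths)
}

#' Interhospital comparison table from cohort files
#'
#' Reads the given cohort CSVs, builds the sites-by-characteristics
#' comparison and writes it as CSV and Markdown.
#'
#' @param paths Character vector of cohort CSV paths.
#' @param out_dir Output directory.
#' @param schema Schema the files conform to (default [default_schema()]).
#' @return Invisibly, the `fc_comparison` object.
#' @export
cmd_cohort_table <- function(paths, out_dir, schema = default_schema()) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(sprintf("missing cohort file(s): %s", paste(missing, collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohorts <- lapply(paths, read_cohort_csv, schema = schema)
  comparison <- build_comparison_table(cohorts)
  write_comparison_csv(comparison, file.path(out_dir, "comparison_table.csv"))
  write_comparison_markdown(comparison, file.path(out_dir, "comparison_table.md"))
  invisible(comparison)
}

#' Run the full strategy-comparison experiment
#'
#' Generates (or accepts) the multi-hospital system, runs every configured
#' model family through every configured strategy under the bootstrap
#' protocol, and writes: the long per-iteration results
#' (`results_long.csv`), the per-site summary (`results_summary.csv`), the
#' rendered strategy table (`strategy_table.csv`/`.md`), federated learning
#' curves (`learning_curves.csv`, from one representative federated run
#' evaluated on a held-out split of the master seed), and a manifest with
#' every seed used.
#'
#' @param config A config list.
#' @param out_dir Output directory.
#' @param cohorts Optional pre-built named list of cohorts; generated from
#'   the config when omitted.
#' @return Invisibly, the list of `fc_experiment` objects keyed
#'   `family.strategy`.
#' @export
cmd_experiment <- function(config = default_experiment_config(), out_dir,
                           cohorts = NULL) {
  validate_experiment_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cohorts)) {
    comp <- config_components(config)
    cohorts <- generate_system(comp$profiles, comp$schema, comp$model,
                               seed = config$seed)
  }
  train_cfg <- config_train_cfg(config)
  boot_cfg <- bootstrap_config(
    n_iterations = config$bootstrap$n_iterations,
    test_fraction = config$bootstrap$test_fraction,
    master_seed = config$seed
  )
  grid <- expand.grid(family = config$families, strategy = config$strategies,
                      stringsAsFactors = FALSE)
  experiments <- lapply(seq_len(nrow(grid)), function(i) {
    family <- grid$family[i]; strategy <- grid$strategy[i]
    run_bootstrap(
      cohorts, family = family, strategy = strategy, train_cfg = train_cfg,
      fed_cfg = config_fed_cfg(config, family, seed = config$seed),
      boot_cfg = boot_cfg, balancing = config$balancing
    )
  })
  names(experiments) <- paste(grid$family, grid$strategy, sep = ".")

  samples <- purrr::list_rbind(lapply(experiments, function(e) e$samples))
  readr::write_csv(samples, file.path(out_dir, "results_long.csv"))
  summary <- purrr::list_rbind(lapply(experiments, function(e) e$summary))
  readr::write_csv(summary, file.path(out_dir, "results_summary.csv"))
  st <- strategy_table(experiments)
  readr::write_csv(st, file.path(out_dir, "strategy_table.csv"))
  writeLines(c(
    paste0("| ", paste(names(st), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(st)), collapse = "|"), "|"),
    apply(st, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  ), file.path(out_dir, "strategy_table.md"))

  if ("federated" %in% config$strategies) {
    curves <- purrr::list_rbind(lapply(config$families, function(family) {
      prep <- lapply(cohorts, function(ch) {
        dm <- encode_cohort(ch)
        prepare_site_iteration(dm, boot_cfg, config$seed + 1,
                               config$balancing, config$seed + 1)
      })
      fit <- run_federated(
        lapply(prep, function(p) p$train), family, train_cfg,
        config_fed_cfg(config, family, seed = config$seed + 7),
        eval_sites = lapply(prep, function(p) p$test)
      )
      mutate(learning_curves(fit$log), family = family, .before = 1)
    }))
    readr::write_csv(curves, file.path(out_dir, "learning_curves.csv"))
  }

  write_manifest(out_dir, config, list(
    master_seed = config$seed,
    iteration_seeds = sprintf("master_seed + b for b in 1..%d",
                              boot_cfg$n_iterations),
    grid = grid
  ))
  invisible(experiments)
}
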