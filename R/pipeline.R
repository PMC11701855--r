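#' Experiment configuration
#'
#' One nested configuration drives a full run: synthetic dataset, ensemble
#' construction (with freely composable method flags: decorrelation,
#' Fourier partitioning, adversarial training, DVERGE), the attack grid,
#' and the evaluation settings. Every random draw in a run derives from the
#' single global `seed`.
#'
#' @param dataset List: `n_per_class`, `frac_train`, plus any
#'   [ecg_generator_config()] arguments (`sampling_rate`, `duration`,
#'   `n_channels`, `band_split`, ...).
#' @param ensemble List: `k` members, `epochs`, `batch_size`,
#'   `learning_rate`, `feature_dim`, method flags `decorrelation`,
#'   `partition`, `adversarial`, `dverge`, and their parameters
#'   (`lambda`, `r`, `eps`, `band_edges_hz`, `rolloff_hz`,
#'   `harden_epsilon`, `harden_inner_steps`, `harden_budget_epochs`).
#' @param attack List: `methods` (subset of `"pgd"`, `"sap"`), `epsilons`,
#'   `steps`, `mode`, kernel bank `widths`/`sigmas`.
#' @param evaluation List: `n_grid` threshold-grid size, `mixed_fractions`
#'   (named by epsilon), `deferral_grid` size.
#' @param seed Global integer seed.
#' @return An object of class `experiment_config` (a validated nested
#'   list).
#' @export
experiment_config <- function(dataset = list(), ensemble = list(),
                              attack = list(), evaluation = list(),
                              seed = 1L) {
  defaults <- list(
    dataset = list(n_per_class = 250L, frac_train = 0.9, sampling_rate = 100,
                   duration = 10, n_channels = 1L, band_split = NULL),
    ensemble = list(k = 3L, epochs = 10L, batch_size = 64L,
                    learning_rate = 1e-3, feature_dim = 64L,
                    decorrelation = FALSE, partition = FALSE,
                    adversarial = FALSE, dverge = FALSE,
                    lambda = 0.2, r = 32L, eps = 1e-5,
                    band_edges_hz = NULL, rolloff_hz = NULL,
                    harden_epsilon = 0.1, harden_inner_steps = 20L,
                    harden_budget_epochs = 1L),
    attack = list(methods = "pgd", epsilons = 0.1, steps = 20L,
                  mode = "ensemble_alternating",
                  kernel_widths = c(5L, 7L, 11L, 15L, 19L),
                  kernel_sigmas = c(1, 3, 5, 7, 10)),
    evaluation = list(n_grid = 201L,
                      mixed_fractions = c("0" = 0.50, "0.025" = 0.25,
                                          "0.05" = 0.15, "0.15" = 0.10),
                      deferral_grid = 201L))
  merge_section <- function(def, user, name) {
    extra <- setdiff(names(user), names(def))
    check_domain(length(extra) == 0,
                 sprintf("unknown %s config key(s): %s", name,
                         paste(extra, collapse = ", ")))
    # NULL-valued user entries mean "use the default" (modifyList would
    # otherwise delete the key and break config round-trips)
    user <- user[!vapply(user, is.null, logical(1))]
    utils::modifyList(def, user)
  }
  cfg <- list(dataset = merge_section(defaults$dataset, dataset, "dataset"),
              ensemble = merge_section(defaults$ensemble, ensemble, "ensemble"),
              attack = merge_section(defaults$attack, attack, "attack"),
              evaluation = merge_section(defaults$evaluation, evaluation,
                                         "evaluation"),
              seed = as.integer(seed))
  check_domain(is_count(cfg$ensemble$k), "`ensemble$k` must be >= 1")
  check_domain(all(cfg$attack$methods %in% c("pgd", "sap")),
               "attack methods must be 'pgd' and/or 'sap'")
  check_domain(abs(sum(cfg$evaluation$mixed_fractions) - 1) <= 1e-9,
               "`evaluation$mixed_fractions` must sum to 1")
  structure(cfg, class = "experiment_config")
}

#' Read / write an experiment configuration as YAML
#'
#' `read_experiment_config(write_experiment_config(cfg, path))` returns a
#' configuration equal to `cfg` (round-trip contract).
#'
#' @param config An [experiment_config()].
#' @param path YAML file path.
#' @return `write_experiment_config` returns `path` invisibly;
#'   `read_experiment_config` returns the validated `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  x <- unclass(config)
  # preserve names of the epsilon-keyed fraction vector through YAML
  x$evaluation$mixed_fractions <- as.list(x$evaluation$mixed_fractions)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$evaluation$mixed_fractions)) {
    x$evaluation$mixed_fractions <- unlist(x$evaluation$mixed_fractions)
  }
  for (s in c("dataset", "ensemble", "attack")) {
    for (nm in names(x[[s]])) {
      if (is.list(x[[s]][[nm]])) x[[s]][[nm]] <- unlist(x[[s]][[nm]])
    }
  }
  experiment_config(dataset = x$dataset %||% list(),
                    ensemble = x$ensemble %||% list(),
                    attack = x$attack %||% list(),
                    evaluation = x$evaluation %||% list(),
                    seed = x$seed %||% 1L)
}

# Generator config derived from the dataset section and the global seed.
dataset_generator_config <- function(config) {
  ds <- config$dataset
  args <- list(sampling_rate = ds$sampling_rate, duration = ds$duration,
               n_channels = ds$n_channels, seed = derive_seed(config$seed, 1L))
  if (!is.null(ds$band_split)) args$band_split <- ds$band_split
  do.call(ecg_generator_config, args)
}

#' Train an ensemble according to a configuration
#'
#' Generates the synthetic dataset, splits it, and trains `K` members
#' sequentially. With decorrelation enabled, each finished member's
#' features are cached immediately and members `k > 0` train against all
#' prior caches; with partitioning enabled, the ring-filter transforms are
#' installed before training; adversarial / DVERGE hardening passes run
#' after natural training. Calibration bounds are computed on the training
#' set with the final weights. The manifest records seeds, the config hash,
#' per-member weight hashes and the bounds, so identical config + seed runs
#' can be verified identical.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory: persists the ensemble, caches and
#'   manifest.
#' @return List: `ensemble`, `bounds`, `data` (train/test split), `traces`
#'   (per-member loss traces), `caches`, `bank`, `manifest`.
#' @export
run_training_pipeline <- function(config, out_dir = NULL) {
  check_that(inherits(config, "experiment_config"),
             "`config` must be an experiment_config")
  ec <- config$ensemble
  gen_cfg <- dataset_generator_config(config)
  full <- generate_dataset(config$dataset$n_per_class, gen_cfg)
  sp <- split_batch(full, config$dataset$frac_train,
                    seed = derive_seed(config$seed, 2L))

  k_tot <- ec$k
  bank <- NULL
  transforms <- vector("list", k_tot)
  if (isTRUE(ec$partition)) {
    check_domain(k_tot >= 2, "partitioning needs K >= 2")
    t_len <- round(gen_cfg$sampling_rate * gen_cfg$duration)
    edges <- ec$band_edges_hz %||% (gen_cfg$sampling_rate / 8)
    roll <- ec$rolloff_hz %||% (gen_cfg$sampling_rate / 50)
    bank <- design_ring_filters(gen_cfg$sampling_rate, t_len, edges, roll)
    check_domain(length(bank$responses) == k_tot - 1L,
                 "partition bank must have K - 1 responses")
    for (j in 2:k_tot) {
      transforms[[j]] <- band_transform(bank$responses[[j - 1L]],
                                        fs = bank$fs,
                                        label = sprintf("band%d", j - 1L))
    }
  }

  dec_cfg <- decorr_config(lambda_weight = ec$lambda, projection_dim = ec$r,
                           stability_eps = ec$eps)
  members <- vector("list", k_tot)
  caches <- list()
  traces <- vector("list", k_tot)
  for (k in seq_len(k_tot)) {
    spec <- classifier_spec(gen_cfg$n_channels, length(gen_cfg$class_names),
                            feature_dim = ec$feature_dim,
                            seed = derive_seed(config$seed, 10L + k))
    tcfg <- train_config(epochs = ec$epochs, batch_size = ec$batch_size,
                         learning_rate = ec$learning_rate,
                         seed = derive_seed(config$seed, 20L + k))
    model <- init_classifier(spec)
    use_dec <- isTRUE(ec$decorrelation) && k > 1L
    res <- train_member(model, sp$train, tcfg,
                        decorr = if (use_dec) dec_cfg else NULL,
                        prior_caches = if (use_dec) caches else list(),
                        transform = transforms[[k]])
    members[[k]] <- res$model
    traces[[k]] <- res$trace
    if (isTRUE(ec$decorrelation)) {
      caches[[k]] <- build_feature_cache(res$model, sp$train,
                                         transform = transforms[[k]],
                                         model_index = k - 1L)
    }
  }
  ensemble <- new_ensemble(members, input_transforms = transforms)

  if (isTRUE(ec$adversarial)) {
    hcfg <- hardening_config(epsilon = ec$harden_epsilon,
                             inner_steps = ec$harden_inner_steps,
                             budget_epochs = ec$harden_budget_epochs,
                             domain_bounds = c(-1, 1),
                             seed = derive_seed(config$seed, 40L))
    tcfg <- train_config(epochs = 1L, batch_size = ec$batch_size,
                         learning_rate = ec$learning_rate,
                         seed = derive_seed(config$seed, 41L))
    ensemble <- harden_ensemble_adversarial(ensemble, sp$train, hcfg, tcfg)
  }
  if (isTRUE(ec$dverge)) {
    tcfg <- train_config(epochs = 1L, batch_size = ec$batch_size,
                         learning_rate = ec$learning_rate,
                         seed = derive_seed(config$seed, 43L))
    for (round in seq_len(ec$harden_budget_epochs)) {
      hcfg <- hardening_config(epsilon = ec$harden_epsilon,
                               inner_steps = ec$harden_inner_steps,
                               budget_epochs = 1L,
                               domain_bounds = c(-1, 1),
                               seed = derive_seed(config$seed, 50L + round))
      dres <- dverge_training_round(ensemble, sp$train, hcfg, tcfg)
      ensemble <- dres$ensemble
    }
  }

  bounds <- calibrate_bounds(ensemble, sp$train)
  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    n_train = n_records(sp$train), n_test = n_records(sp$test),
    member_hashes = vapply(members, function(m) rlang::hash(m$params),
                           character(1)),
    ensemble_hash = rlang::hash(lapply(ensemble$members, `[[`, "params")),
    bounds = list(i_min = bounds$i_min, i_max = bounds$i_max),
    cache_files = if (length(caches)) sprintf("cache_model%d.rds",
                                              seq_along(caches) - 1L)
                  else character(0),
    methods = list(decorrelation = isTRUE(ec$decorrelation),
                   partition = isTRUE(ec$partition),
                   adversarial = isTRUE(ec$adversarial),
                   dverge = isTRUE(ec$dverge)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(ensemble, file.path(out_dir, "ensemble.rds"))
    for (j in seq_along(caches)) {
      write_feature_cache(caches[[j]],
                          file.path(out_dir, manifest$cache_files[j]))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(ensemble = ensemble, bounds = bounds, data = sp, traces = traces,
       caches = caches, bank = bank, manifest = manifest)
}

#' Evaluate a trained ensemble over the attack grid
#'
#' For the clean held-out set and every `(method, epsilon)` combination:
#' craft the white-box attack against this ensemble, score uncertainty,
#' and report accuracy, the three threshold-metric AUCs and the
#' incorrect-vs-correct uncertainty gap. A partially attacked dataset is
#' built per the mixed-fraction spec and summarized by deferral curves for
#' both the natural and the mixed set.
#'
#' @param config The [experiment_config()] used for training.
#' @param trained The result of [run_training_pipeline()].
#' @param out_dir Optional directory for CSV/JSON reports.
#' @return List: `report` (one tibble row per dataset), `scores` (named
#'   list of per-record tibbles), `deferral` (natural and mixed
#'   [deferral_curve()]s), `mixed_annotations`.
#' @export
run_evaluation_pipeline <- function(config, trained, out_dir = NULL) {
  ens <- trained$ensemble
  bounds <- trained$bounds
  test <- trained$data$test
  av <- config$attack
  bank <- build_kernel_bank(av$kernel_widths, av$kernel_sigmas)

  score_one <- function(batch) score_batch(ens, batch, bounds)
  summarize_scores <- function(scores, method, epsilon) {
    tc <- curve_and_auc(scores, config$evaluation$n_grid)
    du <- delta_uncertainty(scores)
    tibble::tibble(method = method, epsilon = epsilon,
                   accuracy = mean(scores$correct),
                   auc_rcc = tc$auc_rcc, auc_riu = tc$auc_riu,
                   auc_ua = tc$auc_ua,
                   delta_inorm = as.numeric(du),
                   delta_one_sided = attr(du, "one_sided"))
  }

  scores <- list(clean = score_one(test))
  rows <- list(summarize_scores(scores$clean, "none", 0))
  for (method in av$methods) {
    for (eps in av$epsilons) {
      acfg <- attack_config(epsilon = eps, n_steps = av$steps,
                            domain_bounds = c(-1, 1),
                            target_mode = av$mode)
      attacked <- craft_attack(method, ens, test, acfg, bank)
      key <- sprintf("%s_eps%g", method, eps)
      scores[[key]] <- score_one(attacked)
      rows[[key]] <- summarize_scores(scores[[key]], method, eps)
    }
  }
  report <- dplyr::bind_rows(rows)

  attack_fn <- function(eps, sub) {
    acfg <- attack_config(epsilon = eps, n_steps = av$steps,
                          domain_bounds = c(-1, 1), target_mode = av$mode)
    craft_attack(av$methods[[1]], ens, sub, acfg, bank)
  }
  mixed <- build_mixed_dataset(test, attack_fn,
                               mixed_dataset_spec(
                                 config$evaluation$mixed_fractions,
                                 base_seed = derive_seed(config$seed, 60L)))
  scores$mixed <- score_one(mixed$batch)
  grid <- seq(0, 1, length.out = config$evaluation$deferral_grid)
  deferral <- list(natural = deferral_curve(scores$clean, grid),
                   mixed = deferral_curve(scores$mixed, grid))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(report, file.path(out_dir, "report.csv"))
    for (nm in names(scores)) {
      write_scores(scores[[nm]], file.path(out_dir, sprintf("scores_%s.csv", nm)))
    }
    jsonlite::write_json(
      list(report = report,
           deferral_auc = list(natural = deferral$natural$auc,
                               mixed = deferral$mixed$auc)),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
  }
  list(report = report, scores = scores, deferral = deferral,
       mixed_annotations = mixed$annotations)
}
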