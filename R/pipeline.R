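# End-to-end orchestration: phantom generation -> labels -> metrics ->
# cohort -> models -> reports, with a single master seed fanned out to
# per-stage seeds so stages can be re-run in isolation.

default_run_config <- function() {
  list(
    stages = c("phantom", "derive", "cohort", "ttest", "sweep", "fit", "svm"),
    out_dir = "herniaquant_run",
    seed = 1L,
    n_phantoms = 3L,
    phantom = list(spacing = c(2.5, 2.5, 5), height = 300,
                   torso_semiaxes = c(120, 95), subcut_thickness = 24,
                   visceral_semiaxes = c(45, 28), label_z_range = c(25, 275)),
    cohort = list(n_bridge = 9L, n_nobridge = 17L),
    sweep = list(alpha_grid = seq(0.1, 1, by = 0.1), n_folds = 5L,
                 nlambda = 40L),
    fit = list(alpha = 0.9, n_folds = "loo"),
    svm = list(features = c("B", "E"), C = 1),
    tps_lambda = 0,
    kappa_margin = 10L,
    threshold = 0.5)
}

#' Validate and complete a run configuration
#'
#' Unknown keys raise a validation error naming them; every tunable defaults
#' to the documented design choice.
#'
#' @param config named list (possibly partial), or path to a JSON config.
#' @return completed config list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop_hq(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
            class = "herniaquant_validation_error")
  out <- utils::modifyList(defaults, config)
  out$seed <- as.integer(out$seed)
  out
}

write_json_report <- function(x, path, config) {
  x$provenance <- list(package = "herniaquant",
                       version = as.character(utils::packageVersion("herniaquant")),
                       seed = config$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes the requested stages in dependency order, writing metrics CSV,
#' reliability/model/sweep JSON and a log to the output directory. Re-runs
#' with the same config and seed produce identical outputs.
#'
#' @param config list or JSON path accepted by [run_config()].
#' @return named list of produced artifact paths, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  artifacts <- list()
  stage_on <- function(s) s %in% cfg$stages
  phantoms <- NULL

  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    logf("[%s] start (seed %d)", name, cfg$seed)
    out <- tryCatch(fun(), error = function(e) {
      logf("[%s] FAILED: %s", name, conditionMessage(e))
      stop_hq(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    logf("[%s] done in %.1f s", name, as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }

  if (stage_on("phantom") || stage_on("derive")) {
    phantoms <- run_stage("phantom", function() {
      lapply(seq_len(cfg$n_phantoms), function(i) {
        args <- cfg$phantom
        args$seed <- child_seed(cfg$seed, i)
        sp <- do.call(phantom_spec, args)
        ph <- make_phantom(sp)
        img <- file.path(cfg$out_dir, sprintf("phantom_%02d_image.nii.gz", i))
        lab <- file.path(cfg$out_dir, sprintf("phantom_%02d_labels.nii.gz", i))
        write_labeled_volume(ph$volume, img, lab)
        ph$paths <- c(image = img, labels = lab)
        ph
      })
    })
    artifacts$phantoms <- lapply(phantoms, `[[`, "paths")
  }

  if (stage_on("derive")) {
    metrics_path <- file.path(cfg$out_dir, "metrics.csv")
    run_stage("derive", function() {
      rows <- lapply(phantoms, function(ph) derive_all(ph$volume, lambda = cfg$tps_lambda))
      names(rows) <- sprintf("phantom_%02d", seq_along(rows))
      write_metrics_table(rows, metrics_path)
    })
    artifacts$metrics <- metrics_path
  }

  if (stage_on("reliability")) {
    rel_path <- file.path(cfg$out_dir, "reliability.json")
    run_stage("reliability", function() {
      reports <- lapply(seq_along(phantoms), function(i) {
        volB <- perturb_labels(phantoms[[i]]$volume, 2, 3,
                               seed = child_seed(cfg$seed, 100L + i))
        reliability_report(phantoms[[i]]$volume, volB, cfg$kappa_margin)
      })
      agg <- aggregate_reliability(reports)
      write_json_report(list(aggregate = agg), rel_path, cfg)
    })
    artifacts$reliability <- rel_path
  }

  cohort <- NULL
  if (stage_on("cohort") || stage_on("ttest") || stage_on("sweep") ||
      stage_on("fit") || stage_on("svm")) {
    cohort_path <- file.path(cfg$out_dir, "cohort.csv")
    cohort <- run_stage("cohort", function() {
      co <- make_cohort(cfg$cohort$n_bridge, cfg$cohort$n_nobridge,
                        seed = child_seed(cfg$seed, 200L))
      write_cohort_table(co, cohort_path)
      co
    })
    artifacts$cohort <- cohort_path
  }

  if (stage_on("ttest")) {
    p <- file.path(cfg$out_dir, "ttests.json")
    run_stage("ttest", function()
      write_json_report(list(ttests = cohort_ttests(cohort)), p, cfg))
    artifacts$ttests <- p
  }

  if (stage_on("sweep")) {
    p <- file.path(cfg$out_dir, "sweep.json")
    run_stage("sweep", function() {
      sw <- loocv_sweep(cohort, alpha_grid = cfg$sweep$alpha_grid,
                        threshold = cfg$threshold, n_folds = cfg$sweep$n_folds,
                        nlambda = cfg$sweep$nlambda,
                        seed = child_seed(cfg$seed, 300L))
      best <- which.min(sw$n_false)
      write_json_report(list(
        curve = as.data.frame(sw),
        best = list(alpha = sw$alpha[best], n_false = sw$n_false[best],
                    accuracy_pct = accuracy_from_counts(sw$n_false[best],
                                                        nrow(cohort)))), p, cfg)
    })
    artifacts$sweep <- p
  }

  fit <- NULL
  if (stage_on("fit") || stage_on("svm")) {
    p <- file.path(cfg$out_dir, "model.json")
    fit <- run_stage("fit", function() {
      f <- exploratory_fit(cohort, alpha = cfg$fit$alpha,
                           n_folds = cfg$fit$n_folds,
                           seed = child_seed(cfg$seed, 400L))
      write_json_report(list(alpha = f$alpha, lambda = f$lambda,
                             beta0 = f$beta0, beta = as.list(f$beta),
                             retained = f$retained), p, cfg)
      f
    })
    artifacts$model <- p
  }

  if (stage_on("svm")) {
    p <- file.path(cfg$out_dir, "svm.json")
    run_stage("svm", function() {
      feats <- cfg$svm$features
      if (length(fit$retained) == 2L) feats <- fit$retained
      X <- cohort_features(cohort)[, feats, drop = FALSE]
      sv <- svm_hyperplane(X, cohort_outcome(cohort), C = cfg$svm$C)
      write_json_report(list(features = feats, w = as.list(sv$w), b = sv$b,
                             margin = sv$margin,
                             n_misclassified = sv$n_misclassified), p, cfg)
    })
    artifacts$svm <- p
  }

  cfg_path <- file.path(cfg$out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  artifacts$config <- cfg_path
  invisible(artifacts)
}

#' Command-line entry point
#'
#' Subcommands: `phantom`, `derive`, `reliability`, `cohort`, `fit`,
#' `sweep`, `svm`, `run`. `run` executes [run_pipeline()] with an optional
#' JSON config; the single-stage subcommands run a pipeline restricted to
#' the stages they need. Invoke via the script in `inst/cli/herniaquant.R`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
hq_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: herniaquant <command> [options]",
    "commands:",
    "  run         [config.json]            full pipeline",
    "  phantom     [config.json]            generate labeled phantoms",
    "  derive      <image.nii> <labels.nii> <out.csv>   metrics for one scan",
    "  reliability <labelsA.nii> <labelsB.nii> <out.json>",
    "  cohort      [config.json]            synthesize a cohort CSV",
    "  ttest       <cohort.csv> <out.json>",
    "  fit         <cohort.csv> <out.json> [alpha]",
    "  sweep       <cohort.csv> <out.json>",
    "  svm         <cohort.csv> <out.json> [featA] [featB]",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]; rest <- args[-1]
  cfg_from <- function() if (length(rest)) run_config(rest[1]) else run_config()
  status <- tryCatch({
    switch(cmd,
      run = run_pipeline(if (length(rest)) rest[1] else list()),
      phantom = run_pipeline(utils::modifyList(unclass(cfg_from()),
                                               list(stages = "phantom"))),
      cohort = run_pipeline(utils::modifyList(unclass(cfg_from()),
                                              list(stages = "cohort"))),
      derive = {
        vol <- read_labeled_volume(rest[1], rest[2])
        write_metrics_table(list(subject = derive_all(vol)), rest[3])
      },
      reliability = {
        volA <- read_labeled_volume(rest[1], rest[1])
        volB <- read_labeled_volume(rest[2], rest[2])
        rep <- reliability_report(volA, volB)
        jsonlite::write_json(rep, rest[3], auto_unbox = TRUE, digits = NA,
                             force = TRUE, pretty = TRUE)
      },
      ttest = {
        co <- read_cohort_table(rest[1])
        jsonlite::write_json(list(ttests = cohort_ttests(co)), rest[2],
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      },
      fit = {
        co <- read_cohort_table(rest[1])
        a <- if (length(rest) >= 3) as.numeric(rest[3]) else 0.9
        f <- exploratory_fit(co, alpha = a)
        jsonlite::write_json(list(alpha = a, lambda = f$lambda, beta0 = f$beta0,
                                  beta = as.list(f$beta), retained = f$retained),
                             rest[2], auto_unbox = TRUE, digits = NA, pretty = TRUE)
      },
      sweep = {
        co <- read_cohort_table(rest[1])
        sw <- loocv_sweep(co, alpha_grid = seq(0.1, 1, by = 0.1), n_folds = 5L,
                          nlambda = 40L)
        jsonlite::write_json(as.data.frame(sw), rest[2], auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
      },
      svm = {
        co <- read_cohort_table(rest[1])
        feats <- if (length(rest) >= 4) rest[3:4] else c("B", "E")
        sv <- svm_hyperplane(cohort_features(co)[, feats], cohort_outcome(co))
        jsonlite::write_json(list(features = feats, w = as.list(sv$w), b = sv$b,
                                  margin = sv$margin,
                                  n_misclassified = sv$n_misclassified),
                             rest[2], auto_unbox = TRUE, digits = NA, pretty = TRUE)
      },
      { message(usage); return(invisible(1L)) })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
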