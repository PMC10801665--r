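#' Pipeline configuration
#'
#' Bundles every stage's configuration for an end-to-end run: phantom
#' generation, network training, digitization, geometric evaluation and
#' dosimetric comparison. Each block is validated by its module's
#' constructor before any stage runs.
#'
#' @param out_dir output directory for reports, logs and the run manifest.
#' @param n_train,n_val numbers of phantoms to generate for training and
#'   held-out evaluation.
#' @param phantom a [phantom_config()] template (its seed is overridden per
#'   phantom from the pipeline seed).
#' @param net a [net_config()].
#' @param train a [train_config()].
#' @param digitize list: `degree`, `step_mm`, `offset_mm`, `max_dwells`,
#'   `dwell_time_s`.
#' @param dose list: `bin_width_gy`, `source` (a [source_model()]),
#'   `prescription_dose_gy`.
#' @param seed single top-level seed; all stage seeds derive from it.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("needletrace_run_"),
                            n_train = 10L, n_val = 3L,
                            phantom = phantom_config(),
                            net = net_config(depth = 3L, base_channels = 8L),
                            train = train_config(max_epochs = 50L),
                            digitize = list(degree = 3L, step_mm = 2.5,
                                            offset_mm = 0, max_dwells = 10L,
                                            dwell_time_s = 10),
                            dose = list(bin_width_gy = 0.01,
                                        source = default_source_model(),
                                        prescription_dose_gy = 6),
                            seed = 1L) {
  stopifnot(inherits(phantom, "phantom_config"), inherits(net, "net_config"),
            inherits(train, "train_config"),
            inherits(dose$source, "source_model"))
  if (n_train < 1L) stop_cfg("pipeline_config: n_train must be >= 1")
  structure(list(out_dir = out_dir, n_train = as.integer(n_train),
                 n_val = as.integer(n_val), phantom = phantom, net = net,
                 train = train, digitize = digitize, dose = dose,
                 seed = as.integer(seed)), class = "pipeline_config")
}

phantom_with_seed <- function(tpl, seed) {
  tpl$seed <- seed
  class(tpl) <- "phantom_config"
  make_phantom(tpl)
}

generate_cohort <- function(cfg) {
  tr <- lapply(seq_len(cfg$n_train), function(i)
    phantom_with_seed(cfg$phantom, derive_seed(cfg$seed, paste0("train", i))))
  va <- lapply(seq_len(cfg$n_val), function(i)
    phantom_with_seed(cfg$phantom, derive_seed(cfg$seed, paste0("val", i))))
  list(train = tr, val = va)
}

as_samples <- function(phantoms) {
  lapply(phantoms, function(p) list(
    volume = p$volume,
    mask = volume3d((p$truth$instance_mask$data > 0) * 1.0,
                    p$volume$spacing, p$volume$origin)))
}

# Build manual (ground truth) and automatic plans over matched needle pairs
# holding dwell counts and times identical, per-pair dwell count limited by
# the shorter of the two needles.
build_plan_pair <- function(pairs, dz_cfg, dose_cfg) {
  manual <- list(); auto <- list()
  for (p in pairs) {
    lmin <- min(p$pred$length_mm, p$truth$length_mm)
    n_dw <- min(dz_cfg$max_dwells,
                floor((lmin - dz_cfg$offset_mm) / dz_cfg$step_mm))
    if (n_dw < 1L) next
    manual[[length(manual) + 1L]] <-
      sample_dwells(p$truth, dz_cfg$step_mm, dz_cfg$offset_mm, n_dw,
                    times = dz_cfg$dwell_time_s)
    auto[[length(auto) + 1L]] <-
      sample_dwells(p$pred, dz_cfg$step_mm, dz_cfg$offset_mm, n_dw,
                    times = dz_cfg$dwell_time_s)
  }
  if (length(manual) == 0L) return(NULL)
  list(manual = brachy_plan(manual, dose_cfg$prescription_dose_gy,
                            dose_cfg$source),
       auto = brachy_plan(auto, dose_cfg$prescription_dose_gy,
                          dose_cfg$source))
}

#' Run the full digitization pipeline
#'
#' Generates a synthetic cohort, trains the configured network, and for every
#' held-out phantom: predicts the needle mask, digitizes predicted and
#' ground-truth masks, computes the geometric report, rebuilds manual and
#' automatic plans with identical dwell counts/times, and compares their
#' DVH metrics. Reports, per-needle CSV, plan JSONs, a structured log and a
#' checksummed manifest are written under `cfg$out_dir`. The entire run is a
#' deterministic function of `cfg$seed`.
#'
#' @param cfg a [pipeline_config()].
#' @param verbose log each stage to the console as well.
#' @return invisible list: `geo` (per-case `geo_report`s), `dvh` (per-case
#'   comparison data.frames), `history` (training history), `manifest`.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  t0 <- Sys.time()
  logf <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
    cat(line, "\n", file = log_path, append = TRUE)
    if (verbose) message(line)
  }
  stage <- "generate"
  result <- tryCatch({
    logf(stage, sprintf("generating %d train + %d val phantoms",
                        cfg$n_train, cfg$n_val))
    cohort <- generate_cohort(cfg)

    stage <- "train"
    tcfg <- cfg$train
    tcfg$seed <- derive_seed(cfg$seed, "trainer")
    class(tcfg) <- "train_config"
    model <- build_model(cfg$net, seed = derive_seed(cfg$seed, "init"))
    logf(stage, sprintf("training %s for %d epochs on %d phantoms",
                        if (cfg$net$use_attention) "CNN+AG" else "CNN",
                        tcfg$max_epochs, cfg$n_train))
    fit <- train_model(model, as_samples(cohort$train),
                       as_samples(cohort$val), tcfg)
    utils::write.csv(fit$history,
                     file.path(cfg$out_dir, "train_history.csv"),
                     row.names = FALSE)

    geo <- list(); dvh <- list()
    for (ci in seq_along(cohort$val)) {
      ph <- cohort$val[[ci]]
      stage <- "predict"
      pred_mask <- predict_mask(fit$model, ph$volume, cfg$train$threshold)

      stage <- "digitize"
      truth_mask <- volume3d((ph$truth$instance_mask$data > 0) * 1.0,
                             ph$volume$spacing, ph$volume$origin)
      pred_traj <- digitize_mask(pred_mask, degree = cfg$digitize$degree)
      truth_traj <- ph$truth$centerlines
      if (length(pred_traj) == 0L) {
        logf(stage, sprintf("case %d: no needles found in prediction", ci))
        next
      }

      stage <- "evaluate"
      rep_ci <- geo_report(pred_mask, truth_mask, pred_traj, truth_traj)
      geo[[length(geo) + 1L]] <- rep_ci
      logf(stage, sprintf(
        "case %d: DSC %.3f JI %.3f HD %.2f mm tip %.2f mm shaft %.2f mm",
        ci, rep_ci$dsc, rep_ci$jaccard, rep_ci$hausdorff_mm,
        rep_ci$tip_error_mm, rep_ci$shaft_error_mm))

      stage <- "dose"
      pairs <- pair_trajectories(pred_traj, truth_traj)
      pairs <- Filter(function(p) !p$pred$flagged && !p$truth$flagged, pairs)
      plans <- if (length(pairs)) build_plan_pair(pairs, cfg$digitize, cfg$dose)
               else NULL
      if (!is.null(plans)) {
        write_plan(plans$manual,
                   file.path(cfg$out_dir, sprintf("case%d_manual_plan.json", ci)))
        write_plan(plans$auto,
                   file.path(cfg$out_dir, sprintf("case%d_auto_plan.json", ci)))
        cmp <- compare_plans(plans$manual, plans$auto, ph$volume,
                             ph$truth$structures,
                             allow_extrapolation = TRUE)
        cmp$case <- ci
        dvh[[length(dvh) + 1L]] <- cmp
        logf(stage, sprintf("case %d: %d DVH metric rows", ci, nrow(cmp)))
      } else logf(stage, sprintf("case %d: no usable needle pairs for dose", ci))
    }

    stage <- "report"
    geo_doc <- lapply(geo, function(g)
      g[c("dsc", "jaccard", "hausdorff_mm", "tip_error_mm",
          "tip_distance_mm", "shaft_error_mm", "n_needles")])
    jsonlite::write_json(geo_doc, file.path(cfg$out_dir, "geo_report.json"),
                         auto_unbox = TRUE, digits = NA)
    dvh_all <- if (length(dvh)) do.call(rbind, dvh) else NULL
    if (!is.null(dvh_all))
      jsonlite::write_json(dvh_all, file.path(cfg$out_dir, "dvh_report.json"),
                           auto_unbox = TRUE, digits = NA)
    per_needle <- do.call(rbind, lapply(seq_along(geo), function(i) {
      df <- geo[[i]]$per_needle; df$case <- i; df
    }))
    if (!is.null(per_needle))
      utils::write.csv(per_needle, file.path(cfg$out_dir, "per_needle.csv"),
                       row.names = FALSE)

    files <- setdiff(list.files(cfg$out_dir), "manifest.json")
    manifest <- list(
      seed = cfg$seed,
      package_version = as.character(utils::packageVersion("needletrace")),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      files = lapply(files, function(f) list(
        name = f,
        md5 = unname(tools::md5sum(file.path(cfg$out_dir, f))))))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    list(geo = geo, dvh = dvh_all, history = fit$history,
         manifest = manifest, model = fit$model)
  }, error = function(e) {
    logf(stage, paste("FAILED:", conditionMessage(e)))
    stop_cfg("run_pipeline: stage '%s' failed: %s", stage, conditionMessage(e))
  })
  invisible(result)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Every block is passed through its module's constructor, so an invalid
#' field fails before any stage runs. Unrecognized keys raise an error.
#'
#' @param path `.yaml`/`.yml` or `.json` configuration file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else stop_cfg("read_pipeline_config: unsupported extension: %s", path)
  build_block <- function(ctor, block) {
    if (is.null(block)) return(ctor())
    known <- names(formals(ctor))
    bad <- setdiff(names(block), known)
    if (length(bad))
      stop_cfg("read_pipeline_config: unknown field(s) %s",
               paste(bad, collapse = ", "))
    do.call(ctor, block)
  }
  args <- list(
    phantom = build_block(phantom_config, doc$phantom),
    net = build_block(net_config, doc$net),
    train = build_block(train_config, doc$train))
  for (nm in c("out_dir", "n_train", "n_val", "seed"))
    if (!is.null(doc[[nm]])) args[[nm]] <- doc[[nm]]
  if (!is.null(doc$digitize)) {
    dz <- formals(pipeline_config)$digitize
    args$digitize <- utils::modifyList(eval(dz), doc$digitize)
  }
  if (!is.null(doc$dose)) {
    base <- list(bin_width_gy = 0.01, source = default_source_model(),
                 prescription_dose_gy = 6)
    args$dose <- utils::modifyList(base, doc$dose)
  }
  do.call(pipeline_config, args)
}
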