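.PIPELINE_STAGES <- c("phantom", "split", "train", "segment", "dsc", "tur",
                      "roc", "stage")

#' Derive a per-stage seed from the master seed
#'
#' Stages draw their seeds from one master seed through a fixed
#' multiplicative-congruential scheme (Lehmer, modulus 2^31 - 1, multiplier
#' 48271), with the stage's index in the pipeline added before reduction.
#' Stages can therefore be re-run in isolation and still reproduce a full
#' run bit-for-bit.
#'
#' @param master integer master seed
#' @param stage stage name (one of the pipeline stages) or `"train_<seq>"`
#' @return integer seed in [1, 2^31 - 2]
#' @export
derive_seed <- function(master, stage) {
  stages <- c(.PIPELINE_STAGES,
              paste0("train_", TUR_SEQUENCES), "train_joint")
  i <- match(stage, stages)
  if (is.na(i)) stop("unknown pipeline stage: ", stage)
  m <- 2147483647
  val <- (48271 * (abs(master) %% m) + i * 8191) %% m
  if (val == 0) val <- 1
  as.integer(val)
}

#' Validate a pipeline configuration
#'
#' Fills defaults, rejects unknown keys (typo protection) and reports the
#' offending key on any bound violation. The U-net sub-configuration is
#' validated through [unet_config()].
#'
#' @param document a named list, or a path to a JSON/YAML file
#' @return `pipeline_config` list
#' @export
validate_config <- function(document = list()) {
  if (is.character(document) && length(document) == 1) {
    document <- if (grepl("\\.ya?ml$", document)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs needs the 'yaml' package")
      yaml::read_yaml(document)
    } else jsonlite::read_json(document, simplifyVector = TRUE)
  }
  stopifnot(is.list(document))
  defaults <- list(
    n_ia = 73L, n_ib = 44L, image_size = 64L, distractors = FALSE,
    noise_sd = 8, split_ratios = c(6, 1, 3),
    fusion_mode = "k_of_n", fusion_k = 2L,
    fusion_sequences = TUR_SEQUENCES,
    seed = 1L, depth = 3L, base_channels = 8L, learning_rate = 3e-4,
    max_epochs = 30L, patience = 10L, batch_size = 4L,
    per_sequence = TRUE, augment_flip = FALSE, class_weights = NULL)
  unknown <- setdiff(names(document), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, document)
  if (cfg$n_ia < 0 || cfg$n_ib < 0)
    stop("invalid config 'n_ia'/'n_ib': cohort sizes must be non-negative")
  if (length(cfg$split_ratios) != 3 || any(cfg$split_ratios < 0))
    stop("invalid config 'split_ratios': three non-negative weights required")
  if (cfg$noise_sd < 0)
    stop("invalid config 'noise_sd': must be non-negative")
  # validates depth/image_size/learning_rate/... and names the field on error
  ucfg <- unet_config(depth = cfg$depth, base_channels = cfg$base_channels,
                      in_size = cfg$image_size,
                      learning_rate = cfg$learning_rate,
                      max_epochs = cfg$max_epochs, patience = cfg$patience,
                      batch_size = cfg$batch_size, seed = cfg$seed,
                      per_sequence = cfg$per_sequence,
                      augment_flip = cfg$augment_flip,
                      class_weights = cfg$class_weights)
  rule <- fusion_rule(cfg$fusion_mode, cfg$fusion_k, cfg$fusion_sequences)
  structure(c(cfg, list(unet = ucfg, rule = rule)),
            class = "pipeline_config")
}

.slice_pairs <- function(cohort, ids, sequences) {
  out <- list()
  for (cs in cohort) {
    if (!cs$patient_id %in% ids) next
    for (sq in sequences) {
      sl <- cs$slices[[sq]]
      out[[length(out) + 1L]] <- list(image = sl$image, mask = sl$mask,
                                      patient_id = cs$patient_id,
                                      sequence = sq, stage = cs$stage)
    }
  }
  out
}

#' Run the full phantom-to-staging pipeline
#'
#' Generates a synthetic cohort, splits it by patient, trains the U-net
#' segmenter(s), predicts test-set masks, and derives DSC, TUR, per-sequence
#' ROC criteria and the fused staging report. Every intermediate artifact is
#' written under `out_dir`; a run record (config snapshot, per-stage timings,
#' artifact paths) is serialized alongside. Re-running with the same config
#' and master seed reproduces all stochastic stages bit-identically.
#'
#' @param config a [validate_config()] result (or a raw list passed through
#'   it)
#' @param out_dir output directory
#' @return (invisibly) the run record list
#' @export
run_pipeline <- function(config = validate_config(), out_dir) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  record <- list(config = config[setdiff(names(config), c("unet", "rule"))],
                 version = as.character(utils::packageVersion("turstage")),
                 timings = list(), artifacts = list())
  persist <- function() {
    jsonlite::write_json(record, file.path(out_dir, "run_record.json"),
                         auto_unbox = TRUE, null = "null", digits = NA,
                         force = TRUE)
  }
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      record$timings[[name]] <<- as.numeric(Sys.time() - t0, units = "secs")
      persist()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    record$timings[[name]] <<- as.numeric(Sys.time() - t0, units = "secs")
    res
  }

  # phantom cohort
  cohort <- run_stage("phantom", function() {
    params <- default_phantom_params(config$image_size, config$distractors)
    for (sq in TUR_SEQUENCES) params[[sq]]$noise_sd <- config$noise_sd
    cases <- sample_cohort(config$n_ia, config$n_ib, params,
                           seed = derive_seed(config$seed, "phantom"))
    write_cohort(cases, file.path(out_dir, "cohort"))
    cases
  })
  record$artifacts$manifest <- file.path(out_dir, "cohort", "manifest.csv")

  split <- run_stage("split", function() {
    ids <- vapply(cohort, `[[`, "", "patient_id")
    sp <- split_dataset(ids, config$split_ratios,
                        seed = derive_seed(config$seed, "split"))
    jsonlite::write_json(unclass(sp), file.path(out_dir, "split.json"))
    sp
  })
  record$artifacts$split <- file.path(out_dir, "split.json")

  models <- run_stage("train", function() {
    groups <- if (config$per_sequence) as.list(TUR_SEQUENCES) else
      list(TUR_SEQUENCES)
    models <- list()
    for (g in groups) {
      tag <- if (length(g) == 1) g else "joint"
      ucfg <- config$unet
      ucfg$seed <- derive_seed(config$seed, paste0("train_", tag))
      tr <- .slice_pairs(cohort, split$train, g)
      va <- .slice_pairs(cohort, split$validation, g)
      fit <- train_unet(build_unet(ucfg), tr, va, ucfg)
      fit$model$sequence <- tag
      save_checkpoint(fit$model, file.path(out_dir, "models", tag))
      for (sq in g) models[[sq]] <- fit$model
    }
    models
  })
  record$artifacts$models <- file.path(out_dir, "models")

  partition_of <- function(id) {
    if (id %in% split$test) "test"
    else if (id %in% split$validation) "validation" else "train"
  }

  predicted <- run_stage("segment", function() {
    dir.create(file.path(out_dir, "predicted"), showWarnings = FALSE)
    all_pairs <- .slice_pairs(cohort, vapply(cohort, `[[`, "", "patient_id"),
                              TUR_SEQUENCES)
    lapply(all_pairs, function(p) {
      pm <- predict_mask(models[[p$sequence]], p$image)
      write_mask(pm, file.path(out_dir, "predicted",
                               paste0(p$patient_id, "_", p$sequence, ".png")))
      c(p, list(pred = pm, partition = partition_of(p$patient_id)))
    })
  })
  record$artifacts$predicted <- file.path(out_dir, "predicted")

  dsc_table <- run_stage("dsc", function() {
    rows <- do.call(rbind, lapply(predicted, function(p) {
      do.call(rbind, lapply(c("uterus", "tumor"), function(st)
        data.frame(patient_id = p$patient_id, sequence = p$sequence,
                   partition = p$partition,
                   structure = st, dsc = dsc(p$mask, p$pred, st),
                   stringsAsFactors = FALSE)))
    }))
    write.csv(rows, file.path(out_dir, "dsc.csv"), row.names = FALSE)
    write.csv(summarize_dsc(rows[rows$partition == "test", ]),
              file.path(out_dir, "dsc_summary.csv"), row.names = FALSE)
    rows
  })
  record$artifacts$dsc <- file.path(out_dir, "dsc.csv")

  tur_table <- run_stage("tur", function() {
    rows <- do.call(rbind, lapply(predicted, function(p)
      data.frame(patient_id = p$patient_id, sequence = p$sequence,
                 partition = p$partition,
                 tur = compute_tur(p$pred), true_stage = p$stage,
                 stringsAsFactors = FALSE)))
    write.csv(rows, file.path(out_dir, "tur.csv"), row.names = FALSE)
    rows
  })
  record$artifacts$tur <- file.path(out_dir, "tur.csv")

  # staging criteria are selected on the test partition, mirroring the
  # clinical workflow's ROC analysis of held-out patients
  rocs <- run_stage("roc", function() {
    rocs <- lapply(TUR_SEQUENCES, function(sq) {
      r <- tur_table[tur_table$sequence == sq &
                       tur_table$partition == "test", ]
      roc <- roc_curve(r$tur, r$true_stage)
      write.csv(data.frame(threshold = roc$thresholds,
                           sensitivity = roc$sensitivity,
                           specificity = roc$specificity),
                file.path(out_dir, paste0("roc_", sq, ".csv")),
                row.names = FALSE)
      roc
    })
    names(rocs) <- TUR_SEQUENCES
    jsonlite::write_json(
      lapply(rocs, function(r) r[c("auc", "criterion", "sens_at_criterion",
                                   "spec_at_criterion")]),
      file.path(out_dir, "roc_summary.json"), auto_unbox = TRUE, digits = NA)
    rocs
  })
  record$artifacts$roc <- file.path(out_dir, "roc_summary.json")

  report <- run_stage("stage", function() {
    criteria <- vapply(rocs, `[[`, 0, "criterion")
    rep <- stage_cohort(tur_table, criteria, config$rule)
    rep$partition <- vapply(rep$patient_id, partition_of, "")
    write.csv(rep, file.path(out_dir, "staging_report.csv"),
              row.names = FALSE)
    test_rep <- rep[rep$partition == "test", ]
    perf <- evaluate_staging(test_rep$fused, test_rep$true_stage)
    jsonlite::write_json(unclass(perf), file.path(out_dir, "performance.json"),
                         auto_unbox = TRUE, digits = NA)
    rep
  })
  record$artifacts$report <- file.path(out_dir, "staging_report.csv")
  record$artifacts$performance <- file.path(out_dir, "performance.json")

  persist()
  invisible(record)
}
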