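## Stage runner behind the command-line interface. One YAML config file
## drives every stage; a manifest written next to each stage's outputs
## records the config hash, the effective seed and input fingerprints so a
## run can be reproduced exactly. No timestamps are written anywhere, so
## identical config + seed give byte-identical artifacts.

pipelineStages <- c("simulate-fixture", "preprocess", "fit-baseline",
                    "train", "generate", "evaluate-utility",
                    "evaluate-privacy", "end-to-end")

readRunConfig <- function(configPath, overrides = list()) {
  assertThat(file.exists(configPath), "config file not found: ", configPath)
  cfg <- yaml::read_yaml(configPath)
  cfg <- utils::modifyList(cfg, overrides)
  assertThat(!is.null(cfg$output_dir), "config field missing: output_dir")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  attr(cfg, "hash") <- unname(tools::md5sum(configPath))
  cfg
}

writeManifest <- function(dir, stage, cfg, inputs = character()) {
  man <- list(stage = stage, config_hash = attr(cfg, "hash"),
              seed = cfg$seed,
              package_version = as.character(utils::packageVersion("longsynth")),
              inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])))
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

stageDir <- function(cfg, ...) {
  d <- file.path(cfg$output_dir, ...)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

specFromConfig <- function(cfg) {
  sim <- cfg$simulate %||% list()
  defaultSimulationSpec(nIndividuals = sim$n_individuals %||% 500L,
                        maxLength = sim$max_length %||% 60L,
                        seed = childSeed(cfg$seed, "simulate"))
}

modelConfigFromConfig <- function(cfg) {
  m <- cfg$model %||% list()
  modelConfig(hiddenSize = m$hidden_size %||% 32L,
              nLayers = m$n_layers %||% 1L,
              embLabel = m$emb_label %||% 8L,
              embAttr = m$emb_attr %||% 6L,
              embBaseline = m$emb_baseline %||% 4L,
              lambda = m$lambda %||% 1,
              batchSize = m$batch_size %||% 64L,
              epochs = m$epochs %||% 20L,
              learningRate = m$learning_rate %||% 0.01,
              window = m$window %||% 120L,
              seed = childSeed(cfg$seed, "train"))
}

#' Run one pipeline stage (or the whole workflow)
#'
#' The end-to-end workflow: `simulate-fixture` writes a ground-truth cohort;
#' `preprocess` computes sojourns, truncates, encodes and chunks it;
#' `fit-baseline` fits the sequential tree seed synthesizer; `train` fits
#' the recurrent generator; `generate` synthesizes a cohort from fresh
#' seeds; `evaluate-utility` and `evaluate-privacy` write the reports.
#' `end-to-end` chains all of the above. Every stage writes a manifest with
#' the config hash, seed, package version and input fingerprints.
#'
#' @param subcommand one of `"simulate-fixture"`, `"preprocess"`,
#'   `"fit-baseline"`, `"train"`, `"generate"`, `"evaluate-utility"`,
#'   `"evaluate-privacy"`, `"end-to-end"`.
#' @param configPath path to the YAML run configuration.
#' @param overrides named list merged over the file config.
#' @return invisibly, a named list of the artifact paths written.
#' @export
runPipeline <- function(subcommand, configPath, overrides = list()) {
  assertThat(subcommand %in% pipelineStages,
             "unknown subcommand '", subcommand, "'; expected one of: ",
             paste(pipelineStages, collapse = ", "))
  cfg <- readRunConfig(configPath, overrides)
  out <- list()
  run <- function(stage) runPipeline(stage, configPath, overrides)

  if (subcommand == "end-to-end") {
    for (s in setdiff(pipelineStages, "end-to-end")) out <- c(out, run(s))
    return(invisible(out))
  }

  realDir <- file.path(cfg$output_dir, "real")
  workDir <- file.path(cfg$output_dir, "work")
  synDir <- file.path(cfg$output_dir, "synthetic")
  repDir <- file.path(cfg$output_dir, "reports")

  if (subcommand == "simulate-fixture") {
    spec <- specFromConfig(cfg)
    cohort <- simulateCohort(spec)
    d <- stageDir(cfg, "real")
    writeCohortDir(cohort, d)
    writeManifest(d, subcommand, cfg)
    out$real <- d
  } else if (subcommand == "preprocess") {
    pp <- cfg$preprocess %||% list()
    cohort <- readCohortDir(realDir)
    cohort <- computeSojourn(cohort)
    cohort <- truncateSequences(cohort, pp$percentile %||% 0.95,
                                pp$hard_cap %||% 1000L)
    enc <- chunkSequences(encodeCohort(cohort),
                          window = pp$window %||% 120L)
    d <- stageDir(cfg, "work")
    saveRDS(enc, file.path(d, "encoded.rds"))
    writeManifest(d, subcommand, cfg,
                  file.path(realDir, c("baseline.csv", "events.csv")))
    out$encoded <- file.path(d, "encoded.rds")
  } else if (subcommand == "fit-baseline") {
    cohort <- computeSojourn(readCohortDir(realDir))
    synth <- fitSeedSynthesizer(cohort,
                                minLeaf = (cfg$baseline %||% list())$min_leaf %||% 5L)
    d <- stageDir(cfg, "work")
    saveRDS(synth, file.path(d, "seed_synth.rds"))
    writeManifest(d, subcommand, cfg)
    out$seedSynth <- file.path(d, "seed_synth.rds")
  } else if (subcommand == "train") {
    enc <- readRDS(file.path(workDir, "encoded.rds"))
    model <- trainGenerator(enc, modelConfigFromConfig(cfg))
    d <- stageDir(cfg, "work")
    saveGeneratorModel(model, file.path(d, "model.rds"))
    write.csv(model@lossTrace, file.path(d, "loss_trace.csv"),
              row.names = FALSE)
    writeManifest(d, subcommand, cfg, file.path(workDir, "encoded.rds"))
    out$model <- file.path(d, "model.rds")
  } else if (subcommand == "generate") {
    g <- cfg$generate %||% list()
    model <- loadGeneratorModel(file.path(workDir, "model.rds"))
    synth <- readRDS(file.path(workDir, "seed_synth.rds"))
    n <- g$n %||% nrow(read.csv(file.path(realDir, "baseline.csv")))
    seeds <- synthesizeSeeds(synth, n, seed = childSeed(cfg$seed, "seeds"))
    syn <- generateCohort(model, seeds,
                          maxLength = g$max_length %||% 60L,
                          temperature = g$temperature %||% 1,
                          seed = childSeed(cfg$seed, "generate"))
    d <- stageDir(cfg, "synthetic")
    writeCohortDir(syn, d)
    writeManifest(d, subcommand, cfg, file.path(workDir, "model.rds"))
    out$synthetic <- d
  } else if (subcommand == "evaluate-utility") {
    u <- cfg$utility %||% list()
    real <- computeSojourn(readCohortDir(realDir))
    syn <- computeSojourn(readCohortDir(synDir))
    rep <- evaluateUtility(real, syn,
                           orders = unlist(u$orders) %||% c(1L, 2L),
                           nQueries = u$n_queries %||% 100L,
                           seed = childSeed(cfg$seed, "utility"))
    d <- stageDir(cfg, "reports")
    m <- rep@metrics
    if (!is.null(m$randomCohorts)) {
      write.csv(m$randomCohorts$log, file.path(d, "query_log.csv"),
                row.names = FALSE)
      m$randomCohorts$log <- NULL
    }
    jsonlite::write_json(m, file.path(d, "utility.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeManifest(d, subcommand, cfg)
    out$utility <- file.path(d, "utility.json")
  } else if (subcommand == "evaluate-privacy") {
    p <- cfg$privacy %||% list()
    real <- computeSojourn(readCohortDir(realDir))
    syn <- computeSojourn(readCohortDir(synDir))
    pcfg <- privacyConfig(quasiIdentifiers = unlist(p$quasi_identifiers) %||% NULL,
                          threshold = p$threshold %||% 0.09,
                          ageBand = p$age_band %||% 5,
                          sensitive = p$sensitive %||% "comorbidity")
    rep <- assessPrivacy(real, syn, pcfg)
    d <- stageDir(cfg, "reports")
    jsonlite::write_json(rep@metrics, file.path(d, "privacy.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeManifest(d, subcommand, cfg)
    out$privacy <- file.path(d, "privacy.json")
  }
  invisible(out)
}
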