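# Run configuration: defaults, YAML loading with strict validation.

default_run_config <- function() {
  structure(list(
    seed = 1L,
    verbosity = 0L,
    paths = list(data = NULL, out = NULL),
    generator = list(samples_per_class_phase = 600L, class_overlap = 0.10,
                     noise_sigma = 0.015, amplitude_sd = 0.02),
    smoothing = smoothing_config(),
    model = model_config(),
    train = train_config(),
    fractions = seq(0.1, 0.9, by = 0.1),
    reps = 5L
  ), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file with any subset of the sections `seed`, `verbosity`,
#' `paths` (`data`, `out`), `generator`, `smoothing`, `model`, `train`,
#' `fractions`, `reps`; omitted fields take the package defaults (the tuned
#' hyperparameter set).  Unknown keys and invalid values are reported
#' together, each with its field path.  An empty file yields the full
#' default configuration.
#'
#' @param path YAML file path.
#' @return object of class `"run_config"`.
#' @seealso [save_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  cfg <- default_run_config()
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)

  known_top <- c("seed", "verbosity", "paths", "generator", "smoothing",
                 "model", "train", "fractions", "reps")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown)) note(paste0("unknown key(s): ", paste(unknown, collapse = ", ")))

  merge_section <- function(section, constructor = NULL) {
    sub <- raw[[section]]
    if (is.null(sub)) return()
    cur <- unclass(cfg[[section]])
    bad <- setdiff(names(sub), names(cur))
    if (length(bad)) {
      note(paste0("unknown key(s) under '", section, "': ", paste(bad, collapse = ", ")))
      sub <- sub[setdiff(names(sub), bad)]
    }
    merged <- utils::modifyList(cur, sub)
    if (is.null(constructor)) {
      cfg[[section]] <<- merged
    } else {
      res <- tryCatch(do.call(constructor, merged[setdiff(names(merged), "seed")]),
                      error = function(e) {
                        note(paste0(section, ": ", conditionMessage(e)))
                        NULL
                      })
      if (!is.null(res)) cfg[[section]] <<- res
    }
  }

  if (!is.null(raw$seed)) {
    if (!is.numeric(raw$seed)) note("seed: must be an integer")
    else cfg$seed <- as.integer(raw$seed)
  }
  if (!is.null(raw$verbosity)) cfg$verbosity <- as.integer(raw$verbosity)
  merge_section("paths")
  merge_section("generator")
  merge_section("smoothing", smoothing_config)
  merge_section("model", model_config)
  if (!is.null(raw$train)) {
    sub <- raw$train
    cur <- unclass(cfg$train)
    bad <- setdiff(names(sub), names(cur))
    if (length(bad)) {
      note(paste0("unknown key(s) under 'train': ", paste(bad, collapse = ", ")))
      sub <- sub[setdiff(names(sub), bad)]
    }
    res <- tryCatch(do.call(train_config, utils::modifyList(cur, sub)),
                    error = function(e) { note(paste0("train: ", conditionMessage(e))); NULL })
    if (!is.null(res)) cfg$train <- res
  }
  with_gen <- cfg$generator
  if (with_gen$samples_per_class_phase < 1L)
    note("generator.samples_per_class_phase: must be >= 1")
  if (with_gen$class_overlap < 0 || with_gen$class_overlap >= 1)
    note("generator.class_overlap: must lie in [0, 1)")
  if (!is.null(raw$fractions)) {
    fr <- as.numeric(raw$fractions)
    if (any(fr <= 0 | fr >= 1)) note("fractions: must lie strictly between 0 and 1")
    else cfg$fractions <- fr
  }
  if (!is.null(raw$reps)) {
    if (raw$reps < 1) note("reps: must be >= 1") else cfg$reps <- as.integer(raw$reps)
  }
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  cfg
}

#' Save a run configuration to YAML
#' @param cfg a `run_config`.
#' @param path output YAML path.
#' @export
save_config <- function(cfg, path) {
  out <- list(seed = cfg$seed, verbosity = cfg$verbosity,
              paths = cfg$paths,
              generator = cfg$generator,
              smoothing = unclass(cfg$smoothing),
              model = unclass(cfg$model),
              train = unclass(cfg$train),
              fractions = cfg$fractions,
              reps = cfg$reps)
  yaml::write_yaml(out, path)
  invisible(path)
}

# Build a generator_config from the scalar generator section of a run_config.
generator_from_run_config <- function(cfg, seed = cfg$seed) {
  g <- cfg$generator
  generator_config(
    archetypes = default_archetypes(noise_sigma = g$noise_sigma,
                                    amplitude_sd = g$amplitude_sd),
    samples_per_class_phase = g$samples_per_class_phase,
    seed = seed,
    class_overlap = g$class_overlap)
}
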