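#' Full pipeline configuration
#'
#' One nested configuration object carrying every tunable of the pipeline
#' stages, all seeded from a single global seed (per-stage seeds are derived
#' from it and recorded in the run manifest).
#'
#' @param seed Global integer seed.
#' @param generator Arguments passed to [generator_config()] (list), or a
#'   ready-made config.
#' @param alignment Arguments passed to [alignment_config()] (list), or a
#'   ready-made config.
#' @param plausibility Named per-channel bounds (see [default_plausibility()]).
#' @param features List with `iqr_k` and `with_co`.
#' @param folds List with `k_outer`, `k_inner`.
#' @param search Arguments passed to [search_spec()] (list), or a ready-made
#'   spec.
#' @return A list of class `co2gap_pipeline_config`.
#' @export
pipeline_config <- function(seed = 42,
                            generator = list(),
                            alignment = list(),
                            plausibility = default_plausibility(),
                            features = list(iqr_k = 3, with_co = TRUE),
                            folds = list(k_outer = 7, k_inner = 6),
                            search = list()) {
  if (!is_number(seed)) stop_config("`seed` must be a single number")
  gen <- if (inherits(generator, "co2gap_generator_config")) generator else {
    check_known_keys(generator, names(formals(generator_config)), "generator")
    generator$seed <- generator$seed %||% derive_seed(seed, "generator")
    do.call(generator_config, generator)
  }
  aln <- if (inherits(alignment, "co2gap_alignment_config")) alignment else {
    check_known_keys(alignment, names(formals(alignment_config)), "alignment")
    do.call(alignment_config, alignment)
  }
  srch <- if (inherits(search, "co2gap_search_spec")) search else {
    check_known_keys(search, names(formals(search_spec)), "search")
    search$seed <- search$seed %||% derive_seed(seed, "search")
    do.call(search_spec, search)
  }
  feat <- utils::modifyList(list(iqr_k = 3, with_co = TRUE), features)
  check_known_keys(feat, c("iqr_k", "with_co"), "features")
  fld <- utils::modifyList(list(k_outer = 7, k_inner = 6), folds)
  check_known_keys(fld, c("k_outer", "k_inner"), "folds")

  cfg <- list(seed = as.integer(seed), generator = gen, alignment = aln,
              plausibility = check_plausibility(plausibility),
              features = feat, folds = fld, search = srch)
  class(cfg) <- "co2gap_pipeline_config"
  cfg
}

check_known_keys <- function(x, known, section) {
  bad <- setdiff(names(x), known)
  if (length(bad) > 0) {
    stop_config("unknown key(s) in `", section, "`: ", paste(bad, collapse = ", "))
  }
  invisible(x)
}

#' Load a pipeline configuration from a YAML file
#'
#' Missing keys take their defaults; unknown keys are rejected with the
#' offending key path. An empty file yields the all-defaults configuration.
#'
#' @param path Path to a YAML file with (optional) top-level sections `seed`,
#'   `generator`, `alignment`, `plausibility`, `features`, `folds`, `search`.
#' @return A [pipeline_config()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  check_known_keys(raw, c("seed", "generator", "alignment", "plausibility",
                          "features", "folds", "search"), "config")
  plaus <- default_plausibility()
  if (!is.null(raw$plausibility)) {
    check_known_keys(raw$plausibility, names(plaus), "plausibility")
    plaus <- utils::modifyList(plaus, lapply(raw$plausibility, as.numeric))
  }
  pipeline_config(
    seed = raw$seed %||% 42,
    generator = raw$generator %||% list(),
    alignment = raw$alignment %||% list(),
    plausibility = plaus,
    features = raw$features %||% list(),
    folds = raw$folds %||% list(),
    search = raw$search %||% list()
  )
}

#' Write a pipeline configuration to YAML
#'
#' Round-trips with [load_config()].
#'
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "co2gap_pipeline_config"))
  gen <- unclass(config$generator)
  aln <- unclass(config$alignment)
  srch <- unclass(config$search)
  out <- list(
    seed = config$seed,
    generator = gen,
    alignment = aln,
    plausibility = config$plausibility,
    features = config$features,
    folds = config$folds,
    search = srch
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
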