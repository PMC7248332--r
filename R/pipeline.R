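#' Read and validate a pipeline configuration
#'
#' YAML (or JSON) with optional blocks `population`, `simulation`,
#' `quantification` and top-level `n_neurons`, `seed`, `measure_intensity`.
#' Unknown probability values, negative densities and other invalid
#' settings fail validation before any computation runs.
#'
#' @param path path to a YAML or JSON configuration file.
#' @return a `pipeline_config`: list with `params` ([population_params()]),
#'   `cfg` ([sim_config()]), `qcfg` ([quant_config()]), `n_neurons`,
#'   `seed`, `measure_intensity`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  pipeline_config(raw)
}

#' @rdname read_pipeline_config
#' @param raw a list with the same structure as the file contents.
#' @export
pipeline_config <- function(raw = list()) {
  pp <- raw$population %||% list()
  pop_args <- list()
  for (f in c("probes", "mode"))
    if (!is.null(pp[[f]])) pop_args[[f]] <- pp[[f]]
  if (!is.null(pp$marker_proportions))
    pop_args$marker_proportions <- unlist(pp$marker_proportions)
  if (!is.null(pp$coexpr_probs))
    pop_args$coexpr_probs <- unlist(pp$coexpr_probs)
  if (!is.null(pp$expr_prob)) {
    m <- do.call(rbind, lapply(pp$expr_prob, unlist))
    pop_args$expr_prob <- m
  }
  if (!is.null(pp$condition_effects))
    pop_args$condition_effects <- as.data.frame(pp$condition_effects)
  params <- do.call(population_params, pop_args)
  sc <- raw$simulation %||% list()
  cfg <- do.call(sim_config, sc[intersect(names(sc),
    c("epsilon", "pixel_size", "roi_diameter", "density",
      "noise_sd", "detect_threshold", "seed"))])
  if (!is.null(sc$omega0)) cfg$psf <- psf_model(omega0 = sc$omega0)
  validate_sim_config(cfg)
  qc <- raw$quantification %||% list()
  qcfg <- do.call(quant_config, qc[intersect(names(qc),
    names(formals(quant_config)))])
  structure(
    list(params = params, cfg = cfg, qcfg = qcfg,
         n_neurons = as.integer(raw$n_neurons %||% 200L),
         seed = as.integer(raw$seed %||% 1L),
         measure_intensity = isTRUE(raw$measure_intensity)),
    class = "pipeline_config"
  )
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

write_csv_with_header <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header_lines), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the end-to-end pipeline
#'
#' Executes population simulation, per-neuron image rendering, spot
#' detection, quantification and the summary statistics, writing CSV
#' artifacts and a JSON run manifest to `out_dir`. Identical configuration
#' and seed reproduce byte-identical CSVs.
#'
#' Outputs: `population.csv` (per-neuron table with ground truth, detected
#' counts, calls and optional intensities), `marker_percentages.csv` (per
#' probe x marker percent positive), `size_classes.csv` (size-class
#' fractions of positive neurons per probe), `coexpression.csv`
#' (combination counts and fractions) and `manifest.json`.
#'
#' @param config a `pipeline_config`, or a path to a YAML/JSON file.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the computed tables and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  hash <- config_hash(config)
  prov <- sprintf("punctasim run; seed=%d; config=%s", seed, hash)

  pop <- sample_population(config$params, config$n_neurons, seed = seed)
  pop <- quantify_population(pop, config$cfg, config$qcfg, seed = seed,
                             measure_intensity = config$measure_intensity)
  probes <- attr(pop, "probes")

  marker_pct <- do.call(rbind, lapply(probes, function(p) {
    t <- marker_percentage_table(pop, p)
    t$probe <- p
    t[, c("probe", "marker", "n", "n_positive", "percent_positive")]
  }))
  size_cls <- do.call(rbind, lapply(probes, function(p) {
    pos <- pop[pop[[paste0("called_", p)]] == 1L, ]
    if (nrow(pos) == 0) {
      return(data.frame(probe = p, size_class = c("small", "medium", "large"),
                        count = 0L, fraction = NA_real_))
    }
    cls <- classify_size(pos$soma_area, config$qcfg)
    tab <- table(cls)
    data.frame(probe = p, size_class = names(tab),
               count = as.integer(tab),
               fraction = as.numeric(tab) / nrow(pos))
  }))
  coexpr <- coexpression_table(pop, probes)

  write_csv_with_header(as.data.frame(pop),
                        file.path(out_dir, "population.csv"), prov)
  write_csv_with_header(marker_pct,
                        file.path(out_dir, "marker_percentages.csv"), prov)
  write_csv_with_header(size_cls,
                        file.path(out_dir, "size_classes.csv"), prov)
  write_csv_with_header(coexpr,
                        file.path(out_dir, "coexpression.csv"), prov)

  manifest <- list(
    package = "punctasim",
    version = as.character(utils::packageVersion("punctasim")),
    seed = seed, config_hash = hash,
    n_neurons = config$n_neurons,
    probes = probes,
    outputs = c("population.csv", "marker_percentages.csv",
                "size_classes.csv", "coexpression.csv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(population = pop, marker_percentages = marker_pct,
                 size_classes = size_cls, coexpression = coexpr,
                 manifest = manifest))
}

#' Generate the bundled deterministic test fixtures
#'
#' Writes three small artifacts used by the test-suite and examples:
#' a 256 x 256 two-emitter rendered image (TIFF + JSON sidecar), an
#' eight-neuron population covering every three-probe combination once
#' (CSV), and a 2038-row multiplex population at the default joint
#' combination probabilities (CSV). A manifest with MD5 checksums makes
#' regressions visible.
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @return invisibly, the manifest list.
#' @export
make_fixtures <- function(seed = 1L, dir = tempfile("fixtures")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- sim_config(seed = seed, noise_sd = 0)

  # 1) two isolated emitters on a 256^2 grid (placed, not Poisson-drawn)
  counts <- matrix(0, 256, 256)
  counts[96, 96] <- 1
  counts[160, 176] <- 1
  img <- psf_render(counts, cfg)
  # trim back to 256^2 so the fixture has the advertised shape
  pad <- img$pad_px
  img <- field_image(img$pixels[(pad + 1):(pad + 256),
                                (pad + 1):(pad + 256)],
                     cfg$pixel_size, pad_px = 0L, channel = "fixture",
                     meta = list(seed = seed))
  tiff_path <- file.path(dir, "two_emitters.tiff")
  write_field_tiff(img, tiff_path)

  # 2) one neuron per combination of the three probes
  labs <- combo_labels(DEFAULT_PROBES)
  pop8 <- sample_population(population_params(), 8, seed = seed)
  for (p in DEFAULT_PROBES) {
    inset <- vapply(strsplit(labs, "+", fixed = TRUE),
                    function(s) p %in% s, logical(1))
    pop8[[paste0("truth_", p)]] <- as.integer(inset)
    pop8[[paste0("true_puncta_", p)]] <- ifelse(inset, 10L, 0L)
    pop8[[paste0("called_", p)]] <- as.integer(inset)
  }
  pop8_path <- file.path(dir, "all_combinations_population.csv")
  write_population_csv(pop8, pop8_path)

  # 3) the 2038-neuron multiplex population at default joint probabilities
  pop_path <- file.path(dir, "multiplex_population.csv")
  write_population_csv(
    sample_population(population_params(mode = "multinomial"), 2038,
                      seed = seed),
    pop_path
  )

  files <- c(tiff_path, pop8_path, pop_path)
  manifest <- list(
    seed = seed,
    artifacts = data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)))
  )
  jsonlite::write_json(manifest, file.path(dir, "fixture_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
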