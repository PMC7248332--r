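#' Parameters of a ground-truth DRG neuron population
#'
#' Bundles everything the population simulator needs: marker-class
#' proportions, per-probe expression probabilities, soma-size distributions
#' and per-cell puncta-count distributions. Two expression-generation modes
#' are supported:
#'
#' * `"bernoulli"` — each probe is expressed independently with the
#'   (marker, probe) probability in `expr_prob`; this mirrors single-probe
#'   assays where only marginal percentages are reported.
#' * `"multinomial"` — the joint expression state over all probes is drawn
#'   from the 2^P-category distribution `coexpr_probs`; this mirrors the
#'   three-probe multiplex experiment whose co-expression pie chart is
#'   reported for 2038 neurons.
#'
#' Default joint probabilities follow the reported multiplex co-expression
#' fractions (ASIC2b only 15%, ASIC3 only 14%, ASIC1a/ASIC3 20%,
#' ASIC2b/ASIC3 18%, triple positive 10%, ASIC1a only 1.5%, ASIC1a/ASIC2b
#' 0.5%, remainder negative). Default Bernoulli marginals follow the
#' reported per-marker percentages (e.g. ASIC3 in 73% of NF200+, 65% of
#' CGRP+ and 10% of IB4+ neurons).
#'
#' @param probes character vector of probe names.
#' @param mode `"multinomial"` or `"bernoulli"` (see above).
#' @param marker_proportions named numeric over
#'   `c("NF200","CGRP","IB4","unlabeled")`, summing to 1.
#' @param expr_prob numeric matrix `markers x probes` of per-probe expression
#'   probabilities (Bernoulli mode).
#' @param coexpr_probs named numeric over the `2^length(probes)` combination
#'   labels produced by [combo_labels()], summing to 1 (multinomial mode).
#' @param soma_area data.frame with columns `marker`, `mean`, `sd` (um^2);
#'   soma areas are drawn from these Gaussians truncated at 0.
#' @param puncta_pos,puncta_neg discrete distributions of the per-cell
#'   puncta count given a probe is truly expressed / not expressed: a list
#'   with `values` (integers) and `probs` (summing to 1). The defaults
#'   (uniform 5–20 when positive; 0 with probability 0.8, else 1–2) make the
#'   ">= 3 puncta" positivity rule nearly noiseless; they are stand-ins, not
#'   literature estimates, and fully configurable.
#' @param condition_effects data.frame describing nerve-injury (cuff)
#'   effects, with columns `segment`, `marker`, `probe`, and either
#'   `new_probability` or `intensity_multiplier` (unused entry `NA`). Sham
#'   animals keep naive parameters.
#' @return an object of class `population_params`.
#' @seealso [sample_population()], [apply_condition_effects()]
#' @export
population_params <- function(probes = DEFAULT_PROBES,
                              mode = c("multinomial", "bernoulli"),
                              marker_proportions = c(
                                NF200 = 0.30, CGRP = 0.25,
                                IB4 = 0.25, unlabeled = 0.20
                              ),
                              expr_prob = default_expr_prob(probes),
                              coexpr_probs = default_coexpr_probs(probes),
                              soma_area = default_soma_area(),
                              puncta_pos = list(values = 5:20,
                                                probs = rep(1 / 16, 16)),
                              puncta_neg = list(values = 0:2,
                                                probs = c(0.8, 0.1, 0.1)),
                              condition_effects = NULL) {
  mode <- match.arg(mode)
  params <- structure(
    list(
      probes = probes, mode = mode,
      marker_proportions = marker_proportions,
      expr_prob = expr_prob, coexpr_probs = coexpr_probs,
      soma_area = soma_area,
      puncta_pos = puncta_pos, puncta_neg = puncta_neg,
      condition_effects = condition_effects
    ),
    class = "population_params"
  )
  validate_population_params(params)
  params
}

#' Combination labels for a probe set
#'
#' All `2^length(probes)` co-expression categories, ordered by increasing
#' subset size then probe order; the empty combination is labelled `"none"`.
#' @param probes character vector of probe names.
#' @return character vector of length `2^length(probes)`.
#' @export
combo_labels <- function(probes = DEFAULT_PROBES) {
  p <- length(probes)
  sets <- lapply(0:(2^p - 1), function(bits) probes[bitwAnd(bits, 2^(seq_len(p) - 1)) > 0])
  labs <- vapply(sets, function(s) if (length(s) == 0) "none" else paste(s, collapse = "+"),
                 character(1))
  labs[order(lengths(sets), match(labs, labs))]
}

default_coexpr_probs <- function(probes = DEFAULT_PROBES) {
  if (!identical(probes, DEFAULT_PROBES)) {
    labs <- combo_labels(probes)
    return(stats::setNames(rep(1 / length(labs), length(labs)), labs))
  }
  c("none" = 0.21,
    "ASIC1a" = 0.015, "ASIC2b" = 0.15, "ASIC3" = 0.14,
    "ASIC1a+ASIC2b" = 0.005, "ASIC1a+ASIC3" = 0.20, "ASIC2b+ASIC3" = 0.18,
    "ASIC1a+ASIC2b+ASIC3" = 0.10)
}

default_expr_prob <- function(probes = DEFAULT_PROBES) {
  full <- matrix(
    c(0.70, 0.80, 0.73,   # NF200
      0.28, 1.00, 0.65,   # CGRP
      0.00, 1.00, 0.10,   # IB4
      0.35, 0.50, 0.60),  # unlabeled
    nrow = 4, byrow = TRUE,
    dimnames = list(DRG_MARKERS, DEFAULT_PROBES)
  )
  if (all(probes %in% DEFAULT_PROBES)) return(full[, probes, drop = FALSE])
  matrix(0.5, nrow = 4, ncol = length(probes),
         dimnames = list(DRG_MARKERS, probes))
}

default_soma_area <- function() {
  data.frame(
    marker = DRG_MARKERS,
    mean = c(900, 420, 380, 500),
    sd = c(250, 120, 100, 150)
  )
}

#' Validate population parameters
#'
#' Checks every probability lies in \[0, 1\], that probability maps sum to 1
#' (tolerance 1e-9) and that soma-area standard deviations are positive;
#' errors name the offending entry.
#' @param params a `population_params` object.
#' @return `params`, invisibly.
#' @export
validate_population_params <- function(params) {
  mp <- params$marker_proportions
  if (!setequal(names(mp), DRG_MARKERS))
    stop_param("marker_proportions must be named over: %s",
               paste(DRG_MARKERS, collapse = ", "))
  check_probs <- function(x, what) {
    bad <- which(!is.finite(x) | x < 0 | x > 1)
    if (length(bad))
      stop_param("%s has probability outside [0, 1]: %s",
                 what, paste(names(x)[bad] %||% bad, collapse = ", "))
  }
  check_probs(mp, "marker_proportions")
  if (abs(sum(mp) - 1) > 1e-9)
    stop_param("marker_proportions must sum to 1 (got %.12f)", sum(mp))
  ep <- params$expr_prob
  if (!is.matrix(ep) || !identical(rownames(ep), DRG_MARKERS) ||
      !identical(colnames(ep), params$probes))
    stop_param("expr_prob must be a markers x probes matrix")
  for (m in rownames(ep)) check_probs(stats::setNames(ep[m, ], colnames(ep)),
                                      sprintf("expr_prob[%s, ]", m))
  if (params$mode == "multinomial") {
    cp <- params$coexpr_probs
    expected <- combo_labels(params$probes)
    if (!setequal(names(cp), expected))
      stop_param("coexpr_probs must be named over the %d combination labels",
                 length(expected))
    check_probs(cp, "coexpr_probs")
    if (abs(sum(cp) - 1) > 1e-9)
      stop_param("coexpr_probs must sum to 1 (got %.12f)", sum(cp))
  }
  sa <- params$soma_area
  if (any(!is.finite(sa$sd) | sa$sd <= 0))
    stop_param("soma_area sd must be > 0 (offending marker: %s)",
               paste(sa$marker[!is.finite(sa$sd) | sa$sd <= 0], collapse = ", "))
  if (any(!is.finite(sa$mean) | sa$mean <= 0))
    stop_param("soma_area mean must be > 0")
  for (d in list(pos = params$puncta_pos, neg = params$puncta_neg)) {
    if (abs(sum(d$probs) - 1) > 1e-9 || any(d$probs < 0))
      stop_param("puncta-count distribution probabilities must be a simplex")
    if (any(d$values < 0 | d$values != round(d$values)))
      stop_param("puncta-count support must be non-negative integers")
  }
  ce <- params$condition_effects
  if (!is.null(ce)) {
    need <- c("segment", "marker", "probe")
    if (!all(need %in% names(ce)))
      stop_param("condition_effects needs columns: %s", paste(need, collapse = ", "))
    bad_probe <- setdiff(ce$probe, params$probes)
    if (length(bad_probe))
      stop_param("condition_effects references unknown probe: %s",
                 paste(bad_probe, collapse = ", "))
    bad_marker <- setdiff(unlist(strsplit(ce$marker, "+", fixed = TRUE)),
                          DRG_MARKERS)
    if (length(bad_marker))
      stop_param("condition_effects references unknown marker: %s",
                 paste(bad_marker, collapse = ", "))
    np <- ce$new_probability %||% rep(NA_real_, nrow(ce))
    if (any(!is.na(np) & (np < 0 | np > 1)))
      stop_param("condition_effects new_probability outside [0, 1]")
  }
  invisible(params)
}

sample_discrete <- function(n, dist) {
  if (n == 0) return(integer(0))
  dist$values[sample.int(length(dist$values), n, replace = TRUE,
                         prob = dist$probs)]
}

rtruncnorm_pos <- function(n, mean, sd) {
  # Gaussian truncated at 0 by inverse-CDF; sd stays well below mean for all
  # defaults so this is numerically benign.
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (1 - lo), mean, sd)
}

#' Simulate a ground-truth population of DRG neurons
#'
#' Draws `n` neurons: marker class from the multinomial
#' `marker_proportions`, true per-probe expression state (joint multinomial
#' or independent Bernoulli depending on `params$mode`), per-probe true
#' puncta counts from the positive/negative count distributions, and soma
#' area from the marker-specific truncated Gaussian.
#'
#' @param params a [population_params()] object.
#' @param n number of neurons (>= 1).
#' @param seed integer seed; identical seeds reproduce the table exactly.
#' @param condition experimental condition label stored on each record.
#' @param segment DRG segment label stored on each record.
#' @return a `data.frame` of class `neuron_population`, one row per neuron,
#'   with columns `id`, `marker`, `segment`, `condition`, `soma_area`, and
#'   per probe `truth_<probe>` (0/1 ground-truth expression),
#'   `true_puncta_<probe>` (ground-truth transcript count) and
#'   `eps_mult_<probe>` (per-cell emitter-brightness multiplier, 1 unless a
#'   condition effect applies). Columns `puncta_<probe>`, `called_<probe>`
#'   and `intensity_<probe>` are added by [quantify_population()].
#' @export
sample_population <- function(params, n, seed = 1L,
                              condition = "naive", segment = "pooled") {
  validate_population_params(params)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop_param("n must be a positive integer")
  n <- as.integer(n)
  probes <- params$probes
  withr::with_seed(derive_seed(seed, "sample_population"), {
    marker <- sample(names(params$marker_proportions), n, replace = TRUE,
                     prob = params$marker_proportions)
    truth <- matrix(FALSE, n, length(probes),
                    dimnames = list(NULL, probes))
    if (params$mode == "multinomial") {
      labs <- combo_labels(probes)
      combo <- sample(labs, n, replace = TRUE,
                      prob = params$coexpr_probs[labs])
      for (p in probes) {
        truth[, p] <- vapply(strsplit(combo, "+", fixed = TRUE),
                             function(s) p %in% s, logical(1))
      }
    } else {
      for (p in probes) {
        truth[, p] <- stats::runif(n) < params$expr_prob[marker, p]
      }
    }
    true_puncta <- matrix(0L, n, length(probes),
                          dimnames = list(NULL, probes))
    for (p in probes) {
      pos <- truth[, p]
      true_puncta[pos, p] <- sample_discrete(sum(pos), params$puncta_pos)
      true_puncta[!pos, p] <- sample_discrete(sum(!pos), params$puncta_neg)
    }
    sa <- params$soma_area
    idx <- match(marker, sa$marker)
    soma_area <- rtruncnorm_pos(n, sa$mean[idx], sa$sd[idx])
  })
  pop <- data.frame(
    id = seq_len(n), marker = marker,
    segment = segment, condition = condition,
    soma_area = soma_area,
    stringsAsFactors = FALSE
  )
  for (p in probes) {
    pop[[paste0("truth_", p)]] <- as.integer(truth[, p])
    pop[[paste0("true_puncta_", p)]] <- true_puncta[, p]
    pop[[paste0("eps_mult_", p)]] <- 1
  }
  structure(pop, probes = probes, class = c("neuron_population", "data.frame"))
}

#' Apply nerve-injury condition effects to a simulated population
#'
#' Relabels the population with the given condition and segment and, for
#' `condition = "cuff"`, applies each matching row of
#' `params$condition_effects`: a `new_probability` redraws the ground-truth
#' expression state (and puncta count) of that probe in neurons of the
#' listed marker with the altered Bernoulli probability; an
#' `intensity_multiplier` scales the emitter brightness (`eps_mult_<probe>`)
#' of truly expressing neurons. Sham populations keep naive parameters, so
#' sham output is statistically identical to the input. Effects whose
#' `segment` differs from `segment` are ignored, which is how
#' segment-specific regulation (e.g. L4-only changes) is modelled.
#'
#' The `marker` field of an effect may also be a `+`-joined set (e.g.
#' `"CGRP+IB4"`) to target several classes at once.
#'
#' @param pop a `neuron_population` from [sample_population()].
#' @param params the [population_params()] holding `condition_effects`.
#' @param condition `"sham"` or `"cuff"`.
#' @param segment segment label of this population (e.g. `"L4"`).
#' @param seed integer seed for the redraws.
#' @return the modified population.
#' @export
apply_condition_effects <- function(pop, params, condition, segment,
                                    seed = 1L) {
  if (!condition %in% c("sham", "cuff"))
    stop_param("condition must be 'sham' or 'cuff'")
  validate_population_params(params)
  probes <- attr(pop, "probes")
  pop$condition <- condition
  pop$segment <- segment
  ce <- params$condition_effects
  if (condition == "sham" || is.null(ce) || nrow(ce) == 0) return(pop)
  withr::with_seed(derive_seed(seed, paste0("effects_", segment)), {
    for (i in seq_len(nrow(ce))) {
      if (ce$segment[i] != segment) next
      markers <- strsplit(ce$marker[i], "+", fixed = TRUE)[[1]]
      p <- ce$probe[i]
      if (!p %in% probes)
        stop_param("condition effect references unknown probe '%s'", p)
      rows <- which(pop$marker %in% markers)
      np <- (ce$new_probability %||% NA_real_)[i]
      if (!is.na(np)) {
        truth <- stats::runif(length(rows)) < np
        pop[[paste0("truth_", p)]][rows] <- as.integer(truth)
        counts <- integer(length(rows))
        counts[truth] <- sample_discrete(sum(truth), params$puncta_pos)
        counts[!truth] <- sample_discrete(sum(!truth), params$puncta_neg)
        pop[[paste0("true_puncta_", p)]][rows] <- counts
      }
      im <- (ce$intensity_multiplier %||% NA_real_)[i]
      if (!is.na(im)) {
        pos <- rows[pop[[paste0("truth_", p)]][rows] == 1L]
        pop[[paste0("eps_mult_", p)]][pos] <-
          pop[[paste0("eps_mult_", p)]][pos] * im
      }
    }
  })
  pop
}

#' Write / read a neuron population as CSV
#'
#' One row per neuron, booleans encoded 0/1; a commented provenance header
#' records the probe set.
#' @param pop a `neuron_population`.
#' @param path file path.
#' @return `path` (write) or the population (read).
#' @export
write_population_csv <- function(pop, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# punctasim neuron population; probes: %s",
                     paste(attr(pop, "probes"), collapse = ",")), con)
  utils::write.csv(as.data.frame(pop), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path) {
  header <- readLines(path, n = 1L)
  probes <- strsplit(sub(".*probes: ", "", header), ",")[[1]]
  pop <- utils::read.csv(path, comment.char = "#")
  structure(pop, probes = probes,
            class = c("neuron_population", "data.frame"))
}
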