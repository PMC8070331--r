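#' Configure a simulated quantification study
#'
#' Bundles the drug library, instrument mode, calibration design, validation
#' design and simulation conditions for [run_calibration_study()] and
#' [run_validation_study()]. Defaults reproduce the built-in study designs:
#' five standard levels in triplicate; recovery by standard addition at
#' three spike sizes onto a fixed sample aliquot; precision over three
#' levels (low/mid/high quality control) x three days x three replicates;
#' robustness at sample masses nominal -2, 0, +2 mg; assay of a formulation
#' simulated at a nominal concentration inside the calibrated range.
#'
#' @param drug `"DOX"`, `"ALM"`, or a [drug_library()].
#' @param mode `"transmittance"` or `"reflectance"`.
#' @param levels Calibration levels, %w/w (default: the library's).
#' @param replicates Replicates per calibration level.
#' @param recovery Tibble with columns `cu`, `ca` (mg per 100 mg mix),
#'   `"auto"` for the drug's built-in design, or `NULL` to skip the section.
#' @param precision_days,precision_replicates Precision grid shape; set
#'   `precision_days = NULL` to skip.
#' @param robustness_deltas Mass perturbations in mg, or `NULL` to skip.
#' @param assay_nominal_conc Nominal formulation concentration, %w/w:
#'   `"auto"` for the middle calibration level, or `NULL` to skip the assay.
#' @param label_claim_mg Labelled content of the simulated dosage unit.
#' @param day_effect_sd Fractional between-day response shift (sd of a
#'   multiplicative day factor) in the precision simulation.
#' @param sim A [sim_config()]; its `seed` is overridden by `seed`.
#' @param seed Integer master seed for every stochastic step.
#' @return A `study_config` object.
#' @export
study_config <- function(drug = c("DOX", "ALM"),
                         mode = c("transmittance", "reflectance"),
                         levels = NULL, replicates = 3L,
                         recovery = "auto",
                         precision_days = 3L, precision_replicates = 3L,
                         robustness_deltas = c(-2, 0, 2),
                         assay_nominal_conc = "auto",
                         label_claim_mg = NULL,
                         day_effect_sd = 0.003,
                         sim = sim_config(),
                         seed = 1L) {
  if (is.character(drug)) {
    drug <- match.arg(drug)
    lib <- switch(drug, DOX = dox_library(), ALM = alm_library())
    if (identical(recovery, "auto")) {
      recovery <- switch(drug,
        DOX = tibble::tibble(cu = 0.5, ca = c(0.1, 0.5, 0.9)),
        ALM = tibble::tibble(cu = 0.15, ca = c(0.05, 0.45, 0.85)))
    }
    if (is.null(label_claim_mg)) {
      label_claim_mg <- switch(drug, DOX = 10, ALM = 150)
    }
  } else if (inherits(drug, "drug_library")) {
    lib <- drug
    if (identical(recovery, "auto")) recovery <- NULL
    if (is.null(label_claim_mg)) label_claim_mg <- 100
  } else {
    stop("`drug` must be \"DOX\", \"ALM\", or a drug_library", call. = FALSE)
  }
  mode <- match.arg(mode)
  if (is.null(levels)) levels <- lib$calibration_levels
  if (identical(assay_nominal_conc, "auto")) {
    assay_nominal_conc <- levels[ceiling(length(levels) / 2)]
  }
  stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(
    list(library = lib, mode = mode, levels = levels,
         replicates = as.integer(replicates), recovery = recovery,
         precision_days = precision_days,
         precision_replicates = precision_replicates,
         robustness_deltas = robustness_deltas,
         assay_nominal_conc = assay_nominal_conc,
         label_claim_mg = label_claim_mg,
         day_effect_sd = day_effect_sd,
         sim = sim, seed = as.integer(seed)),
    class = "study_config"
  )
}

cfg_sim <- function(cfg, seed_offset = 0L) {
  s <- cfg$sim
  s$seed <- cfg$seed + seed_offset
  s
}

#' Run a simulated calibration study
#'
#' Simulates replicate standard spectra, quantifies each to a band area over
#' the library's analytical window, fits the standard plot on the per-level
#' mean areas, and retains one calibration fit per replicate set so the
#' intercept standard deviation for the detection limits can be formed.
#'
#' @param cfg A [study_config()].
#' @param points Optional measured calibration table (columns
#'   `concentration`, `area`, optional `replicate`): when given, no spectra
#'   are simulated and the fits run directly on the table.
#' @return List with `model` (the [fit_calibration()] fit on level means,
#'   with `sigma_intercept` filled in when replicate fits exist),
#'   `replicate_models`, `areas` (tibble `level`, `replicate`, `area`), and
#'   `truth` (`NULL` for measured input).
#' @export
run_calibration_study <- function(cfg, points = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  if (!is.null(points)) {
    points <- tibble::as_tibble(points)
    if (!"replicate" %in% names(points)) points$replicate <- 1L
    areas <- tibble::tibble(level = points$concentration,
                            replicate = points$replicate,
                            area = points$area)
    truth <- NULL
  } else {
    set <- generate_calibration_set(cfg$library, cfg$levels, cfg$replicates,
                                    cfg$mode, cfg_sim(cfg, 0L))
    w <- cfg$library$analytical_window
    areas <- set$design
    areas$area <- vapply(set$spectra, function(s) quantify(s, w)$value,
                         numeric(1))
    truth <- set$truth
  }
  means <- stats::aggregate(area ~ level, data = as.data.frame(areas), FUN = mean)
  model <- fit_calibration(tibble::tibble(concentration = means$level,
                                          area = means$area))
  reps <- sort(unique(areas$replicate))
  replicate_models <- NULL
  if (length(reps) >= 2L &&
      all(vapply(reps, function(r) sum(areas$replicate == r) >= 3L, logical(1)))) {
    replicate_models <- lapply(reps, function(r) {
      sub <- areas[areas$replicate == r, , drop = FALSE]
      fit_calibration(tibble::tibble(concentration = sub$level, area = sub$area))
    })
    model$sigma_intercept <- replicate_intercept_sd(replicate_models)
  }
  list(model = model, replicate_models = replicate_models,
       areas = tibble::as_tibble(areas), truth = truth)
}

#' Run a full simulated validation study
#'
#' Executes the whole ICH Q2(R1) battery on simulated spectra: linearity
#' (calibration), accuracy (both recovery formulas on a standard-addition
#' design), repeatability and intermediate precision, detection and
#' quantitation limits from the replicate-intercept sigma, robustness to
#' sample-mass perturbation, and a formulation assay against label claim.
#' Any design section set to `NULL` in the configuration is marked
#' `"not performed"` and the run continues.
#'
#' @param cfg A [study_config()].
#' @return A `validation_report`: named list of section results plus the
#'   configuration echo (`drug`, `mode`, `seed`).
#' @export
run_validation_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  lib <- cfg$library
  w <- lib$analytical_window
  gen <- switch(cfg$mode,
                transmittance = generate_transmittance_spectrum,
                reflectance = generate_reflectance_spectrum)
  cal <- run_calibration_study(cfg)
  model <- cal$model
  measure <- function(conc, sim) {
    predict_concentration(model, quantify(gen(lib, conc, sim), w)$value)$concentration
  }

  linearity <- list(
    slope = model$slope, intercept = model$intercept, r2 = model$r2,
    n_points = model$n_points, conc_range = model$conc_range
  )

  lodloq <- if (is.finite(model$sigma_intercept)) {
    c(lod_loq(model$sigma_intercept, model$slope),
      list(sigma_intercept = model$sigma_intercept))
  } else "not performed"

  accuracy <- if (is.null(cfg$recovery)) "not performed" else {
    des <- tibble::as_tibble(cfg$recovery)
    sim <- cfg_sim(cfg, 1L); sim_free <- sim; sim_free$seed <- NULL
    rows <- with_sim_seed(sim$seed, {
      lapply(seq_len(nrow(des)), function(i) {
        total <- des$cu[[i]] + des$ca[[i]] # mg per 100 mg mix == %w/w
        cv <- vapply(seq_len(3L), function(r) measure(total, sim_free), numeric(1))
        tibble::tibble(
          cu = des$cu[[i]], ca = des$ca[[i]], cv_mean = mean(cv),
          recovery_overall = mean(recovery_overall(des$cu[[i]], des$ca[[i]], cv)),
          recovery_standard_addition =
            mean(recovery_standard_addition(des$cu[[i]], des$ca[[i]], cv)),
          rsd = percent_rsd(cv)
        )
      })
    })
    do.call(rbind, rows)
  }

  precision <- if (is.null(cfg$precision_days)) "not performed" else {
    qc_levels <- cfg$levels[unique(c(1L, ceiling(length(cfg$levels) / 2),
                                     length(cfg$levels)))]
    sim <- cfg_sim(cfg, 2L); sim_free <- sim; sim_free$seed <- NULL
    grid <- with_sim_seed(sim$seed, {
      do.call(rbind, lapply(seq_len(cfg$precision_days), function(d) {
        day_factor <- 1 + stats::rnorm(1, 0, cfg$day_effect_sd)
        do.call(rbind, lapply(qc_levels, function(lv) {
          vals <- vapply(seq_len(cfg$precision_replicates),
                         function(r) measure(lv * day_factor, sim_free),
                         numeric(1))
          data.frame(level = lv, day = d, replicate = seq_along(vals),
                     value = vals)
        }))
      }))
    })
    c(precision_summary(grid), list(grid = tibble::as_tibble(grid)))
  }

  robustness <- if (is.null(cfg$robustness_deltas)) "not performed" else {
    qc_levels <- cfg$levels[unique(c(1L, ceiling(length(cfg$levels) / 2),
                                     length(cfg$levels)))]
    nominal <- cfg$sim$nominal_mass[[cfg$mode]]
    sim <- cfg_sim(cfg, 3L); sim_free <- sim; sim_free$seed <- NULL
    res <- with_sim_seed(sim$seed, {
      do.call(rbind, lapply(qc_levels, function(lv) {
        do.call(rbind, lapply(cfg$robustness_deltas, function(dm) {
          s <- sim_free; s$mixture_mass <- nominal + dm
          data.frame(level = lv, mix_mass_mg = nominal + dm,
                     value = measure(lv, s))
        }))
      }))
    })
    c(list(summary = robustness_summary(res)),
      list(results = tibble::as_tibble(res)))
  }

  assay <- if (is.null(cfg$assay_nominal_conc)) "not performed" else {
    sim <- cfg_sim(cfg, 4L); sim_free <- sim; sim_free$seed <- NULL
    found <- with_sim_seed(sim$seed, {
      vapply(seq_len(5L), function(r) {
        s <- generate_formulation_spectrum(lib, cfg$assay_nominal_conc,
                                           mode = cfg$mode, cfg = sim_free)
        predict_concentration(model, quantify(s, w)$value)$concentration
      }, numeric(1))
    })
    per_rep <- assay_formulation(found, cfg$assay_nominal_conc, cfg$label_claim_mg)
    list(amount_found_mg = mean(per_rep$amount_found),
         amount_found_sd = stats::sd(per_rep$amount_found),
         label_claim_mg = cfg$label_claim_mg,
         purity_pct = mean(per_rep$purity_pct),
         purity_sd = stats::sd(per_rep$purity_pct),
         n = length(found))
  }

  structure(
    list(drug = lib$name, mode = cfg$mode, seed = cfg$seed,
         linearity = linearity, accuracy = accuracy, precision = precision,
         lod_loq = lodloq, robustness = robustness, assay = assay,
         calibration = cal),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  f3 <- function(v) formatC(v, format = "f", digits = 3)
  cat(sprintf("Validation report: %s (%s mode, seed %d)\n", x$drug, x$mode, x$seed))
  cat(sprintf("  Linearity: area = %s * conc + %s, r2 = %s (n = %d, range %s-%s %%w/w)\n",
              f3(x$linearity$slope), f3(x$linearity$intercept), f3(x$linearity$r2),
              x$linearity$n_points, f3(x$linearity$conc_range[1]),
              f3(x$linearity$conc_range[2])))
  if (is.character(x$accuracy)) cat("  Accuracy: not performed\n") else {
    cat("  Accuracy (overall / standard-addition %recovery, %RSD):\n")
    for (i in seq_len(nrow(x$accuracy))) {
      a <- x$accuracy[i, ]
      cat(sprintf("    cu %s + ca %s: %s / %s (%s)\n", f3(a$cu), f3(a$ca),
                  f3(a$recovery_overall), f3(a$recovery_standard_addition),
                  f3(a$rsd)))
    }
  }
  if (is.character(x$precision)) cat("  Precision: not performed\n") else {
    p <- x$precision$per_level
    for (i in seq_len(nrow(p))) {
      cat(sprintf("  Precision level %s: intra-day %%RSD %s, inter-day %%RSD %s\n",
                  f3(p$level[i]), f3(p$intra_day_rsd[i]), f3(p$inter_day_rsd[i])))
    }
  }
  if (is.character(x$lod_loq)) cat("  LOD/LOQ: not performed\n") else {
    cat(sprintf("  LOD %s, LOQ %s %%w/w (sigma %s)\n", f3(x$lod_loq$lod),
                f3(x$lod_loq$loq), f3(x$lod_loq$sigma_intercept)))
  }
  if (is.character(x$robustness)) cat("  Robustness: not performed\n") else {
    r <- x$robustness$summary
    cat(sprintf("  Robustness %%RSD by level: %s\n",
                paste(sprintf("%s: %s", f3(r$level), f3(r$rsd)), collapse = ", ")))
  }
  if (is.character(x$assay)) cat("  Assay: not performed\n") else {
    cat(sprintf("  Assay: %s mg found of %s mg claim, purity %s%% (SD %s)\n",
                f3(x$assay$amount_found_mg), f3(x$assay$label_claim_mg),
                f3(x$assay$purity_pct), f3(x$assay$purity_sd)))
  }
  invisible(x)
}

#' Write a validation report to JSON
#'
#' Serialises every section at full numeric precision. The report layout is
#' described by the JSON schema shipped at
#' `system.file("schema", "validation_report.json", package = "mirquant")`.
#'
#' @param report A [run_validation_study()] report.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  out <- report[c("drug", "mode", "seed", "linearity", "accuracy",
                  "precision", "lod_loq", "robustness", "assay")]
  if (!is.character(out$precision)) out$precision$grid <- NULL
  if (!is.character(out$robustness)) out$robustness$results <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
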