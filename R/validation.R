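#' Percent relative standard deviation
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation — the precision
#' metric used throughout ICH Q2(R1) validation. Scale-invariant: multiplying
#' every value by a positive constant leaves it unchanged.
#'
#' @param values Numeric vector, length >= 2, with nonzero mean.
#' @return %RSD as a single number.
#' @export
percent_rsd <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("at least 2 values required for %RSD", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("mean is zero; %RSD undefined", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Overall recovery: measured total over nominal total
#'
#' `100 * Cv / (Cu + Ca)` — the fraction of the total drug present (sample
#' plus spike) that the method measures back. This is the statistic that
#' published recovery tables for these methods tabulate.
#'
#' @param cu Drug amount already present, mg per 100 mg mix.
#' @param ca Drug amount added (spike), mg per 100 mg mix.
#' @param cv Total drug amount measured after addition, mg per 100 mg mix.
#' @return % recovery (vectorised over the inputs).
#' @seealso [recovery_standard_addition()] for the spike-only formula; the
#'   two coincide (both 100%) exactly when `cv == cu + ca`.
#' @export
recovery_overall <- function(cu, ca, cv) {
  check_recovery_args(cu, ca, cv, require_ca = FALSE)
  if (any(cu + ca <= 0)) stop("cu + ca must be > 0", call. = FALSE)
  100 * cv / (cu + ca)
}

#' Standard-addition recovery of the spike
#'
#' `100 * (Cv - Cu) / Ca` — the fraction of the *added* drug recovered,
#' attributing the pre-existing amount Cu to the sample. This is the textbook
#' standard-addition formula; it differs from [recovery_overall()] whenever
#' the unspiked measurement does not recover Cu exactly, and both are
#' reported side by side rather than silently reconciled.
#'
#' @inheritParams recovery_overall
#' @return % recovery of the addition (vectorised).
#' @export
recovery_standard_addition <- function(cu, ca, cv) {
  check_recovery_args(cu, ca, cv, require_ca = TRUE)
  100 * (cv - cu) / ca
}

check_recovery_args <- function(cu, ca, cv, require_ca) {
  stopifnot(is.numeric(cu), is.numeric(ca), is.numeric(cv))
  if (any(cu < 0) || any(cv < 0)) stop("cu and cv must be >= 0", call. = FALSE)
  if (require_ca && any(ca <= 0)) stop("ca must be > 0 for standard addition", call. = FALSE)
  if (!require_ca && any(ca < 0)) stop("ca must be >= 0", call. = FALSE)
  invisible(TRUE)
}

#' Drug mass contributed by stock-mixture aliquots
#'
#' Gravimetric bookkeeping for powder standards: stocks are drug-in-KBr
#' mixtures at a fixed drug mass fraction (a "1:10 w/w" stock carries 0.10 mg
#' drug per mg of stock, "1:20 w/w" carries 0.05), and aliquots of one or
#' more stocks are diluted with KBr to a total mix mass.
#'
#' @param aliquot_mg Numeric vector of stock aliquot masses, mg.
#' @param stock_ratio Numeric vector (recycled) of drug mass fractions of the
#'   stocks, in (0, 1); e.g. 0.10 for a 1:10 w/w drug:mix stock, 0.05 for
#'   1:20 w/w.
#' @param total_mix_mg Total mass of the final mix, mg (default 100).
#' @return List with `drug_mg` (total drug mass in the mix, mg) and
#'   `conc_pct_ww` (drug concentration of the mix, %w/w).
#' @examples
#' mix_mass_to_concentration(3.0, 0.05)           # 0.15 mg in 100 mg
#' mix_mass_to_concentration(c(5, 1), 0.10)       # sample + spike aliquots
#' @export
mix_mass_to_concentration <- function(aliquot_mg, stock_ratio, total_mix_mg = 100) {
  stopifnot(is.numeric(aliquot_mg), is.numeric(stock_ratio),
            is.numeric(total_mix_mg), length(total_mix_mg) == 1L)
  if (any(aliquot_mg <= 0) || total_mix_mg <= 0) {
    stop("masses must be > 0", call. = FALSE)
  }
  if (any(stock_ratio <= 0) || any(stock_ratio >= 1)) {
    stop("stock_ratio is a drug mass fraction in (0, 1)", call. = FALSE)
  }
  if (sum(aliquot_mg) > total_mix_mg) {
    stop("aliquots exceed the total mix mass", call. = FALSE)
  }
  drug <- sum(aliquot_mg * stock_ratio)
  list(drug_mg = drug, conc_pct_ww = 100 * drug / total_mix_mg)
}

#' Intra- and inter-day precision summary
#'
#' Repeatability (intra-day) and intermediate precision (inter-day) per
#' concentration level. Intra-day pools each day's repeated sessions into
#' one same-day replicate set and computes SD and %RSD per (level, day); the
#' per-level intra-day figures are the means of those per-day statistics.
#' Inter-day statistics are computed over all values of a level across days.
#'
#' @param grid A data frame with numeric columns `level`, `value` and a `day`
#'   column (any type); one row per measurement. Each (level, day) needs
#'   >= 2 replicates and each level >= 2 days.
#' @return List with `per_level` (tibble: `level`, `intra_day_sd`,
#'   `intra_day_rsd`, `inter_day_sd`, `inter_day_rsd`, `n`) and `per_day`
#'   (tibble: `level`, `day`, `sd`, `rsd`, `n`).
#' @export
precision_summary <- function(grid) {
  grid <- as.data.frame(grid)
  if (!all(c("level", "day", "value") %in% names(grid))) {
    stop("`grid` needs columns level, day, value", call. = FALSE)
  }
  levels_ <- sort(unique(grid$level))
  per_day <- do.call(rbind, lapply(levels_, function(lv) {
    gl <- grid[grid$level == lv, , drop = FALSE]
    days <- unique(gl$day)
    if (length(days) < 2L) {
      stop(sprintf("level %g has fewer than 2 days", lv), call. = FALSE)
    }
    do.call(rbind, lapply(days, function(d) {
      v <- gl$value[gl$day == d]
      if (length(v) < 2L) {
        stop(sprintf("level %g, day %s has fewer than 2 replicates", lv, d),
             call. = FALSE)
      }
      data.frame(level = lv, day = as.character(d),
                 sd = stats::sd(v), rsd = percent_rsd(v), n = length(v))
    }))
  }))
  per_level <- do.call(rbind, lapply(levels_, function(lv) {
    gl <- grid[grid$level == lv, , drop = FALSE]
    pd <- per_day[per_day$level == lv, , drop = FALSE]
    data.frame(
      level = lv,
      intra_day_sd = mean(pd$sd),
      intra_day_rsd = mean(pd$rsd),
      inter_day_sd = stats::sd(gl$value),
      inter_day_rsd = percent_rsd(gl$value),
      n = nrow(gl)
    )
  }))
  list(per_level = tibble::as_tibble(per_level),
       per_day = tibble::as_tibble(per_day))
}

#' Robustness to sample-mass perturbation
#'
#' %RSD of the measured response across deliberate mixture-mass variants
#' (nominally -2, 0, +2 mg around the method's pellet or cup mass), per
#' concentration level. Computed on predicted concentration by default
#' (mass perturbation propagates through the whole quantification chain);
#' raw band area can be summarised the same way by passing it as `value`.
#'
#' @param results Data frame with numeric columns `level`, `mix_mass_mg`,
#'   `value`; >= 2 mass variants per level.
#' @return Tibble with `level`, `sd`, `rsd`, `n_masses`.
#' @export
robustness_summary <- function(results) {
  results <- as.data.frame(results)
  if (!all(c("level", "mix_mass_mg", "value") %in% names(results))) {
    stop("`results` needs columns level, mix_mass_mg, value", call. = FALSE)
  }
  levels_ <- sort(unique(results$level))
  out <- do.call(rbind, lapply(levels_, function(lv) {
    rl <- results[results$level == lv, , drop = FALSE]
    if (length(unique(rl$mix_mass_mg)) < 2L) {
      stop(sprintf("level %g has fewer than 2 mass variants", lv), call. = FALSE)
    }
    data.frame(level = lv, sd = stats::sd(rl$value),
               rsd = percent_rsd(rl$value), n_masses = length(unique(rl$mix_mass_mg)))
  }))
  tibble::as_tibble(out)
}

#' Formulation assay against label claim
#'
#' Scales the label claim by measured over nominal concentration:
#' `amount_found = label_claim * measured / nominal`; purity is
#' `100 * amount_found / label_claim`. Dimensionally invariant to the unit
#' the masses are expressed in.
#'
#' @param measured_conc Measured drug concentration of the assay mix, %w/w.
#' @param nominal_conc Nominal (label-implied) concentration, %w/w, > 0.
#' @param label_claim Labelled drug content per dosage unit, mg, > 0.
#' @return List with `amount_found` (mg), `label_claim` (mg), `purity_pct`.
#' @examples
#' assay_formulation(0.9283, 1.0, 10)  # 92.83% purity
#' @export
assay_formulation <- function(measured_conc, nominal_conc, label_claim) {
  stopifnot(is.numeric(measured_conc), is.numeric(nominal_conc),
            is.numeric(label_claim))
  if (any(nominal_conc <= 0) || any(label_claim <= 0) || any(measured_conc < 0)) {
    stop("nominal_conc and label_claim must be > 0; measured_conc >= 0",
         call. = FALSE)
  }
  amount <- label_claim * measured_conc / nominal_conc
  list(amount_found = amount, label_claim = label_claim,
       purity_pct = 100 * amount / label_claim)
}
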