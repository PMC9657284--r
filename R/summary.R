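# Group-level descriptive and mixed-model summaries.

#' Descriptive summaries of per-stride variables
#'
#' Median, interquartile range and stride count per grouping cell for every
#' numeric stride variable, pooling strides within the cell (the pooled-
#' stride convention: each stride is one observation).
#'
#' @param stride_table tibble of per-stride rows (e.g. the `strides`
#'   element of [analyze_trial()], possibly stacked over horses with
#'   identifier columns added).
#' @param keys character vector of grouping columns (e.g.
#'   `c("breed", "gait", "condition")`).
#' @return tibble, one row per group x variable: `variable`, `median`,
#'   `iqr`, `n_strides`. Empty groups are omitted.
#' @export
describe_strides <- function(stride_table, keys) {
  stopifnot(all(keys %in% names(stride_table)))
  num <- setdiff(names(stride_table)[vapply(stride_table, is.numeric, logical(1))],
                 c(keys, "stride_index"))
  stride_table |>
    tidyr::pivot_longer(dplyr::all_of(num), names_to = "variable", values_to = "value") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys)), .data$variable) |>
    dplyr::summarise(median = stats::median(.data$value, na.rm = TRUE),
                     iqr = stats::IQR(.data$value, na.rm = TRUE),
                     n_strides = sum(!is.na(.data$value)),
                     .groups = "drop")
}

#' Mixed-model group comparisons with EMMs and Tukey contrasts
#'
#' Fits the three standard models of the analysis, each with a random
#' intercept per horse, on per-stride rows:
#' \describe{
#'   \item{romz}{vertical range of motion ~ breed x segment + (1 | horse):
#'     effect of breed and anatomical location, with their interaction.}
#'   \item{timing}{each extremum-timing variable ~ breed + (1 | horse).}
#'   \item{temporal}{each temporal limb variable (suspension, stride
#'     duration, diagonal dissociation) ~ breed + (1 | horse).}
#' }
#' Estimated marginal means with confidence bounds and Tukey-adjusted
#' pairwise breed contrasts are extracted for every model; for the romz
#' model, breed contrasts are reported both averaged over segments and
#' within each segment, plus segment contrasts within breed.
#'
#' @param stride_table tibble with columns `horse_id`, `breed`, and the
#'   variables of the requested models: `romz_head`/`romz_withers`/
#'   `romz_pelvis` (romz), `*_pct_stance` columns (timing),
#'   `suspension_pct`/`stride_duration_s`/`diagonal_dissociation_pct`
#'   (temporal).
#' @param models subset of `c("romz", "timing", "temporal")`.
#' @param df_method degrees-of-freedom method passed to emmeans for
#'   `lmerMod` objects: `"satterthwaite"` (default), `"kenward-roger"` or
#'   `"asymptotic"` (z tests; fastest, used in large replicate loops).
#' @param alpha significance level recorded next to each contrast.
#' @return list with one element per requested model: `fit` (the lmerMod,
#'   or `NULL` when non-estimable), `emm` (tibble of EMMs with lower/upper
#'   confidence bounds), `contrasts` (tibble with Tukey-adjusted p values
#'   and a `significant` flag), `diagnostics` (tibble of fitted values and
#'   residuals for residual-vs-fitted and QQ checks) and `note`.
#' @export
fit_models <- function(stride_table, models = c("romz", "timing", "temporal"),
                       df_method = "satterthwaite", alpha = 0.05) {
  models <- match.arg(models, several.ok = TRUE)
  stopifnot(all(c("horse_id", "breed") %in% names(stride_table)))
  stride_table$breed <- factor(stride_table$breed)
  stride_table$horse_id <- factor(stride_table$horse_id)
  n_breeds <- nlevels(stride_table$breed)
  horses_per_breed <- stride_table |>
    dplyr::distinct(.data$breed, .data$horse_id) |>
    dplyr::count(.data$breed)
  estimable <- n_breeds >= 2 && all(horses_per_breed$n >= 2)
  lmer_df <- df_method
  out <- list()

  emm_tables <- function(fit, spec) {
    # emmeans warns that breed EMMs averaged over segment involve an
    # interaction; that averaging is exactly what is being requested
    em <- suppressMessages(emmeans::emmeans(fit, spec, lmer.df = lmer_df))
    emt <- tibble::as_tibble(as.data.frame(em))
    # asymptotic inference labels its bounds differently; normalize
    names(emt)[names(emt) == "asymp.LCL"] <- "lower.CL"
    names(emt)[names(emt) == "asymp.UCL"] <- "upper.CL"
    list(emm = emt,
         contrasts = tibble::as_tibble(as.data.frame(
           emmeans::contrast(em, method = "pairwise", adjust = "tukey"))))
  }

  if ("romz" %in% models) {
    long <- stride_table |>
      tidyr::pivot_longer(dplyr::all_of(c("romz_head", "romz_withers", "romz_pelvis")),
                          names_to = "segment", values_to = "romz_mm",
                          names_prefix = "romz_") |>
      dplyr::filter(!is.na(.data$romz_mm))
    if (!estimable) {
      out$romz <- list(fit = NULL, emm = NULL, contrasts = NULL, diagnostics = NULL,
                       note = "non-estimable: need >= 2 breeds with >= 2 horses each")
    } else {
      fit <- lme4::lmer(romz_mm ~ breed * segment + (1 | horse_id), data = long)
      breed_avg <- emm_tables(fit, ~breed)
      breed_by_seg <- emm_tables(fit, ~ breed | segment)
      seg_by_breed <- emm_tables(fit, ~ segment | breed)
      ct <- dplyr::bind_rows(
        dplyr::mutate(breed_avg$contrasts, family = "breed (averaged over segments)"),
        dplyr::mutate(breed_by_seg$contrasts, family = "breed within segment"),
        dplyr::mutate(seg_by_breed$contrasts, family = "segment within breed"))
      ct$significant <- ct$p.value < alpha
      out$romz <- list(fit = fit,
                       emm = dplyr::mutate(breed_by_seg$emm, .model = "romz"),
                       contrasts = ct,
                       diagnostics = tibble::tibble(model = "romz",
                                                    fitted = stats::fitted(fit),
                                                    residual = stats::resid(fit)),
                       note = NULL)
    }
  }

  one_way <- function(vars, label) {
    vars <- intersect(vars, names(stride_table))
    if (length(vars) == 0 || !estimable) {
      return(list(fit = NULL, emm = NULL, contrasts = NULL, diagnostics = NULL,
                  note = if (!estimable) "non-estimable: need >= 2 breeds with >= 2 horses each"
                         else sprintf("no %s variables in table", label)))
    }
    emms <- list(); cts <- list(); diags <- list(); fits <- list()
    for (v in vars) {
      dat <- stride_table[!is.na(stride_table[[v]]), ]
      if (nrow(dat) == 0 || length(unique(dat$breed)) < 2) next
      fml <- stats::as.formula(paste(v, "~ breed + (1 | horse_id)"))
      fit <- tryCatch(lme4::lmer(fml, data = dat), error = function(e) NULL)
      if (is.null(fit)) next
      tb <- emm_tables(fit, ~breed)
      emms[[v]] <- dplyr::mutate(tb$emm, variable = v)
      cts[[v]] <- dplyr::mutate(tb$contrasts, variable = v,
                                significant = .data$p.value < alpha)
      diags[[v]] <- tibble::tibble(model = v, fitted = stats::fitted(fit),
                                   residual = stats::resid(fit))
      fits[[v]] <- fit
    }
    list(fit = fits, emm = dplyr::bind_rows(emms), contrasts = dplyr::bind_rows(cts),
         diagnostics = dplyr::bind_rows(diags), note = NULL)
  }

  if ("timing" %in% models) {
    out$timing <- one_way(grep("_pct_stance$", names(stride_table), value = TRUE), "timing")
  }
  if ("temporal" %in% models) {
    out$temporal <- one_way(c("suspension_pct", "stride_duration_s",
                              "diagonal_dissociation_pct"), "temporal")
  }
  out
}

#' Simulate a multi-breed cohort of per-stride ROMz observations
#'
#' Stride-level generator for exercising the statistical stage at scale:
#' per-horse random intercepts (between-horse variation) plus independent
#' per-stride residuals around breed-by-segment means. Default dispersions
#' are derived from the reference EMM confidence-interval widths
#' (between-horse SD about 21 mm for cohorts of ~20 horses).
#'
#' @param breed_means named list: breed -> named vector
#'   `c(head = , withers = , pelvis = )` of mean ROMz (mm).
#' @param n_horses horses per breed (scalar or named per breed).
#' @param n_strides strides per horse.
#' @param sd_horse between-horse SD (mm).
#' @param sd_stride within-horse, stride-to-stride SD (mm).
#' @param seed integer seed.
#' @return tibble: `horse_id`, `breed`, `romz_head`, `romz_withers`,
#'   `romz_pelvis`, one row per stride.
#' @export
simulate_romz_cohort <- function(breed_means, n_horses = 20, n_strides = 8,
                                 sd_horse = 21, sd_stride = 10, seed = 1L) {
  stopifnot(is.list(breed_means), length(breed_means) >= 1)
  if (length(n_horses) == 1) {
    n_horses <- stats::setNames(rep(n_horses, length(breed_means)), names(breed_means))
  }
  with_seed_if(seed, {
    rows <- list()
    for (breed in names(breed_means)) {
      mu <- breed_means[[breed]]
      for (h in seq_len(n_horses[[breed]])) {
        horse_off <- stats::rnorm(1, 0, sd_horse)
        for (seg in c("head", "withers", "pelvis")) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            horse_id = sprintf("%s_%02d", breed, h),
            breed = breed,
            segment = seg,
            romz_mm = mu[[seg]] + horse_off + stats::rnorm(n_strides, 0, sd_stride),
            stride = seq_len(n_strides))
        }
      }
    }
    dplyr::bind_rows(rows) |>
      tidyr::pivot_wider(names_from = "segment", values_from = "romz_mm",
                         names_prefix = "romz_") |>
      dplyr::select(-"stride")
  })
}
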