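#' Simulate a complete imaging study
#'
#' Generates, per subject, a multi-component lesion mask, a noisy ADC
#' volume, and clinical covariates, plus one shared toy atlas. The AF
#' outcome follows a logistic model on standardized age, female sex, and
#' the z-scored log of the true component count (multifocality standing
#' in for the embolic pattern). Per-subject component counts, radii and
#' dispersion vary across subjects so the downstream morphometry sees a
#' heterogeneous cohort.
#'
#' @param n_subjects number of subjects.
#' @param seed master RNG seed; per-subject seeds are derived from it.
#' @param grid_shape,spacing_mm image geometry for every subject.
#' @param noise_sd ADC noise standard deviation (mm^2/s).
#' @param max_components upper bound for the per-subject component count.
#' @return A list with `subjects` (list of `id`, `adc`, `brain_mask`,
#'   `ground_truth`), `clinical` (data.frame `id`, `age`, `female`,
#'   `nihss`, `af`), and `atlas`.
#' @export
simulate_study <- function(n_subjects = 20, seed = 1,
                           grid_shape = c(48, 48, 48),
                           spacing_mm = c(1.5, 1.5, 1.5),
                           noise_sd = 25e-6, max_components = 4) {
  with_rng_seed(seed, {
    sub_seeds <- sample.int(2^31 - 2, n_subjects * 2)
    n_comp <- sample.int(max_components, n_subjects, replace = TRUE)
    dispersion <- runif(n_subjects, 5, 18)
    age <- rnorm(n_subjects, 66, 14)
    female <- rbinom(n_subjects, 1, 0.375)
    nihss <- round(rlnorm(n_subjects, log(2), 1))
    lp <- qlogis(0.123) + log(2.13) * (age - 66) / 14 +
      log(2.45) * female +
      log(1.72) * (log(n_comp) - mean(log(n_comp))) /
        max(sd(log(n_comp)), 0.5)
    af <- rbinom(n_subjects, 1, plogis(lp))

    subjects <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      cfg <- lesion_sim_config(
        grid_shape = grid_shape, spacing_mm = spacing_mm,
        n_components = n_comp[s], radius_range_mm = c(3, 6),
        dispersion_mm = dispersion[s], seed = sub_seeds[2 * s - 1])
      sim <- make_lesion_mask(cfg)
      adc <- make_adc_volume(sim$mask, noise_sd = noise_sd,
                             seed = sub_seeds[2 * s])
      brain <- lesion_mask(array(1L, grid_shape), spacing_mm)
      subjects[[s]] <- list(id = sprintf("sub-%04d", s), adc = adc,
                            brain_mask = brain,
                            ground_truth = sim$ground_truth)
    }
    # a thick cortical shell, so that dispersed lesions can reach "cortex"
    list(subjects = subjects,
         clinical = data.frame(id = sprintf("sub-%04d", seq_len(n_subjects)),
                               age = age, female = female, nihss = nihss,
                               af = af, stringsAsFactors = FALSE),
         atlas = make_toy_atlas(grid_shape, spacing_mm,
                                shell_voxels = round(grid_shape[1] / 6)))
  })
}

#' Run the full lesion-shape analysis pipeline
#'
#' Per subject: segment the lesion from the ADC map (threshold + small
#' component removal; skipped when a mask is supplied directly), compute
#' the six shape descriptors, and classify location against the atlas.
#' Subjects whose segmentation is empty are excluded with reason
#' "no acute lesion", mirroring the exclusion of patients without an
#' acute ischemic lesion; no subject is lost silently. The per-subject
#' feature table is then joined with the clinical table and analyzed:
#' group comparison, univariate models for every prepared feature, the
#' multivariate shape + clinical model, and backward stepwise
#' elimination.
#'
#' @param subjects list of per-subject lists with `id` plus either `mask`
#'   (a [lesion_mask()]) or `adc` + `brain_mask`.
#' @param clinical data.frame with `id`, `age`, `female`, `nihss`, `af`.
#' @param atlas an [atlas_volume()], or NULL to skip location.
#' @param threshold,min_volume_mm3 segmentation parameters.
#' @param connectivity,area_method shape parameters.
#' @param min_voxels location overlap threshold.
#' @param alpha stepwise significance level.
#' @param mc_replicates,seed Monte-Carlo settings for group comparisons.
#' @param out_dir if non-NULL, writes `features.csv`,
#'   `group_comparison.csv`, `univariate.csv`, `multivariate.csv`,
#'   `stepwise.csv`, `exclusions.csv` and a `manifest.json` there.
#' @return A list: `features`, `group_comparison`, `univariate`,
#'   `multivariate`, `stepwise` (with trace), `exclusions`.
#' @export
run_pipeline <- function(subjects, clinical, atlas = NULL,
                         threshold = 620e-6, min_volume_mm3 = 10,
                         connectivity = 26, area_method = "mesh",
                         min_voxels = 100, alpha = 0.05,
                         mc_replicates = 10000, seed = 1,
                         out_dir = NULL) {
  feats <- list()
  excl <- data.frame(id = character(), reason = character(),
                     stringsAsFactors = FALSE)
  for (sub in subjects) {
    row <- tryCatch({
      mask <- sub$mask
      if (is.null(mask)) {
        mask <- segment_adc(sub$adc, sub$brain_mask, threshold = threshold)
        mask <- remove_small_components(mask, min_volume_mm3,
                                        connectivity = connectivity)
      }
      if (!any(mask$data == 1L)) stop("no acute lesion", call. = FALSE)
      sd_row <- shape_descriptors(mask, connectivity = connectivity,
                                  area_method = area_method)
      if (!is.null(atlas)) {
        loc <- locate_lesion(mask, atlas, min_voxels = min_voxels)
        sd_row$cortical_involved <- as.integer(loc$cortical_involved)
        sd_row$multiple_territories <-
          as.integer(identical(loc$territory, "multiple"))
        sd_row$bilateral <- as.integer(identical(loc$hemisphere, "both"))
        sd_row$location_below_threshold <- as.integer(loc$below_threshold)
      }
      cbind(data.frame(id = sub$id, stringsAsFactors = FALSE), sd_row)
    }, error = function(e) conditionMessage(e))
    if (is.character(row)) {
      excl <- rbind(excl, data.frame(id = sub$id, reason = row,
                                     stringsAsFactors = FALSE))
    } else {
      feats[[length(feats) + 1L]] <- row
    }
  }
  if (!length(feats)) stopf("no subject produced a usable lesion")
  features <- do.call(rbind, feats)
  stopifnot(nrow(features) + nrow(excl) == length(subjects))

  cohort <- merge(clinical, features, by = "id", sort = TRUE)
  comparison <- compare_groups(cohort, mc_replicates = mc_replicates,
                               seed = seed)
  prepared <- prepare_features(cohort)
  uni_vars <- intersect(c(.clinical_continuous, "female", .shape_features,
                          "cortical_involved", "multiple_territories",
                          "bilateral"),
                        names(prepared))
  univariate <- do.call(rbind, lapply(uni_vars, function(v)
    tryCatch(fit_univariate(prepared, v), error = function(e)
      data.frame(variable = v, estimate = NA_real_, se = NA_real_,
                 or = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                 p = NA_real_, n = sum(stats::complete.cases(
                   prepared[, c("af", v)])), stringsAsFactors = FALSE))))
  multi_vars <- intersect(c(.default_shape_model, "age", "female", "nihss",
                            "cortical_involved", "multiple_territories"),
                          names(prepared))
  multi_vars <- multi_vars[vapply(multi_vars, function(v)
    length(unique(prepared[[v]])) > 1, logical(1))]
  # small cohorts cannot support the full model: cap the predictor count at
  # half the minority-class size (events-per-variable rule), then back off
  # further if the fit still separates
  epv_cap <- max(1L, floor(min(table(cohort$af)) / 2))
  try_sets <- lapply(rev(seq_len(min(length(multi_vars), epv_cap))),
                     function(k) multi_vars[seq_len(k)])
  try_sets <- c(try_sets, as.list(multi_vars[-1]))
  multivariate <- NULL
  for (vars in try_sets) {
    multivariate <- tryCatch(fit_multivariate(prepared, vars),
                             error = function(e) NULL)
    if (!is.null(multivariate)) break
  }
  if (is.null(multivariate)) {
    # not enough events to support any predictor: report intercept-only
    vars <- character(0)
    multivariate <- logistic_fit_table(
      suppressWarnings(glm(af ~ 1, family = binomial(), data = prepared)),
      sum(!is.na(prepared$af)))
    attr(multivariate, "intercept_only") <- TRUE
    stepwise <- multivariate
    attr(stepwise, "trace") <- data.frame(step = integer(),
                                          removed = character(),
                                          p = numeric())
  } else {
    stepwise <- tryCatch(stepwise_eliminate(prepared, vars, alpha = alpha),
                         error = function(e) {
                           out <- multivariate
                           attr(out, "trace") <- data.frame(
                             step = integer(), removed = character(),
                             p = numeric())
                           out
                         })
  }

  result <- list(features = features, group_comparison = comparison,
                 univariate = univariate, multivariate = multivariate,
                 stepwise = stepwise, exclusions = excl)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) write.csv(df, file.path(out_dir, name),
                                       row.names = FALSE)
    wr(features, "features.csv")
    wr(comparison, "group_comparison.csv")
    wr(univariate, "univariate.csv")
    wr(multivariate, "multivariate.csv")
    wr(stepwise, "stepwise.csv")
    wr(attr(stepwise, "trace"), "stepwise_trace.csv")
    wr(excl, "exclusions.csv")
    manifest <- list(
      n_subjects = length(subjects), n_analyzed = nrow(features),
      n_excluded = nrow(excl), threshold = threshold,
      min_volume_mm3 = min_volume_mm3, connectivity = connectivity,
      area_method = area_method, min_voxels = min_voxels, alpha = alpha,
      mc_replicates = mc_replicates, seed = seed,
      package_version = as.character(utils::packageVersion("lesionshape")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}
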