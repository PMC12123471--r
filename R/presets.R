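#' Preset cohort configurations
#'
#' Ready-made generative configurations whose attribute composition and
#' admission structure mirror publicly documented emergency-department
#' cohorts:
#'
#' * `"adult_ed"` - two protected attributes (`ethnoracial`, 5 levels;
#'   `gender`, 2 levels) with highly imbalanced intersections - the smallest
#'   cell (`ethnoracial=AIAN; gender=Men`) has prevalence 0.1% and the
#'   largest (`ethnoracial=White; gender=Women`) 31.4% - group-varying
#'   admission log-odds, and an overall admission rate near 29.5%. No
#'   interaction offsets: `true_risk` is exactly representable by a
#'   main-effects logistic model.
#' * `"adult_ed_biased"` - same composition plus interaction log-odds
#'   offsets at the intersectional cells. A learner (or calibrator) that
#'   only sees marginal structure cannot fit these cells, so intersectional
#'   miscalibration is planted by construction.
#' * `"pediatric_ed"` - three protected attributes (`race` 6 levels,
#'   `ethnicity` 2, `gender` 2) with an overall admission rate near 16%,
#'   plus mild three-way interaction offsets.
#'
#' Feature columns are generic stand-ins for triage data: `age` (years,
#' normal), `acuity` (ordinal 1-5, 1 = most urgent), `prior_visits`
#' (lognormal count-like), `pulse` (normal).
#'
#' @param name Preset name.
#' @param n_visits Number of visits to configure.
#' @param seed Master seed stored in the config.
#' @return A [cohort_config()].
#' @examples
#' cfg <- cohort_preset("adult_ed_biased", n_visits = 1000, seed = 7)
#' cohort <- generate_cohort(cfg)
#' table(cohort$ethnoracial, cohort$gender)
#' @export
cohort_preset <- function(name = c("adult_ed", "adult_ed_biased", "pediatric_ed"),
                          n_visits = 20000L, seed = 1L) {
  name <- match.arg(name)
  features <- list(
    list(name = "age", family = "normal", mean = 53, sd = 19.3),
    list(name = "acuity", family = "ordinal", values = 1:5,
         probs = c(0.055, 0.302, 0.577, 0.064, 0.002)),
    list(name = "prior_visits", family = "lognormal", meanlog = 0, sdlog = 0.8),
    list(name = "pulse", family = "normal", mean = 85, sd = 16)
  )
  coef <- c(age = 0.015, acuity = -1.1, prior_visits = 0.15, pulse = 0.008)

  if (name %in% c("adult_ed", "adult_ed_biased")) {
    levels <- list(
      ethnoracial = c("AIAN", "Asian", "Black", "Hispanic", "White"),
      gender = c("Men", "Women")
    )
    # Joint cell probabilities in expand.grid(ethnoracial, gender) order:
    # rows vary ethnoracial fastest. AIAN-Men pinned at 0.1%, White-Women at
    # 31.4%; ethnoracial marginals 0.3/3.7/26.2/10.0/59.8%.
    joint <- c(
      # Men: AIAN, Asian, Black, Hispanic, White
      0.0010, 0.0158, 0.1116, 0.0426, 0.2840,
      # Women
      0.0020, 0.0212, 0.1504, 0.0574, 0.3140
    )
    main_effects <- list(
      ethnoracial = c(AIAN = 0.30, Asian = 0.25, Black = -0.95,
                      Hispanic = -0.95, White = 0.40),
      gender = c(Men = 0.25, Women = -0.20)
    )
    interactions <- numeric(0)
    if (name == "adult_ed_biased") {
      interactions <- c(0.9, -0.5, -0.6, 0.7, 0.6, -0.8, 1.2, 0.25, -0.25)
      names(interactions) <- c(
        cell_label(c(ethnoracial = "Asian", gender = "Men")),
        cell_label(c(ethnoracial = "Asian", gender = "Women")),
        cell_label(c(ethnoracial = "Black", gender = "Men")),
        cell_label(c(ethnoracial = "Black", gender = "Women")),
        cell_label(c(ethnoracial = "Hispanic", gender = "Men")),
        cell_label(c(ethnoracial = "Hispanic", gender = "Women")),
        cell_label(c(ethnoracial = "AIAN", gender = "Men")),
        cell_label(c(ethnoracial = "White", gender = "Men")),
        cell_label(c(ethnoracial = "White", gender = "Women"))
      )
    }
    # Intercept chosen so the overall admission rate sits near 0.295 under
    # the feature and offset distributions above (computed once by Monte
    # Carlo at n = 2e6 and frozen).
    intercept <- if (name == "adult_ed") 0.254 else 0.206
    return(cohort_config(
      n_visits = n_visits,
      attribute_levels = levels,
      attribute_joint_probs = joint,
      features = features,
      outcome = list(intercept = intercept, coef = coef,
                     main_effects = main_effects,
                     interactions = interactions),
      seed = seed
    ))
  }

  # pediatric_ed: three protected attributes, independence joint.
  levels <- list(
    race = c("AIAN", "Asian", "Black", "NHPI", "White", "Other"),
    ethnicity = c("Hispanic", "NotHispanic"),
    gender = c("Men", "Women")
  )
  marginals <- list(
    race = c(0.001, 0.040, 0.197, 0.002, 0.377, 0.383),
    ethnicity = c(0.306, 0.694),
    gender = c(0.521, 0.479)
  )
  features_ped <- list(
    list(name = "age", family = "normal", mean = 8.2, sd = 6.8),
    list(name = "acuity", family = "ordinal", values = 1:5,
         probs = c(0.006, 0.225, 0.458, 0.276, 0.035)),
    list(name = "prior_visits", family = "lognormal", meanlog = 0, sdlog = 0.8),
    list(name = "pulse", family = "normal", mean = 110, sd = 20)
  )
  coef_ped <- c(age = 0.02, acuity = -1.3, prior_visits = 0.15, pulse = 0.005)
  main_effects <- list(
    race = c(AIAN = 0.4, Asian = 0.0, Black = -0.5, NHPI = 0.0,
             White = 0.45, Other = -0.25),
    ethnicity = c(Hispanic = -0.45, NotHispanic = 0.15),
    gender = c(Men = 0.1, Women = -0.05)
  )
  interactions <- c(0.8, -0.6, 0.7, -0.5)
  names(interactions) <- c(
    cell_label(c(race = "Asian", ethnicity = "NotHispanic", gender = "Men")),
    cell_label(c(race = "Black", ethnicity = "Hispanic", gender = "Women")),
    cell_label(c(race = "White", ethnicity = "Hispanic", gender = "Women")),
    cell_label(c(race = "Other", ethnicity = "NotHispanic", gender = "Men"))
  )
  # Intercept frozen from a one-off Monte Carlo calibration to a ~16.3%
  # overall admission rate.
  cohort_config(
    n_visits = n_visits,
    attribute_levels = levels,
    attribute_marginals = marginals,
    features = features_ped,
    outcome = list(intercept = 1.114, coef = coef_ped,
                   main_effects = main_effects,
                   interactions = interactions),
    seed = seed
  )
}
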