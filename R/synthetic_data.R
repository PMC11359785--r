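#' Default four-trial study-design set
#'
#' Synthetic stand-in for the four pooled clinical trials informing the
#' reference model: a single-dose crossover with an IV 0.25 mg and an oral
#' 0.25 mg arm (the IV arm is what identifies F), a second single oral
#' 0.25 mg study, a two-dose oral 0.75 mg study (12 h apart) with and
#' without efavirenz 600 mg, and a 150 mg implant study sampled over
#' 48 weeks with and without efavirenz. Sampling grids are dense early and
#' sparse late, as is typical of such designs; the observed values
#' themselves are always generated, never digitized.
#'
#' @return List of [study_design()] objects (7 arms over 4 studies).
#' @export
default_study_designs <- function() {
  t_sd <- c(0.5, 1, 2, 4, 8, 12, 24, 48, 72)
  t_implant_h <- seq(4, 48, by = 4) * 7 * 24  # weeks -> h
  list(
    study_design("iv", 0.25, t_sd, study_id = "crossover"),
    study_design("oral", 0.25, t_sd, study_id = "crossover"),
    study_design("oral", 0.25, t_sd, study_id = "single_oral"),
    study_design("oral", 0.75, c(1, 2, 4, 8, 12, 13, 14, 16, 20, 24, 36, 48, 72),
                 dose_times_h = c(0, 12), study_id = "two_dose"),
    study_design("oral", 0.75, c(1, 2, 4, 8, 12, 13, 14, 16, 20, 24, 36, 48, 72),
                 dose_times_h = c(0, 12), efv = TRUE, study_id = "two_dose"),
    study_design("implant", 150, t_implant_h, study_id = "implant"),
    study_design("implant", 150, t_implant_h, efv = TRUE, study_id = "implant")
  )
}

#' Generate synthetic trial-mean datasets
#'
#' Draws the reference model's stated statistical structure: one study-level
#' random effect on logit(F) per study (shared across arms of the same
#' study), typical-study mean predictions, and multiplicative proportional
#' residual noise `(1 + eps)`, `eps ~ N(0, sigma_prop^2)` truncated so
#' concentrations stay positive. Fully reproducible from `seed`.
#'
#' @param truth A [mem_params()] used as the generating truth.
#' @param designs List of [study_design()]s (default the four-trial set).
#' @param seed Mandatory integer seed.
#' @return List of `list(design, conc)` pairs, ready for [fit_mem()];
#'   the drawn `eta_f` is attached as attribute `eta` per element.
#' @export
gen_trial_means <- function(truth, designs = default_study_designs(), seed) {
  stopifnot(inherits(truth, "mem_params"))
  if (missing(seed)) stop("gen_trial_means(): seed is mandatory")
  set.seed(seed)
  ids <- vapply(designs, function(d) d$study_id, character(1))
  uid <- unique(ids)
  etas <- stats::setNames(stats::rnorm(length(uid), 0, truth$omega_f), uid)
  lapply(designs, function(d) {
    eta <- unname(etas[d$study_id])
    mu <- predict_means(truth, d, eta_f = eta)
    eps <- stats::rnorm(length(mu), 0, truth$sigma_prop)
    # truncation: redraw the rare draws that would flip the sign
    bad <- which(1 + eps <= 0)
    while (length(bad)) {
      eps[bad] <- stats::rnorm(length(bad), 0, truth$sigma_prop)
      bad <- which(1 + eps <= 0)
    }
    structure(list(design = d, conc = mu * (1 + eps)), eta = eta)
  })
}

#' Virtual-population specification
#'
#' Log-normal inter-individual variability about the calibrated typical
#' values, median-preserving (the typical value is the median of each
#' sampled distribution). Default coefficients of variation: 30% on
#' clearance-determining intrinsic clearance, 15% on hepatic blood flow,
#' 20% on Vss, 15% on body weight about a 67.3 kg median. The fraction
#' unbound is fixed by default (protein-binding variation is explored by
#' the dedicated sweep, not the population).
#'
#' @param n_subjects Number of virtual women (default 200).
#' @param cv_clint,cv_flow,cv_vss,cv_weight Coefficients of variation.
#' @param vary_fu Logical; if `TRUE`, fu also varies (30% CV).
#' @param seed Mandatory integer seed.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_subjects = 200, cv_clint = 0.30,
                            cv_flow = 0.15, cv_vss = 0.20,
                            cv_weight = 0.15, vary_fu = FALSE, seed) {
  if (missing(seed)) stop("population_spec(): seed is mandatory")
  stopifnot(n_subjects >= 1, cv_clint >= 0, cv_flow >= 0, cv_vss >= 0,
            cv_weight >= 0)
  structure(list(n_subjects = as.integer(n_subjects), cv_clint = cv_clint,
                 cv_flow = cv_flow, cv_vss = cv_vss, cv_weight = cv_weight,
                 vary_fu = isTRUE(vary_fu), seed = as.integer(seed)),
            class = "population_spec")
}

# median-preserving log-normal draw about `typical` with coefficient of
# variation `cv` (sdlog = sqrt(log(1 + cv^2)))
lnorm_about <- function(n, typical, cv) {
  if (cv <= 0) return(rep(typical, n))
  stats::rlnorm(n, meanlog = log(typical), sdlog = sqrt(log(1 + cv^2)))
}

#' Generate a virtual population
#'
#' Independent median-preserving log-normal perturbations of the
#' clearance-determining parameters about the calibrated typical subject.
#' All randomness flows through `spec$seed`; repeated calls with the
#' same spec return identical populations.
#'
#' @param spec A [population_spec()].
#' @param base_pk Calibrated typical [victim_pk()].
#' @param base_subject Typical [physiology()].
#' @return List of `n_subjects` elements, each
#'   `list(subject = physiology, pk = victim_pk)`.
#' @export
gen_population <- function(spec, base_pk, base_subject) {
  stopifnot(inherits(spec, "population_spec"), inherits(base_pk, "victim_pk"),
            inherits(base_subject, "physiology"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  clint <- lnorm_about(n, base_pk$clint_u_total, spec$cv_clint)
  flow <- lnorm_about(n, base_subject$hepatic_blood_flow, spec$cv_flow)
  vss <- lnorm_about(n, base_pk$vss, spec$cv_vss)
  bw <- lnorm_about(n, base_subject$body_weight, spec$cv_weight)
  fu <- if (spec$vary_fu) lnorm_about(n, base_pk$fu, 0.30) else rep(base_pk$fu, n)
  lapply(seq_len(n), function(i) {
    pk_i <- base_pk
    pk_i$clint_u_total <- clint[i]
    pk_i$vss <- vss[i]
    pk_i$fu <- min(fu[i], 1)
    subj_i <- base_subject
    subj_i$hepatic_blood_flow <- flow[i]
    subj_i$body_weight <- bw[i]
    list(subject = subj_i, pk = pk_i)
  })
}
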