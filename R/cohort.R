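#' Specification of a synthetic three-arm treatment cohort
#'
#' Describes the study conditions the generator emulates: three
#' negative-pressure arms (-105/-125/-145 mmHg) with 11/13/12 subjects,
#' pre-treatment thickness around 3.5-4.3 mm, arm-dependent post/pre
#' thickness ratios and regional modulus multipliers, and strongly
#' correlated per-subject effects across the E1/E2/E3 regions.
#'
#' Default location parameters are the published cohort summaries (arm means
#' of thickness, regional moduli and post/pre percentage ratios); spread
#' parameters are subject-level standard deviations reconstructed from the
#' reported standard errors (\eqn{SD = SE \sqrt{n}}). Treatment effects are
#' multiplicative with mean-one log-normal subject noise, so the expected
#' post/pre ratio of an arm equals its configured ratio mean exactly.
#'
#' @param arms treatment magnitude labels, mmHg.
#' @param n subjects per arm.
#' @param pre_thickness_mean,pre_thickness_sd per-arm initial thickness
#'   distribution, mm (normal, truncated below at `thickness_floor`).
#' @param thickness_floor lower truncation bound for drawn thickness, mm.
#' @param thickness_ratio_mean,thickness_ratio_sd per-arm post/pre thickness
#'   ratio distribution (fractions, not percent).
#' @param e1_pre_mean,e1_pre_cv per-arm pre-treatment toe-region modulus
#'   (kPa): log-normal mean and coefficient of variation.
#' @param stiffening_mean,stiffening_cv per-arm stiffening-rate
#'   distribution (log-normal).
#' @param modulus_effect 3 x 3 matrix (arm x region) of mean post/pre
#'   modulus multipliers.
#' @param modulus_effect_cv 3 x 3 matrix of their coefficients of variation.
#' @param rho inter-region correlation of the latent per-subject effect
#'   noise, in \[-1, 1\].
#' @param relax_time,relax_strength viscous component shared by all
#'   subjects (s; dimensionless).
#' @param noise_scale measurement-noise multiplier for all subjects.
#' @param seed master seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(arms = c(-105, -125, -145),
                        n = c(11, 13, 12),
                        pre_thickness_mean = c(3.7, 4.3, 3.5),
                        pre_thickness_sd = c(0.663, 1.803, 1.039),
                        thickness_floor = 1.5,
                        thickness_ratio_mean = c(0.745, 0.913, 0.844),
                        thickness_ratio_sd = c(0.109, 0.079, 0.076),
                        e1_pre_mean = c(51.2, 52.6, 42.1),
                        e1_pre_cv = c(1.393, 0.727, 1.086),
                        stiffening_mean = c(1.230, 3.656, 9.995),
                        stiffening_cv = c(0.2, 0.2, 0.2),
                        modulus_effect = rbind(c(2.097, 2.023, 1.948),
                                               c(1.840, 1.883, 2.179),
                                               c(4.137, 5.037, 4.409)),
                        modulus_effect_cv = rbind(c(1.530, 1.262, 1.011),
                                                  c(0.705, 0.565, 0.549),
                                                  c(0.549, 1.153, 1.173)),
                        rho = 0.9,
                        relax_time = 0.3, relax_strength = 0.1,
                        noise_scale = 1, seed = 1L) {
  k <- length(arms)
  if (length(n) != k || any(n < 2))
    stop("'n' must give a size >= 2 for each arm", call. = FALSE)
  if (any(thickness_ratio_mean <= 0))
    stop("thickness ratio means must be > 0", call. = FALSE)
  if (abs(rho) > 1) stop("'rho' must lie in [-1, 1]", call. = FALSE)
  modulus_effect <- matrix(modulus_effect, k, 3)
  modulus_effect_cv <- matrix(modulus_effect_cv, k, 3)
  if (any(modulus_effect <= 0))
    stop("modulus effect multipliers must be > 0", call. = FALSE)
  structure(list(arms = arms, n = n,
                 pre_thickness_mean = pre_thickness_mean,
                 pre_thickness_sd = pre_thickness_sd,
                 thickness_floor = thickness_floor,
                 thickness_ratio_mean = thickness_ratio_mean,
                 thickness_ratio_sd = thickness_ratio_sd,
                 e1_pre_mean = e1_pre_mean, e1_pre_cv = e1_pre_cv,
                 stiffening_mean = stiffening_mean,
                 stiffening_cv = stiffening_cv,
                 modulus_effect = modulus_effect,
                 modulus_effect_cv = modulus_effect_cv,
                 rho = rho, relax_time = relax_time,
                 relax_strength = relax_strength,
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Null (no-treatment-effect) cohort specification
#'
#' All effect multipliers are 1 and subject-level effect noise is reduced to
#' a test-retest repeatability level, so post-treatment truth differs from
#' pre-treatment truth only by zero-mean repeatability noise. Used for
#' type-I-error calibration of the statistical pipeline.
#'
#' @param retest_cv coefficient of variation of the mean-one log-normal
#'   test-retest noise on regional moduli.
#' @param thickness_retest_sd standard deviation of the mean-one thickness
#'   retest ratio.
#' @param ... further arguments passed to [cohort_spec()].
#' @return a `cohort_spec`.
#' @export
null_cohort_spec <- function(retest_cv = 0.2, thickness_retest_sd = 0.05,
                             ...) {
  cohort_spec(thickness_ratio_mean = c(1, 1, 1),
              thickness_ratio_sd = rep(thickness_retest_sd, 3),
              modulus_effect = matrix(1, 3, 3),
              modulus_effect_cv = matrix(retest_cv, 3, 3),
              ...)
}

## mean-one log-normal multiplier: E[m] = mean, CV = cv
rlnorm_mean1 <- function(n, mean, cv, z = stats::rnorm(n)) {
  s <- sqrt(log(1 + cv^2))
  mean * exp(s * z - s^2 / 2)
}

#' Generate a paired pre/post ground-truth cohort
#'
#' Draws one [tissue_ground_truth()] pair per subject. Pre-treatment truth
#' follows the arm's thickness and modulus distributions with an exponential
#' J-shaped law; the treatment transform multiplies thickness by a mean-one
#' log-normal ratio and the three regional moduli by correlated mean-one
#' log-normal multipliers (latent Gaussian with exchangeable correlation
#' `rho`). Post-treatment moduli are stored as regional anchors at
#' 5/10/15% strain, through which the post constitutive law interpolates.
#'
#' Each subject has its own child seed derived from the master seed, so the
#' cohort is bit-reproducible and insensitive to generation order.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `scar_cohort`: a list of subject entries with
#'   elements `subject_id`, `group`, `pre`, `post` and `truth_ratios`.
#' @export
#' @examples
#' coh <- make_cohort(cohort_spec(seed = 42))
#' length(coh)  # 36 subjects
make_cohort <- function(spec = cohort_spec()) {
  strains <- c(0.05, 0.10, 0.15)
  subjects <- list()
  idx <- 0L
  for (g in seq_along(spec$arms)) {
    for (i in seq_len(spec$n[g])) {
      idx <- idx + 1L
      seed <- child_seed(spec$seed, idx)
      subjects[[idx]] <- local({
        old <- .Random.seed_save()
        on.exit(.Random.seed_restore(old))
        set.seed(seed)

        h0 <- repeat_until(
          function() stats::rnorm(1, spec$pre_thickness_mean[g],
                                  spec$pre_thickness_sd[g]),
          function(x) x >= spec$thickness_floor)
        e1 <- rlnorm_mean1(1, spec$e1_pre_mean[g], spec$e1_pre_cv[g])
        gam <- rlnorm_mean1(1, spec$stiffening_mean[g], spec$stiffening_cv[g])
        toe <- e1 / exp(gam * strains[1])
        pre <- tissue_ground_truth(
          subject_id = sprintf("S%02d", idx), group = spec$arms[g],
          h0 = h0, toe_modulus = toe, stiffening_rate = gam,
          relax_time = spec$relax_time,
          relax_strength = spec$relax_strength,
          noise_scale = spec$noise_scale)

        ratio <- rlnorm_mean1(1, spec$thickness_ratio_mean[g],
                              spec$thickness_ratio_sd[g] /
                                spec$thickness_ratio_mean[g])
        ## correlated region effects via an exchangeable Gaussian copula
        z0 <- stats::rnorm(1)
        zr <- sqrt(abs(spec$rho)) * sign(spec$rho) * z0 +
          sqrt(1 - abs(spec$rho)) * stats::rnorm(3)
        mult <- vapply(1:3, function(r)
          rlnorm_mean1(1, spec$modulus_effect[g, r],
                       spec$modulus_effect_cv[g, r], z = zr[r]), 0)
        E_pre <- truth_regional_moduli(pre, strains)
        anchors <- stats::setNames(E_pre * mult, format(strains))
        slope <- (log(anchors[[3]]) - log(anchors[[1]])) / 0.1
        post <- tissue_ground_truth(
          subject_id = pre$subject_id, group = pre$group,
          h0 = h0 * ratio,
          toe_modulus = anchors[[1]] / exp(slope * strains[1]),
          stiffening_rate = max(slope, 0),
          relax_time = spec$relax_time,
          relax_strength = spec$relax_strength,
          noise_scale = spec$noise_scale,
          regional_anchors = anchors)

        list(subject_id = pre$subject_id, group = spec$arms[g],
             pre = pre, post = post,
             truth_ratios = c(thickness = ratio,
                              stats::setNames(mult, c("E1", "E2", "E3"))))
      })
    }
  }
  structure(subjects, class = "scar_cohort", spec = spec)
}

## save/restore the global RNG state so seeded subject draws do not disturb
## the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

repeat_until <- function(draw, ok, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    x <- draw()
    if (ok(x)) return(x)
  }
  stop("rejection sampling failed after ", max_tries, " tries", call. = FALSE)
}

#' @export
as.data.frame.scar_cohort <- function(x, ...) {
  do.call(rbind, lapply(x, function(s) {
    pre <- truth_regional_moduli(s$pre)
    post <- truth_regional_moduli(s$post)
    data.frame(subject_id = s$subject_id, group = s$group,
               h0_pre = s$pre$h0, h0_post = s$post$h0,
               E1_pre = pre[["E1"]], E2_pre = pre[["E2"]],
               E3_pre = pre[["E3"]],
               E1_post = post[["E1"]], E2_post = post[["E2"]],
               E3_post = post[["E3"]])
  }))
}

#' @export
print.scar_cohort <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("Synthetic indentation cohort: %d subjects in %d arms (%s mmHg)\n",
              length(x), length(spec$arms),
              paste(spec$arms, collapse = "/")))
  invisible(x)
}
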