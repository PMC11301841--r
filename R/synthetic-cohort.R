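#' Configuration for synthetic two-eye cohort generation
#'
#' Describes a cohort of highly myopic subjects, two eyes each, with
#' maculopathy categories C0 (no macular lesions), C1 (tessellated fundus)
#' and C2 (diffuse chorioretinal atrophy, DCA: the threshold for pathological
#' myopia), demographic and biometric traits drawn from per-category normal
#' distributions, and choroidal metrics derived from category-specific
#' thickness and vascularity distributions. The default category mix
#' (6.6 / 76.0 / 17.4 percent) and the trait means/SDs reflect a
#' hospital-based adult high-myopia cohort: e.g., axial length 26.33 +/- 1.02
#' mm in C0 rising to 27.90 +/- 1.20 mm in C2, choroids thinning from about
#' 230 um (C0) to about 105 um (C2) at the vertical meridian with CVI rising
#' slightly, and nasal perifoveal (N2) choroids thinnest of all.
#'
#' Between-eye correlation of continuous traits within a subject is induced
#' by a shared subject-level standard-normal effect:
#' value = mean_g + sd_g * (sqrt(rho) * z_subject + sqrt(1 - rho) * z_eye),
#' matching an exchangeable working-correlation structure. Visual-field mean
#' deviation (MD, dB) is generated from a linear link on age, height, AL,
#' corneal curvature and vertical-meridian luminal area, with the default
#' coefficients of the cohort's all-eyes model.
#'
#' `dcaMode` decides how the DCA label is produced: `"category"` (default)
#' sets `dca = (category == "C2")`, so any DCA-metric association arises from
#' the group structure; `"logistic"` instead draws DCA from a logistic link
#' on the standardized vertical luminal area
#' (`logit p = logistic_intercept + logistic_beta_la * z(LA_V)`) and labels
#' the drawn cases C2 — the mode used for parameter-recovery validation.
#'
#' @param n_subjects number of subjects (eyes = 2x).
#' @param group_proportions named or ordered length-3 simplex weights for
#'   (C0, C1, C2); must sum to 1.
#' @param intra_subject_correlation rho in \[0, 1) between the two eyes.
#' @param age_mean,age_sd,al_mean,al_sd,height_mean,height_sd,cc_mean,cc_sd
#'   per-category (C0, C1, C2) means/SDs for age (years), axial length (mm),
#'   height (cm), corneal curvature (D).
#' @param ser_mean,ser_sd per-category spherical equivalent (D).
#' @param chtv_mean,chtv_sd per-category vertical-meridian ChT (um).
#' @param chtn2_mean,chtn2_sd per-category N2-region ChT (um).
#' @param cvi_mean,cvi_sd per-category CVI (dimensionless).
#' @param male_prop subject-level male proportion.
#' @param md_coefs named numeric: `intercept`, `age`, `height`, `AL`, `cc`,
#'   `LA_V` — the MD linear link.
#' @param md_noise_sd residual SD of MD, dB.
#' @param vf_reliable_prop share of eyes with reliable visual-field tests.
#' @param dcaMode `"category"` or `"logistic"` (see above).
#' @param logistic_intercept,logistic_beta_la logistic-link coefficients used
#'   when `dcaMode = "logistic"` (`logistic_beta_la` is per SD of LA_V).
#' @param seed integer seed.
#' @return list of class `"CohortSimConfig"`.
#' @export
cohortSimConfig <- function(n_subjects = 720L,
                            group_proportions = c(C0 = 0.066, C1 = 0.760,
                                                  C2 = 0.174),
                            intra_subject_correlation = 0.7,
                            age_mean = c(32.8, 35.1, 39.1),
                            age_sd = c(10.4, 9.6, 10.1),
                            al_mean = c(26.33, 26.79, 27.90),
                            al_sd = c(1.02, 1.02, 1.20),
                            height_mean = c(162.7, 162.5, 161.0),
                            height_sd = c(9.3, 8.1, 7.6),
                            cc_mean = c(44.1, 43.8, 43.6),
                            cc_sd = c(1.6, 1.4, 1.5),
                            ser_mean = c(-7.37, -8.06, -10.11),
                            ser_sd = c(1.23, 1.69, 2.69),
                            chtv_mean = c(230, 185, 105),
                            chtv_sd = c(60, 60, 40),
                            chtn2_mean = c(160, 120, 45),
                            chtn2_sd = c(55, 50, 30),
                            cvi_mean = c(0.60, 0.61, 0.63),
                            cvi_sd = c(0.03, 0.03, 0.03),
                            male_prop = 0.30,
                            md_coefs = c(intercept = 17.247, age = 0,
                                         height = 0.022, AL = -0.440,
                                         cc = -0.311, LA_V = 1.512),
                            md_noise_sd = 2.0,
                            vf_reliable_prop = 0.86,
                            dcaMode = c("category", "logistic"),
                            logistic_intercept = -2.2,
                            logistic_beta_la = log(0.1),
                            seed = 1L) {
  dcaMode <- match.arg(dcaMode)
  gp <- as.numeric(group_proportions)
  if (length(gp) != 3L || any(gp < 0) || abs(sum(gp) - 1) > 1e-8)
    stop("'group_proportions' must be 3 non-negative weights summing to 1")
  rho <- intra_subject_correlation
  if (rho < 0 || rho >= 1) stop("intra-subject correlation must be in [0, 1)")
  sds <- list(age_sd, al_sd, height_sd, cc_sd, ser_sd, chtv_sd, chtn2_sd,
              cvi_sd)
  if (any(unlist(sds) < 0)) stop("SDs must be >= 0")
  structure(as.list(environment()), class = "CohortSimConfig")
}

# eye-level trait with shared subject effect: per-category mean/sd vectors,
# gi = per-eye group index (1..3), zs = subject z replicated per eye
.eyeTrait <- function(mean3, sd3, gi, zs, rho) {
  ze <- stats::rnorm(length(gi))
  mean3[gi] + sd3[gi] * (sqrt(rho) * zs + sqrt(1 - rho) * ze)
}

#' Simulate a two-eye cohort with known generating parameters
#'
#' Draws per-eye maculopathy categories from the configured proportions,
#' continuous traits from category-specific normals with the configured
#' between-eye correlation, derives choroidal areas from thickness and CVI
#' (LA_V = ChT_V(mm) x 6 mm x CVI over the 6-mm vertical section;
#' N2 areas over the 1.5-mm region), generates MD from the linear link, and
#' labels DCA per `dcaMode`. Exclusion-flag columns (`excl_*`) are emitted
#' all-FALSE; tests and pipelines set them as needed. Subject-level traits
#' (age, height, gender) use the subject's worse eye category.
#'
#' @param config a [cohortSimConfig()].
#' @return list with `cohort` (data.frame, two rows per subject) and `truth`
#'   (the generating parameters: the config plus derived link coefficients).
#' @examples
#' sim <- simulateCohort(cohortSimConfig(n_subjects = 50, seed = 3))
#' table(sim$cohort$category)
#' @export
simulateCohort <- function(config = cohortSimConfig()) {
  stopifnot(inherits(config, "CohortSimConfig"))
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = globalenv()))
  set.seed(config$seed)

  ns <- config$n_subjects
  ne <- 2L * ns
  subject <- rep(seq_len(ns), each = 2L)
  eye <- rep(c("OD", "OS"), ns)
  rho <- config$intra_subject_correlation
  gi <- sample.int(3L, ne, replace = TRUE, prob = config$group_proportions)
  category <- c("C0", "C1", "C2")[gi]

  zs <- function() rep(stats::rnorm(ns), each = 2L)
  age_e <- .eyeTrait(config$age_mean, config$age_sd, gi, zs(), rho)
  height_e <- .eyeTrait(config$height_mean, config$height_sd, gi, zs(), rho)
  AL <- .eyeTrait(config$al_mean, config$al_sd, gi, zs(), rho)
  cc <- .eyeTrait(config$cc_mean, config$cc_sd, gi, zs(), rho)
  SER <- .eyeTrait(config$ser_mean, config$ser_sd, gi, zs(), rho)
  ChT_V <- pmax(.eyeTrait(config$chtv_mean, config$chtv_sd, gi, zs(), rho), 5)
  ChT_N2 <- pmax(.eyeTrait(config$chtn2_mean, config$chtn2_sd, gi, zs(), rho),
                 5)
  CVI_V <- pmin(pmax(.eyeTrait(config$cvi_mean, config$cvi_sd, gi, zs(), rho),
                     0.3), 0.85)
  CVI_N2 <- pmin(pmax(.eyeTrait(config$cvi_mean, config$cvi_sd, gi, zs(),
                                rho), 0.3), 0.85)

  # subject-level age/height/gender taken from the worse eye's category
  worse <- rep(tapply(gi, subject, max), each = 2L)
  ageS <- tapply(age_e, subject, mean)
  age <- rep(as.numeric(ageS), each = 2L)
  age <- pmin(pmax(age, 18), 60)
  height <- rep(as.numeric(tapply(height_e, subject, mean)), each = 2L)
  gender <- rep(ifelse(stats::runif(ns) < config$male_prop, "male",
                       "female"), each = 2L)

  TCA_V <- ChT_V / 1000 * 6          # mm^2 over the 6-mm section
  LA_V <- TCA_V * CVI_V
  SA_V <- TCA_V - LA_V
  TCA_N2 <- ChT_N2 / 1000 * 1.5      # mm^2 over the 1.5-mm N2 region
  LA_N2 <- TCA_N2 * CVI_N2
  SA_N2 <- TCA_N2 - LA_N2

  b <- config$md_coefs
  MD <- b[["intercept"]] + b[["age"]] * age + b[["height"]] * height +
    b[["AL"]] * AL + b[["cc"]] * cc + b[["LA_V"]] * LA_V +
    config$md_noise_sd * (sqrt(rho) * zs() + sqrt(1 - rho) * stats::rnorm(ne))

  if (config$dcaMode == "logistic") {
    zla <- (LA_V - mean(LA_V)) / stats::sd(LA_V)
    p <- stats::plogis(config$logistic_intercept +
                         config$logistic_beta_la * zla)
    dca <- stats::runif(ne) < p
    category <- ifelse(dca, "C2", ifelse(category == "C2", "C1", category))
  } else {
    dca <- category == "C2"
  }

  cohort <- data.frame(
    subject_id = sprintf("S%04d", subject), eye = eye, age = age,
    gender = gender, height = height, AL = AL, SER = SER,
    corneal_curvature = cc, category = category, dca = dca,
    MD = MD, vf_reliable = stats::runif(ne) < config$vf_reliable_prop,
    ChT_V = ChT_V, LA_V = LA_V, SA_V = SA_V, TCA_V = TCA_V, CVI_V = CVI_V,
    ChT_N2 = ChT_N2, LA_N2 = LA_N2, SA_N2 = SA_N2, CVI_N2 = CVI_N2,
    excl_choroiditis = FALSE, excl_pcv = FALSE, excl_severe_mm = FALSE,
    excl_fce_picc = FALSE, excl_rd = FALSE,
    stringsAsFactors = FALSE)
  list(cohort = cohort,
       truth = list(config = config, md_coefs = b,
                    md_noise_sd = config$md_noise_sd,
                    logistic_intercept = config$logistic_intercept,
                    logistic_beta_la = config$logistic_beta_la))
}
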