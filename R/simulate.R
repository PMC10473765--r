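# Synthetic two-species cohorts and paired expression matrices with known
# ground truth. Region volumes are built so that the *marginal* variance of
# each region equals the square of its volume scale, which makes the
# planted standardized sex effect equal (asymptotically) to the sex
# coefficient recovered by fit_sex_effect() on the z-scored volume.

#' Cohort simulation settings
#'
#' Bundles the ground-truth parameters of a synthetic single-species
#' cohort. Defaults emulate the two study populations: the human-style
#' cohort has 597 females / 496 males aged 22-35 years, a large TTV sex
#' shift (1.3 standardized units) and mild male variance inflation, Euler
#' numbers as the QC covariate, a single acquisition batch, and sibling
#' pairs; the mouse-style cohort has 213 females / 216 males aged
#' postnatal days 56-90, no TTV sex shift, equal variances, background
#' strain as the QC covariate, and 18 acquisition cohorts needing
#' harmonization. Default per-region true effects are the built-in
#' published effect sizes of the matching species.
#'
#' @param species `"human"` or `"mouse"`.
#' @param n_female,n_male Subjects per sex.
#' @param betas Named vector of true standardized sex effects, one per
#'   region (names become `vol_` column suffixes).
#' @param ttv_mean,ttv_sd TTV location and spread, mm^3.
#' @param ttv_sex_shift True standardized sex effect on TTV.
#' @param age_range Two-element range (years or postnatal days).
#' @param age_slope,qc_slope Standardized effect per SD of centered age /
#'   of the QC covariate.
#' @param strain_offset Standardized shift for the second background
#'   strain (mouse only).
#' @param variance_ratio Male/female residual SD ratio (> 0).
#' @param n_batches Number of acquisition batches (round-robin assignment).
#' @param batch_offset_sd SD of per-batch additive shifts, standardized
#'   units (0 when `n_batches = 1`).
#' @param batch_scale_range Range of per-batch multiplicative noise scales.
#' @param noise_sd Residual noise SD in standardized units; together with
#'   the planted effects it must leave the implied variance budget below 1.
#' @param baseline_frac Region baseline volume as a fraction of mean TTV.
#' @param twin_fraction Fraction of subjects in two-person families
#'   (human only).
#' @param heavy_tails Use scaled t(3) residuals instead of Gaussian ones
#'   (stress test for robust statistics).
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(species = c("human", "mouse"),
                        n_female = NULL, n_male = NULL, betas = NULL,
                        ttv_mean = NULL, ttv_sd = NULL,
                        ttv_sex_shift = NULL, age_range = NULL,
                        age_slope = 0.1, qc_slope = 0.05,
                        strain_offset = 0.2,
                        variance_ratio = NULL, n_batches = NULL,
                        batch_offset_sd = 0.2,
                        batch_scale_range = c(0.8, 1.25),
                        noise_sd = 0.7, baseline_frac = 0.01,
                        twin_fraction = 0.3, heavy_tails = FALSE,
                        seed = 1) {
  species <- match.arg(species)
  human <- species == "human"
  if (is.null(n_female)) n_female <- if (human) 597L else 213L
  if (is.null(n_male)) n_male <- if (human) 496L else 216L
  if (is.null(betas)) {
    tab <- builtin_pair_table()
    betas <- stats::setNames(if (human) tab$human_beta else tab$mouse_beta,
                             tab$key)
  }
  if (is.null(names(betas)))
    names(betas) <- paste0("region_", seq_along(betas))
  if (is.null(ttv_mean)) ttv_mean <- if (human) 1.25e6 else 450
  if (is.null(ttv_sd)) ttv_sd <- if (human) 1.0e5 else 15
  if (is.null(ttv_sex_shift)) ttv_sex_shift <- if (human) 1.3 else 0
  if (is.null(age_range)) age_range <- if (human) c(22, 35) else c(56, 90)
  if (is.null(variance_ratio)) variance_ratio <- if (human) 1.2 else 1
  if (is.null(n_batches)) n_batches <- if (human) 1L else 18L
  if (n_batches == 1L) batch_offset_sd <- 0
  spec <- list(species = species, n_female = n_female, n_male = n_male,
               betas = betas, ttv_mean = ttv_mean, ttv_sd = ttv_sd,
               ttv_sex_shift = ttv_sex_shift, age_range = age_range,
               age_slope = age_slope, qc_slope = qc_slope,
               strain_offset = strain_offset,
               variance_ratio = variance_ratio, n_batches = n_batches,
               batch_offset_sd = batch_offset_sd,
               batch_scale_range = batch_scale_range, noise_sd = noise_sd,
               baseline_frac = baseline_frac,
               twin_fraction = twin_fraction, heavy_tails = heavy_tails,
               seed = seed)
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

#' @keywords internal
#' @noRd
validate_cohort_spec <- function(spec) {
  if (spec$n_female < 2L || spec$n_male < 2L)
    stop("need at least 2 subjects per sex", call. = FALSE)
  if (spec$variance_ratio <= 0)
    stop("'variance_ratio' must be positive", call. = FALSE)
  if (spec$noise_sd <= 0)
    stop("'noise_sd' must be positive", call. = FALSE)
  if (any(!is.finite(spec$betas)))
    stop("true effect sizes must be finite", call. = FALSE)
  if (abs(spec$ttv_sex_shift) >= 2)
    stop("'ttv_sex_shift' beyond +/-2 standardized units is infeasible",
         call. = FALSE)
  invisible(spec)
}

# Variance bookkeeping: a region's volume is
#   V = base * (TTV / mean TTV) + s * eta,
#   eta = beta*male + age_slope*age_z + qc_slope*qc_z + strain shift
#         + batch offset + batch_scale * vr(sex) * noise_sd * e .
# Var(V) = A + B*s + C*s^2 with A the TTV-path variance, B twice the
# TTV-sex covariance path, C = Var(eta). Solving Var(V) = s^2 for s makes
# the standardized sex effect on z-scored V equal the planted beta.
#' @keywords internal
#' @noRd
solve_volume_scale <- function(beta, A, B_unit, C_rest, v_male) {
  C <- C_rest + beta^2 * v_male
  if (C >= 1)
    stop("infeasible spec: planted effects and noise imply a variance ",
         "budget >= 1; reduce 'noise_sd', slopes, or effect sizes",
         call. = FALSE)
  B <- B_unit * beta
  (B + sqrt(B^2 + 4 * (1 - C) * A)) / (2 * (1 - C))
}

#' Simulate a single-species cohort
#'
#' Generates a subject table realizing the spec: sex, age uniform over the
#' range, TTV normal with the planted standardized sex shift, round-robin
#' batch assignment with additive offsets and multiplicative noise scales,
#' a QC covariate (Euler numbers or background strain), optional sibling
#' pairs, and one `vol_` column per region combining TTV-proportional
#' allometry, the planted sex effect, age and QC slopes, batch structure,
#' and per-sex scaled noise. Fully deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return Subject table (data frame); the true effect sizes and volume
#'   scales are attached as attributes `truth` and `volume_scale`.
#' @examples
#' tab <- simulate_cohort(cohort_spec("mouse", n_female = 20, n_male = 20,
#'                                    betas = c(a = 0.5, b = 0), seed = 7))
#' head(tab)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  human <- spec$species == "human"
  n <- spec$n_female + spec$n_male
  sex <- factor(rep(c("F", "M"), c(spec$n_female, spec$n_male)),
                levels = c("F", "M"))
  male <- as.numeric(sex == "M")
  p_m <- mean(male)
  v_male <- p_m * (1 - p_m)

  with_seed(spec$seed, {
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    age_z <- (age - mean(age)) / stats::sd(age)

    delta_ttv <- spec$ttv_sex_shift * spec$ttv_sd /
      sqrt(1 - spec$ttv_sex_shift^2 * v_male)
    ttv <- spec$ttv_mean + spec$ttv_sd * stats::rnorm(n) + delta_ttv * male

    batch <- factor(paste0("batch", rep_len(seq_len(spec$n_batches), n)))
    offsets <- stats::rnorm(spec$n_batches, 0, spec$batch_offset_sd)
    scales <- if (spec$n_batches > 1L)
      stats::runif(spec$n_batches, spec$batch_scale_range[1],
                   spec$batch_scale_range[2]) else 1
    b_off <- offsets[as.integer(batch)]
    b_scale <- scales[as.integer(batch)]

    if (human) {
      qc <- pmin(0, round(stats::rnorm(n, -55, 45)))
      qc_z <- (qc - mean(qc)) / stats::sd(qc)
      strain_term <- 0
      var_strain <- 0
    } else {
      # strain follows the acquisition cohort, 2/3 J : 1/3 N
      strain_of_batch <- ifelse(seq_len(spec$n_batches) <=
                                  ceiling(2 * spec$n_batches / 3),
                                "C57BL6J", "C57BL6N")
      qc <- strain_of_batch[as.integer(batch)]
      qc_z <- 0
      is_n <- as.numeric(qc == "C57BL6N")
      p_n <- mean(is_n)
      strain_term <- spec$strain_offset * is_n
      var_strain <- spec$strain_offset^2 * p_n * (1 - p_n)
    }

    vr <- ifelse(male == 1, spec$variance_ratio, 1)
    mean_vr2 <- p_m * spec$variance_ratio^2 + (1 - p_m)
    mean_scale2 <- if (spec$n_batches > 1L) {
      lo <- spec$batch_scale_range[1]; hi <- spec$batch_scale_range[2]
      (lo^2 + lo * hi + hi^2) / 3
    } else 1

    base <- spec$baseline_frac * spec$ttv_mean
    A <- (base / spec$ttv_mean)^2 * (spec$ttv_sd^2 + delta_ttv^2 * v_male)
    B_unit <- 2 * (base / spec$ttv_mean) * delta_ttv * v_male
    C_rest <- spec$age_slope^2 + (if (human) spec$qc_slope^2 else 0) +
      var_strain + spec$batch_offset_sd^2 +
      spec$noise_sd^2 * mean_vr2 * mean_scale2

    regions <- names(spec$betas)
    vols <- matrix(NA_real_, n, length(regions),
                   dimnames = list(NULL, paste0("vol_", regions)))
    scale_used <- stats::setNames(numeric(length(regions)), regions)
    for (j in seq_along(regions)) {
      beta <- spec$betas[j]
      s <- solve_volume_scale(beta, A, B_unit, C_rest, v_male)
      e <- if (spec$heavy_tails)
        stats::rt(n, df = 3) / sqrt(3) else stats::rnorm(n)
      eta <- beta * male + spec$age_slope * age_z +
        (if (human) spec$qc_slope * qc_z else 0) + strain_term + b_off +
        b_scale * vr * spec$noise_sd * e
      vols[, j] <- base * (ttv / spec$ttv_mean) + s * eta
      scale_used[j] <- s
    }

    out <- data.frame(subject_id = sprintf("%s_%04d", spec$species,
                                           seq_len(n)),
                      sex = sex, age = age, ttv = ttv,
                      batch = batch, stringsAsFactors = FALSE)
    if (human) {
      out$euler <- qc
      n_twin_fam <- floor(spec$twin_fraction * n / 2)
      fam <- c(rep(seq_len(n_twin_fam), each = 2),
               n_twin_fam + seq_len(n - 2 * n_twin_fam))
      out$family_id <- sprintf("fam_%04d", sample(fam))
    } else {
      out$strain <- qc
    }
    out <- cbind(out, as.data.frame(vols, check.names = FALSE))
    attr(out, "truth") <- spec$betas
    attr(out, "volume_scale") <- scale_used
    attr(out, "spec") <- spec
    out
  })
}

#' Paired expression simulation settings
#'
#' @param rho Named vector of true per-region cross-species congruence
#'   values in \[-1, 1\] (names = region keys). Default: 0.3 for every
#'   expression-bearing region of the built-in map.
#' @param n_genes Number of homologous genes (>= 10), default 2835.
#' @param shared_sd SD of the latent shared and independent profiles.
#' @param noise_sd SD of additive measurement noise (attenuates the
#'   realized correlation by `shared_sd^2 / (shared_sd^2 + noise_sd^2)`).
#' @param seed Integer seed.
#' @return A list of class `expression_pair_spec`.
#' @export
expression_pair_spec <- function(rho = NULL, n_genes = 2835,
                                 shared_sd = 1, noise_sd = 0.1, seed = 1) {
  if (is.null(rho)) {
    map <- load_homologous_regions()
    keys <- if ("expression_available" %in% names(map))
      map$key[map$expression_available] else map$key
    rho <- stats::setNames(rep(0.3, length(keys)), keys)
  }
  if (any(abs(rho) > 1))
    stop("congruence values must lie in [-1, 1]", call. = FALSE)
  if (n_genes < 10L)
    stop("'n_genes' must be at least 10", call. = FALSE)
  structure(list(rho = rho, n_genes = n_genes, shared_sd = shared_sd,
                 noise_sd = noise_sd, seed = seed),
            class = "expression_pair_spec")
}

#' Simulate a paired region-by-gene expression data set
#'
#' For each region a latent gene profile is shared between species:
#' `human = sqrt(|rho|) * latent + sqrt(1 - |rho|) * independent + noise`
#' (and likewise for the mouse, with `sign(rho)` applied to the latent
#' part), so the expected cross-species per-region correlation is
#' approximately `rho`. Gene symbols follow species casing conventions
#' (human upper case, mouse title case); the returned homolog map pairs
#' them one-to-one.
#'
#' @param spec An [expression_pair_spec()].
#' @return List with `human` and `mouse` (`region_gene_matrix`, not yet
#'   z-scored) and `map` (homologous-gene pairs).
#' @export
simulate_expression_pair <- function(spec) {
  stopifnot(inherits(spec, "expression_pair_spec"))
  g <- spec$n_genes
  human_genes <- toupper(sprintf("GENE%04d", seq_len(g)))
  mouse_genes <- sprintf("Gene%04d", seq_len(g))
  keys <- names(spec$rho)
  with_seed(spec$seed, {
    h <- matrix(NA_real_, length(keys), g, dimnames = list(keys, human_genes))
    m <- matrix(NA_real_, length(keys), g, dimnames = list(keys, mouse_genes))
    for (i in seq_along(keys)) {
      rho <- spec$rho[i]
      latent <- stats::rnorm(g, sd = spec$shared_sd)
      h[i, ] <- sqrt(abs(rho)) * latent +
        sqrt(1 - abs(rho)) * stats::rnorm(g, sd = spec$shared_sd) +
        stats::rnorm(g, sd = spec$noise_sd)
      m[i, ] <- sign(rho) * sqrt(abs(rho)) * latent +
        sqrt(1 - abs(rho)) * stats::rnorm(g, sd = spec$shared_sd) +
        stats::rnorm(g, sd = spec$noise_sd)
    }
    list(human = new_region_gene_matrix(h, "human"),
         mouse = new_region_gene_matrix(m, "mouse"),
         map = data.frame(human = human_genes, mouse = mouse_genes,
                          stringsAsFactors = FALSE))
  })
}

#' Parameter-recovery report
#'
#' Per-parameter bias and root-mean-square error of pipeline estimates
#' against the generating truth.
#'
#' @param truth Named numeric vector of true parameter values.
#' @param estimates Data frame with columns `parameter` and `estimate`
#'   (multiple rows per parameter = replicates), or a named numeric vector.
#' @param path Optional TSV path to write the report to.
#' @return Data frame with columns `parameter`, `truth`, `n_estimates`,
#'   `bias`, `rmse`.
#' @export
recovery_report <- function(truth, estimates, path = NULL) {
  if (is.numeric(estimates) && !is.null(names(estimates)))
    estimates <- data.frame(parameter = names(estimates),
                            estimate = unname(estimates),
                            stringsAsFactors = FALSE)
  if (!all(c("parameter", "estimate") %in% names(estimates)))
    stop("'estimates' needs 'parameter' and 'estimate' columns",
         call. = FALSE)
  extra <- setdiff(unique(estimates$parameter), names(truth))
  if (length(extra) > 0)
    stop("estimate(s) with no matching truth: ",
         paste(extra, collapse = ", "), call. = FALSE)
  params <- names(truth)
  rows <- lapply(params, function(pm) {
    est <- estimates$estimate[estimates$parameter == pm]
    if (length(est) == 0L)
      stop("no estimates for parameter '", pm, "'", call. = FALSE)
    data.frame(parameter = pm, truth = truth[[pm]],
               n_estimates = length(est),
               bias = mean(est) - truth[[pm]],
               rmse = sqrt(mean((est - truth[[pm]])^2)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
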