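#' Align per-species sex effects on the homologous-region map
#'
#' Joins human and mouse standardized sex-effect results into one row per
#' homologous region. Each map row is matched in a species' results by its
#' canonical key (`"<region> (<hemisphere>)"`, see [region_key()]), by the
#' bare region name for midline regions, or by any of the species-specific
#' atlas labels listed in the map. Regions that cannot be resolved in both
#' species are reported together in a single error.
#'
#' @param human,mouse `sex_effects` data frames (or any data frame with
#'   columns `region`, `beta_sex`, `significant`).
#' @param map A `homologous_region_map` from [load_homologous_regions()].
#' @return An `effect_size_pair_table`, one row per map region.
#' @export
align_homologs <- function(human, mouse, map = load_homologous_regions()) {
  match_one <- function(results, key, region, labels) {
    # tiered: exact key, then bare region name, then atlas labels
    tiers <- list(key, region, strsplit(labels, ";", fixed = TRUE)[[1]])
    for (candidates in tiers) {
      hit <- which(results$region %in% candidates)
      if (length(hit) == 1L) return(hit)
      if (length(hit) > 1L)
        stop("ambiguous match for region '", key, "'", call. = FALSE)
    }
    NA_integer_
  }
  hi <- mapply(match_one, key = map$key, region = map$region,
               labels = map$human_labels, MoreArgs = list(results = human))
  mi <- mapply(match_one, key = map$key, region = map$region,
               labels = map$mouse_labels, MoreArgs = list(results = mouse))
  missing_h <- map$key[is.na(hi)]
  missing_m <- map$key[is.na(mi)]
  if (length(missing_h) > 0 || length(missing_m) > 0)
    stop("unresolvable homologous region(s) - ",
         if (length(missing_h)) paste0("human: ",
                                       paste(missing_h, collapse = ", "), "; "),
         if (length(missing_m)) paste0("mouse: ",
                                       paste(missing_m, collapse = ", ")),
         call. = FALSE)
  as_pair_table(data.frame(
    region = map$region,
    hemisphere = map$hemisphere,
    compartment = map$compartment,
    key = map$key,
    human_beta = human$beta_sex[hi],
    mouse_beta = mouse$beta_sex[mi],
    human_sig = human$significant[hi],
    mouse_sig = mouse$significant[mi],
    stringsAsFactors = FALSE))
}

#' Cross-species correlation of regional sex effects
#'
#' Percentage-bend robust correlation between the human and mouse
#' standardized sex-effect sizes across homologous regions, optionally
#' restricted to one brain compartment.
#'
#' @param pairs An `effect_size_pair_table`.
#' @param compartment `"all"`, `"cortical"`, or `"non_cortical"`.
#' @param bend_constant Bending proportion, default 0.2.
#' @return A `cor_result`.
#' @examples
#' cross_species_effect_correlation(builtin_pair_table())
#' @export
cross_species_effect_correlation <- function(pairs, compartment = "all",
                                             bend_constant = 0.2) {
  sub <- filter_compartment(pairs, compartment)
  if (nrow(sub) < 4L)
    stop("insufficient data: fewer than 4 regions after filtering",
         call. = FALSE)
  percentage_bend_correlation(sub$human_beta, sub$mouse_beta, bend_constant)
}

#' Anatomical sex-effect similarity scores
#'
#' Per homologous region, the product of the human and mouse standardized
#' sex-effect sizes. The product is positive when the two species agree in
#' the direction of sex bias (congruent) and negative when they disagree,
#' and its magnitude grows with the size of both effects.
#'
#' @param pairs An `effect_size_pair_table`.
#' @return A data frame of class `similarity_scores` with columns `region`,
#'   `hemisphere`, `compartment`, `key`, `anatomical`, and a
#'   `transcriptional` column of `NA` placeholders to be filled by
#'   [transcriptional_similarity()].
#' @export
anatomical_similarity_scores <- function(pairs) {
  out <- data.frame(
    region = pairs$region,
    hemisphere = pairs$hemisphere,
    compartment = pairs$compartment,
    key = pairs$key,
    anatomical = pairs$human_beta * pairs$mouse_beta,
    transcriptional = NA_real_,
    stringsAsFactors = FALSE)
  class(out) <- c("similarity_scores", "data.frame")
  out
}

#' Quadrant classification of paired sex effects
#'
#' Labels each homologous region by the sign pair of its two effect sizes -
#' the quadrants of the human-vs-mouse effect-size scatter: `both_male`
#' (+, +), `both_female` (-, -), `human_male_mouse_female` (+, -),
#' `human_female_mouse_male` (-, +), or `indeterminate` when either beta is
#' exactly zero. A second facet records where the effect reaches
#' significance: `both`, `human_only`, `mouse_only`, or `neither`.
#'
#' @param pairs An `effect_size_pair_table`.
#' @return A data frame with columns `region`, `hemisphere`, `key`,
#'   `quadrant`, `significance`.
#' @export
quadrant_classification <- function(pairs) {
  sh <- sign(pairs$human_beta)
  sm <- sign(pairs$mouse_beta)
  quadrant <- ifelse(sh == 0 | sm == 0, "indeterminate",
              ifelse(sh > 0 & sm > 0, "both_male",
              ifelse(sh < 0 & sm < 0, "both_female",
              ifelse(sh > 0, "human_male_mouse_female",
                     "human_female_mouse_male"))))
  significance <- ifelse(pairs$human_sig & pairs$mouse_sig, "both",
                  ifelse(pairs$human_sig, "human_only",
                  ifelse(pairs$mouse_sig, "mouse_only", "neither")))
  data.frame(region = pairs$region, hemisphere = pairs$hemisphere,
             key = pairs$key, quadrant = quadrant,
             significance = significance, stringsAsFactors = FALSE)
}

#' Scatter plot of paired sex effects
#'
#' Human (x) versus mouse (y) standardized sex effects with quadrant
#' shading: upper-right = male-biased in both species, lower-left =
#' female-biased in both, off-diagonal quadrants = incongruent.
#'
#' @param x An `effect_size_pair_table`.
#' @param ... Further arguments to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.effect_size_pair_table <- function(x, ...) {
  col <- ifelse(x$compartment == "cortical", "#1b9e77", "#7570b3")
  graphics::plot(x$human_beta, x$mouse_beta, pch = 19, col = col,
                 xlab = "human standardized sex effect",
                 ylab = "mouse standardized sex effect", ...)
  graphics::abline(h = 0, v = 0, lty = 2, col = "grey50")
  graphics::legend("topleft", legend = c("cortical", "non-cortical"),
                   col = c("#1b9e77", "#7570b3"), pch = 19, bty = "n")
  invisible(x)
}
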