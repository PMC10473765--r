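#' Load a homologous-region map
#'
#' Reads a tab-separated region map describing brain regions with an
#' established human-mouse homology. Required columns: `region`,
#' `hemisphere` (one of `left`, `right`, `midline`), `compartment`
#' (`cortical` or `non_cortical`), `human_labels`, `mouse_labels` (atlas
#' label names, `;`-joined within a cell). Optional columns (for example
#' effect sizes, significance flags, `expression_available`) are carried
#' through untouched.
#'
#' @param path Path to a TSV file; defaults to the bundled 60-region map
#'   (28 bilateral regions plus 4 midline regions).
#' @return A data frame of class `homologous_region_map`, one row per
#'   (region, hemisphere), with a `key` column uniquely identifying rows.
#' @export
load_homologous_regions <- function(path = default_region_map_path()) {
  if (!file.exists(path))
    stop("region map file not found: ", path, call. = FALSE)
  map <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE, quote = "")
  required <- c("region", "hemisphere", "compartment",
                "human_labels", "mouse_labels")
  missing_cols <- setdiff(required, names(map))
  if (length(missing_cols) > 0)
    stop("region map is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad_hemi <- setdiff(unique(map$hemisphere), c("left", "right", "midline"))
  if (length(bad_hemi) > 0)
    stop("unknown hemisphere value(s): ", paste(bad_hemi, collapse = ", "),
         call. = FALSE)
  bad_comp <- setdiff(unique(map$compartment), c("cortical", "non_cortical"))
  if (length(bad_comp) > 0)
    stop("unknown compartment value(s): ", paste(bad_comp, collapse = ", "),
         call. = FALSE)
  key <- region_key(map$region, map$hemisphere)
  dup <- key[duplicated(key)]
  if (length(dup) > 0)
    stop("duplicate (region, hemisphere) entries: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  map$key <- key
  class(map) <- c("homologous_region_map", "data.frame")
  map
}

#' @keywords internal
#' @noRd
default_region_map_path <- function() {
  system.file("extdata", "homologous_regions.tsv", package = "sexcongr",
              mustWork = TRUE)
}

#' Canonical region key
#'
#' Builds the `"<region> (<hemisphere>)"` identifier used to key rows of
#' pair tables, similarity scores, and expression matrices. Midline regions
#' are keyed by name alone.
#'
#' @param region Character vector of region names.
#' @param hemisphere Character vector: `left`, `right`, or `midline`.
#' @return Character vector of keys.
#' @export
region_key <- function(region, hemisphere) {
  ifelse(hemisphere == "midline", region,
         paste0(region, " (", hemisphere, ")"))
}

#' @export
print.homologous_region_map <- function(x, ...) {
  cat(sprintf("Homologous region map: %d regions (%d bilateral pairs, %d midline)\n",
              nrow(x), sum(x$hemisphere != "midline") %/% 2L,
              sum(x$hemisphere == "midline")))
  cat(sprintf("  cortical: %d, non-cortical: %d\n",
              sum(x$compartment == "cortical"),
              sum(x$compartment == "non_cortical")))
  invisible(x)
}

#' Built-in table of published paired effect sizes
#'
#' Returns the bundled table of standardized sex-effect sizes for volumetric
#' sex differences in 60 homologous brain regions (28 bilateral + 4
#' midline), with one row per (region, hemisphere): the human and mouse
#' standardized betas (positive = male-biased), per-species FDR-significance
#' flags, and compartment labels. Values are stored exactly as printed
#' (3 decimals).
#'
#' @return A data frame of class `effect_size_pair_table` with columns
#'   `region`, `hemisphere`, `compartment`, `key`, `human_beta`,
#'   `mouse_beta`, `human_sig`, `mouse_sig`.
#' @examples
#' tab <- builtin_pair_table()
#' nrow(tab)  # 60
#' @export
builtin_pair_table <- function() {
  map <- load_homologous_regions()
  as_pair_table(map[, c("region", "hemisphere", "compartment", "key",
                        "human_beta", "mouse_beta",
                        "human_sig", "mouse_sig")])
}

#' @keywords internal
#' @noRd
as_pair_table <- function(df) {
  required <- c("region", "hemisphere", "compartment", "key",
                "human_beta", "mouse_beta", "human_sig", "mouse_sig")
  stopifnot(all(required %in% names(df)))
  if (any(!is.finite(df$human_beta)) || any(!is.finite(df$mouse_beta)))
    stop("pair table contains non-finite effect sizes", call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("effect_size_pair_table", "data.frame")
  df
}

#' @export
print.effect_size_pair_table <- function(x, ...) {
  cat(sprintf("Paired sex-effect sizes: %d homologous regions\n", nrow(x)))
  cat(sprintf("  significant in both species: %d; congruent sign: %d\n",
              sum(x$human_sig & x$mouse_sig),
              sum(sign(x$human_beta) == sign(x$mouse_beta))))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ... and", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Filter a pair table by brain compartment
#'
#' @param table An `effect_size_pair_table` (or any data frame with a
#'   `compartment` column).
#' @param compartment `"cortical"`, `"non_cortical"`, or `"all"` (identity).
#' @return The filtered table, same class as the input.
#' @export
filter_compartment <- function(table, compartment = "all") {
  if (!compartment %in% c("cortical", "non_cortical", "all"))
    stop("unknown compartment: ", compartment,
         " (expected 'cortical', 'non_cortical', or 'all')", call. = FALSE)
  if (compartment == "all") return(table)
  out <- table[table$compartment == compartment, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a pair table
#'
#' Plain TSV round-trip for [builtin_pair_table()]-shaped tables; effect
#' sizes survive bit-identically (written with full precision).
#'
#' @param table An `effect_size_pair_table`.
#' @param path Output (or input) TSV path.
#' @return `write_pair_table()` returns `path` invisibly;
#'   `read_pair_table()` returns an `effect_size_pair_table`.
#' @export
write_pair_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_table
#' @export
read_pair_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "")
  as_pair_table(df)
}
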