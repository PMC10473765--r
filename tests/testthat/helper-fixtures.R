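# Small in-code fixtures shared across test files.

# Minimal valid region-map data frame, written to a temp TSV.
write_toy_map <- function(rows, path = tempfile(fileext = ".tsv")) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_map_rows <- function() {
  data.frame(
    region = c("Alpha", "Alpha", "Beta"),
    hemisphere = c("left", "right", "midline"),
    compartment = c("cortical", "cortical", "non_cortical"),
    human_labels = c("A1;A2", "A1;A2", "B"),
    mouse_labels = c("Am", "Am", "Bm"),
    stringsAsFactors = FALSE)
}

# A tiny deterministic subject table with hand-enterable numbers.
toy_subject_table <- function() {
  data.frame(
    subject_id = paste0("s", 1:6),
    sex = factor(c("F", "F", "F", "M", "M", "M"), levels = c("F", "M")),
    age = c(24, 26, 30, 25, 27, 31),
    ttv = c(1100, 1180, 1210, 1250, 1330, 1340),
    euler = c(-10, -25, -30, -80, -50, -5),
    vol_r1 = c(10, 12, 14, 15, 17, 19),
    stringsAsFactors = FALSE)
}

# Paired z-scored expression matrices with identical profiles.
toy_zscored_pair <- function(n_regions = 6, n_genes = 8, seed = 42) {
  set.seed(seed)
  vals <- matrix(rnorm(n_regions * n_genes), n_regions, n_genes,
                 dimnames = list(paste0("reg", seq_len(n_regions)),
                                 sprintf("G%02d", seq_len(n_genes))))
  vals <- scale(vals)
  h <- sexcongr:::new_region_gene_matrix(`attributes<-`(vals,
         attributes(vals)[c("dim", "dimnames")]), "human", zscored = TRUE)
  m <- sexcongr:::new_region_gene_matrix(unclass(h), "mouse", zscored = TRUE)
  list(human = h, mouse = m)
}
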