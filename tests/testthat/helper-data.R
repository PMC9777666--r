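# Shared fixture builders used across the test files.

# Tiny replicate-level table: two compounds, one sample, two replicates.
tiny_compound_table <- function() {
  compound_table(data.frame(
    sample = "M-C-JH",
    replicate = rep(1:2, 2),
    compound = rep(c("Glu", "Arg"), each = 2),
    value = c(6, 8, 100, 100)))
}

# Per-sample mean concentration of one compound, in study sample order.
compound_means <- function(summary, compound) {
  idx <- match(paste(crab_samples(), compound),
               paste(summary$sample, summary$compound))
  stats::setNames(summary$mean[idx], crab_samples())
}

# Sample x variable matrix of mean concentrations for one compound class.
compound_matrix <- function(summary, class) {
  voc <- compound_vocabulary()
  comps <- voc$compound[voc$class == class]
  m <- sapply(comps, function(cp) compound_means(summary, cp))
  rownames(m) <- crab_samples()
  m
}

# Printed per-sample value of one summary row (UFAA/SFAA/BFAA/FAA/EUC).
printed_row <- function(row) {
  df <- load_crab_printed_sums()
  sub <- df[df$row == row, ]
  stats::setNames(sub$mean, sub$sample)[crab_samples()]
}
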