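#!/usr/bin/env Rscript
# Univariate comparison of the seven taxa per modality: Gaussian feature
# tables sampled from the per-taxon descriptor book, then per-descriptor
# one-way ANOVA + Tukey HSD compact-letter tables (the layout of the study's
# descriptor tables: mean +- SD with grouping letters per column).

suppressMessages(library(pollenmorph))

out_dir <- file.path("results", "univariate")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

seed <- 20260930L
n_per_taxon <- 300L

for (modality in c("BF", "DF", "Ph")) {
  tab <- sample_feature_table(n_per_taxon, modality,
                              seed = derive_seed(seed, modality))
  letters_tab <- do.call(rbind, lapply(descriptor_names(), function(d) {
    s <- tukey_letters(tab, d)$summary
    s$descriptor <- d
    s
  }))
  path <- file.path(out_dir, sprintf("tukey_letters_%s.csv", modality))
  write.csv(letters_tab, path, row.names = FALSE)
  n_groups <- vapply(split(letters_tab, letters_tab$descriptor),
                     function(s) length(unique(s$letters)), 1L)
  message(sprintf(
    "%s: %d descriptors; distinct letter groups per descriptor: median %.0f, max %d (%s)",
    modality, length(n_groups), median(n_groups), max(n_groups),
    names(n_groups)[which.max(n_groups)]))
}
message("wrote ", out_dir)
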