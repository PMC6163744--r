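#!/usr/bin/env Rscript
# Build the synthetic study corpus: ~3900 posts from simulated Spanish
# rare-disease groups over one year, plus a reference priority document.
# All later analysis scripts read these files, so the whole workflow is a
# deterministic function of the generator seed.

suppressPackageStartupMessages(library(postmine))

cfg <- generator_config(seed = 20180830)
posts <- generate_posts(cfg)
doc <- generate_reference_document(cfg)

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
write_posts(posts, "results/data/posts.tsv")
writeLines(doc, "results/data/reference.txt")

cat(sprintf("generated %d posts across %d post types\n",
            nrow(posts), length(unique(posts$post_type))))
cat(sprintf("date range: %s .. %s (%s)\n",
            min(posts$created), max(posts$created),
            lubridate::tz(posts$created)))
cat(sprintf("reference document: %d tokens\n",
            length(tokenize(doc))))
cat("written: results/data/posts.tsv, results/data/reference.txt\n")
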