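#!/usr/bin/env Rscript
# First-look characterization of the post corpus: per-type interaction
# means/spreads and the engagement summary. Mirrors the standard
# "describe the dataset" table of a social-media engagement study.

suppressPackageStartupMessages(library(postmine))

posts <- read_posts("results/data/posts.tsv")
tbl <- characterize(posts)
readr::write_csv(tbl, "results/characterization.csv")

types <- tbl[tbl$post_type != "total", ]
cat("per-type engagement means:\n")
print(as.data.frame(types[c("post_type", "n", "engagement_mean")]),
      row.names = FALSE, digits = 3)
cat(sprintf("\nhighest mean engagement: %s posts (%.1f)\n",
            types$post_type[which.max(types$engagement_mean)],
            max(types$engagement_mean)))
cat(sprintf("highest mean comments:  %s posts (%.1f)\n",
            types$post_type[which.max(types$comments_mean)],
            max(types$comments_mean)))
cat("engagement mean equals comments + shares + reactions means on every row:",
    all(abs(tbl$engagement_mean -
              (tbl$comments_mean + tbl$shares_mean + tbl$reactions_mean)) < 1e-9),
    "\n")
cat("written: results/characterization.csv\n")
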